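#' Declare an atom selection
#'
#' A selection names a chain, one or more inclusive residue-number ranges, and
#' optionally an atom-name filter (e.g. backbone `c("N","CA","C","O")`, or
#' `"CA"` only). Residue numbering is the author numbering carried in the PDB
#' `res_seq` field, 1-based, ranges inclusive at both ends.
#'
#' @param chain chain identifier (single character string).
#' @param res_ranges residue ranges: a length-2 vector `c(start, end)`, a list
#'   of such vectors, or a 2-column matrix with one range per row.
#' @param atom_names optional character vector of atom names to keep (applied
#'   after the residue filter).
#' @return An object of class `trj_selection`.
#' @export
select_atoms <- function(chain, res_ranges, atom_names = NULL) {
  if (length(chain) != 1 || !nzchar(chain)) stop("chain must be a single non-empty string")
  if (is.numeric(res_ranges) && length(res_ranges) == 2) {
    res_ranges <- list(res_ranges)
  }
  if (is.matrix(res_ranges)) {
    res_ranges <- lapply(seq_len(nrow(res_ranges)), function(i) res_ranges[i, ])
  }
  if (!is.list(res_ranges) || length(res_ranges) == 0) {
    stop("res_ranges must be one or more (start, end) pairs")
  }
  res_ranges <- lapply(res_ranges, function(r) {
    r <- as.integer(r)
    if (length(r) != 2 || any(is.na(r)) || r[2] < r[1]) {
      stop("each residue range must be an inclusive (start, end) pair with start <= end")
    }
    r
  })
  structure(list(chain = as.character(chain), res_ranges = res_ranges,
                 atom_names = atom_names),
            class = "trj_selection")
}

selection_residues <- function(sel) {
  sort(unique(unlist(lapply(sel$res_ranges, function(r) seq(r[1], r[2])))))
}

#' Resolve a selection to atom indices
#'
#' Returns atom indices in topology order. Every residue requested by the
#' selection must exist in the structure; missing residues raise an error
#' listing them (they are never silently dropped). The atom-name filter is
#' applied after the residue filter; resolution is deterministic and
#' idempotent.
#'
#' @param sel a `trj_selection`.
#' @param s a `trj_structure`.
#' @return integer vector of atom indices into the structure's atom table.
#' @export
resolve_selection <- function(sel, s) {
  stopifnot(inherits(sel, "trj_selection"), inherits(s, "trj_structure"))
  at <- s$atoms
  if (!sel$chain %in% at$chain) {
    stop(sprintf("chain '%s' not present in structure", sel$chain))
  }
  wanted <- selection_residues(sel)
  have <- unique(at$res_seq[at$chain == sel$chain])
  missing <- setdiff(wanted, have)
  if (length(missing) > 0) {
    stop(sprintf("unresolved selection: chain '%s' is missing residues %s",
                 sel$chain, format_ranges(missing)))
  }
  idx <- which(at$chain == sel$chain & at$res_seq %in% wanted)
  if (!is.null(sel$atom_names)) {
    idx <- idx[at$atom_name[idx] %in% sel$atom_names]
  }
  if (length(idx) == 0) {
    stop("selection resolves to zero atoms after the atom-name filter")
  }
  idx
}

# "841-855, 900" style compaction of an integer vector for error messages.
format_ranges <- function(v) {
  v <- sort(unique(v))
  brk <- c(0, which(diff(v) != 1), length(v))
  parts <- vapply(seq_len(length(brk) - 1), function(i) {
    seg <- v[(brk[i] + 1):brk[i + 1]]
    if (length(seg) == 1) as.character(seg) else paste0(seg[1], "-", seg[length(seg)])
  }, character(1))
  paste(parts, collapse = ", ")
}

#' @export
print.trj_selection <- function(x, ...) {
  rng <- paste(vapply(x$res_ranges, function(r) paste0(r[1], "-", r[2]), character(1)),
               collapse = ", ")
  cat(sprintf("<trj_selection> chain %s, residues %s%s\n", x$chain, rng,
              if (is.null(x$atom_names)) "" else
                paste0(", atoms [", paste(x$atom_names, collapse = " "), "]")))
  invisible(x)
}
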