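# Fixed-column PDB reading/writing, including multi-model trajectory files.
# Column layout follows the wwPDB format description for ATOM/HETATM records:
#   13-16 atom name, 17 altLoc, 18-20 resName, 22 chainID, 23-26 resSeq,
#   27 iCode, 31-54 x/y/z (8.3f each), 77-78 element.

parse_atom_lines <- function(lines, line_numbers) {
  short <- nchar(lines) < 54
  if (any(short)) {
    stop(sprintf("parse error at line %d: ATOM/HETATM record shorter than 54 columns",
                 line_numbers[which(short)[1]]))
  }
  altloc <- substr(lines, 17, 17)
  bad <- !(altloc %in% c(" ", "A"))
  if (any(bad)) {
    stop(sprintf("parse error at line %d: alternate location '%s' not supported (only blank or 'A')",
                 line_numbers[which(bad)[1]], altloc[which(bad)[1]]))
  }
  icode <- substr(lines, 27, 27)
  bad <- icode != " "
  if (any(bad)) {
    stop(sprintf("parse error at line %d: insertion codes are not supported",
                 line_numbers[which(bad)[1]]))
  }
  num_field <- function(txt, what, cols) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- is.na(v) | !nzchar(trimws(txt))
    if (any(bad)) {
      stop(sprintf("parse error at line %d: non-numeric %s field '%s'",
                   line_numbers[which(bad)[1]], what, trimws(txt[which(bad)[1]])))
    }
    v
  }
  res_seq <- num_field(substr(lines, 23, 26), "residue number")
  x <- num_field(substr(lines, 31, 38), "x")
  y <- num_field(substr(lines, 39, 46), "y")
  z <- num_field(substr(lines, 47, 54), "z")
  element <- trimws(substr(lines, 77, 78))
  atom_name <- trimws(substr(lines, 13, 16))
  element[!nzchar(element)] <- guess_element(atom_name[!nzchar(element)])
  atoms <- data.frame(chain = substr(lines, 22, 22),
                      res_seq = as.integer(res_seq),
                      res_name = trimws(substr(lines, 18, 20)),
                      atom_name = atom_name,
                      element = element,
                      stringsAsFactors = FALSE)
  list(atoms = atoms, xyz = cbind(x = x, y = y, z = z))
}

# Splits a PDB file into models; files without MODEL records are one model.
split_models <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0) {
    idx <- which(is_atom)
    if (length(idx) == 0) stop("empty input: no ATOM/HETATM records found")
    return(list(list(lines = lines[idx], line_numbers = idx)))
  }
  model_ends <- which(startsWith(lines, "ENDMDL"))
  if (length(model_ends) < length(model_starts)) {
    model_ends <- c(model_ends, length(lines))
  }
  models <- lapply(seq_along(model_starts), function(i) {
    span <- seq(model_starts[i], model_ends[i])
    idx <- span[is_atom[span]]
    list(lines = lines[idx], line_numbers = idx)
  })
  models <- Filter(function(m) length(m$lines) > 0, models)
  if (length(models) == 0) stop("empty input: no ATOM/HETATM records found")
  models
}

#' Read a PDB file (first model)
#'
#' Parses ATOM/HETATM records of the first model of a fixed-column PDB file.
#' Insertion codes and alternate-location indicators other than blank or `'A'`
#' are rejected; malformed records raise an error naming the offending line.
#'
#' @param path path to a PDB file.
#' @return A [new_structure()] object.
#' @seealso [read_trajectory()] for multi-model files.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  m <- split_models(lines)[[1]]
  p <- parse_atom_lines(m$lines, m$line_numbers)
  new_structure(p$atoms, p$xyz)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Every MODEL block must contain the identical atom sequence (chain, residue
#' number, atom name, in the same order) as model 1; any mismatch raises a
#' topology-mismatch error naming the frame. Time is attached via `dt_ns`
#' because the PDB format carries no time axis: frame f (0-based) maps to
#' `f * dt_ns` ns.
#'
#' @param path path to a multi-model PDB file.
#' @param dt_ns time per frame in nanoseconds.
#' @param label trajectory label (defaults to the file name).
#' @return A [new_trajectory()] object.
#' @export
read_trajectory <- function(path, dt_ns, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  models <- split_models(lines)
  parsed <- lapply(models, function(m) parse_atom_lines(m$lines, m$line_numbers))
  ref <- parsed[[1]]$atoms
  ref_key <- paste(ref$chain, ref$res_seq, ref$atom_name, sep = "|")
  for (i in seq_along(parsed)) {
    a <- parsed[[i]]$atoms
    if (nrow(a) != nrow(ref)) {
      stop(sprintf("topology mismatch at frame %d: %d atoms, expected %d",
                   i, nrow(a), nrow(ref)))
    }
    key <- paste(a$chain, a$res_seq, a$atom_name, sep = "|")
    if (!identical(key, ref_key)) {
      j <- which(key != ref_key)[1]
      stop(sprintf("topology mismatch at frame %d: atom %d is '%s', expected '%s'",
                   i, j, key[j], ref_key[j]))
    }
  }
  coords <- array(0, dim = c(length(parsed), nrow(ref), 3))
  for (i in seq_along(parsed)) coords[i, , ] <- parsed[[i]]$xyz
  topo <- new_structure(ref, parsed[[1]]$xyz)
  new_trajectory(topo, coords, dt_ns = dt_ns,
                 label = label %||% sub("\\.pdb$", "", basename(path)))
}

format_atom_lines <- function(atoms, xyz) {
  name <- ifelse(nchar(atoms$atom_name) >= 4,
                 substr(atoms$atom_name, 1, 4),
                 sprintf(" %-3s", atoms$atom_name))
  sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          seq_len(nrow(atoms)) %% 100000, name, atoms$res_name, atoms$chain,
          atoms$res_seq, xyz[, 1], xyz[, 2], xyz[, 3], atoms$element)
}

#' Write a structure to a PDB file
#' @param s a `trj_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "trj_structure"))
  writeLines(c(format_atom_lines(s$atoms, s$xyz), "END"), path)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#' @param traj a `trj_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trj_trajectory"))
  at <- traj$topology$atoms
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL %8d", f), con)
    writeLines(format_atom_lines(at, traj$coords[f, , , drop = TRUE]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
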