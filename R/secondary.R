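# Helix/coil assignment from backbone hydrogen bonding, following the
# Kabsch-Sander electrostatic model: a backbone C=O (acceptor) and N-H
# (donor) group are hydrogen bonded when
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  <  -0.5 kcal/mol.
# Only the two-class alphabet {H, C} is distinguished: a residue is helical
# when the i -> i+4 bond pattern holds for two consecutive turns (the minimal
# alpha-helix rule); 3-10/pi helices and strands are lumped into C.

KS_PREFACTOR <- 0.084 * 332  # kcal/mol * Angstrom, dipole-dipole coupling

#' Kabsch-Sander hydrogen-bond energy
#'
#' Electrostatic energy of a backbone C=O ... H-N pair. A hydrogen bond is
#' conventionally declared when the energy is below -0.5 kcal/mol.
#'
#' @param C,O acceptor-group carbon and oxygen coordinates (3-vectors, A).
#' @param N,H donor-group nitrogen and amide-hydrogen coordinates.
#' @return Energy in kcal/mol.
#' @examples
#' # all four cross distances equal => E = 0 (not bonded)
#' @export
hbond_energy <- function(C, O, N, H) {
  r_ON <- vnorm(O - N); r_CH <- vnorm(C - H)
  r_OH <- vnorm(O - H); r_CN <- vnorm(C - N)
  if (min(r_ON, r_CH, r_OH, r_CN) <= 0.5) {
    stop("geometry error: coincident atoms (pairwise distance <= 0.5 A)")
  }
  KS_PREFACTOR * (1 / r_ON + 1 / r_CH - 1 / r_OH - 1 / r_CN)
}

# Amide hydrogen rebuilt 1.0 A from N, opposite the C(i-1)-N-CA bisector;
# MD-exported PDB files often lack hydrogens and this is the reconstruction
# dssp itself applies.
reconstruct_amide_h <- function(N, C_prev, CA) {
  N + unit(unit(N - C_prev) + unit(N - CA))
}

#' Per-residue, per-frame helix/coil assignment
#'
#' Assigns each selected residue in each frame one of two codes: `H`
#' (alpha-helix) or `C` (everything else). Residue i..i+4 backbone hydrogen
#' bonds are scored with [hbond_energy()] (amide H reconstructed geometrically
#' when not present in the topology); residues i+1..i+4 of two consecutive
#' bonded turns i, i+1 are labeled `H`. Chain breaks (C(i)-N(i+1) > 2.5 A) act
#' as segment boundaries.
#'
#' @param traj a `trj_trajectory`.
#' @param sel selection of residues to assign; each residue must carry
#'   backbone N, CA, C, O atoms.
#' @param energy_cutoff hydrogen-bond energy threshold in kcal/mol
#'   (default -0.5, the Kabsch-Sander convention).
#' @param stride assign every `stride`-th frame (default 1).
#' @return An object of class `ss_matrix`: `residues` (data.frame chain,
#'   res_seq), `times_ns`, and `codes` (residues x frames character matrix of
#'   `"H"`/`"C"`).
#' @export
assign_ss <- function(traj, sel, energy_cutoff = -0.5, stride = 1) {
  stopifnot(inherits(traj, "trj_trajectory"))
  at <- traj$topology$atoms
  res <- selection_residues(sel)
  chain <- sel$chain
  idx_of <- function(r, name) {
    i <- which(at$chain == chain & at$res_seq == r & at$atom_name == name)
    if (length(i) != 1) {
      stop(sprintf("residue %s/%d lacks backbone atom %s", chain, r, name))
    }
    i
  }
  iN <- vapply(res, idx_of, integer(1), name = "N")
  iCA <- vapply(res, idx_of, integer(1), name = "CA")
  iC <- vapply(res, idx_of, integer(1), name = "C")
  iO <- vapply(res, idx_of, integer(1), name = "O")
  has_h <- vapply(res, function(r)
    any(at$chain == chain & at$res_seq == r & at$atom_name == "H"), logical(1))
  iH <- rep(NA_integer_, length(res))
  iH[has_h] <- vapply(res[has_h], idx_of, integer(1), name = "H")
  # residues must be consecutively numbered to participate in a turn
  consecutive <- c(diff(res) == 1, FALSE)

  frames <- seq(1, n_frames(traj), by = stride)
  nres <- length(res)
  codes <- matrix("C", nres, length(frames))
  broke <- FALSE
  for (fi in seq_along(frames)) {
    xyz <- traj$coords[frames[fi], , , drop = TRUE]
    # per-frame chain breaks: C(i)-N(i+1) > 2.5 A
    linked <- consecutive
    if (nres > 1) {
      j <- which(consecutive[-nres])
      if (length(j) > 0) {
        dcn <- sqrt(rowSums((xyz[iC[j], , drop = FALSE] - xyz[iN[j + 1], , drop = FALSE])^2))
        far <- dcn > 2.5
        if (any(far)) {
          linked[j[far]] <- FALSE
          broke <- TRUE
        }
      }
    }
    turn <- rep(FALSE, nres)
    for (i in seq_len(nres - 4)) {
      if (!all(linked[i:(i + 3)])) next
      j <- i + 4
      H <- if (!is.na(iH[j])) xyz[iH[j], ] else
        reconstruct_amide_h(xyz[iN[j], ], xyz[iC[j - 1], ], xyz[iCA[j], ])
      e <- tryCatch(hbond_energy(xyz[iC[i], ], xyz[iO[i], ], xyz[iN[j], ], H),
                    error = function(err) 0)
      turn[i] <- e < energy_cutoff
    }
    for (i in seq_len(max(0, nres - 5))) {
      if (turn[i] && turn[i + 1]) codes[(i + 1):(i + 4), fi] <- "H"
    }
  }
  if (broke) message("assign_ss: chain break(s) detected; treated as segment boundaries")
  structure(list(residues = data.frame(chain = chain, res_seq = res,
                                       stringsAsFactors = FALSE),
                 times_ns = (frames - 1) * traj$dt_ns,
                 codes = codes),
            class = "ss_matrix")
}

#' @export
print.ss_matrix <- function(x, ...) {
  cat(sprintf("<ss_matrix> %d residues x %d frames, helix fraction %.2f\n",
              nrow(x$codes), ncol(x$codes), mean(x$codes == "H")))
  invisible(x)
}

#' Write a secondary-structure matrix as CSV
#' @param ssm an `ss_matrix`.
#' @param path output path (rows = residues, columns = frames, cells H/C).
#' @param meta optional named list written as a '#' header block.
#' @return `path`, invisibly.
#' @export
write_ss_csv <- function(ssm, path, meta = list()) {
  df <- cbind(ssm$residues, as.data.frame(ssm$codes))
  names(df)[-(1:2)] <- sprintf("t%g", ssm$times_ns)
  write_csv_with_header(df, path, meta)
}

#' Per-frame helical fraction
#'
#' Fraction of the requested residues labeled `H` in each frame; transient
#' local helix formation in a disordered segment shows up as excursions of
#' this trace above zero.
#'
#' @param ssm an `ss_matrix` from [assign_ss()].
#' @param res_seq optional residue numbers to restrict to (default: all
#'   residues of the matrix).
#' @return A [time_series()] with values in `[0, 1]`.
#' @export
helix_fraction_series <- function(ssm, res_seq = NULL) {
  stopifnot(inherits(ssm, "ss_matrix"))
  rows <- if (is.null(res_seq)) seq_len(nrow(ssm$codes)) else
    which(ssm$residues$res_seq %in% res_seq)
  if (length(rows) == 0) stop("empty residue range")
  vals <- colMeans(ssm$codes[rows, , drop = FALSE] == "H")
  time_series(ssm$times_ns, vals, label = "helix fraction", units = "fraction")
}
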