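#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD
#' between paired point sets, via SVD of the cross-covariance matrix.
#' Reflections are corrected through the sign of the smallest singular value,
#' so `det(R) = +1` always. The fitted transform maps a mobile point x to
#' `R x + t`.
#'
#' @param mobile numeric n x 3 matrix of mobile coordinates.
#' @param target numeric n x 3 matrix of target coordinates (same n >= 3).
#' @return A list of class `kabsch_fit` with elements `rotation` (3 x 3),
#'   `translation` (length 3) and `rmsd` (Angstrom).
#' @examples
#' pts <- matrix(rnorm(30), ncol = 3)
#' fit <- kabsch(pts, pts)
#' fit$rmsd  # 0
#' @export
kabsch <- function(mobile, target) {
  mobile <- as.matrix(mobile)
  target <- as.matrix(target)
  if (ncol(mobile) != 3 || ncol(target) != 3) stop("coordinate sets must be n x 3")
  if (nrow(mobile) != nrow(target)) stop("point counts differ")
  if (nrow(mobile) < 3) stop("degenerate input: need at least 3 points")
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(target, 2, ct)
  H <- crossprod(P, Q)
  sv <- svd(H)
  if (sv$d[2] <= max(sv$d[1], 1e-12) * 1e-10) {
    stop("degenerate input: points are collinear (rank-deficient cross-covariance)")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = as.numeric(ct - R %*% cm), rmsd = rmsd),
            class = "kabsch_fit")
}

#' Apply a rigid transform to coordinates
#' @param xyz numeric n x 3 coordinate matrix.
#' @param fit a `kabsch_fit`.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, fit) {
  stopifnot(inherits(fit, "kabsch_fit"))
  sweep(as.matrix(xyz) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' @export
print.kabsch_fit <- function(x, ...) {
  ang <- acos(clamp((sum(diag(x$rotation)) - 1) / 2, -1, 1)) * 180 / pi
  cat(sprintf("<kabsch_fit> rmsd = %.4f A, rotation %.2f deg, |t| = %.3f A\n",
              x$rmsd, ang, vnorm(x$translation)))
  invisible(x)
}

#' Per-frame RMSD series against a reference structure
#'
#' For every frame: superpose the frame onto the reference using the atoms of
#' `align_sel` (backbone of a rigid core, typically), then measure the RMSD
#' over `measure_sel` atoms without refitting. With `measure_sel` equal to
#' `align_sel` this is the self-aligned RMSD of the selection itself.
#'
#' @param traj a `trj_trajectory`.
#' @param align_sel selection used for the superposition fit.
#' @param ref reference `trj_structure` (defaults topology-compatible with
#'   `traj`).
#' @param measure_sel selection over which RMSD is computed (default:
#'   `align_sel`).
#' @return A [time_series()] of RMSD in Angstrom.
#' @export
rmsd_series <- function(traj, align_sel, ref, measure_sel = align_sel) {
  stopifnot(inherits(traj, "trj_trajectory"), inherits(ref, "trj_structure"))
  ai <- resolve_selection(align_sel, traj$topology)
  mi <- resolve_selection(measure_sel, traj$topology)
  ai_ref <- resolve_selection(align_sel, ref)
  mi_ref <- resolve_selection(measure_sel, ref)
  if (length(ai) != length(ai_ref) || length(mi) != length(mi_ref)) {
    stop("selection resolves to different atom counts on trajectory and reference")
  }
  nf <- n_frames(traj)
  vals <- numeric(nf)
  ref_a <- ref$xyz[ai_ref, , drop = FALSE]
  ref_m <- ref$xyz[mi_ref, , drop = FALSE]
  for (f in seq_len(nf)) {
    fit <- kabsch(traj$coords[f, ai, , drop = TRUE], ref_a)
    moved <- apply_transform(traj$coords[f, mi, , drop = TRUE], fit)
    vals[f] <- sqrt(mean(rowSums((moved - ref_m)^2)))
  }
  time_series(frame_times(traj), vals,
              label = paste0(traj$label, " rmsd"), units = "A")
}

#' Per-residue RMSF about the mean structure
#'
#' Frames are superposed on `align_sel` onto the iterated mean structure (two
#' mean/alignment passes for self-consistency, the standard fluctuation
#' definition), then `RMSF_i = sqrt(mean_f |x_i(f) - <x_i>|^2)` is reported
#' for each residue of `target_sel`, which must resolve to exactly one atom
#' per residue (conventionally the C-alpha).
#'
#' @param traj a `trj_trajectory` with at least two frames.
#' @param align_sel selection defining the alignment reference frame.
#' @param target_sel selection of one atom per residue to report.
#' @param reference `"mean"` (default, iterated mean structure) or `"frame0"`
#'   to align on the first frame only.
#' @return data.frame with columns chain, res_seq, res_name, rmsf_A.
#' @export
rmsf_per_residue <- function(traj, align_sel, target_sel, reference = c("mean", "frame0")) {
  reference <- match.arg(reference)
  stopifnot(inherits(traj, "trj_trajectory"))
  nf <- n_frames(traj)
  if (nf < 2) stop("RMSF is undefined for a single-frame trajectory")
  ai <- resolve_selection(align_sel, traj$topology)
  ti <- resolve_selection(target_sel, traj$topology)
  at <- traj$topology$atoms
  res_key <- paste(at$chain[ti], at$res_seq[ti])
  if (anyDuplicated(res_key)) {
    stop("target selection must resolve to exactly one atom per residue; ",
         "add an atom-name filter (e.g. \"CA\")")
  }
  na <- n_atoms(traj$topology)
  aligned <- array(0, dim = c(nf, na, 3))
  ref_xyz <- traj$coords[1, ai, , drop = TRUE]
  n_pass <- if (reference == "mean") 2 else 1
  for (pass in seq_len(n_pass)) {
    for (f in seq_len(nf)) {
      fit <- kabsch(traj$coords[f, ai, , drop = TRUE], ref_xyz)
      aligned[f, , ] <- apply_transform(traj$coords[f, , , drop = TRUE], fit)
    }
    if (reference == "mean") {
      ref_xyz <- apply(aligned[, ai, , drop = FALSE], c(2, 3), mean)
    }
  }
  mean_xyz <- apply(aligned[, ti, , drop = FALSE], c(2, 3), mean)
  dev2 <- vapply(seq_along(ti), function(j) {
    d <- sweep(aligned[, ti[j], , drop = TRUE], 2, mean_xyz[j, ])
    mean(rowSums(d^2))
  }, numeric(1))
  data.frame(chain = at$chain[ti], res_seq = at$res_seq[ti],
             res_name = at$res_name[ti], rmsf_A = sqrt(dev2),
             stringsAsFactors = FALSE)
}
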