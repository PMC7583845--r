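# Rigid-domain rotation/translation mapping relative to a reference structure
# after alignment on a fixed core: the coordinates of rotation/displacement
# state maps used to place conformations among crystal-structure states.

#' Align a structure on a core selection
#'
#' Superposes the mobile structure onto the reference using the C-alpha atoms
#' of `core_sel` (a Kabsch fit), then applies the fitted transform to ALL
#' atoms.
#'
#' @param mobile a `trj_structure`.
#' @param ref reference `trj_structure`.
#' @param core_sel core selection; a C-alpha filter is imposed on top of it.
#' @return The transformed `trj_structure`, with the `kabsch_fit` attached as
#'   attribute `"fit"`.
#' @export
core_align <- function(mobile, ref, core_sel) {
  stopifnot(inherits(mobile, "trj_structure"), inherits(ref, "trj_structure"))
  ca_sel <- select_atoms(core_sel$chain, core_sel$res_ranges, atom_names = "CA")
  im <- resolve_selection(ca_sel, mobile)
  ir <- resolve_selection(ca_sel, ref)
  if (length(im) != length(ir)) {
    stop("core selection resolves to different C-alpha counts on mobile and reference")
  }
  fit <- kabsch(mobile$xyz[im, , drop = FALSE], ref$xyz[ir, , drop = FALSE])
  out <- new_structure(mobile$atoms, apply_transform(mobile$xyz, fit))
  attr(out, "fit") <- fit
  out
}

# Rotation angle (deg, folded to [0, 180]) and rotation axis of a proper
# rotation matrix. The axis sign is chosen so the rotation is right-handed
# about it with a non-negative angle.
rotation_angle_axis <- function(R) {
  ang <- acos(clamp((sum(diag(R)) - 1) / 2, -1, 1))
  if (sin(ang) > 1e-8) {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(ang))
  } else if (ang < 1e-8) {
    axis <- c(0, 0, 1)  # identity: axis undefined, fixed by convention
  } else {
    # angle ~ 180 deg: axis from the symmetric part
    ev <- eigen((R + diag(3)) / 2, symmetric = TRUE)
    axis <- ev$vectors[, 1]
    nz <- which(abs(axis) > 1e-8)[1]
    if (axis[nz] < 0) axis <- -axis
  }
  list(angle_deg = ang * 180 / pi, axis = unit(axis))
}

#' Rotation and displacement of a rigid domain
#'
#' The mobile structure must already be core-aligned (see [core_align()]).
#' The domain's C-alpha atoms are Kabsch-fitted to the reference; the reported
#' rotation is `acos((trace(R) - 1) / 2)` in degrees, folded to `[0, 180]`,
#' with the corresponding right-handed unit axis. The translation is the
#' displacement of the domain centroid measured after core alignment but
#' before the domain fit (`translation = "centroid"`, the default); the
#' magnitude of the fitted transform's translation vector is available with
#' `translation = "fit_vector"`.
#'
#' @param mobile_aligned core-aligned `trj_structure`.
#' @param ref reference `trj_structure`.
#' @param domain_sel domain selection (C-alpha filter imposed; >= 3 atoms).
#' @param translation `"centroid"` or `"fit_vector"`.
#' @return list: `rotation_deg`, `axis` (unit 3-vector), `translation_A`.
#' @export
domain_rotation <- function(mobile_aligned, ref, domain_sel,
                            translation = c("centroid", "fit_vector")) {
  translation <- match.arg(translation)
  ca_sel <- select_atoms(domain_sel$chain, domain_sel$res_ranges, atom_names = "CA")
  im <- resolve_selection(ca_sel, mobile_aligned)
  ir <- resolve_selection(ca_sel, ref)
  if (length(im) < 3) stop("domain selection must contain at least 3 C-alpha atoms")
  mob <- mobile_aligned$xyz[im, , drop = FALSE]
  tgt <- ref$xyz[ir, , drop = FALSE]
  fit <- kabsch(mob, tgt)
  aa <- rotation_angle_axis(fit$rotation)
  trans <- switch(translation,
                  centroid = vnorm(colMeans(mob) - colMeans(tgt)),
                  fit_vector = vnorm(fit$translation))
  list(rotation_deg = aa$angle_deg, axis = aa$axis, translation_A = trans,
       fit_rmsd = fit$rmsd)
}

#' Rotation/displacement map over trajectories
#'
#' For each (strided) frame of each trajectory: align on the core C-alpha
#' atoms to the reference, then report rotation angle, axis and centroid
#' displacement of each labeled domain. Single structures (e.g. crystal
#' structures) can be scored by wrapping them with
#' [as_one_frame_trajectory()].
#'
#' @param trajs a `trj_trajectory` or list of them.
#' @param ref reference `trj_structure`.
#' @param core_sel fixed-core selection used for alignment.
#' @param domain_sels named list of domain selections (names become the
#'   `domain` column).
#' @param stride frame stride (default 1).
#' @param translation passed to [domain_rotation()].
#' @return Long-format data.frame: label, frame, time_ns, domain,
#'   rotation_deg, axis_x, axis_y, axis_z, translation_A.
#' @export
motion_map <- function(trajs, ref, core_sel, domain_sels, stride = 1,
                       translation = "centroid") {
  if (inherits(trajs, "trj_trajectory")) trajs <- list(trajs)
  if (is.null(names(domain_sels)) || any(!nzchar(names(domain_sels)))) {
    stop("domain_sels must be a named list")
  }
  rows <- list()
  for (tr in trajs) {
    topo <- tr$topology
    frames <- seq(1, n_frames(tr), by = stride)
    for (f in frames) {
      s <- new_structure(topo$atoms, tr$coords[f, , , drop = TRUE])
      s <- core_align(s, ref, core_sel)
      for (dn in names(domain_sels)) {
        dm <- domain_rotation(s, ref, domain_sels[[dn]], translation = translation)
        rows[[length(rows) + 1]] <- data.frame(
          label = tr$label, frame = f - 1, time_ns = (f - 1) * tr$dt_ns,
          domain = dn, rotation_deg = dm$rotation_deg,
          axis_x = dm$axis[1], axis_y = dm$axis[2], axis_z = dm$axis[3],
          translation_A = dm$translation_A, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
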