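# Protein-protein interface metrics: residue contact occupancy fractions,
# salt-bridge distance/denticity classification, and named-atom hydrogen-bond
# persistence.

#' Residue contact occupancy maps for two groups
#'
#' A residue of group A "contacts" in a frame when the minimum distance
#' between its (heavy) atoms and any (heavy) atom of group B is at most
#' `cutoff`; its occupancy fraction (OF) is the fraction of contacting frames,
#' pooled frame-weighted over all supplied trajectories. Both directions (A
#' against B, B against A) are computed from the same pair-distance matrix in
#' one pass.
#'
#' Hydrogens are excluded by default: a 3 A criterion is conventionally a
#' heavy-atom one (including hydrogens at 3 A would miss most van der Waals
#' contacts).
#'
#' @param trajs a `trj_trajectory` or list of them (identical topology).
#' @param group_a,group_b disjoint selections for the two sides.
#' @param cutoff contact distance cutoff in Angstrom (default 3.0).
#' @param heavy_only exclude hydrogens (default TRUE).
#' @return list with elements `a` and `b`, each a data.frame (chain, res_seq,
#'   res_name, OF, n_frames_total); per-trajectory tables are attached as
#'   attribute `"per_trajectory"`.
#' @export
occupancy_map <- function(trajs, group_a, group_b, cutoff = 3.0, heavy_only = TRUE) {
  if (inherits(trajs, "trj_trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1, cutoff > 0)
  topo <- trajs[[1]]$topology
  ia <- resolve_selection(group_a, topo)
  ib <- resolve_selection(group_b, topo)
  if (length(intersect(ia, ib)) > 0) stop("group_a and group_b selections overlap")
  if (heavy_only) {
    ia <- ia[topo$atoms$element[ia] != "H"]
    ib <- ib[topo$atoms$element[ib] != "H"]
    if (length(ia) == 0 || length(ib) == 0) stop("a group is empty after removing hydrogens")
  }
  at <- topo$atoms
  res_a <- factor(paste(at$chain[ia], at$res_seq[ia]),
                  levels = unique(paste(at$chain[ia], at$res_seq[ia])))
  res_b <- factor(paste(at$chain[ib], at$res_seq[ib]),
                  levels = unique(paste(at$chain[ib], at$res_seq[ib])))
  ga <- split(seq_along(ia), res_a)
  gb <- split(seq_along(ib), res_b)
  cut2 <- cutoff^2

  count_a <- numeric(length(ga))
  count_b <- numeric(length(gb))
  per_traj <- list()
  total_frames <- 0
  for (tr in trajs) {
    if (n_atoms(tr$topology) != n_atoms(topo)) {
      stop("all trajectories must share one topology")
    }
    nf <- n_frames(tr)
    ca <- numeric(length(ga))
    cb <- numeric(length(gb))
    for (f in seq_len(nf)) {
      d2 <- cross_dist2(tr$coords[f, ia, , drop = TRUE],
                        tr$coords[f, ib, , drop = TRUE])
      hit_a_atom <- matrixStats_rowMins(d2) <= cut2
      hit_b_atom <- matrixStats_rowMins(t(d2)) <= cut2
      ca <- ca + vapply(ga, function(g) any(hit_a_atom[g]), logical(1))
      cb <- cb + vapply(gb, function(g) any(hit_b_atom[g]), logical(1))
    }
    count_a <- count_a + ca
    count_b <- count_b + cb
    total_frames <- total_frames + nf
    per_traj[[tr$label]] <- list(a = ca / nf, b = cb / nf, n_frames = nf)
  }
  if (total_frames == 0) stop("empty pooled frame set")

  table_for <- function(groups, sel_idx, counts) {
    first <- vapply(groups, function(g) sel_idx[g[1]], integer(1))
    data.frame(chain = at$chain[first], res_seq = at$res_seq[first],
               res_name = at$res_name[first], OF = counts / total_frames,
               n_frames_total = total_frames, stringsAsFactors = FALSE)
  }
  out <- list(a = table_for(ga, ia, count_a), b = table_for(gb, ib, count_b))
  attr(out, "per_trajectory") <- per_traj
  attr(out, "cutoff") <- cutoff
  out
}

# rowMins without a matrixStats dependency
matrixStats_rowMins <- function(m) {
  do.call(pmin, c(as.data.frame(m), list(na.rm = FALSE)))
}

#' Residues exceeding an occupancy threshold
#'
#' Strict exceedance (`OF > threshold`), sorted by OF descending.
#'
#' @param tab an occupancy table (data.frame with an `OF` column).
#' @param threshold occupancy threshold in `[0, 1]` (default 0.75).
#' @return The filtered, sorted data.frame.
#' @export
classify_high_occupancy <- function(tab, threshold = 0.75) {
  stopifnot(is.data.frame(tab), threshold >= 0, threshold <= 1)
  out <- tab[tab$OF > threshold, , drop = FALSE]
  out[order(out$OF, decreasing = TRUE), , drop = FALSE]
}

#' Salt-bridge distance and denticity classification
#'
#' Per frame, reports the distance from a phosphorus (or other probe) atom to
#' each named partner atom, whether each pair is favorable (distance strictly
#' below `favorable_cutoff`, default 6 A), and the denticity of the
#' phosphate-guanidinium geometry: the number of distinct phosphate oxygens
#' within `denticity_cutoff` of a guanidinium nitrogen - 0 = none, 1 =
#' monodentate, >= 2 = bidentate.
#'
#' @param traj a `trj_trajectory`.
#' @param p_atom probe atom reference `c(chain, res_seq, atom_name)` (the
#'   phosphorus of a phosphoserine, typically).
#' @param partner_atoms named list of partner atom references, e.g.
#'   `list(arg_CZ = c("A", 324, "CZ"), lys_NZ = c("A", 328, "NZ"))`.
#' @param favorable_cutoff favorable-interaction distance (A), default 6.
#' @param denticity_cutoff oxygen-nitrogen pairing distance (A), default 3.5
#'   (a standard salt-bridge contact distance).
#' @param guanidinium_res residue reference `c(chain, res_seq)` carrying the
#'   guanidinium nitrogens (defaults to the residue of the first partner
#'   atom).
#' @param phosphate_oxygen_names atom names counted as phosphate oxygens.
#' @param guanidinium_nitrogen_names atom names counted as guanidinium
#'   nitrogens.
#' @return data.frame with one row per frame: frame, time_ns, one distance and
#'   one favorable column per partner, n_on_pairs, denticity.
#' @export
salt_bridge_series <- function(traj, p_atom, partner_atoms,
                               favorable_cutoff = 6.0, denticity_cutoff = 3.5,
                               guanidinium_res = NULL,
                               phosphate_oxygen_names = c("O1P", "O2P", "O3P", "OG"),
                               guanidinium_nitrogen_names = c("NH1", "NH2", "NE")) {
  stopifnot(inherits(traj, "trj_trajectory"))
  topo <- traj$topology
  find_atom <- function(ref) {
    i <- which(topo$atoms$chain == ref[1] &
                 topo$atoms$res_seq == as.integer(ref[2]) &
                 topo$atoms$atom_name == ref[3])
    if (length(i) != 1) {
      stop(sprintf("atom %s/%s/%s not found in topology", ref[1], ref[2], ref[3]))
    }
    i
  }
  ip <- find_atom(p_atom)
  ipart <- vapply(partner_atoms, find_atom, integer(1))
  if (is.null(guanidinium_res)) guanidinium_res <- partner_atoms[[1]][1:2]
  iox <- which(topo$atoms$chain == p_atom[1] &
                 topo$atoms$res_seq == as.integer(p_atom[2]) &
                 topo$atoms$atom_name %in% phosphate_oxygen_names)
  init <- which(topo$atoms$chain == guanidinium_res[1] &
                  topo$atoms$res_seq == as.integer(guanidinium_res[2]) &
                  topo$atoms$atom_name %in% guanidinium_nitrogen_names)
  nf <- n_frames(traj)
  dists <- matrix(0, nf, length(ipart))
  n_pairs <- integer(nf)
  n_ox <- integer(nf)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[f, , , drop = TRUE]
    dists[f, ] <- sqrt(colSums((t(xyz[ipart, , drop = FALSE]) - xyz[ip, ])^2))
    if (length(iox) > 0 && length(init) > 0) {
      d2 <- cross_dist2(xyz[iox, , drop = FALSE], xyz[init, , drop = FALSE])
      on <- d2 < denticity_cutoff^2
      n_pairs[f] <- sum(on)
      n_ox[f] <- sum(rowSums(on) > 0)
    }
  }
  denticity <- ifelse(n_pairs == 0, "none",
                      ifelse(n_ox >= 2, "bidentate", "monodentate"))
  out <- data.frame(frame = seq_len(nf) - 1, time_ns = frame_times(traj))
  for (j in seq_along(ipart)) {
    out[[paste0("dist_", names(partner_atoms)[j], "_A")]] <- dists[, j]
    out[[paste0("favorable_", names(partner_atoms)[j])]] <- dists[, j] < favorable_cutoff
  }
  out$n_on_pairs <- n_pairs
  out$denticity <- denticity
  attr(out, "favorable_cutoff") <- favorable_cutoff
  attr(out, "denticity_cutoff") <- denticity_cutoff
  out
}

#' Hydrogen-bond criteria
#'
#' Geometric criterion: donor-heavy-atom to acceptor distance at most
#' `d_cutoff` AND donor-H...acceptor angle (at the hydrogen) at least
#' `angle_cutoff`. Defaults 3.5 A / 120 degrees, the common geometric
#' convention.
#'
#' @param donor `c(chain, res_seq, heavy_atom_name)` donor reference.
#' @param acceptor `c(chain, res_seq, atom_name)` acceptor reference.
#' @param h_name optional explicit hydrogen atom name on the donor residue;
#'   when absent and the donor is a backbone `N`, the amide hydrogen is
#'   reconstructed geometrically.
#' @param d_cutoff donor-acceptor distance cutoff (A).
#' @param angle_cutoff minimum D-H...A angle in degrees (0, 180].
#' @return An object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(donor, acceptor, h_name = NULL,
                           d_cutoff = 3.5, angle_cutoff = 120) {
  stopifnot(d_cutoff > 0, angle_cutoff > 0, angle_cutoff <= 180)
  structure(list(donor = donor, acceptor = acceptor, h_name = h_name,
                 d_cutoff = d_cutoff, angle_cutoff = angle_cutoff),
            class = "hbond_criteria")
}

#' Hydrogen-bond presence over a trajectory
#'
#' @param traj a `trj_trajectory`.
#' @param crit an [hbond_criteria()].
#' @return list with `series` (a 0/1 [time_series()]) and `percent_formed`
#'   (the mean of the indicator, i.e. the fraction of frames with the bond
#'   formed).
#' @export
hbond_presence <- function(traj, crit) {
  stopifnot(inherits(traj, "trj_trajectory"), inherits(crit, "hbond_criteria"))
  topo <- traj$topology
  find_atom <- function(chain, res, name, required = TRUE) {
    i <- which(topo$atoms$chain == chain & topo$atoms$res_seq == as.integer(res) &
                 topo$atoms$atom_name == name)
    if (length(i) != 1) {
      if (required) stop(sprintf("atom %s/%s/%s not found in topology", chain, res, name))
      return(NA_integer_)
    }
    i
  }
  idon <- find_atom(crit$donor[1], crit$donor[2], crit$donor[3])
  iacc <- find_atom(crit$acceptor[1], crit$acceptor[2], crit$acceptor[3])
  ih <- NA_integer_
  iC_prev <- iCA <- NA_integer_
  if (!is.null(crit$h_name)) {
    ih <- find_atom(crit$donor[1], crit$donor[2], crit$h_name)
  } else if (crit$donor[3] == "N") {
    iC_prev <- find_atom(crit$donor[1], as.integer(crit$donor[2]) - 1, "C")
    iCA <- find_atom(crit$donor[1], crit$donor[2], "CA")
  } else {
    stop(sprintf("no hydrogen available for donor %s/%s/%s: give h_name or use a backbone N donor",
                 crit$donor[1], crit$donor[2], crit$donor[3]))
  }
  nf <- n_frames(traj)
  present <- numeric(nf)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[f, , , drop = TRUE]
    D <- xyz[idon, ]; A <- xyz[iacc, ]
    d <- vnorm(D - A)
    H <- if (!is.na(ih)) xyz[ih, ] else
      reconstruct_amide_h(D, xyz[iC_prev, ], xyz[iCA, ])
    ang <- angle_deg(D, H, A)
    present[f] <- as.numeric(d <= crit$d_cutoff && ang >= crit$angle_cutoff)
  }
  list(series = time_series(frame_times(traj), present,
                            label = "hbond presence", units = "indicator"),
       percent_formed = mean(present))
}
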