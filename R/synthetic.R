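# Seeded generator of toy two-chain trajectories with programmable ground
# truth. The generator realizes every programmed event *geometrically* (atoms
# are actually placed at contact / hydrogen-bond / mixture-drawn distances),
# so downstream detectors are exercised through geometry, never through
# labels. One global seed drives an independent, deterministic substream per
# program entry: adding a contact pair does not perturb any other stream.

#' Specify a synthetic trajectory scenario
#'
#' A scenario is a set of ideal secondary-structure elements plus optional
#' "programs" that script the ground truth frame by frame:
#'
#' * `mobile_domain`: a rigid selection rotated/translated on a per-frame
#'   schedule (emulating a mobile cytosolic domain over a fixed core);
#' * `disordered`: a selection receiving isotropic Gaussian positional noise
#'   (an unstructured peptide segment);
#' * `contacts`: residue pairs with per-frame contact probabilities; when the
#'   indicator fires the designated atom of the second residue is placed
#'   `on_dist` (default 2.8 A) from the anchor atom, otherwise `off_dist`
#'   (default 7.5 A);
#' * `hbonds`: donor/acceptor atom pairs with per-frame presence
#'   probabilities, realized at 2.9 A with a linear donor-H-acceptor geometry
#'   when present and at 5.5 A when absent;
#' * `mixtures`: residue pairs whose C-alpha--C-alpha distance is drawn from a
#'   specified 1-D Gaussian mixture each frame;
#' * `salt_bridge`: a phosphate group placed per frame in a bidentate,
#'   monodentate, or unbound geometry relative to static guanidinium/amine
#'   partner atoms, with given state probabilities.
#'
#' Probabilities may be a scalar (constant over frames) or a length-`n_frames`
#' vector. Two programs may not write coordinates of the same residue.
#'
#' @param seed integer seed driving all randomness.
#' @param n_frames number of frames.
#' @param dt_ns time per frame (ns).
#' @param helices list of helix descriptors: `list(chain, start_res, n_res,
#'   origin, axis)` (ideal alpha-geometry, see [build_ideal_helix()]).
#' @param segments list of extended-chain descriptors with the same fields.
#' @param extra_atoms optional data.frame of additional named atoms
#'   (`chain, res_seq, res_name, atom_name, x, y, z`), e.g. side-chain atoms
#'   used by interaction programs.
#' @param mobile_domain `list(sel, axis, rotation_deg, translation_A,
#'   translation_dir, pivot)`; `rotation_deg` and `translation_A` are scalars
#'   or length-`n_frames` schedules; `pivot` defaults to the selection's
#'   centroid in the reference conformation.
#' @param disordered `list(sel, sigma)` with `sigma` in Angstrom.
#' @param contacts list of `list(res_a = c(chain, res), atom_a, res_b, atom_b,
#'   p, on_dist, off_dist, direction)`.
#' @param hbonds list of `list(donor = c(chain, res), donor_atom, h_atom,
#'   acceptor = c(chain, res), acceptor_atom, p, direction)`. The donor heavy
#'   atom and its hydrogen are moved relative to the static acceptor.
#' @param mixtures list of `list(res_a = c(chain, res), res_b, weights, means,
#'   sds, direction)`; the CA of `res_b` is placed at the drawn distance from
#'   the CA of `res_a`.
#' @param salt_bridge `list(p_res = c(chain, res), arg_res, lys_res, anchor,
#'   p_states = c(none, mono, bi))`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(seed, n_frames, dt_ns, helices, segments = list(),
                          extra_atoms = NULL, mobile_domain = NULL,
                          disordered = NULL, contacts = list(), hbonds = list(),
                          mixtures = list(), salt_bridge = NULL) {
  stopifnot(length(seed) == 1, length(n_frames) == 1, n_frames >= 1, dt_ns > 0)
  spec <- structure(list(seed = as.integer(seed), n_frames = as.integer(n_frames),
                         dt_ns = dt_ns, helices = helices, segments = segments,
                         extra_atoms = extra_atoms, mobile_domain = mobile_domain,
                         disordered = disordered, contacts = contacts,
                         hbonds = hbonds, mixtures = mixtures,
                         salt_bridge = salt_bridge),
                    class = "scenario_spec")
  validate_scenario(spec)
  spec
}

expand_schedule <- function(x, n_frames, what) {
  if (length(x) == 1) x <- rep(x, n_frames)
  if (length(x) != n_frames) {
    stop(sprintf("%s schedule must have length 1 or n_frames (%d), got %d",
                 what, n_frames, length(x)))
  }
  x
}

validate_scenario <- function(spec) {
  nf <- spec$n_frames
  for (ct in spec$contacts) {
    p <- expand_schedule(ct$p, nf, "contact probability")
    if (any(p < 0 | p > 1)) stop("contact probabilities must lie in [0, 1]")
  }
  for (hb in spec$hbonds) {
    p <- expand_schedule(hb$p, nf, "hbond probability")
    if (any(p < 0 | p > 1)) stop("hbond probabilities must lie in [0, 1]")
  }
  for (mx in spec$mixtures) {
    if (abs(sum(mx$weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
    if (any(mx$weights <= 0) || any(mx$sds <= 0)) {
      stop("mixture weights and sds must be positive")
    }
    if (length(mx$means) != length(mx$weights) || length(mx$sds) != length(mx$weights)) {
      stop("mixture weights, means and sds must have equal length")
    }
  }
  if (!is.null(spec$salt_bridge)) {
    ps <- spec$salt_bridge$p_states
    if (length(ps) != 3 || any(ps < 0) || abs(sum(ps) - 1) > 1e-9) {
      stop("salt_bridge p_states must be 3 probabilities (none, mono, bi) summing to 1")
    }
  }
  if (!is.null(spec$mobile_domain)) {
    expand_schedule(spec$mobile_domain$rotation_deg %||% 0, nf, "rotation")
    expand_schedule(spec$mobile_domain$translation_A %||% 0, nf, "translation")
  }
  # no two programs may write coordinates of the same residue
  writer_res <- character(0)
  claim <- function(chain, res, who) {
    key <- paste(chain, res)
    if (key %in% writer_res) {
      stop(sprintf("overlapping residue assignment: %s claims chain %s residue %s, already written by another program",
                   who, chain, res))
    }
    key
  }
  if (!is.null(spec$disordered)) {
    rr <- selection_residues(spec$disordered$sel)
    writer_res <- c(writer_res, vapply(rr, function(r)
      claim(spec$disordered$sel$chain, r, "disordered segment"), character(1)))
  }
  if (!is.null(spec$mobile_domain)) {
    rr <- selection_residues(spec$mobile_domain$sel)
    writer_res <- c(writer_res, vapply(rr, function(r)
      claim(spec$mobile_domain$sel$chain, r, "mobile domain"), character(1)))
  }
  for (ct in spec$contacts) {
    writer_res <- c(writer_res, claim(ct$res_b[1], ct$res_b[2], "contact program"))
  }
  for (hb in spec$hbonds) {
    writer_res <- c(writer_res, claim(hb$donor[1], hb$donor[2], "hbond program"))
  }
  for (mx in spec$mixtures) {
    writer_res <- c(writer_res, claim(mx$res_b[1], mx$res_b[2], "mixture program"))
  }
  if (!is.null(spec$salt_bridge)) {
    writer_res <- c(writer_res,
                    claim(spec$salt_bridge$p_res[1], spec$salt_bridge$p_res[2],
                          "salt-bridge program"))
  }
  invisible(spec)
}

# Local geometry of the salt-bridge stage, one rigid phosphate placement per
# state. Coordinates are in the local frame anchored at the arginine CZ; the
# guanidinium (CZ, NH1, NH2, NE) and the lysine NZ are static, the phosphate
# group (P, O1P, O2P, O3P) moves. In the "bi" state two distinct phosphate
# oxygens sit 2.8 A from NH1 and NH2; in "mono" exactly one oxygen-nitrogen
# pair is within 3.5 A; in "none" every pair exceeds 6 A and P-CZ > 6 A.
salt_bridge_geometry <- function() {
  partner <- rbind(CZ = c(0, 0, 0),
                   NH1 = c(0.665, 1.1518, 0),
                   NH2 = c(0.665, -1.1518, 0),
                   NE = c(-1.33, 0, 0),
                   NZ = c(0.665, 2.6, 3.0))
  states <- list(
    bi = rbind(P = c(2.504, 0, 0),
               O1P = c(3.465, 1.1518, 0),
               O2P = c(3.465, -1.1518, 0),
               O3P = c(2.504, 0, 1.5)),
    mono = rbind(P = c(0.665, 5.4518, 0),
                 O1P = c(0.665, 3.9518, 0),
                 O2P = c(2.165, 5.4518, 0),
                 O3P = c(-0.835, 5.4518, 0)),
    none = rbind(P = c(0.665, 9.5, 0),
                 O1P = c(0.665, 8.0, 0),
                 O2P = c(2.165, 9.5, 0),
                 O3P = c(-0.835, 9.5, 0)))
  list(partner = partner, states = states)
}

atom_row <- function(chain, res_seq, res_name, atom_name, xyz) {
  data.frame(chain = chain, res_seq = res_seq, res_name = res_name,
             atom_name = atom_name, x = xyz[1], y = xyz[2], z = xyz[3],
             stringsAsFactors = FALSE)
}

#' Reference conformation of a scenario
#'
#' Returns the unperturbed base conformation of the scenario: ideal
#' secondary-structure elements at their specified placements, with every
#' programmed interaction in its "off"/baseline placement (contacts at
#' `off_dist`, hydrogen bonds absent, mixture pairs at the first component
#' mean, salt bridge unbound). This is the alignment reference and the frame-0
#' topology of [build_scenario()].
#'
#' @param spec a [scenario_spec()].
#' @return A `trj_structure`.
#' @export
emit_reference <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  parts <- c(
    lapply(spec$helices, function(h)
      build_ideal_helix(h$chain, h$start_res, h$n_res,
                        origin = h$origin %||% c(0, 0, 0),
                        axis = h$axis %||% c(0, 0, 1))),
    lapply(spec$segments, function(h)
      build_extended_chain(h$chain, h$start_res, h$n_res,
                           origin = h$origin %||% c(0, 0, 0),
                           axis = h$axis %||% c(0, 0, 1))))
  atoms <- do.call(rbind, lapply(parts, function(p)
    cbind(p$atoms[c("chain", "res_seq", "res_name", "atom_name")],
          as.data.frame(p$xyz))))
  if (!is.null(spec$extra_atoms)) {
    ea <- spec$extra_atoms
    atoms <- rbind(atoms, ea[c("chain", "res_seq", "res_name", "atom_name", "x", "y", "z")])
  }
  if (!is.null(spec$salt_bridge)) {
    sb <- spec$salt_bridge
    geo <- salt_bridge_geometry()
    anchor <- sb$anchor %||% c(0, 0, 0)
    pn <- geo$partner
    atoms <- rbind(atoms,
                   atom_row(sb$arg_res[1], as.integer(sb$arg_res[2]), "ARG", "CZ", pn["CZ", ] + anchor),
                   atom_row(sb$arg_res[1], as.integer(sb$arg_res[2]), "ARG", "NH1", pn["NH1", ] + anchor),
                   atom_row(sb$arg_res[1], as.integer(sb$arg_res[2]), "ARG", "NH2", pn["NH2", ] + anchor),
                   atom_row(sb$arg_res[1], as.integer(sb$arg_res[2]), "ARG", "NE", pn["NE", ] + anchor),
                   atom_row(sb$lys_res[1], as.integer(sb$lys_res[2]), "LYS", "NZ", pn["NZ", ] + anchor))
    ph <- geo$states$none
    for (nm in rownames(ph)) {
      atoms <- rbind(atoms, atom_row(sb$p_res[1], as.integer(sb$p_res[2]), "SEP", nm,
                                     ph[nm, ] + anchor))
    }
  }
  ord <- order(atoms$chain, atoms$res_seq)
  atoms <- atoms[ord, ]
  s <- new_structure(atoms[c("chain", "res_seq", "res_name", "atom_name")],
                     as.matrix(atoms[c("x", "y", "z")]))
  # apply the baseline ("off") placement of the movable program atoms
  apply_program_placements(s$xyz, s, spec,
                           contact_on = rep(FALSE, length(spec$contacts)),
                           hbond_on = rep(FALSE, length(spec$hbonds)),
                           mixture_d = vapply(spec$mixtures, function(m) m$means[1], numeric(1)),
                           sb_state = "none") -> xyz
  new_structure(s$atoms, xyz)
}

atom_index <- function(s, chain, res, atom) {
  i <- which(s$atoms$chain == chain & s$atoms$res_seq == as.integer(res) &
               s$atoms$atom_name == atom)
  if (length(i) != 1) {
    stop(sprintf("atom %s/%s/%s not found in scenario topology", chain, res, atom))
  }
  i
}

# Writes the per-frame placements of contact, hbond, mixture and salt-bridge
# atoms into `xyz` (current frame coordinates) and returns it. Anchor
# positions are read from the current coordinates, so programs see the mobile
# domain already moved.
apply_program_placements <- function(xyz, s, spec, contact_on, hbond_on,
                                     mixture_d, sb_state) {
  for (k in seq_along(spec$contacts)) {
    ct <- spec$contacts[[k]]
    ia <- atom_index(s, ct$res_a[1], ct$res_a[2], ct$atom_a %||% "CB")
    ib <- atom_index(s, ct$res_b[1], ct$res_b[2], ct$atom_b %||% "CB")
    u <- ct$direction %||% {
      ica <- atom_index(s, ct$res_a[1], ct$res_a[2], "CA")
      unit(xyz[ia, ] - xyz[ica, ])
    }
    d <- if (contact_on[k]) ct$on_dist %||% 2.8 else ct$off_dist %||% 7.5
    xyz[ib, ] <- xyz[ia, ] + d * unit(u)
  }
  for (k in seq_along(spec$hbonds)) {
    hb <- spec$hbonds[[k]]
    iacc <- atom_index(s, hb$acceptor[1], hb$acceptor[2], hb$acceptor_atom %||% "O")
    idon <- atom_index(s, hb$donor[1], hb$donor[2], hb$donor_atom)
    ih <- atom_index(s, hb$donor[1], hb$donor[2], hb$h_atom)
    u <- unit(hb$direction %||% c(1, 0.2, 0.1))
    d <- if (hbond_on[k]) 2.9 else 5.5
    don <- xyz[iacc, ] + d * u
    xyz[idon, ] <- don
    xyz[ih, ] <- don - 1.0 * u  # H on the donor-acceptor line: D-H...A angle 180
  }
  for (k in seq_along(spec$mixtures)) {
    mx <- spec$mixtures[[k]]
    ia <- atom_index(s, mx$res_a[1], mx$res_a[2], "CA")
    ib <- atom_index(s, mx$res_b[1], mx$res_b[2], "CA")
    u <- unit(mx$direction %||% c(0.3, 1, 0.25))
    xyz[ib, ] <- xyz[ia, ] + mixture_d[k] * u
  }
  if (!is.null(spec$salt_bridge)) {
    sb <- spec$salt_bridge
    geo <- salt_bridge_geometry()
    anchor <- sb$anchor %||% c(0, 0, 0)
    ph <- geo$states[[sb_state]]
    for (nm in rownames(ph)) {
      xyz[atom_index(s, sb$p_res[1], sb$p_res[2], nm), ] <- ph[nm, ] + anchor
    }
  }
  xyz
}

#' Build a synthetic trajectory with known ground truth
#'
#' Deterministic for a fixed seed. The returned ground truth records, per
#' frame, the applied rotation angle and translation of the mobile domain, the
#' realized contact and hydrogen-bond indicators, the mixture component drawn
#' for each programmed distance pair (and the drawn distance), and the
#' salt-bridge state.
#'
#' @param spec a [scenario_spec()].
#' @return `list(trajectory = trj_trajectory, ground_truth = list)`.
#' @export
build_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  validate_scenario(spec)
  ref <- emit_reference(spec)
  nf <- spec$n_frames
  na <- n_atoms(ref)

  # --- draw all random variates up front, one substream per program entry ---
  contact_on <- matrix(FALSE, nf, max(1, length(spec$contacts)))[, seq_along(spec$contacts), drop = FALSE]
  for (k in seq_along(spec$contacts)) {
    ct <- spec$contacts[[k]]
    p <- expand_schedule(ct$p, nf, "contact probability")
    sseed <- substream_seed(spec$seed, paste0("contact|", ct$res_a[1], ct$res_a[2],
                                              "|", ct$res_b[1], ct$res_b[2]))
    contact_on[, k] <- with_seed(sseed, stats::runif(nf) < p)
  }
  hbond_on <- matrix(FALSE, nf, max(1, length(spec$hbonds)))[, seq_along(spec$hbonds), drop = FALSE]
  for (k in seq_along(spec$hbonds)) {
    hb <- spec$hbonds[[k]]
    p <- expand_schedule(hb$p, nf, "hbond probability")
    sseed <- substream_seed(spec$seed, paste0("hbond|", hb$donor[1], hb$donor[2],
                                              "|", hb$acceptor[1], hb$acceptor[2]))
    hbond_on[, k] <- with_seed(sseed, stats::runif(nf) < p)
  }
  mixture_comp <- matrix(0L, nf, max(1, length(spec$mixtures)))[, seq_along(spec$mixtures), drop = FALSE]
  mixture_dist <- matrix(0, nf, max(1, length(spec$mixtures)))[, seq_along(spec$mixtures), drop = FALSE]
  for (k in seq_along(spec$mixtures)) {
    mx <- spec$mixtures[[k]]
    sseed <- substream_seed(spec$seed, paste0("mixture|", mx$res_a[1], mx$res_a[2],
                                              "|", mx$res_b[1], mx$res_b[2]))
    draw <- with_seed(sseed, {
      comp <- sample.int(length(mx$weights), nf, replace = TRUE, prob = mx$weights)
      list(comp = comp,
           d = stats::rnorm(nf, mean = mx$means[comp], sd = mx$sds[comp]))
    })
    mixture_comp[, k] <- draw$comp
    mixture_dist[, k] <- pmax(draw$d, 0.5)  # distances cannot go non-physical
  }
  sb_states <- NULL
  if (!is.null(spec$salt_bridge)) {
    sseed <- substream_seed(spec$seed, "saltbridge")
    sb_states <- with_seed(sseed, {
      c("none", "mono", "bi")[sample.int(3, nf, replace = TRUE,
                                         prob = spec$salt_bridge$p_states)]
    })
  }
  noise <- NULL
  dis_idx <- NULL
  if (!is.null(spec$disordered) && spec$disordered$sigma > 0) {
    dis_idx <- resolve_selection(spec$disordered$sel, ref)
    sseed <- substream_seed(spec$seed, "disordered")
    noise <- with_seed(sseed,
      array(stats::rnorm(nf * length(dis_idx) * 3, sd = spec$disordered$sigma),
            dim = c(nf, length(dis_idx), 3)))
  }

  # --- mobile-domain schedule (deterministic) ---
  mob <- spec$mobile_domain
  rot_sched <- trans_sched <- NULL
  mob_idx <- NULL
  if (!is.null(mob)) {
    mob_idx <- resolve_selection(mob$sel, ref)
    rot_sched <- expand_schedule(mob$rotation_deg %||% 0, nf, "rotation")
    trans_sched <- expand_schedule(mob$translation_A %||% 0, nf, "translation")
    pivot <- mob$pivot %||% colMeans(ref$xyz[mob_idx, , drop = FALSE])
    axis <- unit(mob$axis %||% c(0, 0, 1))
    tdir <- unit(mob$translation_dir %||% axis)
  }

  coords <- array(0, dim = c(nf, na, 3))
  for (f in seq_len(nf)) {
    xyz <- ref$xyz
    if (!is.null(mob)) {
      R <- rotation_matrix(axis, rot_sched[f])
      moved <- sweep(sweep(xyz[mob_idx, , drop = FALSE], 2, pivot) %*% t(R), 2, pivot, "+")
      xyz[mob_idx, ] <- sweep(moved, 2, trans_sched[f] * tdir, "+")
    }
    if (!is.null(noise)) {
      xyz[dis_idx, ] <- xyz[dis_idx, ] + noise[f, , ]
    }
    xyz <- apply_program_placements(xyz, ref, spec,
                                    contact_on = contact_on[f, ],
                                    hbond_on = hbond_on[f, ],
                                    mixture_d = mixture_dist[f, ],
                                    sb_state = if (is.null(sb_states)) "none" else sb_states[f])
    coords[f, , ] <- xyz
  }

  gt <- list(rotation_deg = if (is.null(mob)) rep(0, nf) else rot_sched,
             translation_A = if (is.null(mob)) rep(0, nf) else trans_sched,
             contacts = contact_on,
             hbonds = hbond_on,
             mixture_component = mixture_comp,
             mixture_distance = mixture_dist,
             salt_bridge_state = sb_states)
  if (length(spec$contacts) > 0) {
    colnames(gt$contacts) <- vapply(spec$contacts, function(ct)
      paste0(ct$res_a[1], ct$res_a[2], "-", ct$res_b[1], ct$res_b[2]), character(1))
  }
  list(trajectory = new_trajectory(ref, coords, dt_ns = spec$dt_ns,
                                   label = paste0("synthetic-seed", spec$seed)),
       ground_truth = gt)
}

#' Draw a sample from a 1-D Gaussian mixture
#'
#' The sampling primitive behind the scenario generator's distance programs,
#' exposed directly for statistical validation work.
#'
#' @param weights component weights (must sum to 1).
#' @param means component means.
#' @param sds component standard deviations.
#' @param n sample size.
#' @param seed integer seed.
#' @return numeric vector of length `n`, with the drawn component index
#'   attached as attribute `"component"`.
#' @export
sample_mixture <- function(weights, means, sds, n, seed) {
  if (abs(sum(weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
  stopifnot(length(means) == length(weights), length(sds) == length(weights))
  with_seed(seed, {
    comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
    x <- stats::rnorm(n, mean = means[comp], sd = sds[comp])
    attr(x, "component") <- comp
    x
  })
}
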