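test_that("occupancy counts contacting frames exactly", {
  # contact scripted in exactly 3 of 4 frames via a degenerate schedule
  spec <- scenario_spec(
    seed = 1, n_frames = 4, dt_ns = 1,
    helices = list(list(chain = "A", start_res = 1, n_res = 14)),
    segments = list(list(chain = "B", start_res = 1, n_res = 12, origin = c(40, 0, 0))),
    contacts = list(list(res_a = c("A", 2), res_b = c("B", 1), p = c(1, 1, 1, 0))))
  built <- build_scenario(spec)
  oc <- occupancy_map(built$trajectory,
                      select_atoms("A", c(1, 14)), select_atoms("B", c(1, 12)))
  expect_identical(oc$b$OF[oc$b$res_seq == 1], 0.75)
  expect_identical(oc$a$OF[oc$a$res_seq == 2], 0.75)
  expect_equal(oc$a$n_frames_total, rep(4L, nrow(oc$a)), ignore_attr = TRUE)
})

test_that("pooling across trajectories is frame-weighted and order-invariant", {
  mk <- function(seed, n, p) {
    spec <- scenario_spec(
      seed = seed, n_frames = n, dt_ns = 1,
      helices = list(list(chain = "A", start_res = 1, n_res = 14)),
      segments = list(list(chain = "B", start_res = 1, n_res = 12, origin = c(40, 0, 0))),
      contacts = list(list(res_a = c("A", 2), res_b = c("B", 1), p = p)))
    build_scenario(spec)$trajectory
  }
  t1 <- mk(1, 10, 1)                          # per-trajectory OF = 1.0
  t2 <- mk(2, 30, c(rep(1, 15), rep(0, 15)))  # per-trajectory OF = 0.5
  ga <- select_atoms("A", c(1, 14))
  gb <- select_atoms("B", c(1, 12))
  oc <- occupancy_map(list(t1, t2), ga, gb)
  expect_equal(oc$b$OF[oc$b$res_seq == 1], (10 + 15) / 40)  # 0.625, by hand
  per <- attr(oc, "per_trajectory")
  expect_equal(unname(per[[t1$label]]$b[1]), 1.0)
  expect_equal(unname(per[[t2$label]]$b[1]), 0.5)

  oc_rev <- occupancy_map(list(t2, t1), ga, gb)
  expect_equal(oc$a$OF, oc_rev$a$OF)
  expect_equal(oc$b$OF, oc_rev$b$OF)
})

test_that("overlapping occupancy groups are rejected", {
  s <- build_ideal_helix("A", 1, 10)
  tr <- make_trajectory(s, list(s$xyz))
  expect_error(occupancy_map(tr, select_atoms("A", c(1, 6)), select_atoms("A", c(5, 10))),
               "overlap")
})

test_that("high-occupancy classification uses strict exceedance", {
  tab <- data.frame(chain = "A", res_seq = 1:3, res_name = "ALA",
                    OF = c(0.8, 0.75, 0.3), n_frames_total = 100)
  hit <- classify_high_occupancy(tab, 0.75)
  expect_equal(hit$res_seq, 1)          # 0.75 itself is excluded
  expect_equal(classify_high_occupancy(tab, 0)$res_seq, c(1, 2, 3))
  empty <- tab[0, ]
  expect_equal(nrow(classify_high_occupancy(empty, 0.5)), 0)
})

salt_bridge_fixture <- function(frames) {
  atoms <- data.frame(
    chain = c(rep("A", 5), rep("B", 4)),
    res_seq = c(324, 324, 324, 324, 328, 16, 16, 16, 16),
    res_name = c(rep("ARG", 4), "LYS", rep("SEP", 4)),
    atom_name = c("CZ", "NH1", "NH2", "NE", "NZ", "P", "O1P", "O2P", "O3P"),
    stringsAsFactors = FALSE)
  partner <- rbind(c(0, 0, 0), c(0.665, 1.1518, 0), c(0.665, -1.1518, 0),
                   c(-1.33, 0, 0), c(0.665, 2.6, 3.0))
  coords <- lapply(frames, function(ph) rbind(partner, ph))
  make_trajectory(make_structure(cbind(atoms,
                                       as.data.frame(coords[[1]]) |> stats::setNames(c("x", "y", "z")))),
                  coords)
}

test_that("constructed salt-bridge geometries classify as expected", {
  bi <- rbind(c(2.504, 0, 0), c(3.465, 1.1518, 0), c(3.465, -1.1518, 0), c(2.504, 0, 1.5))
  mono <- rbind(c(0.665, 5.4518, 0), c(0.665, 3.9518, 0), c(2.165, 5.4518, 0), c(-0.835, 5.4518, 0))
  none <- rbind(c(0.665, 9.5, 0), c(0.665, 8.0, 0), c(2.165, 9.5, 0), c(-0.835, 9.5, 0))
  tr <- salt_bridge_fixture(list(bi, mono, none))
  sb <- salt_bridge_series(tr, c("B", 16, "P"),
                           list(arg_CZ = c("A", 324, "CZ"), lys_NZ = c("A", 328, "NZ")))
  expect_equal(sb$denticity, c("bidentate", "monodentate", "none"))
  expect_equal(sb$favorable_arg_CZ, c(TRUE, TRUE, FALSE))
  expect_equal(sb$favorable_lys_NZ, c(TRUE, TRUE, FALSE))
  # two oxygens at 2.8 A from the two NH nitrogens in the bidentate frame
  expect_equal(sb$dist_arg_CZ_A[1], 2.504, tolerance = 1e-9)
})

test_that("a probe exactly past the favorable cutoff is unfavorable", {
  far <- rbind(c(6.5, 0, 0), c(8, 0, 0), c(8, 1, 0), c(8, -1, 0))
  tr <- salt_bridge_fixture(list(far))
  sb <- salt_bridge_series(tr, c("B", 16, "P"), list(arg_CZ = c("A", 324, "CZ")))
  expect_false(sb$favorable_arg_CZ)  # favorable means strictly < 6 A
  expect_equal(sb$denticity, "none")
  expect_error(salt_bridge_series(tr, c("B", 16, "PX"), list(arg = c("A", 324, "CZ"))),
               "PX")
})

test_that("shrinking the denticity cutoff never promotes the classification", {
  bi <- rbind(c(2.504, 0, 0), c(3.465, 1.1518, 0), c(3.465, -1.1518, 0), c(2.504, 0, 1.5))
  mono <- rbind(c(0.665, 5.4518, 0), c(0.665, 3.9518, 0), c(2.165, 5.4518, 0), c(-0.835, 5.4518, 0))
  tr <- salt_bridge_fixture(list(bi, mono))
  rank <- c(none = 0, monodentate = 1, bidentate = 2)
  cutoffs <- c(3.5, 3.0, 2.9, 2.5, 1.0)
  dent <- sapply(cutoffs, function(cc)
    rank[salt_bridge_series(tr, c("B", 16, "P"), list(arg = c("A", 324, "CZ")),
                            denticity_cutoff = cc)$denticity])
  expect_true(all(apply(dent, 1, function(r) all(diff(r) <= 0))))
})

test_that("hydrogen-bond presence applies both the distance and the angle gate", {
  atoms <- data.frame(chain = c("A", "A", "B"), res_seq = c(1, 1, 2),
                      atom_name = c("ND2", "HD2", "O"),
                      x = 0, y = 0, z = 0)
  linear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0))    # 2.9 A, angle 180
  bent <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1.9, 0))      # 2.15 A, angle 90
  s <- make_structure(cbind(atoms[1:3], x = linear[, 1], y = linear[, 2], z = linear[, 3]))
  crit <- hbond_criteria(c("A", 1, "ND2"), c("B", 2, "O"), h_name = "HD2")

  tr_ok <- make_trajectory(s, list(linear, linear, linear))
  expect_equal(hbond_presence(tr_ok, crit)$percent_formed, 1.0)

  tr_bent <- make_trajectory(s, list(bent, bent))
  expect_equal(hbond_presence(tr_bent, crit)$percent_formed, 0.0)

  expect_error(hbond_presence(tr_ok, hbond_criteria(c("A", 1, "NX"), c("B", 2, "O"),
                                                    h_name = "HD2")), "NX")
  expect_error(hbond_criteria(c("A", 1, "N"), c("B", 2, "O"), angle_cutoff = 200),
               "angle_cutoff")
})

test_that("a programmed 9-of-10 hydrogen bond reports 0.9 exactly", {
  spec <- scenario_spec(
    seed = 5, n_frames = 10, dt_ns = 1,
    helices = list(list(chain = "A", start_res = 1, n_res = 10)),
    segments = list(list(chain = "B", start_res = 1, n_res = 6, origin = c(40, 0, 0))),
    extra_atoms = data.frame(chain = "B", res_seq = c(3L, 3L), res_name = "ASN",
                             atom_name = c("ND2", "HD2"),
                             x = c(40, 41), y = 0, z = 0),
    hbonds = list(list(donor = c("B", 3), donor_atom = "ND2", h_atom = "HD2",
                       acceptor = c("A", 5), acceptor_atom = "O",
                       p = c(rep(1, 9), 0))))
  built <- build_scenario(spec)
  crit <- hbond_criteria(c("B", 3, "ND2"), c("A", 5, "O"), h_name = "HD2")
  hp <- hbond_presence(built$trajectory, crit)
  expect_identical(hp$percent_formed, 0.9)
  expect_equal(hp$series$values, as.numeric(built$ground_truth$hbonds[, 1]))
})

test_that("a backbone amide donor works without an explicit hydrogen", {
  h <- build_ideal_helix("A", 1, 8)
  tr <- make_trajectory(h, list(h$xyz))
  # the i -> i+4 backbone bond of the ideal helix, through the geometric H
  crit <- hbond_criteria(c("A", 6, "N"), c("A", 2, "O"))
  hp <- hbond_presence(tr, crit)
  expect_equal(hp$percent_formed, 1.0)
})
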