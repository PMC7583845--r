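test_that("the generator is bit-identical for a fixed seed", {
  spec <- demo_scenario(seed = 42, n_frames = 8)
  b1 <- build_scenario(spec)
  b2 <- build_scenario(spec)
  expect_identical(b1$trajectory$coords, b2$trajectory$coords)
  expect_identical(b1$ground_truth, b2$ground_truth)
})

test_that("a degenerate schedule freezes the trajectory at the reference", {
  spec <- scenario_spec(
    seed = 1, n_frames = 5, dt_ns = 1,
    helices = list(list(chain = "A", start_res = 1, n_res = 10)),
    mobile_domain = list(sel = select_atoms("A", c(6, 10)),
                         axis = c(0, 0, 1), rotation_deg = 0, translation_A = 0))
  built <- build_scenario(spec)
  ref <- emit_reference(spec)
  for (f in 1:5) {
    expect_equal(built$trajectory$coords[f, , ], built$trajectory$coords[1, , ])
  }
  expect_equal(built$trajectory$coords[1, , ], ref$xyz, ignore_attr = TRUE)
})

test_that("degenerate contact probabilities fix the indicators", {
  spec <- occupancy_scenario(seed = 3, n_frames = 6, probs = c(1, 0, 1))
  gt <- build_scenario(spec)$ground_truth
  expect_true(all(gt$contacts[, 1]))
  expect_false(any(gt$contacts[, 2]))
  expect_true(all(gt$contacts[, 3]))
})

test_that("the reference shares the trajectory topology and frame-0 geometry", {
  spec <- demo_scenario(seed = 9, n_frames = 3)
  ref <- emit_reference(spec)
  built <- build_scenario(spec)
  expect_identical(ref$atoms, built$trajectory$topology$atoms)

  one_helix <- scenario_spec(seed = 1, n_frames = 2, dt_ns = 1,
                             helices = list(list(chain = "A", start_res = 1, n_res = 12)))
  r <- emit_reference(one_helix)
  expect_equal(length(unique(r$atoms$res_seq)), 12)
  expect_setequal(unique(r$atoms$atom_name), c("N", "CA", "C", "O", "CB"))
  expect_equal(n_atoms(r), 60)
  expect_equal(build_scenario(one_helix)$trajectory$coords[1, , ], r$xyz,
               ignore_attr = TRUE)
})

test_that("empirical contact frequency converges to the programmed probability", {
  n <- 500
  probs <- c(0.9, 0.5, 0.1)
  gt <- build_scenario(occupancy_scenario(seed = 11, n_frames = n, probs = probs))$ground_truth
  freq <- colMeans(gt$contacts)
  bound <- 3 * sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(freq - probs) <= bound))
})

test_that("programmed distance mixtures reproduce their component means", {
  spec <- scenario_spec(
    seed = 21, n_frames = 3000, dt_ns = 1,
    helices = list(list(chain = "A", start_res = 1, n_res = 6)),
    extra_atoms = data.frame(chain = "A", res_seq = 50L, res_name = "GLY",
                             atom_name = "CA", x = 0, y = 20, z = 0),
    mixtures = list(list(res_a = c("A", 3), res_b = c("A", 50),
                         weights = c(0.6, 0.4), means = c(21, 27), sds = c(1.5, 3))))
  built <- build_scenario(spec)
  gt <- built$ground_truth
  d <- ca_distance_series(built$trajectory, c("A", 3), c("A", 50))
  expect_equal(d$values, gt$mixture_distance[, 1], tolerance = 1e-12)
  for (k in 1:2) {
    xk <- d$values[gt$mixture_component[, 1] == k]
    mu_k <- c(21, 27)[k]
    sd_k <- c(1.5, 3)[k]
    expect_lt(abs(mean(xk) - mu_k), 4 * sd_k / sqrt(length(xk)))
  }
})

test_that("invalid scenario programs are rejected", {
  helix <- list(list(chain = "A", start_res = 1, n_res = 10))
  strand <- list(list(chain = "B", start_res = 1, n_res = 6, origin = c(30, 0, 0)))
  expect_error(scenario_spec(
    seed = 1, n_frames = 4, dt_ns = 1, helices = helix, segments = strand,
    contacts = list(list(res_a = c("A", 2), res_b = c("B", 1), p = 1.2))),
    "\\[0, 1\\]")
  expect_error(scenario_spec(
    seed = 1, n_frames = 4, dt_ns = 1, helices = helix, segments = strand,
    contacts = list(list(res_a = c("A", 2), res_b = c("B", 1), p = c(1, 0)))),
    "schedule")
  # two programs writing the same residue
  expect_error(scenario_spec(
    seed = 1, n_frames = 4, dt_ns = 1, helices = helix, segments = strand,
    contacts = list(list(res_a = c("A", 2), res_b = c("B", 1), p = 0.5),
                    list(res_a = c("A", 5), res_b = c("B", 1), p = 0.5))),
    "overlapping")
  expect_error(scenario_spec(
    seed = 1, n_frames = 4, dt_ns = 1, helices = helix, segments = strand,
    mixtures = list(list(res_a = c("A", 1), res_b = c("B", 3),
                         weights = c(0.5, 0.4), means = c(5, 9), sds = c(1, 1)))),
    "sum to 1")
})

test_that("adding a program entry does not perturb other streams", {
  base <- occupancy_scenario(seed = 7, n_frames = 50, probs = c(0.7, 0.4, 0.2))
  more <- base
  more$contacts <- c(more$contacts,
                     list(list(res_a = c("A", 4), res_b = c("B", 11), p = 0.5)))
  gt1 <- build_scenario(base)$ground_truth
  gt2 <- build_scenario(more)$ground_truth
  expect_identical(gt1$contacts, gt2$contacts[, 1:3])
})
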