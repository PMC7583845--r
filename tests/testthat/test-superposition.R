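test_that("self-superposition gives the identity transform", {
  set.seed(1)
  pts <- matrix(rnorm(30, sd = 4), ncol = 3)
  fit <- kabsch(pts, pts)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit$translation, rep(0, 3), tolerance = 1e-10)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
})

test_that("a constructed rotation + shift is recovered exactly", {
  set.seed(2)
  mobile <- matrix(rnorm(30, sd = 3), ncol = 3)
  R30 <- oracle_rodrigues(c(0, 0, 1), 30)
  target <- sweep(mobile %*% t(R30), 2, c(1, 2, 3), "+")
  fit <- kabsch(mobile, target)
  ang <- acos((sum(diag(fit$rotation)) - 1) / 2) * 180 / pi
  expect_equal(ang, 30, tolerance = 1e-6)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(apply_transform(mobile, fit), target, tolerance = 1e-9)
})

test_that("kabsch matches the brute-force rotation-grid oracle on a noisy instance", {
  set.seed(3)
  mobile <- matrix(rnorm(30, sd = 2), ncol = 3)
  R <- oracle_rodrigues(c(1, 2, 0.5), 47)
  target <- mobile %*% t(R) + matrix(rnorm(30, sd = 0.1), ncol = 3)
  fit <- kabsch(mobile, target)
  grid <- grid_kabsch_rmsd(mobile, target)
  expect_lte(fit$rmsd, grid + 1e-12)  # kabsch is the optimum
  expect_lt(abs(fit$rmsd - grid), 1e-3)
})

test_that("RMSD is invariant under a common rigid transform and symmetric", {
  set.seed(4)
  a <- matrix(rnorm(36, sd = 3), ncol = 3)
  b <- a + matrix(rnorm(36, sd = 0.5), ncol = 3)
  base <- kabsch(a, b)$rmsd
  R <- oracle_rodrigues(c(1, -1, 2), 63)
  shift <- c(5, -2, 9)
  a2 <- sweep(a %*% t(R), 2, shift, "+")
  b2 <- sweep(b %*% t(R), 2, shift, "+")
  expect_equal(kabsch(a2, b2)$rmsd, base, tolerance = 1e-9)
  expect_equal(kabsch(b, a)$rmsd, base, tolerance = 1e-9)
})

test_that("degenerate inputs are rejected", {
  expect_error(kabsch(matrix(rnorm(6), ncol = 3), matrix(rnorm(6), ncol = 3)),
               "at least 3")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch(line, line), "collinear")
})

test_that("rmsd_series is zero for a static trajectory equal to the reference", {
  ref <- build_ideal_helix("A", 1, 10)
  tr <- make_trajectory(ref, list(ref$xyz, ref$xyz, ref$xyz))
  ts <- rmsd_series(tr, select_atoms("A", c(1, 10), atom_names = "CA"), ref)
  expect_equal(ts$values, rep(0, 3), tolerance = 1e-10)
})

test_that("a rigidly displaced domain yields a strictly positive, constant series", {
  ref <- build_ideal_helix("A", 1, 20)
  core_sel <- select_atoms("A", c(1, 10), atom_names = c("N", "CA", "C", "O"))
  dom_sel <- select_atoms("A", c(11, 20), atom_names = c("N", "CA", "C", "O"))
  dom_idx <- resolve_selection(select_atoms("A", c(11, 20)), ref)
  R <- oracle_rodrigues(c(1, 0, 0), 15)
  pivot <- colMeans(ref$xyz[dom_idx, , drop = FALSE]) + c(20, 0, 0)
  moved <- ref$xyz
  moved[dom_idx, ] <- sweep(sweep(ref$xyz[dom_idx, , drop = FALSE], 2, pivot) %*% t(R),
                            2, pivot, "+")
  tr <- make_trajectory(ref, list(moved, moved, moved))
  ts <- rmsd_series(tr, core_sel, ref, dom_sel)
  expect_true(all(ts$values > 1))
  expect_equal(diff(range(ts$values)), 0, tolerance = 1e-10)
})

test_that("rmsd_series agrees with a per-frame grid-search recomputation", {
  spec <- scenario_spec(
    seed = 13, n_frames = 10, dt_ns = 1,
    helices = list(list(chain = "A", start_res = 1, n_res = 8)),
    segments = list(list(chain = "A", start_res = 20, n_res = 5, origin = c(15, 0, 0))),
    disordered = list(sel = select_atoms("A", c(20, 24)), sigma = 1.0))
  built <- build_scenario(spec)
  ref <- emit_reference(spec)
  align <- select_atoms("A", c(1, 8), atom_names = c("N", "CA", "C", "O"))
  meas <- select_atoms("A", c(20, 24), atom_names = "CA")
  ts <- rmsd_series(built$trajectory, align, ref, meas)

  ai <- resolve_selection(align, ref)
  mi <- resolve_selection(meas, ref)
  naive <- vapply(seq_len(10), function(f) {
    xyz <- built$trajectory$coords[f, , ]
    # oracle alignment: exhaustive rotation grid on the align set (the align
    # set here is rigid, so the grid settles on the identity)
    P <- xyz[ai, ]; Q <- ref$xyz[ai, ]
    Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
    best <- list(rmsd = Inf, R = diag(3))
    for (deg in seq(0, 180, by = 4)) {
      axes <- if (deg == 0) matrix(c(0, 0, 1), 1) else oracle_fib_sphere(200)
      for (j in seq_len(nrow(axes))) {
        R <- oracle_rodrigues(axes[j, ], deg)
        r <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
        if (r < best$rmsd) best <- list(rmsd = r, R = R)
      }
    }
    # naive double loop over the measured atoms under the oracle alignment
    M <- sweep(xyz[mi, ], 2, colMeans(P)) %*% t(best$R)
    Mref <- sweep(ref$xyz[mi, ], 2, colMeans(Q))
    sq <- 0
    for (i in seq_len(nrow(M))) sq <- sq + sum((M[i, ] - Mref[i, ])^2)
    sqrt(sq / nrow(M))
  }, numeric(1))
  expect_lt(abs(mean(ts$values) - mean(naive)) / mean(naive), 0.05)
})

test_that("RMSF is zero for a static trajectory and exact for a scripted atom", {
  ref <- build_ideal_helix("A", 1, 6)
  tr <- make_trajectory(ref, list(ref$xyz, ref$xyz, ref$xyz, ref$xyz))
  align <- select_atoms("A", c(1, 6), atom_names = c("N", "CA", "C", "O"))
  target <- select_atoms("A", c(1, 6), atom_names = "CA")
  rf <- rmsf_per_residue(tr, align, target)
  expect_equal(rf$rmsf_A, rep(0, 6), tolerance = 1e-10)

  # one CA alternating +-1 A along x, aligned on the other residues
  idx <- resolve_selection(select_atoms("A", c(3, 3), atom_names = "CA"), ref)
  frames <- lapply(1:4, function(f) {
    xyz <- ref$xyz
    xyz[idx, 1] <- xyz[idx, 1] + c(1, -1, 1, -1)[f]
    xyz
  })
  tr2 <- make_trajectory(ref, frames)
  align2 <- select_atoms("A", list(c(1, 2), c(4, 6)), atom_names = c("N", "CA", "C", "O"))
  rf2 <- rmsf_per_residue(tr2, align2, target)
  expect_equal(rf2$rmsf_A[rf2$res_seq == 3], 1.0, tolerance = 1e-9)
})

test_that("isotropic Gaussian jitter gives RMSF = sigma * sqrt(3)", {
  sigma <- 0.5
  spec <- scenario_spec(
    seed = 17, n_frames = 2000, dt_ns = 1,
    helices = list(list(chain = "A", start_res = 1, n_res = 8)),
    segments = list(list(chain = "A", start_res = 30, n_res = 4, origin = c(20, 0, 0))),
    disordered = list(sel = select_atoms("A", c(30, 33)), sigma = sigma))
  built <- build_scenario(spec)
  rf <- rmsf_per_residue(built$trajectory,
                         select_atoms("A", c(1, 8), atom_names = c("N", "CA", "C", "O")),
                         select_atoms("A", c(30, 33), atom_names = "CA"))
  expect_equal(rf$rmsf_A, rep(sigma * sqrt(3), 4), tolerance = 0.05)
})

test_that("RMSF is invariant to frame order and undefined for one frame", {
  built <- build_scenario(occupancy_scenario(seed = 23, n_frames = 12))
  tr <- built$trajectory
  align <- select_atoms("A", c(1, 14), atom_names = c("N", "CA", "C", "O"))
  target <- select_atoms("B", c(1, 12), atom_names = "CA")
  rf1 <- rmsf_per_residue(tr, align, target)
  perm <- rev(seq_len(n_frames(tr)))
  tr2 <- new_trajectory(tr$topology, tr$coords[perm, , , drop = FALSE], tr$dt_ns)
  rf2 <- rmsf_per_residue(tr2, align, target)
  expect_equal(rf1$rmsf_A, rf2$rmsf_A, tolerance = 1e-9)

  tr1 <- new_trajectory(tr$topology, tr$coords[1, , , drop = FALSE], tr$dt_ns)
  expect_error(rmsf_per_residue(tr1, align, target), "single-frame")
})
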