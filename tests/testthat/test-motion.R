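# Fixture: a static core helix plus a separate domain helix whose frames are
# rotated/translated by explicit (oracle) transforms, never by package code.
motion_fixture <- function() {
  core <- build_ideal_helix("A", 1, 12)
  dom <- build_ideal_helix("A", 20, 12, origin = c(18, 0, 0))
  atoms <- rbind(core$atoms, dom$atoms)
  xyz <- rbind(core$xyz, dom$xyz)
  ref <- new_structure(atoms, xyz)
  dom_idx <- which(ref$atoms$res_seq >= 20)
  ca_idx <- which(ref$atoms$res_seq >= 20 & ref$atoms$atom_name == "CA")
  list(ref = ref, dom_idx = dom_idx,
       ca_centroid = colMeans(ref$xyz[ca_idx, , drop = FALSE]))
}

rotate_domain <- function(ref, dom_idx, axis, deg, pivot, shift = c(0, 0, 0)) {
  R <- oracle_rodrigues(axis, deg)
  xyz <- ref$xyz
  xyz[dom_idx, ] <- sweep(sweep(xyz[dom_idx, , drop = FALSE], 2, pivot) %*% t(R),
                          2, pivot + shift, "+")
  xyz
}

core_sel <- function() select_atoms("A", c(1, 12))
dom_sel <- function() select_atoms("A", c(20, 31))

test_that("a static trajectory equal to the reference maps to (0 deg, 0 A)", {
  fx <- motion_fixture()
  tr <- make_trajectory(fx$ref, list(fx$ref$xyz, fx$ref$xyz))
  mm <- motion_map(tr, fx$ref, core_sel(), list(D = dom_sel()))
  expect_equal(mm$rotation_deg, c(0, 0), tolerance = 1e-6)
  expect_equal(mm$translation_A, c(0, 0), tolerance = 1e-9)
})

test_that("scripted rotations about the domain centroid are recovered", {
  fx <- motion_fixture()
  angles <- c(5, 15, 30)
  frames <- lapply(angles, function(a)
    rotate_domain(fx$ref, fx$dom_idx, c(0, 1, 0), a, fx$ca_centroid))
  tr <- make_trajectory(fx$ref, frames)
  mm <- motion_map(tr, fx$ref, core_sel(), list(D = dom_sel()))
  expect_equal(mm$rotation_deg, angles, tolerance = 0.01)
  expect_true(all(mm$translation_A < 1e-6))
  expect_equal(abs(mm$axis_y), rep(1, 3), tolerance = 1e-6)
})

test_that("an offset rotation axis produces the chord-length displacement", {
  fx <- motion_fixture()
  d <- 10
  theta <- 20
  pivot <- fx$ca_centroid + c(0, 0, d)   # offset perpendicular to axis (0,1,0)
  tr <- make_trajectory(fx$ref,
                        list(rotate_domain(fx$ref, fx$dom_idx, c(0, 1, 0), theta, pivot)))
  mm <- motion_map(tr, fx$ref, core_sel(), list(D = dom_sel()))
  expect_equal(mm$rotation_deg, theta, tolerance = 0.01)
  expect_equal(mm$translation_A, 2 * sin(theta / 2 * pi / 180) * d, tolerance = 1e-3)
})

test_that("rotations about a fixed axis compose additively with a stable axis", {
  fx <- motion_fixture()
  axis <- c(0.3, 1, -0.2)
  f10 <- rotate_domain(fx$ref, fx$dom_idx, axis, 10, fx$ca_centroid)
  f25 <- rotate_domain(fx$ref, fx$dom_idx, axis, 25, fx$ca_centroid)
  tr <- make_trajectory(fx$ref, list(f10, f25))
  mm <- motion_map(tr, fx$ref, core_sel(), list(D = dom_sel()))
  expect_equal(mm$rotation_deg[2] - mm$rotation_deg[1], 15, tolerance = 0.01)
  ax1 <- c(mm$axis_x[1], mm$axis_y[1], mm$axis_z[1])
  ax2 <- c(mm$axis_x[2], mm$axis_y[2], mm$axis_z[2])
  expect_equal(abs(sum(ax1 * ax2)), 1, tolerance = 1e-6)
})

test_that("a scripted angular ramp is monotone with the scripted endpoint", {
  fx <- motion_fixture()
  angles <- seq(0, 30, length.out = 16)
  frames <- lapply(angles, function(a)
    rotate_domain(fx$ref, fx$dom_idx, c(1, 0, 0), a, fx$ca_centroid))
  mm <- motion_map(make_trajectory(fx$ref, frames), fx$ref, core_sel(),
                   list(D = dom_sel()))
  expect_true(all(diff(mm$rotation_deg) > 0))
  expect_equal(mm$rotation_deg[16], 30, tolerance = 0.05)
})

test_that("two scripted motion clusters are recovered by k-means", {
  fx <- motion_fixture()
  mk <- function(deg, shift_A, n) {
    lapply(seq_len(n), function(i)
      rotate_domain(fx$ref, fx$dom_idx, c(0, 1, 0), deg, fx$ca_centroid,
                    shift = c(shift_A, 0, 0)))
  }
  frames <- c(mk(5, 2, 15), mk(25, 8, 15))
  mm <- motion_map(make_trajectory(fx$ref, frames), fx$ref, core_sel(),
                   list(D = dom_sel()))
  km <- stats::kmeans(cbind(mm$rotation_deg, mm$translation_A), centers = 2, nstart = 5)
  centers <- km$centers[order(km$centers[, 1]), ]
  expect_equal(unname(centers[, 1]), c(5, 25), tolerance = 1)
  expect_equal(unname(centers[, 2]), c(2, 8), tolerance = 0.5)
})

test_that("rotation angle is invariant under a joint rigid transform", {
  fx <- motion_fixture()
  moved <- rotate_domain(fx$ref, fx$dom_idx, c(0, 0, 1), 17, fx$ca_centroid)
  s_mob <- new_structure(fx$ref$atoms, moved)
  dm0 <- domain_rotation(core_align(s_mob, fx$ref, core_sel()), fx$ref, dom_sel())

  R <- oracle_rodrigues(c(2, 1, 1), 51)
  shift <- c(-3, 8, 2)
  ref2 <- new_structure(fx$ref$atoms, sweep(fx$ref$xyz %*% t(R), 2, shift, "+"))
  mob2 <- new_structure(fx$ref$atoms, sweep(moved %*% t(R), 2, shift, "+"))
  dm1 <- domain_rotation(core_align(mob2, ref2, core_sel()), ref2, dom_sel())
  expect_equal(dm1$rotation_deg, dm0$rotation_deg, tolerance = 1e-6)
  expect_equal(dm1$translation_A, dm0$translation_A, tolerance = 1e-6)
})

test_that("core alignment is exact on identity and improves noisy cores", {
  fx <- motion_fixture()
  al <- core_align(fx$ref, fx$ref, core_sel())
  expect_equal(al$xyz, fx$ref$xyz, tolerance = 1e-10)
  expect_equal(attr(al, "fit")$rmsd, 0, tolerance = 1e-10)

  set.seed(9)
  noisy <- fx$ref$xyz + matrix(rnorm(length(fx$ref$xyz), sd = 0.2), ncol = 3)
  shifted <- sweep(noisy, 2, c(4, 4, 4), "+")
  s <- new_structure(fx$ref$atoms, shifted)
  ca <- resolve_selection(select_atoms("A", c(1, 12), atom_names = "CA"), fx$ref)
  before <- sqrt(mean(rowSums((shifted[ca, ] - fx$ref$xyz[ca, ])^2)))
  after_s <- core_align(s, fx$ref, core_sel())
  after <- sqrt(mean(rowSums((after_s$xyz[ca, ] - fx$ref$xyz[ca, ])^2)))
  expect_lte(after, before)
})
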