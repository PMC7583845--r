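# Independent oracles and fixture builders. Everything here is deliberately
# written from first principles (no calls into the package's own numerical
# paths) so the tests compare two genuinely different routes.

# --- brute-force rotation grid search -------------------------------------
# Global axis-angle grid (Fibonacci sphere x angle sweep) followed by local
# grid refinement to ~0.05 degree resolution. Used as the superposition
# oracle: it minimizes RMSD over rotations by exhaustive evaluation, with no
# SVD anywhere.

oracle_rodrigues <- function(axis, deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

oracle_fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

grid_kabsch_rmsd <- function(mobile, target) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(target, 2, colMeans(target))
  eval_rot <- function(axis, deg) {
    R <- oracle_rodrigues(axis, deg)
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  # global stage: every (axis, angle) on the coarse grid, keeping the best
  # few well-separated candidates so refinement cannot be trapped in a
  # secondary basin
  axes <- oracle_fib_sphere(300)
  cand <- list()
  for (deg in seq(0, 180, by = 6)) {
    ax_set <- if (deg == 0) matrix(c(0, 0, 1), 1) else axes
    for (j in seq_len(nrow(ax_set))) {
      r <- eval_rot(ax_set[j, ], deg)
      cand[[length(cand) + 1]] <- list(rmsd = r, axis = ax_set[j, ], deg = deg)
    }
  }
  ord <- order(vapply(cand, function(c) c$rmsd, numeric(1)))
  seeds <- list()
  for (k in ord) {
    c_k <- cand[[k]]
    distinct <- all(vapply(seeds, function(s)
      abs(sum(s$axis * c_k$axis)) < 0.95 || abs(s$deg - c_k$deg) > 12, logical(1)))
    if (length(seeds) == 0 || distinct) seeds[[length(seeds) + 1]] <- c_k
    if (length(seeds) >= 6) break
  }
  radii <- c(0.12, 0.03, 0.008, 0.002)      # axis perturbation (radians)
  windows <- c(6, 1.5, 0.4, 0.1)            # angle half-window (degrees)
  refine <- function(best) {
    for (lvl in seq_along(radii)) {
      a0 <- best$axis
      ref <- if (abs(a0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- ref - sum(ref * a0) * a0
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(a0[2] * e1[3] - a0[3] * e1[2],
              a0[3] * e1[1] - a0[1] * e1[3],
              a0[1] * e1[2] - a0[2] * e1[1])
      for (i in -2:2) {
        for (j in -2:2) {
          ax <- a0 + radii[lvl] * (i * e1 + j * e2)
          ax <- ax / sqrt(sum(ax^2))
          for (deg in best$deg + seq(-windows[lvl], windows[lvl], length.out = 7)) {
            r <- eval_rot(ax, deg)
            if (r < best$rmsd) best <- list(rmsd = r, axis = ax, deg = deg)
          }
        }
      }
    }
    best
  }
  min(vapply(seeds, function(s) refine(s)$rmsd, numeric(1)))
}

# --- Kabsch-Sander energy, evaluated from scratch -------------------------
oracle_ks_energy <- function(C, O, N, H) {
  d <- function(a, b) sqrt(sum((a - b)^2))
  0.084 * 332 * (1 / d(O, N) + 1 / d(C, H) - 1 / d(O, H) - 1 / d(C, N))
}

# Helix/coil assignment run by hand on a single conformation: i -> i+4 turns
# from the energy above (amide H rebuilt 1 A from N opposite the
# C(i-1)-N-CA bisector), residues i+1..i+4 of two consecutive turns helical.
oracle_assign_helix <- function(s, chain, residues) {
  g <- function(r, name) s$xyz[s$atoms$chain == chain & s$atoms$res_seq == r &
                                 s$atoms$atom_name == name, ]
  nres <- length(residues)
  turn <- rep(FALSE, nres)
  for (i in seq_len(nres - 4)) {
    ri <- residues[i]; rj <- residues[i + 4]
    N <- g(rj, "N")
    u1 <- N - g(rj - 1, "C"); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- N - g(rj, "CA"); u2 <- u2 / sqrt(sum(u2^2))
    H <- N + (u1 + u2) / sqrt(sum((u1 + u2)^2))
    turn[i] <- oracle_ks_energy(g(ri, "C"), g(ri, "O"), N, H) < -0.5
  }
  codes <- rep("C", nres)
  for (i in seq_len(max(0, nres - 5))) {
    if (turn[i] && turn[i + 1]) codes[(i + 1):(i + 4)] <- "H"
  }
  codes
}

# --- hand-written fixed-column PDB text -----------------------------------
# Formats records independently of write_pdb() for parser tests.
oracle_pdb_line <- function(serial, name, res_name, chain, res_seq, x, y, z,
                            altloc = " ", icode = " ", element = "") {
  sprintf("ATOM  %5d %-4s%s%3s %s%4d%s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, altloc, res_name, chain, res_seq, icode, x, y, z, element)
}

write_tiny_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

# Three-atom glycine (N, CA, C) used across the I/O tests.
tiny_gly_lines <- function(res_seq = 7, chain = "A") {
  c(oracle_pdb_line(1, " N", "GLY", chain, res_seq, 1.0, 2.0, 3.0, element = "N"),
    oracle_pdb_line(2, " CA", "GLY", chain, res_seq, 2.5, 2.0, 3.0, element = "C"),
    oracle_pdb_line(3, " C", "GLY", chain, res_seq, 3.2, 3.1, 3.0, element = "C"))
}

# --- small structure builders ---------------------------------------------
# A structure from a compact spec: data.frame(chain, res_seq, atom_name, x, y, z).
make_structure <- function(df, res_name = "ALA") {
  new_structure(data.frame(chain = df$chain, res_seq = df$res_seq,
                           res_name = res_name, atom_name = df$atom_name,
                           stringsAsFactors = FALSE),
                as.matrix(df[, c("x", "y", "z")]))
}

# Trajectory from a list of coordinate matrices over one topology.
make_trajectory <- function(topology, frames, dt_ns = 1, label = "test") {
  coords <- array(0, dim = c(length(frames), n_atoms(topology), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  new_trajectory(topology, coords, dt_ns = dt_ns, label = label)
}

# Well-separated two-chain scenario for occupancy recovery: one chain-A helix
# and a distant chain-B strand, with programmed contacts only.
occupancy_scenario <- function(seed, n_frames, probs = c(0.9, 0.5, 0.1)) {
  scenario_spec(
    seed = seed, n_frames = n_frames, dt_ns = 1,
    helices = list(list(chain = "A", start_res = 1, n_res = 14)),
    segments = list(list(chain = "B", start_res = 1, n_res = 12,
                         origin = c(40, 0, 0))),
    contacts = list(
      list(res_a = c("A", 2), res_b = c("B", 1), p = probs[1]),
      list(res_a = c("A", 7), res_b = c("B", 5), p = probs[2]),
      list(res_a = c("A", 12), res_b = c("B", 9), p = probs[3])))
}
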