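# Construction of idealized peptide geometry from standard internal
# coordinates (NeRF chain extension). Bond lengths: N-CA 1.458, CA-C 1.525,
# C-N 1.329, C=O 1.231, CA-CB 1.530 Angstrom; angles: C(-1)-N-CA 121.7,
# N-CA-C 111.0, CA-C-N(+1) 117.2, CA-C-O 120.5, N-CA-CB 110.5 degrees.

# Place atom D given references A, B, C, the C-D bond length, the B-C-D bond
# angle (deg) and the A-B-C-D dihedral (deg).
place_atom <- function(A, B, C, bond, angle, dihedral) {
  th <- angle * pi / 180
  ph <- dihedral * pi / 180
  bc <- unit(C - B)
  n <- unit(pracma_cross(B - A, bc))
  m <- pracma_cross(n, bc)
  d_local <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  C + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

dihedral_deg <- function(A, B, C, D) {
  b1 <- B - A
  b2 <- C - B
  b3 <- D - C
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(pracma_cross(n1, n2) * unit(b2))
  atan2(y, x) * 180 / pi
}

# Backbone (+CB, +O) chain with uniform phi/psi/omega. Returns a
# trj_structure; residues are named ALA.
build_peptide <- function(chain, start_res, n_res, phi, psi, omega = 180) {
  stopifnot(n_res >= 1)
  b_NCA <- 1.458; b_CAC <- 1.525; b_CN <- 1.329; b_CO <- 1.231; b_CACB <- 1.530
  a_CNCA <- 121.7; a_NCAC <- 111.0; a_CACN <- 117.2; a_CACO <- 120.5; a_NCACB <- 110.5
  N <- vector("list", n_res); CA <- vector("list", n_res)
  C <- vector("list", n_res); O <- vector("list", n_res); CB <- vector("list", n_res)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(b_NCA, 0, 0)
  th <- a_NCAC * pi / 180
  C[[1]] <- CA[[1]] + b_CAC * c(-cos(th), sin(th), 0)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]], b_CN, a_CACN, psi)
      CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]], b_NCA, a_CNCA, omega)
      C[[i]] <- place_atom(C[[i - 1]], N[[i]], CA[[i]], b_CAC, a_NCAC, phi)
    }
    O[[i]] <- place_atom(N[[i]], CA[[i]], C[[i]], b_CO, a_CACO, psi + 180)
    CB[[i]] <- place_atom(C[[i]], N[[i]], CA[[i]], b_CACB, a_NCACB, 122.6)
  }
  per_res <- c("N", "CA", "C", "O", "CB")
  atoms <- data.frame(chain = chain,
                      res_seq = rep(start_res + seq_len(n_res) - 1, each = length(per_res)),
                      res_name = "ALA",
                      atom_name = rep(per_res, n_res),
                      stringsAsFactors = FALSE)
  xyz <- matrix(0, nrow(atoms), 3)
  for (i in seq_len(n_res)) {
    r0 <- (i - 1) * length(per_res)
    xyz[r0 + 1, ] <- N[[i]]; xyz[r0 + 2, ] <- CA[[i]]; xyz[r0 + 3, ] <- C[[i]]
    xyz[r0 + 4, ] <- O[[i]]; xyz[r0 + 5, ] <- CB[[i]]
  }
  new_structure(atoms, xyz)
}

# Rotate/translate a built chain so that its CA principal axis (oriented
# N-terminus -> C-terminus) lies along `axis` and the CA centroid sits at
# `origin`.
orient_chain <- function(s, origin = c(0, 0, 0), axis = c(0, 0, 1)) {
  ca <- s$xyz[s$atoms$atom_name == "CA", , drop = FALSE]
  centroid <- colMeans(ca)
  centered <- sweep(ca, 2, centroid)
  pc <- svd(centered)$v[, 1]
  if (sum((ca[nrow(ca), ] - ca[1, ]) * pc) < 0) pc <- -pc
  axis <- unit(axis)
  v <- pracma_cross(pc, axis)
  s_ <- vnorm(v)
  c_ <- sum(pc * axis)
  R <- if (s_ < 1e-12) {
    if (c_ > 0) diag(3) else rotation_matrix(orthobasis(axis)$e1, 180)
  } else {
    K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    diag(3) + K + K %*% K * ((1 - c_) / s_^2)
  }
  xyz <- sweep(sweep(s$xyz, 2, centroid) %*% t(R), 2, origin, "+")
  new_structure(s$atoms, xyz)
}

#' Build an ideal alpha-helix
#'
#' Backbone (N, CA, C, O) plus CB, built from standard internal coordinates
#' with phi = -57, psi = -47 degrees and trans peptide bonds, then oriented so
#' the helix axis lies along `axis` with the C-alpha centroid at `origin`.
#'
#' @param chain chain identifier.
#' @param start_res first residue number.
#' @param n_res number of residues.
#' @param origin 3-vector, C-alpha centroid position (Angstrom).
#' @param axis 3-vector, helix axis direction.
#' @return A `trj_structure`.
#' @export
build_ideal_helix <- function(chain, start_res, n_res, origin = c(0, 0, 0),
                              axis = c(0, 0, 1)) {
  orient_chain(build_peptide(chain, start_res, n_res, phi = -57, psi = -47),
               origin = origin, axis = axis)
}

#' Build a fully extended chain
#'
#' Same atom complement as [build_ideal_helix()] but with phi = psi = 180
#' degrees (an extended, unstructured conformation).
#'
#' @inheritParams build_ideal_helix
#' @return A `trj_structure`.
#' @export
build_extended_chain <- function(chain, start_res, n_res, origin = c(0, 0, 0),
                                 axis = c(0, 0, 1)) {
  orient_chain(build_peptide(chain, start_res, n_res, phi = 180, psi = 180),
               origin = origin, axis = axis)
}
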