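#' Bundled demonstration scenario
#'
#' A two-chain synthetic study emulating the statistical structure of a
#' pump-peptide regulatory complex on the microsecond scale:
#'
#' * chain A ("pump"): a rigid four-helix transmembrane core (residues
#'   831-855, 895-915, 933-948, 966-994), a second membrane helix 795-815
#'   carrying the backbone acceptor of the inhibitory hydrogen bond (residue
#'   801), a static cytosolic helix 315-330 carrying a cationic site (Arg-324
#'   guanidinium and Lys-328 amine partner atoms), a cytosolic anchor helix
#'   130-150, a mobile cytosolic helix 340-370 following a scripted rotation
#'   (0 to 12 degrees) and translation (0 to 2 A) ramp, and a single loop
#'   residue 426 whose C-alpha distance to residue 139 is drawn from a
#'   five-component Gaussian mixture (means 7.5/11/20/27/33 A);
#' * chain B ("peptide", 52 residues): a disordered N-terminal segment
#'   (residues 1-26, extended geometry with 2 A positional noise), a stable
#'   transmembrane helix 27-52, a phosphate group on residue 16 forming
#'   bidentate/monodentate salt bridges with the chain-A cationic site
#'   (state probabilities 0.20/0.25/0.55 for none/mono/bi), persistent
#'   transmembrane contacts (p = 0.85-0.9) and transient N-terminal contacts
#'   (p = 0.2-0.3) to chain A, and a side-chain hydrogen-bond donor on
#'   residue 34 bonded to A-801 with probability 0.9.
#'
#' Frame spacing is 10 ns over 300 frames (3 microseconds per trajectory), so
#' a 200-ns burn-in removes the first 20 frames.
#'
#' @param seed integer seed.
#' @param n_frames number of frames (default 300).
#' @param dt_ns frame spacing in ns (default 10).
#' @return A [scenario_spec()].
#' @export
demo_scenario <- function(seed = 101, n_frames = 300, dt_ns = 10) {
  helices <- list(
    list(chain = "A", start_res = 795, n_res = 21, origin = c(-10, 0, 0)),
    list(chain = "A", start_res = 831, n_res = 25, origin = c(0, 0, 0)),
    list(chain = "A", start_res = 895, n_res = 21, origin = c(10, 0, 0)),
    list(chain = "A", start_res = 933, n_res = 16, origin = c(0, 10, 0)),
    list(chain = "A", start_res = 966, n_res = 29, origin = c(10, 10, 0)),
    list(chain = "A", start_res = 130, n_res = 21, origin = c(-15, 30, 35)),
    list(chain = "A", start_res = 315, n_res = 16, origin = c(0, -12, 32)),
    list(chain = "A", start_res = 340, n_res = 31, origin = c(20, 20, 40)),
    list(chain = "B", start_res = 27, n_res = 26, origin = c(-5, 6, 0)))
  segments <- list(
    list(chain = "B", start_res = 1, n_res = 26, origin = c(-25, -12, 28),
         axis = c(1, 0.3, 0.15)))
  extra_atoms <- rbind(
    atom_row("A", 426L, "ASP", "CA", c(-12, 38, 38)),
    atom_row("B", 34L, "ASN", "ND2", c(-15, 2, 1)),
    atom_row("B", 34L, "ASN", "HD2", c(-14.2, 2, 1)))
  ramp <- function(to) seq(0, to, length.out = n_frames)
  scenario_spec(
    seed = seed, n_frames = n_frames, dt_ns = dt_ns,
    helices = helices, segments = segments, extra_atoms = extra_atoms,
    mobile_domain = list(sel = select_atoms("A", c(340, 370)),
                         axis = c(0, 0, 1),
                         rotation_deg = ramp(12),
                         translation_A = ramp(2),
                         translation_dir = c(1, 0, 0)),
    disordered = list(sel = select_atoms("B", list(c(2, 2), c(4, 5), c(7, 15), c(17, 26))),
                      sigma = 2.0),
    contacts = list(
      list(res_a = c("A", 802), res_b = c("B", 31), p = 0.90),
      list(res_a = c("A", 939), res_b = c("B", 38), p = 0.85),
      list(res_a = c("A", 805), res_b = c("B", 42), p = 0.90),
      list(res_a = c("A", 345), res_b = c("B", 1), p = 0.25),
      list(res_a = c("A", 350), res_b = c("B", 3), p = 0.20),
      list(res_a = c("A", 355), res_b = c("B", 6), p = 0.30)),
    hbonds = list(
      list(donor = c("B", 34), donor_atom = "ND2", h_atom = "HD2",
           acceptor = c("A", 801), acceptor_atom = "O", p = 0.9,
           direction = c(-1, 0.25, 0.1))),
    mixtures = list(
      list(res_a = c("A", 139), res_b = c("A", 426),
           weights = c(0.15, 0.15, 0.30, 0.25, 0.15),
           means = c(7.5, 11, 20, 27, 33),
           sds = c(0.8, 0.8, 1.5, 1.5, 1.5))),
    salt_bridge = list(p_res = c("B", 16), arg_res = c("A", 324),
                       lys_res = c("A", 328), anchor = c(6, -12, 32),
                       p_states = c(none = 0.20, mono = 0.25, bi = 0.55)))
}
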