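#' Construct a molecular structure object
#'
#' A structure is an ordered atom table (chain, residue number, residue name,
#' atom name, element) plus an n x 3 coordinate matrix in Angstrom. Atom order
#' is significant: it is shared by every frame of any trajectory built on the
#' same topology, and `(chain, res_seq, atom_name)` must be unique.
#'
#' @param atoms data.frame with columns `chain`, `res_seq`, `res_name`,
#'   `atom_name` and optionally `element` (derived from the atom name when
#'   absent).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @return An object of class `trj_structure`.
#' @export
new_structure <- function(atoms, xyz) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("chain", "res_seq", "res_name", "atom_name")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0) {
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  }
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3) stop("xyz must be a numeric n x 3 matrix")
  if (nrow(xyz) != nrow(atoms)) stop("atom table and coordinate matrix differ in length")
  if (nrow(atoms) == 0) stop("empty structure: no atoms")
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  atoms$chain <- as.character(atoms$chain)
  atoms$res_seq <- as.integer(atoms$res_seq)
  atoms$res_name <- as.character(atoms$res_name)
  atoms$atom_name <- as.character(atoms$atom_name)
  if (is.null(atoms$element) || all(is.na(atoms$element)) || all(atoms$element == "")) {
    atoms$element <- guess_element(atoms$atom_name)
  }
  atoms$element <- as.character(atoms$element)
  key <- paste(atoms$chain, atoms$res_seq, atoms$atom_name, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (chain, res_seq, atom_name) entries: ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  }
  rownames(atoms) <- NULL
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz), class = "trj_structure")
}

# Element symbol from a PDB atom name: leading digits stripped, a leading 'H'
# (incl. 1HB-style names) means hydrogen, otherwise the first letter.
guess_element <- function(atom_name) {
  nm <- sub("^[0-9]+", "", trimws(atom_name))
  el <- substr(nm, 1, 1)
  el[el == ""] <- "X"
  el
}

#' Number of atoms in a structure
#' @param x a `trj_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  stopifnot(inherits(x, "trj_structure"))
  nrow(x$atoms)
}

#' @export
print.trj_structure <- function(x, ...) {
  cat(sprintf("<trj_structure> %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$res_seq))),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

#' Construct a trajectory object
#'
#' A trajectory is a frame-indexed stack of coordinate sets over one shared
#' topology, plus a frame-to-time mapping: frame f (0-based) occurs at time
#' `f * dt_ns`.
#'
#' @param topology a `trj_structure` giving the atom table.
#' @param coords numeric array `n_frames x n_atoms x 3` (Angstrom).
#' @param dt_ns time per frame in nanoseconds (> 0).
#' @param label trajectory label, e.g. `"MD1"`.
#' @return An object of class `trj_trajectory`.
#' @export
new_trajectory <- function(topology, coords, dt_ns, label = "traj") {
  stopifnot(inherits(topology, "trj_structure"))
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    stop("coords must be an n_frames x n_atoms x 3 array")
  }
  if (dim(coords)[2] != n_atoms(topology)) {
    stop("coords second dimension must equal the topology atom count")
  }
  if (!is.numeric(dt_ns) || length(dt_ns) != 1 || dt_ns <= 0) {
    stop("dt_ns must be a single positive number")
  }
  if (any(!is.finite(coords))) stop("trajectory coordinates must be finite")
  structure(list(topology = topology, coords = coords, dt_ns = dt_ns,
                 label = as.character(label)),
            class = "trj_trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `trj_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trj_trajectory"))
  dim(traj$coords)[1]
}

#' Frame times of a trajectory
#' @param traj a `trj_trajectory`.
#' @return numeric vector of times in ns (frame f at `f * dt_ns`, 0-based).
#' @export
frame_times <- function(traj) {
  (seq_len(n_frames(traj)) - 1) * traj$dt_ns
}

#' Extract one frame of a trajectory as a structure
#' @param traj a `trj_trajectory`.
#' @param frame 1-based frame index.
#' @return a `trj_structure`.
#' @export
frame_structure <- function(traj, frame) {
  stopifnot(frame >= 1, frame <= n_frames(traj))
  new_structure(traj$topology$atoms, traj$coords[frame, , , drop = TRUE])
}

#' Wrap a single structure as a one-frame trajectory
#'
#' Useful for scoring individual (e.g. crystal) structures with operations
#' defined on trajectories, such as [motion_map()].
#'
#' @param s a `trj_structure`.
#' @param dt_ns nominal time step (default 1 ns; irrelevant for one frame).
#' @param label trajectory label.
#' @return a one-frame `trj_trajectory`.
#' @export
as_one_frame_trajectory <- function(s, dt_ns = 1, label = "structure") {
  coords <- array(0, dim = c(1, n_atoms(s), 3))
  coords[1, , ] <- s$xyz
  new_trajectory(s, coords, dt_ns = dt_ns, label = label)
}

#' @export
print.trj_trajectory <- function(x, ...) {
  cat(sprintf("<trj_trajectory> '%s': %d frames x %d atoms, dt = %g ns (%g ns total)\n",
              x$label, n_frames(x), n_atoms(x$topology), x$dt_ns,
              (n_frames(x) - 1) * x$dt_ns))
  invisible(x)
}
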