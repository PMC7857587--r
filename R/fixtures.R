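## Deterministic synthetic-fixture generators: ideal backbone structures,
## toy rotamer-library bundles, two-state trajectories with exactly known
## inter-label distances, and noisy synthetic DEER form factors. All
## generators are pure functions of their arguments (fixed seed => identical
## output), so every pipeline stage is testable without external data.

# Canonical backbone triad shared by the toy library and the two-state
# trajectory builder (nm): CA at the origin, N along -x, C at 111 degrees.
.canonical_triad <- function() {
  rbind(N  = c(-0.1458, 0, 0),
        CA = c(0, 0, 0),
        C  = c(0.0546, 0.1424, 0))
}

#' Generate an ideal synthetic backbone structure
#'
#' Builds a poly-alanine-like backbone (N, CA, C, O, amide H, CB per
#' residue; six atoms each) on an ideal alpha-helix (2.3 Angstrom radius,
#' 100 degrees and 1.5 Angstrom rise per residue) or an extended zigzag, and
#' writes it as a PDB file parseable by [read_ensemble()].
#'
#' @param n_residues Number of residues (at least 3).
#' @param geometry \code{"helix"} (default) or \code{"extended"}.
#' @param file Output PDB path; a tempfile when \code{NULL}.
#' @param chain Chain identifier (default "A").
#' @return The PDB text as a character vector, invisibly carrying the path
#'   in attribute \code{path}.
#' @export
make_structure <- function(n_residues, geometry = c("helix", "extended"),
                           file = NULL, chain = "A") {
  geometry <- match.arg(geometry)
  stopifnot(n_residues >= 3)
  if (is.null(file)) file <- tempfile(fileext = ".pdb")
  ks <- 0:(n_residues + 1)
  if (geometry == "helix") {
    th <- ks * 100 * pi / 180
    ca <- cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * ks)
    u_out <- cbind(cos(th), sin(th), 0)
  } else {
    ca <- cbind(3.5 * ks, 1.2 * (-1)^ks, 0)
    u_out <- matrix(rep(c(0, 0, 1), each = length(ks)), ncol = 3)
  }
  unit <- function(v) v / sqrt(sum(v^2))
  coords <- NULL
  names_ <- c("N", "CA", "C", "O", "H", "CB")
  elements <- c("N", "C", "C", "O", "H", "C")
  for (k in seq_len(n_residues)) {
    i <- k + 1  # row in the extended ca table
    tvec <- unit(ca[i + 1, ] - ca[i - 1, ])
    b <- unit(pracma::cross(tvec, u_out[i, ]))
    N <- ca[i, ] + 0.38 * (ca[i - 1, ] - ca[i, ]) + 0.35 * b
    C <- ca[i, ] + 0.40 * (ca[i + 1, ] - ca[i, ]) + 0.35 * b
    O <- C + 1.23 * u_out[i, ]
    H <- N - 0.98 * b
    w <- unit(pracma::cross(N - ca[i, ], C - ca[i, ]))
    if (sum(w * u_out[i, ]) < 0) w <- -w
    CB <- ca[i, ] + 1.53 * w
    coords <- rbind(coords, N, ca[i, ], C, O, H, CB)
  }
  A <- 6 * n_residues
  atoms <- data.frame(name = rep(names_, n_residues),
                      element = rep(elements, n_residues),
                      stringsAsFactors = FALSE)
  .write_pdb_atoms(file, atoms, matrix(t(coords), nrow = 1),
                   resno = rep(seq_len(n_residues), each = 6),
                   chain = rep(chain, A),
                   resid = rep("ALA", A))
  txt <- readLines(file)
  attr(txt, "path") <- file
  invisible(txt)
}

#' Generate a toy rotamer library
#'
#' Builds a pseudo-nitroxide library for testing: a canonical backbone triad
#' plus a linear probe arm (CB, CG, nitroxide N1-O1) pointing roughly along
#' +z, with per-conformer directions jittered by \code{spread}. The chemistry
#' is schematic; only the data-model contract (triad, N-O pair, weights)
#' matters.
#'
#' @param R Number of conformers.
#' @param weights Intrinsic weights (uniform when \code{NULL}); normalized.
#' @param arm_length CA-to-nitroxide-N distance in nm (default 0.7,
#'   MTSSL-like).
#' @param spread Standard deviation (nm) of the positional jitter applied to
#'   the arm tip before renormalizing the arm direction (default 0.25).
#' @param seed RNG seed for the jitter (default 1).
#' @param directions Optional \code{R x 3} matrix of arm directions
#'   (normalized internally), overriding the random jitter.
#' @param name Library name (default "toy").
#' @param dir When given, the bundle (weights, topology, conformers,
#'   manifest) is also written there via [save_library()].
#' @return A \code{rotamer_library}.
#' @export
make_toy_library <- function(R, weights = NULL, arm_length = 0.7,
                             spread = 0.25, seed = 1, directions = NULL,
                             name = "toy", dir = NULL) {
  stopifnot(R >= 1)
  tri <- .canonical_triad()
  if (is.null(directions)) {
    set.seed(seed)
    directions <- t(vapply(seq_len(R), function(i) {
      j <- c(0, 0, arm_length) + stats::rnorm(3, 0, spread)
      if (j[3] < 0.2 * arm_length) j[3] <- 0.2 * arm_length + abs(j[3])
      j / sqrt(sum(j^2))
    }, numeric(3)))
  } else {
    directions <- as.matrix(directions)
    stopifnot(nrow(directions) == R, ncol(directions) == 3)
    directions <- directions / sqrt(rowSums(directions^2))
  }
  atoms <- data.frame(
    name = c("N", "CA", "C", "CB", "CG", "N1", "O1"),
    element = c("N", "C", "C", "C", "C", "N", "O"),
    stringsAsFactors = FALSE)
  coords <- array(0, c(R, 7, 3))
  for (i in seq_len(R)) {
    u <- directions[i, ]
    coords[i, 1:3, ] <- tri
    coords[i, 4, ] <- 0.153 * u
    coords[i, 5, ] <- 0.40 * u
    coords[i, 6, ] <- arm_length * u
    coords[i, 7, ] <- (arm_length + 0.125) * u
  }
  lib <- rotamer_library(name, atoms, coords,
                         weights %||% rep(1, R),
                         triad = 1:3, nitroxide = 6:7)
  if (!is.null(dir)) save_library(lib, dir)
  lib
}

#' Generate a two-state two-label trajectory with known distances
#'
#' Builds a minimal two-chain system (three residues per chain) and a
#' multi-model trajectory in which the inter-label paramagnetic-center
#' distance alternates between exactly \code{d1} (a fraction \code{f} of the
#' frames) and \code{d2}. Both sites use a single-conformer library whose arm
#' points along the inter-chain axis, so the ensemble P(r) must recover the
#' two distances with masses \code{f} and \code{1 - f}. Emulates two-state
#' conformational mixing resolved as separate P(r) peaks.
#'
#' @param f Fraction of frames in state 1; \code{f * n_frames} must be a
#'   whole number.
#' @param d1,d2 Center-center distances (nm) of the two states.
#' @param n_frames Number of frames (default 20).
#' @param arm_length Label arm length in nm (default 0.5).
#' @param dir Output directory (created; default a tempdir).
#' @return List with \code{topology} and \code{trajectory} paths, the
#'   single-rotamer \code{lib}, the labelled \code{residues} and
#'   \code{chains}, and the exact \code{center_offset} used.
#' @export
make_two_state_trajectory <- function(f = 0.5, d1 = 2, d2 = 4,
                                      n_frames = 20, arm_length = 0.5,
                                      dir = NULL) {
  stopifnot(f >= 0, f <= 1, d1 > 0, d2 > 0, n_frames >= 1)
  n1 <- f * n_frames
  if (abs(n1 - round(n1)) > 1e-9) {
    stop("f * n_frames must be a whole number for an exact two-state mix")
  }
  n1 <- round(n1)
  if (is.null(dir)) dir <- tempfile("twostate")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  lib <- make_toy_library(R = 1, arm_length = arm_length,
                          directions = matrix(c(0, 0, 1), 1),
                          name = "twostate_single")
  c0z <- arm_length + 0.125 / 2   # z of the N-O midpoint in canonical frame

  tri <- .canonical_triad()
  resblock <- function(off) {
    N <- tri[1, ] + off
    CA <- tri[2, ] + off
    C <- tri[3, ] + off
    O <- C + c(0, 0.123, 0)
    H <- N + c(0, -0.098, 0)
    CB <- CA + c(0, -0.089, -0.124)
    rbind(N, CA, C, O, H, CB)
  }
  chainA <- do.call(rbind, lapply(c(-0.38, 0, 0.38),
                                  function(x) resblock(c(x, 0, 0))))
  rx_pi <- diag(c(1, -1, -1))   # rotation by pi about x
  atoms <- data.frame(
    name = rep(c("N", "CA", "C", "O", "H", "CB"), 6),
    element = rep(c("N", "C", "C", "O", "H", "C"), 6),
    stringsAsFactors = FALSE)
  frame_xyz <- function(d) {
    chainB <- sweep(chainA %*% t(rx_pi), 2, c(0, 0, d + 2 * c0z), `+`)
    rbind(chainA, chainB) * 10   # nm -> Angstrom
  }
  d_per_frame <- c(rep(d1, n1), rep(d2, n_frames - n1))
  xyz <- t(vapply(d_per_frame, function(d) as.numeric(t(frame_xyz(d))),
                  numeric(36 * 3)))

  top <- file.path(dir, "twostate_top.pdb")
  traj <- file.path(dir, "twostate_traj.pdb")
  meta <- list(resno = rep(rep(1:3, each = 6), 2),
               chain = rep(c("A", "B"), each = 18),
               resid = rep("ALA", 36))
  .write_pdb_atoms(top, atoms, xyz[1, , drop = FALSE],
                   resno = meta$resno, chain = meta$chain, resid = meta$resid)
  .write_pdb_atoms(traj, atoms, xyz,
                   resno = meta$resno, chain = meta$chain, resid = meta$resid)
  list(topology = top, trajectory = traj, lib = lib,
       residues = c(2, 2), chains = c("A", "B"),
       f = f, d = c(d1, d2), center_offset = c0z)
}

#' Generate a synthetic DEER form factor with noise
#'
#' Back-calculates S(t) from a distance distribution, applies a modulation
#' depth and adds seeded Gaussian noise, producing the two-column series used
#' to exercise modulation-depth fitting.
#'
#' @param dist A \code{distance_distribution}.
#' @param lam True modulation depth.
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed RNG seed (default 1).
#' @param t_min,t_max,dt Time grid in microseconds.
#' @return Data frame with columns \code{t} and \code{V}.
#' @export
make_synthetic_trace <- function(dist, lam, noise_sd = 0, seed = 1,
                                 t_min = 0.01, t_max = 5.5, dt = 0.01) {
  t <- seq(t_min, t_max, by = dt)
  S <- dipolar_signal(dist, t)
  set.seed(seed)
  V <- 1 + lam * (S - 1) + stats::rnorm(length(t), 0, noise_sd)
  data.frame(t = t, V = V)
}

#' Write a DCD trajectory file
#'
#' Minimal CHARMM-format DCD writer (little-endian, no unit cell) used to
#' emit rotamer-library conformer bundles; output is readable by
#' \code{bio3d::read.dcd}.
#'
#' @param file Output path.
#' @param xyz Matrix of coordinates, one frame per row, columns
#'   \code{x1, y1, z1, x2, ...} in Angstrom.
#' @return The path, invisibly.
#' @export
write_dcd <- function(file, xyz) {
  xyz <- as.matrix(xyz)
  nf <- nrow(xyz)
  natom <- ncol(xyz) / 3
  stopifnot(natom == round(natom))
  con <- file(file, "wb")
  on.exit(close(con))
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L
  writeBin(84L, con, size = 4, endian = "little")
  writeChar("CORD", con, nchars = 4, eos = NULL)
  writeBin(icntrl, con, size = 4, endian = "little")
  writeBin(84L, con, size = 4, endian = "little")
  title <- sprintf("%-80s", "synthetic rotamer conformers")
  writeBin(84L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 4, endian = "little")
  writeChar(title, con, nchars = 80, eos = NULL)
  writeBin(84L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 4, endian = "little")
  writeBin(as.integer(natom), con, size = 4, endian = "little")
  writeBin(4L, con, size = 4, endian = "little")
  idx <- seq(1, 3 * natom, by = 3)
  for (f in seq_len(nf)) {
    for (d in 0:2) {
      writeBin(as.integer(4 * natom), con, size = 4, endian = "little")
      writeBin(xyz[f, idx + d], con, size = 4, endian = "little")
      writeBin(as.integer(4 * natom), con, size = 4, endian = "little")
    }
  }
  invisible(file)
}
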