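## Placement of rotamers at a labelled site: rigid superposition of the
## library backbone triad onto the site triad, steric (Lennard-Jones)
## external energies against the protein, and Boltzmann re-weighting with
## the steric partition function Z.

#' Describe a spin-labelled site
#'
#' @param resno Residue number as given in the input structure.
#' @param chain Chain identifier (single character) or \code{NA} for
#'   single-chain structures.
#' @param triad_coords 3 x 3 matrix of N, CA, C coordinates (rows, nm).
#' @return An object of class \code{labeled_site}.
#' @export
labeled_site <- function(resno, chain = NA, triad_coords) {
  triad_coords <- as.matrix(triad_coords)
  stopifnot(all(dim(triad_coords) == c(3, 3)))
  if (.triangle_area(triad_coords) <= 1e-6) {
    stop("collinear backbone triad at residue ", resno)
  }
  structure(list(resno = resno, chain = chain, triad = triad_coords),
            class = "labeled_site")
}

# Kabsch superposition of source points P onto target points Q (rows are
# points). Returns list(R, t) with x' = x %*% t(R) + t; reflections are
# excluded by flipping the sign of the smallest singular vector.
.kabsch <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(R = R, t = as.numeric(cq - cp %*% t(R)))
}

#' Superpose library rotamers onto a labelled site
#'
#' Each conformer is rigidly transformed (rotation plus translation, no
#' reflection or scaling) by the least-squares superposition of its backbone
#' (N, CA, C) triad onto the site triad.
#'
#' @param lib A \code{rotamer_library}.
#' @param site A \code{labeled_site}.
#' @return An \code{R x A x 3} array of transformed coordinates (nm), with an
#'   attribute \code{triad_rmsd} giving the post-fit triad RMSD per conformer.
#' @export
fit_rotamers <- function(lib, site) {
  if (.triangle_area(site$triad) <= 1e-6) stop("collinear site triad")
  R <- lib$n_rotamers
  out <- lib$coords
  rmsd <- numeric(R)
  for (i in seq_len(R)) {
    tri <- lib$coords[i, lib$triad, , drop = TRUE]
    tf <- .kabsch(tri, site$triad)
    xi <- matrix(lib$coords[i, , ], ncol = 3)
    out[i, , ] <- sweep(xi %*% t(tf$R), 2, tf$t, `+`)
    fitted_tri <- out[i, lib$triad, , drop = TRUE]
    rmsd[i] <- sqrt(mean(rowSums((fitted_tri - site$triad)^2)))
  }
  attr(out, "triad_rmsd") <- rmsd
  out
}

#' Lennard-Jones external energy of one placed conformer
#'
#' Sums the 6-12 Lennard-Jones energy over all pairs of rotamer heavy atoms
#' (excluding the backbone triad, which coincides with protein backbone atoms
#' after superposition) and environment heavy atoms within the cutoff.
#' Pair parameters follow Lorentz-Berthelot combination and sigma is scaled
#' by \code{sigma_scaling} before evaluation, softening the repulsive wall to
#' mimic protein relaxation around the probe. The result is converted from
#' kJ/mol to units of kT at the given temperature.
#'
#' @param conformer \code{A x 3} matrix of conformer coordinates (nm).
#' @param rot_elements Element symbols for the conformer atoms considered
#'   (heavy, non-triad).
#' @param rot_index Integer indices (rows of \code{conformer}) entering the
#'   energy; pass heavy non-triad atoms.
#' @param env \code{E x 3} matrix of environment heavy-atom coordinates (nm);
#'   may have zero rows.
#' @param env_elements Element symbols of the environment atoms.
#' @param lj Lennard-Jones table as from [lj_default_table()].
#' @param cutoff Pair-distance cutoff in nm (default 1.0).
#' @param sigma_scaling Scaling of sigma (default 0.5).
#' @param temperature Temperature in K for the kT conversion (default 298).
#' @return Scalar energy in kT.
#' @export
external_energy <- function(conformer, rot_elements, rot_index, env,
                            env_elements, lj = lj_default_table(),
                            cutoff = 1.0, sigma_scaling = 0.5,
                            temperature = 298) {
  stopifnot(temperature > 0, cutoff > 0,
            sigma_scaling > 0, sigma_scaling <= 1)
  if (length(rot_index) == 0 || is.null(env) || nrow(env) == 0) return(0)
  xi <- conformer[rot_index, , drop = FALSE]
  pr <- .lj_lookup(rot_elements, lj)
  pe <- .lj_lookup(env_elements, lj)
  # pairwise squared distances rotamer x environment
  d2 <- outer(rowSums(xi^2), rowSums(env^2), `+`) - 2 * (xi %*% t(env))
  d2[d2 < 0] <- 0
  within <- d2 <= cutoff^2 & d2 > 0
  if (!any(within)) return(0)
  sig <- sigma_scaling * outer(pr$sigma, pe$sigma, `+`) / 2
  eps <- sqrt(outer(pr$epsilon, pe$epsilon))
  s6 <- (sig[within]^2 / d2[within])^3
  e_kj <- sum(4 * eps[within] * (s6^2 - s6))   # kJ/mol
  e_kj / (.const$R_kJ * temperature)
}

#' Boltzmann re-weighting of rotamers by steric energy
#'
#' Combines intrinsic rotamer probabilities with external steric energies:
#' \eqn{Z = \sum_i p^{int}_i e^{-\epsilon^{ext}_i}} and
#' \eqn{p_i = p^{int}_i e^{-\epsilon^{ext}_i} / Z}. Z is the steric partition
#' function quantifying how well the probe fits at the site; low Z flags
#' clashes. Energies above 700 kT are treated as hard clashes (weight zero).
#'
#' @param p_int Intrinsic probabilities summing to one.
#' @param eps_ext External energies in kT (may be \code{Inf}).
#' @return List with \code{p} (posterior probabilities; empty when
#'   \code{Z = 0}) and \code{Z}.
#' @export
boltzmann_weights <- function(p_int, eps_ext) {
  stopifnot(length(p_int) == length(eps_ext),
            abs(sum(p_int) - 1) < 1e-6)
  w <- p_int * exp(-eps_ext)
  w[eps_ext > 700] <- 0
  Z <- sum(w)
  p <- if (Z > 0) w / Z else numeric(0)
  list(p = p, Z = Z)
}

#' Paramagnetic centers of placed rotamers
#'
#' The unpaired electron is located at the midpoint of the nitroxide N-O
#' bond of each conformer.
#'
#' @param conformers \code{R x A x 3} array of (transformed) coordinates (nm).
#' @param lib The \code{rotamer_library} providing the nitroxide indices.
#' @return \code{R x 3} matrix of center coordinates (nm).
#' @export
paramagnetic_centers <- function(conformers, lib) {
  n <- matrix(conformers[, lib$nitroxide[1], ], ncol = 3)
  o <- matrix(conformers[, lib$nitroxide[2], ], ncol = 3)
  (n + o) / 2
}

# Full placement at one site of one frame: fit, energies, weights, centers.
# env is a list(coords, elements) of protein heavy atoms excluding the
# labelled residue's side chain.
.place_rotamers <- function(lib, site, env, lj = lj_default_table(),
                            cutoff = 1.0, sigma_scaling = 0.5,
                            temperature = 298, frame = 1L) {
  fitted <- fit_rotamers(lib, site)
  keep <- which(lib$atoms$heavy & !(seq_len(nrow(lib$atoms)) %in% lib$triad))
  eps <- vapply(seq_len(lib$n_rotamers), function(i) {
    external_energy(matrix(fitted[i, , ], ncol = 3),
                    lib$atoms$element[keep], keep,
                    env$coords, env$elements, lj,
                    cutoff, sigma_scaling, temperature)
  }, numeric(1))
  bw <- boltzmann_weights(lib$p_int, eps)
  centers <- paramagnetic_centers(fitted, lib)
  structure(list(centers = centers, eps_ext = eps, p = bw$p, Z = bw$Z,
                 site = site, frame = frame),
            class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat("Placement at residue ", x$site$resno,
      if (!is.na(x$site$chain)) paste0(" chain ", x$site$chain) else "",
      " (frame ", x$frame, "): Z = ", signif(x$Z, 5), "\n", sep = "")
  invisible(x)
}

#' Scan candidate residues by steric partition function
#'
#' Places the rotamer library at each candidate residue of a structure frame
#' and reports the steric partition function Z. Sites where the probe cannot
#' be accommodated yield low Z; the scan is the standard way to shortlist
#' positions for site-directed spin labeling. Per-residue failures (e.g.
#' missing backbone atoms) are recorded and the scan continues.
#'
#' @param ensemble An ensemble object from [read_ensemble()].
#' @param residues Integer vector of candidate residue numbers.
#' @param lib A \code{rotamer_library}.
#' @param chain Chain identifier or \code{NA}.
#' @param frame Frame index (default 1).
#' @param lj,cutoff,sigma_scaling,temperature Energy parameters as in
#'   [external_energy()].
#' @return Data frame with columns \code{resno}, \code{Z} (\code{NA} where
#'   placement failed) and \code{error} (failure message or \code{NA}).
#' @export
site_z_scan <- function(ensemble, residues, lib, chain = NA, frame = 1L,
                        lj = lj_default_table(), cutoff = 1.0,
                        sigma_scaling = 0.5, temperature = 298) {
  Z <- rep(NA_real_, length(residues))
  err <- rep(NA_character_, length(residues))
  for (k in seq_along(residues)) {
    res <- tryCatch({
      site <- site_from_frame(ensemble, residues[k], chain, frame)
      env <- environment_atoms(ensemble, residues[k], chain, frame)
      .place_rotamers(lib, site, env, lj, cutoff, sigma_scaling,
                      temperature, frame)$Z
    }, error = function(e) e)
    if (inherits(res, "error")) err[k] <- conditionMessage(res) else Z[k] <- res
  }
  data.frame(resno = residues, Z = Z, error = err, stringsAsFactors = FALSE)
}
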