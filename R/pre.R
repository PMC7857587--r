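## PRE back-calculation: electron-proton distances from rotamer placements,
## model-free order parameters factored into radial and angular parts,
## Solomon-Bloembergen transverse relaxation rates, ensemble averaging and
## HSQC intensity ratios.

#' PRE model parameters
#'
#' Correlation times and experimental settings entering the
#' Solomon-Bloembergen spectral density and the intensity-ratio estimate.
#' \code{tau_c} is the effective correlation time (dominated by protein
#' tumbling for nitroxide labels; typically 1-10 ns) and \code{tau_t} the
#' total correlation time including the internal label motion, so
#' \code{tau_t <= tau_c} must hold.
#'
#' @param tau_c Effective correlation time in seconds.
#' @param tau_t Total internal correlation time in seconds.
#' @param delay INEPT delay t_d of the HSQC measurement in seconds
#'   (default 1e-2).
#' @param r2_dia Transverse relaxation rate of the diamagnetic (reduced)
#'   state in 1/s (default 12.6).
#' @param larmor_MHz Proton Larmor frequency in MHz (default 750).
#' @return An object of class \code{pre_parameters}.
#' @export
pre_parameters <- function(tau_c, tau_t, delay = 1e-2, r2_dia = 12.6,
                           larmor_MHz = 750) {
  stopifnot(tau_c > 0, tau_t > 0, delay >= 0, r2_dia >= 0, larmor_MHz > 0)
  if (tau_t > tau_c) {
    stop("tau_t (", tau_t, " s) must not exceed tau_c (", tau_c, " s)")
  }
  structure(list(tau_c = tau_c, tau_t = tau_t, delay = delay,
                 r2_dia = r2_dia, larmor_MHz = larmor_MHz,
                 omega_I = 2 * pi * larmor_MHz * 1e6, s_e = 0.5),
            class = "pre_parameters")
}

#' Electron-proton distances and directions for one placement
#'
#' Distances (and unit vectors) from each target amide proton to the
#' paramagnetic center of every placed rotamer.
#'
#' @param placement A \code{placement_result} with \code{Z > 0}.
#' @param protons Data frame with columns \code{resno} and \code{x, y, z}
#'   (nm) of the amide protons.
#' @return List with \code{resno}, distance matrix \code{r}
#'   (residues x rotamers, nm) and unit-vector array \code{u}
#'   (residues x rotamers x 3; proton-to-center direction).
#' @export
electron_proton_distances <- function(placement, protons) {
  stopifnot(placement$Z > 0, nrow(protons) > 0)
  centers <- placement$centers
  R <- nrow(centers)
  n <- nrow(protons)
  r <- matrix(0, n, R)
  u <- array(0, c(n, R, 3))
  H <- as.matrix(protons[, c("x", "y", "z")])
  for (i in seq_len(R)) {
    dvec <- sweep(H, 2, centers[i, ], `-`) * -1   # H -> center
    ri <- sqrt(rowSums(dvec^2))
    r[, i] <- ri
    u[, i, ] <- dvec / ri
  }
  list(resno = protons$resno, r = r, u = u)
}

#' Model-free order parameters for a discrete rotamer ensemble
#'
#' Treats the rotamer states as a discrete jump model and factors the
#' generalized order parameter into radial and angular parts:
#' \deqn{S^2_{radial} = \langle r^{-3}\rangle^2 / \langle r^{-6}\rangle,
#'  \quad S^2_{angular} = \sum_{i,j} [\tfrac{3}{2}\cos^2\Omega_{ij} -
#'  \tfrac12]\, p_i p_j,}
#' with \eqn{\Omega_{ij}} the angle between the proton-to-center vectors of
#' rotamers i and j and averages weighted by the rotamer probabilities.
#'
#' @param r Length-R distances (nm), all positive.
#' @param u \code{R x 3} matrix of unit vectors (proton to center).
#' @param p Rotamer probabilities summing to one.
#' @return List with \code{s2_radial}, \code{s2_angular},
#'   \code{mean_r3inv} (1/nm^3) and \code{mean_r6inv} (1/nm^6).
#' @export
order_parameters <- function(r, u, p) {
  stopifnot(length(r) == length(p), abs(sum(p) - 1) < 1e-6)
  if (any(r <= 0)) stop("degenerate geometry: zero electron-proton distance")
  u <- matrix(u, ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  m3 <- sum(p * r^-3)
  m6 <- sum(p * r^-6)
  cosm <- u %*% t(u)
  s2a <- sum((1.5 * cosm^2 - 0.5) * (p %o% p))
  list(s2_radial = m3^2 / m6, s2_angular = s2a,
       mean_r3inv = m3, mean_r6inv = m6)
}

# Solomon-Bloembergen prefactor (SI): (1/15) (mu0/4pi)^2 gammaI^2 g^2 muB^2
# s(s+1), with s = 1/2.
.sb_prefactor <- function(s_e = 0.5) {
  (1 / 15) * (.const$mu0 / (4 * pi))^2 * .const$gamma_H^2 *
    .const$g_e^2 * .const$mu_B^2 * s_e * (s_e + 1)
}

#' Transverse PRE rate from Solomon-Bloembergen theory
#'
#' \deqn{\Gamma_2 = \frac{1}{15}\left(\frac{\mu_0}{4\pi}\right)^2
#'   \gamma_I^2 g^2 \mu_B^2\, s_e(s_e+1)\,[4 J(0) + 3 J(\omega_I)]}
#' with the model-free spectral density
#' \deqn{J(\omega) = \langle r^{-6}\rangle\left[\frac{S^2 \tau_c}
#'   {1 + \omega^2\tau_c^2} + \frac{(1 - S^2)\,\tau_t}
#'   {1 + \omega^2\tau_t^2}\right].}
#'
#' @param mean_r6inv \eqn{\langle r^{-6}\rangle} in 1/nm^6.
#' @param s2 Generalized order parameter in [0, 1].
#' @param params A \code{pre_parameters} object.
#' @return Rate in 1/s.
#' @export
gamma2 <- function(mean_r6inv, s2, params) {
  stopifnot(mean_r6inv > 0, s2 >= 0, s2 <= 1 + 1e-12)
  r6_SI <- mean_r6inv * 1e54   # nm^-6 -> m^-6
  J <- function(w) {
    r6_SI * (s2 * params$tau_c / (1 + w^2 * params$tau_c^2) +
             (1 - s2) * params$tau_t / (1 + w^2 * params$tau_t^2))
  }
  .sb_prefactor(params$s_e) * (4 * J(0) + 3 * J(params$omega_I))
}

#' Ensemble average of per-frame PRE rates
#'
#' Frames whose steric partition function is below \code{z_cutoff} are
#' excluded; the remaining frame weights are renormalized (uniform when
#' absent) and \eqn{\langle\Gamma_2\rangle = \sum_k w_k \Gamma_{2,k}} is
#' returned per residue. If every frame is excluded the result is a row of
#' \code{NA} (a missing-value marker, not an error).
#'
#' @param per_frame Matrix of rates, frames x residues (may contain
#'   \code{NA}).
#' @param weights Optional per-frame weights.
#' @param z_values Per-frame steric partition functions.
#' @param z_cutoff Exclusion threshold (default 0.05).
#' @return Numeric vector of ensemble rates, one per residue.
#' @export
ensemble_gamma2 <- function(per_frame, weights = NULL, z_values = NULL,
                            z_cutoff = 0.05) {
  per_frame <- as.matrix(per_frame)
  M <- nrow(per_frame)
  if (!is.null(weights) && length(weights) != M) {
    stop("weight list length does not match frame count")
  }
  keep <- rep(TRUE, M)
  if (!is.null(z_values)) keep <- z_values >= z_cutoff
  if (!any(keep)) return(rep(NA_real_, ncol(per_frame)))
  w <- if (is.null(weights)) rep(1, M) else weights
  w[!keep] <- 0
  w <- w / sum(w)
  idx <- which(w > 0)
  colSums(per_frame[idx, , drop = FALSE] * w[idx])
}

#' HSQC intensity ratio from a PRE rate
#'
#' Assuming exponential decay of proton magnetization by transverse
#' relaxation during the INEPT transfers,
#' \deqn{I_{para}/I_{dia} = \frac{R_2^{red}\, e^{-\Gamma_2 t_d}}
#'   {R_2^{red} + \Gamma_2}.}
#' Missing rates propagate to missing ratios.
#'
#' @param g2 PRE rate(s) in 1/s, non-negative or \code{NA}.
#' @param params A \code{pre_parameters} object.
#' @return Ratio(s) in [0, 1].
#' @export
intensity_ratio <- function(g2, params) {
  ifelse(is.na(g2), NA_real_,
         params$r2_dia * exp(-g2 * params$delay) / (params$r2_dia + g2))
}

#' PRE rates with the C-beta electron approximation
#'
#' Places the unpaired electron at the C-beta atom of the labelled residue in
#' every frame instead of modelling the probe explicitly. With a single
#' electron position the order parameter is 1, so only \code{tau_c} enters
#' the spectral density. Provided for side-by-side comparison with the
#' rotamer-library mode; glycine sites (no C-beta) are rejected.
#'
#' @param ensemble An ensemble object from [read_ensemble()].
#' @param residue Labelled residue number.
#' @param params A \code{pre_parameters} object.
#' @param chain Chain identifier or \code{NA}.
#' @param weights Optional frame weights.
#' @param stride Frame stride (default 1).
#' @return Object of class \code{pre_result} (see [run_pre()]).
#' @export
cbeta_gamma2 <- function(ensemble, residue, params, chain = NA,
                         weights = NULL, stride = 1L) {
  frames <- iterate_frames(ensemble, stride)
  protons0 <- amide_protons(ensemble, residue, chain, frames[1])
  nres <- nrow(protons0)
  g2 <- matrix(NA_real_, length(frames), nres)
  for (k in seq_along(frames)) {
    cb <- .atom_coord(ensemble, residue, chain, "CB", frames[k])
    if (is.null(cb)) {
      stop("residue ", residue, " has no CB atom (glycine site?); ",
           "the C-beta approximation is unsupported here")
    }
    protons <- amide_protons(ensemble, residue, chain, frames[k])
    H <- as.matrix(protons[, c("x", "y", "z")])
    r <- sqrt(rowSums(sweep(H, 2, cb, `-`)^2))
    g2[k, ] <- vapply(r, function(ri) gamma2(ri^-6, 1, params), numeric(1))
  }
  g2_mean <- ensemble_gamma2(g2, weights)
  .pre_result(protons0$resno, g2_mean, intensity_ratio(g2_mean, params),
              g2, rep(1, length(frames)), params, residue, chain,
              mode = "cbeta")
}

.pre_result <- function(resno, g2_mean, ratio, per_frame, z, params,
                        residue, chain, mode) {
  structure(list(
    residues = data.frame(resno = resno, gamma2 = g2_mean, ratio = ratio),
    per_frame = per_frame, Z = z, params = params,
    site = list(resno = residue, chain = chain), mode = mode),
    class = "pre_result")
}

#' @export
print.pre_result <- function(x, ...) {
  cat("PRE prediction (", x$mode, " mode) for label at residue ",
      x$site$resno, ": ", nrow(x$residues), " target residues, ",
      nrow(as.matrix(x$per_frame)), " frames\n", sep = "")
  invisible(x)
}
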