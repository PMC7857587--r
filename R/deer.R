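## DEER back-calculation: electron-electron distance distributions from
## rotamer placements, Gaussian low-pass filtering, and the dipolar signal
## S(t) / form factor V(t) through the Fresnel-integral kernel.

#' Distance-distribution container
#'
#' P(r) on a uniform grid of half-open bins \eqn{[k\,dr, (k+1)\,dr)} covering
#' \eqn{[0, r_{max})}; \code{r} holds bin centers and \code{density} the
#' probability density (1/nm), so \code{sum(density) * dr = 1} whenever any
#' mass is present.
#'
#' @param density Density values (1/nm), one per bin.
#' @param r_max Grid upper limit in nm (default 12).
#' @param dr Bin width in nm (default 0.05).
#' @return An object of class \code{distance_distribution}.
#' @export
distance_distribution <- function(density, r_max = 12, dr = 0.05) {
  n <- round(r_max / dr)
  stopifnot(length(density) == n, all(density >= 0))
  structure(list(r = (seq_len(n) - 0.5) * dr, density = density,
                 dr = dr, r_max = r_max),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  m <- sum(x$density) * x$dr
  cat("Distance distribution on [0, ", x$r_max, ") nm, dr = ", x$dr,
      " nm; integral = ", signif(m, 6), sep = "")
  if (m > 0) {
    cat(", mode = ", x$r[which.max(x$density)], " nm", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Single-frame electron-electron distance histogram
#'
#' For every rotamer pair (i at site A, j at site B) deposits the combined
#' probability \eqn{p_i p_j} into the distance bin containing the separation
#' of the two paramagnetic centers. Distances at or beyond \code{r_max} are
#' dropped with a warning.
#'
#' @param placement_a,placement_b \code{placement_result} objects with
#'   \code{Z > 0}.
#' @param r_max,dr Grid parameters in nm.
#' @return A \code{distance_distribution} for the frame.
#' @export
frame_distribution <- function(placement_a, placement_b, r_max = 12,
                               dr = 0.05) {
  stopifnot(placement_a$Z > 0, placement_b$Z > 0)
  ca <- placement_a$centers
  cb <- placement_b$centers
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), `+`) - 2 * (ca %*% t(cb))
  d <- sqrt(pmax(d2, 0))
  w <- placement_a$p %o% placement_b$p
  n <- round(r_max / dr)
  idx <- floor(d / dr) + 1
  drop <- idx > n
  if (any(drop)) {
    warning(sprintf("%.3g of pair probability at distances >= r_max dropped",
                    sum(w[drop])))
  }
  dens <- numeric(n)
  keep <- !drop
  if (any(keep)) {
    acc <- tapply(w[keep], idx[keep], sum)
    dens[as.integer(names(acc))] <- acc
    s <- sum(dens)
    if (s > 0) dens <- dens / s / dr
  }
  distance_distribution(dens, r_max, dr)
}

#' Ensemble average of per-frame distance distributions
#'
#' Frames whose smaller steric partition function is below \code{z_cutoff}
#' are excluded (a low Z marks protein conformations that cannot accommodate
#' the probe); the remaining frame weights are renormalized (uniform when
#' absent) and the densities averaged.
#'
#' @param per_frame List of \code{distance_distribution} objects.
#' @param weights Optional frame weights (same length as \code{per_frame}).
#' @param z_pairs Matrix with one row per frame and columns \code{Z_A},
#'   \code{Z_B} (a single column is accepted for one-label work).
#' @param z_cutoff Exclusion threshold (default 0.05).
#' @return The ensemble \code{distance_distribution}.
#' @export
ensemble_distribution <- function(per_frame, weights = NULL, z_pairs = NULL,
                                  z_cutoff = 0.05) {
  M <- length(per_frame)
  stopifnot(M >= 1)
  if (!is.null(weights) && length(weights) != M) {
    stop("weight list length (", length(weights),
         ") does not match frame count (", M, ")")
  }
  keep <- rep(TRUE, M)
  if (!is.null(z_pairs)) {
    zmin <- apply(as.matrix(z_pairs), 1, min)
    keep <- zmin >= z_cutoff
  }
  if (!any(keep)) {
    stop("all ", M, " frames excluded by the Z cutoff ", z_cutoff)
  }
  w <- if (is.null(weights)) rep(1, M) else weights
  w[!keep] <- 0
  w <- w / sum(w)
  tmpl <- per_frame[[1]]
  dens <- Reduce(`+`, Map(function(f, wk) wk * f$density, per_frame, w))
  distance_distribution(dens, tmpl$r_max, tmpl$dr)
}

#' Gaussian low-pass filter of a distance distribution
#'
#' Convolves the density with a unit-area Gaussian of standard deviation
#' \code{filter_stdev} (truncated at 6 sigma) and renormalizes to unit
#' integral, suppressing the discreteness of the finite rotamer pool.
#' \code{filter_stdev = 0} is the identity.
#'
#' @param dist A \code{distance_distribution}.
#' @param filter_stdev Gaussian standard deviation in nm (default 0.05).
#' @return The filtered \code{distance_distribution}.
#' @export
lowpass_filter <- function(dist, filter_stdev = 0.05) {
  stopifnot(filter_stdev >= 0)
  if (filter_stdev == 0) return(dist)
  dr <- dist$dr
  h <- ceiling(6 * filter_stdev / dr)
  kern <- stats::dnorm(seq(-h, h) * dr, 0, filter_stdev)
  kern <- kern / sum(kern)
  full <- stats::convolve(dist$density, rev(kern), type = "open")
  dens <- full[(h + 1):(h + length(dist$density))]
  dens[dens < 0] <- 0  # FFT round-off
  s <- sum(dens) * dr
  if (s > 0) dens <- dens / s
  distance_distribution(dens, dist$r_max, dr)
}

#' Electron-electron dipolar frequency
#'
#' \eqn{\omega = (\mu_0 / 4\pi)\, g^2 \mu_B^2 / (\hbar r^3)}: the angular
#' frequency of the secular dipolar coupling between two unpaired electrons
#' at separation r. At r = 1 nm, \eqn{\omega / 2\pi \approx 52.04} MHz.
#'
#' @param r Separation(s) in nm, positive.
#' @return Angular frequency in rad/s.
#' @export
dipolar_frequency <- function(r) {
  if (any(r <= 0)) stop("dipolar frequency requires r > 0")
  (.const$mu0 / (4 * pi)) * .const$g_e^2 * .const$mu_B^2 /
    (.const$hbar * (r * 1e-9)^3)
}

#' DEER kernel
#'
#' Powder-averaged dipolar modulation
#' \eqn{K(r,t) = \int_0^1 \cos[(3x^2 - 1)\,\omega t]\,dx}, evaluated in
#' closed form through Fresnel integrals:
#' \deqn{K = \sqrt{\pi/(6\omega t)}\,[\cos(\omega t)\,C(z) +
#'   \sin(\omega t)\,S(z)], \quad z = \sqrt{6\omega t/\pi}.}
#' \eqn{K(r, 0) = 1} by continuity and \eqn{|K| \le 1} everywhere.
#'
#' @param r Separation in nm (scalar, positive).
#' @param t Time(s) in microseconds, non-negative.
#' @return Kernel values, one per element of \code{t}.
#' @export
deer_kernel <- function(r, t) {
  stopifnot(r > 0, all(t >= 0))
  x <- dipolar_frequency(r) * t * 1e-6
  K <- rep(1, length(x))
  nz <- x > 1e-10
  if (any(nz)) {
    xn <- x[nz]
    z <- sqrt(6 * xn / pi)
    K[nz] <- sqrt(pi / (6 * xn)) *
      (cos(xn) * pracma::fresnelC(z) + sin(xn) * pracma::fresnelS(z))
  }
  K
}

#' Dipolar signal from a distance distribution
#'
#' \eqn{S(t) = \int P(r) K(r, t)\,dr}, evaluated by trapezoidal quadrature on
#' the distribution's uniform grid, restricted to bins carrying probability
#' mass.
#'
#' @param dist A \code{distance_distribution} with unit integral.
#' @param t Time grid in microseconds.
#' @return Vector S(t).
#' @export
dipolar_signal <- function(dist, t) {
  n <- length(dist$density)
  wt <- rep(dist$dr, n)
  wt[c(1, n)] <- dist$dr / 2
  idx <- which(dist$density > 0)
  if (length(idx) == 0) return(rep(0, length(t)))
  S <- numeric(length(t))
  for (k in idx) {
    S <- S + dist$density[k] * wt[k] * deer_kernel(dist$r[k], t)
  }
  S
}

#' Form factor from dipolar signal and modulation depth
#'
#' \eqn{V(t) = 1 + \lambda\,[S(t) - 1]}, where the modulation depth
#' \eqn{\lambda} quantifies the efficiency of the DEER pump pulse and is
#' physically constrained to \eqn{[0.02, 0.5]}.
#'
#' @param S Dipolar signal.
#' @param lam Modulation depth in [0.02, 0.5].
#' @return Vector V(t).
#' @export
form_factor <- function(S, lam) {
  if (lam < 0.02 || lam > 0.5) {
    stop("modulation depth must lie in [0.02, 0.5], got ", lam)
  }
  1 + lam * (S - 1)
}

#' Fit the modulation depth to an experimental form factor
#'
#' Least-squares estimate of \eqn{\lambda} matching a predicted dipolar
#' signal to a background-corrected experimental form factor:
#' \eqn{\hat\lambda = \sum (V - 1)(S - 1) / \sum (S - 1)^2}, with the
#' predicted S linearly interpolated to the experimental time points. The
#' estimate is clipped to [0.02, 0.5] with a warning.
#'
#' @param exp_t,exp_v Experimental time (microseconds) and form-factor values.
#' @param pred_t,pred_s Predicted time grid and dipolar signal.
#' @return The fitted modulation depth.
#' @export
fit_modulation_depth <- function(exp_t, exp_v, pred_t, pred_s) {
  s <- stats::approx(pred_t, pred_s, xout = exp_t, rule = 2)$y
  denom <- sum((s - 1)^2)
  if (denom < 1e-12) stop("predicted signal is constant; cannot fit lambda")
  lam <- sum((exp_v - 1) * (s - 1)) / denom
  if (lam < 0.02 || lam > 0.5) {
    clipped <- min(max(lam, 0.02), 0.5)
    warning(sprintf("fitted modulation depth %.4g outside [0.02, 0.5]; clipped to %.2g",
                    lam, clipped))
    lam <- clipped
  }
  lam
}

#' Assemble a DEER time trace
#'
#' @param dist A filtered \code{distance_distribution}.
#' @param lam Modulation depth.
#' @param t_min,t_max,dt Time grid in microseconds (defaults 0.01, 5.5, 0.01;
#'   endpoints inclusive).
#' @return Object of class \code{deer_trace} with \code{t}, \code{S},
#'   \code{V} and \code{lam}.
#' @export
deer_trace <- function(dist, lam = 0.5, t_min = 0.01, t_max = 5.5,
                       dt = 0.01) {
  t <- seq(t_min, t_max, by = dt)
  S <- dipolar_signal(dist, t)
  structure(list(t = t, S = S, V = form_factor(S, lam), lam = lam),
            class = "deer_trace")
}

#' @export
print.deer_trace <- function(x, ...) {
  cat("DEER trace: t in [", min(x$t), ", ", max(x$t), "] us (",
      length(x$t), " points), lambda = ", x$lam, "\n", sep = "")
  invisible(x)
}
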