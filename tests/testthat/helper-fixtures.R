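# Shared fixture builders. All are deterministic so expected values frozen
# in the tests stay valid.

# A small helix ensemble written once per test run.
helix_ensemble <- local({
  cache <- new.env()
  function(n = 10) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      txt <- make_structure(n, "helix")
      cache[[key]] <- read_ensemble(attr(txt, "path"))
    }
    cache[[key]]
  }
})

# Single-conformer library with the arm along a fixed direction.
single_lib <- function(direction = c(0, 0, 1), arm_length = 0.5) {
  make_toy_library(R = 1, directions = matrix(direction, 1),
                   arm_length = arm_length)
}

# A random unit-norm rotation matrix (no reflection), seeded.
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Brute-force quadrature oracle for the DEER kernel.
kernel_oracle <- function(r, t) {
  omega <- dipolar_frequency(r)
  vapply(t, function(tk) {
    stats::integrate(function(x) cos((3 * x^2 - 1) * omega * tk * 1e-6),
                     0, 1, rel.tol = 1e-10, subdivisions = 5000L)$value
  }, numeric(1))
}

# A normalized random distance distribution on the default grid.
random_distribution <- function(seed, r_max = 12, dr = 0.05) {
  set.seed(seed)
  n <- round(r_max / dr)
  dens <- runif(n)
  # keep mass away from the grid edges as physical distributions are
  dens[c(1:20, (n - 19):n)] <- 0
  dens <- dens / sum(dens) / dr
  distance_distribution(dens, r_max, dr)
}
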