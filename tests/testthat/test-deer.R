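make_placement <- function(centers, p) {
  structure(list(centers = matrix(centers, ncol = 3), p = p, Z = 1,
                 eps_ext = rep(0, length(p)),
                 site = NULL, frame = 1L),
            class = "placement_result")
}

test_that("frame histograms deposit pair probabilities into the right bins", {
  # single rotamer per site at 3.00 nm: all mass in bin [3.00, 3.05)
  pa <- make_placement(c(0, 0, 0), 1)
  pb <- make_placement(c(3, 0, 0), 1)
  h <- frame_distribution(pa, pb)
  expect_equal(sum(h$density) * h$dr, 1)
  expect_equal(h$density[round(3 / 0.05) + 1] * h$dr, 1)

  # two equiprobable A rotamers at 2 and 4 nm from the single B rotamer
  pa2 <- make_placement(rbind(c(2, 0, 0), c(4, 0, 0)), c(0.5, 0.5))
  pb2 <- make_placement(c(0, 0, 0), 1)
  h2 <- frame_distribution(pa2, pb2)
  mass <- h2$density * h2$dr
  expect_equal(mass[round(2 / 0.05) + 1], 0.5)
  expect_equal(mass[round(4 / 0.05) + 1], 0.5)
  expect_equal(sum(mass), 1)
})

test_that("frame histogram equals a brute-force double loop over pairs", {
  set.seed(21)
  ca <- matrix(runif(15, 0, 2), 5)
  cb <- matrix(runif(15, 2, 5), 5)
  pa <- make_placement(ca, {w <- runif(5); w / sum(w)})
  pb <- make_placement(cb, {w <- runif(5); w / sum(w)})
  h <- frame_distribution(pa, pb)

  oracle <- numeric(length(h$density))
  for (i in 1:5) {
    for (j in 1:5) {
      d <- sqrt(sum((ca[i, ] - cb[j, ])^2))
      k <- floor(d / h$dr) + 1
      oracle[k] <- oracle[k] + pa$p[i] * pb$p[j]
    }
  }
  expect_equal(h$density, oracle / h$dr, tolerance = 1e-12)
})

test_that("distances beyond the grid are dropped with a warning", {
  pa <- make_placement(rbind(c(0, 0, 0), c(0, 0, 0.05)), c(0.5, 0.5))
  pb <- make_placement(rbind(c(3, 0, 0), c(20, 0, 0)), c(0.5, 0.5))
  expect_warning(h <- frame_distribution(pa, pb), "r_max")
  expect_equal(sum(h$density) * h$dr, 1)  # renormalized over kept mass
})

test_that("ensemble averaging honors weights and the Z cutoff", {
  h1 <- random_distribution(31)
  h2 <- random_distribution(32)
  h3 <- random_distribution(33)

  # one frame: identity
  e1 <- ensemble_distribution(list(h1))
  expect_equal(e1$density, h1$density)

  # uniform explicit weights match absent weights
  ew <- ensemble_distribution(list(h1, h1), weights = c(0.5, 0.5))
  ea <- ensemble_distribution(list(h1, h1))
  expect_equal(ew$density, ea$density)

  # Z filtering: frame 1 excluded, output is the mean of frames 2 and 3
  z <- cbind(c(0.01, 0.5, 0.5), c(0.9, 0.9, 0.9))
  e <- ensemble_distribution(list(h1, h2, h3), z_pairs = z, z_cutoff = 0.05)
  expect_equal(e$density, (h2$density + h3$density) / 2, tolerance = 1e-12)

  # all frames excluded is an informative error
  expect_error(
    ensemble_distribution(list(h1), z_pairs = cbind(0.01, 0.9),
                          z_cutoff = 0.05),
    "Z cutoff 0.05")
  # weight-length mismatch rejected
  expect_error(ensemble_distribution(list(h1, h2), weights = 1), "length")
})

test_that("the low-pass filter is a unit-area Gaussian convolution", {
  # filtering a delta yields a discrete Gaussian of the right width
  n <- 240
  dens <- numeric(n)
  dens[round(3 / 0.05) + 1] <- 1 / 0.05
  delta <- distance_distribution(dens)
  f <- lowpass_filter(delta, 0.1)
  expect_equal(sum(f$density) * f$dr, 1, tolerance = 1e-9)
  mu <- sum(f$r * f$density) * f$dr
  sdev <- sqrt(sum((f$r - mu)^2 * f$density) * f$dr)
  expect_equal(sdev, 0.1, tolerance = 0.02 * 0.1 + 1e-4)

  # zero width is the identity
  expect_equal(lowpass_filter(delta, 0)$density, delta$density)

  # matches a naive O(n^2) convolution with the same truncated kernel
  d <- random_distribution(41)
  sig <- 0.05
  f2 <- lowpass_filter(d, sig)
  h <- ceiling(6 * sig / d$dr)
  kern <- dnorm(seq(-h, h) * d$dr, 0, sig)
  kern <- kern / sum(kern)
  naive <- numeric(length(d$density))
  for (i in seq_along(naive)) {
    for (k in -h:h) {
      j <- i - k
      if (j >= 1 && j <= length(naive)) {
        naive[i] <- naive[i] + d$density[j] * kern[k + h + 1]
      }
    }
  }
  naive <- naive / (sum(naive) * d$dr)
  expect_lt(max(abs(f2$density - naive)), 1e-9)
})

test_that("the dipolar frequency has the CODATA value and r^-3 scaling", {
  expect_error(dipolar_frequency(0), "r > 0")
  expect_equal(dipolar_frequency(1.3) / dipolar_frequency(2.6), 8)

  # independent evaluation of the dipolar constant at r = 1 nm
  cst <- spin_constants()
  oracle_MHz <- 1e-7 * cst$g_e^2 * cst$mu_B^2 /
    (cst$hbar * 1e-27) / (2 * pi) / 1e6
  expect_equal(dipolar_frequency(1) / (2 * pi) / 1e6, oracle_MHz,
               tolerance = 1e-12)
  expect_equal(oracle_MHz, 52.04, tolerance = 0.001 * 52.04)
  expect_equal(dipolar_frequency(2) / (2 * pi) / 1e6, 6.505,
               tolerance = 0.001 * 6.505)
})

test_that("the Fresnel kernel matches the quadrature oracle", {
  # short-time limit and global bound
  expect_equal(deer_kernel(3, 1e-9), 1, tolerance = 1e-6)
  expect_equal(deer_kernel(3, 0), 1)
  set.seed(51)
  for (r in runif(5, 1, 8)) {
    expect_true(all(abs(deer_kernel(r, runif(20, 0, 6))) <= 1 + 1e-12))
  }
  # 20-point grid against direct numerical integration
  for (r in c(1.5, 2, 3, 5, 8)) {
    t <- c(0.05, 0.5, 2, 5)
    expect_lt(max(abs(deer_kernel(r, t) - kernel_oracle(r, t))), 1e-6)
  }
})

test_that("the dipolar signal is the kernel average over P(r)", {
  # delta distribution: S(t) is the kernel at its support
  n <- 240
  dens <- numeric(n)
  dens[61] <- 1 / 0.05  # bin centered at 3.025 nm
  delta <- distance_distribution(dens)
  t <- seq(0.01, 5.5, by = 0.11)
  expect_equal(dipolar_signal(delta, t), deer_kernel(delta$r[61], t),
               tolerance = 1e-12)
  # short-time limit: S ~ 1 - 0.4 (omega t)^2, about 5.6e-3 below 1 here
  x <- dipolar_frequency(delta$r[61]) * 0.01e-6
  expect_equal(dipolar_signal(delta, 0.01), 1 - 0.4 * x^2, tolerance = 1e-4)
  expect_lte(dipolar_signal(delta, 0.01), 1)

  # brute-force double loop oracle on a random distribution
  d <- random_distribution(61)
  S <- dipolar_signal(d, t)
  oracle <- vapply(t, function(tk) {
    acc <- 0
    for (k in which(d$density > 0)) {
      acc <- acc + d$density[k] * d$dr * deer_kernel(d$r[k], tk)
    }
    acc
  }, numeric(1))
  expect_lt(max(abs(S - oracle)), 1e-9)

  # linearity in P
  d2 <- random_distribution(62)
  mix <- distance_distribution(0.3 * d$density + 0.7 * d2$density)
  expect_equal(dipolar_signal(mix, t),
               0.3 * dipolar_signal(d, t) + 0.7 * dipolar_signal(d2, t),
               tolerance = 1e-9)
})

test_that("moving mass to larger distances slows the initial decay", {
  n <- 240
  near <- numeric(n); near[round(2.5 / 0.05) + 1] <- 1 / 0.05
  far <- numeric(n);  far[round(4.5 / 0.05) + 1] <- 1 / 0.05
  t_small <- c(0.05, 0.1, 0.2)
  S_near <- dipolar_signal(distance_distribution(near), t_small)
  S_far <- dipolar_signal(distance_distribution(far), t_small)
  expect_true(all(S_far > S_near))
})

test_that("the form factor interpolates between 1 and S by lambda", {
  expect_equal(form_factor(rep(1, 4), 0.02), rep(1, 4))
  expect_equal(form_factor(0.5, 0.3), 0.85)
  expect_equal(form_factor(0, 0.5), 0.5)
  expect_error(form_factor(0.5, 0.01), "modulation depth")
  expect_error(form_factor(0.5, 0.6), "modulation depth")
})

test_that("modulation-depth fitting inverts clean and noisy synthetic data", {
  d <- lowpass_filter(random_distribution(71), 0.1)
  t <- seq(0.01, 5.5, by = 0.01)
  S <- dipolar_signal(d, t)

  # exact inversion at zero noise
  tr <- make_synthetic_trace(d, lam = 0.10, noise_sd = 0)
  expect_equal(fit_modulation_depth(tr$t, tr$V, t, S), 0.10,
               tolerance = 1e-12)

  # noisy recovery within 0.005 at sd 0.002
  trn <- make_synthetic_trace(d, lam = 0.10, noise_sd = 0.002, seed = 7)
  expect_equal(fit_modulation_depth(trn$t, trn$V, t, S), 0.10,
               tolerance = 0.005)

  # out-of-range true depth is clipped with a warning
  V6 <- 1 + 0.6 * (S - 1)
  expect_warning(lam6 <- fit_modulation_depth(t, V6, t, S), "clipped")
  expect_equal(lam6, 0.5)

  # constant predicted signal cannot be fitted
  expect_error(fit_modulation_depth(t, S, t, rep(1, length(t))),
               "constant")
})
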