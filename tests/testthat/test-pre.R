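test_that("pre_parameters enforces the correlation-time hierarchy", {
  p <- pre_parameters(2e-9, 2e-10, delay = 1e-2, r2_dia = 12.6,
                      larmor_MHz = 750)
  expect_equal(p$omega_I, 2 * pi * 750e6)
  expect_equal(p$s_e, 0.5)
  expect_error(pre_parameters(2e-10, 2e-9), "must not exceed")
  expect_error(pre_parameters(-1e-9, 2e-10))
})

test_that("electron-proton distances are Euclidean and translation-invariant", {
  pl <- structure(list(centers = matrix(c(0, 0, 0), 1), p = 1, Z = 1),
                  class = "placement_result")
  protons <- data.frame(resno = 1, x = 0, y = 0, z = 2)
  epd <- electron_proton_distances(pl, protons)
  expect_equal(as.numeric(epd$r), 2)
  expect_equal(as.numeric(epd$u[1, 1, ]), c(0, 0, -1))

  # translating centers and protons together changes nothing
  set.seed(81)
  ctr <- matrix(runif(9), 3)
  pl3 <- structure(list(centers = ctr, p = rep(1 / 3, 3), Z = 1),
                   class = "placement_result")
  pr5 <- data.frame(resno = 1:5, x = runif(5, 2, 3), y = runif(5, 2, 3),
                    z = runif(5, 2, 3))
  epd1 <- electron_proton_distances(pl3, pr5)
  v <- c(1, -2, 3)
  pl3b <- pl3
  pl3b$centers <- sweep(ctr, 2, v, `+`)
  pr5b <- pr5
  pr5b[, c("x", "y", "z")] <- sweep(as.matrix(pr5[, c("x", "y", "z")]),
                                    2, v, `+`)
  epd2 <- electron_proton_distances(pl3b, pr5b)
  expect_equal(epd1$r, epd2$r, tolerance = 1e-12)

  # oracle: independent recomputation of each distance
  for (j in 1:5) {
    for (i in 1:3) {
      expect_equal(epd1$r[j, i],
                   sqrt(sum((as.numeric(pr5[j, c("x", "y", "z")]) -
                             ctr[i, ])^2)),
                   tolerance = 1e-12)
    }
  }
})

test_that("order parameters reproduce the discrete-jump hand cases", {
  # a single state is fully ordered
  op1 <- order_parameters(2, matrix(c(0, 0, 1), 1), 1)
  expect_equal(op1$s2_radial, 1)
  expect_equal(op1$s2_angular, 1)

  # two orthogonal equal-weight vectors: 0.25 + 0.25 + 2 * 0.25 * (-0.5)
  op2 <- order_parameters(c(1, 1),
                          rbind(c(1, 0, 0), c(0, 1, 0)), c(0.5, 0.5))
  expect_equal(op2$s2_angular, 0.25, tolerance = 1e-12)

  # distances (r, 2r) at equal weight: 0.5625^2 / 0.5078125
  op3 <- order_parameters(c(1, 2), rbind(c(1, 0, 0), c(1, 0, 0)),
                          c(0.5, 0.5))
  expect_equal(op3$s2_radial, 0.5625^2 / 0.5078125, tolerance = 1e-12)
  expect_equal(op3$s2_radial, 0.6231, tolerance = 1e-4)
  expect_equal(op3$mean_r3inv, 0.5625)
  expect_equal(op3$mean_r6inv, 0.5078125)

  expect_error(order_parameters(c(0, 1), rbind(c(1, 0, 0), c(1, 0, 0)),
                                c(0.5, 0.5)),
               "degenerate")
})

test_that("order parameters stay in [0, 1] over random rotamer geometries", {
  set.seed(91)
  for (rep in 1:1000) {
    R <- sample(2:8, 1)
    u <- matrix(rnorm(3 * R), R)
    r <- runif(R, 0.5, 4)
    p <- runif(R)
    p <- p / sum(p)
    op <- order_parameters(r, u, p)
    expect_gte(op$s2_radial, 0)
    expect_lte(op$s2_radial, 1 + 1e-12)
    expect_gte(op$s2_angular, -1e-12)
    expect_lte(op$s2_angular, 1 + 1e-12)
  }
})

test_that("gamma2 matches an independent Solomon-Bloembergen evaluation", {
  params <- pre_parameters(2e-9, 2e-10, larmor_MHz = 750)

  # independent closed form, written out from scratch
  sb_oracle <- function(r_nm, s2, tau_c, tau_t, nu_MHz) {
    mu0 <- 4 * pi * 1e-7; muB <- 9.2740100783e-24
    gI <- 2.67522e8; g <- 2.0023
    wI <- 2 * pi * nu_MHz * 1e6
    r6 <- (r_nm * 1e-9)^-6
    J <- function(w) r6 * (s2 * tau_c / (1 + w^2 * tau_c^2) +
                           (1 - s2) * tau_t / (1 + w^2 * tau_t^2))
    (1 / 15) * (mu0 / (4 * pi))^2 * gI^2 * g^2 * muB^2 * 0.75 *
      (4 * J(0) + 3 * J(wI))
  }
  g <- gamma2(2^-6, 1, params)
  expect_equal(g, sb_oracle(2, 1, 2e-9, 2e-10, 750), tolerance = 1e-10)

  # with S2 = 1 the internal correlation time drops out
  params2 <- pre_parameters(2e-9, 1e-10, larmor_MHz = 750)
  expect_equal(gamma2(2^-6, 1, params2), g, tolerance = 1e-12)

  # halving every distance scales the rate by exactly 64
  expect_equal(gamma2(1^-6, 0.7, params) / gamma2(2^-6, 0.7, params), 64,
               tolerance = 1e-12)
})

test_that("gamma2 decreases in every distance", {
  params <- pre_parameters(2e-9, 2e-10)
  p <- c(0.3, 0.7)
  u <- rbind(c(1, 0, 0), c(0, 1, 0))
  base <- c(1.5, 2.5)
  g0 <- with(order_parameters(base, u, p),
             gamma2(mean_r6inv, s2_radial * s2_angular, params))
  for (i in 1:2) {
    r2 <- base
    r2[i] <- r2[i] + 0.3
    g1 <- with(order_parameters(r2, u, p),
               gamma2(mean_r6inv, s2_radial * s2_angular, params))
    expect_lt(g1, g0)
  }
})

test_that("ensemble averaging of rates honors weights, cutoff and absence", {
  expect_equal(ensemble_gamma2(matrix(5, 1, 1)), 5)
  expect_equal(ensemble_gamma2(matrix(c(10, 20), 2, 1),
                               weights = c(0.25, 0.75)), 17.5)

  # 20-frame fixture with 3 frames under the cutoff: manual oracle
  set.seed(101)
  g2 <- matrix(runif(20 * 4, 0, 50), 20, 4)
  z <- runif(20, 0.1, 1)
  z[c(3, 11, 17)] <- 0.01
  w <- runif(20)
  keep <- z >= 0.05
  oracle <- colSums(g2[keep, ] * (w[keep] / sum(w[keep])))
  expect_equal(ensemble_gamma2(g2, w, z, 0.05), oracle, tolerance = 1e-12)

  # all frames excluded: missing values, not an error
  expect_true(all(is.na(ensemble_gamma2(g2, w, rep(0.01, 20), 0.05))))
})

test_that("intensity ratios follow the INEPT attenuation formula", {
  params <- pre_parameters(2e-9, 2e-10, delay = 1e-2, r2_dia = 12.6)
  expect_equal(intensity_ratio(0, params), 1)

  p0 <- pre_parameters(2e-9, 2e-10, delay = 0, r2_dia = 12.6)
  expect_equal(intensity_ratio(12.6, p0), 0.5)

  # delay 10 ms: 0.5 exp(-0.126)
  expect_equal(intensity_ratio(12.6, params), 0.5 * exp(-0.126),
               tolerance = 1e-12)
  expect_equal(intensity_ratio(12.6, params), 0.4404, tolerance = 1e-3)

  # strictly decreasing in the rate, vanishing at large rates
  g <- seq(0, 500, length.out = 100)
  ratios <- intensity_ratio(g, params)
  expect_true(all(diff(ratios) < 0))
  expect_lt(intensity_ratio(1e6, params), 1e-12)
  expect_true(is.na(intensity_ratio(NA, params)))
})

test_that("the C-beta mode equals the single-state closed form", {
  params <- pre_parameters(2e-9, 2e-10)
  ens <- helix_ensemble(8)
  res <- run_pre(ensemble = ens, residue = 4, lib = single_lib(),
                 params = params, mode = "cbeta")

  # oracle: rate from each CB-H distance with S2 = 1
  cb <- spinlabelr:::.atom_coord(ens, 4, "A", "CB", 1)
  protons <- amide_protons(ens, 4, "A", 1)
  for (j in seq_len(nrow(protons))) {
    r <- sqrt(sum((as.numeric(protons[j, c("x", "y", "z")]) - cb)^2))
    expect_equal(res$residues$gamma2[j], gamma2(r^-6, 1, params),
                 tolerance = 1e-12)
  }

  # a one-rotamer library whose center sits at CB gives identical rates
  ctr <- c(0, 0, 0.5625)  # center offset of the unit-arm library
  site <- site_from_frame(ens, 4, "A", 1)
  fitted_ctr <- function(lib) {
    pl <- spinlabelr:::.place_rotamers(
      lib, site, list(coords = matrix(numeric(0), 0, 3),
                      elements = character(0)))
    pl$centers
  }
  lib1 <- single_lib(c(0, 0, 1), arm_length = 0.5)
  # place the arm so that the transformed center lands on CB: solve in the
  # canonical frame by mapping CB back through the site triad fit
  tf <- spinlabelr:::.kabsch(site$triad, lib1$coords[1, lib1$triad, ])
  cb_canon <- as.numeric(cb %*% t(tf$R) + tf$t)
  arm <- sqrt(sum(cb_canon^2)) - 0.125 / 2
  lib_cb <- make_toy_library(R = 1, directions = matrix(cb_canon, 1),
                             arm_length = arm)
  pl <- spinlabelr:::.place_rotamers(
    lib_cb, site, list(coords = matrix(numeric(0), 0, 3),
                       elements = character(0)))
  expect_lt(max(abs(pl$centers - matrix(cb, 1))), 1e-9)
  # a non-interacting LJ table isolates the geometry: an electron jammed
  # against the backbone would otherwise be (rightly) Z-filtered away
  lj0 <- lj_default_table()
  lj0$epsilon <- 0
  res_rla <- run_pre(ensemble = ens, residue = 4, lib = lib_cb,
                     params = params, z_cutoff = 0, lj = lj0)
  expect_equal(res_rla$residues$gamma2, res$residues$gamma2,
               tolerance = 1e-6)

  # with a genuinely displaced probe arm the two modes disagree
  res_arm <- run_pre(ensemble = ens, residue = 4,
                     lib = single_lib(c(0, 0, 1), arm_length = 1.2),
                     params = params, z_cutoff = 0, lj = lj0)
  expect_gt(max(abs(res_arm$residues$gamma2 - res$residues$gamma2)), 1)

  # glycine-like sites (no CB) are rejected in cbeta mode
  ts <- make_two_state_trajectory(f = 1, n_frames = 1)
  ens2 <- read_ensemble(ts$topology)
  # strip CB atoms by relabeling them: simulate a glycine at the site
  ens2$atoms$elety[ens2$atoms$elety == "CB" & ens2$atoms$resno == 2 &
                     ens2$atoms$chain == "A"] <- "XX"
  expect_error(run_pre(ensemble = ens2, residue = 2, chain = "A",
                       lib = single_lib(), params = params, mode = "cbeta"),
               "no CB")
})
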