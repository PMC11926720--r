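pfp <- pfp_properties()

test_that("dimensionless work reproduces its closed-form anchors", {
  expect_equal(dimensionless_work(1, 0), 1)
  expect_equal(dimensionless_work(2, 1 / 16), 0)
  expect_equal(dimensionless_work(4 / 3, 27 / 256), 32 / 27,
               tolerance = 1e-12)
  expect_error(dimensionless_work(-0.1, 0), class = "dropnuc_validation")
})

test_that("stationary points classify the four confinement regimes", {
  g0 <- stationary_points(0)
  expect_equal(g0$X_CR, 1)
  expect_true(is.na(g0$X_SCR))
  expect_identical(g0$regime, "no_elasticity")
  expect_equal(g0$barrier, 1)

  gl <- stationary_points(27 / 256)
  expect_identical(gl$regime, "degenerate")
  expect_equal(gl$X_CR, 4 / 3, tolerance = 1e-10)
  expect_equal(gl$X_SCR, 4 / 3, tolerance = 1e-10)

  gn <- stationary_points(1 / 16)
  expect_identical(gn$regime, "bistable")
  expect_equal(gn$X_SCR, 2, tolerance = 1e-10)
  # the CR is the remaining real root of X^3 + 2X^2 + 4X - 8 after
  # factoring X = 2 out of the quartic
  cr_oracle <- uniroot(function(x) x^3 + 2 * x^2 + 4 * x - 8, c(0.5, 2),
                       tol = 1e-14)$root
  expect_equal(gn$X_CR, cr_oracle, tolerance = 1e-10)
  expect_true(gn$X_CR > 1 && gn$X_CR < 4 / 3 && gn$X_SCR > 4 / 3)

  gs <- stationary_points(0.2)
  expect_identical(gs$regime, "super_stabilized")
  expect_true(is.na(gs$X_CR) && is.na(gs$X_SCR))
})

test_that("root solver matches brute-force extremization of the work", {
  set.seed(421)
  for (gamma in runif(50, 1e-4, 27 / 256 - 1e-4)) {
    sp <- stationary_points(gamma)
    X_end <- 1.2 * gamma^(-1 / 3)    # SCR bound: X^3 < 1/gamma
    X <- seq(1e-6, X_end, length.out = 1e5)
    w <- dimensionless_work(X, gamma)
    dw <- diff(w)
    turn <- which(diff(sign(dw)) != 0)
    expect_gte(length(turn), 2)
    X_max <- X[turn[1] + 1L]
    X_min <- X[turn[length(turn)] + 1L]
    tol <- 2 * (X[2] - X[1])
    expect_lt(abs(sp$X_CR - X_max), tol)
    expect_lt(abs(sp$X_SCR - X_min), tol)
  }
})

test_that("coalescence and equilibrium parameters solve the stated systems", {
  gl <- gamma_limit()
  expect_equal(gl$gamma, 27 / 256, tolerance = 1e-10)
  expect_equal(gl$X, 4 / 3, tolerance = 1e-10)
  gn <- gamma_equilibrium()
  expect_equal(gn$gamma, 1 / 16, tolerance = 1e-10)
  expect_equal(gn$X, 2, tolerance = 1e-10)
})

test_that("the barrier grows monotonically with confinement", {
  g <- seq(1e-4, 27 / 256 - 1e-4, length.out = 60)
  barrier <- vapply(g, function(x) stationary_points(x)$barrier,
                    numeric(1))
  expect_true(all(diff(barrier) > 0))
  expect_true(all(barrier >= 1))
})

test_that("gamma parameter has the stated scalings", {
  expect_equal(gamma_parameter(5.5e-3, 0, 140e-9, 7e5, -4.5e6), 0)
  g <- gamma_parameter(5.5e-3, 4e5, 140e-9, 6.94e5, -4.5e6)
  expect_equal(g, 8 * (5.5e-3)^3 * 4e5 / ((140e-9)^3 * (6.94e5 + 4.5e6)^4))
  expect_lt(g, 1e-6)  # negligible at paper-scale parameters
  # linear in K, inverse-cube in R20, even in the tension
  expect_equal(gamma_parameter(5.5e-3, 8e5, 140e-9, 6.94e5, -4.5e6), 2 * g)
  expect_equal(gamma_parameter(5.5e-3, 4e5, 280e-9, 6.94e5, -4.5e6), g / 8)
  expect_equal(gamma_parameter(5.5e-3, 4e5, 140e-9, -4.5e6, 6.94e5), g)
  expect_error(gamma_parameter(5.5e-3, 4e5, 140e-9, 1e5, 1e5),
               class = "dropnuc_domain")
})

test_that("unconfined critical radius is the Young-Laplace balance", {
  expect_equal(critical_radius_unconfined(6.81e-3, 4.464e6 - 1e5, -1e5),
               2 * 6.81e-3 / 4.464e6)
  expect_equal(critical_radius_unconfined(6.81e-3, 2 * 4.464e6, 0),
               critical_radius_unconfined(6.81e-3, 4.464e6, 0) / 2)
  expect_error(critical_radius_unconfined(6.81e-3, -1e6, -1e6),
               class = "dropnuc_no_drive")
})

test_that("critical work matches Eq-form and the W1wo identity", {
  W <- critical_work(6.81e-3, 4.464e6, 0)
  expect_equal(W, 16 * pi * (6.81e-3)^3 / (3 * (4.464e6)^2))
  expect_equal(W, 2.66e-19, tolerance = 5e-3)
  expect_equal(critical_work(6.81e-3, 2 * 4.464e6, 0), W / 4)
  # (16 pi / 3) s^3 / dP^2 == (4 pi / 3) s (2 s / dP)^2 for random states
  set.seed(7)
  for (i in 1:20) {
    s <- runif(1, 1e-3, 2e-2); dP <- runif(1, 1e5, 1e7)
    expect_equal(critical_work(s, dP, 0),
                 4 * pi / 3 * s * critical_radius_unconfined(s, dP, 0)^2)
  }
})

test_that("kinetic prefactor has the standard CNT form", {
  J0 <- kinetic_prefactor(6.81e-3, 310, pfp)
  expect_equal(J0, or_prefactor(6.81e-3, 310), tolerance = 1e-12)
  expect_equal(J0, 2.6e38, tolerance = 0.03)
  expect_equal(kinetic_prefactor(4 * 6.81e-3, 310, pfp), 2 * J0)
  expect_error(kinetic_prefactor(0, 310, pfp), class = "dropnuc_validation")
})

test_that("nucleation rate is consistent and monotone in tension", {
  Pspin <- liquid_spinodal(310, pfp)$P
  res <- nucleation_rate(-4.5e6, 310, pfp)
  st <- res$state
  expect_equal(res$J, st$J0 * exp(-st$W_star /
                                    (physical_constants()$kB * 310)))
  expect_equal(st$P1, 135e3 + 5.59e5)
  # J rises strictly as the liquid pressure drops toward the spinodal.
  # (In the last ~5 kPa sliver above the spinodal the sqrt(sigma1)
  # prefactor dependence overturns the trend once W* < kB T / 6, so the
  # monotonicity window stops just short of it.)
  P2g <- seq(-3e6, Pspin + 5e4, length.out = 50)
  J <- vapply(P2g, function(p)
    nucleation_rate(p, 310, pfp, Pspin = Pspin)$J, numeric(1))
  expect_true(all(diff(J) > 0))
  expect_true(all(J <= vapply(P2g, function(p)
    nucleation_rate(p, 310, pfp, Pspin = Pspin)$state$J0, numeric(1))))
  suppressWarnings(  # compressed-liquid flag fires first, then the error
    expect_error(nucleation_rate(2e6, 310, pfp, gases = list()),
                 class = "dropnuc_no_drive"))
})

test_that("temperature raises the rate at fixed liquid pressure", {
  # user-supplied Psat per temperature: the package refuses to
  # extrapolate the single-temperature preset
  cold <- pfp_properties(Psat = 70e3)
  hot <- pfp_properties(Psat = 400e3)
  J_cold <- nucleation_rate(-2.2e6, 294, cold)$J
  J_hot <- nucleation_rate(-2.2e6, 343, hot)$J
  expect_gt(log10(J_hot) - log10(J_cold), 10)
})

test_that("confined barrier feeds through the rate", {
  Pspin <- liquid_spinodal(310, pfp)$P
  plain <- nucleation_rate(-4.5e6, 310, pfp, Pspin = Pspin)
  conf <- nucleation_rate(-4.5e6, 310, pfp, Pspin = Pspin,
                          K = series_modulus(2.2e9, 0.4e6), R20 = 140e-9)
  expect_lt(conf$J, plain$J)
  expect_gt(conf$state$gamma, 0)
  expect_identical(conf$state$regime, "bistable")
  # strong confinement of a tiny droplet removes the barrier maximum
  expect_error(
    nucleation_rate(-2e6, 310, pfp, Pspin = Pspin, K = 1e9, R20 = 5e-9),
    class = "dropnuc_super_stabilized")
})

test_that("nucleation probability follows Poisson statistics", {
  V20 <- droplet_config()$V20
  tau <- 2e-8
  expect_equal(nucleation_probability(log(2) / (V20 * tau), V20, tau), 0.5)
  expect_equal(nucleation_probability(0, V20, tau), 0)
  J <- 10^seq(24, 28, length.out = 30)
  S <- vapply(J, nucleation_probability, numeric(1), V20 = V20, tau = tau)
  expect_true(all(diff(S) > 0) && all(S >= 0 & S < 1))
})

test_that("critical rate reproduces both window conventions", {
  V20 <- droplet_config()$V20
  expect_equal(critical_rate(V20, 1 / 5e6), 4.4e26, tolerance = 0.02)
  expect_equal(critical_rate(V20, 1 / (10 * 5e6)), 1 / (V20 * 2e-8))
  expect_equal(critical_rate(2 * V20, 2e-7),
               critical_rate(V20, 2e-7) / 2)
})
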