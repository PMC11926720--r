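pfp <- pfp_properties()

test_that("default threshold matches the independent fixed-point oracle", {
  thr <- solve_threshold()
  fp <- or_threshold_fp()
  expect_true(thr$converged)
  expect_equal(thr$P_INT, fp$P_INT, tolerance = 1e-3)
  expect_equal(thr$P2_at_threshold, fp$P2, tolerance = 1e-3)
  # defining condition at the root
  expect_equal(thr$Sigma_at_star, 0.5, tolerance = 1e-6)
  # magnitude convention
  expect_equal(thr$P_INT, abs(thr$Pat_star))
  expect_gt(thr$P2_at_threshold, thr$Pspin)
  expect_equal(liquid_pressure_at_threshold(thr), thr$P2_at_threshold)
})

test_that("feeding the root back through the energetics recovers J*", {
  thr <- solve_threshold()
  tau <- thr$config_echo$tau
  J_target <- log(2) / (thr$config_echo$droplet$V20 * tau)
  expect_equal(thr$J_at_star, J_target, tolerance = 1e-4)
})

test_that("dissolved gas lowers the threshold by less than its partial pressure", {
  with_gas <- solve_threshold(include_gas = TRUE)
  no_gas <- solve_threshold(include_gas = FALSE)
  d <- no_gas$P_INT - with_gas$P_INT
  expect_gt(d, 0)
  expect_lte(d, 5.59e5)
})

test_that("threshold is insensitive to K3 when only the work barrier carries it", {
  # gamma ~ 1e-7 at paper-scale parameters: the threshold moves by < 1 Pa
  thr <- lapply(c(0, 0.4e6, 0.67e6), function(k3)
    solve_threshold(tissue = tissue_config(K3 = k3)))
  P <- vapply(thr, `[[`, numeric(1), "P_INT")
  expect_equal(P[2] / P[1], 1, tolerance = 1e-6)
  expect_equal(P[3] / P[1], 1, tolerance = 1e-6)
  # and yet monotone: confinement can only raise the barrier
  expect_true(all(diff(P) >= 0))
  g <- vapply(thr, `[[`, numeric(1), "gamma_at_threshold")
  expect_true(all(diff(g) > 0))
})

test_that("confinement pressure shifts the threshold one-for-one", {
  base <- solve_threshold()
  conf <- solve_threshold(tissue = tissue_config(K3 = 0, Pc_conf = 3e5))
  expect_equal(conf$P_INT - base$P_INT, 3e5, tolerance = 1e-5)
})

test_that("probability curve is sigmoidal and crosses 0.5 at the root", {
  thr <- solve_threshold()
  grid <- seq(-5.6e6, 0, length.out = 57)
  pc <- probability_curve(Pat_grid = grid)
  expect_true(all(pc$status == "ok"))
  expect_lt(pc$Sigma[nrow(pc)], 1e-6)          # ~0 at rest
  ok <- pc$Sigma
  expect_true(all(diff(ok) <= 0))              # falls as |Pat| falls
  at_root <- probability_curve(Pat_grid = thr$Pat_star)
  expect_equal(at_root$Sigma, 0.5, tolerance = 1e-6)
  # steepest slope within 0.5 MPa of the root
  sl <- abs(diff(ok) / diff(grid))
  z <- (grid[-1] + grid[-length(grid)]) / 2
  expect_lt(abs(z[which.max(sl)] - thr$Pat_star), 5e5)
  # rows past the spinodal are flagged, not fatal
  deep <- probability_curve(Pat_grid = c(-6.5e6, -1e6))
  expect_identical(deep$status, c("beyond_spinodal", "ok"))
  expect_true(is.na(deep$Sigma[1]))
})

test_that("radius sweep: larger droplets nucleate at lower pressure", {
  tab <- sweep_threshold("R20", c(50, 100, 140, 300, 1000) * 1e-9)
  expect_true(all(tab$status == "ok"))
  expect_true(all(diff(tab$P_INT_Pa) < 0))
})

test_that("frequency sweep: shorter windows need slightly more tension", {
  tab <- sweep_threshold("f", c(0.1, 0.5, 1, 2, 5) * 1e6)
  expect_true(all(diff(tab$P_INT_Pa) > 0))
  rise <- tab$P_INT_Pa[5] - tab$P_INT_Pa[1]
  expect_gt(rise, 0)
  expect_lt(rise, 1e6)
})

test_that("interfacial tension sweep: coated droplets nucleate sooner", {
  tab <- sweep_threshold("sigma2", c(14e-3, 56e-3))
  expect_lt(tab$P_INT_Pa[1], tab$P_INT_Pa[2])
})

test_that("gas sweep rows mirror the on/off solves", {
  tab <- sweep_threshold("gas", c(TRUE, FALSE))
  expect_lt(tab$P_INT_Pa[1], tab$P_INT_Pa[2])
  expect_identical(attr(tab, "parameter"), "gas")
})

test_that("oracle equivalence holds across scenario variations", {
  for (case in list(list(R20 = 100e-9, sigma2 = 56e-3, f = 5e6),
                    list(R20 = 200e-9, sigma2 = 14e-3, f = 1e6))) {
    thr <- solve_threshold(
      droplet_config(R20 = case$R20, sigma2 = case$sigma2), f = case$f)
    fp <- or_threshold_fp(R20 = case$R20, sigma2 = case$sigma2,
                          f = case$f)
    expect_equal(thr$P_INT, fp$P_INT, tolerance = 1e-3)
  }
})

test_that("underpressure at threshold falls with temperature", {
  tab <- underpressure_at_threshold(
    T_values = c(294, 302, 310, 343),
    Psat_values = c(70e3, 101.325e3, 135e3, 400e3))
  expect_true(all(tab$status == "ok"))
  expect_true(all(diff(tab$dP_Pa) < 0))
  # single-row consistency with the direct solve
  dr <- droplet_config(); dr$T0 <- 294
  thr <- solve_threshold(dr, fluid = pfp_properties(Psat = 70e3))
  expect_equal(tab$P_INT_Pa[1], thr$P_INT, tolerance = 1e-9)
})

test_that("sweep validates its inputs and reports failed rows", {
  expect_error(sweep_threshold("R20", numeric(0)),
               class = "dropnuc_validation")
  expect_error(sweep_threshold("bogus", 1))
})
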