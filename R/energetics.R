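#' Dimensionless nucleation work
#'
#' The work to nucleate a bubble of dimensionless radius `X = R1/R1wo*`
#' (R1wo* the unconfined critical radius), in units of the unconfined
#' barrier `W1wo = (4 pi / 3) sigma1 R1wo*^2`:
#'
#'   `w(X; gamma) = 3 X^2 - 2 X^3 + gamma X^6`
#'
#' The first two terms are the classical surface + bulk competition; the
#' `gamma X^6` term is the elastic energy stored in compressing the
#' droplet/tissue series spring, `gamma = 8 sigma1^3 K / (R20^3 (P1 -
#' P2wo)^4)`.
#'
#' @param X Dimensionless bubble radius, >= 0; vectorized.
#' @param gamma Dimensionless confinement parameter, >= 0.
#' @return w, same length as `X`.
#' @export
#' @examples
#' dimensionless_work(1, 0)         # classical barrier = 1
#' dimensionless_work(2, 1 / 16)    # 0: bubble/droplet energetic tie
dimensionless_work <- function(X, gamma) {
  check_number(gamma, "gamma", nonneg = TRUE)
  if (any(X < 0)) stop_domain("X must be >= 0", "dropnuc_validation")
  3 * X^2 - 2 * X^3 + gamma * X^6
}

#' Stationary points of the dimensionless work landscape
#'
#' Positive roots of `w'(X) = 0`, i.e. of `1 - X + gamma X^4 = 0`. For
#' `0 < gamma < 27/256` there are two: the smaller is the critical radius
#' (CR, local maximum of w), the larger the stable critical radius (SCR,
#' local minimum at which growth arrests). They coalesce at
#' `gamma = 27/256` (X = 4/3) and disappear beyond it
#' (super-stabilization: confinement removes the nucleation pathway).
#'
#' @param gamma Dimensionless confinement parameter, >= 0.
#' @return List with `X_CR`, `X_SCR` (NA when absent), `barrier`
#'   (`w(X_CR)`, NA in the super-stabilized regime) and `regime`, one of
#'   `"no_elasticity"`, `"bistable"`, `"degenerate"`,
#'   `"super_stabilized"`.
#' @export
#' @examples
#' stationary_points(1 / 16)$X_SCR  # exactly 2
#' stationary_points(0.2)$regime    # "super_stabilized"
stationary_points <- function(gamma) {
  check_number(gamma, "gamma", nonneg = TRUE)
  gl <- 27 / 256
  if (gamma == 0) {
    return(list(X_CR = 1, X_SCR = NA_real_, barrier = 1,
                regime = "no_elasticity"))
  }
  q <- function(x) 1 - x + gamma * x^4
  qp <- function(x) -1 + 4 * gamma * x^3
  roots <- polyroot(c(1, -1, 0, 0, gamma))
  re <- Re(roots)[abs(Im(roots)) < 1e-6 & Re(roots) > 0]
  # polish by Newton (guards the 1e-10 closed-form anchors)
  re <- vapply(re, function(x) {
    for (i in 1:6) {
      d <- qp(x)
      if (abs(d) < 1e-14) break
      x <- x - q(x) / d
    }
    x
  }, numeric(1))
  re <- sort(unique(round(re, 12)))
  re <- re[abs(q(re)) < 1e-8]
  if (length(re) == 0L) {
    return(list(X_CR = NA_real_, X_SCR = NA_real_, barrier = NA_real_,
                regime = "super_stabilized"))
  }
  if (length(re) == 1L || abs(re[length(re)] - re[1L]) < 1e-6) {
    # coalescing double root: Newton converges only linearly there, but
    # the root also satisfies q'(X) = 0, which pins it in closed form
    Xd <- (1 / (4 * gamma))^(1 / 3)
    if (abs(q(Xd)) < 1e-9) {
      return(list(X_CR = Xd, X_SCR = Xd,
                  barrier = dimensionless_work(Xd, gamma),
                  regime = "degenerate"))
    }
    return(list(X_CR = re[1L], X_SCR = re[1L],
                barrier = dimensionless_work(re[1L], gamma),
                regime = "degenerate"))
  }
  list(X_CR = re[1L], X_SCR = re[length(re)],
       barrier = dimensionless_work(re[1L], gamma),
       regime = "bistable")
}

# generic damped Newton on a 2-equation system with numeric Jacobian
newton2 <- function(fun, x0, tol = 1e-13, maxit = 100L) {
  x <- x0
  for (i in seq_len(maxit)) {
    f <- fun(x)
    if (max(abs(f)) < tol) break
    h <- 1e-7 * pmax(abs(x), 1)
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      xp <- x; xp[j] <- xp[j] + h[j]
      J[, j] <- (fun(xp) - f) / h[j]
    }
    x <- x - solve(J, f)
  }
  x
}

#' Limiting confinement parameter (CR/SCR coalescence)
#'
#' Solves `w'(X) = 0` and `w''(X) = 0` simultaneously for the value of
#' gamma at which the work curve's maximum and minimum merge, together
#' with the coalescence radius ratio. The solution is computed
#' numerically (damped Newton); analytically it is gamma = 27/256,
#' X = 4/3.
#'
#' @return List with `gamma` and `X`.
#' @export
gamma_limit <- function() {
  f <- function(p) {
    X <- p[1]; g <- p[2]
    c(6 * X - 6 * X^2 + 6 * g * X^5,      # dw/dX
      6 - 12 * X + 30 * g * X^4)          # d2w/dX2
  }
  p <- newton2(f, c(1.2, 0.08))
  list(gamma = p[2], X = p[1])
}

#' Energetic-equilibrium confinement parameter
#'
#' Solves `w(X) = 0` and `w'(X) = 0` simultaneously: the confinement at
#' which the arrested bubble has the same energy as the intact droplet.
#' Numerically computed; analytically gamma = 1/16 with the stable point
#' at X = 2.
#'
#' @return List with `gamma` and `X`.
#' @export
gamma_equilibrium <- function() {
  f <- function(p) {
    X <- p[1]; g <- p[2]
    c(3 * X^2 - 2 * X^3 + g * X^6,
      6 * X - 6 * X^2 + 6 * g * X^5)
  }
  p <- newton2(f, c(1.9, 0.07))
  list(gamma = p[2], X = p[1])
}

#' Dimensionless work curve with stationary-point annotation
#'
#' @param gamma Dimensionless confinement parameter.
#' @param X_max Upper end of the X grid; default covers the SCR when it
#'   exists.
#' @param n Number of grid points.
#' @return Object of class `work_curve`: list with `gamma`, `X`, `w`,
#'   `X_CR`, `X_SCR`, `barrier`, `regime`.
#' @export
work_curve <- function(gamma, X_max = NULL, n = 601L) {
  sp <- stationary_points(gamma)
  if (is.null(X_max))
    X_max <- if (!is.na(sp$X_SCR)) 1.6 * sp$X_SCR else 2.5
  X <- seq(0, X_max, length.out = n)
  # pin the stationary points onto the grid so exported curves carry the
  # exact extrema
  X <- sort(unique(c(X, sp$X_CR[!is.na(sp$X_CR)],
                     sp$X_SCR[!is.na(sp$X_SCR)])))
  structure(c(list(gamma = gamma, X = X, w = dimensionless_work(X, gamma)),
              sp),
            class = "work_curve")
}

#' @export
print.work_curve <- function(x, ...) {
  cat(sprintf("<work_curve: gamma = %g, regime = %s>\n", x$gamma, x$regime))
  if (!is.na(x$X_CR))
    cat(sprintf("  X_CR = %.6f (barrier w = %.6f)\n", x$X_CR, x$barrier))
  if (!is.na(x$X_SCR))
    cat(sprintf("  X_SCR = %.6f\n", x$X_SCR))
  invisible(x)
}

#' Dimensionless confinement parameter gamma
#'
#' `gamma = 8 sigma1^3 K / (R20^3 (P1 - P2wo)^4)`. Even in the tension, so
#' the sign of `P1 - P2wo` is immaterial.
#'
#' @param sigma1 Effective bubble surface tension (N/m).
#' @param K Series modulus (Pa) from [series_modulus()].
#' @param R20 Droplet radius (m).
#' @param P1 Bubble internal pressure (Pa).
#' @param P2wo Bubble-free liquid pressure (Pa).
#' @return gamma (dimensionless).
#' @export
gamma_parameter <- function(sigma1, K, R20, P1, P2wo) {
  check_number(sigma1, "sigma1", nonneg = TRUE)
  check_number(K, "K", nonneg = TRUE)
  check_number(R20, "R20", positive = TRUE)
  if (P1 == P2wo)
    stop_domain("P1 = P2wo: gamma diverges (no finite tension)",
                "dropnuc_domain")
  8 * sigma1^3 * K / (R20^3 * (P1 - P2wo)^4)
}

#' Unconfined critical radius
#'
#' Young-Laplace balance of the embryo: `R1wo* = 2 sigma1 / (P1 - P2wo)`.
#'
#' @inheritParams gamma_parameter
#' @return Radius (m).
#' @export
critical_radius_unconfined <- function(sigma1, P1, P2wo) {
  check_number(sigma1, "sigma1", nonneg = TRUE)
  if (P1 <= P2wo)
    stop_domain("P1 <= P2wo: no nucleation drive", "dropnuc_no_drive")
  2 * sigma1 / (P1 - P2wo)
}

#' Classical critical work
#'
#' `W* = 16 pi sigma1^3 / (3 (P1 - P2)^2)`, identical to
#' `(4 pi / 3) sigma1 R1wo*^2` evaluated at the unconfined critical
#' radius. With confinement enabled the effective barrier is that value
#' times `w(X_CR; gamma)` (see [stationary_points()]).
#'
#' @param sigma1 Effective bubble surface tension (N/m).
#' @param P1 Bubble internal pressure (Pa).
#' @param P2 Liquid pressure (Pa).
#' @return Work (J).
#' @export
critical_work <- function(sigma1, P1, P2) {
  check_number(sigma1, "sigma1", nonneg = TRUE)
  if (P1 <= P2)
    stop_domain("P1 <= P2: no nucleation drive", "dropnuc_no_drive")
  16 * pi * sigma1^3 / (3 * (P1 - P2)^2)
}

#' Kinetic prefactor of the homogeneous nucleation rate
#'
#' Standard CNT attempt-frequency estimate
#' `J0 = (rho2(T)/m) sqrt(2 sigma1 / (pi m))` with `m` the molecular mass
#' `molar_mass / NA`. Exposed as a plain function so alternative
#' prefactors can be substituted; the threshold depends only
#' logarithmically on it.
#'
#' @param sigma1 Effective bubble surface tension (N/m), > 0.
#' @param T Temperature (K).
#' @param fluid A [fluid_properties()] object.
#' @return Prefactor (m^-3 s^-1).
#' @export
kinetic_prefactor <- function(sigma1, T, fluid) {
  check_number(sigma1, "sigma1", positive = TRUE)
  m <- fluid$molar_mass / .const$NAv
  (liquid_density(T, fluid) / m) * sqrt(2 * sigma1 / (pi * m))
}

#' Homogeneous nucleation rate in the metastable droplet
#'
#' `J = J0 exp(-W*/(kB T))` with `W* = 16 pi sigma1^3 / (3 (P1 - P2)^2)`
#' (times the confined-barrier factor `w(X_CR; gamma)` when `K > 0` and
#' `R20` is supplied), `sigma1` the metastability-scaled surface tension
#' at the bubble-free liquid pressure `P2`, and `P1 = Psat + Pg1`.
#'
#' @param P2 Bubble-free liquid pressure (Pa).
#' @param T Temperature (K).
#' @param fluid A [fluid_properties()] object.
#' @param gases List of [gas_species()]; use `list()` for degassed liquid.
#' @param Pspin Optional precomputed spinodal pressure (Pa).
#' @param K Series modulus (Pa); 0 disables the elastic barrier
#'   correction.
#' @param R20 Droplet radius (m); required when `K > 0`.
#' @return List with `J` (m^-3 s^-1) and `state`, a list of all
#'   intermediates (`P1`, `Pv1`, `Pg1`, `sigma1`, `R1wo_star`, `W1wo`,
#'   `gamma`, `barrier_J`, `J0`, plus the confined stationary points).
#' @export
#' @examples
#' nucleation_rate(-4.5e6, 310, pfp_properties())$J
nucleation_rate <- function(P2, T, fluid, gases = default_gases(),
                            Pspin = NULL, K = 0, R20 = NULL) {
  if (is.null(Pspin)) Pspin <- liquid_spinodal(T, fluid)$P
  sigma1 <- effective_surface_tension(P2, T, fluid, Pspin)
  Pv1 <- fluid$Psat
  Pg1 <- gas_partial_pressure(gases)
  P1 <- Pv1 + Pg1
  if (P1 <= P2)
    stop_domain("P1 <= P2: no nucleation drive", "dropnuc_no_drive")
  R1wo <- critical_radius_unconfined(sigma1, P1, P2)
  W1wo <- 4 * pi / 3 * sigma1 * R1wo^2
  gamma <- 0
  sp <- list(X_CR = 1, X_SCR = NA_real_, barrier = 1,
             regime = "no_elasticity")
  if (K > 0) {
    if (is.null(R20))
      stop_domain("R20 required when the elastic barrier is enabled",
                  "dropnuc_validation")
    gamma <- gamma_parameter(sigma1, K, R20, P1, P2)
    sp <- stationary_points(gamma)
    if (sp$regime == "super_stabilized")
      stop_domain(
        sprintf("super-stabilized: gamma = %.3g >= 27/256, no barrier maximum",
                gamma),
        "dropnuc_super_stabilized")
  }
  W_star <- W1wo * sp$barrier
  J0 <- kinetic_prefactor(sigma1, T, fluid)
  J <- J0 * exp(-W_star / (.const$kB * T))
  list(J = J,
       state = list(P2 = P2, P1 = P1, Pv1 = Pv1, Pg1 = Pg1,
                    sigma1 = sigma1, R1wo_star = R1wo,
                    R1_star = if (is.na(sp$X_SCR)) NA_real_ else
                      sp$X_SCR * R1wo,
                    W1wo = W1wo, W_star = W_star, gamma = gamma,
                    X_CR = sp$X_CR, X_SCR = sp$X_SCR,
                    regime = sp$regime, J0 = J0, J = J))
}

#' Nucleation probability in one droplet over a time window
#'
#' Poisson statistics of embryo formation:
#' `Sigma = 1 - exp(-J V20 tau)`.
#'
#' @param J Nucleation rate (m^-3 s^-1).
#' @param V20 Droplet volume (m^3).
#' @param tau Nucleation time window (s).
#' @return Probability in `[0, 1)`.
#' @export
nucleation_probability <- function(J, V20, tau) {
  check_number(J, "J", nonneg = TRUE)
  check_number(V20, "V20", nonneg = TRUE)
  check_number(tau, "tau", nonneg = TRUE)
  -expm1(-J * V20 * tau)
}

#' Critical nucleation rate for a first bubble
#'
#' Rate at which, on average, one bubble forms in the droplet volume
#' within the window: `J* = 1 / (V20 tau)`.
#'
#' @param V20 Droplet volume (m^3), > 0.
#' @param tau Time window (s), > 0. The steady-state convention is
#'   `tau = 1/(10 f)`; a full acoustic period `tau = 1/f` is the
#'   rate-map convention.
#' @return Rate (m^-3 s^-1).
#' @export
critical_rate <- function(V20, tau) {
  check_number(V20, "V20", positive = TRUE)
  check_number(tau, "tau", positive = TRUE)
  1 / (V20 * tau)
}
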