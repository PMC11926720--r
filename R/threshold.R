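# Self-consistent initial-nucleation-threshold (INT) solver and the
# parameter sweeps built on it. The INT is the tensile acoustic amplitude
# at which the probability of nucleating the first vapor embryo in one
# droplet within the window tau reaches 50%.

# Evaluate the nucleation probability at a candidate acoustic pressure.
# Domain errors map to the physically correct probability: no vapor drive
# or a super-stabilized landscape both mean "no nucleation" (Sigma = 0).
# The compressed-liquid warning (delta < 0 near Pat = 0) is muffled here:
# it is expected while bracketing.
sigma_at <- function(Pat, droplet, tissue, fluid, tau, gases, K, P0,
                     Pspin) {
  P2wo <- resting_liquid_pressure(droplet, tissue, Pat, P0)
  res <- withCallingHandlers(
    tryCatch(
      nucleation_rate(P2wo, droplet$T0, fluid, gases, Pspin,
                      K = K, R20 = droplet$R20),
      dropnuc_no_drive = function(e) NULL,
      dropnuc_super_stabilized = function(e) e),
    warning = function(w) {
      if (grepl("compressed liquid", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (is.null(res))
    return(list(Sigma = 0, state = NULL, super = FALSE))
  if (inherits(res, "condition"))
    return(list(Sigma = 0, state = NULL, super = TRUE))
  list(Sigma = nucleation_probability(res$J, droplet$V20, tau),
       state = res$state, super = FALSE)
}

#' Solve for the initial nucleation threshold (INT)
#'
#' Finds the rarefactional acoustic pressure `Pat* <= 0` at which the
#' single-droplet nucleation probability
#' `Sigma = 1 - exp(-J V20 tau)` reaches 50%, with
#' `tau = 1/(tau_divisor f)` and the bubble-free liquid pressure
#' `P2wo = P0 + Plap + Pat + Pc_conf`. The effective surface tension is
#' evaluated at `P2wo`; when `include_elastic_barrier` is TRUE the energy
#' barrier is the confined value `W1wo w(X_CR; gamma)` rather than the
#' classical one. Sigma is monotone in |Pat| and the spinodal bounds the
#' bracket, so the root is found by bisection (via [stats::uniroot()]) to
#' an absolute tolerance of 1e-3 Pa, which pins Sigma to 0.5 within 1e-6.
#'
#' @param droplet A [droplet_config()].
#' @param tissue A [tissue_config()]; default fluid-like (K3 = 0).
#' @param f Drive frequency (Hz).
#' @param tau_divisor Window convention: `tau = 1/(tau_divisor f)`.
#'   Default 10 (a tenth of a period, where the tensile trough is
#'   roughly flat); use 1 for the full-period convention.
#' @param include_gas Include the dissolved-gas partial pressure in the
#'   bubble (default TRUE).
#' @param include_elastic_barrier Apply the confined-barrier correction
#'   (default TRUE; negligible at fluid-tissue defaults where
#'   gamma ~ 1e-7).
#' @param fluid A [fluid_properties()] object.
#' @param P0 Ambient pressure (Pa).
#' @return Object of class `threshold_result` with fields `P_INT`
#'   (threshold magnitude, Pa), `Pat_star` (signed, Pa),
#'   `P2_at_threshold`, `sigma1_at_threshold`, `R1wo_star`,
#'   `gamma_at_threshold`, `Sigma_at_star`, `J_at_star`, `converged`,
#'   `iterations`, and `config_echo`.
#' @export
#' @examples
#' \donttest{
#' solve_threshold(droplet_config(), tissue_config(K3 = 0), f = 5e6)
#' }
solve_threshold <- function(droplet = droplet_config(),
                            tissue = tissue_config(K3 = 0),
                            f = 5e6, tau_divisor = 10,
                            include_gas = TRUE,
                            include_elastic_barrier = TRUE,
                            fluid = pfp_properties(),
                            P0 = physical_constants()$P0) {
  stopifnot(inherits(droplet, "droplet_config"),
            inherits(tissue, "tissue_config"))
  check_number(f, "f", positive = TRUE)
  check_number(tau_divisor, "tau_divisor", positive = TRUE)
  tau <- 1 / (tau_divisor * f)
  gases <- if (include_gas) droplet$gases else list()
  K <- if (include_elastic_barrier)
    series_modulus(droplet$K2, tissue$K3) else 0
  Pspin <- liquid_spinodal(droplet$T0, fluid)$P
  Plap <- laplace_pressure(droplet$R20, droplet$sigma2,
                           droplet$laplace_factor)
  # bracket: P2wo ranges over (Pspin, P0 + Plap + Pc_conf]
  Pat_lo <- Pspin - P0 - Plap - tissue$Pc_conf + 1
  ev <- function(Pat) sigma_at(Pat, droplet, tissue, fluid, tau, gases,
                               K, P0, Pspin)
  lo <- ev(Pat_lo)
  if (lo$Sigma < 0.5) {
    if (lo$super)
      stop_domain(
        "super-stabilized throughout the bracket: no 50% threshold exists",
        "dropnuc_super_stabilized")
    stop_domain(
      "Sigma < 0.5 everywhere above the spinodal: threshold would require spinodal decomposition",
      "dropnuc_spinodal_exceeded")
  }
  hi <- ev(0)
  if (hi$Sigma >= 0.5)
    stop_domain("Sigma >= 0.5 already at Pat = 0: droplet not metastable at rest",
                "dropnuc_validation")
  root <- stats::uniroot(function(p) ev(p)$Sigma - 0.5,
                         lower = Pat_lo, upper = 0,
                         tol = 1e-3, maxiter = 200L)
  Pat_star <- root$root
  at <- ev(Pat_star)
  st <- at$state
  structure(list(
    P_INT = abs(Pat_star),
    Pat_star = Pat_star,
    P2_at_threshold = st$P2,
    sigma1_at_threshold = st$sigma1,
    R1wo_star = st$R1wo_star,
    R1_star = st$R1_star,
    gamma_at_threshold = st$gamma,
    Sigma_at_star = at$Sigma,
    J_at_star = st$J,
    W_star = st$W_star,
    Pspin = Pspin,
    converged = abs(at$Sigma - 0.5) < 1e-6,
    iterations = root$iter,
    config_echo = list(droplet = droplet, tissue = tissue, f = f,
                       tau_divisor = tau_divisor, tau = tau,
                       include_gas = include_gas,
                       include_elastic_barrier = include_elastic_barrier,
                       fluid = fluid, P0 = P0)),
    class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat("<threshold_result>\n")
  cat(sprintf("  P_INT   = %.4f MPa (Pat* = %.4f MPa)\n",
              x$P_INT / 1e6, x$Pat_star / 1e6))
  cat(sprintf("  P2(thr) = %.4f MPa  (Pspin = %.4f MPa)\n",
              x$P2_at_threshold / 1e6, x$Pspin / 1e6))
  cat(sprintf("  sigma1  = %.4g N/m, R1wo* = %.3f nm, gamma = %.3g\n",
              x$sigma1_at_threshold, x$R1wo_star * 1e9,
              x$gamma_at_threshold))
  cat(sprintf("  Sigma   = %.8f, converged = %s (%d iterations)\n",
              x$Sigma_at_star, x$converged, x$iterations))
  invisible(x)
}

#' Liquid pressure at the moment of nucleation
#'
#' @param result A converged [solve_threshold()] result.
#' @return `P2_at_threshold` (Pa). Errors if the solution sits at or
#'   below the spinodal (which the solver's bracket should preclude).
#' @export
liquid_pressure_at_threshold <- function(result) {
  stopifnot(inherits(result, "threshold_result"))
  if (!isTRUE(result$converged))
    stop_domain("threshold result did not converge", "dropnuc_validation")
  if (result$P2_at_threshold <= result$Pspin)
    stop_domain("threshold liquid pressure at/below spinodal",
                "dropnuc_beyond_spinodal")
  result$P2_at_threshold
}

#' Underpressure (tension) at threshold versus temperature
#'
#' Solves the 50% threshold at each temperature, with a user-supplied
#' saturation pressure per temperature (the package refuses to
#' extrapolate a single-temperature Psat preset), and reports the
#' underpressure `dP = P1 - P2` at nucleation.
#'
#' @param T_values Temperatures (K).
#' @param Psat_values Saturation pressures (Pa), one per temperature.
#' @param droplet A [droplet_config()] (its `T0` is overridden per row).
#' @param tissue A [tissue_config()].
#' @param f Drive frequency (Hz).
#' @param ... Passed to [solve_threshold()].
#' @return `data.frame` with columns `T_K`, `Psat_Pa`, `P_INT_Pa`,
#'   `P2_thr_Pa`, `dP_Pa`, `status`.
#' @export
underpressure_at_threshold <- function(T_values, Psat_values,
                                       droplet = droplet_config(),
                                       tissue = tissue_config(K3 = 0),
                                       f = 5e6, ...) {
  if (length(T_values) != length(Psat_values))
    stop_domain("T_values and Psat_values must have equal length",
                "dropnuc_validation")
  rows <- Map(function(T, Psat) {
    base <- pfp_properties(Psat = Psat)
    dr <- droplet; dr$T0 <- T
    out <- tryCatch({
      thr <- solve_threshold(dr, tissue, f = f, fluid = base, ...)
      Pg1 <- if (isTRUE(thr$config_echo$include_gas))
        gas_partial_pressure(dr$gases) else 0
      data.frame(T_K = T, Psat_Pa = Psat, P_INT_Pa = thr$P_INT,
                 P2_thr_Pa = thr$P2_at_threshold,
                 dP_Pa = Psat + Pg1 - thr$P2_at_threshold,
                 status = "ok")
    }, dropnuc_error = function(e)
      data.frame(T_K = T, Psat_Pa = Psat, P_INT_Pa = NA_real_,
                 P2_thr_Pa = NA_real_, dP_Pa = NA_real_,
                 status = class(e)[1L]))
    out
  }, T_values, Psat_values)
  do.call(rbind, rows)
}

#' Nucleation probability curve over a grid of acoustic amplitudes
#'
#' @param droplet A [droplet_config()].
#' @param tissue A [tissue_config()].
#' @param f Drive frequency (Hz).
#' @param Pat_grid Signed acoustic pressures (Pa, <= 0 for tension).
#' @param tau_divisor,include_gas,include_elastic_barrier,fluid,P0 As in
#'   [solve_threshold()].
#' @return `data.frame` with columns `Pat_Pa`, `Sigma`, `status`; rows
#'   whose liquid pressure falls below the spinodal are flagged
#'   `"beyond_spinodal"` with `Sigma = NA`, not errors.
#' @export
probability_curve <- function(droplet = droplet_config(),
                              tissue = tissue_config(K3 = 0),
                              f = 5e6, Pat_grid,
                              tau_divisor = 10, include_gas = TRUE,
                              include_elastic_barrier = TRUE,
                              fluid = pfp_properties(),
                              P0 = physical_constants()$P0) {
  tau <- 1 / (tau_divisor * f)
  gases <- if (include_gas) droplet$gases else list()
  K <- if (include_elastic_barrier)
    series_modulus(droplet$K2, tissue$K3) else 0
  Pspin <- liquid_spinodal(droplet$T0, fluid)$P
  rows <- lapply(Pat_grid, function(Pat) {
    P2wo <- resting_liquid_pressure(droplet, tissue, Pat, P0)
    if (P2wo <= Pspin)
      return(data.frame(Pat_Pa = Pat, Sigma = NA_real_,
                        status = "beyond_spinodal"))
    s <- sigma_at(Pat, droplet, tissue, fluid, tau, gases, K, P0, Pspin)
    data.frame(Pat_Pa = Pat, Sigma = s$Sigma,
               status = if (s$super) "super_stabilized" else "ok")
  })
  do.call(rbind, rows)
}

#' Threshold parameter sweep
#'
#' Re-solves the INT while one scenario parameter varies. Supported
#' parameters: `"K3"` (tissue bulk modulus, Pa), `"R20"` (droplet
#' radius, m), `"sigma2"` (interfacial tension, N/m), `"f"` (drive
#' frequency, Hz) and `"gas"` (logical: dissolved gas on/off).
#'
#' @param parameter Name of the swept parameter.
#' @param values Values to sweep (ordered as given).
#' @param droplet Base [droplet_config()].
#' @param tissue Base [tissue_config()].
#' @param f Base drive frequency (Hz).
#' @param ... Passed to [solve_threshold()].
#' @return `data.frame` of class `sweep_table` with columns
#'   `swept_value`, `P_INT_Pa`, `P2_thr_Pa`, `sigma1_Npm`, `gamma`,
#'   `status`; attribute `parameter` records the swept name. Rows whose
#'   solve fails carry the error class in `status`.
#' @export
sweep_threshold <- function(parameter = c("K3", "R20", "sigma2", "f",
                                          "gas"),
                            values,
                            droplet = droplet_config(),
                            tissue = tissue_config(K3 = 0),
                            f = 5e6, ...) {
  parameter <- match.arg(parameter)
  if (length(values) == 0L)
    stop_domain("`values` must be nonempty", "dropnuc_validation")
  rows <- lapply(values, function(v) {
    dr <- droplet; ti <- tissue; fv <- f; extra <- list(...)
    switch(parameter,
           K3 = { ti$K3 <- v },
           R20 = { dr$R20 <- v; dr$V20 <- 4 * pi / 3 * v^3 },
           sigma2 = { dr$sigma2 <- v },
           f = { fv <- v },
           gas = { extra$include_gas <- as.logical(v) })
    out <- tryCatch({
      thr <- do.call(solve_threshold,
                     c(list(droplet = dr, tissue = ti, f = fv), extra))
      data.frame(swept_value = as.numeric(v), P_INT_Pa = thr$P_INT,
                 P2_thr_Pa = thr$P2_at_threshold,
                 sigma1_Npm = thr$sigma1_at_threshold,
                 gamma = thr$gamma_at_threshold, status = "ok")
    }, dropnuc_error = function(e)
      data.frame(swept_value = as.numeric(v), P_INT_Pa = NA_real_,
                 P2_thr_Pa = NA_real_, sigma1_Npm = NA_real_,
                 gamma = NA_real_, status = class(e)[1L]))
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "parameter") <- parameter
  class(out) <- c("sweep_table", class(out))
  out
}
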