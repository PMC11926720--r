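#' Thermophysical property set for the droplet liquid
#'
#' Bundles the constants needed by the Redlich-Kwong (RK) equation of
#' state, the liquid-density power series and the macroscopic
#' surface-tension correlation. [pfp_properties()] returns the shipped
#' perfluoropentane (PFP, C5F12) preset.
#'
#' @param Tc Critical temperature (K).
#' @param Pc_crit Critical pressure (Pa).
#' @param molar_mass Molar mass (kg/mol).
#' @param rho_ref Reference (critical) density rho20 (kg/m^3) anchoring the
#'   density series.
#' @param density_coeffs Numeric vector B1..B6 of dimensionless coefficients
#'   of the `(1 - T/Tc)^(i/3)` density expansion.
#' @param sigma_coeff_A Amplitude A (N/m) of the surface-tension correlation
#'   `sigma_inf(T) = A (1 - T/Tc)^(2 v)`.
#' @param critical_exponent_v Critical exponent v (dimensionless).
#' @param Psat Saturation vapor pressure at the working temperature (Pa).
#'   Treated as an input, not derived from the EOS (see
#'   [rk_saturation_pressure()] for the optional Maxwell construction).
#' @param name Label for printing.
#' @return Object of class `fluid_properties`.
#' @seealso [pfp_properties()], [rk_pressure()], [liquid_spinodal()]
#' @export
fluid_properties <- function(Tc, Pc_crit, molar_mass, rho_ref,
                             density_coeffs, sigma_coeff_A,
                             critical_exponent_v, Psat,
                             name = "custom") {
  check_number(Tc, "Tc", positive = TRUE)
  check_number(Pc_crit, "Pc_crit", positive = TRUE)
  check_number(molar_mass, "molar_mass", positive = TRUE)
  check_number(rho_ref, "rho_ref", positive = TRUE)
  check_number(sigma_coeff_A, "sigma_coeff_A", nonneg = TRUE)
  check_number(critical_exponent_v, "critical_exponent_v", positive = TRUE)
  check_number(Psat, "Psat", positive = TRUE)
  if (!is.numeric(density_coeffs) || length(density_coeffs) != 6L)
    stop_domain("`density_coeffs` must be a numeric vector B1..B6",
                "dropnuc_validation")
  structure(
    list(Tc = Tc, Pc_crit = Pc_crit, molar_mass = molar_mass,
         rho_ref = rho_ref, density_coeffs = as.numeric(density_coeffs),
         sigma_coeff_A = sigma_coeff_A,
         critical_exponent_v = critical_exponent_v,
         Psat = Psat, name = name),
    class = "fluid_properties")
}

#' Perfluoropentane property preset
#'
#' Default working fluid: Tc = 420 K, Pc = 2.045 MPa, rho20 = 759.53 kg/m^3,
#' density coefficients B1..B6 = (-0.425, 8.191, -17.91, 19.63, -10.92,
#' 2.655), surface-tension correlation A = 0.0425 N/m with critical exponent
#' v = 0.6, and Psat = 135 kPa at the 310 K working temperature. The molar
#' mass (0.28803 kg/mol, C5F12) is fixed here as a documented constant; it
#' enters only the kinetic prefactor.
#'
#' @param Psat Saturation vapor pressure (Pa) at the working temperature.
#' @return A [fluid_properties()] object.
#' @export
#' @examples
#' pfp <- pfp_properties()
#' macroscopic_surface_tension(310, pfp)
pfp_properties <- function(Psat = 135e3) {
  fluid_properties(
    Tc = 420, Pc_crit = 2.045e6, molar_mass = 0.28803,
    rho_ref = 759.53,
    density_coeffs = c(-0.425, 8.191, -17.91, 19.63, -10.92, 2.655),
    sigma_coeff_A = 0.0425, critical_exponent_v = 0.6,
    Psat = Psat, name = "PFP (C5F12)")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("<fluid_properties: %s>\n", x$name))
  cat(sprintf("  Tc = %g K, Pc = %g MPa, M = %g kg/mol\n",
              x$Tc, x$Pc_crit / 1e6, x$molar_mass))
  cat(sprintf("  rho20 = %g kg/m^3, A = %g N/m, v = %g, Psat = %g kPa\n",
              x$rho_ref, x$sigma_coeff_A, x$critical_exponent_v,
              x$Psat / 1e3))
  invisible(x)
}

#' Redlich-Kwong attraction and covolume parameters
#'
#' `a = Omega_a R^2 Tc^2 / Pc` and `b = Omega_b R Tc / Pc` with
#' Omega_a = 0.42748 and Omega_b = 0.08664.
#'
#' @param fluid A [fluid_properties()] object.
#' @return Named numeric vector `c(a = , b = )`; `a` in Pa m^6/mol^2,
#'   `b` in m^3/mol.
#' @export
#' @examples
#' rk_parameters(pfp_properties())
rk_parameters <- function(fluid) {
  stopifnot(inherits(fluid, "fluid_properties"))
  R <- .const$R
  c(a = 0.42748 * R^2 * fluid$Tc^2 / fluid$Pc_crit,
    b = 0.08664 * R * fluid$Tc / fluid$Pc_crit)
}

#' Redlich-Kwong pressure
#'
#' `P = R T / (V - b) - a alpha(T) / (V (V + b))` with the reduced-temperature
#' attraction scaling `alpha(T) = (T/Tc)^(-1/2)`.
#'
#' @param V Molar volume (m^3/mol); vectorized. Must exceed the covolume b.
#' @param T Temperature (K).
#' @param fluid A [fluid_properties()] object.
#' @return Pressure (Pa), same length as `V`.
#' @export
rk_pressure <- function(V, T, fluid) {
  check_number(T, "T", positive = TRUE)
  ab <- rk_parameters(fluid)
  if (any(V <= ab[["b"]]))
    stop_domain("molar volume inside covolume (V <= b)", "dropnuc_domain")
  alpha <- (T / fluid$Tc)^(-0.5)
  .const$R * T / (V - ab[["b"]]) - ab[["a"]] * alpha / (V * (V + ab[["b"]]))
}

# analytic dP/dV of the RK isotherm
rk_dPdV <- function(V, T, fluid) {
  ab <- rk_parameters(fluid)
  a <- ab[["a"]]; b <- ab[["b"]]
  alpha <- (T / fluid$Tc)^(-0.5)
  -.const$R * T / (V - b)^2 + a * alpha * (2 * V + b) / (V^2 * (V + b)^2)
}

#' Liquid-branch spinodal of the RK isotherm
#'
#' Locates the smallest-volume stationary point of P(V) with positive
#' curvature: the local minimum of the isotherm that marks the tensile
#' stability limit of the liquid. Sign changes of the analytic dP/dV are
#' bracketed on a log-spaced grid in (1.01 b, 50 b) and refined by
#' bisection to relative tolerance 1e-10.
#'
#' @param T Temperature (K), strictly below the critical temperature.
#' @param fluid A [fluid_properties()] object.
#' @return List with `V` (m^3/mol) and `P` (Pa) at the spinodal.
#' @export
#' @examples
#' liquid_spinodal(310, pfp_properties())$P / 1e6  # about -5.24 MPa
liquid_spinodal <- function(T, fluid) {
  check_number(T, "T", positive = TRUE)
  if (T >= fluid$Tc)
    stop_domain("T >= Tc: supercritical, no liquid spinodal",
                "dropnuc_supercritical")
  b <- rk_parameters(fluid)[["b"]]
  Vg <- exp(seq(log(1.01 * b), log(50 * b), length.out = 4000L))
  s <- sign(rk_dPdV(Vg, T, fluid))
  idx <- which(diff(s) != 0)
  if (length(idx) == 0L)
    stop_domain("no stationary point of P(V) found below Tc",
                "dropnuc_domain")
  # derivative goes from negative (stiff liquid branch) to positive at the
  # liquid minimum; the first sign change is the liquid spinodal
  i <- idx[1L]
  root <- stats::uniroot(function(v) rk_dPdV(v, T, fluid),
                         lower = Vg[i], upper = Vg[i + 1L],
                         tol = 1e-10 * Vg[i])$root
  list(V = root, P = rk_pressure(root, T, fluid))
}

#' Spinodal line over a set of temperatures
#'
#' @param T_values Numeric vector of temperatures (K), each in (0, Tc).
#' @param fluid A [fluid_properties()] object.
#' @return `data.frame` with columns `T_K`, `V_m3_per_mol`, `P_Pa`.
#' @export
spinodal_line <- function(T_values, fluid) {
  rows <- lapply(T_values, function(T) {
    sp <- liquid_spinodal(T, fluid)
    data.frame(T_K = T, V_m3_per_mol = sp$V, P_Pa = sp$P)
  })
  if (length(rows) == 0L)
    return(data.frame(T_K = numeric(), V_m3_per_mol = numeric(),
                      P_Pa = numeric()))
  do.call(rbind, rows)
}

#' Sampled RK isotherm
#'
#' @param T Temperature (K).
#' @param fluid A [fluid_properties()] object.
#' @param V_range Molar-volume range (m^3/mol) as multiples of the covolume
#'   b; default `c(1.05, 50)`.
#' @param n Number of log-spaced samples.
#' @return `data.frame` with columns `V_m3_per_mol`, `P_Pa`; if T < Tc the
#'   spinodal point is attached as attributes `spinodal_V`, `spinodal_P`.
#' @export
rk_isotherm <- function(T, fluid, V_range = c(1.05, 50), n = 400L) {
  b <- rk_parameters(fluid)[["b"]]
  V <- exp(seq(log(V_range[1] * b), log(V_range[2] * b), length.out = n))
  out <- data.frame(V_m3_per_mol = V, P_Pa = rk_pressure(V, T, fluid))
  if (T < fluid$Tc) {
    sp <- liquid_spinodal(T, fluid)
    attr(out, "spinodal_V") <- sp$V
    attr(out, "spinodal_P") <- sp$P
  }
  out
}

#' Temperature-dependent liquid density
#'
#' Power-series correlation
#' `rho2(T) = rho20 (1 + sum_i Bi (1 - T/Tc)^(i/3))`, i = 1..6.
#'
#' @param T Temperature (K), 0 < T <= Tc; vectorized.
#' @param fluid A [fluid_properties()] object.
#' @return Density (kg/m^3).
#' @export
#' @examples
#' liquid_density(310, pfp_properties())  # about 1284 kg/m^3
liquid_density <- function(T, fluid) {
  if (any(T <= 0) || any(T > fluid$Tc))
    stop_domain("T must satisfy 0 < T <= Tc", "dropnuc_domain")
  t <- 1 - T / fluid$Tc
  B <- fluid$density_coeffs
  corr <- vapply(t, function(ti) sum(B * ti^((1:6) / 3)), numeric(1))
  fluid$rho_ref * (1 + corr)
}

#' Macroscopic (flat-interface) surface tension
#'
#' Critical-scaling correlation `sigma_inf(T) = A (1 - T/Tc)^(2 v)`.
#'
#' @inheritParams liquid_density
#' @return Surface tension (N/m), zero at T = Tc.
#' @export
macroscopic_surface_tension <- function(T, fluid) {
  if (any(T <= 0) || any(T > fluid$Tc))
    stop_domain("T must satisfy 0 < T <= Tc", "dropnuc_domain")
  fluid$sigma_coeff_A * (1 - T / fluid$Tc)^(2 * fluid$critical_exponent_v)
}

#' Saturation pressure by Maxwell equal-area construction (optional)
#'
#' Computes the RK coexistence pressure at `T` by requiring equal areas
#' between the isotherm and the horizontal tie line. This is provided for
#' sensitivity studies only; the pipeline treats `Psat` as a user input
#' (the shipped PFP preset fixes 135 kPa at 310 K) and never substitutes
#' this construction silently.
#'
#' @param T Temperature (K), below Tc.
#' @param fluid A [fluid_properties()] object.
#' @return Saturation pressure (Pa).
#' @export
rk_saturation_pressure <- function(T, fluid) {
  if (T >= fluid$Tc)
    stop_domain("T >= Tc: supercritical", "dropnuc_supercritical")
  ab <- rk_parameters(fluid)
  b <- ab[["b"]]
  sp_liq <- liquid_spinodal(T, fluid)
  # vapor spinodal: next stationary point (the local maximum); start
  # clear of the liquid minimum where dP/dV is zero to machine noise
  Vg <- exp(seq(log(1.05 * sp_liq$V), log(5000 * b), length.out = 6000L))
  s <- sign(rk_dPdV(Vg, T, fluid))
  i <- which(diff(s) != 0)[1L]
  Vmax <- stats::uniroot(function(v) rk_dPdV(v, T, fluid),
                         lower = Vg[i], upper = Vg[i + 1L],
                         tol = 1e-10 * Vg[i])$root
  Pmax <- rk_pressure(Vmax, T, fluid)
  area_mismatch <- function(P) {
    Vl <- stats::uniroot(function(v) rk_pressure(v, T, fluid) - P,
                         lower = b * (1 + 1e-9), upper = sp_liq$V,
                         tol = 1e-13 * b)$root
    Vv <- stats::uniroot(function(v) rk_pressure(v, T, fluid) - P,
                         lower = Vmax, upper = 1e9 * b,
                         tol = 1e-12 * Vmax, extendInt = "downX")$root
    stats::integrate(function(v) rk_pressure(v, T, fluid) - P, Vl, Vv,
                     rel.tol = 1e-10, subdivisions = 2000L)$value
  }
  lo <- max(sp_liq$P, 0) + 1e-6 * abs(Pmax)
  stats::uniroot(area_mismatch, lower = lo, upper = Pmax * (1 - 1e-9),
                 tol = 1e-6)$root
}
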