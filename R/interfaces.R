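#' Non-condensable dissolved gas species
#'
#' @param name Label.
#' @param Ki Volatility constant from Henry's law (Pa per unit
#'   concentration).
#' @param Cgi Dissolved concentration (dimensionless).
#' @return Object of class `gas_species`.
#' @export
#' @examples
#' gas_species("O2", 4.9e6, 0.07)
gas_species <- function(name, Ki, Cgi) {
  check_number(Ki, "Ki", nonneg = TRUE)
  check_number(Cgi, "Cgi", nonneg = TRUE)
  structure(list(name = name, Ki = Ki, Cgi = Cgi), class = "gas_species")
}

#' Default dissolved-gas content of liquid PFP
#'
#' O2 (Ki = 4.9e6 Pa, Cgi = 0.07) and CO2 (Ki = 7.2e5 Pa, Cgi = 0.3), the
#' two species whose solubility dominates in perfluorocarbon liquids.
#'
#' @return List of [gas_species()] objects.
#' @export
default_gases <- function() {
  list(gas_species("O2", 4.9e6, 0.07),
       gas_species("CO2", 7.2e5, 0.3))
}

#' Nanodroplet scenario configuration
#'
#' @param R20 Initial droplet radius (m). Default 140 nm.
#' @param sigma2 Droplet-tissue interfacial tension (N/m). Default 56 mN/m
#'   (uncoated PFP); lipid/fluorosurfactant coatings reduce it to ~14 mN/m.
#' @param T0 Working temperature (K). Default 310 K.
#' @param K2 Droplet (liquid) bulk modulus (Pa). Default 2.2 GPa,
#'   water-like.
#' @param gases List of [gas_species()]; default [default_gases()].
#' @param laplace_factor Numeric factor in the Laplace term
#'   `Plap = laplace_factor * sigma2 / R20`. The model convention is 1
#'   (not the textbook 2); the switch exists for sensitivity studies.
#' @return Object of class `droplet_config` with derived volume `V20`.
#' @export
#' @examples
#' droplet_config()
droplet_config <- function(R20 = 140e-9, sigma2 = 56e-3, T0 = 310,
                           K2 = 2.2e9, gases = default_gases(),
                           laplace_factor = 1) {
  check_number(R20, "R20", positive = TRUE)
  check_number(sigma2, "sigma2", nonneg = TRUE)
  check_number(T0, "T0", positive = TRUE)
  check_number(K2, "K2", positive = TRUE)
  check_number(laplace_factor, "laplace_factor", positive = TRUE)
  stopifnot(all(vapply(gases, inherits, logical(1), "gas_species")))
  structure(
    list(R20 = R20, sigma2 = sigma2, T0 = T0, K2 = K2, gases = gases,
         laplace_factor = laplace_factor, V20 = 4 * pi / 3 * R20^3),
    class = "droplet_config")
}

#' Tissue confinement configuration
#'
#' @param K3 Tissue bulk modulus (Pa). Either `K3` or `G` must be given.
#' @param G Tissue shear modulus (Pa); converted by the linear-elastic
#'   relation `K3 = 4 G / 3`.
#' @param Pc_conf Optional static confinement pressure (Pa) added to the
#'   droplet resting pressure; default 0 (no formula is asserted for it,
#'   it is an explicit free parameter).
#' @return Object of class `tissue_config`.
#' @export
#' @examples
#' tissue_config(G = 0.3e6)$K3  # 0.4 MPa
tissue_config <- function(K3 = NULL, G = NULL, Pc_conf = 0) {
  if (is.null(K3) && is.null(G))
    stop_domain("supply either K3 or G", "dropnuc_validation")
  if (!is.null(G)) {
    check_number(G, "G", nonneg = TRUE)
    if (!is.null(K3))
      stop_domain("supply K3 or G, not both", "dropnuc_validation")
    K3 <- 4 * G / 3
  }
  check_number(K3, "K3", nonneg = TRUE)
  check_number(Pc_conf, "Pc_conf", nonneg = TRUE)
  structure(list(K3 = K3, G = G, Pc_conf = Pc_conf),
            class = "tissue_config")
}

#' Laplace pressure of the droplet
#'
#' `Plap = factor * sigma2 / R20`. The model convention uses factor 1.
#'
#' @param R20 Droplet radius (m).
#' @param sigma2 Droplet-tissue interfacial tension (N/m).
#' @param factor Laplace factor (default 1).
#' @return Pressure (Pa).
#' @export
laplace_pressure <- function(R20, sigma2, factor = 1) {
  check_number(R20, "R20", positive = TRUE)
  check_number(sigma2, "sigma2", nonneg = TRUE)
  factor * sigma2 / R20
}

#' Total partial pressure of non-condensable dissolved gases
#'
#' Henry's law: `Pg1 = sum_i Ki Cgi`.
#'
#' @param gases List of [gas_species()] objects (possibly empty).
#' @return Pressure (Pa).
#' @export
#' @examples
#' gas_partial_pressure(default_gases())  # 5.59e5 Pa
gas_partial_pressure <- function(gases) {
  if (length(gases) == 0L) return(0)
  stopifnot(all(vapply(gases, inherits, logical(1), "gas_species")))
  sum(vapply(gases, function(g) g$Ki * g$Cgi, numeric(1)))
}

#' Series (harmonic) modulus of droplet and tissue
#'
#' Two springs in series: `K = K2 K3 / (K2 + K3)`.
#'
#' @param K2 Droplet bulk modulus (Pa), > 0.
#' @param K3 Tissue bulk modulus (Pa), >= 0.
#' @return Effective modulus (Pa); 0 when the tissue is fluid-like
#'   (K3 = 0).
#' @export
series_modulus <- function(K2, K3) {
  check_number(K2, "K2", positive = TRUE)
  check_number(K3, "K3", nonneg = TRUE)
  K2 * K3 / (K2 + K3)
}

#' Elastic back-pressure from a nucleated bubble
#'
#' Linearized compression of the droplet/tissue series spring by a bubble
#' of radius `R1`: `dP = K (R1/R20)^3`. The liquid pressure with the bubble
#' present is `P2 = P2wo + dP`.
#'
#' @param R1 Bubble radius (m), >= 0.
#' @param R20 Droplet radius (m).
#' @param K Series modulus (Pa) from [series_modulus()].
#' @return Pressure increment (Pa).
#' @export
elastic_back_pressure <- function(R1, R20, K) {
  check_number(R1, "R1", nonneg = TRUE)
  check_number(R20, "R20", positive = TRUE)
  check_number(K, "K", nonneg = TRUE)
  K * (R1 / R20)^3
}

#' Bubble-free liquid pressure inside the driven droplet
#'
#' `P2wo = P0 + Plap + Pat + Pc_conf` with rarefactional (tensile)
#' acoustic pressure negative.
#'
#' @param droplet A [droplet_config()].
#' @param tissue A [tissue_config()] (contributes `Pc_conf`); may be NULL.
#' @param Pat Applied acoustic pressure (Pa, <= 0 at rarefaction).
#' @param P0 Ambient pressure (Pa), default 1 atm.
#' @return Pressure (Pa).
#' @export
resting_liquid_pressure <- function(droplet, tissue = NULL, Pat = 0,
                                    P0 = .const$P0) {
  stopifnot(inherits(droplet, "droplet_config"))
  Pc <- if (is.null(tissue)) 0 else tissue$Pc_conf
  P0 + laplace_pressure(droplet$R20, droplet$sigma2,
                        droplet$laplace_factor) + Pat + Pc
}

#' Degree of liquid metastability
#'
#' `delta = (Psat - P2) / (Psat - Pspin)`: 0 for a saturated liquid, 1 at
#' the spinodal. Values beyond 1 mean the liquid is unstable (spontaneous
#' spinodal decomposition) and raise a classed error; negative values
#' (compressed liquid) are returned with a warning.
#'
#' @param P2 Liquid pressure (Pa).
#' @param T Temperature (K).
#' @param fluid A [fluid_properties()] object supplying `Psat`.
#' @param Pspin Spinodal pressure (Pa); computed via [liquid_spinodal()]
#'   when not supplied (pass it to avoid recomputation in tight loops).
#' @return delta (dimensionless).
#' @export
metastability_delta <- function(P2, T, fluid, Pspin = NULL) {
  if (is.null(Pspin)) Pspin <- liquid_spinodal(T, fluid)$P
  delta <- (fluid$Psat - P2) / (fluid$Psat - Pspin)
  if (delta > 1)
    stop_domain(
      sprintf("beyond spinodal: P2 = %.4g Pa < Pspin = %.4g Pa", P2, Pspin),
      "dropnuc_beyond_spinodal")
  if (delta < 0)
    warning("compressed liquid: delta < 0 (P2 above Psat)",
            call. = FALSE)
  delta
}

#' Effective surface tension of the critical vapor embryo
#'
#' Metastability scaling of the flat-interface tension:
#' `sigma1 = sigma_inf(T) phi^(1/3)` with
#' `phi = (1 - delta)(1 + delta/2)^2`. sigma1 equals sigma_inf for a
#' saturated liquid and vanishes at the spinodal, where the barrier to
#' phase change disappears.
#'
#' @inheritParams metastability_delta
#' @return Effective surface tension (N/m).
#' @export
#' @examples
#' effective_surface_tension(-3.77e6, 310, pfp_properties())
effective_surface_tension <- function(P2, T, fluid, Pspin = NULL) {
  delta <- metastability_delta(P2, T, fluid, Pspin)
  phi <- (1 - delta) * (1 + 0.5 * delta)^2
  macroscopic_surface_tension(T, fluid) * phi^(1 / 3)
}
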