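# Independent oracles: plain-formula implementations kept deliberately
# separate from the package's code paths. Constants are restated here so
# an error in the package's constant table would be caught.

or_const <- list(R = 8.314462618, kB = 1.380649e-23,
                 NAv = 6.02214076e23, P0 = 101325)

or_pfp <- list(Tc = 420, Pc = 2.045e6, M = 0.28803, rho20 = 759.53,
               B = c(-0.425, 8.191, -17.91, 19.63, -10.92, 2.655),
               A = 0.0425, v = 0.6)

or_rk_ab <- function(Tc = or_pfp$Tc, Pc = or_pfp$Pc) {
  c(a = 0.42748 * or_const$R^2 * Tc^2 / Pc,
    b = 0.08664 * or_const$R * Tc / Pc)
}

or_rk_pressure <- function(V, T, Tc = or_pfp$Tc, Pc = or_pfp$Pc) {
  ab <- or_rk_ab(Tc, Pc)
  or_const$R * T / (V - ab["b"]) -
    ab["a"] * (T / Tc)^(-0.5) / (V * (V + ab["b"]))
}

# brute-force liquid-branch minimum of the isotherm on a dense grid:
# the first interior local minimum coming from the covolume side (the
# global minimum would land on the ideal-gas tail for shallow,
# near-critical isotherms)
or_spinodal_grid <- function(T, n = 1e5, span = c(1.01, 20)) {
  b <- or_rk_ab()["b"]
  V <- exp(seq(log(span[1] * b), log(span[2] * b), length.out = n))
  P <- or_rk_pressure(V, T)
  i <- which(diff(sign(diff(P))) > 0)[1] + 1L
  list(V = V[i], P = P[i])
}

or_density <- function(T) {
  or_pfp$rho20 * (1 + sum(or_pfp$B * (1 - T / or_pfp$Tc)^((1:6) / 3)))
}

or_sigma_inf <- function(T) {
  or_pfp$A * (1 - T / or_pfp$Tc)^(2 * or_pfp$v)
}

or_sigma1 <- function(P2, T, Psat, Pspin) {
  delta <- (Psat - P2) / (Psat - Pspin)
  phi <- (1 - delta) * (1 + 0.5 * delta)^2
  or_sigma_inf(T) * phi^(1 / 3)
}

or_prefactor <- function(sigma1, T) {
  m <- or_pfp$M / or_const$NAv
  or_density(T) / m * sqrt(2 * sigma1 / (pi * m))
}

# Independent fixed-point formulation of the 50% threshold: invert
# Sigma = 0.5 analytically into W*(P2) = kB T ln(J0 V20 tau / ln 2) and
# root-find in P2 space (the package solver bisects in Pat space).
or_threshold_fp <- function(R20 = 140e-9, sigma2 = 56e-3, T0 = 310,
                            f = 5e6, tau_div = 10, gas = TRUE,
                            Psat = 135e3, Pspin = NULL,
                            laplace_factor = 1) {
  if (is.null(Pspin)) Pspin <- or_spinodal_grid(T0, n = 2e5)$P
  Pg1 <- if (gas) 4.9e6 * 0.07 + 7.2e5 * 0.3 else 0
  P1 <- Psat + Pg1
  V20 <- 4 * pi / 3 * R20^3
  tau <- 1 / (tau_div * f)
  h <- function(P2) {
    s1 <- or_sigma1(P2, T0, Psat, Pspin)
    J0 <- or_prefactor(s1, T0)
    16 * pi * s1^3 / (3 * (P1 - P2)^2) -
      or_const$kB * T0 * log(J0 * V20 * tau / log(2))
  }
  P2 <- uniroot(h, lower = Pspin + 10, upper = Psat - 10,
                tol = 1e-7)$root
  Plap <- laplace_factor * sigma2 / R20
  list(P2 = P2, P_INT = -(P2 - or_const$P0 - Plap))
}

# closed-form on-axis pressure amplitude of a focused bowl (apex at
# z = 0, focus at z = roc), lossless medium
or_onaxis_bowl <- function(z, f, roc, aperture, p0, c0 = 1500) {
  k <- 2 * pi * f / c0
  theta_max <- asin(aperture / (2 * roc))
  Re <- sqrt(roc^2 + (z - roc)^2 + 2 * roc * (z - roc) * cos(theta_max))
  2 * p0 / abs(1 - z / roc) * abs(sin(k * (Re - z) / 2))
}

# shared tiny-scenario builders
tiny_droplet <- function(...) droplet_config(...)
no_tissue <- function() tissue_config(K3 = 0)
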