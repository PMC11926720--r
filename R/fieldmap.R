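# Simplified linear axisymmetric focused-field mapper. A monochromatic
# Rayleigh-type diffraction integral over a spherically focused bowl
# stands in for a full nonlinear wave simulation: it reproduces focal
# geometry (focal gain, axial/radial asymmetry, pre-focal shift under
# attenuation) but none of the nonlinear waveform distortion, so the
# derived nucleation-area maps are qualitative.

#' Focused-transducer configuration
#'
#' Geometry: spherical bowl with apex at z = 0 and geometric focus at
#' `z = roc` on the beam axis. Propagation is linear and monochromatic in
#' a water/tissue bilayer with a single sound speed; tissue attenuation
#' is applied as an axial-depth amplitude factor
#' `10^(-alpha0 f_MHz^y d_cm / 20)` beyond the water path.
#'
#' @param f Drive frequency (Hz).
#' @param roc Radius of curvature (m), default 60 mm.
#' @param aperture_diameter Aperture diameter (m), default equal to `roc`
#'   (F-number 1); must not exceed `2 roc`.
#' @param source_pressure Uniform surface pressure amplitude
#'   `p0 = rho c u0` (Pa), default 0.2 MPa.
#' @param water_path Water standoff before the tissue interface (m),
#'   default 30 mm.
#' @param alpha0 Tissue attenuation coefficient (dB cm^-1 MHz^-y),
#'   default 0.5.
#' @param alpha_power Frequency power y of the attenuation law, default 1.
#' @param c0 Sound speed (m/s), default 1500.
#' @return Object of class `transducer_config`.
#' @export
transducer_config <- function(f, roc = 0.060,
                              aperture_diameter = roc,
                              source_pressure = 0.2e6,
                              water_path = 0.030,
                              alpha0 = 0.5, alpha_power = 1,
                              c0 = 1500) {
  check_number(f, "f", positive = TRUE)
  check_number(roc, "roc", positive = TRUE)
  check_number(aperture_diameter, "aperture_diameter", positive = TRUE)
  if (aperture_diameter > 2 * roc)
    stop_domain("aperture exceeds the bowl diameter (2 roc)",
                "dropnuc_validation")
  check_number(source_pressure, "source_pressure", positive = TRUE)
  check_number(water_path, "water_path", nonneg = TRUE)
  check_number(alpha0, "alpha0", nonneg = TRUE)
  check_number(alpha_power, "alpha_power", nonneg = TRUE)
  check_number(c0, "c0", positive = TRUE)
  structure(list(f = f, roc = roc,
                 aperture_diameter = aperture_diameter,
                 source_pressure = source_pressure,
                 water_path = water_path, alpha0 = alpha0,
                 alpha_power = alpha_power, c0 = c0),
            class = "transducer_config")
}

# discretize the bowl into rings (polar-angle midpoint rule)
bowl_rings <- function(config, n_rings = NULL) {
  Fz <- config$roc
  theta_max <- asin(config$aperture_diameter / (2 * Fz))
  lambda <- config$c0 / config$f
  if (is.null(n_rings))
    n_rings <- max(128L, ceiling(Fz * theta_max / (lambda / 6)))
  dth <- theta_max / n_rings
  th <- (seq_len(n_rings) - 0.5) * dth
  list(zs = Fz * (1 - cos(th)), rs = Fz * sin(th),
       dS = 2 * pi * Fz^2 * sin(th) * dth, theta_max = theta_max)
}

# depth-dependent tissue attenuation amplitude factor
attenuation_factor <- function(z, config) {
  d_cm <- pmax(0, z - config$water_path) * 100
  10^(-(config$alpha0 * (config$f / 1e6)^config$alpha_power * d_cm) / 20)
}

#' Linear focused-bowl peak-negative-pressure map
#'
#' Computes the monochromatic pressure amplitude |p| on an axisymmetric
#' (z, r) grid by numerical diffraction integration over the bowl
#' aperture, then applies the tissue attenuation factor along depth. For
#' a linear monochromatic field the peak negative pressure (PNP) equals
#' the amplitude.
#'
#' @param config A [transducer_config()].
#' @param z_range Axial window (m), default `c(0.01, 0.11)`.
#' @param dz Axial grid step (m), default 0.1 mm.
#' @param r_max Radial half-width (m), default 5 mm.
#' @param dr Radial grid step (m), default 0.1 mm.
#' @param n_rings,n_phi Optional overrides of the source quadrature
#'   (rings along the bowl polar angle; azimuthal nodes per ring).
#' @return Object of class `field_map`: list with `z`, `r`, matrix `PNP`
#'   (length(z) x length(r), Pa) and the `config`.
#' @export
linear_focused_field <- function(config,
                                 z_range = c(0.010, 0.110), dz = 1e-4,
                                 r_max = 0.005, dr = 1e-4,
                                 n_rings = NULL, n_phi = NULL) {
  stopifnot(inherits(config, "transducer_config"))
  lambda <- config$c0 / config$f
  if (dz > lambda / 4 || dr > lambda / 4)
    stop_domain(
      sprintf("grid too coarse: spacing must be <= lambda/4 = %.3g m",
              lambda / 4),
      "dropnuc_grid")
  k <- 2 * pi / lambda
  rings <- bowl_rings(config, n_rings)
  z <- seq(z_range[1], z_range[2], by = dz)
  r <- seq(0, r_max, by = dr)
  if (min(z) <= max(rings$zs))
    stop_domain("axial window intersects the transducer surface",
                "dropnuc_validation")
  if (is.null(n_phi)) {
    dz_min <- min(z) - max(rings$zs)
    dR <- sqrt((r_max + max(rings$rs))^2 + dz_min^2) -
      sqrt((r_max - max(rings$rs))^2 + dz_min^2)
    n_phi <- max(64L, 8L * ceiling(k * dR / (2 * pi)))
  }
  grid <- expand.grid(z = z, r = r)
  amp <- bowl_field_cpp(grid$z, grid$r, rings$zs, rings$rs, rings$dS,
                        k, as.integer(n_phi))
  pnp <- matrix(amp * k * config$source_pressure / (2 * pi),
                nrow = length(z), ncol = length(r))
  pnp <- pnp * attenuation_factor(z, config)  # recycles down columns
  structure(list(z = z, r = r, PNP = pnp, config = config,
                 n_phi = n_phi, n_rings = length(rings$zs)),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  imax <- which(x$PNP == max(x$PNP), arr.ind = TRUE)[1, ]
  cat(sprintf("<field_map: %g MHz, %d x %d grid>\n",
              x$config$f / 1e6, length(x$z), length(x$r)))
  cat(sprintf("  max PNP = %.3f MPa at z = %.1f mm, r = %.1f mm\n",
              max(x$PNP) / 1e6, x$z[imax[1]] * 1e3, x$r[imax[2]] * 1e3))
  invisible(x)
}

# connected component (4-neighbour) of `mask` containing linear index
# `start`; mask is a logical matrix
flood_component <- function(mask, start) {
  nz <- nrow(mask); nr <- ncol(mask)
  comp <- matrix(FALSE, nz, nr)
  comp[start] <- TRUE
  frontier <- start
  while (length(frontier) > 0L) {
    i <- (frontier - 1L) %% nz + 1L
    j <- (frontier - 1L) %/% nz + 1L
    nb <- c(frontier[i > 1L] - 1L,
            frontier[i < nz] + 1L,
            frontier[j > 1L] - nz,
            frontier[j < nr] + nz)
    nb <- unique(nb[mask[nb] & !comp[nb]])
    comp[nb] <- TRUE
    frontier <- nb
  }
  comp
}

# linear interpolation of the super-level crossing between an inside
# sample (value vi at coordinate xi) and an outside sample (vo at xo)
edge_interp <- function(xi, vi, xo, vo, level) {
  xi + (xo - xi) * (vi - level) / (vi - vo)
}

#' Achievable nucleation area per droplet size
#'
#' For each (diameter, INT) pair, identifies the connected region of the
#' field map where PNP >= INT that contains the field maximum, and
#' reports its axial length, radial width and mirrored cross-sectional
#' area. Larger droplets have lower INT, so their regions nest around
#' those of smaller droplets.
#'
#' @param map A [linear_focused_field()] result.
#' @param thresholds `data.frame` with columns `diameter` (m) and
#'   `P_INT` (Pa).
#' @return `data.frame` with columns `diameter_nm`, `INT_Pa`,
#'   `length_mm`, `width_mm`, `area_mm2` (zero-extent rows when the
#'   threshold exceeds the field maximum).
#' @export
nucleation_area <- function(map, thresholds) {
  stopifnot(inherits(map, "field_map"),
            is.data.frame(thresholds),
            all(c("diameter", "P_INT") %in% names(thresholds)))
  if (any(thresholds$P_INT <= 0))
    stop_domain("thresholds must be positive", "dropnuc_validation")
  P <- map$PNP; z <- map$z; r <- map$r
  dz <- z[2] - z[1]; dr <- r[2] - r[1]
  imax <- which.max(P)
  rows <- lapply(seq_len(nrow(thresholds)), function(ii) {
    level <- thresholds$P_INT[ii]
    dia <- thresholds$diameter[ii]
    if (max(P) < level)
      return(data.frame(diameter_nm = dia * 1e9, INT_Pa = level,
                        length_mm = 0, width_mm = 0, area_mm2 = 0))
    comp <- flood_component(P >= level, imax)
    idx <- which(comp, arr.ind = TRUE)
    zi <- idx[, 1]; ri <- idx[, 2]
    # axial extent with sub-cell edge interpolation
    i_lo <- min(zi); i_hi <- max(zi)
    j_lo <- ri[which.min(zi)]; j_hi <- ri[which.max(zi)]
    z_lo <- if (i_lo > 1L)
      edge_interp(z[i_lo], P[i_lo, j_lo], z[i_lo - 1L],
                  P[i_lo - 1L, j_lo], level) else z[i_lo]
    z_hi <- if (i_hi < length(z))
      edge_interp(z[i_hi], P[i_hi, j_hi], z[i_hi + 1L],
                  P[i_hi + 1L, j_hi], level) else z[i_hi]
    # radial extent (mirrored across the axis)
    j_max <- max(ri)
    i_rm <- zi[which.max(ri)]
    r_hi <- if (j_max < length(r))
      edge_interp(r[j_max], P[i_rm, j_max], r[j_max + 1L],
                  P[i_rm, j_max + 1L], level) else r[j_max]
    cell_w <- ifelse(r[ri] == 0, dr, 2 * dr)
    data.frame(diameter_nm = dia * 1e9, INT_Pa = level,
               length_mm = (z_hi - z_lo) * 1e3,
               width_mm = 2 * r_hi * 1e3,
               area_mm2 = sum(dz * cell_w) * 1e6)
  })
  do.call(rbind, rows)
}
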