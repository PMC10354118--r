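#' Thermal and optical material constants
#'
#' A medium bundles the constants entering the heat-conduction model: the
#' thermal diffusivity \eqn{\nu} (um^2/us), the thermal conductivity
#' \eqn{K} (W m^-1 K^-1) and, optionally, density (kg m^-3), specific heat
#' (J kg^-1 K^-1) and the thermo-optic coefficient dn/dT (K^-1).
#' When density and specific heat are both supplied, consistency
#' \eqn{\nu = K / (\rho c_p)} is enforced to within 1%.
#'
#' The volumetric heat capacity used internally is derived as
#' \eqn{C = K/\nu} and stored in uJ um^-3 K^-1.
#'
#' @param name label for the material.
#' @param thermal_diffusivity diffusivity in um^2/us. Must be positive.
#' @param thermal_conductivity conductivity in W m^-1 K^-1. Must be positive.
#' @param density optional density in kg m^-3.
#' @param specific_heat optional specific heat in J kg^-1 K^-1.
#' @param dn_dT optional thermo-optic coefficient in K^-1 (negative for
#'   liquid water in the visible).
#' @return An object of class `medium`.
#' @examples
#' water_medium()
#' medium("glycerol", thermal_diffusivity = 0.095, thermal_conductivity = 0.29)
#' @export
medium <- function(name, thermal_diffusivity, thermal_conductivity,
                   density = NULL, specific_heat = NULL, dn_dT = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  nu <- as.numeric(thermal_diffusivity)
  K <- as.numeric(thermal_conductivity)
  if (!is.finite(nu) || nu <= 0) stop("thermal_diffusivity must be > 0")
  if (!is.finite(K) || K <= 0) stop("thermal_conductivity must be > 0")
  if (!is.null(density) && !is.null(specific_heat)) {
    # K/(rho c_p) in m^2/s; 1 m^2/s = 1e6 um^2/us
    nu_implied <- K / (density * specific_heat) * 1e6 # -> um^2/us
    if (abs(nu_implied / nu - 1) > 0.01) {
      stop(sprintf(
        "inconsistent constants: K/(rho c_p) = %.4g um^2/us but thermal_diffusivity = %.4g",
        nu_implied, nu
      ))
    }
  }
  structure(
    list(
      name = name, thermal_diffusivity = nu, thermal_conductivity = K,
      density = density, specific_heat = specific_heat, dn_dT = dn_dT,
      # volumetric heat capacity, uJ um^-3 K^-1
      vol_heat = K * 1e-6 / nu
    ),
    class = "medium"
  )
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf(
    "<medium> %s: nu = %.3g um^2/us, K = %.3g W/m/K, C = %.3g uJ/um^3/K%s\n",
    x$name, x$thermal_diffusivity, x$thermal_conductivity, x$vol_heat,
    if (!is.null(x$dn_dT)) sprintf(", dn/dT = %.3g /K", x$dn_dT) else ""
  ))
  invisible(x)
}

#' Liquid water at room temperature
#'
#' Constants for liquid water: nu = 0.146 um^2/us, K = 0.618 W m^-1 K^-1
#' and dn/dT = -1.4e-4 K^-1 (visible, room temperature). The thermo-optic
#' coefficient only sets the scale of absolute phase values; it cancels in
#' every normalized design metric.
#'
#' @param dn_dT thermo-optic coefficient override, K^-1.
#' @return A `medium`.
#' @export
water_medium <- function(dn_dT = -1.4e-4) {
  medium("water", 0.146, 0.618, dn_dT = dn_dT)
}

#' Calcium fluoride substrate
#'
#' Constants for a CaF2 window: nu = 2.92 um^2/us, K = 9.71 W m^-1 K^-1.
#'
#' @return A `medium`.
#' @export
caf2_medium <- function() {
  medium("CaF2", 2.92, 9.71)
}

#' Pulsed heating source description
#'
#' Describes how absorbed mid-infrared energy is deposited: the temporal
#' mode, the pulse duration and the spatial footprint (either a uniformly
#' heated sphere or a lateral Gaussian with exponential axial attenuation).
#' The absorbed intensity term \eqn{I \alpha / (\rho c_p)} of the heat
#' equation is lumped into a single volumetric deposition rate in K/us.
#'
#' Modes:
#' \describe{
#'   \item{constant_power}{heating at `deposition_rate` K/us for
#'     `pulse_duration` us (a long-pulse or CW-like source).}
#'   \item{constant_energy}{the deposited energy is held fixed while the
#'     duration varies: the instantaneous rate is
#'     `deposition_rate * reference_duration / pulse_duration`.}
#'   \item{impulse}{all energy deposited at t = 0 as an initial
#'     temperature field (duration ignored).}
#' }
#'
#' @param mode one of `"constant_power"`, `"constant_energy"`, `"impulse"`.
#' @param pulse_duration pulse duration in us (required unless impulse).
#' @param sphere_radius radius in um of a uniformly heated sphere.
#' @param lateral_fwhm FWHM in um of a lateral Gaussian footprint
#'   (layered geometry); `Inf` gives a laterally uniform deposit.
#' @param axial_attenuation 1/e attenuation depth in um of the axial
#'   Lambert-Beer profile, or `NULL` for no axial variation.
#' @param axial_cutoff if `TRUE`, the axial profile is a hard cutoff at
#'   `axial_attenuation` um instead of an exponential.
#' @param deposition_rate peak volumetric deposition rate in K/us
#'   (temperature-rise rate while the pulse is on).
#' @param reference_duration reference duration in us for
#'   `constant_energy` mode (default 0.01 us = 10 ns).
#' @return An object of class `heating_profile`.
#' @examples
#' heating_profile("constant_power", pulse_duration = 0.1, sphere_radius = 0.25)
#' @export
heating_profile <- function(mode = c("constant_power", "constant_energy", "impulse"),
                            pulse_duration = NULL,
                            sphere_radius = NULL, lateral_fwhm = NULL,
                            axial_attenuation = NULL, axial_cutoff = FALSE,
                            deposition_rate = 1,
                            reference_duration = 0.01) {
  mode <- match.arg(mode)
  if (is.null(sphere_radius) == is.null(lateral_fwhm)) {
    stop("exactly one of sphere_radius / lateral_fwhm must be set")
  }
  if (mode != "impulse") {
    if (is.null(pulse_duration) || !is.finite(pulse_duration) || pulse_duration <= 0) {
      stop("pulse_duration must be > 0 unless mode = 'impulse'")
    }
  }
  structure(
    list(
      mode = mode, pulse_duration = pulse_duration,
      sphere_radius = sphere_radius, lateral_fwhm = lateral_fwhm,
      axial_attenuation = axial_attenuation, axial_cutoff = axial_cutoff,
      deposition_rate = deposition_rate,
      reference_duration = reference_duration
    ),
    class = "heating_profile"
  )
}

#' Radial grid for the spherically symmetric solver
#'
#' Nodes sit at r = 0, dr, ..., r_max. The time step is chosen from the
#' FTCS stability bound dt = safety * dr^2 / (6 nu) (three dimensions);
#' an explicitly supplied `dt` above the bound is refused.
#'
#' @param dr node spacing, um.
#' @param r_max outer domain radius, um.
#' @param dt optional explicit time step, us.
#' @param safety fraction of the stability bound used for the automatic
#'   time step (default 0.4).
#' @return An object of class `radial_grid`.
#' @export
radial_grid <- function(dr, r_max, dt = NULL, safety = 0.4) {
  stopifnot(dr > 0, r_max > dr)
  n_r <- floor(r_max / dr) + 1L
  structure(
    list(dr = dr, n_r = n_r, r = (seq_len(n_r) - 1) * dr,
         r_max = (n_r - 1) * dr, dt = dt, safety = safety),
    class = "radial_grid"
  )
}

# Stability-checked time step for a radial grid in a given medium.
radial_dt <- function(grid, medium) {
  bound <- grid$dr^2 / (6 * medium$thermal_diffusivity)
  if (!is.null(grid$dt)) {
    if (grid$dt > bound) {
      stop(sprintf(
        "unstable time step: dt = %.3g us exceeds the FTCS bound dr^2/(6 nu) = %.3g us",
        grid$dt, bound
      ))
    }
    return(grid$dt)
  }
  grid$safety * bound
}

# Default grid for a sphere problem: dr = R/points_per_radius and
# r_max at least 20 source radii (larger when diffusion will travel far).
default_sphere_grid <- function(radius, t_total, medium,
                                points_per_radius = 20, r_max = NULL) {
  if (is.null(r_max)) {
    reach <- 6 * sqrt(2 * medium$thermal_diffusivity * max(t_total, 0))
    r_max <- max(20 * radius, radius + reach)
  }
  radial_grid(dr = radius / points_per_radius, r_max = r_max)
}

#' Layered substrate/sample/substrate stack
#'
#' An ordered list of (medium, thickness) layers along the optical axis,
#' discretized with node spacing `dz`. Material interfaces are aligned
#' with control-volume faces so the interface flux-continuity condition
#' K_1 dT/dz = K_2 dT/dz holds in the discrete scheme.
#'
#' @param layers list of `list(medium, thickness)` entries, ordered along z.
#' @param dz axial node spacing, um. Every layer must span at least 3 nodes.
#' @param phase_layer index of the layer whose line-integrated temperature
#'   constitutes the observed phase (the water layer; substrate thermo-optic
#'   response is not included).
#' @return An object of class `layered_stack`.
#' @examples
#' layered_stack(
#'   list(list(caf2_medium(), 200), list(water_medium(), 10), list(caf2_medium(), 200)),
#'   dz = 0.5, phase_layer = 2
#' )
#' @export
layered_stack <- function(layers, dz, phase_layer = 2L) {
  stopifnot(length(layers) >= 2L, dz > 0)
  thick <- vapply(layers, function(l) l[[2]], numeric(1))
  if (any(abs(thick / dz - round(thick / dz)) > 1e-9)) {
    stop("layer thicknesses must be integer multiples of dz (interfaces on grid faces)")
  }
  if (any(round(thick / dz) < 3)) {
    stop("every layer must span at least 3 nodes; decrease dz")
  }
  n_per <- as.integer(round(thick / dz))
  med_idx <- rep(seq_along(layers), n_per)
  media <- lapply(layers, function(l) l[[1]])
  nu <- vapply(media, function(m) m$thermal_diffusivity, numeric(1))[med_idx]
  K <- vapply(media, function(m) m$thermal_conductivity, numeric(1))[med_idx]
  z <- (seq_along(med_idx) - 0.5) * dz # cell centres, origin at stack top
  structure(
    list(layers = layers, dz = dz, z = z, nu = nu, K = K,
         vol_heat = K / nu, layer_index = med_idx,
         phase_layer = as.integer(phase_layer),
         offsets = c(0, cumsum(thick))),
    class = "layered_stack"
  )
}
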