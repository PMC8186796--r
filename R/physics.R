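#' Fluid medium descriptor
#'
#' The buoyancy/drag environment of the settling experiment: the suspension
#' buffer in which spheroids free-fall while the channel flow is at rest.
#'
#' @param density fluid mass density (kg/m^3). Default 1005, a water-like
#'   value representative of Dulbecco's phosphate-buffered saline at 25 C.
#' @param viscosity dynamic viscosity (Pa.s). If `NULL`, derived from
#'   `temperature` with [water_viscosity()].
#' @param temperature temperature in degrees Celsius (annotation, and input
#'   to the viscosity helper when `viscosity` is `NULL`).
#' @return an object of class `fluid_medium` with fields `density`,
#'   `viscosity`, `temperature`.
#' @examples
#' fluid_medium()                      # DPBS-like default
#' fluid_medium(1000, temperature = 20) # water at 20 C
#' @export
fluid_medium <- function(density = 1005, viscosity = NULL, temperature = 25) {
  check_finite(density, "density")
  ss_check(density > 0, "fluid density must be > 0")
  if (is.null(viscosity)) viscosity <- water_viscosity(temperature)
  check_finite(viscosity, "viscosity")
  ss_check(viscosity > 0, "fluid viscosity must be > 0")
  structure(list(density = density, viscosity = viscosity,
                 temperature = temperature),
            class = "fluid_medium")
}

#' Vertical channel geometry
#'
#' @param radius channel inner radius (m).
#' @param gravity gravitational acceleration (m/s^2), default standard
#'   gravity 9.80665.
#' @return an object of class `channel_geometry`.
#' @export
channel_geometry <- function(radius = 0.5e-3, gravity = 9.80665) {
  check_finite(radius, "radius"); check_finite(gravity, "gravity")
  ss_check(radius > 0, "channel radius must be > 0")
  ss_check(gravity > 0, "gravity must be > 0")
  structure(list(radius = radius, gravity = gravity),
            class = "channel_geometry")
}

#' Spheroid physical state
#'
#' @param radius spheroid radius (m).
#' @param mass_density spheroid mass density (kg/m^3).
#' @return an object of class `spheroid_physics`; carries a
#'   `qc_flags` attribute with `"outside_operative_range"` when the diameter
#'   falls outside the 50-500 um operative range of the measurement device.
#' @export
spheroid_physics <- function(radius, mass_density) {
  check_finite(radius, "radius"); check_finite(mass_density, "mass_density")
  ss_check(radius > 0, "spheroid radius must be > 0")
  ss_check(mass_density > 0, "spheroid mass density must be > 0")
  flags <- character()
  d_um <- 2 * radius * 1e6
  if (d_um < 50 || d_um > 500) flags <- "outside_operative_range"
  structure(list(radius = radius, mass_density = mass_density,
                 qc_flags = flags),
            class = "spheroid_physics")
}

#' On-axis cylindrical-tube wall correction factor
#'
#' Multiplicative reduction of the settling velocity of a sphere on the axis
#' of a cylindrical tube relative to an unbounded fluid, as a function of
#' the radius ratio `lambda = r / R`. Polynomial form
#' `K = 1 - 2.104 l + 2.089 l^3 - 0.948 l^5`, clamped to (0, 1].
#'
#' @param lambda sphere-to-tube radius ratio, in `[0, 1)`.
#' @return correction factor `K` in `(0, 1]`.
#' @examples
#' wall_correction_factor(0)    # 1: unbounded fluid
#' wall_correction_factor(0.1)  # ~0.792
#' @export
wall_correction_factor <- function(lambda) {
  check_finite(lambda, "lambda")
  ss_check(all(lambda >= 0), "lambda must be >= 0")
  if (any(lambda >= 1))
    ss_stop("sphere radius must be smaller than the channel radius (lambda < 1)",
            "spherosed_geometry_error")
  k <- 1 - 2.104 * lambda + 2.089 * lambda^3 - 0.948 * lambda^5
  pmin(pmax(k, .Machine$double.eps), 1)
}

#' Stokes terminal velocity of a settling spheroid
#'
#' Closed-form terminal velocity `v = (2/9) (rho_s - rho_f) g r^2 / mu` of a
#' rigid sphere in a quiescent viscous fluid, optionally multiplied by the
#' on-axis cylindrical wall correction `K(r/R)`. Positive values mean the
#' spheroid sinks (density above the fluid's).
#'
#' @param sph a [spheroid_physics()] object.
#' @param fluid a [fluid_medium()] object.
#' @param chan a [channel_geometry()] object.
#' @param wall_correction apply the finite-channel correction? Default
#'   `FALSE` (unbounded-fluid Stokes law).
#' @return terminal velocity in m/s (signed).
#' @examples
#' sph <- spheroid_physics(100e-6, 1050)
#' fl  <- fluid_medium(1000, viscosity = 1e-3)
#' terminal_velocity(sph, fl, channel_geometry())  # ~1.09e-3 m/s
#' @export
terminal_velocity <- function(sph, fluid, chan, wall_correction = FALSE) {
  ss_check(inherits(sph, "spheroid_physics"), "`sph` must be a spheroid_physics")
  ss_check(inherits(fluid, "fluid_medium"), "`fluid` must be a fluid_medium")
  ss_check(inherits(chan, "channel_geometry"), "`chan` must be a channel_geometry")
  if (sph$radius >= chan$radius)
    ss_stop("spheroid radius must be smaller than the channel radius",
            "spherosed_geometry_error")
  v <- 2 / 9 * (sph$mass_density - fluid$density) * chan$gravity *
    sph$radius^2 / fluid$viscosity
  if (wall_correction) v <- v * wall_correction_factor(sph$radius / chan$radius)
  v
}

#' Invert a terminal velocity to a mass density
#'
#' Exact algebraic inverse of [terminal_velocity()]:
#' `rho_s = rho_f + 9 mu v / (2 g r^2 K)`.
#'
#' @param v terminal velocity (m/s, positive = sinking).
#' @param r spheroid radius (m).
#' @param fluid a [fluid_medium()].
#' @param chan a [channel_geometry()].
#' @param wall_correction must match the flag used in the forward model.
#' @return spheroid mass density (kg/m^3).
#' @export
invert_density <- function(v, r, fluid, chan, wall_correction = FALSE) {
  check_finite(v, "v"); check_finite(r, "r")
  ss_check(r > 0, "radius must be > 0")
  k <- 1
  if (wall_correction) {
    if (r >= chan$radius)
      ss_stop("spheroid radius must be smaller than the channel radius",
              "spherosed_geometry_error")
    k <- wall_correction_factor(r / chan$radius)
  }
  fluid$density + 9 * fluid$viscosity * v / (2 * chan$gravity * r^2 * k)
}

#' Spheroid mass and buoyant weight
#'
#' @param rho_s spheroid mass density (kg/m^3).
#' @param r spheroid radius (m).
#' @param fluid a [fluid_medium()] (for the buoyancy term).
#' @param g gravitational acceleration (m/s^2).
#' @return list with `mass_ug` (micrograms) and `buoyant_weight_nN`
#'   (nanonewtons, `(rho_s - rho_f) V g`).
#' @examples
#' mass_and_weight(1050, 100e-6, fluid_medium(1000, viscosity = 1e-3))
#' @export
mass_and_weight <- function(rho_s, r, fluid, g = 9.80665) {
  check_finite(rho_s, "rho_s"); check_finite(r, "r")
  ss_check(rho_s > 0, "rho_s must be > 0")
  ss_check(r > 0, "r must be > 0")
  vol <- 4 / 3 * pi * r^3                       # m^3
  list(mass_ug = rho_s * vol * 1e9,             # kg -> ug
       buoyant_weight_nN = (rho_s - fluid$density) * vol * g * 1e9)  # N -> nN
}

#' Particle Reynolds number
#'
#' `Re = rho_f |v| d / mu` with `d = 2 r`; a validity guard for the Stokes
#' (creeping-flow) regime. Measurements with `Re > 0.5` are flagged rather
#' than refused, since Stokes drag degrades by only a few percent there.
#'
#' @param v velocity (m/s).
#' @param r spheroid radius (m).
#' @param fluid a [fluid_medium()].
#' @return dimensionless Reynolds number (>= 0).
#' @export
reynolds_number <- function(v, r, fluid) {
  check_finite(v, "v"); check_finite(r, "r")
  fluid$density * abs(v) * 2 * r / fluid$viscosity
}

#' Transient settling dynamics of a spheroid
#'
#' Integrates `m_eff dv/dt = (rho_s - rho_f) V g - 6 pi mu r v / K` with
#' `m_eff = rho_s V`, i.e. inertial relaxation toward the Stokes terminal
#' velocity, together with the vertical position `y` (increasing downward).
#' Backs the synthetic video generator and serves as the independent
#' transient-model check of the closed form.
#'
#' @param sph,fluid,chan as in [terminal_velocity()].
#' @param v0 initial velocity (m/s).
#' @param duration total integration time (s).
#' @param dt output time step (s).
#' @param y0 initial position (m).
#' @param wall_correction apply the wall factor to the drag.
#' @param times optional explicit output times (overrides duration/dt).
#' @return data.frame with columns `t`, `y`, `v`.
#' @export
settle_ode <- function(sph, fluid, chan, v0 = 0, duration = NULL, dt = NULL,
                       y0 = 0, wall_correction = FALSE, times = NULL) {
  if (is.null(times)) {
    ss_check(is.numeric(duration) && duration > 0, "duration must be > 0")
    ss_check(is.numeric(dt) && dt > 0, "dt must be > 0")
    times <- seq(0, duration, by = dt)
  }
  check_finite(v0, "v0")
  k <- if (wall_correction)
    wall_correction_factor(sph$radius / chan$radius) else 1
  vol <- 4 / 3 * pi * sph$radius^3
  m_eff <- sph$mass_density * vol
  f_grav <- (sph$mass_density - fluid$density) * vol * chan$gravity
  drag_c <- 6 * pi * fluid$viscosity * sph$radius / k
  deriv <- function(t, state, parms) {
    list(c(dy = state[["v"]],
           dv = (f_grav - drag_c * state[["v"]]) / m_eff))
  }
  out <- deSolve::lsoda(c(y = y0, v = v0), times, deriv, parms = NULL,
                        rtol = 1e-12, atol = 1e-14)
  data.frame(t = out[, "time"], y = out[, "y"], v = out[, "v"])
}

#' Viscous relaxation time of the settling transient
#'
#' `tau = m_eff / (6 pi mu r / K) = (2/9) rho_s r^2 K / mu`; the e-folding
#' time over which [settle_ode()] converges to the terminal velocity.
#'
#' @inheritParams terminal_velocity
#' @return relaxation time (s).
#' @export
relaxation_time <- function(sph, fluid, chan, wall_correction = FALSE) {
  k <- if (wall_correction)
    wall_correction_factor(sph$radius / chan$radius) else 1
  2 / 9 * sph$mass_density * sph$radius^2 * k / fluid$viscosity
}

#' Dynamic viscosity of water
#'
#' Vogel-type empirical curve `mu = A exp(B / (T_K - C))` with
#' `A = 2.939e-5 Pa.s`, `B = 507.88 K`, `C = 149.3 K`; within 2% of the
#' reference value 1.002e-3 Pa.s at 20 C over the validity range.
#'
#' @param temperature temperature in degrees Celsius, in (0, 60).
#' @return dynamic viscosity (Pa.s).
#' @examples
#' water_viscosity(20)  # ~1.00e-3
#' @export
water_viscosity <- function(temperature) {
  check_finite(temperature, "temperature")
  ss_check(all(temperature > 0 & temperature < 60),
           "temperature must be in (0, 60) C")
  2.939e-5 * exp(507.88 / (temperature + 273.15 - 149.3))
}

#' Assemble a per-spheroid biophysical measurement record
#'
#' Bundles the quantities the sedimentation assay reports for one spheroid,
#' enforcing unit consistency between density, diameter, mass, buoyant
#' weight and Reynolds number.
#'
#' @param terminal_velocity m/s. @param velocity_se m/s.
#' @param diameter_um spheroid diameter, micrometers.
#' @param mass_density_kg_m3 spheroid density, kg/m^3.
#' @param fluid a [fluid_medium()]. @param chan a [channel_geometry()].
#' @param n_repetitions number of fall repetitions averaged.
#' @param qc_flags character vector of warning codes.
#' @param reynolds_threshold flag "stokes_regime_violated" above this.
#' @return object of class `biophysical_measurement`: fields
#'   `terminal_velocity`, `velocity_se`, `diameter` (um), `mass_density`
#'   (g/cm^3), `mass` (ug), `buoyant_weight` (nN), `reynolds`,
#'   `n_repetitions`, `qc_flags`.
#' @export
biophysical_measurement <- function(terminal_velocity, velocity_se,
                                    diameter_um, mass_density_kg_m3,
                                    fluid, chan, n_repetitions = 1L,
                                    qc_flags = character(),
                                    reynolds_threshold = 0.5) {
  check_finite(terminal_velocity, "terminal_velocity")
  check_finite(diameter_um, "diameter_um")
  ss_check(diameter_um > 0, "diameter must be > 0")
  r_m <- diameter_um / 2 * 1e-6
  mw <- mass_and_weight(mass_density_kg_m3, r_m, fluid, chan$gravity)
  re <- reynolds_number(terminal_velocity, r_m, fluid)
  if (re > reynolds_threshold)
    qc_flags <- union(qc_flags, "stokes_regime_violated")
  if (diameter_um < 50 || diameter_um > 500)
    qc_flags <- union(qc_flags, "outside_operative_range")
  structure(list(
    terminal_velocity = terminal_velocity,
    velocity_se = velocity_se,
    diameter = diameter_um,
    mass_density = mass_density_kg_m3 / 1000,  # g/cm^3
    mass = mw$mass_ug,
    buoyant_weight = mw$buoyant_weight_nN,
    reynolds = re,
    n_repetitions = as.integer(n_repetitions),
    qc_flags = qc_flags
  ), class = "biophysical_measurement")
}

#' @export
print.biophysical_measurement <- function(x, ...) {
  cat("Spheroid biophysical measurement\n")
  cat(sprintf("  terminal velocity: %.4g m/s (se %.2g)\n",
              x$terminal_velocity, x$velocity_se))
  cat(sprintf("  diameter:          %.1f um\n", x$diameter))
  cat(sprintf("  mass density:      %.4f g/cm^3\n", x$mass_density))
  cat(sprintf("  mass:              %.4g ug\n", x$mass))
  cat(sprintf("  buoyant weight:    %.4g nN\n", x$buoyant_weight))
  cat(sprintf("  Reynolds number:   %.3g\n", x$reynolds))
  cat(sprintf("  repetitions:       %d\n", x$n_repetitions))
  if (length(x$qc_flags))
    cat("  QC flags:          ", paste(x$qc_flags, collapse = "; "), "\n")
  invisible(x)
}
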