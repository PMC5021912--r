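# Per-lung parameters, state, and the pressure/volume/mass rate equations.
#
# Each lung is a variable-volume container of isothermal ideal gas
# (p V = m R theta) whose wall obeys a linear compliance C = dV/dp.
# Substituting dV = C dp into the differential gas law
#   V dp/dt + p dV/dt = R theta q
# gives the closed-form pressure rate
#   dp/dt = R theta q V / (V^2 + C m R theta),
# with dV/dt = C dp/dt and dm/dt = q.

#' Lung parameters
#'
#' Clinical-unit parameters of one lung compartment: linear respiratory
#' compliance, equivalent throttle geometry, and resting gas volume.
#'
#' @param C Respiratory compliance in mL/cmH2O.
#' @param d Equivalent throttle inlet diameter in mm.
#' @param Cd Discharge coefficient of the throttle, default 1.
#' @param V0 Initial (resting) gas volume in litres. Default 1.5 L, an
#'   adult-lung-simulator scale; the pressure rate depends on V only weakly
#'   because the compliance term dominates the denominator.
#' @return An object of class `"lung_parameters"`: `C` (mL/cmH2O), `C_si`
#'   (m^3/Pa), `throttle` ([throttle_geometry()]), `V0` (L), `V0_si` (m^3).
#' @examples
#' lung_parameters()            # reference lung: C 10 mL/cmH2O, d 3.2 mm
#' lung_parameters(C = 8)       # stiffer lung
#' @export
lung_parameters <- function(C = 10, d = 3.2, Cd = 1, V0 = 1.5) {
  if (!is.numeric(C) || length(C) != 1 || !is.finite(C) || C <= 0)
    stop("compliance 'C' must be a positive scalar (mL/cmH2O)", call. = FALSE)
  if (!is.numeric(V0) || length(V0) != 1 || !is.finite(V0) || V0 <= 0)
    stop("initial volume 'V0' must be a positive scalar (L)", call. = FALSE)
  structure(list(C = C, C_si = C * 1e-6 / .cmh2o_pa,
                 throttle = throttle_geometry(d, Cd),
                 V0 = V0, V0_si = V0 * 1e-3),
            class = "lung_parameters")
}

#' @export
print.lung_parameters <- function(x, ...) {
  cat(sprintf("Lung: C %g mL/cmH2O, throttle d %g mm (Cd %g), V0 %g L\n",
              x$C, x$throttle$d, x$throttle$Cd, x$V0))
  invisible(x)
}

#' Lung state
#'
#' Instantaneous gas state of one lung in SI units.
#'
#' @param p Absolute gas pressure (Pa).
#' @param V Gas volume (m^3).
#' @param m Gas mass (kg).
#' @return An object of class `"lung_state"`.
#' @export
lung_state <- function(p, V, m) {
  if (any(!is.finite(c(p, V, m))) || p <= 0 || V <= 0 || m <= 0)
    stop("lung state requires positive finite p, V, m", call. = FALSE)
  structure(list(p = p, V = V, m = m), class = "lung_state")
}

#' Initialise a lung state on the gas law
#'
#' Builds a [lung_state()] at a given gauge pressure and the lung's resting
#' volume, with the mass forced by the ideal-gas law so the state starts
#' exactly on the constraint manifold.
#'
#' @param params A [lung_parameters()] object.
#' @param gas A [gas_properties()] object.
#' @param p_start Starting pressure, cmH2O gauge (typically the EPAP level).
#' @return A [lung_state()] with zero ideal-gas residual.
#' @examples
#' st <- init_lung_state(lung_parameters(), gas_properties(), p_start = 4)
#' ideal_gas_residual(st, gas_properties())
#' @export
init_lung_state <- function(params, gas, p_start) {
  stopifnot(inherits(params, "lung_parameters"), inherits(gas, "gas_properties"))
  p <- cmh2o_to_pa(p_start)
  V <- params$V0_si
  lung_state(p, V, p * V / (gas$R_specific * gas$theta))
}

# closed-form rates, no validation; q in kg/s, C_si in m^3/Pa
.lung_rates <- function(p, V, m, q, C_si, Rs, theta) {
  dp <- Rs * theta * q * V / (V * V + C_si * m * Rs * theta)
  c(dp = dp, dV = C_si * dp, dm = q)
}

#' Lung state rates
#'
#' Time derivatives of (p, V, m) for a given instantaneous mass inflow,
#' from the isothermal ideal-gas law combined with linear compliance:
#' `dp/dt = R theta q V / (V^2 + C m R theta)`, `dV/dt = C dp/dt`,
#' `dm/dt = q`.
#'
#' @param state A [lung_state()].
#' @param q Mass inflow (kg s^-1), signed (negative during expiration).
#' @param params A [lung_parameters()] object (compliance used in SI form).
#' @param gas A [gas_properties()] object.
#' @return Named numeric vector `c(dp, dV, dm)` in Pa/s, m^3/s, kg/s.
#' @export
lung_rates <- function(state, q, params, gas) {
  stopifnot(inherits(state, "lung_state"), inherits(params, "lung_parameters"),
            inherits(gas, "gas_properties"))
  .lung_rates(state$p, state$V, state$m, q, params$C_si,
              gas$R_specific, gas$theta)
}

#' Relative ideal-gas residual
#'
#' The gas law `p V = m R theta` is an algebraic invariant of the rate
#' equations; along an exact trajectory it is conserved, so its relative
#' residual `(p V - m R theta) / (p V)` measures integrator drift.
#'
#' @param state A [lung_state()].
#' @param gas A [gas_properties()] object.
#' @return Dimensionless relative residual (0 for a consistent state).
#' @export
ideal_gas_residual <- function(state, gas) {
  stopifnot(inherits(state, "lung_state"), inherits(gas, "gas_properties"))
  (state$p * state$V - state$m * gas$R_specific * gas$theta) /
    (state$p * state$V)
}
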