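# Gas constants, clinical <-> SI unit conversions, and the compressible
# orifice mass-flow law. All internal computation is SI: Pa absolute, m^3,
# kg, s, K. Clinical units (cmH2O gauge, mm, mL, L) appear only at the
# configuration and reporting boundaries.

# unit constants: 1 cmH2O in Pa, and the atmospheric reference (Pa absolute)
.cmh2o_pa <- 98.0665
.p_atm <- 101325

#' Critical pressure ratio of an orifice
#'
#' Downstream/upstream absolute-pressure ratio at which compressible orifice
#' flow chokes: `b = (2/(k+1))^(k/(k-1))`. For ratios at or below `b` the
#' flow is sonic and no longer depends on the downstream pressure; the
#' subsonic and sonic flow expressions coincide exactly at `b`.
#'
#' @param k Ratio of specific heats (dimensionless), must exceed 1.
#'   For air, `k = 1.4` gives `b` close to 0.5283.
#' @return The critical pressure ratio, in (0, 1).
#' @examples
#' critical_pressure_ratio(1.4)
#' @export
critical_pressure_ratio <- function(k) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 1))
    stop("heat-capacity ratio 'k' must be finite and > 1", call. = FALSE)
  (2 / (k + 1))^(k / (k - 1))
}

#' Gas properties of the ventilated air
#'
#' Bundles the constants entering the flow and pressure equations: the
#' specific gas constant, the heat-capacity ratio, the (single, constant)
#' absolute temperature of the isothermal model, and the critical pressure
#' ratio derived from `k`.
#'
#' @param R_specific Specific gas constant (J kg^-1 K^-1). Default 287.05,
#'   dry air.
#' @param k Ratio of specific heats (dimensionless). Default 1.4.
#' @param theta Absolute temperature (K). Default 293.15 (20 degrees C).
#'   One temperature governs both the orifice law and the lung gas law;
#'   the whole process is modelled as isothermal.
#' @return An object of class `"gas_properties"`: list with `R_specific`,
#'   `k`, `theta`, `b`.
#' @examples
#' gas_properties()
#' @export
gas_properties <- function(R_specific = 287.05, k = 1.4, theta = 293.15) {
  if (!is.numeric(R_specific) || length(R_specific) != 1 || R_specific <= 0)
    stop("'R_specific' must be a positive scalar", call. = FALSE)
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0)
    stop("'theta' must be a positive scalar (absolute temperature, K)",
         call. = FALSE)
  b <- critical_pressure_ratio(k)
  structure(list(R_specific = R_specific, k = k, theta = theta, b = b),
            class = "gas_properties")
}

#' @export
print.gas_properties <- function(x, ...) {
  cat("Gas properties:\n")
  cat(sprintf("  R = %.2f J/(kg K), k = %.3f, theta = %.2f K, b = %.4f\n",
              x$R_specific, x$k, x$theta, x$b))
  invisible(x)
}

#' Convert cmH2O gauge pressure to absolute Pa
#'
#' Clinical airway pressures are quoted in cmH2O gauge; the gas dynamics
#' require absolute pascals. Uses 1 cmH2O = 98.0665 Pa and an atmospheric
#' reference of 101325 Pa.
#'
#' @param p_gauge Gauge pressure(s) in cmH2O.
#' @return Absolute pressure(s) in Pa.
#' @seealso [pa_to_cmh2o()] for the exact inverse.
#' @examples
#' cmh2o_to_pa(0)    # atmospheric
#' cmh2o_to_pa(22)   # reference IPAP
#' @export
cmh2o_to_pa <- function(p_gauge) {
  p <- .p_atm + p_gauge * .cmh2o_pa
  if (any(!is.finite(p)) || any(p <= 0))
    stop("gauge pressure below vacuum: absolute pressure must be positive",
         call. = FALSE)
  p
}

#' Convert absolute Pa to cmH2O gauge
#'
#' @param p_abs Absolute pressure(s) in Pa.
#' @return Gauge pressure(s) in cmH2O.
#' @export
pa_to_cmh2o <- function(p_abs) (p_abs - .p_atm) / .cmh2o_pa

#' Equivalent throttle geometry
#'
#' The respiratory tract plus tubing of each lung is lumped into one
#' equivalent throttle (orifice). Its effective area is
#' `Ae = Cd * pi * (d/2)^2`.
#'
#' @param d Inlet diameter in mm.
#' @param Cd Discharge coefficient in (0, 1]; default 1 (the inlet diameter
#'   is taken as the diameter of the effective area).
#' @return An object of class `"throttle_geometry"`: list with `d` (mm),
#'   `Cd`, and `Ae` (m^2).
#' @examples
#' throttle_geometry(3.2)
#' @export
throttle_geometry <- function(d, Cd = 1) {
  if (!is.numeric(d) || length(d) != 1 || !is.finite(d) || d <= 0)
    stop("throttle diameter 'd' must be a positive scalar (mm)", call. = FALSE)
  if (!is.numeric(Cd) || length(Cd) != 1 || Cd <= 0 || Cd > 1)
    stop("discharge coefficient 'Cd' must lie in (0, 1]", call. = FALSE)
  Ae <- Cd * pi * (d * 1e-3 / 2)^2
  structure(list(d = d, Cd = Cd, Ae = Ae), class = "throttle_geometry")
}

# bare-metal orifice flow used inside the integrator: no validation,
# scalar or vector inputs, constants passed explicitly
.orifice_q <- function(p_up, p_down, Ae, Rs, k, theta, b) {
  s <- ifelse(p_up >= p_down, 1, -1)
  u <- pmax(p_up, p_down)
  w <- pmin(p_up, p_down)
  r <- pmax(w / u, b)  # choked flow: freeze the ratio at b
  phi <- r^(2 / k) - r^((k + 1) / k)
  s * Ae * u * sqrt(1 / theta) * sqrt((2 * k / (k - 1)) * phi / Rs)
}

#' Compressible orifice mass flow
#'
#' Signed mass flow through an equivalent throttle between two absolute
#' pressures. With `u = max(p_up, p_down)`, `w = min(p_up, p_down)` and
#' pressure ratio `r = w/u`, the subsonic branch (`r > b`) is
#' \deqn{q = Ae\, u \sqrt{1/\theta}\sqrt{\frac{2k}{k-1}\frac{1}{R}
#'       \left(r^{2/k} - r^{(k+1)/k}\right)},}
#' and for `r <= b` the flow is choked: the same expression evaluated at
#' the critical ratio `b`, independent of the downstream pressure. The sign
#' follows the pressure gradient: positive when `p_up >= p_down` (flow from
#' the nominal upstream port into the nominal downstream port), negative
#' otherwise, so one throttle carries both inspiratory and expiratory flow.
#'
#' @param p_up,p_down Absolute pressures (Pa) at the nominal upstream and
#'   downstream ports. Vectorised.
#' @param Ae Effective orifice area (m^2), `>= 0`.
#' @param gas A [gas_properties()] object.
#' @return Mass flow in kg s^-1 (signed).
#' @examples
#' g <- gas_properties()
#' orifice_mass_flow(cmh2o_to_pa(22), cmh2o_to_pa(4),
#'                   throttle_geometry(3.2)$Ae, g)
#' @export
orifice_mass_flow <- function(p_up, p_down, Ae, gas = gas_properties()) {
  if (any(!is.finite(p_up)) || any(p_up <= 0) ||
      any(!is.finite(p_down)) || any(p_down <= 0))
    stop("absolute pressures must be positive and finite", call. = FALSE)
  if (any(!is.finite(Ae)) || any(Ae < 0))
    stop("effective area 'Ae' must be non-negative", call. = FALSE)
  stopifnot(inherits(gas, "gas_properties"))
  .orifice_q(p_up, p_down, Ae, gas$R_specific, gas$k, gas$theta, gas$b)
}
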