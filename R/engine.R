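# Coupled ventilator--two-lung integration. The setpoint waveform is only
# piecewise smooth, so the integrator is restarted at the waveform
# breakpoints {0, Tr, Ti} of every cycle and never steps across a corner
# or the expiratory step discontinuity.

#' Simulation control parameters
#'
#' @param n_warmup Number of warm-up breath cycles integrated before
#'   recording starts (default 5; the reference scenario reaches a periodic
#'   state within 2--3 cycles).
#' @param n_record Number of recorded cycles (default 3).
#' @param rel_tol,abs_tol Integrator tolerances (lsoda), in SI state units.
#' @param output_dt Uniform reporting grid spacing (s), default 1 ms.
#' @param steady_tol Relative change threshold on per-cycle tidal volumes
#'   between the last two warm-up cycles below which the run is flagged
#'   steady.
#' @param max_step Maximum integrator step (s); default `Tr/10` so the
#'   ramp is always resolved.
#' @return An object of class `"sim_control"`.
#' @export
sim_control <- function(n_warmup = 5, n_record = 3, rel_tol = 1e-8,
                        abs_tol = 1e-10, output_dt = 1e-3,
                        steady_tol = 1e-4, max_step = NULL) {
  if (n_warmup < 0 || n_record < 1)
    stop("need n_warmup >= 0 and n_record >= 1", call. = FALSE)
  if (rel_tol <= 0 || abs_tol <= 0 || output_dt <= 0 || steady_tol <= 0)
    stop("tolerances and output_dt must be positive", call. = FALSE)
  if (!is.null(max_step) && max_step <= 0)
    stop("'max_step' must be positive", call. = FALSE)
  structure(list(n_warmup = as.integer(n_warmup),
                 n_record = as.integer(n_record),
                 rel_tol = rel_tol, abs_tol = abs_tol,
                 output_dt = output_dt, steady_tol = steady_tol,
                 max_step = max_step),
            class = "sim_control")
}

#' System derivatives of the two-lung BIPAP circuit
#'
#' One right-hand-side evaluation of the coupled model: the ventilator
#' setpoint (an ideal pressure source) drives each lung through its
#' equivalent throttle, `q_i = orifice_mass_flow(p_vent, p_i, Ae_i)`, and
#' each lung responds with [lung_rates()]. Total flow is `q_s = q_r + q_l`.
#'
#' @param t Time (s) on the ventilator clock.
#' @param state_r,state_l [lung_state()] of the right and left lung.
#' @param settings [ventilator_settings()].
#' @param params_r,params_l [lung_parameters()] of the two lungs.
#' @param gas [gas_properties()].
#' @return List with `q_r`, `q_l`, `q_s` (kg/s), `p_vent` (cmH2O gauge),
#'   and `rates_r`, `rates_l` (named `c(dp, dV, dm)` vectors).
#' @export
system_derivatives <- function(t, state_r, state_l, settings,
                               params_r, params_l, gas) {
  pv <- cmh2o_to_pa(pressure_setpoint(t, settings))
  q_r <- orifice_mass_flow(pv, state_r$p, params_r$throttle$Ae, gas)
  q_l <- orifice_mass_flow(pv, state_l$p, params_l$throttle$Ae, gas)
  list(q_r = q_r, q_l = q_l, q_s = q_r + q_l,
       p_vent = pa_to_cmh2o(pv),
       rates_r = lung_rates(state_r, q_r, params_r, gas),
       rates_l = lung_rates(state_l, q_l, params_l, gas))
}

# volume excursion (max - min) over a set of rows
.excursion <- function(v) max(v) - min(v)

#' Simulate the BIPAP two-lung system
#'
#' Integrates the coupled pressure/volume/mass equations of both lungs
#' under the BIPAP setpoint waveform for `n_warmup + n_record` breath
#' cycles and returns the recorded cycles on a uniform time grid. The
#' integration is restarted at every waveform breakpoint (end of ramp, end
#' of inspiration, end of cycle) so the piecewise-smooth forcing never
#' degrades the integrator order.
#'
#' @param settings [ventilator_settings()].
#' @param lung_r,lung_l [lung_parameters()] for the right and left lung;
#'   `lung_l` defaults to the same parameters as `lung_r`.
#' @param gas [gas_properties()].
#' @param control [sim_control()].
#' @param p_init Initial lung pressure, cmH2O gauge; default the EPAP
#'   level (steady cycling starts from the expiratory baseline).
#' @return An object of class `"bipap_sim"`: a list with
#'   \describe{
#'     \item{trajectory}{data frame over the recorded cycles, one row per
#'       grid point (half-open in time, `n_record * T / output_dt` rows):
#'       `t` (s), `cycle`, `phase` ("insp"/"exp"), `p_vent`, `p_r`, `p_l`
#'       (cmH2O gauge), `p_r_pa`, `p_l_pa` (Pa absolute), `V_r`, `V_l`
#'       (m^3), `m_r`, `m_l` (kg), `q_r`, `q_l`, `q_s` (kg/s; `q_s` is the
#'       exact sum of the other two).}
#'     \item{steady}{logical: did per-cycle tidal volumes of both lungs
#'       change by less than `steady_tol` between the last two warm-up
#'       cycles? `NA` if fewer than two warm-up cycles.}
#'     \item{warmup_vt}{matrix of warm-up per-cycle volume excursions
#'       (m^3), columns `r`, `l`.}
#'   }
#'   plus the inputs (`settings`, `lung_r`, `lung_l`, `gas`, `control`)
#'   and `period` (s). A non-steady run raises a warning, not an error.
#' @examples
#' \donttest{
#' sim <- simulate_bipap(ventilator_settings(), lung_parameters(),
#'                       control = sim_control(n_warmup = 2, n_record = 1))
#' sim
#' }
#' @export
simulate_bipap <- function(settings = ventilator_settings(),
                           lung_r = lung_parameters(),
                           lung_l = lung_r,
                           gas = gas_properties(),
                           control = sim_control(),
                           p_init = NULL) {
  stopifnot(inherits(settings, "ventilator_settings"),
            inherits(lung_r, "lung_parameters"),
            inherits(lung_l, "lung_parameters"),
            inherits(gas, "gas_properties"),
            inherits(control, "sim_control"))
  if (is.null(p_init)) p_init <- settings$EPAP

  T_cyc <- cycle_period(settings)
  dt <- control$output_dt
  n_tot <- control$n_warmup + control$n_record
  hmax <- if (is.null(control$max_step)) settings$Tr / 10 else control$max_step

  # constants captured by the RHS closure
  Rs <- gas$R_specific; th <- gas$theta; k <- gas$k; b <- gas$b
  Ae_r <- lung_r$throttle$Ae; Ae_l <- lung_l$throttle$Ae
  Cr <- lung_r$C_si; Cl <- lung_l$C_si
  IPAP <- settings$IPAP; EPAP <- settings$EPAP
  BPM <- settings$BPM; Ti <- settings$Ti; Tr <- settings$Tr

  # the setpoint is only piecewise smooth; each integration segment gets
  # the smooth extension of its own piece (parms = c(slope, intercept) on
  # the local clock), so a small internal overshoot of the segment end
  # never crosses the expiratory step discontinuity
  cflow <- sqrt(2 * k / (k - 1) / Rs) * sqrt(1 / th)  # constant factor of the flow law
  e1 <- 2 / k; e2 <- (k + 1) / k
  rhs <- function(t, y, parms) {
    pv <- .p_atm + (parms[1] * t + parms[2]) * .cmh2o_pa
    # scalar orifice flow, subsonic or choked, sign along the gradient
    p1 <- y[1]
    if (pv >= p1) { u <- pv; r <- p1 / pv; s <- 1 } else { u <- p1; r <- pv / p1; s <- -1 }
    if (r < b) r <- b
    q_r <- s * Ae_r * u * cflow * sqrt(r^e1 - r^e2)
    p2 <- y[4]
    if (pv >= p2) { u <- pv; r <- p2 / pv; s <- 1 } else { u <- p2; r <- pv / p2; s <- -1 }
    if (r < b) r <- b
    q_l <- s * Ae_l * u * cflow * sqrt(r^e1 - r^e2)
    dpr <- Rs * th * q_r * y[2] / (y[2] * y[2] + Cr * y[3] * Rs * th)
    dpl <- Rs * th * q_l * y[5] / (y[5] * y[5] + Cl * y[6] * Rs * th)
    list(c(dpr, Cr * dpr, q_r, dpl, Cl * dpl, q_l))
  }

  st_r <- init_lung_state(lung_r, gas, p_init)
  st_l <- init_lung_state(lung_l, gas, p_init)
  y <- c(st_r$p, st_r$V, st_r$m, st_l$p, st_l$V, st_l$m)

  n_grid <- round(n_tot * T_cyc / dt)
  t_grid <- (0:n_grid) * dt
  out <- matrix(NA_real_, n_grid + 1L, 6L)
  out[1L, ] <- y

  segs <- c(0, Tr, Ti, T_cyc)
  for (cyc in seq_len(n_tot) - 1L) {
    t_cyc0 <- cyc * T_cyc
    # (slope, intercept) of the setpoint piece on the global clock
    ramp <- (IPAP - EPAP) / Tr
    piece <- list(c(ramp, EPAP - ramp * t_cyc0),  # rise
                  c(0, IPAP),                      # plateau
                  c(0, EPAP))                      # expiration
    for (s in 1:3) {
      a <- t_cyc0 + segs[s]
      bnd <- t_cyc0 + segs[s + 1]
      if (bnd - a < 1e-12) next  # degenerate segment (e.g. Tr == Ti)
      gi <- which(t_grid > a + 1e-12 & t_grid <= bnd + 1e-12)
      times <- c(a, t_grid[gi])
      if (length(times) < 2 || times[length(times)] < bnd - 1e-12)
        times <- c(times, bnd)
      sol <- deSolve::lsoda(y, times, rhs, parms = piece[[s]],
                            rtol = control$rel_tol, atol = control$abs_tol,
                            hmax = hmax)
      if (attr(sol, "istate")[1] < 0)
        stop(sprintf("integration failed in cycle %d, segment [%g, %g] s",
                     cyc + 1L, a, bnd), call. = FALSE)
      y <- as.numeric(sol[nrow(sol), -1])
      if (length(gi))
        out[gi, ] <- sol[match(t_grid[gi], sol[, 1]), -1, drop = FALSE]
    }
  }

  # warm-up per-cycle volume excursions and steadiness flag
  warm_vt <- NULL
  steady <- NA
  if (control$n_warmup >= 1) {
    warm_vt <- t(vapply(seq_len(control$n_warmup), function(i) {
      rows <- which(t_grid >= (i - 1) * T_cyc - 1e-12 &
                    t_grid < i * T_cyc - 1e-12)
      c(r = .excursion(out[rows, 2]), l = .excursion(out[rows, 5]))
    }, numeric(2)))
    if (control$n_warmup >= 2) {
      a <- warm_vt[control$n_warmup - 1L, ]
      bb <- warm_vt[control$n_warmup, ]
      denom <- pmax(a, .Machine$double.eps)
      steady <- all(abs(bb - a) / denom < control$steady_tol | a + bb == 0)
      if (!steady)
        warning("tidal volumes still changing after warm-up; trajectory may not be at periodic steady state")
    }
  }

  # recorded portion: half-open [t0, t0 + n_record*T), uniform grid
  t0 <- control$n_warmup * T_cyc
  rec <- which(t_grid >= t0 - 1e-12 & t_grid < n_tot * T_cyc - 1e-12)
  tt <- t_grid[rec]
  pv_cm <- .setpoint(tt, IPAP, EPAP, BPM, Ti, Tr)
  pv_pa <- .p_atm + pv_cm * .cmh2o_pa
  q_r <- .orifice_q(pv_pa, out[rec, 1], Ae_r, Rs, k, th, b)
  q_l <- .orifice_q(pv_pa, out[rec, 4], Ae_l, Rs, k, th, b)
  tloc <- (tt - t0) %% T_cyc
  traj <- data.frame(
    t = tt,
    cycle = pmin(floor((tt - t0) / T_cyc + 1e-12), control$n_record - 1L) + 1L,
    phase = ifelse(tloc < Ti - 1e-12, "insp", "exp"),
    p_vent = pv_cm,
    p_r = pa_to_cmh2o(out[rec, 1]), p_l = pa_to_cmh2o(out[rec, 4]),
    p_r_pa = out[rec, 1], p_l_pa = out[rec, 4],
    V_r = out[rec, 2], V_l = out[rec, 5],
    m_r = out[rec, 3], m_l = out[rec, 6],
    q_r = q_r, q_l = q_l, q_s = q_r + q_l)

  structure(list(trajectory = traj, settings = settings,
                 lung_r = lung_r, lung_l = lung_l, gas = gas,
                 control = control, period = T_cyc,
                 steady = steady, warmup_vt = warm_vt),
            class = "bipap_sim")
}

#' Per-cycle segmentation of a trajectory
#'
#' Splits the recorded trajectory into breath cycles and each cycle into
#' inspiration (`[0, Ti)` on the waveform clock) and expiration
#' (`[Ti, T)`). Ranges are half-open sample index sets: non-overlapping
#' and jointly covering every trajectory row.
#'
#' @param sim A `"bipap_sim"` object.
#' @return A list with one element per recorded cycle, each a list with
#'   `cycle`, `idx`, `insp`, `exp` (integer row indices into
#'   `sim$trajectory`).
#' @export
segment_cycles <- function(sim) {
  stopifnot(inherits(sim, "bipap_sim"))
  traj <- sim$trajectory
  if (nrow(traj) == 0) stop("trajectory spans less than one cycle", call. = FALSE)
  lapply(seq_len(sim$control$n_record), function(i) {
    idx <- which(traj$cycle == i)
    list(cycle = i, idx = idx,
         insp = idx[traj$phase[idx] == "insp"],
         exp = idx[traj$phase[idx] == "exp"])
  })
}
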