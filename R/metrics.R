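# Breath metrics: instantaneous flow-split ratio and per-cycle tidal
# volumes / tidal-volume share.

#' Flow-split ratio time series
#'
#' The instantaneous fraction of total mass flow entering the right lung,
#' `q_r(t) / q_s(t)`. The ratio is ill-conditioned where the total flow
#' vanishes (phase switches, and the zero-flow tails after each lung
#' equilibrates with the setpoint), so samples with `|q_s| <= eps` are
#' masked rather than clamped; on unmasked samples the ratio may lie
#' outside `[0, 1]` when the two lung flows have opposite signs
#' (transient inter-lung redistribution) and is reported raw.
#'
#' @param sim A `"bipap_sim"` object from [simulate_bipap()].
#' @param eps Mass-flow floor (kg s^-1) below which `|q_s|` is treated as
#'   zero; default 1e-7 (about 0.005 L/min of air).
#' @return Data frame with `t`, `cycle`, `phase`, `ratio` (`NA` where
#'   masked) and logical `valid`.
#' @examples
#' \donttest{
#' sim <- simulate_bipap(control = sim_control(n_warmup = 2, n_record = 1))
#' fr <- flow_ratio_series(sim)
#' range(fr$ratio[fr$valid])
#' }
#' @export
flow_ratio_series <- function(sim, eps = 1e-7) {
  stopifnot(inherits(sim, "bipap_sim"))
  if (eps < 0) stop("'eps' must be non-negative", call. = FALSE)
  traj <- sim$trajectory
  valid <- abs(traj$q_s) > eps
  data.frame(t = traj$t, cycle = traj$cycle, phase = traj$phase,
             ratio = ifelse(valid, traj$q_r / traj$q_s, NA_real_),
             valid = valid)
}

#' Per-cycle tidal volumes and tidal-volume share
#'
#' Tidal volume is the per-cycle gas volume excursion of each lung,
#' `VT_i = max V_i - min V_i` over the cycle (for a periodic breath this
#' equals the integral of inspiratory volumetric flow). The share is
#' `VT_r / (VT_r + VT_l)`.
#'
#' @param sim A `"bipap_sim"` object.
#' @return Data frame with one row per recorded cycle: `cycle`, `VT_r_mL`,
#'   `VT_l_mL`, `VT_s_mL`, `vt_share_r`. In the degenerate case
#'   `VT_s = 0` (e.g. IPAP = EPAP) the share is `NA` and the row is
#'   flagged by the logical `degenerate` column.
#' @examples
#' \donttest{
#' sim <- simulate_bipap(control = sim_control(n_warmup = 2, n_record = 1))
#' tidal_volumes(sim)
#' }
#' @export
tidal_volumes <- function(sim) {
  stopifnot(inherits(sim, "bipap_sim"))
  cyc <- segment_cycles(sim)
  traj <- sim$trajectory
  rows <- lapply(cyc, function(cc) {
    vt_r <- .excursion(traj$V_r[cc$idx]) * 1e6  # m^3 -> mL
    vt_l <- .excursion(traj$V_l[cc$idx]) * 1e6
    vt_s <- vt_r + vt_l
    data.frame(cycle = cc$cycle, VT_r_mL = vt_r, VT_l_mL = vt_l,
               VT_s_mL = vt_s,
               vt_share_r = if (vt_s > 0) vt_r / vt_s else NA_real_,
               degenerate = vt_s == 0)
  })
  do.call(rbind, rows)
}

#' Summarise a set of swept scenarios
#'
#' Builds the one-row-per-scenario sweep table: swept value, mean per-cycle
#' tidal volumes, tidal-volume share, and the flow-ratio extrema within
#' each breath phase. Rows are ordered by the swept value.
#'
#' @param sims List of `"bipap_sim"` objects, one per scenario.
#' @param parameter Character scalar (or vector, one per scenario) naming
#'   the swept parameter; mixing different parameters in one table is an
#'   error.
#' @param values Numeric vector of swept values, same length as `sims`.
#' @param eps Mass-flow floor passed to [flow_ratio_series()].
#' @return Data frame with columns `parameter`, `value`, `VT_r_mL`,
#'   `VT_l_mL`, `VT_s_mL`, `vt_share_r`, `ratio_insp_min`,
#'   `ratio_insp_max`, `ratio_exp_min`, `ratio_exp_max`.
#' @export
sweep_summary <- function(sims, parameter, values, eps = 1e-7) {
  if (length(unique(parameter)) != 1L)
    stop("cannot mix different swept parameters in one sweep table",
         call. = FALSE)
  if (length(sims) != length(values) || length(sims) == 0)
    stop("'sims' and 'values' must be non-empty and of equal length",
         call. = FALSE)
  rows <- Map(function(sim, val) {
    stopifnot(inherits(sim, "bipap_sim"))
    tv <- tidal_volumes(sim)
    fr <- flow_ratio_series(sim, eps)
    ext <- function(ph) {
      r <- fr$ratio[fr$valid & fr$phase == ph]
      if (!length(r)) c(NA_real_, NA_real_) else range(r)
    }
    ri <- ext("insp"); re <- ext("exp")
    data.frame(parameter = parameter[1], value = val,
               VT_r_mL = mean(tv$VT_r_mL), VT_l_mL = mean(tv$VT_l_mL),
               VT_s_mL = mean(tv$VT_s_mL),
               vt_share_r = mean(tv$vt_share_r),
               ratio_insp_min = ri[1], ratio_insp_max = ri[2],
               ratio_exp_min = re[1], ratio_exp_max = re[2])
  }, sims, values)
  tab <- do.call(rbind, rows)
  tab[order(tab$value), , drop = FALSE]
}
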