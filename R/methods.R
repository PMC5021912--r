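# S3 methods for simulation and sweep objects.

#' @export
print.bipap_sim <- function(x, ...) {
  s <- x$settings
  cat("BIPAP two-lung simulation\n")
  cat(sprintf("  ventilator: IPAP %g / EPAP %g cmH2O, %g bpm, Ti %g s, Tr %g s\n",
              s$IPAP, s$EPAP, s$BPM, s$Ti, s$Tr))
  cat(sprintf("  right lung: C %g mL/cmH2O, d %g mm;  left lung: C %g mL/cmH2O, d %g mm\n",
              x$lung_r$C, x$lung_r$throttle$d, x$lung_l$C, x$lung_l$throttle$d))
  cat(sprintf("  %d warm-up + %d recorded cycles (period %g s), %d samples",
              x$control$n_warmup, x$control$n_record, x$period,
              nrow(x$trajectory)))
  if (!is.na(x$steady))
    cat(sprintf(", %ssteady", if (x$steady) "" else "NOT "))
  cat("\n")
  invisible(x)
}

#' Summary of a BIPAP simulation
#'
#' @param object A `"bipap_sim"` object.
#' @param eps Mass-flow floor for the flow-ratio series.
#' @param ... Unused.
#' @return A `"summary.bipap_sim"` list: per-cycle tidal-volume table,
#'   flow-ratio range and masked fraction, peak flows, and the worst
#'   ideal-gas residual along the trajectory.
#' @export
summary.bipap_sim <- function(object, eps = 1e-7, ...) {
  tv <- tidal_volumes(object)
  fr <- flow_ratio_series(object, eps)
  traj <- object$trajectory
  res <- residuals(object)
  out <- list(settings = object$settings, steady = object$steady,
              tidal = tv,
              ratio_range = if (any(fr$valid)) range(fr$ratio[fr$valid])
                            else c(NA_real_, NA_real_),
              masked_fraction = mean(!fr$valid),
              peak_q_s = max(abs(traj$q_s)),
              max_gas_residual = max(abs(res)))
  class(out) <- "summary.bipap_sim"
  out
}

#' @export
print.summary.bipap_sim <- function(x, ...) {
  print(x$settings)
  cat("Per-cycle tidal volumes (mL) and right-lung share:\n")
  print(x$tidal, row.names = FALSE, digits = 6)
  cat(sprintf("Flow ratio q_r/q_s on valid samples: [%.4f, %.4f]  (%.1f%% masked near q_s = 0)\n",
              x$ratio_range[1], x$ratio_range[2], 100 * x$masked_fraction))
  cat(sprintf("Peak |q_s| %.3g kg/s; max |ideal-gas residual| %.2g\n",
              x$peak_q_s, x$max_gas_residual))
  invisible(x)
}

#' Ideal-gas residuals along a trajectory
#'
#' @param object A `"bipap_sim"` object.
#' @param ... Unused.
#' @return Matrix with columns `r` and `l`: the relative residual
#'   `(p V - m R theta)/(p V)` of each lung at every output sample. Values
#'   above the integrator tolerance indicate integration error.
#' @export
residuals.bipap_sim <- function(object, ...) {
  traj <- object$trajectory
  g <- object$gas
  rt <- g$R_specific * g$theta
  cbind(r = (traj$p_r_pa * traj$V_r - traj$m_r * rt) / (traj$p_r_pa * traj$V_r),
        l = (traj$p_l_pa * traj$V_l - traj$m_l * rt) / (traj$p_l_pa * traj$V_l))
}

#' @export
as.data.frame.bipap_sim <- function(x, ...) x$trajectory

#' Plot a BIPAP simulation
#'
#' Three stacked panels over the recorded cycles: pressures (setpoint and
#' both lungs, cmH2O gauge), mass flows (kg/s), and the flow-split ratio
#' `q_r/q_s` (masked samples omitted).
#'
#' @param x A `"bipap_sim"` object.
#' @param eps Mass-flow floor for the ratio panel.
#' @param ... Passed to `matplot`.
#' @return Invisibly, `x`.
#' @export
plot.bipap_sim <- function(x, eps = 1e-7, ...) {
  traj <- x$trajectory
  fr <- flow_ratio_series(x, eps)
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::matplot(traj$t, cbind(traj$p_vent, traj$p_r, traj$p_l),
                    type = "l", lty = c(2, 1, 1), col = c(1, 2, 4),
                    xlab = "t (s)", ylab = "p (cmH2O)", ...)
  graphics::legend("topright", c("setpoint", "right", "left"),
                   lty = c(2, 1, 1), col = c(1, 2, 4), bty = "n")
  graphics::matplot(traj$t, cbind(traj$q_r, traj$q_l, traj$q_s),
                    type = "l", lty = c(1, 1, 2), col = c(2, 4, 1),
                    xlab = "t (s)", ylab = "q (kg/s)")
  graphics::abline(h = 0, col = "grey")
  graphics::plot(fr$t, fr$ratio, type = "l", xlab = "t (s)",
                 ylab = "q_r / q_s", ylim = range(fr$ratio, 0, 1, na.rm = TRUE))
  graphics::abline(h = 0.5, col = "grey", lty = 3)
  invisible(x)
}

#' @export
print.bipap_sweep <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Sweep of %s (%d scenarios)\n", spec$parameter, nrow(x)))
  print(as.data.frame(x), row.names = FALSE, digits = 5)
  invisible(x)
}

#' Plot a sweep table
#'
#' Right-lung tidal-volume share against the swept parameter value.
#'
#' @param x A `"bipap_sweep"` object.
#' @param ... Passed to `plot`.
#' @return Invisibly, `x`.
#' @export
plot.bipap_sweep <- function(x, ...) {
  spec <- attr(x, "spec")
  graphics::plot(x$value, 100 * x$vt_share_r, type = "b", pch = 16,
                 xlab = sprintf("%s", spec$parameter),
                 ylab = "VT_r / VT_s (%)", ...)
  graphics::abline(h = 50, col = "grey", lty = 3)
  invisible(x)
}
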