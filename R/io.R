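# Trajectory/metrics writers and the scenario config reader used by the
# command-line wrapper.

#' Write a trajectory to CSV
#'
#' @param sim A `"bipap_sim"` object.
#' @param file Output path.
#' @param units `"clinical"` (pressures in cmH2O gauge, volumes in mL,
#'   flows in kg/s) or `"si"` (Pa absolute, m^3, kg/s).
#' @return Invisibly, the written data frame.
#' @export
write_trajectory <- function(sim, file, units = c("clinical", "si")) {
  stopifnot(inherits(sim, "bipap_sim"))
  units <- match.arg(units)
  traj <- sim$trajectory
  out <- if (units == "clinical") {
    data.frame(t = traj$t, p_vent = traj$p_vent,
               p_r = traj$p_r, p_l = traj$p_l,
               q_r = traj$q_r, q_l = traj$q_l, q_s = traj$q_s,
               V_r_mL = traj$V_r * 1e6, V_l_mL = traj$V_l * 1e6)
  } else {
    data.frame(t = traj$t, p_vent_pa = cmh2o_to_pa(traj$p_vent),
               p_r_pa = traj$p_r_pa, p_l_pa = traj$p_l_pa,
               q_r = traj$q_r, q_l = traj$q_l, q_s = traj$q_s,
               V_r = traj$V_r, V_l = traj$V_l,
               m_r = traj$m_r, m_l = traj$m_l)
  }
  utils::write.csv(out, file, row.names = FALSE)
  invisible(out)
}

#' Write per-cycle breath metrics to CSV
#'
#' @param sim A `"bipap_sim"` object.
#' @param file Output path.
#' @return Invisibly, the written data frame.
#' @export
write_metrics <- function(sim, file) {
  tv <- tidal_volumes(sim)
  utils::write.csv(tv, file, row.names = FALSE)
  invisible(tv)
}

#' Write the flow-ratio series to CSV
#'
#' @param sim A `"bipap_sim"` object.
#' @param file Output path.
#' @param eps Mass-flow floor for masking.
#' @return Invisibly, the written data frame (with the mask column).
#' @export
write_flow_ratio <- function(sim, file, eps = 1e-7) {
  fr <- flow_ratio_series(sim, eps)
  utils::write.csv(fr, file, row.names = FALSE)
  invisible(fr)
}

#' Read a scenario configuration file
#'
#' Reads a YAML scenario with optional blocks `ventilator`, `lung_r`,
#' `lung_l`, `gas`, `sim`; omitted blocks (or fields) take the reference
#' defaults. `lung_l` defaults to `lung_r`.
#'
#' @param path Path to a YAML file.
#' @return A list with `settings`, `lung_r`, `lung_l`, `gas`, `control`.
#' @export
read_scenario <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading scenario files requires the 'yaml' package", call. = FALSE)
  cfg <- yaml::yaml.load_file(path)
  build <- function(f, args) do.call(f, args[names(args) %in% names(formals(f))])
  settings <- build(ventilator_settings, c(cfg$ventilator, list()))
  lung_r <- build(lung_parameters, c(cfg$lung_r, list()))
  lung_l <- if (is.null(cfg$lung_l)) lung_r
            else build(lung_parameters, c(cfg$lung_l, list()))
  gas <- build(gas_properties, c(cfg$gas, list()))
  control <- build(sim_control, c(cfg$sim, list()))
  list(settings = settings, lung_r = lung_r, lung_l = lung_l,
       gas = gas, control = control)
}
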