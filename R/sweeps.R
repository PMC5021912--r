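# One-at-a-time parameter sweeps against the fixed reference lung:
# perturb one of {C_r, d_r, IPAP, EPAP, BPM, Ti, Tr}, leave everything
# else at the reference operating point.

#' The reference scenario
#'
#' Two identical lungs (C = 10 mL/cmH2O, d = 3.2 mm, V0 = 1.5 L) on a
#' BIPAP ventilator at IPAP 22 / EPAP 4 cmH2O, 20 breaths/min, Ti 1 s,
#' Tr 0.3 s, air at 293.15 K.
#'
#' @return A list with `settings`, `lung_r`, `lung_l`, `gas`.
#' @export
reference_scenario <- function() {
  lung <- lung_parameters(C = 10, d = 3.2)
  list(settings = ventilator_settings(IPAP = 22, EPAP = 4, BPM = 20,
                                      Ti = 1, Tr = 0.3),
       lung_r = lung, lung_l = lung, gas = gas_properties())
}

.sweep_parameters <- c("C_r", "d_r", "IPAP", "EPAP", "BPM", "Ti", "Tr")

# rebuild a full scenario with one parameter replaced; constructors do the
# validation, so an out-of-range value fails here, before any simulation
.apply_sweep_value <- function(base, parameter, value) {
  s <- base$settings
  r <- base$lung_r
  tryCatch(
    switch(parameter,
      C_r  = { base$lung_r <- lung_parameters(C = value, d = r$throttle$d,
                                              Cd = r$throttle$Cd, V0 = r$V0); base },
      d_r  = { base$lung_r <- lung_parameters(C = r$C, d = value,
                                              Cd = r$throttle$Cd, V0 = r$V0); base },
      IPAP = { base$settings <- ventilator_settings(value, s$EPAP, s$BPM, s$Ti, s$Tr); base },
      EPAP = { base$settings <- ventilator_settings(s$IPAP, value, s$BPM, s$Ti, s$Tr); base },
      BPM  = { base$settings <- ventilator_settings(s$IPAP, s$EPAP, value, s$Ti, s$Tr); base },
      Ti   = { base$settings <- ventilator_settings(s$IPAP, s$EPAP, s$BPM, value, s$Tr); base },
      Tr   = { base$settings <- ventilator_settings(s$IPAP, s$EPAP, s$BPM, s$Ti, value); base }),
    error = function(e)
      stop(sprintf("invalid sweep value %g for parameter '%s': %s",
                   value, parameter, conditionMessage(e)), call. = FALSE))
}

#' Specify a one-dimensional parameter sweep
#'
#' @param parameter One of `"C_r"` (right-lung compliance, mL/cmH2O),
#'   `"d_r"` (right throttle diameter, mm), `"IPAP"`, `"EPAP"` (cmH2O),
#'   `"BPM"`, `"Ti"`, `"Tr"` (s).
#' @param values Non-empty, strictly increasing numeric vector of values
#'   the parameter takes; every resulting scenario must be valid.
#' @param base Base scenario to perturb (default [reference_scenario()]).
#' @return An object of class `"sweep_spec"`.
#' @examples
#' sweep_spec("C_r", c(5, 10, 15, 20, 25, 30))
#' @export
sweep_spec <- function(parameter, values, base = reference_scenario()) {
  parameter <- match.arg(parameter, .sweep_parameters)
  if (!is.numeric(values) || length(values) == 0 || any(!is.finite(values)))
    stop("'values' must be a non-empty finite numeric vector", call. = FALSE)
  if (is.unsorted(values, strictly = TRUE))
    stop("'values' must be strictly increasing", call. = FALSE)
  structure(list(parameter = parameter, values = values, base = base),
            class = "sweep_spec")
}

#' @export
print.sweep_spec <- function(x, ...) {
  cat(sprintf("Sweep of %s over {%s}\n", x$parameter,
              paste(x$values, collapse = ", ")))
  invisible(x)
}

#' Run a parameter sweep
#'
#' Validates every perturbed scenario up front (an invalid value aborts
#' before any simulation runs, naming the offending value), then simulates
#' each scenario and assembles the [sweep_summary()] table. Scenarios are
#' independent; the table is ordered by swept value.
#'
#' @param spec A [sweep_spec()].
#' @param control A [sim_control()].
#' @param eps Mass-flow floor for the flow-ratio extrema.
#' @return Data frame of class `"bipap_sweep"` (see [sweep_summary()]),
#'   with the per-scenario `"bipap_sim"` objects in `attr(, "sims")` and
#'   the spec in `attr(, "spec")`.
#' @examples
#' \donttest{
#' sw <- run_sweep(sweep_spec("C_r", c(8, 10, 12)),
#'                 control = sim_control(n_warmup = 2, n_record = 1))
#' sw
#' }
#' @export
run_sweep <- function(spec, control = sim_control(), eps = 1e-7) {
  stopifnot(inherits(spec, "sweep_spec"))
  scenarios <- lapply(spec$values, function(v)
    .apply_sweep_value(spec$base, spec$parameter, v))
  sims <- lapply(scenarios, function(sc)
    simulate_bipap(sc$settings, sc$lung_r, sc$lung_l, sc$gas, control))
  tab <- sweep_summary(sims, spec$parameter, spec$values, eps)
  structure(tab, class = c("bipap_sweep", "data.frame"),
            sims = sims, spec = spec)
}

#' Manifest of the reference parameter studies
#'
#' The full one-at-a-time study design around the reference scenario, as
#' data (nothing is executed): for each of the seven swept parameters, the
#' grid used for the flow-ratio comparison (`flow_grid`, three values,
#' where the study defines one) and the grid used for the tidal-volume
#' share curve (`share_grid`).
#'
#' @return Named list of seven sweep families (`C_r`, `d_r`, `IPAP`,
#'   `EPAP`, `BPM`, `Ti`, `Tr`), each a list with `parameter`, `units`,
#'   `flow_grid` (or `NULL`), `share_grid`.
#' @examples
#' names(reference_sweep_suite())
#' reference_sweep_suite()$IPAP
#' @export
reference_sweep_suite <- function() {
  list(
    C_r  = list(parameter = "C_r",  units = "mL/cmH2O",
                flow_grid = c(8, 12, 14), share_grid = seq(5, 30, by = 5)),
    d_r  = list(parameter = "d_r",  units = "mm",
                flow_grid = c(2.0, 2.8, 4.0),
                share_grid = seq(1.6, 4.0, by = 0.4)),
    IPAP = list(parameter = "IPAP", units = "cmH2O",
                flow_grid = NULL, share_grid = c(18, 22, 24)),
    EPAP = list(parameter = "EPAP", units = "cmH2O",
                flow_grid = NULL, share_grid = c(4, 6, 8)),
    BPM  = list(parameter = "BPM",  units = "1/min",
                flow_grid = NULL, share_grid = c(20, 25, 30)),
    Ti   = list(parameter = "Ti",   units = "s",
                flow_grid = NULL, share_grid = c(1, 1.2, 1.4)),
    Tr   = list(parameter = "Tr",   units = "s",
                flow_grid = NULL, share_grid = c(0.2, 0.3, 0.4))
  )
}

#' Run the full reference study suite
#'
#' Runs the `share_grid` sweep of every family in
#' [reference_sweep_suite()] and (optionally) writes one CSV per family.
#'
#' @param outdir Output directory for the CSV tables, or `NULL` to skip
#'   writing.
#' @param control A [sim_control()].
#' @return Invisible named list of `"bipap_sweep"` tables.
#' @export
run_reference_suite <- function(outdir = NULL, control = sim_control()) {
  suite <- reference_sweep_suite()
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  res <- lapply(suite, function(fam) {
    sw <- run_sweep(sweep_spec(fam$parameter, fam$share_grid), control)
    if (!is.null(outdir))
      utils::write.csv(as.data.frame(sw),
                       file.path(outdir, paste0("sweep_", fam$parameter, ".csv")),
                       row.names = FALSE)
    sw
  })
  invisible(res)
}
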