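#' Voltammogram container
#'
#' Potential-current series with pulse settings and acquisition metadata.
#'
#' @param potentials_V Strictly monotone potentials (V).
#' @param currents_uA_cm2 Currents (uA cm-2), same length.
#' @param pulse A [pulse_params()].
#' @param temperature_K Temperature (K).
#' @param electrode_area_cm2 Working-electrode area (cm2), > 0.
#' @param reference_scale Reference scale of `potentials_V`.
#' @param metadata Free-form named list (provenance, generator ground truth,
#'   baseline bookkeeping, ...).
#' @return Object of class `voltammogram`.
#' @export
voltammogram <- function(potentials_V, currents_uA_cm2,
                         pulse = pulse_params(), temperature_K = .T_DEFAULT,
                         electrode_area_cm2 = 3.1, reference_scale = "SHE",
                         metadata = list()) {
  if (!is.numeric(potentials_V) || !is.numeric(currents_uA_cm2) ||
      length(potentials_V) != length(currents_uA_cm2) ||
      length(potentials_V) == 0L)
    stop_dpv("potentials and currents must be equal-length numeric vectors",
             "dpvkit_invalid_input")
  d <- diff(potentials_V)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop_dpv("`potentials_V` must be strictly monotone",
             "dpvkit_invalid_input")
  check_number(electrode_area_cm2, "electrode_area_cm2", 0,
               strict_lower = TRUE)
  check_number(temperature_K, "temperature_K", 0, strict_lower = TRUE)
  structure(list(potentials_V = as.numeric(potentials_V),
                 currents_uA_cm2 = as.numeric(currents_uA_cm2),
                 pulse = pulse, temperature_K = temperature_K,
                 electrode_area_cm2 = electrode_area_cm2,
                 reference_scale = normalize_ref_scale(reference_scale),
                 metadata = metadata),
            class = "voltammogram")
}

#' @export
print.voltammogram <- function(x, ...) {
  cat(sprintf(
    "voltammogram: %d points, %.0f .. %.0f mV vs %s, T = %.2f K%s\n",
    length(x$potentials_V), 1000 * min(x$potentials_V),
    1000 * max(x$potentials_V), x$reference_scale, x$temperature_K,
    if (!is.null(x$metadata$name)) paste0(" [", x$metadata$name, "]") else ""))
  invisible(x)
}

#' Event annotation for a chronoamperometry trace
#'
#' @param time_s Event time (s).
#' @param kind `"flavin_addition"`, `"potential_step"` or `"pH_change"`.
#' @param payload Named list: `flavin` + `conc_uM` for additions,
#'   `potential_V` for steps, `pH` for pH changes.
#' @return Object of class `trace_event`.
#' @export
trace_event <- function(time_s, kind = c("flavin_addition", "potential_step",
                                         "pH_change"), payload = list()) {
  kind <- match.arg(kind)
  check_number(time_s, "time_s", 0)
  structure(list(time_s = time_s, kind = kind, payload = payload),
            class = "trace_event")
}

#' @rdname trace_event
#' @param flavin `"RF"` or `"FMN"`.
#' @param conc_uM Added concentration (uM).
#' @export
flavin_addition <- function(time_s, flavin = c("FMN", "RF"), conc_uM = 2) {
  flavin <- match.arg(flavin)
  trace_event(time_s, "flavin_addition",
              list(flavin = flavin, conc_uM = conc_uM))
}

#' Chronoamperometry trace container
#'
#' Time-current series at fixed electrode potential with event annotations.
#'
#' @param times_s Strictly increasing times (s).
#' @param currents_uA_cm2 Currents (uA cm-2).
#' @param potential_V Poised potential (V vs SHE).
#' @param pH Electrolyte pH.
#' @param strain `"WT"`, `"dOmcA"` or `"dMtrC"`.
#' @param flavin `"none"`, `"RF"` or `"FMN"`.
#' @param flavin_conc_uM Flavin concentration (uM).
#' @param events List of [trace_event()] within the time span.
#' @param metadata Free-form named list.
#' @return Object of class `current_trace`.
#' @export
current_trace <- function(times_s, currents_uA_cm2, potential_V = 0.4,
                          pH = 7.8, strain = "WT", flavin = "none",
                          flavin_conc_uM = 0, events = list(),
                          metadata = list()) {
  if (!is.numeric(times_s) || !is.numeric(currents_uA_cm2) ||
      length(times_s) != length(currents_uA_cm2) || length(times_s) < 2L)
    stop_dpv("times and currents must be equal-length numeric vectors (n >= 2)",
             "dpvkit_invalid_input")
  if (any(diff(times_s) <= 0))
    stop_dpv("`times_s` must be strictly increasing", "dpvkit_invalid_input")
  for (ev in events) {
    if (!inherits(ev, "trace_event"))
      stop_dpv("`events` must be a list of trace_event objects",
               "dpvkit_invalid_input")
    if (ev$time_s < min(times_s) || ev$time_s > max(times_s))
      stop_dpv("event time outside the trace time range",
               "dpvkit_invalid_input")
  }
  structure(list(times_s = as.numeric(times_s),
                 currents_uA_cm2 = as.numeric(currents_uA_cm2),
                 potential_V = potential_V, pH = pH, strain = strain,
                 flavin = flavin, flavin_conc_uM = flavin_conc_uM,
                 events = events, metadata = metadata),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf(
    "current trace: %s/%s, %+.1f V vs SHE, pH %.1f, %.1f h, %d events\n",
    x$strain, x$flavin, x$potential_V, x$pH,
    max(x$times_s) / 3600, length(x$events)))
  invisible(x)
}
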