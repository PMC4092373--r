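## Enhancement-factor analysis of flavin additions to chronoamperometry
## traces, and assembly of the potential/pH dependency panels.

interp_current <- function(trace, t) {
  approx(trace$times_s, trace$currents_uA_cm2, xout = t, rule = 1)$y
}

#' Enhancement factor of a flavin addition
#'
#' Protocol: the microbial current is sampled immediately before (mean over
#' the 60 s preceding the event) and 1000 s after the addition; both are
#' corrected for the non-metabolic background current measured at the same
#' potential without lactate, and the enhancement factor is their ratio:
#' `EF = (i(t + 1000) - i_bg) / (mean pre - i_bg)`.
#'
#' @param trace A [current_trace()] extending at least 1000 s past the event.
#' @param event A `flavin_addition` [trace_event()]; defaults to the first
#'   flavin addition recorded in `trace`.
#' @param background Matched no-lactate [current_trace()] at the same
#'   potential, or a scalar background current (uA cm-2). If omitted, 0 is
#'   used with a warning.
#' @param pre_window_s Averaging window before the event (s).
#' @param post_delay_s Sampling delay after the event (s).
#' @return Object of class `enhancement_result`: `EF`, `potential_V`, `pH`,
#'   `flavin`, and the pre/post/background currents.
#' @export
enhancement_factor <- function(trace, event = NULL, background = NULL,
                               pre_window_s = 60, post_delay_s = 1000) {
  stopifnot(inherits(trace, "current_trace"))
  if (is.null(event)) {
    adds <- Filter(function(e) e$kind == "flavin_addition", trace$events)
    if (!length(adds))
      stop_dpv("no flavin_addition event in the trace",
               "dpvkit_invalid_input")
    event <- adds[[1]]
  }
  te <- event$time_s
  if (te < min(trace$times_s) || te > max(trace$times_s))
    stop_dpv("event time outside the trace", "dpvkit_invalid_input")
  if (max(trace$times_s) < te + post_delay_s)
    stop_dpv(sprintf("trace must extend at least %g s past the addition",
                     post_delay_s), "dpvkit_trace_too_short")
  pre_idx <- trace$times_s >= te - pre_window_s & trace$times_s < te
  i_pre <- if (any(pre_idx)) mean(trace$currents_uA_cm2[pre_idx])
  else interp_current(trace, te - pre_window_s / 2)
  i_post <- interp_current(trace, te + post_delay_s)
  if (is.null(background)) {
    warning("no background trace supplied; assuming zero background current",
            call. = FALSE)
    background <- 0
  }
  if (inherits(background, "current_trace")) {
    bt <- background$times_s
    pre_t <- trace$times_s[pre_idx]
    pre_t <- pre_t[pre_t >= min(bt) & pre_t <= max(bt)]
    bg_pre <- if (length(pre_t))
      mean(approx(bt, background$currents_uA_cm2, xout = pre_t,
                  rule = 2)$y)
    else mean(background$currents_uA_cm2)
    bg_post <- approx(bt, background$currents_uA_cm2,
                      xout = te + post_delay_s, rule = 2)$y
  } else {
    check_number(background, "background")
    bg_pre <- bg_post <- background
  }
  denom <- i_pre - bg_pre
  if (!is.finite(denom) || denom <= 0)
    stop_dpv("pre-addition current does not exceed the background; enhancement factor undefined",
             "dpvkit_undefined_ef")
  structure(list(EF = (i_post - bg_post) / denom,
                 potential_V = trace$potential_V, pH = trace$pH,
                 flavin = event$payload$flavin %||% trace$flavin,
                 pre_current = i_pre, post_current = i_post,
                 background_pre = bg_pre, background_post = bg_post),
            class = "enhancement_result")
}

#' Assemble an enhancement-factor panel
#'
#' Groups enhancement results by flavin and by the chosen axis (electrode
#' potential or pH) and reports mean, standard error of the mean and n per
#' cell, sorted by axis value.
#'
#' @param results List of [enhancement_factor()] results.
#' @param axis `"potential"` or `"pH"`.
#' @return Data frame with columns `axis`, `value`, `flavin`, `mean_EF`,
#'   `sem`, `n`.
#' @export
build_panel <- function(results, axis = c("potential", "pH")) {
  axis <- match.arg(axis)
  if (!length(results))
    stop_dpv("`results` must contain at least one enhancement result",
             "dpvkit_invalid_input")
  df <- do.call(rbind, lapply(results, function(r) {
    stopifnot(inherits(r, "enhancement_result"))
    data.frame(potential = r$potential_V, pH = r$pH, flavin = r$flavin,
               EF = r$EF)
  }))
  other <- if (axis == "potential") "pH" else "potential"
  for (fl in unique(df$flavin)) for (val in unique(df[[axis]])) {
    cell <- df[df$flavin == fl & df[[axis]] == val, ]
    if (length(unique(cell[[other]])) > 1L)
      warning(sprintf(
        "mixed %s values within the %s = %g / %s panel cell", other, axis,
        val, fl), call. = FALSE)
  }
  agg <- do.call(rbind, lapply(split(df, list(df[[axis]], df$flavin),
                                     drop = TRUE), function(cell) {
    data.frame(axis = axis, value = cell[[axis]][1],
               flavin = cell$flavin[1], mean_EF = mean(cell$EF),
               sem = if (nrow(cell) > 1) sd(cell$EF) / sqrt(nrow(cell))
               else 0,
               n = nrow(cell))
  }))
  rownames(agg) <- NULL
  agg[order(agg$flavin, agg$value), ]
}

#' @export
print.enhancement_result <- function(x, ...) {
  cat(sprintf(
    "EF = %.2f (%s at %+.1f V vs SHE, pH %.1f; pre %.3g, post %.3g, bg %.3g uA cm-2)\n",
    x$EF, x$flavin, x$potential_V, x$pH, x$pre_current, x$post_current,
    x$background_pre))
  invisible(x)
}
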