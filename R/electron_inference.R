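#' Infer the electron count from an observed DPV half-width
#'
#' Compares the observed half-width with the theoretical reversible widths
#' for each candidate electron number and returns the nearest. Because the
#' theoretical width decreases with `n`, any broadening beyond the
#' one-electron width (dispersion, heterogeneity) still maps to n = 1 under
#' this rule. At 50 mV amplitude and 303.15 K the rule reproduces the
#' standard calls: ~60 mV widths are two-electron (free flavin Ox/Rd),
#' 130-150 mV widths are one-electron (bound flavin Ox/Sq).
#'
#' @param W_obs_mV Observed half-width (mV), > 0.
#' @param amplitude_mV Pulse amplitude (mV).
#' @param T_K Temperature (K).
#' @param candidates Candidate integer electron counts.
#' @param ambiguity_mV Flag the call as ambiguous when the two nearest
#'   theoretical widths are within this distance of being equally good.
#' @return Object of class `electron_call`: `n_best`, `margin_mV` (distance
#'   between the two nearest candidate discrepancies), `ambiguous`,
#'   `widths_table` and the observed width.
#' @export
classify_n <- function(W_obs_mV, amplitude_mV = 50, T_K = .T_DEFAULT,
                       candidates = c(1L, 2L), ambiguity_mV = 5) {
  check_number(W_obs_mV, "W_obs_mV", 0, strict_lower = TRUE)
  if (length(candidates) == 0L)
    stop_dpv("`candidates` must be a non-empty integer set",
             "dpvkit_invalid_parameter")
  candidates <- sort(unique(as.integer(candidates)))
  widths <- vapply(candidates,
                   function(n) theoretical_half_width(n, amplitude_mV, T_K),
                   numeric(1))
  names(widths) <- paste0("n", candidates)
  d <- abs(W_obs_mV - widths)
  best <- which.min(d)
  margin <- if (length(d) > 1L) diff(sort(d))[1] else Inf
  structure(list(n_best = candidates[best], margin_mV = margin,
                 ambiguous = is.finite(margin) && margin < ambiguity_mV,
                 widths_table = widths, W_obs_mV = W_obs_mV,
                 amplitude_mV = amplitude_mV, T_K = T_K),
            class = "electron_call")
}

#' @export
print.electron_call <- function(x, ...) {
  cat(sprintf(
    "n = %d (observed width %.1f mV; theoretical %s; margin %.1f mV%s)\n",
    x$n_best, x$W_obs_mV,
    paste(sprintf("%s: %.1f", names(x$widths_table), x$widths_table),
          collapse = ", "),
    x$margin_mV, if (x$ambiguous) ", AMBIGUOUS" else ""))
  invisible(x)
}
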