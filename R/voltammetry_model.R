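#' DPV pulse waveform parameters
#'
#' Describes the staircase differential-pulse waveform. Defaults are the
#' instrument settings used throughout the study conditions emulated by this
#' package: 5.0 mV increments, 50 mV pulse amplitude, 300 ms pulse width and a
#' 5.0 s pulse period, with the current sampled over the final 10 ms of each
#' pulse.
#'
#' @param increment_mV Potential step per staircase cycle (mV), > 0.
#' @param amplitude_mV Pulse amplitude (mV), > 0.
#' @param width_ms Pulse duration (ms), 0 < width < period.
#' @param period_ms Cycle duration (ms).
#' @param sampling_delay_ms Time after the pulse edge at which the current is
#'   sampled (ms), <= width.
#' @param scan_direction `"anodic"` (potential increasing; the default, as
#'   cells oxidize lactate with the electrode as acceptor) or `"cathodic"`.
#' @return An object of class `pulse_params`.
#' @export
pulse_params <- function(increment_mV = 5, amplitude_mV = 50,
                         width_ms = 300, period_ms = 5000,
                         sampling_delay_ms = 290,
                         scan_direction = c("anodic", "cathodic")) {
  scan_direction <- match.arg(scan_direction)
  check_number(increment_mV, "increment_mV", 0, strict_lower = TRUE)
  check_number(amplitude_mV, "amplitude_mV", 0, strict_lower = TRUE)
  check_number(width_ms, "width_ms", 0, strict_lower = TRUE)
  check_number(period_ms, "period_ms", 0, strict_lower = TRUE)
  check_number(sampling_delay_ms, "sampling_delay_ms", 0)
  if (width_ms >= period_ms)
    stop_dpv("pulse width must be smaller than the pulse period",
             "dpvkit_invalid_parameter")
  if (sampling_delay_ms > width_ms)
    stop_dpv("sampling delay cannot exceed the pulse width",
             "dpvkit_invalid_parameter")
  structure(list(increment_mV = increment_mV, amplitude_mV = amplitude_mV,
                 width_ms = width_ms, period_ms = period_ms,
                 sampling_delay_ms = sampling_delay_ms,
                 scan_direction = scan_direction),
            class = "pulse_params")
}

#' A reversible redox couple
#'
#' @param E0_V Formal potential (V vs SHE).
#' @param n Electrons transferred. Apparent (non-integer) values are allowed;
#'   physically meaningful couples here have n = 1 (flavin Ox/Sq bound to
#'   outer-membrane cytochromes) or n = 2 (free flavin Ox/Rd).
#' @param magnitude Peak response scale (uA cm-2); the DPV peak height.
#' @param label Free-text label, e.g. `"bound FMN Ox/Sq"`.
#' @return An object of class `redox_couple`.
#' @export
redox_couple <- function(E0_V, n = 1, magnitude = 1, label = "") {
  check_number(E0_V, "E0_V")
  check_number(n, "n", 0, strict_lower = TRUE)
  check_number(magnitude, "magnitude", 0)
  structure(list(E0_V = E0_V, n = n, magnitude = magnitude,
                 label = as.character(label)), class = "redox_couple")
}

#' A DPV peak described by position, half-width and height
#'
#' @param Ep_V Peak potential (V vs SHE).
#' @param W_mV Half-width (full width at half maximum, mV), > 0.
#' @param height Peak current (uA cm-2), >= 0.
#' @param shape Component line shape: `"sigmoid_diff"` (Nernstian
#'   sigmoid-difference, used for flavin couples) or `"gauss"` (broad heme
#'   envelope).
#' @return An object of class `peak_shape`.
#' @export
peak_shape <- function(Ep_V, W_mV, height,
                       shape = c("sigmoid_diff", "gauss")) {
  shape <- match.arg(shape)
  check_number(Ep_V, "Ep_V")
  check_number(W_mV, "W_mV", 0, strict_lower = TRUE)
  check_number(height, "height", 0)
  structure(list(Ep_V = Ep_V, W_mV = W_mV, height = height, shape = shape),
            class = "peak_shape")
}

## Nernstian scale factor RT/(nF) in volts.
nernst_scale_V <- function(n, T_K) .RGAS * T_K / (n * .FARADAY)

#' Nernstian reduced fraction
#'
#' Equilibrium fraction of the couple in its reduced state at potential `E`:
#' `1 / (1 + exp(nF(E - E0)/RT))`. Strictly decreasing in `E`.
#'
#' @param E_V Electrode potential(s), V (same reference scale as `couple`).
#' @param couple A [redox_couple()].
#' @param T_K Temperature (K), > 0.
#' @return Fraction(s) in `[0, 1]`.
#' @export
nernst_reduced_fraction <- function(E_V, couple, T_K = .T_DEFAULT) {
  if (!inherits(couple, "redox_couple"))
    stop_dpv("`couple` must be a redox_couple", "dpvkit_invalid_parameter")
  check_number(T_K, "T_K", 0, strict_lower = TRUE)
  if (!is.numeric(E_V) || length(E_V) == 0L)
    stop_dpv("`E_V` must be a non-empty numeric vector",
             "dpvkit_invalid_input")
  k <- nernst_scale_V(couple$n, T_K)
  1 / (1 + exp((E_V - couple$E0_V) / k))
}

## Normalized sigmoid-difference line shape with unit peak height.
## Ep is the PEAK position; the underlying formal potential sits at
## Ep + s*dE/2.  kscale = RT/(nF) in volts, dE = pulse amplitude in volts,
## s = +1 anodic / -1 cathodic.
sigmoid_diff_shape <- function(E, Ep, kscale, dE_V, s = 1) {
  E0 <- Ep + s * dE_V / 2
  f <- function(x) 1 / (1 + exp((x - E0) / kscale))
  abs(f(E) - f(E + s * dE_V)) / tanh(abs(dE_V) / (4 * kscale))
}

gauss_shape <- function(E, Ep, sigma) exp(-((E - Ep)^2) / (2 * sigma^2))

#' Closed-form DPV response of a reversible couple
#'
#' Difference of Nernstian reduced fractions at `E` and `E + s*dE`
#' (s = +1 anodic), scaled so the peak height equals `couple$magnitude`. The
#' response is non-negative, single-peaked and symmetric, with its maximum at
#' `E0 - s*dE/2`. This shape is exact for a reversible surface-confined couple
#' with full relaxation between pulses and reproduces the peak position,
#' half-width and height phenomenology analyzed here for solution couples as
#' well.
#'
#' @param E_grid Potentials (V), monotone in the scan direction.
#' @inheritParams nernst_reduced_fraction
#' @param pulse A [pulse_params()].
#' @return Currents (uA cm-2) on `E_grid`.
#' @export
dpv_response <- function(E_grid, couple, pulse = pulse_params(),
                         T_K = .T_DEFAULT) {
  if (!is.numeric(E_grid) || length(E_grid) == 0L)
    stop_dpv("`E_grid` must be a non-empty numeric vector",
             "dpvkit_invalid_input")
  if (!inherits(pulse, "pulse_params"))
    stop_dpv("`pulse` must be a pulse_params object",
             "dpvkit_invalid_parameter")
  check_number(T_K, "T_K", 0, strict_lower = TRUE)
  s <- if (pulse$scan_direction == "anodic") 1 else -1
  if (length(E_grid) > 1L) {
    d <- diff(E_grid)
    if (any(s * d <= 0))
      stop_dpv("`E_grid` must be strictly monotone in the scan direction",
               "dpvkit_invalid_input")
  }
  k <- nernst_scale_V(couple$n, T_K)
  Ep <- couple$E0_V - s * pulse$amplitude_mV / 1000 / 2
  couple$magnitude *
    sigmoid_diff_shape(E_grid, Ep, k, pulse$amplitude_mV / 1000, s)
}

## FWHM (mV) of the sigmoid-difference shape with scale kscale_mV and pulse
## amplitude dE_mV; independent of peak position and height.
fwhm_sigmoid_diff <- function(kscale_mV, dE_mV) {
  # far below the thermal scale the pulse no longer broadens the peak and
  # the closed-form logistic-derivative limit is numerically safer
  if (dE_mV <= 1e-6 * kscale_mV)
    return(2 * kscale_mV * log(3 + 2 * sqrt(2)))
  r <- function(E) 1 / (1 + exp(E / kscale_mV)) -
    1 / (1 + exp((E + dE_mV) / kscale_mV))
  Ep <- -dE_mV / 2
  half <- r(Ep) / 2
  span <- 40 * kscale_mV + dE_mV
  left <- uniroot(function(E) r(E) - half, c(Ep - span, Ep),
                  tol = 1e-12)$root
  right <- uniroot(function(E) r(E) - half, c(Ep, Ep + span),
                   tol = 1e-12)$root
  right - left
}

## Invert FWHM -> kscale (mV) at fixed pulse amplitude.  The width of the
## sigmoid-difference shape is bounded below by the pulse amplitude.
kscale_from_width <- function(W_mV, dE_mV) {
  check_number(W_mV, "W_mV", 0, strict_lower = TRUE)
  if (W_mV <= dE_mV)
    stop_dpv(sprintf(
      "half-width %.3g mV is not attainable: the sigmoid-difference width is bounded below by the pulse amplitude (%.3g mV)",
      W_mV, dE_mV), "dpvkit_invalid_parameter")
  uniroot(function(k) fwhm_sigmoid_diff(k, dE_mV) - W_mV,
          lower = 1e-4 * W_mV, upper = W_mV, tol = 1e-10)$root
}

#' Theoretical DPV half-width of a reversible n-electron couple
#'
#' Full width at half maximum of [dpv_response()]. Decreasing in `n`,
#' increasing in the pulse amplitude; in the small-amplitude limit it
#' converges to `2 (RT/nF) ln(3 + 2 sqrt(2))`, about `90.6/n` mV at 298.15 K.
#'
#' @param n Electrons transferred, > 0 (may be non-integer).
#' @param amplitude_mV Pulse amplitude (mV), >= 0.
#' @param T_K Temperature (K).
#' @return Half-width (mV).
#' @export
theoretical_half_width <- function(n, amplitude_mV = 50, T_K = .T_DEFAULT) {
  check_number(n, "n", 0, strict_lower = TRUE)
  check_number(amplitude_mV, "amplitude_mV", 0)
  check_number(T_K, "T_K", 0, strict_lower = TRUE)
  fwhm_sigmoid_diff(nernst_scale_V(n, T_K) * 1000, amplitude_mV)
}

#' Apparent electron number from an observed half-width
#'
#' Inverts [theoretical_half_width()] in `n`. Broadened peaks give apparent
#' n below the integer electron count; widths at or below the pulse amplitude
#' are not representable by the reversible model and return `NA`.
#'
#' @param W_mV Observed half-width (mV).
#' @inheritParams theoretical_half_width
#' @return Apparent (real-valued) electron number, or `NA_real_`.
#' @export
apparent_n_from_width <- function(W_mV, amplitude_mV = 50, T_K = .T_DEFAULT) {
  check_number(W_mV, "W_mV", 0, strict_lower = TRUE)
  if (W_mV <= amplitude_mV) return(NA_real_)
  k <- kscale_from_width(W_mV, amplitude_mV)
  .RGAS * T_K / .FARADAY * 1000 / k
}

## -------------------------------------------------------------------------
## Reference-electrode scales

.REF_ALIASES <- c(
  "she" = "SHE",
  "agagcl_satkcl" = "AgAgCl_satKCl",
  "ag/agcl_satkcl" = "AgAgCl_satKCl",
  "ag/agcl" = "AgAgCl_satKCl",
  "agagcl" = "AgAgCl_satKCl")

normalize_ref_scale <- function(scale) {
  key <- tolower(trimws(scale))
  if (!key %in% names(.REF_ALIASES))
    stop_dpv(sprintf("unknown reference scale '%s'", scale),
             "dpvkit_unknown_scale")
  unname(.REF_ALIASES[key])
}

#' Convert potentials between reference-electrode scales
#'
#' `SHE = Ag/AgCl(sat. KCl) + offset`. The default offset is +0.199 V; the
#' round numbers quoted for this cell (+0.2 V vs Ag/AgCl = +0.4 V vs SHE)
#' imply 0.200 V, so the offset is configurable.
#'
#' @param E_V Potential(s), V.
#' @param from,to `"SHE"` or `"AgAgCl_satKCl"` (aliases `"Ag/AgCl"`,
#'   `"Ag/AgCl_satKCl"` accepted).
#' @param offset_V Ag/AgCl(sat KCl) -> SHE offset, V.
#' @return Converted potential(s), V.
#' @export
convert_reference <- function(E_V, from, to, offset_V = 0.199) {
  from <- normalize_ref_scale(from)
  to <- normalize_ref_scale(to)
  check_number(offset_V, "offset_V")
  if (!is.numeric(E_V)) stop_dpv("`E_V` must be numeric",
                                 "dpvkit_invalid_input")
  she <- if (from == "SHE") E_V else E_V + offset_V
  if (to == "SHE") she else she - offset_V
}

#' @export
print.pulse_params <- function(x, ...) {
  cat(sprintf(
    "DPV pulse: %g mV increment, %g mV amplitude, %g/%g ms width/period (%s)\n",
    x$increment_mV, x$amplitude_mV, x$width_ms, x$period_ms,
    x$scan_direction))
  invisible(x)
}

#' @export
print.redox_couple <- function(x, ...) {
  cat(sprintf("redox couple%s: E0 = %+.0f mV vs SHE, n = %.3g, magnitude = %.3g uA cm-2\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              1000 * x$E0_V, x$n, x$magnitude))
  invisible(x)
}
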