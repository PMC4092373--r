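## Langmuir binding analysis: site occupancy, Kd estimation from
## peak-current titrations, and the order-of-magnitude estimate of the
## outer-membrane cytochrome site concentration over the electrode.

#' Langmuir fractional occupancy
#'
#' `theta = C / (C + Kd)`; `Kd` is the ligand concentration at which the
#' binding sites are half occupied.
#'
#' @param C_uM Ligand concentration(s) (uM), >= 0.
#' @param Kd_uM Dissociation constant (uM), > 0.
#' @return Occupancy fraction(s) in `[0, 1)`.
#' @export
langmuir_occupancy <- function(C_uM, Kd_uM) {
  check_number(Kd_uM, "Kd_uM", 0, strict_lower = TRUE)
  if (!is.numeric(C_uM) || any(is.na(C_uM)) || any(C_uM < 0))
    stop_dpv("`C_uM` must be non-negative", "dpvkit_invalid_parameter")
  C_uM / (C_uM + Kd_uM)
}

as_titration_series <- function(series) {
  if (inherits(series, "dpv_titration")) series <- series$series
  if (!is.data.frame(series) || ncol(series) < 2L)
    stop_dpv("`series` must be a data frame of concentration vs peak current",
             "dpvkit_invalid_input")
  names(series)[1:2] <- c("concentration_uM", "peak_current_uA_cm2")
  series[order(series$concentration_uM), 1:2]
}

#' Nonlinear Langmuir fit of a peak-current titration
#'
#' Least-squares fit of `i(C) = i_max C / (C + Kd)` by Levenberg-Marquardt,
#' initialized with `i_max = max(i)` and `Kd` at the linearly interpolated
#' concentration of half-maximal current. Standard errors come from the
#' Jacobian at the optimum.
#'
#' @param series Data frame `(concentration_uM, peak_current_uA_cm2)` or a
#'   [make_titration()] result.
#' @return Object of class `binding_fit` with `Kd_uM`, `i_max`, standard
#'   errors, `n_points` and `method = "nls"`.
#' @export
fit_langmuir <- function(series) {
  s <- as_titration_series(series)
  if (length(unique(s$concentration_uM)) < 3L)
    stop_dpv("Langmuir fitting needs at least 3 distinct concentrations",
             "dpvkit_insufficient_data")
  C <- s$concentration_uM
  i <- s$peak_current_uA_cm2
  imax0 <- max(i)
  half <- imax0 / 2
  Kd0 <- if (any(i <= half) && any(i >= half))
    approx(i, C, xout = half, ties = "ordered")$y
  else median(C)
  if (!is.finite(Kd0) || Kd0 <= 0) Kd0 <- median(C)
  fit <- tryCatch(
    minpack.lm::nlsLM(i ~ imax * C / (C + Kd),
                      start = list(imax = imax0, Kd = Kd0),
                      lower = c(imax = 1e-9, Kd = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop_dpv(
      paste0("Langmuir fit did not converge: ", conditionMessage(e)),
      "dpvkit_nonconvergence"))
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    c(imax = NA_real_, Kd = NA_real_))
  structure(list(Kd_uM = unname(est["Kd"]), i_max = unname(est["imax"]),
                 se_Kd = unname(se["Kd"]), se_imax = unname(se["imax"]),
                 n_points = nrow(s), method = "nls", fit = fit),
            class = "binding_fit")
}

#' Half-saturation estimate of the dissociation constant
#'
#' The back-of-the-envelope estimator used when only a saturating endpoint
#' is trusted: the current at the largest concentration is taken as `i_max`
#' (assuming that point saturates the sites), and `Kd` is the linearly
#' interpolated concentration at which the current crosses `i_max / 2`.
#' When the top concentration does not truly saturate, the estimate is
#' biased low relative to the nonlinear fit.
#'
#' @inheritParams fit_langmuir
#' @return `Kd` (uM) with attribute `method = "half_saturation"`.
#' @export
kd_from_half_saturation <- function(series) {
  s <- as_titration_series(series)
  C <- s$concentration_uM
  i <- s$peak_current_uA_cm2
  imax <- i[length(i)]
  target <- imax / 2
  tol <- 1e-9 * max(abs(i), 1)
  if (i[1] > target + tol)
    stop_dpv("series does not span half of its maximum (lowest point already above half-max)",
             "dpvkit_invalid_input")
  cross <- which(i >= target - tol)
  if (!length(cross))
    stop_dpv("series never crosses half of its maximum",
             "dpvkit_invalid_input")
  j <- cross[1]
  Kd <- if (j == 1L || abs(i[j] - target) <= tol) C[j]
  else C[j - 1] + (C[j] - C[j - 1]) * (target - i[j - 1]) / (i[j] - i[j - 1])
  structure(Kd, method = "half_saturation")
}

#' Order-of-magnitude concentration of outer-membrane cytochrome sites
#'
#' Treats the electrode as carrying a monolayer biofilm with a given
#' fractional surface coverage of outer-membrane cytochromes and converts
#' the resulting site count into a molar concentration in the reactor
#' volume:
#' `concentration = cells_per_area * area * sites_per_cell / (N_A * volume)`.
#' The cell and protein footprints are invented, flagged defaults; coverage
#' 10-30% is the literature range and the reactor defaults (3.14 cm2, 5 mL)
#' are the study's cell.
#'
#' @param coverage_fraction Fraction of the cell surface covered by the
#'   cytochromes, in (0, 1).
#' @param electrode_area_cm2 Electrode area (cm2).
#' @param volume_L Electrolyte volume (L).
#' @param cell_footprint_um2 Area of one adhered cell (um2; invented).
#' @param protein_footprint_nm2 Area of one cytochrome (nm2; invented).
#' @param cells_per_area Cells per cm2; default a close-packed monolayer,
#'   `1 / cell_footprint`.
#' @param sites_per_cell Binding sites per cell; default
#'   `coverage_fraction * cell_footprint / protein_footprint`.
#' @return Object of class `site_concentration`: `concentration_M`,
#'   `concentration_nM` and the inputs (with `invented_defaults` noted).
#' @export
estimate_site_concentration <- function(coverage_fraction = 0.2,
                                        electrode_area_cm2 = 3.14,
                                        volume_L = 0.005,
                                        cell_footprint_um2 = 2,
                                        protein_footprint_nm2 = 50,
                                        cells_per_area = NULL,
                                        sites_per_cell = NULL) {
  check_number(coverage_fraction, "coverage_fraction", 0, 1,
               strict_lower = TRUE)
  if (coverage_fraction >= 1)
    stop_dpv("`coverage_fraction` must be in (0, 1)",
             "dpvkit_invalid_parameter")
  check_number(electrode_area_cm2, "electrode_area_cm2", 0,
               strict_lower = TRUE)
  check_number(volume_L, "volume_L", 0, strict_lower = TRUE)
  check_number(cell_footprint_um2, "cell_footprint_um2", 0,
               strict_lower = TRUE)
  check_number(protein_footprint_nm2, "protein_footprint_nm2", 0,
               strict_lower = TRUE)
  cells_per_area <- cells_per_area %||% (1 / (cell_footprint_um2 * 1e-8))
  sites_per_cell <- sites_per_cell %||%
    (coverage_fraction * cell_footprint_um2 * 1e6 / protein_footprint_nm2)
  conc <- cells_per_area * electrode_area_cm2 * sites_per_cell /
    (.AVOGADRO * volume_L)
  structure(list(concentration_M = conc, concentration_nM = conc * 1e9,
                 cells_per_area = cells_per_area,
                 sites_per_cell = sites_per_cell,
                 coverage_fraction = coverage_fraction,
                 electrode_area_cm2 = electrode_area_cm2,
                 volume_L = volume_L,
                 invented_defaults = c("cell_footprint_um2",
                                       "protein_footprint_nm2")),
            class = "site_concentration")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Langmuir fit (n = %d): Kd = %.3g +- %.2g uM, i_max = %.3g +- %.2g uA cm-2\n",
              x$n_points, x$Kd_uM, x$se_Kd, x$i_max, x$se_imax))
  invisible(x)
}

#' @export
print.site_concentration <- function(x, ...) {
  cat(sprintf(
    "OM c-Cyt site concentration: %.2g nM (%.0f%% coverage, %.3g sites/cell over %.3g cm2 in %.3g mL)\n",
    x$concentration_nM, 100 * x$coverage_fraction, x$sites_per_cell,
    x$electrode_area_cm2, 1000 * x$volume_L))
  invisible(x)
}
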