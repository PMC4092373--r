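test_that("EF is 1 for a constant trace and guards the degenerate cases", {
  times <- seq(0, 5000, by = 10)
  tr <- current_trace(times, rep(4, length(times)),
                      events = list(flavin_addition(2000, "FMN")))
  r <- enhancement_factor(tr, background = 0)
  expect_equal(r$EF, 1)
  # trace too short after the event
  short <- current_trace(times, rep(4, length(times)),
                         events = list(flavin_addition(4500, "FMN")))
  expect_error(enhancement_factor(short, background = 0),
               class = "dpvkit_trace_too_short")
  # pre-addition current at/below background is undefined
  expect_error(enhancement_factor(tr, background = 4),
               class = "dpvkit_undefined_ef")
  # missing background warns and assumes zero
  expect_warning(enhancement_factor(tr), "background")
})

test_that("default -0.2 V traces reproduce the reported enhancement factors", {
  fmn <- make_clean_trace_pair("FMN", -0.2)
  r_fmn <- enhancement_factor(fmn$trace, fmn$event, fmn$background)
  expect_equal(r_fmn$EF, 15, tolerance = 0.1)
  rf <- make_clean_trace_pair("RF", -0.2)
  r_rf <- enhancement_factor(rf$trace, rf$event, rf$background)
  expect_equal(r_rf$EF, 3, tolerance = 0.1)
})

test_that("EF is invariant to common offsets and unit rescaling", {
  p <- make_clean_trace_pair("FMN", -0.2)
  r0 <- enhancement_factor(p$trace, p$event, p$background)
  # add a constant offset to both trace and background
  tr2 <- p$trace; tr2$currents_uA_cm2 <- tr2$currents_uA_cm2 + 3.7
  bg2 <- p$background; bg2$currents_uA_cm2 <- bg2$currents_uA_cm2 + 3.7
  r_off <- enhancement_factor(tr2, p$event, bg2)
  expect_equal(r_off$EF, r0$EF, tolerance = 1e-9)
  # rescale the current unit
  tr3 <- p$trace; tr3$currents_uA_cm2 <- tr3$currents_uA_cm2 * 1000
  bg3 <- p$background; bg3$currents_uA_cm2 <- bg3$currents_uA_cm2 * 1000
  r_sc <- enhancement_factor(tr3, p$event, bg3)
  expect_equal(r_sc$EF, r0$EF, tolerance = 1e-9)
})

test_that("a ten-fold current step yields EF 10 within 2% at default noise", {
  times <- seq(0, 10000, by = 10)
  set.seed(42)
  base <- ifelse(times < 5000, 2, 20)
  tr <- current_trace(times, base + rnorm(length(times), 0, 0.02),
                      events = list(flavin_addition(5000, "FMN")))
  r <- enhancement_factor(tr, background = 0)
  expect_equal(r$EF, 10, tolerance = 0.02)
})

test_that("panels aggregate with SEM and reproduce the qualitative trends", {
  p <- make_clean_trace_pair("FMN", -0.2)
  r <- enhancement_factor(p$trace, p$event, p$background)
  pan <- build_panel(list(r, r, r), axis = "potential")
  expect_equal(pan$sem, 0)
  expect_equal(pan$n, 3L)
  # potential panel: EF grows toward negative potentials for both flavins
  mk <- function(fl, pot, pH = 7.8) {
    q <- make_clean_trace_pair(fl, pot, pH)
    enhancement_factor(q$trace, q$event, q$background)
  }
  pots <- c(-0.2, 0.4, 0.8)
  res <- c(lapply(pots, function(p) mk("FMN", p)),
           lapply(pots, function(p) mk("RF", p)))
  pan_pot <- build_panel(res, axis = "potential")
  for (fl in c("FMN", "RF")) {
    ef <- pan_pot$mean_EF[pan_pot$flavin == fl]
    expect_true(all(diff(ef) < 0))  # sorted by increasing potential
  }
  # pH panel: RF minimum at pH 7, maximum at pH 6; FMN non-decreasing
  phs <- c(6, 7, 7.8, 9)
  res_ph <- c(lapply(phs, function(p) mk("FMN", 0.4, p)),
              lapply(phs, function(p) mk("RF", 0.4, p)))
  pan_ph <- build_panel(res_ph, axis = "pH")
  rf <- pan_ph[pan_ph$flavin == "RF", ]
  expect_equal(rf$value[which.min(rf$mean_EF)], 7)
  expect_equal(rf$value[which.max(rf$mean_EF)], 6)
  expect_gt(rf$mean_EF[rf$value == 6], rf$mean_EF[rf$value == 7])
  fmn <- pan_ph[pan_ph$flavin == "FMN", ]
  expect_true(all(diff(fmn$mean_EF) >= 0))
  # inconsistent other-axis settings warn
  mixed <- list(mk("FMN", 0.4, 6), mk("FMN", 0.4, 9))
  expect_warning(build_panel(mixed, axis = "potential"), "mixed")
})

test_that("the 1000 s sampling rule sees most of the first-order rise", {
  p <- make_clean_trace_pair("FMN", -0.2)
  r <- enhancement_factor(p$trace, p$event, p$background)
  # the generator approaches EF x pre-current with tau = 200 s, so at
  # 1000 s the measured EF sits just below the injected target
  target <- p$trace$metadata$EF_target
  expect_lt(r$EF, target)
  expect_gt(r$EF, target * 0.99)
})
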