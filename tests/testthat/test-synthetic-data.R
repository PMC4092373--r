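test_that("fixtures are deterministic in the seed and reject unknown names", {
  v1 <- make_dpv_fixture("bound_FMN_WT", noise_sd = 0.02, seed = 7)
  v2 <- make_dpv_fixture("bound_FMN_WT", noise_sd = 0.02, seed = 7)
  v3 <- make_dpv_fixture("bound_FMN_WT", noise_sd = 0.02, seed = 8)
  expect_identical(v1$currents_uA_cm2, v2$currents_uA_cm2)
  expect_false(identical(v1$currents_uA_cm2, v3$currents_uA_cm2))
  v0a <- make_dpv_fixture("free_RF", noise_sd = 0, seed = 1)
  v0b <- make_dpv_fixture("free_RF", noise_sd = 0, seed = 99)
  expect_identical(v0a$currents_uA_cm2, v0b$currents_uA_cm2)
  expect_error(make_dpv_fixture("no_such_fixture"),
               class = "dpvkit_unknown_fixture")
  # seeding does not disturb the global RNG stream
  set.seed(123); a <- rnorm(1)
  set.seed(123); invisible(make_dpv_fixture("free_FMN", seed = 4))
  expect_identical(rnorm(1), a)
})

test_that("noise-free fixtures place the flavin peak at the registry E_p", {
  for (nm in c("free_FMN", "bound_FMN_WT", "bound_RF_WT",
               "bound_RF_dmtrC")) {
    v <- make_dpv_fixture(nm, noise_sd = 0)
    truth <- v$metadata$truth
    fl <- truth$components[truth$components$role != "heme", ][1, ]
    resid <- v$currents_uA_cm2 - truth$baseline
    # subtract the other generated components to isolate the flavin peak
    others <- truth$components[truth$components$Ep_V != fl$Ep_V, ,
                               drop = FALSE]
    if (nrow(others))
      resid <- resid - dpvkit:::component_curve(others, v$potentials_V,
                                                v$pulse$amplitude_mV)
    expect_lt(abs(v$potentials_V[which.max(resid)] - fl$Ep_V), 5.1e-3)
  }
})

test_that("generated free-flavin width agrees with two-electron theory", {
  v <- make_dpv_fixture("free_FMN", noise_sd = 0)
  truth <- v$metadata$truth
  W_gen <- truth$components$W_mV[1]
  expect_lt(abs(W_gen - theoretical_half_width(2, 50, 303.15)), 3)
})

test_that("titration magnitudes follow the Langmuir isotherm", {
  tt <- make_titration(noise_frac = 0)
  s <- tt$series
  expect_true(all(diff(s$peak_current_uA_cm2) > 0))
  # half-saturation point: C = Kd gives i_max/2
  i_at <- function(C) tt$i_max * C / (C + tt$Kd_uM)
  expect_equal(i_at(tt$Kd_uM), tt$i_max / 2)
  # C = 52, Kd = 10: magnitude = 52/62 i_max (= 7 uA cm-2 by calibration)
  expect_equal(s$peak_current_uA_cm2[s$concentration_uM == 52],
               52 / 62 * tt$i_max)
  expect_equal(s$peak_current_uA_cm2[s$concentration_uM == 52], 7)
  # free-flavin peak grows linearly with concentration
  h_free <- unname(vapply(tt$voltammograms, function(v) {
    cmp <- v$metadata$truth$components
    cmp$height[cmp$role == "flavin_free"]
  }, numeric(1)))
  expect_equal(h_free / s$concentration_uM,
               rep(h_free[1] / s$concentration_uM[1], nrow(s)))
  expect_error(make_titration(concentrations_uM = numeric()),
               class = "dpvkit_invalid_input")
})

test_that("current traces hit the tabulated plateaus and lag behaviour", {
  # WT with either flavin plateaus near 15 uA cm-2
  for (fl in c("FMN", "RF")) {
    tr <- make_current_trace("WT", fl, 4, 0.4, 7.8, noise_sd = 0)
    expect_equal(tail(tr$currents_uA_cm2, 1), 15, tolerance = 0.05)
  }
  # dOmcA with and without RF are equivalent
  a <- make_current_trace("dOmcA", "RF", 2, 0.4, 7.8, noise_sd = 0)
  b <- make_current_trace("dOmcA", "none", 0, 0.4, 7.8, noise_sd = 0)
  expect_equal(a$currents_uA_cm2, b$currents_uA_cm2, tolerance = 1e-10)
  # deletion strains start below 0.1 uA cm-2
  expect_lt(max(b$currents_uA_cm2[b$times_s < 5 * 3600]), 0.1)
  # dOmcA + FMN reaches ~10x the no-flavin current at t = 35 h
  c35 <- function(tr) approx(tr$times_s, tr$currents_uA_cm2,
                             35 * 3600)$y
  fmn <- make_current_trace("dOmcA", "FMN", 2, 0.4, 7.8, noise_sd = 0)
  expect_equal(c35(fmn) / c35(b), 10, tolerance = 0.1)
  # trace determinism
  t1 <- make_current_trace("WT", "none", 0, 0.4, 7.8, seed = 3)
  t2 <- make_current_trace("WT", "none", 0, 0.4, 7.8, seed = 3)
  expect_identical(t1$currents_uA_cm2, t2$currents_uA_cm2)
  expect_error(make_current_trace("WT", "quinone"))
})

test_that("every registry fixture closes the loop through the pipeline", {
  comps <- list(free_FMN = "flavin", free_RF = "flavin",
                bound_FMN_WT = c("flavin", "heme"),
                bound_RF_WT = c("flavin", "heme"),
                bound_RF_dmtrC = c("flavin", "heme"))
  for (nm in names(comps)) {
    v <- make_dpv_fixture(nm, noise_sd = 0)
    a <- suppressWarnings(analyze_dpv(v, components = comps[[nm]]))
    truth <- v$metadata$truth$components
    fl <- truth[truth$role != "heme", ][1, ]
    got <- a$peaks[a$peaks$role == "flavin", ][1, ]
    expect_lt(abs(got$Ep_mV - 1000 * fl$Ep_V), 2)
    expect_lt(abs(got$half_width_mV - fl$W_mV), 5)
  }
  # the broad heme-only control closes loosely (its parameters are
  # generator-invented and flagged; they are not reference values)
  v <- make_dpv_fixture("heme_envelope", noise_sd = 0)
  a <- suppressWarnings(analyze_dpv(v, components = "heme"))
  truth <- v$metadata$truth$components
  expect_lt(abs(a$peaks$Ep_mV[1] - 1000 * truth$Ep_V[1]), 15)
  expect_lt(abs(a$peaks$half_width_mV[1] - truth$W_mV[1]), 25)
})
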