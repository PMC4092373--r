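test_that("nernst_reduced_fraction matches the closed form and its limits", {
  cp <- redox_couple(E0_V = -0.1, n = 1)
  expect_equal(nernst_reduced_fraction(-0.1, cp, 303.15), 0.5)
  expect_equal(nernst_reduced_fraction(-10, cp, 303.15), 1.0)
  expect_equal(nernst_reduced_fraction(10, cp, 303.15), 0.0)
  # direct evaluation with RT/F = 26.12 mV at 303.15 K
  expect_equal(nernst_reduced_fraction(-0.1 + 0.02612, cp, 303.15),
               0.26897, tolerance = 1e-4)
  # strictly decreasing in E
  E <- seq(-0.4, 0.2, by = 0.01)
  expect_true(all(diff(nernst_reduced_fraction(E, cp, 303.15)) < 0))
  expect_error(nernst_reduced_fraction(0, cp, T_K = -1),
               class = "dpvkit_invalid_parameter")
  expect_error(redox_couple(0, n = 0), class = "dpvkit_invalid_parameter")
})

test_that("dpv_response is single-peaked, symmetric, linear in magnitude", {
  pulse <- pulse_params()
  cp <- redox_couple(E0_V = -0.12, n = 1, magnitude = 2)
  E <- seq(-0.45, 0.25, by = 1e-4)
  y <- dpv_response(E, cp, pulse, 303.15)
  expect_true(all(y >= 0))
  # peak at E0 - dE/2 (anodic) within one grid step
  expect_equal(E[which.max(y)], -0.12 - 0.025, tolerance = 1.1e-4)
  # single-peaked: increasing then decreasing
  d <- sign(diff(y))
  expect_equal(sum(diff(d) != 0), 1L)
  # symmetry about the peak
  Ep <- -0.12 - 0.025
  x <- seq(0, 0.15, by = 1e-3)
  expect_lt(max(abs(dpv_response(Ep + x, cp, pulse) -
                    rev(dpv_response(Ep - rev(x), cp, pulse)))),
            1e-9 * max(y))
  # linearity in magnitude
  cp2 <- redox_couple(E0_V = -0.12, n = 1, magnitude = 4)
  expect_equal(dpv_response(E, cp2, pulse), 2 * y)
  # cathodic scan peaks at E0 + dE/2
  pc <- pulse_params(scan_direction = "cathodic")
  Ec <- rev(E)
  yc <- dpv_response(Ec, cp, pc, 303.15)
  expect_equal(Ec[which.max(yc)], -0.12 + 0.025, tolerance = 1.1e-4)
  expect_error(dpv_response(numeric(0), cp, pulse),
               class = "dpvkit_invalid_input")
  expect_error(dpv_response(c(0, -0.1), cp, pulse),
               class = "dpvkit_invalid_input")
})

test_that("theoretical half-width matches the numeric FWHM oracle", {
  # small-amplitude limit: 2 (RT/nF) ln(3 + 2 sqrt 2), about 90.6/n mV at 298 K
  lim <- 2 * 8.314462618 * 298.15 / 96485.33212 * 1000 * log(3 + 2 * sqrt(2))
  expect_equal(theoretical_half_width(1, 1e-12, 298.15), lim,
               tolerance = 1e-6)
  expect_equal(theoretical_half_width(1, 1e-12, 298.15), 90.6,
               tolerance = 0.01)
  # oracle-frozen values at the study's pulse settings
  expect_equal(theoretical_half_width(1, 50, 303.15),
               oracle_fwhm_mV(1, 50, 303.15), tolerance = 1e-6)
  expect_equal(theoretical_half_width(1, 50, 303.15), 100.47,
               tolerance = 1e-4)
  expect_equal(theoretical_half_width(2, 50, 303.15), 62.247,
               tolerance = 1e-4)
  # matches FWHM measured on dpv_response output to < 0.5 mV
  for (n in c(1, 2)) for (a in c(0.1, 25, 50)) {
    cp <- redox_couple(-0.1, n = n)
    E <- seq(-0.5, 0.3, by = 5e-5)
    y <- dpv_response(E, cp, pulse_params(amplitude_mV = a), 303.15)
    expect_lt(abs(grid_fwhm(E, y) * 1000 - theoretical_half_width(n, a, 303.15)),
              0.5)
  }
  # strictly decreasing in n, increasing in amplitude
  W_n <- vapply(c(0.5, 1, 1.5, 2, 3), theoretical_half_width,
                numeric(1), amplitude_mV = 50)
  expect_true(all(diff(W_n) < 0))
  W_a <- vapply(c(1, 10, 25, 50, 80), function(a)
    theoretical_half_width(1, a), numeric(1))
  expect_true(all(diff(W_a) > 0))
})

test_that("apparent n inverts the half-width relation", {
  for (n in c(0.5, 1, 2)) {
    W <- theoretical_half_width(n, 50, 303.15)
    expect_equal(apparent_n_from_width(W, 50, 303.15), n, tolerance = 1e-6)
  }
  expect_true(is.na(apparent_n_from_width(40, 50)))
})

test_that("reference-scale conversion is exact and invertible", {
  expect_equal(convert_reference(0.2, "Ag/AgCl", "SHE"), 0.399)
  expect_equal(convert_reference(0.2, "Ag/AgCl", "SHE", offset_V = 0.2), 0.4)
  x <- c(-0.26, 0, 0.4)
  expect_equal(convert_reference(x, "SHE", "SHE"), x)
  expect_equal(convert_reference(
    convert_reference(x, "SHE", "AgAgCl_satKCl"), "AgAgCl_satKCl", "SHE"), x)
  expect_error(convert_reference(0, "SCE", "SHE"),
               class = "dpvkit_unknown_scale")
})

test_that("pulse parameter invariants are enforced", {
  expect_error(pulse_params(increment_mV = 0),
               class = "dpvkit_invalid_parameter")
  expect_error(pulse_params(width_ms = 5000, period_ms = 5000),
               class = "dpvkit_invalid_parameter")
  expect_error(pulse_params(sampling_delay_ms = 400, width_ms = 300),
               class = "dpvkit_invalid_parameter")
})
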