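# Independent numeric oracles used to freeze expected values.

# FWHM measured directly on a dense model curve by bisection, independent of
# the package's closed-form/uniroot implementation.
oracle_fwhm_mV <- function(n, dE_mV, T_K) {
  k <- 8.314462618 * T_K / (n * 96485.33212) * 1000
  r <- function(E) 1 / (1 + exp(E / k)) - 1 / (1 + exp((E + dE_mV) / k))
  Ep <- -dE_mV / 2
  half <- r(Ep) / 2
  bisect <- function(lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if ((r(mid) - half) * (r(lo) - half) <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  span <- 40 * k + dE_mV
  bisect(Ep, Ep + span) - bisect(Ep - span, Ep)
}

# FWHM measured on sampled curve values by linear interpolation (for checks
# against dpv_response output on a grid).
grid_fwhm <- function(x, y) {
  pk <- which.max(y)
  half <- y[pk] / 2
  li <- max(which(y[1:pk] <= half))
  ri <- pk - 1 + min(which(y[pk:length(y)] <= half))
  xl <- x[li] + (x[li + 1] - x[li]) * (half - y[li]) / (y[li + 1] - y[li])
  xr <- x[ri] + (x[ri + 1] - x[ri]) * (half - y[ri]) / (y[ri + 1] - y[ri])
  xr - xl
}

make_clean_trace_pair <- function(flavin, potential_V, pH = 7.8,
                                  t_add_h = 40, seed = 1) {
  ev <- flavin_addition(t_add_h * 3600, flavin, 2)
  list(trace = make_current_trace("WT", flavin, 2, potential_V, pH,
                                  events = list(ev), noise_sd = 0,
                                  seed = seed),
       event = ev,
       background = make_background_trace("WT", potential_V, pH,
                                          noise_sd = 0, seed = seed))
}
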