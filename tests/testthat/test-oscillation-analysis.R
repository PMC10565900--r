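test_that("harmonic regression recovers noiseless sinusoids exactly", {
  for (Tp in c(10, 15, 25)) {
    y <- make_sine_series(amplitude = 0.2, period = Tp, noise_sd = 0,
                          length = 150)
    fit <- harmonic_regression(y)
    expect_equal(fit$peak_period, Tp)
    expect_equal(fit$fits$amplitude[fit$fits$period == Tp], 0.2,
                 tolerance = 1e-8)
  }
})

test_that("constant and short series are handled as contracts say", {
  fit <- harmonic_regression(rep(0.4, 60))
  expect_true(fit$degenerate)
  expect_true(all(fit$fits$amplitude < 1e-12))
  expect_true(is.na(peak_period(fit)))
  expect_error(harmonic_regression(c(1, 2)), "at least 3")
  expect_error(harmonic_regression(1:10, periods = c(1, 5)), ">= 2")
})

test_that("peak period takes the smallest period on ties", {
  # two tones of equal amplitude at periods 10 and 30, both resolvable
  t <- 1:300
  y <- sin(2 * pi * t / 10) + sin(2 * pi * t / 30)
  fit <- harmonic_regression(y, periods = c(10, 30))
  expect_equal(unname(abs(diff(fit$fits$amplitude))) < 1e-8, TRUE)
  expect_equal(fit$peak_period, 10)
  fit1 <- harmonic_regression(make_sine_series(0.1, 12, 0, 144),
                              periods = 12)
  expect_equal(fit1$peak_period, 12)
})

test_that("the period-2 harmonic is fit with its identifiable component only", {
  # sin(pi * t) vanishes at integer t; the fit must not blow up there
  y <- make_sine_series(0.2, 15, 0, 150)
  amp2 <- harmonic_regression(y, periods = 2)$fits$amplitude
  expect_lt(amp2, 0.05)
  # an alternating series is a pure period-2 cosine
  alt <- rep(c(0.6, 0.4), 40)
  fit <- harmonic_regression(alt, periods = 2:10)
  expect_equal(fit$peak_period, 2)
  expect_equal(fit$fits$amplitude[fit$fits$period == 2], 0.1,
               tolerance = 1e-8)
})

test_that("amplitude CIs cover the truth at nominal rate on noisy fixtures", {
  hits <- 0
  for (s in 1:100) {
    y <- make_sine_series(amplitude = 0.2, period = 15, noise_sd = 0.05,
                          length = 150, seed = 1000 + s)
    fit <- harmonic_regression(y, periods = 15)
    hits <- hits + (fit$fits$ci_low <= 0.2 && 0.2 <= fit$fits$ci_high)
  }
  expect_gte(hits, 90)
})

test_that("dft amplitude matches pure tones and its invariances", {
  expect_error(dft_amplitude(c(1, 2, 3)), "at least 4")
  expect_equal(dft_amplitude(rep(0.7, 32)), 0)
  y <- 0.5 + 0.25 * sin(2 * pi * (1:60) / 15)  # integer periods in window
  expect_equal(dft_amplitude(y), 0.25, tolerance = 1e-9)
  expect_equal(dft_amplitude(rev(y)), dft_amplitude(y), tolerance = 1e-12)
  expect_equal(dft_amplitude(y + 3), dft_amplitude(y), tolerance = 1e-9)
  expect_equal(dft_amplitude(2 * y), 2 * dft_amplitude(y), tolerance = 1e-9)
})

test_that("dft and harmonic regression agree on a pure tone", {
  y <- make_sine_series(0.15, 10, 0, 200)
  fit <- harmonic_regression(y, periods = 10)
  expect_equal(dft_amplitude(y), fit$fits$amplitude, tolerance = 1e-6)
})

test_that("white-noise dft amplitude shrinks with series length", {
  mean_amp <- function(L) {
    mean(vapply(1:30, function(s) {
      set.seed(s)
      dft_amplitude(rnorm(L, sd = 0.1))
    }, numeric(1)))
  }
  amps <- vapply(c(32, 128, 512), mean_amp, numeric(1))
  expect_true(all(diff(amps) < 0))
})

test_that("amplitude_sweep averages replicates and records failures as NA", {
  sw <- amplitude_sweep(0.3, 0.7, function(a, b, seed) list(amplitude = a + b))
  expect_equal(unname(sw$amplitude[1, 1]), 1)
  # replicate averaging with seed-dependent runner
  sw <- amplitude_sweep(1, 1, function(a, b, seed) seed %% 7, replicates = 5,
                        seed = 2)
  expect_equal(unname(sw$amplitude[1, 1]), mean(sw$long$amplitude))
  expect_equal(nrow(sw$long), 5)
  # same master seed, same child seeds, same result
  sw2 <- amplitude_sweep(1, 1, function(a, b, seed) seed %% 7, replicates = 5,
                         seed = 2)
  expect_identical(sw$amplitude, sw2$amplitude)
  expect_warning(
    swf <- amplitude_sweep(c(0, 1), 0.5, function(a, b, seed) {
      if (a == 0) stop("boom") else 0.2
    }),
    "run failed")
  expect_true(is.na(swf$amplitude[1, 1]))
  expect_equal(unname(swf$amplitude[2, 1]), 0.2)
})

test_that("scenario-2 sweep: the a = 0 row never oscillates once stabilized", {
  # long window because the marginal cell b = 0.5 (where h * (1 - b) = 1)
  # drifts monotonically toward fixation for hundreds of cycles
  passage <- passage_params(n_cycles = 1000, burn_in_cycles = 800)
  sw <- amplitude_sweep(0, c(0, 0.5, 1), scenario2_runner(passage = passage))
  expect_true(all(sw$amplitude < 1e-3))
})
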