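make_spec <- function(y, wl = seq(330, 850, by = 1)) {
  spectrum(wl, y, timestamp = 0)
}

test_that("Savitzky-Golay reproduces polynomials up to its degree exactly", {
  wl <- seq(330, 850, by = 1)
  for (coefs in list(c(0.5, 0, 0, 0), c(0.1, 2e-3, -4e-6, 1e-9))) {
    y <- coefs[1] + coefs[2] * wl + coefs[3] * wl^2 + coefs[4] * wl^3
    sm <- savgol_smooth(make_spec(y, wl), 21, 3)
    expect_lt(max(abs(sm$absorbances - y)), 1e-9)
  }
})

test_that("Savitzky-Golay centre matches an independent normal-equations fit", {
  n <- 101
  y <- rep(0, n); y[51] <- 1
  sm <- savgol_smooth(make_spec(y, seq_len(n)), 21, 3)
  # brute-force local cubic fit at every point, solved via lm()
  oracle <- vapply(11:91, function(i) {
    idx <- (i - 10):(i + 10)
    d <- data.frame(x = idx - i, y = y[idx])
    unname(stats::coef(stats::lm(y ~ x + I(x^2) + I(x^3), d))[1])
  }, numeric(1))
  expect_equal(sm$absorbances[11:91], oracle, tolerance = 1e-9)
})

test_that("Savitzky-Golay rejects invalid settings", {
  s <- make_spec(rep(0.2, 50), seq_len(50))
  expect_error(savgol_smooth(s, 20, 3), "odd")
  expect_error(savgol_smooth(s, 51, 3), "fewer than window")
  expect_error(savgol_smooth(s, 5, 5), "degree")
})

test_that("baseline subtraction zeroes the 600-850 nm mean and is a pure shift", {
  wl <- seq(330, 850, by = 1)
  set.seed(1)
  y <- 0.3 * exp(-0.5 * ((wl - 446) / 15)^2) + 0.02 + rnorm(length(wl), 0, 0.002)
  out <- subtract_baseline(make_spec(y, wl))
  band <- wl >= 600 & wl <= 850
  expect_lt(abs(mean(out$absorbances[band])), 1e-12)
  # the subtracted scalar is exactly the band mean computed independently
  expect_equal(y - out$absorbances, rep(mean(y[band]), length(wl)),
               tolerance = 1e-12)
  # shift invariance
  out2 <- subtract_baseline(make_spec(y + 0.137, wl))
  expect_equal(out2$absorbances, out$absorbances, tolerance = 1e-12)
  # flat spectrum maps to zero
  expect_equal(subtract_baseline(make_spec(rep(0.2, length(wl)), wl))$absorbances,
               rep(0, length(wl)), tolerance = 1e-14)
  expect_error(subtract_baseline(make_spec(y, wl), band = c(900, 1000)),
               "baseline band")
})

test_that("smoothing and baseline subtraction commute up to a vanishing constant", {
  # the filter is linear and constant-preserving, so the two orders can
  # differ only by a constant (the band mean of the smoothed vs raw
  # spectrum); on noise-free band-limited input even that constant vanishes
  wl <- seq(330, 850, by = 1)
  y0 <- 0.4 * exp(-0.5 * ((wl - 390) / 30)^2) + 0.02
  s0 <- make_spec(y0, wl)
  ab0 <- subtract_baseline(savgol_smooth(s0))$absorbances
  ba0 <- savgol_smooth(subtract_baseline(s0))$absorbances
  expect_lt(max(abs(ab0 - ba0)), 1e-9)

  set.seed(2)
  y <- y0 + rnorm(length(wl), 0, 0.01)
  s <- make_spec(y, wl)
  d <- subtract_baseline(savgol_smooth(s))$absorbances -
    savgol_smooth(subtract_baseline(s))$absorbances
  expect_lt(max(abs(d - mean(d))), 1e-12)  # a pure constant shift
  expect_lt(abs(mean(d)), 1e-3)            # and a tiny one
})

test_that("trace extraction picks the nearest grid point, lower on ties", {
  pre <- spectral_preset(tau = 40, rate = 2, duration = 300, noise_sigma = 0)
  s <- simulate_spectral_series(pre)
  tr <- extract_trace(s, 390)
  expect_equal(nrow(tr), 600)
  expect_equal(tr$t, seq(0, 299.5, by = 0.5))
  expect_equal(tr$A, s$absorbance[, which(s$wavelengths == 390)])

  # equidistant neighbours 389.6 / 390.4 resolve to 389.6
  s2 <- spectral_series(c(380, 389.6, 390.4, 400), c(0, 1),
                        matrix(1:8, nrow = 2))
  tr2 <- extract_trace(s2, 390)
  expect_equal(tr2$A, s2$absorbance[, 2])
  expect_error(extract_trace(s2, 500), "outside grid")
})

test_that("decay fitting recovers noiseless traces and matches a log-linear oracle", {
  t <- seq(0, 100, by = 0.5)
  for (truth in list(c(tau = 40, amp = 0.3, off = 0.1),
                     c(tau = 6, amp = 0.3, off = 0.1))) {
    y <- truth["off"] + truth["amp"] * exp(-t / truth["tau"])
    fit <- fit_decay(data.frame(t = t, A = y))
    expect_true(fit$converged)
    expect_equal(fit$tau, unname(truth["tau"]), tolerance = 1e-3)
    expect_equal(fit$amplitude, unname(truth["amp"]), tolerance = 1e-3)
    expect_equal(fit$offset, unname(truth["off"]), tolerance = 1e-3)
    # log-linear regression of (A - true offset) gives the same rate
    slope <- unname(stats::coef(stats::lm(log(y - truth["off"]) ~ t))[2])
    expect_equal(-1 / fit$tau, slope, tolerance = 1e-6)
  }
})

test_that("flat traces are flagged, not fitted", {
  fit <- fit_decay(data.frame(t = 1:10, A = rep(0.2, 10)))
  expect_false(fit$converged)
  expect_true(is.na(fit$tau))
  expect_error(fit_decay(data.frame(t = 1:3, A = 1:3)), "at least 5")
})

test_that("smoothing does not degrade tau recovery under noise", {
  # scaled down to 25 replicates to keep the default run fast
  taus <- sapply(1:25, function(seed) {
    pre <- spectral_preset(tau = 40, rate = 2, duration = 120,
                           noise_sigma = 0.005, seed = seed)
    s <- simulate_spectral_series(pre)
    with_sm <- fit_spectral_series(s)$tau
    raw_tr <- extract_trace(s, 390)
    no_sm <- fit_decay(raw_tr)$tau
    c(with_sm, no_sm)
  })
  expect_lte(sd(taus[1, ]), sd(taus[2, ]))
})

test_that("pipeline recovers tau within 5% on most replicates", {
  # scaled down to 12 replicates (property holds at 50)
  rel_err <- sapply(1:12, function(seed) {
    pre <- spectral_preset(tau = 40, rate = 2, duration = 300,
                           noise_sigma = 0.005, seed = seed)
    abs(fit_spectral_series(simulate_spectral_series(pre))$tau - 40) / 40
  })
  expect_gte(mean(rel_err <= 0.05), 0.9)
})
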