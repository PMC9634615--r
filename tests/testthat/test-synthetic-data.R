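test_that("noiseless occupancy series follows the closed forms and conserves the total", {
  p <- photocycle_params(tau_C = 39, ps_L_fraction = 0.75,
                         delays = c(1e-9, 39, 90), noise_sigma_occ = 0)
  s <- simulate_occupancy_series(p)

  total <- s$occ_A + s$occ_B + s$occ_C
  expect_lt(max(abs(total - 1)), 1e-12)

  # renormalization leaves occ_C slightly off the raw exponential; compare
  # the raw (pre-renormalization) closed form
  raw_C <- function(t) 0.75 * exp(-t / 39)
  raw_A <- function(t) p$dark_A_fraction -
    (p$dark_A_fraction - (1 - 0.75)) * exp(-t / p$tau_A)
  raw_B <- function(t) (1 - p$dark_A_fraction) * (1 - exp(-t / p$tau_B))
  tot <- raw_C(p$delays) + raw_A(p$delays) + raw_B(p$delays)
  expect_equal(s$occ_C, raw_C(p$delays) / tot, tolerance = 1e-12)

  # t = 0: occ_C equals the PS L fraction exactly (total is 1 there)
  expect_equal(s$occ_C[1], 0.75, tolerance = 1e-6)
  # t = tau_C: raw ratio is exactly 1/e
  expect_equal(raw_C(39) / raw_C(0), exp(-1), tolerance = 1e-12)
  # direct closed-form evaluation at t = 90 s
  expect_equal(raw_C(90), 0.75 * exp(-90 / 39), tolerance = 1e-12)
  expect_equal(0.75 * exp(-90 / 39), 0.0746, tolerance = 1e-3)
})

test_that("noiseless occ_C decreases and occ_B increases strictly", {
  p <- photocycle_params(delays = sort(unique(default_delays())),
                         noise_sigma_occ = 0)
  s <- simulate_occupancy_series(p)
  expect_true(all(diff(s$occ_C) < 0))
  expect_true(all(diff(s$occ_B) > 0))
})

test_that("occupancy simulator validates parameters and is seed-reproducible", {
  expect_error(photocycle_params(tau_C = -1), "time constants")
  expect_error(photocycle_params(delays = numeric(0)), "non-empty")
  expect_error(photocycle_params(delays = c(1, -2)), "positive")

  p <- photocycle_params(seed = 7)
  s1 <- simulate_occupancy_series(p)
  s2 <- simulate_occupancy_series(p)
  expect_identical(s1, s2)
  s3 <- simulate_occupancy_series(photocycle_params(seed = 8))
  expect_false(identical(s1$occ_C, s3$occ_C))
})

test_that("spectral series has the stated grid, limits and half-life", {
  pre <- spectral_preset(tau = 40, rate = 2, duration = 300, noise_sigma = 0)
  s <- simulate_spectral_series(pre)
  expect_length(s$times, 600)
  expect_equal(s$times[1:3], c(0, 0.5, 1.0))
  expect_equal(max(s$times), 299.5)

  tr <- extract_trace(s, 390)
  # analytic A(infinity) at 390 nm: baseline + fully recovered dark bands
  a_inf <- pre$baseline_offset +
    sum(pre$dark_band_amplitudes *
          exp(-0.5 * ((390 - pre$dark_band_centres) / pre$dark_band_widths)^2))
  # the last sample still carries exp(-299.5/40) of the decaying part
  expect_equal(tr$A[600], a_inf, tolerance = 5e-3)
  expect_gt(tr$A[600], a_inf)
  # closed-form half-life: A(t) - A(inf) decays as exp(-t/40), so over the
  # grid interval closest to 40 ln 2 ~ 27.7 s the excess nearly halves
  i0 <- which(tr$t == 100)
  i1 <- which(tr$t == 127.5)
  expect_equal((tr$A[i1] - a_inf) / (tr$A[i0] - a_inf),
               exp(-(127.5 - 100) / 40), tolerance = 1e-9)
  expect_equal(exp(-40 * log(2) / 40), 0.5, tolerance = 1e-12)
})

test_that("spectral preset rejects degenerate acquisition settings", {
  expect_error(spectral_preset(duration = 1, rate = 2), "too short")
  expect_error(spectral_preset(tau = 0), "tau")
  expect_error(spectral_preset(wl_max = 700), "baseline")
})

test_that("simulated reflections are a noiseless passthrough and seed-stable", {
  m <- toy_crystal(1)
  refl <- simulate_reflections(m, c(C = 1, A = 0), noise_sigma = 0,
                               dmin = 2.5)
  direct <- calc_structure_factors(m, ops_ortho(), dmin = 2.5)
  expect_equal(refl$amplitude, direct$amplitude, tolerance = 1e-12)

  r1 <- simulate_reflections(toy_crystal(), c(C = 0.5, A = 0.5),
                             noise_sigma = 0.03, seed = 11, dmin = 2.5)
  r2 <- simulate_reflections(toy_crystal(), c(C = 0.5, A = 0.5),
                             noise_sigma = 0.03, seed = 11, dmin = 2.5)
  expect_identical(r1, r2)
  expect_error(simulate_reflections(m, c(C = 1.2, A = -0.2)), "\\[0, 1\\]")
  expect_error(simulate_reflections(m, c(C = 0.8, A = 0.1)), "sum to 1")
})

test_that("symmetry series plateaus and logistic midpoint behave as stated", {
  sets <- simulate_symmetry_series(74, 5, delays = c(2, 74, 1620), seed = 3,
                                   n_pairs = 400)
  cons <- symmetry_consistency_series(sets)
  expect_gte(cons$fraction_tetragonal[1], 0.9)
  expect_lte(cons$fraction_tetragonal[3], 0.15)
  # logistic midpoint: expected consistency 0.5; binomial sd ~ 0.025
  expect_equal(cons$fraction_tetragonal[2], 0.5, tolerance = 0.1)
  expect_error(simulate_symmetry_series(-1, 5), "transition_time")
  expect_error(simulate_symmetry_series(74, 0), "width")
})

test_that("generator outputs round-trip through their text formats", {
  p <- photocycle_params(seed = 5)
  s <- simulate_occupancy_series(p)
  f <- file.path(tempdir(), "occ.csv")
  write_occupancy_csv(s, f)
  s2 <- read_occupancy_csv(f)
  expect_equal(s2$occ_C, s$occ_C, tolerance = 1e-12)
  expect_equal(s2$ps_L_occupancy, s$ps_L_occupancy)

  pre <- spectral_preset(duration = 3, rate = 2, noise_sigma = 0.005,
                         seed = 2)
  ser <- simulate_spectral_series(pre)
  d <- file.path(tempdir(), "spectra")
  write_spectra_csv(ser, d)
  ser2 <- read_spectra_csv(d)
  expect_equal(ser2$absorbance, ser$absorbance, tolerance = 1e-10)

  refl <- simulate_reflections(toy_crystal(), c(C = 0.65, A = 0.35),
                               noise_sigma = 0.03, seed = 1, dmin = 3)
  rf <- file.path(tempdir(), "refl.txt")
  write_reflections(refl, rf)
  refl2 <- read_reflections(rf)
  expect_equal(refl2$hkl, refl$hkl)
  expect_equal(refl2$amplitude, refl$amplitude, tolerance = 1e-9)
  expect_equal(refl2$cell, refl$cell)
})
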