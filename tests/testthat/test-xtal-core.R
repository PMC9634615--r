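test_that("operator sets have the right counts and are closed under composition", {
  expect_length(ops_p1()$R, 1)
  expect_length(ops_ortho()$R, 4)
  expect_length(ops_tetra()$R, 8)
  for (ops in list(ops_ortho(), ops_tetra())) {
    keys <- vapply(seq_along(ops$R), function(i) {
      paste(c(ops$R[[i]], round(ops$t[[i]] %% 1, 6)), collapse = ",")
    }, character(1))
    expect_true(any(keys == paste(c(diag(3), 0, 0, 0), collapse = ",")))
    for (i in seq_along(ops$R)) for (j in seq_along(ops$R)) {
      Rij <- ops$R[[i]] %*% ops$R[[j]]
      tij <- (ops$R[[i]] %*% ops$t[[j]] + ops$t[[i]]) %% 1
      expect_true(paste(c(Rij, round(tij, 6)), collapse = ",") %in% keys)
    }
  }
})

test_that("symmetry expansion multiplies atom counts by the operator count", {
  m <- tiny_model(1)
  expect_equal(nrow(expand_symmetry(m, ops_p1())$atoms), 1)
  expect_equal(nrow(expand_symmetry(m, ops_ortho())$atoms), 4)
  expect_equal(nrow(expand_symmetry(m, ops_tetra())$atoms), 8)
  expect_equal(expand_symmetry(m, ops_p1())$atoms$x, m$atoms$x)
})

test_that("structure factors match an independent brute-force summation", {
  m <- tiny_model(3)
  hkl <- generate_hkl(m$cell, 3.0)[seq(1, 60, by = 3), ]
  for (ops in list(ops_p1(), ops_ortho())) {
    sf <- calc_structure_factors(m, ops, hkl = hkl)
    oracle <- brute_force_sf(m, ops, hkl)
    expect_lt(max(Mod(sf_as_complex(sf) - oracle)), 1e-9)
  }
})

test_that("single atom at the origin gives |F| = form factor with zero phase", {
  m <- tiny_model(1)
  m$atoms[c("x", "y", "z")] <- 0
  m$atoms$b <- 0
  hkl <- generate_hkl(m$cell, 3.0)
  sf <- calc_structure_factors(m, ops_p1(), hkl = hkl)
  s2 <- relaxmx:::refl_s2(hkl, m$cell)
  expect_equal(sf$amplitude,
               unname(form_factor(m$atoms$element, s2)), tolerance = 1e-12)
  expect_lt(max(abs(sf$phase)), 1e-9)
})

test_that("Friedel symmetry holds for real scatterers", {
  m <- tiny_model(4)
  hkl <- generate_hkl(m$cell, 2.8)[1:40, ]
  sf_p <- calc_structure_factors(m, ops_ortho(), hkl = hkl)
  sf_m <- calc_structure_factors(m, ops_ortho(), hkl = -hkl)
  expect_lt(max(abs(sf_p$amplitude - sf_m$amplitude)), 1e-9)
})

test_that("screw axes extinguish odd axial reflections on random models", {
  for (seed in 1:3) {
    m <- tiny_model(5, seed = seed)
    ax <- rbind(c(1, 0, 0), c(3, 0, 0), c(0, 1, 0), c(0, 3, 0),
                c(0, 0, 1), c(0, 0, 3))
    sf <- calc_structure_factors(m, ops_ortho(), hkl = ax)
    expect_lt(max(sf$amplitude), 1e-9)
    even <- calc_structure_factors(m, ops_ortho(),
                                   hkl = rbind(c(2, 0, 0), c(0, 2, 0)))
    expect_gt(min(even$amplitude), 1e-6)
  }
})

test_that("Fourier synthesis satisfies the stated conventions", {
  cell <- c(20, 20, 25, 90, 90, 90)
  # all amplitudes zero -> zero map
  z <- reflection_set(hkl = rbind(c(1, 0, 0), c(0, 1, 1)),
                      amplitude = c(0, 0), phase = c(0, 0), cell = cell,
                      resolution_limit = 10)
  expect_equal(max(abs(fourier_map(z, grid = c(8, 8, 8))$values)), 0)
  # single (1,0,0), amplitude 1, phase 0: cosine along x, peak 2/V
  one <- reflection_set(hkl = matrix(c(1, 0, 0), 1), amplitude = 1,
                        phase = 0, cell = cell, resolution_limit = 20)
  mp <- fourier_map(one, grid = c(40, 4, 4))
  v <- relaxmx:::cell_volume(cell)
  expect_equal(max(mp$values), 2 / v, tolerance = 1e-9)
  expect_equal(mp$values[1, 1, 1], 2 / v, tolerance = 1e-12)
  expect_equal(mp$values[11, 1, 1], 0, tolerance = 1e-12)  # quarter period
  # Parseval on a random set: sum |F|^2 / V = integral rho^2 dV
  set.seed(3)
  hkl <- generate_hkl(cell, 4)[sample(1:50, 20), ]
  rs <- reflection_set(hkl = hkl, amplitude = runif(20, 0.5, 3),
                       phase = runif(20, -180, 180), cell = cell,
                       resolution_limit = 4)
  mp2 <- fourier_map(rs, grid = c(16, 16, 18))
  lhs <- 2 * sum(rs$amplitude^2) / v       # Friedel-completed sum
  rhs <- mean(mp2$values^2) * v
  expect_equal(rhs, lhs, tolerance = 1e-6)
  expect_error(fourier_map(z <- reflection_set(hkl = matrix(c(1, 0, 0), 1),
                                               amplitude = 1, cell = cell,
                                               resolution_limit = 5)),
               "no phases")
})

test_that("difference maps vanish at the truth, negate on swap and localise omitted atoms", {
  m <- toy_crystal(0.65)
  ops <- ops_ortho()
  fo <- calc_structure_factors(m, ops, dmin = 2.5)
  zero <- difference_map(fo, fo, grid = c(12, 12, 15))
  expect_lt(max(abs(zero$values)), 1e-12)

  momit <- atomic_model(m$atoms[-10, ], m$cell, m$spacegroup)
  fc <- calc_structure_factors(momit, ops, hkl = fo$hkl)
  dm <- difference_map(fo, fc)
  idx <- which(dm$values == max(dm$values), arr.ind = TRUE)[1, ]
  peak_frac <- (idx - 1) / dm$dim
  copies <- expand_symmetry(atomic_model(m$atoms[10, , drop = FALSE],
                                         m$cell, m$spacegroup), ops)$atoms
  dists <- apply(copies[c("x", "y", "z")], 1, function(p) {
    d <- peak_frac - as.numeric(p)
    d <- d - round(d)
    sqrt(sum((d * m$cell[1:3])^2))
  })
  expect_lt(min(dists), 0.5)

  # swapping obs/calc roles negates the unscaled map; both sets carry the
  # same phases here so the antisymmetry is exact
  fo_shared <- fc
  fo_shared$amplitude <- fo$amplitude
  ab <- difference_map(fo_shared, fc, grid = c(10, 10, 10), scale = FALSE)
  ba <- difference_map(fc, fo_shared, grid = c(10, 10, 10), scale = FALSE)
  expect_lt(max(abs(ab$values + ba$values)), 1e-9)
})

test_that("difference map sigma from Parseval matches the grid sigma", {
  m <- toy_crystal(0.4)
  ops <- ops_ortho()
  fo <- simulate_reflections(m, c(C = 0.6, A = 0.4), noise_sigma = 0,
                             dmin = 2.0)
  fc <- calc_structure_factors(toy_crystal(0.5), ops, hkl = fo$hkl)
  co <- relaxmx:::difference_coefficients(fo, fc)
  sig_parseval <- relaxmx:::difference_map_sigma(co)
  mp <- fourier_map(co)
  # population sd over the grid (map mean is 0 without F000)
  sig_grid <- sqrt(mean(mp$values^2))
  expect_equal(sig_parseval, sig_grid, tolerance = 1e-3)
})

test_that("R factor matches hand-computed values and is scale invariant", {
  cell <- c(20, 20, 25, 90, 90, 90)
  mk <- function(f) reflection_set(hkl = cbind(seq_along(f), 1, 2),
                                   amplitude = f,
                                   cell = cell, resolution_limit = 5)
  fo <- mk(c(1, 1, 1, 2))
  fc <- mk(c(1, 1, 1, 1))
  # least-squares scale on |Fc|: k = sum(fo fc)/sum(fc^2) = 5/4
  # R = sum|fo - k fc| / sum fo = (3 * 1/4 + 3/4) / 5 = 0.3
  expect_equal(r_factor(fo, fc), 0.3, tolerance = 1e-12)
  expect_equal(r_factor(fo, fo), 0, tolerance = 1e-14)
  # doubling observations changes nothing
  fo2 <- mk(2 * c(1, 1, 1, 2))
  expect_equal(r_factor(fo2, fc), 0.3, tolerance = 1e-12)
  # F_obs = 2 F_calc -> 0
  expect_equal(r_factor(mk(2 * c(1, 2, 3, 4)), mk(c(1, 2, 3, 4))), 0,
               tolerance = 1e-14)
})

test_that("R of small relative perturbations approaches the half-normal mean", {
  m <- toy_crystal(0.65)
  fo <- calc_structure_factors(m, ops_ortho(), dmin = 2.5)
  set.seed(9)
  rs <- replicate(40, {
    pert <- fo
    pert$amplitude <- fo$amplitude * (1 + rnorm(length(fo$amplitude), 0, 0.03))
    r_factor(pert, fo)
  })
  expect_equal(mean(rs), 0.03 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("scale and B refinement recovers truth, perturbations and scale", {
  m <- toy_crystal(0.65)
  ops <- ops_ortho()
  fo <- simulate_reflections(m, c(C = 0.65, A = 0.35), noise_sigma = 0)
  ref <- refine_scale_and_b(m, fo, ops)
  expect_lt(ref$r_final, 1e-6)
  expect_lt(max(abs(ref$b_iso - m$atoms$b)), 0.1)

  mtrue <- m
  mtrue$atoms$b[3] <- 60
  fo2 <- simulate_reflections(mtrue, c(C = 0.65, A = 0.35), noise_sigma = 0)
  ref2 <- refine_scale_and_b(m, fo2, ops)
  expect_lt(abs(ref2$b_iso[3] - 60), 2)
  expect_lt(max(abs(ref2$b_iso[-3] - 20)), 2)

  fo3 <- fo
  fo3$amplitude <- fo$amplitude / 3
  ref3 <- refine_scale_and_b(m, fo3, ops)
  expect_equal(ref3$scale, 1 / 3, tolerance = 1e-6)
})

test_that("PDB files round-trip bit-consistent models", {
  m <- toy_crystal(0.65)
  f <- file.path(tempdir(), "toy.pdb")
  write_pdb(m, f)
  m2 <- read_pdb(f)
  expect_equal(m2$atoms$element, m$atoms$element)
  expect_equal(m2$atoms$altloc, m$atoms$altloc)
  expect_equal(m2$atoms$occ, m$atoms$occ, tolerance = 1e-6)
  expect_equal(m2$atoms$b, m$atoms$b, tolerance = 1e-6)
  # PDB stores 3 decimals in Angstrom: fractional agreement to ~1e-4
  expect_lt(max(abs(m2$atoms$x - m$atoms$x)), 1e-4)
  expect_equal(m2$cell, m$cell)
  # the packaged fixture parses to the in-code toy crystal
  fx <- system.file("extdata", "toy_crystal_synthetic.pdb",
                    package = "relaxmx")
  mfx <- read_pdb(fx)
  expect_equal(nrow(mfx$atoms), nrow(m$atoms))
  expect_equal(mfx$atoms$occ, m$atoms$occ, tolerance = 1e-6)
})
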