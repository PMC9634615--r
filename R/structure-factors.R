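# Single-Gaussian-plus-constant atomic form factors, f(q) = a exp(-b q^2) + c
# with q = sin(theta)/lambda = 1/(2d). Coefficients chosen so f(0) = Z; an
# intentionally coarse stand-in for the 4-Gaussian tabulations, adequate at
# toy (~2 A) resolution.
FORM_FACTORS <- list(
  H = c(a = 0.9, b = 28.0, c = 0.1),
  C = c(a = 4.6, b = 22.0, c = 1.4),
  N = c(a = 5.4, b = 16.0, c = 1.6),
  O = c(a = 6.1, b = 12.5, c = 1.9),
  P = c(a = 9.0, b = 11.5, c = 6.0),
  S = c(a = 9.5, b = 10.5, c = 6.5))

#' Atomic scattering factor
#'
#' @param element Element symbol (H, C, N, O, P or S).
#' @param s2 `1/d^2` values (inverse square Angstrom).
#' @return Scattering factor at each `s2`.
#' @export
form_factor <- function(element, s2) {
  ff <- FORM_FACTORS[[toupper(element)]]
  if (is.null(ff)) stopf("no form factor for element '%s'", element)
  q2 <- s2 / 4
  ff["a"] * exp(-ff["b"] * q2) + ff["c"]
}

# Complex structure factors by direct summation over atoms and symmetry
# operators. Returns a complex vector aligned with the rows of hkl.
structure_factors_complex <- function(model, ops, hkl) {
  s2 <- refl_s2(hkl, model$cell)
  a <- model$atoms
  coef <- vapply(seq_len(nrow(a)), function(j) {
    a$occ[j] * form_factor(a$element[j], s2) * exp(-a$b[j] * s2 / 4)
  }, numeric(nrow(hkl)))          # n_refl x n_atoms
  xyz <- as.matrix(a[c("x", "y", "z")])
  f <- complex(real = numeric(nrow(hkl)), imaginary = numeric(nrow(hkl)))
  for (i in seq_along(ops$R)) {
    pos <- xyz %*% t(ops$R[[i]]) + rep(ops$t[[i]], each = nrow(xyz))
    phase <- 2 * pi * (hkl %*% t(pos))   # n_refl x n_atoms
    f <- f + rowSums(coef * exp(1i * phase))
  }
  f
}

#' Calculate structure factors by direct summation
#'
#' \deqn{F(h) = \sum_{sym} \sum_{atoms} occ \cdot f_{elem}(s) \cdot
#'   e^{-B s^2 / 4} \cdot e^{2\pi i\, h \cdot (Rx + t)}}
#' with `s = 1/d`. Amplitudes and phases are returned for the supplied
#' Friedel-unique index list.
#'
#' @param model An `rx_model` (asymmetric unit).
#' @param ops An `rx_symops`.
#' @param hkl Integer matrix of Miller indices; defaults to all unique
#'   indices to `dmin`.
#' @param dmin Resolution limit used when `hkl` is `NULL`.
#' @return An `rx_reflections` with amplitudes and phases.
#' @export
calc_structure_factors <- function(model, ops, hkl = NULL, dmin = 2.0) {
  stopifnot(inherits(model, "rx_model"), inherits(ops, "rx_symops"))
  if (nrow(model$atoms) == 0) stopf("model has no atoms")
  if (is.null(hkl)) hkl <- generate_hkl(model$cell, dmin)
  f <- structure_factors_complex(model, ops, hkl)
  reflection_set(hkl = hkl, amplitude = Mod(f),
                 phase = Arg(f) * 180 / pi,
                 cell = model$cell, spacegroup = ops$label,
                 resolution_limit = if (is.null(hkl)) dmin else
                   1 / sqrt(max(refl_s2(hkl, model$cell))))
}

# Electron density at arbitrary fractional points by Fourier synthesis with
# Friedel completion: rho(x) = (2/V) sum_half |F| cos(2 pi h.x - phi).
# F(000) is excluded by construction (it is never in the stored half set).
density_at_points <- function(refl, points, chunk = 4096L) {
  if (is.null(refl$phase)) stopf("reflection set has no phases")
  v <- cell_volume(refl$cell)
  phi <- refl$phase * pi / 180
  fc <- refl$amplitude * cos(phi)
  fs <- refl$amplitude * sin(phi)
  points <- as.matrix(points)
  rho <- numeric(nrow(points))
  idx <- split(seq_len(nrow(points)),
               ceiling(seq_len(nrow(points)) / chunk))
  for (ii in idx) {
    ang <- 2 * pi * (points[ii, , drop = FALSE] %*% t(refl$hkl))
    rho[ii] <- (cos(ang) %*% fc + sin(ang) %*% fs) * 2 / v
  }
  rho
}

# FFT-friendly (5-smooth) grid dimensions: sampling at ~resolution/3 per axis.
map_grid_dim <- function(cell, dmin) {
  smooth5 <- function(n) {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    m == 1L
  }
  vapply(ceiling(cell[1:3] / (dmin / 3)), function(n) {
    n <- as.integer(n)
    while (!smooth5(n)) n <- n + 1L
    n
  }, integer(1))
}

#' Fourier synthesis of an electron-density map
#'
#' Inverse discrete Fourier synthesis over the unit cell from amplitudes and
#' phases, with Friedel completion; F(000) is excluded, so the map mean is
#' zero and densities are relative to the cell average.
#'
#' @param refl An `rx_reflections` with phases.
#' @param grid Integer length-3 grid dimensions; defaults to sampling at one
#'   third of the resolution limit.
#' @return An object of class `rx_map`: list with `dim`, `values` (3D
#'   array), `cell`, `mean` and `sigma`.
#' @export
fourier_map <- function(refl, grid = NULL) {
  stopifnot(inherits(refl, "rx_reflections"))
  if (is.null(refl$phase)) stopf("reflection set has no phases")
  if (is.null(grid)) {
    grid <- map_grid_dim(refl$cell, refl$resolution_limit %||% 2.0)
  }
  grid <- as.integer(grid)
  pts <- as.matrix(expand.grid(x = (seq_len(grid[1]) - 1) / grid[1],
                               y = (seq_len(grid[2]) - 1) / grid[2],
                               z = (seq_len(grid[3]) - 1) / grid[3]))
  rho <- density_at_points(refl, pts)
  vals <- array(rho, dim = grid)
  structure(list(dim = grid, values = vals, cell = refl$cell,
                 mean = mean(vals), sigma = stats::sd(as.numeric(vals))),
            class = "rx_map")
}

#' @export
print.rx_map <- function(x, ...) {
  cat(sprintf("Density map %d x %d x %d, mean %.3g, sigma %.3g e/A^3\n",
              x$dim[1], x$dim[2], x$dim[3], x$mean, x$sigma))
  invisible(x)
}

#' Export a density map as a plain-text grid
#'
#' @param map An `rx_map`.
#' @param path File path. Format: a header with dimensions and cell, then
#'   one value per line in Fortran (x fastest) order.
#' @return `path`, invisibly.
#' @export
write_map_text <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# grid %d %d %d cell %s", map$dim[1], map$dim[2],
                     map$dim[3],
                     paste(format(map$cell, trim = TRUE), collapse = " ")),
             con)
  writeLines(format(as.numeric(map$values), digits = 8), con)
  invisible(path)
}

# Match two reflection sets on their common Miller indices; returns index
# vectors into each.
match_reflections <- function(a, b) {
  ka <- paste(a$hkl[, 1], a$hkl[, 2], a$hkl[, 3])
  kb <- paste(b$hkl[, 1], b$hkl[, 2], b$hkl[, 3])
  m <- match(ka, kb)
  keep <- !is.na(m)
  if (!any(keep)) stopf("reflection sets share no Miller indices")
  list(ia = which(keep), ib = m[keep])
}

#' Fobs - Fcalc difference map
#'
#' Synthesises a map with coefficients `(k|Fobs| - |Fcalc|) exp(i phi_calc)`
#' over the common reflections, where `k` is the least-squares scale bringing
#' the observed amplitudes onto the calculated ones.
#'
#' @param f_obs Observed `rx_reflections` (amplitudes).
#' @param f_calc Calculated `rx_reflections` with phases.
#' @param grid Optional grid dimensions (see [fourier_map()]).
#' @param scale Apply the least-squares scale to `|Fobs|` (default); with
#'   `FALSE` the raw amplitude difference is used, making the synthesis
#'   exactly antisymmetric under swapping the two roles.
#' @return An `rx_map`; its `sigma` is the map standard deviation used for
#'   sigma-level thresholding.
#' @export
difference_map <- function(f_obs, f_calc, grid = NULL, scale = TRUE) {
  co <- difference_coefficients(f_obs, f_calc, scale)
  fourier_map(co, grid)
}

# Reflection set holding the (k|Fo| - |Fc|, phi_c) difference coefficients.
difference_coefficients <- function(f_obs, f_calc, scale = TRUE) {
  if (is.null(f_calc$phase)) stopf("f_calc must carry phases")
  m <- match_reflections(f_obs, f_calc)
  fo <- f_obs$amplitude[m$ia]
  fc <- f_calc$amplitude[m$ib]
  k <- if (scale) sum(fo * fc) / sum(fo^2) else 1
  dF <- k * fo - fc
  reflection_set(hkl = f_calc$hkl[m$ib, , drop = FALSE],
                 amplitude = abs(dF),
                 phase = f_calc$phase[m$ib] + ifelse(dF < 0, 180, 0),
                 cell = f_calc$cell, spacegroup = f_calc$spacegroup,
                 resolution_limit = f_calc$resolution_limit)
}

# Analytic map sigma of a difference synthesis via Parseval: with the mean 0
# (no F000), var = sum_all |F|^2 / V^2 = 2 sum_half |F|^2 / V^2.
difference_map_sigma <- function(coefs) {
  sqrt(2 * sum(coefs$amplitude^2)) / cell_volume(coefs$cell)
}

#' Crystallographic R factor
#'
#' `R = sum | |Fobs| - k |Fcalc| | / sum |Fobs|` over common reflections,
#' with `k` the least-squares scale applied to `|Fcalc|`.
#'
#' @param f_obs,f_calc `rx_reflections` sharing Miller indices.
#' @return Unitless R factor.
#' @export
r_factor <- function(f_obs, f_calc) {
  m <- match_reflections(f_obs, f_calc)
  fo <- f_obs$amplitude[m$ia]
  fc <- f_calc$amplitude[m$ib]
  if (sum(fo) <= 0) stopf("all-zero observed amplitudes")
  k <- sum(fo * fc) / sum(fc^2)
  sum(abs(fo - k * fc)) / sum(fo)
}

#' Refine overall scale and per-atom isotropic B-factors
#'
#' Minimises the least-squares misfit `sum(|Fobs| - k |Fcalc(B)|)^2`, with
#' the scale `k` profiled analytically and the per-atom B values optimised by
#' bounded quasi-Newton iteration (analytic gradient via the envelope
#' theorem) within `[2, 150]` A^2. Starting values are the model's current B
#' values, so the refinement is deterministic. Positional parameters are
#' deliberately not refined: the scan operates on fixed toy geometry.
#'
#' @param model An `rx_model`.
#' @param f_obs Observed `rx_reflections`.
#' @param ops An `rx_symops`.
#' @param b_bounds Bounds (A^2) on refined B values.
#' @return List with `model` (refined B values), `scale` (k applied to
#'   `|Fcalc|`), `b_iso` (refined per-atom B), `r_initial`, `r_final`,
#'   `improved` (whether R was reduced).
#' @export
refine_scale_and_b <- function(model, f_obs, ops, b_bounds = c(2, 150)) {
  stopifnot(inherits(model, "rx_model"))
  m <- match_reflections(f_obs, calc_structure_factors(model, ops,
                                                       hkl = f_obs$hkl))
  hkl <- f_obs$hkl[m$ia, , drop = FALSE]
  fo <- f_obs$amplitude[m$ia]
  a <- model$atoms
  n_at <- nrow(a)
  if (length(fo) < n_at + 1) stopf("fewer observations than parameters")
  s2 <- refl_s2(hkl, model$cell)
  # B-independent per-atom symmetry sums and form-factor weights
  xyz <- as.matrix(a[c("x", "y", "z")])
  psi <- matrix(0i, nrow(hkl), n_at)
  for (i in seq_along(ops$R)) {
    pos <- xyz %*% t(ops$R[[i]]) + rep(ops$t[[i]], each = n_at)
    psi <- psi + exp(2i * pi * (hkl %*% t(pos)))
  }
  w <- vapply(seq_len(n_at), function(j) {
    a$occ[j] * form_factor(a$element[j], s2)
  }, numeric(nrow(hkl)))
  fcalc_of <- function(b) {
    psi_w <- psi * (w * exp(-outer(s2 / 4, b)))
    rowSums(psi_w)
  }
  objective <- function(b) {
    fc <- Mod(fcalc_of(b))
    num <- sum(fo * fc)
    sum(fo^2) - num^2 / sum(fc^2)
  }
  gradient <- function(b) {
    fcplx <- fcalc_of(b)
    fc <- Mod(fcplx)
    k <- sum(fo * fc) / sum(fc^2)
    # envelope theorem: differentiate at the optimal profiled scale k
    resid <- k * (k * fc - fo)
    cab <- w * exp(-outer(s2 / 4, b))
    # d|Fc|/dB_a = -(s2/4) Re(conj(Fc) c_a) / |Fc|
    dfc <- -(s2 / 4) * Re(Conj(fcplx) * psi) * cab / pmax(fc, 1e-12)
    2 * as.numeric(crossprod(dfc, resid))
  }
  b0 <- pmin(b_bounds[2], pmax(b_bounds[1], a$b))
  fc0 <- Mod(fcalc_of(b0))
  r_init <- sum(abs(fo - sum(fo * fc0) / sum(fc0^2) * fc0)) / sum(fo)
  opt <- stats::nlminb(b0, objective, gradient = gradient,
                       lower = b_bounds[1], upper = b_bounds[2],
                       control = list(iter.max = 200))
  b_new <- opt$par
  fc <- Mod(fcalc_of(b_new))
  r_fin <- sum(abs(fo - sum(fo * fc) / sum(fc^2) * fc)) / sum(fo)
  if (r_fin > r_init) {           # keep best-so-far, flag the failure
    b_new <- b0
    fc <- fc0
    r_fin <- r_init
  }
  scale <- sum(fo * fc) / sum(fc^2)
  out <- model
  out$atoms$b <- b_new
  list(model = out, scale = scale, b_iso = b_new,
       r_initial = r_init, r_final = r_fin, improved = r_fin <= r_init)
}
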