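#' Tetragonal symmetry consistency of a reflection set
#'
#' Surrogate for the spot-indexing percentage used to monitor the
#' tetragonal-to-orthorhombic phase transition. Reflections indexed on the
#' orthorhombic-compatible lattice are grouped into mmm-equivalence classes
#' `(|h|, |k|, |l|)`; the extra tetragonal 4-fold relates the class
#' `(|h|, |k|, |l|)` to `(|k|, |h|, |l|)`. For each such pair present in the
#' set, the pair is consistent iff `|I1 - I2| / max(I1, I2) <= rel_tol`.
#' The fraction of consistent pairs has the same 50% decision semantics as
#' the indexing percentage. Merging residuals (`Rsym`-style,
#' `sum |I - <I>| / sum I` over equivalence classes) are reported under both
#' symmetry assumptions; the orthorhombic classes are subsets of the
#' tetragonal classes, so `r_sym_ortho <= r_sym_tet` always.
#'
#' @param refl An `rx_reflections` with intensities (or amplitudes, which
#'   are squared).
#' @param rel_tol Relative intensity tolerance for pair consistency.
#' @param delay Optional delay (s) carried into the output.
#' @return An object of class `rx_sym_consistency`: list with `delay`,
#'   `fraction_tetragonal`, `n_pairs`, `r_sym_tet`, `r_sym_ortho`.
#' @export
tetragonal_consistency <- function(refl, rel_tol = 0.15, delay = NA_real_) {
  stopifnot(inherits(refl, "rx_reflections"))
  I <- refl_intensity(refl)
  h <- abs(refl$hkl[, 1]); k <- abs(refl$hkl[, 2]); l <- abs(refl$hkl[, 3])
  ortho_key <- paste(h, k, l)
  # mean intensity per orthorhombic class
  cls <- tapply(I, ortho_key, mean)
  ck <- names(cls)
  parts <- do.call(rbind, strsplit(ck, " "))
  hh <- as.integer(parts[, 1]); kk <- as.integer(parts[, 2])
  ll <- as.integer(parts[, 3])
  partner <- paste(kk, hh, ll)
  cand <- which(hh < kk)               # one representative per unordered pair
  has_partner <- partner[cand] %in% ck
  pairs <- cand[has_partner]
  if (length(pairs) == 0) stopf("no tetragonal-related reflection pairs in set")
  i1 <- as.numeric(cls[ck[pairs]])
  i2 <- as.numeric(cls[partner[pairs]])
  rel <- abs(i1 - i2) / pmax(i1, i2)
  frac <- mean(rel <= rel_tol)

  r_sym <- function(key) {
    mu <- stats::ave(I, key, FUN = mean)
    sum(abs(I - mu)) / sum(I)
  }
  tet_key <- paste(pmin(h, k), pmax(h, k), l)
  structure(list(delay = delay, fraction_tetragonal = frac,
                 n_pairs = length(pairs),
                 r_sym_tet = r_sym(tet_key),
                 r_sym_ortho = r_sym(ortho_key)),
            class = "rx_sym_consistency")
}

#' @export
print.rx_sym_consistency <- function(x, ...) {
  cat(sprintf("Tetragonal consistency: %.3f (%d pairs, Rsym tet %.3f / ortho %.3f)\n",
              x$fraction_tetragonal, x$n_pairs, x$r_sym_tet, x$r_sym_ortho))
  invisible(x)
}

#' Simulate a symmetry-consistency reflection series
#'
#' Generates, for each delay, a reflection set of tetragonal-equivalent
#' pairs whose expected consistency follows a logistic drop centred at
#' `transition_time`: each pair keeps (near-)equal intensities with
#' probability `1 / (1 + exp((t - t0) / width))`, otherwise a fixed two-fold
#' asymmetry is injected (distinct intensities for the 4-fold-related
#' mates). Base intensities are Wilson-like (exponential) with small
#' relative measurement noise.
#'
#' @param transition_time Transition centre t0 (s), `> 0`.
#' @param width Logistic width (s), `> 0`.
#' @param delays Delays (s) at which sets are generated.
#' @param seed Integer RNG seed.
#' @param n_pairs Number of tetragonal-related pairs per set.
#' @param noise Relative intensity noise on every record.
#' @param mean_intensity Mean of the Wilson intensity distribution.
#' @return Named list (one element per delay, names are the delays) of
#'   `rx_reflections` carrying intensities.
#' @export
simulate_symmetry_series <- function(transition_time, width,
                                     delays = default_delays(), seed = 1L,
                                     n_pairs = 200L, noise = 0.02,
                                     mean_intensity = 100) {
  if (transition_time <= 0) stopf("transition_time must be > 0")
  if (width <= 0) stopf("width must be > 0")
  cell <- c(20, 20, 25, 90, 90, 90)
  # distinct (h, k, l) with h < k so each index and its tetragonal mate
  # (k, h, l) are both representable on the orthorhombic lattice
  base <- expand.grid(h = 1:12, k = 1:12, l = 0:12)
  base <- base[base$h < base$k, ]
  if (nrow(base) < n_pairs) stopf("n_pairs too large for the index range")
  with_seed(seed, {
    out <- vector("list", length(delays))
    names(out) <- make.unique(as.character(delays))
    for (di in seq_along(delays)) {
      t <- delays[di]
      p_sym <- 1 / (1 + exp((t - transition_time) / width))
      pick <- base[sample.int(nrow(base), n_pairs), ]
      I0 <- stats::rexp(n_pairs, rate = 1 / mean_intensity)
      sym <- stats::runif(n_pairs) < p_sym
      # asymmetric pairs: one mate doubled, the other halved
      up <- stats::runif(n_pairs) < 0.5
      f1 <- ifelse(sym, 1, ifelse(up, 2, 0.5))
      f2 <- ifelse(sym, 1, ifelse(up, 0.5, 2))
      i1 <- I0 * f1 * (1 + stats::rnorm(n_pairs, 0, noise))
      i2 <- I0 * f2 * (1 + stats::rnorm(n_pairs, 0, noise))
      hkl <- rbind(as.matrix(pick),
                   as.matrix(data.frame(h = pick$k, k = pick$h, l = pick$l)))
      ints <- pmax(c(i1, i2), 1e-6)
      out[[di]] <- reflection_set(
        hkl = hkl, intensity = ints, sigma = noise * ints,
        cell = cell, spacegroup = "P 21 21 21",
        resolution_limit = 1 / sqrt(max(refl_s2(hkl, cell))))
      attr(out[[di]], "delay") <- t
    }
    out
  })
}

#' Locate the phase-transition time from a consistency series
#'
#' Fits an isotonic (monotone decreasing) regression of consistency
#' fraction versus delay, then linearly interpolates the 50% crossing. The
#' reported window is the bracketing pair of measured delays. A series
#' entirely above or below 0.5 yields a no-crossing report rather than an
#' error.
#'
#' @param series A list of `rx_sym_consistency` objects, or a data frame
#'   with columns `delay` and `fraction_tetragonal`.
#' @param level Crossing level (default 0.5).
#' @return An object of class `rx_transition_estimate`: list with `t_cross`
#'   (s, `NA` if no crossing), `window` (length-2 delays bracketing the
#'   crossing), `method`, and the isotonic `fitted` values.
#' @export
detect_transition <- function(series, level = 0.5) {
  d <- if (is.data.frame(series)) series else {
    data.frame(delay = vapply(series, `[[`, numeric(1), "delay"),
               fraction_tetragonal = vapply(series, `[[`, numeric(1),
                                            "fraction_tetragonal"))
  }
  d <- d[order(d$delay), ]
  # isotonic decreasing fit = isotonic increasing fit of the negated series
  fit <- -stats::isoreg(d$delay, -d$fraction_tetragonal)$yf
  below <- which(fit < level)
  above <- which(fit >= level)
  if (length(below) == 0 || length(above) == 0) {
    return(structure(list(t_cross = NA_real_, window = c(NA_real_, NA_real_),
                          method = "no-crossing", fitted = fit,
                          delays = d$delay),
                     class = "rx_transition_estimate"))
  }
  i <- max(above)                     # last fitted value at or above level
  j <- min(below)                     # first below
  t1 <- d$delay[i]; t2 <- d$delay[j]
  f1 <- fit[i]; f2 <- fit[j]
  t_cross <- if (f1 == f2) (t1 + t2) / 2 else
    t1 + (f1 - level) * (t2 - t1) / (f1 - f2)
  structure(list(t_cross = t_cross, window = c(t1, t2),
                 method = "isotonic+interpolation", fitted = fit,
                 delays = d$delay),
            class = "rx_transition_estimate")
}

#' @export
print.rx_transition_estimate <- function(x, ...) {
  if (is.na(x$t_cross)) {
    cat("Phase transition: no 50% crossing in the series\n")
  } else {
    cat(sprintf("Phase transition: 50%% crossing at %.1f s (window %g-%g s)\n",
                x$t_cross, x$window[1], x$window[2]))
  }
  invisible(x)
}

#' Consistency series for a list of reflection sets
#'
#' @param refl_list Named list of `rx_reflections` (names or `"delay"`
#'   attributes give the delays).
#' @param rel_tol Pair tolerance, see [tetragonal_consistency()].
#' @return Data frame, one row per delay.
#' @export
symmetry_consistency_series <- function(refl_list, rel_tol = 0.15) {
  rows <- lapply(seq_along(refl_list), function(i) {
    delay <- attr(refl_list[[i]], "delay") %||%
      as.numeric(names(refl_list)[i])
    sc <- tetragonal_consistency(refl_list[[i]], rel_tol, delay)
    data.frame(delay = sc$delay, fraction_tetragonal = sc$fraction_tetragonal,
               n_pairs = sc$n_pairs, r_sym_tet = sc$r_sym_tet,
               r_sym_ortho = sc$r_sym_ortho)
  })
  do.call(rbind, rows)
}
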