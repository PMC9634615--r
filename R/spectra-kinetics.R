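#' Savitzky-Golay smoothing of a spectrum
#'
#' Least-squares local-polynomial smoothing on the (near-uniform) wavelength
#' grid. Interior points use the central convolution coefficients; the first
#' and last `(window - 1) / 2` points are obtained by evaluating the
#' polynomial fitted to the edge window at those positions, so the output has
#' the same length as the input.
#'
#' @param spec An [spectrum()] object.
#' @param window Odd window width in data points (default 21).
#' @param degree Polynomial degree (default 3); must be `< window`.
#' @return A smoothed `rx_spectrum` on the same grid.
#' @export
savgol_smooth <- function(spec, window = 21L, degree = 3L) {
  stopifnot(inherits(spec, "rx_spectrum"))
  window <- as.integer(window); degree <- as.integer(degree)
  if (window %% 2L == 0L) stopf("window must be odd, got %d", window)
  if (degree >= window) stopf("degree must be smaller than window")
  n <- length(spec$absorbances)
  if (n < window) stopf("spectrum has %d points, fewer than window = %d", n, window)
  dw <- diff(spec$wavelengths)
  if (max(dw) / min(dw) > 1.01) {
    stopf("wavelength grid must be near-uniform for Savitzky-Golay smoothing")
  }
  spectrum(spec$wavelengths,
           savgol_filter(spec$absorbances, window, degree),
           spec$timestamp)
}

# Hat matrix of the local polynomial fit: H = X (X'X)^{-1} X' for offsets
# -m..m. Row m+1 gives the central smoothing coefficients; rows 1..m give the
# edge-window evaluations.
savgol_hat <- function(window, degree) {
  m <- (window - 1L) %/% 2L
  x <- seq.int(-m, m)
  X <- outer(x, 0:degree, `^`)
  X %*% solve(crossprod(X), t(X))
}

savgol_filter <- function(y, window, degree) {
  n <- length(y)
  m <- (window - 1L) %/% 2L
  H <- savgol_hat(window, degree)
  out <- as.numeric(stats::filter(y, rev(H[m + 1L, ]), sides = 2))
  out[seq_len(m)] <- H[seq_len(m), ] %*% y[seq_len(window)]
  out[(n - m + 1L):n] <- H[(m + 2L):window, ] %*% y[(n - window + 1L):n]
  out
}

#' Subtract the common red-region baseline
#'
#' Subtracts the average absorbance over the baseline band (600-850 nm by
#' default) from the whole spectrum, so that all spectra of a series share
#' the same baseline.
#'
#' @param spec An [spectrum()] object.
#' @param band Length-2 numeric, baseline wavelength interval (nm).
#' @return An `rx_spectrum` whose mean over the band is zero.
#' @export
subtract_baseline <- function(spec, band = c(600, 850)) {
  stopifnot(inherits(spec, "rx_spectrum"), length(band) == 2)
  sel <- spec$wavelengths >= band[1] & spec$wavelengths <= band[2]
  if (sum(sel) < 5) {
    stopf("baseline band [%g, %g] nm overlaps fewer than 5 grid points",
          band[1], band[2])
  }
  spectrum(spec$wavelengths, spec$absorbances - mean(spec$absorbances[sel]),
           spec$timestamp)
}

#' Extract a single-wavelength trace from a series
#'
#' Takes the absorbance at the grid point nearest the requested wavelength
#' (no interpolation; equidistant neighbours resolve to the lower
#' wavelength), for every spectrum of the series, sorted by timestamp.
#'
#' @param series An `rx_spectral_series`.
#' @param wavelength Target wavelength (nm), within the grid.
#' @return A data frame with columns `t` (s) and `A` (AU).
#' @export
extract_trace <- function(series, wavelength = 390) {
  stopifnot(inherits(series, "rx_spectral_series"))
  if (length(series$times) == 0) stopf("empty spectral series")
  wl <- series$wavelengths
  if (wavelength < min(wl) || wavelength > max(wl)) {
    stopf("wavelength %g nm outside grid [%g, %g]", wavelength, min(wl), max(wl))
  }
  d <- abs(wl - wavelength)
  # ties toward the lower wavelength: which.min takes the first minimum on an
  # increasing grid
  j <- which.min(d)
  ord <- order(series$times)
  data.frame(t = series$times[ord], A = series$absorbance[ord, j])
}

#' Fit a monoexponential decay to a trace
#'
#' Least-squares fit of `A(t) = offset + amplitude * exp(-t / tau)`. The
#' linear parameters are profiled out (variable projection), and `tau` is
#' found by a log-spaced grid search refined with bounded quasi-Newton
#' iteration, which is deterministic and needs no starting guess. Bounds:
#' `tau` in `[0.1, 1e4]` s.
#'
#' @param trace Data frame with columns `t` and `A` (as from
#'   [extract_trace()]), or a two-column matrix.
#' @return An object of class `rx_trace_fit`: list with `tau`, `amplitude`,
#'   `offset`, `residual_rms`, `n_points`, `converged`.
#' @export
fit_decay <- function(trace) {
  trace <- as.data.frame(trace)
  names(trace)[1:2] <- c("t", "A")
  if (nrow(trace) < 5) stopf("need at least 5 points to fit a decay")
  t <- trace$t; y <- trace$A
  if (diff(range(y)) < 1e-12) {
    return(structure(list(tau = NA_real_, amplitude = NA_real_,
                          offset = mean(y), residual_rms = 0,
                          n_points = length(y), converged = FALSE),
                     class = "rx_trace_fit"))
  }
  fit <- vp_exp_fit(t, y, function(t, tau) cbind(1, exp(-t / tau)),
                    tau_bounds = c(0.1, 1e4))
  structure(list(tau = fit$tau, amplitude = fit$coef[2], offset = fit$coef[1],
                 residual_rms = fit$rms, n_points = length(y),
                 converged = fit$converged),
            class = "rx_trace_fit")
}

# Variable-projection fit of y(t) = X(tau) %*% beta: profile the linear
# coefficients and minimise the profiled RSS over log(tau) by grid search
# plus nlminb polish.
vp_exp_fit <- function(t, y, basis, tau_bounds, n_grid = 200L) {
  rss <- function(log_tau) {
    X <- basis(t, exp(log_tau))
    f <- stats::lm.fit(X, y)
    sum(f$residuals^2)
  }
  grid <- seq(log(tau_bounds[1]), log(tau_bounds[2]), length.out = n_grid)
  vals <- vapply(grid, rss, numeric(1))
  opt <- stats::nlminb(grid[which.min(vals)], rss,
                       lower = log(tau_bounds[1]), upper = log(tau_bounds[2]))
  tau <- exp(opt$par)
  X <- basis(t, tau)
  f <- stats::lm.fit(X, y)
  at_bound <- tau / tau_bounds[1] < 1.001 || tau_bounds[2] / tau < 1.001
  list(tau = tau, coef = unname(stats::coef(f)),
       rms = sqrt(mean(f$residuals^2)),
       converged = opt$convergence == 0 && !at_bound)
}

#' @export
print.rx_trace_fit <- function(x, ...) {
  cat(sprintf("Exponential decay fit: tau = %s s, amplitude = %s AU, offset = %s AU\n",
              format(x$tau, digits = 4), format(x$amplitude, digits = 4),
              format(x$offset, digits = 4)))
  cat(sprintf("  %d points, residual rms %.3g AU, converged: %s\n",
              x$n_points, x$residual_rms, x$converged))
  invisible(x)
}

#' Run the full spectral pipeline on a series
#'
#' Applies, in order: Savitzky-Golay smoothing of each spectrum, common
#' baseline subtraction over the 600-850 nm band, extraction of the trace at
#' the monitoring wavelength, and a monoexponential decay fit.
#'
#' @param series An `rx_spectral_series`.
#' @param wavelength Monitoring wavelength (nm), default 390.
#' @param window,degree Savitzky-Golay settings (defaults 21, 3).
#' @param baseline_band Baseline interval (nm), default `c(600, 850)`.
#' @return An `rx_trace_fit` with the processed trace attached as
#'   attribute `"trace"`.
#' @export
fit_spectral_series <- function(series, wavelength = 390, window = 21L,
                                degree = 3L, baseline_band = c(600, 850)) {
  stopifnot(inherits(series, "rx_spectral_series"))
  proc <- series
  for (i in seq_along(series$times)) {
    s <- savgol_smooth(get_spectrum(series, i), window, degree)
    s <- subtract_baseline(s, baseline_band)
    proc$absorbance[i, ] <- s$absorbances
  }
  trace <- extract_trace(proc, wavelength)
  fit <- fit_decay(trace)
  attr(fit, "trace") <- trace
  fit
}
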