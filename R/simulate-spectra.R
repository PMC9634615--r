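#' Simulate a UV-Vis absorption time series
#'
#' Each spectrum is a constant baseline plus Gaussian bands in wavelength.
#' The light-state band (390 nm) is scaled by `exp(-t/tau)`; the dark-state
#' bands (446 and 475 nm) are scaled by `(1 - c * exp(-t/tau))` where the
#' mixing constant `c` is the photostationary L-state fraction, so the ground
#' state recovers as the photoadduct decays. I.i.d. Gaussian noise is added
#' per wavelength. Timestamps are spaced `1/rate` starting at 0.
#'
#' @param preset An [spectral_preset()] object.
#' @return An object of class `rx_spectral_series`: a list with
#'   `wavelengths` (nm), `times` (s) and `absorbance`
#'   (matrix, one row per time point).
#' @export
simulate_spectral_series <- function(preset) {
  stopifnot(inherits(preset, "rx_spectral_preset"))
  wl <- preset$wavelengths
  # rate * duration spectra at 0, 1/rate, ...: a 2 Hz, 300 s series has 600
  # spectra with timestamps 0 .. 299.5 s
  times <- seq(0, by = 1 / preset$rate,
               length.out = floor(preset$rate * preset$duration))

  gauss <- function(centre, width) exp(-0.5 * ((wl - centre) / width)^2)
  light_shape <- preset$light_band_amplitude *
    gauss(preset$light_band_centre, preset$light_band_width)
  dark_shape <- rep(0, length(wl))
  for (i in seq_along(preset$dark_band_centres)) {
    dark_shape <- dark_shape + preset$dark_band_amplitudes[i] *
      gauss(preset$dark_band_centres[i], preset$dark_band_widths[i])
  }
  decay <- exp(-times / preset$tau)
  a <- outer(decay, light_shape) +
    outer(1 - preset$ps_L_fraction * decay, dark_shape) +
    preset$baseline_offset
  if (preset$noise_sigma > 0) {
    with_seed(preset$seed, {
      a <- a + matrix(stats::rnorm(length(a), 0, preset$noise_sigma),
                      nrow = nrow(a))
    })
  }
  spectral_series(wavelengths = wl, times = times, absorbance = a)
}

#' Construct a spectral series
#'
#' @param wavelengths Shared wavelength grid (nm), strictly increasing.
#' @param times Timestamps (s since end of illumination), one per spectrum.
#' @param absorbance Matrix of absorbances (AU), `length(times)` rows and
#'   `length(wavelengths)` columns.
#' @return An object of class `rx_spectral_series`.
#' @export
spectral_series <- function(wavelengths, times, absorbance) {
  absorbance <- as.matrix(absorbance)
  if (any(diff(wavelengths) <= 0)) stopf("wavelengths must be strictly increasing")
  if (nrow(absorbance) != length(times) ||
      ncol(absorbance) != length(wavelengths)) {
    stopf("absorbance must be a length(times) x length(wavelengths) matrix")
  }
  if (anyNA(absorbance)) stopf("absorbance must not contain missing values")
  structure(list(wavelengths = as.numeric(wavelengths),
                 times = as.numeric(times), absorbance = absorbance),
            class = "rx_spectral_series")
}

#' Construct a single spectrum
#'
#' @param wavelengths Wavelength grid (nm), strictly increasing.
#' @param absorbances Absorbances (AU), same length.
#' @param timestamp Seconds since the end of illumination.
#' @return An object of class `rx_spectrum`.
#' @export
spectrum <- function(wavelengths, absorbances, timestamp = NA_real_) {
  if (length(wavelengths) != length(absorbances)) {
    stopf("wavelengths and absorbances must have equal length")
  }
  if (any(diff(wavelengths) <= 0)) stopf("wavelengths must be strictly increasing")
  if (anyNA(absorbances)) stopf("absorbances must not contain missing values")
  structure(list(wavelengths = as.numeric(wavelengths),
                 absorbances = as.numeric(absorbances),
                 timestamp = timestamp),
            class = "rx_spectrum")
}

#' @export
print.rx_spectral_series <- function(x, ...) {
  cat(sprintf("Spectral series: %d spectra, %d wavelengths (%g-%g nm), t = %g-%g s\n",
              length(x$times), length(x$wavelengths), min(x$wavelengths),
              max(x$wavelengths), min(x$times), max(x$times)))
  invisible(x)
}

#' Extract the i-th spectrum of a series
#'
#' @param series An `rx_spectral_series`.
#' @param i Index.
#' @return An `rx_spectrum`.
#' @export
get_spectrum <- function(series, i) {
  spectrum(series$wavelengths, series$absorbance[i, ], series$times[i])
}

#' Write / read a spectral series as CSV files
#'
#' One two-column CSV (`wavelength_nm, absorbance`) per timestamp plus a
#' `manifest.csv` mapping file names to timestamps.
#'
#' @param series An `rx_spectral_series`.
#' @param dir Output directory (created if needed).
#' @return `write_spectra_csv` returns `dir` invisibly; `read_spectra_csv`
#'   returns an `rx_spectral_series`.
#' @export
write_spectra_csv <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("spectrum_%05d.csv", seq_along(series$times))
  for (i in seq_along(series$times)) {
    utils::write.csv(data.frame(wavelength_nm = series$wavelengths,
                                absorbance = series$absorbance[i, ]),
                     file.path(dir, files[i]), row.names = FALSE)
  }
  utils::write.csv(data.frame(file = files, timestamp_s = series$times),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  first <- utils::read.csv(file.path(dir, man$file[1]))
  a <- matrix(NA_real_, nrow = nrow(man), ncol = nrow(first))
  for (i in seq_len(nrow(man))) {
    a[i, ] <- utils::read.csv(file.path(dir, man$file[i]))$absorbance
  }
  spectral_series(first$wavelength_nm, man$timestamp_s, a)
}
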