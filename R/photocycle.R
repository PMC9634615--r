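#' Photocycle kinetic parameters
#'
#' Ground-truth constants of the slow relaxation branch of the LOV photocycle:
#' the photoadduct conformer C decays exponentially while the two ground-state
#' conformers A (fast rise to a plateau) and B (slow saturating rise) recover.
#' These parameters drive every simulator in the package.
#'
#' @param tau_C Decay time constant (s) of the photoadduct conformation C.
#' @param tau_A Rise time constant (s) of the major ground conformer A.
#' @param tau_B Rise time constant (s) of the minor ground conformer B.
#' @param ps_L_fraction L-state occupancy at the photostationary equilibrium,
#'   in `[0, 1]`. In-crystallo measurements put this between 0.60 and 0.90;
#'   the default 0.65 corresponds to roughly two thirds photoadduct.
#' @param dark_A_fraction Conformer-A share of the recovered ground state at
#'   t -> Inf, in `(0, 1)`.
#' @param delays Measurement delays (s) after the end of illumination.
#' @param noise_sigma_occ Gaussian noise sd added to each conformer occupancy.
#' @param seed Integer RNG seed.
#' @return An object of class `rx_photocycle_params`.
#' @seealso [simulate_occupancy_series()]
#' @export
photocycle_params <- function(tau_C = 39, tau_A = 15, tau_B = 67,
                              ps_L_fraction = 0.65, dark_A_fraction = 0.5,
                              delays = default_delays(),
                              noise_sigma_occ = 0.03, seed = 1L) {
  if (any(c(tau_C, tau_A, tau_B) <= 0)) stopf("all time constants must be > 0")
  if (ps_L_fraction < 0 || ps_L_fraction > 1) {
    stopf("ps_L_fraction must lie in [0, 1]")
  }
  if (dark_A_fraction <= 0 || dark_A_fraction >= 1) {
    stopf("dark_A_fraction must lie in (0, 1)")
  }
  if (length(delays) == 0) stopf("delays must be non-empty")
  if (any(delays <= 0)) stopf("delays must be strictly positive")
  if (noise_sigma_occ < 0) stopf("noise_sigma_occ must be >= 0")
  structure(list(tau_C = tau_C, tau_A = tau_A, tau_B = tau_B,
                 ps_L_fraction = ps_L_fraction,
                 dark_A_fraction = dark_A_fraction,
                 delays = as.numeric(delays),
                 noise_sigma_occ = noise_sigma_occ,
                 seed = as.integer(seed)),
            class = "rx_photocycle_params")
}

#' The printed delay schedule of the relaxation series
#'
#' The 19 delays (s) at which relaxation datasets were recorded after the end
#' of actinic illumination; 62 s appears twice because two independent
#' datasets were recorded at that delay.
#'
#' @return Numeric vector of 19 delays in seconds.
#' @export
default_delays <- function() {
  c(2, 3, 7, 10, 13, 21, 35, 51, 62, 62, 67, 72, 80, 90, 130, 166, 258,
    630, 1620)
}

#' Load the packaged photocycle parameter file
#'
#' @param path Path to a JSON parameter file; defaults to the file shipped
#'   with the package.
#' @return An `rx_photocycle_params` object.
#' @export
load_photocycle_params <- function(path = system.file("extdata",
                                                      "photocycle_default.json",
                                                      package = "relaxmx")) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  photocycle_params(tau_C = p$tau_C, tau_A = p$tau_A, tau_B = p$tau_B,
                    ps_L_fraction = p$ps_L_fraction,
                    dark_A_fraction = p$dark_A_fraction,
                    delays = p$delays,
                    noise_sigma_occ = p$noise_sigma_occ,
                    seed = p$seed)
}

#' @export
print.rx_photocycle_params <- function(x, ...) {
  cat("Photocycle parameters\n")
  cat(sprintf("  tau_C = %g s, tau_A = %g s, tau_B = %g s\n",
              x$tau_C, x$tau_A, x$tau_B))
  cat(sprintf("  PS L-fraction = %g, dark A-fraction = %g\n",
              x$ps_L_fraction, x$dark_A_fraction))
  cat(sprintf("  %d delays: %s s\n", length(x$delays),
              paste(x$delays, collapse = ", ")))
  invisible(x)
}

#' Spectral simulation preset
#'
#' Parameters of a simulated UV-Vis absorption time series following the end
#' of blue-light illumination. The dark state absorbs maximally at 446 and
#' 475 nm; the light state (photoadduct) absorbs maximally at 390 nm and its
#' band relaxes exponentially with time constant `tau`.
#'
#' @param tau Relaxation time constant (s) of the light-state band.
#' @param rate Acquisition rate in Hz (spectra per second).
#' @param duration Total acquisition time (s).
#' @param dark_band_centres Dark-state band centres (nm).
#' @param light_band_centre Light-state band centre (nm).
#' @param dark_band_widths Gaussian sd (nm) of the dark bands.
#' @param light_band_width Gaussian sd (nm) of the light band.
#' @param dark_band_amplitudes Peak absorbances (AU) of the dark bands at
#'   full dark-state occupancy.
#' @param light_band_amplitude Peak absorbance (AU) of the light band at full
#'   photostationary occupancy.
#' @param ps_L_fraction Photostationary L-state fraction: the dark bands start
#'   bleached by this factor and recover as the light band decays.
#' @param baseline_offset Constant absorbance offset (AU).
#' @param noise_sigma Per-wavelength Gaussian noise sd (AU).
#' @param wl_min,wl_max,wl_step Wavelength grid (nm); must cover the
#'   600-850 nm baseline region.
#' @param seed Integer RNG seed.
#' @return An object of class `rx_spectral_preset`.
#' @export
spectral_preset <- function(tau = 40, rate = 2, duration = 300,
                            dark_band_centres = c(446, 475),
                            light_band_centre = 390,
                            dark_band_widths = c(15, 15),
                            light_band_width = 30,
                            dark_band_amplitudes = c(0.50, 0.45),
                            light_band_amplitude = 0.40,
                            ps_L_fraction = 0.65,
                            baseline_offset = 0.05,
                            noise_sigma = 0.005,
                            wl_min = 330, wl_max = 850, wl_step = 1,
                            seed = 1L) {
  if (tau <= 0) stopf("tau must be > 0")
  if (rate <= 0 || duration <= 0) stopf("rate and duration must be > 0")
  if (duration < 3 / rate) stopf("duration too short: fewer than 3 spectra")
  wl <- seq(wl_min, wl_max, by = wl_step)
  centres <- c(dark_band_centres, light_band_centre)
  if (any(centres < wl_min | centres > wl_max)) {
    stopf("band centres must lie within the wavelength grid")
  }
  if (wl_max < 850 || wl_min > 600) {
    stopf("wavelength grid must cover the 600-850 nm baseline region")
  }
  structure(list(tau = tau, rate = rate, duration = duration,
                 dark_band_centres = dark_band_centres,
                 light_band_centre = light_band_centre,
                 dark_band_widths = dark_band_widths,
                 light_band_width = light_band_width,
                 dark_band_amplitudes = dark_band_amplitudes,
                 light_band_amplitude = light_band_amplitude,
                 ps_L_fraction = ps_L_fraction,
                 baseline_offset = baseline_offset,
                 noise_sigma = noise_sigma,
                 wavelengths = wl, seed = as.integer(seed)),
            class = "rx_spectral_preset")
}

#' Packaged ground-truth spectral presets
#'
#' `spectral_preset_solution()` encodes the solution-state relaxation
#' (tau = 6.0 s, 2 Hz, 100 s); `spectral_preset_crystal()` encodes the
#' in-crystallo relaxation (tau = 40 s, 2 Hz, 300 s).
#'
#' @param seed Integer RNG seed.
#' @param noise_sigma Per-wavelength noise sd (AU).
#' @return An `rx_spectral_preset`.
#' @export
spectral_preset_solution <- function(seed = 1L, noise_sigma = 0.005) {
  preset_from_file("spectral_preset_solution.json", seed, noise_sigma)
}

#' @rdname spectral_preset_solution
#' @export
spectral_preset_crystal <- function(seed = 1L, noise_sigma = 0.005) {
  preset_from_file("spectral_preset_crystal.json", seed, noise_sigma)
}

preset_from_file <- function(fname, seed, noise_sigma) {
  path <- system.file("extdata", fname, package = "relaxmx")
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spectral_preset(tau = p$tau, rate = p$rate, duration = p$duration,
                  dark_band_centres = p$dark_band_centres,
                  light_band_centre = p$light_band_centre,
                  dark_band_widths = p$dark_band_widths,
                  light_band_width = p$light_band_width,
                  dark_band_amplitudes = p$dark_band_amplitudes,
                  light_band_amplitude = p$light_band_amplitude,
                  ps_L_fraction = p$ps_L_fraction,
                  baseline_offset = p$baseline_offset,
                  noise_sigma = noise_sigma, seed = seed)
}
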