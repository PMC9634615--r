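#' Simulate a conformer occupancy series
#'
#' Generates per-delay occupancies of the three conformations of the
#' photoactive cysteine: C (photoadduct, present only in the L-state),
#' A (major ground conformer, fast rise to a plateau) and B (minor ground
#' conformer, slow saturating rise). The closed forms are
#' \deqn{occ_C(t) = L_{PS} e^{-t/\tau_C}}
#' \deqn{occ_A(t) = A_\infty - (A_\infty - A_0) e^{-t/\tau_A}}
#' \deqn{occ_B(t) = B_\infty (1 - e^{-t/\tau_B})}
#' with \eqn{A_\infty + B_\infty = 1}, \eqn{A_0 = 1 - L_{PS}} (the pseudo
#' ground state D' holds only conformer A), after which the three occupancies
#' are renormalized to sum exactly to 1 at every delay. Three independent
#' exponentials cannot conserve the total exactly, so the renormalization
#' defines the ground truth the downstream kinetic fits must recover; it is a
#' mild distortion at the packaged defaults. Optional Gaussian noise
#' (truncated to `[0, 1]`) is added per conformer before renormalization.
#'
#' @param params An [photocycle_params()] object.
#' @param crystal_id Identifier carried through to the output.
#' @return An object of class `rx_occseries`: a list with `delays`, `occ_A`,
#'   `occ_B`, `occ_C`, `crystal_id` and `ps_L_occupancy`.
#' @export
simulate_occupancy_series <- function(params, crystal_id = "sim") {
  stopifnot(inherits(params, "rx_photocycle_params"))
  t <- params$delays
  psL <- params$ps_L_fraction
  A_inf <- params$dark_A_fraction
  B_inf <- 1 - A_inf
  A_0 <- 1 - psL

  occ_C <- psL * exp(-t / params$tau_C)
  occ_A <- A_inf - (A_inf - A_0) * exp(-t / params$tau_A)
  occ_B <- B_inf * (1 - exp(-t / params$tau_B))

  if (params$noise_sigma_occ > 0) {
    with_seed(params$seed, {
      occ_C <- pmin(1, pmax(0, occ_C + stats::rnorm(length(t), 0, params$noise_sigma_occ)))
      occ_A <- pmin(1, pmax(0, occ_A + stats::rnorm(length(t), 0, params$noise_sigma_occ)))
      occ_B <- pmin(1, pmax(0, occ_B + stats::rnorm(length(t), 0, params$noise_sigma_occ)))
    })
  }
  total <- occ_A + occ_B + occ_C
  occupancy_series(delays = t, occ_A = occ_A / total, occ_B = occ_B / total,
                   occ_C = occ_C / total, crystal_id = crystal_id,
                   ps_L_occupancy = psL)
}

#' Construct a conformer occupancy series
#'
#' @param delays Delays (s).
#' @param occ_A,occ_B,occ_C Occupancies in `[0, 1]`, one per delay. A small
#'   tolerance above 1 is allowed for normalized series.
#' @param crystal_id Identifier of the crystal the series was recorded on.
#' @param ps_L_occupancy L-state occupancy of that crystal's photostationary
#'   equilibrium.
#' @return An object of class `rx_occseries`.
#' @export
occupancy_series <- function(delays, occ_A, occ_B, occ_C,
                             crystal_id = "xtal", ps_L_occupancy = NA_real_) {
  n <- length(delays)
  if (length(occ_A) != n || length(occ_B) != n || length(occ_C) != n) {
    stopf("delays and occupancies must have equal length")
  }
  occ <- c(occ_A, occ_B, occ_C)
  if (any(occ < -1e-9 | occ > 1.5 + 1e-9)) {
    stopf("occupancies must lie in [0, 1.5]")
  }
  structure(list(delays = as.numeric(delays), occ_A = as.numeric(occ_A),
                 occ_B = as.numeric(occ_B), occ_C = as.numeric(occ_C),
                 crystal_id = crystal_id,
                 ps_L_occupancy = ps_L_occupancy),
            class = "rx_occseries")
}

#' @export
print.rx_occseries <- function(x, ...) {
  cat(sprintf("Conformer occupancy series '%s' (%d delays, PS L = %s)\n",
              x$crystal_id, length(x$delays), format(x$ps_L_occupancy)))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' @export
as.data.frame.rx_occseries <- function(x, ...) {
  data.frame(crystal_id = x$crystal_id, delay_s = x$delays,
             occ_A = x$occ_A, occ_B = x$occ_B, occ_C = x$occ_C,
             ps_L = x$ps_L_occupancy)
}

#' Read / write occupancy series as CSV
#'
#' The CSV dialect has columns `crystal_id, delay_s, occ_A, occ_B, occ_C,
#' ps_L`, one row per delay.
#'
#' @param series An `rx_occseries`.
#' @param path File path.
#' @return `write_occupancy_csv` returns `path` invisibly;
#'   `read_occupancy_csv` returns an `rx_occseries`.
#' @export
write_occupancy_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occupancy_csv
#' @export
read_occupancy_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  occupancy_series(delays = d$delay_s, occ_A = d$occ_A, occ_B = d$occ_B,
                   occ_C = d$occ_C, crystal_id = d$crystal_id[1],
                   ps_L_occupancy = d$ps_L[1])
}
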