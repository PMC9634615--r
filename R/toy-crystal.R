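#' The packaged toy crystal
#'
#' A synthetic ~20-atom two-conformer site in a 20 x 20 x 25 Angstrom
#' orthorhombic cell (P212121), standing in for the photoactive
#' cysteine/flavin site: a short backbone fragment and a four-atom
#' chromophore stand-in are common atoms; the photoadduct conformation (tag
#' `C`, cysteine side chain swung towards the chromophore) and the major
#' dark conformation (tag `A`, swung away) form one alternate group whose
#' occupancies sum to 1. Three optional feature groups -- the minor dark
#' conformation of the cysteine (tag `B`), a C-terminus stand-in and a
#' tryptophan-flip stand-in -- are available for feature detection.
#'
#' @param occ_L Occupancy of the light-state conformer C; the dark conformer
#'   A gets `1 - occ_L`.
#' @param b_iso Uniform starting isotropic B-factor (A^2).
#' @return An `rx_model` (without the optional feature groups).
#' @export
toy_crystal <- function(occ_L = 0.65, b_iso = 20) {
  if (occ_L < 0 || occ_L > 1) stopf("occ_L must lie in [0, 1]")
  at <- toy_site_atoms()
  at <- at[attr(at, "group") %in% c("common", "alt") &
             at$altloc %in% c("", "A", "C"), , drop = FALSE]
  at$occ[at$altloc == "C"] <- occ_L
  at$occ[at$altloc == "A"] <- 1 - occ_L
  at$b <- b_iso
  atomic_model(at, cell = c(20, 20, 25, 90, 90, 90),
               spacegroup = "P 21 21 21")
}

# Hand-placed cartesian coordinates (Angstrom) of the toy site, compact
# around (5, 3, 2.5) so symmetry copies do not collide.
toy_site_atoms <- function() {
  d <- rbind(
    # backbone fragment (common)
    c("N", "N",   "", 4.00, 2.00, 2.00),
    c("C", "CA",  "", 5.40, 2.40, 2.20),
    c("C", "C",   "", 6.30, 1.20, 2.50),
    c("O", "O",   "", 5.90, 0.05, 2.40),
    c("C", "CB",  "", 5.95, 3.40, 1.15),
    # chromophore stand-in (common)
    c("N", "N1",  "", 8.50, 4.50, 3.60),
    c("C", "C2",  "", 9.60, 5.20, 3.20),
    c("C", "C4",  "", 9.80, 3.60, 4.60),
    c("O", "O2",  "", 10.70, 4.90, 2.40),
    # photoadduct conformation C: sulfur bonded towards the chromophore
    c("S", "SG",  "C", 7.40, 4.10, 0.60),
    c("C", "CD1", "C", 8.30, 5.30, 1.40),
    c("C", "CD2", "C", 8.90, 2.90, 0.90),
    # dark conformation A: side chain swung away
    c("S", "SG",  "A", 5.10, 4.90, 0.20),
    c("C", "CD1", "A", 3.80, 5.80, 0.80),
    c("C", "CD2", "A", 4.60, 5.50, 1.90),
    # optional minor dark conformation B of the cysteine
    c("S", "SG",  "B", 6.40, 3.10, 3.90),
    # optional C-terminus stand-in
    c("C", "CT1", "", 2.20, 6.50, 3.40),
    c("C", "CT2", "", 1.10, 7.40, 3.00),
    c("O", "OT",  "", 0.30, 7.90, 3.90),
    # optional tryptophan-flip stand-in
    c("C", "CW1", "", 11.80, 2.20, 4.20),
    c("C", "CW2", "", 12.70, 1.40, 3.40))
  group <- c(rep("common", 9), rep("alt", 6), "featB",
             rep("featCT", 3), rep("featW", 2))
  cell <- c(20, 20, 25)
  out <- data.frame(element = d[, 1], name = d[, 2], altloc = d[, 3],
                    chain = "A",
                    resno = c(rep(1L, 5), rep(2L, 4), rep(1L, 7),
                              rep(3L, 3), rep(4L, 2)),
                    resname = c(rep("CYS", 5), rep("FMN", 4), rep("CYS", 7),
                                rep("CTR", 3), rep("TRP", 2)),
                    x = as.numeric(d[, 4]) / cell[1],
                    y = as.numeric(d[, 5]) / cell[2],
                    z = as.numeric(d[, 6]) / cell[3],
                    occ = 1, b = 20, stringsAsFactors = FALSE)
  attr(out, "group") <- group
  out
}

#' Optional feature groups of the toy crystal
#'
#' Returns the named list of optional atom groups used by
#' [detect_features()]: `C426_B` (minor cysteine conformation), `cterm`
#' (C-terminus stand-in) and `W_flip` (tryptophan-flip stand-in), each as an
#' atom data frame with the given trial occupancy.
#'
#' @param occ Trial occupancy given to each feature's atoms.
#' @return Named list of atom data frames.
#' @export
toy_feature_groups <- function(occ = 0.5) {
  at <- toy_site_atoms()
  g <- attr(at, "group")
  mk <- function(sel) {
    a <- at[sel, , drop = FALSE]
    a$occ <- occ
    rownames(a) <- NULL
    a
  }
  list(C426_B = mk(g == "featB"), cterm = mk(g == "featCT"),
       W_flip = mk(g == "featW"))
}

#' Endmember models of the toy crystal
#'
#' The light endmember carries only conformer C (occupancy 1); the dark
#' endmember only conformer A. Both share the common atoms.
#'
#' @param b_iso Uniform isotropic B (A^2).
#' @return List with elements `light` and `dark`, each an `rx_model`.
#' @export
toy_endmembers <- function(b_iso = 20) {
  strip <- function(m, tag) {
    keep <- m$atoms$altloc %in% c("", tag)
    atomic_model(m$atoms[keep, , drop = FALSE], m$cell, m$spacegroup)
  }
  list(light = strip(toy_crystal(occ_L = 1, b_iso = b_iso), "C"),
       dark = strip(toy_crystal(occ_L = 0, b_iso = b_iso), "A"))
}

#' Simulate observed reflection amplitudes for an occupancy mixture
#'
#' Computes `|F|` by direct summation on the occupancy-weighted toy model,
#' then multiplies each amplitude by `(1 + eps)` with
#' `eps ~ N(0, noise_sigma^2)`; sigmas are set to `noise_sigma * |F|`.
#' Phases are dropped: this is an amplitude-only observation.
#'
#' @param crystal An `rx_model` whose alternate-group atoms carry conformer
#'   tags (see [toy_crystal()]).
#' @param occupancies Named numeric, occupancy per conformer tag (e.g.
#'   `c(C = 0.65, A = 0.35)`); must lie in `[0, 1]` and sum to 1 over the
#'   alternate group.
#' @param noise_sigma Relative amplitude noise (0 for noiseless).
#' @param seed Integer RNG seed.
#' @param dmin Resolution limit (Angstrom).
#' @return An `rx_reflections` with amplitudes and sigmas, complete to
#'   `dmin`.
#' @export
simulate_reflections <- function(crystal, occupancies, noise_sigma = 0.03,
                                 seed = 1L, dmin = 2.0) {
  stopifnot(inherits(crystal, "rx_model"))
  if (any(occupancies < 0 | occupancies > 1)) {
    stopf("occupancies must lie in [0, 1]")
  }
  tags <- unique(crystal$atoms$altloc[crystal$atoms$altloc != ""])
  named <- intersect(names(occupancies), tags)
  if (length(named) && abs(sum(occupancies[named]) - 1) > 1e-9) {
    stopf("occupancies must sum to 1 within the alternate group")
  }
  m <- crystal
  for (tag in named) {
    m$atoms$occ[m$atoms$altloc == tag] <- occupancies[[tag]]
  }
  ops <- spacegroup_ops(m$spacegroup)
  fc <- calc_structure_factors(m, ops, dmin = dmin)
  amp <- fc$amplitude
  if (noise_sigma > 0) {
    with_seed(seed, {
      amp <- amp * (1 + stats::rnorm(length(amp), 0, noise_sigma))
    })
    amp <- pmax(amp, 0)
  }
  reflection_set(hkl = fc$hkl, amplitude = amp,
                 sigma = noise_sigma * fc$amplitude,
                 cell = m$cell, spacegroup = m$spacegroup,
                 resolution_limit = dmin)
}
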