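#' Build the occupancy scan grid
#'
#' Candidate (light-state, dark-state) occupancy pairs from 0/100% to 100/0%
#' in the given step; step 5% yields 21 candidate models.
#'
#' @param step Grid step in percent; must divide 100.
#' @return An object of class `rx_scan_grid`: data frame with columns
#'   `occ_L` and `occ_D` (percent), pairs summing to 100.
#' @export
build_grid <- function(step = 5) {
  if (step <= 0 || 100 %% step != 0) stopf("step must divide 100")
  occ_L <- seq(0, 100, by = step)
  structure(data.frame(occ_L = occ_L, occ_D = 100 - occ_L),
            class = c("rx_scan_grid", "data.frame"))
}

# Grid points (fractional coordinates) of the map grid lying within
# `radius` Angstrom of any alternate-conformer atom, with minimum-image
# wrapping. This is the integration mask of the difference-map score.
alt_conformer_mask <- function(model, dmin = 2.0, radius = 2.0,
                               atoms = NULL) {
  alt <- atoms %||% model$atoms[model$atoms$altloc != "", , drop = FALSE]
  if (nrow(alt) == 0) stopf("model has no alternate-conformer atoms: empty mask")
  grid <- map_grid_dim(model$cell, dmin)
  pts <- as.matrix(expand.grid(x = (seq_len(grid[1]) - 1) / grid[1],
                               y = (seq_len(grid[2]) - 1) / grid[2],
                               z = (seq_len(grid[3]) - 1) / grid[3]))
  M <- frac_to_cart_matrix(model$cell)
  keep <- rep(FALSE, nrow(pts))
  for (j in seq_len(nrow(alt))) {
    d <- pts - rep(as.numeric(alt[j, c("x", "y", "z")]), each = nrow(pts))
    d <- d - round(d)                      # minimum image in fractions
    cart <- d %*% t(M)
    keep <- keep | rowSums(cart^2) <= radius^2
  }
  pts[keep, , drop = FALSE]
}

#' Difference-map residual score of a candidate model
#'
#' Quantitative replacement for visual difference-map inspection: the
#' Fobs - Fcalc synthesis is evaluated at map grid points within 2 Angstrom
#' of any alternate-conformer atom, and the score is the mean over those
#' points of `max(0, |rho| - sigma_level * sigma_map)`, i.e. the
#' above-threshold residual density per masked grid point (normalisation by
#' mask size keeps scores comparable across grids). Lower is better; a model
#' that explains the data at the inspection level scores 0.
#'
#' @param model A refined `rx_model` (see [refine_scale_and_b()]).
#' @param f_obs Observed `rx_reflections`.
#' @param ops An `rx_symops`.
#' @param sigma_level Threshold in map-sigma units (default 2.0, the
#'   inspection level).
#' @param mask_radius Mask radius (Angstrom) around alternate-conformer
#'   atoms.
#' @param mask_atoms Optional atom data frame defining the mask centres
#'   (defaults to the model's alternate-conformer atoms).
#' @return Non-negative residual score.
#' @export
score_model <- function(model, f_obs, ops, sigma_level = 2.0,
                        mask_radius = 2.0, mask_atoms = NULL) {
  f_calc <- calc_structure_factors(model, ops, hkl = f_obs$hkl)
  co <- difference_coefficients(f_obs, f_calc)
  sig <- difference_map_sigma(co)
  mask <- alt_conformer_mask(model, dmin = f_obs$resolution_limit %||% 2.0,
                             radius = mask_radius, atoms = mask_atoms)
  rho <- density_at_points(co, mask)
  mean(pmax(0, abs(rho) - sigma_level * sig))
}

#' Run the two-state occupancy scan
#'
#' For every grid occupancy, builds the mixed two-conformer model from the
#' endmembers, refines overall scale and per-atom B-factors against the
#' observations, and computes the difference-map residual score. The best
#' occupancy is the argmin of the score; exact ties resolve toward the lower
#' light-state occupancy.
#'
#' @param endmembers List with `light` and `dark` `rx_model`s sharing common
#'   atoms and differing only in their alternate groups.
#' @param f_obs Observed `rx_reflections`.
#' @param ops An `rx_symops`; defaults to the endmembers' space group.
#' @param grid An [build_grid()] grid.
#' @param sigma_level Score threshold in sigma units.
#' @param refine Logical; refine scale/B at each grid point (default TRUE).
#' @return An object of class `rx_scan_result`: list with `best_occ_L`
#'   (percent), `score_curve`, `refined_r`, `grid`, `failed` (grid points
#'   whose refinement failed, excluded from the argmin).
#' @export
run_scan <- function(endmembers, f_obs, ops = NULL, grid = build_grid(5),
                     sigma_level = 2.0, refine = TRUE) {
  light <- endmembers$light
  dark <- endmembers$dark
  stopifnot(inherits(light, "rx_model"), inherits(dark, "rx_model"))
  if (is.null(ops)) ops <- spacegroup_ops(light$spacegroup)
  n <- nrow(grid)
  score <- rep(NA_real_, n)
  rfac <- rep(NA_real_, n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    m <- mix_endmembers(light, dark, grid$occ_L[i] / 100)
    res <- tryCatch({
      if (refine) {
        ref <- refine_scale_and_b(m, f_obs, ops)
        m <- ref$model
        rfac[i] <- ref$r_final
      } else {
        rfac[i] <- r_factor(f_obs, calc_structure_factors(m, ops,
                                                          hkl = f_obs$hkl))
      }
      score[i] <- score_model(m, f_obs, ops, sigma_level)
      TRUE
    }, error = function(e) FALSE)
    if (!isTRUE(res)) failed[i] <- TRUE
  }
  ok <- which(!failed)
  if (length(ok) == 0) stopf("refinement failed at every grid point")
  best <- ok[which.min(score[ok])]   # first minimum = lower occ_L on ties
  structure(list(best_occ_L = grid$occ_L[best], score_curve = score,
                 refined_r = rfac, grid = grid, failed = failed),
            class = "rx_scan_result")
}

# Mixed-occupancy model: common atoms (occupancy 1) + light alternate atoms
# at occ_L + dark alternate atoms at 1 - occ_L.
mix_endmembers <- function(light, dark, occ_L) {
  common <- light$atoms[light$atoms$altloc == "", , drop = FALSE]
  la <- light$atoms[light$atoms$altloc != "", , drop = FALSE]
  da <- dark$atoms[dark$atoms$altloc != "", , drop = FALSE]
  la$occ <- occ_L
  da$occ <- 1 - occ_L
  atomic_model(rbind(common, la, da), light$cell, light$spacegroup)
}

#' @export
print.rx_scan_result <- function(x, ...) {
  cat(sprintf("Occupancy scan: best occ_L = %g%% over %d grid points\n",
              x$best_occ_L, nrow(x$grid)))
  if (any(x$failed)) {
    cat(sprintf("  %d grid points failed refinement and were excluded\n",
                sum(x$failed)))
  }
  invisible(x)
}

#' Greedy detection of optional structural features
#'
#' Evaluates candidate atom groups (e.g. a minor cysteine conformation, a
#' C-terminus conformer, a tryptophan flip) in a fixed, documented order.
#' Each feature is added to the current model, the model refined and scored,
#' and the feature kept iff it lowers the score by more than
#' `improvement_threshold` relative to the current score.
#'
#' @param base An `rx_model`.
#' @param features Named list of atom data frames (disjoint groups) with
#'   trial occupancies, evaluated in list order.
#' @param f_obs Observed `rx_reflections`.
#' @param ops An `rx_symops`.
#' @param improvement_threshold Relative score improvement required to keep
#'   a feature.
#' @param refine Logical; refine each candidate model.
#' @return Named list, one element per feature: list with `included`
#'   (logical), `score_without`, `score_with`, `improvement` (relative).
#' @export
detect_features <- function(base, features, f_obs, ops,
                            improvement_threshold = 0.1, refine = TRUE) {
  stopifnot(inherits(base, "rx_model"), is.list(features))
  keys <- lapply(features, function(f) paste(f$name, f$altloc, f$resno))
  if (anyDuplicated(unlist(keys))) stopf("features must be disjoint atom groups")
  # a fixed mask (alternate atoms plus every candidate feature region) keeps
  # the scores of successive greedy steps comparable
  mask_atoms <- rbind(base$atoms[base$atoms$altloc != "", , drop = FALSE],
                      do.call(rbind, unname(features)))
  eval_score <- function(m) {
    if (refine) m <- refine_scale_and_b(m, f_obs, ops)$model
    score_model(m, f_obs, ops, mask_atoms = mask_atoms)
  }
  current <- base
  s0 <- eval_score(current)
  out <- list()
  for (nm in names(features)) {
    cand <- atomic_model(rbind(current$atoms, features[[nm]]),
                         current$cell, current$spacegroup)
    s1 <- eval_score(cand)
    improvement <- (s0 - s1) / max(s0, .Machine$double.eps)
    included <- is.finite(improvement) && improvement > improvement_threshold
    out[[nm]] <- list(included = included, score_without = s0,
                      score_with = s1, improvement = improvement)
    if (included) {
      current <- cand
      s0 <- s1
    }
  }
  out
}
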