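#' Normalized B-factor of a residue selection
#'
#' Mean isotropic B over the selected atoms divided by the mean B over the
#' whole structure: values above 1 flag selections more disordered than
#' average. Means are unweighted by occupancy by default; an
#' occupancy-weighted mode is available.
#'
#' @param model An `rx_model`.
#' @param chain Chain identifier.
#' @param residues Integer vector of residue numbers (e.g. `493:495`).
#' @param occupancy_weighted Weight atoms by occupancy in both means.
#' @param protein_only Restrict the whole-structure mean to standard protein
#'   residues (exclude ligands/waters); default uses all atoms.
#' @return An object of class `rx_order_metric`: list with
#'   `mean_b_selection`, `mean_b_all`, `normalized_b`, `n_selected`,
#'   `selection`.
#' @export
normalized_b <- function(model, chain, residues,
                         occupancy_weighted = FALSE, protein_only = FALSE) {
  stopifnot(inherits(model, "rx_model"))
  a <- model$atoms
  sel <- a$chain == chain & a$resno %in% residues
  if (!any(sel)) stopf("empty selection: chain %s residues %s", chain,
                       paste(range(residues), collapse = "-"))
  all_idx <- if (protein_only) {
    !(a$resname %in% c("HOH", "WAT", "FMN", "LIG"))
  } else rep(TRUE, nrow(a))
  wmean <- function(idx) {
    w <- if (occupancy_weighted) a$occ[idx] else rep(1, sum(idx))
    sum(a$b[idx] * w) / sum(w)
  }
  mb_sel <- wmean(sel)
  mb_all <- wmean(all_idx)
  if (mb_all <= 0) stopf("whole-structure mean B must be > 0")
  structure(list(mean_b_selection = mb_sel, mean_b_all = mb_all,
                 normalized_b = mb_sel / mb_all, n_selected = sum(sel),
                 selection = sprintf("%s:%s", chain,
                                     paste(range(residues), collapse = "-"))),
            class = "rx_order_metric")
}

#' @export
print.rx_order_metric <- function(x, ...) {
  cat(sprintf("Normalized B of %s: %.3f (%.2f / %.2f A^2, %d atoms)\n",
              x$selection, x$normalized_b, x$mean_b_selection,
              x$mean_b_all, x$n_selected))
  invisible(x)
}

# Kabsch least-squares rotation superposing moving onto fixed (both n x 3,
# already centred). Returns the 3 x 3 rotation matrix.
kabsch_rotation <- function(fixed, moving) {
  s <- svd(crossprod(moving, fixed))     # M'F = U S V'
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)    # maximises tr(R' M' F)
}

#' Interchain translation after anchor-chain superposition
#'
#' Superposes `dimer2` onto `dimer1` using the C-alpha atoms of the anchor
#' chain only (Kabsch least squares), then reports the displacement of the
#' centroid of the second chain. This measures the sliding of one monomer
#' relative to the other between two dimer models, independent of any global
#' rigid motion of either input.
#'
#' @param dimer1,dimer2 `rx_model`s containing the anchor chain and one
#'   other chain with matching residue numbering.
#' @param anchor_chain Chain identifier used for the superposition.
#' @return List with `displacement` (Angstrom vector along the cell axes),
#'   `magnitude` (Angstrom), `anchor_rmsd` (post-fit RMSD of the anchor
#'   C-alphas) and `moved_chain`.
#' @export
interchain_shift <- function(dimer1, dimer2, anchor_chain = "A") {
  stopifnot(inherits(dimer1, "rx_model"), inherits(dimer2, "rx_model"))
  ca <- function(m, ch) {
    a <- m$atoms[m$atoms$chain == ch & m$atoms$name == "CA", , drop = FALSE]
    a[order(a$resno), , drop = FALSE]
  }
  a1 <- ca(dimer1, anchor_chain)
  a2 <- ca(dimer2, anchor_chain)
  shared <- intersect(a1$resno, a2$resno)
  if (length(shared) < 3) stopf("fewer than 3 matching C-alpha atoms in anchor chain")
  a1 <- a1[a1$resno %in% shared, ]
  a2 <- a2[a2$resno %in% shared, ]
  x1 <- frac_to_cart(a1[c("x", "y", "z")], dimer1$cell)
  x2 <- frac_to_cart(a2[c("x", "y", "z")], dimer2$cell)
  c1 <- colMeans(x1); c2 <- colMeans(x2)
  R <- kabsch_rotation(sweep(x1, 2, c1), sweep(x2, 2, c2))
  fit2 <- sweep(sweep(x2, 2, c2) %*% R, 2, c1, `+`)
  rmsd <- sqrt(mean(rowSums((fit2 - x1)^2)))

  other1 <- setdiff(unique(dimer1$atoms$chain), anchor_chain)[1]
  other2 <- setdiff(unique(dimer2$atoms$chain), anchor_chain)[1]
  if (is.na(other1) || is.na(other2)) stopf("both models need a second chain")
  b1 <- dimer1$atoms[dimer1$atoms$chain == other1, , drop = FALSE]
  b2 <- dimer2$atoms[dimer2$atoms$chain == other2, , drop = FALSE]
  y1 <- frac_to_cart(b1[c("x", "y", "z")], dimer1$cell)
  y2 <- frac_to_cart(b2[c("x", "y", "z")], dimer2$cell)
  y2fit <- sweep(sweep(y2, 2, c2) %*% R, 2, c1, `+`)
  disp <- colMeans(y2fit) - colMeans(y1)
  list(displacement = stats::setNames(disp, c("a", "b", "c")),
       magnitude = sqrt(sum(disp^2)), anchor_rmsd = rmsd,
       moved_chain = other1)
}

#' Tabulate order metrics across a model series
#'
#' Convenience wrapper producing one row per model per selection, for
#' plotting C-terminus ordering or side-chain reorientation curves.
#'
#' @param models Named list of `rx_model`s (names used as time labels).
#' @param selections List of lists with fields `chain` and `residues`.
#' @param ... Passed to [normalized_b()].
#' @return Data frame with columns `model`, `selection`, `normalized_b`,
#'   `mean_b_selection`, `mean_b_all`, `n_selected`.
#' @export
order_metric_table <- function(models, selections, ...) {
  rows <- list()
  for (mn in names(models)) {
    for (s in selections) {
      m <- normalized_b(models[[mn]], s$chain, s$residues, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        model = mn, selection = m$selection,
        normalized_b = m$normalized_b,
        mean_b_selection = m$mean_b_selection,
        mean_b_all = m$mean_b_all, n_selected = m$n_selected)
    }
  }
  do.call(rbind, rows)
}
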