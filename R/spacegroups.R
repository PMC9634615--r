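#' Space-group symmetry operators
#'
#' Operator sets for the three groups the package needs: triclinic P1, the
#' orthorhombic group P212121 (4 general positions, three perpendicular
#' 2-fold screw axes) and the tetragonal group P43212 (8 general positions,
#' 4-fold screw). The tetragonal-to-orthorhombic phase transition removes the
#' 4-fold screw, halving the operator count. Operators are hard-coded from
#' the standard general positions and validated by closure tests.
#'
#' @param label One of `"P 1"`, `"P 21 21 21"`, `"P 43 21 2"` (spaces
#'   optional).
#' @return An object of class `rx_symops`: list with `label`, `R` (list of
#'   3x3 rotation matrices) and `t` (list of translation triplets), acting on
#'   fractional coordinates as `R %*% x + t`.
#' @export
spacegroup_ops <- function(label) {
  key <- toupper(gsub("[ _]", "", label))
  op <- function(rot, tr) list(R = matrix(rot, 3, 3, byrow = TRUE), t = tr)
  ops <- switch(key,
    "P1" = list(op(c(1,0,0, 0,1,0, 0,0,1), c(0, 0, 0))),
    "P212121" = list(
      op(c( 1,0,0,  0, 1,0,  0,0, 1), c(0,   0,   0)),
      op(c(-1,0,0,  0,-1,0,  0,0, 1), c(1/2, 0,   1/2)),
      op(c(-1,0,0,  0, 1,0,  0,0,-1), c(0,   1/2, 1/2)),
      op(c( 1,0,0,  0,-1,0,  0,0,-1), c(1/2, 1/2, 0))),
    "P43212" = list(
      op(c( 1,0,0,  0, 1,0,  0,0, 1), c(0,   0,   0)),
      op(c(-1,0,0,  0,-1,0,  0,0, 1), c(0,   0,   1/2)),
      op(c( 0,-1,0, 1, 0,0,  0,0, 1), c(1/2, 1/2, 3/4)),
      op(c( 0,1,0, -1, 0,0,  0,0, 1), c(1/2, 1/2, 1/4)),
      op(c(-1,0,0,  0, 1,0,  0,0,-1), c(1/2, 1/2, 3/4)),
      op(c( 1,0,0,  0,-1,0,  0,0,-1), c(1/2, 1/2, 1/4)),
      op(c( 0,1,0,  1, 0,0,  0,0,-1), c(0,   0,   0)),
      op(c( 0,-1,0,-1, 0,0,  0,0,-1), c(0,   0,   1/2))),
    stopf("unknown space group label '%s'", label))
  structure(list(label = label,
                 R = lapply(ops, `[[`, "R"),
                 t = lapply(ops, `[[`, "t")),
            class = "rx_symops")
}

#' @export
print.rx_symops <- function(x, ...) {
  cat(sprintf("Space group %s: %d operators\n", x$label, length(x$R)))
  invisible(x)
}

#' Expand a model to all symmetry copies
#'
#' Applies every operator of the group to every atom and wraps the resulting
#' coordinates into the unit cell.
#'
#' @param model An `rx_model`.
#' @param ops An `rx_symops`.
#' @return An `rx_model` containing `n_ops * n_atoms` atoms.
#' @export
expand_symmetry <- function(model, ops) {
  stopifnot(inherits(model, "rx_model"), inherits(ops, "rx_symops"))
  xyz <- as.matrix(model$atoms[c("x", "y", "z")])
  pieces <- lapply(seq_along(ops$R), function(i) {
    a <- model$atoms
    new <- xyz %*% t(ops$R[[i]]) + rep(ops$t[[i]], each = nrow(xyz))
    a[c("x", "y", "z")] <- new - floor(new)
    a
  })
  atomic_model(do.call(rbind, pieces), model$cell, model$spacegroup)
}
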