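# Shared fixtures, built in code at test time.

ops_p1 <- function() relaxmx:::spacegroup_ops("P 1")
ops_ortho <- function() relaxmx:::spacegroup_ops("P 21 21 21")
ops_tetra <- function() relaxmx:::spacegroup_ops("P 43 21 2")

# A tiny P1 model with n atoms at fixed pseudo-random positions.
tiny_model <- function(n = 3, cell = c(20, 20, 25, 90, 90, 90),
                       elements = c("C", "N", "O", "S", "P"),
                       b = 20, seed = 42) {
  set.seed(seed)
  atoms <- data.frame(element = rep_len(elements, n),
                      name = sprintf("X%d", seq_len(n)), altloc = "",
                      chain = "A", resno = seq_len(n), resname = "GLY",
                      x = runif(n), y = runif(n), z = runif(n),
                      occ = 1, b = b, stringsAsFactors = FALSE)
  atomic_model(atoms, cell, "P 1")
}

# Independent brute-force structure-factor oracle: plain double loop over
# operators and atoms, sharing no code with the package implementation.
brute_force_sf <- function(model, ops, hkl) {
  cellm <- model$cell
  # reciprocal metric from first principles (orthogonal cells only)
  stopifnot(all(cellm[4:6] == 90))
  vapply(seq_len(nrow(hkl)), function(i) {
    h <- hkl[i, ]
    s2 <- sum((h / cellm[1:3])^2)
    f <- 0 + 0i
    for (k in seq_along(ops$R)) {
      for (j in seq_len(nrow(model$atoms))) {
        a <- model$atoms[j, ]
        ff <- relaxmx:::FORM_FACTORS[[a$element]]
        fj <- ff[["a"]] * exp(-ff[["b"]] * s2 / 4) + ff[["c"]]
        pos <- ops$R[[k]] %*% c(a$x, a$y, a$z) + ops$t[[k]]
        f <- f + a$occ * fj * exp(-a$b * s2 / 4) *
          exp(2i * pi * sum(h * pos))
      }
    }
    f
  }, complex(1))
}

sf_as_complex <- function(refl) {
  refl$amplitude * exp(1i * refl$phase * pi / 180)
}

# Build a two-chain helical dimer for superposition tests.
dimer_model <- function(cell = c(60, 60, 60, 90, 90, 90)) {
  mk_chain <- function(chain, origin) {
    n <- 8
    th <- seq(0, 2.2, length.out = n)
    data.frame(element = "C", name = "CA", altloc = "", chain = chain,
               resno = seq_len(n), resname = "ALA",
               x = (origin[1] + 5 * cos(th)) / cell[1],
               y = (origin[2] + 5 * sin(th)) / cell[2],
               z = (origin[3] + 1.5 * th) / cell[3],
               occ = 1, b = 20, stringsAsFactors = FALSE)
  }
  atomic_model(rbind(mk_chain("A", c(15, 15, 10)),
                     mk_chain("B", c(30, 22, 12))), cell, "P 1")
}

# Apply a global rigid motion (rotation about z by angle, then translation
# in Angstrom) to a model.
rigid_move <- function(model, angle = 0, shift = c(0, 0, 0), chains = NULL) {
  Rz <- matrix(c(cos(angle), -sin(angle), 0,
                 sin(angle), cos(angle), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- relaxmx:::frac_to_cart(model$atoms[c("x", "y", "z")], model$cell)
  sel <- if (is.null(chains)) rep(TRUE, nrow(xyz)) else
    model$atoms$chain %in% chains
  xyz[sel, ] <- xyz[sel, , drop = FALSE] %*% t(Rz) +
    rep(shift, each = sum(sel))
  out <- model
  out$atoms[c("x", "y", "z")] <- relaxmx:::cart_to_frac(xyz, model$cell)
  out
}
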