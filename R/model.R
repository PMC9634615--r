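#' Construct an atomic model
#'
#' The crystallographic substrate: a table of atoms with fractional
#' coordinates, occupancy, isotropic B-factor and an alternate-conformer tag,
#' plus the unit cell and a space-group label.
#'
#' @param atoms Data frame with columns `element`, `name`, `altloc`
#'   (one of `"A"`, `"B"`, `"C"` or `""` for common atoms), `chain`,
#'   `resno`, `resname`, `x`, `y`, `z` (cell fractions), `occ`, `b` (A^2).
#' @param cell Numeric length 6: a, b, c (Angstrom), alpha, beta, gamma (deg).
#' @param spacegroup Space-group label, e.g. `"P 21 21 21"`.
#' @return An object of class `rx_model`.
#' @export
atomic_model <- function(atoms, cell, spacegroup = "P 1") {
  required <- c("element", "name", "altloc", "chain", "resno", "resname",
                "x", "y", "z", "occ", "b")
  miss <- setdiff(required, names(atoms))
  if (length(miss)) stopf("atoms is missing columns: %s", paste(miss, collapse = ", "))
  if (length(cell) != 6 || any(cell[1:3] <= 0)) {
    stopf("cell must be (a, b, c, alpha, beta, gamma) with positive lengths")
  }
  if (any(atoms$occ < 0 | atoms$occ > 1)) stopf("occupancies must lie in [0, 1]")
  if (any(atoms$b < 0)) stopf("B-factors must be >= 0")
  atoms[c("x", "y", "z")] <- lapply(atoms[c("x", "y", "z")],
                                    function(v) v - floor(v))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, cell = as.numeric(cell),
                 spacegroup = spacegroup),
            class = "rx_model")
}

#' @export
print.rx_model <- function(x, ...) {
  cat(sprintf("Atomic model: %d atoms, cell %s, space group %s\n",
              nrow(x$atoms),
              paste(format(x$cell, digits = 4), collapse = " "),
              x$spacegroup))
  invisible(x)
}

# Fractional -> cartesian transformation matrix (general triclinic).
frac_to_cart_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), c * cos(be),
           0, b * sin(ga), c * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, c * v / sin(ga)),
         nrow = 3, byrow = TRUE)
}

cell_volume <- function(cell) {
  det(frac_to_cart_matrix(cell))
}

# Reciprocal metric tensor; 1/d^2 = h' G* h for Miller index row h.
reciprocal_metric <- function(cell) {
  M <- frac_to_cart_matrix(cell)
  solve(crossprod(t(M)))
}

frac_to_cart <- function(xyz, cell) {
  t(frac_to_cart_matrix(cell) %*% t(as.matrix(xyz)))
}

cart_to_frac <- function(xyz, cell) {
  t(solve(frac_to_cart_matrix(cell)) %*% t(as.matrix(xyz)))
}

#' Write an atomic model in PDB format
#'
#' Emits a CRYST1 record for the cell and fixed-column ATOM records with the
#' altLoc column carrying the conformer tag. Coordinates are converted from
#' cell fractions to orthogonal Angstroms.
#'
#' @param model An `rx_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "rx_model"))
  cl <- model$cell
  lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                   cl[1], cl[2], cl[3], cl[4], cl[5], cl[6],
                   model$spacegroup, 1L)
  xyz <- frac_to_cart(model$atoms[c("x", "y", "z")], cl)
  a <- model$atoms
  for (i in seq_len(nrow(a))) {
    name <- a$name[i]
    # PDB atom-name column convention: element right-justified in cols 13-14
    fname <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    lines <- c(lines, sprintf(
      "ATOM  %5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, fname, ifelse(a$altloc[i] == "", " ", a$altloc[i]), a$resname[i],
      a$chain[i], a$resno[i], xyz[i, 1], xyz[i, 2], xyz[i, 3],
      a$occ[i], a$b[i], a$element[i]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read an atomic model from a PDB file
#'
#' Parses CRYST1 and ATOM/HETATM records (fixed columns: altLoc 17,
#' occupancy 55-60, B 61-66, element 77-78) and converts coordinates to cell
#' fractions.
#'
#' @param path PDB file path.
#' @return An `rx_model`.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  cr <- lines[startsWith(lines, "CRYST1")]
  if (length(cr) == 0) stopf("no CRYST1 record in %s", path)
  cell <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                       substr(cr[1], 25, 33), substr(cr[1], 34, 40),
                       substr(cr[1], 41, 47), substr(cr[1], 48, 54)))
  sg <- trimws(substr(cr[1], 56, 66))
  at <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (length(at) == 0) stopf("no ATOM records in %s", path)
  f <- function(from, to) trimws(substr(at, from, to))
  xyz_cart <- cbind(as.numeric(f(31, 38)), as.numeric(f(39, 46)),
                    as.numeric(f(47, 54)))
  xyz <- cart_to_frac(xyz_cart, cell)
  atoms <- data.frame(element = f(77, 78), name = f(13, 16),
                      altloc = sub(" ", "", substr(at, 17, 17)),
                      chain = f(22, 22), resno = as.integer(f(23, 26)),
                      resname = f(18, 20),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      occ = as.numeric(f(55, 60)), b = as.numeric(f(61, 66)),
                      stringsAsFactors = FALSE)
  blank <- atoms$element == ""
  if (any(blank)) atoms$element[blank] <- substr(atoms$name[blank], 1, 1)
  atomic_model(atoms, cell, sg)
}

#' Select atoms of a model
#'
#' @param model An `rx_model`.
#' @param chain Optional chain identifier.
#' @param residues Optional integer vector of residue numbers.
#' @param altloc Optional conformer tags to keep.
#' @return An `rx_model` restricted to the selection.
#' @export
select_atoms <- function(model, chain = NULL, residues = NULL, altloc = NULL) {
  keep <- rep(TRUE, nrow(model$atoms))
  if (!is.null(chain)) keep <- keep & model$atoms$chain %in% chain
  if (!is.null(residues)) keep <- keep & model$atoms$resno %in% residues
  if (!is.null(altloc)) keep <- keep & model$atoms$altloc %in% altloc
  if (!any(keep)) stopf("empty atom selection")
  atomic_model(model$atoms[keep, , drop = FALSE], model$cell, model$spacegroup)
}
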