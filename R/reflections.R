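#' Construct a reflection set
#'
#' Unique Miller indices with amplitudes (and/or intensities), sigmas and
#' optional phases. Friedel mates are stored once.
#'
#' @param hkl Integer matrix, one row per reflection (columns h, k, l).
#' @param amplitude Structure-factor amplitudes `|F|` (electrons), `>= 0`.
#' @param sigma Amplitude uncertainties; may be `NULL`.
#' @param phase Phases in degrees; `NULL` for amplitude-only data.
#' @param intensity Optional intensities; derived as `amplitude^2` on demand
#'   when absent.
#' @param cell Unit cell (a, b, c, alpha, beta, gamma).
#' @param spacegroup Space-group label.
#' @param resolution_limit High-resolution limit (Angstrom).
#' @return An object of class `rx_reflections`.
#' @export
reflection_set <- function(hkl, amplitude = NULL, sigma = NULL, phase = NULL,
                           intensity = NULL, cell, spacegroup = "P 1",
                           resolution_limit = NA_real_) {
  hkl <- matrix(as.integer(round(hkl)), ncol = 3,
                dimnames = list(NULL, c("h", "k", "l")))
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  if (anyDuplicated(key)) stopf("duplicate Miller indices in reflection set")
  if (!is.null(amplitude) && any(amplitude < 0)) {
    stopf("amplitudes must be >= 0")
  }
  if (is.null(amplitude) && is.null(intensity)) {
    stopf("either amplitudes or intensities must be given")
  }
  structure(list(hkl = hkl, amplitude = amplitude, sigma = sigma,
                 phase = phase, intensity = intensity,
                 cell = as.numeric(cell), spacegroup = spacegroup,
                 resolution_limit = resolution_limit),
            class = "rx_reflections")
}

#' @export
print.rx_reflections <- function(x, ...) {
  cat(sprintf("Reflection set: %d reflections to %.2f A, cell %s, %s\n",
              nrow(x$hkl), x$resolution_limit %||% NA,
              paste(format(x$cell[1:3], digits = 4), collapse = " "),
              x$spacegroup))
  cat(sprintf("  amplitudes: %s, phases: %s, intensities: %s\n",
              !is.null(x$amplitude), !is.null(x$phase), !is.null(x$intensity)))
  invisible(x)
}

refl_intensity <- function(refl) {
  refl$intensity %||% refl$amplitude^2
}

# 1/d^2 for each stored reflection.
refl_s2 <- function(hkl, cell) {
  G <- reciprocal_metric(cell)
  rowSums((hkl %*% G) * hkl)
}

#' Enumerate unique Miller indices to a resolution limit
#'
#' Generates the Friedel-unique half set (h > 0, or h = 0 and k > 0, or
#' h = k = 0 and l > 0) complete to `dmin`.
#'
#' @param cell Unit cell.
#' @param dmin High-resolution limit (Angstrom).
#' @return Integer matrix with columns h, k, l.
#' @export
generate_hkl <- function(cell, dmin) {
  stopifnot(dmin > 0)
  lim <- floor(cell[1:3] / dmin)
  g <- expand.grid(h = -lim[1]:lim[1], k = -lim[2]:lim[2], l = -lim[3]:lim[3])
  hkl <- as.matrix(g)
  s2 <- refl_s2(hkl, cell)
  keep <- s2 <= 1 / dmin^2 & s2 > 0
  hkl <- hkl[keep, , drop = FALSE]
  h <- hkl[, 1]; k <- hkl[, 2]; l <- hkl[, 3]
  half <- h > 0 | (h == 0 & k > 0) | (h == 0 & k == 0 & l > 0)
  unname(hkl[half, , drop = FALSE])
}

#' Write / read reflections as whitespace-delimited text
#'
#' Format: a header line `# cell a b c alpha beta gamma spacegroup <label>
#' dmin <d>`, a column-name line, then one record per reflection with columns
#' `h k l F sigma [phase]` (or `h k l I sigma` for intensity data).
#'
#' @param refl An `rx_reflections`.
#' @param path File path.
#' @return `write_reflections` returns `path` invisibly; `read_reflections`
#'   an `rx_reflections`.
#' @export
write_reflections <- function(refl, path) {
  stopifnot(inherits(refl, "rx_reflections"))
  use_int <- is.null(refl$amplitude)
  val <- if (use_int) refl$intensity else refl$amplitude
  cols <- c("h", "k", "l", if (use_int) "I" else "F", "sigma",
            if (!is.null(refl$phase)) "phase")
  d <- data.frame(refl$hkl, val, refl$sigma %||% rep(0, length(val)))
  if (!is.null(refl$phase)) d$phase <- refl$phase
  names(d) <- cols
  header <- sprintf("# cell %s spacegroup %s dmin %s",
                    paste(format(refl$cell, trim = TRUE), collapse = " "),
                    gsub(" ", "", refl$spacegroup),
                    format(refl$resolution_limit))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, paste(cols, collapse = " ")), con)
  utils::write.table(d, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_reflections
#' @export
read_reflections <- function(path) {
  header <- readLines(path, n = 2)
  toks <- strsplit(trimws(sub("^#", "", header[1])), "\\s+")[[1]]
  cell <- as.numeric(toks[2:7])
  sg_raw <- toks[match("spacegroup", toks) + 1]
  sg <- toupper(gsub("[ _]", "", sg_raw))
  sg <- switch(sg, "P1" = "P 1", "P212121" = "P 21 21 21",
               "P43212" = "P 43 21 2", sg_raw)
  dmin <- as.numeric(toks[match("dmin", toks) + 1])
  cols <- strsplit(trimws(header[2]), "\\s+")[[1]]
  d <- utils::read.table(path, skip = 2, col.names = cols)
  reflection_set(hkl = as.matrix(d[c("h", "k", "l")]),
                 amplitude = if ("F" %in% cols) d$F else NULL,
                 intensity = if ("I" %in% cols) d$I else NULL,
                 sigma = d$sigma,
                 phase = if ("phase" %in% cols) d$phase else NULL,
                 cell = cell, spacegroup = sg, resolution_limit = dmin)
}
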