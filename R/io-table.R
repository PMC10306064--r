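# Coefficient tables live on disk as TSV with a '#'-prefixed JSON header
# line declaring the basis metadata, so the component-major layout is
# self-describing.

#' Write a per-particle coefficient table
#'
#' First line: `#` + JSON basis metadata (l_max, n_max, radius, center,
#' reference_id, n_basis); second line: column names; then one TSV row per
#' particle with values at full double precision (%.17g), so a read/write
#' round trip is lossless.
#'
#' @param table a [CoefficientTable-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCoeffTable <- function(table, path) {
  b <- ncol(table@coeffs) / 3L
  meta <- list(l_max = table@lMax, n_max = table@nMax, radius = table@radius,
               center = table@center, reference_id = table@referenceId,
               n_basis = b)
  header <- paste0("#", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  coefNames <- paste0(rep(c("x", "y", "z"), each = b), "_", seq_len(b))
  cols <- c("particle_id", "rot", "tilt", "psi", "shift_x", "shift_y", coefNames)
  p <- table@particles
  numPart <- vapply(c("rot", "tilt", "psi", "shift_x", "shift_y"),
                    function(cn) sprintf("%.17g", p[[cn]]),
                    character(nrow(p)))
  if (nrow(p) == 1L) numPart <- matrix(numPart, nrow = 1)
  coefChr <- matrix(sprintf("%.17g", table@coeffs), nrow = nrow(p))
  body <- cbind(p$particle_id, numPart, coefChr)
  writeLines(c(header, paste(cols, collapse = "\t"),
               apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read a per-particle coefficient table
#'
#' Inverse of [writeCoeffTable()]. Every row must carry exactly 3 * n_basis
#' coefficients consistent with the header's degree bounds; a mismatch is
#' reported with the offending row index.
#'
#' @param path path to a coefficient TSV.
#' @return a [CoefficientTable-class].
#' @export
readCoeffTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || !startsWith(lines[1], "#"))
    stop("format error: missing '#'-prefixed JSON header line")
  meta <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  b <- zernikeBasisSize(meta$l_max, meta$n_max)
  if (!is.null(meta$n_basis) && meta$n_basis != b)
    stop(sprintf("header inconsistent: n_basis %d but (l_max=%d, n_max=%d) gives %d",
                 meta$n_basis, meta$l_max, meta$n_max, b))
  rows <- lines[-(1:2)]
  rows <- rows[nzchar(rows)]
  m <- length(rows)
  if (m == 0L) stop("format error: table has no data rows")
  parts <- strsplit(rows, "\t", fixed = TRUE)
  want <- 6L + 3L * b
  for (i in seq_len(m)) {
    if (length(parts[[i]]) != want)
      stop(sprintf("format error at data row %d: %d fields, expected %d (3*B + 6 with B = %d)",
                   i, length(parts[[i]]), want, b))
  }
  fields <- do.call(rbind, parts)
  num <- matrix(as.numeric(fields[, -1, drop = FALSE]), nrow = m)
  particles <- data.frame(
    particle_id = fields[, 1],
    rot = num[, 1], tilt = num[, 2], psi = num[, 3],
    shift_x = num[, 4], shift_y = num[, 5],
    stringsAsFactors = FALSE
  )
  new("CoefficientTable", particles = particles,
      coeffs = num[, -(1:5), drop = FALSE],
      lMax = as.integer(meta$l_max), nMax = as.integer(meta$n_max),
      radius = as.numeric(meta$radius), center = as.numeric(meta$center),
      referenceId = as.character(meta$reference_id))
}

#' Write a normal-mode set to TSV
#'
#' TSV with a '#'-prefixed JSON header (kind, eigenvalues, atom count,
#' zero-mode count) followed by the mode matrix, one row per coordinate.
#'
#' @param modes a [NormalModeSet-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeModes <- function(modes, path) {
  meta <- list(kind = modes@kind, eigenvalues = modes@eigenvalues,
               n_atoms = modes@nAtoms, zero_mode_count = modes@zeroModeCount)
  header <- paste0("#", jsonlite::toJSON(meta, digits = NA))
  body <- apply(matrix(sprintf("%.17g", modes@modes), nrow(modes@modes)),
                1, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a normal-mode set from TSV
#'
#' @param path path written by [writeModes()].
#' @return a [NormalModeSet-class].
#' @export
readModes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1], "#"))
    stop("format error: missing '#'-prefixed JSON header line")
  meta <- jsonlite::fromJSON(sub("^#", "", lines[1]))
  body <- lines[-1]
  body <- body[nzchar(body)]
  u <- do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE), as.numeric))
  new("NormalModeSet", modes = u, eigenvalues = as.numeric(meta$eigenvalues),
      kind = as.character(meta$kind), nAtoms = as.integer(meta$n_atoms),
      zeroModeCount = as.integer(meta$zero_mode_count))
}
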