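#' Read an atomic structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) into an [AtomSet-class], one atom
#' per record with coordinates in Angstrom. Insertion codes and alternate
#' location indicators are preserved in the labels; where a position has
#' several altlocs only the first is kept.
#'
#' @param path path to a PDB file.
#' @return an [AtomSet-class].
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  recs <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(recs)) stop(sprintf("format error: no ATOM/HETATM records in %s", path))
  # validate fixed-column coordinate fields before handing off to bio3d so
  # malformed records are reported with their line number
  for (i in which(recs)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("format error at line %d: record shorter than coordinate columns", i))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop(sprintf("format error at line %d: unparseable coordinates", i))
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  alt <- ifelse(is.na(at$alt), "", at$alt)
  ins <- ifelse(is.na(at$insert), "", at$insert)
  key <- paste(at$chain, at$resno, ins, at$elety, sep = "|")
  keep <- !duplicated(key)  # first altloc wins
  at <- at[keep, , drop = FALSE]
  AtomSet(
    coords = cbind(at$x, at$y, at$z),
    labels = data.frame(
      chain = ifelse(is.na(at$chain), "A", at$chain),
      resno = at$resno,
      resid = at$resid,
      atom = at$elety,
      element = ifelse(is.na(at$elesy) | at$elesy == "",
                       substr(trimws(at$elety), 1, 1), at$elesy),
      insert = ins[keep],
      altloc = alt[keep],
      stringsAsFactors = FALSE
    )
  )
}

#' Write an atomic structure to a PDB file
#'
#' Coordinates are written at standard PDB precision (1e-3 Angstrom), so
#' a write/read round trip reproduces them to that precision.
#'
#' @param atoms an [AtomSet-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeStructure <- function(atoms, path) {
  lb <- atoms@labels
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(atoms@coords)),
    resno = lb$resno,
    resid = lb$resid,
    chain = lb$chain,
    elety = lb$atom,
    insert = ifelse(lb$insert == "", NA, lb$insert),
    elesy = lb$element
  )
  invisible(path)
}
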