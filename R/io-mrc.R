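# MRC2014 reader/writer (mode 2, float32, little-endian). The format is a
# 1024-byte header of 4-byte words followed by the raw grid, x fastest.

#' Read an MRC2014 density map
#'
#' Supports mode 2 (float32) maps with isotropic voxels. The voxel size is
#' cell length / grid sampling; the origin is taken from the MRC2014
#' ORIGIN words (Angstrom).
#'
#' @param path path to an MRC/CCP4 map file.
#' @return a [VoxelMap-class].
#' @export
readMap <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  readBin(con, "numeric", n = 3, size = 4, endian = "little")  # cell angles
  readBin(con, "integer", n = 3, size = 4, endian = "little")  # axis order
  readBin(con, "numeric", n = 3, size = 4, endian = "little")  # dmin/max/mean
  readBin(con, "integer", n = 2, size = 4, endian = "little")  # ispg, nsymbt
  readBin(con, "raw", n = 25 * 4)                              # extra
  origin <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  magic <- rawToChar(readBin(con, "raw", n = 4))
  if (magic != "MAP ")
    stop(sprintf("format error: '%s' is not an MRC2014 file (missing MAP magic)", path))
  if (mode != 2L)
    stop(sprintf("unsupported MRC mode %d (only mode 2, float32)", mode))
  seek(con, 1024)
  grid <- readBin(con, "numeric", n = nx * ny * nz, size = 4, endian = "little")
  vs <- cella / ints[8:10]  # cell length over grid sampling MX/MY/MZ
  if (max(abs(vs - vs[1])) > 1e-4 * vs[1])
    stop("isotropic voxel size required")
  VoxelMap(array(grid, dim = c(nx, ny, nz)), voxelSize = vs[1],
           origin = origin)
}

#' Write an MRC2014 density map
#'
#' Mode 2 (float32). A write followed by a read reproduces the grid
#' bit-exactly at float32 precision and preserves voxel size and origin.
#'
#' @param map a [VoxelMap-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeMap <- function(map, path) {
  d <- dim(map@grid)
  g <- as.vector(map@grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wInt <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wInt(c(d, 2L))                       # nx ny nz mode
  wInt(c(0L, 0L, 0L))                  # nxstart
  wInt(d)                              # mx my mz
  wFlt(d * map@voxelSize)              # cell lengths
  wFlt(c(90, 90, 90))                  # cell angles
  wInt(c(1L, 2L, 3L))                  # axis order
  wFlt(c(min(g), max(g), mean(g)))     # dmin dmax dmean
  wInt(c(1L, 0L))                      # ispg, nsymbt
  writeBin(raw(25 * 4), con)           # extra
  wFlt(map@origin)                     # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wFlt(stats::sd(g))                   # rms
  wInt(0L)                             # nlabl
  writeBin(raw(200 * 4), con)          # labels
  wFlt(g)
  invisible(path)
}
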