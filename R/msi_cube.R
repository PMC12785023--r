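#' MSI datacube constructor
#'
#' An `msi_cube` holds a pixel raster with a shared m/z axis: a matrix of
#' per-pixel intensities (rows = pixels, columns = m/z bins), the integer
#' grid position of every pixel, and acquisition metadata. Coordinates are
#' 0-based with x increasing rightward and y downward (imzML's top-left
#' origin convention). Intensities are kept in double precision in memory
#' and serialized as 32-bit floats on disk.
#'
#' @param coords integer matrix `[n_pixels x 2]` of (x, y) grid positions,
#'   0-based; every row unique and inside `[0, width) x [0, height)`.
#' @param mz numeric vector of strictly increasing bin-center m/z values (Da).
#' @param intensities numeric matrix `[n_pixels x n_bins]`, nonnegative.
#' @param width,height raster extent in pixels.
#' @param mode ionization mode, `"positive"` or `"negative"`.
#' @param raster_um pixel pitch in micrometres (default 30).
#' @param provenance character vector of processing-log lines; every
#'   transforming operation appends to it, never truncates.
#' @return an object of class `msi_cube`.
#' @export
msi_cube <- function(coords, mz, intensities, width, height,
                     mode = c("positive", "negative"), raster_um = 30,
                     provenance = character()) {
  mode <- match.arg(mode)
  coords <- matrix(as.integer(coords), ncol = 2L,
                   dimnames = list(NULL, c("x", "y")))
  mz <- as.numeric(mz)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  cube <- structure(
    list(width = as.integer(width), height = as.integer(height),
         coords = coords, mz = mz, intensities = intensities,
         mode = mode, raster_um = as.numeric(raster_um),
         provenance = as.character(provenance)),
    class = "msi_cube")
  validate_msi_cube(cube)
  cube
}

#' Validate an MSI datacube's structural invariants
#'
#' @param cube an `msi_cube`.
#' @return `cube`, invisibly; stops with an informative error on violation.
#' @export
validate_msi_cube <- function(cube) {
  stopifnot(inherits(cube, "msi_cube"))
  n <- nrow(cube$coords)
  if (n == 0L) stop("cube has no pixels")
  if (nrow(cube$intensities) != n)
    stop("intensity matrix has ", nrow(cube$intensities),
         " rows but there are ", n, " pixels")
  if (ncol(cube$intensities) != length(cube$mz))
    stop("intensity matrix has ", ncol(cube$intensities),
         " columns but the m/z axis has ", length(cube$mz), " bins")
  if (length(cube$mz) == 0L) stop("empty m/z axis")
  if (any(diff(cube$mz) <= 0)) stop("m/z axis is not strictly increasing")
  if (any(cube$intensities < 0)) stop("negative intensities present")
  if (any(cube$coords[, 1] < 0L) || any(cube$coords[, 1] >= cube$width) ||
      any(cube$coords[, 2] < 0L) || any(cube$coords[, 2] >= cube$height))
    stop("pixel coordinates outside the [0,width) x [0,height) grid")
  if (anyDuplicated(cube$coords)) stop("duplicate pixel coordinates")
  invisible(cube)
}

n_pixels <- function(cube) nrow(cube$coords)

# Append a processing-log line; provenance only ever grows.
add_provenance <- function(cube, line) {
  cube$provenance <- c(cube$provenance, line)
  cube
}

# Row-major linear index (y * width + x) of each pixel; used for the
# deterministic tie-break rules that reference "first pixel in row-major
# order".
row_major_index <- function(cube) {
  cube$coords[, 2] * cube$width + cube$coords[, 1]
}

#' @export
print.msi_cube <- function(x, ...) {
  cat(sprintf("<msi_cube> %d x %d grid, %d pixels, %d m/z bins (%.2f-%.2f Da), %s mode\n",
              x$width, x$height, n_pixels(x), length(x$mz),
              min(x$mz), max(x$mz), x$mode))
  if (length(x$provenance))
    cat("provenance:", paste(x$provenance, collapse = " | "), "\n")
  invisible(x)
}
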