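#' Per-pixel cluster label image
#'
#' A `label_map` assigns an integer cluster id in `[0, k)` to every tissue
#' pixel of a raster; grid positions not covered by tissue carry `NA`
#' (the NO_TISSUE sentinel) and are excluded from all statistics.
#'
#' @param labels integer matrix `[height x width]` (row 1 = y 0); values in
#'   `[0, k)` or `NA` for positions without tissue.
#' @param k number of clusters; every label in `[0, k)` must occur.
#' @return an object of class `label_map`.
#' @export
label_map <- function(labels, k) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  k <- as.integer(k)
  present <- sort(unique(labels[!is.na(labels)]))
  if (length(present) == 0L) stop("label map contains no tissue pixels")
  if (min(present) < 0L || max(present) >= k)
    stop("labels outside [0, k)")
  if (!setequal(present, 0:(k - 1L)))
    stop("every label in [0, k) must occur at least once")
  structure(list(labels = labels, k = k,
                 width = ncol(labels), height = nrow(labels)),
            class = "label_map")
}

#' Deterministic segmentation palette
#'
#' A fixed, ordered sequence of up to 10 maximally distinct RGB colors for
#' cluster labels plus one background color for NO_TISSUE positions. The
#' ordering never changes between calls, so identical label maps always
#' render to identical bytes.
#'
#' @param k number of cluster colors required (1..10).
#' @return a list with `colors` (k x 3 integer matrix, 8-bit channels) and
#'   `background` (length-3 integer vector).
#' @export
default_palette <- function(k = 10) {
  base <- rbind(
    c(230,  25,  75),  # red
    c( 60, 180,  75),  # green
    c(255, 225,  25),  # yellow
    c(  0, 130, 200),  # blue
    c(245, 130,  48),  # orange
    c(145,  30, 180),  # purple
    c( 70, 240, 240),  # cyan
    c(240,  50, 230),  # magenta
    c(128, 128,   0),  # olive
    c(  0,   0, 128))  # navy
  if (k < 1 || k > nrow(base))
    stop("palette supports 1..", nrow(base),
         " clusters; extend default_palette() for k = ", k)
  list(colors = base[seq_len(k), , drop = FALSE],
       background = c(0L, 0L, 0L))
}

#' Render a label map to a PNG file
#'
#' Writes one image pixel per raster position, 8-bit RGB, non-interlaced,
#' with no ancillary chunks carrying timestamps or text, so that the byte
#' size of the file is a pure function of (labels, palette). That purity is
#' what makes the compressed file size usable as an information-content
#' statistic for segmented images.
#'
#' @param map a `label_map`.
#' @param palette a palette from [default_palette()]; must cover `map$k`.
#' @param path output file path.
#' @return the exact byte count of the written file.
#' @export
render_png <- function(map, palette = default_palette(map$k), path) {
  stopifnot(inherits(map, "label_map"))
  if (map$k > nrow(palette$colors))
    stop("map has k = ", map$k, " clusters but the palette holds only ",
         nrow(palette$colors), " colors; extend the palette")
  all_rgb <- rbind(palette$colors, palette$background)
  # NA (no tissue) -> background row
  idx <- map$labels
  idx[is.na(idx)] <- nrow(all_rgb) - 1L  # 0-based background index
  img <- array(0, dim = c(map$height, map$width, 3L))
  for (ch in 1:3)
    img[, , ch] <- matrix(all_rgb[idx + 1L, ch], nrow = map$height) / 255
  png::writePNG(img, target = path)
  as.numeric(file.size(path))
}
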