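#' Mass-range window
#'
#' Windows are half-open `[low, high)` in Da, except the terminal window of
#' the acquisition range, which closes at its upper edge so the last bin of
#' the axis is not orphaned.
#'
#' @param low,high window edges in Da, `low < high`.
#' @param inclusive_high whether `high` itself belongs to the window.
#' @return an object of class `mass_window`.
#' @export
mass_window <- function(low, high, inclusive_high = FALSE) {
  if (!(low < high)) stop("mass window requires low < high")
  structure(list(low = low, high = high,
                 inclusive_high = isTRUE(inclusive_high)),
            class = "mass_window")
}

#' The four canonical 200-Da analysis windows
#'
#' 200-400, 400-600, 600-800 and 800-1000 Da, half-open except the last,
#' which includes 1000 Da.
#'
#' @return named list of four `mass_window` objects.
#' @export
canonical_windows <- function() {
  list(`200-400`  = mass_window(200, 400),
       `400-600`  = mass_window(400, 600),
       `600-800`  = mass_window(600, 800),
       `800-1000` = mass_window(800, 1000, inclusive_high = TRUE))
}

window_label <- function(window) sprintf("%g-%g", window$low, window$high)

in_window <- function(mz, window) {
  if (window$inclusive_high) mz >= window$low & mz <= window$high
  else mz >= window$low & mz < window$high
}

#' Total-ion-current normalization
#'
#' Rescales every pixel's spectrum so its intensity sum (total ion current)
#' equals a common target, removing per-pixel acquisition variability. The
#' default target is the grand mean of the raw per-pixel TICs, which keeps
#' intensities on the scale of the input; any positive constant gives an
#' identical segmentation under Euclidean distance up to a global scale.
#'
#' @param cube an `msi_cube`.
#' @param tic_target `"grand_mean"` or an explicit positive number.
#' @param zero_tic_policy what to do with pixels whose raw TIC is zero:
#'   `"keep_zero_and_flag"` leaves them all-zero and lists them in the
#'   provenance log; `"drop_pixel"` removes them from the cube.
#' @return the normalized `msi_cube`; every pixel with positive raw TIC sums
#'   to the target within a relative 1e-9.
#' @export
tic_normalize <- function(cube, tic_target = "grand_mean",
                          zero_tic_policy = c("keep_zero_and_flag",
                                              "drop_pixel")) {
  validate_msi_cube(cube)
  zero_tic_policy <- match.arg(zero_tic_policy)
  tic <- rowSums(cube$intensities)
  if (all(tic == 0)) stop("all pixels have zero total ion current")
  target <- if (identical(tic_target, "grand_mean")) mean(tic)
            else as.numeric(tic_target)
  if (!is.finite(target) || target <= 0) stop("TIC target must be positive")

  zero <- tic == 0
  scale <- ifelse(zero, 0, target / tic)
  cube$intensities <- cube$intensities * scale
  if (any(zero)) {
    if (zero_tic_policy == "drop_pixel") {
      keep <- !zero
      cube$coords <- cube$coords[keep, , drop = FALSE]
      cube$intensities <- cube$intensities[keep, , drop = FALSE]
      cube <- add_provenance(cube,
        sprintf("tic_normalize: dropped %d zero-TIC pixels", sum(zero)))
    } else {
      cube <- add_provenance(cube,
        sprintf("tic_normalize: zero-TIC pixels kept at zero: %s",
                paste(which(zero), collapse = ",")))
    }
  }
  add_provenance(cube, sprintf("tic_normalize: target = %.10g", target))
}

#' Restrict a datacube to a mass-range window
#'
#' Keeps only the m/z bins whose centers fall in the window; the pixel set
#' is unchanged. The pipeline normalizes on the full acquisition range
#' first and windows afterwards, and the provenance log records the order.
#'
#' @param cube an `msi_cube`.
#' @param window a `mass_window`.
#' @return the windowed `msi_cube`.
#' @export
window_mass_range <- function(cube, window) {
  validate_msi_cube(cube)
  keep <- in_window(cube$mz, window)
  if (!any(keep))
    stop("no m/z bins fall in window ", window_label(window), " Da")
  cube$mz <- cube$mz[keep]
  cube$intensities <- cube$intensities[, keep, drop = FALSE]
  add_provenance(cube, sprintf("window_mass_range: %s Da, %d bins kept",
                               window_label(window), sum(keep)))
}

#' Bin per-pixel peak lists onto a shared m/z axis
#'
#' Fixed-width binning anchored at the lower edge of the range: peak
#' `m` lands in the half-open bin `[low + i*w, low + (i+1)*w)` whose center
#' is `low + (i + 0.5)*w`. Intensities of peaks sharing a bin are summed.
#' Bins empty across all pixels are dropped from the axis; peaks outside
#' the range are excluded and counted in the provenance log.
#'
#' @param peaklists list with one two-column matrix `(mz, intensity)` per
#'   pixel (zero-row matrices allowed).
#' @param coords integer matrix of 0-based (x, y) pixel positions.
#' @param width,height raster extent in pixels.
#' @param bin_width bin width in Da (default 0.1).
#' @param range a `mass_window` delimiting the axis.
#' @param mode,raster_um passed through to the cube.
#' @return an `msi_cube` on the binned axis.
#' @export
bin_spectra <- function(peaklists, coords, width, height, bin_width = 0.1,
                        range = mass_window(200, 1000, inclusive_high = TRUE),
                        mode = "positive", raster_um = 30) {
  if (bin_width <= 0) stop("bin_width must be positive")
  n <- length(peaklists)
  # small forward nudge so values sitting exactly on a bin boundary are
  # assigned to the bin they open, despite floating-point division error
  bin_of <- function(mz) floor((mz - range$low) / bin_width + 1e-9)

  idx_list <- vector("list", n)
  dropped <- 0L
  for (i in seq_len(n)) {
    pl <- peaklists[[i]]
    if (is.null(pl) || nrow(pl) == 0L) { idx_list[[i]] <- integer() ; next }
    ok <- in_window(pl[, 1], range)
    dropped <- dropped + sum(!ok)
    idx_list[[i]] <- bin_of(pl[ok, 1])
    attr(idx_list[[i]], "intensity") <- pl[ok, 2]
  }
  used <- sort(unique(unlist(idx_list)))
  if (length(used) == 0L) stop("no peaks fall inside the binning range")
  intens <- matrix(0, nrow = n, ncol = length(used))
  for (i in seq_len(n)) {
    bi <- idx_list[[i]]
    if (length(bi) == 0L) next
    cols <- match(bi, used)
    vals <- attr(bi, "intensity")
    for (j in seq_along(cols))
      intens[i, cols[j]] <- intens[i, cols[j]] + vals[j]
  }
  centers <- range$low + (used + 0.5) * bin_width
  cube <- msi_cube(coords, centers, intens, width, height, mode = mode,
                   raster_um = raster_um,
                   provenance = sprintf(
                     "bin_spectra: width %.3g Da on %s Da, %d bins, %d out-of-range peaks excluded",
                     bin_width, window_label(range), length(used), dropped))
  cube
}
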