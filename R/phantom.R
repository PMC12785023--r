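# Ground-truthed synthetic MSI phantoms.
#
# A phantom emulates the structure the study's tissue sections exhibit: a
# peritumor background, a tumor with heterogeneous subregions, a chemically
# distinct margin band, and optionally fat. Each region carries its own
# panel of peaks in 200-1000 Da; per-pixel amplitude variability, a
# multiplicative TIC drift and additive detector noise are layered on top.
# Everything is a deterministic function of the spec's seed.

PEAK_SIGMA_DA <- 0.05   # Gaussian peak shape width on the 0.1 Da bin grid
BIN_WIDTH_DA <- 0.1

# Fixed compound pool for inter-case variability: 80 masses spread over the
# acquisition range with metabolite-like mantissas.
compound_pool <- function() {
  base <- seq(207, 993, length.out = 80)
  round(base + 0.17 * sin(seq_along(base)), 2)
}

# Discriminant masses the tumor gains over the peritumor, per canonical
# window (anchored at the reported margin/tumor features 864.15 and
# 885.75 Da in the terminal window); the margin band's own feature sits at
# 465.94 Da.
TUMOR_DISCRIMINANTS <- list(
  `200-400`  = c(301.14, 345.22),
  `400-600`  = c(478.33, 520.41),
  `600-800`  = c(645.52, 702.61),
  `800-1000` = c(864.15, 885.75))
MARGIN_FEATURE_MZ <- 465.94

region_spec <- function(name, geometry, peaks, baseline = 0.5) {
  stopifnot(is.matrix(peaks) || is.null(peaks))
  list(name = name, geometry = geometry, peaks = peaks, baseline = baseline)
}

peak_panel <- function(mz, amp, cv = 0.25) {
  cbind(mz = mz, amp = amp, cv = rep(cv, length.out = length(mz)))
}

ellipse_mask <- function(width, height, cx, cy, rx, ry) {
  x <- matrix(rep(0:(width - 1), each = height), nrow = height)
  y <- matrix(rep(0:(height - 1), width), nrow = height)
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
}

band_mask <- function(width, height, cx, cy, rx, ry, scale_hi) {
  x <- matrix(rep(0:(width - 1), each = height), nrow = height)
  y <- matrix(rep(0:(height - 1), width), nrow = height)
  r2 <- ((x - cx) / rx)^2 + ((y - cy) / ry)^2
  r2 > 1 & r2 <= scale_hi^2
}

geometry_mask <- function(geom, width, height) {
  switch(geom$type,
    full = matrix(TRUE, height, width),
    ellipse = ellipse_mask(width, height, geom$cx, geom$cy, geom$rx, geom$ry),
    band = band_mask(width, height, geom$cx, geom$cy, geom$rx, geom$ry,
                     geom$scale_hi),
    stop("unknown geometry type: ", geom$type))
}

#' Specification of a synthetic MSI phantom
#'
#' Later regions overwrite earlier ones where they overlap, so the list is
#' ordered background-first. The seed fully determines the generated cube.
#'
#' @param width,height raster extent in pixels.
#' @param regions ordered list of region specs (see
#'   [default_phantom_spec()] for the standard layout).
#' @param noise_sd additive detector-noise standard deviation (intensity
#'   units); negative-mode acquisitions are emulated with a larger value
#'   than positive-mode ones.
#' @param tic_drift_cv coefficient of variation of the multiplicative
#'   per-pixel TIC drift (lognormal).
#' @param mode ionization mode tag.
#' @param seed integer seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(width, height, regions, noise_sd = 1.5,
                         tic_drift_cv = 0.3, mode = "negative", seed = 1) {
  structure(list(width = as.integer(width), height = as.integer(height),
                 regions = regions, noise_sd = noise_sd,
                 tic_drift_cv = tic_drift_cv, mode = mode,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Standard phantom layout
#'
#' A 40 x 40 raster with a peritumor background, an elliptical tumor with a
#' biochemically distinct subregion (heterogeneity), a margin band around
#' the tumor, and a small fat deposit. Two margin presets are available:
#' `"distinct"` gives the margin band its own panel anchored at 465.94 Da
#' while keeping its tumor-side features close to the tumor's (a margin
#' that is "a class of its own"), `"gradient"` makes the margin a 50/50
#' tumor/peritumor mixture. `contrast` scales the tumor-specific peaks per
#' canonical window; `identical_panels = TRUE` collapses tumor, subregion
#' and margin onto the peritumor panel (the no-signal control).
#'
#' @param seed integer seed.
#' @param mode `"positive"` (noise_sd 0.5) or `"negative"` (noise_sd 1).
#' @param width,height raster extent.
#' @param contrast length-4 multiplier of tumor-specific peak amplitudes in
#'   the four canonical windows (default full contrast everywhere).
#' @param margin_preset `"distinct"` or `"gradient"`.
#' @param identical_panels no-signal control flag.
#' @param with_fat include the fat deposit.
#' @return a `phantom_spec`.
#' @export
default_phantom_spec <- function(seed = 1, mode = c("negative", "positive"),
                                 width = 40, height = 40,
                                 contrast = c(1, 1, 1, 1),
                                 margin_preset = c("distinct", "gradient"),
                                 identical_panels = FALSE, with_fat = TRUE) {
  mode <- match.arg(mode)
  margin_preset <- match.arg(margin_preset)
  noise_sd <- if (mode == "negative") 1.0 else 0.5

  shared <- peak_panel(c(304.24, 428.37, 616.47, 744.55, 834.53),
                       c(20, 20, 20, 30, 25))
  tumor_extra <- do.call(rbind, lapply(seq_along(TUMOR_DISCRIMINANTS),
    function(wi) {
      if (contrast[wi] <= 0) return(NULL)
      peak_panel(TUMOR_DISCRIMINANTS[[wi]],
                 c(80, 100) * contrast[wi])
    }))
  tumor <- rbind(shared, tumor_extra)
  # subregion: same features, shifted stoichiometry -> denary heterogeneity
  tumor_b <- tumor
  if (!is.null(tumor_extra)) {
    ib <- nrow(shared) + seq_len(nrow(tumor_extra))
    tumor_b[ib, "amp"] <- tumor_b[ib, "amp"] * rep(c(0.45, 1.15),
                                                   length.out = length(ib))
  }
  tumor_b[2, "amp"] <- tumor_b[2, "amp"] * 2.5

  margin <- if (margin_preset == "distinct") {
    m <- tumor
    m[, "amp"] <- m[, "amp"] * 0.85
    rbind(m, peak_panel(MARGIN_FEATURE_MZ, 60 * max(contrast)))
  } else {
    m <- tumor
    m[, "amp"] <- m[, "amp"] * 0.5
    s <- shared; s[, "amp"] <- s[, "amp"] * 0.5
    rbind(m, s)
  }
  fat <- peak_panel(c(575.50, 603.50, 885.75), c(60, 60, 20))

  if (identical_panels) { tumor <- shared; tumor_b <- shared; margin <- shared }

  cx <- 0.60 * width; cy <- 0.55 * height
  rx <- 0.22 * width; ry <- 0.25 * height
  regions <- list(
    region_spec("peritumor", list(type = "full"), shared),
    region_spec("margin_band",
                list(type = "band", cx = cx, cy = cy, rx = rx, ry = ry,
                     scale_hi = 1.30), margin),
    region_spec("tumor_core_a",
                list(type = "ellipse", cx = cx, cy = cy, rx = rx, ry = ry),
                tumor),
    region_spec("tumor_core_b",
                list(type = "ellipse", cx = cx - 0.05 * width,
                     cy = cy - 0.04 * height, rx = 0.09 * width,
                     ry = 0.10 * height), tumor_b))
  if (with_fat)
    regions <- c(regions, list(
      region_spec("fat",
                  list(type = "ellipse", cx = 0.12 * width,
                       cy = 0.85 * height, rx = 0.10 * width,
                       ry = 0.08 * height), fat)))
  phantom_spec(width, height, regions, noise_sd = noise_sd, mode = mode,
               seed = seed)
}

# Paint the region label map: later regions overwrite earlier ones.
region_map_from_spec <- function(spec) {
  map <- matrix(NA_character_, spec$height, spec$width)
  for (r in spec$regions) {
    m <- geometry_mask(r$geometry, spec$width, spec$height)
    map[m] <- r$name
  }
  if (anyNA(map)) stop("phantom regions leave uncovered pixels")
  map
}

# Deterministic ROI auto-placement: two square tumor ROIs well inside the
# tumor cores and two peritumor ROIs well inside the peritumor region; no
# ROI ever touches the margin band.
auto_rois <- function(region_map, half = NULL) {
  h <- nrow(region_map); w <- ncol(region_map)
  # ROI squares are (2*half+1)^2; shrink on small rasters
  if (is.null(half)) half <- max(1L, min(2L, as.integer(min(h, w) %/% 16)))
  interior <- function(allowed) {
    ok <- matrix(FALSE, h, w)
    for (yy in (half + 1):(h - half)) for (xx in (half + 1):(w - half)) {
      block <- region_map[(yy - half):(yy + half), (xx - half):(xx + half)]
      ok[yy, xx] <- all(block %in% allowed)
    }
    ok
  }
  square <- function(yy, xx) {
    m <- matrix(FALSE, h, w)
    m[(yy - half):(yy + half), (xx - half):(xx + half)] <- TRUE
    m
  }
  pick_two <- function(allowed, what) {
    ok <- interior(allowed)
    cand <- which(ok, arr.ind = TRUE)
    if (nrow(cand) < 2L)
      stop("cannot place two ", what, " ROIs inside their region")
    # first and last candidate in row-major order: maximally separated,
    # deterministic
    a <- cand[1, ]; b <- cand[nrow(cand), ]
    list(square(a[1], a[2]), square(b[1], b[2]))
  }
  tum <- pick_two(c("tumor_core_a", "tumor_core_b"), "tumor")
  per <- pick_two("peritumor", "peritumor")
  roi_set(c(tum, per), c("tumor", "tumor", "peritumor", "peritumor"))
}

#' Generate a phantom MSI datacube with ground truth
#'
#' Per pixel, the intensity vector is the sum over the pixel's region's
#' peaks of a Gaussian peak shape (sigma 0.05 Da sampled onto the 0.1 Da
#' bin grid) scaled by a per-pixel lognormal amplitude draw, plus the
#' region baseline, all multiplied by a lognormal TIC-drift factor, plus
#' truncated-Gaussian (absolute-value) detector noise. The m/z axis keeps
#' only bins within 0.3 Da of some peak, matching what binning of sparse
#' centroided data produces.
#'
#' @param spec a `phantom_spec`.
#' @return list with `cube` (an `msi_cube`) and `truth` (class
#'   `phantom_truth`: `region_map`, `spec`, `rois`).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  w <- spec$width; h <- spec$height
  region_map <- region_map_from_spec(spec)
  rois <- auto_rois(region_map)

  all_mz <- sort(unique(unlist(lapply(spec$regions,
                                      function(r) r$peaks[, "mz"]))))
  bins <- sort(unique(unlist(lapply(all_mz, function(m) {
    i0 <- floor((m - 200) / BIN_WIDTH_DA + 1e-9)
    (i0 - 3L):(i0 + 3L)
  }))))
  centers <- 200 + (bins + 0.5) * BIN_WIDTH_DA

  # row-major pixel order: y outer, x inner
  ys <- rep(0:(h - 1), each = w)
  xs <- rep(0:(w - 1), times = h)
  coords <- cbind(xs, ys)
  n <- nrow(coords)
  region_of <- region_map[cbind(ys + 1L, xs + 1L)]

  intens <- matrix(0, n, length(centers))
  for (r in spec$regions) {
    px <- which(region_of == r$name)
    if (length(px) == 0L) next
    for (j in seq_len(nrow(r$peaks))) {
      mz <- r$peaks[j, "mz"]; amp <- r$peaks[j, "amp"]; cv <- r$peaks[j, "cv"]
      wts <- stats::dnorm(centers, mz, PEAK_SIGMA_DA) * BIN_WIDTH_DA
      nz <- which(wts > 1e-6)
      sdlog <- sqrt(log(1 + cv^2))
      draws <- stats::rlnorm(length(px), log(amp) - sdlog^2 / 2, sdlog)
      intens[px, nz] <- intens[px, nz] + outer(draws, wts[nz])
    }
    intens[px, ] <- intens[px, ] + r$baseline
  }
  sdlog_t <- sqrt(log(1 + spec$tic_drift_cv^2))
  drift <- stats::rlnorm(n, -sdlog_t^2 / 2, sdlog_t)
  intens <- intens * drift
  if (spec$noise_sd > 0)
    intens <- intens + abs(matrix(stats::rnorm(n * length(centers), 0,
                                               spec$noise_sd),
                                  n, length(centers)))

  cube <- msi_cube(coords, centers, intens, w, h, mode = spec$mode,
                   raster_um = 30,
                   provenance = sprintf("make_phantom: seed %d, %s mode",
                                        spec$seed, spec$mode))
  truth <- structure(list(region_map = region_map, spec = spec, rois = rois),
                     class = "phantom_truth")
  list(cube = cube, truth = truth)
}

#' Binary ground-truth partition of a phantom
#'
#' Tumor side (both cores and the margin band, the tissue a binary
#' segmentation groups against the background) versus everything else.
#'
#' @param truth a `phantom_truth`.
#' @return factor vector over pixels in row-major order.
#' @export
truth_binary <- function(truth) {
  rm <- truth$region_map
  v <- as.vector(t(rm))  # row-major: y outer
  factor(ifelse(v %in% c("tumor_core_a", "tumor_core_b", "margin_band"),
                "tumor", "background"))
}

#' Generate a multi-case synthetic study collection
#'
#' Emulates a patient collection: per-case peak panels are drawn as random
#' subsets of a fixed compound pool (inter-individual variability, so cases
#' share only a few m/z values), tumor-specific discriminant peaks are
#' added per window scaled by `contrast_by_window`, and each case is
#' rendered in both ionization modes (identical panels, mode-specific
#' noise). All randomness flows from `seed` through per-case subseeds.
#'
#' @param n_cases number of cases.
#' @param contrast_by_window length-4 multipliers of tumor-specific peaks
#'   in the four canonical windows; `c(0, 0, 0, 1)` confines the
#'   tumor/peritumor contrast to 800-1000 Da.
#' @param seed master seed.
#' @param width,height raster extent per case.
#' @return list of cases; each case is a list with `cubes` (named list
#'   `positive`/`negative`), `truth` (a `phantom_truth`) and `panel_mz`
#'   (the case's distinct peak masses).
#' @export
make_case_collection <- function(n_cases, contrast_by_window = c(0, 0, 0, 1),
                                 seed = 1, width = 40, height = 40) {
  stopifnot(n_cases >= 1, length(contrast_by_window) == 4)
  set.seed(seed)
  case_seeds <- sample.int(10^6, n_cases)
  pool <- compound_pool()
  lapply(seq_len(n_cases), function(ci) {
    cs <- case_seeds[ci]
    set.seed(cs)
    # stratified draw: three compounds per canonical window, so every
    # window carries signal (real spectra have peaks across the range)
    shared_mz <- sort(unlist(lapply(c(200, 400, 600, 800), function(lo) {
      sample(pool[pool >= lo & pool < lo + 200], 3)
    })))
    shared_amp <- stats::runif(12, 15, 35)
    shared <- peak_panel(shared_mz, shared_amp)

    tumor_extra <- do.call(rbind, lapply(1:4, function(wi) {
      if (contrast_by_window[wi] <= 0) return(NULL)
      peak_panel(TUMOR_DISCRIMINANTS[[wi]],
                 c(80, 100) * contrast_by_window[wi])
    }))
    tumor <- rbind(shared, tumor_extra)
    tumor_b <- tumor
    if (!is.null(tumor_extra)) {
      ib <- nrow(shared) + seq_len(nrow(tumor_extra))
      tumor_b[ib, "amp"] <- tumor_b[ib, "amp"] *
        rep(c(0.45, 1.15), length.out = length(ib))
    }
    tumor_b[1, "amp"] <- tumor_b[1, "amp"] * 2.5
    margin <- {
      m <- tumor
      m[, "amp"] <- m[, "amp"] * 0.85
      rbind(m, peak_panel(MARGIN_FEATURE_MZ, 60 * max(contrast_by_window)))
    }

    build_spec <- function(mode, sub) {
      cx <- 0.60 * width; cy <- 0.55 * height
      rx <- 0.22 * width; ry <- 0.25 * height
      regions <- list(
        region_spec("peritumor", list(type = "full"), shared),
        region_spec("margin_band",
                    list(type = "band", cx = cx, cy = cy, rx = rx, ry = ry,
                         scale_hi = 1.30), margin),
        region_spec("tumor_core_a",
                    list(type = "ellipse", cx = cx, cy = cy, rx = rx,
                         ry = ry), tumor),
        region_spec("tumor_core_b",
                    list(type = "ellipse", cx = cx - 0.05 * width,
                         cy = cy - 0.04 * height, rx = 0.09 * width,
                         ry = 0.10 * height), tumor_b))
      phantom_spec(width, height, regions,
                   noise_sd = if (mode == "negative") 1.0 else 0.5,
                   mode = mode, seed = cs + sub)
    }
    pos <- make_phantom(build_spec("positive", 1L))
    neg <- make_phantom(build_spec("negative", 2L))
    list(cubes = list(positive = pos$cube, negative = neg$cube),
         truth = neg$truth,
         panel_mz = sort(unique(c(shared_mz,
                                  if (!is.null(tumor_extra))
                                    tumor_extra[, "mz"],
                                  MARGIN_FEATURE_MZ))))
  })
}

#' Write a small fixed-seed fixture suite
#'
#' Three cases in both ionization modes as imzML/ibd pairs with truth and
#' ROI JSON sidecars, plus a manifest of MD5 checksums. Reruns into a fresh
#' directory reproduce identical files.
#'
#' @param dir output directory (created if needed).
#' @param seed fixture seed (fixed default so reruns are identical).
#' @return the manifest data.frame, invisibly; also written as
#'   `manifest.json`.
#' @export
write_fixture_suite <- function(dir, seed = 20260101) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  collection <- make_case_collection(3, contrast_by_window = c(0, 0, 0, 1),
                                     seed = seed %% 1000000L)
  files <- character()
  set.seed(seed %% 1000000L)  # fixes the writer's UUID draws
  for (ci in seq_along(collection)) {
    case <- collection[[ci]]
    for (mode in names(case$cubes)) {
      base <- file.path(dir, sprintf("case%02d_%s", ci, mode))
      write_imzml(case$cubes[[mode]], paste0(base, ".imzML"))
      files <- c(files, paste0(base, ".imzML"), paste0(base, ".ibd"))
    }
    tj <- file.path(dir, sprintf("case%02d_truth.json", ci))
    jsonlite::write_json(list(region_map = case$truth$region_map),
                         tj, matrix = "rowmajor")
    rj <- file.path(dir, sprintf("case%02d_rois.json", ci))
    jsonlite::write_json(
      list(roles = case$truth$rois$roles,
           masks = lapply(case$truth$rois$masks, function(m) {
             ij <- which(m, arr.ind = TRUE)
             list(x = ij[, "col"] - 1L, y = ij[, "row"] - 1L)
           })),
      rj, auto_unbox = FALSE)
    files <- c(files, tj, rj)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows")
  invisible(manifest)
}
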