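#' Region-of-interest set for margin assessment
#'
#' Exactly four pixel masks on the raster grid: two over the tumor and two
#' over the peritumor region, mirroring the pathologist's ROI protocol.
#'
#' @param masks list of four logical matrices `[height x width]`.
#' @param roles character vector of four role tags; exactly two `"tumor"`
#'   and two `"peritumor"`.
#' @return an object of class `roi_set`.
#' @export
roi_set <- function(masks, roles) {
  if (length(masks) != 4L || length(roles) != 4L)
    stop("an ROI set holds exactly four masks")
  if (sum(roles == "tumor") != 2L || sum(roles == "peritumor") != 2L)
    stop("roles must be exactly two 'tumor' and two 'peritumor'")
  dims <- unique(lapply(masks, dim))
  if (length(dims) != 1L) stop("ROI masks disagree on grid dimensions")
  if (any(!vapply(masks, any, logical(1)))) stop("empty ROI mask")
  structure(list(masks = masks, roles = roles), class = "roi_set")
}

roi_union <- function(rois, role) {
  m <- Reduce(`|`, rois$masks[rois$roles == role])
  m
}

#' Reference cluster label of the tumor
#'
#' The modal segmentation label over the union of the two tumor ROIs; the
#' "color of the tumor" against which peritumor pixels are matched. Ties
#' resolve to the smaller label; NO_TISSUE positions are ignored.
#'
#' @param map a `label_map`.
#' @param rois an `roi_set` on the same grid.
#' @return the modal cluster id (integer).
#' @export
tumor_reference_label <- function(map, rois) {
  labs <- map$labels[roi_union(rois, "tumor")]
  labs <- labs[!is.na(labs)]
  if (length(labs) == 0L)
    stop("tumor ROIs cover no tissue pixels")
  counts <- table(labs)
  as.integer(names(counts)[which.max(counts)])  # ties: first = smallest label
}

#' Percentage of peritumor pixels matching the tumor's label
#'
#' The margin statistic: `100 *` (peritumor-ROI pixels carrying the tumor
#' reference label) / (all peritumor-ROI tissue pixels), pooled over both
#' peritumor ROIs. NO_TISSUE positions are excluded from both counts. The
#' margin is deemed correctly localized when this percentage is strictly
#' below the threshold (default 10%).
#'
#' @param map a `label_map`.
#' @param rois an `roi_set`.
#' @param tumor_label reference label from [tumor_reference_label()].
#' @return the matching percentage in `[0, 100]`.
#' @export
peritumor_match_pct <- function(map, rois, tumor_label) {
  labs <- map$labels[roi_union(rois, "peritumor")]
  labs <- labs[!is.na(labs)]
  if (length(labs) == 0L)
    stop("peritumor ROIs cover no tissue pixels")
  100 * sum(labs == tumor_label) / length(labs)
}

#' Assess margin recognition on one segmented image
#'
#' @param map a `label_map` (binary segmentation in the standard protocol).
#' @param rois an `roi_set`.
#' @param threshold recognition threshold in percent (default 10); the
#'   margin counts as recognized iff `match_pct < threshold`, strictly.
#' @return list with `tumor_label`, `match_pct`, `recognized`, `threshold`.
#' @export
margin_assessment <- function(map, rois, threshold = 10) {
  tl <- tumor_reference_label(map, rois)
  pct <- peritumor_match_pct(map, rois, tl)
  list(tumor_label = tl, match_pct = pct,
       recognized = pct < threshold, threshold = threshold)
}

#' Exact one-sided binomial test of margin recognition
#'
#' Upper-tail probability `P(X >= successes)` for `X ~ Binomial(trials,
#' 1/2)`: the chance probability 1/2 encodes a margin call randomly
#' associated with the pathologist's gold standard. For 9 recognitions in
#' 10 cases the tail is 11/1024 = 0.0107..., printed as 0.011.
#'
#' @param successes number of recognized cases.
#' @param trials number of cases.
#' @return list with `successes`, `trials`, `p_value`.
#' @export
recognition_binomial_test <- function(successes, trials) {
  stopifnot(trials >= 1, successes >= 0, successes <= trials)
  p <- stats::pbinom(successes - 1, size = trials, prob = 0.5,
                     lower.tail = FALSE)
  list(successes = as.integer(successes), trials = as.integer(trials),
       p_value = p)
}

#' Information content of a segmented image
#'
#' The byte size of the label image after lossless PNG compression: a
#' surrogate complexity measure. More heterogeneous segmentations compress
#' worse, so denary images carry more bytes than binary ones. Sizes are
#' reported both as raw bytes and as kb = bytes / 1024 (binary kilobytes;
#' display convention only).
#'
#' @param map a `label_map`.
#' @param palette palette used for rendering (defaults to the built-in).
#' @return list with `bytes` and `kb`.
#' @export
info_content <- function(map, palette = default_palette(map$k)) {
  tf <- tempfile(fileext = ".png")
  on.exit(unlink(tf), add = TRUE)
  bytes <- render_png(map, palette, tf)
  list(bytes = bytes, kb = bytes / 1024)
}

#' Trend tests on information content across mass windows
#'
#' Ordinary least squares of image size (kb) on the window index (1-4,
#' categorical ranges treated as an ordinal regressor), pooled over cases
#' within each ionization mode. Reports, per mode, the slope and the
#' one-sided t-test p-value for a decreasing trend, and between modes the
#' two-sided t-test of the slope difference via the interaction term of a
#' joint two-mode regression.
#'
#' Degenerate fits are handled explicitly: with zero residual variance the
#' slope's standard error is 0, and the one-sided p-value is reported as 0
#' for a negative slope and 1 otherwise (never NaN).
#'
#' @param records data.frame with columns `mode`, `window_index`, `kb`
#'   (and typically `case`).
#' @return list with `per_mode` (data.frame: mode, slope, se, p_decreasing)
#'   and, when two modes are present, `slope_difference` (estimate, se,
#'   p_value).
#' @export
trend_tests <- function(records) {
  records <- as.data.frame(records)
  stopifnot(all(c("mode", "window_index", "kb") %in% names(records)))
  if (length(unique(records$window_index)) < 2L)
    stop("trend tests need at least two mass windows")

  one_mode <- function(df) {
    fit <- stats::lm(kb ~ window_index, data = df)
    df_res <- fit$df.residual
    if (df_res < 1L)
      stop("not enough observations for a slope test within a mode")
    co <- stats::coef(fit)
    slope <- unname(co["window_index"])
    rss <- sum(stats::residuals(fit)^2)
    sxx <- sum((df$window_index - mean(df$window_index))^2)
    se <- sqrt(rss / df_res / sxx)
    if (se == 0) {
      p <- if (slope < 0) 0 else 1
    } else {
      p <- stats::pt(slope / se, df = df_res)  # lower tail: H1 slope < 0
    }
    c(slope = slope, se = se, p_decreasing = p)
  }

  modes <- unique(records$mode)
  per_mode <- do.call(rbind, lapply(modes, function(m) {
    res <- one_mode(records[records$mode == m, , drop = FALSE])
    data.frame(mode = m, slope = res["slope"], se = res["se"],
               p_decreasing = res["p_decreasing"], row.names = NULL)
  }))

  out <- list(per_mode = per_mode)
  if (length(modes) == 2L) {
    records$mode <- factor(records$mode, levels = modes)
    fit <- stats::lm(kb ~ window_index * mode, data = records)
    sm <- stats::summary.lm(fit)$coefficients
    irow <- grep(":", rownames(sm))
    est <- sm[irow, "Estimate"]; se <- sm[irow, "Std. Error"]
    if (se == 0) {
      p <- if (est == 0) 1 else 0
    } else {
      p <- sm[irow, "Pr(>|t|)"]
    }
    if (!is.finite(p)) p <- 0
    out$slope_difference <- list(estimate = unname(est), se = unname(se),
                                 p_value = unname(p))
  }
  out
}

#' Full per-case margin and information-content report
#'
#' Runs the whole assessment factorial for one case: for every ionization
#' mode, canonical mass window and cluster count `k`, the cube is
#' TIC-normalized on the full acquisition range, windowed, segmented, and
#' scored. Margin recognition is decided on the binary segmentation; for
#' `k = 10` the match statistic is still computed but flagged advisory-only
#' (denary matching against a single tumor color is unreliable), and the
#' number of distinct denary labels inside the tumor ROIs is reported as a
#' heterogeneity index. One minimum-spanning tree per (mode, window) is
#' reused for both cuts.
#'
#' @param cubes_by_mode named list of full-range `msi_cube`s, one per mode.
#' @param rois an `roi_set`.
#' @param k_values cluster counts (default `c(2, 10)`).
#' @param windows list of `mass_window`s (default the four canonical).
#' @param threshold recognition threshold in percent.
#' @return data.frame with one row per (mode, window, k): `match_pct`,
#'   `recognized`, `advisory_only`, `tumor_label`, `heterogeneity`,
#'   `bytes`, `kb`, `dominant_mz`.
#' @export
assess_case <- function(cubes_by_mode, rois, k_values = c(2, 10),
                        windows = canonical_windows(), threshold = 10) {
  rows <- list()
  for (mode in names(cubes_by_mode)) {
    cube <- tic_normalize(cubes_by_mode[[mode]])
    for (wi in seq_along(windows)) {
      win <- windows[[wi]]
      wcube <- window_mass_range(cube, win)
      edges <- euclidean_mst(wcube$intensities)
      for (k in k_values) {
        seg <- segment_from_mst(wcube, edges, k)
        ma <- margin_assessment(seg$label_map, rois, threshold)
        tumor_mask <- roi_union(rois, "tumor")
        tlabs <- seg$label_map$labels[tumor_mask]
        het <- length(unique(tlabs[!is.na(tlabs)]))
        ic <- info_content(seg$label_map)
        margin_label <- k - 1L  # smallest cluster: candidate margin class
        dm <- tryCatch(
          dominant_mz(seg$mean_spectra[margin_label + 1L, ], seg$mz)$mz,
          error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          mode = mode, window = window_label(win), window_index = wi,
          k = k, tumor_label = ma$tumor_label, match_pct = ma$match_pct,
          recognized = ma$recognized, advisory_only = (k != 2L),
          heterogeneity = het, bytes = ic$bytes, kb = ic$kb,
          dominant_mz = dm)
      }
    }
  }
  do.call(rbind, rows)
}
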