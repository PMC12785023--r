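# Independent oracles and generators shared across the test files.

# Naive O(n^3) agglomerative single-linkage clustering over a full distance
# matrix: repeatedly merge the closest cluster pair (lexicographic
# tie-break), stop at k clusters. Deliberately independent of the package's
# MST implementation.
naive_single_linkage <- function(X, k) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  comp <- seq_len(n)
  Dc <- D  # distances between cluster representatives
  n_clust <- n
  while (n_clust > k) {
    m <- min(Dc)
    idx <- which(Dc == m, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    comp[comp == j] <- i
    # single linkage: representative i absorbs j with the pairwise minimum
    newrow <- pmin(Dc[i, ], Dc[j, ])
    Dc[i, ] <- newrow; Dc[, i] <- newrow
    Dc[i, i] <- Inf
    Dc[j, ] <- Inf; Dc[, j] <- Inf
    n_clust <- n_clust - 1L
  }
  comp
}

# Canonical form of a partition: clusters renumbered by first appearance.
canon_partition <- function(p) match(p, unique(p))

same_partition <- function(a, b) identical(canon_partition(a),
                                           canon_partition(b))

# Random datacube on a (possibly non-rectangular) subset of a grid.
random_cube <- function(n_pixels, n_bins, width = 20, height = 20,
                        mode = "positive") {
  all_pos <- expand.grid(x = 0:(width - 1), y = 0:(height - 1))
  pick <- sort(sample.int(nrow(all_pos), n_pixels))
  coords <- as.matrix(all_pos[pick, ])
  mz <- sort(200 + cumsum(stats::runif(n_bins, 0.1, 5)))
  intens <- matrix(stats::runif(n_pixels * n_bins, 0, 100),
                   n_pixels, n_bins)
  msi_cube(coords, mz, intens, width, height, mode = mode)
}

# Labels of a segmentation in cube pixel (storage) order.
labels_in_pixel_order <- function(seg, cube) {
  seg$label_map$labels[cbind(cube$coords[, 2] + 1L, cube$coords[, 1] + 1L)]
}

# Phantom ground-truth binary factor vs segmentation labels ARI.
phantom_binary_ari <- function(seg, cube, truth) {
  mclust::adjustedRandIndex(truth_binary(truth),
                            labels_in_pixel_order(seg, cube))
}

python_bin <- function() Sys.which("python")
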