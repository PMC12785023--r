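# Exact single-linkage hierarchical segmentation of pixel spectra.
#
# Single-linkage agglomeration over Euclidean distances is equivalent to
# building the Euclidean minimum spanning tree of the pixels and cutting its
# k-1 heaviest edges: the resulting connected components are exactly the
# k clusters a naive agglomerative scheme produces. The MST route needs
# O(n^2) time and O(n) memory instead of a full distance matrix, which makes
# exact whole-image clustering of tens of thousands of pixels feasible.

# Prim's algorithm on implicit Euclidean distances; returns the n-1 MST
# edges as a matrix (from, to, weight) with from < to. Ties in the nearest-
# fringe choice are broken toward the smallest pixel index (storage order),
# which makes the tree deterministic.
euclidean_mst <- function(X) {
  n <- nrow(X)
  if (n == 1L) return(matrix(numeric(0), ncol = 3,
                             dimnames = list(NULL, c("from", "to", "w"))))
  rn <- rowSums(X^2)
  intree <- logical(n)
  mind <- rep(Inf, n)
  edge_to <- integer(n)
  intree[1] <- TRUE
  d1 <- sqrt(pmax(rn + rn[1] - 2 * drop(X %*% X[1, ]), 0))
  mind <- d1; mind[1] <- Inf
  edge_to[] <- 1L
  from <- integer(n - 1L); to <- integer(n - 1L); w <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    u <- which.min(replace(mind, intree, Inf))
    from[step] <- min(edge_to[u], u)
    to[step] <- max(edge_to[u], u)
    w[step] <- mind[u]
    intree[u] <- TRUE
    du <- sqrt(pmax(rn + rn[u] - 2 * drop(X %*% X[u, ]), 0))
    upd <- !intree & du < mind
    mind[upd] <- du[upd]
    edge_to[upd] <- u
  }
  cbind(from = from, to = to, w = w)
}

# Components after keeping the n-k lightest MST edges. Equal-weight edges
# are processed in lexicographic (from, to) order so chained ties resolve
# deterministically. Union-find with full path compression (the parent
# vector lives in this frame so compression persists across finds).
cut_mst <- function(edges, n, k) {
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) {
      nxt <- parent[i]
      parent[i] <<- root
      i <- nxt
    }
    root
  }
  if (k < n && nrow(edges) > 0) {
    ord <- order(edges[, "w"], edges[, "from"], edges[, "to"])
    keep <- ord[seq_len(n - k)]
    ef <- as.integer(edges[, "from"]); et <- as.integer(edges[, "to"])
    for (e in keep) {
      a <- find(ef[e])
      b <- find(et[e])
      if (a != b) parent[a] <- b
    }
  }
  vapply(seq_len(n), find, integer(1), USE.NAMES = FALSE)
}

# Relabel an arbitrary partition to 0..k-1, ordered by descending cluster
# size with ties broken by the smallest member pixel in row-major order.
canonical_labels <- function(comp, rm_index) {
  ids <- unique(comp)
  size <- vapply(ids, function(g) sum(comp == g), numeric(1))
  first <- vapply(ids, function(g) min(rm_index[comp == g]), numeric(1))
  ord <- order(-size, first)
  new <- integer(length(comp))
  for (r in seq_along(ord)) new[comp == ids[ord[r]]] <- r - 1L
  new
}

#' Segment an MSI datacube by single-linkage hierarchical clustering
#'
#' Clusters the pixel spectra with Euclidean distance and single (nearest
#' neighbor) linkage, computed exactly through the minimum-spanning-tree
#' formulation, and cuts the hierarchy into `k` classes. `k = 2` gives the
#' binary segmentation used for margin depiction and `k = 10` the denary
#' segmentation used for heterogeneity mapping. The procedure is fully
#' deterministic: equal-weight merges resolve in lexicographic pixel order
#' and the final labels are ordered by descending cluster size (ties by the
#' first member pixel in row-major order), so colors are stable across
#' reruns.
#'
#' @param cube an `msi_cube` (typically TIC-normalized and windowed).
#' @param k number of clusters, `1 <= k <=` number of distinct spectra.
#' @return an object of class `segmentation_result`: `label_map`, `k`,
#'   `metric`, `linkage`, `mean_spectra` (`k x n_bins`), `cluster_sizes`,
#'   `mz`, `mode`.
#' @export
hca_segment <- function(cube, k) {
  validate_msi_cube(cube)
  n <- n_pixels(cube)
  if (k < 1L) stop("k must be at least 1")
  if (k > n) stop("k = ", k, " exceeds the number of pixels (", n, ")")
  edges <- euclidean_mst(cube$intensities)
  segment_from_mst(cube, edges, k)
}

# Shared cut + bookkeeping so callers can reuse one MST for several k.
segment_from_mst <- function(cube, edges, k) {
  n <- n_pixels(cube)
  if (k > 1L && nrow(edges) > 0) {
    max_k <- sum(edges[, "w"] > 0) + 1L
    if (k > max_k)
      stop("only ", max_k, " distinct spectra present; k = ", k,
           " clusters are not achievable (maximum ", max_k, ")")
  }
  comp <- cut_mst(edges, n, k)
  labels01 <- canonical_labels(comp, row_major_index(cube))

  lab_mat <- matrix(NA_integer_, nrow = cube$height, ncol = cube$width)
  lab_mat[cbind(cube$coords[, 2] + 1L, cube$coords[, 1] + 1L)] <- labels01
  map <- label_map(lab_mat, k)

  ms <- cluster_mean_spectra(cube, map)
  structure(list(label_map = map, k = as.integer(k), metric = "euclidean",
                 linkage = "single", mean_spectra = ms$mean_spectra,
                 cluster_sizes = ms$cluster_sizes, mz = cube$mz,
                 mode = cube$mode),
            class = "segmentation_result")
}

#' Per-cluster mean spectra
#'
#' Arithmetic mean intensity vector of the member pixels of every cluster,
#' plus the cluster pixel counts. Conservation holds exactly: the
#' size-weighted sum of the cluster means recomposes the total intensity.
#'
#' @param cube an `msi_cube`.
#' @param map a `label_map` on the same grid.
#' @return list with `mean_spectra` (`k x n_bins` matrix, row `c` = cluster
#'   label `c - 1`) and `cluster_sizes` (length-`k` integer vector).
#' @export
cluster_mean_spectra <- function(cube, map) {
  labs <- map$labels[cbind(cube$coords[, 2] + 1L, cube$coords[, 1] + 1L)]
  if (anyNA(labs))
    stop("label map has NO_TISSUE at ", sum(is.na(labs)), " cube pixels")
  present <- sort(unique(labs))
  if (!setequal(present, 0:(map$k - 1L)))
    stop("labels ", paste(setdiff(0:(map$k - 1L), present), collapse = ","),
         " absent from the map over this cube")
  sizes <- as.integer(table(factor(labs, levels = 0:(map$k - 1L))))
  sums <- rowsum(cube$intensities, group = labs)
  means <- sums / sizes
  list(mean_spectra = unname(as.matrix(means)), cluster_sizes = sizes)
}

#' Dominant m/z of a mean spectrum
#'
#' The bin center at which a cluster's mean spectrum attains its global
#' maximum; ties resolve to the lowest m/z. The dominant m/z of the
#' margin-class spectrum is the quantity handed to annotation.
#'
#' @param mean_spectrum numeric intensity vector.
#' @param mz_axis matching vector of bin centers (Da).
#' @return list with `mz` and `intensity`.
#' @export
dominant_mz <- function(mean_spectrum, mz_axis) {
  stopifnot(length(mean_spectrum) == length(mz_axis),
            length(mean_spectrum) >= 1)
  if (all(mean_spectrum == 0))
    stop("all-zero spectrum has no dominant peak")
  i <- which.max(mean_spectrum)  # which.max returns the first (lowest m/z) tie
  list(mz = mz_axis[i], intensity = mean_spectrum[i])
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> k = %d (%s linkage, %s), sizes: %s\n",
              x$k, x$linkage, x$metric,
              paste(x$cluster_sizes, collapse = ", ")))
  invisible(x)
}
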