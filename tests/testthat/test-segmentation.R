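line_cube <- function(values, width = length(values)) {
  msi_cube(cbind(0:(length(values) - 1), 0L), 300,
           matrix(values, ncol = 1), width, 1)
}

test_that("well-separated duplicate spectra split into their groups", {
  cube <- msi_cube(cbind(0:3, 0L), c(300, 500),
                   rbind(c(10, 0), c(10, 0), c(0, 10), c(0, 10)), 4, 1)
  seg <- hca_segment(cube, 2)
  labs <- labels_in_pixel_order(seg, cube)
  expect_equal(labs[1], labs[2])
  expect_equal(labs[3], labs[4])
  expect_true(labs[1] != labs[3])
  expect_equal(labs[1], 0L)  # label 0 holds the first row-major pixel (tie rule)
})

test_that("single-linkage chains across small gaps before large ones", {
  cube <- line_cube(c(0, 1, 2.1, 10))
  seg <- hca_segment(cube, 2)
  labs <- labels_in_pixel_order(seg, cube)
  expect_equal(canon_partition(labs), c(1L, 1L, 1L, 2L))
  expect_equal(seg$cluster_sizes, c(3L, 1L))
})

test_that("degenerate k values behave per contract", {
  cube <- line_cube(c(0, 1, 2.1, 10))
  expect_equal(hca_segment(cube, 4)$cluster_sizes, rep(1L, 4))
  expect_equal(hca_segment(cube, 1)$cluster_sizes, 4L)
  expect_error(hca_segment(cube, 5), "exceeds")
  dup <- line_cube(c(3, 3, 3, 7))
  expect_error(hca_segment(dup, 3), "distinct")
})

test_that("MST cut matches the naive agglomeration oracle on random cubes", {
  set.seed(101)
  for (rep in 1:12) {
    n <- sample(10:80, 1)
    cube <- random_cube(n, sample(2:10, 1), width = 12, height = 12)
    for (k in c(2, min(10, n))) {
      seg <- hca_segment(cube, k)
      oracle <- naive_single_linkage(cube$intensities, k)
      expect_true(same_partition(labels_in_pixel_order(seg, cube), oracle))
    }
  }
})

test_that("MST cut matches hclust single-linkage cutree", {
  set.seed(55)
  for (rep in 1:10) {
    cube <- random_cube(sample(10:60, 1), 4, width = 10, height = 10)
    hc <- stats::hclust(stats::dist(cube$intensities), method = "single")
    for (k in c(2, 5)) {
      expect_true(same_partition(labels_in_pixel_order(hca_segment(cube, k), cube),
                                 stats::cutree(hc, k)))
    }
  }
})

test_that("partition is equivariant under pixel storage permutation", {
  set.seed(77)
  cube <- random_cube(40, 5)
  perm <- sample(40)
  shuffled <- msi_cube(cube$coords[perm, ], cube$mz,
                       cube$intensities[perm, ], cube$width, cube$height)
  a <- hca_segment(cube, 3)$label_map$labels
  b <- hca_segment(shuffled, 3)$label_map$labels
  expect_identical(a, b)  # canonical relabeling makes maps identical
})

test_that("partition is invariant to global intensity scaling", {
  set.seed(78)
  cube <- random_cube(35, 6)
  scaled <- cube; scaled$intensities <- cube$intensities * 7.3
  expect_identical(hca_segment(cube, 4)$label_map$labels,
                   hca_segment(scaled, 4)$label_map$labels)
})

test_that("two runs render byte-identical segmented images", {
  set.seed(80)
  ph <- make_phantom(default_phantom_spec(seed = 7, width = 20, height = 20))
  wc <- window_mass_range(tic_normalize(ph$cube),
                          canonical_windows()[["800-1000"]])
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  b1 <- render_png(hca_segment(wc, 2)$label_map, default_palette(2), f1)
  b2 <- render_png(hca_segment(wc, 2)$label_map, default_palette(2), f2)
  expect_identical(readBin(f1, "raw", b1), readBin(f2, "raw", b2))
  unlink(c(f1, f2))
})

test_that("cluster means average members and recompose the total", {
  cube <- msi_cube(cbind(0:3, 0L), c(300, 500),
                   rbind(c(2, 0), c(4, 2), c(8, 8), c(0, 2)), 4, 1)
  labs <- matrix(c(0L, 0L, 1L, 0L), 1, 4)  # [height x width]
  map <- label_map(labs, 2)
  ms <- cluster_mean_spectra(cube, map)
  expect_equal(ms$mean_spectra[1, ], c(2, 4/3))
  expect_equal(ms$mean_spectra[2, ], c(8, 8))   # singleton keeps its spectrum
  recomposed <- colSums(ms$mean_spectra * ms$cluster_sizes)
  expect_equal(recomposed, colSums(cube$intensities), tolerance = 1e-12)
  bad <- label_map(matrix(c(0L, 0L, 1L, 0L), 1, 4), 2)
  bad$labels[1, 3] <- NA_integer_
  expect_error(cluster_mean_spectra(cube, bad), "NO_TISSUE")
})

test_that("dominant m/z takes the maximum with low-m/z tie-break", {
  expect_equal(dominant_mz(c(1, 9, 4), c(300.05, 465.95, 700.05))$mz, 465.95)
  expect_equal(dominant_mz(c(5, 5), c(300.05, 500.05))$mz, 300.05)
  expect_equal(dominant_mz(3, 421.15)$mz, 421.15)
  expect_error(dominant_mz(c(0, 0), c(1, 2)), "dominant")
})

test_that("phantom margin class peaks at the 465.95 Da bin", {
  # contrast confined to 800-1000 Da, so within 400-600 Da the margin's own
  # 465.94 Da feature is the tallest peak of its mean spectrum
  ph <- make_phantom(default_phantom_spec(seed = 3, mode = "positive",
                                          contrast = c(0, 0, 0, 1)))
  wc <- window_mass_range(tic_normalize(ph$cube), mass_window(400, 600))
  rm_v <- as.vector(t(ph$truth$region_map))
  margin_mean <- colMeans(wc$intensities[rm_v == "margin_band", ])
  expect_equal(dominant_mz(margin_mean, wc$mz)$mz, 465.95)
})
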