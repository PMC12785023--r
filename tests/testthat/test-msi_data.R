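test_that("cube construction enforces the structural invariants", {
  coords <- cbind(c(0L, 1L), c(0L, 0L))
  expect_s3_class(msi_cube(coords, c(200, 300), rbind(c(1, 2), c(3, 4)),
                           2, 1), "msi_cube")
  expect_error(msi_cube(coords, c(300, 200), rbind(c(1, 2), c(3, 4)), 2, 1),
               "increasing")
  expect_error(msi_cube(coords, c(200, 300), rbind(c(1, -2), c(3, 4)), 2, 1),
               "negative")
  expect_error(msi_cube(rbind(c(0L, 0L), c(0L, 0L)), c(200, 300),
                        rbind(c(1, 2), c(3, 4)), 2, 1), "duplicate")
  expect_error(msi_cube(cbind(2L, 0L), 200, matrix(1), 2, 1), "grid")
})

test_that("imzML write/read round-trips a cube at float32 precision", {
  set.seed(11)
  cube <- random_cube(8, 5, width = 4, height = 4)
  path <- file.path(tempdir(), "rt.imzML")
  write_imzml(cube, path)
  back <- read_imzml(path)
  expect_equal(back$coords, cube$coords, ignore_attr = TRUE)
  expect_equal(back$width, cube$width)
  expect_equal(back$mode, cube$mode)
  # float32 has ~7 significant digits
  expect_lt(max(abs(back$mz - cube$mz) / cube$mz), 1e-6)
  expect_lt(max(abs(back$intensities - cube$intensities) /
                  pmax(cube$intensities, 1)), 1e-6)
})

test_that("imzML round-trip holds over random small cubes (property)", {
  set.seed(21)
  for (rep in 1:5) {
    cube <- random_cube(sample(2:12, 1), sample(2:8, 1),
                        width = 5, height = 5,
                        mode = sample(c("positive", "negative"), 1))
    path <- file.path(tempdir(), sprintf("rt%d.imzML", rep))
    back <- read_imzml(write_imzml(cube, path))
    expect_equal(back$mode, cube$mode)
    expect_lt(max(abs(back$intensities - cube$intensities) /
                    pmax(cube$intensities, 1)), 1e-6)
  }
})

test_that("imzML I/O rejects degenerate inputs", {
  path <- file.path(tempdir(), "orphan.imzML")
  set.seed(3)
  cube <- random_cube(4, 3, width = 2, height = 2)
  write_imzml(cube, path)
  file.remove(sub("imzML$", "ibd", path))
  expect_error(read_imzml(path), "ibd")
  expect_error(read_imzml(file.path(tempdir(), "absent.imzML")),
               "not found")
})

test_that("written imzML passes an independent parser's structural checks", {
  set.seed(5)
  ph <- make_phantom(default_phantom_spec(seed = 5, width = 12, height = 12))
  path <- file.path(tempdir(), "phantom12.imzML")
  write_imzml(ph$cube, path)
  script <- sprintf(
    "from pyimzml.ImzMLParser import ImzMLParser\np = ImzMLParser('%s')\nmz, it = p.getspectrum(0)\nprint(len(p.coordinates), len(mz), '%%.4f' %% mz[0], '%%.4f' %% float(it[3]))",
    path)
  out <- system2(python_bin(), c("-c", shQuote(script)), stdout = TRUE)
  parts <- strsplit(out[length(out)], " ")[[1]]
  expect_equal(as.integer(parts[1]), nrow(ph$cube$coords))
  expect_equal(as.integer(parts[2]), length(ph$cube$mz))
  expect_equal(as.numeric(parts[3]), ph$cube$mz[1], tolerance = 1e-4)
  expect_equal(as.numeric(parts[4]), ph$cube$intensities[1, 4],
               tolerance = 1e-4)
})

test_that("reader resamples processed-mode files written by pyimzml", {
  base <- file.path(tempdir(), "processed")
  script <- sprintf(
    paste0("from pyimzml.ImzMLWriter import ImzMLWriter\n",
           "with ImzMLWriter('%s.imzML', mode='processed') as w:\n",
           "    w.addSpectrum([465.93, 465.95], [5.0, 7.0], (1, 1, 1))\n",
           "    w.addSpectrum([300.05], [2.0], (2, 1, 1))\n"),
    base)
  system2(python_bin(), c("-c", shQuote(script)))
  cube <- read_imzml(paste0(base, ".imzML"), mode = "positive",
                     bin_width = 0.1)
  # both peaks in pixel 1 share the 0.1 Da bin centered at 465.95
  j <- which.min(abs(cube$mz - 465.95))
  expect_equal(cube$mz[j], 465.95, tolerance = 1e-9)
  expect_equal(cube$intensities[1, j], 12, tolerance = 1e-5)
  expect_equal(sum(cube$intensities[1, ]), 12, tolerance = 1e-5)
  expect_equal(sum(cube$intensities[2, ]), 2, tolerance = 1e-6)
})

test_that("render_png is deterministic and label maps color correctly", {
  set.seed(9)
  labs <- matrix(sample(0:1, 2500, replace = TRUE), 50, 50)
  map <- label_map(labs, 2)
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  b1 <- render_png(map, default_palette(2), f1)
  b2 <- render_png(map, default_palette(2), f2)
  expect_identical(readBin(f1, "raw", b1), readBin(f2, "raw", b2))
  expect_equal(b1, file.size(f1))
  unlink(c(f1, f2))
})

test_that("a constant image never compresses worse than two-color maps", {
  f <- tempfile(fileext = ".png")
  for (n in c(20, 200)) {
    b_const <- render_png(label_map(matrix(0L, n, n), 1),
                          default_palette(1), f)
    checker <- label_map(outer(1:n, 1:n, function(i, j) (i + j) %% 2), 2)
    expect_lt(b_const, render_png(checker, default_palette(2), f))
  }
  const_map <- label_map(matrix(0L, 100, 100), 1)
  b_const <- render_png(const_map, default_palette(1), f)
  set.seed(33)
  for (r in 1:20) {
    m <- label_map(matrix(sample(0:1, 1e4, replace = TRUE), 100, 100), 2)
    expect_lte(b_const, render_png(m, default_palette(2), f))
  }
  unlink(f)
})

test_that("rendering fails when labels exceed the palette", {
  map <- label_map(matrix(c(0L, 1L, 2L, 2L), 2, 2), 3)
  expect_error(render_png(map, default_palette(2), tempfile()), "palette")
  expect_error(default_palette(11), "extend")
})
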