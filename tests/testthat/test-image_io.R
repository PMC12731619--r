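# image_io: raster reading, ROI rasterization, result tables.

test_that("TIFF round trip preserves pixel values at all supported depths", {
  set.seed(11)
  m8 <- matrix(sample(0:255, 12 * 9, TRUE), 12, 9)
  m16 <- matrix(sample(0:65535, 12 * 9, TRUE), 12, 9)
  mf <- matrix(runif(12 * 9), 12, 9)
  f8 <- tempfile(fileext = ".tif"); f16 <- tempfile(fileext = ".tif")
  ff <- tempfile(fileext = ".tif")
  write_tiff(m8, f8, bits = 8L)
  write_tiff(m16, f16, bits = 16L)
  write_tiff(mf, ff, sample_format = "float")
  expect_identical(unname(read_tiff(f8)[[1]] == m8), matrix(TRUE, 12, 9))
  expect_identical(unname(read_tiff(f16)[[1]] == m16), matrix(TRUE, 12, 9))
  expect_equal(read_tiff(ff)[[1]], mf, ignore_attr = TRUE,
               tolerance = 1e-7)  # float32 storage precision
  # multi-page: pages come back in order
  fm <- tempfile(fileext = ".tif")
  write_tiff(list(m8, 255 - m8), fm, bits = 8L)
  pages <- read_tiff(fm)
  expect_length(pages, 2)
  expect_true(all(pages[[2]] == 255 - m8))
})

test_that("probability rasters are normalized by on-disk depth", {
  m <- matrix(c(0L, 128L, 255L, 51L), 2, 2)
  f <- tempfile(fileext = ".tif")
  write_tiff(m, f, bits = 8L)
  pm <- read_raster(f, "probability")
  expect_equal(pm$probs[1, 2], 1.0)          # 255 -> 1.0
  expect_equal(pm$probs[2, 2], 51 / 255)
  expect_identical(pm$source_scale, "eight_bit")

  z <- matrix(0L, 3, 3)
  write_tiff(z, f, bits = 8L)
  expect_true(all(read_raster(f, "probability")$probs == 0))

  f16 <- tempfile(fileext = ".tif")
  write_tiff(matrix(65535L, 2, 2), f16, bits = 16L)
  expect_true(all(read_raster(f16, "probability")$probs == 1))

  bad <- tempfile(fileext = ".tif")
  write_tiff(matrix(c(0.2, 1.5, 0.1, 0), 2, 2), bad, sample_format = "float")
  expect_error(read_raster(bad, "probability"), "outside \\[0, 1\\]")
  # same file is fine as an intensity image
  expect_s3_class(read_raster(bad, "intensity"), "intensity_image")
})

test_that("read_raster is deterministic and validates inputs", {
  f <- tempfile(fileext = ".tif")
  write_tiff(matrix(7L, 4, 4), f, bits = 8L)
  a <- read_raster(f, "probability"); b <- read_raster(f, "probability")
  expect_identical(a, b)
  expect_error(read_raster(tempfile(), "intensity"), "not found")
  expect_error(intensity_image(matrix(-1, 2, 2)), ">= 0")
  expect_error(probability_mask(matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("roi_to_mask matches the pixel-center even-odd definition", {
  # axis-aligned rectangle (0,0)-(4,4) on a 10x10 grid: 16 interior centres
  roi <- roi_spec(polygon = cbind(x = c(0, 4, 4, 0), y = c(0, 0, 4, 4)))
  m <- roi_to_mask(roi, c(10, 10))
  expect_identical(sum(m), 16L)
  expect_true(all(which(m, arr.ind = TRUE) <= 4))

  # mask input of matching shape is returned unchanged
  rm <- roi_spec(mask = m)
  expect_identical(roi_to_mask(rm, c(10, 10)), m)
  expect_error(roi_to_mask(rm, c(5, 5)), "shape")

  # degenerate polygon and out-of-grid polygon
  expect_error(roi_spec(polygon = cbind(c(2, 2, 2), c(3, 3, 3))), "degenerate")
  far <- roi_spec(polygon = cbind(x = c(50, 60, 55), y = c(50, 50, 60)))
  expect_error(roi_to_mask(far, c(10, 10)), "no pixel centres")
})

test_that("roi_to_mask agrees with a winding-number oracle on random polygons", {
  set.seed(42)
  for (rep in 1:25) {
    # random convex polygon: convex hull of jittered points (non-grid-aligned
    # so no centre sits exactly on an edge, where conventions could differ)
    pts <- cbind(runif(8, 0.3, 15.7), runif(8, 0.3, 15.7)) + 1e-3 * rnorm(16)
    hull <- pts[chull(pts), , drop = FALSE]
    if (nrow(hull) < 3) next
    roi <- roi_spec(polygon = hull)
    got <- tryCatch(roi_to_mask(roi, c(16, 16)), error = function(e) NULL)
    cx <- rep(seq_len(16) - 0.5, each = 16)
    cy <- rep(seq_len(16) - 0.5, times = 16)
    want <- matrix(oracle_point_in_polygon(cx, cy, hull[, 1], hull[, 2]), 16, 16)
    if (is.null(got)) {
      expect_identical(sum(want), 0L)  # empty-ROI error iff oracle says empty
    } else {
      expect_identical(got, want)
    }
  }
})

test_that("ImageJ .roi and text polygon files round-trip", {
  poly <- cbind(x = c(2, 11, 13, 6, 1), y = c(1, 2, 9, 12, 7))
  roi <- roi_spec(polygon = poly, name = "lobe")
  f <- tempfile(fileext = ".roi")
  write_imagej_roi(roi, f)
  back <- read_roi(f)
  expect_equal(unname(back$polygon), unname(poly))

  ft <- tempfile(fileext = ".txt")
  writeLines(c("# optic lobe outline", apply(poly, 1, paste, collapse = ",")), ft)
  back2 <- read_roi(ft)
  expect_equal(unname(back2$polygon), unname(poly))
  # identical rasterization whichever container carried the polygon
  expect_identical(roi_to_mask(back, c(16, 16)), roi_to_mask(back2, c(16, 16)))
})

test_that("write_table is deterministic, sorted, and round-trips exactly", {
  recs <- rbind(
    quant_record("img2", "azot", 200, 30),
    quant_record("img1", "TUNEL", 180, 10,
                 partner_signal = "azot", overlap_area_px = 4,
                 overlap_percent = 4 / 180 * 100),
    quant_record("img1", "azot", 180, 25.5))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_table(recs, f1); write_table(recs, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_table_csv(f1)
  expect_identical(nrow(back), 3L)
  expect_identical(back$image_id, c("img1", "img1", "img2"))  # sorted
  # field-for-field value recovery, including non-terminating decimals
  key <- paste(back$image_id, back$signal)
  orig <- recs[order(recs$image_id, recs$signal), ]
  expect_identical(back$area_percent, orig$area_percent)
  expect_equal(as.numeric(back$overlap_area_px[key == "img1 TUNEL"]), 4)

  # empty record list -> header-only file
  fe <- tempfile(fileext = ".csv")
  write_table(recs[0, ], fe)
  expect_length(readLines(fe), 1L)
  expect_identical(nrow(read_table_csv(fe)), 0L)
})
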