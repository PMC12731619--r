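# segmentation: thresholding, labeling, size filtering.

test_that("binarize_probability uses strict inequality", {
  m <- matrix(c(0.00, 0.04, 0.06, 0.05), 2, 2)
  b <- binarize_probability(m, 0.05)
  expect_identical(as.vector(b), c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(as.vector(binarize_probability(m, 0.1)),
                   rep(FALSE, 4))  # 0.1 threshold excludes everything here
  # boundaries
  expect_true(binarize_probability(matrix(1e-9, 1, 1), 0)[1, 1])
  expect_false(any(binarize_probability(matrix(1, 2, 2), 1)))
  expect_error(binarize_probability(m, 1.5), "\\[0, 1\\]")
})

test_that("label_objects respects connectivity and is deterministic", {
  b <- matrix(FALSE, 4, 4)
  b[1, 1] <- TRUE; b[2, 2] <- TRUE  # diagonal touch
  expect_identical(nrow(label_objects(b, 8L)$objects), 1L)
  expect_identical(nrow(label_objects(b, 4L)$objects), 2L)
  # label order follows raster order of first pixels
  b2 <- matrix(FALSE, 3, 5)
  b2[3, 1] <- TRUE; b2[1, 4] <- TRUE
  lab <- label_objects(b2, 8L)$labels
  expect_identical(lab[1, 4], 1L)  # row-major raster: (1,4) before (3,1)
  expect_identical(lab[3, 1], 2L)
})

test_that("label_objects matches the flood-fill oracle on random grids", {
  set.seed(7)
  for (i in 1:60) {
    b <- random_binary_matrix(12, 12, p = runif(1, 0.2, 0.7))
    for (conn in c(4L, 8L)) {
      got <- label_objects(b, conn)$labels
      want <- oracle_flood_fill(b, conn)
      expect_identical(label_partition(got), label_partition(want))
    }
  }
})

test_that("minimum-size filter keeps the boundary object", {
  # a 16-px object dies under min size 17; a 17-px object survives
  mk <- function(npx) {
    b <- matrix(FALSE, 10, 10)
    b[cbind((seq_len(npx) - 1) %% 5 + 1, (seq_len(npx) - 1) %/% 5 + 1)] <- TRUE
    label_objects(b, 8L)
  }
  expect_identical(nrow(filter_min_size(mk(16), 17)$objects), 0L)
  expect_identical(nrow(filter_min_size(mk(17), 17)$objects), 1L)
  expect_identical(filter_min_size(mk(17), 17)$objects$area_px, 17L)
  # min_size 1 is the identity
  om <- mk(16)
  expect_identical(filter_min_size(om, 1)$labels, om$labels)
  # survivors are relabeled consecutively preserving order
  b <- matrix(FALSE, 6, 12)
  b[1:2, 1:2] <- TRUE        # 4 px, label 1
  b[1, 6] <- TRUE            # 1 px, label 2
  b[4:5, 9:10] <- TRUE       # 4 px, label 3
  fil <- filter_min_size(label_objects(b, 8L), 2)
  expect_identical(fil$objects$label, c(1L, 2L))
  expect_identical(unique(as.vector(fil$labels[4:5, 9:10])), 2L)
})

test_that("segment composes threshold, labeling and size filter", {
  probs <- matrix(0, 32, 32)
  ctr <- expand.grid(r = 1:32, c = 1:32)
  disk <- (ctr$r - 16)^2 + (ctr$c - 16)^2 <= 9.5  # 30-ish px disk
  probs[cbind(ctr$r[disk], ctr$c[disk])] <- 1
  npx <- sum(disk)
  om <- segment(probability_mask(probs), segmentation_params(0.05, 17))
  expect_identical(nrow(om$objects), 1L)
  expect_identical(om$objects$area_px, as.integer(npx))
  # min size above the object area removes it
  om2 <- segment(probability_mask(probs), segmentation_params(0.05, npx + 1))
  expect_identical(nrow(om2$objects), 0L)
  # object table is consistent with the label grid
  expect_identical(sum(om$labels > 0), sum(om$objects$area_px))
})

test_that("object_mean mode drops weak objects that pixel mode keeps", {
  probs <- matrix(0, 20, 40)
  probs[5:10, 3:8] <- 0.9    # strong object
  probs[5:10, 20:25] <- 0.3  # weak object: above 0.25 floor, mean <= 0.5
  pm <- probability_mask(probs)
  pixel <- segment(pm, segmentation_params(0.25, 17, probability_mode = "pixel"))
  objm <- segment(pm, segmentation_params(0.5, 17, probability_mode = "object_mean"))
  expect_identical(nrow(pixel$objects), 2L)
  expect_identical(nrow(objm$objects), 1L)
  expect_gt(objm$objects$mean_probability, 0.5)
})

test_that("intensity reference segmentation matches probability segmentation on a perfect pair", {
  img <- matrix(0, 24, 24)
  img[4:9, 4:9] <- 100; img[15:20, 12:17] <- 100
  probs <- (img > 0) * 1.0
  ref <- intensity_segment_reference(img, 50, min_size_px = 17)
  auto <- segment(probability_mask(probs), segmentation_params(0.05, 17))
  expect_identical(ref$labels, auto$labels)
  # threshold above the maximum -> nothing; threshold 0 on positive image -> one object
  expect_identical(nrow(intensity_segment_reference(img, 101)$objects), 0L)
  allpos <- matrix(5, 6, 6)
  expect_identical(nrow(intensity_segment_reference(allpos, 0)$objects), 1L)
  expect_identical(intensity_segment_reference(allpos, 0)$objects$area_px, 36L)
})

test_that("labeled area is monotone in the thresholds", {
  set.seed(19)
  for (i in 1:20) {
    probs <- matrix(runif(400), 20, 20)
    thr <- sort(runif(3))
    areas <- vapply(thr, function(t)
      sum(segment(probability_mask(probs),
                  segmentation_params(t, 1))$labels > 0), 0L)
    expect_true(all(diff(areas) <= 0))
    sizes <- sort(sample(1:8, 3))
    counts <- vapply(sizes, function(s)
      nrow(segment(probability_mask(probs),
                   segmentation_params(0.5, s))$objects), 0L)
    expect_true(all(diff(counts) <= 0))
  }
})
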