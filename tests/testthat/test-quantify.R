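# quantify: ROI-normalized area, colocalization, CTCF, method agreement.

make_map <- function(shape, ...) {
  # build a labeled_object_map from pixel index lists
  b <- matrix(FALSE, shape[1], shape[2])
  for (px in list(...)) b[px] <- TRUE
  label_objects(b, 8L)
}

test_that("area_fraction counts only ROI pixels", {
  roi <- matrix(FALSE, 20, 20); roi[1:10, 1:20] <- TRUE  # 200 px
  b <- matrix(FALSE, 20, 20)
  b[1:5, 1:6] <- TRUE    # 30 px inside ROI
  b[15:19, 1] <- TRUE    # 5 px outside
  sq <- area_fraction(label_objects(b, 8L), roi)
  expect_identical(sq$roi_area_px, 200L)
  expect_identical(sq$signal_area_px, 30L)
  expect_equal(sq$area_percent, 15.0)
  # zero and full coverage
  expect_equal(area_fraction(label_objects(matrix(FALSE, 20, 20), 8L), roi)$area_percent, 0)
  expect_equal(area_fraction(label_objects(roi, 8L), roi)$area_percent, 100)
  expect_error(area_fraction(label_objects(b, 8L), roi & FALSE), "empty")
})

test_that("colocalize distinguishes partial from total containment", {
  # constructed 6x6 scene, checked exhaustively by hand-computable pixel sets:
  # A1 fully inside B, A2 half inside B, A3 disjoint from B
  A <- matrix(FALSE, 6, 6); B <- matrix(FALSE, 6, 6)
  A[1:2, 1:2] <- TRUE            # A1: 4 px
  A[5, 1:4] <- TRUE              # A2: 4 px
  A[1:2, 5:6] <- TRUE            # A3: 4 px
  B[1:3, 1:3] <- TRUE            # covers A1 entirely
  B[5, 1:2] <- TRUE              # covers half of A2
  roi <- matrix(TRUE, 6, 6)
  mA <- label_objects(A, 8L); mB <- label_objects(B, 8L)
  partial <- colocalize(mA, mB, roi, "partial")
  total <- colocalize(mA, mB, roi, "total")
  expect_identical(partial$overlap_area_px, 6L)   # 4 (A1) + 2 (A2)
  expect_identical(partial$n_A_objects_colocalized, 2L)
  expect_identical(total$n_A_objects_colocalized, 1L)
  expect_identical(partial$n_A_objects_total, 3L)
  expect_equal(partial$overlap_percent_of_roi, 100 * 6 / 36)
  # disjoint channels
  none <- colocalize(mA, label_objects(matrix(FALSE, 6, 6), 8L), roi)
  expect_identical(none$overlap_area_px, 0L)
  expect_identical(none$n_A_objects_colocalized, 0L)
})

test_that("overlap area is symmetric and bounded by single-signal areas", {
  set.seed(23)
  for (i in 1:20) {
    A <- label_objects(random_binary_matrix(15, 15, 0.35), 8L)
    B <- label_objects(random_binary_matrix(15, 15, 0.35), 8L)
    roi <- random_binary_matrix(15, 15, 0.8)
    if (!any(roi)) next
    ab <- colocalize(A, B, roi); ba <- colocalize(B, A, roi)
    expect_identical(ab$overlap_area_px, ba$overlap_area_px)
    fa <- area_fraction(A, roi); fb <- area_fraction(B, roi)
    expect_lte(ab$overlap_percent_of_roi, min(fa$area_percent, fb$area_percent))
    expect_lte(ab$n_A_objects_colocalized, ab$n_A_objects_total)
  }
})

test_that("ctcf satisfies its defining identity and invariances", {
  img <- matrix(0, 10, 10)
  cell <- matrix(FALSE, 10, 10); cell[1:5, 1:10] <- TRUE   # 50 px
  bg <- matrix(FALSE, 10, 10); bg[8:10, 1:10] <- TRUE
  img[cell] <- 20; img[bg] <- 2
  r <- ctcf(img, cell, bg)
  expect_equal(r$integrated_density, 1000)
  expect_equal(r$background_mean, 2)
  expect_equal(r$ctcf, 1000 - 50 * 2)
  # uniform image -> 0; zero background -> integrated density
  expect_equal(ctcf(matrix(7, 10, 10), cell, bg)$ctcf, 0)
  img0 <- img; img0[bg] <- 0
  expect_equal(ctcf(img0, cell, bg)$ctcf, 1000)
  # fuzzed identity + shift invariance
  set.seed(3)
  for (i in 1:20) {
    im <- matrix(runif(100, 0, 50), 10, 10)
    r1 <- ctcf(im, cell, bg)
    expect_equal(r1$ctcf, r1$integrated_density - r1$cell_area_px * r1$background_mean)
    r2 <- ctcf(im + 5, cell, bg)
    expect_equal(r2$ctcf, r1$ctcf)
  }
  expect_error(ctcf(img, cell, cell), "overlap")
  expect_error(ctcf(img, matrix(FALSE, 10, 10), bg), "empty")
})

test_that("method_agreement handles identity and extra objects", {
  m <- make_map(c(8, 8), cbind(1:3, 1:3), cbind(6:7, 6))
  idem <- method_agreement(m, m)
  expect_identical(idem$n_matched, 2L)
  expect_identical(idem$n_only_reference, 0L)
  expect_identical(idem$n_only_automated, 0L)
  m2 <- make_map(c(8, 8), cbind(1:3, 1:3), cbind(6:7, 6), cbind(8, 1:2))
  extra <- method_agreement(m, m2)
  expect_identical(extra$n_matched, 2L)
  expect_identical(extra$n_only_automated, 1L)
})

test_that("method_agreement equals the exhaustive maximum-matching oracle", {
  set.seed(31)
  for (i in 1:30) {
    # small scenes, <= 6 objects each side
    R <- label_objects(random_binary_matrix(9, 9, 0.25), 8L)
    A <- label_objects(random_binary_matrix(9, 9, 0.25), 8L)
    nR <- nrow(R$objects); nA <- nrow(A$objects)
    if (nR > 6 || nA > 6) next
    ma <- method_agreement(R, A)
    inc <- matrix(FALSE, nR, nA)
    for (r in seq_len(nR)) for (a in seq_len(nA))
      inc[r, a] <- any(R$labels == r & A$labels == a)
    expect_identical(ma$n_matched, oracle_max_matching(inc))
    expect_identical(ma$n_only_reference, nR - ma$n_matched)
    expect_identical(ma$n_only_automated, nA - ma$n_matched)
  }
})
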