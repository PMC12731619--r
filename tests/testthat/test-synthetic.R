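# synthetic generators: determinism, ground-truth consistency, closed loops.

test_that("scene generation is deterministic and truth matches the render", {
  sp <- scene_spec(overlap_fraction = 0.5, seed = 21)
  s1 <- generate_scene(sp); s2 <- generate_scene(sp)
  expect_identical(s1$masks$azot$probs, s2$masks$azot$probs)
  expect_identical(s1$truth$labels, s2$truth$labels)
  s3 <- generate_scene(scene_spec(overlap_fraction = 0.5, seed = 22))
  expect_false(identical(s1$truth$labels, s3$truth$labels))
  # rendered binary mask == ground-truth labels, pixel for pixel
  for (ch in 1:2) {
    expect_identical(unname(s1$masks[[ch]]$probs == 1),
                     unname(s1$truth$labels[[ch]] > 0))
    expect_identical(as.integer(tabulate(s1$truth$labels[[ch]])),
                     as.integer(s1$truth$areas[[ch]]))
  }
  expect_identical(
    sum(s1$truth$labels[[1]] > 0 & s1$truth$labels[[2]] > 0),
    as.integer(s1$truth$overlap_area_px))
})

test_that("engineered overlap hits its endpoints exactly", {
  s0 <- generate_scene(scene_spec(overlap_fraction = 0, seed = 2))
  expect_identical(as.integer(s0$truth$overlap_area_px), 0L)
  roi <- matrix(TRUE, 128, 128)
  cq0 <- colocalize(segment(s0$masks[[1]], segmentation_params(0.1, 17)),
                    segment(s0$masks[[2]], segmentation_params(0.05, 17)), roi)
  expect_identical(cq0$overlap_area_px, 0L)

  s1 <- generate_scene(scene_spec(overlap_fraction = 1, seed = 2))
  # matched radii: full overlap equals the smaller (= equal) object areas
  expect_identical(as.integer(s1$truth$overlap_area_px),
                   as.integer(sum(s1$truth$areas[[2]])))
})

test_that("an over-dense scene errors rather than looping forever", {
  sp <- scene_spec(shape = c(24L, 24L),
                   channels = list(list(name = "a", n_objects = 40L,
                                        radius = 4, prob = 1, intensity = 10)),
                   overlap_pair = NULL)
  expect_error(generate_scene(sp), "placement failed")
})

test_that("trajectory generator matches its analytic activity value", {
  # 300 s at 3 mm/s: everything above 2.7
  g <- generate_trajectory(trajectory_spec(seed = 1))
  expect_equal(analytic_time_above(g, 2.7), 300)
  a <- activity_above_threshold(g$trajectory)
  expect_equal(a$time_above_s, analytic_time_above(g, 2.7))
  # immobile run of 61 s is excluded by QC
  g61 <- generate_trajectory(trajectory_spec(
    immobile_runs = data.frame(start_s = 50, length_s = 61), seed = 1))
  expect_true(activity_above_threshold(g61$trajectory)$excluded)
  # determinism
  ga <- generate_trajectory(trajectory_spec(seed = 8))
  gb <- generate_trajectory(trajectory_spec(seed = 8))
  expect_identical(ga$trajectory$x, gb$trajectory$x)
  # invalid recipes rejected
  expect_error(trajectory_spec(segments = data.frame(length_s = 100,
                                                     speed_mm_s = 1)),
               "tile")
  expect_error(trajectory_spec(duration_s = 1, dt_s = 0.3,
                               segments = data.frame(length_s = 1,
                                                     speed_mm_s = 1)),
               "multiples")
})

test_that("generate_groups is deterministic and shift-sensitive", {
  g1 <- generate_groups(3, 10, seed = 6)
  g2 <- generate_groups(3, 10, seed = 6)
  expect_identical(g1, g2)
  expect_identical(lengths(unclass(g1)), c(group1 = 10L, group2 = 10L,
                                           group3 = 10L))
  # large shifts are detected essentially always
  gs <- generate_groups(3, 10, shift = c(0, 5, 10), seed = 6)
  expect_lt(kruskal_wallis(gs)$p_value, 1e-4)
})

test_that("scene fixtures written to disk reproduce in-memory quantification", {
  sc <- generate_scene(scene_spec(overlap_fraction = 0.5, seed = 12))
  d <- tempfile()
  paths <- write_scene_fixtures(sc, d, image_id = "t1")
  pm <- read_raster(paths$mask_azot, "probability")
  expect_equal(pm$probs, sc$masks$azot$probs, tolerance = 1e-7)
  roi <- roi_to_mask(read_roi(paths$roi), dim(pm$probs))
  om_disk <- segment(pm, segmentation_params(0.1, 17))
  om_mem <- segment(sc$masks$azot, segmentation_params(0.1, 17))
  expect_identical(om_disk$labels, om_mem$labels)
  truth <- read_table_csv(paths$truth)
  expect_equal(as.numeric(truth$total_area_px),
               vapply(sc$truth$areas, function(a) sum(as.numeric(a)), 0))
})
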