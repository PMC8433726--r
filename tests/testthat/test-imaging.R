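test_that("a clean disk segments to one object of the analytic area", {
  prof <- cell_type_profile("THP1", mean_area = pi * 20^2, shape_class = "round", area_cv = 0)
  img <- synthesize_micrograph(prof, counts = c(THP1 = 1),
    image_shape = c(128, 128), pixel_size = 1, seed = 2
  )
  seg <- segment_cells(img)
  expect_equal(seg$n_objects, 1)
  expect_equal(seg$areas$pixels, 1256.6, tolerance = 0.05)
})

test_that("thresholding edge cases behave as specified", {
  blank <- matrix(0.5, 32, 32)
  expect_error(segment_cells(blank), "blank image")
  seg <- segment_cells(blank, threshold_policy = "fixed", threshold_value = 0.9)
  expect_equal(seg$n_objects, 0)
  expect_error(segment_cells(blank, threshold_policy = "fixed"), "threshold_value")
})

test_that("labelling is 8-connected and respects the size filter", {
  m <- matrix(0, 8, 8)
  m[2, 2] <- 1
  m[3, 3] <- 1 # touches only diagonally
  seg <- segment_cells(m, threshold_policy = "fixed", threshold_value = 0.5,
                       min_object_size = 0)
  expect_equal(seg$n_objects, 1)

  m[6, 6] <- 1 # isolated single pixel
  seg2 <- segment_cells(m, threshold_policy = "fixed", threshold_value = 0.5,
                        min_object_size = 0)
  expect_equal(seg2$n_objects, 2)
  seg3 <- segment_cells(m, threshold_policy = "fixed", threshold_value = 0.5,
                        min_object_size = 2)
  expect_equal(seg3$n_objects, 1) # the lone pixel is filtered out
})

test_that("segmented areas match generator ground truth on noise-free images", {
  img <- synthesize_micrograph(default_cell_profiles(), counts = 8,
    image_shape = c(600, 600), pixel_size = 1, seed = 13
  )
  seg <- segment_cells(img)
  expect_equal(seg$n_objects, nrow(img$truth_areas))
  # area conservation after filtering
  expect_equal(sum(seg$areas$pixels), sum(seg$label_mask > 0L))

  # per-object pixel counts agree with the generator's ground truth
  # (noise-free, clean contrast: the mask is recovered exactly)
  labelled <- label_objects_by_truth(seg, img)
  expect_true(all(!is.na(labelled$cell_type)))
  expect_equal(sort(labelled$pixels), sort(img$truth_areas$pixels))
  expect_equal(
    sort(labelled$area_um2[labelled$cell_type == "MAC"]),
    sort(img$truth_areas$area_um2[img$truth_areas$cell_type == "MAC"])
  )
})

test_that("physical areas scale with the square of the pixel size", {
  m <- matrix(0, 32, 32)
  m[5:14, 5:14] <- 1 # 100 px square
  seg <- segment_cells(m, threshold_policy = "fixed", threshold_value = 0.5)
  expect_equal(measure_areas(seg, pixel_size = 0.5)$area_um2, 25) # 100 x 0.25
  expect_equal(measure_areas(seg, pixel_size = 1)$area_um2, seg$areas$pixels)
  expect_equal(
    measure_areas(seg, pixel_size = 2)$area_um2,
    4 * measure_areas(seg, pixel_size = 1)$area_um2
  )
  expect_error(measure_areas(seg, pixel_size = 0), "pixel_size")

  # random masks: areas equal brute-force pixel counts times the scale
  set.seed(21)
  rnd <- matrix(as.numeric(runif(900) > 0.7), 30, 30)
  seg_r <- segment_cells(rnd, threshold_policy = "fixed", threshold_value = 0.5,
                         min_object_size = 0)
  a <- measure_areas(seg_r, pixel_size = 1.5)
  oracle <- tabulate(seg_r$label_mask[seg_r$label_mask > 0L]) * 1.5^2
  expect_equal(a$area_um2, oracle)
})

test_that("type area comparisons reproduce hand arithmetic and detect identity", {
  areas <- list(
    THP1 = c(10, 12, 14),
    DC = c(20, 22, 24)
  )
  cmp <- compare_type_areas(areas)
  expect_equal(cmp$ordering, c("DC", "THP1"))
  s <- cmp$summary
  expect_equal(s$mean_um2[s$cell_type == "THP1"], 12)
  expect_equal(s$sem_um2[s$cell_type == "THP1"], sd(c(10, 12, 14)) / sqrt(3))

  same <- compare_type_areas(list(A = c(5, 6, 7), B = c(5, 6, 7)))
  expect_equal(same$pairwise$p_value, 1)

  expect_error(compare_type_areas(list(A = c(1, 2), B = 3)), ">= 2 cells")
})

test_that("mean-area ordering MAC > DC > THP1 is recovered from synthetic micrographs", {
  pooled <- list()
  for (k in 1:2) {
    img <- synthesize_micrograph(default_cell_profiles(), counts = 20,
      image_shape = c(800, 800), pixel_size = 1, seed = 100 + k
    )
    seg <- segment_cells(img)
    pooled[[k]] <- label_objects_by_truth(seg, img)
  }
  all_areas <- do.call(rbind, pooled)
  cmp <- compare_type_areas(all_areas[!is.na(all_areas$cell_type), ])
  expect_equal(cmp$ordering, c("MAC", "DC", "THP1"))
  expect_true(all(cmp$pairwise$significant))
})
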