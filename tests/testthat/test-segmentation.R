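uniform_img <- function(rgb, nr = 8, nc = 8) {
  a <- array(0, c(nr, nc, 3))
  for (k in 1:3) a[, , k] <- rgb[k]
  a
}

test_that("channel thresholding keeps green, rejects blue, validates config", {
  green <- build_channel_stack(uniform_img(c(40, 180, 50)))
  expect_true(all(channel_threshold_mask(green, seg_config())))
  blue <- build_channel_stack(uniform_img(c(50, 60, 160)))
  expect_false(any(channel_threshold_mask(blue, seg_config())))
  brown <- build_channel_stack(uniform_img(c(110, 85, 60)))
  expect_false(any(channel_threshold_mask(brown, seg_config())))
  expect_error(seg_config(hue_window = c(120, 35)), "degenerate")
})

test_that("enlarging the hue window never shrinks the thresholded mask", {
  set.seed(11)
  img <- array(round(runif(16 * 16 * 3, 0, 255)), c(16, 16, 3))
  st <- build_channel_stack(img)
  narrow <- channel_threshold_mask(st, seg_config(hue_window = c(50, 100)))
  wide <- channel_threshold_mask(st, seg_config(hue_window = c(35, 120)))
  expect_true(all(wide[narrow]))
})

test_that("median denoise matches the brute-force oracle and its examples", {
  m <- random_mask(1)
  expect_identical(median_denoise(m, 0), m)

  speck <- matrix(FALSE, 9, 9); speck[5, 5] <- TRUE
  expect_false(any(median_denoise(speck, 1)))

  # solid block: edges and interior survive the majority; the four
  # corners (only 4 true neighbors of 9) are shaved, per the oracle
  block <- matrix(FALSE, 11, 11); block[4:8, 4:8] <- TRUE
  med <- median_denoise(block, 1)
  expect_identical(med, oracle_median(block, 1))
  expect_true(all(med[5:7, 4:8]) && all(med[4:8, 5:7]))

  for (s in 1:20) {
    m <- random_mask(s)
    expect_identical(median_denoise(m, 1), oracle_median(m, 1))
  }
  expect_identical(median_denoise(random_mask(3), 2),
                   oracle_median(random_mask(3), 2))
  expect_error(median_denoise(m, -1), ">= 0")
})

test_that("opening removes specks, preserves blocks, and is idempotent", {
  speck <- matrix(FALSE, 7, 7); speck[4, 4] <- TRUE
  expect_false(any(morphological_refine(speck, seg_config())))

  block <- matrix(FALSE, 14, 14); block[3:12, 3:12] <- TRUE
  opened <- morphological_refine(block, seg_config())
  expect_identical(opened,
                   oracle_dilate(oracle_erode(block, 3), 3))
  expect_identical(opened, block)

  cfg0 <- seg_config(morph_iterations = 0)
  m <- random_mask(5)
  expect_identical(morphological_refine(m, cfg0), m)

  once <- morphological_refine(m, seg_config())
  expect_identical(morphological_refine(once, seg_config()), once)
})

test_that("erosion is anti-extensive and dilation extensive vs the set oracle", {
  for (s in 1:25) {
    m <- random_mask(s)
    er <- phenoscan:::erode_square(m, 3)
    di <- phenoscan:::dilate_square(m, 3)
    expect_identical(er, oracle_erode(m, 3))
    expect_identical(di, oracle_dilate(m, 3))
    expect_true(all(m[er]))   # erosion subset of mask
    expect_true(all(di[m]))   # mask subset of dilation
  }
})

test_that("hole filling matches flood fill from the border and is idempotent", {
  sq <- matrix(FALSE, 9, 9); sq[3:7, 3:7] <- TRUE; sq[5, 5] <- FALSE
  filled <- fill_holes(sq)
  expect_true(filled[5, 5])
  expect_identical(filled, oracle_fill_holes(sq))

  expect_false(any(fill_holes(matrix(FALSE, 6, 6))))

  ring <- matrix(FALSE, 11, 11)
  ring[3, 3:9] <- TRUE; ring[9, 3:9] <- TRUE; ring[3:9, 3] <- TRUE; ring[3:9, 9] <- TRUE
  disk <- fill_holes(ring)
  expect_identical(disk, oracle_fill_holes(ring))
  expect_true(all(disk[4:8, 4:8]))

  for (s in 1:15) {
    m <- random_mask(s, p = 0.55)
    f <- fill_holes(m)
    expect_identical(f, oracle_fill_holes(m))
    expect_identical(fill_holes(f), f)
  }
})

test_that("small-component removal respects 8-connectivity", {
  m <- matrix(FALSE, 10, 10)
  m[2:5, 2:5] <- TRUE        # 16 px component
  m[7, 7] <- TRUE; m[8, 8] <- TRUE  # diagonal pair: one 2-px component
  out <- remove_small_components(m, 3)
  expect_true(all(out[2:5, 2:5]))
  expect_false(out[7, 7] || out[8, 8])
  keep2 <- remove_small_components(m, 2)
  expect_true(keep2[7, 7] && keep2[8, 8])  # diagonal neighbors join up
})

test_that("full segmentation recovers a synthetic seedling and is deterministic", {
  sc <- generate_seedling_image(3, image_size = c(256, 256), base_row = 230,
                                blade_length_px = c(80, 150),
                                noise_rate = 0.002)
  m1 <- segment_plant(sc$image)
  m2 <- segment_plant(sc$image)
  expect_identical(m1, m2)
  expect_gte(scene_f1(m1, sc$truth_mask), 0.95)

  # salt noise in the background never survives the refinement chain:
  # any surviving foreground sits on (or immediately against) the plant
  near_truth <- phenoscan:::dilate_square(sc$truth_mask, 5)
  expect_false(any(m1 & !near_truth))

  bg <- uniform_img(c(110, 85, 60), 32, 32)
  expect_false(any(segment_plant(bg)))
})
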