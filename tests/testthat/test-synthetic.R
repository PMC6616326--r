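test_that("scene generation is deterministic with consistent ground truth", {
  s1 <- generate_seedling_image(5, image_size = c(200, 200), base_row = 180,
                                blade_length_px = c(60, 120), noise_rate = 0.003)
  s2 <- generate_seedling_image(5, image_size = c(200, 200), base_row = 180,
                                blade_length_px = c(60, 120), noise_rate = 0.003)
  expect_identical(unclass(s1$image), unclass(s2$image))
  expect_identical(s1$truth_mask, s2$truth_mask)

  expect_equal(s1$truth_area_px, pixel_area(s1$truth_mask))
  rows <- which(rowSums(s1$truth_mask) > 0)
  expect_equal(s1$truth_tip_row, min(rows))
  expect_equal(s1$truth_base_row, max(rows))
  expect_equal(projected_height(s1$truth_mask),
               s1$truth_base_row - s1$truth_tip_row + 1L)
})

test_that("a single fixed-length blade spans exactly length + 1 rows", {
  sc <- generate_seedling_image(2, n_blades = 1, blade_length_px = c(200, 200),
                                image_size = c(1000, 400), base_row = 900)
  expect_equal(sc$truth_tip_row, 700)
  expect_equal(sc$truth_base_row, 900)
  expect_equal(projected_height(sc$truth_mask), 201L)
})

test_that("scene parameter violations are rejected", {
  expect_error(generate_seedling_image(1, image_size = c(2000, 2000)),
               "1024")
  expect_error(generate_seedling_image(1, blade_length_px = c(600, 700),
                                       image_size = c(512, 512),
                                       base_row = 460),
               "frame")
  expect_error(generate_seedling_image(1, n_blades = 9), "blades")
})

test_that("RIL simulation is reproducible and obeys its design constants", {
  p1 <- simulate_ril_population(8, n_lines = 30)
  p2 <- simulate_ril_population(8, n_lines = 30)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_identical(p1$records, p2$records)

  expect_equal(nrow(p1$map), 224)
  expect_equal(length(unique(p1$map$chromosome)), 12)
  expect_equal(dim(p1$genotypes), c(30, 224))
  expect_equal(nrow(p1$records), 30 * 8)
  expect_true(all(p1$genotypes %in% c(0, 1)))
})

test_that("perfect heritability separates line means into two QTL clusters", {
  pop <- simulate_ril_population(3, n_lines = 50, heritability = 1,
                                 qtl = data.frame(chromosome = "1",
                                                  position_cM = 45, effect = 5))
  means <- least_square_means(pop$records, "PH_mm")
  vals <- sort(unique(round(means$lsmean, 9)))
  expect_equal(length(vals), 2)
  expect_equal(diff(vals), 10)  # 2 x additive effect between homozygotes
})

test_that("marker allele frequencies and recombination match the model", {
  map2 <- data.frame(marker = c("m1", "m2"), chromosome = "1",
                     position_cM = c(0, 10), stringsAsFactors = FALSE)
  pop <- simulate_ril_population(12, n_lines = 10000, map = map2, qtl = NULL)
  g <- pop$genotypes
  expect_lt(abs(mean(g[, 1]) - 0.5), 0.05)
  expect_lt(abs(mean(g[, 2]) - 0.5), 0.05)
  emp_R <- mean(g[, 1] != g[, 2])
  expect_lt(abs(emp_R - ril_r(10)), 0.01)
})

test_that("planted QTL must sit on the map", {
  expect_error(
    simulate_ril_population(1, qtl = data.frame(chromosome = "1",
                                                position_cM = 500, effect = 1)),
    "off the map")
})

test_that("study fixture matches the reference design shape", {
  fx <- generate_study_fixture(2, n_scenes = 4, image_size = c(160, 160))
  expect_equal(length(unique(fx$records$line_id)), 162)
  expect_equal(max(fx$records$replicate), 8)
  expect_equal(length(unique(fx$map$chromosome)), 12)
  expect_equal(nrow(fx$map), 224)
  expect_setequal(unique(fx$records$trait), c("PH_mm", "FW_g"))
  expect_length(fx$scenes, 4)
  expect_equal(fx$planted_qtl$PH_mm$chromosome, c("1", "4", "12"))
  expect_equal(fx$planted_qtl$FW_g$chromosome, "1")

  fx2 <- generate_study_fixture(2, n_scenes = 4, image_size = c(160, 160))
  expect_identical(fx$records, fx2$records)
  expect_identical(unclass(fx$scenes[[3]]$image), unclass(fx2$scenes[[3]]$image))
})

test_that("fixture genetic values carry the planted trait correlation", {
  in_band <- vapply(1:5, function(s) {
    fx <- generate_study_fixture(s, n_scenes = 0)
    r <- stats::cor(fx$genetic_values[, "PH_mm"], fx$genetic_values[, "FW_g"])
    # Fisher-z 95% sampling band around the planted 0.66 at n = 162
    abs(atanh(r) - atanh(0.66)) < 1.96 / sqrt(162 - 3)
  }, logical(1))
  expect_gte(sum(in_band), 4)
})

test_that("fixture scenes encode the simulated plant heights", {
  fx <- generate_study_fixture(4, n_scenes = 6, image_size = c(176, 176))
  truth_h <- vapply(fx$scenes, function(s)
    s$truth_base_row - s$truth_tip_row + 1L, integer(1))
  expect_equal(truth_h, fx$scene_info$blade_length_px + 1L,
               ignore_attr = TRUE)
})
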