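two_marker_probs <- function(gL, gR, d = 20, step = 10) {
  map <- data.frame(marker = c("mL", "mR"), chromosome = "1",
                    position_cM = c(0, d), stringsAsFactors = FALSE)
  geno <- matrix(c(gL, gR), 1, 2, dimnames = list("L1", NULL))
  conditional_genotype_probs(map, geno, step_cM = step)
}

test_that("map function identities hold", {
  expect_equal(haldane_r(0), 0)
  expect_equal(haldane_r(10), (1 - exp(-0.2)) / 2, tolerance = 1e-12)
  r <- haldane_r(10)
  expect_equal(ril_r(10), 2 * r / (1 + 2 * r), tolerance = 1e-12)
  expect_lt(ril_r(1e4), 0.5 + 1e-9)
})

test_that("conditional genotype probabilities condition correctly on flanks", {
  # at an observed marker the probability is the observed call
  pr <- two_marker_probs(1, 0)
  expect_equal(unname(pr$prob_AA[1, pr$positions$position_cM == 0]), 1)
  expect_equal(unname(pr$prob_AA[1, pr$positions$position_cM == 20]), 0)

  # distance 0 from a single flank: P follows the flank exactly
  map1 <- data.frame(marker = "m", chromosome = "1", position_cM = 0)
  g1 <- matrix(1, 1, 1, dimnames = list("L1", NULL))
  pr1 <- conditional_genotype_probs(map1, g1, step_cM = 1)
  expect_equal(as.vector(pr1$prob_AA), 1)

  # midpoint between two AA markers 20 cM apart: path enumeration oracle
  pr2 <- two_marker_probs(1, 1)
  mid <- pr2$prob_AA[1, pr2$positions$position_cM == 10]
  expect_equal(unname(mid), oracle_ril_prob(1, 1, 10, 10), tolerance = 1e-12)

  # discordant flanks at the midpoint are maximally uncertain
  pr3 <- two_marker_probs(1, 0)
  expect_equal(unname(pr3$prob_AA[1, pr3$positions$position_cM == 10]), 0.5,
               tolerance = 1e-12)

  # off-grid asymmetric point against the oracle
  pr4 <- two_marker_probs(1, 0, d = 20, step = 5)
  expect_equal(unname(pr4$prob_AA[1, pr4$positions$position_cM == 5]),
               oracle_ril_prob(1, 0, 5, 15), tolerance = 1e-12)
})

test_that("genotype class probabilities are proper probabilities", {
  pop <- simulate_ril_population(4, n_lines = 40, map = tiny_map(2, 6),
                                 heritability = 0.5,
                                 qtl = data.frame(chromosome = "1",
                                                  position_cM = 20, effect = 1))
  geno <- pop$genotypes
  geno[sample(length(geno), 30)] <- NA   # knock out calls incl. chromosome ends
  pr <- conditional_genotype_probs(pop$map, geno, step_cM = 2)
  expect_true(all(pr$prob_AA >= 0 & pr$prob_AA <= 1))
  # the two classes are complementary: the oracle with parental roles
  # swapped must give exactly 1 - P(AA)
  for (d in c(2, 7, 13)) {
    pAA <- oracle_ril_prob(1, 0, d, 20 - d)
    pBB <- 1 - pAA
    swap <- oracle_ril_prob(0, 1, 20 - d, d)   # mirror-symmetric case
    expect_equal(pBB + pAA, 1, tolerance = 1e-15)
    expect_equal(swap, pAA, tolerance = 1e-12)
    got <- two_marker_probs(1, 0, d = 20, step = 1)
    expect_equal(unname(got$prob_AA[1, got$positions$position_cM == d]), pAA,
                 tolerance = 1e-12)
  }
})

test_that("heterozygote input codes are recoded missing with a warning", {
  map <- tiny_map(1, 3)
  geno <- matrix(c(1, 0.5, 0), 1, 3, dimnames = list("L1", NULL))
  expect_warning(pr <- conditional_genotype_probs(map, geno, 5),
                 "recoded to missing")
  expect_true(all(pr$prob_AA >= 0 & pr$prob_AA <= 1))
})

test_that("LOD at a fully informative marker equals the closed form", {
  pop <- simulate_ril_population(11, n_lines = 100,
                                 qtl = data.frame(chromosome = "1",
                                                  position_cM = 45, effect = 2),
                                 heritability = 0.5)
  means <- least_square_means(pop$records, "PH_mm")
  pr <- conditional_genotype_probs(pop$map, pop$genotypes, step_cM = 5)
  scan <- interval_mapping_scan(pr, means, "PH_mm")
  # marker at chr 1, 45 cM is observed for every line
  idx <- which(scan$chromosome == "1" & scan$position_cM == 45)
  y <- means$lsmean[match(rownames(pop$genotypes), means$line_id)]
  x <- pop$genotypes[, pop$map$marker[pop$map$chromosome == "1" &
                                        pop$map$position_cM == 45]]
  r2 <- stats::cor(x, y)^2
  expect_equal(scan$lod[idx], (length(y) / 2) * log10(1 / (1 - r2)),
               tolerance = 1e-9)
})

test_that("null phenotypes give a flat near-zero LOD profile", {
  pop <- simulate_ril_population(101, n_lines = 100, qtl = NULL)
  means <- least_square_means(pop$records, "PH_mm")
  pr <- conditional_genotype_probs(pop$map, pop$genotypes, step_cM = 2)
  scan <- interval_mapping_scan(pr, means, "PH_mm")
  expect_true(all(scan$lod >= 0))
  expect_lt(max(scan$lod), 3)  # genome-wide max under the null, typical seed
})

test_that("a phenotype equal to the genotype code maxes out the LOD", {
  pop <- simulate_ril_population(7, n_lines = 60, map = tiny_map(1, 5))
  marker <- pop$map$marker[3]
  means <- data.frame(line_id = rownames(pop$genotypes),
                      lsmean = pop$genotypes[, marker],
                      stringsAsFactors = FALSE)
  pr <- conditional_genotype_probs(pop$map, pop$genotypes, step_cM = 10)
  scan <- interval_mapping_scan(pr, means, "x")
  idx <- which(scan$position_cM == pop$map$position_cM[3])
  # RSS1 floored at 1e-12 * RSS0 -> LOD = (n/2) * 12
  expect_gte(scan$lod[idx], (60 / 2) * 12 - 1e-6)
})

test_that("permutation thresholds are reproducible and quantile-correct", {
  pop <- simulate_ril_population(31, n_lines = 50, map = tiny_map(2, 8),
                                 qtl = NULL)
  means <- least_square_means(pop$records, "PH_mm")
  pr <- conditional_genotype_probs(pop$map, pop$genotypes, step_cM = 5)
  t1 <- permutation_threshold(pr, means, n_perm = 50, seed = 42)
  t2 <- permutation_threshold(pr, means, n_perm = 50, seed = 42)
  expect_identical(t1$threshold_lod, t2$threshold_lod)
  expect_identical(t1$max_lods, t2$max_lods)

  one <- permutation_threshold(pr, means, n_perm = 1, seed = 9)
  expect_equal(one$threshold_lod, one$max_lods[1])

  expect_equal(t1$threshold_lod,
               unname(stats::quantile(t1$max_lods, 0.95, type = 7)))
  expect_error(permutation_threshold(pr, means, n_perm = 10, alpha = 1.5,
                                     seed = 1), "alpha")
  expect_error(permutation_threshold(pr, means, n_perm = 10), "seed")
})

test_that("larger genomes yield permutation thresholds at least as high", {
  wins <- 0
  for (s in 1:20) {
    pop_big <- simulate_ril_population(s, n_lines = 60, qtl = NULL)
    means <- least_square_means(pop_big$records, "PH_mm")
    pr_big <- conditional_genotype_probs(pop_big$map, pop_big$genotypes,
                                         step_cM = 5)
    one_chr <- pop_big$map$chromosome == "1"
    pr_one <- conditional_genotype_probs(pop_big$map[one_chr, ],
                                         pop_big$genotypes[, one_chr],
                                         step_cM = 5)
    thr_big <- permutation_threshold(pr_big, means, n_perm = 60, seed = s)
    thr_one <- permutation_threshold(pr_one, means, n_perm = 60, seed = s)
    if (thr_big$threshold_lod >= thr_one$threshold_lod) wins <- wins + 1
  }
  expect_gte(wins, 19)  # paired seeds; allow one interpolation tie-break
})

test_that("peak calling finds planted architecture and handles empty scans", {
  pop <- simulate_ril_population(13, n_lines = 162,
                                 qtl = data.frame(chromosome = "1",
                                                  position_cM = 45, effect = 1),
                                 heritability = 0.3)
  means <- least_square_means(pop$records, "PH_mm")
  pr <- conditional_genotype_probs(pop$map, pop$genotypes, step_cM = 1)
  scan <- interval_mapping_scan(pr, means, "PH_mm")
  thr <- permutation_threshold(pr, means, n_perm = 100, seed = 2)
  pk <- call_qtl_peaks(scan, thr)
  expect_gte(nrow(pk), 1)
  top <- pk[which.max(pk$peak_lod), ]
  expect_equal(top$chromosome, "1")
  expect_lte(abs(top$peak_cM - 45), 5)
  expect_true(top$ci_low_cM <= top$peak_cM && top$peak_cM <= top$ci_high_cM)
  expect_true(all(pk$peak_lod > thr$threshold_lod))

  # a cutoff above the whole profile yields an empty frame
  empty <- call_qtl_peaks(scan, max(scan$lod) + 1)
  expect_equal(nrow(empty), 0)
})

test_that("additive effect is recovered at the peak", {
  pop <- simulate_ril_population(23, n_lines = 162,
                                 qtl = data.frame(chromosome = "2",
                                                  position_cM = 40, effect = 3),
                                 heritability = 0.5)
  means <- least_square_means(pop$records, "PH_mm")
  pr <- conditional_genotype_probs(pop$map, pop$genotypes, step_cM = 1)
  est <- additive_effect_at(pr, means, "2", 40)
  expect_lt(abs(abs(est) - 3) / 3, 0.25)
})
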