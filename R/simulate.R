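# Synthetic data generators: seedling scenes with per-pixel ground truth
# for the imaging pipeline, and simulated RIL populations with planted
# QTL for the mapping pipeline. All generators are pure functions of
# (seed, parameters).

#' Build an equally spaced RIL genetic map
#'
#' Default geometry: 224 markers over 12 chromosomes — eight chromosomes
#' of 19 markers (0-90 cM at 5 cM spacing) and four of 18 markers
#' (0-85 cM) — mirroring a typical rice RIL map of ~224 PCR-based
#' markers with simple, regular geometry.
#'
#' @param n_chr Number of chromosomes.
#' @param markers_per_chr Integer vector (recycled) of marker counts.
#' @param spacing_cM Distance between adjacent markers.
#' @return A genetic map data.frame (`marker`, `chromosome`,
#'   `position_cM`).
#' @export
make_ril_map <- function(n_chr = 12,
                         markers_per_chr = c(rep(19L, 8), rep(18L, 4)),
                         spacing_cM = 5) {
  counts <- rep_len(as.integer(markers_per_chr), n_chr)
  maps <- lapply(seq_len(n_chr), function(ch) {
    k <- counts[ch]
    data.frame(marker = sprintf("M%02d_%02d", ch, seq_len(k)),
               chromosome = as.character(ch),
               position_cM = (seq_len(k) - 1) * spacing_cM,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, maps)
}

# Simulate RIL genotypes at given loci by a chromosome-wise Markov walk:
# the first locus is AA with probability 1/2 and the parental type flips
# between adjacent loci with probability R(d) = 2r/(1+2r), Haldane r.
.simulate_geno_at_loci <- function(n_lines, loci) {
  # loci: data.frame(chromosome, position_cM), ordered within chromosome
  g <- matrix(NA_real_, n_lines, nrow(loci))
  for (ch in unique(loci$chromosome)) {
    idx <- which(loci$chromosome == ch)
    p <- loci$position_cM[idx]
    g[, idx[1]] <- as.numeric(stats::runif(n_lines) < 0.5)
    if (length(idx) > 1L) for (j in 2:length(idx)) {
      R <- ril_r(p[j] - p[j - 1])
      flip <- stats::runif(n_lines) < R
      g[, idx[j]] <- ifelse(flip, 1 - g[, idx[j - 1]], g[, idx[j - 1]])
    }
  }
  g
}

#' Simulate a RIL population with planted QTL
#'
#' Genotypes follow a chromosome-wise Markov walk with RIL-expanded
#' Haldane recombination between adjacent loci (QTL positions are
#' simulated jointly with the markers, then hidden from the returned
#' genotype matrix). Line genetic values are the sum of planted additive
#' effects on the signed genotype x = +/-1; replicate-level records add
#' Gaussian within-line noise scaled so that the line-mean heritability
#' equals `heritability` in expectation:
#' Ve(line mean) = Vg (1 - h^2)/h^2 with Vg = sum(effect^2) +
#' `polygenic_sd`^2, and the per-replicate noise SD is
#' sqrt(n_reps * Ve).
#'
#' @param seed Integer RNG seed.
#' @param n_lines Number of RILs (the reference design uses 162).
#' @param map Genetic map (default [make_ril_map()], 224 markers).
#' @param qtl NULL for a null trait, or a data.frame with columns
#'   `chromosome`, `position_cM`, `effect` (additive effect, trait
#'   units).
#' @param heritability Line-mean heritability in (0, 1].
#' @param n_reps Replicate plants per line (reference design: 8).
#' @param trait Trait label for the records.
#' @param trait_mean Grand mean added to all values (keeps records
#'   non-negative on realistic scales).
#' @param polygenic_sd SD of an unlinked line-level polygenic term.
#' @param noise_sd Residual SD used when there is no genetic variance
#'   (null trait), for which `heritability` is ignored.
#' @return A list of class `ril_population`: `map`, `genotypes` (lines x
#'   markers, coded 1/0), `qtl`, `genetic_values`, `records` (trait
#'   data.frame), `heritability`, `n_reps`, `seed`.
#' @export
simulate_ril_population <- function(seed, n_lines = 162, map = make_ril_map(),
                                    qtl = NULL, heritability = 0.5, n_reps = 8,
                                    trait = "PH_mm", trait_mean = 100,
                                    polygenic_sd = 0, noise_sd = 1) {
  validate_genetic_map(map)
  if (heritability <= 0 || heritability > 1)
    stop("`heritability` must be in (0, 1]", call. = FALSE)
  if (!is.null(qtl)) {
    for (i in seq_len(nrow(qtl))) {
      chp <- map$position_cM[map$chromosome == qtl$chromosome[i]]
      if (length(chp) == 0L || qtl$position_cM[i] < min(chp) ||
          qtl$position_cM[i] > max(chp))
        stop("planted QTL ", i, " lies off the map", call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  loci <- map[, c("chromosome", "position_cM")]
  loci$kind <- "marker"
  loci$effect <- 0
  if (!is.null(qtl) && nrow(qtl) > 0) {
    loci <- rbind(loci,
                  data.frame(chromosome = as.character(qtl$chromosome),
                             position_cM = qtl$position_cM, kind = "qtl",
                             effect = qtl$effect, stringsAsFactors = FALSE))
  }
  ord <- order(match(loci$chromosome, unique(map$chromosome)), loci$position_cM,
               loci$kind)  # markers before coincident QTL, order stable
  loci <- loci[ord, , drop = FALSE]
  g_all <- .simulate_geno_at_loci(n_lines, loci)
  is_q <- loci$kind == "qtl"
  geno <- g_all[, !is_q, drop = FALSE]
  line_ids <- sprintf("RIL%03d", seq_len(n_lines))
  rownames(geno) <- line_ids
  colnames(geno) <- map$marker
  gv <- if (any(is_q)) {
    as.vector((2 * g_all[, is_q, drop = FALSE] - 1) %*% loci$effect[is_q])
  } else rep(0, n_lines)
  if (polygenic_sd > 0) gv <- gv + stats::rnorm(n_lines, 0, polygenic_sd)
  vg <- sum(loci$effect[is_q]^2) + polygenic_sd^2
  if (vg > 0) {
    ve_mean <- vg * (1 - heritability) / heritability
    rep_sd <- sqrt(n_reps * ve_mean)
  } else {
    rep_sd <- noise_sd
  }
  values <- trait_mean + rep(gv, each = n_reps) +
    if (rep_sd > 0) stats::rnorm(n_lines * n_reps, 0, rep_sd) else 0
  records <- data.frame(line_id = rep(line_ids, each = n_reps),
                        replicate = rep(seq_len(n_reps), times = n_lines),
                        trait = trait, value = values,
                        stringsAsFactors = FALSE)
  structure(
    list(map = map, genotypes = geno, qtl = qtl, genetic_values = gv,
         records = records, heritability = heritability,
         n_reps = as.integer(n_reps), seed = as.integer(seed)),
    class = "ril_population")
}

#' Render a synthetic seedling scene with per-pixel ground truth
#'
#' Draws 1-5 quasi-vertical green blades growing upward from a base row
#' on a non-green (soil-colored) background, with hard color boundaries
#' (no anti-aliasing) and optional single-pixel green salt noise in the
#' background. The exact foreground mask, tip/base rows and pixel area
#' are recorded as ground truth (salt noise is excluded from the truth).
#'
#' A blade of length L px from base row b occupies rows b - L .. b
#' (vertical extent L + 1).
#'
#' @param seed Integer RNG seed.
#' @param n_blades Number of blades (1-5).
#' @param blade_length_px Length-2 range of blade lengths (px).
#' @param blade_width_px Odd blade width in px.
#' @param hue_jitter Half-range of the uniform per-pixel RGB jitter on
#'   blade pixels (0-255 counts).
#' @param background RGB triple of the background color.
#' @param image_size (rows, cols); must be below 1024 x 1024 to keep
#'   scenes fast to render and process.
#' @param base_row Row the blades grow from (row 1 = top).
#' @param noise_rate Fraction of background pixels turned into green
#'   salt noise.
#' @return A list of class `synthetic_scene`: `image` ([rgb_image()]),
#'   `truth_mask`, `truth_tip_row`, `truth_base_row`, `truth_area_px`,
#'   `seed`.
#' @export
generate_seedling_image <- function(seed, n_blades = 3,
                                    blade_length_px = c(150, 300),
                                    blade_width_px = 5, hue_jitter = 15,
                                    background = c(110, 85, 60),
                                    image_size = c(512, 512), base_row = 460,
                                    noise_rate = 0) {
  if (any(image_size > 1024))
    stop("synthetic scenes are capped below 1024 x 1024", call. = FALSE)
  if (n_blades < 1 || n_blades > 5)
    stop("`n_blades` must be between 1 and 5", call. = FALSE)
  if (base_row - max(blade_length_px) < 1 || base_row > image_size[1])
    stop("blade lengths exceed the image frame", call. = FALSE)
  set.seed(as.integer(seed))
  nr <- image_size[1]; nc <- image_size[2]
  mask <- matrix(FALSE, nr, nc)
  hw <- (blade_width_px - 1) %/% 2
  center <- nc / 2
  for (bl in seq_len(n_blades)) {
    len <- round(stats::runif(1, blade_length_px[1], blade_length_px[2]))
    col0 <- round(center + stats::runif(1, -nc / 8, nc / 8))
    slope <- stats::runif(1, -0.25, 0.25)
    for (t in 0:len) {
      r0 <- base_row - t
      cc <- round(col0 + slope * t) + (-hw):hw
      cc <- cc[cc >= 1 & cc <= nc]
      mask[r0, cc] <- TRUE
    }
  }
  # crossing blades can enclose background pockets; the pipeline's
  # target output is the hole-filled silhouette, so the ground truth is
  # the filled silhouette as well (only mask pixels are painted green,
  # so enclosed pockets keep the background color in the rendered image)
  truth <- fill_holes(mask)
  # base colors with hard boundaries
  img <- array(0, dim = c(nr, nc, 3))
  n_px <- nr * nc
  bg_noise <- function(base) pmin(pmax(base +
    stats::runif(n_px, -8, 8), 0), 255)
  img[, , 1] <- bg_noise(background[1])
  img[, , 2] <- bg_noise(background[2])
  img[, , 3] <- bg_noise(background[3])
  paint_green <- function(img, sel, n_sel) {
    jit <- function(base) pmin(pmax(base +
      stats::runif(n_sel, -hue_jitter, hue_jitter), 0), 255)
    ch <- c(60, 170, 50)
    for (k in 1:3) {
      plane <- img[, , k]
      plane[sel] <- jit(ch[k])
      img[, , k] <- plane
    }
    img
  }
  img <- paint_green(img, which(mask), sum(mask))
  if (noise_rate > 0) {
    bg_idx <- which(!mask)
    n_noise <- round(noise_rate * length(bg_idx))
    if (n_noise > 0) {
      sel <- sample(bg_idx, n_noise)
      img <- paint_green(img, sel, n_noise)
    }
  }
  img <- rgb_image(round(img))
  rows <- which(rowSums(truth) > 0)
  structure(
    list(image = img, truth_mask = truth,
         truth_tip_row = min(rows), truth_base_row = max(rows),
         truth_area_px = as.integer(sum(truth)), seed = as.integer(seed)),
    class = "synthetic_scene")
}

#' Generate the paired imaging + mapping study fixture
#'
#' A desk-scale emulation of the full study shape: 162 RILs x 8
#' replicate plants genotyped at 224 markers over 12 chromosomes, with a
#' height-like trait (`PH_mm`, QTL on chromosomes 1, 4 and 12) and a
#' fresh-weight-like trait (`FW_g`, QTL on chromosome 1 only, in the
#' same region). The two traits share the chromosome-1 locus and their
#' genetic values are planted at correlation 0.66; a small independent
#' polygenic term on FW makes that correlation attainable with a single
#' shared locus.
#'
#' A batch of reduced-size seedling scenes is rendered for the first
#' `n_scenes` (line, replicate) pairs, with blade length tied to that
#' plant's simulated height, so the imaging pipeline can be exercised
#' end-to-end against both pixel ground truth and the simulated traits.
#'
#' @param seed Integer RNG seed.
#' @param n_lines,n_reps Population design (defaults 162 x 8).
#' @param heritability Line-mean heritability of both traits.
#' @param n_scenes Number of scenes to render.
#' @param image_size Scene size (rows, cols), kept small for speed.
#' @return A list of class `study_fixture`: `map`, `genotypes`,
#'   `records` (PH_mm and FW_g), `genetic_values` (2-column matrix),
#'   `planted_qtl` (list per trait), `scenes`, `scene_info`
#'   (scene-to-plant bookkeeping incl. rendered blade length), `seed`.
#' @export
generate_study_fixture <- function(seed, n_lines = 162, n_reps = 8,
                                   heritability = 0.8, n_scenes = 16,
                                   image_size = c(192, 192)) {
  map <- make_ril_map()
  qtl_ph <- data.frame(chromosome = c("1", "4", "12"),
                       position_cM = c(45, 45, 40),
                       effect = c(9, 6, 6), stringsAsFactors = FALSE)
  # FW shares the chr-1 locus; effect and polygenic term chosen so that
  # cor(genetic PH, genetic FW) = 0.66 exactly in expectation:
  # cor = b1 * a1 / (sd_gPH * sd_gFW) with sd_gPH = sqrt(81+36+36),
  # sd_gFW fixed at 0.1 g.
  sd_gph <- sqrt(sum(qtl_ph$effect^2))
  sd_gfw <- 0.1
  b1 <- 0.66 * sd_gph * sd_gfw / qtl_ph$effect[1]
  poly_fw <- sqrt(sd_gfw^2 - b1^2)
  qtl_fw <- data.frame(chromosome = "1", position_cM = 45, effect = b1,
                       stringsAsFactors = FALSE)

  set.seed(as.integer(seed))
  loci <- map[, c("chromosome", "position_cM")]
  loci$kind <- "marker"
  extra <- data.frame(chromosome = c("1", "4", "12"),
                      position_cM = c(45, 45, 40), kind = "qtl",
                      stringsAsFactors = FALSE)
  loci <- rbind(loci, extra)
  loci <- loci[order(match(loci$chromosome, unique(map$chromosome)),
                     loci$position_cM, loci$kind), , drop = FALSE]
  g_all <- .simulate_geno_at_loci(n_lines, loci)
  is_q <- loci$kind == "qtl"
  geno <- g_all[, !is_q, drop = FALSE]
  line_ids <- sprintf("RIL%03d", seq_len(n_lines))
  rownames(geno) <- line_ids
  colnames(geno) <- map$marker
  xq <- 2 * g_all[, is_q, drop = FALSE] - 1   # chr1, chr4, chr12 in map order
  q_chr <- loci$chromosome[is_q]
  x1 <- xq[, q_chr == "1"]; x4 <- xq[, q_chr == "4"]; x12 <- xq[, q_chr == "12"]
  gv_ph <- qtl_ph$effect[1] * x1 + qtl_ph$effect[2] * x4 + qtl_ph$effect[3] * x12
  gv_fw <- b1 * x1 + stats::rnorm(n_lines, 0, poly_fw)

  make_records <- function(gv, vg, trait, mean0) {
    ve <- vg * (1 - heritability) / heritability
    rep_sd <- sqrt(n_reps * ve)
    values <- mean0 + rep(gv, each = n_reps) +
      stats::rnorm(n_lines * n_reps, 0, rep_sd)
    data.frame(line_id = rep(line_ids, each = n_reps),
               replicate = rep(seq_len(n_reps), times = n_lines),
               trait = trait, value = pmax(values, 0),
               stringsAsFactors = FALSE)
  }
  rec_ph <- make_records(gv_ph, sd_gph^2, "PH_mm", 200)
  rec_fw <- make_records(gv_fw, sd_gfw^2, "FW_g", 0.8)

  # scenes: blade length follows the plant's simulated height (0.6 px/mm)
  base_row <- image_size[1] - 16
  scene_info <- data.frame(
    line_id = rec_ph$line_id[seq_len(n_scenes)],
    replicate = rec_ph$replicate[seq_len(n_scenes)],
    ph_mm = rec_ph$value[seq_len(n_scenes)], stringsAsFactors = FALSE)
  scene_info$blade_length_px <- round(scene_info$ph_mm * 0.6)
  scenes <- lapply(seq_len(n_scenes), function(i) {
    len <- min(scene_info$blade_length_px[i], base_row - 2)
    generate_seedling_image(seed = seed + i, n_blades = 2,
                            blade_length_px = c(len, len),
                            blade_width_px = 5, image_size = image_size,
                            base_row = base_row, noise_rate = 0.001)
  })
  structure(
    list(map = map, genotypes = geno,
         records = rbind(rec_ph, rec_fw),
         genetic_values = cbind(PH_mm = gv_ph, FW_g = gv_fw),
         planted_qtl = list(PH_mm = qtl_ph, FW_g = qtl_fw),
         scenes = scenes, scene_info = scene_info,
         heritability = heritability, seed = as.integer(seed)),
    class = "study_fixture")
}
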