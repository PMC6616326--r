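# QTL interval mapping on RIL populations: Haldane map function,
# conditional genotype probabilities at pseudo-positions, Haley-Knott
# regression LOD scans, genome-wide permutation thresholds, and peak
# calling with LOD-drop support intervals.
#
# Genotypes are coded 1 = AA (first parent), 0 = BB, NA = missing.
# RILs are treated as fully inbred (F-infinity): no heterozygote class.

#' Haldane map function and RIL-expanded recombination fraction
#'
#' `haldane_r()` converts genetic distance d (cM) to a single-meiosis
#' recombination fraction r = (1 - exp(-2d/100))/2, assuming no
#' interference. `ril_r()` applies the selfed-RIL expansion
#' R = 2r/(1 + 2r), the recombination fraction observable between fully
#' inbred line genotypes after accumulated meioses.
#'
#' @param d_cM Genetic distance(s) in centimorgans, >= 0.
#' @return Recombination fraction(s) in \[0, 0.5).
#' @export
haldane_r <- function(d_cM) {
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' @rdname haldane_r
#' @export
ril_r <- function(d_cM) {
  r <- haldane_r(d_cM)
  2 * r / (1 + 2 * r)
}

validate_genetic_map <- function(map) {
  need <- c("marker", "chromosome", "position_cM")
  if (!is.data.frame(map) || !all(need %in% names(map)))
    stop("map needs columns marker, chromosome, position_cM", call. = FALSE)
  if (anyDuplicated(map$marker))
    stop("marker names must be unique", call. = FALSE)
  for (ch in unique(map$chromosome)) {
    p <- map$position_cM[map$chromosome == ch]
    if (is.unsorted(p)) stop("positions must be non-decreasing within chromosome ",
                             ch, call. = FALSE)
  }
  invisible(map)
}

# Recode heterozygote calls to missing (RILs treated as fully inbred).
sanitize_genotypes <- function(geno) {
  if (!is.matrix(geno)) stop("genotypes must be a lines x markers matrix",
                             call. = FALSE)
  bad <- !(geno %in% c(0, 1)) & !is.na(geno)
  if (any(bad)) {
    warning(sum(bad), " non-homozygous genotype call(s) recoded to missing",
            call. = FALSE)
    geno[bad] <- NA
  }
  geno
}

#' Conditional genotype probabilities at pseudo-positions
#'
#' For each line and each pseudo-position (a step-cM grid along every
#' chromosome, always including the marker positions themselves),
#' computes P(AA) given the nearest informative flanking marker
#' genotypes. The RIL genotype process along a chromosome is treated as
#' Markov with transition probability R(d) = 2r/(1+2r) (Haldane r) of
#' switching parental type over distance d; with both flanks observed,
#' \deqn{P(AA \mid g_L, g_R) = \frac{P(g_L \to AA)\,P(AA \to g_R)}
#'   {P(g_L \to AA)P(AA \to g_R) + P(g_L \to BB)P(BB \to g_R)}}
#' which normalises the two genotype classes to 1 exactly. With one
#' flank the single transition applies; with none, P(AA) = 1/2.
#'
#' @param map Genetic map data.frame (`marker`, `chromosome`,
#'   `position_cM`).
#' @param geno Lines x markers matrix coded 1 = AA, 0 = BB, NA missing;
#'   columns in map order.
#' @param step_cM Positive scan step in cM (default 1).
#' @return A list of class `genotype_probs`: `positions` (data.frame
#'   `chromosome`, `position_cM`) and `prob_AA` (lines x positions
#'   matrix).
#' @export
conditional_genotype_probs <- function(map, geno, step_cM = 1) {
  validate_genetic_map(map)
  if (step_cM <= 0) stop("`step_cM` must be > 0", call. = FALSE)
  geno <- sanitize_genotypes(geno)
  if (ncol(geno) != nrow(map))
    stop("genotype columns must match map markers", call. = FALSE)
  n <- nrow(geno)
  pos_list <- list()
  prob_list <- list()
  for (ch in unique(map$chromosome)) {
    mi <- which(map$chromosome == ch)
    if (length(mi) == 0L) { warning("empty chromosome ", ch, call. = FALSE); next }
    p <- map$position_cM[mi]
    g <- geno[, mi, drop = FALSE]
    grid <- sort(unique(c(seq(p[1], p[length(p)], by = step_cM), p)))
    k <- length(p)
    # forward/backward fill of nearest informative marker index per line
    left_idx <- matrix(NA_integer_, n, k)
    right_idx <- matrix(NA_integer_, n, k)
    cur <- rep(NA_integer_, n)
    for (j in seq_len(k)) {
      cur[!is.na(g[, j])] <- j
      left_idx[, j] <- cur
    }
    cur <- rep(NA_integer_, n)
    for (j in rev(seq_len(k))) {
      cur[!is.na(g[, j])] <- j
      right_idx[, j] <- cur
    }
    probs <- matrix(NA_real_, n, length(grid))
    for (qi in seq_along(grid)) {
      x <- grid[qi]
      jL <- findInterval(x, p)                       # largest marker with pos <= x
      jR <- if (jL < k && p[jL] < x) jL + 1L else jL # smallest with pos >= x
      if (x == p[jR]) jL <- jR
      li <- left_idx[, jL]
      ri <- right_idx[, jR]
      pA <- rep(0.5, n)
      hasL <- !is.na(li); hasR <- !is.na(ri)
      both <- hasL & hasR
      only_l <- hasL & !hasR
      only_r <- hasR & !hasL
      if (any(both)) {
        dL <- x - p[li[both]]
        dR <- p[ri[both]] - x
        gL <- g[cbind(which(both), li[both])]
        gR <- g[cbind(which(both), ri[both])]
        RL <- ril_r(dL); RR <- ril_r(dR)
        tLA <- ifelse(gL == 1, 1 - RL, RL)   # P(gL -> AA)
        tAR <- ifelse(gR == 1, 1 - RR, RR)   # P(AA -> gR)
        tLB <- 1 - tLA                       # P(gL -> BB)
        tBR <- 1 - tAR                       # P(BB -> gR)
        pA[both] <- tLA * tAR / (tLA * tAR + tLB * tBR)
      }
      if (any(only_l)) {
        dL <- x - p[li[only_l]]
        gL <- g[cbind(which(only_l), li[only_l])]
        RL <- ril_r(dL)
        pA[only_l] <- ifelse(gL == 1, 1 - RL, RL)
      }
      if (any(only_r)) {
        dR <- p[ri[only_r]] - x
        gR <- g[cbind(which(only_r), ri[only_r])]
        RR <- ril_r(dR)
        pA[only_r] <- ifelse(gR == 1, 1 - RR, RR)
      }
      probs[, qi] <- pA
    }
    pos_list[[length(pos_list) + 1L]] <-
      data.frame(chromosome = ch, position_cM = grid, stringsAsFactors = FALSE)
    prob_list[[length(prob_list) + 1L]] <- probs
  }
  positions <- do.call(rbind, pos_list)
  prob_AA <- do.call(cbind, prob_list)
  rownames(prob_AA) <- rownames(geno)
  structure(list(positions = positions, prob_AA = prob_AA),
            class = "genotype_probs")
}

# LOD profile of y against each column of X (expected genotype), via the
# single-predictor identity RSS1 = RSS0 (1 - r^2). RSS1 is floored at
# 1e-12 * RSS0 so perfect fits yield a large finite LOD.
.lod_profile <- function(X, y) {
  n <- length(y)
  yc <- y - mean(y)
  ss_y <- sum(yc^2)
  Xc <- sweep(X, 2, colMeans(X))
  ss_x <- colSums(Xc^2)
  r <- as.vector(crossprod(Xc, yc)) / sqrt(pmax(ss_x, .Machine$double.xmin) * ss_y)
  r[ss_x == 0] <- 0
  ratio <- pmax(1 - r^2, 1e-12)
  (n / 2) * log10(1 / ratio)
}

#' Haley-Knott regression LOD scan
#'
#' At each pseudo-position, regresses the per-line trait mean on the
#' expected genotype E\[g\] = P(AA) and converts the fit to a LOD score,
#' LOD = (n/2) log10(RSS0/RSS1). Lines with missing means are dropped;
#' monomorphic positions get LOD 0 with a warning.
#'
#' @param probs A [conditional_genotype_probs()] result.
#' @param line_means Output of [least_square_means()] (or any data.frame
#'   with `line_id` and `lsmean`); line IDs must match the genotype
#'   probability rows.
#' @param trait Trait label carried into the scan object.
#' @return A data.frame of class `qtl_scan` with columns `chromosome`,
#'   `position_cM`, `lod`, and attributes `trait` and `n`.
#' @export
interval_mapping_scan <- function(probs, line_means, trait = "trait") {
  stopifnot(inherits(probs, "genotype_probs"))
  ids <- rownames(probs$prob_AA)
  if (is.null(ids)) stop("genotype probabilities must have line rownames",
                         call. = FALSE)
  m <- match(ids, line_means$line_id)
  y <- line_means$lsmean[m]
  keep <- !is.na(y)
  if (sum(keep) < 10L)
    stop("need at least 10 lines with phenotype and genotype data", call. = FALSE)
  X <- probs$prob_AA[keep, , drop = FALSE]
  if (any(apply(X, 2, stats::sd) == 0))
    warning("monomorphic position(s): LOD set to 0", call. = FALSE)
  lod <- .lod_profile(X, y[keep])
  out <- data.frame(chromosome = probs$positions$chromosome,
                    position_cM = probs$positions$position_cM,
                    lod = lod, stringsAsFactors = FALSE)
  attr(out, "trait") <- trait
  attr(out, "n") <- sum(keep)
  class(out) <- c("qtl_scan", "data.frame")
  out
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the line means across lines `n_perm` times, rescans the
#' genome for each permutation, records the genome-wide maximum LOD, and
#' returns the empirical (1 - alpha) quantile (type-7 interpolation) as
#' the significance threshold. The RNG seed is a required input so
#' thresholds are bit-reproducible.
#'
#' @inheritParams interval_mapping_scan
#' @param n_perm Number of permutations (>= 1; >= 100 recommended for
#'   quantile stability).
#' @param alpha Genome-wide significance level in (0, 1); 0.05 gives the
#'   95% threshold.
#' @param seed Integer RNG seed.
#' @return A list of class `perm_threshold` with `alpha`, `n_perm`,
#'   `threshold_lod`, `seed`, and the vector `max_lods`.
#' @export
permutation_threshold <- function(probs, line_means, trait = "trait",
                                  n_perm = 1000, alpha = 0.05, seed) {
  stopifnot(inherits(probs, "genotype_probs"))
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  if (n_perm < 1L) stop("`n_perm` must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  ids <- rownames(probs$prob_AA)
  m <- match(ids, line_means$line_id)
  y <- line_means$lsmean[m]
  keep <- !is.na(y)
  X <- probs$prob_AA[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  set.seed(as.integer(seed))
  perm <- matrix(0, n, n_perm)
  for (b in seq_len(n_perm)) perm[, b] <- y[sample.int(n)]
  # all permutations share the phenotype sum of squares
  Xc <- sweep(X, 2, colMeans(X))
  ss_x <- colSums(Xc^2)
  Pc <- perm - mean(y)
  ss_y <- sum((y - mean(y))^2)
  num <- crossprod(Xc, Pc)                     # positions x perms
  r2 <- (num / sqrt(pmax(ss_x, .Machine$double.xmin) * ss_y))^2
  r2[ss_x == 0, ] <- 0
  lods <- (n / 2) * log10(1 / pmax(1 - r2, 1e-12))
  max_lods <- apply(lods, 2, max)
  structure(
    list(alpha = alpha, n_perm = as.integer(n_perm),
         threshold_lod = as.numeric(stats::quantile(max_lods, 1 - alpha, type = 7)),
         seed = as.integer(seed), max_lods = max_lods),
    class = "perm_threshold")
}

#' Call QTL peaks from a LOD scan
#'
#' Finds, per chromosome, local maxima above the permutation threshold
#' and attaches a LOD-drop support interval: the contiguous region
#' around the peak within `drop_lod` of the peak LOD. Above-threshold
#' positions inside an already-claimed support interval, inside the
#' claimed contiguous above-threshold run, or within `min_sep_cM` of a
#' called peak are merged into that peak rather than called separately,
#' and a candidate whose own support interval contains an already-called
#' peak merges into it as well.
#'
#' @param scan A [interval_mapping_scan()] result.
#' @param thr A [permutation_threshold()] result (or a single numeric
#'   LOD cutoff).
#' @param drop_lod Support-interval LOD drop (default 1.5).
#' @param min_sep_cM Minimum separation between called peaks on one
#'   chromosome (default 30 cM): candidate maxima closer than this to an
#'   already-called peak are treated as the same signal. Linked QTL
#'   closer than ~30 cM are not separable at populations of this size,
#'   so closer secondary maxima are shoulders of one hump, not evidence
#'   of a second locus.
#' @return A data.frame with columns `trait`, `chromosome`, `peak_cM`,
#'   `peak_lod`, `ci_low_cM`, `ci_high_cM` (possibly zero rows).
#' @export
call_qtl_peaks <- function(scan, thr, drop_lod = 1.5, min_sep_cM = 30) {
  stopifnot(inherits(scan, "qtl_scan"))
  cutoff <- if (inherits(thr, "perm_threshold")) thr$threshold_lod else as.numeric(thr)
  trait <- attr(scan, "trait")
  peaks <- list()
  for (ch in unique(scan$chromosome)) {
    s <- scan[scan$chromosome == ch, , drop = FALSE]
    lod <- s$lod
    claimed <- rep(FALSE, nrow(s))
    called_idx <- integer(0)
    repeat {
      cand <- which(!claimed & lod > cutoff)
      if (length(cand) == 0L) break
      pk <- cand[which.max(lod[cand])]
      lo <- pk; hi <- pk
      while (lo > 1L && lod[lo - 1L] >= lod[pk] - drop_lod) lo <- lo - 1L
      while (hi < nrow(s) && lod[hi + 1L] >= lod[pk] - drop_lod) hi <- hi + 1L
      # claim the contiguous above-threshold run around the peak and
      # everything within the minimum peak separation, so shoulders of
      # the same hump are not re-called as extra loci
      clo <- pk; chi <- pk
      while (clo > 1L && lod[clo - 1L] > cutoff) clo <- clo - 1L
      while (chi < nrow(s) && lod[chi + 1L] > cutoff) chi <- chi + 1L
      claimed[min(lo, clo):max(hi, chi)] <- TRUE
      claimed[abs(s$position_cM - s$position_cM[pk]) < min_sep_cM] <- TRUE
      # a candidate whose support interval cannot exclude an already
      # called peak is not independent evidence of a second locus
      if (any(called_idx >= lo & called_idx <= hi)) next
      called_idx <- c(called_idx, pk)
      peaks[[length(peaks) + 1L]] <- data.frame(
        trait = trait, chromosome = ch,
        peak_cM = s$position_cM[pk], peak_lod = lod[pk],
        ci_low_cM = s$position_cM[lo], ci_high_cM = s$position_cM[hi],
        stringsAsFactors = FALSE)
    }
  }
  if (length(peaks) == 0L)
    return(data.frame(trait = character(), chromosome = character(),
                      peak_cM = numeric(), peak_lod = numeric(),
                      ci_low_cM = numeric(), ci_high_cM = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, peaks)
  out[order(out$chromosome, out$peak_cM), , drop = FALSE]
}

#' Estimate the additive effect at a map position
#'
#' Haley-Knott regression coefficient of the line mean on the signed
#' expected genotype x = 2 P(AA) - 1, i.e. half the fitted difference
#' between the two homozygote classes.
#'
#' @inheritParams interval_mapping_scan
#' @param chromosome,position_cM Position at which to estimate.
#' @return The additive effect (same units as the trait).
#' @export
additive_effect_at <- function(probs, line_means, chromosome, position_cM) {
  stopifnot(inherits(probs, "genotype_probs"))
  idx <- which(probs$positions$chromosome == chromosome &
                 abs(probs$positions$position_cM - position_cM) < 1e-9)
  if (length(idx) == 0L)
    idx <- which.min(abs(probs$positions$position_cM - position_cM) +
                       ifelse(probs$positions$chromosome == chromosome, 0, Inf))
  ids <- rownames(probs$prob_AA)
  y <- line_means$lsmean[match(ids, line_means$line_id)]
  keep <- !is.na(y)
  x <- 2 * probs$prob_AA[keep, idx[1]] - 1
  stats::coef(stats::lm(y[keep] ~ x))[["x"]]
}
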