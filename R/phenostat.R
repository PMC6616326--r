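# Downstream trait statistics: per-line least-square means, Pearson
# correlations among line means, and the residual-variance F test that
# compares measurement precision between two traits.

#' Per-line least-square means of a trait
#'
#' Fits the one-way fixed-effects line model; for this layout the LS
#' mean of each line equals its arithmetic mean, balanced or not.
#'
#' @param records Trait records (see [extract_traits_batch()]).
#' @param trait Trait name to summarise.
#' @return A data.frame with columns `line_id`, `trait`, `lsmean`,
#'   `n_obs`, one row per line.
#' @export
least_square_means <- function(records, trait) {
  validate_trait_records(records)
  sub <- records[records$trait == trait, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no records for trait '", trait, "'", call. = FALSE)
  means <- tapply(sub$value, sub$line_id, mean)
  ns <- tapply(sub$value, sub$line_id, length)
  data.frame(line_id = names(means), trait = trait,
             lsmean = as.numeric(means), n_obs = as.integer(ns),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pearson correlation with a two-sided t test
#'
#' Sample Pearson r computed from the definitional covariance/SD
#' formula; the p-value comes from the t transform
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} with n - 2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, both with nonzero
#'   variance.
#' @return A list of class `correlation_result` with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  dx <- x - mean(x); dy <- y - mean(y)
  ssx <- sum(dx^2); ssy <- sum(dy^2)
  if (ssx == 0 || ssy == 0)
    stop("correlation undefined: zero variance input", call. = FALSE)
  r <- sum(dx * dy) / sqrt(ssx * ssy)
  r <- min(max(r, -1), 1)
  p <- if (abs(r) == 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  structure(list(r = r, p_value = p, n = n), class = "correlation_result")
}

#' Residual-variance F test between two traits
#'
#' Tests the null hypothesis that the residual variances of two traits
#' are equal, i.e. that one measurement is as precise as the other.
#' F is the ratio of the residual mean squares
#' \eqn{s^2 = \sum r_i^2 / df}; the p-value is two-sided,
#' \eqn{2\,\min\{P(F \le f),\ P(F \ge f)\}}, since the null states
#' equality with no directional alternative.
#'
#' @param resid_x,resid_y Residual vectors (each length >= 2).
#' @param df_x,df_y Residual degrees of freedom; for residuals from a
#'   one-way line model pass `n_obs - n_lines`. Defaults to `n - 1`
#'   (residuals about a single mean).
#' @return A list of class `variance_ftest` with `df1`, `df2`, `f_stat`,
#'   `p_value`.
#' @export
residual_variance_ftest <- function(resid_x, resid_y,
                                    df_x = length(resid_x) - 1L,
                                    df_y = length(resid_y) - 1L) {
  if (length(resid_x) < 2L || length(resid_y) < 2L)
    stop("need at least 2 residuals per trait", call. = FALSE)
  if (df_x < 1L || df_y < 1L) stop("degrees of freedom must be >= 1", call. = FALSE)
  s2x <- sum(resid_x^2) / df_x
  s2y <- sum(resid_y^2) / df_y
  if (s2y == 0 || s2x == 0)
    stop("zero residual variance: F statistic undefined", call. = FALSE)
  f <- s2x / s2y
  # both tails evaluated in their own orientation so that swapping the
  # traits permutes the two terms and the p-value is bitwise symmetric
  p <- 2 * min(stats::pf(f, df_x, df_y), stats::pf(s2y / s2x, df_y, df_x))
  p <- min(p, 1)
  structure(list(df1 = as.integer(df_x), df2 = as.integer(df_y),
                 f_stat = f, p_value = p),
            class = "variance_ftest")
}

#' Residuals of the one-way line model for a trait
#'
#' Residuals are trait value minus the line LS mean. Because traits sit
#' on different measurement scales, values are by default z-scaled by
#' the trait's grand SD before the residuals are formed, so residual
#' variances are comparable across traits; set `standardize = FALSE` for
#' raw-scale residuals.
#'
#' @param records Trait records.
#' @param trait Trait name.
#' @param standardize Divide by the grand SD first (default TRUE).
#' @return A list with `residuals` and `df` (= n_obs - n_lines).
#' @export
one_way_residuals <- function(records, trait, standardize = TRUE) {
  validate_trait_records(records)
  sub <- records[records$trait == trait, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no records for trait '", trait, "'", call. = FALSE)
  v <- sub$value
  if (standardize) {
    s <- stats::sd(v)
    if (s == 0) stop("trait has zero variance", call. = FALSE)
    v <- v / s
  }
  fit <- v - stats::ave(v, sub$line_id)
  list(residuals = fit, df = length(v) - length(unique(sub$line_id)))
}

#' Residual-variance F test between two traits in a record table
#'
#' Convenience wrapper: computes the one-way line-model residuals of
#' both traits (z-scaled by default) and applies
#' [residual_variance_ftest()] with df = n_obs - n_lines per trait.
#'
#' @inheritParams one_way_residuals
#' @param trait_x,trait_y The two trait names to compare.
#' @return A `variance_ftest` result.
#' @export
trait_variance_ftest <- function(records, trait_x, trait_y, standardize = TRUE) {
  rx <- one_way_residuals(records, trait_x, standardize)
  ry <- one_way_residuals(records, trait_y, standardize)
  residual_variance_ftest(rx$residuals, ry$residuals, rx$df, ry$df)
}

#' Pairwise Pearson correlations among per-line trait means
#'
#' All trait pairs are correlated on the lines present for both traits
#' (complete-case policy); pairs with fewer than 3 shared lines are
#' skipped.
#'
#' @param means Row-bound output of [least_square_means()] for two or
#'   more traits.
#' @return A data.frame with columns `trait_x`, `trait_y`, `r`,
#'   `p_value`, `n`, one row per unordered pair.
#' @export
trait_correlation_matrix <- function(means) {
  stopifnot(is.data.frame(means),
            all(c("line_id", "trait", "lsmean") %in% names(means)))
  traits <- unique(means$trait)
  if (length(traits) < 2L)
    stop("need at least 2 traits to correlate", call. = FALSE)
  out <- list()
  for (i in seq_len(length(traits) - 1L)) for (j in (i + 1L):length(traits)) {
    a <- means[means$trait == traits[i], c("line_id", "lsmean")]
    b <- means[means$trait == traits[j], c("line_id", "lsmean")]
    m <- merge(a, b, by = "line_id")
    if (nrow(m) < 3L) next
    cr <- pearson_correlation(m$lsmean.x, m$lsmean.y)
    out[[length(out) + 1L]] <- data.frame(
      trait_x = traits[i], trait_y = traits[j],
      r = cr$r, p_value = cr$p_value, n = cr$n, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    stop("no trait pair shares at least 3 lines", call. = FALSE)
  do.call(rbind, out)
}
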