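# Independent brute-force oracles used to cross-check the vectorized
# implementations. These are deliberately slow, literal translations of
# the definitions and share no code with the package internals.

# --- binary filter oracles ---------------------------------------------------

# Median (majority) filter with replicate padding, pixel by pixel.
oracle_median <- function(mask, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- logical(0)
    for (di in -radius:radius) for (dj in -radius:radius) {
      ii <- min(max(i + di, 1), nr)
      jj <- min(max(j + dj, 1), nc)
      vals <- c(vals, mask[ii, jj])
    }
    out[i, j] <- median(vals) > 0.5
  }
  out
}

# Erosion/dilation with a k x k square element; outside the frame is
# background.
oracle_erode <- function(mask, k) {
  r <- (k - 1) %/% 2
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    keep <- TRUE
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      v <- if (ii < 1 || ii > nr || jj < 1 || jj > nc) FALSE else mask[ii, jj]
      keep <- keep && v
    }
    out[i, j] <- keep
  }
  out
}

oracle_dilate <- function(mask, k) {
  r <- (k - 1) %/% 2
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    hit <- FALSE
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      v <- if (ii < 1 || ii > nr || jj < 1 || jj > nc) FALSE else mask[ii, jj]
      hit <- hit || v
    }
    out[i, j] <- hit
  }
  out
}

# Hole filling by explicit breadth-first flood fill of background from
# the border (4-connectivity); unreached background becomes foreground.
oracle_fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  reach <- matrix(FALSE, nr, nc)
  queue <- list()
  for (i in seq_len(nr)) for (j in c(1, nc))
    if (!mask[i, j]) queue[[length(queue) + 1]] <- c(i, j)
  for (j in seq_len(nc)) for (i in c(1, nr))
    if (!mask[i, j]) queue[[length(queue) + 1]] <- c(i, j)
  while (length(queue) > 0) {
    p <- queue[[1]]; queue <- queue[-1]
    i <- p[1]; j <- p[2]
    if (reach[i, j] || mask[i, j]) next
    reach[i, j] <- TRUE
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
          !mask[ii, jj] && !reach[ii, jj])
        queue[[length(queue) + 1]] <- c(ii, jj)
    }
  }
  !reach
}

random_mask <- function(seed, nr = 16, nc = 16, p = 0.4) {
  set.seed(seed)
  matrix(runif(nr * nc) < p, nr, nc)
}

# --- color oracle ------------------------------------------------------------

# Scalar sRGB -> XYZ -> Lab conversion. The matrix and white point were
# derived independently (solve of the sRGB primary system at D65) and
# frozen here to 10 decimals; the arithmetic is plain scalar code.
oracle_srgb_to_lab <- function(rgb255) {
  M <- matrix(c(0.4123907993, 0.3575843394, 0.1804807884,
                0.2126390059, 0.7151686788, 0.0721923154,
                0.0193308187, 0.1191947798, 0.9505321522), 3, byrow = TRUE)
  wn <- c(0.9504559271, 1, 1.0890577508)
  lin <- function(u) if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  v <- vapply(rgb255 / 255, lin, 0)
  xyz <- as.vector(M %*% v)
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  fx <- f(xyz[1] / wn[1]); fy <- f(xyz[2] / wn[2]); fz <- f(xyz[3] / wn[3])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# Inverse geometric HSI -> RGB (sector formulas), for round-trip checks.
oracle_hsi_to_rgb <- function(h, s, i) {
  if (h < 120) {
    b <- i * (1 - s)
    r <- i * (1 + s * cos(h * pi / 180) / cos((60 - h) * pi / 180))
    g <- 3 * i - (r + b)
  } else if (h < 240) {
    h2 <- h - 120
    r <- i * (1 - s)
    g <- i * (1 + s * cos(h2 * pi / 180) / cos((60 - h2) * pi / 180))
    b <- 3 * i - (r + g)
  } else {
    h2 <- h - 240
    g <- i * (1 - s)
    b <- i * (1 + s * cos(h2 * pi / 180) / cos((60 - h2) * pi / 180))
    r <- 3 * i - (g + b)
  }
  c(r, g, b) * 255
}

# --- statistics oracles ------------------------------------------------------

# One-way LS means via an explicit normal-equations solve of the cell
# means model X beta = y.
oracle_lsmeans <- function(line_id, value) {
  X <- stats::model.matrix(~ 0 + factor(line_id))
  beta <- solve(t(X) %*% X, t(X) %*% value)
  stats::setNames(as.vector(beta), levels(factor(line_id)))
}

# Two-sided variance-ratio p-value by numeric quadrature of the F
# density.
oracle_ftest_p <- function(f, df1, df2) {
  lower <- stats::integrate(function(x) stats::df(x, df1, df2), 0, f,
                            rel.tol = 1e-12)$value
  2 * min(lower, 1 - lower)
}

# --- RIL probability oracle --------------------------------------------------

# P(AA at a point between two flanking markers) by explicit enumeration
# of the intermediate genotype paths, with Haldane r expanded to the
# selfed-RIL recombination fraction per interval.
oracle_ril_prob <- function(gL, gR, dL, dR) {
  Rfun <- function(d) { r <- (1 - exp(-2 * d / 100)) / 2; 2 * r / (1 + 2 * r) }
  trans <- function(a, b, d) if (a == b) 1 - Rfun(d) else Rfun(d)
  num <- trans(gL, 1, dL) * trans(1, gR, dR)
  den <- num + trans(gL, 0, dL) * trans(0, gR, dR)
  num / den
}

# --- misc --------------------------------------------------------------------

scene_f1 <- function(mask, truth) {
  tp <- sum(mask & truth)
  if (tp == 0) return(0)
  2 * tp / (sum(mask) + sum(truth))
}

tiny_map <- function(n_chr = 1, n_mark = 5, spacing = 10) {
  make_ril_map(n_chr = n_chr, markers_per_chr = n_mark, spacing_cM = spacing)
}
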