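# Independent brute-force oracles used to pin down expected values.
# Each oracle deliberately uses explicit loops / first-principles formulas,
# never the package's own code paths.

# Exhaustive per-voxel count behind the NE statistic.
oracle_ne_count <- function(emap, tumor, mu, sigma, n_sd = 1) {
  thr <- mu + n_sd * sigma
  n_tum <- 0L
  n_above <- 0L
  dm <- dim(emap)
  for (i in seq_len(dm[1])) {
    for (j in seq_len(dm[2])) {
      for (k in seq_len(dm[3])) {
        if (tumor[i, j, k]) {
          n_tum <- n_tum + 1L
          if (emap[i, j, k] > thr) n_above <- n_above + 1L
        }
      }
    }
  }
  100 * n_above / n_tum
}

# Two-pass mean / sample SD.
oracle_two_pass <- function(vals) {
  n <- length(vals)
  s <- 0
  for (v in vals) s <- s + v
  mu <- s / n
  ss <- 0
  for (v in vals) ss <- ss + (v - mu)^2
  list(mu = mu, sigma = sqrt(ss / (n - 1)))
}

# AUC as the exhaustive concordant-pair count with half-weight ties.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) tot <- tot + 1 else if (p == q) tot <- tot + 0.5
    }
  }
  tot / (length(pos) * length(neg))
}

# ICC(A,1) from explicit group sums.
oracle_icc_a1 <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- sum(m) / (n * k)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  sse <- sum((m - grand)^2) - k * sum((rowMeans(m) - grand)^2) -
    n * sum((colMeans(m) - grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Two-sided Fisher exact p by full enumeration of tables with the observed
# margins (summing hypergeometric probabilities <= the observed table's,
# with the same relative tolerance convention as the exact test).
oracle_fisher_enum <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  lo <- max(0L, c1 - (n - r1))
  hi <- min(r1, c1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  tot <- 0
  for (x in lo:hi) {
    px <- dhyper(x, c1, n - c1, r1)
    if (px <= p_obs * (1 + 1e-7)) tot <- tot + px
  }
  tot
}

# Product-limit estimator computed by hand over the distinct event times.
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / at_risk)
    out$surv[i] <- s
  }
  out
}

# Welch statistic from the textbook formula.
oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

# Max over A of the distance to set B, by exhaustive pairwise distances.
oracle_directed_hausdorff <- function(mask_a, mask_b, spacing) {
  ca <- which(mask_a, arr.ind = TRUE)
  cb <- which(mask_b, arr.ind = TRUE)
  ca <- sweep(ca, 2, spacing, "*")
  cb <- sweep(cb, 2, spacing, "*")
  worst <- 0
  for (i in seq_len(nrow(ca))) {
    d2 <- (cb[, 1] - ca[i, 1])^2 + (cb[, 2] - ca[i, 2])^2 +
      (cb[, 3] - ca[i, 3])^2
    worst <- max(worst, sqrt(min(d2)))
  }
  worst
}

# Small random enhancement "phantom": an emap plus a random non-empty
# tumor mask on an 8^3 grid.
random_mini_phantom <- function(seed, side = 8L) {
  set.seed(seed)
  emap <- array(rnorm(side^3, 40, 25), rep(side, 3L))
  tumor <- array(runif(side^3) < 0.3, rep(side, 3L))
  if (sum(tumor) == 0) tumor[1, 1, 1] <- TRUE
  list(emap = emap, tumor = tumor)
}

# Quick valid study/mask fixture on a small grid.
tiny_study <- function(seed = 1, side = 8L, spacing = 1) {
  set.seed(seed)
  dm <- rep(side, 3L)
  registered_study(array(rnorm(side^3, 40, 5), dm),
                   array(rnorm(side^3, 90, 8), dm),
                   array(rnorm(side^3, 80, 8), dm),
                   spacing_mm = spacing)
}
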