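# Independent naive-loop oracles. These deliberately avoid the package's
# vectorized code paths: plain loops, no shared helpers.

# All seven features from explicit loops over the masked pixels.
naive_features <- function(pixels, mask, n_bins = 32L) {
  vals <- c()
  for (i in seq_len(nrow(pixels))) {
    for (j in seq_len(ncol(pixels))) {
      if (mask[i, j]) vals <- c(vals, pixels[i, j])
    }
  }
  n <- length(vals)
  m <- 0
  for (v in vals) m <- m + v
  m <- m / n
  ss <- 0
  for (v in vals) ss <- ss + (v - m)^2
  sdev <- if (n >= 2) sqrt(ss / (n - 1)) else 0
  m2 <- ss / n
  if (m2 > 0) {
    m3 <- 0; m4 <- 0
    for (v in vals) {
      m3 <- m3 + (v - m)^3
      m4 <- m4 + (v - m)^4
    }
    skew <- (m3 / n) / m2^1.5
    kurt <- (m4 / n) / m2^2
  } else {
    skew <- NA_real_; kurt <- NA_real_
  }
  lo <- min(vals); hi <- max(vals)
  counts <- rep(0L, n_bins)
  if (hi > lo) {
    width <- (hi - lo) / n_bins
    for (v in vals) {
      b <- floor((v - lo) / width) + 1
      if (b > n_bins) b <- n_bins
      counts[b] <- counts[b] + 1L
    }
  } else {
    counts[1] <- n
  }
  p <- counts / n
  unif <- 0; ent <- 0
  for (pi in p) {
    unif <- unif + pi^2
    if (pi > 0) ent <- ent - pi * log2(pi)
  }
  if (hi > lo) {
    en <- 0
    for (v in vals) en <- en + ((v - lo) / (hi - lo))^2
    en <- en / n
  } else {
    en <- 1
  }
  list(mean = m, sd = sdev, skewness = skew, kurtosis = kurt,
       uniformity = unif, energy = en, entropy = ent, counts = counts)
}

# Random masked image with a mix of continuous and tied intensities.
random_masked_image <- function(nr = sample(6:40, 1), nc = sample(6:40, 1)) {
  kind <- sample(c("normal", "uniform", "lognormal", "discrete"), 1)
  px <- switch(kind,
    normal = rnorm(nr * nc, 100, 25),
    uniform = runif(nr * nc, 0, 500),
    lognormal = rlnorm(nr * nc, 4, 0.6),
    discrete = sample(0:20, nr * nc, replace = TRUE) * 10)
  msk <- matrix(runif(nr * nc) < 0.6, nr, nc)
  if (!any(msk)) msk[sample(nr * nc, 3)] <- TRUE
  masked_image(matrix(px, nr, nc), msk)
}

# AUC by explicit enumeration of all positive-negative pairs.
pair_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  tot / (length(pos) * length(neg))
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments
# (untied data only).
enum_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  r <- rank(pooled)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments
# (untied nonzero differences only).
enum_sr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_le <- mean(vs <= v_obs)
  p_ge <- mean(vs >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Small default-spec cohort features, shared across test files to avoid
# regenerating (59 patients x 2 timepoints x 2 raters).
cached_cohort_features <- local({
  cache <- NULL
  function(seed = 101) {
    if (is.null(cache)) {
      co <- generate_cohort(cohort_spec(seed = seed))
      cache <<- extract_cohort_features(co)
    }
    cache
  }
})
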