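# Independent brute-force oracles used across test files. These deliberately
# use plain loops / enumeration, not the package's code paths.

# elementwise max over z by an explicit triple loop
oracle_max_project <- function(arr) {
  d <- dim(arr)
  out <- matrix(-Inf, d[2L], d[3L])
  for (z in seq_len(d[1L])) {
    for (y in seq_len(d[2L])) {
      for (x in seq_len(d[3L])) {
        if (arr[z, y, x] > out[y, x]) out[y, x] <- arr[z, y, x]
      }
    }
  }
  out
}

# mean intensity over a logical mask by an explicit double loop
oracle_mask_mean <- function(img, mask) {
  s <- 0; n <- 0L
  for (y in seq_len(nrow(img))) {
    for (x in seq_len(ncol(img))) {
      if (mask[y, x]) { s <- s + img[y, x]; n <- n + 1L }
    }
  }
  s / n
}

# exhaustive between-class-variance maximizer on a 256-bin histogram;
# returns the smallest maximizing threshold bin (0-based)
oracle_otsu_bin <- function(values, step) {
  bins <- pmin(values %/% step, 255)
  best_t <- NA_integer_; best_v <- -Inf
  n <- length(bins)
  for (t in 0:254) {
    w0 <- sum(bins <= t); w1 <- n - w0
    if (w0 == 0L || w1 == 0L) next
    mu0 <- mean(bins[bins <= t]); mu1 <- mean(bins[bins > t])
    v <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# exact two-sided Mann-Whitney p by complete enumeration of which ranks go
# to sample x (valid with or without ties via mid-ranks)
oracle_mw_exact <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  dev_obs <- abs(u_obs - m * n / 2)
  combos <- utils::combn(m + n, m)
  devs <- apply(combos, 2L, function(idx) {
    abs(sum(r[idx]) - m * (m + 1) / 2 - m * n / 2)
  })
  mean(devs >= dev_obs - 1e-12)
}

# two-sided Fisher p by direct hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
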