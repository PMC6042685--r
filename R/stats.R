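#' Group summaries of behavioral outcomes
#'
#' Per-genotype mean and standard error. Latency summaries include censored
#' animals at the 11 s cap value (the protocol's convention); response
#' summaries report the observed proportion (percent) with the binomial
#' standard error \eqn{\sqrt{\hat p (1-\hat p)/n}}.
#'
#' @param table a [behavior_table()].
#' @param outcome `"latency"` or `"response"`.
#' @return Data.frame with one row per genotype: `genotype`, `n`, `mean`,
#'   `se`, and `censored_count` (latency) or `n_responded` (response).
#'   Means and SEs of response outcomes are in percent.
#' @export
summarize_behavior <- function(table, outcome = c("latency", "response")) {
  outcome <- match.arg(outcome)
  col <- if (outcome == "latency") "latency_s" else "responded"
  if (!col %in% names(table)) {
    stop_format("table has no '", col, "' column")
  }
  rows <- lapply(unique(table$genotype), function(g) {
    v <- table[[col]][table$genotype == g]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      warning("genotype '", g, "' has no ", outcome, " data; skipped")
      return(NULL)
    }
    if (outcome == "latency") {
      data.frame(genotype = g, n = length(v), mean = mean(v),
                 se = if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_,
                 censored_count = sum(v == LATENCY_CAP_S))
    } else {
      p <- mean(v)
      data.frame(genotype = g, n = length(v), mean = 100 * p,
                 se = 100 * sqrt(p * (1 - p) / length(v)),
                 n_responded = sum(v))
    }
  })
  do.call(rbind, rows)
}

.tie_term <- function(v) {
  t <- tabulate(match(v, unique(v)))
  sum(t^3 - t)
}

#' Two-sided Mann-Whitney U test
#'
#' Mid-ranks throughout (stacks of censored 11 s latencies form tie
#' blocks). The p-value is exact (null distribution of U) when the combined
#' sample size is at most 20 and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples.
#' @return A one-row data.frame: `method`, `statistic` (U for `x`),
#'   `p_value`, `n_x`, `n_y`, `alternative`, `adjustment`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  m <- length(x); n <- length(y); N <- m + n
  combined <- c(x, y)
  r <- rank(combined)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(combined) > 0L
  exact <- (N <= 20L) && !ties
  if (exact) {
    p <- if (U > m * n / 2) {
      pwilcox(U - 1, m, n, lower.tail = FALSE)
    } else {
      pwilcox(U, m, n)
    }
    p <- min(1, 2 * p)
    method <- "Mann-Whitney U (exact)"
  } else {
    mu <- m * n / 2
    sigma2 <- m * n / 12 * ((N + 1) - .tie_term(combined) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      z <- z - sign(z) * 0.5  # continuity correction
      p <- min(1, 2 * pnorm(-abs(z) / sqrt(sigma2)))
    }
    method <- "Mann-Whitney U (normal approximation, tie-corrected)"
  }
  data.frame(method = method, statistic = U, p_value = p,
             n_x = m, n_y = n, alternative = "two.sided",
             adjustment = "none")
}

# Standardized two-sample rank-sum statistic for one control-vs-group
# contrast (mid-ranks, tie-corrected variance). Returns 0 when degenerate.
.steel_stat <- function(control, g) {
  n0 <- length(control); nj <- length(g); N <- n0 + nj
  v <- c(control, g)
  r <- rank(v)
  W <- sum(r[(n0 + 1):N])
  EW <- nj * (N + 1) / 2
  VW <- n0 * nj / 12 * ((N + 1) - .tie_term(v) / (N * (N - 1)))
  if (VW <= 0) return(0)
  (W - EW) / sqrt(VW)
}

# One-factor joint tail of k standardized rank statistics sharing the
# control sample: corr(T_i, T_j) = sqrt(rho_i rho_j), rho_j = nj/(n0+nj).
.steel_asymptotic_p <- function(t_obs, n0, nj) {
  rho <- nj / (n0 + nj)
  vapply(abs(t_obs), function(t) {
    if (!is.finite(t)) return(NA_real_)
    inner <- function(u) {
      prob <- rep(1, length(u))
      for (r in rho) {
        a <- sqrt(r); b <- sqrt(1 - r)
        prob <- prob * (pnorm((t - a * u) / b) - pnorm((-t - a * u) / b))
      }
      dnorm(u) * prob
    }
    1 - integrate(inner, -8, 8, rel.tol = 1e-9)$value
  }, numeric(1))
}

#' Steel's many-to-one rank test
#'
#' Nonparametric analogue of Dunnett's test: each treatment group is
#' compared with the shared control by a standardized two-sample rank-sum
#' statistic, and familywise error over the k contrasts is controlled
#' jointly. The reference implementation is a seeded Monte-Carlo
#' permutation of the maximum absolute standardized statistic (all
#' observations relabelled across groups; tie-corrected standardization
#' recomputed per resample); the reported per-group p-value is
#' \eqn{(1 + \#\{\max_j |T^*_j| \ge |T_j|\}) / (B + 1)}. The asymptotic
#' variant uses the exact one-factor correlation structure of the
#' statistics under the multivariate normal limit.
#'
#' @param control numeric control sample.
#' @param treatment_groups named list of numeric treatment samples.
#' @param resamples number of permutation resamples (default 1e5).
#' @param seed integer seed (the test is reproducible bit-for-bit given it).
#' @param method `"permutation"` (reference) or `"asymptotic"`.
#' @return Data.frame with one row per treatment group: `method`, `group`,
#'   `statistic`, `p_value` (familywise-adjusted), `n_control`, `n_group`,
#'   `alternative`, `adjustment`.
#' @export
steel_test <- function(control, treatment_groups, resamples = 1e5,
                       seed = 1L, method = c("permutation", "asymptotic")) {
  method <- match.arg(method)
  if (!is.list(treatment_groups) || length(treatment_groups) == 0L) {
    stop_format("treatment_groups must be a nonempty list of samples")
  }
  if (is.null(names(treatment_groups))) {
    names(treatment_groups) <- paste0("group", seq_along(treatment_groups))
  }
  stopifnot(length(control) >= 1L,
            all(vapply(treatment_groups, length, integer(1)) >= 1L))
  k <- length(treatment_groups)
  n0 <- length(control)
  nj <- vapply(treatment_groups, length, integer(1))
  t_obs <- vapply(treatment_groups, function(g) .steel_stat(control, g),
                  numeric(1))
  if (method == "asymptotic") {
    p <- .steel_asymptotic_p(t_obs, n0, nj)
    adjustment <- "steel-joint (asymptotic)"
  } else {
    pooled <- c(control, unlist(treatment_groups, use.names = FALSE))
    N <- length(pooled)
    ends <- n0 + cumsum(nj)
    starts <- c(n0 + 1L, head(ends, -1L) + 1L)
    B <- as.integer(resamples)
    exceed <- numeric(k)
    with_seed(seed, {
      for (b in seq_len(B)) {
        perm <- pooled[sample.int(N)]
        ctrl <- perm[seq_len(n0)]
        tmax <- 0
        for (j in seq_len(k)) {
          tj <- abs(.steel_stat(ctrl, perm[starts[j]:ends[j]]))
          if (tj > tmax) tmax <- tj
        }
        exceed <- exceed + (tmax >= abs(t_obs))
      }
    })
    p <- (1 + exceed) / (B + 1)
    adjustment <- "steel-joint (permutation)"
  }
  data.frame(method = paste0("Steel many-to-one (", method, ")"),
             group = names(treatment_groups),
             statistic = t_obs, p_value = as.numeric(p),
             n_control = n0, n_group = nj,
             alternative = "two.sided", adjustment = adjustment,
             row.names = NULL)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, with
#' margins fixed, of tables at most as probable as the observed one
#' (delegated to [stats::fisher.test()]).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return One-row data.frame: `method`, `statistic` (sample odds ratio),
#'   `p_value`, `n`, `alternative`, `adjustment`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop_format("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop_format("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_validation("degenerate margin: every row and column needs counts")
  }
  ft <- fisher.test(table, alternative = "two.sided")
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  data.frame(method = "Fisher exact (two-sided)", statistic = or,
             p_value = ft$p.value, n = sum(table),
             alternative = "two.sided", adjustment = "none")
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` elementwise; `m` defaults to the number of p-values in
#' the call.
#'
#' @param p_values numeric vector of p-values.
#' @param m number of comparisons in the family (`m >= length(p_values)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) {
    stop_validation("m must be at least the number of p-values")
  }
  pmin(1, p_values * m)
}
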