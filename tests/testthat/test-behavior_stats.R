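test_that("group summaries report mean and standard error per genotype", {
  tab <- behavior_table(data.frame(genotype = "g", latency_s = c(1, 2, 3)))
  s <- summarize_behavior(tab, "latency")
  expect_equal(s$mean, 2)
  expect_equal(s$se, 0.577, tolerance = 1e-3)
  expect_equal(s$censored_count, 0L)

  # binomial SE on proportions: 143 of 191 responders
  tab2 <- behavior_table(data.frame(
    genotype = "g", responded = rep(c(TRUE, FALSE), c(143, 48))))
  s2 <- summarize_behavior(tab2, "response")
  expect_equal(round(s2$mean, 1), 74.9)
  expect_equal(round(s2$se, 1), 3.1)

  # all-censored group: mean at the cap, zero SE
  tab3 <- behavior_table(data.frame(genotype = "g", latency_s = rep(11, 8)))
  s3 <- summarize_behavior(tab3, "latency")
  expect_equal(s3$mean, 11)
  expect_equal(s3$se, 0)
  expect_equal(s3$censored_count, 8L)
})

test_that("Mann-Whitney U matches closed forms and the enumeration oracle", {
  x <- c(5, 5, 5); y <- c(5, 5, 5)
  expect_equal(mann_whitney_u(x, y)$p_value, 1)

  # x = (1,2) vs y = (3,4): exact two-sided p = 2/6
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$statistic, 0)

  # exact branch equals complete enumeration on small tie-free datasets
  set.seed(20)
  for (i in 1:20) {
    m <- sample(2:4, 1); n <- sample(2:4, 1)
    v <- sample(1:50, m + n)  # distinct, no ties
    x <- v[1:m]; y <- v[-(1:m)]
    expect_equal(mann_whitney_u(x, y)$p_value, oracle_mw_exact(x, y),
                 tolerance = 1e-12, info = paste("case", i))
  }

  # censored 11 s stacks are mid-ranked tie blocks (approximate branch)
  x2 <- c(2, 3, 11, 11, 11); y2 <- c(1, 11, 11, 11, 11, 11)
  r2 <- mann_whitney_u(x2, y2)
  expect_true(r2$p_value > 0 && r2$p_value <= 1)
  expect_match(r2$method, "tie-corrected")
})

test_that("Mann-Whitney approximation tracks a large permutation oracle", {
  set.seed(21)
  x <- rlnorm(30, 0.5, 0.6); y <- rlnorm(30, 0.9, 0.6)
  r <- mann_whitney_u(x, y)
  # permutation oracle on |U - mn/2|
  m <- length(x); n <- length(y)
  rk <- rank(c(x, y))
  dev_obs <- abs(sum(rk[1:m]) - m * (m + 1) / 2 - m * n / 2)
  B <- 1e5
  devs <- replicate(B, {
    idx <- sample.int(m + n, m)
    abs(sum(rk[idx]) - m * (m + 1) / 2 - m * n / 2)
  })
  p_perm <- mean(devs >= dev_obs)
  expect_equal(r$p_value, p_perm, tolerance = 2e-3)
  # and the approximation agrees with R's reference implementation
  expect_equal(r$p_value,
               suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE)$p.value),
               tolerance = 1e-10)
})

test_that("Steel's test controls the family and reduces sensibly", {
  ctrl <- c(1.2, 3.4, 2.2, 5.1, 0.8, 2.9)
  # groups identical to control: statistics 0, adjusted p = 1
  s <- steel_test(ctrl, list(a = ctrl, b = ctrl), resamples = 500, seed = 1)
  expect_true(all(s$statistic == 0))
  expect_true(all(s$p_value >= 0.9))

  # k = 1 reduces to the exact two-sided Mann-Whitney p (tie-free, small n)
  x <- c(1.1, 3.2, 5.3, 7.1, 9.6, 11.2)
  y <- c(2.4, 4.8, 6.1, 8.9, 10.3, 12.7)
  B <- 4e4
  s1 <- steel_test(x, list(g = y), resamples = B, seed = 2)
  p_exact <- mann_whitney_u(x, y)$p_value
  mc_se <- sqrt(p_exact * (1 - p_exact) / B)
  expect_lt(abs(s1$p_value - p_exact), 4 * mc_se)

  # reproducible bit-for-bit given the seed
  s2 <- steel_test(x, list(g = y), resamples = 1000, seed = 77)
  s3 <- steel_test(x, list(g = y), resamples = 1000, seed = 77)
  expect_identical(s2, s3)

  # permutation and asymptotic variants agree to first order
  set.seed(30)
  ctrl2 <- rlnorm(15); grps <- list(a = rlnorm(15) * 1.8, b = rlnorm(15))
  sp <- steel_test(ctrl2, grps, resamples = 2e4, seed = 3)
  sa <- steel_test(ctrl2, grps, method = "asymptotic")
  expect_lt(max(abs(sp$p_value - sa$p_value)), 0.05)

  expect_error(steel_test(ctrl, list()), class = "nociquant_format_error")
})

test_that("Steel adjusted p matches exhaustive relabeling at tiny n", {
  # k = 3 groups of 3 with a control of 3: all 12!/(3!)^4 = 369600
  # relabelings enumerated exactly
  set.seed(33)
  vals <- round(rlnorm(12, 1, 0.7), 2)
  ctrl <- vals[1:3]
  groups <- list(a = vals[4:6], b = vals[7:9], c = vals[10:12])

  steel_stat <- function(c0, g) {
    v <- c(c0, g); r <- rank(v)
    W <- sum(r[4:6])
    tt <- tabulate(match(v, unique(v)))
    VW <- 9 / 12 * (7 - sum(tt^3 - tt) / (6 * 5))
    if (VW <= 0) return(0)
    (W - 3 * 7 / 2) / sqrt(VW)
  }
  t_obs <- abs(vapply(groups, function(g) steel_stat(ctrl, g), numeric(1)))

  combs1 <- utils::combn(12, 3)
  exceed <- c(0, 0, 0); total <- 0
  for (i1 in seq_len(ncol(combs1))) {
    c_idx <- combs1[, i1]
    rest1 <- setdiff(1:12, c_idx)
    c0 <- vals[c_idx]
    # precompute |T| for every candidate group triple under this control
    trip <- utils::combn(rest1, 3)
    stat_of <- new.env(hash = TRUE)
    for (j in seq_len(ncol(trip))) {
      key <- paste(trip[, j], collapse = ",")
      assign(key, abs(steel_stat(c0, vals[trip[, j]])), envir = stat_of)
    }
    look <- function(idx) get(paste(sort(idx), collapse = ","),
                              envir = stat_of)
    combs2 <- utils::combn(rest1, 3)
    for (i2 in seq_len(ncol(combs2))) {
      a_idx <- combs2[, i2]
      rest2 <- setdiff(rest1, a_idx)
      combs3 <- utils::combn(rest2, 3)
      for (i3 in seq_len(ncol(combs3))) {
        b_idx <- combs3[, i3]
        d_idx <- setdiff(rest2, b_idx)
        tmax <- max(look(a_idx), look(b_idx), look(d_idx))
        exceed <- exceed + (tmax >= t_obs - 1e-12)
        total <- total + 1
      }
    }
  }
  p_enum <- exceed / total

  B <- 2e4
  s <- steel_test(ctrl, groups, resamples = B, seed = 5)
  mc_se <- sqrt(p_enum * (1 - p_enum) / B)
  expect_true(all(abs(s$p_value - p_enum) <= 3 * mc_se + 2 / B))
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)

  tab <- matrix(c(48, 106, 143, 48), 2, byrow = TRUE)
  r <- fisher_exact(tab)
  expect_equal(r$p_value, oracle_fisher_p(tab), tolerance = 1e-10)
  expect_lt(r$p_value, 0.001)

  # invariance under row swap and transposition
  expect_equal(fisher_exact(tab[2:1, ])$p_value, r$p_value)
  expect_equal(fisher_exact(t(tab))$p_value, r$p_value)

  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               class = "nociquant_validation_error")
  expect_error(fisher_exact(matrix(c(1.5, 2, 3, 4), 2)),
               class = "nociquant_format_error")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.6, 2), 1.0)
  ps <- c(0.01, 0.02, 0.4)
  expect_equal(bonferroni(ps), vapply(ps, bonferroni, numeric(1), m = 3))
  expect_error(bonferroni(c(0.1, 0.2), m = 1),
               class = "nociquant_validation_error")
})

test_that("reconstructed reference cohorts reproduce published summaries", {
  ref <- reference_behavior_tables()
  lat <- summarize_behavior(ref$latency, "latency")
  expect_equal(lat$n, c(119L, 114L))
  resp <- summarize_behavior(ref$response, "response")
  expect_equal(resp$n_responded, c(48L, 143L, 39L))
  tabs <- reference_response_tables()
  expect_equal(unname(tabs$hiwND8_ChR2),
               matrix(c(48, 106, 143, 48), 2, byrow = TRUE))
})
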