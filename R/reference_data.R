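# Moments of a lognormal(meanlog, sdlog) right-censored at `cap`.
.censored_lnorm_moments <- function(meanlog, sdlog, cap = LATENCY_CAP_S) {
  zl <- (log(cap) - meanlog) / sdlog
  e1 <- exp(meanlog + sdlog^2 / 2) * pnorm(zl - sdlog) +
    cap * pnorm(zl, lower.tail = FALSE)
  e2 <- exp(2 * meanlog + 2 * sdlog^2) * pnorm(zl - 2 * sdlog) +
    cap^2 * pnorm(zl, lower.tail = FALSE)
  c(mean = e1, sd = sqrt(max(e2 - e1^2, 0)))
}

# Fit (meanlog, sdlog) so the censored lognormal matches a target
# mean/sd; used to reconstruct latency cohorts from published summaries.
.fit_censored_lnorm <- function(target_mean, target_sd) {
  obj <- function(par) {
    m <- .censored_lnorm_moments(par[1], exp(par[2]))
    (m["mean"] - target_mean)^2 + (m["sd"] - target_sd)^2
  }
  fit <- optim(c(log(target_mean), log(1)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  c(meanlog = fit$par[1], sdlog = exp(fit$par[2]))
}

# Deterministic midpoint-quantile sample of size n from the censored
# lognormal: latencies at probabilities (i - 0.5)/n, capped at 11 s.
.quantile_latencies <- function(n, meanlog, sdlog, cap = LATENCY_CAP_S) {
  p <- (seq_len(n) - 0.5) / n
  pmin(qlnorm(p, meanlog, sdlog), cap)
}

#' Synthetic reconstruction of the published behavioral cohorts
#'
#' The package ships no measured per-animal data; this builds deterministic
#' synthetic stand-ins consistent with the published group summaries of the
#' thermal and optogenetic nociception assays, for use in worked examples
#' and end-to-end checks of the summary/statistics pipeline.
#'
#' \itemize{
#'   \item Latency cohorts (46 degree C probe): `w1118` (n = 119,
#'     1.8 +/- 0.2 s) and `hiwND8` (n = 114, 5.1 +/- 0.3 s). Each cohort is
#'     a midpoint-quantile sample of a lognormal right-censored at the 11 s
#'     cap, with parameters moment-matched to the published mean and SE.
#'   \item Response cohorts (optogenetic stimulation): responder counts
#'     reconstructed exactly from the published n and percentages —
#'     `w1118_ChR2` 48/154 (31%), `hiwND8_ChR2` 143/191 (75%),
#'     `hiw_rescue_ChR2` 39/112 (35%).
#' }
#'
#' @return List with two [behavior_table()]s: `latency` and `response`.
#' @export
reference_behavior_tables <- function() {
  lat_spec <- data.frame(
    genotype = c("w1118", "hiwND8"),
    n = c(119L, 114L),
    mean = c(1.8, 5.1),
    se = c(0.2, 0.3)
  )
  lat_rows <- lapply(seq_len(nrow(lat_spec)), function(i) {
    s <- lat_spec[i, ]
    par <- .fit_censored_lnorm(s$mean, s$se * sqrt(s$n))
    data.frame(genotype = s$genotype,
               latency_s = .quantile_latencies(s$n, par["meanlog"],
                                               par["sdlog"]))
  })
  latency <- do.call(rbind, lat_rows)
  latency$animal_id <- seq_len(nrow(latency))

  resp_spec <- data.frame(
    genotype = c("w1118_ChR2", "hiwND8_ChR2", "hiw_rescue_ChR2"),
    n = c(154L, 191L, 112L),
    n_responded = c(48L, 143L, 39L)
  )
  resp_rows <- lapply(seq_len(nrow(resp_spec)), function(i) {
    s <- resp_spec[i, ]
    data.frame(genotype = s$genotype,
               responded = rep(c(TRUE, FALSE),
                               c(s$n_responded, s$n - s$n_responded)))
  })
  response <- do.call(rbind, resp_rows)
  response$animal_id <- seq_len(nrow(response))

  list(latency = behavior_table(latency),
       response = behavior_table(response))
}

#' Response counts as 2x2 tables for Fisher's exact test
#'
#' Control-versus-group contingency tables (responders / non-responders)
#' from the reconstructed response cohorts of
#' [reference_behavior_tables()].
#'
#' @return Named list of 2x2 matrices, one per non-control genotype.
#' @export
reference_response_tables <- function() {
  tab <- reference_behavior_tables()$response
  s <- summarize_behavior(tab, "response")
  ctrl <- s[s$genotype == "w1118_ChR2", ]
  others <- s[s$genotype != "w1118_ChR2", ]
  out <- lapply(seq_len(nrow(others)), function(i) {
    g <- others[i, ]
    matrix(c(ctrl$n_responded, ctrl$n - ctrl$n_responded,
             g$n_responded, g$n - g$n_responded),
           nrow = 2, byrow = TRUE,
           dimnames = list(c(ctrl$genotype, g$genotype),
                           c("responder", "non_responder")))
  })
  names(out) <- others$genotype
  out
}
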