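# Independent oracle implementations used to cross-check the package's
# statistics. These deliberately share no code with the implementation.

prr_oracle <- function(a, b, c, d) (a / (a + b)) / (c / (c + d))

prr_se_oracle <- function(a, b, c, d) {
  sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
}

ror_oracle <- function(a, b, c, d) (a * d) / (b * c)

ror_se_oracle <- function(a, b, c, d) sqrt(1 / a + 1 / b + 1 / c + 1 / d)

chi2_oracle <- function(a, b, c, d, yates = TRUE) {
  m <- matrix(c(a, c, b, d), nrow = 2)
  unname(suppressWarnings(stats::chisq.test(m, correct = yates))$statistic)
}

# Second, independent Dirichlet sampler: stick-breaking via Beta marginals
# (the implementation uses normalized gammas).
dirichlet_sb <- function(n, alpha) {
  stopifnot(length(alpha) == 4)
  p1 <- stats::rbeta(n, alpha[1], alpha[2] + alpha[3] + alpha[4])
  p2 <- (1 - p1) * stats::rbeta(n, alpha[2], alpha[3] + alpha[4])
  p3 <- (1 - p1 - p2) * stats::rbeta(n, alpha[3], alpha[4])
  cbind(p1, p2, p3, 1 - p1 - p2 - p3)
}

ic_draws_oracle <- function(n, a, b, c, d, pseudo = 0.5) {
  p <- dirichlet_sb(n, c(a, b, c, d) + pseudo)
  log2(p[, 1] / ((p[, 1] + p[, 2]) * (p[, 1] + p[, 3])))
}

# Batch-means MC standard error of an empirical quantile.
quantile_mc_se <- function(draws, prob, nb = 10) {
  usable <- length(draws) - length(draws) %% nb
  batches <- matrix(draws[seq_len(usable)], ncol = nb)
  stats::sd(apply(batches, 2, stats::quantile, probs = prob, names = FALSE)) / sqrt(nb)
}

# Small hand-built report set: 4 reports covering both drugs-roles and
# multi-event reports.
tiny_reports <- function() {
  icsr_set(
    report_id = c("T1", "T2", "T3", "T4"),
    sex = c("male", "female", "male", "female"),
    age_years = c(65, 34, 71, 15),
    causality = c("certain", "probable", "possible", "possible"),
    serious = c(TRUE, FALSE, FALSE, FALSE),
    seriousness_type = c("hospitalization", "none", "none", "none"),
    drugs = list(
      tibble::tibble(atc_code = c("AAA", "BBB"), suspected = c(TRUE, TRUE)),
      tibble::tibble(atc_code = c("AAA", "CCC"), suspected = c(TRUE, FALSE)),
      tibble::tibble(atc_code = "BBB", suspected = TRUE),
      tibble::tibble(atc_code = "CCC", suspected = TRUE)
    ),
    events = list(
      c("headache", "nausea", "rash"),
      c("headache", "dizziness"),
      "nausea",
      "headache"
    )
  )
}

# A random-but-seeded synthetic configuration for property tests.
prop_config <- function(seed, n = 400, contamination = list()) {
  synthetic_config(
    n_reports = n,
    drugs = setNames(runif(6, 0.5, 2), paste0("DR", 1:6)),
    events = setNames(runif(10, 0.5, 2), paste0("ev", 1:10)),
    drugs_per_report = c("1" = 0.7, "2" = 0.3),
    events_per_report = c("1" = 0.6, "2" = 0.3, "3" = 0.1),
    contamination = contamination,
    seed = seed
  )
}

# Crude odds ratio of outcome by exposure from a design tibble.
crude_or <- function(design) {
  a <- sum(design$exposure & design$outcome)
  b <- sum(design$exposure & !design$outcome)
  c <- sum(!design$exposure & design$outcome)
  d <- sum(!design$exposure & !design$outcome)
  (a * d) / (b * c)
}
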