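# Disproportionality statistics on 2x2 screening tables.
#
# Cell layout (see build_contingency): a = drug & event, b = drug & other
# events, c = other drugs & event, d = other drugs & other events.

as_cells <- function(table) {
  if (inherits(table, "contingency_table")) {
    c(a = table$a, b = table$b, c = table$c, d = table$d)
  } else if (is.numeric(table) && length(table) == 4) {
    setNames(as.numeric(table), c("a", "b", "c", "d"))
  } else {
    stop("expected a contingency_table or a numeric vector (a, b, c, d)", call. = FALSE)
  }
}

# Haldane-Anscombe: add 0.5 to every cell of tables containing a zero.
# Vectorized over cell vectors; returns list of corrected cells + flag.
ha_correct <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  k <- 0.5 * zero
  list(a = a + k, b = b + k, c = c + k, d = d + k, corrected = zero)
}

prr_vec <- function(a, b, c, d, correct = TRUE) {
  if (correct) {
    cc <- ha_correct(a, b, c, d)
  } else {
    cc <- list(a = a, b = b, c = c, d = d, corrected = rep(FALSE, length(a)))
  }
  prr <- (cc$a / (cc$a + cc$b)) / (cc$c / (cc$c + cc$d))
  se <- sqrt(1 / cc$a - 1 / (cc$a + cc$b) + 1 / cc$c - 1 / (cc$c + cc$d))
  lo <- exp(log(prr) - 1.96 * se)
  hi <- exp(log(prr) + 1.96 * se)
  undef <- !correct & a == 0
  prr[undef] <- 0
  lo[undef] <- NA_real_
  hi[undef] <- NA_real_
  list(prr = prr, ci_low = lo, ci_high = hi, corrected = cc$corrected)
}

ror_vec <- function(a, b, c, d) {
  cc <- ha_correct(a, b, c, d)
  ror <- (cc$a * cc$d) / (cc$b * cc$c)
  se <- sqrt(1 / cc$a + 1 / cc$b + 1 / cc$c + 1 / cc$d)
  list(ror = ror,
       ci_low = exp(log(ror) - 1.96 * se),
       ci_high = exp(log(ror) + 1.96 * se),
       corrected = cc$corrected)
}

chi2_vec <- function(a, b, c, d, yates = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  ok <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  ea <- r1 * c1 / n
  dev <- abs(a - ea)                       # |O - E| is identical in all 4 cells
  if (yates) dev <- dev - pmin(dev, 0.5)   # continuity correction, floored at 0
  # sum over cells of dev^2 / E_cell with E_cell = row * col / n
  inv_e <- n / (r1 * c1) + n / (r1 * c2) + n / (r2 * c1) + n / (r2 * c2)
  ifelse(ok, dev^2 * inv_e, 0)
}

#' Proportional reporting ratio (PRR) with 95% confidence interval
#'
#' PRR = (a/(a+b)) / (c/(c+d)): the fraction of the target event among the
#' target drug's reports over the same fraction among all other drugs. The
#' 95% CI is computed on the log scale with
#' SE = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)).
#'
#' @param table A `contingency_table` or numeric `c(a, b, c, d)`.
#' @param correct Apply the Haldane-Anscombe +0.5 correction to tables with a
#'   zero cell (flagged in the result). With `correct = FALSE` and `a = 0`
#'   the point estimate is 0 and the CI is undefined (`NA`).
#' @return List with `prr`, `ci_low`, `ci_high`, `corrected`.
#' @export
#' @examples
#' compute_prr(contingency_table(10, 90, 10, 890))
compute_prr <- function(table, correct = TRUE) {
  x <- as_cells(table)
  r <- prr_vec(x["a"], x["b"], x["c"], x["d"], correct = correct)
  lapply(r, unname)
}

#' Reporting odds ratio (ROR) with 95% confidence interval
#'
#' ROR = (a*d)/(b*c), the odds of the target event under the target drug over
#' the odds under all other drugs; 95% CI on the log scale with
#' SE = sqrt(1/a + 1/b + 1/c + 1/d). Tables with any zero cell receive the
#' Haldane-Anscombe +0.5 correction, flagged in the result.
#'
#' @inheritParams compute_prr
#' @return List with `ror`, `ci_low`, `ci_high`, `corrected`.
#' @export
compute_ror <- function(table) {
  x <- as_cells(table)
  r <- ror_vec(x["a"], x["b"], x["c"], x["d"])
  lapply(r, unname)
}

#' Pearson chi-square for a 2x2 screening table
#'
#' Yates continuity correction (default) shrinks |O - E| by 0.5, floored at
#' zero, in every cell — the classical companion to the PRR/ROR >= 2 signal
#' thresholds. A table with a zero margin returns 0 by convention.
#'
#' @inheritParams compute_prr
#' @param yates Apply the continuity correction.
#' @return The chi-square statistic (scalar).
#' @export
compute_chi2 <- function(table, yates = TRUE) {
  x <- as_cells(table)
  unname(chi2_vec(x["a"], x["b"], x["c"], x["d"], yates = yates))
}

#' Shrinkage prior and Monte-Carlo settings for the information component
#'
#' @param pseudo Pseudo-count added to each cell of the Dirichlet posterior
#'   and to the observed/expected counts of the point estimate (default 0.5).
#' @param n_mc Monte-Carlo draws for the credible interval.
#' @param credible_level Credible-interval mass (default 0.95).
#' @return An `ic_prior` list.
#' @export
ic_prior <- function(pseudo = 0.5, n_mc = 100000, credible_level = 0.95) {
  stopifnot(pseudo > 0, n_mc >= 1, credible_level > 0, credible_level < 1)
  structure(list(pseudo = pseudo, n_mc = as.integer(n_mc),
                 credible_level = credible_level),
            class = "ic_prior")
}

# One Dirichlet(cells + pseudo) posterior sample of the IC, via normalized
# gammas. Returns n_mc draws of log2(p_a / ((p_a+p_b) (p_a+p_c))).
ic_draws <- function(a, b, c, d, pseudo, n_mc) {
  ga <- rgamma(n_mc, a + pseudo)
  gb <- rgamma(n_mc, b + pseudo)
  gc <- rgamma(n_mc, c + pseudo)
  gd <- rgamma(n_mc, d + pseudo)
  tot <- ga + gb + gc + gd
  log2(ga * tot / ((ga + gb) * (ga + gc)))
}

#' BCPNN information component (IC) with Monte-Carlo credible interval
#'
#' The IC measures, on a log2 scale, how much more often the drug and event
#' are co-reported than expected under independence. Point estimate:
#' `log2((a + s) / (E + s))` with expected count `E = (a+b)(a+c)/n` and
#' shrinkage pseudo-count `s` (default 0.5), so sparse tables are pulled
#' toward 0. The credible interval is obtained by sampling the cell
#' probabilities from a Dirichlet(cells + s) posterior, recomputing the IC
#' per draw, and taking empirical quantiles; a signal requires the lower
#' bound to exceed 0.
#'
#' @inheritParams compute_prr
#' @param prior An [ic_prior()].
#' @param seed Integer seed for the Monte-Carlo draws (reproducible; the
#'   caller's RNG state is untouched). `NULL` uses the current RNG stream.
#' @return List with `ic`, `ci_low`, `ci_high`, and `mc_se_low`, the
#'   batch-means Monte-Carlo standard error of the lower bound. A warning is
#'   issued when `mc_se_low` exceeds 0.05 log2 units.
#' @export
#' @examples
#' compute_ic(contingency_table(10, 90, 10, 890), seed = 1)
compute_ic <- function(table, prior = ic_prior(), seed = NULL) {
  stopifnot(inherits(prior, "ic_prior"))
  x <- as_cells(table)
  if (sum(x) == 0) stop("empty table: n_total = 0", call. = FALSE)
  e <- (x["a"] + x["b"]) * (x["a"] + x["c"]) / sum(x)
  ic <- unname(log2((x["a"] + prior$pseudo) / (e + prior$pseudo)))
  alpha <- (1 - prior$credible_level) / 2
  draws <- with_seed(seed, ic_draws(x["a"], x["b"], x["c"], x["d"],
                                    prior$pseudo, prior$n_mc))
  ci <- unname(quantile(draws, c(alpha, 1 - alpha), names = FALSE))
  # MC uncertainty of the lower quantile via 10-batch means
  nb <- 10L
  usable <- prior$n_mc - prior$n_mc %% nb
  se_low <- if (usable >= nb * 20) {
    batches <- matrix(draws[seq_len(usable)], ncol = nb)
    sd(apply(batches, 2, quantile, probs = alpha, names = FALSE)) / sqrt(nb)
  } else NA_real_
  if (!is.na(se_low) && se_low > 0.05) {
    warning("IC credible bound is Monte-Carlo unstable (se = ",
            signif(se_low, 2), "); increase n_mc", call. = FALSE)
  }
  list(ic = ic, ci_low = ci[1], ci_high = ci[2], mc_se_low = se_low)
}

#' Screen a collection of contingency tables
#'
#' Computes PRR, ROR, chi-square, and IC (with intervals) for every table,
#' deterministically given `seed`.
#'
#' @param tables Tibble from [build_all_contingency()] (columns `drug`,
#'   `event`, `a`, `b`, `c`, `d`).
#' @param prior An [ic_prior()]; lower `n_mc` (e.g. 2000) for large screens.
#' @param yates Use the Yates-corrected chi-square.
#' @param seed Integer seed for the IC Monte-Carlo draws.
#' @return Tibble with one row per table: `drug`, `event`, `n` (the `a`
#'   cell), `prr`, `prr_l`, `prr_u`, `ror`, `ror_l`, `ror_u`, `chi2`, `ic`,
#'   `ic_l`, `ic_u`, `corrected`.
#' @export
#' @examples
#' kept <- apply_inclusion_filters(antivegf_fixture())$reports
#' tabs <- build_all_contingency(build_pairs(kept), min_a = 3)
#' screen(tabs, prior = ic_prior(n_mc = 5000), seed = 7)
screen <- function(tables, prior = ic_prior(), yates = TRUE, seed = 20160701) {
  stopifnot(all(c("drug", "event", "a", "b", "c", "d") %in% names(tables)))
  if (nrow(tables) == 0) {
    return(tibble::tibble(drug = character(), event = character(), n = numeric(),
                          prr = numeric(), prr_l = numeric(), prr_u = numeric(),
                          ror = numeric(), ror_l = numeric(), ror_u = numeric(),
                          chi2 = numeric(), ic = numeric(), ic_l = numeric(),
                          ic_u = numeric(), corrected = logical()))
  }
  a <- tables$a; b <- tables$b; c <- tables$c; d <- tables$d
  pr <- prr_vec(a, b, c, d, correct = TRUE)
  ro <- ror_vec(a, b, c, d)
  x2 <- chi2_vec(a, b, c, d, yates = yates)
  n <- a + b + c + d
  e <- (a + b) * (a + c) / n
  ic_pt <- log2((a + prior$pseudo) / (e + prior$pseudo))
  alpha <- (1 - prior$credible_level) / 2
  ci <- with_seed(seed, vapply(seq_along(a), function(i) {
    quantile(ic_draws(a[i], b[i], c[i], d[i], prior$pseudo, prior$n_mc),
             c(alpha, 1 - alpha), names = FALSE)
  }, numeric(2)))
  tibble::tibble(
    drug = tables$drug, event = tables$event, n = a,
    prr = pr$prr, prr_l = pr$ci_low, prr_u = pr$ci_high,
    ror = ro$ror, ror_l = ro$ci_low, ror_u = ro$ci_high,
    chi2 = x2,
    ic = ic_pt, ic_l = ci[1, ], ic_u = ci[2, ],
    corrected = pr$corrected
  )
}
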