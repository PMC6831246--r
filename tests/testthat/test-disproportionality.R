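test_that("PRR matches hand arithmetic and the fraction-ratio oracle", {
  expect_equal(compute_prr(contingency_table(5, 45, 10, 90))$prr, 1.0)
  r <- compute_prr(contingency_table(10, 90, 10, 890))
  expect_equal(r$prr, 9.0)
  expect_equal(r$prr, prr_oracle(10, 90, 10, 890))
  expect_false(r$corrected)
  se <- prr_se_oracle(10, 90, 10, 890)
  expect_equal(r$ci_low, exp(log(9) - 1.96 * se), tolerance = 1e-12)
  expect_equal(r$ci_high, exp(log(9) + 1.96 * se), tolerance = 1e-12)

  z <- compute_prr(contingency_table(3, 0, 5, 12))
  expect_true(z$corrected)
  u <- compute_prr(contingency_table(0, 10, 5, 85), correct = FALSE)
  expect_equal(u$prr, 0)
  expect_true(is.na(u$ci_low))
})

test_that("ROR matches the odds-ratio oracle, with zero-cell correction flagged", {
  r0 <- compute_ror(contingency_table(5, 5, 5, 5))
  expect_equal(r0$ror, 1.0)
  expect_true(r0$ci_low < 1 && r0$ci_high > 1)

  r <- compute_ror(contingency_table(10, 90, 10, 890))
  expect_equal(r$ror, 9.888889, tolerance = 1e-6)
  expect_equal(r$ror, ror_oracle(10, 90, 10, 890))
  se <- ror_se_oracle(10, 90, 10, 890)
  expect_equal(r$ci_low, exp(log(r$ror) - 1.96 * se), tolerance = 1e-9)

  z <- compute_ror(contingency_table(3, 0, 5, 12))
  expect_true(z$corrected)
  expect_equal(z$ror, ror_oracle(3.5, 0.5, 5.5, 12.5))
})

test_that("chi-square agrees with the independent oracle and behaves at the edges", {
  # proportional rows: observed = expected
  expect_equal(compute_chi2(contingency_table(10, 90, 20, 180), yates = FALSE), 0)
  expect_equal(compute_chi2(contingency_table(10, 90, 20, 180), yates = TRUE), 0)
  expect_equal(compute_chi2(contingency_table(10, 90, 10, 890), yates = FALSE),
               chi2_oracle(10, 90, 10, 890, yates = FALSE), tolerance = 1e-12)
  expect_lte(compute_chi2(contingency_table(10, 90, 10, 890), yates = TRUE),
             compute_chi2(contingency_table(10, 90, 10, 890), yates = FALSE))
  # zero margin convention
  expect_equal(compute_chi2(contingency_table(0, 0, 10, 90)), 0)
})

test_that("IC point estimate follows the shrinkage formula", {
  r <- compute_ic(contingency_table(10, 90, 10, 890),
                  ic_prior(n_mc = 20000), seed = 42)
  expect_equal(r$ic, log2(10.5 / 2.5), tolerance = 1e-12)
  expect_equal(r$ic, 2.070389, tolerance = 1e-6)
  expect_true(r$ci_low <= r$ic && r$ic <= r$ci_high)

  # large exact-independence table: |IC| bounded by the shrinkage term
  big <- compute_ic(contingency_table(1000, 9000, 9000, 81000),
                    ic_prior(n_mc = 5000), seed = 1)
  expect_lt(abs(big$ic), 0.05)

  # deficit direction when nothing is co-reported; the heavy-tailed posterior
  # of an empty a cell also trips the MC-instability guard at modest n_mc
  expect_warning(
    none <- compute_ic(contingency_table(0, 100, 100, 800),
                       ic_prior(n_mc = 5000), seed = 1),
    "Monte-Carlo unstable")
  expect_lt(none$ic, 0)
  expect_error(compute_ic(contingency_table(0, 0, 0, 0)), "n_total")
})

test_that("IC credible interval is reproducible, seed-isolated, and converges in n_mc", {
  tab <- contingency_table(10, 90, 10, 890)
  a <- compute_ic(tab, ic_prior(n_mc = 10000), seed = 7)
  b <- compute_ic(tab, ic_prior(n_mc = 10000), seed = 7)
  expect_identical(a, b)
  # the caller's RNG stream is untouched
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(compute_ic(tab, ic_prior(n_mc = 1000), seed = 3))
  expect_identical(runif(1), before)
  # doubling n_mc moves the bounds by less than 3 MC standard errors
  small <- compute_ic(tab, ic_prior(n_mc = 20000), seed = 11)
  large <- compute_ic(tab, ic_prior(n_mc = 40000), seed = 12)
  expect_lt(abs(small$ci_low - large$ci_low),
            3 * sqrt(small$mc_se_low^2 + large$mc_se_low^2))
})

test_that("independence tables are null for every statistic", {
  tab <- contingency_table(40, 360, 160, 1440)   # rows proportional
  expect_equal(compute_prr(tab)$prr, 1)
  expect_equal(compute_ror(tab)$ror, 1)
  expect_equal(compute_chi2(tab, yates = FALSE), 0)
  ic <- compute_ic(tab, ic_prior(n_mc = 2000), seed = 1)
  expect_lt(abs(ic$ic), 0.05)
})

test_that("ROR >= PRR exactly when d(a+b) >= b(c+d)", {
  set.seed(202)
  for (i in 1:200) {
    x <- sample(1:300, 4, replace = TRUE)
    prr <- compute_prr(x)$prr
    ror <- compute_ror(x)$ror
    lhs <- x[4] * (x[1] + x[2])
    rhs <- x[2] * (x[3] + x[4])
    expect_equal(ror >= prr, lhs >= rhs)
  }
})

test_that("scaling all cells up narrows the PRR and ROR intervals", {
  base <- c(8, 72, 15, 905)
  for (k in c(2, 5, 10)) {
    p1 <- compute_prr(base); p2 <- compute_prr(base * k)
    r1 <- compute_ror(base); r2 <- compute_ror(base * k)
    expect_lt(log(p2$ci_high / p2$ci_low), log(p1$ci_high / p1$ci_low))
    expect_lt(log(r2$ci_high / r2$ci_low), log(r1$ci_high / r1$ci_low))
  }
})

test_that("screen composes the per-statistic operations deterministically", {
  expect_equal(nrow(screen(tibble::tibble(drug = character(), event = character(),
                                          a = numeric(), b = numeric(),
                                          c = numeric(), d = numeric()))), 0)
  tabs <- tibble::tibble(drug = "X", event = "y", a = 10, b = 90, c = 10, d = 890)
  res <- screen(tabs, prior = ic_prior(n_mc = 20000), seed = 5)
  expect_equal(res$prr, compute_prr(contingency_table(10, 90, 10, 890))$prr)
  expect_equal(res$ror, compute_ror(contingency_table(10, 90, 10, 890))$ror)
  expect_equal(res$chi2, compute_chi2(contingency_table(10, 90, 10, 890), yates = TRUE))
  expect_equal(res$ic, compute_ic(contingency_table(10, 90, 10, 890),
                                  ic_prior(n_mc = 100), seed = 1)$ic)
  expect_identical(res, screen(tabs, prior = ic_prior(n_mc = 20000), seed = 5))
  expect_false(identical(res$ic_l,
                         screen(tabs, prior = ic_prior(n_mc = 20000), seed = 6)$ic_l))
})
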