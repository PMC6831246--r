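test_that("design flags are derived per report", {
  reports <- tiny_reports()
  design <- suppressWarnings(build_design(reports, "AAA", "headache"))
  expect_equal(design$exposure, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(design$outcome, c(TRUE, TRUE, FALSE, TRUE))
  # concomitant-only use of the drug is not exposure
  expect_false(build_design(tiny_reports(), "CCC", "headache")$exposure[2])
})

test_that("design flag counts match a brute-force recount on synthetic data", {
  kept <- apply_inclusion_filters(generate_reports(prop_config(8, n = 500)))$reports
  design <- suppressWarnings(build_design(kept, "DR1", "ev1"))
  brute_exp <- sum(vapply(kept$drugs, function(d) "DR1" %in% d$atc_code[d$suspected],
                          logical(1)))
  brute_out <- sum(vapply(kept$events, function(e) "ev1" %in% e, logical(1)))
  expect_equal(sum(design$exposure), brute_exp)
  expect_equal(sum(design$outcome), brute_out)
  expect_equal(nrow(design), nrow(kept))
})

test_that("with constant covariates the adjusted OR equals the crude OR", {
  set.seed(31)
  n <- 800
  design <- tibble::tibble(
    report_id = as.character(1:n),
    exposure = runif(n) < 0.3,
    sex = factor("male"),
    age_group = factor("ge60")
  )
  design$outcome <- runif(n) < ifelse(design$exposure, 0.3, 0.1)
  fit <- suppressWarnings(fit_logistic(design))
  expect_equal(fit$or_adjusted, crude_or(design), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$n_used, n)
})

test_that("the fitted solution satisfies the score equations", {
  kept <- apply_inclusion_filters(generate_reports(prop_config(9, n = 2000)))$reports
  design <- build_design(kept, "DR2", "ev3")
  fit <- fit_logistic(design)
  # independent gradient evaluation: X'(y - p) at the estimate
  X <- stats::model.matrix(~ exposure + sex + age_group, data = design)
  beta <- fit$coefficients$estimate[match(colnames(X), fit$coefficients$term)]
  p <- stats::plogis(drop(X %*% beta))
  grad <- drop(crossprod(X, design$outcome - p))
  expect_lt(max(abs(grad)), 1e-6)
})

test_that("adjusted and crude ORs agree without confounding", {
  cfg <- synthetic_config(
    20000,
    drugs = c(DX = 1, DY = 1, DZ = 2),
    events = setNames(rep(1, 10), paste0("ev", 1:10)),
    lambda = data.frame(drug = "DX", event = "ev1", lambda = 5),
    seed = 21)
  kept <- apply_inclusion_filters(generate_reports(cfg))$reports
  design <- build_design(kept, "DX", "ev1")
  fit <- fit_logistic(design)
  expect_true(fit$converged)
  expect_equal(log(fit$or_adjusted), log(crude_or(design)), tolerance = 0.1)
})

test_that("confounding by age biases the crude but not the adjusted OR", {
  cfg <- synthetic_config(
    20000,
    drugs = c(DX = 1, DY = 1, DZ = 1),
    events = c(filler1 = 1, filler2 = 1, filler3 = 1),
    drug_age_mult = list(DX = c(0.3, 0.5, 1, 3)),
    bernoulli_events = list(list(event = "target event", drug = "DX", or = 3,
                                 base_odds = c(0.01, 0.02, 0.05, 0.12))),
    seed = 22)
  kept <- apply_inclusion_filters(generate_reports(cfg))$reports
  design <- build_design(kept, "DX", "target event")
  fit <- fit_logistic(design)
  expect_true(fit$converged)
  expect_true(fit$ci_low <= 3 && 3 <= fit$ci_high)
  expect_gt(crude_or(design), fit$or_adjusted)
})

test_that("separation is reported, not silently fixed", {
  n <- 60
  design <- tibble::tibble(
    report_id = as.character(1:n),
    exposure = rep(c(TRUE, FALSE), each = n / 2),
    outcome = rep(c(TRUE, FALSE), each = n / 2),   # perfectly separated
    sex = factor(rep(c("male", "female"), n / 2)),
    age_group = factor(rep(c("40_59", "ge60"), n / 2))
  )
  fit <- suppressWarnings(fit_logistic(design))
  expect_false(fit$converged)
})

test_that("adjusted_screen composes fit_logistic over the pair list", {
  expect_equal(nrow(adjusted_screen(tiny_reports(),
                                    tibble::tibble(drug = character(),
                                                   event = character()))), 0)
  kept <- apply_inclusion_filters(generate_reports(prop_config(10, n = 2000)))$reports
  out <- adjusted_screen(kept, tibble::tibble(drug = c("DR1", "DR2"),
                                              event = c("ev1", "ev2")))
  expect_equal(nrow(out), 2)
  direct <- fit_logistic(build_design(kept, "DR1", "ev1"))
  expect_equal(out$or[1], direct$or_adjusted)
  expect_equal(out$ci_l[1], direct$ci_low)
  expect_equal(out$n_used[1], direct$n_used)
})
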