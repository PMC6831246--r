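# Case/non-case logistic regression: sex- and age-adjusted reporting odds
# ratios at the report level. One row per retained report; the outcome is
# "report mentions the target event", the exposure "report names the target
# drug among its suspected drugs".

#' Build a case/non-case design for one drug-event combination
#'
#' @param reports Filtered report-set tibble.
#' @param drug Target ATC code (exposure: suspected drug entries only, the
#'   same qualification rule as [build_pairs()]).
#' @param event Target event preferred term (outcome: any event of the
#'   report, canonicalized comparison).
#' @return Tibble with one row per report: `report_id`, `outcome`,
#'   `exposure` (logicals), `sex` and `age_group` (factors; the age
#'   reference level is the youngest non-empty group). Degenerate designs
#'   (single outcome or exposure class) are flagged with a warning and a
#'   `degenerate` attribute.
#' @export
build_design <- function(reports, drug, event) {
  reports <- validate_reports(reports)
  exposure <- vapply(reports$drugs, function(d) {
    any(d$suspected & !is.na(d$atc_code) & d$atc_code == toupper(trimws(drug)))
  }, logical(1))
  outcome <- vapply(reports$events, function(e) {
    canonical_term(event) %in% canonical_term(e)
  }, logical(1))
  age_group <- cut_age(reports$age_years)
  age_group <- droplevels(age_group)          # reference = youngest non-empty
  design <- tibble::tibble(
    report_id = reports$report_id,
    outcome = outcome,
    exposure = exposure,
    sex = droplevels(factor(reports$sex, levels = c("male", "female", "missing"))),
    age_group = age_group
  )
  degenerate <- character()
  if (length(unique(design$outcome)) < 2) degenerate <- c(degenerate, "outcome")
  if (length(unique(design$exposure)) < 2) degenerate <- c(degenerate, "exposure")
  if (length(degenerate) > 0) {
    warning("degenerate design: single class for ",
            paste(degenerate, collapse = ", "), call. = FALSE)
  }
  attr(design, "degenerate") <- degenerate
  design
}

#' Fit the adjusted logistic model for one design
#'
#' Maximum-likelihood logistic regression of the outcome on exposure, sex,
#' and age group (Fisher-scoring IRLS, convergence tolerance 1e-12, up to
#' 100 iterations). The adjusted reporting odds ratio is the exponentiated
#' exposure coefficient with a Wald 95% CI, `exp(beta +/- 1.96 se)`.
#' Covariates with a single observed level are dropped with a warning.
#' Separation or non-convergence is reported via `converged = FALSE` (a
#' diverging coefficient or an exploding standard error), never silently
#' "fixed".
#'
#' @param design Tibble from [build_design()].
#' @return An `adjusted_or` list: `or_adjusted`, `ci_low`, `ci_high`,
#'   `coefficients` (tibble of term/estimate/se), `converged`, `diagnostics`
#'   (captured fitter warnings, e.g. separation symptoms), `n_used`.
#' @export
fit_logistic <- function(design) {
  stopifnot(all(c("outcome", "exposure", "sex", "age_group") %in% names(design)))
  if (length(unique(design$outcome)) < 2 || length(unique(design$exposure)) < 2) {
    stop("design needs both outcome classes and both exposure classes", call. = FALSE)
  }
  df <- design[!is.na(design$age_group) & !is.na(design$sex), , drop = FALSE]
  df$sex <- droplevels(df$sex)
  df$age_group <- droplevels(df$age_group)
  covars <- c("sex", "age_group")
  keep <- vapply(covars, function(v) nlevels(df[[v]]) > 1, logical(1))
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(covars[!keep], collapse = ", "), call. = FALSE)
  }
  rhs <- paste(c("exposure", covars[keep]), collapse = " + ")
  diagnostics <- character()
  fit <- withCallingHandlers(
    glm(stats::as.formula(paste("outcome ~", rhs)),
        family = binomial(), data = df,
        control = glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      # glm.fit emits separation symptoms as warnings; record, do not spam
      diagnostics <<- c(diagnostics, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  beta <- est[["exposureTRUE"]]
  se_b <- se[["exposureTRUE"]]
  converged <- isTRUE(fit$converged) && all(is.finite(se)) &&
    max(abs(est)) < 20 && max(se) < 50
  structure(list(
    or_adjusted = exp(beta),
    ci_low = exp(beta - 1.96 * se_b),
    ci_high = exp(beta + 1.96 * se_b),
    coefficients = tibble::tibble(term = names(est), estimate = unname(est),
                                  se = unname(se)),
    converged = converged,
    diagnostics = diagnostics,
    n_used = nrow(df)
  ), class = "adjusted_or")
}

#' @export
print.adjusted_or <- function(x, ...) {
  cat(sprintf("adjusted ROR %.3f (95%% CI %.3f-%.3f), n = %d%s\n",
              x$or_adjusted, x$ci_low, x$ci_high, x$n_used,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Adjusted reporting odds ratios for a set of drug-event combinations
#'
#' Runs [build_design()] and [fit_logistic()] for every row of
#' `pairs_of_interest` (typically the detected signals). Per-combination
#' failures (degenerate designs, separation) are reported in the output, not
#' raised.
#'
#' @param reports Filtered report-set tibble.
#' @param pairs_of_interest Tibble/data frame with columns `drug` and `event`.
#' @return Tibble with columns `drug`, `event`, `or`, `ci_l`, `ci_u`,
#'   `converged`, `n_used`; the full per-fit coefficient tables are attached
#'   as the `fits` attribute (a named list).
#' @export
adjusted_screen <- function(reports, pairs_of_interest) {
  stopifnot(all(c("drug", "event") %in% names(pairs_of_interest)))
  reports <- validate_reports(reports)
  fits <- list()
  rows <- lapply(seq_len(nrow(pairs_of_interest)), function(i) {
    drug <- pairs_of_interest$drug[i]
    event <- pairs_of_interest$event[i]
    res <- tryCatch({
      design <- suppressWarnings(build_design(reports, drug, event))
      fit <- fit_logistic(design)
      fits[[paste(drug, event, sep = "|")]] <<- fit$coefficients
      tibble::tibble(drug = drug, event = event, or = fit$or_adjusted,
                     ci_l = fit$ci_low, ci_u = fit$ci_high,
                     converged = fit$converged, n_used = fit$n_used)
    }, error = function(e) {
      tibble::tibble(drug = drug, event = event, or = NA_real_,
                     ci_l = NA_real_, ci_u = NA_real_,
                     converged = FALSE, n_used = NA_integer_)
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "fits") <- fits
  out
}
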