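# Enum vocabularies for ICSR fields. Tokens are canonical lower-case; readers
# accept any case.

pv_enums <- list(
  report_type = c("spontaneous", "post_marketing_surveillance", "literature", "other"),
  reporter = c("doctor", "pharmacist", "nurse", "consumer", "other", "unknown"),
  sex = c("male", "female", "missing"),
  causality = c("certain", "probable", "possible", "unlikely", "unassessable",
                "unclassified", "missing"),
  seriousness_type = c("hospitalization", "other_including_death", "none")
)

age_group_levels <- c("lt20", "20_39", "40_59", "ge60")

#' Assign the standard pharmacovigilance age groups
#'
#' Cut-points follow the reproductive-period grouping used in spontaneous-report
#' analyses: under 20, 20-39, 40-59, and 60 or older (the 60+ group is
#' inclusive of age 60).
#'
#' @param age_years Numeric vector of ages in years; `NA` allowed.
#' @return Factor with levels `lt20`, `20_39`, `40_59`, `ge60`.
#' @export
#' @examples
#' cut_age(c(5, 19, 20, 39.9, 40, 59, 60, 85))
cut_age <- function(age_years) {
  stopifnot(is.numeric(age_years))
  idx <- findInterval(age_years, c(0, 20, 40, 60))
  idx[!is.na(age_years) & age_years < 0] <- NA_integer_
  factor(age_group_levels[idx], levels = age_group_levels)
}

#' Round half away from zero
#'
#' Presentation rounding for percentages: 31.25 rounds to 31.3, unlike base R's
#' round-half-to-even. Internal statistics are never rounded.
#'
#' @param x Numeric vector.
#' @param digits Decimal places to keep.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Canonical form for preferred-term comparison: lower-case, trimmed,
# whitespace-collapsed.
canonical_term <- function(x) {
  stringr::str_squish(tolower(as.character(x)))
}

# Evaluate `expr` with the RNG seeded from `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
# seed = NULL uses (and advances) the current RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Match a vector of tokens against an enum, case-insensitively. Empty/NA cells
# map to `missing_to` (if given). Unknown tokens raise a validation error
# naming the column and offending rows.
match_enum <- function(x, field, missing_to = NULL) {
  levels <- pv_enums[[field]]
  x <- tolower(trimws(as.character(x)))
  if (!is.null(missing_to)) x[is.na(x) | x == ""] <- missing_to
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    stop(sprintf("invalid %s token(s) %s at row(s) %s",
                 field,
                 paste(sQuote(unique(x[bad])), collapse = ", "),
                 paste(head(which(bad), 5), collapse = ", ")),
         call. = FALSE)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
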