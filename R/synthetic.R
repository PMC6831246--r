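# Seeded synthetic ICSR generator. Reports carry a primary suspected drug,
# optional concomitant drugs, and one or more events whose selection
# probability is proportional to baseline weight x lambda(drug, event) —
# lambda is the generative analogue of the reporting-rate disproportionality
# that PRR/ROR/IC estimate (lambda = 1 everywhere means independence).

check_probs <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || sum(p) <= 0) {
    stop(what, " must be non-negative with positive sum", call. = FALSE)
  }
  p / sum(p)
}

#' Configuration for the synthetic report generator
#'
#' @param n_reports Number of reports to generate.
#' @param drugs Named numeric vector: ATC code -> marginal sampling weight of
#'   the primary suspected drug.
#' @param events Named numeric vector: preferred term -> baseline weight.
#' @param lambda Optional data frame with columns `drug`, `event`, `lambda`
#'   (> 0): multiplies the event's weight when the report's primary suspected
#'   drug matches. Omitted combinations default to 1 (independence).
#' @param drugs_per_report,events_per_report Named numeric vectors giving the
#'   distribution of per-report drug/event counts, e.g. `c("1" = 0.8, "2" = 0.2)`.
#'   Event counts must be >= 1 (reports always carry at least one event).
#' @param sex_probs,age_probs Sampling distributions for sex
#'   (male/female) and age group (`lt20`, `20_39`, `40_59`, `ge60`).
#' @param drug_age_mult Optional named list: drug -> length-4 multiplier on
#'   its weight per age group (the exposure side of the confounding knob).
#' @param bernoulli_events Optional list of independent-inclusion events (the
#'   outcome side of the confounding knob, with an exact conditional odds
#'   ratio). Each element is a list with `event`, `base_odds` (scalar or
#'   length-4 per age group), and optionally `drug` and `or` (> 0): the
#'   inclusion odds are `base_odds[age] * or^(primary drug == drug)`, so the
#'   within-age-group odds ratio between exposed and unexposed reports is
#'   exactly `or`.
#' @param p_serious Probability a report is serious.
#' @param report_type_probs,reporter_probs,causality_probs Categorical
#'   sampling distributions for the respective fields.
#' @param year_range Integer vector `c(first, last)` reporting year.
#' @param contamination Named list of rates (summing to < 1) for planted
#'   filter-failing records: `missing_sex`, `missing_age`, `missing_atc`,
#'   `followup`, `bad_causality`. Contaminated reports carry a
#'   `contaminant:<rule>` tag in the `note` column.
#' @param seed Integer seed; identical configurations and seeds produce
#'   byte-identical output.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_reports,
                             drugs,
                             events,
                             lambda = NULL,
                             drugs_per_report = c("1" = 1),
                             events_per_report = c("1" = 1),
                             sex_probs = c(male = 0.5, female = 0.5),
                             age_probs = c(lt20 = 0.05, "20_39" = 0.2,
                                           "40_59" = 0.35, ge60 = 0.4),
                             drug_age_mult = NULL,
                             bernoulli_events = NULL,
                             p_serious = 0.15,
                             report_type_probs = c(spontaneous = 0.6,
                                                   post_marketing_surveillance = 0.25,
                                                   literature = 0.1, other = 0.05),
                             reporter_probs = c(doctor = 0.55, pharmacist = 0.15,
                                                nurse = 0.1, consumer = 0.1,
                                                other = 0.05, unknown = 0.05),
                             causality_probs = c(certain = 0.1, probable = 0.3,
                                                 possible = 0.6),
                             year_range = c(2007L, 2016L),
                             contamination = list(),
                             seed = 1L) {
  stopifnot(n_reports >= 1, length(drugs) >= 1, length(events) >= 2,
            !is.null(names(drugs)), !is.null(names(events)))
  if (any(!is.finite(drugs)) || any(drugs <= 0)) stop("drug weights must be positive", call. = FALSE)
  if (any(!is.finite(events)) || any(events <= 0)) stop("event weights must be positive", call. = FALSE)
  if (!is.null(lambda)) {
    stopifnot(all(c("drug", "event", "lambda") %in% names(lambda)),
              all(lambda$lambda > 0))
  }
  if (any(as.integer(names(events_per_report)) < 1)) {
    stop("events_per_report counts must be >= 1", call. = FALSE)
  }
  contamination <- modifyList(list(missing_sex = 0, missing_age = 0,
                                   missing_atc = 0, followup = 0,
                                   bad_causality = 0), as.list(contamination))
  rates <- unlist(contamination)
  if (any(rates < 0) || sum(rates) >= 1) stop("contamination rates must be in [0, 1)", call. = FALSE)
  stopifnot(p_serious >= 0, p_serious <= 1, length(year_range) == 2)
  if (!is.null(drug_age_mult)) {
    stopifnot(is.list(drug_age_mult),
              all(vapply(drug_age_mult, length, integer(1)) == 4))
  }
  if (!is.null(bernoulli_events)) {
    for (be in bernoulli_events) {
      stopifnot(!is.null(be$event), length(be$base_odds) %in% c(1, 4),
                all(be$base_odds > 0), is.null(be$or) || be$or > 0)
    }
  }
  structure(list(
    n_reports = as.integer(n_reports),
    drugs = drugs, events = events, lambda = lambda,
    drugs_per_report = check_probs(drugs_per_report, "drugs_per_report"),
    events_per_report = check_probs(events_per_report, "events_per_report"),
    sex_probs = check_probs(sex_probs, "sex_probs"),
    age_probs = check_probs(age_probs, "age_probs"),
    drug_age_mult = drug_age_mult,
    bernoulli_events = bernoulli_events,
    p_serious = p_serious,
    report_type_probs = check_probs(report_type_probs, "report_type_probs"),
    reporter_probs = check_probs(reporter_probs, "reporter_probs"),
    causality_probs = check_probs(causality_probs, "causality_probs"),
    year_range = as.integer(year_range),
    contamination = contamination,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

# Event weight vector for a given primary drug: baseline x lambda(drug, .)
event_weights_for <- function(config, drug) {
  w <- config$events
  if (!is.null(config$lambda)) {
    hit <- config$lambda$drug == drug
    if (any(hit)) {
      idx <- match(config$lambda$event[hit], names(w))
      ok <- !is.na(idx)
      w[idx[ok]] <- w[idx[ok]] * config$lambda$lambda[hit][ok]
    }
  }
  w
}

#' Generate a synthetic spontaneous-report dataset
#'
#' Sampling order: age group, sex, primary suspected drug (weights optionally
#' age-modulated), concomitant drugs, categorical events (weights
#' `baseline x lambda`), independent Bernoulli events, then report metadata
#' and contamination. The caller's RNG state is preserved.
#'
#' @param config A [synthetic_config()].
#' @return A report-set tibble (see [icsr_set()]).
#' @export
#' @examples
#' cfg <- synthetic_config(50, drugs = c(A = 1, B = 1),
#'                         events = c(x = 1, y = 1, z = 2), seed = 7)
#' reports <- generate_reports(cfg)
#' nrow(reports)
generate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_reports
  with_seed(config$seed, {
    age_idx <- sample.int(4, n, replace = TRUE, prob = config$age_probs)
    age_lo <- c(1, 20, 40, 60)[age_idx]
    age_hi <- c(19, 39, 59, 90)[age_idx]
    age_years <- age_lo + floor(runif(n) * (age_hi - age_lo + 1))
    sex <- names(config$sex_probs)[sample.int(length(config$sex_probs), n,
                                              replace = TRUE, prob = config$sex_probs)]

    drug_names <- names(config$drugs)
    primary <- character(n)
    for (g in 1:4) {
      idx <- which(age_idx == g)
      if (length(idx) == 0) next
      w <- config$drugs
      if (!is.null(config$drug_age_mult)) {
        for (d in names(config$drug_age_mult)) {
          w[d] <- w[d] * config$drug_age_mult[[d]][g]
        }
      }
      primary[idx] <- drug_names[sample.int(length(w), length(idx),
                                            replace = TRUE, prob = w)]
    }
    n_drugs <- as.integer(names(config$drugs_per_report))[
      sample.int(length(config$drugs_per_report), n, replace = TRUE,
                 prob = config$drugs_per_report)]

    event_names <- names(config$events)
    n_events <- as.integer(names(config$events_per_report))[
      sample.int(length(config$events_per_report), n, replace = TRUE,
                 prob = config$events_per_report)]
    events <- vector("list", n)
    for (d in unique(primary)) {
      w <- event_weights_for(config, d)
      idx <- which(primary == d)
      singles <- idx[n_events[idx] == 1]
      if (length(singles) > 0) {
        picks <- event_names[sample.int(length(w), length(singles),
                                        replace = TRUE, prob = w)]
        events[singles] <- as.list(picks)
      }
      for (i in idx[n_events[idx] > 1]) {
        k <- min(n_events[i], length(event_names))
        events[[i]] <- event_names[sample.int(length(w), k, prob = w)]
      }
    }
    if (!is.null(config$bernoulli_events)) {
      for (be in config$bernoulli_events) {
        odds <- if (length(be$base_odds) == 4) be$base_odds[age_idx] else rep(be$base_odds, n)
        if (!is.null(be$drug)) {
          odds <- odds * (be$or %||% 1)^(primary == be$drug)
        }
        inc <- runif(n) < odds / (1 + odds)
        events[inc] <- lapply(events[inc], function(e) unique(c(e, be$event)))
      }
    }

    drugs <- vector("list", n)
    extra_pool <- drug_names
    for (i in seq_len(n)) {
      extras <- if (n_drugs[i] > 1 && length(extra_pool) > 1) {
        setdiff(extra_pool[sample.int(length(extra_pool), min(n_drugs[i] - 1,
                                                              length(extra_pool)))],
                primary[i])
      } else character()
      k <- 1L + length(extras)
      drugs[[i]] <- tibble::new_tibble(
        list(atc_code = c(primary[i], extras),
             suspected = c(TRUE, rep(FALSE, length(extras)))),
        nrow = k)
    }

    serious <- runif(n) < config$p_serious
    seriousness_type <- ifelse(serious,
                               ifelse(runif(n) < 0.5, "hospitalization",
                                      "other_including_death"),
                               "none")
    out <- icsr_set(
      report_id = sprintf("SR%06d", seq_len(n)),
      is_initial = TRUE,
      report_year = sample(seq(config$year_range[1], config$year_range[2]),
                           n, replace = TRUE),
      report_type = names(config$report_type_probs)[
        sample.int(length(config$report_type_probs), n, replace = TRUE,
                   prob = config$report_type_probs)],
      reporter = names(config$reporter_probs)[
        sample.int(length(config$reporter_probs), n, replace = TRUE,
                   prob = config$reporter_probs)],
      sex = sex,
      age_years = age_years,
      causality = names(config$causality_probs)[
        sample.int(length(config$causality_probs), n, replace = TRUE,
                   prob = config$causality_probs)],
      serious = serious,
      seriousness_type = seriousness_type,
      drugs = drugs,
      events = events,
      note = NA_character_
    )

    rates <- unlist(config$contamination)
    if (sum(rates) > 0) {
      u <- runif(n)
      cs <- cumsum(rates)
      rule <- findInterval(u, cs) + 1L   # u >= max(cs) -> no contamination
      rule[rule > length(rates)] <- NA_integer_
      rule_name <- names(rates)[rule]
      hit <- which(!is.na(rule_name))
      for (i in hit) {
        out$note[i] <- paste0("contaminant:", rule_name[i])
        switch(rule_name[i],
               missing_sex = { out$sex[i] <- "missing" },
               missing_age = { out$age_years[i] <- NA_real_ },
               missing_atc = {
                 d <- out$drugs[[i]]
                 d$atc_code <- NA_character_
                 out$drugs[[i]] <- d
               },
               followup = { out$is_initial[i] <- FALSE },
               bad_causality = { out$causality[i] <- "unlikely" })
      }
    }
    out
  })
}
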