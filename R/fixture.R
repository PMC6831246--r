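# Deterministic worked-example dataset: an anti-VEGF spontaneous-report
# extract whose report-level marginals are back-calculated from the published
# per-drug percentages (count = round(pct * total / 100), each count verified
# to re-round to the printed percentage under half-up presentation rounding).
# Contains no randomness: regeneration is byte-identical.

rep_counts <- function(labels, counts) rep(labels, times = counts)

# Deterministic decorrelating permutation: i -> (i * k) mod n with k coprime
# to n, so different attributes are not assigned in the same blocks.
scatter <- function(x, k) {
  n <- length(x)
  x[order((seq_len(n) * k) %% n, seq_len(n))]
}

one_drug <- function(atc) {
  list(tibble::new_tibble(list(atc_code = atc, suspected = TRUE), nrow = 1L))
}

#' Deterministic anti-VEGF worked-example report set
#'
#' A synthetic raw extract emulating a national spontaneous-report database
#' slice for two intravitreal anti-VEGF agents — aflibercept (`S01LA05`) and
#' ranibizumab (`S01LA04`) — plus a comparator background of other drugs.
#' After the standard inclusion filters exactly 32 aflibercept and 103
#' ranibizumab reports remain, with category counts chosen so the
#' characteristics table reproduces the published per-drug percentages
#' (male 71.9/62.1, age 60+ 84.4/77.7, post-marketing surveillance 31.3/46.6,
#' consumer-reported 9.4/1.9, SAE ratio 75.0/19.4 for
#' aflibercept/ranibizumab). Seven planted contaminant records — one per
#' inclusion rule, tagged `contaminant:<rule>` in the `note` column — must be
#' removed by [apply_inclusion_filters()].
#'
#' This is a constructed fixture for demonstrations and tests, not a real
#' database extract: pair-level event frequencies are invented (only the
#' report-level marginals above are constrained).
#'
#' @return A raw report-set tibble of 502 records (135 anti-VEGF, 360
#'   background, 7 contaminants).
#' @export
#' @examples
#' res <- apply_inclusion_filters(antivegf_fixture())
#' res$log
antivegf_fixture <- function() {
  afl <- "S01LA05"
  ran <- "S01LA04"
  bg_drugs <- c("N02BE01", "J01CA04", "C09AA05", "A02BC01", "M01AE01", "R06AE07")

  afl_events <- rep_counts(
    c("endophthalmitis", "conjunctivitis", "muscae volitantes",
      "retinal disorder", "ocular haemorrhage", "intraocular pressure increased",
      "visual acuity decreased", "eye abnormality"),
    c(12, 5, 4, 3, 3, 2, 2, 1))
  afl_tbl <- tibble::tibble(
    drug = afl,
    event = afl_events,
    sex = scatter(rep_counts(c("male", "female"), c(23, 9)), 13),
    age_years = scatter(c(rep(c(62, 68, 74, 81), length.out = 27),
                          45, 52, 58, 33, 15), 17),
    report_type = scatter(rep_counts(
      c("post_marketing_surveillance", "spontaneous", "literature", "other"),
      c(10, 16, 4, 2)), 7),
    reporter = scatter(rep_counts(c("doctor", "pharmacist", "nurse", "consumer"),
                                  c(20, 6, 3, 3)), 11),
    serious = scatter(rep_counts(c(TRUE, FALSE), c(24, 8)), 5),
    causality = scatter(rep_counts(c("certain", "probable", "possible"),
                                   c(6, 10, 16)), 3),
    report_year = scatter(rep_counts(2013:2016, c(2, 6, 10, 14)), 9)
  )

  ran_events <- rep_counts(
    c("retinal disorder", "medicine ineffective", "conjunctival haemorrhage",
      "acanthosis", "endophthalmitis", "retinal detachment",
      "retinal haemorrhage", "vision abnormal", "conjunctivitis",
      "muscae volitantes", "visual acuity decreased",
      "intraocular pressure increased", "eye pain", "headache"),
    c(15, 15, 9, 8, 8, 7, 7, 7, 7, 6, 5, 4, 3, 2))
  ran_tbl <- tibble::tibble(
    drug = ran,
    event = ran_events,
    sex = scatter(rep_counts(c("male", "female"), c(64, 39)), 13),
    age_years = scatter(c(rep(c(61, 66, 72, 79, 84), length.out = 80),
                          rep(c(42, 48, 55, 58), length.out = 12),
                          rep(c(25, 31, 37), length.out = 8),
                          18, 19, 17), 17),
    report_type = scatter(rep_counts(
      c("post_marketing_surveillance", "literature", "spontaneous"),
      c(48, 50, 5)), 7),
    reporter = scatter(rep_counts(c("doctor", "pharmacist", "nurse", "consumer"),
                                  c(70, 20, 11, 2)), 11),
    serious = scatter(rep_counts(c(TRUE, FALSE), c(20, 83)), 5),
    causality = scatter(rep_counts(c("certain", "probable", "possible"),
                                   c(15, 35, 53)), 3),
    report_year = scatter(rep_counts(2008:2016,
                                     c(1, 1, 2, 2, 2, 21, 22, 25, 27)), 9)
  )

  bg_events <- rep_counts(
    c("headache", "nausea", "rash", "dizziness", "pruritus", "pyrexia",
      "urticaria", "injection site reaction", "conjunctivitis",
      "retinal disorder", "vision abnormal", "endophthalmitis",
      "retinal haemorrhage", "muscae volitantes", "conjunctival haemorrhage",
      "visual acuity decreased"),
    c(80, 60, 50, 40, 30, 30, 20, 15, 8, 6, 5, 4, 4, 3, 3, 2))
  nb <- length(bg_events)   # 360
  bg_tbl <- tibble::tibble(
    drug = rep(bg_drugs, each = nb / length(bg_drugs)),
    event = scatter(bg_events, 13),
    sex = rep_len(c("male", "female"), nb),
    age_years = rep_len(c(8, 16, 24, 33, 41, 47, 56, 63, 71, 78, 85), nb),
    report_type = "spontaneous",
    reporter = rep_len(c("doctor", "doctor", "pharmacist", "nurse", "consumer"), nb),
    serious = rep_len(c(rep(FALSE, 6), TRUE), nb),
    causality = rep_len(c("certain", "probable", "possible", "possible"), nb),
    report_year = rep_len(2007:2016, nb)
  )

  main <- dplyr::bind_rows(afl_tbl, ran_tbl, bg_tbl)
  n <- nrow(main)
  out <- icsr_set(
    report_id = sprintf("FX%04d", seq_len(n)),
    is_initial = TRUE,
    report_year = main$report_year,
    report_type = main$report_type,
    reporter = main$reporter,
    sex = main$sex,
    age_years = main$age_years,
    causality = main$causality,
    serious = main$serious,
    seriousness_type = ifelse(main$serious,
                              rep_len(c("hospitalization", "other_including_death"), n),
                              "none"),
    drugs = lapply(main$drug, function(d) {
      tibble::new_tibble(list(atc_code = d, suspected = TRUE), nrow = 1L)
    }),
    events = as.list(main$event),
    note = NA_character_
  )

  # One planted record per exclusion rule; each must be dropped by the filter.
  contaminants <- dplyr::bind_rows(
    icsr_set("CT0001", sex = "missing", age_years = 70, drugs = one_drug(afl),
             events = list("endophthalmitis"), note = "contaminant:missing_sex"),
    icsr_set("CT0002", sex = "female", age_years = NA, drugs = one_drug(ran),
             events = list("retinal disorder"), note = "contaminant:missing_age"),
    icsr_set("CT0003", age_years = 66,
             drugs = list(tibble::new_tibble(list(atc_code = NA_character_,
                                                  suspected = TRUE), nrow = 1L)),
             events = list("conjunctivitis"), note = "contaminant:missing_atc"),
    icsr_set("CT0004", age_years = 72, drugs = one_drug(ran),
             events = list(character(0)), note = "contaminant:missing_event"),
    icsr_set("CT0005", is_initial = FALSE, age_years = 61, drugs = one_drug(afl),
             events = list("endophthalmitis"), note = "contaminant:followup"),
    icsr_set("CT0006", age_years = 68, causality = "unlikely", drugs = one_drug(ran),
             events = list("retinal haemorrhage"), note = "contaminant:causality"),
    icsr_set("CT0007", age_years = 55,
             drugs = list(tibble::new_tibble(list(atc_code = "N02BE01",
                                                  suspected = FALSE), nrow = 1L)),
             events = list("headache"), note = "contaminant:no_suspected_drug")
  )
  validate_reports(dplyr::bind_rows(out, contaminants))
}
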