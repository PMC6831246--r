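# Descriptive surfaces: Table-1-style characteristics and annual trends.

drug_reports <- function(reports, drug) {
  sel <- vapply(reports$drugs, function(d) {
    any(d$suspected & !is.na(d$atc_code) & d$atc_code == toupper(trimws(drug)))
  }, logical(1))
  reports[sel, , drop = FALSE]
}

count_levels <- function(x, levels, total) {
  n <- as.integer(table(factor(x, levels = levels)))
  tibble::tibble(level = levels, n = n,
                 pct = if (total > 0) round_half_up(100 * n / total, 1) else NA_real_)
}

#' Report-level characteristics table per drug
#'
#' Counts and percentages by sex, age group, report type, reporter
#' profession, causality level, and seriousness, per drug, over the reports
#' naming that drug among their suspected drugs. Percentages use the drug's
#' total report count, rounded half-up to one decimal (presentation only;
#' internal values are exact). The `serious` stratum's `serious` row is the
#' SAE-to-AE ratio.
#'
#' @param reports Filtered report-set tibble.
#' @param drugs Character vector of ATC codes to tabulate.
#' @return A long tibble: `drug`, `variable`, `level`, `n`, `pct`. The
#'   `total` row carries the drug's report count. Drugs with zero reports
#'   get zero counts and `NA` percentages.
#' @export
#' @examples
#' kept <- apply_inclusion_filters(antivegf_fixture())$reports
#' tab <- summarize_characteristics(kept, c("S01LA05", "S01LA04"))
#' tab[tab$variable == "sex", ]
summarize_characteristics <- function(reports, drugs) {
  reports <- validate_reports(reports)
  strata <- list(
    sex = pv_enums$sex,
    age_group = age_group_levels,
    report_type = pv_enums$report_type,
    reporter = pv_enums$reporter,
    causality = pv_enums$causality,
    seriousness_type = pv_enums$seriousness_type,
    serious = c("serious", "non_serious")
  )
  purrr::map_dfr(drugs, function(drug) {
    sub <- drug_reports(reports, drug)
    total <- nrow(sub)
    vals <- list(
      sex = sub$sex,
      age_group = as.character(cut_age(sub$age_years)),
      report_type = sub$report_type,
      reporter = sub$reporter,
      causality = sub$causality,
      seriousness_type = sub$seriousness_type,
      serious = ifelse(sub$serious, "serious", "non_serious")
    )
    body <- purrr::map_dfr(names(strata), function(v) {
      dplyr::mutate(count_levels(vals[[v]], strata[[v]], total),
                    variable = v, .before = 1)
    })
    dplyr::bind_rows(
      tibble::tibble(variable = "total", level = "reports", n = total, pct = NA_real_),
      body
    ) |>
      dplyr::mutate(drug = drug, .before = 1)
  })
}

#' Annual report and SAE counts per drug
#'
#' Per (drug, year): number of reports, number of serious reports, and the
#' SAE-to-AE ratio as a percentage (half-up, one decimal; `NA` for years
#' with no reports). Years are contiguous over the observed range across the
#' requested drugs, with explicit zero rows.
#'
#' @inheritParams summarize_characteristics
#' @return Tibble with columns `drug`, `year`, `n_ae`, `n_sae`, `sae_ratio`.
#' @export
annual_trends <- function(reports, drugs) {
  reports <- validate_reports(reports)
  subs <- lapply(drugs, function(d) drug_reports(reports, d))
  all_years <- unlist(lapply(subs, function(s) s$report_year))
  if (length(all_years) == 0) {
    return(tibble::tibble(drug = character(), year = integer(),
                          n_ae = integer(), n_sae = integer(),
                          sae_ratio = numeric()))
  }
  years <- seq(min(all_years), max(all_years))
  purrr::map_dfr(seq_along(drugs), function(i) {
    sub <- subs[[i]]
    n_ae <- as.integer(table(factor(sub$report_year, levels = years)))
    n_sae <- as.integer(table(factor(sub$report_year[sub$serious], levels = years)))
    tibble::tibble(
      drug = drugs[i], year = years, n_ae = n_ae, n_sae = n_sae,
      sae_ratio = ifelse(n_ae > 0, round_half_up(100 * n_sae / n_ae, 1), NA_real_)
    )
  })
}
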