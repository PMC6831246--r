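#' Explode filtered reports into drug-event pairs
#'
#' Each retained report contributes one pair per (qualifying drug, distinct
#' event) combination — the one-to-one drug/AE correspondence that defines the
#' unit of disproportionality analysis. Covariates (sex, age group, year,
#' seriousness) are copied from the parent report. Duplicate preferred terms
#' within a report are de-duplicated first, so a repeated PT never
#' double-counts a pair.
#'
#' @param reports Report-set tibble, already filtered.
#' @param suspected_only Use only suspected drug entries (default); otherwise
#'   all ATC-coded entries qualify.
#' @return A pair tibble with columns `report_id`, `atc_code`, `event_pt`,
#'   `sex`, `age_group`, `report_year`, `serious`, in deterministic order
#'   (report order, then drug order, then event order).
#' @export
#' @examples
#' kept <- apply_inclusion_filters(antivegf_fixture())$reports
#' pairs <- build_pairs(kept)
#' nrow(pairs)
build_pairs <- function(reports, suspected_only = TRUE) {
  reports <- validate_reports(reports)
  base <- tibble::tibble(
    report_id = reports$report_id,
    sex = reports$sex,
    age_group = cut_age(reports$age_years),
    report_year = reports$report_year,
    serious = reports$serious,
    drugs = reports$drugs,
    events = lapply(reports$events, function(e) unique(e[!is.na(e) & nzchar(e)]))
  )
  out <- tidyr::unnest(base, "drugs")
  if (nrow(out) > 0 && suspected_only) out <- out[out$suspected, , drop = FALSE]
  out <- out[!is.na(out$atc_code), , drop = FALSE]
  out <- tidyr::unnest(out, "events")
  out <- dplyr::rename(out, event_pt = "events")
  out <- dplyr::distinct(out, .data$report_id, .data$atc_code, .data$event_pt,
                         .keep_all = TRUE)
  out[, c("report_id", "atc_code", "event_pt", "sex", "age_group",
          "report_year", "serious")]
}

#' 2x2 contingency table for one drug-event combination
#'
#' Cell layout of the screening table: `a` = pairs with the target drug and
#' target event, `b` = target drug with all other events, `c` = all other
#' drugs with the target event, `d` = all other drugs with all other events.
#' The comparator is everything else in the supplied pair set; no external
#' background is consulted.
#'
#' @param pairs Pair tibble from [build_pairs()].
#' @param drug Target ATC code.
#' @param event Target event preferred term.
#' @return A `contingency_table` object.
#' @export
#' @examples
#' tab <- contingency_table(10, 90, 10, 890)
#' tab$n_total
build_contingency <- function(pairs, drug, event) {
  stopifnot(nrow(pairs) > 0)
  is_drug <- toupper(trimws(pairs$atc_code)) == toupper(trimws(drug))
  is_event <- canonical_term(pairs$event_pt) == canonical_term(event)
  contingency_table(
    a = sum(is_drug & is_event),
    b = sum(is_drug & !is_event),
    c = sum(!is_drug & is_event),
    d = sum(!is_drug & !is_event),
    drug = drug, event = event
  )
}

#' @rdname build_contingency
#' @param a,b,c,d Non-negative integer cell counts.
#' @export
contingency_table <- function(a, b, c, d, drug = NA_character_, event = NA_character_) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) stop("cells must be non-negative", call. = FALSE)
  structure(list(drug = drug, event = event,
                 a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d),
                 n_total = as.numeric(a + b + c + d)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 screening table%s\n",
              if (!is.na(x$drug)) sprintf(" [%s / %s]", x$drug, x$event) else ""))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2,
              dimnames = list(c("target drug", "other drugs"),
                              c("target event", "other events")))
  print(m)
  invisible(x)
}

#' All observed drug-event contingency tables
#'
#' Screening convenience: one table per observed (drug, event) combination
#' with at least `min_a` co-reported pairs.
#'
#' @param pairs Pair tibble from [build_pairs()].
#' @param min_a Minimum `a` cell to retain (default 0 keeps all observed
#'   combinations).
#' @return Tibble with columns `drug`, `event`, `a`, `b`, `c`, `d`.
#' @export
build_all_contingency <- function(pairs, min_a = 0) {
  stopifnot(min_a >= 0)
  n <- nrow(pairs)
  ab <- dplyr::count(pairs, .data$atc_code, name = "n_drug")
  ac <- dplyr::count(pairs, .data$event_pt, name = "n_event")
  out <- dplyr::count(pairs, .data$atc_code, .data$event_pt, name = "a")
  out <- dplyr::left_join(out, ab, by = "atc_code")
  out <- dplyr::left_join(out, ac, by = "event_pt")
  out <- dplyr::mutate(out,
                       b = .data$n_drug - .data$a,
                       c = .data$n_event - .data$a,
                       d = n - .data$n_drug - .data$n_event + .data$a)
  out <- dplyr::rename(out, drug = "atc_code", event = "event_pt")
  out <- out[out$a >= min_a, c("drug", "event", "a", "b", "c", "d")]
  tibble::as_tibble(out)
}
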