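#' Individual case safety report (ICSR) tables
#'
#' A report set is a tibble with one row per spontaneous report and the
#' following columns:
#'
#' * `report_id` — opaque string, unique within the set
#' * `is_initial` — logical; `FALSE` marks follow-up reports
#' * `report_year` — integer reporting year
#' * `report_type` — one of `spontaneous`, `post_marketing_surveillance`,
#'   `literature`, `other`
#' * `reporter` — one of `doctor`, `pharmacist`, `nurse`, `consumer`,
#'   `other`, `unknown`
#' * `sex` — `male`, `female`, or `missing`
#' * `age_years` — non-negative number, `NA` if missing
#' * `causality` — WHO-UMC category (`certain`, `probable`, `possible`,
#'   `unlikely`, `unassessable`, `unclassified`, `missing`)
#' * `serious` — logical seriousness flag
#' * `seriousness_type` — `hospitalization`, `other_including_death`, `none`
#' * `drugs` — list-column of tibbles with `atc_code` (string, `NA` if
#'   missing) and `suspected` (logical)
#' * `events` — list-column of character vectors of adverse-event preferred
#'   terms (WHO-ART PT style)
#' * `note` — optional free-text provenance tag
#'
#' In the flat CSV/TSV form the two list columns are packed into single cells:
#' each drug entry is `S:<atc>` (suspected) or `C:<atc>` (concomitant) and
#' entries/events are joined with `|`.
#'
#' @param report_id,is_initial,report_year,report_type,reporter,sex,age_years,causality,serious,seriousness_type,drugs,events,note
#'   Column vectors as described above; scalars are recycled.
#' @return A validated report-set tibble.
#' @export
icsr_set <- function(report_id, is_initial = TRUE, report_year = 2016L,
                     report_type = "spontaneous", reporter = "doctor",
                     sex = "male", age_years = 60, causality = "possible",
                     serious = FALSE, seriousness_type = "none",
                     drugs = list(), events = list(), note = NA_character_) {
  out <- tibble::tibble(
    report_id = as.character(report_id),
    is_initial = as.logical(is_initial),
    report_year = as.integer(report_year),
    report_type = as.character(report_type),
    reporter = as.character(reporter),
    sex = as.character(sex),
    age_years = as.numeric(age_years),
    causality = as.character(causality),
    serious = as.logical(serious),
    seriousness_type = as.character(seriousness_type),
    drugs = drugs,
    events = events,
    note = as.character(note)
  )
  validate_reports(out)
}

icsr_columns <- c("report_id", "is_initial", "report_year", "report_type",
                  "reporter", "sex", "age_years", "causality", "serious",
                  "seriousness_type", "drugs", "events", "note")

#' Validate a report-set tibble
#'
#' Checks the column schema, enum tokens, uniqueness of `report_id`, and the
#' seriousness consistency rule (`serious = FALSE` implies
#' `seriousness_type = "none"`).
#'
#' @param reports A report-set tibble (see [icsr_set()]).
#' @return The input, invisibly canonicalized (lower-case enum tokens).
#' @export
validate_reports <- function(reports) {
  missing_cols <- setdiff(setdiff(icsr_columns, "note"), names(reports))
  if (length(missing_cols) > 0) {
    stop("report set is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!("note" %in% names(reports))) reports$note <- NA_character_
  if (anyDuplicated(reports$report_id)) {
    stop("duplicate report_id: ",
         paste(unique(reports$report_id[duplicated(reports$report_id)]), collapse = ", "),
         call. = FALSE)
  }
  for (f in c("report_type", "reporter", "causality", "seriousness_type")) {
    reports[[f]] <- match_enum(reports[[f]], f,
                               missing_to = if (f == "causality") "missing" else NULL)
  }
  reports$sex <- match_enum(reports$sex, "sex", missing_to = "missing")
  if (any(!is.na(reports$age_years) & reports$age_years < 0)) {
    stop("negative age_years", call. = FALSE)
  }
  reports$drugs <- lapply(reports$drugs, function(d) {
    atc <- toupper(trimws(as.character(d$atc_code)))
    atc[!is.na(atc) & !nzchar(atc)] <- NA_character_
    d$atc_code <- atc
    d
  })
  reports$events <- lapply(reports$events, function(e) {
    e <- canonical_term(e)
    e[!is.na(e) & !nzchar(e)] <- NA_character_
    e
  })
  bad_serious <- !reports$serious & reports$seriousness_type != "none"
  if (any(bad_serious)) {
    stop("non-serious report(s) with a seriousness_type at row(s) ",
         paste(head(which(bad_serious), 5), collapse = ", "), call. = FALSE)
  }
  stopifnot(is.list(reports$drugs), is.list(reports$events))
  reports[icsr_columns]
}

pack_drugs <- function(drugs) {
  vapply(drugs, function(d) {
    if (is.null(d) || nrow(d) == 0) return("")
    atc <- ifelse(is.na(d$atc_code), "", d$atc_code)
    paste0(ifelse(d$suspected, "S:", "C:"), atc, collapse = "|")
  }, character(1))
}

unpack_drugs <- function(cells) {
  lapply(cells, function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) {
      return(tibble::tibble(atc_code = character(), suspected = logical()))
    }
    toks <- strsplit(cell, "|", fixed = TRUE)[[1]]
    role <- toupper(substr(trimws(toks), 1, 1))
    has_role <- role %in% c("S", "C") & substr(trimws(toks), 2, 2) == ":"
    if (!all(has_role)) {
      stop("malformed drug entry: ", paste(sQuote(toks[!has_role]), collapse = ", "),
           call. = FALSE)
    }
    atc <- toupper(trimws(sub("^[SCsc]:", "", trimws(toks))))
    tibble::tibble(atc_code = ifelse(nzchar(atc), atc, NA_character_),
                   suspected = role == "S")
  })
}

pack_events <- function(events) {
  vapply(events, function(e) paste(ifelse(is.na(e), "", e), collapse = "|"),
         character(1))
}

unpack_events <- function(cells) {
  lapply(cells, function(cell) {
    if (is.na(cell) || !nzchar(cell)) return(character())
    e <- trimws(strsplit(cell, "|", fixed = TRUE)[[1]])
    ifelse(nzchar(e), canonical_term(e), NA_character_)
  })
}

parse_flag <- function(x, column) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  bad <- is.na(out) & !is.na(x) & x != ""
  if (any(bad)) {
    stop(sprintf("invalid logical in column %s at row(s) %s", column,
                 paste(head(which(bad), 5), collapse = ", ")), call. = FALSE)
  }
  out
}

#' Read ICSR reports from a delimited file
#'
#' Parses the flat one-row-per-report schema documented in [icsr_set()].
#' Structurally malformed rows are not silently dropped: with
#' `strict = FALSE` they are collected in a rejects tibble attached as
#' `attr(result, "rejects")` (columns `row`, `report_id`, `reason`); with
#' `strict = TRUE` (default) the first problem raises a validation error
#' naming the row and column. Missing sex/age/ATC are *not* rejects — they
#' parse to `missing`/`NA` and are handled later by
#' [apply_inclusion_filters()].
#'
#' @param path Path to a CSV (or TSV) file.
#' @param delim Field delimiter, `","` by default.
#' @param strict Raise an error on the first malformed row instead of
#'   rejecting it.
#' @return A report-set tibble, with a `rejects` attribute.
#' @seealso [write_reports()], [apply_inclusion_filters()]
#' @export
read_reports <- function(path, delim = ",", strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                           na = character(), progress = FALSE)
  needed <- setdiff(setdiff(icsr_columns, "note"), names(raw))
  if (length(needed) > 0) {
    stop("header is missing column(s): ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (!("note" %in% names(raw))) raw$note <- NA_character_

  rejects <- tibble::tibble(row = integer(), report_id = character(), reason = character())
  parse_row <- function(i) {
    r <- raw[i, ]
    icsr_set(
      report_id = r$report_id,
      is_initial = parse_flag(r$is_initial, "is_initial"),
      report_year = as.integer(r$report_year),
      report_type = r$report_type,
      reporter = r$reporter,
      sex = r$sex,
      age_years = suppressWarnings(as.numeric(ifelse(r$age_years == "", NA, r$age_years))),
      causality = r$causality,
      serious = parse_flag(r$serious, "serious"),
      seriousness_type = r$seriousness_type,
      drugs = unpack_drugs(r$drugs),
      events = unpack_events(r$events),
      note = ifelse(r$note == "", NA_character_, r$note)
    )
  }
  rows <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    parsed <- tryCatch(parse_row(i), error = function(e) e)
    if (inherits(parsed, "error")) {
      if (strict) {
        stop(sprintf("row %d: %s", i, conditionMessage(parsed)), call. = FALSE)
      }
      rejects <- dplyr::bind_rows(rejects, tibble::tibble(
        row = i, report_id = as.character(raw$report_id[i]),
        reason = conditionMessage(parsed)))
    } else {
      rows[[i]] <- parsed
    }
  }
  out <- validate_reports(dplyr::bind_rows(rows))
  attr(out, "rejects") <- rejects
  out
}

#' Write ICSR reports to a delimited file
#'
#' Inverse of [read_reports()]: list columns are packed with the `|`
#' within-cell delimiter and enum tokens are written in canonical lower-case.
#'
#' @param reports Report-set tibble.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_reports <- function(reports, path, delim = ",") {
  reports <- validate_reports(reports)
  flat <- reports
  flat$drugs <- pack_drugs(reports$drugs)
  flat$events <- pack_events(reports$events)
  readr::write_delim(flat, path, delim = delim, na = "")
  invisible(path)
}

#' Inclusion criteria for spontaneous-report analyses
#'
#' The defaults encode the standard national-database inclusion rules: keep
#' only reports whose WHO-UMC causality is certain/probable/possible, only
#' initial reports, only complete records (non-missing sex, age, at least one
#' ATC-coded drug and one coded event), and only reports naming at least one
#' suspected drug.
#'
#' @param allowed_causality Character vector of admissible causality levels.
#' @param require_initial Drop follow-up reports.
#' @param require_complete Drop reports with missing sex/age and drug entries
#'   or events without codes.
#' @param suspected_only Require at least one suspected drug entry.
#' @return A `filter_criteria` list.
#' @export
filter_criteria <- function(allowed_causality = c("certain", "probable", "possible"),
                            require_initial = TRUE,
                            require_complete = TRUE,
                            suspected_only = TRUE) {
  allowed_causality <- match_enum(allowed_causality, "causality")
  if (length(allowed_causality) == 0) stop("allowed_causality must be non-empty", call. = FALSE)
  structure(list(allowed_causality = allowed_causality,
                 require_initial = isTRUE(require_initial),
                 require_complete = isTRUE(require_complete),
                 suspected_only = isTRUE(suspected_only)),
            class = "filter_criteria")
}

#' Apply inclusion filters with an auditable exclusion log
#'
#' Each excluded report is attributed to the *first* failing rule in the fixed
#' order `missing_field` -> `non_initial` -> `causality` ->
#' `no_suspected_drug`, so the log reconciles exactly:
#' `n_in - n_out = sum(counts_removed_by_reason)`.
#'
#' When `require_complete` is active, events with a missing/empty preferred
#' term and drug entries with a missing ATC code are first dropped from each
#' report; a report left with no event, no drug, missing sex, or missing age
#' is excluded under `missing_field`. Input order is preserved, and the
#' operation is idempotent.
#'
#' @param reports Report-set tibble.
#' @param criteria A [filter_criteria()] object.
#' @return A list with elements `reports` (the retained set) and `log` (a
#'   `filter_log` list: `n_in`, `n_out`, `counts_removed_by_reason`).
#' @export
#' @examples
#' raw <- antivegf_fixture()
#' kept <- apply_inclusion_filters(raw)
#' kept$log$counts_removed_by_reason
apply_inclusion_filters <- function(reports, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  reports <- validate_reports(reports)
  n_in <- nrow(reports)
  reasons <- c("missing_field", "non_initial", "causality", "no_suspected_drug")

  if (criteria$require_complete && n_in > 0) {
    reports$events <- lapply(reports$events, function(e) {
      unique(e[!is.na(e) & nzchar(e)])
    })
    reports$drugs <- lapply(reports$drugs, function(d) {
      d[!is.na(d$atc_code) & nzchar(d$atc_code), , drop = FALSE]
    })
  }

  n_events <- vapply(reports$events, length, integer(1))
  n_drugs <- vapply(reports$drugs, nrow, integer(1))
  has_suspected <- vapply(reports$drugs, function(d) any(d$suspected), logical(1))

  fail_missing <- criteria$require_complete &
    (reports$sex == "missing" | is.na(reports$age_years) | n_events == 0 | n_drugs == 0)
  fail_initial <- criteria$require_initial & !reports$is_initial
  fail_causality <- !(reports$causality %in% criteria$allowed_causality)
  fail_suspected <- criteria$suspected_only & !has_suspected

  reason <- rep(NA_character_, n_in)
  reason[fail_suspected] <- "no_suspected_drug"
  reason[fail_causality] <- "causality"
  reason[fail_initial] <- "non_initial"
  reason[fail_missing] <- "missing_field"

  kept <- reports[is.na(reason), , drop = FALSE]
  removed <- table(factor(reason[!is.na(reason)], levels = reasons))
  log <- structure(list(
    n_in = n_in,
    n_out = nrow(kept),
    counts_removed_by_reason = setNames(as.integer(removed), reasons)
  ), class = "filter_log")
  stopifnot(log$n_in - log$n_out == sum(log$counts_removed_by_reason))
  list(reports = kept, log = log)
}

#' Write a filter log as JSON
#'
#' @param log A `filter_log` from [apply_inclusion_filters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_log <- function(log, path) {
  jsonlite::write_json(unclass(log), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.filter_log <- function(x, ...) {
  cat(sprintf("ICSR inclusion filter: %d in, %d kept, %d removed\n",
              x$n_in, x$n_out, x$n_in - x$n_out))
  for (r in names(x$counts_removed_by_reason)) {
    cat(sprintf("  %-18s %d\n", r, x$counts_removed_by_reason[[r]]))
  }
  invisible(x)
}
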