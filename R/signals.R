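#' Signal thresholds for the triple criterion
#'
#' Defaults are the classical spontaneous-report criteria: PRR >= 2 with
#' chi-square >= 4 and at least 3 co-reported cases; ROR >= 2 with the same
#' companions; and an IC 95% interval whose lower bound is strictly above 0.
#'
#' @param prr_min,ror_min Minimum PRR / ROR (inclusive).
#' @param chi2_min Minimum chi-square (inclusive), applied to both the PRR
#'   and ROR component criteria.
#' @param n_min Minimum number of co-reported cases, the `a` cell (inclusive).
#' @param ic_lower_min The IC interval's lower bound must *exceed* this value
#'   (strict inequality).
#' @return A `signal_criteria` list.
#' @export
signal_criteria <- function(prr_min = 2, ror_min = 2, chi2_min = 4,
                            n_min = 3, ic_lower_min = 0) {
  vals <- c(prr_min, ror_min, chi2_min, n_min, ic_lower_min)
  if (any(!is.finite(vals)) || n_min < 0) stop("thresholds must be finite, n_min >= 0", call. = FALSE)
  structure(list(prr_min = prr_min, ror_min = ror_min, chi2_min = chi2_min,
                 n_min = n_min, ic_lower_min = ic_lower_min),
            class = "signal_criteria")
}

#' Apply the triple signal criterion to screening results
#'
#' A (drug, event) combination is a signal when all three component criteria
#' hold: the PRR criterion (PRR, chi-square, and case count over their
#' thresholds), the analogous ROR criterion, and the IC criterion (interval
#' lower bound above `ic_lower_min`).
#'
#' @param results Screening tibble from [screen()] (vectorized; a single-row
#'   tibble works for one result).
#' @param criteria A [signal_criteria()].
#' @return `results` with logical columns `prr_criterion`, `ror_criterion`,
#'   `ic_criterion`, and `is_signal` appended.
#' @export
#' @examples
#' res <- screen(tibble::tibble(drug = "X", event = "y",
#'                              a = 10, b = 90, c = 10, d = 890),
#'               prior = ic_prior(n_mc = 5000), seed = 1)
#' evaluate_criteria(res)$is_signal
evaluate_criteria <- function(results, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"),
            all(c("n", "prr", "ror", "chi2", "ic_l") %in% names(results)))
  results$prr_criterion <- results$prr >= criteria$prr_min &
    results$chi2 >= criteria$chi2_min & results$n >= criteria$n_min
  results$ror_criterion <- results$ror >= criteria$ror_min &
    results$chi2 >= criteria$chi2_min & results$n >= criteria$n_min
  results$ic_criterion <- results$ic_l > criteria$ic_lower_min
  results$is_signal <- results$prr_criterion & results$ror_criterion &
    results$ic_criterion
  results
}

#' Drug-label reference for expectedness classification
#'
#' @param jurisdiction Label jurisdiction code, e.g. `"KR"` or `"US"`.
#' @param entries Named list mapping a drug identifier (ATC code) to a
#'   character vector of labeled event preferred terms.
#' @return A `label_reference` object. Term and drug comparison is
#'   case- and whitespace-insensitive.
#' @export
label_reference <- function(jurisdiction, entries) {
  stopifnot(is.character(jurisdiction), length(jurisdiction) == 1,
            is.list(entries), !is.null(names(entries)))
  entries <- lapply(entries, function(terms) unique(canonical_term(unlist(terms))))
  names(entries) <- toupper(trimws(names(entries)))
  structure(list(jurisdiction = toupper(jurisdiction), entries = entries),
            class = "label_reference")
}

#' Read a label reference from JSON
#'
#' Expected shape: `{"jurisdiction": "KR", "entries": {"<drug>": ["term", ...]}}`.
#'
#' @param path Path to a JSON file.
#' @return A [label_reference()] object.
#' @export
#' @examples
#' path <- system.file("extdata", "labels_kr_synthetic.json", package = "pvsignal")
#' read_label_reference(path)$jurisdiction
read_label_reference <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$jurisdiction) || is.null(x$entries)) {
    stop("label JSON must contain 'jurisdiction' and 'entries'", call. = FALSE)
  }
  label_reference(x$jurisdiction, as.list(x$entries))
}

#' Classify detected signals as expected or unexpected against a label
#'
#' A signal whose event term appears among the drug's labeled terms is
#' `expected`; a signal absent from the label is `unexpected` (the new-AE
#' candidates); a signal for a drug that has no entry in the reference is
#' `unknown_drug`. Non-signal rows pass through with `NA` expectedness.
#'
#' @param decisions Tibble from [evaluate_criteria()].
#' @param labels A [label_reference()].
#' @return `decisions` with an `expectedness` column appended.
#' @export
classify_expectedness <- function(decisions, labels) {
  stopifnot(inherits(labels, "label_reference"),
            all(c("drug", "event", "is_signal") %in% names(decisions)))
  drug_key <- toupper(trimws(decisions$drug))
  known <- drug_key %in% names(labels$entries)
  on_label <- mapply(function(d, e, k) {
    k && canonical_term(e) %in% labels$entries[[d]]
  }, drug_key, decisions$event, known, USE.NAMES = FALSE)
  decisions$expectedness <- dplyr::case_when(
    !decisions$is_signal ~ NA_character_,
    !known ~ "unknown_drug",
    on_label ~ "expected",
    .default = "unexpected"
  )
  decisions
}
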