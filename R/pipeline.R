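#' Run the full signal-detection pipeline
#'
#' Chains the stages filter -> pairs -> tables -> screen -> signals ->
#' adjusted RORs -> descriptives on one input, writing every intermediate
#' artifact plus a reproducibility manifest (parameters, seed, input/output
#' md5 digests) to `out_dir`. Identical inputs, parameters, and seed
#' reproduce every artifact byte-identically.
#'
#' @param config Either a path to a YAML/JSON file or a list, with elements:
#'   * `input`: path to a raw report CSV, or the string `"fixture"` for
#'     [antivegf_fixture()]
#'   * `drugs`: optional character vector of study drugs (default: drugs with
#'     the most pairs, up to 2) used for descriptives
#'   * `labels`: optional path to a label-reference JSON
#'   * `criteria`: optional list of [signal_criteria()] overrides
#'   * `filter`: optional list of [filter_criteria()] overrides
#'   * `min_a`: minimum co-report count for screening tables (default 1)
#'   * `yates`: use the Yates-corrected chi-square (default `TRUE`)
#'   * `ic`: optional list of [ic_prior()] overrides
#'   * `seed`: integer seed for the IC Monte-Carlo draws (default 20160701)
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config), !is.null(config$input))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 20160701L)
  criteria <- do.call(signal_criteria, as.list(config$criteria %||% list()))
  fcrit <- do.call(filter_criteria, as.list(config$filter %||% list()))
  prior <- do.call(ic_prior, as.list(config$ic %||% list()))
  min_a <- config$min_a %||% 1
  yates <- config$yates %||% TRUE

  raw <- if (identical(config$input, "fixture")) antivegf_fixture()
         else read_reports(config$input)
  filtered <- apply_inclusion_filters(raw, fcrit)
  kept <- filtered$reports

  paths <- list(
    kept = file.path(out_dir, "kept.csv"),
    filter_log = file.path(out_dir, "filterlog.json"),
    pairs = file.path(out_dir, "pairs.csv"),
    tables = file.path(out_dir, "tables.csv"),
    dispro = file.path(out_dir, "dispro.csv"),
    signals = file.path(out_dir, "signals.csv"),
    adjusted = file.path(out_dir, "adjusted.csv"),
    characteristics = file.path(out_dir, "table1.csv"),
    trends = file.path(out_dir, "trends.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )

  write_reports(kept, paths$kept)
  write_filter_log(filtered$log, paths$filter_log)

  pairs <- build_pairs(kept, suspected_only = fcrit$suspected_only)
  readr::write_csv(pairs, paths$pairs)
  tables <- build_all_contingency(pairs, min_a = min_a)
  readr::write_csv(tables, paths$tables)

  results <- screen(tables, prior = prior, yates = yates, seed = seed)
  readr::write_csv(results, paths$dispro)

  decisions <- evaluate_criteria(results, criteria)
  if (!is.null(config$labels)) {
    decisions <- classify_expectedness(decisions, read_label_reference(config$labels))
  }
  readr::write_csv(decisions, paths$signals)

  drugs <- config$drugs %||% {
    counts <- sort(table(pairs$atc_code), decreasing = TRUE)
    names(counts)[seq_len(min(2, length(counts)))]
  }
  sig_pairs <- decisions[decisions$is_signal & decisions$drug %in% drugs,
                         c("drug", "event")]
  adjusted <- adjusted_screen(kept, sig_pairs)
  readr::write_csv(adjusted, paths$adjusted)

  readr::write_csv(summarize_characteristics(kept, drugs), paths$characteristics)
  readr::write_csv(annual_trends(kept, drugs), paths$trends)

  manifest <- list(
    tool = paste0("pvsignal ", as.character(utils::packageVersion("pvsignal"))),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    input = if (identical(config$input, "fixture")) "fixture" else
      list(path = config$input,
           md5 = unname(tools::md5sum(config$input))),
    parameters = list(
      filter = unclass(fcrit), criteria = unclass(criteria),
      ic_prior = unclass(prior), min_a = min_a, yates = yates, seed = seed
    ),
    outputs = lapply(paths[names(paths) != "manifest"], function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
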