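test_that("packaged example file parses with the documented row count", {
  path <- system.file("extdata", "example_reports.csv", package = "pvsignal")
  reports <- read_reports(path)
  expect_equal(nrow(reports), 17)
  expect_equal(nrow(attr(reports, "rejects")), 0)
})

test_that("write then read is the identity on a report set", {
  reports <- tiny_reports()
  path <- withr::local_tempfile(fileext = ".csv")
  write_reports(reports, path)
  back <- read_reports(path)
  attr(back, "rejects") <- NULL
  expect_equal(back, reports)
})

test_that("missing sex parses to the missing level; filtering is separate", {
  path <- withr::local_tempfile(fileext = ".csv")
  reports <- tiny_reports()
  reports$sex[2] <- "missing"
  write_reports(reports, path)
  back <- read_reports(path)
  expect_equal(nrow(back), 4)
  expect_equal(back$sex[2], "missing")
})

test_that("unknown enum tokens are a validation error naming row and column", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_reports(tiny_reports(), path)
  lines <- readLines(path)
  lines[4] <- sub("possible", "implausible", lines[4])
  writeLines(lines, path)
  expect_error(read_reports(path), "row 3.*causality.*implausible")
  rejected <- read_reports(path, strict = FALSE)
  expect_equal(nrow(rejected), 3)
  rej <- attr(rejected, "rejects")
  expect_equal(rej$row, 3L)
  expect_match(rej$reason, "causality")
})

test_that("fixture contaminants are each removed under their planted rule", {
  raw <- antivegf_fixture()
  res <- apply_inclusion_filters(raw)
  expect_equal(res$log$n_in, 502)
  expect_equal(res$log$n_out, 495)
  expect_equal(res$log$counts_removed_by_reason,
               c(missing_field = 4L, non_initial = 1L, causality = 1L,
                 no_suspected_drug = 1L))
  removed <- setdiff(raw$report_id, res$reports$report_id)
  expect_setequal(removed, sprintf("CT%04d", 1:7))
  expect_true(all(grepl("^contaminant:", raw$note[raw$report_id %in% removed])))
})

test_that("a causality outside the whitelist is excluded under the causality rule", {
  reports <- tiny_reports()
  reports$causality[3] <- "unlikely"
  res <- apply_inclusion_filters(reports)
  expect_false("T3" %in% res$reports$report_id)
  expect_equal(res$log$counts_removed_by_reason[["causality"]], 1L)
})

test_that("empty input filters to an empty output with a zero log", {
  empty <- tiny_reports()[0, ]
  res <- apply_inclusion_filters(empty)
  expect_equal(nrow(res$reports), 0)
  expect_equal(res$log$n_in, 0)
  expect_equal(res$log$n_out, 0)
})

test_that("filtering is idempotent and permissive criteria are the identity", {
  raw <- antivegf_fixture()
  once <- apply_inclusion_filters(raw)
  twice <- apply_inclusion_filters(once$reports)
  expect_equal(twice$reports, once$reports)
  expect_equal(sum(twice$log$counts_removed_by_reason), 0)

  permissive <- filter_criteria(allowed_causality = c("certain", "probable",
                                                      "possible", "unlikely",
                                                      "unassessable", "unclassified",
                                                      "missing"),
                                require_initial = FALSE,
                                require_complete = FALSE,
                                suspected_only = FALSE)
  res <- apply_inclusion_filters(raw, permissive)
  expect_equal(nrow(res$reports), nrow(raw))
  expect_equal(res$reports$report_id, raw$report_id)
})

test_that("filter log arithmetic reconciles on random contaminated inputs", {
  for (seed in 1:5) {
    cfg <- prop_config(seed, n = 300,
                       contamination = list(missing_sex = 0.05, missing_age = 0.05,
                                            missing_atc = 0.04, followup = 0.06,
                                            bad_causality = 0.08))
    res <- apply_inclusion_filters(generate_reports(cfg))
    expect_equal(res$log$n_in - res$log$n_out,
                 sum(res$log$counts_removed_by_reason))
    expect_equal(res$log$n_in, 300)
    # retained reports satisfy every active criterion
    kept <- res$reports
    expect_true(all(kept$is_initial))
    expect_true(all(kept$causality %in% c("certain", "probable", "possible")))
    expect_true(all(kept$sex != "missing"), info = seed)
    expect_false(any(is.na(kept$age_years)))
    expect_true(all(vapply(kept$drugs, function(d) any(d$suspected), logical(1))))
  }
})
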