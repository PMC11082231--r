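test_that("parser reads the long dialect: one trace per (segment, measure)", {
  rows <- c(
    vapply(1:5, function(i) tsv_row("p1", "A4C", 1, "LS", (i - 1) / 4, -i), ""),
    vapply(1:5, function(i) tsv_row("p1", "A4C", 2, "LS", (i - 1) / 4, -2 * i), ""))
  traces <- parse_strain_table(table_text(rows))
  expect_length(traces, 2L)
  expect_true(all(vapply(traces, function(tr) length(tr$times), 1L) == 5L))
  expect_equal(traces[[1]]$segment, 1L)
  expect_equal(traces[[2]]$values, -2 * (1:5))
})

test_that("parser auto-detects CSV vs TSV and ms vs cycle-fraction times", {
  rows_csv <- vapply(1:5, function(i)
    paste("p1", "SAX_MID", 3, "CS", 200 * (i - 1), -i, sep = ","), "")
  traces <- parse_strain_table(
    paste(c("patient_id,view,segment,measure,time,value", rows_csv), collapse = "\n"))
  expect_length(traces, 1L)
  # 0..800 ms rescaled so the last sample is cycle fraction 1
  expect_equal(traces[[1]]$times, (0:4) / 4)
})

test_that("parser errors name the offending row", {
  good <- vapply(1:4, function(i) tsv_row("p1", "A4C", 1, "LS", (i - 1) / 3, -i), "")
  expect_error(parse_strain_table(table_text(c(good, "p1\tA4C\t1\tLS\t0.9"))),
               "row 6")
  expect_error(parse_strain_table(
    table_text(c(good, tsv_row("p1", "A4C", 1, "LS", "oops", -1)))),
    "non-numeric")
  expect_error(parse_strain_table(
    table_text(c(good, tsv_row("p1", "A4C", 50, "LS", 0.9, -1)))),
    "segment out of range")
  expect_error(parse_strain_table(
    table_text(c(good, tsv_row("p1", "A4C", 1, "LS", 0, -9)))),
    "duplicate")
  expect_error(parse_strain_table(
    table_text(tsv_row("p1", "A4C", 1, "CS", 0, -9))),
    "does not belong")
})

test_that("empty table body yields no traces with a warning", {
  expect_warning(traces <- parse_strain_table(table_text(character(0))), "empty")
  expect_length(traces, 0L)
})

test_that("write/parse round-trips traces bit-exactly", {
  traces <- simulate_patient("p1", small_preset("NL"), seed = 11)[1:20]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_strain_table(traces, f)
  back <- parse_strain_table(f)
  expect_length(back, length(traces))
  for (i in seq_along(traces)) {
    expect_identical(back[[i]]$values, traces[[i]]$values)
    expect_identical(back[[i]]$times, traces[[i]]$times)
  }
})

test_that("completeness rule retains 51 of 54 CP patients in the enrollment fixture", {
  # 54 enrolled CP patients; 3 have an unusable series (all-NaN values)
  cohort <- simulate_cohort(small_spec(c(CP = 54L), seed = 21))
  dat <- cohort$data
  bad <- sprintf("CP%03d", c(7L, 21L, 40L))
  dat[dat$patient_id %in% bad & dat$measure == "RS" & dat$segment == 40L,
      "value"] <- NaN
  flt <- filter_complete(strain_cohort(dat, cohort$labels))
  expect_equal(sum(flt$kept$labels == "CP"), 51L)
  expect_setequal(flt$dropped$patient_id, bad)
  expect_match(flt$dropped$reason[1], "RS")
})

test_that("filtering is idempotent and reasons name the failing pair", {
  cohort <- simulate_cohort(small_spec(c(NL = 3L), seed = 5))
  dat <- cohort$data
  dat[dat$patient_id == "NL002" & dat$measure == "CS" & dat$segment == 33L,
      "value"] <- NaN   # segment 33 is in the lateral SAX region
  flt <- filter_complete(strain_cohort(dat, cohort$labels))
  expect_equal(flt$dropped$patient_id, "NL002")
  expect_match(flt$dropped$reason, "CS, lat", fixed = TRUE)
  again <- filter_complete(flt$kept)
  expect_equal(nrow(again$dropped), 0L)
  expect_identical(names(again$kept$labels), names(flt$kept$labels))
})

test_that("a series with internal NaN but >= 4 finite samples is repairable, not missing", {
  cohort <- simulate_cohort(small_spec(c(NL = 1L), seed = 6))
  dat <- cohort$data
  ix <- which(dat$patient_id == "NL001" & dat$measure == "LS" & dat$segment == 1L)
  dat[ix[3], "value"] <- NaN  # 11 finite samples remain
  flt <- filter_complete(strain_cohort(dat, cohort$labels))
  expect_equal(nrow(flt$dropped), 0L)
})

test_that("fully complete cohort is kept unchanged and summarised", {
  cohort <- simulate_cohort(small_spec(c(CP = 2L, NL = 2L), seed = 7))
  flt <- filter_complete(cohort)
  expect_equal(nrow(flt$dropped), 0L)
  expect_identical(flt$kept$labels, cohort$labels)
  sm <- cohort_summary(flt$kept, flt$dropped)
  expect_equal(sm$n_patients, 4L)
  expect_equal(sm$n_per_class$CP, 2L)
  expect_length(sm$dropped, 0L)
})
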