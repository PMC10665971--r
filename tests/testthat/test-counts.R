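test_that("bundled fixture loads with the expected shape", {
  counts <- rule48_counts()
  cohorts <- rule48_cohorts()
  expect_equal(nrow(counts), 32)
  expect_equal(length(unique(counts$variable)), 16)
  expect_equal(nrow(cohorts), 2)
  expect_setequal(counts$variable, rule48_taxonomy()$variable)
  # one record per (cohort, variable)
  expect_equal(nrow(dplyr::distinct(counts, cohort, variable)), 32)
})

test_that("raw display arithmetic reproduces every published raw cell", {
  counts <- add_raw_columns(rule48_counts())
  ref <- reference_proportions()
  for (i in seq_len(nrow(ref))) {
    pre <- counts[counts$cohort == "2006-2010" & counts$variable == ref$variable[i], ]
    post <- counts[counts$cohort == "2014-2019" & counts$variable == ref$variable[i], ]
    expect_equal(pre$raw_display, ref$pct_pre[i], info = ref$variable[i])
    expect_equal(post$raw_display, ref$pct_post[i], info = ref$variable[i])
  }
  inc <- add_raw_columns(incidence_counts(rule48_counts(), rule48_cohorts()))
  refi <- reference_incidence()
  for (i in seq_len(nrow(refi))) {
    pre <- inc[inc$cohort == "2006-2010" & inc$variable == refi$variable[i], ]
    post <- inc[inc$cohort == "2014-2019" & inc$variable == refi$variable[i], ]
    expect_equal(pre$raw_display, refi$rate_pre[i], info = refi$variable[i])
    expect_equal(post$raw_display, refi$rate_post[i], info = refi$variable[i])
  }
})

test_that("video coverage matches the published percentages", {
  vc <- video_coverage(rule48_cohorts())
  pooled <- vc[vc$label == "pooled", ]
  expect_equal(pooled$n_video, 688)
  expect_equal(pooled$n_total, 817)
  expect_equal(round_half_up(pooled$coverage_pct, 1), 84.2)
  # non-coded share of the pre cohort: 70 of 301
  expect_equal(round_half_up(video_coverage(70, 301), 1), 23.3)
  expect_equal(video_coverage(0, 10), 0)
  expect_error(video_coverage(5, 0), "positive")
})

test_that("raw helpers validate and round half-up", {
  expect_equal(round_half_up(c(6.15, 2.25, -2.25, 50.649), 1),
               c(6.2, 2.3, -2.3, 50.6))
  expect_equal(raw_incidence_per_100(0, 4920), 0)
  expect_error(raw_incidence_per_100(10, 0), "positive")
  expect_error(raw_proportion(5, 0), "positive")
  expect_error(raw_proportion(11, 10), "numerator")
  expect_equal(raw_proportion(231, 231), 100)
})

test_that("read_counts validates rows and rejects malformed input", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "cohort,variable,numerator,denominator,denominator_kind",
    "2006-2010,open ice,108,231,events_with_video"
  ), tmp)
  got <- read_counts(tmp)
  expect_equal(got$numerator, 108)
  expect_equal(got$denominator, 231)

  # header-only file: empty, no error
  writeLines("cohort,variable,numerator,denominator,denominator_kind", tmp)
  expect_equal(nrow(read_counts(tmp)), 0)

  # numerator exceeding denominator names the offending row
  writeLines(c(
    "cohort,variable,numerator,denominator,denominator_kind",
    "2006-2010,open ice,108,231,events_with_video",
    "2006-2010,glove,300,231,events_with_video"
  ), tmp)
  expect_error(read_counts(tmp), "Row 2.*exceeds denominator")

  # unknown variable rejected
  writeLines(c(
    "cohort,variable,numerator,denominator,denominator_kind",
    "2006-2010,zamboni,1,231,events_with_video"
  ), tmp)
  expect_error(read_counts(tmp), "Unknown characteristic")

  # event denominators cross-checked against the cohort video total
  writeLines(c(
    "cohort,variable,numerator,denominator,denominator_kind",
    "2006-2010,open ice,240,260,events_with_video"
  ), tmp)
  expect_error(read_counts(tmp, cohorts = rule48_cohorts()),
               "video-documented total")
})

test_that("write_counts and read_counts round-trip validated tables", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  counts <- rule48_counts()
  write_counts(counts, tmp)
  expect_equal(read_counts(tmp), counts)
})

test_that("unicode minus in labels is normalized on ingest", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "cohort,variable,numerator,denominator,denominator_kind",
    "2006−2010,open ice,108,231,events_with_video"
  ), tmp)
  expect_equal(read_counts(tmp)$cohort, "2006-2010")
})

test_that("incidence_counts re-denominates over games and adds the overall row", {
  inc <- incidence_counts(rule48_counts(), rule48_cohorts())
  expect_equal(nrow(inc), 34)
  expect_true(all(inc$denominator_kind == "games"))
  lat <- inc[inc$variable == "lateral hit to head" & inc$cohort == "2006-2010", ]
  expect_equal(lat$numerator, 80)
  expect_equal(lat$denominator, 4920)
  ov <- inc[inc$variable == "all concussions", ]
  expect_equal(ov$numerator, c(301, 516))
})
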