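small_config <- function(seed = 1L, incidence = 0.08, n_games = 800,
                         video_rate = 0.85) {
  season_config("test", n_games = n_games, incidence_per_game = incidence,
                video_rate = video_rate, seed = seed)
}

test_that("season_config validates its mixtures", {
  expect_error(
    season_config("x", 10, 0.05, 0.8,
                  mixtures = utils::modifyList(default_mixtures(),
                                               list(zone = c(0.5, 0.4)))),
    "sum to 1"
  )
  expect_error(
    season_config("x", 10, 0.05, 0.8, mixtures = list(location = c(1))),
    "missing"
  )
})

test_that("zero incidence yields zero events", {
  s <- simulate_season(small_config(incidence = 0))
  expect_equal(sum(s$event), 0)
  expect_equal(nrow(s), 800)
  expect_true(all(is.na(s$location)))
})

test_that("identical seeds give bit-identical event tables", {
  expect_identical(simulate_season(small_config(seed = 99)),
                   simulate_season(small_config(seed = 99)))
  expect_false(identical(simulate_season(small_config(seed = 99)),
                         simulate_season(small_config(seed = 100))))
})

test_that("event and video counts follow binomial moments", {
  # 200 replicate seasons at the pre-cohort scale
  n_games <- 4920; p <- 301 / 4920
  cfg <- small_config(n_games = n_games, incidence = p, video_rate = 0.842)
  tot <- vid <- numeric(200)
  for (r in 1:200) {
    cfg$seed <- r
    s <- simulate_season(cfg)
    tot[r] <- sum(s$event)
    vid[r] <- sum(s$video, na.rm = TRUE)
  }
  expect_lt(abs(mean(tot) - 301), 3 * sqrt(n_games * p * (1 - p) / 200))
  frac <- sum(vid) / sum(tot)
  expect_lt(abs(frac - 0.842), 3 * sqrt(0.842 * 0.158 / sum(tot)))
})

test_that("aggregation mirrors the video-coding rules", {
  s <- simulate_season(small_config(seed = 17))
  agg <- aggregate_events(s)
  n_vid <- sum(s$video, na.rm = TRUE)
  expect_true(all(agg$counts$denominator == n_vid))
  expect_equal(agg$cohorts$n_concussions_total, sum(s$event))
  expect_equal(agg$cohorts$n_concussions_video, n_vid)
  expect_equal(agg$cohorts$n_games, 800)
  # hand-check one numerator against the raw table
  vid_rows <- s[s$event & s$video, ]
  expect_equal(agg$counts$numerator[agg$counts$variable == "open ice"],
               sum(vid_rows$location == "open ice"))
  # nesting: head-hit subtypes sum to the head-hit count
  cnt <- function(v) agg$counts$numerator[agg$counts$variable == v]
  expect_equal(cnt("shoulder") + cnt("glove") + cnt("arm"),
               cnt("body checks to head"))
  expect_lte(cnt("body checks to head"), cnt("all body checks"))
  # unknown labels are rejected
  s2 <- s
  s2$zone[which(s2$event)[1]] <- "parking lot"
  expect_error(aggregate_events(s2), "Unknown zone")
})

test_that("all-missing video drops proportion records with a warning", {
  s <- simulate_season(small_config(video_rate = 0, seed = 3))
  expect_warning(agg <- aggregate_events(s), "No video")
  expect_equal(nrow(agg$counts), 0)
  expect_gt(agg$cohorts$n_concussions_total, 0)
})

test_that("aggregated proportions converge to the mixtures at large n", {
  cfg <- season_config("big", n_games = 50000, incidence_per_game = 0.1,
                       video_rate = 1, seed = 23)
  agg <- aggregate_events(simulate_season(cfg))
  prop <- function(v) {
    r <- agg$counts[agg$counts$variable == v, ]
    r$numerator / r$denominator
  }
  mx <- cfg$mixtures
  expect_lt(abs(prop("open ice") - mx$location[["open ice"]]), 0.01)
  expect_lt(abs(prop("first period") - mx$period[["first"]]), 0.01)
  expect_lt(abs(prop("forward") - mx$position[["forward"]]), 0.015)
  p_head <- sum(mx$mechanism[c("shoulder_to_head", "glove_to_head",
                               "arm_to_head")])
  expect_lt(abs(prop("body checks to head") - p_head), 0.01)
  expect_lt(abs(prop("lateral hit to head") - p_head * mx$lateral_given_head),
            0.01)
})

test_that("calibrated configs reproduce the fixture's marginal structure", {
  cfgs <- calibrated_season_configs()
  expect_equal(cfgs$pre$n_games, 4920)
  expect_equal(cfgs$post$n_games, 6232)
  expect_equal(cfgs$pre$incidence_per_game, 301 / 4920)
  expect_equal(cfgs$post$video_rate, 457 / 516)
  expect_equal(cfgs$pre$mixtures$location[["open ice"]], 108 / 231)
  expect_equal(cfgs$post$mixtures$period[["first"]], 158 / 440)
  # the pipeline runs end to end on simulated data without schema errors
  agg <- aggregate_events(simulate_season(cfgs$pre))
  fit <- fit_contrasts(
    dplyr::bind_rows(
      agg$counts,
      dplyr::mutate(aggregate_events(simulate_season(cfgs$post))$counts)
    ),
    scale = "pp", engine = "quadrature",
    pre = "2006-2010", post = "2014-2019", seed = 5
  )
  expect_equal(nrow(fit$results), 16)
})

test_that("pipeline recovers configured shifts at survey scale", {
  cfgs <- calibrated_season_configs(seed_pre = 301L, seed_post = 302L)
  # true open-ice shift implied by the calibrated mixtures
  true_shift <- 100 * (cfgs$post$mixtures$location[["open ice"]] -
                         cfgs$pre$mixtures$location[["open ice"]])
  counts <- dplyr::bind_rows(
    aggregate_events(simulate_season(cfgs$pre))$counts,
    aggregate_events(simulate_season(cfgs$post))$counts
  )
  fit <- fit_contrasts(counts, scale = "pp", engine = "quadrature", seed = 6)
  got <- fit$results$mean_diff[fit$results$variable == "open ice"]
  expect_equal(got, true_shift, tolerance = 3)
})

test_that("single-replicate calibration study returns a coverage record", {
  cfgs <- calibrated_season_configs()
  suppressMessages(
    cal <- calibration_study(cfgs$pre, cfgs$pre, true_diff = 0, n_reps = 1,
                             seed = 77)
  )
  expect_equal(nrow(cal$replicates), 1)
  expect_true(cal$coverage %in% c(0, 1))
  expect_true(is.finite(cal$mean_bias))
})

test_that("poisson variant allows multiple events per game", {
  cfg <- small_config(incidence = 0.9, n_games = 300, seed = 8)
  s <- simulate_season(cfg, events_per_game = "poisson")
  expect_gt(nrow(s), 300) # some games carry 2+ events
  expect_gt(max(table(s$game[s$event])), 1)
})
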