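#' Configure a synthetic season of games
#'
#' Describes the data-generating process the binomial-logit model assumes:
#' each game independently produces at most one concussion event (Bernoulli
#' at `incidence_per_game`); each event draws its characteristics
#' independently from per-group categorical mixtures; and each event carries
#' a video-availability flag (events without video are never characteristic-
#' coded, mirroring real surveillance). A Poisson-per-game variant is
#' available in [simulate_season()] for model-misspecification stress tests.
#'
#' @param label Cohort label.
#' @param n_games Number of games.
#' @param incidence_per_game Per-game event probability.
#' @param video_rate Probability an event has usable video.
#' @param seed RNG seed; identical configs give bit-identical tables.
#' @param mixtures Named list of categorical mixtures and Bernoulli rates:
#'   `location` (open ice / perimeter), `zone` (offensive / neutral /
#'   defensive), `period` (first / later), `mechanism` (shoulder to head /
#'   glove to head / arm to head / other body check / other),
#'   `lateral_given_head` (probability a head hit is lateral), `position`
#'   (forward / defense / goalie), `puck_possession`, `penalty`. Each
#'   categorical mixture must sum to 1 (tolerance 1e-9).
#' @return A `season_config` list.
#' @export
season_config <- function(label, n_games, incidence_per_game, video_rate,
                          seed = 1L, mixtures = default_mixtures()) {
  stopifnot(n_games >= 0, incidence_per_game >= 0, incidence_per_game <= 1,
            video_rate >= 0, video_rate <= 1)
  req <- c("location", "zone", "period", "mechanism", "lateral_given_head",
           "position", "puck_possession", "penalty")
  miss <- setdiff(req, names(mixtures))
  if (length(miss) > 0) {
    abort(paste0("`mixtures` is missing: ", paste(miss, collapse = ", ")))
  }
  for (nm in c("location", "zone", "period", "mechanism", "position")) {
    if (abs(sum(mixtures[[nm]]) - 1) > 1e-9) {
      abort(paste0("Mixture ", shQuote(nm), " must sum to 1."))
    }
  }
  structure(
    list(label = label, n_games = as.integer(n_games),
         incidence_per_game = incidence_per_game, video_rate = video_rate,
         seed = as.integer(seed), mixtures = mixtures),
    class = "season_config"
  )
}

#' Default characteristic mixtures
#'
#' A neutral, roughly uniform mixture set for quick simulations; see
#' [calibrated_season_configs()] for cohort-calibrated mixtures.
#'
#' @return A named list suitable for [season_config()].
#' @export
default_mixtures <- function() {
  list(
    location = c("open ice" = 0.45, "perimeter" = 0.55),
    zone = c(offensive = 0.34, neutral = 0.20, defensive = 0.46),
    period = c(first = 0.45, later = 0.55),
    mechanism = c(shoulder_to_head = 0.30, glove_to_head = 0.05,
                  arm_to_head = 0.10, other_body_check = 0.30, other = 0.25),
    lateral_given_head = 0.6,
    position = c(forward = 0.65, defense = 0.30, goalie = 0.05),
    puck_possession = 0.20,
    penalty = 0.25
  )
}

#' Cohort-calibrated synthetic season configurations
#'
#' A pair of [season_config()]s whose marginal structure matches the bundled
#' NHL two-cohort fixture: game counts, per-game incidence, video rates, and
#' characteristic mixtures derived from the observed counts. The pre-period
#' config can be reused for both cohorts (with fresh seeds) to simulate a
#' true null shift.
#'
#' @param seed_pre,seed_post Seeds for the two configs.
#' @return Named list with elements `pre` and `post`.
#' @export
calibrated_season_configs <- function(seed_pre = 101L, seed_post = 202L) {
  counts <- rule48_counts()
  cohorts <- rule48_cohorts()
  mix_for <- function(lab) {
    cell <- function(v) {
      r <- counts[counts$cohort == lab & counts$variable == v, ]
      r$numerator / r$denominator
    }
    p_open <- cell("open ice")
    zone <- c(offensive = cell("offensive"), neutral = cell("neutral"),
              defensive = cell("defensive"))
    zone <- zone / sum(zone)
    p_head <- cell("body checks to head")
    mech <- c(
      shoulder_to_head = cell("shoulder"), glove_to_head = cell("glove"),
      arm_to_head = cell("arm"),
      other_body_check = cell("all body checks") - p_head
    )
    # renormalize the head-hit subtypes to the head-hit total so nesting is
    # exact, then give the remainder to non-body-check mechanisms
    mech[1:3] <- mech[1:3] * (p_head / sum(mech[1:3]))
    mech <- c(mech, other = 1 - sum(mech))
    pos <- c(forward = cell("forward"), defense = cell("defense"),
             goalie = cell("goalie"))
    pos <- pos / sum(pos)
    list(
      location = c("open ice" = p_open, "perimeter" = 1 - p_open),
      zone = zone,
      period = c(first = cell("first period"), later = 1 - cell("first period")),
      mechanism = mech,
      lateral_given_head = cell("lateral hit to head") / p_head,
      position = pos,
      puck_possession = cell("puck possession"),
      penalty = cell("penalty called")
    )
  }
  cfg <- function(lab, seed) {
    ch <- cohorts[cohorts$label == lab, ]
    season_config(
      label = lab, n_games = ch$n_games,
      incidence_per_game = ch$n_concussions_total / ch$n_games,
      video_rate = ch$n_concussions_video / ch$n_concussions_total,
      seed = seed, mixtures = mix_for(lab)
    )
  }
  list(pre = cfg("2006-2010", seed_pre), post = cfg("2014-2019", seed_post))
}

#' Simulate one season of game-level events
#'
#' @param config A [season_config()].
#' @param events_per_game `"bernoulli"` (default: at most one event per
#'   game, matching the binomial contrast model exactly) or `"poisson"`
#'   (multiple events per game allowed, for misspecification stress tests).
#' @return A tibble with one row per event-free game and one row per event:
#'   columns `game`, `cohort`, `event`, `location`, `zone`, `period`,
#'   `mechanism`, `lateral`, `position`, `puck_possession`, `penalty`,
#'   `video`. Characteristic columns are `NA` for rows without an event.
#' @export
simulate_season <- function(config,
                            events_per_game = c("bernoulli", "poisson")) {
  stopifnot(inherits(config, "season_config"))
  events_per_game <- match.arg(events_per_game)
  set.seed(config$seed)
  n <- config$n_games
  counts_per_game <- if (events_per_game == "bernoulli") {
    rbinom(n, 1, config$incidence_per_game)
  } else {
    stats::rpois(n, config$incidence_per_game)
  }
  game_idx <- rep(seq_len(n), pmax(counts_per_game, 1))
  is_event <- rep(counts_per_game > 0, pmax(counts_per_game, 1))
  n_ev <- sum(counts_per_game)
  mx <- config$mixtures
  draw_cat <- function(mix, k) {
    names(mix)[sample.int(length(mix), k, replace = TRUE, prob = mix)]
  }
  out <- tibble::tibble(
    game = game_idx,
    cohort = config$label,
    event = is_event,
    location = NA_character_, zone = NA_character_, period = NA_character_,
    mechanism = NA_character_, lateral = NA, position = NA_character_,
    puck_possession = NA, penalty = NA, video = NA
  )
  if (n_ev > 0) {
    ev <- which(out$event)
    out$location[ev] <- draw_cat(mx$location, n_ev)
    out$zone[ev] <- draw_cat(mx$zone, n_ev)
    out$period[ev] <- draw_cat(mx$period, n_ev)
    out$mechanism[ev] <- draw_cat(mx$mechanism, n_ev)
    head_hit <- out$mechanism[ev] %in%
      c("shoulder_to_head", "glove_to_head", "arm_to_head")
    out$lateral[ev] <- head_hit &
      (runif(n_ev) < mx$lateral_given_head)
    out$position[ev] <- draw_cat(mx$position, n_ev)
    out$puck_possession[ev] <- runif(n_ev) < mx$puck_possession
    out$penalty[ev] <- runif(n_ev) < mx$penalty
    out$video[ev] <- runif(n_ev) < config$video_rate
  }
  out
}

#' Aggregate simulated events to characteristic counts and cohort totals
#'
#' Events without video are excluded from proportion numerators and
#' denominators (they are never characteristic-coded); incidence
#' denominators use all games and incidence totals use all events, video or
#' not — mirroring how the real surveillance counts are assembled.
#'
#' @param events A [simulate_season()] table (one cohort).
#' @param taxonomy Label vocabulary; unknown simulated labels are an error.
#' @return List with `counts` (kind `events_with_video`) and `cohorts` (one
#'   row). Variables whose denominator would be zero are dropped with a
#'   warning.
#' @export
aggregate_events <- function(events, taxonomy = rule48_taxonomy()) {
  if (nrow(events) == 0) abort("`events` is empty.")
  lab <- unique(events$cohort)
  stopifnot(length(lab) == 1)
  ev <- events[events$event, ]
  known <- list(
    location = c("open ice", "perimeter"),
    zone = c("offensive", "neutral", "defensive"),
    period = c("first", "later"),
    mechanism = c("shoulder_to_head", "glove_to_head", "arm_to_head",
                  "other_body_check", "other"),
    position = c("forward", "defense", "goalie")
  )
  for (col in names(known)) {
    bad <- setdiff(unique(ev[[col]]), c(known[[col]], NA))
    if (length(bad) > 0) {
      abort(paste0("Unknown ", col, " label(s): ",
                   paste(shQuote(bad), collapse = ", ")))
    }
  }
  vid <- ev[!is.na(ev$video) & ev$video, ]
  n_vid <- nrow(vid)
  head_hit <- vid$mechanism %in% c("shoulder_to_head", "glove_to_head",
                                   "arm_to_head")
  numerators <- c(
    "open ice" = sum(vid$location == "open ice"),
    "offensive" = sum(vid$zone == "offensive"),
    "neutral" = sum(vid$zone == "neutral"),
    "defensive" = sum(vid$zone == "defensive"),
    "all body checks" = sum(head_hit | vid$mechanism == "other_body_check"),
    "body checks to head" = sum(head_hit),
    "shoulder" = sum(vid$mechanism == "shoulder_to_head"),
    "glove" = sum(vid$mechanism == "glove_to_head"),
    "arm" = sum(vid$mechanism == "arm_to_head"),
    "lateral hit to head" = sum(vid$lateral),
    "first period" = sum(vid$period == "first"),
    "puck possession" = sum(vid$puck_possession),
    "penalty called" = sum(vid$penalty),
    "forward" = sum(vid$position == "forward"),
    "defense" = sum(vid$position == "defense"),
    "goalie" = sum(vid$position == "goalie")
  )
  counts <- tibble::tibble(
    cohort = lab, variable = names(numerators),
    numerator = as.integer(numerators), denominator = n_vid,
    denominator_kind = "events_with_video"
  )
  if (n_vid == 0) {
    warn("No video-documented events: all proportion records dropped.")
    counts <- counts[0, ]
  }
  cohorts <- tibble::tibble(
    label = lab, n_games = max(events$game),
    n_concussions_total = nrow(ev), n_concussions_video = n_vid
  )
  list(counts = counts, cohorts = cohorts)
}

#' Interval calibration study on synthetic cohorts
#'
#' Repeatedly simulates a pre and a post cohort, runs the full pipeline
#' (prior tuning at the pre-period observed value, per-cohort posterior,
#' contrast) for one characteristic, and records whether the 90% credible
#' interval covers the configured true difference and the signed estimation
#' error. With the skeptical prior, estimates of a true nonzero shift are
#' biased toward 0 (shrinkage), while coverage at a true null is at or
#' above nominal.
#'
#' @param config_pre,config_post [season_config()]s for the two cohorts.
#' @param true_diff True difference on the reporting scale (pp), post minus
#'   pre, implied by the two configs for `variable`.
#' @param n_reps Number of replicates (at least 100 for reported coverage).
#' @param seed Master seed; replicate r uses derived substreams.
#' @param variable Characteristic to analyze (default `"open ice"`).
#' @param target_sd_diff Prior tuning target (pp).
#' @param engine Posterior engine; the deterministic quadrature engine is
#'   the default for speed.
#' @param tune_n_sim Prior replicates per tuner evaluation.
#' @return List with `coverage` (fraction of replicates whose 90% CrI covers
#'   `true_diff`), `mean_bias` (mean of estimate minus `true_diff`, pp),
#'   `n_reps`, and the per-replicate tibble `replicates`.
#' @export
calibration_study <- function(config_pre, config_post, true_diff, n_reps,
                              seed = 1L, variable = "open ice",
                              target_sd_diff = 10,
                              engine = c("quadrature", "mcmc"),
                              tune_n_sim = 1e5) {
  engine <- match.arg(engine)
  if (n_reps < 100) {
    inform("Fewer than 100 replicates: coverage estimate will be coarse.")
  }
  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    cp <- config_pre
    cq <- config_post
    cp$seed <- substream_seed(seed, 2L * r)
    cq$seed <- substream_seed(seed, 2L * r + 1L)
    agg_pre <- aggregate_events(simulate_season(cp))
    agg_post <- aggregate_events(simulate_season(cq))
    cell <- function(agg) {
      row <- agg$counts[agg$counts$variable == variable, ]
      c(y = row$numerator, n = row$denominator)
    }
    a <- cell(agg_pre)
    b <- cell(agg_post)
    p0 <- if (a["y"] == 0 || a["y"] == a["n"]) {
      (a["y"] + 0.5) / (a["n"] + 1)
    } else {
      a["y"] / a["n"]
    }
    pr <- tune_sigma(p0, target_sd_diff = target_sd_diff,
                     seed = substream_seed(seed, 10000L + r),
                     n_sim = tune_n_sim)
    fit <- function(cell, cohort) {
      if (engine == "quadrature") {
        posterior_quadrature(cell["y"], cell["n"], pr, variable = variable,
                             cohort = cohort)
      } else {
        posterior_mcmc(cell["y"], cell["n"], pr, variable = variable,
                       cohort = cohort, seed = substream_seed(seed, 20000L + r))
      }
    }
    ct <- make_contrast(fit(a, "pre"), fit(b, "post"), scale = "pp",
                        seed = substream_seed(seed, 30000L + r))
    tibble::tibble(
      rep = r, estimate = ct$mean_diff,
      cri90_lo = ct$cri90[1], cri90_hi = ct$cri90[2],
      covered = ct$cri90[1] <= true_diff & true_diff <= ct$cri90[2]
    )
  })
  list(
    coverage = mean(reps$covered),
    mean_bias = mean(reps$estimate - true_diff),
    n_reps = n_reps,
    replicates = reps
  )
}
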