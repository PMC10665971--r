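#' Round half away from zero
#'
#' Display rounding used for all reported percentages and rates: ties go away
#' from zero (so 6.15 -> 6.2), unlike base [round()] which rounds half to
#' even. Full precision is always retained internally; this is applied only
#' at reporting time.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(c(6.15, 2.25, -2.25), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Raw proportion of events with a characteristic, in percent
#'
#' @param numerator Count of events bearing the characteristic.
#' @param denominator Count of events assessed for it (must be positive).
#' @return `100 * numerator / denominator`, unrounded. Use [round_half_up()]
#'   for display.
#' @examples
#' raw_proportion(113, 231) # 48.9 after 1-decimal rounding
#' @export
raw_proportion <- function(numerator, denominator) {
  stopifnot(is.numeric(numerator), is.numeric(denominator))
  if (any(denominator <= 0)) abort("`denominator` must be positive.")
  if (any(numerator < 0) || any(numerator > denominator)) {
    abort("`numerator` must lie in [0, denominator].")
  }
  100 * numerator / denominator
}

#' Raw incidence per 100 games
#'
#' @param numerator Event count.
#' @param n_games Number of games (must be positive).
#' @return `100 * numerator / n_games`, unrounded.
#' @examples
#' raw_incidence_per_100(301, 4920) # 6.1 after 1-decimal rounding
#' @export
raw_incidence_per_100 <- function(numerator, n_games) {
  stopifnot(is.numeric(numerator), is.numeric(n_games))
  if (any(n_games <= 0)) abort("`n_games` must be positive.")
  if (any(numerator < 0)) abort("`numerator` must be nonnegative.")
  100 * numerator / n_games
}

#' Video coverage of diagnosed concussions, in percent
#'
#' Fraction of diagnosed concussions for which usable video documentation
#' exists (events without video are excluded from characteristic coding).
#'
#' @param cohorts A cohort tibble (see [read_cohorts()]) — coverage is
#'   computed per cohort and pooled — or a numeric count of video events.
#' @param n_total Total diagnosed concussions, when `cohorts` is numeric.
#' @return For the data-frame form, a tibble with one row per cohort plus a
#'   `"pooled"` row and columns `label`, `n_video`, `n_total`, `coverage_pct`;
#'   for the numeric form, the percentage as a bare number.
#' @examples
#' video_coverage(688, 817) # 84.2 after rounding
#' @export
video_coverage <- function(cohorts, n_total = NULL) {
  if (is.data.frame(cohorts)) {
    ch <- validate_cohorts(cohorts)
    out <- tibble::tibble(
      label = c(ch$label, "pooled"),
      n_video = c(ch$n_concussions_video, sum(ch$n_concussions_video)),
      n_total = c(ch$n_concussions_total, sum(ch$n_concussions_total))
    )
    out$coverage_pct <- video_coverage(out$n_video, out$n_total)
    return(out)
  }
  if (any(n_total <= 0)) abort("Total concussion count must be positive.")
  if (any(cohorts < 0) || any(cohorts > n_total)) {
    abort("Video count must lie in [0, total].")
  }
  100 * cohorts / n_total
}

## ---- validation -----------------------------------------------------------

normalize_minus <- function(x) gsub("−", "-", x)

validate_cohorts <- function(cohorts) {
  req <- c("label", "n_games", "n_concussions_total", "n_concussions_video")
  miss <- setdiff(req, names(cohorts))
  if (length(miss) > 0) {
    abort(paste0("Cohort table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  cohorts$label <- normalize_minus(as.character(cohorts$label))
  bad <- cohorts$n_concussions_video > cohorts$n_concussions_total
  if (any(bad)) {
    abort(paste0("Cohort ", shQuote(cohorts$label[which(bad)[1]]),
                 ": video count exceeds total concussion count."))
  }
  tibble::as_tibble(cohorts[req])
}

#' Validate a characteristic count table
#'
#' Checks column presence, the numerator/denominator ordering, the
#' denominator-kind vocabulary, that every variable resolves to the taxonomy,
#' and (when a cohort table is supplied) that event-based denominators do not
#' exceed the cohort's video-documented event count. Per-variable denominators
#' may legitimately be *smaller* than the cohort total because of missing data
#' on individual characteristics.
#'
#' @param counts Data frame with columns `cohort`, `variable`, `numerator`,
#'   `denominator`, `denominator_kind`.
#' @param cohorts Optional cohort table for cross-checks.
#' @param taxonomy Label vocabulary, default [rule48_taxonomy()].
#' @return The validated counts as a tibble (invisibly usable in pipes).
#' @export
validate_counts <- function(counts, cohorts = NULL,
                            taxonomy = rule48_taxonomy()) {
  req <- c("cohort", "variable", "numerator", "denominator",
           "denominator_kind")
  miss <- setdiff(req, names(counts))
  if (length(miss) > 0) {
    abort(paste0("Count table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  counts <- tibble::as_tibble(counts[req])
  counts$cohort <- normalize_minus(as.character(counts$cohort))
  counts$variable <- normalize_minus(as.character(counts$variable))
  validate_variables(counts$variable, taxonomy)
  kinds <- c("events_with_video", "games")
  bad_kind <- !counts$denominator_kind %in% kinds
  if (any(bad_kind)) {
    abort(paste0("Row ", which(bad_kind)[1], ": denominator_kind must be one of ",
                 paste(shQuote(kinds), collapse = ", "), "."))
  }
  num_ok <- is.finite(counts$numerator) & is.finite(counts$denominator) &
    counts$numerator >= 0 & counts$denominator > 0 &
    counts$numerator == floor(counts$numerator)
  if (any(!num_ok)) {
    abort(paste0("Row ", which(!num_ok)[1],
                 ": counts must be nonnegative integers with a positive denominator."))
  }
  over <- counts$numerator > counts$denominator
  if (any(over)) {
    abort(paste0("Row ", which(over)[1], " (", counts$variable[which(over)[1]],
                 "): numerator exceeds denominator."))
  }
  if (!is.null(cohorts)) {
    ch <- validate_cohorts(cohorts)
    ev <- counts[counts$denominator_kind == "events_with_video", ]
    m <- match(ev$cohort, ch$label)
    bad <- !is.na(m) & ev$denominator > ch$n_concussions_video[m]
    if (any(bad)) {
      i <- which(bad)[1]
      abort(paste0("Variable ", shQuote(ev$variable[i]), " in cohort ",
                   shQuote(ev$cohort[i]),
                   ": event denominator exceeds the cohort's video-documented total."))
    }
  }
  counts
}

## ---- I/O ------------------------------------------------------------------

#' Read a characteristic count table from CSV
#'
#' Expects header columns `cohort,variable,numerator,denominator,
#' denominator_kind`. Unicode minus signs in labels are normalized to ASCII
#' hyphens on ingest. An empty file (header only) yields an empty, valid
#' tibble.
#'
#' @param path CSV file path.
#' @param taxonomy Label vocabulary used to reject unknown variables.
#' @param cohorts Optional cohort table (or path to one) for cross-checks.
#' @return A validated tibble of characteristic counts.
#' @export
read_counts <- function(path, taxonomy = rule48_taxonomy(), cohorts = NULL) {
  counts <- readr::read_csv(
    path,
    col_types = readr::cols(
      cohort = readr::col_character(),
      variable = readr::col_character(),
      numerator = readr::col_double(),
      denominator = readr::col_double(),
      denominator_kind = readr::col_character()
    )
  )
  if (is.character(cohorts)) cohorts <- read_cohorts(cohorts)
  validate_counts(counts, cohorts = cohorts, taxonomy = taxonomy)
}

#' Write a characteristic count table to CSV
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(x, f))` is the
#' identity on validated tables.
#'
#' @param counts Validated count tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  counts <- validate_counts(counts)
  readr::write_csv(counts, path)
  invisible(path)
}

#' Read a cohort summary table from CSV
#'
#' Columns: `label`, `n_games`, `n_concussions_total`, `n_concussions_video`.
#'
#' @param path CSV file path.
#' @return A validated cohort tibble.
#' @export
read_cohorts <- function(path) {
  validate_cohorts(readr::read_csv(
    path,
    col_types = readr::cols(
      label = readr::col_character(),
      n_games = readr::col_double(),
      n_concussions_total = readr::col_double(),
      n_concussions_video = readr::col_double()
    )
  ))
}

#' Bundled NHL Rule 48 count fixture
#'
#' The published two-cohort count tables for regular-season NHL concussions
#' before (2006-2010, 4 seasons) and after (2014-2019, 5 seasons) the
#' introduction of Rule 48: 16 characteristic variables per cohort with the
#' per-variable denominators implied by the printed percentages (missing data
#' make some denominators smaller than the cohort's 231/457 video-documented
#' events), plus cohort totals (301/516 diagnosed concussions in 4920/6232
#' games).
#'
#' @return `rule48_counts()`: a 32-row count tibble; `rule48_cohorts()`: a
#'   2-row cohort tibble.
#' @examples
#' rule48_counts()
#' rule48_cohorts()
#' @export
rule48_counts <- function() {
  read_counts(system.file("extdata", "nhl_rule48_counts.csv",
                          package = "headcheck", mustWork = TRUE))
}

#' @rdname rule48_counts
#' @export
rule48_cohorts <- function() {
  read_cohorts(system.file("extdata", "nhl_rule48_cohorts.csv",
                           package = "headcheck", mustWork = TRUE))
}

#' Re-denominate characteristic counts as per-game incidence records
#'
#' Characteristic incidence uses the same video-coded event numerators but
#' the cohort's full game count as denominator. Optionally adds an
#' `"all concussions"` row per cohort using the total diagnosed count (video
#' and non-video), which is how the overall incidence is defined.
#'
#' @param counts Event-based count tibble (kind `events_with_video`).
#' @param cohorts Cohort tibble supplying `n_games` and totals.
#' @param include_overall Add the overall row? Default `TRUE`.
#' @return A count tibble with `denominator_kind == "games"`.
#' @export
incidence_counts <- function(counts, cohorts, include_overall = TRUE) {
  counts <- validate_counts(counts)
  ch <- validate_cohorts(cohorts)
  ev <- counts[counts$denominator_kind == "events_with_video", ]
  m <- match(ev$cohort, ch$label)
  if (anyNA(m)) {
    abort(paste0("Cohort ", shQuote(ev$cohort[which(is.na(m))[1]]),
                 " not present in the cohort table."))
  }
  out <- tibble::tibble(
    cohort = ev$cohort,
    variable = ev$variable,
    numerator = ev$numerator,
    denominator = ch$n_games[m],
    denominator_kind = "games"
  )
  if (include_overall) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      cohort = ch$label,
      variable = "all concussions",
      numerator = ch$n_concussions_total,
      denominator = ch$n_games,
      denominator_kind = "games"
    ))
  }
  out
}

#' Append display-ready raw columns to a count table
#'
#' @param counts Validated count tibble.
#' @return The same tibble with `raw_value` (unrounded percent or per-100
#'   rate, by denominator kind) and `raw_display` (1-decimal, half-up).
#' @export
add_raw_columns <- function(counts) {
  counts <- validate_counts(counts)
  counts$raw_value <- ifelse(
    counts$denominator_kind == "games",
    raw_incidence_per_100(counts$numerator, counts$denominator),
    raw_proportion(counts$numerator, counts$denominator)
  )
  counts$raw_display <- round_half_up(counts$raw_value, 1)
  counts
}
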