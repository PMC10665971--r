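#' Equal-tailed percentile credible interval
#'
#' Quantiles at `(1 - mass)/2` and `1 - (1 - mass)/2` with linear
#' interpolation between order statistics (base type-7 rule).
#'
#' @param diff_draws Numeric sample vector.
#' @param mass Interval mass in (0, 1].
#' @return Length-2 numeric `(lower, upper)`.
#' @examples
#' percentile_interval(1:100, 0.90) # c(5.95, 95.05)
#' @export
percentile_interval <- function(diff_draws, mass) {
  if (length(diff_draws) == 0) abort("`diff_draws` must be nonempty.")
  if (mass <= 0 || mass > 1) abort("`mass` must lie in (0, 1].")
  if (length(diff_draws) < 100) {
    warn("Fewer than 100 draws: reported interval endpoints will be coarse.")
  }
  tail <- (1 - mass) / 2
  quantile(diff_draws, c(tail, 1 - tail), names = FALSE, type = 7)
}

#' Posterior probability mass above zero
#'
#' @param diff_draws Numeric sample vector of difference draws.
#' @return Fraction of draws strictly greater than 0. Draws exactly at 0 are
#'   counted in neither direction; see [make_contrast()] for the full
#'   three-way split.
#' @export
probability_mass_positive <- function(diff_draws) {
  if (length(diff_draws) == 0) abort("`diff_draws` must be nonempty.")
  mean(diff_draws > 0)
}

#' Between-cohort posterior contrast
#'
#' Pairs posterior draws from two independent cohort fits and summarizes the
#' difference `100 * (p_post - p_pre)`: posterior mean, equal-tailed 70% and
#' 90% credible intervals, and the probability mass on each side of zero.
#' Differences are always stored signed as post minus pre; reporting layers
#' may flip sign for display. By default both draw vectors are independently
#' permuted (seeded) before pairing, so that the ordered pseudo-draws of the
#' quadrature engine still produce valid independent pairings.
#'
#' @param draws_pre,draws_post `posterior_draws` for the two cohorts; equal
#'   draw counts and matching variables required.
#' @param scale `"pp"` (difference in proportions, percentage points) or
#'   `"per_100_games"` (difference in incidence). Label only; both are
#'   `100 *` the probability difference.
#' @param seed Seed for the pairing permutation.
#' @param permute Permute before pairing? Default `TRUE`.
#' @param intervals Interval masses to report (default 0.7 and 0.9).
#' @return A `contrast_result`: list with `variable`, `scale`, `mean_diff`,
#'   `cri70`, `cri90`, `pm_positive`, `pm_negative`, `pm_zero`, `n_draws`,
#'   and the difference draws in `diff_draws`.
#' @export
make_contrast <- function(draws_pre, draws_post,
                          scale = c("pp", "per_100_games"), seed = 1L,
                          permute = TRUE, intervals = c(0.7, 0.9)) {
  scale <- match.arg(scale)
  d_pre <- draws_pre$draws_prob
  d_post <- draws_post$draws_prob
  if (length(d_pre) != length(d_post)) {
    abort("Cohort draw counts differ; refit with equal numbers of draws.")
  }
  v_pre <- draws_pre$variable
  v_post <- draws_post$variable
  if (!identical(v_pre, v_post) && !(is.na(v_pre) && is.na(v_post))) {
    abort(sprintf("Variable mismatch: %s vs %s.", v_pre, v_post))
  }
  if (permute) {
    set.seed(substream_seed(seed, 1L))
    d_pre <- d_pre[sample.int(length(d_pre))]
    set.seed(substream_seed(seed, 2L))
    d_post <- d_post[sample.int(length(d_post))]
  }
  diff <- 100 * (d_post - d_pre)
  cri <- lapply(sort(intervals), function(m) percentile_interval(diff, m))
  names(cri) <- sprintf("cri%02d", round(100 * sort(intervals)))
  out <- list(
    variable = v_pre, scale = scale,
    mean_diff = mean(diff),
    cri70 = cri[["cri70"]] %||% NULL,
    cri90 = cri[["cri90"]] %||% NULL,
    intervals = cri,
    pm_positive = mean(diff > 0),
    pm_negative = mean(diff < 0),
    pm_zero = mean(diff == 0),
    n_draws = length(diff),
    diff_draws = diff
  )
  class(out) <- "contrast_result"
  out
}

#' @export
print.contrast_result <- function(x, ...) {
  unit <- if (x$scale == "pp") "pp" else "/100 games"
  cat(sprintf(
    "<contrast_result> %s: mean %s%.1f %s, 90%% CrI (%.1f to %.1f), PM>0 = %.1f%%\n",
    x$variable %||% "?", if (x$mean_diff >= 0) "+" else "", x$mean_diff, unit,
    x$cri90[1], x$cri90[2], 100 * x$pm_positive
  ))
  invisible(x)
}

#' @export
tidy.contrast_result <- function(x, ...) {
  tibble::tibble(
    variable = x$variable, scale = x$scale, mean_diff = x$mean_diff,
    cri70_lo = x$cri70[1], cri70_hi = x$cri70[2],
    cri90_lo = x$cri90[1], cri90_hi = x$cri90[2],
    pm_positive = x$pm_positive, pm_negative = x$pm_negative,
    pm_zero = x$pm_zero, n_draws = x$n_draws
  )
}
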