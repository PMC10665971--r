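#' Empirically centered skeptical priors on the log-odds intercept
#'
#' The contrast model places an independent Gaussian prior alpha ~ N(mu,
#' sigma) on each cohort's log-odds intercept. Skepticism about a
#' between-group difference is encoded by centering *both* cohorts at the
#' pre-period (2006-2010) observed proportion and tuning sigma by
#' prior-predictive simulation until the implied between-group difference has
#' a target spread (default: SD 10 on the reporting scale, i.e. 10
#' percentage points or 10 events/100 games). By symmetry the implied prior
#' mean difference is 0.
#'
#' @name prior_builder
NULL

#' Log-odds center for an empirically centered prior
#'
#' @param p_center Observed pre-period proportion, strictly inside (0, 1).
#' @return `log(p_center / (1 - p_center))`.
#' @examples
#' center_prior(0.5) # 0
#' @export
center_prior <- function(p_center) {
  if (any(!is.finite(p_center)) || any(p_center <= 0) || any(p_center >= 1)) {
    abort(paste0(
      "`p_center` must lie strictly in (0, 1). For a degenerate observed ",
      "proportion (zero or full cell) use the continuity-adjusted center ",
      "(y + 0.5) / (n + 1), as prior_spec() does automatically."
    ))
  }
  log(p_center / (1 - p_center))
}

#' Construct a prior specification
#'
#' @param p_center Prior center on the probability scale. Degenerate values
#'   from a zero/full cell can be avoided by passing `y` and `n` instead, in
#'   which case the continuity-adjusted center `(y + 0.5)/(n + 1)` is used
#'   when needed.
#' @param sigma_logit Prior SD on the log-odds scale.
#' @param target_sd_diff Tuning target this sigma was derived for (reporting
#'   scale), or `NA` if set by hand.
#' @param tuning_seed Seed used by the tuner, or `NA`.
#' @param y,n Optional raw cell behind `p_center`.
#' @return A one-row tibble of class `prior_spec` with columns `mu_logit`,
#'   `sigma_logit`, `center_probability`, `target_sd_diff`, `tuning_seed`.
#' @export
prior_spec <- function(p_center = NULL, sigma_logit, target_sd_diff = NA_real_,
                       tuning_seed = NA_integer_, y = NULL, n = NULL) {
  if (is.null(p_center)) {
    stopifnot(!is.null(y), !is.null(n))
    p_center <- if (y == 0 || y == n) (y + 0.5) / (n + 1) else y / n
  }
  if (!is.finite(sigma_logit) || sigma_logit <= 0) {
    abort("`sigma_logit` must be a positive number.")
  }
  out <- tibble::tibble(
    mu_logit = center_prior(p_center),
    sigma_logit = sigma_logit,
    center_probability = p_center,
    target_sd_diff = target_sd_diff,
    tuning_seed = as.integer(tuning_seed)
  )
  class(out) <- c("prior_spec", class(out))
  out
}

as_prior <- function(prior) {
  if (is.data.frame(prior)) {
    stopifnot(nrow(prior) == 1)
    list(mu = prior$mu_logit, sigma = prior$sigma_logit)
  } else {
    list(mu = prior$mu_logit %||% prior$mu, sigma = prior$sigma_logit %||% prior$sigma)
  }
}

## common random numbers shared by every sigma evaluation within one tuning
## run, so the SD is exactly monotone in sigma and bisection is well posed
prior_diff_draws <- function(mu, sigma, z1, z2, scale_factor = 100) {
  scale_factor * (plogis(mu + sigma * z2) - plogis(mu + sigma * z1))
}

#' Prior-predictive SD of the between-group difference
#'
#' Draws two independent intercepts per replicate from the prior, maps them
#' through the inverse logit, and returns the sample SD of the paired
#' difference on the reporting scale (x100). The mean of the difference is 0
#' by symmetry.
#'
#' @param prior A [prior_spec()] (only `mu_logit`/`sigma_logit` are used).
#' @param n_sim Number of prior replicates, at least 10000.
#' @param seed RNG seed.
#' @return The SD, in reporting units (pp or events/100 games).
#' @export
prior_sd_of_difference <- function(prior, n_sim = 1e5, seed = 1L) {
  if (n_sim < 1e4) abort("`n_sim` must be at least 10000.")
  pr <- as_prior(prior)
  if (pr$sigma < 0) abort("`sigma_logit` must be nonnegative.")
  if (pr$sigma == 0) return(0)
  set.seed(seed)
  z1 <- rnorm(n_sim)
  z2 <- rnorm(n_sim)
  sd(prior_diff_draws(pr$mu, pr$sigma, z1, z2))
}

#' Tune the prior width to a target difference spread
#'
#' Bisection on sigma in `[1e-3, 10]` until the prior-predictive SD of the
#' between-group difference is within `tol` of `target_sd_diff`. All
#' evaluations share one set of common random numbers, making the objective
#' exactly monotone in sigma.
#'
#' @param p_center Prior center on the probability scale (see
#'   [prior_spec()] for degenerate cells).
#' @param target_sd_diff Target SD on the reporting scale; default 10.
#' @param seed RNG seed for the shared prior replicates.
#' @param n_sim Prior replicates per evaluation (default 1e5).
#' @param tol Convergence tolerance on the achieved SD, in reporting units.
#' @param bracket Search interval for sigma.
#' @return A [prior_spec()] with an extra `achieved_sd_diff` column.
#' @examples
#' tune_sigma(0.5, target_sd_diff = 10, seed = 1)
#' @export
tune_sigma <- function(p_center, target_sd_diff = 10, seed = 1L, n_sim = 1e5,
                       tol = 0.1, bracket = c(1e-3, 10)) {
  if (target_sd_diff <= 0) abort("`target_sd_diff` must be positive.")
  mu <- center_prior(p_center)
  set.seed(seed)
  z1 <- rnorm(n_sim)
  z2 <- rnorm(n_sim)
  f <- function(s) sd(prior_diff_draws(mu, s, z1, z2))
  lo <- bracket[1]
  hi <- bracket[2]
  f_lo <- f(lo)
  f_hi <- f(hi)
  if (f_lo > target_sd_diff || f_hi < target_sd_diff) {
    abort(sprintf(
      "Target SD %.3f is outside the achievable range [%.4f, %.4f] for sigma in [%g, %g].",
      target_sd_diff, f_lo, f_hi, lo, hi
    ))
  }
  sigma <- (lo + hi) / 2
  for (i in seq_len(200)) {
    val <- f(sigma)
    if (abs(val - target_sd_diff) < tol) break
    if (val > target_sd_diff) hi <- sigma else lo <- sigma
    sigma <- (lo + hi) / 2
  }
  out <- prior_spec(p_center, sigma, target_sd_diff, seed)
  out$achieved_sd_diff <- f(sigma)
  out
}

#' Build tuned priors for every variable in a count table
#'
#' Centers each variable's prior at the pre-period cohort's observed value
#' (continuity-adjusted for zero/full cells) and tunes its width to the
#' target difference spread.
#'
#' @param counts Validated count tibble (a single denominator kind).
#' @param pre Label of the pre-period cohort used for centering.
#' @param target_sd_diff Tuning target, reporting scale.
#' @param seed Master seed; each variable gets a derived substream.
#' @param n_sim Replicates per tuner evaluation.
#' @return A tibble with one row per variable: the prior-spec columns plus
#'   `variable` and `achieved_sd_diff`. Exportable with [readr::write_csv()]
#'   so a run is reproducible from its artifacts.
#' @export
build_priors <- function(counts, pre = "2006-2010", target_sd_diff = 10,
                         seed = 1L, n_sim = 1e5) {
  counts <- validate_counts(counts, taxonomy = rule48_taxonomy())
  base <- counts[counts$cohort == pre, ]
  if (nrow(base) == 0) {
    abort(paste0("No rows for pre-period cohort ", shQuote(pre), "."))
  }
  purrr::map_dfr(seq_len(nrow(base)), function(i) {
    y <- base$numerator[i]
    n <- base$denominator[i]
    p <- if (y == 0 || y == n) (y + 0.5) / (n + 1) else y / n
    sp <- tune_sigma(p, target_sd_diff = target_sd_diff,
                     seed = substream_seed(seed, i), n_sim = n_sim)
    dplyr::bind_cols(tibble::tibble(variable = base$variable[i]), sp)
  })
}

#' Prior sensitivity grid
#'
#' Documented variants of a base prior for sensitivity analysis: sigma
#' multipliers 0.5, 1, 2 and 5 (keeping the empirical center) plus an
#' uncentered variant with `mu = 0` at the base width.
#'
#' @param prior A base [prior_spec()].
#' @return A 5-row tibble with a `label` column.
#' @export
sensitivity_grid <- function(prior) {
  pr <- as_prior(prior)
  p0 <- if (is.data.frame(prior)) prior$center_probability else plogis(pr$mu)
  mult <- c(0.5, 1, 2, 5)
  base <- purrr::map_dfr(mult, function(m) {
    prior_spec(p0, pr$sigma * m)
  })
  flat <- prior_spec(0.5, pr$sigma) # mu = 0 uncentered variant
  out <- dplyr::bind_rows(base, flat)
  out$label <- c(sprintf("sigma_x%.1f", mult), "uncentered")
  out
}

## deterministic 32-bit substream derivation from a master seed
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 9973) %% 2147483647)
}
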