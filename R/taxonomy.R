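#' Characteristic taxonomy for concussion surveillance variables
#'
#' The label vocabulary used throughout the package: each injury
#' characteristic belongs to exactly one group. "Location" holds both the
#' open-ice/perimeter split and the zone split as marginal variables;
#' "Mechanism" holds the body-check chain (all body checks, body checks to
#' the head, the contacting body part, and lateral hits to the head);
#' "Game situation" and "Position" hold the remaining marginal flags. Each
#' variable is analyzed marginally, so no hierarchy constraint is imposed
#' between e.g. "all body checks" and its nested mechanism rows.
#'
#' @return A tibble with columns `group` (ordered as above) and `variable`.
#' @examples
#' rule48_taxonomy()
#' @export
rule48_taxonomy <- function() {
  tibble::tibble(
    group = rep(
      c("Location", "Mechanism", "Game situation", "Position"),
      times = c(4L, 6L, 3L, 3L)
    ),
    variable = c(
      "open ice", "offensive", "neutral", "defensive",
      "all body checks", "body checks to head", "shoulder", "glove", "arm",
      "lateral hit to head",
      "first period", "puck possession", "penalty called",
      "forward", "defense", "goalie"
    )
  )
}

## internal: assert that every variable resolves to exactly one taxonomy entry
validate_variables <- function(variables, taxonomy = rule48_taxonomy(),
                               extra_allowed = "all concussions") {
  known <- c(taxonomy$variable, extra_allowed)
  bad <- setdiff(unique(variables), known)
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown characteristic variable(s): ",
      paste(shQuote(bad), collapse = ", "),
      ". Known variables are defined by rule48_taxonomy()."
    ))
  }
  invisible(TRUE)
}
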