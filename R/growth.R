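#' Logistic canopy growth curve
#'
#' Canopy cover over the season is emulated with a logistic curve
#' \eqn{c(\mathrm{dap}) = c_{max} / (1 + e^{-r(\mathrm{dap} - m)})}:
#' monotone increasing in days after planting (DAP), half of the asymptote
#' at the midpoint, saturating at `cover_max`.
#'
#' @param dap Days after planting (vectorized).
#' @param cover_max Asymptotic cover fraction in (0, 1].
#' @param rate Growth rate per day.
#' @param midpoint DAP at which cover reaches half of `cover_max`.
#' @return Cover fractions in `[0, cover_max]`.
#' @examples
#' growth_curve(45, cover_max = 0.8, rate = 0.15, midpoint = 45)  # 0.4
#' @export
growth_curve <- function(dap, cover_max, rate = 0.15, midpoint = 45) {
  if (any(cover_max <= 0 | cover_max > 1)) {
    stop("cover_max must lie in (0, 1]", call. = FALSE)
  }
  cover_max / (1 + exp(-rate * (dap - midpoint)))
}

#' Sampling-date schedules for early-season canopy imaging
#'
#' The default schedule is the eight early-season dates of a 2015-style
#' campaign (15 to 54 DAP); `"late"` gives the seven-date 20 to 56 DAP
#' alternative of a season with faster canopy growth.
#'
#' @param schedule `"early"` or `"late"`.
#' @return Integer vector of DAP values.
#' @export
sampling_dates <- function(schedule = c("early", "late")) {
  switch(match.arg(schedule),
         early = c(15L, 29L, 34L, 37L, 44L, 47L, 51L, 54L),
         late = c(20L, 27L, 31L, 37L, 42L, 52L, 56L))
}

#' True canopy cover trajectory matching a target ACC
#'
#' Given a line's target average canopy coverage (mean cover over the
#' sampling dates), rescales a logistic growth curve so that the mean of the
#' per-date covers equals the target, and returns the per-date true covers.
#' Targets larger than the mean of the unit-asymptote logistic over the
#' schedule are not reachable with `cover_max <= 1` and are clamped (with a
#' warning).
#'
#' @param acc Target average cover fraction(s) in `[0, 1)`.
#' @param dates DAP schedule (default [sampling_dates()]).
#' @inheritParams growth_curve
#' @return A matrix of true covers, `length(acc)` rows x `length(dates)`
#'   columns.
#' @export
true_cover_schedule <- function(acc, dates = sampling_dates(), rate = 0.15,
                                midpoint = 45) {
  if (any(acc < 0 | acc >= 1)) stop("acc must lie in [0, 1)", call. = FALSE)
  base <- growth_curve(dates, cover_max = 1, rate = rate, midpoint = midpoint)
  m <- mean(base)
  cover_max <- acc / m
  if (any(cover_max > 1)) {
    warning("target ACC not reachable with cover_max <= 1; clamping")
    cover_max <- pmin(cover_max, 1)
  }
  out <- outer(cover_max, base)
  dimnames(out) <- list(names(acc), paste0("dap", dates))
  out
}
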