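# Behavioral summary measures: signal detection, ANT network scores,
# reaction-time summaries.

#' Signal-detection sensitivity and bias
#'
#' Computes d-prime (`qnorm(H) - qnorm(F)`) and criterion
#' (`-(qnorm(H) + qnorm(F)) / 2`) from trial counts, using the log-linear
#' correction `H = (hits + 0.5) / (hits + misses + 1)` (and similarly for
#' false alarms) so both statistics stay finite for perfect or empty cells.
#'
#' @param hits,misses Signal-trial outcome counts.
#' @param fas,crs Noise-trial outcome counts (false alarms, correct
#'   rejections).
#' @returns A tibble with columns `hit_rate`, `fa_rate` (corrected rates),
#'   `sensitivity` (d', SD units) and `bias` (criterion c, SD units).
#' @examples
#' signal_detection(hits = 24, misses = 0, fas = 0, crs = 24)
#' @export
signal_detection <- function(hits, misses, fas, crs) {
  for (nm in c("hits", "misses", "fas", "crs")) {
    x <- get(nm)
    check_number(x, nm)
    if (any(x < 0)) abort(sprintf("`%s` must be non-negative.", nm))
  }
  if (any(hits + misses == 0)) abort("no signal trials.")
  if (any(fas + crs == 0)) abort("no noise trials.")
  h <- (hits + 0.5) / (hits + misses + 1)
  f <- (fas + 0.5) / (fas + crs + 1)
  tibble(
    hit_rate = h,
    fa_rate = f,
    sensitivity = qnorm(h) - qnorm(f),
    bias = -(qnorm(h) + qnorm(f)) / 2
  )
}

#' Attentional-network scores from condition-mean RTs
#'
#' `alerting = rt_0cue - rt_2cue`, `orienting = rt_center - rt_spatial`,
#' `conflict = rt_incongruent - rt_congruent`, all in ms. Scores can be
#' negative; adding a constant to every condition RT leaves them unchanged.
#'
#' @param rt_0cue,rt_2cue,rt_center,rt_spatial,rt_congruent,rt_incongruent
#'   Mean correct-trial RTs (ms) for the six cue/flanker conditions.
#' @returns A tibble with columns `alerting`, `orienting`, `conflict`.
#' @export
ant_network_scores <- function(rt_0cue, rt_2cue, rt_center, rt_spatial,
                               rt_congruent, rt_incongruent) {
  args <- list(rt_0cue = rt_0cue, rt_2cue = rt_2cue, rt_center = rt_center,
               rt_spatial = rt_spatial, rt_congruent = rt_congruent,
               rt_incongruent = rt_incongruent)
  for (nm in names(args)) check_number(args[[nm]], nm, positive = TRUE)
  tibble(
    alerting = rt_0cue - rt_2cue,
    orienting = rt_center - rt_spatial,
    conflict = rt_incongruent - rt_congruent
  )
}

#' Summarize reaction times over correct trials
#'
#' @param rts Trial RTs in ms.
#' @param correct Logical mask of correct trials (default: all correct).
#' @param statistic `"mean"` or `"median"` (the median is conventional for
#'   go/no-go RTs; the mean elsewhere).
#' @returns A single RT summary in ms.
#' @export
rt_summary <- function(rts, correct = rep(TRUE, length(rts)),
                       statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  check_number(rts, "rts", positive = TRUE)
  if (length(correct) != length(rts)) {
    abort("`correct` must match `rts` in length.")
  }
  kept <- rts[correct]
  if (length(kept) == 0) abort("no correct trials.")
  if (statistic == "mean") mean(kept) else median(kept)
}
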