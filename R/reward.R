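# Reward for one visit-to-visit transition, driven by the change in the
# discretized HbA1c control band (1 = well controlled ... 3 = poorly
# controlled). Improvement (a drop in band) earns positive reward, reaching
# the controlled band earns a bonus, landing in the uncontrolled band a
# penalty. The greedy policy is invariant to positive rescaling of these
# weights, so their absolute magnitudes are conventions, not clinical claims.

#' Reward-function weights
#'
#' @param improvement_weight Weight on the (signed) drop in HbA1c band per
#'   transition. Default 1.
#' @param controlled_bonus Bonus added when the next band is 1 (well
#'   controlled, HbA1c at or below 7%). Default 1.
#' @param uncontrolled_penalty Penalty subtracted when the next band is 3
#'   (poorly controlled, HbA1c above 9%). Default 1.
#' @return A list of class `reward_params`.
#' @export
reward_params <- function(improvement_weight = 1, controlled_bonus = 1,
                          uncontrolled_penalty = 1) {
  w <- c(improvement_weight, controlled_bonus, uncontrolled_penalty)
  if (!is.numeric(w) || anyNA(w) || any(w < 0) || all(w == 0)) {
    stop("reward weights must be nonnegative and not all zero.", call. = FALSE)
  }
  structure(
    list(improvement_weight = improvement_weight,
         controlled_bonus = controlled_bonus,
         uncontrolled_penalty = uncontrolled_penalty),
    class = "reward_params"
  )
}

#' Reward for a change in HbA1c control band
#'
#' `r = w_imp * (band_before - band_after) + bonus * 1[band_after == 1] -
#' penalty * 1[band_after == 3]`. Moving toward the controlled band never
#' earns less than deteriorating from the same starting band.
#'
#' @param level_before,level_after Integer vectors of HbA1c bands in
#'   `{1, 2, 3}` at consecutive visits.
#' @param params A [reward_params()] object.
#' @return Numeric vector of rewards.
#' @examples
#' compute_reward(2, 1) # improvement into the controlled band
#' compute_reward(1, 3) # deterioration into the uncontrolled band
#' @export
compute_reward <- function(level_before, level_after, params = reward_params()) {
  stopifnot(inherits(params, "reward_params"))
  ok <- level_before %in% 1:3 & level_after %in% 1:3
  if (!all(ok)) {
    stop("HbA1c bands must lie in {1, 2, 3}.", call. = FALSE)
  }
  params$improvement_weight * (level_before - level_after) +
    params$controlled_bonus * (level_after == 1) -
    params$uncontrolled_penalty * (level_after == 3)
}
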