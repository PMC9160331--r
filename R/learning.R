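# Value learning (Rescorla-Wagner), softmax action selection, taste-predictor
# learning, and the tonic LPBN / DREADD selection-time bias.

#' Tonic selection-time bias (LPBN suppression and DREADD cancellation)
#'
#' A tonic negative bias `lpbn` is subtracted from one action's value at
#' selection time only, modelling parabrachial (LPBN) suppression of sodium
#' appetite.  Chemogenetic silencing (DREADD) is modelled as the addition
#' of a cancelling positive term `drd`; in the canonical experiment
#' `drd = lpbn`, so the bias cancels exactly.  The biased value is an
#' ephemeral quantity used only to choose the action: stored action values
#' are never modified by the bias.
#'
#' @param lpbn Nonnegative real, the tonic negative bias.
#' @param drd Nonnegative real, the DREADD cancellation term.
#' @param dreadd_on Logical; is the DREADD manipulation active?
#' @param biased_action Label of the action the bias applies to
#'   (conventionally the saltwater-intake action).
#' @return An object of class `hrl_bias_params`.
#' @export
bias_params <- function(lpbn = 0, drd = 0, dreadd_on = FALSE, biased_action) {
  .check(is.numeric(lpbn) && length(lpbn) == 1 && is.finite(lpbn) && lpbn >= 0,
         "`lpbn` must be a single nonnegative number")
  .check(is.numeric(drd) && length(drd) == 1 && is.finite(drd) && drd >= 0,
         "`drd` must be a single nonnegative number")
  .check(is.logical(dreadd_on) && length(dreadd_on) == 1 && !is.na(dreadd_on),
         "`dreadd_on` must be TRUE or FALSE")
  .check(is.character(biased_action) && length(biased_action) == 1,
         "`biased_action` must be a single action label")
  structure(list(lpbn = as.numeric(lpbn), drd = as.numeric(drd),
                 dreadd_on = dreadd_on, biased_action = biased_action),
            class = "hrl_bias_params")
}

#' Selection-time effective action values
#'
#' Returns the stored action values with `-lpbn` added to the biased action
#' (plus `+drd` when the DREADD manipulation is on).  All other actions,
#' and the stored values themselves, are untouched.
#'
#' @param q Named numeric vector of stored action values.
#' @param bias A [bias_params()] object, or `NULL` for no bias.
#' @return A numeric vector of the same length and names as `q`.
#' @export
effective_values <- function(q, bias = NULL) {
  q <- unlist(q)
  .check(is.numeric(q) && length(q) >= 1, "`q` must be a numeric vector")
  if (is.null(bias)) return(q)
  stopifnot(inherits(bias, "hrl_bias_params"))
  .check(!is.null(names(q)) && bias$biased_action %in% names(q),
         "biased action '%s' is not among the action labels (%s)",
         bias$biased_action, paste(names(q), collapse = ", "))
  q[bias$biased_action] <- q[bias$biased_action] - bias$lpbn +
    if (bias$dreadd_on) bias$drd else 0
  q
}

#' Softmax choice probabilities
#'
#' `P(a_k) = exp(beta q_k) / sum_j exp(beta q_j)`, with `beta` the inverse
#' temperature (`beta = 0` gives the uniform distribution).  Computed with
#' max-subtraction, which is exact by translation invariance and avoids
#' overflow for large `beta * q`.
#'
#' @param values Numeric vector of (effective) action values.
#' @param beta Nonnegative inverse temperature.
#' @return A probability vector of the same length (and names) as
#'   `values`; components are positive and sum to one.
#' @examples
#' action_probabilities(c(1, 0), beta = 1)  # c(e, 1)/(e + 1)
#' @export
action_probabilities <- function(values, beta) {
  values <- unlist(values)
  .check(is.numeric(values) && length(values) >= 1,
         "`values` must contain at least one action value")
  .check(all(is.finite(values)), "action values must be finite")
  .check(is.numeric(beta) && length(beta) == 1 && is.finite(beta) && beta >= 0,
         "`beta` must be a single nonnegative number")
  z <- beta * values
  e <- exp(z - max(z))
  e / sum(e)
}

#' Draw one action index from a probability vector
#'
#' Inversion sampling on the running RNG stream: a single `runif(1)` draw
#' is mapped through the cumulative distribution, so the sequence of
#' chosen indices is reproducible from the seed.
#'
#' @param probs Probability vector (positive or zero components summing to
#'   one within `1e-8`).
#' @return An integer index into `probs`.
#' @export
sample_action <- function(probs) {
  probs <- unlist(probs)
  .check(is.numeric(probs) && length(probs) >= 1 && all(is.finite(probs)) &&
           all(probs >= 0),
         "`probs` must be a vector of nonnegative probabilities")
  .check(abs(sum(probs) - 1) <= 1e-8,
         "`probs` must sum to 1 (got %.12f)", sum(probs))
  .sample_index(probs)
}

.sample_index <- function(probs) {
  u <- stats::runif(1)
  which(u <= cumsum(probs))[1L]
}

#' Rescorla-Wagner update of an action value
#'
#' `Q' = Q + alpha_q (r - Q)`: the value of the taken action moves toward
#' the obtained reward by a fraction `alpha_q` of the reward prediction
#' error.  The fixed point is `Q = r`.
#'
#' @param q Current action value (scalar).
#' @param reward Obtained reward.
#' @param alpha_q Learning rate in `(0, 1]`.
#' @return The updated value.
#' @export
update_q <- function(q, reward, alpha_q) {
  .check(is.numeric(alpha_q) && length(alpha_q) == 1 &&
           alpha_q > 0 && alpha_q <= 1,
         "`alpha_q` must lie in (0, 1]")
  .check(is.numeric(q) && length(q) == 1 && is.finite(q),
         "`q` must be a single finite number")
  .check(is.numeric(reward) && length(reward) == 1 && is.finite(reward),
         "`reward` must be a single finite number")
  q + alpha_q * (reward - q)
}

#' Delta-rule update of a taste predictor
#'
#' The taste predictor `K-hat` of an action is the learned estimate of the
#' internal-state change that the action's taste signals.  After the
#' action is taken it moves componentwise toward the actually delivered
#' intake: `K-hat' = K-hat + alpha_khat (K - K-hat)`.
#'
#' @param k_hat Current predictor vector.
#' @param k_actual Actually delivered intake vector (same length).
#' @param alpha_khat Learning rate in `(0, 1]`.
#' @return The updated predictor vector.
#' @export
update_taste_predictor <- function(k_hat, k_actual, alpha_khat) {
  k_hat <- as.numeric(k_hat); k_actual <- as.numeric(k_actual)
  .check(length(k_hat) == length(k_actual),
         "`k_hat` has %d dimensions but `k_actual` has %d",
         length(k_hat), length(k_actual))
  .check(all(is.finite(k_hat)) && all(is.finite(k_actual)),
         "predictor and intake vectors must be finite")
  .check(is.numeric(alpha_khat) && length(alpha_khat) == 1 &&
           alpha_khat > 0 && alpha_khat <= 1,
         "`alpha_khat` must lie in (0, 1]")
  k_hat + alpha_khat * (k_actual - k_hat)
}
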