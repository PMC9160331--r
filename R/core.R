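# Homeostatic space: drive function, internal-state dynamics, drive-reduction
# reward.  Internal states are plain numeric vectors, one entry per
# physiological dimension (convention: dimension 1 = water, dimension 2 =
# sodium in two-dimensional experiments; single-dimension experiments use
# sodium only).

.check <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

#' Drive-function parameters
#'
#' The drive function measures the distance of the internal state `H` from
#' the ideal point (setpoint) `H*` of the homeostatic space,
#' \deqn{D(H) = \left(\sum_i |H^*_i - H_i|^{n}\right)^{1/m},}
#' with free exponents `n` and `m` shaping the geometry of the space.  The
#' defaults `n = 4`, `m = 3` are the values used throughout the shipped
#' experiment configurations; they make the space markedly more sensitive
#' to large deviations than to small ones, so overshoot far beyond the
#' setpoint is punished much more strongly than a small surplus.
#'
#' @param setpoint Numeric vector, the ideal internal state `H*`, one entry
#'   per dimension (abstract internal-state units).
#' @param exponent_n Positive real, exponent applied to each per-dimension
#'   deviation.
#' @param exponent_m Positive real, root applied to the summed deviations.
#' @return An object of class `hrl_drive_params`.
#' @examples
#' dp <- drive_params(setpoint = 50)
#' drive(0, dp)
#' @seealso [drive()], [drive_reward()]
#' @export
drive_params <- function(setpoint, exponent_n = 4, exponent_m = 3) {
  setpoint <- as.numeric(setpoint)
  .check(length(setpoint) >= 1 && all(is.finite(setpoint)),
         "`setpoint` must be a non-empty finite numeric vector")
  .check(is.numeric(exponent_n) && length(exponent_n) == 1 && exponent_n > 0,
         "`exponent_n` must be a single positive number")
  .check(is.numeric(exponent_m) && length(exponent_m) == 1 && exponent_m > 0,
         "`exponent_m` must be a single positive number")
  structure(list(setpoint = setpoint,
                 exponent_n = as.numeric(exponent_n),
                 exponent_m = as.numeric(exponent_m)),
            class = "hrl_drive_params")
}

#' Temporal decay parameters
#'
#' Natural loss of each internal-state dimension: one trial multiplies
#' dimension `i` by `(1 - 1/tau_i)`.  `tau = 1` means total loss in a
#' single trial; `tau < 1` would flip the sign of the state every trial and
#' is rejected.
#'
#' @param tau Numeric vector of decay constants, one per dimension, in
#'   trials; every entry must be `>= 1`.
#' @return An object of class `hrl_decay_params`.
#' @export
decay_params <- function(tau) {
  tau <- as.numeric(tau)
  .check(length(tau) >= 1 && all(is.finite(tau)),
         "`tau` must be a non-empty finite numeric vector")
  .check(all(tau >= 1), "every decay constant `tau` must be >= 1")
  structure(list(tau = tau), class = "hrl_decay_params")
}

# internal fast path shared by drive() and the agent loop
.drive <- function(state, setpoint, n, m) {
  sum(abs(setpoint - state)^n)^(1 / m)
}

#' Drive: distance of the internal state from the setpoint
#'
#' @param state Numeric vector, the internal state `H` (same length as the
#'   setpoint).
#' @param params A [drive_params()] object.
#' @return A single nonnegative number; zero exactly when `state` equals
#'   the setpoint.
#' @examples
#' dp <- drive_params(setpoint = 50, exponent_n = 4, exponent_m = 3)
#' drive(0, dp)   # (50^4)^(1/3)
#' drive(50, dp)  # 0
#' @export
drive <- function(state, params) {
  stopifnot(inherits(params, "hrl_drive_params"))
  state <- as.numeric(state)
  .check(length(state) == length(params$setpoint),
         "internal state has %d dimensions but the setpoint has %d",
         length(state), length(params$setpoint))
  .check(all(is.finite(state)), "internal state must be finite")
  .drive(state, params$setpoint, params$exponent_n, params$exponent_m)
}

#' Apply one trial of natural decay to an internal state
#'
#' Each dimension is multiplied by `(1 - 1/tau_i)`; the magnitude of the
#' state never increases.
#'
#' @param state Numeric internal-state vector.
#' @param decay A [decay_params()] object with the same number of
#'   dimensions.
#' @return The decayed internal state.
#' @export
decay_state <- function(state, decay) {
  stopifnot(inherits(decay, "hrl_decay_params"))
  state <- as.numeric(state)
  .check(length(state) == length(decay$tau),
         "internal state has %d dimensions but `tau` has %d",
         length(state), length(decay$tau))
  .check(all(is.finite(state)), "internal state must be finite")
  (1 - 1 / decay$tau) * state
}

#' One-trial state transition: decay then intake
#'
#' Decay is applied first and the intake vector is added afterwards,
#' `H' = (1 - 1/tau) H + K`.  This transition runs on every trial,
#' including do-nothing trials (where `K` is the zero vector).
#'
#' @param state Numeric internal-state vector.
#' @param intake Numeric intake vector `K` (componentwise `>= 0`), same
#'   length as `state`.
#' @param decay A [decay_params()] object.
#' @return The next internal state.
#' @export
next_state <- function(state, intake, decay) {
  intake <- as.numeric(intake)
  .check(length(intake) == length(as.numeric(state)),
         "intake vector has %d dimensions but the state has %d",
         length(intake), length(state))
  .check(all(is.finite(intake)), "intake vector must be finite")
  decay_state(state, decay) + intake
}

#' Drive-reduction reward for one transition
#'
#' Reward is the change in drive across the transition,
#' `r(H, K) = D(H) - D((1 - 1/tau) H + K)`: positive when the transition
#' brings the state closer to the setpoint, negative (a punishment) when it
#' moves it farther away.  The same operation serves both the
#' actual-intake reward (pass the action's true intake `K`) and the
#' taste-predicted reward (pass the learned predictor `K-hat`, optionally
#' plus an ambient oral stimulus); only the caller's choice of vector
#' differs.
#'
#' @param state Numeric internal-state vector before the transition.
#' @param intake Intake (or predicted-intake) vector entering the reward.
#' @param drive_p A [drive_params()] object.
#' @param decay A [decay_params()] object.
#' @return A single real reward value.
#' @examples
#' dp <- drive_params(50); dc <- decay_params(10)
#' drive_reward(0, 50, dp, dc)  # from empty to the setpoint: +D(0)
#' @export
drive_reward <- function(state, intake, drive_p, decay) {
  drive(state, drive_p) - drive(next_state(state, intake, decay), drive_p)
}
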