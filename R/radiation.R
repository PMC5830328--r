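#' Surviving fraction of proliferating tumor cells after one radiation fraction
#'
#' Single-parameter (linear) cell-survival model: `exp(-alpha * dose)`. The
#' complementary fraction of the proliferating volume is transferred to the
#' radiation-damaged, non-proliferating compartment at the fraction time. The
#' quadratic term of the classical linear-quadratic model is not carried
#' (fractions are restricted to <= 10 Gy, where the linear component
#' dominates the calibrated effect).
#'
#' @param dose radiation dose in Gy, >= 0 (vectorized).
#' @param params a [model_params()] record (uses `alpha`).
#' @return Surviving fraction(s) in (0, 1].
#' @export
#' @examples
#' surviving_fraction(2, model_params())  # exp(-0.292)
surviving_fraction <- function(dose, params) {
  stopifnot(inherits(params, "model_params"))
  if (any(dose < 0)) stop("surviving_fraction: dose must be >= 0 Gy", call. = FALSE)
  exp(-params$alpha * dose)
}

#' Apply one radiation fraction to a system state
#'
#' Instantaneous transformation at the fraction time: the non-surviving share
#' of `TV` moves to `TV_d` (total volume is conserved exactly) and the mean
#' double-strand-break load rises by `delta * dose`. All other components are
#' unchanged. Between fractions, `TV_d` is cleared at rate `mu` and DSB repair
#' proceeds at rate `1/tau` (handled by the ODE right-hand side).
#'
#' @param state named numeric state vector (see [initial_state()]).
#' @param dose dose in Gy, must lie in (0, 10].
#' @param params a [model_params()] record.
#' @return Transformed state vector.
#' @export
#' @examples
#' s <- initial_state(TV = 100)
#' apply_fraction(s, 2, model_params())
apply_fraction <- function(state, dose, params) {
  stopifnot(inherits(params, "model_params"))
  if (length(dose) != 1 || !is.finite(dose) || dose <= 0 || dose > 10) {
    stop("apply_fraction: dose must be a single value in (0, 10] Gy", call. = FALSE)
  }
  .check_state(state)
  sf <- surviving_fraction(dose, params)
  killed <- state[["TV"]] * (1 - sf)
  state[["TV"]] <- state[["TV"]] - killed
  state[["TV_d"]] <- state[["TV_d"]] + killed
  state[["DSB"]] <- state[["DSB"]] + params$delta * dose
  state
}
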