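#' Sample virtual individuals (random effect on S_L)
#'
#' Draws individual infiltration parameters `S_L_i = S_L_pop * exp(eta_i)`,
#' `eta_i ~ Normal(0, omega_SL^2)`. Draws are deterministic given the seed
#' and do not disturb the caller's RNG state.
#'
#' @param n number of individuals (>= 1).
#' @param iav an [iav_params()] record.
#' @param seed integer seed.
#' @return Numeric vector of `n` individual S_L values (RU).
#' @export
#' @examples
#' sample_individuals(5, iav_params(), seed = 1)
sample_individuals <- function(n, iav = iav_params(), seed = 1) {
  stopifnot(inherits(iav, "iav_params"))
  if (n < 1) stop("sample_individuals: n must be >= 1", call. = FALSE)
  eta <- .with_seed(seed, stats::rnorm(n, 0, iav$omega_SL))
  iav$S_L_pop * exp(eta)
}

#' Apply the residual-error model to predicted tumor volumes
#'
#' Adds measurement noise to model-predicted volumes. Under the default
#' combined model the SD is `sqrt(a_err^2 + (b_err * y)^2)`; the alternative
#' `"additive_sd"` form uses `a_err + b_err * y`. Negative perturbed values
#' are floored at zero; the number of floored observations is recorded in the
#' `"n_floored"` attribute.
#'
#' @param y_pred predicted volumes (uL), >= 0 (vectorized).
#' @param iav an [iav_params()] record.
#' @param seed integer seed (or `NULL` to use the current RNG state).
#' @return Observed volumes with attribute `n_floored`.
#' @export
#' @examples
#' apply_residual_error(c(0, 100, 1000), iav_params(), seed = 7)
apply_residual_error <- function(y_pred, iav = iav_params(), seed = NULL) {
  stopifnot(inherits(iav, "iav_params"))
  if (any(y_pred < 0)) {
    stop("apply_residual_error: y_pred must be >= 0", call. = FALSE)
  }
  sd <- residual_sd(y_pred, iav)
  draw <- function() stats::rnorm(length(y_pred), 0, 1)
  z <- if (is.null(seed)) draw() else .with_seed(seed, draw())
  y <- y_pred + sd * z
  n_floored <- sum(y < 0)
  y[y < 0] <- 0
  attr(y, "n_floored") <- n_floored
  y
}

#' Residual-error standard deviation at a predicted volume
#'
#' @param y_pred predicted volumes (uL).
#' @param iav an [iav_params()] record.
#' @return SD of the observation error at each prediction.
#' @export
residual_sd <- function(y_pred, iav = iav_params()) {
  stopifnot(inherits(iav, "iav_params"))
  if (iav$error_model == "additive_variance") {
    sqrt(iav$a_err^2 + (iav$b_err * y_pred)^2)
  } else {
    iav$a_err + iav$b_err * y_pred
  }
}

# run code with a local, restored RNG state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Draw a perturbed parameter set from estimation uncertainty
#'
#' Lognormal perturbation of the estimated parameters using their relative
#' standard errors as coefficients of variation (see [param_rse()]). Used by
#' the virtual-trial engine to propagate parameter uncertainty across
#' studies.
#'
#' @param params a [model_params()] record (the point estimates).
#' @param iav an [iav_params()] record.
#' @param seed integer seed.
#' @return List with perturbed `params` and `iav` records.
#' @export
perturb_params <- function(params = model_params(), iav = iav_params(), seed = 1) {
  stopifnot(inherits(params, "model_params"), inherits(iav, "iav_params"))
  rse <- param_rse() / 100
  z <- .with_seed(seed, stats::rnorm(length(rse)))
  fac <- stats::setNames(exp(rse * z - rse^2 / 2), names(rse))
  pl <- unclass(params)
  for (nm in c("k_LN", "S_L", "K_pdl", "S_R", "alpha")) pl[[nm]] <- pl[[nm]] * fac[[nm]]
  il <- unclass(iav)
  il$S_L_pop <- il$S_L_pop * fac[["S_L"]]
  il$omega_SL <- il$omega_SL * fac[["omega_SL"]]
  il$a_err <- il$a_err * fac[["a_err"]]
  il$b_err <- il$b_err * fac[["b_err"]]
  list(params = do.call(model_params, pl), iav = do.call(iav_params, il))
}
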