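#' Model parameters for the cancer-immunity-cycle simulator
#'
#' Constructs the full fixed-effect parameter record of the tumor-immune ODE
#' system, radiation effect and immuno-suppression axes. Defaults are the
#' published CT26 calibration values; the reconstruction constants
#' (`w_pdl`, `k_dcm_decay`, `k_ag`, `q_ag`, `k_isc`, `h_isc`, `c_apo`) were
#' calibrated once against the behavioral anchors of the model (see the
#' methods vignette and `scripts/calibrate.R`) and are frozen here.
#'
#' @param ... named overrides of any default value, e.g. `model_params(r = 0.5)`.
#'   Unknown names are rejected.
#'
#' @return An object of class `model_params`: a named list with elements
#' \describe{
#'   \item{r}{tumor growth rate, 1/day}
#'   \item{TV_max}{carrying capacity of the tumor, uL}
#'   \item{d0}{spontaneous tumor-cell death rate, 1/day}
#'   \item{k_LN}{maximal influx rate of naive effector precursors, cells/day}
#'   \item{S_L}{half-saturation of T-cell infiltration vs systemic antigen, RU
#'     (smaller values mean stronger infiltration)}
#'   \item{k_pro, k_dif, k_el}{naive-effector proliferation / differentiation /
#'     elimination rate constants, 1/day}
#'   \item{k_apo}{effector apoptosis rate constant, 1/day}
#'   \item{e}{tumor-cell kill rate per effector cell, 1/(day cell)}
#'   \item{K_pdl}{half-saturation of PD-L1 up-regulation vs effector count, cells}
#'   \item{k_pdl}{PD-L1 relaxation rate, 1/day}
#'   \item{K_tcd}{half-saturation of the DC-maturation stimulus vs the
#'     specific tumor-cell death rate TCD/(TV+TV_d), 1/day}
#'   \item{S_R}{half-saturation of suppressive-cell accumulation vs systemic
#'     antigen, RU}
#'   \item{alpha}{linear component of the radiation effect, 1/Gy}
#'   \item{delta}{DNA double-strand breaks formed per cell per Gy}
#'   \item{tau}{DSB repair time constant, days}
#'   \item{mu}{elimination rate of radiation-damaged tumor cells, 1/day}
#'   \item{w_pdl}{weight of the PD-L1 axis within total immuno-suppression,
#'     dimensionless in \[0, 1\]}
#'   \item{k_dcm_decay}{relaxation rate of the mature-DC level, 1/day}
#'   \item{k_ag}{turnover rate of systemic antigen, 1/day}
#'   \item{q_ag}{antigen presentation capacity: steady-state systemic antigen
#'     (RU) per uL of tumor at full DC maturation}
#'   \item{c_apo}{exhaustion steepness: effector apoptosis runs at
#'     `k_apo * (1 + c_apo * (1 - IAR))`, accelerating as activation falls}
#'   \item{h_isc}{Hill coefficient of suppressive-cell recruitment vs
#'     systemic antigen (cooperative accumulation)}
#'   \item{k_isc}{turnover rate of the suppressive-cell level, 1/day}
#' }
#' @export
#' @examples
#' p <- model_params()
#' p$alpha
#' model_params(S_L = 1.77)$S_L
model_params <- function(...) {
  defaults <- list(
    r        = 0.4,
    TV_max   = 2500,
    d0       = 0.01,
    k_LN     = 279,
    S_L      = 8.89,
    k_pro    = 3.0,
    k_dif    = 3.2,
    k_el     = 0.2,
    k_apo    = 2.0,
    e        = 0.001,
    K_pdl    = 478,
    k_pdl    = 1.0,
    K_tcd    = 0.2,
    S_R      = 30.5,
    alpha    = 0.146,
    delta    = 19,
    tau      = 0.02,
    mu       = 0.1725,
    # reconstruction constants (calibrated once, frozen; see vignette)
    w_pdl       = 0.25,
    k_dcm_decay = 1.0,
    k_ag        = 1.0,
    q_ag        = 9.0,
    k_isc       = 0.7,
    h_isc       = 2.0,
    c_apo       = 3.0
  )
  p <- .merge_params(defaults, list(...), "model_params")
  validate_model_params(p)
  structure(p, class = "model_params")
}

#' Pharmacokinetic parameters for the anti-PD-(L)1 antibody
#'
#' One-compartment intraperitoneal depot model with first-order absorption and
#' elimination. PD-1- and PD-L1-directed antibodies share this model.
#' `mw_mab` and `body_weight` are standard-mouse constants used to convert
#' mg/kg doses into nanomoles; both are exposed so their influence can be
#' examined.
#'
#' @param ... named overrides of the defaults. Unknown names are rejected.
#' @return An object of class `pk_params` with elements `V_d` (distribution
#'   volume, L), `k_a` (absorption rate, 1/day), `kel_mAB` (elimination rate,
#'   1/day), `K_D` (binding affinity, nM), `mw_mab` (antibody molecular
#'   weight, g/mol) and `body_weight` (kg).
#' @export
#' @examples
#' pk_params()$K_D
pk_params <- function(...) {
  defaults <- list(
    V_d         = 0.003,
    k_a         = 8.0,
    kel_mAB     = 0.15,
    K_D         = 30,
    mw_mab      = 150000,
    body_weight = 0.020
  )
  p <- .merge_params(defaults, list(...), "pk_params")
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1))]
  if (length(bad)) {
    stop("pk_params: all parameters must be positive finite scalars; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(p, class = "pk_params")
}

#' Inter-animal-variability and residual-error parameters
#'
#' The single random effect of the population model acts on the infiltration
#' parameter `S_L`: individual values are `S_L_pop * exp(eta)` with
#' `eta ~ Normal(0, omega_SL^2)`. The residual error on observed tumor volume
#' combines an additive and a proportional component.
#'
#' @param ... named overrides of the defaults. Unknown names are rejected.
#' @return An object of class `iav_params` with elements `S_L_pop` (RU),
#'   `omega_SL` (SD of log S_L), `a_err` (additive residual SD, uL), `b_err`
#'   (proportional residual component) and `error_model`, one of
#'   `"additive_variance"` (SD = sqrt(a^2 + (b y)^2), the default) or
#'   `"additive_sd"` (SD = a + b y).
#' @export
#' @examples
#' iav_params(omega_SL = 0)$omega_SL
iav_params <- function(...) {
  defaults <- list(
    S_L_pop  = 8.89,
    omega_SL = 0.696,
    a_err    = 21.2,
    b_err    = 0.176,
    error_model = "additive_variance"
  )
  p <- .merge_params(defaults, list(...), "iav_params")
  num <- c("S_L_pop", "omega_SL", "a_err", "b_err")
  bad <- num[!vapply(p[num], function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0, logical(1))]
  if (length(bad)) {
    stop("iav_params: parameters must be non-negative finite scalars; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (p$S_L_pop <= 0) stop("iav_params: S_L_pop must be > 0", call. = FALSE)
  p$error_model <- match.arg(p$error_model, c("additive_variance", "additive_sd"))
  structure(p, class = "iav_params")
}

#' Relative standard errors of the estimated parameters
#'
#' RSE percentages reported for the parameters estimated from tumor growth
#' data, used by the virtual-trial engine to propagate parameter uncertainty
#' (lognormal draws with CV = RSE/100).
#'
#' @return Named numeric vector of RSE percentages.
#' @export
param_rse <- function() {
  c(k_LN = 8, S_L = 13, omega_SL = 10, K_pdl = 23, S_R = 12, alpha = 9,
    a_err = 13, b_err = 10)
}

validate_model_params <- function(p) {
  num_ok <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))
  if (!all(num_ok)) {
    stop("model_params: all parameters must be finite numeric scalars; offending: ",
         paste(names(p)[!num_ok], collapse = ", "), call. = FALSE)
  }
  neg <- names(p)[unlist(p) < 0]
  if (length(neg)) {
    stop("model_params: all rates and constants must be >= 0; offending: ",
         paste(neg, collapse = ", "), call. = FALSE)
  }
  if (p$TV_max <= 0) stop("model_params: TV_max must be > 0", call. = FALSE)
  if (p$w_pdl > 1) stop("model_params: w_pdl must lie in [0, 1]", call. = FALSE)
  if (p$tau <= 0) stop("model_params: tau must be > 0", call. = FALSE)
  invisible(p)
}

.merge_params <- function(defaults, overrides, what) {
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == "")) {
      stop(what, ": all overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown)) {
      stop(what, ": unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    defaults[nm] <- overrides
  }
  defaults
}

#' Write a parameter set to a flat key-value file
#'
#' Serializes a `model_params`, `pk_params` or `iav_params` record (or a plain
#' named list combining them) to JSON or YAML, one key per parameter symbol.
#'
#' @param params parameter record to write.
#' @param path output file; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  x <- unclass(params)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else {
    stop("write_params: unsupported extension '", ext, "' (use json or yaml)",
         call. = FALSE)
  }
  invisible(path)
}

#' Read a parameter set from a flat key-value file
#'
#' Inverse of [write_params()]. Keys must exactly match the parameter symbols
#' of the requested record type; unknown keys are rejected.
#'
#' @param path JSON or YAML file written by [write_params()] (or by hand).
#' @param type which constructor to route the values through: `"model"`,
#'   `"pk"` or `"iav"`.
#' @return A validated parameter object of the requested class.
#' @export
read_params <- function(path, type = c("model", "pk", "iav")) {
  type <- match.arg(type)
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("read_params: unsupported extension '", ext, "'", call. = FALSE)
  }
  ctor <- switch(type, model = model_params, pk = pk_params, iav = iav_params)
  do.call(ctor, as.list(x))
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> cancer-immunity-cycle parameters\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.pk_params <- function(x, ...) {
  cat("<pk_params> i.p. antibody one-compartment model\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.iav_params <- function(x, ...) {
  cat("<iav_params> lognormal random effect on S_L + residual error (",
      x$error_model, ")\n", sep = "")
  print(unlist(unclass(x)[c("S_L_pop", "omega_SL", "a_err", "b_err")]))
  invisible(x)
}
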