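#' Plasma antibody concentration after intraperitoneal dosing
#'
#' Closed-form solution of the one-compartment depot model
#' `dA/dt = -k_a A`, `dC/dt = k_a A / V_d - kel_mAB C`, superposed over all
#' doses (the model is linear). Each dose adds
#' `mg_per_kg * body_weight / mw_mab` nanomoles to the depot at its dose time.
#'
#' @param t time(s) in days post-inoculation (vectorized).
#' @param doses data frame with columns `day` and `mg_per_kg` (e.g. the `mab`
#'   element of a [treatment_schedule()]); `NULL` or empty means no dosing.
#' @param pk a [pk_params()] record.
#' @return Plasma concentration in nM at each `t`; 0 before the first dose.
#' @export
#' @examples
#' pk <- pk_params()
#' mab_concentration(c(7, 7.5, 9), mab_regimen_3qw(7), pk)
mab_concentration <- function(t, doses, pk) {
  stopifnot(inherits(pk, "pk_params"))
  if (any(t < 0)) stop("mab_concentration: t must be >= 0", call. = FALSE)
  out <- numeric(length(t))
  if (is.null(doses) || nrow(doses) == 0) return(out)
  # mg -> nmol: mg * 1e-3 g / (g/mol) * 1e9 nmol/mol
  amt_nmol <- doses$mg_per_kg * pk$body_weight / pk$mw_mab * 1e6
  ka <- pk$k_a
  ke <- pk$kel_mAB
  for (i in seq_len(nrow(doses))) {
    dt <- t - doses$day[i]
    on <- dt >= 0
    if (!any(on)) next
    out[on] <- out[on] + .bateman(dt[on], amt_nmol[i], ka, ke, pk$V_d)
  }
  out
}

.bateman <- function(dt, amt_nmol, ka, ke, vd) {
  if (abs(ka - ke) < 1e-10) {
    # repeated-eigenvalue limit
    amt_nmol * ka * dt * exp(-ka * dt) / vd
  } else {
    amt_nmol * ka / (vd * (ka - ke)) * (exp(-ke * dt) - exp(-ka * dt))
  }
}

#' Receptor occupancy of the PD-1/PD-L1 axis
#'
#' Fraction of the axis blocked by the antibody at plasma concentration `C`:
#' `C / (C + K_D)`, a value in \[0, 1).
#'
#' @param C concentration(s) in nM; must be >= 0.
#' @param pk a [pk_params()] record (uses `K_D`).
#' @return Occupancy fraction(s).
#' @export
#' @examples
#' receptor_occupancy(30, pk_params())  # 0.5 at K_D
receptor_occupancy <- function(C, pk) {
  stopifnot(inherits(pk, "pk_params"))
  if (any(C < 0)) stop("receptor_occupancy: concentration must be >= 0", call. = FALSE)
  C / (C + pk$K_D)
}

#' Occupancy over time for a schedule
#'
#' Convenience composition of [mab_concentration()] and
#' [receptor_occupancy()].
#'
#' @inheritParams mab_concentration
#' @return Occupancy fraction at each `t`.
#' @export
occupancy_at <- function(t, doses, pk) {
  receptor_occupancy(mab_concentration(t, doses, pk), pk)
}
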