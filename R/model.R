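#' State variable names of the cancer-immunity-cycle system
#'
#' The nine dynamic quantities, in canonical order: `TV` (proliferating tumor
#' volume, uL), `TV_d` (radiation-damaged non-proliferating volume, uL),
#' `DSB` (mean unrepaired double-strand breaks per cell), `DC_m` (mature
#' dendritic-cell level, RU in \[0, 1\]), `Ag_sys` (systemic tumor-antigen
#' level, RU), `nTeff` (non-differentiated effector precursors in tumor,
#' cells), `dTeff` (cytotoxic effectors in tumor, cells), `ISC`
#' (immuno-suppressive cell level, RU in \[0, 1\]) and `PDL1` (normalized
#' PD-L1 expression, RU in \[0, 1\]).
#'
#' @return Character vector of state names.
#' @export
state_names <- function() {
  c("TV", "TV_d", "DSB", "DC_m", "Ag_sys", "nTeff", "dTeff", "ISC", "PDL1")
}

#' Initial system state at tumor-cell inoculation
#'
#' Simulation time 0 is the inoculation of 5e5 tumor cells, taken as 0.5 uL
#' at 1e6 cells/uL. All immune states start at zero: the immune response is
#' driven entirely by tumor-cell death.
#'
#' @param TV initial proliferating tumor volume, uL.
#' @param ... overrides for other state components (rarely needed).
#' @return Named numeric vector over [state_names()].
#' @export
#' @examples
#' initial_state()
initial_state <- function(TV = 0.5, ...) {
  s <- stats::setNames(numeric(9), state_names())
  s[["TV"]] <- TV
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), state_names())
    if (length(unknown)) {
      stop("initial_state: unknown state component(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    s[names(dots)] <- unlist(dots)
  }
  .check_state(s)
  s
}

.check_state <- function(state) {
  if (!is.numeric(state) || is.null(names(state)) ||
      !all(state_names() %in% names(state))) {
    stop("state must be a named numeric vector with components ",
         paste(state_names(), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(state[state_names()]))) {
    stop("state contains non-finite components", call. = FALSE)
  }
  if (any(state[state_names()] < 0)) {
    bad <- state_names()[state[state_names()] < 0]
    stop("negative state component(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(state)
}

# Vectorized driving-function kernel. All suppression components live on a
# unit scale; IAR multiplies them complementarily.
.driving <- function(TV, TV_d, dTeff, ISC, PDL1, occupancy, p) {
  TCD <- p$d0 * TV + p$e * dTeff * TV + p$mu * TV_d
  supp_pdl <- p$w_pdl * PDL1 * (1 - occupancy)
  supp_isc <- pmin(pmax(ISC, 0), 1)
  IAR <- (1 - supp_pdl) * (1 - supp_isc)
  list(TCD = TCD, IAR = IAR, supp_pdl = supp_pdl, supp_isc = supp_isc)
}

#' Driving functions of the immune response
#'
#' Computes, for one system state, the total tumor-cell death rate `TCD`
#' (spontaneous death + effector kill + clearance of radiation-damaged
#' cells), the two suppression components and the immune activation rate
#' `IAR = (1 - supp_pdl) * (1 - supp_isc)`. The PD-L1 component is
#' `w_pdl * PDL1 * (1 - occupancy)`, so full receptor occupancy removes that
#' axis entirely; the cellular component saturates with the suppressive-cell
#' level.
#'
#' @param state named numeric state vector; all components must be >= 0.
#' @param occupancy fraction of the PD-1/PD-L1 axis blocked, in \[0, 1\].
#' @param params a [model_params()] record.
#' @return List with elements `TCD` (uL/day), `IAR`, `supp_pdl`, `supp_isc`
#'   (all dimensionless in \[0, 1\] except TCD).
#' @export
#' @examples
#' compute_driving(initial_state(), occupancy = 0, model_params())
compute_driving <- function(state, occupancy, params) {
  stopifnot(inherits(params, "model_params"))
  .check_state(state)
  if (occupancy < 0 || occupancy > 1) {
    stop("compute_driving: occupancy must lie in [0, 1]", call. = FALSE)
  }
  .driving(state[["TV"]], state[["TV_d"]], state[["dTeff"]], state[["ISC"]],
           state[["PDL1"]], occupancy, params)
}

#' Right-hand side of the cancer-immunity-cycle ODE system
#'
#' Time-derivatives of the nine state variables. Tumor growth is logistic in
#' total volume with spontaneous death and effector kill; damaged cells are
#' cleared at rate `mu`; DSB repair at rate `1/tau`; mature DCs relax toward a
#' first-order Hill function of the *specific* death rate `TCD/(TV + TV_d)`
#' (units 1/day, the scale of `K_tcd`); systemic antigen relaxes toward
#' `q_ag * DC_m * TV`; precursor influx, proliferation and differentiation
#' are gated by IAR; effector apoptosis accelerates as IAR falls (rate
#' `k_apo * (1 + c_apo * (1 - IAR))`); suppressive cells relax toward a
#' cooperative (Hill-2) function of antigen; PD-L1 relaxes toward a Hill
#' function of the effector count.
#'
#' @param t time in days (unused directly; kept for solver compatibility).
#' @param state named numeric state vector.
#' @param params a [model_params()] record.
#' @param occupancy PD-1/PD-L1 axis occupancy at `t`, in \[0, 1\].
#' @param k_LN_scale multiplier on effector influx (0 under CD8 depletion).
#' @return Named numeric vector of derivatives, same order as the state.
#' @export
cic_rhs <- function(t, state, params, occupancy = 0, k_LN_scale = 1) {
  stopifnot(inherits(params, "model_params"))
  .check_state(state)
  d <- .rhs_core(state[state_names()], params, occupancy, k_LN_scale)
  if (any(!is.finite(d))) {
    bad <- state_names()[!is.finite(d)]
    stop("cic_rhs: non-finite derivative for component(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  stats::setNames(d, state_names())
}

# Unchecked numeric kernel used by the integrator. `y` in state_names() order.
# The DC-maturation stimulus uses the *specific* tumor-cell death rate
# (total death flux per unit tumor volume, 1/day), the scale on which K_tcd
# is expressed; spontaneous death alone (d0) stimulates little, a radiation
# fraction a lot.
.rhs_core <- function(y, p, occ, k_LN_scale) {
  TV <- y[1]; TV_d <- y[2]; DSB <- y[3]; DC_m <- y[4]; Ag <- y[5]
  nT <- y[6]; dT <- y[7]; ISC <- y[8]; PDL1 <- y[9]

  TV_tot <- TV + TV_d
  TCD <- p$d0 * TV + p$e * dT * TV + p$mu * TV_d
  tcd_spec <- if (TV_tot > 0) TCD / TV_tot else 0
  supp_pdl <- p$w_pdl * PDL1 * (1 - occ)
  supp_isc <- min(max(ISC, 0), 1)
  IAR <- (1 - supp_pdl) * (1 - supp_isc)

  influx <- k_LN_scale * p$k_LN * Ag / (Ag + p$S_L)

  c(
    p$r * TV * (1 - TV_tot / p$TV_max) - p$d0 * TV - p$e * dT * TV, # TV
    -p$mu * TV_d,                                                   # TV_d
    -DSB / p$tau,                                                   # DSB
    p$k_dcm_decay * (tcd_spec / (tcd_spec + p$K_tcd) - DC_m),       # DC_m
    p$k_ag * (p$q_ag * DC_m * TV - Ag),                             # Ag_sys
    IAR * (influx + (p$k_pro - p$k_dif) * nT) - p$k_el * nT,        # nTeff
    p$k_dif * IAR * nT - p$k_apo * (1 + p$c_apo * (1 - IAR)) * dT,  # dTeff
    p$k_isc * (Ag^p$h_isc / (Ag^p$h_isc + p$S_R^p$h_isc) - ISC),    # ISC
    p$k_pdl * (dT / (dT + p$K_pdl) - PDL1)                          # PDL1
  )
}

#' Simulate one individual under a treatment schedule
#'
#' Integrates the cancer-immunity-cycle system from inoculation to `t_end`
#' with a stiff-capable adaptive solver (lsoda). Integration is restarted at
#' every discrete event (radiation fraction, antibody dose, CD8-depletion
#' switch) so that bolus effects are reproducible; radiation fractions are
#' applied as instantaneous state transformations before any same-time
#' antibody dose takes effect. Antibody exposure enters through the
#' closed-form plasma concentration, converted to receptor occupancy.
#'
#' @param params a [model_params()] record.
#' @param schedule a [treatment_schedule()]; events must lie in `[0, t_end]`.
#' @param S_L individual infiltration parameter (RU); defaults to the
#'   population value in `params`.
#' @param pk a [pk_params()] record.
#' @param t_end end of simulation, days post-inoculation.
#' @param dt output grid spacing, days.
#' @param rtol,atol solver tolerances.
#' @param init initial state (default [initial_state()]).
#' @return An object of class `trajectory`: a list with `data` (tibble of
#'   time, the nine states, `TV_tot`, `occupancy` and the driving functions
#'   `TCD`, `IAR`, `supp_pdl`, `supp_isc`), plus the schedule and parameters
#'   used.
#' @export
#' @examples
#' traj <- simulate_individual(t_end = 30, dt = 0.5)
#' head(traj$data)
simulate_individual <- function(params = model_params(),
                                schedule = treatment_schedule(),
                                S_L = params$S_L,
                                pk = pk_params(),
                                t_end = 60,
                                dt = 0.1,
                                rtol = 1e-8,
                                atol = 1e-10,
                                init = initial_state()) {
  stopifnot(inherits(params, "model_params"), inherits(pk, "pk_params"),
            inherits(schedule, "treatment_schedule"))
  if (!is.finite(S_L) || S_L <= 0) {
    stop("simulate_individual: S_L must be a positive number", call. = FALSE)
  }
  p <- unclass(params)
  p$S_L <- S_L

  ev_days <- c(schedule$rt$day, schedule$mab$day, schedule$cd8_depletion_day)
  ev_days <- ev_days[is.finite(ev_days)]
  if (any(ev_days > t_end)) {
    stop("simulate_individual: schedule events must lie within [0, t_end]",
         call. = FALSE)
  }

  grid <- sort(unique(c(seq(0, t_end, by = dt), t_end, ev_days)))
  breaks <- sort(unique(c(0, ev_days, t_end)))

  doses <- schedule$mab
  occ_fun <- if (!is.null(doses) && nrow(doses) > 0) {
    amt <- doses$mg_per_kg * pk$body_weight / pk$mw_mab * 1e6
    dday <- doses$day
    ka <- pk$k_a; ke <- pk$kel_mAB; vd <- pk$V_d; kd <- pk$K_D
    function(t) {
      dtv <- t - dday
      on <- dtv >= 0
      if (!any(on)) return(0)
      C <- sum(amt[on] * ka / (vd * (ka - ke)) *
                 (exp(-ke * dtv[on]) - exp(-ka * dtv[on])))
      C / (C + kd)
    }
  } else {
    function(t) 0
  }

  dep_day <- schedule$cd8_depletion_day
  neg_tol <- max(100 * atol, 1e-8)

  # unpack parameters once; the rhs closure below avoids per-call list lookups
  r <- p$r; TV_max <- p$TV_max; d0 <- p$d0; k_LN <- p$k_LN; S_Lv <- p$S_L
  k_pro <- p$k_pro; k_dif <- p$k_dif; k_el <- p$k_el; k_apo <- p$k_apo
  e_kill <- p$e; K_pdl <- p$K_pdl; k_pdl <- p$k_pdl; K_tcd <- p$K_tcd
  S_R <- p$S_R; tau <- p$tau; mu <- p$mu; w_pdl <- p$w_pdl
  k_dcm_decay <- p$k_dcm_decay; k_ag <- p$k_ag; q_ag <- p$q_ag
  k_isc <- p$k_isc; c_apo <- p$c_apo; h_isc <- p$h_isc; S_Rh <- S_R^h_isc

  y <- init[state_names()]
  rows <- list()
  for (k in seq_len(length(breaks) - 1)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1]
    # radiation fractions scheduled at the segment start
    frs <- schedule$rt[schedule$rt$day == t0 & schedule$rt$gray > 0, , drop = FALSE]
    if (nrow(frs)) {
      for (g in frs$gray) y <- apply_fraction(y, g, params)
    }
    k_LN_eff <- if (!is.na(dep_day) && t0 >= dep_day) 0 else k_LN
    times <- grid[grid >= t0 & grid <= t1]
    if (length(times) < 2) times <- c(t0, t1)
    func <- function(t, yy, parms) {
      occ <- occ_fun(t)
      TV <- yy[1]; TV_d <- yy[2]
      dT <- yy[7]
      TV_tot <- TV + TV_d
      TCD <- d0 * TV + e_kill * dT * TV + mu * TV_d
      tcd_spec <- if (TV_tot > 0) TCD / TV_tot else 0
      ISCc <- min(max(yy[8], 0), 1)
      IAR <- (1 - w_pdl * yy[9] * (1 - occ)) * (1 - ISCc)
      Ag <- yy[5]
      influx <- k_LN_eff * Ag / (Ag + S_Lv)
      list(c(
        r * TV * (1 - TV_tot / TV_max) - d0 * TV - e_kill * dT * TV,
        -mu * TV_d,
        -yy[3] / tau,
        k_dcm_decay * (tcd_spec / (tcd_spec + K_tcd) - yy[4]),
        k_ag * (q_ag * yy[4] * TV - Ag),
        IAR * (influx + (k_pro - k_dif) * yy[6]) - k_el * yy[6],
        k_dif * IAR * yy[6] - k_apo * (1 + c_apo * (1 - IAR)) * dT,
        k_isc * (Ag^h_isc / (Ag^h_isc + S_Rh) - yy[8]),
        k_pdl * (dT / (dT + K_pdl) - yy[9])
      ))
    }
    sol <- deSolve::lsoda(y = y, times = times, func = func, parms = NULL,
                          rtol = rtol, atol = atol, maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0) {
      stop("simulate_individual: solver failed near t = ",
           signif(max(sol[, 1]), 6), " days", call. = FALSE)
    }
    m <- unname(sol[, -1, drop = FALSE])
    if (any(m < -neg_tol)) {
      stop("simulate_individual: negative-state excursion beyond tolerance in ",
           paste(state_names()[apply(m < -neg_tol, 2, any)], collapse = ", "),
           call. = FALSE)
    }
    m[m < 0] <- 0
    rows[[k]] <- cbind(time = sol[, 1], m)
    y <- stats::setNames(m[nrow(m), ], state_names())
  }

  out <- do.call(rbind, rows)
  # at event times keep the post-event row so the grid is strictly monotone
  out <- out[!duplicated(out[, "time"], fromLast = TRUE), , drop = FALSE]
  colnames(out) <- c("time", state_names())

  occ <- vapply(out[, "time"], occ_fun, numeric(1))
  drv <- .driving(out[, "TV"], out[, "TV_d"], out[, "dTeff"], out[, "ISC"],
                  out[, "PDL1"], occ, p)
  data <- tibble::as_tibble(as.data.frame(out))
  data$TV_tot <- data$TV + data$TV_d
  data$occupancy <- occ
  data$TCD <- drv$TCD
  data$IAR <- drv$IAR
  data$supp_pdl <- drv$supp_pdl
  data$supp_isc <- drv$supp_isc

  structure(list(data = data, schedule = schedule, params = params, pk = pk,
                 S_L = S_L, t_end = t_end,
                 solver = list(rtol = rtol, atol = atol, dt = dt)),
            class = "trajectory")
}

#' Interpolate a trajectory variable at arbitrary times
#'
#' Linear interpolation on the trajectory's output grid.
#'
#' @param traj a `trajectory`.
#' @param times times in days; must lie within the simulated range.
#' @param var variable name (state, `TV_tot`, or driving function).
#' @return Numeric vector of interpolated values.
#' @export
trajectory_at <- function(traj, times, var = "TV_tot") {
  stopifnot(inherits(traj, "trajectory"))
  tt <- traj$data$time
  if (any(times < min(tt) - 1e-9) || any(times > max(tt) + 1e-9)) {
    stop("trajectory_at: requested time outside simulated range [",
         signif(min(tt), 4), ", ", signif(max(tt), 4), "] days", call. = FALSE)
  }
  if (!var %in% names(traj$data)) {
    stop("trajectory_at: unknown variable '", var, "'", call. = FALSE)
  }
  stats::approx(tt, traj$data[[var]], xout = pmin(pmax(times, min(tt)), max(tt)),
                ties = "ordered")$y
}

.var_units <- function() {
  c(TV = "uL", TV_d = "uL", TV_tot = "uL", DSB = "breaks/cell", DC_m = "RU",
    Ag_sys = "RU", nTeff = "cells", dTeff = "cells", ISC = "RU", PDL1 = "RU",
    occupancy = "fraction", TCD = "uL/day", IAR = "fraction",
    supp_pdl = "fraction", supp_isc = "fraction")
}

#' Export a trajectory as tidy CSV
#'
#' One row per (time, variable) with columns `time_days`, `variable`,
#' `value`, `unit`.
#'
#' @param traj a `trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  units <- .var_units()
  vars <- setdiff(names(traj$data), "time")
  long <- do.call(rbind, lapply(vars, function(v) {
    data.frame(time_days = traj$data$time, variable = v,
               value = traj$data[[v]], unit = unname(units[v]))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", nrow(x$data), " points over [0, ", x$t_end,
      "] days, S_L = ", signif(x$S_L, 4), "\n", sep = "")
  cat("  final TV_tot: ", signif(x$data$TV_tot[nrow(x$data)], 4), " uL\n", sep = "")
  invisible(x)
}
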