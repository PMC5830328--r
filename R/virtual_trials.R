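#' Virtual-trial design
#'
#' Bundles a treatment schedule with the cohort structure, endpoint and seed
#' of a virtual experiment. The endpoint follows the complete-response
#' definition used throughout: total tumor volume at `eval_day` days after
#' treatment start at or below `threshold_mm3` (1 mm^3 = 1 uL).
#'
#' @param schedule a [treatment_schedule()].
#' @param n_animals animals per virtual study (default 100).
#' @param n_studies number of virtual studies (default 1000).
#' @param eval_day evaluation day, days post treatment start (default 50).
#' @param threshold_mm3 responder threshold, mm^3 (default 10; inclusive).
#' @param seed integer seed driving all sampling.
#' @param cd8_depleted if `TRUE`, CD8+ effector influx is abolished from
#'   treatment start (anti-CD8 co-treatment).
#' @param propagate_uncertainty if `TRUE`, each study draws a perturbed
#'   parameter set from the reported relative standard errors
#'   (see [perturb_params()]); if `FALSE` (default) studies differ only by
#'   the sampled individuals.
#' @return An object of class `trial_design`.
#' @export
#' @examples
#' trial_design(treatment_schedule(rt = rt_fractions("5x2", 7)),
#'              n_animals = 10, n_studies = 5)
trial_design <- function(schedule = treatment_schedule(),
                         n_animals = 100,
                         n_studies = 1000,
                         eval_day = 50,
                         threshold_mm3 = 10,
                         seed = 1,
                         cd8_depleted = FALSE,
                         propagate_uncertainty = FALSE) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  if (n_animals < 1 || n_studies < 1) {
    stop("trial_design: n_animals and n_studies must be >= 1", call. = FALSE)
  }
  if (threshold_mm3 <= 0) stop("trial_design: threshold must be > 0", call. = FALSE)
  if (cd8_depleted && is.na(schedule$cd8_depletion_day)) {
    schedule$cd8_depletion_day <- treatment_start(schedule)
  }
  structure(list(schedule = schedule, n_animals = as.integer(n_animals),
                 n_studies = as.integer(n_studies), eval_day = eval_day,
                 threshold_mm3 = threshold_mm3, seed = as.integer(seed),
                 cd8_depleted = cd8_depleted,
                 propagate_uncertainty = propagate_uncertainty),
            class = "trial_design")
}

#' Classify one trajectory as responder / non-responder
#'
#' A responder shows complete tumor response: total tumor volume at
#' `eval_day` days after treatment start at or below the threshold
#' (inclusive).
#'
#' @param traj a `trajectory` from [simulate_individual()].
#' @param design a [trial_design()] (uses `eval_day`, `threshold_mm3`).
#' @return Logical scalar.
#' @export
classify_responder <- function(traj, design) {
  stopifnot(inherits(traj, "trajectory"), inherits(design, "trial_design"))
  t_eval <- treatment_start(traj$schedule) + design$eval_day
  if (max(traj$data$time) < t_eval - 1e-9) {
    stop("classify_responder: trajectory ends at ", max(traj$data$time),
         " days but evaluation requires ", t_eval, " days", call. = FALSE)
  }
  trajectory_at(traj, t_eval, "TV_tot") <= design$threshold_mm3
}

# simulate + classify one individual; shared by threshold search and exact runs
.simulate_responder <- function(S_L, design, params, pk, sim_opts) {
  ts <- treatment_start(design$schedule)
  traj <- simulate_individual(params, design$schedule, S_L = S_L, pk = pk,
                              t_end = ts + design$eval_day,
                              dt = sim_opts$dt, rtol = sim_opts$rtol,
                              atol = sim_opts$atol)
  classify_responder(traj, design)
}

.default_sim_opts <- function(sim_opts = NULL) {
  # virtual-trial tolerance: classification is tolerance-stable well beyond this
  utils::modifyList(list(dt = 0.5, rtol = 1e-6, atol = 1e-8), sim_opts %||% list())
}

#' Infiltration threshold of response for a design
#'
#' Response is monotone in the infiltration parameter: individuals with
#' small-enough `S_L` reject the tumor, the rest progress. This locates the
#' critical `S_L` by bisection on a log scale. Returns 0 when no individual
#' responds and `Inf` when all do.
#'
#' @param design a [trial_design()].
#' @param params a [model_params()] record.
#' @param pk a [pk_params()] record.
#' @param bracket search interval for S_L (RU).
#' @param iters bisection iterations (default 13: < 0.2 % relative precision).
#' @param sim_opts optional list overriding solver options (`dt`, `rtol`, `atol`).
#' @return Critical S_L value (RU).
#' @export
response_threshold <- function(design, params = model_params(), pk = pk_params(),
                               bracket = c(0.05, 200), iters = 13,
                               sim_opts = NULL) {
  stopifnot(inherits(design, "trial_design"))
  so <- .default_sim_opts(sim_opts)
  lo <- bracket[1]; hi <- bracket[2]
  if (!.simulate_responder(lo, design, params, pk, so)) return(0)
  if (.simulate_responder(hi, design, params, pk, so)) return(Inf)
  for (i in seq_len(iters)) {
    mid <- sqrt(lo * hi)
    if (.simulate_responder(mid, design, params, pk, so)) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

#' Run one virtual trial
#'
#' Samples `n_studies` cohorts of `n_animals` individuals, classifies each
#' individual as responder / non-responder, and summarizes per-study response
#' rates as the median and the 5th-95th percentile interval. Per-individual
#' classification uses either the monotone infiltration threshold
#' (`method = "threshold"`, the default: one bisection per parameter set,
#' then all sampled individuals are classified by comparison with the
#' critical S_L) or brute-force simulation of every individual
#' (`method = "exact"`). Both methods agree wherever response is monotone in
#' S_L, which is asserted by the package test-suite.
#'
#' @param design a [trial_design()].
#' @param params a [model_params()] record (point estimates).
#' @param iav an [iav_params()] record.
#' @param pk a [pk_params()] record.
#' @param method classification strategy (see above).
#' @param sim_opts optional list overriding solver options.
#' @return An object of class `trial_result`: list with `rates` (per-study
#'   response rates, %), `median_rate`, `ci90` (5th/95th percentiles across
#'   studies), `responders` (per-study counts), `max_DC_m` and `max_dTeff`
#'   (peak values for the typical individual), and the design.
#' @export
#' @examples
#' des <- trial_design(treatment_schedule(rt = rt_fractions("5x2", 7),
#'                                        mab = mab_regimen_3qw(7)),
#'                     n_animals = 20, n_studies = 10, seed = 42)
#' run_trial(des)
run_trial <- function(design, params = model_params(), iav = iav_params(),
                      pk = pk_params(), method = c("threshold", "exact"),
                      sim_opts = NULL) {
  stopifnot(inherits(design, "trial_design"), inherits(iav, "iav_params"))
  method <- match.arg(method)
  so <- .default_sim_opts(sim_opts)

  s_l <- matrix(sample_individuals(design$n_studies * design$n_animals, iav,
                                   seed = design$seed),
                nrow = design$n_studies)

  if (method == "threshold") {
    if (design$propagate_uncertainty) {
      responders <- integer(design$n_studies)
      for (s in seq_len(design$n_studies)) {
        pp <- perturb_params(params, iav,
                             seed = (design$seed + 104729 * s) %% 2147483647)
        s_star <- response_threshold(design, pp$params, pk, sim_opts = so)
        responders[s] <- sum(s_l[s, ] <= s_star)
      }
    } else {
      s_star <- response_threshold(design, params, pk, sim_opts = so)
      responders <- as.integer(rowSums(s_l <= s_star))
    }
  } else {
    if (design$propagate_uncertainty) {
      stop("run_trial: exact method supports propagate_uncertainty = FALSE only",
           call. = FALSE)
    }
    resp <- apply(s_l, c(1, 2), function(v) {
      .simulate_responder(v, design, params, pk, so)
    })
    responders <- as.integer(rowSums(resp))
  }

  rates <- 100 * responders / design$n_animals
  qs <- stats::quantile(rates, c(0.05, 0.5, 0.95), names = FALSE)

  typical <- simulate_individual(params, design$schedule, S_L = iav$S_L_pop,
                                 pk = pk,
                                 t_end = treatment_start(design$schedule) +
                                   design$eval_day,
                                 dt = so$dt, rtol = so$rtol, atol = so$atol)

  structure(list(rates = rates, responders = responders,
                 median_rate = qs[2], ci90 = c(lower = qs[1], upper = qs[3]),
                 max_DC_m = max(typical$data$DC_m),
                 max_dTeff = max(typical$data$dTeff),
                 design = design, method = method),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("<trial_result> ", x$design$n_studies, " studies x ",
      x$design$n_animals, " animals\n", sep = "")
  cat(sprintf("  median response rate: %.1f%% (90%% interval %.1f-%.1f%%)\n",
              x$median_rate, x$ci90[1], x$ci90[2]))
  cat(sprintf("  typical-individual peaks: DC_m %.3f, dTeff %.0f cells\n",
              x$max_DC_m, x$max_dTeff))
  invisible(x)
}

#' Scheduling/sequencing sweep grid
#'
#' Builds the grid of treatment cells explored in the dose-scheduling
#' analysis: every RT regimen (conventional 5 x 2 Gy fractionation,
#' hypo-fractionated 2 x 5 Gy, single 5/7/10 Gy) starting on day 5, 7 or 12,
#' crossed with anti-PD-L1 start days 3, 5, 7, 12, 19 (3qw for 3 weeks) and
#' with the antibody omitted (RT monotherapy), plus the antibody-only cells.
#'
#' @param rt_regimens RT regimen codes (see [rt_fractions()]).
#' @param rt_start_days RT start days post-inoculation.
#' @param mab_days anti-PD-L1 first-dose days; `NA` encodes "no antibody".
#' @param include_mab_only add antibody-monotherapy cells.
#' @return Tibble with one row per cell: `rt_regimen`, `rt_start_day`,
#'   `mab_day`, `label`, `type` (combination / rt_only / mab_only).
#' @export
sweep_grid <- function(rt_regimens = c("5x2", "2x5", "1x5", "1x7", "1x10"),
                       rt_start_days = c(5, 7, 12),
                       mab_days = c(3, 5, 7, 12, 19, NA),
                       include_mab_only = TRUE) {
  g <- expand.grid(rt_regimen = rt_regimens, rt_start_day = rt_start_days,
                   mab_day = mab_days, stringsAsFactors = FALSE)
  g$type <- ifelse(is.na(g$mab_day), "rt_only", "combination")
  if (include_mab_only) {
    m <- data.frame(rt_regimen = "none", rt_start_day = NA_real_,
                    mab_day = mab_days[!is.na(mab_days)], type = "mab_only")
    g <- rbind(g, m)
  }
  g$label <- paste0(
    ifelse(g$rt_regimen == "none", "no-RT", paste0(g$rt_regimen, "Gy@d", g$rt_start_day)),
    "+", ifelse(is.na(g$mab_day), "no-mAb", paste0("aPDL1@d", g$mab_day))
  )
  tibble::as_tibble(g[, c("label", "rt_regimen", "rt_start_day", "mab_day", "type")])
}

# build the schedule of one sweep cell
.cell_schedule <- function(rt_regimen, rt_start_day, mab_day) {
  rt <- if (identical(rt_regimen, "none")) NULL else rt_fractions(rt_regimen, rt_start_day)
  mab <- if (is.na(mab_day)) NULL else mab_regimen_3qw(mab_day)
  treatment_schedule(rt = rt, mab = mab)
}

#' Run the scheduling/sequencing sweep
#'
#' Evaluates [run_trial()] on every cell of a sweep grid, with one shared
#' seed (common random numbers across cells: a one-cell grid therefore
#' reproduces `run_trial` on that design exactly). Cell failures are caught,
#' reported as a warning and returned as `NA` rows.
#'
#' @param grid tibble from [sweep_grid()] (or same columns).
#' @param params,iav,pk parameter records.
#' @param n_animals,n_studies cohort structure per cell.
#' @param eval_day,threshold_mm3 endpoint definition.
#' @param seed shared seed.
#' @param sim_opts optional solver-option overrides.
#' @return The grid with columns `median_rate`, `ci90_lower`, `ci90_upper`,
#'   `max_DC_m`, `max_dTeff` appended.
#' @export
schedule_sweep <- function(grid = sweep_grid(), params = model_params(),
                           iav = iav_params(), pk = pk_params(),
                           n_animals = 100, n_studies = 1000,
                           eval_day = 50, threshold_mm3 = 10, seed = 1,
                           sim_opts = NULL) {
  out <- grid
  out$median_rate <- NA_real_
  out$ci90_lower <- NA_real_
  out$ci90_upper <- NA_real_
  out$max_DC_m <- NA_real_
  out$max_dTeff <- NA_real_
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      des <- trial_design(
        .cell_schedule(grid$rt_regimen[i], grid$rt_start_day[i], grid$mab_day[i]),
        n_animals = n_animals, n_studies = n_studies, eval_day = eval_day,
        threshold_mm3 = threshold_mm3, seed = seed
      )
      run_trial(des, params, iav, pk, sim_opts = sim_opts)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("schedule_sweep: cell '", grid$label[i], "' failed: ",
              conditionMessage(res), call. = FALSE)
    } else {
      out$median_rate[i] <- res$median_rate
      out$ci90_lower[i] <- res$ci90[1]
      out$ci90_upper[i] <- res$ci90[2]
      out$max_DC_m[i] <- res$max_DC_m
      out$max_dTeff[i] <- res$max_dTeff
    }
  }
  out
}

#' Preset scenarios of the calibration and mechanism analyses
#'
#' Returns the treatment arms used throughout: the six-arm calibration study
#' design (treatments starting day 7 post-inoculation), the CD8-depletion
#' validation arm, and the responder / typical / non-responder individuals
#' used for stratified mechanism simulation (S_L = 1.77, 6.95 and 22.63 RU,
#' the empirical 10th percentile, median and 90th percentile of the
#' individual infiltration estimates).
#'
#' @param name one of `"control"`, `"aPDL1_only"`, `"RT_only"`,
#'   `"combo_concurrent"`, `"combo_seq1_day12"`, `"combo_seq2_day19"`,
#'   `"cd8_depletion"`, `"responder_vs_nonresponder"`.
#' @return List with `name`, `schedule` and `s_l` (named vector of S_L values
#'   to simulate: the stratified trio for the mechanism preset, the typical
#'   individual otherwise).
#' @export
#' @examples
#' scenario_presets("combo_seq2_day19")$schedule
scenario_presets <- function(name) {
  presets <- c("control", "aPDL1_only", "RT_only", "combo_concurrent",
               "combo_seq1_day12", "combo_seq2_day19", "cd8_depletion",
               "responder_vs_nonresponder")
  if (!is.character(name) || length(name) != 1 || !name %in% presets) {
    stop("scenario_presets: unknown scenario; valid names: ",
         paste(presets, collapse = ", "), call. = FALSE)
  }
  strat <- c(responder = 1.77, typical = 6.95, nonresponder = 22.63)
  typ <- c(typical = 8.89)
  rt7 <- rt_fractions("5x2", 7)
  sched <- switch(name,
    control            = treatment_schedule(),
    aPDL1_only         = treatment_schedule(mab = mab_regimen_3qw(7)),
    RT_only            = treatment_schedule(rt = rt7),
    combo_concurrent   = treatment_schedule(rt = rt7, mab = mab_regimen_3qw(7)),
    combo_seq1_day12   = treatment_schedule(rt = rt7, mab = mab_regimen_3qw(12)),
    combo_seq2_day19   = treatment_schedule(rt = rt7, mab = mab_regimen_3qw(19)),
    cd8_depletion      = treatment_schedule(rt = rt7, mab = mab_regimen_3qw(7),
                                            cd8_depletion_day = 7),
    responder_vs_nonresponder =
      treatment_schedule(rt = rt7, mab = mab_regimen_3qw(7))
  )
  s_l <- if (name == "responder_vs_nonresponder") strat else typ
  list(name = name, schedule = sched, s_l = s_l)
}
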