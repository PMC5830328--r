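#' Specification of a synthetic tumor-growth study
#'
#' Describes a multi-arm CT26-style efficacy study to be generated by
#' [generate_study()]: treatment arms with animal counts, an observation
#' grid, the generating ("truth") parameters and a seed. The default design
#' mirrors the six-arm calibration study: 59 animals split across control,
#' anti-PD-L1 (day 7), fractionated RT (5 x 2 Gy, days 7-11), and the
#' concurrent / day-12 / day-19 combination arms, observed every third day
#' from day 7 to day 40.
#'
#' @param arms data frame with columns `label` (a [scenario_presets()] arm
#'   name) and `n_animals`; per-arm counts of 7-16 animals are the sampled
#'   design range.
#' @param obs_days observation days post-inoculation (within \[7, 50\]).
#' @param params,iav,pk truth parameter records.
#' @param seed integer seed.
#' @param enroll_trigger_mm3 optional size trigger: if set, each animal's
#'   schedule is shifted so treatment starts on the first observation-grid
#'   day its untreated tumor reaches this volume (default `NULL`: fixed
#'   calendar schedules).
#' @return An object of class `study_spec`.
#' @export
#' @examples
#' study_spec()$arms
study_spec <- function(arms = NULL,
                       obs_days = seq(7, 40, by = 3),
                       params = model_params(),
                       iav = iav_params(),
                       pk = pk_params(),
                       seed = 1,
                       enroll_trigger_mm3 = NULL) {
  if (is.null(arms)) {
    arms <- data.frame(
      label = c("control", "aPDL1_only", "RT_only", "combo_concurrent",
                "combo_seq1_day12", "combo_seq2_day19"),
      n_animals = c(10, 10, 10, 10, 10, 9)
    )
  }
  stopifnot(is.data.frame(arms), all(c("label", "n_animals") %in% names(arms)))
  if (any(arms$n_animals < 1)) stop("study_spec: n_animals must be >= 1", call. = FALSE)
  if (any(obs_days < 0) || is.unsorted(obs_days, strictly = TRUE)) {
    stop("study_spec: obs_days must be strictly increasing and >= 0", call. = FALSE)
  }
  structure(list(arms = arms, obs_days = obs_days, params = params, iav = iav,
                 pk = pk, seed = as.integer(seed),
                 enroll_trigger_mm3 = enroll_trigger_mm3),
            class = "study_spec")
}

#' Generate a synthetic observed tumor-volume dataset
#'
#' Simulates every animal of a [study_spec()] at its sampled individual
#' infiltration value, evaluates total tumor volume on the observation grid
#' and perturbs it with the residual-error model. The generating truth
#' (parameters and per-animal S_L) is attached for recovery testing.
#' Regeneration with the same spec is deterministic.
#'
#' @param spec a [study_spec()].
#' @param sim_opts optional solver-option overrides (`dt`, `rtol`, `atol`).
#' @return An `observed_dataset`: tibble with columns `animal_id`, `arm`,
#'   `day`, `volume_mm3`, plus attributes `truth` (list: `params`, `iav`,
#'   `s_l` per animal) and `spec`.
#' @export
#' @examples
#' ds <- generate_study(study_spec(arms = data.frame(label = "control",
#'                                                   n_animals = 2)))
#' head(ds)
generate_study <- function(spec = study_spec(), sim_opts = NULL) {
  stopifnot(inherits(spec, "study_spec"))
  so <- .default_sim_opts(sim_opts)
  n_total <- sum(spec$arms$n_animals)
  n_days <- length(spec$obs_days)

  draws <- .with_seed(spec$seed, {
    list(eta = stats::rnorm(n_total, 0, spec$iav$omega_SL),
         z = stats::rnorm(n_total * n_days))
  })
  s_l <- spec$iav$S_L_pop * exp(draws$eta)

  t_end <- max(spec$obs_days) + 1
  rows <- vector("list", n_total)
  ids <- character(n_total)
  arm_of <- character(n_total)
  k <- 0
  failures <- character(0)
  for (a in seq_len(nrow(spec$arms))) {
    label <- spec$arms$label[a]
    sched0 <- scenario_presets(label)$schedule
    for (j in seq_len(spec$arms$n_animals[a])) {
      k <- k + 1
      id <- sprintf("%s_%02d", label, j)
      ids[k] <- id
      arm_of[k] <- label
      sched <- if (is.null(spec$enroll_trigger_mm3)) sched0 else {
        .shift_schedule_to_trigger(sched0, spec, s_l[k], so)
      }
      pred <- tryCatch({
        traj <- simulate_individual(spec$params, sched, S_L = s_l[k],
                                    pk = spec$pk, t_end = t_end,
                                    dt = so$dt, rtol = so$rtol, atol = so$atol)
        trajectory_at(traj, spec$obs_days, "TV_tot")
      }, error = function(e) e)
      if (inherits(pred, "error")) {
        failures <- c(failures, paste0(id, ": ", conditionMessage(pred)))
        next
      }
      zk <- draws$z[((k - 1) * n_days + 1):(k * n_days)]
      vol <- pred + residual_sd(pred, spec$iav) * zk
      vol[vol < 0] <- 0
      rows[[k]] <- data.frame(animal_id = id, arm = label,
                              day = spec$obs_days, volume_mm3 = vol)
    }
  }
  if (length(failures)) {
    stop("generate_study: simulation failed for ", length(failures),
         " animal(s):\n", paste(failures, collapse = "\n"), call. = FALSE)
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  attr(out, "truth") <- list(params = spec$params, iav = spec$iav,
                             s_l = stats::setNames(s_l, ids))
  attr(out, "spec") <- spec
  class(out) <- c("observed_dataset", class(out))
  out
}

# shift a schedule so the first event lands on the first obs-grid day where
# the untreated tumor reaches the enrollment trigger
.shift_schedule_to_trigger <- function(sched, spec, s_l, so) {
  base <- treatment_start(sched)
  if (!length(c(sched$rt$day, sched$mab$day))) return(sched)
  unt <- simulate_individual(spec$params, treatment_schedule(), S_L = s_l,
                             pk = spec$pk, t_end = max(spec$obs_days) + 1,
                             dt = so$dt, rtol = so$rtol, atol = so$atol)
  vols <- trajectory_at(unt, spec$obs_days, "TV_tot")
  hit <- which(vols >= spec$enroll_trigger_mm3)
  start <- if (length(hit)) spec$obs_days[hit[1]] else max(spec$obs_days)
  shift <- start - base
  rt <- sched$rt; mab <- sched$mab
  if (nrow(rt)) rt$day <- rt$day + shift
  if (nrow(mab)) mab$day <- mab$day + shift
  treatment_schedule(rt = rt, mab = mab,
                     cd8_depletion_day = sched$cd8_depletion_day +
                       if (!is.na(sched$cd8_depletion_day)) shift else 0)
}

#' Write / read an observed dataset as tidy CSV
#'
#' The CSV carries the observation table only (`animal_id`, `arm`, `day`,
#' `volume_mm3`); the truth manifest of a generated study can be written
#' separately with [write_truth_manifest()].
#'
#' @param dataset an `observed_dataset` (or any data frame with the four
#'   columns).
#' @param path CSV path.
#' @return `path` (write) or the dataset tibble (read).
#' @export
write_dataset <- function(dataset, path) {
  cols <- c("animal_id", "arm", "day", "volume_mm3")
  stopifnot(all(cols %in% names(dataset)))
  utils::write.csv(as.data.frame(dataset)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("animal_id", "arm", "day", "volume_mm3")
  if (!all(cols %in% names(x))) {
    stop("read_dataset: file must have columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  x <- x[order(x$animal_id, x$day), cols]
  if (any(x$volume_mm3 < 0)) stop("read_dataset: negative volumes", call. = FALSE)
  out <- tibble::as_tibble(x)
  class(out) <- c("observed_dataset", class(out))
  out
}

#' Write the truth manifest of a generated study
#'
#' JSON record of the generating parameters, residual-error settings, seed
#' and per-animal S_L values of a [generate_study()] dataset.
#'
#' @param dataset an `observed_dataset` produced by [generate_study()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(dataset, path) {
  truth <- attr(dataset, "truth")
  spec <- attr(dataset, "spec")
  if (is.null(truth)) {
    stop("write_truth_manifest: dataset carries no truth attribute", call. = FALSE)
  }
  jsonlite::write_json(
    list(params = unclass(truth$params), iav = unclass(truth$iav),
         s_l = as.list(truth$s_l), seed = spec$seed,
         obs_days = spec$obs_days,
         arms = spec$arms),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
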