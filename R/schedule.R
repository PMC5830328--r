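#' Treatment schedule: radiation fractions and antibody doses
#'
#' Bundles the timed interventions applied to one individual. Radiation
#' fractions are instantaneous state transformations (see
#' [apply_fraction()]); antibody doses are instantaneous additions to the
#' intraperitoneal depot. When a fraction and a dose share the same time, the
#' fraction is applied first.
#'
#' @param rt data frame with columns `day` (days post-inoculation) and `gray`
#'   (dose per fraction, Gy), or `NULL` for no radiotherapy. Doses must lie in
#'   (0, 10]; the model is not valid above 10 Gy per fraction.
#' @param mab data frame with columns `day` and `mg_per_kg`, or `NULL` for no
#'   antibody.
#' @param cd8_depletion_day day from which CD8+ effector influx is abolished
#'   (anti-CD8 co-treatment), or `NA` for no depletion.
#' @return An object of class `treatment_schedule`.
#' @export
#' @examples
#' treatment_schedule(rt = rt_fractions("5x2", start_day = 7),
#'                    mab = mab_regimen_3qw(start_day = 7))
treatment_schedule <- function(rt = NULL, mab = NULL, cd8_depletion_day = NA) {
  rt <- .norm_events(rt, "gray", "rt")
  mab <- .norm_events(mab, "mg_per_kg", "mab")
  if (nrow(rt)) {
    # zero-dose fractions are tolerated as explicit no-ops
    if (any(rt$gray < 0)) stop("treatment_schedule: RT doses must be >= 0 Gy", call. = FALSE)
    if (any(rt$gray > 10)) {
      stop("treatment_schedule: RT fractions above 10 Gy are outside the model's validity range",
           call. = FALSE)
    }
  }
  if (nrow(mab) && any(mab$mg_per_kg < 0)) {
    stop("treatment_schedule: antibody doses must be >= 0 mg/kg", call. = FALSE)
  }
  structure(list(rt = rt, mab = mab,
                 cd8_depletion_day = as.numeric(cd8_depletion_day)),
            class = "treatment_schedule")
}

.norm_events <- function(x, value_col, what) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    out <- data.frame(day = numeric(0))
    out[[value_col]] <- numeric(0)
    return(out)
  }
  if (!is.data.frame(x) || !all(c("day", value_col) %in% names(x))) {
    stop("treatment_schedule: '", what, "' needs columns day and ", value_col,
         call. = FALSE)
  }
  x <- as.data.frame(x)[, c("day", value_col)]
  if (any(!is.finite(x$day)) || any(x$day < 0)) {
    stop("treatment_schedule: event days must be finite and >= 0", call. = FALSE)
  }
  x[order(x$day), , drop = FALSE]
}

#' Standard radiotherapy regimens
#'
#' Expands a regimen shorthand into per-fraction events. Available regimens:
#' `"5x2"` (conventional fractionation, 2 Gy on five consecutive days),
#' `"2x5"` (hypo-fractionation, 5 Gy on two consecutive days), and single
#' doses `"1x5"`, `"1x7"`, `"1x10"`.
#'
#' @param regimen regimen code.
#' @param start_day day post-inoculation of the first fraction.
#' @return Data frame with columns `day`, `gray`.
#' @export
#' @examples
#' rt_fractions("5x2", 7)
rt_fractions <- function(regimen = c("5x2", "2x5", "1x5", "1x7", "1x10"),
                         start_day = 7) {
  regimen <- match.arg(regimen)
  spec <- switch(regimen,
    "5x2"  = list(n = 5, gy = 2),
    "2x5"  = list(n = 2, gy = 5),
    "1x5"  = list(n = 1, gy = 5),
    "1x7"  = list(n = 1, gy = 7),
    "1x10" = list(n = 1, gy = 10)
  )
  data.frame(day = start_day + seq_len(spec$n) - 1, gray = spec$gy)
}

#' Three-times-weekly antibody regimen
#'
#' Expands the "3qw" shorthand used for checkpoint-blockade dosing: doses on
#' days 0, 2 and 4 of each week relative to the first dose.
#'
#' @param start_day day post-inoculation of the first dose.
#' @param weeks number of weeks of dosing (default 3).
#' @param mg_per_kg dose level (default 10 mg/kg).
#' @return Data frame with columns `day`, `mg_per_kg`.
#' @export
#' @examples
#' mab_regimen_3qw(7)
mab_regimen_3qw <- function(start_day = 7, weeks = 3, mg_per_kg = 10) {
  offsets <- as.vector(outer(c(0, 2, 4), 7 * (seq_len(weeks) - 1), "+"))
  data.frame(day = start_day + offsets, mg_per_kg = mg_per_kg)
}

#' Treatment start time of a schedule
#'
#' The earliest intervention (RT fraction or antibody dose). For an untreated
#' schedule the convention is day 0, so that evaluation windows expressed
#' relative to treatment start remain defined for control arms.
#'
#' @param schedule a [treatment_schedule()].
#' @return Day of treatment start (numeric scalar).
#' @export
treatment_start <- function(schedule) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  days <- c(schedule$rt$day, schedule$mab$day)
  if (!length(days)) 0 else min(days)
}

#' Read a treatment schedule from a config file
#'
#' Accepts JSON or YAML with keys `rt` (list of `{day, gray}`) and `mab`
#' (either a list of `{day, mg_per_kg}` or a shorthand object
#' `{regimen: "3qw", start_day, weeks, mg_per_kg}`), plus optional
#' `cd8_depletion_day`.
#'
#' @param path config file path.
#' @return A [treatment_schedule()].
#' @export
read_schedule <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("read_schedule: unsupported extension '", ext, "'", call. = FALSE)
  }
  rt <- x$rt
  if (!is.null(rt) && !is.data.frame(rt)) rt <- do.call(rbind.data.frame, rt)
  mab <- x$mab
  if (!is.null(mab)) {
    if (!is.null(mab$regimen)) {
      if (!identical(mab$regimen, "3qw")) {
        stop("read_schedule: unknown mab regimen '", mab$regimen, "'", call. = FALSE)
      }
      mab <- mab_regimen_3qw(
        start_day = mab$start_day %||% 7,
        weeks = mab$weeks %||% 3,
        mg_per_kg = mab$mg_per_kg %||% 10
      )
    } else if (!is.data.frame(mab)) {
      mab <- do.call(rbind.data.frame, mab)
    }
  }
  treatment_schedule(rt = rt, mab = mab,
                     cd8_depletion_day = x$cd8_depletion_day %||% NA)
}

#' Write a treatment schedule to a config file
#'
#' @param schedule a [treatment_schedule()].
#' @param path output file (`.json`, `.yaml` or `.yml`).
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "treatment_schedule"))
  x <- list(rt = schedule$rt, mab = schedule$mab)
  if (!is.na(schedule$cd8_depletion_day)) {
    x$cd8_depletion_day <- schedule$cd8_depletion_day
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    x$rt <- unname(split(x$rt, seq_len(max(nrow(x$rt), 0))))
    x$mab <- unname(split(x$mab, seq_len(max(nrow(x$mab), 0))))
    yaml::write_yaml(x, path)
  } else {
    stop("write_schedule: unsupported extension '", ext, "'", call. = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.treatment_schedule <- function(x, ...) {
  cat("<treatment_schedule>\n")
  if (nrow(x$rt)) {
    cat("  RT fractions:", paste0(x$rt$gray, " Gy @ d", x$rt$day, collapse = ", "), "\n")
  } else cat("  RT fractions: none\n")
  if (nrow(x$mab)) {
    cat("  mAb doses:", nrow(x$mab), "x", x$mab$mg_per_kg[1], "mg/kg, days",
        paste(x$mab$day, collapse = ", "), "\n")
  } else cat("  mAb doses: none\n")
  if (!is.na(x$cd8_depletion_day)) {
    cat("  CD8 depletion from day", x$cd8_depletion_day, "\n")
  }
  invisible(x)
}
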