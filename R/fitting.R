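#' Log-likelihood of one animal's tumor-volume series
#'
#' Gaussian observation model: each measured volume is the model-predicted
#' total tumor volume plus residual error with SD given by [residual_sd()].
#'
#' @param params a [model_params()] record.
#' @param S_L_i the individual's infiltration parameter (RU).
#' @param data_i data frame with columns `day`, `volume_mm3` (one animal).
#' @param schedule the animal's [treatment_schedule()].
#' @param iav an [iav_params()] record (residual-error components).
#' @param pk a [pk_params()] record.
#' @param sim_opts optional solver-option overrides.
#' @return Log-likelihood (scalar).
#' @export
individual_loglik <- function(params, S_L_i, data_i, schedule,
                              iav = iav_params(), pk = pk_params(),
                              sim_opts = NULL) {
  if (!nrow(data_i)) stop("individual_loglik: empty data", call. = FALSE)
  so <- .default_sim_opts(sim_opts)
  traj <- simulate_individual(params, schedule, S_L = S_L_i, pk = pk,
                              t_end = max(data_i$day) + 1,
                              dt = so$dt, rtol = so$rtol, atol = so$atol)
  pred <- trajectory_at(traj, data_i$day, "TV_tot")
  sum(stats::dnorm(data_i$volume_mm3, mean = pred,
                   sd = residual_sd(pred, iav), log = TRUE))
}

#' Precompute arm prediction grids for population fitting
#'
#' Simulates each treatment arm over a log-spaced grid of S_L values and
#' stores predicted total tumor volume at the observation days. The
#' population objective marginalizes the random effect by quadrature over
#' this grid, so the ODE system is integrated once per (arm, grid point)
#' rather than once per objective evaluation.
#'
#' @param dataset an `observed_dataset` (defines arms and observation days).
#' @param params a [model_params()] record.
#' @param pk a [pk_params()] record.
#' @param s_l_grid grid of S_L values (default 101 log-spaced points spanning
#'   0.15-350 RU, beyond +/- 5 population SDs around the default median).
#' @param sim_opts optional solver-option overrides.
#' @return List of per-arm lists with `days`, `grid` and the days-by-grid
#'   prediction matrix, for use as the `predictors` argument of
#'   [fit_population()].
#' @export
build_arm_predictors <- function(dataset, params = model_params(),
                                 pk = pk_params(),
                                 s_l_grid = exp(seq(log(0.15), log(350),
                                                    length.out = 101)),
                                 sim_opts = NULL) {
  so <- .default_sim_opts(sim_opts)
  arms <- unique(dataset$arm)
  out <- list()
  for (a in arms) {
    days <- sort(unique(dataset$day[dataset$arm == a]))
    sched <- scenario_presets(a)$schedule
    P <- matrix(NA_real_, nrow = length(days), ncol = length(s_l_grid))
    for (j in seq_along(s_l_grid)) {
      traj <- simulate_individual(params, sched, S_L = s_l_grid[j], pk = pk,
                                  t_end = max(days) + 1,
                                  dt = so$dt, rtol = so$rtol, atol = so$atol)
      P[, j] <- trajectory_at(traj, days, "TV_tot")
    }
    out[[a]] <- list(days = days, grid = s_l_grid, pred = P)
  }
  out
}

# log-likelihood of every animal at every grid point: animals x grid matrix
.ll_grid_matrix <- function(by_animal, pred, iav) {
  n_g <- length(pred[[1]]$grid)
  L <- matrix(NA_real_, nrow = length(by_animal), ncol = n_g)
  for (i in seq_along(by_animal)) {
    d <- by_animal[[i]]
    pr <- pred[[d$arm[1]]]
    idx <- match(d$day, pr$days)
    for (g in seq_len(n_g)) {
      mu <- pr$pred[idx, g]
      L[i, g] <- sum(stats::dnorm(d$volume_mm3, mu, residual_sd(mu, iav),
                                  log = TRUE))
    }
  }
  L
}

# sum over animals of the log marginal likelihood: trapezoid quadrature of
# the lognormal random-effect density over the fixed S_L grid, renormalized
# on the grid (truncated prior). Degenerate omega collapses to the nearest
# grid evaluation of the population value.
.marginal_from_grid <- function(L, log_grid, s_l_pop, omega) {
  if (omega <= 0) {
    j <- which.min(abs(log_grid - log(s_l_pop)))
    return(sum(L[, j]))
  }
  lw <- stats::dnorm(log_grid, log(s_l_pop), omega, log = TRUE)
  # trapezoid weights on the (uniform in log) grid
  dg <- diff(log_grid)
  tw <- c(dg[1] / 2, (dg[-length(dg)] + dg[-1]) / 2, dg[length(dg)] / 2)
  lw <- lw + log(tw)
  lw <- lw - .logsumexp(lw)  # renormalize the truncated prior
  total <- 0
  for (i in seq_len(nrow(L))) total <- total + .logsumexp(L[i, ] + lw)
  total
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Fit the population model to a tumor-volume dataset
#'
#' Maximum-likelihood estimation of the mixed-effects model: a lognormal
#' random effect on the infiltration parameter S_L around the population
#' value `S_L_pop` with SD `omega_SL`, plus the combined residual-error
#' model. The marginal likelihood of each animal integrates the individual
#' likelihood over the random effect by quadrature on a fixed log-spaced
#' S_L grid (individual likelihoods are precomputed on the grid from the arm
#' prediction matrices, so each objective evaluation is a reweighting). By
#' default only `S_L_pop` and `omega_SL` are estimated; structural model
#' parameters may be freed, at the cost of re-simulating the prediction
#' grids at every objective evaluation.
#'
#' @param dataset an `observed_dataset` with arm labels matching
#'   [scenario_presets()] names.
#' @param which_free names of parameters to estimate; any of `"S_L_pop"`,
#'   `"omega_SL"` plus structural [model_params()] names
#'   (`"k_LN"`, `"K_pdl"`, `"S_R"`, `"alpha"`, `"mu"`).
#' @param params starting/fixed structural parameters.
#' @param iav starting/fixed population parameters (also supplies the
#'   residual-error components, which are held fixed).
#' @param pk a [pk_params()] record.
#' @param predictors optional precomputed [build_arm_predictors()] output
#'   (only used when no structural parameter is freed); built on the fly if
#'   `NULL`.
#' @param sim_opts optional solver-option overrides for grid building.
#' @param control passed to [stats::optim()] (Nelder-Mead on log scale).
#' @return An object of class `fit_result`: `estimates` (named vector),
#'   `rse_percent` (from the observed information, delta method),
#'   `ofv` (-2 log marginal likelihood), `eb` (tibble of empirical-Bayes
#'   individual S_L estimates), `trace` (objective evaluations),
#'   `convergence` (optim code, 0 = success).
#' @export
#' @examples
#' \donttest{
#' ds <- generate_study(study_spec(seed = 1))
#' fit <- fit_population(ds)
#' fit$estimates
#' }
fit_population <- function(dataset,
                           which_free = c("S_L_pop", "omega_SL"),
                           params = model_params(),
                           iav = iav_params(),
                           pk = pk_params(),
                           predictors = NULL,
                           sim_opts = NULL,
                           control = list(maxit = 300)) {
  stopifnot(inherits(dataset, "observed_dataset") || is.data.frame(dataset))
  pop_free <- intersect(which_free, c("S_L_pop", "omega_SL"))
  struct_free <- setdiff(which_free, pop_free)
  allowed <- c("k_LN", "K_pdl", "S_R", "alpha", "mu")
  if (length(setdiff(struct_free, allowed))) {
    stop("fit_population: free parameters must be among S_L_pop, omega_SL, ",
         paste(allowed, collapse = ", "), call. = FALSE)
  }
  arms <- unique(dataset$arm)
  if (length(arms) < 2 && length(struct_free)) {
    stop("fit_population: structural fits need >= 2 arms", call. = FALSE)
  }

  by_animal <- split(as.data.frame(dataset)[c("arm", "day", "volume_mm3")],
                     dataset$animal_id)

  theta0 <- c(S_L_pop = iav$S_L_pop, omega_SL = iav$omega_SL,
              unlist(unclass(params)[struct_free]))
  free <- c(pop_free, struct_free)
  if (!length(free)) stop("fit_population: nothing to estimate", call. = FALSE)
  if (any(theta0[free] <= 0)) {
    stop("fit_population: free parameters need positive starting values ",
         "(omega_SL = 0 cannot be freed; fix it instead)", call. = FALSE)
  }

  make_ll_matrix <- function(pl) {
    pred <- if (is.null(pl) && !is.null(predictors)) predictors else {
      build_arm_predictors(dataset,
                           if (is.null(pl)) params else do.call(model_params, pl),
                           pk, sim_opts = sim_opts)
    }
    list(L = .ll_grid_matrix(by_animal, pred, iav),
         log_grid = log(pred[[1]]$grid), pred = pred)
  }

  static <- if (length(struct_free)) NULL else make_ll_matrix(NULL)

  trace_env <- new.env()
  trace_env$rows <- list()

  neg2ll <- function(log_free) {
    th <- theta0
    th[free] <- exp(log_free)
    mat <- static
    if (is.null(mat)) {
      pl <- unclass(params)
      pl[struct_free] <- th[struct_free]
      mat <- make_ll_matrix(pl)
    }
    val <- -2 * .marginal_from_grid(mat$L, mat$log_grid, th[["S_L_pop"]],
                                    th[["omega_SL"]])
    trace_env$rows[[length(trace_env$rows) + 1]] <- c(th[free], ofv = val)
    val
  }

  x0 <- log(theta0[free])
  opt <- if (length(free) == 1) {
    stats::optim(x0, neg2ll, method = "Brent",
                 lower = x0 - log(100), upper = x0 + log(100))
  } else {
    stats::optim(x0, neg2ll, method = "Nelder-Mead", control = control)
  }
  theta <- theta0
  theta[free] <- exp(opt$par)

  H <- tryCatch(stats::optimHess(opt$par, neg2ll), error = function(e) NULL)
  rse <- rep(NA_real_, length(free))
  names(rse) <- free
  if (!is.null(H)) {
    cov <- tryCatch(solve(H / 2), error = function(e) NULL)  # H is for -2ll
    if (!is.null(cov)) {
      d <- diag(as.matrix(cov))
      rse[d > 0] <- 100 * sqrt(d[d > 0])  # SD of log = CV of the parameter
    }
  }

  final <- if (length(struct_free)) {
    pl <- unclass(params)
    pl[struct_free] <- theta[struct_free]
    make_ll_matrix(pl)
  } else static
  eb <- .empirical_bayes(names(by_animal), final$L, final$log_grid,
                         theta[["S_L_pop"]], theta[["omega_SL"]])

  if (opt$convergence != 0) {
    warning("fit_population: optimizer did not converge (code ",
            opt$convergence, "); inspect the $trace element", call. = FALSE)
  }

  structure(list(estimates = theta[free], rse_percent = rse,
                 ofv = opt$value, eb = eb,
                 trace = tibble::as_tibble(as.data.frame(
                   do.call(rbind, trace_env$rows))),
                 convergence = opt$convergence,
                 fixed = theta0[setdiff(names(theta0), free)]),
            class = "fit_result")
}

# posterior-mode individual S_L over the grid
.empirical_bayes <- function(ids, L, log_grid, s_l_pop, omega) {
  if (omega <= 0) {
    return(tibble::tibble(animal_id = ids,
                          S_L_i = rep(s_l_pop, length(ids))))
  }
  lprior <- stats::dnorm(log_grid, log(s_l_pop), omega, log = TRUE)
  idx <- apply(L + matrix(lprior, nrow(L), ncol(L), byrow = TRUE), 1, which.max)
  tibble::tibble(animal_id = ids, S_L_i = exp(log_grid[idx]))
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> -2LL =", round(x$ofv, 2), "\n")
  est <- data.frame(estimate = signif(x$estimates, 4),
                    rse_percent = round(x$rse_percent, 1))
  print(est)
  invisible(x)
}
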