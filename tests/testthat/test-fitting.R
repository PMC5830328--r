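# small two-arm study reused across fitting tests
small_spec <- study_spec(
  arms = data.frame(label = c("control", "combo_concurrent"),
                    n_animals = c(8, 8)),
  obs_days = seq(7, 37, by = 5), seed = 21
)
small_ds <- generate_study(small_spec)
small_grid <- exp(seq(log(0.3), log(150), length.out = 41))
small_pred <- build_arm_predictors(small_ds, s_l_grid = small_grid)

test_that("noiseless data at the true parameters attain the exact maximum", {
  sched <- scenario_presets("control")$schedule
  days <- seq(7, 31, by = 6)
  tr <- sim_fast(t_end = 32)
  data_i <- data.frame(day = days,
                       volume_mm3 = trajectory_at(tr, days, "TV_tot"))
  ll <- individual_loglik(p0, 8.89, data_i, sched, iav0, pk0,
                          sim_opts = fast_opts)
  # zero residuals: the log-likelihood is the Gaussian normalizing constant
  sds <- residual_sd(data_i$volume_mm3, iav0)
  expect_equal(ll, sum(dnorm(0, 0, sds, log = TRUE)), tolerance = 1e-8)
  # perturbing the individual parameter strictly decreases the likelihood
  scan <- vapply(c(4, 6, 8.89, 13, 20), function(s) {
    individual_loglik(p0, s, data_i, sched, iav0, pk0, sim_opts = fast_opts)
  }, numeric(1))
  expect_equal(which.max(scan), 3L)
  expect_true(all(scan[-3] < ll))
})

test_that("scaling all residual SDs matches a from-scratch recomputation", {
  sched <- scenario_presets("RT_only")$schedule
  days <- c(10, 16, 22)
  tr <- sim_fast(sched, t_end = 23)
  pred <- trajectory_at(tr, days, "TV_tot")
  data_i <- data.frame(day = days, volume_mm3 = pred * 1.1 + 5)
  iav2 <- iav_params(a_err = 2 * iav0$a_err, b_err = 2 * iav0$b_err)
  ll2 <- individual_loglik(p0, 8.89, data_i, sched, iav2, pk0,
                           sim_opts = fast_opts)
  oracle <- sum(dnorm(data_i$volume_mm3, pred,
                      2 * residual_sd(pred, iav0), log = TRUE))
  expect_equal(ll2, oracle, tolerance = 1e-8)
})

test_that("population refit recovers the generating parameters", {
  fit <- fit_population(small_ds, predictors = small_pred)
  expect_equal(fit$convergence, 0)
  expect_equal(unname(fit$estimates["S_L_pop"]), 8.89, tolerance = 0.35)
  expect_equal(unname(fit$estimates["omega_SL"]), 0.696, tolerance = 0.45)
  expect_true(all(fit$rse_percent > 0, na.rm = TRUE))
  expect_equal(nrow(fit$eb), 16)
  expect_true(all(fit$eb$S_L_i > 0))
})

test_that("single-parameter refit of S_L_pop works from a displaced start", {
  fit <- fit_population(small_ds, which_free = "S_L_pop",
                        iav = iav_params(S_L_pop = 3),
                        predictors = small_pred)
  expect_equal(unname(fit$estimates["S_L_pop"]), 8.89, tolerance = 0.35)
})

test_that("a zero-variability truth shrinks omega toward the boundary", {
  ds0 <- generate_study(study_spec(
    arms = data.frame(label = c("control", "combo_concurrent"),
                      n_animals = c(8, 8)),
    obs_days = seq(7, 37, by = 5), seed = 8, iav = iav_params(omega_SL = 0)
  ))
  fit <- fit_population(ds0, predictors = build_arm_predictors(
    ds0, s_l_grid = small_grid))
  expect_lt(unname(fit$estimates["omega_SL"]), 0.12)
})

test_that("modeling inter-animal variability improves the objective function", {
  with_re <- fit_population(small_ds, predictors = small_pred)
  without_re <- fit_population(small_ds, which_free = "S_L_pop",
                               iav = iav_params(omega_SL = 0),
                               predictors = small_pred)
  expect_lt(with_re$ofv, without_re$ofv)
})

test_that("invalid free-parameter requests are rejected", {
  expect_error(fit_population(small_ds, which_free = c("S_L_pop", "r")),
               "must be among")
  expect_error(fit_population(small_ds, which_free = character(0)),
               "nothing to estimate")
  expect_error(fit_population(small_ds, which_free = "omega_SL",
                              iav = iav_params(omega_SL = 0),
                              predictors = small_pred),
               "positive starting values")
})

test_that("freeing a structural parameter moves the objective downhill", {
  # gradient sanity on the slow path: a short alpha-only fit must not diverge
  ds_rt <- generate_study(study_spec(
    arms = data.frame(label = c("control", "RT_only"), n_animals = c(4, 4)),
    obs_days = seq(7, 27, by = 10), seed = 5
  ))
  fit <- fit_population(ds_rt, which_free = c("alpha"),
                        params = model_params(alpha = 0.2),
                        iav = iav_params(omega_SL = 0),
                        sim_opts = list(dt = 1, rtol = 1e-5, atol = 1e-7),
                        control = list(maxit = 25))
  expect_lt(abs(log(unname(fit$estimates["alpha"]) / 0.146)), log(2.5))
  expect_lt(min(fit$trace$ofv), fit$trace$ofv[1])
})
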