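test_that("responder classification is inclusive at the 10 mm3 threshold", {
  des <- trial_design(sched_combo7, n_animals = 1, n_studies = 1)
  mk <- function(v50) {
    structure(list(
      data = tibble::tibble(time = c(0, 57, 60), TV_tot = c(0.5, v50, v50)),
      schedule = sched_combo7, t_end = 60
    ), class = "trajectory")
  }
  expect_true(classify_responder(mk(9), des))    # below threshold
  expect_true(classify_responder(mk(10), des))   # exactly at threshold
  expect_false(classify_responder(mk(11), des))  # above threshold
  short <- structure(list(
    data = tibble::tibble(time = c(0, 30), TV_tot = c(0.5, 40)),
    schedule = sched_combo7, t_end = 30
  ), class = "trajectory")
  expect_error(classify_responder(short, des), "57")
})

test_that("trials are seed-deterministic and grids reduce to single runs", {
  des <- trial_design(sched_combo7, n_animals = 20, n_studies = 8, seed = 7)
  a <- run_trial(des)
  b <- run_trial(des)
  expect_identical(a$rates, b$rates)
  expect_identical(a$median_rate, b$median_rate)
  g <- sweep_grid(rt_regimens = "5x2", rt_start_days = 7, mab_days = 7,
                  include_mab_only = FALSE)
  sw <- schedule_sweep(g, n_animals = 20, n_studies = 8, seed = 7)
  expect_equal(sw$median_rate, unname(a$median_rate))
  expect_equal(c(sw$ci90_lower, sw$ci90_upper), unname(a$ci90))
})

test_that("threshold classification agrees with exact per-animal simulation", {
  des <- trial_design(sched_combo7, n_animals = 12, n_studies = 3, seed = 31)
  thr <- run_trial(des, method = "threshold")
  exact <- run_trial(des, method = "exact")
  expect_identical(thr$responders, exact$responders)
})

test_that("response is monotone non-increasing in the infiltration parameter", {
  des <- trial_design(sched_combo7, n_animals = 1, n_studies = 1)
  flags <- vapply(c(1, 4, 8, 16, 40), function(s) {
    rtimmune:::.simulate_responder(s, des, p0, pk0, fast_opts)
  }, logical(1))
  expect_true(all(diff(flags) <= 0))
  s_star <- response_threshold(des)
  expect_true(s_star > 1 && s_star < 40)
  # the bisected threshold separates the grid flags
  expect_true(all(c(1, 4, 8, 16, 40)[flags] <= s_star + 1e-6))
  expect_true(all(c(1, 4, 8, 16, 40)[!flags] >= s_star - 1e-6))
})

test_that("CD8 depletion collapses the combination response", {
  des <- trial_design(sched_combo7, n_animals = 30, n_studies = 4, seed = 2,
                      cd8_depleted = TRUE)
  res <- run_trial(des)
  expect_equal(unname(res$median_rate), 0)
  # even the strongest infiltrator cannot reject without effector influx
  expect_false(rtimmune:::.simulate_responder(0.1, des, p0, pk0, fast_opts))
})

test_that("parameter-uncertainty propagation widens the study-level spread", {
  des_fix <- trial_design(sched_combo7, n_animals = 40, n_studies = 12, seed = 5)
  des_unc <- trial_design(sched_combo7, n_animals = 40, n_studies = 12, seed = 5,
                          propagate_uncertainty = TRUE)
  fixed <- run_trial(des_fix)
  unc <- run_trial(des_unc)
  expect_gte(diff(unc$ci90), diff(fixed$ci90))
  expect_identical(run_trial(des_unc)$rates, unc$rates)
})

test_that("scenario presets encode the calibration-study arms", {
  s19 <- scenario_presets("combo_seq2_day19")
  expect_equal(s19$schedule$rt$day, 7:11)
  expect_equal(unique(s19$schedule$rt$gray), 2)
  expect_equal(min(s19$schedule$mab$day), 19)
  expect_equal(scenario_presets("responder_vs_nonresponder")$s_l,
               c(responder = 1.77, typical = 6.95, nonresponder = 22.63))
  ctrl <- scenario_presets("control")$schedule
  expect_equal(nrow(ctrl$rt), 0)
  expect_equal(nrow(ctrl$mab), 0)
  expect_equal(treatment_start(ctrl), 0)
  dep <- scenario_presets("cd8_depletion")$schedule
  expect_equal(dep$cd8_depletion_day, 7)
  expect_error(scenario_presets("miracle_cure"), "control, aPDL1_only")
})

test_that("sweep grids enumerate the scheduling cells", {
  g <- sweep_grid()
  expect_equal(nrow(g), 5 * 3 * 6 + 5)  # regimens x starts x mab-days + mab-only
  expect_setequal(unique(g$type), c("combination", "rt_only", "mab_only"))
  expect_true(all(is.na(g$mab_day[g$type == "rt_only"])))
  expect_true(all(g$rt_regimen[g$type == "mab_only"] == "none"))
})

test_that("schedule config files round-trip, including the 3qw shorthand", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "rt:",
    "  - {day: 7, gray: 2}",
    "  - {day: 8, gray: 2}",
    "mab: {regimen: 3qw, start_day: 7, weeks: 2}"
  ), f)
  sch <- read_schedule(f)
  expect_equal(sch$rt$day, c(7, 8))
  expect_equal(nrow(sch$mab), 6)
  unlink(f)
  f2 <- tempfile(fileext = ".json")
  write_schedule(sched_combo7, f2)
  back <- read_schedule(f2)
  expect_equal(back$rt, sched_combo7$rt)
  expect_equal(back$mab, sched_combo7$mab)
  unlink(f2)
})
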