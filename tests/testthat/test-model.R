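test_that("extinction is a fixed point of the dynamics", {
  s <- stats::setNames(numeric(9), state_names())
  d <- cic_rhs(0, s, p0)
  expect_equal(unname(d), numeric(9))
})

test_that("growth vanishes at carrying capacity", {
  s <- initial_state(TV = p0$TV_max)
  d <- cic_rhs(0, s, p0)
  expect_equal(d[["TV"]], -p0$d0 * p0$TV_max)
})

test_that("small tumors grow exponentially with doubling time ln2/r", {
  # immune arm and spontaneous death off: the pure logistic term at TV << K
  p <- model_params(k_LN = 0, d0 = 0)
  tr <- simulate_individual(p, treatment_schedule(), pk = pk0, t_end = 5,
                            dt = 0.1)
  tv <- trajectory_at(tr, c(0, 1.733), "TV")
  expect_equal(tv[2] / tv[1], 2, tolerance = 2e-3)  # ln2/0.4 = 1.733 days
})

test_that("without T-cell influx the tumor follows the logistic closed form", {
  p <- model_params(k_LN = 0)
  tr <- simulate_individual(p, treatment_schedule(), pk = pk0, t_end = 40,
                            dt = 0.5)
  tt <- c(5, 10, 20, 30, 40)
  expect_equal(trajectory_at(tr, tt, "TV"),
               logistic_tv(tt, 0.5, p$r, p$TV_max, p$d0),
               tolerance = 5e-3)
})

test_that("driving functions obey their identities and bounds", {
  s <- initial_state(TV = 10)
  # no suppression: IAR is exactly 1
  d <- compute_driving(s, occupancy = 0, p0)
  expect_equal(d$IAR, 1)
  expect_equal(d$supp_pdl, 0)
  expect_equal(d$supp_isc, 0)
  # full blockade removes the PD-L1 axis regardless of expression
  s2 <- initial_state(TV = 10, PDL1 = 1, ISC = 0.5)
  expect_equal(compute_driving(s2, occupancy = 1, p0)$supp_pdl, 0)
  # at full PD-L1 expression and no blockade, IAR = 1 - w_pdl;
  # the axis never explains more than ~25% of total suppression
  s3 <- initial_state(TV = 10, PDL1 = 1)
  d3 <- compute_driving(s3, occupancy = 0, p0)
  expect_equal(d3$IAR, 1 - p0$w_pdl)
  expect_lte(p0$w_pdl, 0.25)
  expect_error(compute_driving(s, occupancy = 1.5, p0), "\\[0, 1\\]")
  s_bad <- initial_state(TV = 10)
  s_bad[["dTeff"]] <- -1
  expect_error(compute_driving(s_bad, 0, p0), "negative state")
})

test_that("suppression is monotone in PDL1 and ISC, relieved by occupancy", {
  base <- initial_state(TV = 50)
  grid <- seq(0, 1, by = 0.1)
  iar_pdl <- vapply(grid, function(v) {
    s <- base; s[["PDL1"]] <- v
    compute_driving(s, 0.2, p0)$IAR
  }, numeric(1))
  iar_isc <- vapply(grid, function(v) {
    s <- base; s[["ISC"]] <- v
    compute_driving(s, 0.2, p0)$IAR
  }, numeric(1))
  s <- base; s[["PDL1"]] <- 0.8; s[["ISC"]] <- 0.3
  iar_occ <- vapply(grid, function(o) compute_driving(s, o, p0)$IAR, numeric(1))
  expect_true(all(diff(iar_pdl) <= 0))
  expect_true(all(diff(iar_isc) <= 0))
  expect_true(all(diff(iar_occ) >= 0))
})

test_that("states stay non-negative and below the carrying capacity everywhere", {
  scens <- list(treatment_schedule(), sched_rt7, sched_apdl7, sched_combo7,
                treatment_schedule(rt = rt_fractions("1x10", 12),
                                   mab = mab_regimen_3qw(5)))
  for (sch in scens) {
    for (s_l in c(0.5, 8.89, 60)) {
      tr <- sim_fast(sch, S_L = s_l)
      m <- as.matrix(tr$data[, state_names()])
      expect_true(all(m >= 0))
      expect_true(all(tr$data$TV_tot <= p0$TV_max * (1 + 1e-6)))
      expect_true(all(tr$data$IAR >= 0 & tr$data$IAR <= 1))
      expect_true(all(tr$data$PDL1 <= 1 + 1e-9))
    }
  }
})

test_that("halving solver tolerances leaves day-50 volume unchanged to 0.1%", {
  for (sch in list(treatment_schedule(), sched_combo7)) {
    a <- simulate_individual(p0, sch, pk = pk0, t_end = 57,
                             rtol = 1e-8, atol = 1e-10, dt = 0.5)
    b <- simulate_individual(p0, sch, pk = pk0, t_end = 57,
                             rtol = 5e-9, atol = 5e-11, dt = 0.5)
    va <- trajectory_at(a, 50, "TV_tot")
    vb <- trajectory_at(b, 50, "TV_tot")
    expect_lt(abs(va - vb) / max(va, 1e-6), 1e-3)
  }
})

test_that("a zero-dose schedule reproduces the untreated trajectory", {
  # the event restart leaves the solution unchanged up to solver accuracy
  zero <- treatment_schedule(rt = data.frame(day = 7, gray = 0))
  expect_equal(sim_fast(zero)$data$TV_tot, sim_fast()$data$TV_tot,
               tolerance = 1e-5)
})

test_that("the integrator agrees with the exported right-hand side", {
  # independent route: feed cic_rhs directly to the solver
  func <- function(t, y, parms) {
    list(unname(cic_rhs(t, stats::setNames(y, state_names()), p0)))
  }
  sol <- deSolve::lsoda(initial_state(), seq(0, 20, 0.5), func, NULL,
                        rtol = 1e-8, atol = 1e-10)
  tr <- simulate_individual(p0, treatment_schedule(), pk = pk0, t_end = 20,
                            dt = 0.5, rtol = 1e-8, atol = 1e-10)
  expect_equal(tr$data$TV[tr$data$time %in% sol[, 1]], unname(sol[, "TV"]),
               tolerance = 1e-6)
  expect_equal(tr$data$dTeff[tr$data$time %in% sol[, 1]], unname(sol[, "dTeff"]),
               tolerance = 1e-5)
})

test_that("control, RT-only and combination reproduce the expected kinetics", {
  ctrl <- sim_fast(t_end = 57)
  # transient immune activation is abrogated: activation falls to a low
  # plateau (~5%) by day 20 and the tumor grows progressively
  expect_lt(trajectory_at(ctrl, 20, "IAR"), 0.10)
  expect_gt(max(ctrl$data$IAR[ctrl$data$time >= 3 & ctrl$data$time <= 14]), 0.5)
  tv <- trajectory_at(ctrl, c(10, 20, 30, 45), "TV_tot")
  expect_true(all(diff(tv) > 0))
  # RT alone: transient control with regrowth under way by days 15-20
  rt <- sim_fast(sched_rt7, t_end = 57)
  expect_lt(trajectory_at(rt, 14, "TV_tot"), trajectory_at(ctrl, 14, "TV_tot"))
  expect_gt(trajectory_at(rt, 20, "TV_tot"), trajectory_at(rt, 13, "TV_tot"))
  expect_gt(trajectory_at(rt, 50, "TV_tot"), 100)
  # concurrent combination in a high-infiltration individual restores
  # activation to ~100% and rejects the tumor
  cmb <- sim_fast(sched_combo7, S_L = 1.77, t_end = 57)
  expect_gte(max(cmb$data$IAR[cmb$data$time >= 7]), 0.95)
  expect_lt(trajectory_at(cmb, 57, "TV_tot"), 10)
})

test_that("trajectories export as tidy CSV and interpolate safely", {
  tr <- sim_fast(t_end = 10)
  f <- tempfile(fileext = ".csv")
  export_trajectory(tr, f)
  x <- read.csv(f)
  expect_identical(names(x), c("time_days", "variable", "value", "unit"))
  expect_setequal(unique(x$variable), setdiff(names(tr$data), "time"))
  expect_equal(unique(x$unit[x$variable == "TV_tot"]), "uL")
  unlink(f)
  expect_error(trajectory_at(tr, 11, "TV_tot"), "outside")
  expect_error(trajectory_at(tr, 5, "nope"), "unknown variable")
  expect_error(simulate_individual(p0, sched_combo7, pk = pk0, t_end = 10),
               "within")
})
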