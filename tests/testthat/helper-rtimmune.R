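# shared fixtures: default records and the coarse solver settings used where
# a test exercises behavior rather than numerical accuracy
p0 <- model_params()
pk0 <- pk_params()
iav0 <- iav_params()

fast_opts <- list(dt = 0.5, rtol = 1e-6, atol = 1e-8)

sim_fast <- function(schedule = treatment_schedule(), S_L = p0$S_L,
                     t_end = 57, params = p0) {
  simulate_individual(params, schedule, S_L = S_L, pk = pk0, t_end = t_end,
                      dt = fast_opts$dt, rtol = fast_opts$rtol,
                      atol = fast_opts$atol)
}

sched_combo7 <- treatment_schedule(rt = rt_fractions("5x2", 7),
                                   mab = mab_regimen_3qw(7))
sched_rt7 <- treatment_schedule(rt = rt_fractions("5x2", 7))
sched_apdl7 <- treatment_schedule(mab = mab_regimen_3qw(7))

# analytic logistic growth with spontaneous death folded in:
# dX/dt = r X (1 - X/K) - d0 X  ==  logistic with rate r-d0, capacity K(1-d0/r)
logistic_tv <- function(t, x0, r, K, d0) {
  rr <- r - d0
  KK <- K * (1 - d0 / r)
  KK / (1 + (KK / x0 - 1) * exp(-rr * t))
}
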