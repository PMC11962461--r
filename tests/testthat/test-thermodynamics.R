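test_that("Shannon entropy handles delta, uniform, zeros and bad input", {
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(0.25, 4)), log(4))
  expect_equal(shannon_entropy(c(0.5, 0.5, 0, 0)), log(2))   # 0 ln 0 = 0
  expect_equal(shannon_entropy(c(0.5, 0.5, -1e-13)), log(2)) # round-off clip
  expect_error(shannon_entropy(c(0.5, -0.1)), "negative probability")
})

test_that("enthalpy is the energy-weighted population sum", {
  expect_equal(enthalpy(c(0, 1, 0), c(10, 20, 30)), 20)
  expect_equal(enthalpy(rep(0.25, 4), rep(120, 4)), 120)
  ## Boltzmann state of the two-level system at 300 K
  pi2 <- exp(-1) / (1 + exp(-1))
  expect_equal(enthalpy(c(1 - pi2, pi2), c(0, kBT300)), kBT300 * pi2,
               tolerance = 1e-12)
  expect_equal(kBT300 * pi2, 56.1, tolerance = 1e-3)
  expect_error(enthalpy(c(1, 0), c(1, 2, 3)), "length mismatch")
})

test_that("free-energy series is zero at t = 0 and reaches the Boltzmann limit", {
  net <- two_state_net(E2 = kBT300)
  traj <- propagate(net$rates, c(1, 0), c(0, 10^seq(-2, 5, length.out = 120)))
  th <- free_energy_series(traj, net)
  expect_equal(th$dH_cm1[1], 0)
  expect_equal(th$minus_TdS_cm1[1], 0)
  expect_equal(th$dG_cm1[1], 0)
  ## analytic end point: dG(inf) = G(pi) - G(delta on low state)
  pi2 <- exp(-1) / (1 + exp(-1))
  S_eq <- -( (1 - pi2) * log(1 - pi2) + pi2 * log(pi2) )
  dG_inf <- kBT300 * pi2 - kBT300 * S_eq
  nt <- nrow(th)
  expect_equal(th$dH_cm1[nt], kBT300 * pi2, tolerance = 1e-9)
  expect_equal(th$dG_cm1[nt], dG_inf, tolerance = 1e-9)
  ## uphill start in the low state: dH(inf) is the analytic Boltzmann gain
  expect_gt(min(th$dH_cm1), -1e-12)
})

test_that("unit consistency: -T dS column equals -T * kB * dS exactly", {
  mim <- generate_mimic(mini_spec(seed = 51))
  ic <- numeric(64); ic[10] <- 1
  traj <- propagate(build_generator(scenario(mim)), ic, default_times(n = 80))
  th <- free_energy_series(traj, mim)
  expect_identical(th$minus_TdS_cm1,
                   -300 * 0.695035 * (th$S_kB - th$S_kB[1]))
  expect_identical(th$dG_cm1, th$dH_cm1 + th$minus_TdS_cm1)
})

test_that("closed-network free energy obeys the H-theorem and the KL identity", {
  kBT <- kBT300
  for (seed in c(52, 53)) {
    mim <- generate_mimic(mini_spec(seed = seed))
    ic <- numeric(64); ic[seed %% 64 + 1] <- 1
    traj <- propagate(mim$rates, ic, default_times(n = 250))
    th <- free_energy_series(traj, mim)
    expect_lt(max(diff(th$dG_cm1)), 1e-10 * kBT)
    ## Delta G(inf) = -kBT D(p0 || pi)
    pi <- boltzmann_equilibrium(mim)
    kl <- sum(ic[ic > 0] * log(ic[ic > 0] / pi[ic > 0]))
    expect_equal(th$dG_cm1[nrow(th)], -kBT * kl, tolerance = 1e-6)
  }
})

test_that("entropy stays within [0, ln N] in raw and conditional modes", {
  mim <- generate_mimic(mini_spec(seed = 54))
  gen <- build_generator(scenario(mim, losses = loss_spec()))
  ic <- numeric(64); ic[33] <- 1
  traj <- propagate(gen, ic, default_times(n = 150))
  for (mode in c("raw", "conditional")) {
    th <- free_energy_series(traj, mim, mode = mode)
    expect_gte(min(th$S_kB), 0)
    expect_lte(max(th$S_kB), log(64))
  }
})

test_that("contraction time: boundary rules and golden-section refinement", {
  ## uniform start on a closed 2-state system: entropy can only fall -> 0
  net <- two_state_net(E2 = kBT300)
  traj <- propagate(net$rates, c(0.5, 0.5), c(0, 10^seq(-2, 4, length.out = 80)))
  th <- free_energy_series(traj, net)
  expect_equal(contraction_time(th)$time_ps, 0)
  ## grid truncated before the entropy maximum is an error, not a guess
  traj2 <- propagate(net$rates, c(1, 0), c(0, 0.01, 0.02, 0.05))
  th2 <- free_energy_series(traj2, net)
  expect_error(contraction_time(th2), "extend time grid")
  ## delta start on a trapped network spreads first: contraction time > 0
  mim <- generate_mimic(mini_spec(seed = 55))
  gen <- build_generator(scenario(mim))
  ic <- numeric(64); ic[25] <- 1
  traj3 <- propagate(gen, ic)
  th3 <- free_energy_series(traj3, mim)
  ct <- contraction_time(th3, gen, ic)
  expect_gt(ct$time_ps, 0)
  ## refined argmax vs dense-grid brute force
  coarse <- th3$time_ps[which.max(th3$S_kB)]
  oracle <- dense_grid_contraction(gen, ic, t_max = 4 * coarse, n = 2e4)
  expect_lt(abs(ct$time_ps - oracle$time), 0.2)
  expect_equal(ct$entropy_max_kB, oracle$entropy, tolerance = 1e-6)
})

test_that("enthalpy peak: downhill funnel peaks at zero, uphill start peaks inside", {
  fun <- generate_control_landscape("funnel", n_states = 10, seed = 5)
  gen <- build_generator(scenario(fun, trap_spec(donor_state_ids = "s10")))
  ic <- numeric(10); ic[1] <- 1                    # top of the funnel
  traj <- propagate(gen, ic, default_times(n = 150))
  th <- free_energy_series(traj, fun)
  pk <- enthalpy_peak(th)
  expect_equal(pk$time_ps, 0)
  expect_equal(pk$dH_peak_cm1, 0)
  ## start at the global energy minimum of a closed network: uphill first
  mim <- generate_mimic(mini_spec(seed = 56))
  icm <- numeric(64); icm[which.min(mim$states$energy_cm1)] <- 1
  trajm <- propagate(mim$rates, icm, default_times(n = 250))
  thm <- free_energy_series(trajm, mim)
  pkm <- enthalpy_peak(thm, mim$rates, icm, E = mim$states$energy_cm1)
  expect_gt(pkm$time_ps, 0)
  expect_gt(pkm$dH_peak_cm1, 0)
  expect_true(all(thm$dH_cm1 >= -1e-9))
})

test_that("flat landscape has identically zero enthalpy change", {
  flat <- generate_control_landscape("flat", n_states = 9, seed = 6)
  ic <- numeric(9); ic[1] <- 1
  traj <- propagate(flat$rates, ic, default_times(n = 100))
  th <- free_energy_series(traj, flat)
  expect_lt(max(abs(th$dH_cm1)), 1e-9)
})

test_that("thermo TSV output round-trips numerically", {
  mim <- generate_mimic(mini_spec(seed = 57))
  ic <- numeric(64); ic[3] <- 1
  traj <- propagate(build_generator(scenario(mim)), ic, default_times(n = 50))
  th <- free_energy_series(traj, mim)
  path <- tempfile(fileext = ".tsv")
  write_thermo(th, path)
  back <- read.delim(path)
  expect_equal(back$dG_cm1, th$dG_cm1, tolerance = 1e-6)
})
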