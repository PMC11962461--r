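test_that("propagation matches the two-state closed form to 1e-9", {
  net <- two_state_net()                      # E2 = 208.51 cm^-1
  ic <- c(1, 0)
  times <- c(0, 10^seq(-2, 4, length.out = 60))
  traj <- propagate(net$rates, ic, times)
  expect_identical(traj$populations[1, ], ic)  # t = 0 row is the IC, exactly
  expect_lt(max(abs(traj$populations[, 2] - two_state_p2(times))), 1e-9)
})

test_that("closed detailed-balanced networks relax to Boltzmann", {
  net <- generate_mimic(mini_spec(seed = 31))
  ic <- numeric(n_states(net)); ic[17] <- 1
  traj <- propagate(net$rates, ic, c(0, 1e6))
  expect_lt(max(abs(traj$populations[2, ] - boltzmann_equilibrium(net))), 1e-8)
})

test_that("propagate validates its inputs", {
  net <- two_state_net()
  expect_error(propagate(net$rates, c(0.4, 0.4), c(0, 1)), "probability")
  expect_error(propagate(net$rates, c(1, 0), c(1, 0.5)), "ascending")
  Kbad <- net$rates; Kbad[1, 1] <- NaN
  expect_error(propagate(Kbad, c(1, 0), c(0, 1)), "non-finite")
})

test_that("pigment initial conditions: delta, tie-break, and uniform Chl a", {
  net <- generate_control_landscape("flat", n_states = 8, seed = 1)
  ic <- initial_condition_for_pigment(net, "site_03")
  expect_equal(unname(ic), c(0, 0, 1, 0, 0, 0, 0, 0))
  ## exciton basis: delta on the state most localized on the named pigment
  map <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2,
                dimnames = list(NULL, c("pigA", "pigB")))
  net2 <- two_state_net()
  expect_equal(unname(initial_condition_for_pigment(net2, "pigA", map)),
               c(1, 0))
  ## exact tie: lowest index wins, with a warning
  map_tie <- matrix(0.5, 2, 2, dimnames = list(NULL, c("pigA", "pigB")))
  expect_warning(ic_t <- initial_condition_for_pigment(net2, "pigA", map_tie),
                 "ambiguous")
  expect_equal(unname(ic_t), c(1, 0))
  ## uniform over Chl a states
  mim <- generate_mimic(mini_spec(seed = 32))
  ica <- initial_condition_chl_a(mim)
  na <- sum(mim$states$is_chl_a)
  expect_equal(sort(unique(ica)), c(0, 1 / na))
  expect_equal(sum(ica > 0), na)
})

test_that("splitting probabilities: symmetry, single trap, and sink census", {
  mim <- generate_mimic(mini_spec(seed = 33))
  gen <- build_generator(scenario(mim), require_absorbing = TRUE)
  perm <- mirror_permutation(mim)
  ## mirror-midline start: equal mass on a mirrored pair of states
  j <- which(mim$states$subunit == "CP43")[1]
  ic <- numeric(n_states(mim)); ic[j] <- 0.5; ic[perm[j]] <- 0.5
  f <- splitting_probabilities(gen, ic)
  expect_equal(f$p_trap1, 0.5, tolerance = 1e-9)
  expect_equal(f$p_trap2, 0.5, tolerance = 1e-9)
  expect_equal(f$p_trap1 + f$p_trap2 + f$p_fluor + f$p_nonrad, 1,
               tolerance = 1e-9)
  ## probabilities over all four sinks still sum to one with losses on
  genl <- build_generator(scenario(mim, losses = loss_spec()))
  fl <- splitting_probabilities(genl, ic, monomer = 1)
  expect_equal(fl$p_trap1 + fl$p_trap2 + fl$p_fluor + fl$p_nonrad, 1,
               tolerance = 1e-9)
  expect_equal(fl$same_monomer_fraction,
               fl$p_trap1 / (fl$p_trap1 + fl$p_trap2))
})

test_that("splitting errors name the problem when nothing absorbs", {
  mim <- generate_mimic(mini_spec(seed = 34))
  g0 <- build_generator(scenario(mim, traps = NULL))
  ic <- numeric(n_states(mim)); ic[1] <- 1
  expect_error(splitting_probabilities(g0, ic), "no absorbing sink")
  ## isolated recurrent class: two components, trap only in one
  st <- data.frame(state_id = c("a", "b", "c", "d"),
                   subunit = c("RC", "ANT", "island", "island"),
                   monomer = 1L, energy_cm1 = 15000)
  K <- matrix(0, 4, 4)
  K[1, 2] <- K[2, 1] <- 1          # a <-> b
  K[3, 4] <- K[4, 3] <- 1          # c <-> d, disconnected
  net <- kinetic_network(st, K)
  gen <- build_generator(scenario(net, trap_spec(donor_state_ids = "a")))
  expect_error(splitting_probabilities(gen, c(0, 0, 1, 0)) ,
               "singular transient")
})

test_that("MFPT: exact small cases and agreement with survival quadrature", {
  ## single transient state, trap rate 1 -> 1 ps
  st1 <- data.frame(state_id = "a", subunit = "RC", monomer = 1L,
                    energy_cm1 = 15000)
  net1 <- kinetic_network(st1, matrix(0, 1, 1))
  g1 <- build_generator(scenario(net1, trap_spec(trap_rate = 1)))
  expect_equal(mean_first_passage_time(g1, 1), 1, tolerance = 1e-12)
  ## irreversible 3-state chain at unit rates: stage means add to 3 ps
  st3 <- data.frame(state_id = c("s1", "s2", "s3"),
                    subunit = c("ANT", "ANT", "RC"), monomer = 1L,
                    energy_cm1 = 15000)
  K3 <- matrix(0, 3, 3); K3[2, 1] <- 1; K3[3, 2] <- 1
  net3 <- kinetic_network(st3, K3)
  g3 <- build_generator(scenario(net3, trap_spec(donor_state_ids = "s3",
                                                 trap_rate = 1)))
  expect_equal(mean_first_passage_time(g3, c(1, 0, 0)), 3, tolerance = 1e-12)
  ## random networks: linear solve vs quadrature of the survival curve
  for (seed in c(41, 42)) {
    net <- random_two_trap_net(12, seed)
    gen <- build_generator(scenario(net), require_absorbing = TRUE)
    ic <- numeric(12); ic[6] <- 1
    tau <- mean_first_passage_time(gen, ic)
    expect_equal(tau, survival_quadrature(gen, ic), tolerance = 1e-3)
  }
  ## refuses to run with loss channels active
  mim <- generate_mimic(mini_spec(seed = 35))
  genl <- build_generator(scenario(mim, losses = loss_spec()))
  expect_error(mean_first_passage_time(genl, rep(1 / 64, 64)),
               "without loss channels")
})

test_that("excitation lifetime: closed forms and quadrature agreement", {
  st1 <- data.frame(state_id = "a", subunit = "X", monomer = 1L,
                    energy_cm1 = 15000, dipole_sq = 1)
  net1 <- kinetic_network(st1, matrix(0, 1, 1))
  ## only nonradiative loss at (2 ns)^-1 -> 2000 ps
  g_nr <- build_generator(scenario(net1, traps = NULL,
                                   losses = loss_spec(mean_fl_lifetime_ns = Inf)))
  lt <- excitation_lifetime(g_nr, 1)
  expect_equal(lt$mean_residence_ps, 2000, tolerance = 1e-9)
  expect_equal(lt$tail_fit_ps, 2000, tolerance = 1e-6)
  ## two parallel sinks add their rates
  g_both <- build_generator(scenario(net1, traps = NULL, losses = loss_spec()))
  lt2 <- excitation_lifetime(g_both, 1)
  expect_equal(lt2$mean_residence_ps, 1 / (1e-3 / 16 + 5e-4), tolerance = 1e-9)
  ## mimic with traps + losses: mean residence vs quadrature within 0.1%
  mim <- generate_mimic(mini_spec(seed = 36))
  gen <- build_generator(scenario(mim, losses = loss_spec()))
  ic <- initial_condition_chl_a(mim)
  lt3 <- excitation_lifetime(gen, ic)
  expect_equal(lt3$mean_residence_ps, survival_quadrature(gen, ic),
               tolerance = 1e-3)
  expect_error(excitation_lifetime(build_generator(scenario(mim, traps = NULL)),
                                   ic), "diverges")
})

test_that("Gillespie is seed-deterministic and matches exact results", {
  st1 <- data.frame(state_id = "a", subunit = "RC", monomer = 1L,
                    energy_cm1 = 15000)
  net1 <- kinetic_network(st1, matrix(0, 1, 1))
  g1 <- build_generator(scenario(net1, trap_spec(trap_rate = 0.5)))
  sim <- gillespie_simulate(g1, 1, n_traj = 4000, seed = 7)
  expect_equal(sim$fate_probs[["trap1"]], 1)
  expect_lt(abs(sim$mean_fp_ps - 2), 3 * sim$se_fp_ps)
  sim2 <- gillespie_simulate(g1, 1, n_traj = 4000, seed = 7)
  expect_identical(sim$fate_counts, sim2$fate_counts)
  expect_identical(sim$mean_fp_ps, sim2$mean_fp_ps)
  ## 8-state network: fate frequencies vs committor linear solve
  net <- random_two_trap_net(8, seed = 43)
  gen <- build_generator(scenario(net), require_absorbing = TRUE)
  ic <- numeric(8); ic[4] <- 1
  f <- splitting_probabilities(gen, ic)
  sim3 <- gillespie_simulate(gen, ic, n_traj = 1e4, seed = 11)
  for (s in c("trap1", "trap2")) {
    p_exact <- if (s == "trap1") f$p_trap1 else f$p_trap2
    se <- max(sim3$fate_se[[s]], 1e-4)
    expect_lt(abs(sim3$fate_probs[[s]] - p_exact), 3 * se + 3e-4)
  }
  expect_lt(abs(sim3$mean_fp_ps - mean_first_passage_time(gen, ic)),
            3 * sim3$se_fp_ps)
})

test_that("survival is monotone non-increasing whenever a sink is active", {
  mim <- generate_mimic(mini_spec(seed = 37))
  gen <- build_generator(scenario(mim, losses = loss_spec()))
  ic <- numeric(64); ic[50] <- 1
  traj <- propagate(gen, ic, default_times(n = 150))
  Nsurv <- rowSums(traj$populations)
  expect_true(all(diff(Nsurv) <= 1e-12))
})
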