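# ML rate estimation, dissociation constants, upper bounds, bootstrap.

census_from_counts <- function(N, t, sites = "K1", conc = 1) {
  states <- kgate:::all_state_labels(sites)
  dimnames(N) <- list(states, states)
  names(t) <- states
  structure(list(states = states, sites = sites, N = N, t = t,
                 n_monomers = 1L, dt = 1, concentration = conc,
                 per_monomer = list(list(N = N, t = t)),
                 compound_fraction = 0),
            class = "transition_census")
}

test_that("the ML rate is transition count over origin dwell time", {
  cen <- census_from_counts(matrix(c(0L, 6L, 4L, 0L), 2, byrow = TRUE),
                            c(3, 2))
  model <- estimate_rate_matrix(cen)
  expect_equal(unname(model$K["apo", "K1"]), 2)
  expect_equal(unname(model$K["K1", "apo"]), 2)
  # zero counts with positive dwell: defined zero rate, flagged "no events"
  cen0 <- census_from_counts(matrix(0L, 2, 2), c(3, 2))
  m0 <- estimate_rate_matrix(cen0)
  expect_equal(unname(m0$K["apo", "K1"]), 0)
  expect_true(m0$no_events["apo", "K1"])
  # counts out of a zero-dwell state are inconsistent
  expect_error(estimate_rate_matrix(
    census_from_counts(matrix(c(0L, 1L, 0L, 0L), 2, byrow = TRUE), c(0, 2))),
    "inconsistent")
})

test_that("K_D is off rate over second-order on rate, in mM", {
  # on 2/us at 1 M, off 0.5/us -> K_D = 0.5/2 M = 250 mM
  cen <- census_from_counts(matrix(c(0L, 20L, 10L, 0L), 2, byrow = TRUE),
                            c(10, 20))
  kd <- dissociation_constants(cen, "K1", n_boot = 0)
  expect_equal(kd$kd_mM, 250)
  expect_equal(kd$k_off, 0.5)
  expect_equal(kd$k_on2, 2)
})

test_that("estimator is invariant to monomer concatenation order", {
  out <- gen_binding_traj(two_state_spec(20, k_off = 1), duration = 30,
                          dt = 0.002, n_monomers = 4, seed = 47)
  occ <- lapply(out$trajectories, discretize_trajectory)
  kd_ab <- dissociation_constants(transition_census(occ), "K1", n_boot = 0)
  kd_ba <- dissociation_constants(transition_census(rev(occ)), "K1",
                                  n_boot = 0)
  expect_equal(kd_ab$kd_mM, kd_ba$kd_mM)
})

test_that("generator K_D of 8 mM is recovered within the bootstrap CI", {
  spec <- two_state_spec(8, concentration_M = 1, k_off = 1)
  out <- gen_binding_traj(spec, duration = 16, dt = 2e-4, n_monomers = 8,
                          seed = 53)
  occ <- lapply(out$trajectories, discretize_trajectory)
  cen <- transition_census(occ)
  kd <- dissociation_constants(cen, "K1", n_boot = 500, seed = 59)
  expect_gt(kd$n_on, 80)
  expect_gt(8, kd$ci[1])
  expect_lt(8, kd$ci[2])
  expect_lt(abs(kd$kd_mM - 8) / 8, 0.3)
})

test_that("bootstrap SD shrinks roughly as 1/sqrt(n_monomers)", {
  out <- gen_binding_traj(two_state_spec(100, k_off = 1), duration = 50,
                          dt = 0.002, n_monomers = 3, seed = 61)
  occ <- lapply(out$trajectories, discretize_trajectory)
  cen1 <- transition_census(occ)
  cen4 <- transition_census(rep(occ, 4))
  s1 <- dissociation_constants(cen1, "K1", n_boot = 400, seed = 2)$sd
  s4 <- dissociation_constants(cen4, "K1", n_boot = 400, seed = 2)$sd
  expect_lt(s4, s1)
  expect_lt(abs(s4 / (s1 / 2) - 1), 0.35)
})

test_that("upper-bound construction reproduces the unit case and scales", {
  # one hypothetical escape in 1 us, observed relocation rate 1/us,
  # reference K_D 30 mM -> bound 30 mM
  sites <- c("K1", "K2")
  states <- kgate:::all_state_labels(sites)
  N <- matrix(0L, 4, 4, dimnames = list(states, states))
  N["K2", "K1"] <- 2L
  t <- stats::setNames(c(1, 1, 2, 0), states)
  cen <- structure(list(states = states, sites = sites, N = N, t = t,
                        n_monomers = 1L, dt = 1, concentration = 1,
                        per_monomer = list(list(N = N, t = t)),
                        compound_fraction = 0),
                   class = "transition_census")
  ub <- kd_upper_bound(cen, "K1", "K2", reference_kd_mM = 30)
  expect_equal(ub$bound_mM, 30)
  # doubling the bound-state dwell time halves the bound
  cen2 <- cen
  cen2$t["K1"] <- 2
  expect_equal(kd_upper_bound(cen2, "K1", "K2", 30)$bound_mM, 15)
  # no observed relocations -> undefined
  cen3 <- cen
  cen3$N["K2", "K1"] <- 0L
  expect_error(kd_upper_bound(cen3, "K1", "K2", 30), "relocations")
})

test_that("upper bound exceeds the true K_D on a relay system with rare escape", {
  # target K1 tight (K_D 5 mM), scavenger K2 loose (30 mM), escape only
  # via relocation back to K2, rare within the simulated time
  k_in <- 0.1             # K2 -> K1 relocation rate
  k_out <- k_in * 5 / 30  # detailed balance on the relocation step
  spec <- rate_spec(c("K1", "K2"),
                    c("apo->K2" = 1000 / 30, "K2->apo" = 1,
                      "K2->K1" = k_in, "K1->K2" = k_out))
  out <- gen_binding_traj(spec, duration = 6, dt = 5e-4, n_monomers = 10,
                          seed = 67)
  cen <- transition_census(lapply(out$trajectories, discretize_trajectory))
  ub <- kd_upper_bound(cen, "K1", "K2", reference_kd_mM = 30)
  expect_gte(ub$bound_mM, 5)
})

test_that("bootstrap machinery matches the analytic standard error", {
  set.seed(71)
  x <- rnorm(50)
  bs <- bootstrap_statistic(x, function(u) mean(unlist(u)), n_boot = 2000,
                            seed = 73)
  expect_lt(abs(bs$sd / (stats::sd(x) / sqrt(50)) - 1), 0.10)
  # constant statistic -> zero SD; same seed -> identical output
  const <- bootstrap_statistic(x, function(u) 42, n_boot = 50, seed = 1)
  expect_equal(const$sd, 0)
  expect_identical(bootstrap_statistic(x, function(u) mean(unlist(u)),
                                       n_boot = 100, seed = 5)$boot,
                   bootstrap_statistic(x, function(u) mean(unlist(u)),
                                       n_boot = 100, seed = 5)$boot)
})
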