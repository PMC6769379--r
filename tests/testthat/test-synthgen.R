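# Ground-truth generators: exact jump sampling, emission separation,
# Crooks-consistent works, Boltzmann umbrella windows, capacitor and
# binding-curve models.

test_that("absorbing apo spec stays unbound for the whole trace", {
  spec <- suppressWarnings(
    rate_spec("K1", stats::setNames(numeric(0), character(0))))
  out <- gen_binding_traj(spec, duration = 5, dt = 0.01, seed = 1)
  expect_true(all(out$trajectories[[1]]$K1 > spec$threshold))
  expect_true(all(out$hidden[[1]] == 0L))
})

test_that("symmetric two-state chain spends half its time bound", {
  spec <- rate_spec("K1", c("apo->K1" = 1, "K1->apo" = 1))
  out <- gen_binding_traj(spec, duration = 1000, dt = 0.01, seed = 42)
  frac <- mean(out$hidden[[1]] == 1L)
  # ~1000 uncorrelated dwell cycles -> SE of the bound fraction ~ 0.5/sqrt(500)
  expect_lt(abs(frac - 0.5), 3 * 0.5 / sqrt(500))
})

test_that("emission keeps bound and unbound distances on opposite sides of the threshold", {
  spec <- rate_spec("K1", c("apo->K1" = 2, "K1->apo" = 2))
  out <- gen_binding_traj(spec, duration = 50, dt = 0.005, seed = 7)
  d <- out$trajectories[[1]]$K1
  bound <- out$hidden[[1]] == 1L
  expect_true(all(d[bound] <= spec$threshold))
  expect_true(all(d[!bound] > spec$threshold))
})

test_that("generators are bit-reproducible given a seed", {
  a <- gen_binding_traj(two_state_spec(500), 5, 0.005, n_monomers = 2,
                        seed = 9)
  b <- gen_binding_traj(two_state_spec(500), 5, 0.005, n_monomers = 2,
                        seed = 9)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(gen_work_samples(5, 2, 50, 50, seed = 3)$forward,
                   gen_work_samples(5, 2, 50, 50, seed = 3)$forward)
  p <- harmonic_pmf(20)
  expect_identical(gen_langevin_trace(p, 1, 0.001, 500, seed = 4),
                   gen_langevin_trace(p, 1, 0.001, 500, seed = 4))
})

test_that("event-driven jumps and fine-dt discretization agree on occupation", {
  spec <- rate_spec("K1", c("apo->K1" = 3, "K1->apo" = 1))
  out <- gen_binding_traj(spec, duration = 400, dt = 0.002, seed = 11)
  # occupation fraction from the frame grid vs the exact jump record
  frame_frac <- mean(out$hidden[[1]] == 1L)
  j <- out$jumps[[1]]
  bounds <- c(j$time, 400)
  dwell <- diff(bounds)
  exact_frac <- sum(dwell[j$state == 2]) / 400
  expect_lt(abs(frame_frac - exact_frac), 0.005)
  # and both near the stationary value 3/4, ~300 cycles
  expect_lt(abs(exact_frac - 0.75), 3 * 0.25 / sqrt(300))
})

test_that("langevin trace on a harmonic profile has variance kT/a", {
  a <- 50
  x <- gen_langevin_trace(harmonic_pmf(a), diffusion = 1, dt = 0.001,
                          n_steps = 2e5, seed = 13)
  expect_lt(abs(stats::var(x) / (thermal_energy(310) / a) - 1), 0.05)
})

test_that("langevin double-well basin fraction matches the Boltzmann integral", {
  pmf <- calibrate_double_well(0.35, barrier = 4)
  x <- gen_langevin_trace(pmf, diffusion = 1, dt = 2e-4, n_steps = 8e5,
                          seed = 17)
  truth <- oracle_closed_fraction(pmf, 0)
  frac <- mean(x < 0)
  # SE from 10 contiguous block means (the trace is autocorrelated)
  blocks <- colMeans(matrix(x < 0, ncol = 10))
  se <- stats::sd(blocks) / sqrt(10)
  expect_lt(abs(frac - truth), 3 * se)
})

test_that("work samples satisfy the Gaussian-Crooks identity and slope test", {
  kt <- thermal_energy(310)
  ws <- gen_work_samples(dg = 10, sigma = 2, n_forward = 1e5,
                         n_reverse = 1e5, seed = 19)
  expect_lt(abs(mean(ws$forward) - (10 + 4 / (2 * kt))), 3 * 2 / sqrt(1e5))
  expect_lt(abs(mean(ws$reverse) - (10 - 4 / (2 * kt))), 3 * 2 / sqrt(1e5))
  # log[P_f(W)/P_r(-W)] vs W must have slope beta and intercept -beta*dG
  breaks <- seq(4, 16, 0.5)
  hf <- graphics::hist(ws$forward, breaks = c(-Inf, breaks, Inf), plot = FALSE)
  hr <- graphics::hist(ws$reverse, breaks = c(-Inf, breaks, Inf), plot = FALSE)
  cf <- hf$counts[2:(length(breaks))]
  cr <- hr$counts[2:(length(breaks))]
  keep <- cf > 25 & cr > 25
  mids <- (breaks[-1] + breaks[-length(breaks)])[keep] / 2
  fit <- stats::lm(log(cf[keep] / cr[keep]) ~ mids)
  beta <- 1 / kt
  expect_lt(abs(unname(stats::coef(fit)[2]) / beta - 1), 0.05)
  expect_lt(abs(-unname(stats::coef(fit)[1]) / beta - 10), 0.5)
})

test_that("degenerate work generator collapses to the true value", {
  ws <- gen_work_samples(dg = 0, sigma = 1e-9, n_forward = 10,
                         n_reverse = 10, seed = 2)
  expect_true(all(abs(c(ws$forward, ws$reverse)) < 1e-6))
})

test_that("single flat-profile umbrella window samples the pure bias Gaussian", {
  flat <- analytic_pmf(function(x) rep(0, length(x)), c(-2, 2))
  us <- gen_umbrella_set(flat, centers = 0.3, force_constant = 500,
                         n_per_window = 5e4, seed = 23)
  s <- us$windows[[1]]$samples
  sd_th <- sqrt(thermal_energy(310) / 500)
  expect_lt(abs(mean(s) - 0.3), 3 * sd_th / sqrt(5e4))
  expect_lt(abs(stats::sd(s) / sd_th - 1), 0.02)
  expect_warning(gen_umbrella_set(flat, 0, 500, n_per_window = 1),
                 "low samples")
})

test_that("capacitor generator hits the null point and the noise scale", {
  ser <- gen_capacitor_series(q_p0 = 2, C0 = 0.5, q_sol_values = c(-2, 0, 2),
                              noise_sd = 0)
  expect_equal(ser$V[ser$q_sol == -2], 0)
  expect_equal(ser$V[ser$q_sol == 2], 8)
  noisy <- gen_capacitor_series(2, 0.5, c(-5, 5), noise_sd = 1.5,
                                n_replicates = 400, seed = 29)
  expect_lt(abs(stats::sd(noisy$V[noisy$q_sol == 5]) / 1.5 - 1), 0.15)
  expect_error(gen_capacitor_series(2, 0, c(-1, 1)), "C0")
})

test_that("binding-curve generator half-saturates at kd and plateaus", {
  conc <- c(1, 30, 1e6)
  cs <- gen_mst_curves(kd = 30, amplitude = 0.4, baseline = 1,
                       concentrations = conc, noise_sd = 0)
  raw <- cs$raw[, 1]
  expect_equal(raw[2], 1 + 0.4 * 0.5)
  expect_equal(raw[3], 1.4, tolerance = 1e-4)
  expect_equal(cs$curves[1, 1], 1)
  expect_error(gen_mst_curves(-1, 1, 1, c(1, 2)), "kd")
})
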