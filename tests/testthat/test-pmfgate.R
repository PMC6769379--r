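# WHAM reconstruction, gate boundaries, closed probabilities, allosteric
# efficacy, RMSF blocks and 2-D histograms.

test_that("WHAM recovers a harmonic profile within 0.2 kJ/mol RMS", {
  a <- 40
  pmf <- harmonic_pmf(a, domain = c(-1, 1))
  centers <- seq(-0.9, 0.9, length.out = 25)
  us <- gen_umbrella_set(pmf, centers, force_constant = 800,
                         n_per_window = 4000, seed = 149)
  prof <- wham_profile(us, n_boot = 0)
  sel <- prof$x >= quantile(prof$x, 0.05) & prof$x <= quantile(prof$x, 0.95)
  g_true <- 0.5 * a * prof$x[sel]^2
  resid <- prof$G[sel] - g_true
  resid <- resid - mean(resid)  # profiles are defined up to a constant
  expect_lt(sqrt(mean(resid^2)), 0.2)
})

test_that("single unbiased window reduces to -kT ln(histogram)", {
  pmf <- double_well_pmf(6, tilt = 2)
  us <- gen_umbrella_set(pmf, centers = 0, force_constant = 1e-12,
                         n_per_window = 3e4, seed = 151)
  prof <- wham_profile(us, n_bins = 60, n_boot = 0)
  h <- graphics::hist(us$windows[[1]]$samples,
                      breaks = seq(min(us$windows[[1]]$samples),
                                   max(us$windows[[1]]$samples),
                                   length.out = 61), plot = FALSE)
  g_ref <- -thermal_energy(310) * log(pmax(h$density, 1e-300))
  g_ref <- g_ref - min(g_ref[h$density > 0])
  expect_lt(max(abs(prof$G - g_ref)[h$density > 0]), 1e-6)
})

test_that("WHAM profile is invariant under window reordering", {
  pmf <- double_well_pmf(8)
  centers <- seq(-1, 1, length.out = 15)
  us <- gen_umbrella_set(pmf, centers, 500, 2000, seed = 157)
  us_rev <- umbrella_set(rev(us$windows), us$temperature)
  p1 <- wham_profile(us, n_boot = 0)
  p2 <- wham_profile(us_rev, n_boot = 0)
  expect_equal(p1$G, p2$G, tolerance = 1e-6)
})

test_that("basin populations of a calibrated double well are recovered", {
  pmf <- calibrate_double_well(0.59, barrier = 10)
  expect_equal(attr(pmf, "p_closed"), 0.59, tolerance = 1e-8)
  us <- gen_umbrella_set(pmf, seq(pmf$domain[1] + 0.05, pmf$domain[2] - 0.05,
                                  length.out = 44),
                         force_constant = 1000, n_per_window = 3000,
                         seed = 163)
  prof <- wham_profile(us, n_boot = 40, seed = 167)
  b <- find_gate_boundary(list(x = prof$x, p = prof$p))
  truth_b <- oracle_closed_fraction(pmf, b)
  pc <- closed_probability(prof, b)
  expect_lt(abs(pc$p_closed - truth_b), 3 * pc$sd + 0.01)
})

test_that("block profiles from a stationary generator overlap above 80%", {
  pmf <- double_well_pmf(6)
  us <- gen_umbrella_set(pmf, seq(-1, 1, length.out = 20), 600, 5000,
                         seed = 173)
  blocks <- wham_blocks(us, n_blocks = 10, n_bins = 100)
  pc <- profile_convergence(blocks)
  expect_true(pc$pass)
  expect_true(all(pc$overlaps > 0.9))
  # identical blocks overlap exactly
  pc_id <- profile_convergence(list(blocks[[1]], blocks[[1]], blocks[[1]]))
  expect_equal(unname(pc_id$overlaps), rep(1, 3), tolerance = 1e-12)
  expect_error(profile_convergence(blocks[1:2]), ">= 3")
})

test_that("gate boundary sits at the first interior minimum", {
  h <- list(mids = 1:6, counts = c(5, 2, 1, 4, 1, 6))
  expect_equal(find_gate_boundary(h, smoothing = 0), 3)
  expect_error(find_gate_boundary(list(mids = 1:5, counts = 1:5),
                                  smoothing = 0), "minimum")
  # bimodal density: boundary within one bin of the analytic minimum
  pmf <- calibrate_double_well(0.4, barrier = 8)
  bz <- pmf_boltzmann(pmf, 201)
  b <- find_gate_boundary(list(x = bz$x, p = bz$p))
  g <- seq(-0.4, 0.4, length.out = 4001)
  analytic_min <- g[which.min(exp(-pmf$G(g) / thermal_energy(310)))]
  expect_lt(abs(b - analytic_min), 2 * (bz$x[2] - bz$x[1]))
})

test_that("closed probability integrates densities and counts frames", {
  flat <- list(x = seq(0.005, 0.995, 0.01), p = rep(1, 100),
               bin_width = 0.01, boot_p = NULL)
  class(flat) <- "pmf_profile"
  expect_equal(closed_probability(flat, 0.3)$p_closed, 0.3)
  tr <- c(rep(0.1, 30), rep(0.9, 70))
  expect_equal(closed_probability(tr, 0.5, n_boot = 0)$p_closed, 0.3)
  expect_error(closed_probability(tr, 2), "outside")
})

test_that("profile- and trace-based closed probabilities agree", {
  pmf <- calibrate_double_well(0.35, barrier = 5)
  us <- gen_umbrella_set(pmf, seq(pmf$domain[1] + 0.1, pmf$domain[2] - 0.1,
                                  length.out = 24), 500, 3000, seed = 179)
  prof <- wham_profile(us, n_boot = 40, seed = 181)
  traces <- lapply(1:4, function(i) {
    gen_langevin_trace(pmf, diffusion = 1, dt = 3e-4, n_steps = 2e5,
                       seed = 190 + i)
  })
  p1 <- closed_probability(prof, 0)
  p2 <- closed_probability(traces, 0, n_boot = 300, seed = 191)
  expect_lt(abs(p1$p_closed - p2$p_closed),
            3 * sqrt(p1$sd^2 + p2$sd^2))
})

test_that("conditional gate histograms partition the total", {
  set.seed(193)
  n <- 4000
  state <- sample(c(0L, 1L), n, replace = TRUE, prob = c(0.3, 0.7))
  gate <- ifelse(state == 1L, rnorm(n, 4, 0.3), rnorm(n, 8, 0.5))
  tr <- make_occ_trace(state, gate = gate)
  ch <- conditional_gate_histograms(tr, breaks = 30)
  expect_setequal(names(ch$histograms), c("apo", "K1"))
  # occupancy-weighted conditional densities reassemble the pooled one
  pooled <- graphics::hist(gate, breaks = ch$breaks, plot = FALSE)$density
  recon <- ch$weights["apo"] * ch$histograms$apo$density +
    ch$weights["K1"] * ch$histograms$K1$density
  expect_equal(unname(recon), pooled, tolerance = 1e-12)
  # the two conditions reflect their emission laws
  m_b <- sum(ch$histograms$K1$mids * ch$histograms$K1$density) /
    sum(ch$histograms$K1$density)
  expect_lt(abs(m_b - 4), 0.1)
})

test_that("allosteric efficacy is the odds ratio with paired bootstrap SD", {
  expect_equal(allosteric_efficacy(0.4, 0.4)$alpha, 1)
  expect_equal(allosteric_efficacy(1 / 3, 2 / 3)$alpha, 4)
  expect_error(allosteric_efficacy(0, 0.5), "inside")
  set.seed(197)
  boot_a <- pmin(pmax(rnorm(400, 0.2, 0.01), 0.01), 0.99)
  boot_b <- pmin(pmax(rnorm(400, 0.833, 0.01), 0.01), 0.99)
  ae <- allosteric_efficacy(0.2, 0.833, boot_a, boot_b, n_pairs = 5000,
                            seed = 199)
  expect_lt(abs(ae$alpha - 20), 0.5)
  expect_true(is.finite(ae$sd) && ae$sd > 0)
  expect_lt(ae$sd / ae$alpha, 0.25)
})

test_that("RMSF blocks recover isotropic jitter and vanish when static", {
  static <- matrix(5, nrow = 40, ncol = 3)
  r0 <- rmsf_blocks(static, n_blocks = 10)
  expect_equal(unname(r0$mean), rep(0, 3))
  set.seed(211)
  s <- 0.7
  jitter <- array(rnorm(6000 * 4 * 3, sd = s), dim = c(6000, 4, 3))
  r <- rmsf_blocks(jitter, n_blocks = 10)
  expect_equal(unname(r$mean), rep(s * sqrt(3), 4), tolerance = 0.03)
  expect_error(rmsf_blocks(matrix(0, 5, 2), n_blocks = 10), "fewer frames")
})

test_that("2-D histogram quadrants behave under correlation and independence", {
  set.seed(223)
  x <- rnorm(5000, 5, 1.5)
  h_corr <- hist2d_gate_saltbridge(x, x, thresholds = c(5, 5))
  expect_equal(h_corr$quadrants["below", "above"] +
                 h_corr$quadrants["above", "below"], 0)
  expect_equal(sum(h_corr$quadrants), 1)
  y <- rnorm(5000, 5, 1.5)
  h_ind <- hist2d_gate_saltbridge(x, y, thresholds = c(5, 5))
  marg_x <- rowSums(h_ind$quadrants)
  marg_y <- colSums(h_ind$quadrants)
  expect_lt(max(abs(h_ind$quadrants - outer(marg_x, marg_y))), 0.03)
})
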