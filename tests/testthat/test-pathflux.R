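# Stationary occupancy, committors, reactive flux and pathway extraction.

chain3 <- function() {
  K <- matrix(0, 3, 3, dimnames = list(1:3, 1:3))
  K[1, 2] <- 1; K[2, 1] <- 2; K[2, 3] <- 1; K[3, 2] <- 1
  kinetic_model(K)
}

test_that("stationary distribution solves detailed-balance chains exactly", {
  K2 <- matrix(c(0, 1, 1, 0), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(stationary_distribution(kinetic_model(K2))),
               c(0.5, 0.5))
  expect_equal(unname(stationary_distribution(chain3())),
               c(0.5, 0.25, 0.25))
})

test_that("stationary distribution matches long-run CTMC occupation", {
  set.seed(79)
  n <- 6
  # random reversible 6-state generator from energies + symmetric barriers
  G <- rnorm(n)
  A <- matrix(runif(n * n, 0.5, 2), n)
  A <- (A + t(A)) / 2
  K <- A * exp(-outer(G, G, function(gi, gj) (gj - gi) / 2))
  diag(K) <- 0
  dimnames(K) <- list(paste0("S", 1:n), paste0("S", 1:n))
  pi_est <- stationary_distribution(kinetic_model(K))
  occ <- oracle_ctmc_occupation(K, t_total = 4000)
  # SE of an occupation fraction from ~4000/mean-dwell sojourns
  expect_lt(max(abs(pi_est - occ)), 3 * 0.02)
})

test_that("committor honors boundary conditions and symmetry", {
  q <- committor(chain3(), "1", "3")
  expect_equal(unname(q["1"]), 0)
  expect_equal(unname(q["3"]), 1)
  # equal-rate linear chain: middle state sits at 1/2
  K <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  K[1, 2] <- 1; K[2, 1] <- 1; K[2, 3] <- 1; K[3, 2] <- 1
  expect_equal(unname(committor(kinetic_model(K), "a", "c")["b"]), 0.5)
  # state adjacent only to the sink commits fully
  K4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  K4[1, 2] <- 1; K4[2, 1] <- 1; K4[2, 4] <- 1; K4[4, 2] <- 1
  K4[3, 4] <- 1; K4[4, 3] <- 1
  expect_equal(unname(committor(kinetic_model(K4), "a", "d")["c"]), 1)
})

test_that("committor matches simulated first-hit frequencies", {
  set.seed(83)
  n <- 5
  G <- rnorm(n)
  A <- matrix(runif(n * n, 0.2, 1.5), n); A <- (A + t(A)) / 2
  K <- A * exp(-outer(G, G, function(gi, gj) (gj - gi) / 2))
  diag(K) <- 0
  dimnames(K) <- list(paste0("S", 1:n), paste0("S", 1:n))
  q <- committor(kinetic_model(K), "S1", "S5")
  hit <- oracle_first_hit(K, "S1", "S5", n_traj = 1e5)
  for (s in c("S2", "S3", "S4")) {
    se <- sqrt(q[s] * (1 - q[s]) / 1e5)
    expect_lt(abs(q[s] - hit[s]), 3 * se + 1e-6)
  }
})

test_that("single-path and parallel-branch networks decompose exactly", {
  K <- matrix(0, 3, 3, dimnames = list(c("A", "m", "B"), c("A", "m", "B")))
  K["A", "m"] <- 2; K["m", "A"] <- 1; K["m", "B"] <- 3; K["B", "m"] <- 1
  fd <- reactive_flux_paths(kinetic_model(K), "A", "B", n_paths = 3)
  expect_length(fd$paths, 1)
  expect_equal(fd$paths[[1]]$states, c("A", "m", "B"))
  expect_equal(fd$paths[[1]]$flux, fd$total_flux)
  # two symmetric parallel branches carry half the flux each
  Kp <- matrix(0, 4, 4, dimnames = list(c("A", "m1", "m2", "B"),
                                        c("A", "m1", "m2", "B")))
  for (m in c("m1", "m2")) {
    Kp["A", m] <- 1; Kp[m, "A"] <- 1; Kp[m, "B"] <- 1; Kp["B", m] <- 1
  }
  fdp <- reactive_flux_paths(kinetic_model(Kp), "A", "B", n_paths = 4)
  expect_length(fdp$paths, 2)
  expect_equal(fdp$paths[[1]]$flux, fdp$paths[[2]]$flux)
  expect_equal(sum(vapply(fdp$paths, `[[`, 0, "flux")), fdp$total_flux)
})

test_that("net flux is conserved at intermediates and paths rank by bottleneck", {
  model <- demo_relay_model()
  fd <- reactive_flux_paths(model, "apo", "K1", n_paths = 8)
  fn <- fd$flux_net
  inter <- setdiff(names(fd$pi), c("apo", "K1"))
  expect_lt(max(abs(rowSums(fn)[inter] - colSums(fn)[inter])),
            1e-10 * fd$total_flux)
  # relay routes through the scavenger sites beat direct association
  expect_equal(fd$paths[[1]]$states, c("apo", "K2", "K1"))
  expect_equal(fd$paths[[2]]$states, c("apo", "K3", "K1"))
  fluxes <- vapply(fd$paths, `[[`, 0, "flux")
  expect_true(all(diff(fluxes) <= 1e-12))
  expect_lte(sum(fluxes), fd$total_flux + 1e-12)
  # exhaustive enumeration agrees on the top bottleneck path
  oracle <- oracle_best_bottleneck(fn, "apo", "K1")
  expect_equal(fd$paths[[1]]$states, oracle$path)
  expect_equal(fd$paths[[1]]$flux, oracle$width)
})

test_that("iterative extraction matches repeated brute-force enumeration", {
  model <- demo_relay_model()
  fd <- reactive_flux_paths(model, "apo", "K1", n_paths = 4)
  g <- fd$flux_net
  for (p in fd$paths) {
    oracle <- oracle_best_bottleneck(g, "apo", "K1")
    expect_equal(p$states, oracle$path)
    expect_equal(p$flux, oracle$width)
    idx <- cbind(p$states[-length(p$states)], p$states[-1])
    g[idx] <- g[idx] - p$flux
  }
})

test_that("reducible chains warn and split mass over recurrent classes", {
  # two disconnected reversible pairs among visited states
  K <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  K["a", "b"] <- 1; K["b", "a"] <- 1
  K["c", "d"] <- 2; K["d", "c"] <- 2
  expect_warning(pi_r <- stationary_distribution(kinetic_model(K)),
                 "reducible")
  expect_equal(sum(pi_r), 1)
  expect_equal(unname(pi_r), rep(0.25, 4))
})
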