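# Shared fixtures and independent oracles used across the suite.

# Build an occupancy trace directly from an encoded state series (bitmask
# over `sites`), bypassing distance emission; used for hand-crafted censuses.
make_occ_trace <- function(state, sites = "K1", dt = 1, concentration = 1,
                           monomer_id = 1L, gate = NULL) {
  flags <- vapply(seq_along(sites), function(s) {
    bitwAnd(state, 2L^(s - 1L)) > 0
  }, logical(length(state)))
  if (length(sites) == 1) flags <- matrix(flags, ncol = 1)
  colnames(flags) <- sites
  structure(list(flags = flags, state = as.integer(state), sites = sites,
                 thresholds = stats::setNames(rep(3.5, length(sites)), sites),
                 dt = dt, concentration = concentration,
                 monomer_id = monomer_id, gate = gate),
            class = "occupancy_trace")
}

# Independent CTMC simulator (jump chain + exponential dwells), kept
# separate from the package's event-driven generator so it can serve as an
# oracle for occupation fractions.
oracle_ctmc_occupation <- function(K, t_total, start = 1L) {
  n <- nrow(K)
  occ <- numeric(n)
  s <- start
  t_now <- 0
  while (t_now < t_total) {
    k_out <- sum(K[s, ])
    dwell <- if (k_out > 0) rexp(1, k_out) else t_total - t_now
    dwell <- min(dwell, t_total - t_now)
    occ[s] <- occ[s] + dwell
    t_now <- t_now + dwell
    if (k_out > 0 && t_now < t_total) {
      s <- sample.int(n, 1, prob = K[s, ])
    }
  }
  occ / sum(occ)
}

# Vectorized first-hit simulation on the embedded jump chain: probability of
# reaching any sink before any source, per starting state.
oracle_first_hit <- function(K, source, sink, n_traj = 1e5) {
  states <- rownames(K)
  P <- K / rowSums(K)
  hit <- numeric(length(states))
  names(hit) <- states
  for (s0 in setdiff(states, c(source, sink))) {
    cur <- rep(match(s0, states), n_traj)
    res <- rep(NA, n_traj)
    absorbed_src <- match(source, states)
    absorbed_snk <- match(sink, states)
    for (step in 1:10000) {
      res[cur %in% absorbed_snk & is.na(res)] <- TRUE
      res[cur %in% absorbed_src & is.na(res)] <- FALSE
      live <- which(is.na(res))
      if (!length(live)) break
      for (s in unique(cur[live])) {
        sel <- live[cur[live] == s]
        cur[sel] <- sample.int(length(states), length(sel), replace = TRUE,
                               prob = P[s, ])
      }
    }
    hit[s0] <- mean(res, na.rm = TRUE)
  }
  hit
}

# Brute-force maximum-bottleneck path by exhaustive simple-path enumeration
# (igraph when available, otherwise recursive DFS).
oracle_best_bottleneck <- function(cap, source, sink) {
  states <- rownames(cap)
  paths <- list()
  dfs <- function(path) {
    u <- path[length(path)]
    if (u %in% sink) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (v in states[cap[u, ] > 0]) {
      if (!(v %in% path)) dfs(c(path, v))
    }
  }
  for (s in source) dfs(s)
  if (!length(paths)) return(NULL)
  widths <- vapply(paths, function(p) {
    min(cap[cbind(p[-length(p)], p[-1])])
  }, numeric(1))
  best <- which(widths == max(widths))
  keys <- vapply(paths[best], paste, "", collapse = ">")
  list(path = paths[best][[order(keys)[1]]], width = max(widths))
}

# Numeric quadrature of the closed-basin Boltzmann fraction of an analytic
# profile (independent of pmf_boltzmann's grid choice).
oracle_closed_fraction <- function(pmf, boundary) {
  kt <- kgate::thermal_energy(pmf$temperature)
  z_all <- stats::integrate(function(x) exp(-pmf$G(x) / kt),
                            pmf$domain[1], pmf$domain[2],
                            rel.tol = 1e-10)$value
  z_lo <- stats::integrate(function(x) exp(-pmf$G(x) / kt),
                           pmf$domain[1], boundary, rel.tol = 1e-10)$value
  z_lo / z_all
}

# Brute-force Nadaraya-Watson evaluation, double loop, no shared code.
oracle_nw <- function(x, y, grid, h) {
  out <- numeric(length(grid))
  for (g in seq_along(grid)) {
    w <- exp(-0.5 * ((grid[g] - x) / h)^2)
    out[g] <- sum(w * y) / sum(w)
  }
  out
}
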