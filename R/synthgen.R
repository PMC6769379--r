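# Synthetic-data generators with known ground truth for every analysis stage.
#
# Binding traces are sampled exactly (event-driven continuous-time Markov
# jumps) and only then emitted on the frame grid, so the hidden occupancy
# path is available alongside every trace for validation.

#' Specification of a continuous-time Markov binding model
#'
#' States are labelled by the set of occupied sites joined with `+`
#' (`"apo"` for none, e.g. `"K1"`, `"K1+K2"`). Rates are pseudo-first-order
#' at the stated bulk concentration, in 1/us.
#'
#' @param sites Character vector of site names, in bit order (site 1 = bit 0
#'   of the encoded occupancy state).
#' @param rates Named numeric vector of transition rates, names of the form
#'   `"from->to"` using the state labels above.
#' @param concentration Bulk cation concentration in M.
#' @param threshold Discretization distance threshold in Angstrom; bound
#'   emission stays at or below it, the unbound process above it.
#' @param bound_mean,bound_sd Bound-state distance emission: Normal mean/SD
#'   in Angstrom, truncated from above at `threshold` so discretization
#'   recovers the hidden path exactly.
#' @param unbound_mean,unbound_sd Unbound-state Ornstein-Uhlenbeck emission
#'   parameters (stationary mean/SD, Angstrom), reflected at
#'   `threshold + 0.5` Angstrom.
#' @param ou_tau Relaxation time of the unbound process in us.
#' @return An object of class `rate_spec`.
#' @export
rate_spec <- function(sites, rates, concentration = 1, threshold = 3.5,
                      bound_mean = 3.0, bound_sd = 0.15,
                      unbound_mean = 15, unbound_sd = 5, ou_tau = 0.001) {
  stopifnot(is.character(sites), length(sites) >= 1)
  if (length(rates) && is.null(names(rates))) {
    stop("rates must be named 'from->to'")
  }
  if (any(rates < 0)) stop("rates must be non-negative")
  states <- all_state_labels(sites)
  edges <- parse_rate_names(names(rates))
  bad <- !(edges$from %in% states) | !(edges$to %in% states)
  if (any(bad)) stop("unknown state in rates: ",
                     paste(names(rates)[bad], collapse = ", "))
  if (any(edges$from == edges$to)) stop("self-transitions are not allowed")
  Q <- matrix(0, length(states), length(states),
              dimnames = list(states, states))
  Q[cbind(match(edges$from, states), match(edges$to, states))] <- rates
  if (all(Q == 0)) warning("degenerate spec: all rates are zero")
  structure(list(sites = sites, states = states, Q = Q,
                 concentration = concentration, threshold = threshold,
                 bound_mean = bound_mean, bound_sd = bound_sd,
                 unbound_mean = unbound_mean, unbound_sd = unbound_sd,
                 ou_tau = ou_tau),
            class = "rate_spec")
}

#' Two-state (apo/bound) binding spec for a target dissociation constant
#'
#' Convenience constructor: given K_D and the bulk concentration, the
#' pseudo-first-order on rate is `k_off * concentration / K_D`.
#'
#' @param kd_mM Ground-truth dissociation constant in mM.
#' @param concentration_M Bulk concentration in M.
#' @param k_off Off rate in 1/us.
#' @param site Site name.
#' @param ... Passed to [rate_spec()].
#' @return A `rate_spec` whose downstream K_D estimate should recover
#'   `kd_mM`.
#' @export
two_state_spec <- function(kd_mM, concentration_M = 1, k_off = 1,
                           site = "K1", ...) {
  stopifnot(kd_mM > 0, concentration_M > 0, k_off > 0)
  k_on <- k_off * concentration_M / (kd_mM / 1000)
  r <- stats::setNames(c(k_on, k_off),
                       c(paste0("apo->", site), paste0(site, "->apo")))
  rate_spec(sites = site, rates = r, concentration = concentration_M, ...)
}

all_state_labels <- function(sites) {
  n <- length(sites)
  vapply(0:(2^n - 1), function(s) {
    on <- sites[bitwAnd(s, bitwShiftL(1L, seq_len(n) - 1L)) > 0]
    if (length(on) == 0) "apo" else paste(on, collapse = "+")
  }, character(1))
}

parse_rate_names <- function(nm) {
  parts <- strsplit(nm, "->", fixed = TRUE)
  ok <- lengths(parts) == 2
  if (!all(ok)) stop("malformed rate name(s): ", paste(nm[!ok], collapse = ", "))
  list(from = vapply(parts, `[`, "", 1), to = vapply(parts, `[`, "", 2))
}

state_site_matrix <- function(sites, states) {
  m <- vapply(states, function(s) {
    on <- if (s == "apo") character() else strsplit(s, "+", fixed = TRUE)[[1]]
    sites %in% on
  }, logical(length(sites)))
  if (length(sites) == 1) m <- matrix(m, nrow = 1)
  dimnames(m) <- list(sites, states)
  m
}

#' Simulate ion-binding distance trajectories from a Markov spec
#'
#' Runs an exact event-driven (Gillespie) jump simulation of the
#' continuous-time Markov chain per monomer, then emits per-site distances on
#' the dt grid: bound frames from a truncated Normal below the threshold,
#' unbound frames from a reflected Ornstein-Uhlenbeck process above it.
#'
#' @param spec A [rate_spec()].
#' @param duration Trace duration per monomer, us.
#' @param dt Frame interval, us. Must be well below the fastest dwell time.
#' @param n_monomers Number of independent monomer traces.
#' @param seed Optional integer seed.
#' @param initial_state Starting state label (default `"apo"`).
#' @return A list of class `binding_traj_set` with elements
#'   `trajectories` (list of `distance_trajectory` data frames with a `time`
#'   column and one distance column per site; attributes `dt`,
#'   `concentration`, `monomer_id`), `hidden` (list of integer vectors: the
#'   true encoded occupancy state per frame), `jumps` (list of jump records),
#'   and the `spec`.
#' @export
gen_binding_traj <- function(spec, duration, dt, n_monomers = 1, seed = NULL,
                             initial_state = "apo") {
  stopifnot(inherits(spec, "rate_spec"), duration > 0, dt > 0)
  kmax <- max(spec$Q)
  if (kmax > 0 && dt > 0.2 / kmax) {
    warning("dt is coarse relative to the fastest rate (dt*kmax = ",
            signif(dt * kmax, 3), "); dwell times may be under-resolved")
  }
  if (!is.null(seed)) set.seed(seed)
  n_frames <- floor(duration / dt)
  if (n_frames < 1) stop("duration shorter than one frame")
  occ <- state_site_matrix(spec$sites, spec$states)
  out_traj <- vector("list", n_monomers)
  out_hidden <- vector("list", n_monomers)
  out_jumps <- vector("list", n_monomers)
  for (m in seq_len(n_monomers)) {
    jumps <- gillespie_path(spec$Q, duration,
                            start = match(initial_state, spec$states))
    frame_t <- (seq_len(n_frames) - 1) * dt
    state_idx <- jumps$state[findInterval(frame_t, jumps$time)]
    dist <- matrix(NA_real_, n_frames, length(spec$sites),
                   dimnames = list(NULL, spec$sites))
    for (s in seq_along(spec$sites)) {
      bound <- occ[s, state_idx]
      x <- ou_reflected(n_frames, spec$unbound_mean, spec$unbound_sd,
                        spec$ou_tau, dt, floor = spec$threshold + 0.5)
      nb <- sum(bound)
      if (nb > 0) {
        x[bound] <- rtrunc_upper(nb, spec$bound_mean, spec$bound_sd,
                                 upper = spec$threshold)
      }
      dist[, s] <- x
    }
    traj <- data.frame(time = frame_t, dist, check.names = FALSE)
    attr(traj, "dt") <- dt
    attr(traj, "concentration") <- spec$concentration
    attr(traj, "monomer_id") <- m
    attr(traj, "sites") <- spec$sites
    class(traj) <- c("distance_trajectory", "data.frame")
    out_traj[[m]] <- traj
    out_hidden[[m]] <- encode_states(occ[, state_idx, drop = FALSE])
    out_jumps[[m]] <- jumps
  }
  structure(list(trajectories = out_traj, hidden = out_hidden,
                 jumps = out_jumps, spec = spec),
            class = "binding_traj_set")
}

# exact CTMC jump sequence up to `duration`; returns piecewise-constant path
gillespie_path <- function(Q, duration, start = 1L) {
  t_now <- 0
  s <- start
  times <- 0
  states <- s
  repeat {
    k_out <- sum(Q[s, ])
    if (k_out <= 0) break  # absorbing
    t_now <- t_now + stats::rexp(1, k_out)
    if (t_now >= duration) break
    s <- sample.int(ncol(Q), 1, prob = Q[s, ])
    times <- c(times, t_now)
    states <- c(states, s)
  }
  list(time = times, state = states, n_jumps = length(times) - 1L)
}

encode_states <- function(occ_cols) {
  # occ_cols: sites x frames logical matrix -> bitmask integer per frame
  bits <- 2L^(seq_len(nrow(occ_cols)) - 1L)
  as.integer(colSums(occ_cols * bits))
}

# AR(1)-exact Ornstein-Uhlenbeck path folded at a lower floor
ou_reflected <- function(n, mean, sd, tau, dt, floor) {
  phi <- exp(-dt / tau)
  innov_sd <- sd * sqrt(1 - phi^2)
  x0 <- stats::rnorm(1, mean, sd)
  eps <- stats::rnorm(n, 0, innov_sd)
  x <- mean + as.numeric(stats::filter(eps, phi, method = "recursive",
                                       init = x0 - mean))
  floor + abs(x - floor)
}

rtrunc_upper <- function(n, mean, sd, upper) {
  pmax_u <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, 0, pmax_u), mean, sd)
}

#' Analytic one-dimensional free-energy profile
#'
#' Container for a ground-truth PMF `G(x)` (kJ/mol) over a bounded reaction
#' coordinate domain, with Boltzmann utilities used by the Langevin and
#' umbrella-window generators and by quadrature oracles in tests.
#'
#' @param G Vectorized function of the reaction coordinate, returning kJ/mol.
#' @param domain Length-2 numeric: coordinate bounds (nm).
#' @param temperature Temperature in K.
#' @return Object of class `analytic_pmf`.
#' @export
analytic_pmf <- function(G, domain, temperature = 310) {
  stopifnot(is.function(G), length(domain) == 2, domain[1] < domain[2])
  test <- G(seq(domain[1], domain[2], length.out = 101))
  if (!all(is.finite(test))) stop("G must be finite on the domain")
  structure(list(G = G, domain = domain, temperature = temperature),
            class = "analytic_pmf")
}

#' @rdname analytic_pmf
#' @param a Curvature of the harmonic profile, kJ/mol per nm^2
#'   (`G = a/2 (x - center)^2`).
#' @param center Minimum position (nm).
#' @export
harmonic_pmf <- function(a, center = 0, domain = center + c(-1, 1),
                         temperature = 310) {
  analytic_pmf(function(x) 0.5 * a * (x - center)^2, domain, temperature)
}

#' @rdname analytic_pmf
#' @param barrier Barrier height above the well level at zero tilt, kJ/mol.
#' @param tilt Free-energy difference G(right well) - G(left well), kJ/mol.
#' @param centers Well positions (nm), length 2.
#' @export
double_well_pmf <- function(barrier, tilt = 0, centers = c(-0.5, 0.5),
                            domain = NULL, temperature = 310) {
  stopifnot(barrier > 0, length(centers) == 2, centers[1] < centers[2])
  mid <- mean(centers); half <- diff(centers) / 2
  if (is.null(domain)) domain <- mid + c(-2.2, 2.2) * half
  analytic_pmf(function(x) {
    u <- (x - mid) / half
    barrier * (u^2 - 1)^2 + 0.5 * tilt * u
  }, domain, temperature)
}

#' Boltzmann density of an analytic PMF on a dense grid
#'
#' @param pmf An [analytic_pmf()].
#' @param n_grid Number of grid points.
#' @return List with `x`, `p` (density integrating to 1), and `dx`.
#' @export
pmf_boltzmann <- function(pmf, n_grid = 4001) {
  x <- seq(pmf$domain[1], pmf$domain[2], length.out = n_grid)
  kt <- thermal_energy(pmf$temperature)
  w <- exp(-(pmf$G(x) - min(pmf$G(x))) / kt)
  dx <- x[2] - x[1]
  list(x = x, p = w / (sum(w) * dx), dx = dx)
}

#' Calibrate a double-well PMF to a target closed-basin probability
#'
#' Adjusts the tilt of a [double_well_pmf()] so that the Boltzmann weight of
#' the closed basin (coordinate below `boundary`) equals `p_closed`, giving
#' a ground-truth profile for gating-probability recovery tests.
#'
#' @param p_closed Target closed fraction in (0, 1).
#' @param barrier Barrier height, kJ/mol.
#' @param centers Well positions (nm).
#' @param boundary Basin divider (nm); default the midpoint.
#' @param temperature K.
#' @return An `analytic_pmf` with attribute `p_closed` (the achieved value,
#'   by quadrature) and `tilt`.
#' @export
calibrate_double_well <- function(p_closed, barrier = 10,
                                  centers = c(-0.5, 0.5),
                                  boundary = mean(centers),
                                  temperature = 310) {
  stopifnot(p_closed > 0, p_closed < 1)
  frac <- function(tilt) {
    pmf <- double_well_pmf(barrier, tilt, centers, temperature = temperature)
    bz <- pmf_boltzmann(pmf)
    sum(bz$p[bz$x < boundary]) * bz$dx - p_closed
  }
  tilt <- stats::uniroot(frac, c(-200, 200), tol = 1e-10)$root
  pmf <- double_well_pmf(barrier, tilt, centers, temperature = temperature)
  attr(pmf, "tilt") <- tilt
  attr(pmf, "p_closed") <- frac(tilt) + p_closed
  pmf
}

#' Overdamped Langevin trace on an analytic PMF
#'
#' Euler-Maruyama integration of `dx = -beta D G'(x) dt + sqrt(2 D dt) xi`,
#' with reflecting domain walls. The stationary histogram converges to the
#' Boltzmann density of the profile. Stability requires the drift step to
#' stay small against the domain; the integrator aborts on non-finite forces
#' and warns when `dt` exceeds the documented bound
#' `0.1 * (kT/a_max) / D` with `a_max` the maximum local curvature.
#'
#' @param pmf An [analytic_pmf()].
#' @param diffusion Diffusion coefficient, nm^2/ns.
#' @param dt Time step, ns.
#' @param n_steps Number of steps.
#' @param x0 Initial coordinate (default domain midpoint).
#' @param seed Optional seed.
#' @return Numeric vector of length `n_steps` (coordinate series, nm).
#' @export
gen_langevin_trace <- function(pmf, diffusion, dt, n_steps, x0 = NULL,
                               seed = NULL) {
  stopifnot(inherits(pmf, "analytic_pmf"), diffusion > 0, dt > 0,
            n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  kt <- thermal_energy(pmf$temperature)
  lo <- pmf$domain[1]; hi <- pmf$domain[2]
  h <- (hi - lo) * 1e-5
  grad <- function(x) (pmf$G(x + h) - pmf$G(x - h)) / (2 * h)
  # curvature-based stability bound over the thermally accessible region
  xs <- seq(lo + 2 * h, hi - 2 * h, length.out = 201)
  gx <- pmf$G(xs)
  xs <- xs[gx - min(gx) < 10 * kt]
  curv <- max(abs((pmf$G(xs + h) - 2 * pmf$G(xs) + pmf$G(xs - h)) / h^2))
  if (curv > 0 && dt > 0.1 * kt / (curv * diffusion)) {
    warning("dt above stability bound 0.1*kT/(a_max*D); integration may be unstable")
  }
  if (is.null(x0)) x0 <- (lo + hi) / 2
  x <- numeric(n_steps)
  noise <- stats::rnorm(n_steps, 0, sqrt(2 * diffusion * dt))
  cur <- x0
  fac <- diffusion * dt / kt
  for (i in seq_len(n_steps)) {
    f <- grad(cur)
    if (!is.finite(f)) stop("non-finite force at x = ", signif(cur, 4))
    cur <- cur - fac * f + noise[i]
    # reflect at the walls
    if (cur < lo) cur <- 2 * lo - cur
    if (cur > hi) cur <- 2 * hi - cur
    x[i] <- cur
  }
  x
}

#' Work-sample container for Crooks analysis
#'
#' Reverse works are stored on the forward free-energy axis, i.e. as minus
#' the work of the reverse process.
#'
#' @param forward,reverse Numeric work samples, kJ/mol.
#' @param temperature K.
#' @return Object of class `work_set`.
#' @export
work_set <- function(forward, reverse, temperature = 310) {
  stopifnot(is.numeric(forward), is.numeric(reverse))
  if (length(forward) < 2 || length(reverse) < 2) {
    stop("need at least 2 work values per direction")
  }
  structure(list(forward = forward, reverse = reverse,
                 temperature = temperature,
                 beta = 1 / thermal_energy(temperature)),
            class = "work_set")
}

#' Gaussian work samples satisfying the Crooks fluctuation relation
#'
#' For a common variance sigma^2, the Crooks relation
#' `P_f(W) = P_r(-W) exp(beta (W - dG))` forces the forward mean to
#' `dG + sigma^2/(2 kT)` and the reverse (-W) mean to `dG - sigma^2/(2 kT)`.
#' Samples are drawn from exactly these two Gaussians.
#'
#' @param dg Ground-truth free-energy difference, kJ/mol.
#' @param sigma Common work SD, kJ/mol (> 0).
#' @param n_forward,n_reverse Sample sizes (>= 2).
#' @param temperature K.
#' @param seed Optional seed.
#' @return A [work_set()] with attribute `dg_true`.
#' @export
gen_work_samples <- function(dg, sigma, n_forward, n_reverse,
                             temperature = 310, seed = NULL) {
  stopifnot(sigma > 0, n_forward >= 2, n_reverse >= 2)
  if (!is.null(seed)) set.seed(seed)
  kt <- thermal_energy(temperature)
  shift <- sigma^2 / (2 * kt)
  ws <- work_set(forward = stats::rnorm(n_forward, dg + shift, sigma),
                 reverse = stats::rnorm(n_reverse, dg - shift, sigma),
                 temperature = temperature)
  attr(ws, "dg_true") <- dg
  ws
}

#' Biased umbrella-window samples on an analytic PMF
#'
#' Each window's samples are drawn exactly from the normalized biased
#' Boltzmann density `exp(-beta (G(x) + k/2 (x - c)^2))` by inverse-CDF
#' sampling on a dense grid. Warns when adjacent biased densities barely
#' overlap (WHAM would be ill-conditioned).
#'
#' @param pmf An [analytic_pmf()].
#' @param centers Window bias centers (nm).
#' @param force_constant Harmonic bias force constant, kJ/mol/nm^2.
#' @param n_per_window Samples per window.
#' @param seed Optional seed.
#' @param min_overlap Adjacent-density intersection below which a warning is
#'   issued.
#' @return Object of class `umbrella_set`: list of `windows`
#'   (each `center`, `force_constant`, `samples`) plus `temperature`.
#' @export
gen_umbrella_set <- function(pmf, centers, force_constant, n_per_window,
                             seed = NULL, min_overlap = 0.02) {
  stopifnot(inherits(pmf, "analytic_pmf"), force_constant > 0,
            n_per_window >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (n_per_window < 10) {
    warning("very low samples per window (n_per_window = ", n_per_window, ")")
  }
  kt <- thermal_energy(pmf$temperature)
  x <- seq(pmf$domain[1], pmf$domain[2], length.out = 8001)
  dx <- x[2] - x[1]
  g0 <- pmf$G(x)
  dens <- lapply(centers, function(c0) {
    e <- g0 + 0.5 * force_constant * (x - c0)^2
    w <- exp(-(e - min(e)) / kt)
    w / (sum(w) * dx)
  })
  ord <- order(centers)
  for (i in seq_len(length(centers) - 1)) {
    ov <- sum(pmin(dens[[ord[i]]], dens[[ord[i + 1]]])) * dx
    if (ov < min_overlap) {
      warning(sprintf("windows at %.3g and %.3g overlap by only %.2g; WHAM will be ill-conditioned",
                      centers[ord[i]], centers[ord[i + 1]], ov))
    }
  }
  windows <- lapply(seq_along(centers), function(i) {
    cdf <- cumsum(dens[[i]]) * dx
    cdf <- cdf / cdf[length(cdf)]
    u <- stats::runif(n_per_window)
    # invert the CDF by interpolation on the dense grid
    smp <- stats::approx(cdf, x, xout = u, ties = "ordered", rule = 2)$y
    list(center = centers[i], force_constant = force_constant, samples = smp)
  })
  structure(list(windows = windows, temperature = pmf$temperature,
                 equilibration = 0),
            class = "umbrella_set")
}

#' Synthetic voltage responses of the membrane/protein capacitor
#'
#' Emulates computational-electrophysiology measurements: the transmembrane
#' voltage responds linearly to the imposed ionic charge imbalance,
#' `V = (q_sol + q_p0) / C0`, plus Gaussian noise per replicate.
#'
#' @param q_p0 Protein contribution to the capacitor charge, e0.
#' @param C0 Total capacitance, e0/mV (> 0).
#' @param q_sol_values Grid of imposed charge imbalances, e0 (>= 2 distinct).
#' @param noise_sd Voltage noise SD, mV.
#' @param n_replicates Independent replicates per imbalance.
#' @param seed Optional seed.
#' @param state State label (conformation x occupancy).
#' @return A `capacitor_series` data frame with columns `state`, `q_sol`,
#'   `V`, `replicate`.
#' @export
gen_capacitor_series <- function(q_p0, C0, q_sol_values, noise_sd = 0,
                                 n_replicates = 1, seed = NULL,
                                 state = "state0") {
  if (C0 <= 0) stop("C0 must be positive")
  if (length(unique(q_sol_values)) < 2) {
    stop("need at least 2 distinct q_sol values")
  }
  if (!is.null(seed)) set.seed(seed)
  df <- expand.grid(q_sol = q_sol_values, replicate = seq_len(n_replicates))
  df$V <- (df$q_sol + q_p0) / C0 + stats::rnorm(nrow(df), 0, noise_sd)
  df$state <- state
  df <- df[, c("state", "q_sol", "V", "replicate")]
  class(df) <- c("capacitor_series", "data.frame")
  attr(df, "truth") <- c(q_p0 = q_p0, C0 = C0)
  df
}

#' Synthetic thermophoresis binding curves
#'
#' Replicate curves follow a hyperbolic (Hill coefficient 1) binding law
#' `baseline + amplitude * c / (c + kd)` with additive Gaussian noise, then
#' are anchored to 1 at the lowest concentration, matching the normalization
#' the fitting module expects.
#'
#' @param kd Ground-truth half-saturation constant, mM (> 0).
#' @param amplitude,baseline Curve shape parameters (normalized fluorescence).
#' @param concentrations Strictly increasing positive concentrations, mM.
#' @param noise_sd Additive noise SD per point.
#' @param n_curves Number of replicate curves.
#' @param seed Optional seed.
#' @return Object of class `mst_curves`: `concentrations`, `curves`
#'   (matrix concentrations x curves, anchored), `raw`, and `kd_true`.
#' @export
gen_mst_curves <- function(kd, amplitude, baseline, concentrations,
                           noise_sd = 0, n_curves = 1, seed = NULL) {
  if (kd <= 0) stop("kd must be positive")
  if (any(concentrations <= 0) || is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be positive and strictly increasing")
  }
  if (!is.null(seed)) set.seed(seed)
  mu <- baseline + amplitude * concentrations / (concentrations + kd)
  raw <- matrix(stats::rnorm(length(mu) * n_curves, mu, noise_sd),
                nrow = length(mu))
  curves <- sweep(raw, 2, raw[1, ], "/")
  structure(list(concentrations = concentrations, curves = curves,
                 raw = raw, kd_true = kd),
            class = "mst_curves")
}

#' Write a distance trajectory (and its hidden path) to CSV
#'
#' The trace file carries a one-line JSON header comment (dt, units, seed,
#' concentration); the ground-truth state path goes to a sibling
#' `<path>.states.csv` file when provided.
#'
#' @param traj A `distance_trajectory`.
#' @param path Output CSV path.
#' @param hidden Optional integer vector of true encoded states per frame.
#' @param seed Seed recorded in the header (documentation only).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, hidden = NULL, seed = NULL) {
  meta <- list(dt_us = attr(traj, "dt"),
               concentration_M = attr(traj, "concentration"),
               monomer_id = attr(traj, "monomer_id"),
               units = list(distance = "Angstrom", time = "us"),
               seed = seed)
  write_timeseries_table(as.data.frame(traj), path, meta = meta)
  if (!is.null(hidden)) {
    utils::write.csv(data.frame(frame = seq_along(hidden), state = hidden),
                     paste0(path, ".states.csv"), row.names = FALSE)
  }
  invisible(path)
}
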