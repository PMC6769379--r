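# WHAM reconstruction of gate-opening free-energy profiles, closed-state
# probabilities, conditional gate histograms, allosteric efficacy, RMSF
# block statistics, and 2-D gate/salt-bridge histograms.

#' Assemble an umbrella set from per-window samples
#'
#' @param windows List of `list(center, force_constant, samples)`.
#' @param temperature K.
#' @param equilibration Fraction of each window's samples dropped from the
#'   head before analysis.
#' @return Object of class `umbrella_set`.
#' @export
umbrella_set <- function(windows, temperature = 310, equilibration = 0) {
  stopifnot(length(windows) >= 1)
  for (w in windows) {
    if (is.null(w$center) || is.null(w$force_constant) || is.null(w$samples)) {
      stop("each window needs center, force_constant, samples")
    }
    if (w$force_constant < 0) stop("force constants must be >= 0")
    if (!all(is.finite(w$samples))) stop("non-finite window samples")
  }
  structure(list(windows = windows, temperature = temperature,
                 equilibration = equilibration),
            class = "umbrella_set")
}

#' Read umbrella windows from xvg-style files plus a metadata table
#'
#' @param files Character vector of per-window two-column (time, coordinate)
#'   files; `#`/`@` comment lines are skipped.
#' @param meta Data frame with columns `center` and `force_constant`, one
#'   row per file in the same order.
#' @param temperature K.
#' @param equilibration Head fraction to drop.
#' @return An [umbrella_set()].
#' @export
read_umbrella_windows <- function(files, meta, temperature = 310,
                                  equilibration = 0) {
  stopifnot(length(files) == nrow(meta),
            all(c("center", "force_constant") %in% names(meta)))
  windows <- lapply(seq_along(files), function(i) {
    df <- read_timeseries_table(files[i])
    list(center = meta$center[i], force_constant = meta$force_constant[i],
         samples = as.numeric(df[[ncol(df)]]))
  })
  umbrella_set(windows, temperature, equilibration)
}

# core self-consistent WHAM iteration on fixed histograms
wham_iterate <- function(H, Nw, cmat, dx, tol, max_iter, f_init = NULL) {
  W <- nrow(H)
  f <- if (is.null(f_init)) numeric(W) else f_init
  pooled <- colSums(H)
  it <- 0
  repeat {
    it <- it + 1
    denom <- colSums(Nw * exp(f) * cmat)          # f in kT units
    p <- pooled / denom
    p[!is.finite(p)] <- 0
    p <- p / (sum(p) * dx)
    f_new <- -log(pmax(as.numeric(cmat %*% p) * dx, .Machine$double.xmin))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol || it >= max_iter) break
  }
  list(p = p, f = f, iter = it, converged = it < max_iter)
}

#' WHAM free-energy profile from umbrella windows
#'
#' Self-consistent weighted-histogram iteration: window free energies are
#' updated until the largest change per sweep falls below `tol` (in kT).
#' The profile is returned as the normalized unbiased density and the
#' min-anchored free energy `G = -kT ln p`. Per-bin errors come from
#' bootstrap resampling of each window's sample set.
#'
#' @param uset An [umbrella_set()].
#' @param n_bins Number of histogram bins over the sampled range.
#' @param tol Convergence tolerance on window free energies, kT.
#' @param max_iter Maximum sweeps.
#' @param n_boot Bootstrap resamples for per-bin errors (0 to skip).
#' @param seed Optional seed.
#' @return Object of class `pmf_profile`: `x` (bin centers), `G` (kJ/mol,
#'   minimum at 0), `p` (density, integrates to 1), `sd_G`, `sd_p`,
#'   `boot_p` (resample densities), `f_windows` (kT), `converged`,
#'   `n_iter`, `bin_width`, `temperature`.
#' @export
wham_profile <- function(uset, n_bins = 200, tol = 1e-6, max_iter = 50000,
                         n_boot = 100, seed = NULL) {
  stopifnot(inherits(uset, "umbrella_set"))
  kt <- thermal_energy(uset$temperature)
  wins <- lapply(uset$windows, function(w) {
    s <- w$samples
    if (uset$equilibration > 0) {
      s <- s[-seq_len(floor(uset$equilibration * length(s)))]
    }
    w$samples <- s
    w
  })
  all_s <- unlist(lapply(wins, `[[`, "samples"))
  rng <- range(all_s)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  dx <- breaks[2] - breaks[1]
  W <- length(wins)
  H <- t(vapply(wins, function(w) {
    as.numeric(graphics::hist(w$samples, breaks = breaks, plot = FALSE)$counts)
  }, numeric(n_bins)))
  Nw <- vapply(wins, function(w) length(w$samples), numeric(1))
  bias <- t(vapply(wins, function(w) {
    0.5 * w$force_constant * (mids - w$center)^2 / kt
  }, numeric(n_bins)))
  cmat <- exp(-bias)
  # non-overlap check on adjacent (by center) windows
  ord <- order(vapply(wins, `[[`, numeric(1), "center"))
  for (i in seq_len(W - 1)) {
    a <- H[ord[i], ] > 0; b <- H[ord[i + 1], ] > 0
    if (!any(a & b)) {
      stop(sprintf("no histogram overlap between windows centered at %.4g and %.4g",
                   wins[[ord[i]]]$center, wins[[ord[i + 1]]]$center))
    }
  }
  fit <- wham_iterate(H, Nw, cmat, dx, tol, max_iter)
  if (!fit$converged) warning("WHAM did not converge in ", max_iter, " sweeps")
  G <- -kt * log(pmax(fit$p, .Machine$double.xmin))
  G <- G - min(G[fit$p > 0])
  boot_p <- NULL; sd_G <- rep(NA_real_, n_bins); sd_p <- sd_G
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    boot_p <- matrix(NA_real_, n_boot, n_bins)
    for (b in seq_len(n_boot)) {
      Hb <- t(vapply(seq_len(W), function(i) {
        if (Nw[i] == 0) return(numeric(n_bins))
        as.numeric(stats::rmultinom(1, Nw[i], pmax(H[i, ], 0) / Nw[i]))
      }, numeric(n_bins)))
      fb <- wham_iterate(Hb, Nw, cmat, dx, tol * 10, max_iter,
                         f_init = fit$f)
      boot_p[b, ] <- fb$p
    }
    sd_p <- apply(boot_p, 2, stats::sd)
    Gb <- -kt * log(pmax(boot_p, .Machine$double.xmin))
    Gb <- Gb - apply(Gb, 1, min)
    sd_G <- apply(Gb, 2, stats::sd)
  }
  structure(list(x = mids, G = G, p = fit$p, sd_G = sd_G, sd_p = sd_p,
                 boot_p = boot_p, f_windows = fit$f,
                 converged = fit$converged, n_iter = fit$iter,
                 bin_width = dx, temperature = uset$temperature),
            class = "pmf_profile")
}

#' Per-block WHAM profiles for convergence assessment
#'
#' Splits each window's samples chronologically into `n_blocks` segments
#' and reconstructs one profile per block.
#'
#' @param uset An [umbrella_set()].
#' @param n_blocks Number of chronological blocks.
#' @param ... Passed to [wham_profile()] (bootstrap disabled).
#' @return List of `pmf_profile`s.
#' @export
wham_blocks <- function(uset, n_blocks = 10, ...) {
  stopifnot(n_blocks >= 1)
  lapply(seq_len(n_blocks), function(b) {
    wins <- lapply(uset$windows, function(w) {
      n <- length(w$samples)
      lo <- floor((b - 1) * n / n_blocks) + 1
      hi <- floor(b * n / n_blocks)
      w$samples <- w$samples[lo:hi]
      w
    })
    wham_profile(umbrella_set(wins, uset$temperature), n_boot = 0, ...)
  })
}

#' Convergence of block probability profiles by histogram intersection
#'
#' Computes the pairwise overlap `sum_bins min(p, q) * dx` of the last
#' three block densities (regridding by interpolation when grids differ)
#' and passes when every pair reaches the threshold.
#'
#' @param block_profiles List of >= 3 `pmf_profile`s (chronological).
#' @param threshold Minimum pairwise overlap.
#' @return List: `overlaps` (named pairwise values), `pass`.
#' @export
profile_convergence <- function(block_profiles, threshold = 0.80) {
  n <- length(block_profiles)
  if (n < 3) stop("need >= 3 block profiles")
  last3 <- block_profiles[(n - 2):n]
  ref <- last3[[1]]
  dens <- lapply(last3, function(pr) {
    if (length(pr$x) == length(ref$x) && all(pr$x == ref$x)) return(pr$p)
    p <- stats::approx(pr$x, pr$p, xout = ref$x, rule = 2)$y
    p / (sum(p) * ref$bin_width)
  })
  pairs <- utils::combn(3, 2)
  ov <- apply(pairs, 2, function(ij) {
    sum(pmin(dens[[ij[1]]], dens[[ij[2]]])) * ref$bin_width
  })
  names(ov) <- apply(pairs, 2, paste, collapse = "-")
  list(overlaps = ov, pass = all(ov >= threshold))
}

#' Open/closed boundary as the first interior minimum of a histogram
#'
#' After optional Gaussian kernel smoothing (width in bins; 0 disables),
#' scans from small distances upward and returns the center of the first
#' interior bin strictly lower than both neighbors. This implements the
#' convention of placing the gate boundary at the first local minimum of
#' the ligand-bound gate-distance histogram.
#'
#' @param histogram Either an object with `mids`/`counts` (as returned by
#'   [graphics::hist()]), or a list with elements `mids` (or `x`) and
#'   `counts` (or `p`).
#' @param smoothing Gaussian kernel SD in bins (default 2).
#' @return The boundary coordinate (bin center).
#' @export
find_gate_boundary <- function(histogram, smoothing = 2) {
  mids <- histogram$mids %||% histogram$x
  y <- histogram$counts %||% histogram$p
  if (is.null(mids) || is.null(y)) stop("histogram needs mids/x and counts/p")
  if (length(y) < 3) stop("histogram needs >= 3 bins")
  if (smoothing > 0) {
    half <- ceiling(4 * smoothing)
    k <- stats::dnorm(-half:half, sd = smoothing)
    k <- k / sum(k)
    ypad <- c(rep(y[1], half), y, rep(y[length(y)], half))
    y <- stats::filter(ypad, k, sides = 2)[(half + 1):(half + length(mids))]
  }
  for (i in 2:(length(y) - 1)) {
    if (y[i] < y[i - 1] && y[i] < y[i + 1]) return(mids[i])
  }
  stop("no interior local minimum found; consider larger smoothing width")
}

#' Closed-state probability below a boundary
#'
#' Profile mode integrates the reconstructed density below the boundary,
#' with the SD taken over the profile's bootstrap resamples. Trace mode
#' (numeric vector or list of per-monomer vectors) takes the fraction of
#' frames below the boundary, with monomer-level bootstrap.
#'
#' @param x A `pmf_profile`, a numeric trace, or a list of numeric traces.
#' @param boundary Boundary coordinate; must lie inside the support.
#' @param n_boot Bootstrap resamples for trace mode.
#' @param seed Optional seed (trace mode).
#' @return List: `p_closed`, `sd`.
#' @export
closed_probability <- function(x, boundary, n_boot = 1000, seed = NULL) {
  if (inherits(x, "pmf_profile")) {
    if (boundary <= min(x$x) || boundary >= max(x$x)) {
      stop("boundary outside the profile support")
    }
    below <- x$x < boundary
    p <- sum(x$p[below]) * x$bin_width
    sd <- if (!is.null(x$boot_p)) {
      stats::sd(rowSums(x$boot_p[, below, drop = FALSE]) * x$bin_width)
    } else NA_real_
    return(list(p_closed = p, sd = sd))
  }
  traces <- if (is.list(x)) x else list(x)
  rng <- range(unlist(traces))
  if (boundary <= rng[1] || boundary >= rng[2]) {
    stop("boundary outside the trace range")
  }
  frac <- function(tr) {
    v <- unlist(tr)
    mean(v < boundary)
  }
  p <- frac(traces)
  sd <- if (length(traces) >= 2 && n_boot > 0) {
    bootstrap_statistic(traces, frac, n_boot = n_boot, seed = seed)$sd
  } else NA_real_
  list(p_closed = p, sd = sd)
}

#' Gate-distance histograms conditioned on occupancy state
#'
#' Splits the gate-distance series of a trajectory by the frame-wise
#' encoded occupancy state and returns one normalized histogram per
#' occupancy condition; conditions with zero frames are omitted with a
#' notice. The histograms, weighted by state occupancy, sum to the
#' unconditioned histogram.
#'
#' @param occ An `occupancy_trace` carrying a `gate` series (or a list of
#'   such traces, pooled).
#' @param breaks Histogram breaks (default 50 bins over the pooled range).
#' @return List: `histograms` (named by state label: `mids`, `density`,
#'   `counts`), `weights` (state occupancy fractions), `breaks`.
#' @export
conditional_gate_histograms <- function(occ, breaks = 50) {
  traces <- if (inherits(occ, "occupancy_trace")) list(occ) else occ
  gate <- unlist(lapply(traces, function(tr) {
    if (is.null(tr$gate)) stop("trace carries no gate series")
    tr$gate
  }))
  state <- unlist(lapply(traces, `[[`, "state"))
  sites <- traces[[1]]$sites
  labels <- all_state_labels(sites)
  if (length(breaks) == 1) {
    breaks <- seq(min(gate), max(gate), length.out = breaks + 1)
  }
  hists <- list()
  weights <- numeric(0)
  for (s in seq_along(labels) - 1L) {
    sel <- state == s
    if (!any(sel)) next
    h <- graphics::hist(pmin(pmax(gate[sel], breaks[1]),
                             breaks[length(breaks)]),
                        breaks = breaks, plot = FALSE)
    hists[[labels[s + 1]]] <- list(mids = h$mids, density = h$density,
                                   counts = h$counts)
    weights[labels[s + 1]] <- mean(sel)
  }
  omitted <- setdiff(labels, names(hists))
  if (length(omitted)) {
    message("occupancy condition(s) with zero frames omitted: ",
            paste(omitted, collapse = ", "))
  }
  list(histograms = hists, weights = weights, breaks = breaks)
}

#' K-type allosteric efficacy from closed-state probabilities
#'
#' The efficacy is the ratio of gate-closure equilibrium constants with and
#' without the ligand bound:
#' `alpha = [p_b / (1 - p_b)] / [p_a / (1 - p_a)]`.
#' The SD pairs the two (independent) bootstrap sample sets.
#'
#' @param p_closed_apo,p_closed_bound Closed probabilities in (0, 1).
#' @param boot_apo,boot_bound Optional bootstrap samples of each
#'   probability (independent simulations; resampled to a common length and
#'   paired).
#' @param n_pairs Number of bootstrap pairs formed.
#' @param seed Optional seed for the pairing.
#' @return List: `alpha`, `sd` (NA without bootstrap input).
#' @export
allosteric_efficacy <- function(p_closed_apo, p_closed_bound,
                                boot_apo = NULL, boot_bound = NULL,
                                n_pairs = 10000, seed = NULL) {
  for (p in c(p_closed_apo, p_closed_bound)) {
    if (!is.finite(p) || p <= 0 || p >= 1) {
      stop("probabilities must lie strictly inside (0, 1); alpha undefined at 0 or 1")
    }
  }
  odds <- function(p) p / (1 - p)
  alpha <- odds(p_closed_bound) / odds(p_closed_apo)
  sd <- NA_real_
  if (!is.null(boot_apo) && !is.null(boot_bound)) {
    if (!is.null(seed)) set.seed(seed)
    a <- sample(boot_apo, n_pairs, replace = TRUE)
    b <- sample(boot_bound, n_pairs, replace = TRUE)
    ok <- a > 0 & a < 1 & b > 0 & b < 1
    sd <- stats::sd(odds(b[ok]) / odds(a[ok]))
  }
  list(alpha = alpha, sd = sd)
}

#' Per-residue RMSF with contiguous-block errors
#'
#' Splits the trajectory into contiguous blocks; within each block the RMSF
#' of a residue is the root mean squared deviation from the block-mean
#' position (inputs are assumed pre-aligned; no superposition is
#' performed). Reports mean and SD across blocks.
#'
#' @param coords Frames x residues matrix (1-D coordinates) or a 3-D array
#'   frames x residues x dimensions.
#' @param n_blocks Number of contiguous blocks (default 10).
#' @return List: `mean`, `sd` (per residue), `blocks` (block x residue
#'   matrix).
#' @export
rmsf_blocks <- function(coords, n_blocks = 10) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(nrow(coords), ncol(coords), 1))
  }
  stopifnot(length(dim(coords)) == 3)
  n_frames <- dim(coords)[1]
  if (n_frames < n_blocks) stop("fewer frames than blocks")
  bounds <- floor(seq(0, n_frames, length.out = n_blocks + 1))
  blocks <- t(vapply(seq_len(n_blocks), function(b) {
    sl <- coords[(bounds[b] + 1):bounds[b + 1], , , drop = FALSE]
    mu <- apply(sl, c(2, 3), mean)
    dev2 <- sweep(sl, c(2, 3), mu)^2
    sqrt(apply(dev2, 2, mean) * dim(coords)[3])
  }, numeric(dim(coords)[2])))
  if (dim(coords)[2] == 1) blocks <- matrix(blocks, ncol = 1)
  list(mean = colMeans(blocks), sd = apply(blocks, 2, stats::sd),
       blocks = blocks)
}

#' 2-D gate/salt-bridge histogram with quadrant occupancies
#'
#' Normalized 2-D histogram of gate distance against a residue-pair
#' distance, plus the occupancy of the four quadrants defined by the two
#' thresholds (at-or-below counts as below, matching the discretization tie
#' rule).
#'
#' @param gate,pair Equal-length numeric series.
#' @param thresholds Length-2 numeric: `c(gate, pair)` thresholds.
#' @param n_bins Bins per axis.
#' @return List: `density` (matrix, integrates to 1), `x_mids`, `y_mids`,
#'   `quadrants` (2x2 matrix of fractions, rows gate below/above, columns
#'   pair below/above; sums to 1).
#' @export
hist2d_gate_saltbridge <- function(gate, pair, thresholds, n_bins = 50) {
  stopifnot(length(gate) == length(pair), length(thresholds) == 2,
            length(gate) > 0)
  bx <- seq(min(gate), max(gate), length.out = n_bins + 1)
  by <- seq(min(pair), max(pair), length.out = n_bins + 1)
  ix <- pmin(pmax(findInterval(gate, bx, all.inside = TRUE), 1), n_bins)
  iy <- pmin(pmax(findInterval(pair, by, all.inside = TRUE), 1), n_bins)
  counts <- matrix(0, n_bins, n_bins)
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1
  dx <- diff(bx[1:2]); dy <- diff(by[1:2])
  gb <- gate <= thresholds[1]
  pb <- pair <= thresholds[2]
  quad <- matrix(c(mean(gb & pb), mean(gb & !pb),
                   mean(!gb & pb), mean(!gb & !pb)),
                 2, 2, byrow = TRUE,
                 dimnames = list(gate = c("below", "above"),
                                 pair = c("below", "above")))
  list(density = counts / (sum(counts) * dx * dy),
       x_mids = (bx[-1] + bx[-length(bx)]) / 2,
       y_mids = (by[-1] + by[-length(by)]) / 2,
       quadrants = quad)
}
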