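# Discretization of distance trajectories into occupancy states, dwell-time
# and transition censuses, and binding-route classification.

#' Construct a distance trajectory from plain series
#'
#' @param distances Data frame or matrix of per-site distance series
#'   (Angstrom), one column per site.
#' @param dt Frame interval, us.
#' @param sites Site names (default the column names).
#' @param gate Optional gate-distance series (e.g. the HP1-HP2 distance),
#'   same length.
#' @param concentration Bulk concentration, M.
#' @param monomer_id Identifier for the monomer.
#' @return Object of class `distance_trajectory`.
#' @export
distance_trajectory <- function(distances, dt, sites = colnames(distances),
                                gate = NULL, concentration = NA_real_,
                                monomer_id = 1L) {
  distances <- as.data.frame(distances)
  if (is.null(sites)) sites <- paste0("K", seq_len(ncol(distances)))
  stopifnot(dt > 0, length(sites) == ncol(distances))
  if (any(distances < 0, na.rm = TRUE)) stop("distances must be non-negative")
  names(distances) <- sites
  traj <- data.frame(time = (seq_len(nrow(distances)) - 1) * dt, distances,
                     check.names = FALSE)
  if (!is.null(gate)) {
    if (length(gate) != nrow(distances)) {
      stop("gate series length mismatch")
    }
    traj$gate <- gate
  }
  attr(traj, "dt") <- dt
  attr(traj, "concentration") <- concentration
  attr(traj, "monomer_id") <- monomer_id
  attr(traj, "sites") <- sites
  class(traj) <- c("distance_trajectory", "data.frame")
  traj
}

#' Discretize a distance trajectory into bound/unbound occupancy states
#'
#' A site is bound in a frame when its distance is at or below the threshold
#' (ties count as bound, a deterministic rule). The per-site flags are packed
#' into an encoded state index with site s on bit s-1 in the order of
#' `sites`, giving the 2^N-state occupancy alphabet.
#'
#' Frames with non-finite distances are dropped with a report; the default
#' threshold 3.5 Angstrom is the midpoint of the 3.3-3.65 Angstrom working
#' range and can be overridden per site.
#'
#' @param traj A `distance_trajectory`.
#' @param thresholds Scalar or per-site named numeric thresholds (Angstrom).
#' @return Object of class `occupancy_trace`: `flags` (frames x sites
#'   logical), `state` (integer bitmask per frame), `sites`, `thresholds`,
#'   `dt`, `concentration`, `monomer_id`, and `gate` when present.
#' @export
discretize_trajectory <- function(traj, thresholds = 3.5) {
  sites <- attr(traj, "sites")
  if (is.null(sites)) {
    sites <- setdiff(names(traj), c("time", "gate"))
  }
  missing_sites <- setdiff(sites, names(traj))
  if (length(missing_sites)) {
    stop("missing site column(s): ", paste(missing_sites, collapse = ", "))
  }
  if (length(thresholds) == 1 && is.null(names(thresholds))) {
    thresholds <- stats::setNames(rep(thresholds, length(sites)), sites)
  }
  if (!all(sites %in% names(thresholds))) {
    stop("thresholds must cover every site")
  }
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  d <- as.matrix(traj[, sites, drop = FALSE])
  ok <- rowSums(!is.finite(d)) == 0
  if (!all(ok)) {
    warning(sum(!ok), " frame(s) with non-finite distances dropped (frames ",
            min(which(!ok)), "..", max(which(!ok)), ")")
    d <- d[ok, , drop = FALSE]
  }
  flags <- sweep(d, 2, thresholds[sites], "<=")
  state <- as.integer(flags %*% 2L^(seq_along(sites) - 1L))
  out <- list(flags = flags, state = state, sites = sites,
              thresholds = thresholds[sites], dt = attr(traj, "dt"),
              concentration = attr(traj, "concentration"),
              monomer_id = attr(traj, "monomer_id"))
  if ("gate" %in% names(traj)) out$gate <- traj$gate[ok]
  structure(out, class = "occupancy_trace")
}

# run-length view of a state series after flicker merging: runs shorter than
# min_dwell are absorbed into the longer flanking run (earlier neighbor wins
# ties), iterating until stable
merge_short_runs <- function(state, min_dwell = 0) {
  r <- rle(state)
  if (min_dwell <= 1 || length(r$lengths) == 1) return(r)
  repeat {
    short <- which(r$lengths < min_dwell)
    short <- short[r$lengths[short] < min_dwell]
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    n <- length(r$lengths)
    if (n == 1) break
    left <- if (i > 1) r$lengths[i - 1] else -Inf
    right <- if (i < n) r$lengths[i + 1] else -Inf
    j <- if (left >= right) i - 1 else i + 1
    r$values[i] <- r$values[j]
    r <- rle(inverse.rle(r))
    if (length(r$lengths) == 1) break
  }
  r
}

#' Dwell-time and transition census over occupancy traces
#'
#' Pools accumulated state dwell times and directed transition counts over
#' monomers. Runs shorter than `min_dwell` frames are first merged into the
#' longer flanking run (flicker filter; the default 0 applies no filter).
#' Compound transitions in which several site flags flip within one frame
#' are counted as the single observed transition; their frequency is
#' reported in `compound_fraction`.
#'
#' @param traces A single `occupancy_trace` or a list of them.
#' @param min_dwell Minimum run length in frames.
#' @return Object of class `transition_census`: `states` (all 2^N labels),
#'   `N` (transition-count matrix), `t` (dwell time per state, us),
#'   `n_monomers`, `dt`, `concentration`, `per_monomer` (per-trace `N`/`t`
#'   for monomer-level bootstrap), `compound_fraction`.
#' @export
transition_census <- function(traces, min_dwell = 0) {
  if (inherits(traces, "occupancy_trace")) traces <- list(traces)
  if (!length(traces)) stop("no traces supplied")
  sites <- traces[[1]]$sites
  states <- all_state_labels(sites)
  ns <- length(states)
  dt <- traces[[1]]$dt
  per <- lapply(traces, function(tr) {
    stopifnot(identical(tr$sites, sites))
    r <- merge_short_runs(tr$state, min_dwell)
    idx <- r$values + 1L
    tvec <- numeric(ns)
    agg <- tapply(r$lengths, idx, sum)
    tvec[as.integer(names(agg))] <- agg * tr$dt
    N <- matrix(0L, ns, ns)
    if (length(idx) > 1) {
      from <- idx[-length(idx)]
      to <- idx[-1]
      for (k in seq_along(from)) N[from[k], to[k]] <- N[from[k], to[k]] + 1L
    }
    # compound transitions flip more than one site bit at once
    nbits <- vapply(seq_along(idx)[-1], function(k) {
      sum(bitwAnd(bitwXor(r$values[k - 1], r$values[k]),
                  2L^(seq_along(sites) - 1L)) > 0)
    }, numeric(1))
    list(N = N, t = tvec, n_trans = length(idx) - 1L,
         n_compound = sum(nbits > 1))
  })
  N <- Reduce(`+`, lapply(per, `[[`, "N"))
  tvec <- Reduce(`+`, lapply(per, `[[`, "t"))
  dimnames(N) <- list(states, states)
  names(tvec) <- states
  n_trans <- sum(vapply(per, `[[`, numeric(1), "n_trans"))
  n_comp <- sum(vapply(per, `[[`, numeric(1), "n_compound"))
  structure(list(states = states, sites = sites, N = N, t = tvec,
                 n_monomers = length(traces), dt = dt,
                 concentration = traces[[1]]$concentration,
                 per_monomer = per,
                 compound_fraction = if (n_trans > 0) n_comp / n_trans else 0),
            class = "transition_census")
}

#' Classify binding routes into a target site
#'
#' For every frame where the target site's flag turns on, the binding event
#' is classified: `second-ion` when another site remains occupied in the new
#' frame (a second ion joined before the first left), otherwise by the
#' occupancy of the immediately preceding frame -- `direct` from apo,
#' `via-<site>` from a single transiently occupied site, `via-multi` from a
#' multiply occupied state.
#'
#' @param traces An `occupancy_trace` or list of them.
#' @param target_site Site name whose binding events are classified.
#' @return Named integer vector of route counts.
#' @export
binding_route_census <- function(traces, target_site) {
  if (inherits(traces, "occupancy_trace")) traces <- list(traces)
  if (!length(traces)) stop("no traces supplied")
  sites <- traces[[1]]$sites
  if (!target_site %in% sites) stop("target site not present: ", target_site)
  routes <- c("direct", paste0("via-", setdiff(sites, target_site)),
              "via-multi", "second-ion")
  counts <- stats::setNames(integer(length(routes)), routes)
  for (tr in traces) {
    f <- tr$flags
    tcol <- f[, target_site]
    on <- which(!tcol[-length(tcol)] & tcol[-1]) + 1L
    for (i in on) {
      others_now <- f[i, setdiff(sites, target_site), drop = TRUE]
      others_prev <- f[i - 1L, setdiff(sites, target_site), drop = TRUE]
      lab <- if (any(others_now)) {
        "second-ion"
      } else if (!any(others_prev)) {
        "direct"
      } else if (sum(others_prev) == 1) {
        paste0("via-", names(which(others_prev)))
      } else {
        "via-multi"
      }
      counts[lab] <- counts[lab] + 1L
    }
  }
  counts
}
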