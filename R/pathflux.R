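# Transition-path analysis on estimated kinetic models: stationary
# occupancy, committors, reactive flux, and highest-flux pathway
# decomposition by iterative bottleneck subtraction.

#' Build a kinetic model directly from a rate matrix
#'
#' Convenience constructor for transition-path analysis on hand-specified
#' networks (e.g. oracle comparisons), bypassing the census estimator.
#'
#' @param K Square rate matrix (1/us) with zero diagonal; dimnames give the
#'   state labels.
#' @param states Optional state labels.
#' @param concentration Bulk concentration, M.
#' @return Object of class `kinetic_model`.
#' @export
kinetic_model <- function(K, states = rownames(K), concentration = NA_real_) {
  K <- as.matrix(K)
  stopifnot(nrow(K) == ncol(K))
  if (is.null(states)) states <- paste0("S", seq_len(nrow(K)))
  dimnames(K) <- list(states, states)
  if (any(K < 0, na.rm = TRUE)) stop("rates must be non-negative")
  diag(K) <- 0
  connected <- rowSums(K, na.rm = TRUE) + colSums(K, na.rm = TRUE) > 0
  if (!any(connected)) connected <- rep(TRUE, nrow(K))
  structure(list(states = states, K = K,
                 visited = connected,
                 no_events = K == 0 & !diag(TRUE, nrow(K)),
                 concentration = concentration, census = NULL),
            class = "kinetic_model")
}

# infinitesimal generator restricted to visited states
generator_of <- function(model) {
  v <- which(model$visited & !apply(is.na(model$K), 1, all))
  Q <- model$K[v, v, drop = FALSE]
  Q[is.na(Q)] <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# communicating classes via boolean reachability on the jump graph
comm_classes <- function(Q) {
  A <- (Q > 0) | diag(TRUE, nrow(Q))
  R <- A
  for (i in seq_len(ceiling(log2(max(2, nrow(Q)))) + 1)) {
    R <- (R %*% R) > 0
  }
  M <- R & t(R)
  cls <- integer(nrow(Q))
  k <- 0
  for (i in seq_len(nrow(Q))) {
    if (cls[i] == 0) {
      k <- k + 1
      cls[M[i, ]] <- k
    }
  }
  cls
}

#' Stationary distribution of the kinetic model
#'
#' Solves `pi Q = 0` with the generator Q (off-diagonal rates, rows summing
#' to zero), normalized to 1. On reducible chains the distribution is
#' computed per recurrent communicating class (transient states get zero)
#' with a warning; class weights are then undefined and split equally
#' between recurrent classes.
#'
#' @param model A `kinetic_model`.
#' @return Named numeric vector pi over the model's visited states.
#' @export
stationary_distribution <- function(model) {
  Q <- generator_of(model)
  n <- nrow(Q)
  if (n == 1) return(stats::setNames(1, rownames(Q)))
  cls <- comm_classes(Q)
  # a class is recurrent iff no rate leaves it
  recurrent <- vapply(seq_len(max(cls)), function(k) {
    inside <- cls == k
    sum(Q[inside, !inside, drop = FALSE] > 0) == 0
  }, logical(1))
  pi_full <- stats::setNames(numeric(n), rownames(Q))
  if (max(cls) > 1) {
    warning("reducible chain: stationary distribution computed per ",
            "recurrent class with equal class weights")
  }
  rec_ids <- which(recurrent)
  for (k in rec_ids) {
    inside <- which(cls == k)
    Qk <- Q[inside, inside, drop = FALSE]
    diag(Qk) <- 0
    diag(Qk) <- -rowSums(Qk)
    A <- rbind(t(Qk), rep(1, length(inside)))
    b <- c(numeric(length(inside)), 1)
    pk <- stats::setNames(qr.solve(A, b), rownames(Qk))
    pi_full[inside] <- pmax(pk, 0) / length(rec_ids)
  }
  pi_full / sum(pi_full)
}

#' Forward committor probabilities
#'
#' The committor q+ of a state is the probability that a trajectory started
#' there reaches the sink set before the source set. Boundary conditions are
#' q+=0 on the source and q+=1 on the sink; intermediates solve the linear
#' system `sum_j Q_ij q+_j = 0`.
#'
#' @param model A `kinetic_model`.
#' @param source_states,sink_states Disjoint non-empty label sets.
#' @return Named numeric vector q+ in [0, 1]. States dynamically
#'   disconnected from both boundaries are flagged `NA` with a warning.
#' @export
committor <- function(model, source_states, sink_states) {
  Q <- generator_of(model)
  states <- rownames(Q)
  if (!length(source_states) || !length(sink_states)) {
    stop("source and sink must be non-empty")
  }
  if (length(intersect(source_states, sink_states))) {
    stop("source and sink must be disjoint")
  }
  missing_lab <- setdiff(c(source_states, sink_states), states)
  if (length(missing_lab)) stop("unknown state(s): ",
                                paste(missing_lab, collapse = ", "))
  q <- stats::setNames(rep(NA_real_, length(states)), states)
  q[source_states] <- 0
  q[sink_states] <- 1
  inter <- setdiff(states, c(source_states, sink_states))
  if (length(inter)) {
    A <- Q[inter, inter, drop = FALSE]
    b <- -Q[inter, sink_states, drop = FALSE] %*% rep(1, length(sink_states))
    sol <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(sol)) {
      # isolate unreachable intermediates, solve the rest
      deg <- rowSums(abs(A)) + rowSums(abs(Q[inter, c(source_states,
                                                      sink_states),
                                             drop = FALSE]))
      dead <- inter[deg == 0]
      live <- setdiff(inter, dead)
      warning("singular committor system; flagging isolated state(s): ",
              paste(dead, collapse = ", "))
      if (length(live)) {
        sol2 <- solve(Q[live, live, drop = FALSE],
                      -Q[live, sink_states, drop = FALSE] %*%
                        rep(1, length(sink_states)))
        q[live] <- sol2
      }
    } else {
      q[inter] <- sol
    }
  }
  pmin(pmax(q, 0), 1)
}

#' Reactive flux decomposition and highest-flux pathways
#'
#' Computes the stationary distribution, forward committor, gross reactive
#' flux `f_ij = pi_i (1 - q+_i) k_ij q+_j`, and net flux
#' `f+_ij = max(f_ij - f_ji, 0)`, then extracts pathways by iterative
#' bottleneck (widest-path) decomposition of the net-flux graph: each
#' extracted path carries its bottleneck capacity, which is subtracted
#' before the next extraction. Ties between equal-bottleneck paths are
#' broken by lexicographic state order.
#'
#' @param model A `kinetic_model`.
#' @param source,sink State label sets.
#' @param n_paths Maximum number of paths to extract.
#' @return Object of class `flux_decomposition`: `pi`, `qplus`,
#'   `flux_gross`, `flux_net`, `total_flux`, `paths` (list of
#'   `list(states, flux)`, ranked non-increasing), `source`, `sink`.
#' @export
reactive_flux_paths <- function(model, source, sink, n_paths = 2) {
  pi_v <- stationary_distribution(model)
  q <- committor(model, source, sink)
  Q <- generator_of(model)
  states <- rownames(Q)
  K <- Q; diag(K) <- 0
  f <- outer(pi_v * (1 - q), q) * K
  f[is.na(f)] <- 0
  diag(f) <- 0
  # no flux within the boundary sets
  f[source, source] <- 0
  f[sink, sink] <- 0
  fnet <- pmax(f - t(f), 0)
  total <- sum(fnet[source, setdiff(states, source), drop = FALSE])
  paths <- list()
  if (total <= 0) {
    message("zero total reactive flux; no pathways to extract")
  } else {
    g <- fnet
    for (p in seq_len(n_paths)) {
      wp <- widest_path(g, source, sink)
      if (is.null(wp) || wp$width <= 0) break
      idx <- match(wp$path, states)
      for (k in seq_len(length(idx) - 1)) {
        g[idx[k], idx[k + 1]] <- g[idx[k], idx[k + 1]] - wp$width
      }
      paths[[p]] <- list(states = wp$path, flux = wp$width)
    }
  }
  structure(list(pi = pi_v, qplus = q, flux_gross = f, flux_net = fnet,
                 total_flux = total, paths = paths,
                 source = source, sink = sink),
            class = "flux_decomposition")
}

# maximum-bottleneck (widest) path from any source to any sink on a
# capacity matrix; deterministic lexicographic tie-breaking on state labels
widest_path <- function(cap, source, sink) {
  states <- rownames(cap)
  n <- length(states)
  width <- stats::setNames(rep(-Inf, n), states)
  width[source] <- Inf
  prev <- stats::setNames(rep(NA_character_, n), states)
  done <- stats::setNames(rep(FALSE, n), states)
  repeat {
    cand <- which(!done & width > -Inf)
    if (!length(cand)) break
    # pick max width; ties -> lexicographically smallest label
    w <- width[cand]
    best <- cand[w == max(w)]
    u <- best[order(states[best])][1]
    done[u] <- TRUE
    if (states[u] %in% sink) next
    for (v in which(cap[u, ] > 0)) {
      nw <- min(width[u], cap[u, v])
      if (nw > width[v] ||
          (nw == width[v] && !is.na(prev[v]) &&
           states[u] < prev[v])) {
        width[v] <- nw
        prev[v] <- states[u]
      }
    }
  }
  reached <- sink[width[sink] > 0]
  if (!length(reached)) return(NULL)
  w <- width[reached]
  end <- reached[w == max(w)]
  end <- end[order(end)][1]
  path <- unname(end)
  while (!is.na(prev[path[1]])) path <- c(unname(prev[path[1]]), path)
  list(path = path, width = unname(width[end]))
}

#' Export a flux decomposition as JSON
#'
#' Nodes carry the stationary occupancy and committor; edges the net flux.
#'
#' @param fd A `flux_decomposition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
flux_to_json <- function(fd, path) {
  edges <- which(fd$flux_net > 0, arr.ind = TRUE)
  states <- names(fd$pi)
  jsonlite::write_json(list(
    nodes = data.frame(state = states, pi = unname(fd$pi),
                       committor = unname(fd$qplus[states])),
    edges = data.frame(from = states[edges[, 1]], to = states[edges[, 2]],
                       net_flux = fd$flux_net[edges]),
    total_flux = fd$total_flux,
    paths = lapply(fd$paths, function(p)
      list(states = p$states, flux = p$flux))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a flux decomposition as DOT graph text
#'
#' @param fd A `flux_decomposition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
flux_to_dot <- function(fd, path) {
  states <- names(fd$pi)
  lines <- c("digraph flux {")
  lines <- c(lines, sprintf('  "%s" [width=%.4f];', states,
                            pmax(0.2, 2 * sqrt(fd$pi))))
  e <- which(fd$flux_net > 0, arr.ind = TRUE)
  if (nrow(e)) {
    lines <- c(lines, sprintf('  "%s" -> "%s" [label="%.3g"];',
                              states[e[, 1]], states[e[, 2]],
                              fd$flux_net[e]))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Demonstration relay-biased occupancy network
#'
#' An occupancy network over sites K1-K3 in which direct apo->K1
#' association is rare and relay through the transient K2/K3 scavenger
#' sites dominates, the regime that makes relay pathways carry the highest
#' reactive flux. Rates are built from per-state free energies with
#' symmetric kinetic prefactors, `k_ij = A_ij exp(-(G_j - G_i)/2)`, so the
#' model satisfies detailed balance by construction.
#'
#' @param concentration_M Bulk concentration, M.
#' @return A `kinetic_model`.
#' @export
demo_relay_model <- function(concentration_M = 1) {
  sites <- c("K1", "K2", "K3")
  states <- all_state_labels(sites)
  G <- c(apo = 0, K1 = -2, K2 = 1, K3 = 2,
         "K1+K2" = -0.5, "K2+K3" = 2.5)
  A <- list(c("apo", "K2", 20), c("apo", "K3", 8), c("apo", "K1", 0.05),
            c("K2", "K1", 10), c("K3", "K1", 5),
            c("K1", "K1+K2", 3), c("K2", "K2+K3", 2))
  K <- matrix(0, 8, 8, dimnames = list(states, states))
  for (e in A) {
    i <- e[1]; j <- e[2]; a <- as.numeric(e[3])
    K[i, j] <- a * exp(-(G[j] - G[i]) / 2)
    K[j, i] <- a * exp(-(G[i] - G[j]) / 2)
  }
  kinetic_model(K, concentration = concentration_M)
}
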