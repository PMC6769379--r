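# Maximum-likelihood rate estimation from dwell-time censuses, per-site
# dissociation constants with monomer-level bootstrap, and the single-event
# upper-bound construction for sites that never unbind.

#' Maximum-likelihood rate matrix from a transition census
#'
#' The ML estimator for chemical reaction rates from a discretized
#' trajectory is `k_ij = N_ij / t_i`: accumulated transition count divided
#' by the accumulated dwell time of the origin state. States never visited
#' (zero dwell time, zero outgoing counts) get flagged undefined rows rather
#' than zeros; a positive count out of a zero-dwell state is an
#' inconsistency and errors.
#'
#' @param census A [transition_census()].
#' @return Object of class `kinetic_model`: `states`, `K` (rate matrix,
#'   1/us, `NA` rows for unvisited states), `visited`, `no_events` (logical
#'   matrix marking defined-but-zero rates), `concentration`, and the
#'   `census`.
#' @export
estimate_rate_matrix <- function(census) {
  stopifnot(inherits(census, "transition_census"))
  N <- census$N
  t_i <- census$t
  bad <- t_i == 0 & rowSums(N) > 0
  if (any(bad)) {
    stop("inconsistent census: transitions out of zero-dwell state(s) ",
         paste(census$states[bad], collapse = ", "))
  }
  K <- N / t_i
  visited <- t_i > 0
  K[!visited, ] <- NA_real_
  diag(K) <- 0
  no_events <- visited & (N == 0)
  diag(no_events) <- FALSE
  structure(list(states = census$states, sites = census$sites, K = K,
                 visited = visited, no_events = no_events,
                 concentration = census$concentration, census = census),
            class = "kinetic_model")
}

# aggregate site-level on/off rates from a census: binding pools every
# transition that sets the site's bit over the dwell time with the bit
# clear, and conversely for unbinding
site_rates <- function(census, site) {
  s <- match(site, census$sites)
  if (is.na(s)) stop("unknown site: ", site)
  bit <- 2L^(s - 1L)
  idx <- seq_along(census$states) - 1L
  has <- bitwAnd(idx, bit) > 0
  n_on <- sum(census$N[!has, has])
  n_off <- sum(census$N[has, !has])
  t_off <- sum(census$t[!has])
  t_on <- sum(census$t[has])
  list(k_on = if (t_off > 0) n_on / t_off else NA_real_,
       k_off = if (t_on > 0) n_off / t_on else NA_real_,
       n_on = n_on, n_off = n_off, t_on = t_on, t_off = t_off)
}

# rebuild a pooled census from a subset of per-monomer components
pool_census <- function(census, idx) {
  per <- census$per_monomer[idx]
  out <- census
  out$N <- Reduce(`+`, lapply(per, `[[`, "N"))
  out$t <- stats::setNames(Reduce(`+`, lapply(per, `[[`, "t")),
                           census$states)
  dimnames(out$N) <- dimnames(census$N)
  out$n_monomers <- length(idx)
  out$per_monomer <- per
  out
}

#' Dissociation constant of a site with bootstrap error
#'
#' K_D is the off rate divided by the second-order on rate, where the
#' second-order on rate is the observed pseudo-first-order on rate divided
#' by the bulk concentration. All compound occupancy states sharing the
#' site's bit are pooled. The error is the SD over bootstrap resamples of
#' complete monomer trajectories.
#'
#' @param census A [transition_census()] (must carry a finite
#'   concentration).
#' @param site Site name.
#' @param n_boot Bootstrap resamples (0 to skip).
#' @param seed Optional seed.
#' @param level Confidence level of the percentile CI.
#' @return List with `kd_mM`, `sd`, `ci`, `boot` (resampled K_D values,
#'   mM), `k_off` (1/us), `k_on2` (1/us/M), `n_on`, `n_off`.
#' @export
dissociation_constants <- function(census, site, n_boot = 1000, seed = NULL,
                                   level = 0.95) {
  stopifnot(inherits(census, "transition_census"))
  conc <- census$concentration
  if (!is.finite(conc) || conc <= 0) {
    stop("census carries no usable bulk concentration")
  }
  kd_of <- function(cn) {
    r <- site_rates(cn, site)
    if (!is.finite(r$k_on) || r$n_on == 0) return(NA_real_)
    1000 * r$k_off / (r$k_on / conc)  # M -> mM
  }
  r0 <- site_rates(census, site)
  if (r0$n_on == 0) {
    stop("no binding events observed for ", site,
         "; use kd_upper_bound() instead")
  }
  kd <- kd_of(census)
  out <- list(kd_mM = kd, sd = NA_real_, ci = c(NA_real_, NA_real_),
              boot = numeric(0), k_off = r0$k_off,
              k_on2 = r0$k_on / conc, n_on = r0$n_on, n_off = r0$n_off)
  if (n_boot > 0) {
    if (census$n_monomers < 2) {
      warning("bootstrap over a single monomer is degenerate")
    }
    bs <- bootstrap_statistic(seq_len(census$n_monomers),
                              function(idx) kd_of(pool_census(census,
                                                              unlist(idx))),
                              n_boot = n_boot, seed = seed, level = level)
    out$sd <- bs$sd
    out$ci <- bs$ci
    out$boot <- bs$boot
  }
  out
}

#' Upper bound on a K_D from a single hypothetical escape event
#'
#' For a site that never unbinds within the sampled time, an upper bound on
#' its dissociation constant follows from positing exactly one relocation
#' out of the site in the accumulated site-bound dwell time
#' (`k_out_max = 1 / t_bound`) and combining it, by detailed balance on the
#' relocation step, with the observed reference-to-target relocation rate
#' and the reference site's known K_D:
#' `K_D(target) <= K_D(reference) * k_out_max / k_in_obs`.
#'
#' @param census A [transition_census()].
#' @param site Target site (never observed unbinding).
#' @param reference_site Site from which relocations into the target were
#'   observed.
#' @param reference_kd_mM Known K_D of the reference site, mM.
#' @return List: `bound_mM`, `t_bound` (us), `k_out_max`, `k_in_obs`
#'   (1/us), `n_relocations`, and `assumption` describing the construction.
#' @export
kd_upper_bound <- function(census, site, reference_site, reference_kd_mM) {
  stopifnot(inherits(census, "transition_census"), reference_kd_mM > 0)
  s <- match(site, census$sites)
  r <- match(reference_site, census$sites)
  if (is.na(s) || is.na(r)) stop("unknown site name")
  bit_s <- 2L^(s - 1L); bit_r <- 2L^(r - 1L)
  idx <- seq_along(census$states) - 1L
  has_s <- bitwAnd(idx, bit_s) > 0
  has_r <- bitwAnd(idx, bit_r) > 0
  t_bound <- sum(census$t[has_s])
  if (t_bound <= 0) stop("no dwell time in ", site, "-bound states")
  # reference -> target relocations: reference on & target off -> target on & reference off
  from <- has_r & !has_s
  to <- has_s & !has_r
  n_reloc <- sum(census$N[from, to])
  t_from <- sum(census$t[from])
  if (n_reloc == 0 || t_from <= 0) {
    stop("no ", reference_site, "->", site,
         " relocations observed; bound undefined")
  }
  k_in <- n_reloc / t_from
  k_out_max <- 1 / t_bound
  list(bound_mM = reference_kd_mM * k_out_max / k_in,
       t_bound = t_bound, k_out_max = k_out_max, k_in_obs = k_in,
       n_relocations = n_reloc,
       assumption = paste0("one hypothetical ", site, "->", reference_site,
                           " relocation in ", signif(t_bound, 4),
                           " us of ", site, "-bound dwell time"))
}

#' Bootstrap a kinetic statistic over monomer trajectories
#'
#' Resamples complete monomer components of a census with replacement,
#' recomputes the statistic on the pooled resample, and reports SD and
#' percentile CI. Failed resamples (statistic undefined) are recorded.
#'
#' @param census A [transition_census()] with at least 2 monomers.
#' @param statistic Function of a pooled `transition_census` returning a
#'   scalar.
#' @param n_boot Number of resamples.
#' @param seed Optional seed.
#' @param level Confidence level.
#' @return As [bootstrap_statistic()].
#' @export
bootstrap_kinetics <- function(census, statistic, n_boot = 1000, seed = NULL,
                               level = 0.95) {
  stopifnot(inherits(census, "transition_census"))
  if (census$n_monomers < 2) stop("need >= 2 monomer trajectories")
  bootstrap_statistic(seq_len(census$n_monomers),
                      function(idx) statistic(pool_census(census,
                                                          unlist(idx))),
                      n_boot = n_boot, seed = seed, level = level)
}
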