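# Crooks Gaussian-intersection free-energy estimation from forward/reverse
# non-equilibrium work distributions, block-convergence diagnostics, and
# double-difference statistics for selectivities and mutation effects.

# intersection of two fitted Gaussian densities; root between the means,
# equal-variance midpoint when the variances are numerically equal
cgi_point <- function(mu_f, s_f, mu_r, s_r, var_tol = 1e-6) {
  if (abs(s_f^2 - s_r^2) < var_tol * max(s_f^2, s_r^2)) {
    return(list(dg = (mu_f + mu_r) / 2, method = "midpoint"))
  }
  a <- 1 / s_f^2 - 1 / s_r^2
  b <- -2 * (mu_f / s_f^2 - mu_r / s_r^2)
  cc <- mu_f^2 / s_f^2 - mu_r^2 / s_r^2 - 2 * log(s_r / s_f)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) {
    return(list(dg = (mu_f + mu_r) / 2, method = "midpoint-fallback"))
  }
  roots <- (-b + c(1, -1) * sqrt(disc)) / (2 * a)
  lo <- min(mu_f, mu_r); hi <- max(mu_f, mu_r)
  inside <- roots[roots >= lo & roots <= hi]
  if (!length(inside)) {
    return(list(dg = (mu_f + mu_r) / 2, method = "midpoint-fallback"))
  }
  list(dg = inside[1], method = "cgi")
}

#' Crooks Gaussian-intersection free-energy estimate
#'
#' Fits a Normal to each work distribution (sample mean, unbiased sample
#' SD) and takes the free-energy change as the work value at which the two
#' fitted densities intersect -- the root of the intersection quadratic
#' lying between the two means. When the fitted variances agree to within
#' tolerance the equal-variance midpoint `(mu_f + mu_r)/2` is used; when no
#' root lies between the means (pathological overlap) the midpoint is used
#' and flagged. The error is the SD over bootstrap resamples of works
#' within each direction; convergence is checked by chronological block
#' splitting.
#'
#' @param works A [work_set()] (reverse works stored as -W of the reverse
#'   process).
#' @param n_boot Bootstrap resamples.
#' @param seed Optional seed.
#' @param drop_head Fraction of each direction's works discarded from the
#'   head (equilibration drop; default 0 for synthetic data).
#' @return Object of class `free_energy_estimate`: `dg` (kJ/mol), `sd`,
#'   `boot` (bootstrap values), `method` (`"cgi"`, `"midpoint"`, or
#'   `"midpoint-fallback"`), `convergence` (from [block_convergence()],
#'   `NULL` when too few works), `mu_f`, `mu_r`, `sd_f`, `sd_r`,
#'   `temperature`.
#' @export
cgi_estimate <- function(works, n_boot = 1000, seed = NULL, drop_head = 0) {
  stopifnot(inherits(works, "work_set"))
  wf <- works$forward
  wr <- works$reverse
  if (drop_head > 0) {
    wf <- wf[-seq_len(floor(drop_head * length(wf)))]
    wr <- wr[-seq_len(floor(drop_head * length(wr)))]
  }
  if (length(wf) < 2 || length(wr) < 2) {
    stop("need >= 2 works per direction after equilibration drop")
  }
  pt <- cgi_point(mean(wf), stats::sd(wf), mean(wr), stats::sd(wr))
  if (pt$method == "midpoint-fallback") {
    warning("no density intersection between the means; midpoint fallback")
  }
  boot <- numeric(0)
  sd_boot <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(b) {
      f <- sample(wf, replace = TRUE)
      r <- sample(wr, replace = TRUE)
      cgi_point(mean(f), stats::sd(f), mean(r), stats::sd(r))$dg
    }, numeric(1))
    sd_boot <- stats::sd(boot)
  }
  conv <- if (length(wf) >= 4 && length(wr) >= 4) {
    block_convergence(work_set(wf, wr, works$temperature))
  } else NULL
  structure(list(dg = pt$dg, sd = sd_boot, boot = boot, method = pt$method,
                 convergence = conv,
                 mu_f = mean(wf), mu_r = mean(wr),
                 sd_f = stats::sd(wf), sd_r = stats::sd(wr),
                 temperature = works$temperature),
            class = "free_energy_estimate")
}

#' Chronological block-convergence check for work sets
#'
#' Splits each direction chronologically into two halves, estimates the
#' free energy on each block, and flags convergence when the two block
#' estimates differ by less than 10% of their mean magnitude. Near-zero
#' mean estimates switch to an absolute criterion of 1 kJ/mol.
#'
#' @param works A [work_set()] with >= 4 works per direction.
#' @param rel_tol Relative difference threshold.
#' @param abs_floor Absolute criterion used when the mean block estimate is
#'   below this magnitude (kJ/mol).
#' @return List: `converged`, `blocks` (the two block estimates),
#'   `rel_diff` (NA when the absolute criterion was used), `criterion`.
#' @export
block_convergence <- function(works, rel_tol = 0.10, abs_floor = 1) {
  stopifnot(inherits(works, "work_set"))
  nf <- length(works$forward); nr <- length(works$reverse)
  if (nf < 4 || nr < 4) stop("need >= 4 works per direction")
  half <- function(x) list(x[seq_len(floor(length(x) / 2))],
                           x[(floor(length(x) / 2) + 1):length(x)])
  hf <- half(works$forward); hr <- half(works$reverse)
  dgs <- vapply(1:2, function(i) {
    cgi_point(mean(hf[[i]]), stats::sd(hf[[i]]),
              mean(hr[[i]]), stats::sd(hr[[i]]))$dg
  }, numeric(1))
  m <- mean(dgs)
  if (abs(m) < abs_floor) {
    list(converged = abs(diff(dgs)) < abs_floor, blocks = dgs,
         rel_diff = NA_real_, criterion = "absolute")
  } else {
    rel <- abs(diff(dgs)) / abs(m)
    list(converged = rel < rel_tol, blocks = dgs, rel_diff = rel,
         criterion = "relative")
  }
}

#' Double difference of two free-energy estimates
#'
#' Computes `ddG = dG_a - dG_b`, the construction behind both ion
#' selectivities (same transformation at two sites/species) and mutation
#' effects (side-chain transformation in the bound vs the apo protein). The
#' default error adds the two bootstrap SDs in quadrature; with
#' `paired = TRUE` and bootstrap samples available on both estimates, the
#' SD of the paired bootstrap differences is used instead.
#'
#' @param est_a,est_b [cgi_estimate()] results.
#' @param paired Pair the bootstrap samples instead of quadrature.
#' @return List: `ddg` (kJ/mol), `sd`, `mode`.
#' @export
double_difference <- function(est_a, est_b, paired = FALSE) {
  stopifnot(inherits(est_a, "free_energy_estimate"),
            inherits(est_b, "free_energy_estimate"))
  ddg <- est_a$dg - est_b$dg
  if (paired) {
    na <- length(est_a$boot); nb <- length(est_b$boot)
    if (na < 2 || nb < 2) stop("paired mode needs bootstrap samples on both")
    n <- min(na, nb)
    list(ddg = ddg, sd = stats::sd(est_a$boot[seq_len(n)] -
                                     est_b$boot[seq_len(n)]),
         mode = "paired")
  } else {
    if (!is.finite(est_a$sd) || !is.finite(est_b$sd)) {
      stop("both estimates need bootstrap SDs for quadrature")
    }
    list(ddg = ddg, sd = sqrt(est_a$sd^2 + est_b$sd^2), mode = "quadrature")
  }
}

#' Read a two-column work table (direction, work)
#'
#' Accepts delimited text with a direction column (`forward`/`reverse`,
#' `f`/`r`, or `0`/`1`) and a work column in kJ/mol; reverse works are
#' interpreted as already negated onto the forward axis.
#'
#' @param path File path (comment lines starting with `#` or `@` skipped).
#' @param temperature K.
#' @param sep Field separator (default comma).
#' @return A [work_set()].
#' @export
read_work_table <- function(path, temperature = 310, sep = ",") {
  df <- read_timeseries_table(path, sep = sep)
  if (ncol(df) < 2) stop("expected (direction, work) columns")
  dir <- tolower(as.character(df[[1]]))
  fwd <- dir %in% c("forward", "f", "0")
  rev <- dir %in% c("reverse", "r", "1")
  if (!all(fwd | rev)) stop("unrecognized direction labels")
  work_set(as.numeric(df[[2]][fwd]), as.numeric(df[[2]][rev]), temperature)
}
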