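# Thermophoresis binding-curve normalization, Nadaraya-Watson kernel
# regression with bootstrap confidence bands, and the band-overlap
# significance test.

#' Normalize raw thermophoresis traces into binding curves
#'
#' The steady-state fluorescence of each trace is divided by the value at
#' the reference time after the temperature jump (the rapid initial drop is
#' a dye property, not thermophoresis); each replicate curve is then
#' anchored to 1 at its lowest concentration. Doubling all raw
#' fluorescence leaves the output unchanged.
#'
#' @param raw Long data frame with columns `curve`, `concentration`
#'   (mM), `time` (s), `fluorescence`.
#' @param reference_time Reference time after the jump, s.
#' @param steady_frac Trailing fraction of each trace averaged as the
#'   steady state.
#' @return Object of class `mst_curves`: `concentrations`, `curves`
#'   (matrix concentrations x curves).
#' @export
normalize_mst <- function(raw, reference_time = 0.4, steady_frac = 0.2) {
  need <- c("curve", "concentration", "time", "fluorescence")
  stopifnot(all(need %in% names(raw)))
  conc <- sort(unique(raw$concentration))
  curves_id <- unique(raw$curve)
  m <- matrix(NA_real_, length(conc), length(curves_id),
              dimnames = list(NULL, curves_id))
  for (cu in curves_id) {
    for (ci in seq_along(conc)) {
      tr <- raw[raw$curve == cu & raw$concentration == conc[ci], ,
                drop = FALSE]
      if (!nrow(tr)) next
      tr <- tr[order(tr$time), ]
      if (reference_time < min(tr$time) || reference_time > max(tr$time)) {
        stop("reference time ", reference_time, " s not covered by trace (curve ",
             cu, ", concentration ", conc[ci], ")")
      }
      ref <- tr$fluorescence[which.min(abs(tr$time - reference_time))]
      tail_n <- max(1, ceiling(steady_frac * nrow(tr)))
      steady <- mean(utils::tail(tr$fluorescence, tail_n))
      m[ci, cu] <- steady / ref
    }
  }
  if (anyNA(m)) stop("missing (curve, concentration) combinations")
  m <- sweep(m, 2, m[1, ], "/")
  structure(list(concentrations = conc, curves = m),
            class = "mst_curves")
}

# Nadaraya-Watson local-constant regression with a Gaussian kernel
nw_regress <- function(x, y, grid, h) {
  K <- stats::dnorm(outer(grid, x, "-") / h)
  as.numeric((K %*% y) / rowSums(K))
}

# Silverman's rule of thumb on the design points
silverman_bw <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  iqr <- stats::IQR(x) / 1.34
  spread <- if (iqr > 0) min(s, iqr) else s
  if (!is.finite(spread) || spread <= 0) {
    stop("cannot compute an automatic bandwidth from degenerate design points")
  }
  0.9 * spread * n^(-1 / 5)
}

#' Kernel-regression fit of binding curves with bootstrap confidence bands
#'
#' Local-constant (Nadaraya-Watson) regression with a Gaussian kernel on
#' the log10-concentration axis (serial dilutions are geometric), with the
#' bandwidth from Silverman's rule of thumb unless given. Complete
#' replicate curves are the independent bootstrap units; percentile bands
#' at the requested level are reported on an evaluation grid.
#'
#' @param curves An `mst_curves` object (or list with `concentrations` and
#'   a `curves` matrix).
#' @param bandwidth `"auto"` (Silverman) or a positive number
#'   (log10-concentration units).
#' @param n_boot Bootstrap resamples of whole curves.
#' @param level Band level (default 0.99).
#' @param seed Optional seed.
#' @param n_grid Evaluation grid size.
#' @return Object of class `mst_fit`: `grid` (log10 mM), `mean`, `lo`,
#'   `hi`, `bandwidth`, `n_boot`, `level`, `single_curve` flag.
#' @export
nw_fit_with_ci <- function(curves, bandwidth = "auto", n_boot = 10000,
                           level = 0.99, seed = NULL, n_grid = 101) {
  conc <- curves$concentrations
  m <- curves$curves
  if (is.null(dim(m))) m <- matrix(m, ncol = 1)
  if (length(conc) < 3) stop("need >= 3 concentrations")
  x <- log10(conc)
  h <- if (identical(bandwidth, "auto")) silverman_bw(x) else bandwidth
  if (!is.finite(h) || h <= 0) stop("bandwidth must be positive")
  grid <- seq(min(x), max(x), length.out = n_grid)
  xx <- rep(x, ncol(m))
  fit_mean <- nw_regress(xx, as.numeric(m), grid, h)
  single <- ncol(m) < 2
  lo <- hi <- rep(NA_real_, n_grid)
  if (!single && n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    boot <- matrix(NA_real_, n_boot, n_grid)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(ncol(m), replace = TRUE)
      mb <- m[, idx, drop = FALSE]
      boot[b, ] <- nw_regress(rep(x, ncol(mb)), as.numeric(mb), grid, h)
    }
    a <- (1 - level) / 2
    qs <- apply(boot, 2, stats::quantile, probs = c(a, 1 - a))
    lo <- qs[1, ]; hi <- qs[2, ]
  } else if (single) {
    warning("single curve: fit reported without confidence bands")
  }
  structure(list(grid = grid, mean = fit_mean, lo = lo, hi = hi,
                 bandwidth = h, n_boot = n_boot, level = level,
                 single_curve = single),
            class = "mst_fit")
}

#' Significance by confidence-band overlap
#'
#' Flags grid points where the two confidence bands are disjoint; the
#' overall verdict is "significant" when a contiguous run of non-overlap
#' spans at least `min_run_frac` of the common grid (a single isolated
#' point does not count, to avoid multiplicity artifacts). Fits on
#' different grids are interpolated onto their common concentration range.
#'
#' @param fit_a,fit_b `mst_fit` objects with bands.
#' @param min_run_frac Minimum contiguous non-overlap run, as a fraction of
#'   the grid.
#' @return List: `grid`, `nonoverlap` (logical per grid point),
#'   `significant`, `longest_run_frac`.
#' @export
ci_overlap_test <- function(fit_a, fit_b, min_run_frac = 0.10) {
  for (f in list(fit_a, fit_b)) {
    if (anyNA(f$lo) || anyNA(f$hi)) stop("both fits need confidence bands")
  }
  lo_c <- max(min(fit_a$grid), min(fit_b$grid))
  hi_c <- min(max(fit_a$grid), max(fit_b$grid))
  if (lo_c >= hi_c) stop("fits cover disjoint concentration ranges")
  grid <- seq(lo_c, hi_c, length.out = max(length(fit_a$grid),
                                           length(fit_b$grid)))
  regrid <- function(f, what) stats::approx(f$grid, f[[what]], grid)$y
  aL <- regrid(fit_a, "lo"); aH <- regrid(fit_a, "hi")
  bL <- regrid(fit_b, "lo"); bH <- regrid(fit_b, "hi")
  non <- (aL > bH) | (bL > aH)
  runs <- rle(non)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  frac <- longest / length(grid)
  list(grid = grid, nonoverlap = non, significant = frac >= min_run_frac,
       longest_run_frac = frac)
}
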