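# Linear voltage-charge capacitor fits and charge displacements between
# conformational/occupancy states.

#' Assemble a capacitor series from plain records
#'
#' @param q_sol Imposed ionic charge imbalances, e0.
#' @param V Measured transmembrane voltages, mV.
#' @param replicate Replicate (trajectory) identifiers.
#' @param state State label (conformation x occupancy).
#' @return A `capacitor_series` data frame.
#' @export
capacitor_series <- function(q_sol, V, replicate = 1L, state = "state0") {
  if (length(unique(q_sol)) < 2) stop("need at least 2 distinct q_sol values")
  df <- data.frame(state = state, q_sol = q_sol, V = V,
                   replicate = replicate)
  class(df) <- c("capacitor_series", "data.frame")
  df
}

#' Fit the linear voltage-charge capacitor model
#'
#' Ordinary least squares of `V = (q_sol + q_p0) / C0`: the fitted slope
#' gives `C0 = 1/slope` and the intercept `q_p0 = intercept/slope`, the
#' protein contribution to the capacitor charge. On the fitted line the
#' voltage vanishes at `q_sol = -q_p0`. A non-positive slope (non-physical
#' capacitance) is rejected. Errors come from bootstrap over complete
#' replicate trajectories at fixed charge imbalance, never over individual
#' points.
#'
#' @param series A `capacitor_series` (columns `q_sol`, `V`, `replicate`).
#' @param n_boot Bootstrap resamples (0 to skip).
#' @param seed Optional seed.
#' @return Object of class `charge_fit`: `C0` (e0/mV), `q_p0` (e0), `sd`
#'   (bootstrap SD of q_p0), `boot` (resampled q_p0), `residuals`,
#'   `state`.
#' @export
fit_capacitor_response <- function(series, n_boot = 1000, seed = NULL) {
  stopifnot(all(c("q_sol", "V") %in% names(series)))
  if (length(unique(series$q_sol)) < 2) {
    stop("need at least 2 distinct q_sol values")
  }
  fit_one <- function(df) {
    fit <- stats::lm(V ~ q_sol, data = df)
    a <- unname(stats::coef(fit)[2])
    b <- unname(stats::coef(fit)[1])
    if (!is.finite(a) || a <= 0) stop("non-physical capacitance: slope <= 0")
    list(C0 = 1 / a, q_p0 = b / a, res = stats::residuals(fit))
  }
  pt <- fit_one(series)
  boot <- numeric(0); sd_b <- NA_real_
  reps <- unique(series$replicate)
  if (n_boot > 0 && length(reps) >= 2) {
    bs <- bootstrap_statistic(reps, function(rs) {
      df <- do.call(rbind, lapply(unlist(rs), function(r) {
        series[series$replicate == r, , drop = FALSE]
      }))
      fit_one(df)$q_p0
    }, n_boot = n_boot, seed = seed)
    boot <- bs$boot
    sd_b <- bs$sd
  }
  structure(list(C0 = pt$C0, q_p0 = pt$q_p0, sd = sd_b, boot = boot,
                 residuals = pt$res,
                 state = if ("state" %in% names(series))
                   as.character(series$state[1]) else "state0"),
            class = "charge_fit")
}

#' Charge displacement between two fitted states
#'
#' The effective charge moved between two protein conformations (or
#' occupancy states) is the difference of their fitted protein charges,
#' `dq = q_p0(state1) - q_p0(state0)`, with the SD combined in quadrature
#' from the two bootstrap SDs.
#'
#' @param fit_state0,fit_state1 [fit_capacitor_response()] results.
#' @return List: `dq` (e0), `sd`, `states`.
#' @export
charge_displacement <- function(fit_state0, fit_state1) {
  stopifnot(inherits(fit_state0, "charge_fit"),
            inherits(fit_state1, "charge_fit"))
  list(dq = fit_state1$q_p0 - fit_state0$q_p0,
       sd = sqrt(fit_state0$sd^2 + fit_state1$sd^2),
       states = c(fit_state0$state, fit_state1$state))
}

#' Displacement matrix across a set of fitted states
#'
#' @param fits Named list of `charge_fit`s.
#' @return List of matrices `dq` and `sd` (state x state).
#' @export
charge_displacement_matrix <- function(fits) {
  n <- length(fits)
  nm <- names(fits) %||% vapply(fits, `[[`, "", "state")
  dq <- matrix(0, n, n, dimnames = list(nm, nm))
  sd <- dq
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- charge_displacement(fits[[i]], fits[[j]])
    dq[i, j] <- d$dq
    sd[i, j] <- d$sd
  }
  list(dq = dq, sd = sd)
}
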