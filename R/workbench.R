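# Shared I/O, bootstrap machinery and the end-to-end pipeline driver.

#' Read a delimited time-series table, skipping xvg-style comments
#'
#' Parses plain delimited text with comment lines beginning with `#` or `@`
#' (the convention of GROMACS xvg output) and optionally renames columns via
#' a column map so that heterogeneous upstream tools can feed the same
#' downstream analysis.
#'
#' @param path File path.
#' @param column_map Optional named character vector mapping desired column
#'   names to the names (or 1-based indices as character) present in the file,
#'   e.g. `c(time = "V1", K1 = "V2")`.
#' @param sep Field separator passed to [utils::read.table()]; default
#'   whitespace.
#' @param header Logical; whether the first non-comment line holds column
#'   names. Default `FALSE` (xvg-style files are headerless).
#' @return A `data.frame` of the data rows.
#' @export
read_timeseries_table <- function(path, column_map = NULL, sep = "",
                                  header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("no data rows in ", path)
  df <- utils::read.table(text = lines[keep], sep = sep, header = header,
                          stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    src <- as.character(column_map)
    idx <- match(src, names(df))
    num <- suppressWarnings(as.integer(src))
    idx[is.na(idx) & !is.na(num)] <- num[is.na(idx) & !is.na(num)]
    if (anyNA(idx) || any(idx > ncol(df))) {
      stop("columns not found: ",
           paste(src[is.na(idx) | idx > ncol(df)], collapse = ", "))
    }
    df <- df[, idx, drop = FALSE]
    names(df) <- names(column_map)
  }
  df
}

#' Write a time-series table with a JSON metadata header
#'
#' Writes CSV preceded by a single `#`-prefixed JSON comment line carrying
#' metadata (time step, units, seed, ...), so files remain self-describing
#' yet parseable by [read_timeseries_table()].
#'
#' @param x A data.frame.
#' @param path Output path.
#' @param meta Named list of metadata serialized into the header comment.
#' @return `path`, invisibly.
#' @export
write_timeseries_table <- function(x, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                             digits = NA)), con)
  }
  utils::write.table(x, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generic bootstrap over independent sampling units
#'
#' Resamples whole units (e.g. complete monomer trajectories) with
#' replacement and recomputes a statistic, following the convention that
#' complete trajectories -- not individual frames -- are the independent
#' samples.
#'
#' @param samples A list (or atomic vector) of sampling units.
#' @param statistic Function applied to a list of units, returning a scalar.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Optional integer seed for reproducibility.
#' @param level Confidence level for the percentile interval.
#' @return List with `mean`, `sd`, `ci` (percentile), `boot` (vector of
#'   resample values), and `failed` (fraction of resamples on which the
#'   statistic errored or returned non-finite).
#' @export
bootstrap_statistic <- function(samples, statistic, n_boot = 1000,
                                seed = NULL, level = 0.95) {
  if (is.atomic(samples)) samples <- as.list(samples)
  n <- length(samples)
  if (n < 1) stop("need at least one sampling unit")
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    val <- tryCatch(statistic(samples[idx]), error = function(e) NA_real_)
    if (length(val) != 1L || !is.finite(val)) NA_real_ else as.numeric(val)
  }, numeric(1))
  failed <- mean(is.na(boot))
  if (failed > 0.5) stop("statistic failed on ", round(100 * failed),
                         "% of resamples")
  ok <- boot[!is.na(boot)]
  a <- (1 - level) / 2
  list(mean = mean(ok), sd = stats::sd(ok),
       ci = unname(stats::quantile(ok, c(a, 1 - a))),
       boot = boot, failed = failed,
       degenerate = n_boot < 2)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the configured stages in dependency order
#' (binding-trace generation, occupancy discretization, kinetics,
#' transition-path analysis; alchemical estimation; gating profiles;
#' capacitor fits; thermophoresis fits), writing each stage's report under
#' `outdir` together with a JSON manifest of parameters and seeds. A stage
#' failure aborts only its downstream dependents; the manifest records
#' partial completion.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Recognized top-level keys: `seed`, `outdir`, and `stages` (a named
#'   list; see the shipped demo configuration in
#'   `system.file("extdata", "demo_config.yaml", package = "kgate")`).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outdir <- if (is.null(config$outdir)) "kgate_out" else config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  if (is.null(stages)) stages <- list()
  manifest <- list(package = "kgate",
                   version = as.character(utils::packageVersion("kgate")),
                   seed = seed, stages = list())
  done <- function(name, status, outputs = character(), note = NULL) {
    manifest$stages[[name]] <<- list(status = status, outputs = outputs,
                                     note = note)
  }

  kinetics_ok <- FALSE
  census <- NULL

  if (!is.null(stages$binding)) {
    p <- stages$binding
    res <- tryCatch({
      spec <- two_state_spec(kd_mM = p$kd_mM %||% 8,
                             concentration_M = p$concentration_M %||% 1,
                             k_off = p$k_off %||% 1)
      trajs <- gen_binding_traj(spec,
                                duration = p$duration_us %||% 20,
                                dt = p$dt_us %||% 0.001,
                                n_monomers = p$n_monomers %||% 4,
                                seed = seed)
      occ <- lapply(trajs$trajectories, discretize_trajectory)
      census <- transition_census(occ)
      kd <- dissociation_constants(census, site = spec$sites[1],
                                   n_boot = p$n_boot %||% 200,
                                   seed = seed + 1L)
      f <- file.path(outdir, "kd_report.json")
      jsonlite::write_json(list(site = spec$sites[1], kd_mM = kd$kd_mM,
                                sd_mM = kd$sd, ci_mM = kd$ci,
                                n_on = kd$n_on, n_off = kd$n_off,
                                true_kd_mM = p$kd_mM %||% 8),
                           f, auto_unbox = TRUE, digits = NA)
      kinetics_ok <- TRUE
      f
    }, error = function(e) e)
    if (inherits(res, "error")) done("binding", "failed", note = conditionMessage(res))
    else done("binding", "ok", res)
  }

  if (!is.null(stages$pathflux)) {
    p <- stages$pathflux
    res <- tryCatch({
      model <- if (kinetics_ok && !is.null(census)) {
        estimate_rate_matrix(census)
      } else if (!is.null(p$rates)) {
        demo_relay_model(concentration_M = p$concentration_M %||% 1)
      } else stop("pathflux needs an upstream census or explicit rates")
      fd <- reactive_flux_paths(model, source = p$source %||% "apo",
                                sink = p$sink %||% model$states[length(model$states)],
                                n_paths = p$n_paths %||% 2)
      f1 <- file.path(outdir, "flux_graph.json")
      f2 <- file.path(outdir, "flux_graph.dot")
      flux_to_json(fd, f1); flux_to_dot(fd, f2)
      c(f1, f2)
    }, error = function(e) e)
    if (inherits(res, "error")) done("pathflux", "failed", note = conditionMessage(res))
    else done("pathflux", "ok", res)
  }

  if (!is.null(stages$alchemy)) {
    p <- stages$alchemy
    res <- tryCatch({
      ws <- gen_work_samples(dg = p$dg %||% 19.7, sigma = p$sigma %||% 4,
                             n_forward = p$n %||% 250, n_reverse = p$n %||% 250,
                             seed = seed + 2L)
      est <- cgi_estimate(ws, n_boot = p$n_boot %||% 1000, seed = seed + 3L)
      f <- file.path(outdir, "cgi_report.json")
      jsonlite::write_json(list(dg_kJmol = est$dg, sd = est$sd,
                                method = est$method,
                                converged = est$convergence$converged,
                                blocks = est$convergence$blocks,
                                true_dg = p$dg %||% 19.7),
                           f, auto_unbox = TRUE, digits = NA)
      f
    }, error = function(e) e)
    if (inherits(res, "error")) done("alchemy", "failed", note = conditionMessage(res))
    else done("alchemy", "ok", res)
  }

  if (!is.null(stages$gating)) {
    p <- stages$gating
    res <- tryCatch({
      pmf <- calibrate_double_well(p_closed = p$p_closed %||% 0.59)
      uset <- gen_umbrella_set(pmf,
                               centers = seq(pmf$domain[1] + 0.05,
                                             pmf$domain[2] - 0.05,
                                             length.out = p$n_windows %||% 44),
                               force_constant = p$force_constant %||% 1000,
                               n_per_window = p$n_per_window %||% 2000,
                               seed = seed + 4L)
      prof <- wham_profile(uset, n_boot = p$n_boot %||% 50,
                           seed = seed + 5L)
      b <- find_gate_boundary(list(mids = prof$x, counts = prof$p))
      pc <- closed_probability(prof, b)
      f <- file.path(outdir, "gating_profile.csv")
      utils::write.csv(data.frame(x = prof$x, G = prof$G, p = prof$p,
                                  sd_G = prof$sd_G), f, row.names = FALSE)
      f2 <- file.path(outdir, "gating_report.json")
      jsonlite::write_json(list(boundary = b, p_closed = pc$p_closed,
                                sd = pc$sd, true_p_closed = p$p_closed %||% 0.59),
                           f2, auto_unbox = TRUE, digits = NA)
      c(f, f2)
    }, error = function(e) e)
    if (inherits(res, "error")) done("gating", "failed", note = conditionMessage(res))
    else done("gating", "ok", res)
  }

  if (!is.null(stages$charge)) {
    p <- stages$charge
    res <- tryCatch({
      ser <- gen_capacitor_series(q_p0 = p$q_p0 %||% 2, C0 = p$C0 %||% 0.5,
                                  q_sol_values = p$q_sol %||% seq(-12, -6, 1.2),
                                  noise_sd = p$noise_sd %||% 2,
                                  n_replicates = p$n_replicates %||% 5,
                                  seed = seed + 6L)
      fit <- fit_capacitor_response(ser, n_boot = p$n_boot %||% 500,
                                    seed = seed + 7L)
      f <- file.path(outdir, "charge_report.json")
      jsonlite::write_json(list(C0 = fit$C0, q_p0 = fit$q_p0, sd = fit$sd,
                                true_q_p0 = p$q_p0 %||% 2),
                           f, auto_unbox = TRUE, digits = NA)
      f
    }, error = function(e) e)
    if (inherits(res, "error")) done("charge", "failed", note = conditionMessage(res))
    else done("charge", "ok", res)
  }

  if (!is.null(stages$mst)) {
    p <- stages$mst
    res <- tryCatch({
      conc <- p$concentrations %||% (3000 / 2^(11:0))
      cs <- gen_mst_curves(kd = p$kd_mM %||% 30, amplitude = p$amplitude %||% 0.2,
                           baseline = p$baseline %||% 1,
                           concentrations = conc,
                           noise_sd = p$noise_sd %||% 0.01,
                           n_curves = p$n_curves %||% 5, seed = seed + 8L)
      fit <- nw_fit_with_ci(cs, n_boot = p$n_boot %||% 2000, seed = seed + 9L)
      f <- file.path(outdir, "mst_fit.csv")
      utils::write.csv(data.frame(log10_conc = fit$grid, mean = fit$mean,
                                  lo = fit$lo, hi = fit$hi), f,
                       row.names = FALSE)
      f
    }, error = function(e) e)
    if (inherits(res, "error")) done("mst", "failed", note = conditionMessage(res))
    else done("mst", "ok", res)
  }

  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
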