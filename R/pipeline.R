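# End-to-end pipeline: simulate a scenario dataset, fit and extrapolate all
# requested families with uncertainty bands, and run the cost-effectiveness
# analysis.  Each command takes a flat configuration list (read from YAML via
# `read_run_config()`), writes CSV/JSON artifacts into `config$out_dir`, and
# embeds the seed and a config fingerprint in a sidecar metadata file so any
# run can be reproduced bit for bit.

default_run_config <- function() {
  # NB: the sample-size key is `sample_size`, not `n` — a bare `n` is a
  # YAML 1.1 boolean and would silently vanish from config files.
  list(scenario = "flat", sample_size = 400, censor_time = 1, seed = 1L,
       dataset_csv = NULL,
       families = SURVIVAL_FAMILIES,
       grid_start = 0.025, observed_end = 1, extrapolation_end = 4,
       grid_step = 0.025,
       method = "mvn", B = 1000, mvn_seed = DEFAULT_SEED,
       mean_horizon = 10,
       hazard_ratio = 0.75, cost_control_2wk = 100,
       cost_intervention_extra_2wk = 100, psa_samples = 1000,
       wtp = 20000,
       out_dir = ".", plots = FALSE)
}

#' Read a pipeline run configuration
#'
#' Reads a flat key-value YAML file and merges it over the documented
#' defaults.  Keys: `scenario` (one of flat/increasing/decreasing/unimodal)
#' or `dataset_csv`; `sample_size`, `censor_time`, `seed`; `families`; grid controls
#' (`grid_start`, `observed_end`, `extrapolation_end`, `grid_step`);
#' uncertainty controls (`method`, `B`, `mvn_seed`, `mean_horizon`); CEA
#' controls (`hazard_ratio`, costs, `psa_samples`, `wtp`); `out_dir`,
#' `plots`.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param ... named overrides applied after the file.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, ...) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (!all(cfg$families %in% SURVIVAL_FAMILIES))
    hazext_error(sprintf("unknown families: %s",
                         paste(setdiff(cfg$families, SURVIVAL_FAMILIES),
                               collapse = ", ")), "hazext_usage_error")
  if (cfg$observed_end >= cfg$extrapolation_end)
    hazext_error("`observed_end` must be below `extrapolation_end`",
                 "hazext_usage_error")
  if (is.null(cfg$dataset_csv) && !cfg$scenario %in% SCENARIO_KINDS)
    hazext_error(sprintf("`scenario` must be one of: %s",
                         paste(SCENARIO_KINDS, collapse = ", ")),
                 "hazext_usage_error")
  structure(cfg, class = c("run_config", "list"))
}

config_fingerprint <- function(cfg) {
  # FNV-1a (32-bit) over the canonical JSON encoding, in double arithmetic
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # h * 16777619 mod 2^32 without losing precision past 2^53
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

write_metadata <- function(cfg, stage, extra, path) {
  meta <- c(list(stage = stage, config = unclass(cfg),
                 config_fingerprint = config_fingerprint(cfg),
                 seed = cfg$seed, package_version =
                   as.character(utils::packageVersion("hazext"))),
            extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

get_dataset <- function(cfg) {
  if (!is.null(cfg$dataset_csv)) return(load_dataset(cfg$dataset_csv))
  make_dataset(scenario_spec(cfg$scenario, n = cfg$sample_size,
                             censor_time = cfg$censor_time,
                             seed = cfg$seed))
}

#' Pipeline stage 1: simulate a scenario dataset
#'
#' Writes `dataset_<scenario>.csv` and a metadata JSON (scenario, seed,
#' event/censor counts, config fingerprint) into `config$out_dir`.
#' Identical configs produce byte-identical CSVs.
#'
#' @param config a [read_run_config()] list.
#' @return The [survival_data()] invisibly; paths in attributes.
#' @export
cmd_simulate <- function(config = read_run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- get_dataset(config)
  csv <- file.path(config$out_dir,
                   sprintf("dataset_%s.csv", config$scenario))
  write_dataset(d, csv)
  meta <- write_metadata(config, "simulate",
                         list(n = nrow(d), n_events = n_events(d),
                              censor_fraction = 1 - n_events(d) / nrow(d)),
                         sub("\\.csv$", "_meta.json", csv))
  message(sprintf("[simulate] %s: n=%d events=%d censored=%.1f%% -> %s",
                  config$scenario, nrow(d), n_events(d),
                  100 * (1 - n_events(d) / nrow(d)), csv))
  attr(d, "csv") <- csv
  attr(d, "meta") <- meta
  invisible(d)
}

fit_summary_list <- function(fit) {
  list(family = fit$family,
       params = fit$fp$params,
       par_est = as.list(fit$par_est),
       se_est = as.list(stats::setNames(sqrt(diag(fit$vcov)),
                                        names(fit$par_est))),
       vcov = unname(apply(fit$vcov, 1, as.list)),
       loglik = fit$loglik, n = fit$n, n_events = fit$n_events,
       converged = fit$converged)
}

#' Pipeline stage 2: fit all families and extrapolate with uncertainty
#'
#' Fits every requested family to the dataset, evaluates hazard and
#' survival curves with 95% bands over a grid running from `grid_start` to
#' `extrapolation_end` (the observed/extrapolated boundary is marked in the
#' tidy output), and computes mean survival at `mean_horizon`.  Writes
#' `curves.csv`, `models.json`, `mean_survival.json` and optional plots.
#' Fits that do not converge are reported with `converged: false`, never
#' dropped silently.
#'
#' @param config a [read_run_config()] list.
#' @return Invisible list with fits, curves and mean-survival estimates.
#' @export
cmd_fit_extrapolate <- function(config = read_run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- get_dataset(config)
  grid <- time_grid(seq(config$grid_start, config$extrapolation_end,
                        by = config$grid_step),
                    observed_end = config$observed_end)
  fits <- list(); curves <- list(); means <- list()
  for (fam in config$families) {
    fit <- tryCatch(fit_parametric(d, fam), error = function(e) e)
    if (inherits(fit, "error")) {
      message(sprintf("[fit] %s FAILED: %s", fam, conditionMessage(fit)))
      fits[[fam]] <- list(family = fam, error = conditionMessage(fit))
      next
    }
    message(sprintf("[fit] %s logLik=%.2f converged=%s", fam, fit$loglik,
                    fit$converged))
    fits[[fam]] <- fit
    mk <- function(q) {
      cv <- if (config$method == "mvn")
        mvn_curve(fit, q, grid, B = config$B, seed = config$mvn_seed)
      else delta_curve(fit, q, grid)
      cv
    }
    for (q in c("hazard", "survival")) {
      cv <- mk(q)
      df <- tidy_curves(cv)
      df$family <- fam
      curves[[paste(fam, q)]] <- df
    }
    means[[fam]] <- mean_survival(fit, horizon = config$mean_horizon,
                                  method = config$method, B = config$B,
                                  seed = config$mvn_seed)
  }
  curve_df <- do.call(rbind, curves)
  utils::write.csv(curve_df, file.path(config$out_dir, "curves.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(fits, function(f)
      if (inherits(f, "hazext_fit")) fit_summary_list(f) else f),
    file.path(config$out_dir, "models.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(lapply(means, unclass),
                       file.path(config$out_dir, "mean_survival.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_metadata(config, "fit_extrapolate",
                 list(n = nrow(d), n_events = n_events(d)),
                 file.path(config$out_dir, "fit_meta.json"))
  if (isTRUE(config$plots)) {
    pdf_path <- file.path(config$out_dir, "curves.pdf")
    grDevices::pdf(pdf_path, width = 8, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    for (nm in names(curves))
      plot_curve_df(curves[[nm]], main = nm,
                    observed_end = config$observed_end)
  }
  invisible(list(fits = fits, curves = curve_df, means = means))
}

#' Pipeline stage 3: cost-effectiveness analysis per candidate model
#'
#' Runs the two-state Markov model and PSA for each requested family fitted
#' to the configured dataset (the increasing-hazard scenario by default, per
#' the case study), writing `cea_summary.json` and `psa_draws.csv`.
#'
#' @param config a [read_run_config()] list; `scenario` defaults to
#'   `"increasing"` for this stage unless a dataset is given.
#' @return Invisible list of per-family PSA summaries.
#' @export
cmd_cea <- function(config = read_run_config(scenario = "increasing")) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- get_dataset(config)
  spec <- markov_spec(hazard_ratio = config$hazard_ratio,
                      cost_control_2wk = config$cost_control_2wk,
                      cost_intervention_extra_2wk =
                        config$cost_intervention_extra_2wk)
  summaries <- list(); draw_rows <- list()
  for (fam in config$families) {
    fit <- tryCatch(fit_parametric(d, fam), error = function(e) e)
    if (inherits(fit, "error")) {
      summaries[[fam]] <- list(family = fam, error = conditionMessage(fit))
      next
    }
    psa <- run_psa(fit, spec, n_samples = config$psa_samples,
                   seed = config$mvn_seed)
    sm <- summary(psa, wtp = config$wtp)
    sm$ceac <- NULL                      # tabulated separately below
    sm$point <- as.list(sm$point)
    sm$mean_outcomes <- as.list(sm$mean_outcomes)
    sm$ceac_at_wtp <- ceac(psa, config$wtp)$p_intervention
    summaries[[fam]] <- sm
    dd <- psa$draws
    dd$family <- fam
    dd$draw <- seq_len(nrow(dd))
    draw_rows[[fam]] <- dd
    message(sprintf("[cea] %s ICER=%.0f EVPI(%g)=%.2f", fam, psa$icer,
                    config$wtp, sm$evpi_at_wtp))
  }
  utils::write.csv(do.call(rbind, draw_rows),
                   file.path(config$out_dir, "psa_draws.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summaries,
                       file.path(config$out_dir, "cea_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_metadata(config, "cea", list(n = nrow(d), n_events = n_events(d)),
                 file.path(config$out_dir, "cea_meta.json"))
  invisible(summaries)
}
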