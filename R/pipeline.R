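#' Default pipeline configuration
#'
#' One nested list holding every constant of the analysis, with defaults
#' matching the experimental protocol and analysis settings the pipeline
#' models: 4 Hz Hartley updates capped at 0.15 cpd on a 60 x 34 cm screen
#' viewed at 20 cm, 15.5 Hz imaging, a 135 ms indicator half-decay with a
#' 10-knot drift spline, fivefold cross-validation with `r_L >= 0.15`
#' selection and > 20 cells per accepted field, 30 um distance bins to
#' 210 um, and 50/150 um near/far cut-offs.
#'
#' @return A nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    screen = list(width_cm = 60, height_cm = 34, distance_cm = 20),
    stimulus = list(update_rate_hz = 4, sf_max_cpd = 0.15, duration_s = 1200),
    imaging_rate_hz = 15.5,
    calcium = list(tau_half_ms = 135, n_knots = 10),
    fit = list(r_L_threshold = 0.15, n_folds = 5, n_lags = 8,
               penalty_grid = as.numeric(10^seq(-0.5, 2.5, by = 1))),
    selection = list(min_cells = 20),
    clustering = list(bin_edges = seq(0, 210, by = 30),
                      near_um = 50, far_um = 150,
                      kurtosis_threshold = 15, peak_sf_min_cpd = 0.025,
                      n_boot = 200,
                      depth_levels = c(0, 40, 80, 120)),
    sheet = list(n_cells = 50, field_um = 250, plane_depths_um = 0,
                 map_length_um = 30, column_decorrelation = 0,
                 interneuron_frac = 0.1, low_sf_bias_weight = 0.3,
                 gain_mean = 5),
    seed = 1
  ), class = "pipeline_config")
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, fills unspecified entries with the defaults of
#' [default_config()], and rejects unknown keys and invalid values.  An
#' empty file yields the full default configuration.
#'
#' @param path Path to a YAML config file.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste("config file not found:", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  merged <- merge_config(default_config(), user, "")
  validate_config(merged)
  structure(merged, class = "pipeline_config")
}

#' @rdname load_config
#' @param config A `pipeline_config` to write.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

merge_config <- function(def, user, prefix) {
  unknown <- setdiff(names(user), names(def))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ",
                 paste0(prefix, unknown, collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      if (!is.list(user[[k]])) abort(paste0("config key ", prefix, k,
                                            " must be a mapping"))
      def[[k]] <- merge_config(def[[k]], user[[k]], paste0(prefix, k, "$"))
    } else {
      def[[k]] <- user[[k]]
    }
  }
  def
}

validate_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) abort(paste("invalid config:", what))
  chk(cfg$stimulus$sf_max_cpd > 0, "stimulus$sf_max_cpd must be > 0")
  chk(cfg$stimulus$update_rate_hz > 0, "stimulus$update_rate_hz must be > 0")
  chk(cfg$stimulus$duration_s > 0, "stimulus$duration_s must be > 0")
  chk(cfg$imaging_rate_hz > 0, "imaging_rate_hz must be > 0")
  chk(cfg$calcium$tau_half_ms > 0, "calcium$tau_half_ms must be > 0")
  chk(all(cfg$fit$penalty_grid > 0), "fit$penalty_grid must be > 0")
  chk(cfg$fit$n_folds >= 2, "fit$n_folds must be >= 2")
  chk(cfg$fit$r_L_threshold >= 0, "fit$r_L_threshold must be >= 0")
  chk(!is.unsorted(cfg$clustering$bin_edges, strictly = TRUE),
      "clustering$bin_edges must increase")
  chk(cfg$sheet$map_length_um >= 0, "sheet$map_length_um must be >= 0")
  chk(cfg$sheet$column_decorrelation >= 0 &&
        cfg$sheet$column_decorrelation <= 1,
      "sheet$column_decorrelation must be in [0, 1]")
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Composes the stages end to end: (optional) synthetic-data generation,
#' preprocessing (neuropil correction, noise estimation, deconvolution,
#' kurtosis), kernel fitting with cross-validated smoothness, `r_L` cell
#' selection and field acceptance, and — when the field is accepted —
#' the clustering analysis: similarity-distance curve, exponential decay
#' fit with bootstrap CI, near/far preference tests, per-field
#' correlation, depth analysis (when several planes exist) and the three
#' robustness filters.  Fully deterministic given `config$seed`.
#'
#' @param config A `pipeline_config` (see [default_config()]).
#' @param dataset Optional input dataset (as produced by
#'   [simulate_dataset()] or [read_dataset()]); when `NULL` a synthetic
#'   dataset is generated from `config$sheet`.
#' @param out_dir Optional directory; when given, per-cell QC and fit
#'   tables, the pair table, the similarity curve and the JSON report
#'   are written there.
#'
#' @return A list of class `run_report` (also serialized to
#'   `report.json` under `out_dir`).
#' @export
run_pipeline <- function(config = default_config(), dataset = NULL,
                         out_dir = NULL) {
  validate_config(config)
  seed <- config$seed
  if (is.null(dataset)) {
    sheet <- do.call(sheet_config, c(
      config$sheet,
      list(duration_s = config$stimulus$duration_s,
           update_rate_hz = config$stimulus$update_rate_hz,
           sf_max_cpd = config$stimulus$sf_max_cpd,
           imaging_rate_hz = config$imaging_rate_hz,
           tau_half_ms = config$calcium$tau_half_ms,
           screen = do.call(screen_geometry, config$screen))
    ))
    dataset <- simulate_dataset(sheet, seed = seed)
  }
  design <- dataset$design
  ts <- preprocess_traces(
    dataset$raw, dataset$neuropil, dataset$imaging_rate_hz,
    config$calcium$tau_half_ms, config$calcium$n_knots,
    config$clustering$kurtosis_threshold, cells = dataset$cells
  )
  fitcfg <- fit_config(
    n_lags = config$fit$n_lags, penalty_grid = config$fit$penalty_grid,
    n_folds = config$fit$n_folds, r_L_threshold = config$fit$r_L_threshold
  )
  fits <- fit_kernels(ts$spikes, design, dataset$running, fitcfg,
                      cells = dataset$cells)
  fits$summary$kurtosis <- ts$kurtosis
  sel <- select_cells(fits, config$fit$r_L_threshold,
                      config$selection$min_cells)
  report <- list(
    package_version = as.character(utils::packageVersion("saltpepper")),
    seed = seed,
    config_hash = rlang::hash(unclass(config)),
    n_cells = nrow(fits$summary),
    n_significant = sel$n_kept,
    field_accepted = sel$accepted
  )
  clustering <- NULL
  if (sel$accepted) {
    clustering <- cluster_field(sel$fits, config)
    report <- c(report, clustering$report)
  } else {
    report$note <- "field rejected: clustering skipped"
  }
  out <- structure(
    list(report = report, dataset = dataset, traces = ts, fits = fits,
         selection = sel, clustering = clustering, config = config),
    class = "run_report"
  )
  if (!is.null(out_dir)) write_report(out, out_dir)
  out
}

# clustering stage on the selected cells of one (possibly multi-plane) field
cluster_field <- function(fits, config) {
  cc <- config$clustering
  cells <- fits$summary
  pairs <- pair_table(cells, fits$W)
  curve <- bin_similarity(pairs, cc$bin_edges)
  decay <- fit_exponential_decay(pairs, cc$bin_edges, n_boot = cc$n_boot,
                                 seed = config$seed)
  nf_ori <- try_or_null(near_far_preference_test(
    pairs, cc$near_um, cc$far_um, "d_ori_deg"))
  nf_sf <- try_or_null(near_far_preference_test(
    pairs, cc$near_um, cc$far_um, "d_log_sf"))
  pf <- try_or_null(per_field_correlation(pairs))
  depth <- NULL
  if (length(unique(cells$depth_um)) > 1) {
    depth <- try_or_null(depth_similarity_analysis(pairs, cc$depth_levels,
                                                   cc$bin_edges))
  }
  filters <- list()
  for (mode in c("kurtosis_ge_15", "peak_sf_gt_0.025", "roi_top_80pct")) {
    filters[[mode]] <- try_or_null({
      keep <- attr(robustness_filter(cells, mode), "kept")
      fp <- pair_table(cells[keep, ], fits$W[, keep, drop = FALSE])
      fc <- bin_similarity(fp, cc$bin_edges)
      list(n_cells = length(keep), curve = fc,
           first_bin_p = fc$ranksum_p_vs_last[1])
    })
  }
  report <- list(
    n_pairs = nrow(pairs),
    lambda_um = decay$length_constant_um,
    lambda_ci95_um = decay$ci95_lambda,
    decay_amplitude = decay$amplitude,
    decay_asymptote = decay$asymptote,
    first_bin_p = curve$ranksum_p_vs_last[1],
    near_far_ori_p = if (is.null(nf_ori)) NA else nf_ori$p,
    near_far_sf_p = if (is.null(nf_sf)) NA else nf_sf$p,
    field_correlation_r = if (is.null(pf)) NA else pf$r,
    field_correlation_p = if (is.null(pf)) NA else pf$p,
    filter_first_bin_p = lapply(filters, function(f) {
      if (is.null(f)) NA else f$first_bin_p
    })
  )
  list(pairs = pairs, curve = curve, decay = decay, near_far_ori = nf_ori,
       near_far_sf = nf_sf, per_field = pf, depth = depth,
       filters = filters, report = report)
}

try_or_null <- function(expr) {
  tryCatch(expr, error = function(e) {
    message("stage skipped: ", conditionMessage(e))
    NULL
  })
}

#' @export
print.run_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("<run_report> %d cells, %d significant; field %s\n",
              r$n_cells, r$n_significant,
              if (r$field_accepted) "accepted" else "rejected"))
  if (!is.null(r$lambda_um)) {
    cat(sprintf("  lambda = %.1f um (95%% CI %.1f-%.1f), first-bin p = %.2g\n",
                r$lambda_um, r$lambda_ci95_um[1], r$lambda_ci95_um[2],
                r$first_bin_p))
  }
  invisible(x)
}

write_report <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(qc_table(run$traces), file.path(out_dir, "qc.csv"),
                   row.names = FALSE)
  utils::write.csv(run$fits$summary, file.path(out_dir, "fits.csv"),
                   row.names = FALSE)
  write_matrix_csv(run$fits$W, file.path(out_dir, "kernels_w.csv"))
  write_matrix_csv(run$fits$V, file.path(out_dir, "kernels_v.csv"))
  if (!is.null(run$clustering)) {
    utils::write.csv(as.data.frame(run$clustering$pairs),
                     file.path(out_dir, "pairs.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(run$clustering$curve),
                     file.path(out_dir, "similarity_curve.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(run$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
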