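#' Signed percent change with direction label
#'
#' `100 * (value - reference) / reference`, reported both as a signed
#' value and as a positive magnitude with an `"increase"` / `"decrease"`
#' direction label (the form used in prose like "RMSE increased by
#' 66.827%").
#'
#' @param reference Baseline value (non-zero).
#' @param value New value.
#' @return List of class `percent_change`: `signed`, `magnitude`,
#'   `direction`.
#' @export
#' @examples
#' percent_change(0.208, 0.347)  # +66.827% increase
percent_change <- function(reference, value) {
  if (!is.finite(reference) || reference == 0) abort_argument("reference must be finite and non-zero")
  signed <- 100 * (value - reference) / reference
  structure(list(signed = signed, magnitude = abs(signed),
                 direction = if (signed > 0) "increase" else if (signed < 0) "decrease" else "none"),
            class = "percent_change")
}

#' @export
print.percent_change <- function(x, digits = 3, ...) {
  if (x$direction == "none") {
    cat("0% (no change)\n")
  } else {
    cat(sprintf("%.*f%% %s\n", digits, x$magnitude, x$direction))
  }
  invisible(x)
}

#' Across-family summary of a model-comparison table
#'
#' Averages R2, RMSE and RPD over the model families for each input set
#' and split, and computes the percent changes of the fused set
#' (`VIs+TIs`) against each single-source set per split and metric.
#'
#' @param results_table Tidy results from [run_experiment()] (columns
#'   `family`, `input_set`, `split`, `R2`, `RMSE`, `RPD`).
#' @return List of class `lai_summary`: `means` (input_set x split means)
#'   and `changes` (percent-change rows `comparison`, `split`, `metric`,
#'   `signed`, `magnitude`, `direction`).
#' @export
summarize_input_sets <- function(results_table) {
  need <- c("family", "input_set", "split", "R2", "RMSE", "RPD")
  if (!all(need %in% names(results_table))) {
    abort_argument(paste0("results table must have columns ", paste(need, collapse = ", ")))
  }
  fams <- unique(results_table$family)
  sets <- unique(results_table$input_set)
  splits <- unique(results_table$split)
  grid <- expand.grid(family = fams, input_set = sets, split = splits,
                      stringsAsFactors = FALSE)
  key <- function(d) paste(d$family, d$input_set, d$split)
  missing_cells <- setdiff(key(grid), key(results_table))
  if (length(missing_cells)) {
    abort_argument(paste0("incomplete results; missing cells: ",
                          paste(missing_cells, collapse = "; ")))
  }
  means <- aggregate(results_table[c("R2", "RMSE", "RPD")],
                     by = results_table[c("input_set", "split")], FUN = mean)
  changes <- NULL
  fused <- "VIs+TIs"
  if (fused %in% sets) {
    refs <- setdiff(sets, fused)
    rows <- list()
    for (ref in refs) {
      for (sp in splits) {
        for (m in c("R2", "RMSE", "RPD")) {
          base <- means[means$input_set == ref & means$split == sp, m]
          val <- means[means$input_set == fused & means$split == sp, m]
          pc <- percent_change(base, val)
          rows[[length(rows) + 1L]] <- data.frame(
            comparison = paste0(fused, " vs ", ref), split = sp, metric = m,
            signed = pc$signed, magnitude = pc$magnitude, direction = pc$direction,
            stringsAsFactors = FALSE)
        }
      }
    }
    changes <- do.call(rbind, rows)
  }
  structure(list(means = means, changes = changes), class = "lai_summary")
}

#' @export
print.lai_summary <- function(x, digits = 3, ...) {
  cat("Across-family means by input set and split:\n")
  m <- x$means
  m[c("R2", "RMSE", "RPD")] <- lapply(m[c("R2", "RMSE", "RPD")], round, digits)
  print(m, row.names = FALSE)
  if (!is.null(x$changes)) {
    cat("\nFused-set percent changes:\n")
    ch <- x$changes
    ch$magnitude <- round(ch$magnitude, digits)
    print(ch[c("comparison", "split", "metric", "magnitude", "direction")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Extract the per-plot feature table from scene rasters
#'
#' For each date scene: reads the multiband raster, computes windowed
#' texture maps for the configured texture bands, and per plot ROI emits
#' the band-mean reflectances (`b444`, ..., `b842`) and the ROI-mean
#' texture features (`mean_650`, ..., `cor_842`). Rows are joined with
#' the LAI table on `(plot_id, date)`.
#'
#' @param raster_paths One multiband TIFF per date.
#' @param dates Date labels, parallel to `raster_paths`.
#' @param rois Named list of ROI objects (from [read_rois()]).
#' @param lai_table Data.frame `plot_id`, `date`, `lai`.
#' @param texture_config A [glcm_config()].
#' @return Feature data.frame: `plot_id`, `date`, `lai`, band means,
#'   24 texture features.
#' @export
extract_features <- function(raster_paths, dates, rois, lai_table,
                             texture_config = glcm_config()) {
  if (length(raster_paths) != length(dates)) {
    abort_argument("raster_paths and dates must be parallel")
  }
  rows <- list()
  for (d in seq_along(raster_paths)) {
    stack <- read_stack(raster_paths[d])
    tmaps <- list()
    for (wl in texture_config$bands) {
      b <- band_index(stack, wl)
      tmaps[[as.character(wl)]] <- texture_maps(stack$pixels[, , b], texture_config)
    }
    for (roi in rois) {
      px <- extract_plot_pixels(stack, roi)
      bm <- plot_mean_reflectance(px)
      names(bm) <- paste0("b", stack$registry$wavelength)
      tx <- roi_texture_means(tmaps, roi)
      rows[[length(rows) + 1L]] <- data.frame(
        plot_id = roi$plot_id, date = as.character(dates[d]),
        as.list(bm), as.list(tx), stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  feats <- do.call(rbind, rows)
  merged <- merge(feats, lai_table[, c("plot_id", "date", "lai")],
                  by = c("plot_id", "date"), sort = FALSE)
  if (nrow(merged) < nrow(feats)) {
    abort_argument(sprintf("LAI table is missing %d plot/date combinations",
                           nrow(feats) - nrow(merged)))
  }
  merged[order(merged$date, merged$plot_id), , drop = FALSE]
}

# Pipeline configuration ---------------------------------------------------

#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent list) with exactly
#' one of a `synthetic` block ([canopy_params()] fields; `seed` mandatory)
#' or an `input` block (`rasters`, `dates`, `rois`, `lai` paths), plus
#' optional `texture` ([glcm_config()] fields), `screening`
#' (`vi_threshold`), and `modeling` (`families`, `folds`) blocks and a
#' top-level `seed`.
#'
#' @param config Path to a YAML file, or a list.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort_io(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort_argument("config must be a list or a YAML path")
  has_syn <- !is.null(config$synthetic)
  has_real <- !is.null(config$input)
  if (has_syn == has_real) {
    abort_argument("exactly one of `synthetic` or `input` must be configured")
  }
  if (is.null(config$seed)) abort_argument("config$seed is mandatory")
  config$seed <- as.integer(config$seed)
  if (has_syn) {
    syn <- config$synthetic
    syn$seed <- if (is.null(syn$seed)) config$seed else as.integer(syn$seed)
    if (!is.null(syn$plot_size)) syn$plot_size <- as.integer(unlist(syn$plot_size))
    if (!is.null(syn$lai_range)) syn$lai_range <- as.numeric(unlist(syn$lai_range))
    config$synthetic <- syn
  } else {
    inp <- config$input
    for (f in c("rasters", "rois", "lai")) {
      if (is.null(inp[[f]])) abort_argument(sprintf("input$%s is required", f))
    }
  }
  tex <- config$texture
  config$texture_config <- glcm_config(
    levels = if (is.null(tex$levels)) 64L else tex$levels,
    window = if (is.null(tex$window)) 3L else tex$window,
    offsets = if (is.null(tex$offsets)) {
      rbind(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
    } else {
      do.call(rbind, lapply(tex$offsets, as.integer))
    },
    symmetric = if (is.null(tex$symmetric)) TRUE else tex$symmetric,
    bands = if (is.null(tex$bands)) c(650, 705, 842) else as.numeric(unlist(tex$bands))
  )
  if (is.null(config$screening$vi_threshold)) config$screening$vi_threshold <- 0.700
  if (is.null(config$modeling$families)) {
    config$modeling$families <- c("SVM", "RF", "BPNN", "PLSR")
  }
  if (is.null(config$modeling$folds)) config$modeling$folds <- 10L
  structure(config, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage end-to-end: synthetic scene generation (when
#' configured) or ingest of real rasters, plot feature extraction,
#' vegetation indices, texture-index traversal and screening, correlation
#' screening, the cross-validated model comparison, and the input-set
#' summary. All tables are written to `out_dir` together with a plain-text
#' run log (row counts at every stage) and a manifest (seed and MD5 hash
#' of every output file).
#'
#' @param config A [pipeline_config()] (or YAML path / list).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory `features`, `screening`,
#'   `experiment`, `summary`, `selected_indices` and the `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logln <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    writeLines(line, log_con)
    message(line)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  logln("pipeline start, seed %d", config$seed)

  if (!is.null(config$synthetic)) {
    gen <- stage("simulate", {
      params <- do.call(canopy_params, config$synthetic)
      generate_dataset(params, file.path(out_dir, "scene"))
    })
    raster_paths <- gen$raster_paths
    dates <- gen$dates
    rois <- read_rois(gen$roi_path)
    lai_table <- read.csv(gen$lai_path, stringsAsFactors = FALSE)
    logln("simulate: %d plots x %d dates -> %d samples",
          length(rois), length(dates), nrow(lai_table))
  } else {
    inp <- config$input
    for (p in c(unlist(inp$rasters), inp$rois, inp$lai)) {
      if (!file.exists(p)) abort_io(paste0("input file not found: ", p))
    }
    raster_paths <- unlist(inp$rasters)
    dates <- if (is.null(inp$dates)) as.character(seq_along(raster_paths)) else unlist(inp$dates)
    rois <- read_rois(inp$rois)
    lai_table <- read.csv(inp$lai, stringsAsFactors = FALSE)
  }

  features <- stage("extract", {
    extract_features(raster_paths, dates, rois, lai_table, config$texture_config)
  })
  logln("extract: %d rows, %d texture features", nrow(features),
        length(intersect(texture_feature_names(config$texture_config$bands),
                         names(features))))

  features <- stage("features", vi_table(features))
  logln("features: +%d vegetation indices", nrow(vi_registry()))
  write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)

  tex_names <- texture_feature_names(config$texture_config$bands)
  cors <- stage("indices", {
    tabs <- traverse_pairs(features, features = tex_names)
    index_lai_correlation(tabs, features$lai)
  })
  for (kind in names(cors)) {
    write.csv(as.data.frame(cors[[kind]]),
              file.path(out_dir, sprintf("texture_index_correlations_%s.csv", kind)))
  }
  selected <- stage("indices", select_best_indices(cors))
  write.csv(selected, file.path(out_dir, "selected_indices.csv"), row.names = FALSE)
  features <- append_texture_indices(features, selected)
  logln("indices: selected %s", paste(selected$name, collapse = ", "))

  screening <- stage("screen", {
    screen_features(features, lai_col = "lai", texture_cols = tex_names,
                    ti_cols = selected$name,
                    vi_threshold = config$screening$vi_threshold)
  })
  write.csv(screening$reports, file.path(out_dir, "correlations.csv"), row.names = FALSE)
  jsonlite::write_json(screening$sets, file.path(out_dir, "feature_sets.json"),
                       pretty = TRUE)
  logln("screen: %d reports; VI set size %d", nrow(screening$reports),
        length(screening$sets$VIs))

  experiment <- stage("train", {
    run_experiment(features, screening$sets, lai_col = "lai",
                   families = config$modeling$families,
                   seed = config$seed, folds = config$modeling$folds)
  })
  write.csv(experiment$results, file.path(out_dir, "results_table.csv"), row.names = FALSE)
  preds <- experiment_predictions(experiment)
  write.csv(preds, file.path(out_dir, "predictions.csv"), row.names = FALSE)
  write.csv(data.frame(row = seq_along(experiment$fold_assignment),
                       fold = experiment$fold_assignment),
            file.path(out_dir, "folds.csv"), row.names = FALSE)
  write.csv(preds[!is.na(preds$yhat), c("family", "input_set", "y", "yhat")],
            file.path(out_dir, "scatter.csv"), row.names = FALSE)
  logln("train: %d models, best %s on %s (Val R2 %.3f)",
        length(experiment$cv), experiment$best$family, experiment$best$input_set,
        experiment$best$R2)

  summ <- stage("report", summarize_input_sets(experiment$results))
  write.csv(summ$means, file.path(out_dir, "summary_means.csv"), row.names = FALSE)
  if (!is.null(summ$changes)) {
    write.csv(summ$changes, file.path(out_dir, "summary_changes.csv"), row.names = FALSE)
  }

  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  files <- files[files != "run.log"]
  manifest <- list(
    package = "laitex",
    version = as.character(utils::packageVersion("laitex")),
    seed = config$seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = as.list(setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logln("pipeline done: %d output files", length(files))

  invisible(list(features = features, screening = screening, experiment = experiment,
                 summary = summ, selected_indices = selected, manifest = manifest,
                 out_dir = out_dir))
}
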