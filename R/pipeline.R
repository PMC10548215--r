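#' Run the full pipeline end to end
#'
#' Orchestrates synthetic generation (or loading from files), reflectance
#' calibration, weekly and accession-mean averaging, the ground-reference
#' multivariate analyses, PCA-loading wavelength selection with cross-week
#' SVM classification, and the RReliefF-PLSR trait predictions (full model,
#' optional transfer and hyperparameter-grid experiments). All tabular
#' outputs are CSV; the dendrogram is Newick; a JSON manifest records seeds,
#' parameters and output digests so any artifact can be regenerated.
#'
#' One global seed is split into per-stage streams by stable string keys
#' ([stage_seed()]), so toggling one stage never changes another stage's
#' draws.
#'
#' @param config A [synthetic_config()], or a list with `design_file`,
#'   `spectra_file`, `traits_file` to load real tables.
#' @param out_dir Output directory (created if needed).
#' @param seed Global integer seed.
#' @param stages Named logical toggles: `groundtruth`, `classify`, `predict`,
#'   `transfer`, `hypergrid`.
#' @param traits_to_predict Trait columns for the prediction stage.
#' @param n_wavelengths,grid_iterations Stage parameters.
#' @param write_spectra Write the weekly plant-level wide-format spectra CSV
#'   (large), default TRUE.
#' @return The manifest (list), invisibly; files are written under `out_dir`.
#' @export
run_all <- function(config = synthetic_config(), out_dir = "results",
                    seed = 1L,
                    stages = list(groundtruth = TRUE, classify = TRUE,
                                  predict = TRUE, transfer = FALSE,
                                  hypergrid = FALSE),
                    traits_to_predict = c("N", "CN", "C"),
                    n_wavelengths = 400, grid_iterations = 10,
                    write_spectra = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("canopyspec")),
                   seed = seed, stages = stages, timings = list())
  tic <- function() proc.time()[["elapsed"]]
  outputs <- character(0)
  emit <- function(obj, name, writer = utils::write.csv) {
    path <- file.path(out_dir, name)
    if (identical(writer, utils::write.csv)) writer(obj, path, row.names = FALSE)
    else writer(obj, path)
    outputs <<- c(outputs, path)
    path
  }

  t0 <- tic()
  if (inherits(config, "synthetic_config")) {
    exper <- generate_experiment(config, seed = stage_seed(seed, "synthetic"))
    design <- exper$design
    traits <- exper$traits
    weekly <- weekly_average(calibrate_scans(exper$scans))
    manifest$config <- unclass(config)
  } else {
    tabs <- load_tables(config$design_file, config$spectra_file,
                        config$traits_file)
    design <- tabs$design
    traits <- tabs$traits
    weekly <- tabs$spectra
    manifest$config <- config
  }
  traits <- transform_traits(traits)
  acc_spec <- accession_mean(weekly, design)
  emit(design, "design.csv")
  emit(traits, "traits.csv")
  if (write_spectra) emit(weekly, "spectra_weekly_wide.csv", write_spectra_wide)
  manifest$timings$data <- tic() - t0

  if (isTRUE(stages$groundtruth)) {
    t0 <- tic()
    corr <- correlation_analysis(traits)
    emit(as.data.frame(corr$r), "trait_correlations.csv")
    acc_tr <- accession_mean_traits(traits, design)
    pc <- trait_pca(acc_tr)
    emit(data.frame(component = seq_along(pc$variance_fraction),
                    variance_fraction = pc$variance_fraction),
         "trait_pca_variance.csv")
    cl <- cluster_accessions(acc_tr, k = 2)
    dendrogram_newick(cl, file.path(out_dir, "trait_dendrogram.nwk"))
    outputs <- c(outputs, file.path(out_dir, "trait_dendrogram.nwk"))
    manifest$timings$groundtruth <- tic() - t0
  }

  if (isTRUE(stages$classify)) {
    t0 <- tic()
    weeks <- sort(unique(acc_spec$meta$week))
    by_week <- lapply(weeks, function(w) {
      keep <- acc_spec$meta$week == w
      spectra_set(acc_spec$grid, acc_spec$values[keep, , drop = FALSE],
                  acc_spec$meta[keep, , drop = FALSE], acc_spec$level)
    })
    names(by_week) <- weeks
    cw <- cross_week_evaluate(by_week,
                              grid_spec(seed = stage_seed(seed, "classify")))
    emit(as.data.frame(cw$accuracy), "svm_accuracy_matrix.csv")
    for (w in names(cw$wavelengths))
      emit(selection_table(cw$wavelengths[[w]]),
           sprintf("wsvm_week%s.csv", w))
    manifest$timings$classify <- tic() - t0
    manifest$classification <- list(weeks = weeks,
                                    accuracy_range = range(cw$accuracy))
  }

  if (isTRUE(stages$predict)) {
    t0 <- tic()
    runs <- list()
    for (tr in traits_to_predict) {
      run <- run_trait_model(weekly, traits, design, tr,
                             n_wavelengths = n_wavelengths,
                             seed = stage_seed(seed, paste0("predict_", tr)))
      runs[[tr]] <- run
      if (run$fittable) {
        emit(run$metrics, sprintf("plsr_metrics_%s.csv", tr))
        emit(run$predictions, sprintf("plsr_predictions_%s.csv", tr))
        emit(selection_table(run$selection), sprintf("wplsr_%s.csv", tr))
      }
    }
    summ <- do.call(rbind, lapply(names(runs), function(tr) {
      r <- runs[[tr]]
      data.frame(trait = tr, fittable = r$fittable,
                 n_components = r$n_components,
                 val_r2 = if (r$fittable) r$metrics$r2[2] else NA_real_,
                 val_rmsep = if (r$fittable) r$metrics$rmsep[2] else NA_real_)
    }))
    emit(summ, "plsr_summary.csv")
    manifest$timings$predict <- tic() - t0
  }

  if (isTRUE(stages$transfer)) {
    t0 <- tic()
    rows <- list()
    for (gv in c("treatment", "subpopulation")) {
      lv <- unique(design[[gv]])
      for (l in lv) {
        tx <- transfer_experiment(weekly, traits, design, "N",
                                  group_var = gv, train_level = l,
                                  seed = stage_seed(seed, paste0("transfer_", gv, l)))
        if (tx$fittable)
          rows[[paste(gv, l)]] <- data.frame(
            group_var = gv, train_level = l,
            cal_r2 = tx$calibration$r2, cal_rmsep = tx$calibration$rmsep,
            val_r2 = tx$validation$r2, val_rmsep = tx$validation$rmsep)
      }
    }
    emit(do.call(rbind, rows), "transfer_metrics.csv")
    manifest$timings$transfer <- tic() - t0
  }

  if (isTRUE(stages$hypergrid)) {
    t0 <- tic()
    gr <- hyperparameter_grid(weekly, traits, design, "N",
                              iterations = grid_iterations,
                              seed = stage_seed(seed, "hypergrid"))
    emit(as.data.frame(gr), "hypergrid.csv")
    manifest$timings$hypergrid <- tic() - t0
  }

  manifest$outputs <- as.list(tools::md5sum(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
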