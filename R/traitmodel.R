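#' Treatment-stratified calibration/validation split
#'
#' Within each stratum, `floor(fraction * stratum size)` samples are drawn
#' without replacement into calibration; the remainder form validation. The
#' two sets are disjoint and exhaustive. With the 80% default, 78 samples
#' (39 per treatment) give 62 calibration samples and 88 give 70.
#'
#' @param sample_ids Vector of sample identifiers.
#' @param strata Stratum label per sample (the treatment).
#' @param fraction Calibration fraction, default 0.8.
#' @param seed Integer seed.
#' @return List with `calibration` and `validation` id vectors.
#' @export
stratified_split <- function(sample_ids, strata, fraction = 0.8, seed = 1L) {
  stopifnot(length(sample_ids) == length(strata),
            fraction > 0, fraction < 1)
  cal <- with_seed(seed, {
    unlist(lapply(unique(strata), function(s) {
      idx <- which(strata == s)
      if (length(idx) < 2) stop("stratum '", s, "' has fewer than 2 samples")
      sample(idx, floor(fraction * length(idx)))
    }), use.names = FALSE)
  })
  list(calibration = sample_ids[sort(cal)],
       validation = sample_ids[setdiff(seq_along(sample_ids), cal)])
}

# assemble the plant-level modeling frame: week spectra joined to a trait
trait_model_frame <- function(spectra, traits, design, trait_name, week) {
  ss <- spectra
  if (!is.null(week)) {
    keep <- ss$meta$week == week
    ss <- spectra_set(ss$grid, ss$values[keep, , drop = FALSE],
                      ss$meta[keep, , drop = FALSE], ss$level)
  }
  ids <- ss$meta$plant_id
  yv <- traits[[trait_name]][match(ids, traits$plant_id)]
  keep <- !is.na(yv)
  di <- match(ids, design$plant_id)
  list(X = ss$values[keep, , drop = FALSE], y = yv[keep],
       plant_id = ids[keep], grid = ss$grid,
       treatment = design$treatment[di][keep],
       subpopulation = design$subpopulation[di][keep])
}

#' RReliefF-PLSR prediction of one trait from weekly spectra
#'
#' The full single-trait pipeline: complete cases only; treatment-stratified
#' 80/20 split; RReliefF wavelength scoring on calibration rows exclusively
#' (no leakage), `m = 100 x n_cal` iterations; top-`n_wavelengths` selection;
#' leave-one-out component selection; jackknife prediction intervals on the
#' validation set; metrics in both contexts (calibration metrics use the LOO
#' predictions at the chosen component count).
#'
#' @param spectra Plant-week [spectra_set()].
#' @param traits Trait table with `plant_id`.
#' @param design Design table (treatment strata).
#' @param trait_name Response column in `traits`.
#' @param n_wavelengths Number of wavelengths to select, default 400.
#' @param week Week whose spectra to use, default 9 (the trait-measurement
#'   week); `NULL` uses all rows.
#' @param fraction Calibration fraction, default 0.8.
#' @param k_neighbors,sigma RReliefF parameters.
#' @param max_components Cap for the LOO component search.
#' @param jackknife Compute jackknife intervals, default TRUE.
#' @param seed Integer seed (split + RReliefF draws).
#' @return A list of class `plsr_run`: `fittable`, `n_components`,
#'   `selection`, `split`, `metrics` (calibration + validation rows),
#'   `predictions` (validation data frame with intervals when requested),
#'   `model`. When the LOO optimum is 0 components the run is marked not
#'   fittable and carries the diagnosis instead of a model.
#' @export
run_trait_model <- function(spectra, traits, design, trait_name,
                            n_wavelengths = 400, week = 9, fraction = 0.8,
                            k_neighbors = 70, sigma = 20,
                            max_components = 20, jackknife = TRUE,
                            seed = 1L) {
  fr <- trait_model_frame(spectra, traits, design, trait_name, week)
  sp <- stratified_split(fr$plant_id, fr$treatment, fraction,
                         seed = stage_seed(seed, "split"))
  ical <- match(sp$calibration, fr$plant_id)
  ival <- match(sp$validation, fr$plant_id)
  X_cal <- fr$X[ical, , drop = FALSE]
  y_cal <- fr$y[ical]
  X_val <- fr$X[ival, , drop = FALSE]
  y_val <- fr$y[ival]

  scores <- rrelieff_rank(X_cal, y_cal, k_neighbors = k_neighbors,
                          sigma = sigma, m_iterations = 100 * nrow(X_cal),
                          seed = stage_seed(seed, "rrelieff"))
  sel <- select_wplsr(scores, min(n_wavelengths, ncol(X_cal)))
  keep <- match(as.character(sel$selected), colnames(fr$X))
  Xc <- X_cal[, keep, drop = FALSE]
  Xv <- X_val[, keep, drop = FALSE]

  loo <- select_components_loo(Xc, y_cal, max_components)
  if (!loo$fittable) {
    return(structure(list(fittable = FALSE, n_components = 0L,
                          trait = trait_name, selection = sel, split = sp,
                          loo = loo,
                          diagnosis = "LOO RMSEP minimised by the 0-component (mean) model"),
                     class = "plsr_run"))
  }
  a <- loo$n_components
  cal_metrics <- evaluate(y_cal, loo$loo_predictions[, a + 1],
                          context = "calibration_loo")
  if (jackknife) {
    pred <- jackknife_predict(Xc, y_cal, a, Xv)
    model <- attr(pred, "model")
  } else {
    model <- fit_plsr(Xc, y_cal, a)
    pred <- data.frame(prediction = predict(model, Xv),
                       lower = NA_real_, upper = NA_real_, se = NA_real_)
  }
  val_metrics <- evaluate(y_val, pred$prediction, context = "validation")
  predictions <- cbind(data.frame(plant_id = sp$validation,
                                  measured = y_val,
                                  stringsAsFactors = FALSE), pred)
  structure(list(fittable = TRUE, n_components = a, trait = trait_name,
                 selection = sel, split = sp, loo = loo,
                 metrics = rbind(cal_metrics, val_metrics),
                 predictions = predictions, model = model),
            class = "plsr_run")
}

#' @export
print.plsr_run <- function(x, ...) {
  if (!x$fittable) {
    cat(sprintf("<plsr_run> trait '%s': NOT FITTABLE (%s)\n", x$trait,
                x$diagnosis))
  } else {
    v <- x$metrics[x$metrics$context == "validation", ]
    cat(sprintf("<plsr_run> trait '%s': %d components, validation R2 %.3f, RMSEP %.3f\n",
                x$trait, x$n_components, v$r2, v$rmsep))
  }
  invisible(x)
}

#' Calibration-transfer experiment across treatments or subpopulations
#'
#' Selects wavelengths and calibrates entirely within one level of a grouping
#' variable, then validates on the entire other level. Used to test whether
#' models trained in one nitrogen treatment (or rice subpopulation) transfer
#' to the other.
#'
#' @param spectra,traits,design,trait_name,week As [run_trait_model()].
#' @param group_var `"treatment"` or `"subpopulation"`.
#' @param train_level Level used for selection and calibration.
#' @param n_wavelengths Default 300 (smaller calibration sets).
#' @param k_neighbors,sigma,max_components As [run_trait_model()].
#' @param seed Integer seed (RReliefF draws).
#' @return List of class `transfer_run`: `calibration` metrics (LOO within
#'   the training level), `validation` metrics (other level), `n_components`,
#'   `selection`, levels used; not-fittable outcomes propagate with
#'   diagnosis.
#' @export
transfer_experiment <- function(spectra, traits, design, trait_name,
                                group_var = c("treatment", "subpopulation"),
                                train_level, n_wavelengths = 300, week = 9,
                                k_neighbors = 70, sigma = 20,
                                max_components = 20, seed = 1L) {
  group_var <- match.arg(group_var)
  fr <- trait_model_frame(spectra, traits, design, trait_name, week)
  g <- fr[[group_var]]
  levels_all <- unique(g)
  if (!train_level %in% levels_all) stop("train_level not present")
  other <- setdiff(levels_all, train_level)
  if (length(other) == 0) stop("no samples outside train_level")
  tr <- g == train_level
  if (stats::var(fr$y[tr]) == 0) stop("constant trait in train_level")
  X_cal <- fr$X[tr, , drop = FALSE]; y_cal <- fr$y[tr]
  X_val <- fr$X[!tr, , drop = FALSE]; y_val <- fr$y[!tr]

  scores <- rrelieff_rank(X_cal, y_cal, k_neighbors = k_neighbors,
                          sigma = sigma, m_iterations = 100 * nrow(X_cal),
                          seed = stage_seed(seed, "rrelieff"))
  sel <- select_wplsr(scores, min(n_wavelengths, ncol(X_cal)))
  keep <- match(as.character(sel$selected), colnames(fr$X))
  Xc <- X_cal[, keep, drop = FALSE]
  Xv <- X_val[, keep, drop = FALSE]
  loo <- select_components_loo(Xc, y_cal, max_components)
  if (!loo$fittable) {
    return(structure(list(fittable = FALSE, trait = trait_name,
                          group_var = group_var, train_level = train_level,
                          diagnosis = "0-component LOO optimum in train_level"),
                     class = "transfer_run"))
  }
  a <- loo$n_components
  model <- fit_plsr(Xc, y_cal, a)
  cal <- evaluate(y_cal, loo$loo_predictions[, a + 1], "calibration_loo")
  val <- evaluate(y_val, predict(model, Xv), "validation")
  structure(list(fittable = TRUE, trait = trait_name, group_var = group_var,
                 train_level = train_level, eval_levels = other,
                 n_components = a, selection = sel,
                 calibration = cal, validation = val, model = model),
            class = "transfer_run")
}

#' Wavelength-count x sample-size hyperparameter grid
#'
#' For every cell of the grid, repeatedly subsamples `n_total` complete-case
#' plants (balanced across treatments), runs the RReliefF-PLSR pipeline, and
#' aggregates the mean and standard error of R2, RMSEP and %RMSEP for both
#' the calibration (LOO) and validation contexts. Iterations whose LOO
#' optimum is 0 components are counted, not errors.
#'
#' @param spectra,traits,design,trait_name,week,fraction As
#'   [run_trait_model()].
#' @param wavelength_counts Candidate numbers of selected wavelengths.
#' @param totals Candidate total sample sizes.
#' @param iterations Subsample iterations per cell, default 100.
#' @param k_neighbors,sigma,max_components As [run_trait_model()].
#' @param seed Integer seed.
#' @return Data frame of class `grid_result`: one row per (n_wavelengths,
#'   n_total) with `mean_`/`se_` columns per metric and context, plus
#'   `n_not_fittable`.
#' @export
hyperparameter_grid <- function(spectra, traits, design, trait_name = "N",
                                wavelength_counts = c(10, 50, 100, 150, 200,
                                                      300, 400, 500, 600, 700),
                                totals = c(48, 60, 70, 78, 88),
                                iterations = 100, week = 9, fraction = 0.8,
                                k_neighbors = 70, sigma = 20,
                                max_components = 20, seed = 1L) {
  fr <- trait_model_frame(spectra, traits, design, trait_name, week)
  if (max(totals) > length(fr$y))
    stop("largest total exceeds available complete cases (", length(fr$y), ")")
  cells <- expand.grid(n_wavelengths = wavelength_counts, n_total = totals,
                       KEEP.OUT.ATTRS = FALSE)
  res <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    nw <- cells$n_wavelengths[ci]; nt <- cells$n_total[ci]
    mets <- vector("list", iterations)
    nf <- 0L
    for (it in seq_len(iterations)) {
      it_seed <- stage_seed(seed, sprintf("grid_%d_%d_%d", nw, nt, it))
      sub <- with_seed(it_seed, {
        unlist(lapply(unique(fr$treatment), function(s) {
          idx <- which(fr$treatment == s)
          sample(idx, min(round(nt / length(unique(fr$treatment))), length(idx)))
        }), use.names = FALSE)
      })
      ss_sub <- spectra_set(fr$grid, fr$X[sub, , drop = FALSE],
                            data.frame(plant_id = fr$plant_id[sub],
                                       week = week), "plant_week")
      tr_sub <- data.frame(plant_id = fr$plant_id[sub], y = fr$y[sub])
      names(tr_sub)[2] <- trait_name
      run <- run_trait_model(ss_sub, tr_sub, design, trait_name,
                             n_wavelengths = nw, week = week,
                             fraction = fraction, k_neighbors = k_neighbors,
                             sigma = sigma, max_components = max_components,
                             jackknife = FALSE, seed = it_seed)
      if (!run$fittable) nf <- nf + 1L else mets[[it]] <- run$metrics
    }
    mets <- do.call(rbind, mets)
    agg <- function(ctx, col) {
      v <- mets[mets$context == ctx, col]
      c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
    }
    row <- data.frame(n_wavelengths = nw, n_total = nt,
                      n_not_fittable = nf, n_fitted = iterations - nf)
    for (ctx in c("calibration_loo", "validation")) {
      short <- if (ctx == "validation") "val" else "cal"
      for (col in c("r2", "rmsep", "pct_rmsep")) {
        a <- if (is.null(mets) || !nrow(mets)) c(mean = NA_real_, se = NA_real_)
             else agg(ctx, col)
        row[[paste("mean", short, col, sep = "_")]] <- a[["mean"]]
        row[[paste("se", short, col, sep = "_")]] <- a[["se"]]
      }
    }
    res[[ci]] <- row
  }
  out <- do.call(rbind, res)
  class(out) <- c("grid_result", class(out))
  out
}
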