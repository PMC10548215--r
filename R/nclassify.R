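#' Grid-search specification for SVM treatment classification
#'
#' Exponential (base-2) grids: rough search over `cost = 2^(-5..15)` and, for
#' the RBF kernel, `gamma = 2^(-15..23)`, both stepping the exponent by 2.
#' The best rough point seeds a fine grid spanning +/- 0.5 in the exponent at
#' step 0.1; when the rough optimum sits on a range boundary the fine window
#' is the best exponent +/- 2, clipped to the rough range. Fine parameters are
#' adopted only on a strict cross-validated accuracy improvement.
#'
#' @param kernel `"rbf"` or `"linear"`.
#' @param cost_exponents,gamma_exponents Rough-grid exponent lattices.
#' @param fine_halfwidth,fine_step Fine-grid exponent half-width and step.
#' @param boundary_halfwidth Fine-grid exponent half-width used when the rough
#'   optimum lies on a boundary.
#' @param folds Number of cross-validation folds, default 23.
#' @param fold_by `"treatment"` (stratified by class, default) or
#'   `"accession"` (one fold per accession).
#' @param seed Seed for the fold assignment.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(kernel = c("rbf", "linear"),
                      cost_exponents = seq(-5, 15, by = 2),
                      gamma_exponents = seq(-15, 23, by = 2),
                      fine_halfwidth = 0.5, fine_step = 0.1,
                      boundary_halfwidth = 2,
                      folds = 23, fold_by = c("treatment", "accession"),
                      seed = 1L) {
  kernel <- match.arg(kernel)
  fold_by <- match.arg(fold_by)
  stopifnot(length(cost_exponents) > 0, fine_step > 0, folds >= 2)
  structure(list(kernel = kernel, cost_exponents = cost_exponents,
                 gamma_exponents = gamma_exponents,
                 fine_halfwidth = fine_halfwidth, fine_step = fine_step,
                 boundary_halfwidth = boundary_halfwidth,
                 folds = folds, fold_by = fold_by, seed = seed),
            class = "grid_spec")
}

# seeded stratified fold assignment: within each class, samples are dealt
# round-robin into folds in a random order
make_folds <- function(labels, folds, seed, groups = NULL) {
  n <- length(labels)
  assign <- integer(n)
  if (!is.null(groups)) {
    g <- unique(groups)
    gf <- with_seed(seed, sample(rep_len(seq_len(folds), length(g))))
    assign <- gf[match(groups, g)]
  } else {
    with_seed(seed, for (cl in unique(labels)) {
      idx <- which(labels == cl)
      assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    })
  }
  assign
}

# pooled CV accuracy for one (cost, gamma) point; X already standardised
cv_accuracy <- function(X, y, folds_assign, kernel, cost, gamma = NULL) {
  correct <- 0L
  for (f in unique(folds_assign)) {
    tr <- folds_assign != f
    if (length(unique(y[tr])) < 2) next
    fit <- if (kernel == "rbf")
      e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                 cost = cost, gamma = gamma, scale = FALSE)
    else
      e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "linear",
                 cost = cost, scale = FALSE)
    pred <- stats::predict(fit, X[!tr, , drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' Rough/fine exponential grid search for an SVM treatment classifier
#'
#' Cross-validated (stratified, seeded folds) accuracy over the rough
#' exponent lattice; the optimum seeds a fine lattice whose parameters are
#' adopted only if they strictly improve CV accuracy.
#'
#' @param X Feature matrix (rows = samples, columns = selected wavelengths).
#' @param labels Factor or character treatment labels (exactly two classes).
#' @param spec A [grid_spec()].
#' @param groups Optional accession labels, used when `spec$fold_by` is
#'   `"accession"` (one fold per accession group).
#' @return A list of class `classifier_run`: `best_cost`, `best_gamma`
#'   (`NULL` for linear), `rough_accuracy`, `fine_accuracy`, `adopted`
#'   (`"rough"` or `"fine"`), `cv_accuracy`, `fold_assignment`, `model` (an
#'   `e1071::svm` fit on all rows), and the feature standardisation
#'   (`center`, `scale`) applied before fitting.
#' @export
grid_search <- function(X, labels, spec = grid_spec(), groups = NULL) {
  X <- as.matrix(X)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("single-class input: nothing to classify")
  if (nrow(X) < spec$folds)
    stop("fewer samples than folds")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  folds_assign <- make_folds(y, spec$folds, spec$seed,
                             groups = if (spec$fold_by == "accession") groups)

  lattice <- if (spec$kernel == "rbf")
    expand.grid(ce = spec$cost_exponents, ge = spec$gamma_exponents)
  else
    data.frame(ce = spec$cost_exponents, ge = NA_real_)
  acc <- vapply(seq_len(nrow(lattice)), function(i)
    cv_accuracy(Xs, y, folds_assign, spec$kernel, 2^lattice$ce[i],
                if (spec$kernel == "rbf") 2^lattice$ge[i]), numeric(1))
  best <- which.max(acc)
  rough_acc <- acc[best]
  best_ce <- lattice$ce[best]
  best_ge <- lattice$ge[best]

  fine_window <- function(e, rough_range) {
    hw <- if (e %in% range(rough_range)) spec$boundary_halfwidth
          else spec$fine_halfwidth
    ex <- seq(e - hw, e + hw, by = spec$fine_step)
    ex[ex >= min(rough_range) & ex <= max(rough_range)]
  }
  fl <- if (spec$kernel == "rbf")
    expand.grid(ce = fine_window(best_ce, spec$cost_exponents),
                ge = fine_window(best_ge, spec$gamma_exponents))
  else
    data.frame(ce = fine_window(best_ce, spec$cost_exponents), ge = NA_real_)
  facc <- vapply(seq_len(nrow(fl)), function(i)
    cv_accuracy(Xs, y, folds_assign, spec$kernel, 2^fl$ce[i],
                if (spec$kernel == "rbf") 2^fl$ge[i]), numeric(1))
  fbest <- which.max(facc)
  fine_acc <- facc[fbest]

  if (fine_acc > rough_acc) {
    adopted <- "fine"; ce <- fl$ce[fbest]; ge <- fl$ge[fbest]; cv <- fine_acc
  } else {
    adopted <- "rough"; ce <- best_ce; ge <- best_ge; cv <- rough_acc
  }
  model <- if (spec$kernel == "rbf")
    e1071::svm(Xs, y, kernel = "radial", cost = 2^ce, gamma = 2^ge,
               scale = FALSE)
  else
    e1071::svm(Xs, y, kernel = "linear", cost = 2^ce, scale = FALSE)
  structure(list(best_cost = 2^ce,
                 best_gamma = if (spec$kernel == "rbf") 2^ge,
                 rough_accuracy = rough_acc, fine_accuracy = fine_acc,
                 adopted = adopted, cv_accuracy = cv,
                 fold_assignment = folds_assign, model = model,
                 center = ctr, scale = scl, kernel = spec$kernel,
                 levels = levels(y)),
            class = "classifier_run")
}

#' Predict treatment labels with a fitted classifier run
#'
#' Applies the training standardisation to new features before prediction.
#'
#' @param object A `classifier_run`.
#' @param newdata Feature matrix with the same columns as used in training.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.classifier_run <- function(object, newdata, ...) {
  Xs <- scale(as.matrix(newdata), center = object$center, scale = object$scale)
  stats::predict(object$model, Xs)
}

#' Cross-week treatment classification matrix
#'
#' For each training week, selects that week's wavelengths by covariance-PCA
#' loadings, tunes an SVM by rough/fine grid search, and evaluates every week
#' by extracting the training week's wavelengths from the evaluation week's
#' spectra. Diagonal entries reuse the training data and are optimistic; the
#' result flags them.
#'
#' @param spectra_by_week Named list of accession-mean [spectra_set()]s, one
#'   per week.
#' @param spec A [grid_spec()].
#' @param var_threshold,top_k Passed to [select_wsvm()].
#' @return List with `accuracy` (matrix, training weeks x evaluation weeks),
#'   `runs` (per training week `classifier_run`s), `wavelengths` (per-week
#'   selections), `diagonal_optimistic = TRUE`.
#' @export
cross_week_evaluate <- function(spectra_by_week, spec = grid_spec(),
                                var_threshold = 0.90, top_k = 10) {
  weeks <- names(spectra_by_week)
  stopifnot(length(weeks) >= 1)
  acc_mat <- matrix(NA_real_, length(weeks), length(weeks),
                    dimnames = list(train = weeks, eval = weeks))
  runs <- list(); sels <- list()
  for (tw in weeks) {
    tr <- spectra_by_week[[tw]]
    sel <- select_wsvm(spectra_pca(tr), var_threshold, top_k)
    sels[[tw]] <- sel
    Xtr <- subset_wavelengths(tr, sel$selected)$values
    run <- grid_search(Xtr, tr$meta$treatment, spec,
                       groups = tr$meta$accession)
    runs[[tw]] <- run
    for (ew in weeks) {
      ev <- spectra_by_week[[ew]]
      Xev <- subset_wavelengths(ev, sel$selected)$values
      pred <- predict(run, Xev)
      acc_mat[tw, ew] <- mean(pred == ev$meta$treatment)
    }
  }
  list(accuracy = acc_mat, runs = runs, wavelengths = sels,
       diagonal_optimistic = TRUE)
}
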