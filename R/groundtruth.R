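#' Derive secondary leaf traits
#'
#' From leaf area, leaf dry weight and elemental carbon/nitrogen content:
#' specific leaf area `SLA = area / dry_weight` (cm2 g-1), carbon-to-nitrogen
#' ratio `C:N = C / N`, specific leaf area with respect to carbon
#' `SLA_C = area / (mg C)` (cm2 mg-1 C), and specific leaf nitrogen
#' `SLN = (mg N) / area` (mg N cm-2). Nonpositive denominators yield `NA`
#' with a warning (an undefined-trait flag), never a silent zero.
#'
#' @param leaf_area Leaf area (cm2).
#' @param dry_weight Leaf dry weight (g).
#' @param C Carbon content (% of dry mass).
#' @param N Nitrogen content (% of dry mass).
#' @return Data frame with columns `SLA`, `CN`, `SLA_C`, `SLN`.
#' @export
derive_traits <- function(leaf_area, dry_weight, C, N) {
  bad <- function(d) !is.na(d) & d <= 0
  if (any(bad(dry_weight) | bad(leaf_area) | bad(N) | bad(C)))
    warning("nonpositive leaf area, dry weight, C or N: derived traits set to NA")
  dw <- ifelse(bad(dry_weight), NA_real_, dry_weight)
  ar <- ifelse(bad(leaf_area), NA_real_, leaf_area)
  Cc <- ifelse(bad(C), NA_real_, C)
  Nn <- ifelse(bad(N), NA_real_, N)
  mg_C <- dw * 1000 * Cc / 100
  mg_N <- dw * 1000 * Nn / 100
  data.frame(SLA = ar / dw, CN = Cc / Nn, SLA_C = ar / mg_C, SLN = mg_N / ar)
}

#' Add transformed trait columns
#'
#' Right-skewed traits (E, gsw, SLN) get natural-log columns; FB, pQY and mQY
#' get min-max normalised columns in `[0, 1]` over non-missing entries.
#' Nonpositive values under a log are flagged missing.
#'
#' @param traits Trait table (one row per plant).
#' @return The table with added `log_E`, `log_gsw`, `log_SLN`, `normFB`,
#'   `normpQY`, `normmQY`.
#' @export
transform_traits <- function(traits) {
  safe_log <- function(x) {
    out <- ifelse(!is.na(x) & x > 0, log(x), NA_real_)
    if (any(!is.na(x) & x <= 0))
      warning("nonpositive value under log transform flagged missing")
    out
  }
  traits$log_E <- safe_log(traits$E)
  traits$log_gsw <- safe_log(traits$gsw)
  traits$log_SLN <- safe_log(traits$SLN)
  traits$normFB <- minmax(traits$FB)
  traits$normpQY <- minmax(traits$pQY)
  traits$normmQY <- minmax(traits$mQY)
  traits
}

# default trait set for the multivariate analyses: log transforms replace the
# raw skewed traits, as applied before the correlation tests and PCA
multivariate_traits <- function() {
  c("A", "C", "N", "CN", "log_E", "log_gsw", "FB", "Jmax", "Vcmax",
    "pQY", "mQY", "SLA", "SLA_C", "SLN")
}

#' Pairwise Pearson correlations with mean imputation
#'
#' Missing entries are replaced by the column mean before the pairwise
#' correlations are computed (so imputation leaves column means unchanged).
#' Significance uses the two-sided t test on `r * sqrt((n-2)/(1-r^2))` at
#' `alpha`, unadjusted.
#'
#' @param traits Trait table.
#' @param columns Trait columns to correlate; defaults to the 14-trait
#'   multivariate set (after [transform_traits()]).
#' @param alpha Significance level, default 0.01.
#' @return List with `r` (correlation matrix), `p` (p-value matrix),
#'   `significant` (logical mask at `alpha`), and `n` (rows used).
#' @export
correlation_analysis <- function(traits, columns = multivariate_traits(),
                                 alpha = 0.01) {
  X <- as.matrix(traits[, columns, drop = FALSE])
  if (nrow(X) < 3) stop("need at least 3 rows")
  X <- apply(X, 2, function(col) {
    m <- mean(col, na.rm = TRUE)
    ifelse(is.na(col), m, col)
  })
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    warning("constant column(s), correlations undefined: ",
            paste(columns[sds == 0], collapse = ", "))
  r <- suppressWarnings(stats::cor(X))
  n <- nrow(X)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- 0
  list(r = r, p = p, significant = p < alpha & !is.na(r), n = n)
}

#' Average traits over replicate plants
#'
#' One row per accession x treatment, the mean over available replicates;
#' when a replicate's value is missing, the remaining replicate(s) represent
#' the accession mean.
#'
#' @param traits Trait table with `plant_id`.
#' @param design Design table.
#' @param columns Trait columns to average.
#' @return Data frame with `accession`, `subpopulation`, `treatment` and the
#'   averaged columns.
#' @export
accession_mean_traits <- function(traits, design,
                                  columns = multivariate_traits()) {
  idx <- match(traits$plant_id, design$plant_id)
  if (anyNA(idx)) stop("plant(s) absent from design")
  key <- paste(design$accession[idx], design$treatment[idx], sep = "\r")
  agg <- stats::aggregate(traits[, columns, drop = FALSE], by = list(key = key),
                          FUN = mean, na.rm = TRUE)
  parts <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
  out <- data.frame(accession = parts[, 1], treatment = parts[, 2],
                    stringsAsFactors = FALSE)
  out$subpopulation <- design$subpopulation[match(out$accession, design$accession)]
  cbind(out, agg[, columns, drop = FALSE])
}

#' Correlation-matrix PCA of accession-mean traits
#'
#' Columns are standardised to unit variance before the decomposition
#' (PCA on the correlation matrix), so the result is invariant to affine
#' rescaling of any input column.
#'
#' @param accession_means Data frame from [accession_mean_traits()].
#' @param columns Trait columns to use.
#' @return A `prcomp` object with an extra `variance_fraction` element.
#' @export
trait_pca <- function(accession_means, columns = multivariate_traits()) {
  X <- as.matrix(accession_means[, columns, drop = FALSE])
  if (anyNA(X)) stop("missing entries; apply replicate fallback upstream")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance trait(s): ", paste(columns[sds == 0], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  pc$variance_fraction <- pc$sdev^2 / sum(pc$sdev^2)
  pc
}

#' Average-linkage clustering of accession-mean traits
#'
#' UPGMA (average linkage) on the Euclidean distance matrix of standardised
#' accession-mean traits. Standardisation makes mixed-unit traits
#' commensurable; `hclust` breaks merge ties deterministically by agenda
#' order, so results are reproducible given the input row order.
#'
#' @param accession_means Data frame from [accession_mean_traits()].
#' @param columns Trait columns to use.
#' @param k Optional number of flat clusters to cut.
#' @return List with `hclust` (the dendrogram), `labels` (row labels), and,
#'   if `k` given, `clusters` (flat assignment).
#' @export
cluster_accessions <- function(accession_means, columns = multivariate_traits(),
                               k = NULL) {
  X <- as.matrix(accession_means[, columns, drop = FALSE])
  if (nrow(X) < 2) stop("need at least 2 rows to cluster")
  if (anyNA(X)) stop("missing entries; apply replicate fallback upstream")
  rownames(X) <- paste(accession_means$accession, accession_means$treatment,
                       sep = "_")
  hc <- stats::hclust(stats::dist(scale(X)), method = "average")
  out <- list(hclust = hc, labels = rownames(X))
  if (!is.null(k)) out$clusters <- stats::cutree(hc, k = k)
  out
}

#' Export a dendrogram as a Newick string
#'
#' @param clustering Result of [cluster_accessions()] (or an `hclust`).
#' @param file Optional path; if given the tree is written there.
#' @return The Newick string, invisibly if written to file.
#' @export
dendrogram_newick <- function(clustering, file = NULL) {
  hc <- if (inherits(clustering, "hclust")) clustering else clustering$hclust
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
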