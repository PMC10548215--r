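#' Construct a wavelength selection result
#'
#' @param method `"pca_loadings"` or `"rrelieff"`.
#' @param scores Named numeric vector of per-wavelength importance (names are
#'   wavelengths in nm): RReliefF weights or maximum absolute PCA loadings.
#' @param selected Numeric vector of selected wavelengths (nm), sorted,
#'   duplicate-free.
#' @param provenance List of context (week, trait, parameters).
#' @return A list of class `selection_result`.
#' @export
selection_result <- function(method, scores, selected = numeric(0),
                             provenance = list()) {
  stopifnot(method %in% c("pca_loadings", "rrelieff"),
            !anyDuplicated(selected))
  structure(list(method = method, scores = scores,
                 selected = sort(selected), provenance = provenance),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> method '%s': %d scored, %d selected\n",
              x$method, length(x$scores), length(x$selected)))
  invisible(x)
}

#' Covariance-matrix PCA of spectra
#'
#' PCA of the centred but unscaled reflectance matrix (variance-covariance
#' PCA): reflectances share units, so loadings weight wavelengths by actual
#' variance contribution.
#'
#' @param spectra A [spectra_set()] (typically weekly accession means).
#' @return A `prcomp` object with an extra `variance_fraction` element and the
#'   wavelength grid in `$grid`.
#' @export
spectra_pca <- function(spectra) {
  X <- spectra$values
  if (nrow(X) < 2) stop("need at least 2 spectra for PCA")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  pc$variance_fraction <- pc$sdev^2 / sum(pc$sdev^2)
  pc$grid <- spectra$grid
  pc
}

#' Select wavelengths from top PCA loadings
#'
#' Retains the minimal leading set of principal components whose cumulative
#' variance fraction strictly exceeds `var_threshold`, takes the `top_k`
#' wavelengths by absolute loading from each retained component, and returns
#' their union sorted by wavelength. Invariant to sign flips of the loadings.
#'
#' @param pca Result of [spectra_pca()].
#' @param var_threshold Cumulative variance fraction to exceed, default 0.90.
#' @param top_k Wavelengths per retained component, default 10.
#' @return A [selection_result()]; `scores` is the maximum absolute loading of
#'   each wavelength over the retained components.
#' @export
select_wsvm <- function(pca, var_threshold = 0.90, top_k = 10) {
  cum <- cumsum(pca$variance_fraction)
  n_pc <- which(cum > var_threshold)[1]
  if (is.na(n_pc)) n_pc <- length(cum)
  grid <- pca$grid %||% as.numeric(rownames(pca$rotation))
  sel <- integer(0)
  for (j in seq_len(n_pc)) {
    load <- abs(pca$rotation[, j])
    sel <- union(sel, order(load, decreasing = TRUE)[seq_len(min(top_k, length(load)))])
  }
  scores <- apply(abs(pca$rotation[, seq_len(n_pc), drop = FALSE]), 1, max)
  names(scores) <- as.character(grid)
  selection_result("pca_loadings", scores, selected = grid[sel],
                   provenance = list(n_pc = n_pc, var_threshold = var_threshold,
                                     top_k = top_k))
}

#' Select the top-ranked wavelengths from RReliefF scores
#'
#' Top `n_wavelengths` by score; ties broken by ascending wavelength; the
#' selection is returned in wavelength order.
#'
#' @param scores A [selection_result()] with RReliefF scores (or any named
#'   score vector keyed by wavelength).
#' @param n_wavelengths Number of wavelengths to keep.
#' @return A [selection_result()] with `selected` filled in.
#' @export
select_wplsr <- function(scores, n_wavelengths) {
  sc <- if (inherits(scores, "selection_result")) scores$scores else scores
  if (n_wavelengths <= 0) stop("n_wavelengths must be positive")
  if (n_wavelengths > length(sc))
    stop("n_wavelengths exceeds number of scored wavelengths")
  wl <- as.numeric(names(sc))
  ord <- order(-sc, wl)
  keep <- wl[ord[seq_len(n_wavelengths)]]
  prov <- if (inherits(scores, "selection_result")) scores$provenance else list()
  prov$n_wavelengths <- n_wavelengths
  selection_result("rrelieff", sc, selected = keep, provenance = prov)
}

#' Serialise a selection result as a table
#'
#' @param selection A [selection_result()].
#' @return Data frame with `wavelength_nm`, `score`, `selected_flag`, `rank`
#'   (rank 1 = best score; ties broken by ascending wavelength).
#' @export
selection_table <- function(selection) {
  wl <- as.numeric(names(selection$scores))
  rank <- match(seq_along(wl), order(-selection$scores, wl))
  data.frame(wavelength_nm = wl, score = as.numeric(selection$scores),
             selected_flag = wl %in% selection$selected, rank = rank)
}
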