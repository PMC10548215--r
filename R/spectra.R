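#' Construct a spectra set
#'
#' A `spectra_set` holds a shared wavelength grid, one reflectance (or digital
#' number) vector per row, and row metadata. Rows may be individual imaging
#' events, plant-week averages, or accession-mean spectra; `level` records
#' which.
#'
#' @param grid Numeric vector of wavelengths (nm), strictly increasing.
#' @param values Numeric matrix, one row per spectrum, `ncol == length(grid)`.
#' @param meta Data frame with one row per spectrum (join keys such as
#'   `plant_id`, `week`, `accession`, `treatment`).
#' @param level Character label: `"event"`, `"plant_week"` or
#'   `"accession_mean"`.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(grid, values, meta, level = "plant_week") {
  values <- as.matrix(values)
  stopifnot(is.numeric(grid), all(diff(grid) > 0),
            ncol(values) == length(grid),
            nrow(values) == nrow(meta))
  if (nrow(values) > 0 && any(apply(values, 1, function(r) all(is.na(r)))))
    stop("spectra_set: row with all-missing values")
  colnames(values) <- as.character(grid)
  structure(list(grid = as.numeric(grid), values = values,
                 meta = as.data.frame(meta, stringsAsFactors = FALSE),
                 level = level),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d wavelengths (%.0f-%.0f nm), level '%s'\n",
              nrow(x$values), length(x$grid), min(x$grid), max(x$grid), x$level))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$values)

#' Subset a spectra set to selected wavelengths
#'
#' @param spectra A [spectra_set()].
#' @param wavelengths Wavelengths (nm) to keep; all must be on the grid.
#' @return A `spectra_set` on the reduced grid.
#' @export
subset_wavelengths <- function(spectra, wavelengths) {
  idx <- match(wavelengths, spectra$grid)
  if (anyNA(idx))
    stop("wavelengths absent from grid: ",
         paste(wavelengths[is.na(idx)], collapse = ", "))
  idx <- sort(idx)
  spectra_set(spectra$grid[idx], spectra$values[, idx, drop = FALSE],
              spectra$meta, spectra$level)
}

#' Calibrate a raw scan to percent reflectance
#'
#' Converts raw digital numbers to relative reflectance using the white and
#' dark reference tests:
#' `reflectance (%) = 100 * (plant - dark) / (white - dark)`, elementwise over
#' the wavelength grid. Values below 0% or above 100% (possible under sensor
#' noise) are retained, not clipped; see [qc_reflectance()].
#'
#' @param scan A raw scan: list with numeric `plant_dn`, `white_dn`, `dark_dn`
#'   on a common `grid`, plus `plant_id` and `week`.
#' @return A list of class `spectrum` with `wavelengths`, `reflectance` (%),
#'   `plant_id`, `week`.
#' @export
calibrate_reflectance <- function(scan) {
  stopifnot(length(scan$plant_dn) == length(scan$grid),
            length(scan$white_dn) == length(scan$grid),
            length(scan$dark_dn) == length(scan$grid))
  denom <- scan$white_dn - scan$dark_dn
  bad <- which(denom <= 0)
  if (length(bad))
    stop(sprintf("calibration error: white_dn <= dark_dn at wavelength(s) %s nm",
                 paste(scan$grid[utils::head(bad, 5)], collapse = ", ")))
  refl <- 100 * (scan$plant_dn - scan$dark_dn) / denom
  structure(list(wavelengths = scan$grid, reflectance = refl,
                 plant_id = scan$plant_id, week = scan$week),
            class = "spectrum")
}

#' Calibrate a whole scan set to a reflectance spectra set
#'
#' Applies [calibrate_reflectance()] row-wise to the output of
#' [generate_experiment()] (or any scan set with matrices of digital numbers).
#'
#' @param scans A `scan_set`: list with `grid`, matrix `plant_dn` (rows =
#'   imaging events), vectors or matrices `white_dn`/`dark_dn`, and `meta`.
#' @return A `spectra_set` at level `"event"`.
#' @export
calibrate_scans <- function(scans) {
  white <- scans$white_dn
  dark <- scans$dark_dn
  if (is.matrix(white)) white <- white[1L, ]
  if (is.matrix(dark)) dark <- dark[1L, ]
  denom <- white - dark
  bad <- which(denom <= 0)
  if (length(bad))
    stop(sprintf("calibration error: white_dn <= dark_dn at wavelength(s) %s nm",
                 paste(scans$grid[utils::head(bad, 5)], collapse = ", ")))
  refl <- 100 * sweep(sweep(scans$plant_dn, 2, dark, "-"), 2, denom, "/")
  spectra_set(scans$grid, refl, scans$meta, level = "event")
}

#' Average imaging events within weeks
#'
#' Imaging events falling in the same week are averaged per plant, giving one
#' stable spectrum per plant and week. Plants with no event in a week are
#' absent from that week (never zero-filled).
#'
#' @param spectra An event-level [spectra_set()] whose `meta` has `plant_id`
#'   and either a `week` column or an `event` column.
#' @param event_to_week Optional named vector mapping `meta$event` values to
#'   week labels; by default `meta$week` is used directly.
#' @return A `spectra_set` at level `"plant_week"`.
#' @export
weekly_average <- function(spectra, event_to_week = NULL) {
  meta <- spectra$meta
  if (is.null(event_to_week)) {
    if (is.null(meta$week)) stop("meta has no 'week' column and no mapping given")
    wk <- meta$week
  } else {
    if (is.null(meta$event)) stop("meta has no 'event' column to map")
    wk <- unname(event_to_week[as.character(meta$event)])
    if (anyNA(wk))
      stop("unmapped imaging event(s): ",
           paste(unique(meta$event[is.na(wk)]), collapse = ", "))
  }
  key <- paste(meta$plant_id, wk, sep = "\r")
  n <- table(key)
  avg <- rowsum(spectra$values, key, reorder = TRUE) / as.vector(n[sort(names(n))])
  parts <- do.call(rbind, strsplit(sort(unique(key)), "\r", fixed = TRUE))
  meta_out <- data.frame(plant_id = parts[, 1],
                         week = utils::type.convert(parts[, 2], as.is = TRUE),
                         n_events = as.vector(n[sort(names(n))]),
                         stringsAsFactors = FALSE)
  spectra_set(spectra$grid, avg, meta_out, level = "plant_week")
}

#' Average replicate plants to accession means
#'
#' One spectrum per accession x treatment x week, the mean over available
#' replicates. When a replicate's spectrum is missing, the remaining
#' replicate(s) represent the accession mean.
#'
#' @param spectra A plant-week [spectra_set()].
#' @param design Design table with `plant_id`, `accession`, `treatment` (and
#'   optionally `subpopulation`).
#' @return A `spectra_set` at level `"accession_mean"` whose meta carries
#'   `accession`, `treatment`, `week` (and `subpopulation` if present),
#'   plus `n_replicates`.
#' @export
accession_mean <- function(spectra, design) {
  meta <- spectra$meta
  idx <- match(meta$plant_id, design$plant_id)
  if (anyNA(idx))
    stop("plant(s) absent from design: ",
         paste(unique(meta$plant_id[is.na(idx)]), collapse = ", "))
  acc <- design$accession[idx]
  trt <- design$treatment[idx]
  key <- paste(acc, trt, meta$week, sep = "\r")
  n <- table(key)
  if (any(n == 0)) stop("accession with zero available replicates")
  avg <- rowsum(spectra$values, key, reorder = TRUE) / as.vector(n[sort(names(n))])
  parts <- do.call(rbind, strsplit(sort(unique(key)), "\r", fixed = TRUE))
  meta_out <- data.frame(accession = parts[, 1], treatment = parts[, 2],
                         week = utils::type.convert(parts[, 3], as.is = TRUE),
                         n_replicates = as.vector(n[sort(names(n))]),
                         stringsAsFactors = FALSE)
  if (!is.null(design$subpopulation))
    meta_out$subpopulation <-
      design$subpopulation[match(meta_out$accession, design$accession)]
  spectra_set(spectra$grid, avg, meta_out, level = "accession_mean")
}

#' Flag spectra with many out-of-range reflectance values
#'
#' Calibrated reflectance is retained unclipped; this QC report flags rows
#' where more than `max_frac` of bands fall outside `bounds`.
#'
#' @param spectra A [spectra_set()].
#' @param bounds Numeric length-2, default `c(-5, 105)` (%).
#' @param max_frac Maximum tolerated fraction of out-of-range bands, default
#'   0.01.
#' @return Data frame: row metadata plus `frac_out_of_range` and `flagged`.
#' @export
qc_reflectance <- function(spectra, bounds = c(-5, 105), max_frac = 0.01) {
  frac <- rowMeans(spectra$values < bounds[1] | spectra$values > bounds[2])
  cbind(spectra$meta,
        data.frame(frac_out_of_range = frac, flagged = frac > max_frac))
}
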