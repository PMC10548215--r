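#' Write spectra in long format
#'
#' Long-format CSV: `plant_id, week, wavelength_nm, value, channel`, with
#' channel in `{plant, white, dark}` for raw scan sets (plus an `event`
#' column) or a single `reflectance` channel for calibrated sets.
#'
#' @param x A `scan_set` or [spectra_set()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_spectra_long <- function(x, file) {
  if (inherits(x, "scan_set")) {
    m <- x$meta
    n <- nrow(m); p <- length(x$grid)
    long <- data.frame(
      plant_id = rep(m$plant_id, each = p),
      week = rep(m$week, each = p),
      event = rep(m$event, each = p),
      wavelength_nm = rep(x$grid, n),
      value = as.vector(t(x$plant_dn)),
      channel = "plant", stringsAsFactors = FALSE)
    refs <- data.frame(
      plant_id = NA_character_, week = NA_integer_, event = NA_integer_,
      wavelength_nm = rep(x$grid, 2),
      value = c(x$white_dn, x$dark_dn),
      channel = rep(c("white", "dark"), each = p), stringsAsFactors = FALSE)
    utils::write.csv(rbind(long, refs), file, row.names = FALSE)
  } else {
    m <- x$meta
    p <- length(x$grid)
    long <- data.frame(
      plant_id = rep(m$plant_id, each = p),
      week = rep(m$week, each = p),
      wavelength_nm = rep(x$grid, nrow(m)),
      value = as.vector(t(x$values)),
      channel = "reflectance", stringsAsFactors = FALSE)
    utils::write.csv(long, file, row.names = FALSE)
  }
  invisible(file)
}

#' Read long-format reflectance spectra
#'
#' @param file CSV written by [write_spectra_long()] (reflectance channel).
#' @return A [spectra_set()] at level `"plant_week"`.
#' @export
read_spectra_long <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("plant_id", "week", "wavelength_nm", "value")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(d$value)) stop("non-numeric value column")
  d <- d[is.na(d$channel) | d$channel == "reflectance" | d$channel == "plant", ]
  key <- paste(d$plant_id, d$week, sep = "\r")
  grid <- sort(unique(d$wavelength_nm))
  rows <- sort(unique(key))
  if (anyDuplicated(paste(key, d$wavelength_nm)))
    stop("duplicate plant_id x week x wavelength entries")
  m <- matrix(NA_real_, length(rows), length(grid))
  m[cbind(match(key, rows), match(d$wavelength_nm, grid))] <- d$value
  parts <- do.call(rbind, strsplit(rows, "\r", fixed = TRUE))
  meta <- data.frame(plant_id = parts[, 1],
                     week = utils::type.convert(parts[, 2], as.is = TRUE),
                     stringsAsFactors = FALSE)
  spectra_set(grid, m, meta, "plant_week")
}

#' Write spectra in wide format
#'
#' One row per spectrum; metadata columns followed by one column per
#' wavelength (named `wl_<nm>`).
#'
#' @param spectra A [spectra_set()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_spectra_wide <- function(spectra, file) {
  v <- as.data.frame(spectra$values)
  names(v) <- paste0("wl_", spectra$grid)
  utils::write.csv(cbind(spectra$meta, v), file, row.names = FALSE)
  invisible(file)
}

#' Read wide-format spectra
#'
#' @param file CSV written by [write_spectra_wide()].
#' @param level Level label for the resulting set.
#' @return A [spectra_set()].
#' @export
read_spectra_wide <- function(file, level = "plant_week") {
  d <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  wl_cols <- grep("^wl_", names(d))
  if (!length(wl_cols)) stop("no wavelength columns (wl_*) found")
  grid <- as.numeric(sub("^wl_", "", names(d)[wl_cols]))
  ord <- order(grid)
  spectra_set(grid[ord], as.matrix(d[, wl_cols[ord], drop = FALSE]),
              d[, -wl_cols, drop = FALSE], level)
}

#' Load design, spectra and trait tables from files
#'
#' Validates schemas and the join: every spectra row must reference a plant in
#' the design table.
#'
#' @param design_file,spectra_file,traits_file CSV paths; the spectra file may
#'   be long or wide format (detected from its header).
#' @return List with `design`, `spectra` (a [spectra_set()]), `traits`.
#' @export
load_tables <- function(design_file, spectra_file, traits_file) {
  design <- utils::read.csv(design_file, stringsAsFactors = FALSE)
  need <- c("plant_id", "accession", "treatment")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design: missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$plant_id))
    stop("design: duplicate plant_id at row(s) ",
         paste(which(duplicated(design$plant_id)), collapse = ", "))
  header <- names(utils::read.csv(spectra_file, nrows = 1))
  spectra <- if (any(grepl("^wl_", header))) read_spectra_wide(spectra_file)
             else read_spectra_long(spectra_file)
  unknown <- setdiff(spectra$meta$plant_id, design$plant_id)
  if (length(unknown))
    stop("spectra reference unknown plant_id: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  traits <- utils::read.csv(traits_file, stringsAsFactors = FALSE)
  if (!"plant_id" %in% names(traits)) stop("traits: missing column plant_id")
  list(design = design, spectra = spectra, traits = traits)
}

#' Write a run configuration to YAML or JSON
#'
#' The format follows the file extension: `.yml`/`.yaml` (requires the yaml
#' package) or `.json`.
#'
#' @param config A [synthetic_config()] or plain named list.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, file) {
  cfg <- unclass(config)
  if (grepl("\\.ya?ml$", file)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML output")
    writeLines(yaml::as.yaml(cfg), file)
  } else {
    jsonlite::write_json(cfg, file, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' Read a run configuration from YAML or JSON
#'
#' Entries are passed to [synthetic_config()], so defaults fill anything the
#' file omits and invariants are re-validated.
#'
#' @param file Path written by [write_config()].
#' @return A [synthetic_config()].
#' @export
read_config <- function(file) {
  cfg <- if (grepl("\\.ya?ml$", file)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML input")
    yaml::read_yaml(file)
  } else {
    jsonlite::read_json(file, simplifyVector = TRUE)
  }
  do.call(synthetic_config, cfg[names(cfg) %in% names(formals(synthetic_config))])
}
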