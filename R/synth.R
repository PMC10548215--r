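#' Configuration for a synthetic rice imaging experiment
#'
#' Defines the design and generative parameters of a synthetic experiment with
#' the same statistical structure the downstream analyses assume: 23 accessions
#' (15 indica + 8 tropical japonica), two nitrogen levels (N1 high, N2 low),
#' 94 occupied pots (22 accessions x 2 replicates x 2 treatments plus one
#' accession x 3 replicates x 2 treatments), four weekly imaging timepoints,
#' and plant-like VNIR+SWIR spectra whose treatment signal concentrates near
#' the Red Edge (~715 nm).
#'
#' Latent plant state is three-dimensional: `chlorophyll` drives visible-light
#' absorption, the Red Edge position, and leaf nitrogen; `water` drives the
#' 1450/1940 nm absorption troughs; `structure` drives the NIR plateau and
#' biomass. The nitrogen treatment acts on the chlorophyll latent
#' (`treatment_chl_effect` is the N1 - N2 mean difference). With
#' `week13_stress = TRUE`, high-nitrogen plants lose chlorophyll expression and
#' water by week 13 (late-experiment water stress interacting with treatment),
#' which erodes the treatment signal in the final week.
#'
#' @param n_accessions_ind,n_accessions_trj Numbers of indica and tropical
#'   japonica accessions.
#' @param reps_per_accession Replicates per accession per treatment.
#' @param extra_rep_accessions How many accessions (taken from the end of the
#'   list) carry one extra replicate per treatment.
#' @param treatments Exactly two treatment labels, high first.
#' @param weeks Integer week indices of the imaging timepoints.
#' @param vnir_range_nm,swir_range_nm,vnir_step_nm,swir_step_nm Camera ranges
#'   (nm) and sampling steps; the merged grid keeps the VNIR sample at the
#'   junction and starts SWIR one step above it.
#' @param events_per_week Imaging events per plant per week (averaged later).
#' @param treatment_chl_effect Mean chlorophyll-latent difference N1 - N2.
#' @param treatment_redge_shift_nm Red-Edge inflection shift (nm) per unit of
#'   the chlorophyll latent.
#' @param accession_sd,residual_sd Chlorophyll-latent standard deviations of
#'   the accession random effect and the within-accession residual.
#' @param water_sd,structure_sd Standard deviations of the other two latents.
#' @param week_drift_chl Linear drift of the chlorophyll latent per week
#'   relative to the trait-measurement week (week 9).
#' @param week13_stress Logical; enable the week-13 water-stress interaction.
#' @param stress_chl_drop,stress_water_drop Week-13 reductions of the
#'   chlorophyll and water latents in the high-nitrogen group.
#' @param treatment_baseline_shift Additive reflectance offset (%) applied to
#'   low-nitrogen spectra, a device for calibration-transfer experiments;
#'   0 (off) by default.
#' @param n_intercept,n_slope Affine map from the chlorophyll latent to leaf
#'   nitrogen (%).
#' @param trait_noise_sd Residual standard deviation of leaf nitrogen (%).
#' @param spectral_noise_sd Additive reflectance noise per event and band (%).
#' @param structured_noise_sd Amplitude (%) of the smooth per-plant-per-week
#'   nuisance spectra (random broad Gaussian bumps emulating architecture and
#'   pose effects of canopy imaging); shared by a plant's events within a
#'   week, so weekly averaging does not remove it.
#' @param persistent_noise_sd Standard deviation (%) of band-level reflectance
#'   deviations that persist across a plant's imaging events within a week
#'   (segmentation and view-geometry artifacts); also unremovable by weekly
#'   averaging, and high-dimensional, which is what makes many-wavelength
#'   models fragile at small calibration sizes.
#' @param n_missing_traits Number of plants with unavailable SLA/C/N.
#' @param seed Default seed for [generate_experiment()].
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_accessions_ind = 15,
                             n_accessions_trj = 8,
                             reps_per_accession = 2,
                             extra_rep_accessions = 1,
                             treatments = c("N1", "N2"),
                             weeks = c(6L, 9L, 10L, 13L),
                             vnir_range_nm = c(400, 1000),
                             swir_range_nm = c(1000, 2500),
                             vnir_step_nm = 2,
                             swir_step_nm = 5,
                             events_per_week = 3,
                             treatment_chl_effect = 1.0,
                             treatment_redge_shift_nm = 6,
                             accession_sd = 0.3,
                             residual_sd = 0.3,
                             water_sd = 0.4,
                             structure_sd = 0.5,
                             week_drift_chl = 0.05,
                             week13_stress = TRUE,
                             stress_chl_drop = 0.7,
                             stress_water_drop = 0.5,
                             treatment_baseline_shift = 0,
                             n_intercept = 1.4,
                             n_slope = 0.9,
                             trait_noise_sd = 0.18,
                             spectral_noise_sd = 0.5,
                             structured_noise_sd = 0.4,
                             persistent_noise_sd = 0.9,
                             n_missing_traits = 6,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_accessions_ind >= 1 || n_accessions_trj >= 1,
            reps_per_accession >= 1,
            length(treatments) == 2, !anyDuplicated(treatments),
            length(weeks) >= 1,
            vnir_step_nm > 0, swir_step_nm > 0,
            spectral_noise_sd >= 0, trait_noise_sd >= 0,
            n_missing_traits >= 0)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Merged VNIR + SWIR wavelength grid
#'
#' Both cameras cover the junction wavelength; the merged grid keeps the VNIR
#' sample there and starts SWIR one step above, so the grid is strictly
#' increasing with no duplicates.
#'
#' @param config A [synthetic_config()].
#' @return Numeric vector of wavelengths (nm).
#' @export
wavelength_grid <- function(config) {
  vnir <- seq(config$vnir_range_nm[1], config$vnir_range_nm[2],
              by = config$vnir_step_nm)
  swir <- seq(max(vnir) + config$swir_step_nm, config$swir_range_nm[2],
              by = config$swir_step_nm)
  c(vnir, swir)
}

#' Build the experimental design table
#'
#' One row per occupied pot: accession, subpopulation (indica accessions
#' first, tropical japonica after), treatment and replicate. Purge pots are
#' never represented. Under the default configuration this yields
#' 22 accessions x 2 replicates x 2 treatments + 1 accession x 3 replicates
#' x 2 treatments = 94 rows.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with `plant_id`, `accession`, `subpopulation`,
#'   `treatment`, `replicate`.
#' @export
make_design <- function(config) {
  n_acc <- config$n_accessions_ind + config$n_accessions_trj
  if (n_acc < 1) stop("design requires at least one accession")
  if (config$reps_per_accession < 1) stop("design requires at least one replicate")
  acc <- sprintf("ACC%02d", seq_len(n_acc))
  subpop <- rep(c("IND", "TRJ"),
                c(config$n_accessions_ind, config$n_accessions_trj))
  reps <- rep(config$reps_per_accession, n_acc)
  if (config$extra_rep_accessions > 0) {
    extra <- utils::tail(seq_len(n_acc), config$extra_rep_accessions)
    reps[extra] <- reps[extra] + 1L
  }
  rows <- do.call(rbind, lapply(seq_len(n_acc), function(i) {
    expand.grid(accession = acc[i], treatment = config$treatments,
                replicate = seq_len(reps[i]),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$accession, rows$treatment, rows$replicate), ]
  rows$subpopulation <- subpop[match(rows$accession, acc)]
  rows$plant_id <- sprintf("P%03d", seq_len(nrow(rows)))
  rownames(rows) <- NULL
  rows[, c("plant_id", "accession", "subpopulation", "treatment", "replicate")]
}

#' Draw latent plant states for a design
#'
#' @param design Output of [make_design()].
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return Data frame keyed by `plant_id` with latents `chlorophyll`, `water`,
#'   `structure` (values at the trait-measurement week, week 9).
#' @export
draw_plant_states <- function(design, config, seed = config$seed) {
  with_seed(seed, {
    acc <- unique(design$accession)
    acc_eff <- stats::rnorm(length(acc), 0, config$accession_sd)
    names(acc_eff) <- acc
    high <- design$treatment == config$treatments[1]
    mu <- 1.5 + ifelse(high, config$treatment_chl_effect / 2,
                       -config$treatment_chl_effect / 2)
    chl <- mu + acc_eff[design$accession] +
      stats::rnorm(nrow(design), 0, config$residual_sd)
    data.frame(plant_id = design$plant_id,
               chlorophyll = as.numeric(chl),
               water = stats::rnorm(nrow(design), 0, config$water_sd),
               structure = stats::rnorm(nrow(design), 0, config$structure_sd),
               stringsAsFactors = FALSE)
  })
}

# latent state at a given week: chlorophyll drifts linearly away from week 9;
# the week-13 stress interaction pulls high-N plants toward the low-N group
# and dries them out.
state_at_week <- function(state, week, high_n, config) {
  chl <- state$chlorophyll + config$week_drift_chl * (week - 9)
  wat <- state$water
  if (config$week13_stress && week >= 13) {
    chl <- chl - ifelse(high_n, config$stress_chl_drop, 0)
    wat <- wat - ifelse(high_n, config$stress_water_drop, 0)
  }
  list(chlorophyll = chl, water = wat, structure = state$structure)
}

#' Noise-free reflectance of a latent plant state
#'
#' A phenomenological plant spectrum: visible reflectance is a low baseline
#' with chlorophyll absorption features (490 and 660 nm) deepening with the
#' chlorophyll latent; a logistic Red-Edge ramp, whose inflection shifts to
#' longer wavelengths with chlorophyll, rises to a NIR plateau set by the
#' structure latent; the SWIR decays smoothly with water absorption troughs at
#' 1450 and 1940 nm deepening with the water latent, plus a fixed
#' cellulose-like feature near 2300 nm. This reproduces the qualitative shape
#' of measured rice canopy spectra without a radiative-transfer model.
#'
#' @param state List or one-row data frame with `chlorophyll`, `water`,
#'   `structure` (scalars or equal-length vectors for vectorised use).
#' @param grid Wavelength grid (nm) within 400-2500.
#' @param config A [synthetic_config()] (controls the Red-Edge gain).
#' @return Matrix of reflectance (%), one row per state element, or a vector
#'   for scalar states.
#' @export
true_reflectance <- function(state, grid,
                             config = synthetic_config()) {
  if (any(grid < 400 | grid > 2500)) stop("grid outside supported 400-2500 nm range")
  chl <- state$chlorophyll
  wat <- state$water
  str <- state$structure
  n <- max(length(chl), 1L)
  lam <- matrix(grid, n, length(grid), byrow = TRUE)

  plateau <- 35 + 5 * pmax(pmin(str, 3), -3)          # NIR plateau level (%)
  vis <- pmax(9 - 1.2 * chl, 1.5)                     # green-peak baseline (%)
  # chlorophyll absorption dips (blue and red)
  dip <- outer(pmin(pmax(0.25 + 0.12 * chl, 0), 0.92), rep(1, length(grid))) *
    (0.8 * exp(-((lam - 490) / 18)^2) + exp(-((lam - 660) / 22)^2))
  lam_re <- 700 + config$treatment_redge_shift_nm * chl  # Red-Edge inflection
  ramp <- 1 / (1 + exp(-(lam - lam_re) / 15))
  vnir <- vis * (1 - dip) * (1 - ramp) + plateau * ramp

  # SWIR: smooth decay from the plateau with water troughs and a cellulose dip
  decay <- 1 - 0.35 * pmin(pmax((lam - 1000) / 1500, 0), 1)
  wdepth <- pmin(pmax(0.25 + 0.12 * wat, 0), 0.9)
  troughs <- 1 - wdepth * exp(-((lam - 1450) / 45)^2) -
    wdepth * 1.1 * exp(-((lam - 1940) / 55)^2) -
    0.12 * exp(-((lam - 2300) / 80)^2)
  swir_w <- 1 / (1 + exp(-(lam - 1050) / 25))  # blend region near the junction
  refl <- vnir * (1 - swir_w) + (plateau * decay * pmax(troughs, 0.02)) * swir_w
  refl <- pmin(pmax(refl, 0), 100)
  if (length(chl) == 1L) as.numeric(refl) else refl
}

# smooth instrument reference spectra (raw digital numbers)
white_reference_dn <- function(grid) 3000 + 0.5 * grid
dark_reference_dn <- function(grid) 80 + 0.01 * grid

# relative noise profile of the two cameras: the SWIR detector is noisier
# than the VNIR one, and signal-to-noise degrades toward both spectral range
# edges; multiplies every reflectance noise sd
band_noise_factor <- function(grid) {
  1 + 1.5 * (grid > 1000) +
    2 * exp(-((grid - 1450) / 60)^2) +   # strong water absorption: little
    3 * exp(-((grid - 1940) / 80)^2) +   # reflected light reaches the sensor
    2 * pmax(0, (grid - 2300) / 200) +
    3 * pmax(0, (430 - grid) / 30)
}

#' Simulate a raw scan for one plant state
#'
#' Constructs raw digital numbers such that white/dark calibration recovers
#' `true_reflectance(state)` plus additive Gaussian noise of standard
#' deviation `noise_sd` (%).
#'
#' @param state Latent state (see [true_reflectance()]).
#' @param grid Wavelength grid (nm).
#' @param noise_sd Reflectance noise sd (%), `>= 0`.
#' @param seed Integer seed.
#' @param config A [synthetic_config()].
#' @param plant_id,week Metadata carried on the scan.
#' @return A raw scan list: `grid`, `plant_dn`, `white_dn`, `dark_dn`,
#'   `plant_id`, `week`.
#' @export
simulate_scan <- function(state, grid, noise_sd = 0, seed = NULL,
                          config = synthetic_config(),
                          plant_id = NA_character_, week = NA_integer_) {
  stopifnot(noise_sd >= 0)
  r <- true_reflectance(state, grid, config)
  r <- with_seed(seed, r + stats::rnorm(length(grid), 0, noise_sd))
  white <- white_reference_dn(grid)
  dark <- dark_reference_dn(grid)
  list(grid = grid, plant_dn = dark + (white - dark) * r / 100,
       white_dn = white, dark_dn = dark, plant_id = plant_id, week = week)
}

#' Simulate ground-reference traits for one or more plants
#'
#' Leaf nitrogen is affine in the chlorophyll latent; carbon is near-constant
#' (~40%), so C:N = C/N is strongly negatively correlated with N. Stomatal
#' conductance is lognormal (right-skewed) and transpiration is exactly
#' proportional to it, so their logs are perfectly correlated. Quantum yields
#' are higher under high nitrogen; final biomass couples weakly to the water
#' latent; specific leaf area is higher under high nitrogen. Leaf area and dry
#' weight are returned so derived traits can be recomputed with
#' [derive_traits()].
#'
#' @param states Data frame from [draw_plant_states()] (or a subset).
#' @param design Matching rows of [make_design()].
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return Data frame of traits, one row per plant.
#' @export
simulate_traits <- function(states, design, config = synthetic_config(),
                            seed = config$seed) {
  stopifnot(nrow(states) == nrow(design),
            all(states$plant_id == design$plant_id))
  n <- nrow(states)
  high <- design$treatment == config$treatments[1]
  with_seed(seed, {
    N <- config$n_intercept + config$n_slope * states$chlorophyll +
      stats::rnorm(n, 0, config$trait_noise_sd)
    N <- pmax(N, 0.8)  # leaf N below ~0.8% of dry mass is not viable tissue
    C <- 40 + stats::rnorm(n, 0, 0.3)
    gsw <- exp(-2.2 + 0.35 * stats::rnorm(n))
    E <- 1.6 * gsw
    pQY <- pmin(pmax(0.72 + 0.04 * high + 0.02 * (states$chlorophyll - 1.5) +
                       stats::rnorm(n, 0, 0.015), 0), 1)
    mQY <- pmin(pmax(0.55 + 0.05 * high + 0.01 * (states$chlorophyll - 1.5) +
                       stats::rnorm(n, 0, 0.03), 0), 1)
    FB <- pmax(18 + 2.5 * states$water + stats::rnorm(n, 0, 1.5), 1)
    A <- stats::rnorm(n, -0.5, 0.3)
    Vcmax <- pmax(55 + 12 * (states$chlorophyll - 1.5) + stats::rnorm(n, 0, 6), 5)
    Jmax <- pmax(1.9 * Vcmax + stats::rnorm(n, 0, 8), 5)
    dw <- pmax(0.35 + 0.05 * states$structure + stats::rnorm(n, 0, 0.04), 0.1)
    sla_target <- pmax(230 + 25 * high + stats::rnorm(n, 0, 15), 60)
    area <- sla_target * dw
    derived <- derive_traits(area, dw, C, N)
    data.frame(plant_id = states$plant_id, A = A, C = C, N = N,
               CN = derived$CN, E = E, gsw = gsw, FB = FB,
               Jmax = Jmax, Vcmax = Vcmax, pQY = pQY, mQY = mQY,
               SLA = derived$SLA, SLA_C = derived$SLA_C, SLN = derived$SLN,
               leaf_area_cm2 = area, dry_weight_g = dw,
               stringsAsFactors = FALSE)
  })
}

#' Generate a full synthetic experiment
#'
#' Composes the design, latent states, weekly raw scans and ground-reference
#' traits. Traits are tied to the latent state at the trait-measurement week
#' (week 9). SLA, C and N (and the traits derived from them) are marked
#' missing for `n_missing_traits` plants.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return List with `design`, `states`, `scans` (a `scan_set` whose
#'   `plant_dn` rows are imaging events), and `traits`.
#' @export
generate_experiment <- function(config = synthetic_config(), seed = config$seed) {
  design <- make_design(config)
  grid <- wavelength_grid(config)
  states <- draw_plant_states(design, config, seed = stage_seed(seed, "states"))
  high <- design$treatment == config$treatments[1]
  low_shift <- ifelse(high, 0, config$treatment_baseline_shift)

  n_events <- config$events_per_week
  meta <- expand.grid(event = seq_len(n_events), week = config$weeks,
                      plant_id = design$plant_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- meta[, c("plant_id", "week", "event")]
  meta <- meta[order(meta$plant_id, meta$week, meta$event), ]
  rownames(meta) <- NULL

  white <- white_reference_dn(grid)
  dark <- dark_reference_dn(grid)
  refl <- matrix(NA_real_, nrow(meta), length(grid))
  scan_seed <- stage_seed(seed, "scans")
  # smooth plant x week nuisance spectra: a few broad Gaussian bumps per
  # plant-week (canopy architecture / pose variation), identical across that
  # week's events so weekly averaging cannot remove them
  nuisance_spectrum <- function(n_bumps = 4L) {
    ctr <- stats::runif(n_bumps, min(grid) + 20, max(grid) - 20)
    wid <- stats::runif(n_bumps, 30, 120)
    amp <- stats::rnorm(n_bumps, 0, config$structured_noise_sd)
    colSums(amp * exp(-((matrix(grid, n_bumps, length(grid), byrow = TRUE) -
                           ctr) / wid)^2))
  }
  with_seed(scan_seed, {
    for (wk in config$weeks) {
      st <- state_at_week(states, wk, high, config)
      base <- true_reflectance(st, grid, config) + low_shift
      if (config$structured_noise_sd > 0)
        base <- base + t(vapply(seq_len(nrow(design)),
                                function(i) nuisance_spectrum(),
                                numeric(length(grid))))
      if (config$persistent_noise_sd > 0)
        base <- base + matrix(stats::rnorm(length(base), 0,
                                           config$persistent_noise_sd),
                              nrow(base), ncol(base)) *
          matrix(band_noise_factor(grid), nrow(base), ncol(base), byrow = TRUE)
      for (ev in seq_len(n_events)) {
        rows <- which(meta$week == wk & meta$event == ev)
        rows <- rows[match(design$plant_id, meta$plant_id[rows])]
        refl[rows, ] <- base +
          matrix(stats::rnorm(length(base), 0, config$spectral_noise_sd),
                 nrow(base), ncol(base)) *
          matrix(band_noise_factor(grid), nrow(base), ncol(base), byrow = TRUE)
      }
    }
  })
  plant_dn <- sweep(sweep(refl / 100, 2, white - dark, "*"), 2, dark, "+")
  scans <- list(grid = grid, plant_dn = plant_dn, white_dn = white,
                dark_dn = dark, meta = meta)
  class(scans) <- "scan_set"

  traits <- simulate_traits(states, design, config,
                            seed = stage_seed(seed, "traits"))
  if (config$n_missing_traits > 0) {
    miss <- with_seed(stage_seed(seed, "missing"),
                      sample(design$plant_id, config$n_missing_traits))
    cols <- c("C", "N", "CN", "SLA", "SLA_C", "SLN",
              "leaf_area_cm2", "dry_weight_g")
    traits[traits$plant_id %in% miss, cols] <- NA_real_
  }
  list(design = design, states = states, scans = scans, traits = traits,
       config = config, seed = seed)
}

#' Analytic noise ceiling for predicting leaf nitrogen from spectra
#'
#' Leaf nitrogen is `n_intercept + n_slope * chlorophyll + noise`. A perfect
#' recovery of the chlorophyll latent from spectra can explain at most
#' `slope^2 Var(chl) / (slope^2 Var(chl) + trait_noise_sd^2)` of the nitrogen
#' variance; treatments are balanced so the latent variance is the
#' between-treatment part plus accession and residual components.
#'
#' @param config A [synthetic_config()].
#' @return The ceiling R-squared (scalar in (0, 1)).
#' @export
noise_ceiling_r2 <- function(config = synthetic_config()) {
  var_chl <- (config$treatment_chl_effect / 2)^2 +
    config$accession_sd^2 + config$residual_sd^2
  s2 <- config$n_slope^2 * var_chl
  s2 / (s2 + config$trait_noise_sd^2)
}
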