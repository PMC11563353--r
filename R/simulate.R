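HISTO_LEVELS <- c("Benign", "MoD", "HiD", "SCC")
POSITIVE_LEVELS <- c("MoD", "HiD", "SCC")

LESION_SITES <- c("Buccal mucosa", "Tongue", "Lip", "Gingiva",
                  "Floor of mouth", "Mandible", "Maxilla", "Palate",
                  "Retromolar")

#' Binary label rule for histopathology grades
#'
#' Moderate dysplasia, high-grade dysplasia and squamous cell carcinoma form
#' the positive (cancer/pre-cancer) class; benign lesions the negative class.
#'
#' @param histopathology Character vector of grades
#'   (`"Benign"`, `"MoD"`, `"HiD"`, `"SCC"`).
#' @return Logical vector, `TRUE` for the positive class.
#' @export
is_positive_grade <- function(histopathology) {
  if (!all(histopathology %in% HISTO_LEVELS))
    stop("histopathology grades must be one of: ",
         paste(HISTO_LEVELS, collapse = ", "))
  histopathology %in% POSITIVE_LEVELS
}

# Deterministic sub-seed derivation: one root seed, expanded per stage /
# patient / fold. Kept below 2^31 - 1.
derive_seed <- function(root, stream, index = 0L) {
  as.integer((as.numeric(root) %% 2147483647 * 1009 +
                stream * 99991 + index * 101) %% 2147483647)
}

# Evaluate expr under a local RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

normalize_triple <- function(x, floor = 1e-3) {
  x <- pmax(x, floor)
  x / sum(x)
}

#' Configuration for the synthetic multispectral cohort simulator
#'
#' Describes the statistical structure of a simulated cohort of paired
#' lesion/healthy multispectral autofluorescence decay cubes: per-class band
#' composition, pixel- and patient-level dispersion of that composition,
#' single-exponential decay constants per band, additive Gaussian noise, a
#' constant baseline offset, and a hard amplitude ceiling emulating detector
#' saturation. Band amplitudes are calibrated so that each band's noise-free
#' discrete (trapezoidal) time integral equals
#' `amplitude_scale * band_fraction`, which makes the normalized integrated
#' intensities recover the configured fractions exactly in the noise-free
#' limit.
#'
#' @param n_patients Number of patients (one lesion + one contralateral
#'   healthy image each).
#' @param positive_fraction Fraction of patients carrying a cancer/pre-cancer
#'   lesion; `round(n_patients * positive_fraction)` patients are positive.
#' @param image_shape Image grid `c(rows, cols)` in pixels.
#' @param n_samples,time_dt Time axis: number of decay samples and step (ns).
#' @param band_labels Ordered emission band names; the three defaults are the
#'   collagen (390 nm), NADH (452 nm) and FAD (>500 nm) channels.
#' @param class_band_fractions Named list (`Benign`, `MoD`, `HiD`, `SCC`) of
#'   mean normalized band-intensity triples, each summing to 1. Healthy
#'   contralateral tissue always uses the `Benign` triple.
#' @param fraction_jitter_sd Per-pixel Gaussian dispersion of the band
#'   fractions (renormalized to sum to 1 after jitter).
#' @param patient_fraction_sd Per-patient Gaussian shift of the band
#'   fractions, the between-patient variability that makes cross-validation
#'   non-degenerate.
#' @param decay_constants Per-band fluorescence lifetime (ns) of the
#'   single-exponential decay model.
#' @param amplitude_scale Photon-count scale of the integrated band signal.
#' @param noise_sd Standard deviation of additive Gaussian noise per time
#'   sample (detector units).
#' @param offset_level Constant baseline offset added to every sample.
#' @param saturation_level Hard amplitude ceiling (detector units).
#' @param saturation_fraction Fraction of pixels per cube whose amplitude is
#'   boosted above `saturation_level` and therefore clipped.
#' @param prepulse_samples Leading time samples before decay onset, carrying
#'   only offset + noise; used downstream for baseline estimation.
#' @param positive_composition Named probabilities over `MoD`, `HiD`, `SCC`
#'   for the grade of positive lesions.
#' @param poisson_noise If `TRUE`, replace additive Gaussian noise by Poisson
#'   shot noise on the clean signal (off by default).
#' @param seed Integer seed; fully determines the simulated cohort.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [default_effect_config()], [simulate_cohort()]
#' @export
simulation_config <- function(n_patients = 67,
                              positive_fraction = 33 / 67,
                              image_shape = c(64, 64),
                              n_samples = 256,
                              time_dt = 0.1,
                              band_labels = c("I390", "I452", "I500"),
                              class_band_fractions = list(
                                Benign = c(0.40, 0.33, 0.27),
                                MoD = c(0.28, 0.38, 0.34),
                                HiD = c(0.28, 0.38, 0.34),
                                SCC = c(0.28, 0.38, 0.34)),
                              fraction_jitter_sd = 0.04,
                              patient_fraction_sd = 0.035,
                              decay_constants = c(5.0, 4.0, 4.5),
                              amplitude_scale = 1000,
                              noise_sd = 5,
                              offset_level = 50,
                              saturation_level = 500,
                              saturation_fraction = 0.01,
                              prepulse_samples = 16,
                              positive_composition = c(MoD = 1, HiD = 3,
                                                       SCC = 29) / 33,
                              poisson_noise = FALSE,
                              seed = 1) {
  cfg <- list(n_patients = as.integer(n_patients),
              positive_fraction = positive_fraction,
              image_shape = as.integer(image_shape),
              n_samples = as.integer(n_samples),
              time_dt = time_dt,
              band_labels = band_labels,
              class_band_fractions = class_band_fractions,
              fraction_jitter_sd = fraction_jitter_sd,
              patient_fraction_sd = patient_fraction_sd,
              decay_constants = decay_constants,
              amplitude_scale = amplitude_scale,
              noise_sd = noise_sd,
              offset_level = offset_level,
              saturation_level = saturation_level,
              saturation_fraction = saturation_fraction,
              prepulse_samples = as.integer(prepulse_samples),
              positive_composition = positive_composition,
              poisson_noise = poisson_noise,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_patients < 1) stop("n_patients must be >= 1")
  if (cfg$positive_fraction < 0 || cfg$positive_fraction > 1)
    stop("positive_fraction must be in [0, 1]")
  if (length(cfg$image_shape) != 2 || any(cfg$image_shape < 1))
    stop("image_shape must be c(rows, cols) with positive entries")
  if (cfg$n_samples < 2 || cfg$time_dt <= 0)
    stop("time axis requires n_samples >= 2 and time_dt > 0")
  nb <- length(cfg$band_labels)
  if (nb != 3) stop("exactly three emission bands are expected")
  if (length(cfg$decay_constants) != nb || any(cfg$decay_constants <= 0))
    stop("decay_constants must give one positive lifetime per band")
  if (!all(HISTO_LEVELS %in% names(cfg$class_band_fractions)))
    stop("class_band_fractions must name all of: ",
         paste(HISTO_LEVELS, collapse = ", "))
  for (cls in names(cfg$class_band_fractions)) {
    fr <- cfg$class_band_fractions[[cls]]
    if (length(fr) != nb || any(fr < 0))
      stop("band fractions for class ", cls, " must be ", nb,
           " non-negative values")
    if (abs(sum(fr) - 1) > 1e-9)
      stop("band fractions for class ", cls, " must sum to 1 (got ",
           format(sum(fr), digits = 12), ")")
  }
  if (cfg$prepulse_samples < 0 || cfg$prepulse_samples >= cfg$n_samples)
    stop("prepulse_samples must be in [0, n_samples)")
  # Decay window (post-onset) must contain >= 99% of each exponential's area.
  window <- (cfg$n_samples - 1 - cfg$prepulse_samples) * cfg$time_dt
  covered <- 1 - exp(-window / cfg$decay_constants)
  if (any(covered < 0.99))
    stop("time window too short: only ",
         paste(sprintf("%.3f", covered), collapse = "/"),
         " of the exponential area covered (need >= 0.99 per band)")
  if (cfg$fraction_jitter_sd < 0 || cfg$patient_fraction_sd < 0 ||
        cfg$noise_sd < 0)
    stop("dispersion parameters must be non-negative")
  if (cfg$saturation_fraction < 0 || cfg$saturation_fraction > 1)
    stop("saturation_fraction must be in [0, 1]")
  if (cfg$saturation_level <= cfg$offset_level)
    stop("saturation_level must exceed offset_level")
  if (abs(sum(cfg$positive_composition) - 1) > 1e-9 ||
        !all(names(cfg$positive_composition) %in% POSITIVE_LEVELS))
    stop("positive_composition must be probabilities over MoD/HiD/SCC summing to 1")
  invisible(cfg)
}

#' Default simulator configuration with planted class effects
#'
#' Returns a [simulation_config()] whose cancer/pre-cancer class differs from
#' the benign/healthy reference in the directions reported for oral
#' malignancy: lower normalized collagen-band intensity (I390,n, collagen
#' crosslink breakdown and epithelial thickening), higher normalized
#' NADH-band intensity (I452,n, increased glycolytic NADH), and a lower
#' optical redox ratio I452/I500. Healthy contralateral tissue shares the
#' benign composition.
#'
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `simulation_config`.
#' @export
default_effect_config <- function(...) {
  simulation_config(...)
}

# Deterministic cohort label assignment: exact positive count, grades drawn
# from positive_composition, order shuffled by the cohort seed.
cohort_labels <- function(config) {
  n <- config$n_patients
  n_pos <- round(n * config$positive_fraction)
  with_seed(derive_seed(config$seed, 1L), {
    grades <- if (n_pos > 0)
      sample(names(config$positive_composition), n_pos, replace = TRUE,
             prob = config$positive_composition)
    else character(0)
    labels <- c(grades, rep("Benign", n - n_pos))
    labels[sample.int(n)]
  })
}

# Single-exponential decay shape with a pre-pulse baseline region, scaled so
# its discrete trapezoidal integral is exactly 1.
decay_shape <- function(config, band_index) {
  t <- (seq_len(config$n_samples) - 1) * config$time_dt
  t0 <- config$prepulse_samples * config$time_dt
  s <- ifelse(t < t0, 0, exp(-(t - t0) / config$decay_constants[band_index]))
  w <- rep(config$time_dt, config$n_samples)
  w[c(1, config$n_samples)] <- config$time_dt / 2
  s / sum(w * s)
}

# One cube for one tissue area: per-pixel band fractions around a
# patient-level triple, unit-integral decay shapes, offset, noise, clipping.
simulate_cube <- function(config, base_fractions) {
  r <- config$image_shape[1]; cl <- config$image_shape[2]
  npix <- r * cl
  nt <- config$n_samples
  nb <- length(config$band_labels)

  patient_triple <- normalize_triple(
    base_fractions + stats::rnorm(nb, 0, config$patient_fraction_sd))
  frac <- matrix(patient_triple, npix, nb, byrow = TRUE) +
    matrix(stats::rnorm(npix * nb, 0, config$fraction_jitter_sd), npix, nb)
  frac <- pmax(frac, 1e-3)
  frac <- frac / rowSums(frac)

  # Amplitude of each pixel/band so the noise-free integral is
  # amplitude_scale * fraction.
  amp <- config$amplitude_scale * frac

  sat_idx <- integer(0)
  if (config$saturation_fraction > 0) {
    k <- round(config$saturation_fraction * npix)
    if (k > 0) {
      sat_idx <- sample.int(npix, k)
      # Boost so the peak of the brightest band clears the ceiling.
      shapes_peak <- vapply(seq_len(nb), function(b) max(decay_shape(config, b)),
                            numeric(1))
      peak <- apply(amp[sat_idx, , drop = FALSE] *
                      matrix(shapes_peak, length(sat_idx), nb, byrow = TRUE),
                    1, max) + config$offset_level
      boost <- 1.5 * (config$saturation_level - config$offset_level) /
        pmax(peak - config$offset_level, .Machine$double.eps)
      amp[sat_idx, ] <- amp[sat_idx, ] * boost
    }
  }

  bands <- vector("list", nb)
  names(bands) <- config$band_labels
  for (b in seq_len(nb)) {
    shape <- decay_shape(config, b)
    clean <- outer(amp[, b], shape) + config$offset_level
    if (config$poisson_noise) {
      trace <- matrix(stats::rpois(npix * nt, pmax(clean, 0)), npix, nt)
    } else {
      trace <- clean + matrix(stats::rnorm(npix * nt, 0, config$noise_sd),
                              npix, nt)
    }
    trace <- pmin(trace, config$saturation_level)
    bands[[b]] <- array(trace, dim = c(r, cl, nt))
  }
  multispectral_cube(bands, config$time_dt,
                     meta = list(patient_triple = patient_triple,
                                 saturated_pixels = sort(sat_idx)))
}

#' Simulate one patient of a synthetic cohort
#'
#' Generates the paired lesion/healthy decay cubes for patient `index` of the
#' cohort described by `config`. Fully deterministic given `config$seed`:
#' patients can be generated independently (streamed) or via
#' [simulate_cohort()] with identical results.
#'
#' @param config A [simulation_config()].
#' @param index Patient index in `1:n_patients`.
#' @param labels Optional precomputed cohort label vector (from the internal
#'   label assignment); computed from `config` when omitted.
#' @return A `lesion_sample`: list with `patient_id`, `lesion_cube`,
#'   `healthy_cube`, `histopathology`, `site`.
#' @export
simulate_patient <- function(config, index, labels = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            index >= 1, index <= config$n_patients)
  if (is.null(labels)) labels <- cohort_labels(config)
  label <- labels[index]
  with_seed(derive_seed(config$seed, 2L, index), {
    site <- sample(LESION_SITES, 1)
    lesion <- simulate_cube(config, config$class_band_fractions[[label]])
    healthy <- simulate_cube(config, config$class_band_fractions[["Benign"]])
    structure(list(patient_id = sprintf("P%03d", index),
                   lesion_cube = lesion,
                   healthy_cube = healthy,
                   histopathology = label,
                   site = site),
              class = "lesion_sample")
  })
}

#' Simulate a full synthetic cohort
#'
#' Generates `n_patients` paired lesion/healthy multispectral decay cubes
#' with class-dependent band composition. Exactly
#' `round(n_patients * positive_fraction)` lesions carry a positive grade
#' (MoD/HiD/SCC per `positive_composition`); all healthy contralateral cubes
#' are drawn from the benign reference composition.
#'
#' For large cohorts the per-patient memory is substantial; prefer
#' [cohort_feature_stacks()] which streams patients through preprocessing and
#' feature extraction without retaining the raw cubes.
#'
#' @param config A [simulation_config()].
#' @return List of `lesion_sample` objects, length `n_patients`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  labels <- cohort_labels(config)
  lapply(seq_len(config$n_patients), function(i)
    simulate_patient(config, i, labels = labels))
}

#' @export
print.lesion_sample <- function(x, ...) {
  cat(sprintf("lesion_sample %s: %s (%s)\n", x$patient_id,
              x$histopathology, x$site))
  invisible(x)
}
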