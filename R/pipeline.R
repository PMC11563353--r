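classifier_defaults <- function() {
  list(pool = "absolute", k = 4, C = 1, pixel_cap = 2000)
}

evaluation_defaults <- function() {
  list(max_fpr = 0.30, baseline = TRUE)
}

# Resolved default configuration for every section.
pipeline_defaults <- function() {
  list(simulation = unclass(simulation_config()),
       preprocess = unclass(preprocess_config()),
       classifier = classifier_defaults(),
       evaluation = evaluation_defaults(),
       seed = 1L,
       overlays = FALSE)
}

merge_section <- function(defaults, user, section) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration key", if (length(unknown) > 1) "s",
         " in section '", section, "': ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, user)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration with sections `simulation`,
#' `preprocess`, `classifier`, `evaluation` plus top-level `seed` and
#' `overlays`, merges it over the package defaults, rejects unknown keys,
#' and validates every section through its constructor. An empty file
#' yields the full default configuration. The resolved configuration
#' round-trips losslessly through [dump_config()].
#'
#' @param path Path to a YAML/JSON file, or `NULL` for pure defaults.
#' @return Object of class `pipeline_config` with every field resolved.
#' @export
load_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("unknown top-level configuration key",
         if (length(unknown) > 1) "s", ": ", paste(unknown, collapse = ", "))
  cfg <- defaults
  for (sec in c("simulation", "preprocess", "classifier", "evaluation"))
    cfg[[sec]] <- merge_section(defaults[[sec]], user[[sec]], sec)
  if (!is.null(user$seed)) cfg$seed <- as.integer(user$seed)
  if (!is.null(user$overlays)) cfg$overlays <- isTRUE(user$overlays)

  # class_band_fractions arrives from YAML as a list of lists; coerce.
  cfg$simulation$class_band_fractions <-
    lapply(cfg$simulation$class_band_fractions, unlist)
  cfg$simulation$positive_composition <-
    unlist(cfg$simulation$positive_composition)

  cfg$simulation$seed <- cfg$seed
  cfg$simulation <- do.call(simulation_config, cfg$simulation)
  # Unless set explicitly, resolve the preprocessing baseline window and
  # saturation threshold from the simulated acquisition (see
  # auto_preprocess_config): the baseline must not overrun the pre-pulse
  # region, and no universal detector ceiling exists.
  user_prep <- names(user$preprocess)
  if (!"baseline_samples" %in% user_prep)
    cfg$preprocess$baseline_samples <-
      max(2L, cfg$simulation$prepulse_samples)
  if (!"saturation_threshold" %in% user_prep)
    cfg$preprocess$saturation_threshold <-
      0.9 * (cfg$simulation$saturation_level - cfg$simulation$offset_level)
  cfg$preprocess <- do.call(preprocess_config, cfg$preprocess)
  if (!all(cfg$classifier$k %in% c(1, 3, 4, 5)))
    stop("classifier k must be among 1, 3, 4, 5")
  if (cfg$evaluation$max_fpr < 0 || cfg$evaluation$max_fpr > 1)
    stop("evaluation max_fpr must be in [0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Write a resolved configuration to YAML
#'
#' Every field — defaulted or not — is emitted explicitly, so the written
#' file reproduces the run exactly when loaded again.
#'
#' @param config A `pipeline_config` from [load_config()].
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
dump_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(simulation = unclass(config$simulation),
              preprocess = unclass(config$preprocess),
              classifier = config$classifier,
              evaluation = config$evaluation,
              seed = config$seed,
              overlays = config$overlays)
  out$simulation$class_band_fractions <-
    lapply(out$simulation$class_band_fractions, as.list)
  out$simulation$positive_composition <-
    as.list(out$simulation$positive_composition)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates the configured cohort, preprocesses it, extracts the 18
#' per-pixel spectral features, runs leave-one-patient-out cross-validation
#' for every requested feature pool and top-k size (plus, optionally, the
#' single-feature baseline), and writes the report files and the resolved
#' configuration to `out_dir`. Every artifact is reproducible from
#' (configuration, seed) alone.
#'
#' @param config A `pipeline_config` (see [load_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, the list of `cv_report` objects.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- cohort_feature_stacks(config$simulation, config$preprocess)
  cls <- config$classifier
  runs <- expand.grid(pool = cls$pool, k = cls$k, stringsAsFactors = FALSE)
  reports <- lapply(seq_len(nrow(runs)), function(i)
    lopocv(cohort, pool = runs$pool[i], k = runs$k[i], C = cls$C,
           pixel_cap = cls$pixel_cap, max_fpr = config$evaluation$max_fpr,
           seed = derive_seed(config$seed, 6L)))
  if (isTRUE(config$evaluation$baseline))
    reports <- c(reports, list(
      velscope_baseline(cohort, C = cls$C, pixel_cap = cls$pixel_cap,
                        max_fpr = config$evaluation$max_fpr,
                        seed = derive_seed(config$seed, 6L))))

  write_report(reports, out_dir,
               cohort = if (isTRUE(config$overlays)) cohort else NULL)
  cfg_path <- file.path(out_dir, "config_resolved.yaml")
  dump_config(config, cfg_path)
  manifest <- list(package = "oralaf",
                   version = as.character(utils::packageVersion("oralaf")),
                   seed = config$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   runs = nrow(runs) + as.integer(config$evaluation$baseline))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(reports)
}
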