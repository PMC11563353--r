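#' Preprocessing configuration
#'
#' Parameters of the five-step decay-cube preprocessing chain: per-pixel
#' offset subtraction, saturation masking, spatial smoothing, SNR masking and
#' manual masking.
#'
#' @param saturation_threshold Amplitude ceiling; pixels whose maximum signal
#'   amplitude (over time, in any band) reaches it are masked. Interpreted
#'   per `saturation_mode`. The default `Inf` disables saturation masking
#'   until a threshold is configured (no universal detector ceiling exists);
#'   [auto_preprocess_config()] resolves one from a simulation config.
#' @param saturation_mode `"absolute"` (threshold in detector units) or
#'   `"fraction_of_max"` (threshold as a fraction of the cube-wide maximum
#'   amplitude).
#' @param smoothing_kernel Odd window size of the spatial averaging filter
#'   (default 5, i.e. 5x5).
#' @param snr_threshold_db Minimum per-band SNR in decibels (default 15);
#'   SNR is `20 * log10(peak amplitude / baseline noise sd)` computed on the
#'   smoothed trace.
#' @param baseline_samples Number of leading (pre-pulse) time samples used to
#'   estimate the per-pixel offset and the noise standard deviation.
#'
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(saturation_threshold = Inf,
                              saturation_mode = c("absolute",
                                                  "fraction_of_max"),
                              smoothing_kernel = 5,
                              snr_threshold_db = 15,
                              baseline_samples = 16) {
  saturation_mode <- match.arg(saturation_mode)
  cfg <- list(saturation_threshold = saturation_threshold,
              saturation_mode = saturation_mode,
              smoothing_kernel = as.integer(smoothing_kernel),
              snr_threshold_db = snr_threshold_db,
              baseline_samples = as.integer(baseline_samples))
  if (cfg$smoothing_kernel < 1 || cfg$smoothing_kernel %% 2 == 0)
    stop("smoothing_kernel must be odd and >= 1")
  if (!is.finite(cfg$snr_threshold_db))
    stop("snr_threshold_db must be finite")
  if (cfg$baseline_samples < 2)
    stop("baseline_samples must be >= 2")
  if (cfg$saturation_mode == "fraction_of_max" &&
        (cfg$saturation_threshold <= 0 || cfg$saturation_threshold > 1))
    stop("fraction_of_max saturation_threshold must be in (0, 1]")
  structure(cfg, class = "preprocess_config")
}

#' Preprocessing configuration matched to a simulation configuration
#'
#' Resolves a saturation threshold appropriate for cubes produced by
#' [simulate_cohort()]: after offset subtraction a clipped pixel's maximum
#' amplitude is about `saturation_level - offset_level`, while unclipped
#' pixels stay far below it, so 90% of that gap cleanly separates the two.
#' The baseline window matches the simulator's pre-pulse region.
#'
#' @param sim_config A [simulation_config()].
#' @param ... Further overrides passed to [preprocess_config()].
#' @return A `preprocess_config`.
#' @export
auto_preprocess_config <- function(sim_config, ...) {
  stopifnot(inherits(sim_config, "simulation_config"))
  args <- list(...)
  if (is.null(args$saturation_threshold))
    args$saturation_threshold <-
      0.9 * (sim_config$saturation_level - sim_config$offset_level)
  if (is.null(args$baseline_samples))
    args$baseline_samples <- max(2L, sim_config$prepulse_samples)
  do.call(preprocess_config, args)
}

#' Subtract per-pixel signal offset
#'
#' Estimates the constant baseline of each pixel trace as the mean of its
#' leading `baseline_samples` (pre-pulse) time samples and subtracts it from
#' the whole trace, independently per band.
#'
#' @param cube A [multispectral_cube()].
#' @param config A [preprocess_config()].
#' @return The offset-subtracted cube.
#' @export
subtract_offset <- function(cube, config) {
  stopifnot(inherits(cube, "multispectral_cube"),
            inherits(config, "preprocess_config"))
  nt <- n_time_samples(cube)
  nb <- config$baseline_samples
  if (nb >= nt)
    stop("baseline_samples (", nb, ") must be < n_samples (", nt, ")")
  bands <- lapply(cube$bands, function(a) {
    d <- dim(a)
    m <- matrix(a, d[1] * d[2], d[3])
    base <- rowMeans(m[, seq_len(nb), drop = FALSE])
    array(m - base, dim = d)
  })
  multispectral_cube(bands, cube$time_dt, cube$meta)
}

# Row-wise maxima via max.col (C-level), much faster than apply(m, 1, max).
row_max <- function(m) m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]

resolve_saturation_threshold <- function(cube, config) {
  thr <- config$saturation_threshold
  if (config$saturation_mode == "fraction_of_max")
    thr <- thr * max(vapply(cube$bands, max, numeric(1)))
  if (!is.na(thr) && thr <= 0)
    stop("resolved saturation threshold must be positive")
  thr
}

#' Mask saturated pixels
#'
#' A pixel is masked (reason `SATURATED`) when its maximum amplitude over
#' time reaches the resolved threshold in any band: every downstream feature
#' needs all three bands, so one clipped band makes the pixel unusable.
#'
#' @param cube A [multispectral_cube()] (offset-subtracted).
#' @param config A [preprocess_config()].
#' @param mask Optional existing [pixel_mask()] to update (earlier reasons
#'   are preserved).
#' @return A [pixel_mask()].
#' @export
mask_saturated <- function(cube, config, mask = NULL) {
  stopifnot(inherits(cube, "multispectral_cube"))
  if (is.null(mask)) mask <- empty_mask(image_shape(cube))
  thr <- resolve_saturation_threshold(cube, config)
  hit <- matrix(FALSE, nrow(mask$valid), ncol(mask$valid))
  for (a in cube$bands) {
    d <- dim(a)
    peak <- row_max(matrix(a, d[1] * d[2], d[3]))
    hit <- hit | matrix(peak >= thr, d[1], d[2])
  }
  mask_update(mask, hit, MASK_SATURATED)
}

# Neighborhood sums of a 3-d array over a k x k spatial window, zero outside
# the image (no padding values are invented). Cumulative sums along the two
# short spatial dimensions keep this O(pixels * samples).
box_sum_3d <- function(a, k) {
  h <- (k - 1L) / 2L
  d <- dim(a)
  if (h == 0L) return(a)
  sum_dim1 <- function(x) {
    dd <- dim(x)
    m <- matrix(x, dd[1], dd[2] * dd[3])
    cs <- m
    for (i in seq_len(dd[1])[-1]) cs[i, ] <- cs[i, ] + cs[i - 1L, ]
    r <- dd[1]
    out <- cs[pmin(seq_len(r) + h, r), , drop = FALSE]
    lo <- seq_len(r) - h - 1L
    sel <- lo >= 1L
    out[sel, ] <- out[sel, , drop = FALSE] - cs[lo[sel], , drop = FALSE]
    array(out, dim = dd)
  }
  a <- sum_dim1(a)
  a <- aperm(a, c(2, 1, 3))
  a <- sum_dim1(a)
  aperm(a, c(2, 1, 3))
}

#' Spatial averaging filter over unmasked neighbors
#'
#' Replaces each time sample of each band by the mean over the
#' `k x k` spatial neighborhood, restricted to in-image, unmasked pixels
#' (the kernel is renormalized over the available neighbors, so no synthetic
#' values leak in at image edges or mask borders). Masked pixels keep their
#' original trace and contribute nothing to their neighbors.
#'
#' @param cube A [multispectral_cube()].
#' @param mask A [pixel_mask()].
#' @param config A [preprocess_config()] (field `smoothing_kernel`).
#' @return The smoothed cube.
#' @export
spatial_smooth <- function(cube, mask, config) {
  stopifnot(inherits(cube, "multispectral_cube"),
            inherits(mask, "pixel_mask"))
  k <- config$smoothing_kernel
  if (k == 1L) return(cube)
  d <- dim(cube)
  v <- mask$valid
  all_valid <- all(v)
  denom <- box_sum_3d(array(as.numeric(v), dim = c(d[1], d[2], 1)), k)[, , 1]
  denom[denom == 0] <- 1  # only masked pixels can have empty neighborhoods
  masked_idx <- which(!v)
  # linear indices of masked pixels across all time samples
  masked_3d <- if (length(masked_idx))
    as.vector(outer(masked_idx, (seq_len(d[3]) - 1L) * d[1] * d[2], `+`))
  bands <- lapply(cube$bands, function(a) {
    va <- if (all_valid) a else a * as.vector(v)
    sm <- box_sum_3d(va, k) / as.vector(denom)
    if (!all_valid) sm[masked_3d] <- a[masked_3d]  # masked keep raw traces
    sm
  })
  multispectral_cube(bands, cube$time_dt, cube$meta)
}

#' Mask low-SNR pixels
#'
#' Per band, the SNR of a pixel is `20 * log10(peak / sigma)` in decibels,
#' where `peak` is the maximum amplitude of the (smoothed, offset-subtracted)
#' trace and `sigma` the standard deviation of its leading
#' `baseline_samples` pre-pulse samples. A pixel is masked (reason
#' `LOW_SNR`) when its SNR falls below the threshold in any band. Noise-free
#' pixels (`sigma == 0`) have infinite SNR and are kept.
#'
#' @param cube Smoothed, offset-subtracted [multispectral_cube()].
#' @param mask A [pixel_mask()] to update.
#' @param config A [preprocess_config()].
#' @return Updated [pixel_mask()].
#' @export
mask_low_snr <- function(cube, mask, config) {
  stopifnot(inherits(cube, "multispectral_cube"),
            inherits(mask, "pixel_mask"))
  d <- dim(cube)
  nb <- config$baseline_samples
  if (nb >= d[3])
    stop("baseline_samples (", nb, ") must be < n_samples (", d[3], ")")
  hit <- matrix(FALSE, d[1], d[2])
  for (a in cube$bands) {
    m <- matrix(a, d[1] * d[2], d[3])
    peak <- row_max(m)
    base <- m[, seq_len(nb), drop = FALSE]
    sigma <- sqrt(pmax(rowMeans(base^2) - rowMeans(base)^2, 0) * nb / (nb - 1))
    snr <- ifelse(sigma == 0, Inf,
                  ifelse(peak <= 0, -Inf, 20 * log10(peak / sigma)))
    hit <- hit | matrix(snr < config$snr_threshold_db, d[1], d[2])
  }
  mask_update(mask, hit, MASK_LOW_SNR)
}

#' Apply a manual pixel mask
#'
#' Marks manually flagged pixels (e.g. teeth regions with strong
#' autofluorescence) with reason `MANUAL`. Monotone: already-masked pixels
#' keep their earlier reason and are never unmasked.
#'
#' @param mask A [pixel_mask()].
#' @param manual Logical matrix matching the image shape; `TRUE` pixels are
#'   masked.
#' @return Updated [pixel_mask()].
#' @export
apply_manual_mask <- function(mask, manual) {
  stopifnot(inherits(mask, "pixel_mask"))
  if (!identical(dim(manual), dim(mask$valid)))
    stop("manual mask shape ", paste(dim(manual), collapse = "x"),
         " does not match image shape ",
         paste(dim(mask$valid), collapse = "x"))
  mask_update(mask, manual & TRUE, MASK_MANUAL)
}

# Five-step chain on a single cube.
preprocess_cube <- function(cube, config, manual = NULL) {
  cube <- subtract_offset(cube, config)
  mask <- mask_saturated(cube, config)
  cube <- spatial_smooth(cube, mask, config)
  mask <- mask_low_snr(cube, mask, config)
  if (!is.null(manual)) mask <- apply_manual_mask(mask, manual)
  list(cube = cube, mask = mask)
}

#' Preprocess a paired lesion/healthy sample
#'
#' Applies, independently to the lesion and the healthy contralateral cube
#' and in this order: (1) per-pixel offset subtraction, (2) saturation
#' masking, (3) spatial smoothing over unmasked neighbors, (4) SNR masking,
#' (5) manual masking. The valid-pixel set shrinks monotonically across
#' steps.
#'
#' @param sample A `lesion_sample` (see [simulate_patient()]).
#' @param config A [preprocess_config()].
#' @param manual_masks Optional list with logical matrices `lesion` and/or
#'   `healthy`.
#' @return List with elements `lesion` and `healthy`, each a list
#'   `(cube, mask)`.
#' @export
preprocess_sample <- function(sample, config, manual_masks = NULL) {
  stopifnot(inherits(sample, "lesion_sample"),
            inherits(config, "preprocess_config"))
  out <- list(
    lesion = preprocess_cube(sample$lesion_cube, config,
                             manual_masks$lesion),
    healthy = preprocess_cube(sample$healthy_cube, config,
                              manual_masks$healthy))
  for (side in names(out))
    if (valid_count(out[[side]]$mask) < 1)
      stop("sample ", sample$patient_id, " unusable: no valid ", side,
           " pixels remain after preprocessing")
  out
}
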