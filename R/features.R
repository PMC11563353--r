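ABSOLUTE_FEATURES <- c("I390n", "I452n", "I500n",
                       "I390/I452", "I390/I500", "I452/I500",
                       "(I452+I500)/I390", "(I390+I500)/I452",
                       "(I390+I452)/I500")
RELATIVE_FEATURES <- paste0("d_", ABSOLUTE_FEATURES)
VELSCOPE_FEATURE <- "I452n+I500n"

#' Canonical spectral feature names
#'
#' The 18 per-pixel spectral intensity features in canonical order: the three
#' normalized band intensities, the six inter-band intensity ratios, and
#' their nine relative (`d_`-prefixed) counterparts, i.e. the lesion value
#' minus the median of the paired healthy map. This order is also the
#' tie-breaking order for feature ranking.
#'
#' @param pool `"absolute"`, `"relative"`, or `"both"`.
#' @return Character vector of feature names (9, 9 or 18).
#' @export
spectral_feature_names <- function(pool = c("both", "absolute", "relative")) {
  pool <- match.arg(pool)
  switch(pool,
         absolute = ABSOLUTE_FEATURES,
         relative = RELATIVE_FEATURES,
         both = c(ABSOLUTE_FEATURES, RELATIVE_FEATURES))
}

#' Per-pixel feature stack
#'
#' Named list of per-pixel feature maps sharing one validity mask. Masked
#' pixels carry `NA`.
#'
#' @param features Named list of numeric matrices (one per feature).
#' @param mask A [pixel_mask()].
#' @param meta Optional metadata list (e.g. total intensity map, patient id).
#' @return An object of class `feature_stack`.
#' @export
feature_stack <- function(features, mask, meta = list()) {
  stopifnot(is.list(features), length(features) >= 1,
            inherits(mask, "pixel_mask"))
  for (f in features) {
    stopifnot(is.matrix(f))
    if (!identical(dim(f), dim(mask$valid)))
      stop("feature map shape does not match mask shape")
  }
  features <- lapply(features, function(f) {
    f[!mask$valid] <- NA_real_
    f
  })
  structure(list(features = features, mask = mask,
                 feature_names = names(features), meta = meta),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("feature_stack: %d features, %d x %d pixels (%d valid)\n",
              length(x$features), nrow(x$mask$valid), ncol(x$mask$valid),
              valid_count(x$mask)))
  cat(paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

# Composite trapezoid weights for a uniform time grid.
trapezoid_weights <- function(n, dt) {
  w <- rep(dt, n)
  w[c(1, n)] <- dt / 2
  w
}

#' Integrated band intensities
#'
#' Numerically integrates each pixel's offset-subtracted decay trace over the
#' acquisition time window (composite trapezoid on the uniform grid), giving
#' the absolute band intensity I_lambda(x, y) in intensity x ns.
#'
#' @param cube Offset-subtracted [multispectral_cube()].
#' @param mask A [pixel_mask()]; masked pixels get `NA`.
#' @return Named list of per-band intensity matrices.
#' @export
integrate_intensity <- function(cube, mask = NULL) {
  stopifnot(inherits(cube, "multispectral_cube"))
  d <- dim(cube)
  if (is.null(mask)) mask <- empty_mask(d[1:2])
  w <- trapezoid_weights(d[3], cube$time_dt)
  lapply(cube$bands, function(a) {
    m <- matrix(matrix(a, d[1] * d[2], d[3]) %*% w, d[1], d[2])
    m[!mask$valid] <- NA_real_
    m
  })
}

# Pixels where any band integral is <= 0 cannot yield normalized intensities
# or ratios; they are masked with a dedicated reason code.
mask_nonpositive <- function(intensities, mask) {
  hit <- Reduce(`|`, lapply(intensities, function(m) {
    h <- m <= 0
    h[is.na(h)] <- FALSE
    h
  }))
  mask_update(mask, hit, MASK_NONPOS_INTENSITY)
}

#' Normalized band intensities
#'
#' I_lambda,n(x, y) = I_lambda(x, y) / sum over bands of I(x, y). The three
#' normalized maps lie in `[0, 1]` and sum to 1 at every valid pixel. Pixels
#' where any band integral is non-positive are masked
#' (reason `NONPOS_INTENSITY`).
#'
#' @param intensities Named list of band integral matrices
#'   (from [integrate_intensity()]).
#' @param mask A [pixel_mask()].
#' @return List with `maps` (three matrices named `I390n`, `I452n`, `I500n`)
#'   and the updated `mask`.
#' @export
normalize_intensity <- function(intensities, mask) {
  stopifnot(length(intensities) == 3)
  mask <- mask_nonpositive(intensities, mask)
  total <- Reduce(`+`, intensities)
  maps <- lapply(intensities, function(m) {
    r <- m / total
    r[!mask$valid] <- NA_real_
    r
  })
  names(maps) <- c("I390n", "I452n", "I500n")
  list(maps = maps, mask = mask)
}

#' Inter-band spectral intensity ratios
#'
#' The six ratios quantifying relative intensities between the collagen
#' (390 nm), NADH (452 nm) and FAD (>500 nm) emission channels, in canonical
#' order: I390/I452, I390/I500, I452/I500 (the optical redox ratio),
#' (I452+I500)/I390, (I390+I500)/I452, (I390+I452)/I500.
#'
#' @inheritParams normalize_intensity
#' @return List with `maps` (six matrices) and the updated `mask`.
#' @export
spectral_ratios <- function(intensities, mask) {
  stopifnot(length(intensities) == 3)
  mask <- mask_nonpositive(intensities, mask)
  i390 <- intensities[[1]]; i452 <- intensities[[2]]; i500 <- intensities[[3]]
  maps <- list(
    "I390/I452" = i390 / i452,
    "I390/I500" = i390 / i500,
    "I452/I500" = i452 / i500,
    "(I452+I500)/I390" = (i452 + i500) / i390,
    "(I390+I500)/I452" = (i390 + i500) / i452,
    "(I390+I452)/I500" = (i390 + i452) / i500)
  maps <- lapply(maps, function(m) {
    m[!mask$valid] <- NA_real_
    m
  })
  list(maps = maps, mask = mask)
}

#' Healthy-tissue reference medians
#'
#' Per absolute feature, the median over valid pixels of the healthy
#' contralateral feature map. These medians anchor the relative (`d_`)
#' features of the paired lesion image.
#'
#' @param healthy_stack A [feature_stack()] with the 9 absolute features.
#' @return Object of class `healthy_reference`: named numeric vector of
#'   medians.
#' @export
healthy_reference <- function(healthy_stack) {
  stopifnot(inherits(healthy_stack, "feature_stack"))
  if (valid_count(healthy_stack$mask) < 1)
    stop("healthy reference undefined: no valid pixels")
  med <- vapply(healthy_stack$features,
                function(m) stats::median(m[healthy_stack$mask$valid]),
                numeric(1))
  structure(med, class = "healthy_reference")
}

#' Relative feature maps
#'
#' d_f(x, y) = f(x, y) - median of the paired healthy map of f, for each of
#' the nine absolute features: the lesion feature distribution normalized to
#' its patient's own healthy baseline.
#'
#' @param lesion_features Named list of the lesion's 9 absolute feature maps.
#' @param ref A [healthy_reference()].
#' @return Named list of 9 `d_`-prefixed matrices.
#' @export
relative_features <- function(lesion_features, ref) {
  stopifnot(inherits(ref, "healthy_reference"))
  missing <- setdiff(names(lesion_features), names(ref))
  if (length(missing) > 0)
    stop("healthy reference missing features: ",
         paste(missing, collapse = ", "))
  out <- lapply(names(lesion_features), function(f)
    lesion_features[[f]] - ref[[f]])
  names(out) <- paste0("d_", names(lesion_features))
  out
}

# The 9 absolute feature maps plus updated mask for one preprocessed cube.
absolute_feature_maps <- function(prep) {
  ints <- integrate_intensity(prep$cube, prep$mask)
  norm <- normalize_intensity(ints, prep$mask)
  rat <- spectral_ratios(ints, norm$mask)
  total <- Reduce(`+`, ints)
  list(maps = c(norm$maps, rat$maps), mask = rat$mask, total = total)
}

#' Build lesion and healthy feature stacks for one sample
#'
#' From a preprocessed lesion/healthy pair, computes the healthy stack (9
#' absolute features, used only for the reference medians) and the lesion
#' stack (9 absolute + 9 relative features, 18 in total, sharing one mask).
#'
#' @param prep Output of [preprocess_sample()].
#' @param meta Optional metadata stored on the lesion stack.
#' @return List with `lesion` (18-feature [feature_stack()]), `healthy`
#'   (9-feature stack) and `reference` (a [healthy_reference()]).
#' @export
build_feature_stacks <- function(prep, meta = list()) {
  ha <- absolute_feature_maps(prep$healthy)
  healthy_stack <- feature_stack(ha$maps, ha$mask,
                                 meta = list(total_intensity = ha$total))
  ref <- healthy_reference(healthy_stack)

  la <- absolute_feature_maps(prep$lesion)
  rel <- relative_features(la$maps, ref)
  meta$total_intensity <- la$total
  lesion_stack <- feature_stack(c(la$maps, rel), la$mask, meta = meta)
  stopifnot(identical(lesion_stack$feature_names, spectral_feature_names()))
  list(lesion = lesion_stack, healthy = healthy_stack, reference = ref)
}

#' Single-feature stack simulating a blue-excitation adjunct
#'
#' Derives the combined normalized NADH + FAD band intensity
#' `I452,n + I500,n` (algebraically `1 - I390,n`) from a lesion feature
#' stack. This single feature emulates the pale-green autofluorescence
#' emission visualized by blue-excitation screening adjuncts such as the
#' VELscope, and serves as the baseline model.
#'
#' @param stack A lesion [feature_stack()] containing `I452n` and `I500n`.
#' @return A single-feature [feature_stack()] named `I452n+I500n`.
#' @export
velscope_stack <- function(stack) {
  stopifnot(inherits(stack, "feature_stack"),
            all(c("I452n", "I500n") %in% stack$feature_names))
  maps <- list(stack$features[["I452n"]] + stack$features[["I500n"]])
  names(maps) <- VELSCOPE_FEATURE
  feature_stack(maps, stack$mask, meta = stack$meta)
}
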