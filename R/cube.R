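# Mask reason codes, in step order; first cause encountered wins.
MASK_OK <- 0L
MASK_SATURATED <- 1L
MASK_LOW_SNR <- 2L
MASK_MANUAL <- 3L
MASK_NONPOS_INTENSITY <- 4L

#' Mask reason codes
#'
#' Integer codes used in the `reason` matrix of a [pixel_mask()]: `OK` (0),
#' `SATURATED` (1), `LOW_SNR` (2), `MANUAL` (3), `NONPOS_INTENSITY` (4).
#' A pixel is valid iff its reason is `OK`; once masked, later preprocessing
#' steps never unmask it, and the reason records the first cause encountered
#' in step order.
#'
#' @return Named integer vector of reason codes.
#' @export
mask_reasons <- function() {
  c(OK = MASK_OK, SATURATED = MASK_SATURATED, LOW_SNR = MASK_LOW_SNR,
    MANUAL = MASK_MANUAL, NONPOS_INTENSITY = MASK_NONPOS_INTENSITY)
}

#' Multispectral decay image cube
#'
#' Container for decay-resolved fluorescence images: one `rows x cols x
#' n_samples` array per emission band, all bands sharing the image grid and
#' a uniform time axis. Intensities are in arbitrary detector units; the
#' time step `time_dt` is in nanoseconds.
#'
#' @param bands Named list of 3-d numeric arrays (`rows x cols x n_samples`),
#'   one per emission band, identical dimensions across bands.
#' @param time_dt Time step between decay samples, ns.
#' @param meta Optional list of acquisition metadata.
#'
#' @return An object of class `multispectral_cube`.
#' @export
multispectral_cube <- function(bands, time_dt, meta = list()) {
  stopifnot(is.list(bands), length(bands) >= 1, !is.null(names(bands)))
  dims <- lapply(bands, dim)
  d0 <- dims[[1]]
  if (length(d0) != 3 || d0[3] < 2)
    stop("each band must be a rows x cols x n_samples array with n_samples >= 2")
  for (d in dims)
    if (!identical(d, d0)) stop("all bands must share shape and time axis")
  if (!is.numeric(time_dt) || length(time_dt) != 1 || time_dt <= 0)
    stop("time_dt must be a positive scalar (ns)")
  structure(list(bands = bands, time_dt = time_dt, meta = meta),
            class = "multispectral_cube")
}

#' @export
dim.multispectral_cube <- function(x) dim(x$bands[[1]])

band_labels <- function(cube) names(cube$bands)

image_shape <- function(cube) dim(cube)[1:2]

n_time_samples <- function(cube) dim(cube)[3]

#' @export
print.multispectral_cube <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("multispectral_cube: %d x %d pixels, %d time samples (dt = %g ns)\n",
              d[1], d[2], d[3], x$time_dt))
  cat("bands:", paste(band_labels(x), collapse = ", "), "\n")
  invisible(x)
}

#' Pixel validity mask
#'
#' Boolean validity map with a per-pixel reason code. The invariant
#' `valid[i, j] == (reason[i, j] == OK)` is enforced on construction.
#'
#' @param reason Integer matrix of codes from [mask_reasons()].
#'
#' @return An object of class `pixel_mask` with elements `valid` (logical
#'   matrix) and `reason` (integer matrix).
#' @export
pixel_mask <- function(reason) {
  stopifnot(is.matrix(reason))
  reason <- matrix(as.integer(reason), nrow(reason), ncol(reason))
  if (any(!reason %in% mask_reasons()))
    stop("unknown mask reason code")
  structure(list(valid = reason == MASK_OK, reason = reason),
            class = "pixel_mask")
}

#' All-valid mask for a given image shape
#'
#' @param shape Integer vector `c(rows, cols)`.
#' @return A [pixel_mask()] with every pixel valid.
#' @export
empty_mask <- function(shape) {
  pixel_mask(matrix(MASK_OK, shape[1], shape[2]))
}

#' Mask additional pixels, preserving earlier reasons
#'
#' Monotone update: pixels already masked keep their original reason; fresh
#' pixels in `hit` receive `reason_code`. The valid set can only shrink.
#'
#' @param mask A [pixel_mask()].
#' @param hit Logical matrix of pixels failing the new criterion.
#' @param reason_code Code from [mask_reasons()] for freshly masked pixels.
#' @return Updated [pixel_mask()].
#' @export
mask_update <- function(mask, hit, reason_code) {
  stopifnot(inherits(mask, "pixel_mask"),
            identical(dim(hit), dim(mask$valid)))
  reason <- mask$reason
  fresh <- hit & mask$valid
  reason[fresh] <- as.integer(reason_code)
  pixel_mask(reason)
}

#' @export
print.pixel_mask <- function(x, ...) {
  tab <- table(factor(x$reason, levels = mask_reasons(),
                      labels = names(mask_reasons())))
  cat(sprintf("pixel_mask: %d x %d, %d valid\n",
              nrow(x$valid), ncol(x$valid), sum(x$valid)))
  print(tab)
  invisible(x)
}

#' Number of valid pixels in a mask
#' @param mask A [pixel_mask()].
#' @return Integer count.
#' @export
valid_count <- function(mask) sum(mask$valid)
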