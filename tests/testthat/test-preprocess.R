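const_cube <- function(value, shape = c(4, 4), nt = 32, dt = 0.5) {
  a <- array(value, dim = c(shape, nt))
  multispectral_cube(list(I390 = a, I452 = a, I500 = a), time_dt = dt)
}

test_that("offset subtraction is exact on pure-offset and pre-pulse traces", {
  cfg <- preprocess_config(baseline_samples = 8)
  # constant trace of value c -> all zero
  out <- subtract_offset(const_cube(3.7), cfg)
  expect_equal(max(abs(out$bands[[1]])), 0)

  # exp decay + known offset, estimated from the pre-pulse region
  nt <- 64; dt <- 0.5; c0 <- 12.5
  t <- (0:(nt - 1)) * dt
  trace <- ifelse(t < 8 * dt, 0, exp(-(t - 8 * dt) / 5)) + c0
  a <- array(rep(trace, each = 16), dim = c(4, 4, nt))
  cube <- multispectral_cube(list(I390 = a, I452 = a, I500 = a), dt)
  out <- subtract_offset(cube, cfg)
  residual <- mean(out$bands[[1]][1, 1, 1:8])
  expect_lt(abs(residual), 1e-9)

  # idempotent when the baseline region is pure offset
  out2 <- subtract_offset(out, cfg)
  expect_equal(out2$bands, out$bands, tolerance = 1e-12)

  expect_error(subtract_offset(const_cube(1, nt = 8),
                               preprocess_config(baseline_samples = 8)),
               "baseline_samples")
})

test_that("saturation masking catches exactly the clipped pixels, any band", {
  cube <- const_cube(1, shape = c(6, 6), nt = 16)
  cfg <- preprocess_config(saturation_threshold = 100)
  m <- mask_saturated(cube, cfg)
  expect_true(all(m$valid))

  # plant k clipped pixels, one of them clipped in a single band only
  planted <- c(3L, 17L, 30L)
  b <- cube$bands
  for (i in planted[1:2]) for (nm in names(b)) b[[nm]][arrayInd(i, c(6, 6))[1],
                                                       arrayInd(i, c(6, 6))[2], 5] <- 100
  b[["I452"]][cbind(arrayInd(planted[3], c(6, 6)), 5)] <- 100  # one band only
  cube2 <- multispectral_cube(b, cube$time_dt)
  m2 <- mask_saturated(cube2, cfg)
  expect_identical(sort(which(!m2$valid)), sort(planted))
  expect_true(all(m2$reason[!m2$valid] == mask_reasons()[["SATURATED"]]))

  expect_error(mask_saturated(cube, preprocess_config(saturation_threshold = -1)),
               "positive")
})

test_that("spatial smoothing: constants, isolated pixels, ramps, variance", {
  cfg <- preprocess_config(smoothing_kernel = 5, saturation_threshold = Inf)

  cube <- const_cube(2.5, shape = c(8, 8))
  sm <- spatial_smooth(cube, empty_mask(c(8, 8)), cfg)
  expect_equal(sm$bands, cube$bands, tolerance = 1e-12)

  # single unmasked pixel surrounded by masked pixels stays unchanged
  reason <- matrix(mask_reasons()[["MANUAL"]], 8, 8)
  reason[4, 4] <- mask_reasons()[["OK"]]
  lone <- pixel_mask(reason)
  noisy <- const_cube(0, shape = c(8, 8))
  noisy$bands[[1]][] <- seq_len(length(noisy$bands[[1]]))
  sm2 <- spatial_smooth(noisy, lone, cfg)
  expect_equal(sm2$bands[[1]][4, 4, ], noisy$bands[[1]][4, 4, ])

  # linear ramp: interior pixels are fixed points of a symmetric box mean
  ramp <- outer(1:12, 1:12, function(i, j) 2 * i + 3 * j)
  a <- array(rep(ramp, 4), dim = c(12, 12, 4))
  cube3 <- multispectral_cube(list(I390 = a, I452 = a, I500 = a), 0.5)
  sm3 <- spatial_smooth(cube3, empty_mask(c(12, 12)), cfg)
  interior <- 3:10
  expect_lt(max(abs(sm3$bands[[1]][interior, interior, ] -
                      a[interior, interior, ])), 1e-9)

  # white noise: 5x5 full-interior kernel cuts variance ~25-fold
  ratios <- sapply(1:10, function(sd) {
    set.seed(sd)
    a <- array(rnorm(24 * 24 * 2), dim = c(24, 24, 2))
    cube <- multispectral_cube(list(I390 = a, I452 = a, I500 = a), 0.5)
    sm <- spatial_smooth(cube, empty_mask(c(24, 24)), cfg)
    var(as.vector(a[5:20, 5:20, ])) / var(as.vector(sm$bands[[1]][5:20, 5:20, ]))
  })
  expect_gt(mean(ratios), 25 * 0.8)
  expect_lt(mean(ratios), 25 * 1.2)
})

test_that("SNR masking follows 20*log10(peak/sigma) with degenerate rules", {
  nt <- 32
  base <- rep(c(1, -1), 4)           # leading 8 samples, sd sqrt(8/7)
  sigma <- sd(base)
  make_trace <- function(peak) c(base, rep(0, 8), peak, rep(0, nt - 17))
  traces <- cbind(make_trace(10 * sigma),   # 20 dB -> kept
                  make_trace(5 * sigma),    # 13.98 dB -> masked
                  rep(0, nt))               # sigma = 0 -> kept
  a <- array(0, dim = c(3, 1, nt))
  for (i in 1:3) a[i, 1, ] <- traces[, i]
  cube <- multispectral_cube(list(I390 = a, I452 = a, I500 = a), 0.5)
  cfg <- preprocess_config(snr_threshold_db = 15, baseline_samples = 8)
  m <- mask_low_snr(cube, empty_mask(c(3, 1)), cfg)
  expect_identical(as.vector(m$valid), c(TRUE, FALSE, TRUE))
  expect_equal(m$reason[2, 1], mask_reasons()[["LOW_SNR"]])
})

test_that("manual masking is monotone and first-reason-wins", {
  reason <- matrix(mask_reasons()[["OK"]], 5, 5)
  reason[1, 1] <- mask_reasons()[["SATURATED"]]
  m <- pixel_mask(reason)

  m_id <- apply_manual_mask(m, matrix(FALSE, 5, 5))
  expect_identical(m_id$reason, m$reason)

  manual <- matrix(FALSE, 5, 5)
  manual[1, 1] <- TRUE   # already saturated: reason must not change
  manual[2, 2] <- TRUE
  manual[3, 3] <- TRUE
  m2 <- apply_manual_mask(m, manual)
  expect_equal(m2$reason[1, 1], mask_reasons()[["SATURATED"]])
  expect_equal(m2$reason[2, 2], mask_reasons()[["MANUAL"]])
  expect_equal(valid_count(m) - valid_count(m2), 2)

  expect_error(apply_manual_mask(m, matrix(FALSE, 4, 4)), "shape")
})

test_that("full preprocessing masks the planted artifact union, monotonically", {
  cfg <- small_sim_config(n_patients = 1, image_shape = c(16, 16),
                          saturation_fraction = 0.05, seed = 21)
  s <- simulate_patient(cfg, 1)
  planted_sat <- s$lesion_cube$meta$saturated_pixels
  expect_gt(length(planted_sat), 0)

  pcfg <- auto_preprocess_config(cfg)
  cube <- subtract_offset(s$lesion_cube, pcfg)
  m1 <- mask_saturated(cube, pcfg)
  expect_identical(which(!m1$valid), planted_sat)

  cube <- spatial_smooth(cube, m1, pcfg)
  m2 <- mask_low_snr(cube, m1, pcfg)
  manual <- matrix(FALSE, 16, 16); manual[1, ] <- TRUE
  m3 <- apply_manual_mask(m2, manual)
  # monotone: valid sets only shrink across steps
  expect_true(all(m2$valid[!m1$valid] == FALSE))
  expect_true(all(m3$valid[!m2$valid] == FALSE))

  # noise-free, offset-free, unsaturated cube: nothing masked
  ccfg <- clean_sim_config(n_patients = 1, seed = 3)
  cs <- simulate_patient(ccfg, 1)
  prep <- preprocess_sample(cs, auto_preprocess_config(ccfg))
  expect_equal(valid_count(prep$lesion$mask), 16 * 16)

  # unusable sample: everything manually masked
  expect_error(preprocess_sample(cs, auto_preprocess_config(ccfg),
                                 manual_masks = list(
                                   lesion = matrix(TRUE, 16, 16))),
               "unusable")
})
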