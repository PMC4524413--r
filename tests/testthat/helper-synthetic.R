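# Shared fixture builders.  All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write.

# Gaussian ion trace as a feature
gaussian_feature <- function(id = "f1", mz = 200, rt = 100, sigma = 5,
                             apex = 1e4, from = rt - 4 * sigma,
                             to = rt + 4 * sigma, by = 1,
                             ion_mode = "positive") {
  times <- seq(from, to, by = by)
  feature(id, mz, times, apex * exp(-(times - rt)^2 / (2 * sigma^2)),
          ion_mode = ion_mode)
}

# centroided sample with one scan per time point; peaks is a list of
# (mz, rt, sigma, apex)
trace_sample <- function(peaks, times = seq(0, 200), id = "s1",
                         ion_mode = "positive") {
  scans <- lapply(seq_along(times), function(i) {
    mz <- numeric(); int <- numeric()
    for (p in peaks) {
      y <- p$apex * exp(-(times[i] - p$rt)^2 / (2 * p$sigma^2))
      if (y >= 1) {
        mz <- c(mz, p$mz)
        int <- c(int, y)
      }
    }
    ms_scan(i - 1L, times[i], mz, int, ion_mode = ion_mode)
  })
  lcms_sample(id, scans)
}

# profile-mode scan: Gaussian peaks sampled on a uniform m/z grid
profile_scan <- function(peak_mz, peak_int, mz_from, mz_to, spacing,
                         sigma_mz, index = 0L, rt = 0) {
  grid <- seq(mz_from, mz_to, by = spacing)
  y <- rep(0, length(grid))
  for (j in seq_along(peak_mz)) {
    y <- y + peak_int[j] * exp(-(grid - peak_mz[j])^2 / (2 * sigma_mz^2))
  }
  ms_scan(index, rt, grid, y, centroided = FALSE)
}

expect_feature_lists_equal <- function(a, b) {
  expect_equal(length(a), length(b))
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$times, b[[i]]$times)
    expect_identical(a[[i]]$intensities, b[[i]]$intensities)
    expect_identical(a[[i]]$mz, b[[i]]$mz)
  }
}
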