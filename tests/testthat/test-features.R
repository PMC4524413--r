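test_that("a noise-free compound becomes exactly one full-width feature", {
  smp <- trace_sample(list(list(mz = 400.2002, rt = 100, sigma = 10,
                                apex = 1e5)),
                      times = seq(60, 140, 1))
  fts <- extract_features(smp, trace_params(tol_ppm = 5))
  expect_length(fts, 1)
  expect_equal(feature_width_scans(fts[[1]]), 81)  # present in every scan
  expect_lt(abs(fts[[1]]$mz - 400.2002) / 400.2002 * 1e6, 5)
  expect_equal(fts[[1]]$rt, 100)
})

test_that("an empty sample yields no features", {
  smp <- lcms_sample("e", list(ms_scan(0, 0, numeric(), numeric())))
  expect_length(extract_features(smp), 0)
})

test_that("compounds 100 ppm apart stay separate at 5 ppm tolerance", {
  mz1 <- 400
  mz2 <- 400 * (1 + 100e-6)
  smp <- trace_sample(list(list(mz = mz1, rt = 100, sigma = 8, apex = 1e5),
                           list(mz = mz2, rt = 100, sigma = 8, apex = 8e4)),
                      times = seq(60, 140, 1))
  fts <- extract_features(smp, trace_params(tol_ppm = 5))
  expect_length(fts, 2)
  expect_lt(abs(fts[[1]]$mz - mz1), 0.01)
  expect_lt(abs(fts[[2]]$mz - mz2), 0.01)
})

test_that("profile scans are rejected with a centroiding hint", {
  s <- ms_scan(0, 0, c(1, 2, 3), c(1, 2, 1), centroided = FALSE)
  smp <- lcms_sample("p", list(s))
  expect_error(extract_features(smp), "centroid")
})

test_that("gap tolerance bridges missing scans, closing after the limit", {
  times <- seq(1, 20)
  scans <- lapply(seq_along(times), function(i) {
    # signal missing in scans 8 and 9 (one two-scan gap)
    if (times[i] %in% c(8, 9)) {
      ms_scan(i - 1L, times[i], numeric(), numeric())
    } else {
      ms_scan(i - 1L, times[i], 300.0, 1000 + 10 * i)
    }
  })
  smp <- lcms_sample("g", scans)
  expect_length(extract_features(smp, trace_params(max_gap_scans = 2)), 1)
  expect_length(extract_features(smp, trace_params(max_gap_scans = 1)), 2)
})

test_that("extraction ignores within-scan pair order", {
  mk <- function(perm) {
    scans <- lapply(1:10, function(i) {
      mzv <- c(200.0, 250.0, 300.0)[perm]
      iv <- (c(1000, 2000, 3000) * i)[perm]
      ms_scan(i - 1L, i, mzv, iv)
    })
    extract_features(lcms_sample("o", scans))
  }
  a <- mk(c(1, 2, 3))
  b <- mk(c(3, 1, 2))
  expect_feature_lists_equal(a, b)
})

test_that("single-apex traces come back unchanged from deconvolution", {
  f <- gaussian_feature("g", rt = 100, sigma = 6)
  out <- deconvolve(f)
  expect_length(out, 1)
  expect_identical(out[[1]]$times, f$times)
  expect_identical(out[[1]]$intensities, f$intensities)
})

test_that("resolved double peaks split; merged ones do not", {
  times <- seq(0, 120)
  two <- 1e4 * exp(-(times - 40)^2 / (2 * 5^2)) +
    8e3 * exp(-(times - 70)^2 / (2 * 5^2))
  f <- feature("two", 300, times, two)
  out <- deconvolve(f, deconvolution_params(valley_fraction = 0.5))
  expect_length(out, 2)
  expect_lt(abs(out[[1]]$rt - 40), 2)
  expect_lt(abs(out[[2]]$rt - 70), 2)
  # heavily overlapped: valley ~93% of the lower apex
  merged <- 1e4 * exp(-(times - 55)^2 / (2 * 8^2)) +
    9e3 * exp(-(times - 70)^2 / (2 * 8^2))
  fm <- feature("one", 300, times, merged)
  expect_length(deconvolve(fm, deconvolution_params(valley_fraction = 0.5)),
                1)
})

test_that("deconvolution conserves total raw intensity", {
  set.seed(41)
  for (i in 1:50) {
    times <- seq(0, 150)
    rt1 <- runif(1, 30, 60)
    rt2 <- rt1 + runif(1, 15, 60)
    s1 <- runif(1, 3, 8); s2 <- runif(1, 3, 8)
    y <- runif(1, 5e3, 5e4) * exp(-(times - rt1)^2 / (2 * s1^2)) +
      runif(1, 5e3, 5e4) * exp(-(times - rt2)^2 / (2 * s2^2)) +
      abs(rnorm(length(times), 0, 50))
    f <- feature("x", 250, times, y)
    parts <- deconvolve(f)
    expect_equal(sum(unlist(lapply(parts, `[[`, "intensities"))),
                 sum(f$intensities), tolerance = 1e-12)
    expect_equal(sum(vapply(parts, feature_width_scans, integer(1))),
                 feature_width_scans(f))
  }
})
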