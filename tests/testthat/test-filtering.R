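test_that("intensity threshold drops pairs below the cutoff, keeps scans", {
  smp <- lcms_sample("x", list(ms_scan(0, 0, c(100, 200), c(50, 150)),
                               ms_scan(1, 1, 300, 20)))
  expect_equal(intensity_threshold(smp, 0)$scans[[1]]$intensity, c(50, 150))
  out <- intensity_threshold(smp, 100)
  expect_equal(out$scans[[1]]$intensity, 150)
  expect_length(out$scans, 2)  # emptied scan retained
  expect_length(out$scans[[2]]$mz, 0)
  out <- intensity_threshold(smp, 1e9)
  expect_true(all(vapply(out$scans, function(s) length(s$mz) == 0,
                         logical(1))))
})

test_that("baseline correction recovers a Gaussian under a constant offset", {
  f0 <- gaussian_feature("g", rt = 100, sigma = 5, apex = 1e4,
                         from = 60, to = 140)
  offset <- feature("g", f0$mz, f0$times, f0$intensities + 2000,
                    ion_mode = "positive")
  corrected <- baseline_correct(offset)
  ratio <- feature_area(corrected) / feature_area(f0)
  expect_gte(ratio, 0.95)
  expect_lte(ratio, 1.05)
})

test_that("baseline correction leaves zero traces and short traces alone", {
  z <- feature("z", 100, 1:10, rep(0, 10))
  expect_equal(baseline_correct(z)$intensities, rep(0, 10))
  short <- feature("s", 100, 1:4, c(1, 5, 4, 2))
  expect_identical(baseline_correct(short)$intensities, short$intensities)
  bad <- feature("b", 100, 1:5, c(1, 2, 3, 2, 1))
  bad$intensities[2] <- NaN
  expect_error(baseline_correct(bad), "non-finite")
})

test_that("baseline correction under linear drift keeps the apex time", {
  f0 <- gaussian_feature("g", rt = 100, sigma = 5, apex = 1e4,
                         from = 60, to = 140)
  drift <- feature("g", f0$mz, f0$times, f0$intensities + 10 * f0$times,
                   ion_mode = "positive")
  corrected <- baseline_correct(drift)
  expect_equal(characteristic_rt(corrected$times, corrected$intensities),
               100)
})

test_that("range filter crops inclusively on all bounds", {
  smp <- lcms_sample("x", list(
    ms_scan(0, 10, c(100, 200, 300), c(1, 2, 3)),
    ms_scan(1, 20, c(150, 250), c(4, 5)),
    ms_scan(2, 30, 180, 6)))
  all_in <- range_filter(smp, range_filter_params(50, 400, 0, 100))
  expect_equal(length(all_in$scans), 3)
  none <- range_filter(smp, range_filter_params(50, 400, 500, 600))
  expect_length(none$scans, 0)
  # boundary values retained: mz == mz_max, rt == rt_min
  out <- range_filter(smp, range_filter_params(100, 200, 20, 30))
  expect_equal(length(out$scans), 2)
  expect_equal(out$scans[[1]]$mz, c(150, 200) [c(1, 2) %in%
                                                 which(c(150, 250) <= 200)])
  expect_true(200 %in% range_filter(
    smp, range_filter_params(100, 200, 0, 100))$scans[[1]]$mz)
})

test_that("scan width filter drops and recovers a 3-scan peak", {
  narrow <- feature("n", 100, c(1, 2, 3), c(1, 5, 1))
  wide <- gaussian_feature("w")
  expect_length(scan_width_filter(list(narrow, wide), 4), 1)   # removed
  expect_length(scan_width_filter(list(narrow, wide), 3), 2)   # retained
  fl <- list(narrow, wide)
  expect_equal(scan_width_filter(fl, 1), fl, ignore_attr = TRUE)
})

test_that("width filter output is monotone in min_scans", {
  set.seed(31)
  feats <- lapply(1:40, function(i) {
    n <- sample(1:12, 1)
    feature(paste0("f", i), runif(1, 100, 900),
            seq_len(n), runif(n, 1, 100))
  })
  ids <- function(x) vapply(x, `[[`, character(1), "id")
  for (k in 1:10) {
    a <- scan_width_filter(feats, k)
    b <- scan_width_filter(feats, k + 1)
    expect_true(all(ids(b) %in% ids(a)))
  }
})

test_that("exclusion filter removes contaminant masses within tolerance", {
  f1 <- gaussian_feature("phthalate", mz = 149.02332)
  f2 <- gaussian_feature("ok", mz = 149.03)  # ~45 ppm away
  expect_length(exclusion_filter(list(f1, f2), numeric(), 10), 2)
  out <- exclusion_filter(list(f1, f2), 149.02332, 10)
  expect_length(out, 1)
  expect_equal(out[[1]]$id, "ok")
})

test_that("filters are idempotent", {
  smp <- trace_sample(list(list(mz = 200, rt = 50, sigma = 5, apex = 1e4),
                           list(mz = 300, rt = 120, sigma = 5, apex = 50)),
                      times = seq(0, 200, 2))
  once <- intensity_threshold(smp, 100)
  twice <- intensity_threshold(once, 100)
  expect_identical(twice, once)
  p <- range_filter_params(150, 250, 10, 190)
  expect_identical(range_filter(range_filter(smp, p), p),
                   range_filter(smp, p))
  feats <- extract_features(smp, trace_params(min_intensity = 10))
  expect_identical(scan_width_filter(scan_width_filter(feats, 3), 3),
                   scan_width_filter(feats, 3))
  expect_identical(exclusion_filter(exclusion_filter(feats, 200, 10), 200, 10),
                   exclusion_filter(feats, 200, 10))
})
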