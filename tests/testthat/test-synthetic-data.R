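test_that("manifests enumerate one trace per adduct and isotopologue", {
  cp <- compound_spec("c1", 250.1, rt = 60, adducts = c("M+H", "M+Na"),
                      isotope_ratios = c(0.1, 0.01))
  out <- generate_sample(list(cp), noise_spec(chemical_noise_density = 0,
                                              seed = 1),
                         "positive", scan_interval = 2, duration = 120)
  expect_equal(nrow(out$truth), 2 * 3)
  expect_setequal(unique(out$truth$adduct), c("M+H", "M+Na"))
  expect_setequal(unique(out$truth$isotope), 0:2)
  mh0 <- out$truth[out$truth$adduct == "M+H" & out$truth$isotope == 0, ]
  expect_equal(mh0$mz, 250.1 + PROTON_MASS, tolerance = 1e-9)
})

test_that("identical seeds give byte-identical mzML files", {
  dir <- withr::local_tempdir()
  cp <- compound_spec("c1", 250.1, rt = 60)
  p1 <- file.path(dir, "a.mzML")
  p2 <- file.path(dir, "b.mzML")
  for (p in c(p1, p2)) {
    generate_sample(list(cp), noise_spec(seed = 99), "positive",
                    scan_interval = 2, duration = 120, path = p, id = "x")
  }
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  p3 <- file.path(dir, "c.mzML")
  generate_sample(list(cp), noise_spec(seed = 100), "positive",
                  scan_interval = 2, duration = 120, path = p3, id = "x")
  expect_false(identical(unname(tools::md5sum(p1)),
                         unname(tools::md5sum(p3))))
})

test_that("noise-free total ion current matches the analytic Gaussian sum", {
  cps <- list(compound_spec("a", 200, rt = 50, peak_sigma = 5,
                            apex_intensity = 1e4, adducts = "M+H",
                            isotope_ratios = c(0.1)),
              compound_spec("b", 300, rt = 80, peak_sigma = 8,
                            apex_intensity = 5e4, adducts = "M+H",
                            isotope_ratios = numeric()))
  ns <- noise_spec(chemical_noise_density = 0, baseline_drift = 0,
                   mz_jitter_ppm = 0, seed = 2)
  out <- generate_sample(cps, ns, "positive", scan_interval = 1,
                         duration = 120)
  tic <- sum(vapply(out$sample$scans, function(s) sum(s$intensity),
                    numeric(1)))
  times <- vapply(out$sample$scans, `[[`, numeric(1), "rt")
  analytic <- sum(vapply(seq_len(nrow(out$truth)), function(i) {
    r <- out$truth[i, ]
    sig <- if (r$compound == "a") 5 else 8
    sum(r$apex * exp(-(times - r$rt)^2 / (2 * sig^2)))
  }, numeric(1)))
  expect_equal(tic, analytic, tolerance = 0.01)
})

test_that("generated files satisfy the reader's scan invariants", {
  dir <- withr::local_tempdir()
  cp <- compound_spec("c1", 180.063, rt = 40, peak_sigma = 4,
                      adducts = "M-H")
  p <- file.path(dir, "inv.mzML")
  generate_sample(list(cp), noise_spec(seed = 4), "negative",
                  scan_interval = 2, duration = 80, path = p, id = "inv")
  smp <- read_mzml(p)
  rts <- vapply(smp$scans, `[[`, numeric(1), "rt")
  expect_false(is.unsorted(rts))
  for (s in smp$scans) {
    expect_false(is.unsorted(s$mz, strictly = TRUE))
    expect_true(all(s$intensity >= 0))
    expect_equal(s$ion_mode, "negative")
  }
})

test_that("the standards suite has the right composition and library", {
  dir <- withr::local_tempdir()
  suite <- generate_standards_suite(3, 2, 1, seed = 5, dir = dir,
                                    duration = 200)
  expect_equal(nrow(suite$library), 6)
  expect_equal(nrow(suite$runs), 3 + 2 + 2 * 1)
  expect_equal(sum(suite$runs$mode == "positive"), 4)
  expect_equal(sum(suite$runs$mode == "negative"), 3)
  expect_true(all(file.exists(suite$runs$path)))
  lib <- read_reference_library(suite$library_csv)
  expect_equal(nrow(lib), 6)
  expect_true(all(lib$neutral_mass >= 100 & lib$neutral_mass <= 600))
  expect_true(all(lib$expected_rt >= 60 & lib$expected_rt <= 900))
  empty <- generate_standards_suite(0, 0, 0, seed = 5,
                                    dir = file.path(dir, "empty"))
  expect_equal(nrow(empty$runs), 0)
  expect_equal(nrow(empty$library), 0)
})

test_that("the suite is deterministic under its seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- generate_standards_suite(2, 1, 0, seed = 6, dir = d1,
                                 duration = 150)
  s2 <- generate_standards_suite(2, 1, 0, seed = 6, dir = d2,
                                 duration = 150)
  expect_equal(s1$library, s2$library)
  for (i in seq_len(nrow(s1$runs))) {
    expect_identical(unname(tools::md5sum(s1$runs$path[i])),
                     unname(tools::md5sum(s2$runs$path[i])))
  }
})

test_that("profile rendering keeps stick intensity as the local maximum", {
  cp <- compound_spec("c1", 400, rt = 30, peak_sigma = 4,
                      apex_intensity = 2e4, adducts = "M+H",
                      isotope_ratios = numeric())
  ns <- noise_spec(chemical_noise_density = 0, mz_jitter_ppm = 0, seed = 7)
  out <- generate_sample(list(cp), ns, "positive", scan_interval = 1,
                         duration = 60, profile = TRUE)
  apex_scan <- out$sample$scans[[31]]
  expect_false(apex_scan$centroided)
  expect_gt(length(apex_scan$mz), 20)
  expect_equal(max(apex_scan$intensity), 2e4, tolerance = 1e-6)
  expect_lt(abs(apex_scan$mz[which.max(apex_scan$intensity)] -
                  (400 + PROTON_MASS)), 0.001)
})
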