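glc <- 180.06339
posrules <- default_adduct_rules("positive")

trio_set <- function(iso_ratio = 0.3, spacing = ISOTOPE_SPACING) {
  base <- gaussian_feature("mh", mz = 181.07066, rt = 100, apex = 1e5)
  iso <- feature("m1", 181.07066 + spacing, base$times,
                 iso_ratio * base$intensities, ion_mode = "positive")
  feature_set("fs", list(base, iso))
}

test_that("carbon-isotope spacing at z=1 is annotated M+1", {
  fs <- annotate_isotopes(trio_set(0.3))
  ann <- fs$features[[2]]$annotations
  expect_length(ann, 1)
  expect_equal(ann[[1]]$kind, "isotope")
  expect_equal(ann[[1]]$label, "M+1")
  expect_equal(ann[[1]]$partner_id, "mh")
  expect_equal(ann[[1]]$charge, 1)
  expect_gt(ann[[1]]$score, 0.99)
  expect_length(fs$features[[1]]$annotations, 0)
})

test_that("half spacing infers a doubly charged isotopologue", {
  fs <- annotate_isotopes(trio_set(0.3, spacing = ISOTOPE_SPACING / 2))
  ann <- fs$features[[2]]$annotations
  expect_length(ann, 1)
  expect_equal(ann[[1]]$label, "M+1")
  expect_equal(ann[[1]]$charge, 2)
})

test_that("the intensity ratio gate blocks implausible isotopes", {
  fs <- annotate_isotopes(trio_set(5.0))
  expect_length(fs$features[[2]]$annotations, 0)
})

test_that("isotope chains anchor at the lightest non-isotope feature", {
  base <- gaussian_feature("m0", mz = 300.1, rt = 100, apex = 1e5)
  i1 <- feature("m1", 300.1 + ISOTOPE_SPACING, base$times,
                0.2 * base$intensities, ion_mode = "positive")
  i2 <- feature("m2", 300.1 + 2 * ISOTOPE_SPACING, base$times,
                0.04 * base$intensities, ion_mode = "positive")
  fs <- annotate_isotopes(feature_set("fs", list(base, i1, i2)))
  labs <- lapply(fs$features, function(f) {
    vapply(f$annotations, `[[`, character(1), "label")
  })
  expect_equal(labs[[2]], "M+1")
  expect_equal(labs[[3]], "M+2")
  expect_equal(fs$features[[3]]$annotations[[1]]$partner_id, "m0")
})

test_that("M+H / M+Na pairs agree on the neutral mass", {
  mh <- gaussian_feature("mh", mz = 181.07066, rt = 100, apex = 1e5)
  mna <- feature("mna", 203.05261, mh$times, 0.5 * mh$intensities,
                 ion_mode = "positive")
  fs <- annotate_adducts(feature_set("fs", list(mh, mna)), posrules,
                         "positive")
  labs <- lapply(fs$features, feature_adduct_labels)
  expect_equal(labs[[1]], "M+H")
  expect_equal(labs[[2]], "M+Na")
  expect_lt(abs(fs$neutral_mass - glc) / glc * 1e6, 5)
})

test_that("no adduct annotation without a consistent partner", {
  lone <- feature_set("fs", list(gaussian_feature("a", mz = 181.07066)))
  expect_length(annotate_adducts(lone, posrules,
                                 "positive")$features[[1]]$annotations, 0)
  # implied neutral masses ~300 ppm apart
  f1 <- gaussian_feature("a", mz = 181.07066)
  f2 <- feature("b", 203.10, f1$times, f1$intensities,
                ion_mode = "positive")
  fs <- annotate_adducts(feature_set("fs", list(f1, f2)), posrules,
                         "positive", annotation_params(tol_ppm = 10))
  expect_length(fs$features[[1]]$annotations, 0)
  expect_null(fs$neutral_mass)
})

test_that("a mode without applicable rules warns and leaves the set", {
  fs <- trio_set()
  expect_warning(out <- annotate_adducts(fs, posrules, "negative"),
                 "no adduct rule")
  expect_identical(out$features, fs$features)
})

test_that("adduct transforms round-trip to machine precision", {
  rules <- rbind(default_adduct_rules("positive"),
                 default_adduct_rules("negative"))
  set.seed(61)
  masses <- runif(200, 50, 1500)
  for (r in seq_len(nrow(rules))) {
    rule <- rules[r, ]
    back <- adduct_neutral_mass(adduct_mz(masses, rule), rule)
    expect_equal(back, masses, tolerance = 1e-12)
  }
})

test_that("annotation preserves feature membership and order", {
  fs <- trio_set()
  ids <- vapply(fs$features, `[[`, character(1), "id")
  out <- annotate_adducts(annotate_isotopes(fs), posrules, "positive")
  expect_identical(vapply(out$features, `[[`, character(1), "id"), ids)
  expect_identical(lapply(out$features, `[[`, "intensities"),
                   lapply(fs$features, `[[`, "intensities"))
})

test_that("reference matching respects mass, rt and mode gates", {
  lib <- data.frame(name = "glucose", neutral_mass = glc,
                    expected_rt = 100, ion_modes = "positive",
                    stringsAsFactors = FALSE)
  mh <- gaussian_feature("mh", mz = 181.07066, rt = 100, apex = 1e5)
  sets <- list(feature_set("fs1", list(mh)))
  res <- match_reference(sets, lib, posrules, "positive",
                         tol_ppm = 10, rt_tol = 10)
  expect_equal(nrow(res$matches), 1)
  expect_equal(res$matches$compound, "glucose")
  expect_equal(res$matches$rule, "M+H")
  expect_lt(abs(res$matches$mz_error_ppm), 5)
  idents <- Filter(function(a) a$kind == "identity",
                   res$feature_sets[[1]]$features[[1]]$annotations)
  expect_length(idents, 1)
  expect_equal(idents[[1]]$label, "glucose")
  # rt off by 3x the tolerance: no match
  lib2 <- transform(lib, expected_rt = 130)
  expect_equal(nrow(match_reference(sets, lib2, posrules, "positive",
                                    tol_ppm = 10, rt_tol = 10)$matches), 0)
  # absent expected rt matches on mass alone
  lib3 <- transform(lib, expected_rt = NA_real_)
  expect_equal(nrow(match_reference(sets, lib3, posrules, "positive",
                                    tol_ppm = 10, rt_tol = 10)$matches), 1)
  expect_equal(nrow(match_reference(list(), lib, posrules, "positive")$matches),
               0)
})

test_that("main peak: adduct label wins, then apex, then lowest m/z", {
  mh <- gaussian_feature("mh", mz = 181.07066, rt = 100, apex = 5e4)
  mna <- feature("mna", 203.05261, mh$times, 2 * mh$intensities,
                 ion_mode = "positive")
  fs <- annotate_adducts(feature_set("fs", list(mh, mna)), posrules,
                         "positive")
  expect_equal(main_peak(fs, "positive")$id, "mh")  # label beats intensity
  # unannotated: intensity argmax
  fs2 <- feature_set("fs", list(mh, mna))
  expect_equal(main_peak(fs2, "positive")$id, "mna")
  # equal intensity: lower m/z
  eq1 <- gaussian_feature("lo", mz = 150, apex = 1e4)
  eq2 <- feature("hi", 250, eq1$times, eq1$intensities,
                 ion_mode = "positive")
  expect_equal(main_peak(feature_set("fs", list(eq1, eq2)),
                         "positive")$id, "lo")
})

test_that("a full synthetic standard annotates M+H, M+Na and M+1 cleanly", {
  set.seed(62)
  n_ok <- 0L
  for (i in 1:100) {
    m <- runif(1, 100, 600)
    rt <- runif(1, 60, 900)
    apex <- 10^runif(1, 4, 5.5)
    times <- seq(rt - 20, rt + 20)
    shape <- exp(-(times - rt)^2 / (2 * 6^2))
    r1 <- min(1, 0.011 * round(m / 14))
    mh <- feature("mh", m + PROTON_MASS, times, apex * shape,
                  ion_mode = "positive")
    m1 <- feature("m1", m + PROTON_MASS + ISOTOPE_SPACING, times,
                  r1 * apex * shape, ion_mode = "positive")
    mna <- feature("mna", m + 22.98922, times, 0.4 * apex * shape,
                   ion_mode = "positive")
    fs <- feature_set("fs", list(mh, m1, mna))
    fs <- annotate_adducts(annotate_isotopes(fs), posrules, "positive")
    lab <- function(id) {
      f <- Filter(function(x) x$id == id, fs$features)[[1]]
      sort(vapply(f$annotations, `[[`, character(1), "label"))
    }
    ok <- identical(lab("m1"), "M+1") &&
      identical(lab("mh"), "M+H") &&
      identical(lab("mna"), "M+Na") &&
      abs(fs$neutral_mass - m) / m * 1e6 < 5
    n_ok <- n_ok + ok
  }
  expect_equal(n_ok, 100L)
})
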