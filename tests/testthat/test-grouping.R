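test_that("profile inner product: identity, disjoint, and exact cosine", {
  f <- gaussian_feature("a")
  expect_equal(profile_inner_product(f, f), 1)
  g1 <- gaussian_feature("b", rt = 100, from = 80, to = 120)
  g2 <- gaussian_feature("c", rt = 300, from = 280, to = 320)
  expect_equal(profile_inner_product(g1, g2), 0)
  # [1,2] vs [2,1] on a shared 2-point grid: cosine = 4/5
  a <- feature("x", 100, c(0, 1), c(1, 2))
  b <- feature("y", 100, c(0, 1), c(2, 1))
  expect_equal(profile_inner_product(a, b), 0.8)
  # all-zero trace
  z <- feature("z", 100, c(0, 1), c(0, 0))
  expect_equal(profile_inner_product(a, z), 0)
})

test_that("inner product is symmetric, bounded, maximal for multiples", {
  set.seed(51)
  for (i in 1:30) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    f1 <- feature("a", 100, sort(runif(n1, 0, 50)), runif(n1, 0, 100))
    f2 <- feature("b", 100, sort(runif(n2, 20, 70)), runif(n2, 0, 100))
    p12 <- profile_inner_product(f1, f2)
    expect_equal(p12, profile_inner_product(f2, f1))
    expect_gte(p12, 0)
    expect_lte(p12, 1)
  }
  f <- gaussian_feature("a")
  f3 <- feature("c", f$mz, f$times, 3.7 * f$intensities)
  expect_equal(profile_inner_product(f, f3), 1)
})

test_that("an adduct/isotope trio with shared elution forms one set", {
  base <- gaussian_feature("mh", mz = 181.0707, rt = 100, apex = 1e5)
  iso <- feature("m1", 182.0741, base$times, 0.07 * base$intensities,
                 ion_mode = "positive")
  na <- feature("mna", 203.0526, base$times, 0.6 * base$intensities,
                ion_mode = "positive")
  sets <- group_features(list(base, iso, na))
  expect_length(sets, 1)
  expect_length(sets[[1]]$features, 3)
  expect_equal(sets[[1]]$rt, 100)
})

test_that("compounds a minute apart become singleton sets", {
  f1 <- gaussian_feature("a", rt = 100)
  f2 <- gaussian_feature("b", mz = 300, rt = 160)
  sets <- group_features(list(f1, f2), grouping_params(rt_tol = 5))
  expect_length(sets, 2)
  expect_true(all(vapply(sets, function(s) length(s$features), integer(1))
                  == 1))
  expect_length(group_features(list()), 0)
})

test_that("mixed ion modes are rejected", {
  f1 <- gaussian_feature("a", ion_mode = "positive")
  f2 <- gaussian_feature("b", ion_mode = "negative")
  expect_error(group_features(list(f1, f2)), "ion mode")
})

test_that("grouping partitions the input", {
  set.seed(52)
  feats <- lapply(seq_len(300), function(i) {
    rt <- runif(1, 0, 900)
    sig <- runif(1, 3, 10)
    gaussian_feature(paste0("f", i), mz = runif(1, 100, 900), rt = rt,
                     sigma = sig, apex = 10^runif(1, 3, 5))
  })
  sets <- group_features(feats, grouping_params(rt_tol = 5,
                                                min_similarity = 0.9))
  ids_out <- sort(unlist(lapply(sets, function(s) {
    vapply(s$features, `[[`, character(1), "id")
  })))
  expect_identical(ids_out, sort(vapply(feats, `[[`, character(1), "id")))
  expect_equal(sum(vapply(sets, function(s) length(s$features),
                          integer(1))), length(feats))
  for (s in sets) {
    expect_equal(s$rt, mean(vapply(s$features, `[[`, numeric(1), "rt")),
                 tolerance = 1e-9)
  }
})

test_that("raising min_similarity only refines the partition", {
  set.seed(53)
  feats <- lapply(seq_len(60), function(i) {
    gaussian_feature(paste0("f", i), mz = runif(1, 100, 900),
                     rt = runif(1, 0, 100), sigma = runif(1, 3, 10))
  })
  part <- function(ms) {
    sets <- group_features(feats, grouping_params(rt_tol = 10,
                                                  min_similarity = ms))
    lapply(sets, function(s) sort(vapply(s$features, `[[`, character(1),
                                         "id")))
  }
  loose <- part(0.5)
  strict <- part(0.95)
  # every strict set is contained in some loose set
  for (s in strict) {
    expect_true(any(vapply(loose, function(l) all(s %in% l), logical(1))))
  }
})
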