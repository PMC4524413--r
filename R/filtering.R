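# Scan- and feature-level cleanup: intensity thresholding, asymmetric
# least squares baseline correction, m/z / retention-time cropping, scan
# width filtering, and contaminant exclusion.

#' Remove low-intensity pairs from every scan
#'
#' Pairs with intensity strictly below `min_intensity` are dropped; scans
#' are retained even if emptied, so scan numbering and retention times are
#' unchanged.
#'
#' @param sample an [lcms_sample()]
#' @param min_intensity counts threshold (>= 0)
#' @return filtered sample
#' @export
intensity_threshold <- function(sample, min_intensity) {
  stopifnot(inherits(sample, "lcms_sample"), min_intensity >= 0)
  scans <- lapply(sample$scans, function(s) {
    keep <- s$intensity >= min_intensity
    ms_scan(s$index, s$rt, s$mz[keep], s$intensity[keep], s$ms_level,
         s$ion_mode, s$precursor_mz, s$centroided)
  })
  lcms_sample(sample$id, scans, sample$metadata)
}

# Asymmetric least squares smoother: minimises
#   sum_i w_i (y_i - z_i)^2 + lambda * sum_i (second difference of z)^2
# with w_i = p where y_i > z_i (signal points barely pull the baseline up)
# and 1 - p below.  Traces are short, so the banded system is solved
# directly with a sparse Cholesky factorisation.
als_baseline <- function(y, p, lambda, max_iter = 20L, tol = 1e-6) {
  n <- length(y)
  d2 <- diff(diag(n), differences = 2L)
  penalty <- lambda * Matrix::Matrix(crossprod(d2), sparse = TRUE)
  w <- rep(1, n)
  z <- y
  for (iter in seq_len(max_iter)) {
    lhs <- penalty + Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(lhs, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (mean(abs(w_new - w)) < tol) {
      w <- w_new
      break
    }
    w <- w_new
  }
  z
}

#' Baseline-correct a feature trace
#'
#' Subtracts an asymmetric-least-squares baseline from the intensity
#' vector: a penalised smoother whose weights are `asymmetry` above the
#' baseline and `1 - asymmetry` below, iterated to convergence.  Residual
#' negative intensities are clamped to zero.  Features narrower than 5
#' scans pass through unchanged (too few points to estimate a baseline).
#'
#' @param f an [feature()] object
#' @param asymmetry weight for points above the baseline, in (0, 1);
#'   small values let peaks stand above the estimated baseline
#' @param smoothness second-difference penalty weight (> 0); larger values
#'   give stiffer baselines
#' @return corrected feature with identical times and characteristic rt
#' @export
baseline_correct <- function(f, asymmetry = 0.01, smoothness = 1e4) {
  stopifnot(inherits(f, "lcms_feature"),
            asymmetry > 0, asymmetry < 1, smoothness > 0)
  if (any(!is.finite(f$intensities))) {
    stop("non-finite intensities in feature ", f$id, call. = FALSE)
  }
  if (feature_width_scans(f) < 5L) return(f)
  z <- als_baseline(f$intensities, asymmetry, smoothness)
  corrected <- pmax(f$intensities - z, 0)
  feature(f$id, f$mz, f$times, corrected, rt = f$rt,
          ion_mode = f$ion_mode, annotations = f$annotations)
}

#' m/z and retention-time crop window
#' @param mz_min,mz_max m/z bounds in Thomson (`mz_min < mz_max`)
#' @param rt_min,rt_max retention-time bounds in seconds (`rt_min < rt_max`)
#' @return list of class `range_filter_params`
#' @export
range_filter_params <- function(mz_min = 0, mz_max = Inf,
                                rt_min = 0, rt_max = Inf) {
  stopifnot(mz_min < mz_max, rt_min < rt_max)
  structure(list(mz_min = mz_min, mz_max = mz_max,
                 rt_min = rt_min, rt_max = rt_max),
            class = "range_filter_params")
}

#' Crop a sample to an m/z and retention-time window
#'
#' Scans with retention time outside `[rt_min, rt_max]` are dropped; pairs
#' with m/z outside `[mz_min, mz_max]` are dropped.  All bounds are
#' inclusive.
#'
#' @param sample an [lcms_sample()]
#' @param params a [range_filter_params()] object
#' @return cropped sample
#' @export
range_filter <- function(sample, params = range_filter_params()) {
  stopifnot(inherits(sample, "lcms_sample"),
            inherits(params, "range_filter_params"))
  kept <- Filter(function(s) s$rt >= params$rt_min & s$rt <= params$rt_max,
                 sample$scans)
  scans <- lapply(kept, function(s) {
    keep <- s$mz >= params$mz_min & s$mz <= params$mz_max
    ms_scan(s$index, s$rt, s$mz[keep], s$intensity[keep], s$ms_level,
         s$ion_mode, s$precursor_mz, s$centroided)
  })
  lcms_sample(sample$id, scans, sample$metadata)
}

#' Drop features narrower than a minimum number of scans
#'
#' Chromatographic peaks spanning very few scans are usually noise spikes,
#' but genuinely sharp peaks can be lost too -- re-running this step with a
#' smaller `min_scans` recovers them.
#'
#' @param features list of [feature()] objects
#' @param min_scans minimum trace width in scans (>= 1)
#' @return filtered list, input order preserved
#' @export
scan_width_filter <- function(features, min_scans) {
  stopifnot(min_scans >= 1)
  out <- Filter(function(f) feature_width_scans(f) >= min_scans, features)
  attr(out, "cell_kind") <- "features"
  out
}

#' Drop features matching an exclusion mass list
#'
#' Removes features whose characteristic m/z lies within `tol_ppm` of any
#' contaminant mass.
#'
#' @param features list of [feature()] objects
#' @param masses numeric vector of contaminant m/z values
#' @param tol_ppm relative tolerance in ppm (> 0)
#' @return filtered list, input order preserved
#' @export
exclusion_filter <- function(features, masses, tol_ppm = 10) {
  stopifnot(tol_ppm > 0)
  masses <- as.numeric(masses)
  out <- Filter(function(f) {
    !any(abs(f$mz - masses) <= f$mz * tol_ppm * 1e-6)
  }, features)
  attr(out, "cell_kind") <- "features"
  out
}
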