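# Continuous-wavelet-transform centroiding of profile-mode spectra.
#
# Profile spectra sample the instrument peak shape; centroiding reduces
# each ion species to a single (m/z, intensity) stick.  The picker follows
# the de-facto standard CWT scheme for mass spectra: convolve the profile
# intensity vector with Ricker (Mexican-hat) kernels over a set of scales,
# keep response maxima that persist across at least two consecutive scales
# (ridge criterion) and exceed a robust signal-to-noise threshold, then
# estimate each centroid m/z as the intensity-weighted mean of the profile
# points in a narrow ppm window around the ridge apex.

#' Centroiding parameters
#'
#' @param scales ascending wavelet scales in units of profile points; a
#'   peak of Gaussian width sigma points responds most strongly at a scale
#'   near sigma
#' @param min_snr minimum ridge signal-to-noise ratio, where noise is the
#'   median absolute deviation (x 1.4826) of the response at the smallest
#'   scale; 0 disables the gate
#' @param window_ppm half-width in ppm of the window around the ridge apex
#'   used for the weighted-mean m/z estimate
#' @return list of class `centroid_params`
#' @export
centroid_params <- function(scales = c(2, 4, 8, 16), min_snr = 3,
                            window_ppm = 10) {
  scales <- as.numeric(scales)
  stopifnot(length(scales) >= 1L, all(scales >= 1),
            !is.unsorted(scales, strictly = TRUE),
            min_snr >= 0, window_ppm > 0)
  structure(list(scales = scales, min_snr = min_snr,
                 window_ppm = window_ppm),
            class = "centroid_params")
}

#' Ricker (Mexican-hat) wavelet kernel
#'
#' The negative, normalised second derivative of a Gaussian,
#' `(1 - (x/scale)^2) * exp(-x^2 / (2 scale^2))` up to the standard
#' normalisation constant.  Symmetric with its maximum at `x = 0`; its
#' integral over the real line is zero, which makes the convolution
#' response insensitive to constant baselines.
#'
#' @param x numeric vector of evaluation points (profile-point offsets)
#' @param scale kernel scale (> 0), in the same units as `x`
#' @return numeric vector of kernel values
#' @export
mexican_hat <- function(x, scale) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("scale must be a positive finite number", call. = FALSE)
  }
  u <- x / scale
  a <- 2 / (sqrt(3 * scale) * pi^0.25)
  a * (1 - u^2) * exp(-u^2 / 2)
}

ricker_kernel <- function(scale) {
  half <- ceiling(5 * scale)
  mexican_hat(seq(-half, half), scale) / sqrt(scale)
}

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n] &
          y[2:(n - 1L)] > 0) + 1L
}

#' Centroid one profile-mode scan
#'
#' @param s a profile-mode [ms_scan()]; an already-centroided scan is passed
#'   through unchanged with a warning
#' @param params a [centroid_params()] object
#' @return a centroided [ms_scan()] whose pairs are the detected peaks, sorted
#'   ascending by m/z
#' @export
cwt_centroid <- function(s, params = centroid_params()) {
  stopifnot(inherits(s, "lcms_scan"), inherits(params, "centroid_params"))
  if (s$centroided) {
    warning("scan ", s$index, " is already centroided; returned unchanged",
            call. = FALSE)
    return(s)
  }
  empty <- function() {
    ms_scan(s$index, s$rt, numeric(), numeric(), s$ms_level, s$ion_mode,
         s$precursor_mz, centroided = TRUE)
  }
  n <- length(s$mz)
  # scales the scan can support; need at least two for a ridge
  scales <- params$scales[2 * params$scales <= n]
  if (length(scales) < 2L) return(empty())
  y <- s$intensity
  resp <- lapply(scales, function(sc) {
    k <- ricker_kernel(sc)
    half <- (length(k) - 1L) %/% 2L
    # zero-pad so peaks at the vector edges still get a full response
    padded <- c(rep(0, half), y, rep(0, half))
    r <- stats::filter(padded, k, method = "convolution", sides = 2L)
    as.numeric(r[(half + 1L):(half + n)])
  })
  maxima <- lapply(resp, local_maxima)
  # ridge criterion: a maximum at scale j persisting (within the coarser
  # scale in points) to scale j+1
  cand <- integer()
  for (j in seq_len(length(scales) - 1L)) {
    mj <- maxima[[j]]
    mk <- maxima[[j + 1L]]
    if (!length(mj) || !length(mk)) next
    tol <- ceiling(scales[j + 1L])
    keep <- vapply(mj, function(p) any(abs(mk - p) <= tol), logical(1))
    cand <- c(cand, mj[keep])
  }
  if (!length(cand)) return(empty())
  # best response across scales at each candidate position
  resp_max <- do.call(pmax, resp)
  cand <- sort(unique(cand))
  # merge candidates closer than the smallest scale (duplicate ridges)
  merged <- integer()
  gap <- max(2, ceiling(scales[1L]))
  i <- 1L
  while (i <= length(cand)) {
    run <- cand[i]
    while (i < length(cand) && cand[i + 1L] - cand[i] <= gap) {
      i <- i + 1L
      run <- c(run, cand[i])
    }
    merged <- c(merged, run[which.max(resp_max[run])])
    i <- i + 1L
  }
  noise <- stats::mad(resp[[1L]])
  if (noise > 0 && params$min_snr > 0) {
    merged <- merged[resp_max[merged] / noise >= params$min_snr]
  }
  if (!length(merged)) return(empty())
  cmz <- numeric(length(merged))
  cint <- numeric(length(merged))
  for (i in seq_along(merged)) {
    p <- merged[i]
    half <- s$mz[p] * params$window_ppm * 1e-6
    w <- which(abs(s$mz - s$mz[p]) <= half)
    tot <- sum(s$intensity[w])
    cmz[i] <- if (tot > 0) sum(s$mz[w] * s$intensity[w]) / tot else s$mz[p]
    cint[i] <- max(s$intensity[w])
  }
  keep <- !duplicated(cmz)
  ms_scan(s$index, s$rt, cmz[keep], cint[keep], s$ms_level, s$ion_mode,
       s$precursor_mz, centroided = TRUE)
}

#' Centroid every profile-mode MS1 scan of a sample
#'
#' Profile MS1 scans are centroided with [cwt_centroid()]; scans already in
#' centroid mode and MS^n scans are carried through unchanged.
#'
#' @param sample an [lcms_sample()]
#' @param params a [centroid_params()] object
#' @return a new sample with all MS1 scans centroided
#' @export
centroid_sample <- function(sample, params = centroid_params()) {
  stopifnot(inherits(sample, "lcms_sample"))
  scans <- lapply(sample$scans, function(s) {
    if (s$ms_level == 1L && !s$centroided) cwt_centroid(s, params) else s
  })
  lcms_sample(sample$id, scans, sample$metadata)
}
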