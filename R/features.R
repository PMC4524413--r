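# Feature extraction: build ion traces from centroided scans, then
# deconvolve each trace into individual chromatographic peaks.

#' Trace-building parameters
#'
#' @param tol_ppm ppm tolerance for extending a trace: a centroid may join
#'   an open trace whose running intensity-weighted mean m/z is within this
#'   relative tolerance
#' @param max_gap_scans number of consecutive MS1 scans a trace may go
#'   unextended before it is closed (>= 0)
#' @param min_intensity traces whose apex is below this are discarded
#' @return list of class `trace_params`
#' @export
trace_params <- function(tol_ppm = 10, max_gap_scans = 1L,
                         min_intensity = 0) {
  stopifnot(tol_ppm > 0, max_gap_scans >= 0, min_intensity >= 0)
  structure(list(tol_ppm = tol_ppm,
                 max_gap_scans = as.integer(max_gap_scans),
                 min_intensity = min_intensity),
            class = "trace_params")
}

#' Extract ion traces (features) from a centroided sample
#'
#' Greedy mass-trace construction over MS1 scans in time order: every
#' centroid joins the open trace whose running intensity-weighted mean m/z
#' lies within `tol_ppm` (the nearest such trace wins; one centroid per
#' trace per scan), otherwise it opens a new trace.  Traces unextended for
#' more than `max_gap_scans` consecutive MS1 scans are closed.  Closed
#' traces with apex intensity below `min_intensity` are discarded.  Each
#' returned feature has m/z equal to the intensity-weighted mean of its
#' member centroids and characteristic rt at its apex.
#'
#' @param sample an [lcms_sample()] whose MS1 scans are all centroided
#' @param params a [trace_params()] object
#' @return list of [feature()] objects, ordered by m/z
#' @export
extract_features <- function(sample, params = trace_params()) {
  stopifnot(inherits(sample, "lcms_sample"),
            inherits(params, "trace_params"))
  ms1 <- Filter(function(s) s$ms_level == 1L, sample$scans)
  if (any(!vapply(ms1, `[[`, logical(1), "centroided"))) {
    stop("sample '", sample$id, "' contains profile-mode MS1 scans; ",
         "run centroid_sample() first", call. = FALSE)
  }
  open <- list()   # each: mz (running mean), wsum, wmzsum, times, ints, last
  done <- list()
  close_trace <- function(tr) {
    if (max(tr$ints) >= params$min_intensity) done[[length(done) + 1L]] <<- tr
  }
  for (k in seq_along(ms1)) {
    s <- ms1[[k]]
    # close stale traces
    if (length(open)) {
      stale <- vapply(open, function(tr) k - tr$last > params$max_gap_scans + 1L,
                      logical(1))
      for (tr in open[stale]) close_trace(tr)
      open <- open[!stale]
    }
    m <- length(s$mz)
    if (m == 0L) next
    n_open <- length(open)
    if (n_open) {
      trace_mz <- vapply(open, `[[`, numeric(1), "mz")
      # candidate (centroid, trace) pairs within tolerance, nearest first
      dmat <- abs(outer(s$mz, trace_mz, "-")) /
        outer(s$mz, rep(1, n_open)) * 1e6
      cand <- which(dmat <= params$tol_ppm, arr.ind = TRUE)
      used_c <- logical(m)
      used_t <- logical(n_open)
      if (nrow(cand)) {
        cand <- cand[order(dmat[cand]), , drop = FALSE]
        for (r in seq_len(nrow(cand))) {
          ci <- cand[r, 1L]; ti <- cand[r, 2L]
          if (used_c[ci] || used_t[ti]) next
          used_c[ci] <- TRUE
          used_t[ti] <- TRUE
          tr <- open[[ti]]
          w <- s$intensity[ci]
          tr$wsum <- tr$wsum + w
          tr$wmzsum <- tr$wmzsum + w * s$mz[ci]
          if (tr$wsum > 0) tr$mz <- tr$wmzsum / tr$wsum
          tr$times <- c(tr$times, s$rt)
          tr$ints <- c(tr$ints, s$intensity[ci])
          tr$last <- k
          open[[ti]] <- tr
        }
      }
      new_idx <- which(!used_c)
    } else {
      new_idx <- seq_len(m)
    }
    for (ci in new_idx) {
      w <- s$intensity[ci]
      open[[length(open) + 1L]] <- list(
        mz = s$mz[ci], wsum = w, wmzsum = w * s$mz[ci],
        times = s$rt, ints = s$intensity[ci], last = k)
    }
  }
  for (tr in open) close_trace(tr)
  if (!length(done)) {
    return(structure(list(), cell_kind = "features"))
  }
  done <- done[order(vapply(done, `[[`, numeric(1), "mz"),
                     vapply(done, function(tr) tr$times[1L], numeric(1)))]
  mode <- if ("positive" %in% sample$ion_modes &&
              !"negative" %in% sample$ion_modes) "positive"
          else if ("negative" %in% sample$ion_modes &&
                   !"positive" %in% sample$ion_modes) "negative"
          else "unknown"
  out <- vector("list", length(done))
  for (i in seq_along(done)) {
    tr <- done[[i]]
    out[[i]] <- feature(
      id = sprintf("%s_F%04d", sample$id, i),
      mz = tr$mz, times = tr$times, intensities = tr$ints,
      ion_mode = mode)
  }
  attr(out, "cell_kind") <- "features"
  out
}

#' Deconvolution parameters
#'
#' @param sg_window Savitzky-Golay smoothing window in scans (odd, >= 5)
#' @param valley_fraction a trace is split between two apexes when the
#'   smoothed valley between them falls to or below this fraction of the
#'   lower apex, in (0, 1]
#' @param min_snr minimum apex signal-to-noise on the smoothed trace, where
#'   noise is the MAD (x 1.4826) of the smoothed-minus-raw residuals
#' @return list of class `deconvolution_params`
#' @export
deconvolution_params <- function(sg_window = 9L, valley_fraction = 0.5,
                                 min_snr = 3) {
  sg_window <- as.integer(sg_window)
  stopifnot(sg_window >= 5L, sg_window %% 2L == 1L,
            valley_fraction > 0, valley_fraction <= 1, min_snr >= 0)
  structure(list(sg_window = sg_window, valley_fraction = valley_fraction,
                 min_snr = min_snr),
            class = "deconvolution_params")
}

#' Split a mass trace into individual chromatographic peaks
#'
#' The trace is smoothed with a second-order Savitzky-Golay filter; local
#' maxima of the smoothed trace with signal-to-noise at least `min_snr`
#' are apex candidates.  Between each adjacent apex pair, if the minimum
#' smoothed intensity is at most `valley_fraction` times the lower apex,
#' the trace is cut at that minimum (the valley point goes to the earlier
#' child).  Children keep the parent m/z, raw (unsmoothed) intensities and
#' a recomputed apex rt.  A trace with a single apex is returned unchanged,
#' so total raw intensity is always conserved across the outputs.
#'
#' @param f an [feature()] object
#' @param params a [deconvolution_params()] object
#' @return list of [feature()] objects partitioning the input trace
#' @export
deconvolve <- function(f, params = deconvolution_params()) {
  stopifnot(inherits(f, "lcms_feature"),
            inherits(params, "deconvolution_params"))
  n <- length(f$intensities)
  win <- min(params$sg_window, if (n %% 2L == 1L) n else n - 1L)
  if (win < 5L) return(structure(list(f), cell_kind = "features"))
  sm <- signal::sgolayfilt(f$intensities, p = 2, n = win)
  sm <- pmax(sm, 0)
  noise <- stats::mad(sm - f$intensities)
  apex <- local_maxima(sm)
  # trace endpoints can be apexes too
  if (n >= 2L && sm[1L] > sm[2L]) apex <- c(1L, apex)
  if (n >= 2L && sm[n] > sm[n - 1L]) apex <- c(apex, n)
  if (noise > 0 && params$min_snr > 0) {
    apex <- apex[sm[apex] / noise >= params$min_snr]
  }
  # ignore numerically negligible ripples of the smoother (relevant on
  # noise-free traces, where the residual-based noise estimate is ~0)
  apex <- apex[sm[apex] >= 1e-3 * max(sm)]
  if (length(apex) <= 1L) return(structure(list(f), cell_kind = "features"))
  cuts <- integer()
  for (j in seq_len(length(apex) - 1L)) {
    lo <- apex[j]; hi <- apex[j + 1L]
    seg <- seq(lo, hi)
    vpos <- seg[which.min(sm[seg])]
    if (sm[vpos] <= params$valley_fraction * min(sm[lo], sm[hi])) {
      cuts <- c(cuts, vpos)
    }
  }
  if (!length(cuts)) return(structure(list(f), cell_kind = "features"))
  bounds <- c(0L, cuts, n)
  out <- vector("list", length(bounds) - 1L)
  for (j in seq_len(length(bounds) - 1L)) {
    idx <- seq(bounds[j] + 1L, bounds[j + 1L])
    out[[j]] <- feature(
      id = sprintf("%s_d%d", f$id, j),
      mz = f$mz, times = f$times[idx], intensities = f$intensities[idx],
      ion_mode = f$ion_mode, annotations = f$annotations)
  }
  attr(out, "cell_kind") <- "features"
  out
}

#' Deconvolve every feature in a list
#' @param features list of [feature()] objects
#' @param params a [deconvolution_params()] object
#' @return flattened list of deconvolved features
#' @export
deconvolve_features <- function(features, params = deconvolution_params()) {
  out <- do.call(c, c(lapply(features, deconvolve, params = params),
                      list(list())))
  attr(out, "cell_kind") <- "features"
  out
}
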