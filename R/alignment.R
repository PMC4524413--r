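# Retention-time alignment across samples and feature-matrix assembly.

new_feature_matrix <- function(groups, sample_ids, values) {
  stopifnot(is.data.frame(groups),
            nrow(values) == nrow(groups),
            ncol(values) == length(sample_ids))
  structure(list(groups = groups, sample_ids = as.character(sample_ids),
                 values = values),
            class = "lcms_feature_matrix")
}

#' @export
print.lcms_feature_matrix <- function(x, ...) {
  cat(sprintf("<feature matrix  %d groups x %d samples  %.1f%% filled>\n",
              nrow(x$values), ncol(x$values),
              if (length(x$values)) 100 * mean(!is.na(x$values)) else 0))
  invisible(x)
}

#' Estimate a retention-time map from one sample onto a reference
#'
#' Landmarks are unique mutual-nearest feature pairs agreeing within
#' `tol_ppm` in m/z and `rt_window` in retention time, ranked by apex
#' intensity (top 50 kept).  The landmarks are pooled into 10 equal-count
#' retention-time bins; a monotone piecewise-linear map from target rt to
#' reference rt is fitted through the per-bin medians (isotonic regression
#' enforces monotonicity).  With fewer than 5 landmarks the identity map
#' is returned with a warning.
#'
#' @param reference list of [feature()] objects of the reference sample
#' @param target list of [feature()] objects of the sample to be warped
#' @param tol_ppm m/z tolerance in ppm for landmark pairing
#' @param rt_window maximum retention-time discrepancy in seconds for
#'   landmark pairing
#' @return function of class `rt_map` mapping target rt (seconds) to
#'   reference rt; carries attributes `landmarks` (data.frame) and
#'   `identity` (logical)
#' @export
estimate_rt_shift <- function(reference, target, tol_ppm = 10,
                              rt_window = 30) {
  stopifnot(length(reference) > 0L, length(target) > 0L,
            tol_ppm > 0, rt_window > 0)
  identity_map <- function(msg) {
    if (!is.null(msg)) warning(msg, call. = FALSE)
    structure(function(rt) rt, class = "rt_map",
              landmarks = data.frame(target_rt = numeric(),
                                     reference_rt = numeric()),
              identity = TRUE)
  }
  ref_mz <- vapply(reference, `[[`, numeric(1), "mz")
  ref_rt <- vapply(reference, `[[`, numeric(1), "rt")
  tgt_mz <- vapply(target, `[[`, numeric(1), "mz")
  tgt_rt <- vapply(target, `[[`, numeric(1), "rt")
  tgt_apex <- vapply(target, apex_intensity, numeric(1))
  # nearest admissible partner of each target feature, and mutuality check
  nearest <- function(mz, rt, cand_mz, cand_rt) {
    ok <- abs(cand_mz - mz) <= mz * tol_ppm * 1e-6 &
      abs(cand_rt - rt) <= rt_window
    if (!any(ok)) return(NA_integer_)
    idx <- which(ok)
    idx[which.min(abs(cand_rt[idx] - rt) / rt_window +
                    abs(cand_mz[idx] - mz) / (mz * tol_ppm * 1e-6))]
  }
  t2r <- vapply(seq_along(target), function(i) {
    nearest(tgt_mz[i], tgt_rt[i], ref_mz, ref_rt)
  }, integer(1))
  r2t <- vapply(seq_along(reference), function(i) {
    nearest(ref_mz[i], ref_rt[i], tgt_mz, tgt_rt)
  }, integer(1))
  mutual <- which(!is.na(t2r) & r2t[t2r] == seq_along(target))
  if (length(mutual) < 5L) {
    return(identity_map(sprintf(
      "only %d landmark pair(s); returning identity retention-time map",
      length(mutual))))
  }
  mutual <- mutual[order(tgt_apex[mutual], decreasing = TRUE)]
  mutual <- mutual[seq_len(min(50L, length(mutual)))]
  lm_t <- tgt_rt[mutual]
  lm_r <- ref_rt[t2r[mutual]]
  o <- order(lm_t)
  lm_t <- lm_t[o]
  lm_r <- lm_r[o]
  nbin <- min(10L, length(lm_t))
  bin <- ceiling(seq_along(lm_t) / (length(lm_t) / nbin))
  bx <- as.numeric(tapply(lm_t, bin, stats::median))
  by <- as.numeric(tapply(lm_r, bin, stats::median))
  if (length(unique(bx)) < 2L) {
    shift <- stats::median(lm_r - lm_t)
    f <- function(rt) rt + shift
  } else {
    # enforce monotonicity of the knots, then interpolate; outside the
    # knot range the boundary shift is extrapolated as a constant offset
    iso <- stats::isoreg(bx, by)
    ky <- if (is.null(iso$ord)) iso$yf else iso$yf[order(iso$ord)]
    kx <- sort(bx)
    f <- function(rt) {
      y <- stats::approx(kx, ky, xout = rt, rule = 1L)$y
      lo <- rt < kx[1L]
      hi <- rt > kx[length(kx)]
      y[lo] <- rt[lo] + (ky[1L] - kx[1L])
      y[hi] <- rt[hi] + (ky[length(ky)] - kx[length(kx)])
      y
    }
  }
  structure(f, class = "rt_map",
            landmarks = data.frame(target_rt = lm_t, reference_rt = lm_r),
            identity = FALSE)
}

#' Apply a retention-time map to a list of features
#'
#' Warps every feature's time vector and characteristic rt through the
#' map.  Strictly increasing time vectors stay strictly increasing because
#' the map is monotone non-decreasing (degenerate flat stretches are
#' resolved by keeping the original spacing around them).
#'
#' @param features list of [feature()] objects
#' @param map an `rt_map` from [estimate_rt_shift()]
#' @return warped feature list
#' @export
apply_rt_map <- function(features, map) {
  stopifnot(inherits(map, "rt_map"))
  out <- lapply(features, function(f) {
    tt <- map(f$times)
    if (length(tt) > 1L && any(diff(tt) <= 0)) {
      # guard against flat map stretches collapsing time points
      tt <- tt + seq_along(tt) * 1e-9
    }
    rt <- map(f$rt)
    rt <- min(max(rt, tt[1L]), tt[length(tt)])
    feature(f$id, f$mz, tt, f$intensities, rt = rt,
            ion_mode = f$ion_mode, annotations = f$annotations)
  })
  attr(out, "cell_kind") <- "features"
  out
}

#' Build the aligned cross-sample feature matrix
#'
#' Greedy centroid-style grouping: all features from all samples are
#' processed in descending apex intensity; each feature joins an existing
#' group when its m/z is within `tol_ppm` of the group's running mean m/z,
#' its rt within `rt_tol` of the running mean rt, and the group has no
#' feature from the same sample yet -- otherwise it founds a new group.
#' Cell values are trapezoidal peak areas ([feature_area()]) or apex
#' heights; cells with no feature stay missing (`NA`).  Groups are ordered
#' by consensus rt, then m/z.
#'
#' @param per_sample_features named list: sample id -> list of (rt-
#'   corrected) [feature()] objects
#' @param tol_ppm m/z tolerance in ppm
#' @param rt_tol retention-time tolerance in seconds
#' @param value `"area"` (default) or `"apex"` intensity per cell
#' @return an `lcms_feature_matrix`
#' @export
build_matrix <- function(per_sample_features, tol_ppm = 10, rt_tol = 5,
                         value = c("area", "apex")) {
  stopifnot(length(per_sample_features) >= 1L,
            !is.null(names(per_sample_features)),
            tol_ppm > 0, rt_tol > 0)
  value <- match.arg(value)
  sample_ids <- names(per_sample_features)
  all_feats <- list()
  all_sample <- character()
  for (sid in sample_ids) {
    fl <- per_sample_features[[sid]]
    all_feats <- c(all_feats, fl)
    all_sample <- c(all_sample, rep(sid, length(fl)))
  }
  if (!length(all_feats)) {
    return(new_feature_matrix(
      data.frame(group_id = character(), mz = numeric(), rt = numeric(),
                 label = character(), stringsAsFactors = FALSE),
      sample_ids, matrix(numeric(), 0L, length(sample_ids))))
  }
  apex <- vapply(all_feats, apex_intensity, numeric(1))
  ord <- order(apex, decreasing = TRUE)
  groups <- list()  # each: mz, rt, n, members (idx), samples (chr)
  for (i in ord) {
    f <- all_feats[[i]]
    sid <- all_sample[i]
    joined <- FALSE
    if (length(groups)) {
      gmz <- vapply(groups, `[[`, numeric(1), "mz")
      grt <- vapply(groups, `[[`, numeric(1), "rt")
      ok <- which(abs(gmz - f$mz) <= f$mz * tol_ppm * 1e-6 &
                    abs(grt - f$rt) <= rt_tol)
      if (length(ok)) {
        ok <- ok[order(abs(grt[ok] - f$rt))]
        for (g in ok) {
          if (sid %in% groups[[g]]$samples) next
          gr <- groups[[g]]
          gr$mz <- (gr$mz * gr$n + f$mz) / (gr$n + 1)
          gr$rt <- (gr$rt * gr$n + f$rt) / (gr$n + 1)
          gr$n <- gr$n + 1
          gr$members <- c(gr$members, i)
          gr$samples <- c(gr$samples, sid)
          groups[[g]] <- gr
          joined <- TRUE
          break
        }
      }
    }
    if (!joined) {
      groups[[length(groups) + 1L]] <- list(
        mz = f$mz, rt = f$rt, n = 1, members = i, samples = sid)
    }
  }
  groups <- groups[order(vapply(groups, `[[`, numeric(1), "rt"),
                         vapply(groups, `[[`, numeric(1), "mz"))]
  ng <- length(groups)
  values <- matrix(NA_real_, ng, length(sample_ids),
                   dimnames = list(NULL, sample_ids))
  labels <- character(ng)
  for (g in seq_len(ng)) {
    gr <- groups[[g]]
    for (j in seq_along(gr$members)) {
      f <- all_feats[[gr$members[j]]]
      values[g, gr$samples[j]] <-
        if (value == "area") feature_area(f) else apex_intensity(f)
    }
    labs <- unlist(lapply(gr$members, function(i) {
      vapply(all_feats[[i]]$annotations, `[[`, character(1), "label")
    }))
    labels[g] <- if (length(labs)) paste(unique(labs), collapse = ";") else ""
  }
  gdf <- data.frame(
    group_id = sprintf("G%05d", seq_len(ng)),
    mz = vapply(groups, `[[`, numeric(1), "mz"),
    rt = vapply(groups, `[[`, numeric(1), "rt"),
    label = labels, stringsAsFactors = FALSE)
  new_feature_matrix(gdf, sample_ids, values)
}
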