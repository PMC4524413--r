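# Core domain types: scan, feature, feature set, sample, annotation.
#
# All containers are plain S3 lists with validating constructors.  Every
# operation in the package is pure: it takes containers in and returns new
# containers, never mutating its inputs.  Times are seconds throughout; m/z
# is in Thomson; intensities are detector counts (arbitrary units).

ION_MODES <- c("positive", "negative", "unknown")
ANNOTATION_KINDS <- c("isotope", "adduct", "fragment", "identity")

#' Validate an ion mode string
#' @param mode character scalar
#' @return the normalized mode ("positive", "negative" or "unknown")
#' @keywords internal
as_ion_mode <- function(mode) {
  if (is.null(mode) || length(mode) != 1L || is.na(mode)) return("unknown")
  mode <- tolower(as.character(mode))
  if (!mode %in% ION_MODES) {
    stop("invalid ion mode: '", mode, "' (expected one of ",
         paste(ION_MODES, collapse = ", "), ")", call. = FALSE)
  }
  mode
}

#' Construct a mass spectrum (scan)
#'
#' A scan is a set of (m/z, intensity) pairs acquired at one retention time.
#' Pairs are stored as two parallel numeric vectors sorted strictly
#' ascending by m/z; duplicate m/z values are merged by summing their
#' intensities.
#'
#' @param index ordinal scan number within the run (0-based, >= 0)
#' @param rt retention time in seconds (>= 0)
#' @param mz numeric vector of mass-to-charge values in Thomson (> 0)
#' @param intensity numeric vector of detector counts (>= 0), same length
#' @param ms_level MS level (1 for full scans, > 1 for fragmentation scans)
#' @param ion_mode "positive", "negative" or "unknown"
#' @param precursor_mz precursor m/z; required iff `ms_level > 1`
#' @param centroided logical; `TRUE` for stick spectra, `FALSE` for
#'   profile-mode (sampled peak shape) spectra
#' @return an object of class `lcms_scan`
#' @export
ms_scan <- function(index, rt, mz = numeric(), intensity = numeric(),
                 ms_level = 1L, ion_mode = "unknown", precursor_mz = NULL,
                 centroided = TRUE) {
  index <- as.integer(index)
  stopifnot(length(index) == 1L, index >= 0L)
  rt <- as.numeric(rt)
  stopifnot(length(rt) == 1L, is.finite(rt), rt >= 0)
  ms_level <- as.integer(ms_level)
  stopifnot(length(ms_level) == 1L, ms_level >= 1L)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have equal length", call. = FALSE)
  }
  if (length(mz)) {
    if (any(!is.finite(mz)) || any(!is.finite(intensity))) {
      stop("non-finite m/z or intensity values", call. = FALSE)
    }
    if (any(mz <= 0)) stop("m/z values must be > 0", call. = FALSE)
    if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
    if (is.unsorted(mz, strictly = TRUE)) {
      o <- order(mz)
      mz <- mz[o]
      intensity <- intensity[o]
      if (anyDuplicated(mz)) {
        intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
        mz <- unique(mz)
      }
    }
  }
  if (ms_level > 1L) {
    if (is.null(precursor_mz) || !is.finite(precursor_mz) || precursor_mz <= 0) {
      stop("precursor_mz required (and > 0) for ms_level > 1", call. = FALSE)
    }
    precursor_mz <- as.numeric(precursor_mz)
  } else {
    precursor_mz <- NULL
  }
  structure(
    list(index = index, rt = rt, mz = mz, intensity = intensity,
         ms_level = ms_level, ion_mode = as_ion_mode(ion_mode),
         precursor_mz = precursor_mz, centroided = isTRUE(centroided)),
    class = "lcms_scan"
  )
}

#' Construct a feature (ion trace)
#'
#' A feature is one ion followed across consecutive scans: a time vector, an
#' intensity vector, a characteristic m/z and a characteristic retention
#' time.  The characteristic retention time defaults to the apex (time of
#' maximum intensity, earliest on ties).
#'
#' @param id unique identifier within a sample (character scalar)
#' @param mz characteristic m/z in Thomson (> 0)
#' @param times strictly increasing numeric vector of seconds
#' @param intensities numeric vector of counts, same length as `times`
#' @param rt characteristic retention time; defaults to the apex time and
#'   must lie within `[times[1], times[length(times)]]`
#' @param ion_mode "positive", "negative" or "unknown"
#' @param annotations list of [annotation()] objects
#' @return an object of class `lcms_feature`
#' @export
feature <- function(id, mz, times, intensities, rt = NULL,
                    ion_mode = "unknown", annotations = list()) {
  id <- as.character(id)
  stopifnot(length(id) == 1L, nzchar(id))
  mz <- as.numeric(mz)
  stopifnot(length(mz) == 1L, is.finite(mz), mz > 0)
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) < 1L || length(times) != length(intensities)) {
    stop("times and intensities must be equal-length vectors of length >= 1",
         call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(intensities))) {
    stop("non-finite times or intensities", call. = FALSE)
  }
  if (length(times) > 1L && is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(intensities < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (is.null(rt)) {
    rt <- characteristic_rt(times, intensities)
  } else {
    rt <- as.numeric(rt)
    stopifnot(length(rt) == 1L, is.finite(rt))
    if (rt < times[1L] || rt > times[length(times)]) {
      stop("rt must lie within the feature's time span", call. = FALSE)
    }
  }
  stopifnot(is.list(annotations))
  structure(
    list(id = id, mz = mz, times = times, intensities = intensities,
         rt = rt, ion_mode = as_ion_mode(ion_mode),
         annotations = annotations),
    class = "lcms_feature"
  )
}

#' Construct an annotation
#'
#' Annotations attach interpretation to a feature: isotope peaks ("M+1",
#' "M+2", ...), adduct identity ("M+H", "M+Na", ...), fragments, or a
#' reference-library identity (compound name).
#'
#' @param kind one of "isotope", "adduct", "fragment", "identity"
#' @param label display label, e.g. `"M+H"` or a compound name
#' @param partner_id id of the related feature; required for isotope,
#'   adduct and fragment annotations
#' @param score dimensionless confidence in `[0, 1]`
#' @param ... extra fields (e.g. `charge`, `neutral_mass`) kept verbatim
#' @return an object of class `lcms_annotation`
#' @export
annotation <- function(kind, label, partner_id = NULL, score = 1, ...) {
  kind <- match.arg(tolower(kind), ANNOTATION_KINDS)
  stopifnot(is.character(label), length(label) == 1L)
  score <- as.numeric(score)
  stopifnot(length(score) == 1L, is.finite(score), score >= 0, score <= 1)
  if (kind %in% c("isotope", "adduct", "fragment") && is.null(partner_id)) {
    stop(kind, " annotations must carry a partner_id", call. = FALSE)
  }
  if (!is.null(partner_id)) partner_id <- as.character(partner_id)
  structure(
    c(list(kind = kind, label = label, partner_id = partner_id,
           score = score), list(...)),
    class = "lcms_annotation"
  )
}

#' Construct a feature set (compound spectrum)
#'
#' A feature set collects co-eluting features believed to belong to one
#' compound (adducts, isotopologues, fragments).  Its retention time is the
#' arithmetic mean of the member characteristic retention times; all
#' members must share one ion mode.
#'
#' @param id unique identifier
#' @param features non-empty list of [feature()] objects
#' @param neutral_mass consensus neutral mass in Da, if known
#' @return an object of class `lcms_feature_set`
#' @export
feature_set <- function(id, features, neutral_mass = NULL) {
  id <- as.character(id)
  stopifnot(length(id) == 1L, nzchar(id))
  if (!is.list(features) || length(features) == 0L ||
      !all(vapply(features, inherits, logical(1), "lcms_feature"))) {
    stop("features must be a non-empty list of lcms_feature objects",
         call. = FALSE)
  }
  modes <- unique(vapply(features, `[[`, character(1), "ion_mode"))
  if (length(modes) > 1L) {
    stop("all features in a set must share one ion mode (found: ",
         paste(modes, collapse = ", "), ")", call. = FALSE)
  }
  rt <- mean(vapply(features, `[[`, numeric(1), "rt"))
  structure(
    list(id = id, features = features, rt = rt, ion_mode = modes,
         neutral_mass = neutral_mass),
    class = "lcms_feature_set"
  )
}

#' Construct a sample (one LC-MS run)
#'
#' @param id run identifier (conventionally derived from the file name)
#' @param scans list of [ms_scan()] objects ordered by index; indices must be
#'   unique and MS1 retention times non-decreasing with index
#' @param metadata named list of free-form strings
#' @return an object of class `lcms_sample`
#' @export
lcms_sample <- function(id, scans, metadata = list()) {
  id <- as.character(id)
  stopifnot(length(id) == 1L, nzchar(id))
  stopifnot(is.list(scans))
  if (length(scans) &&
      !all(vapply(scans, inherits, logical(1), "lcms_scan"))) {
    stop("scans must be a list of lcms_scan objects", call. = FALSE)
  }
  idx <- vapply(scans, `[[`, integer(1), "index")
  if (anyDuplicated(idx)) stop("scan indices must be unique", call. = FALSE)
  scans <- scans[order(idx)]
  rts <- vapply(scans, `[[`, numeric(1), "rt")
  if (length(rts) > 1L && is.unsorted(rts)) {
    stop("retention times must be non-decreasing with scan index",
         call. = FALSE)
  }
  modes <- unique(vapply(scans, `[[`, character(1), "ion_mode"))
  if (length(modes) == 0L) modes <- "unknown"
  structure(
    list(id = id, scans = scans, ion_modes = modes, metadata = metadata),
    class = "lcms_sample"
  )
}

# ---- elementary operations -------------------------------------------------

#' Characteristic retention time of a trace
#'
#' The apex: the time at which intensity is maximal, with ties broken by the
#' earliest time.
#'
#' @param times numeric vector of seconds
#' @param intensities numeric vector of counts, same length
#' @return apex time in seconds
#' @export
characteristic_rt <- function(times, intensities) {
  if (length(times) == 0L || length(times) != length(intensities)) {
    stop("times and intensities must be non-empty vectors of equal length",
         call. = FALSE)
  }
  times[which.max(intensities)]
}

#' Integrated area of a feature
#'
#' Trapezoidal integral of intensity over time, in counts * seconds.  A
#' single-point feature has zero area.
#'
#' @param f an [feature()] object
#' @return numeric scalar
#' @export
feature_area <- function(f) {
  stopifnot(inherits(f, "lcms_feature"))
  n <- length(f$times)
  if (n < 2L) return(0)
  sum(diff(f$times) * (f$intensities[-n] + f$intensities[-1L]) / 2)
}

#' Width of a feature in scans
#'
#' The number of scans the ion trace spans, i.e. the length of its time
#' vector.
#'
#' @param f an [feature()] object
#' @return integer scalar
#' @export
feature_width_scans <- function(f) {
  stopifnot(inherits(f, "lcms_feature"))
  length(f$times)
}

#' Apex intensity of a feature
#' @param f an [feature()] object
#' @return numeric scalar, the maximum of the intensity vector
#' @export
apex_intensity <- function(f) {
  stopifnot(inherits(f, "lcms_feature"))
  max(f$intensities)
}

#' Extracted ion chromatogram
#'
#' For every MS1 scan in the sample, sums the intensity of all pairs whose
#' m/z lies within `tol_ppm` (relative) of `mz`; scans with no matching pair
#' contribute zero.
#'
#' @param sample an [lcms_sample()] object
#' @param mz target m/z in Thomson
#' @param tol_ppm relative tolerance in parts per million (> 0)
#' @return list with numeric vectors `times` and `intensities`, one entry
#'   per MS1 scan
#' @export
xic <- function(sample, mz, tol_ppm = 10) {
  stopifnot(inherits(sample, "lcms_sample"), tol_ppm > 0, mz > 0)
  ms1 <- Filter(function(s) s$ms_level == 1L, sample$scans)
  half <- mz * tol_ppm * 1e-6
  times <- vapply(ms1, `[[`, numeric(1), "rt")
  ints <- vapply(ms1, function(s) {
    hit <- abs(s$mz - mz) <= half
    if (any(hit)) sum(s$intensity[hit]) else 0
  }, numeric(1))
  list(times = times, intensities = ints)
}

# ---- printing --------------------------------------------------------------

#' @export
print.lcms_scan <- function(x, ...) {
  cat(sprintf("<scan #%d  rt %.2f s  MS%d  %s  %d pairs%s>\n",
              x$index, x$rt, x$ms_level, x$ion_mode, length(x$mz),
              if (x$centroided) "" else "  profile"))
  invisible(x)
}

#' @export
print.lcms_feature <- function(x, ...) {
  labs <- vapply(x$annotations, `[[`, character(1), "label")
  cat(sprintf("<feature %s  m/z %.5f  rt %.2f s  %d scans  apex %.3g%s>\n",
              x$id, x$mz, x$rt, length(x$times), max(x$intensities),
              if (length(labs)) paste0("  [", paste(labs, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' @export
print.lcms_feature_set <- function(x, ...) {
  cat(sprintf("<feature set %s  rt %.2f s  %d features%s>\n",
              x$id, x$rt, length(x$features),
              if (!is.null(x$neutral_mass))
                sprintf("  M %.5f Da", x$neutral_mass) else ""))
  invisible(x)
}

#' @export
print.lcms_sample <- function(x, ...) {
  cat(sprintf("<sample %s  %d scans  modes: %s>\n",
              x$id, length(x$scans), paste(x$ion_modes, collapse = "/")))
  invisible(x)
}
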