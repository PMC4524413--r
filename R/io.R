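# I/O: mzML ingestion (via mzR), typed snapshots, CSV side-inputs
# (adduct rules, reference libraries, exclusion masses) and the feature
# matrix writer.

SNAPSHOT_MAGIC <- "MCC1"
SNAPSHOT_VERSION <- 1L

#' Read an mzML file into a sample
#'
#' Parses an mzML 1.1.0 file (indexed or plain, compressed or uncompressed
#' binary arrays, 32- or 64-bit floats) through the proteowizard-backed
#' `mzR` parser.  Retention times are converted to seconds, per-spectrum
#' polarity terms become the scan ion mode (missing polarity yields
#' `"unknown"` with a warning), MS level and precursor m/z are carried over,
#' and each spectrum's pairs are sorted ascending by m/z if the file stores
#' them unsorted.
#'
#' @param path path to an mzML file
#' @param id sample identifier; defaults to the file name without extension
#' @return an [lcms_sample()] object with scans in file order (0-based
#'   indices)
#' @export
read_mzml <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  handle <- tryCatch(
    suppressWarnings(mzR::openMSfile(path, backend = "pwiz")),
    error = function(e) {
      # fall back to a plain XML parse for a location-bearing message
      detail <- conditionMessage(e)
      if (requireNamespace("xml2", quietly = TRUE)) {
        probe <- tryCatch({ xml2::read_xml(path); NULL },
                          error = function(e2) conditionMessage(e2))
        if (!is.null(probe)) detail <- probe
      }
      stop("cannot parse mzML file '", path, "': ", detail, call. = FALSE)
    })
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  n <- nrow(hdr)
  if (n == 0L) return(lcms_sample(id, list()))
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  if (any(hdr$polarity < 0)) {
    warning("spectra without polarity term in '", basename(path),
            "': ion mode set to unknown", call. = FALSE)
  }
  scans <- vector("list", n)
  for (i in seq_len(n)) {
    m <- pk[[i]]
    lvl <- hdr$msLevel[i]
    scans[[i]] <- ms_scan(
      index = i - 1L,
      rt = hdr$retentionTime[i],
      mz = m[, 1L], intensity = m[, 2L],
      ms_level = lvl,
      ion_mode = if (hdr$polarity[i] > 0) "positive"
                 else if (hdr$polarity[i] == 0) "negative" else "unknown",
      precursor_mz = if (lvl > 1L) hdr$precursorMZ[i] else NULL,
      centroided = isTRUE(hdr$centroided[i])
    )
  }
  lcms_sample(id, scans, metadata = list(source = path))
}

# ---- snapshots -------------------------------------------------------------

#' Cell kind of a processing result
#'
#' Every object passed between pipeline stages has one of three kinds:
#' `"sample"` (scans), `"features"` (a list of ion traces) or
#' `"feature_sets"` (a list of grouped compound spectra).  Stage ports are
#' typed by these kinds.
#'
#' @param obj a sample, list of features, or list of feature sets
#' @return character scalar kind
#' @export
cell_kind <- function(obj) {
  if (inherits(obj, "lcms_sample")) return("sample")
  if (inherits(obj, "lcms_feature_matrix")) return("feature_matrix")
  if (is.list(obj)) {
    if (length(obj) == 0L) {
      k <- attr(obj, "cell_kind")
      if (!is.null(k)) return(k)
      stop("cannot infer cell kind of an empty unannotated list; ",
           "set attr(x, 'cell_kind')", call. = FALSE)
    }
    if (all(vapply(obj, inherits, logical(1), "lcms_feature"))) {
      return("features")
    }
    if (all(vapply(obj, inherits, logical(1), "lcms_feature_set"))) {
      return("feature_sets")
    }
  }
  stop("object is not a recognised cell kind", call. = FALSE)
}

# Doubles are serialised as "%.17g" strings: 17 significant digits
# round-trip IEEE doubles exactly through strtod, which generic JSON
# number formatting does not guarantee.
num_out <- function(x) {
  if (!length(x)) return(character())
  s <- sprintf("%.17g", as.numeric(x))
  s[is.na(x)] <- "NA"
  s
}
num_in <- function(x) {
  x <- as.character(unlist(x))
  if (!length(x)) return(numeric())
  out <- rep(NA_real_, length(x))
  ok <- x != "NA"
  out[ok] <- as.numeric(x[ok])
  out
}
looks_numeric <- function(x) {
  is.character(x) &&
    all(grepl("^[-+]?((\\d+\\.?\\d*|\\.\\d+)([eE][-+]?\\d+)?|NA|Inf)$", x))
}

annotation_to_plain <- function(a) {
  lapply(unclass(a), function(v) if (is.numeric(v)) num_out(v) else v)
}

plain_to_annotation <- function(p) {
  p <- lapply(p, function(v) {
    v <- unlist(v)
    if (looks_numeric(v)) num_in(v) else v
  })
  do.call(annotation, c(
    list(kind = p$kind, label = p$label,
         partner_id = if (is.null(p$partner_id)) NULL else p$partner_id,
         score = p$score),
    p[setdiff(names(p), c("kind", "label", "partner_id", "score"))]
  ))
}

feature_to_plain <- function(f) {
  list(id = f$id, mz = num_out(f$mz), times = num_out(f$times),
       intensities = num_out(f$intensities), rt = num_out(f$rt),
       ion_mode = f$ion_mode,
       annotations = lapply(f$annotations, annotation_to_plain))
}

plain_to_feature <- function(p) {
  feature(id = p$id, mz = num_in(p$mz), times = num_in(p$times),
          intensities = num_in(p$intensities), rt = num_in(p$rt),
          ion_mode = p$ion_mode,
          annotations = lapply(p$annotations, plain_to_annotation))
}

scan_to_plain <- function(s) {
  list(index = s$index, rt = num_out(s$rt), mz = num_out(s$mz),
       intensity = num_out(s$intensity), ms_level = s$ms_level,
       ion_mode = s$ion_mode,
       precursor_mz = if (is.null(s$precursor_mz)) NULL else
         num_out(s$precursor_mz),
       centroided = s$centroided)
}

plain_to_scan <- function(p) {
  ms_scan(index = p$index, rt = num_in(p$rt), mz = num_in(p$mz),
       intensity = num_in(p$intensity), ms_level = p$ms_level,
       ion_mode = p$ion_mode,
       precursor_mz = if (is.null(p$precursor_mz)) NULL else
         num_in(p$precursor_mz),
       centroided = p$centroided)
}

obj_to_plain <- function(obj, kind) {
  switch(kind,
    sample = list(id = obj$id, metadata = obj$metadata,
                  scans = lapply(obj$scans, scan_to_plain)),
    features = lapply(obj, feature_to_plain),
    feature_sets = lapply(obj, function(fs) {
      list(id = fs$id,
           neutral_mass = if (is.null(fs$neutral_mass)) NULL else
             num_out(fs$neutral_mass),
           features = lapply(fs$features, feature_to_plain))
    }),
    feature_matrix = list(
      groups = lapply(seq_len(nrow(obj$groups)), function(i) {
        list(group_id = obj$groups$group_id[i],
             mz = num_out(obj$groups$mz[i]),
             rt = num_out(obj$groups$rt[i]),
             label = obj$groups$label[i])
      }),
      sample_ids = obj$sample_ids,
      values = lapply(seq_len(nrow(obj$values)),
                      function(i) num_out(obj$values[i, ]))),
    stop("unknown cell kind: ", kind, call. = FALSE))
}

plain_to_obj <- function(plain, kind) {
  switch(kind,
    sample = lcms_sample(plain$id, lapply(plain$scans, plain_to_scan),
                         metadata = plain$metadata),
    features = structure(lapply(plain, plain_to_feature),
                         cell_kind = "features"),
    feature_sets = structure(lapply(plain, function(p) {
      fs <- feature_set(p$id, lapply(p$features, plain_to_feature))
      fs$neutral_mass <- if (is.null(p$neutral_mass)) NULL else
        num_in(p$neutral_mass)
      fs
    }), cell_kind = "feature_sets"),
    feature_matrix = {
      g <- do.call(rbind, lapply(plain$groups, function(r) {
        data.frame(group_id = r$group_id, mz = num_in(r$mz),
                   rt = num_in(r$rt), label = r$label,
                   stringsAsFactors = FALSE)
      }))
      if (is.null(g)) {
        g <- data.frame(group_id = character(), mz = numeric(),
                        rt = numeric(), label = character(),
                        stringsAsFactors = FALSE)
      }
      sample_ids <- as.character(unlist(plain$sample_ids))
      vals <- do.call(rbind, lapply(plain$values, num_in))
      if (is.null(vals)) vals <- matrix(numeric(), 0L, length(sample_ids))
      colnames(vals) <- sample_ids
      new_feature_matrix(g, sample_ids, vals)
    },
    stop("unknown cell kind: ", kind, call. = FALSE))
}

#' Write a typed snapshot of a processing result
#'
#' Snapshots make every intermediate pipeline result inspectable and
#' resumable: after any stage, the stage's output can be serialised and
#' later re-read with full numeric precision (doubles round-trip
#' bit-identically).  The format is self-describing: a 4-byte magic prefix,
#' the cell kind and a schema version precede the payload, so the kind of a
#' snapshot can be checked without deserialising it.
#'
#' @param obj a sample, feature list, feature-set list or feature matrix
#' @param path output path (conventionally `.mcc`)
#' @return `path`, invisibly
#' @export
write_snapshot <- function(obj, path) {
  kind <- cell_kind(obj)
  body <- jsonlite::toJSON(obj_to_plain(obj, kind), digits = NA,
                           auto_unbox = TRUE, null = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(paste0(SNAPSHOT_MAGIC, "\n", kind, "\n", SNAPSHOT_VERSION, "\n"),
            con, eos = NULL)
  writeChar(as.character(body), con, eos = NULL)
  invisible(path)
}

#' Inspect a snapshot's cell kind without reading its payload
#' @param path snapshot file path
#' @return character scalar kind
#' @export
snapshot_kind <- function(path) {
  head <- readLines(path, n = 2L, warn = FALSE)
  if (length(head) < 2L || head[1L] != SNAPSHOT_MAGIC) {
    stop("not a snapshot file (bad magic): ", path, call. = FALSE)
  }
  head[2L]
}

#' Read a typed snapshot
#'
#' @param path snapshot file path written by [write_snapshot()]
#' @param expect optional kind (`"sample"`, `"features"`,
#'   `"feature_sets"`, `"feature_matrix"`); a mismatch raises a typed error
#'   naming the expected and found kinds
#' @return the deserialised object
#' @export
read_snapshot <- function(path, expect = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L || lines[1L] != SNAPSHOT_MAGIC) {
    stop("not a snapshot file (bad magic): ", path, call. = FALSE)
  }
  kind <- lines[2L]
  if (!is.null(expect) && !identical(kind, expect)) {
    stop(sprintf("snapshot kind mismatch in '%s': expected '%s', found '%s'",
                 path, expect, kind), call. = FALSE)
  }
  payload <- jsonlite::fromJSON(paste(lines[-(1:3)], collapse = "\n"),
                                simplifyVector = FALSE)
  plain_to_obj(payload, kind)
}

# ---- CSV side inputs -------------------------------------------------------

#' Read an adduct rule table
#'
#' An adduct rule describes an ion species nM+X by its name, the signed
#' mass shift in Da, the signed charge and the molecular multiplier n.  The
#' observed m/z of a neutral mass M under a rule is
#' `(multiplier * M + mass_shift) / |charge|`.
#'
#' @param path CSV file with header columns `name,mass_shift,charge,multiplier`
#' @return data.frame of class `adduct_rules` with those columns
#' @export
read_adduct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "mass_shift", "charge", "multiplier")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("adduct table '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$mass_shift <- as.numeric(df$mass_shift)
  df$charge <- as.integer(df$charge)
  df$multiplier <- as.integer(df$multiplier)
  bad <- which(!is.finite(df$mass_shift) | is.na(df$charge) |
                 df$charge == 0L | is.na(df$multiplier) | df$multiplier < 1L)
  if (length(bad)) {
    stop("invalid adduct rule(s) in '", path, "' at data row(s) ",
         paste(bad, collapse = ", "),
         " (charge must be non-zero, multiplier >= 1, mass_shift numeric)",
         call. = FALSE)
  }
  df <- df[, required]
  class(df) <- c("adduct_rules", "data.frame")
  df
}

#' Build an adduct rule table in code
#' @param name,mass_shift,charge,multiplier equal-length vectors
#' @return data.frame of class `adduct_rules`
#' @export
adduct_rules <- function(name, mass_shift, charge, multiplier = 1L) {
  df <- data.frame(name = as.character(name),
                   mass_shift = as.numeric(mass_shift),
                   charge = as.integer(charge),
                   multiplier = as.integer(rep_len(multiplier, length(name))),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$charge != 0L), all(df$multiplier >= 1L))
  class(df) <- c("adduct_rules", "data.frame")
  df
}

#' Built-in adduct rules for one ion mode
#'
#' Protonation/deprotonation plus the common ESI cation and anion adducts,
#' with mass shifts from CODATA atomic masses (electron mass accounted
#' for).
#'
#' @param mode `"positive"` or `"negative"`
#' @return data.frame of class `adduct_rules`
#' @export
default_adduct_rules <- function(mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  if (mode == "positive") {
    adduct_rules(
      name = c("M+H", "M+Na", "M+K", "M+NH4"),
      mass_shift = c(PROTON_MASS, 22.98922, 38.96316, 18.03383),
      charge = 1L
    )
  } else {
    adduct_rules(
      name = c("M-H", "M+Cl", "M+FA-H"),
      mass_shift = c(-PROTON_MASS, 34.96940, 44.99820),
      charge = -1L
    )
  }
}

#' Read a reference compound library
#'
#' @param path CSV with header `name,neutral_mass,expected_rt,ion_modes`;
#'   `expected_rt` may be blank (unknown retention time); `ion_modes` is a
#'   `/`- or `;`-separated list of modes the standard was acquired in
#' @return data.frame of class `reference_library` with columns `name`,
#'   `neutral_mass` (Da), `expected_rt` (seconds, `NA` if absent),
#'   `ion_modes` (character)
#' @export
read_reference_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(expected_rt = "character"))
  required <- c("name", "neutral_mass", "expected_rt", "ion_modes")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("reference library '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mass <- suppressWarnings(as.numeric(df$neutral_mass))
  bad <- which(!is.finite(mass) | mass <= 0)
  if (length(bad)) {
    stop("non-numeric or non-positive neutral_mass in '", path,
         "' at data row(s) ", paste(bad, collapse = ", "), call. = FALSE)
  }
  df$neutral_mass <- mass
  rt_chr <- trimws(df$expected_rt)
  df$expected_rt <- suppressWarnings(as.numeric(rt_chr))
  bad_rt <- which(nzchar(rt_chr) & !is.finite(df$expected_rt))
  if (length(bad_rt)) {
    stop("non-numeric expected_rt in '", path, "' at data row(s) ",
         paste(bad_rt, collapse = ", "), call. = FALSE)
  }
  df <- df[, required]
  class(df) <- c("reference_library", "data.frame")
  df
}

#' Read an exclusion (contaminant) mass list
#'
#' @param path CSV with a single header column `mz`
#' @return numeric vector of m/z values
#' @export
read_exclusion_masses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"mz" %in% names(df)) {
    stop("exclusion list '", path, "' lacks an 'mz' column", call. = FALSE)
  }
  mz <- suppressWarnings(as.numeric(df$mz))
  bad <- which(!is.finite(mz) | mz <= 0)
  if (length(bad)) {
    stop("non-positive or non-numeric exclusion mass in '", path,
         "' at data row(s) ", paste(bad, collapse = ", "), call. = FALSE)
  }
  mz
}

#' Write a feature matrix as CSV
#'
#' One row per aligned feature group; columns: group id, consensus m/z,
#' consensus rt, annotation label, then one intensity column per sample.
#' Missing measurements are written as empty cells.
#'
#' @param matrix an `lcms_feature_matrix` (see [build_matrix()])
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_feature_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "lcms_feature_matrix"))
  out <- cbind(matrix$groups,
               as.data.frame(matrix$values,
                             col.names = matrix$sample_ids,
                             optional = TRUE))
  names(out) <- c(names(matrix$groups), matrix$sample_ids)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
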