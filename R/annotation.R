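# Isotope, adduct and identity annotation of feature sets.

#' Annotation parameters
#'
#' @param tol_ppm ppm tolerance for all mass-difference matching (> 0)
#' @param max_isotopes highest isotopologue index k (M+k) to annotate
#' @param isotope_max_ratio maximum allowed apex-intensity ratio of an
#'   isotope peak to its anchor (M+1 of small molecules is well below the
#'   monoisotopic peak; the default 1.1 leaves headroom for noise)
#' @return list of class `annotation_params`
#' @export
annotation_params <- function(tol_ppm = 10, max_isotopes = 3L,
                              isotope_max_ratio = 1.1) {
  stopifnot(tol_ppm > 0, max_isotopes >= 1L, isotope_max_ratio > 0)
  structure(list(tol_ppm = tol_ppm, max_isotopes = as.integer(max_isotopes),
                 isotope_max_ratio = isotope_max_ratio),
            class = "annotation_params")
}

#' m/z of a neutral mass under an adduct rule
#' @param neutral_mass neutral monoisotopic mass in Da
#' @param rule one row of an [adduct_rules()] table (data.frame or list)
#' @return observed m/z, `(multiplier * M + mass_shift) / |charge|`
#' @export
adduct_mz <- function(neutral_mass, rule) {
  (rule$multiplier * neutral_mass + rule$mass_shift) / abs(rule$charge)
}

#' Neutral mass implied by an observed m/z under an adduct rule
#'
#' Inverse of [adduct_mz()]: `(mz * |charge| - mass_shift) / multiplier`.
#' @param mz observed m/z in Thomson
#' @param rule one row of an [adduct_rules()] table
#' @return implied neutral mass in Da
#' @export
adduct_neutral_mass <- function(mz, rule) {
  (mz * abs(rule$charge) - rule$mass_shift) / rule$multiplier
}

rules_for_mode <- function(rules, mode) {
  if (mode == "positive") rules[rules$charge > 0L, , drop = FALSE]
  else if (mode == "negative") rules[rules$charge < 0L, , drop = FALSE]
  else rules
}

#' Annotate isotopologue peaks within a feature set
#'
#' Features are scanned in ascending m/z.  A feature q is annotated as the
#' M+k isotopologue of a lighter, non-isotope anchor p when the spacing
#' `mz(q) - mz(p)` matches `k * 1.0033548 / z` within `tol_ppm` for some
#' `k <= max_isotopes` and charge `z` in {1, 2} (charge inferred from the
#' spacing, singly charged preferred on ties), and q's apex intensity is at
#' most `isotope_max_ratio` times p's.  The annotation carries the anchor
#' as partner, the inferred charge, and the elution-profile similarity as
#' score.  Chains always anchor at the lightest non-isotope feature.
#'
#' @param fs a [feature_set()]
#' @param params an [annotation_params()] object
#' @return the feature set with isotope annotations added (features
#'   unchanged otherwise, order preserved)
#' @export
annotate_isotopes <- function(fs, params = annotation_params()) {
  stopifnot(inherits(fs, "lcms_feature_set"),
            inherits(params, "annotation_params"))
  feats <- fs$features
  n <- length(feats)
  if (n < 2L) return(fs)
  ord <- order(vapply(feats, `[[`, numeric(1), "mz"))
  mzs <- vapply(feats, `[[`, numeric(1), "mz")
  apex <- vapply(feats, apex_intensity, numeric(1))
  is_iso <- logical(n)
  for (qi in seq_along(ord)[-1L]) {
    q <- ord[qi]
    best <- NULL
    for (pi in seq_len(qi - 1L)) {
      p <- ord[pi]
      if (is_iso[p]) next
      delta <- mzs[q] - mzs[p]
      tol <- mzs[q] * params$tol_ppm * 1e-6
      for (z in 1:2) {
        for (k in seq_len(params$max_isotopes)) {
          err <- abs(delta - k * ISOTOPE_SPACING / z)
          if (err <= tol && apex[q] <= params$isotope_max_ratio * apex[p]) {
            if (is.null(best) || err < best$err) {
              best <- list(p = p, k = k, z = z, err = err)
            }
          }
        }
      }
    }
    if (!is.null(best)) {
      is_iso[q] <- TRUE
      feats[[q]]$annotations <- c(feats[[q]]$annotations, list(annotation(
        "isotope", sprintf("M+%d", best$k),
        partner_id = feats[[best$p]]$id,
        score = max(0, profile_inner_product(feats[[best$p]], feats[[q]])),
        charge = best$z)))
    }
  }
  out <- feature_set(fs$id, feats)
  out$neutral_mass <- fs$neutral_mass
  out
}

#' Annotate adduct pairs within a feature set
#'
#' For every feature pair and every pair of distinct mode-applicable
#' rules, the implied neutral masses ([adduct_neutral_mass()]) are
#' compared; agreement within `tol_ppm` annotates both features with
#' their rule names and mutual partner ids.  The mean of all agreeing
#' implied masses is recorded on the set as its consensus neutral mass.
#' Features already annotated as isotopologues are skipped (their
#' envelopes would otherwise pair up as spurious adducts one isotope
#' spacing off), so run [annotate_isotopes()] first.
#'
#' @param fs a [feature_set()]
#' @param rules an [adduct_rules()] table (non-empty)
#' @param mode ion mode of the sample; selects the applicable rules
#' @param params an [annotation_params()] object
#' @return the feature set with adduct annotations and, if any pair
#'   agreed, a consensus `neutral_mass`
#' @export
annotate_adducts <- function(fs, rules, mode = fs$ion_mode,
                             params = annotation_params()) {
  stopifnot(inherits(fs, "lcms_feature_set"), nrow(rules) > 0L,
            inherits(params, "annotation_params"))
  mode <- as_ion_mode(mode)
  rr <- rules_for_mode(rules, mode)
  if (nrow(rr) == 0L) {
    warning("no adduct rule applicable to ion mode '", mode,
            "'; set unchanged", call. = FALSE)
    return(fs)
  }
  feats <- fs$features
  n <- length(feats)
  if (n < 2L) return(fs)
  mzs <- vapply(feats, `[[`, numeric(1), "mz")
  implied <- sapply(seq_len(nrow(rr)), function(r) {
    adduct_neutral_mass(mzs, rr[r, ])
  })
  implied <- matrix(implied, nrow = n)  # features x rules
  agreeing <- numeric()
  has_label <- function(f, lab, partner) {
    any(vapply(f$annotations, function(a) {
      a$kind == "adduct" && a$label == lab &&
        identical(a$partner_id, partner)
    }, logical(1)))
  }
  iso <- vapply(feats, is_isotope_feature, logical(1))
  for (i in seq_len(n - 1L)) {
    if (iso[i]) next
    for (j in seq(i + 1L, n)) {
      if (iso[j]) next
      for (r1 in seq_len(nrow(rr))) {
        for (r2 in seq_len(nrow(rr))) {
          if (r1 == r2) next
          m1 <- implied[i, r1]
          m2 <- implied[j, r2]
          if (m1 <= 0 || m2 <= 0) next
          if (abs(m1 - m2) <= ((m1 + m2) / 2) * params$tol_ppm * 1e-6) {
            sc <- max(0, profile_inner_product(feats[[i]], feats[[j]]))
            if (!has_label(feats[[i]], rr$name[r1], feats[[j]]$id)) {
              feats[[i]]$annotations <- c(feats[[i]]$annotations,
                list(annotation("adduct", rr$name[r1],
                                partner_id = feats[[j]]$id, score = sc)))
            }
            if (!has_label(feats[[j]], rr$name[r2], feats[[i]]$id)) {
              feats[[j]]$annotations <- c(feats[[j]]$annotations,
                list(annotation("adduct", rr$name[r2],
                                partner_id = feats[[i]]$id, score = sc)))
            }
            agreeing <- c(agreeing, m1, m2)
          }
        }
      }
    }
  }
  out <- feature_set(fs$id, feats)
  out$neutral_mass <- if (length(agreeing)) mean(agreeing) else fs$neutral_mass
  out
}

#' Adduct labels carried by a feature
#' @param f an [feature()] object
#' @return character vector of adduct annotation labels (may be empty)
#' @export
feature_adduct_labels <- function(f) {
  vapply(Filter(function(a) a$kind == "adduct", f$annotations),
         `[[`, character(1), "label")
}

#' Is a feature annotated as an isotopologue peak?
#' @param f an [feature()] object
#' @return logical scalar
#' @export
is_isotope_feature <- function(f) {
  any(vapply(f$annotations, function(a) a$kind == "isotope", logical(1)))
}

#' Main peak of a feature set
#'
#' The protonated (M+H, positive mode) or deprotonated (M-H, negative
#' mode) feature if annotated; otherwise the non-isotope feature with the
#' highest apex intensity, ties broken by lowest m/z.
#'
#' @param fs a [feature_set()]
#' @param mode ion mode deciding which adduct label designates the main
#'   peak
#' @return an [feature()] object
#' @export
main_peak <- function(fs, mode = fs$ion_mode) {
  stopifnot(inherits(fs, "lcms_feature_set"), length(fs$features) >= 1L)
  mode <- as_ion_mode(mode)
  want <- if (mode == "negative") "M-H" else "M+H"
  for (f in fs$features) {
    if (want %in% feature_adduct_labels(f)) return(f)
  }
  cand <- Filter(Negate(is_isotope_feature), fs$features)
  if (!length(cand)) cand <- fs$features
  apex <- vapply(cand, apex_intensity, numeric(1))
  mzs <- vapply(cand, `[[`, numeric(1), "mz")
  best <- which(apex == max(apex))
  cand[[best[which.min(mzs[best])]]]
}

#' Match feature sets against a reference library
#'
#' A feature set matches a library entry when some member feature's m/z
#' lies within `tol_ppm` of the entry's neutral mass transformed by some
#' mode-applicable adduct rule, and either the entry has no expected
#' retention time or the set rt agrees within `rt_tol`.  All candidate
#' matches are reported (no forced uniqueness); matched members gain an
#' identity annotation with the compound name.
#'
#' @param fs_list list of [feature_set()] objects
#' @param library a [read_reference_library()] table
#' @param rules an [adduct_rules()] table
#' @param mode ion mode of the sample
#' @param tol_ppm m/z tolerance in ppm
#' @param rt_tol retention-time tolerance in seconds
#' @return list with `matches` (data.frame: set_id, compound, rule,
#'   feature_id, mz_error_ppm, rt_error_s) and `feature_sets` (the input
#'   list with identity annotations added)
#' @export
match_reference <- function(fs_list, library, rules, mode,
                            tol_ppm = 10, rt_tol = 10) {
  stopifnot(nrow(library) > 0L, tol_ppm > 0, rt_tol > 0)
  mode <- as_ion_mode(mode)
  rr <- rules_for_mode(rules, mode)
  rows <- list()
  for (si in seq_along(fs_list)) {
    fs <- fs_list[[si]]
    for (ei in seq_len(nrow(library))) {
      entry <- library[ei, ]
      rt_err <- if (is.na(entry$expected_rt)) NA_real_
                else fs$rt - entry$expected_rt
      if (!is.na(rt_err) && abs(rt_err) > rt_tol) next
      for (ri in seq_len(nrow(rr))) {
        expected <- adduct_mz(entry$neutral_mass, rr[ri, ])
        if (expected <= 0) next
        for (fi in seq_along(fs$features)) {
          f <- fs$features[[fi]]
          err_ppm <- (f$mz - expected) / expected * 1e6
          if (abs(err_ppm) <= tol_ppm) {
            fs$features[[fi]]$annotations <-
              c(fs$features[[fi]]$annotations,
                list(annotation("identity", entry$name, score = 1)))
            rows[[length(rows) + 1L]] <- data.frame(
              set_id = fs$id, compound = entry$name, rule = rr$name[ri],
              feature_id = f$id, mz_error_ppm = err_ppm,
              rt_error_s = rt_err, stringsAsFactors = FALSE)
          }
        }
      }
    }
    fs_list[[si]] <- fs
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set_id = character(), compound = character(),
               rule = character(), feature_id = character(),
               mz_error_ppm = numeric(), rt_error_s = numeric(),
               stringsAsFactors = FALSE)
  attr(fs_list, "cell_kind") <- "feature_sets"
  list(matches = matches, feature_sets = fs_list)
}
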