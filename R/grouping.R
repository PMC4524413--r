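# Grouping of co-eluting features into feature sets (compound spectra).
#
# Ions derived from one compound (adducts, isotopologues, in-source
# fragments) elute together: their chromatographic profiles coincide.  Two
# features are linked when their characteristic retention times agree
# within a tolerance AND the normalised inner product (cosine) of their
# elution profiles exceeds a similarity threshold; connected components of
# that graph become feature sets.

#' Grouping parameters
#'
#' @param rt_tol maximum difference of characteristic retention times in
#'   seconds for two features to be linked (> 0)
#' @param min_similarity minimum elution-profile cosine similarity in
#'   `[0, 1]`
#' @return list of class `grouping_params`
#' @export
grouping_params <- function(rt_tol = 5, min_similarity = 0.9) {
  stopifnot(rt_tol > 0, min_similarity >= 0, min_similarity <= 1)
  structure(list(rt_tol = rt_tol, min_similarity = min_similarity),
            class = "grouping_params")
}

#' Elution-profile similarity of two features
#'
#' Both intensity traces are resampled by linear interpolation onto the
#' union of their time points restricted to the overlap of their spans
#' (a feature contributes zero outside its own span); the value is the
#' normalised inner product (cosine) of the two resampled vectors.
#' Disjoint elution windows, or an all-zero trace, give 0; a feature with
#' itself gives 1.
#'
#' @param a,b [feature()] objects from the same sample
#' @return similarity in `[0, 1]`
#' @export
profile_inner_product <- function(a, b) {
  stopifnot(inherits(a, "lcms_feature"), inherits(b, "lcms_feature"))
  lo <- max(a$times[1L], b$times[1L])
  hi <- min(a$times[length(a$times)], b$times[length(b$times)])
  if (lo > hi) return(0)
  grid <- sort(unique(c(a$times, b$times)))
  grid <- grid[grid >= lo & grid <= hi]
  if (!length(grid)) return(0)
  resample <- function(f) {
    if (length(f$times) == 1L) {
      return(ifelse(grid == f$times, f$intensities, 0))
    }
    stats::approx(f$times, f$intensities, xout = grid, rule = 2L)$y
  }
  va <- resample(a)
  vb <- resample(b)
  na <- sqrt(sum(va^2))
  nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(0)
  min(1, sum(va * vb) / (na * nb))
}

#' Group co-eluting features into feature sets
#'
#' Builds the graph linking feature pairs with `|delta rt| <= rt_tol` and
#' [profile_inner_product()] `>= min_similarity`, and returns one feature
#' set per connected component (single linkage, so chains of pairwise
#' similar ions end up together).  Every input feature appears in exactly
#' one output set; features linked to nothing become singleton sets.  The
#' set retention time is the mean of the member characteristic rts.
#'
#' @param features list of [feature()] objects from one sample and one ion
#'   mode
#' @param params a [grouping_params()] object
#' @return list of [feature_set()] objects, ordered by retention time
#' @export
group_features <- function(features, params = grouping_params()) {
  stopifnot(inherits(params, "grouping_params"))
  n <- length(features)
  if (n == 0L) return(structure(list(), cell_kind = "feature_sets"))
  modes <- unique(vapply(features, `[[`, character(1), "ion_mode"))
  if (length(modes) > 1L) {
    stop("group_features requires a single ion mode (found: ",
         paste(modes, collapse = ", "), ")", call. = FALSE)
  }
  rts <- vapply(features, `[[`, numeric(1), "rt")
  # union-find over rt-gated, similarity-passing pairs
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(rts)
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    for (b in seq((a + 1L), n)) {
      if (b > n) break
      j <- ord[b]
      if (rts[j] - rts[i] > params$rt_tol) break
      if (profile_inner_product(features[[i]], features[[j]]) >=
            params$min_similarity) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), roots)
  sets <- lapply(seq_along(comps), function(k) {
    members <- features[comps[[k]]]
    members <- members[order(vapply(members, `[[`, numeric(1), "mz"))]
    feature_set(sprintf("FS%04d", k), members)
  })
  sets <- sets[order(vapply(sets, `[[`, numeric(1), "rt"))]
  for (k in seq_along(sets)) sets[[k]]$id <- sprintf("FS%04d", k)
  attr(sets, "cell_kind") <- "feature_sets"
  sets
}
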