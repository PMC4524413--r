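# Ground-truth synthetic LC-MS sample generation.
#
# Emulates reference-standard runs: each compound elutes as a Gaussian
# chromatographic peak and appears as one trace per requested adduct plus
# its 13C isotopologue envelope, on top of random chemical noise peaks and
# an optional linear baseline.  Profile mode renders every stick as a
# sampled Gaussian of instrument width.  A truth manifest records every
# injected trace, so recall and precision of every processing stage can be
# scored without external data.

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Specification of one synthetic compound
#'
#' @param name compound name
#' @param neutral_mass monoisotopic neutral mass in Da
#' @param rt elution apex in seconds
#' @param peak_sigma Gaussian chromatographic peak width (sigma) in seconds
#' @param apex_intensity apex counts of the most abundant adduct trace
#' @param adducts names of adduct rules to emit (must exist in the rule
#'   table passed to [generate_sample()])
#' @param isotope_ratios intensity ratios of M+1, M+2, ... relative to the
#'   monoisotopic peak; the default is a crude carbon-count heuristic
#'   (M+1 ratio 0.011 x round(mass / 14), M+2 its square over two) --
#'   synthetic, not chemically exact
#' @return list of class `compound_spec`
#' @export
compound_spec <- function(name, neutral_mass, rt, peak_sigma = 6,
                          apex_intensity = 1e5, adducts = "M+H",
                          isotope_ratios = NULL) {
  stopifnot(neutral_mass > 0, rt >= 0, peak_sigma > 0, apex_intensity > 0,
            length(adducts) >= 1L)
  if (is.null(isotope_ratios)) {
    r1 <- min(1, 0.011 * round(neutral_mass / 14))
    isotope_ratios <- c(r1, r1^2 / 2)
  }
  stopifnot(all(isotope_ratios >= 0), all(isotope_ratios <= 1))
  structure(list(name = as.character(name), neutral_mass = neutral_mass,
                 rt = rt, peak_sigma = peak_sigma,
                 apex_intensity = apex_intensity,
                 adducts = as.character(adducts),
                 isotope_ratios = isotope_ratios),
            class = "compound_spec")
}

#' Noise model for synthetic samples
#'
#' @param chemical_noise_density mean number of random noise peaks per scan
#'   (Poisson)
#' @param noise_intensity_scale mean intensity of noise peaks (exponential)
#' @param baseline_drift linear baseline slope in counts per second, added
#'   to every emitted peak intensity
#' @param mz_jitter_ppm Gaussian per-peak m/z jitter (ppm)
#' @param rt_jitter_s uniform jitter applied once per compound to its
#'   elution apex (run-to-run retention variation)
#' @param seed integer RNG seed; identical seeds give byte-identical files
#' @return list of class `noise_spec`
#' @export
noise_spec <- function(chemical_noise_density = 5,
                       noise_intensity_scale = 100,
                       baseline_drift = 0, mz_jitter_ppm = 2,
                       rt_jitter_s = 0, seed = 1L) {
  stopifnot(chemical_noise_density >= 0, noise_intensity_scale >= 0,
            baseline_drift >= 0, mz_jitter_ppm >= 0, rt_jitter_s >= 0)
  structure(list(chemical_noise_density = chemical_noise_density,
                 noise_intensity_scale = noise_intensity_scale,
                 baseline_drift = baseline_drift,
                 mz_jitter_ppm = mz_jitter_ppm,
                 rt_jitter_s = rt_jitter_s, seed = as.integer(seed)),
            class = "noise_spec")
}

render_profile <- function(mz, intensity, resolving_power) {
  if (!length(mz)) return(list(mz = numeric(), intensity = numeric()))
  o <- order(mz)
  mz <- mz[o]
  intensity <- intensity[o]
  sigma <- mz / resolving_power / 2.3548
  # cluster sticks whose 4-sigma windows touch, render each cluster on a
  # uniform local grid at one third of the narrowest peak sigma
  gaps <- c(Inf, diff(mz))
  cluster <- cumsum(gaps > 8 * sigma)
  out_mz <- list()
  out_int <- list()
  for (cl in unique(cluster)) {
    idx <- which(cluster == cl)
    s <- sigma[idx]
    grid <- seq(mz[idx[1L]] - 4 * max(s), mz[idx[length(idx)]] + 4 * max(s),
                by = min(s) / 3)
    y <- rep(0, length(grid))
    for (j in idx) {
      y <- y + intensity[j] * exp(-(grid - mz[j])^2 / (2 * sigma[j]^2))
    }
    out_mz[[length(out_mz) + 1L]] <- grid
    out_int[[length(out_int) + 1L]] <- y
  }
  list(mz = unlist(out_mz), intensity = unlist(out_int))
}

#' Generate one synthetic LC-MS run with ground truth
#'
#' Scans are emitted every `scan_interval` seconds over `duration`.  Each
#' compound contributes, per listed adduct, a Gaussian elution profile at
#' the adduct m/z plus isotopologue peaks at `+k * 1.0033548 / |z|` scaled
#' by its isotope ratios.  Chemical noise peaks (uniform m/z,
#' exponential intensity, Poisson count per scan) and a linear baseline
#' are added, and every emitted peak m/z receives Gaussian ppm jitter.
#' The manifest records every injected trace's true m/z, retention time,
#' adduct, isotope index and apex intensity.
#'
#' @param compounds list of [compound_spec()] objects
#' @param noise a [noise_spec()] object
#' @param mode ion mode of the run ("positive" or "negative")
#' @param scan_interval seconds between MS1 scans (> 0)
#' @param duration run length in seconds (> 0)
#' @param profile render profile-mode spectra instead of centroids
#' @param path if non-`NULL`, write the run as mzML here
#' @param rules adduct rule table resolving the compounds' adduct names
#' @param mz_range m/z range of the instrument (bounds for noise peaks)
#' @param resolving_power instrument resolving power (FWHM-based) used for
#'   profile rendering
#' @param id sample identifier
#' @return list with `sample` (an [lcms_sample()]), `truth` (manifest
#'   data.frame: compound, adduct, isotope, charge, mz, rt, apex) and
#'   `path` (the mzML path, or `NULL`)
#' @export
generate_sample <- function(compounds, noise = noise_spec(),
                            mode = "positive", scan_interval = 1,
                            duration = 960, profile = FALSE, path = NULL,
                            rules = default_adduct_rules(
                              if (identical(mode, "negative")) "negative"
                              else "positive"),
                            mz_range = c(50, 1000),
                            resolving_power = 30000,
                            id = "synthetic") {
  stopifnot(duration > 0, scan_interval > 0)
  mode <- as_ion_mode(mode)
  restore <- local_seed(noise$seed)
  on.exit(restore())
  scan_times <- seq(0, duration, by = scan_interval)
  n_scans <- length(scan_times)
  scan_mz <- vector("list", n_scans)
  scan_int <- vector("list", n_scans)
  truth <- list()
  for (cp in compounds) {
    stopifnot(inherits(cp, "compound_spec"))
    rt_true <- cp$rt + if (noise$rt_jitter_s > 0) {
      stats::runif(1, -noise$rt_jitter_s, noise$rt_jitter_s)
    } else 0
    for (ad in cp$adducts) {
      ri <- which(rules$name == ad)
      if (!length(ri)) {
        stop("unknown adduct rule '", ad, "' for compound ", cp$name,
             call. = FALSE)
      }
      rule <- rules[ri[1L], ]
      base_mz <- adduct_mz(cp$neutral_mass, rule)
      z <- abs(rule$charge)
      for (k in 0:length(cp$isotope_ratios)) {
        scale <- if (k == 0L) 1 else cp$isotope_ratios[k]
        if (scale <= 0) next
        mz_k <- base_mz + k * ISOTOPE_SPACING / z
        apex_k <- cp$apex_intensity * scale
        truth[[length(truth) + 1L]] <- data.frame(
          compound = cp$name, adduct = ad, isotope = k, charge = z,
          mz = mz_k, rt = rt_true, apex = apex_k,
          stringsAsFactors = FALSE)
        in_window <- which(abs(scan_times - rt_true) <= 4 * cp$peak_sigma)
        for (si in in_window) {
          inten <- apex_k *
            exp(-(scan_times[si] - rt_true)^2 / (2 * cp$peak_sigma^2))
          jit <- if (noise$mz_jitter_ppm > 0) {
            1 + stats::rnorm(1) * noise$mz_jitter_ppm * 1e-6
          } else 1
          scan_mz[[si]] <- c(scan_mz[[si]], mz_k * jit)
          scan_int[[si]] <- c(scan_int[[si]], inten)
        }
      }
    }
  }
  scans <- vector("list", n_scans)
  for (si in seq_len(n_scans)) {
    mzs <- scan_mz[[si]]
    ints <- scan_int[[si]]
    if (noise$chemical_noise_density > 0) {
      n_noise <- stats::rpois(1, noise$chemical_noise_density)
      if (n_noise > 0) {
        mzs <- c(mzs, stats::runif(n_noise, mz_range[1L], mz_range[2L]))
        ints <- c(ints, stats::rexp(n_noise, 1 / noise$noise_intensity_scale))
      }
    }
    if (noise$baseline_drift > 0 && length(ints)) {
      ints <- ints + noise$baseline_drift * scan_times[si]
    }
    if (profile) {
      rendered <- render_profile(mzs, ints, resolving_power)
      mzs <- rendered$mz
      ints <- rendered$intensity
    }
    scans[[si]] <- ms_scan(si - 1L, scan_times[si], mzs, ints,
                        ms_level = 1L, ion_mode = mode,
                        centroided = !profile)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(compound = character(), adduct = character(),
               isotope = integer(), charge = integer(), mz = numeric(),
               rt = numeric(), apex = numeric(), stringsAsFactors = FALSE)
  smp <- lcms_sample(id, scans)
  if (!is.null(path)) write_mzml(smp, path)
  list(sample = smp, truth = truth, path = path)
}

#' Generate a suite of reference-standard runs plus their library
#'
#' Emulates a standards campaign: random compounds with neutral masses in
#' [100, 600] Da and retention times in [60, 900] s, each acquired as its
#' own run -- `n_pos` compounds in positive mode only, `n_neg` in negative
#' mode only, and `n_both` in both modes (two runs each).  The matching
#' reference library CSV (one row per compound, with expected rt and ion
#' modes) is written alongside.  Deterministic under `seed`.
#'
#' @param n_pos,n_neg,n_both compound counts per mode category (>= 0)
#' @param seed integer master seed
#' @param dir output directory for mzML files and the library CSV
#' @param profile render profile-mode spectra (exercises the centroider)
#' @param noise_template a [noise_spec()] whose fields (except seed) apply
#'   to every run
#' @param scan_interval,duration acquisition grid passed to
#'   [generate_sample()]
#' @return list with `runs` (data.frame: path, compound, mode, sample_id),
#'   `library_csv` (path), `library` (data.frame), `truth` (combined
#'   manifest with a sample_id column) and `compounds`
#' @export
generate_standards_suite <- function(n_pos = 30L, n_neg = 16L,
                                     n_both = 12L, seed = 1L,
                                     dir = tempfile("standards_"),
                                     profile = FALSE,
                                     noise_template = noise_spec(),
                                     scan_interval = 1, duration = 960) {
  stopifnot(n_pos >= 0, n_neg >= 0, n_both >= 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  restore <- local_seed(seed)
  on.exit(restore())
  n <- n_pos + n_neg + n_both
  modes <- c(rep("positive", n_pos), rep("negative", n_neg),
             rep("both", n_both))
  lib <- data.frame(
    name = sprintf("STD%03d", seq_len(n)),
    neutral_mass = if (n) stats::runif(n, 100, 600) else numeric(),
    expected_rt = if (n) stats::runif(n, 60, 900) else numeric(),
    ion_modes = c("positive", "negative",
                  "positive/negative")[match(modes,
                                             c("positive", "negative",
                                               "both"))],
    stringsAsFactors = FALSE)
  sigmas <- if (n) stats::runif(n, 4, 8) else numeric()
  apexes <- if (n) 10^stats::runif(n, 4.7, 5.5) else numeric()
  run_seeds <- if (n) sample.int(.Machine$integer.max - 1L, 2L * n) else
    integer()
  compounds <- vector("list", n)
  runs <- list()
  ri <- 0L
  for (i in seq_len(n)) {
    run_modes <- if (modes[i] == "both") c("positive", "negative") else
      modes[i]
    for (m in run_modes) {
      ri <- ri + 1L
      cp <- compound_spec(
        name = lib$name[i], neutral_mass = lib$neutral_mass[i],
        rt = lib$expected_rt[i], peak_sigma = sigmas[i],
        apex_intensity = apexes[i],
        adducts = if (m == "positive") c("M+H", "M+Na") else
          c("M-H", "M+Cl"))
      compounds[[i]] <- cp
      sid <- sprintf("%s_%s", lib$name[i], substr(m, 1, 3))
      ns <- noise_template
      ns$seed <- run_seeds[ri]
      out <- generate_sample(
        list(cp), noise = ns, mode = m, scan_interval = scan_interval,
        duration = duration, profile = profile,
        path = file.path(dir, paste0(sid, ".mzML")), id = sid)
      tr <- out$truth
      tr$sample_id <- sid
      runs[[ri]] <- list(
        row = data.frame(path = out$path, compound = lib$name[i],
                         mode = m, sample_id = sid,
                         stringsAsFactors = FALSE),
        truth = tr)
    }
  }
  library_csv <- file.path(dir, "reference_library.csv")
  utils::write.csv(lib, library_csv, row.names = FALSE, na = "")
  run_df <- if (length(runs)) do.call(rbind, lapply(runs, `[[`, "row")) else
    data.frame(path = character(), compound = character(),
               mode = character(), sample_id = character(),
               stringsAsFactors = FALSE)
  truth <- if (length(runs)) do.call(rbind, lapply(runs, `[[`, "truth")) else
    data.frame()
  list(runs = run_df, library_csv = library_csv, library = lib,
       truth = truth, compounds = compounds)
}
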