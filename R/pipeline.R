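# Typed stage-graph executor.
#
# A workflow is a DAG of named stages.  Every stage consumes one cell kind
# ("sample", "features" or "feature_sets"; sources consume "none") and
# produces one; an edge is valid only when the producer's out-kind equals
# the consumer's in-kind, so a workflow that passes validation can never
# hit a kind mismatch at run time.  Each input file is processed
# independently (batch isolation); after every stage the output can be
# snapshotted, and execution can later resume from any snapshot with
# changed downstream parameters.

# ---- stage registry --------------------------------------------------------

check_num <- function(lo = -Inf, hi = Inf) {
  function(x) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo ||
        x > hi) {
      sprintf("expected a number in [%s, %s]", format(lo), format(hi))
    } else TRUE
  }
}
check_numvec <- function(x) {
  if (!is.numeric(x) || !length(x)) "expected a non-empty numeric vector"
  else TRUE
}
check_table_or_path <- function(x) {
  if (is.character(x) && length(x) == 1L) TRUE
  else if (is.data.frame(x)) TRUE
  else "expected a data.frame or a CSV path"
}

resolve_rules <- function(x) {
  if (is.data.frame(x)) x else read_adduct_table(x)
}
resolve_library <- function(x) {
  if (is.data.frame(x)) x else read_reference_library(x)
}
resolve_masses <- function(x) {
  if (is.character(x)) read_exclusion_masses(x) else as.numeric(x)
}

stage_registry <- new.env(parent = emptyenv())

register_stage <- function(method, in_kind, out_kind, schema, fn) {
  assign(method, list(method = method, in_kind = in_kind,
                      out_kind = out_kind, schema = schema, fn = fn),
         envir = stage_registry)
}

#' Available pipeline stage methods
#' @return data.frame with columns method, in_kind, out_kind
#' @export
list_stages <- function() {
  entries <- lapply(ls(stage_registry), get, envir = stage_registry)
  df <- do.call(rbind, lapply(entries, function(e) {
    data.frame(method = e$method, in_kind = e$in_kind,
               out_kind = e$out_kind, stringsAsFactors = FALSE)
  }))
  df[order(df$method), ]
}

local({
  register_stage("read_mzml", "none", "sample", list(), {
    function(input, p, ctx) read_mzml(ctx$path)
  })
  register_stage("centroid", "sample", "sample", list(
    scales = check_numvec, min_snr = check_num(0), window_ppm = check_num(0)
  ), function(input, p, ctx) {
    centroid_sample(input, do.call(centroid_params, p))
  })
  register_stage("intensity_threshold", "sample", "sample", list(
    min_intensity = check_num(0)
  ), function(input, p, ctx) {
    intensity_threshold(input, p$min_intensity %||% 0)
  })
  register_stage("range_filter", "sample", "sample", list(
    mz_min = check_num(0), mz_max = check_num(0),
    rt_min = check_num(0), rt_max = check_num(0)
  ), function(input, p, ctx) {
    range_filter(input, do.call(range_filter_params, p))
  })
  register_stage("extract", "sample", "features", list(
    tol_ppm = check_num(0), max_gap_scans = check_num(0),
    min_intensity = check_num(0)
  ), function(input, p, ctx) {
    extract_features(input, do.call(trace_params, p))
  })
  register_stage("width_filter", "features", "features", list(
    min_scans = check_num(1)
  ), function(input, p, ctx) {
    scan_width_filter(input, p$min_scans %||% 1)
  })
  register_stage("exclusion", "features", "features", list(
    masses = function(x) {
      if (is.character(x) || is.numeric(x)) TRUE
      else "expected a numeric vector or a CSV path"
    },
    tol_ppm = check_num(0)
  ), function(input, p, ctx) {
    exclusion_filter(input, resolve_masses(p$masses %||% numeric()),
                     p$tol_ppm %||% 10)
  })
  register_stage("baseline", "features", "features", list(
    asymmetry = check_num(0, 1), smoothness = check_num(0)
  ), function(input, p, ctx) {
    out <- lapply(input, baseline_correct,
                  asymmetry = p$asymmetry %||% 0.01,
                  smoothness = p$smoothness %||% 1e4)
    attr(out, "cell_kind") <- "features"
    out
  })
  register_stage("deconvolve", "features", "features", list(
    sg_window = check_num(5), valley_fraction = check_num(0, 1),
    min_snr = check_num(0)
  ), function(input, p, ctx) {
    deconvolve_features(input, do.call(deconvolution_params, p))
  })
  register_stage("group", "features", "feature_sets", list(
    rt_tol = check_num(0), min_similarity = check_num(0, 1)
  ), function(input, p, ctx) {
    group_features(input, do.call(grouping_params, p))
  })
  register_stage("isotopes", "feature_sets", "feature_sets", list(
    tol_ppm = check_num(0), max_isotopes = check_num(1),
    isotope_max_ratio = check_num(0)
  ), function(input, p, ctx) {
    out <- lapply(input, annotate_isotopes,
                  params = do.call(annotation_params, p))
    attr(out, "cell_kind") <- "feature_sets"
    out
  })
  register_stage("adducts", "feature_sets", "feature_sets", list(
    rules = check_table_or_path, tol_ppm = check_num(0)
  ), function(input, p, ctx) {
    rules <- if (is.null(p$rules)) default_adduct_rules(
      if (ctx$ion_mode == "negative") "negative" else "positive")
    else resolve_rules(p$rules)
    ap <- annotation_params(tol_ppm = p$tol_ppm %||% 10)
    out <- lapply(input, annotate_adducts, rules = rules,
                  mode = ctx$ion_mode, params = ap)
    attr(out, "cell_kind") <- "feature_sets"
    out
  })
  register_stage("match", "feature_sets", "feature_sets", list(
    library = check_table_or_path, rules = check_table_or_path,
    tol_ppm = check_num(0), rt_tol = check_num(0)
  ), function(input, p, ctx) {
    rules <- if (is.null(p$rules)) default_adduct_rules(
      if (ctx$ion_mode == "negative") "negative" else "positive")
    else resolve_rules(p$rules)
    res <- match_reference(input, resolve_library(p$library), rules,
                           mode = ctx$ion_mode,
                           tol_ppm = p$tol_ppm %||% 10,
                           rt_tol = p$rt_tol %||% 10)
    ctx$record_matches(res$matches)
    res$feature_sets
  })
})

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- workflow specification ------------------------------------------------

#' Define a workflow
#'
#' @param stages named list; each element is `list(method = <registry
#'   method>, params = <named list>)`.  A parameter may be mode-specific by
#'   giving `list(positive = ..., negative = ...)`; the variant matching
#'   each sample's ion mode is selected at run time.
#' @param edges optional list of `c(producer, consumer)` stage-name pairs;
#'   if omitted the stages form a linear chain in list order
#' @param snapshot_dir if set, every stage output of every sample is
#'   serialised here via [write_snapshot()]
#' @param options named list: `seed` (integer, applied per sample before
#'   execution), `ion_mode` (override when files carry no polarity)
#' @return object of class `lcms_workflow`
#' @export
workflow <- function(stages, edges = NULL, snapshot_dir = NULL,
                     options = list()) {
  stopifnot(is.list(stages), length(stages) >= 1L,
            !is.null(names(stages)), all(nzchar(names(stages))))
  if (is.null(edges)) {
    nm <- names(stages)
    edges <- if (length(nm) > 1L) {
      lapply(seq_len(length(nm) - 1L), function(i) c(nm[i], nm[i + 1L]))
    } else list()
  }
  structure(list(stages = stages, edges = edges,
                 snapshot_dir = snapshot_dir, options = options),
            class = "lcms_workflow")
}

#' Read a workflow from a YAML file
#'
#' Layout: a top-level `stages` list (each entry: `name`, `method`,
#' optional `params`), optional `edges` (list of `[from, to]` pairs),
#' optional `snapshot_dir` and `options`.
#'
#' @param path YAML file path
#' @return an `lcms_workflow`
#' @export
read_workflow <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$stages)) stop("workflow file lacks 'stages'", call. = FALSE)
  stages <- list()
  for (st in doc$stages) {
    if (is.null(st$name) || is.null(st$method)) {
      stop("every stage needs 'name' and 'method'", call. = FALSE)
    }
    stages[[st$name]] <- list(method = st$method,
                              params = st$params %||% list())
  }
  edges <- if (is.null(doc$edges)) NULL else
    lapply(doc$edges, function(e) c(e[[1L]], e[[2L]]))
  workflow(stages, edges, snapshot_dir = doc$snapshot_dir,
           options = doc$options %||% list())
}

stage_def <- function(method) {
  if (!exists(method, envir = stage_registry)) return(NULL)
  get(method, envir = stage_registry)
}

topo_order <- function(names, edges) {
  incoming <- stats::setNames(rep(0L, length(names)), names)
  adj <- stats::setNames(vector("list", length(names)), names)
  for (e in edges) {
    adj[[e[1L]]] <- c(adj[[e[1L]]], e[2L])
    incoming[e[2L]] <- incoming[e[2L]] + 1L
  }
  queue <- names[incoming[names] == 0L]
  out <- character()
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, v)
    for (w in adj[[v]]) {
      incoming[w] <- incoming[w] - 1L
      if (incoming[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) < length(names)) NULL else out
}

is_mode_variant <- function(v) {
  is.list(v) && !is.null(names(v)) && length(v) > 0L &&
    all(names(v) %in% c("positive", "negative"))
}

#' Validate a workflow
#'
#' Checks, without executing anything: every stage method exists; the
#' graph is acyclic; every edge connects a producer whose out-kind equals
#' the consumer's in-kind; every non-source in-port is fed by exactly one
#' producer (sources by none); and all parameters pass their stage's
#' declared schema.  Problems are returned as data, not raised.
#'
#' @param wf an [workflow()] object
#' @return character vector of problems; empty when the workflow is valid
#' @export
validate_workflow <- function(wf) {
  stopifnot(inherits(wf, "lcms_workflow"))
  problems <- character()
  nm <- names(wf$stages)
  if (anyDuplicated(nm)) {
    problems <- c(problems, "duplicate stage names")
  }
  for (e in wf$edges) {
    for (v in e) {
      if (!v %in% nm) {
        problems <- c(problems, sprintf("edge references unknown stage '%s'", v))
      }
    }
  }
  defs <- lapply(wf$stages, function(st) stage_def(st$method))
  for (i in seq_along(nm)) {
    st <- wf$stages[[i]]
    def <- defs[[i]]
    if (is.null(def)) {
      problems <- c(problems,
                    sprintf("stage '%s': unknown method '%s'", nm[i],
                            st$method))
      next
    }
    for (pn in names(st$params)) {
      if (!pn %in% names(def$schema)) {
        problems <- c(problems,
                      sprintf("stage '%s': unknown parameter '%s'", nm[i], pn))
        next
      }
      val <- st$params[[pn]]
      variants <- if (is_mode_variant(val)) val else list(val)
      for (v in variants) {
        res <- def$schema[[pn]](v)
        if (!isTRUE(res)) {
          problems <- c(problems,
                        sprintf("stage '%s': parameter '%s': %s", nm[i], pn,
                                res))
        }
      }
    }
  }
  ok_edges <- Filter(function(e) all(e %in% nm), wf$edges)
  if (is.null(topo_order(nm, ok_edges))) {
    problems <- c(problems, "workflow graph contains a cycle")
  }
  fed <- table(vapply(ok_edges, `[[`, character(1), 2L))
  for (i in seq_along(nm)) {
    def <- defs[[i]]
    if (is.null(def)) next
    n_in <- if (nm[i] %in% names(fed)) fed[[nm[i]]] else 0L
    if (def$in_kind == "none") {
      if (n_in > 0L) {
        problems <- c(problems,
                      sprintf("stage '%s' is a source but has an incoming edge",
                              nm[i]))
      }
    } else if (n_in == 0L) {
      problems <- c(problems,
                    sprintf("stage '%s' has an unfed in-port (needs '%s')",
                            nm[i], def$in_kind))
    } else if (n_in > 1L) {
      problems <- c(problems,
                    sprintf("stage '%s' in-port fed by %d producers", nm[i],
                            n_in))
    }
  }
  for (e in ok_edges) {
    dp <- stage_def(wf$stages[[e[1L]]]$method)
    dc <- stage_def(wf$stages[[e[2L]]]$method)
    if (is.null(dp) || is.null(dc)) next
    if (dc$in_kind != "none" && dp$out_kind != dc$in_kind) {
      problems <- c(problems,
                    sprintf("edge %s -> %s: kind mismatch ('%s' produced, '%s' required)",
                            e[1L], e[2L], dp$out_kind, dc$in_kind))
    }
  }
  problems
}

# ---- execution -------------------------------------------------------------

resolve_stage_params <- function(params, mode) {
  out <- list()
  for (pn in names(params)) {
    v <- params[[pn]]
    if (is_mode_variant(v)) {
      if (!mode %in% names(v)) {
        stop("parameter '", pn, "' has no variant for ion mode '", mode,
             "'", call. = FALSE)
      }
      v <- v[[mode]]
    }
    out[[pn]] <- v
  }
  out
}

obj_ion_mode <- function(obj) {
  kind <- cell_kind(obj)
  modes <- switch(kind,
    sample = setdiff(obj$ion_modes, "unknown"),
    features = unique(vapply(obj, `[[`, character(1), "ion_mode")),
    feature_sets = unique(vapply(obj, `[[`, character(1), "ion_mode")),
    character())
  modes <- setdiff(modes, "unknown")
  if (length(modes) == 1L) modes else "unknown"
}

result_count <- function(obj) {
  switch(cell_kind(obj),
         sample = length(obj$scans),
         features = length(obj),
         feature_sets = length(obj),
         feature_matrix = nrow(obj$values),
         NA_integer_)
}

snapshot_path <- function(dir, sample_id, stage) {
  file.path(dir, sprintf("%s__%s.mcc", sample_id, stage))
}

sample_id_for <- function(path) tools::file_path_sans_ext(basename(path))

has_mode_variants <- function(wf) {
  any(vapply(wf$stages, function(st) {
    any(vapply(st$params, is_mode_variant, logical(1)))
  }, logical(1)))
}

run_one <- function(wf, path, order, start_at, snapshot_dir, seed,
                    mode_override) {
  sample_id <- sample_id_for(path)
  rows <- list()
  matches <- list()
  ctx <- new.env()
  ctx$path <- path
  ctx$ion_mode <- mode_override %||% "unknown"
  ctx$record_matches <- function(df) {
    if (nrow(df)) {
      df$sample_id <- sample_id
      matches[[length(matches) + 1L]] <<- df
    }
  }
  outputs <- list()
  if (!is.null(seed)) set.seed(seed)
  run_from <- match(start_at %||% order[1L], order)
  if (is.na(run_from)) stop("unknown stage: ", start_at, call. = FALSE)
  producer_of <- function(stage) {
    for (e in wf$edges) if (e[2L] == stage) return(e[1L])
    NULL
  }
  if (run_from > 1L) {
    # resume: load the snapshot of each resumed stage's upstream producer
    for (k in seq(run_from, length(order))) {
      prod <- producer_of(order[k])
      if (is.null(prod) || prod %in% order[seq(run_from, length(order))]) next
      sp <- snapshot_path(snapshot_dir, sample_id, prod)
      if (!file.exists(sp)) {
        stop("missing snapshot for sample '", sample_id, "', stage '", prod,
             "' (", sp, "); run the full workflow with a snapshot_dir first",
             call. = FALSE)
      }
      outputs[[prod]] <- read_snapshot(
        sp, expect = stage_def(wf$stages[[prod]]$method)$out_kind)
    }
    loaded_modes <- unlist(lapply(outputs, obj_ion_mode))
    loaded_modes <- setdiff(unique(loaded_modes), "unknown")
    if (length(loaded_modes) == 1L && is.null(mode_override)) {
      ctx$ion_mode <- loaded_modes
    }
  }
  for (k in seq(run_from, length(order))) {
    stage <- order[k]
    st <- wf$stages[[stage]]
    def <- stage_def(st$method)
    prod <- producer_of(stage)
    input <- if (def$in_kind == "none") NULL else outputs[[prod]]
    t0 <- proc.time()[["elapsed"]]
    n_warn <- 0L
    out <- withCallingHandlers(
      def$fn(input, resolve_stage_params(st$params, ctx$ion_mode), ctx),
      warning = function(w) {
        n_warn <<- n_warn + 1L
        invokeRestart("muffleWarning")
      })
    if (def$out_kind == "sample" && identical(ctx$ion_mode, "unknown") &&
        is.null(mode_override)) {
      m <- obj_ion_mode(out)
      if (m != "unknown") ctx$ion_mode <- m
    }
    if (identical(ctx$ion_mode, "unknown") && k < length(order)) {
      # mode-specific params downstream demand a known mode
      remaining <- order[seq(k + 1L, length(order))]
      needs_mode <- any(vapply(wf$stages[remaining], function(s) {
        any(vapply(s$params, is_mode_variant, logical(1)))
      }, logical(1)))
      if (needs_mode) {
        stop("ion mode of sample '", sample_id, "' is unknown but ",
             "mode-specific parameters are configured; set options$ion_mode",
             call. = FALSE)
      }
    }
    outputs[[stage]] <- out
    if (!is.null(snapshot_dir)) {
      write_snapshot(out, snapshot_path(snapshot_dir, sample_id, stage))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = sample_id, stage = stage, status = "ok",
      n = result_count(out), warnings = n_warn,
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      message = "", stringsAsFactors = FALSE)
  }
  sinks <- setdiff(order, vapply(wf$edges, `[[`, character(1), 1L))
  list(rows = do.call(rbind, rows),
       matches = if (length(matches)) do.call(rbind, matches) else NULL,
       outputs = outputs[intersect(order, sinks)],
       sample_id = sample_id)
}

#' Run a workflow over a batch of input files
#'
#' Every input file is processed independently through the stage graph in
#' topological order.  Mode-specific parameters (see [workflow()]) are
#' resolved per sample from its mzML polarity (or `options$ion_mode`).
#' A failure in one sample is recorded in the report and does not abort
#' the others.
#'
#' @param wf a validated [workflow()] (run [validate_workflow()] first;
#'   a non-empty problem list raises an error here)
#' @param inputs character vector of mzML paths
#' @param snapshot_dir overrides `wf$snapshot_dir`; if set, each (sample,
#'   stage) output is written as a snapshot there
#' @return object of class `lcms_run_report`: `$log` (per-sample,
#'   per-stage status data.frame), `$matches` (combined reference-match
#'   table), `$outputs` (per sample: the sink-stage outputs), `$failures`
#' @export
run_workflow <- function(wf, inputs, snapshot_dir = wf$snapshot_dir) {
  stopifnot(inherits(wf, "lcms_workflow"), length(inputs) >= 1L)
  problems <- validate_workflow(wf)
  if (length(problems)) {
    stop("invalid workflow:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  if (!is.null(snapshot_dir)) {
    dir.create(snapshot_dir, showWarnings = FALSE, recursive = TRUE)
  }
  order <- topo_order(names(wf$stages), wf$edges)
  execute_batch(wf, inputs, order, start_at = NULL, snapshot_dir)
}

#' Resume a workflow from stored snapshots
#'
#' Re-executes `from_stage` and everything downstream of it, loading each
#' sample's input from the snapshot its upstream producer wrote during a
#' previous [run_workflow()].  Typical use: loosen a filter parameter and
#' re-run only the affected tail of the pipeline.
#'
#' @param wf the (possibly re-parameterised) [workflow()]
#' @param from_stage stage name to resume at
#' @param inputs the same input files as the original run (used to derive
#'   the sample ids)
#' @param snapshot_dir snapshot directory of the original run
#' @return an `lcms_run_report`
#' @export
rerun_from <- function(wf, from_stage, inputs,
                       snapshot_dir = wf$snapshot_dir) {
  stopifnot(inherits(wf, "lcms_workflow"), length(inputs) >= 1L,
            !is.null(snapshot_dir))
  if (!from_stage %in% names(wf$stages)) {
    stop("unknown stage: '", from_stage, "'", call. = FALSE)
  }
  problems <- validate_workflow(wf)
  if (length(problems)) {
    stop("invalid workflow:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  order <- topo_order(names(wf$stages), wf$edges)
  execute_batch(wf, inputs, order, start_at = from_stage, snapshot_dir)
}

execute_batch <- function(wf, inputs, order, start_at, snapshot_dir) {
  logs <- list()
  matches <- list()
  outputs <- list()
  failures <- list()
  seed <- wf$options$seed
  mode_override <- wf$options$ion_mode
  for (path in inputs) {
    res <- tryCatch(
      run_one(wf, path, order, start_at, snapshot_dir, seed, mode_override),
      error = function(e) e)
    if (inherits(res, "error")) {
      sid <- sample_id_for(path)
      failures[[sid]] <- conditionMessage(res)
      logs[[length(logs) + 1L]] <- data.frame(
        sample_id = sid, stage = start_at %||% order[1L],
        status = "failed", n = NA_integer_, warnings = 0L,
        seconds = NA_real_, message = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      logs[[length(logs) + 1L]] <- res$rows
      if (!is.null(res$matches)) {
        matches[[length(matches) + 1L]] <- res$matches
      }
      outputs[[res$sample_id]] <- res$outputs
    }
  }
  structure(list(
    log = do.call(rbind, logs),
    matches = if (length(matches)) do.call(rbind, matches) else
      data.frame(),
    outputs = outputs,
    failures = failures), class = "lcms_run_report")
}

#' @export
print.lcms_run_report <- function(x, ...) {
  n_samples <- length(unique(x$log$sample_id))
  cat(sprintf("<run report  %d sample(s), %d failed, %d reference match(es)>\n",
              n_samples, length(x$failures),
              if (is.null(x$matches)) 0L else nrow(x$matches)))
  agg <- stats::aggregate(status ~ stage, x$log,
                          function(s) sum(s == "ok"))
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-20s ok in %d sample(s)\n", agg$stage[i], agg$status[i]))
  }
  invisible(x)
}
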