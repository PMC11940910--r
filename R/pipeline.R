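#' Pipeline run configuration
#'
#' Describes one full analysis run: either track/outline tables per
#' condition read from disk, or a simulation specification — never both —
#' plus every analysis parameter downstream stages use, so that a report
#' is fully reproducible from its configuration.
#'
#' @param conditions named character vector or list of track-table CSV
#'   paths, one per condition (input mode 1).
#' @param outlines optional path to a cell-outline CSV (input mode 1;
#'   required for zone statistics / heat maps on real data).
#' @param sim a list with elements `base` (a [sim_config]) and
#'   `overrides` (as in [simulate_conditions]) (input mode 2).
#' @param frame_interval,localization_precision acquisition metadata for
#'   tracks read from disk.
#' @param min_frames minimum track length (default 5).
#' @param K_max largest K for jump-distance model selection (default 3).
#' @param gmm_K components of the pooled cross-condition GMM (default 2).
#' @param dwell_radius,dwell_min_frames dwell-event definition (defaults
#'   0.12 um and 9 detections).
#' @param n_boot bootstrap resamples for dwell errors (default 1000).
#' @param septal,polar zone thresholds on the relative long axis.
#' @param mobility_threshold relative f_slow change (%) above which a
#'   condition is labelled more static / more diffusive (default 20).
#' @param localization_threshold zone-fraction change (points, 0-1 scale)
#'   above which a localization shift is labelled (default 0.10).
#' @param reference reference condition label (default: first condition).
#' @param seed integer seed for bootstrap (and nothing else; simulation
#'   seeds live in the sim config).
#' @param out_dir optional output directory; when set, [run_pipeline]
#'   writes the report JSON and all intermediate tables there.
#' @return object of class `run_config`.
#' @export
run_config <- function(conditions = NULL, outlines = NULL, sim = NULL,
                       frame_interval = 0.02, localization_precision = 0.04,
                       min_frames = 5, K_max = 3, gmm_K = 2,
                       dwell_radius = 0.12, dwell_min_frames = 9,
                       n_boot = 1000, septal = 0.2, polar = 0.8,
                       mobility_threshold = 20, localization_threshold = 0.10,
                       reference = NULL, seed = 1, out_dir = NULL) {
  if (is.null(conditions) == is.null(sim)) {
    stop("exactly one input mode: either `conditions` (paths) or `sim`",
         call. = FALSE)
  }
  if (!is.null(conditions)) {
    conditions <- as.list(conditions)
    if (is.null(names(conditions)) || any(names(conditions) == "")) {
      stop("`conditions` must be named (condition label -> path)",
           call. = FALSE)
    }
    for (p in conditions) {
      if (!file.exists(p)) stop("track table not found: ", p, call. = FALSE)
    }
    if (!is.null(outlines) && !file.exists(outlines)) {
      stop("outline table not found: ", outlines, call. = FALSE)
    }
  } else {
    stopifnot(is.list(sim), inherits(sim$base, "sim_config"),
              is.list(sim$overrides))
  }
  structure(
    list(conditions = conditions, outlines = outlines, sim = sim,
         frame_interval = frame_interval,
         localization_precision = localization_precision,
         min_frames = min_frames, K_max = K_max, gmm_K = gmm_K,
         dwell_radius = dwell_radius, dwell_min_frames = dwell_min_frames,
         n_boot = n_boot, septal = septal, polar = polar,
         mobility_threshold = mobility_threshold,
         localization_threshold = localization_threshold,
         reference = reference, seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full condition-comparison pipeline
#'
#' Executes, in fixed order: input (simulate or read) -> minimum-length
#' filter -> per-condition jump-distance model selection -> pooled
#' cross-condition GMM -> population-shift table -> dwell-time analysis
#' with pairwise Levene comparisons -> standardized-cell zone statistics
#' -> qualitative change classification. Every stage logs its sample
#' sizes and convergence counts; identical configurations (including
#' seeds) produce identical reports.
#'
#' Conditions whose dwell-event count is below the fitting minimum get an
#' `NA` dwell fit and a log note rather than aborting the run; all other
#' stage errors propagate with the stage name.
#'
#' @param cfg a [run_config].
#' @return object of class `condition_report`: named lists of per-
#'   condition `jd` fits, `dwell` fits and `zones`, the pooled `gmm`,
#'   `shift_table`, `dwell_comparison`, a `classification` table, the
#'   echoed `params`, and a `log` character vector. Written to
#'   `cfg$out_dir` as JSON/TSV/CSV when set.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  # --- input stage ---------------------------------------------------
  if (!is.null(cfg$sim)) {
    sims <- .stage("simulate",
                   simulate_conditions(cfg$sim$base, cfg$sim$overrides))
    tss <- lapply(sims, function(s) s$tracks)
    outline_spec <- cfg$sim$base$cell
    note("simulated %d condition(s) from seed %d", length(tss),
         cfg$sim$base$seed)
  } else {
    tss <- .stage("read", lapply(names(cfg$conditions), function(lab) {
      read_tracks(cfg$conditions[[lab]],
                  frame_interval = cfg$frame_interval,
                  localization_precision = cfg$localization_precision,
                  condition = lab)
    }))
    names(tss) <- names(cfg$conditions)
    outline_spec <- if (!is.null(cfg$outlines)) read_outlines(cfg$outlines)
    note("read %d condition(s) from disk", length(tss))
  }
  labels <- names(tss)
  reference <- if (is.null(cfg$reference)) labels[1L] else cfg$reference
  if (!reference %in% labels) {
    stop("reference condition '", reference, "' not among conditions",
         call. = FALSE)
  }
  for (lab in labels) {
    note("condition %s: %d tracks, %d detections", lab, n_tracks(tss[[lab]]),
         nrow(tss[[lab]]$tracks))
  }

  # --- jump-distance fits -------------------------------------------
  jd <- .stage("jd_fit", lapply(tss, function(ts) {
    fit <- select_model(extract_jumps(ts, cfg$min_frames), cfg$K_max)
    attr(fit, "all_fits") <- NULL
    fit
  }))
  for (lab in labels) {
    note("jd %s: K = %d, n = %d jumps, %d EM iterations", lab,
         jd[[lab]]$K, jd[[lab]]$n, jd[[lab]]$iterations)
  }

  # --- pooled GMM ----------------------------------------------------
  disp <- .stage("displacements", extract_displacements(tss, cfg$min_frames))
  gmm <- .stage("pooled_gmm", fit_pooled_gmm(disp, K = cfg$gmm_K))
  note("pooled GMM: %d EM iterations, shared D = %s", gmm$iterations,
       paste(sprintf("%.4f", gmm$D), collapse = "/"))
  shift <- population_shift_table(gmm, reference)

  # --- dwell analysis ------------------------------------------------
  dcfg <- dwell_config(cfg$dwell_radius, cfg$dwell_min_frames,
                       tss[[1L]]$frame_interval)
  events <- .stage("dwell_events",
                   lapply(tss, extract_dwell_events, cfg = dcfg))
  dwell <- lapply(labels, function(lab) {
    ev <- events[[lab]]
    note("dwell %s: %d events", lab, nrow(ev))
    tryCatch(
      fit_dwell_exponential(ev, dcfg, n_boot = cfg$n_boot, seed = cfg$seed),
      smt_samplesize_error = function(e) {
        note("dwell %s: %s (fit skipped)", lab, conditionMessage(e))
        NULL
      })
  })
  names(dwell) <- labels
  fitted <- dwell[!vapply(dwell, is.null, logical(1))]
  dwell_comparison <- if (length(fitted) >= 2L) compare_dwell(fitted) else NULL

  # --- spatial zones -------------------------------------------------
  zones <- if (!is.null(outline_spec)) {
    .stage("zones", lapply(tss, function(ts) {
      locs <- standardize_trackset(ts, outline_spec)
      zone_fractions(locs, cfg$septal, cfg$polar)
    }))
  } else {
    note("no outlines supplied: zone statistics skipped")
    NULL
  }

  report <- structure(
    list(conditions = labels, reference = reference, jd = jd, gmm = gmm,
         shift_table = shift, dwell = dwell,
         dwell_comparison = dwell_comparison, zones = zones,
         params = cfg, log = log),
    class = "condition_report"
  )
  report$classification <- classify_changes(report, reference)
  if (!is.null(cfg$out_dir)) .write_report(report, cfg$out_dir)
  report
}

#' Classify per-condition changes versus a reference
#'
#' Applies the single quantitative labelling rule for mobility — a
#' condition is "more static" or "more diffusive" when the relative
#' change of its slow fraction exceeds the threshold (default 20%),
#' sign-directed, and "-" otherwise — plus a configurable localization
#' rule: the zone whose occupancy increased the most labels the condition
#' ("more septal"/"more polar"/"more peripheral") when the largest
#' absolute zone-fraction change exceeds its threshold.
#'
#' @param report a [run_pipeline] `condition_report`.
#' @param reference reference condition label.
#' @param mobility_threshold relative f_slow change in percent (default
#'   taken from the report's parameters, else 20).
#' @param localization_threshold zone-fraction change on the 0-1 scale
#'   (default from the report's parameters, else 0.10).
#' @return data.frame with columns `condition`, `mobility`,
#'   `localization`.
#' @export
classify_changes <- function(report, reference,
                             mobility_threshold = NULL,
                             localization_threshold = NULL) {
  stopifnot(inherits(report, "condition_report"))
  if (!reference %in% report$conditions) {
    stop("unknown reference condition: ", reference, call. = FALSE)
  }
  if (is.null(mobility_threshold)) {
    mobility_threshold <- report$params$mobility_threshold %||% 20
  }
  if (is.null(localization_threshold)) {
    localization_threshold <- report$params$localization_threshold %||% 0.10
  }
  shift <- if (identical(reference, report$reference)) {
    report$shift_table
  } else {
    population_shift_table(report$gmm, reference)
  }
  mob <- vapply(report$conditions, function(lab) {
    rel <- shift$rel_change_pct[shift$condition == lab]
    if (lab == reference || abs(rel) <= mobility_threshold) "-"
    else if (rel > 0) "more static" else "more diffusive"
  }, character(1))
  loc <- rep("-", length(report$conditions))
  names(loc) <- report$conditions
  if (!is.null(report$zones)) {
    ref_fr <- report$zones[[reference]]$fractions
    zone_label <- c(septal = "more septal", lateral = "more peripheral",
                    polar = "more polar")
    for (lab in report$conditions) {
      if (lab == reference) next
      delta <- report$zones[[lab]]$fractions - ref_fr
      if (max(abs(delta)) > localization_threshold) {
        loc[lab] <- zone_label[[names(which.max(delta))]]
      }
    }
  }
  data.frame(condition = report$conditions, mobility = unname(mob),
             localization = unname(loc), row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.condition_report <- function(x, ...) {
  cat("condition_report:", length(x$conditions), "condition(s), reference",
      shQuote(x$reference), "\n\n")
  print(x$gmm)
  cat("\npopulation shifts:\n")
  print(x$shift_table, row.names = FALSE)
  cat("\nclassification:\n")
  print(x$classification, row.names = FALSE)
  invisible(x)
}

# serialize a condition report (JSON + TSV tables) into a directory
.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jd_list <- lapply(report$jd, function(f) {
    f[c("K", "D", "f", "loglik", "bic", "r2", "n")]
  })
  dwell_list <- lapply(report$dwell, function(f) {
    if (is.null(f)) return(NULL)
    list(tau = f$tau, mean_residence = f$mean_residence, se = f$se,
         n_events = f$n_events, t_min = f$t_min)
  })
  zones_list <- if (is.null(report$zones)) NULL else {
    lapply(report$zones, function(z) as.list(z$fractions))
  }
  payload <- list(
    conditions = report$conditions, reference = report$reference,
    jd = jd_list,
    gmm = list(K = report$gmm$K, D = report$gmm$D, sigma = report$gmm$sigma,
               weights = report$gmm$weights, n = report$gmm$n),
    shift_table = report$shift_table,
    dwell = dwell_list, dwell_comparison = report$dwell_comparison,
    zones = zones_list, classification = report$classification,
    log = report$log)
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  utils::write.table(report$shift_table,
                     file.path(out_dir, "shift_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$dwell_comparison)) {
    utils::write.table(report$dwell_comparison,
                       file.path(out_dir, "dwell_comparison.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(report$classification,
                     file.path(out_dir, "classification.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}
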