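#' Dwell-time analysis configuration
#'
#' @param radius confinement radius in um (default 0.12, i.e. 120 nm —
#'   about three times a typical localization error).
#' @param min_frames minimum number of detections a molecule must stay
#'   within the radius for the stay to count as a dwell event (default 9).
#' @param frame_interval acquisition interval in seconds (default 0.02).
#' @return object of class `dwell_config`.
#' @export
dwell_config <- function(radius = 0.12, min_frames = 9,
                         frame_interval = 0.02) {
  if (!(radius > 0)) stop("radius must be > 0", call. = FALSE)
  if (!(min_frames >= 2)) stop("min_frames must be >= 2", call. = FALSE)
  if (!(frame_interval > 0)) stop("frame_interval must be > 0", call. = FALSE)
  structure(list(radius = radius, min_frames = as.integer(min_frames),
                 frame_interval = frame_interval),
            class = "dwell_config")
}

#' Extract confinement (dwell) events from a track set
#'
#' Scans each track left to right. An event opens at detection i and
#' extends while every subsequent detection lies within `radius` of
#' detection i's position (the anchor is the event's first localization,
#' not a running centroid). When a detection exits, the event closes —
#' kept if it spans at least `min_frames` detections — and scanning
#' resumes at the exiting detection, so events within a track never
#' overlap. Durations count intervals: `duration = (n_frames - 1) * dt`.
#'
#' @param ts a [track_set]; its frame interval must match `cfg`.
#' @param cfg a [dwell_config].
#' @return data.frame of class `dwell_events` with columns `track_id`,
#'   `start_frame`, `n_frames`, `duration` (seconds).
#' @export
extract_dwell_events <- function(ts, cfg) {
  stopifnot(inherits(ts, "track_set"), inherits(cfg, "dwell_config"))
  if (abs(ts$frame_interval - cfg$frame_interval) > 1e-12) {
    stop("track_set and dwell_config disagree on frame_interval",
         call. = FALSE)
  }
  tr <- ts$tracks
  ids <- character(0); starts <- integer(0); nfr <- integer(0)
  r2 <- cfg$radius^2
  for (tid in unique(tr$track_id)) {
    sub <- tr[tr$track_id == tid, , drop = FALSE]
    x <- sub$x_um; y <- sub$y_um; fr <- sub$frame
    n <- length(x)
    i <- 1L
    while (i <= n) {
      if (i == n) break  # single trailing detection cannot open an event
      d2 <- (x - x[i])^2 + (y - y[i])^2
      exits <- which(d2[(i + 1L):n] > r2)
      j <- if (length(exits) == 0L) n + 1L else i + exits[1L]  # first exit
      len <- j - i  # detections i .. j-1 stay within the radius
      if (len >= cfg$min_frames) {
        ids <- c(ids, tid); starts <- c(starts, fr[i]); nfr <- c(nfr, len)
      }
      i <- if (j > n) n + 1L else j
    }
  }
  out <- data.frame(track_id = ids, start_frame = starts, n_frames = nfr,
                    duration = (nfr - 1L) * cfg$frame_interval)
  class(out) <- c("dwell_events", "data.frame")
  out
}

#' Fit a one-component truncated-exponential residence time
#'
#' Dwell durations are observed only above the truncation point
#' `t_min = (min_frames - 1) * dt`. Under an exponential residence law
#' the left-truncated MLE is `tau = mean(duration) - t_min`
#' (memorylessness), with the mean residence time of recorded events
#' `mean_residence = t_min + tau`. The standard error comes from seeded
#' bootstrap resampling of events. Bleaching shortens observed dwells, so
#' the uncorrected values underestimate true binding times; an optional
#' competing-risk correction `1/tau_true = 1/tau - 1/tau_bleach` is
#' available but off by default, matching how residence times are
#' conventionally reported.
#'
#' @param events a [extract_dwell_events] data.frame.
#' @param cfg the [dwell_config] used to extract them.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap (default 1).
#' @param bleach_half_life optional fluorophore half-life in seconds; if
#'   supplied, a bleaching-corrected `tau_corrected` is added.
#' @return object of class `dwell_fit`: `tau` (s, excess over t_min),
#'   `mean_residence` (s), `se` (s), `n_events`, `bootstrap_taus`,
#'   `t_min`, `boundary` (TRUE if tau hit the 0 boundary).
#' @export
fit_dwell_exponential <- function(events, cfg, n_boot = 1000, seed = 1,
                                  bleach_half_life = NULL) {
  stopifnot(inherits(cfg, "dwell_config"), is.data.frame(events))
  ne <- nrow(events)
  if (ne < 20L) {
    stop(.condition_error("smt_samplesize_error",
         sprintf("need >= 20 dwell events to fit (have %d)", ne)))
  }
  t_min <- (cfg$min_frames - 1L) * cfg$frame_interval
  dur <- events$duration
  tau <- mean(dur) - t_min
  boundary <- tau <= .Machine$double.eps
  if (boundary) {
    warning("all dwell durations at the truncation point: tau = 0 boundary",
            call. = FALSE)
    tau <- 0
  }
  set.seed(as.integer(seed))
  boot <- vapply(seq_len(n_boot), function(b) {
    mean(dur[sample.int(ne, ne, replace = TRUE)]) - t_min
  }, numeric(1))
  out <- list(tau = tau, mean_residence = t_min + tau,
              se = stats::sd(boot), n_events = ne,
              bootstrap_taus = boot, t_min = t_min, boundary = boundary)
  if (!is.null(bleach_half_life)) {
    tau_bleach <- bleach_half_life / log(2)
    out$tau_corrected <- if (tau > 0 && tau < tau_bleach) {
      1 / (1 / tau - 1 / tau_bleach)
    } else NA_real_
  }
  structure(out, class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf(
    "dwell_fit: mean residence %.3f s (tau = %.3f s above t_min = %.2f s) +/- %.4f s, %d events\n",
    x$mean_residence, x$tau, x$t_min, x$se, x$n_events))
  invisible(x)
}

#' Classic (mean-centred) Levene test for equality of variances
#'
#' Computes the Levene W statistic on absolute deviations from the group
#' means and its F reference p-value. This is the classic variant (group
#' means, not medians).
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`.
#' @return list with `W`, `p`, `df1`, `df2`.
#' @export
levene_test <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2L)
  z <- abs(values - stats::ave(values, groups))
  N <- length(z); k <- nlevels(groups)
  zbar <- mean(z)
  zbar_g <- tapply(z, groups, mean)
  n_g <- tabulate(groups)
  num <- sum(n_g * (zbar_g - zbar)^2) / (k - 1)
  den <- sum((z - stats::ave(z, groups))^2) / (N - k)
  W <- if (den <= .Machine$double.eps) {
    if (num <= .Machine$double.eps) 0 else Inf
  } else num / den
  p <- if (W == 0) 1 else stats::pf(W, k - 1, N - k, lower.tail = FALSE)
  list(W = W, p = p, df1 = k - 1, df2 = N - k)
}

#' Pairwise condition comparison of dwell-time fits
#'
#' Applies the classic Levene test to the bootstrap tau replicate sets of
#' every pair of conditions, the reconstruction of comparing "variances of
#' the tau" across conditions. Significance tiers: `*` for p < 0.1,
#' `***` for p < 0.01.
#'
#' @param fits a named list of [fit_dwell_exponential] `dwell_fit`
#'   objects (>= 2 conditions).
#' @return data.frame with one row per unordered pair: `condition_a`,
#'   `condition_b`, `W`, `p`, `signif`.
#' @export
compare_dwell <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2L)
  labels <- names(fits)
  if (is.null(labels) || any(labels == "")) {
    stop("fits must be a named list (condition labels)", call. = FALSE)
  }
  for (f in fits) {
    if (!inherits(f, "dwell_fit") || length(f$bootstrap_taus) == 0L) {
      stop("every element must be a dwell_fit with bootstrap replicates",
           call. = FALSE)
    }
  }
  pairs <- utils::combn(labels, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    x <- c(fits[[a]]$bootstrap_taus, fits[[b]]$bootstrap_taus)
    g <- rep(c(a, b), c(length(fits[[a]]$bootstrap_taus),
                        length(fits[[b]]$bootstrap_taus)))
    lt <- levene_test(x, g)
    data.frame(condition_a = a, condition_b = b, W = lt$W, p = lt$p,
               signif = if (lt$p < 0.01) "***" else if (lt$p < 0.1) "*" else "")
  })
  do.call(rbind, rows)
}
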