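#' Construct a track set
#'
#' A `track_set` bundles single-molecule trajectories (per-frame x/y
#' localizations in micrometres) with the acquisition metadata the
#' downstream fits need: the frame interval and the localization
#' precision, plus a condition label identifying the experimental
#' treatment.
#'
#' @param tracks data.frame with columns `track_id`, `frame` (0-based,
#'   non-negative integer), `x_um`, `y_um` and optionally `cell_id`.
#'   Frames must be strictly increasing within each track. Tracks with
#'   fewer than two detections are dropped (a single detection carries no
#'   dynamic information).
#' @param frame_interval time between frames in seconds (default 0.02,
#'   i.e. 20 ms stream acquisition).
#' @param localization_precision per-axis localization error sigma in
#'   micrometres (default 0.04; typical YFP-based SMT precision is below
#'   50 nm).
#' @param condition label for the experimental condition.
#' @return an object of class `track_set`.
#' @export
track_set <- function(tracks, frame_interval = 0.02,
                      localization_precision = 0.04,
                      condition = "untreated") {
  stopifnot(is.data.frame(tracks))
  required <- c("track_id", "frame", "x_um", "y_um")
  missing_cols <- setdiff(required, names(tracks))
  if (length(missing_cols) > 0L) {
    stop("track table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be a single positive number (seconds)",
         call. = FALSE)
  }
  if (!is.numeric(localization_precision) ||
      length(localization_precision) != 1L ||
      !is.finite(localization_precision) || localization_precision < 0) {
    stop("localization_precision must be a single non-negative number (um)",
         call. = FALSE)
  }
  tracks$track_id <- as.character(tracks$track_id)
  tracks$frame <- as.integer(tracks$frame)
  if (nrow(tracks) > 0L) {
    if (any(!is.finite(tracks$x_um)) || any(!is.finite(tracks$y_um))) {
      stop("coordinates must be finite", call. = FALSE)
    }
    if (any(tracks$frame < 0L)) {
      stop("frame indices must be non-negative", call. = FALSE)
    }
    ord <- order(tracks$track_id, tracks$frame)
    tracks <- tracks[ord, , drop = FALSE]
    dup <- duplicated(tracks[, c("track_id", "frame")])
    if (any(dup)) {
      bad <- unique(tracks$track_id[dup])
      stop("duplicated (track_id, frame) in track(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    len <- table(tracks$track_id)
    keep <- names(len)[len >= 2L]
    tracks <- tracks[tracks$track_id %in% keep, , drop = FALSE]
    rownames(tracks) <- NULL
  }
  structure(
    list(tracks = tracks,
         frame_interval = frame_interval,
         localization_precision = localization_precision,
         condition = as.character(condition)[1L]),
    class = "track_set"
  )
}

#' Number of tracks in a track set
#' @param ts a `track_set`.
#' @return integer count.
#' @export
n_tracks <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  length(unique(ts$tracks$track_id))
}

#' Track lengths (detections per track)
#' @param ts a `track_set`.
#' @return named integer vector, one entry per track.
#' @export
track_lengths <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  if (nrow(ts$tracks) == 0L) return(integer(0))
  tab <- table(ts$tracks$track_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf(
    "track_set: %d tracks, %d detections | condition '%s' | dt = %g s, sigma = %g um\n",
    n_tracks(x), nrow(x$tracks), x$condition,
    x$frame_interval, x$localization_precision))
  invisible(x)
}

#' Read a track table from CSV
#'
#' Reads the fixed track-table dialect: comma-separated with header
#' `track_id,frame,x_um,y_um[,cell_id]`. Rows are grouped by `track_id`
#' and ordered by `frame`; duplicated (track_id, frame) pairs are a
#' validation error.
#'
#' @param path CSV file path.
#' @inheritParams track_set
#' @return a [track_set].
#' @export
read_tracks <- function(path, frame_interval = 0.02,
                        localization_precision = 0.04,
                        condition = "untreated") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  track_set(df, frame_interval = frame_interval,
            localization_precision = localization_precision,
            condition = condition)
}

#' Write a track table to CSV
#'
#' Emits the same dialect [read_tracks] consumes, so that a
#' write/read round trip reproduces all fields.
#'
#' @param ts a `track_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  utils::write.csv(ts$tracks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a spherocylindrical cell outline
#'
#' Rod-shaped cells are parameterized as 2-D spherocylinders: a rectangle
#' of length `length - width` capped by two semicircles of diameter
#' `width`, centred at `center` and rotated by `orientation`.
#'
#' @param cell_id identifier.
#' @param center numeric length-2, cell centre (x, y) in um.
#' @param orientation long-axis angle in radians.
#' @param length pole-to-pole length L in um.
#' @param width cell width W in um; must satisfy `length >= width > 0`.
#' @return an object of class `cell_outline`.
#' @export
cell_outline <- function(cell_id = "cell1", center = c(0, 0),
                         orientation = 0, length = 3, width = 1) {
  stopifnot(is.numeric(center), length(center) == 2L,
            is.numeric(orientation), length(orientation) == 1L)
  if (!(length >= width && width > 0)) {
    stop("cell outline requires length >= width > 0", call. = FALSE)
  }
  structure(
    list(cell_id = as.character(cell_id)[1L],
         center = as.numeric(center), orientation = as.numeric(orientation),
         length = as.numeric(length), width = as.numeric(width)),
    class = "cell_outline"
  )
}

#' The standardized medium-sized cell (3 x 1 um)
#'
#' Reference cell into which localizations are projected for population
#' heat maps.
#'
#' @return a [cell_outline] of length 3 um and width 1 um at the origin.
#' @export
standard_cell <- function() cell_outline("standard", c(0, 0), 0, 3, 1)

#' Read / write cell-outline tables
#'
#' CSV dialect:
#' `cell_id,center_x_um,center_y_um,orientation_rad,length_um,width_um`.
#'
#' @param path CSV file path.
#' @return `read_outlines`: a named list of [cell_outline] objects.
#' @export
read_outlines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_id", "center_x_um", "center_y_um",
                "orientation_rad", "length_um", "width_um")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("outline table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    cell_outline(df$cell_id[i],
                 c(df$center_x_um[i], df$center_y_um[i]),
                 df$orientation_rad[i], df$length_um[i], df$width_um[i])
  })
  stats::setNames(out, as.character(df$cell_id))
}

#' @rdname read_outlines
#' @param outlines a list of [cell_outline] objects (or a single one).
#' @return `write_outlines`: `path`, invisibly.
#' @export
write_outlines <- function(outlines, path) {
  if (inherits(outlines, "cell_outline")) outlines <- list(outlines)
  df <- do.call(rbind, lapply(outlines, function(o) {
    data.frame(cell_id = o$cell_id,
               center_x_um = o$center[1], center_y_um = o$center[2],
               orientation_rad = o$orientation,
               length_um = o$length, width_um = o$width)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter tracks by minimum length
#'
#' Retains only trajectories with at least `min_frames` detections, the
#' standard pre-filter before any displacement analysis (default 5,
#' i.e. at least 4 displacement steps). Idempotent; never increases the
#' track count.
#'
#' @param ts a `track_set`.
#' @param min_frames minimum number of detections per track (>= 2).
#' @return the filtered `track_set` (possibly empty), order preserved.
#' @export
filter_min_length <- function(ts, min_frames = 5) {
  stopifnot(inherits(ts, "track_set"))
  if (!is.numeric(min_frames) || length(min_frames) != 1L || min_frames < 2) {
    stop("min_frames must be a single number >= 2", call. = FALSE)
  }
  len <- table(ts$tracks$track_id)
  keep <- names(len)[len >= min_frames]
  out <- ts
  out$tracks <- ts$tracks[ts$tracks$track_id %in% keep, , drop = FALSE]
  rownames(out$tracks) <- NULL
  out
}

#' Crop a movie to its trailing single-molecule window
#'
#' Stream-acquisition movies start above the single-molecule regime; the
#' analysis uses only the trailing `keep` frames (2001 of 3000 in the
#' standard protocol), once early bleaching has brought the density down
#' to single-molecule level.
#'
#' @param movie_length total number of frames in the movie.
#' @param keep number of trailing frames to retain (default 2001).
#' @return integer vector `c(first_kept_frame, last_kept_frame)`,
#'   inclusive 0-based indices.
#' @export
crop_to_single_molecule <- function(movie_length, keep = 2001) {
  stopifnot(is.numeric(movie_length), length(movie_length) == 1L,
            is.numeric(keep), length(keep) == 1L)
  movie_length <- as.integer(movie_length)
  keep <- as.integer(keep)
  if (keep > movie_length) {
    stop("keep (", keep, ") exceeds movie length (", movie_length, ")",
         call. = FALSE)
  }
  c(first_kept_frame = movie_length - keep,
    last_kept_frame = movie_length - 1L)
}

#' Estimate the single-molecule onset frame from a spot-count decay curve
#'
#' Fits N(t) = A * exp(-t / tau_b) + B to the per-frame spot counts by
#' least squares and returns the first frame at which the fitted count
#' drops to B + 1 (one molecule above baseline), the point where the
#' movie reaches the single-molecule regime. Diagnostic companion to
#' [crop_to_single_molecule].
#'
#' @param counts_per_frame non-negative integer vector of detected spots
#'   per frame.
#' @return 0-based frame index (integer).
#' @export
estimate_onset_from_decay <- function(counts_per_frame) {
  y <- as.numeric(counts_per_frame)
  if (length(y) == 0L) stop("counts_per_frame is empty", call. = FALSE)
  if (any(!is.finite(y)) || any(y < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (all(y == 0)) {
    stop("degenerate input: all counts are zero", call. = FALSE)
  }
  t <- seq_along(y) - 1
  n <- length(y)
  B0 <- mean(utils::tail(y, max(1L, n %/% 10L)))
  A0 <- max(y[1] - B0, 1e-6)
  if (diff(range(y)) < .Machine$double.eps^0.5) {
    # flat curve: already at (or below) single-molecule level everywhere
    return(0L)
  }
  # crude tau from the decay of the above-baseline excess
  excess <- pmax(y - B0, 1e-9)
  pos <- which(excess > 1e-6)
  tau0 <- if (length(pos) >= 2L) {
    sl <- stats::coef(stats::lm(log(excess[pos]) ~ t[pos]))[2]
    if (is.finite(sl) && sl < 0) -1 / sl else n / 4
  } else n / 4
  sse <- function(par) {
    A <- par[1]; tau <- exp(par[2]); B <- par[3]
    sum((y - (A * exp(-t / tau) + B))^2)
  }
  opt <- stats::optim(c(A0, log(max(tau0, 1e-3)), B0), sse,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  A <- opt$par[1]; tau <- exp(opt$par[2]); B <- opt$par[3]
  fitted <- A * exp(-t / tau) + B
  hit <- which(fitted <= B + 1)
  idx <- if (length(hit) > 0L) hit[1] - 1L else n - 1L
  as.integer(idx)
}

#' Greedy nearest-neighbour detection linking
#'
#' Minimal frame-to-frame linker used for synthetic fixtures only (a
#' stand-in for full cost-matrix trackers). Detections in each frame are
#' matched to the nearest open track end within `max_radius`, globally
#' greedily by increasing distance, ties broken toward the smaller track
#' id; unmatched detections start new tracks. Track ends unseen for more
#' than `max_gap + 1` frames are closed.
#'
#' @param detections data.frame with columns `frame`, `x_um`, `y_um`.
#' @param max_radius maximum linking distance in um (> 0).
#' @param max_gap number of missed frames tolerated before a track end is
#'   closed (default 0: consecutive frames only).
#' @return data.frame with columns `track_id`, `frame`, `x_um`, `y_um`
#'   (may include single-detection tracks; build a [track_set] to drop
#'   them).
#' @export
link_detections <- function(detections, max_radius, max_gap = 0) {
  stopifnot(is.data.frame(detections),
            all(c("frame", "x_um", "y_um") %in% names(detections)))
  if (!is.numeric(max_radius) || max_radius <= 0) {
    stop("max_radius must be > 0", call. = FALSE)
  }
  det <- detections[order(detections$frame), , drop = FALSE]
  out_id <- integer(nrow(det))
  # open track ends: id, last frame, last position
  end_id <- integer(0); end_frame <- integer(0)
  end_x <- numeric(0); end_y <- numeric(0)
  next_id <- 1L
  for (fr in sort(unique(det$frame))) {
    rows <- which(det$frame == fr)
    open <- which(end_frame >= fr - 1L - max_gap & end_frame < fr)
    if (length(open) > 0L && length(rows) > 0L) {
      dmat <- outer(det$x_um[rows], end_x[open], "-")^2 +
        outer(det$y_um[rows], end_y[open], "-")^2
      dmat <- sqrt(dmat)
      dmat[dmat > max_radius] <- NA_real_
      while (any(is.finite(dmat))) {
        mn <- min(dmat, na.rm = TRUE)
        cand <- which(dmat == mn, arr.ind = TRUE)
        # ties: smaller track id wins, then earlier detection row
        cand <- cand[order(end_id[open[cand[, 2]]], cand[, 1]), , drop = FALSE]
        i <- cand[1, 1]; j <- cand[1, 2]
        r <- rows[i]; e <- open[j]
        out_id[r] <- end_id[e]
        end_frame[e] <- fr; end_x[e] <- det$x_um[r]; end_y[e] <- det$y_um[r]
        dmat[i, ] <- NA_real_
        dmat[, j] <- NA_real_
      }
    }
    for (r in rows) {
      if (out_id[r] == 0L) {
        out_id[r] <- next_id
        end_id <- c(end_id, next_id)
        end_frame <- c(end_frame, fr)
        end_x <- c(end_x, det$x_um[r]); end_y <- c(end_y, det$y_um[r])
        next_id <- next_id + 1L
      }
    }
  }
  data.frame(track_id = out_id, frame = det$frame,
             x_um = det$x_um, y_um = det$y_um)
}
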