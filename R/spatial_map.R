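#' Project localizations into the standardized cell
#'
#' Maps raw (x, y) localizations in field-of-view coordinates into the
#' relative coordinates of a standardized rod cell: the point is
#' translated by minus the cell centre, rotated by minus the cell
#' orientation, and scaled so that `x_rel = 2 x' / L` (long axis, +/-1 at
#' the poles) and `y_rel = 2 y' / W` (short axis). Points outside the
#' cell outline dilated by `max_outside` um are rejected (localization
#' noise straddles the membrane, so a small margin is tolerated); the
#' survivors are clamped to [-1, 1].
#'
#' @param x,y numeric vectors of raw coordinates in um.
#' @param outline a [cell_outline].
#' @param max_outside dilation margin in um (default 0.2).
#' @return data.frame of class `relative_localizations` with columns
#'   `x_rel`, `y_rel`; the number of rejected points is in
#'   `attr(, "rejected")`.
#' @export
normalize_localizations <- function(x, y, outline, max_outside = 0.2) {
  stopifnot(inherits(outline, "cell_outline"), length(x) == length(y))
  th <- outline$orientation
  xd <- x - outline$center[1]; yd <- y - outline$center[2]
  xl <- cos(th) * xd + sin(th) * yd
  yl <- -sin(th) * xd + cos(th) * yd
  L <- outline$length; W <- outline$width
  inside <- .in_cell_local(xl, yl, L + 2 * max_outside, W + 2 * max_outside)
  rejected <- sum(!inside)
  out <- data.frame(
    x_rel = pmax(-1, pmin(1, 2 * xl[inside] / L)),
    y_rel = pmax(-1, pmin(1, 2 * yl[inside] / W)))
  class(out) <- c("relative_localizations", "data.frame")
  attr(out, "rejected") <- rejected
  out
}

#' Project a whole track set into standardized-cell coordinates
#'
#' Convenience wrapper over [normalize_localizations]: every detection of
#' every track is projected using the outline of its cell (matched by
#' `cell_id`; a single outline is recycled for all detections when the
#' table has no `cell_id` column).
#'
#' @param ts a [track_set].
#' @param outlines a [cell_outline], or a named list of them keyed by
#'   `cell_id` (as returned by [read_outlines]).
#' @param max_outside dilation margin in um (default 0.2).
#' @return a `relative_localizations` data.frame (rejected count in
#'   `attr(, "rejected")`).
#' @export
standardize_trackset <- function(ts, outlines, max_outside = 0.2) {
  stopifnot(inherits(ts, "track_set"))
  tr <- ts$tracks
  if (inherits(outlines, "cell_outline")) {
    return(normalize_localizations(tr$x_um, tr$y_um, outlines, max_outside))
  }
  stopifnot(is.list(outlines), !is.null(names(outlines)))
  if (!"cell_id" %in% names(tr)) {
    stop("track table has no cell_id column; pass a single outline",
         call. = FALSE)
  }
  parts <- lapply(split(tr, tr$cell_id), function(sub) {
    o <- outlines[[as.character(sub$cell_id[1])]]
    if (is.null(o)) stop("no outline for cell_id ", sub$cell_id[1],
                         call. = FALSE)
    normalize_localizations(sub$x_um, sub$y_um, o, max_outside)
  })
  out <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("relative_localizations", "data.frame")
  attr(out, "rejected") <- sum(vapply(parts, function(p) {
    as.numeric(attr(p, "rejected"))
  }, numeric(1)))
  out
}

#' Build a localization probability heat map
#'
#' 2-D histogram of relative localizations over the standardized cell,
#' normalized to a probability grid. With `symmetrize = TRUE` (default)
#' each count contributes to all four mirror images (+/-x, +/-y): a rod
#' cell population has no intrinsic left/right or up/down labelling, so
#' folded maps average out arbitrary cell orientations. Probabilities
#' always sum to 1.
#'
#' @param locs a `relative_localizations` data.frame (or any data.frame
#'   with `x_rel`, `y_rel` in [-1, 1]).
#' @param bins integer length-2: bins along the long and short axis
#'   (default `c(60, 20)`, i.e. 50 nm bins in the 3 x 1 um cell).
#' @param symmetrize fold by reflection about both axes (default TRUE).
#' @return object of class `heatmap_grid`: `prob` (nx x ny matrix summing
#'   to 1), `counts`, `x_breaks`, `y_breaks`, `symmetrized`, `n`.
#' @export
build_heatmap <- function(locs, bins = c(60, 20), symmetrize = TRUE) {
  stopifnot(is.data.frame(locs), nrow(locs) > 0L,
            all(c("x_rel", "y_rel") %in% names(locs)))
  nx <- as.integer(bins[1]); ny <- as.integer(bins[2])
  xb <- seq(-1, 1, length.out = nx + 1L)
  yb <- seq(-1, 1, length.out = ny + 1L)
  bin_index <- function(v, breaks, nbin) {
    i <- findInterval(v, breaks, rightmost.closed = TRUE)
    pmin(pmax(i, 1L), nbin)
  }
  tab <- function(xs, ys) {
    ix <- bin_index(xs, xb, nx); iy <- bin_index(ys, yb, ny)
    m <- matrix(0, nx, ny)
    for (k in seq_along(ix)) m[ix[k], iy[k]] <- m[ix[k], iy[k]] + 1
    m
  }
  counts <- tab(locs$x_rel, locs$y_rel)
  if (symmetrize) {
    counts <- counts + tab(-locs$x_rel, locs$y_rel) +
      tab(locs$x_rel, -locs$y_rel) + tab(-locs$x_rel, -locs$y_rel)
  }
  structure(
    list(prob = counts / sum(counts), counts = counts,
         x_breaks = xb, y_breaks = yb, symmetrized = symmetrize,
         n = nrow(locs)),
    class = "heatmap_grid"
  )
}

#' Plot a heat map grid
#'
#' @param x a `heatmap_grid`.
#' @param ... passed to [graphics::image].
#' @export
plot.heatmap_grid <- function(x, ...) {
  graphics::image(x = x$x_breaks, y = x$y_breaks, z = x$prob,
                  xlab = "relative long-axis position",
                  ylab = "relative short-axis position",
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Zone occupancy fractions (septal / lateral / polar)
#'
#' Classifies localizations by long-axis position in the standardized
#' cell: septal for `|x_rel| < septal`, polar for `|x_rel| > polar`,
#' lateral otherwise. The thresholds quantify the qualitative
#' localization categories (septal enrichment, peripheral, polar) and are
#' configurable.
#'
#' @param locs a `relative_localizations` data.frame.
#' @param septal septal half-width on the relative axis (default 0.2).
#' @param polar polar cutoff on the relative axis (default 0.8).
#' @return object of class `zone_stats`: `fractions` (named, summing to
#'   1), `counts`, `n`, thresholds.
#' @export
zone_fractions <- function(locs, septal = 0.2, polar = 0.8) {
  stopifnot(is.data.frame(locs), nrow(locs) > 0L, septal < polar)
  ax <- abs(locs$x_rel)
  counts <- c(septal = sum(ax < septal),
              lateral = sum(ax >= septal & ax <= polar),
              polar = sum(ax > polar))
  structure(
    list(fractions = counts / sum(counts), counts = counts,
         n = nrow(locs), septal_threshold = septal, polar_threshold = polar),
    class = "zone_stats"
  )
}

#' @export
print.zone_stats <- function(x, ...) {
  cat(sprintf("zone_stats (n = %d): septal %.1f%% | lateral %.1f%% | polar %.1f%%\n",
              x$n, 100 * x$fractions["septal"], 100 * x$fractions["lateral"],
              100 * x$fractions["polar"]))
  invisible(x)
}
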