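#' Extract 1-D displacement components across conditions
#'
#' For each condition, pools the x and y components of every
#' consecutive-frame step of every track surviving the minimum-length
#' filter. Both axes are pooled as independent draws: for 2-D Brownian
#' motion each component is zero-mean Gaussian with sd
#' `sqrt(2 * D_app * dt)`, and pooling doubles the sample while keeping
#' the sign information the step histograms display.
#'
#' @param ts_list a named list of [track_set] objects (one per condition);
#'   all must share the same frame interval.
#' @param min_frames minimum track length in detections (default 5).
#' @return object of class `displacement_sample`: list with `d` (named
#'   list of numeric vectors, one per condition) and `frame_interval`.
#' @export
extract_displacements <- function(ts_list, min_frames = 5) {
  if (inherits(ts_list, "track_set")) ts_list <- list(ts_list)
  stopifnot(is.list(ts_list), length(ts_list) > 0L,
            all(vapply(ts_list, inherits, logical(1), "track_set")))
  dts <- vapply(ts_list, function(ts) ts$frame_interval, numeric(1))
  if (length(unique(dts)) != 1L) {
    stop("all conditions must share the same frame_interval", call. = FALSE)
  }
  labels <- names(ts_list)
  if (is.null(labels)) {
    labels <- vapply(ts_list, function(ts) ts$condition, character(1))
  }
  if (anyDuplicated(labels)) stop("duplicate condition labels", call. = FALSE)
  d <- lapply(ts_list, function(ts) {
    fts <- filter_min_length(ts, min_frames)
    tr <- fts$tracks
    if (nrow(tr) == 0L) {
      stop("condition '", ts$condition,
           "' has no tracks after filtering", call. = FALSE)
    }
    ok <- tr$track_id[-1L] == tr$track_id[-nrow(tr)] &
      (tr$frame[-1L] - tr$frame[-nrow(tr)] == 1L)
    dx <- tr$x_um[-1L][ok] - tr$x_um[-nrow(tr)][ok]
    dy <- tr$y_um[-1L][ok] - tr$y_um[-nrow(tr)][ok]
    c(dx, dy)
  })
  structure(list(d = stats::setNames(d, labels), frame_interval = dts[1L]),
            class = "displacement_sample")
}

#' Pooled Gaussian mixture fit with shared diffusion coefficients
#'
#' Fits a zero-mean K-component Gaussian mixture to the 1-D displacement
#' components of several experimental conditions simultaneously. The
#' component standard deviations (hence the apparent diffusion
#' coefficients `D_i = sigma_i^2 / (2 dt)`) are shared across all
#' conditions, while the population weights are free per condition —
#' keeping D at one value calculated for all conditions so that changes
#' in population sizes can be compared directly.
#'
#' EM details: responsibilities are computed per condition with that
#' condition's weights; the M step updates each shared variance from the
#' responsibility-weighted second moments pooled over all conditions and
#' each condition's weights from its own responsibilities.
#'
#' @param s a [extract_displacements] `displacement_sample`.
#' @param K number of shared components (default 2, the two-state model);
#'   every condition needs at least `100 * K` components.
#' @param init optional list with `sigma` (length K) and optionally
#'   `weights` (conditions x K matrix) as starting values, e.g. taken from
#'   per-condition jump-distance fits.
#' @param tol relative log-likelihood tolerance (default 1e-8).
#' @param max_iter maximum EM iterations (default 2000).
#' @return object of class `pooled_gmm_fit`: `K`, `sigma` (ascending,
#'   um), `D` (um^2/s), `weights` (conditions x K matrix, rows summing to
#'   1), `loglik`, `n` (per condition), `iterations`, `frame_interval`.
#' @export
fit_pooled_gmm <- function(s, K = 2, init = NULL, tol = 1e-8,
                           max_iter = 2000) {
  stopifnot(inherits(s, "displacement_sample"))
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  labels <- names(s$d)
  C <- length(labels)
  n_c <- vapply(s$d, length, integer(1))
  if (any(n_c < 100L * K)) {
    stop(.condition_error("smt_samplesize_error",
         sprintf("every condition needs >= %d displacement components", 100L * K)))
  }
  dt <- s$frame_interval
  pooled <- unlist(s$d, use.names = FALSE)
  if (!is.null(init)) {
    sigma <- sort(as.numeric(init$sigma))
    stopifnot(length(sigma) == K, all(sigma > 0))
    weights <- if (!is.null(init$weights)) {
      w <- matrix(init$weights, nrow = C, ncol = K)
      w / rowSums(w)
    } else matrix(1 / K, C, K)
  } else if (K == 1L) {
    sigma <- sqrt(mean(pooled^2))
    weights <- matrix(1, C, 1)
  } else {
    a <- abs(pooled)
    grp <- cut(rank(a, ties.method = "first"), K, labels = FALSE)
    sigma <- sort(vapply(1:K, function(i) sqrt(mean(pooled[grp == i]^2)),
                         numeric(1)))
    weights <- matrix(1 / K, C, K)
  }
  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ll <- 0
    ssq <- numeric(K)   # responsibility-weighted sums of d^2, pooled
    nk_pool <- numeric(K)
    w_new <- weights
    for (ci in seq_len(C)) {
      d <- s$d[[ci]]
      logd <- vapply(1:K, function(i) {
        log(weights[ci, i]) + stats::dnorm(d, 0, sigma[i], log = TRUE)
      }, numeric(length(d)))
      if (is.null(dim(logd))) logd <- matrix(logd, nrow = length(d))
      mx <- apply(logd, 1L, max)
      w <- exp(logd - mx)
      rs <- rowSums(w)
      ll <- ll + sum(mx + log(rs))
      gamma <- w / rs
      Nk <- colSums(gamma)
      w_new[ci, ] <- Nk / length(d)
      ssq <- ssq + colSums(gamma * d^2)
      nk_pool <- nk_pool + Nk
    }
    if (ll < ll_old - 1e-7 * max(1, abs(ll_old))) {
      stop("EM log-likelihood decreased; numerical failure", call. = FALSE)
    }
    sigma_new <- sqrt(ssq / nk_pool)
    converged <- is.finite(ll_old) &&
      abs(ll - ll_old) <= tol * max(1, abs(ll_old))
    sigma <- sigma_new; weights <- w_new; ll_old <- ll
    if (converged) break
    if (iter >= max_iter) {
      stop(.condition_error("smt_convergence_error",
           sprintf("pooled GMM EM did not converge in %d iterations", max_iter),
           data = list(sigma = sigma, weights = weights, loglik = ll)))
    }
  }
  ord <- order(sigma)
  sigma <- sigma[ord]
  weights <- weights[, ord, drop = FALSE]
  dimnames(weights) <- list(labels, paste0("component", seq_len(K)))
  structure(
    list(K = K, sigma = sigma, D = sigma^2 / (2 * dt), weights = weights,
         loglik = ll_old, n = stats::setNames(n_c, labels),
         iterations = iter, frame_interval = dt),
    class = "pooled_gmm_fit"
  )
}

#' @export
print.pooled_gmm_fit <- function(x, ...) {
  cat(sprintf("pooled_gmm_fit: K = %d shared components over %d condition(s)\n",
              x$K, nrow(x$weights)))
  cat("  shared D (um^2/s):", paste(sprintf("%.4f", x$D), collapse = ", "), "\n")
  for (lab in rownames(x$weights)) {
    cat(sprintf("  %-14s f = %s  (n = %d)\n", lab,
                paste(sprintf("%.1f%%", 100 * x$weights[lab, ]),
                      collapse = " / "), x$n[lab]))
  }
  invisible(x)
}

#' Population-shift table relative to a reference condition
#'
#' Tabulates each condition's slow (first-component) fraction and its
#' absolute and relative change versus a reference condition, the way
#' cross-condition population shifts are reported: relative change =
#' 100 * (f_c - f_ref) / f_ref, signed, rounded to one decimal.
#'
#' @param fit a [fit_pooled_gmm] result.
#' @param reference label of the reference condition (must be present).
#' @return data.frame with columns `condition`, `f_slow_pct`,
#'   `abs_change_points`, `rel_change_pct` (1 decimal).
#' @export
population_shift_table <- function(fit, reference) {
  stopifnot(inherits(fit, "pooled_gmm_fit"))
  labels <- rownames(fit$weights)
  if (!reference %in% labels) {
    stop("unknown reference condition: ", reference, call. = FALSE)
  }
  f <- 100 * fit$weights[, 1L]
  f_ref <- f[[reference]]
  data.frame(
    condition = labels,
    f_slow_pct = as.numeric(f),
    abs_change_points = as.numeric(f - f_ref),
    rel_change_pct = round(100 * (as.numeric(f) - f_ref) / f_ref, 1),
    row.names = NULL
  )
}
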