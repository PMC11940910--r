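#' Extract single-interval jump distances from a track set
#'
#' Applies the minimum-length filter, then collects the Euclidean
#' displacement r between every pair of consecutive-frame detections in
#' every surviving track. Steps spanning frame gaps are skipped, not
#' interpolated, so every jump corresponds to exactly one frame interval.
#' For 2-D Brownian motion r is Rayleigh distributed and the squared
#' displacement u = r^2 is exponential with mean 4 * D_app * dt, which is
#' what the mixture fit exploits.
#'
#' @param ts a [track_set].
#' @param min_frames minimum track length in detections (default 5).
#' @return an object of class `jump_sample`: list with `r`, `u = r^2`,
#'   `frame_interval`, `localization_precision`, `condition`, `n`.
#' @export
extract_jumps <- function(ts, min_frames = 5) {
  stopifnot(inherits(ts, "track_set"))
  fts <- filter_min_length(ts, min_frames)
  tr <- fts$tracks
  if (nrow(tr) == 0L) {
    stop("no tracks survive the minimum-length filter (min_frames = ",
         min_frames, ")", call. = FALSE)
  }
  same <- tr$track_id[-1L] == tr$track_id[-nrow(tr)]
  consec <- tr$frame[-1L] - tr$frame[-nrow(tr)] == 1L
  ok <- same & consec
  dx <- tr$x_um[-1L][ok] - tr$x_um[-nrow(tr)][ok]
  dy <- tr$y_um[-1L][ok] - tr$y_um[-nrow(tr)][ok]
  r <- sqrt(dx^2 + dy^2)
  if (length(r) == 0L) {
    stop("no consecutive-frame jumps found after filtering", call. = FALSE)
  }
  structure(
    list(r = r, u = r^2,
         frame_interval = fts$frame_interval,
         localization_precision = fts$localization_precision,
         condition = fts$condition, n = length(r)),
    class = "jump_sample"
  )
}

#' @export
print.jump_sample <- function(x, ...) {
  cat(sprintf(
    "jump_sample: %d jumps | condition '%s' | dt = %g s | mean u = %.5f um^2\n",
    x$n, x$condition, x$frame_interval, mean(x$u)))
  invisible(x)
}

# log-likelihood of the K-component exponential mixture on u
# m: component means (4 D dt), f: fractions
.exp_mixture_loglik <- function(u, m, f) {
  dens <- vapply(seq_along(m),
                 function(i) f[i] * stats::dexp(u, rate = 1 / m[i]),
                 numeric(length(u)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(u))
  sum(log(pmax(rowSums(dens), .Machine$double.xmin)))
}

.condition_error <- function(class, message, data = NULL) {
  structure(class = c(class, "error", "condition"),
            list(message = message, call = sys.call(-1), data = data))
}

#' Fit a K-component Rayleigh (squared-displacement) mixture
#'
#' Maximum-likelihood fit of the jump-distance model in which the squared
#' displacement u is a K-component exponential mixture with component
#' means `m_i = 4 * D_i * dt` (equivalently, r is a Rayleigh mixture),
#' fitted by EM with closed-form updates. The fitted coefficients are
#' *apparent*: localization noise inflates them by `sigma^2 / dt`. An
#' optional correction subtracts that term.
#'
#' @param s a [extract_jumps] `jump_sample`.
#' @param K number of components, 1 to 3; requires `n >= 50 * K`.
#' @param correct_precision if TRUE, report `D = D_app - sigma^2 / dt`
#'   using the sample's localization precision (default FALSE: apparent
#'   coefficients, the convention used for reported values).
#' @param init optional list with elements `m` (component means of u) and
#'   `f` (fractions) to override the default K-quantile initialization;
#'   used mainly to verify initialization invariance.
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter maximum EM iterations (default 5000; near-degenerate
#'   component merges converge slowly along a likelihood ridge);
#'   non-convergence
#'   raises a condition of class `smt_convergence_error` carrying the last
#'   iterate in its `data` field.
#' @return an object of class `jd_fit`: `K`, `D` (ascending, um^2/s), `f`
#'   (fractions summing to 1), `m` (component means of u), `loglik`,
#'   `bic = -2 loglik + (2K - 1) log(n)`, `r2` (coefficient of
#'   determination between empirical and fitted CDF of u), `n`,
#'   `iterations`, `frame_interval`, `condition`.
#' @export
fit_rayleigh_mixture <- function(s, K, correct_precision = FALSE,
                                 init = NULL, tol = 1e-8, max_iter = 5000) {
  stopifnot(inherits(s, "jump_sample"))
  K <- as.integer(K)
  if (K < 1L || K > 3L) stop("K must be 1, 2 or 3", call. = FALSE)
  n <- s$n
  if (n < 50L * K) {
    stop(.condition_error("smt_samplesize_error",
         sprintf("need at least %d jumps for K = %d (have %d)", 50L * K, K, n)))
  }
  u <- s$u
  u[u <= 0] <- .Machine$double.xmin  # zero-length jumps carry no scale info
  dt <- s$frame_interval
  if (!is.null(init)) {
    m <- as.numeric(init$m); f <- as.numeric(init$f)
    stopifnot(length(m) == K, length(f) == K, all(m > 0), all(f > 0))
    f <- f / sum(f)
  } else if (K == 1L) {
    m <- mean(u); f <- 1
  } else {
    # K-quantile split of u
    grp <- cut(rank(u, ties.method = "first"), K, labels = FALSE)
    m <- vapply(1:K, function(i) mean(u[grp == i]), numeric(1))
    f <- rep(1 / K, K)
  }
  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E step
    logd <- vapply(1:K, function(i) log(f[i]) - log(m[i]) - u / m[i],
                   numeric(n))
    if (is.null(dim(logd))) logd <- matrix(logd, nrow = n)
    mx <- apply(logd, 1L, max)
    w <- exp(logd - mx)
    rs <- rowSums(w)
    ll <- sum(mx + log(rs))
    if (ll < ll_old - 1e-7 * max(1, abs(ll_old))) {
      stop("EM log-likelihood decreased; numerical failure", call. = FALSE)
    }
    gamma <- w / rs
    # M step
    Nk <- colSums(gamma)
    f_new <- Nk / n
    m_new <- colSums(gamma * u) / Nk
    converged <- is.finite(ll_old) &&
      abs(ll - ll_old) <= tol * max(1, abs(ll_old))
    f <- f_new; m <- m_new; ll_old <- ll
    if (converged) break
    if (iter >= max_iter) {
      stop(.condition_error("smt_convergence_error",
           sprintf("EM did not converge in %d iterations", max_iter),
           data = list(m = m, f = f, loglik = ll)))
    }
  }
  ord <- order(m)
  m <- m[ord]; f <- f[ord]
  ll <- .exp_mixture_loglik(u, m, f)
  D_app <- m / (4 * dt)
  D <- if (correct_precision) {
    pmax(D_app - s$localization_precision^2 / dt, 0)
  } else D_app
  bic <- -2 * ll + (2 * K - 1) * log(n)
  us <- sort(u)
  ecdf_u <- seq_len(n) / n
  Fu <- 1 - colSums(f * exp(-outer(1 / m, us)))
  r2 <- 1 - sum((ecdf_u - Fu)^2) / sum((ecdf_u - mean(ecdf_u))^2)
  structure(
    list(K = K, D = D, f = f, m = m, loglik = ll, bic = bic, r2 = r2,
         n = n, iterations = iter, corrected = correct_precision,
         frame_interval = dt, condition = s$condition),
    class = "jd_fit"
  )
}

#' @export
print.jd_fit <- function(x, ...) {
  cat(sprintf("jd_fit (K = %d, n = %d jumps, condition '%s')\n",
              x$K, x$n, x$condition))
  for (i in seq_len(x$K)) {
    cat(sprintf("  D%d = %.4f um^2/s  (%.1f%%)\n", i, x$D[i], 100 * x$f[i]))
  }
  cat(sprintf("  loglik = %.2f | BIC = %.2f | CDF R^2 = %.4f\n",
              x$loglik, x$bic, x$r2))
  invisible(x)
}

#' Select the number of diffusive states by BIC
#'
#' Fits K = 1..K_max mixtures and returns the fit minimizing the Bayesian
#' Information Criterion, which penalizes extra components and so guards
#' against over-fitting. Ties break toward the smaller K.
#'
#' @inheritParams fit_rayleigh_mixture
#' @param K_max largest component count to consider (default 3).
#' @param ... passed on to [fit_rayleigh_mixture].
#' @return the BIC-minimizing `jd_fit`, with an attribute `all_fits`
#'   holding every per-K fit.
#' @export
select_model <- function(s, K_max = 3, ...) {
  stopifnot(inherits(s, "jump_sample"))
  K_max <- as.integer(K_max)
  fits <- lapply(seq_len(K_max), function(k) fit_rayleigh_mixture(s, k, ...))
  bics <- vapply(fits, function(fit) fit$bic, numeric(1))
  best <- fits[[which.min(bics)]]  # which.min takes the first (smallest K) tie
  attr(best, "all_fits") <- fits
  best
}
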