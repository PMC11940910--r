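#' Configuration for the two-state membrane diffusion simulator
#'
#' Describes the full generative model: a molecule diffuses on the 2-D
#' projection of a spherocylindrical cell membrane, switching between a
#' slow (substrate-bound) and a fast (freely diffusive) state, observed
#' with Gaussian localization noise at fixed frame intervals until it
#' photobleaches.
#'
#' Switching is a discretized two-state Markov chain: per frame the
#' molecule leaves its state with probability `1 - exp(-dt / mean_dwell)`.
#' When `mean_state_dwell_fast` is `NULL` (default) it is derived as
#' `mean_state_dwell_slow * (1 - f_slow) / f_slow`, so the chain is
#' stationary at `f_slow` and the long-run state occupancy equals the
#' requested slow fraction. Supplying it explicitly overrides the
#' derivation, in which case `f_slow` only sets the initial-state
#' probability.
#'
#' @param D_slow,D_fast true diffusion coefficients of the two states in
#'   um^2/s (`D_fast >= D_slow >= 0`). Note the fitted, *apparent*
#'   coefficients are inflated by localization noise:
#'   `D_app = D + sigma^2 / dt`.
#' @param f_slow stationary probability of the slow state in `[0, 1]`.
#' @param mean_state_dwell_slow mean residence in the slow state, seconds.
#' @param mean_state_dwell_fast mean residence in the fast state, seconds,
#'   or `NULL` to derive it from `f_slow` (see Details).
#' @param frame_interval acquisition interval dt in seconds (default 0.02).
#' @param localization_precision per-axis localization noise sigma in um
#'   (default 0.03, within the usual sub-50-nm precision of YFP-based SMT;
#'   with dt = 0.02 s the default true coefficients then produce the
#'   canonical apparent pair `D_app = D + sigma^2/dt` = (0.08, 0.57)).
#' @param bleach_half_life fluorophore half-life in seconds (default 1.2,
#'   typical for YFP); per-frame survival is `2^(-dt / half_life)`.
#' @param n_tracks number of molecules to simulate.
#' @param max_frames_per_track hard cap on track length in frames.
#' @param cell a [cell_outline] confining the motion (default the
#'   standardized 3 x 1 um cell).
#' @param zone_bias optional initial-position sampling weights over the
#'   (septal, lateral, polar) long-axis zones: either a numeric length-3
#'   vector applied to both states, or a list with elements `slow` and
#'   `fast`. `NULL` (default) samples uniformly over the cell area.
#'   Motion itself is never biased.
#' @param seed master integer seed; per-track streams are derived by
#'   counter, so generation is reproducible and order-independent.
#' @param condition label attached to the generated [track_set].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(D_slow = 0.035, D_fast = 0.525, f_slow = 0.5,
                       mean_state_dwell_slow = 0.5,
                       mean_state_dwell_fast = NULL,
                       frame_interval = 0.02,
                       localization_precision = 0.03,
                       bleach_half_life = 1.2,
                       n_tracks = 1000, max_frames_per_track = 600,
                       cell = standard_cell(), zone_bias = NULL,
                       seed = 1, condition = "sim") {
  if (!(f_slow >= 0 && f_slow <= 1)) stop("f_slow must be in [0, 1]", call. = FALSE)
  if (!(D_fast >= D_slow && D_slow >= 0)) {
    stop("require D_fast >= D_slow >= 0", call. = FALSE)
  }
  if (is.null(mean_state_dwell_fast)) {
    mean_state_dwell_fast <- if (f_slow > 0 && f_slow < 1) {
      mean_state_dwell_slow * (1 - f_slow) / f_slow
    } else {
      mean_state_dwell_slow  # switching disabled below for f_slow in {0,1}
    }
  }
  for (v in c(mean_state_dwell_slow = mean_state_dwell_slow,
              mean_state_dwell_fast = mean_state_dwell_fast,
              frame_interval = frame_interval,
              bleach_half_life = bleach_half_life)) {
    if (!is.finite(v) || v <= 0) {
      stop("durations and rates must be positive and finite", call. = FALSE)
    }
  }
  if (localization_precision < 0) stop("localization_precision must be >= 0", call. = FALSE)
  if (n_tracks < 1 || max_frames_per_track < 2) {
    stop("need n_tracks >= 1 and max_frames_per_track >= 2", call. = FALSE)
  }
  stopifnot(inherits(cell, "cell_outline"))
  if (!is.null(zone_bias) && !is.list(zone_bias)) {
    zone_bias <- list(slow = zone_bias, fast = zone_bias)
  }
  if (!is.null(zone_bias)) {
    for (w in zone_bias) {
      if (length(w) != 3L || any(w < 0) || sum(w) <= 0) {
        stop("zone_bias weights must be 3 non-negative numbers (septal, lateral, polar)",
             call. = FALSE)
      }
    }
  }
  structure(
    list(D_slow = D_slow, D_fast = D_fast, f_slow = f_slow,
         mean_state_dwell_slow = mean_state_dwell_slow,
         mean_state_dwell_fast = mean_state_dwell_fast,
         frame_interval = frame_interval,
         localization_precision = localization_precision,
         bleach_half_life = bleach_half_life,
         n_tracks = as.integer(n_tracks),
         max_frames_per_track = as.integer(max_frames_per_track),
         cell = cell, zone_bias = zone_bias,
         seed = as.integer(seed), condition = condition),
    class = "sim_config"
  )
}

# point-in-spherocylinder test, local (unrotated, centred) coordinates
.in_cell_local <- function(x, y, L, W) {
  h <- (L - W) / 2  # half-length of the straight section
  R <- W / 2
  ifelse(abs(x) <= h, abs(y) <= R, (abs(x) - h)^2 + y^2 <= R^2)
}

# reflect a proposed point back into the spherocylinder (local coords)
.reflect_into_cell <- function(x, y, L, W) {
  h <- (L - W) / 2
  R <- W / 2
  for (it in 1:20) {
    if (.in_cell_local(x, y, L, W)) return(c(x, y))
    if (abs(x) <= h) {
      # straight section: reflect across y = +/- R
      y <- sign(y) * (2 * R - abs(y))
    } else {
      # cap: radial reflection about the circle of radius R
      cx <- sign(x) * h
      dx <- x - cx; dy <- y
      rho <- sqrt(dx^2 + dy^2)
      if (rho < .Machine$double.eps) return(c(cx, 0))
      rho2 <- 2 * R - rho
      if (rho2 < 0) rho2 <- -rho2  # very large jump: fold again
      x <- cx + dx * rho2 / rho
      y <- dy * rho2 / rho
    }
  }
  # pathological jump: clamp to the boundary direction
  rho <- sqrt(x^2 + y^2)
  c(x, y) * min(1, (L / 2) / max(rho, .Machine$double.eps)) * 0.99
}

# sample one initial position, optionally zone-biased (local coords)
.sample_initial <- function(L, W, weights = NULL, septal = 0.2, polar = 0.8) {
  repeat {
    x <- stats::runif(1, -L / 2, L / 2)
    y <- stats::runif(1, -W / 2, W / 2)
    if (!.in_cell_local(x, y, L, W)) next
    if (is.null(weights)) return(c(x, y))
    xr <- abs(2 * x / L)
    zone <- if (xr < septal) 1L else if (xr > polar) 3L else 2L
    if (stats::runif(1) < weights[zone] / max(weights)) return(c(x, y))
  }
}

#' Simulate a two-state track set with ground truth
#'
#' Realizes the generative model described in [sim_config]: per-frame
#' Markov state switching, per-axis Gaussian displacement steps with
#' variance `2 * D_state * dt`, reflection at the cell outline, additive
#' Gaussian localization noise, and geometric photobleaching. Tracks that
#' bleach before their second frame are discarded. Identical seeds yield
#' identical output.
#'
#' @param cfg a [sim_config].
#' @return a list of class `sim_result` with elements
#'   \describe{
#'     \item{tracks}{the observed [track_set] (noisy positions);}
#'     \item{truth}{data.frame of per-detection ground truth:
#'       `track_id`, `frame`, `state` ("slow"/"fast"), `x_true_um`,
#'       `y_true_um`.}
#'   }
#' @export
simulate_trackset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  dt <- cfg$frame_interval
  L <- cfg$cell$length; W <- cfg$cell$width
  sd_step <- c(slow = sqrt(2 * cfg$D_slow * dt),
               fast = sqrt(2 * cfg$D_fast * dt))
  # per-frame switch probabilities; disabled at the degenerate fractions
  switching <- cfg$f_slow > 0 && cfg$f_slow < 1
  p_leave <- c(slow = 1 - exp(-dt / cfg$mean_state_dwell_slow),
               fast = 1 - exp(-dt / cfg$mean_state_dwell_fast))
  p_survive <- 2^(-dt / cfg$bleach_half_life)
  theta <- cfg$cell$orientation
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  res <- vector("list", cfg$n_tracks)
  for (i in seq_len(cfg$n_tracks)) {
    set.seed((cfg$seed %% 1000003L) * 2011L + i)
    nf <- min(1L + stats::rgeom(1, 1 - p_survive), cfg$max_frames_per_track)
    if (nf < 2L) next
    state <- integer(nf)  # 1 slow, 2 fast
    state[1] <- if (stats::runif(1) < cfg$f_slow) 1L else 2L
    if (switching && nf > 1L) {
      u <- stats::runif(nf - 1L)
      for (k in 2:nf) {
        s <- state[k - 1L]
        state[k] <- if (u[k - 1L] < p_leave[s]) 3L - s else s
      }
    } else {
      state[] <- state[1]
    }
    wts <- if (is.null(cfg$zone_bias)) NULL else {
      cfg$zone_bias[[c("slow", "fast")[state[1]]]]
    }
    pos <- matrix(0, nf, 2)
    pos[1, ] <- .sample_initial(L, W, wts)
    if (nf > 1L) {
      steps <- matrix(stats::rnorm(2 * (nf - 1L)), nf - 1L, 2) *
        sd_step[state[2:nf]]
      for (k in 2:nf) {
        p <- pos[k - 1L, ] + steps[k - 1L, ]
        pos[k, ] <- .reflect_into_cell(p[1], p[2], L, W)
      }
    }
    noise <- if (cfg$localization_precision > 0) {
      matrix(stats::rnorm(2 * nf, sd = cfg$localization_precision), nf, 2)
    } else matrix(0, nf, 2)
    obs <- pos + noise
    # local -> world coordinates
    pos_w <- pos %*% t(rot)
    obs_w <- obs %*% t(rot)
    res[[i]] <- data.frame(
      track_id = rep.int(i, nf), frame = 0:(nf - 1L),
      x_um = obs_w[, 1] + cfg$cell$center[1],
      y_um = obs_w[, 2] + cfg$cell$center[2],
      x_true_um = pos_w[, 1] + cfg$cell$center[1],
      y_true_um = pos_w[, 2] + cfg$cell$center[2],
      state = c("slow", "fast")[state])
  }
  all <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(all) || nrow(all) == 0L) {
    stop("simulation produced no tracks of length >= 2; increase bleach_half_life",
         call. = FALSE)
  }
  all$cell_id <- cfg$cell$cell_id
  ts <- track_set(all[, c("track_id", "frame", "x_um", "y_um", "cell_id")],
                  frame_interval = dt,
                  localization_precision = cfg$localization_precision,
                  condition = cfg$condition)
  truth <- all[, c("track_id", "frame", "state", "x_true_um", "y_true_um")]
  truth$track_id <- as.character(truth$track_id)
  rownames(truth) <- NULL
  structure(list(tracks = ts, truth = truth, config = cfg),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result (two-state diffusion)\n")
  print(x$tracks)
  occ <- mean(x$truth$state == "slow")
  cat(sprintf("  ground-truth slow-state occupancy: %.3f\n", occ))
  invisible(x)
}

# stable 31-bit string hash for label-derived seeds
.label_hash <- function(label) {
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483629
  as.integer(h)
}

#' Simulate several experimental conditions sharing diffusion coefficients
#'
#' Generates one track set per condition label. All conditions share the
#' base configuration's diffusion coefficients and acquisition settings
#' and differ only in slow-state fraction and (optionally) the spatial
#' zone bias — the design the pooled cross-condition mixture fit assumes.
#' Each condition's seed is derived deterministically from the base seed
#' and the label, so permuting the override order does not change any
#' per-label output.
#'
#' @param base a [sim_config] providing shared parameters.
#' @param overrides a list of per-condition overrides; each element is a
#'   list with `label` (required, unique), and optionally `f_slow`,
#'   `zone_bias`, `n_tracks`.
#' @return a named list of [simulate_trackset] results (class
#'   `sim_result`), one per label.
#' @export
simulate_conditions <- function(base, overrides) {
  stopifnot(inherits(base, "sim_config"), is.list(overrides),
            length(overrides) > 0L)
  labels <- vapply(overrides, function(o) as.character(o$label), character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate condition labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(overrides, function(o) {
    cfg <- base
    cfg$condition <- o$label
    cfg$seed <- as.integer((base$seed + .label_hash(o$label)) %% 2147483629)
    if (!is.null(o$f_slow)) {
      cfg$f_slow <- o$f_slow
      # keep the chain stationary at the new fraction
      if (o$f_slow > 0 && o$f_slow < 1) {
        cfg$mean_state_dwell_fast <-
          cfg$mean_state_dwell_slow * (1 - o$f_slow) / o$f_slow
      }
    }
    if (!is.null(o$zone_bias)) {
      zb <- o$zone_bias
      if (!is.list(zb)) zb <- list(slow = zb, fast = zb)
      cfg$zone_bias <- zb
    }
    if (!is.null(o$n_tracks)) cfg$n_tracks <- as.integer(o$n_tracks)
    simulate_trackset(cfg)
  })
  stats::setNames(out, labels)
}
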