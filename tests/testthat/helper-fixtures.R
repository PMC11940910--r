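# shared fixture builders (all synthetic, generated at test time)

make_track_df <- function(track_id, frames, x, y, cell_id = NULL) {
  df <- data.frame(track_id = track_id, frame = frames, x_um = x, y_um = y)
  if (!is.null(cell_id)) df$cell_id <- cell_id
  df
}

# a stationary track of n detections at (x0, y0)
stationary_track <- function(id, n, x0 = 0, y0 = 0, start_frame = 0) {
  make_track_df(rep(id, n), start_frame + 0:(n - 1), rep(x0, n), rep(y0, n))
}

# random-walk track table with given per-track lengths
random_tracks <- function(lengths, step_sd = 0.05, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(lengths), function(i) {
    n <- lengths[i]
    make_track_df(rep(i, n), 0:(n - 1),
                  cumsum(c(stats::runif(1, -1, 1), stats::rnorm(n - 1, 0, step_sd))),
                  cumsum(c(stats::runif(1, -1, 1), stats::rnorm(n - 1, 0, step_sd))))
  }))
}

# jump_sample built directly from squared displacements (bypasses tracks)
make_jump_sample <- function(u, dt = 0.02, sigma = 0, condition = "synthetic") {
  structure(list(r = sqrt(u), u = u, frame_interval = dt,
                 localization_precision = sigma, condition = condition,
                 n = length(u)),
            class = "jump_sample")
}

# exponential-mixture squared displacements at apparent D and fractions f
mixture_u <- function(n, D, f, dt = 0.02, seed = 1) {
  set.seed(seed)
  comp <- sample.int(length(D), n, replace = TRUE, prob = f)
  stats::rexp(n, rate = 1 / (4 * D[comp] * dt))
}

# displacement_sample built directly from per-condition component vectors
make_displacement_sample <- function(d_list, dt = 0.02) {
  structure(list(d = d_list, frame_interval = dt),
            class = "displacement_sample")
}

# pooled_gmm_fit stub with given slow-fraction percentages (for shift tables)
make_gmm_stub <- function(f_slow_pct, dt = 0.02, sigma = c(0.06, 0.17)) {
  w <- cbind(f_slow_pct / 100, 1 - f_slow_pct / 100)
  dimnames(w) <- list(names(f_slow_pct), c("component1", "component2"))
  structure(list(K = 2L, sigma = sigma, D = sigma^2 / (2 * dt), weights = w,
                 loglik = 0, n = stats::setNames(rep(1000L, length(f_slow_pct)),
                                                 names(f_slow_pct)),
                 iterations = 1L, frame_interval = dt),
            class = "pooled_gmm_fit")
}

# dwell events table from durations in seconds
make_events <- function(durations, dt = 0.02) {
  data.frame(track_id = as.character(seq_along(durations)),
             start_frame = 0L,
             n_frames = as.integer(round(durations / dt)) + 1L,
             duration = durations)
}

# the Pbp-style recovery worlds: printed values are APPARENT coefficients;
# the generator takes true D = D_app - sigma^2/dt at sigma = 30 nm
apparent_world <- function(D1_app, D2_app, f_slow, seed, n_tracks = 300, ...) {
  sigma <- 0.03
  corr <- sigma^2 / 0.02
  sim_config(D_slow = D1_app - corr, D_fast = D2_app - corr, f_slow = f_slow,
             localization_precision = sigma, n_tracks = n_tracks,
             seed = seed, ...)
}
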