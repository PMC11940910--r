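test_that("dwell events follow the radius / nine-interval convention", {
  dc <- dwell_config(0.12, 9, 0.02)
  # perfectly stationary 12-frame track: one event spanning the track
  ts12 <- track_set(stationary_track("a", 12), frame_interval = 0.02,
                    localization_precision = 0)
  ev <- extract_dwell_events(ts12, dc)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_frames, 12L)
  expect_equal(ev$duration, 11 * 0.02)

  # an 8-frame stay is below the nine-frame threshold
  ts8 <- track_set(stationary_track("b", 8), localization_precision = 0)
  expect_equal(nrow(extract_dwell_events(ts8, dc)), 0L)

  # 5-9 frame stationary tracks never yield events (they are simply too short)
  short <- track_set(do.call(rbind, lapply(5:8, function(n) {
    stationary_track(paste0("t", n), n, x0 = n)
  })), localization_precision = 0)
  expect_equal(nrow(extract_dwell_events(short, dc)), 0L)

  # a molecule that leaves the radius closes the event at the exit point
  x <- c(rep(0, 10), 1, rep(1, 10))
  tr <- track_set(make_track_df(rep(1, 21), 0:20, x, rep(0, 21)),
                  localization_precision = 0)
  ev2 <- extract_dwell_events(tr, dc)
  expect_equal(nrow(ev2), 2L)
  expect_equal(ev2$start_frame, c(0L, 10L))
  expect_equal(ev2$n_frames, c(10L, 11L))
})

test_that("extractor agrees with an independent brute-force scanner", {
  # independent reference: for each anchor, walk forward point by point
  brute <- function(x, y, fr, radius, min_frames) {
    out <- list(); i <- 1L; n <- length(x)
    while (i <= n) {
      j <- i + 1L
      while (j <= n && sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2) <= radius) {
        j <- j + 1L
      }
      len <- j - i
      if (len >= min_frames) out[[length(out) + 1L]] <- c(fr[i], len)
      i <- if (j > n) n + 1L else j
    }
    do.call(rbind, out)
  }
  dc <- dwell_config(0.1, 6, 0.02)
  set.seed(64)
  df <- random_tracks(sample(6:40, 100, replace = TRUE), step_sd = 0.04,
                      seed = 64)
  ts <- track_set(df, localization_precision = 0)
  ev <- extract_dwell_events(ts, dc)
  ref <- do.call(rbind, lapply(unique(ts$tracks$track_id), function(id) {
    sub <- ts$tracks[ts$tracks$track_id == id, ]
    b <- brute(sub$x_um, sub$y_um, sub$frame, dc$radius, dc$min_frames)
    if (is.null(b)) return(NULL)
    data.frame(track_id = id, start_frame = b[, 1], n_frames = b[, 2])
  }))
  expect_equal(nrow(ev), nrow(ref))
  expect_equal(ev$start_frame, ref$start_frame)
  expect_equal(ev$n_frames, as.integer(ref$n_frames))
  # events never overlap within a track
  by_track <- split(ev, ev$track_id)
  for (sub in by_track) {
    if (nrow(sub) < 2) next
    expect_true(all(diff(sub$start_frame) >= sub$n_frames[-nrow(sub)]))
  }
})

test_that("fast-state tracks almost never produce dwell events", {
  dc <- dwell_config(0.12, 9, 0.02)
  rates <- vapply(1:10, function(s) {
    cfg <- sim_config(D_slow = 0.57, D_fast = 0.57, f_slow = 1,
                      localization_precision = 0, bleach_half_life = 1e6,
                      n_tracks = 200, max_frames_per_track = 50, seed = 400 + s)
    sim <- simulate_trackset(cfg)
    nrow(extract_dwell_events(sim$tracks, dc)) / n_tracks(sim$tracks)
  }, numeric(1))
  expect_lt(mean(rates), 0.01)
})

test_that("truncated-exponential fit recovers the residence time", {
  dc <- dwell_config(0.12, 9, 0.02)
  t_min <- (9 - 1) * 0.02
  set.seed(12)
  tau_true <- 0.30
  ev <- make_events(t_min + stats::rexp(1e4, 1 / tau_true))
  fit <- fit_dwell_exponential(ev, dc, n_boot = 200, seed = 4)
  # memorylessness: mean kept duration = t_min + tau
  expect_lt(abs(fit$tau - tau_true) / tau_true, 0.03)
  expect_equal(fit$mean_residence, fit$tau + t_min)
  expect_gt(fit$se, 0)

  # degenerate: all durations at the truncation point
  flat <- make_events(rep(t_min, 50))
  expect_warning(f0 <- fit_dwell_exponential(flat, dc, n_boot = 50),
                 "boundary")
  expect_equal(f0$tau, 0)
  expect_true(f0$boundary)

  # bootstrap is reproducible under a fixed seed
  f1 <- fit_dwell_exponential(ev, dc, n_boot = 100, seed = 9)
  f2 <- fit_dwell_exponential(ev, dc, n_boot = 100, seed = 9)
  expect_identical(f1$bootstrap_taus, f2$bootstrap_taus)

  expect_error(fit_dwell_exponential(make_events(rep(0.2, 5)), dc),
               class = "smt_samplesize_error")
})

test_that("optional bleaching correction lengthens tau", {
  dc <- dwell_config(0.12, 9, 0.02)
  set.seed(2)
  ev <- make_events(0.16 + stats::rexp(500, 1 / 0.25))
  fit <- fit_dwell_exponential(ev, dc, n_boot = 50, bleach_half_life = 1.2)
  expect_gt(fit$tau_corrected, fit$tau)
})

test_that("Levene comparison separates unequal dwell variances", {
  dc <- dwell_config(0.12, 9, 0.02)
  # identical replicate sets: W = 0, p = 1
  set.seed(30)
  ev <- make_events(0.16 + stats::rexp(300, 1 / 0.2))
  fa <- fit_dwell_exponential(ev, dc, n_boot = 500, seed = 1)
  cmp0 <- compare_dwell(list(a = fa, b = fa))
  expect_equal(cmp0$W, 0)
  expect_equal(cmp0$p, 1)

  # three-fold tau difference at 1000 replicates: detected at p < 0.01
  ev1 <- make_events(0.16 + stats::rexp(300, 1 / 0.1))
  ev3 <- make_events(0.16 + stats::rexp(300, 1 / 0.3))
  f1 <- fit_dwell_exponential(ev1, dc, n_boot = 1000, seed = 2)
  f3 <- fit_dwell_exponential(ev3, dc, n_boot = 1000, seed = 3)
  cmp <- compare_dwell(list(lo = f1, hi = f3))
  expect_lt(cmp$p, 0.01)
  expect_equal(cmp$signif, "***")

  # C conditions -> C (C - 1) / 2 rows
  cmp4 <- compare_dwell(list(a = fa, b = f1, c = f3, d = fa))
  expect_equal(nrow(cmp4), 6L)
  expect_error(compare_dwell(list(fa, f1)), "named")
})

test_that("levene_test matches its textbook definition on a worked case", {
  # independent hand computation of the classic mean-centred statistic
  x <- c(1, 2, 3, 4, 10, 12, 14, 16)
  g <- rep(c("a", "b"), each = 4)
  z <- abs(x - ave(x, g))
  za <- z[1:4]; zb <- z[5:8]
  W_ref <- (8 - 2) / (2 - 1) *
    (4 * (mean(za) - mean(z))^2 + 4 * (mean(zb) - mean(z))^2) /
    (sum((za - mean(za))^2) + sum((zb - mean(zb))^2))
  lt <- levene_test(x, g)
  expect_equal(lt$W, W_ref, tolerance = 1e-12)
  expect_equal(lt$p, stats::pf(W_ref, 1, 6, lower.tail = FALSE))
})
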