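test_that("read_tracks parses minimal files and round-trips generated tables", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,frame,x_um,y_um", "1,0,0.5,0.25", "1,1,0.52,0.24"),
             tmp)
  ts <- read_tracks(tmp)
  expect_s3_class(ts, "track_set")
  expect_equal(n_tracks(ts), 1L)
  expect_equal(nrow(ts$tracks), 2L)
  expect_equal(ts$frame_interval, 0.02)

  # round trip on a generated multi-track table, coordinates to 6 decimals
  df <- random_tracks(c(5, 8, 3, 12), seed = 42)
  ts1 <- track_set(df, frame_interval = 0.05, localization_precision = 0.02,
                   condition = "roundtrip")
  out <- withr::local_tempfile(fileext = ".csv")
  write_tracks(ts1, out)
  ts2 <- read_tracks(out, frame_interval = 0.05,
                     localization_precision = 0.02, condition = "roundtrip")
  expect_identical(ts2$tracks$track_id, ts1$tracks$track_id)
  expect_identical(ts2$tracks$frame, ts1$tracks$frame)
  expect_equal(ts2$tracks$x_um, ts1$tracks$x_um, tolerance = 1e-6)
  expect_equal(ts2$tracks$y_um, ts1$tracks$y_um, tolerance = 1e-6)
})

test_that("track table validation catches format and invariant violations", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,frame,x_um", "1,0,0.5"), tmp)
  expect_error(read_tracks(tmp), "y_um")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("track_id,frame,x_um,y_um", "7,3,0,0", "7,3,0.1,0.1"), dup)
  expect_error(read_tracks(dup), "7")

  expect_error(track_set(make_track_df(1, 0:1, c(0, NaN), c(0, 0))), "finite")
  expect_error(track_set(make_track_df(1, c(-1, 0), c(0, 0), c(0, 0))),
               "non-negative")
  expect_error(track_set(make_track_df(1, 0:1, 0:1, 0:1),
                         frame_interval = 0), "frame_interval")
})

test_that("cell outline tables round-trip and validate geometry", {
  o1 <- cell_outline("a", c(1.5, -2), 0.3, 3.2, 0.9)
  o2 <- cell_outline("b", c(0, 0), -1.1, 2.8, 1.1)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_outlines(list(o1, o2), tmp)
  back <- read_outlines(tmp)
  expect_named(back, c("a", "b"))
  expect_equal(back$a$center, o1$center, tolerance = 1e-9)
  expect_equal(back$b$orientation, o2$orientation, tolerance = 1e-9)
  expect_error(cell_outline("bad", c(0, 0), 0, length = 0.5, width = 1),
               "length >= width")
})

test_that("filter_min_length applies the 5-frame rule and is idempotent", {
  df <- random_tracks(c(4, 5, 6), seed = 7)
  ts <- track_set(df)
  kept <- filter_min_length(ts, 5)
  expect_equal(n_tracks(kept), 2L)

  # min_frames = 2 is the identity on any valid track_set
  expect_identical(filter_min_length(ts, 2)$tracks, ts$tracks)

  # recount oracle on 1000 tracks with a known length distribution
  set.seed(11)
  lengths <- sample(2:12, 1000, replace = TRUE)
  big <- track_set(random_tracks(lengths, seed = 12))
  survivors <- filter_min_length(big, 5)
  expect_equal(n_tracks(survivors), sum(lengths >= 5))

  # idempotent and never increasing
  twice <- filter_min_length(survivors, 5)
  expect_identical(twice$tracks, survivors$tracks)
  expect_lte(n_tracks(survivors), n_tracks(big))
  expect_error(filter_min_length(ts, 1), "min_frames")
})

test_that("crop_to_single_molecule returns the trailing window", {
  expect_equal(unname(crop_to_single_molecule(3000, 2001)), c(999, 2999))
  expect_equal(unname(crop_to_single_molecule(2001, 2001)), c(0, 2000))
  expect_error(crop_to_single_molecule(2000, 2001), "exceeds")

  # property: window length == keep and window is a suffix, random cases
  set.seed(3)
  for (i in 1:50) {
    m <- sample(10:5000, 1)
    k <- sample(2:m, 1)
    w <- crop_to_single_molecule(m, k)
    expect_equal(unname(w[2] - w[1] + 1L), k)
    expect_equal(unname(w[2]), m - 1L)
  }
})

test_that("estimate_onset_from_decay finds the single-molecule crossing", {
  expect_equal(estimate_onset_from_decay(rep(1, 100)), 0L)
  expect_error(estimate_onset_from_decay(numeric(0)), "empty")
  expect_error(estimate_onset_from_decay(rep(0, 50)), "zero")

  # analytic crossing of A exp(-t/tau) + B at B + 1: t = tau * log(A)
  set.seed(21)
  t <- 0:999
  counts <- round(50 * exp(-t / 100) + 1 + stats::rnorm(1000, 0, 0.3))
  counts[counts < 0] <- 0
  onset <- estimate_onset_from_decay(counts)
  expect_lt(abs(onset - 100 * log(50)), 10)

  # monotone-decreasing synthetic counts give a valid index
  dec <- sort(sample(0:30, 200, replace = TRUE), decreasing = TRUE)
  idx <- estimate_onset_from_decay(dec)
  expect_gte(idx, 0L)
  expect_lt(idx, 200L)
})

test_that("link_detections links by nearest neighbour within the radius", {
  two <- data.frame(frame = c(0, 1), x_um = c(0, 0.05), y_um = c(0, 0))
  linked <- link_detections(two, max_radius = 0.3)
  expect_equal(length(unique(linked$track_id)), 1L)

  far <- data.frame(frame = c(0, 1), x_um = c(0, 0.5), y_um = c(0, 0))
  expect_equal(length(unique(link_detections(far, 0.3)$track_id)), 2L)

  # 50 well-separated simulated molecules: recovered count equals truth
  set.seed(5)
  nmol <- 50; nfr <- 10
  truth <- do.call(rbind, lapply(seq_len(nmol), function(i) {
    x0 <- (i %% 10) * 5; y0 <- (i %/% 10) * 5
    data.frame(frame = 0:(nfr - 1),
               x_um = x0 + cumsum(stats::rnorm(nfr, 0, 0.02)),
               y_um = y0 + cumsum(stats::rnorm(nfr, 0, 0.02)))
  }))
  truth <- truth[order(truth$frame), ]
  linked <- link_detections(truth, max_radius = 0.3)
  expect_equal(length(unique(linked$track_id)), nmol)
  expect_true(all(table(linked$track_id) == nfr))
})
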