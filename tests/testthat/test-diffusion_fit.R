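test_that("extract_jumps counts and values are exact", {
  # one 5-detection track -> 4 jumps; Pythagoras on a single step
  df <- make_track_df(rep(1, 5), 0:4,
                      c(0, 0.1, 0.1, 0.2, 0.2), c(0, 0, 0.1, 0.1, 0.3))
  s <- extract_jumps(track_set(df))
  expect_equal(s$n, 4L)
  expect_equal(s$r[1], 0.1)
  expect_equal(s$u[1], 0.01)
  expect_identical(s$u, s$r^2)

  # frame gaps are skipped, not interpolated
  gap <- make_track_df(rep(1, 5), c(0, 1, 2, 5, 6),
                       c(0, 1, 2, 3, 4), rep(0, 5))
  expect_equal(extract_jumps(track_set(gap))$n, 3L)

  # recount oracle on 100 generated tracks
  lengths <- sample(2:15, 100, replace = TRUE)
  big <- track_set(random_tracks(lengths, seed = 33))
  s2 <- extract_jumps(big, min_frames = 5)
  expect_equal(s2$n, sum(lengths[lengths >= 5] - 1L))

  expect_error(extract_jumps(track_set(random_tracks(c(2, 3), seed = 1)), 5),
               "no tracks survive")
})

test_that("single-component fit recovers a pure diffusion coefficient", {
  D <- 0.5; dt <- 0.02
  u <- mixture_u(1e5, D, 1, dt = dt, seed = 101)
  expect_lt(abs(mean(u) - 4 * D * dt) / (4 * D * dt), 0.02)
  fit <- fit_rayleigh_mixture(make_jump_sample(u, dt), 1)
  expect_equal(fit$K, 1L)
  expect_lt(abs(fit$D - D) / D, 0.02)
  expect_equal(sum(fit$f), 1)
})

test_that("two-component fit recovers the printed two-state parameters", {
  # the four printed parameter sets (apparent D and slow fractions)
  sets <- list(list(D = c(0.08, 0.57), f = 0.47),
               list(D = c(0.06, 0.54), f = 0.49),
               list(D = c(0.09, 0.57), f = 0.40),
               list(D = c(0.06, 0.54), f = 0.65))
  for (i in seq_along(sets)) {
    p <- sets[[i]]
    u <- mixture_u(2e4, p$D, c(p$f, 1 - p$f), seed = 500 + i)
    fit <- fit_rayleigh_mixture(make_jump_sample(u), 2)
    expect_lt(abs(fit$D[1] - p$D[1]) / p$D[1], 0.10)
    expect_lt(abs(fit$D[2] - p$D[2]) / p$D[2], 0.10)
    expect_lt(abs(fit$f[1] - p$f), 0.03)
    expect_equal(sum(fit$f), 1, tolerance = 1e-9)
    expect_true(all(diff(fit$D) > 0))
  }
})

test_that("EM matches a brute-force likelihood grid on a small sample", {
  u <- mixture_u(500, c(0.08, 0.57), c(0.5, 0.5), seed = 77)
  s <- make_jump_sample(u)
  em <- fit_rayleigh_mixture(s, 2)

  # independent oracle: dense grid search over (D1, D2, f1)
  dt <- 0.02
  D1g <- seq(0.04, 0.16, by = 0.002)
  D2g <- seq(0.35, 0.80, by = 0.005)
  fg <- seq(0.25, 0.75, by = 0.005)
  best <- c(-Inf, NA, NA, NA)
  for (D1 in D1g) {
    d1 <- stats::dexp(u, 1 / (4 * D1 * dt))
    for (D2 in D2g) {
      d2 <- stats::dexp(u, 1 / (4 * D2 * dt))
      ll <- colSums(log(outer(d1 - d2, fg) + d2))
      j <- which.max(ll)
      if (ll[j] > best[1]) best <- c(ll[j], D1, D2, fg[j])
    }
  }
  expect_lt(abs(em$D[1] - best[2]) / best[2], 0.05)
  expect_lt(abs(em$D[2] - best[3]) / best[3], 0.05)
  expect_lt(abs(em$f[1] - best[4]) / best[4], 0.05)
  # and the EM solution is at least as likely as the grid optimum
  expect_gte(em$loglik, best[1] - 1e-6)
})

test_that("fit is invariant to initialization and consistent in the equal-D limit", {
  u <- mixture_u(5000, c(0.08, 0.57), c(0.45, 0.55), seed = 13)
  s <- make_jump_sample(u)
  f1 <- fit_rayleigh_mixture(s, 2, tol = 1e-10,
                             init = list(m = c(0.001, 0.08), f = c(0.3, 0.7)))
  f2 <- fit_rayleigh_mixture(s, 2, tol = 1e-10,
                             init = list(m = c(0.08, 0.001), f = c(0.8, 0.2)))
  expect_equal(f1$D, f2$D, tolerance = 1e-6)
  expect_equal(f1$f, f2$f, tolerance = 1e-6)

  # D1 -> D2: the two-component likelihood collapses onto one component
  k1 <- fit_rayleigh_mixture(s, 1)
  m <- k1$m
  ll2 <- smt2state:::.exp_mixture_loglik(s$u, c(m, m), c(0.4, 0.6))
  expect_equal(ll2, k1$loglik, tolerance = 1e-9)
})

test_that("localization-error correction subtracts sigma^2/dt", {
  u <- mixture_u(2e4, 0.5, 1, seed = 5)
  s <- make_jump_sample(u, sigma = 0.04)
  raw <- fit_rayleigh_mixture(s, 1)
  corr <- fit_rayleigh_mixture(s, 1, correct_precision = TRUE)
  expect_equal(raw$D - corr$D, 0.04^2 / 0.02, tolerance = 1e-12)
})

test_that("select_model picks K by BIC with ties toward smaller K", {
  # two-state sample: K = 2 wins and the CDF fit is tight
  u2 <- mixture_u(2e4, c(0.08, 0.57), c(0.474, 0.526), seed = 21)
  best <- select_model(make_jump_sample(u2), 3)
  expect_equal(best$K, 2L)
  expect_gte(best$r2, 0.98)
  all_fits <- attr(best, "all_fits")
  expect_length(all_fits, 3L)
  expect_true(best$bic <= min(vapply(all_fits, `[[`, numeric(1), "bic")))

  # single-population sample: K = 1 wins
  u1 <- mixture_u(1e4, 0.3, 1, seed = 22)
  expect_equal(select_model(make_jump_sample(u1), 3)$K, 1L)

  # K_max = 1 returns the one-component fit unconditionally
  expect_equal(select_model(make_jump_sample(u2), 1)$K, 1L)
})

test_that("fit errors are informative", {
  small <- make_jump_sample(mixture_u(60, 0.5, 1, seed = 1))
  expect_error(fit_rayleigh_mixture(small, 2), class = "smt_samplesize_error")
  expect_error(fit_rayleigh_mixture(small, 4), "K must be")
  # non-convergence carries the last iterate
  u <- mixture_u(5000, c(0.08, 0.57), c(0.5, 0.5), seed = 2)
  err <- tryCatch(fit_rayleigh_mixture(make_jump_sample(u), 2, max_iter = 2),
                  smt_convergence_error = function(e) e)
  expect_s3_class(err, "smt_convergence_error")
  expect_named(err$data, c("m", "f", "loglik"))
})
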