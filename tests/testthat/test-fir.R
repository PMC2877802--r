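test_that("FIR design columns count overlapping events", {
  # one event, no overlap: each in-range lag column has exactly one 1
  X <- build_fir_design(list(30), 600, window = c(-4, 8),
                        sample_interval = 0.1)
  expect_equal(attr(X, "n_lags"), 120L)
  expect_equal(ncol(X), 121L)
  expect_equal(colSums(X[, 1:120]), rep(1, 120), ignore_attr = TRUE)
  # two events 2 s apart, 12 s window: their windows share 100 rows,
  # each touched once per event through different lag columns
  X2 <- build_fir_design(list(c(20, 22)), 600, window = c(-4, 8),
                         sample_interval = 0.1)
  rs <- rowSums(X2[, 1:120])
  expect_equal(sum(rs == 2), 100)
  expect_equal(max(X2[, 1:120]), 1)
  # coincident events stack counts within a column
  X3 <- build_fir_design(list(c(20, 20)), 600, window = c(-4, 8),
                         sample_interval = 0.1)
  expect_equal(max(X3[, 1:120]), 2)
  expect_error(build_fir_design(list(1), 100, window = c(-4, 8.05),
                                sample_interval = 0.1),
               "whole number")
})

test_that("design times true kernel reproduces the forward model", {
  k <- default_kernel(0.1)
  set.seed(2)
  tms <- round(sort(runif(6, 4.5, 50)), 1)
  tr <- event_train(tms, rep(1, 6), anchor = "onset")
  rec <- convolve_events(tr, k, 60, 0.1, baseline = 1.7)
  X <- build_fir_design(list(tms), 600, window = k$window,
                        sample_interval = 0.1)
  expect_equal(drop(X %*% c(k$values, 1.7)), rec$samples,
               tolerance = 1e-12)
})

test_that("estimate_rf recovers the generating kernel exactly without noise", {
  k <- default_kernel(0.1)
  set.seed(5)
  recs <- list(); evs <- list()
  for (e in 1:3) {
    tms <- round(sort(runif(8, 4.5, 50)), 1)
    evs[[e]] <- event_train(tms, rep(1, 8), anchor = "onset")
    recs[[e]] <- convolve_events(evs[[e]], k, 60, 0.1, baseline = 1 + e)
  }
  fit <- estimate_rf(recs, evs)
  expect_equal(fit$rf$values, k$values, tolerance = 1e-8)
  expect_equal(fit$intercepts, c(2, 3, 4), tolerance = 1e-8)
  expect_gte(fit$r2, 1 - 1e-12)
})

test_that("one isolated event makes the RF equal the signal segment", {
  k <- default_kernel(0.1)
  rec <- convolve_events(event_train(20, 1), k, 60, 0.1, baseline = 2)
  fit <- estimate_rf(list(rec), list(event_train(20, 1)))
  expect_equal(fit$rf$values, k$values, tolerance = 1e-8)
})

test_that("FIR solutions match explicit normal equations", {
  k <- default_kernel(0.1)
  set.seed(6)
  tms <- round(sort(runif(7, 4.5, 50)), 1)
  tr <- event_train(tms, rep(1, 7), anchor = "onset")
  rec <- convolve_events(tr, k, 60, 0.1, baseline = 2)
  rec$samples <- rec$samples + rnorm(600, 0, 0.02)
  # shared-kernel direction
  X <- build_fir_design(list(tms), 600, window = c(-4, 8),
                        sample_interval = 0.1)
  beta <- solve(crossprod(X), crossprod(X, rec$samples))
  fit <- estimate_rf(list(rec), list(tr))
  expect_equal(c(fit$rf$values, fit$intercepts), drop(beta),
               tolerance = 1e-10, ignore_attr = TRUE)
  # per-event amplitude direction
  amps <- c(0.2, 0.5, 0.3)
  tr2 <- event_train(c(10, 13, 40), amps, anchor = "onset")
  rec2 <- convolve_events(tr2, k, 60, 0.1, baseline = 1)
  rec2$samples <- rec2$samples + rnorm(600, 0, 0.01)
  n <- 600; lag0 <- round(k$window[1] / 0.1)
  Xa <- matrix(0, n, 4)
  for (i in 1:3) {
    idx <- round(tr2$times[i] / 0.1) + 1 + lag0 + seq_along(k$values) - 1
    keep <- idx >= 1 & idx <= n
    Xa[idx[keep], i] <- k$values[keep]
  }
  Xa[, 4] <- 1
  beta_a <- solve(crossprod(Xa), crossprod(Xa, rec2$samples))
  afit <- estimate_amplitudes(rec2, tr2, k)
  expect_equal(c(afit$amplitudes, afit$intercepts), drop(beta_a),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("amplitudes of overlapping events are recovered without noise", {
  k <- default_kernel(0.1)
  tr <- event_train(c(10, 12, 30), c(0.2, 0.5, 0.3), anchor = "onset")
  rec <- convolve_events(tr, k, 60, 0.1, baseline = 1.5)
  fit <- estimate_amplitudes(rec, tr, k)
  expect_equal(fit$amplitudes, c(0.2, 0.5, 0.3), tolerance = 1e-8)
  expect_equal(fit$intercepts, 1.5, tolerance = 1e-8, ignore_attr = TRUE)
  # flat epoch: all amplitudes zero
  flat <- sc_record(rep(2, 600), 0.1)
  fit0 <- estimate_amplitudes(flat, tr, k)
  expect_equal(fit0$amplitudes, rep(0, 3), tolerance = 1e-10)
})

test_that("coincident events raise a rank error naming the columns", {
  k <- default_kernel(0.1)
  tr <- event_train(c(10, 10), c(0.2, 0.5), anchor = "onset")
  rec <- convolve_events(tr, k, 60, 0.1, baseline = 1)
  expect_error(estimate_amplitudes(rec, tr, k), "collinear")
})

test_that("noisy fits have the analytically expected variance explained", {
  # r2 ~ var(signal) / (var(signal) + sigma^2) for white noise
  k <- default_kernel(0.1)
  set.seed(8)
  sigma <- 0.05
  r2s <- replicate(20, {
    tms <- round(sort(runif(10, 4.5, 50)), 1)
    tr <- event_train(tms, rep(1, 10), anchor = "onset")
    rec <- convolve_events(tr, k, 60, 0.1, baseline = 2)
    clean <- rec$samples
    rec$samples <- rec$samples + rnorm(600, 0, sigma)
    fit <- estimate_rf(list(rec), list(tr))
    c(fit$r2, var(clean))
  })
  expected <- mean(r2s[2, ] / (r2s[2, ] + sigma^2))
  expect_equal(mean(r2s[1, ]), expected, tolerance = 0.03)
})

test_that("variance_explained matches direct sums of squares", {
  expect_equal(variance_explained(1:10, 1:10, rep(5.5, 10)), 1)
  expect_equal(variance_explained(1:10, rep(5.5, 10), rep(5.5, 10)), 0)
  set.seed(10)
  obs <- rnorm(50); fitv <- obs + rnorm(50, 0, 0.5); ctr <- rep(mean(obs), 50)
  expect_equal(variance_explained(obs, fitv, ctr),
               1 - sum((obs - fitv)^2) / sum((obs - ctr)^2))
  expect_error(variance_explained(rep(1, 5), rep(1, 5), rep(1, 5)),
               "zero total variance")
  expect_error(variance_explained(1:3, 1:4, 1:3), "equal length")
})
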