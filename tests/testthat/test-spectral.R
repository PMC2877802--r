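test_that("power spectrum of a constant is zero and of a tone is one bin", {
  expect_equal(power_spectrum(sc_record(rep(2, 128), 0.1))$total_power, 0)
  n <- 256; dt <- 0.1
  f0 <- 10 / (n * dt)   # exact bin frequency
  x <- 3 + sin(2 * pi * f0 * (0:(n - 1)) * dt)
  sp <- power_spectrum(sc_record(x, dt))
  nonzero <- which(sp$power > 1e-9 * max(sp$power))
  # one bin at f0 plus the DC bin introduced by min-subtraction
  expect_true(all(nonzero %in% c(1, 11)))
  expect_true(sp$power[11] > 0)
  expect_equal(sp$frequencies[11], f0)
})

test_that("Parseval's identity holds under the stated normalisation", {
  for (n in c(100, 101, 256)) {
    set.seed(n)
    x <- 2 + abs(rnorm(n, 0, 0.5))
    sp <- power_spectrum(sc_record(x, 0.1))
    expect_equal(sp$total_power, sum((x - min(x))^2),
                 tolerance = 1e-10)
    expect_true(all(sp$power >= 0))
    expect_equal(sp$frequencies[1], 0)
    expect_equal(max(sp$frequencies), floor(n / 2) / (n * 0.1))
  }
})

test_that("the discrete convolution theorem holds to near machine precision", {
  k <- default_kernel(0.1)
  expect_lte(verify_convolution_theorem(event_train(10, 1), k, 60, 0.1),
             1e-10)
  set.seed(12)
  tr <- event_train(sort(runif(12, 0, 59.9)), runif(12, 0.1, 1))
  expect_lte(verify_convolution_theorem(tr, k, 60, 0.1), 1e-10)
  expect_equal(verify_convolution_theorem(event_train(), k, 60, 0.1), 0)
})

test_that("pulse-train Fourier coefficients match numeric Fourier analysis", {
  n <- 0.2; d <- 0.8   # burst rate Hz, duration s
  for (i in c(1, 2, 5)) {
    analytic <- rect_train_fourier(i, n, d)$coefficient
    numeric <- rect_fourier_numeric(i, n, d, dt = 1e-4)
    expect_equal(analytic, numeric, tolerance = 1e-3)
  }
  # zero of the sine at i*n*d = 1
  expect_equal(rect_train_fourier(5, 0.25, 0.8)$coefficient, 0,
               tolerance = 1e-15)
})

test_that("the printed burst-rate derivative matches central differences", {
  d <- 0.8; h <- 1e-6
  for (i in c(1, 3, 10)) for (n in c(0.05, 0.2, 0.5)) {
    fd <- (rect_train_fourier(i, n + h, d)$coefficient -
           rect_train_fourier(i, n - h, d)$coefficient) / (2 * h)
    expect_equal(rect_train_fourier(i, n, d)$d_coefficient_dn, fd,
                 tolerance = 1e-6)
  }
  # sensitivity concentrates at low harmonics while nd < 1
  sens <- abs(rect_train_fourier(c(1, 10), 0.1, 0.8)$d_coefficient_dn)
  expect_gte(sens[1], sens[2])
  expect_warning(rect_train_fourier(1, 2, 0.8), "duty cycle")
})

test_that("noiseless circular deconvolution is the identity on the drive", {
  k <- default_kernel(0.1)
  set.seed(13)
  tr <- event_train(sort(runif(8, 0, 59.9)), runif(8, 0.2, 0.8))
  rec <- convolve_events(tr, k, 60, 0.1, baseline = 0, mode = "circular")
  rec$samples <- rec$samples - min(rec$samples) # scl correction no-op shift
  drive <- naive_deconvolve(rec, k)
  truth <- numeric(600)
  for (i in seq_along(tr$times)) {
    j <- round(tr$times[i] / 0.1) + 1
    truth[j] <- truth[j] + tr$amplitudes[i]
  }
  # min-subtraction removes the drive's DC offset; compare shapes
  expect_equal(drive - mean(drive), truth - mean(truth),
               tolerance = 1e-6)
  expect_equal(naive_deconvolve(sc_record(rep(0, 600), 0.1), k),
               rep(0, 600), tolerance = 1e-10)
  expect_error(naive_deconvolve(rec, response_function(rep(0, 120),
                                                       c(-4, 8), 0.1)),
               "all-zero")
})

test_that("inverse-filter error grows with measurement noise", {
  k <- default_kernel(0.1)
  set.seed(14)
  tr <- event_train(sort(runif(6, 0, 59.9)), runif(6, 0.2, 0.8))
  clean <- convolve_events(tr, k, 60, 0.1, baseline = 2,
                           mode = "circular")
  truth <- numeric(600)
  for (i in seq_along(tr$times))
    truth[round(tr$times[i] / 0.1) + 1] <- tr$amplitudes[i]
  noise <- rnorm(600)
  rmse <- vapply(c(0, 0.01, 0.05, 0.1), function(s) {
    rec <- clean
    rec$samples <- rec$samples + s * noise
    d <- naive_deconvolve(rec, k)
    sqrt(mean((d - mean(d) - (truth - mean(truth)))^2))
  }, 0)
  expect_true(all(diff(rmse) > 0))
})
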