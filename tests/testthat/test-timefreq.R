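sine_epochs <- function(f_hz, n_tr = 1, fs = 256, amp = 1) {
  n <- 4 * fs
  t_s <- (-1000 + (0:(n - 1)) / fs * 1000) / 1000
  d <- array(rep(amp * sin(2 * pi * f_hz * t_s), each = n_tr),
             dim = c(n_tr, 1, n))
  epoch_set(d, fs, -1000, "Cz")
}

test_that("the frequency grid is 78 linearly spaced bins from 3 to 80 Hz", {
  fr <- seq(3, 80, length.out = 78)
  expect_length(fr, 78)
  expect_equal(unique(round(diff(fr), 10)), 1)
  tfr <- morlet_tfr(sine_epochs(10))
  expect_equal(tfr$frequencies, fr)
  expect_true(all(tfr$times_ms >= 0 & tfr$times_ms <= 2000))
  # nominal 50.25 Hz realized as every 5th sample of the 256-Hz grid
  expect_equal(unique(round(diff(tfr$times_ms), 6)), 5 / 256 * 1000)
})

test_that("a pure 10-Hz tone peaks at the 10-Hz bin at interior timepoints", {
  tfr <- morlet_tfr(sine_epochs(10))
  pow <- Mod(tfr$coefficients[1, 1, , ])^2
  interior <- tfr$times_ms > 300 & tfr$times_ms < 1700
  peak_bin <- apply(pow[, interior], 2, which.max)
  expect_true(all(tfr$frequencies[peak_bin] == 10))
})

test_that("wavelet coefficients match an explicit convolution loop", {
  n <- 1024
  ep <- epoch_set(array(0, dim = c(1, 1, n)), 256, -1000, "Cz")
  ep$data[1, 1, 513] <- 1                      # unit impulse at t = 1000 ms
  tfr <- morlet_tfr(ep)
  keep <- which(epoch_times(ep) >= 0)[1] + 5 * (seq_along(tfr$times_ms) - 1)
  x <- ep$data[1, 1, ]
  for (fi in c(1, 30, 78)) {
    w <- oscmvpa:::morlet_kernel(tfr$frequencies[fi], 256, 5)
    half <- (length(w) - 1) / 2
    oracle <- vapply(keep, function(k) {
      acc <- 0 + 0i
      for (m in seq_len(n)) {
        j <- k + half - m + 1
        if (j >= 1 && j <= length(w)) acc <- acc + x[m] * w[j]
      }
      acc / 256
    }, complex(1))
    expect_lt(max(Mod(tfr$coefficients[1, 1, fi, ] - oracle)), 1e-8)
  }
})

test_that("epochs without margin for the longest wavelet are refused", {
  ep <- epoch_set(array(0, dim = c(1, 1, 600)), 256, -100, "Cz")
  expect_error(morlet_tfr(ep), "margin")
})

test_that("frequency bins belong to exactly one band, lower band on ties", {
  bins <- band_bins(seq(3, 80, length.out = 78))
  fr <- seq(3, 80, length.out = 78)
  expect_equal(fr[bins$delta], c(3, 4))
  expect_equal(fr[bins$theta], c(5, 6, 7))
  expect_equal(fr[bins$alpha], 8:14)
  expect_equal(fr[bins$beta], 15:30)
  expect_equal(fr[bins$gamma], 31:80)
  expect_equal(sum(lengths(bins)), 78)          # no bin double-counted
})

test_that("windowed band covariance behaves on degenerate geometries", {
  tfr <- morlet_tfr(sine_epochs(10, n_tr = 3))
  wb <- band_windowed_covariance(tfr, "alpha", c(400, 700))
  expect_true(all(wb$covs >= 0))                # 1x1 "covariance" = power

  # duplicated channel -> rank-1 matrix with off-diagonal = diagonal
  ep <- sine_epochs(10, n_tr = 2)
  d2 <- array(0, dim = c(2, 2, dim(ep$data)[3]))
  d2[, 1, ] <- ep$data[, 1, ]; d2[, 2, ] <- ep$data[, 1, ]
  ep2 <- epoch_set(d2, 256, -1000, c("Cz", "Pz"))
  wb2 <- band_windowed_covariance(morlet_tfr(ep2), "alpha", c(400, 700))
  for (tr in 1:2) {
    C <- wb2$covs[tr, , ]
    expect_equal(C[1, 2], C[1, 1], tolerance = 1e-10)
    expect_equal(C[2, 2], C[1, 1], tolerance = 1e-10)
  }
  expect_error(band_windowed_covariance(tfr, "alpha", c(3000, 3300)),
               "timepoints")
})

test_that("band covariance of white noise matches a time-domain FIR oracle", {
  skip_if_not_installed("signal")
  set.seed(8)
  n_tr <- 200
  d <- array(rnorm(n_tr * 3 * 1024), dim = c(n_tr, 3, 1024))
  # correlate channels 1 and 2
  d[, 2, ] <- 0.7 * d[, 1, ] + 0.5 * d[, 2, ]
  ep <- epoch_set(d, 256, -1000, c("C3", "Cz", "C4"))
  tfr <- morlet_tfr(ep)
  wb <- band_windowed_covariance(tfr, "alpha", c(500, 1500))
  C_wavelet <- apply(wb$covs, c(2, 3), mean)
  fir <- signal::fir1(128, c(8, 14) / 128, type = "pass")
  t_ms <- epoch_times(ep)
  idx <- t_ms >= 500 & t_ms <= 1500
  C_fir <- matrix(0, 3, 3)
  for (tr in seq_len(n_tr)) {
    filt <- vapply(1:3, function(ch)
      as.numeric(signal::filtfilt(fir, d[tr, ch, ])), numeric(1024))
    seg <- filt[idx, , drop = FALSE]
    C_fir <- C_fir + crossprod(seg) / sum(idx)
  }
  C_fir <- C_fir / n_tr
  expect_gt(cor(as.numeric(C_wavelet), as.numeric(C_fir)), 0.9)
})

test_that("total wavelet power grows linearly with input variance", {
  tot <- vapply(1:5, function(k) {
    set.seed(20 + k)
    d <- array(rnorm(2 * 1 * 1024, sd = k), dim = c(2, 1, 1024))
    tfr <- morlet_tfr(epoch_set(d, 256, -1000, "Cz"))
    mean(Mod(tfr$coefficients)^2)
  }, numeric(1))
  fit <- summary(lm(tot ~ I((1:5)^2)))
  expect_gt(fit$r.squared, 0.99)
})

test_that("per-trial covariances are PSD and independent of batch composition", {
  dec <- cached_decodable()
  for (s in c(1, 17)) {
    ev <- eigen(matrix(dec$wbc$covs[3, , s],
                       dec$wbc$n_channels, dec$wbc$n_channels),
                symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-10))
  }
  # cropping/decimation act per trial: a subset run reproduces its trials
  sub <- dec$epochs
  sub$data <- dec$epochs$data[1:5, , , drop = FALSE]
  sub$trial_labels <- dec$epochs$trial_labels[1:5, , drop = FALSE]
  tfr_sub <- morlet_tfr(sub)
  expect_equal(tfr_sub$coefficients[3, , , ],
               dec$tfr$coefficients[3, , , ], tolerance = 1e-12)
})
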