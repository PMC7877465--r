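make_epochs <- function(data, fs = 256, t0 = -1000, roles = NULL) {
  ch <- c("FP1", "FP2", "Cz", "Pz", "O1", "O2", "F3", "F4")[seq_len(dim(data)[2])]
  epoch_set(data, fs, t0, ch, channel_roles = roles)
}

test_that("baseline correction zeroes the interval mean", {
  # constant signal -> all zero
  d <- array(5, dim = c(3, 2, 512))
  ep <- make_epochs(d, t0 = -1000)
  out <- baseline_correct(ep, c(-300, -100))
  expect_equal(max(abs(out$data)), 0)

  # default interval mean is 0 per trial/channel
  set.seed(1)
  d <- array(rnorm(4 * 2 * 1024), dim = c(4, 2, 1024))
  ep <- make_epochs(d)
  out <- baseline_correct(ep)
  t_ms <- epoch_times(out)
  idx <- t_ms >= -300 & t_ms <= -100
  base <- apply(out$data[, , idx], c(1, 2), mean)
  expect_lt(max(abs(base)), 1e-12)

  # linear ramp: output = t - mean(t over interval), closed form
  ep <- make_epochs(array(0, dim = c(1, 1, 1024)))
  t_ms <- epoch_times(ep)
  ep$data[1, 1, ] <- t_ms
  out <- baseline_correct(ep, c(-300, -100))
  m <- mean(t_ms[t_ms >= -300 & t_ms <= -100])
  for (k in c(1, 500, 1024))
    expect_equal(out$data[1, 1, k], t_ms[k] - m, tolerance = 1e-12)

  expect_error(baseline_correct(ep, c(-2000, -1500)), "outside")
})

test_that("baseline correction is idempotent", {
  set.seed(2)
  ep <- make_epochs(array(rnorm(3 * 2 * 1024), dim = c(3, 2, 1024)))
  once <- baseline_correct(ep)
  twice <- baseline_correct(once)
  expect_equal(once$data, twice$data, tolerance = 1e-12)
})

test_that("identical epochs are never rejected", {
  one <- array(rnorm(2 * 1024), dim = c(1, 2, 1024))
  d <- array(rep(one, each = 10), dim = c(10, 2, 1024))
  for (e in 1:10) d[e, , ] <- one[1, , ]
  ep <- make_epochs(d)
  res <- reject_epochs(ep)
  expect_equal(res$report$fraction_rejected, 0)
  expect_equal(dim(res$epochs$data)[1], 10)
})

test_that("a voltage spike is flagged by rule 1, matching a direct oracle", {
  set.seed(3)
  n <- 60
  d <- array(rnorm(n * 2 * 1024, sd = 5), dim = c(n, 2, 1024))
  d[7, 1, 500:510] <- d[7, 1, 500:510] + 500
  ep <- make_epochs(d)
  res <- reject_epochs(ep)
  expect_true(7 %in% res$report$rule1)
  # oracle: recompute per-epoch max 400-ms windowed range and its percentile
  t_ms <- epoch_times(ep)
  starts <- seq(-1000, max(t_ms) - 400, by = 100)
  starts <- starts[starts + 400 <= max(t_ms)]
  stat <- vapply(seq_len(n), function(e) {
    max(vapply(starts, function(s) {
      idx <- t_ms >= s & t_ms <= s + 400
      max(apply(d[e, , idx, drop = FALSE][1, , ], 1,
                function(v) max(v) - min(v)))
    }, numeric(1)))
  }, numeric(1))
  thr <- unname(quantile(stat, 0.99, type = 7))
  expect_equal(sort(res$report$rule1), sort(which(stat > thr)))
})

test_that("a steep linear drift with good fit is flagged by rule 2", {
  set.seed(4)
  n <- 50
  d <- array(rnorm(n * 2 * 512, sd = 2), dim = c(n, 2, 512))
  t_ms <- -1000 + (0:511) / 256 * 1000
  d[5, 1, ] <- d[5, 1, ] + 0.2 * t_ms          # strong drift, R^2 >> 0.3
  ep <- make_epochs(d)
  res <- reject_epochs(ep)
  expect_true(5 %in% res$report$rule2)
})

test_that("an onset-locked frontal spike is flagged by rule 3 only", {
  set.seed(5)
  n <- 50
  d <- array(rnorm(n * 4 * 1024, sd = 5), dim = c(n, 4, 1024))
  ep <- make_epochs(d)                          # FP1 FP2 Cz Pz
  t_ms <- epoch_times(ep)
  burst <- which(t_ms >= -50 & t_ms <= 30)
  d[9, 1, burst] <- d[9, 1, burst] + 120        # FP1, small window, near onset
  ep <- make_epochs(d)
  res <- reject_epochs(ep)
  expect_true(9 %in% res$report$rule3)
})

test_that("surviving trials keep their order and labels", {
  set.seed(6)
  n <- 30
  d <- array(rnorm(n * 2 * 512, sd = 5), dim = c(n, 2, 512))
  d[4, 1, 100:120] <- 400
  ep <- make_epochs(d)
  ep$trial_labels$outcome <- paste0("t", seq_len(n))
  res <- reject_epochs(ep)
  kept <- setdiff(seq_len(n), res$report$rejected)
  expect_equal(res$epochs$trial_labels$outcome, paste0("t", kept))
})

test_that("i.i.d. epochs keep rule-1 rejection near its nominal 1%", {
  frac <- vapply(1:20, function(r) {
    set.seed(200 + r)
    d <- array(rnorm(100 * 2 * 256), dim = c(100, 2, 256))
    ep <- make_epochs(d, t0 = -200)
    length(reject_epochs(ep)$report$rule1) / 100
  }, numeric(1))
  expect_lte(mean(frac), 0.10)
})

test_that("channel interpolation replaces only the target channel", {
  # neighbors constant c -> interpolated channel equals c
  d <- array(0, dim = c(2, 4, 64))
  d[, 2, ] <- 3; d[, 3, ] <- 3                  # neighbors of Cz-like channel
  ep <- epoch_set(d, 256, 0, c("A", "B", "C", "D"))
  nb <- list(A = c("B", "C"))
  out <- interpolate_channel(ep, "A", nb)
  expect_true(all(out$data[, 1, ] == 3))

  # two neighbors 2 and 4 -> mean 3
  d <- array(0, dim = c(1, 3, 8))
  d[, 2, ] <- 2; d[, 3, ] <- 4
  ep <- epoch_set(d, 256, 0, c("X", "Y", "Z"))
  out <- interpolate_channel(ep, "X", list(X = c("Y", "Z")))
  expect_true(all(out$data[, 1, ] == 3))

  # full montage: only the bad channel changes
  set.seed(7)
  sp <- simulation_spec(n_trials_per_class = c(correct = 2, incorrect = 2),
                        seed = 2)
  ep <- generate_subject_epochs(sp)
  out <- interpolate_channel(ep, "Cz")
  ci <- match("Cz", ep$channel_names)
  expect_false(isTRUE(all.equal(out$data[, ci, ], ep$data[, ci, ])))
  expect_equal(out$data[, -ci, ], ep$data[, -ci, ])

  expect_error(interpolate_channel(ep, "Cz", list(Fz = "F3")),
               "no configured neighbors")
  expect_error(interpolate_channel(ep, "nope"), "not present")
})
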