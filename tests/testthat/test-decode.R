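test_that("the standard grid has 86 windows with midpoints 150..1850", {
  g <- build_window_grid(c(0, 2000), 300, 20)
  expect_equal(nrow(g$windows), 86)
  expect_equal(g$windows$midpoint, seq(150, 1850, by = 20))
  expect_equal(unlist(g$windows[1, ]), c(start = 0, end = 300, midpoint = 150))
  expect_equal(unlist(g$windows[86, ]),
               c(start = 1700, end = 2000, midpoint = 1850))

  expect_equal(nrow(build_window_grid(c(0, 300), 300, 20)$windows), 1)
  # direct enumeration: (1000 - 300) / 100 + 1 = 8
  expect_equal(nrow(build_window_grid(c(0, 1000), 300, 100)$windows), 8)
  expect_error(build_window_grid(c(0, 200), 300, 20), "exceeds")
})

test_that("stratified folds partition 47 trials as {10,10,9,9,9}", {
  y <- rep(c("a", "b"), c(28, 19))
  f <- make_folds(y, k = 5, seed = 1)
  expect_equal(sort(as.numeric(table(f)), decreasing = TRUE),
               c(10, 10, 9, 9, 9))
  # class counts per fold differ by at most one
  tab <- table(f, y)
  expect_lte(max(tab[, "a"]) - min(tab[, "a"]), 1)
  expect_lte(max(tab[, "b"]) - min(tab[, "b"]), 1)
  expect_error(make_folds(rep(c("a", "b"), c(3, 40)), k = 5), "at least k")
})

test_that("naive Bayes matches a direct density computation", {
  # symmetric class means -> decision boundary near 0
  set.seed(15)
  f <- matrix(c(rnorm(50, -1, 1), rnorm(50, 1, 1)))
  y <- rep(c("lo", "hi"), each = 50)
  m <- train_nb(f, y)
  expect_equal(predict_nb(m, matrix(c(-3, 3))), c("lo", "hi"))

  set.seed(16)
  f2 <- matrix(rnorm(40 * 2), 40)
  y2 <- rep(c("a", "b"), each = 20)
  m2 <- train_nb(f2, y2)
  pt <- matrix(c(0.3, -0.7), 1)
  post <- predict_nb(m2, pt, type = "posterior")
  dens <- vapply(1:2, function(ci) {
    m2$priors[ci] * prod(dnorm(pt, m2$means[ci, ], sqrt(m2$vars[ci, ])))
  }, numeric(1))
  expect_lt(max(abs(post - dens / sum(dens))), 1e-10)

  # degenerate zero-variance feature: floored, no division error
  f3 <- cbind(f2, 1)
  m3 <- train_nb(f3, y2)
  expect_true(all(is.finite(m3$vars)))
  expect_silent(predict_nb(m3, cbind(pt, 1)))
  expect_error(train_nb(f2, rep("a", 40)), "2 classes")
})

test_that("cross-validated accuracy separates a strong synthetic effect", {
  dec <- cached_decodable()
  acc <- crossval_accuracy(dec$tfr, dec$labels, c(400, 700), seed = 1)
  expect_gte(acc, 80)
  # determinism
  acc2 <- crossval_accuracy(dec$tfr, dec$labels, c(400, 700), seed = 1)
  expect_identical(acc, acc2)
  expect_error(crossval_accuracy(dec$tfr, rep(c("a", "b"), c(57, 3)),
                                 c(400, 700)), "k_folds")
})

test_that("compiled and reference decoding engines agree", {
  dec <- cached_decodable()
  tc_cpp <- sliding_window_decode(dec$wbc, dec$labels, dec$grid, seed = 2)
  tc_r <- sliding_window_decode(dec$wbc, dec$labels, dec$grid, seed = 2,
                                engine = "r")
  expect_equal(tc_cpp$accuracy_pct, tc_r$accuracy_pct, tolerance = 1e-10)
})

test_that("decodability clusters on windows overlapping the injected effect", {
  dec <- cached_decodable()
  tc <- sliding_window_decode(dec$wbc, dec$labels, dec$grid, seed = 3)
  expect_equal(nrow(tc), nrow(dec$grid$windows))
  overlap <- tc$midpoint_ms >= 400 - 150 & tc$midpoint_ms <= 700 + 150
  expect_lt(suppressWarnings(
    wilcox.test(tc$accuracy_pct[overlap], tc$accuracy_pct[!overlap],
                alternative = "greater")$p.value), 0.01)
  # a cluster of at least 3 consecutive overlapping windows well above chance
  hot <- tc$accuracy_pct > 65
  runs <- rle(hot)
  expect_gte(max(runs$lengths[runs$values]), 3)
  # same seed -> identical timecourse
  tc2 <- sliding_window_decode(dec$wbc, dec$labels, dec$grid, seed = 3)
  expect_identical(tc$accuracy_pct, tc2$accuracy_pct)
})

test_that("paper-literal fit scope inflates apparent accuracy", {
  dec <- cached_decodable()
  g1 <- build_window_grid(c(500, 800), 300, 300)
  wbc1 <- windowed_band_covs(dec$tfr, g1)
  y <- dec$labels
  set.seed(17)
  yp <- sample(y)                                # no information
  a_fold <- mean(vapply(1:10, function(r)
    crossval_accuracy(wbc1, yp, c(500, 800), seed = r), numeric(1)))
  a_all <- mean(vapply(1:10, function(r)
    crossval_accuracy(wbc1, yp, c(500, 800), seed = r, fit_scope = "all"),
    numeric(1)))
  expect_gt(a_all, a_fold)                       # leakage shows up
})

test_that("three-class identity decoding behaves at chance and at ceiling", {
  sp <- tiny_spec(seed = 21, effect_band = "beta", effect_size = 1,
                  effect_window = c(400, 700))
  sp$effect_amplitude <- 25
  ep <- generate_identity_epochs(sp, n_per_identity = 20)
  tfr <- morlet_tfr(ep)
  g <- build_window_grid(c(400, 700), 300, 300)
  wbc <- windowed_band_covs(tfr, g)
  id <- ep$trial_labels$context_identity

  # separable: disjoint spatial profiles
  acc <- multiclass_decode(wbc, id, g, seed = 1)$accuracy_pct
  expect_gte(acc, 80)

  # label-independent data: accuracy near 33.3%
  accs <- vapply(1:12, function(r) {
    set.seed(300 + r)
    multiclass_decode(wbc, sample(id), g, seed = r)$accuracy_pct
  }, numeric(1))
  expect_lt(abs(mean(accs) - 100 / 3), 8)

  # permuting class labels leaves the accuracy distribution unchanged
  relab <- c(A = "B", B = "C", C = "A")[id]
  acc_perm <- vapply(1:12, function(r) {
    set.seed(300 + r)
    multiclass_decode(wbc, sample(relab), g, seed = r)$accuracy_pct
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(accs, acc_perm)$p.value), 0.05)

  expect_error(multiclass_decode(wbc, rep(c("A", "B"), 30), g), "3 classes")
})
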