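ctx_table <- function(n_match, n_mismatch, hits, fas) {
  data.frame(feature = "color", role = "target", attention = "color",
             item_status = "old", item_response = "old",
             context_status = rep(c("match", "mismatch"), c(n_match, n_mismatch)),
             context_response = c(rep(c("match", "mismatch"),
                                      c(hits, n_match - hits)),
                                  rep(c("match", "mismatch"),
                                      c(fas, n_mismatch - fas))),
             stringsAsFactors = FALSE)
}

test_that("context d-prime follows the inverse-normal difference formula", {
  # equal proportions -> exactly 0 (chance)
  expect_identical(context_dprime(ctx_table(20, 20, 10, 10)), 0)

  # 0.84 / 0.16 -> qnorm oracle, ~1.989
  d <- context_dprime(ctx_table(100, 100, 84, 16))
  expect_equal(d, qnorm(0.84) - qnorm(0.16), tolerance = 1e-12)
  expect_equal(d, 1.9884, tolerance = 1e-3)

  # boundary proportion clipped to 35.5/36 -> finite
  d <- context_dprime(ctx_table(36, 36, 36, 6))
  expect_true(is.finite(d))
  expect_equal(d, qnorm(35.5 / 36) - qnorm(6 / 36), tolerance = 1e-12)

  # antisymmetry: swapping proportions negates d-prime
  expect_equal(context_dprime(ctx_table(50, 50, 40, 10)),
               -context_dprime(ctx_table(50, 50, 10, 40)), tolerance = 1e-12)

  expect_error(context_dprime(ctx_table(5, 5, 3, 1), feature = "scene"),
               "at least one")
})

test_that("item d-prime scores old/new recognition", {
  tab <- data.frame(item_status = rep(c("old", "new"), c(40, 40)),
                    item_response = c(rep(c("old", "new"), c(38, 2)),
                                      rep(c("old", "new"), c(4, 36))))
  expect_equal(item_dprime(tab), qnorm(0.95) - qnorm(0.10), tolerance = 1e-12)
  tab$item_response <- ifelse(tab$item_status == "old", "old", "new")
  expect_true(is.finite(item_dprime(tab)))      # clipping at the boundary
  equal <- data.frame(item_status = rep(c("old", "new"), each = 10),
                      item_response = rep(rep(c("old", "new"), each = 5), 2))
  # hit rate == false-alarm rate -> 0
  expect_equal(item_dprime(equal), 0)
  all_new <- data.frame(item_status = rep("new", 10),
                        item_response = rep("new", 10))
  expect_error(item_dprime(all_new), "both old and new")
})

test_that("the KS statistic equals the enumerated ECDF-CDF gap", {
  x <- c(-1.3, -0.2, 0.1, 0.8, 2.1)
  res <- ks_normality(x)
  z <- sort((x - mean(x)) / sd(x))
  n <- length(z)
  gap <- max(vapply(seq_len(n), function(i)
    max(abs(i / n - pnorm(z[i])), abs((i - 1) / n - pnorm(z[i]))),
    numeric(1)))
  expect_equal(unname(res$statistic), gap, tolerance = 1e-12)

  # calibration on normal data, power on a skewed alternative
  pn <- vapply(1:100, function(r)
    with_seed(1000 + r, ks_normality(rnorm(500))$p), numeric(1))
  expect_gte(mean(pn > 0.05), 0.9)
  pe <- vapply(1:40, function(r)
    with_seed(2000 + r, ks_normality(rexp(416))$p), numeric(1))
  expect_gte(mean(pe < 0.01), 0.95)

  expect_error(ks_normality(rep(3, 10)), "zero variance")
  expect_error(ks_normality(c(1, 2)), "at least 5")
})

test_that("signed-rank test matches full enumeration and wilcox.test", {
  # shifted pairs, no ties: minimal one-tailed p = 1 / 2^n
  x <- c(1, 2, 3, 4, 5, 6.5)
  y <- x + c(0.5, 0.3, 0.9, 1.1, 0.2, 0.4)
  res <- wilcoxon_one_tailed(x, y, "x<y")
  expect_equal(res$p, 1 / 2^6, tolerance = 1e-12)
  expect_equal(unname(res$statistic), 0)

  # n = 6 random pairs vs brute-force 2^6 enumeration
  set.seed(31)
  x <- rnorm(6); y <- rnorm(6)
  res <- wilcoxon_one_tailed(x, y, "x<y")
  d <- x - y
  r <- rank(abs(d))
  T_obs <- sum(r[d > 0])
  all_T <- vapply(0:63, function(m) {
    signs <- as.integer(intToBits(m))[1:6]
    sum(r[signs == 1])
  }, numeric(1))
  expect_equal(res$p, mean(all_T <= T_obs), tolerance = 1e-12)
  res_gt <- wilcoxon_one_tailed(x, y, "x>y")
  expect_equal(res_gt$p, mean(all_T >= T_obs), tolerance = 1e-12)
  expect_gte(res$p + res_gt$p, 1)               # point mass counted twice

  # agreement with wilcox.test on tie-free data
  wt <- wilcox.test(x, y, paired = TRUE, alternative = "less", exact = TRUE)
  expect_equal(unname(res$statistic), unname(wt$statistic))
  expect_equal(res$p, wt$p.value, tolerance = 1e-12)

  # exact and normal-approximation paths agree closely at n = 12
  deltas <- vapply(1:100, function(r) {
    set.seed(3000 + r)
    a <- rnorm(12); b <- rnorm(12)
    p_ex <- wilcoxon_one_tailed(a, b, "x<y")$p
    p_ap <- wilcoxon_one_tailed(a, b, "x<y", exact_max = 0)$p
    abs(p_ex - p_ap)
  }, numeric(1))
  expect_lt(max(deltas), 0.02)

  expect_error(wilcoxon_one_tailed(1:4, 1:4 + 1, "x<y"), "at least 5")
  expect_error(wilcoxon_one_tailed(1:6, 1:6, "x<y"), "at least 5")
})

test_that("age regression matches the closed-form normal equations", {
  ages <- c(21, 34, 45, 52, 60, 68, 25, 39, 57, 71)
  set.seed(32)
  yv <- 400 + 0.8 * ages + rnorm(10, sd = 15)
  res <- age_regression(yv, ages)
  # normal-equations oracle
  b <- sum((ages - mean(ages)) * (yv - mean(yv))) / sum((ages - mean(ages))^2)
  a <- mean(yv) - b * mean(ages)
  ssr <- sum((a + b * ages - mean(yv))^2)
  sst <- sum((yv - mean(yv))^2)
  r2 <- ssr / sst
  Fv <- r2 / (1 - r2) * (10 - 2)
  expect_equal(res$beta, b, tolerance = 1e-10)
  expect_equal(res$r_squared, r2, tolerance = 1e-10)
  expect_equal(unname(res$statistic), Fv, tolerance = 1e-8)
  expect_equal(res$p, pf(Fv, 1, 8, lower.tail = FALSE), tolerance = 1e-10)

  const <- age_regression(rep(5, 10), ages)
  expect_equal(const$beta, 0)
  expect_equal(const$r_squared, 0)
  perfect <- age_regression(2 * ages + 1, ages)
  expect_equal(perfect$r_squared, 1, tolerance = 1e-12)
  expect_error(age_regression(yv, rep(40, 10)), "zero variance")
})

test_that("the verdict table reproduces the canonical patterns", {
  # significant complexity ordering only when the prioritized feature is
  # attended, with the across-condition contrast significant -> hybrid
  v <- model_verdict(list(attended = 0.008, unattended = 0.325,
                          interaction = 0.046, across = 0.039))
  expect_equal(v$verdict, "hybrid")

  # ordering holds in both attention conditions -> hierarchical
  v <- model_verdict(list(attended = 0.01, unattended = 0.02,
                          interaction = 0.5, across = 0.01))
  expect_equal(v$verdict, "hierarchical")

  # ordering tracks the attended feature -> attention
  v <- model_verdict(list(attended = 0.01, unattended = 0.9,
                          unattended_reversed = 0.01,
                          interaction = 0.01, across = 0.6))
  expect_equal(v$verdict, "attention")

  v <- model_verdict(list(attended = 0.5, unattended = 0.5,
                          interaction = 0.5, across = 0.5))
  expect_equal(v$verdict, "indeterminate")
  expect_error(model_verdict(list(attended = 0.01)), "missing contrasts")
})

test_that("scenario cohorts at the peak level recover their verdicts", {
  for (sc in c("hierarchical", "attention", "hybrid")) {
    hits <- vapply(1:5, function(r) {
      pk <- simulate_scenario_peak_table(sc, n_subjects = 25,
                                         seed = derive_seed(55, r))
      classify_cohort(pk)$verdict == sc
    }, logical(1))
    expect_gte(mean(hits), 0.8)
  }
})
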