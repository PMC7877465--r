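# Inverse-normal difference with the 1/(2N) boundary correction.
dprime_from_props <- function(p_hit, n_hit, p_fa, n_fa) {
  clip <- function(p, n) min(max(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  qnorm(clip(p_hit, n_hit)) - qnorm(clip(p_fa, n_fa))
}

#' Context-memory discriminability (d-prime)
#'
#' `d' = Z(proportion of "match" responses to matching contexts) -
#' Z(proportion of "match" responses to mismatching contexts)`, with
#' proportions clipped to `[1/(2N), 1 - 1/(2N)]` so boundary proportions
#' stay finite. Chance level is 0; equal proportions give exactly 0.
#'
#' @param table behavioral table (one row per trial) with columns `feature`,
#'   `role`, `context_status` ("match"/"mismatch") and `context_response`.
#' @param feature context feature to score (e.g. "color", "scene").
#' @param role `"target"` (attended at encoding) or `"distractor"`.
#' @return d-prime value.
#' @export
context_dprime <- function(table, feature = NULL, role = NULL) {
  rows <- table
  if (!is.null(feature)) rows <- rows[rows$feature == feature, , drop = FALSE]
  if (!is.null(role)) rows <- rows[rows$role == role, , drop = FALSE]
  m <- rows$context_status == "match"
  if (sum(m) == 0 || sum(!m) == 0)
    stopf("cell needs at least one matching and one mismatching trial")
  dprime_from_props(mean(rows$context_response[m] == "match"), sum(m),
                    mean(rows$context_response[!m] == "match"), sum(!m))
}

#' Item-recognition discriminability (d-prime)
#'
#' Hits are "old" responses to old items, false alarms "old" responses to
#' new items; same inverse-normal formula and boundary correction as
#' [context_dprime()].
#'
#' @param table behavioral table with columns `item_status` ("old"/"new")
#'   and `item_response`.
#' @return d-prime value.
#' @export
item_dprime <- function(table) {
  old <- table$item_status == "old"
  if (sum(old) == 0 || sum(!old) == 0)
    stopf("item d-prime needs both old and new test items")
  dprime_from_props(mean(table$item_response[old] == "old"), sum(old),
                    mean(table$item_response[!old] == "old"), sum(!old))
}

group_test <- function(statistic, p, n, method, extra = NULL) {
  structure(c(list(statistic = statistic, p = p, n = n, method = method),
              extra),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %s: %s = %.4g, p = %.4g (n = %d)\n", x$method,
              names(x$statistic)[1], x$statistic[1], x$p, x$n))
  invisible(x)
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Standardizes the values and compares their empirical distribution to the
#' standard normal using the asymptotic KS distribution (the screening step
#' that decides between parametric and rank-based group contrasts).
#'
#' @param values numeric sample (n >= 5, nonzero variance).
#' @return a `group_test` with the KS statistic and p-value.
#' @export
ks_normality <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 5) stopf("need at least 5 values")
  if (sd(values) == 0) stopf("values have zero variance")
  z <- (values - mean(values)) / sd(values)
  res <- suppressWarnings(ks.test(z, "pnorm", exact = FALSE))
  group_test(c(KS = unname(res$statistic)), res$p.value, length(values),
             "one-sample Kolmogorov-Smirnov vs standard normal")
}

# Exact distribution of the positive-rank sum via convolution over the
# realized (tie-averaged) ranks; ranks are doubled so half-ranks stay
# integral. Returns P(W+ <= t) and P(W+ >= t) including the point mass.
signed_rank_exact_tail <- function(ranks2, t2) {
  maxs <- sum(ranks2)
  dist <- numeric(maxs + 1)
  dist[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), dist[seq_len(maxs + 1 - r)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  s <- 0:maxs
  c(le = sum(dist[s <= t2 + 1e-9]), ge = sum(dist[s >= t2 - 1e-9]))
}

#' One-tailed Wilcoxon signed-rank test
#'
#' Paired-sample signed-rank test with tie-averaged ranks and zero
#' differences dropped. The statistic T is the sum of ranks of positive
#' differences `x - y`. For n <= `exact_max` pairs the one-tailed p-value
#' comes from the exact permutation distribution of the realized ranks
#' (computed by convolution); above it, from the normal approximation with
#' tie correction and continuity correction.
#'
#' @param x,y paired samples.
#' @param direction `"x<y"` tests whether x tends to be smaller (e.g. an
#'   earlier latency), `"x>y"` the reverse.
#' @param exact_max largest n for the exact path.
#' @return a `group_test` with statistic `T` and the one-tailed p.
#' @export
wilcoxon_one_tailed <- function(x, y, direction = c("x<y", "x>y"),
                                exact_max = 12) {
  direction <- match.arg(direction)
  keep <- !is.na(x) & !is.na(y)
  d <- x[keep] - y[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n < 5) stopf("need at least 5 nonzero paired differences")
  r <- rank(abs(d))
  T_plus <- sum(r[d > 0])
  if (n <= exact_max) {
    tails <- signed_rank_exact_tail(as.integer(round(2 * r)),
                                    2 * T_plus)
    p <- if (direction == "x<y") tails["le"] else tails["ge"]
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- if (direction == "x<y") (T_plus - mu + 0.5) / sqrt(sig2)
    else (T_plus - mu - 0.5) / sqrt(sig2)
    p <- if (direction == "x<y") pnorm(z) else pnorm(z, lower.tail = FALSE)
  }
  group_test(c(T = T_plus), unname(p), n,
             sprintf("one-tailed Wilcoxon signed-rank (%s)", direction),
             extra = list(direction = direction))
}

#' Linear regression of peaks (or peak differences) on age
#'
#' Ordinary least squares `outcome ~ age`, reporting the slope, R-squared,
#' the F(1, n-2) statistic and its two-tailed p-value.
#'
#' @param outcome numeric outcome per subject (peak latency or latency
#'   difference, ms).
#' @param ages subject ages in years.
#' @return a `group_test` with statistic `F` and fields `beta`, `r_squared`.
#' @export
age_regression <- function(outcome, ages) {
  keep <- !is.na(outcome) & !is.na(ages)
  outcome <- outcome[keep]; ages <- ages[keep]
  if (length(outcome) < 3) stopf("need at least 3 subjects")
  if (sd(ages) == 0) stopf("ages have zero variance")
  if (sd(outcome) == 0)
    return(group_test(c(F = 0), 1, length(outcome),
                      "linear regression on age",
                      extra = list(beta = 0, r_squared = 0)))
  fit <- lm(outcome ~ ages)
  sm <- suppressWarnings(summary(fit))   # perfect fits warn harmlessly
  Fv <- if (is.null(sm$fstatistic)) 0 else unname(sm$fstatistic[1])
  p <- if (is.null(sm$fstatistic)) 1
  else unname(stats::pf(Fv, sm$fstatistic[2], sm$fstatistic[3],
                        lower.tail = FALSE))
  group_test(c(F = Fv), p, length(outcome), "linear regression on age",
             extra = list(beta = unname(coef(fit)[2]),
                          r_squared = sm$r.squared))
}

as_p <- function(x) if (inherits(x, "group_test")) x$p else as.numeric(x)

#' Latency-ordering model verdict
#'
#' Adjudicates between the three candidate accounts of context-feature
#' latency ordering from the pattern of one-tailed contrasts on peak
#' latencies within a phase:
#' \itemize{
#'   \item \strong{hierarchical} — the complexity-ordered latency difference
#'     (simple feature earlier) is significant whether or not the simple
#'     feature is attended;
#'   \item \strong{attention} — the order tracks the attended feature: the
#'     complexity-ordered difference holds when the prioritized feature is
#'     attended but reverses when the other feature is attended, and the
#'     attended-prioritized vs attended-other contrast is flat;
#'   \item \strong{hybrid} — the complexity-ordered difference is
#'     significant only when the prioritized feature is also attended, and
#'     the attended-prioritized peak still precedes the attended-other
#'     peak;
#'   \item \strong{indeterminate} — any other pattern.
#' }
#'
#' @param comparisons named list of one-tailed p-values or `group_test`
#'   objects: `attended` (complexity-ordered contrast when the prioritized
#'   feature is attended), `unattended` (same contrast when it is not),
#'   `interaction` (attention widens the latency gap), `across`
#'   (attended-prioritized vs attended-other peak); optionally
#'   `unattended_reversed` (reverse-direction contrast when unattended),
#'   which the attention verdict additionally requires when supplied.
#' @param alpha significance level.
#' @param phase label copied into the result.
#' @return a `model_verdict`: `verdict`, per-comparison significance
#'   pattern, `alpha`.
#' @export
model_verdict <- function(comparisons, alpha = 0.05, phase = NA_character_) {
  req <- c("attended", "unattended", "interaction", "across")
  missing_c <- setdiff(req, names(comparisons))
  if (length(missing_c) > 0)
    stopf("missing contrasts: %s", paste(missing_c, collapse = ", "))
  p <- vapply(comparisons, as_p, numeric(1))
  sig <- p < alpha
  rev_ok <- if ("unattended_reversed" %in% names(comparisons))
    sig[["unattended_reversed"]] else TRUE
  verdict <-
    if (sig[["attended"]] && sig[["unattended"]]) "hierarchical"
    else if (sig[["attended"]] && !sig[["unattended"]] && sig[["across"]]) "hybrid"
    else if (sig[["attended"]] && !sig[["unattended"]] && !sig[["across"]] &&
             rev_ok) "attention"
    else "indeterminate"
  structure(list(verdict = verdict, p_values = p, significant = sig,
                 alpha = alpha, phase = phase),
            class = "model_verdict")
}

#' @export
print.model_verdict <- function(x, ...) {
  cat(sprintf("<model_verdict> %s (alpha = %g%s)\n", x$verdict, x$alpha,
              if (is.na(x$phase)) "" else paste0(", phase ", x$phase)))
  for (nm in names(x$p_values))
    cat(sprintf("  %-20s p = %.4g %s\n", nm, x$p_values[nm],
                if (x$significant[nm]) "*" else ""))
  invisible(x)
}
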