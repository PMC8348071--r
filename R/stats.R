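stat_result <- function(statistic, p_value, method, n_effective,
                        degenerate = FALSE, extra = list()) {
  structure(
    c(list(statistic = statistic, p_value = p_value, method = method,
           n_effective = as.integer(n_effective), degenerate = degenerate),
      extra),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %.4g, p = %.4g, n = %d%s\n",
              x$method, x$statistic, x$p_value, x$n_effective,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' @export
tidy.stat_result <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p_value = x$p_value,
         n_effective = x$n_effective, degenerate = x$degenerate)
}

# paired differences from the accepted input shapes
paired_diffs <- function(a, b) {
  if (is.null(b)) {
    if (!is.data.frame(a) || !all(c("score_ref", "score_rt") %in% names(a))) {
      stop_cscine("need two vectors or a data frame with score_ref / score_rt",
                  "cscine_invalid_spec")
    }
    as.numeric(a$score_rt) - as.numeric(a$score_ref)
  } else {
    if (length(a) != length(b)) {
      stop_cscine("paired samples must have equal length", "cscine_invalid_spec")
    }
    as.numeric(b) - as.numeric(a)
  }
}

# exact null distribution of W+ (sum of positive ranks) by dynamic
# programming over the 2^n equiprobable sign assignments; ranks are
# midranks, so doubling makes them integers
wilcoxon_exact_p <- function(ranks, w_obs) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (v in r2) {
    shifted <- c(rep(0, v), counts[seq_len(total + 1 - v)])
    counts <- counts + shifted
  }
  counts <- counts / 2^length(r2)
  w2 <- round(2 * w_obs)
  centre <- total / 2
  dev <- abs(w2 - centre)
  support <- 0:total
  sum(counts[abs(support - centre) >= dev - 1e-9])
}

#' Wilcoxon signed-rank test for paired ordinal scores
#'
#' Two-sided paired signed-rank test with midranks for ties. Zero
#' differences are dropped by default (classic convention); with
#' `zero_method = "pratt"` zeros participate in the ranking before being
#' discarded from the statistic. The exact null distribution (enumeration
#' over all sign assignments, via its generating function) is used when the
#' effective sample size is at most `exact_max`; beyond that, a normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param a Either a numeric vector (first condition) or a paired-score
#'   data frame with columns `score_ref` and `score_rt` (differences are
#'   `rt - ref`).
#' @param b Second condition, if `a` is a vector (differences are `b - a`).
#' @param zero_method `"wilcox"` (drop zero differences) or `"pratt"`.
#' @param exact_max Largest effective n for exact enumeration (default 25).
#' @return A `stat_result`; `statistic` is the positive-rank sum `V`, with
#'   the centred statistic in `$signed`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4), c(2, 3, 4, 6))
#' @export
wilcoxon_signed_rank <- function(a, b = NULL,
                                 zero_method = c("wilcox", "pratt"),
                                 exact_max = 25) {
  zero_method <- match.arg(zero_method)
  d <- paired_diffs(a, b)
  if (length(d) < 1) stop_cscine("no pairs supplied", "cscine_insufficient_data")
  nz <- d != 0
  if (!any(nz)) {
    return(stat_result(0, 1, "Wilcoxon signed-rank (degenerate: all ties)", 0,
                       degenerate = TRUE, extra = list(signed = 0)))
  }
  if (zero_method == "wilcox") {
    dd <- d[nz]
    ranks <- rank(abs(dd))
  } else {
    all_ranks <- rank(abs(d))
    dd <- d[nz]
    ranks <- all_ranks[nz]
  }
  n_eff <- length(dd)
  w <- sum(ranks[dd > 0])
  centre <- sum(ranks) / 2
  if (n_eff <= exact_max) {
    p <- wilcoxon_exact_p(ranks, w)
    method <- "Wilcoxon signed-rank (exact)"
  } else {
    sigma <- sqrt(sum(ranks^2) / 4)
    z <- (w - centre - sign(w - centre) * 0.5) / sigma
    p <- 2 * pnorm(-abs(z))
    method <- "Wilcoxon signed-rank (normal approximation)"
  }
  stat_result(w, min(p, 1), method, n_eff,
              extra = list(signed = w - centre, zero_method = zero_method))
}

#' Paired Student's t test
#'
#' Classical two-sided paired t test, used for continuous paired quantities
#' such as per-patient edge-sharpness values and ARA rates. Zero-variance
#' differences yield a flagged degenerate result rather than an error.
#'
#' @param values_a,values_b Matched numeric vectors.
#' @return A `stat_result` with the t statistic and two-sided p, and the
#'   mean difference (`b - a`) in `$mean_difference`.
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b) || length(values_a) < 2) {
    stop_cscine("need matched vectors of length >= 2", "cscine_insufficient_data")
  }
  d <- values_b - values_a
  if (sd(d) <= 1e-14 * max(abs(d), 1)) {
    return(stat_result(NA_real_, 1, "Paired t (degenerate: constant differences)",
                       length(d), degenerate = TRUE,
                       extra = list(mean_difference = mean(d))))
  }
  tt <- stats::t.test(values_b, values_a, paired = TRUE)
  stat_result(unname(tt$statistic), tt$p.value, "Paired t", length(d),
              extra = list(mean_difference = mean(d)))
}

#' Intraclass correlation for interobserver agreement
#'
#' Single-measure intraclass correlation from a two-way model. The default
#' `"ICC2"` is the two-way random-effects, absolute-agreement form
#' ICC(2,1), the usual choice when two raters score the same subjects and
#' systematic rater offsets should count against agreement; `"ICC3"` gives
#' the consistency form ICC(3,1).
#'
#' @param ratings Numeric matrix or data frame, subjects in rows, raters in
#'   columns (>= 2 of each).
#' @param model `"ICC2"` (absolute agreement) or `"ICC3"` (consistency).
#' @return A `stat_result` whose statistic is the ICC (p-value from the
#'   F test of subject effect).
#' @export
icc_absolute <- function(ratings, model = c("ICC2", "ICC3")) {
  model <- match.arg(model)
  x <- as.matrix(ratings)
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop_cscine("need >= 2 subjects and >= 2 raters",
                                  "cscine_insufficient_data")
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= 1e-14 * max(abs(x), 1)) {
    return(stat_result(NA_real_, 1, "ICC (degenerate: no between-subject variance)",
                       n, degenerate = TRUE))
  }
  icc <- if (model == "ICC2") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
  f <- msr / mse
  p <- stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  stat_result(icc, p, paste0("Intraclass correlation ", model, ",1"), n,
              extra = list(msr = msr, msc = msc, mse = mse))
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement between two categorical raters, optionally
#' with linear weights for ordinal scales (weighted kappa with weight
#' `1 - |i - j| / (C - 1)`).
#'
#' @param rater1,rater2 Vectors of categories (factors or coercible).
#' @param weights `"none"` or `"linear"`.
#' @return A `stat_result` whose statistic is kappa.
#' @export
cohen_kappa <- function(rater1, rater2, weights = c("none", "linear")) {
  weights <- match.arg(weights)
  if (length(rater1) != length(rater2)) {
    stop_cscine("raters must score the same subjects", "cscine_invalid_spec")
  }
  levs <- sort(unique(c(as.character(rater1), as.character(rater2))))
  if (length(levs) < 2) {
    return(stat_result(NA_real_, 1, "Cohen's kappa (degenerate: one category)",
                       length(rater1), degenerate = TRUE))
  }
  f1 <- factor(as.character(rater1), levels = levs)
  f2 <- factor(as.character(rater2), levels = levs)
  tab <- table(f1, f2) / length(f1)
  C <- length(levs)
  w <- if (weights == "none") {
    diag(C)
  } else {
    1 - abs(outer(seq_len(C), seq_len(C), `-`)) / (C - 1)
  }
  po <- sum(w * tab)
  pe <- sum(w * outer(rowSums(tab), colSums(tab)))
  if (abs(1 - pe) < 1e-14) {
    return(stat_result(NA_real_, 1, "Cohen's kappa (degenerate: chance agreement 1)",
                       length(rater1), degenerate = TRUE))
  }
  kappa <- (po - pe) / (1 - pe)
  stat_result(kappa, NA_real_, paste0("Cohen's kappa (", weights, " weights)"),
              length(rater1))
}

#' Median and range summary
#'
#' The non-parametric summary used for ordinal scores: median with minimum
#' and maximum. For even n the median is the midpoint of the two central
#' order statistics, so integer ordinal data can yield a half-integer.
#'
#' @param values Non-empty numeric vector.
#' @return A one-row tibble: `median`, `min`, `max`, `n`.
#' @export
median_range <- function(values) {
  if (length(values) < 1) stop_cscine("empty input", "cscine_insufficient_data")
  tibble(median = median(values), min = min(values), max = max(values),
         n = length(values))
}
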