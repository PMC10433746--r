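# Per-feature differential statistics for both omics: fold change on the raw
# abundance scale, pooled two-sample t-test on the log2 scale, BH adjustment,
# strict threshold calling, and the summary-statistics t-test used for sperm
# quality tables reported as mean +/- SEM.

#' Per-feature log2 fold change (PS over FS)
#'
#' `log2((mean_PS + eps) / (mean_FS + eps))` on the raw abundance scale, so a
#' negative value means the feature is reduced after freezing. The pseudocount
#' `eps` bounds the magnitude for features absent in one group; its size
#' relative to the abundance scale determines the extreme magnitudes (a
#' feature abundant in FS but absent in PS yields roughly
#' `log2(eps / mean_FS)`).
#'
#' @param x An [expression_matrix()].
#' @param eps Positive pseudocount added to both group means (default 1e-3).
#' @param ref,alt Group labels for the reference (denominator) and altered
#'   (numerator) condition; defaults `"FS"` and `"PS"`.
#' @return Named numeric vector of log2 fold changes per feature.
#' @export
log2_fold_change <- function(x, eps = 1e-3, ref = "FS", alt = "PS") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (!is_scalar_num(eps) || eps <= 0) cry_abort("eps must be > 0", "domain")
  idx <- split(seq_along(x$groups), x$groups)
  for (g in c(ref, alt)) {
    if (is.null(idx[[g]]) || length(idx[[g]]) == 0) {
      cry_abort(sprintf("group '%s' is empty", g), "domain")
    }
  }
  m_ref <- rowMeans(x$values[, idx[[ref]], drop = FALSE])
  m_alt <- rowMeans(x$values[, idx[[alt]], drop = FALSE])
  log2((m_alt + eps) / (m_ref + eps))
}

# Pooled-variance two-sample t for summary stats; returns t, df, p and a
# degenerate flag implementing the zero-variance conventions: equal means with
# zero pooled variance -> t = 0, p = 1; unequal means -> t = +/-Inf, p = 0.
pooled_t <- function(mean1, var1, n1, mean2, var2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var1 + (n2 - 1) * var2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  delta <- mean1 - mean2
  degenerate <- se == 0
  t <- ifelse(degenerate, ifelse(delta == 0, 0, sign(delta) * Inf), delta / se)
  p <- ifelse(degenerate, ifelse(delta == 0, 1, 0), 2 * stats::pt(-abs(t), df))
  list(t = t, df = df, p = p, degenerate = degenerate)
}

#' Per-feature two-sample t-test
#'
#' Pooled-variance (Student's) two-sample t-test per feature with
#' `df = n1 + n2 - 2` and a two-sided p-value, computed by default on
#' log2-transformed abundance (`log2(value + eps)`). The statistic is oriented
#' `alt - ref` (PS minus FS), matching the sign of [log2_fold_change()].
#' Features with zero pooled variance are flagged `degenerate` and assigned
#' p = 1 when the group means are equal and p = 0 otherwise, rather than being
#' dropped.
#'
#' @param x An [expression_matrix()] with at least two samples per group.
#' @param log2_scale Test on `log2(value + eps)` (default) or on the raw scale.
#' @param eps Pseudocount for the log transform.
#' @param ref,alt Group labels (denominator/numerator convention as in
#'   [log2_fold_change()]).
#' @param welch Use the Welch (unequal-variance) test instead of the pooled
#'   test.
#' @return Data frame with columns `feature`, `t`, `df`, `p`, `degenerate`.
#' @export
student_t_test <- function(x, log2_scale = TRUE, eps = 1e-3, ref = "FS",
                           alt = "PS", welch = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  idx <- group_index(x)
  if (is.null(idx[[ref]]) || is.null(idx[[alt]])) {
    cry_abort(sprintf("groups '%s' and '%s' are both required", ref, alt), "domain")
  }
  v <- x$values
  if (log2_scale) v <- log2(v + eps)
  a <- v[, idx[[alt]], drop = FALSE]
  r <- v[, idx[[ref]], drop = FALSE]
  n1 <- ncol(a)
  n2 <- ncol(r)
  m1 <- rowMeans(a)
  m2 <- rowMeans(r)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((r - m2)^2) / (n2 - 1)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- ifelse(se2 > 0,
      se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
      n1 + n2 - 2
    )
    delta <- m1 - m2
    degenerate <- se2 == 0
    t <- ifelse(degenerate, ifelse(delta == 0, 0, sign(delta) * Inf),
      delta / sqrt(se2)
    )
    p <- ifelse(degenerate, ifelse(delta == 0, 1, 0), 2 * stats::pt(-abs(t), df))
    res <- list(t = t, df = df, p = p, degenerate = degenerate)
  } else {
    res <- pooled_t(m1, v1, n1, m2, v2, n2)
  }
  data.frame(
    feature = rownames(v), t = res$t, df = res$df, p = res$p,
    degenerate = res$degenerate, row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `p_(i) * m / i` with a cumulative minimum taken from the
#' largest rank downwards, capped at 1; tied p-values share the adjusted value
#' of their common rank position. Results are returned in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of BH-adjusted values (FDR).
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) cry_abort("p-values must be numeric", "domain")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    cry_abort("p-values must lie in [0, 1]", "domain")
  }
  stats::p.adjust(p, method = "BH")
}

#' Apply fold-change and FDR gates to a differential table
#'
#' Calls each feature `up` when `log2FC > lfc_threshold` and
#' `fdr < alpha`, `down` when `log2FC < -lfc_threshold` and `fdr < alpha`, and
#' `ns` otherwise. Both inequalities are strict, so features sitting exactly
#' on a threshold are not called. The defaults follow the usual gates for the
#' two omics: genes `lfc_threshold = 1`, proteins `lfc_threshold = 0.263`,
#' `alpha = 0.05` for both.
#'
#' @param table Data frame with columns `log2FC` and `fdr`.
#' @param lfc_threshold Positive log2 fold-change threshold.
#' @param alpha FDR significance level.
#' @return `table` with a `call` column (`"up"`, `"down"`, `"ns"`); the counts
#'   of up/down/ns calls are attached as attribute `"counts"`.
#' @export
call_differential <- function(table, lfc_threshold = 1, alpha = 0.05) {
  if (!all(c("log2FC", "fdr") %in% names(table))) {
    cry_abort("table needs columns 'log2FC' and 'fdr'", "domain")
  }
  if (!is_scalar_num(lfc_threshold) || lfc_threshold < 0) {
    cry_abort("lfc_threshold must be a non-negative number", "domain")
  }
  sig <- table$fdr < alpha
  call <- rep("ns", nrow(table))
  call[sig & table$log2FC > lfc_threshold] <- "up"
  call[sig & table$log2FC < -lfc_threshold] <- "down"
  table$call <- call
  attr(table, "counts") <- c(
    up = sum(call == "up"), down = sum(call == "down"), ns = sum(call == "ns")
  )
  table
}

#' Full differential table for one omics block
#'
#' Convenience wrapper running [log2_fold_change()], [student_t_test()],
#' [bh_adjust()] and [call_differential()] in sequence.
#'
#' @inheritParams student_t_test
#' @inheritParams call_differential
#' @return Data frame with columns `feature`, `log2FC`, `t`, `df`, `p_raw`,
#'   `fdr`, `degenerate`, `call`.
#' @export
differential_table <- function(x, eps = 1e-3, lfc_threshold = 1, alpha = 0.05,
                               ref = "FS", alt = "PS", welch = FALSE) {
  lfc <- log2_fold_change(x, eps = eps, ref = ref, alt = alt)
  tt <- student_t_test(x, eps = eps, ref = ref, alt = alt, welch = welch)
  tab <- data.frame(
    feature = tt$feature, log2FC = unname(lfc[tt$feature]), t = tt$t,
    df = tt$df, p_raw = tt$p, fdr = bh_adjust(tt$p),
    degenerate = tt$degenerate, row.names = NULL, stringsAsFactors = FALSE
  )
  call_differential(tab, lfc_threshold = lfc_threshold, alpha = alpha)
}

#' Pooled t-test from published summary statistics
#'
#' Reconstructs the two-sample pooled-variance t-test from group means,
#' standard errors of the mean and group sizes, as printed in tables of the
#' form "mean +/- SEM". The standard deviation is recovered as
#' `sd = sem * sqrt(n)`; `df = n1 + n2 - 2`; the p-value is two-sided.
#'
#' @param mean1,sem1,n1 Summary statistics for the first group.
#' @param mean2,sem2,n2 Summary statistics for the second group.
#' @return List with elements `t`, `df`, `p`, `degenerate`. The statistic is
#'   oriented `mean1 - mean2`.
#' @examples
#' ttest_from_summary(82.63, 3.55, 3, 34.10, 2.90, 3)$p # < 0.001
#' @export
ttest_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2) {
  if (any(c(n1, n2) < 2)) cry_abort("group sizes must be at least 2", "domain")
  if (any(c(sem1, sem2) < 0)) cry_abort("SEMs must be non-negative", "domain")
  pooled_t(mean1, sem1^2 * n1, n1, mean2, sem2^2 * n2, n2)
}
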