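#' Per-gene log2 fold change between two conditions
#'
#' `l2fc_g = log2((mean_A(g) + eps) / (mean_B(g) + eps))` on normalized
#' coverage, with a pseudocount guarding zero-coverage genes.
#'
#' @param matrix Genes x samples coverage matrix.
#' @param cond_a,cond_b Sample id (column) sets for the two conditions.
#' @param pseudocount Pseudocount epsilon > 0 (RPM/kb units).
#' @return Numeric vector named by gene.
#' @export
log2_fold_change <- function(matrix, cond_a, cond_b, pseudocount = 0.01) {
  check_condition_columns(matrix, cond_a, "A", min_n = 1L)
  check_condition_columns(matrix, cond_b, "B", min_n = 1L)
  if (pseudocount <= 0) stop_("pseudocount must be > 0")
  ma <- rowMeans(matrix[, cond_a, drop = FALSE])
  mb <- rowMeans(matrix[, cond_b, drop = FALSE])
  log2((ma + pseudocount) / (mb + pseudocount))
}

check_condition_columns <- function(matrix, cols, label, min_n = 2L) {
  if (length(cols) < min_n) {
    stop_("condition ", label, " needs at least ", min_n, " replicate(s)")
  }
  missing <- setdiff(cols, colnames(matrix))
  if (length(missing)) {
    stop_("condition ", label, " column(s) not in matrix: ",
          paste(missing, collapse = ", "))
  }
}

#' Per-gene t-tests on log coverage
#'
#' Two-sided t-test per gene on `log2(value + pseudocount)`. The default uses
#' the pooled-variance (Student) form: with equal replicate numbers the t
#' statistic equals Welch's, but the degrees of freedom stay at
#' `n_A + n_B - 2` even when one condition (typically the repaired one, with
#' far fewer fragments) has intrinsically lower counting variance.
#' `var_equal = FALSE` gives the Welch test. Genes with zero variance in both
#' conditions and equal means get p = 1; with zero variance but unequal
#' means, the zero variances are floored at `var_floor`.
#'
#' @param matrix Genes x samples coverage matrix.
#' @param cond_a,cond_b Sample id sets (>= 2 replicates each).
#' @param pseudocount Pseudocount for the log transform.
#' @param var_floor Variance floor for degenerate zero-variance genes.
#' @param var_equal Pool variances (Student, default) or not (Welch).
#' @return Numeric vector of raw two-sided p-values named by gene, with the
#'   t statistics in `attr(, "statistic")`.
#' @export
per_gene_test <- function(matrix, cond_a, cond_b, pseudocount = 0.01,
                          var_floor = 1e-8, var_equal = TRUE) {
  check_condition_columns(matrix, cond_a, "A")
  check_condition_columns(matrix, cond_b, "B")
  a <- log2(matrix[, cond_a, drop = FALSE] + pseudocount)
  b <- log2(matrix[, cond_b, drop = FALSE] + pseudocount)
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  flat <- va == 0 & vb == 0 & ma == mb
  va <- ifelse(va == 0, var_floor, va)
  vb <- ifelse(vb == 0, var_floor, vb)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, length(se2))
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- (ma - mb) / sqrt(se2)
  p <- 2 * pt(-abs(tstat), df)
  p[flat] <- 1
  tstat[flat] <- 0
  p <- setNames(pmin(p, 1), rownames(matrix))
  attr(p, "statistic") <- tstat
  attr(p, "df") <- df
  p
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` elementwise.
#'
#' @param p Raw p-values in [0, 1].
#' @param m Number of tests (>= number of p-values supplied).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_("p-values must lie in [0, 1]")
  if (m < length(p)) stop_("m must be at least the number of tested genes")
  pmin(1, m * p)
}

#' Call genes with significantly elevated coverage
#'
#' A gene is `dependent` when its Bonferroni-adjusted p-value is below
#' `alpha` and its log2 fold change is positive; genes whose mean coverage is
#' below `min_coverage` in every condition are `excluded`; everything else is
#' `non_changing`.
#'
#' @param l2fc Per-gene log2 fold changes.
#' @param p_adj Per-gene adjusted p-values (NA allowed for excluded genes).
#' @param alpha Significance level in (0, 1).
#' @param mean_a,mean_b Optional per-gene mean coverage per condition, used
#'   for the minimum-coverage filter.
#' @param min_coverage Minimum-coverage threshold.
#' @return Factor with levels `dependent`, `non_changing`, `excluded`.
#' @export
call_dependent_genes <- function(l2fc, p_adj, alpha = 0.05,
                                 mean_a = NULL, mean_b = NULL,
                                 min_coverage = 0.1) {
  if (!is_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop_("alpha must be in (0, 1)")
  }
  excluded <- if (!is.null(mean_a) && !is.null(mean_b)) {
    mean_a < min_coverage & mean_b < min_coverage
  } else {
    rep(FALSE, length(l2fc))
  }
  call <- rep("non_changing", length(l2fc))
  call[!excluded & !is.na(p_adj) & p_adj < alpha & l2fc > 0] <- "dependent"
  call[excluded] <- "excluded"
  factor(call, levels = c("dependent", "non_changing", "excluded"))
}

#' Differential DPC coverage between two conditions
#'
#' The per-gene comparison used to call transcription-dependent repair
#' (flavopiridol vs untreated at 6 h) and CSB-dependent repair (CSB knockout
#' vs WT at 6 h): log2 fold change of mean normalized coverage, Welch t-test
#' on log coverage, Bonferroni correction over the tested genes, and a
#' direction-aware call. Genes below `min_coverage` in both conditions are
#' excluded from testing and from the Bonferroni multiplier.
#'
#' @inheritParams per_gene_test
#' @param alpha Significance level for the adjusted p-values.
#' @param min_coverage Minimum mean normalized coverage.
#' @return data.frame (one row per gene): `gene_id`, `mean_a`, `mean_b`,
#'   `l2fc`, `p`, `p_adj`, `call`; the Bonferroni multiplier is stored in
#'   `attr(, "m")`.
#' @export
compare_coverage <- function(matrix, cond_a, cond_b, alpha = 0.05,
                             pseudocount = 0.01, min_coverage = 0.1,
                             var_floor = 1e-8) {
  ma <- rowMeans(matrix[, cond_a, drop = FALSE])
  mb <- rowMeans(matrix[, cond_b, drop = FALSE])
  l2fc <- log2_fold_change(matrix, cond_a, cond_b, pseudocount)
  keep <- !(ma < min_coverage & mb < min_coverage)
  p <- rep(NA_real_, nrow(matrix))
  p[keep] <- per_gene_test(matrix[keep, , drop = FALSE], cond_a, cond_b,
                           pseudocount, var_floor)
  m <- sum(keep)
  p_adj <- ifelse(is.na(p), NA_real_, pmin(1, m * p))
  call <- call_dependent_genes(l2fc, p_adj, alpha, ma, mb, min_coverage)
  out <- data.frame(gene_id = rownames(matrix), mean_a = ma, mean_b = mb,
                    l2fc = l2fc, p = p, p_adj = p_adj, call = call,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  out
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Differences `d = x - y`; zero differences are dropped, tied absolute
#' differences are mid-ranked. The two-sided p-value is exact (computed from
#' the full sign-assignment distribution via a shift-algorithm convolution
#' over doubled mid-ranks, so ties are handled exactly) when the number of
#' nonzero pairs is at most `exact_threshold`, and otherwise uses the normal
#' approximation with tie and continuity corrections. If all differences are
#' zero, `W = 0` and `p = 1`.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_threshold Largest n for the exact distribution.
#' @return List of class `GroupTestResult`: `n_pairs` (nonzero pairs),
#'   `statistic` (W, sum of positive-difference ranks), `p_value`, `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_threshold = 25L) {
  if (length(x) != length(y)) stop_("x and y must have equal length")
  if (length(x) < 1L) stop_("need at least one pair")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(n_pairs = 0L, statistic = 0, p_value = 1,
                          method = "exact"), class = "GroupTestResult"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_threshold) {
    p <- exact_signed_rank_p(r, w)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(w - mu) * 0.5
    z <- if (sigma2 > 0) (w - mu - cc) / sqrt(sigma2) else 0
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(list(n_pairs = n, statistic = w, p_value = p, method = method),
            class = "GroupTestResult")
}

# Exact two-sided signed-rank p-value over all 2^n sign assignments, via a
# polynomial convolution on doubled ranks (integers even with midrank ties).
exact_signed_rank_p <- function(r, w) {
  r2 <- as.integer(round(2 * r))
  n <- length(r2)
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  cur <- 0L
  for (ri in r2) {
    idx <- seq_len(cur + 1L)
    f[idx + ri] <- f[idx + ri] + f[idx]
    cur <- cur + ri
  }
  probs <- f / 2^n
  w2 <- as.integer(round(2 * w))
  p_le <- sum(probs[seq_len(w2 + 1L)])
  p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' @export
print.GroupTestResult <- function(x, ...) {
  cat(sprintf("Wilcoxon signed rank: W = %g, n = %d, p = %.4g (%s)\n",
              x$statistic, x$n_pairs, x$p_value, x$method))
  invisible(x)
}

#' Paired Wilcoxon tests within gene groups
#'
#' For each gene group, runs the paired two-sided Wilcoxon signed-rank test
#' across genes (the gene is the pairing unit) comparing two per-gene
#' quantities, e.g. the 6 h / 0 h log2 fold change with versus without
#' flavopiridol. Groups with no nonzero pair are flagged degenerate (p = 1).
#'
#' @param x,y Per-gene paired quantities, aligned to the same genes.
#' @param groups Factor (or vector) of group labels, same length.
#' @param exact_threshold Passed to [wilcoxon_signed_rank()].
#' @return data.frame with one row per group: `group`, `n_pairs`,
#'   `statistic`, `p_value`, `method`, `degenerate`.
#' @export
group_recovery_test <- function(x, y, groups, exact_threshold = 25L) {
  if (length(x) != length(y) || length(x) != length(groups)) {
    stop_("x, y and groups must have equal length")
  }
  groups <- as.factor(groups)
  res <- lapply(levels(groups), function(g) {
    i <- groups == g
    if (!any(i) || all(x[i] == y[i])) {
      return(data.frame(group = g, n_pairs = 0L, statistic = 0, p_value = 1,
                        method = "degenerate", degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    t <- wilcoxon_signed_rank(x[i], y[i], exact_threshold)
    data.frame(group = g, n_pairs = t$n_pairs, statistic = t$statistic,
               p_value = t$p_value, method = t$method, degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
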