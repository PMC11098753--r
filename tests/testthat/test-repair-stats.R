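test_that("log2 fold change uses condition means with a pseudocount", {
  m <- matrix(c(8, 0, 8, 0, 2, 0, 2, 0), 2, 4,
              dimnames = list(c("G1", "G2"), c("a1", "a2", "b1", "b2")))
  l <- log2_fold_change(m, c("a1", "a2"), c("b1", "b2"), pseudocount = 1e-9)
  expect_equal(unname(l[1]), 2, tolerance = 1e-6)
  expect_equal(unname(l[2]), 0)  # pseudocount null at zero coverage
  # antisymmetry
  l_rev <- log2_fold_change(m, c("b1", "b2"), c("a1", "a2"), pseudocount = 1e-9)
  expect_equal(l_rev, -l)
})

test_that("per-gene t-tests match stats::t.test and honor degenerate rules", {
  set.seed(1)
  m <- matrix(rlnorm(50 * 6), 50, 6,
              dimnames = list(sprintf("G%02d", 1:50), sprintf("s%d", 1:6)))
  a <- paste0("s", 1:3); b <- paste0("s", 4:6)
  eps <- 0.01

  p_pooled <- per_gene_test(m, a, b)
  p_welch <- per_gene_test(m, a, b, var_equal = FALSE)
  oracle <- vapply(1:50, function(i) {
    c(t.test(log2(m[i, a] + eps), log2(m[i, b] + eps),
             var.equal = TRUE)$p.value,
      t.test(log2(m[i, a] + eps), log2(m[i, b] + eps))$p.value)
  }, numeric(2L))
  expect_equal(as.numeric(p_pooled), oracle[1, ], tolerance = 1e-10)
  expect_equal(as.numeric(p_welch), oracle[2, ], tolerance = 1e-10)

  # identical replicate vectors across conditions -> t = 0 -> p = 1
  m2 <- rbind(G1 = c(1, 2, 3, 1, 2, 3), G2 = c(5, 5, 5, 5, 5, 5),
              G3 = c(5, 5, 5, 7, 7, 7))
  colnames(m2) <- c(a, b)
  p2 <- per_gene_test(m2, a, b)
  expect_equal(unname(p2[1]), 1)
  expect_equal(unname(p2[2]), 1)  # zero variance, equal means
  expect_lt(p2[3], 1e-6)          # zero variance, unequal means: floored

  expect_error(per_gene_test(m2, "s1", b), "at least 2")
})

test_that("Bonferroni adjustment is capped, monotone and validated", {
  expect_equal(bonferroni_adjust(1e-6, m = 1e4), 0.01)
  expect_equal(bonferroni_adjust(0.5, m = 3), 1)
  expect_equal(bonferroni_adjust(0.123), 0.123)  # m = 1 identity
  expect_error(bonferroni_adjust(1.2), "\\[0, 1\\]")
  set.seed(2)
  p <- sort(runif(100))
  adj <- bonferroni_adjust(p, 200)
  expect_true(all(diff(adj) >= 0))
  expect_equal(adj, p.adjust(p, "bonferroni", n = 200))
})

test_that("dependent-gene calls require direction, significance and coverage", {
  call <- call_dependent_genes(l2fc = c(2, -0.5, 1, 0.2),
                               p_adj = c(0.001, 0.01, 1, NA),
                               alpha = 0.05,
                               mean_a = c(5, 5, 5, 0.01),
                               mean_b = c(1, 9, 5, 0.02))
  expect_equal(as.character(call),
               c("dependent", "non_changing", "non_changing", "excluded"))
  expect_true(all(call_dependent_genes(c(1, 2), c(1, 1)) == "non_changing"))
  expect_error(call_dependent_genes(1, 0.5, alpha = 1.5), "alpha")
})

test_that("exact Wilcoxon signed-rank matches full sign-pattern enumeration", {
  # frozen reference cases
  r1 <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(r1$statistic, 15)
  expect_equal(r1$p_value, 0.0625)
  expect_equal(r1$method, "exact")

  r2 <- wilcoxon_signed_rank(c(2, 4), c(1, 2))
  expect_equal(r2$p_value, 0.5)

  r3 <- wilcoxon_signed_rank(1:4, 1:4)
  expect_equal(r3$p_value, 1)
  expect_equal(r3$statistic, 0)

  # 200 random instances, n <= 12, with ties and zeros
  set.seed(7)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    d <- sample(-4:4, n, replace = TRUE)
    got <- wilcoxon_signed_rank(d, rep(0, n))
    want <- enum_signed_rank(d)
    expect_equal(got$statistic, want$W)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }

  # agreement with stats::wilcox.test on tie-free data
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    got <- wilcoxon_signed_rank(x, y)
    want <- wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(got$p_value, want, tolerance = 1e-12)
  }
})

test_that("normal approximation is close to the exact p at n = 25", {
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(25, mean = 0.3); y <- rnorm(25)
    ex <- wilcoxon_signed_rank(x, y, exact_threshold = 25L)
    ap <- wilcoxon_signed_rank(x, y, exact_threshold = 0L)
    expect_equal(ap$method, "normal_approx")
    expect_lt(abs(ex$p_value - ap$p_value), 0.01)
  }
})

test_that("group recovery tests flag degenerate groups and detect shifts", {
  x <- c(1, 2, 3, 4); y <- x
  g <- factor(c("a", "a", "b", "b"))
  res <- group_recovery_test(x, y, g)
  expect_true(all(res$p_value == 1))
  expect_true(all(res$degenerate))

  # all-positive differences, n = 30: exact p = 2/2^30 < 1e-6; the normal
  # approximation is conservative at this extreme tail but still tiny
  set.seed(10)
  x2 <- rnorm(30) + 2; y2 <- x2 - runif(30, 0.5, 1.5)
  r30 <- group_recovery_test(x2, y2, factor(rep("g", 30)))
  expect_equal(r30$method, "normal_approx")
  expect_lt(r30$p_value, 1e-5)
  exact30 <- wilcoxon_signed_rank(x2, y2, exact_threshold = 30L)
  expect_equal(exact30$p_value, 2 / 2^30)
  expect_lt(exact30$p_value, 1e-6)

  # the approximation tracks exact enumeration at n = 20 (all positive)
  x3 <- rnorm(20) + 2; y3 <- x3 - runif(20, 0.5, 1.5)
  ex <- wilcoxon_signed_rank(x3, y3, exact_threshold = 25L)
  ap <- wilcoxon_signed_rank(x3, y3, exact_threshold = 0L)
  expect_equal(ex$p_value, 2 / 2^20)
  expect_lt(ap$p_value, 1e-3)
})

test_that("flavopiridol delays recovery most in high-occupancy gene groups", {
  # The flavopiridol-vs-untreated gap in the 6 h / 0 h recovery fold change
  # grows monotonically with RNAPII occupancy, and the paired Wilcoxon in the
  # high-occupancy group is overwhelmingly significant with a positive shift.
  # (Two-sided p-values in the low groups are dominated by the global RPM
  # composition shift under pure counting noise, so the monotone quantity is
  # the group mean paired difference, not the p-value itself.)
  cfg <- simulation_config(n_genes = 400L, depth_per_sample = 5e5,
                           n_replicates = 2L)
  conds <- data.frame(genotype = "WT", treatment = "FA",
                      drug = c("none", "none", "flavopiridol"),
                      recovery_h = c(0, 6, 6), stringsAsFactors = FALSE)
  res <- lapply(1:5, function(s) {
    sim <- simulate_dpcseq(cfg, seed = s, conditions = conds)
    mat <- coverage_matrix(sim$fragments, sim$genes)
    ss <- sim$samplesheet
    ids <- function(d, h) ss$sample_id[ss$drug == d & ss$recovery_h == h]
    l_wt <- log2_fold_change(mat, ids("none", 6), ids("none", 0))
    l_fl <- log2_fold_change(mat, ids("flavopiridol", 6), ids("none", 0))
    grp <- quantile_groups(sim$covariates$occupancy, 4L)
    gt <- group_recovery_test(l_fl, l_wt, grp$group)
    list(shift = tapply(l_fl - l_wt, grp$group, mean), p = gt$p_value)
  })
  shifts <- rowMeans(sapply(res, `[[`, "shift"))
  expect_true(all(diff(shifts) > 0))      # monotone low -> high
  p_high <- sapply(res, function(r) r$p[4])
  expect_true(all(p_high < 1e-6))
  expect_gt(shifts[4], 1)                 # strong delay at active genes
  expect_lt(abs(shifts[1]), 0.25)         # near-null at inactive genes
})
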