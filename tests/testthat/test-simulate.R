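test_that("generated genomes respect layout constraints and are reproducible", {
  cfg <- simulation_config(n_genes = 100L, gene_length_range = c(3000L, 6000L),
                           intergenic_gap_min = 2000L)
  g1 <- generate_genome(cfg, seed = 7L)
  g2 <- generate_genome(cfg, seed = 7L)
  expect_identical(g1, g2)

  genes <- g1$genes
  expect_equal(nrow(genes), 100L)
  o <- order(genes$start)
  gaps <- genes$start[o][-1L] - genes$end[o][-100L]
  expect_true(all(gaps >= 2000L))
  expect_true(all(genes$length >= 3000L & genes$length <= 6000L))
  expect_setequal(unique(genes$strand), c("+", "-"))

  small <- simulation_config(n_genes = 100L,
                             gene_length_range = c(3000L, 6000L),
                             chromosome_length_budget = 1e5)
  expect_error(generate_genome(small, 1L), "chromosome_length_budget")
})

test_that("occupancy-accessibility rank correlation matches the copula target", {
  cfg <- simulation_config(n_genes = 2000L,
                           occupancy_accessibility_correlation = 0.8)
  rhos <- vapply(1:20, function(s) {
    cv <- generate_genome(cfg, seed = s)$covariates
    cor(cv$accessibility, cv$occupancy, method = "spearman")
  }, numeric(1L))
  expect_lt(abs(mean(rhos) - 0.8), 0.05)
})

test_that("induction follows beta0 + beta1/accessibility with a TSS peak", {
  genes <- generate_genome(tiny_config(), 1L)$genes
  cv <- data.frame(gene_id = genes$gene_id, accessibility = 2,
                   occupancy = 1)

  cfg <- tiny_config(induction = list(beta0 = 0.5, beta1 = 1, gamma = 0.3,
                                      tss_halfwidth = 500))
  land <- simulate_induction(genes, cv, cfg)
  expect_true(all(land$genes$body_density == land$genes$body_density[1]))
  expect_equal(land$genes$body_density[1], 0.5 + 1 / 2)
  expect_equal(land$genes$tss_weight, rep(0.3, nrow(genes)))
  expect_equal(land$background_density, 0.5 + 1 / 2)

  # null model: flat landscape
  flat_cfg <- tiny_config(induction = list(beta0 = 0.7, beta1 = 0, gamma = 0,
                                           tss_halfwidth = 500))
  flat <- simulate_induction(genes, cv, flat_cfg)
  expect_true(all(flat$genes$body_density == 0.7))
  expect_equal(flat$background_density, 0.7)

  # doubling accessibility halves the pure-accessibility density
  cv2 <- cv; cv2$accessibility <- 4
  pure_cfg <- tiny_config(induction = list(beta0 = 0, beta1 = 1, gamma = 0,
                                           tss_halfwidth = 500))
  d1 <- simulate_induction(genes, cv, pure_cfg)$genes$body_density
  d2 <- simulate_induction(genes, cv2, pure_cfg)$genes$body_density
  expect_equal(d2, d1 / 2)

  cv$accessibility[1] <- 0
  expect_error(simulate_induction(genes, cv, cfg), "positive")
})

test_that("repair kinetics match the closed-form exponential", {
  genes <- generate_genome(tiny_config(), 1L)$genes
  cv <- data.frame(gene_id = genes$gene_id, accessibility = 1, occupancy = 1)
  cfg <- tiny_config(repair = list(k_global = 0.1, k_tc = 0.2, k_tss = 0.4,
                                   proteasome_fraction = 0.7,
                                   dependence_rate_threshold = log(2) / 6))
  land0 <- simulate_induction(genes, cv, cfg)

  # t = 0 is the identity
  same <- apply_repair_kinetics(land0, "WT", "none", 0, cfg)
  expect_equal(same$genes$body_density, land0$genes$body_density)
  expect_equal(same$genes$tss_weight, land0$genes$tss_weight)

  # k_global = 0.1, k_tc * r = 0.2, t = 6: WT exp(-1.8), CSB_KO exp(-0.6)
  wt <- apply_repair_kinetics(land0, "WT", "none", 6, cfg)
  ko <- apply_repair_kinetics(land0, "CSB_KO", "none", 6, cfg)
  expect_equal(wt$genes$body_density / land0$genes$body_density,
               rep(exp(-1.8), nrow(genes)))
  expect_equal(ko$genes$body_density / land0$genes$body_density,
               rep(exp(-0.6), nrow(genes)))
  expect_equal(exp(-1.8), 0.1653, tolerance = 1e-3)
  expect_equal(exp(-0.6), 0.5488, tolerance = 1e-3)

  # genotype never touches the TSS peak
  expect_equal(wt$genes$tss_weight, ko$genes$tss_weight)

  # flavopiridol removes exactly the k_tc term
  flavo <- apply_repair_kinetics(land0, "WT", "flavopiridol", 6, cfg)
  expect_equal(flavo$genes$body_density, ko$genes$body_density)
  expect_equal(flavo$genes$tss_weight, ko$genes$tss_weight)
  expect_equal(flavo$background_density, ko$background_density)

  # MG132 scales the global and TSS rates by (1 - phi), not the k_tc term
  mg <- apply_repair_kinetics(land0, "WT", "MG132", 6, cfg)
  m <- 1 - 0.7
  expect_equal(mg$background_density / land0$background_density,
               exp(-0.1 * m * 6))
  expect_equal(mg$genes$tss_weight / land0$genes$tss_weight,
               rep(exp(-0.4 * m * 6), nrow(genes)))
  expect_equal(mg$genes$body_density / land0$genes$body_density,
               rep(exp(-(0.1 * m + 0.2) * 6), nrow(genes)))

  # with k_tc = 0, WT and CSB_KO are identical at all times
  cfg0 <- tiny_config(repair = list(k_global = 0.1, k_tc = 0, k_tss = 0.4,
                                    proteasome_fraction = 0.7,
                                    dependence_rate_threshold = log(2) / 6))
  land00 <- simulate_induction(genes, cv, cfg0)
  for (t in c(1, 6)) {
    wt_t <- apply_repair_kinetics(land00, "WT", "none", t, cfg0)
    ko_t <- apply_repair_kinetics(land00, "CSB_KO", "none", t, cfg0)
    expect_equal(wt_t$genes, ko_t$genes)
    expect_equal(wt_t$background_density, ko_t$background_density)
  }

  # repair is mass-decreasing
  t3 <- apply_repair_kinetics(land0, "WT", "none", 3, cfg)
  expect_true(all(t3$genes$body_density >= wt$genes$body_density))
  expect_true(all(land0$genes$body_density >= t3$genes$body_density))
})

test_that("dependence labels equal the closed-form flavopiridol mass-ratio rule", {
  cfg <- simulation_config(n_genes = 300L)
  g <- generate_genome(cfg, seed = 3L)
  land0 <- simulate_induction(g$genes, g$covariates, cfg)
  none6 <- apply_repair_kinetics(land0, "WT", "none", 6, cfg)
  flavo6 <- apply_repair_kinetics(land0, "WT", "flavopiridol", 6, cfg)
  ratio <- landscape_mass(flavo6)$body_mass / landscape_mass(none6)$body_mass
  thr <- exp(cfg$repair$dependence_rate_threshold * 6)
  expect_identical(g$truth$transcription_dependent, ratio >= thr - 1e-12)
  expect_true(sum(g$truth$transcription_dependent) > 0)
})

test_that("fragment sampling is seeded, mass-proportional and guards empty landscapes", {
  cfg <- tiny_config()
  g <- generate_genome(cfg, 2L)
  land <- simulate_induction(g$genes, g$covariates, cfg)

  f1 <- sample_fragments(land, cfg, seed = 11L)
  f2 <- sample_fragments(land, cfg, seed = 11L)
  expect_identical(f1, f2)
  expect_gt(f1$total_fragments, 0L)
  expect_true(all(f1$fragments$start < f1$fragments$end))
  expect_true(all(f1$fragments$start >= 0L))

  zero_depth <- tiny_config(depth_per_sample = 0)
  expect_equal(sample_fragments(land, zero_depth, 1L)$total_fragments, 0L)

  dead_cfg <- tiny_config(induction = list(beta0 = 0, beta1 = 0, gamma = 0,
                                           tss_halfwidth = 500))
  dead <- simulate_induction(g$genes, g$covariates, dead_cfg)
  expect_error(sample_fragments(dead, dead_cfg, 1L), "no mass")
})

test_that("two equal genes on a flat landscape split fragments binomially", {
  cfg <- simulation_config(n_genes = 2L, gene_length_range = c(8000L, 8000L),
                           induction = list(beta0 = 1, beta1 = 0, gamma = 0,
                                            tss_halfwidth = 500),
                           depth_per_sample = 1e5)
  g <- generate_genome(cfg, 5L)
  land <- simulate_induction(g$genes, g$covariates, cfg)
  fs <- sample_fragments(land, cfg, seed = 9L)
  counts <- count_fragments_per_gene(fs, g$genes)
  n <- sum(counts)
  # gene 1 count ~ Binomial(n, 1/2) by symmetry
  expect_lt(abs(counts[1] - n / 2), 3 * sqrt(n * 0.25))
})

test_that("expected per-gene fragment counts track landscape mass share", {
  # short fragments so any-overlap edge capture is negligible, and no TSS
  # kernel (half of a TSS kernel lies upstream of the gene by construction,
  # so gene-overlap counts would undershoot the raw TSS mass)
  cfg <- simulation_config(n_genes = 40L, gene_length_range = c(3000L, 9000L),
                           induction = list(beta0 = 1, beta1 = 0.5, gamma = 0,
                                            tss_halfwidth = 500),
                           fragment_length_range = c(10L, 20L),
                           depth_per_sample = 2e4)
  g <- generate_genome(cfg, 4L)
  land <- apply_repair_kinetics(
    simulate_induction(g$genes, g$covariates, cfg), "WT", "none", 2, cfg)
  mass <- landscape_mass(land)
  total_mass <- sum(mass$body_mass + mass$tss_mass) +
    attr(mass, "background_mass")
  expected <- 2e4 * (mass$body_mass + mass$tss_mass) / total_mass

  counts <- rowMeans(vapply(1:20, function(s) {
    count_fragments_per_gene(sample_fragments(land, cfg, seed = s), g$genes)
  }, numeric(40L)))
  se <- sqrt(expected / 20)
  expect_true(all(abs(counts - expected) < 5 * se + 0.05 * expected))
})

test_that("simulate_dpcseq builds a paired replicate design deterministically", {
  cfg <- tiny_config(n_replicates = 2L)
  sim <- simulate_dpcseq(cfg, seed = 21L)
  ss <- sim$samplesheet
  expect_equal(nrow(ss), 5L * 2L)
  expect_setequal(names(sim$fragments), ss$sample_id)
  expect_equal(sort(unique(ss$replicate)), c(1L, 2L))
  # replicate index pairs conditions
  expect_equal(sum(ss$replicate == 1L), 5L)

  sim2 <- simulate_dpcseq(cfg, seed = 21L)
  expect_identical(sim$fragments, sim2$fragments)
  expect_identical(sim$truth, sim2$truth)
})
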