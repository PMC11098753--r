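#' Simulation configuration for synthetic DPC-seq datasets
#'
#' Bundles and validates all parameters of the synthetic-data generator. The
#' defaults define the package's reference scenario: 2,000 non-overlapping
#' genes of 5-20 kb separated by at least 2 kb, formaldehyde induction that
#' deposits more cross-links in inaccessible chromatin plus an RNAPII
#' cross-link peak at TSSs, and first-order repair over a 6 h recovery whose
#' gene-body rate increases with RNAPII occupancy (the transcription-coupled
#' component, lost in CSB knockouts or under flavopiridol) on top of a global
#' proteasome-dependent component (suppressed by MG132).
#'
#' @param n_genes Number of genes.
#' @param gene_length_range Integer min/max gene length (bp).
#' @param intergenic_gap_min Minimum gap between adjacent genes (bp).
#' @param chrom_pad Gene-free padding at chromosome ends (bp).
#' @param chromosome_length_budget Optional maximum chromosome length (bp);
#'   the generator errors if the layout cannot fit.
#' @param accessibility List with `meanlog`, `sdlog` of the log-normal
#'   per-gene ATAC accessibility.
#' @param occupancy List describing the RNAPII occupancy marginal: a
#'   two-component log-normal mixture with `active_fraction` and
#'   `meanlog_low`/`sdlog_low`, `meanlog_active`/`sdlog_active`. Most genes
#'   are lowly transcribed; a distinct active class carries high occupancy.
#' @param occupancy_accessibility_correlation Target Spearman rank
#'   correlation between accessibility and occupancy (Gaussian copula).
#' @param induction List with `beta0` (baseline cross-links/kb), `beta1`
#'   (inaccessibility coefficient; body density is `beta0 + beta1 / a_g`),
#'   `gamma` (TSS-peak cross-links per unit occupancy) and `tss_halfwidth`
#'   (bp, symmetric triangular kernel).
#' @param repair List with rates in 1/h: `k_global` (accessibility- and
#'   transcription-independent), `k_tc` (per unit occupancy; WT only, and
#'   abolished by flavopiridol), `k_tss` (TSS-peak resolution, genotype
#'   independent), `proteasome_fraction` phi in [0,1] (MG132 multiplies the
#'   global and TSS rates by 1 - phi), and `dependence_rate_threshold`
#'   (1/h): a gene is labelled transcription/CSB dependent when
#'   `k_tc * r_g` is at or above it (default `log(2)/6`, i.e. at least
#'   twofold extra clearance over 6 h).
#' @param depth_per_sample Expected sequenced fragments per sample.
#' @param fragment_length_range Integer min/max fragment length (bp),
#'   matching the 400-1,000 bp size selection of the assay.
#' @param n_replicates Replicates per condition.
#' @param overdispersion Optional negative-binomial size for the per-sample
#'   fragment count; `NULL` (default) uses Poisson depth.
#'
#' @return A validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(
    n_genes = 2000L,
    gene_length_range = c(5000L, 20000L),
    intergenic_gap_min = 2000L,
    chrom_pad = 5000L,
    chromosome_length_budget = NULL,
    accessibility = list(meanlog = 0, sdlog = 1),
    occupancy = list(active_fraction = 0.15,
                     meanlog_low = log(0.1), sdlog_low = 0.8,
                     meanlog_active = log(12), sdlog_active = 0.35),
    occupancy_accessibility_correlation = 0.6,
    induction = list(beta0 = 1, beta1 = 0.5, gamma = 1, tss_halfwidth = 500),
    repair = list(k_global = 0.15, k_tc = 0.04, k_tss = 0.6,
                  proteasome_fraction = 0.7,
                  dependence_rate_threshold = log(2) / 6),
    depth_per_sample = 2e6,
    fragment_length_range = c(400L, 1000L),
    n_replicates = 3L,
    overdispersion = NULL) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    intergenic_gap_min = as.integer(intergenic_gap_min),
    chrom_pad = as.integer(chrom_pad),
    chromosome_length_budget = chromosome_length_budget,
    accessibility = accessibility,
    occupancy = occupancy,
    occupancy_accessibility_correlation = occupancy_accessibility_correlation,
    induction = induction,
    repair = repair,
    depth_per_sample = depth_per_sample,
    fragment_length_range = as.integer(fragment_length_range),
    n_replicates = as.integer(n_replicates),
    overdispersion = overdispersion
  )
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  if (cfg$n_genes < 1L) stop_("n_genes must be >= 1")
  if (cfg$gene_length_range[1L] > cfg$gene_length_range[2L] ||
      cfg$gene_length_range[1L] < 1L) {
    stop_("invalid gene_length_range")
  }
  rho <- cfg$occupancy_accessibility_correlation
  if (!is_number(rho) || rho < -1 || rho > 1) {
    stop_("occupancy_accessibility_correlation must be in [-1, 1]")
  }
  rates <- c(unlist(cfg$induction), cfg$repair$k_global, cfg$repair$k_tc,
             cfg$repair$k_tss, cfg$repair$dependence_rate_threshold)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop_("induction/repair parameters must be finite and >= 0")
  }
  phi <- cfg$repair$proteasome_fraction
  if (!is_number(phi) || phi < 0 || phi > 1) {
    stop_("proteasome_fraction must be in [0, 1]")
  }
  fr <- cfg$fragment_length_range
  if (fr[1L] < 1L || fr[1L] > fr[2L]) stop_("invalid fragment_length_range")
  if (fr[2L] > cfg$intergenic_gap_min + cfg$gene_length_range[2L]) {
    stop_("fragment lengths must not exceed min gene gap + max gene length")
  }
  if (cfg$depth_per_sample < 0) stop_("depth_per_sample must be >= 0")
  if (cfg$n_replicates < 1L) stop_("n_replicates must be >= 1")
  structure(cfg, class = "SimulationConfig")
}

# Quantile function of the two-component log-normal occupancy mixture,
# by bisection on log(x); strictly increasing so copula rank structure is
# preserved exactly.
qocc_mixture <- function(u, occ) {
  w <- occ$active_fraction
  pmix <- function(lx) {
    (1 - w) * plnorm(exp(lx), occ$meanlog_low, occ$sdlog_low) +
      w * plnorm(exp(lx), occ$meanlog_active, occ$sdlog_active)
  }
  lo <- rep(-30, length(u)); hi <- rep(30, length(u))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    below <- pmix(mid) < u
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  exp((lo + hi) / 2)
}

#' Generate a synthetic genome with per-gene covariates and ground truth
#'
#' Lays `n_genes` non-overlapping genes on a synthetic chromosome with
#' intergenic gaps of at least `intergenic_gap_min` bp and alternating
#' strands, draws per-gene accessibility (log-normal) and RNAPII occupancy
#' (mixture marginal) coupled through a Gaussian copula with the configured
#' rank correlation, and derives deterministic dependence labels: a gene is
#' transcription-dependent (and CSB-dependent) when its transcription-coupled
#' repair rate `k_tc * r_g` reaches `dependence_rate_threshold`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `genes` (gene table; chromosome lengths in
#'   `attr(, "chrom_lengths")`), `covariates` and `truth` data frames.
#' @export
generate_genome <- function(config, seed = 1L) {
  config <- validate_simulation_config(unclass(config))
  n <- config$n_genes
  with_seed(seed, {
    lens <- config$gene_length_range[1L] +
      sample.int(diff(config$gene_length_range) + 1L, n, replace = TRUE) - 1L
    gaps <- config$intergenic_gap_min +
      sample.int(config$intergenic_gap_min + 1L, n, replace = TRUE) - 1L
    starts <- config$chrom_pad + cumsum(c(0, head(lens + gaps, -1L)))
    ends <- starts + lens
    chrom_len <- ends[n] + config$chrom_pad

    if (!is.null(config$chromosome_length_budget) &&
        chrom_len > config$chromosome_length_budget) {
      stop_("infeasible layout: required chromosome length ", chrom_len,
            " bp exceeds chromosome_length_budget of ",
            config$chromosome_length_budget, " bp")
    }

    # Gaussian copula: convert target Spearman rho to the normal-score
    # correlation rho' = 2 sin(pi * rho / 6).
    rho <- config$occupancy_accessibility_correlation
    rho_n <- 2 * sin(pi * rho / 6)
    z1 <- rnorm(n)
    z2 <- rho_n * z1 + sqrt(1 - rho_n^2) * rnorm(n)
    acc <- qlnorm(pnorm(z1), config$accessibility$meanlog,
                  config$accessibility$sdlog)
    occ <- qocc_mixture(pnorm(z2), config$occupancy)

    # biotype: active genes are predominantly protein coding
    active_ish <- occ > exp((config$occupancy$meanlog_low +
                               config$occupancy$meanlog_active) / 2)
    biotypes <- c("protein_coding", "lncRNA", "rRNA", "tRNA")
    bio <- character(n)
    n_act <- sum(active_ish)
    bio[active_ish] <- sample(biotypes, n_act, replace = TRUE,
                              prob = c(0.95, 0.04, 0.005, 0.005))
    bio[!active_ish] <- sample(biotypes, n - n_act, replace = TRUE,
                               prob = c(0.75, 0.19, 0.02, 0.04))

    genes <- as_gene_table(data.frame(
      gene_id = sprintf("G%04d", seq_len(n)),
      chrom = "sim1",
      start = starts, end = ends,
      strand = rep_len(c("+", "-"), n),
      biotype = bio,
      stringsAsFactors = FALSE
    ))
    attr(genes, "chrom_lengths") <- c(sim1 = chrom_len)

    covariates <- data.frame(gene_id = genes$gene_id, accessibility = acc,
                             occupancy = occ, stringsAsFactors = FALSE)

    k_tc_term <- config$repair$k_tc * occ
    dep <- k_tc_term >= config$repair$dependence_rate_threshold
    truth <- data.frame(
      gene_id = genes$gene_id,
      accessibility = acc,
      occupancy = occ,
      body_density_0 = config$induction$beta0 + config$induction$beta1 / acc,
      tss_weight_0 = config$induction$gamma * occ,
      k_tc_term = k_tc_term,
      transcription_dependent = dep,
      csb_dependent = dep,
      stringsAsFactors = FALSE
    )
    list(genes = genes, covariates = covariates, truth = truth)
  })
}

#' Compute the induced DPC landscape from covariates
#'
#' Formaldehyde deposits cross-links preferentially in inaccessible,
#' histone-rich chromatin: gene-body density is `beta0 + beta1 / a_g`
#' (cross-links per kb, monotone decreasing in accessibility), the TSS
#' carries an RNAPII cross-link peak of total weight `gamma * r_g` spread as
#' a symmetric triangular kernel, and intergenic background has density
#' `beta0 + beta1 / median(a)`.
#'
#' @param genome Gene table (as from [generate_genome()]; needs the
#'   `chrom_lengths` attribute for downstream fragment sampling).
#' @param covariates Per-gene covariate table covering every gene.
#' @param config A [simulation_config()].
#' @return A `DpcLandscape` object at recovery time 0.
#' @export
simulate_induction <- function(genome, covariates, config) {
  config <- validate_simulation_config(unclass(config))
  idx <- match(genome$gene_id, covariates$gene_id)
  if (anyNA(idx)) {
    stop_("covariates missing for gene(s): ",
          paste(head(genome$gene_id[is.na(idx)], 10L), collapse = ", "))
  }
  a <- covariates$accessibility[idx]
  r <- covariates$occupancy[idx]
  if (any(a <= 0)) stop_("accessibility must be positive for all genes")
  ind <- config$induction
  g <- genome
  g$accessibility <- a
  g$occupancy <- r
  g$body_density <- ind$beta0 + ind$beta1 / a
  g$tss_weight <- ind$gamma * r
  g$tss_pos <- ifelse(g$strand == "+", g$start, g$end)
  structure(list(
    genes = g,
    background_density = ind$beta0 + ind$beta1 / median(a),
    tss_halfwidth = ind$tss_halfwidth,
    chrom_lengths = attr(genome, "chrom_lengths"),
    genotype = NA_character_, drug = NA_character_, recovery_h = 0
  ), class = "DpcLandscape")
}

#' @export
print.DpcLandscape <- function(x, ...) {
  cat("DpcLandscape:", nrow(x$genes), "genes;",
      sprintf("background %.3f xlinks/kb;", x$background_density),
      "recovery", x$recovery_h, "h\n")
  invisible(x)
}

#' Apply first-order repair kinetics to a DPC landscape
#'
#' Gene-body density decays as `lambda_g(t) = lambda_g(0) * exp(-k_g t)` with
#' `k_g = k_global * m + k_tc * r_g * [genotype == WT] * [drug != flavopiridol]`
#' and `m = 1 - phi * [drug == MG132]`. The TSS peak decays genotype
#' independently with rate `k_tss * m`, and the intergenic background with
#' `k_global * m`.
#'
#' @param landscape A `DpcLandscape` (typically at t = 0).
#' @param genotype `"WT"` or `"CSB_KO"`.
#' @param drug `"none"`, `"flavopiridol"` or `"MG132"`.
#' @param recovery_h Recovery time in hours (>= 0).
#' @param config The [simulation_config()] holding the repair rates.
#' @return A new `DpcLandscape` at the requested recovery time.
#' @export
apply_repair_kinetics <- function(landscape, genotype = c("WT", "CSB_KO"),
                                  drug = c("none", "flavopiridol", "MG132"),
                                  recovery_h, config) {
  stopifnot(inherits(landscape, "DpcLandscape"))
  genotype <- match.arg(genotype)
  drug <- match.arg(drug)
  if (!is_number(recovery_h) || recovery_h < 0) {
    stop_("recovery_h must be a single number >= 0")
  }
  config <- validate_simulation_config(unclass(config))
  rp <- config$repair
  m <- 1 - rp$proteasome_fraction * (drug == "MG132")
  k_body <- rp$k_global * m +
    rp$k_tc * landscape$genes$occupancy *
      (genotype == "WT") * (drug != "flavopiridol")
  if (any(!is.finite(k_body))) stop_("non-finite repair rate")
  out <- landscape
  out$genes$body_density <- landscape$genes$body_density *
    exp(-k_body * recovery_h)
  out$genes$tss_weight <- landscape$genes$tss_weight *
    exp(-rp$k_tss * m * recovery_h)
  out$background_density <- landscape$background_density *
    exp(-rp$k_global * m * recovery_h)
  out$genotype <- genotype
  out$drug <- drug
  out$recovery_h <- landscape$recovery_h + recovery_h
  out
}

# Segment table used for fragment sampling and mass accounting:
# one row per gene body, per TSS kernel, and per intergenic region.
landscape_segments <- function(landscape) {
  g <- landscape$genes
  segs <- list()
  segs$body <- data.frame(
    chrom = g$chrom, start = g$start, end = g$end,
    mass = g$body_density * (g$end - g$start) / 1000,
    kind = "body", stringsAsFactors = FALSE
  )
  segs$tss <- data.frame(
    chrom = g$chrom, start = g$tss_pos, end = g$tss_pos,
    mass = g$tss_weight, kind = "tss", stringsAsFactors = FALSE
  )
  gaps <- do.call(rbind, lapply(unique(g$chrom), function(chr) {
    d <- g[g$chrom == chr, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    clen <- unname(landscape$chrom_lengths[chr])
    if (is.na(clen) || is.null(clen)) clen <- max(d$end)
    bs <- c(0L, d$end)
    be <- c(d$start, clen)
    keep <- be > bs
    data.frame(chrom = chr, start = bs[keep], end = be[keep],
               mass = landscape$background_density * (be[keep] - bs[keep]) / 1000,
               kind = "gap", stringsAsFactors = FALSE)
  }))
  out <- rbind(segs$body, segs$tss, gaps)
  rownames(out) <- NULL
  out
}

#' Total DPC mass per gene and in the background
#'
#' Expected cross-link mass (integrated density) for each gene body and TSS
#' peak, plus the total intergenic background mass; fragment midpoints are
#' sampled proportional to these masses.
#'
#' @param landscape A `DpcLandscape`.
#' @return data.frame with `gene_id`, `body_mass`, `tss_mass`; total
#'   background mass in `attr(, "background_mass")`.
#' @export
landscape_mass <- function(landscape) {
  stopifnot(inherits(landscape, "DpcLandscape"))
  g <- landscape$genes
  out <- data.frame(gene_id = g$gene_id,
                    body_mass = g$body_density * (g$end - g$start) / 1000,
                    tss_mass = g$tss_weight, stringsAsFactors = FALSE)
  segs <- landscape_segments(landscape)
  attr(out, "background_mass") <- sum(segs$mass[segs$kind == "gap"])
  out
}

#' Sample sequencing fragments from a DPC landscape
#'
#' Draws the fragment count (Poisson with mean `depth_per_sample`, or
#' negative binomial when `overdispersion` is set), places fragment midpoints
#' proportional to the landscape density (gene bodies and intergenic
#' background uniform within segment; TSS peaks triangular), and assigns
#' lengths uniform over `fragment_length_range`. Fragments are clipped to
#' chromosome bounds by shifting, preserving length.
#'
#' @param landscape A `DpcLandscape`.
#' @param config A [simulation_config()].
#' @param seed Integer seed; identical `(seed)` gives identical fragments.
#' @return A `FragmentSet`.
#' @export
sample_fragments <- function(landscape, config, seed = 1L) {
  stopifnot(inherits(landscape, "DpcLandscape"))
  config <- validate_simulation_config(unclass(config))
  segs <- landscape_segments(landscape)
  total_mass <- sum(segs$mass)
  with_seed(seed, {
    nfrag <- if (config$depth_per_sample == 0) {
      0L
    } else if (is.null(config$overdispersion)) {
      rpois(1L, config$depth_per_sample)
    } else {
      rnbinom(1L, mu = config$depth_per_sample, size = config$overdispersion)
    }
    if (nfrag > 0L && total_mass <= 0) {
      stop_("no mass to sample: landscape densities are all zero")
    }
    if (nfrag == 0L) {
      return(fragment_set(data.frame(chrom = character(), start = integer(),
                                     end = integer())))
    }
    idx <- sample.int(nrow(segs), nfrag, replace = TRUE, prob = segs$mass)
    # plain vectors: row-subsetting a data frame is too slow at 1e6+ draws
    seg_chrom <- factor(segs$chrom)
    chrom_i <- as.integer(seg_chrom)[idx]
    st <- segs$start[idx]
    wd <- (segs$end - segs$start)[idx]
    is_tss <- (segs$kind == "tss")[idx]
    mid <- numeric(nfrag)
    # uniform within gene bodies and gaps
    if (any(!is_tss)) {
      mid[!is_tss] <- st[!is_tss] + floor(runif(sum(!is_tss)) * wd[!is_tss])
    }
    # symmetric triangular kernel of half-width w around the TSS
    if (any(is_tss)) {
      hw <- landscape$tss_halfwidth
      n_t <- sum(is_tss)
      mid[is_tss] <- st[is_tss] + round(hw * (runif(n_t) + runif(n_t) - 1))
    }
    fr <- config$fragment_length_range
    len <- fr[1L] + sample.int(fr[2L] - fr[1L] + 1L, nfrag,
                               replace = TRUE) - 1L
    fs <- round(mid) - len %/% 2L
    fe <- fs + len
    # clip by shifting so lengths are preserved
    clens <- if (is.null(landscape$chrom_lengths)) {
      rep(Inf, nfrag)
    } else {
      cl <- landscape$chrom_lengths[levels(seg_chrom)][chrom_i]
      cl[is.na(cl)] <- Inf
      cl
    }
    shift_r <- pmax(0, -fs)
    fs <- fs + shift_r; fe <- fe + shift_r
    shift_l <- pmax(0, fe - clens)
    fs <- fs - shift_l; fe <- fe - shift_l
    fs <- pmax(fs, 0)
    o <- order(chrom_i, fs, fe)
    fragment_set(data.frame(chrom = levels(seg_chrom)[chrom_i[o]],
                            start = as.integer(fs[o]),
                            end = as.integer(fe[o]),
                            stringsAsFactors = FALSE))
  })
}

default_conditions <- function() {
  data.frame(
    genotype = c("WT", "WT", "WT", "CSB_KO", "CSB_KO"),
    treatment = "FA",
    drug = c("none", "none", "flavopiridol", "none", "none"),
    recovery_h = c(0, 6, 6, 0, 6),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete DPC-seq dataset
#'
#' Generates a genome, induces the formaldehyde DPC landscape, applies the
#' repair kinetics for each requested condition and samples replicate
#' fragment sets, each from an independent child stream derived
#' deterministically from `(seed, sample index)`.
#'
#' @param config A [simulation_config()].
#' @param seed Master integer seed.
#' @param conditions data.frame with columns `genotype`, `treatment`, `drug`,
#'   `recovery_h`; default: WT at 0 h and 6 h, WT + flavopiridol at 6 h and
#'   CSB knockout at 0 h and 6 h, all formaldehyde treated.
#' @return List with `genes`, `covariates`, `truth`, `samplesheet`,
#'   `fragments` (named list of `FragmentSet`s) and the induced `landscape`.
#' @export
simulate_dpcseq <- function(config = simulation_config(), seed = 1L,
                            conditions = default_conditions()) {
  config <- validate_simulation_config(unclass(config))
  genome <- generate_genome(config, derive_seed(seed, 1L))
  landscape <- simulate_induction(genome$genes, genome$covariates, config)

  reps <- seq_len(config$n_replicates)
  ss <- conditions[rep(seq_len(nrow(conditions)), each = length(reps)), ,
                   drop = FALSE]
  ss$replicate <- rep(reps, nrow(conditions))
  ss$sample_id <- sprintf("%s_%s_%gh_r%d", ss$genotype, ss$drug,
                          ss$recovery_h, ss$replicate)
  rownames(ss) <- NULL
  ss <- validate_sample_sheet(ss[c("sample_id", "genotype", "treatment",
                                   "recovery_h", "drug", "replicate")])

  fragments <- vector("list", nrow(ss))
  names(fragments) <- ss$sample_id
  for (i in seq_len(nrow(ss))) {
    land_i <- apply_repair_kinetics(landscape, ss$genotype[i], ss$drug[i],
                                    ss$recovery_h[i], config)
    fragments[[i]] <- sample_fragments(land_i, config,
                                       derive_seed(seed, 1000L + i))
  }
  list(genes = genome$genes, covariates = genome$covariates,
       truth = genome$truth, samplesheet = ss, fragments = fragments,
       landscape = landscape, config = config, seed = seed)
}
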