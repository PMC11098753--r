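# Independent oracles and small fixture builders used across test files.

# O(n*m) all-pairs overlap scan (half-open intervals).
brute_count_fragments <- function(frag_df, genes) {
  vapply(seq_len(nrow(genes)), function(i) {
    sum(frag_df$chrom == genes$chrom[i] &
          frag_df$start < genes$end[i] &
          frag_df$end > genes$start[i])
  }, numeric(1L))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
enum_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(W = 0, p = 1))
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- apply(grid, 1L, function(s) sum(r[s]))
  list(W = w_obs,
       p = min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs))))
}

make_genes <- function(start, end, strand = rep("+", length(start)),
                       chrom = "chr1",
                       id = sprintf("G%d", seq_along(start)),
                       biotype = "protein_coding") {
  data.frame(gene_id = id, chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, biotype = biotype,
             length = as.integer(end - start), stringsAsFactors = FALSE)
}

make_frags <- function(start, end, chrom = "chr1") {
  fragment_set(data.frame(chrom = chrom, start = as.integer(start),
                          end = as.integer(end), stringsAsFactors = FALSE))
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 50L, gene_length_range = c(3000L, 6000L),
         depth_per_sample = 5e4),
    list(...))
  do.call(simulation_config, args)
}

# independent per-(seed, replicate) stream ids for test simulations
derive_seed_test <- function(a, b) {
  as.integer((a * 7919 + b * 104729) %% 2147483000 + 1)
}

# Deterministic synthetic DrugZ-format table (labelled synthetic: the real
# screen tables are not shipped with the package).
synthetic_screen_table <- function(n = 500L, seed = 42L) {
  set.seed(seed)
  data.frame(
    GENE = sprintf("GENE%03d", seq_len(n)),
    normZ = rnorm(n),
    fdr_synth = runif(n),
    fdr_supp = runif(n),
    biotype = sample(c("protein_coding", "noncoding"), n, replace = TRUE,
                     prob = c(0.7, 0.3)),
    stringsAsFactors = FALSE
  )
}
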