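#' Count fragments overlapping each gene
#'
#' A fragment is counted for a gene when it overlaps the half-open interval
#' `[start, end)` by at least 1 bp (bedtools-coverage semantics); a fragment
#' spanning a gene boundary still counts once. Fragments overlapping no gene
#' are ignored here but still contribute to `total_fragments`.
#'
#' @param fragments A `FragmentSet`.
#' @param genes A gene table.
#' @return Integer vector of counts, named by `gene_id`.
#' @export
count_fragments_per_gene <- function(fragments, genes) {
  stopifnot(inherits(fragments, "FragmentSet"))
  fr <- fragments$fragments
  counts <- setNames(integer(nrow(genes)), genes$gene_id)
  if (nrow(fr) == 0L) return(counts)
  unknown <- setdiff(unique(fr$chrom), unique(genes$chrom))
  if (length(unknown)) {
    warning(sum(fr$chrom %in% unknown), " fragment(s) on chromosome(s) ",
            paste(unknown, collapse = ", "),
            " absent from the gene table; they overlap no gene",
            call. = FALSE)
  }
  gene_gr <- GRanges(genes$chrom, IRanges(genes$start + 1L, genes$end))
  frag_gr <- GRanges(fr$chrom, IRanges(fr$start + 1L, fr$end))
  # disjoint seqlevel warnings are already covered by the message above
  counts[] <- suppressWarnings(countOverlaps(gene_gr, frag_gr))
  counts
}

#' Normalize fragment counts to reads per million per kilobase
#'
#' Per-gene coverage normalized to reads per sample and gene length:
#' `value = count / (total / 1e6) / (length / 1e3)`.
#'
#' @param counts Integer vector or genes x samples matrix of fragment counts.
#' @param total_fragments Total fragments per sample (scalar or per-column).
#' @param gene_lengths Gene lengths in bp (>= 1).
#' @return Numeric vector or matrix of normalized coverage.
#' @export
normalize_coverage <- function(counts, total_fragments, gene_lengths) {
  if (any(gene_lengths < 1)) stop_("gene lengths must be >= 1")
  if (is.matrix(counts)) {
    if (length(total_fragments) != ncol(counts)) {
      stop_("need one total_fragments per sample column")
    }
    zero <- which(total_fragments <= 0)
    if (length(zero)) {
      nm <- colnames(counts)[zero] %||% as.character(zero)
      stop_("total_fragments is zero for sample(s): ",
            paste(nm, collapse = ", "))
    }
    per_kb <- counts / (gene_lengths / 1e3)
    sweep(per_kb, 2L, total_fragments / 1e6, "/")
  } else {
    if (length(total_fragments) != 1L || total_fragments <= 0) {
      stop_("total_fragments is zero for sample(s): ",
            names(total_fragments) %||% "1")
    }
    counts / (total_fragments / 1e6) / (gene_lengths / 1e3)
  }
}

#' Build a genes-by-samples normalized coverage matrix
#'
#' Counts fragments per gene for every sample and normalizes to reads per
#' million per kilobase.
#'
#' @param fragments_list Named list of `FragmentSet`s (one per sample).
#' @param genes A gene table.
#' @return Numeric matrix, genes x samples.
#' @export
coverage_matrix <- function(fragments_list, genes) {
  stopifnot(length(fragments_list) > 0L)
  counts <- vapply(fragments_list, count_fragments_per_gene,
                   integer(nrow(genes)), genes = genes)
  counts <- matrix(counts, nrow = nrow(genes),
                   dimnames = list(genes$gene_id, names(fragments_list)))
  totals <- vapply(fragments_list, function(f) f$total_fragments, numeric(1L))
  normalize_coverage(counts, totals, genes$length)
}

# per-chromosome fragment coverage as an RleList
fragment_coverage <- function(fragments) {
  fr <- fragments$fragments
  if (nrow(fr) == 0L) return(NULL)
  coverage(GRanges(fr$chrom, IRanges(fr$start + 1L, fr$end)))
}

# Extract per-bp coverage over the 0-based half-open window [s0, e0),
# padding with zeros beyond the covered extent.
extract_coverage <- function(covlist, chrom, s0, e0) {
  width <- e0 - s0
  if (is.null(covlist) || !(chrom %in% names(covlist))) return(numeric(width))
  r <- covlist[[chrom]]
  len <- length(r)
  lo <- max(s0, 0L)
  hi <- min(e0, len)
  core <- if (hi > lo) as.numeric(window(r, start = lo + 1L, end = hi)) else numeric(0L)
  c(numeric(max(0L, lo - s0)), core, numeric(max(0L, e0 - hi)))
}

profile_bins <- function(v, breaks) {
  cs <- c(0, cumsum(v))
  widths <- diff(breaks)
  (cs[breaks[-1L] + 1L] - cs[breaks[-length(breaks)] + 1L]) / widths
}

#' Metagene profile of fragment coverage
#'
#' Scales each gene body to `body_bins` equal-width bins flanked by
#' fixed-width bins, orients profiles 5' to 3' by gene strand, and averages
#' the per-bp coverage (RPM-normalized) over genes. Genes shorter than
#' `body_bins` bp are excluded.
#'
#' @param fragments A `FragmentSet`.
#' @param genes A gene table.
#' @param body_bins Number of scaled gene-body bins.
#' @param flank_bp Flank width upstream and downstream, in bp.
#' @param flank_bin_bp Width of each flank bin (must divide `flank_bp`).
#' @return A `MetageneProfile`: list with `bin_labels`, `values` (mean RPM
#'   per bp per bin) and `n_genes`.
#' @export
metagene_profile <- function(fragments, genes, body_bins = 100L,
                             flank_bp = 3000L, flank_bin_bp = 100L) {
  stopifnot(inherits(fragments, "FragmentSet"))
  if (body_bins < 1L) stop_("body_bins must be >= 1")
  if (flank_bp %% flank_bin_bp != 0L) {
    stop_("flank_bp must be a multiple of flank_bin_bp")
  }
  keep <- genes$length >= body_bins
  if (!all(keep)) {
    message(sum(!keep), " gene(s) shorter than ", body_bins,
            " bp excluded from the metagene")
  }
  g <- genes[keep, , drop = FALSE]
  if (nrow(g) == 0L) stop_("no genes pass the metagene length filter")

  n_flank <- as.integer(flank_bp / flank_bin_bp)
  nbin <- 2L * n_flank + body_bins
  covlist <- fragment_coverage(fragments)
  acc <- numeric(nbin)
  for (i in seq_len(nrow(g))) {
    v <- extract_coverage(covlist, g$chrom[i], g$start[i] - flank_bp,
                          g$end[i] + flank_bp)
    if (g$strand[i] == "-") v <- rev(v)
    L <- g$length[i]
    up <- colMeans(matrix(v[seq_len(flank_bp)], nrow = flank_bin_bp))
    body <- profile_bins(v[flank_bp + seq_len(L)],
                         round(seq(0, L, length.out = body_bins + 1L)))
    down <- colMeans(matrix(v[flank_bp + L + seq_len(flank_bp)],
                            nrow = flank_bin_bp))
    acc <- acc + c(up, body, down)
  }
  vals <- acc / nrow(g)
  if (fragments$total_fragments > 0L) {
    vals <- vals / (fragments$total_fragments / 1e6)
  }
  structure(list(
    bin_labels = c(paste0("up", seq_len(n_flank)),
                   paste0("body", seq_len(body_bins)),
                   paste0("down", seq_len(n_flank))),
    values = vals,
    n_genes = nrow(g),
    body_bins = body_bins, flank_bp = flank_bp, flank_bin_bp = flank_bin_bp
  ), class = "MetageneProfile")
}

#' Fixed-window TSS profile of fragment coverage
#'
#' Bins coverage in a fixed window centered on each TSS (strand oriented),
#' RPM-normalizes and averages over genes.
#'
#' @param fragments A `FragmentSet`.
#' @param genes A gene table.
#' @param window_bp Half-window around the TSS (profile spans +/- window_bp).
#' @param bin_bp Bin width; must divide `window_bp`.
#' @return A `MetageneProfile` whose bins run from -window_bp to +window_bp.
#' @export
tss_profile <- function(fragments, genes, window_bp = 5000L, bin_bp = 100L) {
  stopifnot(inherits(fragments, "FragmentSet"))
  if (window_bp %% bin_bp != 0L) stop_("window_bp must be a multiple of bin_bp")
  if (nrow(genes) == 0L) stop_("no genes supplied")
  nbin <- as.integer(2L * window_bp / bin_bp)
  covlist <- fragment_coverage(fragments)
  tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  acc <- numeric(nbin)
  for (i in seq_len(nrow(genes))) {
    v <- extract_coverage(covlist, genes$chrom[i], tss[i] - window_bp,
                          tss[i] + window_bp)
    if (genes$strand[i] == "-") v <- rev(v)
    acc <- acc + colMeans(matrix(v, nrow = bin_bp))
  }
  vals <- acc / nrow(genes)
  if (fragments$total_fragments > 0L) {
    vals <- vals / (fragments$total_fragments / 1e6)
  }
  centers <- seq(-window_bp + bin_bp / 2, window_bp - bin_bp / 2, by = bin_bp)
  structure(list(bin_labels = as.character(centers), values = vals,
                 n_genes = nrow(genes), window_bp = window_bp,
                 bin_bp = bin_bp),
            class = "MetageneProfile")
}

#' @export
print.MetageneProfile <- function(x, ...) {
  cat("MetageneProfile:", length(x$values), "bins over", x$n_genes,
      "genes; peak", sprintf("%.4g", max(x$values)), "RPM/bp\n")
  invisible(x)
}
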