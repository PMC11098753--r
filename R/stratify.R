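#' Assign genes to quantile groups
#'
#' Splits genes into `k` equal-probability groups of a per-gene quantity
#' (e.g. ATAC accessibility into low/medium/high, or RNAPII occupancy into
#' low / mid-low / mid-high / high). Ties are broken by the stable input
#' order, so group sizes are balanced (differ by at most 1).
#'
#' @param values Per-gene numeric values, in gene-table order.
#' @param k Number of groups (>= 2).
#' @param labels Optional group labels, low to high; defaults to
#'   `low/medium/high` for k = 3 and `low/mid-low/mid-high/high` for k = 4.
#' @param ids Optional gene ids used to name the result.
#' @return A `GeneGroups` list: `group` (ordered factor per gene),
#'   `boundaries` (upper value cut points of groups 1..k-1) and `k`.
#' @export
quantile_groups <- function(values, k, labels = NULL, ids = NULL) {
  if (k < 2L) stop_("k must be >= 2")
  if (length(unique(values)) < k) {
    stop_("fewer than k distinct values; cannot form ", k, " groups")
  }
  n <- length(values)
  if (is.null(labels)) {
    labels <- if (k == 3L) c("low", "medium", "high")
    else if (k == 4L) c("low", "mid-low", "mid-high", "high")
    else paste0("q", seq_len(k))
  }
  if (length(labels) != k) stop_("need exactly k labels")
  sizes <- diff(round(seq(0, n, length.out = k + 1L)))
  ord <- order(values)  # stable: ties keep input (gene_id) order
  grp <- integer(n)
  grp[ord] <- rep(seq_len(k), times = sizes)
  boundaries <- vapply(seq_len(k - 1L), function(i) {
    values[ord[cumsum(sizes)[i]]]
  }, numeric(1L))
  group <- factor(labels[grp], levels = labels, ordered = TRUE)
  if (!is.null(ids)) names(group) <- ids
  structure(list(group = group, boundaries = boundaries, k = k),
            class = "GeneGroups")
}

#' Assign genes to occupancy x accessibility quadrants
#'
#' Thresholds are the medians of RNAPII occupancy and accessibility over the
#' analyzed gene universe; values at or above the median go to the high side.
#'
#' @param covariates Covariate table with `gene_id`, `accessibility`,
#'   `occupancy` (complete and finite).
#' @return Factor named by gene_id with levels
#'   `low_occ.low_acc`, `low_occ.high_acc`, `high_occ.low_acc`,
#'   `high_occ.high_acc`; thresholds in `attr(, "thresholds")`.
#' @export
quadrant_assign <- function(covariates) {
  need <- c("gene_id", "accessibility", "occupancy")
  if (!all(need %in% names(covariates))) {
    stop_("covariates need columns: ", paste(need, collapse = ", "))
  }
  bad <- !is.finite(covariates$accessibility) | !is.finite(covariates$occupancy)
  if (any(bad)) {
    stop_("missing/non-finite covariate for gene(s): ",
          paste(head(covariates$gene_id[bad], 10L), collapse = ", "))
  }
  med_occ <- median(covariates$occupancy)
  med_acc <- median(covariates$accessibility)
  occ <- ifelse(covariates$occupancy >= med_occ, "high_occ", "low_occ")
  acc <- ifelse(covariates$accessibility >= med_acc, "high_acc", "low_acc")
  q <- factor(paste(occ, acc, sep = "."),
              levels = c("low_occ.low_acc", "low_occ.high_acc",
                         "high_occ.low_acc", "high_occ.high_acc"))
  names(q) <- covariates$gene_id
  attr(q, "thresholds") <- c(occupancy = med_occ, accessibility = med_acc)
  q
}

#' Percentage of a gene set in each quadrant
#'
#' @param gene_set Character vector of gene ids (non-empty, all inside the
#'   quadrant-assigned universe).
#' @param quadrants Factor from [quadrant_assign()], named by gene_id.
#' @return data.frame with `quadrant`, `n`, `percentage` (1 decimal).
#' @export
quadrant_percentages <- function(gene_set, quadrants) {
  if (length(gene_set) == 0L) stop_("gene_set is empty")
  missing <- setdiff(gene_set, names(quadrants))
  if (length(missing)) {
    stop_("gene(s) outside the analyzed universe: ",
          paste(head(missing, 10L), collapse = ", "))
  }
  tab <- table(quadrants[gene_set])
  out <- data.frame(quadrant = names(tab), n = as.integer(tab),
                    percentage = round(100 * as.integer(tab) / length(gene_set), 1),
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- attr(quadrants, "thresholds")
  out
}

#' Genomic-feature enrichment of a gene set relative to a background
#'
#' For categorical features (biotype classes) the ratio of the fraction in
#' the set to the fraction in the background; for continuous features (gene
#' length, accessibility, RNAPII occupancy) the ratio of medians. Used to ask
#' what distinguishes e.g. CSB-dependent genes from non-changing genes.
#'
#' @param gene_set,background_set Character vectors of gene ids (non-empty).
#' @param genes Gene table (provides biotype and length).
#' @param covariates Covariate table (provides accessibility and occupancy).
#' @return data.frame with `feature`, `type`, `set_value`,
#'   `background_value`, `ratio`, `undefined` (TRUE when the background
#'   fraction/median is zero and the ratio is therefore undefined).
#' @export
feature_enrichment <- function(gene_set, background_set, genes, covariates) {
  if (length(gene_set) == 0L || length(background_set) == 0L) {
    stop_("gene_set and background_set must be non-empty")
  }
  gidx <- function(ids) match(ids, genes$gene_id)
  cidx <- function(ids) match(ids, covariates$gene_id)
  if (anyNA(gidx(gene_set)) || anyNA(gidx(background_set))) {
    stop_("gene set contains ids absent from the gene table")
  }
  rows <- list()
  bios <- sort(unique(genes$biotype[gidx(c(gene_set, background_set))]))
  for (b in bios) {
    fs <- mean(genes$biotype[gidx(gene_set)] == b)
    fb <- mean(genes$biotype[gidx(background_set)] == b)
    rows[[length(rows) + 1L]] <- data.frame(
      feature = paste0("biotype_", b), type = "categorical",
      set_value = fs, background_value = fb,
      ratio = if (fb > 0) fs / fb else NA_real_, undefined = fb == 0,
      stringsAsFactors = FALSE)
  }
  cont <- list(
    gene_length = list(genes$length, gidx),
    accessibility = list(covariates$accessibility, cidx),
    occupancy = list(covariates$occupancy, cidx)
  )
  for (nm in names(cont)) {
    vals <- cont[[nm]][[1L]]
    ix <- cont[[nm]][[2L]]
    ms <- median(vals[ix(gene_set)])
    mb <- median(vals[ix(background_set)])
    rows[[length(rows) + 1L]] <- data.frame(
      feature = nm, type = "continuous", set_value = ms,
      background_value = mb,
      ratio = if (mb > 0) ms / mb else NA_real_, undefined = mb == 0,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Draw a size-matched control gene set
#'
#' Uniform sample without replacement from a candidate pool (disjoint from
#' the query set), deterministic given the seed. Used to contrast e.g.
#' transcription-dependent genes with a matched group that shows no
#' transcription-dependent repair.
#'
#' @param gene_set Character vector of gene ids.
#' @param candidate_pool Character vector, disjoint from `gene_set`, at least
#'   as large.
#' @param seed Integer seed.
#' @return Character vector of `length(gene_set)` ids from the pool.
#' @export
match_size_control <- function(gene_set, candidate_pool, seed = 1L) {
  if (length(intersect(gene_set, candidate_pool))) {
    stop_("candidate_pool must be disjoint from gene_set")
  }
  if (length(candidate_pool) < length(gene_set)) {
    stop_("candidate_pool smaller than gene_set")
  }
  with_seed(seed, sample(candidate_pool, length(gene_set)))
}
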