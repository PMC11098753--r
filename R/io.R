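#' Read a gene annotation into a gene table
#'
#' Reads gene intervals from BED6, minimal GTF (gene features only) or a
#' plain TSV and returns the validated gene table used by all per-gene
#' statistics. Coordinates are 0-based half-open internally (BED convention);
#' GTF records (1-based inclusive) are converted on read.
#'
#' @param path Path to the annotation file.
#' @param format One of `"BED6"`, `"GTF"`, `"TSV"`. A TSV must carry a header
#'   with columns `gene_id`, `chrom`, `start`, `end`, `strand` and optionally
#'   `biotype`; its coordinates are taken as already 0-based half-open.
#' @param min_gene_length Optional minimum gene length in bp; shorter genes
#'   are dropped (the default keeps every gene).
#'
#' @return A `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`, `length`, validated so that `start < end`, gene ids
#'   are unique and genes on the same chromosome do not overlap.
#' @export
read_gene_table <- function(path, format = c("BED6", "GTF", "TSV"),
                            min_gene_length = NULL) {
  format <- match.arg(toupper(format[1L]), c("BED6", "GTF", "TSV"))
  if (!file.exists(path)) stop_("file not found: ", path)
  genes <- switch(format,
    BED6 = read_genes_bed6(path),
    GTF = read_genes_gtf(path),
    TSV = read_genes_tsv(path)
  )
  if (!is.null(min_gene_length)) {
    genes <- genes[genes$end - genes$start >= min_gene_length, , drop = FALSE]
  }
  as_gene_table(genes)
}

read_genes_bed6 <- function(path) {
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               quote = "", stringsAsFactors = FALSE,
               col.names = c("chrom", "start", "end", "gene_id", "score",
                             "strand"),
               colClasses = c("character", "integer", "integer", "character",
                              "character", "character")),
    error = function(e) stop_("malformed BED6 file '", path, "': ",
                              conditionMessage(e))
  )
  data.frame(gene_id = df$gene_id, chrom = df$chrom, start = df$start,
             end = df$end, strand = df$strand, biotype = "unknown",
             stringsAsFactors = FALSE)
}

read_genes_gtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop_("malformed GTF file '", path,
                                           "': ", conditionMessage(e)))
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    gr <- gr[as.character(gr$type) == "gene"]
  }
  if (length(gr) == 0L) stop_("no gene features found in GTF: ", path)
  ids <- as.character(gr$gene_id)
  if (anyNA(ids)) stop_("GTF gene feature without gene_id attribute")
  bio <- if ("gene_biotype" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$gene_biotype)
  } else {
    rep("unknown", length(gr))
  }
  # collapse multiple records per gene_id to one interval
  df <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # 1-based inclusive -> 0-based
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = ifelse(is.na(bio), "unknown", bio),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$gene_id)) {
    sp <- split(seq_len(nrow(df)), df$gene_id)
    df <- do.call(rbind, lapply(sp, function(i) {
      d <- df[i, , drop = FALSE]
      if (length(unique(d$chrom)) > 1L) {
        stop_("gene ", d$gene_id[1L], " spans multiple chromosomes")
      }
      d$start[1L] <- min(d$start); d$end[1L] <- max(d$end)
      d[1L, , drop = FALSE]
    }))
    rownames(df) <- NULL
  }
  df
}

read_genes_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_("gene TSV missing column(s): ",
                          paste(miss, collapse = ", "))
  if (is.null(df$biotype)) df$biotype <- "unknown"
  df[c("gene_id", "chrom", "start", "end", "strand", "biotype")]
}

# Validate and finalize a gene table (shared by readers and the simulator).
as_gene_table <- function(df) {
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(!(df$start < df$end))
  if (length(bad)) {
    stop_("start >= end for gene record(s) at line(s): ",
          paste(head(bad, 10L), collapse = ", "))
  }
  bad_strand <- which(!df$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stop_("unknown strand symbol '", df$strand[bad_strand[1L]],
          "' at line ", bad_strand[1L])
  }
  if (anyDuplicated(df$gene_id)) {
    stop_("duplicated gene_id: ",
          paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  # non-overlap within chromosome
  for (chr in unique(df$chrom)) {
    d <- df[df$chrom == chr, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L) {
      ov <- which(d$start[-1L] < d$end[-nrow(d)])
      if (length(ov)) {
        pairs <- paste0(d$gene_id[ov], "/", d$gene_id[ov + 1L])
        stop_("overlapping genes on ", chr, ": ",
              paste(head(pairs, 10L), collapse = ", "))
      }
    }
  }
  df$length <- df$end - df$start
  rownames(df) <- NULL
  df
}

#' Read sequenced fragment intervals from a BED file
#'
#' Loads BED3+ fragment intervals into a `FragmentSet`. Input need not be
#' sorted; fragments on chromosomes absent from the gene annotation are
#' retained (they simply never overlap a gene) and flagged when counting.
#'
#' @param path Path to a BED3(+) file (0-based half-open intervals).
#' @return A `FragmentSet`: a list with elements `fragments` (data.frame with
#'   `chrom`, `start`, `end`) and `total_fragments`.
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  if (file.size(path) == 0L) {
    return(fragment_set(data.frame(chrom = character(), start = integer(),
                                   end = integer())))
  }
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               quote = "", stringsAsFactors = FALSE),
    error = function(e) stop_("malformed BED file '", path, "': ",
                              conditionMessage(e))
  )
  if (ncol(df) < 3L) stop_("BED file needs at least 3 columns: ", path)
  frags <- data.frame(chrom = as.character(df[[1L]]),
                      start = as.integer(df[[2L]]),
                      end = as.integer(df[[3L]]),
                      stringsAsFactors = FALSE)
  bad <- which(!(frags$start < frags$end))
  if (length(bad)) {
    stop_("start >= end for fragment(s) at line(s): ",
          paste(head(bad, 10L), collapse = ", "))
  }
  fragment_set(frags)
}

#' Construct a FragmentSet from a data frame of intervals
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return A `FragmentSet` object.
#' @export
fragment_set <- function(fragments) {
  stopifnot(is.data.frame(fragments),
            all(c("chrom", "start", "end") %in% names(fragments)))
  if (nrow(fragments) && any(fragments$start >= fragments$end)) {
    stop_("fragment with start >= end")
  }
  structure(list(fragments = fragments[c("chrom", "start", "end")],
                 total_fragments = nrow(fragments)),
            class = "FragmentSet")
}

#' @export
print.FragmentSet <- function(x, ...) {
  cat("FragmentSet with", x$total_fragments, "fragments on",
      length(unique(x$fragments$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Write a FragmentSet to a BED3 file
#'
#' @param fragments A `FragmentSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  stopifnot(inherits(fragments, "FragmentSet"))
  utils::write.table(fragments$fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a normalized coverage matrix to TSV
#'
#' Writes the genes-by-samples coverage matrix with a `gene_id` column and
#' sample ids as header; round-tripping through [read_coverage_matrix()]
#' reproduces values to full printed precision (15 significant digits).
#'
#' @param matrix Numeric genes x samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_matrix <- function(matrix, path) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop_("coverage matrix must be a numeric matrix")
  }
  if (any(!is.finite(matrix))) stop_("coverage matrix contains non-finite values")
  if (any(matrix < 0)) stop_("coverage matrix contains negative values")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop_("coverage matrix needs gene and sample dimnames")
  }
  df <- data.frame(gene_id = rownames(matrix),
                   format(matrix, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a coverage matrix written by [write_coverage_matrix()]
#'
#' @param path Path to the TSV.
#' @return Numeric genes x samples matrix.
#' @export
read_coverage_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id") stop_("first column must be gene_id")
  m <- as.matrix(df[-1L])
  mode(m) <- "numeric"
  rownames(m) <- df$gene_id
  m
}

#' Read a sample sheet
#'
#' @param path TSV with header columns `sample_id`, `genotype`, `treatment`,
#'   `recovery_h`, `drug`, `replicate`.
#' @return Validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  need <- c("sample_id", "genotype", "treatment", "recovery_h", "drug",
            "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_("sample sheet missing column(s): ",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop_("duplicated sample_id")
  if (!all(df$genotype %in% c("WT", "CSB_KO"))) {
    stop_("genotype must be WT or CSB_KO")
  }
  if (!all(df$drug %in% c("none", "flavopiridol", "MG132"))) {
    stop_("drug must be none, flavopiridol or MG132")
  }
  if (any(df$recovery_h < 0)) stop_("recovery_h must be >= 0")
  if (any(df$replicate < 1)) stop_("replicate index must be >= 1")
  df
}

#' Read a per-gene covariate table (accessibility and RNAPII occupancy)
#'
#' @param path TSV with header columns `gene_id`, `accessibility`,
#'   `occupancy`.
#' @param genes Optional gene table; if given, every gene must have a row.
#' @return Validated data.frame.
#' @export
read_covariate_table <- function(path, genes = NULL) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "accessibility", "occupancy")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_("covariate table missing column(s): ",
                          paste(miss, collapse = ", "))
  if (any(!is.finite(df$accessibility)) || any(!is.finite(df$occupancy))) {
    stop_("covariates must be finite")
  }
  if (any(df$accessibility < 0) || any(df$occupancy < 0)) {
    stop_("covariates must be non-negative")
  }
  if (!is.null(genes)) {
    missing_genes <- setdiff(genes$gene_id, df$gene_id)
    if (length(missing_genes)) {
      stop_("covariates missing for gene(s): ",
            paste(head(missing_genes, 10L), collapse = ", "))
    }
  }
  df
}
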