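#' Load a DrugZ-format CRISPRi screen table
#'
#' Reads per-gene DrugZ output (normalized Z-scores with sensitizer- and
#' suppressor-side FDRs) and maps its columns onto the screen data model.
#'
#' @param path TSV with a header row.
#' @param column_map Named character vector mapping the model fields
#'   `gene_id`, `normZ`, `fdr_sensitizer`, `fdr_suppressor` and optionally
#'   `biotype` to the file's column names. The default matches DrugZ output
#'   (`GENE`, `normZ`, `fdr_synth`, `fdr_supp`).
#' @return data.frame with columns `gene_id`, `normZ`, `fdr_sensitizer`,
#'   `fdr_suppressor`, `biotype` (rows without a biotype column are labelled
#'   `unknown`, with a warning).
#' @export
read_screen_table <- function(path,
                              column_map = c(gene_id = "GENE",
                                             normZ = "normZ",
                                             fdr_sensitizer = "fdr_synth",
                                             fdr_suppressor = "fdr_supp",
                                             biotype = "biotype")) {
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   stringsAsFactors = FALSE)
  need <- c("gene_id", "normZ", "fdr_sensitizer", "fdr_suppressor")
  for (field in need) {
    col <- column_map[[field]]
    if (is.null(col) || !(col %in% names(df))) {
      stop_("screen table missing mapped column for '", field, "'",
            if (!is.null(col)) paste0(" ('", col, "')"))
    }
  }
  out <- data.frame(
    gene_id = as.character(df[[column_map[["gene_id"]]]]),
    normZ = as.numeric(df[[column_map[["normZ"]]]]),
    fdr_sensitizer = as.numeric(df[[column_map[["fdr_sensitizer"]]]]),
    fdr_suppressor = as.numeric(df[[column_map[["fdr_suppressor"]]]]),
    stringsAsFactors = FALSE
  )
  bio_col <- column_map["biotype"]
  if (!is.na(bio_col) && bio_col %in% names(df)) {
    out$biotype <- as.character(df[[bio_col]])
  } else {
    warning("no biotype column; labelling all rows 'unknown'", call. = FALSE)
    out$biotype <- "unknown"
  }
  for (col in c("fdr_sensitizer", "fdr_suppressor")) {
    bad <- which(!is.finite(out[[col]]) | out[[col]] < 0 | out[[col]] > 1)
    if (length(bad)) {
      stop_(col, " outside [0, 1] at row(s): ",
            paste(head(bad, 10L), collapse = ", "))
    }
  }
  if (anyDuplicated(out$gene_id)) stop_("duplicated gene_id in screen table")
  out
}

#' Classify CRISPRi screen hits at an FDR cutoff
#'
#' Sensitizers are genes whose downregulation confers drug sensitivity
#' (sensitizer-side FDR strictly below the cutoff), suppressors confer
#' resistance (suppressor-side FDR below the cutoff). A gene can be neither;
#' it can be both only if both FDR columns pass.
#'
#' @param table Screen table from [read_screen_table()].
#' @param fdr_cutoff FDR cutoff in (0, 1]; the reference analysis used 0.1.
#' @param restrict_biotype Optional biotype (e.g. `"protein_coding"`)
#'   restricting both hit lists.
#' @return List of class `HitSummary`: `sensitizers`, `suppressors` (sorted
#'   gene ids), `n_sensitizers`, `n_suppressors`, `fdr_cutoff`,
#'   `restrict_biotype`.
#' @export
classify_hits <- function(table, fdr_cutoff = 0.1, restrict_biotype = NULL) {
  if (nrow(table) == 0L) stop_("empty screen table")
  if (!is_number(fdr_cutoff) || fdr_cutoff <= 0 || fdr_cutoff > 1) {
    stop_("fdr_cutoff must be in (0, 1]")
  }
  keep <- if (is.null(restrict_biotype)) {
    rep(TRUE, nrow(table))
  } else {
    table$biotype %in% restrict_biotype
  }
  sens <- sort(table$gene_id[keep & table$fdr_sensitizer < fdr_cutoff])
  supp <- sort(table$gene_id[keep & table$fdr_suppressor < fdr_cutoff])
  structure(list(sensitizers = sens, suppressors = supp,
                 n_sensitizers = length(sens), n_suppressors = length(supp),
                 fdr_cutoff = fdr_cutoff,
                 restrict_biotype = restrict_biotype),
            class = "HitSummary")
}

#' @export
print.HitSummary <- function(x, ...) {
  cat(sprintf("Screen hits at FDR < %g%s: %d sensitizers, %d suppressors\n",
              x$fdr_cutoff,
              if (is.null(x$restrict_biotype)) "" else
                paste0(" (", paste(x$restrict_biotype, collapse = ","), ")"),
              x$n_sensitizers, x$n_suppressors))
  invisible(x)
}
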