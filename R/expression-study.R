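#' Construct an expression study
#'
#' Bundles one cohort's log2 expression matrix with its binary response
#' labels. This is the unit of input to the differential-expression stage:
#' each study (or each pairwise comparison extracted from a multi-stratum
#' cohort) contributes one fold-change ranking to the meta-analysis.
#'
#' @param exprs Numeric matrix of log2 expression values, genes in rows
#'   (unique rownames required), samples in columns.
#' @param labels Character or factor vector, one entry per column of
#'   `exprs`, with values `"responder"` or `"nonresponder"`. At least two
#'   samples per group are required.
#' @param study_id Character scalar identifying the cohort.
#' @param comparison Optional tag distinguishing multiple pairwise
#'   comparisons drawn from the same cohort (e.g. responsive vs
#'   nonresponsive and responsive vs low-responsive). Defaults to
#'   `study_id`.
#'
#' @return An object of class `"expression_study"`: a list with elements
#'   `exprs`, `labels` (named by sample), `study_id` and `comparison`.
#' @export
#' @examples
#' m <- matrix(rnorm(40), nrow = 10,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' expression_study(m, c("responder", "responder",
#'                       "nonresponder", "nonresponder"), "demo")
expression_study <- function(exprs, labels, study_id, comparison = NULL) {
  stop_if_not(is.matrix(exprs) && is.numeric(exprs),
              "`exprs` must be a numeric matrix (genes x samples)")
  stop_if_not(all(is.finite(exprs)), "`exprs` must contain only finite values")
  stop_if_not(!is.null(rownames(exprs)) && !anyDuplicated(rownames(exprs)),
              "`exprs` must have unique rownames (gene ids)")
  labels <- as.character(labels)
  stop_if_not(length(labels) == ncol(exprs),
              "`labels` must have one entry per sample (column)")
  stop_if_not(all(labels %in% c("responder", "nonresponder")),
              "labels must be 'responder' or 'nonresponder'")
  if (is.null(colnames(exprs))) {
    colnames(exprs) <- paste0("sample", seq_len(ncol(exprs)))
  }
  n_r <- sum(labels == "responder")
  n_n <- sum(labels == "nonresponder")
  stop_if_not(n_r >= 2 && n_n >= 2,
              "each response group needs >= 2 samples (got %d responders, %d nonresponders)",
              n_r, n_n)
  structure(
    list(exprs = exprs,
         labels = setNames(labels, colnames(exprs)),
         study_id = as.character(study_id),
         comparison = as.character(comparison %||% study_id)),
    class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("Expression study '%s' (comparison '%s')\n", x$study_id, x$comparison))
  cat(sprintf("  %d genes x %d samples (%d responders, %d nonresponders)\n",
              nrow(x$exprs), ncol(x$exprs),
              sum(x$labels == "responder"), sum(x$labels == "nonresponder")))
  invisible(x)
}

#' Read an expression study from TSV files
#'
#' `matrix_path` must be a TSV with gene ids in the first column and one
#' column per sample; `labels_path` a two-column TSV (sample, label) with
#' labels `responder`/`nonresponder`.
#'
#' @param matrix_path,labels_path Paths to the matrix and label TSVs.
#' @param study_id Study identifier; defaults to the matrix file name.
#' @inheritParams expression_study
#' @return An [expression_study()] object.
#' @export
read_study_tsv <- function(matrix_path, labels_path,
                           study_id = sub("\\.[^.]*$", "", basename(matrix_path)),
                           comparison = NULL) {
  m <- read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(m[[1L]])
  exprs <- as.matrix(m[, -1L, drop = FALSE])
  rownames(exprs) <- genes
  lab <- read.delim(labels_path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if_not(ncol(lab) >= 2, "labels file needs columns: sample, label")
  labels <- setNames(as.character(lab[[2L]]), as.character(lab[[1L]]))
  stop_if_not(all(colnames(exprs) %in% names(labels)),
              "every sample column must appear in the labels file")
  expression_study(exprs, labels[colnames(exprs)], study_id, comparison)
}

#' Write an expression study to TSV files
#'
#' Writes `<prefix>_matrix.tsv` (gene column + one column per sample) and
#' `<prefix>_labels.tsv` (sample, label).
#'
#' @param study An [expression_study()] object.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix; defaults to the study id.
#' @return Invisibly, the two file paths.
#' @export
write_study_tsv <- function(study, dir, prefix = study$study_id) {
  stop_if_not(inherits(study, "expression_study"), "`study` must be an expression_study")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mp <- file.path(dir, paste0(prefix, "_matrix.tsv"))
  lp <- file.path(dir, paste0(prefix, "_labels.tsv"))
  out <- data.frame(gene = rownames(study$exprs), study$exprs,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- data.frame(sample = names(study$labels), label = unname(study$labels),
                    stringsAsFactors = FALSE)
  write.table(lab, lp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix = mp, labels = lp))
}
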