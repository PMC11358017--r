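#' Score a gene signature per sample
#'
#' Mean of within-cohort z-scored expression over the signature genes
#' present in the matrix: each gene is standardized across samples
#' (variance floor for constant genes, which then contribute 0), and the
#' per-sample score is the average over signature genes. By construction
#' each signature's scores average to ~0 over the cohort.
#'
#' @param study An [expression_study()] object or a plain numeric matrix
#'   (genes x samples).
#' @param genes Character vector of signature gene ids; at least one must
#'   be present in the matrix.
#' @return Named numeric vector of per-sample scores with attributes
#'   `n_used` and `n_missing` (signature genes absent from the matrix).
#' @export
score_signature <- function(study, genes) {
  m <- if (inherits(study, "expression_study")) study$exprs else study
  stop_if_not(is.matrix(m) && is.numeric(m), "need a numeric expression matrix")
  genes <- unique(as.character(genes))
  present <- intersect(genes, rownames(m))
  stop_if_not(length(present) >= 1,
              "no signature gene is present in the expression matrix")
  sub <- m[present, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- sqrt(row_vars(sub))
  sdv[sdv < 1e-12] <- Inf  # constant genes contribute a z-score of 0
  z <- (sub - mu) / sdv
  structure(colMeans(z), n_used = length(present),
            n_missing = length(genes) - length(present))
}

#' Dichotomize a cohort on two signature scores
#'
#' Median-split stratification: stratum `a_high_b_low` contains samples
#' with signature-A score strictly above the cohort median of A *and*
#' signature-B score strictly below the median of B; `a_low_b_high` is
#' the converse; all other samples (including median ties) are excluded,
#' which is why the two strata may be unequal in size.
#'
#' @param score_a,score_b Named numeric score vectors over the same
#'   samples (as returned by [score_signature()]).
#' @param labels Length-2 character vector naming the two strata.
#' @return data.frame (`sample`, `stratum`) where `stratum` is a factor
#'   with levels `labels[1]`, `labels[2]`, `"excluded"`.
#' @export
dichotomize <- function(score_a, score_b,
                        labels = c("a_high_b_low", "a_low_b_high")) {
  stop_if_not(length(score_a) == length(score_b),
              "score vectors must cover the same samples")
  stop_if_not(length(score_a) >= 4, "need >= 4 samples to dichotomize")
  if (!is.null(names(score_a)) && !is.null(names(score_b))) {
    stop_if_not(setequal(names(score_a), names(score_b)),
                "score vectors must cover the same samples")
    score_b <- score_b[names(score_a)]
  }
  ma <- median(score_a)
  mb <- median(score_b)
  stratum <- rep("excluded", length(score_a))
  stratum[score_a > ma & score_b < mb] <- labels[1]
  stratum[score_a < ma & score_b > mb] <- labels[2]
  data.frame(sample = names(score_a) %||% seq_along(score_a),
             stratum = factor(stratum, levels = c(labels, "excluded")),
             stringsAsFactors = FALSE)
}

#' Compare one gene's expression between two strata
#'
#' Unpaired, two-tailed pooled-variance Student's t-test of a single
#' gene's expression between the two (non-excluded) strata.
#'
#' @param x Named numeric vector of one gene's expression per sample.
#' @param strata A [dichotomize()] result (or any data.frame with
#'   `sample` and `stratum` whose first two factor levels are the groups).
#' @return List with `t`, `df`, `p_two`, `n` (per-group sizes) and
#'   `means` (per-group means).
#' @export
compare_groups <- function(x, strata) {
  stop_if_not(is.data.frame(strata) &&
                all(c("sample", "stratum") %in% names(strata)),
              "`strata` needs columns `sample` and `stratum`")
  lev <- levels(factor(strata$stratum))
  lev <- setdiff(lev, "excluded")[1:2]
  g1 <- strata$sample[strata$stratum == lev[1]]
  g2 <- strata$sample[strata$stratum == lev[2]]
  if (!is.null(names(x))) {
    x1 <- x[as.character(g1)]
    x2 <- x[as.character(g2)]
  } else {
    x1 <- x[strata$stratum == lev[1]]
    x2 <- x[strata$stratum == lev[2]]
  }
  stop_if_not(length(x1) >= 2 && length(x2) >= 2,
              "each stratum needs >= 2 samples")
  if (sd(c(x1, x2)) < 1e-12) {  # identical groups: no evidence either way
    return(list(t = 0, df = length(x1) + length(x2) - 2, p_two = 1,
                n = c(length(x1), length(x2)),
                means = c(mean(x1), mean(x2))))
  }
  tt <- t.test(x1, x2, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_two = tt$p.value, n = c(length(x1), length(x2)),
       means = c(mean(x1), mean(x2)))
}

#' Correlate per-cell-type mean expression across datasets
#'
#' Treats datasets as observations: for entries `x = (gene, cell type)`
#' and `y = (gene, cell type)`, correlates the per-dataset average
#' expression of `x` against that of `y` over the datasets where both are
#' present (pairwise-complete), e.g. CDA in cancer cells versus P2RY6 in
#' macrophages across 16 single-cell atlases.
#'
#' @param table Long data.frame with columns `dataset`, `gene`,
#'   `cell_type`, `mean_expr` (missing combinations simply absent).
#' @param x,y Either `"GENE:celltype"` strings or length-2 character
#'   vectors `c(gene, cell_type)`.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `r`, `p` (two-sided), `n` (datasets used) and
#'   `method`.
#' @export
celltype_mean_correlation <- function(table, x, y,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  need <- c("dataset", "gene", "cell_type", "mean_expr")
  stop_if_not(is.data.frame(table) && all(need %in% names(table)),
              "`table` needs columns dataset, gene, cell_type, mean_expr")
  parse_key <- function(k) {
    if (length(k) == 1) k <- strsplit(k, ":", fixed = TRUE)[[1]]
    stop_if_not(length(k) == 2, "entries must be 'GENE:celltype' or c(gene, cell_type)")
    k
  }
  x <- parse_key(x)
  y <- parse_key(y)
  pick <- function(k) {
    sel <- table$gene == k[1] & table$cell_type == k[2]
    setNames(table$mean_expr[sel], table$dataset[sel])
  }
  vx <- pick(x)
  vy <- pick(y)
  ds <- intersect(names(vx)[is.finite(vx)], names(vy)[is.finite(vy)])
  stop_if_not(length(ds) >= 3,
              "need >= 3 datasets with both entries present (got %d)", length(ds))
  ct <- cor.test(vx[ds], vy[ds], method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ds),
       method = method)
}

#' Dot-plot summary statistics per gene and group
#'
#' For each gene: group means are standard-scaled to `[0, 1]` by min-max
#' over the groups (color channel of a dot plot) and the fraction of
#' samples with expression above `threshold` is reported (dot size). With
#' a single group, or when all group means coincide, the scaled mean is 1
#' by convention (degenerate scaling).
#'
#' @param study An [expression_study()] object or numeric matrix.
#' @param genes Genes to summarize (must be rows of the matrix).
#' @param groups Factor/character vector assigning each sample (column)
#'   to a group; must partition the samples.
#' @param threshold Expression level above which a sample counts as
#'   expressing (default 0).
#' @return data.frame with columns `group`, `gene`, `mean_expr`,
#'   `scaled_mean`, `fraction_expressing`.
#' @export
dotplot_summary <- function(study, genes, groups, threshold = 0) {
  m <- if (inherits(study, "expression_study")) study$exprs else study
  stop_if_not(all(genes %in% rownames(m)), "all `genes` must be in the matrix")
  stop_if_not(length(groups) == ncol(m), "`groups` must label every sample")
  stop_if_not(!anyNA(groups), "`groups` must partition the samples (no NA)")
  groups <- factor(groups)
  out <- expand.grid(group = levels(groups), gene = genes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean_expr <- NA_real_
  out$scaled_mean <- NA_real_
  out$fraction_expressing <- NA_real_
  for (g in genes) {
    x <- m[g, ]
    mu <- tapply(x, groups, mean)
    fr <- tapply(x > threshold, groups, mean)
    rng <- range(mu)
    scaled <- if (diff(rng) < 1e-12) rep(1, length(mu)) else
      (mu - rng[1]) / diff(rng)
    sel <- out$gene == g
    idx <- match(out$group[sel], names(mu))
    out$mean_expr[sel] <- mu[idx]
    out$scaled_mean[sel] <- scaled[idx]
    out$fraction_expressing[sel] <- fr[idx]
  }
  out[, c("group", "gene", "mean_expr", "scaled_mean", "fraction_expressing")]
}
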