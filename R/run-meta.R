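#' Cross-cohort rank-product meta-analysis
#'
#' Orchestrates the full pipeline over a set of responder/non-responder
#' cohorts: per-comparison differential expression, fold-change ranking
#' (rank 1 = most up-regulated in non-responders), rank-product
#' combination, rank-product p-values (gamma approximation, exact
#' enumeration or permutation), Benjamini-Hochberg adjustment, one-sided
#' Fisher combination of the per-study upper-tail p-values, and the
#' metabolic gene-set filter with final re-ranking.
#'
#' Two p-value routes are reported side by side: the rank-product p with
#' BH adjustment (`p_rp`, `p_adj`) and the Fisher combination of
#' one-tailed moderated-t p-values (`fisher_X`, `p_fisher`). The headline
#' ordering (`meta_rank`) follows the rank product `rho`.
#'
#' @param studies List of [expression_study()] objects (>= 2 comparisons).
#' @param metabolic Character vector of metabolic gene ids (or a gene-set
#'   list from [read_gmt()], flattened). `NULL` skips the filter (the
#'   full universe is ranked).
#' @param method Per-comparison statistic: `"moderated"` (empirical-Bayes
#'   moderated t, the default) or `"welch"`.
#' @param pmethod Rank-product p-value method: `"gamma"` (default),
#'   `"exact"` (enumeration; only feasible for tiny universes) or
#'   `"perm"` (Monte-Carlo with `B` draws).
#' @param min_studies Minimum number of comparisons a gene must appear in
#'   (default: all).
#' @param filter_before_bh If `TRUE`, restrict to metabolic genes before
#'   BH adjustment instead of after (default `FALSE`: the filter is
#'   applied to the adjusted results).
#' @param B Permutation draws per gene when `pmethod = "perm"`.
#' @param eps Floor for zero one-tailed p-values entering the Fisher
#'   combination.
#' @param seed Seed used by the permutation method.
#' @return An object of class `"rank_meta"`: a list with
#'   \describe{
#'     \item{table}{the metabolic-filtered table, ordered by `meta_rank`
#'       (equal to the full table if no filter was supplied);}
#'     \item{full_table}{per-gene statistics on the whole universe:
#'       `gene`, `k`, per-comparison ranks, `raw_product`, `rho`, `p_rp`,
#'       `p_adj`, `fisher_X`, `fisher_df`, `p_fisher`, `is_metabolic`;}
#'     \item{comparisons}{list of per-comparison `comparison_result`s;}
#'     \item{manifest}{run metadata: settings, universe sizes, config
#'       hash, package version.}
#'   }
#' @export
run_meta <- function(studies, metabolic = NULL,
                     method = c("moderated", "welch"),
                     pmethod = c("gamma", "exact", "perm"),
                     min_studies = NULL, filter_before_bh = FALSE,
                     B = 10000, eps = 1e-300, seed = 1L) {
  method <- match.arg(method)
  pmethod <- match.arg(pmethod)
  stop_if_not(is.list(studies) && length(studies) >= 2,
              "meta-analysis needs >= 2 comparisons")
  stop_if_not(all(vapply(studies, inherits, TRUE, "expression_study")),
              "`studies` must be a list of expression_study objects")
  if (is.list(metabolic) && !is.data.frame(metabolic)) {
    metabolic <- unlist(metabolic, use.names = FALSE)
  }

  comparisons <- lapply(studies, function(s) {
    if (method == "moderated") moderated_t(s) else welch_t(s)
  })
  rank_tables <- lapply(comparisons, rank_by_lfc)
  rp <- rank_product(rank_tables, min_studies = min_studies)
  sizes <- attr(rp, "sizes")
  rank_cols <- paste0("rank_", names(sizes))
  rk <- as.matrix(rp[, rank_cols, drop = FALSE])

  p_rp <- switch(pmethod,
    gamma = rp_pvalue_gamma(rk, sizes),
    exact = vapply(seq_len(nrow(rp)), function(i) {
      ok <- !is.na(rk[i, ])
      rp_pvalue_exact(rp$raw_product[i], sizes[ok])
    }, 0),
    perm = vapply(seq_len(nrow(rp)), function(i) {
      ok <- !is.na(rk[i, ])
      rp_pvalue_permutation(rp$rho[i], sizes[ok], B = B,
                            seed = seed + i)$p
    }, 0))

  # one-tailed p per comparison, aligned to the rank-product gene list
  p_one <- matrix(NA_real_, nrow = nrow(rp), ncol = length(comparisons),
                  dimnames = list(rp$gene, NULL))
  for (i in seq_along(comparisons)) {
    cmp <- comparisons[[i]]
    idx <- match(cmp$gene, rp$gene)
    keep <- !is.na(idx)
    p_one[idx[keep], i] <- cmp$p_one_up[keep]
  }
  fisher <- t(apply(p_one, 1, function(p) {
    f <- fisher_combine(p[!is.na(p)], eps = eps)
    c(f$X, f$df, f$p)
  }))

  full <- rp
  full$p_rp <- p_rp
  full$is_metabolic <- if (is.null(metabolic)) TRUE else full$gene %in% metabolic
  if (filter_before_bh) {
    full$p_adj <- NA_real_
    full$p_adj[full$is_metabolic] <- bh_adjust(p_rp[full$is_metabolic])
  } else {
    full$p_adj <- bh_adjust(p_rp)
  }
  full$fisher_X <- fisher[, 1]
  full$fisher_df <- as.integer(fisher[, 2])
  full$p_fisher <- fisher[, 3]
  full <- full[, c("gene", "k", rank_cols, "raw_product", "rho", "p_rp",
                   "p_adj", "fisher_X", "fisher_df", "p_fisher",
                   "is_metabolic")]

  table <- filter_and_rank_metabolic(full, full$gene[full$is_metabolic])

  cfg <- list(method = method, pmethod = pmethod,
              min_studies = min_studies %||% length(comparisons),
              filter_before_bh = filter_before_bh, B = B, eps = eps,
              seed = seed, sizes = as.list(sizes),
              n_metabolic = sum(full$is_metabolic))
  manifest <- c(cfg, list(config_hash = config_hash(cfg),
                          package_version = as.character(
                            utils::packageVersion("resistrank"))))

  structure(list(table = table, full_table = full,
                 comparisons = comparisons, manifest = manifest),
            class = "rank_meta")
}

# md5 of the deparsed settings list (written via a temp file so no extra
# dependency is needed for hashing)
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg), f)
  unname(tools::md5sum(f))
}

#' @export
print.rank_meta <- function(x, n = 10, ...) {
  m <- x$manifest
  cat(sprintf("Rank-product meta-analysis: %d comparisons, %d genes (%d after metabolic filter)\n",
              length(x$comparisons), nrow(x$full_table), nrow(x$table)))
  cat(sprintf("  statistic: %s t; p-values: %s; filter %s BH\n",
              m$method, m$pmethod,
              if (m$filter_before_bh) "before" else "after"))
  cat("Top genes:\n")
  cols <- c("meta_rank", "gene", "k", "rho", "p_rp", "p_adj", "p_fisher")
  print(head(x$table[, cols], n), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.rank_meta <- function(object, alpha = 0.05, ...) {
  tab <- object$table
  out <- list(
    n_comparisons = length(object$comparisons),
    n_genes = nrow(object$full_table),
    n_metabolic = nrow(tab),
    n_signif_bh = sum(tab$p_adj <= alpha, na.rm = TRUE),
    n_signif_fisher = sum(bh_adjust(tab$p_fisher) <= alpha),
    alpha = alpha,
    top = head(tab, 10))
  class(out) <- "summary.rank_meta"
  out
}

#' @export
print.summary.rank_meta <- function(x, ...) {
  cat(sprintf("%d comparisons over %d genes; %d metabolic genes ranked\n",
              x$n_comparisons, x$n_genes, x$n_metabolic))
  cat(sprintf("  BH-adjusted rank-product p <= %.3g: %d genes\n",
              x$alpha, x$n_signif_bh))
  cat(sprintf("  BH-adjusted Fisher p <= %.3g:       %d genes\n",
              x$alpha, x$n_signif_fisher))
  cat("Top of the ranking:\n")
  cols <- c("meta_rank", "gene", "rho", "p_rp", "p_adj", "p_fisher")
  print(x$top[, cols], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a meta-analysis result to TSV (plus a JSON run manifest)
#'
#' @param meta A `"rank_meta"` object from [run_meta()].
#' @param path Output TSV path; the manifest is written next to it as
#'   `<path>.manifest.json`.
#' @param full If `TRUE`, write the full-universe table instead of the
#'   metabolic-filtered one.
#' @return Invisibly, `path`.
#' @export
write_meta_tsv <- function(meta, path, full = FALSE) {
  stop_if_not(inherits(meta, "rank_meta"), "`meta` must come from run_meta()")
  tab <- if (full) meta$full_table else meta$table
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(meta$manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
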