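#' Rank genes by log2 fold change within one comparison
#'
#' The most up-regulated gene in non-responders receives rank 1 and the
#' most down-regulated the highest rank; ties receive the average of the
#' tied positions.
#'
#' @param comparison A `comparison_result` from [moderated_t()] /
#'   [welch_t()], or any data.frame with columns `gene` and `log2fc`.
#' @return A data.frame (`gene`, `rank`) of class `"rank_table"` with
#'   attributes `n` (number of ranked genes) and `comparison_id`.
#' @export
rank_by_lfc <- function(comparison) {
  stop_if_not(is.data.frame(comparison) &&
                all(c("gene", "log2fc") %in% names(comparison)),
              "`comparison` needs columns `gene` and `log2fc`")
  stop_if_not(nrow(comparison) > 0, "empty comparison")
  stop_if_not(all(is.finite(comparison$log2fc)), "log2fc must be finite")
  r <- rank(-comparison$log2fc, ties.method = "average")
  structure(data.frame(gene = comparison$gene, rank = r,
                       stringsAsFactors = FALSE),
            n = nrow(comparison),
            comparison_id = attr(comparison, "comparison_id") %||% NA_character_,
            class = c("rank_table", "data.frame"))
}

#' Combine per-comparison ranks into rank products
#'
#' For gene `g` present in `k_g` comparisons with ranks `r_i` out of `n_i`
#' ranked genes, the statistic is the relative geometric mean
#' `rho_g = (prod r_i / n_i)^(1/k_g)`; the raw integer product
#' `prod r_i` is also reported and is the statistic of the enumeration
#' oracle [rp_pvalue_exact()]. Small values indicate consistent
#' up-regulation in non-responders across studies.
#'
#' @param rank_tables List of [rank_by_lfc()] outputs.
#' @param min_studies Minimum number of comparisons a gene must appear in
#'   to be retained; default: all comparisons.
#' @return data.frame of class `"rank_product_table"` with columns `gene`,
#'   `k`, per-comparison rank columns `rank_<id>`, `raw_product`, `rho`;
#'   attribute `sizes` holds the per-comparison universe sizes `n_i`.
#' @export
rank_product <- function(rank_tables, min_studies = NULL) {
  stop_if_not(is.list(rank_tables) && length(rank_tables) >= 1,
              "need at least one rank table")
  k <- length(rank_tables)
  min_studies <- min_studies %||% k
  stop_if_not(is_count(min_studies) && min_studies <= k,
              "`min_studies` must be in [1, number of comparisons]")
  ids <- vapply(seq_len(k), function(i) {
    id <- attr(rank_tables[[i]], "comparison_id")
    if (is.null(id) || is.na(id)) paste0("cmp", i) else id
  }, character(1))
  ids <- make.unique(ids)
  genes <- sort(unique(unlist(lapply(rank_tables, `[[`, "gene"))))
  rk <- matrix(NA_real_, nrow = length(genes), ncol = k,
               dimnames = list(genes, ids))
  n <- integer(k)
  for (i in seq_len(k)) {
    tab <- rank_tables[[i]]
    n[i] <- attr(tab, "n")
    rk[tab$gene, i] <- tab$rank
  }
  kg <- rowSums(!is.na(rk))
  keep <- kg >= min_studies
  stop_if_not(any(keep), "no gene is present in >= min_studies comparisons")
  rk <- rk[keep, , drop = FALSE]
  kg <- kg[keep]
  rel <- sweep(rk, 2, n, "/")
  rho <- exp(rowSums(log(rel), na.rm = TRUE) / kg)
  raw <- apply(rk, 1, prod, na.rm = TRUE)  # exact for integer ranks
  out <- data.frame(gene = rownames(rk), k = kg, rk, raw_product = raw,
                    rho = rho, stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[seq_len(k) + 2L] <- paste0("rank_", ids)
  rownames(out) <- NULL
  structure(out, sizes = setNames(n, ids),
            class = c("rank_product_table", "data.frame"))
}

#' Exact rank-product p-value by enumeration
#'
#' The exact null probability, under independent uniform integer ranks
#' `r_i` on `[1, n_i]`, that the raw product `prod r_i` is at most the
#' observed value. Computed by a recursion over comparisons that sums the
#' truncated counts without materializing the tuple grid. This is the
#' reference the gamma approximation is validated against.
#'
#' @param raw_product Observed integer rank product.
#' @param n Vector of per-comparison universe sizes `n_i`.
#' @param budget Maximum number of rank tuples `prod(n)` the enumeration
#'   will take on (default 1e7); beyond it, use [rp_pvalue_gamma()] or
#'   [rp_pvalue_permutation()].
#' @return Exact p-value in `(0, 1]`.
#' @export
#' @examples
#' rp_pvalue_exact(2, c(4, 4))  # 3/16: tuples (1,1), (1,2), (2,1)
rp_pvalue_exact <- function(raw_product, n, budget = 1e7) {
  stop_if_not(length(n) >= 1 && all(n >= 1) && all(n == round(n)),
              "`n` must be positive integers")
  stop_if_not(length(raw_product) == 1 && raw_product >= 1,
              "`raw_product` must be >= 1")
  stop_if_not(abs(raw_product - round(raw_product)) < 1e-8,
              paste("`raw_product` is not an integer (tied ranks?);",
                    "use rp_pvalue_gamma() or rp_pvalue_permutation()"))
  stop_if_not(prod(n) <= budget,
              paste("enumeration over %.3g tuples exceeds the budget (%.3g);",
                    "use rp_pvalue_gamma() or rp_pvalue_permutation()"),
              prod(n), budget)
  P <- round(raw_product)
  k <- length(n)
  count <- function(i, bound) {
    if (bound < 1) return(0)
    if (i == k) return(min(n[k], bound))
    s <- 0
    for (r in seq_len(min(n[i], bound))) s <- s + count(i + 1L, bound %/% r)
    s
  }
  count(1L, P) / prod(n)
}

#' Gamma approximation to the rank-product p-value
#'
#' In the continuous limit, `-sum(log(r_i/n_i))` is a sum of `k` standard
#' exponentials, i.e. Gamma(k, 1); the upper tail at the observed value
#' approximates the rank-product p-value. The half-offset `(r - 1/2)/n`
#' is the module's discreteness correction (a midpoint rule on the rank
#' lattice). For `k = 1` no approximation is needed and the exact uniform
#' tail `r/n` is returned. Accuracy grows with the universe size: the
#' approximation error is of order `1/n`, negligible at genomic `n`, while
#' for very small universes the discrete null is lumpy and
#' [rp_pvalue_exact()] should be preferred.
#'
#' @param ranks Vector of per-comparison ranks for one gene (`NA` allowed
#'   for comparisons the gene is missing from), or a matrix with genes in
#'   rows for vectorized use.
#' @param n Per-comparison universe sizes, recycled against the columns of
#'   `ranks`.
#' @return Approximate p-value(s) in `(0, 1]`.
#' @export
rp_pvalue_gamma <- function(ranks, n) {
  if (!is.matrix(ranks)) ranks <- matrix(ranks, nrow = 1)
  n <- rep_len(n, ncol(ranks))
  nm <- matrix(n, nrow = nrow(ranks), ncol = ncol(ranks), byrow = TRUE)
  ok <- !is.na(ranks)
  stop_if_not(all(ranks[ok] >= 1 & ranks[ok] <= nm[ok]),
              "ranks must lie in [1, n]")
  k <- rowSums(ok)
  stop_if_not(all(k >= 1), "each gene needs at least one rank")
  tstat <- -rowSums(log((ranks - 0.5) / nm), na.rm = TRUE)
  p <- pgamma(tstat, shape = k, rate = 1, lower.tail = FALSE)
  if (any(k == 1)) {
    one <- which(k == 1)
    idx <- max.col(ok[one, , drop = FALSE], ties.method = "first")
    p[one] <- ranks[cbind(one, idx)] / nm[cbind(one, idx)]
  }
  pmin(1, p)
}

#' Permutation p-value for the rank product
#'
#' Monte-Carlo reference: draws `B` null tuples of independent uniform
#' integer ranks, computes their relative geometric-mean rank product, and
#' reports `p = (1 + #[rho* <= rho]) / (B + 1)` with its binomial standard
#' error. Serves as fallback and as a validation oracle for the gamma
#' approximation when enumeration is infeasible.
#'
#' @param rho Observed relative geometric-mean rank product.
#' @param n Per-comparison universe sizes.
#' @param B Number of Monte-Carlo draws (>= 1000).
#' @param seed Integer RNG seed.
#' @return List with elements `p` and `se`.
#' @export
rp_pvalue_permutation <- function(rho, n, B = 10000, seed = 1L) {
  stop_if_not(length(rho) == 1 && rho > 0 && rho <= 1, "`rho` must be in (0, 1]")
  stop_if_not(is_count(B) && B >= 1000, "`B` must be an integer >= 1000")
  k <- length(n)
  with_seed(seed, {
    lp <- matrix(0, nrow = B, ncol = k)
    for (i in seq_len(k)) {
      lp[, i] <- log(sample.int(n[i], B, replace = TRUE) / n[i])
    }
    rho_null <- exp(rowSums(lp) / k)
    p <- (1 + sum(rho_null <= rho + 1e-12)) / (B + 1)
    list(p = p, se = sqrt(p * (1 - p) / B))
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (with the usual monotonicity
#' enforcement), delegated to `stats::p.adjust(method = "BH")` after
#' validating that all inputs lie in `(0, 1]`.
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @return Vector of BH-adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stop_if_not(is.numeric(p) && length(p) >= 1, "`p` must be a numeric vector")
  stop_if_not(all(is.finite(p)) && all(p > 0) && all(p <= 1),
              "p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Fisher's combined probability test (one sided)
#'
#' Combines independent one-tailed p-values across studies:
#' `X = -2 * sum(log(p_i))` is chi-squared with `2k` degrees of freedom
#' under the null. Zeros are floored at `eps` and flagged rather than
#' erroring.
#'
#' @param p_one Vector of one-tailed p-values (one per study).
#' @param eps Floor applied to zero p-values (default 1e-300).
#' @return List with `X` (statistic), `df` (`2k`), `p` (combined upper
#'   tail) and `floored` (TRUE if any input was floored).
#' @export
#' @examples
#' fisher_combine(rep(0.05, 4))  # X = 23.97, df = 8
fisher_combine <- function(p_one, eps = 1e-300) {
  stop_if_not(is.numeric(p_one) && length(p_one) >= 1,
              "`p_one` must be a numeric vector")
  stop_if_not(all(is.finite(p_one)) && all(p_one >= 0) && all(p_one <= 1),
              "p-values must lie in [0, 1]")
  floored <- any(p_one <= 0)
  p_one <- pmax(p_one, eps)
  X <- -2 * sum(log(p_one))
  df <- 2L * length(p_one)
  list(X = X, df = df, p = pchisq(X, df, lower.tail = FALSE), floored = floored)
}

#' Restrict a meta-analysis table to metabolic genes and re-rank
#'
#' Applies the metabolic-gene filter *after* the meta-analysis statistics
#' have been computed on the full gene universe: rows are restricted to
#' the gene set and the final meta-rank is re-assigned 1..m by ascending
#' rank product; p-values are not recomputed.
#'
#' @param meta data.frame with at least columns `gene` and `rho` (as
#'   produced inside [run_meta()]).
#' @param metabolic Character vector of metabolic gene ids (or a
#'   single-element list as returned by [read_gmt()]).
#' @return The filtered table with a `meta_rank` column (1 = strongest
#'   resistance association).
#' @export
filter_and_rank_metabolic <- function(meta, metabolic) {
  if (is.list(metabolic) && !is.data.frame(metabolic)) {
    metabolic <- unlist(metabolic, use.names = FALSE)
  }
  stop_if_not(is.data.frame(meta) && all(c("gene", "rho") %in% names(meta)),
              "`meta` needs columns `gene` and `rho`")
  keep <- meta$gene %in% metabolic
  stop_if_not(any(keep), "no metabolic gene is present in the meta table")
  out <- meta[keep, , drop = FALSE]
  ord <- order(out$rho, out$gene)
  out$meta_rank <- NA_integer_
  out$meta_rank[ord] <- seq_len(nrow(out))
  out <- out[order(out$meta_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
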