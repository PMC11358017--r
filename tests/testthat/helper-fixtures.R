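# Small builders shared across test files.

# A study with explicit per-group values for a handful of genes:
# `responder` and `nonresponder` are matrices/vectors of group values,
# rows = genes.
make_study <- function(responder, nonresponder, study_id = "s1") {
  responder <- rbind(responder)
  nonresponder <- rbind(nonresponder)
  genes <- rownames(responder) %||% paste0("g", seq_len(nrow(responder)))
  m <- cbind(responder, nonresponder)
  rownames(m) <- genes
  colnames(m) <- paste0("smp", seq_len(ncol(m)))
  expression_study(m, rep(c("responder", "nonresponder"),
                          c(ncol(responder), ncol(nonresponder))), study_id)
}

# Random null study: G genes, n per arm, N(mean, 1) everywhere.
null_study <- function(G, n = 5, seed = 1, mean = 5, study_id = "null") {
  set.seed(seed)
  m <- matrix(rnorm(G * 2 * n, mean), nrow = G,
              dimnames = list(paste0("g", seq_len(G)),
                              paste0("smp", seq_len(2 * n))))
  expression_study(m, rep(c("responder", "nonresponder"), each = n), study_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive gamma-vs-exact comparison over all rank tuples for one
# universe-size vector; returns the max absolute deviation.
max_gamma_exact_error <- function(n) {
  grid <- as.matrix(expand.grid(lapply(n, seq_len)))
  errs <- apply(grid, 1, function(r) {
    abs(rp_pvalue_exact(prod(r), n) - rp_pvalue_gamma(r, n))
  })
  max(errs)
}
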