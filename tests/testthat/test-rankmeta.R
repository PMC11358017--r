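cmp_from_lfc <- function(lfc, id = "c1") {
  structure(data.frame(gene = names(lfc) %||% character(0),
                       log2fc = unname(lfc), stringsAsFactors = FALSE),
            comparison_id = id)
}

test_that("fold-change ranking: direction, ties, symmetry and rank-sum invariant", {
  rt <- rank_by_lfc(cmp_from_lfc(c(a = 3, b = 1, c = 2)))
  expect_equal(rt$rank, c(1, 3, 2))
  # two genes tied at the top of four share the average rank 1.5
  rt2 <- rank_by_lfc(cmp_from_lfc(c(a = 5, b = 5, c = 1, d = 0)))
  expect_equal(rt2$rank, c(1.5, 1.5, 3, 4))
  # reversing the label convention reverses ranks for untied genes
  lfc <- c(a = 2.3, b = -1.1, c = 0.4, d = 5)
  r_fwd <- rank_by_lfc(cmp_from_lfc(lfc))$rank
  r_rev <- rank_by_lfc(cmp_from_lfc(-lfc))$rank
  expect_equal(r_rev, length(lfc) + 1 - r_fwd)
  # rank sums are n(n+1)/2
  set.seed(1)
  for (n in c(5, 17)) {
    r <- rank_by_lfc(cmp_from_lfc(setNames(rnorm(n), paste0("g", 1:n))))$rank
    expect_equal(sum(r), n * (n + 1) / 2)
  }
  expect_error(rank_by_lfc(cmp_from_lfc(numeric(0))), "empty")
})

test_that("rank products combine relative ranks geometrically", {
  one <- rank_product(list(rank_by_lfc(cmp_from_lfc(c(a = 3, b = 1, c = 2)))))
  expect_equal(one$rho, one$rank_c1 / 3)  # k = 1 identity
  # best-possible product across four cohorts of 1321 genes
  mk <- function(r, n, id) {
    structure(data.frame(gene = c("hit", paste0("f", seq_len(n - 1))),
                         rank = c(r, setdiff(seq_len(n), r))),
              n = n, comparison_id = id, class = c("rank_table", "data.frame"))
  }
  rp <- rank_product(lapply(1:4, function(i) mk(1, 1321, paste0("s", i))))
  hit <- rp[rp$gene == "hit", ]
  expect_equal(hit$raw_product, 1)
  expect_equal(hit$rho, 1 / 1321)
  # hand arithmetic: ranks (2,3) out of (4,4)
  rp2 <- rank_product(list(mk(2, 4, "x"), mk(3, 4, "y")))
  hit2 <- rp2[rp2$gene == "hit", ]
  expect_equal(hit2$raw_product, 6)
  expect_equal(hit2$rho, sqrt(6 / 16), tolerance = 1e-12)
  # genes absent everywhere are rejected; min_studies retains partial genes
  expect_error(rank_product(list(mk(1, 4, "x"), mk(1, 4, "y")),
                            min_studies = 3), "min_studies")
})

test_that("exact rank-product p-values enumerate the discrete null", {
  expect_equal(rp_pvalue_exact(3, 10), 0.3)          # k = 1 uniform tail
  expect_equal(rp_pvalue_exact(2, c(4, 4)), 3 / 16)  # (1,1), (1,2), (2,1)
  expect_equal(rp_pvalue_exact(16, c(4, 4)), 1)      # maximal statistic
  expect_error(rp_pvalue_exact(5, c(100, 100, 100), budget = 1e4),
               "rp_pvalue_gamma")
  expect_error(rp_pvalue_exact(2.5, c(4, 4)), "tied")
})

test_that("gamma approximation: identities, tails and monotonicity", {
  # k = 1 needs no approximation: exact uniform tail, p = 1 at the worst rank
  expect_equal(rp_pvalue_gamma(7, 10), 0.7)
  expect_equal(rp_pvalue_gamma(10, 10), 1)
  # four rank-1 hits among 1321-gene cohorts are overwhelming evidence
  expect_lt(rp_pvalue_gamma(c(1, 1, 1, 1), 1321), 1e-9)
  expect_equal(rp_pvalue_gamma(c(1, 1, 1, 1), 1321),
               pgamma(4 * log(1321 / 0.5), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  # monotone nondecreasing in rho at fixed k and n
  p_seq <- rp_pvalue_gamma(cbind(1:50, 1:50), c(50, 50))
  expect_true(all(diff(p_seq) > 0))
  # missing comparisons reduce k gene-wise
  pm <- rp_pvalue_gamma(rbind(c(2, NA, 5), c(2, 3, 5)), c(10, 10, 10))
  expect_gt(pm[1], 0)
  expect_true(pm[1] != pm[2])
  expect_error(rp_pvalue_gamma(c(0, 2), c(10, 10)), "ranks")
})

test_that("permutation p-values are seeded and agree with enumeration", {
  n <- c(6, 6)
  # worst statistic: p = 1 within 1/(B+1)
  pw <- rp_pvalue_permutation(1, n, B = 2000, seed = 4)
  expect_gte(pw$p, 1 - 1 / 2001)
  # determinism under a fixed seed
  expect_identical(rp_pvalue_permutation(0.3, n, B = 2000, seed = 8),
                   rp_pvalue_permutation(0.3, n, B = 2000, seed = 8))
  # oracle cross-check at B = 1e5: within 3 Monte-Carlo SEs of exact
  for (raw in c(2, 6, 12)) {
    rho <- sqrt(raw / 36)
    pe <- rp_pvalue_exact(raw, n)
    pp <- rp_pvalue_permutation(rho, n, B = 1e5, seed = 17)
    expect_lt(abs(pp$p - pe), 3 * pp$se + 1e-4)
  }
})

test_that("BH adjustment handles hand-worked vectors and is order-invariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.037), 0.037)
  set.seed(3)
  p <- runif(100)
  perm <- sample(100)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Fisher's one-sided combination matches the chi-squared closed form", {
  expect_equal(fisher_combine(0.123)$p, 0.123, tolerance = 1e-12)  # k = 1
  f <- fisher_combine(rep(0.05, 4))
  expect_equal(f$X, 23.9659, tolerance = 1e-4)
  expect_equal(f$df, 8L)
  expect_equal(f$p, 0.002322, tolerance = 1e-4)
  # p_i = 1 contributes nothing to the statistic
  expect_equal(fisher_combine(c(0.2, 1))$X, fisher_combine(c(0.2, 0.9999999999))$X,
               tolerance = 1e-6)
  expect_equal(fisher_combine(c(0.2, 1))$X, -2 * log(0.2))
  # exchangeable in its arguments
  p <- c(0.01, 0.6, 0.33)
  expect_equal(fisher_combine(p), fisher_combine(rev(p)))
  # zeros are floored and flagged, not fatal
  fz <- fisher_combine(c(0, 0.5))
  expect_true(fz$floored)
  expect_true(is.finite(fz$X))
})

test_that("metabolic filtering restricts rows and re-ranks without recomputing p", {
  set.seed(12)
  meta <- data.frame(gene = sprintf("g%05d", 1:10000), rho = runif(10000),
                     p_rp = runif(10000), stringsAsFactors = FALSE)
  metabolic <- sample(meta$gene, 1321)
  out <- filter_and_rank_metabolic(meta, metabolic)
  expect_equal(nrow(out), 1321)
  expect_equal(sort(out$meta_rank), 1:1321)  # a permutation of 1..m
  expect_equal(out$gene[out$meta_rank == 1],
               meta$gene[meta$gene %in% metabolic][
                 which.min(meta$rho[meta$gene %in% metabolic])])
  expect_equal(out$p_rp, meta$p_rp[match(out$gene, meta$gene)])  # p untouched
  # full-universe filter is a no-op up to ranking
  all_out <- filter_and_rank_metabolic(meta, meta$gene)
  expect_equal(nrow(all_out), 10000)
  # the overall top gene keeps rank 1 when metabolic
  top <- meta$gene[which.min(meta$rho)]
  expect_equal(filter_and_rank_metabolic(meta, c(top, metabolic))$gene[1], top)
  expect_error(filter_and_rank_metabolic(meta, "absent"), "no metabolic gene")
})

test_that("run_meta wires the pipeline together with coherent outputs", {
  expect_error(run_meta(list(null_study(20))), ">= 2 comparisons")
  cfg <- sim_config(n_genes = 300, n_studies = 3, n_responders = 5,
                    n_nonresponders = 5, spike = c(gene005 = 3),
                    metabolic_fraction = 0.5, seed = 8)
  sim <- simulate_cohorts(cfg)
  meta <- run_meta(sim$studies, metabolic = sim$metabolic_genes)
  full <- meta$full_table
  expect_equal(nrow(full), 300)
  expect_true(all(full$rho > 0 & full$rho <= 1))
  expect_true(all(full$p_adj >= full$p_rp - 1e-15))
  expect_true(all(full$fisher_X >= 0))
  expect_equal(sort(meta$table$meta_rank), seq_len(nrow(meta$table)))
  expect_equal(meta$table$gene[1], "gene005")
  expect_equal(nrow(meta$table), length(sim$metabolic_genes))
  expect_true(nchar(meta$manifest$config_hash) == 32)
  # exact and permutation p routes agree with gamma on a tiny problem
  cfg2 <- sim_config(n_genes = 12, n_studies = 2, n_responders = 3,
                     n_nonresponders = 3, seed = 4)
  sim2 <- simulate_cohorts(cfg2)
  m_g <- run_meta(sim2$studies, pmethod = "gamma")
  m_e <- run_meta(sim2$studies, pmethod = "exact")
  m_p <- run_meta(sim2$studies, pmethod = "perm", B = 20000, seed = 2)
  expect_equal(m_e$full_table$gene, m_g$full_table$gene)
  expect_lt(max(abs(m_e$full_table$p_rp - m_p$full_table$p_rp)), 0.05)
  # TSV + manifest round trip
  tmp <- tempfile(fileext = ".tsv")
  write_meta_tsv(meta, tmp)
  expect_true(file.exists(tmp) && file.exists(paste0(tmp, ".manifest.json")))
  back <- read.delim(tmp)
  expect_equal(nrow(back), nrow(meta$table))
})

test_that("null meta-analysis rarely produces significant adjusted p-values", {
  worst <- vapply(1:10, function(i) {
    cfg <- sim_config(n_genes = 1000, n_studies = 4, n_responders = 5,
                      n_nonresponders = 5, seed = 700 + i)
    sim <- simulate_cohorts(cfg)
    min(run_meta(sim$studies)$full_table$p_adj)
  }, 0)
  expect_gte(sum(worst > 0.05), 8)
})
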