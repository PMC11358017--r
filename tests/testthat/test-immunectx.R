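test_that("signature scores are z-score means with degenerate-input handling", {
  st <- null_study(30, n = 4, seed = 5)
  # singleton signature: score equals that gene's z-score
  x <- st$exprs["g7", ]
  z <- (x - mean(x)) / sd(x)
  expect_equal(as.numeric(score_signature(st, "g7")), unname(z), tolerance = 1e-12)
  # constant matrix: all scores zero (variance floor)
  cm <- matrix(3, 5, 6, dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  expect_equal(as.numeric(score_signature(cm, c("g1", "g2"))), rep(0, 6))
  # invariant under gene-wise affine rescaling
  sig <- c("g1", "g5", "g9")
  set.seed(11)
  m2 <- sweep(sweep(st$exprs, 1, runif(nrow(st$exprs), 0.5, 4), "*"),
              1, rnorm(nrow(st$exprs)), "+")
  expect_equal(as.numeric(score_signature(m2, sig)), as.numeric(score_signature(st$exprs, sig)),
               tolerance = 1e-10)
  # missing genes are counted, absent signatures rejected
  sc <- score_signature(st, c("g1", "not_a_gene"))
  expect_equal(attr(sc, "n_missing"), 1)
  expect_error(score_signature(st, "nope"), "no signature gene")
})

test_that("signature scoring separates shifted samples", {
  hits <- 0
  for (i in 1:20) {
    set.seed(300 + i)
    m <- matrix(rnorm(50 * 20), 50, 20,
                dimnames = list(paste0("g", 1:50), paste0("s", 1:20)))
    sig <- paste0("g", 1:10)
    m[sig, 11:20] <- m[sig, 11:20] + 2  # +2 SD shift in half the samples
    sc <- score_signature(m, sig)
    if (min(sc[11:20]) > max(sc[1:10])) hits <- hits + 1
  }
  expect_equal(hits, 20)
})

test_that("median dichotomization forms disjoint strata with exclusion of intermediates", {
  # perfectly anti-correlated scores: nobody excluded
  a <- setNames(seq(-2, 2, length.out = 8), paste0("s", 1:8))
  d <- dichotomize(a, -a)
  expect_equal(sum(d$stratum == "excluded"), 0)
  expect_equal(as.vector(table(d$stratum)[1:2]), c(4, 4))
  # all-equal scores: everyone excluded (strict inequalities)
  e <- dichotomize(setNames(rep(1, 6), paste0("s", 1:6)),
                   setNames(rep(2, 6), paste0("s", 1:6)))
  expect_true(all(e$stratum == "excluded"))
  # strata partition the sample set
  set.seed(2)
  b <- setNames(rnorm(101), paste0("s", 1:101))
  cc <- setNames(rnorm(101), paste0("s", 1:101))
  d2 <- dichotomize(b, cc)
  expect_equal(nrow(d2), 101)
  expect_true(all(levels(d2$stratum) == c("a_high_b_low", "a_low_b_high", "excluded")))
  # independent scores: about n/4 in each stratum
  set.seed(9)
  frac <- replicate(50, {
    s1 <- rnorm(100); s2 <- rnorm(100)
    names(s1) <- names(s2) <- paste0("s", 1:100)
    d <- dichotomize(s1, s2)
    mean(d$stratum == "a_high_b_low")
  })
  expect_lt(abs(mean(frac) - 0.25), 3 * sd(frac) / sqrt(50))
  expect_error(dichotomize(a[1:3], a[1:3]), ">= 4 samples")
})

test_that("stratum comparison is an unpaired two-tailed pooled t-test", {
  strata <- data.frame(sample = paste0("s", 1:6),
                       stratum = factor(rep(c("a_high_b_low", "a_low_b_high"),
                                            each = 3),
                                        levels = c("a_high_b_low",
                                                   "a_low_b_high", "excluded")))
  x <- setNames(c(1, 2, 3, 4, 5, 6), paste0("s", 1:6))
  res <- compare_groups(x, strata)
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$p_two, 0.021312, tolerance = 1e-4)
  # identical groups
  res0 <- compare_groups(setNames(rep(2, 6), paste0("s", 1:6)), strata)
  expect_equal(res0$t, 0)
  expect_equal(res0$p_two, 1)
  # swapping group order negates t, preserves p
  strata_sw <- strata
  strata_sw$stratum <- factor(
    rep(c("a_low_b_high", "a_high_b_low"), each = 3),
    levels = levels(strata$stratum))
  res_sw <- compare_groups(x, strata_sw)
  expect_equal(res_sw$t, -res$t)
  expect_equal(res_sw$p_two, res$p_two)
})

test_that("cross-dataset cell-type correlations treat datasets as observations", {
  mk_table <- function(vx, vy) {
    ds <- paste0("d", seq_along(vx))
    rbind(data.frame(dataset = ds, gene = "CDA", cell_type = "cancer",
                     mean_expr = vx),
          data.frame(dataset = ds, gene = "P2RY6", cell_type = "macrophage",
                     mean_expr = vy))
  }
  set.seed(6)
  vx <- rnorm(16)
  tab <- mk_table(vx, vx)
  self <- celltype_mean_correlation(tab, "CDA:cancer", "P2RY6:macrophage")
  expect_equal(self$r, 1, tolerance = 1e-12)
  neg <- celltype_mean_correlation(mk_table(vx, -2 * vx + 3),
                                   c("CDA", "cancer"),
                                   c("P2RY6", "macrophage"))
  expect_equal(neg$r, -1, tolerance = 1e-12)
  expect_equal(neg$n, 16)
  # Spearman is invariant under monotone transforms
  vy <- rnorm(16)
  r1 <- celltype_mean_correlation(mk_table(vx, vy), "CDA:cancer",
                                  "P2RY6:macrophage", "spearman")$r
  r2 <- celltype_mean_correlation(mk_table(exp(vx), vy^3 + 5 * vy),
                                  "CDA:cancer", "P2RY6:macrophage",
                                  "spearman")$r
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_error(celltype_mean_correlation(mk_table(vx[1:2], vy[1:2]),
                                         "CDA:cancer", "P2RY6:macrophage"),
               ">= 3 datasets")
})

test_that("correlation recovery at 16 datasets matches its sampling distribution", {
  ok <- 0
  for (i in 1:200) {
    set.seed(400 + i)
    x <- rnorm(16)
    y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(16)
    r <- cor(x, y)
    if (r > 0.5 && r < 0.95) ok <- ok + 1
  }
  expect_gte(ok / 200, 0.9)
})

test_that("dot-plot summaries min-max scale group means and count expressing samples", {
  m <- matrix(0, 2, 6, dimnames = list(c("gA", "gB"), paste0("s", 1:6)))
  m["gA", ] <- c(2, 2, 2, 6, 6, 6)
  groups <- rep(c("resp", "nonresp"), each = 3)
  out <- dotplot_summary(m, c("gA", "gB"), groups)
  a <- out[out$gene == "gA", ]
  expect_equal(sort(a$scaled_mean), c(0, 1))  # means 2 and 6 -> (0, 1)
  expect_equal(a$fraction_expressing, c(1, 1))
  b <- out[out$gene == "gB", ]
  expect_equal(b$fraction_expressing, c(0, 0))  # expressed nowhere
  expect_equal(b$scaled_mean, c(1, 1))          # degenerate scaling convention
  one <- dotplot_summary(m, "gA", rep("all", 6))
  expect_equal(one$scaled_mean, 1)
  expect_error(dotplot_summary(m, "gA", c(groups[-1], NA)), "partition")
})
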