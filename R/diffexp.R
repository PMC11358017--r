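#' Per-gene log2 fold changes (non-responder minus responder)
#'
#' The sign convention follows the meta-analysis: positive values mean
#' higher expression in non-responders (resistance-associated), and the
#' most up-regulated genes later receive the lowest ranks.
#'
#' @param study An [expression_study()] object.
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
log2_fold_changes <- function(study) {
  stop_if_not(inherits(study, "expression_study"),
              "`study` must be an expression_study")
  nr <- study$labels == "nonresponder"
  rowMeans(study$exprs[, nr, drop = FALSE]) -
    rowMeans(study$exprs[, !nr, drop = FALSE])
}

row_vars <- function(m) {
  d <- m - rowMeans(m)
  rowSums(d * d) / (ncol(m) - 1)
}

# Per-gene pooled within-group variances and residual df.
# Zero-variance genes are floored at the 1st percentile of positive
# variances (keeps them in the rank universe with a finite t) and flagged.
pooled_variances <- function(study) {
  nr <- study$labels == "nonresponder"
  n1 <- sum(!nr)
  n2 <- sum(nr)
  v1 <- row_vars(study$exprs[, !nr, drop = FALSE])
  v2 <- row_vars(study$exprs[, nr, drop = FALSE])
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  flag <- s2 <= 0
  if (any(flag)) {
    pos <- s2[s2 > 0]
    stop_if_not(length(pos) > 0, "all gene variances are zero")
    s2[flag] <- quantile(pos, 0.01)
  }
  list(s2 = s2, df = n1 + n2 - 2, n1 = n1, n2 = n2, floored = flag)
}

#' Moderated-t prior parameters
#'
#' Container for the variance-shrinkage prior: prior degrees of freedom
#' `d0` (0 disables shrinkage; `Inf` shrinks every gene fully to `s0_2`)
#' and prior variance `s0_2`.
#'
#' @param d0 Prior df, `>= 0`; `Inf` allowed.
#' @param s0_2 Prior variance, `> 0`.
#' @return An object of class `"moderated_t_params"`.
#' @export
moderated_t_params <- function(d0, s0_2) {
  stop_if_not(is.numeric(d0) && length(d0) == 1 && d0 >= 0, "`d0` must be >= 0")
  stop_if_not(is.numeric(s0_2) && length(s0_2) == 1 && s0_2 > 0, "`s0_2` must be > 0")
  structure(list(d0 = d0, s0_2 = s0_2), class = "moderated_t_params")
}

# Newton inversion of the trigamma function (solve trigamma(y) = x).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Estimate the variance-shrinkage prior by moment matching
#'
#' Fits the scaled-F hierarchical model for gene-wise sample variances:
#' `s_g^2 ~ s0^2 * F(d_g, d0)` in distribution, equivalently
#' `log s_g^2` has moments determined by digamma/trigamma functions of
#' `d_g/2` and `d0/2`. The first two moments of `log s_g^2` are matched;
#' `d0` solves a trigamma equation (Newton inversion) and `s0^2` follows
#' from the mean. When the observed dispersion of `log s_g^2` does not
#' exceed the sampling floor `trigamma(d_g/2)`, the variances are treated
#' as effectively common: `d0 = Inf` and `s0^2` is their geometric mean.
#'
#' @param s2 Vector of gene-wise variances (>= 10 genes with positive
#'   variance required).
#' @param df Residual df per gene (scalar, or vector recycled per gene).
#' @return A [moderated_t_params()] object.
#' @export
estimate_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2)]
  stop_if_not(sum(s2 > 0) >= 10,
              "need >= 10 genes with positive variance to estimate the prior")
  stop_if_not(any(s2 > 0), "all variances are zero")
  df <- rep_len(df, length(s2))
  keep <- s2 > 0
  s2 <- s2[keep]
  df <- df[keep]
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_2 <- exp(mean(z))
  }
  moderated_t_params(d0, s0_2)
}

# Shared result assembly for the t-type statistics.
comparison_result <- function(study, lfc, s2, df_resid, s2_post, tstat,
                              df_total, flag) {
  p_two <- 2 * pt(abs(tstat), df_total, lower.tail = FALSE)
  p_one_up <- pt(tstat, df_total, lower.tail = FALSE)
  out <- data.frame(
    gene = names(lfc), log2fc = unname(lfc), s2 = unname(s2),
    df = unname(rep_len(df_resid, length(lfc))),
    s2_post = unname(s2_post), t = unname(tstat),
    df_total = unname(rep_len(df_total, length(lfc))),
    p_two = unname(p_two), p_one_up = unname(p_one_up),
    flag = unname(flag), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, study_id = study$study_id, comparison_id = study$comparison,
            n1 = sum(study$labels == "responder"),
            n2 = sum(study$labels == "nonresponder"),
            class = c("comparison_result", "data.frame"))
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' For each gene, the pooled variance is shrunk toward the prior:
#' `s2_post = (d0 * s0^2 + d * s2) / (d0 + d)`, the statistic is
#' `t = log2FC / sqrt(s2_post * (1/n1 + 1/n2))`, and p-values come from a
#' Student t distribution with `d0 + d` degrees of freedom. With `d0 = 0`
#' this is exactly the classical pooled-variance t-test; with `d0 = Inf`
#' every gene uses the common prior variance. The one-tailed p-value
#' `p_one_up` is the upper tail (evidence for up-regulation in
#' non-responders) and feeds the Fisher combination.
#'
#' @param study An [expression_study()] object.
#' @param params Optional [moderated_t_params()]; estimated from the
#'   study's own variances via [estimate_prior()] when omitted.
#' @return A `comparison_result` data.frame with columns `gene`, `log2fc`,
#'   `s2`, `df`, `s2_post`, `t`, `df_total`, `p_two`, `p_one_up`, `flag`
#'   (variance floored), and attributes `study_id`, `comparison_id`.
#' @export
moderated_t <- function(study, params = NULL) {
  stop_if_not(inherits(study, "expression_study"),
              "`study` must be an expression_study")
  pv <- pooled_variances(study)
  if (is.null(params)) params <- estimate_prior(pv$s2, pv$df)
  stop_if_not(inherits(params, "moderated_t_params"),
              "`params` must come from moderated_t_params()/estimate_prior()")
  lfc <- log2_fold_changes(study)
  d0 <- params$d0
  s2_post <- if (is.infinite(d0)) {
    rep(params$s0_2, length(pv$s2))
  } else {
    (d0 * params$s0_2 + pv$df * pv$s2) / (d0 + pv$df)
  }
  names(s2_post) <- names(pv$s2)
  se <- sqrt(s2_post * (1 / pv$n1 + 1 / pv$n2))
  comparison_result(study, lfc, pv$s2, pv$df, s2_post, lfc / se,
                    d0 + pv$df, pv$floored)
}

#' Welch two-sample t-test per gene
#'
#' Unequal-variance alternative to [moderated_t()] with Satterthwaite
#' degrees of freedom; useful when gene-wise variances differ between the
#' response groups. Genes where both group variances are zero are floored
#' (1st percentile of positive per-group variances) and flagged.
#'
#' @param study An [expression_study()] object.
#' @return A `comparison_result` data.frame (see [moderated_t()]); `s2`
#'   holds the Welch squared standard error times a harmonic sample-size
#'   factor, `df_total` the per-gene Satterthwaite df.
#' @export
welch_t <- function(study) {
  stop_if_not(inherits(study, "expression_study"),
              "`study` must be an expression_study")
  nr <- study$labels == "nonresponder"
  n1 <- sum(!nr)
  n2 <- sum(nr)
  v1 <- row_vars(study$exprs[, !nr, drop = FALSE])
  v2 <- row_vars(study$exprs[, nr, drop = FALSE])
  flag <- (v1 + v2) <= 0
  if (any(flag)) {
    pos <- c(v1[v1 > 0], v2[v2 > 0])
    stop_if_not(length(pos) > 0, "all gene variances are zero")
    fl <- quantile(pos, 0.01)
    v1[flag] <- fl
    v2[flag] <- fl
  }
  se2 <- v1 / n1 + v2 / n2
  df_w <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  lfc <- log2_fold_changes(study)
  comparison_result(study, lfc, se2 / (1 / n1 + 1 / n2), n1 + n2 - 2,
                    se2 / (1 / n1 + 1 / n2), lfc / sqrt(se2), df_w, flag)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Comparison '%s' (study '%s'): %d genes, %d + %d samples\n",
              attr(x, "comparison_id"), attr(x, "study_id"), nrow(x),
              attr(x, "n1"), attr(x, "n2")))
  NextMethod()
}
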