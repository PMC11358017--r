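#' Peak calcium response from a Fura-2 ratio trace
#'
#' Quantifies a ratiometric calcium trace as the normalized peak response:
#' `(max post-stimulus ratio - mean pre-stimulus ratio) / ionomycin
#' amplitude`, i.e. the peak increase of the F340/F380 ratio expressed as
#' a fraction of the maximal (ionophore) response of the same
#' preparation.
#'
#' @param time Time vector (s), strictly increasing.
#' @param ratio F340/F380 ratio vector (positive), same length as `time`.
#' @param stim_time Stimulus time (s), within the record; at least 5
#'   samples must precede it.
#' @param ionomycin Ionomycin response amplitude (delta-ratio units), > 0.
#' @return Normalized peak response (dimensionless).
#' @export
peak_delta_ratio <- function(time, ratio, stim_time, ionomycin) {
  stop_if_not(length(time) == length(ratio), "`time` and `ratio` lengths differ")
  stop_if_not(all(diff(time) > 0), "`time` must be strictly increasing")
  stop_if_not(all(ratio > 0), "`ratio` must be positive")
  stop_if_not(stim_time > min(time) && stim_time < max(time),
              "`stim_time` must lie within the record")
  stop_if_not(is.numeric(ionomycin) && ionomycin > 0,
              "`ionomycin` amplitude must be > 0")
  pre <- ratio[time < stim_time]
  stop_if_not(length(pre) >= 5, "need >= 5 pre-stimulus samples")
  (max(ratio[time >= stim_time]) - mean(pre)) / ionomycin
}

validate_dose_response <- function(data) {
  stop_if_not(is.data.frame(data), "`data` must be a data.frame")
  cn <- names(data)
  conc_col <- intersect(c("concentration_M", "concentration", "conc"), cn)[1]
  stop_if_not(!is.na(conc_col) && "response" %in% cn,
              "`data` needs a concentration column and a `response` column")
  conc <- data[[conc_col]]
  resp <- data$response
  stop_if_not(all(is.finite(conc)) && all(conc >= 0),
              "concentrations must be finite and >= 0")
  stop_if_not(all(is.finite(resp)), "responses must be finite")
  stop_if_not(length(unique(conc[conc > 0])) >= 4,
              "need >= 4 distinct positive concentrations for fitting")
  data.frame(concentration = conc, response = resp)
}

#' Fit a Hill concentration-response curve
#'
#' Least-squares fit of `response = baseline + Emax * c^h / (EC50^h +
#' c^h)` to replicated (concentration, response) data, with the EC50
#' optimized on the log scale. A multi-start strategy over a log-spaced
#' EC50 grid (spanning the observed concentration range extended one log
#' unit either side) guards against local minima; the candidate with the
#' lowest residual sum of squares is returned. Asymptotic standard errors
#' come from the Jacobian at the optimum; `SE(EC50)` is obtained from
#' `SE(log EC50)` by the delta method.
#'
#' Defaults follow the quantification conventions of ionomycin-normalized
#' peak responses: the baseline is fixed at 0 (responses are already
#' baseline-subtracted by [peak_delta_ratio()]) and the Hill coefficient
#' is fitted freely within `h_bounds` (fix it with `fix_h = 1` when the
#' concentration grid is too sparse to identify the slope).
#'
#' @param data data.frame with a concentration column (`concentration_M`,
#'   `concentration` or `conc`; molar units) and a `response` column. All
#'   points are fitted (replicates are not averaged) unless
#'   `on_means = TRUE`.
#' @param fix_baseline If `TRUE` (default), the baseline is fixed at 0.
#' @param fix_h Optional fixed Hill coefficient (e.g. `1`); `NULL` fits it.
#' @param h_bounds Box constraints for a free Hill coefficient.
#' @param n_starts Number of multi-start EC50 grid points.
#' @param on_means Fit on per-concentration means instead of all points.
#' @return An object of class `"hill_fit"` with components `params`
#'   (a [hill_params()]), `se` (named SEs, including `log_ec50`), `rss`,
#'   `sigma` (residual SD), `converged`, `identifiable` (FALSE when
#'   `SE(EC50)/EC50 > 1`), `extrapolated` (EC50 outside the concentration
#'   range extended one log unit), `data`, and the underlying `nls` fit.
#'   Supported methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot`, `simulate`.
#' @export
#' @examples
#' d <- simulate_dose_response(hill_params(42e-9, emax = 0.8), seed = 1)
#' fit <- fit_hill(d)
#' coef(fit)
fit_hill <- function(data, fix_baseline = TRUE, fix_h = NULL,
                     h_bounds = c(0.3, 4), n_starts = 7, on_means = FALSE) {
  d <- validate_dose_response(data)
  if (on_means) {
    d <- aggregate(response ~ concentration, d, mean)
  }
  pos <- d$concentration > 0
  crange <- range(d$concentration[pos])
  lgrid <- seq(log(crange[1]) - log(10), log(crange[2]) + log(10),
               length.out = n_starts)
  resp_span <- max(d$response) - min(d$response)

  free_h <- is.null(fix_h)
  if (!free_h) {
    stop_if_not(is.numeric(fix_h) && fix_h > 0, "`fix_h` must be > 0")
  }

  model_fun <- function(lec50, h, emax, baseline) {
    ch <- exp(h * (log(pmax(d$concentration, .Machine$double.xmin)) - lec50))
    ch[d$concentration == 0] <- 0
    baseline + emax * ch / (1 + ch)
  }

  fits <- list()
  for (lec0 in lgrid) {
    start <- list(lec50 = lec0)
    lower <- c(lec50 = log(crange[1]) - 3 * log(10))
    upper <- c(lec50 = log(crange[2]) + 3 * log(10))
    if (free_h) {
      start$h <- 1
      lower <- c(lower, h = h_bounds[1])
      upper <- c(upper, h = h_bounds[2])
    }
    start$emax <- max(resp_span, 0.05)
    lower <- c(lower, emax = 0)
    upper <- c(upper, emax = Inf)
    if (!fix_baseline) {
      start$baseline <- min(d$response)
      lower <- c(lower, baseline = -Inf)
      upper <- c(upper, baseline = Inf)
    }
    form <- if (free_h && !fix_baseline) {
      response ~ model_fun(lec50, h, emax, baseline)
    } else if (free_h) {
      response ~ model_fun(lec50, h, emax, 0)
    } else if (!fix_baseline) {
      response ~ model_fun(lec50, fix_h, emax, baseline)
    } else {
      response ~ model_fun(lec50, fix_h, emax, 0)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = d, start = start,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
  }
  stop_if_not(length(fits) > 0, "all multi-start fits failed")

  rss <- vapply(fits, function(f) sum(residuals(f)^2), 0)
  best <- fits[[which.min(rss)]]
  cf <- coef(best)
  est <- list(ec50 = exp(cf[["lec50"]]),
              h = if (free_h) cf[["h"]] else fix_h,
              emax = cf[["emax"]],
              baseline = if (fix_baseline) 0 else cf[["baseline"]])

  se <- tryCatch({
    s <- summary(best)$coefficients[, "Std. Error"]
    names(s) <- names(cf)
    s
  }, error = function(e) setNames(rep(NA_real_, length(cf)), names(cf)))
  se_out <- c(log_ec50 = unname(se["lec50"]),
              ec50 = unname(est$ec50 * se["lec50"]),
              h = if (free_h) unname(se["h"]) else 0,
              emax = unname(se["emax"]),
              baseline = if (fix_baseline) 0 else unname(se["baseline"]))

  converged <- isTRUE(best$convInfo$isConv)
  dfres <- max(1L, nrow(d) - length(cf))
  identifiable <- is.finite(se_out["ec50"]) &&
    se_out["ec50"] / est$ec50 <= 1 && est$emax > 1e-6
  extrapolated <- est$ec50 < crange[1] / 10 || est$ec50 > crange[2] * 10

  structure(
    list(params = hill_params(est$ec50, est$h, min(est$emax, 1.5),
                              est$baseline),
         estimates = est, se = se_out,
         rss = min(rss), candidate_rss = rss,
         sigma = sqrt(min(rss) / dfres),
         converged = converged, identifiable = unname(identifiable),
         extrapolated = extrapolated,
         fixed = list(baseline = fix_baseline, h = if (free_h) NULL else fix_h),
         data = d, fit = best,
         method = sprintf("nlsLM multi-start (%d starts)", length(lgrid))),
    class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) {
  with(object$estimates,
       c(ec50 = ec50, h = h, emax = emax, baseline = baseline))
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) {
    object$data$concentration
  } else if (is.data.frame(newdata)) {
    validate_col <- intersect(c("concentration_M", "concentration", "conc"),
                              names(newdata))[1]
    stop_if_not(!is.na(validate_col), "`newdata` needs a concentration column")
    newdata[[validate_col]]
  } else {
    as.numeric(newdata)
  }
  e <- object$estimates
  ch <- ifelse(conc > 0, (conc / e$ec50)^e$h, 0)
  e$baseline + e$emax * ch / (1 + ch)
}

#' @export
fitted.hill_fit <- function(object, ...) predict(object)

#' @export
residuals.hill_fit <- function(object, ...) {
  object$data$response - fitted(object)
}

#' @export
simulate.hill_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- fitted(object)
  with_seed(seed, {
    out <- replicate(nsim, mu + rnorm(length(mu), 0, object$sigma))
    as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
  })
}

#' @export
print.hill_fit <- function(x, ...) {
  e <- x$estimates
  cat("Hill concentration-response fit\n")
  cat(sprintf("  EC50 = %.3g M (%.1f nM), h = %.3g, Emax = %.3g, baseline = %.3g\n",
              e$ec50, e$ec50 * 1e9, e$h, e$emax, e$baseline))
  cat(sprintf("  RSS = %.4g on %d points; %s\n", x$rss, nrow(x$data),
              if (x$converged) "converged" else "NOT converged"))
  if (!x$identifiable) cat("  warning: EC50 poorly identified (SE/EC50 > 1 or Emax ~ 0)\n")
  if (x$extrapolated) cat("  warning: EC50 outside the sampled concentration range (extrapolated)\n")
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  e <- object$estimates
  tab <- data.frame(
    estimate = c(e$ec50, e$h, e$emax, e$baseline),
    se = unname(object$se[c("ec50", "h", "emax", "baseline")]),
    row.names = c("ec50", "h", "emax", "baseline"))
  out <- list(coefficients = tab, rss = object$rss, sigma = object$sigma,
              n = nrow(object$data), converged = object$converged,
              identifiable = object$identifiable,
              extrapolated = object$extrapolated, method = object$method)
  class(out) <- "summary.hill_fit"
  out
}

#' @export
print.summary.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (%s) on %d points\n", x$method, x$n))
  print(x$coefficients, digits = 4)
  cat(sprintf("Residual SD %.4g; RSS %.4g; converged: %s; identifiable: %s\n",
              x$sigma, x$rss, x$converged, x$identifiable))
  invisible(x)
}

#' @export
plot.hill_fit <- function(x, ...) {
  d <- x$data[x$data$concentration > 0, ]
  cr <- range(d$concentration)
  grid <- 10^seq(log10(cr[1]) - 0.5, log10(cr[2]) + 0.5, length.out = 200)
  plot(d$concentration, d$response, log = "x",
       xlab = "concentration (M)", ylab = "normalized response", ...)
  lines(grid, predict(x, grid), col = "firebrick", lwd = 2)
  abline(v = x$estimates$ec50, lty = 2, col = "grey50")
  invisible(x)
}

#' Potency ratio between two Hill fits
#'
#' Ratio of half-maximal effective concentrations `EC50_B / EC50_A` with
#' a confidence interval obtained by error propagation on the log scale
#' (`SE(log EC50) = SE(EC50)/EC50`, variances added, interval
#' exponentiated).
#'
#' @param fit_a,fit_b Converged [fit_hill()] objects; `fit_a` is the
#'   reference (more potent agonist for ratios > 1).
#' @param level Confidence level (default 0.95).
#' @return List of class `"potency_ratio"`: `ratio`, `ci` (length 2),
#'   `level`, `log_se`.
#' @export
compare_potency <- function(fit_a, fit_b, level = 0.95) {
  stop_if_not(inherits(fit_a, "hill_fit") && inherits(fit_b, "hill_fit"),
              "both arguments must be hill_fit objects")
  stop_if_not(fit_a$converged && fit_b$converged,
              "both fits must have converged")
  la <- log(fit_a$estimates$ec50)
  lb <- log(fit_b$estimates$ec50)
  se <- sqrt(fit_a$se[["log_ec50"]]^2 + fit_b$se[["log_ec50"]]^2)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(ratio = exp(lb - la),
                 ci = exp(c(lb - la - z * se, lb - la + z * se)),
                 level = level, log_se = se),
            class = "potency_ratio")
}

#' @export
print.potency_ratio <- function(x, ...) {
  cat(sprintf("EC50 ratio (B/A): %.3f, %d%% CI [%.3f, %.3f]\n",
              x$ratio, round(100 * x$level), x$ci[1], x$ci[2]))
  invisible(x)
}
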