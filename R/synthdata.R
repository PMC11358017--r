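#' Simulation configuration for multi-cohort expression data
#'
#' Describes a synthetic multi-cohort experiment emulating pretreatment
#' transcriptomic cohorts of immunotherapy responders and non-responders:
#' `n_studies` heterogeneous cohorts share a common gene universe, a small
#' spike table of genes is truly shifted up in non-responders, and each
#' study carries its own per-gene batch offset so that cross-study rank
#' agreement is driven only by true effects.
#'
#' The expression model is Gaussian on the log2 scale: the downstream
#' meta-analysis consumes log-scale values and fold-change ranks, so
#' count-level simulation is unnecessary for the statistic.
#'
#' @param n_genes Number of genes in the shared universe.
#' @param n_studies Number of cohorts `k`.
#' @param n_responders,n_nonresponders Per-study group sizes; scalars are
#'   recycled to length `n_studies`. Each arm needs >= 2 samples.
#' @param base_mean,base_sd Mean and SD of the per-gene baseline log2
#'   expression level (drawn once, shared across studies).
#' @param batch_sd SD of the per-study, per-gene additive batch offset
#'   (cohort heterogeneity; mimics combining cohorts from different
#'   platforms and species).
#' @param spike Spike table: either a named numeric vector (gene -> log2
#'   effect delta applied in every study) or a numeric matrix with spiked
#'   genes in rownames and `n_studies` columns of per-study deltas.
#'   Positive delta = up in non-responders. `NULL` for a null simulation.
#' @param noise_sd Residual Gaussian noise SD (log2 units), >= 0.
#' @param dropout Probability that a measured value is set to
#'   `dropout_floor`, in `[0, 1]`.
#' @param dropout_floor Value substituted for dropped-out measurements.
#' @param metabolic_fraction Fraction of the gene universe flagged as
#'   metabolic (emulating a curated metabolic gene list).
#' @param metabolic_genes Optional explicit character vector of metabolic
#'   gene ids, overriding `metabolic_fraction`.
#' @param seed Integer RNG seed; the simulation is fully determined by it.
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @seealso [simulate_cohorts()], [read_sim_config()]
#' @export
sim_config <- function(n_genes = 10000, n_studies = 4,
                       n_responders = 10, n_nonresponders = 10,
                       base_mean = 6, base_sd = 2, batch_sd = 0.5,
                       spike = NULL, noise_sd = 1,
                       dropout = 0, dropout_floor = 0,
                       metabolic_fraction = 0.1321, metabolic_genes = NULL,
                       seed = 1L) {
  stop_if_not(is_count(n_genes), "`n_genes` must be a positive integer")
  stop_if_not(is_count(n_studies), "`n_studies` must be a positive integer")
  n_responders <- rep_len(as.integer(n_responders), n_studies)
  n_nonresponders <- rep_len(as.integer(n_nonresponders), n_studies)
  stop_if_not(all(n_responders >= 2) && all(n_nonresponders >= 2),
              "group sizes must be >= 2 per arm")
  stop_if_not(is.numeric(noise_sd) && noise_sd >= 0, "`noise_sd` must be >= 0")
  stop_if_not(is.numeric(base_sd) && base_sd >= 0, "`base_sd` must be >= 0")
  stop_if_not(is.numeric(batch_sd) && batch_sd >= 0, "`batch_sd` must be >= 0")
  stop_if_not(is.numeric(dropout) && dropout >= 0 && dropout <= 1,
              "`dropout` must be in [0, 1]")
  stop_if_not(is.numeric(metabolic_fraction) &&
                metabolic_fraction >= 0 && metabolic_fraction <= 1,
              "`metabolic_fraction` must be in [0, 1]")
  genes <- sprintf("gene%0*d", nchar(as.character(n_genes)), seq_len(n_genes))
  if (!is.null(spike)) {
    if (is.matrix(spike)) {
      stop_if_not(ncol(spike) == n_studies,
                  "spike matrix must have `n_studies` columns")
      stop_if_not(!is.null(rownames(spike)), "spike matrix needs gene rownames")
    } else {
      stop_if_not(is.numeric(spike) && !is.null(names(spike)),
                  "`spike` must be a named numeric vector or a matrix")
      spike <- matrix(rep(spike, n_studies), ncol = n_studies,
                      dimnames = list(names(spike), NULL))
    }
    stop_if_not(all(is.finite(spike)), "spike effects must be finite")
    stop_if_not(all(rownames(spike) %in% genes),
                "spike table references genes outside the gene universe")
  }
  if (!is.null(metabolic_genes)) {
    stop_if_not(all(metabolic_genes %in% genes),
                "`metabolic_genes` must be a subset of the gene universe")
  }
  structure(
    list(n_genes = as.integer(n_genes), n_studies = as.integer(n_studies),
         n_responders = n_responders, n_nonresponders = n_nonresponders,
         base_mean = base_mean, base_sd = base_sd, batch_sd = batch_sd,
         spike = spike, noise_sd = noise_sd,
         dropout = dropout, dropout_floor = dropout_floor,
         metabolic_fraction = metabolic_fraction,
         metabolic_genes = metabolic_genes,
         genes = genes, seed = as.integer(seed)),
    class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' Reads a YAML file whose keys match the arguments of [sim_config()].
#' The packaged default (`system.file("extdata", "sim_default.yaml",
#' package = "resistrank")`) mirrors the shape of the study this generator
#' emulates: 4 cohorts, a 10,000-gene universe with 1,321 metabolic genes,
#' 10 responders vs 10 non-responders per cohort.
#'
#' @param path Path to a YAML file.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `"sim_config"` object.
#' @export
read_sim_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  spike <- y$spike
  if (!is.null(spike)) spike <- unlist(spike)
  y$spike <- NULL
  args <- modifyList(y, list(...))
  do.call(sim_config, c(args, list(spike = spike)))
}

#' Simulate multi-cohort responder/non-responder expression data
#'
#' Generates `k` expression studies over a shared gene universe. Each
#' value is `baseline(gene) + batch(gene, study) + delta(gene, study) *
#' I(nonresponder) + noise`, so for spiked genes the non-responder group
#' mean exceeds the responder mean by `delta` on the log2 scale in
#' expectation. A truth table records exactly the spiked genes for
#' recovery tests.
#'
#' Spiked genes are always included in the metabolic set (the recovery
#' question the simulator serves is whether the pipeline finds them after
#' the metabolic filter); the remainder of the set is sampled uniformly.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"sim_cohorts"` with elements:
#'   \describe{
#'     \item{studies}{list of [expression_study()] objects;}
#'     \item{truth}{data.frame with one row per spiked gene: `gene`,
#'       per-study effect columns `delta_<study>`, and `is_metabolic`;}
#'     \item{metabolic_genes}{character vector of metabolic gene ids;}
#'     \item{config}{the configuration used.}
#'   }
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 50, n_studies = 2, n_responders = 3,
#'                   n_nonresponders = 3, spike = c(gene01 = 2), seed = 7)
#' sim <- simulate_cohorts(cfg)
#' sim$truth
simulate_cohorts <- function(config) {
  stop_if_not(inherits(config, "sim_config"), "`config` must come from sim_config()")
  genes <- config$genes
  G <- config$n_genes
  k <- config$n_studies
  with_seed(config$seed, {
    baseline <- rnorm(G, config$base_mean, config$base_sd)
    names(baseline) <- genes
    delta <- matrix(0, nrow = G, ncol = k, dimnames = list(genes, NULL))
    if (!is.null(config$spike)) delta[rownames(config$spike), ] <- config$spike
    studies <- vector("list", k)
    for (s in seq_len(k)) {
      n1 <- config$n_responders[s]
      n2 <- config$n_nonresponders[s]
      n <- n1 + n2
      batch <- rnorm(G, 0, config$batch_sd)
      mu <- baseline + batch
      m <- matrix(rnorm(G * n, sd = config$noise_sd), nrow = G) + mu
      m[, (n1 + 1):n] <- m[, (n1 + 1):n] + delta[, s]
      if (config$dropout > 0) {
        drop <- matrix(runif(G * n) < config$dropout, nrow = G)
        m[drop] <- config$dropout_floor
      }
      sid <- paste0("study", s)
      dimnames(m) <- list(genes, paste0(sid, "_s", seq_len(n)))
      studies[[s]] <- expression_study(
        m, rep(c("responder", "nonresponder"), c(n1, n2)), sid)
    }
    names(studies) <- vapply(studies, `[[`, "", "study_id")
    spiked <- rownames(config$spike) %||% character(0)
    if (!is.null(config$metabolic_genes)) {
      metabolic <- config$metabolic_genes
    } else {
      n_met <- round(config$metabolic_fraction * G)
      pool <- setdiff(genes, spiked)
      extra <- sample(pool, max(0L, min(n_met - length(spiked), length(pool))))
      metabolic <- union(spiked, extra)
    }
    truth <- data.frame(gene = spiked, stringsAsFactors = FALSE)
    if (length(spiked)) {
      d <- delta[spiked, , drop = FALSE]
      colnames(d) <- paste0("delta_study", seq_len(k))
      truth <- cbind(truth, as.data.frame(d))
      truth$is_metabolic <- spiked %in% metabolic
    }
    rownames(truth) <- NULL
    structure(list(studies = studies, truth = truth,
                   metabolic_genes = sort(metabolic), config = config),
              class = "sim_cohorts")
  })
}

#' @export
print.sim_cohorts <- function(x, ...) {
  cat(sprintf("Synthetic cohorts: %d studies x %d genes (%d metabolic, %d spiked)\n",
              length(x$studies), x$config$n_genes,
              length(x$metabolic_genes), nrow(x$truth)))
  invisible(x)
}

#' Hill concentration-response parameters
#'
#' Parameters of the Hill model `response(c) = baseline +
#' Emax * c^h / (EC50^h + c^h)` used both to simulate calcium
#' dose-response data and as the target of [fit_hill()]. Responses are on
#' the ionomycin-normalized scale, i.e. expressed as a fraction of the
#' maximal (ionophore) response of the same preparation.
#'
#' @param ec50 Half-maximal effective concentration in molar units, > 0.
#' @param h Hill coefficient (dimensionless), > 0.
#' @param emax Maximal normalized response, in `[0, 1.5]`.
#' @param baseline Normalized response at zero agonist.
#' @return An object of class `"hill_params"`.
#' @export
hill_params <- function(ec50, h = 1, emax = 1, baseline = 0) {
  stop_if_not(is.numeric(ec50) && length(ec50) == 1 && ec50 > 0, "`ec50` must be > 0")
  stop_if_not(is.numeric(h) && length(h) == 1 && h > 0, "`h` must be > 0")
  stop_if_not(is.numeric(emax) && emax >= 0 && emax <= 1.5,
              "`emax` must be in [0, 1.5]")
  stop_if_not(is.numeric(baseline) && is.finite(baseline), "`baseline` must be finite")
  structure(list(ec50 = ec50, h = h, emax = emax, baseline = baseline),
            class = "hill_params")
}

#' Evaluate the Hill model
#'
#' @param conc Vector of agonist concentrations (M); zeros allowed and map
#'   to the baseline.
#' @param params A [hill_params()] object.
#' @return Vector of noise-free responses.
#' @export
hill_response <- function(conc, params) {
  stop_if_not(inherits(params, "hill_params"), "`params` must come from hill_params()")
  stop_if_not(all(conc >= 0), "concentrations must be >= 0")
  ch <- conc^params$h
  params$baseline + params$emax * ch / (params$ec50^params$h + ch)
}

#' Default half-log concentration grid
#'
#' Eight half-log-spaced agonist concentrations starting at 1 nM (1 nM to
#' ~3.16 uM), the grid used for synthetic dose-response data.
#'
#' @return Numeric vector of concentrations in molar units.
#' @export
default_concentrations <- function() 10^seq(-9, -5.5, by = 0.5)

#' Simulate calcium dose-response data
#'
#' Draws replicated normalized peak responses from the Hill model with
#' additive Gaussian noise, emulating ionomycin-normalized Fura-2 peak
#' responses at a grid of agonist concentrations.
#'
#' @param params A [hill_params()] object.
#' @param concentrations Agonist concentrations (M); zero-concentration
#'   baseline points are allowed.
#' @param replicates Number of replicates per concentration.
#' @param noise_sd Gaussian noise SD on the normalized-response scale, >= 0.
#' @param seed Integer RNG seed.
#' @return data.frame with columns `concentration_M`, `replicate`,
#'   `response`.
#' @export
#' @examples
#' simulate_dose_response(hill_params(42e-9, emax = 0.8), seed = 1)
simulate_dose_response <- function(params,
                                   concentrations = default_concentrations(),
                                   replicates = 3, noise_sd = 0.05, seed = 1L) {
  stop_if_not(inherits(params, "hill_params"), "`params` must come from hill_params()")
  stop_if_not(all(concentrations >= 0), "concentrations must be >= 0")
  stop_if_not(is_count(replicates), "`replicates` must be a positive integer")
  stop_if_not(is.numeric(noise_sd) && noise_sd >= 0, "`noise_sd` must be >= 0")
  conc <- rep(concentrations, each = replicates)
  mu <- hill_response(conc, params)
  with_seed(seed, {
    resp <- mu + if (noise_sd > 0) rnorm(length(mu), 0, noise_sd) else 0
    data.frame(concentration_M = conc,
               replicate = rep(seq_len(replicates), times = length(concentrations)),
               response = resp)
  })
}
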