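#' Simulation configuration for synthetic expression data
#'
#' Defines both halves of the generator: (i) a reflective latent-factor
#' model (blocks of indicator genes reflecting hormone / transcription
#' factor / antioxidant pathway-activity latents, connected by a directed
#' acyclic structural graph) and (ii) a negative-binomial count model with
#' timepoint fold-change effects for differential-expression screening.
#'
#' The default topology is the mediation shape used throughout the package:
#' one hormone latent feeding three transcription-factor mediators and one
#' antioxidant outcome latent, with a direct hormone-to-antioxidant edge
#' (seven edges in total). Defaults: 4 timepoints x 3 replicates = 12
#' samples, 2000 background genes, NB baseline mean 100 with dispersion
#' 0.05 (variance = mu + alpha * mu^2), 10% DE genes at log2 fold-change 2,
#' outer loadings 0.85 with unit-variance indicators.
#'
#' @param n_samples Number of samples for the latent/indicator matrices.
#'   Defaults to `length(timepoints) * replicates`.
#' @param block_spec Named integer vector: indicator genes per latent block.
#' @param structural_edges Data frame with columns `from`, `to`, `coef`
#'   (standardized path coefficients in \[-1, 1\]); must be acyclic over the
#'   block names.
#' @param loadings Outer loadings in \[-1, 1\]: a scalar recycled to every
#'   indicator, or a named list giving one value (or one per indicator) per
#'   block.
#' @param indicator_noise_sd Indicator noise standard deviation. `NULL`
#'   (default) picks `sqrt(1 - loading^2)` per indicator so indicators have
#'   unit population variance.
#' @param n_genes Number of background genes in the count matrix.
#' @param count_baseline_mean Positive NB baseline mean.
#' @param count_dispersion Nonnegative NB dispersion alpha
#'   (variance = mu + alpha mu^2); 0 means Poisson.
#' @param de_fraction Fraction of background genes given a timepoint effect.
#' @param de_log2fc log2 fold-change applied at every non-control timepoint
#'   for DE genes.
#' @param timepoints Ordered timepoint labels; the first is the control.
#' @param replicates Replicates per timepoint.
#' @param seed Integer seed; every simulation operation is deterministic
#'   given the config seed.
#' @return A `SimulationConfig` list.
#' @examples
#' cfg <- sim_config(seed = 7)
#' cfg$block_spec
#' @export
sim_config <- function(n_samples = NULL,
                       block_spec = c(ABA = 10L, ICE1 = 3L, CBF = 3L,
                                      bZIP = 3L, AO = 10L),
                       structural_edges = default_structural_edges(),
                       loadings = 0.85,
                       indicator_noise_sd = NULL,
                       n_genes = 2000L,
                       count_baseline_mean = 100,
                       count_dispersion = 0.05,
                       de_fraction = 0.1,
                       de_log2fc = 2,
                       timepoints = c("0d", "4d", "8d", "12d"),
                       replicates = 3L,
                       seed = 1L) {
  if (is.null(n_samples)) n_samples <- length(timepoints) * replicates
  stopifnot(n_samples >= 1, replicates >= 1, length(timepoints) >= 1)
  blocks <- names(block_spec)
  if (is.null(blocks) || anyDuplicated(blocks)) {
    stop("block_spec must be a named vector with unique block names")
  }
  if (any(block_spec < 1)) stop("each block needs at least one indicator")
  ed <- as.data.frame(structural_edges, stringsAsFactors = FALSE)
  if (nrow(ed) && !all(c("from", "to", "coef") %in% names(ed))) {
    stop("structural_edges needs columns from, to, coef")
  }
  if (nrow(ed)) {
    if (!all(c(ed$from, ed$to) %in% blocks)) {
      stop("structural edge endpoint not in block_spec")
    }
    if (any(abs(ed$coef) > 1)) stop("|path coefficient| must be <= 1")
    if (!is_dag(blocks, ed)) stop("structural_edges must form a DAG")
  }
  lam <- expand_loadings(loadings, block_spec)
  if (any(abs(lam) > 1)) stop("|loading| must be <= 1")
  if (!is.null(indicator_noise_sd) && any(indicator_noise_sd < 0)) {
    stop("indicator_noise_sd must be nonnegative")
  }
  if (count_baseline_mean <= 0) stop("count_baseline_mean must be positive")
  if (count_dispersion < 0) stop("count_dispersion must be nonnegative")
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must be in [0,1]")
  cfg <- list(n_samples = as.integer(n_samples), block_spec = block_spec,
              structural_edges = ed, loadings = lam,
              indicator_noise_sd = indicator_noise_sd,
              n_genes = as.integer(n_genes),
              count_baseline_mean = count_baseline_mean,
              count_dispersion = count_dispersion,
              de_fraction = de_fraction, de_log2fc = de_log2fc,
              timepoints = timepoints, replicates = as.integer(replicates),
              seed = as.integer(seed))
  # fails early when the configured paths imply explained variance > 1
  implied_latent_cov(cfg)
  class(cfg) <- "SimulationConfig"
  cfg
}

#' @rdname sim_config
#' @export
default_structural_edges <- function() {
  # 0.5 on the first-order (hormone -> TF) edges, 0.3 on the second-order
  # (TF -> AO) edges and 0.2 on the direct hormone -> AO edge. The AO
  # latent has four correlated parents, so uniformly strong coefficients
  # would push its explained variance past 1; this graded profile keeps
  # every latent at unit variance with residual variance 0.375 for AO.
  data.frame(
    from = c("ABA", "ABA", "ABA", "ICE1", "CBF", "bZIP", "ABA"),
    to   = c("ICE1", "CBF", "bZIP", "AO", "AO", "AO", "AO"),
    coef = c(0.5, 0.5, 0.5, 0.3, 0.3, 0.3, 0.2),
    stringsAsFactors = FALSE
  )
}

# Expand scalar / per-block loadings into a named per-indicator vector.
expand_loadings <- function(loadings, block_spec) {
  ids <- indicator_ids(block_spec)
  if (is.numeric(loadings) && length(loadings) == 1L) {
    return(stats::setNames(rep(loadings, length(ids)), ids))
  }
  if (is.numeric(loadings) && length(loadings) == length(ids)) {
    return(stats::setNames(as.numeric(loadings), ids))
  }
  if (is.list(loadings)) {
    out <- numeric(0)
    for (b in names(block_spec)) {
      v <- loadings[[b]]
      if (is.null(v)) stop("no loadings given for block ", b)
      v <- rep_len(v, block_spec[[b]])
      out <- c(out, v)
    }
    return(stats::setNames(out, ids))
  }
  stop("loadings must be a scalar, a full vector, or a per-block list")
}

indicator_ids <- function(block_spec) {
  unlist(lapply(names(block_spec), function(b) {
    sprintf("%s_%02d", b, seq_len(block_spec[[b]]))
  }), use.names = FALSE)
}

#' Indicator gene annotation implied by a simulation config
#'
#' @param config A `SimulationConfig`.
#' @return Data frame with columns `gene`, `label` mapping each indicator
#'   gene to its latent block.
#' @export
indicator_annotation <- function(config) {
  bs <- config$block_spec
  data.frame(gene = indicator_ids(bs),
             label = rep(names(bs), bs),
             stringsAsFactors = FALSE)
}

# Implied covariance of the latents under the configured structural model,
# built in topological order with unit-variance latents: for each
# endogenous latent the residual variance is 1 - b' Sigma_pp b.
# Errors when explained variance exceeds 1.
implied_latent_cov <- function(config) {
  blocks <- names(config$block_spec)
  ed <- config$structural_edges
  ord <- topo_sort(blocks, ed)
  if (is.null(ord)) stop("structural_edges must form a DAG")
  L <- length(blocks)
  S <- matrix(0, L, L, dimnames = list(blocks, blocks))
  resid_var <- stats::setNames(numeric(L), blocks)
  for (j in ord) {
    parents <- ed$from[ed$to == j]
    if (!length(parents)) {
      S[j, j] <- 1
      resid_var[j] <- 1
      next
    }
    b <- ed$coef[ed$to == j]
    explained <- drop(t(b) %*% S[parents, parents, drop = FALSE] %*% b)
    if (explained > 1 + 1e-10) {
      stop(sprintf("explained variance of latent '%s' exceeds 1 (%.3f)",
                   j, explained))
    }
    resid_var[j] <- max(0, 1 - explained)
    for (k in blocks) {
      if (k == j) next
      S[j, k] <- S[k, j] <- sum(b * S[parents, k])
    }
    S[j, j] <- 1
  }
  list(cov = S, resid_var = resid_var, order = ord)
}

#' Simulate latent pathway-activity scores
#'
#' Exogenous latents are i.i.d. standard normal; each endogenous latent is
#' the coefficient-weighted sum of its parents plus Gaussian noise whose
#' variance is solved from the implied covariance so that every latent has
#' population variance 1. Configured paths are therefore directly
#' interpretable as standardized coefficients.
#'
#' @param config A `SimulationConfig`.
#' @return `n_samples` x latents numeric matrix (columns named by block).
#' @examples
#' cfg <- sim_config(n_samples = 200, seed = 3)
#' sc <- simulate_latents(cfg)
#' round(cor(sc), 2)
#' @export
simulate_latents <- function(config) {
  info <- implied_latent_cov(config)
  blocks <- names(config$block_spec)
  n <- config$n_samples
  ed <- config$structural_edges
  set.seed(config$seed)
  scores <- matrix(NA_real_, n, length(blocks),
                   dimnames = list(NULL, blocks))
  for (j in info$order) {
    parents <- ed$from[ed$to == j]
    noise <- rnorm(n, 0, sqrt(info$resid_var[j]))
    if (!length(parents)) {
      scores[, j] <- noise
    } else {
      b <- ed$coef[ed$to == j]
      scores[, j] <- scores[, parents, drop = FALSE] %*% b + noise
    }
  }
  scores
}

#' Simulate reflective indicator genes from latent scores
#'
#' Each indicator gene reflects its block latent:
#' `x = loading * latent + N(0, noise_sd^2)`. With the default
#' `indicator_noise_sd = NULL` the noise sd is `sqrt(1 - loading^2)`, so
#' indicators have unit population variance and configured loadings are
#' the population indicator-latent correlations.
#'
#' @param latents Matrix from [simulate_latents()].
#' @param config The same `SimulationConfig`.
#' @return `ExpressionMatrix` (mode `"log"`), genes x samples; gene IDs are
#'   `<block>_<k>` and carry their block in [indicator_annotation()].
#' @export
simulate_indicators <- function(latents, config) {
  bs <- config$block_spec
  lam <- config$loadings
  ids <- indicator_ids(bs)
  blocks_of <- rep(names(bs), bs)
  n <- nrow(latents)
  set.seed(config$seed + 1L)
  X <- matrix(NA_real_, length(ids), n, dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    l <- lam[[ids[i]]]
    sdk <- if (is.null(config$indicator_noise_sd)) {
      sqrt(max(0, 1 - l^2))
    } else {
      config$indicator_noise_sd
    }
    X[i, ] <- l * latents[, blocks_of[i]] + rnorm(n, 0, sdk)
  }
  colnames(X) <- sim_sample_ids(config, n)
  design <- sim_design(config, n)
  expression_matrix(X, design = design, mode = "log")
}

sim_sample_ids <- function(config, n) {
  full <- length(config$timepoints) * config$replicates
  if (n == full) {
    paste0(rep(config$timepoints, each = config$replicates), "_r",
           rep(seq_len(config$replicates), length(config$timepoints)))
  } else {
    paste0("s", seq_len(n))
  }
}

sim_design <- function(config, n) {
  full <- length(config$timepoints) * config$replicates
  if (n != full) return(NULL)
  data.frame(sample = sim_sample_ids(config, n),
             timepoint = rep(config$timepoints, each = config$replicates),
             replicate = rep(seq_len(config$replicates),
                             length(config$timepoints)),
             stringsAsFactors = FALSE)
}

#' Simulate a negative-binomial count matrix with timepoint effects
#'
#' Counts for gene g in sample s are NB with mean `mu * f` and dispersion
#' alpha (variance = mu + alpha mu^2; alpha = 0 draws Poisson), where
#' `f = 2^de_log2fc` at every non-control timepoint for DE genes and 1
#' otherwise. DE genes are sampled with probability `de_fraction`.
#'
#' @param config A `SimulationConfig` with at least 2 timepoints and 2
#'   replicates.
#' @param gene_ids Optional gene IDs (defaults to `g0001..`); extra genes
#'   in `force_de` are appended and always given the timepoint effect.
#' @param force_de Character vector of gene IDs (not necessarily in
#'   `gene_ids`) forced into the DE set; used by [simulate_dataset()] to
#'   embed the latent-model indicator genes in the count matrix.
#' @return List with `counts` (`ExpressionMatrix`, counts mode) and
#'   `de_genes` (character vector).
#' @examples
#' cfg <- sim_config(n_genes = 50, seed = 11)
#' cs <- simulate_counts(cfg)
#' length(cs$de_genes)
#' @export
simulate_counts <- function(config, gene_ids = NULL, force_de = character(0)) {
  if (length(config$timepoints) < 2) stop("need at least 2 timepoints")
  if (config$replicates < 2) stop("need at least 2 replicates")
  if (config$count_baseline_mean <= 0) stop("nonpositive baseline mean")
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  }
  gene_ids <- union(gene_ids, force_de)
  n_genes <- length(gene_ids)
  tp <- rep(config$timepoints, each = config$replicates)
  n <- length(tp)
  set.seed(config$seed + 2L)
  eligible <- setdiff(gene_ids, force_de)
  de <- eligible[stats::runif(length(eligible)) < config$de_fraction]
  de <- c(de, force_de)
  mu <- config$count_baseline_mean
  alpha <- config$count_dispersion
  f <- 2^config$de_log2fc
  treated <- tp != config$timepoints[1L]
  counts <- matrix(0L, n_genes, n,
                   dimnames = list(gene_ids, sim_sample_ids(config, n)))
  for (i in seq_len(n_genes)) {
    m <- rep(mu, n)
    if (gene_ids[i] %in% de) m[treated] <- mu * f
    counts[i, ] <- if (alpha == 0) {
      stats::rpois(n, m)
    } else {
      stats::rnbinom(n, mu = m, size = 1 / alpha)
    }
  }
  list(counts = expression_matrix(counts, design = sim_design(config, n),
                                  mode = "counts"),
       de_genes = sort(de))
}

#' Simulate a complete synthetic dataset with known truth
#'
#' Ties the two generator halves together into one coherent study: latent
#' scores and reflective indicator genes on the continuous (log) scale for
#' path modeling, and an NB count matrix for the differential-expression
#' screen. The indicator genes are embedded in the count matrix and forced
#' into the DE set so they survive the chilling-responsive-gene screen and
#' the pipeline is testable end to end.
#'
#' @param config A `SimulationConfig` whose `n_samples` equals
#'   `length(timepoints) * replicates`.
#' @return A `SyntheticDataset` list: `expression` (continuous indicators),
#'   `counts`, `true_scores`, `true_paths`, `true_loadings`, `de_genes`,
#'   `annotation`, `config`.
#' @export
simulate_dataset <- function(config) {
  full <- length(config$timepoints) * config$replicates
  if (config$n_samples != full) {
    stop("n_samples must equal |timepoints| * replicates for a full dataset")
  }
  scores <- simulate_latents(config)
  expr <- simulate_indicators(scores, config)
  cs <- simulate_counts(config, force_de = rownames(expr$values))
  ds <- list(expression = expr,
             counts = cs$counts,
             true_scores = scores,
             true_paths = config$structural_edges,
             true_loadings = config$loadings,
             de_genes = cs$de_genes,
             annotation = indicator_annotation(config),
             config = config)
  class(ds) <- "SyntheticDataset"
  ds
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf(
    "SyntheticDataset: %d indicator genes, %d count genes, %d samples, %d DE genes\n",
    nrow(x$expression$values), nrow(x$counts$values),
    ncol(x$counts$values), length(x$de_genes)))
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits `expression.tsv`, `counts.tsv`, `design.tsv`, `annotation.tsv`
#' and `truth.yaml` (paths, loadings, DE genes) under `dir`.
#'
#' @param ds A `SyntheticDataset`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             counts = file.path(dir, "counts.tsv"),
             design = file.path(dir, "design.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth.yaml"))
  write_expression_tsv(ds$expression, paths[["expression"]])
  write_expression_tsv(ds$counts, paths[["counts"]])
  write_design_tsv(ds$counts$design, paths[["design"]])
  utils::write.table(ds$annotation, paths[["annotation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(
    paths = lapply(seq_len(nrow(ds$true_paths)), function(i) {
      list(from = ds$true_paths$from[i], to = ds$true_paths$to[i],
           coef = ds$true_paths$coef[i])
    }),
    loadings = as.list(ds$true_loadings),
    de_genes = as.list(ds$de_genes))
  yaml::write_yaml(truth, paths[["truth"]])
  invisible(paths)
}

#' Simulate a qRT-PCR Ct table consistent with given log2 fold-changes
#'
#' Builds a synthetic two-condition Ct table (reference gene at a fixed
#' cycle threshold) in which the treated sample's target Ct is shifted by
#' `-(log2fc + noise)` cycles relative to the calibrator, so that 2^-ddCt
#' recovers the fold-change up to the configured noise.
#'
#' @param log2fc Named numeric vector of true log2 fold-changes per gene.
#' @param noise_sd Gaussian noise added to each gene's log2 fold-change on
#'   the Ct scale (cycles).
#' @param calibrator,treated Sample labels.
#' @param seed Integer seed.
#' @return Data frame with columns `gene`, `sample`, `ct_target`,
#'   `ct_reference` (a `CtTable` as consumed by [ddct()]).
#' @export
simulate_ct_table <- function(log2fc, noise_sd = 0.25,
                              calibrator = "C0d", treated = "L12d",
                              seed = 1L) {
  stopifnot(!is.null(names(log2fc)))
  set.seed(seed)
  genes <- names(log2fc)
  eps <- rnorm(length(genes), 0, noise_sd)
  rbind(
    data.frame(gene = genes, sample = calibrator,
               ct_target = 25, ct_reference = 20,
               stringsAsFactors = FALSE),
    data.frame(gene = genes, sample = treated,
               ct_target = 25 - (log2fc + eps), ct_reference = 20,
               stringsAsFactors = FALSE)
  )
}
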