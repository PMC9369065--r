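#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted
#' to genes with a positive geometric mean across samples, i.e. no zero
#' count) of the ratio `count_gs / geomean_g`. This is the standard
#' count-depth normalization for NB differential-expression testing.
#'
#' @param counts `ExpressionMatrix` in counts mode, or a counts matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @examples
#' m <- matrix(c(4L, 9L), 1, 2, dimnames = list("g1", c("a", "b")))
#' size_factors(expression_matrix(m, mode = "counts"))  # 4/6 and 9/6
#' @export
size_factors <- function(counts) {
  v <- as_values_matrix(counts)
  if (any(colSums(v) == 0)) stop("sample with all-zero counts")
  pos <- rowSums(v == 0) == 0L
  if (!any(pos)) stop("no gene with positive counts in every sample")
  geo <- exp(rowMeans(log(v[pos, , drop = FALSE])))
  sf <- apply(v[pos, , drop = FALSE] / geo, 2L, stats::median)
  stats::setNames(sf, colnames(v))
}

#' Method-of-moments NB dispersion for one gene
#'
#' `alpha = max(floor, (s^2 - xbar) / xbar^2)` from normalized counts,
#' under the convention variance = mu + alpha mu^2 (alpha = 0 is Poisson).
#'
#' @param x Numeric vector of normalized counts for one gene (>= 2 values).
#' @param floor Lower bound returned when the moment estimate is negative
#'   or zero (default 1e-8).
#' @return Nonnegative dispersion, or `NA` (with a warning) when the mean
#'   is zero and the dispersion is undefined.
#' @examples
#' estimate_dispersion(c(80, 100, 120))
#' @export
estimate_dispersion <- function(x, floor = 1e-8) {
  if (length(x) < 2) stop("need at least 2 samples")
  m <- mean(x)
  if (m == 0) {
    warning("zero mean: dispersion undefined; gene should be excluded")
    return(NA_real_)
  }
  max(floor, (stats::var(x) - m) / m^2)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: `adj_(i) = min_{j >= i} m * p_(j) / j`, clipped at
#' 1; ties share the adjusted value of their order statistic. Adjusted
#' values never fall below the raw p-value and are monotone in p.
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must be in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# Pooled two-group MoM dispersion per gene (vectorized over genes).
# Pooled within-group variance with n1+n2-2 df and count-weighted pooled
# mean, then alpha = (s2 - m) / m^2 floored. With 2-3 replicates per
# group the per-gene moment estimate is very noisy and its low tail
# inflates Wald statistics, so the value used for testing is the maximum
# of the per-gene estimate and the across-gene median ("maximum" sharing,
# the conservative information-sharing rule of early NB DE testing).
pooled_dispersion <- function(xc, xt, floor = 1e-8, share = TRUE) {
  n1 <- ncol(xc); n2 <- ncol(xt)
  m1 <- rowMeans(xc); m2 <- rowMeans(xt)
  v1 <- rowSums((xc - m1)^2) / (n1 - 1)
  v2 <- rowSums((xt - m2)^2) / (n2 - 1)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mp <- (n1 * m1 + n2 * m2) / (n1 + n2)
  alpha <- pmax(floor, (s2 - mp) / mp^2)
  if (share && length(alpha) > 1L) {
    alpha <- pmax(alpha, stats::median(alpha))
  }
  alpha
}

#' NB Wald test for one timepoint contrast
#'
#' Transparent negative-binomial Wald screen: counts are normalized by
#' median-of-ratios size factors; per gene,
#' `log2fc = log2((xbar_t + c) / (xbar_c + c))` with pseudocount `c`; the
#' standard error comes from the delta method with NB variance
#' `xbar + alpha xbar^2` at the pooled two-group method-of-moments
#' dispersion (per gene, taken as the maximum of the gene's pooled
#' moment estimate and the across-gene median, the conservative
#' "maximum" information-sharing rule that keeps the small-sample Wald
#' test from being anticonservative); two-sided p-values from the
#' standard normal; FDR by
#' [bh_adjust()] within the contrast. Genes with zero counts in every
#' tested sample are dropped (reported via a message and the
#' `n_dropped` attribute).
#'
#' @param counts `ExpressionMatrix` in counts mode with a design.
#' @param control_timepoint,treatment_timepoint Timepoint labels present
#'   in the design; both groups need >= 2 replicates.
#' @param pseudocount Added to group means before the log-ratio
#'   (default 0.5).
#' @param dispersion_floor Lower bound for the dispersion (default 1e-8).
#' @return Data frame (class `ContrastResult`) with columns `gene`,
#'   `mean_control`, `mean_treatment`, `log2fc`, `p_value`, `fdr`;
#'   attribute `contrast` carries the label.
#' @examples
#' cfg <- sim_config(n_genes = 100, seed = 5)
#' cs <- simulate_counts(cfg)
#' res <- test_contrast(cs$counts, "0d", "4d")
#' head(res)
#' @export
test_contrast <- function(counts, control_timepoint, treatment_timepoint,
                          pseudocount = 0.5, dispersion_floor = 1e-8) {
  stopifnot(inherits(counts, "ExpressionMatrix"), counts$mode == "counts")
  design <- counts$design
  if (is.null(design)) stop("counts must carry a sample design")
  cs <- design$sample[design$timepoint == control_timepoint]
  ts <- design$sample[design$timepoint == treatment_timepoint]
  if (length(cs) < 2 || length(ts) < 2) {
    stop("both groups need at least 2 replicates")
  }
  v <- counts$values[, c(cs, ts), drop = FALSE]
  sf <- size_factors(v)
  nv <- sweep(v, 2L, sf, "/")
  keep <- rowSums(nv) > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " gene(s) with all-zero counts dropped from testing")
  }
  nv <- nv[keep, , drop = FALSE]
  xc <- nv[, cs, drop = FALSE]
  xt <- nv[, ts, drop = FALSE]
  mc <- rowMeans(xc)
  mt <- rowMeans(xt)
  alpha <- pooled_dispersion(xc, xt, floor = dispersion_floor)
  lfc <- log2((mt + pseudocount) / (mc + pseudocount))
  var_mt <- (mt + alpha * mt^2) / length(ts)
  var_mc <- (mc + alpha * mc^2) / length(cs)
  se <- sqrt(var_mt / (mt + pseudocount)^2 +
             var_mc / (mc + pseudocount)^2) / log(2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  res <- data.frame(gene = rownames(nv),
                    mean_control = mc, mean_treatment = mt,
                    log2fc = lfc, p_value = p, fdr = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "contrast") <- paste(control_timepoint, "vs", treatment_timepoint)
  attr(res, "n_dropped") <- n_dropped
  class(res) <- c("ContrastResult", "data.frame")
  res
}

#' Screen differentially expressed genes
#'
#' A gene passes when `fdr <= fdr_max` and `|log2fc| >= min_abs_log2fc`
#' (both boundaries inclusive; fold-change >= 2 is |log2fc| >= 1).
#'
#' @param result A `ContrastResult` from [test_contrast()].
#' @param fdr_max FDR ceiling (default 0.01).
#' @param min_abs_log2fc Minimum absolute log2 fold-change (default 1).
#' @return Data frame of passing genes with columns `gene`, `log2fc`,
#'   `fdr`, `direction` (`"up"`/`"down"`); contrast label kept as an
#'   attribute.
#' @export
screen_degs <- function(result, fdr_max = 0.01, min_abs_log2fc = 1) {
  if (fdr_max <= 0 || min_abs_log2fc <= 0) {
    stop("thresholds must be positive")
  }
  pass <- result$fdr <= fdr_max & abs(result$log2fc) >= min_abs_log2fc
  out <- data.frame(gene = result$gene[pass],
                    log2fc = result$log2fc[pass],
                    fdr = result$fdr[pass],
                    direction = ifelse(result$log2fc[pass] >= 0, "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- attr(result, "contrast")
  out
}

#' Intersect per-contrast DEG sets into a chilling-responsive gene set
#'
#' Genes differentially expressed in every listed contrast; also reports
#' all Venn region sizes keyed by membership pattern (e.g. `"110"` = in
#' the first two sets only).
#'
#' @param deg_sets List (>= 2) of character vectors of gene IDs; names are
#'   used as contrast labels.
#' @return List of class `CRGSet` with elements `genes` (sorted
#'   intersection), `contrasts`, `venn` (named integer vector).
#' @examples
#' intersect_crgs(list(a = c("A", "B", "C"), b = c("B", "C", "D"),
#'                     c = c("B", "C", "E")))$genes
#' @export
intersect_crgs <- function(deg_sets) {
  if (length(deg_sets) < 2) stop("need at least 2 DEG sets")
  if (is.null(names(deg_sets))) {
    names(deg_sets) <- paste0("set", seq_along(deg_sets))
  }
  uni <- sort(unique(unlist(deg_sets)))
  membership <- vapply(deg_sets, function(s) uni %in% s, logical(length(uni)))
  if (length(uni) == 1L) membership <- matrix(membership, nrow = 1L)
  pattern <- apply(membership, 1L, function(r) paste(as.integer(r), collapse = ""))
  all_patterns <- apply(expand.grid(rep(list(c(1L, 0L)), length(deg_sets))),
                        1L, paste, collapse = "")
  all_patterns <- setdiff(all_patterns, strrep("0", length(deg_sets)))
  venn <- stats::setNames(integer(length(all_patterns)), all_patterns)
  tab <- table(pattern)
  venn[names(tab)] <- as.integer(tab)
  structure(list(genes = uni[rowSums(membership) == length(deg_sets)],
                 contrasts = names(deg_sets),
                 venn = venn),
            class = "CRGSet")
}

#' @export
print.CRGSet <- function(x, ...) {
  cat(sprintf("CRGSet: %d genes in all %d contrasts (%s)\n",
              length(x$genes), length(x$contrasts),
              paste(x$contrasts, collapse = "; ")))
  invisible(x)
}
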