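#' Relative quantification by the 2^-ddCt method
#'
#' Per gene and sample, `dCt = Ct_target - Ct_reference`; `ddCt` is taken
#' relative to the calibrator sample's dCt for the same gene; relative
#' expression is `2^-ddCt`, so the calibrator maps to exactly 1.
#' Technical replicates (duplicate gene/sample rows) are averaged on the
#' Ct scale before dCt.
#'
#' @param ct Data frame with columns `gene`, `sample`, `ct_target`,
#'   `ct_reference` (all Ct values finite).
#' @param calibrator Calibrator sample label; must be present for every
#'   gene.
#' @return Data frame with columns `gene`, `sample`, `delta_ct`,
#'   `delta_delta_ct`, `rel_expr`.
#' @examples
#' ct <- data.frame(gene = "g", sample = c("cal", "trt"),
#'                  ct_target = c(27, 25), ct_reference = c(20, 20))
#' ddct(ct, "cal")  # treated sample: ddCt = -2, rel_expr = 4
#' @export
ddct <- function(ct, calibrator) {
  need <- c("gene", "sample", "ct_target", "ct_reference")
  if (!all(need %in% names(ct))) {
    stop("ct table needs columns gene, sample, ct_target, ct_reference")
  }
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_reference))) {
    stop("Ct values must be finite")
  }
  # average technical replicates on the Ct scale
  agg <- stats::aggregate(cbind(ct_target, ct_reference) ~ gene + sample,
                          data = ct, FUN = mean)
  agg$delta_ct <- agg$ct_target - agg$ct_reference
  cal <- agg[agg$sample == calibrator, c("gene", "delta_ct")]
  names(cal)[2L] <- "dct_cal"
  missing_cal <- setdiff(unique(agg$gene), cal$gene)
  if (length(missing_cal)) {
    stop("missing calibrator row for gene(s): ",
         paste(missing_cal, collapse = ", "))
  }
  out <- merge(agg, cal, by = "gene", sort = FALSE)
  out$delta_delta_ct <- out$delta_ct - out$dct_cal
  out$rel_expr <- 2^(-out$delta_delta_ct)
  out <- out[order(out$gene, out$sample),
             c("gene", "sample", "delta_ct", "delta_delta_ct", "rel_expr")]
  rownames(out) <- NULL
  out
}

#' RNA-seq / qRT-PCR fold-change concordance regression
#'
#' Ordinary least squares of the qPCR log2 fold-changes on the RNA-seq
#' log2 fold-changes (qPCR on the y-axis), with the Pearson correlation
#' and its two-sided p-value from the t distribution with n - 2 degrees
#' of freedom. Genes are matched by name.
#'
#' @param log2fc_rnaseq,log2fc_qpcr Named numeric vectors of per-gene
#'   log2 fold-changes; at least 3 shared genes with finite values.
#' @return List of class `ConcordanceResult`: `slope`, `intercept`, `r`,
#'   `p`, `n`.
#' @examples
#' x <- c(a = 1, b = 2, c = 3); concordance(x, x)  # slope 1, r 1
#' @export
concordance <- function(log2fc_rnaseq, log2fc_qpcr) {
  if (is.null(names(log2fc_rnaseq)) || is.null(names(log2fc_qpcr))) {
    stop("fold-change vectors must be named by gene")
  }
  genes <- intersect(names(log2fc_rnaseq), names(log2fc_qpcr))
  x <- log2fc_rnaseq[genes]
  y <- log2fc_qpcr[genes]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 shared genes with finite values")
  if (stats::sd(x) == 0) stop("zero variance in RNA-seq fold-changes")
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r = unname(ct$estimate),
                 p = ct$p.value,
                 n = length(x)),
            class = "ConcordanceResult")
}

#' @export
print.ConcordanceResult <- function(x, ...) {
  cat(sprintf(
    "Concordance: slope = %.3f, intercept = %.3f, r = %.3f, p = %.3g, n = %d\n",
    x$slope, x$intercept, x$r, x$p, x$n))
  invisible(x)
}
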