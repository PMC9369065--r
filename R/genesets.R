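# Controlled vocabulary for gene-block labels: hormone signal-transduction
# classes, the three cold-response TF families, and the antioxidant system.
BLOCK_VOCABULARY <- c("ABA", "IAA", "CTK", "ETH", "BR", "GA", "JA", "SA",
                      "SL", "ICE1", "CBF", "bZIP", "AO")

#' Read a gene annotation TSV (gene, label)
#'
#' @param file TSV with columns `gene`, `label`; a gene may carry several
#'   labels on separate rows.
#' @return Data frame with unique (gene, label) rows.
#' @export
read_annotation_tsv <- function(file) {
  ann <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("gene", "label") %in% names(ann))) {
    stop("annotation needs columns gene, label")
  }
  unique(ann[, c("gene", "label")])
}

#' Partition a CRG set into annotated gene blocks
#'
#' Each chilling-responsive gene receives every label it carries in the
#' annotation; unlabeled CRGs go to `unassigned`. Labels outside the
#' controlled vocabulary (hormone classes, ICE1/CBF/bZIP, AO) are kept as
#' user-defined terms with a warning. Block order and within-block gene
#' order follow first appearance in the annotation (deterministic).
#'
#' @param crgs A `CRGSet` or character vector of gene IDs.
#' @param annotation Data frame with columns `gene`, `label`.
#' @return List of class `GeneSetPartition`: `blocks` (named list of gene
#'   vectors) and `unassigned` (character vector).
#' @examples
#' ann <- data.frame(gene = c("g1", "g2", "g2"),
#'                   label = c("ABA", "JA", "AO"))
#' assign_blocks(c("g1", "g2", "g3"), ann)
#' @export
assign_blocks <- function(crgs, annotation) {
  genes <- if (inherits(crgs, "CRGSet")) crgs$genes else crgs
  ann <- unique(annotation[, c("gene", "label")])
  unknown <- setdiff(unique(ann$label), BLOCK_VOCABULARY)
  if (length(unknown)) {
    warning("label(s) outside the controlled vocabulary kept as user-defined: ",
            paste(unknown, collapse = ", "))
  }
  ann <- ann[ann$gene %in% genes, , drop = FALSE]
  blocks <- list()
  for (i in seq_len(nrow(ann))) {
    blocks[[ann$label[i]]] <- c(blocks[[ann$label[i]]], ann$gene[i])
  }
  assigned <- unique(ann$gene)
  structure(list(blocks = blocks,
                 unassigned = setdiff(genes, assigned)),
            class = "GeneSetPartition")
}

#' @export
print.GeneSetPartition <- function(x, ...) {
  cat("GeneSetPartition:",
      paste(sprintf("%s=%d", names(x$blocks), lengths(x$blocks)),
            collapse = ", "),
      sprintf("| unassigned=%d\n", length(x$unassigned)))
  invisible(x)
}

#' Hypergeometric over-representation test across annotation labels
#'
#' For each label, the upper-tail hypergeometric probability of observing
#' at least the overlap between the selected genes and the label's genes,
#' given the universe; BH adjustment across labels. Labels with no genes
#' in the universe get p = 1 by convention.
#'
#' @param selected Character vector of selected genes (subset of
#'   `universe`).
#' @param universe Character vector of background genes.
#' @param annotation Data frame with columns `gene`, `label`.
#' @return Data frame with columns `label`, `overlap`, `label_size`,
#'   `selected_size`, `universe_size`, `expected`, `p`, `fdr`.
#' @examples
#' ann <- data.frame(gene = paste0("g", 1:5), label = "AO")
#' ora_hypergeometric(paste0("g", 1:5), paste0("g", 1:20), ann)
#' @export
ora_hypergeometric <- function(selected, universe, annotation) {
  selected <- unique(selected)
  universe <- unique(universe)
  if (!all(selected %in% universe)) stop("selected must be a subset of universe")
  labels <- unique(annotation$label)
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(labels, function(lab) {
    set <- intersect(annotation$gene[annotation$label == lab], universe)
    K <- length(set)
    k <- length(intersect(set, selected))
    p <- if (K == 0L) 1 else stats::phyper(k - 1L, K, N - K, n,
                                           lower.tail = FALSE)
    data.frame(label = lab, overlap = k, label_size = K,
               selected_size = n, universe_size = N,
               expected = n * K / N, p = min(1, p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out[order(out$p, out$label), , drop = FALSE]
}

#' Row-wise Z-score normalization
#'
#' Per gene row: `(x - mean) / sd` with the sample sd (denominator n-1),
#' the transform used for expression heatmaps and as the default input to
#' path modeling. Constant rows are mapped to all zeros and flagged via
#' the `constant_rows` attribute (with a message).
#'
#' @param matrix An `ExpressionMatrix` (or plain matrix) with >= 2 samples.
#' @return `ExpressionMatrix` in zscore mode (or a plain matrix if given
#'   one), same dimensions.
#' @examples
#' m <- matrix(c(1, 2, 3), 1, 3, dimnames = list("g1", paste0("s", 1:3)))
#' zscore_rows(m)
#' @export
zscore_rows <- function(matrix) {
  v <- as_values_matrix(matrix)
  if (ncol(v) < 2) stop("need at least 2 samples")
  mu <- rowMeans(v)
  s <- sqrt(rowSums((v - mu)^2) / (ncol(v) - 1))
  const <- s == 0
  if (any(const)) {
    message(sum(const), " constant row(s) set to zero in Z-score output")
    s[const] <- 1
  }
  z <- (v - mu) / s
  z[const, ] <- 0
  if (inherits(matrix, "ExpressionMatrix")) {
    out <- expression_matrix(z, design = matrix$design, mode = "zscore")
    attr(out, "constant_rows") <- rownames(v)[const]
    out
  } else {
    attr(z, "constant_rows") <- rownames(v)[const]
    z
  }
}
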