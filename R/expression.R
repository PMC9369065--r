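#' Gene-by-sample expression matrix with sample design
#'
#' Lightweight container pairing a numeric genes x samples matrix with a
#' per-sample design table (timepoint, replicate). `mode` records what the
#' values are: raw `"counts"`, `"fpkm"`, continuous `"log"`-scale expression,
#' or row-standardized `"zscore"` values.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene IDs, unique),
#'   samples in columns (colnames = sample IDs, unique).
#' @param design Data frame with columns `sample`, `timepoint`, `replicate`,
#'   one row per column of `values` (matched by `sample`). May be `NULL` for
#'   matrices without a timepoint design (e.g. plain latent-recovery input).
#' @param mode One of `"counts"`, `"fpkm"`, `"log"`, `"zscore"`. Counts must
#'   be nonnegative integers.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `design`, `mode`.
#' @examples
#' m <- matrix(rpois(12, 10), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' em <- expression_matrix(m, mode = "counts")
#' dim(em$values)
#' @export
expression_matrix <- function(values, design = NULL,
                              mode = c("counts", "fpkm", "log", "zscore")) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene IDs")
  if (anyDuplicated(colnames(values))) stop("duplicate sample IDs")
  if (mode == "counts") {
    if (any(values < 0) || any(values != round(values))) {
      stop("counts mode requires nonnegative integer values")
    }
  }
  if (!is.null(design)) {
    need <- c("sample", "timepoint", "replicate")
    if (!all(need %in% names(design))) {
      stop("design must have columns sample, timepoint, replicate")
    }
    if (!setequal(design$sample, colnames(values))) {
      stop("design samples do not match matrix columns")
    }
    design <- design[match(colnames(values), design$sample), , drop = FALSE]
    rownames(design) <- NULL
  }
  structure(list(values = values, design = design, mode = mode),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d genes x %d samples\n",
              x$mode, nrow(x$values), ncol(x$values)))
  if (!is.null(x$design)) {
    cat("timepoints:", paste(unique(x$design$timepoint), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

as_values_matrix <- function(x) {
  if (inherits(x, "ExpressionMatrix")) x$values else x
}

#' Write / read a gene x sample TSV
#'
#' First column `gene_id`, remaining columns one per sample. Counts
#' round-trip exactly; continuous values round-trip to full printed
#' precision (15 significant digits).
#'
#' @param em An `ExpressionMatrix`.
#' @param file Path of the TSV to write or read.
#' @return `write_expression_tsv` returns `file` invisibly;
#'   `read_expression_tsv` returns an `ExpressionMatrix`.
#' @export
write_expression_tsv <- function(em, file) {
  v <- as_values_matrix(em)
  df <- data.frame(gene_id = rownames(v),
                   format(v, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (inherits(em, "ExpressionMatrix") && em$mode == "counts") {
    df <- data.frame(gene_id = rownames(v), v,
                     check.names = FALSE, stringsAsFactors = FALSE)
  }
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @param design_file Optional design TSV (columns sample, timepoint,
#'   replicate) to attach.
#' @param mode Value mode of the matrix being read.
#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(file, design_file = NULL,
                                mode = c("counts", "fpkm", "log", "zscore")) {
  mode <- match.arg(mode)
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  design <- if (!is.null(design_file)) read_design_tsv(design_file) else NULL
  expression_matrix(m, design = design, mode = mode)
}

#' Write / read the sample design TSV (sample, timepoint, replicate)
#' @param design Data frame with columns sample, timepoint, replicate.
#' @param file Path to write to / read from.
#' @export
write_design_tsv <- function(design, file) {
  utils::write.table(design, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `FPKM_gs = count_gs * 1e9 / (length_g * total_s)` with `total_s` the
#' per-sample count sum.
#'
#' @param counts `ExpressionMatrix` in counts mode.
#' @param gene_lengths_bp Named numeric vector of transcript lengths in bp,
#'   covering every gene in `counts`; all lengths must be positive.
#' @return `ExpressionMatrix` in fpkm mode.
#' @examples
#' m <- matrix(c(100L, 50L), 1, 2,
#'             dimnames = list("g1", c("s1", "s2")))
#' # the per-sample totals equal the single gene's counts here
#' fpkm(expression_matrix(m, mode = "counts"), c(g1 = 1000))
#' @export
fpkm <- function(counts, gene_lengths_bp) {
  stopifnot(inherits(counts, "ExpressionMatrix"), counts$mode == "counts")
  v <- counts$values
  lens <- gene_lengths_bp[rownames(v)]
  if (anyNA(lens)) stop("missing gene lengths")
  if (any(lens <= 0)) stop("zero or negative length gene")
  totals <- colSums(v)
  if (any(totals <= 0)) stop("sample with nonpositive total count")
  out <- sweep(v * 1e9 / lens, 2L, totals, "/")
  expression_matrix(out, design = counts$design, mode = "fpkm")
}
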