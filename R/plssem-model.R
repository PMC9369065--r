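#' Define a PLS path model
#'
#' Latent variables are reflective (Mode A) blocks of indicator genes
#' connected by a directed acyclic structural graph.
#'
#' @param latents Named list: latent name -> character vector of indicator
#'   gene IDs (>= 1 each; no indicator may appear in two latents).
#' @param edges Data frame with columns `from`, `to` (latent names);
#'   must form a DAG.
#' @param scheme Inner weighting scheme: `"path"` (default; regression
#'   weights toward predecessors, correlations toward successors),
#'   `"centroid"` (sign of the score correlation) or `"factorial"` (the
#'   score correlation).
#' @return Object of class `PathModel`.
#' @examples
#' m <- path_model(list(H = c("h1", "h2"), T = c("t1", "t2")),
#'                 data.frame(from = "H", to = "T"))
#' m$scheme
#' @export
path_model <- function(latents, edges,
                       scheme = c("path", "centroid", "factorial")) {
  scheme <- match.arg(scheme)
  if (is.null(names(latents)) || anyDuplicated(names(latents))) {
    stop("latents must be a uniquely named list")
  }
  if (any(lengths(latents) < 1L)) stop("every latent needs >= 1 indicator")
  all_ind <- unlist(latents, use.names = FALSE)
  if (anyDuplicated(all_ind)) {
    stop("an indicator may not be shared between latents")
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(edges))) {
    stop("edges needs columns from, to")
  }
  if (!all(c(edges$from, edges$to) %in% names(latents))) {
    stop("edge endpoint is not a declared latent")
  }
  if (anyDuplicated(edges[, c("from", "to")])) stop("duplicate edge")
  if (!is_dag(names(latents), edges)) stop("edges must form a DAG")
  structure(list(latents = lapply(latents, as.character),
                 edges = edges[, c("from", "to")],
                 scheme = scheme),
            class = "PathModel")
}

#' @export
print.PathModel <- function(x, ...) {
  cat(sprintf("PathModel: %d latents, %d edges, scheme = %s\n",
              length(x$latents), nrow(x$edges), x$scheme))
  for (nm in names(x$latents)) {
    cat(sprintf("  %s (%d indicators)\n", nm, length(x$latents[[nm]])))
  }
  invisible(x)
}

#' Read a path-model specification from YAML
#'
#' Expected layout:
#' ```yaml
#' latents:
#'   - name: ABA
#'     indicators: [ABA_01, ABA_02]
#' edges:
#'   - {from: ABA, to: AO}
#' scheme: path
#' ```
#'
#' @param file Path to the YAML file.
#' @return A `PathModel`.
#' @export
read_path_model <- function(file) {
  y <- yaml::read_yaml(file)
  lat <- stats::setNames(
    lapply(y$latents, function(l) unlist(l$indicators)),
    vapply(y$latents, function(l) l$name, character(1)))
  edges <- do.call(rbind, lapply(y$edges, function(e) {
    data.frame(from = e$from, to = e$to, stringsAsFactors = FALSE)
  }))
  path_model(lat, edges, scheme = y$scheme %||% "path")
}

#' Write a path-model specification to YAML
#' @param model A `PathModel`.
#' @param file Output path.
#' @export
write_path_model <- function(model, file) {
  y <- list(
    latents = lapply(names(model$latents), function(nm) {
      list(name = nm, indicators = as.list(model$latents[[nm]]))
    }),
    edges = lapply(seq_len(nrow(model$edges)), function(i) {
      list(from = model$edges$from[i], to = model$edges$to[i])
    }),
    scheme = model$scheme)
  yaml::write_yaml(y, file)
  invisible(file)
}

#' Path model implied by a simulation config
#'
#' Convenience constructor building the `PathModel` whose latents are the
#' generator's blocks (with their indicator gene IDs) and whose edges are
#' the generator's structural edges.
#'
#' @param config A `SimulationConfig`.
#' @param scheme Inner weighting scheme.
#' @return A `PathModel`.
#' @export
model_from_config <- function(config, scheme = "path") {
  ann <- indicator_annotation(config)
  lat <- split(ann$gene, factor(ann$label, levels = names(config$block_spec)))
  path_model(lat, config$structural_edges[, c("from", "to")], scheme = scheme)
}

#' Export a fitted path diagram to Graphviz DOT
#'
#' Edge width is proportional to the absolute path coefficient; positive
#' effects are drawn red and negative effects blue.
#'
#' @param fit A `PLSFit` from [fit_pls()].
#' @param file Output path for the DOT text file.
#' @return `file`, invisibly.
#' @export
export_dot <- function(fit, file) {
  pc <- fit$path_coefficients
  lines <- c("digraph pls_model {",
             "  rankdir=LR;",
             "  node [shape=ellipse, fontsize=11];")
  for (nm in names(fit$model$latents)) {
    lines <- c(lines, sprintf("  \"%s\";", nm))
  }
  for (i in seq_len(nrow(pc))) {
    col <- if (pc$estimate[i] >= 0) "red" else "blue"
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [label=\"%.3f\", color=%s, penwidth=%.2f];",
      pc$from[i], pc$to[i], pc$estimate[i], col,
      0.5 + 3 * abs(pc$estimate[i])))
  }
  lines <- c(lines, "}")
  writeLines(lines, file)
  invisible(file)
}
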