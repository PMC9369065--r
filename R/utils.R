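# Internal helpers shared across modules.

# Kahn topological sort. `edges` is a data.frame with columns from/to.
# Returns the node order, or NULL when the graph contains a cycle.
topo_sort <- function(nodes, edges) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(edges)) {
    tab <- table(factor(edges$to, levels = nodes))
    indeg[names(tab)] <- as.integer(tab)
  }
  queue <- nodes[indeg == 0L]
  order <- character(0)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    order <- c(order, v)
    if (nrow(edges)) {
      for (w in edges$to[edges$from == v]) {
        indeg[w] <- indeg[w] - 1L
        if (indeg[w] == 0L) queue <- c(queue, w)
      }
    }
  }
  if (length(order) != length(nodes)) return(NULL)
  order
}

is_dag <- function(nodes, edges) !is.null(topo_sort(nodes, edges))

# Column standardization with the population (1/n) standard deviation.
# Pinned so latent scores are bit-stable; correlations and standardized
# regression coefficients are invariant to the 1/n vs 1/(n-1) choice.
scale_pop <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  s <- sqrt(colSums(Xc^2) / n)
  if (any(s == 0)) {
    stop("constant column(s): ", paste(colnames(X)[s == 0], collapse = ", "))
  }
  sweep(Xc, 2L, s, "/")
}

# Population standard deviation of a vector.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
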