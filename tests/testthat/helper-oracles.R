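# Independent brute-force oracles, kept deliberately naive and separate
# from the package's implementation paths.

# BH step-up by its definition: adj_(i) = min(1, min_{j >= i} m p_(j) / j),
# computed with an explicit double loop over the sorted vector.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    adj_sorted[i] <- min(1, best)
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Upper-tail hypergeometric probability P(X >= k) by direct summation of
# binomial-coefficient ratios.
hyper_tail_bruteforce <- function(k, K, N, n) {
  if (K == 0) return(1)
  t <- k:min(K, n)
  sum(choose(K, t) * choose(N - K, n - t)) / choose(N, n)
}

# All directed paths from `from` to `to` in an edge list; returns the sum
# over multi-edge paths of the product of coefficients plus the direct one.
enumerate_effects <- function(edges, from, to) {
  paths <- list()
  walk <- function(node, prod, len) {
    out <- edges[edges$from == node, , drop = FALSE]
    for (i in seq_len(nrow(out))) {
      p2 <- prod * out$estimate[i]
      if (out$to[i] == to) {
        paths[[length(paths) + 1L]] <<- list(prod = p2, len = len + 1L)
      } else {
        walk(out$to[i], p2, len + 1L)
      }
    }
  }
  walk(from, 1, 0L)
  direct <- sum(vapply(paths, function(p) if (p$len == 1L) p$prod else 0,
                       numeric(1)))
  indirect <- sum(vapply(paths, function(p) if (p$len > 1L) p$prod else 0,
                         numeric(1)))
  list(direct = direct, indirect = indirect, total = direct + indirect)
}

# Random DAG over nodes v1..vk (edges only forward in index order).
random_dag_edges <- function(k, p_edge = 0.4) {
  nodes <- paste0("v", seq_len(k))
  combs <- utils::combn(k, 2)
  keep <- stats::runif(ncol(combs)) < p_edge
  data.frame(from = nodes[combs[1, keep]],
             to = nodes[combs[2, keep]],
             estimate = stats::runif(sum(keep), -0.9, 0.9),
             stringsAsFactors = FALSE)
}

# Draw 7 coefficients for the mediation-shaped DAG, redrawing until the
# configuration keeps every latent's explained variance below 1.
draw_feasible_paths <- function(lim = 0.7) {
  repeat {
    ed <- default_structural_edges()
    ed$coef <- stats::runif(7, -lim, lim)
    ok <- tryCatch({
      sim_config(n_samples = 10, structural_edges = ed)
      TRUE
    }, error = function(e) FALSE)
    if (ok) return(ed)
  }
}

# Two-latent, single-indicator-each model.
bivariate_model <- function() {
  path_model(list(X = "x1", Y = "y1"), data.frame(from = "X", to = "Y"))
}
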