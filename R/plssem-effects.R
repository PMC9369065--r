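#' Direct, indirect and total effects on the structural DAG
#'
#' For every ordered latent pair, the direct effect is the edge
#' coefficient (0 without an edge), the indirect effect is the sum over
#' all directed multi-edge paths of the product of their edge
#' coefficients, and the total effect is their sum. On a DAG the power
#' series of the coefficient matrix terminates, so the enumeration is
#' exact: with B the (latent x latent) path-coefficient matrix, total
#' effects are `B + B^2 + ... + B^(L-1)`.
#'
#' In the mediation topology used throughout the package (one hormone
#' latent, three TF mediators, one antioxidant outcome) this reduces to
#' the classic decomposition: indirect = a1*b1 + a2*b2 + a3*b3 on top of
#' the direct hormone -> antioxidant edge.
#'
#' @param fit A `PLSFit`, or a data frame with columns `from`, `to`,
#'   `estimate` (a path-coefficient table).
#' @param model A `PathModel`; defaults to `fit$model` when `fit` is a
#'   `PLSFit`.
#' @return Data frame (class `EffectTable`) with columns `from`, `to`,
#'   `direct`, `indirect`, `total` for every ordered pair of distinct
#'   latents.
#' @examples
#' pc <- data.frame(from = c("H", "T", "H"), to = c("T", "A", "A"),
#'                  estimate = c(0.5, 0.4, 0.2))
#' m <- path_model(list(H = "h", T = "t", A = "a"), pc[, 1:2])
#' pls_effects(pc, m)  # indirect H->A = 0.2, total = 0.4
#' @export
pls_effects <- function(fit, model = NULL) {
  if (inherits(fit, "PLSFit")) {
    pc <- fit$path_coefficients
    model <- model %||% fit$model
  } else {
    pc <- as.data.frame(fit, stringsAsFactors = FALSE)
    if (is.null(model)) stop("a PathModel is required with a coefficient table")
  }
  lat <- names(model$latents)
  if (!is_dag(lat, model$edges)) stop("cyclic model")
  L <- length(lat)
  B <- matrix(0, L, L, dimnames = list(lat, lat))
  for (i in seq_len(nrow(pc))) {
    B[pc$from[i], pc$to[i]] <- pc$estimate[i]
  }
  total <- B
  acc <- B
  k <- 1L
  while (k < L) {
    acc <- acc %*% B
    if (all(acc == 0)) break
    total <- total + acc
    k <- k + 1L
  }
  pairs <- expand.grid(from = lat, to = lat, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  out <- data.frame(
    from = pairs$from, to = pairs$to,
    direct = B[cbind(pairs$from, pairs$to)],
    indirect = total[cbind(pairs$from, pairs$to)] -
      B[cbind(pairs$from, pairs$to)],
    stringsAsFactors = FALSE, row.names = NULL)
  out$total <- out$direct + out$indirect
  class(out) <- c("EffectTable", "data.frame")
  out
}
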