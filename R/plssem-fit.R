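#' Fit a PLS path model (Lohmöller iteration, Mode A)
#'
#' From-scratch partial least squares path modeling. Indicator columns are
#' standardized (population sd); outer weights start at 1; the algorithm
#' alternates (a) outer estimation — each latent score is the standardized
#' weighted sum of its indicators — and (b) inner estimation under the
#' chosen scheme. Under the path weighting scheme the inner weight of a
#' predecessor is its multiple-OLS coefficient from regressing the latent's
#' score on all predecessor scores, and the inner weight of a successor is
#' the score correlation; the centroid and factorial schemes use the sign
#' of, respectively the value of, the score correlation for every
#' neighbor. Outer weights are then updated Mode A style as
#' indicator-proxy correlations. Iteration stops when the largest absolute
#' change of the unit-norm outer weight vectors falls below `tol`.
#'
#' After convergence, scores are re-standardized, each latent is flipped
#' if its loading sum is negative (deterministic sign orientation),
#' loadings are indicator-score correlations, and path coefficients come
#' from per-endogenous-latent OLS of its score on its predecessors'
#' scores (standardized coefficients), which also yields the R² values.
#'
#' @param data Indicator data: an `ExpressionMatrix` (genes x samples) or
#'   a plain samples x indicators matrix with indicator column names.
#'   Every model indicator must be present and non-constant; `n >= 3`.
#' @param model A [path_model()].
#' @param tol Convergence tolerance on outer weight change (default 1e-7).
#' @param max_iter Maximum iterations (default 300); non-convergence is
#'   flagged, with partial results returned.
#' @param scheme Optional override of the model's inner weighting scheme.
#' @return Object of class `PLSFit`: `outer_weights`, `loadings` (data
#'   frames with latent/indicator/estimate), `scores` (samples x latents,
#'   mean 0 variance 1), `path_coefficients` (from/to/estimate),
#'   `r_squared`, `ave`, `composite_reliability` (named vectors),
#'   `n_iterations`, `converged`, `n`, `model`.
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- 0.7 * x + rnorm(50, 0, 0.7)
#' d <- cbind(h1 = x, t1 = y)
#' m <- path_model(list(H = "h1", T = "t1"), data.frame(from = "H", to = "T"))
#' f <- fit_pls(d, m)
#' all.equal(f$path_coefficients$estimate, cor(x, y))
#' @export
fit_pls <- function(data, model, tol = 1e-7, max_iter = 300, scheme = NULL) {
  stopifnot(inherits(model, "PathModel"))
  scheme <- scheme %||% model$scheme
  scheme <- match.arg(scheme, c("path", "centroid", "factorial"))
  X <- pls_data_matrix(data, model)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples")
  lat_names <- names(model$latents)
  L <- length(lat_names)
  blocks <- lapply(model$latents, function(ind) match(ind, colnames(X)))
  parents <- lapply(lat_names, function(j) model$edges$from[model$edges$to == j])
  children <- lapply(lat_names, function(j) model$edges$to[model$edges$from == j])
  names(parents) <- names(children) <- lat_names
  max_pred <- max(c(0L, lengths(parents)))
  if (n < max_pred + 1L) {
    stop("n_samples must exceed the largest number of predecessors")
  }
  p_total <- ncol(X)
  if (n < p_total) {
    warning(sprintf(
      "low-n regime: %d samples for %d indicators; PLS estimates rest on poorly determined correlations",
      n, p_total))
  }

  X <- scale_pop(X)
  w <- lapply(blocks, function(ix) rep(1, length(ix)))
  w_norm_old <- lapply(w, function(v) v / sqrt(sum(v^2)))
  Y <- matrix(0, n, L, dimnames = list(NULL, lat_names))
  for (j in seq_len(L)) {
    Y[, j] <- standardize_vec(X[, blocks[[j]], drop = FALSE] %*% w[[j]])
  }

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    C <- crossprod(Y) / n
    E <- matrix(0, L, L, dimnames = list(lat_names, lat_names))
    for (j in seq_len(L)) {
      nm <- lat_names[j]
      pr <- parents[[nm]]
      ch <- children[[nm]]
      nb <- c(pr, ch)
      if (!length(nb)) next
      if (scheme == "path") {
        if (length(pr)) {
          E[pr, j] <- solve(C[pr, pr, drop = FALSE], C[pr, nm])
        }
        if (length(ch)) E[ch, j] <- C[ch, nm]
      } else if (scheme == "centroid") {
        E[nb, j] <- sign(C[nb, nm])
      } else {
        E[nb, j] <- C[nb, nm]
      }
    }
    Z <- Y %*% E
    for (j in seq_len(L)) {
      # isolated latent: proxy falls back to its own score
      if (all(E[, j] == 0)) Z[, j] <- Y[, j]
      Z[, j] <- standardize_vec(Z[, j])
    }
    delta <- 0
    for (j in seq_len(L)) {
      ix <- blocks[[j]]
      w_new <- crossprod(X[, ix, drop = FALSE], Z[, j]) / n  # Mode A
      w[[j]] <- drop(w_new)
      wn <- w[[j]] / sqrt(sum(w[[j]]^2))
      delta <- max(delta, max(abs(wn - w_norm_old[[j]])))
      w_norm_old[[j]] <- wn
      Y[, j] <- standardize_vec(X[, ix, drop = FALSE] %*% w[[j]])
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("PLS iteration did not converge in ", max_iter,
            " iterations; returning partial results")
  }

  # loadings + deterministic sign orientation (flip latent if sum < 0)
  loadings <- vector("list", L)
  for (j in seq_len(L)) {
    ix <- blocks[[j]]
    lam <- drop(crossprod(X[, ix, drop = FALSE], Y[, j])) / n
    if (sum(lam) < 0) {
      Y[, j] <- -Y[, j]
      w[[j]] <- -w[[j]]
      lam <- -lam
    }
    loadings[[j]] <- lam
  }

  C <- crossprod(Y) / n
  paths <- model$edges
  paths$estimate <- NA_real_
  r2 <- stats::setNames(rep(NA_real_, L), lat_names)
  for (nm in lat_names) {
    pr <- parents[[nm]]
    if (!length(pr)) next
    b <- solve(C[pr, pr, drop = FALSE], C[pr, nm])
    paths$estimate[paths$to == nm] <- b[match(paths$from[paths$to == nm], pr)]
    r2[nm] <- drop(crossprod(b, C[pr, nm]))
  }

  lam_all <- unlist(loadings, use.names = FALSE)
  ave <- vapply(loadings, function(l) mean(l^2), numeric(1))
  cr <- vapply(loadings, function(l) {
    s <- sum(l)^2
    s / (s + sum(1 - l^2))
  }, numeric(1))
  names(ave) <- names(cr) <- lat_names

  fit <- list(
    outer_weights = data.frame(
      latent = rep(lat_names, lengths(blocks)),
      indicator = unlist(model$latents, use.names = FALSE),
      estimate = unlist(w, use.names = FALSE),
      stringsAsFactors = FALSE),
    loadings = data.frame(
      latent = rep(lat_names, lengths(blocks)),
      indicator = unlist(model$latents, use.names = FALSE),
      estimate = lam_all,
      stringsAsFactors = FALSE),
    scores = Y,
    path_coefficients = paths,
    r_squared = r2,
    ave = ave,
    composite_reliability = cr,
    n_iterations = iter,
    converged = converged,
    n = n,
    scheme = scheme,
    model = model)
  class(fit) <- "PLSFit"
  fit
}

standardize_vec <- function(v) {
  v <- v - mean(v)
  s <- sqrt(mean(v^2))
  if (s == 0) stop("degenerate (constant) latent score")
  v / s
}

# Accept ExpressionMatrix (genes x samples) or samples x indicators matrix;
# returns samples x indicators restricted to the model's indicators.
pls_data_matrix <- function(data, model) {
  need <- unlist(model$latents, use.names = FALSE)
  if (inherits(data, "ExpressionMatrix")) {
    miss <- setdiff(need, rownames(data$values))
    if (length(miss)) stop("indicator(s) missing from data: ",
                           paste(miss, collapse = ", "))
    return(t(data$values[need, , drop = FALSE]))
  }
  data <- as.matrix(data)
  miss <- setdiff(need, colnames(data))
  if (length(miss)) stop("indicator(s) missing from data: ",
                         paste(miss, collapse = ", "))
  data[, need, drop = FALSE]
}

#' @export
print.PLSFit <- function(x, ...) {
  cat(sprintf("PLSFit: %d latents, n = %d, scheme = %s, %s in %d iteration(s)\n",
              length(x$model$latents), x$n, x$scheme,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  print(x$path_coefficients)
  invisible(x)
}

#' Average variance extracted (AVE)
#'
#' Mean of the squared outer loadings of a latent's indicators; the
#' conventional convergent-validity metric (adequate measurement is
#' usually read as AVE >= 0.5).
#'
#' @param fit A `PLSFit`.
#' @param latent Latent name; `NULL` returns the vector for all latents.
#' @return AVE value(s) in \[0, 1\].
#' @examples
#' # loadings (0.8, 0.6) give AVE (0.64 + 0.36) / 2 = 0.5
#' @export
pls_ave <- function(fit, latent = NULL) {
  if (is.null(latent)) return(fit$ave)
  if (!latent %in% names(fit$ave)) stop("unknown latent: ", latent)
  fit$ave[[latent]]
}

#' Composite reliability
#'
#' `(sum lambda)^2 / ((sum lambda)^2 + sum(1 - lambda^2))` over a latent's
#' loadings; companion internal-consistency metric to [pls_ave()].
#'
#' @inheritParams pls_ave
#' @return Composite reliability value(s) in \[0, 1\].
#' @export
composite_reliability <- function(fit, latent = NULL) {
  if (is.null(latent)) return(fit$composite_reliability)
  if (!latent %in% names(fit$composite_reliability)) {
    stop("unknown latent: ", latent)
  }
  fit$composite_reliability[[latent]]
}

#' Convergent-validity report for a fitted model
#'
#' Flags every latent whose AVE falls below `ave_min` (inclusive pass at
#' the boundary), alongside composite reliability and the loadings.
#'
#' @param fit A `PLSFit`.
#' @param ave_min AVE threshold (default 0.5).
#' @return Data frame with columns `latent`, `n_indicators`, `ave`,
#'   `composite_reliability`, `min_loading`, `pass`.
#' @export
validate_model <- function(fit, ave_min = 0.5) {
  lat <- names(fit$ave)
  min_load <- vapply(lat, function(nm) {
    min(fit$loadings$estimate[fit$loadings$latent == nm])
  }, numeric(1))
  data.frame(latent = lat,
             n_indicators = lengths(fit$model$latents)[lat],
             ave = fit$ave[lat],
             composite_reliability = fit$composite_reliability[lat],
             min_loading = min_load,
             pass = fit$ave[lat] >= ave_min,
             stringsAsFactors = FALSE, row.names = NULL)
}
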