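#' Bootstrap inference for a PLS path model
#'
#' Resamples sample rows with replacement, refits the model on each
#' resample, aligns signs, and summarizes every parameter (outer weights,
#' loadings, path coefficients) with its bootstrap mean, standard error,
#' t value (original / SE), two-sided p-value on the normal reference,
#' and percentile confidence interval.
#'
#' Sign policies address the sign indeterminacy of latent scores across
#' resamples:
#' \describe{
#'   \item{individual}{each bootstrap outer weight and loading whose sign
#'     differs from the original estimate is flipped individually; each
#'     construct is then re-oriented by the majority vote of its aligned
#'     loadings, and path coefficients are recomputed under those
#'     construct orientations (coefficient times source and target flips).}
#'   \item{construct}{each construct is flipped as a whole when the
#'     majority of its loadings disagree in sign with the original
#'     estimates; paths follow the construct flips.}
#'   \item{none}{raw bootstrap estimates.}
#' }
#' Resamples whose fit fails (e.g. a constant indicator column after
#' resampling) or does not converge are dropped and counted.
#'
#' @param data Indicator data as in [fit_pls()].
#' @param model A [path_model()].
#' @param B Number of bootstrap resamples (>= 2; default 5000).
#' @param sign_policy `"individual"` (default), `"construct"` or `"none"`.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param conf_level Percentile CI level (default 0.95).
#' @param tol,max_iter Passed to [fit_pls()].
#' @return Object of class `BootstrapSummary`: `summary` (data frame with
#'   columns `type`, `latent`/`from`, `indicator`/`to`, `original`,
#'   `boot_mean`, `se`, `t`, `p`, `ci_lower`, `ci_upper`), plus
#'   `B`, `B_effective`, `n_failed`, `sign_policy`, `conf_level`, `seed`
#'   and the original `fit`.
#' @export
bootstrap_pls <- function(data, model, B = 5000,
                          sign_policy = c("individual", "construct", "none"),
                          seed = 1L, conf_level = 0.95,
                          tol = 1e-7, max_iter = 300) {
  sign_policy <- match.arg(sign_policy)
  if (B < 2) stop("B must be >= 2")
  fit0 <- fit_pls(data, model, tol = tol, max_iter = max_iter)
  X <- pls_data_matrix(data, model)
  n <- nrow(X)
  lat_names <- names(model$latents)
  lat_of_ind <- fit0$loadings$latent
  p <- nrow(fit0$loadings)
  ne <- nrow(fit0$path_coefficients)

  w0 <- fit0$outer_weights$estimate
  l0 <- fit0$loadings$estimate
  b0 <- fit0$path_coefficients$estimate

  Wb <- matrix(NA_real_, B, p)
  Lb <- matrix(NA_real_, B, p)
  Pb <- matrix(NA_real_, B, ne)
  set.seed(seed)
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    fb <- tryCatch(
      suppressWarnings(fit_pls(X[idx, , drop = FALSE], model,
                               tol = tol, max_iter = max_iter)),
      error = function(e) NULL)
    if (is.null(fb) || !fb$converged) {
      n_failed <- n_failed + 1L
      next
    }
    wb <- fb$outer_weights$estimate
    lb <- fb$loadings$estimate
    pb <- fb$path_coefficients$estimate
    if (sign_policy != "none") {
      if (sign_policy == "individual") {
        flip_ind <- ifelse(sign(lb) * sign(l0) < 0, -1, 1)
        lb <- lb * flip_ind
        wb <- wb * ifelse(sign(fb$outer_weights$estimate) * sign(w0) < 0, -1, 1)
        # construct orientation by majority of the alignment flips
        constr <- vapply(lat_names, function(nm) {
          v <- sum(flip_ind[lat_of_ind == nm])
          if (v < 0) -1 else 1
        }, numeric(1))
      } else {
        constr <- vapply(lat_names, function(nm) {
          agree <- sum(sign(lb[lat_of_ind == nm]) * sign(l0[lat_of_ind == nm]))
          if (agree < 0) -1 else 1
        }, numeric(1))
        flip_ind <- constr[lat_of_ind]
        lb <- lb * flip_ind
        wb <- wb * flip_ind
      }
      pb <- pb * constr[fit0$path_coefficients$from] *
        constr[fit0$path_coefficients$to]
    }
    Wb[b, ] <- wb
    Lb[b, ] <- lb
    Pb[b, ] <- pb
  }
  if (n_failed == B) stop("all bootstrap resamples failed to fit")

  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  summarize <- function(orig, mat) {
    se <- apply(mat, 2L, stats::sd, na.rm = TRUE)
    tval <- ifelse(se > 0, orig / se, ifelse(orig == 0, 0, Inf))
    ci <- apply(mat, 2L, stats::quantile, probs = probs, na.rm = TRUE)
    data.frame(original = orig,
               boot_mean = colMeans(mat, na.rm = TRUE),
               se = se,
               t = tval,
               p = 2 * stats::pnorm(-abs(tval)),
               ci_lower = ci[1L, ],
               ci_upper = ci[2L, ],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  sw <- cbind(data.frame(type = "outer_weight",
                         latent = fit0$outer_weights$latent,
                         indicator = fit0$outer_weights$indicator,
                         from = NA_character_, to = NA_character_,
                         stringsAsFactors = FALSE),
              summarize(w0, Wb))
  sl <- cbind(data.frame(type = "loading",
                         latent = fit0$loadings$latent,
                         indicator = fit0$loadings$indicator,
                         from = NA_character_, to = NA_character_,
                         stringsAsFactors = FALSE),
              summarize(l0, Lb))
  sp <- cbind(data.frame(type = "path",
                         latent = NA_character_, indicator = NA_character_,
                         from = fit0$path_coefficients$from,
                         to = fit0$path_coefficients$to,
                         stringsAsFactors = FALSE),
              summarize(b0, Pb))
  structure(list(summary = rbind(sw, sl, sp),
                 B = B, B_effective = B - n_failed, n_failed = n_failed,
                 sign_policy = sign_policy, conf_level = conf_level,
                 seed = seed, fit = fit0),
            class = "BootstrapSummary")
}

#' @export
print.BootstrapSummary <- function(x, ...) {
  cat(sprintf(
    "BootstrapSummary: B = %d (%d effective, %d failed), sign policy = %s\n",
    x$B, x$B_effective, x$n_failed, x$sign_policy))
  print(x$summary[x$summary$type == "path",
                  c("from", "to", "original", "se", "t", "p",
                    "ci_lower", "ci_upper")])
  invisible(x)
}
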