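# Model comparison: saturated/independence reference fits, RMSEA/CFI/AIC/BIC,
# likelihood-ratio tests, bootstrap percentile intervals, and the
# general-factor indices of fitted source-specific loading structures.

#' Saturated reference fit
#'
#' Maximum-likelihood fit of an unstructured symmetric covariance matrix per
#' zygosity (means fixed at 0, the residualized-data convention). With
#' complete data the MLE is the observed second-moment matrix; with missing
#' data it is found by an EM algorithm on the missingness patterns.
#'
#' @param data a [twin_data] object.
#' @param max_iter,tol EM iteration cap and -2LL convergence tolerance.
#' @return a `twin_fit`-like list: `minus2LL`, `n_free_params`,
#'   `n_pairs_used`, `converged`, `kind = "saturated"`, and the fitted
#'   `sigma_mz`, `sigma_dz`.
#' @export
fit_saturated <- function(data, max_iter = 500L, tol = 1e-6) {
  Y <- pair_matrix(data)
  p2 <- ncol(Y)
  mu <- numeric(p2)
  out <- list(kind = "saturated",
              n_free_params = 2L * p2 * (p2 + 1L) / 2L,
              minus2LL = 0, n_pairs_used = 0L, converged = TRUE)
  for (zyg in c("MZ", "DZ")) {
    rows <- data$pairs$zygosity == zyg
    pats <- build_patterns(Y[rows, , drop = FALSE])
    N <- sum(vapply(pats, `[[`, 0, "n"))
    out$n_pairs_used <- out$n_pairs_used + N
    if (N == 0L) next
    # start: observed second moments, missing entries imputed from diagonal
    sigma <- diag(p2)
    cnt <- matrix(0, p2, p2)
    acc <- matrix(0, p2, p2)
    for (pat in pats) {
      acc[pat$obs, pat$obs] <- acc[pat$obs, pat$obs] + pat$CP
      cnt[pat$obs, pat$obs] <- cnt[pat$obs, pat$obs] + pat$n
    }
    sigma <- acc / pmax(cnt, 1)
    diag(sigma)[diag(cnt) == 0] <- 1
    ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
    sigma <- ev$vectors %*% (pmax(ev$values, 1e-6) * t(ev$vectors))
    complete <- length(pats) == 1L && length(pats[[1L]]$obs) == p2
    if (complete) {
      sigma <- pats[[1L]]$CP / N
      m2 <- m2ll_patterns(pats, sigma, mu)$value
    } else {
      m2_old <- Inf
      for (it in seq_len(max_iter)) {
        # E-step: expected complete-data second moments
        Tm <- matrix(0, p2, p2)
        for (pat in pats) {
          o <- pat$obs
          mis <- setdiff(seq_len(p2), o)
          Soo_inv <- chol2inv(chol(sigma[o, o, drop = FALSE]))
          Tm[o, o] <- Tm[o, o] + pat$CP
          if (length(mis)) {
            B <- sigma[mis, o, drop = FALSE] %*% Soo_inv
            Tmo <- B %*% pat$CP
            Tm[mis, o] <- Tm[mis, o] + Tmo
            Tm[o, mis] <- Tm[o, mis] + t(Tmo)
            Vm <- sigma[mis, mis, drop = FALSE] -
              sigma[mis, o, drop = FALSE] %*% Soo_inv %*%
              sigma[o, mis, drop = FALSE]
            Tm[mis, mis] <- Tm[mis, mis] + B %*% pat$CP %*% t(B) + pat$n * Vm
          }
        }
        sigma <- (Tm + t(Tm)) / (2 * N)
        m2 <- m2ll_patterns(pats, sigma, mu)$value
        if (abs(m2_old - m2) < tol) break
        m2_old <- m2
      }
      if (it == max_iter) out$converged <- FALSE
    }
    out$minus2LL <- out$minus2LL + m2
    out[[if (zyg == "MZ") "sigma_mz" else "sigma_dz"]] <- sigma
  }
  class(out) <- "twin_fit"
  out
}

#' Independence (baseline) reference fit
#'
#' Diagonal covariance per zygosity with free variances, zero cross-twin
#' covariance, means fixed at 0. The FIML MLE is closed form: each variance
#' is the mean square of the observed values of that coordinate.
#'
#' @param data a [twin_data] object.
#' @return a `twin_fit`-like list (`kind = "independence"`).
#' @export
fit_independence <- function(data) {
  Y <- pair_matrix(data)
  p2 <- ncol(Y)
  out <- list(kind = "independence", n_free_params = 2L * p2,
              minus2LL = 0, n_pairs_used = 0L, converged = TRUE)
  for (zyg in c("MZ", "DZ")) {
    rows <- data$pairs$zygosity == zyg
    Yz <- Y[rows & rowSums(!is.na(Y)) > 0, , drop = FALSE]
    out$n_pairs_used <- out$n_pairs_used + nrow(Yz)
    if (!nrow(Yz)) next
    v <- colMeans(Yz^2, na.rm = TRUE)
    v[!is.finite(v) | v <= 0] <- 1
    nobs <- colSums(!is.na(Yz))
    ssq <- colSums(Yz^2, na.rm = TRUE)
    out$minus2LL <- out$minus2LL +
      sum(nobs * (log(2 * pi) + log(v))) + sum(ssq / v)
    out[[if (zyg == "MZ") "sigma_mz" else "sigma_dz"]] <- diag(v, p2)
  }
  class(out) <- "twin_fit"
  out
}

#' Fit statistics relative to saturated and independence models
#'
#' Computes the five conventional statistics. With `chi2 = -2LL_model -
#' (-2LL_saturated)` and `df = k_saturated - k_model`:
#' `RMSEA = sqrt(max(0, chi2 - df) / (df (N - 1)))`;
#' `CFI = 1 - max(0, chi2 - df) / max(chi2_b - df_b, chi2 - df, 0)` with `b`
#' the independence baseline; `AIC = -2LL + 2k`; `BIC = -2LL + k log(N)`.
#' `N` is the number of twin pairs contributing data (the pair is the
#' independent sampling unit).
#'
#' @param fit,saturated_fit,independence_fit `twin_fit` objects on the same
#'   data.
#' @param N sample-size convention; defaults to `fit$n_pairs_used`.
#' @return object of class `fit_statistics` with fields `minus2LL`, `aic`,
#'   `bic`, `rmsea`, `cfi`, `df`, `chi2_vs_saturated`, `k`, `N`.
#' @export
fit_statistics <- function(fit, saturated_fit, independence_fit,
                           N = fit$n_pairs_used) {
  chi2 <- max(0, fit$minus2LL - saturated_fit$minus2LL)
  df <- saturated_fit$n_free_params - fit$n_free_params
  if (df <= 0) stop("model has no fewer parameters than the saturated model")
  chi2_b <- max(0, independence_fit$minus2LL - saturated_fit$minus2LL)
  df_b <- saturated_fit$n_free_params - independence_fit$n_free_params
  num <- max(0, chi2 - df)
  den <- max(chi2_b - df_b, chi2 - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  k <- fit$n_free_params
  structure(list(
    minus2LL = fit$minus2LL,
    aic = fit$minus2LL + 2 * k,
    bic = fit$minus2LL + k * log(N),
    rmsea = sqrt(num / (df * (N - 1))),
    cfi = min(max(cfi, 0), 1),
    df = df, chi2_vs_saturated = chi2, k = k, N = N
  ), class = "fit_statistics")
}

#' @export
print.fit_statistics <- function(x, ...) {
  cat(sprintf(
    "RMSEA = %.3f  CFI = %.3f  -2LL = %.1f  AIC = %.1f  BIC = %.1f (df = %d)\n",
    x$rmsea, x$cfi, x$minus2LL, x$aic, x$bic, x$df))
  invisible(x)
}

#' Likelihood-ratio test of nested twin models
#'
#' @param full,nested `twin_fit` objects; `nested` must be the same family
#'   and structure with a subset of the full model's variance components.
#' @return list with `delta_chi2` (clipped at 0), `delta_df`, `p_value`.
#' @export
lrt <- function(full, nested) {
  if (!is.null(full$spec) && !is.null(nested$spec)) {
    same <- identical(full$spec$family, nested$spec$family) &&
      identical(full$spec$structure$group_of, nested$spec$structure$group_of)
    subset_ok <- all(strsplit(nested$spec$components, "")[[1L]] %in%
                       strsplit(full$spec$components, "")[[1L]])
    if (!same || !subset_ok) stop("models are not nested")
  }
  delta_df <- full$n_free_params - nested$n_free_params
  if (delta_df < 0) stop("nested model has more free parameters than the full model")
  delta <- max(0, nested$minus2LL - full$minus2LL)
  p <- if (delta_df == 0) as.numeric(delta == 0) else
    stats::pchisq(delta, delta_df, lower.tail = FALSE)
  list(delta_chi2 = delta, delta_df = delta_df, p_value = p)
}

#' Bootstrap percentile confidence intervals for twin-model statistics
#'
#' Resamples twin pairs with replacement within zygosity strata, refits the
#' model (starting from the point estimate to cut runtime), and returns
#' 2.5/97.5 percentile intervals of the selected statistics. Replicates that
#' fail to converge are dropped with a count; the result is flagged when
#' more than 5% were dropped.
#'
#' @param data a [twin_data] object.
#' @param spec a [model_spec].
#' @param B number of bootstrap replicates (>= 2).
#' @param seed integer seed (resampling is bit-reproducible given it).
#' @param statistic function mapping a `twin_fit` to a named numeric vector.
#' @param fit optional precomputed point-estimate fit.
#' @param level confidence level (default 0.95).
#' @param ... passed to [fit_model()] for the replicate fits.
#' @return list with `estimate`, `lower`, `upper`, `level`, `B`,
#'   `n_dropped`, `flagged`, and the replicate matrix `replicates`.
#' @export
bootstrap_ci <- function(data, spec, B = 1000L, seed = 1L, statistic,
                         fit = NULL, level = 0.95, ...) {
  if (B < 2L) stop("B must be >= 2")
  dots <- list(...)
  fit <- fit %||% do.call(fit_model, c(list(data, spec), dots))
  dots$n_starts <- NULL   # replicates always single-start from the estimate
  dots$start <- NULL
  est <- statistic(fit)
  idx_mz <- which(data$pairs$zygosity == "MZ")
  idx_dz <- which(data$pairs$zygosity == "DZ")
  set.seed(seed)
  reps <- matrix(NA_real_, B, length(est),
                 dimnames = list(NULL, names(est)))
  dropped <- 0L
  for (b in seq_len(B)) {
    take <- c(sample(idx_mz, length(idx_mz), replace = TRUE),
              sample(idx_dz, length(idx_dz), replace = TRUE))
    bd <- data
    bd$pairs <- data$pairs[take, ]
    bd$pairs$pair_id <- as.character(seq_len(nrow(bd$pairs)))
    rf <- tryCatch(
      do.call(fit_model,
              c(list(bd, spec, start = fit$params, n_starts = 1L), dots)),
      error = function(e) NULL)
    if (is.null(rf) || !rf$converged) {
      dropped <- dropped + 1L
      next
    }
    reps[b, ] <- statistic(rf)
  }
  ok <- stats::complete.cases(reps)
  a <- (1 - level) / 2
  qs <- apply(reps[ok, , drop = FALSE], 2L, stats::quantile,
              probs = c(a, 1 - a), names = FALSE)
  list(estimate = est, lower = stats::setNames(qs[1L, ], names(est)),
       upper = stats::setNames(qs[2L, ], names(est)), level = level,
       B = B, n_dropped = dropped, flagged = dropped > 0.05 * B,
       replicates = reps[ok, , drop = FALSE])
}

#' Standardized source-specific loading matrices of an IP fit
#'
#' Divides each source loading by the model-implied item standard deviation,
#' putting all three bifactor structures on the unit-item-variance metric.
#'
#' @param fit a `twin_fit` from an IP-family model.
#' @return list with loading matrices `A`, `C`, `E` and vector `unique_var`
#'   (standardized item-unique variance, all sources pooled).
#' @export
standardized_source_loadings <- function(fit) {
  if (fit$spec$family != "ip") stop("source loadings require an IP-family fit")
  p <- fit$params
  v <- rowSums(unclass(p$lambda_a)^2) + rowSums(unclass(p$lambda_c)^2) +
    rowSums(unclass(p$lambda_e)^2) + rowSums(p$unique_paths^2)
  sd <- sqrt(v)
  st <- p$structure
  list(A = loading_matrix(unclass(p$lambda_a) / sd, st),
       C = loading_matrix(unclass(p$lambda_c) / sd, st),
       E = loading_matrix(unclass(p$lambda_e) / sd, st),
       unique_var = rowSums(p$unique_paths^2) / v,
       unique_var_by_source = cbind(A = p$unique_paths[, "a"]^2 / v,
                                    C = p$unique_paths[, "c"]^2 / v,
                                    E = p$unique_paths[, "e"]^2 / v))
}

#' General-factor indices per variance source of an IP fit
#'
#' Applies omega-hierarchical, the H-index and ECV to the standardized A, C
#' and E loading structures of a fitted bifactor independent pathway model.
#' Each source is treated as its own bifactor solution: the omega
#' denominator is that source's composite variance (its general and group
#' factor column sums plus its own item-unique variance), so each omega
#' asks "how coherent a general dimension does this source carry?"
#' independently of the source's overall magnitude. ECV is computed within
#' each source's common variance. Cutoffs (omega_h > 0.5, H > 0.7) and
#' pass/fail flags are attached.
#'
#' @param fit a `twin_fit` from an IP-family model.
#' @param cutoffs named vector with elements `omega_h` and `h`.
#' @return named list of `index_report` objects (`A`, `C`, `E`).
#' @export
twin_bifactor_indices <- function(fit, cutoffs = c(omega_h = 0.5, h = 0.7)) {
  if (fit$spec$family != "ip") {
    stop("per-source indices are undefined for CP-family fits")
  }
  std <- standardized_source_loadings(fit)
  out <- lapply(c(A = "A", C = "C", E = "E"), function(s) {
    L <- unclass(std[[s]])
    L <- pmin(pmax(L, -0.999), 0.999)
    rep <- index_report(L, uniquenesses = std$unique_var_by_source[, s],
                        label = paste0(s, " source"), cutoffs = cutoffs)
    rep
  })
  out
}
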