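# Phenotypic bifactor workflow: Direct Schmid-Leiman estimation and the
# general-factor reliability indices (omega-hierarchical, H, ECV).

# Squared multiple correlations, the usual communality start for principal
# axis extraction. Falls back to max |r| per row when R is near-singular.
smc <- function(R) {
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv)) {
    h <- apply(abs(R - diag(diag(R))), 1L, max)
  } else {
    h <- 1 - 1 / diag(inv)
  }
  pmin(pmax(h, 0), 0.995)
}

# Oblique quartimin rotation (oblimin with gamma = 0) by the gradient
# projection algorithm of Jennrich (2002). Returns the rotated pattern and
# the factor correlation matrix. Several starts guard against the saddle
# points that bifactor-structured data produce for rotation criteria.
quartimin_rotate <- function(A, n_starts = 10L, max_iter = 500L, tol = 1e-6) {
  m <- ncol(A)
  N <- matrix(1, m, m) - diag(m)
  crit <- function(L) {
    L2 <- L^2
    list(f = sum(L2 * (L2 %*% N)) / 4, Gq = L * (L2 %*% N))
  }
  run <- function(Tm) {
    al <- 1
    Ti <- solve(Tm)
    L <- A %*% t(Ti)
    cv <- crit(L)
    f <- cv$f
    G <- -t(t(L) %*% cv$Gq %*% Ti)
    for (it in seq_len(max_iter)) {
      Gp <- G - Tm %*% diag(colSums(Tm * G), m)
      s <- sqrt(sum(Gp^2))
      if (s < tol) break
      al <- 2 * al
      repeat {
        X <- Tm - al * Gp
        Tt <- X %*% diag(1 / sqrt(colSums(X^2)), m)
        Ti <- solve(Tt)
        L <- A %*% t(Ti)
        cv <- crit(L)
        if (cv$f < f - 0.5 * s^2 * al || al < 1e-12) break
        al <- al / 2
      }
      Tm <- Tt
      f <- cv$f
      G <- -t(t(L) %*% cv$Gq %*% Ti)
    }
    list(loadings = L, Phi = t(Tm) %*% Tm, f = f)
  }
  best <- run(diag(m))
  for (s in seq_len(n_starts - 1L)) {
    Tm <- qr.Q(qr(matrix(stats::rnorm(m * m), m, m)))
    cand <- run(Tm)
    if (cand$f < best$f) best <- cand
  }
  best
}

# Principal-axis factor extraction: iterate communalities on the reduced
# correlation matrix. Returns n x m unrotated loadings.
pa_extract <- function(R, m, max_iter = 500L, tol = 1e-7) {
  n <- nrow(R)
  h2 <- smc(R)
  L <- NULL
  for (it in seq_len(max_iter)) {
    Rh <- R
    diag(Rh) <- h2
    e <- eigen(Rh, symmetric = TRUE)
    d <- pmax(e$values[seq_len(m)], 0)
    L <- e$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(d), m)
    h2_new <- pmin(rowSums(L^2), 0.999)
    delta <- max(abs(h2_new - h2))
    h2 <- h2_new
    if (delta < tol) break
  }
  # communality cycling within ~1e-4 is harmless for the later rotation steps
  if (it == max_iter && delta > 1e-4) {
    warning("principal-axis extraction did not fully converge")
  }
  L
}

#' Direct Schmid-Leiman bifactor estimation
#'
#' Estimates an orthogonal bifactor loading pattern (one general factor plus
#' `m` group factors) from a correlation matrix in four steps: (i) extract
#' `m` factors and rotate obliquely to a pattern `P` with factor correlations
#' `Phi`; (ii) fit a one-factor solution to `Phi`, giving second-order
#' loadings `gamma`; (iii) form the classic Schmid-Leiman target,
#' general = `P gamma`, groups = `P diag(sqrt(1 - gamma^2))`; (iv) extract
#' `m + 1` unrotated factors and rotate them orthogonally (Procrustes) onto
#' that target. Group-factor columns are matched to the structure's groups,
#' every column is sign-flipped to a nonnegative sum, and structural zeros
#' are imposed on the returned matrix (the unconstrained solution, with
#' cross-loadings, is kept in attribute `"raw"`).
#'
#' @param R symmetric positive semi-definite correlation matrix with unit
#'   diagonal.
#' @param structure a [bifactor_structure] with `nrow(R)` items.
#' @return a [loading_matrix]; attribute `"raw"` holds the pre-zeroing
#'   loadings needed to check subscale assignment.
#' @export
fit_dsl_bifactor <- function(R, structure) {
  R <- as.matrix(R)
  n <- structure$n_items
  m <- structure$n_groups
  stopifnot(nrow(R) == n, ncol(R) == n)
  if (max(abs(R - t(R))) > 1e-8 || max(abs(diag(R) - 1)) > 1e-8) {
    stop("R must be a symmetric correlation matrix with unit diagonal")
  }
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("R is not positive semi-definite")
  }
  # degenerate case: no common variance at all
  if (max(abs(R[upper.tri(R)])) < 1e-12) {
    return(loading_matrix(matrix(0, n, m + 1L), structure))
  }
  # (i) m-factor oblique solution (quartimin over principal-axis extraction)
  L1 <- pa_extract(R, m)
  rot <- quartimin_rotate(L1)
  P <- rot$loadings
  Phi <- rot$Phi
  # sign convention before the second-order step
  flip <- sign(colSums(P))
  flip[flip == 0] <- 1
  P <- sweep(P, 2L, flip, `*`)
  Phi <- diag(flip) %*% Phi %*% diag(flip)
  # (ii) second-order loadings from the factor correlations
  if (m == 2L) {
    gamma <- rep(sqrt(max(Phi[1L, 2L], 0)), 2L)
  } else {
    gamma <- as.numeric(pa_extract(stats::cov2cor(Phi), 1L))
    gamma <- abs(gamma)
  }
  gamma <- pmin(gamma, 0.999)
  # (iii) Schmid-Leiman target
  target <- cbind(P %*% gamma, P %*% diag(sqrt(1 - gamma^2), m))
  # (iv) full-rank extraction + orthogonal Procrustes onto the target
  L2 <- pa_extract(R, m + 1L)
  sv <- svd(crossprod(L2, target))
  B <- L2 %*% (sv$u %*% t(sv$v))
  # column 1 is the general factor by target construction; match each group
  # column to the structure's group with the largest mean absolute loading
  matched <- apply(abs(B[, -1L, drop = FALSE]), 2L, function(col) {
    which.max(vapply(seq_len(m),
                     function(g) mean(col[structure$group_of == g]), 0))
  })
  B <- B[, c(1L, 1L + order(matched)), drop = FALSE]
  B <- apply_sign_convention(B)
  out <- loading_matrix(B, structure, enforce_zeros = TRUE)
  attr(out, "raw") <- B
  out
}

#' Omega-hierarchical of the general factor
#'
#' Proportion of total composite-score variance attributable to the general
#' factor of an orthogonal bifactor solution:
#' \deqn{\omega_h = (\sum \lambda_g)^2 / [(\sum \lambda_g)^2 +
#'   \sum_k (\sum_i \lambda_{ik})^2 + \sum_i u_i]}
#' where the inner sums run over each group-factor column and \eqn{u_i} are
#' the item uniquenesses on the unit-variance metric.
#'
#' @param L a [loading_matrix] (or plain matrix, general column first).
#' @param uniquenesses nonnegative vector of length `n`; defaults to
#'   `1 - rowSums(L^2)`.
#' @return omega-hierarchical in `[0, 1]`.
#' @export
omega_hierarchical <- function(L, uniquenesses = NULL) {
  L <- unclass(L)
  if (is.null(uniquenesses)) uniquenesses <- 1 - rowSums(L^2)
  if (length(uniquenesses) != nrow(L)) stop("uniqueness length mismatch")
  if (any(uniquenesses < -1e-8)) stop("uniquenesses must be nonnegative")
  gen <- sum(L[, 1L])^2
  grp <- sum(colSums(L[, -1L, drop = FALSE])^2)
  gen / (gen + grp + sum(pmax(uniquenesses, 0)))
}

#' Hancock-Mueller construct reliability (H-index)
#'
#' `H = S / (1 + S)` with `S = sum(lambda^2 / (1 - lambda^2))` over the
#' factor's standardized indicator loadings. Measures how well the latent
#' factor is replicated by its indicators.
#'
#' @param general_loadings numeric vector with all `|lambda| < 1`.
#' @return H in `[0, 1]`.
#' @export
h_index <- function(general_loadings) {
  lam <- as.numeric(general_loadings)
  if (any(abs(lam) >= 1)) stop("all |loadings| must be < 1")
  S <- sum(lam^2 / (1 - lam^2))
  S / (1 + S)
}

#' Explained common variance of the general factor
#'
#' Share of all common (non-unique) variance carried by the general factor:
#' `sum(lambda_general^2) / sum(lambda^2 over all columns)`.
#'
#' @param L a [loading_matrix] or plain matrix, general column first.
#' @return ECV in `[0, 1]`.
#' @export
ecv <- function(L) {
  L <- unclass(L)
  tot <- sum(L^2)
  if (tot == 0) stop("all-zero loading matrix")
  sum(L[, 1L]^2) / tot
}

#' General-factor index report
#'
#' Bundles omega-hierarchical, the H-index and ECV for one loading set with
#' the conventional adequacy cutoffs (omega_h > 0.5, H > 0.7).
#'
#' @param L loading matrix (general column first).
#' @param uniquenesses passed to [omega_hierarchical()].
#' @param label name of the loading set evaluated.
#' @param cutoffs named vector with elements `omega_h` and `h`.
#' @return object of class `index_report`: list with `omega_h`, `h_index`,
#'   `ecv`, `label`, `cutoffs`, and logical `pass` flags.
#' @export
index_report <- function(L, uniquenesses = NULL, label = "loadings",
                         cutoffs = c(omega_h = 0.5, h = 0.7)) {
  oh <- omega_hierarchical(L, uniquenesses)
  h <- h_index(unclass(L)[, 1L])
  e <- ecv(L)
  structure(list(omega_h = oh, h_index = h, ecv = e, label = label,
                 cutoffs = cutoffs,
                 pass = c(omega_h = unname(oh > cutoffs[["omega_h"]]),
                          h_index = unname(h > cutoffs[["h"]]))),
            class = "index_report")
}

#' @export
print.index_report <- function(x, ...) {
  cat(sprintf("General-factor indices (%s)\n", x$label))
  cat(sprintf("  omega_h = %.3f (cutoff > %.2f: %s)\n", x$omega_h,
              x$cutoffs[["omega_h"]], ifelse(x$pass[["omega_h"]], "pass", "fail")))
  cat(sprintf("  H-index = %.3f (cutoff > %.2f: %s)\n", x$h_index,
              x$cutoffs[["h"]], ifelse(x$pass[["h_index"]], "pass", "fail")))
  cat(sprintf("  ECV     = %.3f\n", x$ecv))
  invisible(x)
}

#' Loading adequacy and dominance summary
#'
#' Summarizes a bifactor loading matrix the way applied reports do:
#' which items fail the adequacy threshold on the general factor, how many
#' items load more strongly on the general factor than on their own group
#' factor, and (from the pre-zeroing cross-loadings, when available) whether
#' each item loads more strongly on its intended group than on the other
#' groups.
#'
#' @param L a [loading_matrix]; if it carries a `"raw"` attribute (as
#'   returned by [fit_dsl_bifactor()] or built with `enforce_zeros = FALSE`)
#'   the cross-loading comparisons use it.
#' @param threshold adequacy threshold on the general loading (default 0.4).
#' @return list with `below_threshold` (item labels), `n_below`,
#'   `general_dominant` (logical per item), `pct_general_dominant`, and
#'   `correct_subscale` (logical per item, `NA` when no cross-loadings are
#'   available).
#' @export
loading_summary <- function(L, threshold = 0.4) {
  st <- attr(L, "structure")
  M <- unclass(L)
  raw <- attr(L, "raw") %||% M          # pre-zeroing variant when available
  n <- nrow(M)
  gof <- st$group_of
  own <- raw[cbind(seq_len(n), gof + 1L)]  # own-group entry, same in both
  below <- M[, 1L] < threshold
  dominant <- M[, 1L] > own
  # intended-vs-other-group comparison needs cross-loadings
  mask <- loading_mask(st)
  has_cross <- any(raw[, -1L][!mask[, -1L]] != 0)
  correct <- rep(NA, n)
  if (has_cross) {
    for (i in seq_len(n)) {
      others <- raw[i, setdiff(seq_len(st$n_groups), gof[i]) + 1L]
      correct[i] <- all(abs(own[i]) > abs(others))
    }
  }
  list(below_threshold = st$item_labels[below],
       n_below = sum(below),
       general_dominant = dominant,
       pct_general_dominant = 100 * mean(dominant),
       correct_subscale = correct)
}

#' Scale reliability: Cronbach's alpha and omega-total
#'
#' Alpha by the standard variance-ratio formula; omega-total from a
#' one-factor principal-axis solution on the item correlation matrix,
#' `(sum lambda)^2 / ((sum lambda)^2 + sum(1 - lambda^2))`.
#'
#' @param item_scores numeric matrix or data frame, rows = respondents;
#'   rows with any missing value are dropped.
#' @return list with `alpha`, `omega_total`, `n_used`.
#' @export
scale_reliability <- function(item_scores) {
  X <- as.matrix(item_scores)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  k <- ncol(X)
  if (k < 2L || nrow(X) < 3L) stop("need >= 2 items and >= 3 complete rows")
  v <- apply(X, 2L, stats::var)
  if (any(v == 0)) stop("zero-variance item")
  alpha <- k / (k - 1) * (1 - sum(v) / stats::var(rowSums(X)))
  lam <- as.numeric(pa_extract(stats::cor(X), 1L))
  if (sum(lam) < 0) lam <- -lam
  omega <- sum(lam)^2 / (sum(lam)^2 + sum(1 - lam^2))
  list(alpha = alpha, omega_total = omega, n_used = nrow(X))
}
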