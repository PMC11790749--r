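#' Common-pathway bifactor parameter set
#'
#' Parameters of the bifactor common pathway (CP) twin model: phenotypic
#' loadings of the items on the general and group factors, ACE path
#' coefficients of each latent factor, and ACE paths of the item-unique
#' residuals. Each latent factor has unit variance, i.e. the standardization
#' constraint `a_F^2 + c_F^2 + e_F^2 = 1` must hold; a dropped variance
#' component (AE/CE/E submodels) has its paths set to exactly 0.
#'
#' @param loadings a [loading_matrix] (phenotypic loadings, structural zeros
#'   enforced).
#' @param factor_paths numeric matrix `(1 + m) x 3`, columns `a, c, e`, one
#'   row per latent factor (general first).
#' @param unique_paths numeric matrix `n x 3`, columns `a, c, e`, one row per
#'   item.
#' @param tol tolerance for the unit-variance check.
#' @return object of class `cp_params`.
#' @export
cp_params <- function(loadings, factor_paths, unique_paths, tol = 1e-6) {
  stopifnot(inherits(loadings, "loading_matrix"))
  st <- attr(loadings, "structure")
  factor_paths <- as.matrix(factor_paths)
  unique_paths <- as.matrix(unique_paths)
  stopifnot(nrow(factor_paths) == st$n_groups + 1L, ncol(factor_paths) == 3L,
            nrow(unique_paths) == st$n_items, ncol(unique_paths) == 3L)
  colnames(factor_paths) <- colnames(unique_paths) <- c("a", "c", "e")
  v <- rowSums(factor_paths^2)
  if (any(abs(v - 1) > tol)) {
    stop("factor paths must satisfy a^2 + c^2 + e^2 = 1 (unit factor variance)")
  }
  structure(list(loadings = loadings, factor_paths = factor_paths,
                 unique_paths = unique_paths, structure = st),
            class = "cp_params")
}

#' Independent-pathway bifactor parameter set
#'
#' Parameters of the bifactor independent pathway (IP) twin model: three
#' source-specific loading matrices (additive genetic A, shared environment
#' C, non-shared environment E), each with the same general + group bifactor
#' pattern, plus item-unique ACE paths. A dropped component zeroes its whole
#' loading matrix and the corresponding unique paths.
#'
#' @param lambda_a,lambda_c,lambda_e [loading_matrix] objects sharing one
#'   [bifactor_structure].
#' @param unique_paths numeric `n x 3` matrix, columns `a, c, e`.
#' @return object of class `ip_params`.
#' @export
ip_params <- function(lambda_a, lambda_c, lambda_e, unique_paths) {
  for (L in list(lambda_a, lambda_c, lambda_e)) {
    stopifnot(inherits(L, "loading_matrix"))
  }
  st <- attr(lambda_a, "structure")
  if (!identical(st$group_of, attr(lambda_c, "structure")$group_of) ||
      !identical(st$group_of, attr(lambda_e, "structure")$group_of)) {
    stop("all three loading matrices must share one bifactor structure")
  }
  unique_paths <- as.matrix(unique_paths)
  stopifnot(nrow(unique_paths) == st$n_items, ncol(unique_paths) == 3L)
  colnames(unique_paths) <- c("a", "c", "e")
  structure(list(lambda_a = lambda_a, lambda_c = lambda_c, lambda_e = lambda_e,
                 unique_paths = unique_paths, structure = st),
            class = "ip_params")
}

#' Published reference loading matrix of the 20-item scale
#'
#' Standardized bifactor loadings (general, inattention, hyperactivity) of
#' the 20 Conners adult self-report items, as printed in a published twin
#' study of adult ADHD symptoms. Cross-loadings are retained as printed;
#' structural zeros are not imposed. Used as a realistic fixture and as the
#' reference input for the reliability-index examples.
#'
#' @return a [loading_matrix] (with `enforce_zeros = FALSE`).
#' @export
conners_loadings <- function() {
  path <- system.file("extdata", "conners_bifactor_loadings.csv",
                      package = "biftwin", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  loading_matrix(as.matrix(df[, c("general", "inattention", "hyperactivity")]),
                 conners_structure(), enforce_zeros = FALSE)
}

#' Published reference mean squared standardized effects (IP model)
#'
#' Mean squared standardized effects across items, by source (A/C/E) and
#' level (general, inattention, hyperactivity, item-unique), from the same
#' published independent-pathway model. Fixture for the aggregation and
#' share computations.
#'
#' @return data frame with columns `level, A, C, E`.
#' @export
ip_reference_effects <- function() {
  path <- system.file("extdata", "ip_effect_estimates.csv",
                      package = "biftwin", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Demonstration CP (AE) parameter set in the published regime
#'
#' A common-pathway AE generator on the 20-item structure: phenotypic
#' loadings are the published matrix with structural zeros imposed; factor
#' heritabilities are 0.40 (general), 0.42 (inattention), 0.33
#' (hyperactivity); item-unique variance (1 minus communality) is split
#' between A and E in the proportion of the published unique effects
#' (A 0.02 : E 0.46). Item variances are exactly 1.
#'
#' @return a `cp_params` object.
#' @export
demo_cp_params <- function() {
  st <- conners_structure()
  L <- loading_matrix(unclass(conners_loadings()), st, enforce_zeros = TRUE)
  h2 <- c(0.40, 0.42, 0.33)
  fp <- cbind(a = sqrt(h2), c = 0, e = sqrt(1 - h2))
  u2 <- 1 - rowSums(unclass(L)^2)
  a_share <- 0.02 / 0.48
  up <- cbind(a = sqrt(u2 * a_share), c = 0, e = sqrt(u2 * (1 - a_share)))
  cp_params(L, fp, up)
}

#' Demonstration IP (ACE) parameter set in the published regime
#'
#' An independent-pathway ACE generator on the 20-item structure whose mean
#' squared standardized effects across items equal the published table:
#' A = (0.08, 0.03, 0.03, 0.02), C = (0.02, 0.01, 0.01, 0.00) and
#' E = (0.18, 0.10, 0.05, rest) for (general, inattention, hyperactivity,
#' unique). Each source's loading columns take the *shape* of the published
#' phenotypic loading matrix, rescaled so the across-all-items mean squared
#' effect matches its target; unique E absorbs the remainder so every item
#' variance is exactly 1. (Equal loadings within a column would leave a
#' two-group bifactor unidentified, so the heterogeneous published shape is
#' essential, not cosmetic.)
#'
#' @return an `ip_params` object.
#' @export
demo_ip_params <- function() {
  st <- conners_structure()
  n <- st$n_items
  shape <- unclass(loading_matrix(unclass(conners_loadings()), st,
                                  enforce_zeros = TRUE))
  # mean-across-all-items targets: rows = general, F1, F2, unique
  tgt <- list(A = c(0.08, 0.03, 0.03, 0.02),
              C = c(0.02, 0.01, 0.01, 0.00),
              E = c(0.18, 0.10, 0.05, NA))  # unique E closes to variance 1
  mk <- function(v) {
    M <- shape
    for (k in seq_len(ncol(M))) {
      ss <- sum(M[, k]^2)
      M[, k] <- M[, k] * sqrt(v[k] * n / ss)
    }
    loading_matrix(M, st)
  }
  la <- mk(tgt$A); lc <- mk(tgt$C); le <- mk(tgt$E)
  common <- rowSums(unclass(la)^2) + rowSums(unclass(lc)^2) +
    rowSums(unclass(le)^2)
  a_u <- rep(sqrt(tgt$A[4]), n)
  c_u <- rep(sqrt(tgt$C[4]), n)
  e_u2 <- 1 - common - a_u^2 - c_u^2
  stopifnot(all(e_u2 > 0))
  ip_params(la, lc, le, cbind(a = a_u, c = c_u, e = sqrt(e_u2)))
}
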