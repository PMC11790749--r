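# Bifactor CP / IP ACE twin models: model-implied covariances, FIML over
# twin pairs with missing data, and maximum-likelihood fitting.
#
# Throughout, the 2n-dimensional pair vector is ordered [twin1 | twin2], the
# additive-genetic cross-twin correlation is 1 (MZ) or 0.5 (DZ), shared
# environment is perfectly correlated across twins and non-shared
# environment uncorrelated. Latent factors are mutually orthogonal with unit
# variance.

r_additive <- function(zygosity) if (zygosity == "MZ") 1 else 0.5

#' Twin model specification
#'
#' @param family `"cp"` (common pathway: ACE acts on latent phenotypic
#'   factors) or `"ip"` (independent pathway: each of A/C/E has its own
#'   bifactor loading structure).
#' @param components `"ACE"`, `"AE"`, `"CE"` or `"E"`; E is always present.
#'   Submodels are nested in ACE by zeroing the dropped component's
#'   parameters.
#' @param structure a [bifactor_structure].
#' @param unique_components components allowed on the item-unique residuals;
#'   defaults to `components`. Set `"E"` for E-only residuals in a CP model.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("cp", "ip"),
                       components = c("ACE", "AE", "CE", "E"),
                       structure = conners_structure(),
                       unique_components = NULL) {
  family <- match.arg(family)
  components <- match.arg(components)
  unique_components <- unique_components %||% components
  stopifnot(unique_components %in% c("ACE", "AE", "CE", "E"))
  structure(list(family = family, components = components,
                 unique_components = unique_components,
                 structure = structure),
            class = "model_spec")
}

has_A <- function(comp) grepl("A", comp)
has_C <- function(comp) grepl("C", comp)

# assemble [[W, X], [X, W]]
assemble_pair_cov <- function(W, X) {
  rbind(cbind(W, X), cbind(X, W))
}

#' Model-implied twin-pair covariance, common pathway model
#'
#' Within-twin block `Lambda Lambda' + diag(a_u^2 + c_u^2 + e_u^2)`;
#' cross-twin block `Lambda diag(r a_F^2 + c_F^2) Lambda' +
#' diag(r a_u^2 + c_u^2)` with `r = 1` (MZ) or `0.5` (DZ).
#'
#' @param params a `cp_params` object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return `2n x 2n` covariance matrix ordered `[twin1 | twin2]`.
#' @export
expected_cov_cp <- function(params, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  r <- r_additive(zygosity)
  L <- unclass(params$loadings)
  fp <- params$factor_paths
  up <- params$unique_paths
  W <- tcrossprod(L) + diag(rowSums(up^2), nrow(L))
  D <- r * fp[, "a"]^2 + fp[, "c"]^2
  X <- L %*% (D * t(L)) + diag(r * up[, "a"]^2 + up[, "c"]^2, nrow(L))
  assemble_pair_cov(W, X)
}

#' Model-implied twin-pair covariance, independent pathway model
#'
#' Within-twin block `LA LA' + LC LC' + LE LE' + diag(u^2)`; cross-twin block
#' `r LA LA' + LC LC' + diag(r a_u^2 + c_u^2)`.
#'
#' @param params an `ip_params` object.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return `2n x 2n` covariance matrix ordered `[twin1 | twin2]`.
#' @export
expected_cov_ip <- function(params, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  r <- r_additive(zygosity)
  LA <- unclass(params$lambda_a)
  LC <- unclass(params$lambda_c)
  LE <- unclass(params$lambda_e)
  up <- params$unique_paths
  n <- nrow(LA)
  W <- tcrossprod(LA) + tcrossprod(LC) + tcrossprod(LE) +
    diag(rowSums(up^2), n)
  X <- r * tcrossprod(LA) + tcrossprod(LC) +
    diag(r * up[, "a"]^2 + up[, "c"]^2, n)
  assemble_pair_cov(W, X)
}

#' Model-implied covariances for both zygosities
#' @param params `cp_params` or `ip_params`.
#' @return list with `sigma_mz`, `sigma_dz`.
#' @export
expected_covariances <- function(params) {
  f <- if (inherits(params, "cp_params")) expected_cov_cp else expected_cov_ip
  list(sigma_mz = f(params, "MZ"), sigma_dz = f(params, "DZ"))
}

## ---- FIML machinery ------------------------------------------------------

# Group the rows of Y (pairs x 2n, NAs for missing) by missingness pattern.
# Rows without any observed entry are dropped (they contribute 0 to the
# likelihood). Returns list of groups: obs index, n, CP = crossprod of the
# observed submatrix, xbar = column means.
build_patterns <- function(Y) {
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0L
  Y <- Y[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  if (nrow(Y) == 0L) return(list())
  key <- apply(obs, 1L, function(b) rawToChar(as.raw(ifelse(b, 49L, 48L))))
  lapply(split(seq_len(nrow(Y)), key), function(rows) {
    o <- which(obs[rows[1L], ])
    X <- Y[rows, o, drop = FALSE]
    list(obs = o, n = length(rows), CP = crossprod(X), xbar = colMeans(X))
  })
}

# -2 log likelihood of one zygosity group given sigma and mean vector.
# If grad = TRUE also returns G with d(-2LL) = tr(G dSigma) and the mean
# gradient dmu (length 2n).
m2ll_patterns <- function(pats, sigma, mu, grad = FALSE, soft = FALSE) {
  p2 <- nrow(sigma)
  val <- 0
  G <- if (grad) matrix(0, p2, p2) else NULL
  dmu <- if (grad) numeric(p2) else NULL
  for (pat in pats) {
    o <- pat$obs
    sub <- sigma[o, o, drop = FALSE]
    ch <- tryCatch(chol(sub), error = function(e) NULL)
    if (is.null(ch)) {
      if (soft) return(list(value = Inf, G = G, dmu = dmu))
      stop("singular observed covariance sub-matrix (pattern of size ",
           length(o), ")")
    }
    subinv <- chol2inv(ch)
    muo <- mu[o]
    d <- pat$xbar - muo
    CPc <- pat$CP - pat$n * (outer(pat$xbar, muo) + outer(muo, pat$xbar)) +
      pat$n * outer(muo, muo)
    val <- val + pat$n * (length(o) * log(2 * pi) + 2 * sum(log(diag(ch)))) +
      sum(subinv * CPc)
    if (grad) {
      G[o, o] <- G[o, o] + pat$n * subinv - subinv %*% CPc %*% subinv
      dmu[o] <- dmu[o] - 2 * pat$n * as.numeric(subinv %*% d)
    }
  }
  if (grad) list(value = val, G = G, dmu = dmu) else list(value = val)
}

#' FIML -2 log-likelihood of a twin dataset
#'
#' Full-information maximum likelihood: each pair contributes
#' `-2 log` of the multivariate-normal density of its observed sub-vector,
#' using the rows/columns of its zygosity's model-implied covariance matrix
#' that match the non-missing entries. Pairs with no observed entries
#' contribute 0.
#'
#' @param data a [twin_data] object.
#' @param sigma_mz,sigma_dz `2n x 2n` covariance matrices.
#' @param means mean vector of length `2n` (default all zero, the
#'   convention after covariate residualization).
#' @return the -2 log-likelihood (a single number).
#' @export
fiml_minus2ll <- function(data, sigma_mz, sigma_dz, means = NULL) {
  Y <- pair_matrix(data)
  p2 <- ncol(Y)
  if (is.null(means)) means <- numeric(p2)
  stopifnot(length(means) == p2, nrow(sigma_mz) == p2, nrow(sigma_dz) == p2)
  z <- data$pairs$zygosity
  val <- 0
  for (zyg in c("MZ", "DZ")) {
    rows <- z == zyg
    if (!any(rows)) next
    pats <- build_patterns(Y[rows, , drop = FALSE])
    sig <- if (zyg == "MZ") sigma_mz else sigma_dz
    val <- val + m2ll_patterns(pats, sig, means)$value
  }
  val
}

## ---- parameter packing ---------------------------------------------------

# Describes the free-parameter vector of a model_spec: named blocks with
# lengths, lower/upper bounds. Loading blocks use the column-major order of
# the structurally-free entries (loading_mask).
param_map <- function(spec) {
  st <- spec$structure
  n <- st$n_items
  m <- st$n_groups
  nf <- sum(loading_mask(st))          # free loading entries (= 2n)
  comp <- spec$components
  ucomp <- spec$unique_components
  blocks <- list()
  add <- function(blocks, name, len, lo, hi) {
    blocks[[name]] <- list(len = len, lo = lo, hi = hi)
    blocks
  }
  if (spec$family == "cp") {
    blocks <- add(blocks, "lam", nf, -3, 3)
    if (has_A(comp)) blocks <- add(blocks, "a_f", m + 1L, -1, 1)
    if (has_C(comp)) blocks <- add(blocks, "c_f", m + 1L, -1, 1)
  } else {
    if (has_A(comp)) blocks <- add(blocks, "lam_a", nf, -3, 3)
    if (has_C(comp)) blocks <- add(blocks, "lam_c", nf, -3, 3)
    blocks <- add(blocks, "lam_e", nf, -3, 3)
  }
  if (has_A(ucomp)) blocks <- add(blocks, "a_u", n, -3, 3)
  if (has_C(ucomp)) blocks <- add(blocks, "c_u", n, -3, 3)
  blocks <- add(blocks, "e_u", n, 1e-4, 3)
  lens <- vapply(blocks, `[[`, 0, "len")
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  list(blocks = blocks, starts = starts, ends = ends,
       npar = sum(lens),
       lower = unlist(lapply(blocks, function(b) rep(b$lo, b$len)),
                      use.names = FALSE),
       upper = unlist(lapply(blocks, function(b) rep(b$hi, b$len)),
                      use.names = FALSE))
}

pm_get <- function(pm, theta, name, default = NULL) {
  if (is.null(pm$blocks[[name]])) return(default)
  theta[pm$starts[[name]]:pm$ends[[name]]]
}

# loading vector (free entries, column-major) -> full n x (m+1) matrix
lam_fill <- function(v, st) {
  mask <- loading_mask(st)
  M <- matrix(0, st$n_items, st$n_groups + 1L)
  M[mask] <- v
  M
}

# Unpack a theta vector into a parameter-set object. CP e_f is derived from
# the unit-variance constraint (paths a, c clamped into the unit disc).
unpack_params <- function(theta, spec, pm) {
  st <- spec$structure
  n <- st$n_items
  m <- st$n_groups
  zero_n <- numeric(n)
  a_u <- pm_get(pm, theta, "a_u", zero_n)
  c_u <- pm_get(pm, theta, "c_u", zero_n)
  e_u <- pm_get(pm, theta, "e_u")
  up <- cbind(a = a_u, c = c_u, e = e_u)
  if (spec$family == "cp") {
    L <- loading_matrix(lam_fill(pm_get(pm, theta, "lam"), st), st)
    a_f <- pm_get(pm, theta, "a_f", numeric(m + 1L))
    c_f <- pm_get(pm, theta, "c_f", numeric(m + 1L))
    s <- a_f^2 + c_f^2
    scl <- ifelse(s > 1, 1 / sqrt(s), 1)   # project into the unit disc
    a_f <- a_f * scl
    c_f <- c_f * scl
    fp <- cbind(a = a_f, c = c_f, e = sqrt(pmax(0, 1 - a_f^2 - c_f^2)))
    cp_params(L, fp, up)
  } else {
    zero_l <- matrix(0, n, m + 1L)
    LA <- lam_fill(pm_get(pm, theta, "lam_a", numeric(sum(loading_mask(st)))), st)
    LC <- lam_fill(pm_get(pm, theta, "lam_c", numeric(sum(loading_mask(st)))), st)
    LE <- lam_fill(pm_get(pm, theta, "lam_e"), st)
    ip_params(loading_matrix(LA, st), loading_matrix(LC, st),
              loading_matrix(LE, st), up)
  }
}

pack_params <- function(params, spec, pm) {
  st <- spec$structure
  mask <- loading_mask(st)
  out <- numeric(pm$npar)
  put <- function(out, name, v) {
    if (!is.null(pm$blocks[[name]])) {
      out[pm$starts[[name]]:pm$ends[[name]]] <- v
    }
    out
  }
  if (spec$family == "cp") {
    out <- put(out, "lam", unclass(params$loadings)[mask])
    out <- put(out, "a_f", params$factor_paths[, "a"])
    out <- put(out, "c_f", params$factor_paths[, "c"])
  } else {
    out <- put(out, "lam_a", unclass(params$lambda_a)[mask])
    out <- put(out, "lam_c", unclass(params$lambda_c)[mask])
    out <- put(out, "lam_e", unclass(params$lambda_e)[mask])
  }
  out <- put(out, "a_u", params$unique_paths[, "a"])
  out <- put(out, "c_u", params$unique_paths[, "c"])
  out <- put(out, "e_u", pmax(params$unique_paths[, "e"], 1e-4))
  out
}

## ---- objective and analytic gradient -------------------------------------

PENALTY_W <- 1e6  # smooth penalty keeping CP factor paths inside the unit disc

# value + gradient of the penalized FIML -2LL for packed theta.
# pats: list(MZ = patterns, DZ = patterns). Means fixed at `mu`.
m2ll_theta <- function(theta, spec, pm, pats, mu, grad = FALSE) {
  st <- spec$structure
  n <- st$n_items
  m <- st$n_groups
  mask <- loading_mask(st)
  penalty <- 0
  gpen <- NULL
  if (spec$family == "cp") {
    a_f <- pm_get(pm, theta, "a_f", numeric(m + 1L))
    c_f <- pm_get(pm, theta, "c_f", numeric(m + 1L))
    exc <- pmax(a_f^2 + c_f^2 - 1, 0)
    penalty <- PENALTY_W * sum(exc^2)
    if (grad) {
      gpen <- list(a_f = PENALTY_W * 4 * exc * a_f,
                   c_f = PENALTY_W * 4 * exc * c_f)
    }
    # expected covariance uses the *unprojected* paths so the penalty is the
    # only force at infeasible points; inside the disc both agree.
    L <- lam_fill(pm_get(pm, theta, "lam"), st)
    up_a <- pm_get(pm, theta, "a_u", numeric(n))
    up_c <- pm_get(pm, theta, "c_u", numeric(n))
    up_e <- pm_get(pm, theta, "e_u")
    u2 <- up_a^2 + up_c^2 + up_e^2
    W <- tcrossprod(L) + diag(u2, n)
    total <- penalty
    gtheta <- if (grad) numeric(pm$npar) else NULL
    for (zyg in c("MZ", "DZ")) {
      if (!length(pats[[zyg]])) next
      r <- r_additive(zyg)
      D <- r * a_f^2 + c_f^2
      X <- L %*% (D * t(L)) + diag(r * up_a^2 + up_c^2, n)
      sig <- assemble_pair_cov(W, X)
      res <- m2ll_patterns(pats[[zyg]], sig, mu, grad = grad, soft = TRUE)
      if (!is.finite(res$value)) {
        # infeasible region (e.g. a_F^2+c_F^2 > 1 makes sigma indefinite):
        # huge value so the line search backtracks; penalty-only gradient
        gtheta <- if (grad) numeric(pm$npar) else NULL
        if (grad && !is.null(pm$blocks$a_f)) {
          gtheta[pm$starts[["a_f"]]:pm$ends[["a_f"]]] <- gpen$a_f
        }
        if (grad && !is.null(pm$blocks$c_f)) {
          gtheta[pm$starts[["c_f"]]:pm$ends[["c_f"]]] <- gpen$c_f
        }
        return(if (grad) list(value = 1e12 + penalty, gradient = gtheta)
               else list(value = 1e12 + penalty))
      }
      total <- total + res$value
      if (grad) {
        idx1 <- seq_len(n); idx2 <- n + idx1
        GW <- res$G[idx1, idx1] + res$G[idx2, idx2]
        GX <- res$G[idx1, idx2] + res$G[idx2, idx1]
        gL <- 2 * GW %*% L + 2 * GX %*% (t(D * t(L)))
        gtheta[pm$starts[["lam"]]:pm$ends[["lam"]]] <-
          gtheta[pm$starts[["lam"]]:pm$ends[["lam"]]] + gL[mask]
        LGXL <- diag(t(L) %*% GX %*% L)
        if (!is.null(pm$blocks$a_f)) {
          i <- pm$starts[["a_f"]]:pm$ends[["a_f"]]
          gtheta[i] <- gtheta[i] + 2 * r * a_f * LGXL
        }
        if (!is.null(pm$blocks$c_f)) {
          i <- pm$starts[["c_f"]]:pm$ends[["c_f"]]
          gtheta[i] <- gtheta[i] + 2 * c_f * LGXL
        }
        dW <- diag(GW); dX <- diag(GX)
        if (!is.null(pm$blocks$a_u)) {
          i <- pm$starts[["a_u"]]:pm$ends[["a_u"]]
          gtheta[i] <- gtheta[i] + 2 * up_a * (dW + r * dX)
        }
        if (!is.null(pm$blocks$c_u)) {
          i <- pm$starts[["c_u"]]:pm$ends[["c_u"]]
          gtheta[i] <- gtheta[i] + 2 * up_c * (dW + dX)
        }
        i <- pm$starts[["e_u"]]:pm$ends[["e_u"]]
        gtheta[i] <- gtheta[i] + 2 * up_e * dW
      }
    }
    if (grad) {
      if (!is.null(pm$blocks$a_f)) {
        i <- pm$starts[["a_f"]]:pm$ends[["a_f"]]
        gtheta[i] <- gtheta[i] + gpen$a_f
      }
      if (!is.null(pm$blocks$c_f)) {
        i <- pm$starts[["c_f"]]:pm$ends[["c_f"]]
        gtheta[i] <- gtheta[i] + gpen$c_f
      }
      list(value = total, gradient = gtheta)
    } else list(value = total)
  } else {
    nf <- sum(mask)
    LA <- lam_fill(pm_get(pm, theta, "lam_a", numeric(nf)), st)
    LC <- lam_fill(pm_get(pm, theta, "lam_c", numeric(nf)), st)
    LE <- lam_fill(pm_get(pm, theta, "lam_e"), st)
    up_a <- pm_get(pm, theta, "a_u", numeric(n))
    up_c <- pm_get(pm, theta, "c_u", numeric(n))
    up_e <- pm_get(pm, theta, "e_u")
    AA <- tcrossprod(LA); CC <- tcrossprod(LC); EE <- tcrossprod(LE)
    W <- AA + CC + EE + diag(up_a^2 + up_c^2 + up_e^2, n)
    total <- 0
    gtheta <- if (grad) numeric(pm$npar) else NULL
    for (zyg in c("MZ", "DZ")) {
      if (!length(pats[[zyg]])) next
      r <- r_additive(zyg)
      X <- r * AA + CC + diag(r * up_a^2 + up_c^2, n)
      sig <- assemble_pair_cov(W, X)
      res <- m2ll_patterns(pats[[zyg]], sig, mu, grad = grad, soft = TRUE)
      if (!is.finite(res$value)) {
        return(if (grad) list(value = 1e12, gradient = numeric(pm$npar))
               else list(value = 1e12))
      }
      total <- total + res$value
      if (grad) {
        idx1 <- seq_len(n); idx2 <- n + idx1
        GW <- res$G[idx1, idx1] + res$G[idx2, idx2]
        GX <- res$G[idx1, idx2] + res$G[idx2, idx1]
        addl <- function(gtheta, name, gmat) {
          if (is.null(pm$blocks[[name]])) return(gtheta)
          i <- pm$starts[[name]]:pm$ends[[name]]
          gtheta[i] <- gtheta[i] + gmat[mask]
          gtheta
        }
        gtheta <- addl(gtheta, "lam_a", 2 * GW %*% LA + 2 * r * GX %*% LA)
        gtheta <- addl(gtheta, "lam_c", 2 * GW %*% LC + 2 * GX %*% LC)
        gtheta <- addl(gtheta, "lam_e", 2 * GW %*% LE)
        dW <- diag(GW); dX <- diag(GX)
        if (!is.null(pm$blocks$a_u)) {
          i <- pm$starts[["a_u"]]:pm$ends[["a_u"]]
          gtheta[i] <- gtheta[i] + 2 * up_a * (dW + r * dX)
        }
        if (!is.null(pm$blocks$c_u)) {
          i <- pm$starts[["c_u"]]:pm$ends[["c_u"]]
          gtheta[i] <- gtheta[i] + 2 * up_c * (dW + dX)
        }
        i <- pm$starts[["e_u"]]:pm$ends[["e_u"]]
        gtheta[i] <- gtheta[i] + 2 * up_e * dW
      }
    }
    if (grad) list(value = total, gradient = gtheta) else list(value = total)
  }
}

## ---- starting values ------------------------------------------------------

# Pooled within-person covariance across twins, pairwise complete.
pooled_item_cov <- function(data) {
  X <- rbind(item_matrix(data, 1L), item_matrix(data, 2L))
  V <- stats::cov(X, use = "pairwise.complete.obs")
  V[!is.finite(V)] <- 0
  V
}

start_values <- function(spec, data) {
  st <- spec$structure
  n <- st$n_items
  V <- pooled_item_cov(data)
  sds <- sqrt(pmax(diag(V), 1e-6))
  R <- stats::cov2cor(V)
  ev <- eigen((R + t(R)) / 2, symmetric = TRUE)
  R <- ev$vectors %*% (pmax(ev$values, 1e-4) * t(ev$vectors))
  R <- stats::cov2cor(R)
  L0 <- tryCatch(suppressWarnings(unclass(fit_dsl_bifactor(R, st))),
                 error = function(e) {
                   M <- matrix(0.3, n, st$n_groups + 1L)
                   M[!loading_mask(st)] <- 0
                   M[, 1L] <- 0.5
                   M
                 })
  if (all(L0 == 0)) L0[, 1L] <- 0.3
  L0 <- L0 * sds                            # back to the raw scale
  u2 <- pmax(diag(V) - rowSums(L0^2), 0.1 * diag(V))
  comp <- spec$components
  ucomp <- spec$unique_components
  wa <- if (has_A(ucomp)) 0.2 else 0
  wc <- if (has_C(ucomp)) 0.05 else 0
  up <- cbind(a = sqrt(u2 * wa), c = sqrt(u2 * wc),
              e = sqrt(u2 * (1 - wa - wc)))
  if (spec$family == "cp") {
    a_f <- if (has_A(comp)) rep(sqrt(0.35), st$n_groups + 1L) else numeric(st$n_groups + 1L)
    c_f <- if (has_C(comp)) rep(sqrt(0.10), st$n_groups + 1L) else numeric(st$n_groups + 1L)
    fp <- cbind(a = a_f, c = c_f, e = sqrt(1 - a_f^2 - c_f^2))
    cp_params(loading_matrix(L0, st), fp, up)
  } else {
    wA <- if (has_A(comp)) 0.35 else 0
    wC <- if (has_C(comp)) 0.10 else 0
    wE <- 1 - wA - wC
    ip_params(loading_matrix(L0 * sqrt(wA), st),
              loading_matrix(L0 * sqrt(wC), st),
              loading_matrix(L0 * sqrt(wE), st), up)
  }
}

jitter_theta <- function(theta, pm, amount = 0.1) {
  th <- theta * (1 + amount * stats::rnorm(length(theta))) +
    0.02 * stats::rnorm(length(theta))
  pmin(pmax(th, pm$lower), pm$upper)
}

## ---- fitting ---------------------------------------------------------------

#' Fit a bifactor twin model by FIML
#'
#' Minimizes the FIML -2 log-likelihood over the free paths of a CP or IP
#' bifactor ACE model (or its AE/CE/E submodels) with L-BFGS-B and analytic
#' gradients. The CP unit-factor-variance constraint `a_F^2+c_F^2+e_F^2 = 1`
#' is enforced by deriving `e_F` and penalizing excursions of `a_F^2+c_F^2`
#' beyond 1. Loading columns are sign-fixed to nonnegative sums after
#' convergence. Means are fixed at 0 (the convention for residualized
#' scores) unless a numeric vector is supplied.
#'
#' @param data a [twin_data] object (scores residualized or centred).
#' @param spec a [model_spec].
#' @param start optional `cp_params`/`ip_params` starting point; defaults to
#'   a Direct Schmid-Leiman-based heuristic.
#' @param n_starts number of optimizer starts (first from `start`, the rest
#'   jittered); the best -2LL is kept.
#' @param means `NULL` for zero means or a numeric vector of length `2n`.
#' @param control list overriding `optim` control parameters `maxit`,
#'   `factr`, `pgtol`.
#' @param seed seed for the jittered starts.
#' @return object of class `twin_fit`: `spec`, `params`, `minus2LL`,
#'   `n_free_params`, `n_pairs_used`, `converged`, `standardized` (per-item
#'   squared standardized effects, rows sum to 1), and for CP fits
#'   `factor_effects` (per-factor a2/c2/e2).
#' @export
fit_model <- function(data, spec, start = NULL, n_starts = 5L, means = NULL,
                      control = list(), seed = 1L) {
  stopifnot(inherits(data, "twin_data"), inherits(spec, "model_spec"))
  pm <- param_map(spec)
  Y <- pair_matrix(data)
  mu <- means %||% numeric(ncol(Y))
  z <- data$pairs$zygosity
  pats <- list(MZ = build_patterns(Y[z == "MZ", , drop = FALSE]),
               DZ = build_patterns(Y[z == "DZ", , drop = FALSE]))
  n_used <- sum(vapply(pats$MZ, `[[`, 0, "n")) +
    sum(vapply(pats$DZ, `[[`, 0, "n"))
  fn <- function(th) m2ll_theta(th, spec, pm, pats, mu)$value
  gr <- function(th) m2ll_theta(th, spec, pm, pats, mu, grad = TRUE)$gradient
  # seed the start heuristics/jitters locally without disturbing the
  # caller's RNG stream (bootstrap resampling relies on it)
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv), add = TRUE)
  }
  set.seed(seed)
  theta0 <- pack_params(start %||% start_values(spec, data), spec, pm)
  theta0 <- pmin(pmax(theta0, pm$lower), pm$upper)
  ctrl <- utils::modifyList(list(maxit = 3000L, factr = 100, pgtol = 1e-6),
                            control)
  set.seed(seed)
  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    th <- if (s == 1L) theta0 else jitter_theta(theta0, pm)
    opt <- tryCatch(
      stats::optim(th, fn, gr, method = "L-BFGS-B",
                   lower = pm$lower, upper = pm$upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimizer starts failed")
  params <- unpack_params(best$par, spec, pm)
  params <- sign_fix_params(params)
  std <- standardized_effects(params)
  out <- list(spec = spec, params = params,
              minus2LL = m2ll_theta(best$par, spec, pm, pats, mu)$value,
              n_free_params = pm$npar, n_pairs_used = n_used,
              converged = best$convergence == 0L,
              optim_message = best$message %||% "",
              standardized = std, theta = best$par)
  if (spec$family == "cp") out$factor_effects <- params$factor_paths^2
  class(out) <- "twin_fit"
  out
}

#' @export
print.twin_fit <- function(x, ...) {
  cat(sprintf("Bifactor %s twin model (%s), -2LL = %.2f, k = %d, pairs = %d%s\n",
              toupper(x$spec$family), x$spec$components, x$minus2LL,
              x$n_free_params, x$n_pairs_used,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

sign_fix_params <- function(params) {
  if (inherits(params, "cp_params")) {
    L <- apply_sign_convention(unclass(params$loadings))
    params$loadings <- loading_matrix(L, params$structure)
  } else {
    for (f in c("lambda_a", "lambda_c", "lambda_e")) {
      params[[f]] <- loading_matrix(
        apply_sign_convention(unclass(params[[f]])), params$structure)
    }
  }
  params
}

#' Per-item squared standardized effects
#'
#' Decomposes each item's model-implied variance into squared standardized
#' effects by source (A, C, E) and level (general factor, each group factor,
#' item-unique). Rows sum to 1 by construction.
#'
#' @param params `cp_params` or `ip_params`.
#' @return numeric matrix, items x effects; column names `A.general`,
#'   `A.<group>`, ..., `A.unique`, then `C.*`, `E.*`.
#' @export
standardized_effects <- function(params) {
  st <- params$structure
  n <- st$n_items
  m <- st$n_groups
  lev <- c("general", st$group_names, "unique")
  cols <- as.vector(outer(lev, c("A", "C", "E"),
                          function(l, s) paste(s, l, sep = ".")))
  out <- matrix(0, n, length(cols), dimnames = list(st$item_labels, cols))
  up <- params$unique_paths
  if (inherits(params, "cp_params")) {
    L2 <- unclass(params$loadings)^2
    fp2 <- params$factor_paths^2
    for (si in 1:3) {
      s <- c("A", "C", "E")[si]
      pth <- c("a", "c", "e")[si]
      for (k in seq_len(m + 1L)) {
        out[, paste(s, lev[k], sep = ".")] <- L2[, k] * fp2[k, pth]
      }
      out[, paste(s, "unique", sep = ".")] <- up[, pth]^2
    }
  } else {
    mats <- list(A = unclass(params$lambda_a)^2,
                 C = unclass(params$lambda_c)^2,
                 E = unclass(params$lambda_e)^2)
    for (s in c("A", "C", "E")) {
      for (k in seq_len(m + 1L)) {
        out[, paste(s, lev[k], sep = ".")] <- mats[[s]][, k]
      }
      pth <- c(A = "a", C = "c", E = "e")[[s]]
      out[, paste(s, "unique", sep = ".")] <- up[, pth]^2
    }
  }
  out / rowSums(out)
}

#' Aggregate standardized effects across items
#'
#' Means over items of the squared standardized effects, by source and
#' level, plus each level's share of its source total (the way published
#' tables summarize independent-pathway models: e.g. the general factor's
#' share of total heritability).
#'
#' @param fit a `twin_fit`, or a standardized effect matrix as returned by
#'   [standardized_effects()], or a named list of per-source mean vectors
#'   (each ordered general, groups..., unique).
#' @return list per source with elements `means` and `shares` (both named
#'   by level), plus `table`: a data frame with one row per source x level.
#' @export
aggregate_standardized_effects <- function(fit) {
  if (inherits(fit, "twin_fit")) fit <- fit$standardized
  if (is.matrix(fit)) {
    cols <- strsplit(colnames(fit), ".", fixed = TRUE)
    src <- vapply(cols, `[[`, "", 1L)
    lev <- vapply(cols, function(x) paste(x[-1L], collapse = "."), "")
    mm <- colMeans(fit)
    fit <- lapply(split(seq_along(mm), src), function(i) {
      stats::setNames(mm[i], lev[i])
    })
  }
  out <- lapply(fit, function(means) {
    if (is.null(names(means))) names(means) <- as.character(seq_along(means))
    tot <- sum(means)
    list(means = means,
         shares = if (tot > 0) means / tot else means * 0)
  })
  rows <- do.call(rbind, lapply(names(out), function(s) {
    data.frame(source = s, level = names(out[[s]]$means),
               mean_effect = as.numeric(out[[s]]$means),
               share = as.numeric(out[[s]]$shares), row.names = NULL)
  }))
  out$table <- rows
  out
}
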