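# Shared fixtures and independent oracles for the test suite.

# small structures used throughout
structure4 <- function() bifactor_structure(rep(1:2, each = 2L))
structure6 <- function() bifactor_structure(rep(1:2, each = 3L))

# a well-identified small CP parameter set (heterogeneous loadings)
small_cp_params <- function(structure = structure6(),
                            h2 = c(0.40, 0.42, 0.33),
                            c2 = c(0, 0, 0),
                            unique_a_share = 0.1, unique_c_share = 0) {
  n <- structure$n_items
  m <- structure$n_groups
  set.seed(20240101)
  M <- matrix(0, n, m + 1L)
  M[, 1L] <- seq(0.45, 0.62, length.out = n)
  for (g in seq_len(m)) {
    idx <- structure$group_of == g
    M[idx, g + 1L] <- seq(0.28, 0.45, length.out = sum(idx))
  }
  L <- loading_matrix(M, structure)
  fp <- cbind(a = sqrt(h2[seq_len(m + 1L)]), c = sqrt(c2[seq_len(m + 1L)]),
              e = sqrt(1 - h2[seq_len(m + 1L)] - c2[seq_len(m + 1L)]))
  u2 <- 1 - rowSums(unclass(L)^2)
  up <- cbind(a = sqrt(u2 * unique_a_share), c = sqrt(u2 * unique_c_share),
              e = sqrt(u2 * (1 - unique_a_share - unique_c_share)))
  cp_params(L, fp, up)
}

# random valid parameter sets for property-style tests
random_cp_params <- function(structure, seed) {
  set.seed(seed)
  n <- structure$n_items
  m <- structure$n_groups
  mask <- biftwin:::loading_mask(structure)
  M <- matrix(0, n, m + 1L)
  M[mask] <- runif(sum(mask), 0.15, 0.7)
  a <- runif(m + 1L, 0.2, 0.7)
  cc <- runif(m + 1L, 0.1, 0.5)
  fp <- cbind(a = a, c = cc, e = sqrt(1 - a^2 - cc^2))
  up <- cbind(a = runif(n, 0.05, 0.4), c = runif(n, 0.05, 0.3),
              e = runif(n, 0.3, 0.8))
  cp_params(loading_matrix(M, structure), fp, up)
}

random_ip_params <- function(structure, seed) {
  set.seed(seed)
  n <- structure$n_items
  m <- structure$n_groups
  mask <- biftwin:::loading_mask(structure)
  mk <- function(lo, hi) {
    M <- matrix(0, n, m + 1L)
    M[mask] <- runif(sum(mask), lo, hi)
    loading_matrix(M, structure)
  }
  ip_params(mk(0.1, 0.4), mk(0.05, 0.3), mk(0.2, 0.6),
            cbind(a = runif(n, 0.05, 0.3), c = runif(n, 0.05, 0.2),
                  e = runif(n, 0.3, 0.7)))
}

# ---- independent structural oracle ----------------------------------------
# Builds the full linear latent system x = B eta explicitly (one latent per
# A/C/E realisation, cross-twin A correlation r in the latent covariance)
# and returns B Cov(eta) B'. Independent of the closed-form builders.

oracle_cov <- function(params, zygosity) {
  r <- if (zygosity == "MZ") 1 else 0.5
  st <- params$structure
  n <- st$n_items
  add_block <- function(state, load1, load2, kind) {
    # kind: "A" (cross-twin corr r), "C" (shared), "E" (independent)
    if (kind == "C") {
      S <- matrix(1, 1L, 1L)
      Bm <- matrix(c(load1, load2), ncol = 1L)
    } else {
      S <- diag(2L)
      if (kind == "A") S[1L, 2L] <- S[2L, 1L] <- r
      Bm <- matrix(0, 2L * n, 2L)
      Bm[seq_len(n), 1L] <- load1
      Bm[n + seq_len(n), 2L] <- load2
    }
    state$B <- cbind(state$B, Bm)
    state$S <- rbind(cbind(state$S, matrix(0, nrow(state$S), ncol(S))),
                     cbind(matrix(0, nrow(S), ncol(state$S)), S))
    state
  }
  state <- list(B = matrix(0, 2L * n, 0L), S = matrix(0, 0L, 0L))
  if (inherits(params, "cp_params")) {
    L <- unclass(params$loadings)
    fp <- params$factor_paths
    for (k in seq_len(ncol(L))) {
      for (s in c("a", "c", "e")) {
        kind <- c(a = "A", c = "C", e = "E")[[s]]
        state <- add_block(state, L[, k] * fp[k, s], L[, k] * fp[k, s], kind)
      }
    }
  } else {
    mats <- list(A = unclass(params$lambda_a), C = unclass(params$lambda_c),
                 E = unclass(params$lambda_e))
    for (s in names(mats)) {
      for (k in seq_len(ncol(mats[[s]]))) {
        state <- add_block(state, mats[[s]][, k], mats[[s]][, k], s)
      }
    }
  }
  up <- params$unique_paths
  for (i in seq_len(n)) {
    e_i <- numeric(n)
    for (s in c("a", "c", "e")) {
      kind <- c(a = "A", c = "C", e = "E")[[s]]
      v <- e_i
      v[i] <- up[i, s]
      state <- add_block(state, v, v, kind)
    }
  }
  state$B %*% state$S %*% t(state$B)
}

# direct per-row multivariate normal -2 log density (complete rows only)
direct_mvn_m2ll <- function(Y, sigma, mu = NULL) {
  mu <- mu %||% numeric(ncol(Y))
  tot <- 0
  for (i in seq_len(nrow(Y))) {
    x <- Y[i, ] - mu
    o <- !is.na(x)
    if (!any(o)) next
    S <- sigma[o, o, drop = FALSE]
    tot <- tot - 2 * (-0.5 * (sum(o) * log(2 * pi) +
                              determinant(S, logarithm = TRUE)$modulus +
                              drop(t(x[o]) %*% solve(S) %*% x[o])))
  }
  as.numeric(tot)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# central finite-difference gradient (own oracle; numDeriv not assumed)
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, 0)
}

# tiny valid twin dataset builder (complete unless NA supplied)
toy_twin_data <- function(structure = structure4(), n_mz = 2L, n_dz = 2L,
                          scores = NULL) {
  n <- structure$n_items
  np <- n_mz + n_dz
  set.seed(99)
  if (is.null(scores)) {
    scores <- matrix(sample(0:3, np * 2L * n, replace = TRUE), np, 2L * n)
  }
  df <- data.frame(pair_id = paste0("p", seq_len(np)),
                   zygosity = rep(c("MZ", "DZ"), c(n_mz, n_dz)),
                   age1 = 22, sex1 = 0L, cohort1 = 1L,
                   age2 = 22, sex2 = 1L, cohort2 = 1L)
  sc <- as.data.frame(scores)
  names(sc) <- biftwin:::item_cols(structure)
  twin_data(cbind(df, sc), structure)
}
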