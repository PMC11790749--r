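#' Simulation configuration
#'
#' Describes a synthetic MZ/DZ twin study generated from a bifactor CP or IP
#' ACE parameter set. Defaults mirror the published study's design: 5227
#' pairs of which 35.1% are MZ (1835 MZ, 3392 DZ), and 17% of twins with
#' missing data (whole-twin MCAR masking). Item-level MCAR masking is
#' available via `missing_unit = "item"`.
#'
#' @param params a `cp_params` or `ip_params` object.
#' @param n_mz,n_dz numbers of MZ and DZ pairs (>= 0).
#' @param missing_rate MCAR masking probability in `[0, 1]`.
#' @param missing_unit `"twin"` (mask all items of a twin at once) or
#'   `"item"` (mask cells independently).
#' @param ordinalize if `TRUE`, continuous scores are cut into ordinal 0-3
#'   scores at `thresholds`.
#' @param thresholds strictly increasing length-3 cut points on the latent
#'   (unit-variance) scale; the default `c(0.15, 0.90, 1.65)` yields a
#'   right-skewed distribution with a population mean total score near
#'   13.5 of 60 on the 20-item battery.
#' @param seed integer seed; all randomness in [simulate_twins()] derives
#'   from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(params, n_mz = 1835, n_dz = 3392,
                       missing_rate = 0.17,
                       missing_unit = c("twin", "item"),
                       ordinalize = FALSE,
                       thresholds = c(0.15, 0.90, 1.65),
                       seed = 1L) {
  stopifnot(inherits(params, "cp_params") || inherits(params, "ip_params"))
  if (n_mz < 0 || n_dz < 0) stop("pair counts must be nonnegative")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0,1]")
  if (ordinalize) {
    if (length(thresholds) != 3L || any(diff(thresholds) <= 0)) {
      stop("thresholds must be strictly increasing and of length 3")
    }
  }
  structure(list(params = params, n_mz = as.integer(n_mz),
                 n_dz = as.integer(n_dz), missing_rate = missing_rate,
                 missing_unit = match.arg(missing_unit),
                 ordinalize = ordinalize, thresholds = thresholds,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Draw a pairs x k matrix of N(0,1) variates filled pair-major, so that the
# first rows are unchanged when the number of pairs grows under one seed.
draw_pair_normals <- function(n_pairs, k) {
  matrix(stats::rnorm(n_pairs * k), nrow = n_pairs, ncol = k, byrow = TRUE)
}

# Latent scores for one zygosity group. Returns list(t1, t2): pairs x k
# matrices for each of A (cross-twin correlation r), C (shared) and E
# (independent). The same number of variates is consumed for MZ and DZ.
draw_ace_scores <- function(n_pairs, k, r_a) {
  A <- draw_pair_normals(n_pairs, 3L * k)  # shared, specific1, specific2
  Csh <- draw_pair_normals(n_pairs, k)
  E <- draw_pair_normals(n_pairs, 2L * k)
  sh <- A[, seq_len(k), drop = FALSE]
  s1 <- A[, k + seq_len(k), drop = FALSE]
  s2 <- A[, 2L * k + seq_len(k), drop = FALSE]
  w <- sqrt(r_a); v <- sqrt(1 - r_a)
  list(A1 = w * sh + v * s1, A2 = w * sh + v * s2,
       C1 = Csh, C2 = Csh,
       E1 = E[, seq_len(k), drop = FALSE],
       E2 = E[, k + seq_len(k), drop = FALSE])
}

# Continuous item scores (pairs x n per twin) for one zygosity.
simulate_items <- function(params, n_pairs, r_a) {
  st <- params$structure
  n <- st$n_items
  if (inherits(params, "cp_params")) {
    k <- st$n_groups + 1L
    fac <- draw_ace_scores(n_pairs, k, r_a)
    uni <- draw_ace_scores(n_pairs, n, r_a)
    fp <- params$factor_paths
    L <- unclass(params$loadings)
    pheno <- function(A, C, E) {
      sweep(A, 2L, fp[, "a"], `*`) + sweep(C, 2L, fp[, "c"], `*`) +
        sweep(E, 2L, fp[, "e"], `*`)
    }
    up <- params$unique_paths
    u <- function(A, C, E) {
      sweep(A, 2L, up[, "a"], `*`) + sweep(C, 2L, up[, "c"], `*`) +
        sweep(E, 2L, up[, "e"], `*`)
    }
    list(x1 = pheno(fac$A1, fac$C1, fac$E1) %*% t(L) + u(uni$A1, uni$C1, uni$E1),
         x2 = pheno(fac$A2, fac$C2, fac$E2) %*% t(L) + u(uni$A2, uni$C2, uni$E2))
  } else {
    k <- st$n_groups + 1L
    sa <- draw_ace_scores(n_pairs, k, r_a)   # A-source factor scores
    sc <- draw_ace_scores(n_pairs, k, r_a)   # only C columns used
    se <- draw_ace_scores(n_pairs, k, r_a)   # only E columns used
    uni <- draw_ace_scores(n_pairs, n, r_a)
    LA <- unclass(params$lambda_a); LC <- unclass(params$lambda_c)
    LE <- unclass(params$lambda_e)
    up <- params$unique_paths
    mk <- function(A, C, E, UA, UC, UE) {
      A %*% t(LA) + C %*% t(LC) + E %*% t(LE) +
        sweep(UA, 2L, up[, "a"], `*`) + sweep(UC, 2L, up[, "c"], `*`) +
        sweep(UE, 2L, up[, "e"], `*`)
    }
    list(x1 = mk(sa$A1, sc$C1, se$E1, uni$A1, uni$C1, uni$E1),
         x2 = mk(sa$A2, sc$C2, se$E2, uni$A2, uni$C2, uni$E2))
  }
}

#' Simulate a twin-pair dataset from bifactor ACE parameters
#'
#' Latent additive-genetic components are drawn with cross-twin correlation 1
#' (MZ) or 0.5 (DZ), shared-environment components are perfectly shared, and
#' non-shared components are independent, at both the factor/source level and
#' the item-unique level. Items are the linear combinations implied by the
#' parameter set; optional ordinalization (0-3 cuts) and MCAR masking follow.
#' Covariates (pair-shared age and cohort, per-twin sex) are generated
#' exogenously and do not influence item scores unless `covariate_effects`
#' is supplied.
#'
#' @param config a [sim_config].
#' @param covariate_effects optional named list with entries `age`, `sex`
#'   and/or `cohort`: regression weights added to every item (age is centred
#'   first). Used to exercise covariate residualization.
#' @return a [twin_data] object; fully reproducible from `config$seed`.
#' @export
simulate_twins <- function(config, covariate_effects = NULL) {
  stopifnot(inherits(config, "sim_config"))
  params <- config$params
  st <- params$structure
  n <- st$n_items
  set.seed(config$seed)
  blocks <- list()
  for (zyg in c("MZ", "DZ")) {
    np <- if (zyg == "MZ") config$n_mz else config$n_dz
    if (np == 0L) next
    xs <- simulate_items(params, np, r_a = if (zyg == "MZ") 1 else 0.5)
    age <- 22.85 + 0.88 * stats::rnorm(np)
    sex1 <- stats::rbinom(np, 1L, 0.401)
    sex2 <- if (zyg == "MZ") sex1 else stats::rbinom(np, 1L, 0.401)
    cohort <- sample.int(3L, np, replace = TRUE)
    if (!is.null(covariate_effects)) {
      add <- function(x, sex) {
        x + (covariate_effects$age %||% 0) * (age - 22.85) +
          (covariate_effects$sex %||% 0) * sex +
          (covariate_effects$cohort %||% 0) * (cohort - 2)
      }
      xs$x1 <- add(xs$x1, sex1); xs$x2 <- add(xs$x2, sex2)
    }
    if (config$ordinalize) {
      cut3 <- function(x) {
        y <- findInterval(x, config$thresholds)
        matrix(as.numeric(y), nrow(x), ncol(x))
      }
      xs$x1 <- cut3(xs$x1); xs$x2 <- cut3(xs$x2)
    }
    if (config$missing_rate > 0) {
      if (config$missing_unit == "item") {
        m1 <- draw_pair_normals(np, n); m2 <- draw_pair_normals(np, n)
        xs$x1[stats::pnorm(m1) < config$missing_rate] <- NA
        xs$x2[stats::pnorm(m2) < config$missing_rate] <- NA
      } else {
        m <- draw_pair_normals(np, 2L)
        xs$x1[stats::pnorm(m[, 1L]) < config$missing_rate, ] <- NA
        xs$x2[stats::pnorm(m[, 2L]) < config$missing_rate, ] <- NA
      }
    }
    df <- data.frame(pair_id = paste0(zyg, seq_len(np)), zygosity = zyg,
                     age1 = age, sex1 = sex1, cohort1 = cohort,
                     age2 = age, sex2 = sex2, cohort2 = cohort,
                     stringsAsFactors = FALSE)
    colnames(xs$x1) <- item_cols(st, 1L)
    colnames(xs$x2) <- item_cols(st, 2L)
    blocks[[zyg]] <- cbind(df, as.data.frame(xs$x1), as.data.frame(xs$x2))
  }
  twin_data(do.call(rbind, blocks), st)
}
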