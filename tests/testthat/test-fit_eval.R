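# fit_eval: reference fits, fit statistics, LRT, bootstrap, source indices

test_that("AIC/BIC identities hold exactly on emitted statistics", {
  fake <- function(m2ll, k, n = 500L) {
    structure(list(minus2LL = m2ll, n_free_params = k, n_pairs_used = n),
              class = "twin_fit")
  }
  sat <- fake(900, 50)
  ind <- fake(1500, 10)
  fs <- fit_statistics(fake(1000, 10), sat, ind, N = 500)
  expect_identical(fs$aic, 1000 + 2 * 10)
  expect_identical(fs$bic, 1000 + 10 * log(500))
  # model == saturated: chi2 = 0, RMSEA = 0, CFI = 1
  fs0 <- fit_statistics(fake(900, 10), sat, ind, N = 500)
  expect_equal(fs0$chi2_vs_saturated, 0)
  expect_equal(fs0$rmsea, 0)
  expect_equal(fs0$cfi, 1)
  expect_error(fit_statistics(fake(1000, 50), sat, ind), "fewer parameters")
})

test_that("fit statistics equal an independently coded formula oracle", {
  cp <- small_cp_params(structure4(), h2 = c(0.4, 0.4, 0.4))
  d <- simulate_twins(sim_config(cp, 150, 200, missing_rate = 0, seed = 13))
  sat <- fit_saturated(d)
  ind <- fit_independence(d)
  # deliberately misspecified: E-only model on AE data
  fit <- fit_model(d, model_spec("cp", "E", structure4()), n_starts = 1,
                   control = list(factr = 1e7))
  fs <- fit_statistics(fit, sat, ind)
  N <- fit$n_pairs_used
  chi2 <- fit$minus2LL - sat$minus2LL
  df <- sat$n_free_params - fit$n_free_params
  chi2_b <- ind$minus2LL - sat$minus2LL
  df_b <- sat$n_free_params - ind$n_free_params
  expect_equal(fs$rmsea, sqrt(max(0, chi2 - df) / (df * (N - 1))))
  expect_equal(fs$cfi, 1 - max(0, chi2 - df) /
                 max(chi2_b - df_b, chi2 - df, 0))
  expect_equal(fs$aic, fit$minus2LL + 2 * fit$n_free_params)
  expect_equal(fs$bic, fit$minus2LL + fit$n_free_params * log(N))
  expect_gt(fs$chi2_vs_saturated, 0)
})

test_that("RMSEA/CFI are invariant to a common -2LL shift", {
  fake <- function(m2ll, k, n = 400L) {
    structure(list(minus2LL = m2ll, n_free_params = k, n_pairs_used = n),
              class = "twin_fit")
  }
  sat <- fake(800, 60); ind <- fake(2000, 10); mod <- fake(950, 30)
  a <- fit_statistics(mod, sat, ind, N = 400)
  shift <- 123.4
  b <- fit_statistics(fake(950 + shift, 30), fake(800 + shift, 60),
                      fake(2000 + shift, 10), N = 400)
  expect_equal(a$rmsea, b$rmsea)
  expect_equal(a$cfi, b$cfi)
})

test_that("saturated fit: closed form on complete data, EM with missingness", {
  st <- structure4()
  cp <- random_cp_params(st, 19)
  d <- simulate_twins(sim_config(cp, 60, 80, missing_rate = 0, seed = 3))
  sat <- fit_saturated(d)
  Y <- biftwin:::pair_matrix(d)
  z <- d$pairs$zygosity
  expect_equal(sat$sigma_mz, crossprod(Y[z == "MZ", ]) / sum(z == "MZ"),
               ignore_attr = TRUE)
  # with missingness: EM likelihood beats the structured model's
  dm <- simulate_twins(sim_config(cp, 80, 100, missing_rate = 0.1,
                                  missing_unit = "item", seed = 4))
  satm <- fit_saturated(dm)
  ec <- expected_covariances(cp)
  expect_lt(satm$minus2LL, fiml_minus2ll(dm, ec$sigma_mz, ec$sigma_dz))
  # EM solution is a stationary point: tiny perturbations only worsen it
  set.seed(5)
  base <- satm$minus2LL
  for (i in 1:3) {
    P <- matrix(rnorm(64, sd = 0.01), 8, 8)
    P <- (P + t(P)) / 2
    expect_gt(fiml_minus2ll(dm, satm$sigma_mz + P, satm$sigma_dz + P), base)
  }
})

test_that("lrt: identity, chi-square oracle, nesting checks", {
  fake <- function(m2ll, k, spec = NULL) {
    structure(list(minus2LL = m2ll, n_free_params = k, spec = spec),
              class = "twin_fit")
  }
  same <- lrt(fake(1000, 20), fake(1000, 20))
  expect_equal(same$delta_chi2, 0)
  expect_equal(same$p_value, 1)
  # frozen chi-square quantile: Delta 3.84 on 1 df is p ~ 0.050
  r <- lrt(fake(1000, 21), fake(1003.84, 20))
  expect_equal(r$delta_df, 1L)
  expect_equal(r$p_value, 0.05, tolerance = 1e-3)
  # non-nested specs rejected
  st <- structure4()
  f_cp <- fake(10, 5, model_spec("cp", "ACE", st))
  f_ip <- fake(12, 4, model_spec("ip", "AE", st))
  expect_error(lrt(f_cp, f_ip), "not nested")
  # reversed nesting: full AE cannot contain ACE
  f_ae <- fake(10, 5, model_spec("cp", "AE", st))
  f_ace <- fake(9, 8, model_spec("cp", "ACE", st))
  expect_error(lrt(f_ae, f_ace), "not nested")
  # parameter counts inconsistent with the claimed nesting
  expect_error(lrt(fake(10, 5), fake(9, 8)), "more free parameters")
})

test_that("bootstrap: degenerate statistic, reproducibility, CI behaviour", {
  cp <- small_cp_params()
  st <- structure6()
  d <- simulate_twins(sim_config(cp, 250, 350, missing_rate = 0, seed = 42))
  spec <- model_spec("cp", "AE", st)
  f0 <- fit_model(d, spec, n_starts = 2, seed = 1)
  # a statistic with zero sampling variance: fixed parameter count
  bc_k <- bootstrap_ci(d, spec, B = 5, seed = 3,
                       statistic = function(f) c(k = f$n_free_params),
                       fit = f0, control = list(factr = 1e7))
  expect_equal(bc_k$lower[["k"]], bc_k$upper[["k"]])
  expect_equal(bc_k$lower[["k"]], f0$n_free_params)
  # seed reproducibility and a sane interval around the point estimate
  stat <- function(f) c(a2 = unname(f$factor_effects[1, "a"]))
  b1 <- bootstrap_ci(d, spec, B = 60, seed = 11, statistic = stat, fit = f0,
                     control = list(factr = 1e7))
  b2 <- bootstrap_ci(d, spec, B = 60, seed = 11, statistic = stat, fit = f0,
                     control = list(factr = 1e7))
  expect_identical(b1$replicates, b2$replicates)
  expect_lt(b1$lower[["a2"]], b1$upper[["a2"]])
  expect_equal(b1$n_dropped, 0L)
  expect_error(bootstrap_ci(d, spec, B = 1, seed = 1, statistic = stat),
               "B must be")
})

test_that("twin_bifactor_indices: delegation, degenerate and contrast cases", {
  st <- conners_structure()
  n <- st$n_items
  mask <- biftwin:::loading_mask(st)
  mk <- function(gen, grp) {
    M <- matrix(0, n, 3)
    M[, 1] <- gen
    M[cbind(seq_len(n), st$group_of + 1L)] <- grp
    loading_matrix(M, st)
  }
  # E: strong coherent general; C: essentially no general factor; A: middling
  shape <- seq(0.9, 1.1, length.out = n)
  la <- mk(0.30 * shape, 0.25 * shape)
  lc <- mk(0.02 * shape * rep(c(1, -1), n / 2), 0.12 * shape)
  le <- mk(0.55 * shape, 0.25 * shape)
  u2 <- 1 - (rowSums(unclass(la)^2) + rowSums(unclass(lc)^2) +
               rowSums(unclass(le)^2))
  ip <- ip_params(la, lc, le, cbind(a = 0.1, c = 0, e = sqrt(u2 - 0.01)))
  fit <- structure(list(spec = model_spec("ip", "ACE", st), params = ip),
                   class = "twin_fit")
  idx <- twin_bifactor_indices(fit)
  # qualitative published pattern: E passes both cutoffs, C fails both
  expect_true(idx$E$pass[["omega_h"]] && idx$E$pass[["h_index"]])
  expect_false(idx$C$pass[["omega_h"]] || idx$C$pass[["h_index"]])
  # ECV delegation identity
  std <- standardized_source_loadings(fit)
  for (s in c("A", "C", "E")) {
    expect_equal(idx[[s]]$ecv, ecv(std[[s]]))
  }
  # all-zero general loadings in a source: ECV 0, fails cutoffs
  lz <- mk(0, 0.4)
  ipz <- ip_params(lz, lc, le,
                   cbind(a = rep(0.1, n), c = rep(0, n), e = rep(0.5, n)))
  fitz <- structure(list(spec = model_spec("ip", "ACE", st), params = ipz),
                    class = "twin_fit")
  iz <- twin_bifactor_indices(fitz)
  expect_equal(iz$A$ecv, 0)
  expect_false(any(iz$A$pass))
  # CP fits are rejected
  fit_cp <- structure(list(spec = model_spec("cp", "ACE", st)),
                      class = "twin_fit")
  expect_error(twin_bifactor_indices(fit_cp), "undefined")
})
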