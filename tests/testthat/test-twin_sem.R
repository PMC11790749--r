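# twin_sem: expected covariances, FIML, fitting, standardized effects

test_that("expected_cov_cp: trivial path-tracing cases", {
  st <- structure4()
  # E-only: cross-twin block identically zero
  L <- loading_matrix(matrix(c(rep(0.5, 4), rep(0.3, 8)), 4, 3), st)
  fp <- cbind(a = 0, c = 0, e = 1)[rep(1, 3), ]
  up <- cbind(a = 0, c = 0, e = rep(0.6, 4))
  s_mz <- expected_cov_cp(cp_params(L, fp, up), "MZ")
  expect_equal(s_mz[1:4, 5:8], matrix(0, 4, 4), ignore_attr = TRUE)

  # single loaded item, pure-A factor: MZ cross 1, DZ cross 0.5
  M <- matrix(0, 4, 3)
  M[1, 1] <- 1
  L1 <- loading_matrix(M, st)
  fp1 <- rbind(c(1, 0, 0), c(0, 0, 1), c(0, 0, 1))
  colnames(fp1) <- c("a", "c", "e")
  up0 <- cbind(a = 0, c = 0, e = rep(1e-4, 4))
  p1 <- cp_params(L1, fp1, up0)
  expect_equal(expected_cov_cp(p1, "MZ")[1, 5], 1)
  expect_equal(expected_cov_cp(p1, "DZ")[1, 5], 0.5)
})

test_that("expected_cov_ip: trivial path-tracing cases", {
  st <- structure4()
  zeroL <- loading_matrix(matrix(0, 4, 3), st)
  M <- matrix(0, 4, 3)
  M[, 1] <- 0.4
  le <- loading_matrix(M, st)
  up <- cbind(a = 0, c = 0, e = rep(0.5, 4))
  pe <- ip_params(zeroL, zeroL, le, up)
  expect_equal(expected_cov_ip(pe, "MZ"), expected_cov_ip(pe, "DZ"))

  Ma <- matrix(0, 4, 3)
  Ma[1, 1] <- 0.3
  pa <- ip_params(loading_matrix(Ma, st), zeroL, le, up)
  expect_equal(expected_cov_ip(pa, "MZ")[1, 5], 0.09)
  expect_equal(expected_cov_ip(pa, "DZ")[1, 5], 0.045)
})

test_that("covariance builders equal the structural oracle (1e-10)", {
  for (seed in 1:5) {
    st <- if (seed %% 2) structure4() else bifactor_structure(rep(1:2, c(3, 2)))
    cp <- random_cp_params(st, seed)
    ip <- random_ip_params(st, seed + 100)
    for (z in c("MZ", "DZ")) {
      expect_lt(max(abs(expected_cov_cp(cp, z) - oracle_cov(cp, z))), 1e-10)
      expect_lt(max(abs(expected_cov_ip(ip, z) - oracle_cov(ip, z))), 1e-10)
    }
  }
})

test_that("MZ minus DZ cross-twin block is PSD for real paths", {
  for (seed in 11:14) {
    p <- if (seed %% 2) random_cp_params(structure4(), seed) else
      random_ip_params(structure4(), seed)
    f <- if (inherits(p, "cp_params")) expected_cov_cp else expected_cov_ip
    diff <- f(p, "MZ")[1:4, 5:8] - f(p, "DZ")[1:4, 5:8]
    ev <- eigen((diff + t(diff)) / 2, symmetric = TRUE, only.values = TRUE)
    expect_gt(min(ev$values), -1e-10)
  }
})

test_that("FIML equals the direct MVN likelihood on complete data", {
  st <- structure4()
  cp <- random_cp_params(st, 3)
  d <- simulate_twins(sim_config(cp, n_mz = 40, n_dz = 60, missing_rate = 0,
                                 seed = 9))
  s_mz <- expected_cov_cp(cp, "MZ")
  s_dz <- expected_cov_cp(cp, "DZ")
  got <- fiml_minus2ll(d, s_mz, s_dz)
  Y <- biftwin:::pair_matrix(d)
  z <- d$pairs$zygosity
  want <- direct_mvn_m2ll(Y[z == "MZ", ], s_mz) +
    direct_mvn_m2ll(Y[z == "DZ", ], s_dz)
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("FIML handles missingness: scalar case and marginalization", {
  st <- structure4()
  # one pair, a single observed value 0 with unit model variance: log(2*pi)
  d <- toy_twin_data(st, 1, 1)
  Y <- matrix(NA_real_, 2, 8)
  Y[1, 1] <- 0
  d$pairs[, biftwin:::item_cols(st)] <- Y
  expect_equal(fiml_minus2ll(d, diag(8), diag(8)), log(2 * pi),
               tolerance = 1e-10)

  # diagonal model: masking one variable removes exactly its own term
  set.seed(12)
  d2 <- toy_twin_data(st, 2, 2)
  v <- seq(0.5, 1.9, length.out = 8)
  m_full <- fiml_minus2ll(d2, diag(v), diag(v))
  x <- d2$pairs$i02_t1[3]
  d2m <- d2
  d2m$pairs$i02_t1[3] <- NA
  m_masked <- fiml_minus2ll(d2m, diag(v), diag(v))
  expect_equal(m_full - m_masked, log(2 * pi) + log(v[2]) + x^2 / v[2],
               tolerance = 1e-8)
  # and FIML with missingness matches the row-wise oracle
  Ym <- biftwin:::pair_matrix(d2m)
  z <- d2m$pairs$zygosity
  want <- direct_mvn_m2ll(Ym[z == "MZ", ], diag(v)) +
    direct_mvn_m2ll(Ym[z == "DZ", ], diag(v))
  expect_equal(m_masked, want, tolerance = 1e-8)
})

test_that("analytic gradients match central finite differences", {
  st <- structure4()
  for (family in c("cp", "ip")) {
    spec <- model_spec(family, "ACE", st)
    p <- if (family == "cp") random_cp_params(st, 41) else
      random_ip_params(st, 42)
    d <- simulate_twins(sim_config(p, 60, 80, missing_rate = 0.12,
                                   missing_unit = "item", seed = 6))
    pm <- biftwin:::param_map(spec)
    Y <- biftwin:::pair_matrix(d)
    z <- d$pairs$zygosity
    pats <- list(MZ = biftwin:::build_patterns(Y[z == "MZ", , drop = FALSE]),
                 DZ = biftwin:::build_patterns(Y[z == "DZ", , drop = FALSE]))
    mu <- numeric(8)
    set.seed(43)
    th <- biftwin:::pack_params(p, spec, pm) * runif(pm$npar, 0.85, 1.15)
    g_an <- biftwin:::m2ll_theta(th, spec, pm, pats, mu, grad = TRUE)$gradient
    g_fd <- fd_grad(function(t) {
      biftwin:::m2ll_theta(t, spec, pm, pats, mu)$value
    }, th)
    expect_lt(max(abs(g_an - g_fd) / (1 + abs(g_fd))), 1e-5)
  }
})

test_that("likelihood is invariant to flipping a loading column's sign", {
  st <- structure4()
  cp <- random_cp_params(st, 77)
  d <- simulate_twins(sim_config(cp, 50, 50, missing_rate = 0, seed = 2))
  base <- fiml_minus2ll(d, expected_cov_cp(cp, "MZ"), expected_cov_cp(cp, "DZ"))
  flipped <- cp
  L <- unclass(flipped$loadings)
  L[, 2] <- -L[, 2]
  flipped$loadings <- loading_matrix(L, st)
  expect_equal(fiml_minus2ll(d, expected_cov_cp(flipped, "MZ"),
                             expected_cov_cp(flipped, "DZ")),
               base, tolerance = 1e-10)
})

test_that("E-only fit recovers unique variances within 0.03 at n = 4000", {
  st <- structure6()
  M <- matrix(0, 6, 3)
  M[, 1] <- seq(0.45, 0.6, length.out = 6)
  M[cbind(1:6, st$group_of + 1L)] <- seq(0.3, 0.42, length.out = 6)
  L <- loading_matrix(M, st)
  e_u <- sqrt(1 - rowSums(unclass(L)^2))
  pe <- cp_params(L, cbind(a = 0, c = 0, e = 1)[rep(1, 3), ],
                  cbind(a = 0, c = 0, e = e_u))
  d <- simulate_twins(sim_config(pe, n_mz = 2000, n_dz = 2000,
                                 missing_rate = 0, seed = 33))
  spec <- model_spec("cp", "E", st)
  fit <- fit_model(d, spec, n_starts = 2, seed = 1)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$params$unique_paths[, "e"]^2 - e_u^2)), 0.03)
})

test_that("refits from jittered starts agree in -2LL within 0.01", {
  cp <- small_cp_params()
  d <- simulate_twins(sim_config(cp, 300, 400, missing_rate = 0, seed = 55))
  spec <- model_spec("cp", "AE", structure6())
  lls <- vapply(1:3, function(s) {
    fit_model(d, spec, n_starts = 2, seed = s)$minus2LL
  }, 0)
  expect_lt(max(lls) - min(lls), 0.01)
})

test_that("standardized effects: row sums and aggregation identities", {
  ip <- demo_ip_params()
  std <- standardized_effects(ip)
  expect_true(all(abs(rowSums(std) - 1) < 1e-10))

  # published A-column aggregation: shares 50/18.75/18.75/12.5
  agg <- aggregate_standardized_effects(
    list(A = c(general = 0.08, inattention = 0.03, hyperactivity = 0.03,
               unique = 0.02)))
  expect_equal(unname(agg$A$shares),
               c(0.500, 0.1875, 0.1875, 0.125))
  # concentrated and uniform cases
  conc <- aggregate_standardized_effects(list(A = c(1, 0, 0, 0)))
  expect_equal(unname(conc$A$shares), c(1, 0, 0, 0))
  unif <- aggregate_standardized_effects(list(A = rep(0.1, 4)))
  expect_equal(unname(unif$A$shares), rep(0.25, 4))
})

test_that("complete-data path equals row-wise FIML through fit objects", {
  cp <- small_cp_params(structure4(), h2 = c(0.4, 0.4, 0.4))
  d <- simulate_twins(sim_config(cp, 80, 80, missing_rate = 0, seed = 71))
  ec <- expected_covariances(cp)
  Y <- biftwin:::pair_matrix(d)
  z <- d$pairs$zygosity
  want <- direct_mvn_m2ll(Y[z == "MZ", ], ec$sigma_mz) +
    direct_mvn_m2ll(Y[z == "DZ", ], ec$sigma_dz)
  expect_equal(fiml_minus2ll(d, ec$sigma_mz, ec$sigma_dz), want,
               tolerance = 1e-6)
})
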