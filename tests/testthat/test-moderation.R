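test_that("zero-beta expected covariance equals the plain Cholesky oracle", {
  pars <- list(a_M = 0.7, c_M = 0.5, e_M = 0.6, a_C = 0.3, e_C = 0.15,
               a_U = 0.65, e_U = 0.45)
  for (zyg in c("MZ", "DZ")) {
    S <- expected_cov_moderation(pars, m1 = 1.7, m2 = -0.4, zygosity = zyg)
    oracle <- cholesky_cov_oracle(0.7, 0.5, 0.6, 0.3, 0.15, 0.65, 0.45, zyg)
    expect_equal(unname(S), unname(oracle), tolerance = 1e-12)
  }
  # full variant with a shared-C path
  pars$c_C <- 0.2
  S <- expected_cov_moderation(pars, 0.3, 0.9, "DZ")
  oracle <- cholesky_cov_oracle(0.7, 0.5, 0.6, 0.3, 0.15, 0.65, 0.45, "DZ",
                                c_C = 0.2)
  expect_equal(unname(S), unname(oracle), tolerance = 1e-12)
})

test_that("a moderator-only model leaves the trait block empty", {
  S <- expected_cov_moderation(list(a_M = 1), 0.5, -0.5, "DZ")
  expect_equal(S[c("T1", "T2"), ], matrix(0, 2, 4,
               dimnames = list(c("T1", "T2"), colnames(S))))
  expect_equal(unname(S[c("M1", "M2"), c("M1", "M2")]),
               matrix(c(1, 0.5, 0.5, 1), 2, 2))
})

test_that("moderated loadings follow the stated hand arithmetic", {
  # a_C = 1, beta_aC = 0.5, m = (2, -2): alpha = (2, 0)
  S <- expected_cov_moderation(list(a_C = 1, beta_aC = 0.5), 2, -2, "MZ")
  expect_equal(S["T1", "T2"], 0)
  expect_equal(S["T1", "T1"], 4)
  expect_equal(S["T2", "T2"], 0)
})

test_that("expected covariance is symmetric and positive semi-definite", {
  set.seed(60)
  pars <- list(a_M = 0.6, c_M = 0.4, e_M = 0.7, a_C = 0.3, e_C = 0.1,
               a_U = 0.6, e_U = 0.4, beta_aC = 0.05, beta_eC = -0.03,
               beta_aU = -0.08, beta_eU = 0.06)
  for (i in 1:20) {
    m <- rnorm(2, 0, 2)
    S <- expected_cov_moderation(pars, m[1], m[2],
                                 sample(c("MZ", "DZ"), 1))
    expect_equal(S, t(S))
    expect_gte(min(eigen(S, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("moderation FIML equals the per-pair 4x4 oracle", {
  ch <- with_resid_cols(simulate_moderation(moderation_sim_spec(
    n_mz_pairs = 40, n_dz_pairs = 60, beta_aU = -0.2, seed = 61)))
  fit <- fit_moderation(ch, "no_shared_C", restarts = 0)
  p <- as.list(fit$params)
  d <- ch$individuals
  ll <- 0
  for (zyg in c("MZ", "DZ")) {
    pr <- ch$pairs[ch$pairs$zygosity == zyg, , drop = FALSE]
    for (i in seq_len(nrow(pr))) {
      i1 <- match(pr$id1[i], d$person_id)
      i2 <- match(pr$id2[i], d$person_id)
      m <- c(d$walkability_resid[i1], d$walkability_resid[i2])
      tt <- c(d$bmi_resid[i1], d$bmi_resid[i2])
      S <- expected_cov_moderation(p, m[1], m[2], zyg)
      mu <- c(p$mu_M, p$mu_T, p$mu_M, p$mu_T)
      ll <- ll + mvn_loglik_oracle(c(m[1], tt[1], m[2], tt[2]), mu, S)
    }
  }
  expect_equal(fit$loglik, ll, tolerance = 1e-8)
})

test_that("moderation loglik is invariant to within-pair twin order", {
  ch <- with_resid_cols(simulate_moderation(moderation_sim_spec(
    n_mz_pairs = 60, n_dz_pairs = 60, beta_eU = 0.15, seed = 62)))
  f1 <- fit_moderation(ch, "no_shared_C", restarts = 0)
  d <- ch$individuals
  d$person_id <- ifelse(grepl("_1$", d$person_id),
                        sub("_1$", "_9", d$person_id),
                        sub("_2$", "_0", d$person_id))
  ch2 <- twin_cohort(d)  # resid columns survive reconstruction
  f2 <- fit_moderation(ch2, "no_shared_C", restarts = 0)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(abs(f1$params), abs(f2$params), tolerance = 1e-4)
})

test_that("beta-constrained fit reproduces the unmoderated Cholesky fit", {
  ch <- with_resid_cols(simulate_moderation(moderation_sim_spec(
    n_mz_pairs = 150, n_dz_pairs = 200, seed = 63)))
  f0 <- fit_moderation(ch, "no_shared_C", fix_betas = TRUE, restarts = 2)
  f1 <- fit_moderation(ch, "no_shared_C", fix_betas = FALSE, restarts = 2)
  # the moderated model nests the unmoderated one
  expect_gte(f1$loglik + 1e-6, f0$loglik)
  expect_equal(f1$k - f0$k, 4)
  # at the constrained optimum the expected covariance equals the plain
  # Cholesky expectation, so the loglik matches the 4x4 oracle there
  p <- as.list(f0$params)
  S_mz <- expected_cov_moderation(p, 0.4, -1.1, "MZ")
  oracle <- cholesky_cov_oracle(p$a_M, p$c_M, p$e_M, p$a_C, p$e_C,
                                p$a_U, p$e_U, "MZ")
  expect_equal(unname(S_mz), unname(oracle), tolerance = 1e-12)
})

test_that("moderation betas are recovered under a fixed alternative", {
  est <- vapply(1:25, function(i) {
    ch <- with_resid_cols(simulate_moderation(moderation_sim_spec(
      n_mz_pairs = 250, n_dz_pairs = 380, beta_aU = -0.3,
      seed = 6000 + i)))
    fit_moderation(ch, "no_shared_C", restarts = 0)$params[["beta_aU"]]
  }, 0)
  expect_gt(mean(est < 0), 0.9)  # sign recovered
  expect_lt(abs(mean(est) + 0.3), 3 * sd(est) / sqrt(25) + 0.02)
})

test_that("the no-shared-C variant wins on data truly lacking shared C", {
  prefer <- vapply(1:9, function(i) {
    ch <- with_resid_cols(simulate_moderation(moderation_sim_spec(
      n_mz_pairs = 150, n_dz_pairs = 220, c_C = 0, seed = 6100 + i)))
    cmp <- compare_moderation_variants(ch, restarts = 0)
    cmp$aic_diff > 0
  }, TRUE)
  expect_gt(mean(prefer), 0.5)
})

test_that("variance profiles are flat without betas and normalized always", {
  pars <- list(a_C = 0.3, e_C = 0.1, a_U = 0.6, e_U = 0.4)
  vp <- variance_profile(pars, seq(-3, 3, by = 0.5))
  expect_equal(diff(range(vp$profile$var_A)), 0)
  expect_equal(diff(range(vp$profile$var_E)), 0)
  expect_equal(vp$profile$share_A + vp$profile$share_E,
               rep(1, nrow(vp$profile)))
  expect_length(vp$intersections, 0)
  expect_error(variance_profile(pars, numeric(0)), "empty")
})

test_that("genetic centre / environmental extremes give two intersections", {
  # A dominates near m = 0; E variance grows quadratically on both sides
  pars <- list(a_C = 0, e_C = 0, a_U = 0.8, beta_aU = 0.05,
               e_U = 0.35, beta_eU = 0.3)
  vp <- variance_profile(pars, seq(-5, 5, length.out = 201))
  expect_length(vp$intersections, 2)
  expect_lt(vp$intersections[1], 0)
  expect_gt(vp$intersections[2], 0)
  # intersections solve var_A(m) = var_E(m) to the bisection tolerance
  g <- function(m) (0.8 + 0.05 * m)^2 - (0.35 + 0.3 * m)^2
  expect_lt(max(abs(vapply(vp$intersections, g, 0))), 1e-3)
  # E dominates at both extremes, A in the centre
  pr <- vp$profile
  expect_gt(pr$share_A[pr$m == 0], 0.5)
  expect_lt(pr$share_A[1], 0.5)
  expect_lt(pr$share_A[nrow(pr)], 0.5)
})

test_that("fit_moderation validates its inputs", {
  ch <- simulate_moderation(moderation_sim_spec(
    n_mz_pairs = 30, n_dz_pairs = 30, seed = 64))
  expect_error(fit_moderation(ch), "residualize")
  small <- with_resid_cols(simulate_moderation(moderation_sim_spec(
    n_mz_pairs = 4, n_dz_pairs = 30, seed = 65)))
  expect_error(fit_moderation(small), "at least 10 complete pairs")
})
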