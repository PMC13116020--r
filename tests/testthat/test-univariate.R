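test_that("ICC handles perfect concordance and independence", {
  d <- make_individuals(20, zygosity = "MZ",
                        walkability = rep(rnorm(20, 43.4, 12), 2))
  icc <- intraclass_correlation(twin_cohort(d), "MZ", "walkability")
  expect_gt(icc$icc, 0.999)

  set.seed(20)
  iccs <- vapply(1:30, function(i) {
    d <- make_individuals(100, zygosity = "DZ",
                          walkability = rnorm(200, 43.4, 12))
    intraclass_correlation(twin_cohort(d), "DZ", "walkability")$icc
  }, 0)
  expect_lt(abs(mean(iccs)), 3 * sd(iccs) / sqrt(30))
})

test_that("ICC equals the constrained-saturated ML estimate and brackets it", {
  set.seed(21)
  z <- matrix(rnorm(400), 200)
  x1 <- z[, 1]
  x2 <- 0.5 * z[, 1] + sqrt(1 - 0.25) * z[, 2]
  d <- make_individuals(200, zygosity = "MZ",
                        walkability = c(x1, x2))
  icc <- intraclass_correlation(twin_cohort(d), "MZ", "walkability")
  # closed-form ML under exchangeability
  mu <- mean(c(x1, x2))
  v <- mean(c((x1 - mu)^2, (x2 - mu)^2))
  expect_equal(icc$icc, mean((x1 - mu) * (x2 - mu)) / v, tolerance = 1e-10)
  expect_lt(icc$ci95[1], icc$icc)
  expect_gt(icc$ci95[2], icc$icc)
  expect_error(intraclass_correlation(twin_cohort(make_individuals(2)),
                                      "MZ", "walkability"),
               "at least 3")
})

test_that("Falconer decomposition follows its closed form", {
  f <- falconer_decomposition(0.46, 0.34)
  expect_equal(c(f$A, f$C, f$E), c(0.24, 0.22, 0.54), tolerance = 1e-12)
  expect_false(f$out_of_range)

  f <- falconer_decomposition(1.0, 0.5)
  expect_equal(c(f$A, f$C, f$E), c(1, 0, 0))

  f <- falconer_decomposition(0.2, 0.3)
  expect_equal(f$A, -0.2)
  expect_true(f$out_of_range)
})

test_that("base-model selection applies the twice-rDZ rule with ties to ACE", {
  expect_equal(select_base_model(0.46, 0.34), "ACE")
  expect_equal(select_base_model(0.6, 0.25), "ADE")
  expect_equal(select_base_model(0.6, 0.30), "ACE")  # boundary not exceeded
})

test_that("expected twin covariances follow the path algebra", {
  p <- list(model = "ACE", a = 1, c_or_d = 0, e = 0)
  expect_equal(expected_cov_univariate(p, "MZ"), matrix(1, 2, 2))
  expect_equal(expected_cov_univariate(p, "DZ"),
               matrix(c(1, 0.5, 0.5, 1), 2, 2))

  p <- list(model = "ACE", a = sqrt(0.22), c_or_d = sqrt(0.22),
            e = sqrt(0.56))
  expect_equal(expected_cov_univariate(p, "MZ")[1, 2], 0.44)
  expect_equal(expected_cov_univariate(p, "DZ")[1, 2], 0.33)
  expect_equal(expected_cov_univariate(p, "MZ")[1, 1], 1.00)

  p <- list(model = "ADE", a = sqrt(0.3), c_or_d = sqrt(0.4), e = sqrt(0.3))
  expect_equal(expected_cov_univariate(p, "MZ")[1, 2], 0.7)
  expect_equal(expected_cov_univariate(p, "DZ")[1, 2], 0.25)
})

test_that("FIML loglik equals the per-pair closed-form oracle", {
  ch <- simulate_univariate(univariate_sim_spec(
    n_mz_pairs = 60, n_dz_pairs = 80, singleton_fraction = 0.15, seed = 33))
  f <- fit_univariate(ch, "ACE", "walkability", ci = "none", restarts = 1)
  expect_equal(f$loglik, uni_loglik_oracle(f, ch, "walkability"),
               tolerance = 1e-8)
  f_ae <- fit_univariate(ch, "AE", "walkability", ci = "none", restarts = 1)
  expect_equal(f_ae$loglik, uni_loglik_oracle(f_ae, ch, "walkability"),
               tolerance = 1e-8)
})

test_that("pure-noise data recover a standardized E near 1", {
  est <- vapply(1:10, function(i) {
    ch <- simulate_univariate(univariate_sim_spec(
      n_mz_pairs = 150, n_dz_pairs = 150, a2 = 0, c2 = 0, e2 = 1,
      seed = 50 + i))
    f <- fit_univariate(ch, "ACE", "walkability", ci = "none", restarts = 2)
    s <- f$standardized
    s$proportion[s$component == "E"]
  }, 0)
  # A and C estimates are non-negative by construction, so sampling noise
  # under a pure-E truth leaves E slightly below 1 on average
  expect_gt(mean(est), 0.9)
})

test_that("nested log-likelihoods are monotone: E <= AE <= ACE", {
  ch <- simulate_univariate(univariate_sim_spec(
    n_mz_pairs = 100, n_dz_pairs = 150, seed = 41))
  ll <- vapply(c("E", "AE", "ACE"), function(m) {
    fit_univariate(ch, m, "walkability", ci = "none", restarts = 2)$loglik
  }, 0)
  expect_lte(ll["E"], ll["AE"] + 1e-6)
  expect_lte(ll["AE"], ll["ACE"] + 1e-6)
})

test_that("estimates are invariant to twin order and row shuffling", {
  ch <- simulate_univariate(univariate_sim_spec(
    n_mz_pairs = 80, n_dz_pairs = 80, seed = 42))
  f1 <- fit_univariate(ch, "ACE", "walkability", ci = "none")

  d <- ch$individuals
  shuffled <- twin_cohort(d[rev(seq_len(nrow(d))), ])
  f2 <- fit_univariate(shuffled, "ACE", "walkability", ci = "none")
  expect_equal(f1$params, f2$params, tolerance = 1e-10)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-10)

  d3 <- d
  d3$person_id <- ifelse(grepl("_1$", d$person_id),
                         sub("_1$", "_9", d$person_id),
                         sub("_2$", "_0", d$person_id))
  f3 <- fit_univariate(twin_cohort(d3), "ACE", "walkability", ci = "none")
  expect_equal(f1$params, f3$params, tolerance = 1e-8)
  expect_equal(f1$loglik, f3$loglik, tolerance = 1e-8)
})

test_that("jittered restarts reach the same optimum", {
  ch <- simulate_univariate(univariate_sim_spec(
    n_mz_pairs = 120, n_dz_pairs = 150, seed = 43))
  f <- fit_univariate(ch, "ACE", "walkability", ci = "none", restarts = 5)
  expect_lt(max(f$loglik_restarts) - min(f$loglik_restarts), 1e-5)
})

test_that("Falconer and FIML agree at large samples", {
  ch <- simulate_univariate(univariate_sim_spec(
    n_mz_pairs = 10000, n_dz_pairs = 10000, seed = 44))
  fal <- falconer_decomposition(
    intraclass_correlation(ch, "MZ", "walkability")$icc,
    intraclass_correlation(ch, "DZ", "walkability")$icc)
  f <- fit_univariate(ch, "ACE", "walkability", ci = "none", restarts = 1)
  sh <- stats::setNames(f$standardized$proportion, f$standardized$component)
  mc_se <- 3 * 0.05 / sqrt(100)  # ~3 MC SEs of a component at this n
  expect_lt(abs(sh[["A"]] - fal$A), 0.02)
  expect_lt(abs(sh[["C"]] - fal$C), 0.02)
  expect_lt(abs(sh[["E"]] - fal$E), 0.02)
})

test_that("profile CIs bracket the estimate and widen for A vs E", {
  ch <- simulate_univariate(univariate_sim_spec(seed = 45))
  f <- fit_univariate(ch, "ACE", "walkability", ci = "profile")
  s <- f$standardized
  expect_true(all(s$ci_lower <= s$proportion + 1e-8))
  expect_true(all(s$ci_upper >= s$proportion - 1e-8))
  expect_true(all(s$ci_lower >= 0 & s$ci_upper <= 1))
  # A is far less precisely determined than E in a twin design
  width <- s$ci_upper - s$ci_lower
  expect_gt(width[s$component == "A"], width[s$component == "E"])
  expect_equal(sum(s$proportion), 1, tolerance = 1e-6)
})

test_that("model comparison reports AIC, LRT and flags the best model", {
  ch <- simulate_univariate(univariate_sim_spec(seed = 46))
  fits <- lapply(c("ACE", "AE", "CE", "E"), function(m) {
    fit_univariate(ch, m, "walkability", ci = "none", restarts = 2)
  })
  cmp <- compare_models(fits, reference = "ACE")
  expect_equal(nrow(cmp), 4)
  expect_equal(cmp$aic, -2 * cmp$loglik + 2 * cmp$k)
  nested <- cmp[cmp$model != "ACE", ]
  expect_equal(nested$lrt_p,
               stats::pchisq(nested$lrt_stat, nested$df, lower.tail = FALSE))
  expect_equal(sum(cmp$best_aic), 1)

  cmp_dup <- compare_models(list(fits[[1]], fits[[1]]), reference = "ACE")
  expect_equal(cmp_dup$aic[1], cmp_dup$aic[2])
  expect_equal(cmp_dup$lrt_p[2], 1)

  other <- simulate_univariate(univariate_sim_spec(seed = 47))
  f_other <- fit_univariate(other, "AE", "walkability", ci = "none")
  expect_error(compare_models(list(fits[[1]], f_other)),
               "different observation sets")
})

test_that("AIC selects the generating model most of the time", {
  picks <- vapply(1:15, function(i) {
    ch <- simulate_univariate(univariate_sim_spec(
      a2 = 0.5, c2 = 0, e2 = 0.5, seed = 800 + i))
    fits <- lapply(c("ACE", "AE", "CE", "E"), function(m) {
      fit_univariate(ch, m, "walkability", ci = "none", restarts = 1)
    })
    cmp <- compare_models(fits, reference = "ACE")
    cmp$model[cmp$best_aic]
  }, "")
  expect_gt(mean(picks == "AE"), 0.5)
})

test_that("dropping a real component worsens AIC at cohort scale", {
  worse <- vapply(1:10, function(i) {
    ch <- simulate_univariate(univariate_sim_spec(seed = 900 + i))
    ace <- fit_univariate(ch, "ACE", "walkability", ci = "none",
                          restarts = 1)
    e_only <- fit_univariate(ch, "E", "walkability", ci = "none",
                             restarts = 1)
    e_only$aic > ace$aic
  }, TRUE)
  expect_gt(mean(worse), 0.9)
})

test_that("saturated model matches cell moments and nests the ACE family", {
  ch <- simulate_univariate(univariate_sim_spec(
    n_mz_pairs = 300, n_dz_pairs = 400, seed = 48))
  free <- fit_saturated(ch, "walkability")
  expect_equal(free$df, 0)
  expect_equal(free$lrt_p, 1)

  # fully constrained saturated model vs ACE fit: same loglik when the
  # sample moments satisfy the twin structure (Falconer estimates in range)
  con <- fit_saturated(ch, "walkability",
                       constraints = c("means_order", "means_zyg",
                                       "vars_order", "vars_zyg"))
  expect_equal(con$k, 4)
  expect_equal(con$df, 6)
  ace <- fit_univariate(ch, "ACE", "walkability", ci = "none", restarts = 2)
  fal <- falconer_decomposition(con$rho[1], con$rho[2])
  if (!fal$out_of_range) {
    expect_equal(ace$loglik, con$loglik, tolerance = 1e-5)
  }
  expect_gte(con$loglik_unconstrained + 1e-6, con$loglik)
})

test_that("a forced twin-order mean shift is detected by the LRT", {
  ch <- simulate_univariate(univariate_sim_spec(
    n_mz_pairs = 477, n_dz_pairs = 734, total_var = 1, mean = 0, seed = 49))
  d <- ch$individuals
  d$walkability[grepl("_1$", d$person_id)] <-
    d$walkability[grepl("_1$", d$person_id)] + 1  # +1 SD on twin 1
  shifted <- twin_cohort(d)
  sat <- fit_saturated(shifted, "walkability", constraints = "means_order")
  expect_equal(sat$df, 2)
  expect_lt(sat$lrt_p, 1e-6)
})
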