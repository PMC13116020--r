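# Shared fixtures built in code.

# Minimal individual-level data.frame; override any column via `...`.
make_individuals <- function(n_pairs = 2,
                             zygosity = rep(c("MZ", "DZ"), length.out = n_pairs),
                             ...) {
  pid <- sprintf("p%02d", seq_len(n_pairs))
  d <- data.frame(
    person_id = c(paste0(pid, "_1"), paste0(pid, "_2")),
    pair_id = rep(pid, 2),
    zygosity = rep(zygosity, 2),
    sex = "female",
    age = 43,
    bmi = 26.5,
    walkability = 43.4,
    work_employed = 1,
    edu_high = 1,
    lives_with_partner = 1,
    deprivation_z = 0,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) d[[nm]] <- over[[nm]]
  d
}

write_cohort_csv <- function(d) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(d, path, row.names = FALSE, na = "", quote = FALSE)
  path
}

# MZ-only cohort in which the walkability-BMI association is purely
# pair-level confounding: a shared factor U drives both the pair's
# walkability level and its BMI, while within-pair walkability variation is
# unrelated to BMI. Used to show the co-twin-control design removes the
# association.
make_confounded_mz <- function(n_pairs, effect = -0.5) {
  U <- rnorm(n_pairs)
  W1 <- 43.4 + 6 * U + 4 * rnorm(n_pairs)
  W2 <- 43.4 + 6 * U + 4 * rnorm(n_pairs)
  B1 <- 26.5 + effect * U + rnorm(n_pairs)
  B2 <- 26.5 + effect * U + rnorm(n_pairs)
  make_individuals(n_pairs, zygosity = "MZ",
                   walkability = c(W1, W2), bmi = c(B1, B2),
                   age = rep(runif(n_pairs, 30, 55), 2),
                   sex = rep(sample(c("male", "female"), n_pairs, TRUE), 2))
}

# Plain per-pair multivariate-normal log-likelihood via solve()/determinant:
# the independent oracle for the vectorized FIML code paths.
mvn_loglik_oracle <- function(x, mu, sigma) {
  k <- length(mu)
  d <- x - mu
  -k / 2 * log(2 * pi) - 0.5 * as.numeric(determinant(sigma)$modulus) -
    0.5 * sum(d * solve(sigma, d))
}

# Oracle FIML log-likelihood of a fitted univariate twin model.
uni_loglik_oracle <- function(fit, cohort, phenotype) {
  pl <- as.list(fit$params)
  params <- list(model = fit$model,
                 a = pl$a %||0% 0,
                 c_or_d = pl$c %||0% pl$d %||0% 0,
                 e = pl$e)
  mu <- fit$mean
  ll <- 0
  d <- cohort$individuals
  for (zyg in c("MZ", "DZ")) {
    S <- expected_cov_univariate(params, zyg)
    pr <- cohort$pairs[cohort$pairs$zygosity == zyg, , drop = FALSE]
    for (i in seq_len(nrow(pr))) {
      v1 <- d[[phenotype]][match(pr$id1[i], d$person_id)]
      v2 <- if (pr$complete[i]) {
        d[[phenotype]][match(pr$id2[i], d$person_id)]
      } else {
        NA_real_
      }
      obs <- c(v1, v2)[!is.na(c(v1, v2))]
      if (length(obs) == 2L) {
        ll <- ll + mvn_loglik_oracle(obs, c(mu, mu), S)
      } else if (length(obs) == 1L) {
        ll <- ll + dnorm(obs, mu, sqrt(S[1, 1]), log = TRUE)
      }
    }
  }
  ll
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

# Unmoderated bivariate Cholesky expected covariance, written directly from
# the path diagram as an independent oracle for expected_cov_moderation().
cholesky_cov_oracle <- function(a_M, c_M, e_M, a_C, e_C, a_U, e_U, zygosity,
                                c_C = 0) {
  r <- if (zygosity == "MZ") 1 else 0.5
  # loadings of (M, T) on the moderator-side latents and trait-unique latents
  one_twin_cov <- matrix(c(
    a_M^2 + c_M^2 + e_M^2, a_M * a_C + c_M * c_C + e_M * e_C,
    a_M * a_C + c_M * c_C + e_M * e_C,
    a_C^2 + c_C^2 + e_C^2 + a_U^2 + e_U^2
  ), 2, 2)
  cross_cov <- matrix(c(
    r * a_M^2 + c_M^2, r * a_M * a_C + c_M * c_C,
    r * a_M * a_C + c_M * c_C,
    r * (a_C^2 + a_U^2) + c_C^2
  ), 2, 2)
  rbind(cbind(one_twin_cov, cross_cov), cbind(t(cross_cov), one_twin_cov))
}

# Attach residualized phenotype columns equal to the raw simulated values
# (the moderation generator already works on mean-zero scales).
with_resid_cols <- function(cohort) {
  cohort$individuals$walkability_resid <- cohort$individuals$walkability
  cohort$individuals$bmi_resid <- cohort$individuals$bmi
  cohort
}
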