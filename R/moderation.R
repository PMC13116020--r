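#' @title Bivariate Cholesky moderation model
#' @description
#' Gene-environment interaction model in which a continuous exposure
#' (walkability, the moderator M) both shares latent genetic and
#' environmental factors with a trait (BMI, T) and linearly moderates the
#' paths toward the trait. The moderator enters the model-expected
#' covariance as an observed per-twin definition variable, so every pair has
#' its own 4x4 expected covariance over (M1, T1, M2, T2). The moderator's
#' own ACE structure simultaneously captures gene-environment correlation.
#' @name moderation_twin
NULL

MOD_PARAMS_CORE <- c("a_M", "c_M", "e_M", "a_C", "e_C", "a_U", "e_U",
                     "beta_aC", "beta_eC", "beta_aU", "beta_eU",
                     "mu_M", "mu_T")
MOD_PARAMS_FULL <- c(MOD_PARAMS_CORE, "c_C", "beta_cC")

as_mod_params <- function(params) {
  p <- as.list(params)
  for (nm in MOD_PARAMS_FULL) p[[nm]] <- p[[nm]] %||% 0
  p
}

#' Model-implied covariance of a twin pair under moderation
#'
#' The 4x4 expected covariance over (M1, T1, M2, T2) given the pair's
#' observed moderator values. With `r` the additive-genetic twin correlation
#' (1 MZ, 0.5 DZ) and moderated loadings `alpha_i = a_C + beta_aC*m_i`
#' (similarly `eps`, `u`, `w`, and `gamma` for the shared-C path):
#' `Var(M) = a_M^2 + c_M^2 + e_M^2`; `Cov(M1, M2) = r*a_M^2 + c_M^2`;
#' `Cov(M_i, T_i) = a_M*alpha_i + e_M*eps_i + c_M*gamma_i`;
#' `Cov(M_i, T_j) = r*a_M*alpha_j + c_M*gamma_j`;
#' `Var(T_i) = alpha_i^2 + eps_i^2 + u_i^2 + w_i^2 + gamma_i^2`;
#' `Cov(T1, T2) = r*(alpha_1*alpha_2 + u_1*u_2) + gamma_1*gamma_2`.
#'
#' @param params named list/vector of path coefficients and betas (see
#'   [moderation_sim_spec()] for the naming); absent entries default to 0.
#' @param m1,m2 the pair's observed (residualized) moderator values.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return Symmetric 4x4 matrix with rows/columns `M1, T1, M2, T2`.
#' @export
expected_cov_moderation <- function(params, m1, m2,
                                    zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  p <- as_mod_params(params)
  r <- if (zygosity == "MZ") 1 else 0.5
  al <- p$a_C + p$beta_aC * c(m1, m2)
  ep <- p$e_C + p$beta_eC * c(m1, m2)
  ga <- p$c_C + p$beta_cC * c(m1, m2)
  u <- p$a_U + p$beta_aU * c(m1, m2)
  w <- p$e_U + p$beta_eU * c(m1, m2)
  vM <- p$a_M^2 + p$c_M^2 + p$e_M^2
  cMM <- r * p$a_M^2 + p$c_M^2
  vT <- al^2 + ep^2 + ga^2 + u^2 + w^2
  cTT <- r * (al[1] * al[2] + u[1] * u[2]) + ga[1] * ga[2]
  cMT_own <- p$a_M * al + p$e_M * ep + p$c_M * ga
  cMT_cross <- r * p$a_M * al + p$c_M * ga  # element j: Cov(M_i, T_j), i != j
  S <- matrix(0, 4, 4,
              dimnames = list(c("M1", "T1", "M2", "T2"),
                              c("M1", "T1", "M2", "T2")))
  S["M1", "M1"] <- vM; S["M2", "M2"] <- vM
  S["M1", "M2"] <- S["M2", "M1"] <- cMM
  S["T1", "T1"] <- vT[1]; S["T2", "T2"] <- vT[2]
  S["T1", "T2"] <- S["T2", "T1"] <- cTT
  S["M1", "T1"] <- S["T1", "M1"] <- cMT_own[1]
  S["M2", "T2"] <- S["T2", "M2"] <- cMT_own[2]
  S["M1", "T2"] <- S["T2", "M1"] <- cMT_cross[2]
  S["M2", "T1"] <- S["T1", "M2"] <- cMT_cross[1]
  S
}

# Vectorized FIML log-likelihood contribution of complete pairs of one
# zygosity. m1, m2, t1, t2 are vectors over pairs. Uses the conditional
# decomposition loglik(M) + loglik(T | M): the M block of the expected
# covariance is constant within zygosity, so the conditional mean and 2x2
# conditional covariance of (T1, T2) have closed elementwise forms.
mod_loglik_zyg <- function(p, r, m1, m2, t1, t2) {
  n <- length(m1)
  if (n == 0L) return(0)
  vM <- p$a_M^2 + p$c_M^2 + p$e_M^2
  cMM <- r * p$a_M^2 + p$c_M^2
  detM <- vM^2 - cMM^2
  if (vM <= 0 || detM <= 0) return(-Inf)
  llM <- bvn_loglik(m1, m2, p$mu_M, p$mu_M, vM, vM, cMM / vM)
  if (!is.finite(llM)) return(-Inf)

  al1 <- p$a_C + p$beta_aC * m1; al2 <- p$a_C + p$beta_aC * m2
  ep1 <- p$e_C + p$beta_eC * m1; ep2 <- p$e_C + p$beta_eC * m2
  ga1 <- p$c_C + p$beta_cC * m1; ga2 <- p$c_C + p$beta_cC * m2
  u1 <- p$a_U + p$beta_aU * m1; u2 <- p$a_U + p$beta_aU * m2
  w1 <- p$e_U + p$beta_eU * m1; w2 <- p$e_U + p$beta_eU * m2

  # S_MT entries: p_kj = Cov(M_k, T_j)
  p11 <- p$a_M * al1 + p$e_M * ep1 + p$c_M * ga1
  p22 <- p$a_M * al2 + p$e_M * ep2 + p$c_M * ga2
  p12 <- r * p$a_M * al2 + p$c_M * ga2
  p21 <- r * p$a_M * al1 + p$c_M * ga1

  vT1 <- al1^2 + ep1^2 + ga1^2 + u1^2 + w1^2
  vT2 <- al2^2 + ep2^2 + ga2^2 + u2^2 + w2^2
  cTT <- r * (al1 * al2 + u1 * u2) + ga1 * ga2

  # B = S_MM^{-1}
  b11 <- vM / detM
  b12 <- -cMM / detM

  c11 <- vT1 - (p11^2 * b11 + 2 * p11 * p21 * b12 + p21^2 * b11)
  c22 <- vT2 - (p12^2 * b11 + 2 * p12 * p22 * b12 + p22^2 * b11)
  c12 <- cTT - (b11 * (p11 * p12 + p21 * p22) +
                  b12 * (p11 * p22 + p21 * p12))
  detC <- c11 * c22 - c12^2
  if (any(c11 <= 0) || any(detC <= 0)) return(-Inf)

  um1 <- m1 - p$mu_M; um2 <- m2 - p$mu_M
  bu1 <- b11 * um1 + b12 * um2
  bu2 <- b12 * um1 + b11 * um2
  mu_t1 <- p$mu_T + p11 * bu1 + p21 * bu2
  mu_t2 <- p$mu_T + p12 * bu1 + p22 * bu2
  d1 <- t1 - mu_t1; d2 <- t2 - mu_t2
  quad <- (d1^2 * c22 - 2 * d1 * d2 * c12 + d2^2 * c11) / detC
  llT <- -n * log(2 * pi) - sum(log(detC)) / 2 - sum(quad) / 2
  llM + llT
}

# Complete-pair moderation data: per-zygosity matrices of (m1, m2, t1, t2).
mod_data <- function(cohort, moderator, trait) {
  d <- cohort$individuals
  get_zyg <- function(zyg) {
    p <- cohort$pairs[cohort$pairs$zygosity == zyg & cohort$pairs$complete, ,
                      drop = FALSE]
    i1 <- match(p$id1, d$person_id)
    i2 <- match(p$id2, d$person_id)
    m1 <- d[[moderator]][i1]; m2 <- d[[moderator]][i2]
    t1 <- d[[trait]][i1]; t2 <- d[[trait]][i2]
    ok <- !is.na(m1) & !is.na(m2) & !is.na(t1) & !is.na(t2)
    list(m1 = m1[ok], m2 = m2[ok], t1 = t1[ok], t2 = t2[ok],
         n_excluded = sum(!ok))
  }
  mz <- get_zyg("MZ"); dz <- get_zyg("DZ")
  n_inc <- sum(!cohort$pairs$complete)
  list(mz = mz, dz = dz,
       n_pairs_used = c(MZ = length(mz$m1), DZ = length(dz$m1)),
       n_pairs_excluded = mz$n_excluded + dz$n_excluded + n_inc)
}

mod_theta_names <- function(variant, fix_betas) {
  nms <- if (variant == "full") MOD_PARAMS_FULL else MOD_PARAMS_CORE
  if (fix_betas) nms <- nms[!startsWith(nms, "beta_")] else nms
}

mod_loglik <- function(theta, nms, dat) {
  p <- as_mod_params(stats::setNames(theta, nms))
  ll <- mod_loglik_zyg(p, 1, dat$mz$m1, dat$mz$m2, dat$mz$t1, dat$mz$t2)
  if (!is.finite(ll)) return(-Inf)
  ll + mod_loglik_zyg(p, 0.5, dat$dz$m1, dat$dz$m2, dat$dz$t1, dat$dz$t2)
}

mod_starts <- function(dat, nms) {
  m_all <- c(dat$mz$m1, dat$mz$m2, dat$dz$m1, dat$dz$m2)
  t_all <- c(dat$mz$t1, dat$mz$t2, dat$dz$t1, dat$dz$t2)
  vM <- stats::var(m_all); sdT <- stats::sd(t_all)
  rmz <- stats::cor(c(dat$mz$m1, dat$mz$m2), c(dat$mz$m2, dat$mz$m1))
  rdz <- stats::cor(c(dat$dz$m1, dat$dz$m2), c(dat$dz$m2, dat$dz$m1))
  fal <- falconer_decomposition(max(min(rmz, 0.9), 0), max(min(rdz, 0.9), 0))
  clamp <- function(x) max(min(x, 0.85), 0.05)
  rmt <- stats::cor(m_all, t_all)
  st <- c(
    a_M = sqrt(clamp(fal$A) * vM), c_M = sqrt(clamp(fal$C) * vM),
    e_M = sqrt(clamp(fal$E) * vM),
    a_C = 0.7 * rmt * sdT, e_C = 0.3 * rmt * sdT,
    a_U = 0.7 * sdT, e_U = 0.55 * sdT,
    beta_aC = 0, beta_eC = 0, beta_aU = 0, beta_eU = 0,
    mu_M = mean(m_all), mu_T = mean(t_all),
    c_C = 0.1 * sdT, beta_cC = 0
  )
  st[nms]
}

#' Fit the bivariate Cholesky moderation model by FIML
#'
#' Maximizes the full-information likelihood over complete pairs (both twins
#' observed on both phenotypes; all other pairs are excluded and counted),
#' with each pair contributing a 4-dimensional normal term whose covariance
#' is [expected_cov_moderation()] evaluated at the pair's own moderator
#' values. Both phenotypes are expected to be residualized for age and sex
#' beforehand. The `"full"` variant includes a shared-C path and its beta;
#' `"no_shared_C"` drops both (the nested model used when the trait shows no
#' shared-environment component). Optimization is quasi-Newton from
#' moment-based starts via an internal no-moderation prefit, plus
#' deterministic jittered restarts.
#'
#' @param cohort a [twin_cohort()].
#' @param variant `"no_shared_C"` (default) or `"full"`.
#' @param moderator,trait phenotype column names (typically the
#'   `_resid` columns from [residualize_phenotype()]).
#' @param fix_betas logical: fix all moderation betas at 0 (the unmoderated
#'   bivariate Cholesky model, used as the LRT null).
#' @param restarts number of jittered optimizer restarts.
#' @return Object of class `twingem_modfit`: `params` (named vector),
#'   `loglik`, `aic` (`-2 logL + 2k`), `k`, `variant`, `fix_betas`,
#'   `n_pairs_used`, `n_pairs_excluded`, `hessian_pd` flag.
#' @export
fit_moderation <- function(cohort, variant = c("no_shared_C", "full"),
                           moderator = "walkability_resid",
                           trait = "bmi_resid",
                           fix_betas = FALSE, restarts = 2L) {
  stopifnot(inherits(cohort, "twin_cohort"))
  variant <- match.arg(variant)
  for (col in c(moderator, trait)) {
    if (is.null(cohort$individuals[[col]])) {
      stop("cohort lacks column '", col,
           "'; residualize the phenotypes first")
    }
  }
  dat <- mod_data(cohort, moderator, trait)
  if (any(dat$n_pairs_used < 10L)) {
    stop("need at least 10 complete pairs per zygosity (have MZ=",
         dat$n_pairs_used["MZ"], ", DZ=", dat$n_pairs_used["DZ"], ")")
  }
  nms <- mod_theta_names(variant, fix_betas)
  negll <- function(th) {
    ll <- mod_loglik(th, nms, dat)
    if (!is.finite(ll)) 1e10 else -ll
  }
  # two-stage default start: fit the unmoderated model from moment starts,
  # then release the betas from that solution
  if (!fix_betas) {
    nms0 <- mod_theta_names(variant, fix_betas = TRUE)
    negll0 <- function(th) {
      ll <- mod_loglik(th, nms0, dat)
      if (!is.finite(ll)) 1e10 else -ll
    }
    pre <- run_optim(mod_starts(dat, nms0), negll0, restarts = 1L)
    start <- stats::setNames(numeric(length(nms)), nms)
    start[nms0] <- pre$par
  } else {
    start <- mod_starts(dat, nms)
  }
  best <- run_optim(start, negll, restarts)
  if (!is.finite(best$value) || best$value >= 1e10) {
    stop("moderation FIML did not converge after ", restarts + 1, " starts")
  }
  theta <- stats::setNames(best$par, nms)
  H <- tryCatch(stats::optimHess(best$par, negll), error = function(e) NULL)
  hessian_pd <- !is.null(H) &&
    all(eigen(H, symmetric = TRUE, only.values = TRUE)$values > 0)
  if (!hessian_pd) {
    warning("Hessian not positive definite at the optimum; ",
            "estimates may sit on a boundary or ridge")
  }
  k <- length(nms)
  structure(list(
    params = theta, loglik = -best$value, aic = 2 * best$value + 2 * k,
    k = k, variant = variant, fix_betas = fix_betas,
    n_pairs_used = dat$n_pairs_used,
    n_pairs_excluded = dat$n_pairs_excluded,
    hessian_pd = hessian_pd,
    moderator = moderator, trait = trait
  ), class = "twingem_modfit")
}

#' @export
print.twingem_modfit <- function(x, ...) {
  cat(sprintf("Bivariate moderation fit (%s%s): logLik = %.3f, AIC = %.2f\n",
              x$variant, if (x$fix_betas) ", betas fixed at 0" else "",
              x$loglik, x$aic))
  cat(sprintf("  complete pairs: MZ %d, DZ %d (excluded %d)\n",
              x$n_pairs_used["MZ"], x$n_pairs_used["DZ"],
              x$n_pairs_excluded))
  print(round(x$params, 4))
  invisible(x)
}

#' Likelihood-ratio test of the moderation betas
#'
#' Fits the moderated and the beta-constrained (unmoderated) model on the
#' same cohort and returns the joint LRT of all betas (chi-square with df =
#' number of betas under the null of no moderation).
#'
#' @inheritParams fit_moderation
#' @return List: `fit_moderated`, `fit_null`, `stat`, `df`, `p`.
#' @export
moderation_lrt <- function(cohort, variant = c("no_shared_C", "full"),
                           moderator = "walkability_resid",
                           trait = "bmi_resid", restarts = 2L) {
  variant <- match.arg(variant)
  full <- fit_moderation(cohort, variant, moderator, trait,
                         fix_betas = FALSE, restarts = restarts)
  null <- fit_moderation(cohort, variant, moderator, trait,
                         fix_betas = TRUE, restarts = restarts)
  df <- full$k - null$k
  stat <- max(2 * (full$loglik - null$loglik), 0)
  list(fit_moderated = full, fit_null = null, stat = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Compare the full and no-shared-C moderation variants
#'
#' Fits both variants and reports AIC for each, the AIC difference, whether
#' the simpler variant is preferred by the "AIC difference > 2" rule, and
#' the LRT of the dropped shared-C parameters.
#'
#' @inheritParams fit_moderation
#' @return List: `fit_full`, `fit_no_shared_C`, `aic_diff`
#'   (`AIC(full) - AIC(no_shared_C)`), `prefer_no_shared_C`, `lrt`.
#' @export
compare_moderation_variants <- function(cohort,
                                        moderator = "walkability_resid",
                                        trait = "bmi_resid",
                                        restarts = 2L) {
  f_full <- fit_moderation(cohort, "full", moderator, trait,
                           restarts = restarts)
  f_red <- fit_moderation(cohort, "no_shared_C", moderator, trait,
                          restarts = restarts)
  aic_diff <- f_full$aic - f_red$aic
  df <- f_full$k - f_red$k
  stat <- max(2 * (f_full$loglik - f_red$loglik), 0)
  list(fit_full = f_full, fit_no_shared_C = f_red, aic_diff = aic_diff,
       prefer_no_shared_C = aic_diff > 2,
       lrt = list(stat = stat, df = df,
                  p = stats::pchisq(stat, df, lower.tail = FALSE)))
}

#' Variance components of the trait along the moderator
#'
#' Projects the fitted moderation model onto a grid of moderator values:
#' `var_A(m) = (a_C + beta_aC*m)^2 + (a_U + beta_aU*m)^2` and
#' `var_E(m) = (e_C + beta_eC*m)^2 + (e_U + beta_eU*m)^2` (a shared-C term
#' `(c_C + beta_cC*m)^2` is reported separately for the full variant),
#' together with the standardized shares. Moderator values where the A and E
#' curves cross are located by sign-change bracketing of `var_A - var_E`
#' on the grid followed by bisection to 1e-6: crossings flag
#' gene-environment interaction (the dominant source of trait variance
#' changes along the exposure).
#'
#' @param fit a `twingem_modfit`, or a named list/vector of moderation
#'   parameters.
#' @param grid numeric vector of moderator values (residualized index
#'   units), e.g. the observed range of the residualized moderator.
#' @return Object of class `twingem_profile`: `profile` data.frame (`m`,
#'   `var_A`, `var_E`, optionally `var_C`, `share_A`, `share_E`, ...) and
#'   `intersections` (moderator values where `var_A = var_E`).
#' @export
variance_profile <- function(fit, grid) {
  if (inherits(fit, "twingem_modfit")) {
    p <- as_mod_params(fit$params)
    has_c <- fit$variant == "full"
  } else {
    p <- as_mod_params(fit)
    has_c <- p$c_C != 0 || p$beta_cC != 0
  }
  grid <- sort(unique(as.numeric(grid)))
  if (length(grid) == 0L) stop("empty moderator grid")
  var_A <- function(m) (p$a_C + p$beta_aC * m)^2 + (p$a_U + p$beta_aU * m)^2
  var_E <- function(m) (p$e_C + p$beta_eC * m)^2 + (p$e_U + p$beta_eU * m)^2
  var_C <- function(m) (p$c_C + p$beta_cC * m)^2
  vA <- var_A(grid); vE <- var_E(grid)
  tot <- vA + vE + if (has_c) var_C(grid) else 0
  prof <- data.frame(m = grid, var_A = vA, var_E = vE)
  if (has_c) prof$var_C <- var_C(grid)
  prof$share_A <- vA / tot
  prof$share_E <- vE / tot
  if (has_c) prof$share_C <- prof$var_C / tot

  # A/E intersections: bracket sign changes of the difference on the grid,
  # then bisect each bracket
  g <- function(m) var_A(m) - var_E(m)
  dg <- g(grid)
  inters <- numeric(0)
  zero_hits <- grid[abs(dg) < 1e-12]
  if (length(grid) > 1L) {
    sgn <- sign(dg)
    for (i in which(sgn[-1] * sgn[-length(sgn)] < 0)) {
      lo <- grid[i]; hi <- grid[i + 1]
      while (hi - lo > 1e-6) {
        mid <- (lo + hi) / 2
        if (sign(g(mid)) == sign(g(lo)) && g(mid) != 0) lo <- mid else
          hi <- mid
      }
      inters <- c(inters, (lo + hi) / 2)
    }
  }
  inters <- sort(unique(c(inters, zero_hits)))
  structure(list(profile = prof, intersections = inters),
            class = "twingem_profile")
}

#' @export
print.twingem_profile <- function(x, ...) {
  rng <- range(x$profile$m)
  cat(sprintf("Variance profile over moderator [%.2f, %.2f] (%d points)\n",
              rng[1], rng[2], nrow(x$profile)))
  if (length(x$intersections)) {
    cat("  A/E intersections at m =",
        paste(formatC(x$intersections, digits = 3, format = "f"),
              collapse = ", "), "\n")
  } else {
    cat("  no A/E intersections in range\n")
  }
  invisible(x)
}
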