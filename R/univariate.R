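#' @title Univariate twin models
#' @description
#' Classical twin-design variance decomposition for a single phenotype:
#' intraclass correlations by zygosity, the Falconer closed form, selection
#' between ACE and ADE starting models, and full-information maximum
#' likelihood (FIML) fitting of the ACE/ADE family with nested-model
#' comparison and saturated-model assumption tests. Complete pairs
#' contribute bivariate-normal likelihood terms and singletons univariate
#' terms, so incomplete pairs still inform means and variances.
#' @name univariate_twin
NULL

#' Intraclass correlation for one zygosity group
#'
#' Maximum-likelihood correlation of a bivariate normal with means and
#' variances constrained equal across twin order (the constrained saturated
#' model): `mu` is the grand mean, `v` the average squared deviation and the
#' ICC the average cross-product over `v`. The 95% CI is obtained by
#' profiling the likelihood on the Fisher-z scale at the chi-square(1)
#' cutoff.
#'
#' @param cohort a [twin_cohort()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @param phenotype column name of the phenotype.
#' @return An object of class `twingem_icc`: `zygosity`, `icc`, `ci95`,
#'   `n_pairs`, `loglik`.
#' @export
intraclass_correlation <- function(cohort, zygosity = c("MZ", "DZ"),
                                   phenotype = "walkability") {
  stopifnot(inherits(cohort, "twin_cohort"))
  zygosity <- match.arg(zygosity)
  pm <- pair_matrix(cohort, zygosity, phenotype)
  x1 <- pm$pairs[, 1]; x2 <- pm$pairs[, 2]
  n <- length(x1)
  if (n < 3L) stop("need at least 3 complete ", zygosity, " pairs")

  mu <- mean(c(x1, x2))
  d1 <- x1 - mu; d2 <- x2 - mu
  s11 <- sum(d1^2); s22 <- sum(d2^2); s12 <- sum(d1 * d2)
  v <- (s11 + s22) / (2 * n)
  rho <- s12 / (n * v)
  rho <- max(min(rho, 1 - 1e-10), -1 + 1e-10)

  prof <- function(r) {
    if (abs(r) >= 1 - 1e-12) return(-Inf)
    vr <- (s11 + s22 - 2 * r * s12) / (2 * n * (1 - r^2))
    bvn_loglik(x1, x2, mu, mu, vr, vr, r)
  }
  ll_max <- prof(rho)
  cut <- stats::qchisq(0.95, 1)
  f <- function(z) {
    val <- 2 * (ll_max - prof(tanh(z))) - cut
    if (!is.finite(val)) 1e12 else val  # degenerate rho: outside the CI
  }
  zh <- atanh(rho)
  lo <- if (f(zh - 8) < 0) -1 else
    tanh(stats::uniroot(f, c(zh - 8, zh), tol = 1e-9)$root)
  hi <- if (f(zh + 8) < 0) 1 else
    tanh(stats::uniroot(f, c(zh, zh + 8), tol = 1e-9)$root)

  structure(list(zygosity = zygosity, icc = rho, ci95 = c(lo, hi),
                 n_pairs = n, loglik = ll_max),
            class = "twingem_icc")
}

#' @export
print.twingem_icc <- function(x, ...) {
  cat(sprintf("ICC (%s, %d pairs): %.3f (95%% CI %.3f, %.3f)\n",
              x$zygosity, x$n_pairs, x$icc, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Falconer decomposition from twin correlations
#'
#' Closed-form variance proportions `A = 2*(r_mz - r_dz)`,
#' `C = 2*r_dz - r_mz`, `E = 1 - r_mz`. Values are returned unclamped with
#' an `out_of_range` flag when any falls outside `[0, 1]`, which happens
#' e.g. when `r_dz > r_mz`.
#'
#' @param r_mz,r_dz intraclass correlations in `[-1, 1]`.
#' @return List with `A`, `C`, `E`, `out_of_range`.
#' @export
falconer_decomposition <- function(r_mz, r_dz) {
  stopifnot(abs(r_mz) <= 1, abs(r_dz) <= 1)
  A <- 2 * (r_mz - r_dz)
  C <- 2 * r_dz - r_mz
  E <- 1 - r_mz
  list(A = A, C = C, E = E,
       out_of_range = any(c(A, C, E) < 0 | c(A, C, E) > 1))
}

#' Choose the starting twin model from the intraclass correlations
#'
#' Returns `"ADE"` if the MZ correlation strictly exceeds twice the DZ
#' correlation (no evidence of shared environment, possible dominance),
#' `"ACE"` otherwise (ties included).
#'
#' @param r_mz,r_dz intraclass correlations.
#' @return `"ACE"` or `"ADE"`.
#' @export
select_base_model <- function(r_mz, r_dz) {
  if (r_mz > 2 * r_dz) "ADE" else "ACE"
}

#' Model-implied twin covariance matrix of a univariate model
#'
#' @param params list with `model` (`"ACE"`, `"ADE"`, `"AE"`, `"CE"`, `"E"`),
#'   path coefficients `a`, `c_or_d`, `e` (unused paths 0).
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return Symmetric 2x2 matrix: diagonal `a^2 + c^2 + e^2` (or `d^2`),
#'   off-diagonal `a^2 + c^2` for MZ and `a^2/2 + c^2` for DZ (ADE:
#'   `a^2 + d^2` MZ, `a^2/2 + d^2/4` DZ).
#' @export
expected_cov_univariate <- function(params, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  a2 <- params$a^2
  cd2 <- params$c_or_d^2
  e2 <- params$e^2
  dominance <- params$model == "ADE"
  vtot <- a2 + cd2 + e2
  off <- if (zygosity == "MZ") {
    a2 + cd2
  } else if (dominance) {
    a2 / 2 + cd2 / 4
  } else {
    a2 / 2 + cd2
  }
  matrix(c(vtot, off, off, vtot), 2, 2)
}

# Extract FIML data for a phenotype: per-zygosity complete-pair matrices and
# singleton values, plus a fingerprint used to verify that model comparisons
# run on identical observations.
fiml_data <- function(cohort, phenotype) {
  mz <- pair_matrix(cohort, "MZ", phenotype)
  dz <- pair_matrix(cohort, "DZ", phenotype)
  singles <- c(mz$singles, dz$singles)
  all_v <- c(mz$pairs, dz$pairs, singles)
  list(mz = mz$pairs, dz = dz$pairs, singles = singles,
       mz_slots = mz$single_slot, dz_slots = dz$single_slot,
       fingerprint = c(n_mz = nrow(mz$pairs), n_dz = nrow(dz$pairs),
                       n_single = length(singles),
                       sum = sum(all_v), sumsq = sum(all_v^2)))
}

uni_model_paths <- function(model) {
  switch(model,
         ACE = c("a", "c", "e"),
         ADE = c("a", "d", "e"),
         AE = c("a", "e"),
         CE = c("c", "e"),
         E = "e",
         stop("unknown model: ", model))
}

# FIML log-likelihood for a univariate twin model. theta = (mu, paths...).
uni_loglik <- function(theta, dat, model) {
  if (!all(is.finite(theta))) return(-Inf)
  mu <- theta[1]
  paths <- theta[-1]
  nm <- uni_model_paths(model)
  a <- if ("a" %in% nm) paths[match("a", nm)] else 0
  cd <- if ("c" %in% nm) paths[match("c", nm)] else
    if ("d" %in% nm) paths[match("d", nm)] else 0
  e <- paths[match("e", nm)]
  p <- list(model = model, a = a, c_or_d = cd, e = e)
  vtot <- a^2 + cd^2 + e^2
  if (vtot <= 0 || e^2 < 1e-12 * max(vtot, 1)) return(-Inf)
  Smz <- expected_cov_univariate(p, "MZ")
  Sdz <- expected_cov_univariate(p, "DZ")
  rmz <- Smz[1, 2] / vtot
  rdz <- Sdz[1, 2] / vtot
  if (abs(rmz) >= 1 || abs(rdz) >= 1) return(-Inf)
  bvn_loglik(dat$mz[, 1], dat$mz[, 2], mu, mu, vtot, vtot, rmz) +
    bvn_loglik(dat$dz[, 1], dat$dz[, 2], mu, mu, vtot, vtot, rdz) +
    uvn_loglik(dat$singles, mu, vtot)
}

# Moment-based starting values: Falconer estimates from sample twin
# correlations, clamped away from the boundary.
uni_starts <- function(dat, model) {
  allv <- c(dat$mz, dat$dz, dat$singles)
  mu0 <- mean(allv)
  v0 <- stats::var(allv)
  cor_of <- function(m) if (nrow(m) >= 3) stats::cor(m[, 1], m[, 2]) else 0.3
  rmz <- cor_of(dat$mz); rdz <- cor_of(dat$dz)
  fal <- falconer_decomposition(max(min(rmz, 0.95), -0.5),
                                max(min(rdz, 0.95), -0.5))
  clamp <- function(x) max(min(x, 0.9), 0.05)
  props <- switch(model,
    ACE = c(a = clamp(fal$A), c = clamp(fal$C), e = clamp(fal$E)),
    ADE = c(a = clamp(fal$A), d = clamp(4 * (rdz - rmz / 2)),
            e = clamp(fal$E)),
    AE = c(a = clamp(2 * rmz - rmz), e = clamp(1 - rmz)),
    CE = c(c = clamp(rdz), e = clamp(1 - rdz)),
    E = c(e = 1)
  )
  props <- props / sum(props)
  c(mu0, sqrt(props * v0))
}

run_optim <- function(start, negll, restarts) {
  best <- stats::optim(start, negll, method = "BFGS",
                       control = list(maxit = 1000, reltol = 1e-14))
  lls <- best$value
  if (restarts > 0) {
    fac <- restart_factors(restarts)
    for (k in seq_len(restarts)) {
      st <- start
      st[-1] <- st[-1] * fac[k]
      cand <- tryCatch(
        stats::optim(st, negll, method = "BFGS",
                     control = list(maxit = 1000, reltol = 1e-14)),
        error = function(e) NULL)
      if (!is.null(cand)) {
        lls <- c(lls, cand$value)
        if (cand$value < best$value - 1e-9) best <- cand
      }
    }
  }
  best$all_values <- lls
  best
}

#' Fit a univariate twin model by full-information maximum likelihood
#'
#' Maximizes the FIML log-likelihood of an ACE/ADE-family model: complete
#' pairs contribute bivariate-normal terms with the model-implied covariance
#' ([expected_cov_univariate()]), singletons univariate terms with the total
#' variance, and a single mean is shared across twins and zygosities. Paths
#' are unbounded during optimization and reported non-negative (their sign
#' is not identified); variance components are the squared paths.
#' Standardized proportions get 95% profile-likelihood CIs at the
#' chi-square(1) cutoff. The optimizer is quasi-Newton (BFGS) from
#' Falconer-based moment starts plus deterministic jittered restarts.
#'
#' The phenotype is expected to be residualized for age and sex beforehand
#' (see [residualize_phenotype()]).
#'
#' @param cohort a [twin_cohort()].
#' @param model `"ACE"`, `"ADE"`, `"AE"`, `"CE"` or `"E"`.
#' @param phenotype phenotype column name (e.g. `"walkability_resid"`).
#' @param ci `"profile"` for likelihood-based CIs on the standardized
#'   components, `"none"` to skip them (faster in simulation loops).
#' @param restarts number of jittered optimizer restarts.
#' @return An object of class `twingem_unifit`: `model`, `params` (paths,
#'   non-negative), `mean`, `loglik`, `aic` (`-2 logL + 2k`, `k` = paths +
#'   mean), `standardized` (data.frame of proportions with CIs),
#'   `n_pairs_used` (per zygosity), `n_singletons_used`, `e_at_bound` flag.
#' @export
fit_univariate <- function(cohort, model = c("ACE", "ADE", "AE", "CE", "E"),
                           phenotype = "walkability",
                           ci = c("profile", "none"), restarts = 5L) {
  stopifnot(inherits(cohort, "twin_cohort"))
  model <- match.arg(model)
  ci <- match.arg(ci)
  dat <- fiml_data(cohort, phenotype)
  if (model %in% c("ACE", "ADE", "AE", "CE") &&
      (nrow(dat$mz) < 10L || nrow(dat$dz) < 10L)) {
    stop("need at least 10 complete pairs per zygosity (have MZ=",
         nrow(dat$mz), ", DZ=", nrow(dat$dz), ")")
  }
  negll <- function(th) {
    ll <- uni_loglik(th, dat, model)
    if (!is.finite(ll)) 1e10 else -ll
  }
  start <- uni_starts(dat, model)
  best <- run_optim(start, negll, restarts)
  if (!is.finite(best$value) || best$value >= 1e10) {
    stop("univariate FIML did not converge; tried ", restarts + 1,
         " starts, best objective ", best$value)
  }
  theta <- best$par
  nm <- uni_model_paths(model)
  paths <- abs(stats::setNames(theta[-1], nm))
  vtot <- sum(paths^2)
  shares <- paths^2 / vtot
  e_at_bound <- shares["e"] < 1e-6
  if (e_at_bound) {
    warning("unique-environment path estimated at its lower bound")
  }
  ll <- -best$value
  k <- length(nm) + 1L
  comp_label <- toupper(nm)

  cis <- matrix(NA_real_, length(nm), 2,
                dimnames = list(comp_label, c("lower", "upper")))
  if (ci == "profile") {
    for (i in seq_along(nm)) {
      cis[i, ] <- profile_share_ci(dat, model, i, shares, vtot,
                                   mean_hat = theta[1], ll_max = ll)
    }
  }
  standardized <- data.frame(
    component = comp_label,
    proportion = unname(shares),
    ci_lower = cis[, 1], ci_upper = cis[, 2],
    row.names = NULL
  )
  structure(list(
    model = model, params = paths, mean = theta[1],
    loglik = ll, aic = -2 * ll + 2 * k, k = k,
    standardized = standardized,
    n_pairs_used = c(MZ = nrow(dat$mz), DZ = nrow(dat$dz)),
    n_singletons_used = length(dat$singles),
    e_at_bound = unname(e_at_bound),
    phenotype = phenotype,
    fingerprint = dat$fingerprint,
    loglik_restarts = -best$all_values
  ), class = "twingem_unifit")
}

# Profile-likelihood CI for the standardized share of component `comp_idx`
# (in model path order): re-maximize the likelihood with the share fixed on
# a grid point, root-find where -2*log-likelihood rises by qchisq(.95, 1).
profile_share_ci <- function(dat, model, comp_idx, shares, vtot, mean_hat,
                             ll_max) {
  nm <- uni_model_paths(model)
  if (length(nm) == 1L) return(c(1, 1))  # E model: share is 1 by definition
  cut <- stats::qchisq(0.95, 1)
  prof <- function(p) {
    # free parameters: mu, log total variance, and (for 3-component models)
    # the split of the remaining share between the other two components
    obj <- if (length(nm) == 3L) {
      function(th) {
        q <- stats::plogis(th[3])
        sh <- numeric(3)
        sh[comp_idx] <- p
        sh[-comp_idx] <- (1 - p) * c(q, 1 - q)
        ll <- uni_loglik(c(th[1], sqrt(sh * exp(th[2]))), dat, model)
        if (!is.finite(ll)) 1e10 else -ll
      }
    } else {
      function(th) {
        sh <- numeric(2)
        sh[comp_idx] <- p
        sh[-comp_idx] <- 1 - p
        ll <- uni_loglik(c(th[1], sqrt(sh * exp(th[2]))), dat, model)
        if (!is.finite(ll)) 1e10 else -ll
      }
    }
    other <- shares[-comp_idx]
    st <- c(mean_hat, log(vtot))
    if (length(nm) == 3L) {
      st <- c(st, stats::qlogis(min(max(other[1] / sum(other), 1e-3),
                                    1 - 1e-3)))
    }
    -stats::optim(st, obj, method = "BFGS",
                  control = list(maxit = 500, reltol = 1e-12))$value
  }
  f <- function(p) 2 * (ll_max - prof(p)) - cut
  p_hat <- shares[comp_idx]
  eps <- 1e-6
  lo <- if (p_hat <= eps || f(eps) < 0) 0 else
    stats::uniroot(f, c(eps, p_hat), tol = 1e-6)$root
  hi <- if (p_hat >= 1 - eps || f(1 - eps) < 0) 1 else
    stats::uniroot(f, c(p_hat, 1 - eps), tol = 1e-6)$root
  c(lo, hi)
}

#' @export
print.twingem_unifit <- function(x, ...) {
  cat(sprintf("Univariate %s fit (%s): logLik = %.3f, AIC = %.2f\n",
              x$model, x$phenotype, x$loglik, x$aic))
  cat(sprintf("  pairs used: MZ %d, DZ %d; singletons %d\n",
              x$n_pairs_used["MZ"], x$n_pairs_used["DZ"],
              x$n_singletons_used))
  s <- x$standardized
  for (i in seq_len(nrow(s))) {
    ci_txt <- if (is.na(s$ci_lower[i])) "" else
      sprintf(" (95%% CI %.2f, %.2f)", s$ci_lower[i], s$ci_upper[i])
    cat(sprintf("  %s: %.2f%s\n", s$component[i], s$proportion[i], ci_txt))
  }
  invisible(x)
}

#' Compare fitted univariate twin models
#'
#' AIC table (`-2 logL + 2k`, smaller is better) and likelihood-ratio tests
#' of each model against the reference, with degrees of freedom equal to the
#' difference in free parameters. All fits must come from identical
#' observations.
#'
#' @param fits list of `twingem_unifit` objects.
#' @param reference model label of the reference (default the first fit).
#' @return A `data.frame` with one row per model: `model`, `k`, `loglik`,
#'   `aic`, `lrt_stat`, `df`, `lrt_p`, `best_aic` flag. Class
#'   `twingem_model_comparison`.
#' @export
compare_models <- function(fits, reference = NULL) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE,
                                          "twingem_unifit")))
  labels <- vapply(fits, `[[`, "", "model")
  names(fits) <- labels
  reference <- reference %||% labels[1]
  if (!reference %in% labels) stop("reference model not among fits")
  fp <- fits[[1]]$fingerprint
  for (f in fits[-1]) {
    if (!isTRUE(all.equal(f$fingerprint, fp))) {
      stop("fits were computed on different observation sets")
    }
  }
  ref_idx <- match(reference, labels)
  ref <- fits[[ref_idx]]
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    is_ref <- i == ref_idx
    df <- ref$k - f$k
    stat <- 2 * (ref$loglik - f$loglik)
    p <- if (is_ref) {
      NA_real_
    } else if (df <= 0L) {
      if (abs(stat) < 1e-8) 1 else NA_real_
    } else {
      stats::pchisq(max(stat, 0), df, lower.tail = FALSE)
    }
    data.frame(model = f$model, k = f$k, loglik = f$loglik, aic = f$aic,
               lrt_stat = ifelse(is_ref, NA, stat),
               df = ifelse(is_ref, NA, df),
               lrt_p = p)
  })
  out <- do.call(rbind, rows)
  out$best_aic <- out$aic == min(out$aic)
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  class(out) <- c("twingem_model_comparison", "data.frame")
  out
}

# ---- saturated model ---------------------------------------------------

# Cells are (zygosity x canonical twin order): MZ1, MZ2, DZ1, DZ2.
SAT_CELLS <- data.frame(
  cell = c("MZ1", "MZ2", "DZ1", "DZ2"),
  zyg = c("MZ", "MZ", "DZ", "DZ"),
  ord = c(1L, 2L, 1L, 2L),
  stringsAsFactors = FALSE
)

sat_groups <- function(collapse_order, collapse_zyg) {
  key <- rep("all", 4L)
  if (!collapse_order && !collapse_zyg) key <- SAT_CELLS$cell
  if (!collapse_order && collapse_zyg) key <- paste0("ord", SAT_CELLS$ord)
  if (collapse_order && !collapse_zyg) key <- SAT_CELLS$zyg
  match(key, unique(key))
}

# Saturated FIML log-likelihood given per-cell means/SDs and per-zygosity
# correlations.
sat_loglik <- function(mu, sd, rho, dat) {
  if (any(sd <= 0) || any(abs(rho) >= 1)) return(-Inf)
  ll <- bvn_loglik(dat$mz[, 1], dat$mz[, 2], mu[1], mu[2],
                   sd[1]^2, sd[2]^2, rho[1]) +
    bvn_loglik(dat$dz[, 1], dat$dz[, 2], mu[3], mu[4],
               sd[3]^2, sd[4]^2, rho[2])
  mz_cells <- ifelse(dat$mz_slots == 1L, 1L, 2L)
  dz_cells <- ifelse(dat$dz_slots == 1L, 3L, 4L)
  mzs <- dat$singles[seq_along(dat$mz_slots)]
  dzs <- dat$singles[length(dat$mz_slots) + seq_along(dat$dz_slots)]
  for (i in seq_along(mzs)) {
    ll <- ll + uvn_loglik(mzs[i], mu[mz_cells[i]], sd[mz_cells[i]]^2)
  }
  for (i in seq_along(dzs)) {
    ll <- ll + uvn_loglik(dzs[i], mu[dz_cells[i]], sd[dz_cells[i]]^2)
  }
  ll
}

fit_sat_constrained <- function(dat, mean_groups, var_groups) {
  n_mu <- max(mean_groups); n_sd <- max(var_groups)
  cell_start_mu <- c(mean(dat$mz[, 1]), mean(dat$mz[, 2]),
                     mean(dat$dz[, 1]), mean(dat$dz[, 2]))
  cell_start_sd <- sqrt(c(stats::var(dat$mz[, 1]), stats::var(dat$mz[, 2]),
                          stats::var(dat$dz[, 1]), stats::var(dat$dz[, 2])))
  start <- c(
    tapply(cell_start_mu, mean_groups, mean),
    log(tapply(cell_start_sd, var_groups, mean)),
    atanh(c(max(min(stats::cor(dat$mz[, 1], dat$mz[, 2]), 0.95), -0.95),
            max(min(stats::cor(dat$dz[, 1], dat$dz[, 2]), 0.95), -0.95)))
  )
  negll <- function(th) {
    mu <- th[mean_groups]
    sd <- exp(th[n_mu + var_groups])
    rho <- tanh(th[n_mu + n_sd + 1:2])
    ll <- sat_loglik(mu, sd, rho, dat)
    if (!is.finite(ll)) 1e10 else -ll
  }
  best <- run_optim_plain(start, negll)
  k <- n_mu + n_sd + 2L
  list(loglik = -best$value, k = k, par = best$par,
       mu = best$par[mean_groups], sd = exp(best$par[n_mu + var_groups]),
       rho = tanh(best$par[n_mu + n_sd + 1:2]))
}

run_optim_plain <- function(start, negll) {
  stats::optim(start, negll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
}

#' Saturated twin model with equality-constraint tests
#'
#' The unconstrained saturated model estimates a mean and variance for every
#' zygosity-by-twin-order cell plus a covariance per zygosity. Constraint
#' sets impose equality of means and/or variances across twin order and/or
#' zygosity; each constrained model is compared to the unconstrained one by
#' a likelihood-ratio test with degrees of freedom equal to the number of
#' imposed equalities. These are the standard assumption checks run before
#' ACE-family modelling.
#'
#' @param cohort a [twin_cohort()].
#' @param phenotype phenotype column name.
#' @param constraints character subset of `"means_order"`, `"means_zyg"`,
#'   `"vars_order"`, `"vars_zyg"`; empty for the unconstrained model only.
#' @return List of class `twingem_satfit`: `loglik`, `aic`, `k`,
#'   `loglik_unconstrained`, `lrt_stat`, `df`, `lrt_p`, fitted cell moments.
#' @export
fit_saturated <- function(cohort, phenotype = "walkability",
                          constraints = character()) {
  stopifnot(inherits(cohort, "twin_cohort"))
  valid <- c("means_order", "means_zyg", "vars_order", "vars_zyg")
  bad <- setdiff(constraints, valid)
  if (length(bad)) stop("unknown constraint(s): ", paste(bad, collapse = ", "))
  dat <- fiml_data(cohort, phenotype)
  if (nrow(dat$mz) < 10L || nrow(dat$dz) < 10L) {
    stop("need at least 10 complete pairs per zygosity")
  }
  free <- fit_sat_constrained(dat, sat_groups(FALSE, FALSE),
                              sat_groups(FALSE, FALSE))
  mg <- sat_groups("means_order" %in% constraints,
                   "means_zyg" %in% constraints)
  vg <- sat_groups("vars_order" %in% constraints,
                   "vars_zyg" %in% constraints)
  con <- fit_sat_constrained(dat, mg, vg)
  df <- free$k - con$k
  stat <- max(2 * (free$loglik - con$loglik), 0)
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(
    constraints = constraints,
    loglik = con$loglik, k = con$k, aic = -2 * con$loglik + 2 * con$k,
    loglik_unconstrained = free$loglik, k_unconstrained = free$k,
    lrt_stat = stat, df = df, lrt_p = p,
    mu = con$mu, sd = con$sd, rho = con$rho,
    phenotype = phenotype
  ), class = "twingem_satfit")
}

#' @export
print.twingem_satfit <- function(x, ...) {
  cat("Saturated twin model (", x$phenotype, ")\n", sep = "")
  cat("  constraints:",
      if (length(x$constraints)) paste(x$constraints, collapse = ", ")
      else "(none)", "\n")
  cat(sprintf("  logLik = %.3f (unconstrained %.3f), AIC = %.2f\n",
              x$loglik, x$loglik_unconstrained, x$aic))
  if (x$df > 0) {
    cat(sprintf("  LRT: chi2 = %.3f, df = %d, p = %.4f\n",
                x$lrt_stat, x$df, x$lrt_p))
  }
  invisible(x)
}
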