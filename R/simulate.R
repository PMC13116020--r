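#' @title Synthetic twin-cohort generators
#' @description
#' Generators producing [twin_cohort()] objects with the statistical
#' structure each analysis stage assumes: Gaussian phenotypes built from
#' standard-normal latent genetic and environmental factors that correlate
#' 1.0 within MZ and 0.5 (additive) / 0.25 (dominance) within DZ pairs.
#' Default pair counts (477 MZ, 734 DZ) and phenotype moments (BMI mean 26.5
#' SD 5.1; walkability mean 43.4 SD 12.0) mirror a combined Finnish twin
#' cohort of middle-aged adults, so recovery tests run at a realistic
#' effective sample size.
#' @name simulate_cohort
NULL

#' Specification for the univariate ACE/ADE generator
#'
#' @param n_mz_pairs,n_dz_pairs pair counts.
#' @param a2,c2,e2 standardized variance proportions (additive genetic,
#'   shared environment, unique environment); must sum to 1.
#' @param d2 dominance proportion; supply `d2` instead of `c2` for an ADE
#'   generative model.
#' @param total_var total phenotype variance (index units squared).
#' @param mean phenotype mean.
#' @param singleton_fraction proportion of pairs that lose one co-twin
#'   completely at random.
#' @param seed integer RNG seed.
#' @return A list of class `univariate_sim_spec`.
#' @export
univariate_sim_spec <- function(n_mz_pairs = 477, n_dz_pairs = 734,
                                a2 = 0.22, c2 = 0.22, e2 = 0.56, d2 = NULL,
                                total_var = 144, mean = 43.4,
                                singleton_fraction = 0, seed = 1L) {
  if (!is.null(d2) && !missing(c2) && c2 != 0) {
    stop("supply either c2 (ACE) or d2 (ADE), not both")
  }
  cd <- if (is.null(d2)) c2 else d2
  props <- c(a2, cd, e2)
  if (any(props < 0)) stop("variance proportions must be non-negative")
  if (abs(sum(props) - 1) > 1e-8) {
    stop("variance proportions must sum to 1 (got ", sum(props), ")")
  }
  stopifnot(n_mz_pairs >= 0, n_dz_pairs >= 0, total_var > 0,
            singleton_fraction >= 0, singleton_fraction <= 1)
  structure(list(
    n_mz_pairs = as.integer(n_mz_pairs), n_dz_pairs = as.integer(n_dz_pairs),
    a2 = a2, c2 = if (is.null(d2)) c2 else 0, d2 = d2 %||% 0, e2 = e2,
    model = if (is.null(d2)) "ACE" else "ADE",
    total_var = total_var, mean = mean,
    singleton_fraction = singleton_fraction, seed = as.integer(seed)
  ), class = "univariate_sim_spec")
}

# Draw latent scores for n pairs with cross-twin correlation r: a matrix
# with columns twin1, twin2, each standard normal.
latent_pairs <- function(n, r) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  if (r == 1) {
    z <- rnorm(n)
    cbind(z, z)
  } else {
    zc <- rnorm(n)
    cbind(sqrt(r) * zc + sqrt(1 - r) * rnorm(n),
          sqrt(r) * zc + sqrt(1 - r) * rnorm(n))
  }
}

# Assemble a twin_cohort data.frame from per-zygosity phenotype matrices.
# Twin ids are zero-padded so lexicographic canonical order equals
# generation order. Sex is shared within MZ pairs; ages are shared within
# every pair (twins are born together).
build_sim_cohort <- function(ph_mz, ph_dz, phenotype, singleton_fraction,
                             extra_mz = NULL, extra_dz = NULL) {
  one_zyg <- function(ph, zyg, extra) {
    n <- nrow(ph)
    if (n == 0L) return(NULL)
    pid <- sprintf("%s%05d", zyg, seq_len(n))
    age <- pmin(pmax(rnorm(n, 42.6, 5.2), 20), 70)
    sex1 <- ifelse(runif(n) < 0.6, "female", "male")
    sex2 <- if (zyg == "MZ") sex1 else ifelse(runif(n) < 0.6, "female", "male")
    base <- data.frame(
      person_id = c(paste0(pid, "_1"), paste0(pid, "_2")),
      pair_id = c(pid, pid),
      zygosity = zyg,
      sex = c(sex1, sex2),
      age = c(age, age),
      bmi = NA_real_, walkability = NA_real_,
      work_employed = rbinom(2 * n, 1, 0.894),
      edu_high = rbinom(2 * n, 1, 0.623),
      lives_with_partner = rbinom(2 * n, 1, 0.721),
      deprivation_z = rnorm(2 * n),
      stringsAsFactors = FALSE
    )
    base[[phenotype]] <- c(ph[, 1], ph[, 2])
    if (!is.null(extra)) {
      for (nm in colnames(extra)) {
        base[[nm]] <- c(extra[seq_len(n), nm], extra[n + seq_len(n), nm])
      }
    }
    base
  }
  d <- rbind(one_zyg(ph_mz, "MZ", extra_mz), one_zyg(ph_dz, "DZ", extra_dz))
  if (singleton_fraction > 0) {
    pair_ids <- unique(d$pair_id)
    n_drop <- round(singleton_fraction * length(pair_ids))
    if (n_drop > 0) {
      drop_pairs <- sample(pair_ids, n_drop)
      d <- d[!(d$pair_id %in% drop_pairs & grepl("_2$", d$person_id)), ,
             drop = FALSE]
    }
  }
  twin_cohort(d)
}

#' Simulate a twin cohort under a univariate ACE or ADE model
#'
#' Each twin's phenotype is `mean + sqrt(total_var) * (a*A + c*C + e*E)`
#' (ADE: `d*D` instead of `c*C`) with standard-normal latents; A correlates
#' 1 within MZ and 0.5 within DZ pairs, D 1 / 0.25, C is shared exactly and
#' E is independent. A `singleton_fraction` of pairs lose twin 2 at random.
#'
#' @param spec a [univariate_sim_spec()].
#' @param phenotype column receiving the simulated trait (default
#'   `"walkability"`).
#' @return A [twin_cohort()]; reproducible from `spec$seed`.
#' @export
simulate_univariate <- function(spec, phenotype = c("walkability", "bmi")) {
  stopifnot(inherits(spec, "univariate_sim_spec"))
  phenotype <- match.arg(phenotype)
  with_seed(spec$seed, {
    a <- sqrt(spec$a2)
    cd <- sqrt(spec$c2 + spec$d2)  # exactly one of c2/d2 is non-zero
    e <- sqrt(spec$e2)
    r_cd_dz <- if (spec$model == "ACE") 1 else 0.25
    gen <- function(n, r_a) {
      A <- latent_pairs(n, r_a)
      CD <- if (spec$model == "ACE") latent_pairs(n, 1) else
        latent_pairs(n, if (r_a == 1) 1 else r_cd_dz)
      E <- latent_pairs(n, 0)
      spec$mean + sqrt(spec$total_var) * (a * A + cd * CD + e * E)
    }
    build_sim_cohort(gen(spec$n_mz_pairs, 1), gen(spec$n_dz_pairs, 0.5),
                     phenotype, spec$singleton_fraction)
  })
}

#' Specification for the bivariate moderation generator
#'
#' Path coefficients follow the bivariate Cholesky moderation layout: the
#' moderator M (walkability) has its own ACE structure (`a_M`, `c_M`, `e_M`);
#' the trait T (BMI) loads on the moderator's latent factors through shared
#' paths (`a_C`, `e_C`, optionally `c_C`) and on its own factors through
#' unique paths (`a_U`, `e_U`). Each `beta_*` adds a linear dependence of the
#' corresponding loading on the twin's own realized moderator value
#' (definition-variable convention), so non-zero betas create
#' gene-environment interaction.
#'
#' @param n_mz_pairs,n_dz_pairs pair counts.
#' @param a_M,c_M,e_M moderator paths (index units).
#' @param a_C,e_C,c_C shared paths toward the trait (kg/m^2 per latent unit).
#' @param a_U,e_U trait-unique paths (kg/m^2 per latent unit).
#' @param beta_aC,beta_eC,beta_cC,beta_aU,beta_eU moderation coefficients
#'   (kg/m^2 per latent unit per index unit).
#' @param mu_M,mu_T phenotype means (defaults 0: the moderation model runs on
#'   age/sex-residualized scales).
#' @param seed integer RNG seed.
#' @return A list of class `moderation_sim_spec`.
#' @export
moderation_sim_spec <- function(n_mz_pairs = 477, n_dz_pairs = 734,
                                a_M = sqrt(0.22), c_M = sqrt(0.22),
                                e_M = sqrt(0.56),
                                a_C = 0.3, e_C = 0.1, c_C = 0,
                                a_U = 0.65, e_U = 0.45,
                                beta_aC = 0, beta_eC = 0, beta_cC = 0,
                                beta_aU = 0, beta_eU = 0,
                                mu_M = 0, mu_T = 0, seed = 1L) {
  if (a_M^2 + c_M^2 + e_M^2 <= 0) stop("moderator variance must be positive")
  stopifnot(n_mz_pairs >= 0, n_dz_pairs >= 0)
  structure(list(
    n_mz_pairs = as.integer(n_mz_pairs), n_dz_pairs = as.integer(n_dz_pairs),
    a_M = a_M, c_M = c_M, e_M = e_M,
    a_C = a_C, e_C = e_C, c_C = c_C, a_U = a_U, e_U = e_U,
    beta_aC = beta_aC, beta_eC = beta_eC, beta_cC = beta_cC,
    beta_aU = beta_aU, beta_eU = beta_eU,
    mu_M = mu_M, mu_T = mu_T, seed = as.integer(seed)
  ), class = "moderation_sim_spec")
}

#' Simulate a twin cohort under the bivariate Cholesky moderation model
#'
#' Per twin, the moderator is `M = mu_M + a_M*A_C + c_M*C_C + e_M*E_C` and
#' the trait is built with loadings moderated by the twin's own realized `M`:
#' `T = mu_T + (a_C + beta_aC*M)*A_C + (e_C + beta_eC*M)*E_C +
#' (a_U + beta_aU*M)*A_U + (e_U + beta_eU*M)*E_U` (plus shared-C terms when
#' `c_C`/`beta_cC` are non-zero). A latents correlate 1 (MZ) / 0.5 (DZ)
#' across co-twins, C latents 1, E latents 0.
#'
#' @param spec a [moderation_sim_spec()].
#' @return A [twin_cohort()] with `walkability` = M and `bmi` = T;
#'   reproducible from `spec$seed`.
#' @export
simulate_moderation <- function(spec) {
  stopifnot(inherits(spec, "moderation_sim_spec"))
  with_seed(spec$seed, {
    gen <- function(n, r) {
      A_C <- latent_pairs(n, r); C_C <- latent_pairs(n, 1)
      E_C <- latent_pairs(n, 0)
      A_U <- latent_pairs(n, r); E_U <- latent_pairs(n, 0)
      M <- spec$mu_M + spec$a_M * A_C + spec$c_M * C_C + spec$e_M * E_C
      Tt <- spec$mu_T +
        (spec$a_C + spec$beta_aC * M) * A_C +
        (spec$e_C + spec$beta_eC * M) * E_C +
        (spec$c_C + spec$beta_cC * M) * C_C +
        (spec$a_U + spec$beta_aU * M) * A_U +
        (spec$e_U + spec$beta_eU * M) * E_U
      list(M = M, T = Tt)
    }
    mz <- gen(spec$n_mz_pairs, 1)
    dz <- gen(spec$n_dz_pairs, 0.5)
    extra <- function(g, n) {
      if (n == 0L) return(NULL)
      cbind(bmi = c(g$T[, 1], g$T[, 2]))
    }
    build_sim_cohort(mz$M, dz$M, "walkability", 0,
                     extra_mz = extra(mz, spec$n_mz_pairs),
                     extra_dz = extra(dz, spec$n_dz_pairs))
  })
}

#' Specification for the regression-recovery generator
#'
#' Generates pair-clustered cohorts for testing the individual-level
#' walkability-BMI regression: walkability with mean 43.4 and SD 12.0
#' (partly pair-shared), BMI built from a linear effect of walkability plus
#' covariate effects and a pair-shared + individual Gaussian residual scaled
#' so the BMI SD is about 5.1. When `covariate_walk_cor` is non-zero the
#' sociodemographic covariates are generated from a latent household
#' socioeconomic factor that also loads on walkability, creating genuine
#' confounding; the `slope` remains the conditional (covariate-adjusted)
#' effect by construction.
#'
#' @param n_pairs number of twin pairs (MZ:DZ ratio fixed at 477:734).
#' @param slope conditional effect of walkability on BMI (kg/m^2 per index
#'   unit).
#' @param covariate_effects named vector of BMI effects for `age`, `female`,
#'   `work_employed`, `edu_high`, `lives_with_partner`, `deprivation_z`.
#' @param within_pair_cor share of residual BMI variance that is pair-shared
#'   (in `[0, 1)`).
#' @param noise_sd total residual SD of BMI (kg/m^2).
#' @param walk_pair_cor pair-shared share of walkability variance.
#' @param covariate_walk_cor loading of the socioeconomic factor on
#'   walkability (0 = covariates independent of walkability).
#' @param walk_mean,walk_sd,bmi_mean marginal moments.
#' @param seed integer RNG seed.
#' @return A list of class `regression_sim_spec`.
#' @export
regression_sim_spec <- function(n_pairs = 2156, slope = -0.04,
                                covariate_effects = c(
                                  age = 0.03, female = -1.0,
                                  work_employed = 0, edu_high = 0,
                                  lives_with_partner = 0, deprivation_z = 0),
                                within_pair_cor = 0.4, noise_sd = 5.0,
                                walk_pair_cor = 0.4, covariate_walk_cor = 0,
                                walk_mean = 43.4, walk_sd = 12.0,
                                bmi_mean = 26.5, seed = 1L) {
  stopifnot(n_pairs >= 1, abs(within_pair_cor) < 1, noise_sd > 0,
            walk_pair_cor >= 0, walk_pair_cor < 1,
            abs(covariate_walk_cor) < 1)
  eff <- c(age = 0, female = 0, work_employed = 0, edu_high = 0,
           lives_with_partner = 0, deprivation_z = 0)
  eff[names(covariate_effects)] <- covariate_effects
  structure(list(
    n_pairs = as.integer(n_pairs), slope = slope, covariate_effects = eff,
    within_pair_cor = within_pair_cor, noise_sd = noise_sd,
    walk_pair_cor = walk_pair_cor, covariate_walk_cor = covariate_walk_cor,
    walk_mean = walk_mean, walk_sd = walk_sd, bmi_mean = bmi_mean,
    seed = as.integer(seed)
  ), class = "regression_sim_spec")
}

#' Simulate a pair-clustered cohort for regression recovery
#'
#' @param spec a [regression_sim_spec()].
#' @return A [twin_cohort()] with `walkability`, `bmi`, age, sex and the four
#'   sociodemographic covariates filled in; reproducible from `spec$seed`.
#' @export
simulate_regression_cohort <- function(spec) {
  stopifnot(inherits(spec, "regression_sim_spec"))
  with_seed(spec$seed, {
    n <- spec$n_pairs
    n_mz <- round(n * 477 / 1211)
    pid <- sprintf("P%05d", seq_len(n))
    zyg <- c(rep("MZ", n_mz), rep("DZ", n - n_mz))
    age <- pmin(pmax(rnorm(n, 42.6, 5.2), 20), 70)
    sex1 <- ifelse(runif(n) < 0.6, "female", "male")
    sex2 <- ifelse(zyg == "MZ", sex1, ifelse(runif(n) < 0.6, "female", "male"))

    # latent household socioeconomic factor, 70% pair-shared
    ses_p <- rnorm(n)
    ses <- sqrt(0.7) * cbind(ses_p, ses_p) +
      sqrt(0.3) * matrix(rnorm(2 * n), n, 2)

    lw <- spec$covariate_walk_cor
    pc <- spec$walk_pair_cor
    if (pc + lw^2 >= 1) stop("walk_pair_cor + covariate_walk_cor^2 must be < 1")
    wp <- rnorm(n)
    W <- spec$walk_mean + spec$walk_sd *
      (sqrt(pc) * cbind(wp, wp) + lw * ses +
         sqrt(1 - pc - lw^2) * matrix(rnorm(2 * n), n, 2))

    # probit link from the socioeconomic factor to the binary covariates,
    # prevalences matched to a middle-aged Finnish cohort
    bin <- function(lambda, p) {
      zst <- lambda * ses + sqrt(1 - lambda^2) * matrix(rnorm(2 * n), n, 2)
      (zst > qnorm(1 - p)) + 0
    }
    work <- bin(0.4, 0.894)
    edu <- bin(0.6, 0.623)
    partner <- bin(0.3, 0.721)
    depr <- -0.5 * ses + sqrt(0.75) * matrix(rnorm(2 * n), n, 2)

    ef <- spec$covariate_effects
    shared <- rnorm(n, 0, spec$noise_sd * sqrt(spec$within_pair_cor))
    indiv <- matrix(rnorm(2 * n, 0, spec$noise_sd *
                            sqrt(1 - spec$within_pair_cor)), n, 2)
    fem <- cbind(sex1 == "female", sex2 == "female") + 0
    B <- spec$bmi_mean + spec$slope * (W - spec$walk_mean) +
      ef["age"] * (cbind(age, age) - 42.6) + ef["female"] * (fem - 0.6) +
      ef["work_employed"] * (work - 0.894) + ef["edu_high"] * (edu - 0.623) +
      ef["lives_with_partner"] * (partner - 0.721) +
      ef["deprivation_z"] * depr + cbind(shared, shared) + indiv

    d <- data.frame(
      person_id = c(paste0(pid, "_1"), paste0(pid, "_2")),
      pair_id = c(pid, pid), zygosity = c(zyg, zyg),
      sex = c(sex1, sex2), age = c(age, age),
      bmi = c(B[, 1], B[, 2]), walkability = c(W[, 1], W[, 2]),
      work_employed = c(work[, 1], work[, 2]),
      edu_high = c(edu[, 1], edu[, 2]),
      lives_with_partner = c(partner[, 1], partner[, 2]),
      deprivation_z = c(depr[, 1], depr[, 2]),
      stringsAsFactors = FALSE
    )
    twin_cohort(d)
  })
}
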