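#' @title Twin cohort data model
#' @description
#' A `twin_cohort` holds individual-level records from a classical twin
#' design together with the pair structure used by every analysis stage.
#' Individuals carry the phenotypes analysed here (BMI in kg/m^2 and a
#' continuous residential walkability index) plus the sociodemographic
#' covariates (age, sex, work status, education, living status, community
#' deprivation z-score). Pairs are monozygotic (MZ) or dizygotic (DZ) and may
#' be incomplete (singletons): individuals with a missing phenotype are kept
#' in the cohort and filtered per analysis, never dropped globally.
#' @name twin_cohort
NULL

# Canonical individual-level columns. Binary coding is fixed:
# work_employed = 1 employed, edu_high = 1 bachelor-or-above,
# lives_with_partner = 1 with partner, sex "female"/"male".
COHORT_COLUMNS <- c(
  "person_id", "pair_id", "zygosity", "sex", "age", "bmi", "walkability",
  "work_employed", "edu_high", "lives_with_partner", "deprivation_z"
)
COVARIATE_COLUMNS <- c(
  "work_employed", "edu_high", "lives_with_partner", "deprivation_z"
)

#' Construct a twin cohort from individual-level records
#'
#' Builds the pair table from `pair_id`, canonicalizes twin order within each
#' pair (twin 1 is the member with the lexicographically smaller `person_id`;
#' all likelihoods are invariant to this ordering) and validates the twin
#' structure.
#'
#' @param individuals data.frame with columns `person_id`, `pair_id`,
#'   `zygosity` (`"MZ"`/`"DZ"`), `sex` (`"male"`/`"female"`), `age`, `bmi`,
#'   `walkability`, `work_employed`, `edu_high`, `lives_with_partner`,
#'   `deprivation_z`. Phenotypes and covariates may be `NA`.
#' @return An object of class `twin_cohort`: a list with elements
#'   `individuals` (the validated data.frame), `pairs` (one row per pair:
#'   `pair_id`, `zygosity`, `id1`, `id2`, `complete`) and `meta` (counts).
#' @examples
#' ind <- data.frame(
#'   person_id = c("a1", "a2", "b1", "b2"),
#'   pair_id = c("pa", "pa", "pb", "pb"),
#'   zygosity = c("MZ", "MZ", "DZ", "DZ"),
#'   sex = c("female", "female", "male", "female"),
#'   age = 43, bmi = c(24, 25, 28, 27), walkability = c(50, 48, 35, 40),
#'   work_employed = 1, edu_high = 1, lives_with_partner = 1,
#'   deprivation_z = 0
#' )
#' cohort <- twin_cohort(ind)
#' cohort$meta$n_pairs
#' @export
twin_cohort <- function(individuals) {
  individuals <- as.data.frame(individuals)
  missing_cols <- setdiff(COHORT_COLUMNS, names(individuals))
  if (length(missing_cols)) {
    stop("missing cohort columns: ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(individuals), COHORT_COLUMNS)
  individuals <- individuals[c(COHORT_COLUMNS, extra)]
  individuals$person_id <- as.character(individuals$person_id)
  individuals$pair_id <- as.character(individuals$pair_id)
  individuals$zygosity <- as.character(individuals$zygosity)
  individuals$sex <- as.character(individuals$sex)
  for (col in c("age", "bmi", "walkability", COVARIATE_COLUMNS)) {
    individuals[[col]] <- as.numeric(individuals[[col]])
  }

  dup <- individuals$person_id[duplicated(individuals$person_id)]
  if (length(dup)) {
    stop("duplicate person_id: ", paste(unique(dup), collapse = ", "))
  }
  bad_zyg <- !individuals$zygosity %in% c("MZ", "DZ")
  if (any(bad_zyg)) {
    stop("unknown zygosity code: ",
         paste(unique(individuals$zygosity[bad_zyg]), collapse = ", "))
  }
  bad_sex <- !individuals$sex %in% c("male", "female")
  if (any(bad_sex)) {
    stop("unknown sex code: ",
         paste(unique(individuals$sex[bad_sex]), collapse = ", "))
  }
  sizes <- table(individuals$pair_id)
  if (any(sizes > 2L)) {
    stop("more than 2 members in pair(s): ",
         paste(names(sizes)[sizes > 2L], collapse = ", "))
  }
  ord <- order(individuals$pair_id, individuals$person_id)
  canon <- individuals[ord, , drop = FALSE]
  first <- !duplicated(canon$pair_id)
  zyg_by_pair <- canon$zygosity[first]
  names(zyg_by_pair) <- canon$pair_id[first]
  mism <- tapply(canon$zygosity, canon$pair_id,
                 function(z) length(unique(z)) > 1L)
  if (any(mism)) {
    stop("zygosity differs within pair(s): ",
         paste(names(mism)[mism], collapse = ", "))
  }
  sex_mism <- tapply(seq_len(nrow(canon)), canon$pair_id, function(ii) {
    canon$zygosity[ii[1L]] == "MZ" && length(unique(canon$sex[ii])) > 1L
  })
  if (any(sex_mism)) {
    stop("MZ co-twins must share sex; offending pair(s): ",
         paste(names(sex_mism)[sex_mism], collapse = ", "))
  }

  id1 <- canon$person_id[first]
  id2 <- rep(NA_character_, length(id1))
  second <- duplicated(canon$pair_id)
  id2[match(canon$pair_id[second], canon$pair_id[first])] <-
    canon$person_id[second]
  pairs <- data.frame(
    pair_id = canon$pair_id[first],
    zygosity = zyg_by_pair,
    id1 = id1,
    id2 = id2,
    complete = !is.na(id2),
    row.names = NULL,
    stringsAsFactors = FALSE
  )

  meta <- list(
    n_individuals = nrow(individuals),
    n_pairs = nrow(pairs),
    n_mz_pairs = sum(pairs$zygosity == "MZ"),
    n_dz_pairs = sum(pairs$zygosity == "DZ"),
    n_complete_mz = sum(pairs$complete & pairs$zygosity == "MZ"),
    n_complete_dz = sum(pairs$complete & pairs$zygosity == "DZ"),
    n_singletons = sum(!pairs$complete)
  )
  structure(
    list(individuals = individuals, pairs = pairs, meta = meta),
    class = "twin_cohort"
  )
}

#' @export
print.twin_cohort <- function(x, ...) {
  m <- x$meta
  cat("Twin cohort:", m$n_individuals, "individuals,", m$n_pairs, "pairs\n")
  cat(sprintf("  MZ pairs: %d (%d complete)   DZ pairs: %d (%d complete)\n",
              m$n_mz_pairs, m$n_complete_mz, m$n_dz_pairs, m$n_complete_dz))
  cat("  singletons:", m$n_singletons, "\n")
  invisible(x)
}

#' Read a twin cohort from CSV
#'
#' Reads comma-separated UTF-8 text with a header row; empty fields are
#' missing values. Column names and category codes in the file are mapped to
#' the canonical schema via `column_map`, `zygosity_codes` and `sex_codes`,
#' so registry exports with local naming can be ingested without editing.
#' Rows whose numeric fields fail to parse are reported with their line
#' numbers and the offending values become `NA`.
#'
#' @param path file path or connection to CSV text.
#' @param column_map named character vector mapping canonical column names
#'   (see [twin_cohort()]) to the names used in the file. Defaults to the
#'   identity mapping.
#' @param zygosity_codes named character vector: codes used in the file for
#'   `MZ` and `DZ` (default `c(MZ = "MZ", DZ = "DZ")`).
#' @param sex_codes named character vector: codes for `male` and `female`.
#' @return A [twin_cohort()].
#' @export
read_cohort <- function(path,
                        column_map = NULL,
                        zygosity_codes = c(MZ = "MZ", DZ = "DZ"),
                        sex_codes = c(male = "male", female = "female")) {
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = "", check.names = FALSE,
                         fileEncoding = "UTF-8")
  column_map <- column_map %||% stats::setNames(COHORT_COLUMNS, COHORT_COLUMNS)
  missing_map <- setdiff(COHORT_COLUMNS, names(column_map))
  if (length(missing_map)) {
    stop("column_map does not cover: ", paste(missing_map, collapse = ", "))
  }
  absent <- setdiff(unname(column_map[COHORT_COLUMNS]), names(raw))
  if (length(absent)) {
    stop("CSV lacks column(s): ", paste(absent, collapse = ", "))
  }
  d <- stats::setNames(raw[unname(column_map[COHORT_COLUMNS])], COHORT_COLUMNS)

  # recode zygosity / sex from declared file codes
  recode <- function(x, codes, what) {
    out <- names(codes)[match(x, codes)]
    bad <- !is.na(x) & is.na(out)
    if (any(bad)) {
      stop("unknown ", what, " code: ",
           paste(unique(x[bad]), collapse = ", "))
    }
    out
  }
  d$zygosity <- recode(d$zygosity, zygosity_codes, "zygosity")
  d$sex <- recode(d$sex, sex_codes, "sex")

  for (col in c("age", "bmi", "walkability", COVARIATE_COLUMNS)) {
    val <- suppressWarnings(as.numeric(d[[col]]))
    bad <- !is.na(d[[col]]) & is.na(val)
    if (any(bad)) {
      # +1 for the header row, so numbers refer to physical file lines
      warning("column '", col, "': unparseable value(s) at line(s) ",
              paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
    }
    d[[col]] <- val
  }
  # raw BMI from a file must be on the kg/m^2 scale (analyses may later
  # residualize it to a mean-zero scale in memory)
  if (any(!is.na(d$bmi) & d$bmi <= 0)) {
    stop("bmi must be positive when present; offending line(s): ",
         paste(which(!is.na(d$bmi) & d$bmi <= 0) + 1L, collapse = ", "))
  }
  twin_cohort(d)
}

#' Write a twin cohort to CSV
#'
#' Inverse of [read_cohort()] for the canonical schema: comma-separated,
#' UTF-8, header row, empty string for missing. Numerics are written with 17
#' significant digits so a read/write round trip reproduces finite values
#' bit-exactly.
#'
#' @param cohort a [twin_cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "twin_cohort"))
  d <- cohort$individuals
  for (col in c("age", "bmi", "walkability", COVARIATE_COLUMNS)) {
    v <- d[[col]]
    d[[col]] <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
  }
  utils::write.csv(d, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Cohort metadata summary as JSON
#'
#' @param cohort a [twin_cohort()].
#' @param path optional file to write the JSON to.
#' @return JSON string (invisibly when `path` is given).
#' @export
cohort_meta_json <- function(cohort, path = NULL) {
  stopifnot(inherits(cohort, "twin_cohort"))
  js <- jsonlite::toJSON(cohort$meta, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Impute missing covariates by the column median
#'
#' Missing sociodemographic covariates (work status, education, living
#' status, deprivation z-score) are replaced by the median over non-missing
#' values; for the 0/1-coded binaries this is the median of the coding, with
#' an exact 0/1 tie resolved to 1. Phenotypes (BMI, walkability) are never
#' imputed. The input cohort is not modified.
#'
#' @param cohort a [twin_cohort()].
#' @return A new `twin_cohort` with covariates completed; the number of
#'   imputed values per column is stored in `attr(, "imputation_counts")`
#'   and reported via `message()`.
#' @export
impute_covariates_median <- function(cohort) {
  stopifnot(inherits(cohort, "twin_cohort"))
  d <- cohort$individuals
  counts <- integer(0)
  for (col in COVARIATE_COLUMNS) {
    v <- d[[col]]
    miss <- is.na(v)
    if (all(miss)) stop("covariate '", col, "' is entirely missing")
    if (any(miss)) {
      med <- stats::median(v[!miss])
      if (col != "deprivation_z" && med == 0.5) med <- 1
      v[miss] <- med
      d[[col]] <- v
    }
    counts[col] <- sum(miss)
  }
  out <- twin_cohort(d)
  attr(out, "imputation_counts") <- counts
  imputed <- counts[counts > 0L]
  if (length(imputed)) {
    message("imputed by median: ",
            paste(sprintf("%s=%d", names(imputed), imputed), collapse = ", "))
  }
  out
}

#' Residualize a variable on a covariate design
#'
#' Ordinary least-squares residuals of `values` on `covariates`, used to
#' adjust phenotypes for age and sex before twin modelling. Rows with a
#' missing value or covariate are excluded pairwise and stay `NA` in the
#' output, which is aligned to the input order.
#'
#' @param values numeric vector.
#' @param covariates numeric design matrix including an intercept column;
#'   same number of rows as `length(values)`.
#' @return Numeric vector of residuals (orthogonal to every design column);
#'   the number of excluded rows is in `attr(, "n_excluded")`.
#' @export
residualize <- function(values, covariates) {
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != length(values)) {
    stop("covariates must have one row per value")
  }
  use <- !is.na(values) & stats::complete.cases(covariates)
  X <- covariates[use, , drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    nm <- colnames(X) %||% paste0("col", seq_len(ncol(X)))
    dropped <- nm[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(X, values[use])
  out <- rep(NA_real_, length(values))
  out[use] <- fit$residuals
  attr(out, "n_excluded") <- sum(!use)
  out
}

#' Residualize a cohort phenotype on age and sex
#'
#' Convenience wrapper: regresses the phenotype on age and sex (female = 1)
#' with an intercept and stores the residuals in a new column
#' `<phenotype>_resid`.
#'
#' @param cohort a [twin_cohort()].
#' @param phenotype `"walkability"` or `"bmi"`.
#' @return The cohort with the residual column added.
#' @export
residualize_phenotype <- function(cohort,
                                  phenotype = c("walkability", "bmi")) {
  stopifnot(inherits(cohort, "twin_cohort"))
  phenotype <- match.arg(phenotype)
  d <- cohort$individuals
  X <- cbind(intercept = 1, age = d$age, female = as.numeric(d$sex == "female"))
  res <- residualize(d[[phenotype]], X)
  out <- cohort
  out$individuals[[paste0(phenotype, "_resid")]] <- as.numeric(res)
  out
}

# Complete pairs of one zygosity for a phenotype: returns a 2-column matrix
# (twin1, twin2 in canonical order) plus the vector of values observed in
# incomplete or half-missing pairs (used as FIML singletons).
pair_matrix <- function(cohort, zygosity, phenotype) {
  d <- cohort$individuals
  p <- cohort$pairs[cohort$pairs$zygosity == zygosity, , drop = FALSE]
  v <- stats::setNames(d[[phenotype]], d$person_id)
  x1 <- unname(v[p$id1])
  x2 <- rep(NA_real_, nrow(p))
  x2[p$complete] <- unname(v[p$id2[p$complete]])
  both <- !is.na(x1) & !is.na(x2)
  singles <- c(x1[!both & !is.na(x1)], x2[!both & !is.na(x2)])
  list(pairs = cbind(x1[both], x2[both]), singles = singles,
       # canonical slot (1 or 2) of each complete pair's members is implicit;
       # slot of singles: observed member's slot
       single_slot = c(rep(1L, sum(!both & !is.na(x1))),
                       rep(2L, sum(!both & !is.na(x2)))))
}
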