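#' Simulate a panel of independent biallelic variants with sex-specific effects
#'
#' Draws `m` biallelic variants with effect-allele frequencies uniform over
#' `maf_range`, per-allele effects on a latent exposure drawn from a bivariate
#' normal across the sexes, and (optionally) direct per-allele effects on the
#' outcome log-odds (pleiotropy). Variants are spaced at least 2 Mb apart on
#' successive chromosomes so that distance-based pruning is a no-op unless the
#' panel is deliberately reconfigured.
#'
#' @param m Number of variants (>= 1).
#' @param maf_range Length-2 numeric interval inside (0, 1) for the
#'   effect-allele frequency draw.
#' @param effect_sd_women,effect_sd_men Standard deviations of the per-allele
#'   exposure effects (exposure-SD units per allele) in each sex.
#' @param effect_correlation Correlation of the per-variant effects across the
#'   sexes, in `[-1, 1]`.
#' @param pleiotropy_fraction Expected share of variants with a nonzero direct
#'   outcome effect.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the per-allele direct
#'   effect (log-odds) for pleiotropic variants; a nonzero mean gives
#'   directional pleiotropy, mean zero gives balanced pleiotropy.
#' @param seed Integer seed; fixed seed gives identical panels.
#' @return A `variant_panel`: a data frame with one row per variant and
#'   columns `variant_id`, `chromosome`, `position`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta_x_women`, `beta_x_men`, `pleiotropy_delta`,
#'   `info_score`, `missing_rate`, `biallelic`.
#' @export
make_variant_panel <- function(m,
                               maf_range = c(0.1, 0.5),
                               effect_sd_women = 0.07,
                               effect_sd_men = 0.07,
                               effect_correlation = 0.8,
                               pleiotropy_fraction = 0,
                               pleiotropy_mean = 0,
                               pleiotropy_sd = 0.02,
                               seed = 1L) {
  if (length(m) != 1L || !is.finite(m) || m < 1)
    stop("'m' must be a single integer >= 1")
  m <- as.integer(m)
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] >= 1)
    stop("'maf_range' must be a non-empty interval inside (0, 1)")
  if (!is.finite(effect_correlation) || abs(effect_correlation) > 1)
    stop("'effect_correlation' must lie in [-1, 1]")
  if (pleiotropy_fraction < 0 || pleiotropy_fraction > 1)
    stop("'pleiotropy_fraction' must lie in [0, 1]")
  set.seed(seed)

  eaf <- stats::runif(m, maf_range[1], maf_range[2])
  z1 <- stats::rnorm(m)
  z2 <- stats::rnorm(m)
  rho <- effect_correlation
  beta_w <- effect_sd_women * z1
  beta_m <- effect_sd_men * (rho * z1 + sqrt(1 - rho^2) * z2)

  pleio <- stats::rbinom(m, 1L, pleiotropy_fraction) == 1L
  delta <- numeric(m)
  delta[pleio] <- stats::rnorm(sum(pleio), pleiotropy_mean, pleiotropy_sd)

  # <= 100 variants per chromosome, >= 2.5 Mb apart within a chromosome
  per_chr <- 100L
  chrom <- as.character(((seq_len(m) - 1L) %/% per_chr) %% 22L + 1L)
  within <- (seq_len(m) - 1L) %% per_chr
  position <- 1e6 + within * 2.5e6
  pairs <- rbind(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))
  alleles <- pairs[sample.int(4L, m, replace = TRUE), , drop = FALSE]

  panel <- data.frame(
    variant_id = sprintf("rs%06d", seq_len(m)),
    chromosome = chrom,
    position = as.integer(position),
    effect_allele = alleles[, 1],
    other_allele = alleles[, 2],
    eaf = eaf,
    beta_x_women = beta_w,
    beta_x_men = beta_m,
    pleiotropy_delta = delta,
    info_score = stats::runif(m, 0.85, 1),
    missing_rate = stats::runif(m, 0, 0.02),
    biallelic = TRUE,
    stringsAsFactors = FALSE
  )
  class(panel) <- c("variant_panel", "data.frame")
  panel
}

#' Simulate additive genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each dosage is an independent Binomial(2, eaf) count of the panel's effect
#' allele; a `missing_rate` share of entries is masked at random.
#'
#' @param panel A [make_variant_panel()] panel.
#' @param n Number of individuals (>= 1).
#' @param missing_rate Proportion of entries set to `NA`, in `[0, 1)`.
#' @param seed Integer seed.
#' @return An `n` by `m` integer matrix with variant ids as column names and
#'   `NA` for masked entries.
#' @export
simulate_genotypes <- function(panel, n, missing_rate = 0, seed = 1L) {
  stopifnot(inherits(panel, "data.frame"), n >= 1)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must lie in [0, 1)")
  set.seed(seed)
  n <- as.integer(n)
  m <- nrow(panel)
  g <- matrix(stats::rbinom(n * m, 2L, rep(panel$eaf, each = n)),
              nrow = n, ncol = m)
  if (missing_rate > 0) {
    mask <- stats::runif(n * m) < missing_rate
    g[mask] <- NA_integer_
  }
  colnames(g) <- panel$variant_id
  g
}

#' Parameters of the synthetic cohort generating model
#'
#' Collects the causal structure used by [simulate_cohort()]: sex-specific
#' causal log-odds effects of the standardized exposure on the disease, an
#' unobserved confounder acting on exposure and outcome, a binary smoking
#' mediator, continuous blood-pressure traits, and a deterministic
#' blood-pressure medication rule. Defaults define the package's reference
#' simulation conditions (see the methods vignette).
#'
#' @param n_individuals Cohort size (>= 2).
#' @param theta_women,theta_men Causal effect of the exposure on the disease,
#'   log-odds per 1 SD of exposure.
#' @param gamma_confounder_x Confounder loading on the exposure.
#' @param phi_confounder_y Confounder loading on the outcome log-odds.
#' @param alpha_intercept Baseline disease log-odds (controls prevalence).
#' @param beta_x_smoking Effect of exposure (per SD) on smoking log-odds.
#' @param alpha_smoking Baseline smoking log-odds.
#' @param beta_smoking_y Effect of smoking on the disease log-odds (the
#'   mediated path; 0 disables mediation).
#' @param beta_x_sbp,beta_x_dbp Linear effect of exposure (per SD) on systolic
#'   and diastolic blood pressure, mmHg.
#' @param sd_sbp,sd_dbp Residual SDs of the blood-pressure traits, mmHg.
#' @param med_rule True-SBP threshold (mmHg) above which antihypertensive
#'   medication use is simulated; medication lowers measured SBP/DBP by
#'   15/10 mmHg.
#' @param sigma_x Residual SD of the latent exposure before standardization.
#' @param excluded_fraction Share of individuals labelled `excluded` for the
#'   disease outcome.
#' @param seed Integer seed for [simulate_cohort()].
#' @return A classed list of validated parameters (`sim_params`).
#' @export
sim_params <- function(n_individuals = 10000L,
                       theta_women = 0.6,
                       theta_men = 0.3,
                       gamma_confounder_x = 0.5,
                       phi_confounder_y = 0.5,
                       alpha_intercept = -1.5,
                       beta_x_smoking = 0.4,
                       alpha_smoking = -1.1,
                       beta_smoking_y = 0,
                       beta_x_sbp = 4,
                       beta_x_dbp = 2.5,
                       sd_sbp = 12,
                       sd_dbp = 8,
                       med_rule = 160,
                       sigma_x = 0.8,
                       excluded_fraction = 0.01,
                       seed = 1L) {
  if (n_individuals < 2) stop("'n_individuals' must be >= 2")
  if (excluded_fraction < 0 || excluded_fraction > 1)
    stop("'excluded_fraction' must lie in [0, 1]")
  if (sigma_x < 0 || sd_sbp < 0 || sd_dbp < 0)
    stop("scale parameters must be non-negative")
  p <- list(n_individuals = as.integer(n_individuals),
            theta_women = theta_women, theta_men = theta_men,
            gamma_confounder_x = gamma_confounder_x,
            phi_confounder_y = phi_confounder_y,
            alpha_intercept = alpha_intercept,
            beta_x_smoking = beta_x_smoking,
            alpha_smoking = alpha_smoking,
            beta_smoking_y = beta_smoking_y,
            beta_x_sbp = beta_x_sbp, beta_x_dbp = beta_x_dbp,
            sd_sbp = sd_sbp, sd_dbp = sd_dbp,
            med_rule = med_rule, sigma_x = sigma_x,
            excluded_fraction = excluded_fraction,
            seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic cohort parameters\n")
  cat(sprintf("  n = %d; theta (women, men) = (%.3g, %.3g) log-odds/SD\n",
              x$n_individuals, x$theta_women, x$theta_men))
  cat(sprintf("  confounder loadings (x, y) = (%.3g, %.3g); baseline log-odds %.3g\n",
              x$gamma_confounder_x, x$phi_confounder_y, x$alpha_intercept))
  invisible(x)
}

# Mean-impute missing dosages with 2*eaf (used for the generating model only;
# downstream scoring does its own imputation).
.impute_dosages <- function(dosages, eaf) {
  if (!anyNA(dosages)) return(dosages)
  for (j in seq_len(ncol(dosages))) {
    miss <- is.na(dosages[, j])
    if (any(miss)) dosages[miss, j] <- 2 * eaf[j]
  }
  dosages
}

#' Simulate a phenotyped cohort with known sex-specific causal structure
#'
#' Generates, per individual: sex (Bernoulli 1/2), a standard-normal unobserved
#' confounder, a latent exposure built from the panel's sex-specific per-allele
#' effects plus the confounder and noise (centred and rescaled to SD 1 so the
#' causal effects are exactly per 1 SD), age/centre/array/PC covariates with
#' small effects on the exposure, a binary smoking mediator, systolic and
#' diastolic blood pressure with a deterministic medication rule (measured
#' values have the 15/10 mmHg treatment effect subtracted, so the standard
#' +15/+10 correction recovers the pre-treatment values), and a binary disease
#' through a logistic link carrying the sex-specific causal effect, the
#' confounder, any mediated smoking path, and any per-variant pleiotropy.
#'
#' @param panel A [make_variant_panel()] panel.
#' @param dosages Dosage matrix from [simulate_genotypes()] with
#'   `params$n_individuals` rows.
#' @param params A [sim_params()] object.
#' @return A list of class `sim_cohort` with elements `cohort` (data frame;
#'   see Details) and `truth` (the realized generating parameters, the
#'   realized exposure SD, the true standardized exposure, and per-sex case
#'   counts).
#' @details The cohort data frame has columns `id`, `sex` (`"female"`/
#'   `"male"`), `age`, `centre`, `array`, `pc1`..`pc10`, `bmi` (the measured
#'   obesity trait, an affine image of the standardized exposure), `sbp_mean`,
#'   `dbp_mean`, `bp_medication`, smoking code fields `field_1239`,
#'   `field_1249`, `field_20116`, and `status_disease` with values
#'   `case`/`control`/`excluded`.
#' @export
simulate_cohort <- function(panel, dosages, params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_individuals
  if (nrow(dosages) != n)
    stop("dosage row count must equal params$n_individuals")
  if (ncol(dosages) != nrow(panel))
    stop("dosage column count must equal the panel size")
  set.seed(params$seed)

  sex <- ifelse(stats::rbinom(n, 1L, 0.5) == 1L, "male", "female")
  u <- stats::rnorm(n)
  dimp <- .impute_dosages(dosages, panel$eaf)
  g_w <- as.numeric(dimp %*% panel$beta_x_women)
  g_m <- as.numeric(dimp %*% panel$beta_x_men)
  g <- ifelse(sex == "female", g_w, g_m)

  age <- floor(stats::runif(n, 40, 70))
  centre <- factor(sample(paste0("c", 1:6), n, replace = TRUE))
  array <- factor(sample(c("axiom", "bileve"), n, replace = TRUE,
                         prob = c(0.8, 0.2)))
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))
  centre_eff <- seq(-0.05, 0.05, length.out = 6)[as.integer(centre)]

  x_raw <- g + params$gamma_confounder_x * u +
    stats::rnorm(n, 0, params$sigma_x) +
    0.01 * (age - 55) + centre_eff
  sd_x <- stats::sd(x_raw)
  x_std <- (x_raw - mean(x_raw)) / sd_x

  # smoking mediator and its three raw code fields
  p_smoke <- stats::plogis(params$alpha_smoking + params$beta_x_smoking * x_std)
  smoker <- stats::rbinom(n, 1L, p_smoke)
  f1239 <- f1249 <- f20116 <- integer(n)
  which_field <- sample.int(3L, n, replace = TRUE)
  code <- sample(1:2, n, replace = TRUE)
  f1239[smoker == 1L & which_field == 1L] <- code[smoker == 1L & which_field == 1L]
  f1249[smoker == 1L & which_field == 2L] <- code[smoker == 1L & which_field == 2L]
  f20116[smoker == 1L & which_field == 3L] <- code[smoker == 1L & which_field == 3L]

  sbp_true <- 120 + params$beta_x_sbp * x_std + 2 * (sex == "male") +
    stats::rnorm(n, 0, params$sd_sbp)
  dbp_true <- 75 + params$beta_x_dbp * x_std + 1 * (sex == "male") +
    stats::rnorm(n, 0, params$sd_dbp)
  bp_med <- sbp_true > params$med_rule
  sbp_meas <- sbp_true - 15 * bp_med
  dbp_meas <- dbp_true - 10 * bp_med

  theta <- ifelse(sex == "female", params$theta_women, params$theta_men)
  pleio <- as.numeric(dimp %*% panel$pleiotropy_delta)
  eta <- params$alpha_intercept + theta * x_std +
    params$phi_confounder_y * u + params$beta_smoking_y * smoker +
    pleio + 0.01 * (age - 55)
  disease <- stats::rbinom(n, 1L, stats::plogis(eta))
  status <- ifelse(disease == 1L, "case", "control")
  excl <- stats::runif(n) < params$excluded_fraction
  status[excl] <- "excluded"

  cohort <- data.frame(
    id = sprintf("id%06d", seq_len(n)),
    sex = sex, age = age, centre = centre, array = array,
    pcs,
    bmi = 27 + 4.5 * x_std,
    sbp_mean = sbp_meas, dbp_mean = dbp_meas,
    bp_medication = bp_med,
    field_1239 = f1239, field_1249 = f1249, field_20116 = f20116,
    status_disease = status,
    stringsAsFactors = FALSE
  )

  truth <- list(
    params = params,
    sd_x = sd_x,
    x_true = x_std,
    u = u,
    smoker = smoker,
    sbp_true = sbp_true,
    dbp_true = dbp_true,
    n_cases = c(women = sum(status == "case" & sex == "female"),
                men = sum(status == "case" & sex == "male")),
    n_controls = c(women = sum(status == "control" & sex == "female"),
                   men = sum(status == "control" & sex == "male")),
    n_excluded = sum(status == "excluded")
  )
  out <- list(cohort = cohort, truth = truth)
  class(out) <- "sim_cohort"
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: n = %d (%d women, %d men)\n",
              nrow(x$cohort), sum(x$cohort$sex == "female"),
              sum(x$cohort$sex == "male")))
  cat(sprintf("  disease cases: %d women / %d men; excluded: %d\n",
              x$truth$n_cases["women"], x$truth$n_cases["men"],
              x$truth$n_excluded))
  cat(sprintf("  realized exposure SD (raw scale): %.4f\n", x$truth$sd_x))
  invisible(x)
}

#' Per-variant summary statistics from a simulated cohort
#'
#' Runs a single-variant regression of the target on each variant's dosage
#' within a sex stratum: least squares for continuous targets, logistic
#' regression for `status_*` case/control targets (excluded individuals and
#' per-variant missing dosages dropped).
#'
#' @param panel The variant panel used to generate the cohort.
#' @param dosages Dosage matrix (rows = individuals).
#' @param cohort Cohort data frame (from [simulate_cohort()]) with the target
#'   column.
#' @param target Column name in `cohort`; `status_` prefixed columns are
#'   treated as binary outcomes.
#' @param stratum One of `"women"`, `"men"`, `"combined"`.
#' @return A data frame in the package's summary-statistics schema:
#'   `variant_id`, `chromosome`, `position`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `p`, `n`, `stratum`.
#' @export
emit_sumstats <- function(panel, dosages, cohort, target,
                          stratum = c("combined", "women", "men")) {
  stratum <- match.arg(stratum)
  if (!target %in% names(cohort)) stop("unknown target: ", target)
  rows <- switch(stratum,
                 women = cohort$sex == "female",
                 men = cohort$sex == "male",
                 combined = rep(TRUE, nrow(cohort)))
  d <- dosages[rows, , drop = FALSE]
  yv <- cohort[[target]][rows]
  binary <- startsWith(target, "status_")
  if (binary) {
    keep <- yv %in% c("case", "control")
    d <- d[keep, , drop = FALSE]
    yv <- as.integer(yv[keep] == "case")
  }

  m <- nrow(panel)
  beta <- se <- p <- rep(NA_real_, m)
  nn <- integer(m)
  eaf_obs <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    gj <- d[, j]
    ok <- !is.na(gj) & !is.na(yv)
    gj <- gj[ok]; yj <- yv[ok]
    nn[j] <- length(gj)
    eaf_obs[j] <- mean(gj) / 2
    if (nn[j] < 3 || stats::var(gj) == 0) next
    if (binary) {
      fit <- stats::glm.fit(cbind(1, gj), yj, family = stats::binomial())
      cf <- fit$coefficients[2]
      rk <- fit$qr$rank
      cov <- chol2inv(fit$qr$qr[seq_len(rk), seq_len(rk), drop = FALSE])
      sej <- sqrt(cov[2, 2])
      beta[j] <- cf; se[j] <- sej
      p[j] <- 2 * stats::pnorm(-abs(cf / sej))
    } else {
      gc <- gj - mean(gj); yc <- yj - mean(yj)
      sxx <- sum(gc^2)
      b <- sum(gc * yc) / sxx
      res <- yc - b * gc
      dfree <- nn[j] - 2L
      s2 <- sum(res^2) / dfree
      sej <- sqrt(s2 / sxx)
      beta[j] <- b; se[j] <- sej
      p[j] <- if (sej == 0) 0 else 2 * stats::pt(-abs(b / sej), dfree)
    }
  }
  data.frame(variant_id = panel$variant_id,
             chromosome = panel$chromosome,
             position = panel$position,
             effect_allele = panel$effect_allele,
             other_allele = panel$other_allele,
             eaf = eaf_obs, beta = beta, se = se, p = p, n = nn,
             stratum = stratum, stringsAsFactors = FALSE)
}

#' Simulate two-sample summary data for a variant panel
#'
#' Draws per-variant exposure effects `bx ~ N(true effect, se_x^2)` and
#' outcome effects `by = theta * true effect + delta + N(0, se_y^2)`, the
#' standard summary-level generating model for two-sample Mendelian
#' randomization, with any panel pleiotropy entering `delta`.
#'
#' @param panel A [make_variant_panel()] panel.
#' @param theta True causal effect of the exposure on the outcome.
#' @param se_x,se_y Standard errors of the exposure and outcome estimates
#'   (recycled per variant).
#' @param stratum Which sex's true exposure effects to use (`"combined"`
#'   averages the two).
#' @param oriented Use trait-increasing orientation (`abs` of the true
#'   exposure effects), the convention of a real oriented instrument; the
#'   pleiotropy term is defined on the trait-increasing allele either way.
#' @param seed Integer seed.
#' @return A data frame of SNP triples: `variant_id`, `bx`, `se_x`, `by`,
#'   `se_y`.
#' @export
simulate_snp_triples <- function(panel, theta, se_x = 0.005, se_y = 0.01,
                                 stratum = c("combined", "women", "men"),
                                 oriented = TRUE, seed = 1L) {
  stratum <- match.arg(stratum)
  set.seed(seed)
  m <- nrow(panel)
  bx_true <- switch(stratum,
                    women = panel$beta_x_women,
                    men = panel$beta_x_men,
                    combined = (panel$beta_x_women + panel$beta_x_men) / 2)
  if (oriented) bx_true <- abs(bx_true)
  se_x <- rep_len(se_x, m)
  se_y <- rep_len(se_y, m)
  data.frame(variant_id = panel$variant_id,
             bx = bx_true + stats::rnorm(m, 0, se_x),
             se_x = se_x,
             by = theta * bx_true + panel$pleiotropy_delta +
               stats::rnorm(m, 0, se_y),
             se_y = se_y,
             stringsAsFactors = FALSE)
}
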