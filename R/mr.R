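# 95% normal quantile fixed for bit-stable confidence intervals.
.Z95 <- 1.959964

.mr_estimate <- function(method, beta, se, trait = NA_character_,
                         outcome = NA_character_, stratum = NA_character_,
                         binary = FALSE, n_snps = NA_integer_,
                         egger_intercept = NULL) {
  p <- 2 * stats::pnorm(-abs(beta / se))
  out <- list(method = method, trait = trait, outcome = outcome,
              stratum = stratum, beta = beta, se = se, p = p,
              or_point = if (binary) exp(beta) else NA_real_,
              ci_low = if (binary) exp(beta - .Z95 * se) else NA_real_,
              ci_high = if (binary) exp(beta + .Z95 * se) else NA_real_,
              binary = binary, n_snps = n_snps,
              egger_intercept = egger_intercept)
  class(out) <- "mr_estimate"
  out
}

#' @export
print.mr_estimate <- function(x, ...) {
  lab <- paste(stats::na.omit(c(x$trait, x$outcome, x$stratum)), collapse = " -> ")
  cat(sprintf("MR estimate (%s)%s\n", x$method,
              if (nzchar(lab)) paste0(": ", lab) else ""))
  cat(sprintf("  beta = %.5g per 1-SD exposure (se %.5g), p = %.3g\n",
              x$beta, x$se, x$p))
  if (x$binary)
    cat(sprintf("  OR %.3f (95%% CI %.3f-%.3f)\n",
                x$or_point, x$ci_low, x$ci_high))
  if (!is.null(x$egger_intercept))
    cat(sprintf("  Egger intercept %.5g (se %.5g), p = %.3g\n",
                x$egger_intercept$beta, x$egger_intercept$se,
                x$egger_intercept$p))
  if (!is.na(x$n_snps)) cat(sprintf("  SNPs: %d\n", x$n_snps))
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) c(beta = object$beta)

#' @export
confint.mr_estimate <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm((1 + level) / 2)
  c(object$beta - z * object$se, object$beta + z * object$se)
}

#' Wald-ratio instrumental-variable estimate
#'
#' The causal estimate is the ratio of the instrument-outcome to the
#' instrument-exposure regression coefficients, `beta = gy / gx`. Its
#' standard error uses the first two terms of the delta expansion of a ratio:
#' `se^2 = se_gy^2 / gx^2 + gy^2 * se_gx^2 / gx^4` (no covariance term; the
#' two regressions are run on separate or partially disjoint samples).
#'
#' @param gy Instrument-outcome association: an `assoc_result` or a list with
#'   `beta` and `se` (log-odds scale for binary outcomes).
#' @param gx Instrument-exposure association (exposure in SD units), same
#'   form; `gx$beta` must be nonzero.
#' @return An `mr_estimate` with method `"wald"`; odds-ratio fields are
#'   filled when `gy` is a logistic fit.
#' @export
wald_ratio <- function(gy, gx) {
  if (gx$beta == 0) stop("undefined ratio: instrument-exposure beta is zero")
  sy <- if (!is.null(gy$stratum)) gy$stratum else NA_character_
  sx <- if (!is.null(gx$stratum)) gx$stratum else NA_character_
  if (!is.na(sy) && !is.na(sx) && sy != sx)
    stop("stratum mismatch between the two regressions")
  beta <- gy$beta / gx$beta
  se <- sqrt(gy$se^2 / gx$beta^2 + gy$beta^2 * gx$se^2 / gx$beta^4)
  binary <- !is.null(gy$type) && identical(gy$type, "logistic")
  .mr_estimate("wald", beta, se,
               trait = if (!is.null(gx$outcome)) gx$outcome else NA_character_,
               outcome = if (!is.null(gy$outcome)) gy$outcome else NA_character_,
               stratum = sy, binary = binary, n_snps = 1L)
}

#' Individual-level Mendelian randomization with a genetic risk score
#'
#' Runs the two regressions behind the Wald ratio on individual-level data:
#' the outcome on the score (logistic for case/control outcomes, linear
#' otherwise) over all included individuals, and the standardized exposure on
#' the score by least squares - restricted to the outcome's controls for
#' binary outcomes (the default), so disease status cannot distort the
#' instrument-exposure relation. Optionally adds smoking status to both
#' covariate sets (the mediation sensitivity analysis).
#'
#' @param score Instrument score vector.
#' @param exposure Standardized exposure (SD units).
#' @param outcome Outcome vector: numeric (continuous) or character/factor
#'   with `case`/`control`/`excluded` labels.
#' @param covariates Optional covariate data frame applied to both
#'   regressions.
#' @param controls_only_exposure Restrict the exposure regression to controls
#'   for binary outcomes (default `TRUE`).
#' @param adjust_smoking Add `smoking` to both covariate sets.
#' @param smoking Logical/0-1 smoking-status vector (required when
#'   `adjust_smoking` is `TRUE`).
#' @param trait,outcome_label,stratum Labels carried into the result.
#' @return An `mr_estimate` with method `"wald"`.
#' @export
individual_level_mr <- function(score, exposure, outcome, covariates = NULL,
                                controls_only_exposure = TRUE,
                                adjust_smoking = FALSE, smoking = NULL,
                                trait = NA_character_,
                                outcome_label = "outcome",
                                stratum = NA_character_) {
  if (adjust_smoking) {
    if (is.null(smoking)) stop("adjust_smoking = TRUE requires 'smoking'")
    covariates <- if (is.null(covariates))
      data.frame(smoking = as.numeric(smoking))
    else cbind(covariates, smoking = as.numeric(smoking))
  }
  binary <- is.character(outcome) || is.factor(outcome) ||
    (is.numeric(outcome) && all(outcome %in% c(0, 1, NA)))
  if (binary) {
    status <- if (is.numeric(outcome))
      ifelse(is.na(outcome), NA, ifelse(outcome == 1, "case", "control"))
    else as.character(outcome)
    gy <- fit_logistic(status, score, covariates,
                       outcome = outcome_label, trait = trait,
                       stratum = stratum)
    idx <- if (controls_only_exposure) which(status == "control")
    else which(status %in% c("case", "control"))
    gx <- fit_linear(exposure[idx], score[idx],
                     if (is.null(covariates)) NULL
                     else covariates[idx, , drop = FALSE],
                     outcome = trait, trait = trait, stratum = stratum)
  } else {
    gy <- fit_linear(outcome, score, covariates,
                     outcome = outcome_label, trait = trait,
                     stratum = stratum)
    gx <- fit_linear(exposure, score, covariates,
                     outcome = trait, trait = trait, stratum = stratum)
  }
  est <- wald_ratio(gy, gx)
  est$trait <- trait
  est$outcome <- outcome_label
  est
}

#' Harmonize exposure and outcome summary statistics into SNP triples
#'
#' Joins external outcome summary statistics to the exposure records by
#' variant identifier and aligns effect alleles: when the external effect
#' allele equals the exposure's other allele, the external beta is negated
#' (and its frequency flipped). Palindromic variants (A/T or C/G) whose
#' external effect-allele frequency lies in `[0.4, 0.6]` are strand-ambiguous
#' and dropped; unmatched identifiers and incompatible allele pairs are also
#' dropped. All exclusions are recorded in the `"harmonize_log"` attribute.
#'
#' @param exposure Data frame with `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se` (per-allele effects on the exposure, e.g.
#'   an oriented instrument's summary statistics).
#' @param external Data frame in the same schema (plus optional `eaf`) for
#'   the outcome.
#' @return Data frame of SNP triples (`variant_id`, `bx`, `se_x`, `by`,
#'   `se_y`) with exclusions in `attr(, "harmonize_log")`.
#' @export
harmonize <- function(exposure, external) {
  flip_pairs <- c(A = "T", T = "A", C = "G", G = "C")
  log <- list()
  rows <- list()
  i <- match(exposure$variant_id, external$variant_id)
  for (k in seq_len(nrow(exposure))) {
    id <- exposure$variant_id[k]
    if (is.na(i[k])) {
      log[[id]] <- "unmatched"
      next
    }
    ext <- external[i[k], ]
    ea <- exposure$effect_allele[k]; oa <- exposure$other_allele[k]
    palindromic <- identical(unname(flip_pairs[ea]), oa)
    if (palindromic && !is.null(ext$eaf) && !is.na(ext$eaf) &&
        ext$eaf >= 0.4 && ext$eaf <= 0.6) {
      log[[id]] <- "palindromic"
      next
    }
    if (ext$effect_allele == ea && ext$other_allele == oa) {
      by <- ext$beta
    } else if (ext$effect_allele == oa && ext$other_allele == ea) {
      by <- -ext$beta
    } else {
      log[[id]] <- "allele_mismatch"
      next
    }
    rows[[id]] <- data.frame(variant_id = id,
                             bx = exposure$beta[k], se_x = exposure$se[k],
                             by = by, se_y = ext$se,
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(variant_id = character(), bx = numeric(),
                  se_x = numeric(), by = numeric(), se_y = numeric())
  rownames(out) <- NULL
  attr(out, "harmonize_log") <-
    data.frame(variant_id = names(log),
               reason = unlist(log, use.names = FALSE),
               stringsAsFactors = FALSE)
  out
}

#' Inverse-variance-weighted two-sample MR estimate
#'
#' Per-SNP ratio estimates `r_j = by_j / bx_j` with first-order standard
#' errors `se_j = se_y_j / |bx_j|` are combined by fixed-effect
#' inverse-variance weighting: `beta = sum(w r) / sum(w)`,
#' `se = 1 / sqrt(sum(w))`, `w_j = 1 / se_j^2`.
#'
#' @param triples Data frame of SNP triples (see [harmonize()]); all `bx`
#'   must be nonzero.
#' @param trait,outcome,stratum Labels carried into the result.
#' @return An `mr_estimate` with method `"ivw"`.
#' @export
ivw <- function(triples, trait = NA_character_, outcome = NA_character_,
                stratum = NA_character_) {
  if (nrow(triples) < 1) stop("need at least one SNP")
  if (any(triples$bx == 0)) stop("bx must be nonzero for the ratio estimates")
  r <- triples$by / triples$bx
  se_r <- triples$se_y / abs(triples$bx)
  w <- 1 / se_r^2
  beta <- sum(w * r) / sum(w)
  .mr_estimate("ivw", beta, 1 / sqrt(sum(w)), trait = trait,
               outcome = outcome, stratum = stratum,
               n_snps = nrow(triples))
}

#' MR-Egger regression estimate with directional-pleiotropy intercept
#'
#' Weighted least squares of the outcome effects on the exposure effects with
#' a free intercept, weights `1 / se_y^2`, after re-orienting SNPs so every
#' `bx` is non-negative (negating each `(bx, by)` pair where needed). The
#' slope is the causal estimate; the intercept estimates the average
#' directional pleiotropy, reported with its own se and p. Standard errors
#' use the multiplicative random-effects convention (residual dispersion
#' floored at 1).
#'
#' @inheritParams ivw
#' @return An `mr_estimate` with method `"egger"` and an `egger_intercept`
#'   component.
#' @export
mr_egger <- function(triples, trait = NA_character_, outcome = NA_character_,
                     stratum = NA_character_) {
  if (nrow(triples) < 3) stop("MR-Egger needs at least 3 SNPs")
  neg <- triples$bx < 0
  bx <- ifelse(neg, -triples$bx, triples$bx)
  by <- ifelse(neg, -triples$by, triples$by)
  if (stats::sd(bx) == 0) stop("no spread in bx: Egger slope unidentified")
  w <- 1 / triples$se_y^2
  x <- cbind(1, bx)
  fit <- stats::lm.wfit(x, by, w)
  k <- length(by)
  rss_w <- sum(w * fit$residuals^2)
  disp <- max(1, rss_w / (k - 2))
  r <- qr.R(fit$qr)
  cov <- chol2inv(r) * disp
  slope <- unname(fit$coefficients[2])
  se_slope <- sqrt(cov[2, 2])
  int <- unname(fit$coefficients[1])
  se_int <- sqrt(cov[1, 1])
  est <- .mr_estimate("egger", slope, se_slope, trait = trait,
                      outcome = outcome, stratum = stratum, n_snps = k)
  est$egger_intercept <- list(beta = int, se = se_int,
                              p = 2 * stats::pnorm(-abs(int / se_int)))
  est
}

# Weighted-median point estimate: ratios sorted ascending, normalized weights
# w, cumulative midpoints s_j = cumsum(w) - w/2, linear interpolation at 0.5.
# A SNP carrying more than half the total weight returns its own ratio (the
# estimator's defining majority-weight property).
.weighted_median_point <- function(ratios, weights) {
  o <- order(ratios)
  r <- ratios[o]
  w <- weights[o] / sum(weights)
  if (any(w > 0.5)) return(r[which(w > 0.5)[1]])
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median two-sample MR estimate
#'
#' The weighted median of the per-SNP ratio estimates: ratios are sorted,
#' inverse-variance weights normalized, and the estimate is the linear
#' interpolation of the ratios at cumulative weight 0.5 (consistent when
#' valid instruments carry at least half the weight). The standard error is
#' the SD of the estimate over `n_boot` parametric resamples of `(bx, by)`
#' at their standard errors, with a fixed seed for determinism.
#'
#' @inheritParams ivw
#' @param n_boot Number of parametric bootstrap resamples.
#' @param seed Integer seed for the bootstrap.
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
weighted_median <- function(triples, n_boot = 1000, seed = 42,
                            trait = NA_character_, outcome = NA_character_,
                            stratum = NA_character_) {
  k <- nrow(triples)
  if (k < 2) stop("need at least two SNPs")
  ratios <- triples$by / triples$bx
  wts <- (abs(triples$bx) / triples$se_y)^2
  beta <- .weighted_median_point(ratios, wts)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(k, triples$bx, triples$se_x)
    by <- stats::rnorm(k, triples$by, triples$se_y)
    .weighted_median_point(by / bx, (abs(bx) / triples$se_y)^2)
  }, numeric(1))
  .mr_estimate("weighted_median", beta, stats::sd(boots), trait = trait,
               outcome = outcome, stratum = stratum, n_snps = k)
}

#' Collect MR estimates into a results table
#'
#' @param estimates List of `mr_estimate` objects.
#' @return Data frame mirroring the forest-plot layout: trait, outcome,
#'   stratum, method, beta, se, p, or, ci_low, ci_high, n_snps,
#'   egger_intercept, egger_intercept_p.
#' @export
mr_table <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e)
    data.frame(trait = e$trait, outcome = e$outcome, stratum = e$stratum,
               method = e$method, beta = e$beta, se = e$se, p = e$p,
               or = e$or_point, ci_low = e$ci_low, ci_high = e$ci_high,
               n_snps = e$n_snps,
               egger_intercept = if (is.null(e$egger_intercept)) NA_real_
               else e$egger_intercept$beta,
               egger_intercept_p = if (is.null(e$egger_intercept)) NA_real_
               else e$egger_intercept$p,
               stringsAsFactors = FALSE)))
}
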