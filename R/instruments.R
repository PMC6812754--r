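#' Assemble per-variant records from stratum-specific summary statistics
#'
#' Joins women-only, men-only, and combined-sexes summary statistics tables on
#' `variant_id` into the per-variant record layout the instrument-building
#' functions consume (`beta_w/se_w/p_w`, `beta_m/se_m/p_m`, `beta_c/se_c/p_c`).
#' Variant identity, alleles, positions, and QC fields are taken from the
#' combined table.
#'
#' @param women,men,combined Summary-statistics data frames (the
#'   [emit_sumstats()] schema). QC columns (`info_score`, `missing_rate`,
#'   `biallelic`, `hwe_p`) are carried through when present.
#' @return A data frame of variant records.
#' @export
variant_records <- function(women, men, combined) {
  keep <- c("variant_id", "chromosome", "position",
            "effect_allele", "other_allele", "eaf",
            intersect(c("info_score", "missing_rate", "biallelic", "hwe_p"),
                      names(combined)))
  rec <- combined[, keep, drop = FALSE]
  rec$beta_c <- combined$beta; rec$se_c <- combined$se; rec$p_c <- combined$p
  iw <- match(rec$variant_id, women$variant_id)
  im <- match(rec$variant_id, men$variant_id)
  rec$beta_w <- women$beta[iw]; rec$se_w <- women$se[iw]; rec$p_w <- women$p[iw]
  rec$beta_m <- men$beta[im]; rec$se_m <- men$se[im]; rec$p_m <- men$p[im]
  rec
}

#' Post-imputation variant quality control
#'
#' Applies the standard post-imputation filters: imputation info score above
#' `info_min`, minor allele frequency at least `maf_min`, Hardy-Weinberg
#' exact-test p-value at least `hwe_p_min` (only when an `hwe_p` column is
#' present), missing call rate at most `missing_max`, and biallelic status.
#' Each excluded variant is tagged with exactly one reason: the first failing
#' rule in that order.
#'
#' @param variants Data frame of variant records with QC columns `info_score`,
#'   `missing_rate`, `biallelic`, and optionally `hwe_p`.
#' @param info_min Info-score threshold (kept when strictly greater).
#' @param maf_min Minimum minor allele frequency (kept when at least this).
#' @param hwe_p_min Minimum Hardy-Weinberg p-value (kept when at least this).
#' @param missing_max Maximum missing call rate (kept when at most this).
#' @return A list with `kept` (data frame of passing variants) and `excluded`
#'   (data frame with `variant_id` and `reason`).
#' @export
qc_filter_variants <- function(variants, info_min = 0.3, maf_min = 1e-4,
                               hwe_p_min = 1e-6, missing_max = 0.05) {
  stopifnot(info_min > 0, maf_min > 0, hwe_p_min > 0, missing_max > 0)
  if (nrow(variants) == 0)
    return(list(kept = variants,
                excluded = data.frame(variant_id = character(),
                                      reason = character())))
  maf <- pmin(variants$eaf, 1 - variants$eaf)
  reason <- rep(NA_character_, nrow(variants))
  fail <- function(cond, tag) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- tag
  }
  fail(variants$info_score <= info_min, "info")
  fail(maf < maf_min, "maf")
  if ("hwe_p" %in% names(variants)) fail(variants$hwe_p < hwe_p_min, "hwe")
  fail(variants$missing_rate > missing_max, "missing")
  if ("biallelic" %in% names(variants)) fail(!variants$biallelic, "not_biallelic")
  keep <- is.na(reason)
  list(kept = variants[keep, , drop = FALSE],
       excluded = data.frame(variant_id = variants$variant_id[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Merge stratum index lists and prune by physical distance
#'
#' Takes the union of per-stratum index variant lists (deduplicated by
#' identifier), then keeps the variant with the lowest combined-sexes p-value
#' within each window: variants are visited in ascending `p_c` order and one
#' is retained only if no already-retained variant on the same chromosome lies
#' within `window_bp` of its position.
#'
#' @param index_lists A list of variant-record data frames (one per stratum),
#'   or a single data frame.
#' @param window_bp Exclusion radius in base pairs (default 1 Mb).
#' @return The retained variant records, sorted by chromosome and position.
#' @export
merge_and_window_prune <- function(index_lists, window_bp = 1e6) {
  if (is.data.frame(index_lists)) index_lists <- list(index_lists)
  all <- do.call(rbind, index_lists)
  all <- all[!duplicated(all$variant_id), , drop = FALSE]
  if (anyNA(all$position)) stop("variant(s) missing position")
  if (anyNA(all$p_c)) stop("variant(s) missing combined-sexes p-value")
  ord <- order(all$p_c, all$variant_id)
  all <- all[ord, , drop = FALSE]
  keep <- logical(nrow(all))
  for (i in seq_len(nrow(all))) {
    prior <- keep & all$chromosome == all$chromosome[i] &
      abs(all$position - all$position[i]) <= window_bp
    keep[i] <- !any(prior)
  }
  out <- all[keep, , drop = FALSE]
  out[order(out$chromosome, out$position), , drop = FALSE]
}

#' Prune variant pairs in long-distance linkage disequilibrium
#'
#' For each listed pair with `r2` above the cap where both members are still
#' retained, the member with the larger combined-sexes p-value is dropped
#' (ties broken by dropping the larger position); applied iteratively until no
#' violating pair remains. Pair identifiers not present among the input
#' variants are ignored with a warning.
#'
#' @param variants Variant-record data frame with `p_c` and `position`.
#' @param ld_pairs Data frame with columns `id_a`, `id_b`, `r2`.
#' @param r2_max LD cap; pairs with `r2 > r2_max` may not both be retained.
#' @return The retained variant records.
#' @export
ld_prune <- function(variants, ld_pairs, r2_max = 0.05) {
  if (is.null(ld_pairs) || nrow(ld_pairs) == 0) return(variants)
  if (any(ld_pairs$r2 < 0 | ld_pairs$r2 > 1)) stop("r2 outside [0, 1]")
  known <- ld_pairs$id_a %in% variants$variant_id &
    ld_pairs$id_b %in% variants$variant_id
  if (any(!known))
    warning(sum(!known), " LD pair(s) reference unknown variants; ignored")
  ld_pairs <- ld_pairs[known & ld_pairs$r2 > r2_max, , drop = FALSE]
  retained <- variants
  repeat {
    live <- ld_pairs$id_a %in% retained$variant_id &
      ld_pairs$id_b %in% retained$variant_id
    if (!any(live)) break
    involved <- unique(c(ld_pairs$id_a[live], ld_pairs$id_b[live]))
    cand <- retained[retained$variant_id %in% involved, , drop = FALSE]
    worst <- cand[order(-cand$p_c, -cand$position), , drop = FALSE][1, ]
    retained <- retained[retained$variant_id != worst$variant_id, , drop = FALSE]
  }
  retained
}

.beta_col <- function(stratum) {
  switch(stratum, women = "beta_w", men = "beta_m", combined = "beta_c",
         stop("unknown stratum: ", stratum))
}

#' Orient variants so the effect allele increases the trait
#'
#' Where the chosen stratum's effect estimate is negative, the effect and
#' other allele labels are swapped, all three strata's betas are negated, and
#' the effect-allele frequency is replaced by its complement. Variants with an
#' exactly zero effect are left unchanged and recorded in the `"orient_log"`
#' attribute.
#'
#' @param variants Variant-record data frame.
#' @param stratum Stratum whose betas define the trait-increasing allele
#'   (`"women"`, `"men"`, or `"combined"`).
#' @return The oriented variant records; the orientation stratum's betas are
#'   all non-negative afterwards.
#' @export
orient_to_trait_increasing <- function(variants,
                                       stratum = c("combined", "women", "men")) {
  stratum <- match.arg(stratum)
  bcol <- .beta_col(stratum)
  b <- variants[[bcol]]
  if (anyNA(b)) stop("orientation stratum has missing betas")
  flip <- b < 0
  if (any(flip)) {
    ea <- variants$effect_allele[flip]
    variants$effect_allele[flip] <- variants$other_allele[flip]
    variants$other_allele[flip] <- ea
    variants$eaf[flip] <- 1 - variants$eaf[flip]
    for (col in intersect(c("beta_w", "beta_m", "beta_c"), names(variants)))
      variants[[col]][flip] <- -variants[[col]][flip]
  }
  attr(variants, "orient_log") <- variants$variant_id[b == 0]
  variants
}

#' Build a genetic risk score instrument
#'
#' Attaches per-variant weights to an oriented variant set. Sex-specific and
#' combined weighting use the absolute value of the corresponding stratum's
#' estimate (non-negative after orientation); unweighted scores use weight 1;
#' external weighting takes the external table's estimate re-oriented to the
#' instrument's trait-increasing allele (external variants that cannot be
#' resolved by identifier and allele pair are excluded and logged).
#'
#' @param variants Oriented variant records.
#' @param trait Trait label (e.g. `"bmi"`).
#' @param stratum Stratum label (`"women"`, `"men"`, `"combined"`).
#' @param weighting One of `"sex_specific"`, `"combined"`, `"unweighted"`,
#'   `"external"`.
#' @param external_table For external weighting: data frame with
#'   `variant_id`, `effect_allele`, `other_allele`, `beta`.
#' @return An `instrument_set`: list with `trait`, `stratum`, `weighting`,
#'   `variants` (data frame with `weight` column), and `log` (exclusions).
#' @export
build_instrument <- function(variants, trait, stratum,
                             weighting = c("sex_specific", "combined",
                                           "unweighted", "external"),
                             external_table = NULL) {
  weighting <- match.arg(weighting)
  log <- data.frame(variant_id = character(), reason = character(),
                    stringsAsFactors = FALSE)
  if (weighting == "sex_specific") {
    bcol <- .beta_col(stratum)
    weight <- abs(variants[[bcol]])
  } else if (weighting == "combined") {
    weight <- abs(variants$beta_c)
  } else if (weighting == "unweighted") {
    weight <- rep(1, nrow(variants))
  } else {
    if (is.null(external_table)) stop("external weighting needs a table")
    i <- match(variants$variant_id, external_table$variant_id)
    weight <- rep(NA_real_, nrow(variants))
    for (k in seq_len(nrow(variants))) {
      if (is.na(i[k])) next
      ext <- external_table[i[k], ]
      if (ext$effect_allele == variants$effect_allele[k] &&
          ext$other_allele == variants$other_allele[k]) {
        weight[k] <- ext$beta
      } else if (ext$effect_allele == variants$other_allele[k] &&
                 ext$other_allele == variants$effect_allele[k]) {
        weight[k] <- -ext$beta
      }
    }
    drop <- is.na(weight)
    if (any(drop)) {
      log <- data.frame(variant_id = variants$variant_id[drop],
                        reason = "unresolved_in_external_table",
                        stringsAsFactors = FALSE)
      variants <- variants[!drop, , drop = FALSE]
      weight <- weight[!drop]
    }
  }
  if (nrow(variants) == 0) stop("instrument is empty after weighting")
  vv <- variants[, c("variant_id", "effect_allele", "other_allele", "eaf")]
  vv$weight <- weight
  out <- list(trait = trait, stratum = stratum, weighting = weighting,
              variants = vv, log = log)
  class(out) <- "instrument_set"
  out
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Genetic risk score instrument: %s, %s stratum (%s weights)\n",
              x$trait, x$stratum, x$weighting))
  cat(sprintf("  %d variants; weight range [%.4g, %.4g]\n",
              nrow(x$variants), min(x$variants$weight), max(x$variants$weight)))
  if (nrow(x$log)) cat(sprintf("  %d exclusions logged\n", nrow(x$log)))
  invisible(x)
}

#' @export
length.instrument_set <- function(x) nrow(x$variants)

#' Score individuals with a genetic risk score (sum of weighted dosages)
#'
#' Computes `score_i = sum_j w_j d_ij` over the instrument's variants, with
#' dosages aligned to the instrument's effect allele (a dosage stored for the
#' other allele enters as `2 - d`) and missing dosages mean-imputed with
#' `2 * eaf`.
#'
#' @param instrument An [build_instrument()] instrument.
#' @param dosages Dosage matrix with variant ids as column names; values in
#'   `[0, 2]` or `NA`.
#' @param counted_alleles Optional named character vector giving, per variant
#'   id, the allele whose copies the dosage column counts; defaults to the
#'   instrument's effect allele.
#' @return Numeric score vector (weighted allele-count units), one per row of
#'   `dosages`.
#' @export
score_individuals <- function(instrument, dosages, counted_alleles = NULL) {
  stopifnot(inherits(instrument, "instrument_set"))
  v <- instrument$variants
  missing_cols <- setdiff(v$variant_id, colnames(dosages))
  if (length(missing_cols))
    stop("variant(s) absent from dosage matrix: ",
         paste(utils::head(missing_cols, 5), collapse = ", "))
  score <- numeric(nrow(dosages))
  for (k in seq_len(nrow(v))) {
    d <- dosages[, v$variant_id[k]]
    if (!is.null(counted_alleles) && v$variant_id[k] %in% names(counted_alleles)) {
      al <- counted_alleles[[v$variant_id[k]]]
      if (al == v$other_allele[k]) d <- 2 - d
      else if (al != v$effect_allele[k])
        stop("counted allele for ", v$variant_id[k],
             " matches neither instrument allele")
    }
    d[is.na(d)] <- 2 * v$eaf[k]
    score <- score + v$weight[k] * d
  }
  unname(score)
}

#' Evaluate instrument strength: variance explained and F-statistic
#'
#' Fits least-squares models of the standardized trait on the covariates with
#' and without the score. Variance explained is the increment in R-squared;
#' the F-statistic is the squared t-statistic of the score term (the 1-df
#' partial F).
#'
#' @param score Instrument score vector.
#' @param trait Standardized trait values (already residualized and
#'   rank-transformed upstream).
#' @param covariates Optional data frame of covariates (e.g. array and 10
#'   principal components).
#' @return An `instrument_fit`: list with `r_squared`, `f_statistic`, `n`.
#' @export
evaluate_instrument <- function(score, trait, covariates = NULL) {
  ok <- !is.na(score) & !is.na(trait)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
  score <- score[ok]; trait <- trait[ok]
  if (stats::var(score) == 0) stop("score has zero variance")
  x0 <- .build_design(if (is.null(covariates)) NULL
                      else covariates[ok, , drop = FALSE], length(score))
  fit0 <- stats::lm.fit(x0, trait)
  fit1 <- .linear_score_fit(trait, score,
                            if (is.null(covariates)) NULL
                            else covariates[ok, , drop = FALSE])
  tss <- sum((trait - mean(trait))^2)
  rss0 <- sum(fit0$residuals^2)
  r2 <- (rss0 - fit1$rss) / tss
  if (r2 >= 1 - 1e-10)
    stop("degenerate fit: score explains (essentially) all trait variance")
  out <- list(r_squared = r2,
              f_statistic = (fit1$beta / fit1$se)^2,
              n = length(trait))
  class(out) <- "instrument_fit"
  out
}

#' @export
print.instrument_fit <- function(x, ...) {
  cat(sprintf("Instrument fit: R^2 = %.4f, F = %.1f (n = %d)\n",
              x$r_squared, x$f_statistic, x$n))
  invisible(x)
}
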