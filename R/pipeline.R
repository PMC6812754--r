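#' Configuration for an end-to-end pipeline run
#'
#' Exactly one of `inputs` (paths to sumstats/dosage/phenotype/LD files) or
#' `simulation` (parameters for the synthetic cohort) must be supplied. All
#' randomness flows from `seed` via fixed per-stage offsets, so a re-run with
#' the same configuration is byte-identical.
#'
#' @param simulation List with `m` (number of variants) and any [sim_params()]
#'   arguments; or `NULL` when `inputs` is given.
#' @param inputs List of file paths (`sumstats_women`, `sumstats_men`,
#'   `sumstats_combined`, `dosages`, `phenotypes`, optionally `ld_pairs`);
#'   or `NULL` when `simulation` is given.
#' @param trait Exposure trait label (a cohort column).
#' @param outcomes Character vector of outcome labels; `status_` columns are
#'   binary, others continuous. `"smoking"` is derived from the code fields.
#' @param weighting Instrument weighting mode (see [build_instrument()]).
#' @param families Named vector of test-family sizes. Defaults: 51
#'   trait-disease, 15 trait-risk-factor, 48 disease heterogeneity, 21
#'   instrument comparisons.
#' @param adjust_smoking,match_cases Sensitivity toggles: adjust MRs for
#'   smoking status; equalize case/control counts across the sexes before the
#'   disease regressions.
#' @param seed Master seed.
#' @return A validated `run_config` list.
#' @export
run_config <- function(simulation = list(m = 50, n_individuals = 4000L),
                       inputs = NULL,
                       trait = "bmi",
                       outcomes = c("status_disease", "smoking",
                                    "sbp_std", "dbp_std"),
                       weighting = "sex_specific",
                       families = c(disease = 51, riskfactor = 15,
                                    het = 48, instrument = 21),
                       adjust_smoking = FALSE,
                       match_cases = FALSE,
                       seed = 1L) {
  if (is.null(simulation) == is.null(inputs))
    stop("exactly one of 'simulation' or 'inputs' must be supplied")
  if (any(families < 1)) stop("family sizes must be >= 1")
  cfg <- list(simulation = simulation, inputs = inputs, trait = trait,
              outcomes = outcomes, weighting = weighting,
              families = families, adjust_smoking = adjust_smoking,
              match_cases = match_cases, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys mirror [run_config()]
#'   arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the 'yaml' package")
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        names(formals(run_config)))]
  if (!is.null(args$families)) args$families <- unlist(args$families)
  if (is.null(args$simulation) && !is.null(args$inputs))
    args["simulation"] <- list(NULL)
  do.call(run_config, args)
}

#' Equalize case and control counts between the sexes
#'
#' Down-samples, without replacement, the cases (and controls) of the sex
#' with the larger count to match the smaller sex's counts; a sex-stratified
#' sensitivity analysis run on the result uses the same number of cases and
#' controls in men and women.
#'
#' @param cohort Cohort data frame with `sex` and the outcome status column.
#' @param outcome Name of the `status_*` column.
#' @param seed Integer seed for the subsampling.
#' @return The subsampled cohort (row subset of the input; excluded
#'   individuals retained).
#' @export
match_case_counts <- function(cohort, outcome, seed = 1L) {
  status <- cohort[[outcome]]
  set.seed(seed)
  keep <- rep(TRUE, nrow(cohort))
  for (lab in c("case", "control")) {
    iw <- which(status == lab & cohort$sex == "female")
    im <- which(status == lab & cohort$sex == "male")
    if (lab == "case" && (length(iw) == 0 || length(im) == 0))
      stop("a sex has zero cases")
    target <- min(length(iw), length(im))
    for (idx in list(iw, im)) {
      if (length(idx) > target)
        keep[sample(idx, length(idx) - target)] <- FALSE
    }
  }
  cohort[keep, , drop = FALSE]
}

# Covariate sets per outcome type: binary outcomes (clinical units) get the
# full set (age, age^2, centre, array, PCs, sex in combined runs); rank
# inverse-normal transformed outcomes get array and PCs only, since age,
# age^2, centre (and sex) were already removed in the transformation.
.pipeline_covars <- function(cohort, rows, stratum, binary) {
  covar_cols <- intersect(c("array", paste0("pc", 1:10)), names(cohort))
  covd <- cohort[rows, covar_cols, drop = FALSE]
  if (binary) {
    covd$age <- cohort$age[rows]
    covd$age_sq <- cohort$age[rows]^2
    covd$centre <- cohort$centre[rows]
    if (stratum == "combined") covd$sex <- cohort$sex[rows]
  }
  covd
}

.stratum_rows <- function(sex, stratum) {
  switch(stratum,
         women = sex == "female",
         men = sex == "male",
         combined = rep(TRUE, length(sex)),
         stop("unknown stratum: ", stratum))
}

# Standardize the trait within each stratum: medication-correct BP traits,
# then residualize on age/age^2/centre (+ sex in the combined run) and RINT.
.standardize_all <- function(cohort, raw_col) {
  vals <- cohort[[raw_col]]
  out <- list()
  for (stratum in c("women", "men", "combined")) {
    rows <- .stratum_rows(cohort$sex, stratum)
    cov <- cohort[rows, c("age", "centre"), drop = FALSE]
    if (stratum == "combined") cov$sex <- cohort$sex[rows]
    z <- rep(NA_real_, nrow(cohort))
    z[rows] <- residualize_rint(vals[rows], cov)
    out[[stratum]] <- z
  }
  out
}

#' Run the full sex-stratified MR analysis
#'
#' Orchestrates simulate/ingest, instrument construction and evaluation,
#' phenotype standardization, association screening with the Bonferroni test
#' families, individual-level Wald-ratio MR for the screened tasks, and
#' male-female heterogeneity tests; optionally writes the four result tables
#' and a provenance log to `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory for the tab-delimited tables and
#'   log.
#' @return Invisibly, a list of class `mr_pipeline_result` with
#'   `instrument_fits`, `associations`, `mr`, `heterogeneity` (data frames),
#'   `tasks`, and `log` (character vector of provenance lines).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  if (!is.null(config$simulation)) {
    simc <- config$simulation
    m <- if (is.null(simc$m)) 50L else simc$m
    pargs <- simc[intersect(names(simc), names(formals(sim_params)))]
    pargs$seed <- seed + 3L
    params <- do.call(sim_params, pargs)
    panel <- make_variant_panel(m, seed = seed + 1L)
    dosages <- simulate_genotypes(panel, params$n_individuals,
                                  missing_rate = if (is.null(simc$missing_rate))
                                    0.01 else simc$missing_rate,
                                  seed = seed + 2L)
    sim <- simulate_cohort(panel, dosages, params)
    cohort <- sim$cohort
    note("simulated cohort: n=%d, m=%d, seed=%d", nrow(cohort), m, seed)
    raw_col <- "bmi"
    ss <- lapply(c(women = "women", men = "men", combined = "combined"),
                 function(s) {
                   std <- rep(NA_real_, nrow(cohort))
                   rows <- .stratum_rows(cohort$sex, s)
                   cov <- cohort[rows, c("age", "centre"), drop = FALSE]
                   if (s == "combined") cov$sex <- cohort$sex[rows]
                   std[rows] <- residualize_rint(cohort[[raw_col]][rows], cov)
                   cohort[[paste0("std_", s)]] <<- std
                   emit_sumstats(panel, dosages, cohort, paste0("std_", s), s)
                 })
    records <- variant_records(ss$women, ss$men, ss$combined)
    ld_pairs <- NULL
  } else {
    inp <- config$inputs
    records <- variant_records(read_sumstats(inp$sumstats_women),
                               read_sumstats(inp$sumstats_men),
                               read_sumstats(inp$sumstats_combined))
    dosages <- if (grepl("\\.vcf(\\.gz)?$", inp$dosages))
      read_vcf_dosages(inp$dosages) else read_dosages(inp$dosages)
    cohort <- read_cohort(inp$phenotypes)
    ld_pairs <- if (!is.null(inp$ld_pairs)) read_ld_pairs(inp$ld_pairs)
    raw_col <- config$trait
    std <- .standardize_all(cohort, raw_col)
    for (s in names(std)) cohort[[paste0("std_", s)]] <- std[[s]]
    note("loaded cohort: n=%d; %d variant records", nrow(cohort),
         nrow(records))
  }

  # blood-pressure correction + standardization, smoking derivation
  bp <- adjust_blood_pressure(cohort$sbp_mean, cohort$dbp_mean,
                              cohort$bp_medication)
  for (s in c("women", "men", "combined")) {
    rows <- .stratum_rows(cohort$sex, s)
    cov <- cohort[rows, c("age", "centre"), drop = FALSE]
    if (s == "combined") cov$sex <- cohort$sex[rows]
    for (tr in c("sbp", "dbp")) {
      z <- rep(NA_real_, nrow(cohort))
      z[rows] <- residualize_rint(bp[[paste0(tr, "_adj")]][rows], cov)
      cohort[[paste0(tr, "_std_", s)]] <- z
    }
  }
  cohort$smoking <- derive_smoking_status(cohort$field_1239,
                                          cohort$field_1249,
                                          cohort$field_20116)

  # instruments
  qc <- qc_filter_variants(records)
  for (i in seq_len(nrow(qc$excluded)))
    note("qc exclusion: %s (%s)", qc$excluded$variant_id[i],
         qc$excluded$reason[i])
  pruned <- merge_and_window_prune(qc$kept)
  note("window pruning: %d -> %d variants", nrow(qc$kept), nrow(pruned))
  if (!is.null(ld_pairs)) {
    n0 <- nrow(pruned)
    pruned <- ld_prune(pruned, ld_pairs)
    note("LD pruning: %d -> %d variants", n0, nrow(pruned))
  }

  covar_cols <- c("array", paste0("pc", 1:10))
  covar_cols <- intersect(covar_cols, names(cohort))
  # dosage columns count the summary statistics' stored effect allele, which
  # orientation may swap; record it so scoring can re-align flipped variants
  counted <- stats::setNames(pruned$effect_allele, pruned$variant_id)
  instruments <- list(); scores <- list(); fits <- list()
  for (s in c("women", "men", "combined")) {
    oriented <- orient_to_trait_increasing(pruned, s)
    inst <- build_instrument(oriented, config$trait, s,
                             weighting = config$weighting)
    sc <- score_individuals(inst, dosages, counted_alleles = counted)
    rows <- .stratum_rows(cohort$sex, s)
    fit <- evaluate_instrument(sc[rows], cohort[[paste0("std_", s)]][rows],
                               cohort[rows, covar_cols, drop = FALSE])
    instruments[[s]] <- inst
    scores[[s]] <- sc
    fits[[s]] <- data.frame(trait = config$trait, stratum = s,
                            n_variants = nrow(inst$variants),
                            r_squared = fit$r_squared,
                            f_statistic = fit$f_statistic, n = fit$n,
                            stringsAsFactors = FALSE)
    note("instrument %s: %d variants, R2=%.4f, F=%.1f", s,
         nrow(inst$variants), fit$r_squared, fit$f_statistic)
  }
  fit_table <- do.call(rbind, fits)

  # association screening
  assoc_res <- list()
  for (oc in config$outcomes) {
    binary <- startsWith(oc, "status_") || oc == "smoking"
    family <- if (startsWith(oc, "status_")) "disease" else "riskfactor"
    for (s in c("women", "men", "combined")) {
      rows <- which(.stratum_rows(cohort$sex, s))
      covd <- .pipeline_covars(cohort, rows, s, binary)
      if (binary) {
        coh_s <- cohort[rows, , drop = FALSE]
        if (config$match_cases && startsWith(oc, "status_") &&
            s != "combined") {
          # matching is applied cohort-wide, then restricted to the stratum
          matched <- match_case_counts(cohort, oc, seed = seed + 7L)
          keep_ids <- matched$id
          sel <- coh_s$id %in% keep_ids
          coh_s <- coh_s[sel, , drop = FALSE]
          covd <- covd[sel, , drop = FALSE]
          rows <- rows[sel]
        }
        y <- if (oc == "smoking") as.integer(coh_s$smoking)
        else coh_s[[oc]]
        r <- fit_logistic(y, scores[[s]][rows], covd, outcome = oc,
                          trait = config$trait, stratum = s)
      } else {
        r <- fit_linear(cohort[[paste0(sub("_std$", "", oc), "_std_", s)]][rows],
                        scores[[s]][rows], covd, outcome = oc,
                        trait = config$trait, stratum = s)
      }
      r$family <- family
      assoc_res[[paste(oc, s)]] <- r
    }
  }
  assoc_tab <- assoc_table(assoc_res)
  assoc_tab$family <- vapply(assoc_res, function(r) r$family, character(1))

  # MR tasks and estimates
  tasks <- screen_for_mr(assoc_tab, config$families)
  estimates <- list()
  for (i in seq_len(nrow(tasks))) {
    oc <- tasks$outcome[i]; s <- tasks$stratum[i]
    rows <- which(.stratum_rows(cohort$sex, s))
    binary_oc <- startsWith(oc, "status_") || oc == "smoking"
    covd <- .pipeline_covars(cohort, rows, s, binary_oc)
    exposure <- cohort[[paste0("std_", s)]][rows]
    outcome <- if (oc == "smoking") as.integer(cohort$smoking[rows])
    else if (startsWith(oc, "status_")) cohort[[oc]][rows]
    else cohort[[paste0(sub("_std$", "", oc), "_std_", s)]][rows]
    est <- individual_level_mr(scores[[s]][rows], exposure, outcome,
                               covariates = covd,
                               adjust_smoking = config$adjust_smoking &&
                                 oc != "smoking",
                               smoking = as.integer(cohort$smoking[rows]),
                               trait = config$trait, outcome_label = oc,
                               stratum = s)
    estimates[[paste(oc, s)]] <- est
  }
  mr_tab <- if (length(estimates)) mr_table(estimates) else
    data.frame(trait = character(), outcome = character(),
               stratum = character(), method = character(),
               beta = numeric(), se = numeric(), p = numeric())

  # male-female heterogeneity on the MR estimates
  het_rows <- list()
  het_m <- config$families[["het"]]
  for (oc in unique(tasks$outcome)) {
    kw <- paste(oc, "women"); km <- paste(oc, "men")
    if (is.null(estimates[[kw]]) || is.null(estimates[[km]])) next
    ew <- estimates[[kw]]; em <- estimates[[km]]
    het <- compare_sexes(ew, em)
    het_rows[[oc]] <- data.frame(
      trait = config$trait, outcome = oc, method = "wald",
      beta_women = ew$beta, se_women = ew$se,
      beta_men = em$beta, se_men = em$se,
      q = het$q, p_het = het$p_het, family = "het",
      passes_threshold = het$p_het < 0.05 / het_m,
      stringsAsFactors = FALSE)
  }
  het_tab <- if (length(het_rows)) do.call(rbind, het_rows) else
    data.frame(trait = character(), outcome = character(),
               method = character(), q = numeric(), p_het = numeric())
  rownames(het_tab) <- NULL
  rownames(assoc_tab) <- NULL
  rownames(mr_tab) <- NULL

  out <- list(instrument_fits = fit_table, associations = assoc_tab,
              mr = mr_tab, heterogeneity = het_tab, tasks = tasks,
              instruments = instruments, log = log, config = config)
  class(out) <- "mr_pipeline_result"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(fit_table, file.path(out_dir, "instrument_fits.tsv"))
    .write_tsv(assoc_tab, file.path(out_dir, "associations.tsv"))
    .write_tsv(mr_tab, file.path(out_dir, "mr_estimates.tsv"))
    .write_tsv(het_tab, file.path(out_dir, "heterogeneity.tsv"))
    writeLines(log, file.path(out_dir, "provenance.log"))
  }
  invisible(out)
}

#' @export
print.mr_pipeline_result <- function(x, ...) {
  cat("Sex-stratified MR pipeline result\n")
  cat(sprintf("  instruments: %d strata; associations: %d rows; MR: %d rows; heterogeneity: %d rows\n",
              nrow(x$instrument_fits), nrow(x$associations), nrow(x$mr),
              nrow(x$heterogeneity)))
  invisible(x)
}
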