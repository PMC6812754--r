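# Shared simulation drivers for the test suite. Every fixture is generated in
# code under a caller-supplied seed; nothing is read from disk.

# Tiny deterministic variant-record table for instrument-rule tests.
toy_records <- function() {
  data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4"),
    chromosome = c("1", "1", "2", "2"),
    position = c(100000L, 600000L, 100000L, 5000000L),
    effect_allele = c("A", "C", "A", "G"),
    other_allele = c("G", "T", "C", "T"),
    eaf = c(0.3, 0.4, 0.2, 0.45),
    info_score = c(0.95, 0.99, 0.97, 0.92),
    missing_rate = c(0.01, 0.02, 0.0, 0.01),
    biallelic = TRUE,
    beta_w = c(-0.05, 0.08, 0.02, 0.04),
    se_w = c(0.01, 0.01, 0.01, 0.01),
    p_w = c(1e-6, 1e-9, 0.04, 1e-4),
    beta_m = c(-0.03, 0.06, 0.03, 0.05),
    se_m = c(0.01, 0.01, 0.01, 0.01),
    p_m = c(1e-3, 1e-7, 0.02, 1e-5),
    beta_c = c(-0.04, 0.07, 0.025, 0.045),
    se_c = c(0.007, 0.007, 0.007, 0.007),
    p_c = c(1e-10, 1e-12, 0.01, 1e-8),
    stringsAsFactors = FALSE
  )
}

# End-to-end single-replicate driver: simulate a cohort, rebuild the
# sex-specific instruments from within-cohort summary statistics, and return
# the two individual-level Wald MR estimates plus the heterogeneity test.
# covariate_set = "minimal" skips the covariate machinery for speed in
# calibration loops (valid because the generator's covariate effects are
# small and identical across the sexes).
sim_mr_replicate <- function(seed, m = 100, n = 50000L,
                             cohort_params = list(),
                             panel_params = list(),
                             covariate_set = c("full", "minimal"),
                             adjust_smoking = FALSE,
                             observational = FALSE) {
  covariate_set <- match.arg(covariate_set)
  panel <- do.call(make_variant_panel,
                   c(list(m = m, seed = seed), panel_params))
  dos <- simulate_genotypes(panel, n, missing_rate = 0.01, seed = seed + 1L)
  sp <- do.call(sim_params,
                c(list(n_individuals = n, seed = seed + 2L), cohort_params))
  sim <- simulate_cohort(panel, dos, sp)
  coh <- sim$cohort
  counted <- stats::setNames(panel$effect_allele, panel$variant_id)
  out <- list(truth = sim$truth)
  for (s in c("women", "men")) {
    rows <- which(coh$sex == if (s == "women") "female" else "male")
    std <- if (covariate_set == "full")
      residualize_rint(coh$bmi[rows], coh[rows, c("age", "centre")])
    else residualize_rint(coh$bmi[rows])
    coh$std_tmp <- rep(NA_real_, nrow(coh))
    coh$std_tmp[rows] <- std
    ss <- emit_sumstats(panel, dos, coh, "std_tmp", s)
    rec <- variant_records(ss, ss, ss)
    oriented <- orient_to_trait_increasing(rec, s)
    inst <- build_instrument(oriented, "bmi", s, "sex_specific")
    sc <- score_individuals(inst, dos, counted_alleles = counted)[rows]
    covd <- if (covariate_set == "full")
      data.frame(age = coh$age[rows], age_sq = coh$age[rows]^2,
                 centre = coh$centre[rows], array = coh$array[rows],
                 coh[rows, paste0("pc", 1:10)])
    else NULL
    smoke <- derive_smoking_status(coh$field_1239[rows], coh$field_1249[rows],
                                   coh$field_20116[rows])
    out[[s]] <- individual_level_mr(
      sc, std, coh$status_disease[rows], covariates = covd,
      adjust_smoking = isTRUE(adjust_smoking), smoking = as.integer(smoke),
      trait = "bmi", outcome_label = "disease", stratum = s)
    if (identical(adjust_smoking, "both"))
      out[[paste0(s, "_adj")]] <- individual_level_mr(
        sc, std, coh$status_disease[rows], covariates = covd,
        adjust_smoking = TRUE, smoking = as.integer(smoke),
        trait = "bmi", outcome_label = "disease", stratum = s)
    if (observational) {
      obs <- fit_logistic(coh$status_disease[rows], std, covd,
                          outcome = "disease", stratum = s)
      out[[paste0("obs_z_", s)]] <- obs$beta / obs$se
    }
  }
  out$het <- compare_sexes(out$women, out$men)
  out
}
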