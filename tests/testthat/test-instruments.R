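test_that("QC filters apply in documented order with a single primary reason", {
  rec <- toy_records()
  rec$info_score[1] <- 0.2            # fails info
  rec$eaf[2] <- 0.00005               # fails maf
  res <- qc_filter_variants(rec)
  expect_identical(res$excluded$reason[res$excluded$variant_id == "rs1"], "info")
  expect_identical(res$excluded$reason[res$excluded$variant_id == "rs2"], "maf")
  expect_identical(res$kept$variant_id, c("rs3", "rs4"))

  # rule-order oracle: for every subset of failing rules, the logged reason is
  # the first in the order info > maf > hwe > missing > biallelic
  rules <- c("info", "maf", "hwe", "missing", "biallelic")
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  for (i in seq_len(nrow(combos))) {
    fails <- unlist(combos[i, ])
    v <- toy_records()[3, ]
    v$hwe_p <- 0.5
    if (fails[1]) v$info_score <- 0.1
    if (fails[2]) v$eaf <- 1e-6
    if (fails[3]) v$hwe_p <- 1e-9
    if (fails[4]) v$missing_rate <- 0.5
    if (fails[5]) v$biallelic <- FALSE
    res <- qc_filter_variants(v)
    if (!any(fails)) {
      expect_identical(nrow(res$excluded), 0L)
    } else {
      expected <- c("info", "maf", "hwe", "missing", "not_biallelic")[which(fails)[1]]
      expect_identical(res$excluded$reason, expected)
    }
  }
})

test_that("window pruning keeps the lowest combined-sexes p within the window and deduplicates", {
  rec <- toy_records()[1:2, ]  # chr1: 100kb (p 1e-10) and 600kb (p 1e-12)
  out <- merge_and_window_prune(rec)
  expect_identical(out$variant_id, "rs2")

  # same variant in two stratum lists appears once
  out2 <- merge_and_window_prune(list(toy_records(), toy_records()[2:3, ]))
  expect_false(anyDuplicated(out2$variant_id) > 0)

  expect_error(merge_and_window_prune(transform(toy_records(),
                                                position = NA)), "position")
})

test_that("greedy window pruning satisfies its fixed-point characterization", {
  set.seed(99)
  for (rep in 1:5) {
    n <- 20
    v <- data.frame(variant_id = paste0("v", 1:n), chromosome = "1",
                    position = sample.int(5e6, n),
                    p_c = runif(n, 1e-12, 1e-2), stringsAsFactors = FALSE)
    out <- merge_and_window_prune(v, window_bp = 1e6)
    kept <- v$variant_id %in% out$variant_id
    rank_key <- order(v$p_c, v$variant_id)
    better <- function(i, j) {  # is i ranked before j in the greedy order?
      which(rank_key == i) < which(rank_key == j)
    }
    for (i in seq_len(n)) {
      conflicts <- which(abs(v$position - v$position[i]) <= 1e6 &
                           seq_len(n) != i &
                           vapply(seq_len(n), better, logical(1), j = i) &
                           kept)
      # retained iff no better-ranked retained variant within the window
      expect_identical(kept[i], length(conflicts) == 0L)
    }
  }
})

test_that("LD pruning drops the weaker member per violating pair and iterates to a fixpoint", {
  rec <- toy_records()
  # pair below the cap: both kept
  out <- ld_prune(rec, data.frame(id_a = "rs1", id_b = "rs2", r2 = 0.04))
  expect_identical(nrow(out), 4L)
  # violating pair: the larger-p_c member (rs1, p 1e-10 vs rs2, p 1e-12) dropped
  out <- ld_prune(rec, data.frame(id_a = "rs1", id_b = "rs2", r2 = 0.2))
  expect_false("rs1" %in% out$variant_id)
  expect_true("rs2" %in% out$variant_id)

  # chain A-B, B-C with p(A) < p(C) < p(B): only B dropped
  chain <- data.frame(variant_id = c("A", "B", "C"), chromosome = "1",
                      position = c(1, 2, 3) * 1e6,
                      p_c = c(1e-12, 1e-6, 1e-8), stringsAsFactors = FALSE)
  pairs <- data.frame(id_a = c("A", "B"), id_b = c("B", "C"), r2 = 0.1)
  out <- ld_prune(chain, pairs)
  expect_setequal(out$variant_id, c("A", "C"))

  # re-scan: no retained pair above the cap
  live <- pairs$id_a %in% out$variant_id & pairs$id_b %in% out$variant_id
  expect_false(any(pairs$r2[live] > 0.05))

  expect_warning(ld_prune(chain, data.frame(id_a = "A", id_b = "zz", r2 = 0.9)),
                 "unknown")
  expect_error(ld_prune(chain, data.frame(id_a = "A", id_b = "B", r2 = 1.2)),
               "r2")
})

test_that("orientation flips alleles, betas, and frequency, and is idempotent", {
  rec <- toy_records()
  out <- orient_to_trait_increasing(rec, "women")
  expect_identical(out$effect_allele[1], "G")
  expect_identical(out$other_allele[1], "A")
  expect_equal(out$beta_w[1], 0.05)
  expect_equal(out$beta_m[1], 0.03)   # all strata negated together
  expect_equal(out$eaf[1], 0.7)
  # already trait-increasing rows untouched
  expect_identical(out$effect_allele[2], rec$effect_allele[2])
  expect_equal(out$beta_w[2], rec$beta_w[2])
  expect_true(all(out$beta_w >= 0))
  # involution collapses: double application is the identity
  expect_equal(orient_to_trait_increasing(out, "women")[, names(rec)],
               out[, names(rec)])
  # zero beta logged, not flipped
  rec$beta_w[3] <- 0
  out0 <- orient_to_trait_increasing(rec, "women")
  expect_identical(attr(out0, "orient_log"), "rs3")
  expect_identical(out0$effect_allele[3], rec$effect_allele[3])
})

test_that("instrument weighting follows the selected scheme", {
  rec <- orient_to_trait_increasing(toy_records(), "women")
  inst_u <- build_instrument(rec, "bmi", "women", "unweighted")
  expect_equal(inst_u$variants$weight, rep(1, 4))
  inst_w <- build_instrument(rec, "bmi", "women", "sex_specific")
  expect_equal(inst_w$variants$weight, abs(rec$beta_w))
  expect_true(all(inst_w$variants$weight >= 0))

  # external table stored on the opposite allele: beta -0.2 becomes +0.2
  ext <- data.frame(variant_id = "rs1",
                    effect_allele = rec$other_allele[1],
                    other_allele = rec$effect_allele[1],
                    beta = -0.2, stringsAsFactors = FALSE)
  inst_e <- build_instrument(rec[1, ], "bmi", "women", "external",
                             external_table = ext)
  expect_equal(inst_e$variants$weight, 0.2)

  # unresolvable external variants are excluded with a logged reason
  inst_e2 <- build_instrument(rec, "bmi", "women", "external",
                              external_table = ext)
  expect_identical(nrow(inst_e2$variants), 1L)
  expect_identical(sort(inst_e2$log$variant_id), c("rs2", "rs3", "rs4"))
  expect_error(build_instrument(rec[0, ], "bmi", "women", "unweighted"),
               "empty")
})

test_that("scoring sums weighted aligned dosages with mean imputation for missing", {
  rec <- orient_to_trait_increasing(toy_records()[1:2, ], "women")
  inst <- build_instrument(rec, "bmi", "women", "sex_specific")
  inst$variants$weight <- c(0.1, 0.2)
  d <- matrix(c(2, 1), 1, 2, dimnames = list(NULL, c("rs1", "rs2")))
  expect_equal(score_individuals(inst, d), 0.4)

  # missing dosage contributes weight * 2 * eaf
  inst1 <- inst; inst1$variants <- inst1$variants[1, ]
  inst1$variants$weight <- 0.5; inst1$variants$eaf <- 0.3
  dmiss <- matrix(NA_real_, 1, 1, dimnames = list(NULL, "rs1"))
  expect_equal(score_individuals(inst1, dmiss), 0.3)

  # single variant: score = weight * dosage
  d1 <- matrix(0:2, 3, 1, dimnames = list(NULL, "rs1"))
  expect_equal(score_individuals(inst1, d1), 0.5 * (0:2))

  expect_error(score_individuals(inst, d[, 1, drop = FALSE]), "absent")
})

test_that("stored allele polarity does not change scores or downstream betas", {
  set.seed(7)
  rec <- orient_to_trait_increasing(toy_records(), "women")
  inst <- build_instrument(rec, "bmi", "women", "sex_specific")
  n <- 300
  d <- sapply(rec$eaf, function(f) rbinom(n, 2, f))
  colnames(d) <- rec$variant_id
  s1 <- score_individuals(inst, d)
  # store rs1 for the other allele and declare it: identical scores
  d2 <- d; d2[, "rs1"] <- 2 - d2[, "rs1"]
  s2 <- score_individuals(inst, d2,
                          counted_alleles = c(rs1 = rec$other_allele[1]))
  expect_identical(s1, s2)
  y <- 0.5 * s1 + rnorm(n)
  f1 <- fit_linear(y, s1)
  f2 <- fit_linear(y, s2)
  expect_identical(f1$beta, f2$beta)
})

test_that("instrument evaluation matches the closed-form F identity and scales with n", {
  set.seed(11)
  n <- 10000
  sc <- rnorm(n)
  r2 <- 0.05
  tr <- sqrt(r2) * sc + sqrt(1 - r2) * rnorm(n)
  tr <- as.numeric(scale(tr))
  fit <- evaluate_instrument(sc, tr)
  r2_hat <- fit$r_squared
  expect_equal(fit$f_statistic, (n - 2) * r2_hat / (1 - r2_hat),
               tolerance = 1e-6)
  expect_equal(r2_hat, r2, tolerance = 0.2)

  # degenerate perfect fit rejected
  expect_error(evaluate_instrument(sc, sc), "degenerate")
  expect_error(evaluate_instrument(rep(1, 50), rnorm(50)), "zero variance")

  # F approximately linear in n at fixed r^2
  fs <- vapply(c(2000, 4000, 8000), function(nn) {
    s <- rnorm(nn)
    t <- sqrt(0.1) * s + sqrt(0.9) * rnorm(nn)
    evaluate_instrument(s, t)$f_statistic
  }, numeric(1))
  expect_equal(fs[2] / fs[1], 2, tolerance = 0.2)
  expect_equal(fs[3] / fs[2], 2, tolerance = 0.2)
})

test_that("a null score's partial F is calibrated against chi-square", {
  set.seed(12)
  f99 <- qchisq(0.999, 1)
  hits <- vapply(1:200, function(i) {
    sc <- rnorm(500)
    tr <- rnorm(500)
    evaluate_instrument(sc, tr)$f_statistic < f99
  }, logical(1))
  expect_gte(mean(hits), 0.97)
})
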