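test_that("Wald ratio and its two-term delta standard error match hand computation", {
  est <- wald_ratio(list(beta = 0.2, se = 0.05), list(beta = 0.5, se = 0.02))
  expect_equal(est$beta, 0.4)
  expect_equal(est$se, sqrt(0.05^2 / 0.25 + 0.04 * 4e-4 / 0.0625))
  expect_equal(est$se, 0.101272, tolerance = 1e-6)

  # zero numerator: second delta term vanishes
  est0 <- wald_ratio(list(beta = 0, se = 0.05), list(beta = 0.5, se = 0.02))
  expect_equal(est0$beta, 0)
  expect_equal(est0$se, 0.05 / 0.5)

  expect_error(wald_ratio(list(beta = 0.2, se = 0.05),
                          list(beta = 0, se = 0.02)), "zero")
  expect_error(wald_ratio(list(beta = 0.2, se = 0.05, stratum = "women"),
                          list(beta = 0.5, se = 0.02, stratum = "men")),
               "stratum")
})

test_that("the delta SE matches the Monte-Carlo SD of the ratio", {
  set.seed(10)
  gx <- rnorm(10000, 0.5, 0.02)
  gy <- rnorm(10000, 0.2, 0.05)
  mc_sd <- sd(gy / gx)
  est <- wald_ratio(list(beta = 0.2, se = 0.05), list(beta = 0.5, se = 0.02))
  expect_equal(est$se, mc_sd, tolerance = 0.05)
})

test_that("Wald SE dominates the first-order SE, with equality only at a null numerator", {
  set.seed(11)
  for (i in 1:50) {
    by <- rnorm(1); bx <- runif(1, 0.1, 2)
    sy <- runif(1, 0.01, 0.5); sx <- runif(1, 0.01, 0.5)
    est <- wald_ratio(list(beta = by, se = sy), list(beta = bx, se = sx))
    expect_gte(est$se, sy / abs(bx))
  }
  est0 <- wald_ratio(list(beta = 0, se = 0.3), list(beta = 0.7, se = 0.2))
  expect_equal(est0$se, 0.3 / 0.7)
})

test_that("IVW reduces to the Wald ratio on a singleton and pools by inverse variance", {
  tr1 <- data.frame(variant_id = "a", bx = 0.5, se_x = 0.02,
                    by = 0.2, se_y = 0.05)
  est <- ivw(tr1)
  expect_equal(est$beta, 0.4, tolerance = 1e-12)
  expect_equal(est$se, 0.05 / 0.5, tolerance = 1e-12)
  w0 <- wald_ratio(list(beta = 0.2, se = 0.05), list(beta = 0.5, se = 0))
  expect_equal(est$beta, w0$beta, tolerance = 1e-12)
  expect_equal(est$se, w0$se, tolerance = 1e-12)

  # hand-computed two-SNP pool: ratios (0.4, 0.6), first-order ses (0.1, 0.2)
  tr2 <- data.frame(variant_id = c("a", "b"), bx = c(1, 1), se_x = 0.01,
                    by = c(0.4, 0.6), se_y = c(0.1, 0.2))
  est2 <- ivw(tr2)
  expect_equal(est2$beta, 0.44)
  expect_equal(est2$se, 0.089443, tolerance = 1e-5)

  # constancy: equal ratios give that ratio back regardless of weights
  tr3 <- data.frame(variant_id = c("a", "b", "c"), bx = c(0.2, 0.5, 1),
                    se_x = 0.01, by = c(0.2, 0.5, 1) * 0.37,
                    se_y = c(0.3, 0.05, 0.11))
  expect_equal(ivw(tr3)$beta, 0.37)
  expect_error(ivw(tr3[0, ]), "at least one")
})

test_that("MR-Egger recovers exact linear data and matches IVW when the intercept is dropped", {
  bx <- c(0.1, 0.2, 0.3, 0.5)
  tr <- data.frame(variant_id = letters[1:4], bx = bx, se_x = 0.01,
                   by = 0.05 + 0.3 * bx, se_y = c(0.1, 0.2, 0.1, 0.3))
  est <- mr_egger(tr)
  expect_equal(est$beta, 0.3, tolerance = 1e-10)
  expect_equal(est$egger_intercept$beta, 0.05, tolerance = 1e-10)

  # no-intercept weighted regression of by on bx == IVW, to 1e-10
  w <- 1 / tr$se_y^2
  slope_ni <- sum(w * tr$bx * tr$by) / sum(w * tr$bx^2)
  expect_equal(ivw(tr)$beta, slope_ni, tolerance = 1e-10)
  expect_equal(ivw(tr)$se, 1 / sqrt(sum(w * tr$bx^2)), tolerance = 1e-10)

  expect_error(mr_egger(tr[1:2, ]), "at least 3")
  tr_flat <- tr; tr_flat$bx <- 0.2
  expect_error(mr_egger(tr_flat), "spread")
})

test_that("the weighted median interpolates the cumulative-midpoint definition", {
  tr <- data.frame(variant_id = c("a", "b", "c"), bx = 1, se_x = 0.01,
                   by = c(0.1, 0.2, 0.3), se_y = 1)
  est <- weighted_median(tr, n_boot = 50, seed = 1)
  expect_equal(est$beta, 0.2)  # equal weights, odd n: the sample median

  # one SNP holding the weight majority returns its own ratio
  tr2 <- data.frame(variant_id = c("a", "b", "c"), bx = 1, se_x = 0.01,
                    by = c(0.1, 0.25, 0.4), se_y = c(0.05, 1, 1))
  expect_equal(weighted_median(tr2, n_boot = 50, seed = 1)$beta, 0.1)

  # random configurations equal a brute-force evaluation of the definition
  brute <- function(ratios, w) {
    o <- order(ratios); r <- ratios[o]; w <- w[o] / sum(w)
    if (any(w > 0.5)) return(r[which.max(w)])
    s <- cumsum(w) - w / 2
    k <- max(which(s < 0.5))
    r[k] + (r[k + 1] - r[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
  }
  set.seed(13)
  for (i in 1:20) {
    tr5 <- data.frame(variant_id = paste0("v", 1:5),
                      bx = runif(5, 0.2, 1), se_x = 0.01,
                      by = rnorm(5, 0.2, 0.3), se_y = runif(5, 0.05, 0.5))
    est <- weighted_median(tr5, n_boot = 10, seed = i)
    expect_equal(est$beta,
                 brute(tr5$by / tr5$bx, (abs(tr5$bx) / tr5$se_y)^2))
  }
  expect_error(weighted_median(tr[1, , drop = FALSE]), "at least two")
})

test_that("all summary estimators are invariant to SNP order", {
  set.seed(14)
  tr <- data.frame(variant_id = paste0("v", 1:8),
                   bx = runif(8, 0.1, 0.6), se_x = 0.01,
                   by = rnorm(8, 0.1, 0.2), se_y = runif(8, 0.05, 0.3))
  perm <- sample(8)
  trp <- tr[perm, ]
  expect_equal(ivw(tr)$beta, ivw(trp)$beta)
  expect_equal(mr_egger(tr)$beta, mr_egger(trp)$beta)
  expect_equal(weighted_median(tr, n_boot = 10, seed = 3)$beta,
               weighted_median(trp, n_boot = 10, seed = 3)$beta)
})

test_that("harmonization aligns alleles, drops ambiguous palindromes, and logs exclusions", {
  expo <- data.frame(variant_id = c("rs1", "rs2", "rs3", "rs4"),
                     effect_allele = c("A", "C", "A", "G"),
                     other_allele = c("G", "T", "T", "C"),
                     beta = c(0.1, 0.2, 0.15, 0.12),
                     se = c(0.01, 0.01, 0.01, 0.01),
                     stringsAsFactors = FALSE)
  ext <- data.frame(variant_id = c("rs1", "rs2", "rs3", "rs5"),
                    effect_allele = c("G", "C", "A", "A"),
                    other_allele = c("A", "T", "T", "G"),
                    eaf = c(0.3, 0.2, 0.5, 0.4),
                    beta = c(-0.2, 0.05, 0.4, 0.1),
                    se = c(0.02, 0.02, 0.02, 0.02),
                    stringsAsFactors = FALSE)
  tri <- harmonize(expo, ext)
  log <- attr(tri, "harmonize_log")
  # swapped alleles: sign flips
  expect_equal(tri$by[tri$variant_id == "rs1"], 0.2)
  # matching alleles pass through
  expect_equal(tri$by[tri$variant_id == "rs2"], 0.05)
  # A/T palindrome at eaf 0.5 is strand-ambiguous
  expect_false("rs3" %in% tri$variant_id)
  expect_identical(log$reason[log$variant_id == "rs3"], "palindromic")
  # absent from the external table
  expect_identical(log$reason[log$variant_id == "rs4"], "unmatched")
})

test_that("two-sample estimators cover the true effect on simulated summary data", {
  theta <- 0.25
  cover <- matrix(NA, 200, 3,
                  dimnames = list(NULL, c("ivw", "egger", "wm")))
  panel <- make_variant_panel(40, pleiotropy_fraction = 0, seed = 1)
  for (r in 1:200) {
    tr <- simulate_snp_triples(panel, theta, se_x = 0.004, se_y = 0.01,
                               seed = 1000 + r)
    for (m in colnames(cover)) {
      est <- switch(m, ivw = ivw(tr), egger = mr_egger(tr),
                    wm = weighted_median(tr, n_boot = 200, seed = r))
      cover[r, m] <- abs(est$beta - theta) <= 1.959964 * est$se
    }
  }
  expect_true(all(colMeans(cover) >= 0.90))
})

test_that("individual-level MR wires the two regressions and the smoking adjustment", {
  set.seed(15)
  n <- 4000
  sc <- rnorm(n)
  x <- 0.5 * sc + rnorm(n)
  x <- as.numeric(scale(x))
  y <- rbinom(n, 1, plogis(-1 + 0.4 * x))
  status <- ifelse(y == 1, "case", "control")
  est <- individual_level_mr(sc, x, status, trait = "bmi",
                             outcome_label = "disease", stratum = "women")
  expect_s3_class(est, "mr_estimate")
  expect_lt(abs(est$beta - 0.4), 3 * est$se)
  expect_true(est$binary)
  expect_equal(exp(est$beta), est$or_point, tolerance = 1e-12)
  expect_true(est$ci_low < est$or_point && est$or_point < est$ci_high)

  smoke <- rbinom(n, 1, 0.3)
  est2 <- individual_level_mr(sc, x, status, adjust_smoking = TRUE,
                              smoking = smoke)
  expect_s3_class(est2, "mr_estimate")
  expect_error(individual_level_mr(sc, x, status, adjust_smoking = TRUE),
               "smoking")

  # continuous outcomes use linear regressions on everyone
  z <- 0.3 * x + rnorm(n)
  est3 <- individual_level_mr(sc, x, z, outcome_label = "sbp")
  expect_false(est3$binary)
  expect_lt(abs(est3$beta - 0.3), 3 * est3$se)
})
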