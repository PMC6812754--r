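# Design-matrix construction shared by the regression wrappers. Numeric
# columns enter linearly; factors/characters enter as indicator contrasts with
# the most frequent level as reference.
.build_design <- function(covariates, n) {
  x <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (is.null(covariates) || (is.data.frame(covariates) && ncol(covariates) == 0))
    return(x)
  if (!is.data.frame(covariates)) covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == n)
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.numeric(v) || is.logical(v)) {
      x <- cbind(x, matrix(as.numeric(v), ncol = 1,
                           dimnames = list(NULL, nm)))
    } else {
      f <- factor(v)
      ref <- names(which.max(table(f)))
      f <- stats::relevel(f, ref = ref)
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(nm, substring(colnames(mm), 2))
      x <- cbind(x, mm)
    }
  }
  x
}

# Least squares of y on [covariates, score]; returns score beta/se/p plus
# bookkeeping. Collinear covariate columns are dropped by pivoted QR; a
# collinear *score* is an error.
.linear_score_fit <- function(y, score, covariates = NULL) {
  n <- length(y)
  x <- cbind(.build_design(covariates, n),
             matrix(score, ncol = 1, dimnames = list(NULL, "score")))
  qx <- qr(x)
  rank <- qx$rank
  piv <- qx$pivot[seq_len(rank)]
  dropped <- colnames(x)[qx$pivot[-seq_len(rank)]]
  if ("score" %in% dropped)
    stop("score carries no information after adjusting for covariates")
  fit <- stats::lm.fit(x[, piv, drop = FALSE], y)
  coefs <- fit$coefficients
  res <- fit$residuals
  dfree <- n - rank
  if (dfree <= 0) stop("more parameters than observations")
  rss <- sum(res^2)
  sigma2 <- rss / dfree
  xtxinv <- chol2inv(qr.R(qr(x[, piv, drop = FALSE])))
  se_all <- sqrt(sigma2 * diag(xtxinv))
  j <- which(colnames(x)[piv] == "score")
  list(beta = unname(coefs[j]), se = unname(se_all[j]), df = dfree,
       rss = rss, dropped = dropped, n = n)
}

#' Linear association of an outcome with a genetic risk score
#'
#' Least-squares regression of a continuous outcome on the score plus
#' covariates, reporting the score term. Collinear covariate columns are
#' dropped (and recorded); a perfect fit (zero residual variance) is flagged
#' as degenerate.
#'
#' @param y Numeric outcome vector.
#' @param score Instrument score vector.
#' @param covariates Optional covariate data frame (numeric columns linear,
#'   factors as indicators).
#' @param outcome,trait,stratum Labels carried into the result.
#' @return An `assoc_result`: beta, se, two-sided p, n, labels, the dropped
#'   covariate columns, and a degeneracy flag.
#' @export
fit_linear <- function(y, score, covariates = NULL,
                       outcome = "y", trait = NA_character_,
                       stratum = NA_character_) {
  ok <- !is.na(y) & !is.na(score)
  if (!is.null(covariates)) {
    ok <- ok & stats::complete.cases(covariates)
    covariates <- covariates[ok, , drop = FALSE]
  }
  y <- y[ok]; score <- score[ok]
  fit <- .linear_score_fit(y, score, covariates)
  degenerate <- fit$se < 1e-12
  p <- if (degenerate) 0 else 2 * stats::pt(-abs(fit$beta / fit$se), fit$df)
  res <- list(outcome = outcome, trait = trait, stratum = stratum,
              beta = fit$beta, se = fit$se, p = p, n = fit$n,
              n_case = NA_integer_, n_control = NA_integer_,
              type = "linear", dropped = fit$dropped,
              degenerate = degenerate, separation = FALSE)
  class(res) <- "assoc_result"
  res
}

#' Logistic association of a case/control outcome with a genetic risk score
#'
#' Maximum-likelihood logistic regression of case status on the score plus
#' covariates (IRLS; relative deviance change below 1e-10, at most 100
#' iterations). Quasi-complete separation is detected and flagged; a
#' single-class outcome or an uninformative (constant) score is an error.
#'
#' @param y Case/control outcome: a 0/1 vector, logical, or character/factor
#'   with values `"case"`/`"control"` (anything else, e.g. `"excluded"`, is
#'   dropped).
#' @inheritParams fit_linear
#' @return An `assoc_result` with log-odds beta, se, two-sided normal p, and
#'   case/control counts.
#' @export
fit_logistic <- function(y, score, covariates = NULL,
                         outcome = "y", trait = NA_character_,
                         stratum = NA_character_) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    keep <- y %in% c("case", "control")
    y <- ifelse(y == "case", 1L, 0L)
    y[!keep] <- NA_integer_
  }
  y <- as.integer(y)
  ok <- !is.na(y) & !is.na(score)
  if (!is.null(covariates)) {
    ok <- ok & stats::complete.cases(covariates)
    covariates <- covariates[ok, , drop = FALSE]
  }
  y <- y[ok]; score <- score[ok]
  if (length(unique(y)) < 2) stop("outcome has a single class")
  if (stats::var(score) == 0) stop("score is constant: no information")
  n <- length(y)
  x <- cbind(.build_design(covariates, n),
             matrix(score, ncol = 1, dimnames = list(NULL, "score")))
  qx <- qr(x)
  rank <- qx$rank
  piv <- qx$pivot[seq_len(rank)]
  dropped <- colnames(x)[qx$pivot[-seq_len(rank)]]
  if ("score" %in% dropped)
    stop("score carries no information after adjusting for covariates")
  xr <- x[, piv, drop = FALSE]
  fit <- stats::glm.fit(xr, y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-10,
                                                     maxit = 100))
  if (!fit$converged) stop("logistic regression did not converge")
  mu <- fit$fitted.values
  separation <- any(mu < 1e-10 | mu > 1 - 1e-10) &&
    max(abs(fit$coefficients)) > 15
  rk <- fit$qr$rank
  cov <- chol2inv(fit$qr$qr[seq_len(rk), seq_len(rk), drop = FALSE])
  j <- which(colnames(xr) == "score")
  beta <- unname(fit$coefficients[j])
  se <- sqrt(cov[j, j])
  res <- list(outcome = outcome, trait = trait, stratum = stratum,
              beta = beta, se = se,
              p = 2 * stats::pnorm(-abs(beta / se)),
              n = n, n_case = sum(y == 1L), n_control = sum(y == 0L),
              type = "logistic", dropped = dropped,
              degenerate = FALSE, separation = separation)
  class(res) <- "assoc_result"
  if (separation)
    warning("possible (quasi-)separation in logistic fit for '", outcome, "'")
  res
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s association: %s ~ score%s\n",
              x$type, x$outcome,
              if (!is.na(x$stratum)) paste0(" [", x$stratum, "]") else ""))
  cat(sprintf("  beta = %.5g (se %.5g), p = %.3g, n = %d\n",
              x$beta, x$se, x$p, x$n))
  if (x$type == "logistic")
    cat(sprintf("  cases/controls: %d/%d\n", x$n_case, x$n_control))
  if (length(x$dropped))
    cat("  dropped collinear columns:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.assoc_result <- function(object, ...) c(score = object$beta)

#' Bonferroni threshold for a test family
#'
#' @param m Number of comparisons in the family (>= 1).
#' @return List with `exact` (`0.05 / m`, used for screening) and `reported`
#'   (rounded to one significant figure, the conventional reporting form).
#' @export
bonferroni_threshold <- function(m) {
  if (length(m) != 1 || !is.finite(m) || m < 1)
    stop("'m' must be a single integer >= 1")
  exact <- 0.05 / m
  list(exact = exact, reported = signif(exact, 1), m = as.integer(m))
}

#' Select trait-outcome pairs for Mendelian randomization
#'
#' Applies the escalation rules to screening results: a combined-sexes hit
#' (p below the family's exact Bonferroni threshold) yields a combined MR
#' task; a hit in either sex yields MR tasks for BOTH sexes so heterogeneity
#' can be assessed; smoking-status tasks are always emitted for every trait
#' and stratum, regardless of p.
#'
#' @param results Data frame with columns `trait`, `outcome`, `stratum`,
#'   `p`, `family`.
#' @param families Named list or vector mapping family name to its number of
#'   comparisons `m`.
#' @param smoking_outcome Outcome label treated as the always-on smoking
#'   analysis.
#' @return Data frame of MR tasks: `trait`, `outcome`, `stratum`.
#' @export
screen_for_mr <- function(results, families, smoking_outcome = "smoking") {
  if (is.list(families)) families <- unlist(families)
  if (any(!results$family %in% names(families)))
    stop("result(s) reference an unknown test family")
  thr <- 0.05 / families[results$family]
  hit <- !is.na(results$p) & results$p < thr
  tasks <- list()
  for (key in unique(paste(results$trait, results$outcome, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    tr <- parts[1]; oc <- parts[2]
    sel <- results$trait == tr & results$outcome == oc
    strata <- character()
    if (oc == smoking_outcome) {
      strata <- unique(results$stratum[sel])
    } else {
      if (any(hit[sel] & results$stratum[sel] == "combined"))
        strata <- c(strata, "combined")
      if (any(hit[sel] & results$stratum[sel] %in% c("women", "men")))
        strata <- c(strata, "women", "men")
    }
    if (length(strata))
      tasks[[key]] <- data.frame(trait = tr, outcome = oc,
                                 stratum = unique(strata),
                                 stringsAsFactors = FALSE)
  }
  if (!length(tasks))
    return(data.frame(trait = character(), outcome = character(),
                      stratum = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, tasks)
  rownames(out) <- NULL
  out
}

#' Collect association results into a table
#'
#' @param results List of `assoc_result` objects.
#' @return Data frame with one row per result (outcome, trait, stratum, beta,
#'   se, p, n, n_case, n_control, type).
#' @export
assoc_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(outcome = r$outcome, trait = r$trait, stratum = r$stratum,
               beta = r$beta, se = r$se, p = r$p, n = r$n,
               n_case = r$n_case, n_control = r$n_control, type = r$type,
               stringsAsFactors = FALSE)))
}
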