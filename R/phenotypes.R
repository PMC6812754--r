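#' Correct measured blood pressure for antihypertensive medication
#'
#' Adds 15 mmHg to systolic and 10 mmHg to diastolic blood pressure for
#' individuals on blood-pressure-lowering medication, the standard correction
#' used in blood-pressure GWAS; unmedicated values pass through unchanged.
#'
#' @param sbp,dbp Measured systolic/diastolic blood pressure, mmHg (positive).
#' @param on_medication Logical vector flagging medication use; `NA` treated
#'   as unmedicated.
#' @return List with `sbp_adj` and `dbp_adj`.
#' @export
adjust_blood_pressure <- function(sbp, dbp, on_medication) {
  if (any(sbp <= 0, na.rm = TRUE) || any(dbp <= 0, na.rm = TRUE))
    stop("blood pressure values must be positive")
  med <- !is.na(on_medication) & as.logical(on_medication)
  list(sbp_adj = sbp + 15 * med, dbp_adj = dbp + 10 * med)
}

#' Residualize a trait on covariates and apply the rank inverse-normal
#' transformation
#'
#' Regresses the trait on the covariates by least squares, ranks the
#' residuals (average ranks for ties), and maps rank `r` among `n`
#' non-missing values to `qnorm((r - 0.5) / n)` (the rankit offset). A column
#' named `age` additionally contributes an `age^2` term; factor covariates
#' enter as indicator contrasts with the most frequent level as reference.
#' Rows with a missing trait or covariate are dropped from the
#' standardization and returned as `NA` (complete-case).
#'
#' @param y Numeric trait vector.
#' @param covariates Optional data frame of covariates (for the combined
#'   stratum include `sex`; include `bmi` only when standardizing a
#'   BMI-adjusted trait).
#' @return Numeric vector, same length as `y`, with mean ~0 and SD ~1 over
#'   the non-missing entries.
#' @export
residualize_rint <- function(y, covariates = NULL) {
  ok <- !is.na(y)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(y))
    ok <- ok & stats::complete.cases(covariates)
  }
  n <- sum(ok)
  if (n < 10) stop("need at least 10 non-missing values")
  yy <- y[ok]
  if (stats::var(yy) == 0) stop("trait is constant")
  if (is.null(covariates)) {
    res <- yy - mean(yy)
  } else {
    cc <- covariates[ok, , drop = FALSE]
    if ("age" %in% names(cc)) cc$age_sq <- as.numeric(cc$age)^2
    x <- .build_design(cc, n)
    qx <- qr(x)
    if (qx$rank < ncol(x))
      warning("singular covariate design; ",
              ncol(x) - qx$rank, " column(s) dropped")
    fit <- stats::lm.fit(x[, qx$pivot[seq_len(qx$rank)], drop = FALSE], yy)
    res <- fit$residuals
  }
  r <- rank(res, ties.method = "average")
  out <- rep(NA_real_, length(y))
  out[ok] <- stats::qnorm((r - 0.5) / n)
  out
}

#' Derive ever-smoker status from coded questionnaire fields
#'
#' True if any of the three smoking code fields carries code 1 or 2 (current
#' or previous smoking); missing fields are ignored, and an individual with
#' all three fields missing is returned as `NA`.
#'
#' @param code_field_1239,code_field_1249,code_field_20116 Integer code
#'   vectors (may contain `NA`).
#' @return Logical vector.
#' @export
derive_smoking_status <- function(code_field_1239, code_field_1249,
                                  code_field_20116) {
  codes <- cbind(code_field_1239, code_field_1249, code_field_20116)
  hit <- codes == 1L | codes == 2L
  any_hit <- apply(hit, 1, function(z) any(z, na.rm = TRUE))
  all_na <- apply(codes, 1, function(z) all(is.na(z)))
  any_hit[all_na] <- NA
  unname(any_hit)
}

#' Resolve an outcome status column into case and control index sets
#'
#' Individuals labelled `excluded` appear in neither group (control-group
#' exclusions are applied after case definition, upstream of this function).
#'
#' @param status Character/factor vector with values `case`, `control`,
#'   `excluded`.
#' @return List with `case` and `control` integer index vectors and `counts`.
#' @export
resolve_outcome <- function(status) {
  status <- as.character(status)
  bad <- setdiff(unique(status[!is.na(status)]),
                 c("case", "control", "excluded"))
  if (length(bad)) stop("unknown status label(s): ", paste(bad, collapse = ", "))
  case <- which(status == "case")
  control <- which(status == "control")
  if (length(control) == 0) stop("no controls")
  if (length(case) == 0) stop("no cases")
  list(case = case, control = control,
       counts = c(case = length(case), control = length(control),
                  excluded = sum(status == "excluded", na.rm = TRUE)))
}
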