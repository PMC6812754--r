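#' Read and write the package's tab-delimited interchange formats
#'
#' Summary statistics, phenotype tables, instrument (scoring) files, and LD
#' pair tables are plain tab-delimited text with a header row and `NA` for
#' missing values. Dosage matrices are whitespace-delimited text (individuals
#' in rows, variants in columns) with a sidecar variant list naming the
#' columns.
#'
#' @param x Object to write.
#' @param path File path.
#' @return Readers return a data frame (or matrix for dosages); writers return
#'   `path` invisibly.
#' @name sexmr-io
NULL

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname sexmr-io
#' @export
write_sumstats <- function(x, path) .write_tsv(x, path)

#' @rdname sexmr-io
#' @export
read_sumstats <- function(path) {
  x <- .read_tsv(path)
  need <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("summary statistics file lacks columns: ", paste(miss, collapse = ", "))
  x
}

#' @rdname sexmr-io
#' @export
write_cohort <- function(x, path) .write_tsv(x, path)

#' @rdname sexmr-io
#' @export
read_cohort <- function(path) .read_tsv(path)

#' @rdname sexmr-io
#' @export
write_dosages <- function(x, path) {
  writeLines(colnames(x), paste0(path, ".variants"))
  utils::write.table(x, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname sexmr-io
#' @export
read_dosages <- function(path) {
  ids <- readLines(paste0(path, ".variants"))
  d <- as.matrix(utils::read.table(path, header = FALSE,
                                   colClasses = "numeric"))
  dimnames(d) <- list(NULL, ids)
  d
}

#' @rdname sexmr-io
#' @export
write_instrument <- function(x, path) {
  stopifnot(inherits(x, "instrument_set"))
  out <- x$variants[, c("variant_id", "effect_allele", "other_allele", "weight")]
  out$source_stratum <- x$stratum
  .write_tsv(out, path)
}

#' Read an additive dosage matrix from a VCF file
#'
#' Uses the `DS` (posterior dosage) FORMAT field when present, otherwise
#' counts ALT alleles from `GT`. Columns are named by the VCF `ID` field;
#' the dosage counts the ALT allele, so summary statistics fed to the
#' instrument builder should carry ALT as the effect allele (or declare the
#' counted allele to [score_individuals()]).
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @return Numeric matrix, individuals in rows, variants in columns.
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF ingestion requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- v@fix[, "ID"]
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  if ("DS" %in% fmt) {
    d <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    d <- matrix(vapply(gt, function(g) {
      if (is.na(g)) return(NA_real_)
      sum(strsplit(g, "[/|]")[[1]] == "1")
    }, numeric(1)), nrow = nrow(gt), dimnames = dimnames(gt))
  }
  d <- t(d)
  colnames(d) <- ids
  rownames(d) <- NULL
  d
}

#' @rdname sexmr-io
#' @export
read_ld_pairs <- function(path) {
  x <- .read_tsv(path)
  miss <- setdiff(c("id_a", "id_b", "r2"), names(x))
  if (length(miss))
    stop("LD pair file lacks columns: ", paste(miss, collapse = ", "))
  x
}
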