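# SNP quality control: call-rate and minor-allele-frequency filters with
# strict thresholds, plus mean imputation of the surviving missing dosages.

#' Filter SNPs on call rate and minor allele frequency
#'
#' A SNP is removed iff its call rate is strictly below
#' \code{min_call_rate} or its minor allele frequency (computed on
#' non-missing dosages) is strictly below \code{min_maf}. Column order is
#' preserved. A GenTrain-style intensity filter cannot be computed from
#' dosages; an externally supplied keep-mask can be passed instead.
#'
#' @param geno a \code{genotypes} object.
#' @param min_call_rate minimum fraction of called genotypes per SNP.
#' @param min_maf minimum minor allele frequency.
#' @param keep_mask optional logical vector (one per SNP) of externally
#'   computed filters (e.g. chip quality scores); \code{FALSE} drops the SNP.
#' @return list with elements \code{genotypes} (filtered) and \code{report}
#'   (class \code{qc_report}).
#' @export
filter_snps <- function(geno, min_call_rate = 0.95, min_maf = 0.01,
                        keep_mask = NULL) {
  stopifnot(inherits(geno, "genotypes"))
  if (min_call_rate < 0 || min_call_rate > 1 || min_maf < 0 || min_maf > 1)
    stop("thresholds must lie in [0, 1]")
  d <- geno$dosage
  if (ncol(d) == 0L || nrow(d) == 0L) stop("empty genotype matrix")

  called <- colMeans(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # SNPs with zero calls

  fail_cr <- called < min_call_rate
  fail_maf <- maf < min_maf
  fail_mask <- if (is.null(keep_mask)) rep(FALSE, ncol(d)) else !keep_mask
  keep <- !(fail_cr | fail_maf | fail_mask)

  report <- structure(list(
    n_input = ncol(d),
    n_fail_call_rate = sum(fail_cr),
    n_fail_maf = sum(fail_maf),
    n_fail_both = sum(fail_cr & fail_maf),
    n_fail_mask = sum(fail_mask),
    n_removed = sum(!keep),
    n_retained = sum(keep),
    min_call_rate = min_call_rate,
    min_maf = min_maf
  ), class = "qc_report")

  if (report$n_retained == 0L)
    warning("all SNPs removed by QC filters")

  out <- genotypes(d[, keep, drop = FALSE], geno$map[keep, , drop = FALSE],
                   imputed = if (!is.null(geno$imputed))
                     geno$imputed[, keep, drop = FALSE])
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.qc_report <- function(x, ...) {
  c(sprintf("SNP quality control (call rate >= %.3g, MAF >= %.3g)",
            x$min_call_rate, x$min_maf),
    sprintf("  input SNPs        : %d", x$n_input),
    sprintf("  failed call rate  : %d", x$n_fail_call_rate),
    sprintf("  failed MAF        : %d", x$n_fail_maf),
    sprintf("  failed both       : %d", x$n_fail_both),
    sprintf("  failed ext. mask  : %d", x$n_fail_mask),
    sprintf("  retained          : %d", x$n_retained))
}

#' Serialize a QC report to JSON
#' @param x a \code{qc_report}.
#' @param path optional file to write to.
#' @return the JSON string, invisibly if written to file.
#' @export
qc_report_json <- function(x, path = NULL) {
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Mean-impute missing dosages
#'
#' Each missing dosage is replaced by the SNP's mean dosage among called
#' individuals; imputed entries are flagged in the \code{imputed} matrix of
#' the result. Errors if any SNP has no called genotype (such SNPs should
#' have been removed by \code{\link{filter_snps}}).
#'
#' @param geno a \code{genotypes} object.
#' @return a \code{genotypes} object with no missing entries.
#' @export
impute_missing <- function(geno) {
  stopifnot(inherits(geno, "genotypes"))
  d <- geno$dosage
  miss <- is.na(d)
  if (!any(miss)) return(geno)
  ncalled <- colSums(!miss)
  if (any(ncalled == 0L))
    stop("SNP(s) with zero called genotypes; filter before imputing")
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(miss, arr.ind = TRUE)
  d[miss] <- mu[idx[, 2]]
  out <- geno
  out$dosage <- d
  out$imputed <- miss
  # imputed dosages are continuous; skip the 0/1/2 revalidation
  out
}
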