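#' Validate a call set against a gold-standard truth set
#'
#' Both sets are first restricted to the confident regions. A call is a
#' true positive iff a truth record matches it exactly on (contig, position,
#' ref, alt) — and, by default, on genotype class as well; otherwise it is a
#' false positive. Truth records with no matching call are false negatives.
#' Duplicate records (possible after multi-allelic decomposition) count
#' once, so `tp + fp` equals the call count N. Specificity is not reported:
#' true negatives are ill-defined for variant calling without a site
#' universe.
#'
#' @param calls,truth Variant record data frames (see [read_snvs()]). Truth
#'   records must all carry non-reference genotypes.
#' @param confident Region data frame ([read_regions()]); must be
#'   non-empty.
#' @param genotype_aware Require genotype-class identity for a match
#'   (default `TRUE`)? With `FALSE`, matching is on site and alleles only.
#' @param stats Optional [compute_stats()] row to attach.
#' @return List of class `validation_report`: `tp`, `fp`, `fn`, `ppv`,
#'   `sensitivity`, `stats`.
#' @export
match_variants <- function(calls, truth, confident, genotype_aware = TRUE,
                           stats = NULL) {
  if (is.null(confident) || nrow(confident) == 0) {
    stop("empty confident-region set: nothing is comparable")
  }
  calls <- restrict_to_regions(calls, confident)
  truth <- restrict_to_regions(truth, confident)
  if (any(!truth$genotype %in% c("het", "hom_alt"))) {
    stop("truth records must all have non-reference genotypes")
  }
  key <- function(r) {
    base <- paste(norm_contig(r$contig), r$pos, r$ref, r$alt, sep = "\r")
    if (genotype_aware) paste(base, r$genotype, sep = "\r") else base
  }
  ck <- unique(key(calls))
  tk <- unique(key(truth))
  tp <- sum(ck %in% tk)
  fp <- length(ck) - tp
  fn <- length(tk) - tp
  structure(list(
    tp = tp, fp = fp, fn = fn,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    stats = stats), class = "validation_report")
}

#' @method print validation_report
#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report: TP =", x$tp, " FP =", x$fp, " FN =", x$fn, "\n")
  cat("  PPV =", format(x$ppv, digits = 6),
      "  sensitivity =", format(x$sensitivity, digits = 6), "\n")
  invisible(x)
}

#' Positive predictive value from TP/FP counts
#'
#' `PPV = TP / (TP + FP)`, the proportion of called variants that are true.
#'
#' @param tp,fp Non-negative counts with `tp + fp > 0`.
#' @return Proportion in `[0, 1]`.
#' @examples
#' ppv_from_counts(35600, 2027) # about 0.9461
#' @export
ppv_from_counts <- function(tp, fp) {
  stopifnot(tp >= 0, fp >= 0)
  if (tp + fp == 0) stop("PPV undefined: tp + fp = 0")
  tp / (tp + fp)
}

#' Turn a validation report into a training-table row
#'
#' @param report A [match_variants()] report whose `stats` slot is set.
#' @return One-row data frame with `y` (= TP), `n` (= TP + FP) and the
#'   call-set statistics columns, appendable into a training table.
#' @export
as_training_row <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  if (is.null(report$stats)) stop("report carries no call-set statistics")
  cbind(data.frame(y = report$tp, n = report$tp + report$fp),
        as.data.frame(report$stats))
}
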