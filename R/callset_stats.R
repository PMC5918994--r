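#' Classify a single-base substitution as transition or transversion
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine swaps
#' (A<->G, C<->T); the other eight ordered substitutions are transversions.
#'
#' @param ref,alt Single bases in `{A, C, G, T}` with `ref != alt`;
#'   vectorized.
#' @return Character vector, `"transition"` or `"transversion"`.
#' @examples
#' classify_substitution("A", "G") # transition
#' classify_substitution("C", "A") # transversion
#' @export
classify_substitution <- function(ref, alt) {
  k <- max(length(ref), length(alt))
  ref <- rep_len(as.character(ref), k); alt <- rep_len(as.character(alt), k)
  if (any(!ref %in% c("A", "C", "G", "T")) ||
      any(!alt %in% c("A", "C", "G", "T"))) {
    stop("bases must be one of A, C, G, T")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  ifelse((ref %in% c("A", "G") & alt %in% c("A", "G")) |
         (ref %in% c("C", "T") & alt %in% c("C", "T")),
         "transition", "transversion")
}

#' Summary quality statistics of an SNV call set
#'
#' Computes the predictor statistics used by the PPV model from a filtered
#' record set: the number of non-reference calls N, the
#' transition/transversion ratio Ti/Tv, the heterozygous/homozygous-alt
#' ratio Het/Hom, the median depth, and the fraction of calls with depth
#' below 5. Records with genotype `hom_ref` or `missing` are excluded from
#' N and from every statistic.
#'
#' @param records Variant record data frame (see [read_snvs()]).
#' @param wes_indicator 1 for a whole-exome call set, 0 for whole-genome.
#' @param kit_label,caller_label Optional labels carried through to the
#'   training table (e.g. `"WES-Nextera"`, `"Samtools"`).
#' @return A one-row data frame of class `callset_stats` with columns
#'   `n_calls`, `titv`, `hethom`, `med_dp`, `dp_lt5`, `wes_indicator`,
#'   `kit_label`, `caller_label`.
#' @examples
#' rec <- data.frame(contig = "1", pos = 1:3, ref = "A",
#'                   alt = c("G", "G", "C"),
#'                   genotype = c("het", "het", "hom_alt"),
#'                   qual = 50, depth = c(3, 5, 7))
#' compute_stats(rec, wes_indicator = 0)
#' @export
compute_stats <- function(records, wes_indicator, kit_label = NA_character_,
                          caller_label = NA_character_) {
  stopifnot(wes_indicator %in% c(0, 1))
  rec <- records[records$genotype %in% c("het", "hom_alt"), , drop = FALSE]
  if (nrow(rec) == 0) {
    stop("no records with a non-reference genotype; statistics undefined")
  }
  cls <- classify_substitution(rec$ref, rec$alt)
  n_tv <- sum(cls == "transversion")
  if (n_tv == 0) stop("undefined statistic 'titv': no transversions")
  n_hom <- sum(rec$genotype == "hom_alt")
  if (n_hom == 0) stop("undefined statistic 'hethom': no hom_alt calls")
  out <- data.frame(
    n_calls = nrow(rec),
    titv = sum(cls == "transition") / n_tv,
    hethom = sum(rec$genotype == "het") / n_hom,
    med_dp = stats::median(rec$depth),
    dp_lt5 = mean(rec$depth < 5),
    wes_indicator = wes_indicator,
    kit_label = kit_label,
    caller_label = caller_label)
  class(out) <- c("callset_stats", class(out))
  out
}
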