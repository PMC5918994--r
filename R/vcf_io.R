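#' Filtering rules for reading an SNV call list
#'
#' @param min_qual Optional QUAL threshold; records with QUAL below it are
#'   dropped (a missing QUAL, `"."`, counts as 0 and fails any positive
#'   threshold).
#' @param min_dp Optional depth threshold (depth taken from the sample
#'   FORMAT `DP`, falling back to INFO `DP`, else 0).
#' @param contigs Optional allowed-contig set, e.g. `c(1:22, "X")`.
#' @param regions Optional region data frame from [read_regions()].
#' @param require_nonref Keep only records whose genotype differs from the
#'   reference (het or hom_alt)?
#' @param normalize_contigs Strip a leading `"chr"` when comparing contig
#'   names between VCF, BED and the allowed set? If `FALSE`, a chr-prefix
#'   style mismatch is an error.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(min_qual = NULL, min_dp = NULL, contigs = NULL,
                        regions = NULL, require_nonref = FALSE,
                        normalize_contigs = TRUE) {
  structure(list(min_qual = min_qual, min_dp = min_dp,
                 contigs = if (!is.null(contigs)) as.character(contigs),
                 regions = regions, require_nonref = require_nonref,
                 normalize_contigs = normalize_contigs),
            class = "filter_spec")
}

norm_contig <- function(x) sub("^chr", "", as.character(x))

#' Read and filter SNV records from a VCF file
#'
#' Parses a VCF v4.x call list, decomposes multi-allelic sites into one
#' record per alternate allele, keeps only biallelic single-nucleotide
#' substitutions (indels and symbolic alleles are dropped), and applies the
#' QUAL / depth / contig / region / non-reference-genotype filters. VCF
#' positions are 1-based; a record at position `p` falls inside a 0-based
#' half-open BED region `(start, end)` iff `start <= p - 1 < end`.
#'
#' @param vcf_source Path to a VCF file (plain or bgzipped).
#' @param filters A [filter_spec()].
#' @return Data frame of variant records: `contig`, `pos`, `ref`, `alt`,
#'   `genotype` (one of `"het"`, `"hom_alt"`, `"hom_ref"`, `"missing"`),
#'   `qual`, `depth`.
#' @export
read_snvs <- function(vcf_source, filters = filter_spec()) {
  stopifnot(inherits(filters, "filter_spec"))
  validate_vcf_lines(vcf_source)
  rec <- parse_vcf_records(vcf_source)
  if (nrow(rec) == 0) return(rec)

  if (!is.null(filters$contigs)) {
    want <- if (filters$normalize_contigs) norm_contig(filters$contigs)
            else filters$contigs
    have <- if (filters$normalize_contigs) norm_contig(rec$contig)
            else rec$contig
    rec <- rec[have %in% want, , drop = FALSE]
  }
  if (!is.null(filters$regions)) {
    rec <- restrict_to_regions(rec, filters$regions,
                               normalize = filters$normalize_contigs)
  }
  if (!is.null(filters$min_qual)) {
    rec <- rec[rec$qual >= filters$min_qual, , drop = FALSE]
  }
  if (!is.null(filters$min_dp)) {
    rec <- rec[rec$depth >= filters$min_dp, , drop = FALSE]
  }
  if (isTRUE(filters$require_nonref)) {
    rec <- rec[rec$genotype %in% c("het", "hom_alt"), , drop = FALSE]
  }
  rownames(rec) <- NULL
  rec
}

# cheap structural check so a malformed line is reported with its number
validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (!nzchar(l) || startsWith(l, "#")) next
    nf <- length(strsplit(l, "\t", fixed = TRUE)[[1]])
    if (nf < 8) {
      stop("malformed VCF line ", i, ": expected >= 8 tab-separated fields, ",
           "found ", nf)
    }
  }
  invisible(length(lines))
}

parse_vcf_records <- function(path) {
  empty <- data.frame(contig = character(), pos = integer(),
                      ref = character(), alt = character(),
                      genotype = character(), qual = numeric(),
                      depth = numeric())
  lines <- readLines(path, warn = FALSE)
  if (!any(!startsWith(lines[nzchar(lines)], "#"))) return(empty)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (nrow(fix) == 0) return(empty)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  qual[is.na(qual)] <- 0  # "." -> 0: missing quality cannot pass a filter
  info_dp <- suppressWarnings(as.numeric(
    sub(".*;DP=([0-9]+).*", "\\1", paste0(";", fix[, "INFO"]))))
  gt_str <- rep(NA_character_, nrow(fix))
  fmt_dp <- rep(NA_real_, nrow(fix))
  if (ncol(vcf@gt) >= 2) {
    fmt <- strsplit(vcf@gt[, 1], ":", fixed = TRUE)
    smp <- strsplit(vcf@gt[, 2], ":", fixed = TRUE)
    for (i in seq_len(nrow(fix))) {
      gi <- match("GT", fmt[[i]]); di <- match("DP", fmt[[i]])
      if (!is.na(gi) && gi <= length(smp[[i]])) gt_str[i] <- smp[[i]][gi]
      if (!is.na(di) && di <= length(smp[[i]])) {
        fmt_dp[i] <- suppressWarnings(as.numeric(smp[[i]][di]))
      }
    }
  }
  depth <- ifelse(is.na(fmt_dp), info_dp, fmt_dp)
  depth[is.na(depth)] <- 0

  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ref <- fix[i, "REF"]
    if (is.na(ref) || !ref %in% c("A", "C", "G", "T")) next
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    keep_alt <- which(alts %in% c("A", "C", "G", "T") & alts != ref)
    if (!length(keep_alt)) next
    out[[i]] <- data.frame(
      contig = unname(fix[i, "CHROM"]),
      pos = as.integer(unname(fix[i, "POS"])),
      ref = unname(ref), alt = alts[keep_alt],
      genotype = unname(vapply(keep_alt, function(k)
        classify_genotype(gt_str[i], k), character(1))),
      qual = qual[i], depth = depth[i], row.names = NULL)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# genotype class of a diploid GT string w.r.t. alt allele index k;
# any missing allele makes the whole genotype "missing"
classify_genotype <- function(gt, k) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  al <- strsplit(gt, "[/|]")[[1]]
  if (length(al) != 2 || any(al == ".")) return("missing")
  hits <- sum(al == as.character(k))
  if (hits == 2) "hom_alt" else if (hits == 1) "het" else "hom_ref"
}

restrict_to_regions <- function(rec, regions, normalize = TRUE) {
  if (nrow(regions) == 0) return(rec[0, , drop = FALSE])
  rcon <- rec$contig; bcon <- regions$contig
  if (normalize) {
    rcon <- norm_contig(rcon); bcon <- norm_contig(bcon)
  } else if (!any(rcon %in% bcon) &&
             any(norm_contig(rcon) %in% norm_contig(bcon))) {
    stop("contig naming mismatch between VCF and BED (chr prefix); ",
         "enable contig normalization or harmonize the files")
  }
  keep <- logical(nrow(rec))
  for (ct in unique(bcon)) {
    ir <- IRanges::IRanges(start = regions$start[bcon == ct] + 1,
                           end = regions$end[bcon == ct])
    idx <- which(rcon == ct)
    if (!length(idx)) next
    qr <- IRanges::IRanges(start = rec$pos[idx], width = 1)
    keep[idx] <- IRanges::overlapsAny(qr, ir)
  }
  rec[keep, , drop = FALSE]
}

#' Read target regions from a BED file
#'
#' Reads a 3+ column BED (0-based half-open) and returns per-contig merged,
#' sorted, non-overlapping intervals.
#'
#' @param bed_source Path to a BED file.
#' @return Data frame with `contig`, `start` (0-based inclusive), `end`
#'   (0-based exclusive).
#' @export
read_regions <- function(bed_source) {
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer())
  lines <- readLines(bed_source, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, integer(1)) < 3)) {
    stop("BED requires at least 3 columns")
  }
  contig <- vapply(parts, `[[`, character(1), 1)
  start_c <- vapply(parts, `[[`, character(1), 2)
  end_c <- vapply(parts, `[[`, character(1), 3)
  if (any(!grepl("^[0-9]+$", c(start_c, end_c)))) {
    stop("non-integer BED coordinates")
  }
  start <- as.integer(start_c); end <- as.integer(end_c)
  if (any(start >= end)) stop("BED interval with start >= end")
  merge_regions(data.frame(contig = contig, start = start, end = end))
}

#' Merge regions into sorted non-overlapping intervals
#'
#' @param regions Data frame with `contig`, `start`, `end` (0-based
#'   half-open). Adjacent/overlapping intervals on one contig are merged.
#' @return Merged region data frame; idempotent.
#' @export
merge_regions <- function(regions) {
  out <- lapply(sort(unique(regions$contig)), function(ct) {
    r <- regions[regions$contig == ct, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = r$start + 1, end = r$end))
    data.frame(contig = ct, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir))
  })
  res <- do.call(rbind, c(out, list(regions[0, c("contig", "start", "end")])))
  rownames(res) <- NULL
  res
}
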