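# in-code fixtures: everything is generated at test time

# a hand-built VCF exercising contig, indel, multi-allelic, QUAL and
# genotype cases; returns the file path
toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT:DP\t0/1:20",
    "chr1\t200\t.\tC\tT\t10\tPASS\t.\tGT:DP\t1/1:3",
    "chrY\t300\t.\tG\tA\t60\tPASS\t.\tGT:DP\t0/1:15",
    "chr1\t400\t.\tT\tTA\t70\tPASS\t.\tGT:DP\t0/1:22",
    "chr1\t500\t.\tG\tA,C\t40\tPASS\t.\tGT:DP\t1/2:18",
    "chr1\t600\t.\tA\tC\t90\tPASS\t.\tGT:DP\t0/0:30",
    "chr1\t700\t.\tC\tG\t.\tPASS\tDP=9\tGT\t0/1"
  ), path)
  path
}

toy_records <- function(n_ti = 6, n_tv = 2, n_het = 4, n_hom = 4,
                        depths = NULL, contig = "1") {
  n <- n_ti + n_tv
  stopifnot(n_het + n_hom == n)
  ref <- c(rep("A", n_ti), rep("C", n_tv))
  alt <- c(rep("G", n_ti), rep("A", n_tv))
  if (is.null(depths)) depths <- rep(20, n)
  data.frame(contig = contig, pos = seq_len(n) * 10L, ref = ref, alt = alt,
             genotype = rep(c("het", "hom_alt"), c(n_het, n_hom)),
             qual = 50, depth = depths)
}

# compact, strongly identified generating model for fast fitting tests
small_config <- function(n_obs = 300, seed = 1, gamma = c(-5), ...) {
  sim_config(n_obs = n_obs, seed = seed,
             spec = bb_spec(c("1", "titv", "med_dp"), "1"),
             beta = c(2.5, 1.2, -0.01), gamma = gamma,
             n_range = c(2000, 20000), ...)
}
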