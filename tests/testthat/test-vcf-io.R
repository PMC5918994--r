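test_that("SNV reading keeps biallelic substitutions on allowed contigs", {
  path <- toy_vcf()
  rec <- read_snvs(path, filter_spec(contigs = c(1:22, "X")))
  expect_false(any(grepl("Y", rec$contig)))
  expect_false(any(nchar(rec$ref) != 1 | nchar(rec$alt) != 1))
  # insertion at 400 dropped; chrY at 300 dropped; multi-allelic site at 500
  # decomposes into two SNV records
  expect_equal(sort(rec$pos), c(100, 200, 500, 500, 600, 700))

  # QUAL threshold: "." counts as 0
  rec <- read_snvs(path, filter_spec(min_qual = 30, contigs = c(1:22, "X")))
  expect_true(all(rec$qual >= 30))
  expect_false(700 %in% rec$pos)
  # depth filter falls back to INFO DP (pos 700 carries DP=9)
  rec <- read_snvs(path, filter_spec(min_dp = 5))
  expect_true(700 %in% rec$pos)
  expect_false(200 %in% rec$pos) # FORMAT DP 3
  # non-reference genotype requirement drops the 0/0 record
  rec <- read_snvs(path, filter_spec(require_nonref = TRUE))
  expect_false(600 %in% rec$pos)
})

test_that("multi-allelic decomposition classifies genotype per alt", {
  rec <- read_snvs(toy_vcf())
  at500 <- rec[rec$pos == 500, ]
  expect_equal(nrow(at500), 2) # G>A and G>C from a 1/2 genotype
  expect_equal(sort(at500$alt), c("A", "C"))
  expect_equal(at500$genotype, c("het", "het"))
})

test_that("filtering is monotone in the QUAL and DP thresholds", {
  path <- toy_vcf()
  n_q <- vapply(c(0, 10, 40, 60, 100), function(q)
    nrow(read_snvs(path, filter_spec(min_qual = q))), integer(1))
  expect_true(all(diff(n_q) <= 0))
  n_d <- vapply(c(0, 3, 10, 25), function(d)
    nrow(read_snvs(path, filter_spec(min_dp = d))), integer(1))
  expect_true(all(diff(n_d) <= 0))
})

test_that("region restriction uses 0-based half-open BED against 1-based POS", {
  path <- tempfile(fileext = ".vcf")
  recs <- data.frame(contig = "1", pos = c(10L, 11L, 20L, 21L),
                     ref = "A", alt = "G", genotype = "het", qual = 50,
                     depth = 10)
  write_vcf(recs, path)
  reg <- data.frame(contig = "1", start = 10L, end = 20L)
  kept <- read_snvs(path, filter_spec(regions = reg))
  # pos p is inside iff start <= p - 1 < end: 11..20 in, 10 and 21 out
  expect_equal(kept$pos, c(11L, 20L))

  # whole-contig region is the identity
  all_reg <- data.frame(contig = "1", start = 0L, end = 1000L)
  expect_equal(read_snvs(path, filter_spec(regions = all_reg)),
               read_snvs(path))
})

test_that("contig-name normalization bridges chr-prefixed styles", {
  path <- toy_vcf() # contigs named chr1, chrY
  reg <- data.frame(contig = "1", start = 0L, end = 1000L)
  kept <- read_snvs(path, filter_spec(regions = reg))
  expect_true(all(kept$pos %in% c(100, 200, 500, 600, 700)))
  expect_error(
    read_snvs(path, filter_spec(regions = reg, normalize_contigs = FALSE)),
    "chr prefix")
})

test_that("malformed VCF lines are reported with their line number", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tA\tG\t50\tPASS\t.",
               "chr1\t200\tbroken line"), path)
  expect_error(read_snvs(path), "line 4")
})

test_that("BED reading validates, merges and sorts intervals", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t15\t30"), path)
  reg <- read_regions(path)
  expect_equal(reg, data.frame(contig = "chr1", start = 10L, end = 30L))

  writeLines(c("chr1\t10\t20", "chr2\t10\t20"), path)
  expect_equal(nrow(read_regions(path)), 2)

  writeLines(character(0), path)
  expect_equal(nrow(read_regions(path)), 0)

  writeLines("chr1\t20\t10", path)
  expect_error(read_regions(path), "start >= end")
  writeLines("chr1\t1.5\t10", path)
  expect_error(read_regions(path), "non-integer")
})

test_that("region merging is idempotent", {
  reg <- data.frame(contig = c("1", "1", "2"), start = c(5L, 8L, 0L),
                    end = c(10L, 20L, 4L))
  m1 <- merge_regions(reg)
  expect_equal(merge_regions(m1), m1)
})
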