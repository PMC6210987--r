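write_mini_vcf <- function(lines_body, path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=c1,length=1000>",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tPOOL",
    lines_body), path)
  path
}

test_that("VCF ingestion computes SNP% from AD and rejects out-of-scope alleles", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf("c1\t100\t.\tT\tC\t.\tPASS\t.\tDP:AD\t13:0,13", f)
  r <- read_pool_vcf(f, "AR")
  expect_equal(r$c_cnt, 13L)
  expect_equal(r$snp_pct, 1.0)
  expect_equal(r$called, "C")

  write_mini_vcf("c1\t100\t.\tT\tC\t.\tPASS\t.\tDP:AD\t10:5,5", f)
  r2 <- read_pool_vcf(f, "AR")
  expect_equal(r2$snp_pct, 0.5)
  expect_equal(r2$called, "C|T")  # het: the reference allele is retained

  write_mini_vcf("c1\t100\t.\tT\t<DEL>\t.\tPASS\t.\tDP:AD\t10:5,5", f)
  expect_error(read_pool_vcf(f, "AR"), "only SNVs and 1-bp deletions")

  write_mini_vcf("c1\t100\t.\tTAA\tT\t.\tPASS\t.\tDP:AD\t10:5,5", f)
  expect_error(read_pool_vcf(f, "AR"), "only SNVs and 1-bp deletions")

  write_mini_vcf("c1\t100\t.\tT\tC\t.\tPASS\t.\tAD\t0,13", f)
  expect_error(read_pool_vcf(f, "AR"), "missing DP")
})

test_that("anchored 1-bp deletions become deletion-marker records", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf("c1\t99\t.\tGA\tG\t.\tPASS\t.\tDP:AD\t12:0,12", f)
  r <- read_pool_vcf(f, "AR")
  expect_equal(r$pos, 100L)          # the deleted base, not the anchor
  expect_equal(r$ref, "A")
  expect_equal(r$called, "-")
  expect_equal(r$del_cnt, 12L)
})

test_that("multi-allelic rows collapse to one record carrying all counts", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf("c1\t100\t.\tT\tC,G\t.\tPASS\t.\tDP:AD\t20:2,12,6", f)
  r <- read_pool_vcf(f, "AR")
  expect_equal(nrow(r), 1)
  expect_equal(r$c_cnt, 12L)
  expect_equal(r$g_cnt, 6L)
  expect_equal(r$snp_pct, 18 / 20)
  expect_equal(called_alleles(r$called, r$ref)[[1]], c("C", "G"))
})

test_that("tabular dialect loads the 63-row fixture with conventions intact", {
  r <- table3_fixture()
  expect_equal(nrow(r), 63)
  bmx <- dplyr::filter(r, feature == "BMX")
  expect_equal(called_alleles(bmx$called, bmx$ref)[[1]], "T")
  expect_equal(bmx$c_cnt, NA_integer_)  # "-" marks the unreported ref column
  expect_true(all(r$snp_pct >= 0.75 & r$snp_pct <= 1))

  f <- withr::local_tempfile(fileext = ".tsv")
  file.create(f)
  expect_equal(nrow(suppressWarnings(read_snp_table(f))), 0)
})

test_that("tabular write/read round trip is lossless", {
  r <- table3_fixture()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_snp_table(r, f)
  r2 <- read_snp_table(f, line_label = "AR")
  expect_equal(as.data.frame(r2), as.data.frame(r))
})

test_that("variant fraction reproduces the worked SNP% examples", {
  expect_equal(variant_fraction(make_record(depth = 4, c = 3L)), 0.75)
  r <- table3_fixture()
  bmx <- dplyr::filter(r, feature == "BMX")
  expect_equal(variant_fraction(bmx), 9 / 12)              # exactly 0.75
  expect_equal(round(variant_fraction(bmx), 2), bmx$snp_pct)
  expect_equal(variant_fraction(make_record(depth = 10, c = 0L), "C"), 0)
  expect_error(variant_fraction(make_record(depth = 0L)), "positive")
  expect_error(variant_fraction(make_record(), "Z"), "invalid allele")
})

test_that("called alleles exclude the reference and keep the deletion marker", {
  expect_equal(called_alleles("T|C", "C")[[1]], "T")
  expect_equal(called_alleles("C", "T")[[1]], "C")
  expect_equal(called_alleles("G|A", "G")[[1]], "A")
  expect_equal(called_alleles("-|A", "A")[[1]], "-")
  expect_error(called_alleles("Z", "A"), "invalid")
})

test_that("SNP% discrepancies beyond rounding are flagged, never dropped", {
  r <- table3_fixture()
  fl <- flag_snp_pct_discrepancies(r)
  expect_equal(sum(fl$snp_pct_flag), 0)  # all printed values within 0.015
  bad <- make_record(depth = 10L, c = 9L, snp_pct = 0.6)
  flb <- flag_snp_pct_discrepancies(bad)
  expect_true(flb$snp_pct_flag)
  expect_equal(nrow(flb), 1)             # flagged but retained
  expect_equal(flb$snp_pct_recomputed, 0.9)
})
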