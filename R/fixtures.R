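# Packaged reference tables: the 63 reliable marker SNPs and the 8 published
# allele-specific primer trios, shipped as plain TSV under inst/extdata.

.fixture_md5 <- c(
  table3_snps.tsv = "ca94918d1fe4900c75b0981f0145a84c",
  table1_primers.tsv = "5a2b3fb94b4af1f2df442a7f23dced89"
)

.fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "linemarker")
  if (p == "") abort(paste0("packaging error: fixture '", file, "' not installed"))
  got <- unname(tools::md5sum(p))
  if (!identical(got, unname(.fixture_md5[[file]]))) {
    abort(paste0("packaging error: checksum mismatch for fixture '", file, "'"))
  }
  p
}

#' The 63 reliable marker SNPs (packaged fixture)
#'
#' The published table of 63 fixed, line-unique, amino-acid-changing SNPs of
#' the tumor-regressing line: site coordinates, reference/called bases,
#' SNP%, per-base read counts, depths, and the printed HGVS-like DNA/AA
#' change pairs. Loaded through [read_snp_table()], so all dialect
#' conventions (the `"-"` reference-column marker, `"X|Y"` heterozygous
#' calls) apply.
#'
#' @return Pooled site record tibble of 63 rows (line `"AR"`), including
#'   `dna_change` / `aa_change` columns with the printed notation pairs.
#' @export
table3_fixture <- function() {
  read_snp_table(.fixture_path("table3_snps.tsv"), line_label = "AR")
}

#' The 8 published allele-specific primer trios (packaged fixture)
#'
#' Reference-type (F1), SNP-type (F3) and common reverse (R) primers with
#' their printed annealing temperatures. The published SNP-type primer of
#' the IGSF trio is labelled "F2"; the fixture normalizes its role to F3 and
#' keeps the original label in `primer_name`.
#'
#' @return A tibble with columns `gene`, `primer_name`, `role` (F1/F3/R),
#'   `sequence`, `annealing_temp`.
#' @export
table1_fixture <- function() {
  raw <- readr::read_tsv(.fixture_path("table1_primers.tsv"),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  tibble(gene = raw$Gene, primer_name = raw$`Primer Name`, role = raw$Role,
         sequence = raw$Sequence, annealing_temp = as.numeric(raw$Annealing))
}
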