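# Hand-built miniature genomes and gene models shared across tests.

# Contig with the ORF ATG AAA TAG at 11..19 (plus strand).
toy_plus <- function() {
  genome <- ref_genome(c(c1 = paste0("CCCCCCCCCC", "ATGAAATAG", "GGGGGGGGGGG")))
  model <- tibble::tibble(gene_id = "gplus", contig = "c1", strand = "+",
                          start = 11L, end = 19L, frame_ok = TRUE)
  list(genome = genome, model = model)
}

# Same interval on the minus strand: genomic bases are the reverse
# complement of ATG AAA TAG, so the oriented CDS is a real ORF.
toy_minus <- function() {
  genome <- ref_genome(c(c1 = paste0("CCCCCCCCCC", "CTATTTCAT", "GGGGGGGGGGG")))
  model <- tibble::tibble(gene_id = "gminus", contig = "c1", strand = "-",
                          start = 11L, end = 19L, frame_ok = TRUE)
  list(genome = genome, model = model)
}

# Two-exon model: CDS segments 11..13 and 21..26 (9 nt total).
spliced_model <- function(strand = "+") {
  tibble::tibble(gene_id = "gsplice", contig = "c1", strand = strand,
                 start = c(11L, 21L), end = c(13L, 26L), frame_ok = TRUE)
}

# One pooled site record row with sensible defaults.
make_record <- function(line = "AR", contig = "c1", pos = 1L, ref = "T",
                        called = "C", depth = 10L, a = 0L, c = 0L, g = 0L,
                        t = NA_integer_, del = 0L, snp_pct = NA_real_) {
  tibble::tibble(line = line, contig = contig, pos = as.integer(pos),
                 ref = ref, called = called, depth = as.integer(depth),
                 a_cnt = a, c_cnt = c, g_cnt = g, t_cnt = t, del_cnt = del,
                 snp_pct = snp_pct)
}

# Independent protein-level oracle: annotate an in-CDS SNV by translating the
# whole mutated CDS with Biostrings and diffing against the reference
# translation (never uses the package's codon-local path).
oracle_snv <- function(cds_seq, cds_pos, cds_alt) {
  tr <- function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       no.init.codon = TRUE))
  }
  ref_p <- tr(cds_seq)
  mut <- cds_seq
  substr(mut, cds_pos, cds_pos) <- cds_alt
  mut_p <- tr(mut)
  d <- which(strsplit(ref_p, "")[[1]] != strsplit(mut_p, "")[[1]])
  residue <- (cds_pos - 1) %/% 3 + 1
  ref_aa <- substr(ref_p, residue, residue)
  alt_aa <- substr(mut_p, residue, residue)
  impact <- if (length(d) == 0) {
    "synonymous"
  } else if (alt_aa == "*" && ref_aa != "*") {
    "nonsense"
  } else if (residue == 1 && ref_aa == "M" && alt_aa != "M") {
    "no-start"
  } else if (ref_aa == "*" && alt_aa != "*") {
    "no-stop"
  } else {
    "non-synonymous"
  }
  list(residue = residue, ref_aa = ref_aa, alt_aa = alt_aa, impact = impact,
       n_changed = length(d))
}
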