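test_that("plus-strand SNV annotation substitutes the right codon", {
  tp <- toy_plus()
  # cds 4 A>G: AAA -> GAA, K2E (genomic pos 14)
  ann <- annotate_snv(14L, "A", "G", tp$model, tp$genome)
  expect_equal(ann$ref_codon, "AAA")
  expect_equal(ann$alt_codon, "GAA")
  expect_equal(ann$p_notation, "p.K2E")
  expect_equal(ann$impact, "non-synonymous")
  expect_equal(ann$c_notation, "c.4A>G")
})

test_that("minus-strand annotation complements alleles before substitution", {
  tm <- toy_minus()
  # genomic T>C at pos 16 is CDS A>G at cds 4 (offset 1 of the K codon): K2E,
  # the same strand geometry as a plus-strand table row whose ref base is T
  # but whose c. change reads A>G
  expect_equal(genome_seq(tm$genome, "c1", 16, 16), "T")
  ann <- annotate_snv(16L, "T", "C", tm$model, tm$genome)
  expect_equal(ann$cds_pos, 4L)
  expect_equal(ann$c_notation, "c.4A>G")
  expect_equal(ann$p_notation, "p.K2E")
  expect_equal(ann$impact, "non-synonymous")
})

test_that("wobble-position substitutions are synonymous", {
  g <- ref_genome(c(c1 = paste0(strrep("C", 10), "ATGCTTTAG", strrep("G", 10))))
  model <- tibble::tibble(gene_id = "g", contig = "c1", strand = "+",
                          start = 11L, end = 19L, frame_ok = TRUE)
  ann <- annotate_snv(16L, "T", "C", model, g)  # CTT -> CTC, L -> L
  expect_equal(ann$impact, "synonymous")
  expect_equal(ann$ref_aa, ann$alt_aa)
})

test_that("impact taxonomy: no-start, nonsense, no-stop, frameshift", {
  tp <- toy_plus()
  # c.2T>C destroys the initiator: p.M1T, displayed N-syn
  ann <- annotate_snv(12L, "T", "C", tp$model, tp$genome)
  expect_equal(ann$impact, "no-start")
  expect_equal(ann$p_notation, "p.M1T")
  expect_equal(ann$impact_display, "N-syn")

  # TAT -> TAG at codon offset 3 is a stop gain, rendered with trailing dot
  g <- ref_genome(c(c1 = paste0(strrep("C", 10), "ATGTATTAG", strrep("G", 10))))
  model <- tibble::tibble(gene_id = "g", contig = "c1", strand = "+",
                          start = 11L, end = 19L, frame_ok = TRUE)
  ann2 <- annotate_snv(16L, "T", "G", model, g)
  expect_equal(ann2$impact, "nonsense")
  expect_equal(ann2$p_notation, "p.Y2.")
  expect_equal(annotate_snv(16L, "T", "G", model, g, stop_char = "*")$p_notation,
               "p.Y2*")

  # destroying the stop codon: TAG -> TAC
  ann3 <- annotate_snv(19L, "G", "C", tp$model, tp$genome)
  expect_equal(ann3$impact, "no-stop")

  # single-base deletion in CDS
  ann4 <- annotate_snv(14L, "A", "-", tp$model, tp$genome)
  expect_equal(ann4$impact, "frameshift")

  expect_equal(classify_impact("K", "K", 5, "AAA", is_deletion = TRUE),
               "frameshift")
})

test_that("out-of-frame models yield the partial-CDS marker", {
  g <- ref_genome(c(c1 = paste0(strrep("C", 10), "ATGAAATAGG", strrep("G", 9))))
  model <- tibble::tibble(gene_id = "g", contig = "c1", strand = "+",
                          start = 11L, end = 20L, frame_ok = FALSE)
  ann <- annotate_snv(14L, "A", "G", model, g)
  expect_equal(ann$impact, "partial-CDS")
  expect_true(is.na(ann$p_notation))
})

test_that("HGVS-like notation covers homozygous, compound het and degenerate", {
  expect_equal(hgvs_c(934, "C", "T"), "c.934C>T")
  expect_equal(hgvs_c(1549, "G", "A", het_with_ref = TRUE),
               "c.[1549G>G]+[1549G>A]")
  expect_equal(hgvs_c(10, "G", "G"), "c.10G>G")  # degenerate identity
  expect_equal(hgvs_p("P", 312, "S"), "p.P312S")
  expect_equal(hgvs_p_compound("D", 517, "N"), "p.D517N, p.D517D")
})

test_that("printed-pair consistency checking accepts truth and rejects errors", {
  good <- check_printed_consistency(
    c("c.4640A>G", "c.1585G>T", "c.333T>G", "c.[1549G>G]+[1549G>A]"),
    c("p.K1547R", "p.A529S", "p.Y111.", "p.D517N, p.D517D"))
  expect_true(all(good$pass))

  bad <- check_printed_consistency("c.10A>G", "p.K3E")  # residue should be 4
  expect_false(bad$pass)
  expect_match(bad$reason, "residue arithmetic")

  unreach <- check_printed_consistency("c.4A>G", "p.K2W")  # no K codon gives W
  expect_false(unreach$pass)

  junk <- check_printed_consistency("c.notanumber", "p.K3E")
  expect_false(junk$pass)
  expect_match(junk$reason, "unparsable")
})

test_that("codon-local annotation matches the full-translation oracle", {
  b <- generate_genome(simulation_config(seed = 13))
  genes <- unique(b$models$gene_id)
  set.seed(99)
  n_checked <- 0
  for (i in 1:400) {
    g <- sample(genes, 1)
    model <- gene_model(b$models, g)
    cds <- cds_sequence(model, b$genome)
    cp <- sample(cds_length(model), 1)
    gp <- cds_to_genomic(model, cp)
    ref <- genome_seq(b$genome, model$contig[1], gp, gp)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    ann <- annotate_snv(gp, ref, alt, model, b$genome, cds_seq = cds)
    cds_alt <- if (model$strand[1] == "-") chartr("ACGT", "TGCA", alt) else alt
    orc <- oracle_snv(cds, cp, cds_alt)
    expect_equal(ann$residue, orc$residue)
    expect_equal(ann$ref_aa, orc$ref_aa)
    expect_equal(ann$alt_aa, orc$alt_aa)
    expect_equal(ann$impact, orc$impact)
    expect_lte(orc$n_changed, 1)  # a SNV can change at most one residue
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 400)
})

test_that("bulk annotation joins records to genes and handles het calls", {
  tp <- toy_plus()
  recs <- dplyr::bind_rows(
    make_record(pos = 14L, ref = "A", called = "G", g = 10L, a = NA_integer_,
                snp_pct = 1),
    make_record(pos = 14L, ref = "A", called = "G|A", g = 8L, a = NA_integer_,
                depth = 12L, snp_pct = 8 / 12),
    make_record(pos = 3L, ref = "C", called = "T", t = 10L, c = NA_integer_))
  ann <- annotate_variants(recs, tp$model, tp$genome)
  expect_equal(nrow(ann), 2)  # the record outside the CDS is skipped
  expect_equal(ann$c_notation[1], "c.4A>G")
  expect_equal(ann$c_notation[2], "c.[4A>A]+[4A>G]")
  expect_equal(ann$p_notation[2], "p.K2E, p.K2K")
})
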