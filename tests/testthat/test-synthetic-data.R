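test_that("genome generation is deterministic and structurally sound", {
  cfg <- simulation_config(seed = 21, n_genes = 10L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- simulate_study(cfg, dir = d1)
  b2 <- simulate_study(cfg, dir = d2)
  for (f in c("genome.fa", "genes.gff3", "manifest.tsv", "AR.vcf", "AP.vcf")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_equal(dplyr::n_distinct(b1$models$gene_id), 10)
  # every CDS is a clean ORF: starts ATG, ends a stop, no internal stop
  ct <- Biostrings::GENETIC_CODE
  for (g in unique(b1$models$gene_id)) {
    cds <- cds_sequence(gene_model(b1$models, g), b1$genome)
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    aa <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(cds))), "")[[1]]
    expect_equal(which(aa == "*"), length(aa))
  }
  # GFF3 written by the generator reloads into equivalent models
  m2 <- read_gene_models(file.path(d1, "genes.gff3"))
  expect_equal(
    as.data.frame(dplyr::arrange(m2, gene_id, start)),
    as.data.frame(dplyr::arrange(b1$models, gene_id, start)))
})

test_that("the manifest books every requested variant class, without collisions", {
  cfg <- simulation_config(seed = 8)
  sim <- generate_genome(cfg)
  man <- plant_variants(cfg, sim)
  expect_equal(nrow(man), cfg$n_unique_nonsyn + cfg$n_unique_syn + cfg$n_shared +
                 cfg$n_lowfreq + cfg$n_intergenic + cfg$n_intronic +
                 cfg$n_nonsense + cfg$n_nostart + cfg$n_nostop + cfg$n_deletion)
  expect_equal(anyDuplicated(paste(man$contig, man$pos)), 0)
  expect_equal(sum(man$impact == "nonsense", na.rm = TRUE), cfg$n_nonsense)
  expect_equal(sum(man$class == "del"), cfg$n_deletion)
  expect_equal(sum(man$region == "intergenic"), cfg$n_intergenic)
  # a start-loss variant sits within the initiator codon
  nostart <- dplyr::filter(man, impact == "no-start")
  expect_true(all(nostart$cds_pos <= 3))
  # the expected-final flag is exactly the spec'd conjunction
  expect_equal(man$expected_final,
               man$freq_a == 1 & man$freq_b == 0 & man$region == "CDS" &
                 man$impact %in% c("non-synonymous", "frameshift", "nonsense",
                                   "no-start", "no-stop") & !is.na(man$impact))
})

test_that("planted coding SNVs agree with the annotation oracle", {
  cfg <- simulation_config(seed = 9)
  sim <- generate_genome(cfg)
  man <- dplyr::filter(plant_variants(cfg, sim), class == "SNV", region == "CDS")
  for (i in seq_len(nrow(man))) {
    m <- man[i, ]
    model <- gene_model(sim$models, m$gene_id)
    cds <- cds_sequence(model, sim$genome)
    cds_alt <- if (model$strand[1] == "-") chartr("ACGT", "TGCA", m$alt) else m$alt
    orc <- oracle_snv(cds, m$cds_pos, cds_alt)
    expect_equal(orc$impact, m$impact)
  }
})

test_that("pooled counts follow the frequency model", {
  cfg0 <- simulation_config(seed = 5, error_rate = 0)
  sim <- generate_genome(cfg0)
  man <- plant_variants(cfg0, sim)
  # without sequencing error a fixed allele soaks up the whole depth
  recs <- simulate_pooled_counts(man, cfg0, sim)
  fixed <- dplyr::semi_join(recs$AR, dplyr::filter(man, freq_a == 1),
                            by = c("contig", "pos"))
  expect_true(all(fixed$snp_pct == 1))
  # binomial concentration at freq 0.5 and depth ~10000
  cfg_deep <- simulation_config(seed = 5, error_rate = 0,
                                coverage = c(AR = 10000, AP = 10000))
  man05 <- dplyr::mutate(man, freq_a = 0.5)
  deep <- simulate_pooled_counts(man05, cfg_deep, sim)
  expect_true(all(abs(deep$AR$snp_pct - 0.5) < 0.02))
})

test_that("the fixture loaders validate their packaged checksums", {
  expect_equal(nrow(table3_fixture()), 63)
  p <- table1_fixture()
  expect_setequal(unique(p$gene),
                  c("BMX", "FAM208B", "IFT140", "IGSF", "LAMB4", "PIK3R4",
                    "THADA", "TOPAZ1"))
  expect_equal(sum(p$role == "F3"), 8)  # includes the relabelled IGSF "F2"
  expect_true("IGSF-F2" %in% p$primer_name)
})
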