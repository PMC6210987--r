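test_that("Wallace rule counts letters and rejects bad alphabets", {
  expect_equal(wallace_tm("AT"), 4)
  expect_equal(wallace_tm("GAACTTACATACAGATCGTC"), 56)
  expect_equal(wallace_tm("CAATGGGACTGTGCTGAGTC"), 62)
  expect_equal(wallace_tm(c("GGGG", "AAAA")), c(16, 8))
  expect_error(wallace_tm("ACGN"), "only A, C, G, T")
  expect_error(wallace_tm(""), "non-empty")
})

test_that("annealing buckets to the member nearest the trio minimum", {
  expect_equal(anneal_bucket(c(56, 54, 60)), 55)
  expect_equal(anneal_bucket(c(62, 60, 60)), 63)
  expect_equal(anneal_bucket(59), 55)  # tie resolves low
})

test_that("the destabilizing mismatch follows the transversion rule", {
  expect_equal(substr(introduce_destabilizing_mismatch("AAAAA", "A"), 3, 3), "C")
  expect_equal(substr(introduce_destabilizing_mismatch("AAGAA", "G"), 3, 3), "T")
  expect_equal(substr(introduce_destabilizing_mismatch("AACAA", "C"), 3, 3), "A")
  expect_equal(substr(introduce_destabilizing_mismatch("AATAA", "T"), 3, 3), "G")
  # primer already carrying the primary transversion: re-substituted so the
  # result still mismatches the template
  p <- introduce_destabilizing_mismatch("AACAA", "A")  # primary A->C == current
  expect_equal(substr(p, 3, 3), "T")
  expect_error(introduce_destabilizing_mismatch("AC", "A"), "at least 3")
})

test_that("published trios differ between F1 and F3 only at the 3' terminus", {
  p <- table1_fixture()
  expect_equal(nrow(p), 24)
  trios <- split(p, p$gene)
  expect_length(trios, 8)
  for (tr in trios) {
    f1 <- tr$sequence[tr$role == "F1"]
    f3 <- tr$sequence[tr$role == "F3"]
    d <- which(strsplit(f1, "")[[1]] != strsplit(f3, "")[[1]])
    expect_equal(d, nchar(f1))
  }
})

test_that("designed trios satisfy the three allele-specific invariants", {
  b <- generate_genome(simulation_config(seed = 3))
  set.seed(4)
  n <- 200
  ctg <- sample(names(b$genome), n, replace = TRUE)
  pos <- vapply(ctg, function(cc) sample(2000:(nchar(b$genome[[cc]]) - 2000), 1), 1L)
  ref <- vapply(seq_len(n), function(i) substr(b$genome[[ctg[i]]], pos[i], pos[i]), "")
  alt <- vapply(ref, function(rr) sample(setdiff(c("A", "C", "G", "T"), rr), 1), "")
  recs <- tibble::tibble(line = "AR", contig = ctg, pos = as.integer(pos),
                         ref = ref, called = alt, depth = 12L, a_cnt = 0L,
                         c_cnt = 0L, g_cnt = 0L, t_cnt = 0L, del_cnt = 0L,
                         snp_pct = 1)
  pr <- design_primers(recs, b$genome)
  expect_true(all(!pr$failed))
  L <- nchar(pr$f1)
  orient <- function(x, st) ifelse(st == "-", chartr("ACGT", "TGCA", x), x)
  # 1: F1 and F3 identical except the 3'-terminal base
  expect_true(all(substr(pr$f1, 1, unique(L) - 1) == substr(pr$f3, 1, unique(L) - 1)))
  expect_true(all(substr(pr$f1, L, L) != substr(pr$f3, L, L)))
  # 2: termini carry the strand-oriented reference / variant alleles
  expect_true(all(substr(pr$f1, L, L) == orient(pr$ref, pr$strand)))
  expect_true(all(substr(pr$f3, L, L) == orient(pr$alt, pr$strand)))
  # 3: third-from-3' base mismatches the template in both forwards
  tmpl <- vapply(seq_len(nrow(pr)), function(i) {
    if (pr$strand[i] == "+") {
      substr(b$genome[[pr$contig[i]]], pr$pos[i] - 2, pr$pos[i] - 2)
    } else {
      chartr("ACGT", "TGCA",
             substr(b$genome[[pr$contig[i]]], pr$pos[i] + 2, pr$pos[i] + 2))
    }
  }, "")
  expect_true(all(substr(pr$f1, L - 2, L - 2) != tmpl))
  expect_true(all(substr(pr$f3, L - 2, L - 2) != tmpl))
  expect_true(all(pr$annealing_temp %in% c(55, 63)))
  expect_true(all(pr$amplicon_length >= 100 & pr$amplicon_length <= 420))
})

test_that("designs too close to a contig edge fail with a reason", {
  g <- ref_genome(c(tiny = "ACGTACGTACGTACG"))
  rec <- make_record(contig = "tiny", pos = 10L, ref = "G", called = "A",
                     a = 9L, g = NA_integer_, t = 0L, depth = 10L)
  pr <- design_primers(rec, g, strand = "+")
  expect_true(pr$failed)
  expect_match(pr$reason, "design failure")
})
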