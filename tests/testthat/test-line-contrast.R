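test_that("unique sites removes shared positions and keeps disjoint ones", {
  a <- make_record(line = "AR", pos = 100L)
  b <- make_record(line = "AP", pos = 100L)
  expect_equal(nrow(unique_sites(a, b)), 0)

  b2 <- make_record(line = "AP", pos = 200L)
  expect_equal(unique_sites(a, b2), a)

  expect_error(unique_sites(a, make_record(line = "AR", pos = 5L)),
               "distinct lines")
  mixed <- dplyr::bind_rows(a, make_record(line = "XX", pos = 7L))
  expect_error(unique_sites(mixed, b2), "single line label")
})

test_that("allele-keyed contrast only removes sites sharing an alt allele", {
  a <- make_record(line = "AR", pos = 100L, ref = "T", called = "C", c = 9L)
  b_same <- make_record(line = "AP", pos = 100L, ref = "T", called = "C", c = 9L)
  b_diff <- make_record(line = "AP", pos = 100L, ref = "T", called = "G",
                        g = 9L, c = 0L)
  expect_equal(nrow(unique_sites(a, b_same, key_mode = "allele")), 0)
  expect_equal(nrow(unique_sites(a, b_diff, key_mode = "allele")), 1)
  # position mode removes regardless of allele
  expect_equal(nrow(unique_sites(a, b_diff, key_mode = "position")), 0)
})

test_that("reciprocal unique sets are disjoint on synthetic pools", {
  b <- simulate_study(simulation_config(seed = 31))
  ua <- unique_sites(b$records$AR, b$records$AP)
  ub <- unique_sites(b$records$AP, b$records$AR)
  overlap <- dplyr::inner_join(ua, ub, by = c("contig", "pos"))
  expect_equal(nrow(overlap), 0)
  # planted truth: every shared fixed site is removed from both
  shared <- dplyr::filter(b$manifest, freq_a == 1, freq_b == 1)
  expect_equal(nrow(dplyr::semi_join(ua, shared, by = c("contig", "pos"))), 0)
})

test_that("region classification follows the documented precedence", {
  feats <- tibble::tibble(
    contig = "c1",
    type   = c("gene", "mRNA", "CDS", "CDS", "ncRNA", "tRNA"),
    start  = c(100L, 100L, 120L, 160L, 300L, 400L),
    end    = c(200L, 200L, 140L, 180L, 320L, 420L),
    strand = "+",
    gene_id = c("g1", "g1", "g1", "g1", "n1", "t1"))
  recs <- make_record(pos = 1L)[rep(1, 6), ]
  recs$pos <- c(130L, 150L, 105L, 310L, 410L, 500L)
  expect_equal(classify_region(recs, feats),
               c("CDS",            # inside a CDS segment
                 "intron",         # in mRNA, between CDS segments
                 "mRNA-noncoding", # in mRNA, outside the CDS span (UTR)
                 "ncRNA", "tRNA", "intergenic"))
})

test_that("the cascade passes all 63 fixture records under published defaults", {
  r <- table3_fixture()
  res <- apply_filter_cascade(r)
  expect_equal(nrow(res$records), 63)
  expect_true(all(res$report$n_out <= res$report$n_in))
  expect_equal(glance(res)$n_pass, 63)
})

test_that("tightening the depth threshold drops exactly the shallow rows", {
  r <- table3_fixture()
  res <- apply_filter_cascade(r, config = filter_config(depth_min = 11))
  expect_equal(nrow(res$records), 28)
  expect_true(all(res$records$depth >= 11))
})

test_that("empty input yields empty output and all-zero tallies", {
  res <- apply_filter_cascade(table3_fixture()[0, ])
  expect_equal(nrow(res$records), 0)
  expect_true(all(res$report$n_in == 0 & res$report$n_out == 0))
})

test_that("invalid thresholds fail before any work", {
  expect_error(filter_config(snp_pct_min = 1.5), "\\[0, 1\\]")
  expect_error(filter_config(depth_min = 0), ">= 1")
})

test_that("raising thresholds never increases the passing count", {
  b <- simulate_study(simulation_config(seed = 17))
  recs <- unique_sites(b$records$AR, b$records$AP)
  ann <- annotate_variants(recs, b$models, b$genome)
  recs$region <- classify_region(recs, b$features)
  set.seed(42)
  for (i in 1:8) {
    s <- sort(runif(2, 0, 1))
    d <- sort(sample(1:20, 2))
    n_loose <- nrow(apply_filter_cascade(recs, ann,
      filter_config(snp_pct_min = s[1], depth_min = d[1]))$records)
    n_tight <- nrow(apply_filter_cascade(recs, ann,
      filter_config(snp_pct_min = s[2], depth_min = d[2]))$records)
    expect_lte(n_tight, n_loose)
  }
})
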