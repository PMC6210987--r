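#' Simulation configuration for synthetic pool-seq data
#'
#' Describes the study design the generator emulates: two divergently
#' selected lines, each sequenced as one pooled library of `pool_size`
#' diploid individuals (so allele frequencies live on the `1/(2*pool_size)`
#' grid and "fixed" means all chromosomes carry the allele), with mean read
#' coverages of 11x and 14x for the focal and contrast line respectively and
#' a symmetric per-base sequencing error rate of 0.001. Planted variant
#' class counts control how many line-unique fixed non-synonymous SNVs (the
#' truth set) and how many decoys of each kind (synonymous, shared,
#' low-frequency, intronic, intergenic, stop-gain/start-loss/stop-loss,
#' 1-bp deletions) the genome carries.
#'
#' @param seed Integer master seed; every downstream draw derives from it.
#' @param n_contigs,contig_length Synthetic genome dimensions.
#' @param n_genes Total protein-coding genes, split across contigs; both
#'   strands and spliced/unspliced structures are generated.
#' @param exons_per_gene Integer range of exon counts.
#' @param cds_length_range CDS length range in nt (rounded to codons).
#' @param intron_length_range Intron length range in nt.
#' @param n_unique_nonsyn,n_unique_syn,n_shared,n_lowfreq,n_intergenic,n_intronic,n_nonsense,n_nostart,n_nostop,n_deletion
#'   Planted counts per variant class.
#' @param coverage Named mean coverages, one per line (focal line first).
#' @param error_rate Per-base sequencing error probability.
#' @param pool_size Diploid individuals per pool.
#' @param lines Two line labels, focal line first.
#' @param low_freq Pool allele frequency of the low-frequency class (on the
#'   chromosome grid).
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L, n_contigs = 2L, contig_length = 60000L,
                              n_genes = 12L, exons_per_gene = c(1L, 3L),
                              cds_length_range = c(300L, 600L),
                              intron_length_range = c(60L, 200L),
                              n_unique_nonsyn = 8L, n_unique_syn = 4L,
                              n_shared = 4L, n_lowfreq = 4L,
                              n_intergenic = 4L, n_intronic = 3L,
                              n_nonsense = 2L, n_nostart = 1L, n_nostop = 1L,
                              n_deletion = 2L,
                              coverage = c(AR = 11, AP = 14),
                              error_rate = 0.001, pool_size = 10L,
                              lines = c("AR", "AP"), low_freq = 0.25) {
  counts <- c(n_unique_nonsyn, n_unique_syn, n_shared, n_lowfreq, n_intergenic,
              n_intronic, n_nonsense, n_nostart, n_nostop, n_deletion)
  if (any(counts < 0)) abort("variant class counts must be >= 0")
  if (any(coverage <= 0)) abort("coverage must be positive")
  if (length(lines) != 2 || lines[1] == lines[2]) {
    abort("exactly two distinct line labels required")
  }
  names(coverage) <- lines
  structure(list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length), n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    cds_length_range = as.integer(cds_length_range),
    intron_length_range = as.integer(intron_length_range),
    n_unique_nonsyn = n_unique_nonsyn, n_unique_syn = n_unique_syn,
    n_shared = n_shared, n_lowfreq = n_lowfreq, n_intergenic = n_intergenic,
    n_intronic = n_intronic, n_nonsense = n_nonsense, n_nostart = n_nostart,
    n_nostop = n_nostop, n_deletion = n_deletion,
    coverage = coverage, error_rate = error_rate,
    pool_size = as.integer(pool_size), lines = lines, low_freq = low_freq
  ), class = "sim_config")
}

.stop_codons <- c("TAA", "TAG", "TGA")

#' Generate a synthetic genome with gene models
#'
#' Deterministic given `config$seed`. Genes are laid out in non-overlapping
#' territories with generous flanks (so primer windows always exist), on
#' random strands, with 1 to `max(exons_per_gene)` exons; every CDS starts
#' with ATG, ends with a stop codon, has no internal stop, and has length
#' divisible by 3.
#'
#' @param config A [simulation_config()].
#' @return A list of class `sim_genome`: `genome` (a `ref_genome`), `models`
#'   (a `gene_models` tibble) and `features` (gene/mRNA/CDS feature tibble).
#' @export
generate_genome <- function(config) {
  set.seed(config$seed)
  edge <- 1500L
  per_contig <- rep(config$n_genes %/% config$n_contigs, config$n_contigs)
  extra <- config$n_genes %% config$n_contigs
  if (extra > 0) per_contig[seq_len(extra)] <- per_contig[seq_len(extra)] + 1L
  max_span <- max(config$cds_length_range) +
    (max(config$exons_per_gene) - 1L) * max(config$intron_length_range) + 10L
  contigs <- list()
  seg_rows <- list()
  for (ci in seq_len(config$n_contigs)) {
    ctg <- paste0("ctg", ci)
    seq_chars <- sample(c("A", "C", "G", "T"), config$contig_length, replace = TRUE)
    ng <- per_contig[ci]
    if (ng > 0) {
      slot <- (config$contig_length - 2L * edge) %/% ng
      if (slot < max_span + 200L) {
        abort("contig too short for the requested number of genes")
      }
      for (gi in seq_len(ng)) {
        gene <- sprintf("gene_%d_%d", ci, gi)
        strand <- sample(c("+", "-"), 1)
        n_cod <- sample(seq(config$cds_length_range[1] %/% 3L,
                            config$cds_length_range[2] %/% 3L), 1)
        body <- sample(setdiff(names(.codon_table()), .stop_codons),
                       n_cod - 2L, replace = TRUE)
        cds <- paste(c("ATG", body, sample(.stop_codons, 1)), collapse = "")
        L3 <- nchar(cds)
        n_ex <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1)
        cuts <- if (n_ex > 1) sort(sample(seq(2L, L3 - 1L), n_ex - 1L)) else integer()
        piece_len <- diff(c(0L, cuts, L3))
        g_start <- edge + (gi - 1L) * slot + sample.int(100L, 1)
        starts <- integer(n_ex); ends <- integer(n_ex)
        cur <- g_start
        for (e in seq_len(n_ex)) {
          starts[e] <- cur
          ends[e] <- cur + piece_len[e] - 1L
          cur <- ends[e] + 1L +
            sample(seq(config$intron_length_range[1],
                       config$intron_length_range[2]), 1)
        }
        model <- tibble(gene_id = gene, contig = ctg, strand = strand,
                        start = starts, end = ends, frame_ok = TRUE)
        gpos <- cds_to_genomic(model, seq_len(L3))
        bases <- strsplit(cds, "")[[1]]
        if (strand == "-") bases <- .complement(bases)
        seq_chars[gpos] <- bases
        seg_rows[[length(seg_rows) + 1]] <- model
      }
    }
    contigs[[ctg]] <- paste(seq_chars, collapse = "")
  }
  models <- bind_rows(seg_rows)
  class(models) <- c("gene_models", class(models))
  per_gene <- models |>
    group_by(.data$gene_id, .data$contig, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  features <- bind_rows(
    mutate(per_gene, type = "gene"),
    mutate(per_gene, type = "mRNA"),
    models |> select("gene_id", "contig", "strand", "start", "end") |>
      mutate(type = "CDS")
  ) |>
    select("contig", "type", "start", "end", "strand", "gene_id") |>
    arrange(.data$contig, .data$start, .data$type)
  structure(list(genome = ref_genome(unlist(contigs)), models = models,
                 features = features),
            class = "sim_genome")
}

# Find a CDS SNV of the desired impact class; returns a one-row manifest stub.
.find_cds_snv <- function(sim, want, used_pos, used_codon, seq_cache) {
  genes <- unique(sim$models$gene_id)
  bases <- c("A", "C", "G", "T")
  for (try in seq_len(2000)) {
    g <- sample(genes, 1)
    model <- gene_model(sim$models, g)
    L3 <- cds_length(model)
    if (is.null(seq_cache[[g]])) seq_cache[[g]] <- cds_sequence(model, sim$genome)
    rng <- switch(want,
                  "no-start" = 1L:3L,
                  "no-stop" = (L3 - 2L):L3,
                  4L:(L3 - 3L))
    cp <- if (length(rng) == 1) rng else sample(rng, 1)
    gp <- cds_to_genomic(model, cp)
    if (gp <= 1L) next
    key <- paste0(model$contig[1], ":", gp)
    ckey <- paste0(g, ":", (cp - 1L) %/% 3L)
    if (key %in% used_pos || ckey %in% used_codon) next
    ref <- genome_seq(sim$genome, model$contig[1], gp, gp)
    for (alt in sample(setdiff(bases, ref))) {
      ann <- annotate_snv(gp, ref, alt, model, sim$genome,
                          cds_seq = seq_cache[[g]])
      if (ann$impact == want) {
        return(tibble(contig = model$contig[1], pos = gp, ref = ref, alt = alt,
                      class = "SNV", region = "CDS", impact = want,
                      gene_id = g, cds_pos = cp, pos_key = key, codon_key = ckey))
      }
    }
  }
  abort(paste0("could not place a '", want, "' variant; increase gene count or CDS length"))
}

#' Plant variants and build the truth manifest
#'
#' Plants every requested variant class into the synthetic genome:
#' line-unique fixed non-synonymous / synonymous / nonsense / start-loss /
#' stop-loss SNVs and 1-bp CDS deletions, shared fixed SNVs, line-unique
#' low-frequency SNVs, and intronic / intergenic SNVs. Positions never
#' collide (nor do two variants share a codon). The `expected_final` flag
#' marks exactly the variants a correct pipeline must recover: fixed in the
#' focal line (frequency 1), absent from the contrast line, in CDS, with an
#' amino-acid-changing impact.
#'
#' @param config A [simulation_config()].
#' @param sim A [generate_genome()] result.
#' @return The truth manifest tibble: `contig`, `pos`, `ref`, `alt`,
#'   `class`, `freq_a`/`freq_b` (focal / contrast pool allele frequencies),
#'   `region`, `impact`, `gene_id`, `cds_pos`, `expected_final`.
#' @export
plant_variants <- function(config, sim) {
  set.seed(config$seed + 1L)
  used_pos <- character(); used_codon <- character()
  seq_cache <- new.env(parent = emptyenv())
  out <- list()
  add <- function(stub, freq_a, freq_b) {
    used_pos <<- c(used_pos, stub$pos_key)
    if (!is.na(stub$codon_key)) used_codon <<- c(used_codon, stub$codon_key)
    out[[length(out) + 1]] <<- mutate(select(stub, -"pos_key", -"codon_key"),
                                      freq_a = freq_a, freq_b = freq_b)
  }
  grab <- function(want) .find_cds_snv(sim, want, used_pos, used_codon, seq_cache)

  for (i in seq_len(config$n_unique_nonsyn)) add(grab("non-synonymous"), 1, 0)
  for (i in seq_len(config$n_nonsense))      add(grab("nonsense"), 1, 0)
  for (i in seq_len(config$n_nostart))       add(grab("no-start"), 1, 0)
  for (i in seq_len(config$n_nostop))        add(grab("no-stop"), 1, 0)
  for (i in seq_len(config$n_unique_syn))    add(grab("synonymous"), 1, 0)
  for (i in seq_len(config$n_shared))        add(grab("non-synonymous"), 1, 1)
  for (i in seq_len(config$n_lowfreq))       add(grab("non-synonymous"), config$low_freq, 0)

  # 1-bp CDS deletions, unique and fixed in the focal line
  genes <- unique(sim$models$gene_id)
  for (i in seq_len(config$n_deletion)) {
    repeat {
      g <- sample(genes, 1)
      model <- gene_model(sim$models, g)
      cp <- sample(4L:(cds_length(model) - 3L), 1)
      gp <- cds_to_genomic(model, cp)
      key <- paste0(model$contig[1], ":", gp)
      ckey <- paste0(g, ":", (cp - 1L) %/% 3L)
      if (gp > 1L && !key %in% used_pos && !ckey %in% used_codon) {
        add(tibble(contig = model$contig[1], pos = gp,
                   ref = genome_seq(sim$genome, model$contig[1], gp, gp),
                   alt = "-", class = "del", region = "CDS",
                   impact = "frameshift", gene_id = g, cds_pos = cp,
                   pos_key = key, codon_key = ckey), 1, 0)
        break
      }
    }
  }

  spans <- sim$models |>
    group_by(.data$gene_id, .data$contig) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  in_any_gene <- function(ctg, p) {
    any(spans$contig == ctg & spans$start <= p & spans$end >= p)
  }
  in_any_cds <- function(ctg, p) {
    any(sim$models$contig == ctg & sim$models$start <= p & sim$models$end >= p)
  }
  # intronic: inside a gene span, outside every CDS segment
  for (i in seq_len(config$n_intronic)) {
    repeat {
      row <- spans[sample.int(nrow(spans), 1), ]
      if (row$end - row$start < 2) next
      p <- sample(seq(row$start, row$end), 1)
      key <- paste0(row$contig, ":", p)
      if (!in_any_cds(row$contig, p) && !key %in% used_pos) {
        ref <- genome_seq(sim$genome, row$contig, p, p)
        add(tibble(contig = row$contig, pos = p, ref = ref,
                   alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1),
                   class = "SNV", region = "intron", impact = NA_character_,
                   gene_id = row$gene_id, cds_pos = NA_integer_,
                   pos_key = key, codon_key = NA_character_), 1, 0)
        break
      }
    }
  }
  # intergenic: outside every gene span (and away from contig edges)
  for (i in seq_len(config$n_intergenic)) {
    repeat {
      ctg <- sample(names(sim$genome), 1)
      p <- sample(seq(500L, nchar(sim$genome[[ctg]]) - 500L), 1)
      key <- paste0(ctg, ":", p)
      if (!in_any_gene(ctg, p) && !key %in% used_pos) {
        ref <- genome_seq(sim$genome, ctg, p, p)
        add(tibble(contig = ctg, pos = p, ref = ref,
                   alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1),
                   class = "SNV", region = "intergenic", impact = NA_character_,
                   gene_id = NA_character_, cds_pos = NA_integer_,
                   pos_key = key, codon_key = NA_character_), 1, 0)
        break
      }
    }
  }

  manifest <- bind_rows(out) |>
    mutate(expected_final = .data$freq_a == 1 & .data$freq_b == 0 &
             .data$region == "CDS" & .data$impact %in% .aa_changing) |>
    mutate(expected_final = !is.na(.data$expected_final) & .data$expected_final) |>
    arrange(.data$contig, .data$pos)
  manifest
}

#' Simulate pooled read counts for each line
#'
#' At each planted variant site the read depth is drawn Poisson around the
#' line's mean coverage (floored at 1) and the variant-supporting count
#' binomially with success probability equal to the pool allele frequency
#' adjusted for sequencing error. Sequencing errors are also sprinkled
#' across non-variant positions at the error rate; any position accumulating
#' at least `min_alt_count` error reads becomes a (low-fraction) record,
#' exactly as a naive caller would report it. Deterministic given the
#' config seed.
#'
#' @param manifest Truth manifest from [plant_variants()].
#' @param config A [simulation_config()].
#' @param sim The [generate_genome()] result.
#' @param min_alt_count Caller's minimum supporting-read count.
#' @return Named list (one element per line) of pooled site record tibbles.
#' @export
simulate_pooled_counts <- function(manifest, config, sim, min_alt_count = 2L) {
  set.seed(config$seed + 2L)
  bases <- c("A", "C", "G", "T")
  e <- config$error_rate
  out <- list()
  for (li in seq_along(config$lines)) {
    line <- config$lines[li]
    cov <- config$coverage[[line]]
    freq <- if (li == 1) manifest$freq_a else manifest$freq_b
    rows <- list()
    for (i in seq_len(nrow(manifest))) {
      f <- freq[i]
      depth <- max(1L, rpois(1, cov))
      p_alt <- f * (1 - e) + (1 - f) * e / 3
      alt_n <- rbinom(1, depth, p_alt)
      if (alt_n < min_alt_count) next
      ref_n <- depth - alt_n
      m <- manifest[i, ]
      counts <- setNames(rep(0L, 4), bases)
      counts[m$ref] <- ref_n
      if (m$class == "del") {
        del_n <- alt_n
        called <- if (ref_n / depth >= 0.2) paste0("-|", m$ref) else "-"
      } else {
        counts[m$alt] <- alt_n
        del_n <- 0L
        called <- if (ref_n / depth >= 0.2) paste0(m$alt, "|", m$ref) else m$alt
      }
      rows[[length(rows) + 1]] <- tibble(
        line = line, contig = m$contig, pos = m$pos, ref = m$ref,
        called = called, depth = depth,
        a_cnt = counts[["A"]], c_cnt = counts[["C"]],
        g_cnt = counts[["G"]], t_cnt = counts[["T"]],
        del_cnt = del_n, snp_pct = alt_n / depth)
    }
    # sequencing-error records at non-variant positions
    var_key <- paste0(manifest$contig, ":", manifest$pos)
    for (ctg in names(sim$genome)) {
      L <- nchar(sim$genome[[ctg]])
      depth_v <- pmax(1L, rpois(L, cov))
      err_v <- rbinom(L, depth_v, e)
      hit <- which(err_v >= min_alt_count)
      if (length(hit)) hit <- hit[!paste0(ctg, ":", hit) %in% var_key]
      for (p in hit) {
        ref <- substr(sim$genome[[ctg]], p, p)
        alt <- sample(setdiff(bases, ref), 1)
        counts <- setNames(rep(0L, 4), bases)
        counts[ref] <- depth_v[p] - err_v[p]
        counts[alt] <- err_v[p]
        rows[[length(rows) + 1]] <- tibble(
          line = line, contig = ctg, pos = p, ref = ref,
          called = paste0(alt, "|", ref), depth = depth_v[p],
          a_cnt = counts[["A"]], c_cnt = counts[["C"]],
          g_cnt = counts[["G"]], t_cnt = counts[["T"]],
          del_cnt = 0L, snp_pct = err_v[p] / depth_v[p])
      }
    }
    recs <- bind_rows(rows)
    out[[line]] <- if (nrow(recs)) arrange(recs, .data$contig, .data$pos)
                   else .empty_records()
  }
  out
}

#' Serialize pooled site records as VCF 4.2 text
#'
#' SNVs are written with single-base REF/ALT; single-base deletions use the
#' left-anchored convention (`REF = anchor+base, ALT = anchor` at
#' `pos - 1`), so [read_pool_vcf()] round-trips the records exactly.
#'
#' @param records Pooled site record tibble (one line).
#' @param genome The `ref_genome` (needed for deletion anchor bases).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pool_vcf <- function(records, genome, path) {
  line <- if (nrow(records)) records$line[1] else "SAMPLE"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=linemarker",
    paste0("##contig=<ID=", names(genome), ",length=", nchar(genome), ">"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Per-allele read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", line, sep = "\t")
  )
  body <- map_chr(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    alts <- called_alleles(r$called, r$ref)[[1]]
    if ("-" %in% alts) {
      anchor <- genome_seq(genome, r$contig, r$pos - 1L, r$pos - 1L)
      pos <- r$pos - 1L
      reff <- paste0(anchor, r$ref)
      altf <- anchor
      ad <- c(allele_count(r, r$ref), r$del_cnt)
    } else {
      pos <- r$pos
      reff <- r$ref
      altf <- paste(alts, collapse = ",")
      ad <- c(allele_count(r, r$ref),
              vapply(alts, function(a) allele_count(r, a), integer(1)))
    }
    ad[is.na(ad)] <- 0L
    paste(r$contig, pos, ".", reff, altf, ".", "PASS", ".", "DP:AD",
          paste0(r$depth, ":", paste(ad, collapse = ",")), sep = "\t")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Generate a complete synthetic study bundle
#'
#' Convenience wrapper running [generate_genome()], [plant_variants()] and
#' [simulate_pooled_counts()], optionally writing FASTA, GFF3, per-line VCF
#' and the manifest TSV to a directory.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory (created if needed).
#' @param min_alt_count Caller's minimum supporting-read count.
#' @return A list of class `sim_bundle`: `config`, `genome`, `models`,
#'   `features`, `manifest`, `records` (named per-line list), and `paths`
#'   when `dir` was given.
#' @export
simulate_study <- function(config = simulation_config(), dir = NULL,
                           min_alt_count = 2L) {
  sim <- generate_genome(config)
  manifest <- plant_variants(config, sim)
  records <- simulate_pooled_counts(manifest, config, sim, min_alt_count)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(dir, "genome.fa"),
      gff3 = file.path(dir, "genes.gff3"),
      manifest = file.path(dir, "manifest.tsv"),
      vcf = setNames(file.path(dir, paste0(config$lines, ".vcf")), config$lines)
    )
    write_genome_fasta(sim$genome, paths$fasta)
    write_gff3(sim$models, paths$gff3)
    readr::write_tsv(manifest, paths$manifest, progress = FALSE)
    for (ln in config$lines) write_pool_vcf(records[[ln]], sim$genome, paths$vcf[[ln]])
  }
  structure(list(config = config, genome = sim$genome, models = sim$models,
                 features = sim$features, manifest = manifest,
                 records = records, paths = paths),
            class = "sim_bundle")
}
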