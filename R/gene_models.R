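#' Read genomic features from GFF3
#'
#' Imports a GFF3 file and returns a flat feature tibble used both for gene
#' model construction (`CDS` rows) and for genomic region classification
#' (`mRNA`, `ncRNA`, `tRNA` spans). Coordinates stay 1-based inclusive, the
#' GFF3 convention.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `contig`, `type`, `start`, `end`, `strand`,
#'   `gene_id`. `gene_id` is taken from the `gene` attribute when present,
#'   otherwise from `Parent`, otherwise from `ID`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  pick <- function(field) {
    if (!field %in% names(mc)) return(rep(NA_character_, length(gr)))
    v <- mc[[field]]
    if (methods::is(v, "List")) {
      vapply(v, function(x) if (length(x)) as.character(x[1]) else NA_character_,
             character(1))
    } else {
      as.character(v)
    }
  }
  gene_id <- dplyr::coalesce(pick("gene"), pick("Parent"), pick("ID"))
  tibble(
    contig  = as.character(GenomicRanges::seqnames(gr)),
    type    = as.character(mc$type),
    start   = GenomicRanges::start(gr),
    end     = GenomicRanges::end(gr),
    strand  = as.character(GenomicRanges::strand(gr)),
    gene_id = gene_id
  )
}

#' Build gene models from a feature table
#'
#' Collects the CDS segments of each gene into a validated gene-model table:
#' one row per CDS segment, segments sorted by genomic start within gene.
#' For minus-strand genes the segments remain in genomic order, but CDS
#' position 1 maps to the highest genomic coordinate (see
#' [genomic_to_cds()]).
#'
#' A gene whose total CDS length is not divisible by 3 is kept but flagged
#' (`frame_ok = FALSE`) with a warning; such models are excluded from
#' protein-level annotation downstream.
#'
#' @param features Feature tibble from [read_gff3()], or any tibble with
#'   columns `contig`, `type`, `start`, `end`, `strand`, `gene_id`.
#' @return A tibble of class `gene_models` with columns `gene_id`, `contig`,
#'   `strand`, `start`, `end`, `frame_ok`.
#' @export
gene_models <- function(features) {
  cds <- features |>
    filter(.data$type == "CDS") |>
    select("gene_id", "contig", "strand", "start", "end")
  if (nrow(cds) == 0) abort("no CDS features found")
  if (any(!cds$strand %in% c("+", "-"))) {
    abort("CDS features must be stranded (+ or -)")
  }
  bad_strand <- cds |>
    group_by(.data$gene_id) |>
    summarise(ns = dplyr::n_distinct(.data$strand),
              nc = dplyr::n_distinct(.data$contig), .groups = "drop") |>
    filter(.data$ns > 1 | .data$nc > 1)
  if (nrow(bad_strand) > 0) {
    abort(paste0("gene(s) with CDS on mixed strands or contigs: ",
                 paste(bad_strand$gene_id, collapse = ", ")))
  }
  cds <- arrange(cds, .data$gene_id, .data$start)
  # non-overlap check within gene
  overl <- cds |>
    group_by(.data$gene_id) |>
    filter(n() > 1,
           .data$start <= dplyr::lag(.data$end, default = .data$start[1] - 1L)) |>
    ungroup()
  if (nrow(overl) > 0) {
    abort(paste0("overlapping CDS segments in gene(s): ",
                 paste(unique(overl$gene_id), collapse = ", ")))
  }
  frame <- cds |>
    group_by(.data$gene_id) |>
    summarise(len = sum(.data$end - .data$start + 1), .groups = "drop") |>
    mutate(frame_ok = .data$len %% 3L == 0L)
  if (any(!frame$frame_ok)) {
    warn(paste0("CDS length not divisible by 3 for gene(s): ",
                paste(frame$gene_id[!frame$frame_ok], collapse = ", "),
                " (kept, excluded from protein-level annotation)"))
  }
  out <- left_join(cds, select(frame, "gene_id", "frame_ok"), by = "gene_id")
  class(out) <- c("gene_models", class(out))
  out
}

#' Read gene models straight from a GFF3 file
#'
#' Convenience wrapper: [read_gff3()] then [gene_models()].
#' @inheritParams read_gff3
#' @return See [gene_models()].
#' @export
read_gene_models <- function(path) gene_models(read_gff3(path))

#' Extract the model of a single gene
#'
#' @param models A `gene_models` tibble.
#' @param gene Gene id.
#' @return The gene's segment tibble, sorted by genomic start.
#' @export
gene_model <- function(models, gene) {
  m <- filter(models, .data$gene_id == gene)
  if (nrow(m) == 0) abort(paste0("gene '", gene, "' not in models"))
  arrange(m, .data$start)
}

#' Total CDS length of a single-gene model
#'
#' @param model Single-gene segment tibble (see [gene_model()]).
#' @return Integer, nucleotides.
#' @export
cds_length <- function(model) sum(model$end - model$start + 1L)

#' Map genomic positions into CDS coordinates
#'
#' Strand-aware spliced mapping. On the plus strand CDS position 1 is the
#' lowest genomic coordinate of the first segment; on the minus strand it is
#' the highest genomic coordinate of the last segment. Positions outside all
#' CDS segments map to `NA` — "not in the CDS" is a value, not an error.
#'
#' @param model Single-gene segment tibble (see [gene_model()]).
#' @param genomic_pos Integer vector of 1-based genomic positions.
#' @return Integer vector of CDS positions (`NA` where outside the CDS).
#' @export
genomic_to_cds <- function(model, genomic_pos) {
  model <- arrange(model, .data$start)
  lens <- model$end - model$start + 1L
  before <- cumsum(lens) - lens        # spliced bases left of each segment
  after <- rev(cumsum(rev(lens))) - lens  # spliced bases right of each segment
  minus <- model$strand[1] == "-"
  vapply(as.integer(genomic_pos), function(p) {
    i <- which(model$start <= p & p <= model$end)
    if (length(i) == 0) return(NA_integer_)
    if (minus) after[i] + (model$end[i] - p + 1L)
    else       before[i] + (p - model$start[i] + 1L)
  }, integer(1))
}

#' Map CDS positions back to genomic coordinates
#'
#' Inverse of [genomic_to_cds()]; the round trip is the identity for every
#' in-range CDS position.
#'
#' @param model Single-gene segment tibble.
#' @param cds_pos Integer vector, 1 <= cds_pos <= [cds_length()].
#' @return Integer vector of genomic positions.
#' @export
cds_to_genomic <- function(model, cds_pos) {
  model <- arrange(model, .data$start)
  lens <- model$end - model$start + 1L
  total <- sum(lens)
  cds_pos <- as.integer(cds_pos)
  if (any(cds_pos < 1L | cds_pos > total)) {
    abort(paste0("cds_pos out of range 1..", total))
  }
  before <- cumsum(lens) - lens
  after <- rev(cumsum(rev(lens))) - lens
  minus <- model$strand[1] == "-"
  vapply(cds_pos, function(p) {
    if (minus) {
      i <- min(which(after < p))
      model$end[i] - (p - after[i] - 1L)
    } else {
      i <- max(which(before < p))
      model$start[i] + (p - before[i] - 1L)
    }
  }, integer(1))
}

#' Spliced, strand-oriented CDS sequence
#'
#' Concatenates the CDS segments in transcription order and reverse
#' complements for minus-strand genes, so the result always starts with the
#' initiator codon for a complete CDS.
#'
#' @param model Single-gene segment tibble.
#' @param genome A `ref_genome`.
#' @return Character scalar of length [cds_length()].
#' @export
cds_sequence <- function(model, genome) {
  model <- arrange(model, .data$start)
  pieces <- map_chr(seq_len(nrow(model)), function(i) {
    genome_seq(genome, model$contig[i], model$start[i], model$end[i])
  })
  s <- paste(pieces, collapse = "")
  if (model$strand[1] == "-") .revcomp(s) else s
}

#' Codon index arithmetic
#'
#' Maps a CDS nucleotide position to its codon (residue) index and the
#' within-codon offset, the arithmetic that links HGVS-like c. positions to
#' p. residue numbers: residue `floor((cds_pos - 1) / 3) + 1`, offset in
#' `{1, 2, 3}`.
#'
#' @param cds_pos Integer vector of CDS positions (>= 1).
#' @return A tibble with columns `cds_pos`, `residue`, `offset`.
#' @examples
#' codon_index(c(1, 4640, 1585))
#' @export
codon_index <- function(cds_pos) {
  cds_pos <- as.integer(cds_pos)
  if (any(cds_pos < 1L)) abort("cds_pos must be >= 1")
  tibble(
    cds_pos = cds_pos,
    residue = (cds_pos - 1L) %/% 3L + 1L,
    offset  = (cds_pos - 1L) %% 3L + 1L
  )
}

#' Write gene models to GFF3
#'
#' Emits one `gene`, one `mRNA` and the CDS rows per gene so that region
#' classification on re-read distinguishes intron/UTR from intergenic.
#'
#' @param models A `gene_models` tibble.
#' @param path Output path.
#' @param extra_features Optional tibble of non-gene features (`contig`,
#'   `type`, `start`, `end`, `strand`, `gene_id`) appended as-is.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path, extra_features = NULL) {
  per_gene <- models |>
    group_by(.data$gene_id, .data$contig, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  lines <- c("##gff-version 3")
  fmt <- function(contig, src, type, start, end, strand, attrs) {
    paste(contig, src, type, start, end, ".", strand, ".", attrs, sep = "\t")
  }
  for (i in seq_len(nrow(per_gene))) {
    g <- per_gene[i, ]
    segs <- filter(models, .data$gene_id == g$gene_id)
    lines <- c(
      lines,
      fmt(g$contig, "linemarker", "gene", g$start, g$end, g$strand,
          paste0("ID=", g$gene_id, ";gene=", g$gene_id)),
      fmt(g$contig, "linemarker", "mRNA", g$start, g$end, g$strand,
          paste0("ID=", g$gene_id, ".t1;Parent=", g$gene_id, ";gene=", g$gene_id)),
      vapply(seq_len(nrow(segs)), function(j) {
        fmt(g$contig, "linemarker", "CDS", segs$start[j], segs$end[j], g$strand,
            paste0("ID=", g$gene_id, ".cds", j, ";Parent=", g$gene_id,
                   ".t1;gene=", g$gene_id))
      }, character(1))
    )
  }
  if (!is.null(extra_features) && nrow(extra_features) > 0) {
    lines <- c(lines, vapply(seq_len(nrow(extra_features)), function(j) {
      f <- extra_features[j, ]
      fmt(f$contig, "linemarker", f$type, f$start, f$end, f$strand,
          paste0("ID=", f$gene_id, ";gene=", f$gene_id))
    }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}
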