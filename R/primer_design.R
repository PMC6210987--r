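#' Wallace-rule melting temperature
#'
#' The classic 2-4 rule for short oligos: `2 * (#A + #T) + 4 * (#G + #C)`
#' degrees Celsius. Crude, but adequate for bucketing primers into a small
#' set of annealing programmes; the Tm model used by [design_primers()] is
#' pluggable.
#'
#' @param sequence Character vector of A/C/G/T strings.
#' @return Numeric vector of temperatures (degrees C).
#' @examples
#' wallace_tm("AT")                     # 4
#' wallace_tm("GAACTTACATACAGATCGTC")   # 56
#' @export
wallace_tm <- function(sequence) {
  if (any(nchar(sequence) == 0)) abort("sequence must be non-empty")
  if (any(str_detect(sequence, "[^ACGT]"))) {
    abort("sequence must contain only A, C, G, T")
  }
  at <- str_count(sequence, "[AT]")
  gc <- str_count(sequence, "[GC]")
  2 * at + 4 * gc
}

#' Pick the annealing temperature bucket for a primer trio
#'
#' Returns the member of `buckets` nearest the trio's minimum estimated Tm
#' (the weakest primer limits the annealing step). Ties resolve to the lower
#' bucket.
#'
#' @param tms Numeric vector of the trio's Tm values.
#' @param buckets Candidate annealing temperatures (degrees C).
#' @return Single numeric bucket.
#' @export
anneal_bucket <- function(tms, buckets = c(55, 63)) {
  mn <- min(tms)
  buckets[which.min(abs(buckets - mn))]
}

#' Introduce the deliberate destabilizing mismatch
#'
#' Replaces the base at the third position from the 3' end with the
#' transversion partner of the template base (A<->C, G<->T); if that
#' substitution would leave the primer unchanged, the other transversion is
#' used. The result always mismatches the template at that position, which
#' sharpens 3'-terminal allele discrimination during PCR.
#'
#' @param primer Primer sequence, 5'->3', length >= 3.
#' @param template_base Template base at the third-from-3' position.
#' @return The modified primer.
#' @export
introduce_destabilizing_mismatch <- function(primer, template_base) {
  if (nchar(primer) < 3) abort("primer must be at least 3 nt")
  pos <- nchar(primer) - 2L
  partner <- c(A = "C", C = "A", G = "T", T = "G")
  alt2 <- c(A = "T", C = "G", G = "C", T = "A")
  sub <- unname(partner[template_base])
  if (is.na(sub)) abort(paste0("invalid template base '", template_base, "'"))
  if (sub == substr(primer, pos, pos)) sub <- unname(alt2[template_base])
  substr(primer, pos, pos) <- sub
  primer
}

# Single-trio design; aborts with a reason on failure.
.design_one <- function(contig, pos, ref, alt, genome, primer_length = 20L,
                        amplicon_min = 100L, amplicon_max = 400L,
                        strand = c("auto", "+", "-"), tm_fun = wallace_tm,
                        buckets = c(55, 63), gene = NA_character_) {
  strand <- match.arg(strand)
  if (!contig %in% names(genome)) abort(paste0("contig '", contig, "' not in genome"))
  clen <- nchar(genome[[contig]])
  L <- as.integer(primer_length)

  design_on <- function(st) {
    if (st == "+") {
      if (pos - L + 1L < 1L) abort("design failure: SNP too close to contig start for forward primer")
      core <- genome_seq(genome, contig, pos - L + 1L, pos)
      o_ref <- ref; o_alt <- alt
      win <- seq.int(pos + amplicon_min, min(pos + amplicon_max, clen))
      win <- win[win - L + 1L > pos]
      if (length(win) == 0) abort("design failure: no reverse-primer window within contig")
      rev_seq <- function(e) .revcomp(genome_seq(genome, contig, e - L + 1L, e))
      amp_len <- function(e) e - (pos - L + 1L) + 1L
    } else {
      if (pos + L - 1L > clen) abort("design failure: SNP too close to contig end for forward primer")
      core <- .revcomp(genome_seq(genome, contig, pos, pos + L - 1L))
      o_ref <- .complement(ref); o_alt <- .complement(alt)
      win <- seq.int(max(pos - amplicon_max, 1L), pos - amplicon_min)
      win <- win[win + L - 1L < pos & win >= 1L]
      if (length(win) == 0) abort("design failure: no reverse-primer window within contig")
      rev_seq <- function(e) genome_seq(genome, contig, e, e + L - 1L)
      amp_len <- function(e) (pos + L - 1L) - e + 1L
    }
    if (substr(core, L, L) != o_ref) {
      abort(paste0("design failure: genome base at ", contig, ":", pos,
                   " is not the stated reference '", ref, "'"))
    }
    template_third <- substr(core, L - 2L, L - 2L)
    f1 <- introduce_destabilizing_mismatch(core, template_third)
    f3 <- f1
    substr(f3, L, L) <- o_alt
    target <- mean(c(tm_fun(f1), tm_fun(f3)))
    cand <- vapply(win, rev_seq, character(1))
    ok <- !str_detect(cand, "[^ACGT]")
    if (!any(ok)) abort("design failure: reverse-primer window contains ambiguous bases only")
    tms <- rep(Inf, length(cand))
    tms[ok] <- tm_fun(cand[ok])
    best <- which.min(abs(tms - target))
    list(f1 = f1, f3 = f3, reverse = cand[best],
         tm_f1 = tm_fun(f1), tm_f3 = tm_fun(f3), tm_rev = tms[best],
         amplicon_length = amp_len(win[best]),
         mismatch_base = substr(f1, L - 2L, L - 2L),
         template_base = template_third, strand = st)
  }

  st <- strand
  if (strand == "auto") {
    # prefer the strand whose base 5'-adjacent to the SNP strengthens the
    # 3' clamp (G/C just inside the discriminating terminus); tie -> +
    up <- if (pos > 1L) substr(genome[[contig]], pos - 1L, pos - 1L) else "N"
    dn <- if (pos < clen) substr(genome[[contig]], pos + 1L, pos + 1L) else "N"
    st <- if (!up %in% c("G", "C") && .complement(dn) %in% c("G", "C")) "-" else "+"
  }
  d <- design_on(st)
  tibble(gene = gene, contig = contig, pos = pos, ref = ref, alt = alt,
         strand = d$strand, f1 = d$f1, f3 = d$f3, reverse = d$reverse,
         tm_f1 = d$tm_f1, tm_f3 = d$tm_f3, tm_rev = d$tm_rev,
         annealing_temp = anneal_bucket(c(d$tm_f1, d$tm_f3, d$tm_rev), buckets),
         amplicon_length = d$amplicon_length, mismatch_offset = 3L,
         mismatch_base = d$mismatch_base)
}

#' Design allele-specific PCR primer trios
#'
#' For each record designs the trio used for allele-specific genotyping: a
#' reference-type forward primer `F1` whose 3'-terminal base is the
#' reference allele, an SNP-type forward `F3` identical except that its
#' 3'-terminal base is the variant allele, and a common reverse primer. Both
#' forwards carry a deliberate destabilizing mismatch at the third position
#' from the 3' end ([introduce_destabilizing_mismatch()]), so extension
#' succeeds only when the terminal base matches the template allele. The
#' reverse primer is picked from the downstream amplicon window by Tm
#' proximity to the forwards, and the trio's annealing temperature is
#' bucketed with [anneal_bucket()].
#'
#' @param records Pooled site record tibble (SNV records; deletion alleles
#'   are skipped with a reason).
#' @param genome A `ref_genome`.
#' @param primer_length Forward/reverse primer length in nt (default 20).
#' @param amplicon_min,amplicon_max Reverse-primer search window: amplicon
#'   lengths in bp (defaults 100-400, a standard agarose-resolvable range).
#' @param strand `"auto"` (default), `"+"` or `"-"`: which genomic strand the
#'   forward primers are designed on.
#' @param tm_fun Tm model, default [wallace_tm()].
#' @param buckets Candidate annealing temperatures.
#' @return A tibble with one row per (record, alt allele): primer sequences
#'   (5'->3'), Tm values, `annealing_temp`, `amplicon_length`,
#'   `mismatch_offset`/`mismatch_base`, and for failed designs `failed =
#'   TRUE` with the `reason`.
#' @export
design_primers <- function(records, genome, primer_length = 20L,
                           amplicon_min = 100L, amplicon_max = 400L,
                           strand = "auto", tm_fun = wallace_tm,
                           buckets = c(55, 63)) {
  rows <- map(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    gene <- if ("feature" %in% names(r)) r$feature else NA_character_
    alts <- called_alleles(r$called, r$ref)[[1]]
    alts <- setdiff(alts, "-")
    if (length(alts) == 0) {
      return(tibble(gene = gene, contig = r$contig, pos = r$pos, ref = r$ref,
                    alt = NA_character_, failed = TRUE,
                    reason = "no SNV alt allele to discriminate"))
    }
    bind_rows(map(alts, function(a) {
      tryCatch(
        mutate(.design_one(r$contig, r$pos, r$ref, a, genome,
                           primer_length = primer_length,
                           amplicon_min = amplicon_min,
                           amplicon_max = amplicon_max, strand = strand,
                           tm_fun = tm_fun, buckets = buckets, gene = gene),
               failed = FALSE, reason = NA_character_),
        error = function(e) {
          tibble(gene = gene, contig = r$contig, pos = r$pos, ref = r$ref,
                 alt = a, failed = TRUE, reason = conditionMessage(e))
        }
      )
    }))
  })
  bind_rows(rows)
}
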