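#' Classify the protein-level impact of a coding change
#'
#' Fine impact taxonomy in precedence order: a single-base deletion in CDS is
#' a `frameshift`; a stop gain (`alt_aa == "*"`, reference not stop) is
#' `nonsense`; a substitution destroying the initiator codon at residue 1 is
#' `no-start`; a substitution destroying the stop codon is `no-stop`; an
#' amino-acid-preserving substitution is `synonymous`; anything else is
#' `non-synonymous`. The coarse display convention folds every
#' amino-acid-changing class into `"N-syn"`.
#'
#' @param ref_aa,alt_aa Single-letter amino acids (`"*"` = stop).
#' @param residue Residue index.
#' @param ref_codon Reference codon (used for the initiator check).
#' @param is_deletion Is the allele a single-base deletion?
#' @return Character scalar impact label.
#' @export
classify_impact <- function(ref_aa, alt_aa, residue, ref_codon,
                            is_deletion = FALSE) {
  if (is_deletion) return("frameshift")
  if (alt_aa == "*" && ref_aa != "*") return("nonsense")
  if (residue == 1 && ref_codon == "ATG" && alt_aa != "M") return("no-start")
  if (ref_aa == "*" && alt_aa != "*") return("no-stop")
  if (ref_aa == alt_aa) return("synonymous")
  "non-synonymous"
}

#' Fold fine impact labels into the coarse display label
#'
#' @param impact Character vector of fine impact labels.
#' @return Character vector where every amino-acid-changing substitution
#'   class reads `"N-syn"`.
#' @export
impact_display <- function(impact) {
  if_else(impact %in% c("non-synonymous", "nonsense", "no-start", "no-stop"),
          .nsyn_display, impact)
}

#' HGVS-like coding (c.) notation
#'
#' Homozygous substitution: `"c.<pos><ref>><alt>"`. A heterozygous call that
#' retains the reference allele is written as the compound
#' `"c.[<pos><ref>><ref>]+[<pos><ref>><alt>]"`. Alleles here are on the
#' coding (CDS) strand.
#'
#' @param cds_pos CDS position.
#' @param ref,alt Coding-strand reference and alternate bases.
#' @param het_with_ref Does the call retain the reference allele?
#' @return Character scalar.
#' @export
hgvs_c <- function(cds_pos, ref, alt, het_with_ref = FALSE) {
  if (het_with_ref) {
    paste0("c.[", cds_pos, ref, ">", ref, "]+[", cds_pos, ref, ">", alt, "]")
  } else {
    paste0("c.", cds_pos, ref, ">", alt)
  }
}

#' HGVS-like protein (p.) notation
#'
#' `"p.<refAA><residue><altAA>"`, with a gained stop rendered using
#' `stop_char` (default the legacy trailing dot, e.g. `"p.Y111."`; set
#' `stop_char = "*"` for the modern style). For a compound heterozygous call
#' pass the alt-allele and reference residues via [hgvs_p_compound()].
#'
#' @param ref_aa,alt_aa Single-letter amino acids (`"*"` = stop).
#' @param residue Residue index.
#' @param stop_char Character used for a gained stop.
#' @return Character scalar.
#' @export
hgvs_p <- function(ref_aa, residue, alt_aa, stop_char = ".") {
  show <- function(a) if (a == "*") stop_char else a
  paste0("p.", show(ref_aa), residue, show(alt_aa))
}

#' @rdname hgvs_p
#' @export
hgvs_p_compound <- function(ref_aa, residue, alt_aa, stop_char = ".") {
  paste0(hgvs_p(ref_aa, residue, alt_aa, stop_char), ", ",
         hgvs_p(ref_aa, residue, ref_aa, stop_char))
}

#' Annotate one SNV against a gene model
#'
#' Strand-aware codon replacement: the alt allele is given on the + genomic
#' strand and is complemented for minus-strand genes before substitution
#' into the spliced CDS. Genes whose CDS length is not divisible by 3 yield
#' a `"partial-CDS"` marker annotation with no protein-level fields.
#'
#' @param pos Genomic position (must fall inside the model's CDS).
#' @param ref,alt Reference and alternate bases on the + genomic strand.
#' @param model Single-gene segment tibble ([gene_model()]).
#' @param genome A `ref_genome`.
#' @param het_with_ref Did the call retain the reference allele?
#' @param stop_char Stop rendering for p. notation.
#' @param cds_seq Optional pre-computed [cds_sequence()] (cache for bulk
#'   annotation).
#' @return One-row tibble: `gene_id`, `pos`, `allele`, `cds_pos`, `residue`,
#'   `offset`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `impact`,
#'   `impact_display`, `c_notation`, `p_notation`.
#' @export
annotate_snv <- function(pos, ref, alt, model, genome, het_with_ref = FALSE,
                         stop_char = ".", cds_seq = NULL) {
  cds_pos <- genomic_to_cds(model, pos)
  if (is.na(cds_pos)) {
    abort(paste0("position ", pos, " is not in the CDS of gene '",
                 model$gene_id[1], "'"))
  }
  gene <- model$gene_id[1]
  if (!is.null(model$frame_ok) && !model$frame_ok[1]) {
    return(tibble(gene_id = gene, pos = pos, allele = alt, cds_pos = cds_pos,
                  residue = NA_integer_, offset = NA_integer_,
                  ref_codon = NA_character_, alt_codon = NA_character_,
                  ref_aa = NA_character_, alt_aa = NA_character_,
                  impact = "partial-CDS", impact_display = "partial-CDS",
                  c_notation = NA_character_, p_notation = NA_character_))
  }
  minus <- model$strand[1] == "-"
  cds_ref <- if (minus) .complement(ref) else ref
  is_del <- alt == "-"
  cds_alt <- if (is_del) "-" else if (minus) .complement(alt) else alt
  if (is.null(cds_seq)) cds_seq <- cds_sequence(model, genome)
  if (substr(cds_seq, cds_pos, cds_pos) != cds_ref) {
    abort(paste0("reference mismatch at ", gene, " cds ", cds_pos,
                 ": genome has ", substr(cds_seq, cds_pos, cds_pos),
                 ", record says ", cds_ref))
  }
  ci <- codon_index(cds_pos)
  if (is_del) {
    return(tibble(gene_id = gene, pos = pos, allele = alt, cds_pos = cds_pos,
                  residue = ci$residue, offset = ci$offset,
                  ref_codon = substr(cds_seq, 3 * ci$residue - 2, 3 * ci$residue),
                  alt_codon = NA_character_, ref_aa = NA_character_,
                  alt_aa = NA_character_, impact = "frameshift",
                  impact_display = "frameshift",
                  c_notation = paste0("c.", cds_pos, "del", cds_ref),
                  p_notation = paste0("p.", ci$residue, "fs")))
  }
  ct <- .codon_table()
  ref_codon <- substr(cds_seq, 3 * ci$residue - 2, 3 * ci$residue)
  alt_codon <- ref_codon
  substr(alt_codon, ci$offset, ci$offset) <- cds_alt
  ref_aa <- unname(ct[ref_codon])
  alt_aa <- unname(ct[alt_codon])
  impact <- classify_impact(ref_aa, alt_aa, ci$residue, ref_codon)
  p_not <- if (het_with_ref) {
    hgvs_p_compound(ref_aa, ci$residue, alt_aa, stop_char)
  } else {
    hgvs_p(ref_aa, ci$residue, alt_aa, stop_char)
  }
  tibble(gene_id = gene, pos = pos, allele = alt, cds_pos = cds_pos,
         residue = ci$residue, offset = ci$offset,
         ref_codon = ref_codon, alt_codon = alt_codon,
         ref_aa = ref_aa, alt_aa = alt_aa,
         impact = impact, impact_display = impact_display(impact),
         c_notation = hgvs_c(cds_pos, cds_ref, cds_alt, het_with_ref),
         p_notation = p_not)
}

#' Annotate pooled site records against gene models
#'
#' For every record whose position falls inside a gene's CDS, annotates each
#' called alt allele (SNV or single-base deletion). Records outside every
#' CDS are skipped (use [classify_region()] to label them).
#'
#' @param records Pooled site record tibble.
#' @param models `gene_models` tibble.
#' @param genome A `ref_genome`.
#' @param stop_char Stop rendering for p. notation.
#' @return Effect-annotation tibble with a `contig` column prepended, one
#'   row per (record, alt allele) that maps into a CDS.
#' @export
annotate_variants <- function(records, models, genome, stop_char = ".") {
  empty <- tibble(contig = character(), line = character(), gene_id = character(),
                  pos = integer(), allele = character(), cds_pos = integer(),
                  residue = integer(), offset = integer(),
                  ref_codon = character(), alt_codon = character(),
                  ref_aa = character(), alt_aa = character(),
                  impact = character(), impact_display = character(),
                  c_notation = character(), p_notation = character())
  if (nrow(records) == 0 || nrow(models) == 0) return(empty)
  gene_ids <- unique(models$gene_id)
  model_list <- map(setNames(gene_ids, gene_ids), gene_model, models = models)
  seq_cache <- new.env(parent = emptyenv())
  get_seq <- function(g) {
    if (is.null(seq_cache[[g]])) seq_cache[[g]] <- cds_sequence(model_list[[g]], genome)
    seq_cache[[g]]
  }
  rows <- map(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    hits <- filter(models, .data$contig == r$contig,
                   .data$start <= r$pos, .data$end >= r$pos)
    if (nrow(hits) == 0) return(NULL)
    alts <- called_alleles(r$called, r$ref)[[1]]
    if (length(alts) == 0) return(NULL)
    het <- str_detect(r$called, stringr::fixed("|")) &
      r$ref %in% str_split(r$called, stringr::fixed("|"))[[1]]
    bind_rows(map(unique(hits$gene_id), function(g) {
      bind_rows(map(alts, function(a) {
        ann <- annotate_snv(r$pos, r$ref, a, model_list[[g]], genome,
                            het_with_ref = het, stop_char = stop_char,
                            cds_seq = get_seq(g))
        mutate(ann, contig = r$contig, line = r$line, .before = 1)
      }))
    }))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) empty else out
}

.aa_codons <- function(aa) {
  ct <- .codon_table()
  names(ct)[ct == aa]
}

.parse_c_parts <- function(s) {
  s <- str_replace_all(s, "\\s", "")
  s <- sub("^c\\.", "", s)
  parts <- if (str_detect(s, "^\\[")) {
    strsplit(s, "+", fixed = TRUE)[[1]]
  } else s
  m <- str_match(gsub("\\[|\\]", "", parts), "^(\\d+)([ACGT])>([ACGT])$")
  if (any(is.na(m[, 1]))) return(NULL)
  tibble(pos = as.integer(m[, 2]), ref = m[, 3], alt = m[, 4])
}

.parse_p_parts <- function(s) {
  s <- str_replace_all(s, "\\s", "")
  s <- sub("^p\\.", "", s)
  parts <- strsplit(s, ",p\\.|,")[[1]]
  parts <- parts[parts != ""]
  m <- str_match(parts, "^([A-Z])(\\d+)([A-Z]|\\.|\\*)$")
  if (any(is.na(m[, 1]))) return(NULL)
  tibble(ref_aa = m[, 2], residue = as.integer(m[, 3]),
         alt_aa = if_else(m[, 4] %in% c(".", "*"), "*", m[, 4]))
}

.check_one_pair <- function(cpart, ppart) {
  ci <- codon_index(cpart$pos)
  if (ci$residue != ppart$residue) {
    return(paste0("residue arithmetic mismatch: c.", cpart$pos, " implies residue ",
                  ci$residue, ", p. says ", ppart$residue))
  }
  ct <- .codon_table()
  cands <- .aa_codons(ppart$ref_aa)
  if (length(cands) == 0) return(paste0("unknown amino acid '", ppart$ref_aa, "'"))
  ok <- FALSE
  for (cd in cands) {
    if (substr(cd, ci$offset, ci$offset) != cpart$ref) next
    mut <- cd
    substr(mut, ci$offset, ci$offset) <- cpart$alt
    if (unname(ct[mut]) == ppart$alt_aa) { ok <- TRUE; break }
  }
  if (!ok) {
    return(paste0("no codon of ", ppart$ref_aa, " with ", cpart$ref,
                  " at offset ", ci$offset, " yields ", ppart$alt_aa,
                  " on substituting ", cpart$alt))
  }
  NA_character_
}

#' Check a printed DNA-change / AA-change pair for internal consistency
#'
#' Validates that a printed pair like `("c.4640A>G", "p.K1547R")` is
#' arithmetically and biochemically coherent: (a) the c. position implies
#' the p. residue number under codon arithmetic, and (b) brute force over
#' all standard codons of the reference amino acid finds at least one codon
#' carrying the c. reference base at the implied within-codon offset whose
#' substitution yields the claimed amino acid (or a stop, for the
#' trailing-dot stop notation). Compound heterozygous notation
#' (`"c.[..]+[..]"` with comma-separated p. parts) is matched set-wise, so
#' the printed ordering of the two allele annotations is irrelevant.
#'
#' @param dna_change Character vector of c. strings.
#' @param aa_change Character vector of p. strings.
#' @return A tibble with columns `dna_change`, `aa_change`, `pass`,
#'   `reason` (`NA` when passing).
#' @examples
#' check_printed_consistency("c.4640A>G", "p.K1547R")
#' check_printed_consistency("c.10A>G", "p.K3E")  # residue should be 4
#' @export
check_printed_consistency <- function(dna_change, aa_change) {
  n <- max(length(dna_change), length(aa_change))
  dna_change <- rep_len(dna_change, n)
  aa_change <- rep_len(aa_change, n)
  res <- map(seq_len(n), function(i) {
    cp <- .parse_c_parts(dna_change[i])
    if (is.null(cp)) {
      return(list(pass = FALSE, reason = paste0("unparsable DNA change '",
                                                dna_change[i], "'")))
    }
    pp <- .parse_p_parts(aa_change[i])
    if (is.null(pp)) {
      return(list(pass = FALSE, reason = paste0("unparsable AA change '",
                                                aa_change[i], "'")))
    }
    if (nrow(cp) != nrow(pp)) {
      return(list(pass = FALSE, reason = "different number of c. and p. parts"))
    }
    # set-wise matching: each c part must pair with a distinct passing p part
    perms <- if (nrow(pp) == 1) list(1L) else list(seq_len(nrow(pp)),
                                                   rev(seq_len(nrow(pp))))
    reasons <- character()
    for (perm in perms) {
      rs <- vapply(seq_len(nrow(cp)), function(k) {
        .check_one_pair(cp[k, ], pp[perm[k], ])
      }, character(1))
      if (all(is.na(rs))) return(list(pass = TRUE, reason = NA_character_))
      reasons <- c(reasons, rs[!is.na(rs)][1])
    }
    list(pass = FALSE, reason = reasons[1])
  })
  tibble(dna_change = dna_change, aa_change = aa_change,
         pass = map_lgl(res, "pass"), reason = map_chr(res, "reason"))
}
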