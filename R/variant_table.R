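#' Pooled variant site records
#'
#' A pooled site record describes one called variant site in one line's pool:
#' reference base, called base(s), read depth, per-base read counts, deletion
#' read count, and the supporting-read fraction ("SNP%", stored as a fraction
#' in `[0, 1]`). Records are plain tibbles with columns:
#' `line`, `contig`, `pos`, `ref`, `called`, `depth`, `a_cnt`, `c_cnt`,
#' `g_cnt`, `t_cnt`, `del_cnt`, `snp_pct`, plus optional annotation columns
#' (`chrom`, `impact`, `feature`, `dna_change`, `aa_change`, `region`).
#'
#' In the `called` column a heterozygous call is written `"X|Y"`; a
#' single-base deletion allele is written `"-"`.
#'
#' @name pooled_site_records
NULL

.record_cols <- c("line", "contig", "pos", "ref", "called", "depth",
                  "a_cnt", "c_cnt", "g_cnt", "t_cnt", "del_cnt", "snp_pct")

.empty_records <- function() {
  tibble(line = character(), contig = character(), pos = integer(),
         ref = character(), called = character(), depth = integer(),
         a_cnt = integer(), c_cnt = integer(), g_cnt = integer(),
         t_cnt = integer(), del_cnt = integer(), snp_pct = double())
}

.validate_records <- function(records) {
  missing <- setdiff(.record_cols, names(records))
  if (length(missing)) {
    abort(paste0("record table missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(records)) {
    mx <- pmax(records$a_cnt, records$c_cnt, records$g_cnt, records$t_cnt,
               na.rm = TRUE)
    if (any(records$depth < mx, na.rm = TRUE)) {
      abort("depth smaller than a single base count")
    }
    if (any(records$snp_pct < 0 | records$snp_pct > 1, na.rm = TRUE)) {
      abort("snp_pct outside [0, 1]")
    }
  }
  invisible(records)
}

#' Alternate alleles of a called genotype
#'
#' Splits the `called` notation on `|` and removes the reference base, so a
#' heterozygous `"T|C"` call against reference `C` yields `"T"`. The
#' single-base deletion marker `"-"` is a valid allele.
#'
#' @param called Character vector of called-base strings.
#' @param ref Character vector of reference bases (recycled).
#' @return A list of character vectors of alt alleles, one per input.
#' @examples
#' called_alleles(c("T|C", "C", "G|A"), c("C", "T", "G"))
#' @export
called_alleles <- function(called, ref) {
  n <- max(length(called), length(ref))
  called <- rep_len(called, n)
  ref <- rep_len(ref, n)
  map2(str_split(called, stringr::fixed("|")), ref, function(al, r) {
    al <- unique(al)
    bad <- setdiff(al, c("A", "C", "G", "T", "-"))
    if (length(bad)) abort(paste0("invalid called allele(s): ", paste(bad, collapse = ", ")))
    setdiff(al, r)
  })
}

#' Read count supporting a given allele
#'
#' @param records Pooled site record tibble.
#' @param allele Character vector of alleles (`A`, `C`, `G`, `T`, or the
#'   deletion marker `"-"`), recycled against the records.
#' @return Integer vector of counts (`NA` where the table did not report the
#'   count, e.g. the reference base's column in the tabular dialect).
#' @export
allele_count <- function(records, allele) {
  allele <- rep_len(allele, nrow(records))
  vapply(seq_len(nrow(records)), function(i) {
    switch(allele[i],
           A = records$a_cnt[i], C = records$c_cnt[i],
           G = records$g_cnt[i], T = records$t_cnt[i],
           "-" = records$del_cnt[i],
           abort(paste0("invalid allele '", allele[i], "'")))
  }, integer(1))
}

#' Supporting-read fraction of an allele ("SNP%")
#'
#' The fraction of reads at a site supporting the given allele:
#' `count / depth`. This is the quantity the filter cascade thresholds at
#' 0.75 to call a site "fixed" within a pool; rounding the result to two
#' decimals reproduces the tabular display convention.
#'
#' @param records Pooled site record tibble (`depth` must be > 0).
#' @param allele Allele whose support is measured; defaults to each record's
#'   first called alt allele.
#' @return Numeric vector of exact fractions in `[0, 1]`.
#' @examples
#' r <- tibble::tibble(line = "AR", contig = "c1", pos = 1L, ref = "T",
#'   called = "C", depth = 4L, a_cnt = 0L, c_cnt = 3L, g_cnt = 0L,
#'   t_cnt = NA_integer_, del_cnt = 0L, snp_pct = NA_real_)
#' variant_fraction(r)  # 3 of 4 -> 0.75
#' @export
variant_fraction <- function(records, allele = NULL) {
  if (nrow(records) == 0) return(double())
  if (any(records$depth <= 0)) abort("depth must be positive")
  if (is.null(allele)) {
    allele <- map_chr(called_alleles(records$called, records$ref),
                      function(a) if (length(a)) a[1] else NA_character_)
  }
  cnt <- allele_count(records, allele)
  cnt[is.na(cnt)] <- 0L
  cnt / records$depth
}

#' Read pooled variant calls from a VCF file
#'
#' Reads a VCF 4.x file with per-sample `DP` (depth) and `AD` (per-allele
#' depth) fields into pooled site records. Multi-allelic rows become a single
#' record carrying all base counts. Single-base deletions written in the
#' anchored `REF=XY, ALT=X` convention become records at the deleted base
#' with the deletion marker `"-"`; symbolic alleles and longer indels are
#' rejected — the scope is SNVs and 1-bp deletions.
#'
#' @param path VCF path.
#' @param line_label Label of the pooled line (e.g. `"AR"`).
#' @param min_alt_count Minimum supporting reads for an alt allele to be
#'   recorded (the caller's minimum SNP count); default 2.
#' @param het_ref_min Reference-allele fraction at or above which the call is
#'   reported heterozygous (`"ALT|REF"`); default 0.2.
#' @return Pooled site record tibble.
#' @export
read_pool_vcf <- function(path, line_label, min_alt_count = 2L,
                          het_ref_min = 0.2) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(.empty_records())
  gt_fields <- strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)
  sample_gt <- strsplit(v@gt[, 2], ":", fixed = TRUE)
  rows <- map(seq_len(nrow(fix)), function(i) {
    ref <- fix$REF[i]
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    site <- paste0(fix$CHROM[i], ":", fix$POS[i])
    if (any(grepl("^<", alts)) || any(nchar(alts) > nchar(ref))) {
      abort(paste0("unsupported allele at ", site,
                   ": only SNVs and 1-bp deletions are in scope"))
    }
    fld <- setNames(sample_gt[[i]], gt_fields[[i]])
    if (!"DP" %in% names(fld) || is.na(fld[["DP"]]) || fld[["DP"]] == ".") {
      abort(paste0("missing DP field at ", site))
    }
    if (!"AD" %in% names(fld)) abort(paste0("missing AD field at ", site))
    depth <- as.integer(fld[["DP"]])
    ad <- as.integer(strsplit(fld[["AD"]], ",", fixed = TRUE)[[1]])
    if (length(ad) != length(alts) + 1L) {
      abort(paste0("AD field length mismatch at ", site))
    }
    is_del <- nchar(alts) == 1L & nchar(ref) == 2L
    is_snv <- nchar(alts) == 1L & nchar(ref) == 1L
    if (any(!is_del & !is_snv)) {
      abort(paste0("unsupported allele at ", site,
                   ": only SNVs and 1-bp deletions are in scope"))
    }
    if (any(is_del) && any(is_snv)) {
      abort(paste0("mixed SNV/deletion alleles at ", site, " not supported"))
    }
    if (any(is_del)) {
      if (length(alts) > 1) abort(paste0("multi-allelic deletion at ", site))
      if (substr(ref, 1, 1) != alts[1]) {
        abort(paste0("non-left-anchored deletion at ", site))
      }
      pos <- as.integer(fix$POS[i]) + 1L
      ref_base <- substr(ref, 2, 2)
      counts <- setNames(rep(0L, 4), c("A", "C", "G", "T"))
      counts[ref_base] <- ad[1]
      del_cnt <- ad[2]
      if (del_cnt < min_alt_count) return(NULL)
      called <- if (ad[1] / depth >= het_ref_min) paste0("-|", ref_base) else "-"
      alt_total <- del_cnt
    } else {
      pos <- as.integer(fix$POS[i])
      ref_base <- ref
      counts <- setNames(rep(0L, 4), c("A", "C", "G", "T"))
      counts[ref_base] <- ad[1]
      keep <- ad[-1] >= min_alt_count
      if (!any(keep)) return(NULL)
      counts[alts] <- ad[-1]
      kept_alts <- alts[keep][order(-ad[-1][keep])]
      called <- paste(c(kept_alts,
                        if (ad[1] / depth >= het_ref_min) ref_base), collapse = "|")
      del_cnt <- 0L
      alt_total <- sum(ad[-1][keep])
    }
    tibble(line = line_label, contig = fix$CHROM[i], pos = pos,
           ref = ref_base, called = called, depth = depth,
           a_cnt = counts[["A"]], c_cnt = counts[["C"]],
           g_cnt = counts[["G"]], t_cnt = counts[["T"]],
           del_cnt = del_cnt, snp_pct = alt_total / depth)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(.empty_records())
  .validate_records(out)
  out
}

# Column headers of the tabular (Table 3 style) dialect, in order.
.table_cols <- c("Contig ID", "C", "Ref Pos", "Ref Base", "Called Base",
                 "Impact", "SNP%", "Feature Name", "DNA Change", "AA Change",
                 "Depth", "A Cnt", "C Cnt", "G Cnt", "T Cnt", "Del")

#' Read pooled variant calls from the tabular SNP dialect
#'
#' Reads the tab-separated per-site table dialect (one row per site with
#' contig, chromosome number, position, reference and called bases, impact
#' label, SNP%, gene feature name, DNA/AA change notation, depth and the five
#' per-base count columns). In the count columns, `"-"` marks the reference
#' base's column, whose count the dialect does not report; it is parsed as
#' `NA`, never as zero.
#'
#' @param path TSV path.
#' @param line_label Line label attached to all records (default `"AR"`).
#' @param min_alt_count Minimum supporting reads for the called allele;
#'   rows below are dropped. Default 2.
#' @return Pooled site record tibble with the extra columns `chrom`,
#'   `impact`, `feature`, `dna_change`, `aa_change`, `region` (set to
#'   `"CDS"` where a DNA change is reported).
#' @export
read_snp_table <- function(path, line_label = "AR", min_alt_count = 2L) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) return(.empty_records())
  missing <- setdiff(.table_cols, names(raw))
  if (length(missing)) {
    abort(paste0("SNP table missing column(s): ", paste(missing, collapse = ", ")))
  }
  parse_count <- function(x) if_else(x == "-", NA_integer_,
                                     suppressWarnings(as.integer(x)))
  num_or_stop <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v))) {
      abort(paste0("unparsable ", what, " in row(s) ",
                   paste(which(is.na(v)), collapse = ", ")))
    }
    v
  }
  out <- tibble(
    line = line_label,
    contig = raw[["Contig ID"]],
    chrom = raw[["C"]],
    pos = as.integer(num_or_stop(raw[["Ref Pos"]], "Ref Pos")),
    ref = raw[["Ref Base"]],
    called = raw[["Called Base"]],
    impact = raw[["Impact"]],
    snp_pct = num_or_stop(raw[["SNP%"]], "SNP%"),
    feature = raw[["Feature Name"]],
    dna_change = raw[["DNA Change"]],
    aa_change = raw[["AA Change"]],
    depth = as.integer(num_or_stop(raw[["Depth"]], "Depth")),
    a_cnt = parse_count(raw[["A Cnt"]]),
    c_cnt = parse_count(raw[["C Cnt"]]),
    g_cnt = parse_count(raw[["G Cnt"]]),
    t_cnt = parse_count(raw[["T Cnt"]]),
    del_cnt = parse_count(raw[["Del"]])
  ) |>
    mutate(region = if_else(!is.na(.data$dna_change) & .data$dna_change != "",
                            "CDS", NA_character_)) |>
    select("line", "contig", "pos", "ref", "called", "depth",
           "a_cnt", "c_cnt", "g_cnt", "t_cnt", "del_cnt", "snp_pct",
           "chrom", "impact", "feature", "dna_change", "aa_change", "region")
  if (any(out$snp_pct < 0 | out$snp_pct > 1)) abort("SNP% outside [0, 1]")
  alt1 <- map_chr(called_alleles(out$called, out$ref),
                  function(a) if (length(a)) a[1] else NA_character_)
  cnt <- allele_count(out, dplyr::coalesce(alt1, out$ref))
  out <- out[is.na(cnt) | cnt >= min_alt_count, ]
  .validate_records(out)
  out
}

#' Write pooled site records in the tabular SNP dialect
#'
#' Inverse of [read_snp_table()]: the round trip through write and re-read is
#' lossless for all record fields, with `NA` counts rendered as `"-"`.
#'
#' @param records Pooled site record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(records, path) {
  fmt_count <- function(x) if_else(is.na(x), "-", as.character(x))
  chr_or_blank <- function(nm) {
    if (nm %in% names(records)) dplyr::coalesce(as.character(records[[nm]]), "")
    else rep("", nrow(records))
  }
  out <- tibble(
    `Contig ID` = records$contig,
    `C` = chr_or_blank("chrom"),
    `Ref Pos` = as.character(records$pos),
    `Ref Base` = records$ref,
    `Called Base` = records$called,
    `Impact` = chr_or_blank("impact"),
    `SNP%` = as.character(records$snp_pct),
    `Feature Name` = chr_or_blank("feature"),
    `DNA Change` = chr_or_blank("dna_change"),
    `AA Change` = chr_or_blank("aa_change"),
    `Depth` = as.character(records$depth),
    `A Cnt` = fmt_count(records$a_cnt),
    `C Cnt` = fmt_count(records$c_cnt),
    `G Cnt` = fmt_count(records$g_cnt),
    `T Cnt` = fmt_count(records$t_cnt),
    `Del` = fmt_count(records$del_cnt)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Flag rows whose printed SNP% disagrees with the count arithmetic
#'
#' For each record carrying both a supporting count and a stored `snp_pct`,
#' compares `count / depth` against the stored value and flags rows where the
#' absolute difference exceeds `tol` (default 0.015, i.e. just beyond
#' two-decimal rounding). Discrepant rows are flagged, never dropped: small
#' display-rounding wobble in published tables is expected, and silently
#' rejecting rows would bias the table.
#'
#' @param records Pooled site record tibble.
#' @param tol Tolerance on the absolute difference.
#' @return The records with logical column `snp_pct_flag` and numeric column
#'   `snp_pct_recomputed` appended.
#' @export
flag_snp_pct_discrepancies <- function(records, tol = 0.015) {
  if (nrow(records) == 0) {
    return(mutate(records, snp_pct_recomputed = double(), snp_pct_flag = logical()))
  }
  alt1 <- map_chr(called_alleles(records$called, records$ref),
                  function(a) if (length(a)) a[1] else NA_character_)
  cnt <- allele_count(records, dplyr::coalesce(alt1, records$ref))
  recomputed <- if_else(is.na(cnt), NA_real_, cnt / records$depth)
  mutate(records,
         snp_pct_recomputed = recomputed,
         snp_pct_flag = !is.na(recomputed) & !is.na(.data$snp_pct) &
           abs(recomputed - .data$snp_pct) > tol)
}
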