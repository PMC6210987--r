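#' Sites unique to one line
#'
#' Removes from `records_a` every site that is also called in `records_b`.
#' With `key_mode = "position"` (default) a site is shared if any record of
#' the other line has the same `(contig, pos)` — the contrast is between
#' *sites*, matching how fixed differences between lines are counted. With
#' `key_mode = "allele"` removal additionally requires a shared alt allele,
#' a stricter contrast offered as an option. Input order is preserved.
#'
#' @param records_a,records_b Pooled site record tibbles from two distinct
#'   lines.
#' @param key_mode `"position"` or `"allele"`.
#' @return The subset of `records_a` unique to its line.
#' @export
unique_sites <- function(records_a, records_b, key_mode = c("position", "allele")) {
  key_mode <- match.arg(key_mode)
  for (r in list(records_a, records_b)) {
    if (nrow(r) > 0 && dplyr::n_distinct(r$line) > 1) {
      abort("each input must carry a single line label")
    }
  }
  if (nrow(records_a) > 0 && nrow(records_b) > 0 &&
      records_a$line[1] == records_b$line[1]) {
    abort("records_a and records_b must come from distinct lines")
  }
  if (nrow(records_a) == 0 || nrow(records_b) == 0) return(records_a)
  if (key_mode == "position") {
    anti_join(records_a, distinct(records_b, .data$contig, .data$pos),
              by = c("contig", "pos"))
  } else {
    expand_alleles <- function(r) {
      tibble(contig = rep(r$contig, lengths(called_alleles(r$called, r$ref))),
             pos = rep(r$pos, lengths(called_alleles(r$called, r$ref))),
             allele = unlist(called_alleles(r$called, r$ref)))
    }
    shared <- dplyr::inner_join(expand_alleles(records_a), expand_alleles(records_b),
                                by = c("contig", "pos", "allele")) |>
      distinct(.data$contig, .data$pos)
    anti_join(records_a, shared, by = c("contig", "pos"))
  }
}

.region_levels <- c("CDS", "mRNA-noncoding", "ncRNA", "tRNA", "intron", "intergenic")

#' Classify the genomic region of each site
#'
#' Assigns one region label per record from
#' `{CDS, mRNA-noncoding, ncRNA, tRNA, intron, intergenic}` using the
#' feature table: inside a CDS segment wins; otherwise inside an mRNA span it
#' is `intron` when between that gene's CDS segments and `mRNA-noncoding`
#' (UTR) when outside them; otherwise ncRNA then tRNA spans; otherwise
#' intergenic. Precedence when features overlap:
#' CDS > mRNA-noncoding > ncRNA > tRNA > intron > intergenic.
#'
#' @param records Pooled site record tibble.
#' @param features Feature tibble ([read_gff3()]); may be empty.
#' @return Character vector of region labels, one per record.
#' @export
classify_region <- function(records, features) {
  if (nrow(records) == 0) return(character())
  cds <- filter(features, .data$type == "CDS")
  mrna <- filter(features, .data$type == "mRNA")
  ncrna <- filter(features, .data$type %in% c("ncRNA", "ncRNA_gene"))
  trna <- filter(features, .data$type == "tRNA")
  cds_span <- if (nrow(cds)) {
    cds |>
      group_by(.data$gene_id, .data$contig) |>
      summarise(span_start = min(.data$start), span_end = max(.data$end),
                .groups = "drop")
  } else {
    tibble(gene_id = character(), contig = character(),
           span_start = integer(), span_end = integer())
  }
  hit <- function(tbl, contig, pos) {
    nrow(tbl) > 0 && any(tbl$contig == contig & tbl$start <= pos & tbl$end >= pos)
  }
  vapply(seq_len(nrow(records)), function(i) {
    ctg <- records$contig[i]; p <- records$pos[i]
    if (hit(cds, ctg, p)) return("CDS")
    in_mrna <- hit(mrna, ctg, p)
    in_cds_span <- nrow(cds_span) > 0 &&
      any(cds_span$contig == ctg & cds_span$span_start <= p & cds_span$span_end >= p)
    if (in_mrna && !in_cds_span) return("mRNA-noncoding")
    if (hit(ncrna, ctg, p)) return("ncRNA")
    if (hit(trna, ctg, p)) return("tRNA")
    if (in_mrna || in_cds_span) return("intron")
    "intergenic"
  }, character(1))
}

# Impact labels counted as amino-acid-changing, and the coarse display label
# that folds start-loss/stop-gain/stop-loss in with missense.
.aa_changing <- c("non-synonymous", "frameshift", "nonsense", "no-start", "no-stop")
.nsyn_display <- "N-syn"

.impact_matches <- function(impact, classes) {
  fine_in_display <- c("non-synonymous", "nonsense", "no-start", "no-stop")
  impact %in% classes |
    (impact == .nsyn_display & any(fine_in_display %in% classes)) |
    (impact %in% fine_in_display & .nsyn_display %in% classes)
}

#' Filter cascade configuration
#'
#' Thresholds of the candidate-marker filter cascade. Defaults follow the
#' published pipeline: supporting-read fraction >= 0.75 (fixed within the
#' pool, allowing for sequencing error), read depth >= 10, CDS-only,
#' amino-acid-changing impacts, and a minimum of 2 supporting reads at
#' ingestion.
#'
#' @param snp_pct_min Minimum supporting-read fraction, in `[0, 1]`.
#' @param depth_min Minimum read depth (>= 1).
#' @param min_alt_count Minimum supporting reads at ingestion.
#' @param impact_classes Impact labels counted as amino-acid-changing.
#' @param cds_only Keep CDS sites only?
#' @param unique_to_line Label of the focal line (documentation only; the
#'   contrast itself is supplied to [apply_filter_cascade()] as `other`).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(snp_pct_min = 0.75, depth_min = 10L,
                          min_alt_count = 2L, impact_classes = .aa_changing,
                          cds_only = TRUE, unique_to_line = "AR") {
  if (snp_pct_min < 0 || snp_pct_min > 1) abort("snp_pct_min must be in [0, 1]")
  if (depth_min < 1) abort("depth_min must be >= 1")
  structure(list(snp_pct_min = snp_pct_min, depth_min = as.integer(depth_min),
                 min_alt_count = as.integer(min_alt_count),
                 impact_classes = impact_classes, cds_only = cds_only,
                 unique_to_line = unique_to_line),
            class = "filter_config")
}

#' Run the candidate-marker filter cascade
#'
#' Applies the published stage order — unique-to-line, supporting-read
#' fraction, CDS region, amino-acid-changing impact, read depth — tallying
#' records in/out at every stage. The stages are pure intersections, so the
#' final set is order-independent, but the per-stage tallies follow this
#' documented order.
#'
#' Region and impact are taken from the records' own `region` / `impact`
#' columns when present (as when loading the tabular dialect), otherwise
#' joined from `annotations` (see [annotate_variants()]) by
#' `(contig, pos)`.
#'
#' @param records Pooled site record tibble of the focal line.
#' @param annotations Optional effect-annotation tibble.
#' @param config A [filter_config()].
#' @param other Optional record tibble of the contrast line; when supplied,
#'   the unique-to-line stage removes shared sites via [unique_sites()].
#' @param key_mode Site-sharing key for the contrast stage.
#' @return A list of class `filter_result`: `records` (passing records,
#'   sorted by contig then position) and `report` (stage tally tibble).
#' @export
apply_filter_cascade <- function(records, annotations = NULL, config = filter_config(),
                                 other = NULL, key_mode = "position") {
  if (!inherits(config, "filter_config")) abort("config must be a filter_config()")
  cur <- records
  if (nrow(cur) > 0 && (!"region" %in% names(cur) || !"impact" %in% names(cur))) {
    if (!is.null(annotations) && nrow(annotations) > 0) {
      ann <- annotations |>
        group_by(.data$contig, .data$pos) |>
        summarise(ann_region = "CDS",
                  ann_impact = dplyr::first(.data$impact), .groups = "drop")
      cur <- left_join(cur, ann, by = c("contig", "pos"))
      if (!"region" %in% names(cur)) {
        cur <- mutate(cur, region = .data$ann_region)
      } else {
        cur <- mutate(cur, region = dplyr::coalesce(.data$region, .data$ann_region))
      }
      if (!"impact" %in% names(cur)) {
        cur <- mutate(cur, impact = .data$ann_impact)
      } else {
        cur <- mutate(cur, impact = dplyr::coalesce(.data$impact, .data$ann_impact))
      }
      cur <- select(cur, -"ann_region", -"ann_impact")
    } else {
      if (!"region" %in% names(cur)) cur <- mutate(cur, region = NA_character_)
      if (!"impact" %in% names(cur)) cur <- mutate(cur, impact = NA_character_)
    }
  }
  stages <- list()
  note <- function(name, n_in, n_out) {
    stages[[length(stages) + 1]] <<- tibble(stage = name, n_in = n_in, n_out = n_out)
  }

  n0 <- nrow(cur)
  if (!is.null(other)) cur <- unique_sites(cur, other, key_mode = key_mode)
  note("unique-to-line", n0, nrow(cur))

  n1 <- nrow(cur)
  if (n1 > 0) cur <- filter(cur, !is.na(.data$snp_pct),
                            .data$snp_pct >= config$snp_pct_min)
  note(paste0("snp_pct>=", config$snp_pct_min), n1, nrow(cur))

  n2 <- nrow(cur)
  if (config$cds_only && n2 > 0) {
    cur <- filter(cur, !is.na(.data$region), .data$region == "CDS")
  }
  note("region=CDS", n2, nrow(cur))

  n3 <- nrow(cur)
  if (n3 > 0) {
    cur <- filter(cur, !is.na(.data$impact),
                  .impact_matches(.data$impact, config$impact_classes))
  }
  note("impact", n3, nrow(cur))

  n4 <- nrow(cur)
  if (n4 > 0) cur <- filter(cur, .data$depth >= config$depth_min)
  note(paste0("depth>=", config$depth_min), n4, nrow(cur))

  cur <- arrange(cur, .data$contig, .data$pos)
  structure(list(records = cur, report = bind_rows(stages), config = config),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("<filter_result> ", nrow(x$records), " record(s) pass\n", sep = "")
  print(as.data.frame(x$report), row.names = FALSE)
  invisible(x)
}

#' @rdname apply_filter_cascade
#' @param x A `filter_result`.
#' @param ... Unused.
#' @method tidy filter_result
#' @export
tidy.filter_result <- function(x, ...) x$report

#' @rdname apply_filter_cascade
#' @method glance filter_result
#' @export
glance.filter_result <- function(x, ...) {
  tibble(n_input = x$report$n_in[1],
         n_pass = nrow(x$records),
         n_stages = nrow(x$report))
}

#' @rdname apply_filter_cascade
#' @param object A `filter_result`.
#' @method autoplot filter_result
#' @export
autoplot.filter_result <- function(object, ...) {
  d <- object$report |>
    mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = .data$n_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "records surviving stage",
                  title = "Filter cascade") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
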