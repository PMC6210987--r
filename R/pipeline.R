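#' Summarize passing SNPs per gene
#'
#' Distinct gene count plus per-gene SNP multiplicity, sorted by
#' multiplicity (descending) then gene name. The gene id is taken from the
#' `feature` column (tabular dialect) or `gene_id`.
#'
#' @param records Annotated record tibble.
#' @return A list of class `gene_summary`: `n_genes` and `per_gene` tibble
#'   (`gene`, `n_snps`).
#' @export
summarize_genes <- function(records) {
  col <- if ("feature" %in% names(records)) "feature" else "gene_id"
  if (nrow(records) == 0 || !col %in% names(records)) {
    return(structure(list(n_genes = 0L,
                          per_gene = tibble(gene = character(), n_snps = integer())),
                     class = "gene_summary"))
  }
  per_gene <- records |>
    filter(!is.na(.data[[col]])) |>
    count(gene = .data[[col]], name = "n_snps") |>
    arrange(dplyr::desc(.data$n_snps), .data$gene)
  structure(list(n_genes = nrow(per_gene), per_gene = per_gene),
            class = "gene_summary")
}

#' @export
print.gene_summary <- function(x, ...) {
  cat("<gene_summary> ", sum(x$per_gene$n_snps), " SNP(s) in ",
      x$n_genes, " gene(s)\n", sep = "")
  multi <- filter(x$per_gene, .data$n_snps > 1)
  if (nrow(multi)) {
    cat("genes with >1 SNP: ",
        paste0(multi$gene, " (", multi$n_snps, ")", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname summarize_genes
#' @param x,object A `gene_summary`.
#' @param ... Unused.
#' @method tidy gene_summary
#' @export
tidy.gene_summary <- function(x, ...) x$per_gene

#' @rdname summarize_genes
#' @method glance gene_summary
#' @export
glance.gene_summary <- function(x, ...) {
  tibble(n_genes = x$n_genes, n_snps = sum(x$per_gene$n_snps))
}

#' Region and impact distribution of a SNP set
#'
#' Tallies counts and percentages per genomic region (classifying via
#' [classify_region()] unless the records already carry a `region` column),
#' and, within CDS, per impact label. Percentages sum to 100 up to rounding;
#' counts sum to the input size.
#'
#' @param records Pooled site record tibble.
#' @param features Optional feature tibble; required when the records have
#'   no `region` column.
#' @param digits Rounding for displayed percentages.
#' @return A list of class `region_report`: `regions` and `impacts` tibbles.
#' @export
region_report <- function(records, features = NULL, digits = 1) {
  if (nrow(records) == 0) {
    return(structure(list(regions = tibble(region = character(), n = integer(),
                                           pct = double()),
                          impacts = tibble(impact = character(), n = integer(),
                                           pct = double())),
                     class = "region_report"))
  }
  region <- if ("region" %in% names(records) && !anyNA(records$region)) {
    records$region
  } else if (!is.null(features)) {
    classify_region(records, features)
  } else {
    abort("records carry no region column and no features were supplied")
  }
  regions <- tibble(region = factor(region, levels = .region_levels)) |>
    count(.data$region, .drop = FALSE) |>
    mutate(region = as.character(.data$region),
           pct = round(100 * .data$n / sum(.data$n), digits))
  in_cds <- region == "CDS"
  impacts <- if ("impact" %in% names(records) && any(in_cds)) {
    records[in_cds, ] |>
      count(.data$impact) |>
      mutate(pct = round(100 * .data$n / sum(.data$n), digits))
  } else {
    tibble(impact = character(), n = integer(), pct = double())
  }
  structure(list(regions = regions, impacts = impacts), class = "region_report")
}

#' @export
print.region_report <- function(x, ...) {
  cat("<region_report>\n")
  print(as.data.frame(x$regions), row.names = FALSE)
  if (nrow(x$impacts)) {
    cat("impacts within CDS:\n")
    print(as.data.frame(x$impacts), row.names = FALSE)
  }
  invisible(x)
}

#' @rdname region_report
#' @param x,object A `region_report`.
#' @param ... Unused.
#' @method tidy region_report
#' @export
tidy.region_report <- function(x, ...) x$regions

#' @rdname region_report
#' @method autoplot region_report
#' @export
autoplot.region_report <- function(object, ...) {
  d <- filter(object$regions, .data$n > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$region, -.data$n),
                                  y = .data$pct)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$n, " (", .data$pct, "%)")),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "% of SNPs", title = "SNPs by genomic region") +
    ggplot2::theme_minimal()
}

#' Pipeline configuration
#'
#' Bundles every input and threshold of an end-to-end run. Inputs may be
#' paths (FASTA / GFF3 / VCF / tabular dialect) or the corresponding
#' in-memory objects.
#'
#' @param genome `ref_genome` or FASTA path.
#' @param features Feature tibble or GFF3 path.
#' @param records_focal Focal-line records tibble, VCF path or tabular path.
#' @param records_other Optional contrast-line records (same forms).
#' @param lines Two labels, focal first; used when reading VCFs.
#' @param filter A [filter_config()].
#' @param key_mode Site-sharing key for the line contrast.
#' @param primer_length,amplicon_min,amplicon_max Primer design parameters
#'   (see [design_primers()]).
#' @param out_dir Optional output directory for artifacts.
#' @param seed Seed recorded in the run log (the pipeline itself is
#'   deterministic given its inputs).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, features, records_focal,
                            records_other = NULL, lines = c("AR", "AP"),
                            filter = filter_config(), key_mode = "position",
                            primer_length = 20L, amplicon_min = 100L,
                            amplicon_max = 400L, out_dir = NULL, seed = 1L) {
  if (length(lines) != 2 || lines[1] == lines[2]) {
    abort("config error: two distinct line labels required")
  }
  for (p in list(genome, features, records_focal, records_other)) {
    if (is.character(p) && !inherits(p, "ref_genome") && length(p) == 1 &&
        !file.exists(p)) {
      abort(paste0("config error: input path does not exist: ", p))
    }
  }
  structure(list(genome = genome, features = features,
                 records_focal = records_focal, records_other = records_other,
                 lines = lines, filter = filter, key_mode = key_mode,
                 primer_length = primer_length, amplicon_min = amplicon_min,
                 amplicon_max = amplicon_max, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.load_records_input <- function(x, line_label, min_alt_count) {
  if (is.data.frame(x)) return(x)
  if (is.character(x) && length(x) == 1) {
    first <- readLines(x, n = 1)
    if (str_detect(first, "^##fileformat=VCF")) {
      return(read_pool_vcf(x, line_label, min_alt_count = min_alt_count))
    }
    return(read_snp_table(x, line_label, min_alt_count = min_alt_count))
  }
  abort("config error: records input must be a tibble or a path")
}

#' Run the full line-contrast pipeline
#'
#' End to end: load inputs, annotate the focal line's sites against the gene
#' models, run the filter cascade (unique-to-line, SNP%, CDS, impact,
#' depth), summarize genes, tally regions, and design allele-specific
#' primers for the passing SNPs. When `out_dir` is set, writes the final
#' table (tabular dialect), the stage report (TSV + JSON), the gene summary,
#' the primer table and a run log recording every threshold; files are
#' staged in a temporary directory and moved into place atomically at the
#' end. Deterministic given inputs and seed.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `final` (annotated passing
#'   records), `filter` (the [apply_filter_cascade()] result), `genes`
#'   ([summarize_genes()]), `regions` ([region_report()] over the focal
#'   line's unique sites), `primers` ([design_primers()] output), `log`
#'   (character vector), `paths` (when written).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) abort("config error: need a pipeline_config()")
  logline <- character()
  say <- function(...) logline <<- c(logline, paste0(...))
  fail_stage <- function(stage, e) {
    abort(paste0("pipeline failed at stage '", stage, "': ", conditionMessage(e)))
  }
  say("linemarker pipeline; seed=", config$seed,
      "; lines=", paste(config$lines, collapse = " vs "))
  say("thresholds: snp_pct_min=", config$filter$snp_pct_min,
      " depth_min=", config$filter$depth_min,
      " min_alt_count=", config$filter$min_alt_count,
      " cds_only=", config$filter$cds_only,
      " impact_classes=", paste(config$filter$impact_classes, collapse = ","),
      " key_mode=", config$key_mode)

  genome <- tryCatch(
    if (inherits(config$genome, "ref_genome")) config$genome
    else read_genome(config$genome),
    error = function(e) fail_stage("load-genome", e))
  features <- tryCatch(
    if (is.character(config$features)) read_gff3(config$features) else config$features,
    error = function(e) fail_stage("load-annotation", e))
  models <- tryCatch(gene_models(features),
                     error = function(e) fail_stage("gene-models", e))
  say("loaded ", length(genome), " contig(s), ",
      dplyr::n_distinct(models$gene_id), " gene model(s)")

  focal <- tryCatch(
    .load_records_input(config$records_focal, config$lines[1],
                        config$filter$min_alt_count),
    error = function(e) fail_stage("load-focal-records", e))
  other <- if (is.null(config$records_other)) NULL else tryCatch(
    .load_records_input(config$records_other, config$lines[2],
                        config$filter$min_alt_count),
    error = function(e) fail_stage("load-contrast-records", e))
  say("focal records: ", nrow(focal),
      if (!is.null(other)) paste0("; contrast records: ", nrow(other)) else "")

  uniq <- tryCatch(
    if (is.null(other)) focal else unique_sites(focal, other, config$key_mode),
    error = function(e) fail_stage("unique-sites", e))
  ann <- tryCatch(annotate_variants(uniq, models, genome),
                  error = function(e) fail_stage("annotate", e))
  region_vec <- tryCatch(classify_region(uniq, features),
                         error = function(e) fail_stage("classify-region", e))
  if ("region" %in% names(uniq)) {
    uniq$region <- dplyr::coalesce(uniq$region, region_vec)
  } else {
    uniq$region <- region_vec
  }
  ann_sum <- ann |>
    group_by(.data$contig, .data$pos) |>
    summarise(.feature = dplyr::first(.data$gene_id),
              .impact = dplyr::first(.data$impact),
              .dna = dplyr::first(.data$c_notation),
              .aa = dplyr::first(.data$p_notation), .groups = "drop")
  uniq <- left_join(uniq, ann_sum, by = c("contig", "pos"))
  take <- function(existing, new) {
    if (is.null(existing)) new else dplyr::coalesce(existing, new)
  }
  uniq$feature <- take(uniq[["feature"]], uniq$.feature)
  uniq$impact <- take(uniq[["impact"]], uniq$.impact)
  uniq$dna_change <- take(uniq[["dna_change"]], uniq$.dna)
  uniq$aa_change <- take(uniq[["aa_change"]], uniq$.aa)
  uniq <- select(uniq, -".feature", -".impact", -".dna", -".aa")
  say("unique sites: ", nrow(uniq), "; annotated in CDS: ", nrow(ann))

  filt <- tryCatch(
    apply_filter_cascade(uniq, config = config$filter),
    error = function(e) fail_stage("filter-cascade", e))
  for (i in seq_len(nrow(filt$report))) {
    say("stage ", filt$report$stage[i], ": ", filt$report$n_in[i], " -> ",
        filt$report$n_out[i])
  }

  genes <- summarize_genes(filt$records)
  say("final: ", nrow(filt$records), " SNP(s) in ", genes$n_genes, " gene(s)")
  regions <- region_report(uniq)
  primers <- tryCatch(
    design_primers(filt$records, genome, primer_length = config$primer_length,
                   amplicon_min = config$amplicon_min,
                   amplicon_max = config$amplicon_max),
    error = function(e) fail_stage("primer-design", e))
  say("primer trios designed: ", sum(!primers$failed),
      "; failed: ", sum(primers$failed))

  paths <- NULL
  if (!is.null(config$out_dir)) {
    stage_dir <- tempfile("linemarker_out_")
    dir.create(stage_dir, recursive = TRUE)
    disp <- mutate(filt$records, impact = impact_display(.data$impact))
    write_snp_table(disp, file.path(stage_dir, "final_snps.tsv"))
    readr::write_tsv(filt$report, file.path(stage_dir, "filter_report.tsv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(stages = filt$report, regions = regions$regions,
           impacts = regions$impacts, n_genes = genes$n_genes,
           per_gene = genes$per_gene),
      file.path(stage_dir, "filter_report.json"), dataframe = "rows",
      auto_unbox = TRUE, digits = NA)
    readr::write_tsv(genes$per_gene, file.path(stage_dir, "gene_summary.tsv"),
                     progress = FALSE)
    readr::write_tsv(primers, file.path(stage_dir, "primers.tsv"),
                     progress = FALSE)
    writeLines(logline, file.path(stage_dir, "run_log.txt"))
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list.files(stage_dir)
    for (f in files) {
      file.copy(file.path(stage_dir, f), file.path(config$out_dir, f),
                overwrite = TRUE)
    }
    unlink(stage_dir, recursive = TRUE)
    paths <- setNames(file.path(config$out_dir, files), files)
  }
  structure(list(final = filt$records, filter = filt, genes = genes,
                 regions = regions, primers = primers, log = logline,
                 paths = paths),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  writeLines(paste0("  ", x$log))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @method tidy pipeline_result
#' @export
tidy.pipeline_result <- function(x, ...) x$final

#' @rdname run_pipeline
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  tibble(n_pass = nrow(x$final), n_genes = x$genes$n_genes,
         n_primer_sets = sum(!x$primers$failed))
}
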