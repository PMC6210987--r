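#' Read a reference genome from FASTA
#'
#' Loads a (small) reference genome into memory as a named character vector of
#' contig sequences. Sequences are upper-cased; only the bases `A`, `C`, `G`,
#' `T` and the placeholder `N` are accepted — IUPAC ambiguity codes other than
#' `N` are rejected, because downstream codon arithmetic and primer design
#' assume unambiguous bases. All coordinates used against the genome are
#' 1-based and inclusive.
#'
#' @param path Path to a FASTA file. Duplicate headers are an error.
#' @return A named character vector of class `ref_genome`, one element per
#'   contig.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgtACGT"), fa)
#' read_genome(fa)
#' @export
read_genome <- function(path) {
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort(paste0("malformed FASTA at '", path, "': ", conditionMessage(e)))
  )
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA header(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- str_to_upper(as.character(set))
  bad <- str_detect(seqs, "[^ACGTN]")
  if (any(bad)) {
    abort(paste0("contig '", ids[which(bad)[1]],
                 "' contains IUPAC ambiguity codes other than N"))
  }
  structure(setNames(seqs, ids), class = "ref_genome")
}

#' Construct a reference genome from in-memory sequences
#'
#' @param sequences Named character vector, contig id -> sequence.
#' @return A `ref_genome` object.
#' @export
ref_genome <- function(sequences) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  if (anyDuplicated(names(sequences))) abort("contig ids must be unique")
  seqs <- setNames(str_to_upper(sequences), names(sequences))
  if (any(str_detect(seqs, "[^ACGTN]"))) {
    abort("genome sequences may only contain A, C, G, T, N")
  }
  structure(seqs, class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat("<ref_genome> ", length(x), " contig(s), ",
      format(sum(nchar(x)), big.mark = ","), " bp total\n", sep = "")
  for (id in head(names(x), 10)) {
    cat("  ", id, ": ", format(nchar(x[[id]]), big.mark = ","), " bp\n", sep = "")
  }
  invisible(x)
}

#' Extract genome subsequence (1-based inclusive)
#'
#' @param genome A `ref_genome`.
#' @param contig Contig id.
#' @param start,end 1-based inclusive bounds.
#' @return Character scalar.
#' @export
genome_seq <- function(genome, contig, start, end) {
  if (!contig %in% names(genome)) abort(paste0("contig '", contig, "' not in genome"))
  len <- nchar(genome[[contig]])
  if (start < 1 || end > len || start > end) {
    abort(paste0("interval ", start, "..", end, " outside contig '", contig,
                 "' (length ", len, ")"))
  }
  substr(genome[[contig]], start, end)
}

#' Write a genome to FASTA
#'
#' @param genome A `ref_genome`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  names(set) <- names(genome)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
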