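# readers for the plain-text formats the pipeline consumes; standard
# genomic formats go through rtracklayer/Biostrings, simple tables through
# readr

#' Read a transcript annotation table
#'
#' Tab-delimited with columns transcript_id, chrom, strand, start, end
#' (1-based inclusive) and optionally coding.
#'
#' @param path File path.
#' @return Tibble suitable for [build_catalog()].
#' @export
read_annotation_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read CAGE tag clusters (chrom, strand, position, width)
#'
#' @param path File path.
#' @return Tibble suitable for [adjust_tss_with_cage()].
#' @export
read_cage_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA file keyed by promoter id.
#' @param seq_window TSS-relative window recorded on the set (default
#'   `c(-300, 100)`), attached as the `"seq_window"` attribute.
#' @return Named character vector of sequences.
#' @export
read_promoter_fasta <- function(path, seq_window = c(-300, 100)) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  attr(out, "seq_window") <- seq_window
  out
}

#' Read a coverage track (bedGraph or wiggle) as a per-base tibble
#'
#' Uses rtracklayer for parsing; intervals are expanded to per-base rows.
#'
#' @param path bedGraph or wig file.
#' @return Tibble with `chrom`, `pos` (1-based), `value`.
#' @export
read_coverage_track <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("rtracklayer is required to read coverage tracks")
  }
  gr <- rtracklayer::import(path)
  n <- GenomicRanges::width(gr)
  tibble(
    chrom = rep(as.character(GenomicRanges::seqnames(gr)), n),
    pos = unlist(lapply(seq_along(gr), function(i)
      seq(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i]))),
    value = rep(gr$score, n)
  )
}

#' Read a peak list from BED (narrowed to center coordinates)
#'
#' @param path BED file; the name column (if any) is taken as the factor.
#' @param factor Factor name used when the BED has no name column.
#' @return Tibble with `factor`, `chrom`, `center`.
#' @export
read_peaks_bed <- function(path, factor = "peak") {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  tibble(
    factor = if (ncol(x) >= 4) as.character(x[[4]]) else factor,
    chrom = as.character(x[[1]]),
    center = floor((x[[2]] + 1 + x[[3]]) / 2)  # BED is 0-based half-open
  )
}

#' Write the annotated promoter catalog
#'
#' @param catalog Catalog tibble (any stage).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  readr::write_tsv(catalog, path)
  invisible(path)
}
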