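#' Build a non-redundant, TSS-unambiguous promoter catalog
#'
#' Reduces a transcript annotation table to a set of promoters in which every
#' retained transcript has an unambiguous TSS. Four rules are applied in
#' order: (1) transcript sets sharing identical start AND end coordinates are
#' collapsed to one representative; (2) among transcripts sharing a TSS, only
#' the shortest is kept; (3) transcripts overlapping another retained
#' transcript with a different TSS are discarded (both members of the pair);
#' (4) transcripts shorter than `min_length` and non-coding transcripts are
#' removed.
#'
#' The TSS is the `start` coordinate on the plus strand and the `end`
#' coordinate on the minus strand. Coordinates are 1-based inclusive.
#'
#' @param annotations Data frame with columns `transcript_id`, `chrom`,
#'   `strand` (`"+"`/`"-"`), `start`, `end`, and either a logical `coding`
#'   column or ids whose `"NR_"` prefix marks non-coding transcripts.
#' @param min_length Minimum transcript length in bp (default 500).
#' @param ignore_strand Should overlap filtering (rule 3) ignore strand?
#'   Default `TRUE` (genomic overlap).
#' @return A tibble of promoter records sorted by (chrom, tss) with columns
#'   `transcript_id`, `chrom`, `strand`, `start`, `end`, `tss`,
#'   `transcript_length`, `coding`. Records rejected for malformed
#'   coordinates are attached as the `"rejected"` attribute with a reason.
#' @export
build_catalog <- function(annotations, min_length = 500, ignore_strand = TRUE) {
  x <- as_tibble(annotations)
  need <- c("transcript_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(x))) {
    abort(paste("annotation table must have columns:", paste(need, collapse = ", ")))
  }
  if (!"coding" %in% names(x)) {
    x$coding <- !startsWith(as.character(x$transcript_id), "NR_")
  }

  bad_strand <- !(x$strand %in% c("+", "-"))
  bad_coord <- !bad_strand & (is.na(x$start) | is.na(x$end) | x$start > x$end)
  rejected <- dplyr::bind_rows(
    dplyr::mutate(x[bad_strand, need], reason = "malformed strand"),
    dplyr::mutate(x[bad_coord, need], reason = "start > end")
  )
  x <- x[!bad_strand & !bad_coord, ]

  x <- dplyr::mutate(x,
    tss = ifelse(.data$strand == "+", .data$start, .data$end),
    transcript_length = .data$end - .data$start + 1L
  )

  # rule 1: identical (chrom, strand, start, end) -> one representative
  x <- dplyr::arrange(x, .data$chrom, .data$start, .data$end, .data$transcript_id)
  x <- dplyr::distinct(x, .data$chrom, .data$strand, .data$start, .data$end,
    .keep_all = TRUE
  )

  # rule 2: per shared TSS keep the shortest transcript
  x <- dplyr::arrange(x, .data$chrom, .data$strand, .data$tss,
    .data$transcript_length, .data$transcript_id)
  x <- dplyr::distinct(x, .data$chrom, .data$strand, .data$tss, .keep_all = TRUE)

  # rule 3: discard both members of overlapping pairs with different TSSs
  drop <- rep(FALSE, nrow(x))
  grp <- if (ignore_strand) x$chrom else paste(x$chrom, x$strand)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2) next
    s <- x$start[idx]; e <- x$end[idx]; t <- x$tss[idx]
    ord <- order(s)
    idx <- idx[ord]; s <- s[ord]; e <- e[ord]; t <- t[ord]
    run_max_e <- cummax(e)
    for (i in 2:length(idx)) {
      if (run_max_e[i - 1] < s[i]) next  # no earlier interval reaches this one
      js <- which(e[1:(i - 1)] >= s[i])
      for (j in js) {
        if (t[j] != t[i]) {
          drop[idx[i]] <- TRUE
          drop[idx[j]] <- TRUE
        }
      }
    }
  }
  x <- x[!drop, ]

  # rule 4: length and coding filters
  x <- x[x$transcript_length >= min_length & x$coding, ]

  out <- dplyr::arrange(
    dplyr::select(x, "transcript_id", "chrom", "strand", "start", "end",
      "tss", "transcript_length", "coding"),
    .data$chrom, .data$tss
  )
  attr(out, "rejected") <- rejected
  out
}

#' Adjust annotated TSSs with CAGE tag clusters
#'
#' For every promoter with at least one same-strand CAGE cluster within
#' `max_dist` bp of its annotated TSS, the nearest cluster's position
#' replaces the TSS and the cluster's width and shape class are attached.
#' Distance ties break toward the smaller genomic coordinate.
#'
#' @param records Promoter catalog from [build_catalog()].
#' @param clusters Data frame with columns `chrom`, `strand`, `position`,
#'   `width` (bp between the 10% and 90% tag quantiles).
#' @param max_dist Maximum distance in bp (default 300).
#' @param focused_max_width Width below which a cluster is focused
#'   (default 10).
#' @return `records` with updated `tss` plus `cage_width` and `shape_class`
#'   columns (`NA` where no cluster was within reach).
#' @export
adjust_tss_with_cage <- function(records, clusters, max_dist = 300,
                                 focused_max_width = 10) {
  records <- as_tibble(records)
  clusters <- as_tibble(clusters)
  records$cage_width <- NA_real_
  records$shape_class <- NA_character_
  if (nrow(clusters) == 0) return(records)
  key <- paste(clusters$chrom, clusters$strand)
  split_idx <- split(seq_len(nrow(clusters)), key)
  for (i in seq_len(nrow(records))) {
    k <- paste(records$chrom[i], records$strand[i])
    ci <- split_idx[[k]]
    if (is.null(ci)) next
    pos <- clusters$position[ci]
    d <- abs(pos - records$tss[i])
    ok <- d <= max_dist
    if (!any(ok)) next
    ci <- ci[ok]; pos <- pos[ok]; d <- d[ok]
    best <- ci[order(d, pos)][1]
    records$tss[i] <- clusters$position[best]
    records$cage_width[i] <- clusters$width[best]
    records$shape_class[i] <- call_promoter_shape(clusters$width[best],
      focused_max_width)
  }
  records
}

#' Classify promoter shape from CAGE cluster width
#'
#' A promoter is focused iff its CAGE tag-cluster width (distance between the
#' 10% and 90% tag quantiles) is strictly smaller than `focused_max_width`.
#'
#' @param width Cluster width(s) in bp, non-negative.
#' @param focused_max_width Strict upper bound for the focused class
#'   (default 10).
#' @return Character vector, `"focused"` or `"dispersed"`.
#' @export
call_promoter_shape <- function(width, focused_max_width = 10) {
  if (any(is.na(width)) || any(width < 0)) abort("CAGE widths must be >= 0")
  ifelse(width < focused_max_width, "focused", "dispersed")
}
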