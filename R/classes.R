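#' Assign circadian transcription factor (CTF) binding to promoters
#'
#' A promoter is CTF-bound iff at least one peak center of any supplied
#' factor (BMAL1, REV-ERB a/b, E4BP4, CLK, ...) lies within `window` bp of
#' its TSS (boundaries inclusive). Per-factor flags are retained.
#'
#' @param promoters Tibble with `transcript_id`, `chrom`, `tss`.
#' @param peaks Tibble with `factor`, `chrom`, `center` (peak center bp).
#' @param window Half window in bp (default 3000; fly CLK convention: 2000).
#' @return `promoters` plus one logical column `ctf_<factor>` per factor and
#'   a combined `ctf_bound`.
#' @export
assign_ctf_binding <- function(promoters, peaks, window = 3000) {
  promoters <- as_tibble(promoters)
  factors <- unique(peaks$factor)
  bound_any <- rep(FALSE, nrow(promoters))
  for (f in factors) {
    pk <- peaks[peaks$factor == f, ]
    centers <- split(pk$center, pk$chrom)
    centers <- lapply(centers, sort)
    flag <- vapply(seq_len(nrow(promoters)), function(i) {
      cs <- centers[[promoters$chrom[i]]]
      if (is.null(cs) || !length(cs)) return(FALSE)
      j <- findInterval(promoters$tss[i], cs)
      d <- Inf
      if (j >= 1) d <- min(d, abs(promoters$tss[i] - cs[j]))
      if (j < length(cs)) d <- min(d, abs(cs[j + 1] - promoters$tss[i]))
      d <= window
    }, logical(1))
    promoters[[paste0("ctf_", tolower(gsub("[^A-Za-z0-9]", "", f)))]] <- flag
    bound_any <- bound_any | flag
  }
  promoters$ctf_bound <- bound_any
  promoters
}

#' Low-CpG flag
#'
#' TRUE iff the CpG observed/expected ratio is strictly below the threshold
#' (the bimodal ratio distribution motivates the 0.5 split).
#'
#' @param cpg_ratio Ratios, >= 0.
#' @param threshold Split point (default 0.5).
#' @return Logical vector (TRUE = LCpG).
#' @export
lcpg_flag <- function(cpg_ratio, threshold = 0.5) {
  stopifnot(all(cpg_ratio >= 0, na.rm = TRUE))
  cpg_ratio < threshold
}

PROMOTER_CLASSES <- c("SCP", "circ_type_I", "circ_type_II", "circ_other",
  "const_type_I", "const_type_II", "const_other", "silent", "other")

#' Promoter taxonomy
#'
#' Assigns the promoter class from resolved flags. Strong circadian
#' promoters (SCPs) are circadian, CTF-bound, and TATA-containing or
#' CpG-poor. Circadian type I: circadian, not CTF-bound, TATA or LCpG;
#' circadian type II: circadian, CTF-bound, TATA-less and HCpG; remaining
#' circadian promoters are `circ_other`. Constitutive type I / type II are
#' the non-CTF analogues; CTF-bound constitutive promoters are
#' `const_other`. Silent and other rhythm labels pass through. The labels
#' are mutually exclusive and exhaustive.
#'
#' @param rhythm_label Factor/character: circadian, constitutive, silent,
#'   other.
#' @param ctf_bound,tata,lcpg Logical flags.
#' @return Factor of class labels (SCP, circ_type_I, circ_type_II,
#'   circ_other, const_type_I, const_type_II, const_other, silent, other).
#' @export
classify_promoter <- function(rhythm_label, ctf_bound, tata, lcpg) {
  n <- length(rhythm_label)
  stopifnot(length(ctf_bound) == n, length(tata) == n, length(lcpg) == n)
  if (anyNA(ctf_bound) || anyNA(tata) || anyNA(lcpg) || anyNA(rhythm_label)) {
    abort("classify_promoter requires resolved (non-missing) flags")
  }
  rl <- as.character(rhythm_label)
  core <- tata | lcpg
  label <- character(n)
  circ <- rl == "circadian"
  const <- rl == "constitutive"
  label[circ & ctf_bound & core] <- "SCP"
  label[circ & !ctf_bound & core] <- "circ_type_I"
  label[circ & ctf_bound & !core] <- "circ_type_II"
  label[circ & !ctf_bound & !core] <- "circ_other"
  label[const & !ctf_bound & core] <- "const_type_I"
  label[const & !ctf_bound & !core] <- "const_type_II"
  label[const & ctf_bound] <- "const_other"
  label[rl == "silent"] <- "silent"
  label[rl == "other"] <- "other"
  factor(label, levels = PROMOTER_CLASSES)
}

#' Fisher enrichment of a flag between two promoter groups
#'
#' Sample odds ratio `ad/bc` (with a 0.5 continuity correction when any cell
#' is zero) and a two-sided Fisher exact p value for the 2x2 table of flag
#' frequency in group A versus group B.
#'
#' @param group_a_flags,group_b_flags Logical vectors (flag per member).
#' @return Tibble with counts, `odds_ratio`, `p_value`.
#' @export
enrichment_table <- function(group_a_flags, group_b_flags) {
  a <- sum(group_a_flags); b <- sum(!group_a_flags)
  c_ <- sum(group_b_flags); d <- sum(!group_b_flags)
  if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) {
    return(tibble(a_flag = a, a_noflag = b, b_flag = c_, b_noflag = d,
      odds_ratio = NA_real_, p_value = NA_real_))
  }
  cc <- if (any(c(a, b, c_, d) == 0)) 0.5 else 0
  or <- ((a + cc) * (d + cc)) / ((b + cc) * (c_ + cc))
  p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
  tibble(a_flag = a, a_noflag = b, b_flag = c_, b_noflag = d,
    odds_ratio = or, p_value = p)
}
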