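#' Specification of a synthetic promoter cohort
#'
#' Defines the stated world the generator emits: class mixture, per-class
#' activity/amplitude/phase distributions, chromatin-track shapes, sequence
#' composition, and noise. Defaults emulate the statistical structure of the
#' mouse liver data the pipeline was designed around: log-normal activities,
#' circadian relative amplitudes of 0.15-0.7 (highest for SCPs), uniform
#' phases, bimodal CpG ratios split at 0.5, TATA boxes planted at -30,
#' nucleosome-depleted regions of class-dependent depth, +1 nucleosomes near
#' +120 with ~185 bp phasing, promoter-proximal Pol II peaks at ~+50, and
#' negative-binomial nascent counts (dispersion 0.05) at 12 time points over
#' two days.
#'
#' @param n_promoters Cohort size (default 2000).
#' @param mixture Named class proportions over SCP, circ_type_I,
#'   circ_type_II, circ_other, const_type_I, const_type_II, silent; must sum
#'   to 1.
#' @param nb_dispersion Negative-binomial dispersion of nascent counts.
#' @param n_timepoints,dt Count sampling design (default 12 samples, 4 h).
#' @param track_depth Poisson sampling depth multiplier for tracks; the
#'   default leaves single-promoter nucleosome tracks too noisy for
#'   single-promoter rhythm calls, forcing the population-level path.
#' @param seed Seed stored with the spec (used by [generate_cohort()]).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_promoters = 2000,
                        mixture = c(SCP = 0.08, circ_type_I = 0.10,
                          circ_type_II = 0.07, circ_other = 0.05,
                          const_type_I = 0.15, const_type_II = 0.35,
                          silent = 0.20),
                        nb_dispersion = 0.05, n_timepoints = 12, dt = 4,
                        track_depth = 30, seed = 1L) {
  stopifnot(abs(sum(mixture) - 1) < 1e-8, all(mixture >= 0))
  class_par <- list(
    #          meanlog sdlog  relamp_lo relamp_hi tata  ndr  pause h2az
    SCP           = list(ml = log(8),    sl = 0.6, ra = c(0.35, 0.70), p_tata = 0.6, ndr = 0.20, pause = 10,  h2az = 0.3),
    circ_type_I   = list(ml = log(2),    sl = 0.7, ra = c(0.15, 0.50), p_tata = 0.6, ndr = 0.90, pause = 1.5, h2az = 0.8),
    circ_type_II  = list(ml = log(3),    sl = 0.7, ra = c(0.15, 0.50), p_tata = 0,   ndr = 0.45, pause = 4,   h2az = 0.9),
    circ_other    = list(ml = log(2),    sl = 0.7, ra = c(0.15, 0.40), p_tata = 0,   ndr = 0.60, pause = 1,   h2az = 0.8),
    const_type_I  = list(ml = log(2),    sl = 0.7, ra = c(0, 0),       p_tata = 0.6, ndr = 0.90, pause = 1,   h2az = 0.8),
    const_type_II = list(ml = log(3),    sl = 0.8, ra = c(0, 0),       p_tata = 0,   ndr = 0.15, pause = 3,   h2az = 1.2),
    silent        = list(ml = log(0.002), sl = 0.35, ra = c(0, 0),      p_tata = 0,   ndr = 0.70, pause = 0.1, h2az = 0.8)
  )
  structure(
    list(n_promoters = n_promoters, mixture = mixture,
      class_par = class_par, nb_dispersion = nb_dispersion,
      n_timepoints = n_timepoints, dt = dt, track_depth = track_depth,
      seed = seed),
    class = "cohort_spec"
  )
}

CLASS_FLAGS <- function(class, p_tata) {
  # flags consistent with the taxonomy definitions
  switch(class,
    SCP = ,
    circ_type_I = ,
    const_type_I = {
      tata <- runif(1) < p_tata
      lcpg <- if (!tata) TRUE else runif(1) < 0.7
      list(tata = tata, lcpg = lcpg)
    },
    circ_type_II = ,
    const_type_II = ,
    circ_other = list(tata = FALSE, lcpg = FALSE),
    silent = list(tata = runif(1) < 0.1, lcpg = runif(1) < 0.3)
  )
}

# iid DNA with given GC, as character vector of bases
random_bases <- function(n, gc) {
  sample(DNA_BASES, n, replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# steer the CpG observed/expected ratio of the -100..+100 window (string
# indices `region`) toward `target` by inserting or destroying CG
# dinucleotides, avoiding `protect`ed indices
adjust_cpg <- function(bases, region, target, protect = integer(),
                       tol = 0.04, max_iter = 400) {
  ratio_of <- function(b) {
    s <- b[region]
    cg <- sum(s[-length(s)] == "C" & s[-1] == "G")
    nC <- sum(s == "C"); nG <- sum(s == "G")
    if (nC == 0 || nG == 0) 0 else cg * length(s) / (nC * nG)
  }
  for (iter in seq_len(max_iter)) {
    r <- ratio_of(bases)
    if (abs(r - target) <= tol) return(bases)
    if (r < target) {
      # plant a CG at a random editable position pair
      cand <- setdiff(region[-length(region)], c(protect, protect - 1L))
      i <- sample(cand, 1)
      bases[i] <- "C"; bases[i + 1] <- "G"
    } else {
      s <- bases[region]
      cg_at <- region[which(s[-length(s)] == "C" & s[-1] == "G")]
      cg_at <- setdiff(cg_at, c(protect, protect - 1L))
      if (!length(cg_at)) return(bases)
      i <- sample(rep(cg_at, 2), 1)  # rep() guards length-1 sample()
      bases[i + 1] <- sample(c("A", "T"), 1)
    }
  }
  abort(sprintf("CpG target %.2f infeasible for this GC background", target))
}

#' Bundled synthetic core-promoter PCMs
#'
#' Consensus-shaped position count matrices for the TATA box, BREu and BREd
#' core promoter elements, constructed for this package (synthetic stand-ins
#' for curated motif-database matrices, which cannot be redistributed here).
#'
#' @param which `"tata"`, `"breu"`, or `"bred"`.
#' @return 4 x w count matrix (rows A, C, G, T).
#' @export
bundled_pcm <- function(which = c("tata", "breu", "bred")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, "_synthetic.jaspar"),
    package = "circprom")
  if (!nzchar(path)) abort("bundled PCM not found")
  read_jaspar(path)
}

#' Generate a synthetic promoter cohort with planted ground truth
#'
#' Emits every input the pipeline consumes: a transcript annotation table
#' (with planted redundancies exercising the catalog rules), promoter
#' sequences with TATA boxes planted at -30 and CpG ratios steered to
#' class-dependent targets, nascent count matrices with cosinor-modulated
#' negative-binomial counts, CAGE clusters (focused for TATA/LCpG promoters),
#' CTF peak lists for bound classes, and (optionally) MNase / Pol II / H2A.Z
#' tracks with NDR troughs, phased +1/+2 nucleosomes and promoter-proximal
#' pause peaks. Deterministic given the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @param tracks Emit per-promoter chromatin tracks for the first
#'   `n_track_promoters` promoters? (default FALSE).
#' @param n_track_promoters Number of promoters given tracks (default 200).
#' @param seq_window Sequence window around the TSS (default `c(-300, 100)`).
#' @param outdir Optional directory: writes FASTA, TSV, BED and bedGraph
#'   files mirroring the in-memory objects.
#' @return List with `annotations`, `sequences` (named character,
#'   sense-strand), `counts` (matrix with times as colnames),
#'   `feature_lengths`, `library_sizes`, `times`, `cage`, `ctf_peaks`,
#'   `truth` (per-promoter planted parameters), and optionally `tracks`.
#' @export
generate_cohort <- function(spec = cohort_spec(), tracks = FALSE,
                            n_track_promoters = 200,
                            seq_window = c(-300, 100), outdir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  run_with_seed(spec$seed, {
    n <- spec$n_promoters
    classes <- sample(names(spec$mixture), n, replace = TRUE,
      prob = spec$mixture)
    ids <- sprintf("NM_%06d", seq_len(n))
    spacing <- 12000L
    tss <- 5000L + spacing * (seq_len(n) - 1L)
    strand <- rep(c("+", "-"), length.out = n)
    tx_len <- sample(800:5000, n, replace = TRUE)
    start <- ifelse(strand == "+", tss, tss - tx_len + 1L)
    end <- ifelse(strand == "+", tss + tx_len - 1L, tss)

    truth <- tibble(
      transcript_id = ids, class = classes, chrom = "synth1",
      strand = strand, tss = tss, transcript_length = tx_len
    )
    par <- spec$class_par
    truth$activity <- vapply(classes, function(cl)
      rlnorm(1, par[[cl]]$ml, par[[cl]]$sl), numeric(1))
    truth$relamp <- vapply(classes, function(cl) {
      ra <- par[[cl]]$ra
      if (ra[2] <= 0) 0 else runif(1, ra[1], ra[2])
    }, numeric(1))
    truth$phase <- runif(n, 0, 24)
    flags <- lapply(seq_len(n), function(i)
      CLASS_FLAGS(classes[i], par[[classes[i]]]$p_tata))
    truth$tata <- vapply(flags, `[[`, logical(1), "tata")
    truth$lcpg <- vapply(flags, `[[`, logical(1), "lcpg")
    truth$cpg_target <- ifelse(truth$lcpg, runif(n, 0.20, 0.42),
      runif(n, 0.58, 0.95))
    truth$ctf_bound <- classes %in% c("SCP", "circ_type_II") |
      (classes == "silent" & runif(n) < 0.1)
    truth$rhythm_class <- dplyr::case_when(
      classes == "silent" ~ "silent",
      startsWith(classes, "const") ~ "constitutive",
      TRUE ~ "circadian"
    )

    # --- annotations, with planted redundancies for the catalog rules ---
    ann <- tibble(transcript_id = ids, chrom = "synth1", strand = strand,
      start = start, end = end)
    dup <- ann[seq_len(min(20, n)), ]
    dup$transcript_id <- paste0(dup$transcript_id, "dup")
    shared_tss <- ann[seq_len(min(10, n)), ]
    shared_tss$transcript_id <- paste0(shared_tss$transcript_id, "alt")
    longer <- pmax(shared_tss$end - shared_tss$start + 1L + 600L, 1L)
    shared_tss$end <- ifelse(shared_tss$strand == "+",
      shared_tss$start + longer - 1L, shared_tss$end)
    shared_tss$start <- ifelse(shared_tss$strand == "-",
      shared_tss$end - longer + 1L, shared_tss$start)
    nr <- tibble(transcript_id = sprintf("NR_%06d", 1:5), chrom = "synth1",
      strand = "+", start = tss[1:5] + 6000L, end = tss[1:5] + 6900L)
    annotations <- dplyr::bind_rows(ann, dup, shared_tss, nr)
    annotations <- annotations[sample.int(nrow(annotations)), ]

    # --- sequences ---
    tata_pcm <- bundled_pcm("tata")
    tata_probs <- regularize_pcm(tata_pcm)
    w_tata <- ncol(tata_pcm)
    offs <- offsets_from(seq_window[1], seq_window[2] - seq_window[1])
    seq_len_total <- length(offs)
    region_idx <- which(offs >= -100 & offs <= 100)
    tata_start_idx <- which(offs == -30)
    sequences <- character(n)
    for (i in seq_len(n)) {
      gc <- if (truth$lcpg[i]) 0.45 else 0.55
      bases <- random_bases(seq_len_total, gc)
      protect <- integer()
      if (truth$tata[i]) {
        draw <- vapply(seq_len(w_tata), function(j)
          sample(DNA_BASES, 1, prob = tata_probs[, j]), character(1))
        idx <- tata_start_idx + seq_len(w_tata) - 1L
        bases[idx] <- draw
        protect <- idx
      }
      bases <- adjust_cpg(bases, region_idx, truth$cpg_target[i],
        protect = protect)
      sequences[i] <- paste(bases, collapse = "")
    }
    names(sequences) <- ids

    # --- nascent counts ---
    times <- seq(0, by = spec$dt, length.out = spec$n_timepoints)
    lib <- round(2e7 * rlnorm(spec$n_timepoints, 0, 0.05))
    mu_rpkm <- outer(seq_len(n), seq_along(times), function(i, j) {
      truth$activity[i] *
        (1 + truth$relamp[i] * cos(2 * pi / 24 * (times[j] - truth$phase[i])))
    })
    mu_counts <- mu_rpkm * outer(tx_len, lib) / 1e9
    counts <- matrix(
      rnbinom(length(mu_counts), mu = pmax(mu_counts, 1e-8),
        size = 1 / spec$nb_dispersion),
      nrow = n, dimnames = list(ids, times))

    # --- CAGE clusters ---
    has_cage <- runif(n) < 0.9
    focused <- truth$tata | truth$lcpg
    cage_width <- ifelse(focused, sample(1:8, n, replace = TRUE),
      sample(15:80, n, replace = TRUE))
    cage <- tibble(
      chrom = "synth1", strand = strand,
      position = tss + sample(-5:5, n, replace = TRUE) *
        ifelse(strand == "+", 1L, -1L),
      width = cage_width
    )[has_cage, ]
    truth$cage_width <- ifelse(has_cage, cage_width, NA_real_)

    # --- CTF peaks ---
    bound <- which(truth$ctf_bound)
    ctf_factors <- c("BMAL1", "REV-ERBa", "E4BP4")
    ctf_peaks <- dplyr::bind_rows(lapply(bound, function(i) {
      fs <- sample(ctf_factors, sample(1:2, 1))
      tibble(factor = fs, chrom = "synth1",
        center = tss[i] + sample(-1500:1500, length(fs), replace = TRUE))
    }))
    # decoy peaks far from any TSS (in the 12 kb gaps, > 3 kb from TSSs)
    decoys <- tibble(factor = "BMAL1", chrom = "synth1",
      center = tss[seq_len(min(50, n))] + 8000L)
    ctf_peaks <- dplyr::bind_rows(ctf_peaks, decoys)

    out <- list(annotations = annotations, sequences = sequences,
      counts = counts, feature_lengths = tx_len, library_sizes = lib,
      times = times, cage = cage, ctf_peaks = ctf_peaks, truth = truth,
      spec = spec)

    if (tracks) {
      nt <- min(n_track_promoters, n)
      out$tracks <- generate_tracks(truth[seq_len(nt), ], spec)
    }
    if (!is.null(outdir)) write_cohort(out, outdir)
    out
  })
}

# class-shaped chromatin tracks over offsets -300..+500 with Poisson noise
generate_tracks <- function(truth, spec) {
  offs <- offset_seq(-300, 500)
  par <- spec$class_par
  depth <- spec$track_depth
  gauss <- function(mu, sd) exp(-((offs - mu)^2) / (2 * sd^2))
  res <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cl <- truth$class[i]
    plus1 <- 120L + sample(-15:15, 1)
    ndr <- par[[cl]]$ndr
    nuc_mu <- 0.25 + 0.9 * (gauss(plus1, 45) + 0.7 * gauss(plus1 + 185, 50) +
      0.5 * gauss(plus1 + 370, 55) + 0.6 * gauss(-220, 60)) -
      (1 - ndr) * 0.55 * gauss(-50, 70)
    nuc_mu <- pmax(nuc_mu, 0.02)
    pol_mu <- 0.05 + par[[cl]]$pause * gauss(50, 35) +
      0.15 * par[[cl]]$pause * as.numeric(offs > 150)
    h2az_mu <- par[[cl]]$h2az * nuc_mu
    res[[i]] <- tibble(
      promoter_id = truth$transcript_id[i], offset = offs,
      mnase = rpois(length(offs), nuc_mu * depth) / depth,
      polii = rpois(length(offs), pol_mu * depth) / depth,
      h2az = rpois(length(offs), h2az_mu * depth) / depth,
      plus1_true = plus1
    )
  }
  dplyr::bind_rows(res)
}

#' Stranded read-start tracks for strand-shift recovery
#'
#' Simulates fragments of fixed length centered on planted point features;
#' top-strand read starts pile up at fragment 5' ends and bottom-strand read
#' starts at the open-interval fragment ends (one past the last fragment
#' base, the BED end convention), so the two pileups are displaced by
#' exactly the fragment length and the optimal equal-and-opposite shift is
#' half the fragment length.
#'
#' @param fragment_length Fragment length in bp (>= 2).
#' @param n_reads Total fragments simulated.
#' @param span Window `c(-L, R)` around each feature set's anchor.
#' @param n_windows Number of windows (promoters) to spread reads over.
#' @param feature_sd Positional jitter of fragment centers (default 20 bp).
#' @param seed Optional seed.
#' @return List with `top` and `bottom` matrices (windows x positions) of
#'   read-start counts and `fragment_length`.
#' @export
generate_reads_for_shift <- function(fragment_length, n_reads = 20000,
                                     span = c(-500, 500), n_windows = 20,
                                     feature_sd = 20, seed = NULL) {
  stopifnot(fragment_length >= 2)
  run_with_seed(seed, {
    width <- span[2] - span[1] + 1
    top <- bottom <- matrix(0, n_windows, width)
    feat <- lapply(seq_len(n_windows), function(i)
      sample(seq(span[1] + 200, span[2] - 200, by = 10), 3))
    per_win <- ceiling(n_reads / n_windows)
    half_lo <- floor(fragment_length / 2)
    half_hi <- fragment_length - 1 - half_lo
    for (i in seq_len(n_windows)) {
      centers <- sample(feat[[i]], per_win, replace = TRUE) +
        round(rnorm(per_win, 0, feature_sd))
      fs <- centers - half_lo          # fragment 5' end
      fe <- centers + half_hi + 1L     # open-interval fragment end
      ok <- fs >= span[1] & fe <= span[2]  # fe already includes the +1
      top_idx <- fs[ok] - span[1] + 1
      bot_idx <- fe[ok] - span[1] + 1
      top[i, ] <- tabulate(top_idx, width)
      bottom[i, ] <- tabulate(bot_idx, width)
    }
    list(top = top, bottom = bottom, fragment_length = fragment_length)
  })
}

# write the cohort out in the plain-text formats the pipeline reads
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$annotations, file.path(outdir, "annotations.tsv"))
  seqs <- Biostrings::DNAStringSet(cohort$sequences)
  Biostrings::writeXStringSet(seqs, file.path(outdir, "promoters.fasta"))
  cnt <- as_tibble(cohort$counts, rownames = "transcript_id")
  readr::write_tsv(cnt, file.path(outdir, "nascent_counts.tsv"))
  readr::write_tsv(cohort$cage, file.path(outdir, "cage_clusters.tsv"))
  bed <- tibble(chrom = cohort$ctf_peaks$chrom,
    start = cohort$ctf_peaks$center - 1L, end = cohort$ctf_peaks$center,
    name = cohort$ctf_peaks$factor)
  readr::write_tsv(bed, file.path(outdir, "ctf_peaks.bed"), col_names = FALSE)
  readr::write_tsv(cohort$truth, file.path(outdir, "ground_truth.tsv"))
  invisible(outdir)
}
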