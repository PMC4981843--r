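# Off-target screening: exact k-mer seed and ungapped extension.
#
# The seed is taken from an arm's 3'-proximal end, where extension blocking
# matters most; poly-T tails and linkers are never seeded (tail binding to
# poly-A is the intended mechanism, and the linker is nonspecific by
# construction). Only the sense strand of each transcript is searched:
# targets are single-stranded mRNAs. A consequence of the single-seed
# design is that a site mutated inside the seed region escapes detection.

#' Screen a blocker design for off-target hybridization sites
#'
#' For each specific arm of the design, takes the exact `seed_len`-mer at
#' the arm's 3'-proximal end, finds every transcriptome position where its
#' reverse complement occurs, extends the match ungapped over the full arm
#' footprint (clipped at transcript ends) counting mismatches, and keeps
#' hits whose perfect-match portion has a duplex Tm within `tm_margin_C` of
#' the arm's on-target Tm. Hits overlapping the design's own target window
#' on its own target are flagged `on_target`.
#'
#' @param design An `oligo_design`.
#' @param transcriptome Transcript tibble to screen against.
#' @param seed_len Exact-seed length (>= 8).
#' @param tm_margin_C Keep hits with perfect-portion Tm >= arm Tm minus this.
#' @param conditions [buffer_conditions()] for hit Tm evaluation.
#'
#' @return A tibble of hits: `oligo_id`, `arm`, `transcript_id`, `start`,
#'   `end` (0-based half-open on the transcript), `matched_len`,
#'   `mismatches`, `tm_C` (perfect-match portion), `on_target`. Zero rows
#'   when nothing binds.
#' @export
screen_offtargets <- function(design, transcriptome, seed_len = 12L,
                              tm_margin_C = 15,
                              conditions = buffer_conditions()) {
  stopifnot(inherits(design, "oligo_design"))
  seed_len <- as.integer(seed_len)
  if (seed_len < 8L) abort("`seed_len` must be >= 8.")
  if (!is.data.frame(transcriptome)) abort("`transcriptome` must be a transcript tibble.")
  arms <- list(arm3 = design$arm3)
  if (!is.null(design$arm5)) arms$arm5 <- design$arm5
  oligo_id <- paste0(design$target_id, "_", design$kind, "_blocker")

  hits <- list()
  for (arm_name in names(arms)) {
    arm <- arms[[arm_name]]
    arm_seq <- arm$arm_seq
    La <- nchar(arm_seq)
    if (La < seed_len) {
      abort(sprintf("Arm '%s' (%d nt) is shorter than `seed_len` (%d).",
                    arm_name, La, seed_len))
    }
    site <- revcomp(arm_seq)           # the genomic-sense binding site
    site_kmer <- substr(site, 1L, seed_len) # = revcomp of the arm's 3' seed
    arm_tm <- arm$thermo$tm_C
    for (i in seq_len(nrow(transcriptome))) {
      tseq <- transcriptome$seq[i]
      m <- gregexpr(site_kmer, tseq, fixed = TRUE)[[1]]
      if (m[1L] == -1L) next
      for (p in as.integer(m)) {
        s <- p
        e <- min(p + La - 1L, nchar(tseq))
        tseq_sub <- substr(tseq, s, e)
        site_sub <- substr(site, 1L, e - s + 1L)
        eq <- strsplit(tseq_sub, "", fixed = TRUE)[[1]] ==
          strsplit(site_sub, "", fixed = TRUE)[[1]]
        mism <- sum(!eq)
        run <- longest_true_run(eq)
        if (run$len < 2L) next
        perfect <- substr(tseq_sub, run$start, run$start + run$len - 1L)
        tm <- duplex_thermo(revcomp(perfect), perfect, conditions)$tm_C
        if (tm < arm_tm - tm_margin_C) next
        start0 <- s - 1L
        end0 <- e
        on_tgt <- transcriptome$id[i] == design$target_id &&
          start0 < arm$end && end0 > arm$start
        hits[[length(hits) + 1L]] <- tibble(
          oligo_id = oligo_id, arm = arm_name,
          transcript_id = transcriptome$id[i],
          start = start0, end = end0,
          matched_len = e - s + 1L, mismatches = mism,
          tm_C = tm, on_target = on_tgt
        )
      }
    }
  }
  if (length(hits)) bind_rows(hits) else {
    tibble(oligo_id = character(), arm = character(),
           transcript_id = character(), start = integer(), end = integer(),
           matched_len = integer(), mismatches = integer(), tm_C = numeric(),
           on_target = logical())
  }
}

longest_true_run <- function(x) {
  best_len <- 0L; best_start <- 1L; cur <- 0L
  for (i in seq_along(x)) {
    if (x[i]) {
      cur <- cur + 1L
      if (cur > best_len) { best_len <- cur; best_start <- i - cur + 1L }
    } else cur <- 0L
  }
  list(start = best_start, len = best_len)
}

#' Check that blockers cannot bind a spike-in set
#'
#' A usable spike-in set must have no blocker binding sites, so that
#' spike-in recovery measures blocker specificity rather than blocker
#' activity. Runs [screen_offtargets()] for every design against every
#' spike-in; the check passes when no hits at all are found.
#'
#' @param designs List of `oligo_design` objects (or one).
#' @param spikeins Transcript tibble of spike-in species.
#' @param ... Passed to [screen_offtargets()].
#'
#' @return A list with `pass` (logical), `hits` (tibble of any offending
#'   hits) and `n_designs`, `n_spikeins`.
#' @export
check_spikein_compatibility <- function(designs, spikeins, ...) {
  if (inherits(designs, "oligo_design")) designs <- list(designs)
  if (!length(designs)) abort("`designs` must be non-empty.")
  if (!is.data.frame(spikeins) || nrow(spikeins) == 0L) {
    abort("`spikeins` must be a non-empty transcript tibble.")
  }
  hits <- bind_rows(map(designs, screen_offtargets, transcriptome = spikeins, ...))
  hits <- hits[!hits$on_target, , drop = FALSE]
  list(pass = nrow(hits) == 0L, hits = hits,
       n_designs = length(designs), n_spikeins = nrow(spikeins))
}
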