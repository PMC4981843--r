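# Seeded generators for every fixture the other modules need.
#
# All generators are bit-reproducible given (seed, parameters). Each draws
# from a named RNG stream derived from the single user seed, so that e.g.
# transcript and count generation from the same seed do not share draws.
# Every generated object is synthetic and labeled as such; the globin-like
# transcripts emulate only the property the design cares about — an
# accessible (beta-like) vs self-binding (alpha-like) 3' end — not real
# globin sequence.

# geometric step of the spike-in concentration ladder; gentle enough that
# the lowest rung stays well above the detection limit at depth 1e6 with
# the default spike-in fraction
LADDER_RATIO <- 1.25

stream_seed <- function(seed, stream) {
  seed <- as.integer(seed)
  h <- sum(utf8ToInt(stream) * seq_len(nchar(stream)))
  (abs(seed) * 7919L + h) %% 2147483549L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Generate a globin-like synthetic transcript
#'
#' Builds a transcript whose 3'-terminal 60 nt are engineered to reproduce
#' the structural dichotomy between the two globin mRNAs: `beta_like` ends
#' are drawn from an A/C alphabet, which admits no intramolecular pairs
#' (neither Watson-Crick nor wobble, nor pairs with the appended poly-A
#' mimic), so the terminal 26-28 nt fold free of self-assembly;
#' `alpha_like` ends carry a forced terminal stem (10 G:C pairs closing at
#' the 3' terminus over the last 30 nt), the tight self-binding structure
#' that competes with blocker hybridization. The transcript body upstream
#' is random-composition ACGT. Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param kind `"alpha_like"` (self-binding 3' end) or `"beta_like"`
#'   (accessible 3' end).
#' @param length Total transcript length (>= 100).
#'
#' @return A one-row transcript tibble.
#' @export
#' @examples
#' assess_accessibility(make_globin_like(1, "beta_like"))$accessible  # TRUE
#' assess_accessibility(make_globin_like(1, "alpha_like"))$accessible # FALSE
make_globin_like <- function(seed, kind = c("beta_like", "alpha_like"),
                             length = 600L) {
  kind <- match.arg(kind)
  length <- as.integer(length)
  if (length < 100L) abort("`length` must be >= 100.")
  with_seed(stream_seed(seed, paste0("globin_", kind)), {
    body <- paste(sample(VALID_BASES, length - 60L, replace = TRUE),
                  collapse = "")
    win <- if (kind == "beta_like") {
      repeat {
        w <- paste(sample(c("A", "C"), 60L, replace = TRUE,
                          prob = c(0.45, 0.55)), collapse = "")
        # avoid long A runs that would collide with spike-in poly-A tails
        # during orthogonality screening
        if (!grepl("AAAAAAAA", w, fixed = TRUE)) break
      }
      w
    } else {
      paste0(strrep("A", 35L), strrep("G", 10L), strrep("A", 5L),
             strrep("C", 10L))
    }
    transcript_tbl(
      id = sprintf("%s_%d", sub("_like", "", kind), as.integer(seed)),
      seq = paste0(body, win),
      species = "synthetic",
      description = sprintf("synthetic %s globin-like transcript (seed %d)",
                            kind, as.integer(seed))
    )
  })
}

#' Generate a blocker-orthogonal poly-adenylated spike-in set
#'
#' Emulates a commercial mix of 92 poly-adenylated artificial mRNA-like
#' species spanning a concentration ladder. Each sequence is rejection
#' sampled so that it shares no `seed_len`-mer with the binding site of any
#' provided blocker arm — the property that makes spike-in recovery a pure
#' specificity readout. Concentrations follow a geometric ladder of
#' `ceiling(n / 4)` levels with 4 species per level and a 1.25x step between
#' levels, an explicitly artificial stand-in for the proprietary
#' formulation. The step is chosen so that every species is detectable at
#' the simulated sequencing depths, keeping the spike-in correlation a pure
#' sampling-noise readout rather than a dropout readout.
#'
#' @param seed Integer seed.
#' @param n Number of species (default 92).
#' @param arm_seqs Character vector of blocker arm sequences (5'->3') the
#'   set must be orthogonal to.
#' @param length Body length of each species (before the poly-A tail).
#' @param tail_a Poly-A tail length appended to each species.
#' @param seed_len k-mer length for the orthogonality rejection test.
#' @param max_tries Bounded retries per species before erroring.
#'
#' @return A transcript tibble with an extra `concentration` column
#'   (relative units).
#' @export
make_spikein_set <- function(seed, n = 92L, arm_seqs = character(),
                             length = 400L, tail_a = 30L, seed_len = 12L,
                             max_tries = 200L) {
  n <- as.integer(n)
  if (n < 1L) abort("`n` must be >= 1.")
  forbidden <- character()
  for (arm in arm_seqs) {
    site <- revcomp(arm)
    if (nchar(site) >= seed_len) {
      forbidden <- c(forbidden,
                     substring(site, 1:(nchar(site) - seed_len + 1L),
                               seed_len:nchar(site)))
    }
  }
  forbidden <- unique(forbidden)
  with_seed(stream_seed(seed, "spikein"), {
    seqs <- character(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        body <- paste(sample(VALID_BASES, length, replace = TRUE),
                      collapse = "")
        cand <- paste0(body, strrep("A", tail_a))
        hit <- length(forbidden) &&
          any(vapply(forbidden, grepl, logical(1), x = cand, fixed = TRUE))
        if (!hit) { seqs[i] <- cand; ok <- TRUE; break }
      }
      if (!ok) {
        abort(sprintf("Could not sample an arm-orthogonal spike-in after %d tries.",
                      max_tries))
      }
    }
    levels <- ceiling(n / 4)
    level <- rep(seq_len(levels), each = 4L)[seq_len(n)]
    out <- transcript_tbl(
      id = sprintf("spike_%03d", seq_len(n)),
      seq = seqs,
      species = "synthetic_spikein",
      description = sprintf("synthetic spike-in, ladder level %d", level)
    )
    out$concentration <- LADDER_RATIO^(max(level) - level)
    out
  })
}

#' Simulation specification for count tables
#'
#' Conditions of the emulated depletion experiment. Defaults reproduce the
#' measured study conditions: a 63.6% total globin fraction in untreated
#' whole-blood libraries, split between alpha (21.4%) and beta (42.2%), and
#' a depletion efficiency of 0.9686 — the per-molecule removal fraction
#' that maps a 63.6% control prevalence to a 5.2% treated prevalence after
#' renormalization.
#'
#' @param seed Integer seed.
#' @param n_spikeins Number of spike-in species (default 92).
#' @param globin_fraction Expected globin fraction of control counts.
#' @param alpha_share Fraction of the globin mass on the alpha-like class.
#' @param depletion_efficiency Fraction of globin molecules removed in
#'   treated samples (before renormalization).
#' @param depth Total reads per sample.
#' @param n_other_genes Number of non-globin, non-spike-in genes.
#' @param spikein_fraction Expected spike-in fraction of control counts.
#' @param n_control,n_treated Number of samples per condition.
#'
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(seed = 1L, n_spikeins = 92L, globin_fraction = 0.636,
                     alpha_share = 21.4 / 63.6, depletion_efficiency = 0.9686,
                     depth = 1e6, n_other_genes = 1000L,
                     spikein_fraction = 0.05, n_control = 1L,
                     n_treated = 1L) {
  if (globin_fraction < 0 || globin_fraction >= 1) {
    abort("`globin_fraction` must be in [0, 1).")
  }
  if (depletion_efficiency < 0 || depletion_efficiency > 1) {
    abort("`depletion_efficiency` must be in [0, 1].")
  }
  if (depth <= 0) abort("`depth` must be > 0.")
  if (globin_fraction + spikein_fraction >= 1) {
    abort("`globin_fraction` + `spikein_fraction` must be < 1.")
  }
  structure(
    list(seed = as.integer(seed), n_spikeins = as.integer(n_spikeins),
         globin_fraction = globin_fraction, alpha_share = alpha_share,
         depletion_efficiency = depletion_efficiency, depth = depth,
         n_other_genes = as.integer(n_other_genes),
         spikein_fraction = spikein_fraction,
         n_control = as.integer(n_control),
         n_treated = as.integer(n_treated)),
    class = "sim_spec"
  )
}

#' Simulate a depletion-experiment count table
#'
#' Draws one multinomial count vector per sample at the specified depth.
#' Control samples put `globin_fraction` of the expected mass on the two
#' globin-like genes (split by `alpha_share`), `spikein_fraction` on the
#' spike-in ladder, and the rest on a fixed long-tailed (log-normal) gene
#' abundance profile shared across conditions. Treated samples multiply the
#' globin mass by `1 - depletion_efficiency` and renormalize, which is what
#' a blocker does: reads lost from globin are redistributed over everything
#' else, spike-ins included, leaving relative non-globin abundances
#' untouched.
#'
#' @param spec A [sim_spec()].
#' @return A long count tibble (`sample`, `condition`, `gene`, `class`,
#'   `count`).
#' @export
simulate_counts <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(stream_seed(spec$seed, "counts"), {
    genes <- c("globin_alpha_like", "globin_beta_like",
               sprintf("spike_%03d", seq_len(spec$n_spikeins)),
               sprintf("gene_%04d", seq_len(spec$n_other_genes)))
    classes <- c("globin_alpha", "globin_beta",
                 rep("spikein", spec$n_spikeins),
                 rep("other", spec$n_other_genes))
    ladder_levels <- rep(seq_len(ceiling(spec$n_spikeins / 4)),
                         each = 4L)[seq_len(spec$n_spikeins)]
    spike_w <- LADDER_RATIO^(max(ladder_levels) - ladder_levels)
    spike_w <- spike_w / sum(spike_w) * spec$spikein_fraction
    other_w <- exp(rnorm(spec$n_other_genes, 0, 1.5))
    other_w <- other_w / sum(other_w) *
      (1 - spec$globin_fraction - spec$spikein_fraction)
    w_control <- c(spec$globin_fraction * spec$alpha_share,
                   spec$globin_fraction * (1 - spec$alpha_share),
                   spike_w, other_w)
    w_treated <- w_control
    w_treated[1:2] <- w_treated[1:2] * (1 - spec$depletion_efficiency)
    w_treated <- w_treated / sum(w_treated)

    draw <- function(w, sample_id, condition) {
      counts <- as.integer(rmultinom(1L, size = spec$depth, prob = w))
      tibble(sample = sample_id, condition = condition, gene = genes,
             class = classes, count = counts)
    }
    out <- bind_rows(
      map(seq_len(spec$n_control), function(i) {
        draw(w_control, sprintf("ctrl_%d", i), "control")
      }),
      map(seq_len(spec$n_treated), function(i) {
        draw(w_treated, sprintf("trt_%d", i), "treated")
      })
    )
    validate_count_tbl(out)
    out
  })
}

#' Simulate a qPCR Ct table
#'
#' Generates replicate Ct values for a control and a treated condition such
#' that `Ct_treated - Ct_control = log_efficiency(true_fold)`, plus a
#' dilution series (undiluted and `dilution_factor`-fold diluted template)
#' per condition, with optional Gaussian Ct noise. With `noise_sd = 0` the
#' table inverts exactly through [qpcr_fold_change()] and
#' [qpcr_efficiency()].
#'
#' @param seed Integer seed.
#' @param efficiency Amplification efficiency in (1, 2].
#' @param true_fold Generating reduction fold (> 0).
#' @param dilution_factor Dilution step of the series (>= 1).
#' @param replicates Replicates per condition and dilution.
#' @param noise_sd Gaussian Ct noise standard deviation.
#' @param target Target gene label.
#' @param base_ct Control undiluted mean Ct.
#'
#' @return A qPCR tibble (`sample`, `target`, `condition`,
#'   `dilution_factor`, `ct`, `replicate`).
#' @export
simulate_ct <- function(seed = 1L, efficiency = 2, true_fold = 8,
                        dilution_factor = 10, replicates = 3L,
                        noise_sd = 0, target = "globin_alpha_like",
                        base_ct = 20) {
  if (efficiency <= 1 || efficiency > 2) abort("`efficiency` must be in (1, 2].")
  if (true_fold <= 0) abort("`true_fold` must be > 0.")
  with_seed(stream_seed(seed, "qpcr"), {
    grid <- expand.grid(
      condition = c("control", "treated"),
      dilution_factor = unique(c(1, dilution_factor)),
      replicate = seq_len(replicates),
      stringsAsFactors = FALSE
    )
    shift <- ifelse(grid$condition == "treated",
                    log(true_fold) / log(efficiency), 0)
    dil_shift <- log(grid$dilution_factor) / log(efficiency)
    ct <- base_ct + shift + dil_shift + rnorm(nrow(grid), 0, noise_sd)
    out <- tibble(
      sample = sprintf("%s_r%d", grid$condition, grid$replicate),
      target = target,
      condition = grid$condition,
      dilution_factor = grid$dilution_factor,
      ct = ct,
      replicate = grid$replicate
    )
    validate_qpcr_tbl(out)
    out
  })
}
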