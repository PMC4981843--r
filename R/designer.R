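# Linear and circular blocker design.
#
# A blocker masks the anchored oligo-dT priming site of a poly-adenylated
# target: a specific arm, complementary to the 3'-terminal protein-coding
# end (flush with the poly-A junction), plus a poly-T tail that pairs with
# the first bases of the poly-A tail. A circular blocker adds a second arm
# against the transcript's 5' end, joined by a nonspecific linker, to
# exploit the mRNA closed-loop geometry. Arms grow inward from the termini
# one nucleotide at a time until a duplex-Tm criterion is met.

#' Anchored oligo-dT primer specification
#'
#' The reverse-transcription primer the blocker competes with: a poly-T
#' stretch with a degenerate 3' anchor (default T30-VN) that fixes cDNA
#' priming at the poly-A junction.
#'
#' @param t_len Poly-T length of the primer.
#' @param anchor Degenerate 3' suffix in IUPAC codes (e.g. `"VN"`).
#' @return A list of class `primer_spec`.
#' @export
primer_spec <- function(t_len = 30L, anchor = "VN") {
  t_len <- as.integer(t_len)
  if (t_len < 1L) abort("`t_len` must be >= 1.")
  if (!grepl("^[ACGTUBDHKMNRSVWY]*$", anchor)) {
    abort("`anchor` must consist of IUPAC nucleotide codes.")
  }
  structure(list(t_len = t_len, anchor = anchor), class = "primer_spec")
}

#' Preset linker lengths
#'
#' Linker lengths used for the human alpha- and beta-globin circular
#' blockers (55 and 44 nt). These are shipped presets, not derived values.
#'
#' @export
linker_presets <- c(globin_alpha = 55L, globin_beta = 44L)

new_oligo_design <- function(kind, target, arm3, arm5 = NULL, tail_len,
                             linker_len = 0L, linker_seq = "",
                             chemistry = "DNA", block = "phosphate",
                             tm_target_C, conditions, warnings = character()) {
  full_seq <- paste0(strrep("T", tail_len), arm3$arm_seq, linker_seq,
                     if (!is.null(arm5)) arm5$arm_seq else "")
  structure(
    list(
      kind = kind,
      target_id = target$id,
      target_len = nchar(target$seq),
      arm3 = arm3,
      arm5 = arm5,
      tail_len = as.integer(tail_len),
      linker_len = as.integer(linker_len),
      linker_seq = linker_seq,
      blocked_3p = TRUE,
      block = block,
      chemistry = chemistry,
      full_seq = full_seq,
      tm_target_C = tm_target_C,
      conditions = conditions,
      warnings = warnings
    ),
    class = "oligo_design"
  )
}

# grow an arm from a transcript terminus: shortest length whose duplex Tm
# satisfies `accept`; returns the capped length with a warning flag otherwise
grow_arm <- function(target_seq, side = c("3p", "5p"), accept, cap,
                     conditions, warn_flag) {
  side <- match.arg(side)
  len <- nchar(target_seq)
  warnings <- character()
  eff_cap <- min(cap, len)
  if (len < cap) warnings <- c(warnings, paste0("arm_", side, "_capped_by_target_length"))
  chosen <- NULL
  for (L in 2:eff_cap) {
    win <- if (side == "3p") substr(target_seq, len - L + 1L, len) else substr(target_seq, 1L, L)
    th <- duplex_thermo(revcomp(win), win, conditions)
    if (accept(th)) {
      chosen <- list(len = L, seq = win, thermo = th)
      break
    }
  }
  if (is.null(chosen)) {
    L <- eff_cap
    win <- if (side == "3p") substr(target_seq, len - L + 1L, len) else substr(target_seq, 1L, L)
    chosen <- list(len = L, seq = win, thermo = duplex_thermo(revcomp(win), win, conditions))
    warnings <- c(warnings, warn_flag)
  }
  chosen$warnings <- warnings
  chosen
}

arm_record <- function(target_seq, len, side, grown) {
  L <- grown$len
  n <- nchar(target_seq)
  list(
    start = if (side == "3p") n - L else 0L,
    end = if (side == "3p") n else L,
    target_seq = grown$seq,
    arm_seq = revcomp(grown$seq),
    thermo = grown$thermo
  )
}

#' Design a linear blocking oligo
#'
#' Builds a linear blocker for one target: the specific arm is the shortest
#' 3'-terminal target suffix whose perfect-duplex Tm reaches `tm_target_C`
#' (capped at `max_arm`; reaching the cap emits the design with a
#' `arm_3p_tm_below_target` warning flag), preceded by a poly-T tail of
#' `tail_len` nucleotides and ending in a 3' extension block. Assembled
#' 5'->3' as poly-T tail, arm, 3'-block.
#'
#' @param transcript One-row transcript tibble (the target).
#' @param tm_target_C Arm melting-temperature target in Celsius.
#' @param max_arm Maximum arm length in nucleotides.
#' @param tail_len Poly-T tail length (capped at `tail_cap`).
#' @param min_tail Minimum tail length accepted at design time; lower it
#'   (e.g. to 0) to construct deliberately short-tailed candidates for
#'   validation sweeps, and keep the default in [validate_design()].
#' @param conditions [buffer_conditions()] for the Tm model.
#' @param chemistry Annotation only: `"DNA"`, `"LNA"` or `"ZNA"`; backbone
#'   modifications are carried as metadata, not modeled thermodynamically.
#' @param tail_cap Upper bound on `tail_len`.
#'
#' @return An `oligo_design`.
#' @export
#' @examples
#' t <- make_globin_like(1, "beta_like")
#' design_linear(t)
design_linear <- function(transcript, tm_target_C = 70, max_arm = 30L,
                          tail_len = 15L, min_tail = 4L,
                          conditions = buffer_conditions(),
                          chemistry = c("DNA", "LNA", "ZNA"),
                          tail_cap = 15L) {
  chemistry <- match.arg(chemistry)
  transcript <- as_single_transcript(transcript)
  if (tm_target_C <= 0) abort("`tm_target_C` must be > 0.")
  tail_len <- as.integer(tail_len)
  if (tail_len < min_tail) {
    abort(sprintf("`tail_len` (%d) is below `min_tail` (%d).", tail_len, min_tail))
  }
  if (tail_len > tail_cap) {
    abort(sprintf("`tail_len` (%d) exceeds the %d nt tail cap.", tail_len, tail_cap))
  }
  grown <- grow_arm(transcript$seq, "3p",
                    accept = function(th) th$tm_C >= tm_target_C,
                    cap = max_arm, conditions = conditions,
                    warn_flag = "arm_3p_tm_below_target")
  arm3 <- arm_record(transcript$seq, nchar(transcript$seq), "3p", grown)
  new_oligo_design("linear", transcript, arm3, tail_len = tail_len,
                   chemistry = chemistry, tm_target_C = tm_target_C,
                   conditions = conditions, warnings = grown$warnings)
}

# low-complexity linker: repeat a weak-pairing unit, rejecting any unit whose
# reverse complement shares a seed-length k-mer with the target
make_linker <- function(linker_len, target_seq, seed_len = 12L) {
  linker_len <- as.integer(linker_len)
  if (linker_len <= 0L) return("")
  for (unit in c("CT", "CA", "TC", "AC", "TG", "AG")) {
    cand <- substr(strrep(unit, ceiling(linker_len / nchar(unit))), 1L, linker_len)
    site <- revcomp(cand)
    if (nchar(site) < seed_len || !shares_kmer(site, target_seq, seed_len)) {
      return(cand)
    }
  }
  abort("Could not generate a target-orthogonal linker; supply `linker_seq` explicitly.")
}

shares_kmer <- function(a, b, k) {
  if (nchar(a) < k || nchar(b) < k) return(FALSE)
  ka <- substring(a, 1:(nchar(a) - k + 1L), k:nchar(a))
  any(vapply(unique(ka), function(x) grepl(x, b, fixed = TRUE), logical(1)))
}

#' Design a circular blocking oligo
#'
#' Extends [design_linear()] with a second arm against the target's 5' end:
#' the 5' arm is the shortest 5'-terminal target prefix whose duplex Tm
#' falls within `tm_tolerance` of the 3' arm's Tm (capped at `arm5_cap`;
#' when no prefix within the cap satisfies the band, the closest-Tm length
#' is used and an `arm_5p_tm_mismatch` warning flag is set). A nonspecific
#' low-complexity linker, generated to share no seed k-mer with the target,
#' joins the two specific regions. Assembled 5'->3' as poly-T tail, 3' arm,
#' linker, 5' arm, 3'-block; with antiparallel pairing this places the
#' poly-T against the poly-A and lets the oligo's 3' region reach the mRNA
#' 5' end across the closed loop. The segment order is a documented
#' convention, overridable only by assembling manually from the arms.
#'
#' @inheritParams design_linear
#' @param arm5_cap Maximum 5' arm length.
#' @param linker_len Linker length in nucleotides; presets for the human
#'   globin designs are in [linker_presets].
#' @param linker_seq Optional explicit linker sequence (overrides generation).
#' @param tm_tolerance Acceptable |Tm(arm5) - Tm(arm3)| band in Celsius.
#'
#' @return An `oligo_design` with both arms.
#' @export
design_circular <- function(transcript, tm_target_C = 70, arm5_cap = 30L,
                            max_arm = 30L, tail_len = 15L, min_tail = 4L,
                            linker_len = linker_presets[["globin_beta"]],
                            linker_seq = NULL, tm_tolerance = 2.5,
                            conditions = buffer_conditions(),
                            chemistry = c("DNA", "LNA", "ZNA"),
                            tail_cap = 15L) {
  chemistry <- match.arg(chemistry)
  transcript <- as_single_transcript(transcript)
  if (linker_len < 0L) abort("`linker_len` must be >= 0.")
  base <- design_linear(transcript, tm_target_C, max_arm, tail_len, min_tail,
                        conditions, chemistry, tail_cap)
  tm3 <- base$arm3$thermo$tm_C
  grown5 <- grow_arm(transcript$seq, "5p",
                     accept = function(th) abs(th$tm_C - tm3) <= tm_tolerance,
                     cap = arm5_cap, conditions = conditions,
                     warn_flag = "arm_5p_tm_mismatch")
  if ("arm_5p_tm_mismatch" %in% grown5$warnings) {
    # no prefix within the band: fall back to the closest-Tm length
    len <- nchar(transcript$seq)
    eff_cap <- min(arm5_cap, len)
    cand <- map(2:eff_cap, function(L) {
      win <- substr(transcript$seq, 1L, L)
      list(len = L, seq = win, thermo = duplex_thermo(revcomp(win), win, conditions))
    })
    dtm <- map_dbl(cand, function(x) abs(x$thermo$tm_C - tm3))
    best <- cand[[which.min(dtm)]]
    best$warnings <- grown5$warnings
    grown5 <- best
  }
  arm5 <- arm_record(transcript$seq, nchar(transcript$seq), "5p", grown5)
  if (is.null(linker_seq)) {
    linker_seq <- make_linker(linker_len, transcript$seq)
  } else {
    assert_dna(linker_seq, "linker_seq")
    linker_len <- nchar(linker_seq)
  }
  new_oligo_design("circular", transcript, base$arm3, arm5,
                   tail_len = tail_len, linker_len = linker_len,
                   linker_seq = linker_seq, chemistry = chemistry,
                   tm_target_C = tm_target_C, conditions = conditions,
                   warnings = unique(c(base$warnings, grown5$warnings)))
}

#' @export
print.oligo_design <- function(x, ...) {
  cat(sprintf("<oligo_design> %s blocker for '%s' (%s)\n",
              x$kind, x$target_id, x$chemistry))
  cat(sprintf("  3' arm: %d nt [%d,%d), Tm %.1f C\n",
              nchar(x$arm3$arm_seq), x$arm3$start, x$arm3$end,
              x$arm3$thermo$tm_C))
  if (!is.null(x$arm5)) {
    cat(sprintf("  5' arm: %d nt [%d,%d), Tm %.1f C; linker %d nt\n",
                nchar(x$arm5$arm_seq), x$arm5$start, x$arm5$end,
                x$arm5$thermo$tm_C, x$linker_len))
  }
  cat(sprintf("  tail: T x %d; 3' block: %s\n", x$tail_len, x$block))
  cat(sprintf("  oligo 5'->3': %s\n", x$full_seq))
  if (length(x$warnings)) {
    cat("  warnings:", paste(x$warnings, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.oligo_design <- function(x, ...) {
  tibble(
    target_id = x$target_id,
    kind = x$kind,
    chemistry = x$chemistry,
    arm3_start = x$arm3$start,
    arm3_end = x$arm3$end,
    arm3_seq = x$arm3$arm_seq,
    arm3_tm_C = x$arm3$thermo$tm_C,
    arm5_start = if (is.null(x$arm5)) NA_integer_ else x$arm5$start,
    arm5_end = if (is.null(x$arm5)) NA_integer_ else x$arm5$end,
    arm5_seq = if (is.null(x$arm5)) NA_character_ else x$arm5$arm_seq,
    arm5_tm_C = if (is.null(x$arm5)) NA_real_ else x$arm5$thermo$tm_C,
    tail_len = x$tail_len,
    linker_len = x$linker_len,
    blocked_3p = x$blocked_3p,
    full_seq = x$full_seq,
    warnings = paste(x$warnings, collapse = ";")
  )
}

#' Tabulate a list of designs as an order sheet
#'
#' @param designs A list of `oligo_design` objects (or a single one).
#' @return A tibble, one row per design.
#' @export
design_sheet <- function(designs) {
  if (inherits(designs, "oligo_design")) designs <- list(designs)
  bind_rows(map(designs, tidy))
}

#' Validate a blocker design against the masking rules
#'
#' Checks the rules that make a blocker actually mask the anchored oligo-dT
#' priming site: the poly-T tail must be at least `min_tail` nucleotides (a
#' shorter tail does not form a stable masking complex before primer
#' hybridization), the oligo 3' end must carry an extension block, and the
#' 3' arm must sit flush with the transcript's 3' terminus (otherwise the
#' primer's anchored binding site at the poly-A junction stays exposed).
#' Arms whose Tm fell short of the design target are reported as warnings.
#'
#' @param design An `oligo_design`.
#' @param primer A [primer_spec()]; recorded in the finding messages.
#' @param min_tail Minimum acceptable poly-T tail length.
#'
#' @return A tibble of findings with columns `rule`, `level` (`"FAIL"` or
#'   `"WARN"`) and `message`; zero rows means the design passes cleanly.
#'   See [design_passes()].
#' @export
validate_design <- function(design, primer = primer_spec(), min_tail = 4L) {
  stopifnot(inherits(design, "oligo_design"))
  f <- list()
  if (design$tail_len < min_tail) {
    f[[length(f) + 1L]] <- tibble(
      rule = "min_tail", level = "FAIL",
      message = sprintf(
        "poly-T tail of %d nt is below the %d nt minimum for a stable masking complex prior to T%d%s hybridization",
        design$tail_len, min_tail, primer$t_len, primer$anchor
      )
    )
  }
  if (!isTRUE(design$blocked_3p)) {
    f[[length(f) + 1L]] <- tibble(
      rule = "blocked_3p", level = "FAIL",
      message = "oligo 3' end is not extension-blocked; it could prime synthesis itself"
    )
  }
  if (design$arm3$end != design$target_len) {
    f[[length(f) + 1L]] <- tibble(
      rule = "not_flush", level = "FAIL",
      message = sprintf(
        "3' arm ends %d nt before the transcript 3' terminus; the anchored primer site at the poly-A junction is not masked",
        design$target_len - design$arm3$end
      )
    )
  }
  if ("arm_3p_tm_below_target" %in% design$warnings) {
    f[[length(f) + 1L]] <- tibble(
      rule = "arm3_tm", level = "WARN",
      message = sprintf("3' arm Tm %.1f C is below the %.1f C design target at the arm cap",
                        design$arm3$thermo$tm_C, design$tm_target_C)
    )
  }
  if ("arm_5p_tm_mismatch" %in% design$warnings) {
    f[[length(f) + 1L]] <- tibble(
      rule = "arm5_tm", level = "WARN",
      message = "5' arm Tm could not be matched to the 3' arm within tolerance at the cap"
    )
  }
  if (length(f)) bind_rows(f) else tibble(rule = character(), level = character(),
                                          message = character())
}

#' Does a design pass validation?
#'
#' @param findings A findings tibble from [validate_design()].
#' @param allow_warnings If `TRUE` (default) only `FAIL` findings block.
#' @return Logical.
#' @export
design_passes <- function(findings, allow_warnings = TRUE) {
  if (allow_warnings) !any(findings$level == "FAIL") else nrow(findings) == 0L
}

#' Design against the first variant and report arm fit across all variants
#'
#' Sequence variation at the extreme 3' end (terminal indel or motif
#' differences between individuals or paralogs) can abolish blocker binding.
#' This designs a linear blocker against the first supplied variant and then
#' reports, for every variant, the Levenshtein distance between the arm's
#' target window and that variant's 3'-terminal suffix; variants where the
#' arm is not a perfect match are flagged, signaling that re-sequencing or
#' additional oligos are needed.
#'
#' @param variants Transcript tibble of alternative 3'-end sequences of the
#'   same gene (>= 1 row); the first row is the design template.
#' @param ... Passed to [design_linear()].
#'
#' @return A list with `design` (the `oligo_design`) and `report`, a tibble
#'   with one row per variant: `id`, `edit_distance`, `perfect_match`.
#' @export
design_for_variants <- function(variants, ...) {
  if (!is.data.frame(variants) || nrow(variants) < 1L) {
    abort("`variants` must be a transcript tibble with at least one row.")
  }
  d <- design_linear(variants[1L, , drop = FALSE], ...)
  arm_target <- d$arm3$target_seq
  L <- nchar(arm_target)
  report <- bind_rows(map(seq_len(nrow(variants)), function(i) {
    v <- variants$seq[i]
    suf <- substr(v, max(1L, nchar(v) - L + 1L), nchar(v))
    dist <- as.integer(adist(arm_target, suf))
    tibble(id = variants$id[i], edit_distance = dist,
           perfect_match = dist == 0L)
  }))
  list(design = d, report = report)
}

#' Write assembled oligos to FASTA
#'
#' @param designs List of `oligo_design` objects (or one).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_oligo_fasta <- function(designs, path) {
  if (inherits(designs, "oligo_design")) designs <- list(designs)
  tb <- transcript_tbl(
    id = map_chr(designs, function(d) paste0(d$target_id, "_", d$kind, "_blocker")),
    seq = map_chr(designs, "full_seq"),
    description = map_chr(designs, function(d) {
      sprintf("tail=T%d %s 3'-%s", d$tail_len, d$chemistry, d$block)
    })
  )
  write_fasta(tb, path)
}
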