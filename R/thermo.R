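# Nearest-neighbor duplex thermodynamics.
#
# Unified DNA/DNA nearest-neighbor parameters (1 M NaCl reference), applied
# to the DNA-blocker:mRNA-target duplex as a DNA:DNA approximation: the
# design only needs the rank order and approximate Tm of candidate arms, and
# a DNA:RNA table can be slotted in behind the same interface later. The
# parameter table ships as a plain-text file so tests can sum it
# independently of this code.

R_GAS <- 1.9872   # cal/(mol K)
T_REF_K <- 310.15 # 37 C

.nn_env <- new.env(parent = emptyenv())

nn_params <- function() {
  if (is.null(.nn_env$tab)) {
    path <- system.file("extdata", "nn_unified.tsv", package = "oligolock",
                        mustWork = TRUE)
    tab <- read.delim(path, stringsAsFactors = FALSE)
    .nn_env$tab <- setNames(
      lapply(seq_len(nrow(tab)), function(i) c(dH = tab$dH_kcal[i], dS = tab$dS_cal[i])),
      tab$stack
    )
  }
  .nn_env$tab
}

#' Hybridization buffer conditions
#'
#' Monovalent cation concentration (K+ treated as Na+-equivalent for the
#' entropic salt correction) and the concentration of the designing oligo,
#' assumed to be in large molar excess over its target. Defaults are the
#' RNA-seq blocking buffer: 150 mM KCl, 5 uM blocker.
#'
#' @param monovalent_mM Monovalent cation concentration in mM (> 0).
#' @param oligo_uM Oligo concentration in uM (> 0).
#' @param temperature_C Reference temperature for the free energy, in Celsius.
#'
#' @return A list of class `buffer_conditions`.
#' @export
buffer_conditions <- function(monovalent_mM = 150, oligo_uM = 5,
                              temperature_C = 37) {
  if (!is.numeric(monovalent_mM) || monovalent_mM <= 0) {
    abort("`monovalent_mM` must be > 0.")
  }
  if (!is.numeric(oligo_uM) || oligo_uM <= 0) abort("`oligo_uM` must be > 0.")
  structure(
    list(monovalent_mM = monovalent_mM, oligo_uM = oligo_uM,
         temperature_C = temperature_C),
    class = "buffer_conditions"
  )
}

#' @export
print.buffer_conditions <- function(x, ...) {
  cat(sprintf("<buffer_conditions> %g mM monovalent, %g uM oligo, %g C\n",
              x$monovalent_mM, x$oligo_uM, x$temperature_C))
  invisible(x)
}

thermo_result <- function(dH, dS, conditions, no_duplex = FALSE) {
  if (no_duplex) {
    res <- list(dH = 0, dS = 0, dG37 = 0, tm_C = NA_real_,
                conditions = conditions, no_duplex = TRUE)
    return(structure(res, class = "thermo_result"))
  }
  tm_K <- 1000 * dH / (dS + R_GAS * log(conditions$oligo_uM * 1e-6))
  structure(
    list(
      dH = dH,
      dS = dS,
      dG37 = dH - T_REF_K * dS / 1000,
      tm_C = tm_K - 273.15,
      conditions = conditions,
      no_duplex = FALSE
    ),
    class = "thermo_result"
  )
}

#' @export
print.thermo_result <- function(x, ...) {
  if (isTRUE(x$no_duplex)) {
    cat("<thermo_result> no duplex (fewer than 2 stacked pairs)\n")
  } else {
    cat(sprintf(
      "<thermo_result> dH %.2f kcal/mol, dS %.2f cal/(mol K), dG37 %.2f kcal/mol, Tm %.2f C\n",
      x$dH, x$dS, x$dG37, x$tm_C
    ))
  }
  invisible(x)
}

#' @export
tidy.thermo_result <- function(x, ...) {
  tibble(dH = x$dH, dS = x$dS, dG37 = x$dG37, tm_C = x$tm_C,
         no_duplex = isTRUE(x$no_duplex))
}

#' Nearest-neighbor thermodynamics of a perfect duplex
#'
#' Sums nearest-neighbor stack enthalpies/entropies plus terminal initiation
#' terms for a perfectly complementary probe:target duplex, applies an
#' entropic monovalent-salt correction of `0.368 * (n - 1) * ln([mono])`
#' cal/(mol K), and computes the melting temperature from the two-state
#' bimolecular formula under the excess-probe assumption:
#' `Tm = 1000 * dH / (dS_salt + R * ln(C_probe))`. `dG37` is reported from
#' the salt-corrected entropy at 37 C.
#'
#' @param probe_seq Probe (oligo) sequence 5'->3', A/C/G/T.
#' @param target_seq Target sequence 5'->3'; must be the exact reverse
#'   complement of `probe_seq` (mismatch thermodynamics are unsupported).
#' @param conditions A [buffer_conditions()] object.
#'
#' @return A `thermo_result`: `dH` (kcal/mol), `dS` (cal/(mol K),
#'   salt-corrected), `dG37` (kcal/mol), `tm_C` (Celsius), `conditions`.
#' @export
#' @examples
#' duplex_thermo(strrep("T", 15), strrep("A", 15), buffer_conditions())
duplex_thermo <- function(probe_seq, target_seq = revcomp(probe_seq),
                          conditions = buffer_conditions()) {
  assert_dna(probe_seq, "probe_seq")
  assert_dna(target_seq, "target_seq")
  if (nchar(probe_seq) < 2L) abort("Duplex must have length >= 2.")
  if (target_seq != revcomp(probe_seq)) {
    abort("`target_seq` is not the exact reverse complement of `probe_seq`; mismatched duplexes are not supported.")
  }
  tab <- nn_params()
  n <- nchar(probe_seq)
  bases <- strsplit(probe_seq, "", fixed = TRUE)[[1]]
  stacks <- paste0(bases[-n], bases[-1L])
  dH <- sum(vapply(tab[stacks], `[[`, numeric(1), "dH"))
  dS <- sum(vapply(tab[stacks], `[[`, numeric(1), "dS"))
  for (end_base in c(bases[1L], bases[n])) {
    init <- if (end_base %in% c("G", "C")) tab[["init_GC"]] else tab[["init_AT"]]
    dH <- dH + init[["dH"]]
    dS <- dS + init[["dS"]]
  }
  if (probe_seq == revcomp(probe_seq)) {
    dH <- dH + tab[["symmetry"]][["dH"]]
    dS <- dS + tab[["symmetry"]][["dS"]]
  }
  dS <- dS + 0.368 * (n - 1) * log(conditions$monovalent_mM / 1000)
  thermo_result(dH, dS, conditions)
}

#' Stability of the poly-T tail : poly-A duplex
#'
#' Thermodynamics of the duplex formed by a blocker's poly-T tail with the
#' target's poly-A tail. Tails shorter than 2 nt cannot stack and return a
#' "no duplex" sentinel (`no_duplex = TRUE`, `tm_C = NA`).
#'
#' @param tail_len Number of T:A pairs (>= 0).
#' @inheritParams duplex_thermo
#'
#' @return A `thermo_result`.
#' @export
tail_stability <- function(tail_len, conditions = buffer_conditions()) {
  tail_len <- as.integer(tail_len)
  if (is.na(tail_len) || tail_len < 0L) abort("`tail_len` must be >= 0.")
  if (tail_len < 2L) return(thermo_result(NA, NA, conditions, no_duplex = TRUE))
  duplex_thermo(strrep("T", tail_len), strrep("A", tail_len), conditions)
}
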