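# Independent oracles. These deliberately re-derive results from first
# principles (parameter-table summation, recursive enumeration) and share no
# code path with the package implementation.

# -- folding ----------------------------------------------------------------

oracle_can_pair <- function(a, b) {
  paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

# maximum pairs by substring-keyed recursion over "first base unpaired or
# paired with some j"; memoized on the substring itself
oracle_max_pairs <- function(seq, min_loop = 3L) {
  memo <- new.env(parent = emptyenv())
  rec <- function(s) {
    n <- nchar(s)
    if (n < min_loop + 2L) return(0L)
    if (!is.null(memo[[s]])) return(memo[[s]])
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    best <- rec(substr(s, 2L, n))
    for (j in (min_loop + 2L):n) {
      if (oracle_can_pair(b[1L], b[j])) {
        inside <- if (j > 2L) rec(substr(s, 2L, j - 1L)) else 0L
        outside <- if (j < n) rec(substr(s, j + 1L, n)) else 0L
        best <- max(best, 1L + inside + outside)
      }
    }
    memo[[s]] <- best
    best
  }
  rec(seq)
}

# exhaustive enumeration of every non-crossing, loop-legal pairing (n small)
oracle_enumerate_pairings <- function(seq, min_loop = 3L) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(list(list()))
    out <- rec(i, j - 1L) # j unpaired
    for (k in i:(j - min_loop - 1L)) {
      if (!oracle_can_pair(b[k], b[j])) next
      left <- if (k > i) rec(i, k - 1L) else list(list())
      right <- if (k + 1L <= j - 1L) rec(k + 1L, j - 1L) else list(list())
      for (P1 in left) for (P2 in right) {
        out[[length(out) + 1L]] <- c(P1, P2, list(c(k, j)))
      }
    }
    out
  }
  rec(1L, length(b))
}

oracle_enum_max_pairs <- function(seq, min_loop = 3L) {
  max(vapply(oracle_enumerate_pairings(seq, min_loop), length, integer(1)))
}

# structural legality of a fold_window result
check_structure_legal <- function(profile, min_loop = 3L) {
  b <- strsplit(profile$seq, "", fixed = TRUE)[[1]]
  prs <- profile$pairs
  if (nrow(prs) == 0L) return(TRUE)
  ok <- TRUE
  for (r in seq_len(nrow(prs))) {
    i <- prs[r, 1L]; j <- prs[r, 2L]
    ok <- ok && oracle_can_pair(b[i], b[j]) && (j - i > min_loop)
  }
  # no position in two pairs
  ok <- ok && !anyDuplicated(c(prs))
  # non-crossing
  for (r in seq_len(nrow(prs))) for (s in seq_len(nrow(prs))) {
    if (r == s) next
    i <- prs[r, 1L]; j <- prs[r, 2L]; k <- prs[s, 1L]; l <- prs[s, 2L]
    if (i < k && k < j && j < l) ok <- FALSE
  }
  ok
}

# -- thermodynamics ---------------------------------------------------------

oracle_nn_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      path <- system.file("extdata", "nn_unified.tsv", package = "oligolock")
      tab <<- read.delim(path, stringsAsFactors = FALSE)
    }
    tab
  }
})

oracle_thermo <- function(probe, monovalent_mM = 150, oligo_uM = 5) {
  tab <- oracle_nn_table()
  row <- function(key) tab[tab$stack == key, , drop = FALSE]
  n <- nchar(probe)
  dH <- 0; dS <- 0
  for (i in 1:(n - 1)) {
    st <- substr(probe, i, i + 1)
    dH <- dH + row(st)$dH_kcal
    dS <- dS + row(st)$dS_cal
  }
  for (end in c(substr(probe, 1, 1), substr(probe, n, n))) {
    key <- if (end %in% c("G", "C")) "init_GC" else "init_AT"
    dH <- dH + row(key)$dH_kcal
    dS <- dS + row(key)$dS_cal
  }
  comp <- chartr("ACGT", "TGCA", probe)
  rc <- paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  if (probe == rc) {
    dH <- dH + row("symmetry")$dH_kcal
    dS <- dS + row("symmetry")$dS_cal
  }
  dS_salt <- dS + 0.368 * (n - 1) * log(monovalent_mM / 1000)
  tm <- 1000 * dH / (dS_salt + 1.9872 * log(oligo_uM * 1e-6)) - 273.15
  list(dH = dH, dS = dS_salt, dG37 = dH - 310.15 * dS_salt / 1000, tm_C = tm)
}

# -- designer ---------------------------------------------------------------

# arm length by evaluating every suffix length 2..cap and returning the
# first whose Tm meets the target (cap otherwise)
oracle_arm_len <- function(target_seq, tm_target = 70, max_arm = 30,
                           monovalent_mM = 150, oligo_uM = 5) {
  len <- nchar(target_seq)
  cap <- min(max_arm, len)
  for (L in 2:cap) {
    win <- substr(target_seq, len - L + 1, len)
    if (oracle_thermo(win, monovalent_mM, oligo_uM)$tm_C >= tm_target) return(L)
  }
  cap
}

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}
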