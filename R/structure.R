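# 3'-end accessibility by maximum base pairing.
#
# A Nussinov-style dynamic program over Watson-Crick plus G:T (G:U) wobble
# pairs with a minimum hairpin-loop length. Structure is used qualitatively
# (accessible vs self-binding 3' terminus), so maximum base pairing is
# preferred over free-energy minimization: it is exhaustively verifiable at
# window scale. Among co-optimal structures the traceback deterministically
# prefers leaving 3'-terminal positions unpaired, so the reported terminal
# unpaired run is the most favorable one among maximum-pairing structures.

PAIRABLE <- matrix(FALSE, 4, 4, dimnames = list(VALID_BASES, VALID_BASES))
PAIRABLE["A", "T"] <- PAIRABLE["T", "A"] <- TRUE
PAIRABLE["G", "C"] <- PAIRABLE["C", "G"] <- TRUE
PAIRABLE["G", "T"] <- PAIRABLE["T", "G"] <- TRUE

#' Fold a sequence window by maximum base pairing
#'
#' Computes a maximum-cardinality set of non-crossing base pairs
#' (Watson-Crick A:T and G:C plus G:T wobble) with hairpin loops of at least
#' `min_loop` unpaired nucleotides, by dynamic programming. The traceback is
#' deterministic and, among maximum-pairing structures, prefers the one
#' leaving the longest unpaired 3' suffix, since terminal accessibility is
#' the decision variable downstream.
#'
#' @param seq A/C/G/T string to fold (typically a 3' window from
#'   [extract_3p_window()], including any appended poly-A mimic).
#' @param min_loop Minimum number of unpaired nucleotides in a hairpin loop.
#' @param appended_a Number of 3'-terminal positions that are appended
#'   poly-A mimic rather than transcript sequence; they are excluded from
#'   the terminal-run summary.
#' @param window Optional provenance tibble (as returned by
#'   [extract_3p_window()]); stored on the profile.
#'
#' @return A `structure_profile`: `seq`, `paired` (logical per position),
#'   `pairs` (two-column matrix of 1-based pair indices), `max_pairs`,
#'   `dot_bracket`, `terminal_unpaired_run` (contiguous unpaired suffix of
#'   the non-appended positions), `appended_a`, `accessible` (NA until
#'   assessed via [assess_accessibility()]).
#' @export
#' @examples
#' fold_window("GGGAAAACCC")$max_pairs # 3
fold_window <- function(seq, min_loop = 3L, appended_a = 0L, window = NULL) {
  assert_dna(seq)
  if (!nzchar(seq)) abort("Cannot fold an empty sequence.")
  min_loop <- as.integer(min_loop)
  if (min_loop < 0L) abort("`min_loop` must be >= 0.")
  appended_a <- as.integer(appended_a)
  n <- nchar(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  pairable <- PAIRABLE[bases, bases, drop = FALSE]

  N <- matrix(0L, n, n)
  if (n >= min_loop + 2L) {
    for (span in (min_loop + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- N[i, j - 1L]
        ks <- i:(j - min_loop - 1L)
        ks <- ks[pairable[ks, j]]
        if (length(ks)) {
          left <- numeric(length(ks))
          sel <- ks > i
          if (any(sel)) left[sel] <- N[i, ks[sel] - 1L]
          inner_ok <- ks + 1L <= j - 1L
          right <- numeric(length(ks))
          if (any(inner_ok)) {
            right[inner_ok] <- N[cbind(ks[inner_ok] + 1L, j - 1L)]
          }
          best <- max(best, max(left + right + 1L))
        }
        N[i, j] <- best
      }
    }
  }

  # traceback: prefer leaving j unpaired (maximizes the unpaired 3' suffix
  # among co-optimal structures); first optimal partner otherwise
  pairs <- matrix(integer(0), ncol = 2)
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1L]; j <- ij[2L]
    if (j - i < min_loop + 1L) next
    if (N[i, j] == N[i, j - 1L]) {
      stack[[length(stack) + 1L]] <- c(i, j - 1L)
      next
    }
    for (k in i:(j - min_loop - 1L)) {
      if (!pairable[k, j]) next
      left <- if (k > i) N[i, k - 1L] else 0L
      right <- if (k + 1L <= j - 1L) N[k + 1L, j - 1L] else 0L
      if (left + right + 1L == N[i, j]) {
        pairs <- rbind(pairs, c(k, j))
        if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
        if (k + 1L <= j - 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
        break
      }
    }
  }

  paired <- rep(FALSE, n)
  if (nrow(pairs)) paired[c(pairs)] <- TRUE
  db <- rep(".", n)
  if (nrow(pairs)) {
    db[pairs[, 1L]] <- "("
    db[pairs[, 2L]] <- ")"
  }
  n_native <- n - appended_a
  run <- 0L
  while (run < n_native && !paired[n_native - run]) run <- run + 1L

  structure(
    list(
      seq = seq,
      window = window,
      paired = paired,
      pairs = pairs,
      max_pairs = nrow(pairs),
      dot_bracket = paste(db, collapse = ""),
      appended_a = appended_a,
      terminal_unpaired_run = run,
      min_loop = min_loop,
      accessible = NA,
      k_terminal = NA_integer_,
      unpaired_fraction = NA_real_
    ),
    class = "structure_profile"
  )
}

#' @export
print.structure_profile <- function(x, ...) {
  cat(sprintf("<structure_profile> %d nt, %d pairs, terminal unpaired run %d\n",
              nchar(x$seq), x$max_pairs, x$terminal_unpaired_run))
  cat(" ", x$seq, "\n ", x$dot_bracket, "\n", sep = "")
  if (!is.na(x$accessible)) {
    cat(sprintf("  accessible: %s (unpaired fraction %.2f over terminal %d nt)\n",
                x$accessible, x$unpaired_fraction, x$k_terminal))
  }
  invisible(x)
}

#' @export
tidy.structure_profile <- function(x, ...) {
  n <- nchar(x$seq)
  tibble(
    position = seq_len(n),
    base = strsplit(x$seq, "", fixed = TRUE)[[1]],
    paired = x$paired,
    appended = seq_len(n) > n - x$appended_a
  )
}

#' Assess 3'-end accessibility of a transcript
#'
#' Extracts the transcript's 3' window with a poly-A mimic appendage
#' ([extract_3p_window()]), folds it ([fold_window()]) and summarizes how
#' much of the terminal (non-appended) sequence is free of intramolecular
#' pairing. A transcript is called accessible when the unpaired fraction of
#' its `k_terminal` last native positions reaches `threshold`. The defaults
#' reflect a beta-globin-like free 3' end of 26-28 nt and 28-nt 3' arms:
#' window 60 nt, A5 appendage, terminal 28 nt, threshold 0.75.
#'
#' @param transcript One-row transcript tibble.
#' @param window_len 3' window length folded (nt).
#' @param append_a Poly-A mimic length appended before folding.
#' @param k_terminal Number of terminal native positions summarized.
#' @param threshold Minimum unpaired fraction of those positions to call the
#'   end accessible.
#' @param min_loop Passed to [fold_window()].
#'
#' @return A `structure_profile` with `accessible`, `k_terminal` and
#'   `unpaired_fraction` filled in.
#' @export
assess_accessibility <- function(transcript, window_len = 60L, append_a = 5L,
                                 k_terminal = 28L, threshold = 0.75,
                                 min_loop = 3L) {
  k_terminal <- as.integer(k_terminal)
  if (k_terminal < 1L || window_len < k_terminal) {
    abort("Require `window_len` >= `k_terminal` >= 1.")
  }
  w <- extract_3p_window(transcript, n = window_len, append_a = append_a)
  prof <- fold_window(w$seq, min_loop = min_loop, appended_a = append_a,
                      window = w$window)
  n_native <- nchar(prof$seq) - prof$appended_a
  idx <- (n_native - k_terminal + 1L):n_native
  frac <- mean(!prof$paired[idx])
  prof$k_terminal <- k_terminal
  prof$unpaired_fraction <- frac
  prof$accessible <- frac >= threshold
  prof
}

#' Plot a structure profile
#'
#' Tile plot of paired/unpaired status along the folded window, with the
#' appended poly-A mimic marked.
#'
#' @param object A `structure_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.structure_profile <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = 1,
                                  fill = .data$paired)) +
    ggplot2::geom_tile(ggplot2::aes(alpha = ifelse(.data$appended, 0.5, 1))) +
    ggplot2::geom_text(ggplot2::aes(label = .data$base), size = 2.5) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "#9ecae1", `TRUE` = "#de2d26")) +
    ggplot2::scale_alpha_identity() +
    ggplot2::labs(x = "window position (5'->3')", y = NULL,
                  fill = "paired",
                  title = "3' window self-pairing") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
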