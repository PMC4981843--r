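# Sequence records, FASTA I/O and 3'-window extraction.
#
# Transcripts are plain tibbles (one row per transcript) with columns
# id, species, seq, description. All internal logic is DNA-alphabet: RNA
# input is normalized U -> T at the read boundary. Coordinates are 0-based,
# half-open on the stored transcript.

VALID_BASES <- c("A", "C", "G", "T")

assert_dna <- function(seq, arg = "seq") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort(sprintf("`%s` must be a single string.", arg))
  }
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L) {
    abort(sprintf(
      "`%s` contains non-ACGT character '%s' at position %d.",
      arg, substr(seq, bad, bad), bad
    ))
  }
  invisible(seq)
}

normalize_seq <- function(seq, id = "?") {
  seq <- toupper(seq)
  seq <- gsub("U", "T", seq, fixed = TRUE)
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L) {
    abort(sprintf(
      "Sequence '%s' has non-IUPAC/ambiguous character '%s' at position %d (only A, C, G, T, U are accepted).",
      id, substr(seq, bad, bad), bad
    ))
  }
  seq
}

#' Build a transcript table
#'
#' Constructs the tibble representation of transcript records used throughout
#' the package: one row per poly-adenylated transcript with a unique `id`, a
#' free `species` tag, an upper-case DNA-alphabet `seq` (U normalized to T)
#' and a free-text `description`.
#'
#' @param id Character vector of unique identifiers.
#' @param seq Character vector of nucleotide sequences over A/C/G/T/U.
#' @param species Character vector (recycled) of species tags.
#' @param description Character vector (recycled) of free-text descriptions.
#'
#' @return A tibble with columns `id`, `species`, `seq`, `description`.
#' @export
#' @examples
#' transcript_tbl("hbb_like", "ACGUACGU")
transcript_tbl <- function(id, seq, species = NA_character_,
                           description = "") {
  if (length(id) != length(seq)) {
    abort("`id` and `seq` must have the same length.")
  }
  if (anyDuplicated(id)) {
    abort(sprintf(
      "Duplicate transcript id '%s'.", id[duplicated(id)][1L]
    ))
  }
  if (any(!nzchar(seq))) abort("Transcript sequences must be non-empty.")
  seq <- vapply(seq_along(seq), function(i) normalize_seq(seq[[i]], id[[i]]),
                character(1))
  tibble(
    id = as.character(id),
    species = rep_len(as.character(species), length(id)),
    seq = seq,
    description = rep_len(as.character(description), length(id))
  )
}

#' Read transcripts from a FASTA file
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped) into a transcript
#' tibble. Sequences are upper-cased and U is normalized to T, so both DNA
#' and mRNA input are accepted; any other non-ACGT character is an error.
#' Record ids are the first whitespace-delimited header token; the remainder
#' of the header becomes the `description`. Input order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param species Species tag applied to every record (FASTA carries none).
#'
#' @return A transcript tibble (see [transcript_tbl()]).
#' @export
read_fasta <- function(path, species = NA_character_) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("FASTA file '%s' has no records.", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate FASTA id '%s' in '%s'.", ids[duplicated(ids)][1L], path))
  }
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) {
    abort(sprintf("Empty sequence for record '%s'.", ids[!nzchar(seqs)][1L]))
  }
  transcript_tbl(ids, seqs, species = species, description = desc)
}

#' Write transcripts to a FASTA file
#'
#' @param transcripts A transcript tibble.
#' @param path Output path.
#' @param width Line-wrap width in nucleotides.
#'
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path, width = 70L) {
  stopifnot(is.data.frame(transcripts), nrow(transcripts) >= 1L)
  set <- Biostrings::DNAStringSet(transcripts$seq)
  hdr <- transcripts$id
  has_desc <- !is.na(transcripts$description) & nzchar(transcripts$description)
  hdr[has_desc] <- paste(hdr[has_desc], transcripts$description[has_desc])
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement of a DNA sequence
#'
#' Blocker arms are reverse complements of target windows; this is the
#' single reverse-complement routine used everywhere in the package.
#'
#' @param seq A single A/C/G/T string.
#'
#' @return The reverse complement, same length.
#' @export
#' @examples
#' revcomp("AAAC") # "GTTT"
revcomp <- function(seq) {
  assert_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract a transcript's 3'-terminal window with a poly-A mimic
#'
#' Returns the last `n` nucleotides of a transcript with `append_a` extra
#' `A` characters appended, mimicking the first bases of the poly-A strand.
#' The FASTA 3' terminus is treated as the poly-A cleavage site; tails
#' already present in the input are not trimmed. Used as the input to
#' structure prediction ([fold_window()]).
#'
#' @param transcript A one-row transcript tibble (or a row index into one).
#' @param n Window length in nucleotides (last `n` of the stored sequence).
#' @param append_a Number of `A` nucleotides appended 3' of the window.
#'
#' @return A list with `seq` (the window string, length `n + append_a`) and
#'   `window`, a one-row tibble recording provenance (`transcript_id`,
#'   0-based half-open `start`/`end` on the stored transcript, `appended_a`).
#' @export
#' @examples
#' t <- transcript_tbl("x", "CCGGTT")
#' extract_3p_window(t, n = 2, append_a = 5)$seq # "TTAAAAA"
extract_3p_window <- function(transcript, n, append_a = 5L) {
  transcript <- as_single_transcript(transcript)
  n <- as.integer(n)
  append_a <- as.integer(append_a)
  if (n < 1L) abort("`n` must be >= 1.")
  if (append_a < 0L) abort("`append_a` must be >= 0.")
  len <- nchar(transcript$seq)
  if (n > len) {
    abort(sprintf(
      "Window length %d exceeds transcript '%s' length %d.",
      n, transcript$id, len
    ))
  }
  win_seq <- paste0(substr(transcript$seq, len - n + 1L, len),
                    strrep("A", append_a))
  list(
    seq = win_seq,
    window = tibble(
      transcript_id = transcript$id,
      start = len - n,
      end = len,
      appended_a = append_a
    )
  )
}

as_single_transcript <- function(x) {
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    abort("Expected a transcript tibble with columns `id` and `seq`.")
  }
  if (nrow(x) != 1L) {
    abort(sprintf("Expected exactly one transcript, got %d rows.", nrow(x)))
  }
  x
}

#' Read a transcript class registry
#'
#' Reads a TSV registry with columns `id`, `species`, `class`; `class` is one
#' of `globin_alpha`, `globin_beta`, `spikein`, `other`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `id`, `species`, `class`.
#' @export
read_registry <- function(path) {
  reg <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  need <- c("id", "species", "class")
  if (!all(need %in% names(reg))) {
    abort(sprintf("Registry must have columns %s.", paste(need, collapse = ", ")))
  }
  ok <- c("globin_alpha", "globin_beta", "spikein", "other")
  if (!all(reg$class %in% ok)) {
    abort(sprintf("Unknown class '%s' in registry.", setdiff(reg$class, ok)[1L]))
  }
  reg
}
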