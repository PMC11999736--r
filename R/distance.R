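encode_sequence <- function(sequence) {
  if (length(sequence) == 1 && nchar(sequence) > 1) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  sequence <- toupper(sequence)
  sequence[sequence == "T"] <- "U"
  code <- match(sequence, RNA_BASES) - 1L
  if (anyNA(code)) {
    bad <- unique(sequence[is.na(code)])
    abort(paste0("invalid base(s) in sequence: ", paste(bad, collapse = ", "),
                 " (alphabet is A, C, G, U; T is accepted as U)."))
  }
  code
}

struct_cpp_args <- function(struct, Lran) {
  mods <- structure_modules(struct)
  list(
    Lran = as.integer(Lran),
    mod_start = as.integer(mods$start - 1L),
    mod_len = as.integer(mods$end - mods$start + 1L),
    cons_pos = as.integer(names(struct$conserved)) - 1L,
    cons_base = match(struct$conserved, RNA_BASES) - 1L,
    pair_a = as.integer(struct$pairs[, 1]) - 1L,
    pair_b = as.integer(struct$pairs[, 2]) - 1L,
    anchored = struct$anchored5
  )
}

#' Minimum mutational distance of a sequence from a structure
#'
#' Scans every frame — every order-preserving, non-overlapping placement of
#' the structure's modules within the sequence, respecting 5' anchoring —
#' and returns the smallest number of violated constraints (mismatched
#' conserved sites plus non-canonical pairs) over all of them. The number of
#' placements considered equals [frame_count()].
#'
#' When no base pair spans two modules the scan uses an exact dynamic
#' programme over module shifts (linear in `Lran` per module); otherwise it
#' falls back to direct enumeration of placements.
#'
#' @param sequence A nucleotide string (or character vector of single
#'   bases) over A, C, G, U; T is normalised to U.
#' @param struct A [structure_constraint()].
#' @return Integer minimum distance in `0..(s + b)`.
#' @examples
#' toy <- structure_constraint(4, conserved = c(`1` = "G"),
#'                             pairs = rbind(c(2, 4)))
#' min_distance_scan("GAAC", toy)
#' @export
min_distance_scan <- function(sequence, struct) {
  stopifnot(inherits(struct, "structure_constraint"))
  seq_code <- encode_sequence(sequence)
  if (length(seq_code) < struct$Lstr) {
    abort("sequence shorter than the structure.")
  }
  a <- struct_cpp_args(struct, length(seq_code))
  cpp_min_distance(seq_code, a$Lran, a$mod_start, a$mod_len, a$cons_pos,
                   a$cons_base, a$pair_a, a$pair_b, a$anchored)
}

# Enumeration-based scan that also counts placements; reference path used
# in tests to confirm the DP and the closed-form frame count.
scan_enumerate <- function(sequence, struct) {
  seq_code <- encode_sequence(sequence)
  a <- struct_cpp_args(struct, length(seq_code))
  cpp_scan_enumerate(seq_code, a$Lran, a$mod_start, a$mod_len, a$cons_pos,
                     a$cons_base, a$pair_a, a$pair_b, a$anchored)
}

#' Empirical distance distribution from random sequences
#'
#' Draws `n_samples` uniform random sequences of length `Lran`, scans each
#' with [min_distance_scan()], and tabulates the minimum distances. With the
#' default `n_samples = 1e6` the tail below about 1e-4 is not resolvable;
#' estimating exact-match frequencies of realistic motifs (1e-8 and below)
#' needs orders of magnitude more samples and is the formulas' job, not the
#' sampler's.
#'
#' @param struct A [structure_constraint()].
#' @param Lran Randomized-region length.
#' @param n_samples Number of random sequences (default 1e6).
#' @param seed Optional integer seed for a reproducible, isolated draw.
#' @return A `distance_distribution` tibble (`m`, `probability`) with an
#'   extra `count` column and attribute `n_samples`.
#' @export
sample_min_distance_distribution <- function(struct, Lran, n_samples = 1e6,
                                             seed = NULL) {
  stopifnot(inherits(struct, "structure_constraint"))
  if (n_samples < 1) abort("`n_samples` must be at least 1.")
  if (Lran < struct$Lstr) abort("`Lran` must be at least `Lstr`.")
  a <- struct_cpp_args(struct, Lran)
  draw <- function() {
    cpp_sample_min_distances(as.integer(n_samples), a$Lran, a$mod_start,
                             a$mod_len, a$cons_pos, a$cons_base, a$pair_a,
                             a$pair_b, a$anchored)
  }
  d <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  counts <- tabulate(d + 1L, nbins = struct$s + struct$b + 1L)
  out <- new_distance_distribution(
    0:(struct$s + struct$b), counts / n_samples,
    frames = frame_count(Lran, struct), s = struct$s, b = struct$b,
    kind = "monte-carlo"
  )
  out$count <- counts
  attr(out, "n_samples") <- n_samples
  out
}

#' Exact distance distribution by full enumeration
#'
#' Enumerates all `4^Lran` sequences and scans each, yielding the exact
#' distribution of the minimum distance — the independent yardstick against
#' which the single- and multi-frame formulas are checked. Guarded to
#' `Lran <= 12` (17M sequences); meant for toy structures.
#'
#' When `Lran = Lstr` (one frame) this equals [single_frame_distribution()]
#' exactly. For `Lran > Lstr` the gap between this enumeration and
#' [multi_frame_distribution()] measures the error of treating overlapping
#' frames as independent.
#'
#' @param struct A [structure_constraint()].
#' @param Lran Sequence length, `>= Lstr` and `<= 12`.
#' @return A `distance_distribution` tibble with an extra `count` column.
#' @export
exhaustive_distance_distribution <- function(struct, Lran) {
  stopifnot(inherits(struct, "structure_constraint"))
  if (Lran < struct$Lstr) abort("`Lran` must be at least `Lstr`.")
  if (Lran > 12) abort("`Lran` must be <= 12 for exhaustive enumeration.")
  a <- struct_cpp_args(struct, Lran)
  counts <- cpp_exhaustive_counts(a$Lran, a$mod_start, a$mod_len, a$cons_pos,
                                  a$cons_base, a$pair_a, a$pair_b,
                                  a$anchored, struct$s + struct$b)
  total <- 4^Lran
  out <- new_distance_distribution(
    0:(struct$s + struct$b), counts / total,
    frames = frame_count(Lran, struct), s = struct$s, b = struct$b,
    kind = "exhaustive"
  )
  out$count <- counts
  attr(out, "n_sequences") <- total
  out
}

#' Generate a pool of uniform random RNA sequences
#'
#' @param n Number of sequences.
#' @param Lran Sequence length.
#' @param seed Optional seed for a reproducible, isolated draw.
#' @return Character vector of RNA sequences.
#' @export
random_pool <- function(n, Lran, seed = NULL) {
  draw <- function() {
    vapply(seq_len(n), function(i) {
      paste(sample(RNA_BASES, Lran, replace = TRUE), collapse = "")
    }, character(1))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Read or write a sequence pool as FASTA
#'
#' Thin wrappers over Biostrings for pools produced by [random_pool()].
#'
#' @param sequences Character vector of RNA sequences.
#' @param path FASTA file path.
#' @return [write_pool_fasta()] returns `path` invisibly;
#'   [read_pool_fasta()] returns a character vector of sequences named by
#'   their FASTA headers.
#' @export
write_pool_fasta <- function(sequences, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required for FASTA input/output.")
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(sequences), path)
  invisible(path)
}

#' @rdname write_pool_fasta
#' @export
read_pool_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("Biostrings is required for FASTA input/output.")
  }
  x <- Biostrings::readRNAStringSet(path)
  setNames(as.character(x), names(x))
}
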