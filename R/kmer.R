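#' Shifted non-overlapping k-mer training sentences
#'
#' Represents a sequence as k "sentences", one per reading frame
#' f = 0..k-1: sentence f holds the contiguous, non-overlapping k-mers
#' starting at positions f, f+k, f+2k, ... Trailing residues shorter than k
#' are dropped. Together the k frames cover every overlapping k-mer start
#' position exactly once, so for k = 3 the total token count over the three
#' frames is L - 2.
#'
#' @param seq A single sequence (character scalar or `AAString`-like).
#' @param k Word length (default 3).
#' @return A list of `k` character vectors of k-mer tokens (possibly empty).
#'   For a sequence shorter than `k`, a list of `k` empty vectors with a
#'   warning.
#' @examples
#' training_sentences("MKVLAT")  # list(c("MKV","LAT"), "KVL", "VLA")
#' @export
training_sentences <- function(seq, k = 3L) {
  s <- as.character(seq)[1L]
  L <- nchar(s)
  if (L < k) {
    warning("sequence shorter than k = ", k, "; no tokens emitted")
    return(rep(list(character(0)), k))
  }
  lapply(seq_len(k) - 1L, function(f) {
    starts <- seq.int(f + 1L, L, by = k)
    starts <- starts[starts + k - 1L <= L]
    if (!length(starts)) return(character(0))
    substring(s, starts, starts + k - 1L)
  })
}

#' Overlapping k-mers of a sequence
#'
#' Returns every contiguous k-mer `seq[i..i+k-1]` for i = 1..L-k+1, in
#' order; this is the tokenization used at embedding time.
#'
#' @param seq A single sequence.
#' @param k Word length (default 3).
#' @return Character vector of `L - k + 1` k-mers.
#' @examples
#' overlapping_kmers("MKVLAT")  # MKV KVL VLA LAT
#' @export
overlapping_kmers <- function(seq, k = 3L) {
  s <- as.character(seq)[1L]
  L <- nchar(s)
  if (L < k) stop("sequence length ", L, " is shorter than k = ", k)
  starts <- seq_len(L - k + 1L)
  substring(s, starts, starts + k - 1L)
}

#' Build a skip-gram training corpus from a sequence set
#'
#' Concatenates the shifted non-overlapping k-mer sentences of every
#' sequence (three sentences per sequence for k = 3).
#'
#' @param seqs An `AAStringSet` (or character vector).
#' @param k Word length.
#' @return List of character vectors (sentences); empty sentences dropped.
#' @export
kmer_corpus <- function(seqs, k = 3L) {
  out <- list()
  for (s in as.character(seqs)) {
    sent <- suppressWarnings(training_sentences(s, k))
    out <- c(out, sent[lengths(sent) > 0L])
  }
  out
}

#' Write a token corpus as whitespace-delimited lines
#'
#' One sentence per line, tokens separated by single spaces — the plain-text
#' interchange format generic word-embedding trainers consume.
#'
#' @param corpus List of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  writeLines(vapply(corpus, paste, character(1L), collapse = " "), path)
  invisible(path)
}

#' Read a whitespace-delimited token corpus
#' @param path Path written by [write_corpus()].
#' @return List of character vectors.
#' @export
read_corpus <- function(path) {
  strsplit(readLines(path), "\\s+")
}
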