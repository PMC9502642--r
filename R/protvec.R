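#' Train a skip-gram k-mer vector model
#'
#' Trains word2vec-style skip-gram vectors with negative sampling on a
#' corpus of k-mer sentences (typically the shifted non-overlapping 3-mer
#' sentences from [kmer_corpus()]). Defaults follow the Protvec
#' configuration: 100-dimensional vectors and a symmetric context window of
#' 25 tokens each side. Every token occurring at least once enters the
#' vocabulary. Training is single-threaded with its own deterministic RNG,
#' so a fixed seed reproduces the vectors exactly.
#'
#' @param sentences List of character vectors of k-mer tokens.
#' @param d Vector dimension (default 100).
#' @param window Symmetric context half-width in tokens (default 25).
#' @param epochs Training passes over the corpus (default 5).
#' @param negative Negative samples per positive pair (default 5); sampling
#'   distribution is unigram frequency raised to 3/4.
#' @param alpha Initial learning rate (default 0.025), decayed linearly to
#'   `alpha / 1e4` over training.
#' @param seed Integer RNG seed.
#' @return An object of class `kmer_vector_model`: list with `vectors`
#'   (token-by-`d` numeric matrix, rownames = tokens), `d`, `window`, and
#'   `training_meta` (epochs, negative, alpha, seed, corpus fingerprint).
#' @examples
#' m <- train_skipgram(list(c("AAA", "AAC"), c("AAC", "AAA")),
#'                     d = 8, window = 2, epochs = 2, seed = 1)
#' dim(m$vectors)
#' @export
train_skipgram <- function(sentences, d = 100L, window = 25L, epochs = 5L,
                           negative = 5L, alpha = 0.025, seed = 1L) {
  stopifnot(d >= 1L, window >= 1L, epochs >= 1L, negative >= 0L)
  sentences <- sentences[lengths(sentences) > 0L]
  if (!length(sentences)) stop("empty corpus: no non-empty sentences")
  tokens <- unlist(sentences, use.names = FALSE)
  klen <- unique(nchar(tokens))
  if (length(klen) != 1L) stop("tokens of mixed length in corpus")
  vocab <- sort(unique(tokens))
  counts <- table(factor(tokens, levels = vocab))
  coded <- lapply(sentences, function(s) match(s, vocab) - 1L)
  vec <- cpp_sgns_train(coded, length(vocab), as.integer(d),
                        as.integer(window), as.integer(epochs),
                        as.integer(negative), alpha, alpha / 1e4,
                        as.numeric(counts)^0.75, as.integer(seed))
  rownames(vec) <- vocab
  structure(
    list(vectors = vec, d = as.integer(d), window = as.integer(window),
         training_meta = list(
           epochs = as.integer(epochs), negative = as.integer(negative),
           alpha = alpha, seed = as.integer(seed), k = klen,
           n_sentences = length(sentences), n_tokens = length(tokens))),
    class = "kmer_vector_model"
  )
}

#' @export
print.kmer_vector_model <- function(x, ...) {
  cat("Skip-gram k-mer vector model: ", nrow(x$vectors), " tokens x ",
      x$d, " dims (window ", x$window, ", epochs ",
      x$training_meta$epochs, ")\n", sep = "")
  invisible(x)
}

#' Norm profile of a k-mer vector model
#'
#' Computes the Euclidean norm (distance from the origin) of every token
#' vector and a Gaussian kernel density estimate of the norm distribution.
#' Long-norm tokens dominate where sequences land in the embedded space, so
#' the upper tail of this distribution is the model's most influential
#' vocabulary. The tail can be delimited either by an absolute threshold or
#' by the n-th largest norm (`top_n`, the default, since absolute norms are
#' not transferable across trainings).
#'
#' @param model A `kmer_vector_model`.
#' @param bw Density bandwidth rule passed to [stats::density()] (default
#'   `"nrd"`, the Scott-style rule of thumb).
#' @param tail_threshold Absolute norm threshold for the tail, or `NULL` to
#'   derive it from `top_n`.
#' @param top_n Number of longest vectors defining the tail when
#'   `tail_threshold` is `NULL` (default 100).
#' @return List of class `norm_profile`: `norms` (named numeric), `density`
#'   (a [stats::density()] object, or `NULL` with a warning for a
#'   single-token model), `tail_threshold`, `tail_tokens`.
#' @export
norm_profile <- function(model, bw = "nrd", tail_threshold = NULL,
                         top_n = 100L) {
  stopifnot(inherits(model, "kmer_vector_model"))
  V <- model$vectors
  norms <- sqrt(rowSums(V^2))
  dens <- NULL
  if (length(norms) < 2L || stats::sd(norms) == 0) {
    warning("fewer than 2 distinct norm values; density estimate skipped")
  } else {
    dens <- stats::density(norms, bw = bw)
  }
  if (is.null(tail_threshold)) {
    ord <- order(-norms, names(norms))
    top_n <- min(top_n, length(norms))
    tail_threshold <- norms[ord[top_n]]
    tail_tokens <- names(norms)[ord[seq_len(top_n)]]
  } else {
    tail_tokens <- names(norms)[norms > tail_threshold]
  }
  structure(list(norms = norms, density = dens,
                 tail_threshold = unname(tail_threshold),
                 tail_tokens = tail_tokens),
            class = "norm_profile")
}

#' Residue composition of the longest k-mer vectors
#'
#' Selects the `n` tokens of largest Euclidean norm (ties broken
#' lexicographically by token) and counts residue occurrences across them;
#' for k-mers the counts sum to `n * k`. Comparing these counts with the
#' BLOSUM62 diagonal shows whether the model has up-weighted residues that
#' are rarely substituted (W, C).
#'
#' @param model A `kmer_vector_model`.
#' @param n Number of longest vectors to inspect (default 100). If the
#'   vocabulary is smaller, all tokens are used with a warning.
#' @return Named integer vector of residue counts, descending.
#' @export
longest_vector_composition <- function(model, n = 100L) {
  stopifnot(inherits(model, "kmer_vector_model"))
  norms <- sqrt(rowSums(model$vectors^2))
  if (length(norms) < n) {
    warning("vocabulary has only ", length(norms), " tokens; using all")
    n <- length(norms)
  }
  ord <- order(-norms, names(norms))
  top <- names(norms)[ord[seq_len(n)]]
  chars <- unlist(strsplit(top, "", fixed = TRUE), use.names = FALSE)
  counts <- table(chars)
  sort(stats::setNames(as.integer(counts), names(counts)), decreasing = TRUE)
}

#' Diagonal of the BLOSUM62 substitution matrix
#'
#' Self-substitution scores of the 20 canonical residues from the standard
#' BLOSUM62 matrix; high values (W = 11, C = 9) mark residues that are
#' rarely substituted in homologous alignments.
#'
#' @return Named integer vector over the 20 residues.
#' @examples
#' blosum62_diagonal()[["W"]]  # 11
#' @export
blosum62_diagonal <- function() {
  c(A = 4L, C = 9L, D = 6L, E = 5L, F = 6L, G = 6L, H = 8L, I = 4L,
    K = 5L, L = 4L, M = 5L, N = 6L, P = 7L, Q = 5L, R = 5L, S = 4L,
    T = 5L, V = 4L, W = 11L, Y = 7L)
}

#' Write a k-mer vector model to a plain-text TSV
#'
#' One line per token: the token then `d` tab-separated floats (9
#' significant digits); hyperparameters go to a JSON-ish sidecar
#' `<path>.meta` (written with [dput()] syntax-free key=value lines).
#'
#' @param model A `kmer_vector_model`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "kmer_vector_model"))
  V <- model$vectors
  lines <- vapply(seq_len(nrow(V)), function(i) {
    paste(c(rownames(V)[i], formatC(V[i, ], format = "g", digits = 9)),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  meta <- c(d = model$d, window = model$window,
            unlist(model$training_meta))
  writeLines(paste0(names(meta), "=", meta), paste0(path, ".meta"))
  invisible(path)
}

#' Read a k-mer vector model written by [write_model()]
#' @param path Model TSV path.
#' @return A `kmer_vector_model` (training metadata restored from the
#'   sidecar when present).
#' @export
read_model <- function(path) {
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  tokens <- vapply(rows, `[[`, character(1L), 1L)
  V <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1L])))
  rownames(V) <- tokens
  meta <- list()
  mp <- paste0(path, ".meta")
  if (file.exists(mp)) {
    kv <- strsplit(readLines(mp), "=", fixed = TRUE)
    meta <- stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, character(1L), 1L))
  }
  window <- if (!is.null(meta$window)) as.integer(meta$window) else NA_integer_
  structure(list(vectors = V, d = ncol(V), window = window,
                 training_meta = meta),
            class = "kmer_vector_model")
}
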