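new_embedding <- function(values, ids, method, normalized = FALSE,
                          oov = rep(0, length(ids))) {
  rownames(values) <- ids
  structure(values, method = method, normalized = normalized,
            oov_fraction = stats::setNames(oov, ids),
            class = c("embedding_matrix", class(values)))
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat("Embedding matrix: ", nrow(x), " sequences x ", ncol(x),
      " dims (method ", attr(x, "method"),
      if (isTRUE(attr(x, "normalized"))) ", z-scored" else "", ")\n",
      sep = "")
  invisible(x)
}

#' Fraction of out-of-vocabulary k-mers per embedded sequence
#' @param matrix An embedding produced by [embed_protvec()].
#' @return Named numeric vector in `[0, 1]`, one entry per row.
#' @export
oov_fraction <- function(matrix) attr(matrix, "oov_fraction")

#' Embed sequences by summing skip-gram k-mer vectors
#'
#' Converts each sequence to its overlapping 3-mers, looks each up in the
#' trained model, and sums the vectors (Protvec-style summation embedding).
#' k-mers absent from the model's vocabulary — expected when embedding
#' held-out sequences with a model trained on other sequences — contribute
#' the zero vector and are counted in the per-row `oov_fraction`.
#'
#' @param seqs An `AAStringSet` (or named character vector); all sequences
#'   must be at least k residues long.
#' @param model A `kmer_vector_model`.
#' @return An `embedding_matrix` (`length(seqs)` x `model$d`), method
#'   `"protvec_sum"`, unnormalized; row order follows the input.
#' @export
embed_protvec <- function(seqs, model) {
  stopifnot(inherits(model, "kmer_vector_model"))
  chars <- as.character(seqs)
  ids <- names(chars)
  if (is.null(ids)) ids <- as.character(seq_along(chars))
  k <- unique(nchar(rownames(model$vectors)))[1L]
  short <- nchar(chars) < k
  if (any(short)) {
    stop("sequence shorter than k = ", k, ": ", ids[which(short)[1L]])
  }
  V <- model$vectors
  out <- matrix(0, nrow = length(chars), ncol = model$d)
  oov <- numeric(length(chars))
  for (i in seq_along(chars)) {
    km <- overlapping_kmers(chars[[i]], k)
    idx <- match(km, rownames(V))
    hit <- !is.na(idx)
    oov[i] <- mean(!hit)
    if (any(hit)) out[i, ] <- colSums(V[idx[hit], , drop = FALSE])
  }
  new_embedding(out, ids, "protvec_sum", oov = oov)
}

#' Embed sequences by reduced-alphabet k-mer frequency
#'
#' Maps each sequence into a reduced amino-acid alphabet, counts its
#' overlapping k-mers against the lexicographically ordered enumeration of
#' all `|alphabet|^k` possible k-mers (1000 coordinates for murphy10 with
#' k = 3 — conceptually the rows of an identity matrix labelled by k-mer),
#' and divides the counts by the sequence length L. Each row therefore sums
#' to (L - 2)/L for k = 3.
#'
#' @param seqs An `AAStringSet`; residues must lie in the scheme's domain.
#' @param scheme An [alphabet_scheme()] (default murphy10).
#' @param k Word length (default 3).
#' @return An `embedding_matrix` with `|alphabet|^k` columns named by
#'   k-mer, method `"kmer_freq"`, unnormalized.
#' @export
embed_kmer_freq <- function(seqs, scheme = alphabet_scheme("murphy10"),
                            k = 3L) {
  red <- reduce_alphabet(seqs, scheme)
  chars <- as.character(red)
  ids <- names(chars)
  if (is.null(ids)) ids <- as.character(seq_along(chars))
  if (any(nchar(chars) < k)) {
    stop("sequence shorter than k = ", k, ": ",
         ids[which(nchar(chars) < k)[1L]])
  }
  coords <- all_kmers(scheme$alphabet, k)
  out <- matrix(0, nrow = length(chars), ncol = length(coords),
                dimnames = list(NULL, coords))
  for (i in seq_along(chars)) {
    km <- overlapping_kmers(chars[[i]], k)
    tab <- table(km)
    out[i, names(tab)] <- as.numeric(tab) / nchar(chars[[i]])
  }
  new_embedding(out, ids, "kmer_freq")
}

#' Z-score standardize an embedding column-wise
#'
#' Subtracts each column's mean and divides by its population standard
#' deviation. Constant columns cannot be scaled and are set to zero with a
#' warning. Idempotent (up to floating point) on non-constant columns.
#'
#' @param matrix An `embedding_matrix` (or plain matrix) with at least 2
#'   rows.
#' @return The standardized `embedding_matrix`, `normalized = TRUE`.
#' @export
zscore <- function(matrix) {
  if (nrow(matrix) < 2L) stop("z-score requires at least 2 rows")
  m <- colMeans(matrix)
  centered <- sweep(unclass(matrix), 2L, m)
  s <- sqrt(colMeans(centered^2))
  const <- s == 0
  if (any(const)) {
    warning(sum(const), " constant column(s) set to 0")
    s[const] <- 1
  }
  out <- sweep(centered, 2L, s, "/")
  new_embedding(out, rownames(matrix),
                method = attr(matrix, "method") %||% "unknown",
                normalized = TRUE,
                oov = attr(matrix, "oov_fraction") %||%
                  rep(0, nrow(matrix)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Project an embedding to low dimension for visualization
#'
#' `method = "pca"` projects onto the top principal axes of the centered
#' matrix (deterministic; each axis is sign-fixed so its largest-magnitude
#' loading is positive). `method = "tsne"` delegates to a pluggable t-SNE
#' implementation (`tsne_fn`; the built-in [tsne_exact()] by default),
#' seeded for reproducibility.
#'
#' @param matrix An `embedding_matrix` or numeric matrix with at least
#'   `dims + 1` rows.
#' @param method `"pca"` or `"tsne"`.
#' @param dims Output dimensionality (default 2).
#' @param seed Integer seed (used by t-SNE).
#' @param tsne_fn Function `(matrix, dims, seed) -> matrix` used when
#'   `method = "tsne"`.
#' @return Numeric matrix (`nrow(matrix)` x `dims`), row order preserved.
#' @export
project <- function(matrix, method = c("pca", "tsne"), dims = 2L,
                    seed = 1L, tsne_fn = tsne_exact) {
  method <- match.arg(method)
  X <- unclass(matrix)
  if (nrow(X) < dims + 1L) stop("need at least dims + 1 rows")
  if (method == "pca") {
    if (dims >= ncol(X)) stop("pca requires dims < number of columns")
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = dims)
    rot <- pc$rotation
    flip <- vapply(seq_len(ncol(rot)), function(j) {
      sign(rot[which.max(abs(rot[, j])), j])
    }, numeric(1L))
    scores <- sweep(pc$x[, seq_len(dims), drop = FALSE], 2L, flip, "*")
    rownames(scores) <- rownames(matrix)
    return(scores)
  }
  out <- tsne_fn(X, dims, seed)
  rownames(out) <- rownames(matrix)
  out
}

#' Exact t-SNE (quadratic-time reference implementation)
#'
#' A compact, seeded, exact t-distributed stochastic neighbor embedding for
#' the small sequence sets this package visualizes (hundreds to a few
#' thousand points): Gaussian input affinities calibrated per point to a
#' target perplexity by bisection, Student-t output kernel, gradient descent
#' with momentum and early exaggeration. Degenerate inputs (coincident
#' points) fall back to uniform affinities so the embedding stays finite.
#'
#' @param X Numeric matrix (rows = points).
#' @param dims Output dimensionality (default 2).
#' @param seed Integer seed for the initial layout.
#' @param perplexity Target perplexity (default `min(30, (n - 1)/3)`).
#' @param n_iter Gradient-descent iterations (default 300).
#' @return Numeric matrix (`nrow(X)` x `dims`).
#' @export
tsne_exact <- function(X, dims = 2L, seed = 1L,
                       perplexity = min(30, (nrow(X) - 1) / 3),
                       n_iter = 300L) {
  n <- nrow(X)
  if (n < 2L) stop("t-SNE needs at least 2 points")
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(max(perplexity, 1))
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    if (max(di) == 0) {  # coincident points: uniform affinities
      P[i, -i] <- 1 / (n - 1)
      next
    }
    beta <- 1; lo <- -Inf; hi <- Inf
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { H <- 0; p <- rep(0, length(di)) }
      else {
        p <- w / sw
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < .Machine$double.eps] <- .Machine$double.eps
  Y <- withr::with_seed(seed,
    matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims))
  G <- matrix(0, n, dims)
  gain <- matrix(1, n, dims)
  for (iter in seq_len(n_iter)) {
    ex <- if (iter <= 50L) 4 else 1
    Q_num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(Q_num) <- 0
    Q <- Q_num / sum(Q_num)
    Q[Q < .Machine$double.eps] <- .Machine$double.eps
    W <- (ex * P - Q) * Q_num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    mom <- if (iter <= 250L) 0.5 else 0.8
    gain <- ifelse(sign(grad) != sign(G), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    G <- mom * G - 100 * gain * grad
    Y <- Y + G
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}

#' Write an embedding matrix as TSV with a metadata sidecar
#' @param matrix An `embedding_matrix`.
#' @param path Output TSV path (`id` column then one column per dimension);
#'   method/normalized flags go to `<path>.meta`.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(matrix, path) {
  df <- data.frame(id = rownames(matrix), unclass(matrix),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(paste0("method=", attr(matrix, "method")),
               paste0("normalized=", isTRUE(attr(matrix, "normalized")))),
             paste0(path, ".meta"))
  invisible(path)
}

#' Read an embedding matrix written by [write_embedding()]
#' @param path TSV path.
#' @return An `embedding_matrix`.
#' @export
read_embedding <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  meta <- c(method = "unknown", normalized = "FALSE")
  mp <- paste0(path, ".meta")
  if (file.exists(mp)) {
    kv <- strsplit(readLines(mp), "=", fixed = TRUE)
    meta[vapply(kv, `[[`, character(1L), 1L)] <-
      vapply(kv, `[[`, character(1L), 2L)
  }
  new_embedding(vals, as.character(df[[1L]]), meta[["method"]],
                normalized = as.logical(meta[["normalized"]]))
}
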