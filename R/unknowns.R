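# k-means++ seeding: first center uniform, then each next center drawn with
# probability proportional to the squared distance to the nearest chosen
# center. Returns row indices (distinct rows whenever possible).
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(X, 2L, X[centers[1L], ])^2)
    for (j in 2:k) {
      prob <- d2
      if (sum(prob) == 0) prob <- rep(1, n)
      centers[j] <- sample.int(n, 1L, prob = prob)
      d2 <- pmin(d2, rowSums(sweep(X, 2L, X[centers[j], ])^2))
    }
  }
  centers
}

#' k-means clustering of an embedding
#'
#' Lloyd iterations from k-means++ initialization; the best of `n_init`
#' seeded restarts by inertia (total within-cluster sum of squares) is
#' returned. A restart whose iteration produces an empty cluster is
#' re-initialized (deterministically, from the same seeded stream).
#'
#' @param matrix An `embedding_matrix` or numeric matrix.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Integer seed; fixed seed gives identical results.
#' @param n_init Number of restarts (default 10).
#' @return Object of class `kmeans_result`: `labels` (per row, 1..k),
#'   `centroids` (k x d), `inertia`, `k`, `seed`.
#' @export
kmeans_embed <- function(matrix, k, seed = 1L, n_init = 10L) {
  X <- unclass(matrix)
  n <- nrow(X)
  if (k < 1L || k > n) stop("k must be in 1..", n)
  best <- NULL
  withr::with_seed(seed, {
    done <- 0L
    guard <- 0L
    while (done < n_init && guard < n_init * 10L) {
      guard <- guard + 1L
      init <- kmeanspp_centers(X, k)
      km <- tryCatch(
        stats::kmeans(X, centers = X[init, , drop = FALSE],
                      algorithm = "Lloyd", iter.max = 100L),
        error = function(e) NULL,
        warning = function(w) {
          # Lloyd often stops on the iteration cap warning; rerun quietly
          suppressWarnings(stats::kmeans(X, centers = X[init, , drop = FALSE],
                                         algorithm = "Lloyd",
                                         iter.max = 100L))
        })
      if (is.null(km) || any(km$size == 0L)) next  # empty cluster: re-seed
      done <- done + 1L
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best)) stop("k-means failed to produce ", k,
                          " non-empty clusters")
  structure(
    list(labels = stats::setNames(as.integer(best$cluster), rownames(X)),
         centroids = unname(best$centers),
         inertia = best$tot.withinss, k = as.integer(k),
         seed = as.integer(seed)),
    class = "kmeans_result")
}

#' @export
print.kmeans_result <- function(x, ...) {
  cat("k-means: k =", x$k, ", n =", length(x$labels),
      ", inertia =", signif(x$inertia, 6), "\n")
  invisible(x)
}

#' Cluster members nearest to their centroid
#'
#' For each cluster, the `min(n, cluster size)` member rows with the
#' smallest Euclidean distance to the cluster centroid — the natural
#' representatives to carry forward to experimental characterization. Ties
#' are broken by row order.
#'
#' @param matrix The embedding that was clustered.
#' @param result A [kmeans_embed()] result.
#' @param n Representatives per cluster (default 100).
#' @return Named list (one element per cluster `1..k`) of row-id character
#'   vectors, nearest first.
#' @export
nearest_to_centroids <- function(matrix, result, n = 100L) {
  stopifnot(inherits(result, "kmeans_result"))
  X <- unclass(matrix)
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  out <- vector("list", result$k)
  for (kk in seq_len(result$k)) {
    member <- which(result$labels == kk)
    d <- sqrt(rowSums(sweep(X[member, , drop = FALSE], 2L,
                            result$centroids[kk, ])^2))
    ord <- member[order(d)]  # order() is stable: ties keep row order
    out[[kk]] <- ids[utils::head(ord, n)]
  }
  stats::setNames(out, paste0("cluster_", seq_len(result$k)))
}

#' Percent identity of a global pairwise alignment
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with gap opening 10 and
#' gap extension 1; identity is the number of identical aligned residue
#' pairs divided by the full alignment length (gap columns included),
#' times 100.
#'
#' @param a,b Sequences (character scalars or `AAString`s), non-empty.
#' @return Percent identity in `[0, 100]`.
#' @examples
#' pairwise_identity("ACDE", "ACDK")  # 75
#' @export
pairwise_identity <- function(a, b) {
  a <- as.character(a)[1L]; b <- as.character(b)[1L]
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
    type = "global")
  s1 <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s2 <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  ident <- s1 == s2 & s1 != "-"
  100 * sum(ident) / length(s1)
}

#' Mean pairwise identity within each cluster
#'
#' For every cluster, the mean percent identity over all member pairs, or
#' over a seeded random sample of `max_pairs` pairs when the pair count
#' exceeds the cap. Low within-cluster identity indicates that the
#' embedding's clusters are not mere homology artifacts.
#'
#' @param seqs An `AAStringSet` aligned with `labels`.
#' @param labels Cluster label per sequence.
#' @param max_pairs Cap on pairs scored per cluster (default 10000).
#' @param seed Seed for pair sampling.
#' @return Data frame with one row per cluster: `cluster`, `n_seqs`,
#'   `n_pairs`, `mean_identity`, `sd_identity` (NA for singletons).
#' @export
cluster_identity_summary <- function(seqs, labels, max_pairs = 10000L,
                                     seed = 1L) {
  if (length(labels) != length(seqs)) stop("labels must align with seqs")
  chars <- as.character(seqs)
  out <- lapply(sort(unique(labels)), function(cl) {
    member <- which(labels == cl)
    m <- length(member)
    if (m < 2L) {
      return(data.frame(cluster = cl, n_seqs = m, n_pairs = 0L,
                        mean_identity = NA_real_, sd_identity = NA_real_))
    }
    pairs <- utils::combn(member, 2L)
    if (ncol(pairs) > max_pairs) {
      keep <- withr::with_seed(seed,
        sample.int(ncol(pairs), max_pairs))
      pairs <- pairs[, keep, drop = FALSE]
    }
    ids <- apply(pairs, 2L, function(p) {
      pairwise_identity(chars[[p[1L]]], chars[[p[2L]]])
    })
    data.frame(cluster = cl, n_seqs = m, n_pairs = ncol(pairs),
               mean_identity = mean(ids), sd_identity = stats::sd(ids))
  })
  do.call(rbind, out)
}
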