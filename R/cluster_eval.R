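#' Agglomerative clustering on Euclidean distances
#'
#' Builds a hierarchical merge tree over the rows of an embedding using
#' [stats::hclust()]. `linkage = "ward"` uses the Ward minimum-variance
#' criterion on Euclidean distances (`"ward.D2"`), consistent with the
#' variance-ratio scoring applied downstream; `"average"` and `"complete"`
#' are selectable.
#'
#' @param matrix An `embedding_matrix` or numeric matrix (>= 2 rows).
#' @param linkage One of `"ward"`, `"average"`, `"complete"`.
#' @return An `hclust` object; `labels` are the row names.
#' @export
agglomerative <- function(matrix, linkage = c("ward", "average", "complete")) {
  linkage <- match.arg(linkage)
  X <- unclass(matrix)
  if (nrow(X) < 2L) stop("need at least 2 rows")
  method <- switch(linkage, ward = "ward.D2", average = "average",
                   complete = "complete")
  stats::hclust(stats::dist(X), method = method)
}

#' Cut a dendrogram into K clusters
#'
#' Removes the K - 1 highest merges; labels are the resulting connected
#' components. Ties in merge height are resolved by merge order (later
#' merges are removed first), which is [stats::cutree()]'s behavior.
#'
#' @param dend An `hclust` object.
#' @param K Number of clusters, `1 <= K <= n`.
#' @return Integer vector of cluster labels in `1..K`, one per leaf, in
#'   input row order.
#' @export
cut_dendrogram <- function(dend, K) {
  n <- length(dend$order)
  if (K < 1L || K > n) stop("K must be in 1..", n)
  stats::cutree(dend, k = K)
}

#' Within- and between-cluster sums of squares
#'
#' For a partition of the rows x into clusters k with means x̄_k and grand
#' mean x̄: `WSS = Σ_k Σ_i ||x_ik − x̄_k||²` and
#' `BSS = Σ_k n_k ||x̄_k − x̄||²` (Euclidean norm). Their sum equals the
#' total sum of squares about the grand mean for every partition.
#'
#' @param matrix Numeric matrix (rows = observations).
#' @param labels Cluster label per row; every cluster must be non-empty.
#' @return Named list `list(WSS=, BSS=)`.
#' @examples
#' m <- rbind(c(0, 0), c(0, 1), c(10, 10), c(10, 11))
#' partition_sums(m, c(1, 1, 2, 2))  # WSS 1, BSS 200
#' @export
partition_sums <- function(matrix, labels) {
  X <- unclass(matrix)
  if (length(labels) != nrow(X)) stop("labels must align with rows")
  f <- factor(labels)
  nk <- as.numeric(table(f))
  if (any(nk == 0)) stop("empty cluster in partition")
  means <- rowsum(X, f) / nk
  grand <- colMeans(X)
  wss <- sum((X - means[as.integer(f), , drop = FALSE])^2)
  bss <- sum(nk * rowSums(sweep(means, 2L, grand)^2))
  list(WSS = wss, BSS = bss)
}

#' Calinski-Harabasz index
#'
#' The variance-ratio criterion `CH(K) = (BSS/WSS) * ((n - K)/(K - 1))`;
#' its peak over K estimates the number of clusters.
#'
#' @param WSS Within-cluster sum of squares (> 0).
#' @param BSS Between-cluster sum of squares (>= 0).
#' @param n Number of observations (> K).
#' @param K Number of clusters (>= 2).
#' @return The CH index, a non-negative real.
#' @examples
#' ch_index(1, 200, n = 4, K = 2)  # 400
#' @export
ch_index <- function(WSS, BSS, n, K) {
  if (K < 2L) stop("CH index requires K >= 2")
  if (n <= K) stop("CH index requires n > K")
  if (WSS <= 0) stop("CH index undefined for WSS = 0 (degenerate partition)")
  (BSS / WSS) * ((n - K) / (K - 1))
}

#' Bootstrapped Calinski-Harabasz profile over a range of K
#'
#' For each of B bootstrap replicates: resample the n rows with replacement
#' (seeded), build one agglomerative dendrogram on the resample, cut it at
#' every K in `K_range`, and record WSS, BSS and CH. The profile stores the
#' replicate values plus per-K means and standard deviations. Replicates
#' that draw fewer than 2 distinct rows are redrawn (at most 10 retries
#' each, counted). With `resample = FALSE` the matrix itself is scored once
#' per replicate (identity bootstrap — useful for exact checks). An
#' optional seeded subsample caps the number of rows profiled.
#'
#' @param matrix An `embedding_matrix` or numeric matrix.
#' @param K_range Integer vector of cluster counts (default `2:150`).
#' @param B Bootstrap replicates (default 500).
#' @param seed Integer seed.
#' @param linkage Linkage passed to [agglomerative()].
#' @param subsample Maximum rows profiled (default 5000); `Inf` disables.
#' @param resample If `FALSE`, skip resampling (identity bootstrap).
#' @return Object of class `ch_profile`: `K`, `B`, `mean_WSS`, `mean_BSS`,
#'   `mean_CH`, `sd_CH` (per K), `replicates` (B x |K| CH matrix),
#'   `optimal_K`, `peak` (`TRUE` if the optimum is an interior peak),
#'   `redraws`.
#' @export
ch_profile <- function(matrix, K_range = 2:150, B = 500L, seed = 1L,
                       linkage = "ward", subsample = 5000L,
                       resample = TRUE) {
  X <- unclass(matrix)
  n0 <- nrow(X)
  if (is.finite(subsample) && n0 > subsample) {
    keep <- withr::with_seed(seed, sort(sample.int(n0, subsample)))
    X <- X[keep, , drop = FALSE]
  }
  n <- nrow(X)
  K_range <- sort(unique(as.integer(K_range)))
  if (n <= max(K_range)) stop("need more rows than max(K_range)")
  ch_rep <- matrix(NA_real_, B, length(K_range))
  wss_rep <- matrix(NA_real_, B, length(K_range))
  bss_rep <- matrix(NA_real_, B, length(K_range))
  redraws <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      if (resample) {
        idx <- sample.int(n, n, replace = TRUE)
        tries <- 0L
        while (length(unique(idx)) < 2L && tries < 10L) {
          idx <- sample.int(n, n, replace = TRUE)
          tries <- tries + 1L
          redraws <- redraws + 1L
        }
        Xi <- X[idx, , drop = FALSE]
      } else {
        Xi <- X
      }
      h <- agglomerative(Xi, linkage)
      cuts <- stats::cutree(h, k = K_range)
      for (j in seq_along(K_range)) {
        ps <- partition_sums(Xi, cuts[, j])
        wss_rep[b, j] <- ps$WSS
        bss_rep[b, j] <- ps$BSS
        ch_rep[b, j] <- if (ps$WSS > 0) {
          ch_index(ps$WSS, ps$BSS, n, K_range[j])
        } else NA_real_
      }
    }
  })
  mean_ch <- colMeans(ch_rep, na.rm = TRUE)
  prof <- structure(
    list(K = K_range, B = B, n = n,
         mean_WSS = colMeans(wss_rep, na.rm = TRUE),
         mean_BSS = colMeans(bss_rep, na.rm = TRUE),
         mean_CH = mean_ch,
         sd_CH = apply(ch_rep, 2L, stats::sd, na.rm = TRUE),
         replicates = ch_rep, linkage = linkage, seed = seed,
         redraws = redraws),
    class = "ch_profile")
  opt <- optimal_k(prof)
  prof$optimal_K <- opt$K
  prof$peak <- opt$peak
  prof
}

#' Optimal cluster count from a CH profile
#'
#' Returns the K maximizing the mean CH index (ties broken toward the
#' smallest K) and whether that optimum is an interior peak — i.e. the mean
#' CH at the optimum strictly exceeds both neighboring K values. A profile
#' that rises monotonically to the boundary of the K range has no interior
#' peak, mirroring embeddings in which the between-cluster variance never
#' comes to dominate.
#'
#' @param profile A `ch_profile`.
#' @return List `list(K=, peak=)` with `peak` logical.
#' @export
optimal_k <- function(profile) {
  stopifnot(inherits(profile, "ch_profile"))
  mc <- profile$mean_CH
  j <- which.max(mc)  # which.max takes the first (smallest K) on ties
  peak <- j > 1L && j < length(mc) &&
    mc[j] > mc[j - 1L] && mc[j] > mc[j + 1L]
  list(K = profile$K[j], peak = peak)
}

#' @export
print.ch_profile <- function(x, ...) {
  cat("CH profile: K in [", min(x$K), ",", max(x$K), "], B =", x$B,
      "bootstraps, n =", x$n, "\n")
  cat("  optimal K =", x$optimal_K,
      if (isTRUE(x$peak)) "(interior peak)" else "(no interior peak)", "\n")
  invisible(x)
}

#' Write a CH profile summary as TSV
#' @param profile A `ch_profile`.
#' @param path Output path (columns K, mean_WSS, mean_BSS, mean_CH, sd_CH,
#'   B).
#' @return `path`, invisibly.
#' @export
write_ch_profile <- function(profile, path) {
  utils::write.table(
    data.frame(K = profile$K, mean_WSS = profile$mean_WSS,
               mean_BSS = profile$mean_BSS, mean_CH = profile$mean_CH,
               sd_CH = profile$sd_CH, B = profile$B),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
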