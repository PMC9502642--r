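# Shared fixtures, built in code at test time.

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".faa")
  writeLines(lines, f)
  f
}

random_aaset <- function(n, len_range = c(10L, 60L), seed = 1L) {
  withr::with_seed(seed, {
    lens <- sample(len_range[1L]:len_range[2L], n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(protspace:::AA_CANONICAL, L, replace = TRUE),
            collapse = "")
    }, character(1L))
    Biostrings::AAStringSet(stats::setNames(seqs, paste0("s", seq_len(n))))
  })
}

# Hand-built k-mer vector model around a given token -> vector matrix.
make_model <- function(V, window = 25L) {
  structure(list(vectors = V, d = ncol(V), window = window,
                 training_meta = list()),
            class = "kmer_vector_model")
}

# Two (or more) well-separated Gaussian blobs.
blob_matrix <- function(centers, n_per = 20L, sd = 1, seed = 1L) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      matrix(stats::rnorm(n_per * ncol(centers), sd = sd),
             n_per, ncol(centers)) +
        matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
    }))
    rownames(X) <- paste0("p", seq_len(nrow(X)))
    X
  })
}

# Independent brute-force oracle for within/between sums of squares:
# plain double loops over clusters and elements.
brute_wss_bss <- function(X, labels) {
  grand <- colMeans(X)
  wss <- 0; bss <- 0
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    ctr <- colMeans(X[rows, , drop = FALSE])
    for (i in rows) wss <- wss + sum((X[i, ] - ctr)^2)
    bss <- bss + length(rows) * sum((ctr - grand)^2)
  }
  list(WSS = wss, BSS = bss)
}

# Exhaustive search over all combinations of internal-node flips of a
# small ptree, returning the minimum entanglement against a fixed order.
exhaustive_min_entanglement <- function(tree, other_order, L = 1.5) {
  paths <- protspace:::internal_paths(tree)
  # apply deepest paths first so ancestor flips cannot re-index them
  paths <- paths[order(-lengths(paths))]
  best <- entanglement(tree_leaves(tree), other_order, L)
  n <- length(paths)
  for (mask in 0:(2^n - 1)) {
    t2 <- tree
    for (j in seq_len(n)) {
      if (bitwAnd(mask, bitwShiftL(1L, j - 1L)) != 0L) {
        t2 <- protspace:::flip_at(t2, paths[[j]])
      }
    }
    e <- entanglement(tree_leaves(t2), other_order, L)
    if (e < best) best <- e
  }
  best
}
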