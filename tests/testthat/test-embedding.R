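test_that("embed_protvec sums overlapping 3-mer vectors", {
  toks <- c("MKV", "KVL", "VLA", "LAT")
  withr::with_seed(1, V <- matrix(rnorm(4 * 6), 4, 6,
                                  dimnames = list(toks, NULL)))
  m <- make_model(V)
  s <- Biostrings::AAStringSet(c(one = "MKV", full = "MKVLAT"))
  emb <- embed_protvec(s, m)
  expect_equal(unname(emb["one", ]), unname(V["MKV", ]))
  # brute-force loop oracle
  acc <- rep(0, 6)
  for (km in overlapping_kmers("MKVLAT")) acc <- acc + V[km, ]
  expect_equal(unname(emb["full", ]), unname(acc))
  expect_equal(unname(oov_fraction(emb)), c(0, 0))
})

test_that("out-of-vocabulary k-mers contribute zero and are counted", {
  V <- matrix(1, 1, 4, dimnames = list("MKV", NULL))
  m <- make_model(V)
  emb <- embed_protvec(Biostrings::AAStringSet(c(x = "ACDEFG")), m)
  expect_equal(unname(emb[1L, ]), rep(0, 4))
  expect_equal(unname(oov_fraction(emb)["x"]), 1)
  expect_error(embed_protvec(Biostrings::AAStringSet(c(tiny = "MK")), m),
               "tiny")
})

test_that("summation embedding is linear over splits of the k-mer list", {
  s <- random_aaset(3, len_range = c(20L, 30L), seed = 6)
  m <- train_skipgram(kmer_corpus(s), d = 8, window = 2, epochs = 1, seed = 1)
  emb <- embed_protvec(s, m)
  for (i in seq_along(s)) {
    kms <- overlapping_kmers(as.character(s[[i]]))
    half <- seq_len(floor(length(kms) / 2))
    part <- function(kk) {
      colSums(m$vectors[intersect(kk, rownames(m$vectors)), , drop = FALSE])
    }
    expect_equal(unname(emb[i, ]),
                 unname(part(kms[half])) + unname(part(kms[-half])),
                 tolerance = 1e-12)
  }
})

test_that("embed_kmer_freq counts reduced k-mers over length", {
  emb <- embed_kmer_freq(Biostrings::AAStringSet(c(a = "AAAA")))
  expect_equal(ncol(emb), 1000L)
  expect_equal(unname(emb[1L, "AAA"]), 0.5)  # two overlapping AAA over L=4
  expect_equal(sum(emb[1L, ] != 0), 1L)
})

test_that("k-mer frequency rows obey the (L-2)/L sum law and bounds", {
  s <- random_aaset(30, len_range = c(5L, 120L), seed = 12)
  emb <- embed_kmer_freq(s)
  L <- Biostrings::width(s)
  expect_equal(unname(rowSums(emb)), (L - 2) / L, tolerance = 1e-12)
  expect_true(all(emb >= 0))
  expect_true(all(emb <= (L - 2) / L + 1e-12))
})

test_that("zscore standardizes columns with population sd", {
  m <- rbind(c(0, 5, 1), c(2, 5, 3))
  expect_warning(z <- zscore(m), "constant")
  expect_equal(unname(z[, 1L]), c(-1, 1))
  expect_equal(unname(z[, 2L]), c(0, 0))  # constant column zeroed
  expect_error(zscore(m[1L, , drop = FALSE]), "2 rows")
})

test_that("zscore meets its audit contract and is idempotent", {
  withr::with_seed(3, X <- matrix(rnorm(200), 20, 10))
  z <- zscore(X)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  sds <- sqrt(colMeans(sweep(unclass(z), 2, colMeans(z))^2))
  expect_lt(max(abs(sds - 1)), 1e-9)
  z2 <- zscore(z)
  expect_equal(unclass(z2), unclass(z), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(attr(z, "normalized"))
})

test_that("pca projection captures rank-1 data and matches the eigen oracle", {
  t_ <- seq(0, 1, length.out = 10)
  line <- cbind(t_, 2 * t_, -t_)
  p <- project(line, "pca", dims = 2)
  expect_gte(stats::var(p[, 1L]) / sum(apply(line, 2, stats::var)),
             1 - 1e-9)
  withr::with_seed(9, X <- matrix(rnorm(100), 20, 5))
  p2 <- project(X, "pca", dims = 2)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values  # oracle
  expect_equal(unname(apply(p2, 2, stats::var)), ev[1:2], tolerance = 1e-9)
  expect_error(project(X, "pca", dims = 5), "dims")
})

test_that("pca axis signs are deterministic", {
  withr::with_seed(4, X <- matrix(rnorm(60), 12, 5))
  p <- project(X, "pca")
  expect_identical(p, project(X, "pca"))
  # scores agree with prcomp up to the fixed sign convention
  ref <- stats::prcomp(X, rank. = 2)$x
  for (j in 1:2) {
    expect_equal(abs(stats::cor(p[, j], ref[, j])), 1, tolerance = 1e-9)
  }
})

test_that("tsne projection stays finite on degenerate input and is seeded", {
  X <- matrix(1, 3, 4)  # three identical points
  out <- project(X, "tsne", dims = 2, seed = 1)
  expect_true(all(is.finite(out)))
  withr::with_seed(5, Y <- rbind(matrix(rnorm(40), 10, 4),
                                 matrix(rnorm(40, mean = 8), 10, 4)))
  a <- project(Y, "tsne", seed = 3)
  b <- project(Y, "tsne", seed = 3)
  expect_identical(a, b)
  # well-separated groups stay separated in the projection
  d <- as.matrix(stats::dist(a))
  within <- mean(d[1:10, 1:10][upper.tri(diag(10))])
  between <- mean(d[1:10, 11:20])
  expect_gt(between, within)
})

test_that("embeddings round-trip through TSV with metadata", {
  s <- random_aaset(4, len_range = c(10L, 20L), seed = 2)
  emb <- embed_kmer_freq(s)
  f <- tempfile(fileext = ".tsv")
  write_embedding(emb, f)
  back <- read_embedding(f)
  expect_equal(rownames(back), rownames(emb))
  expect_equal(unclass(back), unclass(emb), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(attr(back, "method"), "kmer_freq")
})
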