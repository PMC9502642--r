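test_that("corpus generation is byte-reproducible for a fixed seed", {
  c1 <- generate_corpus(F = 3, n_per_family = 4, seed = 9)
  c2 <- generate_corpus(F = 3, n_per_family = 4, seed = 9)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(c1$sequences, f1); write_fasta(c2$sequences, f2)
  expect_identical(readLines(f1), readLines(f2))
  c3 <- generate_corpus(F = 3, n_per_family = 4, seed = 10)
  expect_false(identical(as.character(c1$sequences),
                         as.character(c3$sequences)))
})

test_that("fully conserved single-family corpora share the motif block", {
  corp <- generate_corpus(F = 1, n_per_family = 6, p_cons = 1,
                          length_range = c(80, 80), seed = 3)
  motif <- corp$motifs[[1L]]
  expect_equal(nchar(motif), 30L)
  for (s in as.character(corp$sequences)) {
    expect_true(grepl(motif, s, fixed = TRUE))
  }
})

test_that("generated corpora pass the default filters and carry full truth", {
  corp <- generate_corpus(F = 4, n_per_family = 5, seed = 6)
  kept <- filter_sequences(corp$sequences)
  expect_equal(length(kept), length(corp$sequences))
  expect_equal(drop_counts(kept), c(ambiguous = 0L, length = 0L))
  expect_equal(nrow(corp$truth), 20L)
  expect_setequal(corp$truth$sequence_id, names(corp$sequences))
})

test_that("unknown families are held out of the annotation table", {
  none <- generate_corpus(F = 5, n_per_family = 4, seed = 2,
                          unknown_fraction = 0)
  expect_length(none$unknown_ids, 0L)
  expect_equal(nrow(none$annotations), 20L)
  some <- generate_corpus(F = 5, n_per_family = 4, seed = 2,
                          unknown_fraction = 0.2)
  expect_length(some$unknown_ids, 4L)  # one whole family withheld
  expect_length(intersect(some$unknown_ids,
                          some$annotations$sequence_id), 0L)
  fams_unknown <- unique(some$truth$family[
    some$truth$sequence_id %in% some$unknown_ids])
  expect_length(fams_unknown, 1L)
})

test_that("the mock ontology nests families pairwise and balanced", {
  corp <- generate_corpus(F = 5, n_per_family = 2, seed = 1)
  ann <- corp$annotations
  expect_length(unique(ann$subsystem), 3L)   # ceiling(5/2)
  expect_length(unique(ann$subclass), 2L)
  expect_length(unique(ann$class), 1L)
  # family -> subsystem assignment is a function of the family index
  merged <- merge(ann, corp$truth, by = "sequence_id")
  expect_equal(unique(merged$subsystem[merged$family == 1]),
               unique(merged$subsystem[merged$family == 2]))
  expect_false(unique(merged$subsystem[merged$family == 3]) ==
                 unique(merged$subsystem[merged$family == 1]))
})

test_that("within-family identity exceeds between-family identity", {
  corp <- generate_corpus(F = 2, n_per_family = 4, p_cons = 0.9,
                          length_range = c(50, 70), seed = 7)
  chars <- as.character(corp$sequences)
  fam <- corp$truth$family
  within <- c(); between <- c()
  for (i in 1:7) {
    for (j in (i + 1):8) {
      pid <- pairwise_identity(chars[[i]], chars[[j]])
      if (fam[i] == fam[j]) within <- c(within, pid)
      else between <- c(between, pid)
    }
  }
  expect_gt(mean(within), mean(between))
})

test_that("label perturbation respects its fraction contract", {
  corp <- generate_corpus(F = 4, n_per_family = 5, seed = 5)
  same <- perturb_labels(corp, swap_fraction = 0, seed = 1)
  expect_identical(same$annotations, corp$annotations)
  all_swapped <- perturb_labels(corp, swap_fraction = 1, seed = 1)
  expect_true(all(all_swapped$annotations$subsystem !=
                    corp$annotations$subsystem))
  # truth labels untouched
  expect_identical(all_swapped$truth, corp$truth)
  half <- perturb_labels(corp, swap_fraction = 0.5, seed = 1)
  expect_equal(sum(half$annotations$subsystem !=
                     corp$annotations$subsystem), 10L)
})

test_that("perturbing the ontology raises embedding-vs-ontology entanglement", {
  corp <- generate_corpus(F = 5, n_per_family = 6, p_cons = 0.95,
                          length_range = c(60, 90), seed = 31)
  emb <- embed_kmer_freq(corp$sequences)
  h <- agglomerative(emb)
  base_tree <- build_annotation_hierarchy(corp$annotations)
  ent <- function(tree) {
    untangle_step2side(tanglegram(h, tree))$entanglement
  }
  e0 <- ent(base_tree)
  wins <- 0L
  for (s in 1:5) {
    pert <- perturb_labels(corp, swap_fraction = 0.5, seed = s)
    e1 <- ent(build_annotation_hierarchy(pert$annotations))
    if (e1 >= e0) wins <- wins + 1L
  }
  # one-sided sign test at alpha = 0.05 over the 5 perturbation seeds
  expect_gte(wins, 5L)
})

test_that("corpus files land on disk as FASTA + TSV", {
  corp <- generate_corpus(F = 2, n_per_family = 3, seed = 8,
                          unknown_fraction = 0.5)
  d <- tempfile()
  write_corpus_files(corp, d)
  seqs <- read_fasta(file.path(d, "sequences.faa"))
  expect_length(seqs, 6L)
  ann <- read_annotations(file.path(d, "annotations.tsv"), n_levels = 4L)
  expect_equal(nrow(ann), nrow(corp$annotations))
  truth <- utils::read.delim(file.path(d, "truth.tsv"))
  expect_equal(nrow(truth), 6L)
})
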