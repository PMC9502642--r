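# Collect (root path of internal labels, leaf id) pairs from a tree.
leaf_paths <- function(tree) {
  out <- list()
  walk <- function(node, labs) {
    if (protspace:::is_leaf(node)) {
      out[[length(out) + 1L]] <<- list(leaf = node$leaf, labels = labs)
      return(invisible(NULL))
    }
    for (ch in node$children) {
      walk(ch, c(labs, node$label))
    }
  }
  walk(tree, character(0))
  out
}

ann_df <- function(ids, ...) {
  data.frame(sequence_id = ids, ..., stringsAsFactors = FALSE)
}

test_that("annotation hierarchies nest labels coarse to fine", {
  ann <- ann_df(c("s1", "s2", "s3", "s4"),
                subclass = rep("Di-oligosaccharides", 4),
                subsystem = c("Maltose", "Maltose", "Lactose", "Lactose"))
  tree <- build_annotation_hierarchy(ann)
  expect_setequal(tree_leaves(tree), ann$sequence_id)
  # 1 subclass node at top, 2 subsystem children, 4 leaves
  expect_equal(tree$label, "Di-oligosaccharides")
  expect_length(tree$children, 2L)
  expect_equal(sort(vapply(tree$children, `[[`, character(1), "label")),
               c("Lactose", "Maltose"))
  single <- build_annotation_hierarchy(ann[1L, ])
  expect_equal(tree_leaves(single), "s1")
})

test_that("hierarchy leaves read back their annotation paths", {
  withr::with_seed(33, {
    n <- 50L
    ann <- ann_df(sprintf("q%02d", 1:n),
                  class = sample(paste0("C", 1:2), n, replace = TRUE),
                  subclass = sample(paste0("SC", 1:3), n, replace = TRUE),
                  subsystem = sample(paste0("SS", 1:5), n, replace = TRUE))
  })
  tree <- build_annotation_hierarchy(ann)
  for (lp in leaf_paths(tree)) {
    row <- ann[ann$sequence_id == lp$leaf, ]
    labs <- setdiff(lp$labels, "root")
    expect_equal(labs, unlist(row[c("class", "subclass", "subsystem")],
                              use.names = FALSE))
  }
  expect_length(tree_leaves(tree), n)
})

test_that("conflicting label paths and unannotated rows are handled", {
  ann <- ann_df(c("s1", "s1"), subsystem = c("A", "B"))
  expect_error(build_annotation_hierarchy(ann), "conflicting.*s1")
  ann2 <- ann_df(c("s1", "s2"), subsystem = c("A", "B"))
  ann2$unannotated <- c(FALSE, TRUE)
  expect_equal(tree_leaves(build_annotation_hierarchy(ann2)), "s1")
})

test_that("entanglement is 0 for identical, 1 for reversed orders", {
  o <- letters[1:8]
  expect_equal(entanglement(o, o), 0)
  expect_equal(entanglement(o, rev(o)), 1)
  expect_equal(entanglement(c("a", "b"), c("b", "a")), 1)  # hand: 2/2
  expect_error(entanglement(c("a", "b"), c("a", "c")), "differ")
})

test_that("entanglement is symmetric and relabeling-invariant", {
  withr::with_seed(21, {
    for (i in 1:10) {
      o1 <- sample(letters[1:9])
      o2 <- sample(letters[1:9])
      expect_equal(entanglement(o1, o2), entanglement(o2, o1),
                   tolerance = 1e-12)
      map <- stats::setNames(LETTERS[1:9], letters[1:9])
      expect_equal(entanglement(unname(map[o1]), unname(map[o2])),
                   entanglement(o1, o2), tolerance = 1e-12)
    }
  })
})

test_that("untangling never increases entanglement and solves mirrors", {
  X <- blob_matrix(rbind(c(0, 0), c(10, 10)), n_per = 3, sd = 1, seed = 5)
  h <- agglomerative(X)
  t1 <- as_ptree(h)
  # mirror every internal node of the right-hand copy
  mirror <- function(node) {
    if (protspace:::is_leaf(node)) return(node)
    node$children <- rev(lapply(node$children, mirror))
    node
  }
  tg <- tanglegram(t1, mirror(t1))
  expect_gt(tg$entanglement, 0)
  ut <- untangle_step2side(tg)
  expect_equal(ut$entanglement, 0)
  expect_lte(ut$entanglement, ut$initial_entanglement)
  # exhaustive flip search confirms 0 is attainable (<= 6 leaves)
  expect_equal(exhaustive_min_entanglement(mirror(t1), tree_leaves(t1)), 0)
  # an already aligned tanglegram is left unchanged
  tg0 <- untangle_step2side(tanglegram(t1, t1))
  expect_equal(tg0$entanglement, 0)
  expect_identical(tree_leaves(tg0$left), tree_leaves(tg0$right))
})

test_that("untangling reaches a flip-local optimum on random 8-leaf pairs", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      X1 <- matrix(rnorm(16), 8, 2, dimnames = list(letters[1:8], NULL))
      X2 <- matrix(rnorm(16), 8, 2, dimnames = list(letters[1:8], NULL))
      tg <- tanglegram(agglomerative(X1), agglomerative(X2))
      ut <- untangle_step2side(tg)
      expect_lte(ut$entanglement, tg$entanglement)
      # every single-flip neighbor is no better (checked exhaustively)
      for (side in c("left", "right")) {
        tree <- ut[[side]]
        other <- tree_leaves(ut[[setdiff(c("left", "right"), side)]])
        for (path in protspace:::internal_paths(tree)) {
          flipped <- protspace:::flip_at(tree, path)
          expect_gte(entanglement(tree_leaves(flipped), other) + 1e-12,
                     ut$entanglement)
        }
      }
    }
  })
})

test_that("subsystem_split_report counts contiguous label blocks", {
  mk_tree <- function(ids) {
    # left-comb tree with the given leaf order
    node <- protspace:::ptree_leaf(ids[1L])
    for (i in seq_along(ids)[-1L]) {
      node <- protspace:::ptree_node(list(node, protspace:::ptree_leaf(ids[i])))
    }
    node
  }
  ann <- ann_df(paste0("s", 1:4), subsystem = c("A", "A", "B", "B"))
  rep1 <- subsystem_split_report(mk_tree(paste0("s", 1:4)), ann)
  expect_equal(rep1$n_blocks, c(1L, 1L))
  ann2 <- ann_df(paste0("s", 1:4), subsystem = c("A", "B", "A", "B"))
  rep2 <- subsystem_split_report(mk_tree(paste0("s", 1:4)), ann2)
  expect_equal(sort(rep2$n_blocks), c(2L, 2L))
  # brute-force run counting oracle on random labelings
  withr::with_seed(41, {
    for (i in 1:30) {
      n <- sample(4:12, 1)
      labs <- sample(LETTERS[1:3], n, replace = TRUE)
      ann3 <- ann_df(paste0("x", 1:n), subsystem = labs)
      rep3 <- subsystem_split_report(mk_tree(paste0("x", 1:n)), ann3)
      for (l in unique(labs)) {
        runs <- 0L
        for (j in seq_len(n)) {
          if (labs[j] == l && (j == 1L || labs[j - 1L] != l)) runs <- runs + 1L
        }
        expect_equal(rep3$n_blocks[rep3$label == l], runs)
      }
    }
  })
})

test_that("trees serialize to Newick that ape can parse", {
  X <- blob_matrix(rbind(c(0, 0), c(5, 5)), n_per = 3, sd = 0.5, seed = 6)
  h <- agglomerative(X)
  nwk <- to_newick(h)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, rownames(X))
  ann <- ann_df(paste0("s", 1:4),
                subclass = c("u", "u", "v", "v"),
                subsystem = c("A", "B", "C", "C"))
  tree <- build_annotation_hierarchy(ann)
  f <- tempfile(fileext = ".nwk")
  to_newick(tree, f)
  phy2 <- ape::read.tree(f)
  expect_setequal(phy2$tip.label, paste0("s", 1:4))
})
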