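# Lightweight rooted-tree representation used for tanglegram work:
# a leaf is list(leaf = <id>); an internal node is
# list(label = <chr or NULL>, children = list(<nodes>)). Leaf order is
# depth-first, left to right. Both binary dendrograms (from hclust) and
# n-ary annotation hierarchies use the same shape, so flips and
# entanglement are defined uniformly.

ptree_leaf <- function(id) structure(list(leaf = id), class = "ptree")

ptree_node <- function(children, label = NULL) {
  structure(list(label = label, children = children), class = "ptree")
}

is_leaf <- function(node) !is.null(node$leaf)

#' Leaf ids of a tree in display (depth-first) order
#' @param tree A `ptree` (see [as_ptree()]).
#' @return Character vector of leaf ids.
#' @export
tree_leaves <- function(tree) {
  if (is_leaf(tree)) return(tree$leaf)
  unlist(lapply(tree$children, tree_leaves), use.names = FALSE)
}

#' Convert a dendrogram to the package's tree representation
#' @param x An `hclust` object.
#' @param ... Unused.
#' @return A `ptree` whose leaf order matches `x$order`.
#' @export
as_ptree <- function(x, ...) UseMethod("as_ptree")

#' @export
as_ptree.hclust <- function(x, ...) {
  labels <- x$labels
  if (is.null(labels)) labels <- as.character(seq_along(x$order))
  build <- function(i) {
    if (i < 0L) return(ptree_leaf(labels[-i]))
    ptree_node(list(build(x$merge[i, 1L]), build(x$merge[i, 2L])))
  }
  build(nrow(x$merge))
}

#' @export
as_ptree.ptree <- function(x, ...) x

#' Build an annotation hierarchy tree from a label table
#'
#' Nests sequences under their hierarchy labels, coarse level at the top and
#' the finest label (e.g. the SEED subsystem) immediately above the leaves;
#' leaves are the annotated sequence ids. Unannotated rows are excluded.
#' Within each node children are ordered lexicographically by label, and
#' leaves by id, so the initial leaf order groups sequences by finest label.
#' Level heights are ordinal (by depth): the ontology carries no branch
#' lengths.
#'
#' @param annotations Data frame from [read_annotations()] (columns:
#'   `sequence_id`, label columns, optional logical `unannotated`).
#' @param levels Character vector naming the label columns to use, coarse to
#'   fine; defaults to all non-id, non-flag columns.
#' @return A `ptree`; internal nodes carry their label.
#' @export
build_annotation_hierarchy <- function(annotations, levels = NULL) {
  df <- annotations
  if (!is.null(df$unannotated)) df <- df[!df$unannotated, , drop = FALSE]
  if (is.null(levels)) {
    levels <- setdiff(names(df), c("sequence_id", "unannotated"))
  }
  if (!length(levels)) stop("no hierarchy levels selected")
  if (anyDuplicated(df$sequence_id)) {
    dup <- unique(df$sequence_id[duplicated(df$sequence_id)])
    paths <- apply(df[levels], 1L, paste, collapse = "/")
    for (d in dup) {
      if (length(unique(paths[df$sequence_id == d])) > 1L) {
        stop("conflicting label paths for sequence '", d, "'")
      }
    }
    df <- df[!duplicated(df$sequence_id), , drop = FALSE]
  }
  nest <- function(rows, depth) {
    if (depth > length(levels)) {
      ids <- sort(df$sequence_id[rows])
      return(lapply(ids, ptree_leaf))
    }
    labs <- df[[levels[depth]]][rows]
    out <- lapply(sort(unique(labs)), function(l) {
      ptree_node(nest(rows[labs == l], depth + 1L), label = l)
    })
    out
  }
  kids <- nest(seq_len(nrow(df)), 1L)
  if (length(kids) == 1L) kids[[1L]] else ptree_node(kids, label = "root")
}

#' Tanglegram entanglement of two leaf orders
#'
#' With `u_i`, `v_i` the ranks of leaf i in the two orders, entanglement is
#' `sum(|u_i - v_i|^L)` normalized by the value attained when one order is
#' the exact reverse of the other, giving a score in `[0, 1]`: 0 for
#' identical orders, 1 for reversed orders.
#'
#' @param order_left,order_right Character vectors over the same leaf set.
#' @param L Exponent (default 1.5, the conventional tanglegram setting).
#' @return Entanglement in `[0, 1]` (0 for a single leaf).
#' @export
entanglement <- function(order_left, order_right, L = 1.5) {
  if (!setequal(order_left, order_right) ||
      length(order_left) != length(order_right)) {
    diffs <- c(setdiff(order_left, order_right),
               setdiff(order_right, order_left))
    stop("leaf sets differ: ", paste(unique(diffs), collapse = ", "))
  }
  n <- length(order_left)
  if (n < 2L) return(0)
  u <- seq_len(n)
  v <- match(order_left, order_right)
  denom <- sum(abs(u - rev(u))^L)
  sum(abs(u - v)^L) / denom
}

#' Pair two trees over the same leaves as a tanglegram
#'
#' @param left,right `ptree` or `hclust` objects exposing identical leaf id
#'   sets.
#' @param L Entanglement exponent (default 1.5).
#' @return Object of class `tanglegram`: `left`, `right`, `L`,
#'   `entanglement` (for the current leaf orders).
#' @export
tanglegram <- function(left, right, L = 1.5) {
  left <- as_ptree(left)
  right <- as_ptree(right)
  e <- entanglement(tree_leaves(left), tree_leaves(right), L)
  structure(list(left = left, right = right, L = L, entanglement = e),
            class = "tanglegram")
}

#' @export
print.tanglegram <- function(x, ...) {
  cat("Tanglegram over", length(tree_leaves(x$left)),
      "leaves; entanglement =", signif(x$entanglement, 4), "\n")
  invisible(x)
}

# Depth-first left-to-right paths to every internal node; a path is an
# integer vector of child indices from the root (root = integer(0)).
internal_paths <- function(tree) {
  out <- list()
  walk <- function(node, path) {
    if (is_leaf(node)) return(invisible(NULL))
    out[[length(out) + 1L]] <<- path
    for (i in seq_along(node$children)) walk(node$children[[i]], c(path, i))
  }
  walk(tree, integer(0))
  out
}

flip_at <- function(tree, path) {
  if (!length(path)) {
    tree$children <- rev(tree$children)
    return(tree)
  }
  i <- path[1L]
  tree$children[[i]] <- flip_at(tree$children[[i]], path[-1L])
  tree
}

#' Untangle a tanglegram by alternating greedy branch flips
#'
#' The step2side heuristic: holding one side fixed, visit the other side's
#' internal nodes depth-first left-to-right and reverse a node's children
#' whenever that strictly decreases the entanglement; then swap roles.
#' Alternation continues until a full round changes nothing or `max_rounds`
#' is reached. The final entanglement never exceeds the initial one.
#'
#' @param tg A [tanglegram()].
#' @param max_rounds Maximum alternation rounds (default 10).
#' @return The untangled `tanglegram`, with `initial_entanglement` and
#'   `rounds` recorded.
#' @export
untangle_step2side <- function(tg, max_rounds = 10L) {
  stopifnot(inherits(tg, "tanglegram"))
  left <- tg$left; right <- tg$right; L <- tg$L
  e0 <- entanglement(tree_leaves(left), tree_leaves(right), L)
  cur <- e0
  rounds <- 0L
  repeat {
    changed <- FALSE
    for (side in c("left", "right")) {
      tree <- if (side == "left") left else right
      other_order <- tree_leaves(if (side == "left") right else left)
      for (path in internal_paths(tree)) {
        cand <- flip_at(tree, path)
        e_new <- entanglement(tree_leaves(cand), other_order, L)
        if (e_new < cur) {
          tree <- cand
          cur <- e_new
          changed <- TRUE
        }
      }
      if (side == "left") left <- tree else right <- tree
    }
    rounds <- rounds + 1L
    if (!changed || rounds >= max_rounds) break
  }
  structure(list(left = left, right = right, L = L, entanglement = cur,
                 initial_entanglement = e0, rounds = rounds),
            class = "tanglegram")
}

#' Report finest-label contiguity in a dendrogram's leaf order
#'
#' For each finest-level annotation label, counts the maximal blocks of
#' consecutive same-label leaves in the dendrogram's display order: 1 means
#' the label's sequences sit in one contiguous clade-run; 2 or more means
#' the label is split across distant parts of the tree (functional labels
#' whose members the embedding separates).
#'
#' @param dend An `hclust` or `ptree` whose leaves are annotated ids.
#' @param annotations Annotation data frame.
#' @param finest_level Name of the label column to score (default the last
#'   non-id, non-flag column).
#' @return Data frame with columns `label`, `n_leaves`, `n_blocks`, sorted
#'   by decreasing `n_blocks`.
#' @export
subsystem_split_report <- function(dend, annotations, finest_level = NULL) {
  ord <- tree_leaves(as_ptree(dend))
  if (is.null(finest_level)) {
    finest_level <- utils::tail(
      setdiff(names(annotations), c("sequence_id", "unannotated")), 1L)
  }
  lab <- annotations[[finest_level]][match(ord, annotations$sequence_id)]
  keep <- !is.na(lab)
  lab <- lab[keep]
  runs <- rle(lab)
  blocks <- table(runs$values)
  counts <- table(lab)
  out <- data.frame(label = names(blocks),
                    n_leaves = as.integer(counts[names(blocks)]),
                    n_blocks = as.integer(blocks),
                    stringsAsFactors = FALSE)
  out[order(-out$n_blocks, out$label), , drop = FALSE]
}

#' Serialize a tree as Newick
#'
#' Dendrograms and annotation hierarchies are written as Newick strings
#' (leaf names = sequence ids; internal annotation labels preserved);
#' `hclust` trees go through [ape::as.phylo()] so merge heights become
#' branch lengths.
#'
#' @param tree A `ptree` or `hclust`.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if `path` is given.
#' @export
to_newick <- function(tree, path = NULL) {
  if (inherits(tree, "hclust")) {
    nwk <- ape::write.tree(ape::as.phylo(tree))
  } else {
    rec <- function(node) {
      if (is_leaf(node)) return(gsub("[ ,;:()]", "_", node$leaf))
      paste0("(", paste(vapply(node$children, rec, character(1L)),
                        collapse = ","), ")",
             if (!is.null(node$label)) gsub("[ ,;:()]", "_", node$label)
             else "")
    }
    nwk <- paste0(rec(tree), ";")
  }
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
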