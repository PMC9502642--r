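#' Generate a synthetic protein corpus with planted families and ontology
#'
#' Emulates a filtered bacterial protein set: F sequence families, each
#' defined by a distinct conserved motif planted over a random background.
#' Every sequence is background residues (uniform over the 20 canonical
#' letters by default) of a length drawn uniformly from `length_range`,
#' with its family's motif written in at a random admissible offset; each
#' motif position is emitted faithfully with probability `p_cons` and
#' replaced by a background draw otherwise. Motifs are redrawn if two
#' families would share more than 50% positional identity, which keeps
#' families separable at high `p_cons`. No sequence contains 'X', so the
#' whole corpus passes [filter_sequences()] at its defaults.
#'
#' Families are nested into a balanced mock 4-level ontology by repeated
#' pairing: families 2j-1, 2j share subsystem j, subsystems pair into
#' subclasses, subclasses into classes, classes into superclasses. A
#' seeded subset of `round(unknown_fraction * F)` whole families is held
#' out as the "unknown" set: their sequences receive no annotation
#' records, mirroring unannotated proteins drawn from functions absent
#' from the ontology.
#'
#' @param F Number of families (>= 1).
#' @param n_per_family Sequences per family.
#' @param length_range Integer `c(min, max)` sequence length (default
#'   `c(30, 300)`; minimum must be >= `motif_len` and >= 30).
#' @param p_cons Per-position motif conservation probability (default 0.9).
#' @param motif_len Motif length (default 30).
#' @param unknown_fraction Fraction of families held out unannotated
#'   (default 0).
#' @param seed Integer seed; the corpus is fully reproducible.
#' @param background Optional length-20 probability vector over
#'   [AA_CANONICAL]-ordered residues (default uniform).
#' @return Object of class `synthetic_corpus`: `sequences`
#'   (`AAStringSet`), `truth` (data frame id/family), `annotations`
#'   (data frame as from [read_annotations()], annotated ids only),
#'   `unknown_ids`, `motifs` (per family), `seed`.
#' @export
generate_corpus <- function(F, n_per_family, length_range = c(30L, 300L),
                            p_cons = 0.9, motif_len = 30L,
                            unknown_fraction = 0, seed = 1L,
                            background = NULL) {
  stopifnot(F >= 1L, n_per_family >= 1L, p_cons >= 0, p_cons <= 1)
  lmin <- as.integer(length_range[1L]); lmax <- as.integer(length_range[2L])
  if (lmin < motif_len || lmin < 30L) {
    stop("minimum length must be >= motif_len and >= 30")
  }
  if (is.null(background)) background <- rep(1 / 20, 20L)
  if (length(background) != 20L) stop("background must have 20 entries")

  corpus <- withr::with_seed(seed, {
    draw_bg <- function(n) sample(AA_CANONICAL, n, replace = TRUE,
                                  prob = background)
    motifs <- list()
    for (f in seq_len(F)) {
      repeat {
        cand <- draw_bg(motif_len)
        clash <- any(vapply(motifs, function(m) {
          mean(m == cand) > 0.5
        }, logical(1L)))
        if (!clash) break
      }
      motifs[[f]] <- cand
    }
    ids <- character(0); seqs <- character(0); fam <- integer(0)
    for (f in seq_len(F)) {
      for (s in seq_len(n_per_family)) {
        L <- lmin + sample.int(lmax - lmin + 1L, 1L) - 1L
        res <- draw_bg(L)
        off <- sample.int(L - motif_len + 1L, 1L)
        keep <- stats::runif(motif_len) < p_cons
        seg <- motifs[[f]]
        seg[!keep] <- draw_bg(sum(!keep))
        res[off:(off + motif_len - 1L)] <- seg
        ids <- c(ids, sprintf("F%02d_S%03d", f, s))
        seqs <- c(seqs, paste(res, collapse = ""))
        fam <- c(fam, f)
      }
    }
    n_unknown_fam <- round(unknown_fraction * F)
    unknown_fams <- if (n_unknown_fam > 0L) {
      sort(sample.int(F, n_unknown_fam))
    } else integer(0)
    list(ids = ids, seqs = seqs, fam = fam, motifs = motifs,
         unknown_fams = unknown_fams)
  })

  sequences <- Biostrings::AAStringSet(
    stats::setNames(corpus$seqs, corpus$ids))
  truth <- data.frame(sequence_id = corpus$ids, family = corpus$fam,
                      stringsAsFactors = FALSE)
  lab <- family_ontology_labels(corpus$fam)
  annotated <- !(corpus$fam %in% corpus$unknown_fams)
  annotations <- cbind(
    data.frame(sequence_id = corpus$ids[annotated],
               stringsAsFactors = FALSE),
    lab[annotated, , drop = FALSE])
  annotations$unannotated <- FALSE
  rownames(annotations) <- NULL
  structure(
    list(sequences = sequences, truth = truth, annotations = annotations,
         unknown_ids = corpus$ids[!annotated],
         motifs = lapply(corpus$motifs, paste, collapse = ""),
         seed = as.integer(seed)),
    class = "synthetic_corpus")
}

# Balanced mock hierarchy: family -> subsystem (pairwise) -> subclass ->
# class -> superclass, each level pairing the one below.
family_ontology_labels <- function(fam) {
  subsystem <- ceiling(fam / 2)
  subclass <- ceiling(subsystem / 2)
  class <- ceiling(subclass / 2)
  superclass <- ceiling(class / 2)
  data.frame(
    superclass = sprintf("superclass_%02d", superclass),
    class = sprintf("class_%02d", class),
    subclass = sprintf("subclass_%02d", subclass),
    subsystem = sprintf("subsystem_%02d", subsystem),
    stringsAsFactors = FALSE)
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("Synthetic corpus:", length(x$sequences), "sequences,",
      length(x$motifs), "families,", length(x$unknown_ids),
      "unannotated\n")
  invisible(x)
}

#' Randomly reassign finest-level labels of annotated sequences
#'
#' Swaps the subsystem (finest) label of a seeded random subset of
#' annotated sequences to a different subsystem's label, leaving the truth
#' labels and coarser levels untouched. This manufactures disagreement
#' between the embedding's organization and the ontology, raising
#' tanglegram entanglement.
#'
#' @param corpus A [generate_corpus()] result.
#' @param swap_fraction Fraction of annotated sequences to relabel, in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @return The corpus with modified `annotations`.
#' @export
perturb_labels <- function(corpus, swap_fraction, seed = 1L) {
  stopifnot(inherits(corpus, "synthetic_corpus"),
            swap_fraction >= 0, swap_fraction <= 1)
  ann <- corpus$annotations
  n <- nrow(ann)
  n_swap <- round(swap_fraction * n)
  if (n_swap == 0L) return(corpus)
  all_subsystems <- unique(ann$subsystem)
  if (length(all_subsystems) < 2L) {
    stop("need at least 2 subsystem labels to perturb")
  }
  withr::with_seed(seed, {
    pick <- sample.int(n, n_swap)
    for (i in pick) {
      others <- setdiff(all_subsystems, ann$subsystem[i])
      ann$subsystem[i] <- sample(others, 1L)
    }
  })
  corpus$annotations <- ann
  corpus
}

#' Write a synthetic corpus to plain-text files
#'
#' @param corpus A `synthetic_corpus`.
#' @param dir Output directory (created if needed): `sequences.faa`,
#'   `annotations.tsv`, `truth.tsv`.
#' @return `dir`, invisibly.
#' @export
write_corpus_files <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(corpus$sequences, file.path(dir, "sequences.faa"))
  write_annotations(corpus$annotations, file.path(dir, "annotations.tsv"))
  utils::write.table(corpus$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
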