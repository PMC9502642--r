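ALLOWED_PARSE <- c(AA_CANONICAL, "X")

#' Read a protein FASTA file into an AAStringSet
#'
#' Residues are upper-cased; the header token before the first whitespace
#' becomes the sequence id and the remainder of the header, if any, is kept
#' as a `description` metadata column. Ids must be unique and residues are
#' restricted to the 20 canonical amino-acid letters plus 'X' (ambiguous);
#' any other character — including the ambiguity codes B, Z, J, U, O — is
#' rejected at parse time rather than silently filtered.
#'
#' @param path Path to a FASTA file.
#' @return An [Biostrings::AAStringSet]; element metadata holds the header
#'   descriptions.
#' @examples
#' f <- tempfile(fileext = ".faa")
#' writeLines(c(">a", "MKV", ">b", "ACDE"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  ids <- character(0)
  desc <- character(0)
  seqs <- character(0)
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, ">")) {
      header <- sub("^>", "", ln)
      id <- sub("\\s.*$", "", header)
      if (!nzchar(id)) stop("empty sequence id at line ", i)
      ids <- c(ids, id)
      desc <- c(desc, sub("^\\S*\\s*", "", header))
      seqs <- c(seqs, "")
      cur <- length(seqs)
    } else {
      if (is.null(cur)) {
        stop("malformed FASTA: sequence data before any header at line ", i)
      }
      seqs[cur] <- paste0(seqs[cur], toupper(gsub("\\s", "", ln)))
    }
  }
  if (length(ids) == 0L) return(Biostrings::AAStringSet())
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  empty <- !nzchar(seqs)
  if (any(empty)) stop("empty sequence for id: ", ids[which(empty)[1L]])
  for (j in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[j]], "", fixed = TRUE)[[1L]])
    bad <- setdiff(chars, ALLOWED_PARSE)
    if (length(bad)) {
      stop("disallowed character '", bad[1L], "' in sequence '", ids[j], "'")
    }
  }
  out <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
  out
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs An `AAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Filter sequences on ambiguity and length
#'
#' Retains exactly the sequences containing no 'X' whose length lies within
#' `[min_len, max_len]`; the bounds are inclusive because only strictly
#' shorter / strictly longer sequences are discarded. Input order is
#' preserved. The ambiguity check is applied before the length check, and
#' drops are reported separately by reason in the `drop_counts` attribute
#' (`ambiguous`, then `length`).
#'
#' @param seqs An `AAStringSet`.
#' @param min_len Minimum retained length (default 30: shorter sequences are
#'   unlikely to form a protein domain).
#' @param max_len Maximum retained length (default 1024).
#' @return Filtered `AAStringSet` with attribute `drop_counts`, a named
#'   integer vector `c(ambiguous=, length=)`; retrieve it with
#'   [drop_counts()].
#' @examples
#' s <- Biostrings::AAStringSet(c(a = strrep("M", 29), b = strrep("M", 30)))
#' drop_counts(filter_sequences(s))
#' @export
filter_sequences <- function(seqs, min_len = 30L, max_len = 1024L) {
  stopifnot(min_len >= 1L, max_len >= min_len)
  has_x <- Biostrings::vcountPattern("X", seqs) > 0L
  len <- Biostrings::width(seqs)
  bad_len <- !has_x & (len < min_len | len > max_len)
  keep <- !has_x & !bad_len
  out <- seqs[keep]
  attr(out, "drop_counts") <- c(ambiguous = sum(has_x), length = sum(bad_len))
  out
}

#' Per-reason drop counts of a filtered sequence set
#' @param seqs Result of [filter_sequences()].
#' @return Named integer vector `c(ambiguous=, length=)`.
#' @export
drop_counts <- function(seqs) {
  dc <- attr(seqs, "drop_counts")
  if (is.null(dc)) stop("no drop counts: was this produced by filter_sequences()?")
  dc
}

#' Draw a uniform random sample of sequences without replacement
#'
#' Deterministic for a fixed seed. With `complement = TRUE` both the sample
#' and its disjoint complement are returned, mirroring a train/embed split.
#' Both subsets preserve the input order.
#'
#' @param seqs An `AAStringSet`.
#' @param n Sample size, `0 <= n <= length(seqs)`.
#' @param seed Integer RNG seed.
#' @param complement If `TRUE`, return `list(sample=, complement=)`.
#' @return An `AAStringSet`, or a two-element list when `complement = TRUE`.
#' @export
random_sample <- function(seqs, n, seed, complement = FALSE) {
  n <- as.integer(n)
  if (n < 0L || n > length(seqs)) {
    stop("n must be between 0 and ", length(seqs), ", got ", n)
  }
  idx <- withr::with_seed(seed, sample.int(length(seqs), n))
  idx <- sort(idx)
  if (!complement) return(seqs[idx])
  list(sample = seqs[idx],
       complement = seqs[setdiff(seq_along(seqs), idx)])
}

#' Read a multi-level annotation table
#'
#' Expects a TSV with a header row; column 1 is the sequence id and the next
#' `n_levels` columns hold hierarchy labels ordered coarse to fine (for the
#' four SEED-style levels: superclass, class, subclass, subsystem). Rows
#' whose label cells are all empty are flagged unannotated.
#'
#' @param path Path to the TSV file.
#' @param n_levels Number of hierarchy levels (4 for SEED-style tables).
#' @return A data.frame with columns `sequence_id`, one column per level
#'   (named `superclass`, `class`, `subclass`, `subsystem` when
#'   `n_levels == 4`, else `level_1..n`), and logical `unannotated`.
#' @export
read_annotations <- function(path, n_levels = 4L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("annotation table has no header")
  want <- n_levels + 1L
  rows <- strsplit(lines, "\t", fixed = TRUE)
  # strsplit drops trailing empty fields, so count columns from the tabs
  ntabs <- nchar(lines) - nchar(gsub("\t", "", lines, fixed = TRUE))
  for (i in seq_along(rows)) {
    if (ntabs[i] + 1L != want) {
      stop("row ", i, ": expected ", want, " tab-separated columns, found ",
           ntabs[i] + 1L)
    }
    rows[[i]] <- c(rows[[i]], rep("", want - length(rows[[i]])))
  }
  body <- rows[-1L]
  level_names <- if (n_levels == 4L) {
    c("superclass", "class", "subclass", "subsystem")
  } else {
    paste0("level_", seq_len(n_levels))
  }
  mat <- do.call(rbind, body)
  df <- data.frame(sequence_id = mat[, 1L], stringsAsFactors = FALSE)
  for (j in seq_len(n_levels)) df[[level_names[j]]] <- mat[, j + 1L]
  df$unannotated <- apply(mat[, -1L, drop = FALSE], 1L,
                          function(r) all(!nzchar(r)))
  df
}

#' Write an annotation table as TSV
#' @param annotations Data frame as returned by [read_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  cols <- setdiff(names(annotations), "unannotated")
  utils::write.table(annotations[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flag annotation rows whose ids are absent from a sequence set
#' @param annotations Annotation data frame.
#' @param seqs An `AAStringSet`.
#' @return Logical vector, `TRUE` for orphan rows.
#' @export
orphan_annotations <- function(annotations, seqs) {
  !(annotations$sequence_id %in% names(seqs))
}
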