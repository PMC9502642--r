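#' @useDynLib protspace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# The 20 canonical residues, alphabetical. 'X' is tolerated at parse time
# only; everything downstream of filtering assumes it is gone.
AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Murphy et al. 10-class reduction. Classes: LVIM, C, A, G, ST, P, FYW,
# EDNQ, KR, H; each class written as its representative letter.
MURPHY10_MAP <- c(
  A = "A", C = "C", D = "E", E = "E", F = "F",
  G = "G", H = "H", I = "L", K = "K", L = "L",
  M = "L", N = "E", P = "P", Q = "E", R = "K",
  S = "S", T = "S", V = "L", W = "F", Y = "F"
)

#' Construct a reduced amino-acid alphabet scheme
#'
#' An alphabet scheme is a total mapping from the 20 canonical residues to a
#' smaller set of class-representative letters. The built-in `"murphy10"`
#' scheme collapses the alphabet to 10 physicochemical classes (aliphatic
#' LVIM, aromatic FYW, polar ST, charged/amide EDNQ, basic KR, and the
#' singletons A, C, G, H, P); the `"identity"` scheme maps every residue to
#' itself.
#'
#' @param name Scheme name: `"murphy10"` or `"identity"`, or any label when
#'   `mapping` is supplied.
#' @param mapping Optional named character vector giving the representative
#'   letter for each of the 20 canonical residues; overrides the built-ins.
#' @return An object of class `alphabet_scheme` with elements `name`,
#'   `mapping` (named character vector over the 20 residues) and `alphabet`
#'   (the sorted image letters).
#' @examples
#' sch <- alphabet_scheme("murphy10")
#' length(sch$alphabet)  # 10
#' @export
alphabet_scheme <- function(name = "murphy10", mapping = NULL) {
  if (is.null(mapping)) {
    mapping <- switch(name,
      murphy10 = MURPHY10_MAP,
      identity = stats::setNames(AA_CANONICAL, AA_CANONICAL),
      stop("unknown alphabet scheme: ", name)
    )
  }
  mapping <- mapping[order(names(mapping))]
  if (!setequal(names(mapping), AA_CANONICAL)) {
    missing <- setdiff(AA_CANONICAL, names(mapping))
    stop("alphabet mapping must cover all 20 canonical residues; missing: ",
         paste(missing, collapse = ", "))
  }
  structure(
    list(name = name,
         mapping = mapping,
         alphabet = sort(unique(unname(mapping)))),
    class = "alphabet_scheme"
  )
}

#' Read an alphabet scheme from a two-column TSV
#'
#' Expects a header line and rows `residue<TAB>representative`.
#'
#' @param path Path to the TSV file.
#' @param name Label to attach to the scheme.
#' @return An `alphabet_scheme`.
#' @export
read_alphabet_scheme <- function(path, name = basename(path)) {
  tab <- utils::read.delim(path, colClasses = "character")
  if (ncol(tab) < 2L) stop("alphabet TSV needs two columns (residue, class)")
  alphabet_scheme(name, mapping = stats::setNames(tab[[2L]], tab[[1L]]))
}

#' @export
print.alphabet_scheme <- function(x, ...) {
  cat("Alphabet scheme '", x$name, "': 20 residues -> ",
      length(x$alphabet), " classes {",
      paste(x$alphabet, collapse = ""), "}\n", sep = "")
  invisible(x)
}

#' Map sequences into a reduced amino-acid alphabet
#'
#' Each residue is replaced by its class-representative letter; sequence
#' length is preserved. Sequences must be free of 'X' and other characters
#' outside the 20-letter alphabet (filter upstream with
#' [filter_sequences()]).
#'
#' @param seqs An [Biostrings::AAStringSet] (or character vector) of
#'   sequences.
#' @param scheme An [alphabet_scheme()].
#' @return An `AAStringSet` of reduced sequences, same names and lengths.
#' @examples
#' reduce_alphabet(Biostrings::AAStringSet(c(s = "LVIM")))  # "LLLL"
#' @export
reduce_alphabet <- function(seqs, scheme = alphabet_scheme("murphy10")) {
  stopifnot(inherits(scheme, "alphabet_scheme"))
  chars <- as.character(seqs)
  nm <- names(chars)
  red <- vapply(chars, function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1L]]
    out <- scheme$mapping[v]
    if (anyNA(out)) {
      pos <- which(is.na(out))[1L]
      stop("residue '", v[pos], "' at position ", pos,
           " is outside the scheme's domain")
    }
    paste(out, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
  Biostrings::AAStringSet(stats::setNames(red, nm))
}

#' Enumerate all k-mers over an alphabet
#'
#' Lexicographically ordered; this fixed order labels the coordinates of the
#' k-mer frequency embedding (the rows of the identity matrix of size
#' `|alphabet|^k`).
#'
#' @param alphabet Character vector of single letters.
#' @param k Word length.
#' @return Character vector of `length(alphabet)^k` k-mers, sorted.
#' @export
all_kmers <- function(alphabet, k = 3L) {
  grids <- rep(list(sort(alphabet)), k)
  g <- do.call(expand.grid, c(rev(grids), stringsAsFactors = FALSE))
  sort(do.call(paste0, rev(g)))
}
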