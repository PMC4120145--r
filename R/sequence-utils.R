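#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the strict \{A,C,G,T\} alphabet.
#' Both strands of the assembly graph are represented through this
#' involution: node \code{-id} spells the reverse complement of node
#' \code{id}.
#'
#' @param x character vector of DNA strings (uppercase A/C/G/T only).
#' @return character vector of the same length with each element
#'   reverse-complemented.
#' @examples
#' reverse_complement(c("AAAC", "ACGT"))
#' @export
reverse_complement <- function(x) {
  if (!is.character(x)) stop("sequences must be a character vector")
  if (length(x) == 0L) return(character(0))
  if (any(grepl("[^ACGT]", x))) {
    stop("reverse_complement: sequence contains a character outside {A,C,G,T}")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical form of k-mers
#'
#' The canonical representative of a k-mer is the lexicographically
#' smaller of the k-mer and its reverse complement.  Each k-mer of the
#' double-stranded graph is stored once under its canonical form; the
#' two orientations are exposed as signed node ids.
#'
#' @param x character vector of k-mers.
#' @return character vector of canonical k-mers.
#' @keywords internal
canonical_kmer <- function(x) {
  if (length(x) == 0L) return(character(0))
  r <- reverse_complement(x)
  ifelse(x <= r, x, r)
}

#' Split sequences into A/C/G/T fragments
#'
#' Uppercases the input and splits each sequence at every run of
#' non-ACGT characters (N, IUPAC ambiguity codes, ...).  No k-mer is
#' ever fabricated across an ambiguous base.
#'
#' @param x character vector of sequences.
#' @return character vector of pure-ACGT fragments (empty fragments
#'   dropped).
#' @keywords internal
sanitize_reads <- function(x) {
  x <- toupper(x)
  frags <- unlist(strsplit(x, "[^ACGT]+"), use.names = FALSE)
  frags[nzchar(frags)]
}

#' Enumerate the k-mers of a set of sequences
#'
#' @param x character vector of ACGT sequences.
#' @param k k-mer length.
#' @return character vector of all k-mer instances (with multiplicity),
#'   in input order; sequences shorter than k contribute nothing.
#' @keywords internal
enumerate_kmers <- function(x, k) {
  n <- nchar(x)
  x <- x[n >= k]
  n <- n[n >= k]
  if (length(x) == 0L) return(character(0))
  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    starts <- seq_len(n[i] - k + 1L)
    out[[i]] <- substring(x[i], starts, starts + k - 1L)
  }
  unlist(out, use.names = FALSE)
}

# longest common suffix of a set of strings ("" when any disagreement at
# the last character or any empty string)
common_suffix <- function(x) {
  if (length(x) == 0L) return("")
  maxlen <- min(nchar(x))
  if (maxlen == 0L) return("")
  rev_chars <- lapply(strsplit(x, ""), rev)
  len <- 0L
  for (j in seq_len(maxlen)) {
    cj <- vapply(rev_chars, `[[`, character(1), j)
    if (length(unique(cj)) > 1L) break
    len <- j
  }
  if (len == 0L) return("")
  substr(x[[1]], nchar(x[[1]]) - len + 1L, nchar(x[[1]]))
}

# hamming distance between two equal-length strings
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming: unequal lengths")
  sum(utf8ToInt(a) != utf8ToInt(b))
}
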