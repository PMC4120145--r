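#' Assembly parameters
#'
#' Bundles the tunable parameters of graph construction and cleaning:
#' the k-mer length `k`, the mean k-mer coverage cutoff `c`, and the
#' maximum spelled length of a dead-end branch clipped as a tip.
#'
#' @param k k-mer length in bases; must be odd and >= 3 so that no
#'   k-mer equals its own reverse complement.
#' @param c non-negative mean k-mer coverage cutoff; nodes with mean
#'   coverage below `c` are removed during cleaning.
#' @param tip_len maximum spelled length (bases) of a dead-end node that
#'   may be clipped as a tip; defaults to `2 * k - 1`, the conventional
#'   "twice k" tip length of de Bruijn assemblers.
#' @return an object of class `sg_params`.
#' @examples
#' sg_params(k = 25, c = 3)
#' @export
sg_params <- function(k, c = 0, tip_len = 2L * k - 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 3L) stop("k must be an integer >= 3")
  if (k %% 2L == 0L) stop("k must be odd (a palindromic k-mer would be its own twin)")
  if (!is.numeric(c) || is.na(c) || c < 0) stop("c must be a non-negative number")
  tip_len <- as.integer(tip_len)
  if (is.na(tip_len) || tip_len < 0L) stop("tip_len must be a non-negative integer")
  structure(list(k = k, c = c, tip_len = tip_len), class = "sg_params")
}

#' Construct a de Bruijn graph object
#'
#' Low-level constructor for the double-stranded de Bruijn graph.  The
#' graph stores one record per node pair: node `id` (positive) spells
#' `seq`, node `-id` spells its reverse complement.  Directed edges use
#' signed ids and are kept twin-closed: edge `(u, v)` is always
#' accompanied by `(-v, -u)`.
#'
#' @param k k-mer length used to build the graph; adjacent nodes'
#'   spelled sequences overlap by exactly `k - 1` bases.
#' @param seqs character vector of forward node sequences; node ids are
#'   assigned 1..length(seqs).
#' @param kmer_count numeric vector, total k-mer instances observed per
#'   node (both strands counted once per read occurrence).
#' @param edges two-column integer matrix or data.frame of signed node
#'   ids `(from, to)`, optionally a third `weight` column.
#' @return an object of class `dbg`.
#' @export
dbg <- function(k, seqs = character(), kmer_count = numeric(), edges = NULL) {
  k <- as.integer(k)
  n <- length(seqs)
  if (length(kmer_count) == 0L && n > 0L) kmer_count <- rep(1, n)
  nodes <- data.frame(
    id = seq_len(n),
    seq = as.character(seqs),
    kmer_count = as.numeric(kmer_count),
    length_k = nchar(seqs) - k + 1L,
    stringsAsFactors = FALSE
  )
  if (is.null(edges)) {
    edges <- data.frame(from = integer(), to = integer(), weight = numeric())
  } else {
    edges <- as.data.frame(edges)
    if (ncol(edges) == 2L) edges$weight <- 1
    names(edges) <- c("from", "to", "weight")
    edges$from <- as.integer(edges$from)
    edges$to <- as.integer(edges$to)
  }
  g <- structure(list(k = k, nodes = nodes, edges = edges), class = "dbg")
  close_twin_edges(g)
}

# re-establish twin closure and drop duplicate edges; deterministic order
close_twin_edges <- function(g) {
  e <- g$edges
  if (nrow(e) > 0L) {
    e2 <- data.frame(from = -e$to, to = -e$from, weight = e$weight)
    e <- rbind(e, e2)
    key <- paste(e$from, e$to)
    e <- e[!duplicated(key), , drop = FALSE]
    e <- e[order(e$from, e$to), , drop = FALSE]
    rownames(e) <- NULL
  }
  g$edges <- e
  g
}

#' @export
print.dbg <- function(x, ...) {
  cat(sprintf(
    "de Bruijn graph (k = %d): %d node pairs, %d directed edges\n",
    x$k, nrow(x$nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' Number of node pairs in a graph
#' @param g a `dbg` object.
#' @return integer count of stored (forward) nodes.
#' @export
n_nodes <- function(g) nrow(g$nodes)

#' Oriented node sequences
#'
#' @param g a `dbg` object.
#' @param ids signed node ids.
#' @return character vector of spelled sequences; negative ids give the
#'   reverse complement of the stored forward sequence.
#' @export
node_seq <- function(g, ids) {
  i <- match(abs(ids), g$nodes$id)
  if (anyNA(i)) stop("node_seq: unknown node id(s): ",
                     paste(ids[is.na(i)], collapse = ", "))
  s <- g$nodes$seq[i]
  neg <- ids < 0L
  if (any(neg)) s[neg] <- reverse_complement(s[neg])
  s
}

#' Mean k-mer coverage per node
#' @param g a `dbg` object.
#' @return named numeric vector, `kmer_count / length_k` per forward node id.
#' @export
mean_coverage <- function(g) {
  stats::setNames(g$nodes$kmer_count / g$nodes$length_k, g$nodes$id)
}

# out-neighbours of one oriented node
successors <- function(g, id) g$edges$to[g$edges$from == id]
predecessors <- function(g, id) g$edges$from[g$edges$to == id]

# degree tables over all oriented nodes: returns list(out, in.) of named
# vectors indexed by signed id as character
oriented_degrees <- function(g) {
  ids <- g$nodes$id
  ov <- c(ids, -ids)
  outd <- stats::setNames(integer(length(ov)), ov)
  ind <- outd
  if (nrow(g$edges) > 0L) {
    tf <- table(factor(as.character(g$edges$from), levels = as.character(ov)))
    tt <- table(factor(as.character(g$edges$to), levels = as.character(ov)))
    outd[] <- as.integer(tf)
    ind[] <- as.integer(tt)
  }
  list(out = outd, in. = ind)
}

# drop a set of node pairs (given by positive ids) plus incident edges
drop_nodes <- function(g, ids) {
  if (is.null(ids) || length(ids) == 0L) return(g)
  ids <- unique(abs(ids))
  keep <- !(g$nodes$id %in% ids)
  g$nodes <- g$nodes[keep, , drop = FALSE]
  e <- g$edges
  g$edges <- e[!(abs(e$from) %in% ids) & !(abs(e$to) %in% ids), , drop = FALSE]
  rownames(g$nodes) <- NULL
  rownames(g$edges) <- NULL
  g
}

# renumber node ids to 1..n preserving order and edge orientation
renumber_nodes <- function(g) {
  old <- g$nodes$id
  map <- stats::setNames(seq_along(old), old)
  g$nodes$id <- seq_along(old)
  if (nrow(g$edges) > 0L) {
    g$edges$from <- as.integer(sign(g$edges$from) * map[as.character(abs(g$edges$from))])
    g$edges$to <- as.integer(sign(g$edges$to) * map[as.character(abs(g$edges$to))])
  }
  g
}

#' Validate structural invariants of a de Bruijn graph
#'
#' Checks twin closure of the edge set, that all edge endpoints exist,
#' and (optionally) that adjacent spelled sequences overlap by exactly
#' `k - 1` bases.
#'
#' @param g a `dbg` object.
#' @param check_overlap also verify the `k - 1` sequence overlap along
#'   every edge (skipped by default for large graphs).
#' @return `TRUE` invisibly; stops with an informative error otherwise.
#' @export
validate_dbg <- function(g, check_overlap = FALSE) {
  e <- g$edges
  ids <- g$nodes$id
  if (any(ids <= 0L)) stop("node ids must be positive")
  if (anyDuplicated(ids)) stop("duplicate node ids")
  if (nrow(e) > 0L) {
    if (!all(abs(e$from) %in% ids) || !all(abs(e$to) %in% ids)) {
      stop("edge endpoint references a missing node")
    }
    key <- paste(e$from, e$to)
    twin <- paste(-e$to, -e$from)
    if (!all(twin %in% key)) stop("twin symmetry violated")
    if (check_overlap) {
      sf <- node_seq(g, e$from)
      st <- node_seq(g, e$to)
      ok <- substr(sf, nchar(sf) - g$k + 2L, nchar(sf)) ==
        substr(st, 1L, g$k - 1L)
      if (!all(ok)) stop("k-1 overlap violated on ", sum(!ok), " edge(s)")
    }
  }
  if (any(nchar(g$nodes$seq) < g$k)) stop("node sequence shorter than k")
  invisible(TRUE)
}
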