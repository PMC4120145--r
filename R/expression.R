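#' Index the k-mers of finalized splicing graphs
#'
#' Maps every canonical k-mer occurring in a node sequence to that
#' node; k-mers spanning an edge junction (built from the last k-1
#' bases of the upstream node and the first k-1 bases of the
#' downstream node) are attributed to the downstream node.  A k-mer
#' occurring in several nodes maps to all of them.
#'
#' @param graphs list of finalized `splicing_graph` objects.
#' @param k k-mer length.
#' @return object of class `node_kmer_index`: a list with `keys`
#'   (canonical k-mers), `map` (list of integer vectors of node-table
#'   rows per key) and `nodes` (data.frame graph_id, node_id, length).
#' @export
index_node_kmers <- function(graphs, k) {
  nodes <- do.call(rbind, lapply(graphs, function(sg) {
    if (length(sg$seqs) == 0L) return(NULL)
    data.frame(graph_id = sg$graph_id, node_id = seq_along(sg$seqs),
               length = nchar(sg$seqs))
  }))
  if (is.null(nodes)) nodes <- data.frame(graph_id = integer(),
                                          node_id = integer(),
                                          length = integer())
  kms <- list()
  rows <- list()
  row0 <- 0L
  for (sg in graphs) {
    m <- length(sg$seqs)
    if (m == 0L) next
    for (v in seq_len(m)) {
      km <- enumerate_kmers(sg$seqs[v], k)
      if (length(km) > 0L) {
        kms[[length(kms) + 1L]] <- km
        rows[[length(rows) + 1L]] <- rep.int(row0 + v, length(km))
      }
    }
    if (nrow(sg$edges) > 0L) {
      for (i in seq_len(nrow(sg$edges))) {
        u <- sg$edges$from[i]
        v <- sg$edges$to[i]
        su <- sg$seqs[u]
        win <- paste0(
          substr(su, max(1L, nchar(su) - k + 2L), nchar(su)),
          substr(sg$seqs[v], 1L, k - 1L)
        )
        km <- enumerate_kmers(win, k)
        if (length(km) > 0L) {
          kms[[length(kms) + 1L]] <- km
          rows[[length(rows) + 1L]] <- rep.int(row0 + v, length(km))
        }
      }
    }
    row0 <- row0 + m
  }
  km_all <- canonical_kmer(unlist(kms, use.names = FALSE))
  row_all <- unlist(rows, use.names = FALSE)
  if (is.null(km_all)) km_all <- character(0)
  if (is.null(row_all)) row_all <- integer(0)
  pair <- !duplicated(paste(km_all, row_all))
  km_all <- km_all[pair]
  row_all <- row_all[pair]
  keys <- sort(unique(km_all))
  map <- unname(split(row_all, factor(km_all, levels = keys)))
  structure(list(keys = keys, map = map, nodes = nodes, k = k),
            class = "node_kmer_index")
}

#' Count reads per node and library
#'
#' A read contributes one count to every node with which it shares at
#' least one canonical k-mer (at most once per node, however many
#' k-mers hit).  Reads sharing no k-mer with any node are excluded
#' from the library's assembled-read total.
#'
#' @param libraries list of [read_library()] objects (or plain
#'   character vectors, named by library).
#' @param index a `node_kmer_index` from [index_node_kmers()].
#' @return object of class `node_expression`: data.frame with columns
#'   graph_id, node_id, node_length and `<lib>_count` per library, plus
#'   attribute `assembled_reads` (named vector) and `total_reads`.
#' @export
count_reads <- function(libraries, index) {
  libraries <- as_read_libraries(libraries)
  k <- index$k
  nn <- nrow(index$nodes)
  tab <- index$nodes
  names(tab)[names(tab) == "length"] <- "node_length"
  assembled <- integer(length(libraries))
  total <- integer(length(libraries))
  names(assembled) <- names(total) <- vapply(libraries, `[[`, "", "name")
  for (li in seq_along(libraries)) {
    lib <- libraries[[li]]
    total[li] <- lib$total_reads
    counts <- integer(nn)
    frags <- sanitize_reads(lib$reads)
    km <- enumerate_kmers_by_read(frags, k)
    if (length(km$kmers) > 0L) {
      canon <- canonical_kmer(km$kmers)
      ki <- match(canon, index$keys)
      ok <- !is.na(ki)
      if (any(ok)) {
        hit_nodes <- index$map[ki[ok]]
        hit_reads <- rep.int(km$read[ok], lengths(hit_nodes))
        pair <- paste(hit_reads, unlist(hit_nodes, use.names = FALSE))
        keep <- !duplicated(pair)
        nodes_hit <- unlist(hit_nodes, use.names = FALSE)[keep]
        reads_hit <- hit_reads[keep]
        counts <- tabulate(nodes_hit, nn)
        assembled[li] <- length(unique(reads_hit))
      }
    }
    tab[[paste0(lib$name, "_count")]] <- counts
  }
  structure(tab, class = c("node_expression", "data.frame"),
            assembled_reads = assembled, total_reads = total)
}

#' Compute per-node per-library RPKM
#'
#' RPKM (reads per kilobase of node per million assembled reads) is
#' `count / ((node_length / 1000) * (assembled / 1e6))` with
#' `assembled` the number of reads of the library that appear in the
#' assembly (share a k-mer with some retained node); reads appearing
#' in the assembly stand in for mapped reads, since no reference is
#' available.  A library with zero assembled reads yields RPKM 0.
#'
#' @param table a `node_expression` table from [count_reads()].
#' @param denominator `"assembled"` (default) or `"total"` reads.
#' @return the table with an additional `<lib>_rpkm` column per library.
#' @export
compute_rpkm <- function(table, denominator = c("assembled", "total")) {
  denominator <- match.arg(denominator)
  assembled <- attr(table, "assembled_reads")
  total <- attr(table, "total_reads")
  stopifnot(all(table$node_length > 0L))
  for (lib in names(assembled)) {
    den <- if (denominator == "assembled") assembled[[lib]] else total[[lib]]
    cnt <- table[[paste0(lib, "_count")]]
    rpkm <- if (den == 0) rep(0, nrow(table)) else {
      cnt / ((table$node_length / 1000) * (den / 1e6))
    }
    table[[paste0(lib, "_rpkm")]] <- rpkm
  }
  table
}

#' Full expression quantification
#'
#' Convenience wrapper: index node k-mers, count reads per library and
#' compute RPKM values.
#'
#' @param graphs list of finalized `splicing_graph` objects.
#' @param libraries list of read libraries (see [count_reads()]).
#' @param k k-mer length.
#' @inheritParams compute_rpkm
#' @return a `node_expression` table with count and rpkm columns.
#' @export
quantify_expression <- function(graphs, libraries, k,
                                denominator = c("assembled", "total")) {
  idx <- index_node_kmers(graphs, k)
  tab <- count_reads(libraries, idx)
  compute_rpkm(tab, denominator)
}
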