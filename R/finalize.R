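#' Splicing graph constructor
#'
#' A splicing graph is one acyclic component of the decomposed de
#' Bruijn graph, renumbered 1..m in topological order, carrying both
#' the raw (k-1 overlapping) and the final non-overlapping node
#' sequences.  Source-to-sink paths spell the candidate transcripts of
#' one gene.
#'
#' @param graph_id integer identifier.
#' @param k k-mer length.
#' @param seqs character vector of node sequences (named by node id
#'   1..m implicitly).
#' @param edges data.frame with integer columns `from`, `to` (node
#'   indices within this graph).
#' @param raw raw overlapping sequences (same order as `seqs`).
#' @param singleton logical: a single-node assembly extracted from a
#'   cyclic region or tangle (bypasses junction adjustment).
#' @return an object of class `splicing_graph`.
#' @export
splicing_graph <- function(graph_id, k, seqs, edges = NULL, raw = seqs,
                           singleton = FALSE) {
  if (is.null(edges)) edges <- data.frame(from = integer(), to = integer())
  structure(
    list(graph_id = as.integer(graph_id), k = as.integer(k),
         seqs = as.character(seqs), raw = as.character(raw),
         edges = data.frame(from = as.integer(edges$from),
                            to = as.integer(edges$to)),
         singleton = isTRUE(singleton)),
    class = "splicing_graph"
  )
}

#' @export
print.splicing_graph <- function(x, ...) {
  cat(sprintf("splicing graph %d: %d nodes, %d edges%s\n",
              x$graph_id, length(x$seqs), nrow(x$edges),
              if (x$singleton) " (singleton assembly)" else ""))
  invisible(x)
}

# Kahn topological order with smallest-index tie-break; NULL on cycle
topo_order <- function(n, edges) {
  indeg <- tabulate(edges$to, n)
  avail <- sort(which(indeg == 0L))
  ord <- integer(0)
  while (length(avail) > 0L) {
    v <- avail[1L]
    avail <- avail[-1L]
    ord <- c(ord, v)
    for (w in edges$to[edges$from == v]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- sort(c(avail, w))
    }
  }
  if (length(ord) < n) NULL else ord
}

#' Build a raw splicing graph from one acyclic component
#'
#' Extracts the induced subgraph over one retained component, renumbers
#' nodes topologically, and removes the first `k - 1` letters of every
#' node sequence so that adjacent node sequences no longer overlap
#' (path spellings lose only their global `k - 1` prefix, recovered by
#' [restore_source_prefixes()]).
#'
#' @param g the [dbg] graph the component was extracted from.
#' @param component integer vector of signed node ids.
#' @param graph_id identifier for the new graph.
#' @return a raw (de-overlapped, unadjusted) `splicing_graph`.
#' @export
deoverlap <- function(g, component, graph_id = 1L) {
  if (length(component) == 0L) {
    return(splicing_graph(graph_id, g$k, character(0)))
  }
  comp <- sort(component)
  raw <- node_seq(g, comp)
  e <- g$edges[g$edges$from %in% comp & g$edges$to %in% comp, , drop = FALSE]
  edges <- data.frame(from = match(e$from, comp), to = match(e$to, comp))
  ord <- topo_order(length(comp), edges)
  if (is.null(ord)) stop("deoverlap: component contains a cycle")
  rank <- match(seq_along(comp), ord)
  perm <- order(rank)
  raw <- raw[perm]
  edges$from <- match(edges$from, perm)
  edges$to <- match(edges$to, perm)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  stopifnot(all(nchar(raw) >= g$k))
  seqs <- substring(raw, g$k)
  splicing_graph(graph_id, g$k, seqs, edges, raw = raw)
}

#' Make merge junctions base-precise
#'
#' For each node at which two or more paths meet and none of the
#' predecessors itself splits (when a split and a merge sit at the two
#' ends of one edge the case is ambiguous and left untouched), the
#' longest common suffix of all predecessor sequences is moved onto the
#' meeting node.  Predecessors emptied by the move are contracted:
#' their incoming edges are rerouted to the meeting node.  A source
#' predecessor is never emptied completely (its sequence carries the
#' restorable k-1 prefix), so at least one letter is kept there.  All
#' path spellings are preserved.  The operation is idempotent.
#'
#' @param sg a de-overlapped `splicing_graph`.
#' @return the adjusted `splicing_graph`.
#' @export
adjust_merge_junctions <- function(sg) {
  n <- length(sg$seqs)
  if (n == 0L || nrow(sg$edges) == 0L) return(sg)
  seqs <- sg$seqs
  edges <- sg$edges
  alive <- rep(TRUE, n)
  ord <- topo_order(n, edges)
  if (is.null(ord)) stop("adjust_merge_junctions: graph contains a cycle")
  for (m in ord) {
    repeat {
      if (!alive[m]) break
      preds <- unique(edges$from[edges$to == m])
      if (length(preds) < 2L) break
      outdeg <- vapply(preds, function(p) length(unique(edges$to[edges$from == p])),
                       integer(1))
      if (any(outdeg > 1L)) break # simultaneous split and merge: skip
      s <- common_suffix(seqs[preds])
      if (!nzchar(s)) break
      len <- nchar(s)
      # never empty a source predecessor: it owns the restorable prefix
      indeg_p <- vapply(preds, function(p) sum(edges$to == p), integer(1))
      src_full <- preds[indeg_p == 0L & nchar(seqs[preds]) == len]
      if (length(src_full) > 0L) {
        len <- min(len, min(nchar(seqs[src_full])) - 1L)
        if (len <= 0L) break
        s <- substring(s, nchar(s) - len + 1L)
      }
      seqs[preds] <- substr(seqs[preds], 1L, nchar(seqs[preds]) - len)
      seqs[m] <- paste0(s, seqs[m])
      emptied <- preds[!nzchar(seqs[preds])]
      for (p in emptied) {
        edges$to[edges$to == p] <- m # reroute grandparents to m
        edges <- unique(edges[edges$from != p, , drop = FALSE])
        alive[p] <- FALSE
      }
      if (length(emptied) == 0L) break
    }
  }
  keep <- which(alive)
  remap <- match(seq_len(n), keep)
  edges$from <- remap[edges$from]
  edges$to <- remap[edges$to]
  edges <- unique(edges[stats::complete.cases(edges), , drop = FALSE])
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  splicing_graph(sg$graph_id, sg$k, seqs[keep], edges, raw = sg$raw[keep],
                 singleton = sg$singleton)
}

#' Restore the k-1 prefix of source nodes
#'
#' Every node with no incoming edges regains the `k - 1` letters that
#' [deoverlap()] removed, taken from its stored raw sequence, so that
#' full source-to-sink path spellings equal the original spelled paths.
#'
#' @param sg an adjusted `splicing_graph`.
#' @return the `splicing_graph` with restored source prefixes.
#' @export
restore_source_prefixes <- function(sg) {
  n <- length(sg$seqs)
  if (n == 0L) return(sg)
  indeg <- tabulate(sg$edges$to, n)
  src <- which(indeg == 0L)
  sg$seqs[src] <- paste0(substr(sg$raw[src], 1L, sg$k - 1L), sg$seqs[src])
  sg
}

#' Minimum and maximum source-to-sink spelled path lengths
#'
#' Dynamic program over the DAG summing node sequence lengths.
#'
#' @param sg a `splicing_graph`.
#' @return `list(min = , max = )` spelled lengths in bases.
#' @export
path_length_range <- function(sg) {
  n <- length(sg$seqs)
  if (n == 0L) return(list(min = 0L, max = 0L))
  len <- nchar(sg$seqs)
  ord <- topo_order(n, sg$edges)
  lo <- rep(NA_real_, n)
  hi <- rep(NA_real_, n)
  indeg <- tabulate(sg$edges$to, n)
  for (v in ord) {
    if (indeg[v] == 0L) {
      lo[v] <- hi[v] <- len[v]
    } else {
      preds <- sg$edges$from[sg$edges$to == v]
      lo[v] <- min(lo[preds]) + len[v]
      hi[v] <- max(hi[preds]) + len[v]
    }
  }
  outdeg <- tabulate(sg$edges$from, n)
  sinks <- which(outdeg == 0L)
  list(min = min(lo[sinks]), max = max(hi[sinks]))
}

#' Filter out short splicing graphs
#'
#' Retains only the graphs in which every source-to-sink path spells
#' strictly more than `2k - 1` bases (single-node assemblies are held
#' to the same floor on their sequence length).
#'
#' @param graphs list of finalized `splicing_graph` objects.
#' @param k k-mer length.
#' @return the retained subset of `graphs`.
#' @export
length_filter <- function(graphs, k) {
  keep <- vapply(graphs, function(sg) {
    path_length_range(sg)$min > 2L * k - 1L
  }, logical(1))
  graphs[keep]
}

#' Enumerate source-to-sink path spellings
#'
#' @param sg a finalized `splicing_graph`.
#' @param max_paths cap on the number of paths returned.
#' @return character vector of spelled paths (concatenated final node
#'   sequences along each source-to-sink path).
#' @export
spell_paths <- function(sg, max_paths = 100L) {
  n <- length(sg$seqs)
  if (n == 0L) return(character(0))
  indeg <- tabulate(sg$edges$to, n)
  outdeg <- tabulate(sg$edges$from, n)
  paths <- list()
  walk <- function(v, acc) {
    if (length(paths) >= max_paths) return()
    acc <- c(acc, v)
    succ <- sort(sg$edges$to[sg$edges$from == v])
    if (length(succ) == 0L) {
      paths[[length(paths) + 1L]] <<- acc
      return()
    }
    for (w in succ) walk(w, acc)
  }
  for (s in sort(which(indeg == 0L))) walk(s, integer(0))
  vapply(paths, function(p) paste(sg$seqs[p], collapse = ""), character(1))
}

#' Spell the raw overlapping paths of an unadjusted component
#'
#' Enumerates source-to-sink paths of a freshly de-overlapped graph and
#' spells them from the raw (k-1 overlapping) node sequences.  Used to
#' verify that junction adjustment conserves path spellings.
#'
#' @param sg a `splicing_graph` straight out of [deoverlap()].
#' @param max_paths cap on the number of paths returned.
#' @return character vector of raw spelled paths.
#' @export
spell_raw_paths <- function(sg, max_paths = 100L) {
  n <- length(sg$raw)
  if (n == 0L) return(character(0))
  indeg <- tabulate(sg$edges$to, n)
  paths <- list()
  walk <- function(v, acc) {
    if (length(paths) >= max_paths) return()
    acc <- c(acc, v)
    succ <- sort(sg$edges$to[sg$edges$from == v])
    if (length(succ) == 0L) {
      paths[[length(paths) + 1L]] <<- acc
      return()
    }
    for (w in succ) walk(w, acc)
  }
  for (s in sort(which(indeg == 0L))) walk(s, integer(0))
  vapply(paths, function(p) {
    paste0(sg$raw[p[1L]],
           paste(substring(sg$raw[p[-1L]], sg$k), collapse = ""))
  }, character(1))
}

#' Finalize the acyclic components of a decomposition
#'
#' Converts every retained acyclic component into a base-precise
#' splicing graph (de-overlap, merge-junction adjustment, source-prefix
#' restoration), wraps every singleton assembly as a single-node graph,
#' and applies the `2k - 1` minimum path length filter.  Graph ids are
#' assigned deterministically (components first, ordered by their
#' smallest node sequence, then singletons ordered by sequence).
#'
#' @param g the cleaned [dbg] graph.
#' @param decomp a `decomposition` from [decompose_graph()].
#' @return list of retained `splicing_graph` objects.
#' @export
build_splicing_graphs <- function(g, decomp) {
  comps <- decomp$acyclic_components
  keyc <- vapply(comps, function(comp) min(node_seq(g, comp)), character(1))
  comps <- comps[order(keyc)]
  graphs <- vector("list", length(comps))
  for (i in seq_along(comps)) {
    sg <- deoverlap(g, comps[[i]], graph_id = i)
    sg <- adjust_merge_junctions(sg)
    sg <- restore_source_prefixes(sg)
    graphs[[i]] <- sg
  }
  singles <- decomp$singleton_assemblies
  if (length(singles) > 0L) {
    sseq <- sort(node_seq(g, singles))
    for (j in seq_along(sseq)) {
      graphs[[length(graphs) + 1L]] <- splicing_graph(
        length(comps) + j, g$k, sseq[j], singleton = TRUE
      )
    }
  }
  graphs <- length_filter(graphs, g$k)
  for (i in seq_along(graphs)) graphs[[i]]$graph_id <- i
  graphs
}
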