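#' Strongly connected components of the oriented graph
#'
#' Computes the maximal strongly connected components of the directed
#' graph over all oriented nodes (forward and twin).  Every edge
#' between two components is itself a trivial "single edge" component;
#' only components of two or more nodes (or a node carrying a
#' self-loop) mark complicated cyclic regions.
#'
#' @param g a [dbg] graph.
#' @return list of integer vectors of signed node ids, one per SCC
#'   (including singleton SCCs), in deterministic order.
#' @export
strongly_connected_components <- function(g) {
  ids <- g$nodes$id
  if (length(ids) == 0L) return(list())
  ov <- c(ids, -ids)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(g$edges$from),
               to = as.character(g$edges$to)),
    directed = TRUE,
    vertices = data.frame(name = as.character(ov))
  )
  memb <- igraph::components(ig, mode = "strong")$membership
  vids <- as.integer(names(memb))
  comps <- split(vids, memb)
  comps <- lapply(unname(comps), sort)
  # deterministic order by smallest member id
  comps[order(vapply(comps, min, integer(1)))]
}

#' Remove cyclic regions from the graph
#'
#' Extracts every node belonging to a strongly connected component of
#' two or more nodes, or carrying a self-loop, together with its
#' incident edges.  The remaining graph contains no directed cycles.
#' Extracted nodes are reported in one orientation only (positive id)
#' and are later emitted as single-node assemblies, discarding the
#' junction information inside these complicated regions.
#'
#' @param g a [dbg] graph.
#' @return `list(graph = <acyclic dbg>, extracted = <positive ids>,
#'   scc_sizes = <node counts of non-trivial SCCs>)`.
#' @export
remove_cyclic_regions <- function(g) {
  if (nrow(g$nodes) == 0L) {
    return(list(graph = g, extracted = integer(0), scc_sizes = integer(0)))
  }
  sccs <- strongly_connected_components(g)
  big <- sccs[vapply(sccs, length, integer(1)) >= 2L]
  selfloop <- unique(abs(g$edges$from[g$edges$from == g$edges$to]))
  cyc <- unique(c(unlist(lapply(big, abs)), selfloop))
  # an SCC and its strand mirror describe the same physical region
  key <- vapply(big, function(x) paste(sort(abs(x)), collapse = ","),
                character(1))
  big <- big[!duplicated(key)]
  scc_sizes <- sort(vapply(big, function(x) length(unique(abs(x))), integer(1)),
                    decreasing = TRUE)
  if (length(cyc) == 0L) {
    return(list(graph = g, extracted = integer(0), scc_sizes = scc_sizes))
  }
  list(graph = drop_nodes(g, cyc), extracted = sort(cyc),
       scc_sizes = scc_sizes)
}

# weakly connected components as list of signed-id vectors
weak_components <- function(g) {
  ids <- g$nodes$id
  if (length(ids) == 0L) return(list())
  ov <- c(ids, -ids)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(g$edges$from),
               to = as.character(g$edges$to)),
    directed = TRUE,
    vertices = data.frame(name = as.character(ov))
  )
  memb <- igraph::components(ig, mode = "weak")$membership
  vids <- as.integer(names(memb))
  comps <- lapply(unname(split(vids, memb)), sort)
  comps[order(vapply(comps, min, integer(1)))]
}

#' Find forward-backward tangles
#'
#' After cycle removal each gene should appear as two disjoint
#' components, one per strand.  A forward-backward tangle is a weakly
#' connected component that contains some node together with its own
#' twin, conflating the two strands.  For each such component the
#' culprit set -- every node whose twin lies in the same component --
#' is returned; removing it separates the strands.
#'
#' @param g an acyclic [dbg] graph (after [remove_cyclic_regions()]).
#' @return list of integer vectors of positive node ids, one per
#'   affected component.
#' @export
find_fb_tangles <- function(g) {
  comps <- weak_components(g)
  out <- list()
  for (comp in comps) {
    culprit <- unique(abs(comp[comp %in% -comp]))
    if (length(culprit) > 0L) out[[length(out) + 1L]] <- sort(culprit)
  }
  out
}

#' Extract acyclic single-orientation components
#'
#' Removes tangle nodes (emitted as single-node assemblies), then
#' extracts the weakly connected components of the remaining graph.
#' Each component now appears twice, once per strand, as two mirror
#' components; exactly one orientation of each pair is retained (the
#' one whose lexicographically smallest node sequence is smaller).
#'
#' @param g an acyclic [dbg] graph.
#' @param tangles culprit sets from [find_fb_tangles()].
#' @param extracted positive ids already extracted from cyclic regions
#'   (reported as singleton assemblies alongside tangle nodes).
#' @param scc_sizes non-trivial SCC sizes carried into the result.
#' @param largest_tangle node count of the largest weakly connected
#'   component of the graph before any extraction.
#' @return an object of class `decomposition` with fields
#'   `acyclic_components` (list of signed-id vectors),
#'   `singleton_assemblies` (positive ids), `scc_sizes`,
#'   `largest_tangle`.
#' @export
extract_components <- function(g, tangles, extracted = integer(0),
                               scc_sizes = integer(0),
                               largest_tangle = NA_integer_) {
  tangle_ids <- sort(unique(unlist(tangles)))
  g2 <- drop_nodes(g, tangle_ids)
  comps <- weak_components(g2)
  kept <- list()
  seen <- character(0)
  for (comp in comps) {
    stopifnot(!any(comp %in% -comp)) # mirror-free by construction
    key <- paste(sort(abs(comp)), collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    mirror <- sort(-comp)
    if (min(node_seq(g2, comp)) <= min(node_seq(g2, mirror))) {
      kept[[length(kept) + 1L]] <- comp
    } else {
      kept[[length(kept) + 1L]] <- mirror
    }
  }
  structure(
    list(
      acyclic_components = kept,
      singleton_assemblies = sort(unique(c(extracted, tangle_ids))),
      scc_sizes = scc_sizes,
      largest_tangle = largest_tangle
    ),
    class = "decomposition"
  )
}

#' Full decomposition of a cleaned graph
#'
#' Runs SCC extraction, forward-backward tangle detection and
#' component extraction in sequence.
#'
#' @param g a cleaned, compacted [dbg] graph.
#' @return a `decomposition` object (see [extract_components()]).
#' @export
decompose_graph <- function(g) {
  pre <- weak_components(g)
  largest_tangle <- if (length(pre) == 0L) 0L else {
    max(vapply(pre, function(x) length(unique(abs(x))), integer(1)))
  }
  cyc <- remove_cyclic_regions(g)
  tangles <- find_fb_tangles(cyc$graph)
  extract_components(cyc$graph, tangles, extracted = cyc$extracted,
                     scc_sizes = cyc$scc_sizes,
                     largest_tangle = largest_tangle)
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf(
    "decomposition: %d acyclic components, %d singleton assemblies, largest SCC %s, largest tangle %s\n",
    length(x$acyclic_components), length(x$singleton_assemblies),
    if (length(x$scc_sizes)) max(x$scc_sizes) else 0L,
    x$largest_tangle
  ))
  invisible(x)
}
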