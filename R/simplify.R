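#' Remove low-coverage nodes
#'
#' Drops every node pair whose mean k-mer coverage
#' (`kmer_count / length_k`) is below the cutoff `c`, together with all
#' incident edges, then recompacts the graph.  With `c = 0` the graph
#' is returned unchanged.  This mirrors the `cov_cutoff` semantics of
#' Velvet: coverage is per node and in mean k-mer coverage units.
#'
#' @param g a [dbg] graph (compacted).
#' @param c non-negative coverage cutoff.
#' @return cleaned, recompacted [dbg] graph.
#' @export
apply_coverage_cutoff <- function(g, c) {
  if (c <= 0 || nrow(g$nodes) == 0L) return(g)
  cov <- g$nodes$kmer_count / g$nodes$length_k
  bad <- g$nodes$id[cov < c]
  if (length(bad) == 0L) return(g)
  compact_unitigs(drop_nodes(g, bad))
}

#' Clip short dead-end tips
#'
#' Iteratively removes tips: nodes that are dead ends on one side
#' (in-degree 0 or out-degree 0 in the forward orientation), have
#' spelled length at most `tip_len`, and hang off a branch that keeps
#' an alternative path after their removal (every neighbour at the
#' attached side retains at least one other incident edge).  Isolated
#' single-node components are never removed.  Candidates are clipped
#' weakest-coverage first; the graph is recompacted and the search
#' repeated until a fixed point.
#'
#' @param g a [dbg] graph (compacted).
#' @param tip_len maximum spelled length of a clippable tip (bases).
#' @return cleaned, recompacted [dbg] graph.
#' @export
clip_tips <- function(g, tip_len) {
  if (tip_len <= 0L) return(g)
  repeat {
    if (nrow(g$nodes) == 0L) return(g)
    deg <- oriented_degrees(g)
    ids <- g$nodes$id
    din <- deg$in.[as.character(ids)]
    dout <- deg$out[as.character(ids)]
    len <- nchar(g$nodes$seq)
    # dead-end on exactly one side, short enough
    cand <- ids[((din == 0L) != (dout == 0L)) & len <= tip_len]
    if (length(cand) == 0L) return(g)
    cov <- (g$nodes$kmer_count / g$nodes$length_k)[match(cand, ids)]
    ord <- order(cov, cand)
    cand <- cand[ord]
    ind_left <- deg$in.
    outd_left <- deg$out
    removed <- integer(0)
    for (t in cand) {
      # orient t so that its dead end is upstream
      o <- if (ind_left[as.character(t)] == 0L) t else -t
      succ <- unique(g$edges$to[g$edges$from == o])
      succ <- setdiff(succ, c(o, -o))
      if (length(succ) == 0L) next
      if (!all(ind_left[as.character(succ)] >= 2L)) next
      removed <- c(removed, t)
      # update remaining degrees as if t were gone
      et <- g$edges[abs(g$edges$from) == t | abs(g$edges$to) == t, , drop = FALSE]
      for (i in seq_len(nrow(et))) {
        ind_left[as.character(et$to[i])] <- ind_left[as.character(et$to[i])] - 1L
        outd_left[as.character(et$from[i])] <- outd_left[as.character(et$from[i])] - 1L
      }
    }
    if (length(removed) == 0L) return(g)
    g <- compact_unitigs(drop_nodes(g, removed))
  }
}

#' Find SNP-induced split-then-merge structures
#'
#' Searches for bubbles of the shape start -> \{p1, .., pm\} -> end
#' (m >= 2) in which all parallel node sequences have equal length,
#' differ only at few well-separated columns, every parallel node has
#' exactly one incoming and one outgoing edge, the end node receives no
#' edges other than those from the parallel nodes, and the structure
#' does not contain a node together with its own twin.  Extra edges
#' into the start node and out of the end node are allowed.  Such
#' bubbles are the graph signature of SNPs/sequencing variants rather
#' than alternative splicing; bubbles whose arms differ in length
#' (short indels) are deliberately not reported.
#'
#' @param g a [dbg] graph (compacted).
#' @param min_match minimum run of exact matches required between two
#'   mismatch columns (default `k`: a k-length exact flank is the
#'   weakest evidence that the bubble is a SNP rather than a repeat).
#' @param max_mismatch_frac maximum fraction of mismatching columns in
#'   the parallel sequences; at least one mismatch column is always
#'   allowed so the canonical single-SNP bubble qualifies.
#' @return list of `snp_structure` objects with fields `start_id`,
#'   `parallel_ids`, `end_id`, `mismatch_positions`.
#' @export
find_snp_structures <- function(g, min_match = g$k, max_mismatch_frac = 0.02) {
  out <- list()
  if (nrow(g$edges) == 0L) return(out)
  deg <- oriented_degrees(g)
  ids <- g$nodes$id
  seen_key <- character(0)
  for (s in sort(c(ids, -ids))) {
    ch <- sort(unique(g$edges$to[g$edges$from == s]))
    if (length(ch) < 2L) next
    st <- check_snp_structure(g, s, ch, deg, min_match, max_mismatch_frac)
    if (is.null(st)) next
    # a structure and its strand mirror are the same object
    key <- paste(sort(abs(c(st$start_id, st$parallel_ids, st$end_id))),
                 collapse = ",")
    if (key %in% seen_key) next
    seen_key <- c(seen_key, key)
    out[[length(out) + 1L]] <- st
  }
  out
}

# validate one candidate bubble rooted at oriented node s with children ch
check_snp_structure <- function(g, s, ch, deg, min_match, max_mismatch_frac) {
  chs <- as.character(ch)
  if (!all(deg$out[chs] == 1L) || !all(deg$in.[chs] == 1L)) return(NULL)
  ends <- vapply(ch, function(p) {
    e <- g$edges$to[g$edges$from == p]
    if (length(e) == 1L) e else NA_integer_
  }, integer(1))
  if (anyNA(ends) || length(unique(ends)) != 1L) return(NULL)
  f <- ends[[1]]
  # no branches into the final node other than from the parallel nodes
  if (deg$in.[as.character(f)] != length(ch)) return(NULL)
  all_ids <- c(s, ch, f)
  if (any(all_ids %in% -all_ids)) return(NULL) # node and twin together
  if (anyDuplicated(abs(all_ids))) return(NULL)
  seqs <- node_seq(g, ch)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) return(NULL) # indel bubble
  mat <- do.call(rbind, lapply(seqs, function(x) utf8ToInt(x)))
  mism <- which(apply(mat, 2L, function(col) length(unique(col)) > 1L))
  if (length(mism) == 0L) return(NULL)
  if (length(mism) > max(1L, floor(max_mismatch_frac * L))) return(NULL)
  if (length(mism) > 1L && any(diff(mism) - 1L < min_match)) return(NULL)
  structure(
    list(start_id = s, parallel_ids = ch, end_id = f,
         mismatch_positions = mism),
    class = "snp_structure"
  )
}

#' Merge SNP bubbles into consensus nodes
#'
#' Chains successive split-then-merge structures (the end node of one
#' being the start node of the next) and replaces each chain -- start
#' node, all parallel columns, all end nodes -- by a single node whose
#' sequence is the coverage-weighted per-column majority consensus
#' (ties broken toward the lexicographically smaller base) and whose
#' `kmer_count` is the sum over all merged nodes.  Structures that
#' conflict with an already-merged chain are skipped (chains are
#' processed in order of smallest start id).  The graph is recompacted
#' afterwards.
#'
#' @param g a [dbg] graph.
#' @param structures list of structures from [find_snp_structures()].
#' @return `list(graph = <dbg>, snp_count = <int>)` where `snp_count`
#'   is the total number of mismatch columns merged.
#' @export
merge_snp_chain <- function(g, structures) {
  if (length(structures) == 0L) return(list(graph = g, snp_count = 0L))
  ord <- order(vapply(structures, function(s) min(abs(s$start_id)), numeric(1)),
               vapply(structures, function(s) s$start_id, numeric(1)))
  structures <- structures[ord]
  start_of <- vapply(structures, function(s) s$start_id, integer(1))
  used <- logical(length(structures))
  consumed_nodes <- integer(0) # abs ids already merged away
  snp_count <- 0L
  new_nodes <- list()
  next_id <- max(g$nodes$id) + 1L
  drop_ids <- integer(0)
  edges <- g$edges
  for (i in seq_along(structures)) {
    if (used[i]) next
    # grow a chain of successive structures
    chain <- list(structures[[i]])
    used[i] <- TRUE
    repeat {
      nxt <- which(!used & start_of == chain[[length(chain)]]$end_id)
      if (length(nxt) == 0L) break
      chain[[length(chain) + 1L]] <- structures[[nxt[1]]]
      used[nxt[1]] <- TRUE
    }
    members <- unique(unlist(lapply(chain, function(s)
      c(s$start_id, s$parallel_ids, s$end_id))))
    if (any(abs(members) %in% consumed_nodes)) next # conflicting chain
    consumed_nodes <- c(consumed_nodes, abs(members))
    # consensus sequence along the chain
    spell <- node_seq(g, chain[[1]]$start_id)
    for (s in chain) {
      cons <- consensus_sequence(g, s$parallel_ids)
      spell <- paste0(spell, substring(cons, g$k))
      spell <- paste0(spell, substring(node_seq(g, s$end_id), g$k))
      snp_count <- snp_count + length(s$mismatch_positions)
    }
    kc <- sum(g$nodes$kmer_count[match(abs(members), g$nodes$id)])
    first <- chain[[1]]$start_id
    last <- chain[[length(chain)]]$end_id
    # rewire: external in-edges of the chain start, out-edges of the end
    rcs <- reverse_complement(spell)
    flip <- rcs < spell
    nid <- next_id
    next_id <- next_id + 1L
    new_nodes[[length(new_nodes) + 1L]] <-
      data.frame(id = nid, seq = if (flip) rcs else spell,
                 kmer_count = kc, length_k = nchar(spell) - g$k + 1L,
                 stringsAsFactors = FALSE)
    o_nid <- if (flip) -nid else nid
    inn <- edges$to == first & !(abs(edges$from) %in% abs(members))
    out <- edges$from == last & !(abs(edges$to) %in% abs(members))
    edges$to[inn] <- o_nid
    edges$from[out] <- o_nid
    # twin copies of those edges
    inn2 <- edges$from == -first & !(abs(edges$to) %in% abs(members))
    out2 <- edges$to == -last & !(abs(edges$from) %in% abs(members))
    edges$from[inn2] <- -o_nid
    edges$to[out2] <- -o_nid
    drop_ids <- c(drop_ids, abs(members))
  }
  if (length(drop_ids) == 0L) return(list(graph = g, snp_count = 0L))
  g$edges <- edges
  g <- drop_nodes(g, drop_ids)
  if (length(new_nodes) > 0L) {
    g$nodes <- rbind(g$nodes, do.call(rbind, new_nodes))
    rownames(g$nodes) <- NULL
  }
  g <- close_twin_edges(g)
  g <- renumber_nodes(g)
  list(graph = compact_unitigs(g), snp_count = snp_count)
}

# degree helper over an explicit edge table
oriented_degrees_edges <- function(edges, ids) {
  ov <- as.character(c(ids, -ids))
  outd <- stats::setNames(integer(length(ov)), ov)
  ind <- outd
  if (nrow(edges) > 0L) {
    tf <- table(factor(as.character(edges$from), levels = ov))
    tt <- table(factor(as.character(edges$to), levels = ov))
    outd[] <- as.integer(tf)
    ind[] <- as.integer(tt)
  }
  list(out = outd, in. = ind)
}

# coverage-weighted majority consensus of equal-length parallel nodes
consensus_sequence <- function(g, ids) {
  seqs <- node_seq(g, ids)
  w <- (g$nodes$kmer_count / g$nodes$length_k)[match(abs(ids), g$nodes$id)]
  mat <- do.call(rbind, lapply(seqs, utf8ToInt))
  cons <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    sc <- tapply(w, col, sum)
    best <- max(sc)
    # tie -> lexicographically smaller base (smaller ASCII code)
    as.integer(min(as.integer(names(sc)[sc == best])))
  }, integer(1))
  intToUtf8(cons)
}

#' Iterate SNP bubble merging to a fixed point
#'
#' Repeatedly runs [find_snp_structures()] and [merge_snp_chain()]
#' until no structure remains, accumulating the merged-SNP count.
#'
#' @inheritParams find_snp_structures
#' @param max_rounds safety bound on iterations.
#' @return `list(graph, snp_count)`.
#' @export
merge_all_snps <- function(g, min_match = g$k, max_mismatch_frac = 0.02,
                           max_rounds = 100L) {
  total <- 0L
  for (i in seq_len(max_rounds)) {
    st <- find_snp_structures(g, min_match, max_mismatch_frac)
    if (length(st) == 0L) break
    res <- merge_snp_chain(g, st)
    if (res$snp_count == 0L) break
    g <- res$graph
    total <- total + res$snp_count
  }
  list(graph = g, snp_count = total)
}
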