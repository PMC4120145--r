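#' Build a compacted de Bruijn graph from reads
#'
#' Constructs the double-stranded de Bruijn graph over the canonical
#' k-mers of the input reads and compacts every maximal branch-free
#' chain into a single unitig node.  A vertex is created for every
#' k-mer appearing in the reads (on either strand); two k-mers are
#' joined by a directed edge when the (k-1)-suffix of the first equals
#' the (k-1)-prefix of the second.  Bases outside \{A,C,G,T\} split a
#' read into fragments so that no k-mer spans an ambiguous base.
#'
#' @param reads character vector of reads, or a list of character
#'   vectors (one element per library); library identity only affects
#'   expression counting downstream, not graph topology.
#' @param params an [sg_params()] object (only `k` is used here).
#' @return a compacted [dbg] graph; `kmer_count` of each node is the
#'   total number of its constituent k-mer instances across all reads.
#' Edges link k-mers that are adjacent within some read (the graph an
#' assembler such as Velvet materialises); at practical k this
#' coincides with the textbook overlap definition, while avoiding
#' spurious chance-overlap edges between k-mers that never co-occur.
#'
#' @examples
#' g <- build_graph("ACGTACGTTT", sg_params(k = 5))
#' @export
build_graph <- function(reads, params) {
  k <- params$k
  if (is.list(reads)) reads <- unlist(reads, use.names = FALSE)
  reads <- as.character(reads)
  if (length(reads) == 0L) return(dbg(k))
  frags <- sanitize_reads(reads)
  if (length(frags) == 0L) return(dbg(k))
  if (all(nchar(frags) < k)) {
    stop("k = ", k, " exceeds the length of every read fragment")
  }
  km <- enumerate_kmers_by_read(frags, k)
  canon <- canonical_kmer(km$kmers)
  tab <- sort_counts(canon)
  # signed oriented id of every k-mer instance
  idx <- match(canon, tab$key)
  sid <- ifelse(km$kmers == tab$key[idx], idx, -idx)
  # read-adjacency edges: consecutive k-mers within one fragment
  adj <- which(km$read[-1L] == km$read[-length(km$read)])
  edges <- NULL
  if (length(adj) > 0L) {
    ef <- unique(data.frame(from = sid[adj], to = sid[adj + 1L]))
    ef$weight <- 1
    edges <- ef
  }
  raw <- dbg(k, seqs = tab$key, kmer_count = tab$count, edges = edges)
  compact_unitigs(raw)
}

# count occurrences of each distinct string, keys sorted
sort_counts <- function(x) {
  s <- sort(x, method = "radix")
  r <- rle(s)
  list(key = r$values, count = as.numeric(r$lengths))
}

# k-mer instances together with the index of the fragment they came from
enumerate_kmers_by_read <- function(x, k) {
  n <- nchar(x)
  keep <- n >= k
  x <- x[keep]
  n <- n[keep]
  if (length(x) == 0L) return(list(kmers = character(0), read = integer(0)))
  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    starts <- seq_len(n[i] - k + 1L)
    out[[i]] <- substring(x[i], starts, starts + k - 1L)
  }
  list(
    kmers = unlist(out, use.names = FALSE),
    read = rep.int(seq_along(x), n - k + 1L)
  )
}

#' Compact all maximal branch-free chains into unitig nodes
#'
#' Replaces every maximal succession of nodes with no branches by a
#' single node spelling the concatenated sequence (respecting the
#' `k - 1` overlap between adjacent nodes).  Works on the raw k-mer
#' graph and on any partially compacted graph, so it is re-run after
#' each cleaning step that removes nodes.  A perfect cycle compacts to
#' one node carrying a self-loop edge.  Twin symmetry is preserved; a
#' chain is never extended across a node's own twin.
#'
#' @param g a [dbg] graph.
#' @return a compacted [dbg] graph spelling the same maximal paths.
#' @export
compact_unitigs <- function(g) {
  n <- nrow(g$nodes)
  if (n == 0L) return(g)
  k <- g$k
  ids <- g$nodes$id
  nv <- 2L * n
  twin_of <- function(i) ifelse(i > n, i - n, i + n)
  # oriented index: +id -> pos in 1..n, -id -> pos + n
  oi <- function(sid) {
    p <- match(abs(sid), ids)
    p + n * (sid < 0L)
  }
  sid_of <- c(ids, -ids) # oriented index -> signed id
  oseq <- c(g$nodes$seq, reverse_complement(g$nodes$seq))

  e <- unique(g$edges[c("from", "to")])
  wtab <- g$edges
  from_i <- oi(e$from)
  to_i <- oi(e$to)
  outd <- tabulate(from_i, nv)
  ind <- tabulate(to_i, nv)
  succ <- rep(NA_integer_, nv)
  sel <- outd[from_i] == 1L
  succ[from_i[sel]] <- to_i[sel]
  # chain_next[u]: unique successor v absorbed into u's chain
  chain_next <- rep(NA_integer_, nv)
  u <- which(!is.na(succ))
  v <- succ[u]
  ok <- ind[v] == 1L & v != u & v != twin_of(u)
  chain_next[u[ok]] <- v[ok]
  chain_prev <- rep(NA_integer_, nv)
  chain_prev[chain_next[u[ok]]] <- u[ok]

  visited <- logical(nv)
  chains <- list()
  consumed <- character(0)
  walk <- function(s) {
    buf <- integer(64L)
    buf[1L] <- s
    len <- 1L
    visited[s] <<- TRUE
    visited[twin_of(s)] <<- TRUE
    cur <- s
    cons <- character(32L)
    nc <- 0L
    repeat {
      nx <- chain_next[cur]
      if (is.na(nx) || nx == s || visited[nx]) break
      len <- len + 1L
      if (len > length(buf)) buf <- c(buf, integer(length(buf)))
      buf[len] <- nx
      visited[nx] <<- TRUE
      visited[twin_of(nx)] <<- TRUE
      nc <- nc + 1L
      if (nc > length(cons)) cons <- c(cons, character(length(cons)))
      cons[nc] <- paste(cur, nx)
      cur <- nx
    }
    if (nc > 0L) {
      cc <- cons[seq_len(nc)]
      consumed <<- c(consumed, cc)
    }
    buf[seq_len(len)]
  }
  starts <- which(is.na(chain_prev))
  for (s in starts) {
    if (visited[s]) next
    chains[[length(chains) + 1L]] <- walk(s)
  }
  # leftover = pure cycles (every vertex interior)
  left <- which(!visited)
  while (length(left) > 0L) {
    s <- left[1L]
    chains[[length(chains) + 1L]] <- walk(s)
    left <- which(!visited)
  }
  # twin-consumed edges are consumed too
  if (length(consumed) > 0L) {
    parts <- strsplit(consumed, " ", fixed = TRUE)
    cu <- as.integer(vapply(parts, `[[`, "", 1L))
    cv <- as.integer(vapply(parts, `[[`, "", 2L))
    consumed <- unique(c(consumed, paste(twin_of(cv), twin_of(cu))))
  }

  m <- length(chains)
  new_seq <- character(m)
  new_count <- numeric(m)
  or_map <- integer(nv) # oriented old index -> signed new id
  for (ci in seq_len(m)) {
    ch <- chains[[ci]]
    seqs <- oseq[ch]
    spell <- if (length(seqs) == 1L) seqs else {
      paste0(seqs[1L], paste(substring(seqs[-1L], k), collapse = ""))
    }
    rcs <- reverse_complement(spell)
    flip <- rcs < spell
    new_seq[ci] <- if (flip) rcs else spell
    # a chain may contain an oriented vertex and its twin (hairpin);
    # count each node pair once
    new_count[ci] <- sum(g$nodes$kmer_count[unique(ifelse(ch > n, ch - n, ch))])
    sgn <- if (flip) -ci else ci
    or_map[ch] <- sgn
    or_map[twin_of(ch)] <- -sgn
  }

  keep <- !(paste(from_i, to_i) %in% consumed)
  edges <- NULL
  if (any(keep)) {
    edges <- data.frame(
      from = or_map[from_i[keep]],
      to = or_map[to_i[keep]],
      weight = 1
    )
    # carry arc weights through where the edge survives unmerged
    wi <- match(paste(e$from[keep], e$to[keep]),
                paste(wtab$from, wtab$to))
    edges$weight <- ifelse(is.na(wi), 1, wtab$weight[wi])
  }
  dbg(k, seqs = new_seq, kmer_count = new_count, edges = edges)
}
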