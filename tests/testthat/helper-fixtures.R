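# shared fixture builders: everything is generated in code, no data files

rnd_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# tile a transcript with every read of length rl (error-free, exhaustive)
tile_reads <- function(x, rl = 40L) {
  substring(x, 1:(nchar(x) - rl + 1L), rl:nchar(x))
}

# an exon-skipping two-isoform gene with base-precise boundaries:
# isoform 1 = e1 e2 e3, isoform 2 = e1 e3
skip_gene <- function(l1 = 120L, l2 = 80L, l3 = 120L) {
  e1 <- rnd_seq(l1); e2 <- rnd_seq(l2); e3 <- rnd_seq(l3)
  substr(e2, 1L, 1L) <- "A"; substr(e3, 1L, 1L) <- "C"
  substr(e2, l2, l2) <- "G"; substr(e1, l1, l1) <- "T"
  list(e1 = e1, e2 = e2, e3 = e3,
       t1 = paste0(e1, e2, e3), t2 = paste0(e1, e3))
}

# random double-stranded graph (arbitrary k-length seqs, twin-closed
# random edges); used for decomposition properties, which never look at
# sequence overlaps
random_dbg <- function(n_nodes, n_edges, k = 5L) {
  seqs <- vapply(seq_len(n_nodes), function(i) rnd_seq(k), character(1))
  from <- sample(c(-n_nodes:-1, 1:n_nodes), n_edges, replace = TRUE)
  to <- sample(c(-n_nodes:-1, 1:n_nodes), n_edges, replace = TRUE)
  dbg(k, seqs = seqs,
      edges = data.frame(from = from, to = to, weight = rep(1, n_edges)))
}

# brute-force SCC oracle: boolean transitive closure over the oriented
# vertices; u and v share an SCC iff each reaches the other
scc_oracle_membership <- function(g) {
  ids <- g$nodes$id
  ov <- c(ids, -ids)
  nv <- length(ov)
  A <- matrix(FALSE, nv, nv)
  diag(A) <- TRUE
  if (nrow(g$edges) > 0L) {
    A[cbind(match(g$edges$from, ov), match(g$edges$to, ov))] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0 | A
    if (identical(A2, A)) break
    A <- A2
  }
  same <- A & t(A)
  # canonical membership label: smallest oriented index in the class
  memb <- apply(same, 1L, function(r) which(r)[1L])
  stats::setNames(memb, ov)
}

# membership vector (named by signed id) from an SCC partition list
scc_membership <- function(sccs, g) {
  ids <- g$nodes$id
  ov <- c(ids, -ids)
  memb <- stats::setNames(integer(length(ov)), ov)
  for (i in seq_along(sccs)) memb[as.character(sccs[[i]])] <- i
  memb
}

# do two membership vectors describe the same partition?
same_partition <- function(m1, m2) {
  stopifnot(length(m1) == length(m2))
  identical(
    outer(m1, m1, "==")[upper.tri(diag(length(m1)))],
    outer(m2, m2, "==")[upper.tri(diag(length(m2)))]
  )
}

# does transcript tr appear verbatim (either strand) as a source-to-sink
# path of graph sg?
has_transcript_path <- function(sg, tr) {
  p <- spell_paths(sg, max_paths = 1000L)
  tr %in% p || reverse_complement(tr) %in% p
}

# write a tiny FASTQ file; qualities given as integer vectors (Phred+33)
write_test_fastq <- function(path, reads, quals = NULL) {
  out <- character(0)
  for (i in seq_along(reads)) {
    q <- if (is.null(quals)) strrep("I", nchar(reads[i])) else {
      intToUtf8(quals[[i]] + 33L)
    }
    out <- c(out, paste0("@r", i), reads[i], "+", q)
  }
  writeLines(out, path)
  path
}
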