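#' Read library container
#'
#' A named collection of reads contributing to per-library RPKM.
#'
#' @param name library name.
#' @param reads character vector of read sequences.
#' @param total_reads total reads in the library before any filtering
#'   (defaults to `length(reads)`).
#' @return an object of class `read_library`.
#' @export
read_library <- function(name, reads, total_reads = length(reads)) {
  structure(list(name = as.character(name), reads = as.character(reads),
                 total_reads = as.integer(total_reads)),
            class = "read_library")
}

#' @export
print.read_library <- function(x, ...) {
  cat(sprintf("read library '%s': %d reads\n", x$name, x$total_reads))
  invisible(x)
}

# coerce a named list of character vectors / read_library objects
as_read_libraries <- function(x) {
  if (inherits(x, "read_library")) return(list(x))
  if (is.character(x)) return(list(read_library("lib1", x)))
  stopifnot(is.list(x))
  nm <- names(x)
  lapply(seq_along(x), function(i) {
    if (inherits(x[[i]], "read_library")) return(x[[i]])
    name <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else paste0("lib", i)
    read_library(name, x[[i]])
  })
}

# classify a sequence file as fasta or fastq by its first character
sniff_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  l <- readLines(con, n = 1L)
  if (length(l) == 0L) return("empty")
  c1 <- substr(l, 1L, 1L)
  if (c1 == ">") "fasta" else if (c1 == "@") "fastq" else
    stop("unrecognised sequence format in ", path)
}

#' Read sequencing libraries from FASTA/FASTQ files
#'
#' Each element of `paths` (a character vector of file paths, possibly
#' named) becomes one library; an element may also be a vector of
#' several files forming a file group.  When `quality_cutoff` is set
#' and the input is FASTQ, each read is truncated at the first base
#' with Phred quality below the cutoff (that base excluded) -- the
#' trimming rule used when sequence quality decays toward read ends.
#' Reads trimmed to nothing are kept as empty strings so that library
#' totals still count them; graph building skips fragments shorter
#' than k.
#'
#' @param paths list (or vector) of file paths, one element per
#'   library; names become library names.
#' @param quality_cutoff optional integer Phred cutoff; requires FASTQ.
#' @return list of `read_library` objects.
#' @export
read_libraries <- function(paths, quality_cutoff = NULL) {
  if (!is.list(paths)) paths <- as.list(paths)
  nm <- names(paths)
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    files <- paths[[i]]
    fmts <- vapply(files, sniff_format, character(1))
    fmts <- unique(fmts[fmts != "empty"])
    if (length(fmts) > 1L) {
      stop("library ", i, " mixes FASTA and FASTQ files")
    }
    reads <- character(0)
    for (f in files) {
      fmt <- sniff_format(f)
      if (fmt == "empty") next
      if (fmt == "fasta") {
        if (!is.null(quality_cutoff)) {
          stop("quality trimming requires FASTQ input (", f, " is FASTA)")
        }
        reads <- c(reads, as.character(Biostrings::readDNAStringSet(f)))
      } else {
        # suppressed: Biostrings warns about dropped metadata columns on
        # perfectly ordinary FASTQ input
        sq <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(f))
        sr <- suppressWarnings(as.character(sq))
        if (!is.null(quality_cutoff)) {
          qs <- suppressWarnings(as(Biostrings::quality(sq), "IntegerList"))
          sr <- vapply(seq_along(sr), function(j) {
            q <- qs[[j]]
            bad <- which(q < quality_cutoff)
            if (length(bad) == 0L) sr[[j]] else substr(sr[[j]], 1L, bad[1L] - 1L)
          }, character(1))
        }
        reads <- c(reads, unname(sr))
      }
    }
    name <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else {
      sub("\\.(fa|fasta|fq|fastq)(\\.gz)?$", "", basename(files[[1]]))
    }
    out[[i]] <- read_library(name, unname(reads))
  }
  out
}

#' Parse a Velvet-style LastGraph file
#'
#' Reads the dialect with a `$NUMBER_OF_NODES $NUMBER_OF_SEQUENCES
#' $HASH_LENGTH` header line, `NODE` blocks carrying two sequence lines
#' (the forward and twin end-sequences, i.e. the node sequence minus
#' its first k-1 bases), and `ARC` lines with signed node ids and a
#' multiplicity.  Twin symmetry is reconstructed (an arc implies its
#' twin arc); the full node sequence is rebuilt from the two
#' end-sequence lines.  For nodes spelling fewer than `k - 1` k-mers
#' part of the interior sequence is not recorded in the file; those
#' positions are filled with `A` and a warning is raised.
#'
#' @param path file path (plain or gzip).
#' @return a [dbg] graph with arc multiplicities as edge weights.
#' @export
parse_lastgraph <- function(path) {
  con <- gzfile(path, "rt")
  lines <- readLines(con)
  close(con)
  if (length(lines) == 0L) stop("empty LastGraph file: ", path)
  hdr <- strsplit(trimws(lines[1L]), "[ \t]+")[[1]]
  if (length(hdr) < 3L || anyNA(suppressWarnings(as.integer(hdr[1:3])))) {
    stop("malformed LastGraph header at line 1 of ", path)
  }
  n_nodes <- as.integer(hdr[1L])
  k <- as.integer(hdr[3L])
  seqs <- character(n_nodes)
  ids <- integer(n_nodes)
  counts <- numeric(n_nodes)
  node_i <- 0L
  arcs <- list()
  pad_warn <- FALSE
  i <- 2L
  while (i <= length(lines)) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) == 0L || !nzchar(f[1L])) { i <- i + 1L; next }
    if (f[1L] == "NODE") {
      if (length(f) < 4L || i + 2L > length(lines)) {
        stop("malformed NODE block at line ", i, " of ", path)
      }
      node_i <- node_i + 1L
      ids[node_i] <- as.integer(f[2L])
      len_k <- as.integer(f[3L])
      counts[node_i] <- as.numeric(f[4L])
      fwd <- toupper(trimws(lines[i + 1L]))
      twn <- toupper(trimws(lines[i + 2L]))
      if (nchar(fwd) != len_k || nchar(twn) != len_k) {
        stop("NODE ", f[2L], " sequence length mismatch at line ", i + 1L,
             " of ", path)
      }
      head_part <- reverse_complement(twn) # S[1..len_k]
      if (len_k >= k - 1L) {
        seqs[node_i] <- paste0(substr(head_part, 1L, k - 1L), fwd)
      } else {
        pad_warn <- TRUE
        gap <- strrep("A", k - 1L - len_k)
        seqs[node_i] <- paste0(head_part, gap, fwd)
      }
      i <- i + 3L
    } else if (f[1L] == "ARC") {
      if (length(f) < 4L) stop("malformed ARC at line ", i, " of ", path)
      arcs[[length(arcs) + 1L]] <- as.numeric(f[2:4])
      i <- i + 1L
    } else {
      i <- i + 1L # unknown record types are skipped
    }
  }
  if (node_i != n_nodes) {
    stop("LastGraph header announces ", n_nodes, " nodes but ", node_i,
         " NODE blocks were found in ", path)
  }
  if (pad_warn) {
    warning("short NODE block(s): interior bases not recorded in the ",
            "file were filled with 'A'")
  }
  ord <- order(ids)
  if (!identical(ids[ord], seq_len(n_nodes))) {
    stop("LastGraph node ids are not 1..", n_nodes, " in ", path)
  }
  edges <- NULL
  if (length(arcs) > 0L) {
    am <- do.call(rbind, arcs)
    bad <- !(abs(am[, 1L]) %in% ids) | !(abs(am[, 2L]) %in% ids)
    if (any(bad)) {
      stop("ARC references unknown node id (first offending arc: ",
           paste(am[which(bad)[1L], 1:2], collapse = " -> "), ") in ", path)
    }
    edges <- data.frame(from = as.integer(am[, 1L]),
                        to = as.integer(am[, 2L]), weight = am[, 3L])
  }
  dbg(k, seqs = seqs[ord], kmer_count = counts[ord], edges = edges)
}

#' Write a graph in the LastGraph dialect
#'
#' Inverse of [parse_lastgraph()]: emits the header, one `NODE` block
#' per node pair (forward and twin end-sequences) and one `ARC` line
#' per edge (twin arcs implied, so each twin pair is written once).
#'
#' @param g a [dbg] graph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lastgraph <- function(g, path) {
  n <- nrow(g$nodes)
  out <- character(0)
  out <- c(out, paste(n, 0L, g$k, sep = "\t"))
  for (i in seq_len(n)) {
    s <- g$nodes$seq[i]
    len_k <- g$nodes$length_k[i]
    fwd <- substring(s, g$k) # S minus first k-1
    twn <- reverse_complement(substr(s, 1L, len_k))
    out <- c(out, paste("NODE", g$nodes$id[i], len_k, g$nodes$kmer_count[i],
                        sep = "\t"), fwd, twn)
  }
  e <- g$edges
  if (nrow(e) > 0L) {
    key <- paste(e$from, e$to)
    twin <- paste(-e$to, -e$from)
    keep <- key <= twin # one arc per twin pair (self-twin arcs once)
    e <- e[keep, , drop = FALSE]
    e <- e[order(e$from, e$to), , drop = FALSE]
    out <- c(out, paste("ARC", e$from, e$to, e$weight, sep = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}

# fixed header grammar of the annotated-FASTA dialect:
#   >g<graph_id>_n<node_id> edges:<id,id,...|-> <lib>=<rpkm> ...
format_annotated_header <- function(graph_id, node_id, out_edges, rpkm) {
  edges_str <- if (length(out_edges) == 0L) "-" else {
    paste(sort(out_edges), collapse = ",")
  }
  rp <- if (length(rpkm) == 0L) "" else {
    paste0(" ", paste(sprintf("%s=%.2f", names(rpkm), rpkm), collapse = " "))
  }
  sprintf(">g%d_n%d edges:%s%s", graph_id, node_id, edges_str, rp)
}

#' Write splicing graphs as annotated FASTA
#'
#' One FASTA record per node; the header embeds the graph id, node id,
#' the node's out-edge list and the per-library RPKM values, so that
#' the full non-linear structure can be reconstructed from the file.
#' Records are ordered by graph id, then node id (node ids are already
#' topological); output is byte-identical across runs.
#'
#' @param graphs list of finalized `splicing_graph` objects.
#' @param path output file path.
#' @param expr optional `node_expression` table with rpkm columns (from
#'   [compute_rpkm()]); omitted, headers carry no RPKM fields.
#' @param width sequence line wrap width.
#' @return `path`, invisibly.
#' @export
write_annotated_fasta <- function(graphs, path, expr = NULL, width = 60L) {
  rpkm_cols <- if (!is.null(expr)) {
    grep("_rpkm$", names(expr), value = TRUE)
  } else character(0)
  out <- character(0)
  for (sg in graphs[order(vapply(graphs, `[[`, integer(1), "graph_id"))]) {
    for (v in seq_along(sg$seqs)) {
      rpkm <- numeric(0)
      if (length(rpkm_cols) > 0L) {
        row <- which(expr$graph_id == sg$graph_id & expr$node_id == v)
        if (length(row) == 1L) {
          rpkm <- vapply(rpkm_cols, function(cl) expr[[cl]][row], numeric(1))
          names(rpkm) <- sub("_rpkm$", "", rpkm_cols)
        }
      }
      hdr <- format_annotated_header(
        sg$graph_id, v, sg$edges$to[sg$edges$from == v], rpkm
      )
      s <- sg$seqs[v]
      starts <- seq.int(1L, nchar(s), by = width)
      out <- c(out, hdr, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Parse an annotated-FASTA file back into splicing graphs
#'
#' Inverse of [write_annotated_fasta()].
#'
#' @param path file path.
#' @return `list(graphs = <list of splicing_graph>, rpkm = <data.frame
#'   graph_id, node_id, library, rpkm>)`.
#' @export
parse_annotated_fasta <- function(path) {
  con <- gzfile(path, "rt")
  lines <- readLines(con)
  close(con)
  hd <- grep("^>", lines)
  if (length(hd) == 0L) return(list(graphs = list(), rpkm = NULL))
  ends <- c(hd[-1L] - 1L, length(lines))
  recs <- lapply(seq_along(hd), function(i) {
    header <- lines[hd[i]]
    seq <- paste(lines[(hd[i] + 1L):ends[i]], collapse = "")
    m <- regmatches(header,
                    regexec("^>g(\\d+)_n(\\d+) edges:([-0-9,]+)(.*)$", header))[[1]]
    if (length(m) == 0L) stop("malformed annotated-FASTA header: ", header)
    rp <- list()
    rest <- trimws(m[5L])
    if (nzchar(rest)) {
      for (tok in strsplit(rest, " +")[[1]]) {
        kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
        rp[[kv[1L]]] <- as.numeric(kv[2L])
      }
    }
    list(graph_id = as.integer(m[2L]), node_id = as.integer(m[3L]),
         edges = if (m[4L] == "-") integer(0) else
           as.integer(strsplit(m[4L], ",")[[1]]),
         rpkm = rp, seq = seq)
  })
  gids <- vapply(recs, `[[`, integer(1), "graph_id")
  graphs <- list()
  rpkm_rows <- list()
  for (gid in sort(unique(gids))) {
    rs <- recs[gids == gid]
    nids <- vapply(rs, `[[`, integer(1), "node_id")
    rs <- rs[order(nids)]
    seqs <- vapply(rs, `[[`, character(1), "seq")
    ef <- list()
    for (r in rs) {
      if (length(r$edges) > 0L) {
        ef[[length(ef) + 1L]] <- data.frame(from = r$node_id, to = r$edges)
      }
      for (lib in names(r$rpkm)) {
        rpkm_rows[[length(rpkm_rows) + 1L]] <- data.frame(
          graph_id = gid, node_id = r$node_id, library = lib,
          rpkm = r$rpkm[[lib]]
        )
      }
    }
    edges <- if (length(ef)) do.call(rbind, ef) else NULL
    k_guess <- NA_integer_
    graphs[[length(graphs) + 1L]] <- splicing_graph(
      gid, 0L, seqs, edges, singleton = length(seqs) == 1L && is.null(edges)
    )
  }
  rpkm <- if (length(rpkm_rows)) do.call(rbind, rpkm_rows) else NULL
  list(graphs = graphs, rpkm = rpkm)
}

#' Write expression estimates as TSV
#'
#' @param expr a `node_expression` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- as.data.frame(expr)
  num <- vapply(df, is.numeric, logical(1)) & grepl("_rpkm$", names(df))
  for (cl in names(df)[num]) df[[cl]] <- sprintf("%.2f", df[[cl]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulated reads as FASTQ
#'
#' @param reads character vector of read sequences.
#' @param path output path.
#' @param quality_char constant quality character (Phred+33).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  ids <- paste0("@read", seq_along(reads))
  out <- as.vector(rbind(ids, reads, "+",
                         strrep(quality_char, nchar(reads))))
  writeLines(out, path)
  invisible(path)
}
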