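#' Generate synthetic genes with alternative splicing
#'
#' Desk-scale stand-in for a real transcript set: each gene is a chain
#' of random exons; a multi-isoform gene carries a second isoform that
#' skips one internal exon (classic exon skipping).  Exon boundary
#' bases flanking alternative events are forced to differ between the
#' alternatives so that splice junctions are locally unambiguous and
#' base-precise junction recovery is well defined (real genomes
#' contain repeat-induced junction ambiguity that this generator does
#' not emulate).
#'
#' @param n_genes number of genes.
#' @param exon_len_range integer length-2 vector, uniform range of exon
#'   lengths in bases.
#' @param isoform_prob probability that a gene gets a second (exon
#'   skipping) isoform.
#' @param n_exon_range range of exon counts per gene (min >= 3 so a
#'   skippable internal exon always exists).
#' @param seed optional integer seed fixing all randomness.
#' @param snp optional list `(gene, pos, fraction)`: place one
#'   heterozygous substitution at transcript position `pos` of gene
#'   `gene`, with alternative-allele fraction `fraction`.
#' @return list of `synthetic_gene` objects with fields `exons`
#'   (character vector), `isoforms` (list of exon-index vectors) and
#'   optionally `snp`.
#' @export
generate_genes <- function(n_genes, exon_len_range = c(100L, 400L),
                           isoform_prob = 0.3, n_exon_range = c(3L, 6L),
                           seed = NULL, snp = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rnd <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  resample <- function(x, n = 1L) x[sample.int(length(x), n, replace = TRUE)]
  genes <- vector("list", n_genes)
  for (gi in seq_len(n_genes)) {
    n_ex <- resample(seq.int(n_exon_range[1L], n_exon_range[2L]))
    lens <- resample(seq.int(exon_len_range[1L], exon_len_range[2L]), n_ex)
    exons <- vapply(lens, rnd, character(1))
    isoforms <- list(seq_len(n_ex))
    if (stats::runif(1) < isoform_prob) {
      skip <- resample(seq.int(2L, n_ex - 1L))
      isoforms[[2]] <- setdiff(seq_len(n_ex), skip)
      # make the split and merge boundaries base-precise:
      # first bases of the alternative successors must differ ...
      a <- substr(exons[skip], 1L, 1L)
      b <- substr(exons[skip + 1L], 1L, 1L)
      if (a == b) {
        substr(exons[skip + 1L], 1L, 1L) <- sample(setdiff(bases, a), 1L)
      }
      # ... and last bases of the alternative predecessors too
      la <- substr(exons[skip], nchar(exons[skip]), nchar(exons[skip]))
      lb <- substr(exons[skip - 1L], nchar(exons[skip - 1L]),
                   nchar(exons[skip - 1L]))
      if (la == lb) {
        n1 <- nchar(exons[skip])
        substr(exons[skip], n1, n1) <- sample(setdiff(bases, lb), 1L)
      }
    }
    genes[[gi]] <- structure(list(exons = exons, isoforms = isoforms),
                             class = "synthetic_gene")
  }
  if (!is.null(snp)) {
    g <- genes[[snp$gene]]
    tr <- gene_transcripts(g)[[1]]
    ref <- substr(tr, snp$pos, snp$pos)
    alt <- sample(setdiff(bases, ref), 1L)
    genes[[snp$gene]]$snp <- list(pos = snp$pos, ref = ref, alt = alt,
                                  fraction = snp$fraction)
  }
  genes
}

#' Transcript sequences of a synthetic gene
#'
#' @param gene a `synthetic_gene`.
#' @return character vector, one spelled transcript per isoform.
#' @export
gene_transcripts <- function(gene) {
  vapply(gene$isoforms, function(ix) paste(gene$exons[ix], collapse = ""),
         character(1))
}

#' Ground-truth splice junctions of a gene set
#'
#' A junction is an adjacent exon pair that differs across isoforms
#' (the successor of the upstream exon, or the predecessor of the
#' downstream exon, is not the same in every isoform containing it);
#' constitutive exon boundaries compact into linear nodes and are not
#' junctions.  Each junction is reported as the 2k-mer obtained by
#' concatenating the k bases immediately left and right of the splice
#' point.
#'
#' @param genes list of `synthetic_gene` objects.
#' @param k k-mer length.
#' @return character vector of 2k-long junction strings (unique).
#' @export
truth_junctions <- function(genes, k) {
  out <- character(0)
  for (g in genes) {
    if (length(g$isoforms) < 2L) next
    pairs <- unique(do.call(rbind, lapply(g$isoforms, function(ix) {
      if (length(ix) < 2L) return(NULL)
      cbind(ix[-length(ix)], ix[-1L])
    })))
    succ <- split(pairs[, 2L], pairs[, 1L])
    pred <- split(pairs[, 1L], pairs[, 2L])
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1L]
      b <- pairs[r, 2L]
      alt <- length(unique(succ[[as.character(a)]])) > 1L ||
        length(unique(pred[[as.character(b)]])) > 1L
      if (!alt) next
      ea <- g$exons[a]
      out <- c(out, paste0(substr(ea, nchar(ea) - k + 1L, nchar(ea)),
                           substr(g$exons[b], 1L, k)))
    }
  }
  unique(out)
}

#' Sample reads from synthetic genes
#'
#' Per transcript, uniform random start positions are drawn until the
#' average nucleotide coverage target is reached; one read anchored at
#' each transcript end is always included so terminal k-mers are
#' observed.  Each base is then substituted independently with
#' probability `mismatch_pct / 100` by a uniformly chosen different
#' base.  For a gene carrying a heterozygous SNP, reads are sampled
#' from the two haplotypes in proportion to the allele fraction.
#'
#' @param genes list of `synthetic_gene` objects.
#' @param coverage target average nucleotide coverage per transcript.
#' @param read_len read length in bases.
#' @param mismatch_pct per-base substitution percentage (e.g. 0.1).
#' @param k k-mer length used for the ground-truth junction strings.
#' @param seed optional integer seed.
#' @return object of class `sim_reads`: list with `reads` (character
#'   vector), `truth` (list with `transcripts` and `junctions`).
#' @export
sample_reads <- function(genes, coverage = 20, read_len = 75,
                         mismatch_pct = 0, k = 25L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  reads <- list()
  transcripts <- character(0)
  for (g in genes) {
    trs <- gene_transcripts(g)
    transcripts <- c(transcripts, trs)
    haplos <- lapply(trs, function(tr) {
      if (is.null(g$snp)) return(stats::setNames(1, tr))
      alt_tr <- tr
      substr(alt_tr, g$snp$pos, g$snp$pos) <- g$snp$alt
      stats::setNames(c(1 - g$snp$fraction, g$snp$fraction), c(tr, alt_tr))
    })
    for (h in haplos) {
      for (hi in seq_along(h)) {
        tr <- names(h)[hi]
        cov <- coverage * h[[hi]]
        if (cov <= 0) next
        L <- nchar(tr)
        if (read_len > L) stop("read_len exceeds transcript length ", L)
        n_reads <- max(2L, ceiling(cov * L / read_len))
        starts <- c(1L, L - read_len + 1L)
        if (n_reads > 2L) {
          starts <- c(starts, sample.int(L - read_len + 1L, n_reads - 2L,
                                         replace = TRUE))
        }
        reads[[length(reads) + 1L]] <- substring(tr, starts,
                                                 starts + read_len - 1L)
      }
    }
  }
  reads <- unlist(reads, use.names = FALSE)
  if (mismatch_pct > 0 && length(reads) > 0L) {
    total <- sum(nchar(reads))
    hits <- which(stats::runif(total) < mismatch_pct / 100)
    if (length(hits) > 0L) {
      offsets <- c(0L, cumsum(nchar(reads)))
      ri <- findInterval(hits - 1L, offsets) # read index per hit base
      pos <- hits - offsets[ri]
      for (j in seq_along(hits)) {
        old <- substr(reads[ri[j]], pos[j], pos[j])
        substr(reads[ri[j]], pos[j], pos[j]) <-
          sample(setdiff(bases, old), 1L)
      }
    }
  }
  structure(
    list(reads = reads,
         truth = list(transcripts = transcripts,
                      junctions = truth_junctions(genes, k), k = k)),
    class = "sim_reads"
  )
}

#' Junction sensitivity and specificity of an assembly
#'
#' Assembly junctions are the 2k-mers spanning each edge of a
#' finalized splicing graph (last k bases of the upstream node, first
#' k of the downstream node, after overlap elimination).  A truth
#' junction counts as recovered when it matches some assembly junction
#' on either strand within `max_mm` mismatches, and vice versa for
#' specificity.  Nodes shorter than k contribute a truncated window;
#' such junctions are flagged.  With no assembly junctions at all,
#' specificity is vacuously 1 and flagged.
#'
#' @param graphs list of finalized `splicing_graph` objects.
#' @param truth either the `truth` element of [sample_reads()] output
#'   or a character vector of 2k junction strings.
#' @param k k-mer length.
#' @param max_mm maximum mismatches tolerated in a 2k comparison.
#' @return list with `sensitivity`, `specificity`, `n_truth`,
#'   `n_assembly`, `vacuous_specificity`, `short_windows`.
#' @export
evaluate_junctions <- function(graphs, truth, k, max_mm = 3L) {
  tj <- if (is.list(truth)) truth$junctions else truth
  aj_left <- character(0)
  aj_right <- character(0)
  short <- 0L
  for (sg in graphs) {
    if (nrow(sg$edges) == 0L) next
    for (i in seq_len(nrow(sg$edges))) {
      su <- sg$seqs[sg$edges$from[i]]
      sv <- sg$seqs[sg$edges$to[i]]
      l <- substr(su, max(1L, nchar(su) - k + 1L), nchar(su))
      r <- substr(sv, 1L, min(k, nchar(sv)))
      if (nchar(l) < k || nchar(r) < k) short <- short + 1L
      aj_left <- c(aj_left, l)
      aj_right <- c(aj_right, r)
    }
  }
  n_assembly <- length(aj_left)
  n_truth <- length(tj)
  jm <- function(tl, tr, l, r) {
    # mismatches between a (possibly truncated) assembly window and a
    # 2k truth string, aligned at the splice boundary
    ml <- hamming(substr(tl, nchar(tl) - nchar(l) + 1L, nchar(tl)), l)
    mr <- hamming(substr(tr, 1L, nchar(r)), r)
    ml + mr
  }
  truth_hit <- logical(n_truth)
  asm_hit <- logical(n_assembly)
  if (n_truth > 0L && n_assembly > 0L) {
    tl <- substr(tj, 1L, k)
    tr <- substr(tj, k + 1L, 2L * k)
    rc <- reverse_complement(tj)
    rl <- substr(rc, 1L, k)
    rr <- substr(rc, k + 1L, 2L * k)
    for (ti in seq_len(n_truth)) {
      for (ai in seq_len(n_assembly)) {
        mm <- min(jm(tl[ti], tr[ti], aj_left[ai], aj_right[ai]),
                  jm(rl[ti], rr[ti], aj_left[ai], aj_right[ai]))
        if (mm <= max_mm) {
          truth_hit[ti] <- TRUE
          asm_hit[ai] <- TRUE
        }
      }
    }
  }
  list(
    sensitivity = if (n_truth == 0L) NA_real_ else mean(truth_hit),
    specificity = if (n_assembly == 0L) 1.0 else mean(asm_hit),
    n_truth = n_truth,
    n_assembly = n_assembly,
    vacuous_specificity = n_assembly == 0L,
    short_windows = short
  )
}
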