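#' N50 of a set of lengths
#'
#' The largest length L in the set such that the summed length of all
#' items of length >= L reaches at least half the total length.
#'
#' @param lengths integer/numeric vector of lengths.
#' @return the N50 value; 0 for an empty input.
#' @examples
#' compute_n50(c(50, 50, 100)) # 100
#' @export
compute_n50 <- function(lengths) {
  if (length(lengths) == 0L) return(0)
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  s[which(cum >= sum(s) / 2)[1L]]
}

#' Run the full postprocessing pipeline
#'
#' Chains the stages in fixed order: graph construction (from reads)
#' or LastGraph import, coverage cutoff, tip clipping, SNP bubble
#' merging, cyclic/tangle decomposition, junction finalization, length
#' filtering, and per-library expression quantification.  All stages
#' are deterministic: identical inputs reproduce identical outputs.
#'
#' @param reads named list of read vectors / `read_library` objects /
#'   a plain character vector (one library).  Mutually exclusive with
#'   `lastgraph`.
#' @param lastgraph path to a LastGraph file to import instead of
#'   building a graph from reads.
#' @param params an [sg_params()] object (k, coverage cutoff, tip
#'   length).
#' @param snp_merge merge SNP split-then-merge bubbles (default TRUE).
#' @param min_match,max_mismatch_frac SNP bubble acceptance parameters
#'   (see [find_snp_structures()]).
#' @param quantify compute per-node per-library RPKM (requires reads).
#' @param rpkm_denominator `"assembled"` or `"total"` reads.
#' @param out_prefix optional output prefix: writes
#'   `<prefix>.fa` (annotated FASTA), `<prefix>_report.tsv`,
#'   `<prefix>_expression.tsv` and `<prefix>_paths.fa`.
#' @param max_paths cap on exported source-to-sink paths per graph.
#' @return object of class `sg_run`: list with `graphs` (retained
#'   splicing graphs), `expression` (or NULL), `decomposition`, and
#'   `report` (a one-row data.frame of run statistics).
#' @export
run_pipeline <- function(reads = NULL, lastgraph = NULL, params,
                         snp_merge = TRUE, min_match = params$k,
                         max_mismatch_frac = 0.02, quantify = !is.null(reads),
                         rpkm_denominator = c("assembled", "total"),
                         out_prefix = NULL, max_paths = 100L) {
  if (is.null(reads) == is.null(lastgraph)) {
    stop("provide exactly one of `reads` or `lastgraph`")
  }
  libraries <- if (!is.null(reads)) as_read_libraries(reads) else NULL
  g <- if (!is.null(lastgraph)) {
    parse_lastgraph(lastgraph)
  } else {
    build_graph(lapply(libraries, `[[`, "reads"), params)
  }
  initial_nodes <- n_nodes(g)
  g <- apply_coverage_cutoff(g, params$c)
  nodes_after_cutoff <- n_nodes(g)
  g <- clip_tips(g, params$tip_len)
  nodes_after_tips <- n_nodes(g)
  snp_count <- 0L
  if (snp_merge) {
    res <- merge_all_snps(g, min_match, max_mismatch_frac)
    g <- res$graph
    snp_count <- res$snp_count
  }
  decomp <- decompose_graph(g)
  graphs <- build_splicing_graphs(g, decomp)
  expr <- NULL
  if (quantify && !is.null(libraries)) {
    expr <- quantify_expression(graphs, libraries, params$k,
                                denominator = rpkm_denominator)
  }
  nn <- vapply(graphs, function(sg) length(sg$seqs), integer(1))
  maxlen <- vapply(graphs, function(sg) path_length_range(sg)$max, numeric(1))
  report <- data.frame(
    k = params$k,
    c = params$c,
    initial_nodes = initial_nodes,
    nodes_after_cutoff = nodes_after_cutoff,
    nodes_after_tips = nodes_after_tips,
    largest_tangle = decomp$largest_tangle,
    largest_scc = if (length(decomp$scc_sizes)) max(decomp$scc_sizes) else 0L,
    splicing_graphs = length(graphs),
    max_length = if (length(maxlen)) max(maxlen) else 0,
    n50 = compute_n50(maxlen),
    multi_node_graphs = sum(nn > 1L),
    max_nodes = if (length(nn)) max(nn) else 0L,
    avg_nodes = if (length(nn)) mean(nn) else 0,
    snps = snp_count
  )
  out <- structure(
    list(graphs = graphs, expression = expr, decomposition = decomp,
         report = report, k = params$k),
    class = "sg_run"
  )
  if (!is.null(out_prefix)) write_run_outputs(out, out_prefix, max_paths)
  out
}

#' @export
print.sg_run <- function(x, ...) {
  cat("splicing-graph run\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

# write the standard output files of a run
write_run_outputs <- function(run, out_prefix, max_paths = 100L) {
  write_annotated_fasta(run$graphs, paste0(out_prefix, ".fa"),
                        expr = run$expression)
  utils::write.table(run$report, paste0(out_prefix, "_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(run$expression)) {
    write_expression_tsv(run$expression, paste0(out_prefix, "_expression.tsv"))
  }
  out <- character(0)
  for (sg in run$graphs) {
    p <- spell_paths(sg, max_paths)
    if (length(p) == 0L) next
    out <- c(out, as.vector(rbind(
      sprintf(">g%d_path%d", sg$graph_id, seq_along(p)), p
    )))
  }
  writeLines(out, paste0(out_prefix, "_paths.fa"))
  invisible(out_prefix)
}
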