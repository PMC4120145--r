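test_that("a minimal LastGraph file parses to one node pair and no edges", {
  f <- tempfile()
  writeLines(c("1\t0\t5", "NODE\t1\t6\t12", "ACGTAC", "GGGTAC"), f)
  # full seq = rc(twin)[1..k-1] + fwd = GTACCC[1:4] + ACGTAC
  g <- parse_lastgraph(f)
  expect_equal(n_nodes(g), 1L)
  expect_equal(g$k, 5L)
  expect_equal(g$nodes$length_k, 6L)
  expect_equal(nchar(g$nodes$seq), 10L)
  expect_equal(substring(g$nodes$seq, 5), "ACGTAC")
  expect_equal(nrow(g$edges), 0L)
})

test_that("an ARC implies its twin arc with the same multiplicity", {
  set.seed(20)
  f <- tempfile()
  writeLines(c(
    "2\t0\t5",
    "NODE\t1\t6\t10", "ACGTAC", "CCGTAC",
    "NODE\t2\t6\t10", "TTTGCA", "AAAGCA",
    "ARC\t1\t2\t5"
  ), f)
  g <- parse_lastgraph(f)
  expect_equal(nrow(g$edges), 2L)
  expect_true(any(g$edges$from == 1 & g$edges$to == 2 & g$edges$weight == 5))
  expect_true(any(g$edges$from == -2 & g$edges$to == -1 & g$edges$weight == 5))
})

test_that("LastGraph write -> parse -> write round-trips byte-identically", {
  set.seed(21)
  gene <- skip_gene()
  g <- build_graph(c(tile_reads(gene$t1), tile_reads(gene$t2)), sg_params(15))
  f1 <- tempfile(); f2 <- tempfile()
  write_lastgraph(g, f1)
  g2 <- parse_lastgraph(f1)
  write_lastgraph(g2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(g$nodes$seq, g2$nodes$seq)
  expect_identical(g$nodes$kmer_count, g2$nodes$kmer_count)
  e1 <- g$edges[order(g$edges$from, g$edges$to), ]
  e2 <- g2$edges[order(g2$edges$from, g2$edges$to), ]
  expect_equal(unname(as.matrix(e1)), unname(as.matrix(e2)))
})

test_that("malformed LastGraph input names the offending line", {
  f <- tempfile()
  writeLines(c("banana"), f)
  expect_error(parse_lastgraph(f), "line 1")
  writeLines(c("1\t0\t5", "NODE\t1\t6\t12", "ACGTAC", "GGGTAC",
               "ARC\t1\t7\t2"), f)
  expect_error(parse_lastgraph(f), "unknown node id")
})

test_that("annotated FASTA headers follow the frozen grammar", {
  sg <- splicing_graph(1L, 25L, "ACGTACGT", singleton = TRUE)
  tab <- structure(
    data.frame(graph_id = 1L, node_id = 1L, node_length = 8L, libA_count = 50L),
    class = c("node_expression", "data.frame"),
    assembled_reads = c(libA = 1e6), total_reads = c(libA = 1e6)
  )
  # 50 reads on an 8 bp node, 1e6 assembled reads
  tab <- compute_rpkm(tab)
  f <- tempfile()
  write_annotated_fasta(list(sg), f, expr = tab)
  lines <- readLines(f)
  expect_match(lines[1], "^>g1_n1 edges:- libA=6250\\.00$")
  expect_equal(lines[2], "ACGTACGT")
})

test_that("annotated FASTA write -> parse reproduces topology and sequences", {
  set.seed(22)
  gene <- skip_gene()
  g <- build_graph(c(tile_reads(gene$t1), tile_reads(gene$t2)), sg_params(15))
  graphs <- build_splicing_graphs(g, decompose_graph(g))
  expr <- quantify_expression(graphs, list(a = tile_reads(gene$t1),
                                           b = tile_reads(gene$t2)), 15)
  f <- tempfile()
  write_annotated_fasta(graphs, f, expr = expr)
  back <- parse_annotated_fasta(f)
  expect_equal(length(back$graphs), length(graphs))
  expect_identical(back$graphs[[1]]$seqs, graphs[[1]]$seqs)
  expect_identical(back$graphs[[1]]$edges, graphs[[1]]$edges)
  expect_setequal(unique(back$rpkm$library), c("a", "b"))
  # determinism: rewriting gives identical bytes
  f2 <- tempfile()
  write_annotated_fasta(graphs, f2, expr = expr)
  expect_identical(readLines(f), readLines(f2))
})

test_that("quality trimming truncates at the first low-quality base", {
  f <- tempfile()
  write_test_fastq(f, "ACGT", list(c(30L, 30L, 10L, 30L)))
  lib <- read_libraries(list(x = f), quality_cutoff = 15)[[1]]
  expect_equal(lib$reads, "AC")
  # cutoff unset: unchanged
  lib2 <- read_libraries(list(x = f))[[1]]
  expect_equal(lib2$reads, "ACGT")
  # an all-low-quality read becomes empty but still counts in the total
  f3 <- tempfile()
  write_test_fastq(f3, c("ACGT", "GGGG"),
                   list(c(30L, 30L, 30L, 30L), c(5L, 5L, 5L, 5L)))
  lib3 <- read_libraries(list(x = f3), quality_cutoff = 15)[[1]]
  expect_equal(lib3$reads, c("ACGT", ""))
  expect_equal(lib3$total_reads, 2L)
})

test_that("mixing FASTA and FASTQ in one library errors", {
  fa <- tempfile(); fq <- tempfile()
  writeLines(c(">s1", "ACGTACGT"), fa)
  write_test_fastq(fq, "ACGTACGT")
  expect_error(read_libraries(list(x = c(fa, fq))), "mixes")
  # a pure-FASTA library loads fine (and refuses quality trimming)
  lib <- read_libraries(list(x = fa))[[1]]
  expect_equal(lib$reads, "ACGTACGT")
  expect_error(read_libraries(list(x = fa), quality_cutoff = 15), "FASTQ")
})
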