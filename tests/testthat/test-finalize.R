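test_that("deoverlap strips the k-1 prefix of every node", {
  g <- dbg(4, seqs = "ACGTACG", kmer_count = 4)
  sg <- deoverlap(g, 1L)
  expect_equal(sg$seqs, "TACG")
  expect_equal(sg$raw, "ACGTACG")
  # chain: concatenation of de-overlapped seqs = spelled path minus prefix
  set.seed(50)
  s <- rnd_seq(30)
  u <- substr(s, 1, 12); v <- substr(s, 9, 30)
  g2 <- dbg(5, seqs = c(u, v),
            edges = data.frame(from = 1, to = 2, weight = 1))
  sg2 <- deoverlap(g2, c(1L, 2L))
  expect_equal(paste(sg2$seqs, collapse = ""), substring(s, 5))
  # empty component -> empty graph
  expect_length(deoverlap(g, integer(0))$seqs, 0L)
})

test_that("merge junction adjustment moves the shared suffix onto the meeting node", {
  sg <- splicing_graph(1L, 3L, seqs = c("AAAG", "CCAG", "TTT"),
                       edges = data.frame(from = c(1L, 2L), to = c(3L, 3L)),
                       raw = c("xxAAAG", "xxCCAG", "xxTTT"))
  out <- adjust_merge_junctions(sg)
  expect_equal(out$seqs, c("AA", "CC", "AGTTT"))
  # no shared suffix: identity
  sg2 <- splicing_graph(1L, 3L, seqs = c("AAAG", "CCAT", "TTT"),
                        edges = data.frame(from = c(1L, 2L), to = c(3L, 3L)))
  expect_equal(adjust_merge_junctions(sg2)$seqs, sg2$seqs)
})

test_that("a merge whose predecessor also splits is left untouched", {
  # 1 -> 3, 1 -> 4, 2 -> 3: node 3 merges but predecessor 1 splits
  sg <- splicing_graph(1L, 3L, seqs = c("AAAG", "CCAG", "GTT", "TAA"),
                       edges = data.frame(from = c(1L, 1L, 2L),
                                          to = c(3L, 4L, 3L)))
  expect_equal(adjust_merge_junctions(sg)$seqs, sg$seqs)
})

test_that("emptied predecessors are contracted and spellings survive", {
  # predecessor 3 consists entirely of the shared suffix; a common
  # ancestor keeps it from being a source
  sg <- splicing_graph(1L, 3L, seqs = c("CC", "TTCAG", "AG", "GGG"),
                       edges = data.frame(from = c(1L, 1L, 2L, 3L),
                                          to = c(2L, 3L, 4L, 4L)),
                       raw = c("xxCC", "xxTTCAG", "xxAG", "xxGGG"))
  before <- sort(spell_paths(sg))
  out <- adjust_merge_junctions(sg)
  expect_equal(sort(spell_paths(out)), before)
  expect_length(out$seqs, 3L) # node 3 ("AG") contracted away
  expect_equal(out$seqs[3], "AGGGG")
})

test_that("source prefixes are restored exactly", {
  set.seed(51)
  gene <- skip_gene()
  g <- build_graph(c(tile_reads(gene$t1), tile_reads(gene$t2)), sg_params(15))
  d <- decompose_graph(g)
  raw_sg <- deoverlap(g, d$acyclic_components[[1]])
  fin <- restore_source_prefixes(adjust_merge_junctions(raw_sg))
  expect_setequal(spell_paths(fin), spell_raw_paths(raw_sg))
  # single node graph: identity recovery
  tr <- rnd_seq(120)
  g1 <- build_graph(tile_reads(tr), sg_params(15))
  sg1 <- restore_source_prefixes(adjust_merge_junctions(deoverlap(g1, 1L)))
  expect_equal(sg1$seqs, g1$nodes$seq)
})

test_that("junction adjustment is idempotent", {
  set.seed(52)
  for (i in 1:5) {
    gene <- skip_gene(sample(60:150, 1), sample(40:100, 1), sample(60:150, 1))
    g <- build_graph(c(tile_reads(gene$t1), tile_reads(gene$t2)), sg_params(15))
    d <- decompose_graph(g)
    for (comp in d$acyclic_components) {
      adj <- adjust_merge_junctions(deoverlap(g, comp))
      expect_identical(adjust_merge_junctions(adj), adj)
    }
  }
})

test_that("the 2k-1 minimum path length filter is a strict boundary", {
  k <- 25L
  g49 <- splicing_graph(1L, k, strrep("A", 49))
  g50 <- splicing_graph(2L, k, strrep("A", 50))
  expect_length(length_filter(list(g49), k), 0L)
  expect_length(length_filter(list(g50), k), 1L)
  # ALL paths must exceed the bound: a bubble with one short arm fails
  bub <- splicing_graph(3L, k,
                        seqs = c(strrep("C", 20), strrep("A", 10),
                                 strrep("G", 90), strrep("T", 10)),
                        edges = data.frame(from = c(1L, 1L, 2L, 3L),
                                           to = c(2L, 3L, 4L, 4L)))
  expect_equal(path_length_range(bub), list(min = 40, max = 120))
  expect_length(length_filter(list(bub), k), 0L)
})

test_that("two error-free isoforms finalize into one graph spelling both", {
  set.seed(53)
  gene <- skip_gene(200, 120, 200)
  g <- build_graph(c(tile_reads(gene$t1, 60), tile_reads(gene$t2, 60)),
                   sg_params(25))
  graphs <- build_splicing_graphs(g, decompose_graph(g))
  expect_length(graphs, 1L)
  expect_true(has_transcript_path(graphs[[1]], gene$t1))
  expect_true(has_transcript_path(graphs[[1]], gene$t2))
  # every retained graph respects the length floor by construction
  expect_gt(path_length_range(graphs[[1]])$min, 2L * 25L - 1L)
})
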