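test_that("gene generation is reproducible and respects isoform_prob", {
  g1 <- generate_genes(5, seed = 101)
  g2 <- generate_genes(5, seed = 101)
  expect_identical(g1, g2)
  g3 <- generate_genes(1, isoform_prob = 0, seed = 102)
  expect_length(g3[[1]]$isoforms, 1L)
  many <- generate_genes(100, isoform_prob = 1, seed = 103)
  expect_gte(sum(vapply(many, function(g) length(g$isoforms), integer(1)) > 1L),
             90L)
  # every isoform references valid exons, all exons >= k-sized
  for (g in many[1:10]) {
    expect_true(all(unlist(g$isoforms) %in% seq_along(g$exons)))
    expect_true(all(nchar(g$exons) >= 25L))
  }
})

test_that("read sampling hits the coverage target with exact substrings at 0% error", {
  genes <- generate_genes(3, seed = 104)
  sim <- sample_reads(genes, coverage = 20, read_len = 75, mismatch_pct = 0,
                      k = 25, seed = 105)
  trs <- sim$truth$transcripts
  doubled <- paste(trs, collapse = " ")
  ok <- vapply(sim$reads, function(r) {
    any(vapply(trs, function(t) grepl(r, t, fixed = TRUE), logical(1)))
  }, logical(1))
  expect_true(all(ok))
  # coverage arithmetic: enough reads per transcript
  expect_gte(length(sim$reads), sum(ceiling(20 * nchar(trs) / 75)))
  # determinism down to the bytes
  sim2 <- sample_reads(genes, coverage = 20, read_len = 75, mismatch_pct = 0,
                       k = 25, seed = 105)
  expect_identical(sim, sim2)
})

test_that("the realized mismatch rate matches the requested rate", {
  genes <- generate_genes(5, seed = 106)
  pct <- 0.1
  sim0 <- sample_reads(genes, coverage = 20, mismatch_pct = 0, seed = 107)
  sim1 <- sample_reads(genes, coverage = 20, mismatch_pct = pct, seed = 107)
  # same seed, same sampling: reads differ only at substituted bases
  expect_equal(length(sim0$reads), length(sim1$reads))
  n_mm <- sum(vapply(seq_along(sim0$reads), function(i) {
    sum(utf8ToInt(sim0$reads[i]) != utf8ToInt(sim1$reads[i]))
  }, numeric(1)))
  total <- sum(nchar(sim0$reads))
  p <- pct / 100
  sigma <- sqrt(total * p * (1 - p))
  expect_lt(abs(n_mm - total * p), 3 * sigma)
})

test_that("truth junctions are 2k-mers at alternative boundaries only", {
  genes <- generate_genes(10, isoform_prob = 1, seed = 108)
  tj <- truth_junctions(genes, 25)
  expect_true(all(nchar(tj) == 50L))
  # one skipping isoform yields exactly three alternative boundaries
  one <- generate_genes(1, isoform_prob = 1, n_exon_range = c(4L, 4L),
                        seed = 109)
  expect_length(truth_junctions(one, 25), 3L)
  # a single-isoform gene has none
  expect_length(truth_junctions(generate_genes(1, isoform_prob = 0,
                                               seed = 110), 25), 0L)
})

test_that("junction evaluation scores exact, mismatched and vacuous cases", {
  set.seed(111)
  gene <- skip_gene(200, 120, 200)
  reads <- c(tile_reads(gene$t1, 60), tile_reads(gene$t2, 60))
  g <- build_graph(reads, sg_params(25))
  graphs <- build_splicing_graphs(g, decompose_graph(g))
  k <- 25
  tj <- c(paste0(substr(gene$e1, 176, 200), substr(gene$e2, 1, 25)),
          paste0(substr(gene$e2, 96, 120), substr(gene$e3, 1, 25)),
          paste0(substr(gene$e1, 176, 200), substr(gene$e3, 1, 25)))
  ev <- evaluate_junctions(graphs, tj, k)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  # up to three mismatches are tolerated
  tj_mm <- tj
  for (p in c(5L, 20L, 40L)) {
    b <- substr(tj_mm[1], p, p)
    substr(tj_mm[1], p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  ev2 <- evaluate_junctions(graphs, tj_mm, k)
  expect_equal(ev2$sensitivity, 1)
  # four mismatches break the match
  p4 <- 45L
  b <- substr(tj_mm[1], p4, p4)
  substr(tj_mm[1], p4, p4) <- setdiff(c("A", "C", "G", "T"), b)[1]
  ev3 <- evaluate_junctions(graphs, tj_mm, k)
  expect_lt(ev3$sensitivity, 1)
  # no assembly junctions: specificity vacuously 1, flagged
  lone <- splicing_graph(1L, k, strrep("A", 60))
  ev4 <- evaluate_junctions(list(lone), tj, k)
  expect_equal(ev4$sensitivity, 0)
  expect_equal(ev4$specificity, 1)
  expect_true(ev4$vacuous_specificity)
})

test_that("junctions are matched on either strand", {
  set.seed(112)
  gene <- skip_gene(200, 120, 200)
  reads <- c(tile_reads(gene$t1, 60), tile_reads(gene$t2, 60))
  g <- build_graph(reads, sg_params(25))
  graphs <- build_splicing_graphs(g, decompose_graph(g))
  tj <- truth_junctions(list(structure(list(
    exons = c(gene$e1, gene$e2, gene$e3),
    isoforms = list(1:3, c(1L, 3L))
  ), class = "synthetic_gene")), 25)
  ev_f <- evaluate_junctions(graphs, tj, 25)
  ev_r <- evaluate_junctions(graphs, reverse_complement(tj), 25)
  expect_equal(ev_f$sensitivity, 1)
  expect_equal(ev_r$sensitivity, 1)
})
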