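test_that("coverage cutoff removes nodes by mean k-mer coverage", {
  set.seed(30)
  # hand-built chain A -> B -> C with k-1 overlaps at k = 5
  s <- rnd_seq(30)
  a <- substr(s, 1, 10); b <- substr(s, 7, 20); cc <- substr(s, 17, 30)
  g <- dbg(5, seqs = c(a, b, cc), kmer_count = c(60, 20, 60),
           edges = data.frame(from = c(1, 2), to = c(2, 3), weight = 1))
  validate_dbg(g, check_overlap = TRUE)
  # node B: 10 k-mers, count 20 -> mean coverage 2
  g2 <- apply_coverage_cutoff(g, 3)
  expect_equal(n_nodes(g2), 2L)
  expect_equal(nrow(g2$edges), 0L) # chain split into two components
  expect_setequal(
    g2$nodes$seq,
    vapply(c(a, cc), function(x) min(x, reverse_complement(x)), character(1),
           USE.NAMES = FALSE)
  )
  # c = 0 is the identity
  expect_identical(apply_coverage_cutoff(g, 0), g)
  # boundary arithmetic: mean 4/2 = 2 < 3 -> removed
  gb <- dbg(3, seqs = "ACGG", kmer_count = 4)
  expect_equal(n_nodes(apply_coverage_cutoff(gb, 3)), 0L)
  expect_equal(n_nodes(apply_coverage_cutoff(gb, 2)), 1L)
})

test_that("short spurs are clipped and the main path recompacts", {
  set.seed(31)
  tr <- rnd_seq(300)
  bad <- substr(tr, 80, 119)
  substr(bad, 40, 40) <- setdiff(c("A", "C", "G", "T"),
                                 substr(bad, 40, 40))[1]
  g <- build_graph(c(rep(tile_reads(tr), 2), bad), sg_params(15))
  expect_gt(n_nodes(g), 1L)
  g2 <- clip_tips(g, 2L * 15L - 1L)
  expect_equal(n_nodes(g2), 1L)
  expect_true(g2$nodes$seq %in% c(tr, reverse_complement(tr)))
  validate_dbg(g2, check_overlap = TRUE)
})

test_that("tip clipping never removes isolated nodes and respects tip_len", {
  set.seed(32)
  g <- build_graph(tile_reads(rnd_seq(60)), sg_params(15))
  expect_equal(n_nodes(clip_tips(g, 10000L)), 1L)
  # tip_len 0 is the identity
  gene <- skip_gene()
  gb <- build_graph(c(tile_reads(gene$t1), tile_reads(gene$t2)), sg_params(15))
  expect_identical(clip_tips(gb, 0L), gb)
})

make_het_reads <- function(tr, pos, alt, rl = 60L, ref_copies = 2L,
                           alt_copies = 1L) {
  alt_tr <- tr
  substr(alt_tr, pos, pos) <- alt
  c(rep(tile_reads(tr, rl), ref_copies), rep(tile_reads(alt_tr, rl), alt_copies))
}

test_that("a heterozygous SNP forms one reportable split-then-merge bubble", {
  set.seed(33)
  tr <- rnd_seq(400)
  ref <- substr(tr, 200, 200)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  g <- build_graph(make_het_reads(tr, 200, alt), sg_params(21))
  st <- find_snp_structures(g)
  expect_length(st, 1L)
  expect_length(st[[1]]$parallel_ids, 2L)
  expect_equal(st[[1]]$mismatch_positions, 21L) # SNP at the bubble centre
  # merging yields a single linear node spelling the majority allele
  res <- merge_all_snps(g)
  expect_equal(res$snp_count, 1L)
  expect_equal(n_nodes(res$graph), 1L)
  expect_true(res$graph$nodes$seq %in% c(tr, reverse_complement(tr)))
  validate_dbg(res$graph, check_overlap = TRUE)
  # idempotent on its own output
  expect_equal(merge_all_snps(res$graph)$snp_count, 0L)
})

test_that("indel bubbles and branched bubbles are never merged", {
  set.seed(34)
  tr <- rnd_seq(300)
  del <- paste0(substr(tr, 1, 150), substr(tr, 154, 300)) # 3 bp deletion
  gi <- build_graph(c(tile_reads(tr), tile_reads(del)), sg_params(21))
  expect_length(find_snp_structures(gi), 0L)
  expect_equal(merge_all_snps(gi)$snp_count, 0L)
  # a parallel node with an extra outgoing edge disqualifies the bubble
  ref <- substr(tr, 200, 200)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  g <- build_graph(make_het_reads(tr, 200, alt), sg_params(21))
  st <- find_snp_structures(g)
  expect_length(st, 1L)
  p <- st[[1]]$parallel_ids[1]
  ps <- node_seq(g, p)
  extra <- paste0(substring(ps, nchar(ps) - 19L), rnd_seq(5)) # k-1 overlap
  g$nodes <- rbind(g$nodes, data.frame(
    id = max(g$nodes$id) + 1L, seq = extra, kmer_count = 1,
    length_k = nchar(extra) - 20L
  ))
  g$edges <- rbind(g$edges, data.frame(from = p, to = max(g$nodes$id), weight = 1))
  g <- splicegraphr:::close_twin_edges(g)
  expect_length(find_snp_structures(g), 0L)
})

test_that("two well-separated SNPs merge as successive bubbles", {
  set.seed(35)
  tr <- rnd_seq(500)
  alt_of <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  alt_tr <- tr
  substr(alt_tr, 150, 150) <- alt_of(substr(tr, 150, 150))
  substr(alt_tr, 350, 350) <- alt_of(substr(tr, 350, 350))
  reads <- c(rep(tile_reads(tr, 60), 2), tile_reads(alt_tr, 60))
  g <- build_graph(reads, sg_params(21))
  expect_gt(n_nodes(g), 1L)
  res <- merge_all_snps(g)
  expect_equal(res$snp_count, 2L)
  expect_equal(n_nodes(res$graph), 1L)
  expect_true(res$graph$nodes$seq %in% c(tr, reverse_complement(tr)))
})

test_that("consensus is the coverage-weighted majority with deterministic ties", {
  # direct check on the consensus kernel: equal-length arms, controlled weights
  g <- dbg(3, seqs = c("ACGTA", "ACCTA"), kmer_count = c(9, 3))
  expect_equal(splicegraphr:::consensus_sequence(g, c(1L, 2L)), "ACGTA")
  g2 <- dbg(3, seqs = c("ACGTA", "ACCTA"), kmer_count = c(3, 3))
  # tie at the middle column -> smaller base C
  expect_equal(splicegraphr:::consensus_sequence(g2, c(1L, 2L)), "ACCTA")
  # merging a balanced bubble is still deterministic end to end
  set.seed(36)
  tr <- rnd_seq(300)
  alt_tr <- tr
  substr(alt_tr, 150, 150) <- setdiff(c("A", "C", "G", "T"),
                                      substr(tr, 150, 150))[1]
  reads <- c(tile_reads(tr, 60), tile_reads(alt_tr, 60))
  r1 <- merge_all_snps(build_graph(reads, sg_params(21)))
  r2 <- merge_all_snps(build_graph(reads, sg_params(21)))
  expect_equal(r1$snp_count, 1L)
  expect_identical(r1$graph$nodes$seq, r2$graph$nodes$seq)
})
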