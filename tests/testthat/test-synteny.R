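ranked_genome <- function(n, seq_id = "chr1", genome = "G") {
  data.frame(gene_id = sprintf("%s_%s_g%03d", genome, seq_id, seq_len(n)),
             genome_id = genome, seq_id = seq_id,
             start = seq_len(n) * 10000L, end = seq_len(n) * 10000L + 3000L,
             stringsAsFactors = FALSE)
}

test_that("two identical gene runs chain into a single block", {
  g1 <- ranked_genome(10, "chr1")
  g2 <- ranked_genome(10, "chr2")
  genes <- gene_ranks(rbind(g1, g2))
  pairs <- data.frame(gene_a = g1$gene_id, gene_b = g2$gene_id, score = 100)
  res <- find_collinear_blocks(genes, pairs)
  expect_equal(nrow(res$blocks), 1L)
  expect_equal(res$blocks$n_anchors, 10L)
  expect_equal(res$blocks$orientation, "same")
  # anchors strictly monotone on both axes
  expect_true(all(diff(res$anchors$rank_a) > 0))
  expect_true(all(diff(res$anchors$rank_b) > 0))
})

test_that("runs below min_anchors or with oversized gaps yield no block", {
  g1 <- ranked_genome(10, "chr1")
  g2 <- ranked_genome(10, "chr2")
  genes <- gene_ranks(rbind(g1, g2))
  pairs4 <- data.frame(gene_a = g1$gene_id[1:4], gene_b = g2$gene_id[1:4],
                       score = 100)
  expect_equal(nrow(find_collinear_blocks(genes, pairs4)$blocks), 0L)
  expect_equal(nrow(find_collinear_blocks(genes, pairs4,
                                          min_anchors = 4)$blocks), 1L)
  # a rank gap beyond max_gap splits the chain
  g3 <- ranked_genome(80, "chr3")
  g4 <- ranked_genome(80, "chr4")
  genes2 <- gene_ranks(rbind(g3, g4))
  idx <- c(1:5, 40:44)                     # 35-rank jump
  pairs <- data.frame(gene_a = g3$gene_id[idx], gene_b = g4$gene_id[idx],
                      score = 100)
  res <- find_collinear_blocks(genes2, pairs)
  expect_equal(sort(res$blocks$n_anchors), c(5L, 5L))
})

test_that("inverted segments are chained with decreasing second ranks", {
  g1 <- ranked_genome(10, "chr1")
  g2 <- ranked_genome(10, "chr2")
  genes <- gene_ranks(rbind(g1, g2))
  pairs <- data.frame(gene_a = g1$gene_id, gene_b = rev(g2$gene_id),
                      score = 100)
  res <- find_collinear_blocks(genes, pairs)
  expect_equal(res$blocks$orientation, "inverted")
  expect_equal(res$blocks$n_anchors, 10L)
})

test_that("greedy chaining matches the exhaustive oracle on small instances", {
  set.seed(606)
  for (rep in 1:30) {
    n <- sample(4:10, 1)
    g1 <- ranked_genome(30, "chr1")
    g2 <- ranked_genome(30, "chr2")
    genes <- gene_ranks(rbind(g1, g2))
    ra <- sample(30, n); rb <- sample(30, n)
    pairs <- data.frame(gene_a = g1$gene_id[ra], gene_b = g2$gene_id[rb],
                        score = 100)
    max_gap <- sample(c(5, 10, 25), 1)
    res <- find_collinear_blocks(genes, pairs, min_anchors = 1,
                                 max_gap = max_gap)
    got <- max(res$blocks$n_anchors)
    expect_equal(got, oracle_max_chain(ra, rb, max_gap))
  }
})

test_that("duplication-type calls recover simulator truth", {
  sim <- simulate_synteny(seed = 47)
  ga <- sim$genes[sim$genes$genome_id == "genomeA", ]
  blocks <- find_collinear_blocks(ga, sim$pairs_within)
  nbs_a <- ga[ga$gene_id %in% sim$nbs_ids, ]
  res <- classify_duplication_types(nbs_a, sim$pairs_within, blocks)
  m <- merge(res$calls, sim$truth, by = "gene_id")
  expect_equal(nrow(m), nrow(sim$truth))
  expect_equal(m$type.x, m$type.y)
  # input order never changes calls
  perm <- nbs_a[sample(nrow(nbs_a)), ]
  res2 <- classify_duplication_types(perm, sim$pairs_within, blocks)
  m2 <- merge(res$calls, res2$calls, by = "gene_id")
  expect_equal(m2$type.x, m2$type.y)
  # summary percentages cover all genes
  expect_equal(sum(res$summary$n), nrow(nbs_a))
  expect_equal(sum(res$summary$pct), 100, tolerance = 0.3)
})

test_that("adjacent homologs with no block are tandem on both sides", {
  g <- gene_ranks(ranked_genome(10, "chr1"))
  nbs <- g[4:5, ]
  pairs <- data.frame(gene_a = g$gene_id[4], gene_b = g$gene_id[5], score = 90)
  empty_blocks <- find_collinear_blocks(g, pairs[0, ])
  res <- classify_duplication_types(nbs, pairs, empty_blocks)
  expect_equal(res$calls$type, c("tandem", "tandem"))
})

test_that("syntenic NBS pairs carry the correct cluster/singleton forms", {
  sim <- simulate_synteny(seed = 58)
  blocks <- find_collinear_blocks(sim$genes, sim$pairs_cross)
  ga <- sim$genes[sim$genes$genome_id == "genomeA", ]
  gb <- sim$genes[sim$genes$genome_id == "genomeB", ]
  cla <- assign_clusters(ga[ga$gene_id %in% sim$nbs_ids & !is.na(ga$seq_id), ])
  clb <- assign_clusters(gb[gb$gene_id %in% sim$nbs_ids, ])
  syn <- syntenic_nbs_pairs(blocks, sim$genes, sim$nbs_ids, cla, clb)
  m <- merge(syn$pairs, sim$truth_forms, by = c("gene_a", "gene_b"))
  expect_equal(nrow(m), nrow(sim$truth_forms))
  expect_equal(m$form.x, m$form.y)
  expect_true(all(c("singleton-to-singleton", "cluster-to-cluster") %in%
                  syn$pairs$form))
  # NBS genes whose ortholog was deleted are presence/absence polymorphic
  expect_equal(unname(syn$n_private["genomeA"]), 2L)
})

test_that("a genome without duplication features yields no within blocks", {
  sim <- simulate_synteny(n_tandem_arrays = 0, n_segmental_blocks = 0,
                          n_dispersed = 0, n_unanchored = 0,
                          n_missing_orthologs = 0, seed = 3)
  ga <- sim$genes[sim$genes$genome_id == "genomeA", ]
  blocks <- find_collinear_blocks(ga, sim$pairs_within)
  expect_equal(nrow(blocks$blocks), 0L)
})
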