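ranks_ab <- function(ra, rb) {
  data.frame(
    gene_id = c(sprintf("a%02d", seq_along(ra)), sprintf("b%02d", seq_along(rb))),
    chromosome = rep(c("A01", "B01"), c(length(ra), length(rb))),
    rank = c(ra, rb), stringsAsFactors = FALSE)
}

pairs_ab <- function(n) {
  data.frame(gene_a = sprintf("a%02d", 1:n), gene_b = sprintf("b%02d", 1:n),
             stringsAsFactors = FALSE)
}

test_that("consecutive anchors chain into one block; reversal inverts it", {
  ranks <- ranks_ab(1:6, 11:16)
  blocks <- chain_collinear_anchors(pairs_ab(6), ranks, min_anchors = 5, max_gap = 25)
  expect_identical(length(unique(blocks$block_id)), 1L)
  expect_identical(nrow(blocks), 6L)
  expect_identical(unique(blocks$orientation), "same")
  validate_blocks(blocks)

  ranks$rank[7:12] <- 16:11 # reverse the b side
  blocks <- chain_collinear_anchors(pairs_ab(6), ranks, min_anchors = 5, max_gap = 25)
  expect_identical(nrow(blocks), 6L)
  expect_identical(unique(blocks$orientation), "inverted")
  validate_blocks(blocks)

  # scattered pairs across chromosome pairs never reach min_anchors
  sc_ranks <- data.frame(gene_id = sprintf("g%d", 1:8),
                         chromosome = sprintf("c%02d", 1:8), rank = 1L)
  sc_pairs <- data.frame(gene_a = sprintf("g%d", 1:4), gene_b = sprintf("g%d", 5:8))
  expect_identical(nrow(chain_collinear_anchors(sc_pairs, sc_ranks)), 0L)
  expect_error(chain_collinear_anchors(data.frame(gene_a = "x", gene_b = "g1"),
                                       sc_ranks), "without rank")
})

test_that("chaining is invariant to input pair order", {
  cfg <- sim_config(n_proteins = 120, seed = 31, n_tandem = 4, n_blocks = 5,
                    block_size = 6, n_dispersed = 4)
  g <- generate_genome_layout(cfg, sprintf("g%03d", 1:120))
  b1 <- chain_collinear_anchors(g$pairs, g$layout)
  set.seed(1)
  b2 <- chain_collinear_anchors(g$pairs[sample(nrow(g$pairs)), ], g$layout)
  expect_identical(b1, b2)
})

test_that("chained block sizes agree with exhaustive enumeration on small instances", {
  set.seed(77)
  for (k in 1:100) {
    n <- sample(4:10, 1)
    ra <- sample(1:40, n)
    rb <- sample(1:40, n)
    ranks <- ranks_ab(ra, rb)
    max_gap <- sample(c(5L, 10L, 25L), 1)
    oracle <- oracle_max_chain(ra, rb, max_gap)
    blocks <- chain_collinear_anchors(pairs_ab(n), ranks, min_anchors = 2L,
                                      max_gap = max_gap)
    got <- if (nrow(blocks) == 0L) 1L else max(table(blocks$block_id))
    if (oracle >= 2L) {
      expect_identical(as.integer(got), as.integer(oracle))
      validate_blocks(blocks, min_anchors = 2L, max_gap = max_gap)
    } else {
      expect_identical(nrow(blocks), 0L)
    }
  }
})

test_that("classify_duplication: tandem beats segmental, dispersed is the fallback", {
  ranks <- rbind(ranks_ab(1:6, 11:16),
                 data.frame(gene_id = c("t1", "t2", "d1"), chromosome = "A01",
                            rank = c(30L, 31L, 500L)))
  pairs <- rbind(pairs_ab(6),
                 data.frame(gene_a = "t1", gene_b = "t2"),
                 data.frame(gene_a = "a01", gene_b = "d1"))
  blocks <- chain_collinear_anchors(pairs, ranks)
  ev <- classify_duplication(pairs, blocks, ranks)
  expect_identical(ev$label[ev$gene_a == "t1"], "tandem")
  expect_identical(ev$label[ev$gene_a == "a01" & ev$gene_b == "b01"], "segmental")
  expect_false(is.na(ev$block_id[ev$gene_a == "a01" & ev$gene_b == "b01"]))
  # same chromosome, rank gap 499, no block -> dispersed
  expect_identical(ev$label[ev$gene_b == "d1"], "dispersed")

  # pairs that are both adjacent and block anchors stay tandem: a same-
  # chromosome ladder (r, r+1) chains into a block, yet every pair is adjacent
  ranks2 <- data.frame(gene_id = sprintf("g%d", 1:6), chromosome = "A01",
                       rank = 1:6, stringsAsFactors = FALSE)
  pairs2 <- data.frame(gene_a = sprintf("g%d", 1:5), gene_b = sprintf("g%d", 2:6))
  blocks2 <- chain_collinear_anchors(pairs2, ranks2, min_anchors = 5, max_gap = 25)
  expect_identical(nrow(blocks2), 5L) # the ladder is a valid collinear chain
  ev2 <- classify_duplication(pairs2, blocks2, ranks2, tandem_max_gap = 1L)
  expect_true(all(ev2$label == "tandem"))
})

test_that("planted layouts are recovered exactly at zero noise", {
  cfg <- sim_config(n_proteins = 197, seed = 41)
  g <- generate_genome_layout(cfg)
  blocks <- chain_collinear_anchors(g$pairs, g$layout)
  validate_blocks(blocks)
  ev <- classify_duplication(g$pairs, blocks, g$layout)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  truth <- g$truth
  got <- ev$label[match(key(truth$gene_a, truth$gene_b), key(ev$gene_a, ev$gene_b))]
  expect_identical(got, truth$label)
  expect_identical(sum(ev$label == "tandem"), 7L)
  expect_identical(sum(ev$label == "segmental"), 53L)
  # planted orientations recovered block by block
  binfo <- unique(blocks[, c("block_id", "chrom_a", "chrom_b", "orientation")])
  tinfo <- unique(truth[truth$label == "segmental", c("block", "orientation")])
  expect_identical(sum(binfo$orientation == "inverted"),
                   sum(tinfo$orientation == "inverted"))
})

test_that("inter-genome collinearity finds both subgenome copies of a diploid", {
  # reference diploid: 12 genes on one chromosome; tetraploid: two subgenomes
  # with the same gene order
  ref <- sprintf("r%02d", 1:12)
  ga <- sprintf("ta%02d", 1:12)
  gd <- sprintf("td%02d", 1:12)
  ranks <- data.frame(
    gene_id = c(ref, ga, gd),
    genome = rep(c("ref", "tet", "tet"), each = 12),
    chromosome = rep(c("c1", "A01", "D01"), each = 12),
    rank = rep(1:12, 3), stringsAsFactors = FALSE)
  pairs <- data.frame(gene_a = c(ref, ref), gene_b = c(ga, gd))
  res <- inter_genome_collinearity(ranks, pairs)
  expect_identical(sort(unique(res$blocks$block_id)), c("block001", "block002"))
  expect_identical(res$pair_counts$n_collinear_pairs, 24L)
  refp <- res$gene_partners[res$gene_partners$genome == "ref", ]
  expect_identical(nrow(refp), 12L)
  expect_true(all(refp$partner_genomes == "tet"))
  # every reference gene is collinear with both subgenome copies
  per_gene <- table(c(res$blocks$gene_a, res$blocks$gene_b))
  expect_true(all(per_gene[ref] == 2L))

  # disjoint gene sets: nothing to chain
  none <- inter_genome_collinearity(ranks, pairs[0, , drop = FALSE])
  expect_identical(nrow(none$blocks), 0L)
})
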