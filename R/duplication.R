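# duplication: classify homolog pairs as tandem, segmental (supported by a
# collinear block of anchored gene pairs), or dispersed. Collinear blocks are
# found by sparse dynamic programming over gene-order ranks, the standard
# microsynteny chaining idea (anchors strictly monotonic on both chromosomes,
# bounded rank gaps), applied per chromosome pair.

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# longest gap-bounded chain among anchors (ra ascending); dir = +1 for
# b-ranks strictly increasing, -1 for strictly decreasing. O(n^2) DP.
chain_dp <- function(ra, rb, dir, max_gap) {
  n <- length(ra)
  len <- rep(1L, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (ra[i] <= ra[j]) next
      if (ra[i] - ra[j] > max_gap) next
      db <- dir * (rb[i] - rb[j])
      if (db <= 0L || db > max_gap) next
      if (len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  best <- which.max(len)
  chain <- integer(0)
  k <- best
  while (!is.na(k)) {
    chain <- c(k, chain)
    k <- prev[k]
  }
  list(length = len[best], chain = chain)
}

#' Chain homolog pairs into collinear blocks
#'
#' For each chromosome pair, anchors (homolog pairs with gene-order ranks on
#' both chromosomes) are chained so that ranks are strictly increasing on the
#' first chromosome and strictly increasing ("same" orientation) or strictly
#' decreasing ("inverted") on the second, with per-step rank gaps bounded by
#' `max_gap` on both axes. Maximal non-overlapping chains with at least
#' `min_anchors` anchors are emitted longest first; each anchor belongs to at
#' most one block. Output is invariant to the order of the input pairs.
#'
#' @param pairs data frame with columns `gene_a`, `gene_b`.
#' @param ranks data frame with columns `gene_id`, `chromosome`, `rank`
#'   (from [gene_ranks()]).
#' @param min_anchors minimum anchors per block (default 5).
#' @param max_gap maximum rank gap between consecutive anchors (default 25).
#' @return data frame, one row per anchor: `block_id`, `chrom_a`, `chrom_b`,
#'   `orientation`, `gene_a`, `gene_b`, `rank_a`, `rank_b`.
#' @export
chain_collinear_anchors <- function(pairs, ranks, min_anchors = 5L, max_gap = 25L) {
  if (nrow(pairs) == 0L) return(empty_block_table())
  known <- ranks$gene_id
  unk <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), known)
  abort_if(length(unk) > 0L, "gene(s) without rank: ", paste(unk, collapse = ", "))
  chrom <- stats::setNames(ranks$chromosome, ranks$gene_id)
  rnk <- stats::setNames(ranks$rank, ranks$gene_id)

  # canonicalize: a-side is the lexicographically smaller (chromosome, rank)
  ca <- chrom[pairs$gene_a]; cb <- chrom[pairs$gene_b]
  ra <- rnk[pairs$gene_a]; rb <- rnk[pairs$gene_b]
  flip <- (cb < ca) | (cb == ca & rb < ra)
  anch <- data.frame(
    gene_a = ifelse(flip, pairs$gene_b, pairs$gene_a),
    gene_b = ifelse(flip, pairs$gene_a, pairs$gene_b),
    chrom_a = ifelse(flip, cb, ca), chrom_b = ifelse(flip, ca, cb),
    rank_a = as.integer(ifelse(flip, rb, ra)),
    rank_b = as.integer(ifelse(flip, ra, rb)),
    stringsAsFactors = FALSE
  )
  anch <- anch[order(anch$chrom_a, anch$chrom_b, anch$rank_a, anch$rank_b), ]

  blocks <- list()
  for (key in unique(paste(anch$chrom_a, anch$chrom_b, sep = "\r"))) {
    sub <- anch[paste(anch$chrom_a, anch$chrom_b, sep = "\r") == key, ]
    repeat {
      if (nrow(sub) < min_anchors) break
      fwd <- chain_dp(sub$rank_a, sub$rank_b, +1L, max_gap)
      rev <- chain_dp(sub$rank_a, sub$rank_b, -1L, max_gap)
      use_fwd <- fwd$length >= rev$length
      best <- if (use_fwd) fwd else rev
      if (best$length < min_anchors) break
      blk <- sub[best$chain, ]
      blk$orientation <- if (use_fwd) "same" else "inverted"
      blocks[[length(blocks) + 1L]] <- blk
      sub <- sub[-best$chain, ]
    }
  }
  if (length(blocks) == 0L) return(empty_block_table())
  blocks <- blocks[order(vapply(blocks, nrow, integer(1)), decreasing = TRUE)]
  out <- do.call(rbind, Map(function(b, i) {
    cbind(data.frame(block_id = sprintf("block%03d", i), stringsAsFactors = FALSE),
          b[, c("chrom_a", "chrom_b", "orientation", "gene_a", "gene_b",
                "rank_a", "rank_b")])
  }, blocks, seq_along(blocks)))
  row.names(out) <- NULL
  out
}

empty_block_table <- function() {
  data.frame(block_id = character(), chrom_a = character(), chrom_b = character(),
             orientation = character(), gene_a = character(), gene_b = character(),
             rank_a = integer(), rank_b = integer(), stringsAsFactors = FALSE)
}

#' Validate a block table against the collinearity invariants
#'
#' Checks, per block: >= `min_anchors` anchors, strictly monotonic ranks on
#' both chromosomes (orientation-consistent on b), and per-step gaps
#' <= `max_gap`.
#'
#' @param blocks block table from [chain_collinear_anchors()].
#' @inheritParams chain_collinear_anchors
#' @return TRUE (invisibly) or an error describing the violated invariant.
#' @export
validate_blocks <- function(blocks, min_anchors = 5L, max_gap = 25L) {
  for (id in unique(blocks$block_id)) {
    b <- blocks[blocks$block_id == id, ]
    abort_if(nrow(b) < min_anchors, id, ": fewer than min_anchors anchors")
    da <- diff(b$rank_a)
    db <- diff(b$rank_b)
    abort_if(any(da <= 0L), id, ": rank_a not strictly increasing")
    abort_if(any(da > max_gap) || any(abs(db) > max_gap), id, ": gap exceeds max_gap")
    ok <- if (b$orientation[1] == "same") all(db > 0L) else all(db < 0L)
    abort_if(!ok, id, ": rank_b not strictly monotonic for its orientation")
  }
  invisible(TRUE)
}

#' Classify duplication events
#'
#' Tandem: same chromosome and rank gap <= `tandem_max_gap` (checked first,
#' so an adjacent pair inside a block still counts as tandem). Segmental: the
#' pair is an anchor of a collinear block. Otherwise dispersed.
#'
#' @param pairs data frame with columns `gene_a`, `gene_b`.
#' @param blocks block table from [chain_collinear_anchors()].
#' @param ranks rank table (see [gene_ranks()]).
#' @param tandem_max_gap maximum rank gap for tandem ("adjacent" = 1).
#' @return data frame: `gene_a`, `gene_b`, `label`, `block_id` (NA unless
#'   segmental).
#' @export
classify_duplication <- function(pairs, blocks, ranks, tandem_max_gap = 1L) {
  chrom <- stats::setNames(ranks$chromosome, ranks$gene_id)
  rnk <- stats::setNames(ranks$rank, ranks$gene_id)
  bkey <- pair_key(blocks$gene_a, blocks$gene_b)
  bid <- stats::setNames(blocks$block_id, bkey)
  key <- pair_key(pairs$gene_a, pairs$gene_b)
  tandem <- chrom[pairs$gene_a] == chrom[pairs$gene_b] &
    abs(rnk[pairs$gene_a] - rnk[pairs$gene_b]) <= tandem_max_gap
  segmental <- key %in% bkey
  label <- ifelse(tandem, "tandem", ifelse(segmental, "segmental", "dispersed"))
  data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b, label = label,
             block_id = ifelse(!tandem & segmental, bid[key], NA_character_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-genome collinearity
#'
#' Applies the same chaining to homolog pairs between genomes. Chromosomes
#' are namespaced as "genome:chromosome" so blocks never mix genomes
#' incorrectly, and per-genome-pair collinear counts plus per-gene partner
#' coverage (which partner genomes each gene is collinear with) are reported.
#'
#' @param ranks data frame with columns `gene_id`, `genome`, `chromosome`,
#'   `rank`; gene ids must be unique across genomes.
#' @param pairs data frame with columns `gene_a`, `gene_b` (cross-genome
#'   homolog pairs).
#' @inheritParams chain_collinear_anchors
#' @return list with `blocks`, `pair_counts` (data frame `genome_a`,
#'   `genome_b`, `n_collinear_pairs`), and `gene_partners` (data frame
#'   `gene_id`, `genome`, `n_partner_genomes`, `partner_genomes`).
#' @export
inter_genome_collinearity <- function(ranks, pairs, min_anchors = 5L, max_gap = 25L) {
  abort_if(anyDuplicated(ranks$gene_id) > 0L,
           "gene ids must be unique across genomes")
  nsranks <- data.frame(gene_id = ranks$gene_id,
                        chromosome = paste(ranks$genome, ranks$chromosome, sep = ":"),
                        rank = ranks$rank, stringsAsFactors = FALSE)
  blocks <- chain_collinear_anchors(pairs, nsranks, min_anchors, max_gap)
  genome_of <- stats::setNames(ranks$genome, ranks$gene_id)
  if (nrow(blocks) > 0L) {
    ga <- genome_of[blocks$gene_a]
    gb <- genome_of[blocks$gene_b]
    glo <- pmin(ga, gb); ghi <- pmax(ga, gb)
    tab <- table(paste(glo, ghi, sep = "\r"))
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    pair_counts <- data.frame(
      genome_a = vapply(parts, `[`, character(1), 1L),
      genome_b = vapply(parts, `[`, character(1), 2L),
      n_collinear_pairs = as.integer(tab), stringsAsFactors = FALSE
    )
    gene <- c(blocks$gene_a, blocks$gene_b)
    partner <- c(gb, ga)
    agg <- tapply(partner, gene, function(x) sort(unique(x)))
    gene_partners <- data.frame(
      gene_id = names(agg),
      genome = genome_of[names(agg)],
      n_partner_genomes = vapply(agg, length, integer(1)),
      partner_genomes = vapply(agg, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    pair_counts <- data.frame(genome_a = character(), genome_b = character(),
                              n_collinear_pairs = integer())
    gene_partners <- data.frame(gene_id = character(), genome = character(),
                                n_partner_genomes = integer(),
                                partner_genomes = character())
  }
  list(blocks = blocks, pair_counts = pair_counts, gene_partners = gene_partners)
}
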