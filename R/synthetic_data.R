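# synthetic_data: generate every input the pipeline consumes, with planted
# ground truth, so all stages are testable without downloads.
#
# The generated world is deliberately "clean": background residues are drawn
# by rejection so that no spurious N-x7-R/K anchor, no spurious signature
# template match, and no spurious zipper registration can arise. That is what
# makes 100% recovery of planted truth a meaningful end-to-end test; the
# generator does not emulate sequencing noise or template drift.

SAFE_UNCHARGED <- c("A", "S", "T", "G", "H", "Y", "W", "P")
A_FILLER <- c("Q", "A", "S", "T")
CHARGED <- c("K", "R", "D", "E")

#' Simulation configuration
#'
#' Defaults are the conditions the characterized cotton family shows: 197
#' members mixed over the 10 signature groups in the published proportions,
#' zipper lengths uniform on 2..9 heptads, a-position Asn frequencies of
#' 58.9% / 57.4% in heptads 2 and 5 (0.11 elsewhere, which makes the pooled
#' Asn-at-a frequency 0.25 under the uniform length mix), 59% Leu at d, 16%
#' charged residues at a, 42.64% interactive g<->e' pairs at the first pair
#' position decaying sharply afterwards, 7 tandem and 10 collinear-block
#' duplications on 10 chromosomes, and a 197 x 9 FPKM matrix with 185 / 76
#' expressed-in-any / expressed-in-all genes.
#'
#' @param n_proteins number of family members.
#' @param group_mix named proportions over the 10 signature groups (sum 1).
#' @param heptad_weights sampling weights for zipper lengths 2..9.
#' @param asn_a_per_heptad probability of Asn at a, per heptad index 1..9.
#' @param charged_a probability that a non-Asn a residue is charged.
#' @param leu_at_d probability of Leu at d (the rest is I/V/M/F).
#' @param d_alternatives sampling weights of I, V, M, F at non-Leu d slots.
#' @param interactive_per_pair probability that g<->e' pair h is charged on
#'   both sides (recycled to the last value for long zippers).
#' @param flank_range,tail_range N-/C-terminal flank length ranges.
#' @param n_chromosomes,n_tandem,n_blocks,block_size,n_dispersed genome
#'   layout plan; `block_size` may be a vector of per-block anchor counts
#'   (recycled to `n_blocks`; the default plants 53 segmental anchor pairs).
#' @param genes_per_chromosome capacity cap per chromosome.
#' @param inverted_fraction fraction of collinear blocks planted inverted.
#' @param tissues tissue (sample) names of the FPKM atlas.
#' @param n_expressed_any,n_expressed_all planted expressed-gene counts
#'   (NULL: the survey proportions 185/197 and 76/197 scaled to `n_proteins`).
#' @param n_high_pref named counts of highly-expressed tissue-preferential
#'   genes per tissue (NULL: 21 root / 23 leaf scaled to `n_proteins`).
#' @param n_up,n_down planted drought up-/down-regulated gene counts (NULL:
#'   20 of 197 scaled).
#' @param drought_fc planted fold change for drought genes.
#' @param noise_sd log-scale s.d. of multiplicative noise on drought genes.
#' @param seed mandatory integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(
    n_proteins = 197L,
    group_mix = c(A = 41, B = 1, C = 13, D = 32, E = 8, `F/K` = 10,
                  `G/M/S` = 62, H = 2, I = 25, J = 2) / 196,
    heptad_weights = rep(1, 8),
    asn_a_per_heptad = c(0.11, 0.589, 0.11, 0.11, 0.574, 0.11, 0.11, 0.11, 0.11),
    charged_a = 0.16 / 0.75,
    leu_at_d = 0.59,
    d_alternatives = c(I = 0.15, V = 0.12, M = 0.08, F = 0.06),
    interactive_per_pair = c(0.4264, 0.25, 0.15, 0.10, 0.08, 0.06, 0.05, 0.04),
    flank_range = c(8L, 40L),
    tail_range = c(5L, 30L),
    n_chromosomes = 10L,
    genes_per_chromosome = NULL,
    n_tandem = 7L,
    n_blocks = 10L,
    block_size = c(8L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L),
    inverted_fraction = 0.3,
    n_dispersed = 10L,
    tissues = c("root", "stem", "leaf", "petal", "anther", "stigma", "ovule",
                "seed", "fiber"),
    n_expressed_any = NULL,
    n_expressed_all = NULL,
    n_high_pref = NULL,
    n_up = NULL,
    n_down = NULL,
    drought_fc = 4,
    noise_sd = 0.25,
    seed) {
  abort_if(missing(seed), "sim_config(): seed is mandatory")
  abort_if(abs(sum(group_mix) - 1) > 1e-8, "group_mix must sum to 1")
  abort_if(any(asn_a_per_heptad < 0 | asn_a_per_heptad > 1) ||
             any(interactive_per_pair < 0 | interactive_per_pair > 1),
           "planted frequencies must lie in [0, 1]")
  cfg <- as.list(environment())
  if (is.null(cfg$genes_per_chromosome)) {
    cfg$genes_per_chromosome <- as.integer(ceiling(n_proteins / n_chromosomes) + 12L)
  }
  # expression plan defaults are the family-survey proportions, scaled to n
  # (exactly 185 / 76 / 21 / 23 / 20 at the default n of 197)
  n <- n_proteins
  if (is.null(cfg$n_expressed_any)) cfg$n_expressed_any <- as.integer(round(n * 185 / 197))
  if (is.null(cfg$n_expressed_all)) cfg$n_expressed_all <- as.integer(round(n * 76 / 197))
  if (is.null(cfg$n_high_pref)) {
    cfg$n_high_pref <- c(root = as.integer(round(n * 21 / 197)),
                         leaf = as.integer(round(n * 23 / 197)))
  }
  if (is.null(cfg$n_up)) cfg$n_up <- max(1L, as.integer(round(n * 20 / 197)))
  if (is.null(cfg$n_down)) cfg$n_down <- max(1L, as.integer(round(n * 20 / 197)))
  structure(cfg, class = "sim_config")
}

# background alphabets, computed once per template table ---------------------

# letters that must never appear at a '*' column: any other template's fixed
# letter there, Asn anywhere (no spurious basic anchors), hydrophobic
# interface letters downstream of the R/K anchor (no spurious zipper anchors)
window_background_sets <- function(templates) {
  excl <- vector("list", SIGNATURE_WIDTH)
  for (j in seq_len(SIGNATURE_WIDTH)) {
    fixed <- unlist(lapply(templates$columns, `[[`, j))
    ex <- unique(c(fixed, "N"))
    if (j > RK_COLUMN) ex <- c(ex, HYDROPHOBIC_D)
    excl[[j]] <- setdiff(AA20, ex)
  }
  excl
}

draw_from <- function(alphabet, n) {
  alphabet[sample.int(length(alphabet), n, replace = TRUE)]
}

# one protein, using the ambient RNG stream -----------------------------------
generate_protein_core <- function(id, group, n_heptads, cfg, templates, bg_sets,
                                  flank_len = NULL, tail_len = NULL) {
  k <- match(group, templates$group)
  abort_if(is.na(k), "unknown group: ", group)
  abort_if(n_heptads < 2L || n_heptads > 9L, "n_heptads must be in 2..9")
  cols <- templates$columns[[k]]

  # 30-column signature window: fixed letters exact ('[XY]' -> first letter),
  # anchors forced canonical (this is the tolerated override for groups whose
  # template letter contradicts the N-x7-R/K anchor), stars from background
  win <- character(SIGNATURE_WIDTH)
  for (j in seq_len(SIGNATURE_WIDTH)) {
    win[j] <- if (is.null(cols[[j]])) draw_from(bg_sets[[j]], 1L) else cols[[j]][1L]
  }
  win[N_COLUMN] <- "N"
  if (!win[RK_COLUMN] %in% c("R", "K")) win[RK_COLUMN] <- "R"

  # zipper: planted a/d and g<->e' pair plan, background at b/c/f
  p_asn <- cfg$asn_a_per_heptad[pmin(seq_len(n_heptads), length(cfg$asn_a_per_heptad))]
  a_res <- vapply(p_asn, function(p) {
    if (stats::runif(1) < p) "N"
    else if (stats::runif(1) < cfg$charged_a) sample(CHARGED, 1L)
    else sample(A_FILLER, 1L)
  }, character(1))
  d_res <- vapply(seq_len(n_heptads), function(i) {
    if (stats::runif(1) < cfg$leu_at_d) "L"
    else sample(names(cfg$d_alternatives), 1L, prob = cfg$d_alternatives)
  }, character(1))
  g_res <- draw_from(SAFE_UNCHARGED, n_heptads)
  e_res <- draw_from(SAFE_UNCHARGED, n_heptads)
  pair_truth <- character(max(n_heptads - 1L, 0L))
  p_int <- cfg$interactive_per_pair[pmin(seq_len(n_heptads - 1L),
                                         length(cfg$interactive_per_pair))]
  for (h in seq_len(n_heptads - 1L)) {
    if (stats::runif(1) < p_int[h]) {
      type <- sample(setdiff(PAIR_TYPES, "incomplete"), 1L)
      ge <- switch(type,
        repulsive_basic = c(sample(c("K", "R"), 1L), sample(c("K", "R"), 1L)),
        repulsive_acidic = c(sample(c("E", "D", "Q"), 1L), sample(c("E", "D", "Q"), 1L)),
        attractive_basic_acidic = c(sample(c("K", "R"), 1L), sample(c("E", "D"), 1L)),
        attractive_acidic_basic = c(sample(c("E", "D"), 1L), sample(c("K", "R"), 1L)))
      g_res[h] <- ge[1L]
      e_res[h + 1L] <- ge[2L]
      pair_truth[h] <- type
    } else {
      pair_truth[h] <- "incomplete"
    }
  }
  bcf <- setdiff(AA20, c("N", HYDROPHOBIC_D))
  zipper <- character(7L * n_heptads)
  for (i in seq_len(n_heptads)) {
    o <- 7L * (i - 1L)
    zipper[o + 1L] <- g_res[i]
    zipper[o + 2L] <- a_res[i]
    zipper[o + 3L] <- draw_from(bcf, 1L)
    zipper[o + 4L] <- draw_from(bcf, 1L)
    zipper[o + 5L] <- d_res[i]
    zipper[o + 6L] <- e_res[i]
    zipper[o + 7L] <- draw_from(bcf, 1L)
  }

  flank_len <- flank_len %||% sample(cfg$flank_range[1]:cfg$flank_range[2], 1L)
  tail_len <- tail_len %||% sample(cfg$tail_range[1]:cfg$tail_range[2], 1L)
  flank <- draw_from(setdiff(AA20, "N"), flank_len)
  tail <- draw_from(setdiff(AA20, c("N", HYDROPHOBIC_D)), tail_len)
  seqv <- c(flank, win, zipper, tail)

  truth <- data.frame(
    protein_id = id, group = group,
    n_pos = flank_len + N_COLUMN, rk_pos = flank_len + RK_COLUMN,
    basic_start = flank_len + 5L, basic_end = flank_len + RK_COLUMN,
    hinge_start = flank_len + RK_COLUMN + 1L, hinge_end = flank_len + 30L,
    zipper_start = flank_len + 31L, n_heptads = n_heptads,
    a_residues = paste(a_res, collapse = ""),
    d_residues = paste(d_res, collapse = ""),
    e_residues = paste(e_res, collapse = ""),
    g_residues = paste(g_res, collapse = ""),
    pair_types = paste(pair_truth, collapse = ","),
    window = paste(win, collapse = ""),
    protein_length = length(seqv),
    stringsAsFactors = FALSE
  )
  list(record = data.frame(id = id, sequence = paste(seqv, collapse = ""),
                           stringsAsFactors = FALSE),
       truth = truth)
}

#' Generate one synthetic bZIP protein
#'
#' The sequence is: random N-terminal flank, the 30-column signature window
#' instantiated from the group's template (fixed letters exact, anchors
#' canonical, '*' columns from a rejection-sampled background), a zipper of
#' `n_heptads` heptads with planted a/d residues and a planted g<->e' pair
#' plan, and a random C-terminal tail. Deterministic given the seed.
#'
#' @param group one of the 10 template groups.
#' @param n_heptads zipper length, 2..9.
#' @param seed integer seed.
#' @param id protein id.
#' @param cfg a `sim_config` (only the planted-frequency fields are used).
#' @param templates template table (default: packaged).
#' @param flank_len,tail_len flank lengths; NULL draws them from `cfg` ranges.
#' @return list with `record` (one-row id/sequence data frame) and `truth`
#'   (one-row truth table).
#' @export
generate_protein <- function(group, n_heptads, seed, id = "synthetic1",
                             cfg = sim_config(seed = seed),
                             templates = load_group_templates(),
                             flank_len = NULL, tail_len = NULL) {
  bg <- window_background_sets(templates)
  withr::with_seed(seed,
    generate_protein_core(id, group, n_heptads, cfg, templates, bg,
                          flank_len = flank_len, tail_len = tail_len))
}

#' Generate a synthetic proteome with truth table
#'
#' @param cfg a `sim_config`.
#' @param groups optional explicit group label per protein (overrides the
#'   multinomial `group_mix` draw).
#' @param n_heptads optional explicit zipper length per protein.
#' @param templates template table.
#' @return list with `proteins` (id/sequence data frame) and `truth`.
#' @export
generate_proteome <- function(cfg, groups = NULL, n_heptads = NULL,
                              templates = load_group_templates()) {
  bg <- window_background_sets(templates)
  n <- cfg$n_proteins
  withr::with_seed(cfg$seed, {
    if (is.null(groups)) {
      groups <- sample(names(cfg$group_mix), n, replace = TRUE,
                       prob = cfg$group_mix)
    }
    if (is.null(n_heptads)) {
      n_heptads <- sample(2:9, n, replace = TRUE, prob = cfg$heptad_weights)
    }
    ids <- sprintf("bzip%03d", seq_len(n))
    out <- lapply(seq_len(n), function(i) {
      generate_protein_core(ids[i], groups[i], n_heptads[i], cfg, templates, bg)
    })
    proteins <- do.call(rbind, lapply(out, `[[`, "record"))
    truth <- do.call(rbind, lapply(out, `[[`, "truth"))
    row.names(proteins) <- row.names(truth) <- NULL
    list(proteins = proteins, truth = truth)
  })
}

# ----- gene models -----------------------------------------------------------

#' Default intra-domain intron plan
#'
#' Cycles deterministically through the four pattern types and the three
#' splicing phases so that every (type, phase) combination occurs, and gives
#' every third gene one extra intron outside the domain.
#'
#' @param truth proteome truth table from [generate_proteome()].
#' @return data frame: `protein_id`, `pattern_type`, `basic_phase`,
#'   `hinge_phase`, `n_extra`.
#' @export
default_intron_plan <- function(truth) {
  n <- nrow(truth)
  types <- rep(c("type1_no_intron", "type2_hinge", "type3_basic", "type4_both"),
               length.out = n)
  phases <- rep(c("P0", "P1", "P2"), length.out = n)
  phases2 <- rep(c("P1", "P2", "P0"), length.out = n)
  data.frame(
    protein_id = truth$protein_id,
    pattern_type = types,
    basic_phase = ifelse(types %in% c("type3_basic", "type4_both"), phases, NA),
    hinge_phase = ifelse(types %in% c("type2_hinge", "type4_both"), phases2, NA),
    n_extra = rep(c(0L, 0L, 1L), length.out = n),
    stringsAsFactors = FALSE
  )
}

# coding offset with the requested phase inside residue interval [rs, re];
# phase P0: offset %% 3 == 0, P1: == 2, P2: == 1
pick_offset <- function(rs, re, phase) {
  nt <- (3L * rs - 2L):(3L * re - 1L)
  want <- c(P0 = 0L, P1 = 2L, P2 = 1L)[[phase]]
  ok <- nt[nt %% 3L == want]
  abort_if(length(ok) == 0L, "region ", rs, "..", re,
           " cannot host a ", phase, " intron")
  ok[sample.int(length(ok), 1L)]
}

#' Generate gene models realizing a planted intron plan
#'
#' CDS length is 3 * (protein length + 1) nucleotides (terminal stop
#' included). Planted introns are placed at coding offsets realizing the
#' requested (region, phase); GFF3-style phases of downstream segments follow
#' automatically. Genes are placed on chromosomes at genomic positions
#' consistent with their layout ranks; strands alternate.
#'
#' @param truth proteome truth table.
#' @param layout layout truth from [generate_genome_layout()] (NULL puts all
#'   genes on one chromosome in truth order).
#' @param intron_plan plan data frame (default [default_intron_plan()]).
#' @param seed integer seed.
#' @param intron_len_range genomic intron length range.
#' @return list with `models` (named list of `gene_model`) and `truth` (one
#'   row per planted intron: `gene_id`, `region`, `phase`, `coding_offset`,
#'   `pattern_type`).
#' @export
generate_gene_models <- function(truth, layout = NULL,
                                 intron_plan = default_intron_plan(truth),
                                 seed, intron_len_range = c(80L, 400L)) {
  abort_if(missing(seed), "generate_gene_models(): seed is mandatory")
  if (is.null(layout)) {
    layout <- data.frame(gene_id = truth$protein_id, chromosome = "chr01",
                         rank = seq_len(nrow(truth)), stringsAsFactors = FALSE)
  }
  plan <- intron_plan[match(truth$protein_id, intron_plan$protein_id), ]
  withr::with_seed(seed, {
    models <- list()
    truth_rows <- list()
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      pl <- plan[i, ]
      cds_len <- 3L * (tr$protein_length + 1L)
      offs <- integer(0)
      rows <- list()
      if (pl$pattern_type %in% c("type3_basic", "type4_both")) {
        abort_if(tr$basic_end < tr$basic_start, "basic region absent for ",
                 tr$protein_id)
        o <- pick_offset(tr$basic_start, tr$basic_end, pl$basic_phase)
        offs <- c(offs, o)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = tr$protein_id, region = "basic", phase = pl$basic_phase,
          coding_offset = o, pattern_type = pl$pattern_type,
          stringsAsFactors = FALSE)
      }
      if (pl$pattern_type %in% c("type2_hinge", "type4_both")) {
        abort_if(tr$hinge_end < tr$hinge_start,
                 "hinge region absent for ", tr$protein_id,
                 "; cannot plant a hinge intron")
        o <- pick_offset(tr$hinge_start, tr$hinge_end, pl$hinge_phase)
        offs <- c(offs, o)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = tr$protein_id, region = "hinge", phase = pl$hinge_phase,
          coding_offset = o, pattern_type = pl$pattern_type,
          stringsAsFactors = FALSE)
      }
      if (pl$n_extra > 0L) {
        lo <- 3L * (tr$hinge_end + 5L)
        hi <- cds_len - 6L
        extra <- sample(seq(lo, hi), pl$n_extra)
        offs <- c(offs, extra)
        for (o in extra) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = tr$protein_id, region = "outside",
            phase = phase_label(o), coding_offset = o,
            pattern_type = pl$pattern_type, stringsAsFactors = FALSE)
        }
      }
      offs <- sort(offs)
      lens <- diff(c(0L, offs, cds_len))
      rank <- layout$rank[layout$gene_id == tr$protein_id]
      chrom <- layout$chromosome[layout$gene_id == tr$protein_id]
      strand <- if (i %% 2L == 0L) "-" else "+"
      ilen <- if (length(offs)) {
        sample(intron_len_range[1]:intron_len_range[2], length(offs), replace = TRUE)
      } else integer(0)
      gstart <- 10000L * rank + 1L
      segs <- matrix(0L, nrow = length(lens), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
      if (strand == "+") {
        s <- gstart
        for (k in seq_along(lens)) {
          segs[k, ] <- c(s, s + lens[k] - 1L)
          if (k < length(lens)) s <- s + lens[k] + ilen[k]
        }
      } else {
        gend <- gstart + sum(lens) + sum(ilen) - 1L
        e <- gend
        for (k in seq_along(lens)) {
          segs[k, ] <- c(e - lens[k] + 1L, e)
          if (k < length(lens)) e <- e - lens[k] - ilen[k]
        }
      }
      models[[tr$protein_id]] <- gene_model(tr$protein_id, chrom, strand,
                                            segs, rank = rank)
      truth_rows <- c(truth_rows, rows)
    }
    intron_truth <- if (length(truth_rows)) {
      do.call(rbind, truth_rows)
    } else {
      data.frame(gene_id = character(), region = character(), phase = character(),
                 coding_offset = integer(), pattern_type = character())
    }
    ptypes <- data.frame(gene_id = plan$protein_id,
                         pattern_type = plan$pattern_type,
                         stringsAsFactors = FALSE)
    list(models = models, truth = intron_truth, plan = ptypes)
  })
}

# ----- genome layout ---------------------------------------------------------

#' Generate a chromosome layout with planted duplication events
#'
#' Plants `n_tandem` adjacent homolog pairs, `n_blocks` collinear blocks of
#' `block_size` consecutive anchors each (each block on its own chromosome
#' pair, a fraction inverted), and `n_dispersed` homolog pairs on chromosome
#' pairs that host no block. Remaining genes are background fillers. Ranks
#' are a permutation of 1..n per chromosome.
#'
#' @param cfg a `sim_config`.
#' @param gene_ids gene identifiers to place (default `bzipNNN` names).
#' @return list with `layout` (gene_id, chromosome, rank), `pairs`
#'   (gene_a, gene_b) and `truth` (pairs plus planted label, block id,
#'   orientation).
#' @export
generate_genome_layout <- function(cfg, gene_ids = sprintf("bzip%03d",
                                                           seq_len(cfg$n_proteins))) {
  n <- length(gene_ids)
  K <- cfg$n_chromosomes
  chroms <- sprintf("chr%02d", seq_len(K))
  all_pairs <- utils::combn(chroms, 2L)
  bs <- rep_len(as.integer(cfg$block_size), cfg$n_blocks)
  abort_if(cfg$n_blocks + cfg$n_dispersed > ncol(all_pairs),
           "not enough chromosome pairs for the requested blocks + dispersed pairs")
  slots_needed <- 2L * sum(bs) + 2L * cfg$n_tandem + 2L * cfg$n_dispersed
  abort_if(slots_needed > n, "not enough genes for the requested plant: need ",
           slots_needed, ", have ", n)

  withr::with_seed(cfg$seed + 1L, {
    pair_idx <- sample(ncol(all_pairs))
    block_pairs <- all_pairs[, pair_idx[seq_len(cfg$n_blocks)], drop = FALSE]
    disp_pairs <- all_pairs[, pair_idx[cfg$n_blocks + seq_len(cfg$n_dispersed)],
                            drop = FALSE]
    inverted <- stats::runif(cfg$n_blocks) < cfg$inverted_fraction

    # per-chromosome list of "units": vectors of slot labels kept contiguous
    units <- stats::setNames(vector("list", K), chroms)
    add_unit <- function(chrom, labels) {
      units[[chrom]][[length(units[[chrom]]) + 1L]] <<- labels
    }
    for (b in seq_len(cfg$n_blocks)) {
      lab <- sprintf("B%02d_%02d", b, seq_len(bs[b]))
      add_unit(block_pairs[1L, b], paste0(lab, "_a"))
      side_b <- paste0(lab, "_b")
      if (inverted[b]) side_b <- base::rev(side_b)
      add_unit(block_pairs[2L, b], side_b)
    }
    tandem_chroms <- sample(chroms, cfg$n_tandem, replace = TRUE)
    for (t in seq_len(cfg$n_tandem)) {
      add_unit(tandem_chroms[t], sprintf("T%02d_%s", t, c("a", "b")))
    }
    for (d in seq_len(cfg$n_dispersed)) {
      add_unit(disp_pairs[1L, d], sprintf("D%02d_a", d))
      add_unit(disp_pairs[2L, d], sprintf("D%02d_b", d))
    }
    # fillers: keep chromosome loads balanced so the planted blocks always fit
    n_filler <- n - slots_needed
    load <- vapply(units, function(u) length(unlist(u)), integer(1))
    for (f in seq_len(n_filler)) {
      ch <- chroms[which.min(load)]
      add_unit(ch, sprintf("F%03d", f))
      load[ch] <- load[ch] + 1L
    }

    # shuffle unit order per chromosome, then rank slots 1..m
    slot_tab <- do.call(rbind, lapply(chroms, function(ch) {
      u <- units[[ch]]
      if (length(u) == 0L) return(NULL)
      labels <- unlist(u[sample(length(u))])
      data.frame(slot = labels, chromosome = ch, rank = seq_along(labels),
                 stringsAsFactors = FALSE)
    }))
    abort_if(any(table(slot_tab$chromosome) > cfg$genes_per_chromosome),
             "overfull chromosome: raise genes_per_chromosome or n_chromosomes")

    # random assignment of genes to slots
    slot_tab$gene_id <- sample(gene_ids)
    gene_of <- stats::setNames(slot_tab$gene_id, slot_tab$slot)

    truth <- list()
    for (b in seq_len(cfg$n_blocks)) {
      for (j in seq_len(bs[b])) {
        lab <- sprintf("B%02d_%02d", b, j)
        truth[[length(truth) + 1L]] <- data.frame(
          gene_a = gene_of[[paste0(lab, "_a")]],
          gene_b = gene_of[[paste0(lab, "_b")]],
          label = "segmental", block = sprintf("B%02d", b),
          orientation = if (inverted[b]) "inverted" else "same",
          stringsAsFactors = FALSE)
      }
    }
    for (t in seq_len(cfg$n_tandem)) {
      truth[[length(truth) + 1L]] <- data.frame(
        gene_a = gene_of[[sprintf("T%02d_a", t)]],
        gene_b = gene_of[[sprintf("T%02d_b", t)]],
        label = "tandem", block = NA_character_, orientation = NA_character_,
        stringsAsFactors = FALSE)
    }
    for (d in seq_len(cfg$n_dispersed)) {
      truth[[length(truth) + 1L]] <- data.frame(
        gene_a = gene_of[[sprintf("D%02d_a", d)]],
        gene_b = gene_of[[sprintf("D%02d_b", d)]],
        label = "dispersed", block = NA_character_, orientation = NA_character_,
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    layout <- slot_tab[, c("gene_id", "chromosome", "rank")]
    row.names(layout) <- NULL
    list(layout = layout,
         pairs = truth[, c("gene_a", "gene_b")],
         truth = truth)
  })
}

# ----- expression ------------------------------------------------------------

#' Generate an FPKM matrix with planted expression classes
#'
#' Tissue atlas: log-normal baseline with planted not-expressed (< 1
#' everywhere), expressed-in-any, expressed-in-all, and highly expressed
#' tissue-preferential genes (>= 20 in their tissue, which also attains the
#' row maximum). Drought panel: paired control/treated root and leaf columns
#' with planted up-/down-regulated genes at the configured fold change.
#'
#' @param cfg a `sim_config`.
#' @param gene_ids gene identifiers (default `bzipNNN` names).
#' @return list with `fpkm` (genes x tissues), `drought` (genes x 4 matrix:
#'   root_control, root_drought, leaf_control, leaf_drought) and `truth`.
#' @export
generate_fpkm <- function(cfg, gene_ids = sprintf("bzip%03d",
                                                  seq_len(cfg$n_proteins))) {
  n <- length(gene_ids)
  tis <- cfg$tissues
  abort_if(cfg$n_expressed_all > cfg$n_expressed_any ||
             cfg$n_expressed_any > n, "inconsistent expression plan")
  abort_if(sum(cfg$n_high_pref) > cfg$n_expressed_all,
           "n_high_pref must fit inside the expressed-in-all set")
  withr::with_seed(cfg$seed + 2L, {
    m <- matrix(stats::rlnorm(n * length(tis), meanlog = log(5), sdlog = 1),
                nrow = n, dimnames = list(gene_ids, tis))
    # keep the un-planted baseline below the high-expression threshold so the
    # planted tissue-preferential sets are recoverable exactly
    m <- pmin(m, 15)
    idx <- sample(n)
    any_idx <- idx[seq_len(cfg$n_expressed_any)]
    all_idx <- any_idx[seq_len(cfg$n_expressed_all)]
    some_idx <- setdiff(any_idx, all_idx)
    off_idx <- setdiff(idx, any_idx)

    m[off_idx, ] <- matrix(stats::runif(length(off_idx) * length(tis), 0, 0.8),
                           nrow = length(off_idx))
    m[all_idx, ] <- pmax(m[all_idx, , drop = FALSE], 1.2)
    for (i in some_idx) {
      hi <- sample(length(tis), 1L)
      lo <- sample(setdiff(seq_along(tis), hi), 1L)
      m[i, hi] <- max(m[i, hi], 1.5)
      m[i, lo] <- stats::runif(1, 0, 0.8)
    }
    high_truth <- data.frame(gene_id = character(), tissue = character())
    pool <- all_idx
    for (t in names(cfg$n_high_pref)) {
      pick <- pool[seq_len(cfg$n_high_pref[[t]])]
      pool <- setdiff(pool, pick)
      m[pick, t] <- 20 + stats::rlnorm(length(pick), log(10), 0.5)
      other <- setdiff(tis, t)
      m[pick, other] <- pmin(m[pick, other, drop = FALSE], 15)
      high_truth <- rbind(high_truth,
                          data.frame(gene_id = gene_ids[pick], tissue = t,
                                     stringsAsFactors = FALSE))
    }

    # drought panel
    dr <- matrix(stats::rlnorm(n * 2L, log(5), 1), nrow = n,
                 dimnames = list(gene_ids, c("root_control", "leaf_control")))
    dpool <- sample(n)
    up_idx <- dpool[seq_len(cfg$n_up)]
    down_idx <- dpool[cfg$n_up + seq_len(cfg$n_down)]
    dr[c(up_idx, down_idx), ] <- pmax(dr[c(up_idx, down_idx), , drop = FALSE], 2)
    treated <- dr * exp(matrix(stats::rnorm(n * 2L, 0, 0.1), nrow = n))
    treated[up_idx, ] <- dr[up_idx, , drop = FALSE] * cfg$drought_fc *
      exp(matrix(stats::rnorm(cfg$n_up * 2L, 0, cfg$noise_sd), ncol = 2L))
    treated[down_idx, ] <- dr[down_idx, , drop = FALSE] / cfg$drought_fc *
      exp(matrix(stats::rnorm(cfg$n_down * 2L, 0, cfg$noise_sd), ncol = 2L))
    drought <- cbind(root_control = dr[, 1L], root_drought = treated[, 1L],
                     leaf_control = dr[, 2L], leaf_drought = treated[, 2L])

    expr_class <- rep("not_expressed", n)
    expr_class[some_idx] <- "expressed_any"
    expr_class[all_idx] <- "expressed_all"
    dr_class <- rep("unchanged", n)
    dr_class[up_idx] <- "up"
    dr_class[down_idx] <- "down"
    truth <- data.frame(gene_id = gene_ids, expression_class = expr_class,
                        drought_class = dr_class, stringsAsFactors = FALSE)
    list(fpkm = m, drought = drought,
         truth = list(genes = truth, high_preferential = high_truth))
  })
}

# ----- one-stop simulation ---------------------------------------------------

#' Generate a full synthetic data set
#'
#' Runs all generators with one configuration and, optionally, writes the
#' pipeline's input files (proteins.fasta, genes.gff3, pairs.tsv, fpkm.tsv,
#' drought.tsv) and truth tables under `out_dir`.
#'
#' @param cfg a `sim_config`.
#' @param out_dir output directory (NULL: nothing written).
#' @return list with `proteins`, `proteome_truth`, `models`, `intron_truth`,
#'   `intron_plan`, `layout`, `pairs`, `duplication_truth`, `fpkm`,
#'   `drought`, `expression_truth`.
#' @export
generate_all <- function(cfg, out_dir = NULL) {
  prot <- generate_proteome(cfg)
  genome <- generate_genome_layout(cfg, prot$truth$protein_id)
  genes <- generate_gene_models(prot$truth, genome$layout, seed = cfg$seed + 3L)
  expr <- generate_fpkm(cfg, prot$truth$protein_id)
  out <- list(proteins = prot$proteins, proteome_truth = prot$truth,
              models = genes$models, intron_truth = genes$truth,
              intron_plan = genes$plan,
              layout = genome$layout, pairs = genome$pairs,
              duplication_truth = genome$truth,
              fpkm = expr$fpkm, drought = expr$drought,
              expression_truth = expr$truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
    write_fasta(out$proteins, file.path(out_dir, "proteins.fasta"))
    write_gff3(out$models, file.path(out_dir, "genes.gff3"))
    write_tsv_commented(out$pairs, file.path(out_dir, "pairs.tsv"))
    write_tsv_commented(as.data.frame(out$fpkm) |>
                          (\(d) cbind(gene_id = rownames(out$fpkm), d))(),
                        file.path(out_dir, "fpkm.tsv"))
    write_tsv_commented(as.data.frame(out$drought) |>
                          (\(d) cbind(gene_id = rownames(out$drought), d))(),
                        file.path(out_dir, "drought.tsv"))
    write_tsv_commented(out$proteome_truth, file.path(out_dir, "truth", "proteins.tsv"))
    write_tsv_commented(out$intron_truth, file.path(out_dir, "truth", "introns.tsv"))
    write_tsv_commented(out$duplication_truth, file.path(out_dir, "truth", "duplications.tsv"))
    write_tsv_commented(out$expression_truth$genes, file.path(out_dir, "truth", "expression.tsv"))
    write_tsv_commented(out$layout, file.path(out_dir, "truth", "layout.tsv"))
  }
  out
}
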