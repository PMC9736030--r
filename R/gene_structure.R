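# gene_structure: map the basic+hinge region onto the gene model and type
# intra-domain introns.
#
# Splicing-phase convention used throughout: P0/P1/P2 = the splice falls
# after the 3rd/2nd/1st nucleotide of a codon. This is the INVERSE of the
# classical intron-phase naming (classical phase 1 = after the 1st
# nucleotide) and is numerically identical to the GFF3 phase value of the CDS
# segment downstream of the intron.

#' Protein length encoded by a CDS
#'
#' @param cds_len CDS length in nucleotides (divisible by 3, >= 6).
#' @return amino-acid count, excluding the terminal stop codon
#'   (`cds_len / 3 - 1`).
#' @examples
#' cds_to_protein_length(1281) # 426
#' @export
cds_to_protein_length <- function(cds_len) {
  abort_if(any(cds_len %% 3 != 0), "CDS length not divisible by 3")
  abort_if(any(cds_len < 6), "CDS length must be >= 6 (start + stop)")
  cds_len / 3 - 1
}

#' Coding-nucleotide interval of a protein residue interval
#'
#' Residue r occupies coding nucleotides 3r-2 .. 3r.
#'
#' @param from,to 1-based residue positions (inclusive).
#' @param protein_length protein length in residues, for bounds checking.
#' @return integer vector `c(start, end)` in coding-nucleotide coordinates.
#' @export
protein_interval_to_coding_nt <- function(from, to = from, protein_length = Inf) {
  abort_if(from < 1 || to < from, "bad residue interval")
  abort_if(to > protein_length, "residue interval beyond protein length")
  c(3L * as.integer(from) - 2L, 3L * as.integer(to))
}

# cumulative coding nucleotides upstream of each intron, translation order
intron_coding_offsets <- function(model) {
  seg <- model$cds_segments
  if (nrow(seg) < 2L) return(integer(0))
  lens <- seg[, "end"] - seg[, "start"] + 1L
  cumsum(lens)[-nrow(seg)]
}

phase_label <- function(c_upstream) {
  m <- c_upstream %% 3L
  c("P0", "P2", "P1")[m + 1L] # m: 0 -> P0, 1 -> P2, 2 -> P1
}

#' Splicing phase of one intron
#'
#' With c = cumulative coding nucleotides upstream of the intron: c mod 3 = 0
#' is P0 (splice after the 3rd nucleotide of a codon), 2 is P1 (after the
#' 2nd), 1 is P2 (after the 1st). The label equals the GFF3 phase of the CDS
#' segment following the intron.
#'
#' @param model a valid `gene_model`.
#' @param intron_index 1-based intron index in translation order.
#' @return "P0", "P1" or "P2".
#' @export
intron_phase <- function(model, intron_index) {
  abort_if(!isTRUE(model$valid), "invalid gene model: ", model$gene_id)
  offs <- intron_coding_offsets(model)
  abort_if(intron_index < 1L || intron_index > length(offs),
           "gene ", model$gene_id, " has no intron ", intron_index)
  phase_label(offs[intron_index])
}

#' Type the intra-domain intron pattern of a gene
#'
#' Introns whose coding offset falls inside the basic region's
#' coding-nucleotide interval are "basic", inside the hinge interval "hinge";
#' introns elsewhere are reported but ignored for typing. An intron after
#' coding nucleotide c lies inside [s, e] iff s <= c <= e - 1 (a splice at a
#' region's right boundary belongs to the next region). Patterns: type 1 no
#' intra-domain intron; types 2/3 exactly one, in the hinge/basic region;
#' type 4 one in each; anything else is atypical.
#'
#' @param model a valid `gene_model`.
#' @param annotation the `bzip_annotation` of the encoded protein.
#' @param protein_length length of the encoded protein in residues; must
#'   equal `cds_to_protein_length(cds_length(model))`.
#' @return list with `gene_id`, `pattern_type`, `atypical`, and `introns`
#'   (data frame: `index`, `coding_offset`, `region`, `phase`).
#' @export
classify_intron_pattern <- function(model, annotation,
                                    protein_length = cds_to_protein_length(cds_length(model))) {
  abort_if(!isTRUE(model$valid), "invalid gene model: ", model$gene_id)
  expected <- cds_to_protein_length(cds_length(model))
  abort_if(expected != protein_length,
           "gene ", model$gene_id, " encodes ", expected,
           " aa but protein ", annotation$protein_id, " has ", protein_length)
  basic_nt <- protein_interval_to_coding_nt(annotation$basic_start,
                                            annotation$basic_end, protein_length)
  hinge_nt <- if (annotation$hinge_end >= annotation$hinge_start) {
    protein_interval_to_coding_nt(annotation$hinge_start,
                                  annotation$hinge_end, protein_length)
  } else NULL

  offs <- intron_coding_offsets(model)
  region <- rep("outside", length(offs))
  region[offs >= basic_nt[1] & offs <= basic_nt[2] - 1L] <- "basic"
  if (!is.null(hinge_nt)) {
    region[offs >= hinge_nt[1] & offs <= hinge_nt[2] - 1L] <- "hinge"
  }
  introns <- data.frame(index = seq_along(offs), coding_offset = offs,
                        region = region, phase = phase_label(offs),
                        stringsAsFactors = FALSE)
  nb <- sum(region == "basic")
  nh <- sum(region == "hinge")
  pattern <- if (nb == 0L && nh == 0L) "type1_no_intron"
    else if (nb == 0L && nh == 1L) "type2_hinge"
    else if (nb == 1L && nh == 0L) "type3_basic"
    else if (nb == 1L && nh == 1L) "type4_both"
    else "atypical"
  list(gene_id = model$gene_id, pattern_type = pattern,
       atypical = pattern == "atypical", introns = introns)
}

#' Intron-count statistics over a gene set
#'
#' @param models list of `gene_model` objects.
#' @param groups optional named character vector (gene_id -> group label);
#'   when supplied, per-group intronless fractions are reported.
#' @return list with `histogram` (data frame: `n_introns`, `n_genes`) and
#'   `per_group` (data frame: `group`, `n_genes`, `n_intronless`,
#'   `intronless_fraction`; NULL when `groups` is missing).
#' @export
intron_count_stats <- function(models, groups = NULL) {
  if (length(models) == 0L) {
    return(list(histogram = data.frame(n_introns = integer(), n_genes = integer()),
                per_group = NULL))
  }
  counts <- vapply(models, function(m) nrow(m$cds_segments) - 1L, integer(1))
  tab <- table(counts)
  hist <- data.frame(n_introns = as.integer(names(tab)), n_genes = as.integer(tab))
  per_group <- NULL
  if (!is.null(groups)) {
    ids <- vapply(models, `[[`, character(1), "gene_id")
    grp <- groups[ids]
    keep <- !is.na(grp)
    per_group <- do.call(rbind, lapply(sort(unique(grp[keep])), function(g) {
      sel <- which(grp == g)
      data.frame(group = g, n_genes = length(sel),
                 n_intronless = sum(counts[sel] == 0L),
                 intronless_fraction = mean(counts[sel] == 0L),
                 stringsAsFactors = FALSE)
    }))
  }
  list(histogram = hist, per_group = per_group)
}
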