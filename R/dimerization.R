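# dimerization: leucine-zipper dimerization properties. Interface content at
# a/d, electrostatic typing of g<->e' pairs (g of heptad i against e of
# heptad i+1, the intra-sequence proxy for the inter-helical pair of a
# parallel dimer), and a per-protein propensity summary.

PAIR_TYPES <- c("repulsive_basic", "repulsive_acidic",
                "attractive_basic_acidic", "attractive_acidic_basic",
                "incomplete")

#' Residue class for dimerization analysis
#'
#' K/R are basic, E/D acidic, and Q "acidic-like": Q takes part in repulsive
#' acidic pairs (E-Q) but is not counted among the charged residues (K, R, D,
#' E) in interface tallies. N is singled out (a-position Asn drives
#' homodimerization through a-a' contacts), and L/I/V/F/M form the
#' hydrophobic interface class.
#'
#' @param aa character vector of single letters.
#' @return character vector: one of "basic", "acidic", "acidic_like",
#'   "polar_N", "hydrophobic", "other".
#' @export
residue_class <- function(aa) {
  abort_if(any(nchar(aa) != 1L), "residue_class() takes single letters")
  aa <- toupper(aa)
  out <- rep("other", length(aa))
  out[aa %in% c("K", "R")] <- "basic"
  out[aa %in% c("E", "D")] <- "acidic"
  out[aa == "Q"] <- "acidic_like"
  out[aa == "N"] <- "polar_N"
  out[aa %in% HYDROPHOBIC_D] <- "hydrophobic"
  out
}

#' Classify one g<->e' pair
#'
#' @param g_res residue at the g position of heptad i.
#' @param e_res residue at the e position of heptad i+1.
#' @return pair type label: like charges are repulsive (Q counting as
#'   acidic-like on both sides), basic-acidic and acidic-basic are the two
#'   attractive orders (strict E/D acidic only), and any pair with an
#'   uncharged member is "incomplete".
#' @export
classify_ge_pair <- function(g_res, e_res) {
  if (is.na(g_res) || is.na(e_res)) return("incomplete")
  cg <- residue_class(g_res)
  ce <- residue_class(e_res)
  acidic_ish <- c("acidic", "acidic_like")
  if (cg == "basic" && ce == "basic") return("repulsive_basic")
  if (cg %in% acidic_ish && ce %in% acidic_ish) return("repulsive_acidic")
  if (cg == "basic" && ce == "acidic") return("attractive_basic_acidic")
  if (cg == "acidic" && ce == "basic") return("attractive_acidic_basic")
  "incomplete"
}

# all evaluable g<->e' pairs of one annotation: g of heptad i, e of heptad i+1
ge_pairs <- function(annotation) {
  hp <- annotation$heptads
  if (nrow(hp) < 2L) {
    return(data.frame(pair_index = integer(), g = character(), e = character(),
                      type = character(), stringsAsFactors = FALSE))
  }
  idx <- seq_len(nrow(hp) - 1L)
  g <- hp$g[idx]
  e <- hp$e[idx + 1L]
  keep <- !is.na(g) & !is.na(e)
  idx <- idx[keep]; g <- g[keep]; e <- e[keep]
  type <- mapply(classify_ge_pair, g, e, USE.NAMES = FALSE)
  data.frame(pair_index = idx, g = g, e = e, type = as.character(type),
             stringsAsFactors = FALSE)
}

#' Residue frequencies at the a, d, e, g interface positions
#'
#' Pooled over all heptads of all annotations: for each position, the
#' frequency of each residue among occupied slots (frequencies sum to 1 per
#' position). The residue class is carried alongside for class-level rollups.
#'
#' @param annotations non-empty list of `bzip_annotation` objects.
#' @return data frame with columns `position`, `residue`, `class`, `count`,
#'   `frequency`.
#' @export
position_frequency_table <- function(annotations) {
  abort_if(length(annotations) == 0L, "position_frequency_table(): no annotations")
  out <- list()
  for (posn in c("a", "d", "e", "g")) {
    res <- unlist(lapply(annotations, function(a) a$heptads[[posn]]))
    res <- res[!is.na(res)]
    tab <- table(res)
    out[[posn]] <- data.frame(
      position = posn, residue = names(tab), class = residue_class(names(tab)),
      count = as.integer(tab), frequency = as.numeric(tab) / sum(tab),
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, out)
  row.names(df) <- NULL
  df
}

#' Per-heptad frequency of Asn at the a position
#'
#' For heptad index h the denominator is the number of proteins whose zipper
#' has an occupied a slot in heptad h.
#'
#' @param annotations list of `bzip_annotation` objects.
#' @return data frame with columns `heptad`, `n_proteins`, `n_asn`,
#'   `frequency` (empty if no annotations).
#' @export
asn_frequency_per_heptad <- function(annotations) {
  a_by_heptad <- list()
  for (ann in annotations) {
    hp <- ann$heptads
    for (i in seq_len(nrow(hp))) {
      if (is.na(hp$a[i])) next
      h <- as.character(hp$index[i])
      a_by_heptad[[h]] <- c(a_by_heptad[[h]], hp$a[i])
    }
  }
  if (length(a_by_heptad) == 0L) {
    return(data.frame(heptad = integer(), n_proteins = integer(),
                      n_asn = integer(), frequency = numeric()))
  }
  hs <- sort(as.integer(names(a_by_heptad)))
  df <- do.call(rbind, lapply(hs, function(h) {
    res <- a_by_heptad[[as.character(h)]]
    data.frame(heptad = h, n_proteins = length(res), n_asn = sum(res == "N"),
               frequency = mean(res == "N"))
  }))
  row.names(df) <- NULL
  df
}

#' Per-heptad g<->e' pair-type frequencies
#'
#' For pair index h (g of heptad h against e of heptad h+1), the frequency of
#' each of the five pair types among evaluable pairs; the five frequencies
#' sum to 1 within each h, and the "interactive" frequency is
#' 1 - freq(incomplete).
#'
#' @param annotations list of `bzip_annotation` objects.
#' @return data frame with columns `heptad`, `n_pairs`, one column per pair
#'   type, and `interactive`.
#' @export
ge_pair_frequency_per_heptad <- function(annotations) {
  pairs <- do.call(rbind, c(lapply(annotations, ge_pairs),
                            make.row.names = FALSE))
  if (is.null(pairs) || nrow(pairs) == 0L) {
    df <- data.frame(heptad = integer(), n_pairs = integer())
    for (pt in PAIR_TYPES) df[[pt]] <- numeric()
    df$interactive <- numeric()
    return(df)
  }
  hs <- sort(unique(pairs$pair_index))
  df <- do.call(rbind, lapply(hs, function(h) {
    sub <- pairs[pairs$pair_index == h, ]
    row <- data.frame(heptad = h, n_pairs = nrow(sub))
    for (pt in PAIR_TYPES) row[[pt]] <- mean(sub$type == pt)
    row$interactive <- 1 - row$incomplete
    row
  }))
  row.names(df) <- NULL
  df
}

#' Dimerization propensity summary of one annotation
#'
#' Raw counts (Asn and charged residues at a, Leu fraction at d, g<->e' pair
#' counts) plus a coarse label: homodimer-favoring needs >= 2 a-position Asn
#' and no repulsive pair; heterodimer-favoring needs >= 1 repulsive pair or
#' >= 2 charged a residues; both conditions give "mixed", neither
#' "indeterminate". The thresholds are reporting conventions, not measured
#' constants; all counts are emitted so users can re-threshold.
#'
#' @param annotation a `bzip_annotation`.
#' @return one-row data frame (class `dimer_summary`).
#' @export
dimer_propensity <- function(annotation) {
  hp <- annotation$heptads
  a_res <- hp$a[!is.na(hp$a)]
  d_res <- hp$d[!is.na(hp$d)]
  asn_a <- sum(a_res == "N")
  charged_a <- sum(a_res %in% c("K", "R", "D", "E"))
  leu_d <- if (length(d_res)) mean(d_res == "L") else NA_real_
  pairs <- ge_pairs(annotation)
  pc <- stats::setNames(vapply(PAIR_TYPES, function(pt) sum(pairs$type == pt),
                               integer(1)), PAIR_TYPES)
  repulsive <- pc[["repulsive_basic"]] + pc[["repulsive_acidic"]]
  homo <- asn_a >= 2L && repulsive == 0L
  hetero <- repulsive >= 1L || charged_a >= 2L
  label <- if (homo && hetero) "mixed" else if (homo) "homodimer_favoring"
           else if (hetero) "heterodimer_favoring" else "indeterminate"
  out <- data.frame(
    protein_id = annotation$protein_id, n_heptads = nrow(hp),
    asn_a_count = asn_a, charged_a_count = charged_a,
    leu_d_fraction = leu_d, t(pc),
    n_pairs = nrow(pairs), propensity = label,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("dimer_summary", class(out))
  out
}

#' Dimerization summaries for a whole annotated proteome
#'
#' @param annotations list of `bzip_annotation` objects.
#' @return data frame, one row per annotation.
#' @export
dimerize_proteome <- function(annotations) {
  if (length(annotations) == 0L) {
    df <- data.frame(protein_id = character(), n_heptads = integer(),
                     asn_a_count = integer(), charged_a_count = integer(),
                     leu_d_fraction = numeric(), stringsAsFactors = FALSE)
    for (pt in PAIR_TYPES) df[[pt]] <- integer()
    df$n_pairs <- integer()
    df$propensity <- character()
    return(df)
  }
  out <- do.call(rbind, lapply(annotations, dimer_propensity))
  row.names(out) <- NULL
  out
}
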