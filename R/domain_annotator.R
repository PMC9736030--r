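# domain_annotator: locate the bZIP architecture in a protein sequence.
#
# Architecture model: a 16-residue DNA-binding basic region ending at the R/K
# of the invariant N-x7-R/K motif, a short hinge, then a leucine zipper of
# 2..9 heptad repeats whose positions are labeled g,a,b,c,d,e,f in sequence
# order (the dimer interface sits at a/d; electrostatic pairing at e/g).

HEPTAD_LABELS <- c("g", "a", "b", "c", "d", "e", "f")

#' Find N-x7-R/K basic-region anchors
#'
#' Scans for every Asn whose eighth downstream residue is Arg or Lys, with
#' room for the seven basic-region residues upstream of the Asn. The
#' 16-residue basic region spans positions `n_pos - 7 .. n_pos + 8`.
#'
#' @param seq amino-acid string (1-based positions).
#' @return data frame with columns `n_pos`, `rk_pos`, `basic_start`,
#'   `basic_end`, hits ordered left to right; zero rows when no motif.
#' @export
find_basic_region <- function(seq) {
  ch <- seq_chars(seq)
  n <- length(ch)
  empty <- data.frame(n_pos = integer(), rk_pos = integer(),
                      basic_start = integer(), basic_end = integer())
  if (n < 16L) return(empty)
  i <- which(ch == "N")
  i <- i[i >= 8L & i + 8L <= n]
  i <- i[ch[i + 8L] %in% c("R", "K")]
  if (length(i) == 0L) return(empty)
  data.frame(n_pos = i, rk_pos = i + 8L, basic_start = i - 7L, basic_end = i + 8L)
}

#' Register leucine-zipper heptads from a d-position anchor
#'
#' The anchor is taken to be the d position of heptad 1 (so the heptad's g
#' starts four residues earlier), and further heptads are tiled every seven
#' residues. Tiling stops at the sequence end, after nine heptads, or when
#' two consecutive heptads carry a non-canonical d (neither is kept); any
#' remaining trailing heptads with non-canonical d are trimmed, so a zipper
#' always ends on a hydrophobic interface residue. A terminal partial heptad
#' is kept only if it includes its d position.
#'
#' @param seq amino-acid string.
#' @param zipper_anchor 1-based index of the first canonical interface
#'   residue (must be one of L, I, V, F, M).
#' @return data frame with columns `index`, `start`, and one column per
#'   position label g,a,b,c,d,e,f (NA where the sequence ends mid-heptad).
#' @export
register_heptads <- function(seq, zipper_anchor) {
  ch <- seq_chars(seq)
  abort_if(zipper_anchor < 1L || zipper_anchor > length(ch),
           "zipper_anchor out of range")
  abort_if(!ch[zipper_anchor] %in% HYDROPHOBIC_D,
           "zipper_anchor must point at one of L, I, V, F, M")
  g1 <- zipper_anchor - 4L
  abort_if(g1 < 1L, "no room for positions g..c before the anchor")

  rows <- list()
  d_ok <- logical(0)
  for (i in 1:9) {
    start <- g1 + 7L * (i - 1L)
    if (start > length(ch)) break
    len <- min(start + 6L, length(ch)) - start + 1L
    if (len < 5L) break # partial heptad without its d position: not kept
    res <- rep(NA_character_, 7L)
    res[seq_len(len)] <- ch[start:(start + len - 1L)]
    ok <- res[5L] %in% HYDROPHOBIC_D
    if (i >= 2L && !ok && !d_ok[i - 1L]) {
      # two consecutive non-canonical d positions terminate the zipper;
      # neither heptad belongs to it
      rows[[i - 1L]] <- NULL
      d_ok <- d_ok[-(i - 1L)]
      break
    }
    rows[[i]] <- c(list(index = i, start = start),
                   stats::setNames(as.list(res), HEPTAD_LABELS))
    d_ok[i] <- ok
  }
  while (length(d_ok) > 0L && !d_ok[length(d_ok)]) {
    rows[[length(d_ok)]] <- NULL
    d_ok <- d_ok[-length(d_ok)]
  }
  if (length(rows) == 0L) {
    out <- data.frame(index = integer(), start = integer())
    for (lab in HEPTAD_LABELS) out[[lab]] <- character()
    return(out)
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Annotate the bZIP domain of one protein
#'
#' For each basic-region hit (left to right), the hinge window (1 to
#' `hinge_max` residues downstream of the basic region) is scanned for the
#' first L/I/V/F/M residue that, taken as the d of heptad 1, yields at least
#' `min_heptads` registered heptads with at least half of their d positions
#' canonical. Anchors whose heptad-1 g would fall inside the basic region are
#' skipped. The first hit that succeeds wins; `NULL` (no-call) otherwise.
#'
#' @param rec one-row data frame (or list) with `id` and `sequence`.
#' @param hinge_max widest hinge searched, in residues (default 16).
#' @param min_heptads minimum zipper length in heptads (default 2).
#' @param min_d_fraction minimum fraction of canonical d residues (default 0.5).
#' @return object of class `bzip_annotation`, or `NULL` for a no-call.
#' @export
annotate_domain <- function(rec, hinge_max = 16L, min_heptads = 2L,
                            min_d_fraction = 0.5) {
  seq <- rec$sequence
  ch <- seq_chars(seq)
  hits <- find_basic_region(seq)
  for (h in seq_len(nrow(hits))) {
    be <- hits$basic_end[h]
    cand <- (be + 1L):min(be + hinge_max, length(ch))
    if (be + 1L > length(ch)) next
    cand <- cand[ch[cand] %in% HYDROPHOBIC_D]
    cand <- cand[cand - 4L >= be + 1L] # keep heptad-1 g out of the basic region
    for (anchor in cand) {
      hp <- register_heptads(seq, anchor)
      if (nrow(hp) < min_heptads) next
      if (mean(hp$d %in% HYDROPHOBIC_D, na.rm = FALSE) < min_d_fraction) next
      g1 <- anchor - 4L
      ann <- structure(
        list(protein_id = rec$id,
             n_pos = hits$n_pos[h], rk_pos = hits$rk_pos[h],
             basic_start = hits$basic_start[h], basic_end = be,
             hinge_start = be + 1L, hinge_end = g1 - 1L,
             heptads = hp),
        class = "bzip_annotation"
      )
      return(ann)
    }
  }
  NULL
}

#' @export
print.bzip_annotation <- function(x, ...) {
  cat(sprintf(
    "<bzip_annotation> %s  basic %d-%d (N%d, R/K%d)  hinge %d-%d  %d heptad(s), d: %s\n",
    x$protein_id, x$basic_start, x$basic_end, x$n_pos, x$rk_pos,
    x$hinge_start, x$hinge_end, nrow(x$heptads),
    paste(x$heptads$d, collapse = "")))
  invisible(x)
}

#' Annotate a whole proteome
#'
#' @param proteins data frame from [read_fasta()].
#' @inheritParams annotate_domain
#' @return named list of `bzip_annotation` objects (no-calls dropped).
#' @export
annotate_proteome <- function(proteins, hinge_max = 16L, min_heptads = 2L,
                              min_d_fraction = 0.5) {
  out <- list()
  for (i in seq_len(nrow(proteins))) {
    ann <- annotate_domain(proteins[i, ], hinge_max = hinge_max,
                           min_heptads = min_heptads,
                           min_d_fraction = min_d_fraction)
    if (!is.null(ann)) out[[ann$protein_id]] <- ann
  }
  out
}

#' Annotation list as a flat table
#'
#' One row per annotated protein: coordinates, heptad count, the residues at
#' each heptad as "gabcdef|gabcdef|..." ('-' where the sequence ends), and
#' the d-position residues.
#'
#' @param annotations list of `bzip_annotation` objects.
#' @return data frame.
#' @export
annotation_table <- function(annotations) {
  if (length(annotations) == 0L) {
    return(data.frame(protein_id = character(), basic_start = integer(),
                      basic_end = integer(), n_pos = integer(),
                      rk_pos = integer(), hinge_span = character(),
                      n_heptads = integer(), heptad_string = character(),
                      d_residues = character()))
  }
  do.call(rbind, lapply(annotations, function(a) {
    hp <- a$heptads
    hstr <- apply(hp[, HEPTAD_LABELS, drop = FALSE], 1L, function(r) {
      paste(ifelse(is.na(r), "-", r), collapse = "")
    })
    data.frame(
      protein_id = a$protein_id, basic_start = a$basic_start,
      basic_end = a$basic_end, n_pos = a$n_pos, rk_pos = a$rk_pos,
      hinge_span = paste0(a$hinge_start, "-", a$hinge_end),
      n_heptads = nrow(hp),
      heptad_string = paste(hstr, collapse = "|"),
      d_residues = paste(ifelse(is.na(hp$d), "-", hp$d), collapse = ""),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))
}
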