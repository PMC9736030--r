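# io_formats: readers/writers for the standard formats the pipeline touches.
# No science here; coordinates are GFF3-native (1-based inclusive) throughout.

#' Read a protein FASTA file
#'
#' Sequences are uppercased, a single trailing '*' (stop) is stripped, and any
#' letter outside the 20 standard amino acids is mapped to 'X'. 'X' never
#' matches a fixed signature position and belongs to no residue class.
#'
#' @param path path to a FASTA file.
#' @return data frame with columns `id` and `sequence`, one row per record.
#' @export
read_fasta <- function(path) {
  abort_if(!file.exists(path), "FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  abort_if(length(set) == 0L, "FASTA file is empty: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  abort_if(length(dup) > 0L,
           "duplicate FASTA ids: ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  seqs <- gsub(paste0("[^", paste(AA20, collapse = ""), "]"), "X", seqs)
  abort_if(any(!nzchar(seqs)), "empty sequence in FASTA: ", path)
  data.frame(id = unname(ids), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param proteins data frame with columns `id`, `sequence`.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  set <- Biostrings::BStringSet(proteins$sequence)
  names(set) <- proteins$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a gene model
#'
#' A gene model is one mRNA's ordered CDS segments. Segments are stored in
#' translation order (ascending genomic coordinate on '+', descending on '-').
#'
#' @param gene_id gene identifier.
#' @param chromosome chromosome name.
#' @param strand "+" or "-".
#' @param cds_segments two-column matrix (start, end), 1-based inclusive,
#'   rows in translation order.
#' @param rank 1-based gene-order rank on the chromosome (NA until assigned).
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chromosome, strand, cds_segments, rank = NA_integer_) {
  abort_if(!strand %in% c("+", "-"), "strand must be '+' or '-'")
  cds_segments <- matrix(as.integer(cds_segments), ncol = 2L,
                         dimnames = list(NULL, c("start", "end")))
  abort_if(any(cds_segments[, "end"] < cds_segments[, "start"]),
           "CDS segment with end < start in ", gene_id)
  o <- order(cds_segments[, "start"])
  ov <- any(cds_segments[o, "start"][-1] <= cds_segments[o, "end"][-nrow(cds_segments)])
  if (nrow(cds_segments) > 1L) abort_if(ov, "overlapping CDS segments in ", gene_id)
  m <- structure(
    list(gene_id = gene_id, chromosome = chromosome, strand = strand,
         rank = as.integer(rank), cds_segments = cds_segments,
         valid = TRUE),
    class = "gene_model"
  )
  if (cds_length(m) %% 3L != 0L) {
    warning("CDS length of ", gene_id, " (", cds_length(m),
            ") is not divisible by 3; model flagged invalid", call. = FALSE)
    m$valid <- FALSE
  }
  m
}

#' Total CDS length of a gene model in nucleotides
#' @param model a `gene_model`.
#' @return integer nucleotide count.
#' @export
cds_length <- function(model) {
  sum(model$cds_segments[, "end"] - model$cds_segments[, "start"] + 1L)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s%s  rank %s  %d CDS segment(s), %d nt%s\n",
              x$gene_id, x$chromosome, x$strand,
              ifelse(is.na(x$rank), "?", x$rank),
              nrow(x$cds_segments), cds_length(x),
              if (x$valid) "" else "  [invalid]"))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' One `gene_model` per mRNA; only CDS features are used (UTR/exon ignored).
#' CDS segments are linked to their mRNA via `Parent` and sorted in
#' translation order. Ranks are assigned per chromosome by gene start
#' position (1 = left-most).
#'
#' @param path GFF3 file with gene/mRNA/CDS features.
#' @return named list of `gene_model` objects (names = gene ids).
#' @export
read_gff3 <- function(path) {
  abort_if(!file.exists(path), "GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  genes <- gr[typ == "gene"]
  mrnas <- gr[typ == "mRNA"]
  cds <- gr[typ == "CDS"]
  abort_if(length(mrnas) == 0L || length(cds) == 0L,
           "GFF3 has no mRNA/CDS features: ", path)

  mrna_id <- as.character(mrnas$ID)
  mrna_parent <- vapply(mrnas$Parent, function(p) as.character(p)[1], character(1))
  gene_start <- stats::setNames(GenomicRanges::start(genes), as.character(genes$ID))
  gene_chrom <- stats::setNames(as.character(GenomicRanges::seqnames(genes)),
                                as.character(genes$ID))

  cds_parent <- vapply(cds$Parent, function(p) as.character(p)[1], character(1))
  models <- vector("list", length(mrnas))
  for (i in seq_along(mrnas)) {
    mid <- mrna_id[i]
    gid <- mrna_parent[i]
    seg <- cds[cds_parent == mid]
    abort_if(length(seg) == 0L, "mRNA ", mid, " has no CDS features")
    segm <- cbind(start = GenomicRanges::start(seg), end = GenomicRanges::end(seg))
    strand <- as.character(GenomicRanges::strand(mrnas[i]))
    segm <- segm[order(segm[, "start"], decreasing = (strand == "-")), , drop = FALSE]
    chrom <- if (gid %in% names(gene_chrom)) gene_chrom[[gid]] else
      as.character(GenomicRanges::seqnames(mrnas[i]))
    models[[i]] <- gene_model(gene_id = gid, chromosome = chrom,
                              strand = strand, cds_segments = segm)
  }
  names(models) <- mrna_parent

  # rank: permutation of 1..n per chromosome, by gene start
  starts <- vapply(models, function(m) {
    if (m$gene_id %in% names(gene_start)) gene_start[[m$gene_id]] else min(m$cds_segments)
  }, numeric(1))
  chroms <- vapply(models, function(m) m$chromosome, character(1))
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    models[idx] <- Map(function(m, r) { m$rank <- r; m }, models[idx],
                       as.integer(rank(starts[idx], ties.method = "first")))
  }
  models
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA, and CDS rows. CDS phase columns are computed from the
#' cumulative coding length upstream of each segment, so the file satisfies
#' the GFF3 phase convention exactly.
#'
#' @param models list of `gene_model` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  rows <- character(0)
  rows <- c("##gff-version 3")
  for (m in models) {
    seg <- m$cds_segments
    gstart <- min(seg)
    gend <- max(seg)
    gid <- m$gene_id
    mid <- paste0(gid, ".1")
    rows <- c(rows,
      paste(m$chromosome, "bzipscan", "gene", gstart, gend, ".", m$strand, ".",
            paste0("ID=", gid), sep = "\t"),
      paste(m$chromosome, "bzipscan", "mRNA", gstart, gend, ".", m$strand, ".",
            paste0("ID=", mid, ";Parent=", gid), sep = "\t"))
    lens <- seg[, "end"] - seg[, "start"] + 1L
    upstream <- c(0L, cumsum(lens))[seq_len(nrow(seg))]
    phase <- (3L - upstream %% 3L) %% 3L
    for (j in seq_len(nrow(seg))) {
      rows <- c(rows,
        paste(m$chromosome, "bzipscan", "CDS", seg[j, "start"], seg[j, "end"],
              ".", m$strand, phase[j],
              paste0("ID=", mid, ".cds", j, ";Parent=", mid), sep = "\t"))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Gene order table from a set of gene models
#'
#' @param models list of `gene_model` objects.
#' @return data frame with columns `gene_id`, `chromosome`, `rank`, `strand`.
#' @export
gene_ranks <- function(models) {
  data.frame(
    gene_id = vapply(models, `[[`, character(1), "gene_id"),
    chromosome = vapply(models, `[[`, character(1), "chromosome"),
    rank = vapply(models, `[[`, integer(1), "rank"),
    strand = vapply(models, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Read a homolog-pair list
#'
#' Two-column TSV (no header required; a header line whose first field is
#' "gene_a" or similar non-data text is fine as long as ids cross-check).
#' Pairs are unordered: (a,b) and (b,a) are deduplicated; self-pairs are
#' dropped with a warning.
#'
#' @param path two-column TSV of gene ids.
#' @param known optional character vector of known gene ids; unknown ids error.
#' @return data frame with columns `gene_a`, `gene_b`.
#' @export
read_pairs_tsv <- function(path, known = NULL) {
  abort_if(!file.exists(path), "pairs file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  abort_if(ncol(df) < 2L, "pairs file must have two columns: ", path)
  if (nrow(df) > 0L && identical(tolower(df[1, 1]), "gene_a")) df <- df[-1, , drop = FALSE]
  a <- as.character(df[[1]]); b <- as.character(df[[2]])
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-pair(s) dropped", call. = FALSE)
    a <- a[!self]; b <- b[!self]
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  out <- data.frame(gene_a = lo[keep], gene_b = hi[keep], stringsAsFactors = FALSE)
  if (!is.null(known)) {
    unk <- setdiff(unique(c(out$gene_a, out$gene_b)), known)
    abort_if(length(unk) > 0L,
             "unknown gene id(s) in pairs file: ", paste(unk, collapse = ", "))
  }
  out
}
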