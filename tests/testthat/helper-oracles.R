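# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-derivations (modular arithmetic, exhaustive
# enumeration, set-based lookups) that share no code with the implementation
# paths they check.

# --- heptad register oracle: position label by (pos - g1) mod 7 -------------

oracle_heptad_label <- function(pos, g1) {
  c("g", "a", "b", "c", "d", "e", "f")[(pos - g1) %% 7 + 1]
}

# check every residue of every returned heptad against the modular rule
expect_heptads_match_oracle <- function(seq, anchor, heptads) {
  ch <- strsplit(seq, "")[[1]]
  g1 <- anchor - 4L
  for (i in seq_len(nrow(heptads))) {
    expect_identical(heptads$start[i], g1 + 7L * (i - 1L))
    for (lab in c("g", "a", "b", "c", "d", "e", "f")) {
      res <- heptads[[lab]][i]
      off <- match(lab, c("g", "a", "b", "c", "d", "e", "f")) - 1L
      pos <- heptads$start[i] + off
      if (pos > length(ch)) {
        expect_true(is.na(res))
      } else {
        expect_identical(res, ch[pos])
        expect_identical(oracle_heptad_label(pos, g1), lab)
      }
    }
  }
}

# --- exhaustive chain enumeration on <= 10 anchors ---------------------------

# longest monotone chain (either orientation) with per-step gaps <= max_gap,
# by depth-first extension over anchors sorted by rank_a
oracle_max_chain <- function(ra, rb, max_gap) {
  o <- order(ra, rb)
  ra <- ra[o]; rb <- rb[o]
  n <- length(ra)
  best <- 0L
  extend <- function(i, len, dir) {
    best <<- max(best, len)
    for (j in seq_len(n)) {
      if (ra[j] <= ra[i] || ra[j] - ra[i] > max_gap) next
      db <- dir * (rb[j] - rb[i])
      if (db <= 0L || db > max_gap) next
      extend(j, len + 1L, dir)
    }
  }
  for (dir in c(1L, -1L)) for (i in seq_len(n)) extend(i, 1L, dir)
  best
}

# --- set-based g<->e' pair typing -------------------------------------------

oracle_pair_type <- function(g, e) {
  if (is.na(g) || is.na(e)) return("incomplete")
  basic <- c("K", "R"); acidic <- c("E", "D"); acidic_ish <- c("E", "D", "Q")
  if (g %in% basic && e %in% basic) "repulsive_basic"
  else if (g %in% acidic_ish && e %in% acidic_ish) "repulsive_acidic"
  else if (g %in% basic && e %in% acidic) "attractive_basic_acidic"
  else if (g %in% acidic && e %in% basic) "attractive_acidic_basic"
  else "incomplete"
}

# per-heptad pair-type frequencies by brute enumeration over all proteins
oracle_ge_frequencies <- function(annotations) {
  rows <- list()
  for (a in annotations) {
    hp <- a$heptads
    if (nrow(hp) < 2) next
    for (h in seq_len(nrow(hp) - 1)) {
      g <- hp$g[h]; e <- hp$e[h + 1]
      if (is.na(g) || is.na(e)) next
      rows[[length(rows) + 1]] <- data.frame(h = h, type = oracle_pair_type(g, e))
    }
  }
  do.call(rbind, rows)
}

# --- small constructors ------------------------------------------------------

# hand-build a bzip_annotation from per-heptad residue strings (7 letters each)
make_annotation <- function(id = "p1", heptad_strings, basic_start = 5L) {
  stopifnot(all(nchar(heptad_strings) <= 7))
  hp <- do.call(rbind, lapply(seq_along(heptad_strings), function(i) {
    res <- strsplit(heptad_strings[i], "")[[1]]
    res <- c(res, rep(NA_character_, 7 - length(res)))
    df <- data.frame(index = i, start = 31L + 7L * (i - 1L), stringsAsFactors = FALSE)
    for (k in 1:7) df[[c("g", "a", "b", "c", "d", "e", "f")[k]]] <- res[k]
    df
  }))
  structure(list(protein_id = id, n_pos = basic_start + 7L,
                 rk_pos = basic_start + 15L, basic_start = basic_start,
                 basic_end = basic_start + 15L, hinge_start = basic_start + 16L,
                 hinge_end = 30L, heptads = hp),
            class = "bzip_annotation")
}

# gene model from translation-order segment lengths on a plus strand
model_from_lengths <- function(lens, gene_id = "g1", chromosome = "chr01",
                               intron_len = 100L, strand = "+") {
  segs <- matrix(0L, nrow = length(lens), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
  s <- 1001L
  for (k in seq_along(lens)) {
    segs[k, ] <- c(s, s + lens[k] - 1L)
    s <- s + lens[k] + intron_len
  }
  if (strand == "-") {
    # mirror the layout so translation order is right-to-left
    hi <- max(segs) + 1000L
    segs <- cbind(start = hi - segs[, "end"], end = hi - segs[, "start"])
  }
  gene_model(gene_id, chromosome, strand, segs)
}
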