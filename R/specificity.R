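# specificity: assign annotated bZIPs to DNA-binding specificity groups from
# a 30-column basic+hinge signature window and report the putative binding
# site. Templates live in inst/extdata/group_templates.tsv (versioned,
# user-replaceable).

SIGNATURE_WIDTH <- 30L
N_COLUMN <- 12L
RK_COLUMN <- 20L

#' Load the group signature templates
#'
#' Each template is a 30-column pattern over the basic region and hinge:
#' columns 1-11 are the residues upstream of the invariant Asn, column 12 the
#' Asn anchor, column 20 the R/K anchor, columns 21-30 the first ten
#' hinge/downstream residues. '*' matches anything; `[XY]` matches X or Y in
#' one column.
#'
#' @param path template TSV; defaults to the packaged table.
#' @return data frame with columns `group`, `tie_priority`, `template`,
#'   `binding_site`, plus a parsed `columns` list-column (per-column allowed
#'   letters, NULL for '*').
#' @export
load_group_templates <- function(path = system.file("extdata", "group_templates.tsv",
                                                    package = "bzipscan")) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df$columns <- lapply(df$template, parse_template)
  bad <- vapply(df$columns, length, integer(1)) != SIGNATURE_WIDTH
  abort_if(any(bad), "template not 30 columns wide for group(s): ",
           paste(df$group[bad], collapse = ", "))
  df
}

# "*ab[XY]c" -> list(NULL, "A", "B", c("X","Y"), "C")
parse_template <- function(tpl) {
  ch <- seq_chars(tpl)
  out <- list()
  i <- 1L
  while (i <= length(ch)) {
    if (ch[i] == "[") {
      j <- i + 1L
      while (j <= length(ch) && ch[j] != "]") j <- j + 1L
      abort_if(j > length(ch), "unterminated '[' in template: ", tpl)
      out[[length(out) + 1L]] <- toupper(ch[(i + 1L):(j - 1L)])
      i <- j + 1L
    } else {
      out[length(out) + 1L] <- list(if (ch[i] == "*") NULL else toupper(ch[i]))
      i <- i + 1L
    }
  }
  out
}

#' Extract the 30-column signature window of an annotation
#'
#' Columns 1-11: the 11 residues upstream of the invariant Asn; 12-20: the
#' N-x7-R/K stretch; 21-30: the first 10 residues after the R/K anchor.
#' Positions outside the sequence are padded with '-'.
#'
#' @param annotation a `bzip_annotation`.
#' @param seq the protein sequence the annotation was made on.
#' @return 30-character string.
#' @export
extract_signature_window <- function(annotation, seq) {
  ch <- seq_chars(seq)
  pos <- (annotation$n_pos - 11L):(annotation$n_pos + 18L)
  win <- ifelse(pos >= 1L & pos <= length(ch), ch[pmax(pos, 1L)], "-")
  paste(win, collapse = "")
}

#' Match a signature window against the group templates
#'
#' A group matches iff every fixed column matches. At the anchor columns (12
#' and 20) a template letter that contradicts the invariant N-x7-R/K anchor
#' is additionally allowed to match the canonical residue (N at 12, R or K at
#' 20); such tolerated matches do not count toward `matched_positions`.
#' Among matching groups the one with the most literally matched fixed
#' columns wins; ties are broken by the template table's `tie_priority`.
#'
#' @param window 30-character string.
#' @param templates template table from [load_group_templates()].
#' @return one-row data frame with `group`, `binding_site`,
#'   `matched_positions` (group "unclassified", site "unknown" if nothing
#'   matches).
#' @export
match_group <- function(window, templates = load_group_templates()) {
  abort_if(nchar(window) != SIGNATURE_WIDTH,
           "signature window must be exactly 30 columns, got ", nchar(window))
  w <- toupper(seq_chars(window))
  best <- NULL
  for (k in seq_len(nrow(templates))) {
    cols <- templates$columns[[k]]
    matched <- 0L
    ok <- TRUE
    for (j in seq_len(SIGNATURE_WIDTH)) {
      allowed <- cols[[j]]
      if (is.null(allowed)) next
      if (w[j] %in% allowed) {
        matched <- matched + 1L
      } else if (j == N_COLUMN && !"N" %in% allowed && w[j] == "N") {
        # tolerated non-canonical anchor column (e.g. group A's K at 12)
      } else if (j == RK_COLUMN && !any(c("R", "K") %in% allowed) &&
                 w[j] %in% c("R", "K")) {
        # tolerated non-canonical anchor column (group J's I at 20)
      } else {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    cand <- list(group = templates$group[k], binding_site = templates$binding_site[k],
                 matched = matched, priority = templates$tie_priority[k])
    if (is.null(best) || cand$matched > best$matched ||
        (cand$matched == best$matched && cand$priority < best$priority)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    return(data.frame(group = "unclassified", binding_site = "unknown",
                      matched_positions = 0L, stringsAsFactors = FALSE))
  }
  data.frame(group = best$group, binding_site = best$binding_site,
             matched_positions = best$matched, stringsAsFactors = FALSE)
}

#' Classify an annotated proteome into specificity groups
#'
#' @param annotations list of `bzip_annotation` objects.
#' @param proteins data frame from [read_fasta()] (provides the sequences).
#' @param templates template table (default: packaged).
#' @return list with `calls` (one row per annotated protein: `protein_id`,
#'   `group`, `binding_site`, `matched_positions`, `window`) and `counts`
#'   (per-group membership counts, a partition of the annotated set).
#' @export
classify_proteome <- function(annotations, proteins,
                              templates = load_group_templates()) {
  seqs <- stats::setNames(proteins$sequence, proteins$id)
  if (length(annotations) == 0L) {
    calls <- data.frame(protein_id = character(), group = character(),
                        binding_site = character(), matched_positions = integer(),
                        window = character(), stringsAsFactors = FALSE)
    return(list(calls = calls, counts = table(factor(character(),
                levels = c(templates$group, "unclassified")))))
  }
  calls <- do.call(rbind, lapply(annotations, function(a) {
    abort_if(!a$protein_id %in% names(seqs),
             "no sequence for annotated protein ", a$protein_id)
    win <- extract_signature_window(a, seqs[[a$protein_id]])
    cbind(data.frame(protein_id = a$protein_id, stringsAsFactors = FALSE),
          match_group(win, templates), data.frame(window = win,
          stringsAsFactors = FALSE))
  }))
  row.names(calls) <- NULL
  counts <- table(factor(calls$group, levels = c(templates$group, "unclassified")))
  list(calls = calls, counts = counts)
}
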