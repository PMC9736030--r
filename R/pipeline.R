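# pipeline: orchestrate the stages and merge their tables into one family
# report. Stage parameters are logged into '#' header comments of every
# output table for provenance.

default_params <- function() {
  list(hinge_max = 16L, min_heptads = 2L, min_d_fraction = 0.5,
       min_anchors = 5L, max_gap = 25L, tandem_max_gap = 1L,
       expressed_threshold = 1, high_threshold = 20,
       min_fc = 2, min_fpkm = 1, eps = 0.01)
}

#' Read a pipeline configuration
#'
#' Accepts an R list, a JSON file, or (when the yaml package is installed) a
#' YAML file. Recognized fields: `proteins` (FASTA, required), `gff`,
#' `pairs`, `fpkm`, `drought` (each optional), `out_dir`, and any parameter
#' from the stage defaults (`hinge_max`, `min_anchors`, `max_gap`,
#' `tandem_max_gap`, `expressed_threshold`, `high_threshold`, `min_fc`,
#' `min_fpkm`, ...).
#'
#' @param config list or path to a JSON/YAML file.
#' @return normalized config list with defaults filled in.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    abort_if(!file.exists(config), "config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) {
      abort_if(!requireNamespace("yaml", quietly = TRUE),
               "YAML config needs the 'yaml' package; use JSON instead")
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  abort_if(!is.list(config), "config must be a list or a file path")
  abort_if(is.null(config$proteins), "config must name a protein FASTA ('proteins')")
  abort_if(!file.exists(config$proteins),
           "protein FASTA not found: ", config$proteins)
  params <- default_params()
  for (p in names(params)) if (!is.null(config[[p]])) params[[p]] <- config[[p]]
  config$params <- params
  config
}

read_matrix_tsv <- function(path) {
  df <- read_tsv_commented(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Run the full characterization pipeline
#'
#' Stages run in dependency order: annotate -> classify -> dimerize, then
#' (when inputs are present) intron typing, duplication classification, and
#' expression filtering. Every input protein keeps one row in the family
#' report; stages without input leave their columns NA.
#'
#' @param config config list or file (see [read_pipeline_config()]).
#' @return invisibly, a list with `report` and the per-stage tables; when
#'   `out_dir` is configured, everything is also written as commented TSV.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  par <- cfg$params
  log_stage <- function(...) message("[bzipscan] ", ...)

  log_stage("reading proteins: ", cfg$proteins)
  proteins <- read_fasta(cfg$proteins)

  log_stage("annotating domains (hinge_max=", par$hinge_max, ")")
  annotations <- annotate_proteome(proteins, hinge_max = par$hinge_max,
                                   min_heptads = par$min_heptads,
                                   min_d_fraction = par$min_d_fraction)
  ann_tab <- annotation_table(annotations)

  log_stage("classifying specificity groups")
  cls <- classify_proteome(annotations, proteins)

  log_stage("predicting dimerization properties")
  dim_tab <- dimerize_proteome(annotations)

  intron_tab <- NULL
  dup_tab <- NULL
  models <- NULL
  if (!is.null(cfg$gff)) {
    log_stage("typing intra-domain introns: ", cfg$gff)
    models <- read_gff3(cfg$gff)
    rows <- list()
    for (id in names(annotations)) {
      if (!id %in% names(models)) next
      m <- models[[id]]
      if (!isTRUE(m$valid)) next
      pat <- classify_intron_pattern(m, annotations[[id]])
      dom <- pat$introns[pat$introns$region != "outside", , drop = FALSE]
      rows[[id]] <- data.frame(
        gene_id = id, pattern_type = pat$pattern_type,
        n_introns = nrow(pat$introns),
        domain_introns = paste(sprintf("%s:%s", dom$region, dom$phase),
                               collapse = ","),
        stringsAsFactors = FALSE)
    }
    intron_tab <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
      else data.frame(gene_id = character(), pattern_type = character(),
                      n_introns = integer(), domain_introns = character())
    if (!is.null(cfg$pairs)) {
      log_stage("classifying duplication events: ", cfg$pairs)
      ranks <- gene_ranks(models)
      pairs <- read_pairs_tsv(cfg$pairs, known = ranks$gene_id)
      blocks <- chain_collinear_anchors(pairs, ranks,
                                        min_anchors = par$min_anchors,
                                        max_gap = par$max_gap)
      dup_tab <- classify_duplication(pairs, blocks, ranks,
                                      tandem_max_gap = par$tandem_max_gap)
    }
  }

  expr <- NULL
  if (!is.null(cfg$fpkm)) {
    log_stage("expression filtering: ", cfg$fpkm)
    m <- read_matrix_tsv(cfg$fpkm)
    sets <- expressed_genes(m, threshold = par$expressed_threshold)
    high <- highly_expressed(m, threshold = par$high_threshold)
    expr <- list(matrix = m, sets = sets, high = high,
                 scaled = row_scale(m))
    if (!is.null(cfg$drought)) {
      dm <- read_matrix_tsv(cfg$drought)
      calls <- sapply(c("root", "leaf"), function(t) {
        differential_call(dm[, paste0(t, "_control")], dm[, paste0(t, "_drought")],
                          min_fc = par$min_fc, min_fpkm = par$min_fpkm,
                          eps = par$eps)
      })
      expr$drought_calls <- calls
    }
  }

  report <- build_family_report(proteins, ann_tab, cls$calls, dim_tab,
                                intron_tab, dup_tab, expr)

  out <- list(report = report, annotations = ann_tab, groups = cls$calls,
              group_counts = cls$counts, dimerization = dim_tab,
              introns = intron_tab, duplications = dup_tab, expression = expr)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    prov <- sprintf("%s=%s", names(par), unlist(par))
    wr <- function(df, name) if (!is.null(df))
      write_tsv_commented(df, file.path(cfg$out_dir, name), comments = prov)
    wr(ann_tab, "annotations.tsv")
    wr(cls$calls, "groups.tsv")
    wr(dim_tab, "dimer.tsv")
    wr(intron_tab, "introns.tsv")
    wr(dup_tab, "events.tsv")
    wr(report, "family_report.tsv")
    log_stage("artifacts written to ", cfg$out_dir)
  }
  invisible(out)
}

# one row per input protein; missing stages leave NA fields, never drop rows
build_family_report <- function(proteins, ann_tab, calls, dim_tab,
                                intron_tab, dup_tab, expr) {
  report <- data.frame(protein_id = proteins$id, stringsAsFactors = FALSE)
  merge_in <- function(report, df, key, cols) {
    if (is.null(df) || nrow(df) == 0L) {
      for (cn in cols) report[[cn]] <- NA
      return(report)
    }
    i <- match(report$protein_id, df[[key]])
    for (cn in cols) report[[cn]] <- df[[cn]][i]
    report
  }
  report <- merge_in(report, ann_tab, "protein_id",
                     c("basic_start", "basic_end", "n_heptads"))
  report <- merge_in(report, calls, "protein_id", c("group", "binding_site"))
  report <- merge_in(report, dim_tab, "protein_id",
                     c("asn_a_count", "charged_a_count", "leu_d_fraction",
                       "propensity"))
  report <- merge_in(report, intron_tab, "gene_id",
                     c("pattern_type", "n_introns"))
  if (!is.null(dup_tab) && nrow(dup_tab) > 0L) {
    lab <- vapply(report$protein_id, function(g) {
      l <- unique(dup_tab$label[dup_tab$gene_a == g | dup_tab$gene_b == g])
      if (length(l)) paste(sort(l), collapse = ",") else NA_character_
    }, character(1))
    report$duplication <- unname(lab)
  } else {
    report$duplication <- NA
  }
  if (!is.null(expr)) {
    report$expressed_any <- report$protein_id %in% expr$sets$any_tissue
    report$expressed_all <- report$protein_id %in% expr$sets$all_tissues
    pref <- expr$high$preferential
    report$preferential_tissues <- vapply(report$protein_id, function(g) {
      t <- names(pref)[vapply(pref, function(v) g %in% v, logical(1))]
      if (length(t)) paste(t, collapse = ",") else ""
    }, character(1))
    if (!is.null(expr$drought_calls)) {
      i <- match(report$protein_id, rownames(expr$drought_calls))
      report$drought_root <- expr$drought_calls[i, "root"]
      report$drought_leaf <- expr$drought_calls[i, "leaf"]
    }
  } else {
    report$expressed_any <- NA
    report$expressed_all <- NA
  }
  report
}
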