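test_that("CDS arithmetic excludes the stop codon", {
  expect_identical(cds_to_protein_length(1281), 426)
  expect_identical(cds_to_protein_length(6), 1)
  expect_error(cds_to_protein_length(100), "divisible by 3")
  expect_identical(protein_interval_to_coding_nt(1), c(1L, 3L))
  expect_identical(protein_interval_to_coding_nt(5, 6), c(13L, 18L))
  expect_error(protein_interval_to_coding_nt(427, 427, protein_length = 426),
               "beyond")
})

test_that("intron_phase follows the splice-after-kth-nucleotide convention", {
  # upstream coding lengths 99 / 101 / 100 -> P0 / P1 / P2
  for (case in list(c(99, "P0"), c(101, "P1"), c(100, "P2"))) {
    c_up <- as.integer(case[1])
    m <- model_from_lengths(c(c_up, 300L - c_up))
    expect_identical(intron_phase(m, 1L), case[2])
  }
  expect_error(intron_phase(model_from_lengths(300), 1L), "no intron")
})

test_that("paper phase label equals downstream GFF3 phase on synthetic models", {
  cfg <- sim_config(n_proteins = 36, n_tandem = 2, n_blocks = 2,
                    block_size = 5, n_dispersed = 2, seed = 8)
  sim <- generate_proteome(cfg)
  genes <- generate_gene_models(sim$truth, seed = 99)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(genes$models, f)
  lines <- readLines(f)
  cds <- lines[grepl("\tCDS\t", lines)]
  fields <- do.call(rbind, strsplit(cds, "\t"))
  parent <- sub(".*Parent=([^;]+)\\.1.*", "\\1", fields[, 9])
  for (id in names(genes$models)) {
    m <- genes$models[[id]]
    phases <- as.integer(fields[parent == id, 8])
    n_int <- nrow(m$cds_segments) - 1L
    if (n_int == 0L) next
    labels <- vapply(seq_len(n_int), function(k) intron_phase(m, k), character(1))
    # phase of the CDS segment following intron k (translation order = file order)
    expect_identical(paste0("P", phases[-1]), labels)
  }
})

test_that("classify_intron_pattern types planted (region, phase) pairs exactly", {
  cfg <- sim_config(n_proteins = 48, n_tandem = 2, n_blocks = 2,
                    block_size = 5, n_dispersed = 2, seed = 12)
  sim <- generate_proteome(cfg)
  genes <- generate_gene_models(sim$truth, seed = 13)
  ann <- annotate_proteome(sim$proteins)
  # the default plan covers all four types and all three phases
  expect_setequal(unique(genes$plan$pattern_type),
                  c("type1_no_intron", "type2_hinge", "type3_basic", "type4_both"))
  expect_setequal(unique(genes$truth$phase[genes$truth$region != "outside"]),
                  c("P0", "P1", "P2"))
  for (id in names(genes$models)) {
    pat <- classify_intron_pattern(genes$models[[id]], ann[[id]])
    expect_identical(pat$pattern_type,
                     genes$plan$pattern_type[genes$plan$gene_id == id])
    want <- genes$truth[genes$truth$gene_id == id &
                          genes$truth$region != "outside", ]
    got <- pat$introns[pat$introns$region != "outside", ]
    expect_identical(nrow(got), nrow(want))
    if (nrow(want)) {
      m <- match(want$coding_offset, got$coding_offset)
      expect_identical(got$region[m], want$region)
      expect_identical(got$phase[m], want$phase)
    }
  }
})

test_that("atypical intron layouts and length mismatches are flagged", {
  ann <- make_annotation("g1", c("SAQRLEA", "SASALEA"), basic_start = 5L)
  # annotation spans residues 5..20 (basic), protein must be long enough
  prot_len <- 60L
  cds <- 3L * (prot_len + 1L)
  # two introns inside the basic region (coding nt 13..60): atypical
  m <- model_from_lengths(c(20, 21, cds - 41))
  pat <- classify_intron_pattern(m, ann, protein_length = prot_len)
  expect_true(pat$atypical)
  expect_identical(pat$pattern_type, "atypical")
  # intronless: type 1
  m0 <- model_from_lengths(cds)
  expect_identical(classify_intron_pattern(m0, ann, protein_length = prot_len)$pattern_type,
                   "type1_no_intron")
  expect_error(classify_intron_pattern(m0, ann, protein_length = 10L),
               "encodes")
})

test_that("intron placement is invisible to protein length and strand", {
  lens <- c(33, 45, 222) # 300 nt total
  for (strand in c("+", "-")) {
    m <- model_from_lengths(lens, strand = strand)
    expect_identical(cds_to_protein_length(cds_length(m)), 99)
  }
  m1 <- model_from_lengths(300)
  expect_identical(cds_to_protein_length(cds_length(m1)), 99)
})

test_that("intron_count_stats histograms and group fractions are exact", {
  models <- c(lapply(1:3, function(i) model_from_lengths(300, sprintf("a%d", i))),
              list(model_from_lengths(c(90, 90, 120), "b1")))
  st <- intron_count_stats(models)
  expect_identical(st$histogram$n_introns, c(0L, 2L))
  expect_identical(st$histogram$n_genes, c(3L, 1L))

  # deterministic S-like plant: 45 of 48 genes intronless -> 93.75%
  s_models <- c(lapply(1:45, function(i) model_from_lengths(300, sprintf("s%d", i))),
                lapply(1:3, function(i) model_from_lengths(c(150, 150), sprintf("t%d", i))))
  grp <- stats::setNames(rep("S", 48), vapply(s_models, `[[`, "", "gene_id"))
  st <- intron_count_stats(s_models, groups = grp)
  expect_identical(st$per_group$intronless_fraction, 0.9375)
  expect_identical(percentage(st$per_group$n_intronless, st$per_group$n_genes), 93.8)

  expect_identical(nrow(intron_count_stats(list())$histogram), 0L)
})
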