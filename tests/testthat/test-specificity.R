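templates <- load_group_templates()

window_from <- function(...) {
  # build a 30-char window from (position = letter) pairs over a 'Z' background
  spec <- list(...)
  w <- rep("Z", 30)
  for (pos in names(spec)) w[as.integer(pos)] <- spec[[pos]]
  paste(w, collapse = "")
}

test_that("signature windows are 30 columns anchored at the invariant Asn", {
  p <- generate_protein("B", 3, seed = 2, flank_len = 10L)
  ann <- annotate_domain(p$record)
  win <- extract_signature_window(ann, p$record$sequence)
  expect_identical(nchar(win), 30L)
  expect_identical(substr(win, 11, 20), "RNRESAQLSR") # group B fixed columns
  expect_identical(win, p$truth$window)

  # N at position 8: only 7 upstream residues, columns 1-4 padded
  seq <- paste0(strrep("A", 7), "N", strrep("Q", 7), "R", strrep("S", 20))
  ann <- annotate_domain(list(id = "edge", sequence = seq))
  expect_null(ann) # hinge is all S: no zipper, so fake the annotation
  fake <- structure(list(n_pos = 8L), class = "bzip_annotation")
  win <- extract_signature_window(fake, seq)
  expect_identical(substr(win, 1, 4), "----")
  expect_identical(substr(win, 12, 12), "N")
  expect_identical(nchar(win), 30L)
})

test_that("match_group applies fixed-column templates with specificity-then-priority", {
  # group D: all 15 fixed columns present
  d_win <- window_from(`9` = "L", `10` = "A", `11` = "Q", `12` = "N", `13` = "Q",
                       `14` = "Q", `15` = "A", `16` = "A", `17` = "Q", `18` = "K",
                       `19` = "S", `20` = "R", `24` = "K", `25` = "A", `26` = "Y",
                       `27` = "V", `28` = "Q", `29` = "Q")
  call <- match_group(d_win, templates)
  expect_identical(call$group, "D")
  expect_identical(call$binding_site, "C-box sequence")
  expect_identical(call$matched_positions, 15L)

  # group A matches its own literal K at the Asn anchor column
  a_win <- window_from(`10` = "M", `11` = "I", `12` = "K",
                       `25` = "Q", `26` = "A", `27` = "Y")
  call <- match_group(a_win, templates)
  expect_identical(call$group, "A")
  expect_match(call$binding_site, "ABREs")

  # ...and tolerates the canonical N there (annotator-derived windows)
  a_win_n <- window_from(`10` = "M", `11` = "I", `12` = "N", `20` = "R",
                         `25` = "Q", `26` = "A", `27` = "Y")
  call <- match_group(a_win_n, templates)
  expect_identical(call$group, "A")
  expect_identical(call$matched_positions, 5L) # tolerated column not counted

  expect_identical(match_group(strrep("Z", 30), templates)$group, "unclassified")
  expect_identical(match_group(strrep("Z", 30), templates)$binding_site, "unknown")
  expect_error(match_group("ZZZ", templates), "30 columns")
})

test_that("more literally matched fixed columns beat sparser templates", {
  # K at 20 satisfies both I (literal) and J (tolerated anchor): I wins
  call <- match_group(window_from(`12` = "N", `20` = "K"), templates)
  expect_identical(call$group, "I")
  expect_identical(call$matched_positions, 1L)
  # a full group-B window also satisfies G/M/S (5 columns): B wins with 10
  b <- strsplit("**********RNRESAQLSR**********", "")[[1]]
  b[b == "*"] <- "Z"
  call <- match_group(paste(b, collapse = ""), templates)
  expect_identical(call$group, "B")
  expect_identical(call$matched_positions, 10L)
  # exhaustive cross-check of the winner's match count
  counts <- vapply(seq_len(nrow(templates)), function(k) {
    cols <- templates$columns[[k]]
    sum(vapply(1:30, function(j) !is.null(cols[[j]]) && b[j] %in% cols[[j]],
               logical(1)))
  }, integer(1))
  expect_identical(max(counts), 10L)
  expect_identical(templates$group[which.max(counts)], "B")
})

test_that("classify_proteome recovers planted groups and partitions the set", {
  groups <- rep(templates$group, each = 5)
  cfg <- sim_config(n_proteins = length(groups), seed = 9)
  sim <- generate_proteome(cfg, groups = groups)
  ann <- annotate_proteome(sim$proteins)
  cls <- classify_proteome(ann, sim$proteins)
  expect_true(all(cls$counts[templates$group] == 5L))
  expect_identical(sum(cls$counts), length(ann))
  truth_grp <- sim$truth$group[match(cls$calls$protein_id, sim$truth$protein_id)]
  expect_identical(cls$calls$group, truth_grp)

  # permutation invariance
  perm <- sample(nrow(sim$proteins))
  cls2 <- classify_proteome(ann[perm], sim$proteins[perm, ])
  m <- match(cls$calls$protein_id, cls2$calls$protein_id)
  expect_identical(cls$calls$group, cls2$calls$group[m])

  empty <- classify_proteome(list(), sim$proteins)
  expect_identical(nrow(empty$calls), 0L)
})

test_that("random windows are unclassified at least as often as planted ones", {
  set.seed(13)
  rand_rate <- mean(vapply(1:200, function(i) {
    w <- paste(sample(setdiff(LETTERS, "B"), 30, replace = TRUE), collapse = "")
    match_group(w, templates)$group == "unclassified"
  }, logical(1)))
  cfg <- sim_config(n_proteins = 50, seed = 10)
  sim <- generate_proteome(cfg)
  ann <- annotate_proteome(sim$proteins)
  planted_rate <- mean(classify_proteome(ann, sim$proteins)$calls$group ==
                         "unclassified")
  expect_identical(planted_rate, 0)
  expect_gte(rand_rate, planted_rate)
})
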