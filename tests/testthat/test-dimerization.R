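test_that("residue_class follows the charged/acidic-like/interface partition", {
  expect_identical(residue_class("K"), "basic")
  expect_identical(residue_class("R"), "basic")
  expect_identical(residue_class(c("E", "D")), c("acidic", "acidic"))
  expect_identical(residue_class("Q"), "acidic_like")
  expect_identical(residue_class("N"), "polar_N")
  expect_identical(residue_class(c("L", "I", "V", "F", "M")),
                   rep("hydrophobic", 5))
  expect_identical(residue_class("G"), "other")
  expect_error(residue_class("KK"), "single letters")
})

test_that("classify_ge_pair reproduces the four electrostatic pair families", {
  expect_identical(classify_ge_pair("K", "K"), "repulsive_basic")
  expect_identical(classify_ge_pair("R", "K"), "repulsive_basic")
  expect_identical(classify_ge_pair("E", "E"), "repulsive_acidic")
  expect_identical(classify_ge_pair("E", "D"), "repulsive_acidic")
  expect_identical(classify_ge_pair("E", "Q"), "repulsive_acidic")
  expect_identical(classify_ge_pair("R", "E"), "attractive_basic_acidic")
  expect_identical(classify_ge_pair("K", "E"), "attractive_basic_acidic")
  for (g in c("E", "D")) for (e in c("R", "K")) {
    expect_identical(classify_ge_pair(g, e), "attractive_acidic_basic")
  }
  expect_identical(classify_ge_pair("A", "E"), "incomplete")
  expect_identical(classify_ge_pair("K", "Q"), "incomplete") # Q is not acidic enough
})

test_that("classify_ge_pair is total and argument swap flips only the attractive order", {
  swap_map <- c(repulsive_basic = "repulsive_basic",
                repulsive_acidic = "repulsive_acidic",
                attractive_basic_acidic = "attractive_acidic_basic",
                attractive_acidic_basic = "attractive_basic_acidic",
                incomplete = "incomplete")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (g in aa) for (e in aa) {
    t1 <- classify_ge_pair(g, e)
    expect_true(t1 %in% names(swap_map))
    expect_identical(classify_ge_pair(e, g), unname(swap_map[t1]))
    expect_identical(t1, oracle_pair_type(g, e))
  }
})

test_that("position frequencies are normalized and recover degenerate inputs", {
  ann <- make_annotation("p1", c("ANQRLEE", "KNSALDK"))
  tab <- position_frequency_table(list(ann))
  a_tab <- tab[tab$position == "a", ]
  expect_identical(a_tab$residue, "N")
  expect_identical(a_tab$frequency, 1)
  for (p in unique(tab$position)) {
    expect_equal(sum(tab$frequency[tab$position == p]), 1)
  }
  expect_error(position_frequency_table(list()), "no annotations")
})

test_that("pooled planted frequencies are recovered within binomial error", {
  cfg <- sim_config(n_proteins = 400, seed = 21)
  sim <- generate_proteome(cfg)
  ann <- annotate_proteome(sim$proteins)
  tab <- position_frequency_table(ann)
  asn_a <- tab$frequency[tab$position == "a" & tab$residue == "N"]
  n_slots <- sum(tab$count[tab$position == "a"])
  expect_lt(abs(asn_a - 0.25), 3 * sqrt(0.25 * 0.75 / n_slots))
  leu_d <- tab$frequency[tab$position == "d" & tab$residue == "L"]
  expect_lt(abs(leu_d - 0.59), 3 * sqrt(0.59 * 0.41 / n_slots))
  # all planted d residues are canonical interface letters
  expect_true(all(tab$class[tab$position == "d"] == "hydrophobic"))
})

test_that("asn_frequency_per_heptad uses occupied a slots as denominators", {
  anns <- list(make_annotation("p1", c("ANQRLEE", "ANSALDK")),
               make_annotation("p2", c("AAQRLEE", "ANSALDK", "ASSALDK")))
  af <- asn_frequency_per_heptad(anns)
  expect_identical(af$n_proteins, c(2L, 2L, 1L)) # p2 alone reaches heptad 3
  expect_identical(af$frequency[af$heptad == 2], 1)
  expect_identical(af$frequency[af$heptad == 1], 0.5)
  expect_identical(af$frequency[af$heptad == 3], 0)
})

test_that("per-heptad pair frequencies match brute-force enumeration", {
  # all (E, K) pairs -> attractive_acidic_basic frequency 1 at every index
  ann <- make_annotation("p1", c("EAQRLKE", "EASALKK", "EASSLKA"))
  gf <- ge_pair_frequency_per_heptad(list(ann))
  expect_identical(gf$attractive_acidic_basic, c(1, 1))
  expect_identical(gf$interactive, c(1, 1))
  expect_identical(gf$n_pairs, c(1L, 1L)) # the last heptad contributes no pair

  cfg <- sim_config(n_proteins = 150, seed = 22)
  sim <- generate_proteome(cfg)
  ann <- annotate_proteome(sim$proteins)
  gf <- ge_pair_frequency_per_heptad(ann)
  oracle <- oracle_ge_frequencies(ann)
  for (h in gf$heptad) {
    sub <- oracle[oracle$h == h, ]
    expect_identical(gf$n_pairs[gf$heptad == h], nrow(sub))
    for (pt in c("repulsive_basic", "repulsive_acidic",
                 "attractive_basic_acidic", "attractive_acidic_basic",
                 "incomplete")) {
      expect_equal(gf[[pt]][gf$heptad == h], mean(sub$type == pt))
    }
    expect_equal(gf$interactive[gf$heptad == h] +
                   gf$incomplete[gf$heptad == h], 1)
  }
})

test_that("dimer_propensity applies the documented thresholds", {
  homo <- make_annotation("h", c("SAQRLEA", "SNSALEA", "ENSALKA"))
  s <- dimer_propensity(homo)
  expect_identical(s$propensity, "homodimer_favoring")
  expect_identical(s$asn_a_count, 2L)
  expect_identical(s$n_pairs, 2L) # n_heptads - 1

  hetero <- make_annotation("x", c("KAQRLEA", "SASALKA", "SASALEA"))
  s <- dimer_propensity(hetero) # (K,K) pair at index 1
  expect_identical(s$repulsive_basic, 1L)
  expect_identical(s$propensity, "heterodimer_favoring")

  neither <- make_annotation("n", c("SAQRLEA", "SASALEA"))
  expect_identical(dimer_propensity(neither)$propensity, "indeterminate")

  mixed <- make_annotation("m", c("SNQRLEA", "SNSALEA", "SKSALEA", "SRSALEA"))
  s <- dimer_propensity(mixed) # 2 Asn + 2 charged at a, no repulsive pair
  expect_identical(s$charged_a_count, 2L)
  expect_identical(s$propensity, "mixed")

  tab <- dimerize_proteome(list(homo, hetero))
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$n_pairs ==
    tab$repulsive_basic + tab$repulsive_acidic + tab$attractive_basic_acidic +
    tab$attractive_acidic_basic + tab$incomplete))
})
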