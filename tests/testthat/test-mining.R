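# Candidate extraction, X-pattern synthesis, pattern statistics and the
# greedy selection of the library.

single_chain_forest_m <- function(entries) {
  cluster_forest(data.frame(chain = paste0(entries, "_A"),
                            C100 = seq_along(entries),
                            C75 = seq_along(entries)), c(100, 75))
}

# alphabet without H/Q/W/E/R/T so no accidental His runs or motif matches
random_aa_fixed <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "D", "F", "G", "I", "K", "L", "M", "N"),
               n, replace = TRUE), collapse = "")
}

test_that("match_pattern honours X wildcards and overlaps", {
  expect_equal(match_pattern("ASXTGGQQMGR", "ASNTGGQQMGR"), 1L)
  expect_equal(match_pattern("XXX", random_aa(10)), 1:8)
  expect_equal(match_pattern("SSPAK", "GGSSPAKGG"), 3L)
  expect_equal(match_pattern("AA", "AAA"), 1:2)      # overlapping
  expect_equal(match_pattern("WWWW", "ACDEF"), integer(0))
})

test_that("candidates are majority-disordered stretches of C100 clusters", {
  seq10 <- "ACDEFGHIKL"
  recs <- chain_records(c("E1", "E2"), "A", seq10,
                       c("UUUUUSSSSS", "SSSSSSSSSS"))
  fo <- cluster_forest(data.frame(chain = c("E1_A", "E2_A"),
                                  C100 = 1L, C75 = 1L), c(100, 75))
  # positions 1-5 have fraction 0.5: "half the cases" is inclusive
  expect_equal(extract_candidates(recs, fo), "ACDEF")

  recs2 <- chain_records(c("E1", "E2"), "A", seq10, "SSSSSSSSSS")
  expect_equal(length(extract_candidates(recs2, fo)), 0L)

  recs3 <- chain_records("E1", "A", seq10, "UUUSSSSSSS")
  fo3 <- cluster_forest(data.frame(chain = "E1_A", C100 = 1L, C75 = 1L),
                        c(100, 75))
  expect_equal(extract_candidates(recs3, fo3), "ACD")

  # duplicates across clusters are dropped, first occurrence kept
  recs4 <- chain_records(c("E1", "E2"), "A", c(seq10, paste0(seq10, seq10)),
                         c("UUUUUSSSSS", paste0(strrep("S", 10), "UUUUUSSSSS")))
  fo4 <- cluster_forest(data.frame(chain = c("E1_A", "E2_A"),
                                   C100 = c(1L, 2L), C75 = c(1L, 2L)),
                        c(100, 75))
  expect_equal(extract_candidates(recs4, fo4), "ACDEF")
})

test_that("allowed substitutions follow the 5-residue bands", {
  expect_equal(allowed_substitutions(c(3, 4, 5)), c(0L, 0L, 0L))
  expect_equal(allowed_substitutions(c(6, 8, 10)), c(1L, 1L, 1L))
  expect_equal(allowed_substitutions(c(11, 13, 15)), c(2L, 2L, 2L))
  expect_equal(allowed_substitutions(16), 3L)  # 3/16 subs keeps >= 80% id
})

test_that("X-pattern synthesis takes the closure of divergence unions", {
  cand <- "ASMTGGQQMGR"
  homs <- c("ASMTGGNNMGR", "ASMTSSQQMGR", "ASNTGGQQMGR")
  got <- synthesize_xpatterns(cand, homs)
  # the published subset of the closure, single divergences first
  expect_true(all(c("ASMTGGQQMGR", "ASMTGGXXMGR", "ASMTXXQQMGR",
                    "ASXTGGQQMGR", "ASMTXXXXMGR", "ASXTXXXXMGR") %in% got))
  # full pairwise closure of the three divergence sets has 2^3 members
  expect_setequal(got, c("ASMTGGQQMGR", "ASMTGGXXMGR", "ASMTXXQQMGR",
                         "ASXTGGQQMGR", "ASMTXXXXMGR", "ASXTGGXXMGR",
                         "ASXTXXQQMGR", "ASXTXXXXMGR"))
  expect_equal(got[1], cand)
  expect_equal(effective_length(c("ASXTXXXXMGR", cand)), c(6L, 11L))

  # a homologue identical to the candidate contributes nothing
  expect_equal(synthesize_xpatterns(cand, cand), cand)

  # disjoint single mismatches at i and j give the four subset patterns
  got2 <- synthesize_xpatterns("ACDEFG", c("WCDEFG", "ACDEFW"))
  expect_setequal(got2, c("ACDEFG", "XCDEFG", "ACDEFX", "XCDEFX"))

  expect_error(synthesize_xpatterns("ACDEFG", "ACD"), "same length")
  expect_error(synthesize_xpatterns("ACDEFG", "WWDEFG"), "exceeds")
})

test_that("find_homologs respects the substitution budget", {
  cand <- "ACDEFGHI"                      # length 8: one substitution
  pool <- c("ACDEFGHI", "ACDEFGHW", "ACDEFGWW", "WCDEFGHI", "ACDEF")
  expect_equal(find_homologs(cand, pool), c("ACDEFGHW", "WCDEFGHI"))
  expect_equal(find_homologs("ACDEF", pool), character(0))  # 3-5: none
})

test_that("pattern_stats counts covered residues with two-level weights", {
  fo1 <- cluster_forest(data.frame(chain = "E1_A", C100 = 1L, C75 = 1L),
                        c(100, 75))
  recs <- chain_records("E1", "A", "QWERT", "UUUUS")
  st <- pattern_stats("QWERT", recs, fo1)
  expect_equal(st[c("n_u", "n_f", "c_u", "c_f", "d")],
               list(n_u = 4, n_f = 1, c_u = 1L, c_f = 0L, d = 3))

  st0 <- pattern_stats("WWWWW", recs, fo1)
  expect_equal(st0$d, 0)
  expect_equal(st0$c_u + st0$c_f, 0L)

  # two C100 sub-clusters inside one C75: means then mean of means
  recs2 <- chain_records(c("E1", "E2", "E3"), "A",
                         c("QWERT", "QWERT", "QWERT"),
                         c("UUUUS", "UUSSS", "UUUUU"))
  fo2 <- cluster_forest(data.frame(chain = c("E1_A", "E2_A", "E3_A"),
                                   C100 = c(1L, 1L, 2L), C75 = 1L),
                        c(100, 75))
  st2 <- pattern_stats("QWERT", recs2, fo2)
  expect_equal(st2$n_u, ((4 + 2) / 2 + 5) / 2)
  expect_equal(st2$n_f, ((1 + 3) / 2 + 0) / 2)

  # consumed residues are not counted again
  consumed <- list(E1_A = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  st3 <- pattern_stats("QWERT", recs, fo1, consumed = consumed)
  expect_equal(st3$n_u, 2)
  expect_equal(st3$n_f, 1)
})

test_that("pattern_stats on singleton clusters equals naive counts", {
  set.seed(51)
  motif <- "MKVLYW"
  seqs <- vapply(1:6, function(i) {
    s <- random_aa(40)
    paste0(substr(s, 1, 17), motif, substr(s, 18, 40))
  }, "")
  masks <- vapply(seq_along(seqs), function(i)
    paste(sample(c("U", "S"), nchar(seqs[i]), TRUE), collapse = ""), "")
  recs <- chain_records(sprintf("E%d", 1:6), "A", seqs, masks)
  fo <- cluster_forest(data.frame(chain = paste0("E", 1:6, "_A"),
                                  C100 = 1:6, C75 = 1:6), c(100, 75))
  st <- pattern_stats(motif, recs, fo)
  naive <- rowSums(vapply(seq_along(seqs), function(i)
    naive_pattern_counts(motif, seqs[i], masks[i]), numeric(2)))
  expect_equal(st$n_u, unname(naive["u"]))
  expect_equal(st$n_f, unname(naive["s"]))
})

test_that("greedy selection applies C1-C3, consumption and D >= 25", {
  expect_equal(nrow(greedy_select(character(0),
                                  chain_records("E1", "A", "AAAA", "SSSS"),
                                  single_chain_forest_m("E1"))), 0L)

  # present in only 4 clusters: fails C1, never selected
  p4 <- plant_motifs(list(list(letters = "QWERTY", n_clusters = 4)),
                     seed = 52)
  lib4 <- greedy_select(extract_candidates(p4$records, p4$forest),
                        p4$records, p4$forest, d_min = 0)
  expect_equal(nrow(lib4), 0L)

  # planted disordered in 6 clusters, 5 residues: selected with d = 30
  p6 <- plant_motifs(list(list(letters = "QWERT", n_clusters = 6)),
                     seed = 53)
  lib6 <- greedy_select(extract_candidates(p6$records, p6$forest),
                        p6$records, p6$forest)
  expect_equal(lib6$pattern, "QWERT")
  expect_equal(lib6$d, 30)
  expect_gte(lib6$d, 25)

  # planted ordered everywhere: fails C3
  po <- plant_motifs(list(list(letters = "QWERTYK", n_clusters = 6,
                               disordered = FALSE)), seed = 54)
  expect_equal(length(extract_candidates(po$records, po$forest)), 0L)
  lib0 <- greedy_select("QWERTYK", po$records, po$forest, d_min = 0)
  expect_equal(nrow(lib0), 0L)

  # low-complexity candidates are filtered out up front
  expect_equal(nrow(greedy_select(c("GSGSGSGS", "KKKKKK"),
                                  p6$records, p6$forest, d_min = 0)), 0L)
})

test_that("greedy recovery of planted motifs is exact and deterministic", {
  spec <- list(list(letters = "QWERTYK", n_clusters = 7),
               list(letters = "MKVLY", n_clusters = 6),
               list(letters = "DDHKW", n_clusters = 5))
  px <- plant_motifs(spec, chains_per_cluster = 2, seed = 55)
  cands <- extract_candidates(px$records, px$forest)
  lib <- greedy_select(cands, px$records, px$forest)
  # exactly the planted motifs, in descending planted-weight order
  expect_equal(lib$pattern, c("QWERTYK", "MKVLY", "DDHKW"))
  expect_equal(lib$d, c(7 * 7, 6 * 5, 5 * 5))
  expect_equal(lib$c_u, c(7L, 6L, 5L))

  # determinism: identical inputs give byte-identical libraries
  px2 <- plant_motifs(spec, chains_per_cluster = 2, seed = 55)
  lib2 <- greedy_select(extract_candidates(px2$records, px2$forest),
                        px2$records, px2$forest)
  expect_identical(lib, lib2)
})

test_that("consumption makes matched residue sets disjoint across picks", {
  # two overlapping candidates: the second only scores its residual residues
  recs <- do.call(rbind, lapply(1:6, function(i)
    chain_records(sprintf("E%d", i), "A", "GGAQWERTYKAGG",
                  "SSUUUUUUUUUSS")))
  fo <- single_chain_forest_m(sprintf("E%d", 1:6))
  lib <- greedy_select(c("AQWERTYKA", "QWERTYK"), recs, fo, d_min = 0)
  expect_equal(lib$pattern, "AQWERTYKA")
  expect_equal(nrow(lib), 1L)  # the nested pattern has nothing left to claim

  # with disjoint patterns both are kept and scores add independently
  recs2 <- do.call(rbind, lapply(1:6, function(i)
    chain_records(sprintf("F%d", i), "A", "AQWERTYKAGGMKVLYW",
                  "UUUUUUUUUSSUUUUUU")))
  fo2 <- single_chain_forest_m(sprintf("F%d", 1:6))
  lib2 <- greedy_select(c("AQWERTYKA", "MKVLYW"), recs2, fo2, d_min = 0)
  expect_equal(lib2$pattern, c("AQWERTYKA", "MKVLYW"))
  expect_equal(lib2$d, c(54, 36))
})

test_that("histidine-tag proximity is measured and binned", {
  # far: no His run anywhere near the occurrences
  far <- chain_records(c("E1", "E2"), "A",
                       c(paste0("QWERT", random_aa_fixed(60, 61)),
                         paste0(random_aa_fixed(60, 62), "QWERT")),
                       strrep("S", 65))
  got <- histag_proximity("QWERT", far)
  expect_equal(got$pc, 0)
  expect_equal(got$bin, "PC = 0%")

  # near: adjacent to an H6 tag
  near <- chain_records("E1", "A", paste0("HHHHHH", "QWERT", "GG"),
                        strrep("S", 13))
  got <- histag_proximity("QWERT", near)
  expect_equal(got$pc, 100)
  expect_equal(got$bin, "PC = 100%")

  # 1 of 3 occurrences near: 33.33 falls in the inclusive middle bin
  seqs3 <- c(paste0("QWERT", strrep("G", 50)),
             paste0("QWERT", strrep("G", 50)),
             paste0("QWERT", strrep("G", 10), "HHHH"))
  recs <- chain_records(c("E1", "E2", "E3"), "A", seqs3,
                        vapply(seqs3, function(s) strrep("S", nchar(s)), ""))
  got <- histag_proximity("QWERT", recs)
  expect_equal(got$pc, 100 / 3, tolerance = 1e-12)
  expect_equal(got$bin, "33% <= PC <= 67%")

  # separation of exactly `window` residues no longer counts as near
  gap40 <- chain_records("E1", "A",
                         paste0("QWERT", strrep("G", 40), "HHHH"),
                         strrep("S", 49))
  expect_equal(histag_proximity("QWERT", gap40)$pc, 0)
  gap39 <- chain_records("E1", "A",
                         paste0("QWERT", strrep("G", 39), "HHHH"),
                         strrep("S", 48))
  expect_equal(histag_proximity("QWERT", gap39)$pc, 100)

  # pattern that never occurs
  got <- histag_proximity("WWWWW", near)
  expect_true(is.na(got$pc))
  expect_equal(got$bin, "not_applicable")
})
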