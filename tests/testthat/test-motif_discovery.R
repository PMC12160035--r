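test_that("segmentation yields five forward and five reverse windows", {
  s <- segment_tripeptides("ABCDEFG")
  expect_equal(s$forward, c("ABC", "BCD", "CDE", "DEF", "EFG"))
  expect_equal(s$reverse, c("GFE", "FED", "EDC", "DCB", "CBA"))
  expect_equal(segment_tripeptides("AAAAAAA"),
               list(forward = rep("AAA", 5), reverse = rep("AAA", 5)))
  expect_error(segment_tripeptides("ABC"), "length 7")
})

test_that("a 638-peptide pool segments into exactly 6380 tripeptides", {
  pool <- random_pool(638, seed = 101)
  st <- count_abundance(pool)
  expect_equal(sum(st$abundance), 6380L)
  expect_equal(sum(st$abundance), 5L * 2L * 638L)
})

test_that("abundance counting keeps orientations separate and distinct keys", {
  st <- count_abundance(c("SLHTAAA", "CLHTDDD"))
  lht <- st[st$motif == "LHT", ]
  thl <- st[st$motif == "THL", ]
  expect_equal(lht$n_forward, 2L)
  expect_equal(lht$n_reverse, 0L)
  expect_equal(thl$n_forward, 0L)
  expect_equal(thl$n_reverse, 2L)
  expect_equal(st$abundance, st$n_forward + st$n_reverse)
  expect_equal(sum(st$abundance), 20L)
})

test_that("count_abundance matches the brute-force window-scan oracle", {
  set.seed(7)
  for (rep in 1:20) {
    pool <- random_pool(sample(3:40, 1))
    st <- count_abundance(pool)
    or <- oracle_abundance(pool)
    expect_setequal(st$motif, or$motif)
    idx <- match(st$motif, or$motif)
    expect_equal(st$n_forward, or$n_forward[idx])
    expect_equal(st$n_reverse, or$n_reverse[idx])
  }
})

test_that("multiplicity weighting re-expands the redundant pool", {
  derep <- dereplicate(c("AAAAAAA", "AAAAAAA", "CCCCCCC"))
  plain <- count_abundance(derep)
  expect_equal(sum(plain$abundance), 20L)  # 2 representatives
  weighted <- count_abundance(
    derep, discovery_config(weight_by_multiplicity = TRUE))
  expect_equal(sum(weighted$abundance), 30L)  # 3 clones
  expect_equal(weighted$abundance[weighted$motif == "AAA"], 20L)
})

test_that("shuffle-invariant pools give p_raw of 1", {
  pool <- c("AAAAAAA", "AAAAAAA")
  st <- count_abundance(pool)
  st <- permutation_test(st, pool,
                         discovery_config(n_permutations = 50, rng_seed = 1))
  expect_equal(st$p_raw[st$motif == "AAA"], 1.0)
})

test_that("permutation p-values are seeded-reproducible and in (0, 1]", {
  pool <- random_pool(60, seed = 55)
  st <- count_abundance(pool)
  cfg <- discovery_config(n_permutations = 200, rng_seed = 99)
  p1 <- permutation_test(st, pool, cfg)$p_raw
  p2 <- permutation_test(st, pool, cfg)$p_raw
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 <= 1))
  # a different seed gives a different (but valid) realisation
  p3 <- permutation_test(
    st, pool, discovery_config(n_permutations = 200, rng_seed = 100))$p_raw
  expect_false(identical(p1, p3))
})

test_that("abundance is conserved inside permutation replicates", {
  # every motif's null count is <= total windows, and the add-one
  # estimator bounds: with B replicates, p_raw is k/(B+1) for integer k
  pool <- random_pool(20, seed = 77)
  st <- count_abundance(pool)
  B <- 100L
  st <- permutation_test(st, pool,
                         discovery_config(n_permutations = B, rng_seed = 3))
  k <- st$p_raw * (B + 1)
  expect_equal(k, round(k))
  expect_true(all(k >= 1 & k <= B + 1))
})

test_that("within-peptide shuffling is available as an alternative null", {
  pool <- random_pool(40, seed = 13)
  st <- count_abundance(pool)
  cfg <- discovery_config(n_permutations = 100, rng_seed = 8,
                          shuffle = "within-peptide")
  st <- permutation_test(st, pool, cfg)
  expect_true(all(st$p_raw > 0 & st$p_raw <= 1))
})

test_that("Bonferroni adjustment is m * p clipped at 1 and monotone in m", {
  st <- data.frame(motif = c("AAA", "CCC", "GGG"),
                   abundance = c(5L, 4L, 3L),
                   p_raw = c(0.01, 0.01, 1e-5))
  adj <- bonferroni_adjust(st, discovery_config())
  expect_equal(adj$p_adj, pmin(1, 3 * st$p_raw))
  expect_equal(attr(adj, "bonferroni_m"), 3L)

  adj8000 <- bonferroni_adjust(st, discovery_config(bonferroni_m = "all-8000"))
  expect_equal(adj8000$p_adj, pmin(1, 8000 * st$p_raw))
  expect_equal(adj8000$p_adj[3], 0.08)
  expect_true(all(adj8000$p_adj >= adj$p_adj))   # monotone in m
  expect_true(all(adj$p_adj >= st$p_raw))
})

test_that("selection applies abundance OR significance with recorded reasons", {
  st <- data.frame(
    motif = c("AAA", "CCC", "GGG", "TTT"),
    abundance = c(25L, 5L, 30L, 10L),
    p_adj = c(0.2, 0.01, 0.001, 0.5))
  sel <- select_motifs(st, discovery_config())
  expect_equal(sel$selected[match(c("AAA", "CCC", "GGG", "TTT"), sel$motif)],
               c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(sel$selection_reason[sel$motif == "AAA"], "abundant")
  expect_equal(sel$selection_reason[sel$motif == "CCC"], "significant")
  expect_equal(sel$selection_reason[sel$motif == "GGG"],
               "abundant,significant")
  # ordering: abundance desc, then p_adj asc
  expect_equal(sel$motif, c("GGG", "AAA", "TTT", "CCC"))

  # the threshold is strict: exactly 20 is not "above twenty"
  st2 <- data.frame(motif = "AAA", abundance = 20L, p_adj = 0.9)
  expect_false(select_motifs(st2, discovery_config())$selected)
})

test_that("an engineered 6-abundant / 7-significant fixture selects the union of 9", {
  n_both <- 4L
  st <- data.frame(
    motif = sprintf("M%02d", 1:20),
    abundance = c(rep(30L, 2), rep(25L, n_both), rep(10L, 3), rep(5L, 11)),
    p_adj = c(rep(0.5, 2), rep(0.01, n_both), rep(0.02, 3), rep(0.9, 11)))
  # 6 motifs above 20, 7 significant, 4 in both sets
  expect_equal(sum(st$abundance > 20), 6L)
  expect_equal(sum(st$p_adj < 0.05), 7L)
  sel <- select_motifs(st, discovery_config())
  expect_equal(sum(sel$selected), 9L)
})

test_that("motif extension recovers a shared consensus around the anchor", {
  out <- extend_motifs("PFP", c("ASPFPTG", "CSPFPTD"))
  expect_equal(out$consensus, "SPFPT")
  expect_true(out$extended)
  expect_equal(out$n_supporters, 2L)
  expect_true(all(out$column_support[[1L]] == 1))

  # no agreement outside the anchor: unextended, consensus = anchor
  none <- extend_motifs("PFP", c("AAPFPGG", "CCPFPTT", "DDPFPSS"))
  expect_equal(none$consensus, "PFP")
  expect_false(none$extended)
})

test_that("supporters found through the reversed orientation are re-oriented", {
  # GFEDCBA read backwards contains ABC; both supporters share DABCE
  out <- extend_motifs("ABC", c("QDABCEF", "FECBADG"))
  expect_equal(out$n_supporters, 2L)
  expect_true(grepl("ABC", out$consensus))
  expect_true(all(vapply(out$supporters[[1L]],
                         function(p) grepl("ABC", p), logical(1))))
})

test_that("anchors with fewer than two supporters are skipped with a notice", {
  expect_message(
    out <- extend_motifs("WWW", c("ASPFPTG", "CSPFPTD")),
    "skipped")
  expect_equal(nrow(out), 0L)
})

test_that("a spiked pool yields the spiked 5-mer as an extended motif", {
  sim <- generate_nnk_library(638, rng_seed = 21,
                              spikes = c(SPFPT = 0.15))
  pool <- dereplicate(data.frame(clone_id = sim$truth$clone_id,
                                 peptide = sim$truth$peptide))
  cfg <- discovery_config(n_permutations = 200, rng_seed = 22)
  disc <- discover_motifs(pool, cfg)
  sel <- disc$stats[disc$stats$selected, ]
  # the spiked 5-mer's forward tripeptides are selected and rank high
  expect_true(all(c("SPF", "PFP", "FPT") %in% sel$motif))
  expect_true(all(match(c("SPF", "PFP", "FPT"), disc$stats$motif) <= 10))
  expect_true("SPFPT" %in% disc$extended$consensus)
})

test_that("empty pools yield empty tables without error", {
  st <- count_abundance(character(0))
  expect_equal(nrow(st), 0L)
  disc <- discover_motifs(character(0),
                          discovery_config(n_permutations = 10, rng_seed = 1))
  expect_equal(disc$pool_size, 0L)
})
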