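test_that("potential site counts match enumeration oracles", {
  # frozen enumeration-derived values
  expect_equal(count_sites("TTT", kappa = 1)[["S"]], 1 / 3)
  expect_equal(count_sites("TTT", kappa = 2)[["S"]], 0.5)
  # CTC: third position fully synonymous (four-fold Leu box)
  s_ctc <- count_sites("CTC", kappa = 1)
  expect_gte(s_ctc[["S"]], 1)
  # classic NG86 equivalence at kappa = 1 over every sense codon
  for (cod in all_sense_codons()) {
    cs <- count_sites(cod, kappa = 1)
    expect_equal(cs[["S"]], oracle_ng86_S(cod), tolerance = 1e-12)
    expect_equal(cs[["S"]] + cs[["N"]], 3)
  }
  expect_error(count_sites("TAA"), "stop")
  expect_error(count_sites("TTT", kappa = 0), "kappa")
})

test_that("pairwise codon difference counting averages over pathways", {
  expect_equal(count_pair_differences("TTT", "TTT"), c(sd = 0, nd = 0))
  expect_equal(count_pair_differences("TTT", "TTC"), c(sd = 1, nd = 0))
  expect_equal(count_pair_differences("TTT", "GTA"), c(sd = 0.5, nd = 1.5))
  # symmetry and Hamming conservation on random sense pairs
  set.seed(101)
  sense <- all_sense_codons()
  for (i in 1:40) {
    c1 <- sample(sense, 1); c2 <- sample(sense, 1)
    v <- count_pair_differences(c1, c2)
    expect_equal(v, count_pair_differences(c2, c1))
    hamming <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    expect_equal(unname(v[1] + v[2]), hamming)
    expect_equal(v, oracle_pair_diffs(c1, c2), tolerance = 1e-12)
  }
  expect_error(count_pair_differences("TGA", "TTT"), "stop")
})

test_that("Jukes-Cantor correction follows the closed form and its domain", {
  expect_equal(jc_correct(0), 0)
  expect_equal(jc_correct(0.05), -0.75 * log(1 - 4 * 0.05 / 3))
  expect_equal(jc_correct(0.05), 0.05174, tolerance = 1e-4)
  expect_error(jc_correct(0.75), "saturation")
  expect_error(jc_correct(-0.1), "non-negative")
})

test_that("distance matrices reproduce hand-derived cases", {
  # identical sequences give zero matrices
  dup <- allele_set(c(a = "AAATTTGGG", b = "AAATTTGGG", c = "AAATTTGGG"))
  d0 <- dnds_distances(dup)
  expect_true(all(d0$dS == 0) && all(d0$dN == 0))

  # 9-codon pair with one synonymous third-position difference:
  # S = 3 per sequence (1/3 per codon), pS = 1/3, dS = jc(1/3), dN = 0
  a <- allele_set(c(x = paste(c(rep("AAA", 8), "TTT"), collapse = ""),
                    y = paste(c(rep("AAA", 8), "TTC"), collapse = "")))
  d <- dnds_distances(a, kappa = 1)
  expect_equal(d$pS[1, 2], 1 / 3)
  expect_equal(d$dS[1, 2], jc_correct(1 / 3))
  expect_equal(d$dS[1, 2], 0.4408, tolerance = 1e-4)
  expect_equal(d$dN[1, 2], 0)
  expect_equal(unname(d$LS_per_seq), c(3, 3))

  # codon-block permutation leaves distances unchanged
  set.seed(7)
  sim <- simulate_alleles(sim_config(seed = 2, n_alleles = 6, n_codons = 60,
                                     branch_scale = 0.05, pbr_mask = NULL))
  x <- sim$alleles
  d1 <- dnds_distances(x, kappa = 2)
  perm <- sample(x$n_codons)
  shuffled <- vapply(x$seq, function(s) {
    cods <- substring(s, 3 * (seq_len(60) - 1) + 1, 3 * seq_len(60))
    paste(cods[perm], collapse = "")
  }, character(1))
  d2 <- dnds_distances(allele_set(shuffled), kappa = 2)
  expect_equal(d1$dS, d2$dS)
  expect_equal(d1$dN, d2$dN)
})

test_that("gapped codons are deleted pairwise", {
  x <- paste(c(rep("AAA", 8), "TTT"), collapse = "")
  y <- paste(c(rep("AAA", 8), "TTC"), collapse = "")
  z <- paste(c("---", rep("AAA", 7), "TTC"), collapse = "")
  d <- dnds_distances(allele_set(c(x = x, y = y, z = z)))
  # x vs z drops the gapped codon: 8 usable codons, S = 8/3, one syn diff
  expect_equal(d$pS["x", "z"], 1 / (8 / 3))
  expect_equal(d$dN["x", "z"], 0)
  # x vs y keeps all 9 codons
  expect_equal(d$pS["x", "y"], 1 / 3)
})

test_that("dN/dS approaches 1 when synonymous and nonsynonymous rates are equal", {
  tr <- ape::read.tree(text = "(A:0.03,B:0.03);")
  sim <- simulate_alleles(sim_config(seed = 21, n_codons = 6000, tree = tr,
                                     pbr_mask = NULL, omega_background = 1))
  d <- dnds_distances(sim$alleles, kappa = 2)
  expect_equal(d$dN[1, 2] / d$dS[1, 2], 1, tolerance = 0.2)
})

test_that("group summaries average within-group pairs", {
  # three alleles in one group with known pairwise dS
  base <- paste(rep("AAA", 8), collapse = "")
  a <- allele_set(c(g1 = paste0(base, "TTT"), g2 = paste0(base, "TTC"),
                    g3 = paste0(base, "TTT"), h1 = paste0(base, "TTT"),
                    h2 = paste0(base, "TTT")))
  d <- dnds_distances(a)
  gs <- group_summary(d, c(g1 = "G", g2 = "G", g3 = "G", h1 = "H", h2 = "H"))
  g <- gs[gs$group == "G", ]
  expect_equal(g$n_pairs, 3L)
  vals <- c(d$dS["g1", "g2"], d$dS["g1", "g3"], d$dS["g2", "g3"])
  expect_equal(g$dS_mean, mean(vals))
  expect_equal(g$dS_max, max(vals))
  # singleton group is skipped with a warning
  expect_warning(
    gs2 <- group_summary(d, c(g1 = "G", g2 = "G", h1 = "solo")),
    "solo"
  )
  expect_equal(gs2$group, "G")
})

test_that("kappa moment estimator recovers transition enrichment", {
  tr <- ape::read.tree(text = "(A:0.04,B:0.04);")
  sim <- simulate_alleles(sim_config(seed = 31, n_codons = 8000, tree = tr,
                                     pbr_mask = NULL, omega_background = 1,
                                     kappa = 4))
  k <- estimate_kappa(sim$alleles)
  expect_gt(k, 2)  # strongly above the unbiased value 1
})
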