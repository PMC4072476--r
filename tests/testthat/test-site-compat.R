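test_that("segregating sites are classified by spectrum and effect", {
  # invariant alignment: nothing segregates
  inv <- allele_set(setNames(rep("ATGGCTAAA", 4), paste0("s", 1:4)))
  expect_equal(nrow(classify_sites(inv)), 0L)

  # ten Phe codons, one TTC variant: synonymous singleton at column 3
  seqs <- setNames(rep("TTTGCA", 10), paste0("s", 1:10))
  seqs[10] <- "TTCGCA"
  cs <- classify_sites(allele_set(seqs))
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$site, 3L)
  expect_equal(cs$category, "singleton")
  expect_equal(cs$effect, "synonymous")
  expect_equal(cs$spectrum, "T:9/C:1")

  # Lys/Arg second-position split 5:5: nonsynonymous informative
  seqs2 <- setNames(c(rep("AAA", 5), rep("AGA", 5)), paste0("s", 1:10))
  cs2 <- classify_sites(allele_set(seqs2))
  expect_equal(cs2$category, "informative")
  expect_equal(cs2$effect, "nonsynonymous")

  # first-position C/T: synonymous for Leu (CTA/TTA) but not Arg/Trp
  # (CGG/TGG) -> mixed
  seqs3 <- c(a = "CTA", b = "TTA", c = "CGG", d = "TGG")
  cs3 <- classify_sites(allele_set(seqs3))
  c1 <- cs3[cs3$site == 1L, ]
  expect_equal(c1$category, "informative")
  expect_equal(c1$effect, "mixed")
})

test_that("four-gamete test distinguishes three from four gametes", {
  expect_true(four_gamete_compatible(c("A", "A", "G"), c("A", "G", "A")))
  expect_false(four_gamete_compatible(c("A", "A", "G", "G"),
                                      c("A", "G", "A", "G")))
  # gaps are dropped pairwise: the gapped row cannot supply a gamete
  expect_true(four_gamete_compatible(c("A", "A", "G", "-"),
                                     c("A", "G", "A", "G")))
  # multi-allelic sites reduce to the two major states and say so
  r <- four_gamete_compatible(c("A", "A", "G", "G", "C"),
                              c("A", "G", "A", "G", "A"))
  expect_false(r[1])
  expect_true(attr(r, "reduced"))
  expect_error(four_gamete_compatible("A", c("A", "G")), "same number")
})

test_that("pair counts follow the informative-site combinatorics", {
  # 4 alleles, k synonymous informative third-position columns
  make_aln <- function(k) {
    pats <- list(c("T", "T", "C", "C"), c("T", "C", "T", "C"),
                 c("T", "C", "C", "T"))
    cods <- lapply(seq_len(k), function(i) {
      paste0("TT", pats[[(i - 1) %% 3 + 1]])
    })
    seqs <- vapply(1:4, function(s) {
      paste(vapply(cods, function(cd) cd[[s]], ""), collapse = "")
    }, "")
    allele_set(setNames(seqs, paste0("s", 1:4)))
  }
  expect_equal(compatibility_report(make_aln(2))$n_pairs, 1L)
  rep5 <- compatibility_report(make_aln(5))
  expect_equal(rep5$n_pairs, choose(5, 2))
  expect_warning(r1 <- compatibility_report(make_aln(1)), "fewer than 2")
  expect_equal(r1$n_pairs, 0L)
})

test_that("sites simulated on one tree without recurrent mutation are all compatible", {
  sim <- simulate_alleles(sim_config(seed = 41, n_alleles = 10,
                                     n_codons = 400, branch_scale = 0.04,
                                     pbr_mask = NULL, infinite_sites = TRUE))
  rep <- compatibility_report(sim$alleles, synonymous_only = FALSE)
  expect_gt(rep$n_informative, 1L)
  expect_equal(nrow(rep$incompatible), 0L)
})

test_that("an engineered recombinant creates incompatibility across its breakpoint", {
  tr <- ape::read.tree(text = paste0(
    "(((A1:0.002,A2:0.002):0.02,(B1:0.002,B2:0.002):0.02):0.02,",
    "(E1:0.002,E2:0.002):0.02);"))
  sim <- simulate_alleles(sim_config(seed = 43, n_codons = 500, tree = tr,
                                     pbr_mask = NULL, infinite_sites = TRUE,
                                     omega_background = 0.5))
  s <- sim$alleles$seq
  rec <- make_recombinant(s[["A1"]], s[["E1"]], 250)
  aln <- allele_set(c(s, REC = unname(rec)))
  rep <- compatibility_report(aln, synonymous_only = FALSE)
  expect_gt(nrow(rep$incompatible), 0L)
  bp_nt <- 3 * 249
  spans <- rep$incompatible$site1 <= bp_nt & rep$incompatible$site2 > bp_nt
  expect_true(any(spans))
  # without the recombinant the same data are fully compatible
  rep0 <- compatibility_report(allele_set(s), synonymous_only = FALSE)
  expect_equal(nrow(rep0$incompatible), 0L)
})
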