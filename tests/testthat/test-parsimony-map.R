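test_that("simple characters map where expected", {
  # two leaves, one synonymous difference: one change on the path
  a2 <- allele_set(c(A = "TTT", B = "TTC"))
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  m2 <- fitch_map(t2, a2, synonymous_only = TRUE)
  expect_equal(sum(m2$edge_counts), 1)
  expect_equal(m2$per_site$n_changes, 1L)
  expect_equal(path_ks(m2, "A", "B"), 1)
  expect_equal(path_ks(m2, "A", "A"), 0)

  # perfect character on a 4-leaf tree: single change on the internal branch
  a4 <- allele_set(c(A = "TTT", B = "TTT", C = "TTC", D = "TTC"))
  t4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m4 <- fitch_map(t4, a4, sites = 3L)
  expect_equal(sum(m4$edge_counts), 1)
  td <- tidy(m4)
  internal <- td[grepl("^node", td$child_label), ]
  expect_equal(sum(internal$n_changes), 1)

  expect_error(fitch_map(t4, allele_set(c(A = "TTT", B = "TTT")), sites = 3L),
               "missing")
})

test_that("per-site counts equal the exhaustive-labeling minimum", {
  set.seed(53)
  for (i in 1:60) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n)
    states <- setNames(sample(NUCS, n, replace = TRUE), tr$tip.label)
    aln <- allele_set(setNames(paste0(states, "TT"), tr$tip.label))
    m <- fitch_map(tr, aln, sites = 1L)
    expect_equal(m$per_site$n_changes, oracle_parsimony_min(tr, states))
  }
})

test_that("per-site totals agree with an independent parsimony engine", {
  sim <- simulate_alleles(sim_config(seed = 59, n_alleles = 12,
                                     n_codons = 150, branch_scale = 0.06,
                                     pbr_mask = NULL))
  x <- sim$alleles
  tr <- sim$truth$tree
  cls <- classify_sites(x)
  m <- fitch_map(tr, x, sites = cls$site)
  ph <- phangorn::phyDat(t(sapply(strsplit(x$seq[tr$tip.label], ""), identity)),
                         type = "DNA")
  expect_equal(sum(m$per_site$n_changes),
               as.numeric(phangorn::parsimony(tr, ph)))
})

test_that("mapped totals are invariant to rooting position", {
  sim <- simulate_alleles(sim_config(seed = 61, n_alleles = 8,
                                     n_codons = 200, branch_scale = 0.05,
                                     pbr_mask = NULL))
  x <- sim$alleles
  tr <- sim$truth$tree
  cls <- classify_sites(x)
  m1 <- fitch_map(tr, x, sites = cls$site)
  un <- ape::unroot(tr)
  m2 <- fitch_map(un, x, sites = cls$site,
                  outgroup = tr$tip.label[[3L]])
  expect_equal(m1$per_site$n_changes, m2$per_site$n_changes)
  # total mapped changes are a rooting-independent quantity; individual
  # path sums may differ between equally parsimonious attributions
  expect_equal(sum(m1$edge_counts), sum(m2$edge_counts))
})

test_that("homoplasy-free simulations are recovered exactly and path counts dominate pairwise differences", {
  sim <- simulate_alleles(sim_config(seed = 67, n_alleles = 10,
                                     n_codons = 400, branch_scale = 0.05,
                                     pbr_mask = NULL, infinite_sites = TRUE))
  x <- sim$alleles
  tr <- sim$truth$tree
  # map all variable sites so synonymous and nonsynonymous truth both count
  cls <- classify_sites(x)
  m <- fitch_map(tr, x, sites = cls$site)
  expect_equal(sum(m$edge_counts),
               sum(sim$truth$branch_syn) + sum(sim$truth$branch_nonsyn))
  # synonymous-only map reproduces the true synonymous path counts
  msyn <- fitch_map(tr, x, synonymous_only = TRUE)
  km <- ks_matrix(msyn)
  tips <- rownames(km$ks)
  expect_equal(km$ks, sim$truth$ks_true[tips, tips])
  # path counts can only exceed the directly observed pairwise
  # synonymous differences (parallel/back changes add, never subtract)
  obs_syn <- function(n1, n2) {
    cods1 <- substring(x$seq[[n1]], 3 * (1:400) - 2, 3 * (1:400))
    cods2 <- substring(x$seq[[n2]], 3 * (1:400) - 2, 3 * (1:400))
    sum(vapply(seq_len(400), function(k) {
      if (cods1[k] == cods2[k]) 0 else
        count_pair_differences(cods1[k], cods2[k])[["sd"]]
    }, numeric(1)))
  }
  for (pr in list(c(1, 2), c(3, 7), c(5, 10))) {
    n1 <- tips[pr[1]]; n2 <- tips[pr[2]]
    expect_gte(km$ks[n1, n2], obs_syn(n1, n2) - 1e-9)
  }
})
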