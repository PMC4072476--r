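test_that("simulation is reproducible and respects degenerate configs", {
  cfg <- sim_config(seed = 5, n_alleles = 6, n_codons = 50,
                    branch_scale = 0.05, pbr_mask = NULL)
  s1 <- simulate_alleles(cfg)
  s2 <- simulate_alleles(cfg)
  expect_identical(s1$alleles$seq, s2$alleles$seq)
  expect_identical(s1$truth$branch_syn, s2$truth$branch_syn)

  # zero-length tree: every sequence equals the ancestor
  tr0 <- ape::read.tree(text = "(A:0,B:0,C:0);")
  s0 <- simulate_alleles(sim_config(seed = 5, tree = tr0, n_codons = 40,
                                    pbr_mask = NULL))
  expect_equal(length(unique(unname(s0$alleles$seq))), 1L)
  expect_equal(sum(s0$truth$column_hits), 0L)
})

test_that("emitted sequences stay in frame with no internal stops", {
  sim <- simulate_alleles(sim_config(seed = 9, n_alleles = 10,
                                     n_codons = 257))
  x <- sim$alleles
  expect_equal(x$alignment_length %% 3L, 0L)
  cm <- matrix(unlist(lapply(x$seq, function(s)
    substring(s, 3 * (1:257) - 2, 3 * (1:257)))), nrow = length(x$seq),
    byrow = TRUE)
  expect_false(any(cm %in% c("TAA", "TAG", "TGA")))
})

test_that("bookkeeping in the truth record is self-consistent", {
  sim <- simulate_alleles(sim_config(seed = 13, n_alleles = 8,
                                     n_codons = 120, branch_scale = 0.06,
                                     pbr_mask = NULL))
  tr <- sim$truth
  expect_equal(sum(tr$branch_syn) + sum(tr$branch_nonsyn),
               sum(tr$column_hits))
  expect_true(all(tr$ks_true >= 0))
  expect_equal(diag(tr$ks_true), setNames(rep(0, 8), rownames(tr$ks_true)))
  # infinite sites: at most one hit per column
  sim2 <- simulate_alleles(sim_config(seed = 13, n_alleles = 8,
                                      n_codons = 300, branch_scale = 0.03,
                                      pbr_mask = NULL,
                                      infinite_sites = TRUE))
  expect_lte(max(sim2$truth$column_hits), 1L)
})

test_that("elevated omega inside the mask raises dN/dS there", {
  tr <- ape::read.tree(text = "(A:0.02,B:0.02);")
  mask <- region_mask(1:40, offset = 0L)
  sim <- simulate_alleles(sim_config(seed = 17, n_codons = 400, tree = tr,
                                     pbr_mask = mask, omega_pbr = 10,
                                     omega_background = 0.5))
  inside <- apply_region_mask(sim$alleles, mask, "include")
  outside <- apply_region_mask(sim$alleles, mask, "exclude")
  din <- dnds_distances(inside, kappa = 2)
  dout <- dnds_distances(outside, kappa = 2)
  ratio_in <- din$dN[1, 2] / max(din$dS[1, 2], 1e-6)
  ratio_out <- dout$dN[1, 2] / max(dout$dS[1, 2], 1e-6)
  expect_gt(ratio_in, ratio_out)
  expect_gt(din$dN[1, 2], dout$dN[1, 2])
})

test_that("splice construction behaves at and away from its edges", {
  s1 <- paste(rep("AAATTT", 4), collapse = "")
  s2 <- paste(rep("GGGCCC", 4), collapse = "")
  expect_error(make_recombinant(s1, s2, 1), "splice")
  expect_error(make_recombinant(s1, s2, 99), "splice")
  expect_error(make_recombinant(s1, substr(s2, 1, 6), 2), "equal length")
  expect_equal(make_recombinant(s1, s1, 4), s1)
  child <- make_recombinant(s1, s2, 5)
  diffs <- which(strsplit(child, "")[[1]] != strsplit(s1, "")[[1]])
  expect_true(all(diffs > 3 * 4))  # all differences right of the breakpoint
  expect_equal(substr(child, 13, 24), substr(s2, 13, 24))
})

test_that("infeasible infinite-sites configurations error out", {
  tr <- ape::read.tree(text = "(A:0.5,B:0.5);")
  expect_error(
    simulate_alleles(sim_config(seed = 1, tree = tr, n_codons = 30,
                                pbr_mask = NULL, infinite_sites = TRUE)),
    "infeasible"
  )
})
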