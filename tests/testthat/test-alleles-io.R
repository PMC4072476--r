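test_that("allele_set validates alignment, frame and alphabet", {
  a <- allele_set(c(a = "ATGAAATTT", b = "ATGAAGTTT", c = "ATGAAATTC"))
  expect_s3_class(a, "allele_set")
  expect_equal(length(a), 3L)
  expect_equal(a$alignment_length, 9L)
  expect_equal(a$n_codons, 3L)

  expect_error(allele_set(c(a = "ATGAAATTT", b = "ATGAAA")), "alignment error")
  expect_error(allele_set(c(a = "ATGAAATTTG")), "frame error")
  expect_error(allele_set(c(a = "ATGAAAXTT")), "alphabet error")
  expect_error(allele_set(c("ATGAAATTT")), "named")
  expect_error(allele_set(c(a = "ATG", a = "ATG")), "duplicate")
})

test_that("IMGT-style allele names parse and round-trip", {
  p <- parse_allele_names(c("HLA-DRB1*11:01", "Patr-DRB1*03:01:02",
                            "Mamu-DRB1*03", "not_an_allele"))
  expect_equal(p$prefix, c("HLA", "Patr", "Mamu", NA))
  expect_equal(p$locus, c("DRB1", "DRB1", "DRB1", NA))
  expect_equal(p$lineage, c("11", "03", "03", NA))
  expect_equal(p$fields[[1]], c("11", "01"))
  expect_equal(p$fields[[2]], c("03", "01", "02"))
  # round trip through the formatter
  expect_equal(format_allele_names(p)[1:3],
               c("HLA-DRB1*11:01", "Patr-DRB1*03:01:02", "Mamu-DRB1*03"))
  expect_true(is.na(format_allele_names(p)[4]))
})

test_that("FASTA read/write round-trips content", {
  a <- allele_set(c("HLA-DRB1*03:01" = "ATGAAATTTGGG",
                    "HLA-DRB1*11:01" = "ATGAAGTTTGG-"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alleles(a, f)
  b <- read_alleles(f)
  expect_equal(b$seq, a$seq)
  expect_equal(names(b), names(a))
})

test_that("region masks partition the alignment cleanly", {
  seqs <- c(x = paste(rep("ATG", 10), collapse = ""),
            y = paste(rep("ATA", 10), collapse = ""))
  a <- allele_set(seqs)
  m <- region_mask(2)
  ex <- apply_region_mask(a, m, "exclude")
  inc <- apply_region_mask(a, m, "include")
  expect_equal(ex$n_codons, 9L)
  expect_equal(inc$n_codons, 1L)
  # include + exclude partition: disjoint and jointly exhaustive
  expect_equal(ex$alignment_length + inc$alignment_length, a$alignment_length)
  expect_equal(paste0(inc$seq[["x"]], ex$seq[["x"]]),
               paste0(substr(seqs[["x"]], 4, 6),
                      substr(seqs[["x"]], 1, 3), substr(seqs[["x"]], 7, 30)))
  expect_error(apply_region_mask(a, region_mask(11), "exclude"), "mask error")
})

test_that("excluding a 27-codon PBR from a 257-codon CDS leaves 690 nt", {
  mask <- default_pbr_mask(offset = 29L)
  expect_length(mask$positions, 27L)
  seqs <- setNames(rep(paste(rep("GCT", 257), collapse = ""), 2), c("a", "b"))
  a <- allele_set(seqs)
  nonpbr <- apply_region_mask(a, mask, "exclude")
  expect_equal(nonpbr$n_codons, 230L)
  expect_equal(nonpbr$alignment_length, 690L)
  pbr <- apply_region_mask(a, mask, "include")
  expect_equal(pbr$n_codons, 27L)
})

test_that("mask files parse with comments and offsets", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "3", " 1 ", "", "2 # trailing"), f)
  m <- read_region_mask(f, offset = 1L)
  expect_equal(m$positions, c(1L, 2L, 3L))
  expect_equal(m$offset, 1L)
  writeLines(c("1", "x"), f)
  expect_error(read_region_mask(f), "non-integer")
})

test_that("non-functional sequences are dropped at ingestion", {
  good <- paste(rep("ATG", 5), collapse = "")
  stopped <- paste(c("ATG", "TAA", rep("ATG", 3)), collapse = "")
  a <- allele_set(c(ok = good, bad = stopped))
  expect_warning(f <- drop_nonfunctional(a), "bad")
  expect_equal(names(f), "ok")
})
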