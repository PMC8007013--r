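test_that("RSCU follows the family-normalized definition", {
  # Ala family with counts (3,1,0,0): first codon has RSCU 3
  cnt <- setNames(c(3, 1, 0, 0), c("GCT", "GCC", "GCA", "GCG"))
  expect_equal(rscu(cnt, "GCT"), 3)
  expect_equal(rscu(cnt, "GCC"), 1)
  expect_equal(rscu(cnt, "GCA"), 0)
  # uniform counts give 1 for every member; a 1-codon family is always 1
  u <- setNames(rep(2, 4), c("GCT", "GCC", "GCA", "GCG"))
  expect_true(all(vapply(names(u), rscu, numeric(1), counts = u) == 1))
  expect_equal(rscu(c(ATG = 7), "ATG"), 1)
  expect_error(rscu(cnt, "TAA"), "sense codon")
  expect_error(rscu(c(TTT = 1), "GGG"), "zero total")
})

test_that("RSCPU normalizes within amino-acid-pair families", {
  # Met-Phe is encoded by exactly 2 codon pairs; counts (4, 0)
  pc <- c(ATGTTT = 4)
  expect_equal(rscpu(pc, "ATGTTT"), 2)
  expect_equal(rscpu(pc, "ATGTTC"), 0)
  expect_equal(rscpu(pc, c("ATG", "TTT")), 2)
  # Met-Trp has a single codon pair: always 1
  expect_equal(rscpu(c(ATGTGG = 9), "ATGTGG"), 1)
  # uniform usage over the family gives 1
  pu <- c(ATGTTT = 5, ATGTTC = 5)
  expect_equal(rscpu(pu, "ATGTTT"), 1)
  expect_error(rscpu(pc, "ATGTAA"), "sense codon")
})

test_that("%MinMax hits the extremes and is scale invariant", {
  u <- toy_codon_usage()
  gc <- Biostrings::GENETIC_CODE
  fam_extreme <- function(which) {
    vapply(split(names(unclass(u)), gc[names(unclass(u))]), function(fam) {
      f <- unclass(u)[fam]
      fam[if (which == "max") which.max(f) else which.min(f)]
    }, character(1))
  }
  # windows made only of most-frequent synonymous codons score +100
  best <- paste(rep(fam_extreme("max")[c("A", "L", "R", "S", "G", "P")], 4),
                collapse = "")
  expect_true(all(percent_minmax(best, u, 17) == 100))
  # only least-frequent codons score -100
  worst <- paste(rep(fam_extreme("min")[c("A", "L", "R", "S", "G", "P")], 4),
                 collapse = "")
  expect_true(all(percent_minmax(worst, u, 17) == -100))
  # single-codon families (Met, Trp) have Max == Avg == Min: value 0
  flat <- paste(rep(c("ATG", "TGG"), 10), collapse = "")
  expect_true(all(percent_minmax(flat, u, 17) == 0))
  # invariant under global rescaling of the usage table
  cds <- sim_cds(60, 0.4, u, seed = 7)
  expect_equal(percent_minmax(cds, u, 17),
               percent_minmax(cds, codon_usage(unclass(u) * 37), 17))
  expect_error(percent_minmax("ATGTGG", u, 17), "shorter than window")
  expect_error(percent_minmax(cds, u, 16), "odd")
})

test_that("CDS splitting rejects internal stops and drops the terminal stop", {
  expect_identical(split_codons("ATGAAATAA"), c("ATG", "AAA"))
  expect_error(split_codons("ATGTAAAAA"), "internal stop")
  expect_error(split_codons("ATGA"), "multiple of 3")
  expect_identical(sum(codon_counts("ATGATGTTT")), 3L)
  expect_identical(codon_pair_counts("ATGATGTTT"),
                   c(ATGATG = 1L, ATGTTT = 1L))
})

test_that("variant codon deltas combine RSCU, RSCPU and %MinMax changes", {
  cnt <- setNames(c(3, 1, 0, 0), c("GCT", "GCC", "GCA", "GCG"))
  u <- toy_codon_usage()
  # 20-codon CDS: GCT at codon 4 (positions 10-12), c.12T>C swaps GCT->GCC
  cds <- paste(c(rep("ATG", 3), "GCT", rep("AAA", 16)), collapse = "")
  v <- parse_hgvs("NM_TEST.1:c.12T>C")
  d <- variant_codon_delta(cds, v, u, counts = cnt, window = 17)
  expect_identical(c(d$old_codon, d$new_codon), c("GCT", "GCC"))
  expect_true(d$synonymous)
  # major (RSCU 3) to minor (RSCU 1): delta -2
  expect_equal(d$delta_rscu, -2)
  expect_length(d$pair_deltas, 2L)       # interior codon: two pairs
  expect_length(d$delta_minmax, 4L)      # windows 1..4 cover codon 4

  # codon 1: exactly one codon pair evaluated
  cds2 <- paste(rep(c("GCT", "GCC", "GCA", "GCG"), 5), collapse = "")
  v1 <- parse_hgvs("NM_TEST.1:c.3T>C")   # first codon GCT -> GCC
  d1 <- variant_codon_delta(cds2, v1, u, window = 17)
  expect_true(d1$synonymous)
  expect_length(d1$pair_deltas, 1L)
  expect_identical(names(d1$pair_deltas), "next")

  # synonymous swap to the same-count codon leaves RSCU unchanged
  cnt2 <- setNames(c(2, 2, 0, 0), c("GCT", "GCC", "GCA", "GCG"))
  d2 <- variant_codon_delta(cds, v, u, counts = cnt2, window = 17)
  expect_equal(d2$delta_rscu, 0)

  expect_error(variant_codon_delta(cds, parse_hgvs("NM_TEST.1:c.12T>A"),
                                   u, window = 17),
               NA)  # GCT->GCA is a valid synonymous change
  expect_error(
    variant_codon_delta(cds, parse_hgvs("NM_TEST.1:c.11A>G"), u),
    "mismatch")  # CDS carries C at position 11, not A
  expect_error(
    variant_codon_delta(cds, parse_hgvs("NM_X.1:c.-5A>G"), u),
    "not in the coding sequence")
})

test_that("rare-codon flag marks bottom-quartile family members", {
  u <- toy_codon_usage()
  gc <- Biostrings::GENETIC_CODE
  ala <- names(gc)[gc == "A"]
  f <- unclass(u)[ala]
  rarest <- ala[which.min(f)]
  commonest <- ala[which.max(f)]
  expect_true(coagvar:::.is_rare_codon(rarest, u))
  expect_false(coagvar:::.is_rare_codon(commonest, u))
  expect_false(coagvar:::.is_rare_codon("ATG", u))  # 1-codon family never rare
  dens <- rare_codon_density(paste(rep(rarest, 20), collapse = ""), u, 17)
  expect_true(all(dens == 1))
})
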