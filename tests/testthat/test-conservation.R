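test_that("edit distance matches definition and is a metric", {
  expect_identical(lev_distance("", "ACG"), 3L)
  expect_identical(lev_distance("kitten", "sitting"), 3L)
  set.seed(11)
  strs <- replicate(9, random_dna(sample(0:6, 1)))
  for (i in 1:20) {
    x <- sample(strs, 3)
    dxy <- lev_distance(x[1], x[2])
    expect_identical(dxy, lev_distance(x[2], x[1]))            # symmetry
    expect_identical(lev_distance(x[1], x[1]), 0L)             # identity
    expect_lte(dxy, lev_distance(x[1], x[3]) + lev_distance(x[3], x[2]))
  }
})

test_that("distance matrix is symmetric, zero-diagonal, computed on de-gapped sequences", {
  m <- msa(c(a = "AC-GT", b = "ACGGT", c = "A---T"), "nuc")
  D <- lev_distance_matrix(m)
  expect_identical(D, t(D))
  expect_identical(unname(diag(D)), c(0L, 0L, 0L))
  expect_identical(D["a", "c"], lev_distance("ACGT", "AT"))
})

test_that("dedup keeps one exemplar per group of identical sequences plus anchors", {
  # single cluster of identical sequences
  m1 <- msa(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "ACGT", e = "ACGT",
              anchor = "TTTT"), "nuc", anchors = "anchor")
  d1 <- dedup_msa(m1)
  expect_identical(sum(!names(d1$seqs) %in% "anchor"), 1L)
  expect_true("anchor" %in% names(d1$seqs))

  # two groups of mutually identical sequences -> one exemplar per group,
  # cross-checked against the brute-force partition of the sequences
  m2 <- msa(c(a = "ACGT", b = "ACGT", c = "ACGT", d = "TTTT", e = "TTTT",
              anchor = "ACGA"), "nuc", anchors = "anchor")
  d2 <- dedup_msa(m2)
  kept <- setdiff(names(d2$seqs), "anchor")
  expect_length(kept, 2L)
  expect_setequal(unique(unname(d2$seqs[kept])), c("ACGT", "TTTT"))

  # anchors-only MSA returned unchanged
  m3 <- msa(c(x = "AC", y = "GT"), "nuc", anchors = c("x", "y"))
  expect_identical(dedup_msa(m3), m3)
})

test_that("dedup is idempotent, never grows, and is deterministic", {
  set.seed(42)
  mutate1 <- function(s) {
    v <- strsplit(s, "")[[1]]
    i <- sample(length(v), 1)
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
    paste(v, collapse = "")
  }
  base <- replicate(3, random_dna(40))
  seqs <- unlist(lapply(1:3, function(g) replicate(5, mutate1(base[g]))))
  names(seqs) <- paste0("g", rep(1:3, each = 5), "_", 1:5)
  m <- msa(seqs, "nuc", anchors = "g1_1")
  d1 <- dedup_msa(m)
  expect_lte(length(d1$seqs), length(m$seqs))
  expect_true("g1_1" %in% names(d1$seqs))
  d2 <- dedup_msa(d1)
  expect_identical(names(d2$seqs), names(d1$seqs))
  expect_identical(names(dedup_msa(m)$seqs), names(d1$seqs))
})

test_that("pairwise fraction matching counts non-gap target columns only", {
  m <- msa(c(r = "ACGT", t1 = "ACGT", t2 = "ACGA", t3 = "AC-A"), "prot")
  expect_equal(pairwise_fraction_matching(m, "r", "t1"), 1.0)
  expect_equal(pairwise_fraction_matching(m, "r", "t2"), 0.75)
  expect_equal(pairwise_fraction_matching(m, "r", "t3"), 2 / 3)
  expect_error(pairwise_fraction_matching(m, "r", "zz"), "unknown")
  m2 <- msa(c(r = "ACGT", g = "----"), "nuc")
  expect_error(pairwise_fraction_matching(m2, "r", "g"), "entirely gaps")
})

test_that("column conservation matches hand counts and handles gaps and zeros", {
  m <- msa(c(ref = "ACGT", s1 = "ACGT", s2 = "ACTT", s3 = "ACAT"), "nuc")
  p <- column_conservation(m, "ref", columns = 3)
  expect_equal(unname(p$p), 0.5)          # 2 of 4 carry the reference G
  expect_equal(p$fraction_matching, unname(p$p))  # single column: exactly P

  # gapped rows excluded from numerator and denominator
  mg <- msa(c(ref = "ACGT", s1 = "AC-T", s2 = "ACGT", s3 = "ACTT"), "nuc")
  pg <- column_conservation(mg, "ref", columns = 3)
  expect_equal(unname(pg$p), 2 / 3)

  # perfect conservation: log-likelihood exactly 0
  mi <- sim_msa(10, 8, q = 1, seed = 3)
  ci <- column_conservation(mi, "ref")
  expect_equal(ci$loglikelihood_sum, 0)
  expect_equal(ci$fraction_matching, 1)

  # a never-matching column contributes -Inf and is reported separately
  mz <- msa(c(ref = "AAAA", s1 = "ACAA", s2 = "ACAA", s3 = "ACAA",
              s4 = "ACAA"), "nuc")
  cz <- column_conservation(mz, "ref", columns = c(1, 2))
  expect_equal(unname(cz$p), c(1, 0.2))
  czz <- column_conservation(mz, "ref")
  expect_identical(czz$zero_columns, integer(0))
  # scoring the reference against the rest of the alignment only:
  # a column nothing else matches has P = 0 and sinks the sum to -Inf
  m0 <- msa(c(ref = "AT", s1 = "AC", s2 = "AC"), "nuc")
  c0 <- column_conservation(m0, "ref", include_ref = FALSE)
  expect_identical(c0$loglikelihood_sum, -Inf)
  expect_identical(c0$zero_columns, 2L)
  expect_true(is.finite(c0$finite_loglikelihood_sum))
  # with the reference counted, its self-match keeps P at 1/n
  cin <- column_conservation(m0, "ref")
  expect_equal(unname(cin$p), c(1, 1 / 3))

  expect_error(column_conservation(m, "ref", columns = 99), "out of range")
})

test_that("fraction matching equals exp(mean log P) when all columns share one P", {
  m <- msa(c(ref = "AAAA", s1 = "AAAA", s2 = "AAAA", s3 = "CCCC"), "nuc")
  cc <- column_conservation(m, "ref")
  expect_true(all(cc$p == 0.75))
  expect_equal(cc$fraction_matching, exp(cc$loglikelihood_mean))
})
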