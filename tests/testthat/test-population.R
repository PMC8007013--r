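test_that("GWAS filtering is inclusive at the padded boundary and strict on p", {
  genes <- data.frame(gene = "VKORC1", chrom = "16", start = 31102000,
                      end = 31106000)
  rec <- data.frame(
    variant = c("at_pad", "past_pad", "at_alpha", "inside_sig", "wrong_chr"),
    chrom = c("16", "16", "16", "16", "7"),
    pos = c(31102000 - 6000, 31102000 - 6001, 31103000, 31103000, 31103000),
    p = c(0.01, 0.01, 0.05, 0.049, 0.01))
  out <- filter_gwas_region(rec, genes, pad = 6000, alpha = 0.05)
  expect_setequal(out$variant, c("at_pad", "inside_sig"))
  expect_error(filter_gwas_region(transform(rec, p = c(0, 0.1, 0.1, 0.1, 0.1)),
                                  genes), "p-values")
})

test_that("simulated GWAS tables are recovered exactly by the filter", {
  genes <- data.frame(gene = c("g1", "g2"), chrom = c("1", "1"),
                      start = c(100000, 400000), end = c(120000, 410000))
  tab <- sim_gwas_table(genes, n_sig = 4, n_decoy = 20, seed = 17)
  out <- filter_gwas_region(tab, genes, pad = 6000, alpha = 0.05)
  expect_setequal(out$variant, attr(tab, "truth"))
})

test_that("carrier probabilities follow Hardy-Weinberg", {
  expect_equal(carrier_probability(0), 0)
  expect_equal(carrier_probability(1), 1)
  expect_equal(carrier_probability(0.5), 0.75)
  expect_error(carrier_probability(1.5), "\\[0, 1\\]")

  expect_equal(prob_any_variant(c(0.1, 0.2)), 1 - 0.81 * 0.64)
  expect_equal(prob_any_variant(c(0.2, 1, 0.001)), 1)
  expect_equal(prob_any_variant(0.3), carrier_probability(0.3))
  expect_equal(prob_any_variant(c(0.1, 0.2), model = "allelic"),
               1 - 0.9 * 0.8)
  expect_message(p <- prob_any_variant(c(0.1, NA)), "missing")
  expect_equal(p, carrier_probability(0.1))
  expect_error(suppressMessages(prob_any_variant(NA_real_)), "no usable")
})

test_that("probability of any variant is monotone and below the union bound", {
  set.seed(23)
  for (i in 1:15) {
    m <- runif(sample(2:6, 1), 0, 0.6)
    p <- prob_any_variant(m)
    expect_lte(p, sum(carrier_probability(m)) + 1e-12)       # union bound
    expect_gte(p, prob_any_variant(m[-1]))                   # set inclusion
    j <- sample(length(m), 1)
    m2 <- m; m2[j] <- min(1, m2[j] + 0.1)
    expect_gte(prob_any_variant(m2), p)                      # per-maf monotone
  }
})

test_that("population risk compares each population with the global column", {
  t5 <- read_frequency_table(extdata("vkorc1_cds_variant_frequencies.tsv"),
                             meta_cols = c("class", "warfarin"))
  syn <- t5$variant[t5$class == "synonymous"]
  pr <- population_risk(t5, variants = syn)
  afr <- pr[pr$population == "African", ]
  # the 19.5% African frequency of one variant dominates the set
  expect_gt(afr$p_any, afr$p_any_global)
  expect_gt(afr$ratio, 2)
  expect_equal(pr$ratio, pr$p_any / pr$p_any_global)
  # adding a variant never lowers the probability
  pr_small <- population_risk(t5, variants = setdiff(syn, "358CT"))
  expect_lte(pr_small[pr_small$population == "African", "p_any"], afr$p_any)
})

test_that("skew scan flags the known African-enriched variant and spiked cells", {
  t5 <- read_frequency_table(extdata("vkorc1_cds_variant_frequencies.tsv"),
                             meta_cols = c("class", "warfarin"))
  sk <- skew_scan(t5)
  hit <- sk[sk$variant == "358CT" & sk$population == "African", ]
  expect_true(hit$flagged)
  expect_equal(hit$pop_maf, 0.19520)
  expect_equal(hit$global_maf, 0.01558)
  expect_gt(hit$fold_change, 5)

  # identical population and global frequencies are never flagged
  even <- sim_freq_table(setNames(rep(0.3, 4), paste0("v", 1:4)),
                         c("P1", "P2", "P3"), noise_sd = 0, seed = 2)
  expect_false(any(skew_scan(even)$flagged))

  # a single spiked cell is flagged, and only that cell (a realistic
  # panel width keeps the weighted global close to the base frequency)
  spiked <- sim_freq_table(setNames(rep(0.01, 5), paste0("v", 1:5)),
                           paste0("P", 1:8),
                           spikes = data.frame(variant = "v2",
                                               population = "P3",
                                               delta = 0.18),
                           noise_sd = 0, seed = 3)
  sk2 <- skew_scan(spiked)
  flg <- sk2[sk2$flagged, ]
  expect_identical(paste(flg$variant, flg$population), "v2 P3")
})

test_that("maximum over other populations matches the published lookups", {
  t5 <- read_frequency_table(extdata("vkorc1_cds_variant_frequencies.tsv"),
                             meta_cols = c("class", "warfarin"))
  m1 <- max_other_population(t5, "358CT", exclude = "African")
  expect_equal(m1$max, 0.01186)
  expect_identical(m1$population, "Latino")
  m2 <- max_other_population(t5, "106GT", exclude = "Ashkenazi Jewish")
  expect_equal(m2$max, 0.0046)
  expect_error(max_other_population(t5, "nope"), "unknown")
})
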