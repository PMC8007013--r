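# coagvar

Variant characterization for coagulation genes whose products interact
with SARS-CoV-2 proteins.

Three human genes central to coagulation — *VKORC1* (vitamin K epoxide
reductase, the warfarin target), *SERPING1* (C1 esterase inhibitor) and
*PABPC4* (activated-platelet protein 1) — encode proteins that bind
SARS-coronavirus proteins, and genetic variants in them are candidate
modifiers of COVID-19–associated coagulopathy. `coagvar` implements the
computational pipeline used to characterize such variants: every stage
takes plain FASTA/TSV inputs, and every stage has a synthetic-data
generator with known ground truth so the whole pipeline is testable
offline.

## What it computes

For a variant set in simplified HGVS c. notation (single-nucleotide
substitutions; `-N` 5' UTR, `N` coding, `N±M` intronic, `*N` 3' UTR):

* **Conservation** — per-column match probability of a reference
  sequence in an MSA, P(xᵢ) = (sequences carrying the reference residue)
  / (non-gap sequences at column i); the additive score Σᵢ log P(xᵢ) is
  non-positive and equals the log-probability of drawing the reference
  from the alignment under column independence. MSAs can first be
  deduplicated by affinity-propagation clustering on the Levenshtein
  distance matrix of the de-gapped sequences (`dedup_msa()`), keeping
  cluster exemplars plus declared anchor sequences.
* **Codon usage (coding variants)** — RSCU
  (n_c / mean count of the synonymous family), RSCPU (the codon-pair
  analogue over pairs encoding the same amino-acid pair), windowed
  %MinMax in [−100, 100], windowed rare-codon density, and per-variant
  deltas of each (`variant_codon_delta()`).
* **mRNA stability** — minimum-free-energy change of a window centered
  on the variant, via a built-in weighted base-pair dynamic program
  (GC −3, AU −2, GU −1, hairpin loops ≥ 3), normalized to a Z-score
  against a null of random single substitutions on the same transcript,
  with a multi-backend consensus rule (mean Z reported only under
  direction agreement; *strong* when every |Z| > 1).
* **Splicing and miRNA regulation** — splice-tool outputs modeled as
  hexamer score tables; a change is *likely* when every table reports a
  nonzero window-score delta exceeding one standard deviation of that
  table's scale, *possible* when all change but not all exceed. miRNA
  binding-score changes are summarized (gained / lost / increase /
  decrease) only when all deltas agree in direction and total ≥ 5.
* **Population frequency** — gnomAD/dbSNP-style tables; per-population
  probability of carrying at least one variant from a set under
  Hardy–Weinberg, 1 − Π(1 − pᵢ)²; skew flagging against the global
  column; GWAS region filtering (gene ± 6000 bp, p < 0.05 strictly).

The packaged data under `inst/extdata/` are the published population
frequency and annotation tables for the three genes, transcribed as
TSV.

## Worked example

```r
library(coagvar)

t5 <- read_frequency_table(
  system.file("extdata", "vkorc1_cds_variant_frequencies.tsv", package = "coagvar"),
  meta_cols = c("class", "warfarin"))

subset(skew_scan(t5), variant == "358CT" & flagged)
#>     variant           population pop_maf global_maf abs_diff fold_change flagged
#> 11    358CT              African  0.1952    0.01558  0.17962   12.528883    TRUE
#> 111   358CT Non-Finnish European  0.0017    0.01558  0.01388    9.164706    TRUE
```

The synonymous warfarin-resistance variant c.358C>T is carried at 19.5%
frequency in African populations against 1.6% globally — a 12.5-fold
skew — and is correspondingly depleted in Europeans. The probability of
carrying at least one synonymous variant from this table:

```r
pr <- population_risk(t5, variants = t5$variant[t5$class == "synonymous"])
pr[pr$population %in% c("African", "East Asian"), ]
#>   population n_variants   p_any p_any_global  ratio difference
#> 2    African         10 0.35659       0.0672 5.3062     0.2894
#> 5 East Asian         10 0.00101       0.0672 0.0151    -0.0662
```

An African-ancestry individual is ~5.3× more likely than the global
average to carry one of these variants; almost all of that excess is
c.358C>T. An MFE change and its Z-score for an intronic variant on a
simulated transcript:

```r
v <- parse_hgvs("NM_024006.4:c.283+837T>C")
tr <- sim_msa(2, 400, q = 1, seed = 11)$seqs[["ref"]]
d <- delta_mfe(tr, 200, "C", window_size = 101)
d
#> <mfe_result> [builtin] window 150-250: WT -83, mutant -81, delta +2
mfe_zscore(d$delta, transcript = tr, window_size = 101,
           n_samples = 200, seed = 1729)$z
#> [1] 1.986
mfe_consensus(c(1.35, 2.2, 1.07))
#> <mfe_consensus> z = (1.350, 2.200, 1.070): mean z 1.540 [strong]
```

A positive delta destabilizes the predicted fold; here the substitution
sits ~2 null standard deviations above random same-transcript changes,
and a three-backend consensus with all |Z| > 1 would be flagged strong.

## Documentation

The methods vignette (`vignettes/coagvar-methods.Rmd`) describes the
statistical model behind each stage, the aggregation rules and their
thresholds, what the synthetic generators do and do not emulate, and
the package's numerical choices and limitations.
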