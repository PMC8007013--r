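---
title: "Methods: variant characterization for coagulation genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant characterization for coagulation genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coagvar)
```

## Scope and model of the data

`coagvar` characterizes single-nucleotide variants of three
coagulation-related genes (*VKORC1*, *SERPING1*, *PABPC4*) whose
protein products interact with SARS-coronavirus proteins. Variants are
named in a restricted HGVS c. notation — substitutions only, which is
the only variant class in the source tables — and carry a region
derived purely from position syntax: a leading `-` places the variant
in the 5' UTR, `*` in the 3' UTR, an exon-anchored `±` offset in an
intron, and a bare position in the CDS. The parser treats the
transcript accession as authoritative and never attempts gene
inference, because published tables occasionally attach an accession to
a prose gene name inconsistently. Internally all coordinates are
1-based at the API surface (matching HGVS and GWAS summary-statistic
conventions); sequence arithmetic is done directly on 1-based indices.

Each annotation stage is independent and joins only in the report
table, so any stage can be run alone, replaced, or fed synthetic input.

## Conservation in multiple sequence alignments

For a reference (wild-type) sequence in an alignment, the per-column
match probability is

$$P(x_i) = \frac{\#\{\text{sequences with the reference residue at } i\}}
               {\#\{\text{non-gap sequences at } i\}}.$$

Gapped rows are excluded from numerator and denominator: a gap records
alignment coverage, not disagreement, and folding it into either count
would conflate the two. The additive score $\sum_i \log P(x_i)$
(natural log) is non-positive, zero only under perfect conservation,
and under column independence equals the log-probability of drawing
the reference residues column-wise from the alignment. The per-column
mean is exposed alongside the sum because the sum scales with the
number of scored columns, which makes cross-protein comparison
otherwise meaningless.

By default the reference is counted as a member of the alignment
(`include_ref = TRUE`), so $P \ge 1/n$ and the additive score is
finite. With `include_ref = FALSE` the reference is scored against the
remaining sequences only; a column where nothing else matches then has
$P = 0$, contributes $-\infty$, and is reported separately together
with a finite sum over the remaining columns, so callers can
distinguish "one catastrophic column" from "uniformly poor".

### Deduplication

Public homolog sets are dominated by near-identical strain sequences,
which would otherwise swamp column statistics. `dedup_msa()` clusters
the *non-anchor* sequences by affinity propagation on the similarity
matrix $-\,\mathrm{Levenshtein}$ of the de-gapped sequences and keeps
only cluster exemplars; anchor sequences (the sequences the analysis
is about) are always retained. Distances are computed on de-gapped
sequences because Levenshtein on aligned strings double-counts
indel columns introduced by the alignment itself.

Numerical choices, all deterministic:

* damping 0.9, at most 1000 message-passing iterations, convergence
  declared after 50 iterations of a stable exemplar set;
* exemplar preference defaults to **half** the median off-diagonal
  similarity. The more common choice, the median itself, sits exactly
  at the decision boundary when all pairwise similarities are alike —
  in that regime it can merge a set of mutually distant exemplars, so
  deduplicating an already-deduplicated alignment would keep shrinking
  it. Halving the preference keeps near-duplicate merging (cluster
  members are far more similar to their exemplar than the typical
  pair) while leaving mutually distant sequences alone, which makes
  the operation idempotent. `preference = "median"` and numeric values
  remain available;
* exactly tied similarity matrices (groups of identical sequences)
  make the messages oscillate symmetrically and never converge; a
  deterministic index-ordered perturbation at $10^{-9}$ of the
  similarity scale breaks the ties without affecting cluster
  structure, and residual ties resolve to the lowest sequence index;
* if message passing still fails to stabilize, the fallback keeps one
  representative per group of identical de-gapped sequences (the
  distance-0 connected components) and warns.

## Codon-usage metrics for coding variants

RSCU is a codon's count divided by the mean count of its synonymous
family (range $[0, k]$ for a $k$-codon family, 1 = unbiased); RSCPU is
the identical construction over codon *pairs*, normalized within all
pairs encoding the same amino-acid pair. Counts can come from the CDS
under analysis (transcript-local view) or from a supplied organism
table — both are exposed because either convention is defensible and
they answer slightly different questions (local composition versus
genomic expectation).

%MinMax compares each sliding window's mean codon usage (Actual)
against the most-used (Max), least-used (Min) and average (Avg)
synonymous alternative at each position:
$+100\,(A - \mathrm{Avg})/(\mathrm{Max} - \mathrm{Avg})$ when
$A > \mathrm{Avg}$, else
$-100\,(\mathrm{Avg} - A)/(\mathrm{Avg} - \mathrm{Min})$; degenerate
families (single-codon, or Max = Avg) contribute 0. The default
window is 17 codons with stride 1 — the convention of the method's
literature — reported at window centers; the statistic is invariant to
a global rescaling of the usage table, which the tests assert.

For a coding substitution, `variant_codon_delta()` reports ΔRSCU of
the affected codon, ΔRSCPU as the mean over the (up to) two codon
pairs containing it (both raw deltas are also returned; terminal
codons have one pair), Δ%MinMax at every window covering the codon,
and a rare-codon flag. "Rare codon" is under-specified in the source
analyses; it is implemented as a documented approximation: the
wild-type codon's usage lies in the bottom quartile of its synonymous
family (single-codon families are never rare), plus a windowed
rare-codon density track for context.

A usage table must cover all 61 sense codons. `toy_codon_usage()` is a
deterministic *constructed* table — geometric fall-off (ratio 0.55)
within each family, scaled to per-thousand — that mimics the shape of
real organism tables (one clear major codon, rare minors) without
claiming any organism's values; real analyses should read an organism
table with `read_codon_usage()`.

## mRNA minimum-free-energy changes

The built-in backend is a Nussinov-style dynamic program: structures
are non-crossing pair sets with hairpin loops of at least 3 unpaired
bases, pair energies GC $-3$, AU $-2$, GU $-1$, fold energy the sum
over pairs, minimized exactly in $O(n^3)$ (implemented in C++). This
is a desk-scale stability *ranker*, not nearest-neighbor
thermodynamics: loop entropies, stacking and pseudoknots are out of
scope. The backend interface is a plain function `seq -> energy`, so a
thermodynamic folder can be swapped in without touching the
normalization layer. The tests hold the DP to exact agreement with an
independent exhaustive enumeration of all structures on sequences up
to length 12.

`delta_mfe()` folds the wild-type and mutant of a window centered on
the variant (default 501 nt, matching the flank width used for miRNA
scoring; truncated at transcript ends) and reports mutant − wild-type
energy, so positive deltas destabilize. Z-scores normalize an observed
delta against a null of `n_samples` (default 1000) random single
substitutions — uniform position, uniform alternate base — on the
*same* transcript with the same window and backend, seeded (default
1729) and bit-reproducible. Random same-transcript substitution was
chosen over dinucleotide-shuffled windows as the null because it asks
the question the annotation needs ("is this substitution's effect
large *for this transcript*?") with no additional modeling
assumptions. A zero null standard deviation (e.g. a window that can
never pair) yields an `NA` z-score with a warning rather than a
division by zero. Each backend is normalized against its own null;
pooling nulls across backends with different energy scales would make
the z-scores incomparable.

The consensus rule over per-backend z-scores: direction agreement
holds when all nonzero z share a sign (exact zeros are neutral); the
mean z is reported only under agreement; the change is *strong* when,
additionally, every $|z| > 1$.

## Splicing and miRNA aggregation rules

External splice-prediction tools are not reimplemented; each is
modeled as a named hexamer score table (`read_score_table()` completes
the map over all 4096 hexamers, defaulting absent keys to 0 and
counting them, so truncated tables are visible). The score of a
position is the sum over the up-to-six hexamers overlapping it within
an 11-nt window clipped at sequence ends. Per table, the delta between
mutant and wild type is compared with one standard deviation of the
table's own score values (`sd_mode = "table"`); the phrase "one
standard deviation from the mean" could equally denote the spread of
per-position window scores, so that reading is available as
`sd_mode = "positional"` and both are unit-tested. The verdict is
*likely* when every table reports a nonzero delta and every delta
exceeds its threshold, *possible* when every table reports a nonzero
delta but not all exceed, *none* otherwise — a change only counts when
all tools see it. Intronic variants carry a highlight flag, intron
splice changes being the more credible signal.

miRNA binding records carry wild-type and mutant scores on the
predictor's 0–100 scale; an absent score means no predicted site and
counts as 0 in the delta, so gains and losses are ordinary deltas. A
summary is issued only when all nonzero deltas share a direction *and*
the total absolute change is at least 5 (under sign agreement the
absolute and net totals coincide; the all-zero case falls out as
"none" before the distinction matters). *Gained*/*lost* are reserved
for sites crossing absence to presence at a score of at least 50 —
the conventional reporting floor of the cited predictor family,
configurable — otherwise *increase*/*decrease*. Upstream (5' UTR)
variants are flagged, a binding change there bearing on translation.
`mirna_global_stats()` pools mean and median deltas over all
variant–miRNA pairs for the dataset-level direction.

## Population-frequency analytics

GWAS records are kept when they fall within a gene interval padded by
6000 bp on both sides (inclusive boundaries — a record exactly at the
pad is in) and have p strictly below 0.05, as the source filter
states. No multiple-testing correction is applied; the upstream
studies report none of these loci as significant after correction, and
the filter is a screen, not a test.

Carrier probabilities use Hardy–Weinberg diploid sampling:
$1 - (1-p)^2$ per variant and $1 - \prod_i (1-p_i)^2$ for at least one
of a set, assuming independence across variants. The allele-counting
alternative $1 - \prod(1-p_i)$ is exposed as `model = "allelic"`
because the source convention is unstated. Independence is wrong in
the presence of linkage disequilibrium — known to occur between the
key synonymous variant and an upstream promoter variant — so the
set-level probabilities should be read as upper-bound-flavored
approximations; missing frequencies are skipped (with a count), never
imputed as zero. The per-population comparison with the global column
is reported both as a ratio and as a difference, the convention again
being unstated.

Skew flagging is explicit configuration, defaults absolute difference
≥ 0.10 or fold change ≥ 5 with the population frequency at least
0.001 (the floor keeps the fold rule from firing on noise-level
frequencies). These defaults mark skews of the size reported for
population-stratified warfarin-response variants (≈19.5% vs ≈1.6%)
while leaving everyday inter-population drift unflagged. Because the
global column is a weighted mean of the populations, a very large
spike in a very small panel drags the global value and can fire the
fold rule on unspiked cells; with realistic panel widths (≥ ~8
populations) the flag set identifies exactly the spiked cells, which
is how the recovery test is framed.

Frequency tables round-trip losslessly: the reader keeps the original
cell strings, blank cells are missing (never zero), duplicate rows
that are bit-identical — which occur in the published tables — are
collapsed with a message, and conflicting duplicates are an error.

## Synthetic-data generators

Every generator takes a mandatory seed, runs on its own stream (seed
plus a stable per-generator offset, so adding a generator never
perturbs existing fixtures) and restores the caller's RNG state.

* `sim_msa()` draws a uniform reference and makes each other sequence
  match it per column with probability $q$, else a uniform different
  residue. With the reference counted, the expected column estimate is
  $(1 + (n-1)q)/n$; the recovery test uses $n = 500$ sequences ×
  60 columns at $q = 0.75$ and checks the estimator against three
  binomial standard errors.
* `sim_cds()` draws amino acids uniformly and codons from a mixture
  interpolating uniform-within-family (bias 0) to always-the-major
  codon (bias 1); bias 1 forces %MinMax to +100 everywhere, bias 0
  centers it near zero. The sign-recovery test uses 200 replicates of
  100 codons at bias 0.5.
* `sim_freq_table()` adds small Gaussian noise (default sd 0.002) to
  per-variant base frequencies, applies spike deltas (errors outside
  $[0,1]$), and computes the global column as the weighted population
  mean — hence always inside the populations' convex hull.
* `sim_hexamer_table()`, `sim_mirna_records()` and `sim_gwas_table()`
  produce score tables of known spread, record sets whose total
  directional change is exact (for probing the ≥ 5 boundary), and GWAS
  tables whose decoys each fail exactly one filter condition, so the
  filter must recover the spiked records exactly.

What the generators deliberately do **not** emulate: phylogenetic
correlation between MSA sequences (rows are i.i.d. given the
reference), amino-acid composition bias, linkage disequilibrium and
shared demography across variants, and realistic RNA thermodynamics.
Passing the recovery tests therefore demonstrates that each stage
measures what it claims under its own model assumptions — not that
those assumptions hold in any particular real dataset.

## Test problem sizes

The suite's simulation sizes — 1000 folding-oracle cases at length
≤ 12, 500 edit-distance oracle cases at length ≤ 7, 500-sequence MSAs,
200 codon-bias replicates, 1000 + 1000 null/evaluation draws at a
101-nt folding window — were chosen as the smallest sizes at which the
binomial/normal error bands in the assertions are meaningfully tight;
the defaults users see (501-nt windows, 1000 null samples) are the
analysis-scale settings.

## Known limitations

* HGVS coverage is substitutions in c. notation only — no indels,
  duplications, or genomic (g.) coordinates, and no transcript-model
  retrieval; positions are taken at face value.
* The built-in folder ranks stability changes; absolute energies are
  not thermodynamic quantities.
* Conservation scores inherit whatever biases the input MSA has;
  deduplication reduces, but cannot remove, database redundancy
  artifacts.
* Carrier probabilities ignore linkage; population labels are taken
  verbatim from the input table and are not harmonized across sources
  (the two packaged tables use different panels).
* The splicing and miRNA stages consume externally produced score
  tables; they aggregate, and cannot be better than, those scores.
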