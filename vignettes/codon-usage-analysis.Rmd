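---
title: "Methods: codon usage bias analysis with codonBias"
author: "codonBias authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage bias analysis with codonBias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonBias)
```

# Scope and model

codonBias implements the classical gene-by-gene analysis of synonymous
codon usage: how unevenly a gene uses the synonyms of each amino acid, how
much of that unevenness is explained by mutational pressure on base
composition, and which codons are preferred where selection is strongest.
The analysis unit is a coding sequence read in frame under the standard
genetic code (61 sense codons; nine 2-fold amino acids, Ile as the single
3-fold, five 4-fold, and Leu/Ser/Arg as 6-fold). Alternative translation
tables are out of scope.

The package assumes its input is a set of annotated CDS, one record per
gene, and enforces only light QC (see below); it does not predict ORFs or
parse feature files.

# Quality filtering

`filterCds()` retains sequences that (i) begin with ATG, (ii) end with a
stop codon at the last complete in-frame codon, (iii) are strictly longer
than `minLenNt` (default 300 nt, so effectively at least 303 nt given
triplet structure), (iv) have length divisible by 3, and (v) are not exact
duplicates of an earlier record (first occurrence kept). Each rejected
record is tallied once, under the first rule it fails, so the tallies plus
retained count always equal the input count, and filtering is idempotent.

Two deliberate conventions: sequences with *internal* stop codons are not
rejected — genome annotations contain them, and the downstream statistics
treat stop codons separately anyway — and codons containing N or other
ambiguity codes are skipped from all counting rather than disqualifying
the gene. The strict `> 300` reading and the non-triplet rejection class
are the package's own choices where common practice varies.

# Composition indices

`compositionProfile()` reports GC, GC1, GC2, GC3, GC12 = (GC1 + GC2)/2,
and the synonymous third-position fractions GC3s / A3s / T3s / C3s / G3s,
all as fractions in [0, 1] (tables render them as percentages). The
terminal stop codon is excluded from every index. The x3s denominators are
the third positions of codons of amino acids with at least two synonyms,
Met/Trp/stops excluded — one self-consistent denominator for all four
bases, so they sum to 1 exactly. (Legacy tools use slightly different
per-base denominators; with this convention GC3s = C3s + G3s by
construction, which we consider the defensible choice and pin in tests.)
Pooled summaries are unweighted means with sample (n − 1) standard
deviations; a single gene reports SD 0.

# Bias indices

**RSCU.** `rscu()` uses the pooled definition `k·x/X` per family. Families
with zero counts give NA, flagged rather than imputed at this level. Both
pooled-counts RSCU and mean-of-per-gene RSCU are obtainable (pool the count
matrix, or average `buildRscuMatrix()` rows); genome reports in the
literature do not always state which they used, and the two differ in the
second decimal on real data.

**ENC.** `enc()` implements Wright's estimator with the corrected family
homozygosity `F = (n·Σp̂² − 1)/(n − 1)` (undefined for n ≤ 1), averaged
within degeneracy classes, and `ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆`.
Numerical conventions, each pinned by a unit test:

* `F = 0` (possible at tiny n, e.g. counts [1, 1]) cannot enter the
  reciprocal average and is treated as undefined for that family.
* If the single 3-fold family (Ile) is undefined, `F̄₃` is replaced by the
  harmonic-style combination `2/(1/F̄₂ + 1/F̄₄)`; if the 6-fold class is
  empty it falls back to `F̄₄`, its nearest class. If the 2-fold or 4-fold
  class is itself empty the ENC is NA.
* The unbiased estimator can exceed 61 on finite samples (e.g. equal
  counts of all 59 codons give a value slightly above 61); results are
  capped at 61. Values below 20 cannot occur.

**Expected ENC and ENC ratio.** The null curve is
`ENCexp(s) = 2 + s + 29/(s² + (1 − s)²)` with `s` = GC3s. Note the
denominator: it is the sum of squared G+C and A+T fractions; a printed
form "S² + (1 − S²)" circulating in the literature collapses to 1
identically and is an evident typo for this expression. The curve's
maximum sits marginally above s = 0.5 (at ~0.502) because of the linear
term; `ENCexp(0.5) = 60.5`. The ENC ratio `(ENCexp − ENCobs)/ENCexp` may
be negative (gene above the curve) and is reported as such.
`encRatioHistogram()` bins ratios into left-closed, right-open intervals
aligned to multiples of the bin width (default 0.1).

**CAI.** `caiWeights()` builds Sharp–Li relative adaptiveness weights
(`w = x/max` within each family, zero-count codons floored at 0.01 to keep
the geometric mean finite); `cai()` is the count-weighted geometric mean
over the gene's codons with Met, Trp and stops excluded, so CAI = 1 holds
exactly iff only family-maximal codons are used. The package is
self-contained by default: `geneIndices()` derives the reference from the
pooled counts of the top 5% of genes by ENC ratio, reusing the
optimal-codon machinery's notion of "most biased" as a proxy for high
expression. A curated external weight table (e.g. from a model yeast) can
be supplied instead and is the better choice when one exists for the
organism.

**GRAVY / aromaticity.** Computed from the translated coding region
(terminal stop excluded; ambiguous codons and internal stops yield no
residue) with the embedded Kyte–Doolittle table; both are order-invariant
and therefore computed directly from codon counts.

# Neutrality regression

`neutralityFit()` is an ordinary least-squares fit of GC12 on GC3 with the
Pearson correlation and its two-sided t-test p-value. The slope is
surfaced as `mutationShare` and its complement as `selectionShare`,
following the standard interpretive convention for neutrality plots
(slope 1 = complete neutrality, slope 0 = complete selective constraint);
the package reports the shares without endorsing a strictly causal
reading. Degenerate inputs (fewer than 3 complete pairs, zero variance in
GC3) raise errors; a constant GC12 yields slope 0 with r set to 0 and
p = 1 rather than an undefined correlation.

# Correspondence analysis

`buildRscuMatrix()` produces the genes × 59 per-gene RSCU matrix (stops,
Met, Trp excluded). A family absent from a gene would leave NA entries;
the package imputes the family-neutral value 1 for each of its codons,
keeping row sums stable instead of dropping short genes, and counts the
imputations per gene. This is a documented deviation from tools that drop
or zero such entries.

`correspondenceAnalysis()` is classical CA: relative frequencies, row and
column masses from the margins, SVD of the standardized residual matrix,
principal coordinates for rows and columns, inertia shares `d²/Σd²`. Total
inertia equals the chi-square statistic over the grand total (tested to
1e-9 against a direct computation). Axis signs are made deterministic by
orienting each axis so its largest-|loading| codon is positive. The rank
is reported rather than truncated: RSCU rows satisfy 18 family-sum
constraints, so about 59 − 18 − 1 = 40 informative dimensions remain
(the CA of imputed RSCU typically reports rank 41 because imputation
slightly relaxes the constraints). An implementation note: CA is computed
directly via `svd()` — some 20 lines — because the package needs exact
control of coordinates, inertia and sign conventions; the test suite
cross-checks the coordinates against `MASS::corresp` and against a
brute-force eigendecomposition.

`correlationReport()` defaults to Spearman rank correlations (robust, the
common choice for index tables whose marginals are far from normal);
Pearson is available by flag. Pairs use pairwise-complete observations;
constant columns yield NA with a warning. Rendered output stars p < 0.05
and p < 0.01.

# Optimal codons

`selectBiasSubsets()` orders genes by ENC ratio descending, breaking ties
by gene id, and takes `ceiling(fraction · N)` genes from each end
(default 5%; the ceiling convention makes a 4870-gene set yield 244-gene
subsets). `optimalCodons()` pools counts within each subset, computes
subset RSCU, and flags codons with `ΔRSCU > 0.08` (strictly greater) as
optimal. Stop codons, Met and Trp are listed for completeness but are
never optimal — published practice agrees: subset tables print stop-codon
contrasts above the threshold without starring them. Codons whose family
is absent from a subset get NA and are never optimal.
`endingBaseTally()` summarizes the third-position bases of the optimal
set.

# The synthetic generator

`generateGenes()` draws, per gene, an interior length (log-normal, clamped
to at least 101 codons so every gene passes the 300-nt filter), amino
acids i.i.d. from the spec's frequencies, and codons within each family
from a third-position mutation kernel — `P(G) = P(C) = t/2`,
`P(A) = P(T) = (1 − t)/2` for the gene's GC3 target `t`, renormalized
within the family — exponentially tilted toward a planted preferred codon
by `exp(s)`. `s = 0` nests pure mutational choice; output is byte-identical
across runs with one seed.

Defaults are chosen once to emulate a filtered fungal CDS set: 4870 genes;
log-normal lengths (meanlog log 400, sdlog 0.6) giving a mean near 500
codons; GC3 targets uniform on [0.20, 0.95], covering the wide third-position
spread such genomes show; and a half-and-half mixture of neutral genes and
selected genes with s ~ Exp(1) capped at 3, which yields per-gene ENC
spanning roughly the upper 20s to 61. The default planted preferred set is
the C-ending codon per family (G-ending for the purine-only families Lys,
Gln, Glu), mirroring the C/G-ending optima of GC-rich genomes. Amino-acid
frequencies default to uniform — a simplification; real proteomes are far
from uniform, which mostly affects GRAVY/aromaticity marginals, not the
synonymous-choice machinery.

What the generator does *not* emulate: codon autocorrelation along genes,
amino-acid composition gradients, expression-correlated gene length,
isochore structure, or any dependence between GC12 and GC3 (families'
first/second positions are fixed by the amino acid). Consequently a
neutrality fit on its default output has slope near 0 — useful as a
negative control, but recovery of planted slopes is exercised with
`generateNeutralitySet()`, which builds genes from the
{GGG, GGA, AAG, AAA} pool so GC12 and GC3 are independently controllable;
with noise 0 and slope 1 the fitted slope is exactly 1 because all genes
share one length (the ATG start shifts every gene's GC3 by the same
offset). Passing tests on synthetic data therefore validate the
statistical machinery, not the biological realism of any particular
genome.

# Validation strategy and problem sizes

The test suite validates each statistic against an independent oracle:
hand-computed values for RSCU/CAI/homozygosity; an independently coded
Wright estimator (200 random small genes, agreement to 1e-9); a
brute-force eigendecomposition and `MASS::corresp` for CA; and planted
parameters for the generator (slope recovery at n = 500–1000 with noise SD
0.02; end-to-end recovery of the planted 18-codon preferred set at s = 5
on 1000 genes with a 20% selected minority; 1000-gene property sweeps for
RSCU family sums and the ENC range). Two published genome-wide summary
tables (the per-codon totals and the high/low-bias subset contrast for
*E. festucae* E2368) are shipped as plain-text fixtures and checked
row-for-row: the ΔRSCU > 0.08 rule reproduces the published 27 optimal
codons, including all three Arg codons, exactly. The published counts and
published RSCU columns of the totals table are not perfectly mutually
consistent (recomputing RSCU from the counts flips Ile ATT just above 1,
giving 26 rather than the published 25 codons above 1); the package
reports what it computes.

# Known limitations

* Standard genetic code only; no alternative starts.
* CA is dense SVD — comfortable at 10^4 genes × 59 codons, not intended
  for much larger matrices.
* The internal CAI reference (ENC-ratio tail) is a proxy; with a real
  expression-ranked reference set the weights will differ.
* Within-group CA, PR2 plots, tAI and ENC-prime variants are out of scope.
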