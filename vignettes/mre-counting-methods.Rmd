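---
title: "Counting miRNA response elements in CDS and 3' UTR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting miRNA response elements in CDS and 3' UTR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mreseek)
```

## The biological problem

Elastin production in the aorta is shut off during postnatal maturation,
and part of that shutdown is post-transcriptional: miR-29 and miR-15
family microRNAs rise sharply in the adult aorta while their
extracellular-matrix targets, prominently elastin (*Eln*) and several
collagens, fall. Unusually for animal miRNA regulation, the relevant
binding sites are found not only in the 3′ UTR but repeatedly in the
coding sequence — elastin's mRNA carries on the order of a dozen miR-29
sites split between CDS and 3′ UTR. `mreseek` implements the
computational side of that observation as a reusable pipeline: deriving
the genomic motif a miRNA family recognises, counting it per transcript
region, asking whether a transcript carries significantly more copies
than a random-sequence model predicts, and checking for the family's
activity signature in expression profiles.

## The seed → MRE model

A miRNA family is identified with its *seed*, nucleotides 2–8 of the
mature miRNA. The site it pairs with on an mRNA (the miRNA response
element, MRE) is the reverse complement of the seed written in DNA:
the miR-29 seed `AGCACCA` recognises `TGGTGCT`, the miR-15/195/497 seed
`AGCAGCA` recognises `TGCTGCT`. A *canonical match* in this package is
exact 7-mer identity to that motif. Two deliberate consequences:

* **8-mer sites are captured automatically** (they contain the 7-mer),
  but 7mer-A1 sites (match to seed 2–7 plus an A opposite position 1)
  are *not* counted — the counting statistic and its null model are
  defined on the single literal 7-mer.
* Families that differ only at mature-miRNA position 1 (miR-195 vs
  miR-497) collapse to one seed; `dedup_seeds()` performs that collapse
  before any counting so no motif is tested twice, while retaining the
  family names for reporting.

Partial or noncanonical sites (e.g. a site matching only seed positions
3–8) are outside canonical counts by design.

## Region conventions

Transcripts are mRNA-sense, single-stranded, with 1-based inclusive CDS
coordinates; 5′ UTR is `1..cds_start−1`, 3′ UTR is `cds_end+1..L`.
Matches are counted with a sliding window at every start position, so
overlapping occurrences all count — this mirrors the null model, which
places a potential start at every position. A match straddling a region
junction is counted in the full-transcript scan only and reported
separately as a junction match; region counts are computed on the region
substrings, so `FULL = FIVE_UTR + CDS + THREE_UTR + junction` holds
exactly and is enforced by tests. `N` bases never match and are excluded
from background estimation. Only contiguous CDS spans are supported:
spliced-location (`join(...)`) records are flagged and treated as
CDS-less, which matches the spliced-mRNA records the pipeline is meant
to consume. CDS-less records are scanned as `FULL` only and excluded
from per-region breakdowns. When a gene has several transcripts, the
longest is kept, with ties broken by smallest transcript ID so the
selection is deterministic and order-independent.

## The Poisson overrepresentation test

For a motif with per-position start probability $p$ (the product of the
background frequencies of its seven bases) in an mRNA of length $L$,
there are $L-6$ possible start positions, and the occurrence count is
modelled as

$$X \sim \mathrm{Poisson}(\lambda), \qquad \lambda = (L-6)\,p,$$

with reported p-value $P(X \ge k) = 1 - \sum_{j<k} e^{-\lambda}
\lambda^j / j!$. The mutual dependence of overlapping occurrences is
deliberately ignored — for rare 7-mers ($\lambda \le 1$ for typical
mRNA lengths) the approximation error is far below sampling noise, and
the test suite verifies calibration against $10^5$-replicate
simulations at both uniform and GC-rich compositions. The tail is
evaluated through the complemented Poisson CDF (`ppois(..., lower.tail
= FALSE)`), which is computed stably in log space; $k=0$ returns
exactly 1. No finite-size or self-overlap correction is applied.

The background is estimated **once over the whole analysed corpus**
(pooled A/C/G/T frequencies of all full-length sequences), not
per-gene; `uniform_background()` gives the $p = 4^{-7} \approx 6.10
\times 10^{-5}$ reference. Raw Poisson tails are reported without
multiple-testing correction; corpus-level scans add a clearly separate
Bonferroni convenience column.

Overlap questions ("how surprising is it that 16 of 17 differentially
expressed multi-MRE genes are down-regulated, when 58% of all
differentially expressed genes are?") use the exact binomial tail
$P(X \ge k)$ via `binomial_tail()`.

## The signature screen

An active miRNA depresses its predicted targets as a population. The
screen compares target vs non-target values of a gene-level expression
vector (a group mean or a between-group difference) with a one-sided
Wilcoxon rank-sum test, alternative "targets lower". The exact null is
used for tiny samples (combined size ≤ 10, no ties); otherwise the
normal approximation with midrank tie correction and continuity
correction. The direction is fixed one-sided by default because the
screen asks specifically for repression; a two-sided option exists. Each
family's p-value is accompanied by a control: the mean ± SE of
$-\log_{10} p$ over ten size-matched uniformly random gene sets, drawn
under a recorded seed so the screen is exactly reproducible.

Note a numerical honesty limit established during validation: for a
group as small as 2 the normal approximation can deviate from the exact
null by more than 0.02 in absolute p, so the exact/approximate
agreement property is asserted for groups of ≥ 3.

## Expression preprocessing

Raw intensities are floored at 1 and log2-transformed; each sample is
shifted so its 75th percentile equals the mean 75th percentile (the
percentile-alignment reading of single-colour array normalisation,
isolated in one function so it can be swapped); each probe's median
across samples is subtracted as baseline. Probes flagged absent or
marginal in *every* sample are removed. Probes mapping to the same gene
are collapsed by their mean.

Differential testing is a per-probe two-sample t-test on normalised
log2 values with Benjamini–Hochberg correction. The **pooled
equal-variance t (df = 4 for the 3 + 3 design) is the default**. This
was a genuinely open design point: the Welch variant is the modern
reflex, but with three samples per group its Satterthwaite degrees of
freedom collapse toward 2 whenever the sample variances differ by
chance, and measured sensitivity for planted 2-fold effects at low
noise then plateaus near 0.7–0.9 — the balanced tiny-group design is
precisely the case where the pooled test is both robust and necessary.
Welch remains available (`var_equal = FALSE`). Fold changes are ratios
of linear-scale group means (from the percentile-aligned matrix, before
baseline subtraction), signed so that +2 means two-fold higher in the
second group; the significant up/down sets require both `q < 0.05` and
|FC| ≥ 2 by default.

A related boundary subtlety: a gene whose *true* fold change sits
exactly on the |FC| ≥ 2 filter boundary is excluded in about half of
noisy replicates by symmetry, whatever the noise level. Sensitivity of
*statistical* recovery is therefore measured at the q-threshold with
correct sign (`min_abs_fc = 1`), while the fold-change filter semantics
are asserted on deterministic fixtures.

## The synthetic-data generator

The generator exists to make every downstream stage testable against
recorded truth, with no downloads.

* **Transcripts** (`simulate_transcripts()`): i.i.d. letters from a
  stated composition; CDS boundaries drawn so all three regions are
  comfortably non-empty; then *scrub-then-plant*: every spurious
  occurrence of a planted motif is re-drawn to a fixpoint before the
  requested sites are planted at random positions ≥ 14 nt apart within
  their region, and a final enforcement pass mutates single background
  bases until the scanned counts equal the planted counts exactly.
  Planted sites never straddle junctions unless the `junction_site`
  flag asks for one deliberately. The default composition `"eln_like"`
  (A 0.22, C 0.26, G 0.34, T 0.18) is a GC-rich profile in the style of
  extracellular-matrix transcripts, chosen so the empirical-background
  path is exercised distinctly from uniform; default lengths 1.5–3.5 kb
  bracket typical mRNA lengths including elastin's ~3.5 kb.
* **Family tables** (`simulate_family_table()`): distinct random 7-mer
  seeds in the TargetScan-style file dialect, always including the
  miR-29 (`AGCACCA`) and miR-15 (`AGCAGCA`) reference seeds; the
  emulated full scale is 373 families.
* **Expression** (`simulate_expression()`): the two-groups-of-three
  pooled-sample design; per-gene log-normal baseline (log2 mean 8, SD
  2), planted fold changes applied to group 2, each repressed family's
  targets shifted down by δ × noise-SD log2 units, i.i.d. Gaussian
  noise (default SD 0.25 log2 units, a typical array residual scale),
  detection flags all present except a configurable absent fraction.

All generators are pure functions of (parameters, seed) and leave the
caller's RNG state untouched; generated corpora round-trip
byte-identically through their writers and readers.

What the generator does **not** emulate: codon usage and real coding
constraints, splice structure, probe-level array artefacts, correlated
noise between samples, or the composition heterogeneity of a real
transcriptome. Passing tests therefore demonstrate the correctness and
calibration of the statistics under their own model assumptions — not
that a real corpus satisfies those assumptions.

## Problem sizes used in validation

The test and acceptance runs use deliberately desk-scale versions of
the study conditions: corpora of tens of genes for counting fixtures,
400 genes for null calibration, $10^5$ sequences for Poisson
calibration, $10^6$ draws for the binomial oracle, 100 replicates of
5,000-gene screens for signature power, and 100 replicates of
1,000-gene matrices for DE recovery. Genome-scale figures (33,394
RefSeq genes, 7,675 genes with at least one miR-29 MRE, 50 genes with
five or more CDS+3′ UTR MREs) depend on a specific 2010 RefSeq
snapshot and are reproduced in kind — via planted-truth corpora — not
in number.

## Known limitations

* Only literal 7-mer matches are counted; no 7mer-A1 class, no
  free-energy, accessibility, or conservation scoring, and no target
  prediction — predicted-target tables are consumed as input.
* The Poisson null is an i.i.d. composition model; it is not a shuffle
  or Markov null, so dinucleotide composition effects (e.g. CpG
  depletion, codon bias in the CDS) register as enrichment signal.
* GenBank parsing is minimal by design: simple contiguous CDS spans,
  `/gene` qualifier, ORIGIN block.
* The rank-sum screen assumes the gene-level expression values are
  exchangeable between targets and non-targets under the null;
  probe-collapse quality and array normalisation feed directly into
  that assumption.
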