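---
title: "Mapping a cell-type-specific regulatory network from knock-down and binding data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a cell-type-specific regulatory network from knock-down and binding data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnmapr)
```

## The problem

A cell type's identity is maintained by a transcriptional regulatory network
(TRN): a set of transcription factors (TFs) regulating each other and the
cell-type-specific gene program. Two experimental readouts probe this network
from complementary sides. Perturbation (siRNA knock-down followed by
expression profiling, qRT-PCR on a small panel or CAGE genome-wide) reveals
which promoters a TF *affects*, but cannot separate direct from indirect
targets. Binding assays (ChIP-seq) reveal where a TF *sits* on the genome,
but many binding events are non-functional. `trnmapr` implements the
integration of the two: a promoter is a likely *direct* target of a TF when
its knock-down significantly represses the promoter and the TF has a binding
site nearby.

The pipeline has five analysis layers, each usable on its own:

1. **Enrichment ranking** — which TFs are candidate state regulators.
2. **Matrix-RNAi edge calling** — a TF x target fold-change matrix from
   qRT-PCR, thresholded into perturbation edges.
3. **Differential expression** — a from-scratch negative-binomial exact test
   for knock-down vs scrambled-control count matrices.
4. **State classification** — is each TF pro- or anti-state, activator or
   repressor.
5. **ChIP-seq integration** — distance-binned responses, direct-target
   calling, and the core TF-TF network.

A seeded synthetic-data generator plants a known TRN so the whole chain can
be validated end to end; nothing in the package requires external downloads.

## Enrichment ranking

For each gene or promoter, expression in the focal sample is compared with
its median across a large reference panel via the pseudocounted log ratio

$$s = \log_{10}\frac{x_\text{focal} + 1}{\tilde{x}_\text{panel} + 1}.$$

A score threshold of 1.25 corresponds to $10^{1.25} \approx 17.8$-fold
enrichment over the median. The same pseudocounted ratio, at a fold
threshold of 3, defines the *enriched-promoter* set used by the state
module; using one formula for both keeps behaviour defined at zero medians
(a `pseudocount = FALSE` raw-ratio mode exists for strictly positive
medians). The panel median includes the focal sample by default — with
panels of hundreds of samples the difference is negligible, and it matches
the natural reading of "median across all samples"; `include_focal = FALSE`
switches the convention. Rank ties break by descending focal TPM and then
id, so rankings are deterministic and order-invariant.

```{r}
pan <- generate_panel(n_genes = 300, n_samples = 30, n_enriched = 12,
                      enrichment_fold = 20, seed = 1)
head(rank_tfs(pan$panel), 3)
```

## Matrix-RNAi edge calling

Replicate fold changes (linear scale, relative to scrambled control) are
averaged as a geometric mean — fold changes are ratios, so averaging happens
in log2 space — and a cell becomes an edge when the mean clears a 1.5-fold
threshold in either direction. The threshold is a pure fold rule with no
multiple-testing control, mirroring common matrix-RNAi practice; the
replicate SD is carried along for reporting. Whether the historical rule
was applied to the mean or to each replicate is not documented; the mean is
the default and `per_replicate = TRUE` provides the stricter reading. The
self cell (a TF measured in its own knock-down) is excluded from edge
calling and reported as knock-down efficiency instead, classified efficient
(< 50% residual), suboptimal (50–77%) or failed.

## The differential-expression engine

Knock-down CAGE data are promoter x library count matrices, biological
triplicates against scrambled controls. The engine is deliberately
self-contained (no call into an external DE package) and has three parts:

**TMM normalization** (`tmm_factors()`): per-library trimmed means of
log2 expression ratios against a reference library, trimming 30% of
M-values and 5% of A-values from each tail, precision-weighted, scaled to a
unit geometric mean. The unit tests cross-check the implementation against
an independent implementation of the same published method.

**Dispersion** (`estimate_dispersion()`): the NB variance model is
$\mathrm{var} = \mu + \phi\mu^2$. The common $\phi$ pools within-group
moments across all promoters as a ratio of sums (floored at zero), and
tagwise values shrink each promoter's own moment estimate toward the common
value with prior weight `prior_n = 10` residual-df units. Promoters with
non-positive or undefined moment estimates take the common value. This
moment-based estimator is simpler than conditional maximum likelihood; the
tests pin down its statistical behaviour (Poisson data give
$\hat\phi < 0.02$; $\phi = 0.1$ data give estimates in $[0.05, 0.2]$ at
5000 promoters x 3 replicates) rather than equality with any specific
external tool.

**Exact test** (`nb_exact_test()`): libraries are adjusted to a common
effective size (geometric mean of `lib_size * factor`), group sums are
formed, and the two-sided p-value comes from the conditional distribution of
the first-group sum given the total — a ratio of NB products using NB size
additivity, which degenerates to the conditional binomial in the Poisson
limit $\phi = 0$. The two-sided rule sums the probability of all outcomes no
more probable than the observed one. Tests verify the conditional pmf
against brute-force convolution of single-library pmfs to 1e-9 and the
Poisson limit against enumeration to 1e-6. `logFC` is the log2 ratio of
normalized group means with a pseudo-count of 0.5 per group, keeping folds
finite at zero counts.

Promoters with all-zero counts are dropped (and counted) before testing.
Significance defaults to raw `p < 0.05` — the convention the surrounding
analyses are built on — with BH q-values always emitted and `use_fdr = TRUE`
switching the criterion. The conditional enumeration is exact but linear in
the count total per promoter, which is well suited to the mean counts (tens
to a few thousand) in the designs this package targets; extremely deep
single-promoter totals would make a normal approximation preferable.

## State classification

With the enriched-promoter set in hand, each knock-down's up/down sets are
cross-tabulated into (up_enr, up_non, down_enr, down_non). Three
hypergeometric upper-tail probabilities ask whether the perturbed, up and
down sets hit the enriched set more often than chance, with the universe
taken as all promoters tested for DE (not the genome) — matching the "than
expected by chance among tested promoters" reading. Association between
direction and enrichment is tested with the Yates-corrected chi-square

$$\chi^2 = \frac{N(|ad - bc| - N/2)^2}{r_1 r_2 c_1 c_2},$$

clamped at zero when $|ad - bc| \le N/2$. The direction of association is
summarized by the ratio of ratios
$(\text{up}_\text{enr}/\text{up}_\text{non}) /
(\text{down}_\text{enr}/\text{down}_\text{non})$: significantly below 1
(enriched promoters skew toward down-regulation when the TF is removed)
calls the TF **pro-state**, above 1 **anti-state**. The inequality direction
is our interpretation of the published ratio plots, which never state it as
a formula; extreme ratios (0 or infinite, from an all-one-sided compartment)
count as pro/anti, with only 0/0 undecidable. Per-TF tests are reported
uncorrected across TFs, as in the source analyses; BH can be applied to the
emitted p-values. Independently, a TF whose knock-down yields at least twice
as many down- as up-regulated promoters overall is called an **activator**,
the reverse a **repressor**, in between **mixed**.

## ChIP-seq integration

All intervals are BED-convention 0-based half-open; adjacent intervals do
not overlap. Replicate consistency uses a simple reciprocal-overlap filter
(`reproducible_peaks()`, >= 1 bp by default, merged intervals reported) —
the full irreproducible-discovery-rate copula model is a published
standalone method and externally computed reproducible peak sets are
accepted as input. Peak-to-TSS distance is measured from the peak
**midpoint** (summits are not part of BED input) to the TSS position,
strand-ignored, with signed distances emitted for diagnostics.

`bin_response()` stratifies promoters by distance to the nearest same-TF
peak into bins [0, 1 kb), [1, 5 kb), [5, 100 kb), [100 kb, inf) and reports
the fraction up / down / unaffected per bin ("unaffected" means
non-significant at alpha, irrespective of fold, so the three fractions
partition each bin). A distance-decaying planted effect produces the
expected signature: a high down-fraction proximal to peaks, decaying with
distance toward the null rate.

`call_direct_targets()` requires all three criteria together — `p < 0.05`,
down-regulation at least 1.5-fold, peak within 50 kb — and `core_trn()`
restricts direct edges to target genes that are themselves enriched TFs,
with any-promoter semantics at the gene level. Because direct calling
demands down-regulation on knock-down, core edges are activating by
construction.

## The synthetic-data generator

The generator emulates the statistical structure of the post-quantification
data, not raw sequencing: it produces matrices and called peaks, never
reads. Its defaults state the study conditions the package is tested under:

- **Baseline expression** log-normal(meanlog 3, sdlog 1) in TPM-like units,
  covering the ~18–600 TPM dynamic range typical of enriched TFs.
- **Counts** NB with $\mathrm{var} = \mu + \phi\mu^2$, $\phi = 0.1$,
  biological triplicates vs scrambled controls, library sizes varying
  +/- 30% around 1e6 to exercise normalization.
- **Planted effects** |log2FC| in 1.5–2.5 for direct targets (negative:
  the profiled TFs are activators), a planted anti-state TF whose targets
  go up on knock-down, and planted TF-TF edges forming a known core network.
- **Peaks** one per direct edge at a distance drawn from a mixture of
  proximal (< 1 kb) and distal (5–45 kb) placements, plus decoy peaks near
  non-target promoters (decoy fraction 0.2) modelling non-functional
  binding. The distal component is capped at 45 kb so that every planted
  direct edge stays recoverable inside the 50 kb calling window; the law is
  a plain function argument and can be replaced (e.g. by a 5–100 kb law) to
  study deliberately unrecoverable distal regulation.
- **Panel** enriched rows are planted so their focal value exceeds the fold
  threshold on the pseudocounted ratio by construction.

What the generator does *not* emulate: mapping artifacts, promoter-level
correlation structure, batch effects, chained indirect cascades (indirect
effects are planted directly rather than propagated through the network),
and ChIP-seq read pileups. Passing recovery tests therefore demonstrates
that the statistical machinery is correct under the stated model, not that
real data meet that model.

Default problem sizes (2000 promoters, 3 perturbed TFs, 60 direct targets
per ChIP TF on a 200 Mb four-chromosome genome) keep a full pipeline run
within seconds while leaving every rate estimable; all sizes are arguments.

## Numerical and degenerate-input choices

- Hypergeometric tails are computed in log space (`phyper(log.p = TRUE)`);
  the test suite checks them against exhaustive enumeration for all
  parameter combinations with $N \le 12$.
- The exact test's adjusted group sums are rounded to integers; p-values are
  therefore depth-invariant only up to count discreteness (median shift
  < 0.005 in the tests).
- Zero-margin 2x2 tables skip the chi-square with a flag; `ud_ratio`
  reports infinite and 0/0 cases explicitly rather than erroring.
- Empty distance bins report `NA` fractions, never 0.
- All-zero libraries, negative dispersions, inverted BED intervals and
  fold changes <= 0 are hard errors naming the offending cell or line.

## Reproducibility

Every generator takes an explicit seed and is a pure function of its
arguments; `run_pipeline()` is deterministic given a `trn_config()` and
writes every stage output as TSV with a header recording package version,
seed and config hash. `scripts/acceptance.R --seed N --out f.json`
recomputes the headline quantities from scratch.

## Known limitations

- The dispersion estimator is moment-based; for very small replicate
  numbers with strong mean-dispersion trends a likelihood-based estimator
  would be more efficient.
- The reproducibility filter is overlap-based, not a probabilistic IDR.
- Direct-target calling uses a fixed distance window; without chromatin
  conformation data, distal enhancer targets beyond the window are
  invisible by design, and nearby bystander promoters within the window can
  be miscalled when they respond for indirect reasons.
- Strand is ignored when measuring peak-to-TSS distance.
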