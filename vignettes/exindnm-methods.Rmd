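---
title: "Comparing germline de novo mutation rates between exons and introns"
author: "exindnm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing germline de novo mutation rates between exons and introns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exindnm)
```

## The question

Population genetics routinely uses intronic sequence as a neutral proxy
when measuring selection on exons. That practice assumes the mutation
rate itself does not differ between exons and their flanking introns once
sequence composition is accounted for. Exons are GC- and CpG-richer than
introns, and CpG sites are hypermutable through spontaneous deamination,
so raw exonic mutation density is expected to be higher for compositional
reasons alone; the scientific question is whether any exon/intron
difference remains *after* conditioning on local sequence context.
`exindnm` implements the full analysis chain needed to ask that question
of germline de novo mutation (DNM) data: context-dependent mutational
models, an internal-exon-centered observed-versus-expected profile with a
permutation test, model selection by AIC, a chromatin-feature binned-gene
analysis, and absolute rate estimation — together with a synthetic-data
generator so that every stage can be exercised and validated end to end
without external downloads.

## Sequence-context mutational models

For a mutation from reference base $H_r$ to alternate $H_a$ with flanking
sequence $\mathbf{X}$ (the $(k-1)/2$ bases on each side), the direct
estimate of the per-site mutation probability is

$$P(H_a \mid H_r, \mathbf{X}) \;=\;
  \frac{N(H_a, H_r, \mathbf{X})}{G(H_r, \mathbf{X})},$$

where $N$ is the genome-wide count of observed mutations with that
context and alternate, and $G$ is the genomic abundance of the reference
$k$-mer. Abundances are counted on the forward strand and mutations used
as reported; no reverse-complement collapsing is applied during
estimation (only the 9-class spectrum display folds strands). The
estimate therefore has the scale of the input cohort: it is a per-site
rate aggregated over all sampled gametogeneses, which is the natural
scale for the profile analysis below (only frequency *ratios* matter
there).

A direct $k$-mer table has $4^k \cdot 3$ free parameters, which outgrows
any realistic DNM count by $k = 7$. The composite-likelihood
decomposition replaces the full table with a core $h$-mer model times
independent per-flank-position corrections:

$$P(H_a \mid H_r, \mathbf{X}) \;\approx\;
  P(H_a \mid H_r)\prod_{i=1}^{g}
  \frac{P_i(H_a \mid H_r, x_i)}{P(H_a \mid H_r)}, \qquad g = k - h,$$

where each marginal $P_i$ is computed by summing mutation counts and
abundances over all flanking sequences that agree at position $i$. This
costs $4^h \cdot 3\,(1 + 3(k-h))$ parameters — 1344 for a 5-mer with
3-mer core, 2496 for a 7-mer with 3-mer core, against 3072 and 49,152
for the direct versions. With $h = k$ the product is empty and the
decomposition reproduces the direct estimate bitwise, which the test
suite asserts.

Two cheap baselines complete the model family: the 1-mer model
(12 parameters) and a CpG-aware single-nucleotide model with six
reference states — A, T, and C/G each split by CpG dinucleotide status —
for 18 parameters. Zero-abundance or zero-count cells yield probability
zero; no pseudocounts are applied anywhere, matching the estimator the
probabilities are defined by.

## The internal-exon-centered profile

Gene models are built by merging all transcripts of a gene into
meta-exon coordinates, removing UTR bases and the first and last exon,
and discarding intronless genes, overlapping genes and non-autosomal
genes. Each surviving internal exon anchors one window of width
$L = 2001$ centered on the exon's middle position (floor of the midpoint
for even-length exons — the floor is an arbitrary but deterministic
choice). Window positions are labeled central-exon, other-exon, intron
or intergenic; windows overlapping a mappability exclusion mask by even
one base can be removed.

Within a window, the per-site mutation frequency under a model is
$f_l = \sum_{a} P(H_a \mid H_r^l, \mathbf{X}^l)$, rescaled to
$f_l^{\mathrm{resc}} = f_l / \sum_{l'} f_{l'}$. Each window's observed
mutation total $n_s$ is redistributed as
$\hat n_s^l = f_l^{\mathrm{resc}} \cdot n_s$, so expected counts are
conserved per window by construction, and summed over the $S$ stacked
windows to give the expected profile $\hat n^l$. The *exonic excess*
statistic compares the observed mutation count at central-exon sites
with its permutation distribution: in each of 1000 permutations every
window's $n_s$ mutations are redrawn over its sites with probabilities
$f^{\mathrm{resc}}$. The effect size is
$100\,(n_e^{\mathrm{obs}} - \bar n_e^{\mathrm{perm}}) /
\bar n_e^{\mathrm{perm}}$ with one permutation standard deviation as its
error, and the empirical one-sided p-value is the fraction of
permutations with at least (excess) or at most (deficit) as many exonic
mutations as observed, floored at $1/n_{\mathrm{perm}}$ so it is never
zero.

Two implementation notes. First, only the central-exon *total* of each
permutation enters the statistic, and the marginal of a multinomial over
a category subset is binomial; the permutations therefore draw the
per-window exonic count directly as
$\mathrm{Binomial}(n_s, \sum_{l \in \mathrm{central}}
f_l^{\mathrm{resc}})$ — an exact distributional equivalent of redrawing
all $L$ sites, at a small fraction of the cost. Second, windows of
neighboring exons can overlap; a mutation falling in two windows counts
in each, in both the observed and expected columns, mirroring the
stacked-window bookkeeping of the site counts.

Stratification by coding consequence replaces, at central-exon sites
only, the full $f_l$ by the sum over alternates producing the chosen
class (synonymous, or anything else — stop gains and losses group with
nonsynonymous), while intronic and flanking sites keep the full
frequency; the observed exonic mutations are restricted to the same
class. Consequences come from a codon-table classifier on the annotated
strand and reading frame. For display, profiles are averaged in bins of
25 positions; a final partial bin is averaged over its actual length.

## Model comparison

Competing context schemes are scored by the full-site log-likelihood
over all window sites: a mutated site contributes
$\log P(H_a \mid H_r, \mathbf{X})$ and an unmutated site
$\log(1 - \sum_a P)$. At a recurrent site one mutation is chosen at
random under a recorded seed. Sites lacking the widest compared scheme's
context are excluded from *all* schemes so likelihoods share a common
sample, and $\mathrm{AIC} = 2\,\mathrm{params} - 2\log L$ ranks the
schemes. Models are trained on the same mutations they are evaluated on,
an in-sample circularity we keep deliberately (the comparison asks which
parameterization describes these data, not which predicts new data); an
observed mutation with zero modeled probability aborts the comparison
loudly rather than being dropped, with an explicit pseudo-probability
floor available as an opt-in.

## Chromatin binned-gene analysis

For a coverage track (bedGraph), each gene's exonic enrichment is the
ratio of exonic to intronic bases covered by reads; genes lacking
coverage in either compartment, or without any observed mutation, are
removed. The model-expected exonic mutation count is
$\hat n_e = n \cdot \mathcal{L}_e / (\mathcal{L}_e + \mathcal{L}_i)$,
with the target sizes $\mathcal{L}$ summing $f_l$ over the gene's
meta-exon and meta-intron sites. Genes are grouped into equal-count bins
by enrichment ratio (the equal-count choice stabilizes per-bin totals
when the ratio distribution is skewed), each bin reporting
$100\,(\sum n_e - \sum\hat n_e)/\sum\hat n_e$ against its median ratio.
The across-bin correlation is fitted by iteratively re-weighted least
squares with weights proportional to the inverse within-bin variance of
the ratio, reporting the slope-sign-consistent square root of the
weighted $R^2$ and the two-sided t-test of the slope. The variance
weighting is one defensible reading of "letting the variance of the
bins influence the weight"; it is exposed as the `x_variances` argument
so other weightings can be substituted.

Nucleosome peaks are called as strict local maxima of the per-base
signal (plateau ties resolve to the plateau midpoint; runs touching a
chromosome boundary never qualify), accepted greedily in decreasing
height order under a minimum separation of 150 bp. Each peak emits the
inclusive region of 73 bp per side — 147 bp in total; the conventional
"146 bp" nucleosome footprint cannot be split symmetrically around a
single coordinate, so the emitted region is one base wider than the
nominal footprint and we document rather than hide that.

## Absolute rates

The per-site per-generation rate is
$\mu = N_{\mathrm{obs}} / (N_{\mathrm{site}} \cdot N_{\mathrm{gen}})$,
with $N_{\mathrm{gen}}$ counting gametogeneses (two per trio) and
exposed directly as an input. The exonic compartment is the set of
central-exon window sites; the intronic proxy is every other window
site, including flanks that contain neighboring exons. Sites and
mutations are counted per window occurrence, so overlapping windows
count shared positions in both numerator and denominator consistently.

## What the synthetic data emulate — and what they do not

The generator produces non-overlapping multi-exon genes (UTR-like
terminal exons, fully coding internal exons with consistent reading
frames), exonic sequence with elevated GC and CpG content (extra CpGs
are created by swapping adjacent GC dinucleotides to CG, which leaves
base composition exactly unchanged), DNMs drawn per site and alternate
from a known 3-mer process — transition/transversion bias, a CpG
deamination boost, and seeded log-normal context heterogeneity — with an
optional exonic rate multiplier, disease-ascertainment enrichment of
nonsynonymous alternates in ASD-labeled gametogeneses (renormalized so
only the mutation *composition* changes, not the total rate), and
chromatin tracks with a configurable exon-to-intron coverage ratio and a
phased-sinusoid nucleosome signal with known maxima. Everything is
byte-deterministic under the configured seed.

Real data differ in ways the generator does not attempt: alternative
splicing beyond simple transcript unions, selection against deleterious
DNMs, mutation-calling artifacts and mappability structure, regional
rate covariates (replication timing, recombination), parental age
effects, and extended (>3-mer) context dependence. Passing the test
suite therefore demonstrates that the *machinery* is correct and
well-calibrated under its stated model, not that any particular
biological conclusion transfers to real cohorts. Per-site mutation
draws are Bernoulli per gametogenesis, an approximation that is
excellent at realistic rates (~$10^{-8}$) and still good at the inflated
rates used to make desk-scale simulations informative.

## Validation design and problem sizes

The package validates itself at two scales, chosen to keep a full test
run within minutes on one CPU. Unit and property tests use a ~0.2 Mb
genome with 24 genes. The calibration and recovery studies use a ~5 Mb
genome with 550 genes (~1650 internal-exon windows) and 2000
gametogeneses at a per-site rate of $3.5 \times 10^{-6}$, giving over
20,000 genic mutations: (i) under the null, 200 replicate datasets
simulated from the fitted model (100 permutations each) yield an
upper-tail p-value that passes a Kolmogorov–Smirnov uniformity test at
$\alpha = 0.01$ and a mean excess within two standard errors of zero;
(ii) an injected exonic multiplier of 1.10 is recovered within two
permutation standard deviations of +10%; (iii) with full disease
ascertainment and a boost of 3, the nonsynonymous-stratified excess is
significantly positive while the synonymous one is not; (iv) AIC
selects the generating 3-mer scheme against 1-mer, CpG and 5-mer
alternatives; and (v) the rate estimator's exact Poisson intervals reach
nominal coverage over 100 replicates. The calibration replicates use a
non-overlapping subset of windows: per-window draws from the fitted
model are then *exactly* the multinomial null the permutation test
assumes, whereas overlapping windows share mutations and would make
replicate counts overdispersed relative to that null — a property of the
study design, not of the test statistic.

## Numerical and design choices

* Coordinates are 1-based with inclusive ends throughout the package —
  the native convention of R, GTF and the Bioconductor interval stack —
  with BED and bedGraph converted at the file boundary. A single
  internal convention is what prevents off-by-one drift; this one
  minimizes conversions in an R implementation.
* Any k-mer containing N is excluded from abundance counts and yields a
  per-site frequency of 0; mutations whose context is unreadable are
  skipped from estimation with a logged count, and a reference-allele
  mismatch between the DNM table and the genome is an error, not a skip.
* Window flanks extending into neighboring genes or intergenic sequence
  are retained and labeled; the excess statistic uses central-exon sites
  only, so flanking exons act as background.
* The p-value uses ties-inclusive comparisons and the $1/n_\mathrm{perm}$
  floor; the effect-size denominator is the permutation mean, not the
  analytic expectation.
* The IRLS fit iterates to a relative coefficient change below $10^{-8}$
  (at most 100 iterations) and falls back to equal weights, with a
  warning, when every bin variance is zero.

## Known limitations

Per-site-by-alternate rate matrices are materialized per chromosome
during genome-wide simulation, which bounds comfortable genome sizes to
tens of megabases; the window machinery itself scales much further. The
consequence classifier covers single-nucleotide substitutions in
unambiguous reading frames (the synthetic annotation guarantees this;
real multi-transcript genes with frame conflicts would need a canonical
transcript choice first). The AIC comparison is in-sample by design, and
the chromatin IRLS weighting is one reading of an under-specified
published procedure, kept configurable for that reason.
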