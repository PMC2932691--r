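---
title: "Calling chromosomal aberrations from quantitative proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling chromosomal aberrations from quantitative proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Aneuploid tumor genomes carry segmental gains and losses of whole gene
neighborhoods. At the protein level these dosage changes are only
partially propagated: stoichiometric buffering, degradation of unassembled
complex subunits and transcriptional compensation attenuate the response,
so the per-gene correlation between copy-number change and protein change
is weak (Pearson r in the low 0.2s, i.e. copy number explains only a few
percent of protein-level variance). `proteocna` implements an analysis
pipeline for exactly this regime:

1. **integrate** — SILAC ratio-of-ratios protein quantification matched by
   gene name to SNP-array derived per-gene copy numbers, both normalized
   to a diploid control;
2. **profile** — a multi-scale sliding-window algorithm that detects
   amplifications and deletions *directly from the protein log-ratios*,
   exploiting the fact that dosage effects are regionally coherent while
   other regulation is not;
3. **annot2d** — a two-dimensional rank-based test that asks, for every
   annotation category (GO, KEGG, complex membership, chromosome), whether
   its members shift coherently in the joint (copy change, protein change)
   space;
4. **report** — amplicon zoom-ins, cancer-gene-census intersections and
   sign-partitioned candidate lists;
5. **simulate** — a generator for all of the above, so every stage is
   testable without access to raw measurements.

## Quantification model

Two samples measured against a common heavy-labeled internal standard are
compared by the ratio-of-ratios, which cancels the standard:

    log2 protein change = log2( (tumor/std) / (control/std) )

Records need at least `min_events = 2` quantification events per
experiment; replicates are combined by the median (robust to one outlier
in a triplicate; the even-count median is the mean of the two middle
values, stated for bit-reproducibility). A gene's copy number is the
median smooth signal of the probes annotated to it, normalized to the
same gene in the diploid control; log ratios are base 2 throughout so
that integer copy numbers sit at integer log values and the profile
converts back by `2 * 2^value`. Protein tracks are median-centered by
default before scanning (`center = TRUE`), treating the bulk of the
proteome as unchanged.

## The genome-profiling algorithm

On each chromosome the matched genes are ordered by position and scanned
with windows of every size from 3 genes up to the whole chromosome in
steps of factors of sqrt(2) (`window_sizes()`), moved with stride 1 so
every gene sees every window phase. Each window mean is tested against
zero with a two-sided one-sample t-test. Because a p-value of a 3-gene
window and of a 300-gene window mean very different things, p-values are
converted to posterior error probabilities (PEPs) by Bayes' rule on
two-dimensional histograms of (log10 p, window size): within each size
stratum, 20 log10-p bins are filled with the observed windows and with
the windows of 10 genome-wide value permutations ("randomized genomes"),
and

    PEP(bin) = min(1, pi0 * expected null count per genome / observed count)

with the null prior pi0 fixed at 1 (conservative). Significance is a
window-level false discovery rate: the largest PEP cutoff t such that
(mean permuted windows at PEP <= t) / (observed windows at PEP <= t) is
at most 2%. The final profile takes, at every gene, the median of the
intersecting significant window whose median deviates most from zero,
and exactly 0 where no significant window intersects.

```{r}
library(proteocna)
segs <- plant_segments(5, 300, n_segments = 6, seed = 11)
track <- simulate_protein_track(5, 300, segs, noise_sd = 0.3, seed = 12)
ap <- genome_profile(track, fdr = 0.02, n_permutations = 10, seed = 13)
profile_segments(ap)
```

### Numerical choices

* **Zero-variance windows**: p = 1 when the mean is 0 (no deviation),
  the smallest representable positive p when it is not (a flat shifted
  window is unambiguous). Keeps degenerate synthetic inputs well-defined.
* **Permutation smoothing**: null histogram counts and the FDR numerator
  carry a +1, so a permutation estimate is never exactly zero. With only
  10 permutations, an observed window whose p beats every permuted window
  would otherwise get PEP = 0 and certify an estimated FDR of 0; on pure
  noise roughly 1 in 11 extreme windows per size stratum would qualify,
  which would destroy the null calibration the FDR is supposed to
  guarantee.
* **Empty observed bins** inherit the PEP of the nearest populated bin,
  and PEPs are monotonized to be non-increasing in -log10 p within each
  size stratum.
* **Ties in |median|** during profile construction go to the shorter
  window; windows never span chromosome boundaries; chromosomes with
  fewer than 3 matched genes are skipped with a warning.
* **Permutation scope** is genome-wide (one value multiset across
  chromosomes), preserving the global log-ratio distribution; the
  alternative per-chromosome scope is not used.
* **FDR denominator** counts windows, not genes: the 2% applies to the
  list of significant windows.
* **Copy state 0** maps to a floored log2 dose (default -5) rather than
  -infinity, mimicking residual protein after homozygous loss and
  keeping t-tests finite; copy numbers are floored at `eps = 0.1`
  smooth-signal units before normalization for the same reason.

## Two-dimensional annotation analysis

Genes are ranked separately by copy log2 ratio and by protein log2 ratio
(average ranks on ties). For a category of m members among n genes, each
dimension yields a standardized, tie-corrected Mann-Whitney statistic
z_d, and z1^2 + z2^2 is referred to a chi-square distribution with 2
degrees of freedom. This realization is rank-based, reduces to the
ordinary two-sided Mann-Whitney test in one dimension, and is exact for
independent dimensions at large n; since correlation between the
dimensions inflates it, an exact label-permutation p-value is available
(`n_perm` argument) as the alternative. Multiple testing is controlled by
Benjamini-Hochberg at 5%. Each dimension is scored by the rescaled mean
member rank

    score = (mean member rank - (n+1)/2) / ((n - m)/2)

the unique affine map sending a background-distributed category to 0 and
all-members-at-the-top to 1 (all-at-bottom gives -1). Chromosomes are
added as pseudo-terms, so arm-level dosage appears as chromosome
categories displaced along the genome axis, while dosage-independent
regulation (e.g. a coherently induced pathway) displaces along the
proteome axis only. Categories smaller than `min_category_size = 5`
after intersection with the matched universe (or larger than n - 5) are
skipped; the background of each category is its complement.

## What the simulator emulates — and what it does not

`simulate_genome()` draws geometric segment lengths (the simplest
stationary segmental model producing both focal and arm-level events),
assigns integer copy states with a dominant diploid state, and observes
them through Gaussian probe noise around the state, clamped at 0; the
control is the same machinery centered on 2. The noise model around
integer copies is an assumption (the array-processing chain is not
modeled) and is configurable. `simulate_proteome()` uses a linear
dosage-response in log space: protein log2 = alpha * log2(c/2) plus
Gaussian noise, with a configurable fraction of dosage-sensitive genes,
so the variance explained by copy number has the closed form

    R^2 = alpha^2 Var(dose) / (alpha^2 Var(dose) + sd^2)

used as an independent oracle in the tests. Positions are synthetic
integers (10 kb per gene, 1 kb per probe) because only ordering matters
downstream. Not emulated: peptide-level evidence, allele-specific
signal/LOH, correlated (non-Gaussian) probe noise, subclonality,
inter-replicate structure, and any real gene annotation. Passing tests
therefore demonstrate the statistical machinery under the stated model,
not performance on any particular array or instrument.

Default generator parameters are chosen to mirror the regime the method
targets: copy-state weights {1: 0.08, 2: 0.72, 3: 0.12, 4: 0.08},
attenuation 0.18 and protein noise sd 0.3 put the closed-form per-gene
r^2 near 6%, i.e. copy number explains only a small minority of
protein-level change, as observed in aneuploid tumor lines.

## Benchmark scales

The packaged checks run at fixed, deliberately moderate sizes: segment
recovery and null calibration on 5 chromosomes x 300 genes over 20 seeds;
correlation amplification on 10 x 300 genes over 10 seeds (attenuation
0.5, protein noise 0.82, arm-level segments of mean length 60, set by the
closed form so the raw per-gene r is ~0.25); the variance-explained
oracle at 5,000 genes; t-test calibration on 10,000 disjoint null
windows; annotation calibration on 1,000 random terms and 50 null
replicates of 1,000 terms each; planted-category power at m = 30 among
n = 3,000.

## Known limitations

* **Boundary resolution.** The profile rule assigns a significant
  window's median to *every* position the window covers. Windows that
  lie mostly inside a true segment but extend beyond it are genuinely
  significant, and their medians are in-segment values, so the non-zero
  profile systematically overshoots segment edges — by up to roughly
  half a window size. Likewise, a chromosome that contains any aberrant
  segment usually has a significantly non-zero whole-chromosome window,
  which paints the remainder of that chromosome at its (small)
  chromosome-wide median. Detection and sign of planted segments are
  essentially perfect under the benchmark conditions, and the painted
  values outside true segments are small, but edge placement is
  window-limited: this profiler is a multi-scale detector, not a
  breakpoint estimator. Users needing breakpoints should follow up with
  a dedicated segmentation method on the copy signal.
* The window-level 2% FDR does not bound the *gene-level* false-call
  fraction directly; one false window can cover many genes. On pure-null
  benchmarks the gene-level rate stays within about twice the window
  rate.
* With 10 permutations the smallest resolvable non-zero FDR estimate is
  coarse; the +1 smoothing makes the procedure conservative rather than
  anti-conservative.
* The chi-square combination of the 2D test assumes weak dependence
  between the copy and protein dimensions; under strong dependence use
  the permutation p-value.
* Replicate aggregation by median and protein median-centering are
  defensible defaults, not uniquely determined choices; both are exposed
  as arguments.
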