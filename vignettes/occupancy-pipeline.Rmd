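---
title: "Comparative PcG occupancy at transcription factor binding sites: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative PcG occupancy at transcription factor binding sites: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgcoloc)
```

This vignette is the package's account of its science: the model behind
each stage, the parameters that matter and why they default the way they
do, what the synthetic generator does and does not emulate, and the
numerical choices a maintainer would want spelled out.

## The biological question and the pipeline's shape

Polycomb repressive complexes are recruited to chromatin by more than one
route. CpG-rich promoter regions act as a default PRC2 platform, while
sequence-specific factors such as REST/NRSF can tether PRC1 and PRC2 to
sites far from CpG islands — and, at CpG-proximal sites, can instead limit
how much PRC2 accumulates. The observable consequence in a knockout is
asymmetric: PcG signal is *lost* at CpG-distal sites that depended on the
factor and *gained* at CpG-proximal sites it had been restraining.

Detecting that fingerprint from ChIP-seq requires a chain of small, well
specified steps: quantify tag signal around peaks, normalize to an IgG
mock, filter out positions with no appreciable signal, classify each site
by its knockout/wild-type ratio, ask whether changed sites are more
frequent than at matched control regions, stratify by CpG proximity, and
check that co-localization of two factors is not a trivial consequence of
both liking promoters. Each step is one exported function; the pipeline is
their composition.

## Signal model

**Coordinates.** Everything is 0-based, half-open; BED files map directly.
The center of an interval is `floor((start + end) / 2)`. Tags are read 5′
positions, used as given (no extension — no fragment model is assumed) and
counted without regard to strand.

**Window counts.** `count_in_window()` counts tags in
`[center − flank, center + flank)` by binary search on the per-chromosome
sorted positions. `mean_reads_per_kb()` divides by the window size in Kb;
with the default ±1 Kb window this is the "reads on average within 1 Kb"
quantity that the positivity filter thresholds at 5. We read "average
within 1 Kb" as per-Kb density in the ±1 Kb window centered on the peak;
a per-bin mean would be the same number divided by the bin count, so only
the threshold's scale depends on the reading, and the 5 reads/Kb default
matches the density reading.

**IgG normalization.** The mock-IP track is treated as a background
estimate, and profiles are depth-scaled ratios:
`(T_b / N_T) / ((G_b + λ) / N_G)` per bin, pseudocount `λ = 0.5` tags/bin.
A ratio (rather than subtraction) keeps the reading "fold enrichment over
background" and is invariant to joint depth changes; the pseudocount
guards empty IgG bins at the cost of exact depth invariance in bins with
no background tags. Bin width is 50 bp for profiles (±3 Kb) and heat-maps
(±1 Kb).

**Orientation.** When a gene table is supplied, each anchor's offset axis
is flipped so its nearest TSS lies at positive offsets before averaging —
profiles then read "toward the gene" on the right. The flip is decided by
TSS position relative to the anchor center; an anchor whose nearest TSS
coincides with its center is not flipped.

**Classification scores.** Peak-level counts are raw tag counts
depth-scaled to the smallest library (`N_min / N_sample`), because the
positivity threshold is stated in reads, not in rates. The fold-change key
used for classification and heat-map sorting is computed within the called
peak interval, not the ±1 Kb window: the loss signal is focused at the
site, while gains spread into the flanks, so the peak interval is the
sharper discriminator.

## Classification and enrichment

The knockout/wild-type ratio is `r = (ko + c) / (wt + c)` with `c = 1`
depth-scaled read; the pseudocount makes 0/0 read as "unchanged" rather
than undefined. Classes are `decreased` iff `r ≤ 1/1.5` and `increased`
iff `r ≥ 1.5` — the boundary counts as changed ("1.5-fold or more").

Matched control regions are the null for "is change enriched at binding
sites?". Signed nearest-TSS distances are binned on a symmetric log scale
(single linear bin below 1 Kb, then 3 bins per decade per sign); for each
peak one control of the same width is drawn uniformly among positions
whose own nearest-TSS distance falls in the same bin, rejecting positions
that intersect any source peak or a previously accepted control. By
construction the control histogram equals the peak histogram exactly at
bin resolution, so a goodness-of-fit statistic between them is degenerate
at zero — that is the point, not a bug.

Enrichment is a 2×2 Pearson χ² (changed vs not × peaks vs controls),
df = 1, no continuity correction, with the direction (`decreased` or
`increased`) chosen per test. Degenerate margins are flagged rather than
tested. Calibration was checked by construction: under an
identical-placement null (both sets receive Poisson(25) counts in both
genotypes, 300 regions a side) the rejection rate at α = 0.05 sits at 5%;
smaller counts make the statistic slightly conservative through the
discreteness of the class counts.

## Co-occurrence

For two peak sets A and B, each gene contributes a Bernoulli indicator per
scan offset: does a peak center fall within a 2,500 bp window centered at
that offset from the TSS (or transcription end), in strand-oriented
coordinates? Observed co-occurrence `O(i,j)` counts genes positive for A
at offset *i* and B at offset *j*; the independence expectation is
`E(i,j) = N·f_A(i)·f_B(j)`. Because each cell is a sum of N Bernoulli
trials, the natural test is a two-tailed exact binomial at rate
`f_A(i)·f_B(j)`, Bonferroni-corrected over the non-masked cells (cells
with a zero marginal are masked). The scan step defaults to 500 bp over
±20 Kb (81 × 81 cells per anchor kind); the window is fixed at 2,500 bp
and the step is a resolution choice, not part of the statistic.

Two numerical notes. First, `mean log2(O/E)` over occupied cells is only
asymptotically centered at zero under independence: Jensen's inequality
biases it by roughly `−1/(2·E·ln 2)`, noticeable below E ≈ 10 — the
package's permutation check therefore runs in a regime with E ≈ 20.
Second, a gene contributes at most once per *cell*, so the valid bound is
`O(i,j) ≤ N·f_A(i)` per cell; row sums can exceed it because one peak
spans several overlapping scan offsets.

## Expression filters

The knockdown analysis is deliberately simple, mirroring spreadsheet-era
practice: per probe, fold change of group means and a two-tailed
equal-variance Student's t-test; a probe passes at fold > 2 *and*
p < 0.05, both strict, with no multiple-testing correction — these are the
filter's stated semantics, not our recommendation for new designs. The
variance prefilter used before clustering keeps probes with at least one
reading above 10 and at least two arrays deviating 1.5-fold from the probe
mean. The density-grid comparisons use Welch (unequal-variance) t-tests,
following the explicit heteroscedastic wording of that analysis; which
bins are compared defaults to the lowest vs highest occupied bin along the
x axis and is exposed in the call.

## The synthetic study

The generator defines the conditions every test runs under:

* **Genome**: 2 chromosomes × 10 Mb, 1,000 non-overlapping genes with
  bodies of 2–20 Kb, strands drawn 50/50. 60% of promoters receive a CpG
  island (500–2,000 bp) overlapping the TSS — the rough mammalian promoter
  fraction.
* **Planted sites**: 200 `rest_dependent_loss` sites (> 1 Kb from any
  island), 200 `cpg_gain` sites (within 1 Kb of an island), 200
  `unchanged` sites, all ≥ 4 Kb apart; plus 1,500 `background_control`
  sites carrying REST-independent, genotype-stable PcG signal. The last
  class is what lets randomly placed control regions score PcG-positive on
  *real* signal: without it, the only positive controls are background
  noise, whose tiny counts classify as "changed" a third of the time and
  wash out the enrichment test — the opposite of how genuine stable PcG
  sites behave.
* **Intensities**: wild-type focal means of 80 (REST) and 60 (PcG factors)
  tags per site; the planted change is 4-fold (loss sites 60 → 15, gain
  sites 20 → 80 — the gain builds on a 3-fold-attenuated wild-type base so
  gained signal is signal the wild type largely lacked, and total focal
  tags stay balanced between genotypes, keeping library-size depth scaling
  unbiased). REST signal is absent everywhere in the knockout; IgG gets
  background only.
* **Tags**: uniform Poisson background at 0.001 tags/bp plus Gaussian
  focal tags (sd 100 bp) around site centers, truncated to the
  chromosome; strands 50/50. At this rate the chance that a random region
  passes the 5 reads/Kb filter on background alone is negligible
  (P(count > 10) ≈ 5·10⁻⁷ at λ = 2 per ±1 Kb window), so control
  positivity reflects the planted REST-independent sites and lands near
  one-fifth — REST sites score positive about five-fold more often.
* **Expression**: probes share a base mean of 100; planted up-regulated
  probes are 4-fold higher in their knockdown group; replicate noise is
  log-normal (sd 0.25 in log2) over 3 replicates per group.

Everything is fixed by the seed; stage seeds are small fixed offsets from
it so stages can be re-run independently.

What the generator does **not** emulate: sequence (no FASTA, no motifs),
fragment-length and PCR-duplicate structure, chromatin-driven background
non-uniformity, broad-domain factors (all focal signal is a single
Gaussian), batch effects, and probe-level cross-hybridization. Passing
tests therefore demonstrate that the *procedures* are correct and
calibrated under a clean model, not that any particular biological dataset
will behave as cleanly.

## Problem sizes and determinism

The default study (20 Mb, 2,100 sites, 12 tag tracks of ~10⁵ tags)
simulates, calls and classifies in a few seconds; the full test suite and
the acceptance script each run in well under a minute on one core — sizes
chosen so that every statistic is stable but iteration stays interactive.
Window counting is O(log n) per query via binary search; the peak caller,
profiles and heat-maps share one vectorized binning core, so the profile
numerator equals the heat-map column sums by construction.

Numerical conventions, in one place: half-open interval semantics
everywhere (adjacent intervals do not overlap); summit = the max-count
step-width bin refined to the local tag center of mass within ±window/2
(the raw modal bin quantizes summits to ±125 bp); heat-map row order is
the fold-change key descending with lexicographic id tie-breaks; the CpG
boundary (gap exactly 1 Kb) is proximal; fold boundaries classify as
changed; matched-control sampling is rejection sampling with a bounded
retry budget that errors naming the offending distance bin rather than
silently relaxing the match.

## Known limitations

Peak boundaries from any thresholded caller are depth-sensitive: doubling
both libraries can widen merged intervals by one step as flanking windows
cross the significance cutoff (summits are stable; the tests pin exactly
that). The χ² enrichment test inherits the usual asymptotic caveats below
~10 expected counts per cell. The co-occurrence binomial treats genes as
exchangeable and ignores gene-length and density covariates beyond the
offset grid itself. The expression filter's uncorrected p < 0.05 is kept
for fidelity to the analysis it reproduces and should not be used as a
discovery criterion elsewhere.
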