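---
title: "Methods: center-weighted nucleosome occupancy, GC correction and Oct4/Sox2 site analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: center-weighted nucleosome occupancy, GC correction and Oct4/Sox2 site analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleotrack)
```

## The problem

Transcription factor (TF) binding motifs occur orders of magnitude more
often in a genome than functional, ChIP-occupied binding sites.
Nucleosomes compete with TFs for DNA, so the intrinsic sequence
preference of the histone octamer — measurable by reconstituting
chromatin from purified DNA and histones *in vitro* and digesting with
micrococcal nuclease (MNase) — is one determinant of which predicted
sites become functional. `nucleotrack` implements the computational side
of a targeted comparison of *in vivo* and *in vitro* mononucleosome
maps over a handful of enriched promoter regions containing predicted
and functional composite Oct4/Sox2 sites: occupancy track construction,
GC-bias correction, motif-site prediction and classification, per-site
fold-change statistics, and a simulator that generates libraries with
known ground truth so every stage is testable without deposited
sequencing data.

## Center-weighted occupancy

Each uniquely mapped mononucleosome fragment is reduced to its center.
A position $d$ bp from the center receives weight

$$w(d) = \exp\left[-\tfrac{1}{2}\,(d/20)^2\right], \qquad |d| \le 73,$$

and zero beyond 73 bp, so the support of one fragment matches the
147 bp nucleosome footprint. For an odd fragment length the center is
the middle basepair. For an even length, the two central basepairs act
as the center in turn; the two profiles are **averaged**, not summed.
That choice is deliberate: averaging makes the deposited mass per
fragment, $\sum_{d=-73}^{73} w(d) \approx 50.13$, independent of length
parity, so libraries with different length mixtures remain comparable.
Summing would double the influence of even-length fragments with no
biological justification.

`build_occupancy()` accumulates per-bp center mass (half mass at each
of the two central positions for even lengths) and convolves it with
the kernel by direct shifted summation (exact arithmetic, no FFT
round-off), which the tests verify against a naive
fragment-by-position double loop to 1e-9. Fragments whose kernel
support straddles a region edge contribute only their in-region
weights; there is no edge renormalization, so the outermost 73 bp of a
region carry boundary-attenuated signal.

`normalize_track()` divides by the grand mean over **all covered
basepairs of all regions in the dataset** — for a targeted-enrichment
experiment the regions *are* the dataset; genome-wide coverage is not
meaningful — making the dataset average exactly 1.

## GC-bias correction

MNase digestion and library chemistry enrich GC-rich sequence. A
naked-DNA MNase control isolates that bias. The control track
(normalized) is tiled into 20 bp bins; each complete bin contributes a
pair (mean score $S$, base GC fraction). An ordinary least-squares
quadratic of $\log S$ on GC, $F(\mathrm{GC})$, is fit over the bins
(`fit_gc_model()`); bins with $S = 0$ are excluded without pseudocount
(a pseudocount would bend the low-coverage tail) and the exclusion
count is reported. The per-bp correction divides the normalized score
$S_i$ by $\exp F(\mathrm{GC}_i)$, with $\mathrm{GC}_i$ computed over a
$\pm 10$ bp window (ambiguous bases excluded from numerator and
denominator; edge windows shrink), and floors the result at 0.01 so
downstream log-ratios stay finite. GC is expressed as a fraction in
[0, 1] in both fitting and application; that pinning makes the
coefficient units well defined and the fit/apply pair internally
consistent.

Two numerical caveats, both verified by tests:

* The model is defined for GC variation at or above the bin/window
  scale. Per-bp (white-noise) GC fluctuation is averaged away
  differently by the 20 bp fitting bins and the 21 bp application
  windows, which attenuates the fit and leaves a residual trend — a
  structural limitation, not a bug. Real genomic GC landscapes vary
  smoothly, which is the regime the self-consistency test uses.
* When the control library itself is built from center-weighted
  fragments, the kernel smooths the injected bias, so fitted
  coefficients are *not* the injected generator coefficients; the
  meaningful criterion — used as an acceptance test — is that applying
  the fit flattens the control: per-GC-decile bin means within 5% of 1.

## Motif sites, classification and fold change

`scan_pwm()` scores every window of both strands with a log2-odds
matrix built from the position frequency matrix counts plus a 0.01
per-cell pseudocount against a uniform (configurable) background. A
window is reported when its relative score
$(s - s_{\min})/(s_{\max} - s_{\min})$ reaches the threshold on either
strand; the higher-scoring strand is reported, ties going to the
forward strand, and overlapping hits are all kept (no merging rule is
imposed). The default threshold of 0.80 is a required, explicit
parameter: the threshold used for the published 58-site count lives in
supplementary material and is not recoverable, so users calibrate
against their own site counts. The shipped PFM
(`inst/extdata/oct4_sox2_synthetic.pfm`) is a **synthetic stand-in**
with a 15 bp composite consensus; it is suitable for testing and
simulation, not for scanning real genomes.

`classify_sites()` averages Oct4 and Sox2 ChIP occupancy per site and
calls a site functional when the mean is $\ge 20$ (the inclusive
boundary is the documented choice where the source description is
ambiguous; the cutoff is configurable). Gene-class labels
(active / poised / bivalent-unregulated) are declarative metadata
supplied as a region-to-class map.

Per site, occupancy is the arithmetic mean of the GC-adjusted track
over the 15 bp span, and the fold change is
$\log_2(\text{in vivo}/\text{in vitro})$. Group summaries report the
mean and SEM ($s/\sqrt{n}$, $n-1$ denominator) of per-site occupancy
but the **median** of fold changes: small in vitro averages produce
extreme ratios that dominate a mean.

The significance test between groups is an **unpaired** two-sample z on
group means, $z = (\bar a - \bar b)/\sqrt{\mathrm{SEM}_a^2 +
\mathrm{SEM}_b^2}$, two-sided normal p. A literal paired test is
impossible for unequal, unpaired site groups; this is the closest
well-defined reading and is documented as such. No multiple-testing
correction is applied.

## The synthetic world

`make_world()` / `sample_library()` generate the stated world the tests
run in:

* six 5 kb regions named after the six targeted loci, two per
  regulatory class, carrying 58 planted consensus motif instances in
  the published per-class functional/nonfunctional counts (10/12, 4/13,
  0/19 — 14 functional);
* sequences drawn from a smooth sinusoidal GC landscape
  (0.5 ± 0.15, 1 kb period);
* an intrinsic preference landscape $\lambda(i) > 0$: a smooth
  sinusoid plus Gaussian positioning elements every 800 bp;
* *in vitro* fragment **centers** sampled $\propto \lambda$;
  *in vivo* centers $\propto \lambda$ times a displacement factor
  $\delta = 0.25$ over a 147 bp window centered on each functional
  motif (a bound TF excludes the whole nucleosome footprint); the naked
  control $\propto \exp F^*(\mathrm{GC}_i)$ with generator coefficients
  $(2, -1, -0.2)$ — a moderate, realistic bias spanning roughly a
  1.8-fold dynamic range over the GC range of the sequences;
* lengths 147 ± 20 bp uniform, so odd and even parities are always
  exercised; even-length fragments place the sampled center on one of
  the two central basepairs at random;
* ChIP truth scores from separated uniforms (functional 25–60,
  nonfunctional 0–15), so the cutoff of 20 classifies planted sites
  perfectly by construction;
* depth 1e5 fragments per library; one seed determines world and
  libraries bit-for-bit.

A design note: the sampling landscape is defined over fragment
*centers*, not start positions. The displacement window, the occupancy
estimator and the recovery invariant (median fold at functional sites
$\to \log_2 \delta$) all live in center space; sampling starts from a
center-depleted landscape would shift the depletion ~73 bp downstream
of the motif and break the very property the simulator exists to test.

What a green end-to-end test establishes: the pipeline recovers a
planted multiplicative displacement through occupancy building,
normalization, GC fitting and correction, scanning and classification,
to within ~0.1 in log2 units (a small positive shift of the fold
distribution is inherent: removing mass at functional sites deflates
the in vivo grand mean slightly, inflating normalized values
everywhere). What it does not establish: realism of MNase cleavage
sequence preference, overdispersed coverage, alignment artifacts, or
cross-species transfer of a GC model — all out of the simulator's
scope, and the GC model is fit on whatever control the user supplies
rather than hard-coding any species.

## Numerical choices

* Threshold comparisons in `scan_pwm()` carry a 1e-9 tolerance so a
  consensus window passes a threshold of exactly 1.0 despite float
  summation order.
* SEM of a single-observation group is reported as 0 with
  `sem_defined = FALSE` rather than NA, keeping downstream tables
  numeric; such groups never enter z-tests (which require $n \ge 2$).
* `two_group_z()` on two identical groups returns $z = 0$, $p = 1$
  (0/0 guarded).
* Spearman p-values use the large-sample t approximation and are
  informational.
* The enrichment-fold genome size is an explicit parameter, never
  hard-coded.

## Known limitations

* No nucleosome calling, phasing or repeat-length estimation — the
  deliverable is the occupancy/fold-change comparison, not positioning.
* GC correction is per-bp multiplicative from a single quadratic; it
  cannot represent sub-bin-scale GC effects or non-GC sequence bias.
* The z-test's normal reference slightly understates tail probability
  for groups of ~14 sites (a t reference would be wider); calibration
  at the study's group sizes stays within the accepted type-I band and
  is checked by simulation.
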