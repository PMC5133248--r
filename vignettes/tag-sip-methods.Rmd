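---
title: "Tag-SIP methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tag-SIP methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagsip)
```

## The measurement

DNA stable isotope probing (SIP) detects substrate assimilation by density:
organisms that incorporate a heavy isotope (here ^15^N) into newly
synthesized DNA band deeper in a CsCl equilibrium gradient than the same
organisms grown on the light isotope. Tag-SIP resolves this per taxon by
amplicon-sequencing every collected gradient fraction, so each OTU's read
counts across fractions trace its own DNA density distribution. The analysis
question is then, for every OTU: did its band in the labeled incubation sit
measurably denser than in the paired unlabeled control?

This is a demanding question for ^15^N, because full labeling raises
buoyant density by only about 0.016 g ml^-1^ — under half of what ^13^C
achieves — while GC content alone spreads community DNA over several times
that range. Everything below exists to read small per-OTU shifts reliably
off noisy fraction-level counts.

## From counts to profiles

Fractions are indexed in collection order; fraction 1 is the densest
(displaced first from the bottom of the tube), and density must decrease
strictly with index — `read_fraction_metadata()` validates this rather than
assuming it. From the ~50 collected fractions, the 20 with the most DNA are
carried to sequencing; `select_fractions()` formalizes "use the DNA
distribution" as the contiguous window maximizing summed DNA quantity, with
ties broken toward the denser end. Contiguity mirrors a physical DNA band
and makes the rule deterministic and scale-invariant.

OTUs enter the analysis only if they rank in the global top 100 by total
reads *and* carry at least ~400 reads per sequenced fraction in at least one
gradient of each analyzed pair (`filter_otus()`). The support rule guards
against pseudo-bands formed by the random scatter of very rare organisms.
Whether "reads per sequenced fraction" means the mean or the minimum is not
a settled convention; we default to the mean (robust to empty edge
fractions, and identical to total/20 when every selected fraction is
tabulated) and expose `stat = "min"` as an alternative rather than guessing
a single intent.

An OTU's profile in one gradient is its read count per fraction divided by
its maximum count in that gradient (`build_profile()`). This "ratio of
quantities" normalization cancels sequencing depth exactly, which is why
shifts are invariant to rescaling any gradient's counts.

## Peak calling

`detect_peaks()` takes the global maximum fraction as the primary peak. Its
*supporting run* is the maximal contiguous set of fractions at or above half
maximum (`support_threshold = 0.5`) containing the mode. A peak is valid
only if the run spans at least `min_support = 3` fractions: half-maximum
width is the standard notion of band width, and the rule automatically
discards single-point spikes, which carry no evidence of a coherent band.
When no valid peak exists the method falls back to comparing the overall
distributions: `method = "centroid"`, the read-weighted mean density.

Secondary peaks — the signature of a differentially active subpopulation
banding denser than the rest of its OTU — are local maxima of at least
`secondary_min_ratio = 0.25` whose own half-maximum run (relative to their
height) spans at least three fractions. They are reported alongside the
primary call, and `use_secondary = TRUE` lets the shift use the densest
peak, for explicit subpopulation analyses; the default uses the primary
peak only, the conservative choice.

### Sub-fraction band centers

Reading the band position as the density of the modal fraction quantizes
every shift to the fraction spacing — 0.0022 g ml^-1^ at the default
50-fraction, 1.66–1.77 g ml^-1^ geometry. That is coarser than the
0.001 g ml^-1^ granularity at which null-treatment shifts need to be
resolved, and it makes the apparent null distribution a coin flip between 0
and one full fraction whenever a band center lies near a fraction boundary.
We therefore refine the peak position by log-quadratic interpolation
through the modal fraction and its two neighbours: for a Gaussian band
sampled on an even density grid, log counts are exactly quadratic in
density, so the parabola vertex recovers the continuous band center. The
refinement is deterministic (identical inputs give identical, exactly-zero
self-shifts), falls back to the modal density at profile edges, zero
neighbours or non-concave triplets, and can be disabled with
`density_estimate = "mode"` if strictly fraction-resolution positions are
wanted. Exact ties at the maximum are broken by the read-weighted mean of
the tied fractions.

## Shifts, the limit of detection, and enrichment

The shift of an OTU is labeled minus control band position
(`compute_shift()`), compared like for like: peak-vs-peak when both calls
are valid, otherwise centroid-vs-centroid for both sides. Shifts are
differenced at full precision and only rounded in reports. Negative shifts
are reported and flagged rather than clipped — a banding method working
correctly should produce none, so they are a diagnostic.

The limit of detection comes from a *null treatment*: an incubation whose
amendment is too small for detectable labeling (under 20% DNA labeling even
assuming a full doubling, see below), so its apparent control-vs-labeled
shifts measure pure banding reproducibility. `calibrate_lod()` sets the
cutoff at `factor = 1.5` times the largest absolute null shift and reports
n, mean, SD (n−1 denominator) and the cutoff's distance from the null mean
in SDs. The distance is computed on the signed null distribution; with a
null of mean 0.0004 and SD 0.0007 g ml^-1^ a 0.003 g ml^-1^ cutoff sits 3.7
SD out. Enrichment is called inclusively: `shift >= cutoff`. An all-zero
null is refused (`tagsip_degenerate_null` condition) rather than silently
yielding a zero cutoff; supply `cutoff` manually in that case.

## Isotope mass-balance calculators

Four closed forms support experimental design and interpretation:

* **Pool mixing** (`pool_atom_percent()`): adding `c_s` µM of labeled
  substrate (stock purity `x_label`) to `c_a` µM ambient gives a pool of
  $100\,(x_\ell c_s + x_n c_a)/(c_s + c_a)$ atom% ^15^N. `x_label`
  defaults to 0.98, the purity of typical commercial ^15^N salts, and
  `x_nat` to 0.003663, natural ^15^N abundance; both are arguments.
* **Semiconservative bound** (`expected_dna_labeling()`): after $g$
  doublings on a pool of $p$ atom%, bulk DNA reaches
  $p\,(1-2^{-g}) + 100\,x_n 2^{-g}$ — exactly halfway to the pool after one
  doubling, because each daughter duplex keeps an unlabeled parental
  strand. This is what makes a low-amendment treatment a usable null: a
  39.4 atom% pool caps single-doubling labeling at 19.9%.
* **Density gain** (`expected_density_shift()`): linear in atom fraction
  excess up to the full-label maxima, 0.016 g ml^-1^ (^15^N) and
  0.036 g ml^-1^ (^13^C) by default — configurable, since published
  estimates vary around these values.
* **Cross-feeding budget** (`cross_feeding_budget()`): primary uptake
  enriches the PON pool to `uptake*duration/pon` (capped at 1); release
  rates times duration times that fraction give the labeled DON/NH~4~^+^
  liberated, expressed as a percentage of N assimilated through the
  competing pathway. The PON enrichment deliberately follows the simple
  field arithmetic — it is not multiplied by the substrate pool's atom
  fraction — so its output is directly comparable with how such budgets
  are quoted.

## The gradient simulator

`generate_paired_experiment()` makes the whole pipeline testable without
sequencing data. Each OTU's band is a Gaussian in density centered at
`1.660 + 0.098*GC + excess*0.016` g ml^-1^ (the classical linear GC
relation plus the linear isotope term), integrated over equal-width
fraction bins; 50 fractions spanning 1.66–1.77 g ml^-1^, of which the
20-fraction maximum-DNA window is "sequenced". Reads are drawn
multinomially (10^6^ per gradient by default, a MiSeq-scale depth at which
a top-100 OTU clears the 400 reads/fraction filter) with expected
proportions proportional to relative abundance times band mass;
per-fraction DNA quantity is community band mass with lognormal noise
(sdlog 0.10) on a 750 ng total. Band SD defaults to 0.004 g ml^-1^, chosen
to visually match published per-OTU profile widths; it is a calibration
knob, not a physical diffusion model. Community GC defaults to
U(0.40, 0.55), the mid-GC band where a mixed marine community's DNA
concentrates and which keeps all bands inside the sequencing window.

A `"null"` treatment draws per-OTU excess from a half-normal scaled so
imposed shifts have SD 0.0002 g ml^-1^ — an order of magnitude below the
fraction spacing, the defining property of an undetectable treatment —
truncated below 0.002 g ml^-1^. All randomness derives from one experiment
seed through per-gradient substreams, so outputs are byte-identical across
runs and adding a treatment never perturbs earlier gradients.

What the simulator does **not** emulate: PCR and primer bias, 16S copy
number variation, chimeras, diffusion/rotor physics, or compositional
artifacts of real amplicon libraries. Passing recovery tests therefore
demonstrates that the *inference* is sound at realistic noise levels, not
that every laboratory artifact is survivable.

## Validation scale and results the tests compute

The parameter-recovery suite simulates 100 OTUs (50 labeled at excess
≥ 0.3, 50 unlabeled) at 10^6^ reads per gradient over 10 seeds, calibrates
the LOD from a simulated null pair, and requires median sensitivity and
specificity of at least 0.95 plus at least 90% of null-pair shifts at or
below 0.001 g ml^-1^. A separate check regresses recovered on imposed
shifts across an excess grid of 0.1–1.0 and requires a slope in
[0.8, 1.2]. These sizes keep the default test run around tens of seconds
while leaving the statistics comfortably away from their thresholds.

## Known limitations

* The LOD rule is an empirical bound, not a significance test; the package
  deliberately implements no shift p-values and no quantitative
  atom-fraction-excess estimation (qSIP-style), which is a different
  method with different data demands.
* Enrichment calls at the cutoff boundary inherit the null treatment's
  sampling: a different null community would give a slightly different
  cutoff. The calibration report (n, mean, SD, max, SD-distance) is
  written precisely so that this sensitivity is visible.
* Centroid-fallback comparisons are biased toward zero when a band is
  truncated by the sequencing window; the window-selection rule makes this
  rare, and affected OTUs are visible through their `method` column.
* `fraction_index` must increase from dense to light; data collected
  top-down must be renumbered before import.
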