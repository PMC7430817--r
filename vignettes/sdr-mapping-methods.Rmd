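---
title: "Methods: mapping a sex locus under sex reversal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping a sex locus under sex reversal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrscan)
```

## The problem and the model

`sdrscan` targets species with male heterogamety (XX/XY) in which the
environment — typically high rearing temperature — can masculinise XX
genotypes. Such *neomales* are phenotypically male but carry no Y
haplotype, so any contrast keyed on phenotypic sex mixes two genetic
classes on the male side. The package models exactly this situation and
implements the standard two-step answer:

* an **individual-based step** (RAD tags) that can see each animal
  separately, and therefore can detect markers carried by only a subset
  of phenotypic males (the true XY males) while absent from all
  females;
* a **pool-based step** (two-pool whole-genome counts) that has genome-wide
  resolution but no individual resolution, and therefore needs a male
  pool free of XX contamination — which the first step supplies.

The genetic model is deliberately minimal. A Y haplotype differs from X
at Y-divergent sites confined to a non-recombining region (the SDR). An
XY individual is heterozygous at every such site; XX individuals are
homozygous for the reference allele. All other polymorphism is shared
between the sexes. Within these assumptions the expected pooled
Y-allele frequency is purely compositional:

$$ f_Y = \frac{n_{XY}}{2\,n_{\text{pool}}} $$

so a pure XY male pool has \(f_Y = 0.5\) (one Y per diploid) and a
half-contaminated pool has \(f_Y = 0.25\). This arithmetic is the single
most load-bearing fact in the design, and it is asserted directly in
the test suite against simulated pools of several compositions.

## Site classification and the window scan

A sync record carries one `A:T:C:G:N:del` count sextet per pool.
Classification follows the published pooled-scan criteria, with
defaults frozen in `poolscan_params()`:

| parameter | default | meaning |
|---|---|---|
| `min_depth` | 10 | minimum per-pool nucleotide depth (A+T+C+G); below it in either pool the site is `low_depth` |
| `freq_het`, `range_het` | 0.5, 0.2 | heterozygous band: both alleles in [0.3, 0.7] |
| `freq_hom`, `range_hom` | 1.0, 0.02 | fixed pool: major allele frequency ≥ 0.98 |
| `window_size` | 100 kb | sliding window width |
| `output_resolution` | 500 bp | distance between output points |

Decisions the criteria themselves do not settle, resolved here as
package policy:

* **Depth excludes N and del.** The frequency bands speak about
  nucleotide alleles; ambiguous bases and deletions carry no allele
  information, so they count toward neither depth nor frequency.
* **"Exactly two alleles" in the heterozygous pool.** A third allele at
  frequency above \(1 - f_{het} - r_{het}\) (0.3 at the defaults)
  disqualifies the site; triallelic noise should not pass as a
  sex-linked heterozygote. With the default band this follows from the
  two-in-band requirement, but the rule is applied explicitly so that
  non-default bands behave sensibly.
* **Boundary tolerance.** Frequencies are ratios of small integers and
  thresholds like 0.3 and 0.98 are compared with a 1e-9 slack, so a
  site at exactly 49/50 = 0.98 passes the homozygosity bound regardless
  of floating-point representation. Ties for the major allele are
  broken by base order (A, T, C, G); the tie only matters in degenerate
  pools that the depth filter removes in practice.
* **Windows are centred** on each output point and clipped at the
  chromosome ends (closed interval `[pos − w/2, pos + w/2]`). Whether
  published tracks centre or left-anchor their windows is not stated;
  centring keeps peaks symmetric around dense regions and is asserted
  against a brute-force interval recount in the tests, so the
  convention is at least internally unambiguous.
* **Depth-ratio track.** Window mean depths are normalised by total
  per-pool depth (library size) and log2-transformed with a pseudocount
  of 1: `log2(((dm+1)/Dm)/((df+1)/Df))`. The pseudocount keeps empty
  windows finite (at 0 when both pools are empty).

## Calling the SDR

The published analysis delimited its sex-determining region from a
figure box; no explicit caller is described. `call_sdr()` therefore
defines one, kept as simple as defensible: flag windows with
male-specific count above the genome-wide mean + `z_threshold` SD
(default 3), merge flagged windows within `merge_gap` (500 kb, enough
to bridge assembly-scale fragmentation of a real signal), report merged
spans at least `min_span` (1 Mb) long. All three constants live in
`sdr_policy()` and are deliberately configurable; the defaults recover
a planted multi-megabase region at desk scale while leaving a
background-only genome call-free (both properties are tested across
seeds).

A genuine limitation of a mean + k·SD rule: it is *relative*. Any
region enriched well above the genome-wide distribution is flagged, no
matter how far its absolute density is below what a pure XY pool would
give. The consequence is quantified below.

## The synthetic-data generator

The generator's defaults encode the emulated study conditions:

* **Cohort**: 30 phenotypic males, 30 phenotypic females
  (`population_params()`); phenotypic females are all XX; each
  phenotypic male is XX with probability `neomale_rate` (default 0.5,
  the share observed in outdoor-reared animals of the emulated study).
* **Genome** (`genome_model()`): five 40 Mb linkage groups with a 12 Mb
  Y-divergent region planted on "LG22" — the scale of the reported
  non-recombining region (~11.7 Mb), on a genome small enough to scan
  in under a second. Background shared SNPs at 1e-4 per bp and
  Y-divergent sites at 1e-3 per bp inside the SDR: a deliberate,
  roughly tenfold thinning of realistic densities that preserves the
  ~100 sites per 100 kb window contrast that drives the scan.
* **Tag depths**: a present tag has depth 1 + Poisson(19) (mean 20);
  presence is thinned by dropout `tag_dropout` (default 0.1, so a tag
  carried by all 15 XY males is typically seen in 12–15 of them, the
  published carrier range). Per-individual RAD depth distributions are
  not published; the shifted Poisson is the simplest model that
  respects the minimum-depth presence filter, not an inference about
  real data.
* **Pool counts**: per-site, per-pool depth is Poisson(`pool_depth`,
  default 50) and allele counts are binomial draws from the pool's
  compositional frequency. Background sites share one uniform(0.1,
  0.9) allele frequency in both pools.
* **Crosses**: Mendelian segregation from an XX or XY sire with an XX
  dam; XX offspring become phenotypic males with probability
  `neomale_rate`; gonads are undifferentiated with probability
  `undiff_rate` (default 0.2, inside the 11–31% range seen in the
  emulated crosses); marker calls flip with probability `discordance`
  (default 0.015, about one discordant call in 65). `run_pipeline()`
  lowers the cross neomale rate to 0.078 by default, emulating indoor
  low-temperature rearing of the validation crosses as opposed to the
  outdoor discovery population.

Every generator accepts a seed and is byte-identical under it; the
pipeline derives one sub-seed per stage.

What the generator does **not** emulate: read-level errors and
mismapping (background sites are clean shared polymorphisms, so the
scan's background of spurious sex-specific SNPs is essentially zero —
cleaner than real data), linked polymorphism/LD, recombination maps,
reference fragmentation, copy-number differences between X and Y
(the depth-ratio track is flat by construction), and XY females beyond
the generic marker discordance. Passing tests therefore demonstrate
correctness of the computations under the stated model, not robustness
to every artefact of real pooled sequencing.

## Sensitivity to neomale contamination

The compositional arithmetic makes the purification step matter: at
50% XX contamination the pooled Y frequency is 0.25, outside the
[0.3, 0.7] detection band in expectation. The package reproduces this
sensitivity, and the tests quantify it: with a pure XY pool ≥ 95% of
planted sites classify male-specific at 50x, while a half-contaminated
pool retains only a minority (the binomial probability of sampling into
the band, about 0.21 at Poisson(50) depth).

One nuance follows from the relative SDR threshold discussed above.
Because sampling leakage leaves ~20% of the diluted sites in the band
while the simulated background contributes none, a mean + 3 SD rule can
still flag the diluted region on an otherwise clean synthetic genome —
dilution degrades the signal fourfold to fivefold but does not erase
it. Against a realistic, noisier background the same dilution is what
buries the signal; on this generator's clean background, complete
suppression requires the band probability itself to collapse, i.e. a
pool Y frequency well below 0.25 (the binomial tail shrinks rapidly as
the realised XY fraction falls). The pipeline-level tests therefore
assert the dilution of the site-level signal, which is the mechanism,
rather than a guaranteed absence of calls.

## Marker discovery choices

* **Presence threshold** `min_depth = 1`: any read counts as presence,
  matching the default of individual-based RAD sex-marker tools; the
  threshold is exposed for stricter use.
* **`min_males = 12` is inclusive.** The emulated study describes
  markers "present in more than 12 males" in one place and "present in
  12–15 males" in another; the inclusive bound is the only reading
  consistent with both, and it is the one implemented.
* **Significance**: Pearson chi-square without continuity correction,
  Bonferroni over carried tags. An exact-test oracle in the test suite
  confirms the chi-square ordering agrees with Fisher's exact test on
  the male-only margin, so the cheaper test ranks tags identically.
  Degenerate tables (no carriers, all carriers, an empty sex) return
  p = 1 rather than NaN.
* **Carrier classification** uses `min_carry_fraction = 0.5`: an
  individual is a Y-carrier when it carries at least half the marker
  tags. At 10% dropout a true XY male loses 16+ of 32 tags with
  probability ~1e-12, and a true XX individual needs as many false
  presences, so the call is effectively error-free under the model;
  the default tolerates much worse dropout before misclassifying.

## Cross statistics conventions

* The female:male ratio is reported truncated toward zero at one
  decimal (83:7 → 11.8, 65:48 → 1.3) — the only rounding convention
  consistent with both published values; percentages are half-up at one
  decimal (7/90 → 7.8).
* Fisher's exact two-sided p sums hypergeometric masses not exceeding
  the observed table's mass with R's `1 + 1e-7` tie tolerance. It is
  implemented directly on the hypergeometric density, which makes the
  exhaustive margins ≤ 40 verification in the test suite (~7.4e5
  tables, against an independent `choose()`-based enumeration and spot
  checks against `stats::fisher.test()`) run in seconds.
* Undifferentiated offspring are excluded from linkage tables, ratio
  and reversal estimates, and reported as a separate count; a cohort
  with no sexed offspring is refused rather than silently returning 0/0.
* The sex-reversal rate of an XX-sired cross uses the exact
  Clopper–Pearson interval (`stats::binom.test()`); its coverage at a
  7.8%-scale rate and n = 90 is verified by simulation (≥ 93/100 seeded
  runs).

## Problem sizes

The default desk-scale configuration — 5 × 40 Mb genome, ~30k sync
sites, 400k scan windows, 2032 tags × 60 individuals, crosses of ~130
offspring — runs the full pipeline in a few seconds, which is what
makes property-style testing across many seeds practical. All sizes
scale through `genome_model()` and the rate parameters; the scan is
O(sites + windows) per chromosome via sorted-position interval
counting.

## Known limitations

* The SDR caller is a z-score outlier rule, not a segmentation model;
  strongly non-stationary backgrounds (real assemblies with repeat
  deserts and collapsed regions) would need a local background model.
* The chi-square sex-bias test is asymptotic; for very small cohorts
  the exact test should be preferred (the package exposes
  `fisher_exact_2x2()` for that purpose).
* Tags are exact units: no clustering across sequencing mismatches, no
  anchoring of tags to an assembly.
* Only two pools (one per sex) and only female-to-male reversal are
  modelled; XY females enter only through marker discordance.
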