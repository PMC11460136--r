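---
title: "Methods: diagnostic-SNP mass quantification and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnostic-SNP mass quantification and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbq)
```

## The measurement model

A pyrosequencing assay at a biallelic diagnostic SNP reports, for each
technical replicate, the fraction of light signal attributable to each base.
herbq treats that fraction as an allele *frequency* on $[0,1]$ and models it
as the DNA-share of the species carrying the base:

$$ R = \frac{\sum_{s \,\in\, \text{carriers}} m_s y_s}
            {\sum_{s \,\in\, \text{amplifying}} m_s y_s} $$

where $m_s$ is the mass of species $s$ in the powder and $y_s$ its DNA
yield per unit mass. Two assumptions make mass quantification possible:

* **Equal yield** ($y_s \equiv 1$): congeneric species contribute DNA in
  proportion to their mass. This is the default and the assumption under
  which the weight equations below are exact. The `yield_factor` argument
  of `mixture_spec()` exists solely for sensitivity analysis — it breaks
  the model deliberately to show how unequal yields would bias weights.
* **Non-amplifying impurities**: soil or flour add mass but no amplifiable
  DNA, so they cancel from both sums. Only the *amplifying* total is ever
  estimable; the impurity mass is invisible to the assay by design.

## The two weight equations

With a known mass $W_{\mathrm{ext}}$ of an external standard — a species
verified absent from the sample, so its site signal is attributable solely
to the spike — measured at mean frequency $R_{\mathrm{ext}}$:

$$ W_{\mathrm{total}} = W_{\mathrm{ext}} / R_{\mathrm{ext}}, \qquad
   W_{\mathrm{tar}} = W_{\mathrm{total}} \times R_{\mathrm{tar}}. $$

These compose to the identity for the standard itself
($W_{\mathrm{total}} \times R_{\mathrm{ext}} = W_{\mathrm{ext}}$), which the
test suite asserts for $10^4$ random inputs, and they are linear in mass, so
rescaling a mixture rescales every output weight — the scale-equivariance
property also under test.

Replicate frequencies are averaged (arithmetic mean) per site *before* the
weight math. Frequencies enter the equations raw by default; the `curve`
argument of `quantify_sample()` optionally inverts a fitted standard curve
$x = (y - b)/m$ first. Raw-by-default matches how such assays are read in
practice: fitted responses are near-identity (slopes within ~1% of 1), and
inversion is a refinement, not a prerequisite.

Internally all quantities are kept at full double precision; rounding to
4 decimal grams and whole-percent frequencies happens only in the report
layer (`print`, `write_quant_result()`). Display-rounded frequencies need
not sum to 100% — a sample whose components read 33% + 20% + 50% is
internally consistent — which is why the consistency check below uses a
tolerance.

## Screening rules and their edge cases

A column is **group-diagnostic** when every target-group sequence carries
one fixed unambiguous base and every adulterant sequence a different fixed
unambiguous base; **species-diagnostic** when one adulterant taxon is fixed
against all other species in the grouping. Policy decisions, each of which
was genuinely open:

* **Gaps and ambiguity codes disqualify a column.** Any `-` or IUPAC
  ambiguity in a considered sequence removes the column from candidacy.
  This is conservative: an N might be compatible with fixedness, but a
  quantitative assay site must not rest on uncertain evidence.
* **Backgrounds must be fixed for a single alternative base** in the
  default mode, matching how such sites are reported (one genotype per
  side). `background = "any"` relaxes this to "background lacks the target
  allele" for exploratory screens; such sites carry `NA` as background
  allele and cannot parameterise the simulator without explicit genotypes.
* **Joint taxa.** Sister species with no private fixed difference (the
  FPB pair in the packaged example) are screened as a named union and
  share one site; their masses are quantified jointly, never split.
* **A-base ranking.** Among group-diagnostic candidates, sites whose
  target or background allele is A rank below A-free sites, because A
  dispensations consume extra substrate and distort quantitative peak
  heights. Unique species sites are exempt — there is no alternative site
  to prefer. Ties break by supporting-sequence count, then position.
* **Support.** Species represented by a single accession yield a warning,
  not an error: toy and pilot alignments are legitimate inputs, but a
  fixedness call from one sequence is weak evidence.
* **Coordinates** are 1-based alignment columns. Published site labels are
  positions within a specific alignment, so reports should always name the
  alignment file alongside the position; the same SNP lands on a different
  column under a different alignment.

The screening implementation is vectorised over a character matrix; the
test suite checks it against an independent per-column oracle (set logic
over `alignment_column()`) on 100+ random alignments with planted sites,
sprinkled gaps and ambiguities, and asserts the monotone property that
adding a violating sequence removes a site.

## Composition calls and the refusal rule

An allele is *present* when its replicate-mean frequency reaches the
presence threshold, default **0.02** — equal to the assay's validated
quantification floor. The sample-level logic is fail-safe:

* pure-target group call → the sample is the target group only;
* mixed group call → target group plus every adulterant whose species
  site is positive;
* mixed group call with *no* positive species site → **unresolved**:
  adulterated, but the adulterant cannot be typed. `quantify_sample()`
  refuses such samples with a classed error rather than distributing
  untyped mass; missing species-site data degrades to unresolved, never
  silently to "pure".

A consistency warning (not an error) fires when identified-component
frequencies sum outside $1 \pm 0.05$; the tolerance absorbs display
rounding and replicate noise while still catching a missing component.

## Validation calculus

* **Repeatability**: RSD = sample standard deviation (the $n-1$
  denominator) over mean, in percent. The $n-1$ convention is not
  arbitrary: on the packaged six-replicate known-proportion table it
  reproduces all six published RSDs to two decimals, while the population
  convention does not (3.21 vs 3.52 for the 15% column) — a discriminating
  check in the test suite.
* **LOD**: lowest adulteration level detected in ≥ 95% of replicates, with
  every higher tested level also passing (the stability clause). A
  replicate counts as *detected* when the adulterant allele's frequency
  reaches 0.01 — deliberately below the 0.02 quantification threshold,
  since detection is a weaker claim than quantification.
* **LOQ**: lowest level with RSD ≤ 25%, same stability clause. LOD and LOQ
  are independent criteria; neither bounds the other.
* **Linearity**: OLS of mean frequency on proportion, gated at R² ≥ 0.99.
* A study with a single tested level leaves LOD and LOQ undefined — one
  level cannot establish stability.

## What the simulator emulates — and what it does not

`simulate_measurements()` draws, per site and replicate,

$$ y = \mathrm{clamp}(a \cdot R + b + \varepsilon,\ 0,\ 1), \qquad
   \varepsilon \sim N(0, \sigma) $$

and mirrors the complementary allele as $1-y$, so biallelic pairs sum to 1
exactly. Defaults and why:

* **$\sigma$ (`noise_sd`) = 0.005** on the frequency scale. This places the
  population RSD at a measured frequency $f$ at $0.005/f$: ≈42% at the
  response to a 1% adulteration level and ≈23% at 2% under the fitted
  response below — i.e., the quantification floor sits at the 2% level,
  with 1% detectable in only ~65% of replicates. That is the calibration
  the validation workflow assumes, surfaced as an explicit parameter.
* **Response $(a,b)$ = identity** by default; the round-trip guarantees
  (exact mass recovery at $\sigma = 0$) are stated against the identity
  response. Validation studies plug in a fitted near-identity response —
  the packaged examples use $(0.994, 0.002)$, a realistic slope/intercept
  for this assay class — which the standard-curve fit then recovers.
* **Seeds** live in the `mixture_spec` and make every simulation
  reproducible; dilution series derive all levels from one seeded stream.

Because a sample RSD over $n = 20$ replicates is itself noisy (standard
error ≈ CV$/\sqrt{2(n-1)}$ ≈ 4 percentage points at the 2% level), the
LOD/LOQ acceptance test asserts the *modal* outcome over 30 independently
seeded 20-replicate studies rather than a single draw; the deterministic
part of the claim (population RSDs straddle 25% between the 1% and 2%
levels, detection clears 95% at 2%) is asserted analytically.

Not modelled, deliberately: PCR amplification bias mechanisms,
pyrosequencing chemistry and pyrogram peak traces (the instrument's
frequency read-out is the modelled level), and DNA fragmentation in heavily
processed products. Passing tests therefore demonstrate the correctness of
the decision rules and mass arithmetic under the stated noise model — not
that a particular wet assay meets its validation gates, which only
instrument data can show.

## Problem sizes

The test and acceptance workloads are desk-scale by construction: toy
alignments up to 30 taxa × 300 columns (100 random instances for the
screening oracle), 1000 seeded 6-replicate quantification runs for the
bias-rate property, and 30 × 5-level × 20-replicate dilution studies for
the LOD/LOQ rule — a few minutes end to end on one core.

## Known limitations

* Weights are relative to the *amplifying* total; non-amplifying impurity
  mass is not estimable from frequencies alone.
* Joint taxa are quantified as a unit.
* Copy-number and yield differences between species violate the equal-yield
  assumption and bias weights proportionally; `yield_factor` lets users
  explore that sensitivity but no correction is attempted.
* The simulator's Gaussian, homoscedastic replicate noise is a modelling
  choice; real replicate scatter at very low levels is heavier-tailed
  (published 1%-level RSDs far exceed what a constant $\sigma$ predicts),
  which is one reason the quantification floor is enforced at 2%.
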