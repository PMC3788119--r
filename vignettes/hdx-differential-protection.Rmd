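---
title: "Differential protection analysis of HDX-MS data with hdxdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential protection analysis of HDX-MS data with hdxdiff}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxdiff)
library(dplyr)
```

## The measurement and the statistic

Backbone amide hydrogens exchange with deuterium when a protein is diluted
into D~2~O. A hydrogen that is hydrogen-bonded or buried exchanges slowly;
an exposed one exchanges fast. Peptide-level HDX-MS reads this out by
quenching the exchange, digesting with pepsin, and measuring the centroid
(intensity-weighted average) mass of each peptic peptide's isotopic
envelope. Comparing two states of the same protein — here a monomer against
a cross-linked dimer — localizes the surface that becomes shielded on
oligomerization.

Raw centroid masses are not comparable across peptides, so each observation
`Mex` is normalized against two technical controls measured for the same
peptide in the same apparatus:

* the **in-exchange control** `Mex0`: deuterium picked up unavoidably
  during quench and digestion (the 0% reference), and
* the **out-exchange control** `Mex100`: the mass after exhaustive
  labeling, which already incorporates the back-exchange losses of the
  workflow (the 100% reference).

The fraction of exchange is

$$f = \frac{M_{ex} - M_{ex0}}{M_{ex100} - M_{ex0}},$$

with mean and sample SD over at least three replicates. For a state pair
the differential statistic is $\Delta = f_{\mathrm{ref}} - f_{\mathrm{test}}$
(positive = more protected in the test state), its error is the **linear
sum** of the two SDs, and a peptide is called protected when
$\Delta > 2\sigma$. The linear SD sum always dominates the quadrature
combination, so calls under this rule are conservative; quadrature is
available through `error_model = "quadrature"`.

## Screening rule

Calls are made per time point. The headline screen asks for significance at
the earliest exchange time, where differences between states are largest
before exchange saturates. By default (`confirm_next = TRUE`) a peptide
must additionally be significant at the second-earliest time point when one
was measured. The reason is calibration: with three replicates, the
one-sided probability that a null peptide exceeds $2(\hat s_1 + \hat s_2)$
is about 0.5% per peptide-time (the sample SDs of $n=3$ are themselves
noisy), so a digest of tens of peptides screened at a single time point
produces a false region every few datasets. Requiring the protection to
persist into the next time point drops the null rate to roughly $3\times
10^{-5}$ per peptide while leaving genuine protection — which decays over
minutes, not seconds — untouched. Setting `confirm_next = FALSE` restores
the literal single-time-point screen. No multiple-testing correction is
applied (a deliberate match to the workflow this package reproduces); the
choice is recorded in every report log.

Charge states are computed and reported separately — agreement of $f$
across charge forms of one peptide is a useful internal consistency check —
and consolidated only at the screen stage, where a peptide is differential
if any of its charge forms passes.

Significant peptide spans are merged into residue-level protected regions.
Overlapping spans always merge; bookended spans (`end + 1 == start`) merge
by default so that single-residue gaps (e.g. a proline that carries no
amide) do not split one region in two (`bookend = FALSE` switches this
off). Merging is idempotent and order-invariant.

## The forward simulator

No public raw data exist for the study design this package targets, so the
package ships a forward simulator with known ground truth; every inference
stage is validated by parameter and region recovery against it.

Exchange is simulated in the EX2 regime: a residue with intrinsic rate
$k_{int}$ and protection factor $P$ has
$d_i(t) = 1 - \exp(-(k_{int}/P)\,t)$. Peptide-level uptake interpolates
between the experimental floor and ceiling,

$$D(t) = \alpha N + (1 - \alpha - \beta) \sum_i d_i(t),$$

where $N$ is the exchangeable-amide count
(length − 1 − prolines beyond position 1; the "exclude residue 2" variant
is a flag), $\alpha$ is the in-exchange fraction and $\beta$ the
back-exchange fraction. This per-site interpolation keeps every expected
mass inside the control bracket $[M_{ex0}, M_{ex100}]$ and makes the
downstream $f$ an unbiased estimator of $\mathrm{mean}(d_i)$; a formulation
that adds the in-exchange floor on top of the scaled uptake would exceed
the out-exchange ceiling at saturation whenever $\alpha > 0$. Control rows
are emitted noise-free at exactly
$M_{ex0} = M + \alpha N \Delta m_D$ and $M_{ex100} = M + (1-\beta) N \Delta m_D$,
with $M$ the centroid of the peptide's natural isotope envelope and
$\Delta m_D = 1.006277$ Da the D–H mass difference.

Defaults (all overridable in `hdx_scenario()`):

| parameter | default | rationale |
|---|---|---|
| time points | 10, 60, 1200 s | the short/medium/long grid of the emulated study |
| replicates | 3 | the study's minimum for reported SDs |
| centroid noise | sd 0.02, fraction units | reproduces the few-percent replicate scatter of peptide-level HDX; per-peptide mass noise is scaled by the control span |
| in-exchange α | 0.03 | "very low, in some cases negligible" |
| back-exchange β | 0.15 | typical loss for a fast LC workflow |
| k~int~ | 1 s⁻¹, uniform | recovery tests need controlled ground truth, not chemical accuracy; a per-residue table can be supplied |
| baseline P landscape | blocks cycling 1 / 1500 / 8 / 200 | emulates intertwined unprotected and protected stretches of a folded multidomain construct |

`rage_scenario()` instantiates the built-in two-state benchmark: a
**synthetic** 304-residue construct (reported as residues 23–326) carrying
the interface motifs at their published positions — SASEL at 129–133,
PRVWEPVPLEE at 227–237 followed by V238-Q239-L240 and the C2-domain start
V241, PARGGDPR at 196–203, GPQESR at 309–314 — on a fixed pseudo-random
background (it is *not* the real RAGE sequence). Interface residues carry
baseline $P = 5$ in both states; the dimer state multiplies $P$ by 20
(configurable) in regions 129–133 and 227–237, so at 10 s the interface
peptides differ by $\Delta f \approx 0.77$, the difference shrinks at 60 s
and vanishes by 1200 s — strongest early, confirmed at one minute, complete
at twenty. The digest contains the four interface peptides (ASEL, SASEL,
PRVWEPVPLE, PRVWEPVPLEE; two charge states each) plus background peptides
tiled around the two interface regions with deterministic gaps chosen so
that sequence coverage is approximately 76%, and three decoy
identifications that fail the quality filters. Because pepsin in the
emulated map produced no other peptide crossing the interface regions, the
expected screen outcome is exactly those four peptides.

What the simulator does **not** emulate: EX1/bimodal envelopes, sequence-
dependent intrinsic rates, retention-time drift, overlapping envelopes, or
peptide-dependent ionization efficiency. Passing recovery tests therefore
demonstrate the correctness of the statistics and bookkeeping, not
robustness to every pathology of real spectra.

## Isotopic envelopes

`natural_isotope_distribution()` convolves per-element isotope patterns
(fixed published abundances) from the peptide's elemental composition,
binning isotopologues by nominal neutron excess while carrying the
abundance-weighted exact mass per bin; the tail is truncated once
cumulative abundance exceeds `1 - trunc_tol` (default `1e-6`).
`deuterated_envelope()` convolves that pattern with the exact
Poisson-binomial distribution of incorporated deuterons, each adding
1.006277 Da. First moments are exact under this representation, so the
centroid shift equals $\Delta m_D \sum d_i$ to machine precision — the
property the uptake statistic relies on. Tests verify both distributions
against brute-force enumeration (all isotopologue combinations with up to
three heavy atoms; all $2^N$ deuteration states for $N \le 12$) at 1e-9.
Averagine-style approximation is deliberately absent: sequences are always
known here.

## Structural interface metrics

`sasa()` implements Shrake–Rupley sampling: a deterministic Fibonacci
lattice of `n_points` directions (default 960) on each atom's
probe-expanded sphere (probe 1.4 Å; radii C 1.70, N 1.55, O 1.52, S 1.80 Å;
hydrogens ignored), points occluded by any neighbouring expanded sphere.
An isolated atom recovers $4\pi(r+probe)^2$ exactly; 960 points agree with
a 10000-point refinement within 2% on fixtures, and rigid motions change
results only at the sampling level. `buried_surface()` computes
$\sum_{chains} SASA_{isolated} - SASA_{complex}$ with a per-residue burial
profile and hydrophobicity flags (A, V, L, I, M, F, W, P, Y);
`contact_profile()` lists inter-chain residue pairs within 4.5 Å
(heavy-atom) and flags Arg/Lys-N to Asp/Glu-O pairs within 4.0 Å as salt
bridges. `burial_energy()` converts hydrophobic buried surface to a
stabilization estimate with a linear coefficient of 11.1 cal mol⁻¹ Å⁻²,
back-calculated so that 900 Å² of hydrophobic burial corresponds to about
10 kcal/mol; reports flag this provenance. These operations are validated
on fixtures and independent oracles — the reference surface-area figures of
the emulated study came from coordinates that were never deposited, so they
are not used as test targets.

## Numerical and degenerate-input choices

* Control spans below 0.1 Da are uninformative; such peptides are excluded
  with a logged reason rather than producing unstable fractions.
* Fractions slightly outside $[0,1]$ are kept for statistics (they are
  legitimate noise excursions) and flagged beyond ±0.15; clipping is a
  display-only option of the Woods plot.
* `significant` uses strict `>` at exactly $2\sigma$.
* Matching ties are broken by smallest m/z deviation, then smallest RT
  deviation.
* Groups with fewer than two replicates are dropped (SD undefined).
* Simulation under a fixed scenario seed is byte-reproducible; the RNG
  state of the caller is restored.

## Problem sizes used in the tests

The shipped suite simulates the 304-residue benchmark (31 peptides, 62
peptide-charge forms, two states, three times, three replicates — about
1100 uptake rows) in roughly a second; the null-calibration check repeats
it over 20 seeds. Structural checks use clusters of 10–48 atoms where the
closed-form, refinement and Monte-Carlo oracles are exact or tight. These
sizes were chosen because every assertion they support is already sharp at
this scale; all generators accept larger designs unchanged.

## Known limitations

* The screen is peptide-level; no sub-peptide (residue-level) deconvolution
  of uptake is attempted.
* Exchange-rate fitting to the kinetics curves is out of scope; the
  package reports fractions, as the workflow it reproduces did.
* EX1 signatures (bimodal envelopes, peak-width analysis) are not modelled
  or detected.
* The burial-energy coefficient is a back-calculated linear proxy, not a
  transferable force-field term.
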