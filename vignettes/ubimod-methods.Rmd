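---
title: "ubimod methods: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ubimod methods: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubimod)
```

This vignette is the package's own account of the four quantitative models
it implements, the assumptions behind them, the tunable parameters and
their defaults, and the numerical decisions taken where a published method
description left the details open.

# Weighted chemical shift perturbation mapping

## Model

A backbone amide cross peak moves between two ¹H–¹⁵N HSQC spectra when the
chemical environment of that residue changes — by a covalent modification
elsewhere in the protein, a point substitution, or ligand binding. The two
dimensions are combined into a single per-residue displacement

$$\Delta\omega = \sqrt{\frac{(\Delta^{1}\mathrm{H})^2 +
\tfrac{1}{25}(\Delta^{15}\mathrm{N})^2}{2}},$$

where the 1/25 factor compensates the roughly five-fold wider dispersion
of ¹⁵N shifts, so both nuclei contribute comparably. `weightedCSP()`
computes this for every residue assigned in both lists; residues present
in only one list (typically broadened beyond detection) are dropped from
the statistics and reported in the profile's `dropped` slot, because a
missing peak carries no usable shift and zero-filling would bias the
cutoffs downward.

Prolines have no backbone amide and are simply absent from peak lists —
never placeholder rows. All downstream statistics operate on the
intersection of assigned residues.

## Significance cutoffs

`significanceCutoffs()` pools the non-excluded $\Delta\omega$ values of
one or more profiles and returns the mean and the mean plus one sample
standard deviation. Values above the mean count as significant, values
above mean + SD as strongly significant. Two conventions matter:

* **Exclusion sets are per profile.** When comparing acetyl-lysine
  variants against the unmodified protein, all lysines are excluded from
  the pooled statistics (the modified residue and its peers dominate
  trivially); when comparing point variants, only the substituted position
  is excluded. Both are caller-configurable, and excluded residues keep
  their values — they are only masked from the cutoff arithmetic and never
  classified.
* **The SD uses the n − 1 denominator.** The method description does not
  specify the estimator; the sample SD is the conventional default and the
  difference is negligible at the pooled sizes involved (tens to hundreds
  of values).

For titration endpoints the cutoffs default to per-experiment pooling;
passing a list of profiles pools across experiments instead. Both modes
exist because published figures draw one pair of cutoff lines per panel
set without stating which pooling produced them.

## Clusters and patches

`classifyAndCluster()` defines a perturbation cluster as a maximal run of
significant residues in sequence space, bridging at most `gapTolerance`
(default 1) consecutive non-significant residues, and keeping runs with at
least `minSize` (default 2) significant members. The published analyses
describe clusters visually without a formula; this rule is the simplest
deterministic surrogate, and both knobs are exposed. Patch overlap
(`patchOverlap()`) then reports how many of the four members of the I44
(L8, I44, H68, V70) or I36 (L8, I36, L71, L73) surface epitopes are
significant — the structural question behind most ubiquitin-binding
events.

A property worth knowing when interpreting cluster output on noisy data:
with a mostly-unperturbed profile the pooled mean sits near
$(\sum \Delta\omega_{planted})/n$, which for a three-residue plant of
0.3 ppm on a 76-residue protein is only ~0.015 ppm. Shift noise of a few
hundredths of a ppm therefore lifts an appreciable fraction of unperturbed
residues above the mean, and adjacent false positives form spurious
two-residue clusters. Exact recovery of a planted span is only guaranteed
when the shift noise is small compared to that pooled mean — the package's
property tests use 0.003 ppm noise against 0.3 ppm plants — not merely
small compared to the planted amplitude. Raising `minSize` or reading only
the mean + SD class is the practical mitigation on real spectra.

# Global 1:1 binding fit

## Model

Assuming a single binding site and fast exchange, the observed CSP at
total protein concentration $P$ and total ligand concentration $L$ is the
bound fraction times a residue-specific saturation amplitude:

$$\Delta\omega^{obs} = \Delta\omega^{max}\,
\frac{P + L + K_d - \sqrt{(P + L + K_d)^2 - 4PL}}{2P}.$$

This is the exact solution of the 1:1 equilibrium — no weak-binding
approximation — so it remains valid when $P \sim K_d$, which is exactly
the regime of the low-micromolar designs the package targets. The
discriminant is clamped at zero against floating-point round-off, making
the stoichiometric limit $K_d \to 0$ ($\Delta\omega \to
\Delta\omega^{max}\min(1, L/P)$) exact.

Concentrations can be given per step or derived from a cumulative dilution
scheme (`concentrationsFromScheme()`): start protein $P_0$ in volume
$V_0$, ligand stock $L_{stock}$, additions $\Delta V_i$, giving
$[P]_t = P_0 V_0/(V_0 + \Sigma\Delta V)$ and
$[L]_t = L_{stock}\Sigma\Delta V/(V_0 + \Sigma\Delta V)$. Both entry
points exist because experimental reports often give start and stock
concentrations but not pipetted volumes.

## Residue selection

Two filters precede the fit, mirroring standard titration practice:

* **Attrition** (`intensityAttrition()`): a residue losing *more than*
  90 % of its step-0 intensity by the final step is in intermediate/slow
  exchange and its apparent CSP is unreliable. The boundary is strict —
  exactly 90 % loss is not flagged — and the rule reads net endpoint loss
  (final vs step 0), not the per-step minimum. A residue absent at the
  final step counts as fraction 0.
* **Significance everywhere** (`selectFitResidues()`): fit residues must
  be above the mean cutoff at the endpoint of *every* experiment being
  compared and attrition-flagged in *none*, so the same reporters are fit
  across variants.

An empty selection is an explicit error: a fit with no valid reporters
should fail loudly, not proceed on arbitrary residues.

## Optimisation and uncertainty

For fixed $K_d$ the model is linear in each $\Delta\omega^{max}$, so every
amplitude has the closed-form least-squares solution
$\hat d_r = \sum_s y_{rs} f_s / \sum_s f_s^2$ (with $f_s$ the bound
fraction at step $s$), truncated at zero to honour non-negativity. The fit
therefore reduces to a one-dimensional profile search on $\log_{10} K_d$:
a 161-point coarse grid over the search bounds ($10^{-3}$–$10^{5}$ µM,
enforcing positivity; roughly 0.05 decades per step) brackets the minimum,
which `stats::optimize()` then refines to machine-level tolerance. Against
an independent brute-force grid oracle the optimum agrees to within one
grid step on every tested stochastic instance. Non-convergence or an
optimum at a search bound is flagged on the result object, never silently
repaired.

The $K_d$ standard error is the asymptotic estimate from the numerical
Jacobian of the full residual vector with respect to
$(\log_{10} K_d, d_1, \dots, d_R)$, delta-transformed back to the $K_d$
scale; an optional seeded residual bootstrap (percentile interval)
complements it, since published ± values on dissociation constants rarely
state their estimation method. At the default design (protein start 33 µM,
seven additions of an 803 µM stock to ~3× molar excess, six reporters with
amplitudes 0.05–0.5 ppm) and 0.005 ppm CSP noise, the package's tests
verify a median relative error below 10 %, with the reported asymptotic SE
of the same order; identifiability degrades once $K_d$ exceeds the largest
sampled $[L]$ (~99 µM in this design), which the tests also exercise — a
titration simply carries little curvature information beyond its
concentration range.

# AE-MS label-free statistics

## Pipeline order

The workflow is fixed: decoy/contaminant filtering → log2 transform (zero
intensity = not detected = missing) → valid-value filter → imputation →
testing. Re-running with the same seed is bit-identical.

* **Valid-value filter:** at least 6 observed values among the 8 runs of
  *at least one* bait group (default). This reading is friendly to
  missing-not-at-random data — a genuine interactor of one bait is absent
  from the other baits' pull-downs by design, and a strict across-all-
  columns count would discard it. The strict mode is available
  (`validAcross = "all"`).
* **Imputation** (`imputeMissing()`): per sample column with observed mean
  $\mu$ and SD $\sigma$, missing entries are drawn from
  $N(\mu - 1.2\sigma, (0.3\sigma)^2)$ — a narrow distribution placed just
  below the detection limit, encoding the left-censoring interpretation of
  missingness. Imputation is per column because detection limits are
  per-run properties. Observed values are never altered.

## Moderated ANOVA and permutation FDR

`anovaS0()` computes per protein
$$d = \frac{\sqrt{MS_{between}}}{\sqrt{MS_{within}} + S_0},$$
with $S_0 = 4$ by default. The exact statistic of the original desktop
software is unpublished; this SAM-style denominator moderation keeps the
same $S_0$ semantics — a protein must show a large absolute between-group
spread, not merely a tiny variance, to score highly — and reduces exactly
to the classical one-way F ranking at $S_0 = 0$ ($d = \sqrt{F}$ then,
which the tests verify against `stats::lm`/`anova`).

FDR comes from permuting the column group labels (250 permutations by
default, seeded; complete enumeration when the design admits fewer
distinct label assignments): for each observed $d^*$,
$$q(d^*) = \frac{\mathrm{mean}_{perm}\,\#\{d_{perm} \ge d^*\}}
{\#\{d_{obs} \ge d^*\}},$$
capped at 1 and monotonised so $q$ never decreases with increasing $d$.
Significance is $q \le$ 0.002. Under a fully null matrix this calibration
yields zero discoveries in at least 95 % of seeded runs (verified on
100-protein, 3 × 4-column nulls in the tests).

## Profiles, clustering, bait correlation

Significant rows are z-scored across all samples (mean 0, SD 1 per row),
replicates collapsed to the per-bait median, and proteins clustered
hierarchically with distance $1 - r$ (Pearson) and average linkage. Rows
are pre-sorted by protein identifier so exact-tie merges and the leaf
order are deterministic. The published description says only "clustered by
correlation"; average linkage is the conventional choice for correlation
distances and is stated here as the package's own. `baitCorrelation()`
reports the Pearson matrix between bait median profiles — the
interactome-similarity heat map between variants.

Two scalar helpers complete the MS toolbox: `prmNormalize()` (targeted-MS
acetylation signal over the signal of the stably abundant C-terminal
ubiquitin peptide, residues 64–73) and `deacetylationFraction()`
(deacetylated over total peak area).

# Minimum-distance matrices

`meanMinDistanceMatrix()` computes, per residue pair and frame, the
minimum distance over all atom pairs, truncates it at the cutoff (default
1 nm), then averages over frames — truncate-then-average, matching the
semantics of the GROMACS `mdmat` tool this descriptor family comes from.
Averaging before truncation would let a single excursion beyond the cutoff
shift an otherwise-contacting pair's mean, which is exactly what the cap
is meant to suppress. All atoms participate by default, hydrogens
included when the model carries them; `heavyOnly = TRUE` restricts to
heavy atoms. The internal unit is nm; PDB Ångströms are converted on read.
When an ensemble comprises several independent replicas, frames are
concatenated before averaging (difference matrices are then taken between
the concatenated means); averaging per replica first and then across
replicas gives the same result for equal replica lengths.

`pairMinDistance()` exposes the underlying per-frame series for a single
residue pair — e.g. tracking whether a modified side chain at position 11
approaches residue 34. `differenceMatrix()` subtracts a reference matrix
elementwise; it requires identical residue sets and cutoffs and is
antisymmetric under argument swap.

# Synthetic-data generators

Each generator is a pure function of its spec and seed, writes the same
on-disk formats the readers consume, and composes with its pipeline stage
to recover planted truth exactly at zero noise:

* `simulateCSPPair()` plants per-residue CSPs using the decomposition
  $\Delta^1H = \Delta\omega\sqrt{2}\cos\theta$,
  $\Delta^{15}N = 5\Delta\omega\sqrt{2}\sin\theta$, an algebraic identity
  under the weighted-CSP formula for any angle $\theta$ (uniform random
  per residue by default). At 76 residues the ubiquitin sequence supplies
  real residue types, proline gaps and the seven lysine positions; base
  chemical shifts are uniform draws from the amide region (6.5–10.5 /
  103–133 ppm), not literature values.
* `simulateTitration()` evaluates the exact isotherm per step and residue,
  adds Gaussian noise on the CSP scale, and decays intensities as
  $I_0(1 - \beta \cdot f_{bound})$ with a per-residue broadening
  coefficient $\beta \in [0,1]$, so $\beta \approx 1$ reporters trip the
  90 %-loss rule near saturation. The default design (33 µM start, 500 µL,
  803 µM stock, additions 4+5+7+9+11+12+14 µL ≈ 3× molar excess, six
  reporters) reproduces the published low-concentration experiment up to
  the unreported pipetting volumes.
* `simulateLFQ()` draws log2 intensities as baseline + bait effect +
  noise, censors below a detection limit (default 22 on log2 scale against
  a 25 ± 2 baseline, so a modest left tail goes missing as in real LFQ
  tables), plants three interactor clusters
  of 20 proteins with 4–6 log2 enrichment on fixed bait subsets among 300
  background proteins, and injects reverse/contaminant decoy rows. These
  sizes keep an end-to-end run around a second while leaving the planted
  structure comfortably recoverable (adjusted Rand index ≥ 0.9 is
  asserted in the tests).
* `simulateEnsemble()` builds an extended-chain template (0.5 nm residue
  spacing) with per-frame Gaussian jitter and an optional systematic
  displacement of selected residues.

**What the generators do not emulate** — and hence what passing tests do
not show about real data: peak overlap and misassignment in crowded
spectra; field-dependent exchange regimes (noise is i.i.d. Gaussian, line
broadening is a deterministic linear decay); correlated, intensity-
dependent proteomics noise and peptide-level effects below the protein
summary; and any physically realistic chemical-shift prediction or
conformational sampling. The generators validate the *statistical
machinery*, not the spectroscopy or the mass spectrometry.

# Degenerate inputs and error policy

Errors are raised early and name the offending entity: duplicate residue
assignments, unparsable peak lines (with line number), empty pairings,
fewer than two pooled cutoff values, empty fit selections, single-step
(unidentifiable) titrations, all-missing imputation columns, zero-variance
correlations, mismatched residue sets in matrix differences, missing
config fields and missing input paths. Warnings (not errors) cover
skipped zero-intensity residues, infinite test statistics at $S_0 = 0$,
zero-variance bait profiles and degenerate (< 2 significant) clustering.

# Problem sizes in the shipped tests

The suite is sized to run comfortably on one CPU: 50 stochastic fitter
instances against the grid oracle, 100 seeded null-matrix calibration runs
at 100 proteins × 12 columns, one full synthetic interactome
(360 proteins × 64 runs) per recovery test, 10⁴ imputation draws for the
moments check, and ensembles of ≤ 10 residues for the exact distance
oracles. These sizes are the package's own choice of demonstration scale;
all of them can be raised through the generator specs.
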