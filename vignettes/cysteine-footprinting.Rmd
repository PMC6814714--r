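---
title: "Quantifying differential cysteine accessibility by spectral counting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying differential cysteine accessibility by spectral counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cysaccess)
```

## The measurement and the model

Covalent-labeling footprinting probes protein conformation in solution: a
thiol-reactive probe (here monobromobimane, mBBr) reacts with accessible
cysteine side chains, the protein is digested with trypsin/LysC, and LC-MS/MS
identifies which peptides carry the modification. A cysteine that becomes
more buried — by a binding partner, by immobilization, or under mechanical
load — labels less; one that becomes more exposed labels more. Comparing
labeling patterns between two conditions therefore reads out conformational
change site by site, including under conditions (such as proteins under
shear force) that crystallography cannot access.

`cysaccess` implements the spectral-counting (SC) quantification of this
experiment. One peptide-spectrum match (PSM) is one spectral count. For a
cysteine at protein residue `s` in one replicate,

* `sc_total(s)` = the number of PSMs whose peptide contains `s`,
* `sc_mod(s)` = the number of those PSMs in which `s` carries the
  modification,
* the labeling ratio is `r = sc_mod / sc_total`, a fraction in [0, 1].

Replicates are combined by a count-weighted mean: replicate `i` contributes
in proportion to the total number of peptides it detected,
`w_i = n_i / N` with `n_i` its `sc_total` and `N = sum(n_i)`, so

```
r_bar = sum(w_i * r_i) = sum(sc_mod_i) / sum(sc_total_i),
```

i.e. the weighted mean is algebraically identical to the pooled ratio, for
*any* split of the same PSMs into replicates. This identity is the core
invariant of the quantification and is tested exactly.

Three uncertainties accompany each estimate:

* the **weighted standard error**
  `SE = sqrt( sum(w_i (r_i - r_bar)^2) / (m - 1) )` over the `m`
  replicates with data (0 when `m = 1`) — between-replicate dispersion;
* the **measurement error** `ME = sqrt(N)/N = 1/sqrt(N)` — the
  signal-to-noise shot limit of a count of `N` spectra; it equals 1 at
  `N = 1` and decreases as `1/sqrt(N)`;
* the **total error** `TE = sqrt(SE^2 + ME^2)`.

The exact dispersion and combination formulas are design choices of this
package: the weighted SE is the simplest normalized-weight dispersion
consistent with a count-weighted mean, and "combining the measurement and
standard error" is taken as a quadrature sum. An RMS variant
(`sqrt((SE^2 + ME^2)/2)`) is available via
`total_error_mode = "rms"` for users who prefer the average-of-squares
reading.

## Differential testing

Differential accessibility between two conditions is tested per site with
Welch's unequal-variance t-test on **replicate-level ratios** (one number
per replicate), the only granularity at which a t-test across replicates is
defined for this design. The test is two-sided, with
Welch–Satterthwaite degrees of freedom; p-values are flagged with the
conventional inclusive star thresholds (≤0.05 *, ≤0.01 **, ≤0.001 ***).
No multiple-testing correction is applied by default because per-site raw
stars are what this kind of experiment conventionally reports;
Benjamini–Hochberg q-values are available with `bh = TRUE`. Experiments
often mix technical replicates and independent preparations; this package
treats every listed replicate as one observation and leaves
technical-vs-biological modeling to the user (a mixed model is out of
scope). Sites with zero variance on both sides are handled explicitly
(equal means: p = 1; unequal: p = 0), and sites detected in only one
condition are reported as presence/absence rows without a p-value.

## Multi-cysteine peptides

Tryptic digestion can leave two cysteines on one peptide (in the
actin-binding domain of alpha-E-catenin, C767/C772 and C787/C793 are close
enough for this), and the MS evidence for *which* cysteine carries the
modification may then be ambiguous. The `localized` flag on a PSM records
that confidence, and two policies govern ambiguous PSMs:

* `localized_only` (default): ambiguous PSMs are excluded from all their
  sites and tracked in `ambiguous_fraction` — conservative, at the cost of
  a small downward bias at multi-Cys sites when ambiguous PSMs are
  predominantly modified ones;
* `fractional`: an unlocalized modification on a k-Cys peptide contributes
  1/k modified count to each contained site — unbiased on average, at the
  cost of attributing counts to sites that may not carry them.

The two agree exactly when every PSM is localized; that equality is tested.

## The synthetic-data generator

No public dataset accompanies this kind of experiment, so the pipeline is
validated against a seeded generator with known truth. `make_toy_protein()`
builds a 900-residue scaffold with cysteines at the twelve positions of
murine alpha-E-catenin (116, 228, 324, 337, 438, 461, 526, 720, 767, 772,
787, 793), inserting K/R anchors so every site falls inside a detectable
tryptic peptide; `simulate_psm_table()` then emits PSMs.

Each cysteine is assigned a *carrier peptide* — the shortest digest peptide
containing it, ties broken leftmost — and nearby cysteines may share one
carrier, exactly as in a real digest. For each condition, replicate, and
distinct carrier, the total count is drawn `n ~ Poisson(mean_depth)`
(acquisition depth varies run to run), and each contained cysteine of each
PSM is modified independently with its site's true probability, so the
per-site modified count is `Binomial(n, p_site)`. Emission is per carrier
rather than per site because per-site emission would double-count totals at
sites sharing a carrier and bias their estimates; the per-carrier scheme
preserves the per-site binomial law at every site. Modified multi-Cys PSMs
are flagged unlocalized with probability `localization_failure_rate`
(an unmodified PSM has nothing to localize).

Defaults are chosen once to represent a realistic experiment of this kind:
4 replicates per condition, mean depth 200 spectral counts per site per
replicate, localization failure rate 0.1, and optional between-replicate
heterogeneity via a logit-normal perturbation of `p_site`
(`replicate_sd`, default 0). What the generator does *not* emulate:
retention-time or intensity structure, inter-site correlation within a
molecule, chemistry-side effects of labeling on conformation, decoy/FDR
machinery, or shared peptides across proteins. Passing recovery and
type-I-error checks on this generator therefore validates the counting,
weighting, and testing arithmetic — not the biology or the chromatography.

Validation performed by the test suite (problem sizes chosen to exercise
the estimator well into its asymptotic regime while keeping the suite
fast): 200 seeded runs at `p = 0.4` recover the truth within 3× total
error for ≥99% of site estimates, and ~2,000 null sites simulated through
the full pipeline hold Welch's test within Monte-Carlo error of its nominal
5% level.

## The shear-force model

To probe force-dependent conformation, His-tagged protein is immobilized on
a functionalized glass plate under a cone-plate rheometer, bound to actin
filaments, and sheared during labeling. The model quantifies the force a
tethered complex experiences:

* shear stress `tau = eta * gammadot`; with the measured viscosity of the
  50% glycerol labeling solution (0.02 Pa s, ~20× water) and shear rate
  6000 1/s, `tau = 120 Pa`;
* a filament lying flat presents a rectangle `A = L * d`; at the mean
  filament length 4.9 um and width 8 nm, `A = 0.039 um^2`;
* the tether force is `F = tau * A ≈ 4.7 pN` at mean length, linear in
  filament length.

Whether filaments indeed lie flat is judged by the Weissenberg number
`Wi = gammadot / D_r`, with the rigid-rod rotational diffusion coefficient

```
D_r = 3 kB T (ln(L/d) - c) / (pi * eta * L^3)
```

using the logarithmic end correction `c = 0.8` and `T = 289.15 K` (16 °C,
the experiment's temperature). These two constants are this package's
choices — the classical dilute-rod formula admits several end-correction
conventions — and with them `Wi ≈ 6.6e5`, in agreement with the reported
6.5e5 within the 5% that the choice of constant can move it. At such Wi,
tethered rods are flow-aligned with tilt angles far below a degree, which
justifies the flat-rectangle area. No tilt-angle correction, filament
flexibility, or secondary-flow effect is modeled.

Filament lengths are modeled as exponential, truncated at `max_length`
(default 20 um, matching the observed upper range), with the rate solved
numerically (by `uniroot`, tolerance 1e-14) so the *truncated* mean equals
4.9 um; whether the quoted mean refers to the truncated or untruncated
distribution is not knowable from the source, and the truncated reading is
the default because the 20 um ceiling is part of the same observation
(`max_length = Inf` gives the untruncated model). The truncated mean can
never exceed `max_length/2`, and the constructor refuses impossible
combinations rather than silently failing to converge. Because `F` is
linear in `L`, force quantiles and exceedance fractions come from the
length distribution in closed form; a seeded inverse-CDF Monte Carlo
cross-checks them, and with the default geometry ~39% of complexes exceed
the mean-length force of 4.7 pN — the long exponential tail is why a small
fraction of complexes experiences substantially larger forces.

## Structural metrics

`shrake_rupley()` computes solvent-accessible surface area by the classic
sphere-point method: `n_points` quasi-uniform points (a deterministic
Fibonacci lattice — no RNG) on each atom's expanded sphere
(`vdw_radius + probe`), counting points not buried in any neighbour's
expanded sphere. Defaults: probe 1.4 Å (water), 960 points, Bondi-type
radii (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, P 1.80 Å; unknown elements
fall back to 1.70 Å with a warning). Neighbour search uses spatial binning
with cell size twice the largest expanded radius, so the cost is linear in
atoms for globular geometries. At 960 points an isolated sphere is within
1% of its closed form `4*pi*(r+probe)^2`, and overlapping pairs are within
2% of a 10^5-point brute-force reference; accuracy rises with `n_points`.
Cysteine side-chain SASA sums CB + SG (+ attached hydrogens), excluding
backbone atoms — the quantity relevant to thiol-probe access. Which
algorithm and radii produced any given published figure is generally
unstated, so absolute agreement with figure bars is not claimed; the
correlation helper (`labeling_sasa_correlation`) supports the standard
observation that solution labeling correlates only weakly with
crystal-structure exposure.

Salt-bridge geometry over trajectory-style multi-frame models uses the
minimum distance between side-chain charged-group heavy atoms (ASP OD1/OD2;
GLU OE1/OE2; ARG NH1/NH2/NE; LYS NZ; HIS ND1/NE2). A "rupture" is flagged
when the distance first stays above a cutoff for a dwell of consecutive
frames; the 4.5 Å default cutoff is a common salt-bridge criterion, chosen
here explicitly (no printed value exists to match), and the dwell default
of 1 frame makes the flag a simple threshold crossing.

## Binding thermodynamics

For ITC tables, `delta_g_from_kd()` applies `dG = R T ln K_D`
(R = 1.987e-3 kcal/(mol K), standard state 1 M, default T = 298.15 K) and
`t_delta_s()` the identity `T dS = dH - dG`. The bundled
`itc_binding_table()` carries the published measurements for
alpha-E-catenin variants binding vinculin D1 and beta-catenin; reproducing
its printed one-decimal dG/TdS columns within 0.2 kcal/mol (to absorb
printing-precision rounding) is part of the acceptance suite. Note the
published claim of a "475×" wild-type-vs-mutant affinity ratio does not
follow from any simple ratio of the printed K_D values (1.8e-6 / 4.1e-9 ≈
439); this package only reports ratios it computes.

## Known limitations

* Spectral counting saturates: ratios near 0 or 1 are insensitive, and the
  shot-noise term understates uncertainty when counts are few and
  overdispersed.
* The Welch test on 2–8 replicates has limited power; absence of stars is
  not evidence of absence of change.
* The force model treats filaments as rigid flat rectangles; flexible or
  end-tethered filaments at low Wi would need the tilt-angle treatment
  deliberately excluded here.
* The SASA module analyzes coordinates it is given; it does not generate
  conformational ensembles, and single-structure SASA is a poor proxy for
  solution accessibility of dynamic regions — which is precisely the
  motivation for the labeling experiment.
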