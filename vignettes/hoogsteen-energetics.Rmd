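---
title: "Hoogsteen base-pair energetics in A-RNA and B-DNA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hoogsteen base-pair energetics in A-RNA and B-DNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgduplex)
```

# The scientific problem

A Hoogsteen (HG) base pair forms when the purine of a Watson-Crick (WC)
pair rotates ~180 degrees about its glycosidic bond into a *syn*
conformation and pairs through its N7 face. For purine-pyrimidine pairs
(A-T/U, G-C+) this also requires the two bases to translate ~2 A closer,
constricting the C1'-C1' distance from ~10.4 A to ~8.5 A. HG pairs are
substantially more costly in A-form RNA than in B-form DNA, and this
package implements the computational machinery for dissecting that
difference into two additive contributions:

* **ddG_syn-anti** - the extra cost, in RNA relative to DNA, of
  sterically accommodating the *syn* purine (measured by comparing the
  melting destabilization of m1G(syn)-G mismatches against C-G pairs in
  both backbones);
* **ddG_constrict** - the extra cost, in RNA relative to DNA, of moving
  the bases into HG hydrogen-bonding distance (estimated from the
  two-state occupancy of the constricted state in duplex simulations).

Their interval sum is the combined HG destabilization ddG_HG-WC. The
package covers the full supporting pipeline: two-state melting
thermodynamics, per-residue and per-pair structural geometry, a
crystal-structure mismatch survey, an idealized helix builder, stacking
overlap areas, trajectory occupancy analysis, nearest-neighbor (NN)
mismatch thermodynamics, and synthetic-data generators so that every
stage runs without downloads.

# Two-state melting thermodynamics

UV absorbance melting curves are modeled as a mixture of linear folded
and unfolded baselines weighted by a two-state folded fraction:

$$A_{260}(T) = (m_{ds} T + b_{ds})\,f(T) + (m_{ss} T + b_{ss})\,(1 - f(T))$$

with, for a bimolecular duplex,

$$f = \frac{1 + 4e - \sqrt{1 + 8e}}{4e},\qquad
  e = \exp\!\left[\left(\frac{1}{T_m} - \frac{1}{T}\right)
  \frac{\Delta H}{R}\right],$$

and for a unimolecular hairpin the logistic form $f = e/(1+e)$. Both
give $f(T_m) = 1/2$ exactly. Entropies follow from
$\Delta S = \Delta H/T_m - R\ln(C_t/2)$ (duplex; $C_t$ the total strand
concentration) or $\Delta S = \Delta H/T_m$ (hairpin), and
$\Delta G = \Delta H - T\Delta S$, with $R = 1.987\times10^{-3}$
kcal/mol/K throughout. Temperatures are kelvin everywhere internally.

**Sign convention.** The closed form for $f$ behaves as a *folded*
fraction only when $\Delta H < 0$, i.e. the fitted enthalpy is the
formation (association) enthalpy. The package adopts formation
quantities for $\Delta H$, $\Delta S$, $\Delta G$ and reports
destabilization as differences of formation free energies; this is
forced by the limits of the fraction expression itself (at
$T \ll T_m$, $f \to 1$ requires the exponent to grow, hence
$\Delta H < 0$).

`fit_melting()` estimates the six parameters by Levenberg-Marquardt
least squares (via minpack.lm) with a deterministic starting policy:
baselines from ordinary least squares on the first and last 15% of
points, $T_m$ from the steepest point of the baseline-normalized curve,
and $\Delta H = -50$ kcal/mol. The returned `meltfit` object supports
the standard modelling generics (`coef`, `vcov`, `predict`,
`residuals`, `plot`, `simulate`). Non-convergence raises an error
carrying the starting values; a fitted $T_m$ more than 30 K outside the
data range raises a warning.

Uncertainties follow the triplicate convention: free energies are
computed per replicate and aggregated by `thermo_replicates()` as mean
and sample standard deviation; `ddg()` then propagates independent
errors in quadrature, $\sigma = \sqrt{\sigma_a^2 + \sigma_b^2}$.
Interval arithmetic (`interval_ddg()`, `interval_sum()`) implements the
range bookkeeping used for the headline numbers: the difference
interval is $[lo_a - hi_b,\; hi_a - lo_b]$ and the penalty sum is
$[lo_a + lo_b,\; hi_a + hi_b]$.

Chemical-shift perturbations combine as
$\Delta\omega = \sqrt{\Delta\omega_H^2 +
(\gamma_{H}/\gamma_{C}\,\Delta\omega_C)^2}$ with the scaling factor
defaulting to $\gamma_H/\gamma_C = 3.976$ — i.e. the carbon term is
*up-weighted*, as in the defining equation, which is the inverse of the
more common down-weighting convention. Because the convention is
genuinely ambiguous in the field, `csp(..., inverse_ratio = TRUE)`
provides the down-weighted alternative; the significance threshold is
0.4 ppm in either mode.

# The ledger

```{r ledger}
run_ledger()
```

The per-system constriction free energies and the syn-accommodation
melting ranges in `ledger_inputs()` are the study conditions of the
analysis (three duplex systems for the constriction comparison; melting
intervals of 5.8-7.0 kcal/mol for RNA and 3.0-4.3 kcal/mol for DNA for
the syn term). Each ledger row records the provenance of its operands.

# Nearest-neighbor mismatch thermodynamics

`duplex_dg()` sums stacked-doublet $\Delta H^\circ/\Delta S^\circ$
terms over an aligned duplex with at most one internal mismatch.
Parameter provenance:

* DNA WC doublets: the unified 1998 set; DNA G.G and T.T mismatch
  doublets: the 1999 like-with-like single-mismatch set. Mismatches are
  modeled as two doublet terms (`mismatch_model = "doublet"`).
* RNA WC doublets: the 1998 set; RNA U.U and G.G mismatches: Turner-2004
  1x1 internal-loop parameters (`mismatch_model = "loop11"`), because
  RNA internal-mismatch energetics are published as loop terms closed by
  the two flanking pairs and cannot be decomposed into independent
  doublets. Entropies are derived from the tabulated
  $(\Delta G_{37}, \Delta H)$ pairs.

All tables ship as plain-text resources with citations in their
headers. The sodium correction is the DNA entropy form
$\Delta S \mathrel{+}= 0.368\,(N_{phos}/2)\ln[\mathrm{Na^+}]$
cal/mol/K with $N_{phos} = 2(L-1)$; it vanishes at the 1 M reference
state, and — because it depends only on length — cancels exactly in any
mismatch-versus-WC difference at equal length. No correction is defined
for the RNA set, which is therefore evaluated at its reference
condition; the headline comparison is unaffected for the same reason.
Helix initiation, terminal and symmetry terms are available but
excluded from `mismatch_ddg()`/`context_sweep()` (they cancel, and the
convention mimics an interior position of a long non-palindromic
duplex).

**Evaluation temperature.** Free energies default to 298.15 K (25 C).
NN tables are conventionally tabulated at 37 C, but the melting
measurements this analysis compares against were performed at 25 C,
and the published destabilization ranges for the U.U/T.T comparison are
reproduced at 25 C (at 37 C the DNA range shifts down by ~0.2-0.3
kcal/mol). `T_eval` is an explicit argument everywhere.

```{r nn}
rna <- context_sweep(c("G", "C"), c("U", "U"), nn_params("RNA"),
                     Na = 0.15, T_eval = 298.15)
dna <- context_sweep(c("G", "C"), c("T", "T"), nn_params("DNA"),
                     Na = 0.15, T_eval = 298.15)
round(c(rna_min = rna$min, rna_max = rna$max,
        dna_min = dna$min, dna_max = dna$max,
        mean_diff = rna$mean - dna$mean), 2)
```

# Structural geometry

Torsions use the IUPAC sign convention; $\chi$ is O4'-C1'-N9-C4 for
purines and O4'-C1'-N1-C2 for pyrimidines. Sugar pucker is summarized
by the pseudorotation phase computed from the five endocyclic torsions;
phases in [0, 36] degrees are C3'-endo (A-form), [144, 180] C2'-endo
(B-form). Classifications follow strict open intervals — *syn* for
$0 < \chi < 90$, *anti* for $-180 < \chi < -90$ — so boundary values
map to `intermediate`; backbone rotamers bin as gauche+ (0, 120],
gauche- (-120, 0], trans otherwise. Missing atoms yield absent torsion
values rather than failures.

Pair classification is geometric:

* **WC**: complementary parents, both $\chi$ anti, at least two
  inter-base donor-acceptor contacts under 3.5 A, C1'-C1' in
  [9.8, 11.0] A. This explicit rule stands in for the unpublished
  criteria of the helix-typing program used in the original survey.
* **HG**: exactly one *syn* purine with at least one hydrogen bond,
  plus a constricted C1'-C1' (< 9.5 A) when the partner is a
  pyrimidine. Purine-purine HG mismatches pair without constriction,
  so no distance cap applies to them.
* **wobble**: G with U/T, anti-anti, two contacts.

Hydrogen-bond detection uses heavy-atom donor/acceptor tables per base
(cytosine N3 is listed as both donor and acceptor to cover the
protonated G-C+ HG pair). The hydrogen-donor-acceptor angle is reported
when hydrogens are present (trajectory frames) and skipped otherwise
(crystal structures); the class rules use distances only.

Coordinates are read from PDB (via bio3d) or mmCIF (a built-in
`atom_site` reader): model 1 only, the highest-occupancy alternate
location retained (ties to the first in file), hetero nucleotides kept
under their author residue names, and residue numbering as authored.
The modified-purine whitelist mapping residue names (1MA, 1MG, I, BGM,
5BU, ...) to canonical parents is an editable packaged table.

# The mismatch survey

`find_pp_mismatches()` reports purine pairs in hydrogen-bonding contact
(>= 1 inter-base donor-acceptor distance < 3.5 A) whose neighbors on
both strands form WC pairs for two steps on each side. The
"duplex-like environment" is operationalized *solely* by this WC-flank
rule; no helix-form requirement is placed on the mismatch itself.
Structures at or above the 3 A resolution cutoff are dropped; entries
on the exclusion list (by default the two mismatch-repair complexes
with intercalation-distorted mismatches) are removed before analysis;
structures without resolution metadata (synthetic fixtures) pass with a
warning. The hydrogen-bond requirement is an explicit choice: purine
pairs merely in apposition, without an inter-base contact, are not
counted as mismatches.

Torsion summaries use circular statistics (vector-mean direction,
$\sqrt{-2\ln \bar R}$ dispersion) because several backbone torsions
live near the $\pm 180^\circ$ wrap where linear means are meaningless;
the report includes the fraction of *syn* residues with both alpha and
gamma in the trans rotamer, the signature rearrangement by which A-form
backbones accommodate *syn* purines.

# Idealized helices and Hoogsteen editing

`build_ideal_helix()` stacks rigid nucleotide templates under a helical
symmetry operation: form A (RNA chemistry) with twist 32.7 degrees,
rise 2.81 A, C3'-endo sugars, and the helix axis displaced ~4.4 A
toward the major groove; form B (DNA chemistry) with twist 36.0
degrees, rise 3.38 A, C2'-endo sugars and the axis through the pair
centers. The second strand is the 180-degree rotation about the pair
dyad of the complementary template, which makes the two backbones exact
dyad images and gives both strands identical junction geometry. The
templates are synthetic idealized geometry constructed by the
development script `data-raw/make_templates.py`: base and sugar
internal geometry from chemical-component-dictionary ideal residues,
sugar rings solved to the target pseudorotation phase by least squares,
backbones grown at canonical torsions, and the remaining free
parameters (glycosidic orientation, lambda angles, beta/gamma, axis
offset) optimized for WC hydrogen bonding, O3'-P junction closure
(1.60 A) and near-canonical emergent alpha/epsilon/zeta. They are
frozen as plain-text resources and stand in for fiber models generated
by external helix builders; step parameters of such tools may differ
from ours in the second decimal.

Editing operations mirror the construction of simulation starting
structures: `syn_flip()` rotates a purine base 180 degrees about the
glycosidic bond (an exact involution); `mutate_base()` swaps a base in
its existing glycosidic frame (e.g. C to anti-G before installing a
G-G mismatch); `hg_place()` superposes a packaged HG pair template
(A(syn)-T, A(syn)-U, G(syn)-C+ or G(syn)-G) onto the target pair by
least squares over matched base heavy atoms and installs it. The
shipped HG templates are themselves synthetic constructions satisfying
the standard HG hydrogen-bond geometry (N7 contacts at 2.9 A,
constricted C1'-C1' of 8.5-8.6 A for purine-pyrimidine, 10.4 A for
G-G); they stand in for experiment-derived template pairs that are not
bundled. By default `hg_place()` replaces the complete nucleotides so
the constricted geometry carries over; `full_residues = FALSE` swaps
base atoms only, leaving the backbone for subsequent relaxation — the
pre-equilibration convention of simulation setups.

Rigid superposition is closed-form least squares with reflections
excluded (degenerate cases resolve to determinant +1); the test suite
cross-checks it against an independent quaternion implementation at
$10^{-9}$ A.

# Stacking overlap

For a dinucleotide step, all base atoms are projected into the plane
orthogonal to the mean of the two base-pair normals. Each base becomes
the convex hull of its projected ring atoms (optionally plus exocyclic
substituents); ring systems are convex to good approximation and the
hull guarantees simple polygons under projection noise. Overlap is the
polygon-intersection area by Sutherland-Hodgman clipping, computed for
the four base combinations of the step (two same-strand, two
cross-strand) and totaled — published overlap tools do not state their
combination accounting, so both the per-combination table and the total
are emitted. `triplet_overlap_change()` compares a mismatched triplet
against an idealized reference duplex built from the sequence of the
strand carrying the *syn* base, with modified bases entering through
their canonical parents, and reports per-step and total differences
with and without exocyclic atoms. The clipping result is verified
against a 0.01 A rasterization oracle to 0.5%.

# Trajectory occupancy and free energies

A frame is HG when all criteria hold simultaneously: C1'-C1' < 9.5 A,
purine $\chi$ strictly within (0, 90) degrees, every required
donor-acceptor distance < 3.5 A, and optionally every
hydrogen-donor-acceptor angle < 30 degrees (off by default, matching
the distance-only definition; enabling it can only shrink the HG set).
Occupancy standard errors use the effective sample size
$n_{\mathrm{eff}} = n/(2\tau + 1)$ with $\tau$ the integrated
autocorrelation time from the initial-positive-sequence estimator,
because trajectory flag series are strongly autocorrelated.

The population free energy is the two-state ratio
$\Delta G = -RT\ln\!\big(f/(1-f)\big)$ at 298 K. The exact
supplementary definition behind the published per-system constriction
energies is not printed; this two-state form is a documented stand-in
validated by consistency with the printed populations (a ~40%
constricted-state occupancy gives +0.24 kcal/mol, matching the reported
~0.3; >99% gives -3.1). At $f \in \{0, 1\}$ the free energy is
unbounded and the function refuses, directing the caller to report a
bound from the frame count instead.

# Synthetic data: what it emulates, and what it does not

`synth_melting_curve()` draws Gaussian noise around the exact two-state
model; `synth_trajectory()` simulates the hidden HG/open state as a
two-state Markov chain with exact stationary occupancy `f_hg` and
switching propensity `switch_rate` (1 gives an i.i.d. series), then
emits descriptors from state-specific centers (HG: c1c1 8.6 A, chi 45
degrees, N7 contact 2.9 A; open: c1c1 11.5 A, N7 broken at 6 A —
splayed-apart bases with chi still syn) plus jitter truncated at three
standard deviations so labels can never cross a classification
threshold. Occupancy tests therefore isolate sampling error from
classification error by construction. All generators are pure functions
of (spec, seed).

What passing these tests shows is that the estimators are correct under
the stated statistical model. Real melting curves violate it through
baseline curvature, wavelength drift and non-two-state intermediates;
real trajectories through metastable sub-states, threshold-straddling
descriptor noise and force-field bias. Results on real data inherit
those caveats; none of them are probed by the synthetic generators.

# Numerical choices and problem sizes

* Torsion boundaries map to `intermediate`; rotamer bins are half-open
  as stated above; pseudorotation amplitude is resolved positive.
* Altloc ties resolve to the first in file; superposition ties to
  proper rotations.
* The noisy-recovery study in the tests and acceptance script uses 120
  points per curve, noise at 0.2% of the transition amplitude and 50
  seeds; occupancy checks use 10,000 frames; the overlap cross-check
  uses 100 random convex polygon pairs at a 0.01 A grid. These sizes
  give comfortable statistical margins for every assertion while
  keeping the default suite around ten seconds.
* Fits are deterministic given data and the starting policy; every
  stochastic step takes an explicit integer seed.

# Known limitations

* The helix builder produces regular helices only: no
  sequence-dependent step parameters, bends, bulges, or solvent.
  A-form pair inclination is not modeled (the axis displacement is).
* The NN module supports a single internal mismatch; no dangling ends,
  terminal mismatches, loops, or Mg2+ corrections.
* The mismatch survey assumes chain order reflects strand direction
  when checking flanking pairs, as is the case for standard deposited
  duplexes.
* `ddG_constrict` rests on the two-state population formula above;
  alternative state definitions would shift per-system values by
  tenths of kcal/mol.
* The CSP scaling-factor ambiguity is documented, not resolved; both
  conventions are available.
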