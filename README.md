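# hgduplex

Hoogsteen (HG) base pairs — the purine flipped *syn*, pairing through
its N7 face — are markedly more destabilizing in A-form RNA than in
B-form DNA. `hgduplex` is an R package for quantifying why. It is
written for structural biologists and biophysical chemists who work
with UV melting data, nucleic-acid coordinates and duplex simulations,
and it implements the complete analysis pipeline behind the
decomposition of the RNA-versus-DNA HG penalty into two contributions:

1. **ΔΔG_syn-anti** — the extra cost of sterically accommodating the
   *syn* purine in an A-form backbone, measured by comparing the
   melting destabilization of m¹G(*syn*)-G mismatches against C-G pairs
   in RNA and DNA;
2. **ΔΔG_constrict** — the extra cost of constricting the bases into HG
   hydrogen-bonding distance (C1′–C1′ < 9.5 Å), estimated from
   two-state occupancies of duplex simulations via
   ΔG = −RT ln(f/(1−f)).

Their interval sum is the combined penalty ΔΔG_HG-WC.

## What is in the package

* **Two-state melting thermodynamics** — `fit_melting()` fits
  A₂₆₀-versus-temperature curves to the linear-baseline two-state model
  (duplex fraction `f = (1 + 4e − √(1+8e))/4e` with
  `e = exp[(1/Tm − 1/T)ΔH/R]`; logistic hairpin variant), returning a
  classed model object with `coef`/`predict`/`plot`/`simulate`
  methods; `thermo_from_fit()` applies ΔS = ΔH/Tm − R ln(Ct/2) and
  ΔG = ΔH − TΔS; `ddg()` and `interval_ddg()`/`interval_sum()` do the
  free-energy bookkeeping with quadrature error propagation; `csp()`
  computes NMR chemical-shift perturbations.
* **Structural geometry** — PDB/mmCIF parsing, backbone and glycosidic
  torsions, sugar pseudorotation, *syn*/*anti* and rotamer
  classification, per-pair geometry with WC/HG/wobble classes
  (`residue_conformation()`, `pair_geometry()`).
* **Mismatch survey** — `find_pp_mismatches()` scans structures for
  purine-purine mismatches flanked by two WC pairs on both sides;
  `torsion_report()` summarizes torsions with circular statistics.
* **Idealized helix builder** — `build_ideal_helix()` (A/B form, from
  embedded idealized templates), `syn_flip()`, `mutate_base()` and
  `hg_place()` for constructing HG-containing fixtures.
* **Stacking overlap** — base-polygon intersection areas per
  dinucleotide step and mismatch-versus-reference triplet differences
  (`step_overlap()`, `triplet_overlap_change()`).
* **Trajectory analysis** — `classify_frames()` (C1′–C1′ < 9.5 Å, χ in
  (0°, 90°), h-bonds < 3.5 Å, optional 30° angle), `occupancy()` with
  autocorrelation-corrected errors, `dg_from_population()`,
  `rmsd_series()`.
* **Nearest-neighbor thermodynamics** — `duplex_dg()`,
  `mismatch_ddg()` and `context_sweep()` over embedded DNA/RNA
  parameter tables, including G·G and T·T/U·U internal mismatches and
  a sodium correction.
* **Synthetic data** — `synth_melting_curve()` and
  `synth_trajectory()` generate every input with known ground truth.

## Worked example

```r
library(hgduplex)

## fit a noisy synthetic melting curve (truth: Tm = 330 K, dH = -55)
sp  <- sim_spec_melt(Tm = 330, dH = -55, Ct = 3e-6, noise_sd = 2e-3)
fit <- fit_melting(synth_melting_curve(sp, seed = 42))
fit
#> Two-state duplex melting fit
#>   Tm = 329.76 K, dH = -53.79 kcal/mol
#>   residual RMS = 0.00201 over 120 points
thermo_from_fit(fit, T_eval = 298.15)
#> dH = -53.79 kcal/mol, dS = -0.1365 kcal/mol/K, dG(298.15 K) = -13.10 kcal/mol

## the Hoogsteen destabilization ledger
run_ledger()
#> Hoogsteen destabilization ledger (kcal/mol, RNA - DNA)
#>   ddG_constrict_A6_AU      3.4      [dG_constrict RNA 0.3 - DNA -3.1]
#>   ddG_constrict_GC10       4.0      [dG_constrict RNA 2.1 - DNA -1.9]
#>   ddG_constrict_A2_AU      3.0      [dG_constrict RNA 0.2 - DNA -2.8]
#>   ddG_constrict_range    3.0-4.0    [range over systems]
#>   ddG_syn_anti           1.5-4.0    [melting intervals [5.8, 7] - [3, 4.3]]
#>   ddG_HG_WC              4.5-8.0    [interval sum ddG_syn_anti + ddG_constrict_range]

## U.U-for-G-C destabilization across all 16 contexts (RNA, 150 mM Na+)
rna <- context_sweep(c("G", "C"), c("U", "U"), nn_params("RNA"),
                     Na = 0.15, T_eval = 298.15)
c(rna$min, rna$max)
#> [1] 5.708672 7.199835    # kcal/mol

## occupancy of a synthetic two-state trajectory at 40% HG
tr <- synth_trajectory(sim_spec_traj(f_hg = 0.4, n_frames = 10000), seed = 1)
oc <- occupancy(classify_frames(tr))
dg_from_population(oc$occupancy)
#> [1] 0.2231104            # kcal/mol: the constricted state is minor

## build a B-form duplex and install an A(syn)-T Hoogsteen pair
hx <- build_ideal_helix("CGCATACGC", form = "B")
pair_geometry(hg_place(hx, "A:4", "B:6", hg_template("AT")), "A:4", "B:6")
#> A:4 (DA) - B:6 (DT): HG, C1'-C1' = 8.50 A, 2 contact(s)
```

The first fit recovers the generating Tm within a quarter kelvin at
0.2% noise; the ledger reproduces the interval arithmetic of the
headline decomposition (1.5–4 kcal/mol for accommodating the *syn*
purine, 3–4 kcal/mol for constriction, 4.5–8.0 kcal/mol combined); the
nearest-neighbor sweep shows a U·U wobble destabilizing RNA by
5.7–7.2 kcal/mol versus 3.8–5.2 kcal/mol for T·T in DNA — a mean
difference of ~1.9 kcal/mol, consistent with constriction being
costlier in A-form geometry.

A thin command-line wrapper over the same functions is included at
`inst/scripts/hgpipe.R` (subcommands `fit`, `ledger`, `nn`,
`simulate-melt`, `simulate-traj`, `traj`, `helix`).

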