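# efbind

Quantitative analysis of EF-hand calcium binding, built for domains like the
calmodulin-like domain (CaMD) of human non-muscle α-actinin-1: helix–loop–helix
proteins whose 12-residue loops chelate a Ca²⁺ ion and whose conformation,
affinity and thermodynamics are probed by NMR titration, structure-ensemble
geometry and isothermal titration calorimetry (ITC). It is aimed at
structural biologists and biophysicists who have a sequence, a set of
HSQC-titration peak lists, an NMR ensemble (PDB), and/or an ITC injection
table, and want the standard quantitative chain over them — plus synthetic
generators so every step can be validated without external data.

## What it computes

**EF-hand motif scanning.** The canonical EF loop coordinates Ca²⁺ in a
pentagonal bipyramid through positions X(1), Y(3), Z(5), −Y(7, backbone
carbonyl), −X(9, water-mediated) and the invariant bidentate Glu/Asp at
−Z(12). `scan_ef_hands()` evaluates windows or annotated loops against a
user-overridable per-position rule set (`ef_rules()`, YAML-configurable) and
`classify_ef_hands()` counts canonical vs degenerate hands.

**Chemical shift perturbation and Kd.** Per residue,
Δδ(H,N) = √(Δδ_H² + (w·Δδ_N)²) with nitrogen weight w = 0.2 by default
(`compute_csp()`, `csp_series()`). The binding site is mapped as the
residues with Δδ(H,N) above a threshold (0.3 ppm default) at the saturating
end point (`map_binding_site()`). The dissociation constant comes from
least-squares fitting of the exact 1:1 isotherm

    Δδ_obs = Δδ_max · [(P₀+L₀+K_d) − √((P₀+L₀+K_d)² − 4P₀L₀)] / (2P₀)

with a global (shared K_d, per-residue Δδ_max) or per-residue mode
(`fit_kd()`). Unassigned peak lists can first be linked across titration
points by greedy nearest-neighbour tracking (`track_peaks()`).

**Ensemble geometry.** `read_ensemble()` parses multi-model PDB/mmCIF into a
tidy atom table; `superpose()` (Kabsch) and `ensemble_rmsd()` report both
to-mean and pairwise backbone RMSD conventions. Each EF hand is reduced to
its entering-helix axis, exiting-helix axis and loop anchor
(`fit_helix_axis()`, `ef_geometry()`); `vgm_angles()` reports the polar
opening angle θ and azimuthal swing φ of the exiting helix in a
loop-anchored frame, `ensemble_vgm()` summarises them per ensemble, and
`compare_states()` gives Δθ/Δφ between apo and holo states.

**ITC thermodynamics.** `simulate_itc()`/`fit_itc()` implement the
single-site injection-heat model with perfusion dilution; `delta_g()` and
`t_delta_s()` complete the linkage ΔG = RT ln K_d and TΔS = ΔH − ΔG
(R = 1.9872×10⁻³ kcal mol⁻¹ K⁻¹, T = 298.15 K by default).

Everything takes and returns tibbles, pipes cleanly, and fitted objects
support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(efbind)

# 1. classify the four EF loops of a CaMD-like construct
demo <- camd_demo_sequence()
hits <- scan_ef_hands(demo$seqs, mode = "annotated",
                      annotations = demo$annotations)
classify_ef_hands(hits)
#> EF-hand classification: 4 hits, 1 canonical, 3 degenerate
#>   id             loop_start loop_sequence canonical reason
#> 1 synthetic_CaMD        759 DPDYSGTLGKIE  TRUE      canonical
#> 2 synthetic_CaMD        800 DKNGAGTLSKIA  FALSE     fails Z,-Z
#> 3 synthetic_CaMD        836 AKNGSGTLSKIQ  FALSE     fails X,-Z
#> 4 synthetic_CaMD        875 GKAGAGTLAKIA  FALSE     fails X,Y,Z,-X,-Z

# 2. titrate, map the binding site, fit Kd
ser <- gen_titration(Kd = 170e-6, seed = 1)   # 15 points, 0-20 eq, P0 0.312 mM
endpoint <- dplyr::filter(csp_series(ser), point == max(point))
map_binding_site(endpoint, threshold = 0.3)
#> [1] 743 746 765 776 781 785
fit_kd(ser, mode = "global")
#> 1:1 isotherm fit (global mode, w = 0.2): Kd = 0.0001724 M (se 1.7e-06),
#> 6 residues, 90 points

# 3. thermodynamic linkage from an ITC dissociation constant
dg <- delta_g(104.2e-6)                       # -5.43 kcal/mol
t_delta_s(2.10, dg)                           #  7.53 kcal/mol
```

The six mapped residues are exactly the six binders planted by the
generator, the fitted 172 ± 2 μM recovers the generating 170 μM constant,
and the linkage numbers are the free energy and entropic term implied by a
104.2 μM constant with ΔH = 2.10 kcal/mol at 25 °C.

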