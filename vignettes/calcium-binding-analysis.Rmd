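---
title: "Methods: EF-hand calcium-binding analysis with efbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EF-hand calcium-binding analysis with efbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efbind)
```

efbind implements the quantitative chain used to characterise calcium
binding by EF-hand domains: motif detection from sequence, chemical shift
perturbation (CSP) titration analysis with 1:1 isotherm fitting,
interhelical-angle geometry of structure ensembles, ensemble RMSD, and
single-site ITC thermodynamics. This vignette records the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## Sequence scanning

An EF hand chelates Ca²⁺ in a pentagonal bipyramid through six loop
positions labelled X(1), Y(3), Z(5), −Y(7), −X(9), −Z(12). The scanner
tests each 12-residue frame against a per-position allowed-residue set:

| position | default allowed | rationale |
|---|---|---|
| X (1) | D | side-chain carboxylate, near-invariant |
| Y (3) | D, N, S | side-chain oxygen donors |
| Z (5) | D, N, S, T | side-chain oxygen donors |
| −Y (7) | any | coordination is via the main-chain carbonyl |
| −X (9) | S, T, D, N, E, G, Q | water-mediated, permissive |
| −Z (12) | E, D | the invariant bidentate ligand |

The sets are a design decision, not a database fact: they are chosen to be
consistent with the published sequence preferences of functional EF loops
and with the documented coordination of the α-actinin-1 EF1 loop
(D759/D761/S763/backbone-T765/water-G767/E770 all pass) while the EF2-type
loop starting at D800 fails Z and −Z. One descriptive discrepancy is
accepted rather than forced: EF2 is described in the literature as also
degenerate at −Y, but since −Y coordinates through the backbone its
sequence identity carries no signal, and a sequence-only scanner cannot
reproduce that call. An optional strict profile
(`ef_rules(strict_backbone = TRUE)`) restricts position 7 to small residues
for users who want a conservative scan. Rule sets are plain YAML
(`read_ef_rules()`/`write_ef_rules()`; the default ships in
`inst/extdata/ef_rules.yaml`), so the scan is fully user-overridable.

Window mode reports every frame whose first residue passes the X rule, with
no non-maximum suppression — the goal is classification, not annotation.
Annotated mode evaluates exactly the provided loop starts, which is how
degenerate loops (whose first residue may not be Asp) are classified.
Sequences shorter than 12 residues are rejected; a 12-residue input is a
single window. `X` in a sequence is a wildcard that fails every constrained
position.

## CSP titration and dissociation constant

The combined amide perturbation is Δδ(H,N) = √(Δδ_H² + (w·Δδ_N)²). The
nitrogen weight defaults to w = 0.2, the common amide scaling that maps the
roughly five-fold wider ¹⁵N shift range onto the ¹H scale; it is recorded
in every CSP table and fit object so a result can always be traced to the
weight that produced it. Peaks missing from either state (exchange
broadening) are flagged and excluded — never imputed as zero shifts.

The binding site is mapped by thresholding the end-point profile at
0.3 ppm by default, the conventional cut for directly coordinating
residues; the same threshold selects the residues entering the headline
K_d fit.

Fitting uses the exact (quadratic) 1:1 isotherm, valid at any ratio of
protein concentration to K_d, rather than the hyperbolic weak-binding
approximation — essential here because P₀ (0.312 mM) exceeds K_d
(~10⁻⁴ M). Two numerical points:

* The bound-complex concentration uses the conjugate form of the smaller
  quadratic root, `2·P0·L0/(s + sqrt(s² − 4·P0·L0))` with
  `s = P0 + L0 + Kd`, which is algebraically identical to the textbook
  `(s − sqrt(...))/2` but avoids catastrophic cancellation when K_d
  dominates; the mass-balance identity then holds to ~10⁻¹¹ relative over
  six orders of magnitude of concentrations.
* The least squares is Levenberg–Marquardt with box bounds
  (K_d ∈ [10⁻⁹, 1] M, Δδ_max ∈ (0, 10] ppm) and three log-spaced K_d
  starts (10⁻⁶, 10⁻⁴, 10⁻² M) to escape the shallow-valley local minima
  typical of isotherm fits. Standard errors come from the fit covariance;
  the convergence flag reflects the optimiser's own termination code.

Global mode shares one K_d across the mapped residues with residue-specific
Δδ_max — the assumption being a single site in fast exchange, so every
reporter senses the same occupancy. Per-residue mode drops that assumption,
fits each residue independently and reports the median as the headline
value; both modes are provided because published CSP-derived constants
rarely state which was used. Δδ_max is always fitted, not fixed at the
last titration point, since 20 equivalents at these concentrations does not
fully saturate weak sites.

`track_peaks()` supports unassigned peak lists: tracks seeded at the
assigned reference point are extended by greedy nearest-neighbour linking
in (Δδ_H, w·Δδ_N) space, taking globally smallest distances first; a link
beyond `max_step` marks the track absent at that point while its position
continues to extrapolate linearly, so peaks broadened out over intermediate
points are re-linked on return. Greedy linking is deliberate: it is
order-independent, transparent, and adequate for the non-crossing
trajectories of a well-resolved titration. Crossing or heavily overlapped
trajectories are out of scope.

## Ensemble geometry

Structures are tidy atom tables (model, chain, author residue number,
residue, atom, x/y/z in Å). Parsing is delegated to bio3d; multi-model
files are split per MODEL block so atom-inventory mismatches can be
reported naming the model and residues. Heteroatoms are dropped, alternate
location A is kept, insertion codes are rejected (not expected in NMR
entries). Backbone means N, CA, C, O.

Superposition is the Kabsch SVD solution with the sign correction that
guarantees a proper rotation (det +1). The "mean" reference is iterated
twice: superpose onto model 1, average, re-superpose onto the average —
enough for the mean structure to stabilise at the precision that matters
here. Collinear selections, for which rotation about the line is
undetermined, are rejected.

Two RMSD conventions are always computed and reported together, because
published ensemble-spread values rarely say which was used:

* `to_mean = sqrt( Σ_m msd_m / (n − 1) )`, where `msd_m` is the mean
  squared deviation of model m's selected atoms from the coordinate mean.
  The n − 1 normalisation makes the estimate unbiased under isotropic
  jitter (expectation σ√3 for per-coordinate noise σ) and yields the exact
  identity `pairwise = √2 · to_mean` for two-model ensembles — a useful
  cross-convention check.
* `pairwise`: the average pairwise RMSD over all model pairs.

Helix axes are the largest-variance principal direction of the selected
atoms, sign-oriented from the N-terminal-half centroid toward the
C-terminal-half centroid, so reversing atom order cannot flip the axis.
The residual used for `rmsd_to_axis` is computed from the perpendicular
residual vectors, not as a difference of squared norms, again to avoid
cancellation.

Interhelical angles use a loop-anchored local frame: z is the entering
helix axis (N→C), x the component of (loop anchor − entering centroid)
orthogonal to z, y = z × x. The classical formulation poses each hand on an
external reference EF-hand structure; replacing that unpinned external
dependency with a self-consistent intrinsic frame preserves the two key
properties — invariance under global rigid motion, and exact recovery of a
constructed geometry — at the cost of an azimuth origin that is defined by
the hand itself. Consequences: θ (the opening angle) is directly comparable
with reference-frame values, while absolute φ values depend on the frame
origin and are best interpreted as differences between states computed in
the same frame; cross-study comparisons of absolute angles should carry a
few degrees of tolerance, and a user-supplied reference structure can be
used by fitting axes on it and applying the same machinery. φ is
right-handed, counterclockwise from +x viewed from +z, reported in
(−180°, 180°]; state differences are wrapped to the same branch, so an apo
φ of +179° and holo φ of −179° is a +2° change. When the exiting axis is
(anti)parallel to z, φ is undefined and reported as 0 with a degeneracy
flag; in ensemble summaries such models are excluded and counted. θ is
averaged arithmetically; φ uses the circular mean and circular SD. The
poorly defined exiting helix of a fourth EF hand is the typical reason to
exclude a hand from state comparisons; exclusion is a per-definition-table
choice, not hard-coded.

## ITC

The single-site model treats n·P as binding-competent sites and solves the
same quadratic equilibrium per injection. Totals follow the perfusion
convention for an overfilled cell: each injection of volume v displaces v
of pre-injection cell content, so totals scale by (1 − v/V₀) before the
syringe contribution is added. The per-injection heat charges the change in
bound concentration, ΔH·V₀·Δ[PL] + offset, with the offset absorbing
dilution/mixing heat per injection. Under this formulation the heats
telescope exactly to ΔH·[PL]_final·V₀ + Σ offset, a conservation identity
the tests verify against an independent root-finding equilibrium solver.
One visible consequence of perfusion dilution is a small post-equivalence
heat of opposite sign (displaced protein lowers [PL] slightly), which is
physical for this convention rather than an artefact.

Fitting mirrors the CSP fitter (bounded Levenberg–Marquardt, three K_d
starts); n may be fixed. ΔG = RT ln K_d with R = 1.9872×10⁻³
kcal mol⁻¹ K⁻¹ and T defaulting to 298.15 K, so association is negative
when favourable; TΔS = ΔH − ΔG. The c-value n·P₀/K_d is reported and
warned about outside [0.01, 1000], the regime where an ITC curve carries
little shape information. An all-zero heat vector is flagged
unidentifiable rather than fitted silently.

## What the generators emulate — and what they do not

`gen_titration()` defaults encode the study conditions this package was
built around: P₀ = 0.312 mM, fifteen points between 0 and 20 molar
equivalents (schedule 0, 0.125, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8,
12, 16, 20 — dense through the first equivalent where the isotherm bends,
sparse toward saturation), 56 residues of which 6 bind, saturation shifts
uniform in 0.3–1.24 ppm, Gaussian shift noise of 0.005 ppm per dimension
(a realistic read-off precision for a well-resolved HSQC), and an optional
broadening window of 0.25–1 equivalents during which selected peaks
disappear. Binder shift trajectories are straight lines in (Δδ_H, w·Δδ_N)
space scaled by the exact isotherm; real titrations add curved paths
(intermediate exchange), ridge noise and peak overlap, none of which are
modelled — so passing tests demonstrate correctness of the analysis
chain, not robustness to pathological spectra.

`gen_helix_pair_ensemble()` builds ideal Cα helices (rise 1.5 Å/residue,
radius 2.3 Å, 100° twist). Because a finite discrete helix's principal
axis deviates slightly from its geometric axis, the generator poses each
helix by its *fitted* axis — it computes the PCA axis of the template and
rotates that onto the target direction — so the analysis recovers the
requested (θ, φ) exactly at zero jitter; jitter perturbs θ and φ directly
with per-model Gaussian noise, giving a known per-model ground truth.
`gen_ensemble_jitter()` applies isotropic per-atom noise for RMSD oracles.
Neither produces realistic side chains, secondary-structure irregularity
or correlated loop motion. `gen_ef_sequences()` embeds constructed loops
in Asp/Glu-free flanks (no accidental canonical window can form, which is
also verified by re-scanning) and records every planted violation.
`gen_itc()` adds Gaussian heat noise proportional to the largest heat.
All generators are deterministic given their seed and attach
machine-readable ground truth.

## Validation problem sizes

The shipped checks use: 1000 random concentration triples for the isotherm
identity; 200 synthetic titrations with true K_d log-uniform in 50–500 μM
(bracketing the constants measured for this system by CSP and ITC) for K_d
recovery; 1000 random (θ, φ) pairs for the angle round trip; 20-model
ensembles for angle and RMSD statistics; and 100 noisy replicates at 2 %
heat noise for ITC recovery. These sizes give stable medians while keeping
the whole suite fast enough to run routinely.

## Configuration and reporting

Configs (rules, hand definitions, ITC metadata, pipeline) are YAML.
`run_end_to_end()` executes scan → titration → angle comparison → RMSD →
ITC on provided inputs, substituting seeded synthetic data for any stage
without input, and serializes a JSON + Markdown report that records every
resolved default (nitrogen weight, threshold, RMSD convention, φ sign
convention, R, T) alongside the results; reruns with the same config and
seed are identical. Outputs are never overwritten without `force = TRUE`.

## Known limitations

* Sequence scanning is rule-based: no profile/HMM scoring, no structural
  verification, no affinity prediction; EF loops shortened by deletions
  simply find no passing frame.
* One-site, two-state fast-exchange binding only: no multi-site,
  cooperative or sequential models in either the CSP or ITC fitters.
* No spectral processing or peak picking; peak lists are the input.
* No secondary-structure assignment: helix ranges come from the user or a
  definition table.
* Absolute φ values are frame-relative (see above); θ and the state
  differences Δθ/Δφ are the robust quantities.
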