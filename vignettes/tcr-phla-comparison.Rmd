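---
title: "Comparing wild-type and affinity-enhanced TCR-pHLA complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing wild-type and affinity-enhanced TCR-pHLA complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrlens)
```

T cell receptors recognise peptides presented by HLA class I molecules
with naturally weak affinities (micromolar K_D, second-scale half-lives).
Engineering campaigns can push the same receptor scaffold to nanomolar or
picomolar affinity, and a central question for the safety and design of
such reagents is *how*: whether the engineered receptor still docks the
way its wild-type progenitor does, which interface contacts and energetic
hot spots it keeps, and where the extra binding energy comes from.
`tcrlens` packages the measurements used to answer that question for a
wild-type/variant pair of complex structures (and, when available,
replica simulation ensembles and per-atom force-field parameters).

This vignette records the models behind each module, the defaults and why
they were chosen, what the synthetic-data generator does and does not
emulate, and the numerical choices that matter for reproducibility.

## Structures, roles and annotation

Structures are read from standard PDB files (`read_structure`), with
waters and hetero-groups retained but flagged and hydrogens excluded from
all default heavy-atom selections. Alternate locations are resolved to a
single conformer by **highest occupancy** (ties broken by altloc
identifier), matching the single-conformer character of the static
comparisons; `"first"` and `"all"` policies are available. Author (PDB)
residue numbering is kept throughout, insertion codes included, because
mutation labels and loop definitions in this field are conventionally
quoted in author numbering.

`annotate_complex` maps chains to the five roles (TCR α/β, HLA heavy
chain, β2-microglobulin, peptide). With no explicit configuration it uses
a length heuristic — peptide 8–13 residues, β2m ≈ 85–115, HLA heavy
≈ 255–300, the two remaining 150–260-residue chains taken as TCRα/TCRβ in
file order — and *errors* rather than guessing when the assignment is
ambiguous. CDR/HV4 loop ranges should be supplied per system; the built-in
defaults (CDR1 24–31, CDR2 48–55, HV4 65–74, CDR3 93–104 on each chain)
are a common-numbering convenience, not a curated truth, and can be
disabled (`default_loops = FALSE`). Sequence comparison
(`diff_sequences`) globally aligns the one-letter chain sequences
(BLOSUM62, gap open 10 / extend 0.5), labels substitutions by loop
membership, reports indels separately, and refuses alignments below a 70%
identity floor since these almost always mean mispaired chains.

## Binding geometry

All geometry is defined in a **groove frame** built from the pHLA:
origin at the peptide Cα centroid; x-axis the first principal component
of the peptide Cα coordinates, oriented N→C; y-axis the α2→α1
helix-centroid direction orthogonalised against x; z = x × y. The
**crossing angle** is the unsigned in-plane angle between the
Vα-centroid→Vβ-centroid vector (projected into the groove plane) and the
peptide axis, reported in [0, 180). Two centroid rules are provided:
`disulfide_ca` (default; centroid of the two conserved cysteine Cα per
variable domain, matching the familiar centroid-sphere depictions) and
`domain_ca` (all variable-domain Cα). Published crossing angles rarely
state their exact formula; every result therefore carries a
`definition_tag`, and agreement with literature values should be expected
only to a few degrees. The **footprint** is the (x, y) displacement of
the combined Vα+Vβ Cα centroid over the groove origin; Cα-only centroids
are used because they are robust to side-chain disorder. **Per-loop
RMSD** superposes the variant on the wild type using HLA heavy-chain Cα
(least squares) — so TCR motion is measured in the antigen frame — and
matches loop positions by residue number; length-mismatched loops are
flagged `comparable = FALSE` instead of erroring.

## Interface contacts

Contacts are heavy-atom pairs with one atom on a TCR chain and one on the
peptide or HLA heavy chain. Defaults follow the conventional cutoffs:
van der Waals ≤ 4.0 Å; hydrogen bond ≤ 3.4 Å with donor/acceptor typing
derived from residue chemistry (backbone N donates except proline,
backbone O accepts, side chains per standard tables); salt bridge
≤ 3.4 Å between Lys NZ / Arg NE,NH1,NH2 (His ND1/NE2 only when flagged
protonated — neutral by default) and Asp/Glu carboxylate oxygens.
Hydrogen-bond detection is **distance-only**: no angle criterion is
applied, because crystal-structure contact counts in this field are
quoted on distance cutoffs alone and most deposited structures lack
hydrogens. Types are *tags on one row*, not exclusive bins: a salt bridge
also counts as a vdW contact (and usually a hydrogen bond), and Δ-counts
per type are computed independently. "Preservation" of the wild type's
top-k contacted pHLA residues (default k = 10) counts a residue preserved
when it receives at least one contact in the variant (threshold
configurable); ranking ties break by residue order. Residues without a
chemistry entry produce a warning and vdW-only rows.

## Surface area and shape complementarity

SASA uses Shrake–Rupley quadrature on a deterministic Fibonacci sphere
lattice (default 960 points/atom, probe 1.4 Å, Bondi-style radii table;
unknown elements are an error, not a silent default). At 960 points an
isolated sphere is exact to well under 1%. BSASA is reported as total
burial over both sides (`half = TRUE` for the per-side convention).
Shape complementarity implements the Lawrence–Colman statistic on dot
surfaces of each side's van der Waals spheres: for each surface point
within a 1.5 Å band of the opposing surface, S = (n_A · −n_B) e^(−w d²)
with w = 0.5 Å⁻², scored as the mean of the two directional medians.
Because the published interface scores for these complexes come from a
different surface implementation, ranking agreement — not numeric
equality — is the appropriate expectation, and the package deliberately
asserts no numeric target for real structures.

## Replica-ensemble statistics

Ensembles are replicas × frames of coordinates on one topology
(`trajectory_ensemble`; multi-model PDB readable via `read_ensemble`, one
file per replica). The default burn-in discards the first 10% of each
replica, mirroring the common practice of analysing only the latter part
of each production run. Frames are aligned by least squares on a Cα
selection against an iterated two-pass mean reference. RMSF is computed
per replica about the replica mean; ΔRMSF compares wild type and variant
with a **two-sample t test per residue on the per-replica RMSF values** —
the replica, not the frame, is the independent statistical unit, so with
10 replicas per side each test has n = 10 per group. Welch's test is the
default (pooled-variance available); no multiple-testing correction is
applied, and the per-residue significance flag at α = 0.05 should be read
accordingly: across ~100 null residues, ~5 false flags are expected by
construction. MD-averaged contact maps average the per-frame per-residue
counts within replicas, then equally across replicas; hydrogen-bond
occupancy is the fraction of analysed frames within 3.4 Å.

## Binding energetics

The estimator is a deliberately simplified single-trajectory MM/GBSA:

* molecular mechanics interaction: gas-phase pairwise Coulomb
  (k = 332.0637 kcal Å mol⁻¹ e⁻², ε_in = 1) and 12-6 Lennard-Jones
  (rmin additive, ε geometric) over inter-set pairs, no cutoff;
* polar solvation: generalized Born with OBC-II-style effective radii
  (pairwise HCT descreening integrals, 0.09 Å offset, tanh rescaling
  α = 1, β = 0.8, γ = 4.85) and the Still pairwise form
  f = √(r² + RᵢRⱼ e^(−r²/4RᵢRⱼ)), with Debye–Hückel salt screening at
  150 mM (κ = √I / 3.047 Å⁻¹) and ε_out = 78.5;
* nonpolar solvation: γ·SASA with γ = 0.0072 kcal mol⁻¹ Å⁻², β = 0.

Receptor (pHLA) and ligand (TCR) conformations are extracted from the
complex snapshots, so internal MM energies cancel exactly and only
interaction plus desolvation remain. Per-residue decomposition splits
every pair term half-half between the partner residues and assigns self
and SASA terms to the owner, so residue contributions sum to the total
*exactly* (the suite asserts conservation to 1e-6 kcal/mol). ΔΔG per
residue is classified favorable ≤ −0.5 / unfavorable ≥ +0.5 kcal/mol with
a neutral band between — the threshold is configurable because published
colour-scale captions are ambiguous about the in-between class, and a
band is the only self-consistent reading. No entropy term is included
(none is part of the protocol being emulated), absolute ΔG values are
therefore not meaningful, and the intended use is *relative* comparison:
sign and rank agreement with experimental ΔΔG = RT ln(K_D ratios) at
298.15 K (R = 1.9872e-3 kcal mol⁻¹ K⁻¹).

Force-field parameters (charge, rmin/2, ε, Born radius, screening factor
per atom) are consumed from user-supplied whitespace tables
(`read_parameters`); deriving them is out of scope, and the built-in
`make_toy_parameters` schemes exist for validation, not physics. The GB
flavour is OBC-style rather than a reimplementation of any specific
production solvation model, whose lookup-table internals are
implementation-specific; this is stated openly and constrains what the
energetics module may be compared against.

## The synthetic-data generator

`make_toy_complex` builds five-chain Cα-level pseudo-complexes with
realistic chain lengths (275/99/9/200/240) whose geometry is known *by
construction*: the peptide lies along x, helices flank at ±9 Å, and the
two variable domains are point-symmetric 110-residue blobs placed so that
the requested crossing angle and footprint are exact (symmetry also makes
the two centroid rules coincide). Contacts are planted as dedicated
atom pairs at requested distances whose construction guarantees no
incidental second contact within the cutoffs. `make_ensemble` adds
per-residue isotropic Gaussian noise (per-coordinate σ, so Cα RMSF = σ√3)
and optional two-state hydrogen-bond switching with Bernoulli occupancy.
All generators draw from a private seeded RNG stream and are
bit-reproducible given (arguments, seed).

What the toys do **not** emulate: real side-chain packing, correlated
backbone motions, solvent structure, or physically meaningful energetics.
Passing the validation suite therefore demonstrates that the *measurement
machinery* is correct (geometry recovery to <0.5°, contact enumeration
equal to an exhaustive oracle, RMSF calibration to the Gaussian closed
form, type-I error at the nominal α, energy bookkeeping exact) — it does
not certify accuracy of any physical prediction on real complexes, which
inherits the usual caveats of the underlying models.

## Problem sizes and numerical choices

The validation suite and `scripts/acceptance.R` run at desk scale, chosen
so the full suite completes in about a minute on one core: RMSF
calibration at 10 replicas × 1000 frames × 30 residues; planted-ΔRMSF
recovery (σ 0.3→0.6 Å on residues 95–100) over 20 generator seeds at
10 × 500 frames; null type-I estimation over 200 repetitions of
10 × 50-frame ensembles (1600 per-residue tests); contact enumeration
against an exhaustive all-pairs oracle on 100 random 120-atom interfaces;
SASA at 960 quadrature points; MM/GBSA fixtures of a few hundred atoms.
Degenerate inputs fail loudly: collinear helix centroids, empty interface
bands, missing parameters or radii, single-frame replicas, non-positive
effective Born radii and overlapping atoms (r < 0.1 Å) are all errors
with named atoms where applicable.

Two statistical design points deserve emphasis. First, because the ΔRMSF
test is uncorrected per-residue at α = 0.05, "recovering a planted
effect" is assessed as *all planted residues flagged* plus a null flag
rate consistent with α — demanding zero false positives would contradict
the test's own definition. Second, replica means (not pooled frames) are
the sampling units everywhere variability is quoted, which keeps the
reported spreads honest in the presence of within-replica correlation.

## Known limitations

mmCIF input, automatic IMGT renumbering and modelling of missing loops
are out of scope; loop definitions for real systems must be curated.
Hydrogen-bond detection has no angular term by default. The shape
complementarity score is discretisation-sensitive at the ±0.02–0.05
level. The energetics module omits entropy, uses a single internal
dielectric, and is a ranking tool only. None of the modules run or
restart molecular dynamics; ensembles must be provided (or synthesised)
by the user.
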