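---
title: "Methods: hydrophobicity-guided template selection and APF screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hydrophobicity-guided template selection and APF screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the conventions it fixes where the underlying methods literature
is silent, and what its synthetic benchmarks do and do not establish.

## 1. The two-stage screening problem

For a receptor with no experimental structure and few known agonists —
olfactory receptors are the motivating family — ligand discovery proceeds in
two stages: a ligand-based screen retaining molecules that superpose well
onto the known agonists' shared feature field, and a structure-based screen
against a homology model.  This package implements the scaffolding around
both stages: the biophysical template-selection cascade that precedes
homology modelling, the stage-1 atomic-property-field (APF) screen, and the
MM-GBSA aggregation arithmetic used to rank final complexes.  Homology model
construction itself, docking, and molecular-dynamics refinement are out of
scope: they are the province of dedicated tools (Modeller, docking engines,
Amber), and this package only consumes or prepares their inputs and outputs.

## 2. Hydrophobicity correspondence

**Model.**  Transmembrane helices are the most structurally conserved
feature of GPCRs, and sequence pairs with similar hydrophobicity patterns
are often structural homologues even at very low identity.  Each helix is
summarised by a moving-window profile over the Eisenberg normalized
consensus scale: `H_n` is the arithmetic mean of the 11 residue values
centred at position `n`.  Two helices are compared after a centre-tethered
alignment (centre residues paired, pairing extended symmetrically, overhangs
dropped), and the correspondence is the sum of squared profile differences
(SSD) over paired positions, divided by the number of paired positions.
Values above 0.1 per residue flag poor correspondence on this scale.

**Conventions fixed here.**

* *Window edges.*  Only full 11-residue windows are evaluated, so a helix of
  length `L` yields `L − 10` profile values.  Padding schemes would invent
  hydrophobicity values for residues that do not exist; restricting to full
  windows keeps every `H_n` a true mean of observed residues.  SSD pairing
  then uses the intersection of defined window centres under the tethered
  alignment.
* *Centre convention.*  For a helix of length `L` the centre is residue
  `floor((L + 1) / 2)` (1-based).  For mixed-parity pairs this fixes the
  pairing uniquely; the convention is tested against its enumerated
  alternative (ceiling centre) so the choice is pinned, not incidental.
  With this convention the pairing always has `min(L_a, L_b)` pairs.
* *Normalisation.*  `ssd_per_residue` divides by the number of *paired
  profile positions* N — the only N that appears in the SSD sum — not by the
  raw helix length.  Both interpretations are defensible readings of
  "per residue"; the paired-position count is the default because it is the
  denominator under which the 0.1 threshold is a per-term mean.
* The scale ships as a checksummed data table and is pluggable; SSD is
  invariant under adding a constant to the scale (window means shift
  equally), which the property tests verify.

## 3. Sequence identity and coverage

Global identity and query coverage are computed from one Needleman–Wunsch
global alignment (BLOSUM62, affine gaps: open 10, extend 0.5 in matrix
units, via Biostrings).  Identity is the percentage of identical pairs among
aligned columns *excluding terminal-gap runs*; coverage is the percentage of
target residues aligned opposite a non-gap template residue.  The
published identity figure this package's validation tier targets (83.5%
between OR1A2 and OR1A1) comes from an unstated alignment protocol, so the
convention here is documented and the validation check carries a ±1
percentage-point tolerance.  An independent plain-R Gotoh dynamic program in
the test suite pins the alignment engine's optimal scores on random small
pairs.

## 4. Orthosteric-pocket comparison

The class A GPCR orthosteric site is represented as 24 Ballesteros–Weinstein
positions (bundled table), with an 11-position mutagenesis-supported subset
for ORs.  Pocket similarity between two receptors is the unweighted sum of
substitution-matrix entries over positions resolvable in both receptors;
positions not covered by a receptor's TM annotation are reported as missing
data rather than errors.  The "percent similar" statistic needs a predicate
the source literature never defines; both options are implemented —
*positive matrix score* (default) and *strict identity* — and every report
names the predicate and matrix used.

**Stand-in matrix.**  The intended matrix is GPCRtm, derived specifically
from GPCR TM alignments.  It could not be obtained in this offline build, so
the bundled file `gpcrtm_synthetic.tsv` carries BLOSUM62 values under a
clearly labelled synthetic name: shape, symmetry and conventions are
preserved, the GPCR-specific values are not.  Validation-tier checks that
compare against published pocket scores therefore fail deliberately until a
user supplies the real matrix and sequences under `inst/extdata/validation/`.

## 5. The atomic property field engine

**Channels.**  Every heavy atom carries a 7-vector φ: H-bond donor (0/1,
N/O bearing ≥1 H), acceptor (0/1, any N/O — Lipinski-style), sp2
hybridisation (0/1, perceived), lipophilicity (Crippen atomic logP, hydrogens
merged), size ((r_vdW/r_vdW(C))³, so carbon = 1), electronegativity (Pauling
EN − 2.55, signed), and partial charge (Gasteiger, hydrogens merged).  All
perception is delegated to RDKit through a batch sidecar; the rules are the
standard ones of the cheminformatics literature and are recorded in output
metadata.

**Field.**  `P_i(r) = (1/n_lig) Σ_atoms φ_i · exp(−|r − r_atom|²/2σ²)` on a
regular grid.  Defaults: σ = 1.0 Å (roughly an atomic radius: features blur
enough to tolerate pose error without washing out), spacing 0.5 Å (≤ σ/2, so
trilinear interpolation error is small against field curvature), padding
3.0 Å (≈ 3σ; beyond it the kernel is negligible), kernel truncated at 4σ.
The reference implementation of APF in the original software has an
unpublished functional form; these choices are therefore this package's own,
configurable, and recorded in every pharmacophore header.

**Scoring.**  A pose scores `E = −Σ_j Σ_i φ_i^j P_i(r_j)` with trilinear
interpolation; `S = −E`.  Atoms outside the grid contribute zero and are
counted in the hit table.  Energies are exactly linear over disjoint atom
subsets and invariant under rigid motion of ligand-plus-frame up to grid
re-discretisation (both property-tested).

**Consensus (the 75% rule).**  With per-ligand fields on a shared grid, a
channel is included iff the number of ligands exhibiting it reaches
`ceiling(0.75 · n)`.  "Exhibiting" is per-ligand-global: the ligand's field
for that channel exceeds (in absolute value) 5% of the channel's global
maximum somewhere on the grid.  A per-grid-point variant of the rule would
also be defensible; per-ligand-global was chosen because with ≤ 13 actives a
per-point vote is extremely sparse and noise-dominated at this grid spacing.
The ceiling arithmetic is tested exhaustively for n = 2..16, including the
13-ligand case (inclusion exactly from 10 ligands).

**Superposition.**  Flexible superposition in the original protocol (effort
parameters, ring sampling) is engine-specific; here ligands are treated as
rigid conformers and flexibility is emulated by multi-conformer input.  Pose
search runs the input pose plus `n_restarts` random starts — rotations
uniform over SO(3) via quaternion sampling, translations centring the ligand
on the field with 1 Å Gaussian jitter — each refined by cyclic coordinate
descent over the six pose parameters (initial steps 0.25 rad / 0.5 Å, halved
on stagnation until 0.005 rad / 0.02 Å).  Everything is seeded;
identical inputs and seed give byte-identical hit tables.

**Threshold.**  A published absolute cutoff ("APF score ≥ 100") does not
transfer across kernels, so the default operating point is the 95th
percentile of the screened library's scores, and any absolute value can be
supplied instead.  Reports record which was used.

## 6. MM-GBSA arithmetic

The package computes only the aggregation layer: per-snapshot
`ΔG_i = G_com,i − G_rec,i − G_lig,i` with mean and standard error, and the
component identities `ΔG_gas = ΔE_vdW + ΔE_Ele`,
`ΔG_bind = ΔG_gas + ΔE_Sol`.  Report rounding is 2 decimals half-away-from-
zero.  The bundled six-complex reference table is audited rather than merely
asserted: recomputation from the printed component triples reproduces all
printed aggregates within 0.02 kcal/mol, with two `ΔG_bind` entries
(control and palmitic acid) and three `ΔG_gas` entries off by exactly 0.01 —
the source's own internal pre-rounding, which the audit records instead of
hiding.  No standard errors were published for that table, so none can be
validated.

## 7. The selection cascade

Stages run in order — resolution/state filter (≤ 2.5 Å, inactive state, best
structure per distinct receptor), HC shortlist (templates minimal in at
least one helix, ties retained), query coverage (≥ 80% by default), ligand
profile (median Tanimoto of the template's ligand against the target's
actives; MACCS fingerprints standing in for the 881-bit PubChem scheme,
recorded as such), pocket comparison — and each stage can be toggled.  The
original study's final call integrated qualitative judgment; no scalar
objective is pretended here.  Instead the report carries every metric, and
the default ranking is an explicit lexicographic order: pocket score
(descending), mean per-helix SSD (ascending), coverage (descending), id.
Survivor sets are monotone non-increasing across stages, a stage that
empties the candidate list sets a flag instead of throwing, and every
reported number is reproducible by calling the underlying module directly
(cross-checked in tests).

## 8. Synthetic data: what it emulates, what it does not

`make_receptor()` emulates the *hydropathy architecture* of a 7TM receptor:
seven helices (lengths 22–28 by default, ~TM-like) whose mean Eisenberg
hydrophobicity is driven to a target (0.8 ± 0.05 by default, a typical TM
mean on this scale) by greedy residue swaps, joined by hydrophilic loops
(8–16 residues) and termini.  Mutants at a controlled substitution rate give
graded template sets.  It does *not* emulate real GPCR motifs, conserved
anchors, loop structure or evolutionary covariation — so a green HC test
establishes correct arithmetic and discrimination on controlled inputs, not
biological validity of any particular template call.

`make_library()` emulates a *scaffold-sharing active series* — a
citronellal-like monoterpenoid aldehyde core with small decorations — against
*physicochemically diverse metabolite-like decoys* (aromatics, acids, amino
acids, polyols, heterocycles) of comparable size, the standard construction
for enrichment benchmarks.  Conformers come from seeded distance-geometry
embedding (ETKDG) with MMFF cleanup.  Decoys are not property-matched to the
actives' logP distribution, so the benchmark measures whether the APF engine
recovers shared-feature molecules, not whether it would beat a
property-matched decoy challenge; absolute scores are not comparable to any
other APF implementation.  Sample sizes in the acceptance benchmark (10
actives / 90 decoys, seeds 0–4) follow the stated test design; enrichment is
reported in the top 10% and top 20 ranks.

The 13-entry ligand manifest bundles the three literature-named OR1A2
agonists with real identifiers and ten clearly labelled synthetic
monoterpenoid placeholders, because the full published list lives in
supplementary material that cannot be redistributed here.

## 9. Numerical choices and degenerate inputs

* Grids: column-major `(nx, ny, nz, 7)` arrays; at least 2 nodes per axis;
  trilinear weights clamp at the upper boundary so on-boundary atoms remain
  inside.
* Ties in hit tables are broken by ligand id; all report rows are sorted, no
  timestamps are written, so reports are byte-reproducible.
* `tanimoto` of two empty fingerprints is defined as 0.
* Profiles require helix length ≥ window; shorter input names the helix in
  the error.  Pocket positions missing from an annotation are data; zero
  *shared* positions is an error.
* Rounding half-away-from-zero is applied only at the reporting layer; raw
  values are kept alongside.

## 10. Known limitations

* APF scores are on this package's kernel scale; only rank behaviour, not
  absolute values, is comparable to other implementations.
* Rigid superposition with multi-conformer input undersamples torsional
  space relative to true flexible alignment.
* The bundled substitution matrix is a stand-in (Section 4); pocket-score
  *values* against published numbers are meaningless until the real matrix
  and sequences are supplied.
* TM annotation and BW anchors are user inputs; no TM prediction or
  generic-numbering inference is attempted.
* MM-GBSA energies are consumed, never computed, and entropy terms are out
  of scope.
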