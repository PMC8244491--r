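# olfscreen

Biophysical template selection and atomic-property-field (APF) screening for
olfactory receptors and other class A GPCRs without experimental structures.

## The problem

Roughly 400 human olfactory receptors (ORs) are seven-transmembrane GPCRs,
almost none of which has a solved structure, and most have only a handful of
known agonists.  Discovering new ligands for such a receptor typically runs
in two stages: a ligand-based screen that keeps only molecules resembling the
known agonists, followed by structure-based docking against a homology model.
Both stages hinge on scaffolding that is rarely packaged reusably:

1. **Template selection for the homology model.**  ORs share <30% sequence
   identity with solved GPCR structures, so identity alone is a poor guide.
   `olfscreen` implements a multi-parameter cascade: resolution/activity-state
   filtering, *hydrophobicity correspondence* (HC), global identity and query
   coverage, ligand-profile comparison, and orthosteric-pocket scoring with a
   substitution matrix.

2. **Stage-1 ligand-based screening.**  A seven-channel atomic property field
   — H-bond donor, acceptor, sp2 hybridisation, lipophilicity, size,
   electronegativity, charge — is splatted onto a 3D grid from the known
   agonists, reduced to a consensus pharmacophore (a channel is kept when ≥
   75% of the ligands exhibit it), and candidate molecules are rigid-body
   superposed and scored.

3. **MM-GBSA aggregation** for the final ranking of docked complexes.

## The core quantities

Hydrophobicity correspondence uses an 11-residue moving window over the
Eisenberg consensus scale,

    H_n = (1/11) * sum_{i=n-5..n+5} h_i

and scores a template helix against the target helix (centre-tethered
alignment) by the sum of squared differences,

    SSD = sum_n (H_template,n − H_target,n)²,

normalised per paired residue; SSD/N > 0.1 flags poor correspondence.

A pose against a property field P_i(r) is scored by the pseudo-energy

    E_APF = − sum_j sum_i  φ_i^j · P_i(r_j),        S = −E_APF

(φ_i^j: channel *i* of atom *j*; trilinear interpolation on the grid; larger
S is better).

MM-GBSA binding energies aggregate per-snapshot free energies,

    ΔG = ⟨G_complex − G_receptor − G_ligand⟩_snapshots,

and per-complex components, ΔG_gas = ΔE_vdW + ΔE_Ele and
ΔG_bind = ΔG_gas + ΔE_Sol.

## Worked example

```r
library(olfscreen)

## synthetic benchmark: 4 scaffold-sharing actives + 6 metabolite-like decoys
lib <- make_library(library_spec(n_actives = 4, n_decoys = 6, seed = 0))
res <- run_stage1_screen(lib$actives, c(lib$actives, lib$decoys),
                         config = list(n_restarts = 8L), seed = 0)
head(res$hits, 6)
#>   ligand_id    score n_atoms_outside_grid   hit
#> 1 active_02 25.02970                    0  TRUE
#> 2 active_03 24.43125                    0 FALSE
#> 3 active_01 24.15091                    0 FALSE
#> 4 active_04 21.23300                    0 FALSE
#> 5  decoy_03 19.73757                    0 FALSE
#> 6  decoy_06 17.96243                    0 FALSE
```

All four actives outrank every decoy: the consensus pharmacophore (here
keeping acceptor, sp2, lipophilicity, size, electronegativity and charge —
the donor channel failed the 75% rule) concentrates the aldehyde scaffold's
features.  `score` is S = −E_APF; `hit` uses the default threshold, the 95th
percentile of the screened library's scores (24.76 above), because the
absolute score scale depends on the kernel.

```r
## template selection against three synthetic candidates of decreasing
## similarity to the target receptor
r <- make_receptor(receptor_spec(seed = 1))
cands <- lapply(1:3, function(i) {
  mut <- mutate_receptor(r, c(0.02, 0.3, 0.5)[i], seed = 100 + i)
  template_candidate(sprintf("tpl%02d", i), sprintf("rec%02d", i),
                     2.0 + 0.1 * i, "inactive", mut$seq, mut$tms, mut$anchors)
})
rep <- run_selection(r, cands)
rep$ranking[1]
#> [1] "tpl01"
rep$metrics[, c("template_id", "TM1", "identity_pct")]
#>   template_id       TM1 identity_pct
#> 1       tpl01 0.0000000         97.8
#> 2       tpl02 0.1307857         74.3
#> 3       tpl03 0.1507605         54.9
```

`TM1` is the per-residue SSD of that helix (tpl02/tpl03 exceed the 0.1
poor-correspondence threshold); the near-identical tpl01 survives every
stage and tops the lexicographic ranking (pocket score, then mean SSD, then
coverage).

```r
## MM-GBSA component aggregation (kcal/mol)
ec <- combine_components(-26.28, -0.87, 7.3753, "control")
c(ec$dG_gas, ec$dG_bind)
#> [1] -27.15 -19.77
```

## Command line

```sh
olfscreen profile         --target-fasta target.fasta --target-tm target_tm.tsv
olfscreen select-template --target-fasta target.fasta --target-tm target_tm.tsv \
                          --candidates candidates.tsv --out-dir out
olfscreen apf-screen      --actives actives.sdf --library library.sdf \
                          --out-dir out --seed 1
olfscreen mmgbsa          --energies energies.csv --out-dir out
```

(`inst/exec/olfscreen`; or call `olfscreen::olfscreen_cli()` directly.)

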