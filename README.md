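# specflex

Quantifies the link between a protease's **substrate specificity** and the
**conformational flexibility** of its binding-site sub-pockets, for
structural bioinformaticians studying substrate readout (the motivating
system is thrombin and its non-prime pockets S6…S1).

The package joins two measurements that live in different data worlds:

* **Cleavage entropy** (specificity) from a MEROPS-style substrate table —
  for each position Pn, the normalized Shannon entropy of residue
  frequencies over known cleavage sites,

  S(Pn) = −Σₐ fₐ log₂₀ fₐ  ∈ [0, 1],

  0 = a single residue type accepted (stringent readout), 1 = all twenty
  residues equally frequent (no preference).

* **Flexibility and interaction metrics** from a conformational ensemble
  (multi-model PDB):
  * Cα B-factors after one global Kabsch alignment, B = (8π²/3)·MSF [Å²];
  * backbone dihedral entropies Sφ, Sψ = −R ∫ p(α) ln p(α) dα [J/(mol·K)]
    from periodic Gaussian-kernel density estimates (data duplicated at
    ±360° so the estimate does not decay at the −180°/180° seam);
  * protease–peptide hydrogen-bond occupancies (heavy-atom distance ≤ 3.0 Å,
    D–H···A deviation from linearity ≤ 45°), reported as mean bonds per
    frame per pocket (values can exceed 1);
  * pairwise 2D RMSD matrices and ten-block convergence diagnostics.

Sub-pockets are defined from a complex structure by the 3.5 Å contact rule
(every protease residue with an atom within 3.5 Å of the peptide residue at
Pn belongs to Sn), residue-wise metrics are pocket-averaged arithmetically,
and each pocket-wise metric is rank-correlated (Spearman ρ, midranks,
pairwise deletion, exact permutation p-value optional) against cleavage
entropy. A synthetic-data module generates substrate tables, torsion series,
coordinate ensembles and toy complexes with closed-form ground truth, so
every estimator is validated by parameter recovery.

## Worked example

```r
library(specflex)

# a packaged six-pocket scenario: S1 rigid/specific ... S6 flexible/unspecific
sc <- thrombin_like_scenario(seed = 1, frames = 20000, substrates = 1000)

# specificity from the substrate table
prof <- cleavage_entropy_profile(sc$substrates$table)
prof
#> SpecificityProfile (cleavage entropy, 0 = stringent, 1 = random):
#>     P6     P5     P4     P3     P2     P1
#> 0.9880 0.9382 0.9069 0.8535 0.3912 0.1078

# global backbone flexibility: align on the rigid core, then B-factors
ens <- sc$coordinates$ensemble
al  <- kabsch_superpose(ens, select_residues(ens, sc$coordinates$anchors, "CA"))
bf  <- calpha_bfactors(al)

# local backbone flexibility: dihedral entropies per residue
dih <- dihedral_entropy_profile(sc$dihedrals$series)

# pocket-wise aggregation and rank correlation against cleavage entropy
report <- correlate_specificity(
  prof,
  list(bfactor = pocket_average(setNames(bf$bfactor, bf$residue),
                                sc$pockets, "bfactor"),
       s_phi   = pocket_average(setNames(dih$s_phi, dih$residue),
                                sc$pockets, "s_phi"),
       hbonds  = hbond_occupancy(sc$interface$ensemble, sc$interface$pockets,
                                 sc$interface$peptide_chain)))
report
#> Pocket-wise metric table:
#>  pocket cleavage_entropy   bfactor    s_phi hbonds
#>      S6        0.9880155 33.366958 46.69487 0.6042
#>      S5        0.9381646 23.872382 41.95853 0.0494
#>      S4        0.9068588 16.029123 38.47946 0.0000
#>      S3        0.8535380  9.642395 36.14540 0.3572
#>      S2        0.3912488  4.923578 32.21837 0.0000
#>      S1        0.1077801  1.773817 28.58481 0.9448
#>
#> Spearman correlations vs cleavage entropy:
#>   bfactor                rho =  1.0000  (n = 6)
#>   s_phi                  rho =  1.0000  (n = 6)
#>   hbonds                 rho = -0.0870  (n = 6)
```

Reading the output: entropy rises from 0.11 (P1, near-stringent readout) to
0.99 (P6, near-random), B-factors and φ entropies rise in the same pocket
order, so both flexibility metrics recover the planted monotone link
(ρ = 1), while hydrogen bonding — planted non-monotone, as observed
empirically — correlates near zero. Flexibility, not hydrogen-bond count,
tracks specificity.

Real data enter the same way: `read_substrate_table()` for a CSV/TSV export
of cleavage sites, `read_multimodel_pdb()` for an ensemble,
`define_subpockets()` / `merge_definitions()` for the pocket map. A thin
command-line wrapper over these functions ships in `inst/cli/specflex.R`
(subcommands `cleavage-entropy`, `bfactors`, `dihedral-entropy`, `rmsd2d`,
`pockets`, `hbonds`, `correlate`, `simulate`).

## Scope

The package analyses ensembles you already have; it does not run molecular
dynamics, prepare structures, or compute solvation thermodynamics, and it
does not download substrate databases.
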