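---
title: "Linking protease substrate specificity to binding-site flexibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking protease substrate specificity to binding-site flexibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Serine proteases such as thrombin read out their substrates position by
position: the residue bound in sub-pocket S1 (Schechter–Berger nomenclature;
Pn is the substrate residue n positions N-terminal of the scissile bond, Sn
the protease pocket that binds it) is selected far more stringently than the
residues bound in the outer pockets. Static structures do not explain this
gradient well, because the outer pockets differ little in their enthalpic
interaction patterns. The hypothesis this package operationalizes is a
*conformational-selection* one: **rigid pockets accept few residue types,
flexible pockets accept many**, so local binding-site flexibility measured
on the *unbound* enzyme should rank-order with substrate specificity
measured on the *degradome*.

`specflex` implements both sides of that comparison and the statistics that
join them:

* **Specificity** — position-wise *cleavage entropy* over a table of known
  cleavage sites,
  $$S_\mathrm{cleavage}(P_n) = -\sum_{a} f_a \log_{20} f_a \in [0, 1],$$
  where $f_a$ is the relative frequency of amino acid $a$ at position $P_n$.
  0 means a single residue type is accepted, 1 means all twenty occur
  equally often.
* **Flexibility** — from a conformational ensemble (multi-model PDB):
  residue-wise Cα B-factors $B = \tfrac{8\pi^2}{3}\,\mathrm{MSF}$ after one
  global Kabsch alignment; backbone dihedral entropies
  $S_\alpha = -R \int p(\alpha) \ln p(\alpha)\, d\alpha$ for $\alpha \in
  \{\varphi, \psi\}$ from a periodic kernel density estimate; pairwise 2D
  RMSD matrices for convergence inspection.
* **Interaction** — protease–peptide hydrogen-bond occupancies (mean bonds
  per frame per pocket, geometric criteria 3.0 Å / 45°).
* **The join** — distance-based sub-pocket definitions (3.5 Å contact rule),
  per-pocket arithmetic averaging of residue-wise metrics, Spearman rank
  correlation of each pocket-wise metric against cleavage entropy,
  complex-minus-unbound difference maps, and ten-block convergence
  diagnostics.

## Cleavage entropy: conventions

The base-20 logarithm is the only normalization for which the two printed
anchors hold exactly (0 for a point distribution over the 20-letter
alphabet, 1 for the uniform one). Further conventions, each chosen to avoid
biasing the statistic:

* $0 \log 0 := 0$, the standard information-theoretic convention.
* Unknown residues (`"X"`) are excluded from numerator *and* denominator.
  Spreading them uniformly would inflate entropy at sparsely annotated
  positions.
* No pseudocounts by default; `cleavage_entropy_profile(..., pseudocount=)`
  exposes additive smoothing for users who want it, but the default is the
  plain maximum-likelihood estimate because the reference analyses apply no
  smoothing.
* Rows are unweighted. Whether a substrate reported several times in a
  database export should count several times is a curation question; the
  parser keeps whatever rows the file contains.
* Prime-side positions are parseable but excluded from the default profile:
  non-prime positions P6…P1 are the ones in direct contact with the
  non-prime binding cleft analysed here.

## Dihedral entropy: estimator and numerical choices

The torsion distribution is estimated with a Gaussian kernel after
duplicating the sample at ±360°, so the kernel does not decay at the
−180°/180° seam; the density is then renormalized to integrate to 1 over one
period. Entropy is integrated on the KDE grid by the rectangle rule (exact
trapezoid on a periodic grid), with $p \ln p := 0$ wherever the density
underflows.

**Units.** Densities are per degree and $R = 8.3145\ \mathrm{J/(mol\,K)}$,
so a uniform torsion gives $R \ln 360 \approx 48.94\ \mathrm{J/(mol\,K)}$
and a peak confined to about 1° gives $\approx 0$ — entropies of folded
backbone torsions land in the familiar 30–40 J/(mol K) range. A width-$w$
box scales as $R \ln w$; the package's tests verify this for
$w \in \{1°, 10°, 60°, 360°\}$.

**Bandwidth.** Silverman's rule on the *circular* standard deviation,
$h = 0.9\,\sigma_c\,n^{-1/5}$. A degenerate sample (zero circular spread)
falls back to a 1° bandwidth with a warning; that floor is a fallback for
pathological input, *not* a lower bound on regular bandwidths — clamping
every bandwidth to ≥1° would smear a genuinely 1°-wide peak to an apparent
entropy of ~12 J/(mol K) and destroy the zero anchor.

**Grid.** 720 points by default; whenever the grid spacing would exceed
$h/3$ the grid is refined to the next power of two (capped at $2^{18}$), so
narrow peaks remain resolved. Doubling the grid changes the entropy of a
typical torsion sample by < 0.05 J/(mol K) (tested).

**What is deliberately not estimated.** One-dimensional torsion entropies
ignore correlations between angles; summed over residues they upper-bound
the true backbone entropy. No mutual-information correction and no
side-chain χ torsions are provided.

## B-factors and superposition

`kabsch_superpose()` performs a single global rigid-body alignment (SVD with
the determinant correction, so a reflection is never returned) of every
frame onto a reference (frame 1 by default — the reference is not critical
for fluctuations, and an external structure can be supplied); `calpha_bfactors()`
then computes, per residue,
$\mathrm{MSF} = \langle \|r - \langle r\rangle\|^2 \rangle$ over frames and
$B = \tfrac{8\pi^2}{3}\mathrm{MSF}$, using the single Cα atom per residue.

One practical caveat the synthetic tests make explicit: if the alignment
selection *includes* strongly fluctuating atoms, the fit absorbs part of
their displacement and deflates their apparent MSF by $O(1/N)$ terms. For
parameter-recovery runs the package therefore aligns on a rigid anchor core
(the generator reports its zero-σ residues for exactly this purpose), which
is the usual core-alignment practice on real trajectories too.

## Sub-pockets, hydrogen bonds, averaging

* A pocket $S_n$ is every protease residue with ≥1 atom (hydrogens
  included) within 3.5 Å of ≥1 atom of the peptide residue at $P_n$, taken
  from a single complex structure (frame 1 of an ensemble). Definitions from
  different complexes are merged by per-pocket set union. Empty pockets are
  kept and flagged, never dropped silently.
* Hydrogen bonds: donors are N/O heavy atoms with a covalently bound
  hydrogen (inferred by an H within 1.2 Å), acceptors are N/O; a bond
  requires heavy-atom distance ≤ 3.0 Å *and* donor–hydrogen–acceptor
  deviation from linearity ≤ 45° (D–H···A angle ≥ 135°), the convention of
  the standard trajectory-analysis tools. Occupancy is the mean *count* of
  bonds per frame attributed to a pocket's residues, so a pocket making
  several simultaneous bonds scores above 1. When a bond's protease residue
  belongs to several pockets it counts toward each; attribution is by
  protease-residue membership, not by peptide position.
* Pocket averaging is the unweighted arithmetic mean over the pocket's
  residues, with residues shared between pockets contributing to each.

## Rank correlation and reporting

Spearman's ρ is computed as the Pearson correlation of midrank vectors
(ties get midranks; without ties this equals $1 - 6\sum d^2 / (n(n^2-1))$).
With six pockets the resolution of ρ is coarse — a single adjacent rank swap
moves it from 1 to 0.943, a displacement of $\sum d^2 = 4$ gives 0.886 — so
the package always reports $n$ alongside ρ, treats zero rank variance as
*undefined* rather than 0, drops incomplete pocket pairs pairwise, and can
attach an exact permutation p-value for $n \le 8$ (all $n!$ orderings;
large-sample approximations are meaningless at $n = 6$).

Published pocket-wise analyses of this kind report ρ values whose exact
reconstruction from the printed pocket tables is not always possible (the
ψ-entropy correlation is a known example: the printed coefficient does not
follow from the printed pocket values under the no-ties formula). The
package takes no side: it reports the signed coefficient it computes,
with the ranks, and leaves interpretation to the caller.

Difference maps are `complex − unbound` on the shared residue set; negative
values mean rigidification upon binding. Block convergence splits the
ensemble into $k$ contiguous blocks (ten blocks mirrors the common practice
of splitting a 1 μs trajectory into 100 ns parts), recomputes the metric per
block and reports, per pocket pair, the fraction of blocks preserving the
full-trajectory rank order.

## The synthetic-data generator

The unpublished microsecond trajectories behind the reference analyses
cannot be redistributed, so the package ships generators that emulate the
*statistical* structure of each input with known ground truth:

* `gen_substrate_table()` — i.i.d. draws from planted positional
  distributions; truth is the closed-form normalized entropy.
* `gen_dihedral_ensemble()` — i.i.d. von Mises (mixture) torsion series;
  truth is the closed form
  $R[\ln(2\pi I_0(\kappa)) - \kappa I_1(\kappa)/I_0(\kappa)] + R\ln(180/\pi)$
  for single components and $10^5$-point quadrature of the analytic mixture
  density otherwise.
* `gen_coordinate_ensemble()` — ideal backbone scaffold plus isotropic
  per-residue Gaussian displacements (truth $B = \tfrac{8\pi^2}{3}3\sigma^2$),
  with optional global rigid-body jitter to verify alignment removes it.
* `gen_interface_ensemble()` — a toy protease/hexapeptide complex with
  contact atoms planted inside the 3.5 Å cutoff and N–H···O bonds formed
  with per-pocket probability $q$ (idealized N–H length 1.01 Å, collinear
  when formed, broken to 5.5 Å otherwise).

`thrombin_like_scenario()` packages a six-pocket study in which substrate
readout and flexibility are planted concordantly (S1 rigid/specific → S6
flexible/unspecific: planted cleavage entropies ≈ 0.11, 0.39, 0.87, 0.92,
0.96, 0.99; Cα σ from 0.15 to 0.65 Å; torsion κ from 60 down to 1.2) and the
hydrogen-bond pattern is deliberately non-monotone (S1 strong, S6 moderate,
S3 partial, S2/S4/S5 ≈ 0), mirroring the empirical observation that
hydrogen bonding does *not* rank-order with specificity. Default problem
sizes — 20,000 frames, 1,000 substrates, 5,000 interface frames — were
chosen once as the point where every estimator's sampling error is far
below the planted between-pocket gaps.

What the generators deliberately do **not** emulate: autocorrelated
dynamics (samples are i.i.d.; real trajectories decorrelate slowly, so real
block diagnostics scatter more), force-field energetics, solvent, side
chains, and anisotropic fluctuations. Passing recovery tests therefore
demonstrates estimator correctness — not that any real protease behaves like
the scenario.

## Worked example

```{r example}
library(specflex)

sc <- thrombin_like_scenario(seed = 1, frames = 20000, substrates = 1000)

prof <- cleavage_entropy_profile(sc$substrates$table)

ens <- sc$coordinates$ensemble
al  <- kabsch_superpose(ens, select_residues(ens, sc$coordinates$anchors, "CA"))
bf  <- calpha_bfactors(al)

dih <- dihedral_entropy_profile(sc$dihedrals$series)

report <- correlate_specificity(
  prof,
  list(bfactor = pocket_average(setNames(bf$bfactor, bf$residue),
                                sc$pockets, "bfactor"),
       s_phi   = pocket_average(setNames(dih$s_phi, dih$residue),
                                sc$pockets, "s_phi"),
       hbonds  = hbond_occupancy(sc$interface$ensemble, sc$interface$pockets,
                                 sc$interface$peptide_chain)))
report
```

On the planted scenario the flexibility metrics recover ρ = 1 against
cleavage entropy while the hydrogen-bond occupancy correlates near zero —
the qualitative pattern the method is designed to expose.

## Known limitations

* Multi-model PDB is the only ensemble format; binary trajectory formats
  need conversion upstream (the `FrameEnsemble` contract is adapter-ready).
* Water and ions are analysed if present in the input; the package does not
  strip them, and it provides no solvation thermodynamics.
* Absolute dihedral-entropy values depend on bandwidth and grid settings;
  between-pocket *ranks* are the robust quantity, which is why the report
  layer is rank-based.
* No p-value machinery beyond the exact permutation test; with six pockets
  any multiple-testing correction would be theater.
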