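---
title: "Disentangled contact statistics for residue-residue interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disentangled contact statistics for residue-residue interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepSRV)
```

## The model

deepSRV predicts which residue pairs between two protein chains are in
contact, using only the two sequences at prediction time. All of its
knowledge comes from inter-chain contact counts observed in solved
complexes, processed in three steps.

**Contacts.** Each residue is reduced to one representative atom — the
C$\beta$, or the C$\alpha$ for glycine, which has no side-chain carbon —
and a cross-interface pair is a contact when the representative atoms are
strictly closer than 6 Å. The strictness matters only on a set of measure
zero in real data, but it fixes the boundary behaviour exactly, and the
test suite pins it. Pooled over complexes, contacts give a symmetric
$20\times 20$ count matrix $O$ over residue types; an unordered contact
between distinct types is counted once and mirrored into both symmetric
cells, and a same-type contact increments the diagonal once. The mirrored
convention is a choice — sources rarely state theirs — so the counter also
offers a doubled-diagonal variant (`diagonalDouble = TRUE`) under which
row sums count residue participations.

**Residuals.** Raw counts mostly reflect residue abundance. Writing
$r_i, c_j, N$ for the margins and total of $O$ and
$e_{ij} = r_i c_j / N$, each cell becomes the adjusted standardized
residual
$$d_{ij} = \frac{o_{ij} - e_{ij}}
  {\sqrt{e_{ij}\,(1 - r_i/N)\,(1 - c_j/N)}},$$
approximately standard normal when contacts are random, so $|d| > 1.96$
flags a 95%-level preference (positive) or avoidance (negative). The
margin-correction factors distinguish this *adjusted* residual from the
plain $ (o-e)/\sqrt{e}$, which is available behind `adjusted = FALSE` for
sensitivity analysis; "adjusted standard residual" is taken in its
standard (Haberman) sense. Cells with zero expectation have no defined
residual: they are stored as 0 and flagged, so the downstream
decomposition always sees a complete matrix, and flagged cells are barred
from significance classes. The resulting matrix is treated as a vector
space (the SRV) whose rows — *r-vectors* — are the interaction profiles
of the 20 residue types.

**Disentanglement.** A residue's contacts are driven by several
overlapping forces (hydrophobic burial, disulfide bonding, charge
complementarity, hydrogen bonding), which entangle in the SRV. Principal
component decomposition separates them: columns are centered by their
means and the covariance (divisor $n-1$) is eigendecomposed. No variance
scaling is applied — the residual transform has already placed every cell
on the standard-normal scale, and rescaling would undo exactly the
statistical calibration the SRV provides. Column centering (rather than
row, or both) is adopted because it is the convention that reproduces the
package's worked three-point example exactly. The r-vectors are projected
onto each retained component ($t_m = (X - \mathbf{1}\mu^\top) v_m$), and
each component is re-projected to residue coordinates as the rank-1
matrix $\mathrm{RSRV}_m = t_m v_m^\top$. Means are *not* added back in the
re-projection: the RSRV isolates the residual structure that one
component explains, and its cells are read as component-specific
residuals on the same $\pm 1.96$ scale. Summing all 20 re-projections and
the mean rows reconstructs the SRV to machine precision, an identity the
tests assert at $10^{-8}$.

**Features and classifier.** A candidate pair $(i, j)$ with $k$
neighbours per side is encoded in $18(2k+1)$ features (with $M = 6$
components): the $M$ projection scores of each of the $2(2k+1)$ window
residues, then for each of the $2k+1$ aligned window pairs the $M$ RSRV
values. Window A is paired left-to-right against window B right-to-left,
so the two centers always face each other — the orientation one obtains
when two chain segments meet head-on. Because an RSRV is not exactly
symmetric after centering, the pair feature is the symmetric average
$(\mathrm{RSRV}_m[a,b] + \mathrm{RSRV}_m[b,a])/2$ by default, with the
ordered entry available behind a flag. The classifier is an ensemble of
1000 extremely randomized trees (uniform-random split points, no
bootstrap, $\sqrt{d}$ candidate features per split, fully grown), fitted
as a probability forest via `ranger`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` | 6.0 Å | contact cutoff on representative-atom distance |
| `z` | 1.96 | two-sided 95% significance level on residuals |
| `nComponents` (M) | 6 | retained principal components; on realistic contact data the top 6 carry roughly 80% of the variance |
| `neighbors` (k) | 3 | window half-width; feature length is 18(2k+1): 18, 54, 90, 126 for k = 0..3 |
| `nTrees` | 1000 | ensemble size |
| `seed` | — | every stochastic step (tree growing, generators, subsampling) is seeded |

## Numerical and degenerate-input choices

* **Eigenvector signs** are arbitrary in any eigendecomposition; they are
  fixed so each component's largest-magnitude loading is positive.
  Comparisons with externally printed projections may therefore require a
  global per-component sign flip; re-projections are invariant under the
  joint flip and need no convention.
* **Tied eigenvalues** keep the stable order returned by `eigen`;
  degenerate subspaces are compared by projection rather than per-vector
  in the tests.
* **Boundary classification**: residuals exactly at $\pm z$ are
  *irrelevant* (strict inequalities).
* **Missing representative atoms** (a non-glycine without a C$\beta$,
  e.g. from partial side-chain density): the residue is skipped with a
  warning rather than given an invented coordinate. Alternate locations
  keep the highest-occupancy copy, ties broken by altLoc identifier;
  multi-model files use the first model; non-standard residues (MSE
  included) are excluded because the residual space is defined over the
  20-letter alphabet.
* **Zero denominators** in confusion metrics (e.g. no positive calls)
  yield 0 by convention, reported via a message.
* **Unknown sequence letters** (X, B, Z) and off-terminus window
  positions map to a pad symbol contributing zero features, keeping the
  dimensionality fixed without inventing residue statistics.

## What the synthetic generator emulates

`plantedPreferenceModel()` plus `generateComplex()` produce a world in
which each cross-chain pair is a contact with probability
`baseRate * factor[a, b]`. The default factor matrix plants the broad
structure real contact statistics show: enrichment (factor 8) within the
hydrophobic group {L, V, I, F, M, A}, within the polar group
{S, T, N, D}, across opposite charges {R, K} × {D, E} and for C–C
(disulfide-like) pairs, and depletion (factor 0.1) between like charges;
the base rate of 0.02 gives interface-like sparsity (a few dozen contacts
per 25 × 25-residue chain pair). These values were chosen once, when the
generator was designed, as a caricature strong enough to be recoverable
yet far from separable; the evaluation study uses 10 such complexes of
25 × 25 residues with k = 3, M = 6 and 1000 trees, sizes at which a full
leave-one-complex-out pass runs in minutes on one core.

What the generator deliberately does **not** emulate: geometry-induced
spatial correlation between neighbouring pairs (labels are independent
given types, except in the `geometric` mode, which places residues in 3-D
only to exercise the distance code), sequence composition bias, chain
redundancy across complexes, and the type-marginal skew of real
proteomes. Consequently, passing the planted-recovery and LOCO tests
shows the statistical machinery and the learning pipeline are sound — it
does not certify performance on real interfaces, where neighbourhood
signal, redundancy handling and composition effects matter.

Two further design points deserve note. In leave-one-complex-out
evaluation the SRV/PCA knowledge is rebuilt in every fold from the
*training* complexes' positive pairs only; building it once from all data
would leak the held-out complex's contact statistics into its own
features. And because negatives outnumber positives roughly 25:1 in the
synthetic world (far more in real data), the trainer keeps all negatives
by default but exposes a seeded per-complex subsampling ratio
(`negativeRatio`) for users who need balanced training sets.

## Known limitations

* The predictor is partner-agnostic: a residue pair's features do not
  depend on which other pairs are predicted positive, so cooperative
  binding effects are invisible.
* The contact definition is a single-atom distance cutoff; no solvent
  accessibility, secondary structure or docking-based filtering is
  applied, by design.
* The 20-letter alphabet excludes modified residues entirely rather than
  mapping them to parents.
* PDB parsing handles the fixed-column ATOM dialect via `bio3d`;
  mmCIF is out of scope.
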