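---
title: "Simulating crosslinking-MS restraints and scoring complex models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating crosslinking-MS restraints and scoring complex models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlcomplex)
```

## The problem

Crosslinking mass spectrometry reports residue pairs that were close
enough in the cell (or in vitro) to be bridged by a reagent of known span.
Each identified link is therefore a noisy upper bound on a Cα–Cα
distance. Used as restraints, such links can guide complex structure
prediction and model selection — but real identification lists contain
false positives at a controlled false-discovery rate (FDR), and any
pipeline that consumes links must be characterised against data whose
noise structure is known. `xlcomplex` provides that characterisation
machinery: a simulator that produces crosslink sets with known truth
labels from a structure, the soft-label encoding that feeds
restraint-aware predictors, and the scoring stack (DockQ, crosslink
satisfaction, model confidence) used to evaluate and select candidate
models.

## The simulation model

Simulation runs in four stages, independently for the inter-chain scope
and for each chain's intra scope, all driven by one seed.

**1. Candidate enumeration.** A residue pair is a candidate when one
residue is reactive for side 1 of the crosslinker and the other for side
2, both are *observable* and *accessible*, and the Cα–Cα distance is
within the reagent bound. The built-in chemistry profiles are:

| profile  | side 1     | side 2      | bound (Å) |
|----------|------------|-------------|-----------|
| SDA      | K, S, T, Y | any surface | 25        |
| DSSO     | K, S, T, Y | K, S, T, Y  | 25        |
| photo-AA | L, M       | any surface | 15        |

SDA's NHS-ester side targets Lys/Ser/Thr/Tyr while its diazirine side
photo-reacts with any surface residue. DSSO reacts primarily with Lys and
also Ser/Thr/Tyr; its distance bound is not pinned by the sources we
model, so the package defaults to 25 Å and exposes it as a parameter.
photo-AA models photo-activatable leucine/methionine analogues with a
tighter 15 Å bound.

*Observability* comes from in-silico tryptic digestion: cleavage
C-terminal to K/R except before P, peptides with up to `max_missed`
internal missed cleavages (default 2 — a crosslinked lysine itself
suppresses cleavage), and a detectability window of 5–50 residues, both
exposed as configuration. *Accessibility* comes from Shrake–Rupley SASA
(probe 1.4 Å, 960 deterministic golden-spiral points per atom) normalised
by Gly-X-Gly maximal areas (Tien et al. theoretical values); residues
with relative SASA ≥ 0.25 count as surface. The 0.25 threshold and point
count are conventional defaults and configurable; the golden-spiral point
set makes results reproducible bit for bit.

**2. Coverage subsampling.** True links are drawn uniformly without
replacement, `n_true = round(coverage × L)` with `L` the length of the
longest chain in the scope — the convention that coverage is sequence
coverage of the longer sequence. The default coverage is 10%. Uniform
subsampling deliberately ignores the lysine affinity and spatial
clustering of real data; the simulation models identification *noise*,
not acquisition bias (see Limitations).

**3. Decoy injection.** `n_decoy = max(1, round(n_true·fdr/(1−fdr)))`
decoys are drawn uniformly from pairs violating the distance bound that
contain at least one K/S/T/Y residue, so decoys/total matches the target
FDR (default 20%) exactly when the counts divide, with a floor of one
incorrect link — at least one crosslink is always wrong, so the realised
FDR of small sets can be much higher. The decoy universe does not demand
digestion observability or accessibility: a false identification does not
have to be chemically plausible, only to name a K/S/T/Y-containing pair
beyond the bound. We additionally restrict decoys to the scope of the
true links they accompany (inter decoys join inter-chain pairs), since a
scope's link list is a self-contained experiment.

**4. Link-level FDR.** The combined set is shuffled with the seed and the
link at position *i* receives `link_fdr = (decoys among 1..i)/i`, the
running incorrect fraction — so the last position always carries the
realised set-level FDR.

Rounding makes the realised decoy fraction deviate from the target by at
most about half a link per scope plus the floor; on the 300/250-residue
reference fixture (three scopes, 85 true links) that is a ceiling of
roughly 2 percentage points, and the realised value is ≈ 20.6% against
the 20% target.

## Restraint encoding

The soft-label contact map is an `N_total × N_total` symmetric matrix
over the concatenated chains in declared job order (not alphabetical; the
order is recorded in the JSON sidecar). Each link writes `1 − link_fdr`
at its cell; colliding links keep the maximum; everything else is zero.
We encode a single scalar occupancy per cell rather than a distance
distogram: the multimer-restraint formulation we target consumes one
soft-label map, and the binned variant used in monomer work is out of
scope. Residue numbers are author numbers mapped through an explicit
per-chain index table — never arithmetic on author numbers — so gapped
numbering is safe.

## Scoring

DockQ per interface is `(Fnat + 1/(1+(iRMS/1.5)²) + 1/(1+(LRMS/8.5)²))/3`.
The 1.5 Å and 8.5 Å scalings are the published DockQ constants: a plain
average of a fraction and two RMSDs would be dimensionally meaningless,
so the scaled forms are required. Conventions: contacts are cross-chain
residue pairs with any heavy-atom distance ≤ 5 Å; the iRMS interface is
defined by native contacts at 10 Å and measured on N/CA/C/O backbone
atoms after least-squares (Kabsch) superposition of the model interface
onto the native; LRMS superposes on the backbone of the *larger* chain
(by residue count, ties to the first chain) and measures the smaller.
Multi-chain complexes average DockQ over native-contacting chain pairs;
pairs without native contacts are skipped. Quality classes split at 0.23
(acceptable), 0.49 (medium, exclusive) and 0.8 (high); the first two
come from the evaluation convention we follow, the 0.8 high threshold
from the DockQ reference.

Chain correspondence between native and model is by chain id; no
chain-permutation search is attempted. Residues or atoms missing on
either side are excluded from the matched backbone (the count is
implicit in `n_atoms`), and a model lacking a linked residue counts that
link as violated rather than undefined.

Crosslink satisfaction is the fraction of (true, when labels are known)
links within the crosslinker bound in the model; noise rejection is the
fraction of decoys beyond it. Model confidence is the standard
`0.8·ipTM + 0.2·pTM` blend; ipTM/pTM are inputs, never computed here.
Selection is either confidence-descending or crosslink-first
(satisfaction, then confidence), with `model_id` as the final stable
tie-break so rankings are input-order invariant.

## Numerical choices and degenerate inputs

* Superposition uses SVD with a determinant correction, so reflections
  are never returned; fewer than 3 points or collinear point sets raise a
  degeneracy error, and chains with fewer than 3 CA-bearing residues are
  rejected for scoring.
* Altloc records resolve to the highest occupancy, ties by altloc letter
  — parsing is deterministic.
* Unknown elements fall back to a 1.8 Å van-der-Waals radius with a
  warning; unknown residue types normalise against the median reference
  area.
* An empty candidate pool still yields the one-decoy floor; an empty
  decoy universe is an error because the requested FDR cannot be
  honoured.
* Empty crosslink sets: encoding gives an all-zero map; link scoring is
  an error (satisfaction of nothing is undefined).

## What the fixtures emulate — and what they don't

`make_ideal_helix` builds ideal-geometry helices (rise 1.5 Å, twist 100°,
CA radius 2.3 Å) with N/CA/C/O and a CB proxy so heavy-atom contact
definitions are non-degenerate; `make_two_chain_complex` places two such
helices in contact; `make_decoy_ladder` produces models with growing
interface deviation and optional coordinate noise. These fixtures give
exact, closed-form-checkable geometry with buried and exposed residues
and heteromeric chain ids; digestion edge cases (KP sites, missed
cleavages) are exercised on hand-written sequences. They are *not* realistic proteins: no side chains beyond CB,
no packing, no physical interfaces. Passing tests demonstrate the
correctness of the combinatorics, geometry and bookkeeping — not that
simulated links reproduce the biases of real crosslinking-MS data
(lysine affinity, spatial clustering, abundance effects), which the
uniform-sampling model explicitly omits.

## Problem sizes used in validation

The packaged checks run the simulator 200 times (seeds varied) on a
300/250-residue two-chain fixture with the default SDA configuration to
verify the realised FDR, the coverage rule and both distance bounds, and
verify DockQ term-by-term against a grid-search/Nelder-Mead superposition
oracle and an O(N²) contact scan on ≤ 100-residue fixtures, with
rigid-motion invariance over 50 random transforms. These sizes give an
ample candidate pool (≈ 1900 inter-chain candidates, ≈ 43000 inter decoy
pairs) while keeping the whole suite under a minute of compute.

## Known limitations

* Euclidean Cα–Cα distances with a SASA filter stand in for
  solvent-accessible-surface *path* distances; buried-but-near pairs are
  slightly over-permitted.
* No nucleic acids, ligands, assembly expansion or structure repair;
  models with permuted chain ids are not re-mapped.
* Homomeric ambiguity (whether a self-link is intra- or inter-chain) is
  not resolved; links carry explicit chain ids.
* The learned projection of the soft-label map inside a predictor is out
  of scope; the scalar map is this package's documented interface.
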