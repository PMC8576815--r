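---
title: "Shortest path maps for allosteric enzyme design: methods and design choices"
author: "alloSPM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shortest path maps for allosteric enzyme design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alloSPM)
```

## The problem

Many enzymes need an allosteric partner to reach their catalytically
competent conformational state.  The β subunit of tryptophan synthase
(TrpB) is the canonical example: its COMM domain must close over the
active site, and in the modern enzyme that closure is gated by complex
formation with TrpA.  Engineering *stand-alone* activity into such a
subunit means finding the handful of residues — often far from the
active site — whose substitution shifts the open/closed conformational
equilibrium, without an exhaustive scan of the ~20^400 sequence space.

alloSPM implements a correlation-network strategy for that search,
plus the ensemble diagnostics used to screen the resulting variants:

1. **Ensemble → DCCM.**  From a conformational ensemble (multi-model
   PDB or topology + XYZ trajectory, one Cα per residue) the dynamical
   cross-correlation matrix of residue displacements is computed,
   \( C_{ij} = \langle \Delta r_i \cdot \Delta r_j \rangle /
   \sqrt{\langle \Delta r_i^2\rangle \langle \Delta r_j^2\rangle} \),
   with displacements taken from the weighted mean structure after
   rigid-body superposition.
2. **DCCM → shortest path map (SPM).**  Residues become graph nodes;
   pairs whose ensemble-mean Cα–Cα distance is below a contact cutoff
   (default 6 Å) are joined by an edge of weight \(-\ln|C_{ij}|\).
   Strongly correlated contacts are cheap to traverse, so minimum-weight
   paths trace chains of coupled contacts.  One shortest path is
   accumulated for every connected residue pair; edges are ranked by
   how many paths use them, and edges above a fraction of the maximum
   usage (default 0.3) — together with their incident residues, the
   *SPM positions* — form the map of conformationally dominant
   communication pathways.
3. **SPM → candidate mutations.**  A stand-alone *template* sequence is
   globally aligned to the allosterically dependent *target*
   (BLOSUM62, affine gaps open 10 / extend 0.5).  At every SPM
   position where the aligned residues differ, the target residue is
   proposed for substitution by the template residue, in target
   numbering (label `A56E` = target's A56 → E).  This is the funnel:
   all residues → SPM positions → the few positions that are both
   conformationally relevant and differ between the two homologs.
4. **MSA conservation banding.**  Per-column conservation of a
   multiple sequence alignment (modal-residue frequency among non-gap
   characters) bands positions as high (≥ 0.90), low (< 0.70) or
   intermediate, to flag which candidates conventional
   conservation analysis would have missed.
5. **Path collective variables and free-energy surfaces.**  Given an
   ordered open-to-closed reference path, each frame is projected onto
   progression \(s\) and path deviation \(z\)
   (\(s = \sum_i \frac{i-1}{N-1} e^{-\lambda\,MSD_i} / \sum_i
   e^{-\lambda\,MSD_i}\), \(z = -\tfrac1\lambda \ln \sum_i
   e^{-\lambda\,MSD_i}\)); a weighted 2-D histogram gives
   \(F = -kT\ln p\), and the weighted fraction of frames in the closed
   s-interval scores closed-state retention.

The package consumes ensembles produced elsewhere (plain MD,
metadynamics, anything that can be exported as frames plus optional
per-frame weights); it does not run dynamics or compute bias
potentials itself.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `cutoff` | 6.0 | Å | contact criterion on ensemble-mean Cα–Cα distance |
| `correlationFloor` | 1e-6 | — | drop edges whose \(-\ln|C|\) weight would be unusably large |
| `spmThreshold` | 0.3 | fraction of max edge usage | SPM inclusion threshold |
| `gapOpening`, `gapExtension` | 10, 0.5 | score | affine gap penalties (BLOSUM62) |
| `conservationHigh`, `conservationLow` | 0.90, 0.70 | frequency | conservation bands |
| `lambda` | \(2.3/\overline{MSD}_{\text{consec}}\) | Å⁻² | path-CV kernel width |
| `kT` | 0.596 | kcal/mol | 300 K thermal energy for the FEL |
| `bins` | 100 × 100 | — | FEL grid over the sample bounding box |
| state ranges | O [0, ⅓), PC [⅓, ⅔), C [⅔, 1] | s | basin labels on the progression axis |

The 6 Å cutoff is the conventional Cα contact distance for this
family of network methods.  The SPM threshold has no canonical value;
0.3 of the maximum usage keeps the map sparse while retaining every
edge of the planted pathway in the synthetic benchmark, and it is
exposed (`--spm-threshold`) because real systems may need tuning.
The λ heuristic makes the exponential kernels of adjacent references
overlap (weight \(e^{-2.3} \approx 0.1\) at one inter-reference MSD).

## What the synthetic generator emulates

No ensembles or sequences are distributed with the package, so every
stage is validated against seeded generators with analytic ground
truth (`syntheticEnsembleSpec()`, `makeSequences()`, `makeMsa()`,
`makeTwoBasinSamples()`).

**Ensembles.**  Sixty Cα beads by default: two arc-shaped chain lobes
joined *only* through a compact cluster of six planted-path residues
(octahedral vertex path, consecutive spacing 3.8 Å, all pairs within
5.4 Å, entries 5 Å outside the cluster), so inter-lobe communication
must traverse the planted chain.  Displacements are drawn i.i.d. per
coordinate from a multivariate normal realizing a prescribed
correlation matrix — background 0.1 everywhere, 0.9 between
consecutive planted residues, and `plantedLevel^span × 0.8` for
non-consecutive planted pairs.  The 0.8 factor keeps shortcut edges
strictly more expensive than the step-by-step chain in \(-\ln|C|\)
weight; exact geometric decay would make every route tie exactly,
because the log-weights would be additive.  Isotropic sampling makes
the ground-truth displacement DCCM equal the prescribed matrix
analytically.  When the prescribed matrix is slightly indefinite it is
repaired to the nearest positive-definite correlation matrix
(`Matrix::nearPD`); the repaired matrix *is* the reported ground truth
and the repair magnitude is returned (generation aborts if it exceeds
0.1).  At the default 20,000 frames the empirical DCCM recovers the
ground truth to a few times 0.01 per entry.

Two caveats are deliberate.  First, the generator emits frames in a
common laboratory frame, i.e. the ensemble is already superposed; the
recovery tests therefore compute the DCCM directly on the generated
coordinates.  Re-superposing would remove the global-translation-like
component that a uniform background correlation represents and bias
the background entries towards zero — the familiar observation that
rigid-body fitting reshapes correlation estimates.  Real trajectories,
which diffuse, must be superposed first (`superposeEnsemble()`), and
the SPM pipeline is robust to this: in the end-to-end tests the
planted path is recovered with or without the extra superposition.
Second, the generator plants *sensitivity*, not specificity: on a
quasi-one-dimensional chain most interior edges carry substantial path
usage, so passing tests demonstrate that planted pathways are found,
not that unrelated residues are excluded — except for the chain ends,
whose low usage is exactly why the decoy mutations planted there must
be rejected by the funnel.

**Sequences.**  The target equals the template with listed
substitutions and one insertion (default 20 residues, mirroring the
numbering shift between homologs that the alignment map must absorb).
Because the inserted segment is random, optimal alignment may slide
the gap block by a residue or two at the junction; numbering-offset
assertions therefore check positions a few residues downstream, where
the +20 offset is exact.  MSA columns draw the template residue with
the planted conservation probability, else a uniform other residue;
with 50-odd sequences the per-column modal frequency has binomial
noise of ~0.04, so recovery is asserted on means over columns sharing
a planted level, not per column.

**Two-basin samples.**  Gaussian mixtures in (s, z) centred at
(0.85, 0.30) and (0.15, 0.80) with populations 0.7/0.3 by default —
a closed-retaining variant against an open-drifting one — sized
(10,000 draws) so state fractions recover populations within the 0.03
binomial band.

## Numerical choices and degenerate inputs

* Superposition is mass-unweighted Kabsch over the selected Cα set
  (via `bio3d::fit.xyz`); "mean" mode refines the weighted mean
  structure with two mean/realign iterations.  Fewer than three
  residues is an error (rotation underdetermined).
* Weighted moments use normalized weights throughout, so rescaling all
  frame weights changes nothing; a residue whose displacement variance
  is below 1e-12 of the largest is rejected by name rather than
  propagating a 0/0.
* Shortest paths use a deterministic Dijkstra: among equal-distance
  relaxations (within 1e-12 relative) the smallest predecessor index
  wins, and the vertex scan picks the smallest index among
  minimum-distance candidates.  Identical inputs give byte-identical
  SPM results.  Whether the original formulation counts all degenerate
  equal-weight paths is not documented; counting one deterministic
  path per pair is a recorded divergence risk when comparing absolute
  usage numbers with other implementations.
* `extractSpm` keeps edges with usage > 0 and normalized usage ≥
  threshold; raising the threshold can only shrink the position set
  (tested as a monotonicity property).
* The path-CV sum is evaluated with the smallest MSD factored out
  (log-sum-exp), so distant references underflow harmlessly; z is
  clamped at 0 against rounding.  Endpoint sharpness depends on the
  reference density: with the default λ heuristic, \(s\) at the first
  reference is approximately \(e^{-2.3}/(N-1)\), so fixtures use
  N = 8 references to keep endpoints below 0.02.
* FEL bins outside the sampled region are masked (NA), never assigned
  an arbitrary large value; the occupied minimum is shifted to zero,
  which makes \(F\) exactly linear in kT (tested by doubling).
* Conservation ties for the modal residue are broken alphabetically
  (the score itself is tie-invariant); columns with > 50% gaps are
  unscored and banded "unscored" rather than low.

## Problem sizes used by the tests

The test-suite and the acceptance script regenerate everything from
seeds: a 20,000-frame × 60-residue ensemble for correlation recovery
and planted-path SPM extraction (the full pipeline variant runs at
2,000 frames, where the SPM is already stable), 50 random graphs of up
to 30 nodes against a Floyd–Warshall oracle, depth-52 alignments for
conservation recovery, and 10,000 two-basin draws.  These sizes were
chosen as the smallest at which the statistical tolerances above are
comfortably met, and they keep a full run to well under a minute
per stage on one CPU.

## Known limitations

* Edge usage counts one deterministic shortest path per pair;
  degenerate-path counting could rank near-tied edges differently.
* The conservation score is the simplest modal-frequency definition;
  published conservation figures computed with entropy- or
  similarity-weighted scores will differ in the intermediate band, and
  the band thresholds are configurable for that reason.
* Metadynamics reweighting is not implemented; per-frame weights are
  accepted as input, which is sufficient for externally reweighted
  ensembles but places the reweighting burden on the caller.
* Replica handling is left to the caller: the reader accepts a single
  ensemble, and whether replicas should be pooled before the SPM is a
  modelling decision, not a package default.
* The synthetic chain layout supports planted paths of 2–6 contiguous
  residues (the octahedral cluster); longer planted pathways would
  need a different mutually-in-contact geometry.

## A worked miniature

```{r example}
spec <- syntheticEnsembleSpec(nFrames = 2000)
syn <- makeSyntheticEnsemble(spec)
C <- computeDccm(syn$ensemble)
d <- meanDistances(syn$ensemble)
spm <- extractSpm(accumulatePaths(buildGraph(C, d)), 0.3)
spm
head(spmPositions(spm))
```

The planted consecutive-pair edges (residues 28–33) sit at the top of
the usage ranking, and the chain termini fall below the inclusion
threshold — the property the design filter relies on when it rejects
differences at conformationally irrelevant positions.
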