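---
title: "Decoy-normalized inverse virtual screening: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoy-normalized inverse virtual screening: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivscreen)
```

## The model

Inverse virtual screening docks one query compound against a panel of
protein structures and asks which structures bind it unusually well. Raw
docking affinities cannot be compared across structures: pocket size,
hydrophobicity and the scoring function's biases make some pockets
systematically "sticky". `ivscreen` normalizes each affinity by a
pocket-specific background,

$$V(s) = \frac{V_0(s)}{V_R(s)},$$

where $V_0(s)$ is the query's best-pose affinity against structure $s$
(kcal/mol, negative = binding) and $V_R(s)$ the arithmetic mean of the
best-pose affinities of a decoy set against the same structure. Because
decoys are matched to the query on molecular weight and hydrogen-bond
donor/acceptor counts but are structurally unrelated, $V_R$ estimates how
well "a molecule like the query, but not the query" scores in that pocket.
$V$ is dimensionless, comparable across structures, and $V > 1$ exactly
when the query out-scores its decoy average. The assumptions worth keeping
in mind:

* affinities are on a free-energy-like scale, so a specific-binding bonus
  is additive in kcal/mol and survives the ratio as a multiplicative lift;
* both $V_0$ and $V_R$ are negative — the implementation enforces this and
  flags violating records as invalid rather than silently keeping them;
* the decoy mean is an unweighted arithmetic mean (no outlier trimming);
  with the default 10 decoys its standard error is roughly
  $\sigma/\sqrt{10}$ of the per-docking noise, which is what makes $V$
  usable at all.

Downstream, structures with $V$ strictly above a threshold are kept,
multiple conformers of one protein are collapsed to the best-$V$
representative, per-target occurrence percentages are computed on the
pre-collapse filtered set, and rankings from several queries can be
intersected.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| decoy count | 10 | molecules | enough to stabilize $V_R$ without inflating engine time |
| MW window | ±25 | Da | property-matched decoy practice; tight enough to hold bulk size constant |
| HBD / HBA window | ±1 / ±1 | counts | same polarity class as the query |
| max Tanimoto similarity | 0.4 | — | radius-2 circular fingerprint; excludes the query's chemotype |
| V threshold | 0.9 | — | slightly below parity, so near-background binders with supportive occurrences are not lost; the filter is strictly `>` ("above"), with a flag for `>=` |
| top_k | 10 | rows | report size of the non-redundant ranking |
| box buffer | 10 | Å | search-space margin added to the site bounding box on every side |
| grid spacing | 1.0 | Å | grid-based engine convention |
| H-bond | ≤ 3.5 Å, ≥ 120° | heavy-atom distance, donor–H–acceptor angle | common interaction-diagram conventions |
| hydrophobic | ≤ 4.0 Å | apolar C–C distance | idem |
| ionic | ≤ 3.7 Å | charged-group heavy atoms | idem |
| water bridge | H-bond on both legs | — | one water simultaneously bonded to ligand and residue |

Feature conventions: molecular weight uses average atomic masses (the
conventional MW reported for compounds), while the `[M−H]⁻` m/z check uses
nominal (most-abundant-isotope) masses, matching how negative-mode ESI-MS
peaks are read. Donor/acceptor counts follow the Lipinski convention (HBD =
O–H plus N–H hydrogens, HBA = N plus O atoms), the standard reading of the
MW/HBD/HBA triple.

Decoy selection is deterministic: eligible candidates are ordered by
`|MW − MW_query|` with lexicographic `compound_id` tie-break and the first
`n` are taken. A `seed` argument exists for reproducibility metadata and
any future stochastic subsampling, but no randomness is involved today.

## Numerical and tie-break choices

* $V$ is kept at full double precision internally; tables round $V$ to 2
  decimals and percentages to 1 decimal at reporting time only. The shipped
  worked-example tables show why this matters: their $V_0$/$V_R$ inputs are
  themselves printed at 1 decimal, so re-dividing them reproduces the
  printed $V$ only within ±0.01 — 14 of the 20 rows agree exactly at
  2-decimal rounding and the remainder carry that input-rounding drift.
  The package does not force agreement beyond the print granularity.
* Ranking order is $V$ descending, ties broken by $V_0$ ascending (the
  stronger raw binder first), then `pdb_id` lexicographic. Ties are
  essentially impossible with continuous scores; the rule exists so that
  reruns and table round-trips are byte-stable.
* Target identity is the registry's `target_name`, compared
  case-insensitively with whitespace collapsed. The registry is the only
  identity source in scope, so no sequence-based grouping is attempted.
* The occurrence denominator is the compound's whole post-filter structure
  list. An alternative reading — per-target structure universe — exists;
  the package reports the former and keeps the pre-collapse table
  available so either can be derived.
* The docking box centers on the ligand bounding-box midpoint, not the
  centroid, so the configured buffer is honored symmetrically on every
  axis; `from_center` sites get a cube of half-side equal to the buffer.
  Cavity detection itself is out of scope (proprietary scoring), so a
  center or ligand coordinates must be supplied; sites reporting fewer
  than 15 site points are rejected as unusable.
* Records with missing decoy coverage get `vr = NA` and are listed as gaps
  in the run manifest; the campaign continues with a warning rather than
  failing.
* In trajectory analytics the reference frame is the first frame, the
  superposition is the least-squares rigid fit of the C-alpha selection,
  and hydrogen bonds fall back to a distance-only criterion (with a
  warning) when the structure carries no hydrogens. Per-residue fractions
  may sum above 1 across interaction types and are never clamped — that is
  the stacked-bar reading of an interactions diagram.

## What the synthetic generator emulates — and what it does not

`generate_campaign()` draws a per-structure stickiness
$\mu_s \sim N(-7, 1)$ kcal/mol, decoy affinities $N(\mu_s, 0.3)$ and query
affinities $N(\mu_s, 0.3) + \delta$, with $\delta < 0$ only on planted
(compound, target) pairs and all values rejection-resampled negative. This
captures exactly the failure mode the normalization exists for — structure-
level stickiness that would dominate a raw-affinity ranking — and the
additive specific-binding signal. It does **not** emulate real chemistry:
no correlation between decoy and query scores beyond $\mu_s$, no
heavy-tailed scoring-function artifacts, no conformer-level correlation
within a target, and no relationship between the registry's site geometry
and the scores. Passing the planted-recovery tests therefore shows the
pipeline's arithmetic and bookkeeping are right, not that any docking
engine will produce such clean signals on real proteins.

`generate_complex_trajectory()` builds a three-residue toy pocket (serine
hydroxyl donor, leucine carbon, aspartate carboxylate, plus a
water-bridged backbone oxygen) and a 5-atom ligand whose dedicated atoms
are placed inside or outside each interaction criterion per frame, so the
planted occupancy is recovered exactly by construction. Real trajectories
have correlated frames, competing contacts and marginal geometries; the
toy validates the detector's thresholds and counting, not its behavior on
ambiguous geometry.

Test and acceptance problem sizes were chosen as the package's own
realistic-but-quick study conditions: the planted-recovery study uses 500
structures over 100 target names (about 5 conformers per target, a
plausible panel redundancy), 10 planted targets at $\delta = -1.5$
kcal/mol, 10 decoys, and 100 seeds; the null-calibration check uses 200
structures; oracle cross-checks run on 1000 random tables.

## Known limitations

* No docking engine and no MD engine are wrapped; the package consumes
  their text output (engine-style pose tables, PDBQT `REMARK` affinities,
  bulk TSVs, multi-model PDB). Exhaustiveness and similar engine settings
  are campaign metadata only.
* Ligand preparation stops at feature computation: protonation-state and
  tautomer enumeration, 3D conformer generation and PDBQT conversion are
  external.
* The circular fingerprint hashes atom environments onto integers; hash
  collisions can in principle merge two environments, which would perturb a
  similarity value slightly (collisions are astronomically unlikely at the
  molecule sizes involved, and the test suite cross-checks against an
  exact environment enumeration).
* PDB files carry no formal charges, so ionic-contact detection on file
  input relies on standard charged side chains plus user-supplied ligand
  charges.
* The published occurrence percentages of the worked example are computed
  on the full panel's filtered list (3060 structures); only their top-10
  excerpt ships with the package, so those percentages are displayed, not
  recomputed.
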