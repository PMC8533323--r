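# ivscreen

Inverse virtual screening (IVS, also called reverse docking or target
fishing) turns conventional virtual screening around: instead of docking a
library of compounds into one protein, one or a few query compounds are
docked against a large panel of protein structures to rank putative
targets. Raw docking scores are a poor ranking signal because some pockets
bind almost anything; `ivscreen` implements the decoy-normalized ranking
that corrects for this, together with the analytics around it, for
computational chemists doing target identification of natural products and
other orphan bioactives.

## The statistic

For a query compound against panel structure *s*,

```
V(s) = V0(s) / VR(s)
```

where `V0` is the query's best-pose binding affinity (kcal/mol,
more-negative-is-better) and `VR` is the arithmetic mean of the best-pose
affinities of a decoy set docked into the same structure. Decoys are chosen
to match the query's molecular weight and Lipinski hydrogen-bond
donor/acceptor counts while being structurally unrelated (low circular-
fingerprint Tanimoto similarity), so `VR` measures how "sticky" the pocket
is for molecules of the query's general physicochemistry. The dimensionless
`V > 1` flags structures the query binds more strongly than its property-
matched background. Structures with `V` above a cutoff (default 0.9) are
kept; multiple crystal structures/conformers of one protein are collapsed
to the best-`V` representative ("non-redundant" ranking) with per-target
occurrence percentages; rankings from several queries can be intersected to
find shared targets.

The package covers the full campaign surface: decoy selection
(`select_decoys()`), panel registries and docking boxes (`load_panel()`,
`build_box()`), docking-engine output parsing (`parse_engine_output()`,
`read_score_table()`), normalization and ranking (`compute_v()`,
`filter_by_threshold()`, `collapse_non_redundant()`,
`intersect_rankings()`), post-hoc molecular dynamics analytics
(`occupancy_fractions()`, `protein_rmsd()`), synthetic campaign/trajectory
generators for testing (`generate_campaign()`,
`generate_complex_trajectory()`), and end-to-end orchestration (`run_ivs()`,
`run_md_report()`, plus a thin CLI at `inst/cli/ivs.R`).

## Worked example

The package ships the reported rankings of two *Gentiana lutea* root
metabolites — loganic acid and gentiopicroside — screened against a
3060-structure inflammation/cancer panel. Re-running the analysis phase on
the gentiopicroside table:

```r
library(ivscreen)
tab <- gentiana_tables("gentiopicroside")
scores <- data.frame(compound_id = "gentiopicroside", pdb_id = tab$pdb_id,
                     conformer = tab$conformer, target_name = tab$target_name,
                     v0 = tab$v0, vr = tab$vr, v = tab$v0 / tab$vr,
                     valid = TRUE)
ranking <- collapse_non_redundant(filter_by_threshold(scores, 0.9), top_k = 10)
print(ranking, digits = 3)
#>                                         target_name pdb_id conformer    v   v0
#> 1                       Alpha-1-Acid Glycoprotein 2   3apw           1.21 -8.5
#> 2                          Alpha-1-Antichymotrypsin   5om2           1.13 -8.7
#> 3                       Prostaglandin H2 Synthase-2   1ddx           1.09 -9.5
#> 4 Tumor Necrosis Factor Ligand Superfamily member 4   2hew           1.08 -9.0
#> 5                       Tyrosine-Protein Kinase BTK   6aub           1.08 -8.0
#>     vr pct
#> 1 -7.0  10
#> 2 -7.7  40
#> 3 -8.7  10
#> 4 -8.3  20
#> 5 -7.4  20
```

The ten structure-level rows collapse to five proteins; the four
alpha-1-antichymotrypsin conformers (5om2/5om3/5om7a/5om7b) reduce to the
best one, 5om2 at V = 1.13, and account for 40% of the post-filter
structures in this table. `pct` is the occurrence percentage computed on
the pre-collapse filtered set — on the full campaign's filtered set the
published percentages differ because the denominator is the whole panel
pass list, not a top-10 excerpt. Intersecting the two compounds' rankings
(`intersect_rankings()`) yields the four shared targets, including
prostaglandin H2 synthase-2 (COX-2).

The compound structures are available too, e.g. for the negative-mode
ESI-MS sanity check:

```r
nominal_deprotonated_mz(gentiana_metabolites())
#>    loganic_acid gentiopicroside
#>             375             355
```

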