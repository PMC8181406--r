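# MissenseStruct

Structural interpretation of missense mutations in a protein packed
against ribosomal RNA, built around the Diamond-Blackfan Anemia (DBA)
mutations of the 40S ribosomal protein S19 (RPS19).

Most pathogenic RPS19 missense mutations act through the protein's 3D
context: they either destabilise the fold (loss of hydrophobic core,
steric crowding of buried sites, helix-breaking proline) or disrupt the
RPS19-18S rRNA interface (loss of inter-molecular hydrogen bonds, charge
reversal on the positively charged contact patches, steric clash at the
interface).  This package implements that analysis as a tested pipeline
for structural bioinformaticians and variant curators:

* **Surface burial** — Shrake-Rupley solvent-accessible surface area with
  a deterministic golden-spiral point set;
  rSASA = SASA / maxSASA(Gly-X-Gly).
* **Interface analysis** — per-residue buried surface area
  BSA = SASA(alone) − SASA(in complex), rBSA = BSA / SASA(alone),
  geometric hydrogen-bond detection (donor-acceptor heavy-atom distance
  d ≤ 3.5 Å, D-H⋯A ≥ 120° when hydrogens are present), and lookup of the
  five conserved rRNA-contact patches I-V.
* **Ensemble flexibility** — per-residue backbone RMSF against the
  average conformation after Kabsch superposition; intrinsically
  disordered regions called as mid-chain runs with RMSF > 2 Å; DBSCAN
  conformation clustering on the pairwise backbone-RMSD matrix.
* **Mutation features and rules** — residue property deltas (Zamyatnin
  volumes, hydrophobicity, formal charge, helix and disorder propensity,
  BLOSUM62), external ΔΔG and conservation tables, and a multi-label rule
  engine assigning each mutation its structural basis (ΔΔG > 1 kcal/mol
  as the destabilisation cutoff).
* **Statistics and prediction** — one-tailed Mann-Whitney U group
  comparisons; an RBF-kernel SVM trained by exhaustively enumerating
  feature subsets (≥ 5 features) and C, γ ∈ {0.001, 0.01, 0.1, 1, 100}
  under stratified fivefold cross-validation maximising the Matthews
  correlation coefficient (MCC), then refit on all data with a monotone
  sigmoid score calibration, and applied as a full saturation scan
  (protein length × 19 substitutions, scores in [0, 1]).
* **Synthetic data** — seeded generators for toy protein-RNA complexes
  with planted contacts, jittered conformational ensembles, and labelled
  feature tables reproducing the published class medians (ΔΔG 1.55 vs
  0.106 kcal/mol; rSASA 0.13 vs 0.42; conservation −0.665 vs 0.0995), so
  every stage is testable without downloads.

## Worked example

```r
library(MissenseStruct)

# a toy protein-RNA complex with hydrogen-bonded contacts at residues 5, 9
complex <- makeToyComplex(nResidues = 12, contactPositions = c(5, 9),
                          hbondPositions = c(5, 9))
iface <- interfaceResidues(complex, "A", "B")
subset(iface, is_interface, select = c(resno, resid, bsa, rbsa))
#>   resno resid      bsa      rbsa
#> 5     5   SER 27.23292 0.3017078
#> 9     9   SER 27.34453 0.2684196

hydrogenBonds(complex, "A", "B")[, c("donor_resno", "donor_atom",
                                     "acceptor_resno", "distance")]
#>   donor_resno donor_atom acceptor_resno distance
#> 1           5         OG           1005 2.853102
#> 2           9         OG           1009 2.874425
```

The two planted contact residues (and only those) are flagged, each
burying ~27 Å² against the RNA chain and donating one hydrogen bond from
its serine hydroxyl to a phosphate oxygen at ~2.9 Å.

```r
# a labelled feature table at the published class medians, n = 29/30
tab <- makeFeatureTable(nPositive = 29, nNegative = 30, seed = 1)
cmp <- mannWhitneyOneTailed(tab$ddg[tab$label == "dba"],
                            tab$ddg[tab$label == "neutral"], "greater")
unlist(cmp[c("median_x", "median_y", "p_value")])
#>  median_x  median_y   p_value
#>  1.55e+00  1.06e-01  6.77e-11

sel <- selectFeaturesAndHyperparams(
  tab, trainingConfig(c("ddg", "rsasa", "conservation", "d_charge",
                        "d_helix", "blosum62"), min_features = 5,
                      seed = 1))
sel[c("features", "C", "gamma", "cv_mcc")]
#> $features: "ddg" "rsasa" "conservation" "d_charge" "d_helix"
#> $C: 100        $gamma: 0.1        $cv_mcc: 0.8987348
```

Disease-class ΔΔG values sit far above the neutral class (medians 1.55
vs 0.106 kcal/mol, one-tailed p ≈ 7e-11), and the selection protocol
finds a five-feature subset whose cross-validated MCC is ~0.9 on this
synthetic table.

For a full run (interface + features + classification + statistics from
a YAML config) see `?runPipeline`.

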