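---
title: "Methods: structural basis analysis of missense mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural basis analysis of missense mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models, the
tunable parameters and their defaults, the numerical choices, what the
synthetic-data generators do and do not emulate, and the known
limitations.  The motivating system is ribosomal protein S19 (RPS19), a
145-residue component of the 40S subunit that contacts the 18S rRNA
through five conserved, positively charged surface patches; missense
mutations in RPS19 are the most frequent cause of Diamond-Blackfan
Anemia (DBA), a dominantly inherited red-cell aplasia driven by
ribosomal-protein haploinsufficiency.

## Coordinates and conventions

Structures are read from PDB or mmCIF through bio3d into a uniform
atom table (`StructureModel`); multi-model files become
`StructureEnsemble` objects whose models must share residue and atom
topology.  Author numbering is used everywhere, matching how individual
residues (Gly127, Trp52, ...) are cited in the literature; mutation
positions are 1-based on the canonical protein sequence and a
chain-to-canonical offset (identity by default) reconciles the two.
Alternate locations are reduced to the highest-occupancy conformer so
all downstream geometry sees a single conformer.  Hydrogens are kept
when present but never required: cryo-EM models are heavy-atom only, and
every geometric criterion below has a heavy-atom form.

## Solvent accessibility

`shrakeRupley()` implements the classic rolling-probe point-sampling
method.  Each atom's van der Waals sphere is inflated by the probe
radius (water, 1.4 Å) and covered with `nPoints = 960` test points from
a deterministic golden-spiral generator — reproducibility without random
seeds, which matters because SASA feeds every interface quantity.  Per
atom, `SASA = exposed/total × 4π(r + probe)²`.  The element radius
table is Bondi-style (C 1.70, N 1.55, O 1.52, S/P 1.80 Å, ...); unknown
elements either error or take a configurable default with a warning.
The tests hold the implementation to within 2% of an independent
Monte-Carlo surface-point oracle on small systems.

Relative SASA divides a residue's SASA by its maximum in an extended
Gly-X-Gly tripeptide context, using the theoretical maxima of Tien et
al. (2013) shipped as a constant table, so rSASA values are bit-stable
across platforms.  Values slightly above 1 are legitimate (conformation
more exposed than the reference) and are kept unless clamping is
requested.  Note a dialect caveat: DSSP-derived SASA differs slightly
from Shrake-Rupley, so published rSASA values for individual residues
are matched to about ±0.03 absolute rather than exactly.

## Interface analysis

A residue is an interface residue when its buried surface area
`BSA = SASA(subject chain alone) − SASA(subject in the subject+partner
complex)` exceeds `bsa_threshold = 0.1 Å²`.  This ΔSASA criterion is the
standard reproducible proxy for interface membership; tools built on
surface complementarity (e.g. PISA) use additional undocumented internal
cutoffs, so interface *counts* against published tables are calibration
targets with a tolerance, not exact invariants.

Hydrogen bonds are detected geometrically over heavy atoms: every
donor-acceptor pair across the two chain groups with distance
`d ≤ d_max = 3.5 Å` counts, and when explicit hydrogens are bonded to
the donor the best D-H⋯A angle must be at least `angle_min = 120°`.
Donor/acceptor typing uses standard role tables: protein backbone N
(donor) and O/OXT (acceptor) plus side-chain roles per residue type, and
for RNA the phosphate and ribose oxygens as acceptors with the 2′-OH as
both donor and acceptor, plus the base-specific ring nitrogens and
carbonyl oxygens.  No energy function is used — with cryo-EM heavy-atom
coordinates a geometric criterion is as far as the data support.  The
published count of 46 inter-molecular bonds at the RPS19-18S rRNA
interface is therefore treated as criteria-calibrated: `d_max` and
`angle_min` are exposed knobs and the acceptance check allows a
tolerance band.

The five conserved patch definitions (patch I-V: the rRNA helix elements
h42, h41, h42+h43, h41es10, h39es9 with their protein residue sets and
nucleotide ranges) are shipped as an exact constant transcription;
`assignPatch()` is a pure lookup.

## Ensemble flexibility

`backboneRmsf()` superposes every model's backbone (N, CA, C, O) onto
the average conformation by Kabsch least squares, re-averaging until the
reference is self-consistent, and reports per-residue RMSF as the root
mean square deviation of the residue's backbone atoms from the
reference.  RMSF is invariant to global rigid-body motion of the
ensemble (tested).  Intrinsically disordered regions are maximal
mid-chain runs with RMSF above `rmsf_threshold = 2.0 Å`; the chain
termini are excluded so terminal fraying is not reported as disorder.

Conformation clustering runs DBSCAN on the pairwise backbone-RMSD matrix
(each pair superposed before the RMSD is taken) with the RMSD cutoff
(2 Å) as the neighbourhood radius.  `min_points = 4` is our choice — the
clustering literature's default of 4-5 is noise-robust yet workable for
small ensembles — and is configurable.  DBSCAN itself is implemented in
the package (no suitable dependency was available); cluster
representatives are medoids and occupancies are member counts over the
total, so noise models leave the occupancies summing below 1.

Eight-state secondary-structure strings simplify positionwise to three
states: G/H/I → H, B/E → E, T/S/C and blank → C.  The package does not
assign secondary structure from geometry; an external DSSP-format string
is accepted, and helix intervals for the rule engine are supplied by the
user for the same reason.

## Residue properties

All scales ship as constants in `propertyTables()` and every function
takes the table as an argument, so any scale can be swapped:

* **Volume**: Zamyatnin residue volumes (Gly 60.1, Arg 173.4, Glu
  138.4 Å³, ...) — the only common table consistent with the volume
  changes quoted for the Gly127 substitutions (+188.52% and +130.28%).
  One caveat: the +134% sometimes quoted for Ser59Phe is not consistent
  with this table (which gives +113%); the discrepancy is documented
  rather than reconciled, and no rule threshold depends on it.
* **Hydrophobicity**: Kyte-Doolittle by default.  Sign-level behaviour
  (does the site get less hydrophobic?) is robust across standard
  scales; exact percentage reproduction of literature values is not
  attempted because the original scale there is not identifiable.
  Because the scale crosses zero, percent change is taken against the
  magnitude of the wild-type value.
* **Formal charge**: K/R +1, D/E −1, His +0.5 by default (configurable;
  His titrates near physiological pH), all others 0.
* **Helix propensity**: Pace-Scholtz free-energy scale (Ala 0, Pro 3.16
  kcal/mol); Δhelix = propensity(mut) − propensity(wt).
* **Disorder propensity**: a TOP-IDP-style scale; Δdisorder defined the
  same way.
* **BLOSUM62**: the standard integer matrix, cross-checked against the
  Biostrings copy in the tests.

## Mutation curation

`parseProteinMutation()` accepts three-letter and one-letter notation.
Dataset curation follows two explicit rules.  Positives (disease) must
meet at least one of: more than one reported patient; a
Pathogenic/Likely-pathogenic annotation; experimental functional
confirmation.  Negatives come from population variants: for an
autosomal-dominant disease with prevalence p and gene fraction f, the
pathogenic allele frequency is at most p·f/2 (heterozygous carriers are
affected), which for p = 5-7 per million and f = 0.25 gives
6.25×10⁻⁷-8.75×10⁻⁷; a variant is accepted as presumed-neutral when its
allele frequency is at least one order of magnitude above the upper
bound (we interpret "one order above" against the upper bound — the
conservative reading) and it is not on the explicit disease-mutation
exclusion list.  cDNA-level notation is out of scope; curation operates
on protein changes.

## Feature extraction

The per-mutation feature vector has 8 core features — BSA, rBSA, HB_Num,
Δcharge, ΔΔG, Δhelix, BLOSUM62, Δdisorder — plus 10 additional
candidates (rSASA, Δvolume%, Δhydrophobicity%, conservation, in-patch
flag, proline-substitution flag, wild-type/mutant volume and
hydrophobicity) filling an 18-feature pool over which selection can
run.  The 8 core features are the authoritative set; the additional ten
are plausible structural/conservation candidates chosen by us so the
selection procedure is exercisable end-to-end, since the original
candidate list beyond the selected eight is not public.

ΔΔG (FoldX-style) and conservation (Consurf-style normalised scores) are
consumed as input tables — the package does not re-implement a
force field or an evolutionary-rate model.  Missing values stay `NA` and
are surfaced, never silently zeroed.  A deliberately simple surrogate
ΔΔG estimator (burial-weighted hydrophobicity loss plus a volume-clash
term) is provided for synthetic tests only and is documented as
non-physical.

## The structural-basis rule engine

Each mutation gets a multi-label basis:

* `destabilizing` ⇔ ΔΔG > 1 kcal/mol (the standard destabilisation
  cutoff), `NA` when no ΔΔG is available.
* `hydrophobic_core_loss`: buried site (rSASA < 0.2) whose
  hydrophobicity decreases, from a typical hydrophobic wild type
  (L/W/V/F) *or* where a charged side chain enters the core.  The
  second arm covers substitutions like Gly→Arg at a fully buried site,
  which damage the core both sterically and by burying charge.
* `steric_core_clash`: buried Gly/Ala replaced by a residue ≥ 30%
  larger.
* `helix_break_proline`: substitution to Pro inside a helix — flagged
  even when the supplied ΔΔG is at or below the cutoff, because
  force-field ΔΔG estimates for proline substitutions are known to be
  unreliable.
* `hbond_loss`: the site makes ≥ 1 inter-molecular hydrogen bond and the
  mutant loses the wild type's side-chain donor/acceptor class or
  changes side-chain reach by ≥ 2 heavy atoms (a proxy for "the bonding
  atom can no longer reach", since mutant side chains are not
  re-modelled).
* `electrostatic_alteration`: patch residue with Δcharge ≤ −1.
* `steric_interface_clash`: interface residue replaced by a residue
  ≥ 30% larger.

The burial cutoff (0.2) and steric cutoff (+30%) are our thresholds:
destabilising disease mutations cluster at much lower rSASA (median
~0.06) so 0.2 separates core from surface with margin, and +30% admits
the documented interface-clash examples (Thr55Met ≈ +40%, Ser59Phe
≈ +113%) while excluding near-isosteric swaps.  Both are configurable
and echoed into every report.  The engine never fails: a mutation with
no triggered rule returns an empty basis with a note, reflecting that
rule-based reasoning cannot cover every mutation.

## Statistics

Group comparisons use the one-tailed Mann-Whitney U test as provided by
`stats::wilcox.test`: exact for small tie-free samples, otherwise the
normal approximation with tie correction and continuity correction
(continuity correction is applied as the standard choice for one-tailed
tests).  Medians of even-sized samples are the mean of the central pair.
No multiple-testing correction is applied, matching the analysis the
package reproduces.  Classifier metrics (ACC, F1, MCC, FPR) follow the
standard confusion-matrix definitions with MCC defined as 0 when any
marginal is empty.

## The predictor protocol

Feature subsets of size ≥ 5 are enumerated exhaustively together with
C, γ ∈ {0.001, 0.01, 0.1, 1, 100}; each candidate is scored by
stratified fivefold cross-validation, and the maximum cross-validated
MCC wins.  Design choices where the protocol is underspecified:

* **Stratification and seed**: folds are stratified and fixed by a seed
  — with ~29/30 class balance an unstratified split can empty a class
  in a fold.
* **Scaling**: features are z-scored *inside* each training fold and
  applied to the held-out fold, never fitted on the full table; a
  regression test verifies that the honest CV does not reproduce the
  inflated resubstitution performance on pure-noise features.
* **Objective**: the pooled-confusion MCC over held-out predictions is
  the selection objective; per-fold MCCs and the pooled count of
  correctly predicted positives are also reported, since pooled and
  fold-averaged summaries can differ.
* **Ties**: equal-MCC optima resolve deterministically to fewer
  features, then smaller C, then smaller γ, then enumeration order.
* **Budget**: a full 18-feature enumeration is ~260k subsets × 25 grid
  points × 5 folds; the selection function guards this behind an
  explicit fit budget (default 10⁶) with `force = TRUE` to override.
  The examples and tests use 6-10 candidate pools.
* **Calibration**: the final model is refit on the full table and its
  decision values are mapped onto [0, 1] by a Platt-style sigmoid fitted
  deterministically in the package (the libsvm-internal probability
  machinery uses a randomised internal CV, which would break
  reproducibility).
* **No nested CV**: hyper-parameters and features are selected on the
  same cross-validation used to report CV performance, mirroring the
  original protocol; the resulting optimistic bias on CV numbers is
  acknowledged here — the independent check is a held-out set.

The saturation scan applies the final model to every (position,
substitution) pair of a sequence through a user-supplied featureizer,
yielding length × 19 scores in [0, 1].

## Synthetic data: what it does and does not show

The generators make every pipeline stage testable offline:

* `makeToyComplex()` plants serine-to-phosphate contacts at chosen
  residues of an ideal helix (donor-acceptor pairs at 2.9 ± 0.1 Å, all
  other residues ≥ ~8 Å from the RNA), so interface and hydrogen-bond
  detection have exact planted ground truth.  The pseudo-RNA uses a
  reduced atom set (P, OP1, OP2, O5′, C1′) — enough for donor/acceptor
  typing, with no real nucleotide geometry.
* `makeEnsemble()` jitters an ideal helix with per-region Gaussian noise
  (rigid 0.3 Å, floppy 2.5 Å per coordinate), so floppy-region RMSF has
  the analytic expectation σ√3 and interval recovery can be required to
  be exact.
* `makeFeatureTable()` samples class-labelled feature tables around the
  published class medians (ΔΔG 1.55 vs 0.106 kcal/mol, log-normal for
  the disease class and normal for the neutral class; rSASA 0.13 vs
  0.42, beta; conservation −0.665 vs 0.0995, normal), with the disease
  class enriched for Arg/Leu/Gly/Ala wild types and for substitutions to
  proline (29.4%), and the table-driven deltas computed from the real
  property tables.  Only the medians are published constraints; the
  dispersions and the interface-feature distributions are our choices.
  Because sample medians of skewed distributions drift at n ≈ 50, each
  class is recentred after sampling (multiplicatively for the
  log-normal, additively for the normal, bounded for the beta) so the
  class medians are reproduced at any n.

Passing tests on these generators demonstrate correctness of the
geometry, the statistics and the training protocol under planted ground
truth.  They do *not* demonstrate performance on real data: real feature
distributions are correlated (burial anti-correlates with interface
membership; conservation correlates with both), real interfaces are not
ideal helices, and real ΔΔG values carry force-field error.  Claims
about the real protein require the external inputs below.

## Reproducing the structure-derived numbers

Two groups of published quantities need inputs the package cannot
redistribute:

1. **Interface statistics** (75 interface residues ≈ 51.7% of the
   protein, 46 inter-molecular hydrogen bonds, rSASA(Trp52) ≈ 0.067,
   rSASA(Gly120) ≈ 0.135): download the deposited human 40S ribosome
   coordinates (PDB entry 6G5H) as mmCIF, place them at
   `inst/extdata/external/6g5h.cif`, and record the chain identifiers in
   `inst/extdata/external/6g5h_chains.txt` (two tab-separated lines:
   `subject <chain>` for the S19 chain, `rrna <chain>` for the 18S
   rRNA).  The entry does not label chains in its text files uniformly
   across mirrors, so the chain map is deliberately an input.
2. **Curated-list composition** (15/51 substitutions to Pro, 10/51 Arg
   wild types, 24/51 in patches I-V): transcribe the curated disease
   mutation list into `inst/extdata/external/dba_mutations.tsv`
   (columns `position`, `wt`, `mut`).

With those files in place, the corresponding acceptance tests run the
full pipeline (interface detection at the default thresholds,
hydrogen-bond detection at d_max = 3.5 Å, packed-context rSASA) and
compare against the published values with the tolerances stated above.
Headline classifier numbers (26/29 cross-validated positives, 8%
held-out false-positive rate, C = 100, γ = 0.01) additionally require
the original ΔΔG and conservation tables and are therefore documented
as this recipe rather than asserted; the confusion-matrix arithmetic
behind the 8% rate is unit-tested.

## Problem sizes and runtime

The shipped tests run at desk scale by design: ensembles of 200-500
models of 20-60 residues for the flexibility checks, toy complexes of
10-15 residues, feature tables of 59-81 mutations, 100-seed
Mann-Whitney power sweeps, and selection demos over 6 candidate features
(875 SVM fits).  The full suite completes in well under a minute on one
CPU; the full 18-feature enumeration is available behind the fit-budget
flag for users who want it.

## Known limitations

* Mutant side chains are never re-modelled; hydrogen-bond loss and
  steric rules are class- and size-based proxies.
* SASA is Shrake-Rupley, not DSSP; small systematic differences against
  DSSP-derived rSASA are expected (±0.03 guidance above).
* The interface criterion is ΔSASA-based; counts from
  complementarity-based tools will differ at the margins.
* No molecular dynamics, no force field, no evolutionary-rate model:
  ensembles, ΔΔG and conservation are inputs.
* The CV protocol is not nested; reported CV MCC is optimistic by
  construction.
* Intra-molecular effects (e.g. a mutation rigidifying a disordered
  region through a new internal hydrogen bond) are recorded as notes,
  not rules.
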