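---
title: "Methods: from somatic variants to validated tumor-rejection neoepitopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from somatic variants to validated tumor-rejection neoepitopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoms)
```

neoms implements the computational core of a mass-spectrometry-driven
neoepitope discovery study in a syngeneic mouse tumor model: somatic
amino-acid substitutions define a mutant search space, MHC class I eluted
peptides are filtered and cross-referenced against it, candidate
neoepitopes are confirmed by heavy/light targeted MS logic, their in vivo
activity is scored from tumor growth curves, and structural metrics
characterize how a mutation changes the peptide as presented to T cells.
This vignette explains each model, its assumptions, and the choices made
where the design was genuinely open.

## Mutant search space

Each somatic single-nucleotide variant is consumed at protein coordinates
(protein id, 1-based position, reference and alternate residue). The
stated reference residue must match the proteome; a mismatch is a hard
error rather than a silent skip, because silently dropped variants distort
the size of the search space against which the target-decoy FDR is later
estimated. Proteins containing nonstandard residue codes (U, X, B, Z) are
excluded from window building with a warning.

Around each substitution a window of up to `2 * flank + 1` residues is
cut from the mutated protein. The default `flank = 15` gives 31-mer
windows — long enough that every 8-11-mer containing the mutation is a
substring of the window — truncated only at protein termini. Candidate
epitopes are exactly the mutation-covering k-mers (k = 8-11 by default),
each paired with the same-coordinates wild-type k-mer, which differs at
exactly one position by construction. An interior mutation therefore
yields k candidates per length; a terminal one yields
min(k, distance to terminus + 1).

The search database concatenates the reference proteome with one FASTA
record per long peptide (header `neo|<protein_id>|p.<ref><pos><alt>`).
Duplicate windows arising from distinct variants are kept as distinct
records so provenance survives; exact-duplicate candidate peptides are
collapsed only in reports.

## Motif scoring and DAI

True binding-affinity prediction is delegated: externally computed IC50
values enter through a TSV interface (`read_ic50()`). What the package
ships is a transparent position-weight-matrix layer for the BALB/c
alleles, sufficient to assign a plausible presenting allele to a peptide:
H-2 Kd (P2 Tyr/Phe, C terminus Leu/Ile/Val), Dd (P2 Gly, P3 Pro, a
permissive P5 secondary anchor, C terminus Leu/Ile/Phe), and Ld (P2 Pro,
C terminus Phe/Leu/Met). The tables live in `inst/extdata/motifs.yaml` as
log-odds weights and can be edited without touching code. A peptide is
assigned the best-scoring allele only when that score clears the motif's
acceptance floor (default 0) and beats the runner-up by a margin (default
1 log-odds unit); ties are never assigned.

The Differential Agretopic Index is fixed as

$$\mathrm{DAI} = \ln \mathrm{IC50}_{wt} - \ln \mathrm{IC50}_{mut},$$

so a mutation that improves binding (lower mutant IC50) scores positive.
Affinity tiers use half-open intervals on IC50 (nM): strong < 50,
intermediate [50, 500), weak [500, 5000), very weak >= 5000; the
cutpoints are arguments, not constants.

## Immunopeptidome filtering and normalization

PSM lists arrive with scores and decoy flags; the package estimates the
peptide-level FDR by target-decoy counting. The retained set is the
targets at or above the smallest score threshold t\* satisfying
`#{decoys >= t} / #{targets >= t} <= fdr` (default 0.05), with the
threshold scanned over the union of observed scores and score ties
retained together. The retained set is monotone in the FDR level.
Peptide length is restricted to 8-25 residues inclusive.

Intensities are log2-transformed (a flag disables the transform for
pre-logged input), median-centered, and scaled asymmetrically: residuals
above the median are divided by `q3 - q2`, residuals below by `q2 - q1`,
with quartiles computed by linear interpolation on the sorted values
(R's type-7 convention, stated explicitly because the upstream
description names no convention). The map sends any value at the median
to 0, q1 to -1, and q3 to +1. One bookkeeping subtlety: when the output
vector's own quantiles are recomputed, q1 and q3 are exactly -1 and +1
for every input (interpolation happens within one arm of the piecewise
map), while the interpolated median is exactly 0 only when the median is
a sample point (odd n); the property tests are written accordingly.
Constant input (q3 = q2 or q2 = q1) is a degenerate-spread error; missing
intensities pass through as missing.

A retained peptide is called a neoepitope iff it is a substring of some
long peptide with its span covering the mutated offset, **and** it occurs
nowhere in the reference proteome as an exact substring. The second
condition matters: a mutation-covering k-mer can coincidentally occur
elsewhere in the proteome, and such a peptide is not tumor-specific; it
is reported (`in_reference = TRUE`) but never flagged. A corollary tested
explicitly is that wild-type counterpart sequences are never flagged.

## PRM co-elution validation

Validation follows the heavy/light spike-in design: a synthetic peptide
carrying a uniformly 13C/15N-labeled residue co-elutes with its
endogenous light counterpart while fragment ions that span the labeled
residue are offset by exactly the label delta divided by the charge.
Monoisotopic masses are used throughout (proton 1.007276 Da, water
18.010565 Da); the shipped label table covers K, R, L, P, V, F and
arbitrary labels are accepted. Fragment chromatograms are extracted by
summing signal within ±0.02 m/z of the target.

Co-elution is scored per fragment as the Pearson correlation of the light
and heavy traces after linear interpolation onto the union of their time
points (the gridding is this package's choice; the source description is
silent on it). The channel apexes come from the summed traces, and the
spectral contrast is the normalized dot product of the per-fragment
intensity vectors read at the two apexes. A pair is validated iff at
least `min_fragments` (3) fragments reach `r >= r_min` (0.9), the apex
difference is at most `max_apex_dt` (0.2 min), and the contrast is at
least 0.9. These defaults are conventional targeted-proteomics practice,
not published constants, and all are arguments; relaxing any threshold
can never turn a validated pair into a rejected one. The
light-contamination QC on a heavy-only run passes when the light-channel
maximum is at most 1% of the heavy apex.

## Tumor Control Index

Tumor growth is recorded as the average of two perpendicular diameters
per mouse per day. The Tumor Control Index used here is a concrete
parameterization of the published concept — three 0-10 components summing
to at most 30 — whose exact component formulas are not printed anywhere;
the formulas below are therefore this package's documented convention,
validated by the maximum-30 bound, the component monotonicities, and the
anchor cases in the test suite.

* **Rejection (0 or 10).** 10 iff the tumor is undetectable (diameter
  below the 1 mm detection floor) at the final observation and has
  remained undetectable ever since the first undetectable day *after*
  the tumor first became measurable. The qualifier matters: every curve
  is undetectable on the challenge day, so anchoring durability at the
  first undetectable day of the whole series would deny a perfect score
  to any mouse whose tumor grew and then durably regressed. A tumor that
  never becomes measurable also scores 10.
* **Inhibition (0-10).** `10 * clamp(1 - AUC / AUC_control, 0, 1)` with
  trapezoidal AUCs on the control day grid; linear in the AUC reduction,
  so a curve at half the control diameter everywhere scores exactly 5.
* **Stability (0-10).** 10 times the fraction of observation days with
  diameter within ±20% of the diameter on the day the tumor first became
  measurable, or undetectable.

Curves are linearly interpolated onto the control-mean day grid,
restricted to each mouse's observed range, so early-euthanasia curves
contribute only over observed days (flagged `truncated`). Group TCI
comparisons use one-way ANOVA with Dunnett's many-to-one follow-up
against the control; AUC comparisons use Tukey's all-pairs follow-up;
both report adjusted p-values. Plain contrasts use the pooled-variance
two-tailed t test.

## Structural metrics

Peptide-MHC models (from any modeling pipeline; model generation is out
of scope) are consumed as standard PDB files, first model only, waters
dropped. Before comparison, the mutant model is least-squares superposed
onto the wild type using only the shared MHC-chain backbone atoms — the
peptide takes no part in the fit — so the reported peptide RMSD (backbone
N/CA/C/O, or all heavy atoms shared by both residue types at each
position) measures conformational change within the groove frame, not
rigid motion of the complex.

Solvent-accessible surface area uses the Shrake-Rupley construction: 960
near-uniform points (golden-spiral) on each atom's probe-expanded sphere,
probe 1.4 Å, radii C 1.70 / N 1.55 / O 1.52 / S 1.80 Å (a documented,
configurable table; the source prints no radii). The isolated-sphere area
is within 1% of the analytic `4*pi*(r + 1.4)^2` at this point count. The
exposed hydrophobic surface of the peptide is the summed SASA, computed
in the full-complex context, of its apolar atoms — carbon or sulfur not
covalently bonded to nitrogen or oxygen, bonds inferred from heavy-atom
distances below 1.9 Å. This operational definition is stated because the
quantity is widely reported but rarely defined; the headline published
comparison (111 to 139 Å², a 25% increase) is reproduced by the relative
change arithmetic, not by re-deriving the absolute areas, which depend on
the stochastic upstream models. Salt bridges pair basic side-chain
nitrogens (Arg NH1/NH2/NE, Lys NZ, optionally His) with acidic side-chain
oxygens (Asp OD1/OD2, Glu OE1/OE2, optionally the C-terminal OXT) at a
4.0 Å cutoff, one record per residue pair at the minimum atom distance.

## Synthetic data: what it does and does not show

Because the underlying study deposits no raw data, every input class is
generated (`sim_config()` and the `gen_*` family), with one master seed
fanned out to independent per-generator streams so that changing one
generator never perturbs another. The defaults are the study conditions
at desk scale: a 30-protein toy proteome (100-400 residues, uniform
residue usage), 40 variants, PSM lists of 300 reference targets + 300
reversed-sequence decoys with well-separated Gaussian score
distributions (means 30 vs 12, sd 5) and log-normal intensities, 8
planted mutation-covering 9-mers, Gaussian co-eluting fragment peaks
(width 0.08 min, 0.5% relative noise), logistic tumor growth to 15 mm
over ~24 days with measurements every 3 days and 8 mice per group, and
idealized extended-peptide coordinate sets.

The generators emulate the *statistical structure* the pipeline assumes —
separated target/decoy scores, co-elution geometry, rejection /
stabilization / progression phenotypes — not the physics that produces
it. No chromatographic tailing, isotope envelopes, interference, missing
values, cage effects, or realistic residue composition are simulated, and
the toy peptide-MHC geometry is an extended chain in a schematic groove,
not a folded structure. Passing tests therefore demonstrate correctness
of the computations under their stated models, not performance on real
instrument data.

## Numerical choices and degenerate inputs

* Quartiles: type-7 linear interpolation everywhere.
* FDR threshold scan: union of observed scores, ties retained; an
  all-decoy input is an error; when no threshold qualifies, the retained
  set is empty.
* Co-elution: all-zero or constant traces have undefined correlation and
  are excluded with a warning; apex of an all-zero channel makes the
  apex difference infinite (never validated).
* Allele assignment: exact ties resolve to "unassigned" regardless of
  margin.
* ANOVA follow-ups refuse near-zero residual variance
  (`sigma < sqrt(eps) * scale`).
* Problem sizes in the test suite (1,000 random PSM sets, 500 random
  peptides for fragment-mass additivity, 1,000-replicate Dunnett null
  simulation with 4 groups of 8, 2,000-replicate t-test null) were chosen
  to make the Monte-Carlo bands (family-wise error 0.05 ± 0.02, type-I
  0.05 ± 0.015) informative while keeping the default suite under a
  minute on one CPU.

## Known limitations

The motif layer is a stand-in for real affinity predictors and should
not be used to rank candidates when measured or predicted IC50s are
available; the TCI parameterization is one defensible instantiation of a
concept whose reference formulas are not public; the co-elution
acceptance rule is conventional rather than derived; and absolute SASA
values depend on the radius table and the hydrophobic-atom rule, so only
relative comparisons between models processed identically are
meaningful.
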