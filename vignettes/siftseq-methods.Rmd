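---
title: "Methods: stimulation-paired TCR reactivity analysis with siftseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulation-paired TCR reactivity analysis with siftseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siftseq)
```

## The problem

A public neoantigen — a tumor-specific peptide arising from a recurrent
driver hotspot mutation presented by a prevalent HLA allele — can be
targeted with T cell receptors (TCRs) shared across many patients. Finding
such TCRs requires distinguishing, among thousands of T cell clonotypes in a
sensitized culture, the few that are activated by the *mutant* antigen but
not its wild-type counterpart. siftseq implements the computational half of
that discovery workflow: matched aliquots of the same T cell pool are
stimulated with mutant (MUT) or wild-type (WT) antigen, profiled by combined
single-cell RNA + V(D)J sequencing, and each clonotype is scored for
stimulation-specific induction of an activation readout gene (IFNG by
default). The package also implements the companion procedures such a study
runs before and after the single-cell screen: the qPCR delta-Ct screen that
nominates candidate wells, recognition-motif derivation from substitution
scans with a proteome cross-reactivity search, cancer-cell-fraction (CCF)
clonality for the target mutation, a simplified allele-specific HLA
loss-of-heterozygosity (LOH) caller, and rigid-body peptide C-alpha RMSD for
comparing bound-peptide conformations.

## The core statistic

For clonotype $c$ with cells in both stimulation aliquots, let
$\bar e_{c,\mathrm{MUT}}$ and $\bar e_{c,\mathrm{WT}}$ be the mean
library-normalized target-gene expression over the clonotype's cells in each
aliquot. The response statistic is

$$
\mathrm{log_2 ratio}(c) \;=\;
\log_2 \frac{\bar e_{c,\mathrm{MUT}} + \varepsilon}
            {\bar e_{c,\mathrm{WT}} + \varepsilon},
\qquad \varepsilon = 0.1 .
$$

Counts are scaled to a common library size (10,000 by default) and
log1p-transformed. The *means in the ratio are taken on the linear
normalized scale*: the statistic is a fold change of transcript abundance,
and averaging log-transformed values instead would compress a genuine
8-fold induction to roughly 2.4-fold at these expression levels. The
per-cell *tests* run on the log scale, where the t-statistic is better
calibrated — the same split used by standard single-cell toolkits.

Clonotypes with a fold ratio of at least 2 are tested with a two-sided
Welch (unequal-variance) t-test comparing per-cell target expression
between the clonotype's MUT and WT cells; a clonotype is a *candidate* when
tested and $p < 0.05$. No multiplicity correction is applied across
clonotypes at this step (raw Welch p-values are reported, matching how such
screens report per-clonotype significance); the per-gene volcano within one
clonotype (`clonotype_de()`) does use Benjamini–Hochberg adjustment, since
there every expressed gene is tested.

Evaluability requires at least 3 cells per condition — the smallest group
size for which the Welch test has a variance estimate with any redundancy.
Clonotypes failing this are carried in the output with an undefined ratio.

HLA-class restriction is predicted from lineage markers: CD3E must be
detected in at least half the clonotype's cells (else the call is
INDETERMINATE); then per-cell CD8A vs CD4 expression is compared with a
two-sided Student t-test — CD8-dominant clonotypes are predicted HLA class
I restricted, CD4-dominant ones class II. A marker gene removed by the
low-detection gene filter is treated as uniformly zero rather than an
error.

## Quality control

The filters and their thresholds, applied in this order with each cell
attributed to the first rule that removes it:

| rule | default | boundary reading |
|---|---|---|
| gene detected in < 3 cells | remove gene | exactly 3 cells: keep |
| cell with < 200 detected genes | remove cell | exactly 200: keep |
| mitochondrial fraction > 15% | remove cell | exactly 15%: keep |
| cell with > 7,000 detected genes | remove cell | doublet/multiplet proxy |
| cell without clonotype information | remove cell | |
| cell with > 2 TRA or > 2 TRB contigs | remove cell | exactly 2 TRA: keep |

Boundaries are read strictly ("fewer than", "more than"); all thresholds
are arguments. Mitochondrial genes are identified by the `MT-` name prefix
(case-insensitive). Because removing cells can push further genes under the
min-cells rule, `run_qc()` repeats the cascade until nothing changes; this
makes the full QC exactly idempotent while preserving per-pass order and
attribution. UMI counts stand in for "read counts" in the mitochondrial
rule, as is standard for droplet data.

## The qPCR screen

Per well, $\Delta C_t = C_t^{WT} - C_t^{MUT}$, so a positive value means
more IFNG transcript under MUT stimulation (each cycle is ~2-fold). A well
is a hit when its $\Delta C_t$ is positive and at least $k = 2$ sample
standard deviations above the plate mean. The mean and sd include the
candidate well by default (the natural reading of "2 s.d. from the mean");
a leave-one-out variant is exposed for small plates where a strong hit
inflates the plate sd enough to mask itself. If the plate sd is zero no
hits are called. Reference-gene normalization (the delta-delta-Ct
convention) is optional because whether the screen normalized to a
housekeeping gene is not determinable; both modes are exposed.

## Motif derivation and proteome scanning

An alanine/glycine substitution scan measures, per peptide position and
substitution, the fraction of maximal TCR response retained. Two derivation
rules are exposed because the two natural readings of a "required" position
disagree for positions with partial loss: `any_detectable` (default) keeps
a position flexible if any amenable substitution retains a detectable
response (>= 10% of maximum), while `half_loss` fixes a position only when
every amenable substitution loses at least half of function. The default
floor of 0.10 is the conventional detectability limit for FACS cytokine
readouts. Positions whose native residue is Ala or Gly cannot be probed by
the matching substitution and inherit wildcard status by default (absence
of evidence of TCR contact), switchable to fixed.

Scanning is the exact-window search of PROSITE-style tools: every length-L
window matches iff each fixed position equals the window residue ('X' in a
protein sequence never satisfies a fixed position); overlapping matches are
reported with 1-based offsets. A brute-force per-character oracle verifies
the scanner in the tests.

## CCF, clonality, and HLA LOH

For a mutation with variant allele fraction $v$, tumor purity $p$, total
tumor copy number $n_t$, normal copy number $n_n$ (2) and mutant-allele
multiplicity $m$:

$$\mathrm{CCF} = \frac{v\,[p\,n_t + (1-p)\,n_n]}{p\,m}.$$

A 95% interval on $v$ (exact Clopper–Pearson) propagates linearly to the
CCF scale. CCF estimates above 1 are reported uncapped with a flag
(diagnosing model misfit) but capped at 1 for the decision rule: CLONAL iff
CCF > 0.8, or CCF > 0.7 with the interval's upper bound above 0.9;
otherwise SUBCLONAL. A plain >= 0.8 threshold variant is exposed for
cohort-level summaries.

The LOH caller is a deliberately simple stand-in for a full
allele-specific copy-number model (no BAF phasing, no ploidy
re-estimation): at each site where the two HLA-A alleles differ, the
depth-normalized allelic ratio $r = \tfrac12 f_T / f_N$ (tumor allele
fraction over twice the normal allele fraction) yields a purity-corrected
allele copy number $(2r - (1-p))/p$, floored at zero. This closed form
gives cn 1 per allele for a balanced diploid tumor and cn 0 for a fully
lost allele in a pure tumor. Allelic imbalance is tested with a two-sided
paired t-test of per-site $\log_2(\mathrm{A1}/\mathrm{A2})$ coverage
ratios, tumor against matched normal (0.5 read pseudocount; a paired
Wilcoxon alternative is exposed). LOH is called only when the smaller
median allele copy number is below 0.5 *and* the imbalance p-value is
below 0.001 — both conditions are required.

## Superposition and peptide RMSD

`kabsch_superpose()` computes the least-squares proper rotation via SVD of
the cross-covariance matrix with the usual determinant sign correction, so
reflections are never returned; collinear inputs warn but still return the
SVD solution. Peptide comparison supports two frames, because a reported
bound-peptide RMSD depends on what was superposed: `peptide` fits on the
peptide C-alphas themselves, while `carrier` (default, the common
structural-biology convention for peptides bound to the same HLA) fits on
the carrier heavy-chain C-alphas and evaluates the peptide RMSD without
re-fitting. Pairing is by residue order. The tests verify the
implementation against an independent quaternion-eigenvalue (Horn) method
to 1e-8 on 1000 random instances.

## The synthetic-data generators

Every pipeline input can be generated with known ground truth, so all
stages are testable without any external download.

`simulate_sc_experiment()` emulates a screen-positive hit well: clonotype
sizes follow a Zipf law (exponent 1.5, 20 clonotypes by default — one
dominant clone plus a skewed tail, typical of a post-sensitization
repertoire); baseline counts are negative-binomial (dispersion 0.5) with
gamma-distributed gene means scaled to a 2,000-UMI mean library over 1,000
genes; 13 `MT-` genes carry ~8% of library mass, placing the mitochondrial
fraction realistically below the 15% QC threshold; CD3E is expressed
throughout, and each clonotype carries a CD8 or CD4 lineage program
(reactive clonotypes default to CD8, as HLA-I-restricted clones). The
planted reactive clonotype has IFNG and its activation gene set (TNF, IL2,
XCL1) multiplied by `effect_fold` (default 8) in MUT cells only —
a one-sided activation signal. QC violations are planted exactly at
`round(rate * n_cells)` on disjoint cell sets: doublets are summed cell
pairs, high-mito cells have their MT counts resampled to a 25–40%
fraction, low-gene cells are thinned below 200 detected genes, multi-chain
cells receive a third TRA contig, and no-V(D)J cells have their contigs
withheld.

What the generator does *not* emulate: ambient RNA, batch effects,
UMI saturation, cell-cycle structure, or realistic V(D)J allele usage.
Passing tests therefore demonstrate correctness of the *procedures* under
a clean count model, not robustness to every artifact of real droplet
data.

The companion generators mirror their procedures' models directly: qPCR
wells draw $\Delta C_t$ from Normal(0 or `hit_delta`, `noise_sd`); scan
tables emit responses bounded away from the decision floor on both sides
(fixed positions < floor, wildcard positions >= 2x floor for at least one
amenable substitution), which makes motif round-trips deterministic by
construction; the mutation cohort draws true CCFs (clonal 1.0, subclonal
Uniform(0.1, 0.7); clonal fraction defaulting to 102/131, the clonal
prevalence of PIK3CA H1047L in the pan-cancer cohort the package
emulates) and samples alt reads binomially at the model-implied VAF; HLA
sites give the lost allele the contamination-only read fraction
$(1-p)/((1-p)\,2 + p)$ under LOH.

## Numerical choices and degenerate inputs

* Welch test with both groups constant: p = 1 if equal, 0 otherwise;
  groups smaller than 2 give an undefined p.
* Genes expressed in neither condition are excluded from DE testing and
  reported untested.
* Zero-total-count cells are removed under the min-genes rule (their
  mitochondrial fraction is undefined) with a warning.
* Structure altlocs resolve by highest occupancy, ties by alphabetical
  altloc id; residues without a C-alpha are skipped with a warning.
* All generators take integer seeds and are bit-reproducible;
  `run_demo()` derives one seed per stage from its single argument.

## Design choices where the design was open

* **Fold ratio means on the linear scale, tests on the log scale** — see
  above; both the normalization (library-size + log1p) and the
  pseudocount are configurable.
* **Ratio gate at fold 2** (log2 = 1): the gate value is exposed because
  the alternative reading (log2 = 2) cannot be excluded; 2 is the default.
* **Naive plate mean/sd in the qPCR rule** with leave-one-out as an
  option.
* **Per-input-table mean** for the qPCR screen rather than any
  per-donor-run grouping.
* **Two motif-derivation rules** with `any_detectable` as default: it
  reproduces the known x-x-x-x-G-W-T-T-K motif behavior on scans where
  central positions retain partial function.
* **Clonotype identity is taken from the upstream clonotype assignment**
  (the 10x `raw_clonotype_id`) rather than re-derived from CDR3
  sequences.
* **Fixpoint QC** rather than single-pass, for exact idempotence.

## Problem sizes used in the checks

The bundled tests and the acceptance script run the screen at 50 cells per
condition with 1,000 genes across 100 simulation replicates, the QC
exactness fixture at 8,000 genes x 500 cells (large enough that planted
doublets exceed the 7,000-detected-genes rule deterministically), 200 qPCR
plates, 1,000 random proteins for the scanner-oracle comparison, a
200-patient mutation cohort at depth 500, 100 HLA-LOH cohorts of 20 sites
at coverage 300, and 1,000 random superposition instances. These sizes give
each stochastic check a Monte-Carlo standard error comfortably below the
margins being asserted while keeping a full run in the order of a minute.

## Known limitations

* The candidate test controls error per clonotype, not per screen; with
  several evaluable non-reactive clonotypes, occasional alpha-level false
  candidates are expected (about one screen in twenty under the default
  simulation), exactly as raw per-clonotype p-values imply.
* The LOH copy-number estimator assumes the tumor's total coverage at the
  locus is uninformative about local copy number; it is biased toward 2
  overall but conservative for the decision rule it feeds.
* CCF confidence intervals propagate only read-sampling uncertainty;
  purity and multiplicity are treated as known.
* The motif scanner implements exact fixed/wildcard patterns only — no
  character classes, ranges or exclusions.
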