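---
title: "Classifying clonal evolution of renal tumor thrombi from multi-region driver profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying clonal evolution of renal tumor thrombi from multi-region driver profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thrombevo)
```

## The problem

In renal cell carcinoma (RCC) the tumor can extend into the renal vein and
inferior vena cava as a **tumor thrombus** (TT). Multi-region sequencing of
the primary tumor (PT) and of the thrombus along its length — adjacent
(TT-A), middle (TT-M) and distal (TT-D) segments — asks two questions:

1. How does the thrombus relate clonally to the primary (same clone,
   subclone, or an independently evolving lineage)?
2. Within the thrombus, did clones accumulate mutations stepwise (linear)
   or split into coexisting branches (branched)?

`thrombevo` implements that analysis as a pipeline over driver-mutation
profiles: consensus retention of somatic variants across a caller ensemble,
a variant-class filter, per-patient driver matrices, rule-based pattern
classification, clone trees, and cohort summaries. Because the patient-level
sequencing data of such studies are controlled-access, the package ships a
synthetic cohort generator with known ground truth; every downstream stage
is tested against it.

## Consensus variant retention

Somatic calls come from an ensemble of callers (the default panel has
seven: MuTect, VarScan, Shimmer, SpeedSeq, Manta, Strelka, Lofreq). A
candidate mutation is retained when at least *K* callers report it, with
*K* = 3 by default. Variant identity for the consensus is the exact key
`(chrom, pos, ref, alt)` within a sample; no indel left-alignment or fuzzy
matching is attempted. This makes the rule deterministic and exhaustively
testable — retention must equal popcount thresholding over the support
subsets, which the tests verify over all $2^7$ subsets (and up to $2^{10}$
for larger panels) — at the cost of treating differently-normalized
representations of the same indel as distinct. Normalization is a future
hook, to be applied upstream of the merge.

Two choices the rule leaves open are resolved as follows and exposed as
flags where sensible:

* **Per-sample consensus.** Support is counted within each sample; a
  variant retained in one region does not rescue a sub-threshold call in
  another. The alternative (patient-level rescue) would blur exactly the
  inter-region differences the classifier feeds on.
* **Annotation conflicts.** If callers disagree on a variant's gene or
  class annotation, the first-seen annotation wins and a warning reports
  the conflict count.

After retention, calls are filtered to the classes considered
driver-relevant: frameshift and non-frameshift substitutions, stop gain,
stop loss, splicing mutations, non-synonymous SNVs, and annotated "known"
mutations. The "known" label is a pass-through from the input annotation —
it is not computed from any hotspot database, since its provenance is
annotation-pipeline-specific.

## Driver matrices and profile granularity

Retained calls are restricted to a driver-gene list (332 genes by default;
`driver_gene_pool()` bundles a synthetic stand-in whose first entries are
the canonical ccRCC drivers — VHL, PBRM1, BAP1, SETD2, … — since the full
curated list is not redistributable) and arranged per patient as a samples
× genes matrix whose cells hold the distinct retained variant keys.

A sample's **profile** is the set of its mutated elements, at one of two
granularities:

* `variant` (default): elements are `gene|chrom:pos:ref:alt` keys. Two
  samples hitting the same gene at different positions are *different*.
* `gene`: multiple variants in a gene collapse to the gene symbol — the
  granularity at which published clone trees are usually drawn.

Both are supported because figure-level descriptions do not pin this down;
all classification rules are granularity-agnostic set operations, and the
synthetic generator plants one variant per driver event so both
granularities coincide on simulated data. Patients with several PT samples
are classified against the *union* of their PT profiles; per-sample
profiles remain available for reporting.

## Arm-level copy number

Gene-level log2 copy ratios (CNVkit-style gene metrics with bin-derived
weights, taken as given input) are converted to absolute copy numbers
against a diploid reference,

$$\mathrm{cn}_g = 2 \cdot 2^{\ell_g},$$

and averaged per chromosome arm with the gene weights:

$$\mathrm{cn}_{\mathrm{arm}} = \frac{\sum_g w_g\,\mathrm{cn}_g}{\sum_g w_g},$$

clipped to the reportable range $[0, 4]$ (normal = 2) *after* averaging, so
that the arm estimate spans exactly the stated range; the unclipped value
is kept as a diagnostic attribute. Two calling rules are implemented
because both appear in practice without a stated precedence:

* **Threshold rule (default):** loss if $\mathrm{cn}_{\mathrm{arm}} \le 1$,
  gain if $\mathrm{cn}_{\mathrm{arm}} \ge 3$, both boundaries inclusive.
  This is the rule tied to explicit numeric cutoffs, hence the default.
* **Fraction rule:** each gene is called individually (gain $\ge 3$, loss
  $\le 1$) and the arm is called when *strictly more than half* of the
  arm's total gene weight is in one altered state; ties are neutral. The
  weight fraction — not the gene-count fraction — is used, for consistency
  with the weighted averaging; this is a documented judgment call.

On a homogeneous arm (all genes at one copy number) the two rules provably
agree, which the tests check. Arm membership comes from an input gene→arm
map; no cytoband parsing, segmentation, or purity/ploidy correction is
done. A zero-total-weight arm is a warned no-call rather than an error.

## Pattern classification

The published pattern categories are narrative and figure-level; the
package formalizes them as the minimal set-containment rules consistent
with every printed description. With $P$ the union PT profile and $T$ the
union TT profile:

| pattern | rule |
|---|---|
| co-evolution / clonal expansion | $P = T$, non-empty |
| private to PT | $T \subsetneq P$ |
| private to TT | $P \subsetneq T$ |
| divergent | $P \setminus T \ne \emptyset$ and $T \setminus P \ne \emptyset$ |
| no driver | $P = T = \emptyset$ |

For patients with at least two TT samples, the **thrombus topology** is
read off the set $D$ of distinct TT profiles: *linear homogeneous* when
$|D| = 1$; *linear heterogeneous* when $|D| \ge 2$ and $D$ is totally
ordered by inclusion (stepwise accumulation); *branched heterogeneous* when
some pair is incomparable (distinct private mutations on separate
branches). Branched is by definition heterogeneous, so there are exactly
three topology classes. Patients with a single TT sample get topology
`undefined` — a label, not an error. Two deliberate non-requirements:

* Spatial order along the thrombus (A → M → D) is **not** required to
  coincide with the inclusion order for a linear call; trees are drawn
  from containment structure, and spatial concordance is an auxiliary
  statistic, not a classifier input.
* `flag_additional_tt_drivers()` compares the thrombus against the PT
  union by default; comparison against the adjacent TT segment is
  available via `relative_to = "adjacent"` since the narrative phrasing
  admits both readings.

All classifications are invariant to sample order and to duplication of
identical samples (property-tested).

## Clone trees

Each distinct profile is a clone. The root is the truncal profile — the
intersection of all sample profiles, possibly an empty virtual root. The
profile family is closed under pairwise intersection, so every branching
point is represented, and each node is attached to a maximal
proper-subset ancestor; edge labels carry the mutations gained relative to
the parent. Gains along any root-to-leaf path are disjoint and union to
the leaf's profile, so every sample profile replays exactly from the root
(this soundness property is tested on a thousand random profile families).

One subtlety: even a meet-closed family can leave a node with two maximal
subset ancestors (e.g. $\{a\}, \{b\}, \{a,b,c\}$ over an empty root). The
attachment is then decided deterministically — largest ancestor profile
first, lexicographic on ties. No homoplasy resolution is attempted: a
mutation present in incomparable profiles is treated as independently
informative (infinite-sites at the profile level). Trees export to Newick
with `[&gained=...]` node comments; standard parsers read the file after
comment stripping.

## The synthetic cohort generator

`simulate_patient()` builds a patient from a scenario template — the pair
(PT-TT pattern, TT topology), 12 combinations in all — so that the
noise-free output classifies *by construction* to the requested scenario:

* a truncal driver set (Poisson, conditioned non-empty) shared by all
  regions;
* topology-specific TT structure: identical profiles (linear homogeneous),
  a chain of cumulative gains (linear heterogeneous; at least one step must
  gain), or at least two branches with obligatory distinct private drivers
  (branched);
* pattern-specific PT structure: the TT union (co-evolution), the TT union
  plus PT-private drivers (private-PT), the trunk only (private-TT), or
  the trunk plus PT-private drivers with obligatory TT gains (divergent).

Poisson draws are re-drawn until a template's minimum is met (for a zero
rate the minimum is used directly). Variants live on a toy genome — one
locus per driver gene, unique and deterministic — so consensus and matrix
stages are exercised without a reference build. Caller noise is layered on
top: each caller reports each true variant independently with probability
`caller_sensitivity` and adds `Poisson(caller_fp_rate)` false calls per
sample in non-driver filler genes at fresh loci (false positives are
therefore singletons and die at any consensus threshold ≥ 2).

Defaults, chosen once as a realistic multi-region ccRCC thrombus study and
not revisited: truncal rate 2 and private rate 1 (ccRCC tumors typically
carry VHL plus a small handful of additional drivers, and subclones gain
one or a few), one PT and three TT samples (the directional A/M/D
sampling), seven callers at sensitivity 0.9 with one false call per sample
per caller. Scenario priors in `simulate_cohort()` are user-set — how often
thrombi carry clones unseen in the sampled PT regions is not estimable from
published counts alone; the `analysis/` drivers use the published cohort
proportions as priors.

Reproducibility: each patient's RNG stream is derived from the master seed
and the patient identifier, so identical `(config, seed)` give
byte-identical cohorts and generation is order-independent.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: no read-level simulation or alignment
artifacts (noise is Bernoulli/Poisson per call, while real caller errors
are correlated across callers at hard sites); no variant-allele-fraction,
purity or subclone-fraction modeling (presence is binary); no
copy-number-driven mutation loss (a deletion never removes a planted SNV);
no inter-gene correlation in driver selection. Recovery rates on synthetic
cohorts measure the classifier logic, not caller performance on real
tumors.

## Numerical and degenerate-input choices

* Arm estimates: exact closed-form weighted mean; agreement with an
  independently coded accumulation loop is required to a relative
  tolerance of 1e-12. Call boundaries are inclusive exactly as stated
  (loss ≤ 1, gain ≥ 3); the fraction rule uses strict majority.
* Empty profiles: a patient whose PT and TT profiles are both empty is
  `no_driver`, reported as its own row, never dropped.
* Percentages: every summary carries its denominator, both one-decimal and
  nearest-integer percents are emitted, and topology percentages run over
  patients with ≥ 2 TT samples while PT-TT percentages run over all
  classified patients.
* Category order in reports is fixed, so repeated writes are
  byte-identical.

## Problem sizes used by the checks

The shipped checks run at desk scale: exhaustive caller-subset enumeration
up to $2^{10}$; 10,000 random gene tables for the arm estimator; 216
noise-free synthetic patients spanning all 12 scenarios (18 seeds each)
plus a 60-patient noisy cohort for reproducibility; 1,000 random profile
families for tree soundness. The `analysis/` workflow simulates a
51-patient multi-TT cohort, mirroring the published cohort size.

## Known limitations

* Binary presence/absence profiles: no CCF or VAF-based subclone
  deconvolution, no timing, no bootstrap support on trees.
* The containment formalization of the four patterns is this package's
  own; the original assignments may have involved manual tree inspection,
  so category boundaries on borderline patients could differ.
* Consensus identity is exact-key; unnormalized indel representations
  split support across keys and can push true variants below threshold.
* Metastasis samples are carried through matrices and reported separately
  but do not enter the TT topology.
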