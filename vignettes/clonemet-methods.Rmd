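---
title: "Models and methods behind clonemet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind clonemet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonemet)
```

clonemet analyses paired primary-tumor / metastasis whole-exome cohorts:
which somatic alterations are clonal in which lesion, how their clonality
shifts during metastatic seeding, what the per-patient phylogeny looks like,
and how HLA loss and transcriptional silencing erode the presentable
neoantigen load. This vignette explains each model, its assumptions, the
tunable parameters, and the design decisions that were genuinely open.

## The CCF model

For a mutation with cancer cell fraction $f$, multiplicity $m$ (mutated
copies per tumor cell), local tumor copy number $C_T$, normal copy number
$C_N$ (2 on autosomes) and tumor purity $\rho$, the expected variant allele
fraction is

$$\mathrm{VAF}(f) = \frac{f\,\rho\,m}{\rho\,C_T + (1-\rho)\,C_N}.$$

`estimate_ccf()` places a uniform prior on the grid
$f \in \{0, 0.01, \dots, 1\}$ and uses the binomial read-count likelihood
$\mathrm{Bin}(t_{alt} \mid t_{depth}, \mathrm{VAF}(f))$. The grid step of
0.01 is below the resolution read counts provide at the 150x depth this
pipeline targets, so a finer grid would only cost time. Multiplicity, when
not supplied, is the rounded inversion of the VAF relation at $f = 1$,
clamped to $[1, C_T]$; joint purity/ploidy inference is deliberately out of
scope — purity and allele-specific copy number are inputs.

Two choices here were genuinely open:

* **Credible interval.** The 95% interval is the highest-posterior-density
  (HPD) set on the grid, not the equal-tailed one. The CCF scale is capped
  at 1 and truly clonal mutations put their posterior mode at the boundary;
  an equal-tailed interval sheds its entire upper tail there and, in
  simulation at depth 150 and purity 0.6, covered the true value for only
  ~82% of clonal mutations. The HPD interval covers ≥ 93% in every stratum
  we simulate while behaving identically to the central interval away from
  the boundary.
* **Clonal probability.** `pr_clonal` is a two-component assignment
  probability: the mutation is either clonal (point mass at $f = 1$) or
  subclonal ($f$ uniform on the grid), with equal prior odds, and
  `pr_clonal` is the posterior weight of the clonal component. The
  alternative convention — posterior tail mass above a CCF of 0.9 under the
  flat prior — is available via `clonal_mass_min`, but at moderate purity it
  is far too conservative: the flat-prior posterior of a clonal mutation at
  depth 150 and purity 0.6 has roughly half its mass below 0.9, so the
  tail-mass rule misses a third of truly clonal mutations. The mixture form
  recovers ~96% of them under the same conditions.

A mutation is **clonal** when `ccf_ci95_high >= 0.95` (equivalently, the
interval reaches 1 on the capped scale) *and* `pr_clonal > pr_subclonal`;
otherwise subclonal. Samples with purity below 0.20 are excluded from
clonality analysis entirely (strict "below": 0.20 itself is kept).

## Evolution patterns

Variants are matched across a patient's lesions by `chrom:pos:ref:alt` —
deliberately not by gene symbol, so annotation differences cannot split a
variant. Each variant's per-lesion status (clonal C, subclonal S, absent 0)
is concatenated into one of eight labels: C-C, C-S, S-C, S-S, 0-C, 0-S,
C-0, S-0. S-C, for example, marks a mutation subclonal in the primary that
became clonal in the metastasis — the signature of a clone selected during
seeding. Timing is ranked by median CCF per gene within a lesion (high
median = early, ancestral event; ties broken lexicographically so rankings
are stable), and cohort-level recurrence requires the same gene-pattern
combination in at least 2 patients by default.

Arm-level copy-number events reuse the same taxonomy. Per arm we take the
segment-length-weighted mean log2 copy ratio; |log2| ≥ 0.2 calls an
amp/del. The 0.2 cutoff is a common exome convention — no threshold is
inherent to the model — and is exposed in `pipeline_config()`. The event
CCF inverts the total-copy-ratio model for a single event of signed copy
change $\Delta$ on a diploid background,

$$f = \frac{2^{\,\mathrm{log2ratio} + 1} - 2}{\rho\,\Delta},$$

which is exact at zero noise but assumes one event per arm; multi-event
arms are not decomposed. Because no interval is available for this
estimator, arm events are called clonal at $f \ge 0.9$ — a declared
approximation, configurable. Arm boundaries come from a packaged hg19 table
(the build the pipeline's coordinate conventions target).

Gene-set enrichment of pattern genes is a one-sided hypergeometric tail
within a user-supplied universe; gene sets are user-supplied, none are
shipped.

## Maximum-parsimony phylogenies

Per patient, variants x samples form a binary presence/absence matrix with
an all-zero matched-normal outgroup; variants observed in the normal are
rejected as germline. All unrooted topologies are enumerated exhaustively
(patients here have 2-3 tumor samples; the hard cap is 8 leaves, beyond
which the package refuses rather than silently switching to a heuristic)
and scored with the Fitch algorithm. Ties between equally parsimonious
topologies are broken by the lexicographically smallest canonical Newick
string — the tie rule has to be *some* deterministic convention, and a
string ordering is reproducible across platforms.

Branch lengths are integer mutation counts, not substitutions per site: a
minimal Fitch reconstruction with the ancestral state fixed at 0 (the
outgroup side) assigns each variant's change to an edge, and homoplastic
variants (more than one change) are flagged. For the common two-sample
case this reduces exactly to trunk = shared, branches = lesion-private
counts, which the tests assert against the mutation-matching module.

## HLA-LOH, neoantigens, and HLA-corrected TMB

Allele-specific HLA copy number is estimated from binned coverage log
ratios: with purity $\rho$, the mean linear ratio $r$ of an allele gives
$\hat{c} = (r - (1-\rho))/\rho$. LOH is called when the minor allele's
$\hat{c} < 0.5$ **and** a paired two-sided t test across bins finds the two
alleles' log ratios significantly different at $p < 0.01$. The named test
is a choice: the criterion is stated as "significant difference between the
per-allele log copy ratios", and the established allele-specific HLA
caller this mirrors uses a paired t test; the test and both thresholds are
configurable. P values are reported raw per gene — no multiplicity
correction across the three class-I genes, which keeps the caller
conservative only through the copy-number guard.

Neoantigen candidates (external binding predictions are inputs, rank ≤ 2
defining a binder by the standard weak-binder convention) pass two depth
screens: records with normal coverage ≤ 5x *and* normal VAF ≥ 2% are
discarded as germline leakage (the coverage bar may be raised to 20x), and
only records with tumor depth ≥ 10x and tumor VAF ≥ 40% are kept. Note the
40% rule presumes near-clonal VAFs at high purity: a clonal heterozygous
diploid site peaks at VAF $\rho/2$, so below $\rho = 0.8$ the screen can
retain nothing. That is faithful behaviour, not a bug; moderate-purity
cohorts must lower `neo_tumor_vaf_cutoff` deliberately. A neoantigen
counts as expressed when ≥ 5 RNA reads cover the site and ≥ 3 carry the
mutant base; records without RNA data are excluded from expression
denominators rather than counted as non-expressed.

HLA-corrected TMB subtracts from the raw mutation count those mutations
*all* of whose binding alleles are lost to HLA-LOH in that sample — they
can no longer yield presentable neoantigens. Mutations with no predicted
binder are unaffected: the correction models lost presentation, not
immunogenicity. The subtraction rule is a declared interpretation of the
"HLA-corrected" concept; the originating description does not give a
formula. TMB is reported as raw counts, with optional per-megabase
normalisation given a capture size (53 Mb matches the exome capture these
conventions target).

## The synthetic cohort generator

Every stage is validated against `simulate_cohort()`, which draws read
counts from known clone structure rather than shipping any patient data.
Per patient: a clone specification gives each clone a CCF in each lesion
and a mutation count; read depth is Poisson around 150x (the stated mean
depth; nothing in the model requires more structure), alt reads are
binomial at the analytic VAF, and a clone with CCF 0 in a lesion
contributes no reads there. A mutation row is emitted only when at least
one alt read is drawn — a caller cannot report a 0-alt site — which at
these depths discards a negligible fraction. Defaults: 15 patients, purity
0.6 in both lesions, 10% of mutations on a 3-copy locus, 20 HLA bins, RNA
depth 50x at expressed sites.

The default template is one truncal clone plus seven lesion-variable
clones covering all eight pattern labels, so every classifier branch is
exercised by every patient; subclonal CCFs sit at 0.30, comfortably away
from both the absence and clonality boundaries. The template is
illustrative — it is not a reconstruction of any real cohort's clonal
architecture. Two realism features matter downstream: per-patient mutation
burdens are scaled by a log-normal multiplier (`burden_dispersion` = 0.5),
because tumor cohorts show wide inter-patient TMB variation and cohort
correlations (e.g. neoantigen total vs non-expressed counts) are
meaningless without it; and the expressed fraction of mutation sites
defaults to 0.35, reflecting the transcriptional depletion of neoantigens
this class of analysis is designed to expose.

What the generator does **not** emulate: sequencing error and
cross-contamination (both zero by default so ground-truth recovery tests
have a clean null), mapping artefacts, FFPE damage, subclonal copy-number
structure beneath arm level, germline variation, and indel-specific error
modes (indels are simulated identically to SNVs, as the tree building
pools both). Passing the recovery suites therefore demonstrates the
estimators are correct under their own model assumptions — not that they
are robust to artefacts real pipelines must handle upstream.

## Problem sizes and numerical choices

The validation suites run at the scale the models target: 15-patient
cohorts at depth 150 (≈ 3,000 lesion-level mutation calls) for
clonality/pattern recovery; 200 random 4-6-leaf matrices against an
independent exhaustive parsimony oracle; 200 replicates each for HLA-LOH
sensitivity (true minor copy number 0, purity 0.5, 20 bins) and
false-positive rate (balanced alleles). Degenerate inputs are defined
errors, not silent results: zero-depth sites, empty clone lists, missing
purity, unequal HLA bin counts, sub-3-leaf trees (returned as the forced
topology), arms with no covered bases (omitted from calls).

Measured on these suites: clonality recovery ≈ 96%, HPD interval coverage
≈ 95%, pattern recovery ≈ 93-94%, parsimony oracle agreement and
trunk/branch exactness 100%, LOH sensitivity ~100% with 0-1% false
positives. Percentages are displayed with half-up integer rounding while
raw fractions and numerator/denominator pairs are always retained, since
printed cohort percentages in the literature mix rounding conventions.

## Known limitations

* CCF estimation conditions on the supplied purity and copy state; errors
  in either propagate directly (no joint re-estimation).
* The SCNA CCF inversion assumes one event per arm on a diploid
  background.
* Pattern labels treat lesion absence as evidence of absence; very low
  depth would blur 0-C against S-C, though at 150x this is negligible.
* The paired t test for HLA-LOH treats bins as independent; correlated
  coverage waviness would inflate significance, which the copy-number
  guard partially absorbs.
* Exhaustive tree search is exact but exponential; the 8-leaf cap is a
  deliberate boundary, not a performance target.
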