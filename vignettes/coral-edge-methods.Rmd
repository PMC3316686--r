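---
title: "Methods: supertree assembly, EDGE prioritization and phylogenetic signal for reef corals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supertree assembly, EDGE prioritization and phylogenetic signal for reef corals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

About a third of the world's zooxanthellate reef-building corals
(Scleractinia) are threatened with extinction. Ranking species for
conservation by extinction risk alone ignores that species are not
interchangeable: some sit at the end of long, isolated branches of the tree
of life and carry far more unique evolutionary history than others. The
EDGE framework (evolutionarily distinct and globally endangered) ranks
species by the *expected loss of evolutionary history*,

$$\mathrm{EDGE}_s = \mathrm{ED}_s \times \mathrm{PE}_s,$$

where ED is fair-proportion evolutionary distinctiveness and PE the
species' probability of extinction over a 100-year horizon derived from its
IUCN Red List category. Around that core ranking sit four companion
analyses: assembling the phylogeny itself from heterogeneous sources
(weighted matrix representation with parsimony, MRP), testing whether risk
and threat-response traits are phylogenetically clumped (Blomberg's K,
Fritz & Purvis' D, independent contrasts), measuring how much phylogenetic
diversity (Faith's PD) would be lost under extinction scenarios, and asking
whether the tree's shape (Colless imbalance) departs from the Yule
expectation. This package implements all of these stages as tested,
reusable functions, exercised end to end on synthetic data; the numbered
scripts under `analysis/` run the whole study in order.

No real sequence or Red List data ship with the package. Everything the
pipeline consumes is produced by the synthetic-data generator, whose
defaults encode the published study conditions (see below), so what the
tests establish is the *correctness and calibration of the machinery*, not
a reproduction of the real coral supertree or its top-30 list.

## Supertree assembly (weighted MRP)

Each source tree is coded Baum–Ragan style: every non-root internal node —
a clade of at least two and fewer than all of that source's taxa — becomes
one binary character with descendants 1, the source's other taxa 0, and
taxa absent from that source missing (`NA`). The character weight is the
node's bootstrap percentage; nodes of taxonomy-derived sources all get
weight 1 so that data, not classification, drive the result. Identical
characters arising from different sources are deliberately kept separate.

Scoring uses the exact two-state dynamic programme (Sankoff recursion with
unit symmetric costs), with missing states as full ambiguities. For binary
characters this equals the Fitch length on the subtree induced by each
character's non-missing taxa, and it is exact on polytomies. The search is
desk-scale by design: exhaustive branch and bound (with score-bound
pruning, guarded to 15 taxa) or random-addition hill climbing with
first-improvement NNI rearrangements under a seeded tie order. Cluster-scale
heuristics (10^5 random additions, 10^7–10^8 rearrangements) are a
non-goal; the algorithms, not the compute, are what the package
contributes.

**Rooting.** Parsimony length is invariant to root placement, so a search
over rooted topologies cannot recover the rooted clades the characters
encode. The search therefore augments the matrix with an implicit all-zero
root taxon (the standard Baum–Ragan device), roots every optimal tree at
it, and removes it before returning. This is exposed as `ragan_root =
FALSE` for callers who want the raw unrooted-equivalent behaviour; with it
disabled, optimal rootings tie and the strict consensus degrades
accordingly.

The strict consensus of equally best trees is delegated to
`ape::consensus(p = 1, rooted = TRUE)`.

## Polytomy resolution

The supertree consensus contains polytomies; downstream statistics need
bifurcating replicates. Two seeded schemes are provided:

* `sequential` (default): repeatedly join two uniformly chosen children of
  the polytomy under a new zero-length node. Simple and fast; exactly
  uniform over the 3 resolutions of a trichotomy, but for $k \ge 4$ it
  weights balanced arrangements more heavily than pectinate ones (for
  $k = 4$: 1/9 per balanced vs. 1/18 per pectinate topology, against 1/15
  under uniformity).
* `uniform`: sequential attachment of each child at a uniformly chosen stem
  of the growing arrangement, which yields the exact uniform law over all
  $(2k-3)!!$ rooted binary arrangements.

Both conserve the tip set, every clade of the base tree, and total branch
length (new edges have length 0). Replicate $i$ is generated from a seed
derived from (master seed, stage, $i$), so it is identical no matter how
many replicates are requested.

Because resolution edges have length zero, fair-proportion ED is
*mathematically invariant* across resolutions: the per-edge tip counts of
pre-existing edges do not change and new edges contribute nothing. The SD
columns of the EDGE table are therefore exactly zero unless the replicates
differ in branch lengths — which is why the single-resolution and
1000-resolution rankings agree. The machinery still computes per-replicate
scores so that length-perturbed replicates, if supplied, aggregate
correctly.

## ED, PE and the EDGE ranking

ED divides every branch equally among the tips descending from it and sums
each tip's shares along its root path; the ED values always sum exactly to
the total branch length, which the tests assert to a relative tolerance of
1e-9 on degraded trees (polytomies, zero-length terminals, a retained root
edge). Species without sequence data get terminal branch length zero but
keep their ancestral shares — a deliberate lower bound on distinctiveness.

PE comes from a category-to-probability table. The default `IUCN100`
transform anchors PE(LC) = 0.001 (about one of 289 LC corals lost in a
century) and PE(NT) = 0.01; the CR/EN/VU values 0.999/0.667/0.1 follow the
commonly used 100-year transformation family and are editable. Data
Deficient species receive a value strictly between LC and NT: the midpoint
0.0055 by default, the geometric mean (≈0.0032) as an alternative — the
choice is a package decision, since only "between" is specified in the
source literature. `Isaac` and `Pessimistic` tables are included for
completeness but drive no default output. Ranks sort by mean EDGE with ties
broken by mean ED and then label, so rankings are deterministic.

`rank_stability()` summarizes ranking robustness between a full and a
reduced analysis as the mean absolute rank difference over the top-k
species and over all shared species.

## Phylogenetic signal

**Blomberg's K** is the ratio of the observed $\mathrm{MSE}_0/\mathrm{MSE}$
(mean squared deviation from the phylogenetically corrected mean, over the
GLS error under the tree's Brownian covariance $V$) to its Brownian
expectation $\big(\operatorname{tr} V - n/\mathbf{1}'V^{-1}\mathbf{1}\big)/(n-1)$.
K is 1 on a star tree for any trait, near 1 for Brownian traits, near 0 for
shuffled ones. The randomization test permutes trait values across tips and
reports $p = (\#\{K_{\mathrm{perm}} \ge K_{\mathrm{obs}}\}+1)/(n+1)$.
Zero-length terminals can make $V$ singular (identical rows); the
implementation then switches to a pseudoinverse with a warning rather than
failing.

**Fritz & Purvis' D** computes the trait's total sister-clade disparity:
nodal values are equal-weight averages of daughter values and the statistic
sums the absolute daughter-minus-node differences over all edges (for a
bifurcation this is exactly the sister difference, and the generalization
handles polytomies). D rescales the observed sum between the means of two
null distributions — tip permutation preserving prevalence (D = 1) and a
unit-rate Brownian liability thresholded so the simulated prevalence
matches the observed count exactly, ties broken by rank (D = 0). Both
p-values are one-sided toward their nulls: `p_vs_random` is the fraction of
permutation sums at or below the observed sum, `p_vs_clumped` the fraction
of Brownian sums at or above it, each with the plus-one rule so no p-value
is ever zero. Calibration on 64-tip pure-birth trees (500 datasets per
condition, prevalences 0.1/0.3/0.5) keeps mean D within [0.9, 1.1] for
permuted and [−0.1, 0.1] for liability-threshold traits.

**Independent contrasts** follow the pruning recursion — contrast
$(x_i-x_j)/\sqrt{v_i+v_j}$, inverse-variance nodal means, branch updating
$v' = v + v_i v_j/(v_i+v_j)$ — with association summarized by the
through-origin regression of y-contrasts on x-contrasts and its t-test.
Zero-length branches (ubiquitous after resolution and zero-terminal
assignment) break the standardization, so for contrasts only they are
replaced by $\varepsilon = 10^{-6} \times$ tree depth, with a message; K
and D use the covariance with exact zeros. Binary traits run through the
same machinery as 0/1 reals; for nested binary traits many contrasts are
zero, so the slope *sign* is a much more reliable signal than its t-test —
the calibration suite asserts a positive slope in at least 90% of
shared-liability simulations rather than significance.

`stratified_signal()` reruns a test inside species strata (abundance
classes, source-tree representation counts), pruning the tree per stratum
and skipping — with a recorded reason, not an error — strata where the
trait is monomorphic or too small, mirroring how such subsets behave in
practice.

## PD loss and tree shape

Faith's PD of a taxon set is the branch length of its spanning subtree,
under the rooted convention by default (the MRCA-to-root path counts, so
PD(all tips) equals total length and PD is additive over nested subsets);
the flag is carried in every result object because it shifts absolute PD
but not equal-richness comparisons. `extinction_scenario_test()` removes
the species at or above a Red List threshold (or an explicit set), measures
survivor PD, and compares it to `n_null` uniform random removals of the
same count. Two p-values are reported: the one-sample t-test of the null
sample against the observed PD — the test used in the source analyses —
and a rank-based empirical p. The distinction matters: when the scenario
itself is a random draw, the t statistic's variance is roughly $n$ times
what the test assumes (the observed value is a single draw from the same
distribution as the null sample, not a fixed constant), so the t-test p is
far from uniform; the empirical p is exactly discrete-uniform and is what
the calibration checks. On trees of ten or fewer tips the Monte-Carlo null
is verified against exhaustive enumeration of all equal-sized removals.

Colless imbalance sums $|L - R|$ over internal nodes of a bifurcating tree
(pectinate trees attain the maximum $(n-1)(n-2)/2$, checked in closed form
for $n = 3..50$). The Yule null simulates topology only — cluster sizes
under the random-join process, whose topology law coincides with the Yule
process — since Colless ignores branch lengths, and reports
$p = (\#\{\mathrm{null} \ge \mathrm{obs}\}+1)/(n+1)$.

## The synthetic study generator

`synthetic_study_config()` fixes the study conditions once:

| parameter | default | rationale |
|---|---|---|
| `n_species` | 837 | the reef-coral census size |
| `tree_model` | Yule, birth rate 1 | neutral branching null; rates only set the time scale |
| `category_frequencies` | 4 CR, 23 EN, 198 VU, 174 NT, 289 LC, 149 DD | the published census, rescaled exactly (largest remainder) for other sizes |
| `missing_data_fraction` | 0.56 | 365 of 837 reef species had sequence data; the rest get zero terminals |
| `polytomy_fraction` | 0.30 | unstated at source; consensus supertrees are heavily unresolved, and 30% collapse reproduces that character |
| `n_source_trees` | 15 | 13 morphological + 1 molecular + 1 taxonomic source |
| trait set | 8 binary traits at prevalences 0.419, 0.116, 0.310, 0.058, 0.134, 0.273, 0.124, 0.157 | the published trait census; susceptibility traits share one Brownian liability to induce the reported cross-trait association; the restricted-range trait is tip-random |

Categories and trait states are assigned as *exact counts* (permutation of
a fixed census, liability thresholds at exact ranks) rather than Bernoulli
draws — matching the fixed published census and stabilizing calibration.
Liability rate is fixed at 1 because thresholds, and hence D, are
scale-free in the liability. Category assignment is a uniform permutation
by default (the negligible-signal situation reported for coral extinction
risk); `clustering = "brownian"` cuts liability-ranked species into
category blocks for power testing.

What the generator does *not* emulate: real sequence data and alignment
error (no DNA is simulated), non-ultrametric branch lengths (pure-birth
trees are ultrametric; real supertrees with fitted lengths are not),
biased taxon sampling in sources (subsets are uniform, with conflict
injected as single NNI perturbations), and spatial/biogeographic structure.
Passing calibration on these synthetic conditions therefore demonstrates
that the estimators and nulls are implemented correctly, not that the real
data would yield any particular value.

## Numerical choices and degenerate inputs

* Seeds: every stage derives its seed deterministically from one master
  seed, a stage label and a replicate index; all derived seeds stay below
  $2^{31}$.
* Score ties in the parsimony search use an absolute tolerance of 1e-9 on
  weighted scores; returned trees are re-verified against `fitch_score()`
  and the search aborts on disagreement.
* Tie-breaks: first-improvement NNI with a seeded move order; stepwise
  addition takes the first best position in a seeded candidate order; EDGE
  ranks break ties by mean ED then label.
* Degenerate inputs: monomorphic binary traits are an error for D (or a
  recorded skip inside strata); scenarios removing none or all species are
  errors; a constant PD null (e.g. a single survivor on an ultrametric
  tree) yields a defined result with `t = NA` instead of a failure;
  single-tip pruning returns a one-tip tree carrying the root-path length.
* Problem sizes in the test and acceptance suites — 64-tip trees with
  500 datasets per calibration condition, 100 trees for the ED identity,
  20 (tests) or 10 (acceptance script) 12-taxon models for the MRP oracle,
  200–500 replicates for type-I error and uniformity checks — were chosen
  as the smallest sizes at which the quantities of interest are estimated
  with comfortable margin over their tolerance bands.

## Known limitations

* The hill climber offers NNI only; TBR/SPR rearrangements and ratchet
  strategies are future work, so very conflicted matrices may need many
  starts.
* Strict consensus is the only consensus flavour; majority-rule is easily
  obtained from `ape` directly on `$trees`.
* The D implementation targets the equal-weights nodal-averaging estimator;
  alternative signal statistics (Pagel's λ, Moran's I) are out of scope.
* EDGE SDs over resolutions are structurally zero under zero-length
  resolution (see above); supplying replicates with independently fitted
  branch lengths is the way to obtain meaningful resolution variance.
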