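---
title: "Inducing virtual binding pockets from ligand activity data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inducing virtual binding pockets from ligand activity data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketqsar)
```

## The model

`pocketqsar` treats 3D-QSAR as a pocket-reconstruction problem.  The
fitted object is a *pocketmol*: a set of typed probes — steric,
hydrogen-bond donor, hydrogen-bond acceptor — positioned in a common
Cartesian frame, together with the optimal bound pose of every
training ligand, the *exploration envelope* those poses sweep out,
and the statistical distributions used to normalize prediction
quality metrics.  The working assumptions are the usual ones for
alignment-based QSAR:

* a common binding mode family exists, so a single frame and a single
  seed alignment hypothesis are meaningful;
* measured activity is monotonically related to the attainable
  interaction score of the best pose, so fitting scores to activities
  (rather than classifying poses) is sensible;
* ligand pairs with similar activities tend to present similar shape
  and polarity to the pocket — the *parsimony* assumption, which is
  what makes the inverse problem identifiable at all.

### Scoring surrogate

Probe–atom interactions use smooth, capped, kind-compatible wells:
steric probes attract steric atoms with a Gaussian well centered at
4.0 Å (width 1.0 Å), polar probes attract complementary polar atoms
(donor probe ↔ acceptor atom, acceptor probe ↔ donor or cationic
atom) with a well at 2.9 Å (width 0.4 Å) and a squared-cosine
directionality factor inside a 60° cone, mimicking carbonyl/amidine
hydrogen-bond geometry.  The per-contact maxima (1.0 pKi steric,
1.5 pKi polar) are set so that roughly six to ten good contacts span
a typical pKi activity range.  Below a hard-core distance (3.0 Å, or
2.2 Å for a compatible polar pair) a linear clash penalty of
2 pKi/Å accrues.  Hydrogens carry no steric attraction and no clash:
the hydrogen of a donor group legitimately sits well inside any
heavy-atom core distance of its acceptor, and penalizing it would
invert the energetics of every hydrogen bond.  Scores are linear in
probe weights, which is what makes the greedy weight optimization
cacheable and fast.

Molecular similarity is a normalized feature-channel Gaussian
overlap: each atom contributes an isotropic Gaussian of width half
its van der Waals radius to its channel; per channel the similarity
is `O(a,b)/sqrt(O(a,a)·O(b,b))`; channels combine with fixed weights
(steric 1.0, donor 0.5, acceptor 0.5).  It is symmetric, bounded in
[0, 1], exactly 1 for identical fields, smooth in coordinates, and
invariant under a common rigid motion — the properties the induction
algorithm actually relies on.  Self-overlaps are invariant under
rigid motion, which the alignment search exploits heavily.

### The selection objective

Probe-subset selection minimizes

$$f = \alpha D + \beta(1-P) + \gamma R + \delta C + \epsilon N$$

with defaults $\alpha=1$, $\beta=20$, $\gamma=20$, $\delta=-1$,
$\epsilon=0.03$.  `D` is the mean squared deviation (pKi²) between
activities and ligand scores, where a ligand's score is the maximum
over its pose pool; `P` the parsimony, an activity-weighted mean of
pairwise optimal-pose similarities with Gaussian activity weights
(width `sigma_act = 1` pKi — identical activities weigh 1.0); `R`
accumulates like-kind probe-pair shortfalls below preferred
separations (2.0 Å steric, 1.5 Å polar); `C ≤ 0` is the mean clash of
the optimal poses; `N` counts probes.  At these weights one unit of
`f` equals 1 pKi² of fit, 0.05 of parsimony, a 0.05 Å redundancy
shortfall, 1 pKi of clash, or about 33 probes — so the probe-count
term only demands that a new probe buy at least 0.03 units of
improvement.

### The greedy procedure

Cold-start optimization runs four deterministic stages from each of
up to ten *pose cliques* (fixing one of the first five poses of the
first or second molecule, then hill-climbing parsimony by pairwise
pose replacement):

1. real-valued probe weights from zero, steepest single-coordinate
   descent at step 0.2 then 0.1, poses fixed at the clique;
2. the same descent with free pose choice, restricted to "good"
   probes (those that ever held positive weight in stage 1);
3. rounding to binary weights and single-flip descent to a local
   optimum;
4. keep the lowest-`f` clique result, then refine probe positions on
   a six-direction stencil (rounds alternate 0.2 Å and 0.1 Å steps),
   accepting only moves that lower `D`, re-picking optimal poses
   after each round.  Composition never changes during refinement.

The good-probe restriction exists purely to bound the cost of the
free-pose stages, so it is applied only when the candidate set
exceeds 32 probes; on smaller problems all probes stay active, and on
instances small enough to enumerate (≤ 4 candidates, ≤ 3 poses per
molecule) the greedy result matches the exhaustive binary-subset
optimum — the test suite asserts this.  All ties break toward the
lowest index (probe, pose, or clique), which together with the
torsion-grid conformer generator makes the whole pipeline
bit-reproducible.

Three candidate models are built at different polar-candidate grid
densities (dedup spacings 0.75, 1.0, 1.5 Å) and the winner is chosen
by a three-metric vote: training Kendall's τ, mean error, and
parsimony; ties break by τ, then error.

### Prediction, pose families, applicability domain

New molecules are posed against the training optimal poses, lightly
rigid-refined on the full objective (interaction + clash + envelope +
constraints), clustered by single-linkage RMSD at 2.0 Å, and ranked
by Boltzmann probabilities of corrected scores.  Three quality
metrics are normalized through the survival function of their
training distributions (`p = 1 − Φ((S−µ)/σ)`): confidence (maximal
similarity to a single training optimal pose), novelty (coverage of
the pose's own similarity field by the union of training fields), and
exclusion (total envelope penalty; since "worse" is more negative,
the survival orientation already maps worse-than-training to high
`p`).  Each pose's ranking value gains `−RT·ln(p)` per metric, so
native-like poses (small `p`) are boosted; `RT` defaults to
0.434 pKi (0.592 kcal/mol at 298 K divided by 1.364 kcal/mol per log
unit).  Reported activities are *never* adjusted — the corrections
only re-rank.  Training distributions are estimated from all
non-self pose pairs after expanding each molecule's contributing set
to pool poses within 1.0 Å RMSD of its optimal pose or within 2.0 pKi
of its optimal score, which stabilizes the moments for small
training sets; a σ floor of 0.05 guards degenerate cases.

The applicability-domain rules follow the quality metrics: in-model
by default means `pNov < 0.85`; a strict rule adds `pConf > 0.35`
and `pExcl < 0.95`; a raw-value fallback (`similarity > 0.70`,
`exclusion > −0.40`) exists for models whose training set is so
narrow that normalized novelty rejects everything.  "Winners" are
in-model predictions at or above 7.5.

### Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| objective weights α, β, γ, δ, ε | 1, 20, 20, −1, 0.03 | mixed | unit-improvement bookkeeping above |
| weight step schedule | 0.2, 0.1 | weight | coarse-then-fine descent; result locally optimal at 0.1 |
| max cycles per stage | 10000 | — | safety cap; convergence is typically far earlier |
| envelope η, κ, λ | −2.0 pKi, −0.75 Å, 0.15 Å | | −0.05 pKi at 0.2 Å, half-penalty at 0.75 Å, cap −2 |
| envelope margin | 0 Å | | penalty starts at the van der Waals union surface; the sigmoid already tolerates ~0.3 Å nearly free |
| `sigma_act` | 1.0 pKi | | parsimony activity-weight width |
| redundancy thresholds | 2.0 / 1.5 / 1.5 Å | steric/donor/acceptor | skews against stacked like-kind probes |
| family RMSD cut | 2.0 Å | | binding-mode-scale clusters; the 1.0 Å value is reserved for distribution expansion |
| RT | 0.434 pKi | | room-temperature Boltzmann factor on the log-activity scale |
| winner cut | 7.5 pKi | | ~30 nM; the usual potency bar for screening bookkeeping |

## The synthetic harness

`make_pocket()` builds 4–8 probes on a concave spherical cap
(radius ≈ 5.5 Å) with at least two steric, one donor and one acceptor
probe, all pairwise separations above the redundancy thresholds, and
polar directions facing the bowl.  `sample_ligand_series()` grows
toy tree-ligands of typed pseudo-atoms in the pocket frame: a
scaffold carbon, contact atoms at the probes' complementary sites
(scaffold contacts at the optimum, decorating contacts
quality-graded by a deterministic offset ladder, second-shell steric
contacts for the largest ligands), optional non-contacting arms that
contribute rotatable bonds, and explicit donor hydrogens.  The true
activity is the best pocket score over the ligand's torsion
conformers; recorded activities add Gaussian noise (default 0.4 log
units, matching typical single-laboratory assay reproducibility of
0.3–0.5).  `dissimilar_split()` reproduces a designed-test-set
protocol: greedy max-min dissimilarity selection (blended with mean
dissimilarity to the rest) under a largest-remainder activity-tertile
quota, so the held-out set is structurally diverse while its activity
histogram tracks the full series.

What the generator deliberately does *not* emulate: valence
chemistry and protonation equilibria, conformational strain,
entropy/desolvation, assay heterogeneity beyond i.i.d. Gaussian
noise, and activity cliffs from specific electronic effects.  A
passing recovery suite therefore demonstrates that the induction
machinery can invert its own forward model under realistic noise and
an adversarial split — not that it will match any particular
experimental dataset.

## Validation problem sizes

The end-to-end recovery check induces a model from twelve training
ligands (pocket seed 7, eighteen ligands at noise 0.3 with zero or
one rotatable arm, one-third held out by the dissimilarity split)
with 14-pose pools, ten cliques, and all three polar densities, then
scores the held-out six.  At these conditions the training fit
reaches τ ≈ 0.88 with MAE ≈ 0.6 pKi and the held-out set τ ≈ 0.67
with MAE ≈ 0.6 pKi.  The determinism check builds a smaller model
(eight ligands, six-pose pools) twice and compares the serialized
JSON byte for byte.  The oracle checks run on three-molecule
instances with at most four candidate probes so that exhaustive
enumeration is feasible.

## Numerical choices and degenerate inputs

* Pose pools always retain the molecule's input pose (replacing the
  last-ranked entry if necessary): input coordinates are first-class
  data and must survive pool truncation.
* Pool deduplication removes poses within 0.05 Å RMSD; ties in every
  greedy scan break toward the lowest index.
* The prediction-side rigid refinement is deliberately light (one
  sweep, 0.1 Å / 0.05 rad): training scores are pool maxima without
  per-pose polishing, and a more aggressive score maximization at
  prediction time would bias predictions upward relative to the
  training calibration.
* `parsimony()` returns 0 with a warning when all pair weights
  vanish; a single-molecule clique takes the same path.
* A probe set with zero probes is rejected by `interaction_score()`;
  an empty pool list is rejected by `place_candidate_probes()`;
  zero-atom structure records are reported by record index.
* `curate_activities()` is idempotent, and averages duplicates before
  the 2-log-unit disagreement filter, so the filter sees the raw
  per-assay range.
* The binarization gap `f(binary) − f(real)` is recorded and flagged
  when it exceeds 1.0 objective unit.

## Known limitations

* The score is a surrogate with generous Gaussian wells; an atom can
  satisfy two adjacent steric probes at once, which inflates scores
  of very large ligands and is the main source of held-out
  overprediction (visible as rising `pExcl` before it appears in the
  error).
* Free-pose maxima are upward-biased estimators; training absorbs
  the bias through probe placement, but ligands far from the
  training manifold inherit it — exactly what the applicability
  domain metrics are for.
* The novelty metric saturates at 1 once the training union covers a
  pose's field, so `pNov` concentrates at 0.5 for in-coverage
  ligands; it discriminates only in the novel direction.
* Substructure constraints match by element-colored subgraph
  isomorphism; symmetry-equivalent matches are resolved by taking
  the least-penalized one, which is deterministic but can mask a
  genuinely strained alternative mapping.
* Serialized models (`write_pocketmol()`) carry everything needed to
  score new ligands but not the training pose pools, so distribution
  re-estimation and incremental training require the in-memory
  object.
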