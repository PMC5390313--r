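---
title: "Fold recognition in an empirical structure feature space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fold recognition in an empirical structure feature space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pessr)
```

## The model

Protein domains that share a three-dimensional topology (a SCOP *fold*)
tend to score similarly when threaded against the same set of structure
templates. `pessr` exploits this by using a fixed, ordered library of
templates as landmarks: a domain's feature vector is its vector of
compatibility scores against every template (an empirical kernel map),
so a library of $p$ templates defines a $p$-dimensional feature space in
which domains of one fold occupy a compact region. Classification then
reduces to geometry in that space:

* **1NN** — a query takes the fold of its Euclidean-nearest training
  example. Because it needs only one example per fold, it scales to the
  full fold inventory, including *orphan* folds (a single training
  example), and adding training data requires no refit.
* **One-vs-all linear SVM** — one binary linear decision function per
  *large* fold (at least `min_examples = 10` training examples), each
  trained fold-vs-rest with misclassification penalty $C = 1/N$, $N$
  being the fold's positive count, so that abundant folds are not
  favoured simply for being abundant. A query's confidence for a fold is
  its signed distance to that fold's hyperplane.
* **Combined two-phase classifier** — every query first goes to the SVM;
  queries whose best confidence is strictly positive take that fold
  (phase `svm`). The rest fall through to a 1NN model trained only on
  the small-fold examples (phase `nn`), so every query is labelled.

Raw scores are made comparable across templates by per-template
z-standardization. The mean and standard deviation of each template
column are learned **from training rows only** and applied unchanged to
queries; all distances, thresholds and hyperplanes live in this
standardized space. Standardization uses the population standard
deviation (divide by $n$); a zero-variance column keeps divisor 1, so a
constant template contributes nothing to any distance rather than
producing NaNs. The `provenance` flag of a `PessMatrix`
(`"trained-on"` vs `"transformed-with"`) records which side of that
contract a matrix is on, and the cross-validation harness refits the
standardization inside every fold so no test information reaches the
transform.

## Open-set rejection and its calibration

A proteome contains domains whose fold is in no training set. The
classifier therefore supports rejection: with a distance threshold $t$,
a query is classified only when its nearest-neighbour distance is
*strictly below* $t$, otherwise it is assigned `NO_CLASSIFICATION` (the
boundary goes to rejection). The threshold is calibrated by a
leave-own-fold-out procedure (`leaveFoldOutDistances`): for each
labelled query we record its NN distance to the full training set
($d_{with}$) and after removing all training rows of its own fold
($d_{without}$). The second population emulates fold-absent queries. At
each grid value $t$,

* FPR$(t)$ = fraction of $d_{without} < t$ (fold-absent queries wrongly
  accepted),
* FNR$(t)$ = fraction of $d_{with} \ge t$ (fold-present queries wrongly
  rejected),

and the chosen threshold minimises $|$FPR $-$ FNR$|$, ties going to the
smaller $t$. The literature that motivated this design names the two
rates but not their construction; the definitions above are this
package's documented interpretation and are echoed in the calibration
report metadata. The default grid runs from 0 to the largest observed
distance in steps of 0.5. `thresholdPresets()` ships the three workflow
constants used by the reference analysis this package operationalises —
classify 17.5, exploratory 20, novelty 30 — but these are defaults of a
particular trained space, **not** transferable constants: the
standardization choices above (population sd, zero-sd floor) affect the
distance scale, so any new template library or training set should be
recalibrated with `calibrateThreshold()`.

## Novel-fold candidates

Domains whose nearest neighbour is at or beyond the novelty threshold
are candidates for folds absent from training. Their standardized
feature rows (only the selected subset is embedded) are projected to 2-D
with an exact t-SNE (perplexity 10, PCA initialisation, fixed seed) and
clustered with DBSCAN (`eps = 5`, `min_samples = 5`, the point itself
counted in its own neighbourhood). Clusters whose mean residue length
exceeds 500 are flagged: typical domains are far shorter, so such
clusters usually indicate unsplit multi-domain segments rather than one
novel fold. Unclustered (noise) points are reported separately since an
isolated domain can be the single representative of a novel fold.

The t-SNE implementation is exact (no Barnes-Hut approximation), which
is appropriate for the subset sizes this stage sees (tens to a few
thousand points). The learning rate defaults to
$\max(n / \text{exaggeration} / 4, 50)$: a fixed large rate, tuned for
tens of thousands of points, overshoots badly on small inputs. Seeded
runs are reproducible on one platform; across platforms only the
geometry (which points are close) is stable, so tests and downstream
checks rely on separation statistics and cluster structure, never on
raw coordinates. `eps` is in embedding units and should be judged
against the embedding's own scale (e.g. a multiple of the typical
nearest-neighbour spacing) when the point count differs greatly from
the reference workflow.

## Data handling

`readAstralFasta` parses the Astral header dialect (`>sid sccs ...`),
tolerantly keeping records with an unparseable classification string
(`fold = NA`, flagged). `parseScopCla` reads `dir.cla`-style annotation
files. The redundancy filter removes a record when some reference
sequence matches it with identity $> 0.25$ over at least $0.9$ of the
*record's* length; identity and coverage come from the optimal
Smith-Waterman local alignment (BLOSUM62, gap open 11 / extend 1)
rather than a BLAST search, which keeps the package free of external
binaries and downloads; no e-value gate is applied. "Length" in the
coverage rule is read as the length of the sequence being filtered,
since that is the sequence whose redundancy is in question.
`makeSplit` reproduces the anchored-subset protocol: optional removal of
template-similar records, removal of records shorter than 25 residues
(threading engines fail on very short sequences), anchors to training
and the rest to test, and removal of test records whose fold has no
training representative. Every removed record carries exactly one
reason code.

The built-in scorer (`standInScore`) is a Smith-Waterman local-alignment
similarity (BLOSUM62, affine gaps 11/1, floored at 0). It is a
*sequence* compatibility score standing in the pipeline position of a
structural threading score so that the full pipeline runs at desk scale;
it is emphatically not a threading score, and real analyses should feed
externally computed threading scores through the score-matrix TSV
interchange format (`readScoreMatrix`), whose column set is validated
and reordered against the template library.

## The synthetic generator

`generateSyntheticPess` emulates the one premise the method rests on:
folds occupy compact, separated regions of the feature space. Fold
centroids are placed on orthonormal directions scaled so that every
pairwise centroid distance is exactly $\Delta$
(`centroid_separation`), and members scatter isotropically with
dispersion $\sigma$ (`noise_sd`) measured on the distance scale: the
per-coordinate noise sd is $\sigma/\sqrt{p}$, so the RMS displacement of
a member from its centroid is $\sigma$ in any dimension. This makes
$\Delta/\sigma$ a dimension-free separation ratio — the quantity the
package's property tests sweep. (Defining $\sigma$ per coordinate
instead would make the within-fold spread grow as $\sigma\sqrt{2p}$ and
the ratio meaningless across dimensions.) The generator does **not**
emulate correlated template scores for homologous templates, fold-size
imbalance beyond explicit member counts, or any length dependence of
raw scores — passing tests on synthetic data therefore demonstrate the
correctness of the machinery under the stated geometry, not performance
on real threading output.

`generateThresholdTestbed` adds held-out centroids on the same
orthonormal frame and draws a stated fraction of queries from them,
giving ground-truth fold-absent queries for calibration tests; the
frame capacity (folds + held-out folds $\le$ templates) bounds the
rejection fraction. `generateToySequences` emits mutated copies of
random base sequences at scheduled identity levels for exercising the
redundancy filter with measured ground truth.

```{r generator}
sim <- generateSyntheticPess(n_folds = 6, members_per_fold = 4,
    n_templates = 30, centroid_separation = 6, noise_sd = 1, seed = 1)
std <- standardizeTrainTest(sim$scores)
model <- trainNN(std$train, sim$labels, params = std$params)
classifyNN(model, std$train)[1:3, ]
```

## Numerical and design choices

* **Tie-breaking is deterministic everywhere**: equal NN distances go to
  the lowest training row index, equal SVM confidences to the
  lexicographically first fold label, equal calibration balance to the
  smaller threshold, and the top-template baseline to the lowest column
  index.
* **SVM backend**: libsvm via e1071 (linear kernel, no internal
  rescaling, tolerance $10^{-4}$, settings recorded in the model
  metadata). The per-fold penalty is applied as each binary problem's
  cost constant — the natural reading of "C = 1/N" in a one-vs-all
  scheme; a global C with per-class weights would be an alternative
  reading, and the constant is exposed should a user want to study the
  difference. Hyperplanes are stored as explicit weight vectors and
  offsets, oriented so positives score higher, which makes confidences
  backend-independent linear algebra. Confidences are geometric signed
  distances (decision value over weight norm) by default; raw decision
  values are available via `scale_by_norm = FALSE` for parity with
  solvers that report them.
* **Population sd** in standardization is a convention choice; with the
  training set sizes this method targets (thousands of rows) the
  difference from the sample sd is negligible, but it does mean
  distance-threshold constants are tied to this package's transform.
* **Baseline**: `topTemplateBaseline` assigns the fold of the
  highest-scoring raw template — the control showing that the feature
  space as a whole, not the single best template, carries the signal.
* **Degenerate inputs** are first-class: constant templates (zeros after
  transform), identical t-SNE rows (finite coordinates), empty novelty
  selections (explicit error naming the minimum), single-row training
  matrices (refused — sd undefined for the intended use).

## Problem sizes in the shipped checks

The test-suite and the acceptance script run entirely on the synthetic
generator, at sizes chosen to exercise every code path while keeping a
full run in the tens of seconds: oracle comparisons up to 200 training
rows and 100 feature dimensions, fold recovery at 20 folds of 5 members
over 10 generator seeds, calibration testbeds of 8 training folds with
half the queries fold-absent, clustering instances of 60 points, and a
sequence-level mini-pipeline of 6 template families. These sizes are
statements about the synthetic geometry, not about the method's
capacity; the real workflow was designed for proteome-scale inputs with
threading scores computed externally and fed in as TSV.

## Known limitations

* The stand-in scorer measures sequence, not structural, compatibility;
  pipeline results with it are demonstrations of machinery.
* Threshold constants do not transfer across template libraries,
  training sets or standardization conventions; recalibrate.
* The SVM loss/solver configuration of the original analysis is not
  fully specified in the literature; any linear max-margin solver
  satisfies the contract here, with settings recorded in metadata.
* t-SNE + DBSCAN cluster counts depend on embedding scale; `eps` wants
  re-judging when the selected subset is much smaller or larger than in
  the reference workflow.
* Macro precision/recall follow the zero-denominator exclusion rule;
  with heavy rejection, excluded-fold counts should be read alongside
  the averages.
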