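---
title: "Methods: chemical-transporter interaction screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical-transporter interaction screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txscreen)
```

txscreen predicts whether a small molecule interacts with each of twelve
drug transporters, in two independent binary endpoints per transporter
(*inhibitor* and *substrate*). Data-rich targets are scored by a directed
message-passing neural network (D-MPNN) ensemble; data-poor targets by
maximum Tanimoto similarity to a reference set of known actives. Every
prediction carries an applicability-domain score so that out-of-domain
calls can be masked. This vignette explains the model and the numerical
choices; function reference documentation covers the interfaces.

## Standardization

Every structure that enters the package passes through
`standardize_smiles()`: a validity check (the SMILES must parse), canonical
rewriting (so equivalent spellings become one string), and salt stripping
(keep the largest organic fragment of a multi-fragment input). The chemistry
itself is delegated to OpenBabel via ChemmineOB; the salt-strip keeps the
fragment with the most heavy atoms among those containing carbon, with ties
broken lexicographically so the choice is deterministic.

```{r}
standardize_smiles(c("OCC", "CCO.Cl", "[Na+].[Cl-]"))
```

Structures with identical canonical SMILES but conflicting labels are
removed entirely by `dedupe_dataset()` — neither label can be trusted, and
keeping either would leak a coin flip into training.

## Fingerprints and similarity

`morgan_fp()` implements a circular (ECFP-like) fingerprint by iterative
neighborhood hashing: each atom starts from an invariant over element,
degree, formal charge, hydrogen count, aromaticity and ring membership;
each of `radius` rounds (default 2) folds in the sorted multiset of
(bond class, neighbor identifier) pairs. Identifiers from every level are
reduced modulo the bit-set width (default 2048). Because neighbor pairs are
sorted before hashing, the bits are invariant to atom input order — a
property the test suite checks explicitly.

The hash is a deliberately simple multiply-and-add scheme over a 2^31
modulus, kept in pure R double arithmetic (all intermediate values stay
well below 2^53, so the arithmetic is exact). Bit collisions merely fold
environments together, which is the usual fingerprint trade-off; they never
affect the identity `tanimoto(a, a) == 1`.

Screening for data-poor targets uses the MAX score — the maximum Tanimoto
similarity between a query and any reference active
(`max_similarity()`) — with 0.5 as the default call threshold.

## Applicability domain

The SDC score sums distance-weighted contributions over the training set:

$$\mathrm{SDC} = \sum_i \exp\!\left(\frac{-3\,TD_i}{1 - TD_i}\right),$$

where $TD_i$ is the Tanimoto distance to training molecule $i$. The weight
is 1 at $TD = 0$ and decays rapidly; at $TD = 1$ the expression is an
indeterminate form whose continuous limit is 0, and the implementation
returns exactly 0 there. The in-domain threshold is calibrated per model by
`calibrate_sdc_threshold()`: each training molecule is scored against the
other $n-1$ (leave-one-out) and the 5th percentile of that distribution
(type-7 quantile, R's default) becomes the cutoff, so roughly 95% of the
model's own chemistry would be called in-domain.

## The D-MPNN classifier

`train_dmpnn()` implements message passing over *directed bond edges*. The
hidden state of edge $v{\to}w$ is initialized from the source-atom and bond
features through a linear map and ReLU; each of depth−1 refinement rounds
replaces it with
$\mathrm{ReLU}(H^0 + W_h \sum_{k \in N(v)\setminus\{w\}} H_{k\to v})$ —
the sum over edges incoming to $v$ *excluding the reverse edge*, so
information does not immediately reflect back along the bond it arrived on.
Atom vectors are the sums of their incoming edge states passed through a
linear layer; the molecule vector is the mean over atoms; a 2-layer
feed-forward head produces one logit.

Implementation note: the excluded-reverse sum is computed as (atom-wise
incoming sum indexed at the source atom) minus (state of the reverse edge),
which needs only atom-by-edge incidence matrices rather than an
edge-by-edge adjacency matrix — the same numbers, substantially less sparse
algebra per step.

Defaults follow the published setup for these endpoints: depth 3, hidden
size 300, 30 epochs, batch size 50, a 10-member ensemble whose prediction
is the mean member probability, and Adam under a Noam-style schedule
(linear warmup from 1e-4 to 1e-3 over two epochs, then exponential decay
back to 1e-4 by the final step). Training minimizes mean binary
cross-entropy computed stably from logits. One deliberate simplification:
minibatch *membership* is drawn once per run and only the visiting order is
reshuffled each epoch; this keeps the precomputed batch graphs reusable
across epochs, and with 30 epochs over randomized batches the difference
from full per-epoch reshuffling is well inside seed-to-seed noise.

All gradients are hand-derived. Correctness is enforced by a finite-
difference check in the test suite (relative error below 1e-5 across all
parameter groups; observed around 1e-7). Training is single-threaded and
deterministic given the member seed; ensemble member $m$ uses seed
`seed + m - 1`.

## Evaluation conventions

`classification_metrics()` reports sensitivity, specificity, accuracy,
balanced accuracy and MCC from a confusion table; MCC is defined as 0
whenever a denominator factor vanishes (the standard convention for
one-sided prediction vectors). `roc_curve_auc()` computes the AUC as the
midrank Mann-Whitney statistic, i.e. the probability that a random positive
outscores a random negative with ties earning half credit — exactly the
exhaustive concordant-pair count, which the acceptance tests verify on
every label pattern of length ≤ 8. `pr_curve_auc()` uses step-wise
interpolation (precision summed over achieved recall increments), not
linear interpolation, which is optimistic for PR curves.

`scaffold_split()` groups molecules by Bemis-Murcko framework (ring systems
plus linkers, side chains pruned; acyclic molecules are their own singleton
class) and fills the test side whole-group, largest group first, so no
scaffold ever appears on both sides. `cross_validate()` runs seeded k-fold
CV, scoring each record exactly once out-of-fold.

## Synthetic study data

Because the published training sets live in external repositories, the
package ships seeded generators whose structure-label relationship is known
exactly:

* `generate_motif_dataset()` assembles alkyl backbones with ring and
  heteroatom substituents; positives carry a grafted carboxylic-acid motif
  and negatives are *verified* motif-free by SMARTS substructure search, so
  at zero label noise the Bayes-optimal classifier is perfect and any gap
  from AUC 1.0 is attributable to the learner.
* `generate_similarity_benchmark()` mirrors the retrieval setting for
  data-poor targets: reference compounds and external actives are decorated
  variants of one fused-ring (naphthalene) family with potencies ≤ 1 µM,
  inactives come from disjoint acyclic/monocyclic families with potencies
  ≥ 10 µM, and the gray zone in between is dropped by the evaluation
  protocol, as are reference-set duplicates.

These generators are *study conditions*, not tuning knobs: the acceptance
runs use their documented defaults. What the synthetic studies do **not**
show: performance on real pharmacological endpoints, where labels are far
noisier, actives are not defined by a single local motif, and chemistry is
much more diverse. A model that clears the synthetic bar has demonstrated
correct mechanics (featurization, optimization, evaluation), not
transporter-level accuracy — for that, see the external validation recipe
below.

## Registry and batch profiling

The packaged registry (`load_registry()`) mirrors the published
twelve-transporter assignment: 24 (target, mode) entries, 9 using the
D-MPNN ("gcnn") approach where training data are plentiful (six inhibitor
targets: Pgp, BCRP, MRP1, BSEP, OATP1B1, OATP1B3; three substrate targets:
Pgp, BCRP, MRP1) and 15 using similarity screening. The shipped
configuration carries no model artifacts — models are fitted on user data
with `fit_transporter_model()`, saved with `save_transporter_model()`, and
referenced from the registry JSON by path. `profile_batch()` then scores
every valid query against every registered model, producing exactly
|queries| × |models| rows, with invalid inputs retained as
`rejected:<reason>` rows so that batch accounting stays auditable.
`write_profile()` emits a long-format CSV plus four call matrices
(inhibitor/substrate × unmasked/AD-masked); masking replaces only
out-of-domain cells with a sentinel and never alters an in-domain value.

## Limitations

* Aromaticity is re-perceived from OpenBabel's kekulized output with a
  Hückel-style electron count over detected rings of size 5-7. Common
  heteroaromatics (pyridine, furan, pyrrole-like rings, fused benzenoids)
  are handled; exotic systems (e.g. azulene-like perimeter aromaticity,
  charged rings) may be classified as non-aromatic, which shifts fingerprint
  bits and network features consistently but away from chemical convention.
* Stereochemistry is carried only as a per-bond "marked" flag in the
  network features; fingerprints are stereo-blind, as is standard for
  2D circular fingerprints.
* The similarity approach presumes the reference actives span the relevant
  chemotypes; its AD threshold (leave-one-out 5th percentile) is meaningful
  only for reference sets of a few dozen members or more.
* Training is pure R on one CPU; at the default scale (hundreds of
  molecules) a 30-epoch member takes a few minutes. The implementation is
  not intended for datasets beyond the low tens of thousands.

## External validation recipe

To validate against real transporter data rather than synthetic fixtures:

1. Obtain a curated labeled dataset per target — e.g. the published
   transporter inhibition/substrate collections, or a ChEMBL/DrugBank
   export — as a CSV with `smiles` and `activity` (0/1) columns.
2. Load and clean: `ds <- dedupe_dataset(read_smiles_dataset("pgp.csv",
   mode = "inhibitor"))$dataset`. Inspect the dedupe report for conflicting
   labels.
3. Cross-validate at the published scale:
   `cv <- cross_validate(ds, dmpnn_config(), k = 5)` and inspect
   `glance(cv)`. For the six data-rich inhibitor targets, mean ROC-AUC in
   the mid-0.8 range (and MCC well above 0.2) is the expected band; markedly
   lower values indicate a data or preprocessing problem rather than noise.
4. Probe novel-chemotype generalization with
   `scaffold_split(ds, 0.2)` + `train_dmpnn()`, which is harder than random
   CV and typically a few AUC points lower.
5. Fit production models on the full set with `fit_transporter_model()`,
   save them, reference them from a registry JSON, and screen with
   `profile_batch()`, reporting the AD-masked matrices.

The final acceptance gate for this recipe is scientific, not mechanical,
so it is documented here rather than enforced in the test suite; the suite
does verify that every step of the recipe runs end-to-end on packaged data.
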