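---
title: "Methods: taste prediction, consensus confidence, and atom attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taste prediction, consensus confidence, and atom attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the modeling stance

Taste perception begins with a molecule binding taste receptors, so to a
useful approximation the taste class of a small molecule is a function of
its structure. `tastekit` treats this as five-way classification — sweet,
bitter, sour, umami, undefined — over molecules given as SMILES strings.
Two classes deserve comment. *Salty* is deliberately not a class: saltiness
is carried by small ions and their solution properties, not by molecular
graph structure, so a structure-based classifier has nothing to learn
there. *Undefined* is the absorbing class for tasteless molecules, salty
compounds, ambiguous profiles, and out-of-domain structures; keeping it in
the label set lets a model flag sodium chloride or a paraffin as "not a
structural tastant" instead of forcing a wrong class.

Multi-taste molecules (the classic case is bittersweet) are represented as
duplicated rows sharing a canonical SMILES with different labels. Models
are trained and scored on single-label rows; the multi-label analysis
(`multilabel_eval()`) probes how a probability vector distributes mass over
a molecule's several true labels.

## Curation

Public tastant collections overlap heavily and mix conventions, so the
package fixes a deterministic filter cascade with per-stage attribution:

1. **invalid** — strings from which no molecular graph can be built;
2. **multiple uncharged fragments** — typically a tastant recorded with a
   solvent; removed rather than guessing which fragment matters. Charged
   fragment pairs (salts) are *not* removed here;
3. **charged** — any formal charge on any atom. Zwitterions with zero net
   charge are also removed: the stated purpose of the filter is to exclude
   species whose counter ions are missing, and a per-atom criterion is the
   conservative reading;
4. **molecular weight** — keep strictly below 2000 Da (ties removed). The
   cutoff exists so token sequences stay inside a small language model's
   context window;
5. **deduplication** on the *(canonical SMILES, label)* pair, so
   multi-taste duplicates survive while true duplicates collapse; the first
   occurrence's source wins.

The order is pinned because the report attributes each removed row to
exactly one stage; an invalid multi-fragment string counts as invalid,
never twice. `n_input = n_output + Σ removed` holds identically and is
fuzz-tested.

The canonical form is the toolkit default of the cheminformatics backend
(OpenBabel's canonical SMILES writer), and that choice is recorded in every
`taste_config()` under `canonicalization` so models carry their own
provenance. Canonicalization here is stereo-agnostic: standardization runs
through a kekulized connection table without coordinates, which does not
preserve wedge/hash stereo, and the classifiers make no use of stereo
descriptors. This is a documented limitation, consistent with the general
insensitivity of token-level classifiers to stereocenter inversion (L- and
D-enantiomers tokenize almost identically).

Train/test splitting groups rows by canonical SMILES before assignment.
Nothing in a multi-label molecule's rows can end up on both sides, and the
intersection of train and test canonical SMILES is empty by construction —
verified across 50 seeds in the tests.

## Featurization

Tree-based backends use 1024-bit, radius-2 Morgan (circular neighborhood)
fingerprints. Bits are computed on the canonical molecular graph — inputs
are canonicalized first — which makes feature vectors exactly invariant to
the SMILES form, including re-kekulization effects that would otherwise
perturb bond-order-dependent neighborhoods. Atom invariants are element,
heavy degree, implicit hydrogen count, formal charge and ring membership;
neighborhoods are hashed order-independently (sorted neighbor invariants)
so atom numbering cannot leak into the bits.

An optional block of 15 topological descriptors (counts, ring and branching
statistics, Wiener index, hydrogen-bond donor/acceptor counts, molecular
weight) can be concatenated. The exact 15-descriptor identity is a
documented default registry, not a law: `descriptor_vector()` accepts any
subset or ordering, making the choice configuration rather than code.
Non-finite descriptor values are replaced by 0 with a warning rather than
failing a whole batch.

## Classifier backends

All backends sit behind `taste_train()` / `predict_proba()` and emit
normalized five-class probability vectors in a fixed label order; argmax
ties (rare but possible with tree vote counts) break toward the lower label
index, deterministically.

* **gbt** — gradient-boosted trees on fingerprints. Depth and shrinkage
  default to 6 and 0.3; a small seeded grid over both, scored by held-out
  multiclass log-loss, is available through `grid` in the config.
* **rf** — a 150-tree random forest.
* **balanced_rf** — the same forest with stratified undersampling: every
  bootstrap draws the minority-class count from *each* class, so trees see
  balanced data. The per-tree in-bag counts are asserted equal in tests.
  This trades majority-class information for minority recall; on imbalanced
  tastant data it typically costs overall accuracy, which is why it is a
  backend, not the default.
* **token_lm** — a small transformer encoder over SMILES tokens: learned
  token embeddings plus sinusoidal positions, two single-head
  self-attention blocks with residual connections and a ReLU feed-forward,
  mean pooling, linear head. The forward and backward passes are written
  explicitly in R; the backward pass is validated against finite
  differences and doubles as the gradient engine for attribution. The
  fine-tuning recipe is: categorical cross-entropy, batch size 16, decoupled
  weight decay 0.01, learning rate 1e-5 by default (the right scale for
  fine-tuning a pre-trained checkpoint; training this small model from
  random initialization in tests uses 1e-2 to 3e-3), and per-epoch
  evaluation loss on a held-out slice with the best checkpoint retained.
  Epochs default to 20 without augmentation and 2 with 10-fold
  augmentation, matching the convention that augmentation multiplies the
  effective epoch count.

The regex SMILES tokenizer emits one token per atom (including two-letter
elements and bracket atoms) plus structural tokens; token order equals atom
order in the molecular graph, which is what makes token-to-atom attribution
a direct mapping. The vocabulary is sorted with a locale-independent radix
sort so trained models are reproducible across systems.

**Training-time augmentation** expands every molecule to k random
synonymous SMILES with the parent's label, uniformly across classes.
Uniformity is a correctness requirement, not a tuning choice: augmenting
classes unevenly teaches the model the augmentation rate rather than the
chemistry (a model fed mostly-augmented minority classes learns to map
*canonical-looking* strings to the majority class). Synonymous strings are
generated by seeded atom-order permutation of the connection table followed
by the order-sensitive SMILES writer; every variant canonicalizes back to
its source, a property asserted at scale (5000 variants) in the tests.

## Consensus confidence

`consensus_predict()` draws k synonymous SMILES (k = 10 by default — a
reasonable ensemble even for small molecules; the number is user-settable),
predicts each, and votes on argmax labels. The modal label is accepted iff
its count reaches the threshold (default: unanimity, τ = k) *and* the mode
is unique; a tied mode abstains, the conservative reading. Voting is on
labels, not averaged probabilities, because agreement-of-decisions is the
quantity with the abstention semantics; the averaged probability vector is
still returned for AUROC computation. All k variants are sampled
independently; the canonical string is not guaranteed a seat in the
ensemble (the sampler may of course produce it).

Support — the fraction of molecules given a non-abstained label — is
reported alongside every confidence evaluation. Under abstention, accuracy
and the per-class metrics are computed on the accepted subset only, with
support carrying the cost; this matches the convention of reporting a
support column next to headline metrics. For backends whose features are
form-invariant (the tree models), every variant yields the same prediction
and support is exactly 1 — a structural fact used as a test.

## Integrated gradients

For a scoring function F, input x and baseline x′ (the zero embedding), the
attribution of feature i is (xᵢ − x′ᵢ) times the path integral of
∂F/∂xᵢ along the straight line from x′ to x. The integral is discretized
with a composite midpoint rule, 64 steps by default. Choices worth stating:

* **What x is.** For the token model, x is the full input representation
  (token embeddings plus positional encodings) and the baseline is the zero
  matrix; a token's attribution is the sum over its embedding dimensions,
  and atom-bearing tokens map to atoms. Attribution mass on structural
  tokens (bonds, digits, parentheses) is reported as `residual_nonatom`, so
  atom scores plus residual always reconstruct the total.
* **Logit vs probability.** Attribution differentiates the raw class logit
  by default (probability-space gradients vanish wherever the softmax
  saturates, which is exactly where trained models live); a flag switches
  to probability.
* **Discretization error.** The midpoint error decays like n⁻² in trend,
  and the completeness identity Σ attr = F(x) − F(x′) holds to ≤2% of the
  score change at 64 steps on trained models. The error's *sign*
  oscillates, so an individual doubling of steps can transiently increase
  the gap when a coarse grid lands near a zero crossing; tests therefore
  assert the decade-scale decay and the 2% completeness bound rather than
  per-doubling monotonicity. For linear scorers the rule is exact at any
  step count (each panel integrates a linear integrand exactly), which the
  tests exploit as a machine-precision oracle.
* **No gradient path for trees.** Tree ensembles get an explicit
  unsupported-backend error rather than a silently different method.

## The synthetic generator

`generate_taste_dataset()` builds molecules from a scaffold-plus-decoration
grammar with a first-match-wins rule set mirroring textbook structure–taste
associations: carboxylic acids (the water-soluble pKa 2–7 regime) → sour;
amides, a recurring umami motif → umami; aliphatic polyols and esters →
sweet; fused or linked polyaromatic, polyphenol-like scaffolds → bitter;
alkanes, ethers and single rings → undefined. The default class mix (61%
sweet, 20% bitter, 10% sour, 1% umami, 8% undefined) reproduces the strong
imbalance of aggregated tastant databases, with umami rare and sweet
dominant. Counts follow the mix by largest-remainder apportionment; label
noise relabels a seeded fraction to a uniformly random other class.

Because the rules are deterministic on the molecular graph, zero-noise
datasets are *exact* ground truth: re-applying the rule set reproduces
every label, a gradient-boosted model recovers the mapping at ≥95% held-out
accuracy, and a token model trained on acid→sour data concentrates its top
positive sour attribution on carboxyl atoms. The generator also emulates
database redundancy — repeated draws produce duplicate canonical SMILES,
which is what makes the deduplication stage meaningful.

What the generator does **not** emulate: the chemical-space breadth of real
tastant collections (its grammar covers a few functional families),
realistic molecular weight distributions, stereochemistry, tautomerism, or
genuinely ambiguous labels whose noise is structured rather than uniform.
Passing tests on this data therefore demonstrate that the pipeline recovers
planted signal under controlled conditions — not that any backend attains a
particular accuracy on real tastants.

`make_curation_fixture()` plants defects in exact counts — unmatched-ring
invalid strings, neutral fragment pairs (tastant "plus water"), charged
species, >2000 Da alkane chains, and duplicates written as non-canonical
rewrites so only canonicalization reveals them — and each defect is caught
by exactly one cascade stage.

## Study sizes and numerical conventions

Test and acceptance runs use deliberately small but sufficient sizes:
2000-record generation for parameter recovery (≈400 unique molecules after
deduplication, 15% held out), 800 records at 15% label noise for the
consensus study (token model, 12 epochs — near its evaluation-loss
plateau), 1200 sour-heavy records and 30 epochs for the attribution study,
500 molecules × 10 variants for augmentation soundness, and 10⁴ fuzzed
cases for the binary-reduction dominance property. These sizes were chosen
once as the smallest at which each property is comfortably demonstrated.

Conventions: 0/0 metric ratios (a class never predicted and/or never true)
are reported as 0 with a `flagged` marker rather than NA, so macro averages
over all five classes stay defined on degenerate test sets; one-vs-rest
AUROC skips (flags) classes lacking both a positive and a negative;
probability vectors are renormalized defensively and asserted to sum to 1
within 1e-9; the multi-label rule uses a *strict* p > 0.2 cutoff, so an
exactly uniform distribution predicts no label.

## Known limitations

* The cheminformatics layer inherits OpenBabel's parsing behavior; a few
  strings other toolkits reject (e.g. an unclosed branch) are tolerated,
  and validity in this package is *defined* as parseability by the backend.
* Stereochemistry is neither standardized nor modeled.
* The token backend is a from-scratch small model: it demonstrates the
  training recipe, consensus and attribution machinery at test scale, and
  accepts larger configurations, but it is not a pre-trained chemical
  language model and its absolute accuracy on real data will reflect that.
* Consensus confidence is a voting heuristic, not a calibrated probability;
  conformal or Bayesian uncertainty is out of scope.
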