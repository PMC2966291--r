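---
title: "Neural grammar networks: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural grammar networks: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling decisions behind `ngn`: the network
construction, the training procedure and its parameters, the conventions
chosen where several readings were defensible, what the synthetic
benchmarks do and do not demonstrate, and the package's known limitations.

## From string to network

A molecule enters the package as a line-notation string (SMILES, or a
simplified InChI). Under a deterministic context-free grammar the string
has exactly one parse tree; the package enforces determinism by building
canonical LR(1) parse tables at grammar load and rejecting any grammar
whose tables contain shift/reduce or reduce/reduce conflicts (canonical
LR(1) accepts a superset of the LALR(1) grammars, so this is at least as
strict a guarantee as LALR(1) conflict-freeness). Parsing itself is
table-driven shift-reduce; the observable contract is the unique tree, not
the algorithm.

Two rule shapes exist. *Acceptance* rules admit one input token from a
token class; *expansion* rules rewrite a symbol into a sequence of
symbols. Expansion rules may also carry inline quoted literals (the SMILES
branch-opening parenthesis is one), which behave as one-token terminal
slots. This mixed shape is required to represent the ten-rule SMILES
teaching subset faithfully: its branch rule places a literal `(` directly
beside an internal symbol, and flattening it into an extra rule would
change both the rule count and every derivation.

The assembled network mirrors the tree: one hidden layer of `hidden_size`
logistic units per internal parse node, a one-hot input per token (a
single processing unit per token the accepting class can admit, the
matched unit at 1.0 and the rest at 0.0), and a one-unit output layer
above the start symbol. Edges do not own weights; they *reference* entries
of a persistent weight-layer library, so the library's size depends only
on the grammar and the accumulated training lives entirely in it.

## Weight-layer binding: two sharing modes

The package implements both defensible readings of how layers bind to the
grammar:

- **`per_symbol_pair`** (default): layers are keyed by (parent symbol,
  child slot), where a symbol's slots are the union of right-hand
  positions over all of its productions (`ngn_child_signature()`), and all
  acceptance rules of one symbol merge into a single terminal slot whose
  vocabulary is the union of their tokens. Under this mode a production
  that does not use a slot leaves it *zero-flushed*: the slot contributes
  a zero activation vector to the parent's net input. This reading is what
  makes zero-flushing meaningful at all, and it is the default because the
  layer-selection rule "indexed by the left-hand and right-hand symbols"
  only produces absent-slot situations under slot sharing.
- **`per_rule`**: one layer per (production, right-hand position). Every
  applied production uses all of its own slots, so no zero-flushing
  arises. This is the reading suggested by drawing one layer stack per
  rule, and it is exposed as `ngn_control(sharing_mode = "per_rule")`.

The two modes generally give different results; nothing in the package
assumes otherwise.

A zero-flushed slot contributes *nothing* to the parent: neither the
matrix product (which is zero anyway) nor its bias, and it receives no
gradient. This convention makes the statement "a weight layer simply is
not updated given the current string" literally true, bias included. The
alternative (always adding every slot's bias) would update biases of
layers whose symbols are absent from the parse, which contradicts the
untouched-layer rule.

Bias placement: each weight layer carries one bias vector at its parent
end. When a parent has several child slots, each present slot's layer
contributes its bias and the contributions are summed. This is a
documented convention; an equally consistent alternative (one bias per
parent node) would merely re-parameterize the same function class when
slots are always present, but differs under zero-flushing.

## Training

Training is online (per-exemplar) gradient descent on squared error with
momentum:

- output gradient δ = (t − o)·o·(1 − o); hidden gradients propagate from
  the root toward the leaves through each node's single parent edge;
- per instantiation of a layer, Δw\_ij = η·δ\_i·α\_j and Δb\_i = η·δ\_i.
  The learning rate η is folded into the instantiation deltas rather than
  applied after summation — equivalent by linearity, fixed for
  bit-reproducibility;
- a shared layer's applied change is the *sum* of its instantiation deltas
  plus `momentum` times its previous applied change; the momentum buffer
  is per layer and per time step, where a time step is one exemplar's
  update (the buffer of an untouched layer keeps its value until that
  layer is next used);
- exemplars are reshuffled every epoch from the run's seeded RNG stream.
  Online updates make presentation order matter, so the order must be
  pinned: identical data, configuration and seed reproduce the final
  library bit for bit;
- epoch RMSE is computed from each exemplar's output just before its own
  update; training converges when it drops below `rmse_threshold`;
- if `max_epochs` is exhausted, the library is re-initialized from fresh
  random weights drawn from the continuing RNG stream and training
  restarts, up to `max_restarts` (default 3) times, after which the fit is
  returned with `converged = FALSE`. Non-converged fits are excluded from
  cross-validation aggregates.

The gradient sign convention was fixed by requiring that updates descend
the squared error; the test suite verifies every analytic delta against
central finite differences (step 1e-5, relative tolerance 1e-4) on
seeded random networks, and verifies the summed-update law exactly.

Initial weights and biases are drawn uniformly from the two-band range
[−`init_high`, −`init_low`] ∪ [`init_low`, `init_high`], band chosen
equiprobably. The default bands [1.0, 1.6] start the logistic units away
from their flat center, which shortens convergence; `init_low = 0`
degenerates to a plain uniform and is how the descriptor-ANN baseline's
(−0.3, 0.3) initialization is expressed.

### Parameter presets

`ngn_control()` ships four presets (overridable field by field):

| preset | η | α | RMSE | epochs | hidden | init bands | output scale |
|---|---|---|---|---|---|---|---|
| `classification` | 0.60 | 0.90 | 0.05 | 5000 | 8 | 1.0–1.6 | (0.2, 0.8) |
| `regression_cv` | 0.30 | 0.10 | 0.03 | 7500 | 8 | 1.0–1.6 | (0.2, 0.8) |
| `regression_designed` | 0.33 | 0.66 | 0.04 | 7500 | 8 | 0.4–1.2 | (0.2, 0.8) |
| `toxicology_ngn` | 0.30 | 0.30 | 0.05 | 10000 | 12 | 1.0–1.6 | (0.2, 0.8) |

The toxicology preset also carries `pretest_rmse = 0.03`, a stricter
threshold for convergence-competence pre-tests on a whole dataset (a
sanity check that a dataset is learnable at all before cross-validation);
the two thresholds are deliberately distinct fields. Targets are mapped
onto the output scale — labels to its endpoints, regression activities by
min-max normalization `ngn_normalize()`, which sends the dataset minimum
to 0.2 and maximum to 0.8 so targets stay inside the logistic range with
headroom. Predicted classes use the midpoint of the output scale (0.5) as
the decision threshold, ties counting as positive; both the threshold and
the direction of activity-based labeling (`ngn_label_by_threshold()`,
at-or-above = positive) are documented conventions with flags to invert.

## Statistics

`ngn_classification_metrics()` computes Q, SE, SP and MCC from confusion
counts, with MCC defined as 0 whenever a factor of its denominator
vanishes. `ngn_q2()` computes PRESS, SD (sum of squared deviations of the
*test-set targets* from their own mean) and q² = 1 − PRESS/SD; constant
test targets are an error rather than a silent 0/0. `ngn_epsilon()` sums
*absolute* residuals — "approaches zero only as residuals vanish" is then
literally true — with a `signed` flag for the cancelling variant, and
reports the spread of a single pair as 0. `ngn_wilcoxon()` drops zero
differences, average-ranks ties, and computes the exact null of the
positive-rank sum by enumerating all 2^n sign patterns for n ≤ 12 (valid
under ties, unlike classical exact tables), switching to a tie-corrected,
continuity-corrected normal approximation above; the default is two-sided.
Method comparison (`ngn_compare()`) pairs trials by fold structure and
declares a winner at p < 0.05, smaller Epsilon (or spread) winning.

## The synthetic-data generator

`ngn_sample_string()` performs a stochastic leftmost derivation: uniform
choice among the productions of a symbol, restricted to productions whose
right-hand symbols can still bottom out within the remaining depth budget,
so generation always terminates and every sampled string parses under the
generating grammar (a property the suite tests). Token-level weights can
tilt the choice among and within acceptance rules; the packaged tasks
default to down-weighting oxygen (`c(O = 0.25)`), which mirrors the
carbon-dominated composition of organic molecules and keeps the
token-absent class well populated when balancing classification sets.

`ngn_make_dataset()` draws unique strings (duplicates are resampled, so
contradictory exemplars cannot block convergence), balances classification
sets to an even split, and min-max-normalizes regression scores onto
(0.2, 0.8) after optional Gaussian noise. Four label rules are provided:
token presence, literal substring presence, token-count threshold, and
scaled token count (regression). Substring presence is deliberately a
*topology* rule — whether a branch opens right after a carbon — because
token-count descriptors cannot express it; the suite uses it to
demonstrate the directional advantage of the grammar network over the
count-descriptor baseline.

What the generator does *not* emulate: chemical validity beyond syntax
(no valence checking), realistic activity distributions, assay noise
structure, activity cliffs, or the scaffold redundancy of curated QSAR
datasets. Passing the synthetic benchmarks therefore shows that the
machinery — parsing, assembly, gradients, weight sharing, convergence,
evaluation — is correct and that grammar-visible structure is learnable;
it does not certify predictive performance on real medicinal-chemistry
data.

### Benchmark problem sizes

The suite's heavier checks use: 200 molecules (depth budget 12) for the
contains-oxygen classification benchmark, requiring convergence in at
least 8 of 10 seeds and held-out concordance ≥ 0.85 over one 80/20 split
per seed; 150 molecules for scaled-carbon-count regression, requiring
held-out-fifth q² ≥ 0.5 in at least 3 of 5 seeds; and 120 molecules over
two seeds for the NGN-versus-ANN topology comparison. These sizes keep
each benchmark's full multi-seed loop in the tens of seconds on one CPU
core while leaving the acceptance margins wide.

## Numerical and degenerate-input choices

- Tokenization is greedy longest-match (needed so `Cl`/`Br` beat
  `C`/`B`). Because the sampler emits token sequences that the lexer
  re-reads, every two-character token in the shipped grammars is chosen so
  it is not the concatenation of two shorter tokens; bracket elements
  violating this (tin, lead) are omitted from `smiles_extended`.
- Token positions are 0-based character offsets.
- A token may belong to exactly one acceptance rule (or be an inline
  literal, but not both); this makes token dispatch unambiguous and is
  validated at grammar load.
- Grammars failing the LR(1) determinism check are rejected at load;
  `allow_conflicts = TRUE` accepts them with a warning, resolving
  conflicts by preferring shifts and the first-listed rule.
- The output head is a dedicated trainable 1×`hidden_size` layer above
  the start symbol: QSAR targets are scalar and the output scale (0.2,
  0.8) presumes a single logistic output.
- Degenerate inputs fail loudly: empty strings, constant normalization
  inputs, constant-target q², zero-variance correlations, all-zero
  Wilcoxon differences, and unparseable exemplars each raise a specific
  error naming the offending quantity or string.
- Model archives are versioned JSON at full floating-point precision
  (weights, biases *and* momentum buffers), since the library is the
  entire accumulated training state.

## Known limitations

- **Signal decay with depth.** Long molecules produce deep trees; the
  error signal crosses one logistic derivative per level and shrinks
  accordingly, so confidence degrades on large molecules.
- **Topology, not sequence geometry.** The network sees where tokens sit
  in the parse structure, not string distances or run lengths; labels
  depending on "how far apart" two tokens are remain out of reach.
- **Grammar coverage bounds the model.** The ten-rule subset cannot even
  derive two branches on one atom; `smiles_extended` covers practical
  organic-subset SMILES but not the full specification (no multi-digit
  ring closures `%nn`, no wildcard or isotope-exotic atoms), and
  `inchi_basic` covers only the version prefix, formula, `/c` and `/h`
  layers.
- **Online order sensitivity.** Per-exemplar updates make results depend
  on presentation order; this is pinned by the seed, not eliminated.
- **High-momentum presets can oscillate.** The classification preset's
  α = 0.90 occasionally needs its restart budget; the restart mechanism is
  part of the procedure, not an afterthought.
- Inputs are assumed pre-canonicalized; the package performs no
  canonicalization, no 3-D handling and no chemical-graph reconstruction.
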