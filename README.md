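# ngn — Neural Grammar Networks for QSAR on Molecular Line Notations

`ngn` is an R package for quantitative structure–activity relationship
(QSAR) modelling that learns directly from a molecule's *string*
representation — SMILES or InChI — instead of from hand-designed descriptor
vectors. For every molecule, the string is parsed under a deterministic
context-free grammar and a tree-shaped neural network is assembled whose
topology **is** the parse tree. The network's weight layers are bound to
grammar productions and drawn from a single persistent library, so one
finite set of parameters processes molecules of any size, and the
structural information in the string reaches the learner losslessly. The
package is aimed at cheminformatics and machine-learning researchers who
want a descriptor-free QSAR baseline, a reference implementation of
backpropagation through structure with production-bound weight sharing, or
a grammar-driven synthetic benchmark generator.

## The model

A grammar is a four-tuple *G* = ⟨*V*, Σ, *s*, *P*⟩ of internal symbols,
terminal token classes, a start symbol and productions. Each production is
either an *expansion* (`chain <- atom chain`) or an *acceptance* of input
tokens (`atom <- 'C' | 'O'`). For a deterministic grammar — validated here
by conflict-free canonical LR(1) table construction — every string in the
language has exactly one parse tree.

The network for a molecule mirrors its parse tree:

- every internal parse node becomes a hidden layer of *h* logistic units
  (default *h* = 8);
- every token becomes a one-hot input: one unit per token its terminal
  class accepts, the matched unit set to 1.0;
- a single-unit output layer sits above the start symbol;
- every edge applies a **shared** weight layer *W* = (*w*, *b*) keyed by
  the production binding it. Activations are
  *α*<sub>u</sub> = L(Σ<sub>slots</sub> *w* · *α*<sub>child</sub> + *b*)
  with L(x) = 1/(1+e<sup>−x</sup>); child slots that a production does not
  use contribute a zero-flushed activation vector.

Training is online backpropagation through structure. The output error
gradient is δ = (t − o)·o·(1 − o); per instantiation of a shared layer,
Δ*w*<sub>ij</sub> = η·δ<sub>i</sub>·α<sub>j</sub>, and because a layer may
occur many times in one network, the applied update is the **sum** of its
instantiation deltas, plus a momentum fraction α of the previous update.
Layers untouched by a molecule's parse are not updated. Training converges
when epoch RMSE drops below a threshold; exhausted epoch budgets trigger a
re-initialization from fresh random weights (two-band uniform,
[−1.6, −1.0] ∪ [1.0, 1.6] by default), up to a restart limit.

Evaluation statistics ship with the package: concordance Q, sensitivity,
specificity and Matthews correlation for classification; PRESS, SD and
q² = 1 − PRESS/SD for regression; summed-residual Epsilon with its spread
for toxicology-style comparisons; Pearson correlation; and a Wilcoxon
signed-rank test that is exact (by exhaustive sign-pattern enumeration,
valid under ties) for small samples. Cross-validation designs —
Leave-20%-Out (5 folds × 10 repetitions), Leave-5%-Out (20 folds),
designed test sets, grouped and random five-fold — are built by
`ngn_folds()` and run by `ngn_run_trials()`. A descriptor-vector
feed-forward baseline (`ngn_ann()` over `ngn_descriptors()` token counts)
supports head-to-head comparisons.

## Worked example

The isopentanol string `CC(C)CCO` under the built-in ten-rule SMILES
subset grammar:

```r
library(ngn)
g <- ngn_grammar("smiles_subset")
print(g)
#> Deterministic context-free grammar 'smiles_subset'
#>   10 rules (3 acceptance), 7 internal symbols, start symbol 'smiles'

tr <- ngn_parse("CC(C)CCO", g)
print(tr)
#> Parse tree for "CC(C)CCO" under grammar 'smiles_subset'
#>   17 rule applications: 1 3 5 4 5 7 8 9 2 5 10 3 5 3 5 2 6

ngn_rule_counts(tr)
#>  1  2  3  4  5  6  7  8  9 10
#>  1  2  3  1  5  1  1  1  1  1
```

The derivation lists the productions of the leftmost rewrite from `smiles`
down to the tokens; the counts say the network for this molecule
instantiates the layer of production 2 (`chain <- atom`) twice, production
3 (`chain <- atom chain`) three times and production 5 (`atom <- 'C'`)
five times — all referencing the same three shared layers.

Training on a synthetic task (does the molecule contain an oxygen?):

```r
task <- ngn_synth_task("classification", "contains_token", token = "O",
                       n = 200, max_depth = 12, seed = 101)
ds <- ngn_make_dataset(task, g)
fit <- ngn(ds$molecule[1:160], ds$label[1:160], g,
           ngn_control("classification"), seed = 4)
print(fit)
#> Neural grammar network (classification), grammar 'smiles_subset'
#>   160 exemplars; converged after 25 epochs (0 restarts), final RMSE 0.01899

cm <- ngn_confusion(predict(fit, ds$molecule[161:200]), ds$label[161:200])
unlist(ngn_classification_metrics(cm))
#>   Q  SE  SP MCC
#>   1   1   1   1
```

The fit converged below the 0.05 RMSE threshold in 25 epochs and
classifies all 40 held-out molecules correctly (Q = SE = SP = MCC = 1).
`summary()`, `coef()`, `plot()` (the RMSE trace), `fitted()` and
`residuals()` work as for other R model objects; `ngn_save()`/`ngn_load()`
round-trip the full weight-layer library through a versioned JSON archive.

## Command line

A thin Rscript front end over the same functions lives at
`inst/cli/ngn.R` (after installation: `system.file("cli/ngn.R", package =
"ngn")`), with subcommands `parse`, `synth`, `train`, `predict`, `eval`
and `crossval`:

```sh
Rscript ngn.R parse --grammar smiles_subset "CC(C)CCO" --show derivation
Rscript ngn.R synth --task contains_token:O --n 200 --seed 7 --out data.csv
Rscript ngn.R train --data data.csv --out model.json --seed 2
Rscript ngn.R crossval --data data.csv --scheme leave20_cv --report report.json
```

## Scope notes

The package consumes pre-canonicalized strings; canonicalization, file
formats beyond `.smi`/CSV (SDF/Molfile), 3-D conformers and external
descriptor toolkits are out of scope. The built-in `inchi_basic` grammar
covers the version prefix, formula layer and `/c`, `/h` layers only. See
the methods vignette (`vignettes/neural-grammar-networks.Rmd`) for the
model's assumptions, parameter meanings and known limitations.
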