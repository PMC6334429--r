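---
title: "Gene Selection Programming: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene Selection Programming: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gspr)
```

## The selection problem

Expression studies of disease phenotypes routinely produce matrices with
50–200 samples and 5,000–15,000 measured genes, of which only a few carry
class information. A classifier trained on all genes overfits; per-gene
filter statistics ignore interactions and keep redundant genes. `gspr`
implements a wrapper search: an evolutionary algorithm proposes gene
subsets, and each subset is scored by the leave-one-out cross-validated
(LOOCV) accuracy of a classifier actually trained on it.

## Chromosomes and decoding

Candidates are encoded in Karva notation. A gene is a string of
`h + t` symbols — a *head* of `h` positions that may hold function symbols
(`+`, `-`, `/`, `Q`) or terminals (gene names), and a *tail* of
`t = h(n - 1) + 1` terminals, `n` being the maximum arity (2 for the
default set). The tail formula is what makes every string decodable: a
breadth-first reading from position 0, in which each function consumes
`arity` later symbols as children, can never run out of terminals. A
chromosome concatenates `N` such genes.

The expression tree is used purely structurally: the subset a chromosome
stands for is the union of the terminals appearing in its genes' decoded
trees. Symbols after the expressed prefix are carried silently (classic GEP
behaviour) and can become active after later mutations. Because fitness
depends only on the expressed subset, genes are combined by set union; no
numeric linking function is defined or needed.

Two decisions here were genuinely open:

* **Gene roots.** Position 0 of each gene is forced to a function symbol.
  A terminal root collapses the gene to a single attribute, which defeats
  multi-gene subset search; the classic ablation mode
  (`gsp_config(classic = TRUE)`) lifts the restriction.
* **Head symbol balance.** Non-root head positions hold a function or a
  terminal with probability 1/2 each, then roulette within the category —
  an unbiased default, configurable in `random_gene()`.

## Attribute weights

Each attribute is discretized by recursive entropy minimisation with the
Fayyad–Irani MDL stopping rule, and its Information Gain (IG) against the
class label is computed in bits. MDL was chosen over fixed binning because
it assigns exactly zero gain to attributes where no cut clears the coding
cost — and zero-gain attributes are treated as irrelevant and excluded from
the terminal pool entirely, which keeps the roulette wheel well defined. An
unsupervised equal-frequency 10-bin fallback is available
(`discretization = "equal_frequency"`).

Ranks are computed once per run and reused (`ig_computation_count()` makes
this observable). Weights are `w_i = r_i / sum(r)`; ties need no breaking
because equal weights already imply equal selection probability. If every
rank is zero — possible only on adversarial inputs such as constant
matrices — the engine warns and falls back to uniform terminal sampling so
it remains runnable.

## Fitness

A chromosome expressing subset size `s` out of `t` attributes with LOOCV
accuracy `AC` scores

    f = 2 r AC + r (t - s) / t

with `r` drawn uniformly from (0.1, 1). Two consequences shape the
implementation:

* The accuracy term spans twice the parsimony term's range, so improving
  accuracy always dominates shrinking the subset.
* `f` is only meaningful *within* a generation, because `r` rescales it.
  `r` is therefore drawn once per generation and shared by every evaluation
  in it, and the global best is tracked by the `r`-free lexicographic order
  (higher accuracy, then smaller subset). The per-generation `r` is logged
  in the run history for audit.

The classifier is a linear-kernel SVM with cost 1 and no internal scaling —
fixed hyperparameters keep fitness deterministic. LOOCV is computed with
the exact support-vector identity: removing a sample that is not a support
vector of the full-data solution leaves that solution unchanged, so only
support-vector folds are refit. This is an algebraic shortcut, not an
approximation; the test suite checks it against a literal per-fold refit. A
degenerate fold whose training half contains one class predicts that class,
which defines behaviour down to `n = 2`. Accuracies are memoized by sorted
subset, so the number of classifier trainings is bounded by
`(n_samples + 1)` times the number of *distinct* subsets evaluated. An
empty expressed subset receives fitness 0 (flagged) rather than an error,
keeping the population totally ordered. A nearest-centroid classifier
(`classifier_spec("nearest_centroid")`) is provided as a fast deterministic
alternative; ties go to the first class in level order.

## Guided operators

**Mutation** scans only expressed terminals — mutating an unexpressed tail
symbol cannot change fitness, so an accept-if-better rule would always
reject it — and targets the one with the lowest weight (ties: lowest
position). The replacement is a function symbol or a higher-weight terminal
for head positions, a higher-weight terminal only for tail positions; the
mutant is kept only if its fitness strictly exceeds the original's. Both
conditions (higher weight *and* higher fitness) are required. Up to 3
proposals are tried (`operator_rates(mutation_retries=)`) before returning
the input unchanged, which bounds the otherwise open-ended retry loop.
A head terminal mutated into a function changes the tree by Karva
re-decoding alone — no symbols are inserted or deleted, so gene length is
invariant.

**Recombination** identifies the higher-fitness parent `hc` and lower
`lc`, and moves `lc`'s strongest gene (highest weight summation over
expressed terminals, counted with multiplicity — the simplest reading;
a distinct-set mode exists in `gene_weight_sum()`) into the slot of `hc`'s
weakest gene. The swap is kept only if the child strictly beats both
parents; otherwise the next-strongest donor gene is tried, at most once per
gene. Classic one-point short-sequence exchange is available for ablation;
it swaps an aligned span within one gene, which preserves head/tail
legality by construction.

**Generational loop.** The GEP evolution cycle implies a survivor-selection
step without fixing a scheme, so the engine uses standard GEP practice: elitism 1 plus
fitness-proportionate parent selection, recombination applied to selected
pairs with probability 0.3 and mutation per chromosome with probability
0.044. Population size is preserved exactly.

## Stopping

Runs halt at the generation cap (default 2000) or after 50 generations
without improvement of the (accuracy, then smaller subset) best. The stall
rule is an addition — the source method defines only the cap — chosen so
that converged runs terminate early; because the order already prefers
smaller subsets at equal accuracy, a run at accuracy 1.0 keeps going while
the subset shrinks. The reported accuracy is recomputed from scratch at
finalisation and must agree with the tracked value.

## The synthetic generator

`simulate_expression()` emulates the shape of benchmark microarray data:
few samples, many attributes, a small informative set. Informative
attribute `j` in class `k` is `N(delta * c(j,k), 1)` with distinct integer
class centres rotated across attributes; noise attributes are `N(0, 1)`;
redundant attributes are informative columns plus `N(0, noise_sd^2)` noise.
Defaults (60 samples, 500 attributes, 5 informative, effect 2.5, 2 classes)
are the study conditions used throughout the tests. The Gaussian
class-conditional model is deliberately the simplest structure under which
both IG ranking and a linear-margin classifier behave as the method
assumes; redundancy is an explicit knob because correlated probes are a
known unhandled issue for this family of methods.

What the generator does **not** emulate: probe-level artifacts, saturation,
batch effects, heavy-tailed expression distributions, or correlated noise.
Passing recovery tests on these fixtures shows the search and scoring
machinery work as specified — not that the method dominates on real
microarrays.

A caveat the simulations make visible: with 60 samples and effect size 2.5,
two informative genes already separate the classes with LOOCV accuracy 1.0,
and the fitness function then strictly prefers the smaller subset — so runs
typically return 2–4 genes, nearly always a subset of the planted truth,
rather than all five planted genes. Parsimony caps recovery; on such data a
complete marker list requires either weaker effects, fewer samples, or
turning the parsimony pressure down.

## Problem sizes and tolerances in the test suite

The suite runs simulation checks at desk scale as the package's own choice
of test conditions: IG against a brute-force joint-count oracle on 500
random instances (tolerance 1e-12); roulette goodness-of-fit at 100,000
draws over 50 seeded weight vectors (chi-square, p > 0.001); operator
contracts over 1,000 random chromosomes with a deterministic stub
evaluator; and subset recovery over 20 seeds at 60 × 500 with population 50
and 100 generations. Every run is reproducible bit-for-bit from its seed;
randomness enters only through R's RNG, which the engine seeds once per
run and restores afterwards.

## Known limitations

* LOOCV accuracy on wrapper-selected subsets is an optimistically biased
  estimate of generalisation (selection bias); an external validation split
  is needed for honest error rates.
* Missing values are rejected by default (optional median imputation); no
  normalisation or batch correction is applied — inputs are taken as-is.
* Multi-class problems are handled through the SVM's one-vs-one scheme and
  multi-valued class entropies, but the parsimony/accuracy balance was
  designed around binary tasks.
* Attribute names must not collide with function symbols (`+`, `-`, `/`,
  `Q`); the loader enforces uniqueness and the engine rejects collisions.
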