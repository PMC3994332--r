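---
title: "Methods: domain combination similarity and its benchmark protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain combination similarity and its benchmark protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements,
the choices that were genuinely open when building it, and what the test
suite does and does not demonstrate.

## The model

The working hypothesis is that proteins with similar Pfam domain
composition — both in themselves and in their interaction context — tend
to share functions.  Domains are independently evolving functional units;
a shared domain repertoire is evidence of shared biochemistry, and a
shared repertoire across two proteins' neighborhoods or complexes is
evidence that the two sit in functionally equivalent positions of the
interactome.

Given a network of $n$ proteins whose proteins collectively carry $M$
distinct domain types, every protein $P$ has

* a **composition set** $DT(P)$: the domain types of $P$ itself, and
* a **context set** $DC(P)$: the union of domain types over $P$'s
  context scope.

Two context scopes are implemented.  Under **DCS** the scope is the
closed neighborhood $N_P$ ($P$ and its interaction partners).  Under
**DSCP** it is $SC_P$, the union of all complexes containing $P$; a
protein in no complex keeps its neighborhood scope.  The fallback is
essential: curated catalogs cover only a minority of network proteins
(in the bundled synthetic benchmark, a few dozen of 200).

For two proteins with context sizes $a = |DC(P_A)|$, $b = |DC(P_B)|$ and
overlap $s = |DC(P_A) \cap DC(P_B)|$, the context similarity is the
negative log of the hypergeometric probability of exactly that overlap:

$$
f_{cont}(P_A, P_B) \;=\; -\log
\frac{\binom{M}{s}\binom{M-s}{a-s}\binom{M-a}{b-s}}
     {\binom{M}{a}\binom{M}{b}}
\;=\; -\log P(X = s), \quad X \sim \mathrm{Hyper}(M, a, b).
$$

$f_{comp}$ is the identical functional applied to the composition sets,
and the combined similarity is the convex mixture
$f_{sim} = \lambda f_{cont} + (1-\lambda) f_{comp}$.

An unannotated protein receives the union of the GO annotations of its
top-$K$ most similar annotated proteins, per aspect (MF, CC, BP),
provided the similarity is strictly positive; otherwise it is reported
as *unpredicted*.

### Assumptions worth stating

* The score treats domain types as exchangeable: only set sizes and the
  overlap matter, not which domains are shared or their copy numbers.
* $M$ is a single network-wide constant, also for complex contexts.
  Complex members that are not in the network contribute no domains —
  otherwise a context could exceed the universe that defines the score.
* Label transfer assumes annotations are missing at random: hiding a
  protein's labels removes nothing but the labels (its edges, domains
  and complex memberships stay visible), which mirrors how a genuinely
  unannotated protein would be treated.
* The score is *not* globally monotone in the overlap: it decreases
  towards the hypergeometric mode before increasing in the upper tail.
  Similar proteins live in the upper tail, where the intended reading
  ("more shared domains, higher score") holds; the sub-mode region is
  implemented exactly as defined and simply documented.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda` | 0.1 | weight of the context term; 0 = composition only, 1 = context only (the Zhang-DC configuration). The small default reflects that a protein's own domains are the stronger signal and the context acts as a correction. |
| `method` | DCS | context scope; DSCP needs a complex catalog (an empty one reduces DSCP to DCS exactly). |
| `k` | 1 | references per query; predicted sets are unions, hence monotone in `k`. |
| `log_base` | natural | a base change rescales every score by one constant and cannot change any ranking or the mixture's argmax; base 10 is offered for cross-tool comparability. |
| `term_filter()` | 10–200, IEA/ND/NAS excluded | the benchmark's reliability window: terms annotating fewer than 10 proteins are too specific to score stably, above 200 too general to be informative. |

Term sizes are counted network-restricted by default (a fixed evaluation
network is the natural scope); corpus-wide counting is available as
`size_scope = "corpus"` because either reading of "number of annotated
proteins" is defensible.

Ancestor propagation over `is_a`/`part_of` is optional and off without
an ontology.  When enabled it runs *after* evidence exclusion (an
excluded record must not seed ancestors) and *before* size filtering
(sizes should describe the propagated annotation).

## Evaluation protocol

Two aggregation modes are deliberately kept apart:

* **Per-term macro averaging** for table-style reports: each surviving
  GO term is one binary classifier; confusion counts accumulate over all
  cross-validation rounds; PPV, TPR and MCC are averaged over terms
  within size bins `[10-30]`, `(30-50]`, `(50-100]`, `(100-200]` and
  overall.  The bin F-measure is the harmonic mean of the bin's mean PPV
  and mean TPR (the convention the reference tables themselves follow,
  as their printed F values reproduce from their printed PPV/TPR pairs).
* **Per-protein micro averaging** for PR curves: at each $K$ of the
  1..50 sweep, precision and recall are computed per test protein from
  its predicted-versus-true term sets and then averaged; a protein with
  an empty prediction contributes recall 0 and is excluded from the
  precision average.

Zero-denominator metrics are `NA`, excluded from averages, and counted
in the report (`n_undefined_*`) — setting them to 0 would silently
punish terms that were never predicted on.

Ties in the reference ranking are broken lexicographically by protein
identifier.  Any "first encountered" rule depends on iteration order;
fixing the order makes results machine-independent, which matters more
than which of two equally similar references is chosen.

Unpredicted proteins stay in the evaluation and contribute one false
negative per true term.  Dropping them would inflate recall exactly for
the hardest cases.

The two classical baselines are reimplemented behind the same protocol:
neighbor counting (term frequency among annotated partners) and its
chi-square correction $(n_f - e_f)^2 / e_f$ with $e_f$ the count
expected from the term's frequency among all annotated network proteins.
In protocol comparisons the rankers are run at $K$ equal to the typical
per-protein term count (3 in the synthetic benchmark), since a term
ranker predicts $K$ terms where the similarity methods predict whole
term sets.

### The permutation null

Absolute cross-validation numbers depend on term-set sizes and the
annotated fraction, so the package's recovery check is relative: shuffle
whole per-protein term sets among the annotated proteins and recompute
the leave-one-out macro F.  Similarities depend only on domains and
topology, so the reference ranking is invariant under the shuffle — only
the transferred labels change.  This makes a 100-shuffle null cheap and
exact for the question "does the similarity carry label information
beyond what set sizes explain".

## The synthetic generator

`generate_bundle()` plants `n_modules` functional modules and makes
topology (stochastic block model, `p_within`/`p_between`), domain
composition (per-module domain pools with `domain_fidelity` leakage),
complexes (`complex_fidelity`) and GO labels (`coupling` toward disjoint
per-module term profiles) all reflect the same module structure.
Defaults — 200 proteins, 5 modules, universe of 60 domain types, 15
terms per aspect, coupling 0.9, 10% unannotated — were chosen once so
that surviving term sizes land inside the 10–200 window and module
recovery is hard enough to leave headroom (leave-one-out F around 0.6,
not 1.0).  Module term profiles are disjoint so "correct transfer" has
an unambiguous ground truth.  One Mersenne-Twister stream per bundle,
seeded from the integer `seed`, makes bundles byte-reproducible; an edge
list cannot represent isolated proteins, so the ground-truth JSON
carries the full protein list and `read_bundle()` restores them.

What the generator does *not* emulate: heavy-tailed degree
distributions, domain promiscuity (one domain spanning many unrelated
families), aspect-specific annotation depth, inter-term hierarchy, or
the biased incompleteness of real interactomes.  Green tests therefore
show the machinery is correct and the method recovers planted modular
signal; they do not certify performance levels on any real interactome.

## Numerical choices

* Binomial coefficients are evaluated via `lchoose` (log-gamma space);
  scores are finite for all valid counts because the PMF at an observed
  overlap is strictly positive.  The five-coefficient form above is used
  as written; it reduces algebraically to the hypergeometric density,
  which an independent `dhyper` cross-check and an exhaustive
  subset-enumeration oracle confirm to 1e-9 in the tests.
* Count invariants ($s \le \min(a,b)$, $a,b \le M$, $a+b-s \le M$) are
  enforced, not clamped — they always hold for genuine set sizes, so a
  violation signals a caller bug.
* Scores are floored at 0 only to absorb `-0`/rounding in the
  probability-1 cases.
* Degenerate inputs: a domain-free protein has score 0 against
  everything (PMF 1) and therefore ends up unpredicted; a lone annotated
  protein in leave-one-out has no references and contributes only false
  negatives; an empty complex catalog makes DSCP identical to DCS on
  every pair.

## Problem sizes

The test suite and the acceptance script run on bundles of 40–200
proteins, the enumeration oracle on universes up to $M = 12$
(exhaustive over all $(a, b, s)$), the permutation null on 100 shuffles
and the leave-percent-out protocol on 50–100 repeats.  These sizes were
picked as the smallest at which every property under test is stably
expressed; all of them are configuration arguments, so larger studies
only change function calls.

## Known limitations

* The chi-square baseline's background-frequency definition is the
  natural one (term frequency among annotated network proteins); other
  definitions exist and would shift its absolute numbers.
* For `k > 1` the prediction TSV reports the top reference per protein;
  the full reference list lives in the R object.
* Similarity matrices are dense in memory during cross-validation,
  which is comfortable to a few thousand proteins but not for
  hundred-thousand-node graphs.
* No weighting of interactions or probabilistic voting over the top-$K$
  references: transfer is a plain set union by design.
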