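# dcsim — domain combination similarity for protein function prediction

Most proteins in a newly mapped interactome carry no experimentally
verified Gene Ontology (GO) annotation.  `dcsim` predicts annotations for
such proteins by transferring the labels of their most functionally
similar annotated neighbors in a protein–protein interaction (PPI)
network, where "similar" is judged from Pfam domain composition rather
than from sequence: two proteins that share domain types — and whose
interaction partners or complexes collectively share domain types — are
likely to share functions.  The package is aimed at computational
biologists benchmarking network-based function prediction: it bundles the
similarity measures, the annotation-transfer rule, the standard
cross-validation metrics, two classical baselines, and a synthetic-data
generator so the whole pipeline is testable without any external
database download.

## The similarity measure

Let *M* be the number of distinct domain types on the proteins of the
network.  For a protein *P*, let DT(*P*) be its own set of domain types
(its *composition*) and DC(*P*) the union of domain types over its
*context scope* (its *context*).  For two proteins *A*, *B* with set sizes
*a* = |DC(*A*)|, *b* = |DC(*B*)| and overlap *s* = |DC(*A*) ∩ DC(*B*)|,
the context similarity is the negative log hypergeometric probability of
observing exactly that overlap by chance:

    f_cont(A, B) = −log [ C(M,s) · C(M−s, a−s) · C(M−a, b−s) ] / [ C(M,a) · C(M,b) ]
                 = −log P(X = s),   X ~ Hypergeometric(M, a, b)

The composition similarity `f_comp` is the same score applied to DT(*A*)
and DT(*B*), and the combined similarity is the convex mixture

    f_sim(A, B) = λ · f_cont(A, B) + (1 − λ) · f_comp(A, B),   λ ∈ [0, 1]

with default λ = 0.1.  Two context scopes are available:

* **DCS** — the closed interaction neighborhood (the protein and its
  partners);
* **DSCP** — the union of the protein complexes containing the protein,
  falling back to the neighborhood for proteins in no complex.  Complex
  catalogs (e.g. CYC2008-style flat files) cover only part of a network
  but are less noisy than raw interactions.

Setting λ = 1 recovers the earlier context-only similarity (Zhang-DC).
An unannotated protein receives the union of the annotations of its top
*K* most similar annotated proteins (default *K* = 1), provided the
similarity is strictly positive; ties break lexicographically so results
are machine-independent.

## Worked example

```r
library(dcsim)

bundle <- generate_bundle(synthetic_config(seed = 7))
bundle
#> Synthetic bundle (seed 7): 200 proteins, 5 modules, 1263 interactions,
#>   10 complexes, 1250 GO records

fit <- dcs(bundle$network, bundle$domains, complexes = bundle$complexes,
           method = "DSCP", lambda = 0.1)

pairwise_similarity(fit, rbind(c("P0001", "P0006"), c("P0001", "P0002")))
#>   protein_a protein_b   f_cont    f_comp     f_sim
#> 1     P0001     P0006 9.158932 1.7147335 2.4591533
#> 2     P0001     P0002 1.730651 0.2106561 0.3626556
```

P0001 and P0006 sit in the same planted module: their contexts overlap
far more than chance predicts (`f_cont` 9.16 versus 1.73 for the
cross-module pair), and the mixture `f_sim` ranks the in-module pair
well above the cross-module one.

```r
cv <- cross_validate(fit, bundle$annotations, aspect = "MF")
cv
#> LOO cross-validation (DSCP, aspect MF, k = 1): 185 rounds, 185 annotated
#> proteins, 15 GO terms
#>   size_bin n_go_terms   ppv   tpr f_measure   mcc ...
#>    [10-30]         13 0.570 0.597     0.584 0.513
#>    (30-50]          2 0.674 0.622     0.647 0.580
#>   In total         15 0.584 0.601     0.592 0.522
```

Each of the 185 annotated proteins is hidden in turn and its molecular
function terms predicted back from the rest; per-term confusion counts
accumulate over rounds and are macro-averaged within term-size bins.  An
F-measure of 0.59 means the nearest-similar-protein transfer recovers
most of the planted module structure; a label permutation null on the
same bundle scores around 0.19.

```r
fa <- filter_annotations(bundle$annotations, term_filter(), bundle$network)
predict(fit, fa$table, aspect = "MF", k = 1)
#> Function predictions: 15 proteins queried, 15 predicted, 33 term assignments
#>    protein aspect       term reference similarity
#> 1    P0033     MF GO:0000003     P0153   2.934466
#> ...
```

The same workflows are scriptable through the thin CLI in `exec/dcsim`
(`simulate`, `predict`, `evaluate` subcommands).

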