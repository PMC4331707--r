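# scmcard

Interpretable prediction of protein functional-class membership from
primary sequence with the **scoring card method (SCM)**, plus the
**SCM-PCP** analysis that explains a trained predictor in terms of
physicochemical properties of amino acids.

The package is aimed at computational biologists who want a classifier
whose decision they can read: instead of a hyperplane or a tree ensemble,
an SCM model is a table of 400 numbers — one propensity score per ordered
dipeptide — and a single decision threshold.

## The method

Given positive (class) and negative (non-class) training sequences:

1. **Initial card.** For each ordered dipeptide *i*, compute the
   difference in pooled dipeptide composition between the classes,
   then min–max normalise the 400 differences to propensity scores
   *Sᵢ* ∈ [0, 1000].
2. **Amino-acid scores.** The propensity of amino acid X is the mean of
   the 40 dipeptide scores whose position slots contain X (the
   homodipeptide XX occupies two slots).
3. **Optimisation.** An elitist genetic algorithm refines the 400 scores,
   maximising

   *fit(S) = w₁ · AUC + w₂ · R*,  (defaults *w₁* = 0.9, *w₂* = 0.1)

   where AUC is the stratified 10-fold cross-validated rank (Mann–Whitney)
   ROC AUC of the card's sequence scores and *R* is the Pearson
   correlation between the current and initial amino-acid scores, which
   anchors the optimised card to the interpretable composition-derived
   one.
4. **Scoring and classification.** A query *P* is scored by
   *S(P) = Σᵢ wᵢ Sᵢ* with *wᵢ* its dipeptide-composition fractions
   (so *S(P)* ∈ [0, 1000] regardless of length), and called positive iff
   *S(P)* strictly exceeds a threshold chosen to maximise training
   accuracy.
5. **SCM-PCP.** The 20 derived amino-acid scores are correlated against
   AAindex property indices; properties with |R| > 0.5 are flagged as
   informative descriptors of the class.

A synthetic-sequence generator with planted, mathematically explicit
dipeptide enrichment (first-order Markov positives over an i.i.d.
background) makes the whole pipeline testable end to end.

## Worked example

```r
library(scmcard)

## synthetic study: 200/200 sequences of 80-120 residues, dipeptide "AP"
## enriched 8-fold in the positive class
d   <- simulate_dataset(200, 200, c(80, 120), planted = c(AP = 8), seed = 42)
fit <- scm_train(d$positives, d$negatives, seed = 42)
fit
#> Scoring-card classifier (SCM)
#>   call: scm_train(positives = d$positives, negatives = d$negatives, seed = 42)
#>   training: 200 positives, 200 negatives
#>   fitness: 0.9601 (AUC 0.9597, R 0.9628) after 50 generations
#>   threshold: 108.9659; training accuracy 89.50%

recovery_report(coef(fit), d)   # did the card find the planted signal?
#>   dipeptide weight    score rank
#> 1        AP      8 953.7534    1

test <- simulate_dataset(5, 5, c(80, 120), planted = c(AP = 8), seed = 43)
predict(fit, test$positives)
#>         id    score    label
#> 1 pos_0001 160.5686 positive
#> 2 pos_0002 128.8863 positive
#> 3 pos_0003 117.1942 positive
#> 4 pos_0004 124.3040 positive
#> 5 pos_0005 106.7264 negative
```

The fitness line reads: the genetic algorithm reached a combined fitness
of 0.9601, trading a little similarity to the initial card (R = 0.9628)
for cross-validated discrimination (AUC = 0.9597). The planted dipeptide
holds rank 1 of 400, and the fifth test sequence shows the kind of
borderline case a threshold classifier produces (score 106.7 vs
threshold 109.0).

The SCM-PCP step, run on the packaged reference propensity scores for
photosynthetic proteins (PSPs):

```r
rc <- scm_fixture("reference_card")
ps <- setNames(rc$propensity, rc$aa)
scan_indices(ps, scm_fixture("aaindex"))
#>    accession                                  description       r n_used informative
#> 1 BLAS910101      Scaled side chain hydrophobicity values  0.7955     20        TRUE
#> 2 PUNT030101    Knowledge-based membrane-propensity scale -0.7947     20        TRUE
#> 3 WOLR810101                           Hydration potential  0.7597     20        TRUE
```

High-propensity residues in that card are the hydrophobic,
membrane-helix-forming, weakly hydrated ones — exactly what thylakoid
membrane proteins should look like.

## Command line

A thin CLI over the same functions ships at `inst/scripts/scmcard.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","scmcard.R",package="scmcard"))')" \
    train --pos pos.fasta --neg neg.fasta --out model/ --seed 1
```

Commands: `train`, `predict`, `evaluate`, `analyze`, `simulate`; every run
writes a `manifest.json` sufficient to replay it.

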