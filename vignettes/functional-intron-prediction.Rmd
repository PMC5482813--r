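---
title: "Predicting functional introns from positional conservation"
author: "funtron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting functional introns from positional conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funtron)
```

## The problem

Many human introns carry functional elements — miRNAs, snoRNAs,
transcription factor binding sites — yet intronic sequence conservation is a
poor detector of them: the elements are short, their position within the
intron drifts, and some intronic functions do not depend on sequence at all.
What *is* conserved for such introns is their position along the coding
sequence across large evolutionary distances. `funtron` implements a
framework that exploits this: gene architectures of orthologous transcripts
are reduced to ternary intron presence–absence patterns over a dated
phylogeny, each unique pattern is summarised by thirteen evolutionary and
positional features, and a logistic classifier — trained with an EM
algorithm that models the *one-sided* incompleteness of functional
annotation — scores each pattern's probability of representing a functional
intron.

A pattern is one column of an mRNA-level multiple alignment of orthologs,
recoded as 1 (last nucleotide of an exon, i.e. an intron immediately
downstream), 0 (any other nucleotide), or 2 (gap or missing ortholog).
Columns with at least 45% missing entries, without any 1, or without an
intron in human are discarded; identical columns are collapsed into *unique
patterns* with a multiplicity. A unique pattern is labeled `functional` when
every one of its occurrences hosts an annotated element, `non-functional`
when none does, and `partial` otherwise; partial patterns are excluded from
training and only scored afterwards.

## The noisy-label logistic model

The probability that pattern $i$ with feature vector $x_i$ is truly
functional ($y_i = 1$) is the logistic
$$p(y_i = 1 \mid x_i;\omega) = \frac{1}{1 + e^{-\omega^T x_i + \omega_0}}.$$
Note the sign convention: the offset $\omega_0$ enters the exponent with a
*plus* sign, so increasing it lowers the probability. The implementation
keeps this convention everywhere (`probFunctional()`), because an offset
whose sign silently flips is the kind of bug no test distinguishes from a
refit.

The observed label $z_i$ is a noisy version of $y_i$ with
$\theta_{ij} = p(z = j \mid y = i)$. Annotation is one-sided: an intron
labeled functional really is ($\theta_{01} = 0$, hence $\theta_{00} = 1$),
but an unlabeled intron may simply be unstudied, so the only free noise
parameter is $\theta_{11}$, the probability that a truly functional intron
is labeled as such. Training maximises the observed-data likelihood
$\sum_t \log \sum_i \theta(i, z_t)\, p(y_t = i \mid x_t)$ by EM:

* **E-step** — responsibilities $c_t = p(y_t = 1 \mid z_t, x_t)$; an
  observed $z_t = 1$ forces $c_t = 1$.
* **M-step** — $\theta_{11} = \sum_t c_t 1\{z_t = 1\} / \sum_t c_t$, and
  $\omega$ from a weighted logistic regression with fractional responses
  $c_t$, solved by step-halved Newton (the objective is concave; a
  gradient-ascent fallback with learning rate $\tau$ handles singular
  Hessians and is also available as `mStepMethod = "gradient"`).

Two derived quantities matter biologically: $\theta_{11}$ itself (the
fraction of functional introns already annotated) and
$P_{10} = p(y = 1 \mid z = 0)$, the probability that an unlabeled pattern
is functional, estimated by averaging
$(1-\theta_{11})p_t / (1 - \theta_{11} p_t)$ over the unlabeled patterns
(`estimateP10()`).

### Numerical choices

* **Convergence.** EM stops when the observed log-likelihood improves by
  less than $10^{-8}$ nats or after 500 iterations per cycle. The
  likelihood surface has a nearly flat ridge between $\theta_{11}$ and
  $\omega_0$ along which plain EM creeps (tens of thousands of iterations on
  weak-signal data), so EM cycles alternate with a safeguarded BFGS
  refinement of the observed likelihood that is accepted only when it
  improves the objective — trajectories stay monotone and every fit reaches
  the same optimum a direct numerical maximisation finds (this equivalence
  is asserted in the test suite).
* **Restarts.** The surface can be multimodal in $\theta_{11}$, so training
  restarts from random $\theta_{11} \sim U(0.05, 0.95)$ (default 100
  restarts), with $\omega$ always warm-started from a plain logistic fit;
  per-parameter mean, SD and coefficient of variation across restarts are
  reported so instability is visible rather than silent.
* **Standardization.** Continuous features are z-scored before fitting
  (binary indicators stay 0/1); the parameters are stored with the model so
  prediction applies the identical transform.
* **Degenerate inputs.** $\theta_{11} = 0$ with an observed functional
  label yields a defined $-\infty$ likelihood rather than a crash; with
  $\theta_{11}$ held at 1 the model reduces *exactly* to ordinary logistic
  regression (used as a correctness check).

### Classification

The classifier thresholds at $T = 0.5$. The package's default score is the
marginal probability of an observed functional label,
$\theta_{11} \cdot p(y=1|x)$, which follows the printed classification rule
verbatim; but note that whenever $\theta_{11} \le T$ this quantity cannot
exceed the threshold, so any non-trivial prediction rate must come from the
conditional probability $p(y = 1 \mid x)$. Both are exposed
(`classifyPatterns(quantity = "marginal" | "conditional")`), ties at $T$
are classified non-functional, and the acceptance script reports recovery
under the conditional quantity.

## The thirteen features

For each unique pattern, `buildFeatureTable()` computes:

| feature | meaning | unit/range |
|---|---|---|
| `LOG_LIKE` | log-likelihood of the pattern under a gain/loss Markov model fitted to the whole collection | nats, $\le 0$ |
| `ONES_KNOWN` | fraction of 1's among non-missing entries | $[0,1]$ |
| `SANKOFF_G1L3` | minimal parsimony cost, loss = 3 × gain | $\ge 0$ |
| `SANKOFF_G3L1` | minimal parsimony cost, gain = 3 × loss | $\ge 0$ |
| `IN_AMPHIBIAN` … `IN_PROTIST` | 1 iff some member of the clade carries the intron | {0,1} |
| `LCA_AGE` | age of the MRCA of intron-bearing species (Dollo single-origin dating) | MY |
| `MED_POSITION` | median distance from CDS start to the junction | nt, 1-based |
| `MED_REL_POSITION` | the same divided by CDS length | $(0,1]$ |

Conventions that needed fixing once and are then load-bearing:

* **Position** is the 1-based count of human non-gap CDS nucleotides from
  the CDS start through the junction-marking nucleotide inclusive, measured
  on the unaligned transcript; only human occurrences enter the medians
  (labeling is human-centred). The median of an even number of occurrences
  is the mean of the two middle values. On-disk interval formats are 0-based
  half-open (BED convention); the internal position is 1-based.
* **Sankoff** treats a missing tip as ambiguous (either state at zero
  cost) and puts no cost on the root state — only gain and loss events are
  priced. The dynamic program is validated against exhaustive enumeration
  over all ancestral assignments on small trees.
* **`LOG_LIKE` surrogate.** The original feature came from an EM package
  with branch-heterogeneous gain/loss rates whose exact model is not
  reproducible from its description; here a *homogeneous* two-state CTMC
  (gain/loss in events per MY, root at the stationary distribution, rates
  fitted by L-BFGS-B on log-rates from several starts, patterns weighted by
  multiplicity by default) supplies the same semantics — "how typical is
  this pattern's evolutionary history" — while being fully specified and
  testable (pruning algorithm checked against brute-force summation;
  parameter recovery checked by simulation). It is a surrogate, and values
  are not numerically comparable to the original tool's.
* **Clade map.** The default groups follow the species grouping that
  defines the clade features (note that it places *Anolis carolinensis*
  with the amphibians, an oddity of the original grouping); the map is a
  plain TSV and user-overridable.

## Fisher-discriminant view

`fisherEmbedding()` reproduces the 2-D visualisation: standardize, project
to the top 7 principal components, compute the Fisher direction
$w \propto S_W^{-1}(m_1 - m_0)$ between functional and non-functional
patterns (partial patterns are projected but do not shape $w$; a ridge
$10^{-6}\,\mathrm{tr}(S_W)/d$ is added only if $S_W$ is singular), then use
the first principal direction of the $w$-residual as the second axis. Signs
are oriented so the functional mean is positive on x and the dominant
loading of the y-direction is positive, making output deterministic.

## Feature importance battery

Four techniques, one shared seed so differences reflect features rather
than restart luck (restarts are reduced to 10 inside the battery):
mutual information between each feature and the predicted labels (plug-in
estimate, continuous features in 10 equal-frequency bins, log base 2);
leave-one-out and single-feature retraining, scored by
$\mathrm{Performance}(F) = \sum_p (Pr_F(p) - Pr_0(p))^2$ against the
full-model predictions; and the sequential "remove two, add one" selection,
which removes the least informative *pair* and re-adds the best feature
from the entire rejected set (including features rejected in earlier
iterations), one net feature per iteration — 13 features yield a survivor
after exactly 12 iterations. An empty working set is handled by an
intercept-only fit so the last iteration is well-defined.

## Supporting statistics

`compareGroups()` runs the two-sided equal-variance t-test and the
Mann–Whitney U test with Bonferroni correction (p × number of tests, capped
at 1); zero pooled variance reports U only. `hypergeomEnrich()` is the
upper-tail hypergeometric probability $P(X \ge k)$. `repositioningTest()`
implements the null that an element is equally likely to sit anywhere it
wholly fits inside any intron of its transcript: the host intron is drawn
with probability proportional to its count of valid start positions, which
is exactly the law of uniform placement over the concatenated intronic
space with boundary-spanning draws rejected, without the rejection loop.
Per-transcript results are summarised by the share of cases with landing
fraction ≥ 0.95.

## The synthetic-data generator

Real architecture datasets of this kind are not redistributable, so the
generator (`simConfig()` / `simulateArchitectures()`) emulates their
statistical structure and is itself first-class, tested code. Defaults are
chosen once as the study conditions:

* a minority functional class (`pFunctional = 0.1`, matching the ~10%
  functional share of unique patterns) with **lower loss rate**
  (1.5e-4 vs 6e-4 events/MY; shared gain 2e-4 — loss-dominated evolution on
  a ~1,768 MY tree keeps roughly half the entries present, as in the real
  feature tables), **older origin** (root presence 0.95 vs 0.6), and
  **5'-biased positions** (relative CDS position Beta(1,6), median ≈ 0.11,
  vs uniform for the background) — the direction, not the magnitude, of the
  real contrasts;
* CDS lengths lognormal(log 2800, 0.35) and intron lengths
  lognormal(log 1500, 0.6) nt; per-set missing-species fractions
  Beta(2, 5), zero-inflated so 40% of sets have complete coverage (complete
  sets are what lets identical patterns recur and collapse with
  multiplicity > 1);
* columns conditioned on presence in human (the human-centred ascertainment
  of the real data), with a regeneration cap and a warning if conditioning
  fails;
* one-sided label noise applied at the **unique-pattern** level
  (`theta11 = 0.2`), then materialised as BED elements for every occurrence
  of an observed-functional pattern, so the emitted files and the ground
  truth are exactly consistent.

What the generator does **not** emulate: insertions/deletions (rows are
trivially aligned), within-set species-specific gap blocks (missingness is
all-or-none per species per set), branch-heterogeneous rates, sequence
content, and correlated evolution between neighbouring introns. Passing
tests therefore demonstrate the machinery's correctness under the assumed
generative structure, not performance on real genomes.

## Problem sizes used in the tests

The suite validates parsimony and likelihood against exhaustive oracles on
trees of up to 6 leaves (1,000 random Sankoff cases), EM against direct
numerical maximisation at $n \le 200$, parameter recovery at $n = 5{,}000$
over $\theta_{11} \in \{0.1, 0.2, 0.5\}$ (20 seeded runs each, ±0.05), the
importance battery on 20 seeded planted-signal runs, and the full pipeline
end-to-end at ~850 simulated ortholog sets. The acceptance script runs the
study at 600 sets with 20 EM restarts. These sizes were chosen to exercise
the asymptotics the estimators rely on while keeping a full run in minutes
on one CPU.

## Known limitations

* The classifier only sees evolutionary signatures, so recently exapted
  introns — whose patterns look like background — are invisible to it by
  construction.
* $\theta_{11}$ and $P_{10}$ are identified through the logistic model; if
  the feature–functionality relationship is badly misspecified, both are
  biased.
* The `LOG_LIKE` surrogate is homogeneous across branches; lineages with
  exceptional loss regimes (e.g. massive intron loss) are scored as
  atypical rather than modeled.
* The packaged 28-species tree is a synthetic fixture with approximate
  round ages, shipped for testing and examples, not an inference-grade
  chronogram.
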