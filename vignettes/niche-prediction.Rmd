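---
title: "Predicting ecological niches from metabolome and transportome models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ecological niches from metabolome and transportome models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecast)
```

## The problem

A bacterium's ecological role — whether it forms biofilms, protects plant
roots from pathogens, promotes plant growth, or causes disease — is rarely
legible from raw sequence similarity. Genomes of organisms with very
different lifestyles can be highly homologous, and hierarchical clustering
of gene-content profiles typically fails to group organisms by role.
`nichecast` implements a different route: transform genome content into
*system-scale capacity scores* — what the encoded metabolism can make and
consume, and what the encoded transporters can move across the membrane —
and learn niche membership from those scores with linear support vector
machines. Niches are treated as non-exclusive: one organism may belong to
any number of them, so each niche gets its own independent binary
classifier.

## From annotation to scores

**Function profiles.** Each genome is reduced to two count vectors: how many
genes carry each enzyme activity (EC number), and how many carry each
transmembrane transporter annotation (KO identifier). Counts come from a
best-hit rule over standard 12-column protein alignment tables: a protein is
assigned the function of its minimum-e-value hit among hits with e-value
strictly below $10^{-10}$. The threshold is strict because the assignment
rule is stated as an inequality, and e-value ties are broken by the higher
bit score and then the lexicographically smaller subject identifier so that
the assignment is a total order — deterministic and invariant to the order
of rows in the hit table. A protein may legitimately count toward both the
enzyme and the transporter profile; the two namespaces never mix.

**The enzyme interaction network (EIN).** A reaction list (function,
substrates, products) becomes a metabolite-by-function matrix $M$: per
reaction, $+1$ for each product and $-1$ for each substrate, summed over a
function's reactions. The matrix deliberately ignores stoichiometric
coefficients, flux and mass balance — it encodes *which* compounds a
function can produce or consume, not how fast or in what ratio. Two
conventions are left open by that definition, and both are exposed as
options with fixed defaults: reversible reactions are counted once in their
annotated direction (`reversible = "both"` adds the mirrored reaction), and
no per-function column normalization is applied (`normalize =
"per_function"` divides each column by the number of compounds the function
touches, a convention some earlier turnover-score implementations used).
A compound appearing on both sides of one reaction cancels to a net zero
contribution for that reaction.

**Scores.** For genome $x$ with count vector $c_x$, reference counts
$c_{\mathrm{ref}}$, and pseudocount $p$,

$$\mathrm{score}(x) \;=\; M \left(\log_2(c_x + p) - \log_2(c_{\mathrm{ref}} + p)\right).$$

With the EIN this is the Predicted Relative Metabolic Turnover (PRMT)
vector over metabolites: positive entries mean an increased relative
capacity to synthesise a compound compared to the reference, negative ones
an increased relative capacity to consume it. With a binary
transporter–ligand matrix $T$ (a 1 where a ligand is moved by a transporter
of that annotation) the identical computation gives the Predicted Relative
Transmembrane Transport (PRTT) vector over ligands. PRTT is implemented as
the exact special case of PRMT — same code path, binary matrix — and a test
asserts the equality. Neither score is a rate, flux, or concentration.

The reference is the across-genome arithmetic mean of the *raw* counts,
log-transformed afterwards; the mean-then-log order follows the raw-count
form in which the average reference is defined (the alternative, averaging
logs, is a different statistic and is not provided). The pseudocount
defaults to 1 so that an absent function maps to $\log_2(0+1) = 0$,
preserving the "no capacity" reading of a zero count; it is exposed because
the handling of zeros is otherwise undefined. Functions present in the
interaction matrix but absent from every genome are kept as zero counts
(with a warning) so a matrix built from a broader reaction catalogue than
the genome set remains usable.

**Secondary metabolism.** The secondary-metabolism feature type is the same
PRMT computation after restricting the reaction list to a designated subset
of enzyme activities (in real use, a secondary-metabolite biosynthesis
pathway set); `subset_network()` filters the reactions and the EIN is
rebuilt from the remainder.

## The classifier

Four feature types feed the learner: raw enzyme function counts, PRMT
scores, secondary-metabolism PRMT scores, and PRTT scores. For each niche,
`niche_svm()` trains a binary linear SVM (niche vs. rest) and validates it
leave-one-out: every genome is held out once, the model is trained on the
rest, and the held-out genome's predicted class and signed distance to the
hyperplane are recorded. Leave-one-out is the right scheme at this scale —
tens of genomes against hundreds of candidate features, with some classes
small enough that a coarser K-fold would leave them unrepresented in
training.

Numerical and procedural choices, with their defaults and reasons:

* **Feature filter.** Before training, features must be nonzero in strictly
  more than half of the genomes and have sample standard deviation strictly
  above 0.2 — presence in most genomes, and variation worth modelling. The
  filter applies to the values exactly as fed to the SVM for each feature
  type. By default it is fit once over all genomes (the conventional
  procedure this package operationalises); `filter_per_fold = TRUE` refits
  it inside every leave-one-out round so the held-out genome can never
  influence feature selection. The package's own recovery tests use the
  leakage-free mode.
* **Cost selection.** The soft-margin cost is chosen per training set by an
  internal stratified 10-fold cross-validation over
  $C \in \{0.01, 0.1, 1, 10, 100\}$, ties going to the smallest $C$. The
  grid is the standard decade grid; the tie rule prefers the smoother
  model and makes selection deterministic. Fold assignment is stratified by
  class and seeded; the seed is recorded in the fit.
* **No feature scaling inside the SVM.** Weights then live in the units of
  the features, which keeps the high-weight rule interpretable; the filter
  has already removed near-constant features.
* **Class weighting.** None by default; `balanced = TRUE` weights classes
  inversely to frequency for strongly imbalanced niches.
* **Degenerate folds.** A leave-one-out round whose training set is
  single-class yields an undefined prediction (recorded as `NA`), not an
  error; a niche with fewer than two genomes in either class is skipped
  with a warning.

**Confidence.** Each held-out prediction gets the confidence
$1 - \int_0^{z}\phi(t)\,dt$, where $z$ is the held-out decision distance
divided by the sample standard deviation of the absolute decision distances
of the positive training examples, and $\phi$ is the standard normal
density. Assignments with confidence $\ge 0.95$ are flagged significant,
which happens for $z \le \Phi^{-1}(0.55) \approx 0.1257$. Taken literally,
the statistic is maximal *at* the hyperplane and decreases with distance —
the opposite of the usual margin-confidence intuition. The literal form is
the default because it is the stated definition; `confidence_mode =
"centered"` instead measures the distance from the mean of the positive
training distances, an alternative reading under which confidence is
maximal in the bulk of the training positives. The package takes no
position on which reading is "right"; both are computed from the same
training quantities. Mathematically the literal statistic lies in
$(0.5, 1]$; at very large $z$ it underflows to exactly 0.5 in floating
point.

**F-score and high-weight features.** Per niche, the leave-one-out
confusion counts give $F = 2PR/(P+R)$ with $P = tp/(tp+fp)$ and $R =
tp/(tp+fn)$; when $P = R = 0$ the F-score is reported as 0 (flagged), and
when a denominator is zero it is reported as not computable. The canonical
weight vector per niche comes from a final model refit on all genomes with
the cross-validated cost — one canonical vector rather than n per-fold
ones, with the per-round costs kept in the fit for inspection. A feature is
high-weight when its weight lies more than two sample standard deviations
from the mean weight. `niche_overlap()` partitions the union of per-niche
high-weight sets by exact membership pattern, as percentages that sum
to 100.

Sample (n−1) standard deviations are used everywhere a standard deviation
appears — filter, high-weight rule, confidence — for consistency with the
default behaviour of the statistical environments these analyses are run
in.

**Clustering baseline.** `cluster_profiles()` provides the contrast the SVM
is measured against: agglomerative clustering of raw profiles under
Bray–Curtis dissimilarity with group-average (UPGMA) linkage — the
canonical community-ecology workflow. Both choices are configurable since
profile clustering conventions vary; the implementation is
`vegan::vegdist()` plus `stats::hclust()`, and the tests check it against a
naive $O(n^3)$ agglomeration oracle.

## What the synthetic generator emulates — and what it does not

`synthetic_niche_data()` generates every input the pipeline reads, from a
single seed:

* **Counts** are negative binomial (mean 1.5, dispersion 2 by default):
  gene-family counts are overdispersed, and these values give a realistic
  zero fraction (~33%) so the "nonzero in more than half" filter actually
  bites.
* **The reaction network** is sparse and random: each enzyme function gets
  a Poisson number of reactions (mean 2, floored at 1) with one or two
  substrates and products each; 20% are marked reversible.
* **The transporter–ligand matrix** is binary with one to a few ligands
  per transporter.
* **Labels** are independent Bernoulli draws per niche (prevalence 0.4 by
  default), mirroring non-exclusive niche tables, with at least two genomes
  forced into each class.
* **Signal** is planted as an additive count shift (default: 5 transporter
  features shifted by 4 in positives of the first niche). Planted
  transporters are given one *dedicated* ligand each, transported by no
  other transporter, so the planted signal has an unambiguous ground truth
  at the score level — the manifest records both the planted functions and
  those ligands, and recovery is judged on the ligands the transportome
  model can actually see.

The default dimensions (60 genomes, 120 enzyme functions, 60 transporters,
150 metabolites, 40 ligands) are the package's study conditions: large
enough that leave-one-out F-scores are stable and the 2-SD high-weight rule
has a meaningful weight distribution to work with, small enough that the
full 4-feature-type × 4-niche factorial fits comfortably in a routine test
run.

What the generator does **not** emulate: phylogenetic correlation among
genomes (real Pseudomonads are not exchangeable draws; related strains
share both labels and profiles), annotation error structure (best-hit
assignment errors are correlated across related genomes), currency
metabolites that touch hundreds of reactions, and any realistic pathway
topology. Passing the recovery tests therefore shows the estimator and its
plumbing are correct — it does not certify performance on real genome sets,
where shared ancestry can inflate apparent accuracy.

## Numerical edge cases

* `log2(count + pseudocount)` with a zero sum is a hard error, not a
  silent `-Inf`.
* A transporter–ligand matrix cell other than 0/1 is fatal, with its
  coordinates; duplicate row or column identifiers are fatal in any
  interaction matrix.
* An all-zero interaction-matrix column (a function whose reactions cancel
  exactly) is a warning, not an error.
* Removing every feature in the filter is fatal with per-rule diagnostics.
* Zero variance in positive training distances makes the confidence
  undefined for that niche (error, with explanation); zero variance in
  weights flags nothing as high-weight (warning).

## Reproducibility

Every stochastic step — generation, fold assignment, permutation controls —
flows from explicit integer seeds, and seeded runs are bit-identical
(`with_seed` restores the caller's RNG state, so library calls do not
perturb user scripts). `run_pipeline()` stamps every output table with a
hash of its configuration and writes a JSON manifest; `read_pipeline_table()`
refuses a table whose stamp disagrees with the manifest beside it, so
intermediates from different runs cannot be silently mixed.

```{r example, eval = FALSE}
bundle <- synthetic_niche_data(synthetic_spec(seed = 42))
res <- run_pipeline(bundle$enzyme_profiles, bundle$transporter_profiles,
                    bundle$reactions, bundle$transportome, bundle$labels,
                    bundle$secondary_functions, seed = 42)
res$f_scores         # feature type x niche LOOV F-scores
plot(res)
```

## Known limitations

* Linear kernels only; the design follows the framework this package
  implements, which found linear margins sufficient at these sample sizes.
  Nonlinear kernels and mixed feature-type models are out of scope.
* The confidence statistic is a calibration heuristic, not a posterior
  probability; see the discussion of its two readings above.
* With very small niches (2–3 positives), leave-one-out F-scores are
  high-variance and the internal 10-fold cost selection can see folds with
  no positive test genomes; such folds are skipped in the accuracy
  average.
* The EIN is stoichiometry-free by construction: scores rank relative
  capacities and must not be read as fluxes or concentrations.
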