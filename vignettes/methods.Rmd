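---
title: "Methods: sequence-only PPI prediction and its downstream network analyses"
author: "ppiforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-only PPI prediction and its downstream network analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the synthetic-data generator that backs its
test suite, and the numerical and design choices made where more than one
reasonable option existed.

## 1. Domain-pair log-of-odds scores

The central premise is that physical interaction between proteins is
mediated by conserved domains, so domain pairs over-represented among
interacting protein pairs carry transferable evidence. Given a set of
verified interacting pairs and each protein's *unique* PFAM domains
(repeats within a protein are collapsed), every interacting pair (P, Q)
contributes one count to every distinct unordered domain combination of
the cross product domains(P) × domains(Q). With `n(Dx,Dy)` the pair count,
`n_p` the total of all pair counts, and `n(Dx)` the number of proteins of
the interaction set carrying `Dx` (counted once per protein regardless of
how many interactions the protein appears in — the set-level reading of
the marginal):

\[
\mathrm{LOD}(D_x,D_y) \;=\; \ln\frac{f(D_x,D_y)}{f(D_x)\,f(D_y)},\qquad
f(D_x,D_y)=\frac{n(D_x,D_y)}{n_p},\quad
f(D_x)=\frac{n(D_x)}{\sum_i n(D_i)} .
\]

Choices worth recording:

* **Log base.** Natural log throughout (here, in the ontology similarity,
  and in the literature score). Base only rescales features monotonically
  and cannot change a tree ensemble's behavior.
* **Unobserved pairs score exactly 0.** Absence from the verified set may
  mean non-detection rather than non-interaction, so unseen pairs are
  neutral, not penalized; `lod_score()` returns 0 rather than −∞.
* **Self-interactions are counted** in the odds stage; exclusion rules
  apply only in downstream evaluation and network stages, where
  self-pairs inflate similarity trivially.
* A held-out split (`holdout_split()`) is taken *before* counting, so
  test interactions never touch the odds table.

## 2. Features and the random-forest protocol

An ordered pair (A, B) yields: `lod_sum`, `lod_max`, `lod_min_ceil0`
(the minimum scored LOD capped at 0 — when every scored combination is
positive the statistic is 0), `n_pairs_scored`, `n_pairs_unscored`,
`n_domine_interacting` and `domine_max_conf` from a domain–domain
interaction catalogue, then the localization feature blocks of A and B.
With no scored combination all three LOD features are 0 (the neutral
score), never −∞. Two presence indicators (`locA_present`,
`locB_present`) accompany the localization blocks; under the default
strict mode they are constantly 1 and carry no information, but they make
the optional zero-fill mode (`allow_missing_loc = TRUE`) explicit to the
classifier rather than silent.

The localization schema is not hard-coded: any consistent named numeric
vector per protein is accepted. `default_localization_schema()` documents
the conventional column set (compartment probabilities plus raw
subprogram scores of a MultiLoc2-style predictor); compartment
probabilities are *not* required to sum to one because raw subprogram
scores are unnormalized by nature.

Training follows the published protocol: positives from the verified set
(default 1,330), a large uniform negative sample (default 101,300), and a
spiked negative set (default 1,300) whose endpoints are drawn with
probability proportional to each protein's multiplicity among the
interacting pairs — this prevents the forest from learning "proteins that
appear in the positive set interact with everything". Every pair enters
the design matrix twice with the localization blocks swapped; domain
features are order-invariant by construction. The forest has 400 fully
grown trees (`nodesize = 1`, conventional classification defaults
otherwise); confidence is the fraction of trees voting positive, which
lands on the same [0, 1] scale as the catalogue confidences.

**Union rule.** Prediction scores both orientations and keeps the
maximum: a union of thresholded sets equals thresholding the max, so this
reproduces set-level union behavior at every threshold simultaneously.
The mean is available behind `combine = "mean"`. Candidate enumeration
covers all n(n+1)/2 pairs including self-pairs; work is split into
deterministic chunks whose merge order is fixed, so the output is
byte-identical for any worker count.

## 3. Evaluation and functional similarity

Sensitivity TP/(TP+FN) and specificity TN/(TN+FP) come from explicit
truth sets; zero denominators yield a flagged `NA`, never silent NaN. AUC
is the midrank Mann–Whitney statistic (ties count ½), which is invariant
under strictly monotone transforms of the scores.

Three plausibility measures compare a network against degree-preserving
rewired versions of itself (self-interactions excluded, network first
narrowed to annotated proteins):

* **Pathway sharing** — fraction of edges whose endpoints share a pathway
  (default), or mean Jaccard (`kegg_jaccard`). Both are exposed because
  "frequency of shared pathways" admits either reading.
* **Ontology similarity** — `p(c)` is the fraction of annotation
  *occurrences* falling on `c` or any descendant; pair similarity is
  −ln of the minimal `p` over shared ancestors, a term counting as its own
  ancestor (otherwise self-similarity would be uninformative); the
  protein-level score is the maximum over term cross pairs; computed per
  namespace when multiple ontologies are used. Terms with `p = 0` are
  dropped with a warning rather than producing infinite scores.
* **Co-expression** — fraction of measurable edges with Pearson ρ > 0.5
  across samples (≥ 3 samples required); a bootstrap CI resamples edges
  (default 250 replicates) and the null CI comes from 250
  degree-preserving randomizations.

## 4. Graph machinery

Degree-preserving randomization uses double edge swaps (10·|E| attempted
swaps per replicate — common practice; exact degree preservation and
simple-graph constraints are asserted in tests). Degree-proportional
random graphs (the null for the disease network) sample endpoint pairs
with probability proportional to a degree template, rejecting duplicates
under a 100× budget; unlike edge swaps this preserves the degree
*distribution* only approximately, which is what that null calls for.

MCL is implemented directly (no Markov-clustering package is available
as a dependency): self-loops with weight equal to the node's maximum
incident weight (the usual convergence device), expansion by squaring,
inflation with exponent 2, pruning below 1e−5, convergence when the
matrix change falls under 1e−6; clusters are the connected components of
the limit matrix's support, which assigns every node exactly once and is
deterministic.

## 5. Pathway linkages, compound sharing, enrichment

Two pathways are linked when one or more predicted interactions join
their member protein sets; predicted self-interactions never count, and a
protein belonging to both pathways contributes interactions, not
identity. A linkage is retained when its observed support strictly
exceeds the support in at least 99.9 % of 10,000 degree-preserving
randomizations of the predicted PPI network (ties count against
retention, the conservative reading of "greater than"). Edge weight is
observed support over the number of possible non-self cross pairs.
Compound sharing among retained linkages discounts compounds present in
more than 15 pathways (ATP-style ubiquity); its null rewires the linkage
graph itself, and the empirical p-value is floored at 1/(n_random + 1).

Cluster enrichment: each pathway annotates every ontology node it
descends from (one annotation per node, through its class terms); for a
cluster with `M_g` annotations of which `M_gt` lie on the node of
interest, against `M_t` of `M_tot` total annotations,

\[
p = \sum_{i=M_{gt}}^{\min(M_g,M_t)}
\binom{M_t}{i}\binom{M_{tot}-M_t}{M_g-i}\Big/\binom{M_{tot}}{M_g},
\]

the hypergeometric upper tail, with significance at 0.05/(n_C·n_O) under
Bonferroni over clusters × ontology nodes. Tests pin this to exhaustive
enumeration for all parameter combinations with `M_tot` ≤ 12.

## 6. Disease associations

Diseases are linked when predicted interactions join their causative gene
sets (self-interactions excluded — a merely shared causative gene never
creates an association), retained under the same exceedance rule. Each
retained pair is scored by literature similarity

\[
\mathrm{sim} = -\frac{|P_x \cap P_y|}{\min(|P_x|,|P_y|)}
\,\ln\!\big(\max(p_{OM}(M_x),\,p_{OM}(M_y))\big),
\]

where each disease keeps only its most significant vocabulary term, `P`
are the terms' PubMed id sets and `p_OM` the disease–term association
p-values; diseases without a mapped term are dropped by the reader. The
observed score distribution is compared against degree-proportional
random networks (default 250) with a one-sided KS test, alternative
"observed stochastically larger"; the p-value uses the standard one-sided
asymptotic bound exp(−2nmD²/(n+m)).

## 7. Duplicate retention after WGD

For one WGD event, `retained ~ log(DC) + DN + log(DC):DN` with a logit
link, where DC is degree centrality d/(n−1) on the thresholded predicted
network and DN the fraction of a gene's neighbors retained in duplicate.
Genes need ≥ 1 interaction; because a single-neighbor gene can only score
DN ∈ {0, 1}, the model is also fit on the ≥ 10-interaction subset, and
both fits are reported. Significance comes from case-resampling bootstrap
(default 10,000 resamples; replicates collapsing to one response class
are redrawn, counted, and capped at 20 attempts) with percentile CIs at
95/99/99.9 %; a coefficient earns one star per level whose interval
excludes 0. CI-exclusion, not Wald tests, defines the stars, matching the
resampling framing of the analysis.

## 8. The synthetic-data generator

The generator mirrors the classifier's two feature families by design, so
positive controls are meaningful: a hidden symmetric domain-affinity
matrix (8 % of domain pairs carry affinity ~ N(3, 0.5)) and a
compartment-agreement term feed a logistic model whose intercept is
calibrated so the expected edge count hits `n_true_interactions`.
Defaults: 200 proteins, 1–3 domains each from a 40-domain vocabulary,
400 expected interactions (mean degree 4, within the range of curated
interactomes), `affinity_strength = 2` — chosen so that the *oracle*
classifier (scoring pairs by their true generative probability) separates
edges from non-edges almost perfectly, leaving the end-to-end benchmark
headroom to demonstrate signal recovery rather than generator noise. The domain-evidence table emulating a
DOMINE-style catalogue is a 70 %-recall noisy view of the planted
affinities with a few spurious entries — the same epistemic relation the
real catalogue has to real interactions. A `"motif"` mode plants
interactions via hidden labels invisible to domain features, emulating
the known failure mode of domain-based predictors on proteins without
informative domains.

Annotation-side tables derive from module labels propagated along true
edges with probability `pathway_coherence` (0 switches the pathway,
ontology and expression nulls on exactly). Expression mixes a per-module
archetype with noise (`expression_edge_cor`). Disease literature uses a
co-citation model: every true interaction contributes one paper cited by
both endpoint genes (with probability `disease_literature_signal`), plus
private and background papers per gene — so diseases genuinely linked
through interacting genes share literature, while module-pool designs
(rejected during development) gave linked-but-distant pairs no overlap.
Retention flags are drawn from the logistic retention model itself (two
Gibbs sweeps so the duplicated-neighbor fraction feeds back), with
generator coefficients (−2.2, −0.5, +2, +0.5): negative degree effect,
positive duplicated-neighbor effect — the gene-balance signature. The
exogenous covariate generator for recovery checks uses heavy-tailed
negative-binomial degrees (n = 1,000 nominal nodes) so log-centrality
spans several units; a narrow degree distribution makes DN and the
interaction term nearly collinear and was rejected during design.

**What passing tests do and do not show.** The generator plants exactly
the signal the method looks for; recovery demonstrates correctness of the
machinery (counting, scoring, nulls, inference), not real-world accuracy.
Real proteomes have correlated domain co-occurrence, shared evolutionary
history between training and test pairs, study bias in verified
interactions, and annotation incompleteness, none of which are emulated.

## 9. Problem sizes and determinism

The package's experiments run at desk scale by choice: 200-protein
proteomes, 200 randomizations at quantile 0.995 for linkage significance
(the published protocol's 10,000 at 0.999 remains the default for real
runs), 1,000-resample bootstraps at n = 2,000 for recovery checks, 20-seed
repetition for specificity/sensitivity properties. Every stochastic
function takes an explicit seed, restores the caller's RNG state, and
yields byte-identical output for any worker count; the command-line
chain is verified end-to-end for byte identity under a fixed seed.

## 10. Known limitations

* Proteins lacking PFAM domains are scored on localization alone; the
  `"motif"` generator mode exists precisely to exhibit this blind spot.
* The LOD table treats domains independently; correlated domain
  architectures inflate apparent evidence.
* The asymptotic one-sided KS bound is anti-conservative for very small
  observed networks; the experiments keep ≥ ~10 edges in play.
* MCL cluster boundaries depend on the inflation parameter; only the
  conventional default (2.0) is exercised by the tests.
* The degree-proportional null reproduces degree distributions only in
  expectation, unlike the exact edge-swap null — both are intentional,
  matching the stage each serves.
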