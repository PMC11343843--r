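---
title: "Methods: from multi-omics contrasts to sign-coherent signaling models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multi-omics contrasts to sign-coherent signaling models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`signalflow` models how a cellular perturbation propagates through the
signaling network. This vignette documents the statistical and
combinatorial machinery behind each step, the assumptions baked into the
defaults, and the choices we made where the design was genuinely open.

```{r setup}
library(signalflow)
```

## Inputs and the causal prior

All analysis is primed by a **prior-knowledge network (PKN)**: a directed
graph of causal interactions under the activity-flow model, each edge
signed +1 (up-regulation, including complex formation) or −1
(down-regulation). Three tabular dialects are parsed:

* *SIGNOR-like* interaction tables (`parse_signor_like()`): effect labels
  beginning with `up-regulates`/`down-regulates` and `form complex` map to
  +1/−1/+1; rows touching `protein family` entities are dropped because a
  family is not a causal actor with a defined gene product; unrecognized
  labels are dropped with a count.
* *PhosphoSitePlus-like* kinase–site and regulatory-role tables
  (`parse_regulatory_sites()`): an inner join on (substrate, residue)
  yields kinase→substrate phosphorylation edges whose sign comes from the
  regulatory-role text; sites with no defined regulatory effect (mapped to
  0) are excluded, because an edge of unknown sign cannot constrain a
  sign-coherent model.
* *Kinome-atlas-like* percentile tables (`parse_kinome_atlas()`): a
  relation enters regulons when its percentile strictly exceeds the regulon
  threshold (default 88) and the PKN when it strictly exceeds the PKN
  threshold (default 99) *and* a regulatory role supplies its sign. Regulon
  weights map the percentile linearly from [threshold, 100] onto
  [0.5, 0.9]; we chose the linear form as the simplest monotone map onto
  that range.

`assemble_pkn()` unions edge sets and applies increasingly exclusive
filters (presets 1–6: direct-only, unfiltered, proteins-only, no-atlas, and
the organism mirror of the first two). When two databases disagree on the
sign of the same (source, target, residue) edge, the manually-curated
record wins; an unresolvable tie drops both records with a message. This
rule is our own: the upstream resources do not document how such conflicts
should collapse, and silently keeping an arbitrary sign would corrupt the
optimization downstream. `preprocess_pkn()` removes edges whose protein
endpoints were not quantified in the experiment (complexes, metabolites and
phenotype nodes are exempt, since they are never directly quantified).

## Step 1 — protein activities

**Footprint enrichment** (`footprint_enrichment()`) scores a regulator by
its targets. Signature statistics are rank-transformed to symmetric normal
quantiles `q = qnorm(rank / (n + 1))`, which makes the score scale-free and
robust to heavy-tailed fold-change distributions. For a regulon with modes
`m` and weights `w`,

`NES = sum(w * m * q) / sqrt(sum(w^2))`.

Under the null (targets exchangeable with the rest of the signature) NES is
approximately standard normal, so a two-sided p-value is read from
`pnorm`. This is the analytic rank-based core of the VIPER family of
methods reduced to a single two-sided test; the original three-tail
combination is deliberately simplified, and the simplification is
compensated by the hypergeometric weighting below. Regulons with fewer than
`min_targets` (default 5, our choice — small regulons give unstable ranks)
targets in the signature are skipped.

**Hypergeometric weighting** (`hypergeometric_weighting()`) multiplies NES
by `1 − P[X ≥ k]` where `X` is hypergeometric over (N analytes, K
significant, n targets, k significant targets). A regulator whose targets
are no more significant than chance keeps little of its score. The
functional form NES·(1 − p) is our own concretization of "weight the
activity by the significantly modulated analytes": it is continuous,
preserves sign, and vanishes exactly when over-representation is absent.

**Proteomics correction** (`proteomics_correction()`) implements the rescue
rule: a regulator that is non-significant by enrichment but significantly
modulated in proteomics enters the activity table with the sign of its
protein fold-change (method `proteomics_rescue`). When both calls are
significant but discordant, the footprint call wins and a flag is set —
footprints reflect activity, abundance only a proxy of it.

**Phospho normalization** (`normalize_phospho()`) subtracts the parent
protein's fold-change from each phosphosite's fold-change, then z-scores
the corrected distribution with its mean and sample standard deviation;
a site is significant iff |z| > 1.96 (strict, i.e. p < 0.05 two-sided).
Sites without a quantified parent pass through unchanged but stay in the
distribution, flagged `parent_quantified = FALSE`. A zero-variance
corrected distribution is an error with guidance rather than silent NaNs.

**PhosphoScore** (`phospho_score()`) averages (site statistic × regulatory
sign) over a protein's significant regulatory sites. With
`activity_only = TRUE` (default) abundance-only sites are excluded so that
the score reads as activity, not stability. Whether all quantified or only
significant sites should contribute is not settled; we default to
significant-only (configurable) to keep the score driven by real signal.
A protein whose site contributions cancel to exactly zero is omitted — its
activity is undetermined, and an arbitrary sign would poison Step 2.

`combine_activities()` unions footprint and PhosphoScore results. When both
methods score a protein the footprint record is kept and agreement recorded
(`phospho_concordant`); proteins absent from the molecular-function
annotation are labeled OTHER with a message.

## Step 2 — the naive network and the exact optimizer

`build_naive_network()` spans the PKN subgraph formed by **all** shortest
paths (not one arbitrary path — ties would otherwise make the network
depend on hash order) of length ≤ `max_len` per layer boundary:
sources → kinases/phosphatases → other signaling proteins → TFs for the
three-layer layout; two- and one-layer layouts merge the downstream sets.
Self-loops are dropped before path search. With `connect_all = TRUE` every
PKN edge between nodes already in the network is added, capturing cross-talk
between parallel branches.

`ilp_optimize()`/`solve_sign_coherent()` finds the global optimum of

minimize  Σ_measured w·|measured − state| + β·(#selected edges)

subject to: states in {−1, 0, +1}; a selected edge (u→v, σ) requires
state_u ≠ 0 and supports state_v = σ·state_u; every nonzero non-source
node has ≥ 1 selected incoming edge; the selected set is acyclic. The
mismatch cost |measured − state| is 0/1/2 for matched/absent/opposed — an
opposed call is twice as bad as no call. Two structural facts make exact
search tractable: (i) any feasible state assignment is *grounded* — every
nonzero node is reachable from a source through coherent edges among
nonzero nodes — and (ii) given grounded states, the cheapest edge set is a
breadth-first parent forest with exactly one incoming edge per nonzero
non-source node. The solver therefore branches over node states only, with
admissible per-node lower bounds, reachability pre-filters (states not
reachable with either sign are never tried; nodes that cannot influence a
measured node are pinned to 0), and a grounding check at each leaf. This is
an exact algorithm for the stated integer program, verified against a
brute-force oracle over all state assignments and edge subsets on random
instances. It is designed for the naive-network scale (tens of nodes after
layering); for very large dense networks the multi-shot decomposition below
is the intended route.

Defaults: β = 0.2 and measured weights |score| normalized to [0, 1] — the
penalty is deliberately below the weight of flipping any strong
measurement, so edges are pruned only when they explain nothing. The
*vanilla* flavor fixes the perturbed nodes' signs; the *inverse* flavor
attaches an artificial perturbation node to a receptor candidate set by
free-sign edge pairs and optimizes over both of its signs, for experiments
where the perturbation target is unknown. Note the inverse perturbation
sign is identifiable only through asymmetries in the receptor set's
downstream coherence, not by construction.

`run_multishot()` (shots 1–3) splits the layer boundaries into consecutive
groups, solves them in order, and seeds each shot with every state solved
so far as fixed-sign sources. Because measurement weights renormalize
within each shot, a weakly-scored kinase that a global solve would sacrifice
to downstream evidence can survive its own shot — this is what lets
three-shot models grow larger than one-shot models. At the union, the more
upstream shot wins state conflicts (logged), incoherent edges are dropped,
and unsupported states are zeroed to a fixed point, so the merged model
still satisfies the coherence and support invariants (the merge is a
heuristic composition, not a global optimum — that is its point).

`validate_edges_with_phospho()` flags phosphorylation edges whose (target,
residue) site is quantified / significant in the phospho table and records
the **SignRatio** — the fraction of model edges validated by significant
phosphorylation events.

## Step 3 — phenotype proximity and PhenoScore

`proxpath_proximity()` measures the functional proximity of model proteins
to phenotype nodes over the PKN augmented with signed protein→phenotype
edges. Sign-constrained shortest paths are computed on a parity-doubled
graph (each node split into +/− copies), so "shortest activating path" and
"shortest inhibiting path" are exact shortest-walk lengths per sign class,
capped at `max_len` (default 4 — long causal chains carry little
regulatory credibility). Each observation is compared to path lengths from
`n_random` (default 100) random source nodes matched on total degree
(sampled without replacement from the nodes closest in degree; as
`n_random` grows the null becomes the exhaustive enumeration), with absent
or over-long paths censored at `max_len + 1`. Significance is z ≤ −1.96 on
`z = (observed − stat(null)) / sd(null)` with `stat` mean (default) or
median. These null choices are our own documented approximation: the
original proximity tool's internals are not restated here, but a
degree-matched null is the standard guard against hub proteins appearing
close to everything. A zero-variance null yields z = 0 (observed equals the
null) or ±∞, which keeps the significance rule total.

`phenotype_activity()` aggregates, per phenotype,

activity = Σᵢ wᵢ·path_signᵢ·activityᵢ / Σᵢ wᵢ

over eligible regulators (model proteins with a significant proximity
path). `use_optimizer_states` chooses between all nonzero model states
(default) and only Step-1-inferred proteins. `remove_cascades` (default on)
drops regulators reachable in the model from another eligible regulator of
the same phenotype, so a linear cascade counts once, through its apex. With
`weight_by_paths` the weight is the regulator's number of significant
sign-coherent routes, computed as walk counts within `max_len` on the
doubled graph — counting simple paths is combinatorially explosive and
walks of bounded length are the standard surrogate. The dominant path sign
of a pair is the sign class with the more negative z; an exact tie breaks
to activating. `attach_phenotypes()` appends one node per phenotype and one
signed edge per contributing regulator.

## Benchmarking and randomization

`prf_rmse()` follows the gold-standard conventions: true/false positives
are inferred entities matching/diverging from the expected sign, false
negatives are inferable gold entities not inferred, and entities flagged
not-inferable are excluded from every count. RMSE compares predicted signs
(scores clipped to ±1) with expected signs over the inferred∩gold set. The
true-negative definition we inherited — "opposite activity than expected
and not inferred" — is internally inconsistent (a protein that was not
inferred carries no sign), so it is implemented literally against an
optional table of candidates scored but excluded from the final output and
defaults to 0; no downstream formula consumes it.

The two combined scores are reproduced exactly:

* Step 2: `(precision·0.5 + recall·0.5 + SignRatio·0.5 + ClusteringCoefficient·0.5) − (NormTime·0.2 + PowerLawFit)`
* Step 3: `(precision + recall) − (normRMSE + normTime·0.5)`

with NormTime/normRMSE each value over its maximum across compared runs.
`PowerLawFit` is the Kolmogorov–Smirnov distance of a maximum-likelihood
discrete power-law fit to the degree distribution (the metric names a
deviation but not an estimator; ML + KS is the standard pairing).

`rewire_network()` randomizes the PKN by double-edge swaps applied
separately within the positive and the negative edge set, preserving every
node's signed in/out degree exactly, until the requested fraction of edges
has moved (densely constrained toy graphs may saturate below the target;
the attempt budget is 200 swaps per edge). `shuffle_analytes()` permutes
the statistic among a seeded `round(fraction·n)` row subset.

## The synthetic fixture generator

`make_toy_pkn()` emulates the structure the pipeline assumes: a connected
signed digraph with stratified roles (TF/KIN/PP counts by `round`, OTHER
the remainder), a layered backbone guaranteeing source → kinase → other →
TF reachability, ~60% activating edges, and phosphorylation mechanisms
with synthetic residues on a configurable fraction of edges.
`make_fixture_bundle()` plants a *coherent* ground truth by propagating the
source perturbation along discovery paths (state = parent state × edge
sign), derives regulons from PKN edges (padded with off-network targets to
`min_targets` — measured analytes need not be network nodes), and simulates
omics as `statistic = mode × activity + N(0, σ)` with σ = 0.5 and
significance at |statistic| > 1.96σ, matching the pipeline's own
z-threshold convention. Test-scale defaults are 25–40 nodes, one perturbed
source, 10 phenotype labels, and a 10% not-inferable gold fraction
(mirroring the shape of curated gold standards, where some expected
proteins are absent from every regulon resource).

What the generator does *not* emulate: mass-spectrometry intensity noise
and missingness (contrasts are taken as given), correlated regulons
(targets are disjoint unless derived from shared PKN edges), isoform and
site-localization ambiguity, and the scale of real PKNs (tens of thousands
of edges). Passing tests therefore demonstrate algorithmic correctness and
statistical behavior under the stated model, not performance claims on any
particular biological dataset.

## Numerical and degenerate-case choices

* Strict inequalities throughout (|z| > 1.96, percentile > threshold,
  z ≤ −1.96 for proximity) so boundary values are never promoted.
* Rank ties are averaged; the quantile transform uses n + 1 to avoid ±∞.
* A saturated hypergeometric table (every analyte significant) weights the
  score to zero and is logged: such a signature carries no selectivity.
* Activity scores of exactly 0 (saturated weighting, cancelling sites) are
  carried in tables but excluded from optimization measurements, where a
  sign is mandatory.
* All generators and null samplers are pure functions of (parameters,
  seed); `run_pipeline()` records the seed and full configuration in its
  run log.

## Limitations

* The exact optimizer's worst case is exponential in the number of
  reachable undetermined nodes; it is intended for layered naive networks,
  with multi-shot composition as the decomposition mechanism.
* Metabolomic, epigenomic and ubiquitylomic layers are out of scope; the
  phenotype vocabulary is whatever the phenotype-edge table provides.
* Organism handling is by explicit gene-symbol namespace; no ortholog
  mapping is attempted.
* The multishot union is a composition heuristic: it preserves coherence
  and support but does not certify global optimality of the merged model.
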