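---
title: "Ancestral domainomes by Dollo parsimony: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral domainomes by Dollo parsimony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domevol)
```

## The model

A domainome is the set of distinct protein-domain types in a genome.
Given per-genome domainomes at the leaves of a rooted species tree,
`domevol` reconstructs ancestral repertoires under Dollo parsimony: each
domain is gained exactly once, and the reconstruction minimizes the
number of subsequent losses. This criterion is appropriate for protein
domains because the independent invention of the same structural domain
is far less likely than repeated loss; it is *not* appropriate for
characters that transfer horizontally, which is why analyses of this
kind restrict themselves to clades where horizontal transfer is
negligible and why the package models no transfer events at all.

For one domain with carrier set $L$ (leaves where it is present), the
gain node is $\mathrm{MRCA}(L)$. Within the gain clade a node is present
iff its subtree contains a member of $L$; every edge from a present node
into a maximal carrier-free subtree is one loss. This assignment
achieves the minimum loss count among all single-gain assignments (the
test suite verifies this against exhaustive enumeration of every
internal-state assignment on every rooted tree shape with up to 7
leaves, binary or not). The tree cost is

$$\mathrm{cost} = \sum_d \big(1 + |\mathrm{losses}(d)|\big),$$

i.e. one gain per domain plus all losses, unweighted. The cost objective
is not uniquely pinned down by the reconstruction itself — one could
count only losses — but for a fixed leaf set the gain term is a constant
($=$ number of domains), so topology *rankings* are unaffected by the
choice; we report both components in the ledger.

Assumptions worth keeping in mind:

* **Rooted, direction-dependent.** Dollo is not invariant to re-rooting.
  Unrooted input is rejected unless an outgroup (`root_on`) is supplied.
  Trees whose outermost node is a polytomy are conventionally written as
  "unrooted" Newick; `assume_rooted = TRUE` accepts them as rooted at
  that node, since published rooted species trees frequently have a
  basal polytomy.
* **Presence/absence only.** Copy number is discarded when a repertoire
  is built; two proteins carrying the same domain contribute one set
  element.
* **Observable domains only.** A domain absent from every analyzed
  genome leaves no trace; all-absent matrix columns are dropped at
  construction (with a warning) because no Dollo event can be placed for
  them. Consequently every inferred ancestral repertoire is a lower
  bound: domains that went extinct in all sampled lineages, or are not
  yet covered by the domain database, are invisible. The simulator makes
  this concrete by flagging fully-lost domains `unobservable` rather
  than deleting them from the truth record.

## Hit filtering

Upstream of the matrix, per-genome hit tables pass three stages, in a
fixed order: score cutoffs, exclusion-list removal, per-protein overlap
resolution (the first two commute; resolution must come last so that a
removed hit cannot suppress a legitimate one).

* **Cutoffs.** Either per-domain curated bit-score thresholds — Pfam
  gathering (GA), noise (NC) or trusted (TC) — applied at the *domain*
  level, or a uniform E-value threshold. Pfam ships sequence-level and
  domain-level threshold pairs; we apply the domain-level value since
  the unit being filtered is a single domain hit. E-value thresholds
  anywhere on and beyond the $10^{-4}\dots10^{-18}$ grid are accepted;
  tightening the threshold can only shrink the repertoire (a tested
  invariant).
* **Exclusion.** Exact string match on version-stripped accessions
  (versions are stripped everywhere so repertoires are comparable across
  database releases). Intended for domains of viral, phage, or
  transposon origin whose presence reflects insertion, not descent.
* **Overlap resolution.** Two hits overlap iff their envelope intervals
  share at least one residue (1-based inclusive; zero tolerance —
  adjacent hits do not overlap). Among overlapping hits the lowest
  E-value wins. Because "lowest E-value" alone is not a total order, we
  rank by (E-value, bit score descending, accession, start) and accept
  greedily; the 4-level key makes the outcome deterministic and
  independent of input order. Resolution is global across all domains,
  not restricted to within-clan competition.

## The functional layer

Domains map to GO terms via the external2go ("pfam2go") line format.
Annotations are closed over `is_a` and `part_of` ancestry — the
true-path rule; `regulates`-type edges are not part of that convention
and are ignored at load. Obsolete terms carry no edges and annotations
to them are dropped with a warning.

A functional profile reports, for each chosen term, the percentage of a
domainome's *annotated* domains carrying that term after propagation.
The denominator is per-namespace (domains with at least one
biological-process annotation, for a biological-process term): genomes
differ in annotation coverage, and an unannotated domain says nothing
about function, so including it would conflate coverage with biology. A
zero denominator yields `NA` rather than 0. Within a namespace the
profile is monotone: a child term's percentage never exceeds an
ancestor's.

Per-branch functional flux counts gained and lost domains annotated to a
category along a user-supplied root-to-node path — the package does not
guess "the" lineage of interest. Each domain counts once per category,
not once per term, to avoid double-counting a domain annotated to
several descendants of the category. Default category and axis terms
are biological regulation (GO:0065007) versus metabolic process
(GO:0008152), and signal transduction (GO:0007165) versus catalytic
activity (GO:0003824); all four are arguments, not constants.

Profile clustering uses average-linkage hierarchical clustering on the
Euclidean distance between percentage vectors, and scores congruence
with a reference tree as the Robinson–Foulds distance normalized to
$[0,1]$ (both trees unrooted for the comparison).

## Enrichment

All methods test one-sided over-representation with the hypergeometric
upper tail, on propagated annotations, against a population that
defaults to the union of annotated domains across all analyzed genomes,
restricted to the tested namespace (biological process by default, per
the convention that gained/lost sets are characterized by process
terms). Terms with zero study hits report $p = 1$.

* **term-for-term**: independent test per term.
* **elim**: terms are processed from most specific to least specific —
  descending longest-path depth, ties broken by term id to keep the
  traversal deterministic — and a term significant at `sig_threshold`
  (default 0.01, the convention of the original elim publication) has
  its annotated study and population domains removed from all its
  ancestors before they are tested. As the threshold tends to zero the
  procedure degenerates to term-for-term exactly (a tested identity).
* **parent-child (union / intersection)**: each term is tested inside
  the union (or intersection) of its parents' annotation sets; the
  namespace root falls back to term-for-term. A term annotated
  identically to its single parent is, by construction, no refinement
  and gets $p = 1$.

Multiple-testing correction (`none`, `bonferroni`, `bh`) is applied
after the fact; the default is `none` so that raw p-values remain
visible and corrections act as sensitivity analyses.

## The synthetic-data generator

The generator produces data with exactly the structure the inference
assumes, plus controlled violations:

* `simulate_domain_evolution()` draws each domain's origin from a
  node-weighted distribution — by default half the mass on the root,
  reflecting that most domain types are ancient, the rest uniform — and
  loses it on each branch inside the origin clade with probability
  `loss_prob` (default 0.1 per branch, a moderate regime in which
  roughly half of root-origin domains survive to the leaves of a
  16-leaf tree). Losses outside the origin clade are meaningless (the
  domain is not there to lose) and are not sampled, which keeps the
  truth's event count comparable to the inferred cost. Every simulated
  truth is a feasible single-gain history, so the inferred cost is
  provably $\le$ the true event count and the inferred gain node is a
  descendant-or-self of the true origin — both are tested, as is exact
  recovery at `loss_prob = 0`.
* `simulate_hit_table()` wraps a known repertoire in one clean hit per
  domain (1–3 domains per synthetic protein, E-values $10^{-30}$ to
  $10^{-10}$, bit scores above the gathering threshold) plus three decoy
  classes: overlapping hits with strictly higher E-values (removed by
  overlap resolution), hits failing the cutoffs, and cutoff-passing
  hits with excluded accessions. The truth record states each row's
  role, so tests can assert the filter output equals the planted set
  exactly — and that without the exclusion list exactly the planted
  contaminants leak through.
* `simulate_go()` builds a single-namespace layered DAG whose layer
  widths grow geometrically with depth ($\propto 4^{\mathrm{depth}}$),
  mirroring real ontologies: few broad terms, many specific ones.
  Direct annotations go only to childless terms, as external2go maps to
  specific terms, with breadth arising via propagation. When asked to
  plant enrichment it selects the most specific term that carries
  enough annotated domains for the requested study fraction *and* whose
  annotation set is at most 0.3 of its parents' overlap: a term whose
  annotations saturate its parents explains them completely and is
  unidentifiable in principle by parent-conditioned tests, so planting
  there would test nothing about the methods.

What the generator does **not** emulate: sequence-level noise, realistic
protein architectures, domain families with correlated gain/loss,
horizontal transfer, or ontology cross-namespace links. Passing tests
therefore demonstrate algorithmic correctness under the model's own
assumptions, not robustness of Dollo parsimony to model violations on
real data (where, e.g., undetected domains masquerade as losses).

## Numerical and interface choices

* Gains are attributed to the branch *entering* the gain node; domains
  gained at the root form a separate root-origin ("ancestral stock")
  set, since the root has no parent branch. The ledger identity
  $\mathrm{present}(child) = \mathrm{present}(parent) \cup
  \mathrm{gained} \setminus \mathrm{lost}$ holds on every branch and is
  asserted at scale.
* Unnamed internal nodes are auto-named `N1..Nk` in preorder, so names
  are stable across runs and across input permutations; polytomies are
  handled natively (nothing in the MRCA / maximal-absent-subtree logic
  assumes binary nodes).
* The sample standard deviation (n−1) is used in clade summaries; a
  single-genome clade reports SD 0 with `sd_defined = FALSE`.
* Every stochastic function takes a mandatory seed, restores the
  caller's RNG state, and is byte-deterministic given its arguments.
* The pipeline writes a manifest with the package version, the seed,
  and MD5 hashes of the canonical config and of every input file, so a
  changed input is detectable and an unchanged rerun is byte-identical.
* The package's interface is its functions plus `run_pipeline()` over a
  YAML config; stages are also callable individually. No shell binary
  is shipped: the intended users drive analyses from R, where the
  composable functions subsume a subcommand-style CLI.

## Problem sizes used in the checks

The package's property checks run at these scales, chosen to exercise
the asymptotic behaviours while staying comfortable on a laptop: all
143 rooted multifurcating tree shapes with 2–7 leaves × 200 random
columns against the enumeration oracle; 50 random 32-leaf trees ×
500-domain matrices for ledger conservation; 2,000 domains for
simulation recovery; 100 replicates × 16 leaves × 1,000 domains for
topology ranking; 1,000 random tables for the hypergeometric oracle and
100 planted studies (population 1,000, study 30) per enrichment method;
100 clustering replicates on 10-leaf trees × 400 domains.

## Known limitations

* Dollo parsimony confounds detection failure with loss; ancestral
  repertoire sizes are lower bounds and grow with database coverage.
* No weighting: a gain "costs" the same as a loss, and all losses cost
  the same. Likelihood or Bayesian gain/loss models are out of scope.
* Enrichment p-values are as interpretable as the annotation: with
  sparse or biased domain–GO mappings the population restriction to
  annotated domains can shift results.
* The clustering congruence score compares unrooted topologies only; it
  ignores branch lengths and rooting.
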