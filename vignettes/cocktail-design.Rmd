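---
title: "Designing minimum-sized phage cocktails from infection networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing minimum-sized phage cocktails from infection networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cocktailnet)
```

## The problem

A phage cocktail is a mixture of bacteriophages intended to lyse every
targetable strain of a bacterial panel. Large cocktails are costly to
manufacture (each phage must be propagated and purified separately) and
increase the opportunity for antagonistic phage-phage interactions, so the
design question is a covering problem: find the *smallest* set of phages
whose combined host ranges reach every susceptible strain.

The starting point is a binary host-range matrix: rows are bacterial
strains, columns are phages, and a cell is 1 when the phage lyses the
strain. Quantitative lysis scores (e.g. efficiency of plating) are reduced
to lytic/non-lytic; `read_host_range()` binarizes cells strictly greater
than a configurable threshold, with 0 as the default so that any recorded
lysis counts. The matrix is viewed as a directed bipartite network — the
phage-bacteria infection network (PBIN) — with one edge per lytic
interaction pointing from phage to bacterium.

## Node importance

Each node is scored by its Expected Importance (EI), a degree-based
centrality on a percentage scale:

* phages: $EI_p = 100 \cdot \mathrm{out}_d / |B|$, the percentage of the
  bacterial panel the phage lyses (0 for a non-infecting phage, 100 for a
  universal lyser);
* bacteria: $EI_b = -100 \cdot (1 - \mathrm{in}_d / |P|)$, which is $-100$
  for a strain no phage can lyse and 0 for a strain lysed by every phage.

The opposite signs put sources and targets on disjoint scales, which is
convenient for network colouring and makes the extremes directly
interpretable: the bacteria that are hardest to cover sit at $-100$, the
most valuable generalist phages near $+100$.

```{r ei}
cells <- cbind(A = c(1, 1, 1, 1, 0, 0), B = c(1, 1, 0, 0, 1, 0),
               C = c(0, 0, 1, 1, 0, 1), D = c(0, 0, 0, 0, 1, 1))
rownames(cells) <- paste0("b", 1:6)
pbin <- build_pbin(cells)
round(pbin$ei_phage, 1)
```

## Cocktail search

Two selection algorithms are provided, and `compare_methods()` runs both.

**Heuristic (network metrics).** Stage 1 adds every phage that is the
unique lyser of some bacterium — such phages are forced into any complete
cocktail. Stage 2 walks the remaining phages in decreasing $EI_p$ order and
adds a phage only if it lyses at least one still-uncovered bacterium,
stopping when every susceptible strain is covered. One pass suffices:
coverage only grows, and a phage is skipped only when it contributes
nothing at that moment, which cannot happen to the last lyser of an
uncovered strain. Ties in $EI_p$ are broken by input column order so runs
are reproducible.

**Exhaustive.** For $k = 1, 2, \dots$ the search establishes the best
coverage attainable with $k$ phages and stops at the first $k$ that covers
every susceptible bacterium; that $k$ is the Minimum Cocktail Size (MCS).
The per-size best coverages are returned as a trace. The size cap defaults
to 12 — mirroring the published implementation of this search, whose
enumeration stops at 12-phage combinations — and when no subset within the
cap covers everything the best capped subset is returned flagged
incomplete. Phages lysing nothing are excluded from enumeration; they can
never improve coverage.

The greedy heuristic is the classical $\ln(n)$-approximation to set cover:
fast, but not optimal. On the worked 6x4 matrix above it returns
`{A, B, C}` while the exhaustive search proves two phages suffice:

```{r search}
compare_methods(pbin)[c("heuristic_size", "exhaustive_size", "gap")]
```

### Exactness and pruning

Naive enumeration of $\binom{|P|}{k}$ subsets is infeasible for realistic
collections, so the exhaustive search is implemented as a branch-and-bound
(compiled, with host sets packed into 64-bit words) built from devices that
are provably value-preserving:

* *At-most-$k$ equivalence.* Since at least $k$ candidate phages always
  exist, padding a smaller subset never lowers coverage, so the best
  exactly-$k$ coverage equals the best at-most-$k$ coverage and zero-gain
  branches can be skipped while computing the value.
* *Admissible completion bound.* A partial selection is abandoned when its
  coverage plus the sum of the largest remaining per-phage gains cannot
  beat the incumbent; a phage's union gain never exceeds its marginal gain
  computed at the node, so the bound only overestimates.
* *Value first, subset second.* The optimal value per size is established
  on a gain-ordered search (fast), then the reported subset is recovered by
  a lexicographic scan that stops at the first subset attaining that value.
  Among equal-coverage subsets of a size this yields the first in
  lexicographic order of phage columns — the documented, deterministic
  tie-break.

`exhaustive_cocktail(..., prune = FALSE)` forces plain enumeration; the
test suite uses it, together with an independent bitmask set-cover oracle,
to validate the pruned search on hundreds of random instances.

## Phage cocktail networks and redundancy

`extract_pcn()` restricts the PBIN to the cocktail's phages and all
susceptible bacteria (resistant strains are excluded — they are unreachable
by any cocktail; they still count in `efficacy()`, the percentage of *all*
bacteria covered). Each bacterium's cocktail indegree $\mathrm{in}_{dc}$ is
its expected number of coinfecting phages.

Redundancy $r$ is the fraction of a network's phages lysing a strain.
Comparing the cocktail network against the full network gives the
redundancy variation

$$ rv = \log_{10}\!\frac{r_{PCN}}{r_{PBIN}}
      = \log_{10}\!\frac{\mathrm{in}_{dc}/|MCS|}{\mathrm{in}_d/|P|}, $$

with analytic bounds $rv_{\min} = \log_{10}(|P| / (|MCS| \cdot
\mathrm{in}_d))$ (exactly one cocktail phage lyses the strain) and
$rv_{\max} = \log_{10}(|P|/|MCS|)$ (every lysing phage made it into the
cocktail), so $rv_{\max} - rv_{\min} = \log_{10}(\mathrm{in}_d)$
identically, and for a single-phage cocktail $rv$ is pinned at $rv_{\min}$.
$rv$ is a log10 scale: a value of 0.8 means coinfection redundancy is
$10^{0.8} \approx 6.3$ times higher inside the cocktail than in the source
network (`rv_to_fold()`). Note that $rv_{\max}$ as printed depends only on
$|P|$ and $|MCS|$; for a strain with $\mathrm{in}_d = 1$ in a single-phage
cocktail the three quantities coincide, but in general negative $rv$ values
are possible (a strain lysed by many phages of which few entered the
cocktail) and the implementation permits them.

`coinfection_distribution()` aggregates $\mathrm{in}_{dc}$ across cocktail
networks grouped by MCS into row-percentage tables, and `rv_by_group()`
summarises $rv$ either by MCS or by the number of lysing phages, using the
midpoint convention for even-count medians.

## Synthetic networks

The generator exists so every pipeline stage is testable without
external data, and its defaults emulate the shape of published host-range
surveys:

* `random_matrix()` — independent Bernoulli cells at a target fill.
* `nested_matrix()` — host ranges totally ordered by inclusion (phage $j$
  lyses the first $k_j$ bacteria, $k_1 \ge k_2 \ge \dots$, chosen to match
  the target fill). Perfect nestedness is the structural ideal empirical
  infection networks approximate, and it forces MCS = 1: the broadest host
  range contains the union of all the others. A `noise` parameter swaps a
  fraction of (lytic, non-lytic) cell pairs at random, eroding the
  hierarchy while conserving fill.
* `corpus_like_sample()` — noisy-nested matrices with ~80% of draws
  bacteria-heavy (log-uniform 7-840 bacteria and 3-66 phages, so node
  counts span roughly 10-900) and the phage-heavy minority drawn small
  (5-80 bacteria, 1.1-2.5x as many phages), with fills 0.1-0.6 and noise
  0.05-0.3. These choices mirror the published 50-dataset corpus this
  package ships metadata for: 58 hosts and 18 phages per dataset on
  average, 80% bacteria-heavy, node counts 10-906, and phage-heavy
  datasets consistently small.

All generators take a seed (default fixed) and restore the caller's RNG
state, so identical calls are bit-identical.

What the generator does *not* emulate: phylogenetic correlation among
strains, modular (multi-species) block structure, quantitative efficiency
of plating, and measurement error beyond uniform random swaps. Passing
tests on synthetic data therefore demonstrate algorithmic correctness on
realistically sized and structured inputs, not biological validity of any
particular cocktail.

## Numerical and design choices

* Binarization is strict (`value > threshold`), threshold 0 by default;
  matrices with intermediate scores should pick a threshold explicitly.
* EI values are stored at full precision; reports round to one decimal.
* Non-infecting phages and resistant bacteria stay in the PBIN (they are
  real features of the assay) but are flagged and ignored by the search.
* Duplicate strain or phage labels are an error rather than being merged:
  merging would silently change degrees and hence every EI value.
* Delimiters are auto-detected among tab/comma/semicolon; source matrices
  in the literature vary.
* The Spearman correlations in `correlate_summaries()` use average ranks
  for ties and a two-sided asymptotic p-value; pairs with a constant
  descriptor are omitted with a warning.
* An all-resistant network yields an empty cocktail of size 0, complete by
  convention (there is nothing to cover) and efficacy 0%.
* In batch runs, exhaustive searches that are incomplete at the size cap
  report `NA` for the MCS with a warning, and unreadable inputs are
  skipped, not fatal.

The test suite and the acceptance script keep simulation sizes modest by
design: oracle comparisons run on hundreds of matrices up to 8x8 (where
full $2^{|P|}$ enumeration is cheap), property suites on networks of tens
of nodes, and end-to-end batches on ten corpus-shaped matrices. Single
instances at the extreme of the corpus-like distribution (hundreds of
bacteria with ~50+ phages and an MCS above the cap) are the known worst
case for the per-size trace and can take a few minutes each; the
branch-and-bound keeps typical corpus-shaped batches in seconds.

## Limitations

Binary host-range data discard infection efficiency; a cocktail optimal on
host range alone may be suboptimal once burst size, latency, MOI or
receptor overlap are considered — the redundancy statistics quantify
coinfection structure precisely so such information can be layered on
later. The MCS is a property of the assayed panel: adding strains can only
grow it, and it says nothing about strains outside the panel. Finally, the
exhaustive search's size cap means networks needing more than 12 phages
(rare in published corpora, where the largest reported minimum cocktail
was 11) are reported as incomplete rather than solved.
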