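---
title: "Detecting multi-site covariant patterns with covtandem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting multi-site covariant patterns with covtandem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covtandem)
```

## The problem

Compensatory mutations make biological sequences change in concert: when a
subpopulation (a viral genotype, a taxonomic family, a resistance lineage)
diverges, several alignment columns shift together, each to a specific
residue. `covtandem` detects these jointly shifting **site-residue
elements** directly, without fitting a phylogeny, and turns the resulting
multi-site patterns into classifiers for the subpopulations that carry
them.

The unit of analysis is the element: residue `R` at 1-based aligned column
`s`, written `s-R`. Working with elements rather than sites keeps the
residue identity in every result — a pattern reads `(1-A 6-T 7-V)`, not
"sites 1, 6, 7 covary".

## Data initialization

Two filters precede detection:

* **Sequence filter.** A record is kept only if strictly more than
  `min_fraction` (default 1/3) of its positions match the consensus.
  This removes unrelated or badly aligned records that would otherwise
  contribute spurious elements. The consensus is the per-column plurality
  of non-gap residues; ties go to the lexicographically smallest residue so
  the result is deterministic and independent of record order, and an
  all-gap column keeps the gap character. Gap-vs-gap positions count as
  matches — the simplest symmetric rule; both choices are configurable.
* **Informative sites.** Elements are only formed at columns where at
  least two distinct non-gap residues each occur in at least `min_count`
  (default 5) sequences. We read the minimum-sample rule per residue type:
  a covariance is only observable if *both* states of a site are backed by
  enough sequences, so the floor must hold for each counted type.
  Gaps never count as a residue type — they encode indels, not
  substitution states.

The sequence filter runs first and the site filter on the surviving
records; the consensus is not recomputed after filtering.

## The independent pair model

For elements $a$ and $b$ at distinct sites, with occurrence counts $n_a$,
$n_b$ and co-occurrence count $n_{ab}$, the purity is

$$P = \frac{2\,n_{ab}}{n_a + n_b},$$

the Sørensen–Dice coefficient of the two occurrence sets. The statistic is
pinned by three anchor configurations: $P = 0$ when the elements never
co-occur, $P = 1$ exactly when their occurrence sets coincide, and
$P = 2/3$ when all of $a$ co-occurs with half of $b$. Among the simple
co-occurrence ratios only the Dice form satisfies all three (the
conditional frequency $n_{ab}/n_a$ gives 1 at the third anchor, Jaccard
gives 1/2), which is why it is the one implemented; it lives behind a
single internal function so an alternative can be swapped in. A sequence
with a gap at either site carries no element there and contributes to
neither count.

Since a transformation is only visible past the 2/3 anchor, the rational
detection range is $2/3 < P \le 1$; the default threshold is the
intermediate correlation 0.7, compared **inclusively** (`>=`) so that the
boundary value $P = 1$ is attainable at threshold 1. Lower thresholds are
allowed for exploratory scans but warn.

A real covariance event converts one residue pair into another, so between
two sites at least **two** distinct element pairs must reach the threshold
simultaneously; a site pair with a single qualifying pair is flagged as
noise and excluded from pattern building. Detected pairs are reported in
canonical order (`site_a < site_b`, sorted by sites then residues) so runs
diff cleanly.

## The correlated tandem model

Confirmed pairs that share an element are joined transitively: the groups
are the connected components of the graph whose nodes are elements and
whose edges are confirmed pairs. Each group is transformed into a
symmetric **purity matrix** over its elements. Every off-diagonal entry is
the purity computed from the data — including element pairs that were never
detected pairs — because the pruning step below re-evaluates the matrix as
a whole; two elements at the same site have disjoint occurrence sets and
entry 0.

The **association degree** of an element is the mean of its row over the
other $n - 1$ elements (the diagonal is excluded: self-purity is
meaningless, and the divisor $n-1$ follows from averaging actual
associations). Let $d_m$ be the smallest degree. While $d_m$ is below the
degree threshold (default 0.7, same intermediate correlation as the pair
threshold but independently settable) the element attaining it is removed
— one per round, since batch removal changes the outcome — and the degrees
are recomputed. Ties at the minimum are broken deterministically: the
element with the largest site, then the lexicographically largest residue,
is removed first. Termination is inclusive (all degrees $\ge$ threshold);
a strict rule would reject a matrix sitting exactly at the threshold.

Three more rules shape the final report:

* **Minimum size 3.** A two-element survivor is just a pair, already
  reported by the pair model.
* **One element per site.** A sequence cannot carry two residues at one
  column, so if two same-site elements both survive the degree loop, the
  lower-degree one is removed (same tie-break) and pruning continues.
* **Disconnection splitting.** Removing an articulation element can
  disconnect a group. Survivors are split into the connected components of
  the confirmed-pair graph restricted to them, and each component is
  re-pruned against the threshold. Whether the original procedure
  re-checks connectivity is a genuinely open design point; splitting was
  chosen because a "pattern" spanning two unlinked components has no
  internal evidence tying its halves together.

Patterns whose element set is a proper subset of another's are dropped,
duplicates collapse, and the output is sorted by size (descending) then
first site.

## Clustering, evaluation, cross-validation

Each pattern defines a cluster: a sequence belongs when at least 45% of
the pattern sites match, **inclusively** ("45% or more"), gaps never
matching. The loose boundary is what makes patterns usable as population
signatures — carriers accumulate private mutations at individual pattern
sites without losing membership. Clusters may overlap and a sequence can
be unassigned.

Against labels, calling membership in a class's cluster a positive gives
per-class confusion counts and $Sen = TP/(TP+FN)$, $Spe = TN/(TN+FP)$,
$Acc = (TP+TN)/N$ over all $N$ sequences, plus unweighted macro averages.
The textbook $(TP+TN)/N$ accuracy is used throughout; per-class accuracy
figures in published genotype tables are sometimes computed per cluster
instead, so exact column-for-column agreement with such tables is not a
goal.

Stratified $k$-fold cross-validation (default 10) splits each class into
$k$ random subsets under a caller-supplied seed; like-numbered subsets form
the test sets. Per fold, patterns are detected on the training portion
only, each pattern is attributed to the **majority class** of its training
cluster (ties to the alphabetically first class), and the **best** pattern
per class — the one maximizing that class's training accuracy, ties broken
by larger pattern then smaller first site — classifies the test portion.
"Majority" and "best" are our concretizations of informally stated rules;
both are deterministic and exposed in code. Stratified subsampling
(`subsample_alignment`, rounded per class with a floor of one) supports
different-scale runs.

## The synthetic-data generator

`simulation_config()` / `generate_alignment()` produce alignments with
known truth: a consensus background; iid per-site substitutions to a
uniformly random alternative residue at `noise_rate`; per class, a planted
tuple of elements (sites disjoint across classes, residues chosen to
differ from the consensus) carried **as a whole** by
`round(carrier_purity × class size)` randomly chosen members; iid gaps
last, over everything, at `gap_rate`. All draws sit under one seeded RNG
scope, so equal configurations give byte-identical FASTA.

The defaults are the package's reference conditions: 500 sequences × 60
sites, three balanced classes with 3-, 4- and 5-site tuples, carrier
purity 0.9, 5% noise, no gaps. Three classes (not two) because the sizes
3/4/5 need a class each, and because with exactly two high-purity classes
a planted tuple and the *other* class's consensus complement ride on the
same carriers and correctly merge into one signature — a third
subpopulation breaks that complementarity so recovery can be scored
verbatim. Carrier purity 0.9 and 5% noise represent a strong but imperfect
subpopulation signature; 500×60 keeps full 10-fold cross-validation within
seconds.

Two structural consequences of the all-or-nothing carrier semantics are
worth stating because they bound what passing tests show:

* Between two planted elements of one class, purity is $\approx 1$
  regardless of carrier purity — carriers hold the whole tuple, so
  co-occurrence equals occurrence up to background collisions.
  `expected_pattern_purity()` gives the closed form
  $2c/(2c + x_a + x_b)$ with $x = (N-c)\,\nu/(A-1)$ collisions expected
  from noise $\nu$ over alphabet size $A$.
* Non-carriers hold background at every pattern site, so no classifier
  built from the planted pattern can call them: per-class sensitivity is
  capped by the carrier fraction and per-class accuracy by
  $1 - (1-\text{purity})/C$ for $C$ balanced classes ($\approx 0.967$ at
  purity 0.9, $C = 3$). The cross-validation observed on the reference
  simulation sits at this ceiling, which says the classifier loses
  essentially nothing beyond what the generative model withholds.

The generator emulates subpopulation structure, not evolution: there is no
phylogenetic correlation in the background, no realistic indel process, no
rate variation across sites. Detection that is clean here can still face
correlated backgrounds in real alignments — the method deliberately does
not attempt to subtract shared-ancestry correlation, trading that for
speed and for keeping residue-level information.

## Numerical and degenerate-input choices

* All comparisons against thresholds are inclusive; all orderings
  (pairs, groups, patterns, removals) have total deterministic tie-breaks,
  so every stage is reproducible and permutation-invariant.
* Purity needs no tolerance: it is a ratio of small integer counts.
* Fewer than two informative sites yields an empty pair table with a
  notice, not an error; an empty pair table yields no groups and no
  patterns.
* Degenerate columns: all-gap columns produce the gap consensus and no
  elements; strictly conserved columns are never informative.
* Validation errors are raised early: non-rectangular FASTA names the
  first offending record, duplicate ids and out-of-range parameters stop
  immediately, a class smaller than $k$ stops cross-validation by name.

## Problem sizes used by the test suite

Oracle-equivalence checks run 200 random alignments of up to 30 sequences
× 10 sites against brute-force re-implementations of pair scoring and of
the full pruning dynamics; recovery and cross-validation run on the
500 × 60 reference simulation. The whole suite and the acceptance script
each complete in well under a minute on a single core.

## Limitations

* Phylogenetic background correlation is not removed; closely related
  sequence sets will show lineage signatures as patterns (which is exactly
  what the classification use-case exploits, but is a confounder for
  contact-prediction-style interpretation).
* The purity statistic carries no explicit null model or p-value; the
  threshold is a correlation scale, not a significance level.
* Frequent recombination breaks the tuple structure the tandem model
  relies on; such regions are out of scope.
* Alignment quality is assumed: the method inherits any column
  misassignment from the upstream aligner.
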