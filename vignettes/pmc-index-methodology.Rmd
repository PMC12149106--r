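---
title: "Evaluating policy corpora with the PMC index model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating policy corpora with the PMC index model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmcindex)
```

## The model

The Policy Modeling Consistency (PMC) index scores how comprehensively a
single policy document covers a predefined evaluation framework. The
framework is a two-level tree: $n$ primary variables $X_1, \dots, X_n$
(evaluation dimensions such as the nature of the policy, its time
horizon, its issuing institution), each refined into $T_i$ binary
sub-variables $X_{ij}$. A coder reads the policy and sets
$X_{ij} \in \{0, 1\}$: 1 if the policy satisfies that criterion, 0
otherwise. All sub-variables carry equal weight. The first-level value
of dimension $i$ is the fraction of its criteria satisfied,

$$X_i = \frac{1}{T_i} \sum_{j=1}^{T_i} X_{ij} \in [0, 1],$$

and the PMC index is their sum,

$$\mathrm{PMC} = \sum_{i=1}^{n} X_i \in [0, n].$$

With the packaged default framework ($n = 9$ primaries, 41
sub-variables in counts 6, 3, 4, 4, 6, 6, 3, 4, 5 — see
`default_schema()`), the index ranges over $[0, 9]$ and is classified
on four intervals: **Bad** $[0, 4)$, **Good** (acceptable) $[4, 6)$,
**Excellent** $[6, 8)$, **Perfect** $[8, 9]$. The intervals are
half-open on the left; we close the top interval so that a policy
satisfying every criterion is classifiable. Frameworks with a different
number of primaries have a different index range, so `pmc()` requires
explicit grade cut-points for them rather than silently reusing the
0–9 scale.

The model assumes the sub-variables are meaningful binary criteria and
that equal weighting is acceptable; it deliberately has no weighting
scheme, no interaction terms, and no significance testing — it is a
transparent coverage score, not an inferential model.

## Rounding: report parity versus full precision

Published PMC score tables print first-level values to two decimals and
report each policy's index as the sum of the *printed* values: a
dimension satisfying 4 of 6 criteria enters as 0.67, not 2/3. Summing
exact fractions gives slightly different totals (up to $n \times 0.005$
away). `pmc_index()` therefore supports two conventions:

* `"report-parity"` (default): round each first-level value half-up to
  2 decimals, then sum. This reproduces published tables digit for
  digit and is what the packaged score table satisfies row by row.
* `"full-precision"`: sum the exact fractions; preferable for
  downstream arithmetic on freshly coded corpora.

Rounding is half *away from zero* (0.125 → 0.13), implemented directly
because base R's `round()` rounds half to even; a $10^{-9}$ guard
absorbs the binary floating-point representation of two-decimal values.
Grade percentages in `summary()` are reported to one decimal, half-up.

## The packaged score table

`table4_scores()` returns the complete published first-level score
table of a 165-policy corpus of Chinese traditional-medicine drug
registration policies (1985–2023), stored verbatim as printed, plus its
printed column-average row. It is the package's reference dataset:
report-parity summation of each row reproduces the printed index for
all 165 rows, and `summary()` over the table reproduces the published
aggregates (mean index 5.858; 39 Excellent, 119 Good, 7 Bad, 0
Perfect; per-variable means including the structurally exact
$X_3 = 0.25$).

Verbatim storage includes typographical quirks. `table4_validation()`
reports — without correcting — cells that are not expressible as a
rounded $j / T_i$ under the framework's sub-variable counts (two X8
cells print 0.67, a third, under a four-criterion dimension), and would
likewise report any row whose printed index failed report parity (none
do). Another stored-as-printed oddity: the three time-horizon
sub-variables of X2 read as mutually exclusive, yet many rows print
$X_2 = 1$; the table is the authority, so no exclusivity is enforced at
scoring time.

```{r fixture}
tab <- table4_scores()
fit <- pmc_from_first_level(as.matrix(tab[paste0("X", 1:9)]),
                            policy_id = sprintf("P%d", 1:nrow(tab)))
summary(fit)
```

## The multi-input–output table and rule-based coding

`read_coding_matrix()` ingests the policies × sub-variables 0/1 matrix
(CSV; `policy_id`, optional `title`/`issuer`/`year`, then one column
per sub-variable id). Blanks and non-binary cells are hard errors
naming the offending row and column: the averaging step assumes
complete columns, so imputation would silently change scores.

Manual coding is the reference procedure, but `apply_rules()` offers a
reproducible alternative: each rule ties a sub-variable to literal
keyword patterns (any-match or all-match). Matching is substring
containment after stripping whitespace and case-folding Latin text —
no stemming, no segmentation — so a rule file is auditable by eye.
Sub-variables without a rule code as 0.

Categorical structure inside the binary format (the four issuer flags,
of which exactly one should be set) is checked by
`check_exclusive_blocks()`, a lint that reports violating rows but
never rewrites data, since the matrix format itself stays general.

## The PMC surface

For nine-primary frameworks, `pmc_surface()` arranges the first-level
values row-major into a 3×3 matrix (row 1 = $X_1, X_2, X_3$, and so
on, matching the printed row grouping of the defining equation; the
layout is a visualisation convention, not a model statement). The mean
of the nine cells times 9 equals the full-precision index, and
`flatten()` inverts the construction exactly.

`plot()`/`render_surface()` draw the matrix as a 3-D surface whose
height and colour depth encode the first-level values, concave where
the policy is weak. Smoothing upsamples the 3×3 anchors with a
tensor-product natural cubic spline (default 25 subdivisions per cell
edge), clamped to $[0, 1]$; the interpolant passes through the nine
anchors exactly, so smoothing only ever adds intermediate points. The
published renderings do not state a grid density or interpolation
scheme, so parity with them is visual; the tested guarantees are anchor
reproduction and range preservation. Output is PNG or SVG by file
extension.

## Text mining

The text-feature stage ranks high-frequency terms and builds the
co-occurrence semantic network. `tokenize_corpus()` splits documents
into sentences on Chinese and Latin terminal punctuation (。！？.!?)
and segments with a pluggable strategy: whitespace splitting (for
pre-tokenized or Latin text), overlapping character n-grams
(dictionary-free baseline for unsegmented Chinese), or forward maximum
matching against a user dictionary, written in the package (longest
dictionary term wins at each position; uncovered CJK characters fall
back to single characters, ASCII runs are kept whole). Stopwords are
removed after segmentation; the packaged default list
(`default_stopwords()`) is an editable starting point, not a canonical
list, since none is published.

`cooccurrence_network()` counts, for each unordered term pair, the
number of *windows* (sentences by default; documents; or sliding spans
of $k$ tokens) containing both terms — once per window regardless of
repeats, the standard convention for semantic maps. Edges below
`min_edge_weight` (default 2) are dropped along with the nodes they
leave isolated; the graph is undirected, loop-free, and exports to
GraphML or an edge-list CSV (`write_network()`), layout being the
viewer's job. `network_centrality()` quantifies core versus peripheral
terms by degree and weighted degree.

## Synthetic data: what it emulates and what it does not

`generate_matrix()` draws coding matrices with the statistical
structure the pipeline assumes: independent Bernoulli columns plus
mutually exclusive blocks sampled from categorical weights, with all
sampled ground truth returned alongside. The defaults are the study
corpus's conditions: 165 policies; the issuer block X3_1..X3_4
exclusive with weights (1, 0, 0, 0) — every policy state-issued, which
pins $X_3$ at exactly 0.25, as in the published corpus; and 0.5 for
free columns, a maximum-entropy choice where no published per-column
rate exists (the published data gives only first-level aggregates, not
the 165 × 41 matrix, which was never deposited).

`generate_corpus()` draws whitespace-tokenizable token streams from a
weighted vocabulary (defaults: 50 documents of 200 tokens) and can
plant term pairs that co-occur per document with an exact configured
probability (natural occurrences of the pair's terms are resampled
away before the planting draw). Both generators take a single integer
seed, derive all randomness from it, and restore the caller's RNG
state.

What passing synthetic tests shows: the arithmetic, validation, and
recovery behaviour of every stage under known ground truth. What it
does not show: anything about real coding quality — the generators
produce neither realistic legal prose nor human coder behaviour, and
column independence is an idealisation (real sub-variables correlate).

## Numerical and design choices

* Problem sizes in the test suite: parameter-recovery checks run at
  10,000 synthetic policies (column means within 3 binomial standard
  errors; the mean index within 4 standard errors of the closed form
  $\sum_i \sum_j p_{ij} / T_i$); oracle-equivalence checks run
  exhaustively on matrices of up to 5 policies and corpora of up to 5
  documents, where brute-force enumeration is feasible and exact.
  Where a fixed-seed test makes many simultaneous 3-SE comparisons, it
  allows the chance exceedances that multiplicity implies instead of
  silently widening the per-column bound.
* Ties in frequency tables break lexicographically, making ranks
  deterministic across platforms and locales.
* Degenerate inputs are errors, not guesses: empty sub-variable lists,
  empty matrices, out-of-range values, unknown segmenters, sliding
  windows narrower than two tokens.
* The schema is data (YAML), so the tool generalises beyond the
  packaged framework; everything downstream is parameterised by the
  schema's counts, and only the grade scale is framework-specific.

## Limitations

The package evaluates coverage of a framework, not policy impact;
grades inherit whatever subjectivity the coding step has. The
rule-based coder is a transparency device, not a substitute for expert
reading. The published corpus itself ships only as first-level values,
so per-sub-variable analyses of it are impossible by construction.
Network figures are qualitative: the published tool's segmentation
dictionary, stopword list and window convention are unstated, so
term-for-term reproduction of its maps is out of reach and out of
scope.
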