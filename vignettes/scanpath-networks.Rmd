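---
title: "Scanpath networks: model, metrics, and the synthetic-reader simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanpath networks: model, metrics, and the synthetic-reader simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanpathnet)
```

## The method in brief

When a person reads, their gaze does not sweep smoothly over the text: it
pauses on some words (fixations), jumps over others (skips), and sometimes
returns to material already read (regressions). The time-ordered sequence of
fixated words — the *visual scanpath* — is a rich behavioural trace, but it
is awkward to compare across readers because its length and content vary
freely. This package quantifies scanpaths by turning each one into a
**directed weighted network**: every fixated word *type* is a node
(reoccurring words merge into one node), and every saccade between two
different words increments a directed edge weight by one. Consecutive
refixations of the same word add no edge, so the adjacency diagonal is
structurally empty.

For the sentence "Could humans live on Mars some day?", a reader fixating
*Could, humans, live, Mars, day, Could, humans* produces a 5-node network
with total edge weight 6 and `w(could → humans) = 2` — the forward sweep plus
one regressive revisit of the sentence onset.

Five graph metrics summarise each reader's network. Writing $W$ for the
weight matrix, $N$ for the node count, $A = W + W^\top$, and
$k_i = \sum_j (w_{ij} + w_{ji})$ for the *strength* (degree) of node $i$:

* **Density** $D = \sum_{i \ne j} w_{ij} \,/\, N(N-1)$ — total transition
  mass per possible directed edge. Dense networks come from many fixations
  and few skips.
* **Freeman centralization**
  $C = \sum_i (C_{\max} - C_i) / ((N-1)(N-2))$ with $C_i = k_i$ — dispersion
  of degree around the most central node; 0 for a chain-like, 1 for a
  star-like unit-weight network, with the conventional topology bands
  [0, 0.2) linear, [0.2, 0.4) hierarchical, [0.4, 0.6) network, [0.6, 1]
  star. With weighted strengths the score can leave $[0,1]$; a `binarize`
  flag (distinct-neighbour degrees) restores the bound when needed.
* **Transitivity**
  $T = \sum_i t_i \big/ \sum_i [k_i(k_i-1) - 2\sum_j w_{ij}w_{ji}]$, with
  $t_i = \tfrac12 \sum_{j,h} A_{ij}A_{ih}A_{jh}$ — closed directed weighted
  triangles over connected triples. Regressions are the behavioural engine of
  triangles: reading *a b c* then regressing to *a* closes one. On binary
  symmetric graphs this reduces exactly to the classic global clustering
  coefficient (an identity the test suite verifies exhaustively over all
  1024 undirected 5-node graphs).
* **Global efficiency**
  $E = \tfrac1N \sum_i \sum_{j \ne i} d_{ij}^{-1} / (N-1)$, where $d_{ij}$
  is the shortest directed path length with each edge of length $1/w$ —
  strong transition links are short. Unreachable pairs contribute 0, so $E$
  is defined on disconnected (e.g. masked) networks.
* **Small-worldness** $S = (C_{\mathrm{cl}}/L) \big/ (C_{rand}/L_{rand})$,
  clustering over characteristic path length, normalized by a random
  reference ensemble with the same number of nodes and directed edges.
  $S > 1$ indicates small-world structure.

### A note on the path-length formula

The method's printed characteristic-path-length formula is algebraically the
printed global-efficiency formula (both average inverse distances). Since $S$
needs a genuine path length, `net_path_length()` offers two modes and every
result records which was used: the default `"mean_distance"` (mean finite
shortest distance over reachable ordered pairs — the standard definition) and
`"as_printed"` (which returns $E$ bit-for-bit, kept for strict formula
fidelity). The package never silently guesses between them.

## Tunable parameters

| Parameter | Default | Where | Why |
|---|---|---|---|
| fixation window | 40–1000 ms, boundary-inclusive | `clean_fixations()` | standard cleaning rule for reading data; "shorter than 40 ms / longer than 1000 ms" are excluded, so the boundary values survive |
| mask thresholds | degree > 5, weight > 0.3 (strict) | `apply_mask()` | drops low-representativeness structure before group visualization; edges are filtered first, degrees recomputed, then nodes — the deterministic order |
| `link_sentences` | `TRUE` | `build_network()` | consecutive fixations spanning a sentence boundary still form an edge; disable to encode strictly sentence-by-sentence |
| `n_refs` | 20 | `random_reference()` | ensemble size for the small-world null; the estimate's spread shrinks roughly as $1/\sqrt{n_{\mathrm{refs}}}$ |
| `l_mode` | `"mean_distance"` | `net_path_length()` | see above |
| `binarize` | `FALSE` | `net_centralization()` | weighted strengths are the faithful reading; binarized degrees respect the $[0,1]$ bound |

Numerical conventions: nodes with $k_i(k_i - 1) \le 0$ contribute 0 to the
clustering mean (leaves and isolates are common in scanpath networks); a
transitivity denominator that is not positive yields 0 with an `undefined`
attribute instead of a division error; metrics whose preconditions fail
inside `metric_set()` come back as `NA` with the reason in `flags`, never
silently dropped.

## The random reference null

The null model is the simplest one satisfying "same number of nodes and
edges": each reference places the source network's directed edge count
uniformly at random over ordered node pairs (no self-loops, no duplicates)
and permutes the original multiset of edge weights onto the new edges.
Everything is reproducible from a seed. Because the normalizer
$C_{rand}/L_{rand}$ is itself an ensemble mean, the ratio carries a small
finite-size bias: matched uniform random graphs score a mean $S$ slightly
below 1 (about 0.96 at $N = 100$, 600 arcs, 20 references), which is why the
calibration check uses a band around 1 rather than an exact equality, while
rewired ring lattices score $S \approx 5$ — far clear of the $S > 1$
criterion.

## What the synthetic readers emulate

`generate_text()` builds a 30-sentence, roughly 300-word expository pseudo-
text: around 40% closed-class function words drawn from a fixed lexicon,
mostly unique pseudo content words, and (by default 2) topic words each
planted in 80% of the sentences. The recurrence default reflects how
expository passages keep naming their topic — it is exactly this hub
prominence that makes centrality differences between readers detectable.
Topic words appearing in at least half the sentences is guaranteed by
construction, not by chance.

`simulate_scanpath()` walks each sentence left to right with four chances to
deviate: skip (class-specific probability), refixate the current word,
or regress to a previously fixated word at most `regress_span` words back in
the same sentence (regressions never cross sentence boundaries, matching
sentence-by-sentence presentation). Durations are truncated-normal inside
the 40–1000 ms window, so simulated fixations survive cleaning unchanged.

The skill presets encode the canonical contrast from the eye-movement
literature:

| | skip fn | skip content | skip topic | regress | refix | fixation (ms) |
|---|---|---|---|---|---|---|
| `skilled_profile()` | 0.60 | 0.25 | 0.05 | 0.08 | 0.05 | 210 ± 50 |
| `less_skilled_profile()` | 0.25 | 0.08 | 0.05 | 0.25 | 0.15 | 275 ± 70 |

Two design points deserve emphasis:

* **Topic words form their own skip class.** Word skipping tracks
  predictability, frequency and length, so skilled readers' extra skips fall
  on function words and peripheral content — not on the informative topic
  words that anchor comprehension. Without this third class, skilled
  simulated readers dismantled their own hubs and the centralization
  contrast between groups became unreliable; with it, skilled readers keep
  hub strength while shedding peripheral nodes and weight, which is exactly
  the mechanism that yields their higher centralization.
* **The skip–density relation is channel-specific.** Skipping *recurring*
  words (function words, whose occurrences merge into one node) removes many
  transitions but few nodes, lowering $D \approx W/N^2$. Skipping *unique*
  content words removes a node along with its transitions and therefore
  *raises* density. The directional property tests target the recurring-word
  channel; the preset contrast combines it with the regression and
  refixation differences, and at 500 paired simulations the group contrast
  (skilled lower density, transitivity, efficiency; higher centralization)
  is reproduced with large margins.

What the simulator deliberately does **not** model: lexical frequency and
length effects on individual words, parafoveal preview, landing-position
noise, drift, binocular disparity, or any cognitive-architecture dynamics
(E-Z Reader / SWIFT class). Passing tests therefore show that the pipeline
computes its quantities correctly and that the encoded mechanisms produce
the expected directional signatures — they do not certify that real readers
behave like the generator.

`generate_cohort()` spaces readers evenly along the preset interpolation,
uses each reader's *actual* simulated reading time as the speed component,
and adds Gaussian noise to the two performance components, so the combined
comprehension ability score (sum of within-cohort z-scores of assessment
accuracy, standardized reading-test score, and reversed reading time
`max − raw`) tracks the generating skill with realistic scatter.

## Reader-level statistics

`comprehension_score()` uses sample (n−1) SDs; the score is invariant to
affine rescaling of any component. `split_groups()` performs a stable median
split (odd cohorts put the median reader in the lower group; boundary ties
break by participant id, with a message). `t_test_groups()` is Student's
pooled-variance t — the convention that gives df = 50 for a 26 + 26 split —
with Cohen's d from the pooled SD. `pearson_r()` reports the two-tailed p
from the t transform on n − 2 df. No multiple-comparison correction is
applied; callers decide.

## Worked pipeline example

```{r pipeline, eval = FALSE}
cfg <- load_run_config()            # package defaults
cfg$paths$out_dir <- tempfile("demo")
cfg$simulate$n_readers <- 20
res <- run_all(cfg)                 # simulate -> build -> metrics -> render
res$correlations$r["comprehension_ability", ]
```

Problem sizes used by the automated checks (chosen to exercise every code
path at desk scale): exhaustive oracle comparison over all 1024 undirected
5-node graphs; shortest-distance oracles over all 64 undirected 4-node
graphs plus 60 random weighted directed 5-node graphs; the directional
preset contrast over 500 paired simulations of a 30-sentence text; lattice
and random small-world calibration at $N = 100$ with 20-member ensembles.

## Known limitations

* Weighted Freeman centralization is not scale-free: doubling every weight
  doubles the score. Comparisons are meaningful within cohorts processed
  identically; use `binarize = TRUE` for a bounded variant.
* The weighted transitivity uses raw weight products as defined, without
  cube-root normalization; with large counts, values are not bounded by 1.
* The mask's strict thresholds were designed for *averaged* (fractional)
  group networks; applying them to single-reader count networks is supported
  but removes most unit-weight structure only when `weight_gt < 1`.
* Networks are held as dense matrices — appropriate for word-level reading
  networks (hundreds of nodes), not for corpora with tens of thousands of
  types.
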