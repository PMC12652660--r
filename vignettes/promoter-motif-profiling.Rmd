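---
title: "Promoter motif profiling: models, calibration and design choices"
author: "promscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter motif profiling: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promscan)
```

## The problem

Flowering in *Arabidopsis thaliana* is controlled by a small set of
transcription factor (TF) genes — MADS-box organ-identity genes such as
*PISTILLATA* (*PI*), the *SEPALLATA* family, *AP1*/*AP3*/*AG*, and meristem
regulators such as *LFY* and *SOC1* — whose promoters integrate many
regulatory inputs. A recurring analysis in this field is to scan
transcription-start-site (TSS) anchored promoter windows with a library of
position weight matrices (PWMs), call binding sites at calibrated p-value
thresholds, and then ask set-level questions of the hit table: which TFs are
predicted to bind *every* promoter in the panel (putative master regulators),
which bind *exactly one* (gene-specific regulators), which bind the promoter
of their *own* gene (candidate autoregulation), and how the predicted sites
distribute upstream versus downstream of the TSS. promscan implements that
pipeline end to end, together with RPKM/RPM expression summaries and
regulatory-network topology, and ships a synthetic-data module so every stage
can be exercised against known ground truth without external downloads.

## Scoring model

A motif of length $L$ is a $4 \times L$ count matrix (PFM). Against a
background model $b$ (independent per-base frequencies, each $> 0$), the
weight of base $\beta$ at position $j$ is the log2 likelihood ratio

$$w_{\beta j} = \log_2 \frac{(c_{\beta j} + b_\beta\,p)\,/\,(C_j + p)}{b_\beta},$$

where $c_{\beta j}$ is the count, $C_j$ the column sum and $p$ the total
pseudocount per column, distributed across bases proportionally to the
background. The score of a word is the sum of its per-position weights, in
bits; a minus-strand match is scored on the reverse complement. Defaults and
why:

* **Pseudocount** `pseudocount_total = 1` per column: the common convention
  in the JASPAR ecosystem; keeps zero counts finite while barely perturbing
  well-populated columns. It may be set to 0 when all counts are positive,
  in which case weights become exactly $\log_2(f_{\beta j}/b_\beta)$ and are
  invariant to rescaling a column's counts.
* **Log base 2** (bits): base only rescales scores and cancels in p-value
  ranks.
* **Background** uniform by default; `background_from_promoters()` estimates
  it from the scanned sequences, or any four positive frequencies may be
  supplied (plant promoters are A/T-rich, roughly 0.3/0.2/0.2/0.3).

## Exact p-value calibration

The p-value of a word is the probability that a random background word of
length $L$ scores at least as high. promscan computes this exactly rather
than by simulation: weights are discretized onto an integer grid
(`grid_scale` units per bit, default 10000) and the full distribution of the
discretized score is obtained by position-wise convolution —
`score_distribution()`. A per-matrix cutoff for a threshold $p$ is then the
smallest grid score whose upper tail is *strictly* below $p$, matching the
"$p <$ threshold" definition of a hit; scanning with that cutoff yields
exactly the words whose p-value is below $p$ at grid resolution. The support
of the distribution is at most $L$ times the per-column weight span, so the
computation is linear in window length and cheap even for long motifs.

Numerical notes:

* Scores reported by the scanner are grid multiples
  (`integer score / grid_scale`), so their p-value lookups are exact;
  `word_pvalue()` scores a word on the same grid for exact agreement. A score
  summed from *unrounded* weights can differ from its grid counterpart by up
  to half a grid unit per position, which matters only when comparing against
  the distribution directly.
* Refining the grid moves any p-value by at most the probability mass of one
  grid cell (a tested property).
* The dynamic program is checked exactly against exhaustive enumeration of
  all $4^L$ words for $L \le 8$, for both tails and cutoffs.

## Scan conventions

* **Dual thresholds.** Hits are called at a lenient p-value (default
  $10^{-4}$) and tiered `stringent` when they also pass the stringent
  threshold (default $10^{-5}$); stringent hits are therefore always a subset
  of lenient hits from the same scan.
* **Coordinates.** TSS-relative with no position 0: $-1$ is the base just
  upstream of the TSS, $+1$ the first transcribed base; the default window
  $-5000..+1000$ spans 6000 bases. Hits are anchored at the 5'-most base of
  the matched window in forward-strand space for both strands, which gives a
  single unambiguous anchor for upstream/downstream classification; a hit
  whose window spans the TSS is classified by that anchor.
* **Both strands** are scanned; opposite-strand hits at the same start are
  distinct. Overlapping hits are all reported — no greedy pruning.
* **N handling.** Windows containing `N` are skipped (never scored) and
  tallied in the scan provenance, avoiding any invented scoring semantics
  for ambiguous bases.

## Profiling definitions

* `count_by_region()` counts hit *events* (matrix, position, strand) per gene
  and tier, upstream versus downstream. Event counting is used because
  per-gene totals in the hundreds can only arise from multiple positions per
  matrix; a distinct-TF summary is attached as an attribute.
* `find_mrtfs()`: a TF is a master regulator at a tier when it has at least
  one hit of that tier in every analyzed promoter, regardless of position.
  Aggregation defaults to TF name (a TF binds if any of its matrices hits);
  matrix-level aggregation is available. The core set is the intersection of
  the lenient and stringent sets — redundant for a single scan (nesting makes
  it the stringent set) but kept general so hit tables from different scans
  can be intersected.
* `find_gene_specific()` lists TFs whose hits all fall in a single promoter,
  computed on the lenient tier only (all hits count; tiers never
  double-count).
* `detect_autoregulation()` joins hits against a TF-to-own-gene map and flags
  TFs with a stringent own-promoter site.
* `proximal_profile()` restricts hits to a central window, default
  $-500..+200$, the region where TSS-proximal clustering is biologically most
  interpretable.
* `match_carg()` finds the MADS-domain CArG-box consensus CC(A/T)₆GG; the
  pattern is its own reverse complement, so a forward search covers both
  strands, and matches cannot overlap.

## Expression summaries

From a count matrix with supplied library sizes $N_s$ and gene lengths $L_g$:
$\mathrm{RPKM}_{gs} = C_{gs} \cdot 10^9 / (N_s L_g)$ and
$\mathrm{RPM}_{gs} = C_{gs} \cdot 10^6 / N_s$. Library sizes are inputs, not
recomputed — they come from the aligner. CV% uses the sample standard
deviation ($n-1$); it is reported as missing for genes with zero mean, and
the descending rank by mean breaks ties in row order so ranking is always a
permutation. The `plus_one` offset exists only for log-scale heatmap export;
statistics use raw values. `compare_groups()` annotates fold changes (e.g. a
more than 5-fold drop as "strongly repressed") without any inferential claim.

## Network topology

Networks are directed, with self-loops marking autoregulation. Degree
counting honours a self-loop policy: the default `out_only` counts a
self-loop in the out-degree only, which is the convention under which the
packaged curated floral edge set reproduces the expected hub values (SEP3:
out-degree 5, in-degree 4); `both` and `none` are selectable. Clustering
coefficients are computed on the undirected simple projection (directions
and self-loops dropped) via igraph, with degree-<2 nodes assigned 0, and are
verified against explicit triangle counting in the tests. The packaged
fixture transcribes a literature-curated edge set (18 edges over 13 genes);
the four "may activate" LFY edges are tagged `putative`.

## What the synthetic data emulates — and what it does not

The generators emulate: TSS-anchored windows of fixed extent with
configurable base composition; motif libraries of controlled per-column
sharpness; exact-consensus plants at known positions and strands (plants
overwrite background, so window lengths are invariant; collisions are
rejected with an error, never silently shifted); fabricated hit tables with
designated master-regulator and exclusive TFs; and negative-binomial
replicate counts with supplied library sizes (dispersion 0 gives Poisson).
All generators are pure functions of (seed, configuration).

They do **not** emulate Markov structure in promoter sequence, chromatin
accessibility, motif clustering or dinucleotide dependence. Passing the
planted-recovery tests therefore demonstrates the correctness of the
scanning and set logic, not predictive performance on real promoters, where
PWM assumptions (positional independence, sequence-only binding) are known
simplifications.

A quantitative caveat worth stating explicitly: at the lenient threshold the
largest achievable tail below $10^{-4}$ for a sharp 10-mer under uniform
background is $P(\mathrm{Binom}(10, 0.25) \ge 9) \approx 3 \times 10^{-5}$
per position-strand, *independent of matrix sharpness*. Across a panel of
6-kb windows this amounts to several chance hits per matrix (about 0.35 per
promoter, both strands). Recall of planted sites is essentially perfect, and
all-promoter (master-regulator) sets are robust because a chance matrix
almost never covers every gene; but *exclusivity* claims — a TF binding
exactly one promoter — are intrinsically fragile at this threshold for short
motifs, since a single chance hit elsewhere destroys them. The reference
planted experiment (`planted_motif_experiment()`) exhibits exactly this
behaviour, and the same caution applies to gene-specific calls on real data.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen to exercise every code path
while completing in seconds: oracle equivalence over 50 random matrices with
$L \le 8$ (full $4^L$ enumeration); the reference planted study with 18
promoters of 6 kb and 20 sharp 10-mers (about 360 matrix-promoter scans);
smaller 5-6-gene variants for nesting and composition properties; 200
replicate samples for the law-of-large-numbers expression check. Larger
libraries (hundreds of matrices) scale linearly in matrices x promoters.

## Known limitations

* No higher-order background or dinucleotide motif models; no
  chromatin-accessibility weighting.
* The p-value calibration is exact for the package's own scoring convention;
  external tools with undocumented score/background conventions will not be
  numerically reproduced hit-for-hit.
* Gene-specific (exclusivity) reports at lenient thresholds are sensitive to
  chance hits, as quantified above; treat them as hypothesis-generating.
* The curated network fixture is a transcription of a published caption, not
  a genome-scale regulatory map.
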