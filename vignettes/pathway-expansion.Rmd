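---
title: "Elucidating small-sample proteomes by pathway expansion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elucidating small-sample proteomes by pathway expansion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteopath)
```

## The problem and the procedure

Shotgun proteomics of very small samples — down to ~50 cells — identifies
only on the order of a thousand proteins per LC-MS/MS run, roughly 10% of
the expressed proteome of a mammalian cell line, and consecutive runs agree
only partially. `proteopath` implements a knowledge-based strategy for
recovering the missing part of the proteome from such data:

1. **Harmonization.** Each run's identification report is cleaned of common
   contaminants (cRAP-style mnemonics, matched by exact accession) and every
   reported gene symbol is mapped to its approved symbol through an
   HGNC-style alias table. Ambiguous aliases and symbol-less records are
   tallied and excluded, never guessed; accessions that resolve to the same
   gene collapse to one symbol, because everything downstream works at
   gene-symbol level.
2. **Replicate structure.** Detected gene sets are combined across runs into
   a presence/absence detection matrix supporting any *k*-of-*n* query;
   for triplicates the standard sets are the *union* (k = 1), *twice*
   (k = 2) and *intersection* (k = 3).
3. **Pathway enrichment.** Each detected set is tested for
   over-representation against a canonical-pathway gene-set collection
   (GMT format) with an exact hypergeometric upper-tail statistic. With a
   universe of $N$ genes (the union of all member genes of the collection),
   a gene set of size $K$, and $n$ detected genes inside that universe of
   which $k$ fall in the set,
   $$P(X = k) = \frac{\binom{K}{k}\binom{N-K}{n-k}}{\binom{N}{n}},
   \qquad p = \sum_{i=k}^{\min(n,K)} P(X = i).$$
   Sets with $p$ below the cutoff (default 0.01, strict inequality, no
   multiple-testing correction — Benjamini–Hochberg is available but off by
   default and flagged in output headers) are retained.
4. **Expansion.** The union of all member genes of the enriched sets is the
   predicted expressed proteome. The expansion is monotone in the cutoff.
5. **Verification.** The expansion is compared against the detected sets
   themselves, against the replicate sets, and against transcript-expression
   structure: probe-level array data are collapsed to one profile per gene,
   sorted by decreasing expression, and the detected proteins are traced
   along that list with a sliding window, a cumulative curve and a
   high/low expression split.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| enrichment cutoff | 0.01 | probability | raw upper-tail p below which a set counts as enriched |
| universe | collection union | genes | $N$ and the restriction applied to $n$ |
| window size `w` | 50 | genes | sliding-window width along the sorted transcript list |
| window `step` | 1 | genes | 1 = true sliding window; `step = w` gives tumbling blocks |
| expression threshold | 6.0 | log-scale array units | high/low split; the boundary belongs to the high group |
| assumed proteome | 10,000 | proteins | denominator of the coverage estimates |

Detected genes outside the collection universe are excluded from $n$
(and tallied in the output attributes), keeping the sampling model
internally consistent: the hypergeometric urn only contains genes that
*could* overlap a set. The raw detected count is always reported alongside.

"Every consecutive 50 genes" can be read as sliding or as tumbling
windows; the default is a true sliding window (`step = 1`), which uses all
the data and makes the monotonicity diagnostics below well-populated, while
`step = w` reproduces the tumbling reading exactly. Under tumbling windows
over a list whose length is a multiple of `w`, window scores sum to the
final cumulative count — a useful cross-check that both code paths share.

## What the synthetic generator emulates

`simulate_bundle()` produces every input the pipeline reads, with ground
truth, under study conditions chosen to mirror a triplicate 50-cell
experiment on a well-profiled breast-cancer cell line:

* **Transcriptome.** 13,187 genes with collapsed levels spanning
  2.80–14.48 log-scale units. The sorted curve is
  $\ell(q) = \ell_{\min} + (\ell_{\max}-\ell_{\min})(1-q)^{a}$ over rank
  quantiles $q$ with shape $a = 1.46$, a concave decay chosen so that the
  6.0-unit threshold falls near rank 7,500 — about 7,750 genes sit at or
  above 6.0. Each gene gets 8 per-sample values with Gaussian jitter
  (SD 0.15 units), small enough that the classical array reproducibility
  ratio (max − min)/mean stays at or below 0.2 for the large majority of
  genes. About 15% of genes carry a second, dimmer probe so the
  highest-mean-wins collapsing rule is exercised, and a handful of probes
  are symbol-less.
* **Detection model.** Detection probability is a function of transcript
  level: a linear ramp from 1.0 at the top of the expression range down to
  a floor of 0.10 at 6.0 units, flat below — the plateau structure seen
  when detected proteins are traced along an expression-sorted transcript
  list. Per-run probabilities are rescaled so each run's expected
  transcript-backed detections equal `run_depth * (1 - frac_protein_only)`
  (default 800), making the realized depth ~1,000 per run.
* **Protein-only genes.** A pool of 1,000 genes without transcript rows is
  detected at a flat per-run probability calibrated to contribute 20% of a
  run's expected detections, emulating the fraction of detected proteins
  that cannot be matched to the transcript set. The 20% target is therefore
  a *per-run* expectation; the union across runs concentrates slightly
  below it because the ramped transcript probabilities inflate faster under
  union than the flat protein-only probability.
* **Identification noise.** Reports carry the 9 cRAP contaminant
  accessions, ~5% duplicate accessions for already-reported genes, 20
  unannotated (symbol-less) rows, and about half of the alias-bearing
  detected genes reported under their previous symbol — so contaminant
  filtering, deduplication and alias resolution all do real work on
  simulated data.
* **Pathways.** 1,452 sets with log-uniform sizes between 10 and 300
  members (right-skewed, like curated collections), sampled with overlap
  from the full gene universe, transcripts and protein-only genes alike.

What the generator does **not** emulate: peptide/spectrum-level processes
(FDR filtering, shared peptides, missing values correlated within
pathways), biologically coherent pathway membership (synthetic sets are
random, so background enrichment is flat), inter-gene expression
correlation, and batch structure between the proteomics and transcriptomics
"studies". Passing recovery tests on these bundles therefore demonstrates
that the machinery measures what it claims under the stated statistical
model — not that real canonical pathways are enriched in real samples.

For the enrichment-recovery benchmark the generator is configured with a
flat background — the detection ramp collapsed so every gene is detected at
the 10% floor, no protein-only pool, and the run depth set to the floor's
expectation — and one pathway planted at 80% per-run detection. This
isolates the statistic: the planted set should surface as the top-ranked
result essentially always, and does so in ≥ 95 of 100 seeds.

## Numerical choices

* The hypergeometric mass is computed as
  `exp(lchoose(K,k) + lchoose(N-K,n-k) - lchoose(N,n))` — log-space
  binomial coefficients, stable at $N \sim 10^4$, $n \sim 10^3$; tail sums
  are clamped to $[0,1]$. Tests require agreement with exact integer
  combinatorics on all small urns ($N \le 20$), with
  `stats::phyper` (an independent log-gamma route) to $10^{-10}$ relative
  on 1,000 random inputs, and with $10^5$-draw Monte-Carlo tail
  frequencies within 3 SD on larger ones.
* Sorting ties: profiles are ordered by decreasing level, then ascending
  symbol; probe collapsing breaks mean ties by probe id. Both rules exist
  purely for cross-platform determinism.
* The expression threshold is inclusive at the boundary (level = 6.0 is
  "high").
* Window-score monotonicity is judged by an antitonic (decreasing isotonic)
  fit: the residual RMSE must stay below $\sqrt{w}/2$ — half the worst-case
  binomial SD of a `w`-gene window score — which a genuinely monotone mean
  profile satisfies comfortably while a non-monotone one does not.
* Degenerate inputs fail loudly: malformed GMT lines, duplicate set names
  or probe ids, non-numeric expression cells, out-of-range *k*-of-*n*
  thresholds and inconsistent hypergeometric counts all raise errors naming
  the offending record; harmonization failures, by contrast, are tallies,
  because partial mapping is the expected state of real reports.
* Every run's ledger must reconcile exactly:
  contaminants + unmapped + ambiguous + duplicate collapses + distinct
  genes = input rows. This is asserted inside the package, not just tested.

## Problem sizes used by the test-suite

Unit tests run on reduced bundles (1,500 transcript genes, 120 pathways,
run depth 250) chosen to exercise every code path at comfortable margins;
the recovery and benchmark checks run at the full default scale
(13,187 genes, 1,452 sets), with 100 seeds for enrichment recovery and
single-seed checks for concordance structure. The acceptance script repeats
the same computations at 20 seeds for the spike benchmark.

## Known limitations

* Unmappable protein records are flagged, not rescued: there is no live
  UniProt lookup, by design. A supplementary offline accession-to-symbol
  table can be folded into the alias table instead.
* Enrichment is over-representation only — no ranked-list statistics, no
  pathway topology; the method treats a pathway as a bag of genes.
* The high/low expression threshold is a configuration input inspected on
  the sorted-expression plot, not an automatically detected change point.
* Percentages are rounded half-up to the printed precision; at a set size
  of ~5,000, the second decimal of a percentage corresponds to half a gene,
  so published tables rounded differently can disagree by 0.01 without any
  substantive difference.
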