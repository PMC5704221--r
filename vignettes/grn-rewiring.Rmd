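---
title: "Methods: building and comparing regulatory networks from accessibility peaks"
author: "grnrewire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and comparing regulatory networks from accessibility peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnrewire)
```

## The model

Open chromatin marks where regulation can happen.  `grnrewire` turns a set
of accessibility peaks (ATAC-seq or DNase-seq) into a directed gene
regulatory network (GRN) in three steps, and then asks how that network
differs between two cellular conditions — for example between circulating
CD8 T cells and their exhausted, tumor-infiltrating counterparts, where
the loss of receptor subnetworks (such as those controlling CD7 or P4HB)
is a candidate mechanism of immune escape.

1. **Peak-to-gene assignment.**  Each peak is reduced to an anchor point —
   its summit when the narrowPeak file provides one, otherwise the
   interval midpoint — and assigned to every gene whose transcription
   start site (TSS) lies within a window of the anchor (default
   ±2,000 bp, closed at the boundary).  No nearest-gene rule is applied: a
   promoter-proximal peak between two close TSSs supports both genes, and
   downstream stages tolerate the multi-assignment.

2. **Motif scanning.**  Every peak sequence is scanned on both strands
   with each position weight matrix (PWM) in a motif library.  A window of
   motif width $w$ gets the log-odds score
   $s = \sum_{i=1}^{w} \log_2 \frac{p'_i(x_i)}{b(x_i)}$,
   where $p'$ is the PWM after pseudocount regularisation
   $p'_i(x) = (p_i(x) + \varepsilon\, b(x)) / (1 + \varepsilon)$ and $b$
   is a 0-order background.  The p-value of a score is its exact upper
   tail under the null that the window is i.i.d. background, computed by
   position-wise convolution of the per-position score distributions on an
   integer grid (step: `granularity` bits, default 0.001).  The observed
   score is rounded *down* onto the grid, so reported p-values are never
   underestimated.  An occurrence is kept when $p \le \alpha$ (default
   $10^{-4}$).  Windows containing `N` are skipped.

3. **Network construction.**  A directed edge TF → gene is created
   whenever some peak assigned to the gene carries an occurrence of one of
   the TF's motifs.  Edges aggregate all supporting occurrences as
   evidence (peak, motif, strand, offset, p-value); a heterodimer motif
   (`TFA::TFB`) contributes one edge per partner, sharing evidence.  There
   is no minimum-evidence rule beyond one qualifying occurrence.

On the resulting networks the package computes hub-regulator rankings,
receptor subnetworks, multi-network set intersections, and differential
networks; a local hypergeometric over-representation test and a
differential-expression screen connect the rewiring to pathways and to
transcription.

## Hub regulators: out-degree and PageRank

The first ranking scores a TF by the number of distinct genes it
regulates.  The second runs PageRank — damping 0.85, uniform teleport,
uniform redistribution of dangling-node mass, power iteration to an L1
residual below $10^{-10}$ — on the **reversed** edge set (gene → TF).
Reversal matters: on TF → gene edges standard PageRank accumulates mass on
heavily-regulated *genes*, whereas the question is which *regulators* are
hubs.  With reversed edges, rank mass flows from targets to their
regulators, and the two rankings become comparable (on dense regulatory
networks they tend to agree closely).  The orientation is an argument
(`reverse = FALSE` restores the standard direction).

## Differential networks and lost receptors

Edge identity for comparisons is the (TF, gene) pair; evidence is ignored,
because rewiring is about wiring, not about which peak supplied it.
`diff_network(a, b)` returns exact set differences of edges and nodes, and
flags a receptor as *lost* when it is regulated in condition A but is not
a regulated node in condition B at all, together with its number of
distinct A-regulators.  `diff_receptor_network(a, b)` is the receptor
subnetwork of A restricted to edges absent from B — the displayable "what
B switched off" object.

## Enrichment and expression

Web-based enrichment services are replaced by the classical hypergeometric
over-representation test: for a query of $n$ genes in a universe of $N$,
a set with $K$ members in the universe and overlap $k$ scores
$P(X \ge k)$ with $X \sim \mathrm{Hypergeom}(N, K, n)$, followed by
Benjamini–Hochberg adjustment across the library.  The universe defaults
to the genes of the network under analysis, which matches testing
"uniquely regulated genes" against the network background rather than the
whole genome.

The modulated-gene screen applies, per gene, Welch's two-sided t-test on
`log2(x + 1)`-transformed expression (a Mann–Whitney alternative is
available), selecting genes with $p$ below a threshold (default 0.01).
The test behind published "significantly modulated genes" heatmaps is
rarely stated; Welch on log counts is the conservative default because it
tolerates unequal variances and the log transform symmetrises bulk
RNA-seq-like intensities.  Genes with zero variance in both groups are
untestable: they are flagged and assigned $p = 1$ rather than an error,
so screening a matrix with constant rows never aborts a pipeline run.
Selected genes are exported as z-scored rows (mean 0, sd 1 across the
compared samples) for heatmap rendering.

## The synthetic study

Real studies of this design start from consortium peak files and public
expression series; those inputs are large, versioned, and not
redistributable inside a package.  `simulate_study()` therefore generates
a fully self-contained miniature with known ground truth for *every*
downstream stage:

* a genome of i.i.d. background bases (default: 2 chromosomes × 120 kb,
  uniform composition — i.i.d. background makes the analytic
  false-positive calibration `expected_background_hits()` exact);
* 30 genes laid out so that no gene's peaks can fall inside another
  gene's assignment window, 5 of them designated receptors (`R1`…`R5`);
* a motif library of 8 planted TFs plus 4 decoy TFs whose motifs are
  never planted, so edge precision is measurable;
* one 200-bp peak per gene near its TSS; each gene draws 2–4 designated
  regulators, and each designated TF → gene edge receives (with
  probability `planting_rate`, default 1) a consensus site written into
  the genome at a random non-overlapping offset and strand within the
  gene's peak;
* condition B: the peaks of the shutdown receptors (default `R1`) are
  removed, deleting all their planted sites and nothing else — the
  regional-subnetwork shutdown this class of analysis is meant to detect;
* an expression matrix (5 samples per group) with log-normal noise
  (sd 0.25 on the log2 scale) in which the shutdown receptors' group-B
  mean is shifted down by 2 log2 units.

Default motifs are point-mass (information content 2 bits per column,
configurable down via `motif_information_content_min`), width 9.  The
width is a deliberate interaction with the scan threshold: at
$\alpha = 10^{-4}$ a width-9 point-mass motif admits *only* its exact
consensus, because the one-mismatch upper tail is
$(1 + 27)/4^9 \approx 1.07\times 10^{-4}$, just above the threshold,
while the consensus itself sits at $4^{-9} \approx 3.8\times 10^{-6}$.
Chance background edges then arrive at a rate of roughly 0.5 per default
run, so planted-edge recall is 1 by construction and precision stays a
meaningful, high readout.  An even width (8 or 10) would either leave the
one-mismatch tail inside the threshold (width 10, ~4 chance edges per
run) or put the exact-match rate an order of magnitude higher (width 8).

What the generator does **not** emulate: nucleosome positioning and
fragment-length structure, peak-calling noise, correlated TF binding,
GC-content bias, single-cell sparsity, and any coupling between chromatin
state and the expression matrix beyond the planted receptor shifts.
Passing the synthetic tests therefore demonstrates that the machinery is
correct — assignment, scanning, p-values, joins, diffs and screens do what
they claim — not that the biological inference is valid on real peaks,
where motif databases are redundant, backgrounds are non-uniform and
regulatory windows are debatable.

## Numerical choices

* Coordinates are 0-based half-open throughout (BED convention); the TSS
  of a `-`-strand gene is `end − 1`.
* The score grid is capped (default $10^7$ cells); an over-fine
  granularity is rejected with advice rather than silently truncated.
  The p-value convolution runs on the sparse set of achievable sums, so
  informative motifs cost far less than the cap suggests.
* Minus-strand windows are scored with the row-reversed, base-complemented
  matrix at the same left offset; their p-values use the same null as the
  forward strand (exact for complement-symmetric backgrounds, including
  the default uniform one).
* Ranking ties are broken lexicographically by TF name; all written
  tables are sorted with C-locale collation, so outputs are byte-stable
  across machines and reruns — `run_synthetic_study()` twice with the same
  seed produces byte-identical trees (logging goes to stderr, never into
  result files, and the run manifest records parameters and input
  checksums but no timestamps).
* PageRank non-convergence at `max_iter` returns the last iterate with a
  warning and a recorded residual instead of failing.

## Problem sizes used in the validation suite

The shipped tests validate each stage against an independent route: the
peak assigner against an all-pairs scan (instances up to 500 × 500), the
p-value convolution against exhaustive enumeration of all $4^w$ words
(widths 4–8), PageRank against a dense linear solve (50-node graphs),
the hypergeometric tail against direct combinatorial sums ($N \le 30$),
scan calibration against the closed-form expectation on 2 Mb of i.i.d.
background, and the end-to-end study over 100 simulation seeds (recall,
precision, and exact recovery of the shutdown receptor set).  These sizes
were chosen to exercise every code path at desk scale; all invariants are
scale-free.

## Known limitations

* Only raw p-value filtering is offered for motif hits (no q-values);
  that is the conventional single-threshold design this pipeline family
  uses, but it ignores the multiplicity of motifs × peaks.
* 0-order backgrounds only; CpG-poor or repeat-rich genomes would need a
  higher-order null the scanner does not implement.
* The GFF/GTF zoo is out of scope: gene models enter as BED6.
* Edge evidence stores occurrences, not effect sizes; the networks are
  unweighted, and no expression-based pruning of motif-derived edges is
  attempted.
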