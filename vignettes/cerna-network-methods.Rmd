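---
title: "Methods: ceRNA network inference with spongenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ceRNA network inference with spongenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongenet)
```

# The model

Competing endogenous RNA (ceRNA) regulation posits that transcripts sharing
miRNA binding sites compete for a limited miRNA pool: when a sponge (an
lncRNA or a circRNA) rises, it sequesters its miRNAs and de-represses the
mRNAs those miRNAs target. In a two-group case/control design this predicts
a characteristic direction pattern — sponge and mRNA move together, the
shared miRNA moves against them (`up-down-up` or `down-up-down`).

`spongenet` turns that hypothesis into a deterministic pipeline over count
matrices and sequences:

1. **Differential expression** per RNA class by Fisher's exact test on
   group-pooled counts, with |log2FC| and class-specific p cut-offs.
2. **Target prediction** by two independent scorers — canonical seed-site
   scanning with a 0–100 context-style score, and local duplex alignment
   with an additive hybridisation energy — intersected under cut-offs
   (context ≥ 50, energy < −10 kcal/mol).
3. **Network assembly**: direction-consistent miRNA–partner edges, sponge–
   miRNA–mRNA triads, integration of the two sponge classes into quads, and
   degree-based hub ranking.
4. **Enrichment** of the DE gene set against user-supplied GMT collections
   by the hypergeometric upper tail.

A synthetic-data generator plants known fold changes and ceRNA triads so
every stage can be validated offline against ground truth.

# Differential expression

For feature $g$, counts are pooled within each group and laid against the
pooled mapped-read totals in a 2×2 table
$[[x_{g,\mathrm{case}}, T_\mathrm{case} - x_{g,\mathrm{case}}],
  [x_{g,\mathrm{ctrl}}, T_\mathrm{ctrl} - x_{g,\mathrm{ctrl}}]]$,
tested two-sided with Fisher's exact test under the minimum-likelihood rule
(the `fisher.test` convention: sum all hypergeometric masses not exceeding
the observed one, with a $1+10^{-7}$ tie guard). Pooling makes the test
well-defined without a replicate model; the cost is that **the test treats
the pooled count as a single draw and ignores biological replication**, so
raw p-values are strongly anticonservative under negative-binomial
overdispersion. On a simulated null (2000 features, 40 vs 40, dispersion
0.1) about 43% of features reach p < 0.05 — yet the *call* rate is 0,
because a direction call also requires |log2FC| > 1, which replicate-level
noise essentially never produces at this depth. The fold-change threshold,
not the p-value, carries the specificity burden; this matches how the
thresholds were used in the source analysis style this pipeline follows,
and is why BH q-values are reported but not used for calling by default.

Fold changes are $\log_2\frac{\bar m_\mathrm{case} + c}{\bar m_\mathrm{ctrl} + c}$
on normalised group means with pseudocount $c = 0.5$ (configurable), which
keeps zero-count features finite and the statistic antisymmetric under
group swap. Normalisation is CPM for mRNA/lncRNA/miRNA and SRPBM
(back-splice junction reads × 10⁹ / mapped reads) for circRNAs; *total*
mapped reads are used as the SRPBM denominator (the uniquely-mapped variant
was not adoptable without alignment-level input). Thresholds default to
|log2FC| > 1 with p < 0.05, except miRNA which uses p < 0.01 — the stricter
figure-legend threshold — both exposed in `de_thresholds()`.

The class-level helpers `ddct_relative_expression()` (comparative
$2^{-\Delta\Delta C_t}$) and `circ_source_summary()` (genomic-origin
proportions) support the qPCR-verification and circRNA-provenance summaries
that usually accompany this analysis.

# Target prediction

**Seed scanning.** Canonical sites are reverse complements of the miRNA
seed: `6mer` (positions 2–7), `7mer-A1` (6mer + A opposite position 1),
`7mer-m8` (positions 2–8), `8mer` (both), reported with the strongest type
per occurrence, 1-based half-open coordinates. Circular targets are scanned
with the first 7 bases appended so junction-spanning sites are found;
starts are reduced modulo length, so `end` may exceed the length for a
wrapped site.

**Context-style score.** TargetScan's published context+ scores are small
negative reals, so a "≥ 50" cut-off only makes sense on a 0–100
percentile-like scale; we implement exactly that: base score per type
(8mer 75, 7mer-m8 60, 7mer-A1 50, 6mer 35) + 20·(AU fraction of the 30-nt
flanks) + 5 for a site within 15 nt of a linear target's end (but not
flush against it), clipped to [0, 100]. The constants place every 8mer
above the 50 cut-off regardless of context, 7mers above it by default, and
6mers below it unless strongly AU-supported — mirroring the relative
signal strengths of the canonical taxonomy.

**Duplex energy.** The miRNA is locally aligned (Smith–Waterman, affine
gaps) against the reversed target window with complementarity scoring:
Watson–Crick +5, G:U +2, mismatch −3 (doubled in the seed, positions 2–8),
gap open −8 / extend −2. The energy of the optimal alignment is
$-(3\,n_{GC} + 2\,n_{AU} + 1\,n_{GU}) + 4\,n_\mathrm{gap\ openings} +
2\,n_\mathrm{mismatches}$ kcal/mol. A gap contributes **once per indel
event**, not per column — the reading consistent with affine scoring, and
the one under which a planted 8mer's duplex always clears the −10 cut-off
(charging every gap column lets long favourable alignments be ruined by the
gap runs that stitched them together). Note that under this additive model
a standalone all-AU 6mer duplex already reaches −12; the 6mer's context
score (35 < 50), not its energy, is what removes seed-only 6mer pairs, so
the two scorers genuinely share the filtering burden. This is a documented
desk-scale analogue, **not** a reproduction of TargetScan v5 or miRanda
v3.3a outputs; no conservation, accessibility, or nearest-neighbour
thermodynamics.

Neither scorer emits a binding p-value. Published descriptions of this
analysis style sometimes quote one; no such quantity is defined by either
program, so the intersection rule (context ≥ 50 AND energy < −10) carries
the entire filtering burden here.

**Intersection.** One candidate row per (miRNA, target) pair with ≥ 1 site:
best site by context score (ties to the smallest start), best duplex as the
minimum energy over windows around the sites (the site plus room for the
miRNA 3′ end on the target 5′ side). `passes` requires both cut-offs — the
stand-in for keeping only predictions shared by both programs.

# Network assembly

Edges require a passing pair whose endpoints are both DE with opposite
directions; `ns` features never enter. Triads join a sponge edge and an
mRNA edge of the same miRNA with sponge and mRNA co-directional; quads join
an lncRNA triad and a circRNA triad sharing **both** the miRNA and the mRNA
(the convergence pattern seen when both sponge classes regulate a shared
hub; miRNA-only sharing is available as `share_mrna = FALSE`). Direction
filtering is strictly sign-based: sample-level expression correlation is
deliberately *not* required, matching the direction-only filtering of the
analysis style this follows. Hubs are mRNAs ranked by distinct-miRNA
degree — "hub" has no standard formal definition in this context, and
degree centrality is the simplest criterion consistent with how hub genes
are reported; ties break lexicographically so output is deterministic.
Exports are SIF, GraphML (class/direction/degree as node attributes), and
plain TSVs, all Cytoscape-ready and byte-reproducible.

# Enrichment

DAVID is a versioned web service and irreproducible offline, so enrichment
is a local hypergeometric upper tail against user-supplied GMT collections:
for a term of size $K$ in a universe of $N$ with a DE set of size $n$ and
overlap $k$, $p = \sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$.
The DE set uses the paper-style gene filter (|log2FC| > 1, p < 0.05); the
universe defaults to all measured features of the class under test (not the
genome), which is the conservative over-representation convention. BH
q-values are reported; the significance flag uses raw p < 0.05. DAVID's
EASE-style deflation (testing $k-1$) is available via `ease = TRUE` but off
by default, since whether it was used upstream is unknowable.

# The synthetic world

`sim_config()` states the world once:

* **Design**: 40 case vs 40 control samples — the PBMC cohort sizes of the
  study design this emulates.
* **Counts**: negative-binomial with dispersion 0.1 (a typical bulk RNA-seq
  value) around log-normal per-feature baselines (meanlog 4, sdlog 1 →
  median ≈ 55 counts). The generator is a noise model for counts only: no
  batch effects, no isoform structure, no read-level simulation.
* **Features**: 400 mRNA / 150 lncRNA / 80 circRNA / 100 miRNA. These are
  desk-scale — hundreds rather than the tens of thousands of a full
  transcriptome — chosen so the complete pipeline runs in seconds while
  keeping realistic *relative* class sizes. A green test therefore
  establishes correctness of the machinery, not performance or calibration
  at transcriptome scale.
* **Effects**: 5% of features per class receive a planted ±2 log2FC
  (case-mean multiplied by 2^±2); 20 planted triads receive coordinated
  signs and a real 8mer site (reverse complement of miRNA positions 2–8
  plus an A) written into both the sponge and the mRNA 3′UTR at recorded
  positions.
* **Sequences**: uniform-random composition over {A,C,G,U}; circRNAs are
  stored linearised with `topology=circular` and the junction at position 1;
  T on input maps to U. Lengths 500/800/400/22 nt (3′UTR, lncRNA, circRNA,
  miRNA).
* **Totals**: per-sample mapped totals are the column sums over all classes
  plus 10⁶ background reads (reads mapping outside the modelled features),
  so CPM/SRPBM denominators behave like library sizes.
* **Determinism**: one integer seed; both generators re-derive the same
  planted-truth plan from it, so sequence and count generation agree even
  when called independently, and identical configs give byte-identical
  files.

Because flanks are random rather than AU-rich, planted sites are *not*
given artificially favourable context; recovery rests on the 8mer base
score and the seed-driven duplex.

# Verification strategy and bands

Every operation with a tractable ground truth is tested against an
independent oracle: Fisher p against explicit table enumeration for all
margins ≤ 30; the seed scanner against a brute-force window scan (linear
and circular); the duplex DP against exhaustive local-alignment enumeration
on strings ≤ 10 nt; triads/quads against triple-loop enumeration; the
hypergeometric tail against exact big-integer arithmetic for all N ≤ 60
(computed in Python, whose integers are unbounded — double-precision
binomials are inexact past C(56, 28)).

Stochastic checks use fixed seeds and documented bands:

* **Null calibration**: direction-call rate at α = 0.05 on a null world
  must stay below 0.05 + 3·√(0.05·0.95/2000) ≈ 0.065; the raw p rate is
  recorded (≈ 0.43, the anticonservatism discussed above) but not banded.
* **Effect recovery**: planted |log2FC| = 2 features with baseline mean
  ≥ 50 recalled at ≥ 90% (observed: ≈ 100%; pooled testing is powerful).
* **End-to-end**: ≥ 90% of 20 planted triads appear in the triad TSV
  (observed: 20/20 across several seeds). Unplanted triads arise from two
  sources — chance seed matches among background DE features, and
  combinatorial mixing (a planted miRNA with two sponges and three mRNAs
  already yields six valid triads) — and stay below 10× the planted count
  at the default configuration (observed ≈ 3–5×). They are not errors: the
  direction-plus-sites rule genuinely admits them, exactly as it would on
  real data.

# Numerical and design choices

* Two-sided Fisher p uses the minimum-likelihood rule with the standard
  $1+10^{-7}$ relative tie guard; degenerate tables (a zero margin) give
  p = 1.
* Coordinates are 1-based, intervals half-open; circular starts reduced to
  [1, L]; equal-scoring sites break ties by smallest start.
* Only the annotated sense strand is scanned — ceRNA logic concerns mature
  transcripts.
* Target prediction in the pipeline defaults to DE features only
  (`predict_de_only = TRUE`). This is a pure optimisation: non-DE features
  can never contribute edges, so the network is identical; the enrichment
  universe still uses all measured features.
* The selection of "top" DE mRNAs used to seed small published network
  figures has no stated criterion; no such pre-filter is applied by
  default (all DE features enter the network), and any reduction is left
  to the caller. Similarly, published miRNA counts inside networks can be
  smaller than the DE totals for reasons not recoverable from text; no
  hidden filter is implemented.
* All stage outputs carry `#` provenance comment lines naming the
  parameters that produced them; ordering is sorted everywhere, so reruns
  are byte-identical.

# Limitations

Pooled-count Fisher testing is not a replicate-aware model — for real
cohort data a DESeq2/edgeR-style NB GLM is the better tool; this module
exists to make a specific published analysis style reproducible and
testable. The target scorers are desk-scale analogues, not the named
programs. The synthetic generator omits batch effects, library-composition
bias, isoform structure, and sequence composition bias, so green tests
bound correctness of the inference machinery, not field performance.
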