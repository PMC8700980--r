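---
title: "Inferring regulatory cascades from developmental transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring regulatory cascades from developmental transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Neurodevelopmental disorders such as autism spectrum disorder (ASD) are
increasingly understood as disorders of gene *regulation* rather than of
single genes. When induced pluripotent stem cells (iPSCs) from patients are
differentiated into neural progenitor cells (NPCs) and neurons, the
transcriptome can be profiled at each stage in both patient-derived and
control lines. The question this package addresses is how to move from those
count matrices to a comparison of *regulatory programs*: which transcription
factors (TFs) drive coordinated expression of their targets at each stage,
how long non-coding RNAs (lncRNAs) slot into those programs, and which
regulatory cascades present in control samples disappear in disease.

`regcascade` implements that workflow end to end, and — because the real
question of whether such a pipeline *works* cannot be answered on data with
unknown truth — ships a synthetic study generator that plants every structure
the pipeline is supposed to find: differentially expressed genes, motif
binding sites, enhancer-linked lncRNA targets, and TF-rooted regulatory
cascades that are selectively broken in the disease condition.

## Pipeline model and assumptions

The pipeline has eight file-handoff stages (`run_pipeline()` executes all of
them under one seed):

1. **Expression filtering.** A gene is unexpressed when its median count
   across *all* samples falls strictly below `min_median_count` (default 20
   reads). The boundary reading matters: a median of exactly 20 survives.
2. **Differential expression.** A negative-binomial Wald test, fully
   specified rather than delegated: DESeq-style median-of-ratios size
   factors (library-size fallback for sparse matrices), method-of-moments
   gene-wise dispersions shrunk 50/50 toward the 20%-trimmed mean of all
   estimates, and a delta-method Wald statistic on the log-mean difference
   with variance `sum over groups (m + phi m^2)/(n m^2)`. Significance uses
   the field's conventional strict `|log2FC| > 1` with Benjamini–Hochberg
   FDR < 0.05. The means in the fold change and the Wald statistic carry a
   +0.5 offset so all-zero groups stay defined; a gene with no counts at all
   reports `p = 1, log2FC = 0` by contract. The test is *calibrated by
   simulation*, not validated against a reference dataset: under a null NB
   simulation (phi = 0.1, n = 10 vs 10, 2000 genes) the fraction of p < 0.05
   must sit in [0.03, 0.07], and planted two-unit fold changes must be
   detected with at least 80% power. Both checks run in the test suite.
3. **Pathway activity.** A per-sample gene-set activity score in the GSVA
   family, specified exactly so it is reproducible to machine precision:
   per-gene ECDFs across samples; within-sample ranking of those ECDF values
   (ties broken by gene id, so results are platform-independent); weights
   `|p/2 - rank|`; a walk over genes in rank order accumulating normalized
   in-set weight against a uniform `1/(p - m)` out-of-set penalty; and the
   score defined as the largest positive deviation plus the largest negative
   deviation (the negative one carries its sign). The ECDF kernel was chosen
   over smoothed alternatives precisely because it is rank-invariant and
   exactly specifiable; the test suite holds the implementation to an
   independently coded literal evaluation of those five steps at 1e-12.
   Group summaries are exact medians; stages are compared with the classical
   pooled-variance two-sample t-test (a paired-by-pathway variant is
   available via `paired = TRUE`; the unpaired form is the default since
   pathway scores at different stages come from different sample sets).
4. **Motif scanning.** JASPAR-format position frequency matrices become
   log-odds PWMs with a total pseudocount of 0.8 split in proportion to the
   background (a common motif-tool default; thresholds depend on it, which
   is why it is configuration, not a constant). The score threshold for a
   match p-value is computed *exactly*: the distribution of PWM scores over
   i.i.d. background sequences is built by dynamic programming over score
   bins of width 1e-3, with floor rounding so the discretized score never
   exceeds the true score — the realized false-positive probability is
   therefore guaranteed not to exceed the requested p-value. Scanning slides
   every PWM over both strands of every promoter (`-1000/+200` bp around the
   strand-aware TSS; a minus-strand promoter is the reverse complement of
   the strand-reflected window) and gates on the same discretized score the
   DP reasons about, so the guarantee applies to the scores actually used.
   The per-position threshold deliberately applies no multiple-testing
   correction across positions: the p-value is strict enough (5e-5) that it
   is treated as a fixed per-position criterion.
5. **Network assembly.** Three evidence layers merge into one
   regulator→target table: reference TF→gene edges filtered to expressed
   endpoints, motif-derived TF→lncRNA edges, and lncRNA→gene edges declared
   when a lncRNA locus overlaps an enhancer interval assigned to that gene.
   All coordinates are 0-based half-open; touching intervals do not overlap,
   and strand is ignored for enhancer overlap since enhancers act
   strand-agnostically.
6. **Correlation gating.** Every edge gets a Pearson correlation per
   (cell type, condition) group, computed on log2-CPM (variance
   stabilization; raw counts would let library size masquerade as
   co-regulation). A pair is "coordinately expressed" when `|r| >= 0.75` —
   the absolute value, because negative regulation is regulation too.
   Enhancer-evidence lncRNA→gene edges are exempt from the gate: they rest
   on physical overlap, not co-expression. Groups with fewer than three
   samples, or constant profiles, yield an undefined correlation and an
   inactive edge rather than NaN propagation.
7. **Cascade growth.** From each root TF, breadth-first, within one group:
   a target joins the next layer when its edge's correlation exceeds 0.8
   *strictly* (exempt enhancer edges join whenever active), up to three
   layers below the root. A gene reachable twice is kept at its first
   encounter, with parents and candidate targets processed in lexicographic
   order — this makes every cascade a deterministic tree. A root with no
   passing regulation is not counted as a cascade (otherwise cascade counts
   would be constant at the number of TFs). The pair cutoff (0.75) and the
   cascade gate (0.8) are deliberately independent knobs: the first defines
   the coordinately-expressed pair lists, the second the stricter growth
   criterion.
8. **Enrichment.** Over-representation of a query set against GMT
   collections uses the standard hypergeometric upper tail with BH
   correction. This is the package's one deliberate methodological
   replacement: web-service annotation engines are not reimplemented, and
   the universe defaults to the expressed genes (configurable), since that
   is the set from which any query here is drawn.

## What the generator emulates — and what it does not

The synthetic study mirrors the reference design: three cell types with
samples 11/17 (iPSC, normal/ASD), 9/21 (NPC) and 8/17 (neuron). Each of six
TFs roots a planted cascade (branching 2, depth 3) of protein-coding genes;
each TF additionally regulates one lncRNA whose promoter carries the TF's
consensus site (both orientations and both gene strands are exercised), and
each lncRNA overlaps an enhancer assigned to one further target gene. A
distractor block of zero-coupling edges under dedicated regulators makes
specificity measurable, and a standalone block of genes carries a +2 log2FC
shift in ASD NPC/neuron samples only — so the qualitative stage signature
(few early DEGs, many later) is a property of the data, not of the test.

Expression follows a latent-activity linear-Gaussian model with NB emission:
root activities are standard normal per sample, each child's latent value is
`beta` times its parent's plus Gaussian noise, and counts are NB with mean
`baseline * 2^latent`. In ASD samples a fixed 30% of the gated planted edges
have `beta` zeroed ("broken"), which removes the whole subtree below the
break from the disease cascade — the mechanism behind lost and shrunken
cascades.

Three generator choices deserve an explicit rationale.

First, the noise budget. The population correlation of a planted edge is
`1/sqrt((1 + s^2 + v)(1 + v))` at layer one, where `s^2` is the latent noise
variance and `v ≈ (phi + 1/mu)/ln(2)^2` the NB contribution on the log2
scale. The recovery guarantee quantifies over *every* planted edge in every
control group — a family of a few hundred correlation draws — so the margin
must be sized family-wise, not per edge. The defaults
(`latent_noise_sd = 0.03`, `nb_dispersion = 0.003`, baseline means floored
at 500 counts) put the planted-edge correlation near 0.985–0.99, about 3.3
to 3.8 Fisher-z standard errors above the 0.8 gate in the smallest group
(n = 8): the expected number of gate slips across the whole family is then
well below one. Noisier settings (e.g. latent sd 0.5, dispersion 0.1) cap
the layer-one correlation near 0.75–0.82 and make the strict gate a coin
flip at these group sizes; they are legitimate for stress testing but
cannot support a planted-truth recovery guarantee, which is the generator's
purpose. The DE calibration simulations intentionally keep the harsher
`phi = 0.1` — they test the statistical test, not cascade recovery.

Second, distractor targets draw their own latent variation (sd 0.3) rather
than sitting at a near-constant baseline: an almost noiseless gene's log-CPM
is dominated by the shared library-size factor, which would correlate the
null edges with one another and bias the null |r| spectrum upward. Their
coupling stays exactly zero.

Third, planted motif truth is kept *complete*: TF consensi are generated
mutually dissimilar (pairwise Hamming distance at least half the motif
length, including reverse complements), and any promoter window that scores
a significant hit for a pair that was not planted has its background bases
resampled (planted bases are protected). A background near-consensus
occurrence is a real match that the scanner correctly reports; leaving it
unrecorded would make the truth file wrong, and recovery tests would be
testing the genome's luck. The scanner's false-positive rate is measured
where it belongs, on independent random sequences against the Poisson count
implied by the threshold's tail mass.

What the generator does *not* emulate, and what passing tests therefore do
not show: realistic library-size variation and GC effects; correlated
biological replicates; overlapping cascades that share targets (planted
trees are disjoint so truth is unambiguous); motif co-occurrence and
cooperative binding; and any real genome sequence composition beyond the
i.i.d. background. Results on real data depend on those factors; the tests
certify the machinery, not biological discovery.

## Numerical choices and degenerate inputs

* PWM score discretization is 1e-3 log-odds units with floor rounding; the
  DP threshold is checked against exhaustive enumeration of all `4^L` words
  for every motif of length ≤ 6.
* A requested motif p-value below the probability of the single best word
  falls back to the maximum score with a logged warning.
* Ranking ties in the activity score break by gene id; medians use the
  midpoint convention.
* The stage t-test reports the degenerate limits (p = 1 for equal constant
  vectors, p = 0 otherwise) instead of failing on zero pooled variance.
* BH input containing NaN is an error, not silently dropped.
* Empty results (no expressed genes, no hits, no cascades) produce empty,
  well-formed tables with warnings, never crashes.

## Problem sizes

The default study is deliberately desk-scale: ~210 genes, 83 samples, six
motifs, ~120 network edges. The full pipeline completes in well under a
minute, and the complete test suite — including two full pipeline runs for
the byte-identity determinism check, the 2000-gene DE calibration, and the
exhaustive PWM oracle — in a few minutes on one CPU. All sizes are design
parameters of `sim_design()`, so scaling the study up is a one-line change.

## Known limitations

* The NB Wald test is a documented, calibrated re-implementation; it is not
  intended to reproduce the exact statistics of quantile-adjusted
  conditional-likelihood DE packages on any given dataset.
* Cascade counts depend on the "at least one regulation" counting rule;
  under a different rule the normal-versus-disease comparison changes by a
  constant.
* Enhancer→gene assignment is taken from the enhancer annotation as given;
  the package does not infer it.
* The scanner is a naive slider — adequate at promoter scale, not a
  genome-wide scanner.
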