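---
title: "Calling chromatin domains from DamID tiling arrays: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling chromatin domains from DamID tiling arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(damidseg)
```

## The measurement and its model

DamID marks the binding sites of a chromatin protein by fusing it to a
DNA adenine methyltransferase; methylated fragments are amplified and
hybridized on a two-channel tiling array against a control expressing
the methylase alone, which absorbs non-specific accessibility. On a
grid of probes spaced ~300 bp apart, the signal at probe $i$ is

$$M_i = \log_2 \frac{\text{fusion}_i}{\text{control}_i}, \qquad
  A_i = \tfrac12 \log_2 (\text{fusion}_i \cdot \text{control}_i).$$

Binding appears as contiguous runs of elevated $M$ (domains, typically
tens of probes) and occasionally as short spikes (single peaks). Two
nuisance components sit on top: per-probe noise, and a smooth
intensity-dependent distortion $f(A)$ — the classic two-channel dye
bias — which LOESS normalization removes. A dye-swap technical
replicate has the two fluorophores exchanged, so its raw $M$ is
sign-flipped; the package negates it before normalization so all
replicates share one orientation, then combines replicates by per-probe
mean with a standard error.

## Normalization

`loess_normalize()` fits a robust local-linear regression of $M$ on
$A$ (tricube weights, span 0.3 — the span is not dictated by the
measurement, 0.3 is standard MA-normalization practice and is
configurable) and subtracts the fit. Bound probes are *one-sided*
outliers: a single robust fit downweights them but still leaks a few
percent of the domain effect into the trend when a sizable fraction of
the genome is bound. The fit is therefore refined once on the probes
lying within 2.5 MADs of the first fit and interpolated back to all
probes — an invariant-probe strategy that keeps the residual
out-of-domain trend within a few hundredths of a log2 unit under the
generator's default conditions (verified per A-decile in the test
suite). If the $A$ axis has essentially no spread (under ~0.01 log2
units) a local fit is meaningless and the global median of $M$ is
subtracted instead; this fallback is exact and is what the noise-free
validation path exercises.

Re-running the normalization on an already-normalized track is *not*
exactly the identity: the residual trend is re-estimated with
local-mean noise of order 0.01 at the default noise level. The test
suite pins this honestly (max change < 0.05, 99th percentile < 0.01)
rather than asserting an idealized fixed point.

## The domain caller

The caller is transition-based. With half-window
$h = (\text{window\_probes}-1)/2$ (default window 199 probes), the
edge statistic at probe $i$ is the difference of flanking half-window
means, center probe excluded:

$$e_i = \overline{M'}_{i+1..i+h} - \overline{M'}_{i-h..i-1}.$$

Scores are left undefined within $h$ probes of a chromosome end rather
than computed on truncated windows, avoiding edge-bias artifacts.
Candidate transitions are probes with $|e_i|$ above the threshold
(default 0.3 log2 units, applied to the raw edge score); non-maximum
suppression keeps one candidate per window and sign class.

**Boundary localization.** For a step at probe $k$ the maximum of
$e$ forms a plateau: $\{k-1, k\}$ when the enriched run is longer than
$h$, but a plateau of width $h-L+1$ when a domain of $L$ probes is
*shorter* than the half-window — and 199-probe windows are routinely
longer than real domains. Two choices make recovery exact at every
domain length:

1. ties are broken toward the *leftmost* maximum for up-transitions and
   the *rightmost* for down-transitions (direction-symmetric, so the
   transitions flank the enclosed probes), and
2. each detected transition is re-scored with the same statistic at a
   small half-window (`boundary_refine_probes`, default 10) within one
   detection window, which collapses the wide short-domain plateau to
   the probe adjacent to the true boundary.

Exact plateau ties are compared with a small numerical tolerance so
that floating-point rounding in the running sums cannot break them.
With detection at the full window and localization at the small one,
noise-free planted domains are recovered exactly (boundary probes
included), and at the default noise level (effect 1.0, noise 0.25, three
replicates) the mean boundary error is about half a probe.

Transitions are then paired — each up with the next down; an unpaired
trailing up closes at the chromosome's last probe and a leading down
opens at the first, both counted in the diagnostics as open-ended — and
a candidate is kept as a domain iff it encloses at least
`min_probes_per_domain` probes (default 3; the rule floor prevents
single-probe domains) **and** at least 70% of the enclosed probes have
a positive normalized ratio. Domain coordinates run from the start of
the first enclosed probe to the end of the last, and the score is the
mean normalized ratio.

The single-peak caller is an explicit extension (the domain model does
not cover short spikes): maximal runs of ≥ 2 probes strictly above the
per-chromosome 0.95 quantile of the ratio, excluding runs overlapping
called domains. On a constant track the quantile equals every value and
the strict inequality yields no peaks.

Thresholds (0.3, 70%) are exposed as configuration; the package does no
auto-tuning.

## Interval comparison and gene assignment

Two domain sets are compared under the 80% rule: a pair matches if at
least one interval has ≥ 80% of its length covered by the other
(`mode = "either"`, the default; `"reciprocal"` demands both).
Matching is one-to-one, greedy by largest overlap, ties toward the
leftmost interval. All coordinates are 0-based half-open.

No gene-assignment rule is dictated by the measurement, so the package
uses the transparent default of gene body plus a 2 kb strand-aware
promoter window (upstream of the transcription start; for minus-strand
genes that means higher coordinates), ≥ 1 bp overlap. Every downstream
bound-fraction number inherits this choice, which is why it is a
parameter object (`gene_assignment_params`) rather than a constant.

## Differential expression

`moderated_t_test()` implements the empirical-Bayes moderated t: the
per-gene pooled variance $s^2$ (on $d$ residual df) is shrunk toward a
prior,

$$\tilde s^2 = \frac{d_0 s_0^2 + d\, s^2}{d_0 + d},$$

with the moderated statistic referred to $t_{d_0+d}$. The prior
$(d_0, s_0^2)$ is estimated by method of moments on the log residual
variances (the estimator agrees with the established empirical-Bayes
fit to numerical precision, which the test suite cross-checks); both
hyper-parameters are overridable, and $d_0 = 0$ recovers the ordinary
pooled-variance two-sample t exactly. Tests are two-sided.

The significance filter keeps genes with p < 0.05 and a fold change of
2 or greater. Whether the 0.05 applies to raw or FDR-adjusted p is
genuinely ambiguous in array practice; the package filters on raw p by
default, always reports the BH q-value alongside, and exposes
`filter_on = "q"` — neither reading is asserted as canonical.

## Integration, profiles, motifs

Set overlaps are scored with the upper-tail hypergeometric test
(depletion behind a flag). The universe is the annotated gene set of
the analysis, never the genome; because enrichment p-values are
meaningless without knowing the universe, its size is carried in every
report. Direction fractions split bound-and-regulated genes into
factor-activated (down upon knockdown) and factor-repressed.

Meta-profiles align regions at center, start, or end (strand-aware for
genes) and average the normalized signal in 300 bp bins of
probe-center distance; probes straddling a bin edge are assigned by
their center, which is unambiguous. The SE is computed across probe
incidences by default; a per-region weighting mode is provided since
either convention is defensible. Chromatin-state summaries average the
signal per region and group by state label.

Motif analysis scans a degenerate IUPAC pattern (default CANNTG, the
HES/Hey-related E-box; it is reverse-complement symmetric, so forward
counting is complete — the dedup mode exists for asymmetric patterns).
Pattern N matches any base; an ambiguous *input* base matches nothing;
overlapping occurrences count. Enrichment is the ratio of mean per-kb
density in bound sequence versus generated random background (6000
sequences of 2–5 kb, GC 0.5 by default since real composition varies by
genome), with an empirical label-permutation p-value — a deliberate
choice of a self-contained statistic over any external motif-model
E-value, which depends on a tool-specific background model.

## Phenotype statistics

Published assays often print only "x% of n". `counts_from_percent()`
reconstructs counts in two modes — nearest integer, and the *full set*
of integers consistent with the printed percentage — so significance
claims can be checked under every consistent reading. Contingency
contrasts use Fisher's exact conditional test (two-sided by the
point-probability rule), appropriate for small counts without
asymptotic assumptions; the sample odds ratio is reported next to the
conditional MLE. G-TRACE lineage-tracing tables are reduced to the four
marker classes of polyploid cells (GFP±/RFP±). Survival tables get a
simple life-table summary — fraction surviving past a horizon
(individuals censored at or before the horizon leave the denominator)
and DT50, the first day cumulative deaths reach half the starting
cohort; no Kaplan–Meier machinery is built because the package only
needs these two summaries.

## The synthetic-data generator

The generator is first-class, tested code and defines the study
conditions everything else is validated against:

* grid: 2 chromosomes × 3 Mb, 300 bp spacing, 50 bp probes;
* 50 planted domains of 15–30 kb (50–100 probes — between a quarter and
  a half of the detection window, the demanding regime for boundary
  localization), log2 effect 1.0, per-probe noise 0.25 — a
  4-standard-deviation effect, realistic for a well-behaved DamID
  experiment;
* intensity model: per-probe baseline $A \sim N(11, 1)$ (NimbleGen-like
  intensities), channels split symmetrically around it, plus a
  half-sine intensity bias of amplitude 0.5 log2 units — smooth,
  non-linear, and entirely removable by a local fit;
* replicates: two biological plus one dye swap (exact channel
  exchange — the level at which the pipeline observes a dye swap);
* domains are snapped to probe boundaries (making exact recovery
  well-defined), kept 100 probes from chromosome ends (so edge
  statistics are defined across every planted boundary) and 100 probes
  apart (so flanking windows of neighbouring domains do not overlap);
* expression: 2000 genes, two groups × 3 replicates, log2 noise 0.25;
  70% of domains are linked to an overlapping gene; planted
  2-fold effects are distributed so that 35% of DE genes are
  domain-linked, and 70% of the bound DE genes are planted as
  factor-activated; unlinked genes are placed with a 2 kb clearance
  from domains so "unbound" is true under the default assignment rule.

Determinism is strict: one global seed, with per-stage seeds derived by
a stable hash of the stage name, so any stage reproduces in isolation.

What the generator does **not** emulate: sequence-composition probe
biases, spatial on-slide artifacts, correlated noise, fragment-level
GATC resolution, or RNA-seq counts. Passing the end-to-end tests
therefore demonstrates the correctness of the algorithms under the
stated model, not robustness to every artifact of real arrays.

## Numerical choices and degenerate inputs

* Intensities get a pseudocount of 1.0 before logging; a probe with
  both channels zero is flagged missing and excluded, never imputed.
* Probes missing in some replicates are averaged over the rest; a
  single available replicate has SE 0 by convention.
* A zero residual variance across all genes with zero differences is
  flagged non-significant with a warning; with non-zero differences it
  is an error (the statistic is undefined).
* The empirical permutation p is $(1 + \#\{\text{exceedances}\})/(B+1)$
  and can never drop below $1/(B+1)$.
* Validation problem sizes: the test suite and the acceptance script
  run the generator at its default scale (10,000–20,000 probes per
  simulation, 20 seeds for caller recovery and test calibration, 10 for
  false-discovery and integration checks, 100 trials for motif null
  calibration), chosen so the full suite completes in a few minutes on
  one CPU while keeping Monte-Carlo error well inside the asserted
  tolerances.

## Known limitations

* The 0.3 transition threshold is applied to the raw edge score; if a
  rescaled statistic is preferred the threshold must be rescaled with
  it.
* Nested or weakly-separated domains are merged by design: the pairing
  takes the first up-transition before the next down.
* Bound-fraction results depend on the gene-assignment window; there is
  no enhancer model.
* The hypergeometric universe must be stated by the caller; enrichment
  p-values are not comparable across different universes.
* The life-table survival summary ignores competing risks and does not
  test group differences; it only summarizes.
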