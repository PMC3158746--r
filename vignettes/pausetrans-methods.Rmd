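---
title: "Calling transcriptional pausing states and quantifying their transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling transcriptional pausing states and quantifying their transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pausetrans)
```

## The model

A protein-coding locus can initiate transcription without elongating it.
`pausetrans` classifies each locus into one of three states from two
orthogonal measurements:

* **initiation** — promoter H3K4me3 enrichment from a two-colour tiling
  ChIP array (H3K4me3 IP in one channel, pan-histone H3 IP in the other),
  probed roughly every 250 bp across ±4 kb of the transcription start
  site (TSS);
* **elongation** — full-length transcript detection on a 3′-biased
  (oligo-dT primed) bead expression array, judged against the array's
  negative-control probes.

The state is the conjunction of the two boolean calls:

| initiating | elongating | state |
|---|---|---|
| yes | yes | ACTIVE |
| yes | no  | PAUSED |
| no  | no  | SILENT |
| no  | yes | DISCORDANT |

The DISCORDANT cell (transcript without the initiation mark) is not part
of the three-state scheme; it is tracked explicitly so the logic is
total, and excluded from transition tallies by default
(`coerce_discordant = "exclude"`; `"active"` folds it into ACTIVE).
On real and synthetic data alike it is rare, because H3K4me3 detection
is the more sensitive of the two assays.

### The binding call

For each locus the probe-level signal is collapsed into a *metagene*:
log2((H3K4me3 + c)/(panH3 + c)) at each signed TSS offset (negative =
upstream, in the direction of transcription), with pseudocount `c = 1`
guarding against zero intensities.  Replicate arrays are averaged
probe-wise *before* the ratio.  The locus is called H3K4me3-bound if

* any point exceeds **1.5** log2 units at any offset, or
* any point exceeds **0.8** log2 units within **[−1250, +750]** bp of
  the TSS.

"Exceeds" is strict; the window endpoints are inclusive.  A "point" is
one probe's log-ratio — no smoothing, binning or interpolation is
applied, so the call is a pure threshold scan and is tested against a
brute-force point-by-point oracle.  The two-tier design reflects how
promoter-proximal nucleosomes carry the mark: a modest enrichment right
at the promoter is as informative as a strong one anywhere in the
tiled region.

### The transcript call

Each expression probe is compared with the sample's negative-control
intensity pool in a one-sided two-sample Student t-test (pooled
variance, probe mean above control mean), computed from bead summaries
(mean, SD, bead count).  A gene produces full-length transcript in a
condition when any retained probe reaches **p < 10⁻³** in any replicate
(both aggregation rules are configurable to `"all"`).  Separately,
probes whose detection score `1 − p` stays below **0.99** in *every*
sample of the study are discarded as never-detected; a gene losing all
its probes is called not-expressed with flag `"no_probe"`.

The pooled-variance (rather than Welch) form follows the named test;
detection is a one-sided question because only signal *above*
background is evidence of transcript.  With zero pooled variance the
p-value degenerates to 0.5 at equal means and to 0/1 on either side,
which keeps noise-free simulations well-defined.  Detection p-values
are computed on raw intensities; quantile normalization
(`quantile_normalize()`, delegated to `limma::normalizeQuantiles` with
tie averaging) equalizes between-sample distributions for reported
expression levels but plays no role in the detection decision,
mirroring the bead-array software's order of operations.

### Transitions

Between two populations there are nine ordered state pairs.  The six
changing ones group into four categories:

* **activation**: P→A, S→A — gaining productive elongation;
* **silencing**: A→P, A→S — losing it;
* **priming**: S→P — gaining initiation in anticipation of future
  expression;
* **archiving**: P→S — losing initiation as alternate lineages shut
  down.

S→A and A→S additionally carry a **direct** flag: they bypass the
paused intermediate.  `tally_transitions()` reports all counts, the
category shares among changing loci, and the share passing through
(versus bypassing) the paused state.  Percentages are rounded
half-to-even at one decimal, the reporting precision used throughout.

### The analyzed locus set

Only loci measurable on *both* platforms can be classified, so the
analyzed set is the intersection of loci with at least one ChIP probe
and at least one expression probe on the arrays.  Deliberately, a locus
whose expression probes are discarded by the never-detected filter
**stays** in the analyzed set (as not-elongating, flag `"no_probe"`):
roughly half the genome is paused or silent in any one population and
never yields transcript in a short two-population study, so
conditioning membership on detection would expel precisely the
paused/silent loci whose priming and archiving the analysis is about.

### Ontology profiles

`profile_terms()` restricts the genome-wide transition records to each
GO term's gene set (direct gene2go annotations only — no propagation up
the GO graph, no enrichment p-values; the readout is descriptive).  For
each term the key summary is the fate of its *paused-start changing*
loci: the percentage archiving (P→S) versus activating (P→A), on that
common denominator.  Terms for lineages being shut down archive; terms
for the lineage being entered activate — which is what makes the
paused-exit profile an early predictor of fate.

## The synthetic study

`simulate_study()` emulates both platforms from a known truth so every
stage is testable without downloads.  Defaults are chosen to look like
a pluripotent→mesoderm differentiation at desk scale:

* **2000 loci**, condition-1 states drawn A/P/S = 0.47/0.48/0.05;
* a transition matrix built (`default_transition_matrix()`) to yield
  ~12% changing loci with category shares
  activation/silencing/priming/archiving = .22/.17/.30/.31 and ~1%
  direct transitions;
* **ChIP**: 33 probes per locus at 250-bp spacing; initiating loci get
  a Gaussian log2-enrichment bump (height 2.0, SD 500 bp) centred on
  the TSS; log-ratio noise SD 0.3.  Channel intensities are
  back-computed so `build_metagene()` recovers the intended log-ratios
  exactly.  The margins make error rates analytically boundable: a
  silent locus needs a 2.7σ noise excursion on one of nine in-window
  probes to trip the 0.8 rule (~3% per locus, ~0.2% of all loci), while
  an initiating locus is essentially never missed;
* **expression**: one probe per locus, 30 beads, a 750-probe
  negative-control pool (mean 100, SD 10); expressed loci shifted +10
  control SDs, giving t ≈ 50 and detection power ≈ 1 against a ~10⁻³
  false-positive rate.  `expr_noise = 0` and `chip_noise_sd = 0` place
  every summary at its expectation for exact-recovery tests;
* **annotations**: three mesoderm-like terms drawing ≥80% of their ~60
  members from P→A loci, three ectoderm-like terms from P→S loci, two
  housekeeping terms from stable-ACTIVE loci, plus random background
  terms.

Every generator draws from its own sub-stream of the study seed, so
outputs are byte-identical across runs.  The peak shape, noise levels
and intensity scales are inventions of the generator — real promoter
arrays have dye bias, spatial artifacts, probe-affinity structure and
correlated backgrounds that it does not model — so passing recovery
tests demonstrates the correctness of the calling and tallying logic
under the stated signal model, not performance on raw array scans.

```{r example}
params <- sim_params(n_genes = 500, seed = 1)
study <- simulate_study(params)
res <- run_transition_analysis(study$tss, study$chip, study$expr,
                               gene2go = study$gene2go)
res
head(fate_report(res$profiles), 4)
```

## Numerical and design notes

* **Thresholds** (1.5, 0.8, window −1250..+750, p < 10⁻³, score floor
  0.99) are exposed in `chip_config()` / `expr_config()` but their
  defaults are the method's definition, not tuning knobs.
* **Ties and rounding**: percentages use half-to-even rounding at one
  decimal; fate-report ties are broken by term id for determinism.
* **Replicates**: ChIP replicate arrays are averaged probe-wise before
  calling (per-replicate calling available via
  `chip_config(average_replicates = FALSE)`); expression replicates are
  aggregated by the `replicate_rule` at call time, defaulting to the
  permissive `"any"`.
* **Degenerate inputs**: genes without probes are excluded from the
  analyzed set (ChIP) or flagged `"no_probe"` (expression); an
  all-stable cohort reports NA category percentages rather than 0/0;
  DISCORDANT transition inputs yield an NA exclusion signal, not an
  error.
* **Problem sizes**: tests and the acceptance script use 300–2000-locus
  studies and 10⁵-profile oracle comparisons, sizes at which every
  property being asserted is already fully exercised.

## Limitations

The package starts from probe-level tables; it does not process raw
Agilent feature-extraction or Illumina IDAT files, call peaks on
genome-wide tiling data, model dye bias, or assign probes to promoters
(a nearest-TSS single assignment is assumed upstream).  It compares
exactly two populations per run — multi-stage paths are a sequence of
pairwise runs — and performs no statistical testing of distribution
differences or GO enrichment.
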