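---
title: "Cross-species expression analysis with orthologous probe selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species expression analysis with orthologous probe selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoarray)
```

## The problem

Short-oligonucleotide expression arrays interrogate each transcript with a
probe set of (typically eleven) 25-mer perfect-match (PM) probes, each
paired with a mismatch (MM) probe that differs only at base 13. Because
many 25-mers are conserved between related species, an array designed for
one species can measure orthologous transcripts of another: probes whose
sequences still match the target species' cDNA are kept, the rest are
discarded, and the surviving probes are reassembled into a custom library
file — a "virtual array" for the target species. Expression estimates
recomputed against that library let one transcriptome (say, treated rat
hepatocytes) be read as if it had been hybridized to the other species'
array, which is useful when the corresponding human in vitro system is
unreliable (primary hepatocyte cultures lose liver-specific expression and
respond weakly to PPAR&alpha; agonists).

orthoarray implements that workflow end to end: sequence-level probe
matching, specificity filtering, library construction, RMA expression
estimation, neural-network transcript ranking, marker-interaction scoring,
and hypergeometric gene-set enrichment, plus a synthetic-data generator
with planted ground truth that every stage is validated against.

## Probe matching

Each PM probe is compared against every transcript of a target-species
cDNA database, in both orientations by default (probe/target strand
conventions vary between probe-table exports; a flag restricts the search
to the given orientation). A match is classified by the longest contiguous
exact run ("core") of the 25-base alignment window:

* **EXACT** — all 25 bases match.
* **END_MM** — core of at least 23 bases; the one or two
  (`max_end_mismatch`) mismatching bases necessarily flank the core at the
  probe ends.
* **TANDEM** — core of at least `min_tandem` (default 20) bases anywhere
  in the probe.
* **RESCUE** (opt-in) — at most `rescue_max_end_mismatch` (default 9)
  mismatches, all outside the core, so a core of at least 16 bases. This
  tier automates what would otherwise be a manual salvage of probe sets
  failing the standard criteria; it is off by default so the headline
  pipeline remains strict and deterministic.

"Terminal" mismatches are defined relative to the longest core: a
mismatch before the core start or after the core end. Transcript `N`
bases match nothing, which conservatively prevents ambiguity codes from
producing spurious orthologs.

The search is seed-and-extend over a k-mer hash index. The seed length is
derived as the shortest core any enabled tier can require — at defaults
`min(min_tandem, 25 - max_end_mismatch) = 20`, shrinking to 16 when the
rescue tier is enabled — which guarantees completeness: every qualifying
hit contains at least one indexed seed. (Deriving k purely from
`min_tandem` would lose END_MM hits if `min_tandem` were raised above 23,
so the derivation also caps at `25 - max_end_mismatch`.) A quadratic
reference scanner with independently coded classification
(`find_hits_bruteforce()`) ships with the package; the test suite asserts
exact hit-set equality between the two paths on dozens of randomized
fixtures, and both emit rows in the total order (probe, transcript,
offset, strand) so outputs are byte-reproducible.

## Library construction

Per probe set, the specificity rules are applied in a fixed order: probes
hitting two or more genes are dropped (a probe hitting several transcripts
of *one* gene is still specific — cDNA databases are redundant per gene);
the set is assigned to the gene with the plurality of surviving probes
(ties: higher summed tier rank, then smallest gene id); probes pointing at
other genes ("intermingling" probes) are dropped; sets with fewer than
three surviving probe pairs are rejected. Remaining redundancy is then
collapsed to exactly one probe set per gene (most probes, then summed
tier rank, then smallest id), giving the library its one-to-one probe-set
to gene structure. Every elimination is recorded with a reason code
(`NO_HITS`, `MULTI_GENE`, `MIN_PROBES`, `REDUNDANT`) so the attrition
ledger always satisfies kept + rejected = input.

All tie-breaks are deterministic and documented, because the original
procedure resolved such cases by manual inspection and a reusable tool
cannot. The library is serialized as schema-versioned JSON (canonical)
with an optional CDF-like text export; MM probes ride along with their PM
partner by position and are never matched independently.

## Expression estimation (RMA)

Intensity data is bound to a library explicitly at call time
(`remap_intensities(cels, library)`); any library name embedded in a CEL
header is ignored. This replaces the historical trick of editing CEL
headers to retarget vendor software at a custom library — same effect,
no file mutation, directly testable.

The RMA implementation is from scratch and PM-only:

1. **Background correction.** Observed intensity = exponential signal
   (mean `alpha`) + normal noise (`mu`, `sigma`); the correction returns
   the posterior mean E(signal | observed), computed through a log-space
   Mills ratio so deep-background values stay finite and strictly
   positive. Parameters are estimated per array with fixed, simple rules:
   `mu` is the mode of a kernel density (bandwidth rule `nrd0`,
   configurable), `sigma` the root-mean-square deviation of the sub-mode
   half times sqrt(2), `alpha` the mean excess above the mode. Parameters
   are estimated from **all** grid cells — unassigned cells and MM probes
   supply the background population, as in whole-chip RMA practice —
   while the correction itself applies to the analysis probes. The
   estimator is validated against numerical integration of the posterior,
   not against any particular legacy implementation.
2. **Quantile normalization** across arrays over the library's PM probes
   (a flag switches to the whole grid, under which an identity library
   reproduces the whole-chip pipeline exactly). Ties within a column
   receive the mean of the reference quantiles they span — stated
   explicitly because implementations differ. A toggle disables
   normalization altogether: forcing identical distributions is exact
   only when group distributions genuinely coincide, and the noiseless
   sanity checks in the test suite use that mode.
3. **log2**, then **median polish** per probe set (row-first sweeps;
   convergence when the total absolute residual changes by less than
   `mp_tol` = 0.01 between sweeps, at most `mp_max_iter` = 10 sweeps);
   the per-sample estimate is overall + column effect.

## Transcript ranking with neural networks

Samples are labelled 0 (control) / 1 (treated). For each transcript
independently, small feed-forward classifiers — one input (the
transcript's min-max-scaled expression), two sigmoid hidden units, one
sigmoid output — are trained under repeated random stratified 60/20/20
train/validation/test splits ("random sample cross-validation", 50
resamples by default). Training is full-batch gradient descent
(learning rate 0.1, momentum 0.9) with early stopping once the validation
error has not improved for `patience` = 25 cycles (at most 300); the test
squared error at the best-validation snapshot is recorded, and the
transcript's score is the mean over resamples. Ascending scores give the
ranking; the top 100 feed the interaction analysis. Single-input models
are used because the stepwise approach treats each transcript as not
initially interacting with any other; the stopping rule reads "fails to
improve", with the literal "fails to increase" reading available as a
config option. Split sizes follow largest-remainder rounding within each
class, so they are a deterministic function of the fractions.

Every (transcript, resample) pair derives its own RNG stream from the
master seed, the transcript's row index, and the resample index, so
rankings are byte-reproducible and appending transcripts never perturbs
the scores of existing ones. The hidden-layer size, learning rate,
momentum and resample count are design choices of this package — the
approach we follow does not pin them — and all are exposed in
`ann_config()`.

For marker interactions, a network predicts each top-ranked marker from
the remaining ones (all samples, no held-out data, best-training-error
snapshot within 300 cycles); the influence of marker i on marker j is the
mean over samples of the signed partial derivative of the output with
respect to input i — the simplest faithful formalization of weight-based
influence analysis. The 10 most positive and 10 most negative entries
form the reported edge list. Constant markers are zeroed with a warning.

## Fold changes and enrichment

Fold changes use the signed convention standard in toxicogenomics
reporting: with r = 2^(mean log2 treated − mean log2 control), FC = r if
r ≥ 1 and −1/r otherwise, so values never fall in (−1, 1). The
differential threshold is deliberately a **required** argument of the
pipeline driver (default |FC| ≥ 2 only at the function level): the
original analysis does not state its cutoff, and a silent default in a
publication pipeline would be worse than an explicit choice.

Enrichment of the differential genes in user-supplied GMT gene sets uses
the hypergeometric upper tail P(X ≥ k), accumulated in log space, against
a background defaulting to the genes represented in the library (the
proprietary pathway database used originally is replaced by GMT input).
Multiplicity is controlled with Benjamini–Hochberg step-up adjustment —
the original states only "false discovery corrected", so the procedure is
fixed here and isolated behind `bh_adjust()` should an alternative ever
be wanted. Significance is FDR < 0.05.

## The synthetic-data generator

`fixture_spec()` defines a complete synthetic study; every artifact is a
pure function of it (same spec, same bytes). The default design mirrors
an 18-sample hepatocyte treatment study — 6 vehicle controls and 12
treated samples (3 replicates × 2 time points × 2 dose levels) — with
probe sets of 11 PM/MM pairs.

The transcriptome is random sequence, 1–3 transcripts per gene sharing a
core, screened so no 20-mer (either strand) is shared between genes:
planted probes are then provably specific to their gene. Probes are
copied from disjoint windows of their target transcript and mutated per
their planted tier (verbatim; both ends flipped; bases 2 and 24 flipped
leaving a 21-base run; four bases flipped at each end leaving a 17-base
core; copied into a second gene behind an N spacer; or rejection-sampled
to share no 16-mer with the transcriptome at all, so clean negatives stay
negative even under the rescue tier). Tier counts follow
largest-remainder rounding of the tier mix and are dealt round-robin so
every probe set has at least three good probes under the default mix.

Intensities follow log2 I = probe affinity + gene expression + noise,
exponentiated, plus an additive optical background on the linear scale
(mean 32, SD 8) applied to every cell — scanners add such a floor, and it
gives the background-correction stage a real quantity to remove. Gene
baselines are uniform on log2 6–10; planted differential genes (10 of
200 by default, i.e. a 5% differential fraction consistent with
quantile normalization's assumption that most genes are unchanged) carry
a ±2 log2 class effect with alternating sign. Defaults `noise_sd` = 0.25
and `probe_affinity_sd` = 1.0 are the study conditions the recovery tests
run at. A separate expression-level generator
(`simulate_ranking_matrix()`) produces the ranking benchmark: 2000
transcripts × 18 samples with 20 informative transcripts shifted by 2 SD.

What the generator does **not** emulate: hybridization physics and
saturation, probe GC/sequence affinity bias, spatial artifacts, batch
effects, and cross-hybridization gradients. Passing the recovery tests
therefore shows the algorithms are implemented correctly under the
declared generative model, not that real arrays will behave this well.

## Numerical and design notes

* Probe grid coordinates are 0-based (x = column, y = row), matching the
  text CEL convention; only the ASCII version-3 CEL dialect is supported,
  and binary CEL files are rejected with a clear message.
* A FASTA gene mapping may come from `gene=` header tags or a two-column
  TSV; the explicit TSV wins on conflict.
* `END_MM` allows mismatches at both ends simultaneously (the
  single-ended reading is expressible by lowering `max_end_mismatch`).
* Degenerate inputs have defined behaviour rather than errors where the
  result is still meaningful: constant intensity columns fall back to
  min-subtraction with a warning, single-column quantile normalization is
  the identity with a warning, constant markers yield zero interactions.
* Probe-set rejections are data (reason-coded records), never exceptions;
  exceptions are reserved for corrupt inputs (duplicate coordinates,
  unmapped transcripts, grid mismatches).
* The pipeline driver (`run_pipeline()`) derives one seed per stochastic
  stage from the master seed by stage name, writes a manifest of input
  and output content hashes, and sets the library's `created` field from
  the input hashes rather than the wall clock, so a rerun of the same
  configuration reproduces every artifact byte-identically.
* Test and validation problem sizes are chosen to exercise the documented
  claims at realistic dimensions while keeping the full suite quick on a
  single CPU: 50 randomized matcher fixtures of 50 transcripts × 400 nt
  with 500 probes; 100 random 11 × 18 median-polish matrices; 200
  random draws for the background quadrature check; the full 2000 × 18
  ranking benchmark with 50 resamples; and an end-to-end run at the
  200-gene defaults.

## Known limitations

* The matcher is ungapped by design: orthology tiers are defined on
  contiguous identity, not alignment score; no E-values are computed.
* The plurality-gene formalization of "intermingling" elimination is one
  consistent reading of a procedure that was originally partly manual.
* Exact agreement with any particular legacy RMA implementation is not a
  goal; the acceptance surface is oracle agreement (quadrature, reference
  median polish, quantile-normalization exactness) and invariants.
* The hierarchical-clustering heatmaps of the original workflow are
  deliberately out of scope; any standard clustering tool applies to the
  exported expression matrix.
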