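---
title: "Calling direct transcription-factor targets: methods and design notes"
author: "tfscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling direct transcription-factor targets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfscreen)
```

## The problem

A transcription factor (TF) that binds DNA may regulate hundreds of genes,
but ChIP-seq alone shows only binding and RNA-seq alone only expression
change. The standard screen for *direct* targets intersects the two: a gene
is a candidate direct target when (a) the TF binds near its transcription
start site (TSS) and (b) the gene's expression responds to perturbing the
TF, in the direction consistent with regulation. `tfscreen` implements this
intersection as a reusable, tested pipeline, together with the quantitative
machinery used to follow up a called target at the bench: core-motif
scanning of promoters and EMSA probes, ChIP-qPCR tiling design and
percent-input enrichment, and Chou–Talalay drug-synergy analysis for
therapeutically targeting the axis the screen uncovers.

## The core procedure

1. **Peak-to-TSS annotation.** Each gene's TSS is the first transcribed
   base (interval start on `+`, `end − 1` on `-`). Peak positions are
   reduced to an anchor — the reported summit when the peak caller emitted
   one, otherwise the interval midpoint `floor((start+end)/2)`; a
   `nearest_edge` anchor is also available. Distances are signed in gene
   orientation (negative = upstream).
2. **DEG selection.** A gene is differentially expressed when
   `|log2FC| > 0.585` (that is, a > 1.5-fold change, since
   `log2(1.5) = 0.585`) and adjusted P `< 0.05`. Both inequalities are
   strict, so boundary genes are excluded; the partition up/down/unchanged
   covers the table exactly.
3. **Integration.** A gene is a candidate iff at least one peak anchor lies
   within the TSS window (default 5000 bp, boundary inclusive) *and* the
   gene is in the up or down set. The direction of change is read through
   the perturbation design: under knockdown, down-regulated bound genes are
   *transactivated* targets and up-regulated ones *repressed*; under
   overexpression the mapping mirrors. `keep = "transactivated"`
   reproduces the final filter of an activation screen.

### Design choices in the core

* **Symmetric window.** "Within 5000 bp of the TSS" is read as
  `|distance| ≤ 5000` on either side. ChIP-qPCR tiling conventionally
  covers only the upstream −5000..0 region, so an upstream-only promoter
  mode is provided, but the symmetric reading is the default for candidate
  calling.
* **Many-to-many candidacy.** For calling, every gene within the window of
  a peak is credited with that peak — a bound gene is never missed because
  a neighbour's TSS is nearer. The single-gene assignment (smallest
  `|distance|`, ties by lexicographic `gene_id`) is used only for the
  feature-class summary, where each peak must land in exactly one of
  promoter > exon > intron > intergenic.
* **Coordinates.** Everything internal is 0-based half-open; GFF3 is
  converted at the boundary and BED passes through. One convention
  eliminates off-by-one drift between modules. Chromosome names are
  matched as exact strings — no silent "chr" aliasing.
* **Ranking.** Candidates are ordered by (regulation, min `|TSS
  distance|`, gene_id). The ranking is a presentation convenience; the
  screen's output is the candidate *set*, which bench validation then
  prunes.
* **Universe mismatches.** DE genes absent from the gene models are
  dropped at integration with a message (selection itself is
  annotation-independent); bound genes without a DE record are reported in
  a separate "bound, not assayed" list rather than silently vanishing.

## Validation-assay arithmetic

**Motif scanning** is exact IUPAC-consensus matching (via Biostrings), with
reverse-complement hits reported on the `-` strand at forward coordinates
and `N` in the scanned sequence never matching. The canonical example is
the TTTCCT core recognition motif: the wild-type EMSA probe carries exactly
one copy (position 11), while the binding-dead mutant probe carries none —
which is precisely why the mutant fails to compete in a shift assay.

**Tiling windows** partition a TSS-relative region into left-aligned,
non-overlapping amplicon windows (last one truncated). The −5000..0
promoter region at the default 500 bp yields the familiar ten primer-pair
tiling.

**Percent input** uses the dilution-adjusted form
$\%\mathrm{input} = 100 \times 2^{(Ct_{input} - \log_2(1/f)) - Ct_{IP}}$,
where $f$ is the input fraction (default 1%). The two textbook variants
differ only in where the dilution factor enters; this form is pinned down
by its fixed point (adjusted input Ct equal to IP Ct gives exactly 100%)
and unit-tested there, and is invariant to a common shift of both Ct
values. Antibody/IgG fold enrichment is the ratio of percent inputs and
algebraically equals $2^{\Delta\Delta Ct}$.

## Median-effect and combination index

Single-agent dose–response is modelled by the median-effect equation
$f_a/(1-f_a) = (D/D_m)^m$, fitted as a least-squares line through
$(\log_{10} D,\ \log_{10}(f_a/(1-f_a)))$; $m$ is the slope, $D_m =
10^{-b/m}$ the median-effect dose (the IC50), and $r$ the correlation of
the linearised points. `median_effect()` returns a classed fit with
`print`, `summary`, `coef`, `predict`, `plot` and `residuals` methods —
the one place in the package where the classic R modelling idiom genuinely
fits.

The combination index of a measured combination $(d_1, d_2)$ producing
effect $f_a$ is $CI = d_1/D_{x1}(f_a) + d_2/D_{x2}(f_a)$, evaluated at the
combination's *observed* effect level (the constant-ratio convention); a
fixed-`fa` grid is available for isobolograms. CI < 1 is synergism, = 1
additive, > 1 antagonism; because CI is a continuous estimate, the
classifier applies a tolerance band `1 ± ε` with `ε = 0.05` by default
(`ε = 0` restores the strict trichotomy).

Numerical edges: fractions affected exactly 0 or 1 — routine in viability
assays — are clamped to `[1e-4, 1 − 1e-4]` with a warning (strict mode
rejects), because the linearisation is undefined at the boundary. Fits
need ≥ 3 points and ≥ 2 distinct doses. CI is invariant under per-drug
dose-unit rescaling, which the tests assert.

## Small-sample statistics

`fisher_exact_2x2()` enumerates all 2×2 tables with the observed margins.
The two-sided p follows the point-probability convention (sum of
hypergeometric probabilities no larger than the observed table's, compared
with relative tolerance 1e-7 against floating-point ties); this is the
convention under which the 9/11-vs-4/13 incidence table yields p = 0.019.
The "doubling" convention is offered as an option. The enumeration is
cross-checked in the tests against both an independently written
`choose()`-based oracle and `stats::fisher.test`. Pearson correlation is a
validated wrapper over `stats::cor`; the upregulation proportion rounds
half-up to one decimal (so 98/151 prints as 64.9); tumor volume is the
caliper formula $l \times w^2/2$ with a warning when width exceeds length.

## What the synthetic data emulate — and what they do not

The generator plants ground truth at the study's own scale: by default 100
non-overlapping genes on a 5-Mb chromosome, 5 transactivated + 3 repressed
targets, one peak per target with its summit uniform within ±2000 bp of
the TSS, 200 background peaks kept ≥ 10 kb from every TSS, target effects
of |log2FC| = 1.0 with significant adjusted P (uniform in [1e-6, 0.01])
and null genes at `N(0, 0.2)` with padj uniform in [0.05, 1]. Dose–response
curves are drawn from the median-effect equation with log10-odds Gaussian
noise (σ = 0.1 in the stochastic suites). These sizes keep the full test
suite and the acceptance script comfortably fast while leaving the
planted structure unambiguous: with zero noise, sensitivity and
specificity are exactly 1 for any window at or above the planting
half-width, which is the pipeline's primary regression test.

Real data differ in ways the generator deliberately does not model: peaks
have irregular shapes and co-occur with open chromatin rather than being
uniform intervals; DE effect sizes and adjusted P values come from a count
model with mean–variance structure, not from stated ranges (DE model
fitting is out of scope — the pipeline consumes any engine's table);
background binding is enriched in promoters of *non*-responsive genes,
which the "decoy-free" background here idealises away. Passing the
recovery suites therefore certifies the *logic* of the intersection, not
performance on noisy genomes.

Determinism: one study seed fans out to fixed per-component substreams
(labelled genome/truth/peaks/de/dose), so regenerating one file never
perturbs another, and identical seeds give byte-identical files and run
reports (timestamp aside). `padj` values are assigned directly from the
stated ranges rather than simulated through a DE fit, since integration
consumes only (log2FC, padj).

Gene placement samples lengths first and then distributes the remaining
slack uniformly at random between genes — the uniform distribution over
non-overlapping arrangements — rather than rejection-sampling positions,
so generation never stalls at high densities.

## A worked example

```{r example}
sim <- simulate_study(file.path(tempdir(), "demo"), seed = 7,
                      config = list(effect_sd = 0, null_sd = 0,
                                    logit_noise_sd = 0))
rep <- run_pipeline(sim$paths$genes, sim$paths$peaks, sim$paths$deg)
rep
all(sort(rep$candidates$gene_id) == sort(sim$truth$gene_id))
```

```{r synergy}
dr <- sim$dose_response
fit1 <- median_effect(fa ~ dose, dr$drug1)
fit2 <- median_effect(fa ~ dose, dr$drug2)
coef(fit1); coef(fit2)
head(ci_table(dr$combos, fit1, fit2))
```

## Interfaces and limitations

The exported functions are the interface: `run_pipeline()` orchestrates
annotate → select → integrate from one parameter source (argument >
config list/YAML > defaults 0.585/0.05/5000 bp/knockdown) and emits a JSON
run report with the stage-by-stage funnel; `simulate_study()` writes a
complete input set plus truth JSON. The package does not call peaks, fit
DE models, align reads, discover motifs de novo, or model tumor growth
curves; per-transcript (vs per-gene) annotation and UTR/TTS feature
classes are likewise out of scope. The Fisher enumeration is exact and
intended for bench-scale tables (totals in the hundreds at most), not as a
replacement for asymptotic tests on large contingency tables.
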