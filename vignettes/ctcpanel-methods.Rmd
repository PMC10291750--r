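---
title: "Models and methods behind ctcpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ctcpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcpanel)
```

## The measurement problem

Circulating tumor cells (CTCs) are rare tumor-derived cells in peripheral
blood. Microfluidic capture devices enrich them by size and deformability,
but every harvest also carries hundreds to thousands of contaminating white
blood cells (WBCs). A multiplexed chemiluminescent array assay quantifies
~70 tumor-marker transcripts plus the pan-leukocyte marker PTPRC (CD45) from
such harvests, down to the RNA content of a single cell (~20 pg of total
RNA). The analytical challenge is to decide which probes report CTCs rather
than the fluctuating leukocyte background, and to use those probes to
separate patients with CTCs from healthy controls.

`ctcpanel` implements that analysis as a tested pipeline, together with a
calibrated simulator that reproduces the statistical structure of the assay
so every stage can be exercised against known ground truth.

## Signal model

Each probe's expected chemiluminescent intensity for a sample is linear in
its RNA inputs,

$$\mu = b + \sum_c \beta_c \, x_c + \gamma \, w,$$

with baseline $b$ (signal units), per-cell-line response rates $\beta_c$
(units per pg of total RNA), WBC response $\gamma$ (units per ng of WBC
RNA), cell-line amounts $x_c$ in pg and WBC load $w$ in ng. Tumor-cell
counts convert at 20 pg per cell. The detector saturates; we model this as
the smooth bounded map

$$S\left(1 - e^{-\mu/S}\right),$$

which is within 1% of $\mu$ below $0.01\,S$ and approaches the ceiling $S$
from below. The instrument's saturation onset is not published per probe,
so ceilings are simulator configuration recorded in the truth output (a
hard clip is available via `saturation = "clip"`). The smooth form keeps
titration regressions well behaved near the top of the dynamic range.

Replicate spots carry independent multiplicative lognormal noise:
$y = \mu\, e^{\varepsilon}$, $\varepsilon \sim N(0, \sigma^2)$ with
$\sigma = 0.25$ by default. Under this choice the probability that two
replicate spots agree within two-fold is
$2\Phi\!\left(\ln 2 / (\sqrt{2}\,\sigma)\right) - 1 \approx 0.95$,
matching the observed "up to two-fold" replicate spread of the assay. Each
probe is printed in triplicate and the reported probe value is the median
of the evaluable spots, which shrinks the effective probe-level log-noise
to about $0.67\,\sigma$.

Seeding is hierarchical: one parent seed spawns a deterministic child
stream per sample (hashed from the sample id), so subsetting a design never
reshuffles the remaining samples.

## From spots to net signal

`summarize_spots()` takes the median over evaluable spots;
`net_signal()` subtracts, per probe, the median over the nine no-template
control (NTC) samples. Negative net values are retained — flooring them
before the titration regressions would bias slopes — and are floored at 1
unit only inside log transforms (so floored background maps to
$\log_2 1 = 0$). Sample QC checks every synthetic-mRNA and hybridization
control probe against configurable limits; the vendor's acceptance metrics
are unpublished, so defaults derive from the panel's expected control
intensities (positive minimum = expected/5).

## Titration screening

For each gene and cell line, the net signal is regressed on the RNA amount
(20–100 pg; the 0 pg samples serve as NTCs and are excluded). The slope and
intercept come from ordinary least squares on the per-amount means; the
correlation coefficient and its two-sided t-based p-value are computed on
the replicate-level points. That replicate-level reading matters: with five
amounts in triplicate, $n = 15$, and $r > 0.65$ then implies $p < 0.05$,
whereas at $n = 5$ it would not.

A probe is *informative* when slope $> 1$ unit/pg **and** $r > 0.65$
(strict inequalities) for at least one cell line; a slope above one means a
single cell (~20 pg) produces ~20 net units. The limit of detection is the
classic three-sigma form $\mathrm{LOD} = k\,\mathrm{SD_{NTC}}/\text{slope}$
with $k = 3$; the assay's own LOD formula is not published, so $k$ is
exposed and reported with results.

## Marker-selection tiers

1. **WBC background** (`wbc_background_screen`): in a constant 1 ng WBC
   background, keep genes that remain responsive (slope above threshold,
   LOD below 20 pg) *and* whose 20 pg samples differ from WBC-only
   replicates by an equal-variance Student t-test at $p < 0.05$.
2. **Spiked harvests** (`spike_screen`): on harvests with variable WBC
   load, keep genes with a $\ge$ 2-fold mean difference between some spiked
   group and the unspiked group at $p \le 0.1$. The phrase "p between 0.05
   and 0.1" in the source analysis describes the p-values observed for the
   chosen genes; we read the rule as $p \le 0.1$, with a banded mode
   (`p_band = TRUE`) for the alternative reading. Fold denominators are
   floored at 1 unit to avoid dividing by near-zero net signals.
3. **PTPRC deconfounding** (`ptprc_regression`, `rank_genes`,
   `exclusive_markers`): because patient harvests carry systematically more
   WBCs than control harvests (the simulator's default MBC/HV WBC-load
   factor is 2.3), any WBC-expressed gene shows a spurious case/control
   difference. Each gene is regressed ($\log_{10}$–$\log_{10}$) on PTPRC
   using only samples above the 10-unit expression threshold, and genes are
   ranked by ascending slope. Genes with fewer than three samples above
   threshold have no meaningful slope and rank first, ordered by
   above-threshold count then id — mirroring the observation that negative
   or undefined slopes at the top of such rankings simply reflect sparse
   expression. The exclusivity rule then keeps genes above threshold in at
   least one case sample and at most `hv_tolerance` (default 0) control
   samples. No multiple-testing correction is applied anywhere, matching
   the source analysis; this is recorded in the report metadata.

The 10-unit threshold is an assay-scale constant: roughly three standard
deviations of NTC background at the default noise, and half the signal a
single cell produces through a slope-1 probe.

## Multivariate recipes

`transform_expression()` applies the figure-style recipe (log2 with floor
1, per-probe centering, optional per-probe scaling; zero-variance probes
become all-zero and are flagged). Distances are either Euclidean or
$d = 1 - \tau_b$ with tie-corrected Kendall $\tau_b$ (computed via
`stats::cor`), which is invariant under monotone transforms and lies in
$[0, 2]$ — the tie correction matters because flooring produces many ties.

Agglomeration is implemented directly with Lance–Williams Ward updates:
`ward_d` applies the update to the dissimilarities as given, `ward_d2` to
their squares (with square-root heights). We implement the loop ourselves
rather than calling `stats::hclust` because the pipeline's contract fixes a
deterministic tie-break — among equal-distance pairs, merge the pair
containing the smallest original leaf index — making results invariant to
sample order; `hclust` leaves tie order unspecified. The implementation is
cross-checked in the test suite against `stats::hclust` (cophenetic
equality on tie-free inputs) and against an exhaustive
error-sum-of-squares merge oracle. PCA is `stats::prcomp`.

## The simulator as study design

Defaults encode the study conditions end to end:

| parameter | default | rationale |
|---|---|---|
| amounts | 20, 40, 60, 80, 100 pg | titration design; 20 pg ≈ one cell |
| replicates | 3 | assay run in triplicate |
| spots/probe | 3 | triplicate printing |
| NTCs | 9 | background-subtraction design |
| `noise_sigma` | 0.25 | ~95% of spot pairs within two-fold |
| WBC background | 1 ng | ~50-fold excess over one cell's RNA |
| cohort | 15 HV / 15 MBC | clinical comparison size |
| `p_ctc_negative_mbc` | 0.35 | fraction of MBC patients without CTCs |
| `wbc_fold_mbc` | 2.3 | MBC/HV PTPRC (WBC-load) ratio |
| `marker_positivity` | 0.25 | heterogeneous marker expression |
| PTPRC rate | 1000 units/ng | with lognormal loads (sdlog 0.6) this spans net intensities of roughly 300–11000 across a cohort |
| tumor burden | 1 + Poisson(2) cells | a few CTCs per positive patient |
| baseline | 20 units | NTC-scale background |

The simulator emulates linear per-gene responses, saturation, replicate
noise, heterogeneous marker positivity and variable WBC contamination. It
does **not** emulate amplification competition between targets, probe
cross-hybridization, batch effects, RNA degradation, or correlated noise
between genes of a sample. Passing tests therefore demonstrate that the
analysis recovers what it claims under the assay's published statistical
structure — not that any particular clinical dataset will behave as well.

## Numerical choices and degenerate inputs

* Constant titration responses report slope 0, $r = 0$, $p = 1$ rather
  than `NA`, so screens treat dead probes as uninformative, not missing.
* LOD is $+\infty$ for non-positive slopes; such probes are flagged
  undetectable and excluded from finite-LOD summaries.
* Fold-change denominators and log arguments are floored at 1 unit.
* Ties in agglomeration break by smallest leaf index; ranking ties break
  by above-threshold count then gene id. All orders are total and
  deterministic.
* Missing cells (failed QC, no evaluable spots) are dropped pairwise per
  fit with the effective n recorded.

## Primer/probe design rules

The design module reproduces the assay's multiplex constraints over
transcript sequences: ~150 nt amplicons (±10) with GC in [0.45, 0.55];
gene-specific primers of 22–38 nt chosen to a 60 °C nearest-neighbor
melting temperature (SantaLucia 1998 unified parameters, 50 mM Na⁺,
250 nM oligo, entropic salt correction) with at most 3 °C between the pair;
a restricted two-letter 3'-end alphabet on forward primers (a preference —
the rule holds "when possible" — enforceable via
`require_three_prime = TRUE`); at least one primer crossing an exon
junction (≥5 nt overhang per side) on multi-exon transcripts; no
self-complementary stem longer than 6 bp (loop ≥ 3 nt) in the tailed
primers — a combinatorial base-pairing screen, deliberately simpler than a
thermodynamic fold, sufficient for a go/no-go rule; no exact 15-mer shared
with other panel transcripts on either strand; and a 25 nt probe centered
in the amplicon with Tm within 5 °C of target. Universal tails are the
assay's fixed forward/reverse/blocker sequences. Every emitted candidate
re-validates against all enabled checks, and coordinates are 0-based
half-open throughout.

## Problem sizes

The test suite and the acceptance script run at the sizes the analyses are
defined at: 72-probe panels, five cell lines, five amounts in triplicate,
100 simulated 15 + 15 cohorts, 10⁵ replicate-pair draws for the noise
calibration, and sub-kilobase design fixtures. A full run of both completes
in a couple of minutes on one core.

## Known limitations

* The LOD constant $k$ and the instrument's spot-evaluability rule are not
  published; both are configuration, and absolute LODs should not be
  compared against instrument-reported values without matching $k$ and the
  noise estimator.
* The hairpin screen counts base pairs, not free energy; G-U wobbles and
  bulged stems are out of scope.
* Cross-homology is exact k-mer sharing within the supplied panel, not a
  transcriptome-wide alignment search.
* The cohort simulator draws marker expression independently per gene and
  patient; real CTC phenotypes are correlated across markers.
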