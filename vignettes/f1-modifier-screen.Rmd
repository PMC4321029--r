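---
title: "Scoring a one-generation dominant modifier screen"
author: "f1screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring a one-generation dominant modifier screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(f1screen)
```

## The screen and its statistic

`f1screen` analyzes a one-generation (F1) dominant modifier screen built on
a Gal4/UAS/Gal80 balancing trick in *Drosophila*. A stable master stock
carries a muscle Gal4 driver, a UAS oncogene (PAX7-FOXO1), and a
Gal4-inhibiting Gal80 transgene on the X chromosome. When the stock is
outcrossed, every F1 female inherits the Gal80 X and is a phenotypically
wild-type control, while every F1 male expresses the transgene. Transgene
expression is semilethal at the chosen rearing temperature, so the fraction
of males among scored F1 adults is a per-line viability read-out: without
modification it averages 22% instead of the Mendelian 50%.

For a line with $M$ F1 males and $F$ control females,

$$\mathrm{pct} = 100\,\frac{M}{M+F}, \qquad
  \mathrm{fold} = \frac{\mathrm{pct}}{22}.$$

A deficiency (heterozygous deletion) is called a **suppressor** when its
display-rounded fold change is $\ge 1.9$ and an **enhancer** when it is
$\le 0.5$; these fixed cutoffs correspond to one standard deviation above
and below the screen mean (mean 26%, SD 15% over the packaged 148-line
screen). Classification is deliberately not gated on significance: an
unpaired two-tailed Student's *t*-test over replicate crosses is reported
alongside, with $\alpha = 0.05$.

### Display rounding, and why it matters

The packaged screen table prints integer percentages and folds with one
decimal place, switching to two decimals only when the one-decimal value is
below 1.0 (a raw fold of 0.95 prints as "1.0", while 0.45 prints as
"0.45"). Rounding is half-up, not banker's. Thresholds operate on the
displayed value, so a raw fold of 1.864 (display 1.9) is a suppressor. All
unrounded values remain available in the scored records; only formatting
and thresholding use the display rule.

Recomputing every row of the packaged table from its counts reproduces the
printed percent column exactly and the printed fold column in 145 of 148
deficiency rows. The three exceptions (`Df(3R)D605`, `Df(2R)BSC49`,
`Df(3R)Exel6193`) carry printed folds derived from the *rounded* percent
(e.g. $10/22 = 0.45$ instead of $9.68/22 = 0.44$); the submapping table
prints 0.44 for the identical `Df(2R)BSC49` counts, confirming these are
printing artifacts of the source table. The report writer flags them in a
`mismatch` column rather than failing. One further transcription repair is
baked into the fixture: the `Df(3R)Exel6203` row's female count is stored
as 127, the only value consistent with the row's own printed total (164)
and percent (23%).

```{r score}
t1 <- read_screen_tsv(f1screen_fixture("table1_screen.tsv"))
records <- score_screen(t1)
summarize_screen(records)
```

An alternative `"sd"` threshold mode recomputes the mean $\pm$ 1 SD cutoffs
from the scored screen itself (or from fixed overrides), for screens whose
baseline differs from 22%.

## Cytogenetic interval algebra

Deficiency breakpoints are printed as polytene map positions: numbered
division (21--100, autosomes only), subdivision letter A--F, band number,
e.g. `46C7`, with arm telomeres written like `3Rt`. Breakpoint uncertainty
is printed as spans (`49C1-4`, `50C23-D2`) whose right endpoint inherits
omitted components from the left. Each deficiency therefore has a
**maximal extent** (everything it could delete) and a **minimal extent**
(everything it certainly deletes).

Three numerical choices keep the interval arithmetic honest at map
resolution:

* A letter-only endpoint (`46C`) denotes the whole subdivision as a
  half-open span; the package never fabricates a terminal band number,
  because the true bands-per-subdivision count is map-dependent.
* Subtraction keeps the subtracted interval's own breakpoint bands as
  (uncertain) endpoints of the flanking pieces — a break falling *inside*
  band `23C5` leaves part of `23C5` behind, which is how the source tables
  report residual candidate intervals such as `23C1;23C5`.
* Ordering compares the proximal edge of the denoted span, then the distal
  edge, giving a deterministic total order; cross-chromosome ordering is an
  error, while cross-chromosome overlap is simply `FALSE`.

One printed line, `Df(2R)50C-36` (`50C19-23;50C21-D5`), has overlapping
proximal and distal uncertainty ranges; its minimal extent is empty
(`minimal_extent()` returns `NULL`) and the arithmetic degrades gracefully.

## Hotspot submapping

`refine_hotspot()` reduces a modifier-containing interval by combining the
classifications of smaller overlapping deletions:

* a same-class smaller deletion narrows the hotspot to the common region of
  parent and same-class deletions (maximal extents; comment code 1);
* nonmodifying deletions exonerate only their *certainly deleted* interior
  (minimal extent; comment code 2 when no same-class evidence exists) —
  conservative under breakpoint uncertainty;
* opposite-class deletions are reported as separate intervals under their
  own class, clipped to the parent and excluding same-class evidence
  (comment code 3).

A case can satisfy several code definitions at once (the packaged table
contains cases with a nonmodifying *and* an opposite-class deletion, printed
with either code); `comment_codes` records every applicable code and the
regression test checks the printed code is among them. When several
same-class deletions exist their *common* region is used, which is what
reproduces the printed worked cases (`46C1-46C7` from two suppressing
deletions whose overlap is exactly that segment, and `26B1;26B3` from the
nested pair). Opposite-class intervals are clipped to the parent's maximal
extent so that every refined range is contained in the parent, even where
the source table prints the smaller deletion's full span.

```{r refine}
refs <- refine_submap(read_submap_tsv(f1screen_fixture("table2_submap.tsv")))
format(refs[["Df(2R)X1"]])
ann <- read_annotation_tsv(f1screen_fixture("table2_genes.tsv"))
genes <- candidate_genes(refined_ranges(refs[["Df(2R)BSC18"]]), ann)
genes
gene_class_filter(genes, ann, exclude_biotypes = "miRNA")
```

Candidate genes are annotated at the resolution the source provides: each
printed candidate list maps its symbols to the list's stated interval, and
membership is by interval intersection (inclusive at edges). Two smaller
deletions with fold change slightly below 1.9 but a statistically
significant male increase were considered suppressors in the source's
second-pass study; the fixture carries that judgment in a `starred` column
which `refine_submap()` honors.

## The generative cross model

The simulator emulates the screen's statistical structure, not fly biology:

* conceived zygotes are male with probability exactly 1/2 (the X-linked
  Gal80 makes sex determine genotype deterministically);
* a male zygote survives to scoring with probability $\min(1, v\,m)$,
  where $v$ is baseline relative male viability and $m$ a multiplicative
  modifier effect; a female survives with probability $\min(1, f)$,
  $f = 1$ by default;
* counts are binomial at a fixed clutch size (a `poisson_clutch` variant
  samples the clutch around its mean, mimicking natural cross-size
  variation).

The closed-form expected male fraction is $s/(s + f')$ with
$s = \min(1, vm)$, $f' = \min(1, f)$, equal to 1/2 exactly at survival
parity. Calibration inverts it at $m = f = 1$: $v = p/(1-p)$, so the 22%
baseline corresponds to $v \approx 0.282$. Effects are recovered by method
of moments, $\hat m = (M/F)/v$.

Defaults and their rationale:

* `v = calibrate_viability(0.22)` — the screen's established baseline.
* `clutch_n = 240` — with the 22% baseline, 240 conceived zygotes leave
  $240 \times (0.5 + 0.5 \times 0.282) \approx 154$ scored adults, the
  median line size of the packaged screen (totals range ~51--498).
* `f = 1` — rescued control females are taken as fully viable. Some
  observed crosses exceed 50% males, which a fixed $f = 1$ cannot produce
  in expectation; the `f` parameter exists for sensitivity analyses but
  its default is an assumption, not a measurement.
* Temperature dependence of the driver is folded into $v$ and not modeled.

Per-line random draws use counter-derived substreams of the single seed, so
a line's tally is invariant under reordering or truncating the line list,
and identical seeds give byte-identical simulated screen TSVs.

```{r simulate}
scr <- generate_screen_table(
  148, list(m = c(1, 0.2, 2.5), prob = c(0.9, 0.05, 0.05)),
  sim_config(seed = 1))
head(score_screen(scr)[, c("line_id", "pct_males", "fold_display",
                           "classification")], 3)
```

### What the simulator does and does not establish

Power computations (`detection_power()`, `false_positive_rate()`) are
Monte-Carlo proportions of simulated crosses crossing the fold cutoffs.
Under the model, a lethal enhancer ($m = 0$) is detected with certainty,
the null false-positive rate at clutch 150 is well under 5%, and effect
recovery across $m \in \{0.2, \dots, 3\}$ at clutch 300 is accurate to a
few percent (the suite checks all of these at $10^4$ replicates; these
problem sizes keep the default test run in tens of seconds). Moderate
suppressors are intrinsically hard: $m = 2$ gives an expected 36% males,
below the ~41.8% suppressor cutoff, so single-cross power is low — which
is why the screen design pools replicate crosses and confirms calls with a
t-test. Passing tests validate the scoring pipeline and the model's
internal consistency; they do not validate biological assumptions the
model idealizes away (viability interactions, sex-ratio distortion,
between-cross heterogeneity beyond clutch size).

## Known limitations

* X and fourth chromosomes are rejected by design; no base-pair
  coordinates or database lookups.
* The annotation fixture resolves gene positions only to candidate-list
  intervals, so `candidate_genes()` is exactly as granular as the source.
* No multiple-testing correction is applied, matching the source protocol.
* Replicate-level counts behind the printed per-line p-values are not
  public; the t-test is validated against a closed-form oracle instead of
  the printed values.
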