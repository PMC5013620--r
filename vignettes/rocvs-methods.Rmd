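---
title: "Ranking metrics for virtual screening: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking metrics for virtual screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rocvs)
```

## The problem

A virtual screen ranks a molecule library by a predicted score against a
target; its quality is judged by how strongly the known active ligands
concentrate at the top of the ranking, above the decoys. Two summaries
dominate practice: the global ROC AUC, and early-recognition measures
(semi-logarithmic ROC plots, enrichment factors, BEDROC), because the
experimental follow-up budget only ever covers the very top of the list.
`rocvs` computes all of these from one shared ranking of one labeled
dataset, so every reported number refers to the same ordering of the same
molecules.

## Input model

A score table is whitespace-delimited text: molecule name in column 1, the
score in any later column (docking outputs often carry several). Scores
may be fitness values (higher is better) or binding energies (lower is
better); polarity is an explicit user choice, `higher_is_better` by
default, since nothing in a score file announces it. Rows whose score cell
is not a finite number are skipped and counted rather than aborting the
run — real docking output is full of header lines and failed-pose
placeholders — and every skip is reported.

Duplicate names (the same molecule scored several times) are collapsed to
one record carrying the arithmetic mean of its scores. The mean is the
plainest averaging statistic; the collapse step is isolated in
`collapse_duplicates()` so a best-score or first-score policy could be
substituted without touching anything else.

Actives are identified by a regular expression matched at the *start* of
the name (benchmark sets conventionally give actives a shared prefix), or
by an explicit name list with exact, case-sensitive matching. A dataset
must contain at least one active and one decoy; anything else leaves every
metric undefined and is an error, not a silent zero.

## The ranking and the tie policy

All metrics consume one stable best-first sort. Ties are where ROC
implementations genuinely differ, so the conventions are worth stating:

- **ROC curve**: one vertex per distinct score value; a block of tied
  scores becomes a single diagonal segment. This is the standard
  pessimism-free construction for scored classifiers.
- **AUC**: trapezoid rule over those vertices. Because tied blocks are
  diagonals, this equals pair counting with half credit for tied
  (active, decoy) pairs — the test suite verifies the equivalence to
  1e-12 on hundreds of random instances.
- **BEDROC and enrichment factors**: rank-based, so a total order is
  needed; tied records keep their input-file order (the sort is stable).
  The value is therefore reproducible for a given file, though another
  tool may resolve ties differently.

## Metric formulas

For *n* actives among *N* molecules (*m* = *N* − *n* decoys, active
fraction `Ra = n/N`):

**Hanley–McNeil standard error.**
`SE = sqrt([A(1−A) + (n−1)(Q1−A²) + (m−1)(Q2−A²)]/(n·m))` with
`Q1 = A/(2−A)`, `Q2 = 2A²/(1+A)`. The numerator vanishes analytically at
A ∈ {0, 1}; a negative floating-point residue inside the root is clamped
to zero. The estimate is symmetric under A → 1−A with the class counts
swapped, and never exceeds 0.5.

**BEDROC.** With `r_i` the 1-based ranks of the actives,
`RIE = [(1/n) Σ exp(−α r_i/N)] / [(1/N)(1−e^{−α})/(e^{α/N}−1)]` and
`BEDROC = RIE · Ra·sinh(α/2)/(cosh(α/2) − cosh(α/2 − α·Ra)) +
1/(1 − e^{α(1−Ra)})`. The exact finite-N RIE denominator is used rather
than the large-N continuum approximation because small datasets (and unit
tests) would otherwise be biased. At the extreme orderings the two terms
cancel to 0 or 1 up to ~1e-16 of floating-point residue, which is clamped
into [0, 1] — the same policy as the SE. Useful intuition for α: the
weight `e^{−α r/N}` decays by 1/e every `N/α` ranks, so α = 20 probes
roughly the top 8 % and α = 160.9 the top 1 %.

**Enrichment factors.** The top-fraction convention
`EFX = (Ligs_X%/Mols_X%)/(Ligs_all/Mols_all)` needs a slice size:
`Mols_X% = round(X/100 · N)` with halves rounded away from zero, floored
at 1 so small files still have a defined slice. The decoy-fraction
convention walks the ranking until `ceiling(X/100 · m)` decoys have been
seen — the ceiling guarantees the stated decoy fraction is actually
*reached* — and reports the percentage of all actives encountered strictly
before that terminating decoy. The rounding rules are this package's
documented choices; the conventions themselves do not pin them down, so
small files may differ by one molecule from other implementations.

## The synthetic-data generator

`simulate_screen()` draws decoy scores from N(`decoy_location`, `spread`²)
and active scores from N(`active_location`, `spread`²). The Gaussian model
is chosen for analytic control: the expected AUC is
`pnorm((active_location − decoy_location)/(spread·√2))`, so the defaults
(unit shift, unit spread) emulate a moderately successful screen with
expected AUC ≈ 0.76, a zero shift gives an exact null (AUC 0.5), and a
huge shift gives perfect separation. A `tie_fraction` share of scores is
rounded to one decimal, mimicking docking programs that print scores at
limited precision and exercising every tie-handling path. Generation is
seeded and leaves the global RNG state untouched; identical arguments
yield byte-identical files.

What the generator does *not* emulate: real docking score distributions
are skewed and heavy-tailed, actives cluster into lead series with
correlated scores, and decoy sets are property-matched rather than
i.i.d. Passing tests therefore demonstrate correctness of the metrics and
plumbing on controlled inputs, not performance claims about any real
screening campaign.

## Figures

Rendering is strictly separated from computation: a `figure_spec` is pure
data, metrics-only runs never initialize a graphics device, and a
rendering run and a metrics-only run print identical numbers. Defaults are
8×6 inches at 100 dpi (pixel size = inches × dpi exactly), solid lines,
and a color cycle starting at black. In semi-logarithmic mode the x axis
starts at a user-chosen floor (e.g. 0.001) and plotted FPR values below it
are clipped *up to* the floor rather than dropped, so every curve visibly
reaches the left edge; the random-selection reference is the identity line
y = x, which becomes a curve on the log axis. Legend placement accepts the
integer codes familiar from matplotlib-style tools (0 best, 1 upper
right, 2 upper left, 3 lower left, 4 lower right, ...) mapped onto base R
keywords. Color tokens accept base R names, hex strings, and a small
alias table for common CSS names (e.g. `teal`) that base R lacks; unknown
tokens are an error naming the token. Font families are passed to the
device and resolved by fontconfig, which substitutes rather than fails
for unknown names — so font validation is delegated to the platform. The
`-kw` keyword passthrough implements a deliberately restricted
`component:{key:value}` grammar (currently `legend:{frameon:...}`);
unknown keys warn and are ignored so a stray keyword never kills a long
run.

## Command-line interface

The short flags (`-an`, `-c`, `-s`, `-p`, `-lp`, `-li`, `-l`, `-cl`,
`-st`, `-la`, `-las`, `-ts`, `-les`, `-lw`, `-aw`, `-f`, `-no`, `-a`,
`-as`, `-kw`, `-EF`, `-EFd`, `-BR`) follow the conventions screeners
already use; every flag also has a long alias because single-dash
multi-letter options are ambiguous in standard parsers, so the tokenizer
registers each short form explicitly. List-valued flags consume tokens
until the next flag; annotation coordinates accept both a plain minus and
the escaped `\-` form so negative offsets survive shells and option
parsers. The default score column is 2 (the simplest name+score file);
with several input files one `-c` applies to all. Exit codes: 0 success,
1 usage/input error, 2 labeling error (zero actives or zero decoys).
Reports print at 12 significant digits; the AUC line's `+ -<se>`
separator reproduces the established report format, with the second
number being one Hanley–McNeil SE.

## Problem sizes in the test suite

The suite checks the AUC/pair-counting equivalence on 200 random datasets
of up to ~1000 molecules, the BEDROC transcription on 1000 random
instances across α ∈ {2, 8, 20, 80.5, 160.9}, the enrichment null on 200
replicates of a 10000-molecule, 500-active random ranking (mean EF within
0.15 of 1), and the generator's null on 200 seeds of a 1000-molecule
screen (mean AUC within 0.02 of 0.5). These sizes give comfortable
statistical resolution for the stated tolerances while keeping the whole
suite in the tens of seconds.

## Known limitations

- No curve-comparison statistics (DeLong tests, confidence bands) — tools
  built for medical ROC analysis already cover that ground.
- No partial AUC or lead-series weighting of actives.
- Tie resolution by input order means BEDROC/EF values on heavily tied
  files depend on file row order (documented above); the AUC does not.
- Raster formats are the tested output path; PDF output works but pixel
  dimensions are then not meaningful.
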