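# rocvs

Evaluation and visualization of virtual-screening performance in R.

When a docking program (or any scoring method) ranks a molecule library
against a target, the standard question is how well the known active
ligands separate from the decoys. `rocvs` takes a plain-text score table —
one row per molecule, name in column 1, score in a column of your choice —
and computes the complete standard panel of ranking metrics, plus
publication-quality ROC figures, from a shell command or from R. It is
aimed at computational chemists benchmarking screening protocols on
active/decoy sets such as DUD-E or DEKOIS-style libraries.

## Metrics

With *n* actives among *N* molecules, ranked best-first:

- **ROC / AUC** — the ROC curve is built in one sweep with one vertex per
  distinct score (tied blocks become diagonal segments), and the
  trapezoidal AUC therefore equals the Mann–Whitney statistic
  P(active outranks decoy), tied pairs counting ½.
- **Hanley–McNeil SE** — the conservative nonparametric standard error
  `SE = sqrt([A(1−A) + (n−1)(Q₁−A²) + (m−1)(Q₂−A²)] / (n·m))` with
  `Q₁ = A/(2−A)`, `Q₂ = 2A²/(1+A)` for *n* actives and *m* decoys.
- **BEDROC(α)** — the exponentially rank-weighted early-recognition metric
  in [0, 1], computed from the robust initial enhancement (RIE) with the
  exact finite-N normalization; larger α focuses on earlier ranks.
- **Enrichment factors, both conventions** —
  `EFX = (Ligs_X%/Mols_X%) / (Ligs_all/Mols_all)` for the top X % of the
  list, and `EFXdec = Ligs_X%dec / Ligs_all × 100`, the percentage of
  actives recovered before X % of the decoys have appeared.

Actives are identified either by a name prefix/regular expression
(`-an CHEMBL`) or by a separate list file (`-af actives.txt`); duplicate
molecule names are averaged before analysis.

## Worked example

Generate a synthetic 1000-molecule screen (50 actives drawn from a
score distribution shifted one standard deviation above the decoys) and
evaluate it:

```r
library(rocvs)
write_screen_fixture("scores.txt", n_actives = 50, n_decoys = 950, seed = 42)
run_cli(c("scores.txt", "-an", "ACT", "-EF", "1", "-EFd", "1", "-BR", "20",
          "-s", "5", "5", "-p", "roc.png"))
```

which prints

```
Loaded 50 actives from scores.txt starting with ['ACT']
Loaded 1000 average scores from scores.txt
AUC = 0.749010526316 + -0.0406365751427
EF_1.0 = 6
EF_1.0%decs = 16
BEDROC_20.0 = 0.356741204149
Plotting ROC Curve...
```

and writes a 500×500-pixel ROC figure. Reading the report: the screen
ranks a random active above a random decoy 74.9 % of the time (± one
Hanley–McNeil SE of 0.041); the top 1 % of the list is 6-fold enriched in
actives over random selection; 16 % of all actives are recovered before
1 % of the decoys; and the early-recognition score BEDROC(20) is 0.36.
The same command works from the shell via the installed `exec/rocvs`
script, with the same flags.

Multiple score files overlay as one curve each (`rocvs 2.txt 3.txt 5.txt
-an CHEMBL -li data1 data2 data3 random ...`); `-lp 0.001` switches to a
semi-logarithmic x axis that magnifies the early-enrichment region;
`-np` computes all numbers without touching a graphics device.

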