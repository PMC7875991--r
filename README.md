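# isotail

Small RNA-seq microtranscriptome analysis in R: miRNA quantification
with a ±2 nt templated window, isomiR calling with nontemplated U-/A-tail
classification, arm-resolved uridylation statistics, 13–17 nt fragment
surveillance, a simplified negative-binomial differential-expression
test, and log-odds PWM scanning of promoter regions — validated end to
end on a fully ground-truthed read simulator.

## The problem

Mature miRNAs are not single sequences. Dicer/Drosha processing is
imprecise and 3′ ends are actively remodelled: reads differ from the
annotated (canonical) sequence by templated extensions or trimmings at
either end, and by **nontemplated additions** (NTA) — mostly mono/oligo
adenylation and uridylation. Oligouridylation by terminal uridylyl
transferases (TUT4/7) marks precursors and fragments for turnover, so
shifts in U-tail frequency and in 13–17 nt 3′-truncated fragments are a
readout of RNA surveillance. Because any modification of the precursor's
3′ end is inherited only by the mature miRNA from the hairpin's 3′ arm
(the 3p product), comparing U-tail frequencies between 5p- and 3p-derived
miRNAs localizes uridylation to the precursor or the mature species.

`isotail` implements that entire analysis as composable, tibble-first R
functions:

* **preprocess** — exact-match 3′ adapter clipping, the 95 %-of-bases ≥
  Q20 quality rule, a 12 nt minimum insert length, and collapsing to
  unique sequences with counts.
* **quantify** — strict mapping (exact, sense, full length) to hairpin
  references; a read is counted for a mature miRNA when *both* ends lie
  within ±2 nt of the canonical ends (templated isoforms), giving a
  miRNA × sample count matrix.
* **isomir** — lenient, end-modification-aware ungapped mapping (all
  placements; ≤ 2 mismatches outside terminal mismatch runs) and
  decomposition of each read into templated 5′/3′ offsets plus
  nontemplated tails by *maximal templated extension*; signatures below
  2 supporting reads are dropped.
* **modstats** — modification-class frequencies, U/A tail-length
  histograms (mono = 1 nt vs oligo ≥ 2 nt), the continuity-corrected
  3p/5p uridylation ratio, fragment counting and per-miRNA fold changes,
  Student's t-tests between conditions, and the 2^−ΔΔCt utility.
* **diffexp** — median-of-ratios size factors, a strict baseMean > 10
  filter, a moment-dispersion negative-binomial Wald test with BH
  adjustment, and cross-experiment log2FC signature regression.
* **motifscan** — JASPAR-format count matrices → log-odds PWMs, both-
  strand scanning of ~1 kb promoter regions with shuffle-based empirical
  p-values.
* **simulate** — a seeded generator of hairpin references, FASTQ reads
  and complete ground truth (isoform mixes, arm-specific tail rates with
  modal 3 nt U-tails, fragments, condition effects), used by every
  validation in this repository.

## Worked example

Simulate a two-condition (control vs knockdown) triplicate experiment in
which condition B halves the 3p-arm U-tail rate and quadruples the
fragment rate, then run the full pipeline:

```r
library(isotail)

fx <- make_fixture(file.path(tempdir(), "demo"), seed = 101, depth = 50000)
cfg <- pipeline_config(
  reference_fasta = fx$reference_fasta,
  reference_gff   = fx$reference_gff,
  sample_sheet    = fx$sample_sheet,
  out_dir         = file.path(tempdir(), "demo_out"))
res <- run_pipeline(cfg)

dplyr::select(res$arm_ratio, sample_id, u_ratio_corrected, a_ratio_corrected)
#> # A tibble: 6 × 3
#>   sample_id u_ratio_corrected a_ratio_corrected
#>   <chr>                 <dbl>             <dbl>
#> 1 A1                    18.0              1.05
#> 2 A2                    14.1              0.950
#> 3 A3                    17.4              1.01
#> 4 B1                     8.34             0.999
#> 5 B2                     9.75             1.08
#> 6 B3                     8.74             1.03
```

The corrected 3p/5p U-ratio is an order of magnitude above 1 in control
samples — uridylation is far more frequent on 3p-derived miRNAs, i.e. it
happens on the precursor — and drops in the knockdown condition, while
the adenylation ratio stays at 1 (mature-level tailing on both arms).
The condition comparison flags the U-tail classes (and the 3′-trim
class, which rises with the fragment burden), not the A-tail classes:

```r
dplyr::filter(res$comparisons, p < 0.05)
#> # A tibble: 7 × 7
#>   statistic    mean_A mean_B     t        p stars zero_variance
#>   <chr>         <dbl>  <dbl> <dbl>    <dbl> <chr> <lgl>
#> 1 3'-add       0.201  0.184  -4.02 0.0159   *     FALSE
#> 2 3'-trim      0.252  0.278  11.8  0.000298 ***   FALSE
#> 3 U-tail len 1 0.142  0.0548 -4.58 0.0102   *     FALSE
#> 4 U-tail len 2 0.296  0.138  -8.60 0.00100  **    FALSE
#> 5 U-tail len 3 0.579  0.245  -9.78 0.000613 ***   FALSE
#> 6 U-tail len 4 0.235  0.112  -6.74 0.00253  **    FALSE
#> 7 U-tail len 5 0.0991 0.0617 -3.68 0.0212   *     FALSE

glance(res$de)
#> # A tibble: 1 × 6
#>   n_input n_tested n_significant  n_up n_down alpha
#>     <int>    <int>         <int> <int>  <int> <dbl>
#> 1      40       40            10     4      6  0.05

head(sort(res$fragment_fold_change$fold_change, decreasing = TRUE), 3)
#> [1] 7.57 6.17 6.00
```

`autoplot(res$de)` draws the MA plot; `plot_tail_length_histogram()`
and `plot_modification_frequencies()` cover the modification summaries.
The exact numbers above come from this seeded fixture; other seeds give
statistically equivalent output.

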