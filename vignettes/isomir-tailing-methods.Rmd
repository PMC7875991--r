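---
title: "Methods: isomiR calling, 3' tailing statistics and validation by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isomiR calling, 3' tailing statistics and validation by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isotail)
```

This vignette records the models, rules and numerical choices behind
`isotail`, the reasoning for the choices that were genuinely open, and
what the simulation-based validation does and does not establish.

## 1. Data model and conventions

All sequences are held in the DNA alphabet (U is converted to T on
ingest): reads come off sequencers as DNA, and a single alphabet lets
reads, references and tails compare byte for byte. All internal
coordinates are 0-based half-open; GFF3 input/output (1-based inclusive)
is converted only at the file boundary. A reference is a set of hairpin
(pre-miRNA) sequences, each annotated with up to two mature miRNAs — the
5p arm product and the 3p arm product, never overlapping and with 5′
ends at least 8 nt apart, which makes the ±2 nt assignment window
provably unambiguous (checked at load time).

## 2. Preprocessing

Reads are clipped at the leftmost exact occurrence of a 3′-adapter
prefix of at least `min_overlap` (default 8) bases that either reaches
the read end or contains the full adapter. Clipping is exact-match by
design: it is the simplest reproducible contract, and the simulator
emits error-free adapters, so clipping behaviour is testable
independently of any error model. Reads without an adapter hit are
flagged and excluded — only adapter-containing reads demonstrably span
their full insert.

The quality rule keeps reads in which at least 95 % of insert bases have
Phred ≥ 20; it is applied to the clipped insert, since adapter bases are
discarded anyway. The minimum insert is 12 nt. Two branches share this
front end: the *quantification branch* additionally caps inserts at
30 nt (mirroring PAGE size selection of the 10–30 nt fraction), while
the *modification branch* is uncapped. Collapsing to unique sequences
with multiplicities is deterministic (count-descending, then
lexicographic), and per-sample accounting
(`in = adapterless + clipped`, `clipped = quality-failed +
length-failed + kept`) is asserted, not just logged.

## 3. Quantification: the ±2 nt templated window

The strict branch maps collapsed reads to hairpins requiring exact,
sense, full-length identity. A hit is attributed to a mature miRNA when
**both** of its ends lie independently within 2 nt of the canonical
ends. The alternative reading — any read contained in the mature region
±2 nt — would count 13-nt fragments as expression, which belongs to a
separate analysis; the both-ends rule admits exactly the "up to 2 nt
longer, templated, and 2 nt shorter" isoforms. A read matching the same
miRNA at several loci is counted once; reads matching distinct miRNAs
count once per miRNA. The per-sample library size is the total collapsed
count entering mapping. By construction tailed reads cannot enter this
branch (no mismatches are tolerated), with one caveat: a trimmed isoform
plus a tail can alias a templated sequence (e.g. trim−1 + U where the
mature ends in T). Such reads are *byte-identical* to templated
isoforms; no sequence-based method can separate them, and they are
counted as what they read as.

## 4. IsomiR calling

### Mapping

The lenient mapper reports, for every read, **all** sense ungapped
placements on all hairpins. At each placement the in-template positions
split into a leading and a trailing contiguous mismatch run — candidate
nontemplated 5′/3′ additions, each allowed up to 8 nt — and the core
between them, which may contain at most 2 mismatches (the familiar
two-mismatch contract, applied where it is meaningful). Terminal runs
must be exempt from the mismatch cap: a fully nontemplated 3-nt U-tail
produces three terminal mismatches, and under a plain cap the most
abundant tailed species in muscle cells would be systematically
unmappable — the cap would silently censor the signal the modification
branch exists to measure. A read may also overhang the hairpin 3′ end by
up to 6 nt; overhanging bases have no template, are never mismatches,
and are nontemplated by definition. At least 8 templated core bases are
required per placement.

One placement is selected deterministically: fewest core mismatches,
then fewest total mismatches, then smallest |5′ start offset| to the
nearest mature on that hairpin, then lexicographically smallest hairpin
id, then smallest start. Reads whose best placement starts more than
5 nt from any mature 5′ end are not assigned.

### Decomposition by maximal templated extension

Walking inward from each read end, the contiguous run of
template-mismatching bases is the nontemplated addition; a terminal base
that matches the template is always attributed to the template. This
makes decompositions unique and conservative: the greedy alternative
(maximal NTA) would count templated extensions as tails and inflate
uridylation estimates. After peeling both runs the remaining core must
match the template exactly; otherwise the read carries an interior
mismatch that no end-modification can explain and it is excluded from
modification statistics. Consequently every kept call reconstructs its
read byte for byte from `hairpin[templated interval]` plus `nta5`/
`nta3` — an invariant the test suite checks read by read, and the whole
caller is checked against a brute-force enumerator of all (placement,
5′-split, 3′-split) decompositions.

Tails are classified U (all T), A (all A), or mixed; lengths are
reported up to 5 nt with longer tails binned at 5; mono vs oligo is
length 1 vs ≥ 2. A (miRNA, modification signature) needs ≥ 2 supporting
reads per sample (the low-input threshold), summed across identical
signatures before filtering.

### Aliasing, and why the caller can be blind to some 5p oligo-tails

A U-tail base that happens to match the template is absorbed into the
templated part (that is the definition of maximal templated extension),
and a tail whose *last* base matches the template while earlier tail
bases do not leaves unexplained core mismatches, so the read is dropped.
On 3p-arm products, whose 3′ ends sit 2 nt from the hairpin end, tails
quickly run off the template and are recovered almost completely; on
5p-arm products the tail lies over hairpin-interior sequence and a
fraction of length-≥3 tails is uncallable. This asymmetry is inherent to
sequence-based tail calling, not an implementation artifact; it slightly
*raises* an observed 3p/5p ratio above the underlying rate ratio, and
never manufactures 3p-specificity where there is none (the adenylation
control stays at 1).

## 5. Modification statistics

Class frequencies (3′-trim, 3′-add, 5′-trim, 5′-add) use as denominator
*all mature-assigned reads of the modification branch* (computed before
the count threshold); a read contributes to every class it exhibits.
The source does not pin this denominator down; it is explicit and
configurable here. 3′-add includes templated extensions as well as NTAs;
the U/A analyses use NTAs only.

The arm-localization statistic is the ratio of the 3p to the 5p U-tail
frequency. Its continuity-corrected companion
`((c3p + 0.5)/n3p) / ((c5p + 0.5)/n5p)` stays finite at zero 5p counts.
Adenylation is computed identically as the negative control: A-tails
happen on mature miRNAs of both arms, so their ratio sits at 1.

A fragment is a read of insert length 13–17 nt whose 5′ end is within
2 nt of a mature 5′ end and whose templated 3′ end is at least 3 nt
inside the canonical end — disjoint by construction from the ±2
quantification window. Per-miRNA fold change between conditions is the
ratio of condition-mean normalized fragment rates with a 0.5-read
pseudocount (scaled to rate units), so no change equals 1 and zero
counts stay finite. Of the two readings the figure-legend wording
admits, only a plain B/A ratio satisfies "no change is equal to 1", so
that is what is computed. Normalization uses library sizes by default;
the pipeline passes median-of-ratios size factors from the expression
matrix instead, because asymmetric expression changes skew total library
size and would bias *every* per-miRNA fragment ratio by the same
compositional factor — with size factors, "no change" actually sits
at 1.

Condition comparisons use the classical two-sided Student's t-test
(equal variances) per statistic, with significance stars at
0.05/0.01/0.001 and a zero-variance guard: equal constant groups give
p = 1, unequal constant groups report p = 0 with an infinite t and a
flag. `ddct_fold_change()` implements
`2^-((Ct_target_B − Ct_ref_B) − (Ct_target_A − Ct_ref_A))`.

## 6. Differential expression: a documented NB surrogate

The package deliberately implements a *simplified*, fully specified
negative-binomial test rather than wrapping a full DE framework, so that
every number it produces is reproducible from the rules on this page:

* median-of-ratios size factors (the median, over features nonzero in
  all samples, of count/geometric-mean ratios);
* features kept at baseMean > 10, strictly;
* per-feature moment dispersion `α = max((s² − μ)/μ², 10⁻⁸)`, pooled
  across the two groups on normalized counts — no shrinkage across
  features, no outlier filtering, no independent filtering;
* `log2FC = log2((μ_B + 0.5)/(μ_A + 0.5))` (pseudocount 0.5 keeps zeros
  finite; positive log2FC means higher in the second condition);
* Wald z with the delta-method standard error
  `SE² = [(μ_B + αμ_B²)/n_B (μ_B+0.5)² + (μ_A + αμ_A²)/n_A (μ_A+0.5)²] / ln 2²`,
  two-sided normal p-values, Benjamini–Hochberg adjustment.

The claims made for this test are its own: simulation shows type-I
error within [0.03, 0.08] at α = 0.05 under a Poisson null (n = 3 + 3,
500 features) and ≥ 80 % sensitivity for twofold effects at baseMean
≈ 500 — not equivalence to any external tool. With large counts and
small dispersion its p-values rank-correlate ρ > 0.95 with a t-test on
log-normalized counts, as they should.

`signature_regression()` joins two result sets on miRNAs significant in
both (padj < 0.05) and fits OLS of one experiment's log2FCs on the
other's, reporting slope, R², and concordant/discordant direction
counts; a negative slope reads as one perturbation inverting the
other's signature.

## 7. Promoter scanning

`pwm_from_counts()` builds a log-odds matrix in bits,
`log2(((counts + pc)/(colsum + 4pc))/background)` with pseudocount 0.25
and uniform background by default. `scan_region()` scores every window
on both strands (reverse complement for −) and returns the top k hits
with deterministic tie-breaks by (position, strand); hits are ranked on
scores rounded to 10⁻⁹ bits so that floating-point summation noise can
never reorder windows whose true scores tie (palindromes, repeated
column values). Instead of a
corpus-calibrated enrichment score — which requires a genome-wide
promoter background this package does not ship — significance is an
empirical p-value from base-shuffled copies of the same region
(`(1 + #{shuffled top ≥ observed})/(n + 1)`), exact for the top hit and
conservative for lower ranks. The bundled MEF2-like matrix
(`inst/extdata/mef2_like_synthetic.jaspar`) is a synthetic fixture with
the A/T-rich core structure of a MEF2 site, for tests and examples; real
scans should load a curated matrix in the same JASPAR text format.

## 8. The read simulator and what passing its tests means

`simulate_reads()` emulates a two-condition × 3-replicate small RNA-seq
design with complete per-read ground truth. Reads are built as mature
isoform + optional nontemplated tail + 3′ adapter (Phred+33, constant
Q40, 50-cycle reads), with 13–17 nt 5′-anchored fragments at a
configurable rate. Defaults are the study conditions this package was
validated under:

* ~200,000 reads/sample (±15 % uniform depth jitter), 20 hairpins;
* log-normal miRNA abundances (sdlog 1.2);
* isoform mix 60 % canonical, 10/5 % templated +1/+2, 15/10 % trim
  −1/−2;
* U-tail rates 3 %/0.3 % per read on 3p/5p arms (precursor-level
  tailing, tenfold arm asymmetry), lengths 10/20/40/20/10 % over
  1–5 nt — modal length 3, predominantly oligo;
* A-tail rate 5 % on both arms (mature-level tailing), lengths
  70/20/7/2/1 % — predominantly mono;
* fragment rate 1 %;
* condition B: |log2FC| = 1 on 25 % of miRNAs (random sign), 3p U-tail
  rate × 0.5, fragment rate × 4;
* replicate-level biological variability: per-sample log-normal jitter
  on abundances (sdlog 0.2) and on tailing/fragment rates (sdlog 0.1).

The replicate jitter deserves a note. With pure multinomial sampling at
these depths, within-condition replicates are so similar that a t-test
detects *any* systematic artifact — including the few-per-mille shifts
in called A-tail percentages that expression changes induce through
composition alone. Real replicates differ biologically; modelling that
at physiological magnitude is what makes "the A-tail classes do not
change" a fair, passable null alongside a still comfortably detectable
twofold oligo-U effect.

Reference geometry: each synthetic hairpin (60–90 nt) carries a 5p
mature starting at position 4 and a 3p mature ending exactly 2 nt before
the hairpin 3′ end — the residual processing overhang, which is also
what makes 3p products inherit precursor 3′ tails. The two templated
bases immediately downstream of each mature are drawn from {C, G} so
that templated +1/+2 extensions can never be aliased by U- or A-tails;
mature sequences are pairwise distinct and never substrings of one
another.

The simulator does **not** model ligation bias, PCR duplication
structure, randomized-adapter (4N) chemistries, 5′ isomiR classes,
internal editing, or cross-mapping between homologous miRNA families.
Passing the validation therefore demonstrates that the *algorithms*
recover known truth under a realistic error-free-adapter regime; it
does not certify accuracy on any particular real library chemistry.

## 9. Validation scales and numerical choices

The test suite and `scripts/acceptance.R` validate, at these problem
sizes (chosen to exercise the claims at full per-sample depth while
completing in minutes on one CPU):

* caller vs brute-force oracle: ~500 randomized reads over 20 hairpins,
  100 % agreement required;
* quantification: exact count-matrix equality against ground truth
  (tails/fragments off) and against a templated-isoform dictionary
  oracle (tails on), at 200k reads/sample × 6;
* tail recovery: modal U-tail length 3 and corrected 3p/5p U-ratio > 5
  with A-ratio in [0.5, 2], U-tails confined to 3p;
* effect detection: 20 independent seeds, oligo-U decrease at p < 0.05
  in ≥ 90 % with A classes non-significant in ≥ 80 %;
* fragment fold change: median per-miRNA FC in [3, 5] at multiplier 4
  and in [0.8, 1.25] at multiplier 1;
* DE calibration and power as in section 6, plus exact BH agreement
  with a step-up oracle;
* inverted-signature regression: negative OLS slope when condition
  effects invert a quarter of the differentiation effects;
* motif scanning vs exhaustive enumeration on 100 random 1 kb regions,
  plus planted-consensus recovery;
* byte-identical pipeline outputs across repeated seeded runs.

Other numerical conventions: TSV outputs round doubles to 6 significant
digits and sort rows deterministically so repeated runs diff clean;
stage-level RNG streams are derived from the master seed by stage name,
so a stage rerun in isolation reproduces its in-pipeline draws; all
derived seeds stay below 2³¹.

## 10. Known limitations

* Multi-mapping across near-identical hairpin families is resolved by a
  deterministic tie-break, not probabilistic assignment.
* The tail caller cannot see tails that are byte-identical to templated
  sequence (section 4); estimates are lower bounds, asymmetrically so
  between arms.
* The NB surrogate has no dispersion shrinkage; at very small baseMean
  its moment dispersion is noisy, which the baseMean > 10 filter only
  partly mitigates.
* The promoter scan's empirical p-value calibrates against a shuffled
  version of the same region (composition preserved, order destroyed),
  not against a matched promoter corpus.
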