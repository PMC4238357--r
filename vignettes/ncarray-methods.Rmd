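---
title: "ncarray: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ncarray: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncarray)
```

ncarray implements a complete desk model of a custom spotted two-color
microarray platform for small noncoding RNAs (miRNAs, snoRNAs, tRNA-derived
fragments, snRNAs, and unclassified species of roughly 18–400 nt): how probes
are chosen and built, how the chip is laid out, how a dye-swap hybridization
behaves, and how differential expression is called from the scans. This
vignette explains the models and the choices behind them; the README shows
the worked end-to-end example.

## Probe target selection from coverage contigs

The design path starts from coverage contigs: genomic intervals assembled
from small-RNA sequencing reads, each carrying a strand, a transcript-sense
sequence, and a per-base read-coverage vector. All coordinates are 0-based
half-open; minus-strand inputs are flipped to transcript sense when read, so
position 1 of every coverage vector is the RNA 5' end and downstream offsets
never need strand arithmetic.

A contig must be supported by at least five reads to enter design
(`selection_config(min_reads = 5)`, threshold inclusive). Short contigs
(< 70 nt) receive exactly one probe target region: the contiguous window of
length `min(25, contig length)` maximizing mean coverage. Longer contigs are
tiled with 30-nt windows anchored at the 5' end (a trailing partial window
survives only if it still fits the 18-nt minimum oligo); every window whose
mean coverage exceeds the contig-wide mean is kept as an "elevated" region,
and if none is elevated — uniform coverage — the single best window is kept.
Ties always resolve leftmost, making the selection deterministic. The tiling
anchor at offset 0 is a convention: any fixed anchor produces a valid
non-overlapping grid, and anchoring at the transcript start keeps the grid
reproducible across runs.

Each contig may additionally contribute one low-coverage control/precursor
region: the grid window of lowest mean coverage, accepted only if that mean
is strictly below one third of the contig's single-base maximum and the
window does not overlap a chosen signal region. These capture the flanks of
processing products (a snoRNA or tRF excised from a longer precursor leaves
a coverage plateau with sharp shoulders), so the chip can distinguish mature
product expression from precursor background. All-zero coverage vectors are
legal; they select the leftmost window and never yield a control region
(nothing is below one third of zero).

An optional `candidate_ids` pre-filter hook restricts selection to an
externally supplied list (for example candidates that changed expression
across a differentiation series); no differentiation data is modeled inside
the package.

## Oligonucleotide design

Within each target region the package enumerates every sub-sequence of
length 18–30 nt and scores it on five criteria, each mapped to `[0, 1]`:

* **delta Tm** — `exp(-|Tm - 60| / 5)`: closeness of the DNA:RNA duplex
  melting temperature to the 60 °C design target. Tm comes from the
  Sugimoto et al. (1995) RNA/DNA nearest-neighbor parameter set, the
  standard thermodynamic model for a DNA probe bound to an RNA target, with
  duplex initiation terms, a total strand concentration of 50 nM (entering
  as CT/4 for non-self-complementary duplexes) and a configurable sodium
  correction of `0.368 (N-1) ln[Na+]` cal/mol/K relative to the 1 M
  reference. The 5 °C decay scale makes one design-grade deviation (~5 °C)
  cost a factor `e` of score.
* **position** — `1 - |center(oligo) - center(region)| / (region/2)`:
  centering inside the selected region, exactly 1 for a centered oligo.
* **complexity** — Shannon entropy of the oligo's overlapping dinucleotide
  composition divided by its maximum (log2 16 bits); homopolymers score 0.
* **folding** — `1 - min(1, stem/10)` where `stem` is the longest
  self-complementary run (the longest common substring between the oligo
  and its own reverse complement), a proxy for hairpin propensity.
* **cross-hybridization** — `1 - match/length` where `match` is the longest
  contiguous run shared with any background transcript other than the
  probe's own source contig, found by a 12-mer seeded scan; runs below the
  seed length are treated as no match, since sub-12-mer identities do not
  hybridize appreciably under array conditions.

The five scores combine as a weighted mean with weights 0.242 (cross-hyb),
0.323 (delta Tm), 0.061 (folding), 0.113 (position) and 0.161 (complexity).
The raw weights deliberately sum to 0.900 and are renormalized to 1 at
combination time, so the stored values remain exactly the platform's stated
emphasis. Ties are broken toward the intended 25-nt length, then leftmost.
The probe is the DNA reverse complement of the winning RNA window, written
5'→3'. The sub-score formulas themselves are this package's own transparent
definitions — published probe-design suites do not disclose theirs — while
every constraint around them (length window, Tm target, center preference,
weights) is the platform's.

Every signal probe gets a single-mismatch (MM) partner: identical except at
position 13 from the probe 5' end (always interior for 18–30-mers, and
opposite the seed/central region that dominates duplex stability). The
substituted base must genuinely mismatch the opposing RNA base and must not
form a G·U or T·G wobble with it — wobble pairs retain enough stability to
defeat the purpose of a specificity control. We read the platform's "no G–T
juxtaposition" rule in the probe-versus-RNA-target sense (the biophysically
meaningful one for a hybridization control) rather than probe-versus-probe;
among allowed bases a fixed priority (transversion partner first, A↔C and
G↔T, then alphabetical) keeps the chip design reproducible. Control-region,
spike-in and snRNA probes are spotted without MM partners.

Chip controls comprise eight random spike-in 25-mers (seeded; GC 40–60%, no
self-complementary stem of 6 nt or more) and 40 probes tiling the U2 and U6
snRNAs (20 each, evenly spaced). The bundled default U2/U6 sequences are
deterministic synthetic stand-ins with realistic lengths (191 and 107 nt);
a production chip would pass the organism's real snRNA sequences.

## Array layout

Probes are spotted on a grid of print-tip blocks. Each PM oligo sits
immediately left of its MM partner (same block, same row, adjacent
columns), so specificity comparisons are spatially local. Every probe
appears eight times, as two quadruplicates placed in disjoint halves of the
block list; when several replicates of a probe land in the same block they
are spread to rows at least two apart. This spatial split is the package's
concrete reading of "distributed to buffer local hybridization artifacts":
a scratch, bubble or gradient confined to one region of the slide can
remove at most one quadruplicate. Layouts are deterministic given the seed,
and an independent validator checks every invariant on any layout file
(GAL-like TSV: Block, Row, Column, ID, Name).

## The hybridization generative model

The simulator produces `2 × n_pairs` two-color scans: each biological
replicate is hybridized twice with the dye-to-condition assignment reversed
(a dye-swap pair); three pairs is the default experiment. Per candidate
`g`, baseline log2 abundance `mu_g ~ N(10, 1)` and a condition effect
`beta_g` (log2 fold change; a `fraction_de = 0.10` subset gets `|beta| = 1`
with random sign) define the specific signal
`S = 2^(mu_g + x beta_g + e)`, where `x` indicates the case condition and
`e ~ N(0, sigma_bio^2)` is drawn per gene × array × condition. Drawing `e`
independently per array reflects that each channel of each array is a
separately labeled RNA aliquot (labeling and RT variation dominate this
term), and it makes the `2 n_pairs` arrays independent measurements — which
is exactly the assumption of the downstream dye-swap model, so the residual
degrees of freedom `d_g = n_arrays - 1` are exact rather than approximate.

MM spots carry `kappa S` with `kappa = 0.3 < 1`, so perfect matches always
dominate on average. Channel foregrounds are

```
F_red   = 2^(+(delta_g + f_b(A))/2) * (S + nu) * exp(eps) + B
F_green = 2^(-(delta_g + f_b(A))/2) * (S + nu) * exp(eps') + B'
```

with `nu = 30` a nonspecific floor, `eps ~ N(0, sigma_eps^2)` spot-level
noise (`sigma_eps = 0.15` natural-log units, ~15% CV), and local background
`B` log-normal around `b = 100`. The gene-wise dye bias
`delta_g ~ N(0, 0.1^2)` and the per-block quadratic intensity curve
`f_b(A) = c0 + c1 z + c2 z^2` (coefficients drawn per block × array with
sds 0.1/0.05/0.02, `z` the centered log2 abundance) enter
*antisymmetrically* in the two channels: they shift the log-ratio M, not
the average intensity A. That placement is deliberate — a factor applied
equally to both channels would cancel in M and give the print-tip
normalization nothing to remove; the antisymmetric form reproduces the
block-wise, intensity-dependent M trends that motivate print-tip loess in
the first place. Tip coefficients are redrawn per array because each
hybridization has its own spatial artifacts.

In the noise-free limit (all sds, `kappa`, `nu`, tip coefficients zero) the
model collapses to `F - B = 2^(mu + x beta)` for PM spots and `F = B` for MM
spots, which the tests use as a closed-form oracle; with noise on, the
magnitudes above give per-gene log-ratio standard deviations around
0.25–0.3, in the range reported for well-run spotted two-color arrays on
inbred animals. The simulator emulates signal structure only: no scanner
saturation, no spatial gradients within a block, no probe-sequence-specific
affinity, and identical truth across replicate spots — so passing tests
demonstrate the pipeline's statistical behavior under the stated model, not
robustness to every artifact of real scans.

The design-input generator (`simulate_design_inputs()`) plays the same role
for the probe-design path: contig lengths log-uniform on 20–400 nt, a
Poisson coverage plateau with one amplified peak aligned to the 30-nt grid
on long contigs (the processing-product pattern), biotype labels drawn at
the platform's candidate composition (snoRNA 11%, tRF 6%, miRNA 13%,
unclassified 70%), and read counts low enough that a realistic minority
fails the five-read filter.

## Expression analysis

The pipeline follows the classic two-color limma workflow, with the
moderation step implemented in-package:

1. **Net intensity**: foreground minus local background per channel; values
   at or below zero are floored to 0.5 before any log2, which avoids
   infinities while penalizing empty spots only mildly.
2. **PM>MM filter**: a candidate is analyzed only if its mean PM net
   intensity exceeds its mean MM net intensity in at least one condition
   (strict inequality; condition-level means pool all spots, arrays and
   channels assigned to that condition). The filter runs on *raw* net
   intensities: it asks a physical question — did the perfect match
   outcompete its mismatch on the glass — and normalization, which rescales
   channels toward comparability, would blur exactly that physical
   comparison. Probes without an MM partner pass automatically and are
   flagged.
3. **Within-array normalization**: per print-tip block, a robust local
   linear regression of M on A (span 0.4, 4 robustness iterations, via
   limma's lowess backend); M is replaced by its residuals, A untouched.
   Blocks under 20 spots fall back to a whole-array fit, reported by a
   message — a 4-parameter local fit on fewer points chases noise.
4. **Between-array normalization**: quantile normalization of the A values
   so every array shares the same intensity distribution, leaving M — the
   within-array contrast that carries all differential-expression
   information — untouched. Quantile-normalizing the channels directly
   would let between-array distortions bleed into within-array ratios; the
   A-only reading keeps the two normalization concerns orthogonal. A
   documented switch (`target = "channels"`) provides the full-channel
   alternative for users who want it. Quantile normalization is idempotent,
   which the tests assert.
5. **Dye-swap linear model**: M values are oriented so positive means
   higher in the case condition, replicate spots are combined within each
   array (plain averaging by default; a common-correlation GLS option
   estimates a compound-symmetry spot correlation and weights arrays by the
   implied precision of their spot means — with balanced spot counts the
   two coincide), and the per-array values are averaged into the log2
   fold-change estimate with `s_g^2`, `d_g = n_arrays - 1` from the
   between-array scatter.
6. **Empirical-Bayes moderation**: the per-gene variances are shrunk toward
   a scaled inverse-chi-square prior whose parameters `d0`, `s0^2` are
   estimated by moment matching on `log s_g^2` (digamma/trigamma
   equations, Newton inversion of the trigamma function). The posterior
   variance `(d0 s0^2 + d_g s_g^2)/(d0 + d_g)` feeds a moderated t on
   `d0 + d_g` degrees of freedom; a degenerate moment equation (no excess
   scatter in the log variances) yields `d0 = Inf`, posterior variances
   equal to the mean sample variance, and a normal reference. The tests
   verify this estimator agrees with limma's `squeezeVar` to eight decimal
   places on hierarchically simulated variances, and that `d0 = 0` recovers
   the ordinary t-test.
7. **Multiple testing**: Benjamini–Hochberg step-up adjustment; candidates
   with adjusted p below 0.05 are called differentially expressed. Twofold
   lines on volcano plots are annotation only, never a filter.

## Operating characteristics and a known calibration property

At the package's study scale — 2000 candidates on 8 blocks, octuplicate
spotting, 3 dye-swap pairs, 10% spiked effects at one log2 unit — repeated
simulation (50 seeds per condition; these sizes keep a full
characterization under a few minutes on one CPU) shows empirical FDR at the
0.05 adjusted-p threshold of about 0.02, sensitivity near 1, and mean
absolute fold-change recovery error below 0.1 log2 units.

One property deserves honest emphasis: with gene-wise dye bias present
(`sigma_dye = 0.1`), the raw null p-values are mildly *conservative*
(fraction below 0.05 is about 0.031 rather than 0.05). This is intrinsic to
the simple dye-swap model, not an implementation artifact: the dye bias
`delta_g` cancels exactly in the balanced dye-swap average — that is the
point of swapping dyes — but its alternating contribution inflates the
between-array scatter that the model uses as its variance estimate, so
every gene's standard error is slightly overstated. limma's own
`lmFit`/`eBayes` on the identical per-array means produces the same rate.
The cost is a small loss of power, never inflated false positives; an
intercept-per-gene model would recover the lost degrees of freedom at the
price of two fewer residual df, and is deliberately out of scope here
because the replicate-df bookkeeping above is the platform's stated model.

## Numerical and degenerate-input conventions

* Leftmost tie-breaking everywhere in region selection; score ties in oligo
  design resolve toward 25-mers, then leftmost.
* The one-third control-region rule compares a window *mean* against the
  single-base *maximum*, strict inequality.
* Net-intensity floor 0.5; an all-background spot has M exactly 0.
* Coverage vectors may be all zero; variance moderation refuses to run on
  fewer than 10 candidates with positive residual df (an exact t-test is
  the right tool at that size); quantile normalization requires equal spot
  counts and at least two arrays.
* All stochastic steps (layout, truth, hybridization, spike-ins) consume an
  explicit integer seed; a fixed seed makes every output byte-identical,
  and every CLI run serializes its configuration next to its outputs.

## Limitations

The package designs and analyzes the platform; it does not attempt the
wet-lab side (labeling chemistry, hybridization kinetics beyond Tm,
scanning) nor upstream read mapping or ncRNA discovery, and the simulator's
idealizations listed above bound what simulation-based tests can certify
about behavior on real scans. Cross-hybridization scoring uses exact
substring identity with a 12-mer seed rather than thermodynamic alignment;
for probe sets targeting families of near-identical paralogs a
thermodynamic screen would be stricter.
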