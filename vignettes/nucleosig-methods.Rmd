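---
title: "Sequence signatures of nucleosome positioning and miRNA homology: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence signatures of nucleosome positioning and miRNA homology: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleosig)
```

`nucleosig` characterizes the DNA sequence landscape around regulatory
elements — the kind of landscape in which an intronic enhancer can both
position a nucleosome and, over evolutionary time, give rise to a
microRNA whose targets share the same sequence signature.  The package
combines five analysis layers (nucleosome-positioning dinucleotide
usage, rotational W/S anisotropy, curvature-symmetry dyad prediction,
PWM cis-motif profiling, and miRNA homology-region scanning), a
transcript-noise statistic for quantifying miRNA buffering, and seeded
generators that plant each signal class into synthetic backgrounds so
every detector can be validated end to end without external data.

This vignette records the models, their assumptions, the tunable
parameters, and the design decisions taken where the methods left
genuine freedom.

## Nucleosome-favouring dinucleotide usage

A 40-bp window is read as 20 non-overlapping dinucleotide frames.  For
each dinucleotide type the observed frame frequency (count/20) is
divided by the expected frequency of any one of the 16 types under
equiprobable bases, $f_{ex} = 1/(4 \times 4) = 0.0625$.  The S class
sums the observed/expected ratios of the flexible, core-favouring types
GG, CC and CG; the W class those of the rigid boundary types AA and TT.
Each class is bounded by $16$ and the two sum to at most $16$; a
uniform random background gives an expected S class of $3 \times
(1/16)/0.0625 = 3$ and W class of $2$.

The expected frequency is applied **per dinucleotide type** (our
reading of the normalization); applying it per class would rescale S by
1/3 and W by 1/2 without changing any detector decision, since both
maps are used comparatively.  Read literally, "consecutive 40-mers"
means a step of 40 bp; the smooth usage maps suggest a sliding window.
Both modes are supported (`step` argument of `dinuc_usage_tracks()`,
default 1) and tested.

Windows with more than 10% `N` bases are masked (`NA`) rather than
scored from partial information.

## W/S rotational anisotropy

Rotational nucleosome positioning favours A/T-containing (WW)
dinucleotides where the minor groove faces the histone octamer and
G/C-containing (SS) dinucleotides where the major groove does.  The
score at a candidate dyad $n$ counts, over a 147-bp frame,

$$S_{W/S}(n) = \sum_{\text{minor}} C_{WW} + \sum_{\text{major}} C_{SS}
             - \sum_{\text{minor}} C_{SS} - \sum_{\text{major}} C_{WW},$$

with 14 minor-groove and 12 major-groove contact sites, so
$S \in [-26, +26]$.  The method we follow does not print the site
offsets; the default `groove_site_table()` uses standard
rotational-positioning geometry at a 10.3-bp helical repeat: minor
sites at $\pm\,\mathrm{round}(10.3i + 5.15)$ for $i = 0..6$ and major
sites at $\pm\,\mathrm{round}(10.3i)$ for $i = 1..6$.  The table is
configurable and validated to the 14/12 cardinality.

Each site is scored by a single dinucleotide.  We orient that
dinucleotide *outward* from the dyad (starting at `dyad + offset` for
positive offsets, ending there for negative ones): this makes the
covered base set mirror-symmetric about the dyad, so the track of a
reverse complement is exactly the reversed track — a property the
simpler "always start at the offset" convention breaks by half a base
on the negative arm.  A poly-A sequence scores $14 - 12 = +2$, poly-G
scores $-2$, and the maximal in-phase construction scores $+26$
exactly.

## Curvature and SymCurv dyad prediction

Curvature is computed from a configurable dinucleotide wedge table
(roll/tilt deflections per step, degrees) under vector summation: each
step's deflection is rotated by the cumulative helical twist (34.3°
per step) and the magnitude of the vector sum over a sliding window is
divided by the window length.  Deflections recurring in phase with the
helical repeat reinforce into macroscopic bends; isotropic ones cancel.
The default table is a consensus-style roll-wedge set of this package:
A-tract steps (AA/TT, AT) nearly straight, flexible pyrimidine–purine
steps (TA, CA/TG, CG) carrying the largest roll, tilt zero, and roll
symmetric under reverse complement.  Absolute curvature units cancel in
the SymCurv ratio, so only the relative geometry of the table matters;
phased A-tracts reproduce the classic bent-DNA signal under the
defaults (a property test asserts this).

**Even-extent handling.** A 30-bp window cannot be centred on a base
symmetrically if it is read as 30 bases.  We define the window as the
30 dinucleotide *steps* between bases $n-15$ and $n+15$, which is
exactly symmetric about $n$.  This matters: with a 15/14 base split the
curvature profile of a mirror-symmetric sequence is symmetric about a
half-integer coordinate and integer-centred symmetry scores never see
it.

SymCurv combines mirror symmetry with local-minimum convexity:

$$S_{sym}(n, m) = \sum_{i=1}^{m} \frac{1}{|\mathrm{Curv}_{n-i} -
\mathrm{Curv}_{n+i}|}, \qquad m = 25,$$

with each difference floored at $\varepsilon = 10^{-6}$ (a perfectly
symmetric profile scores $m/\varepsilon$), and

$$S_{min}(n) = \frac{1}{\mathrm{Curv}_{n-1} + \mathrm{Curv}_{n+1} -
2\,\mathrm{Curv}_n},$$

the reciprocal discrete second difference, positive exactly at strict
local minima.  The printed form of this denominator,
$(\mathrm{Curv}_{n-1} - \mathrm{Curv}_n) - (\mathrm{Curv}_{n+1} -
\mathrm{Curv}_n)$, simplifies to $\mathrm{Curv}_{n-1} -
\mathrm{Curv}_{n+1}$, which is approximately zero at any symmetric
minimum and carries no convexity information; because the method
explicitly anchors dyads at local curvature minima we treat the minus
as a typographic slip for plus and implement the second difference.
Both readings are available (`smin_mode`), and neither is asserted as
the original intent.  A zero denominator is replaced by
$1/\varepsilon$ with its sign and flagged.

`predict_dyad()` enumerates strict local minima
($\mathrm{Curv}_n < \mathrm{Curv}_{n-1}$,
$\mathrm{Curv}_n \le \mathrm{Curv}_{n+1}$; the leftmost wins flat
ties) with full $\pm m$ support and returns the maximizer of
$S_{sym} \cdot S_{min}$; exact ties resolve to the leftmost position,
making the call deterministic.  SymCurv is evaluated on the raw (not
smoothed) curvature.  An exhaustive brute-force search over all
admissible positions reproduces the winner on every test fixture.

Superhelical locations (SHL) express distance from the dyad in helical
turns rounded to the nearest half turn.  The occupancy profile gives
the two half-integer bins bracketing a feature's midpoint one count
each per sequence (a midpoint exactly on a bin contributes to the bins
half a turn either side), so counts always sum to twice the number of
scored sequences.

## Structural alignment of anisotropy tracks

The original analysis aligned W/S oscillation plots by cross-correlation
followed by manual curation.  We replace curation with a deterministic
exhaustive search: for each track, all integer shifts within one
helical turn (±10 bp by default) are scored by the normalized
cross-correlation

$$\mathrm{norm\_corr}(x, y) = \frac{\sum_n x(n)\,y(n)}
{\sqrt{\sum_n x(n)^2 \sum_n y(n)^2}},$$

computed exactly as printed, **without mean-centering** (a `center`
flag provides the Pearson variant for sensitivity analysis).
Correlations are computed on the overlapping span only; tracks whose
overlap falls below 50% at a shift are not scored there, and constant
tracks are excluded with a warning.  Ties resolve to the smallest
absolute shift, negative first.

Because the helical repeat (10.3 bp) is close to a 10-bp shift, a pure
sinusoidal track shifted by one turn is nearly self-similar: the
one-turn alias is intrinsic to this estimator, which is presumably why
the original workflow curated offsets by hand.  Recovery is reliable
when the tracks carry harmonics or an envelope — the W/S tracks of
nucleosomal frames have both.  The package's recovery experiments use
W/S-type two-phase pulse waveforms with signal-to-noise ratio
(sd(signal)/sd(noise)) of 2, where exact recovery exceeds 95%, and a
two-frame sequence-level plant for the cross-module check.

The aligned consensus is the per-position mean over shifted tracks
with a seeded percentile bootstrap CI over the track set (default
1000 resamples, 2.5/97.5 percentiles).  The 20-mer cross-correlation
heat map averages `norm_corr` over all unordered track pairs per
segment.

## Cis-motif profiling

PWMs are read from JASPAR PFM text.  Counts are converted to
probabilities with a total pseudocount of 0.8 per column split by the
background (uniform by default) and scanned as log2-odds on both
strands.  The relative score min-max normalizes the raw score by the
matrix's own score range — the convention of the scanning function the
original analysis used — and hits at relative score ≥ 0.80 (the
original operating threshold) are reported.  Overlapping hits are all
kept; clustering is described downstream by positional histograms, not
by merging.  Our scanner agrees exactly with `Biostrings::matchPWM`
under the same pseudocount scheme (cross-checked in the test suite,
where `matchPWM` serves as an independent reference, not as the
implementation).

Histogram resolution follows the bin-width selection of Shimazaki and
Shinomoto: over a candidate list, the width $\Delta$ minimizing
$C(\Delta) = (2\bar{k} - v)/\Delta^2$, with $\bar{k}$ and $v$ the mean
and biased variance of the bin counts.  Ties resolve to the smaller
width.  Degenerate inputs (all positions identical) return the
smallest candidate by convention: with a single occupied bin the
counts carry no width information, and the formula alone would
otherwise diverge toward arbitrarily wide bins.

Class statistics report per-class counts and the TFAP2A/B/C : TCF3/4
ratio; the ratio is flagged missing when the TCF class is empty.
Upstream/downstream polarity is defined relative to the homology-region
midpoint on the plus strand of the symmetrized frame.

## miRNA homology regions (miR_HR)

Candidate homology regions are ungapped full-query-length windows on
either strand with identity strictly above 68% (T ≡ U; the identity
denominator is always the full query length, per the no-gaps rule).
Candidates must contain the high-affinity consensus
`5'-GGCTCCTGCC-3'` — or its reverse complement — as an exact
substring.  The source describes this consensus in two lengths
(the decamer above and an octamer prefix `GGCTCCTG`); the decamer is
the default and the octamer remains selectable, with neither asserted
as the single intent.

Surviving candidates are filtered on hybridization energy.  The
original workflow used a full hybridization folding engine; this
package deliberately does not reproduce that model.  Instead
`duplex_delta_g()` is a transparent nearest-neighbor approximation:
the miRNA is paired antiparallel against the complement of the
strand-oriented site, positions pair as Watson-Crick or G:U wobble,
and

$$\Delta G = \Delta G_{init} + \sum_{\text{stacks}} \Delta G_{stack}
+ n_{\text{interruptions}} \times p,$$

summing standard RNA/RNA nearest-neighbor stack values over
consecutive paired positions, with simplified negative values for
wobble-containing stacks, a +4.09 kcal/mol initiation, and a
+3.0 kcal/mol penalty per maximal unpaired run enclosed by helix
(dangling unpaired ends are not penalized; a site with no pairs at all
returns the bare initiation).  No bulges, asymmetric loops or
suboptimal structures are modelled.  The −36 kcal/mol cutoff is applied
to this score and is configurable, as are the penalty and the table.
The approximation is adequate for its only role here — a threshold
filter — and is validated against an independent table-summing oracle,
not against the folding engine it replaces.

`palindrome_stem()` sizes the longest inverted repeat centred within
±5 bp of a position, as a sequence-level proxy for the hairpin the
region could form as RNA.  The loop must be at least 3 bases (the
physical hairpin minimum) by default; `min_loop = 0` admits contiguous
palindromes such as `GGGCCC`, whose arms abut with no loop, and both
conventions are exercised in the tests.

## GC isochores and divergence tracks

`segment_gc()` performs recursive binary segmentation on base
composition: at each step the split maximizing the Jensen-Shannon
statistic $2N \cdot \mathrm{JSD}$ (natural log, $N$ = informative
bases) between the GC compositions of the two parts is accepted while
the statistic is at least the halting parameter $t_0 = 100$ and both
parts are at least 3000 bp, the settings of the isochore-mapping
platform the original analysis cites.  That platform's halting
statistic is not reproduced bit-exactly — the cited settings name
parameters, not a formula — and our statistic is documented as an
approximation of it.  Segments always tile the input; `N` bases are
excluded from GC counts.  Family labels follow configurable cutoffs
with the GC-richest family H3 assigned *strictly above* 52% GC; the
lower cutoffs (37/41/46%) are implementation defaults.

Windowed Levenshtein tracks (`levenshtein_track()`) score the edit
distance between two same-coordinate windows — the linear form of an
intronic divergence heat map.  The original windowing is unstated;
the defaults are a 100-bp window stepped by 20 bp, both configurable.

## Transcript-noise statistics

For a panel of genes sampled at 20-min timepoints ($t_0 .. t_{180}$),
each gene's trajectory is normalized to its own expression at time
zero.  Per timepoint the pooled cross-gene summary includes the sample
standard deviation

$$S = \sqrt{\tfrac{1}{n-1}\sum_i (x_i - \bar{x})^2},$$

whose upper limit is controlled by the largest normalized value:
buffering that pulls $\max(x_i)$ toward $\bar{x}$ drives $S$ toward
its minimum.  The percent reduction of the upper limit between a
control and a miRNA-amplified condition is

$$100 \times \left(1 - U_{treated}/U_{control}\right),$$

where $U$ is the pooled maximum by default; the 97.5th percentile is
provided as a robust alternative because the source does not define
the estimator ("upper limit") operationally.  Negative reductions
(amplification) are legal and flagged.

## Synthetic data: what it emulates and what it does not

All generators are pure functions of their parameters and a seed.
`gen_background()` draws i.i.d. bases at a chosen GC fraction;
`plant_signal()` overwrites intervals with the five signal classes the
detectors target (G/C core with poly-A/T boundaries; WW/SS dinucleotides
at the groove sites of a frame, with a phase; a mirror
reverse-complement flank pair around a dyad, with a straight A/T
valley and a fixed high-roll boundary step so the dyad is a genuine
curvature minimum; PWM-sampled motif clusters at regular spacing; and
query copies with exactly k substitutions placed outside the consensus).
Ground truth is returned alongside every plant.

The expression generator models telegraph-style transcription per gene
— Poisson burst arrivals (0.15/min), geometric burst sizes (mean 20),
first-order decay (0.15/min, half-life ≈ 4.6 min, the short-lived
regime in which 20-min sampling shows visible dynamics), a small
constitutive floor (0.1/min) — *averaged over 100 effective cells*,
because the emulated measurement is a population-level qPCR panel, not
single-cell counts.  Burst totals per minute are drawn as negative
binomials (a Poisson number of geometric bursts), integrated in 1-min
steps with a 100-min burn-in.  In the `miR_high` condition burst sizes
are multiplied by the suppression factor (0.35) inside the M-phase
window (80, 100] minutes and by an amplification factor (default 1,
i.e. off) afterwards.  Under these defaults the deterministic limit of
the t100 upper-limit reduction is
$\approx 100\,(1 - e^{-\gamma \tau} - \phi\,(1 - e^{-\gamma \tau}))
\approx 60\%$ (with $\gamma \tau = 3$ over the 20-min window and
suppressed inflow fraction $\phi \approx 0.37$), and the simulated
reductions fall in the 50–80% band that brackets the ≈55–65% regime
reported for the real panel.  Because suppression opens *after* the
t80 measurement under this window convention, the simulated reduction
at t80 is near zero — reproducing the reported t80 effect would require
suppression beginning around t60, which the fixed window deliberately
does not model.

What passing these tests shows — and does not.  The plants are clean,
isolated signals in i.i.d. backgrounds: recovering them demonstrates
that each statistic is implemented correctly and is sensitive at
realistic signal strengths, not that it would detect the far noisier,
repeat-laden, composition-heterogeneous signals of real genomes at the
same rates.  The expression model reproduces summary behaviour (burst
noise, suppression arithmetic), not the biology of cell-cycle phase
structure or miRNA kinetics.

## Numerical conventions and problem sizes

Coordinates are 0-based half-open everywhere internally; BED and
bedGraph outputs follow their standards; only human-readable reports
are 1-based.  Epsilon floors default to $10^{-6}$ and are configurable.
Deterministic tie-breaks: leftmost dyad, smallest-then-negative shift,
smallest bin width, plus-strand-first hit ordering.

The validation experiments use problem sizes chosen to make their
statistics sharp while keeping the whole suite quick to run on a
laptop: 500–700-bp sequences for dyad work (20 seeds), 250-point
tracks for the 100-trial phase experiment, 6-kb genomes for the
5-plant/5-decoy homology screens (20 seeds), 43-gene panels (20 seed
pairs) for the noise regime, and 12+12-kb two-isochore sequences for
boundary recovery.

## Known limitations

* The curvature wedge table is a consensus-style default, not a fitted
  physical parameter set; only SymCurv's scale-free combination is
  invariant to it.
* The duplex energy is a filter-grade approximation; it must not be
  read as a hybridization free energy for ranking beyond the cutoff.
* One-turn phase aliasing limits offset estimation on near-sinusoidal
  tracks; inspect the reported correlations when tracks are short.
* The isochore statistic approximates the cited platform; segment
  boundaries can differ from it in detail even though planted
  composition boundaries are recovered within ±200 bp.
* The telegraph generator's defaults are calibrated to the regime the
  analyses probe, not fitted to data.
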