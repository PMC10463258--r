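---
title: "Methods: isoform fractions from mixed traces and gel densitometry"
author: "splicefrac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform fractions from mixed traces and gel densitometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicefrac)
```

## The measurement problem

Two alternative splice-site choices at consecutive introns insert,
independently of each other, a 3-nt serine codon and/or a 42-nt acidic
cluster into one mRNA. RT-PCR across the region therefore yields two
fragment lengths — a long band carrying the 42-nt insert and a short band
without it — and *each* band is itself a mixture of transcripts with and
without the 3-nt insert, which co-migrate because 3 nt is below gel
resolution. The experiment measures three numbers per sample:

* `f_long`, the long-band fraction, from lane densitometry;
* `s_short` and `s_long`, the 3-nt-insert fraction inside each excised
  band, from the band's mixed Sanger trace.

Assuming the two events combine multiplicatively within a band — forced by
the design, since each band is sequenced separately and the within-band
serine fraction times the band fraction is the only estimator the data
admit — the four isoform fractions are

$$A = (1-f_L)(1-s_S),\quad C = (1-f_L)\,s_S,\quad
  B = f_L(1-s_L),\quad D = f_L\,s_L ,$$

a bijection between $(f_L, s_S, s_L) \in (0,1)^3$ and interior profiles
(`combine_isoform_fractions()` / `splice_fractions()`). Technical
replicates are aggregated *after* combination: fractions are averaged and
the per-isoform sample SD reported, matching the mean ± SD per quantity
that replicate figures display. Whether one should average raw
amplitudes instead is genuinely open; averaging last keeps each replicate
a self-contained measurement and propagates between-replicate variation
into the reported SD.

## Trace forward model

`simulate_trace()` writes the mixed electropherogram as
$f\,T(\mathrm{long}) + (1-f)\,T(\mathrm{short})$, where $T(s)$ places for
base $i$ (0-based) a Gaussian peak of SD `peak_sigma` at scan
$i\cdot\texttt{peak\_spacing}$ in that base's channel with height
$\texttt{base\_amplitude}\cdot e^{-\texttt{decay\_rate}\cdot i}$;
`crosstalk` leaks a fraction of each peak equally into the other three
channels (conserving the channel sum), and i.i.d. Gaussian noise is added
per scan and channel with the signal truncated at zero. Both species share
one scan grid — co-amplified fragments run in a single reaction, so no
mobility shift. Defaults, chosen once as typical of analyzed capillary
traces:

| parameter        | default | units         | why |
|------------------|---------|---------------|-----|
| `peak_spacing`   | 12      | scans/base    | typical analyzed-trace sampling |
| `peak_sigma`     | 1       | scans         | peaks sharp enough that a peak's tail is < 2e-8 of its height at the neighbouring read-out window's edge; wider peaks make the window-max table read neighbour tails (1.1% at SD 2) and pure species would no longer read as pure |
| `base_amplitude` | 1000    | arbitrary     | scale only |
| `decay_rate`     | 0.002   | /base         | mild signal decay along the read |
| `noise_sd`       | 50      | arbitrary     | 5% of base amplitude, the noise level the recovery properties are stated at |
| `crosstalk`      | 0.02    | fraction      | small residual spectral overlap after matrix correction |

The simulator records ground truth (mixture fraction, clean per-peak
amplitudes) and is byte-reproducible from its seed; `generate_dataset()`
derives per-replicate seeds deterministically from one master seed.

What the generator does **not** emulate: PCR amplification bias, primer
artifacts, dye blobs, base-caller miscalls, mobility shifts, or saturating
detectors. Passing tests therefore demonstrate correctness of the
*estimators* under a clean additive-noise measurement model, not
robustness to every artifact a real capillary run can show.

## Reading peak amplitudes

`extract_peak_amplitudes()` assigns each scan to its nearest called peak
(ties to the lower index, windows of half a peak spacing) and offers two
readings per peak and channel:

* `"max"` — the window maximum, the number a person reads off a printed
  profile;
* `"height"` (default for estimation) — the least-squares height of the
  trace's own peak shape fitted to the windowed signal, with the shape SD
  estimated by log-parabola interpolation at peak apexes
  (`estimate_peak_width()`, exact for a Gaussian sampled on the grid).

The two coincide on clean traces. Under per-scan noise, however, the
window maximum is an order statistic over ~12 scans: on a weak channel it
is dominated by the largest noise excursion and biases the read upward
(about +0.03 on the estimated fraction at a true fraction of 0.1 with 5%
noise — large enough to break the package's own recovery requirements).
The shape-fit height is a linear functional of the data, hence unbiased
under additive noise; and since all four channels at a peak share one
shape, even an imperfect width estimate cancels in between-channel
ratios. This is why the estimators default to `"height"`; the classical
`"max"` reading remains available for comparability.

## The two fraction estimators

`fit_trace_mixture(method = "amplitude")` implements the three-nucleotide
ratio described above. Site selection (`find_informative_sites()`) takes
the *first* `n_sites` positions after the junction where the two species'
reads disagree: which three nucleotides the original protocol used is not
specified anywhere, and the earliest sites carry the strongest signal
under decay. The ratio uses only the two predicted channels, ignoring the
other two, so unrelated baseline does not enter. Sites where both
predicted channels read zero are dropped with a warning (all dropped is an
error); per-site fractions and the overall mean are clamped to `[0, 1]`
because fractions are proportions. With a single usable site the SD is 0.

`fit_trace_mixture(method = "lsq")` fits all window positions at once:
per-peak amplitudes are normalised by their channel sum (removing the
per-peak scale, i.e. decay) and projected onto the segment between the two
species' indicator templates,

$$\hat f \;=\; \mathrm{clip}_{[0,1]}
  \frac{\sum_{p,c} (P-M)_{pc}\,(y'-M)_{pc}}{\sum_{p,c} (P-M)_{pc}^2},$$

a closed form — no iteration, no initialisation, no tie-breaking. If the
templates agree everywhere in the window (e.g. a homopolymer insertion)
the mixture is unidentifiable and the fit errors. The brute-force
`grid_search_fraction()` evaluates the same objective on a 0.001 grid and
is used as an independent oracle: on noisy simulated traces the closed
form agrees with it to within one grid step.

Strand handling is explicit: reads from the reverse primer are quantified
against `reverse_complement(refs)`; nothing is inferred from the data.

## Gel forward model and densitometry

`simulate_lane()` places one Gaussian band per fragment at
`migration_model(length)` (default linear in log10 length, ~28 px between
500 and 542 nt at band SD 3 px) with volume proportional to molar
abundance (`stain_mode = "molar"`) or to abundance × length (`"mass"`,
how intercalating stains respond), on a constant background with additive
noise truncated at zero.

Quantification (`quantify_bands()`) is deliberately parameter-free:
background is removed by a line through the first/last 5% of the profile
(or a rolling minimum); each labelled band is the local maximum nearest
its expected centre within a tolerance; its half-width comes from the
interpolated half-maximum crossings; and the volume is the trapezoidal
integral over centre ± 3 half-widths. An absent band keeps its label with
volume 0; two labels claiming one maximum go to the nearer expected
centre, and an exact tie is an error rather than a guess. The ± 3
half-width (≈ 3.5 SD) truncation leaves ~0.04% of a Gaussian band
outside the window; identical truncation in both bands cancels in the
long/short ratio, which is also invariant to global intensity rescaling.

`long_fraction()` reports the plain intensity ratio by default — what
interactive gel densitometry produces — because the length bias is small
(a 42-nt-longer fragment is ~8% brighter per molecule at 500 nt under a
mass-responsive stain) and reporting the uncorrected ratio reproduces the
measurement as practised; passing `length_correction` divides volumes by
fragment length to expose and remove that bias.

## Statistics

Group comparisons use the unpaired two-tailed Student t test (pooled by
default, Welch optional); degenerate zero-variance inputs return p = 1
for equal means and p = 0 otherwise instead of erroring. Dispersion
comparisons use the variance-ratio F test with
$p = 2\min\{P(F\le f), P(F\ge f)\}$ capped at 1 — two-tailed because no
direction of the dispersion difference is assumed; this is the
conservative default and is stated in the output. Factorial designs use
two-way ANOVA with Type II sums of squares computed from nested
least-squares fits, so unbalanced layouts (three or four experiments per
group) are handled marginally; an effect with zero sum of squares reports
F = 0, p = 1 even when the residual variance is also zero, and a nonzero
effect over zero residual variance reports F = Inf, p = 0. A 5%
significance level is reported but never hard-coded into library
functions; only the command-line report flags significance.

## Verification sizes and numerical tolerances

The test suite checks, among others: exact (≤ 1e-6) round-trip of both
estimators on noiseless traces across the full fraction range; agreement
of the closed-form least squares with the grid oracle within one 0.001
step on 100 noisy instances; recovery within 0.05 in ≥ 95% of 200
replicates at 5% amplitude noise for fractions 0.1/0.3/0.5; end-to-end
recovery of 50 Dirichlet(2)-sampled four-isoform truths (three replicates
each) with mean absolute error ≤ 0.05 per isoform and exact sum-to-one at
every stage; densitometry volume recovery within 2% over 200 lanes with
bands ≥ 4 combined SD apart and noise at 1% of each band's peak height;
and type-I error of the t and F tests within 0.05 ± 0.01 over 10,000 null
simulations, with exhaustive-permutation and hand-computed ANOVA oracles.
Dirichlet(2) truth sampling reflects the interior isoform profiles that
tissue panels show while still exercising skewed compositions; the
permutation oracle uses the mid-p convention since the pooled example data
are heavily tied and a discrete permutation distribution is compared
against a continuous parametric p value. These sizes keep the whole suite
around twenty seconds on one core while leaving Monte-Carlo margins far
from the asserted bounds.

## Known limitations

* Only two-species mixtures are decomposed; chimeric reads, more than one
  co-amplified indel per band, and general base calling are out of scope.
* The serine-junction default sequence is a synthetic stand-in (the real
  junction nucleotides are not published); it is a parameter everywhere
  and estimators never depend on it.
* Absolute transcript quantification is not attempted — all outputs are
  fractions, plus a reference-normalised expression ratio against a
  loading control.
* The amplitude estimators presume analyzed (mobility- and
  spectrally-corrected) traces; raw ABIF channels (DATA1-4) are rejected
  rather than silently mis-read.
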