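# splicefrac

Quantifying the relative abundance of mRNA splice variants that differ by
short insertions at exon–exon junctions, from the two readouts an RT-PCR
experiment actually produces:

1. **Mixed Sanger chromatograms.** When two co-amplified transcripts are
   identical up to a short insertion (here, a 3-nt serine codon introduced
   by an alternative 3′ splice site), their sequencing reads are
   frame-shifted against each other downstream of the junction, and the
   electropherogram superimposes both base signals at every position. At an
   *informative site* — a read position where the two species predict
   different bases — the fraction of the insertion-bearing transcript can
   be read off the channel amplitudes.
2. **Agarose-gel densitometry.** A longer insertion (here, 42 nt encoding a
   14-aa acidic cluster) resolves the RT-PCR products into a long and a
   short band, whose integrated lane intensities give the long-fragment
   fraction directly.

This is the situation for human *SORCS2*-type two-event splicing, where
four variants arise from two independent insertion events: A (neither
insert), B (long insert), C (short insert), D (both).

## The estimators

**Amplitude ratio** (the classical three-nucleotide reading): at each of
`k` informative sites (default `k = 3`, the earliest differing positions
after the junction, where signal decay is smallest),

    f_i = a_i(+) / ( a_i(+) + a_i(−) ),     f̂ = mean(f_i),  SD across sites,

where `a_i(+)` and `a_i(−)` are the peak amplitudes of the channels
predicted by the insertion-bearing and reference species. Both channels at
a site share the same positional decay, so the ratio cancels it exactly.

**Constrained least squares** (generalisation with a brute-force oracle):
per-peak channel amplitudes over a window after the junction are
normalised by their channel sum and fitted to
`f·E(+) + (1−f)·E(−)`, the indicator templates of the two species, by a
closed-form projection onto `[0, 1]`. `grid_search_fraction()` evaluates
the same objective on an explicit grid as an independent slow oracle.

**Isoform combination.** With `f_long` from the gel and the within-band
serine fractions `s_short`, `s_long` from sequencing each excised band,

    A = (1 − f_long)(1 − s_short)   C = (1 − f_long)·s_short
    B = f_long(1 − s_long)          D = f_long·s_long

which sums to 1 exactly; technical replicates are aggregated as per-isoform
mean ± SD. The comparison statistics used by such studies are included:
unpaired two-tailed t test (pooled or Welch), a two-tailed variance-ratio
F test for dispersion differences, and two-way ANOVA with Type II sums of
squares.

A forward simulator (`simulate_trace()`, `simulate_lane()`,
`generate_dataset()`) produces chromatograms, gel lanes and full replicate
datasets with known ground truth, so every stage of the chain is testable
without wet-lab data. `read_trace()` reads ABIF/AB1 capillary files
(analyzed channels DATA9–12, FWO_ channel order, PLOC peaks, PBAS calls)
as well as the package's plain-text trace format.

## Worked example

```r
library(splicefrac)

truth <- synthetic_truth(c(A = 0.55, B = 0.20, C = 0.15, D = 0.10), seed = 42)
truth
#> Synthetic isoform truth (3 replicates, seed 42)
#>    A    B    C    D
#> 0.55 0.20 0.15 0.10
#> f_long = 0.3000, s_short = 0.2143, s_long = 0.3333

ds <- generate_dataset(truth)                       # 3 replicates: 2 traces + 1 lane each

fit <- fit_trace_mixture(ds$replicates[[1]]$trace_short, ds$refs)
summary(fit)
#> Mixture fit (amplitude_ratio): insertion-bearing fraction = 0.2005 (sd 0.0309, 3 sites)
#>  peak_index base_plus base_minus fraction
#>          19         G          C   0.2046
#>          20         C          G   0.1678
#>          22         C          T   0.2292

quantify_dataset(ds)                                # gel + traces -> 4 isoforms, mean ± SD
#> Isoform profile (3 replicates):
#>               A      B      C      D
#> fraction 0.5439 0.1938 0.1551 0.1072
#> sd       0.0200 0.0046 0.0121 0.0050
```

The short-band trace is a mixture at the true within-band serine fraction
(0.214); the three informative sites read 0.20 ± 0.03 under the default 5%
amplitude noise. The full pipeline recovers the four-isoform truth to
about ±0.01 per isoform from three technical replicates.

Dispersion comparison between two groups of expression values:

```r
f_test_variance(c(1.2, 4.6, 0.8, 5.1, 2.7), c(3.1, 2.4, 2.8, 3.3, 2.9))
#> f_test : statistic = 32.76, df = 4, 4, p = 0.005161
```

A thin command-line front end wraps the same functions:

```sh
exec/splicefrac combine --f-long 0.312 --s-short 0 --s-long 0
#> {"A":0.688,"B":0.312,"C":0,"D":0}
```

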