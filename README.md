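# rhythmpencil

Detection of superimposed circadian (~24-h), ultradian 12-h, and ~8-h
rhythms in uniformly sampled omics time courses, for chronobiologists and
computational biologists analysing gene-expression, binding-intensity, or
coverage time series — e.g. a liver RNA-Seq course sampled every 2 h for
48 h in duplicate, or a ChIP-Seq binding course at 4-h steps.

Most rhythm detectors fit one oscillation per gene inside a prespecified
period window, which misreads genes whose 12-h component is superimposed on
a larger circadian one. `rhythmpencil` instead decomposes each series into
*all* of its damped sinusoids at once with the eigenvalue/matrix-pencil
method, and classifies genes afterwards from the recovered parameters.

## The model and estimator

Each replicate-averaged series is modelled as

    x(t) = mu + sum_k A_k * d_k^(t/T_k) * cos(2*pi*t/T_k + phi_k) + noise

with period `T_k` (hours), per-cycle decay `d_k` (1 = sustained), amplitude
`A_k`, and phase `phi_k`; the time of peak is `p_k = ((-phi_k) mod 2*pi) *
T_k / (2*pi)`. The mean-adjusted series is arranged into a Hankel matrix;
the signal poles `z_k = d_k^(dt/T_k) * exp(±2*pi*i*dt/T_k)` are recovered
as eigenvalues of a rank-truncated matrix pencil, complex amplitudes by
least squares on the pole basis. Components are ranked by amplitude and the
top `k` (default 3) reported. A gene is then classified per inclusive
windows — e.g. 12-h class: period 10.5–13.5 h, decay 0.8–1.2, mean
expression > 0.1 — with class-level false discovery rates estimated by
time-label permutation.

The package also provides circular phase statistics (polar histograms,
wrapped mean phase differences, the Watson-Wheeler uniform-scores test,
progressive phase-delay assessment), two-condition differential-rhythm
categorization (abolished / dampened / increased / gained), harmonic
period-lock checks, AUC-based initiation/elongation metrics for coverage
tracks with bona fide rhythmic binding-site selection, and a synthetic-data
generator with full per-gene ground truth that makes the entire pipeline
testable end to end.

## Worked example

```r
library(rhythmpencil)
library(dplyr)

# one gene: a damped circadian rhythm superimposed with a smaller 12-h one
t <- seq(0, 46, by = 2)
x <- 5 + 2 * 0.95^(t/24) * cos(2*pi*(t - 8)/24) + 0.8 * cos(2*pi*(t - 1)/12)
pencil_decompose(x, dt = 2)
#> Matrix-pencil decomposition: 24 samples at dt = 2 h (L = 12, k = 3)
#>   mean 5, residual RMS 7.66497e-15
#>   component period decay amplitude phase peak_time
#>           1     24 0.950     2.00   4.19     8.00
#>           2     12 1.00      0.800  5.76     1.000
```

Both components are recovered exactly: the 24-h rhythm (decay 0.95,
amplitude 2, peaking at CT8) and the sustained 12-h rhythm (amplitude 0.8,
peaking at CT1).

```r
# a 500-gene synthetic control/knockout pair with known ground truth
spec <- synthetic_spec(n_genes = 500, seed = 42)
two  <- simulate_two_conditions(spec)

comps_a <- average_replicates(two$expression_a) |> decompose_genes()
comps_b <- average_replicates(two$expression_b) |> decompose_genes()

deltas <- categorize_rhythms(comps_a, comps_b, criteria_preset("liver_12h"))
cohort_summary(deltas)
#>   category      n fraction percent
#> 1 abolished    96   0.505     50.5
#> 2 dampened     51   0.268     26.8
#> 3 increased    26   0.137     13.7
#> 4 gained       17   0.0895     8.9

glance(estimate_fdr(average_replicates(two$expression_a),
                    criteria_preset("liver_12h"),
                    n_permutations = 100, seed = 1))
#>   criteria  observed permuted_mean permuted_sd   fdr undefined n_permutations
#> 1 liver_12h      173          37.6        20.0 0.218 FALSE              100
```

Of the genes with a 12-h rhythm in either condition, half lost it outright
in the knockout and a quarter kept a dampened version — close to the
generator's 54.5/31.6/13.9 effect mix, with the residual misclassification
coming from the noise. 173 genes are called 12-h rhythmic in the control,
against a mean 37.6 false positives across 100 label permutations, an
estimated FDR of 0.22 for the class.

The methods vignette
(`vignettes/rhythm-detection-methods.Rmd`) documents the model, the
parameter conventions (per-cycle decay, biological phase), the permutation
scheme, the generator's design choices, and known limitations.

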