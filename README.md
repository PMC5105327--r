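# circaphase

Estimating and comparing the circadian phase of gene expression across
tissues, datasets and species.

Mammalian organs each run a circadian clock, and the expression phase of
the core clock genes (ARNTL, DBP, NR1D1, NR1D2, PER1, PER2, PER3) is an
accurate readout of a tissue's internal time. Comparing those phases
across tissues — say, human blood sampled repeatedly through the day
versus postmortem brain with one circadian time per donor — requires a
chain of steps that are easy to get subtly wrong: removing subject-,
area- and dataset-level batch effects without destroying the circadian
signal, fitting a periodic mean curve, deciding which genes are rhythmic
enough to trust, and doing all phase arithmetic on a circle where CT23
and CT1 are two hours apart. circaphase packages that chain for R users
working with time-stamped expression matrices.

## The model

For each gene *j* within one dataset, a cyclic cubic spline f<sub>j</sub>(t)
(period 24 h, three evenly spaced knots, ordinary least squares) is fit
to log-scale expression against circadian time, and summarized by

- peak time = argmax f<sub>j</sub>(t), trough time = argmin f<sub>j</sub>(t),
- SNR<sub>j</sub> = (max f<sub>j</sub> − min f<sub>j</sub>) / s<sub>j</sub>,
  with s<sub>j</sub> the root-mean-square residual; genes with
  SNR > 1 count as clearly rhythmic.

Phases are compared with circular statistics: signed differences in
(−12, 12], absolute differences in [0, 12], and group means via the
circular mean t̄ = (24/2π)·atan2(Σ sin(2πtᵢ/24), Σ cos(2πtᵢ/24)).
A Monte-Carlo module measures the estimator's peak-time accuracy, and a
synthetic-study generator produces multi-organ, multi-dataset studies
with known ground truth (organ phase offsets, subject and dataset
effects, an age-dependent phase advance, dense and one-time-per-subject
sampling designs).

## Worked example

Generate a two-organ study whose brain clock is offset by 8.5 h, fit
phases per dataset after batch adjustment, and compare the organs:

```r
library(circaphase)

cfg <- study_config(
  organs = data.frame(organ = c("blood", "brain"), phase_offset = c(0, 8.5)),
  datasets = list(
    list(dataset_id = "blood1", organ = "blood",
         n_subjects = 12, n_samples = 120),
    list(dataset_id = "brain1", organ = "brain",
         n_subjects = 30, n_samples = 120,
         sampling = "one_per_subject", age_mean = 52, age_sd = 15)),
  seed = 42)
study <- generate_study(cfg)

blood_sel <- study$samples$dataset_id == "blood1"
blood_x <- batch_adjust(study$expression[, blood_sel],
                        study$samples$subject_id[blood_sel])  # by subject
blood <- estimate_phases(blood_x, study$samples[blood_sel, ],
                         genes = default_clock_panel()$gene_id)
print(blood)
#> Phase estimates: 7 rhythmic, 0 excluded, 0 not measured
#>  gene_id dataset_id organ  peak_time trough_time      snr n_samples
#>    ARNTL     blood1 blood  0.1766411    12.43155 2.174242       120
#>      DBP     blood1 blood  7.9170570    19.79456 2.225126       120
#>    NR1D1     blood1 blood  8.8814075    21.80686 2.495845       120
#>    NR1D2     blood1 blood 10.0804585    23.04227 2.119607       120
#>     PER1     blood1 blood 11.1359494    23.63293 1.782454       120
#>     PER2     blood1 blood 13.0633735     0.46195 2.469396       120
#>     PER3     blood1 blood 15.3989324     2.66544 1.768195       120
```

The estimated peaks recover the configured gene phases (ARNTL at 0 h,
the others over 8–14 h) to within the estimator's precision at SNR ≈ 2.
Brain uses anatomical area as the batch (one circadian time per subject
— correcting by subject would erase the rhythm):

```r
brain_sel <- study$samples$dataset_id == "brain1"
brain_x <- batch_adjust(study$expression[, brain_sel],
                        study$samples$batch_id[brain_sel])    # by area
brain <- estimate_phases(brain_x, study$samples[brain_sel, ],
                         genes = default_clock_panel()$gene_id)

print(compare_groups(blood$estimates, brain$estimates, "blood", "brain"))
#> Phase comparison blood vs brain: |dpeak| = 8.51 +/- 0.66 h (M +/- SD; median 8.29 h; 7 pairs)
```

The pooled pairwise absolute phase difference, 8.51 h, recovers the
configured 8.5-h organ offset. How precise is a single peak estimate?

```r
print(run_accuracy_sim(sim_condition(n_obs = 200, expected_snr = 2,
                                     n_sim = 200, seed = 1)))
#> Peak-time accuracy: n_obs=200, SNR=2, 200 replicates
#>   central-95% error interval: width 1.883 h (+/- 0.942 h)
```

So with 200 samples at SNR 2 (typical for human datasets), peak times
carry a 95% margin of roughly ±1 h — small against an 8.5-h organ
difference.

`run_pipeline()` chains these steps (validation, per-dataset adjustment
and fits, relative phases, group comparisons, group circular means) from
a YAML or list config and writes TSV tables plus a JSON manifest;
reruns are byte-identical. See the methods vignette
(`vignettes/circadian-phasing-methods.Rmd`) for the model, numerical
choices and known limitations.

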