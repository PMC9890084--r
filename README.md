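# aifnet

Neural correction of arterial input function (AIF) saturation for
quantitative stress perfusion cardiac MR, with a complete myocardial blood
flow (MBF) quantification pipeline and a physics-based synthetic
dual-sequence data generator.

## The problem

Quantitative first-pass perfusion CMR estimates MBF by deconvolving the
myocardial tissue curve with the arterial input function sampled in the LV
blood pool. The saturation-recovery signal

    S = g · (1 − exp(−TS · R1)),   R1 = 1/T1_0 + r1 · C

is concave in gadolinium concentration *C*, so at the standard saturation
time (TS = 100 ms) the AIF peak is strongly compressed and the linear
relative-enhancement conversion

    C(t) = (S(t) − S(0)) / (r1 · T1b · S_LV(0))

under-reads it, biasing MBF. Dual-sequence protocols add a short-TS
(23.5 ms) AIF image with little saturation, but are not generally
available. `aifnet` takes the alternative route: a 1D U-Net (five
resolution steps, two conv–batchnorm–ReLU–dropout blocks per step, global
residual connection) learns the mapping from the saturated AIF of a
standard acquisition to its unsaturated counterpart, using paired
dual-sequence curves for supervision. Downstream, MBF is estimated by
Fermi-function-constrained deconvolution

    C_t(t) = (MBF/60) ∫ C_a(τ − δ) · R(t − τ) dτ,
    R(u) = (1 + e^(−k·τ0)) / (1 + e^(k·(u − τ0)))

with segment/vessel classification at the 1.35 mL/min/g stress-MBF
threshold, and the two AIF routes are compared with NMSE, curve shape
metrics (PV/TTP/FWHM), Mann–Whitney tests, Bland–Altman agreement and
diagnostic agreement. A synthetic cohort generator (gamma-variate boluses,
Fermi tissue kinetics, both saturation times rendered through the signal
model, calibrated to clinical stress-AIF shape statistics) makes the whole
method trainable and testable with no patient data. The package is aimed
at perfusion-quantification researchers who want a transparent, fully
seeded reference implementation of this training-and-evaluation loop.

## Worked example

```r
library(aifnet)

# Fermi deconvolution recovers ground truth on a noiseless forward curve
aif    <- gen_aif_concentration(
  gamma_variate_params(t0 = 4, alpha = 2.5, beta = 1.5, peak = 3),
  seq(0, 45, by = 0.75))
tissue <- gen_tissue_curve(aif, fermi_kinetics(mbf = 2.4, tau0 = 4, k = 0.3, delay = 0.5))
fermi_deconvolve(aif, tissue)
#> <fermi_fit> MBF 2.400 mL/min/g (tau0 4.00 s, k 0.300 /s, delay 0.50 s), rss 1.71e-30

# A small end-to-end demonstration (a few minutes on one CPU;
# train_config(scaled = TRUE) is the package's full compact recipe)
cohort <- gen_cohort(cohort_config(n_subjects = 40, fractions = c(0.7, 0.1, 0.2), seed = 1))
model  <- train_unet(cohort_pairs(cohort$train), cohort_pairs(cohort$val),
                     config    = unet_config(base_channels = 16),
                     train_cfg = train_config(iterations = 500, seed = 1))
model
#> <aif_model> 1D U-Net, depth 5, 678817 parameters; best val MSE 0.00735

evaluate_pipeline(cohort$test, model = model)
#> <aif_evaluation> 8 subjects, 128 segments
#>   median NMSE 2.90% (uncorrected 7.59%)
#>   MBF bias 0.493 mL/min/g [LoA -0.664, 1.650]; segment agreement 92.2%
```

Reading the output: the network's predicted AIF is much closer to the
dual-sequence reference than the uncorrected saturated input (median NMSE
2.90% vs 7.59% on held-out subjects even in this 500-iteration demo), and
the MBF values quantified from the predicted AIF agree with those from the
reference AIF for 92% of AHA segments at the diagnostic threshold. With
the full compact recipe (2 000 iterations, 200 training subjects — what
the tests and acceptance script run) the median NMSE drops well below 1%
and the Bland–Altman bias to roughly 0.1–0.2 mL/min/g. `tidy()`/`glance()` give
tabular access to every result object, and `autoplot()` draws the
Bland–Altman and training-history figures.

There is also a command-line shell over the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/aifnet.R", package = "aifnet"))')
Rscript $CLI simulate --n 20 --seed 1 --out cohort/
Rscript $CLI train    --cohort cohort/ --seed 1 --out model.rds
Rscript $CLI evaluate --cohort cohort/ --model model.rds --out report/
```

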