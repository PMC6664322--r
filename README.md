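# twostepfit

Simulation, model fitting, and statistical analysis for two-step
sequential decision experiments with a working-memory co-task, aimed at
within-subject (e.g. neurostimulation) designs with three conditions.

Human choice in the two-step task mixes two controllers: a *model-free*
(habitual) system updating cached action values with reward prediction
errors, and a *model-based* (goal-directed) system planning through the
task's transition structure. The package implements the standard hybrid
learner — stage-wise softmax reliabilities β₁, β₂, learning rates α₁, α₂,
eligibility λ, a perseveration rate, and the mixture weight **w ∈ [0, 1]**
(0 = habitual, 1 = goal-directed) — and estimates each subject's
parameters by maximum likelihood:

- stage 2 (SARSA): `Q2(s,a) += α₂ (r − Q2(s,a))`
- stage 1, model-free: `QMF(a) += α₁ (Q2(s,a₂) − QMF(a)) + α₁ λ δ₂`
- stage 1, model-based: `QMB(a) = Σ_s P(s|a) max_a' Q2(s,a')`
- choice: softmax over `β₁ [w·QMB + (1−w)·QMF] + persev·rep(a)`

Around the model sit: a task engine (Gaussian-random-walk reward
probabilities with reflecting bounds, 0.7/0.3 transitions, 67-trial
sessions), a delayed-estimation working-memory analysis (circular SD of
orientation errors on the period-π circle; precision = 1/SD), a
statistical battery (RM-ANOVA with an order covariate, planned paired
contrasts with dual effect sizes, exact Wilcoxon signed-rank by full sign
enumeration, rank ANCOVA, ICC(3,k), Bayesian correlation log BF₁₀,
noncentral-t power analysis, stay-probability logistic signatures,
rare-transition RT slowing), and a synthetic-cohort generator with sealed
ground truth for recovery and calibration studies.

## Worked example

Simulate a 29-subject cohort (three counterbalanced stimulation
conditions; the IPS→LPFC condition carries a +0.15 shift of true w), fit
every subject × condition session, and run the analysis battery:

```r
library(twostepfit)

report <- run_pipeline(run_config(
  mode = "full", output_dir = "demo_run",
  cohort = cohort_config(master_seed = 42),
  fit = fit_settings(n_restarts = 6),
  seed = 42, verbose = FALSE))

report$descriptives_w
#>    condition  n      mean    median        sd        skew
#>      control 29 0.4068076 0.5162845 0.3374905 -0.03478985
#>  LPFC_to_IPS 29 0.3053744 0.2732747 0.2775679  0.46012957
#>  IPS_to_LPFC 29 0.4314321 0.4388573 0.3362452  0.12472428

report$anova_w
#>           effect df1 df2         F         p
#>            order   2  26 0.5618673 0.5769128
#>        condition   2  52 1.5844868 0.2147927
#>  condition:order   4  52 0.3918715 0.8135165

report$contrast_ips_vs_control
#> [paired_t] statistic=0.3202 df=28 p=0.7512 mean_diff=0.02462
#>            dz=0.05946 r_t=0.0604 r_z=0.06814 n=29

report$icc_w
#> [icc_3k_consistency_average] icc=0.4708 statistic=1.89 df1=28 df2=56
#>                              p=0.02154
```

Reading the output: fitted w averages ~0.3–0.43 per condition with the
expected right skew in the ground truth; the condition RM-ANOVA (df 2, 52
with the order covariate retained) and the planned IPS→LPFC-vs-control
contrast are *not* significant in this particular replicate even though
the generative shift is real — a single 67-trial session measures w with
substantial error, so a +0.15 shift is detected in only a minority of
cohorts (the methods vignette quantifies this). The ICC line shows the
subjects' relative standing in w is moderately consistent across the
three sessions. The working-memory ANOVA in the same report shows the
dominant set-size effect on log precision (`report$anova_wm`), and
`report$ratio_correlation$bayes` gives the log BF₁₀ for the Δw–Δp
association (−0.84 here: evidence for the null).

The power calculation behind the design's sample size:

```r
solve_n(dz = 0.7, power = 0.95, alpha = 0.05)
#> [1] 29
```

A command-line entry point with the same stages
(`simulate | fit | analyze | full`) is installed at
`system.file("cli", "twostepfit.R", package = "twostepfit")`.

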