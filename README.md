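# proxbias

Observer-proximity bias in animal social association networks.

## The problem

Social network analysis of wild animal groups usually rests on direct
observation of habituated animals: an observer follows a focal individual
and records which group members are within a set of proximity buffers
(here 5 m, 2.5 m, 1 m, and touching). This assumes the observer is a
neutral stimulus. But even in well-habituated groups, individuals differ
consistently in how close they let an observer approach — their
*displacement tolerance*, assayed by flight initiation distance (FID). If
intolerant animals relocate when the observer is near, they are
under-sampled as neighbours exactly when the observer works at close
range, and the measured association network becomes a function of where
the observer stood.

`proxbias` implements the full analysis chain for quantifying this bias,
together with a mechanistic simulator of observer-induced displacement so
that every stage can be validated against known ground truth:

1. **simdata** — simulates a habituated group (default 65 individuals):
   repeatable log-normal flight thresholds, affinity-structured spatial
   positions, an observer at a log-normal end distance, and explicit
   displacement geometry (a neighbour closer to the observer than its
   realized threshold relocates radially away until its observer distance
   equals the threshold).
2. **fid model** — Gaussian mixed model on log FID
   (`y_ij = mu + u_i + e_ij`, `u_i ~ N(0, s2_id)`), REML via `lme4`;
   per-individual conditional modes (BLUPs) by closed-form
   empirical-Bayes shrinkage
   `mode_i = n_i s2_id / (n_i s2_id + s2_res) * dbar_i`; repeatability
   `ICC = s2_id / (s2_id + s2_res)`. Tolerance is the negated mode (high
   = tolerant).
3. **sampling** — splits focals into close/far strata at the median end
   observer distance (close inclusive), down-samples to an even number of
   focals per individual per year, and counts how often each individual
   occurs as a neighbour of the other n−1 group members per
   (buffer × stratum × year) cell, with exposure = focals of the others.
4. **occurrence model** — Poisson regression of the counts on the
   stratum × tolerance × year factorial with a log-exposure offset
   (own IRLS implementation), uncertainty by a cluster bootstrap over
   individuals (default) or a random-slope Poisson GLMM (`glmmTMB`);
   summaries in the Bayesian-workflow style: 89% highest density
   interval, fraction of the HDI in the ROPE [−0.1, 0.1], probability of
   direction (pd), and Bayesian R².
5. **networks** — proportion-weighted symmetric association matrices
   (`weight_ij = count_ij / (f_i + f_j)`), Mantel permutation tests
   (Spearman, 999 joint row/column permutations, one-sided with the
   add-one rule), and weighted degree/closeness/betweenness centralities
   (weights treated as distances) with close-vs-far rank concordance.

## Worked example

```r
library(proxbias)

cfg   <- group_config(seed = 42)        # 65 animals, displacement on
study <- simulate_study(cfg)

fit <- fit_fid_model(study$approaches)  # REML on log FID
icc(fit)
#> 0.66
tol <- conditional_modes(fit)
head(tol, 3)
#>   individual_id n_obs       mode        sd  tolerance
#> 1          ID01    24  1.0383281 0.1272643 -1.0383281
#> 2          ID02    24 -0.4214290 0.1272643  0.4214290
#> 3          ID03    24  0.2414289 0.1272643 -0.2414289

foc <- split_by_distance(study$focals)            # close <= median < far
foc <- downsample_focals(foc, cfg$year_plan, seed = 43)
cnt <- count_all_occurrences(foc)

occ <- fit_occurrence_model(cnt[cnt$buffer == "n5", ], tol,
                            n_draws = 1000, seed = 44)
occ
#> Occurrence model (n5 buffer, backend = bootstrap, 1000 draws)
#> Bayesian R2: 0.39 (0.12)   Pearson dispersion: 4.77
#>                             term estimate  hdi_low hdi_high rope_fraction    pd
#>                      (Intercept)   -3.344   -3.427   -3.264         0.000 100.0
#>                     stratumclose   -0.093   -0.150   -0.039         0.589  99.2
#>                        tolerance    0.081   -0.032    0.186         0.635  86.8
#>                         year2019    0.058    0.017    0.102         0.991  98.8
#>           stratumclose:tolerance    0.086    0.024    0.160         0.625  98.6
#>  ...
```

The positive `stratumclose:tolerance` interaction (pd = 98.6%) is the
bias signature: tolerant animals are over-represented as neighbours only
when the observer is inside the median working distance. The tolerance
main effect (the far stratum) stays neutral.

```r
m_close <- build_association_matrix(foc, "n5", "close", "2018")
m_far   <- build_association_matrix(foc, "n5", "far",   "2018")
mantel(m_close, m_far, n_perm = 999, seed = 45)
#> Mantel r = 0.185, p = 0.001 (spearman, 999 random permutations)

compare_centralities(centralities(m_close), centralities(m_far))
#>        metric        rho df            p defined
#> 1      degree  0.2003157 63 1.096156e-01    TRUE
#> 2   closeness -0.8030594 63 8.473569e-16    TRUE
#> 3 betweenness -0.8909135 63 2.844027e-23    TRUE
```

Despite being built from the same animals over the same weeks, the close
and far networks agree only weakly (Mantel r = 0.19) and individuals do
not keep their network positions across observation distances.

`run_pipeline(pipeline_config(simulate = group_config(seed = 1)))` runs
all of the above (4 occurrence models, 16 matrices, 8 Mantel tests, 24
concordance correlations) in one call and can write every table as CSV
with a hash manifest.

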