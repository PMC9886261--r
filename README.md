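# actifrail

Physical-function monitoring for older adults from a single trunk-worn
device. `actifrail` turns 24-hour recordings of tri-axial acceleration
(50 Hz, in g) and barometric pressure/temperature (5 Hz, mbar/K) into nine
daily physical-function features, screens and scales them at cohort level,
and evaluates how well they separate frail from robust wearers under
daily and longitudinal decision designs. It is aimed at researchers in
digital health and geriatrics who want a fully scripted, testable version
of this monitoring pipeline, including a synthetic-data generator that
stands in for clinical recordings.

## The features

For one subject-day with acceleration magnitude `||a|| = sqrt(ax²+ay²+az²)`
cut into 30-s windows:

| Feature | Meaning |
|---|---|
| G1 | activity rate: fraction of windows with demeaned rms > 0.03 g |
| G2 | sleep calmness: % of the overnight lying span spent in still ≥ 5-min "sleep cycles" |
| G3 | steps: band-passed magnitude peaks in standing + active windows |
| G4 | periodicity rate: % of the observed day in windows whose autocorrelation has ≥ 3 peaks > 0.3 |
| G5 | gait period T_p (s): mean autocorrelation peak spacing of periodic windows |
| G6 | weightlessness time (s): `\|\|a\|\| < 0.3 g` intervals (airborne phases) |
| G7, G8 | lift and stair counts from barometric altitude `H = T/0.0065·(1−(P'/1013.25)^0.19)`: monotone runs ≥ 6 s with slope 0.6–0.9 m/s while still (lift) or 0.25–0.6 m/s while active (stairs) |
| G9 | energy expenditure: Σ MET × duration(h) × weight(kg), weight-normalised by default (kcal/kg) |

Cohort analysis averages days per subject, retains features by a
two-sample Wilcoxon rank-sum screen (p < 0.05), scales by z-score or
sigmoid `1/(1+exp(−(f−μ)/σ))`, and runs leave-subject-out (LSO)
cross-validation of five classifiers (NN, SVM-RBF, kNN, random forest,
gradient boosting) under three designs: daily prediction, 5-day feature
averaging, and 5-day majority voting.

## Worked example

Generate one synthetic robust day, extract its features, and compare with
the generator's ground truth:

```r
library(actifrail)

g  <- generate_day(robust_profile(), seed = 11)
ex <- extract_day(g$recording)
round(unlist(ex$features[paste0("G", 1:9)]), 3)
#>       G1       G2       G3       G4       G5       G6       G7       G8       G9
#>    0.200   99.500 4244.000    3.125    1.180    0.000    4.000    0.000   28.965
round(unlist(g$truth$features[paste0("G", 1:9)]), 3)
#>       G1       G2       G3       G4       G5       G6       G7       G8       G9
#>    0.200   99.500 4220.000    3.125    1.180    0.000    4.000    0.000   28.965
```

The wearer was active in 20% of windows, slept calmly (99.5%), took about
4.2k steps at a 1.18-s gait period with 3.1% of the day in periodic
movement, rode the lift four times, and burned ≈ 29 kcal/kg — and every
extracted value matches the injected truth (steps within 0.6%).

A cohort-level run:

```r
co  <- generate_cohort(seed = 1)               # 9 frail + 9 robust subjects
sel <- rank_sum_select(subject_means(co$features))
sel$feature[sel$retained]
#> [1] "G3" "G4" "G5" "G8" "G9"

x   <- as.matrix(co$features[, sel$feature[sel$retained]])
rep <- evaluate_designs(x, co$features$label, co$features$subject,
                        co$features$date,
                        models = list(model_spec("NN", seed = 7),
                                      model_spec("RF", seed = 7),
                                      model_spec("GBM", seed = 7)))
rep[, c("model", "design", "sensitivity", "specificity", "accuracy")]
#>   model      design sensitivity specificity accuracy
#> 1    NN       daily       89.42       91.86    90.63
#> 2    RF       daily       94.55       96.42    95.48
#> 3   GBM       daily       94.55       97.72    96.12
#> 4   GBM averaging-5       67.80      100.00    83.90
#> 5   GBM    voting-5       98.31      100.00    99.15
#> 6    RF averaging-5       67.80       96.61    82.20
#> 7    RF    voting-5       98.31      100.00    99.15
#> 8    NN averaging-5       98.31       98.31    98.31
#> 9    NN    voting-5       98.31       98.31    98.31
```

Steps (G3), periodicity rate (G4), gait period (G5), stair use (G8) and
energy expenditure (G9) are retained; activity rate, sleep calmness and
lift use are not (on some cohort draws one of the boundary features also
crosses p = 0.05). Daily accuracy sits in the 90s, 5-day majority voting
raises it further, and 5-day feature averaging trades a large share of
the sensitivity away for specificity — the reason a voting-based
longitudinal design is the recommended alerting mode.

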