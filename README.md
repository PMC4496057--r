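# reefpoint

Percent-cover estimation of benthic substrata from random point
annotations of survey photoquadrats, with semi- and fully-automated
annotation modes.

## The problem

Reef monitoring programs estimate the cover of corals, algal functional
groups and other substrata by superimposing random points on survey
images and having experts label each point; the cover of label *m* in
image *i* for annotator *a* is the fraction of points carrying it,
c<sub>i</sub><sup>a</sup>(m). Manual annotation is the bottleneck:
automated patch classifiers are fast but less accurate than experts.
`reefpoint` is a toolkit for the whole trade-off, aimed at benthic
ecologists and the computer-vision people who support them:

* **Data model & processing** — ordered label sets with functional
  groups Ψ and dataset-scoped remaps; annotation tables (CSV in/out);
  the transect-hardware majority rule; reference-pool rebalancing that
  raises a focal group's proportion by a stated relative fraction.
* **Automated annotator** — pluggable patch encoder (color statistics +
  oriented gradient-energy histograms by default) and a one-versus-rest
  linear SVM reduced to affine scoring rules s<sub>m</sub>(x) =
  w<sub>m</sub>ᵀx + b<sub>m</sub>, with a per-point score vector over
  all labels.
* **Operational modes** —
  * *deferral* (semi-automated): keep the automated label where
    max[s<sub>i,k</sub>] > ε, defer to the human otherwise; the level of
    alleviation λ(ε) is the automated fraction and thresholds are picked
    from the achievable step function;
  * *cover correction* (fully automated): per-image covers corrected by
    the inverse-transpose of a cross-validated confusion matrix,
    c<sup>corrected</sup> = (Q′)<sup>−T</sup> c<sup>auto</sup> —
    unbiased, with larger variance;
  * *suggestion*: top-k (default 5) ranked labels per point.
* **Evaluation** — Cohen's κ and binary group κ_Ψ, annotator confusion
  matrices, per-image cover differences d, bias e, MAE, one-sample
  sign-flip permutation t-tests (exact for n ≤ 12, Bonferroni threshold
  0.05/8 = 0.00625 by default) and percentile-t bootstrap intervals.
* **Synthetic generators** — Voronoi texture mosaics with exact
  pixel-level ground truth, simulated annotators drawn from confusion
  matrices, and simulated score matrices whose maxima are informative of
  correctness — so the full pipeline is testable without field data.

## Worked example

The bundled workflow generates mosaic imagery, trains the classifier on
a reference set, scores a held-out evaluation set, runs all three modes
and evaluates them against the ground truth:

```r
library(reefpoint)
cfg <- run_config(seed = 1)
report <- run_end_to_end(cfg)
cat(sprintf("automated kappa: %.3f\n", report$kappa$automated))
cat(sprintf("host kappa:      %.3f\n", report$kappa$host))
cat(sprintf("alleviate kappa: %.3f (level %.2f, epsilon %.2f)\n",
            report$kappa$alleviate, report$alleviate$level,
            report$alleviate$epsilon))
print(report$alleviation_curve, digits = 3)
```

```
automated kappa: 0.961
host kappa:      0.876
alleviate kappa: 0.946 (level 0.50, epsilon 5.05)
  level achieved_level epsilon kappa
1  0.00           0.00    7.52 0.876
2  0.25           0.25    6.03 0.923
3  0.50           0.50    5.05 0.946
4  0.75           0.75    3.68 0.961
5  1.00           1.00   -2.77 0.961
```

Reading this: the simulated host annotator agrees with ground truth at
κ = 0.876; on these well-separated synthetic mosaics the classifier is
even better (κ = 0.961), so the deferral curve *rises* with automation —
on real imagery the curve falls and the interesting question is how much
automation keeps the drop under 5%. The curve endpoints are exactly the
human-only and automated-only kappas. `report$cover_bias` holds the
per-label cover bias e of each annotation mode against the reference,
and `report$mae` its absolute mean per mode.

A shell interface covering simulate/train/annotate/alleviate/abundance/
refine/evaluate/sweep lives in `inst/cli/reefpoint` (installed under
`system.file("cli", "reefpoint", package = "reefpoint")`), a thin
wrapper over `reefpoint_cli()`.

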