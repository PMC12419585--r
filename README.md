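# boolgrn

Boolean regulatory-network dynamics from two-group RNA-seq counts.

## What problem this solves

Small-n two-condition transcriptome studies — four control versus four
treated animals is typical — often want more than a list of differentially
expressed genes: they want a mechanistic picture of how the perturbation
(say, a high-fat diet) pushes a regulatory system from one stable activity
pattern to another. `boolgrn` is for analysts who want to take such a count
matrix all the way to a discrete dynamical model and interrogate it:

- normalize counts with **median-of-ratios size factors**
  (`size_factors()`, with a mean–SD diagnostic in `mean_sd_trend()`);
- call DEGs with an **empirical-Bayes moderated t**: per-gene variances
  s² with d residual df are shrunk via hyperparameters (d₀, s₀²) fitted by
  method of moments on log s², giving
  t = Δmean / (s̃ √(1/n₁+1/n₂)) with s̃² = (d₀s₀² + d s²)/(d₀+d) and d₀+d
  df (`moderated_t()`), then gate on p < α and |log₂FC| > 1.5
  (`classify_degs()`);
- infer a **directed network** by per-target random-forest importance
  (total split variance reduction, normalized per target;
  `genie3_importances()`, `threshold_edges()`);
- compile the network into **Boolean update rules** by exact 1-D
  two-cluster binarization plus best-fit truth-table learning
  (`binarize()`, `fit_boolean_rule()`, `build_boolean_model()`);
- analyse the **synchronous dynamics** exactly: every state's successor,
  all attractors with basin sizes, oscillating gene sets of limit cycles,
  and clamped-gene perturbations modelling over-expression (1) and
  knockout (0) (`successor()`, `enumerate_attractors()`, `perturb()`,
  `report_cycles()`);
- summarize the **topology** (hubs, mean degree 2E/N, density E/(N(N−1)),
  closeness, betweenness, degree entropy; `compute_metrics()`).

A planted-truth synthetic generator (`generate_network()`,
`simulate_expression()`) emulates the whole study design — a Boolean
network drives latent on/off states sampled at attractors, emitted as
negative-binomial counts with library-size variation — so every stage is
testable against a known ground truth (`score_recovery()`).

## Worked example

```r
library(boolgrn)

# plant a 12-gene network; treat the "HFD" group by clamping g01 on, g04 off
net   <- generate_network(12, mean_in_degree = 1.5, max_in_degree = 2, seed = 42)
truth <- ground_truth(net, clamp_spec = c(g01 = 1L, g04 = 0L),
                      n_control = 40, n_treated = 40, seed = 43)
sim   <- simulate_expression(truth)
sim$counts
#> count_matrix: 12 genes x 80 samples (40 ND, 40 HFD)

report <- run_pipeline(pipeline_config(sim$counts, out_dir = "run42",
                                       n_trees = 500, seed = 43))
report
#> run_report: 12 genes, 80 samples; DEGs up/down = 3/1
#>   network: 12 nodes, 24 edges; attractors baseline/perturbed = 3/1

report_cycles(report$attractors_baseline)
#>   attractor length basin     oscillating
#> 1         1      2  1024 g01,g03,g05,g09
#> 2         2      1   512
#> 3         3      1  2560

round(unlist(score_recovery(report, truth)), 3)
#>         edge_aupr        prevalence    rule_agreement attractor_jaccard
#>             0.204             0.114             0.573             0.000
```

Reading the output: the fitted model's baseline dynamics settle into three
attractors — one a two-state limit cycle in which `g01`, `g03`, `g05` and
`g09` oscillate (basin: 1024 of the 4096 states) — while the perturbed
(clamped) system collapses to a single attractor, the qualitative signature
of a forcing intervention. The recovery scores compare the run against the
planted truth: the edge ranking (AUPR 0.204 vs a 0.114 no-skill
prevalence) and rule agreement (0.573) quantify how little *directed
structure* purely observational steady-state snapshots carry — see the
vignette's discussion of why attractor-only sampling limits structure
discovery — even though the downstream dynamics machinery is exact.

Every stage writes its artifact (size factors, DEG table, edge lists, rule
file, attractor JSONs, metrics, run report) into `out_dir`, each stamped
with the seed and a config hash.

## Documentation

The methods vignette (`vignettes/boolean-network-pipeline.Rmd`) documents
the statistical models, every tunable with its default and rationale, the
generator's scope and its known structural limitation, and the numerical
conventions (state encoding, tie-breaks, tolerances).
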