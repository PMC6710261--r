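# ptscam

Cam-mechanism analysis of the primate talus: geometric measurement of the
posterior trochlear shelf (PTS), a kinematic model of its effect on the
flexor fibularis tendon, and phylogenetic comparative inference over
euarchontan trees.

## The problem and who this is for

The PTS is a bony extension on the posterior talar body that diagnoses
crown primates but whose function has been contested. Treating the talus
as the driver of a **cam mechanism** — the PTS as the cam's *rise*, the
flexor fibularis tendon (running in a groove on the posterior talus, and
flexing the grasping digits) as the *follower* — gives the feature a
testable biomechanical role: a developed rise lengthens the tendon's path
in dorsiflexed foot postures, passively tensioning the digital flexors
exactly when an animal grasps a vertical support. `ptscam` is for
evolutionary morphologists who want to quantify that mechanism from 3-D
bone scans and trace its evolutionary history on phylogenies that may
include fossil tips.

The core quantity is the **PTS index**,

```
PTS index = Axis to Groove / Radius
```

where *Radius* is the radius of the best-fit cylinder to the lateral
tibial facet (the cylinder axis models the talocrural joint axis and its
radius the cam's base circle) and *Axis to Groove* = Radius + the signed
distance from the flexor-fibularis-groove landmark to the cylinder
surface. An index of 1 means no rise beyond the base circle; indices
above 1 indicate a developed cam.

Around that measurement the package implements, end to end:

* mesh I/O (ASCII PLY/OBJ/STL + JSON region sidecars), orthogonal
  least-squares cylinder fitting, curvature-based saddle-point
  landmarking (`fit_cylinder()`, `locate_ffg_landmark()`,
  `measure_specimen()`);
* a 2-D cam-follower model of tendon path length across ankle flexion
  (`cam_profile()`, `tendon_path_length()`, `cam_excursion()`);
* BM-family evolutionary models with Pagel's delta/kappa/lambda
  transforms, ML and MCMC fitting, stepping-stone marginal likelihoods,
  log Bayes factors, and Bayesian ancestral state reconstruction
  (`fit_ml()`, `mcmc_sample()`, `stepping_stone()`, `compare_models()`,
  `reconstruct_ancestors()`);
* multi-regime Ornstein–Uhlenbeck fitting with a stepwise forward
  (shift-adding) and backward (convergence-collapsing) search, plus
  genus-level consolidation (`fit_hansen()`, `surface_forward()`,
  `surface_backward()`, `genus_consolidate()`);
* clade statistics: one-sample t against index 1, pairwise ANOVA, OLS and
  PGLS regression (`one_sample_t()`, `anova_pairwise()`, `ols()`,
  `pgls()`);
* a synthetic-data generator producing talus-like meshes with known
  geometry and traits simulated under BM/OU, so the whole chain is
  testable offline (`make_synthetic_talus()`, `simulate_tree()`,
  `simulate_bm()`, `simulate_ou()`);
* a pipeline orchestrator with config validation and a JSON run manifest
  (`run_pipeline()`, `validate_config()`), and a thin CLI at
  `inst/cli/ptscam.R`.

Results are tibbles or small S3 objects with `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

Measure a synthetic talus with a known shelf (radius 3 mm, groove saddle
1.5 mm beyond the base circle, so the true index is 1.5), feed the index
into the cam model, and reconstruct an ancestral state on a simulated
clade:

```r
library(ptscam)

tal <- make_synthetic_talus(synthetic_talus_spec(
  trochlea_radius = 3, shelf_offset = 1.5, mesh_resolution = 0.15))
m <- measure_specimen(
  tal$mesh,
  select_region(tal$mesh, ids = tal$truth$facet_vertex_ids),
  select_region(tal$mesh, ids = tal$truth$groove_vertex_ids),
  specimen_id = "demo", taxon = "Synthetic_taxon")
m
#> # A tibble: 1 × 7
#>   specimen taxon           radius groove_to_cylinder axis_to_groove pts_index
#>   <chr>    <chr>            <dbl>              <dbl>          <dbl>     <dbl>
#> 1 demo     Synthetic_taxon   3.00               1.50           4.50      1.50
#>   ln_pts_index
#>          <dbl>
#> 1        0.405
```

The fitted radius is the cam base circle and the index is recovered to
three decimals. The cam model turns the index into a tendon path-length
curve; for this specimen the path length peaks in dorsiflexion (+42°) with
a total excursion of ~0.10 mm under the default dimensionless geometry
(absolute excursions depend on that geometry; the ordinal statements —
more rise, more excursion, maximal when dorsiflexed — are the conclusions):

```r
curve <- cam_excursion(profile_from_index(m$pts_index, m$radius), n = 61)
attr(curve, "excursion")
#> [1] 0.1047693
attr(curve, "argmax_angle") * 180 / pi
#> [1] 42
```

Evolutionary inference on a simulated 24-tip clade (trait evolved with
delta = 0.5, i.e. change concentrated early):

```r
tr <- simulate_tree(24, seed = 2)
traits <- simulate_bm(tr, sigma2 = 0.05, root_state = 1.2,
                      transform = list(kind = "delta", value = 0.5), seed = 3)
chain <- mcmc_sample(tr, traits, scaling = "delta",
                     generations = 8000, burn_in = 2000, seed = 4)
tidy(chain)
#> # A tibble: 3 × 5
#>   term          estimate std.error hpd95_low hpd95_high
#>   <chr>            <dbl>     <dbl>     <dbl>      <dbl>
#> 1 root            1.07      0.191    0.721       1.46
#> 2 sigma2          0.0310    0.0227   0.00819     0.0696
#> 3 scaling_value   1.14      0.629    0.143       2.39

reconstruct_ancestors(tr, traits, chain,
                      nodes = list(root = tr$tip.label), seed = 5)
#> # A tibble: 1 × 5
#>    node label posterior_mean hpd95_low hpd95_high
#>   <int> <chr>          <dbl>     <dbl>      <dbl>
#> 1    25 root            1.08     0.670       1.44
```

The true root (1.2) sits inside the 95% HPD; the wide interval on the
scaling value is honest — delta is weakly identified at this tree size.

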