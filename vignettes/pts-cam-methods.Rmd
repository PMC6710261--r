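---
title: "Measuring and modelling the posterior trochlear shelf as a cam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling the posterior trochlear shelf as a cam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ptscam)
```

# The scientific problem

The posterior trochlear shelf (PTS) is a bony extension on the posterior
talar body that diagnoses crown primates, but whose function has long been
debated. `ptscam` implements a biomechanical reading of the PTS as the
*rise* of a cam mechanism: the talus is the driver rotating about the
talocrural (ankle) joint axis, and the tendon of the flexor fibularis —
which runs through a groove (FFG) on the posterior talus and flexes the
grasping digits — is the follower. If the groove sits farther from the
joint axis than the articular base circle, dorsiflexing the foot lengthens
the tendon's path and effectively tensions the digital flexors without
extra muscular work: a passive grasping aid for animals clinging to
vertical supports with strongly dorsiflexed feet.

The package covers the full analysis chain: (1) geometric measurement of
the **PTS index** from a bone surface mesh; (2) a 2-D kinematic model
quantifying the ordinal consequences of the rise; (3) phylogenetic
comparative inference — Brownian-motion (BM) models with Pagel transforms,
MCMC with stepping-stone marginal likelihoods, Bayesian ancestral state
reconstruction, and multi-regime Ornstein–Uhlenbeck (OU) fitting with a
stepwise regime-shift search; and (4) a synthetic-data generator that makes
every stage testable without any external downloads.

# The PTS index and its measurement protocol

Three measurements define the index:

* **Radius** — the radius of the best-fit cylinder to the lateral tibial
  facet (LTF). The cylinder's axis models the talocrural joint axis; its
  radius is the cam's base circle.
* **Groove to Cylinder** — the signed distance from a landmark in the FFG
  to the cylinder *surface*; negative when the landmark lies inside the
  cylinder.
* **Axis to Groove** — their sum, i.e. the landmark's distance from the
  joint axis.

$$\text{PTS index} = \frac{\text{Axis to Groove}}{\text{Radius}}$$

An index of 1 means the groove landmark lies on the curvature of the
facet; values above 1 indicate a developed cam rise. The natural log of
the index is computed and stored alongside, but all default analyses use
the raw index; a flag selects the transform where wanted.

**Cylinder fit.** `fit_cylinder()` minimises $\sum_i (d_i - r)^2$ over the
axis (point and direction) and radius, where $d_i$ is the orthogonal
distance of vertex $i$ to the axis. The radius is profiled out (the
optimal $r$ for a fixed axis is the mean $d_i$), leaving a 4-parameter
axis search started from the principal axes of the selected points with
deterministic quasi-random restarts as a fallback — partial arcs below
180° make the objective locally multimodal, so a single start is not
trusted. Convergence tolerance is `1e-10` on the objective. The fit is
unconstrained by the surface, so the cylinder need not touch the mesh.

**Groove landmark.** The FFG is almost always saddle-shaped (concave
mediolaterally, convex dorsoplantarly). Rather than reproduce the manual,
view-dependent protocol (rotating the bone until the groove's main axis is
orthogonal to the viewing plane and clicking the saddle), the package uses
a view-independent criterion: per-vertex principal curvatures are
estimated by local quadric fits over an adaptive neighbourhood (default
radius 3× the mean edge length — smaller neighbourhoods are unstable at
scan resolution), and the landmark is the vertex with $k_1 > 0 > k_2$
maximising $|k_1 k_2|$. When a groove is convex in both directions (a
documented rare morphology), saddle mode signals the condition and
`convex_max` mode takes the vertex of maximal mean curvature instead. A
manually chosen vertex id can override both modes for fidelity to the
original workflow.

Units are millimetres throughout; meshes in other units are rescaled at
load time (`read_mesh(scale = )`).

```{r measure}
tal <- make_synthetic_talus(synthetic_talus_spec(
  trochlea_radius = 3, shelf_offset = 1.5, mesh_resolution = 0.15))
measure_specimen(
  tal$mesh,
  select_region(tal$mesh, ids = tal$truth$facet_vertex_ids),
  select_region(tal$mesh, ids = tal$truth$groove_vertex_ids),
  specimen_id = "demo", taxon = "Synthetic_taxon")
```

# The cam model

`cam_profile()` abstracts the talus to its sagittal cross-section: a base
circle of the fitted radius plus a raised-cosine rise of height
$(\text{PTS index} - 1) \times r$ (a raised cosine is smooth and convex
enough to avoid tangency artefacts at the rise shoulders). The tendon is a
taut string from a proximal origin to a distal insertion that may not
cross the cam body; `tendon_path_length()` computes its length by
discretising the profile into a dense polygon (2048 segments by default)
and wrapping the string around the profile's convex hull when the straight
segment is blocked.

Two modelling choices deserve emphasis:

* **The endpoints are fixed and the profile rotates.** A rotating
  insertion would add a pulley term — present for any profile, circular or
  not — that carries no information about the rise. Holding both endpoints
  fixed isolates the cam effect proper: a circular profile then yields a
  path length exactly constant in the flexion angle, and all excursion is
  attributable to the rise.
* **Default geometry.** The source anatomy provides no tendon geometry, so
  the defaults are dimensionless multiples of the base radius: origin at
  $(1.1r, 10r)$ (proximal, just posterior to the trochlear margin),
  insertion at $(1.1r, -3r)$, rise centred at $-\pi/4$ so that
  dorsiflexion (positive angles) rotates the rise into the tendon path.
  The taut tendon clears the base circle by $0.1 r$, so a rise must exceed
  that clearance before it engages. Because the geometry is invented,
  only *ordinal* claims are treated as conclusions: more rise means more
  excursion, the maximum occurs in dorsiflexion, and sub-unit indices
  produce no cam effect. Absolute millimetre excursions are artefacts of
  the default geometry.

```{r cam}
curve <- cam_excursion(profile_from_index(1.5, 3), n = 61)
attr(curve, "excursion")          # total path-length change, mm
attr(curve, "argmax_angle") * 180 / pi  # maximal in dorsiflexion
```

The model is 2-D by construction; medial rotation of the talus during
dorsiflexion, lateral groove positions and PTS "twisting" are outside its
scope.

# Evolutionary models

## BM family and Pagel transforms

Continuous-trait evolution is modelled as a multivariate normal over the
tips: mean equal to the root state (plus a trend times root-to-tip length
under the directional model, identifiable only on non-ultrametric trees)
and covariance $\sigma^2$ times the shared-path-length matrix of the
(transformed) tree. The three Pagel transforms reshape that matrix:
$\delta$ powers node depths after normalising tree depth to 1 (so
$\delta$ is scale-free; $\delta < 1$ concentrates change early —
the signature of a trait that evolved rapidly at a radiation's base),
$\kappa$ powers branch lengths ($\kappa = 0$ is speciational change),
$\lambda$ scales internal branches ($\lambda = 0$ erases phylogenetic
signal). Zero-length branches receive a `1e-8` floor inside covariance
matrices only, and singular covariances get a documented `1e-10` ridge
with a warning.

## MCMC, stepping stones, and ancestral states

Priors are not dictated by the source analyses (they are unreported), so
the defaults are weakly informative and data-scaled: root
$\mathrm{N}(\bar x, 10\,\mathrm{sd}(x))$; $\sigma^2$ half-Cauchy scaled by
the variance of the phylogenetically independent contrasts; scaling
parameters uniform on $(0,3)$ for $\delta, \kappa$ and $(0,1)$ for
$\lambda$; trend $\mathrm{N}(0, 10\,\mathrm{sd}(x)/T)$. All are
configurable; exact posterior numbers therefore reproduce only
approximately, which is why parameter-recovery checks are phrased as
coverage statements rather than point equalities. The sampler is
Gibbs-within-Metropolis: the root (and trend) conditionals are conjugate
normals given the variance and scaling value and are drawn exactly, while
`log(sigma2)` and the scaling value take adaptive random-walk steps
(adaptation during burn-in only, so the retained chain is a valid Markov
chain). In calibration runs on plain-BM data the root's 95% HPD covers
the truth at nominal rates; when a weakly identified delta is co-estimated
the root interval inherits some of delta's uncertainty and coverage in the
package's recovery study sits right at the 80% line (15-17 of 20
simulations, depending on chain length and seed), which is reported as
measured.

The stepping-stone sampler estimates log marginal likelihoods along a
power posterior path from prior to posterior with stones spaced by
Beta(0.3, 1) quantiles (concentrating effort near the prior, where the
integrand changes fastest). Two independent replicate runs are built in
and their difference reported as the convergence diagnostic. Log Bayes
factors follow the doubled-difference convention
$2(\log \mathrm{ML}_i - \log \mathrm{ML}_j)$, with 2 the threshold for
positive evidence. Full-scale sampler settings (1000 stones × 10,000
generations; 20,050,000-generation reconstruction runs) are honoured as
configuration defaults, but the package's own studies run scaled-down
(64 stones × 2,000 generations for the conjugate calibration; 12,000
generations per recovery fit), sizes chosen so the whole validation suite
completes on a laptop while leaving Monte-Carlo error well inside the
stated tolerances.

Ancestral states are reconstructed per posterior draw: transform the tree
by the drawn scaling value, form the conditional normal of each node given
the tips under BM, sample, pool draws across two independent runs, and
report the mean with an empirical 95% highest-posterior-density interval.
At a tip the conditional is degenerate at the observed value.

## Multi-regime OU and the stepwise search

The Hansen model attracts each lineage towards the optimum
$\theta_{r}$ of the regime painted on its branch, with shared attraction
$\alpha$ and diffusion $\sigma^2$; the root state is fixed at the basal
regime's optimum by default, which makes the $\alpha \to 0$ limit exactly
BM. Likelihoods accept non-ultrametric trees (fossil tips are first-class
citizens). $\alpha$ is bounded in $[10^{-8}, 50/T]$; boundary hits are
flagged, not hidden. Optima are profiled by GLS and $\sigma^2$ in closed
form, leaving a one-dimensional search in $\log \alpha$.

The forward phase greedily adds the regime shift (on any branch) that most
improves AICc; the backward phase greedily merges regime pairs while AICc
improves, and regimes that end up sharing an optimum despite independent
origins are reported as convergent. The AICc parameter count is
`2 + #shifts + #distinct optima`: counting shifts and optima separately is
what makes a convergent merge profitable (one parameter saved, shifts
kept) and gives the backward phase a reward for deleting a shift outright
by merging a regime into its parent.

**A known limitation, stated plainly.** Stepwise AICc shift selection
overfits. A shift placed on a terminal branch can absorb that tip's
residual entirely, and the best such gain across all branches behaves like
the maximum of many half-chi-squared draws — typically 3–5 log-likelihood
units, which exceeds any AICc penalty with high probability. In the
package's own recovery study (64 tips, two disjoint clades shifted to a
shared high optimum against a low basal optimum), the true shift branches
are found first and the convergent merge is recovered reliably, but the
final model usually carries one to three extra singleton shifts. Users
should read the *first* accepted shifts and the convergence classes, not
the raw shift count. Genus-level consolidation (`genus_consolidate()`,
weighting species means by specimen counts by default, with an unweighted
option and a per-genus exception list) removes the short terminal branches
that attract many of these spurious shifts, and is how the method is meant
to be deployed on real assemblages.

# The synthetic-data generator

`make_synthetic_talus()` builds the two anatomical elements the protocol
touches — a partial cylinder of known radius (arc 120° by default) and a
saddle patch whose saddle point sits at a known signed offset from the
base circle (principal curvatures ±0.8 mm⁻¹ by default, a groove a
scanner can resolve) — tagged with vertex-id regions carried in a JSON
sidecar, since no mesh format has standard region labels. Noise is applied
along analytic vertex normals after tagging, mimicking scan roughness
without breaking topology; resolutions coarser than the curvature radii
are rejected because the saddle would be unresolvable. The generator makes
no attempt at realistic talar anatomy: passing its tests shows that the
measurement chain recovers known geometry, not that region segmentation
on a real, unlabelled talus would succeed — on real data the LTF/FFG
selections are inputs.

Trees are pure-birth (`ape::rphylo`), made non-ultrametric by truncating
pendant branches by a uniform fraction in (0.2, 0.8) — the simplest
fossil-tip generator. Trait simulators draw branchwise Gaussian increments
(BM, with transforms applied to the tree first) or exact OU transitions
(child ∼ N(θ + (parent − θ)e^{−αt}, σ²(1 − e^{−2αt})/2α)); every
generator takes an explicit integer seed and records it in its output.

Simulation study sizes in the validation suite — 20 datasets of 128 tips
for parameter recovery, 20 of 64 tips for regime-shift recovery, 100
random trees of ≤ 16 tips for likelihood-oracle agreement — were chosen
once, as the smallest sizes at which the corresponding statistical
statements are stable across seeds.

# Numerical choices, degenerate inputs, open decisions

* Coincident vertices are merged and zero-area faces dropped at mesh load;
  empty meshes are errors.
* Selections under six vertices are refused (a cylinder fit needs five
  degrees of freedom; curvature estimation needs 2-ring neighbourhoods).
* Coplanar or collinear facet selections are rejected as degenerate rather
  than returning an unstable fit.
* Cylinder axis direction is sign-canonicalised (first non-zero component
  positive) so fits are comparable across runs.
* The taut string wraps the profile's convex hull; hull chords across the
  rise shoulders are exactly the taut configuration, and a
  rubber-band relaxation fallback covers endpoint-inside-hull geometries.
* Which analyses in the source used the ln-transformed index is not
  recorded; the package defaults to the raw index everywhere and exposes
  the transform as a column and a flag.
* Whether the commercial best-fit cylinder minimises orthogonal distance
  exactly as here is undocumented; $\sum (d_i - r)^2$ is the standard
  reading and the one the tests pin down.
* Pairwise ANOVA p-values are Bonferroni-adjusted by default (the source
  does not name an adjustment); the method is a parameter.
* "Averages weighted by species representation" in genus consolidation is
  read as weighting by specimen counts; `weight_by = "species"` gives the
  unweighted alternative.

# What the tests do and do not show

The test suite demonstrates: exact recovery of known synthetic geometry
(2% end-to-end tolerance at resolutions finer than radius/20); agreement
of every likelihood with dense matrix-construction oracles to 1e-8;
stepping-stone agreement with an analytic conjugate marginal to 0.1 log
units; calibrated HPD coverage for the Bayesian machinery; and correct
localisation and convergence-collapse behaviour of the stepwise OU search.
It does not — cannot — show that measurements of real, hand-segmented tali
match a human operator's landmark choices, nor that the stepwise search's
shift *count* is trustworthy (see the limitation above), nor anything
about the adequacy of the cam model's default tendon geometry beyond its
ordinal claims.
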