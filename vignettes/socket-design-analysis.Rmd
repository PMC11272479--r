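---
title: "Quantifying transtibial socket design: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transtibial socket design: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A transtibial prosthetic socket is designed by *rectifying* a scan of the
residual limb: carving material from the mould where the limb tolerates load
(so the socket presses in) and building it up where the limb is vulnerable
(so the socket stands off). Practice spans two philosophies — patella tendon
bearing (PTB), with pronounced local rectifications, and total surface
bearing (TSB), with a larger global volume reduction and subtler local work —
but real CAD/CAM design records show a continuous spectrum between them.
`socketmap` turns pairs of 3D surface scans (residual limb + socket or mould
design) into quantitative design variables and models how expert prosthetists
combine them.

The pipeline has four stages, each exposed as ordinary functions and driven
end-to-end by the scripts under `analysis/`:

1. **Alignment** (`coarse_align()`, `icp_align()`, `align_pair()`): the
   socket is brought into the limb frame, first coarsely from the principal
   axes and the mid-patella / distal-tibia landmarks (Kabsch fit of the two
   landmark pairs plus the centroids), then refined by point-to-surface ICP
   restricted to the anterior, sub-patellar vertex mask.
2. **Rectification mapping** (`compute_deviation_map()`, `region_size()`,
   `volume_reduction()`, `extract_profile()`): a signed per-vertex
   limb-to-socket distance field (positive = carve, negative = build), the
   98th-percentile size of each of seven rectification regions — patellar
   tendon (PT, carve), fibular head (FH, build), medial/lateral paratibial
   (MP/LP, carves), tibial crest (TC, build), distal end (DE, build),
   lateral–medial supracondylar (LMC, carve) — and the volume reduction VR,
   the mean percentage cross-sectional area difference over ten sections
   between the mid patellar tendon and distal tibia levels.
3. **Cohort statistics** (`cohort_summary()`, `mann_whitney_u()`,
   `bonferroni_adjust()`, `spearman_matrix()`, `compare_designs()`):
   demographic summaries, PTB-vs-TSB comparisons and the 8 × 8 rank
   correlation matrix.
4. **Probabilistic design model** (`fit_kde()`, `kde_percentiles()`,
   `fit_conditional_nb()`, `conditional_probabilities()`,
   `generate_template()`, `render_template_map()`): kernel density estimates
   define low/mid/high size categories (cuts at the KDE's 33rd/67th
   percentiles; exemplar values at its 10th/50th/90th), Gaussian naive Bayes
   gives `P(category of one rectification | the size already chosen for
   another)`, and the arg-max categories form a template design that can be
   rendered on any limb mesh.

Because the underlying patient scans are restricted healthcare data, the
package carries a first-class synthetic generator (`generate_limb()`,
`generate_socket()`, `generate_cohort_table()`) whose ground truth makes
every stage testable.

## Units and conventions

Everything geometric is in millimetres; areas in mm²; VR in percent. The
canonical limb frame points distal along +z, anterior along +x, lateral
along +y. Deviations are measured at limb vertices along their outward
normals; positive deviation means the socket surface lies inside the limb
(carve). Region sizes are magnitudes in the region's expected direction,
floored at zero, with the raw signed percentile kept as a diagnostic.
On-disk vertex indices (mask JSON) are 0-based; in R they are 1-based.

## Alignment details

The principal axis is the leading eigenvector of the vertex covariance.
Its sign is fixed anatomically: the axis points in the direction of
decreasing radial spread — residual limbs taper distally. (A farthest-vertex
rule is the fallback for untapered shapes; for limb-like proportions the two
axial extremes are nearly equidistant from the centroid, so a farthest-point
rule alone is numerically unstable.) Shapes whose two leading eigenvalues
agree within 1% are rejected as axis-degenerate.

ICP is point-to-point with point-to-triangle correspondences through a
uniform-grid spatial index (compiled code; ties broken toward the lowest
triangle index, so runs are deterministic with no RNG). Iterations stop when
the RMS improves by less than `tol` (default 1e-4 mm) or at `max_iter`
(default 50); non-convergence returns the best transform with
`converged = FALSE` rather than failing. There is no outlier trimming by
default (an optional maximum pair distance exists for noisy scans).

Two properties of masked ICP on limb-like geometry matter for
interpretation:

* A surface of revolution is invariant under rotation about its own axis, so
  that pose component is unobservable to ICP; it is fixed by the landmark
  stage. The ICP unit tests therefore use a limb with an asymmetric radial
  modulation when they assert full pose recovery.
* When rectifications fall inside the anterior mask (the PT carve sits in
  it by definition), ICP converges to a compromise pose roughly 1 mm away
  from the ground-truth alignment, under-reading anterior carves and
  over-reading anterior builds. This mirrors clinical pipelines, which
  follow automatic registration with expert inspection; `align_pair()`
  accepts a deterministic `override` transform to play that role. The
  extraction-accuracy guarantees below are stated for correctly aligned
  pairs.

The anterior sub-patellar mask itself is an input. For synthetic limbs it is
the ±45° sector about anterior between the mid patellar tendon level and 40%
of limb length.

## Sizing and sectioning choices

The 98th percentile (linear interpolation between order statistics) is taken
over the signed deviations oriented in the region's expected direction, not
over absolute values: an absolute-value reading would let opposite-signed
noise inflate a region. Regions need at least 10 usable vertices; vertices
whose normal ray misses the socket within 50 mm are excluded, and a region
with more than half its mask missing is an error.

VR uses per-section normalisation, `(A_limb − A_socket) / A_limb`, averaged
over 10 planes with *inclusive* endpoints at the two landmark levels; the
sectioning axis is the limb principal axis. Cross-section areas come from
exact triangle–plane intersection, chaining the segments into closed
contours (endpoint tolerance 1e-6 mm) and applying the shoelace formula;
multiple contours sum. Open meshes are accepted — limb scans are open
proximally — but each section contour must close.

Duplicate vertices are merged at 1e-9 mm on read (STL stores each facet's
corners independently). These tolerances are engineering choices, below
scanner resolution and above float noise; the source study does not state
its mesh resolution.

## The synthetic generator

`generate_limb()` builds a tapered surface of revolution: by default 180 mm
long, 55 mm proximal radius tapering linearly to 35 mm, closed by a 30 mm
elliptical cap, meshed at 180 × 120 (tests use 96 × 64; recovery guarantees
hold from 90 × 60). Landmarks sit at fixed anterior stations (11%, 19.5% and
78% of length); the seven region masks are angular-sector × axial-band
vertex sets at anatomically plausible stations, pairwise disjoint.

`generate_socket()` composes, in order:

1. an exact radial scaling by `sqrt(1 − VR/100)`, so every cross-section
   shrinks by exactly VR percent;
2. one displacement bump per rectified region along the limb normals —
   inward for carves, outward for builds. Bumps have a plateaued-cosine
   profile (flat over the central 35% of the bump support, cosine decay to
   zero at the support edge; support is 70% of the mask half-extent). A pure
   Gaussian peak would put fewer than 2% of mask vertices near the peak, so
   the 98th-percentile extractor would systematically under-read by about
   5%; the plateau makes the percentile land on the true size. Bumps are
   anchored to the *unreduced* limb: the plateau deviation equals the
   requested size as measured from the limb, which is exactly what the
   extractor measures. Zero-size regions are left on the reduced surface;
3. optionally a rigid pose perturbation and i.i.d. vertex noise, recorded in
   the ground truth.

One measurement-theoretic subtlety: a local carve smaller than the local VR
shrink (about 0.2–2.6 mm over the realistic VR range) is invisible to the
98th-percentile estimator — the region's deviation field is dominated by the
global reduction. The ground truth therefore also records
`expected_measured`, the analytic 98th percentile of the deviation field the
construction actually places in each region; the inverse-property tests
compare extraction against it (and against the raw input sizes via
per-region medians, which are robust to the rare masked cases).

`generate_cohort_table()` draws the eight design variables from a Gaussian
copula: normal marginals centred on the published category mid values with
spreads matching the published 10th–90th ranges, coupled through the
published pairwise Spearman pattern (converted to the normal-score scale by
`2 sin(πρ/6)`, eigenvalue-clipped to the nearest correlation matrix if
needed). Design labels follow the published PTB/TSB/PTB-SC mixture
(135:21:7), with TSB mean shifts (LP −1.2, MP −0.7, DE −2.0 mm, VR +2.5
points) reflecting the reported group differences. Local sizes are floored
at 0; a negative VR (socket larger than limb) is kept and flagged. An
explicit conditional rule such as `P(DE = high | VR at its 90th percentile)
= 0.5` overrides the copula entry for its pair, with the normal-score
correlation solved numerically so the *true* tercile-conditional probability
at the conditioning point equals the request. The published matrix itself
contains a mild tension — a negative DE–VR rank correlation alongside a
strongly positive conditional association — which a single Gaussian copula
cannot reproduce simultaneously; scenarios that exercise the conditional
rule therefore adopt the rule for that pair.

What the generator does *not* emulate: real limbs are not surfaces of
revolution (no tibial crest ridge, no bony prominences), masks are supplied
rather than expert-identified, scan noise is i.i.d. rather than structured,
and rectification *shape* varies only through the fixed bump profile. A
passing recovery suite therefore demonstrates correctness of the measurement
chain, not robustness to anatomical variation.

## Statistical choices

* **Mann–Whitney U**: rank-sum U with midranks for ties; exact enumeration
  when the combined sample is ≤ 16 and untied, otherwise the normal
  approximation with tie-corrected variance and continuity correction (via
  `stats::wilcox.test`, with the branch forced explicitly). The two branches
  agree within 0.01 wherever p < 0.25; the worst disagreement across all
  attainable U at n = 8 vs 8 is 0.011, at mid-range U.
* **Bonferroni** with an explicit family size, default m = 8 (one test per
  design variable); the source study does not print its m.
* **Spearman** rho as the Pearson correlation of midranks; two-sided p from
  the t approximation on n − 2 degrees of freedom. Constant variables give
  `NA`, not 0. PTB-SC sockets join the PTB group in two-group tests by
  default (a documented flag).
* **KDE**: Gaussian kernels, Scott's bandwidth `h = s · n^(−1/5)`
  (configurable); percentiles by trapezoid integration of the density on a
  512-point grid over `[min − 4h, max + 4h]` and monotone inverse
  interpolation. The percentile split is applied to the *fitted KDE*, not
  the empirical CDF.
* **Naive Bayes**: target classes from the KDE cuts (half-open intervals,
  boundary value goes to the upper class); empirical priors; class-wise
  Gaussian likelihood of the *raw continuous* conditioning size, variance
  floored at `1e-9 ×` the overall variance; classes with fewer than five
  sockets fall back to the pooled variance with a warning. One conditioning
  feature per model, matching pairwise reporting. Template arg-max ties
  break toward the lower category — the conservative rectification.

## Problem sizes

The bundled tests and the acceptance script run the geometry at 96 × 64 mesh
resolution, 20 random sockets for the inverse property, 20 random poses for
alignment recovery, and 20 synthetic cohorts of n = 163 for the rank and
naive-Bayes recovery checks; the analysis scripts use the full 180 × 120
default. These sizes put every synthetic estimate within a standard error
comfortably inside its stated tolerance.

## Known limitations

* Statistics at the published-cohort scale (correlation matrix entries,
  category tables, conditional probabilities) can only be checked against
  the deposited processed dataset, which users must download themselves
  (`read_deposited_cohort()`); the package ships no patient-derived data.
* The masked-ICP anterior bias described above means fully automatic
  end-to-end extraction carries a ~1 mm systematic component on anterior
  regions; the override slot exists precisely to absorb expert corrections.
* Rectification area, shape and location descriptors are out of scope, as is
  any automatic delineation of rectification regions or automated socket
  design: templates are decision support, and an expert prosthetist remains
  responsible for the design.
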