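# socketmap

Quantitative analysis of transtibial prosthetic socket design from 3D scan
pairs. Given a residual-limb surface scan and the corresponding CAD/CAM
socket (or mould) design, `socketmap` aligns the pair, extracts a signed
**rectification map** — the per-vertex limb-to-socket distance, positive
where material is carved from the mould and negative where it is built up —
and reduces each socket to eight design variables:

| variable | region | direction | unit |
|---|---|---|---|
| PT | patellar tendon | carve | mm |
| FH | fibular head | build | mm |
| MP / LP | medial / lateral paratibial | carve | mm |
| TC | tibial crest | build | mm |
| DE | distal end elongation | build | mm |
| LMC | lateral–medial supracondylar | carve | mm |
| VR | volume reduction | — | % |

Each local size is the 98th-percentile deviation over its expert-defined
vertex cluster (robust to single-vertex noise); VR is the mean of
`(A_limb − A_socket)/A_limb` over ten cross-sections between the mid
patellar tendon and distal tibia levels. Cohorts of such profiles are then
analysed with Mann–Whitney U tests (PTB vs TSB designs, Bonferroni-adjusted),
a Spearman rank-correlation matrix, and a probabilistic design model: kernel
density estimates split each variable into low/mid/high categories (cuts at
the KDE's 33rd/67th percentiles, exemplar values at its 10th/50th/90th), and
a Gaussian naive Bayes classifier estimates

P(category of rectification *t* | size chosen for rectification *c*) ∝
π_cat · N(x_c; μ_cat, σ²_cat),

from which most-probable **template designs** follow a prior clinical
decision (say, a high volume reduction) and can be rendered on any limb mesh.

The package is aimed at prosthetics researchers and rehabilitation engineers
analysing CAD/CAM design records. Because patient scans are restricted
healthcare data, a synthetic limb/socket generator with known ground truth
(surface-of-revolution limbs, plateaued displacement bumps, Gaussian-copula
cohorts) makes the entire pipeline testable offline; it is a first-class,
tested module, not a fixture.

## Worked example

Generate a synthetic limb, rectify a socket from it with known sizes, and
recover them:

```r
library(socketmap)

limb   <- generate_limb(limb_spec(n_angular = 96, n_axial = 64))
truth  <- rectification_profile(PT = 5.8, FH = 2.1, MP = 3.2, LP = 3.6,
                                TC = 2.7, DE = 5.8, LMC = 5.5, VR = 4.3)
socket <- generate_socket(limb, truth)
extract_profile(limb$mesh, socket$mesh, limb$landmarks, limb$masks)
#> <rectification_profile>
#>   PT    5.80 mm (carve)
#>   FH    2.07 mm (build)
#>   MP    3.20 mm (carve)
#>   LP    3.60 mm (carve)
#>   TC    2.70 mm (build)
#>   DE    5.80 mm (build)
#>   LMC   5.41 mm (carve)
#>   VR    4.46 %
```

Every size is recovered within 2% and the volume reduction within 0.2
percentage points of the generating values. On a cohort, the conditional
design model reads, for example, the probability of each distal-end
elongation category given a high volume reduction:

```r
rules  <- list(list(target = "DE", conditioning = "VR", prob = 0.5))
cohort <- generate_cohort_table(163, cohort_structure(rules = rules), seed = 42)
cuts   <- fit_all_categories(cohort)
nb     <- fit_conditional_nb(cohort, target = "DE", conditioning = "VR",
                             cuts = cuts$DE)
round(conditional_probabilities(nb, cuts$VR$exemplar_high), 3)
#>        low   mid  high
#> [1,] 0.223 0.341 0.436
```

so a socket with a high volume reduction most probably carries a high distal
end elongation — space for the displaced soft tissue. `generate_template()`
assembles the arg-max categories of all eight variables into a template, and
`render_template_map()` paints it onto a limb mesh as a deviation map
(exportable as a per-vertex scalar in PLY).

The numbered scripts under `analysis/` run the whole study shape end to end
— simulate scan pairs, batch-extract profiles (`run_extract()`), cohort
statistics, and the probabilistic model with rendered templates
(`run_analysis()`) — writing their tables under `results/`.

## Data

Raw limb/socket scans from the motivating study are restricted; its
processed per-socket data are publicly deposited by the study authors.
`read_deposited_cohort()` loads a locally downloaded copy (default location
`data-raw/deposited_cohort.csv`); no patient-derived data ships with this
package. `reference_cohort_counts()` provides the published demographic
counts table, from which `cohort_from_counts()` reconstructs a per-socket
demographic cohort.

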