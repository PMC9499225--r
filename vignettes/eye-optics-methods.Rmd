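---
title: "Measuring eye optics and comparing them across species: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring eye optics and comparing them across species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ommatidics)
```

## What the package models

Apposition compound eyes resolve a tradeoff between sensitivity and
resolution. Each ommatidium images independently through its facet lens;
a wider facet (diameter $D$, µm) captures more photons, while a smaller
angle between the optical axes of adjacent ommatidia
(the interommatidial angle $\Delta\varphi$) samples the scene more
finely. The eye parameter $\rho = D \cdot \Delta\varphi$ (µm·rad)
summarizes where an eye sits on this axis: low values are typical of
day-active insects, values near or above 2 of night-active ones. Facet
area, $\tfrac{\pi}{4}D^2$, is the dominant geometric term in photon
capture, so the fold difference in light-gathering between two eyes at
matched body size is $(D_1/D_2)^2$.

`ommatidics` implements these estimators for measurements digitized from
profile photographs of ant eyes, the cuticular-brightness protocol that
classifies species as pale or dark (a surrogate for nocturnal versus
diurnal/variable foraging), and the comparative statistics that control
species comparisons for body size. It ships the species-level tables the
comparative analysis runs on, and synthetic generators that provide
ground truth for every estimator.

## The interommatidial-angle construction

The input is an `eye_profile`: ordered $(x, y)$ points (mm) digitized
along the eye edge, anterior to posterior, one point per facet-row
boundary, with one point marked as the apex. From the apex a chord is
drawn to the point `rows_per_step` boundaries away anteriorly and its
perpendicular bisector taken; likewise posteriorly. On a locally
circular edge each bisector passes through the center of curvature, and
because each chord's midpoint sits `rows_per_step`/2 facets from the
apex, the angle between the bisectors equals `rows_per_step` per-facet
angles. Dividing by `rows_per_step` recovers $\Delta\varphi$; the
default step of 2 reproduces the classical two-facet-rows-away,
divide-by-two protocol, and the generalization keeps the estimator
consistent for step 1 or 3. The estimate depends only on relative point
positions, so it is invariant under translation, rotation and uniform
scaling of the digitization — properties the test suite asserts at
1e-9.

Degeneracies are explicit: if the three construction points are
collinear (a locally flat edge), the bisectors are parallel and the
package raises a degenerate-geometry error rather than returning a
spurious angle. Bisectors are declared parallel when the cross product
of their unit directions falls below 1e-12. The protocol measures
$\Delta\varphi$ three times in the same region; `replicate_dphi()`
takes explicit apex choices for the replicates, because the original
protocol does not specify how replicates differed, and averages them.

## Visual field span

The span is the angle between surface normals at the anterior and
posterior eye edges; for a constant-curvature edge the normals meet at
the center and the angle equals the arc subtended. The local tangent at
each edge is taken from the circle through the three outermost points.
A two-point secant was considered and rejected: on a circular arc the
secant's normal corresponds to the chord midpoint, not the endpoint, so
the estimated span would be one facet pitch short of the true arc; the
three-point circle fit is exact for constant curvature, uses the
minimal number of points that determine curvature, and needs no
stated pitch. This is why the profile format requires at least three
points at each edge.

## Brightness protocol and classification

Brightness follows the HSB convention of standard image editors,
$B = \max(R, G, B)/255 \times 100$ per pixel, averaged over an
11×11-pixel patch. The tool used in the original protocol names the
color window but not the formula; max-channel HSB brightness is that
window's definition. A worker's value averages the head, mesosoma and
gaster patches (missing tagmata are averaged over with a warning, never
silently), and a species averages its workers. Classification uses the
empirical gap observed in the study species: pale above 65, dark below
60, indeterminate in between; the photographic survey uses a single
cut at 70. The pale/dark brightness comparison is a pooled-variance
two-sample t on species means — the printed 24 degrees of freedom
(10 + 16 − 2) identify the pooled rather than Welch variant — computed
for the dark-minus-pale contrast, matching the alphabetical group
ordering (and the negative sign) of the original analysis.

## Comparative statistics

Species are compared within genus by MANCOVA on eye area, facet count
and facet diameter with mesosoma length (Weber's length) as the
covariate. Fits use `stats::lm`; type-III tests (the convention of the
original analysis software) use `car` with sum-to-zero contrasts; both
Wilks' $\Lambda$ and Pillai's trace are reported with the standard
Rao/Pillai F approximations, computed directly from the hypothesis and
error SSP matrices. Estimated marginal means are computed from the
model's own contrast machinery — each group's mean prediction with the
covariate held at the grand mean of included observations (overridable,
e.g. to a published evaluation point), other factors averaged with
equal weight — and are cross-checked against `emmeans` in the tests
rather than delegated to it. In the univariate limit the multivariate
criteria collapse to the ANCOVA F, which the suite asserts at 1e-8.

Assumption checks mirror the analysis they guard: Box's M (authored
here; no installed implementation) with the chi-square approximation
and the conventional strict threshold of 0.001, under which Pillai's
trace is preferred to Wilks' $\Lambda$; Levene's test on absolute
deviations from group means (`car::leveneTest`, `center = mean`, the
original software's default); and a multivariate test of the group ×
covariate interaction for homogeneity of slopes. Post-hoc comparisons
are unadjusted pairwise t tests (LSD) on the marginal means, or
Tukey-Kramer via the studentized range for across-genus comparisons;
letter displays use the insert-and-absorb algorithm, order letters by
descending mean (`a` = largest), and verify themselves against their
own p matrix on every call, including non-transitive overlap patterns.
A stricter post-hoc alpha (0.01) can be requested where variance
homogeneity fails, mirroring the convention used for the one genus that
failed Levene's test.

Regional facet-diameter variation uses a one-way repeated-measures
ANOVA over the five eye regions: Mauchly's W (via
`stats::mauchly.test`, with the chi-square statistic reported on
$k(k-1)/2 - 1 = 9$ df for five regions), the sphericity-assumed
within-subjects F, a one-sample multivariate (Wilks/Hotelling) test on
the difference scores, and paired LSD comparisons. Small-sample exact
sphericity p-values are not attempted; the standard chi-square
approximation with the multiplicative correction is used. Identical
columns (zero within-subject variation) are reported as F = 0 with a
degeneracy flag rather than 0/0 noise.

The color × activity association uses Fisher's exact test for r × c
tables by full enumeration of all tables with the observed margins —
the two-sided p sums the probabilities of tables no more probable than
the observed one, the conventional exact definition (r × c two-sided
conventions vary, so this is stated). A guard refuses enumerations
beyond ~1e7 tables and suggests Monte-Carlo instead. The enumeration is
checked against an independent brute-force oracle and against
`stats::fisher.test`.

Data transformations are never applied silently; responses are passed
as-is and any transformation is the caller's explicit choice.

## Synthetic generators and what they do (and do not) show

The generators provide ground truth, not realism:

* `synth_eye_profile()` — constant-curvature arcs with points at facet
  boundaries plus isotropic Gaussian jitter. The circular model is
  chosen because the $\Delta\varphi$ construction is exactly a
  radius-of-curvature method, so the closed form $\Delta\varphi = D/R$
  is a principled oracle, not a fitted one. Real eye edges are only
  locally circular; the generator does not model aspherical caps, so
  passing tests certify the estimator, not the biology.
* `synth_morphometry()` — per-species linear responses to mesosoma
  length with Gaussian residuals, matching the structure the MANCOVA
  assumes (responses increasing with body size within species). The
  default two-species table separates facet diameter by ~6 µm at equal
  body size — the magnitude of the pale/dark gap between size-paired
  congeners — with about a dozen workers per species from a handful of
  colonies, the study's sampling scale. Colony labels are round-robin;
  colony-level variance components are not modeled (the comparative
  analysis treats workers as the unit).
* `synth_patch()` — grayscale patches with truncated Gaussian noise
  around a target brightness. Truncation at the 0/255 bounds biases
  the mean only at the extremes; unbiasedness is therefore asserted in
  the interior of the scale.
* `synth_regional_D()` — subject intercept + region effect + noise,
  compound-symmetric by construction, at the study's repeated-measures
  sample sizes (12–14 workers, five regions).

Each generator is deterministic under its seed and emits its generating
truth alongside the data. When a simulation is replicated inside one
test, replicates are drawn from a single seeded stream rather than from
sequential per-replicate seeds, which can carry correlated artifacts
through short runs.

## Numerical and calibration choices

Angles are computed in radians internally (via `atan2`, stable near 0
and $\pi$) and reported in degrees; displays round angles and ratios to
2 decimals and t statistics to 1, the print precision of the source
tables, while JSON serialization keeps full precision. The validation
battery runs null simulations of 500 replicates (1000 for Box's M at
its 0.001 threshold) and requires empirical size within 99% binomial
bounds of the nominal level; parameter-recovery checks require the
known group offset inside ±2 SE in at least 93% of 500 replicates.
These sizes keep the whole suite under a minute on one CPU while
leaving Monte-Carlo slack well below the effects being detected. The
Levene null calibration uses 60 observations per group because the
absolute-deviation F is asymptotic and measurably liberal at small n
(~0.06 at n = 15); the small-n behavior is a property of the method,
not of this implementation.

## Known limitations

* Per-worker raw data behind the packaged species tables are not
  published; the reproduction pipeline therefore reports only
  fixture-derivable statistics, and the worker-level statistical
  machinery is demonstrated on synthetic data. The split is explicit.
* The survey's dark-congener reference values are carried as per-genus
  maxima of relative eye size (the only published form); the screen
  needs nothing finer.
* No phylogenetic correction is implemented (none was performed in the
  source analysis), and no image processing: inputs are already
  digitized points and pixel patches, not photographs.
* The printed pale/dark group brightness means (74.6/45.4) are not
  exactly recoverable from the species means (which give 74.4/45.7,
  with the same t); the report prints both rather than asserting
  equality.
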