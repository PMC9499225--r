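# ommatidics

Comparative visual ecology of ants links three things: how much pigment a
worker carries in its cuticle, when it forages, and how its compound eye
trades off sensitivity against resolution. Nocturnal species tend to be
pale and to carry eyes built for photon capture — larger eye area, larger
facet lenses, wider visual fields — while diurnal congeners are dark and
favor resolution. `ommatidics` packages the measurement protocols and
statistics needed to run this kind of analysis end to end: a
cuticular-brightness protocol with pale/dark classification, geometric
estimators of eye optics from digitized eye-edge profiles,
covariate-adjusted comparative statistics, species-level data tables, and
synthetic-data generators that make every stage testable against known
ground truth.

## The quantities at the core

For an apposition compound eye with facet diameter *D* (µm):

* **Interommatidial angle** Δφ — the angle between the optical axes of
  adjacent ommatidia; smaller Δφ means finer spatial resolution. It is
  estimated by the radius-of-curvature construction: from a point at the
  eye apex, chords are drawn to points two facet-row boundaries away
  anteriorly and posteriorly; on a locally circular eye edge the two
  perpendicular bisectors meet at the center of curvature and the angle
  between them, divided by two, is Δφ (equivalently Δφ = *D*/*R* for
  facet pitch *D* and local radius *R*).
* **Visual field span** — the angle between surface normals erected at
  the anterior and posterior eye edges; for a constant-curvature edge it
  equals the arc subtended by the eye.
* **Eye parameter** ρ = *D* (µm) × Δφ (rad) — the classic
  sensitivity/resolution tradeoff index; day-active insects sit low,
  night-active ones near or above 2 µm·rad.
* **Facet area** = π/4 · *D*² — the dominant geometric term in photon
  capture per ommatidium; fold differences between species are
  (*D*₁/*D*₂)².
* **Brightness** B — per pixel max(R,G,B)/255 × 100 (the HSB brightness
  convention), averaged over an 11 × 11 patch on head, mesosoma and
  gaster, then over the three tagmata per worker, then over workers per
  species.

Species comparisons control for body size (mesosoma length, Weber's
length) via MANCOVA/ANCOVA with type-III tests, Wilks' Λ / Pillai's
trace, estimated marginal means with LSD or Tukey post-hoc letter
displays, Box's M / Levene / homogeneity-of-slopes assumption checks,
repeated-measures ANOVA with Mauchly's sphericity test for regional
facet-diameter variation, and Fisher's exact r × c test (full
enumeration) for the color × activity association.

## Worked example

```r
library(ommatidics)

# Eye optics from a digitized profile (here synthetic, truth = 2.2918 deg)
sim <- synth_eye_profile(eye_sim_spec(radius_R = 0.5, facet_pitch = 0.02,
                                      span_deg = 100))
measure_eye(sim$profile, D_um = 20,
            apex_indices = sim$profile$apex_index + (-1:1))
#> Eye optics: dphi = 2.29 deg, span = 98.55 deg, rho = 0.800 um rad,
#> facet area = 314.16 um^2 (D = 20.00 um)

# The packaged species tables, end to end
reproduce_main()
#> Reproduction report
#>   Classification: 10 pale / 16 dark / 0 indeterminate
#>   Brightness t-test (dark - pale): t = -10.1, 24 df, p = 4.3e-10
#>   Group means (species-weighted): pale 74.4, dark 45.7
#>   Fisher exact (color x activity): p = 3.2e-06 (37 tables)
#>   Covariate-adjusted facet-diameter ratios (pale / dark):
#>     Myrmecocystus  christineae / yuma: D ratio 1.44, facet-area fold 2.08
#>     ...
#>   Survey screen: 21 of 21 candidates flagged
```

The report reads: the 26 species split cleanly into 10 pale (B > 65) and
16 dark (B < 60) with no intermediate; brightness differs strongly
between the classes (pooled t on species means, 24 df); color predicts
activity period (exact test over all 37 tables with the observed
margins); and at matched body size the pale member of each size-paired
congener pair carries facets 1.13–1.44× wider, i.e. up to ~2.1-fold more
facet area, than its dark partner.

Worker-level MANCOVAs, the two-way genus × activity ANCOVAs and the
repeated-measures machinery run on user data or on the generators in
`synth_morphometry()` / `synth_regional_D()`; see the vignette in
`vignettes/eye-optics-methods.Rmd`.

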