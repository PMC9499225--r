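# Geometric estimators for apposition-eye optics measured from digitized
# eye-edge profiles: interommatidial angle by the radius-of-curvature
# construction, anterior-posterior visual field span, and the derived
# sensitivity/resolution quantities (eye parameter, facet area, ratios).

DEG <- 180 / pi

# Perpendicular-bisector direction of the chord p -> q, plus its midpoint.
.chord_bisector <- function(p, q) {
  d <- q - p
  list(mid = (p + q) / 2, dir = c(-d[2L], d[1L]))
}

.angle_between <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop_validation("degenerate zero-length direction")
  # atan2 form is stable near 0 and pi
  atan2(abs(u[1L] * v[2L] - u[2L] * v[1L]), sum(u * v))
}

#' Interommatidial angle from an eye-edge profile
#'
#' Implements the radius-of-curvature construction. From the apex point a
#' chord is drawn to the profile point `rows_per_step` facet-row
#' boundaries away in the anterior direction, and its perpendicular
#' bisector taken; the same is done posteriorly. On a locally circular
#' eye edge both bisectors pass through the center of curvature and the
#' angle between them equals `rows_per_step` facet angles, so dividing by
#' `rows_per_step` recovers the angle between the optical axes of
#' adjacent ommatidia. The default step of 2 reproduces the
#' two-facet-rows-away, divide-by-two protocol. The estimate is invariant
#' under translation, rotation and uniform scaling of the digitized
#' coordinates.
#'
#' @param profile an [eye_profile()].
#' @param apex_index optional override of the profile's apex index.
#' @param rows_per_step integer number of facet-row boundaries spanned by
#'   each chord (default the profile's `facet_rows_per_step`).
#' @return Interommatidial angle in degrees.
#' @examples
#' sim <- synth_eye_profile(eye_sim_spec(radius_R = 0.5, facet_pitch = 0.02))
#' interommatidial_angle(sim$profile)  # ~ 0.02/0.5 rad = 2.2918 deg
#' @export
interommatidial_angle <- function(profile, apex_index = NULL,
                                  rows_per_step = NULL) {
  stopifnot(inherits(profile, "eye_profile"))
  pts <- profile$points
  n <- nrow(pts)
  i <- if (is.null(apex_index)) profile$apex_index else as.integer(apex_index)
  s <- if (is.null(rows_per_step)) profile$facet_rows_per_step
       else as.integer(rows_per_step)
  if (s < 1L) stop_validation("rows_per_step must be a positive integer")
  if (i - s < 1L || i + s > n)
    stop_validation(sprintf(
      "apex index %d too close to profile end for step %d (n = %d)", i, s, n))
  apex <- pts[i, ]; ant <- pts[i - s, ]; post <- pts[i + s, ]
  b1 <- .chord_bisector(apex, ant)
  b2 <- .chord_bisector(apex, post)
  u <- b1$dir / sqrt(sum(b1$dir^2))
  v <- b2$dir / sqrt(sum(b2$dir^2))
  cross <- abs(u[1L] * v[2L] - u[2L] * v[1L])
  if (cross < 1e-12)
    stop_validation(
      "construction points are collinear (flat eye edge): bisectors parallel",
      class = "ommatidics_degenerate_geometry")
  theta <- .angle_between(u, v)
  # bisectors are undirected lines; fold to the acute angle between them
  if (theta > pi / 2) theta <- pi - theta
  theta / s * DEG
}

#' Replicate-averaged interommatidial angle
#'
#' The protocol measures the angle three times in the same eye region and
#' analyzes the average; replicates differ in the apex point chosen.
#'
#' @param profile an [eye_profile()].
#' @param apex_indices integer vector of apex choices (typically 3 nearby
#'   points).
#' @param rows_per_step see [interommatidial_angle()].
#' @return list with `mean_deg` and the per-replicate `replicates_deg`.
#' @export
replicate_dphi <- function(profile, apex_indices, rows_per_step = NULL) {
  if (length(apex_indices) < 1L)
    stop_validation("need at least one apex choice")
  vals <- vapply(seq_along(apex_indices), function(k) {
    tryCatch(
      interommatidial_angle(profile, apex_index = apex_indices[k],
                            rows_per_step = rows_per_step),
      error = function(e) stop_validation(sprintf(
        "replicate %d (apex %d) failed: %s", k, apex_indices[k],
        conditionMessage(e))))
  }, numeric(1L))
  list(mean_deg = mean(vals), replicates_deg = vals)
}

# Circumcenter of the circle through three points; NULL when collinear.
.circumcenter <- function(a, b, c) {
  d <- 2 * (a[1L] * (b[2L] - c[2L]) + b[1L] * (c[2L] - a[2L]) +
              c[1L] * (a[2L] - b[2L]))
  scale <- max(abs(c(a - b, b - c)))
  if (scale == 0 || abs(d) < 1e-12 * scale^2) return(NULL)
  ux <- (sum(a^2) * (b[2L] - c[2L]) + sum(b^2) * (c[2L] - a[2L]) +
           sum(c^2) * (a[2L] - b[2L])) / d
  uy <- (sum(a^2) * (c[1L] - b[1L]) + sum(b^2) * (a[1L] - c[1L]) +
           sum(c^2) * (b[1L] - a[1L])) / d
  c(ux, uy)
}

#' Anterior-posterior visual field span
#'
#' Normals to the eye surface are erected at the anterior and posterior
#' edges of the profile and the span is the angle between them: for an
#' eye edge of constant curvature the normals meet at the center of
#' curvature and the angle equals the arc subtended by the eye. The local
#' tangent at each edge is taken from the circle through the three
#' outermost points, which is exact for a circular edge and uses the
#' minimum number of points that determine curvature. Invariant under
#' rigid motions and uniform scaling.
#'
#' @param profile an [eye_profile()] with at least 3 points at each edge.
#' @return Span in degrees, in (0, 180].
#' @examples
#' sim <- synth_eye_profile(eye_sim_spec(span_deg = 100))
#' visual_field_span(sim$profile)  # ~ realized arc angle
#' @export
visual_field_span <- function(profile) {
  stopifnot(inherits(profile, "eye_profile"))
  pts <- profile$points
  n <- nrow(pts)
  if (n < 6L)
    stop_validation("span estimation needs at least 3 points at each edge")
  c1 <- .circumcenter(pts[1L, ], pts[2L, ], pts[3L, ])
  c2 <- .circumcenter(pts[n, ], pts[n - 1L, ], pts[n - 2L, ])
  if (is.null(c1) || is.null(c2))
    stop_validation("edge points are collinear or repeated: tangent undefined",
                    class = "ommatidics_degenerate_geometry")
  u <- c1 - pts[1L, ]   # inward normal at the anterior edge
  v <- c2 - pts[n, ]    # inward normal at the posterior edge
  .angle_between(u, v) * DEG
}

#' Eye parameter (sensitivity-resolution tradeoff index)
#'
#' The product of facet diameter D (um) and interommatidial angle in
#' radians. Values near or above 2 um rad indicate an eye biased toward
#' sensitivity (typical of night-active insects); low values favor
#' resolution.
#'
#' @param D_um facet diameter in um, positive.
#' @param dphi_deg interommatidial angle in degrees, positive.
#' @return Eye parameter in um rad.
#' @examples
#' eye_parameter(20, 2.8648)  # ~ 1.0
#' @export
eye_parameter <- function(D_um, dphi_deg) {
  if (any(D_um <= 0) || any(dphi_deg <= 0))
    stop_validation("D and the interommatidial angle must be positive")
  D_um * dphi_deg * pi / 180
}

#' Facet area from facet diameter
#'
#' Treats the facet as a circle of diameter D: area = pi/4 * D^2. Facet
#' area is the dominant geometric term in photon capture per ommatidium.
#'
#' @param D_um facet diameter in um, nonnegative.
#' @return Area in um^2.
#' @export
facet_area <- function(D_um) {
  if (any(D_um < 0)) stop_validation("D must be nonnegative")
  pi / 4 * D_um^2
}

#' Fold difference in facet area between two eyes
#'
#' The ratio of facet areas, (pi/4 D1^2)/(pi/4 D2^2) = (D1/D2)^2,
#' summarizing the relative light-gathering potential of two facet sizes.
#'
#' @param D_num,D_den facet diameters in um, positive.
#' @return Dimensionless fold ratio.
#' @examples
#' sensitivity_fold(20.81, 14.42)  # ~ 2.08
#' @export
sensitivity_fold <- function(D_num, D_den) {
  if (any(D_den == 0)) stop_validation("denominator diameter must be nonzero")
  if (any(D_num <= 0) || any(D_den < 0))
    stop_validation("diameters must be positive")
  (D_num / D_den)^2
}

#' Facet diameter ratio
#'
#' @param D_num,D_den facet diameters in um, positive.
#' @return `D_num / D_den`.
#' @export
diameter_ratio <- function(D_num, D_den) {
  if (any(D_den == 0)) stop_validation("denominator diameter must be nonzero")
  if (any(D_num <= 0) || any(D_den < 0))
    stop_validation("diameters must be positive")
  D_num / D_den
}

#' Relative eye size
#'
#' Eye area divided by mesosoma length, a body-size-standardized eye size
#' used in the survey screen and the one-way eye-area comparisons.
#'
#' @param eye_area_mm2 eye area in mm^2, nonnegative.
#' @param mesosoma_mm mesosoma (Weber's) length in mm, positive.
#' @return Relative eye size in mm.
#' @export
relative_eye_size <- function(eye_area_mm2, mesosoma_mm) {
  if (any(mesosoma_mm <= 0)) stop_validation("mesosoma length must be positive")
  if (any(eye_area_mm2 < 0)) stop_validation("eye area must be nonnegative")
  eye_area_mm2 / mesosoma_mm
}

#' Regional facet diameter from a three-facet run
#'
#' Regional D is measured as the total length of three facets in one row,
#' divided by three, with an optional scale factor converting the raw
#' measurement to um.
#'
#' @param three_facet_total total length of the three-facet run (raw
#'   units), positive.
#' @param scale_um_per_unit multiplier to um (default 1, i.e. input
#'   already in um; use 1000 for mm input).
#' @return Mean facet diameter in um.
#' @examples
#' regional_facet_diameter(60)            # 20 um
#' regional_facet_diameter(0.0633, 1000)  # 21.1 um
#' @export
regional_facet_diameter <- function(three_facet_total, scale_um_per_unit = 1) {
  if (any(three_facet_total <= 0))
    stop_validation("three-facet total length must be positive")
  if (scale_um_per_unit <= 0) stop_validation("scale must be positive")
  three_facet_total / 3 * scale_um_per_unit
}

#' Centroid facet diameter
#'
#' D at the eye centroid is the average of the diameters of the four
#' adjoining facets at the centroid.
#'
#' @param adjoining_diameters numeric vector of exactly 4 positive facet
#'   diameters in um.
#' @return Mean diameter in um.
#' @export
centroid_facet_diameter <- function(adjoining_diameters) {
  if (length(adjoining_diameters) != 4L)
    stop_validation("exactly 4 adjoining facet diameters are required")
  if (any(!is.finite(adjoining_diameters)) || any(adjoining_diameters <= 0))
    stop_validation("facet diameters must be positive")
  mean(adjoining_diameters)
}

#' Full optics summary for one eye
#'
#' Convenience wrapper combining the replicate-averaged interommatidial
#' angle, visual field span, eye parameter and facet area for one profile
#' and facet diameter.
#'
#' @param profile an [eye_profile()].
#' @param D_um facet diameter in um.
#' @param apex_indices replicate apex choices; default is the profile apex
#'   alone.
#' @return list of class `optics_result` with `dphi_deg`, `span_deg`,
#'   `eye_parameter_rho`, `facet_area_um2`, `D_um`, `replicates`.
#' @export
measure_eye <- function(profile, D_um, apex_indices = NULL) {
  if (is.null(apex_indices)) apex_indices <- profile$apex_index
  rep <- replicate_dphi(profile, apex_indices)
  structure(list(
    dphi_deg = rep$mean_deg,
    span_deg = visual_field_span(profile),
    eye_parameter_rho = eye_parameter(D_um, rep$mean_deg),
    facet_area_um2 = facet_area(D_um),
    D_um = D_um,
    replicates = rep$replicates_deg), class = "optics_result")
}

#' @export
print.optics_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Eye optics: dphi = %.2f deg, span = %.2f deg, rho = %.3f um rad, ",
    "facet area = %.2f um^2 (D = %.2f um)\n"),
    x$dphi_deg, x$span_deg, x$eye_parameter_rho, x$facet_area_um2, x$D_um))
  invisible(x)
}
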