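# Synthetic data with the geometric and statistical structure the analysis
# assumes: circular-arc eye profiles with known curvature and facet pitch,
# worker morphometry that is linear in body size within species, noisy
# brightness patches, and compound-symmetric regional facet diameters.
# Every generator is deterministic under its seed and returns its ground
# truth alongside the data.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Specification for a synthetic eye profile
#'
#' The synthetic truth is an eye edge of constant curvature: profile
#' points sit at facet-row boundaries along a circular arc of radius
#' `radius_R` subtending `span_deg`, spaced `facet_pitch` apart in arc
#' length, optionally jittered with isotropic Gaussian noise. The ground
#' truth interommatidial angle is `facet_pitch / radius_R` radians.
#'
#' @param radius_R local radius of curvature of the eye edge, mm.
#' @param facet_pitch arc length per facet row, mm; must be < `radius_R`.
#' @param span_deg arc subtended by the whole profile, degrees, in
#'   (0, 180].
#' @param noise_sd isotropic digitization jitter SD, mm.
#' @param seed integer RNG seed.
#' @return list of class `eye_sim_spec`.
#' @export
eye_sim_spec <- function(radius_R = 0.5, facet_pitch = 0.02, span_deg = 100,
                         noise_sd = 0, seed = 1L) {
  if (radius_R <= 0) stop_validation("radius_R must be positive")
  if (facet_pitch <= 0 || facet_pitch >= radius_R)
    stop_validation("facet_pitch must satisfy 0 < pitch < R")
  if (span_deg <= 0 || span_deg > 180)
    stop_validation("span_deg must lie in (0, 180]")
  if (noise_sd < 0) stop_validation("noise_sd must be nonnegative")
  structure(list(radius_R = radius_R, facet_pitch = facet_pitch,
                 span_deg = span_deg, noise_sd = noise_sd, seed = seed),
            class = "eye_sim_spec")
}

#' Generate a synthetic eye-edge profile
#'
#' @param spec an [eye_sim_spec()].
#' @return list with `profile` (an [eye_profile()]) and `truth`
#'   (`dphi_deg` = pitch/R in degrees, `span_deg` = the realized arc angle
#'   between the first and last generated point, `radius_R`, `n_points`).
#' @examples
#' sim <- synth_eye_profile(eye_sim_spec(radius_R = 0.5, facet_pitch = 0.02))
#' sim$truth$dphi_deg  # 2.2918
#' @export
synth_eye_profile <- function(spec) {
  stopifnot(inherits(spec, "eye_sim_spec"))
  R <- spec$radius_R
  step <- spec$facet_pitch / R              # per-facet angle, rad
  span <- spec$span_deg * pi / 180
  n <- floor(span / step) + 1L
  if (n < 5L)
    stop_validation(
      "facet pitch too coarse for the requested span: fewer than 5 points")
  theta <- (seq_len(n) - 1L) * step - (n - 1L) * step / 2
  pts <- cbind(R * sin(theta), R * cos(theta))  # apex up, anterior first
  if (spec$noise_sd > 0)
    pts <- pts + with_seed(spec$seed,
                           matrix(stats::rnorm(2L * n, 0, spec$noise_sd), n, 2L))
  profile <- eye_profile(pts, apex_index = as.integer(ceiling(n / 2)),
                         specimen_id = "synthetic")
  list(profile = profile,
       truth = list(dphi_deg = step * 180 / pi,
                    span_deg = (n - 1L) * step * 180 / pi,
                    radius_R = R, n_points = n))
}

#' Specification for synthetic worker morphometry
#'
#' Each species has its own intercept and slope for every response
#' against mesosoma length, plus Gaussian residuals; mesosoma lengths are
#' drawn uniformly over `mesosoma_range`. Defaults emulate the observed
#' study design: responses eye area (mm^2), facet count and facet
#' diameter D (um), about a dozen workers per species drawn from a few
#' colonies, and within-species positive slopes on body size.
#'
#' @param species data frame with column `species` and one
#'   `intercept_<resp>` / `slope_<resp>` pair per response.
#' @param residual_sd named numeric vector of residual SDs per response.
#' @param mesosoma_range length-2 numeric range, mm.
#' @param n_workers workers per species (recycled).
#' @param n_colonies colonies per species; labels assigned round-robin.
#' @param seed integer RNG seed.
#' @return list of class `morpho_sim_spec`.
#' @export
morpho_sim_spec <- function(species,
                            residual_sd = c(eye_area = 0.008,
                                            facet_count = 15,
                                            facet_diameter_D = 0.8),
                            mesosoma_range = c(1.1, 2.3),
                            n_workers = 12L, n_colonies = 4L, seed = 1L) {
  if (!is.data.frame(species) || nrow(species) == 0L)
    stop_validation("`species` must be a non-empty data frame")
  if (!"species" %in% names(species))
    stop_validation("`species` needs a `species` column")
  resp <- sub("^intercept_", "", grep("^intercept_", names(species),
                                      value = TRUE))
  if (length(resp) == 0L)
    stop_validation("no intercept_/slope_ response columns found")
  missing_slopes <- setdiff(paste0("slope_", resp), names(species))
  if (length(missing_slopes))
    stop_validation(paste("missing columns:",
                          paste(missing_slopes, collapse = ", ")))
  n_workers <- rep_len(as.integer(n_workers), nrow(species))
  if (any(n_workers < 2L)) stop_validation("need n >= 2 workers per species")
  if (any(residual_sd[resp] < 0) || anyNA(residual_sd[resp]))
    stop_validation("residual SDs must be nonnegative for every response")
  structure(list(species = species, responses = resp,
                 residual_sd = residual_sd,
                 mesosoma_range = mesosoma_range, n_workers = n_workers,
                 n_colonies = as.integer(n_colonies), seed = seed),
            class = "morpho_sim_spec")
}

#' Default species table for [morpho_sim_spec()]
#'
#' Two species whose facet-diameter offset (~6 um at equal body size)
#' mirrors the pale/dark D gap observed between size-paired congeners,
#' with equal positive slopes on mesosoma length.
#'
#' @param d_offset facet-diameter offset of species B relative to A, um.
#' @return data frame usable as the `species` argument.
#' @export
default_morpho_species <- function(d_offset = 6) {
  data.frame(
    species = c("pale_sp", "dark_sp"),
    intercept_eye_area = c(0.02, 0.02),
    slope_eye_area = c(0.04, 0.04),
    intercept_facet_count = c(150, 150),
    slope_facet_count = c(110, 110),
    intercept_facet_diameter_D = c(8 + d_offset, 8),
    slope_facet_diameter_D = c(6, 6),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic worker morphometry table
#'
#' @param spec a [morpho_sim_spec()].
#' @return Data frame with columns `species`, `colony`, `mesosoma_length`
#'   and one column per response; the generating spec is attached as
#'   attribute `"truth"`.
#' @export
synth_morphometry <- function(spec) {
  stopifnot(inherits(spec, "morpho_sim_spec"))
  with_seed(spec$seed, {
    rows <- lapply(seq_len(nrow(spec$species)), function(i) {
      sp <- spec$species[i, ]
      n <- spec$n_workers[i]
      x <- stats::runif(n, spec$mesosoma_range[1L], spec$mesosoma_range[2L])
      out <- data.frame(
        species = sp$species,
        colony = paste0(sp$species, "_c",
                        rep_len(seq_len(spec$n_colonies), n)),
        mesosoma_length = x, stringsAsFactors = FALSE)
      for (r in spec$responses) {
        mu <- sp[[paste0("intercept_", r)]] + sp[[paste0("slope_", r)]] * x
        out[[r]] <- mu + stats::rnorm(n, 0, spec$residual_sd[[r]])
      }
      out
    })
    res <- do.call(rbind, rows)
    attr(res, "truth") <- spec
    res
  })
}

#' Generate a noisy grayscale brightness patch
#'
#' Pixel values are `B_true`/100 * 255 plus Gaussian noise (expressed on
#' the brightness percent scale), truncated to [0, 255].
#'
#' @param B_true target mean brightness, percent in [0, 100].
#' @param noise_sd pixel noise SD on the percent scale.
#' @param size patch side length (default 11, the protocol patch).
#' @param seed integer RNG seed.
#' @return A [pixel_patch()].
#' @export
synth_patch <- function(B_true, noise_sd = 0, size = 11L, seed = 1L) {
  if (B_true < 0 || B_true > 100)
    stop_validation("B_true must lie in [0, 100]")
  if (size < 1L) stop_validation("size must be >= 1")
  if (noise_sd < 0) stop_validation("noise_sd must be nonnegative")
  base <- B_true / 100 * 255
  v <- if (noise_sd > 0)
    with_seed(seed, base + stats::rnorm(size * size, 0, noise_sd / 100 * 255))
  else rep(base, size * size)
  pixel_patch(matrix(pmin(255, pmax(0, v)), size, size))
}

#' Generate a subjects x regions facet-diameter table
#'
#' Compound-symmetric by construction: value = subject intercept + region
#' effect + residual noise, emulating per-worker regional facet-diameter
#' measurements over the five eye regions.
#'
#' @param subject_sd SD of the Gaussian subject intercepts, um.
#' @param region_effects named numeric vector of region offsets, um; at
#'   least 3 regions.
#' @param resid_sd residual SD, um.
#' @param n_subjects number of subjects (workers), >= 3.
#' @param grand_mean baseline facet diameter, um.
#' @param seed integer RNG seed.
#' @return Numeric matrix `n_subjects` x regions with the region effects
#'   attached as attribute `"truth"`.
#' @export
synth_regional_D <- function(subject_sd = 1,
                             region_effects = c(anterior = 0, dorsal = 0,
                                                lateral = 0, posterior = 0,
                                                ventral = 0),
                             resid_sd = 0.5, n_subjects = 14L,
                             grand_mean = 20, seed = 1L) {
  k <- length(region_effects)
  if (k < 3L) stop_validation("need at least 3 regions")
  if (n_subjects < 3L) stop_validation("need at least 3 subjects")
  if (subject_sd < 0 || resid_sd < 0)
    stop_validation("SDs must be nonnegative")
  with_seed(seed, {
    subj <- stats::rnorm(n_subjects, 0, subject_sd)
    Y <- outer(subj, rep(1, k)) +
      outer(rep(1, n_subjects), region_effects + grand_mean) +
      matrix(stats::rnorm(n_subjects * k, 0, resid_sd), n_subjects, k)
    colnames(Y) <- names(region_effects)
    if (resid_sd == 0 && all(region_effects == region_effects[1L]))
      attr(Y, "degenerate") <- TRUE
    attr(Y, "truth") <- region_effects
    Y
  })
}
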