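#' @keywords internal
"_PACKAGE"

# Sentinel for a biologically absent structure (e.g. an ocellus that is
# lacking), distinct from NA which means "not measured".
#' Marker for a biologically absent structure
#'
#' Distinguishes a structure that is truly lacking in a specimen (a
#' biological state, e.g. a missing anterior ocellus) from a measurement
#' that was simply not taken (`NA`).
#'
#' @return An object of class `"absent"`.
#' @export
absent <- function() structure(list(), class = "absent")

#' @export
print.absent <- function(x, ...) cat("<absent>\n")

#' Test for the absent marker
#' @param x object to test
#' @return logical
#' @export
is_absent <- function(x) inherits(x, "absent")

stop_validation <- function(msg, class = "ommatidics_validation_error") {
  stop(errorCondition(msg, class = c(class, "error", "condition")))
}

stop_config <- function(msg) {
  stop_validation(msg, class = "ommatidics_config_error")
}

#' Construct a digitized eye-edge profile
#'
#' An `eye_profile` is an ordered sequence of 2D points (in mm) digitized
#' along the edge of a compound eye viewed in profile, running anterior to
#' posterior. Consecutive points mark boundaries between facet rows. One
#' point, the apex, sits at the most protruding part of the eye edge and is
#' the anchor for the interommatidial-angle construction.
#'
#' @param points two-column numeric matrix or data frame of (x, y)
#'   coordinates in mm, ordered anterior to posterior.
#' @param apex_index integer index (1-based) of the apex point. Defaults to
#'   the middle point.
#' @param facet_rows_per_step integer; how many facet-row boundaries one
#'   index step represents (default 2 matches the two-facet-rows-away
#'   construction).
#' @param scale_mm_per_unit positive multiplier applied to raw coordinates
#'   to obtain mm (default 1, i.e. coordinates already in mm).
#' @param specimen_id optional specimen label.
#'
#' @return An object of class `eye_profile` with elements `points`
#'   (n x 2 matrix, mm), `apex_index`, `facet_rows_per_step`,
#'   `scale_mm_per_unit`, `specimen_id`.
#' @examples
#' th <- seq(-0.5, 0.5, length.out = 11)
#' pr <- eye_profile(cbind(0.5 * cos(th), 0.5 * sin(th)))
#' pr$apex_index
#' @export
eye_profile <- function(points, apex_index = NULL, facet_rows_per_step = 2L,
                        scale_mm_per_unit = 1, specimen_id = NA_character_) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 2L)
    stop_validation("`points` must be a two-column numeric matrix of (x, y)")
  if (anyNA(pts)) stop_validation("profile coordinates contain missing values")
  n <- nrow(pts)
  if (n < 5L) stop_validation(sprintf(
    "an eye profile needs at least 5 points, got %d", n))
  if (!is.numeric(scale_mm_per_unit) || length(scale_mm_per_unit) != 1L ||
      scale_mm_per_unit <= 0)
    stop_validation("`scale_mm_per_unit` must be a single positive number")
  if (is.null(apex_index)) apex_index <- as.integer(ceiling(n / 2))
  apex_index <- as.integer(apex_index)
  if (apex_index < 3L || apex_index > n - 2L)
    stop_validation(sprintf(
      "apex_index %d must leave at least 2 points on each side (n = %d)",
      apex_index, n))
  d <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  if (any(d == 0)) stop_validation("consecutive profile points must be distinct")
  structure(
    list(points = unname(pts) * scale_mm_per_unit,
         apex_index = apex_index,
         facet_rows_per_step = as.integer(facet_rows_per_step),
         scale_mm_per_unit = scale_mm_per_unit,
         specimen_id = specimen_id),
    class = "eye_profile")
}

#' @export
print.eye_profile <- function(x, ...) {
  cat(sprintf("<eye_profile: %d points, apex at %d%s>\n",
              nrow(x$points), x$apex_index,
              if (is.na(x$specimen_id)) "" else paste0(", ", x$specimen_id)))
  invisible(x)
}

#' Construct a pixel patch
#'
#' A small rectangular sample of pixels over which cuticular brightness is
#' averaged; the measurement protocol uses an 11 x 11 patch. Either a
#' grayscale matrix or an RGB array (height x width x 3) with channel
#' values in 0-255.
#'
#' @param values numeric matrix (grayscale) or 3D array (RGB), values in
#'   0-255.
#' @return An object of class `pixel_patch`.
#' @examples
#' p <- pixel_patch(matrix(128, 11, 11))
#' patch_brightness(p)
#' @export
pixel_patch <- function(values) {
  v <- if (is.data.frame(values)) as.matrix(values) else values
  if (!is.numeric(v)) stop_validation("patch values must be numeric")
  dims <- dim(v)
  if (is.null(dims) || !(length(dims) %in% c(2L, 3L)))
    stop_validation("patch must be a matrix or a height x width x 3 array")
  if (length(dims) == 3L && dims[3L] != 3L)
    stop_validation("an RGB patch needs exactly 3 channels")
  if (length(v) == 0L || dims[1L] < 1L || dims[2L] < 1L)
    stop_validation("patch must be non-empty")
  if (anyNA(v) || any(v < 0) || any(v > 255))
    stop_validation("all channel values must lie in [0, 255]")
  structure(list(values = v, height = dims[1L], width = dims[2L],
                 channels = if (length(dims) == 3L) 3L else 1L),
            class = "pixel_patch")
}

#' @export
print.pixel_patch <- function(x, ...) {
  cat(sprintf("<pixel_patch %dx%d, %s>\n", x$height, x$width,
              if (x$channels == 3L) "RGB" else "grayscale"))
  invisible(x)
}

#' Load a packaged data table
#'
#' Returns one of the species/contingency/survey tables shipped with the
#' package: `"table1"` (26 species with brightness, activity, and -- for
#' the 23 morphometrically measured species -- raw and covariate-adjusted
#' means for eye area, facet number and facet diameter D, plus mesosoma
#' length), `"table2"` (the 2 x 3 color-by-activity contingency table),
#' `"table5"` (21 candidate pale taxa from the photographic survey), and
#' `"tableS1"` (the per-genus dark-congener reference maxima of relative
#' eye size).
#'
#' @param name one of `"table1"`, `"table2"`, `"table5"`, `"tableS1"`.
#' @return For `"table2"`, an integer matrix with color classes as rows and
#'   activity classes as columns; otherwise a data frame.
#' @examples
#' t2 <- load_fixture("table2")
#' rowSums(t2)
#' @export
load_fixture <- function(name = c("table1", "table2", "table5", "tableS1")) {
  if (length(name) != 1L || !name %in% c("table1", "table2", "table5", "tableS1"))
    stop_config(sprintf("unknown fixture name: %s",
                        paste(as.character(name), collapse = ", ")))
  file <- switch(name,
    table1  = "table1_species.csv",
    table2  = "table2_contingency.csv",
    table5  = "table5_survey.csv",
    tableS1 = "tableS1_dark_references.csv")
  path <- system.file("extdata", file, package = "ommatidics", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (name == "table2") {
    m <- as.matrix(df[, -1L])
    storage.mode(m) <- "integer"
    dimnames(m) <- list(df$color_class, colnames(df)[-1L])
    return(m)
  }
  if (name == "table1") {
    df$color_class <- factor(df$color_class, levels = c("pale", "dark"))
    df$activity_class <- factor(df$activity_class,
                                levels = c("nocturnal", "variable", "diurnal"))
  }
  df
}

#' Read a digitized eye profile from CSV or JSON
#'
#' CSV files carry columns `row` (1-based), `x`, `y` and optionally
#' `is_apex` (0/1 flag on exactly one row). JSON files carry `points` (list
#' of (x, y) pairs), optional `apex_index` (1-based) and optional
#' `scale_mm_per_unit`.
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`; inferred from the file extension when
#'   omitted.
#' @param ... passed on to [eye_profile()].
#' @return An [eye_profile()].
#' @export
read_eye_profile <- function(path, format = c("auto", "csv", "json"), ...) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) stop_validation(
                     sprintf("could not parse %s: %s", path, conditionMessage(e))))
    if (!all(c("x", "y") %in% names(df)))
      stop_validation("eye profile CSV needs columns `x` and `y`")
    if (!is.numeric(df$x) || !is.numeric(df$y))
      stop_validation("eye profile coordinates must be numeric")
    apex <- NULL
    if ("is_apex" %in% names(df)) {
      w <- which(df$is_apex %in% c(1, TRUE))
      if (length(w) == 1L) apex <- w
      else if (length(w) > 1L) stop_validation("more than one row flagged is_apex")
    }
    eye_profile(cbind(df$x, df$y), apex_index = apex, ...)
  } else {
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e) stop_validation(
                      sprintf("could not parse %s: %s", path, conditionMessage(e))))
    pts <- obj$points
    if (is.null(pts)) stop_validation("eye profile JSON needs a `points` field")
    pts <- if (is.list(pts)) do.call(rbind, pts) else as.matrix(pts)
    args <- list(points = pts, ...)
    if (!is.null(obj$apex_index)) args$apex_index <- obj$apex_index
    if (!is.null(obj$scale_mm_per_unit))
      args$scale_mm_per_unit <- obj$scale_mm_per_unit
    do.call(eye_profile, args)
  }
}

#' Write an eye profile to CSV
#'
#' Coordinates are written at 6 decimal places with columns
#' `row,x,y,is_apex`, the format read back by [read_eye_profile()].
#'
#' @param profile an [eye_profile()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_eye_profile <- function(profile, path) {
  stopifnot(inherits(profile, "eye_profile"))
  n <- nrow(profile$points)
  df <- data.frame(row = seq_len(n),
                   x = sprintf("%.6f", profile$points[, 1L]),
                   y = sprintf("%.6f", profile$points[, 2L]),
                   is_apex = as.integer(seq_len(n) == profile$apex_index))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pixel patch from CSV or PNG
#'
#' CSV patches are plain numeric grids in 0-255 (no header). PNG patches
#' are decoded with the png package; RGB(A) images keep their first three
#' channels, and intensities are rescaled from 0-1 to 0-255.
#'
#' @param path file path ending in `.csv` or `.png`.
#' @return A [pixel_patch()].
#' @export
read_patch <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , seq_len(min(3L, dim(img)[3L])), drop = TRUE]
    pixel_patch(img * 255)
  } else {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    if (!is.numeric(m)) stop_validation("patch CSV must be numeric")
    pixel_patch(unname(m))
  }
}

#' Construct one worker's morphometric record
#'
#' @param species_id,colony_id identifiers.
#' @param mesosoma_length Weber's length in mm (body-size proxy); positive.
#' @param eye_area compound-eye area in mm^2.
#' @param facet_count number of ommatidial facets.
#' @param facet_diameter_D mean facet diameter at the eye centroid, um.
#' @param ocellus_diameter anterior ocellus diameter in um, `NA` if not
#'   measured, or [absent()] when the ocellus is biologically lacking.
#' @param dphi_deg,span_deg optional interommatidial angle and visual field
#'   span, degrees.
#' @param regional_D optional named list of per-region facet diameters (um)
#'   with names among anterior, dorsal, lateral, posterior, ventral.
#' @return A `worker_record` list.
#' @export
worker_record <- function(species_id, colony_id = NA_character_,
                          mesosoma_length, eye_area = NA_real_,
                          facet_count = NA_integer_,
                          facet_diameter_D = NA_real_,
                          ocellus_diameter = NA_real_,
                          dphi_deg = NA_real_, span_deg = NA_real_,
                          regional_D = list()) {
  if (!is.numeric(mesosoma_length) || mesosoma_length <= 0)
    stop_validation("mesosoma_length must be positive")
  if (!is.na(eye_area) && eye_area < 0)
    stop_validation("eye_area must be nonnegative")
  if (!is.na(facet_diameter_D) && facet_diameter_D < 0)
    stop_validation("facet diameter must be nonnegative")
  if (!is.na(facet_count) && facet_count < 0)
    stop_validation("facet_count must be nonnegative")
  regions <- c("anterior", "dorsal", "lateral", "posterior", "ventral")
  if (length(regional_D) &&
      !all(names(regional_D) %in% regions))
    stop_validation(sprintf("regional_D names must be among: %s",
                            paste(regions, collapse = ", ")))
  structure(list(species_id = species_id, colony_id = colony_id,
                 mesosoma_length = mesosoma_length, eye_area = eye_area,
                 facet_count = facet_count,
                 facet_diameter_D = facet_diameter_D,
                 ocellus_diameter = ocellus_diameter,
                 dphi_deg = dphi_deg, span_deg = span_deg,
                 regional_D = regional_D),
            class = "worker_record")
}

#' Verify packaged table integrity
#'
#' Recomputes basic structural invariants of the shipped tables: Table 1
#' holds 26 species (23 with morphometric means), Table 2 row sums are 10
#' and 16 with grand total 26, Table 5 has 21 candidates and the dark
#' reference table one row per surveyed genus.
#'
#' @return `TRUE` invisibly, or an error describing the failed check.
#' @export
check_fixtures <- function() {
  t1 <- load_fixture("table1")
  if (nrow(t1) != 26L) stop_validation("table1 must have 26 species rows")
  if (sum(!is.na(t1$D_raw)) != 23L)
    stop_validation("table1 must have 23 morphometrically measured species")
  t2 <- load_fixture("table2")
  if (!all(rowSums(t2) == c(10, 16)) || sum(t2) != 26)
    stop_validation("table2 margins must be 10/16 with grand total 26")
  t5 <- load_fixture("table5")
  if (nrow(t5) != 21L) stop_validation("table5 must have 21 candidate rows")
  s1 <- load_fixture("tableS1")
  if (!setequal(s1$genus, unique(t5$genus)))
    stop_validation("dark references must cover every surveyed genus")
  invisible(TRUE)
}
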