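# Cuticular brightness protocol: HSB brightness averaged over a small pixel
# patch, three tagmata per worker, workers per species.

#' Mean brightness of a pixel patch
#'
#' Brightness follows the HSB convention of standard image editors: per
#' pixel, B = max(R, G, B) / 255 * 100; for grayscale input B =
#' value / 255 * 100. The patch value is the mean over all pixels, in
#' percent.
#'
#' @param patch a [pixel_patch()], or a numeric matrix/array coercible to
#'   one.
#' @return Brightness in percent, in `[0, 100]`.
#' @examples
#' patch_brightness(pixel_patch(matrix(255, 11, 11)))  # 100
#' @export
patch_brightness <- function(patch) {
  if (!inherits(patch, "pixel_patch")) patch <- pixel_patch(patch)
  v <- patch$values
  per_pixel <- if (patch$channels == 3L) {
    pmax(v[, , 1L], v[, , 2L], v[, , 3L])
  } else {
    v
  }
  mean(per_pixel) / 255 * 100
}

#' Worker-level brightness from the three tagmata
#'
#' One brightness reading is taken on each major body region (head just
#' posterior to the eye, center of the mesopleura, first gastral tergum)
#' and the worker value is their arithmetic mean, which absorbs
#' within-individual color variation. If a tagma value is `NA` the mean is
#' taken over the present tagmata with a warning.
#'
#' @param head_B,mesosoma_B,gaster_B brightness percentages in `[0, 100]`.
#' @return Worker brightness in percent.
#' @examples
#' worker_brightness(60, 70, 80)  # 70
#' @export
worker_brightness <- function(head_B, mesosoma_B, gaster_B) {
  b <- c(head = head_B, mesosoma = mesosoma_B, gaster = gaster_B)
  present <- !is.na(b)
  if (!any(present)) stop_validation("all three tagma values are missing")
  if (any(b[present] < 0 | b[present] > 100))
    stop_validation("tagma brightness values must lie in [0, 100]")
  if (!all(present))
    warning(sprintf("averaging over %d of 3 tagmata (%s missing)",
                    sum(present), paste(names(b)[!present], collapse = ", ")))
  mean(b[present])
}

#' Classify a species as pale or dark from mean brightness
#'
#' Two schemes are used. In the main comparative analysis the pale and
#' dark classes are separated by an empirical gap: pale above 65, dark
#' below 60, indeterminate in between. The photographic survey uses a
#' single cut at 70: pale above, dark otherwise.
#'
#' @param species_B species mean brightness in percent.
#' @param scheme `"main_study"` or `"survey"`.
#' @return factor level `"pale"`, `"dark"` or `"indeterminate"`
#'   (vectorized over `species_B`).
#' @examples
#' classify_color(c(74.6, 45.4, 62), "main_study")
#' @export
classify_color <- function(species_B, scheme = c("main_study", "survey")) {
  if (length(scheme) != 1L || !scheme %in% c("main_study", "survey"))
    stop_config(sprintf("unknown classification scheme: %s",
                        paste(as.character(scheme), collapse = ", ")))
  if (any(!is.na(species_B) & (species_B < 0 | species_B > 100)))
    stop_validation("brightness must lie in [0, 100]")
  out <- if (scheme == "main_study") {
    ifelse(species_B > 65, "pale",
           ifelse(species_B < 60, "dark", "indeterminate"))
  } else {
    ifelse(species_B > 70, "pale", "dark")
  }
  factor(out, levels = c("pale", "dark", "indeterminate"))
}

#' Pooled-variance t-test of pale versus dark brightness
#'
#' Compares species-mean brightness between the pale and dark classes with
#' a pooled two-sample t-test (df = n1 + n2 - 2). The statistic is
#' computed for the contrast dark minus pale -- the alphabetical group
#' ordering of the original analysis -- so a brighter pale group yields a
#' negative t.
#'
#' @param pale_Bs,dark_Bs numeric vectors of species-mean brightness, at
#'   least 2 values each.
#' @return list with `t`, `df`, `p` (two-sided), and the two group means.
#' @examples
#' brightness_group_test(c(70, 75, 72), c(40, 45, 50))
#' @export
brightness_group_test <- function(pale_Bs, dark_Bs) {
  pale_Bs <- pale_Bs[!is.na(pale_Bs)]
  dark_Bs <- dark_Bs[!is.na(dark_Bs)]
  n1 <- length(dark_Bs); n2 <- length(pale_Bs)
  if (n1 < 2L || n2 < 2L)
    stop_validation("each group needs at least 2 values")
  sp2 <- ((n1 - 1) * stats::var(dark_Bs) + (n2 - 1) * stats::var(pale_Bs)) /
    (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- if (se == 0) 0 else (mean(dark_Bs) - mean(pale_Bs)) / se
  df <- n1 + n2 - 2L
  list(t = tval, df = df,
       p = 2 * stats::pt(-abs(tval), df),
       mean_pale = mean(pale_Bs), mean_dark = mean(dark_Bs))
}
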