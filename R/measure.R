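# Front end: one call from an annotation to the four radii per structure.

#' Measure femoral sagittal bowing from an annotation
#'
#' Runs the full measurement pipeline on an annotated radiograph: constructs
#' the landmark endpoints from the traced borders and the three marked
#' points, extracts the central line of each requested structure by the
#' equal-speed territory method, and fits the whole-curve and per-third
#' radii of curvature.
#'
#' @param annotation An annotation document (see [annotation_document()]) or
#'   the path of an annotation JSON file.
#' @param structures Structures to measure: subset of
#'   `c("outline", "canal")`.
#' @param supersample Territory-grid supersampling factor (cells per image
#'   pixel).
#' @param pixel_spacing,magnification Optional overrides of the annotation's
#'   calibration fields.
#' @param n_resample Uniform resampling of the midline before circle
#'   fitting.
#' @return An object of class `bowing_measurement` with the `landmarks`, the
#'   per-structure `midlines` and `radii` (`radius_measurement` objects),
#'   and the trimmed `borders`. Methods: `print`, `summary`, `coef` (mm
#'   radius matrix), `residuals` (whole-fit orthogonal residuals, px),
#'   `as.data.frame` (measurement-table rows), `plot` (annotation overlay).
#' @examples
#' ph <- generate_three_arc_femur(seed = 1)
#' ann <- annotation_document(ph$outline, ph$canal, ph$marks$p1,
#'                            ph$marks$p2, ph$marks$p3, pixel_spacing = 0.15)
#' \donttest{
#' m <- measure_bowing(ann, structures = "outline")
#' coef(m)
#' }
#' @export
measure_bowing <- function(annotation, structures = c("outline", "canal"),
                           supersample = 2L, pixel_spacing = NULL,
                           magnification = NULL, n_resample = 300L) {
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  annotation <- validate_annotation(annotation)
  structures <- match.arg(structures, several.ok = TRUE)
  spacing <- pixel_spacing %||% annotation$pixel_spacing
  mag <- magnification %||% annotation$magnification %||% 1
  outline <- border_pair(annotation$borders$outline_upper,
                         annotation$borders$outline_lower, "outline")
  canal <- border_pair(annotation$borders$canal_upper,
                       annotation$borders$canal_lower, "canal")
  lm <- construct_landmarks(outline, canal, annotation$landmarks$p1,
                            annotation$landmarks$p2, annotation$landmarks$p3)
  pairs <- list(outline = outline, canal = canal)
  midlines <- radii <- list()
  for (st in structures) {
    ml <- compute_midline(pairs[[st]], lm, supersample = supersample)
    midlines[[st]] <- ml
    radii[[st]] <- measure_radii(ml, spacing, mag, n_resample = n_resample,
                                 subject = annotation$subject$id %||% NA_character_,
                                 observer = annotation$observer %||% NA_character_,
                                 repeat_index = annotation$repeat_index %||% NA_integer_)
  }
  base::structure(list(landmarks = lm, midlines = midlines, radii = radii,
                       borders = pairs, pixel_spacing = spacing,
                       magnification = mag, supersample = supersample,
                       subject = annotation$subject,
                       observer = annotation$observer %||% NA_character_,
                       repeat_index = annotation$repeat_index %||% NA_integer_,
                       call = match.call()),
                  class = "bowing_measurement")
}

#' @export
print.bowing_measurement <- function(x, ...) {
  cat("Femoral sagittal bowing measurement\n")
  cat(sprintf("  pixel spacing %.4g mm/px, magnification %.3g, supersample %d\n",
              x$pixel_spacing, x$magnification, x$supersample))
  print(coef(x))
  invisible(x)
}

#' @export
coef.bowing_measurement <- function(object, ...) {
  parts <- c("whole", "proximal", "middle", "distal")
  out <- t(vapply(object$radii,
                  function(r) vapply(parts, function(p) r[[p]], numeric(1)),
                  numeric(4L)))
  colnames(out) <- paste0(parts, "_mm")
  out
}

#' @export
summary.bowing_measurement <- function(object, ...) {
  cat("Femoral sagittal bowing measurement\n")
  cat(sprintf("  subject %s, observer %s, repeat %s\n",
              object$subject$id %||% NA, object$observer,
              object$repeat_index))
  cat(sprintf("  pixel spacing %.4g mm/px, magnification %.3g, supersample %d\n",
              object$pixel_spacing, object$magnification, object$supersample))
  cat(sprintf("  equal-angle landmark residual %.4f deg\n",
              object$landmarks$angle_residual))
  for (st in names(object$radii)) {
    r <- object$radii[[st]]
    ml <- object$midlines[[st]]
    cat(sprintf("  %s: midline %.1f px, equidistance residual %.3f px\n",
                st, arc_length(ml$points), ml$equidistance_residual))
    for (p in c("whole", "proximal", "middle", "distal"))
      cat(sprintf("    %-8s %8.1f mm  (fit rms %.3f px%s)\n", p, r[[p]],
                  r$rms_residuals[[p]],
                  if (r$near_straight[[p]]) ", near-straight" else ""))
  }
  invisible(object)
}

#' @export
residuals.bowing_measurement <- function(object, ...) {
  lapply(object$radii, function(r) {
    f <- r$fits$whole
    pts <- NULL
    # orthogonal residuals of the whole-curve fit at the resampled points
    ml <- object$midlines[[r$structure]]
    pts <- resample_uniform(ml$points, 300L)
    sqrt((pts[, 1L] - f$center[1L])^2 + (pts[, 2L] - f$center[2L])^2) - f$radius
  })
}

#' @export
as.data.frame.bowing_measurement <- function(x, ...) {
  out <- do.call(rbind, lapply(x$radii, as.data.frame))
  rownames(out) <- NULL
  out$sex <- x$subject$sex %||% NA_character_
  out$age <- x$subject$age %||% NA_real_
  out
}

#' @export
plot.bowing_measurement <- function(x, structures = names(x$midlines),
                                    circles = TRUE, ...) {
  allp <- do.call(rbind, unlist(lapply(x$borders[structures], function(p)
    list(p$upper, p$lower)), recursive = FALSE))
  plot(NA, xlim = range(allp[, 1L]), ylim = rev(range(allp[, 2L])),
       asp = 1, xlab = "x (px)", ylab = "y (px)", ...)
  cols <- c(outline = "grey30", canal = "steelblue")
  for (st in structures) {
    b <- x$borders[[st]]
    lines(b$upper, col = cols[[st]])
    lines(b$lower, col = cols[[st]])
    ml <- x$midlines[[st]]
    lines(ml$points, col = "deeppink", lwd = 2)
    if (circles) {
      f <- x$radii[[st]]$fits$whole
      if (!f$near_straight) {
        th <- seq(0, 2 * pi, length.out = 720)
        lines(f$center[1L] + f$radius * cos(th),
              f$center[2L] + f$radius * sin(th),
              col = "darkorange", lty = 3)
      }
    }
  }
  lm <- x$landmarks
  pts <- rbind(lm$p1, lm$p2, lm$p3, lm$p4, lm$a, lm$b, lm$c, lm$d)
  points(pts, pch = 19, col = "red", cex = 0.8)
  invisible(x)
}
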