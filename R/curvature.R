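# Circle fitting and radius-of-curvature measurement.
#
# The radius of each (sub)curve is the radius of the least-squares circle:
# an algebraic (Kasa) fit followed by one geometric Gauss-Newton refinement
# pass on the orthogonal-distance residuals. All-points fitting is used
# rather than a three-point circle because the latter is fragile to tracing
# noise. Pixel radii convert to mm only here: mm = px * pixel_spacing /
# magnification.

straight_segment_error <- function(msg, span) {
  stop(errorCondition(msg, span = span,
                      class = c("straight_segment_error", "error")))
}

#' Least-squares circle fit
#'
#' Algebraic least-squares circle (minimizing the algebraic residual of
#' `x^2 + y^2 + D x + E y + F`) followed by one Gauss-Newton refinement pass
#' on the orthogonal distances.
#'
#' @param points An `n x 2` matrix of points, `n >= 3`, not all collinear.
#' @return An object of class `circle_fit`: `center` (`c(x, y)`), `radius`
#'   (px), `rms_residual` (root-mean-square orthogonal distance, px), and
#'   `near_straight` (`TRUE` when `radius > 1e5` px).
#' @export
fit_circle <- function(points) {
  pts <- matrix(as.numeric(points), ncol = 2L)
  if (nrow(pts) < 3L) stop("circle fit needs at least 3 points")
  if (!all(is.finite(pts))) stop("non-finite coordinates")
  ctr <- colMeans(pts)
  x <- pts[, 1L] - ctr[1L]
  y <- pts[, 2L] - ctr[2L]
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  qrA <- qr(A)
  span <- max(dist(rbind(range(pts[, 1L]), range(pts[, 2L]))))
  # collinearity: the normal equations become rank deficient
  R <- qr.R(qrA)
  if (qrA$rank < 3L || abs(R[1L, 1L] * R[2L, 2L]) < 1e-12 * max(abs(R)) ||
      rcond(crossprod(A)) < 1e-14)
    straight_segment_error("points are collinear: no finite circle", span)
  sol <- unname(qr.coef(qrA, b))
  cx <- -sol[1L] / 2
  cy <- -sol[2L] / 2
  r2 <- cx^2 + cy^2 - sol[3L]
  if (!is.finite(r2) || r2 <= 0)
    straight_segment_error("degenerate circle fit", span)
  r <- sqrt(r2)
  # one geometric (orthogonal-distance) Gauss-Newton pass
  ux <- x - cx; uy <- y - cy
  di <- sqrt(ux^2 + uy^2)
  if (all(di > 0)) {
    J <- cbind(-ux / di, -uy / di, -1)
    rhs <- -(di - r)
    step <- tryCatch(qr.coef(qr(J), rhs), error = function(e) NULL)
    if (!is.null(step) && all(is.finite(step))) {
      cx2 <- cx + step[1L]; cy2 <- cy + step[2L]; rr2 <- r + step[3L]
      d2 <- sqrt((x - cx2)^2 + (y - cy2)^2)
      if (rr2 > 0 && sqrt(mean((d2 - rr2)^2)) <= sqrt(mean((di - r)^2))) {
        cx <- cx2; cy <- cy2; r <- rr2; di <- d2
      }
    }
  }
  structure(list(center = c(x = cx + ctr[1L], y = cy + ctr[2L]),
                 radius = r,
                 rms_residual = sqrt(mean((di - r)^2)),
                 near_straight = r > 1e5),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("<circle_fit> radius %.2f px, center (%.2f, %.2f), rms residual %.4f px%s\n",
              x$radius, x$center[1L], x$center[2L], x$rms_residual,
              if (x$near_straight) " [near-straight]" else ""))
  invisible(x)
}

#' Split a central line into three equal arc-length segments
#'
#' Contiguous proximal/middle/distal sub-polylines of equal arc length; the
#' two interior boundary points are interpolated exactly and duplicated into
#' both neighbouring segments.
#'
#' @param midline A `midline` or a polyline matrix.
#' @return A list of three polylines: `proximal`, `middle`, `distal`.
#' @export
split_equal_thirds <- function(midline) {
  pts <- if (inherits(midline, "midline")) midline$points else as_polyline(midline)
  cs <- cumulative_arc(pts)
  L <- cs[length(cs)]
  if (L <= 0) stop("midline has zero arc length")
  cut <- function(s0, s1) {
    inner <- pts[cs > s0 + 1e-12 & cs < s1 - 1e-12, , drop = FALSE]
    out <- rbind(point_at_arc(pts, s0), inner, point_at_arc(pts, s1))
    d <- sqrt(rowSums((out[-1L, , drop = FALSE] -
                       out[-nrow(out), , drop = FALSE])^2))
    if (any(d < 1e-12)) out <- out[c(TRUE, d >= 1e-12), , drop = FALSE]
    as_polyline(out)
  }
  list(proximal = cut(0, L / 3),
       middle = cut(L / 3, 2 * L / 3),
       distal = cut(2 * L / 3, L))
}

#' Measure the four radii of curvature of a central line
#'
#' Resamples the midline to `n_resample` uniform points, fits a circle to the
#' whole curve and to each equal arc-length third, and converts pixel radii
#' to millimetres: `mm = px * pixel_spacing / magnification`.
#'
#' @param midline A `midline` (or polyline matrix).
#' @param pixel_spacing Pixel spacing in mm/px (`> 0`).
#' @param magnification Radiograph projection magnification factor (`> 0`);
#'   1 means no correction.
#' @param n_resample Number of uniform resampling points before fitting.
#' @param subject,observer,repeat_index Optional metadata carried into the
#'   result.
#' @return An object of class `radius_measurement` with mm radii `whole`,
#'   `proximal`, `middle`, `distal`, the per-part `circle_fit`s (`fits`),
#'   `rms_residuals` (px), `near_straight` flags, `structure`,
#'   `pixel_spacing`, `magnification` and the metadata.
#' @export
measure_radii <- function(midline, pixel_spacing, magnification = 1,
                          n_resample = 300L, subject = NA_character_,
                          observer = NA_character_, repeat_index = NA_integer_) {
  if (!is.numeric(pixel_spacing) || pixel_spacing <= 0)
    stop("pixel_spacing must be positive (mm per pixel)")
  if (!is.numeric(magnification) || magnification <= 0)
    stop("magnification must be positive")
  pts <- if (inherits(midline, "midline")) midline$points else as_polyline(midline)
  structure_tag <- if (inherits(midline, "midline")) midline$source else NA_character_
  pts <- resample_uniform(pts, n_resample)
  thirds <- split_equal_thirds(pts)
  fit_part <- function(p, part) {
    tryCatch(fit_circle(p), straight_segment_error = function(e) {
      straight_segment_error(
        sprintf("%s segment is straight (span %.1f px)", part,
                e$span %||% NA_real_),
        e$span)
    })
  }
  fits <- list(whole = fit_part(pts, "whole"),
               proximal = fit_part(thirds$proximal, "proximal"),
               middle = fit_part(thirds$middle, "middle"),
               distal = fit_part(thirds$distal, "distal"))
  to_mm <- pixel_spacing / magnification
  structure(list(whole = fits$whole$radius * to_mm,
                 proximal = fits$proximal$radius * to_mm,
                 middle = fits$middle$radius * to_mm,
                 distal = fits$distal$radius * to_mm,
                 rms_residuals = vapply(fits, function(f) f$rms_residual,
                                        numeric(1)),
                 near_straight = vapply(fits, function(f) f$near_straight,
                                        logical(1)),
                 fits = fits, structure = structure_tag,
                 pixel_spacing = pixel_spacing, magnification = magnification,
                 subject = subject, observer = observer,
                 repeat_index = repeat_index),
            class = "radius_measurement")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.radius_measurement <- function(x, ...) {
  cat(sprintf("<radius_measurement> %s (spacing %.4g mm/px, magnification %.3g)\n",
              x$structure, x$pixel_spacing, x$magnification))
  for (p in c("whole", "proximal", "middle", "distal"))
    cat(sprintf("  %-8s %8.1f mm%s\n", p, x[[p]],
                if (x$near_straight[[p]]) " [near-straight]" else ""))
  invisible(x)
}

#' @export
as.data.frame.radius_measurement <- function(x, ...) {
  data.frame(subject = x$subject, structure = x$structure,
             observer = x$observer, repeat_index = x$repeat_index,
             whole_mm = x$whole, proximal_mm = x$proximal,
             middle_mm = x$middle, distal_mm = x$distal,
             rms_whole_px = x$rms_residuals[["whole"]],
             rms_proximal_px = x$rms_residuals[["proximal"]],
             rms_middle_px = x$rms_residuals[["middle"]],
             rms_distal_px = x$rms_residuals[["distal"]],
             stringsAsFactors = FALSE)
}
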