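# Construction of the measurement endpoints on a lateral femur radiograph.
#
# Operator input: the distal shaft/condyle junctions on the upper and lower
# cortical borders (points 1, 2) and the bottom of the lesser trochanter on
# the lower cortical border (point 3). Derived here: the distal end line
# (through 1 and 2) and its canal crossings (a, b); the proximal end line
# through 3 making equal acute angles with both cortical borders, its upper
# cortical crossing (point 4) and its canal crossings (c, d).

#' Construct a border pair
#'
#' The upper (anterior) and lower (posterior) traced borders of one
#' structure, both ordered proximal to distal.
#'
#' @param upper,lower Polylines (see [as_polyline()]), ordered proximal to
#'   distal.
#' @param structure `"outline"` (cortical shaft outline) or `"canal"`
#'   (medullary canal).
#' @return An object of class `border_pair`.
#' @export
border_pair <- function(upper, lower, structure = c("outline", "canal")) {
  structure_tag <- match.arg(structure)
  base::structure(list(upper = as_polyline(upper), lower = as_polyline(lower),
                       structure = structure_tag),
                  class = "border_pair")
}

#' @export
print.border_pair <- function(x, ...) {
  cat(sprintf("<border_pair> %s: upper %d pts (%.1f px), lower %d pts (%.1f px)\n",
              x$structure, nrow(x$upper), arc_length(x$upper),
              nrow(x$lower), arc_length(x$lower)))
  invisible(x)
}

landmark_error <- function(msg) {
  stop(errorCondition(msg, class = c("landmark_construction_error", "error")))
}

# pick the intersection of line with one border, preferring the most distal
# (end = "distal") or most proximal (end = "proximal") crossing
border_line_crossing <- function(line, border, end, what) {
  hits <- intersect_line_polyline(line, border)
  if (nrow(hits) == 0L)
    landmark_error(sprintf("end line does not intersect the %s", what))
  row <- if (end == "distal") hits[nrow(hits), ] else hits[1L, ]
  c(x = row$x, y = row$y)
}

#' Distal end line and distal canal endpoints
#'
#' Draws the line through the two marked distal cortical junctions and
#' intersects it with both medullary-canal borders; when a border crosses the
#' line more than once the most distal crossing is taken.
#'
#' @param p1,p2 Marked distal junction points on the upper and lower cortical
#'   borders, `c(x, y)`.
#' @param canal A `border_pair` with `structure = "canal"`.
#' @return A list with `line` (a [line2d()] through `p1` and `p2`), `a`
#'   (crossing with the upper canal border) and `b` (lower canal border).
#' @export
distal_line_and_canal_ends <- function(p1, p2, canal) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (all(p1 == p2)) stop("p1 and p2 must be distinct points")
  stopifnot(inherits(canal, "border_pair"))
  line <- line_through(p1, p2)
  list(line = line,
       a = border_line_crossing(line, canal$upper, "distal",
                                "upper medullary-canal border"),
       b = border_line_crossing(line, canal$lower, "distal",
                                "lower medullary-canal border"))
}

#' Proximal canal endpoints
#'
#' Intersects the proximal end line with both medullary-canal borders,
#' taking the most proximal crossing of each.
#'
#' @param proximal_line The equal-angle proximal end line (a [line2d()]).
#' @param canal A `border_pair` with `structure = "canal"`.
#' @return A list with points `c` (upper canal border) and `d` (lower).
#' @export
proximal_canal_ends <- function(proximal_line, canal) {
  stopifnot(inherits(proximal_line, "line2d"), inherits(canal, "border_pair"))
  list(c = border_line_crossing(proximal_line, canal$upper, "proximal",
                                "upper medullary-canal border"),
       d = border_line_crossing(proximal_line, canal$lower, "proximal",
                                "lower medullary-canal border"))
}

#' Equal-angle proximal end line
#'
#' Finds the line through the marked lesser-trochanter point `p3` whose acute
#' angle to the local tangent of the lower cortical border at `p3` equals its
#' acute angle to the local tangent of the upper cortical border at the
#' crossing point. Solved by bisection of the signed angle difference over a
#' search range centred on the perpendicular to the lower border's tangent;
#' when every direction satisfies the equality (locally parallel borders) the
#' perpendicular itself is returned.
#'
#' @param p3 Marked point at the bottom of the lesser trochanter; must lie on
#'   `outline$lower` within 0.5 px.
#' @param outline A `border_pair` with `structure = "outline"`.
#' @param search_range Half-width of the direction search range around the
#'   perpendicular, degrees.
#' @param tol Angle-residual tolerance in degrees.
#' @param tangent_window Window (px) for local tangent estimation; default
#'   spans 21 vertices of a 300-point uniform resampling of the border.
#' @return A list with `line` (the proximal end line), `p4` (its crossing
#'   with the upper cortical border) and `residual` (final absolute angle
#'   difference, degrees).
#' @export
equal_angle_proximal_line <- function(p3, outline, search_range = 60,
                                      tol = 0.05, tangent_window = NULL) {
  stopifnot(inherits(outline, "border_pair"))
  p3 <- as.numeric(p3)
  lower <- outline$lower
  upper <- outline$upper
  # default window spans 21 points of a 300-point uniform resampling
  if (is.null(tangent_window))
    tangent_window <- 21 * arc_length(lower) / 299
  pr <- project_onto_polyline(p3, lower)
  if (pr$distance > 0.5)
    landmark_error("p3 does not lie on the lower cortical border (within 0.5 px)")
  tau_low <- local_tangent_angle(lower, pr$s, tangent_window)
  phi0 <- tau_low + 90   # perpendicular to the lower border at p3

  angle_diff <- function(phi) {
    ln <- line2d(p3, phi)
    hits <- intersect_line_polyline(ln, upper)
    if (nrow(hits) == 0L) return(NA_real_)
    # crossing nearest to p3 (the anatomically adjacent part of the border)
    i <- which.min((hits$x - p3[1L])^2 + (hits$y - p3[2L])^2)
    tau_up <- local_tangent_angle(upper, hits$s[i], tangent_window)
    acute_between(phi, tau_low) - acute_between(phi, tau_up)
  }

  grid <- seq(phi0 - search_range, phi0 + search_range, by = 1)
  fg <- vapply(grid, angle_diff, numeric(1))
  ok <- which(is.finite(fg))
  if (length(ok) == 0L)
    landmark_error("no direction in the search range intersects the upper cortical border")

  # degenerate (parallel borders): every direction works -> perpendicular
  if (max(abs(fg[ok])) <= tol) {
    phi <- phi0
  } else {
    # bracket sign changes between consecutive finite samples
    roots <- numeric(0)
    for (k in seq_len(length(ok) - 1L)) {
      i <- ok[k]; j <- ok[k + 1L]
      if (j != i + 1L) next
      if (fg[i] == 0) { roots <- c(roots, grid[i]); next }
      if (sign(fg[i]) * sign(fg[j]) < 0) {
        lo <- grid[i]; hi <- grid[j]; flo <- fg[i]
        for (it in 1:60) {
          mid <- (lo + hi) / 2
          fm <- angle_diff(mid)
          if (!is.finite(fm) || abs(fm) <= tol / 4 || (hi - lo) < 1e-5) break
          if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
        }
        roots <- c(roots, (lo + hi) / 2)
      }
    }
    if (length(roots) == 0L) {
      # no sign change: accept a grid minimum that meets the tolerance
      i <- ok[which.min(abs(fg[ok]))]
      if (abs(fg[i]) <= tol) roots <- grid[i]
      else landmark_error(
        "equal-angle condition has no solution in the search range")
    }
    phi <- roots[which.min(abs(roots - phi0))]  # root nearest perpendicular
  }

  line <- line2d(p3, phi)
  hits <- intersect_line_polyline(line, outline$upper)
  if (nrow(hits) == 0L)
    landmark_error("proximal line does not intersect the upper cortical border")
  i <- which.min((hits$x - p3[1L])^2 + (hits$y - p3[2L])^2)
  res <- angle_diff(phi)
  list(line = line, p4 = c(x = hits$x[i], y = hits$y[i]),
       residual = if (is.finite(res)) abs(res) else NA_real_)
}

#' Trim a border pair to its measurement endpoints
#'
#' Clips each border polyline to the sub-curve between its proximal and
#' distal endpoints, inserting the endpoints as exact first/last vertices.
#' Each endpoint must lie on its border within 0.5 px.
#'
#' @param pair A `border_pair`.
#' @param start_upper,end_upper Proximal and distal endpoints of the upper
#'   border.
#' @param start_lower,end_lower Proximal and distal endpoints of the lower
#'   border.
#' @return A trimmed `border_pair`.
#' @export
trim_to_endpoints <- function(pair, start_upper, end_upper,
                              start_lower, end_lower) {
  stopifnot(inherits(pair, "border_pair"))
  trim_one <- function(poly, a, b, which_border) {
    pa <- project_onto_polyline(a, poly)
    pb <- project_onto_polyline(b, poly)
    if (pa$distance > 0.5 || pb$distance > 0.5)
      landmark_error(sprintf("endpoint not on the %s border (within 0.5 px)",
                             which_border))
    s0 <- min(pa$s, pb$s); s1 <- max(pa$s, pb$s)
    if (pa$s > pb$s) { tmp <- pa; pa <- pb; pb <- tmp; tmp <- a; a <- b; b <- tmp }
    cs <- cumulative_arc(poly)
    keep <- which(cs > s0 + 1e-9 & cs < s1 - 1e-9)
    out <- rbind(as.numeric(a), poly[keep, , drop = FALSE], as.numeric(b))
    # drop interior vertices coincident with the inserted endpoints
    d <- sqrt(rowSums((out[-1L, , drop = FALSE] - out[-nrow(out), , drop = FALSE])^2))
    if (any(d < 1e-9)) out <- out[c(TRUE, d >= 1e-9), , drop = FALSE]
    as_polyline(out)
  }
  border_pair(trim_one(pair$upper, start_upper, end_upper, "upper"),
              trim_one(pair$lower, start_lower, end_lower, "lower"),
              pair$structure)
}

#' Construct the full landmark set
#'
#' Runs the endpoint constructions in order: distal end line through the
#' marked junctions `p1`, `p2` with canal crossings `a`, `b`; equal-angle
#' proximal line through `p3` with upper cortical crossing `p4`; proximal
#' canal crossings `c`, `d`.
#'
#' @param outline,canal `border_pair`s for the cortical outline and the
#'   medullary canal.
#' @param p1,p2,p3 Operator-marked points (see [equal_angle_proximal_line()]
#'   and [distal_line_and_canal_ends()]).
#' @param ... Passed to [equal_angle_proximal_line()].
#' @return An object of class `landmark_set` with fields `p1`, `p2`, `p3`,
#'   `p4`, `a`, `b`, `c`, `d`, `proximal_line`, `distal_line`,
#'   `angle_residual`.
#' @export
construct_landmarks <- function(outline, canal, p1, p2, p3, ...) {
  dl <- distal_line_and_canal_ends(p1, p2, canal)
  pl <- equal_angle_proximal_line(p3, outline, ...)
  pc <- proximal_canal_ends(pl$line, canal)
  structure(list(p1 = as.numeric(p1), p2 = as.numeric(p2),
                 p3 = as.numeric(p3), p4 = as.numeric(pl$p4),
                 a = as.numeric(dl$a), b = as.numeric(dl$b),
                 c = as.numeric(pc$c), d = as.numeric(pc$d),
                 proximal_line = pl$line, distal_line = dl$line,
                 angle_residual = pl$residual),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set>\n")
  for (nm in c("p1", "p2", "p3", "p4", "a", "b", "c", "d"))
    cat(sprintf("  %-2s (%8.2f, %8.2f)\n", nm, x[[nm]][1L], x[[nm]][2L]))
  cat(sprintf("  proximal line angle %.3f deg (equal-angle residual %.4f deg)\n",
              x$proximal_line$angle, x$angle_residual))
  cat(sprintf("  distal   line angle %.3f deg\n", x$distal_line$angle))
  invisible(x)
}

# endpoints of one structure's borders, in trim order
landmark_endpoints <- function(landmarks, structure) {
  if (structure == "outline")
    list(start_upper = landmarks$p4, end_upper = landmarks$p1,
         start_lower = landmarks$p3, end_lower = landmarks$p2)
  else
    list(start_upper = landmarks$c, end_upper = landmarks$a,
         start_lower = landmarks$d, end_lower = landmarks$b)
}
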