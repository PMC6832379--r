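# Planar geometry primitives shared by all pipeline stages.
#
# Conventions: continuous pixel coordinates, origin at the top-left of the
# image, x rightward, y downward. A polyline is an n x 2 numeric matrix with
# columns x, y; all geometry is in pixels. Angles are in degrees, 0 = +x,
# counterclockwise positive in image axes.

#' Coerce to a polyline
#'
#' A polyline is an open, ordered planar curve stored as an `n x 2` numeric
#' matrix with columns `x` and `y` (continuous pixel coordinates, `n >= 2`,
#' consecutive points distinct).
#'
#' @param p A two-column matrix or data frame of coordinates, or a list with
#'   elements `x` and `y`.
#' @return An `n x 2` numeric matrix with columns `x`, `y`.
#' @export
as_polyline <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.list(p) && !is.matrix(p) && all(c("x", "y") %in% names(p)))
    p <- cbind(p$x, p$y)
  if (!is.matrix(p) || ncol(p) != 2L)
    stop("polyline must be an n x 2 matrix of (x, y) coordinates")
  storage.mode(p) <- "double"
  if (nrow(p) < 2L)
    stop("invalid polyline: fewer than 2 points")
  if (!all(is.finite(p)))
    stop("invalid polyline: non-finite coordinates")
  d <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (any(d == 0))
    stop("invalid polyline: consecutive points must be distinct")
  colnames(p) <- c("x", "y")
  p
}

#' Total arc length of a polyline
#'
#' @param poly A polyline (see [as_polyline()]).
#' @return Length in pixels (sum of consecutive Euclidean distances).
#' @examples
#' arc_length(rbind(c(0, 0), c(3, 4))) # 5
#' @export
arc_length <- function(poly) {
  poly <- as_polyline(poly)
  sum(sqrt(rowSums((poly[-1L, , drop = FALSE] -
                    poly[-nrow(poly), , drop = FALSE])^2)))
}

# cumulative arc-length positions of each vertex (first = 0)
cumulative_arc <- function(poly) {
  d <- sqrt(rowSums((poly[-1L, , drop = FALSE] -
                     poly[-nrow(poly), , drop = FALSE])^2))
  c(0, cumsum(d))
}

# point on the polyline at arc-length position s (clamped to [0, L])
point_at_arc <- function(poly, s) {
  cs <- cumulative_arc(poly)
  s <- pmin(pmax(s, 0), cs[length(cs)])
  x <- approx(cs, poly[, 1L], xout = s, ties = "ordered")$y
  y <- approx(cs, poly[, 2L], xout = s, ties = "ordered")$y
  cbind(x = x, y = y)
}

#' Resample a polyline at uniform arc-length spacing
#'
#' Returns `n` points at equal arc-length steps along the curve; the first and
#' last points of the input are preserved exactly.
#'
#' @param poly A polyline.
#' @param n Number of output points (`n >= 2`).
#' @return An `n x 2` polyline matrix.
#' @export
resample_uniform <- function(poly, n) {
  poly <- as_polyline(poly)
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("n must be a single integer >= 2")
  n <- as.integer(n)
  out <- poly
  # iterate to the equal-chord fixed point so the operation is idempotent
  for (it in 1:6) {
    cs <- cumulative_arc(out)
    L <- cs[length(cs)]
    new <- point_at_arc(out, seq(0, L, length.out = n))
    new[1L, ] <- poly[1L, ]
    new[n, ] <- poly[nrow(poly), ]
    moved <- if (nrow(out) == n) max(abs(new - out)) else Inf
    out <- new
    if (moved < 1e-8) break
  }
  out
}

#' Construct an infinite 2-D line
#'
#' @param anchor Point on the line, `c(x, y)`.
#' @param angle Direction angle in degrees (0 = +x, counterclockwise positive
#'   in image axes).
#' @return An object of class `line2d` with fields `anchor`, `angle`, `dir`
#'   (unit direction vector).
#' @export
line2d <- function(anchor, angle) {
  anchor <- as.numeric(anchor)
  stopifnot(length(anchor) == 2L, all(is.finite(anchor)), is.finite(angle))
  th <- angle * pi / 180
  structure(list(anchor = anchor, angle = as.numeric(angle),
                 dir = c(cos(th), sin(th))),
            class = "line2d")
}

#' Line through two distinct points
#'
#' @param p,q Points `c(x, y)`; must be distinct.
#' @return A `line2d` anchored at `p` pointing towards `q`.
#' @export
line_through <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (all(p == q)) stop("cannot construct a line through two identical points")
  line2d(p, atan2(q[2L] - p[2L], q[1L] - p[1L]) * 180 / pi)
}

#' @export
print.line2d <- function(x, ...) {
  cat(sprintf("<line2d> anchor (%.2f, %.2f), angle %.3f deg\n",
              x$anchor[1L], x$anchor[2L], x$angle))
  invisible(x)
}

# signed perpendicular distance of points (n x 2) from a line2d
line_point_offset <- function(line, pts) {
  pts <- matrix(pts, ncol = 2L)
  dx <- pts[, 1L] - line$anchor[1L]
  dy <- pts[, 2L] - line$anchor[2L]
  line$dir[1L] * dy - line$dir[2L] * dx
}

#' Intersections of an infinite line with a polyline
#'
#' All crossing points of the line with the polyline's segments, ordered by
#' arc-length position along the polyline. Tangential touches (including
#' shared vertices of adjacent segments) are reported once.
#'
#' @param line A [line2d()].
#' @param poly A polyline.
#' @return A data frame with columns `x`, `y`, `segment` (1-based index of the
#'   crossed segment) and `s` (arc-length position), zero rows when the line
#'   misses the polyline.
#' @export
intersect_line_polyline <- function(line, poly) {
  poly <- as_polyline(poly)
  n <- nrow(poly)
  p <- poly[-n, , drop = FALSE]
  q <- poly[-1L, , drop = FALSE]
  d <- line$dir
  a <- line$anchor
  ex <- q[, 1L] - p[, 1L]
  ey <- q[, 2L] - p[, 2L]
  denom <- ex * d[2L] - ey * d[1L]          # cross(edge, dir)
  apx <- a[1L] - p[, 1L]
  apy <- a[2L] - p[, 2L]
  # cross(p->a, dir): signed offset of segment start relative to the line
  u <- (apx * d[2L] - apy * d[1L]) / denom  # param along segment
  ok <- is.finite(u) & u >= 0 & u <= 1
  if (!any(ok)) {
    return(data.frame(x = numeric(0), y = numeric(0),
                      segment = integer(0), s = numeric(0)))
  }
  seg <- which(ok)
  u <- u[ok]
  xi <- p[seg, 1L] + u * ex[seg]
  yi <- p[seg, 2L] + u * ey[seg]
  cs <- cumulative_arc(poly)
  slen <- sqrt(ex[seg]^2 + ey[seg]^2)
  s <- cs[seg] + u * slen
  ord <- order(s)
  out <- data.frame(x = xi[ord], y = yi[ord], segment = seg[ord], s = s[ord])
  # collapse duplicates (shared vertices, tangential touches) by arc position
  if (nrow(out) > 1L) {
    keep <- c(TRUE, diff(out$s) > 1e-9)
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# fold an angle in degrees into (-90, 90]
fold_angle <- function(a) {
  a <- a %% 180
  ifelse(a > 90, a - 180, a)
}

# acute angle in [0, 90] between two directions given in degrees
acute_between <- function(a, b) {
  d <- abs((a - b) %% 180)
  pmin(d, 180 - d)
}

#' Local tangent direction of a polyline
#'
#' Direction angle of the total-least-squares line through all polyline
#' vertices within `window / 2` arc length of the query position. Total least
#' squares (principal axis of the point scatter) is used so the estimate is
#' equivariant under rotation of the curve. With fewer than two vertices in
#' the window, the containing segment's direction is returned.
#'
#' @param poly A polyline.
#' @param at Arc-length position in `[0, arc_length(poly)]`.
#' @param window Window width in pixels (`> 0`).
#' @return Angle in degrees, folded into `(-90, 90]`.
#' @export
local_tangent_angle <- function(poly, at, window) {
  poly <- as_polyline(poly)
  if (!is.finite(window) || window <= 0) stop("window must be positive")
  cs <- cumulative_arc(poly)
  L <- cs[length(cs)]
  if (!is.finite(at) || at < -1e-9 || at > L + 1e-9)
    stop("position outside [0, arc length]")
  at <- min(max(at, 0), L)
  sel <- cs >= at - window / 2 & cs <= at + window / 2
  if (sum(sel) >= 2L) {
    pts <- poly[sel, , drop = FALSE]
    ctr <- sweep(pts, 2L, colMeans(pts))
    cv <- crossprod(ctr) / nrow(ctr)
    ev <- eigen(cv, symmetric = TRUE)
    v <- ev$vectors[, 1L]
    return(fold_angle(atan2(v[2L], v[1L]) * 180 / pi))
  }
  # fallback: direction of the segment containing the position
  seg <- max(1L, min(nrow(poly) - 1L, findInterval(at, cs)))
  v <- poly[seg + 1L, ] - poly[seg, ]
  unname(fold_angle(atan2(v[2L], v[1L]) * 180 / pi))
}

#' Distance from points to a polyline
#'
#' Minimum Euclidean distance from each query point to the polyline
#' (piecewise-linear, exact point-to-segment distances).
#'
#' @param pts An `m x 2` matrix of query points (or a single `c(x, y)`).
#' @param poly A polyline.
#' @return Numeric vector of length `m`.
#' @export
point_polyline_distance <- function(pts, poly) {
  poly <- as_polyline(poly)
  pts <- matrix(pts, ncol = 2L)
  n <- nrow(poly)
  p <- poly[-n, , drop = FALSE]
  e <- poly[-1L, , drop = FALSE] - p
  elen2 <- rowSums(e^2)
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    wx <- pts[i, 1L] - p[, 1L]
    wy <- pts[i, 2L] - p[, 2L]
    t <- pmin(pmax((wx * e[, 1L] + wy * e[, 2L]) / elen2, 0), 1)
    out[i] <- sqrt(min((wx - t * e[, 1L])^2 + (wy - t * e[, 2L])^2))
  }
  out
}

# project a single point onto a polyline: nearest point, its arc position and
# the projection distance
project_onto_polyline <- function(pt, poly) {
  poly <- as_polyline(poly)
  pt <- as.numeric(pt)
  n <- nrow(poly)
  p <- poly[-n, , drop = FALSE]
  e <- poly[-1L, , drop = FALSE] - p
  elen2 <- rowSums(e^2)
  wx <- pt[1L] - p[, 1L]
  wy <- pt[2L] - p[, 2L]
  t <- pmin(pmax((wx * e[, 1L] + wy * e[, 2L]) / elen2, 0), 1)
  d2 <- (wx - t * e[, 1L])^2 + (wy - t * e[, 2L])^2
  i <- which.min(d2)
  cs <- cumulative_arc(poly)
  list(point = p[i, ] + t[i] * e[i, ],
       s = cs[i] + t[i] * sqrt(elen2[i]),
       distance = sqrt(d2[i]),
       segment = i)
}
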