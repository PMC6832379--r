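# Two-seed region-growing territory extraction of the central line.
#
# Both trimmed borders are rasterized onto a (optionally supersampled) grid
# and act as seed sets that claim territory at equal speed; a cell belongs to
# the border whose Euclidean distance is smaller, realized directly through
# exact Euclidean distance transforms (isotropic propagation, deterministic,
# order-independent). The meeting locus of the two territories is the central
# line. Exact ties belong to the boundary set, not to either territory.

#' Grid specification for territory growth
#'
#' A raster grid covering a border pair with a margin. Cell `(i, j)` (i along
#' x, j along y) has pixel-coordinate center
#' `(origin[1] + (i - 1) / supersample, origin[2] + (j - 1) / supersample)`.
#'
#' @param pair A `border_pair` (normally already trimmed to its endpoints).
#' @param supersample Integer `>= 1`: grid cells per image pixel. Higher
#'   values reduce raster quantization of the midline.
#' @param margin Margin around the borders, in grid cells.
#' @return An object of class `grid_spec` with fields `nx`, `ny`, `origin`,
#'   `supersample`.
#' @export
grid_spec <- function(pair, supersample = 2L, margin = 4L) {
  stopifnot(inherits(pair, "border_pair"))
  supersample <- as.integer(supersample)
  if (supersample < 1L) stop("supersample must be a positive integer")
  pts <- rbind(pair$upper, pair$lower)
  xr <- range(pts[, 1L]); yr <- range(pts[, 2L])
  nx <- ceiling(diff(xr) * supersample) + 2L * margin + 1L
  ny <- ceiling(diff(yr) * supersample) + 2L * margin + 1L
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 origin = c(xr[1L] - margin / supersample,
                            yr[1L] - margin / supersample),
                 supersample = supersample),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, supersample %d, origin (%.2f, %.2f)\n",
              x$nx, x$ny, x$supersample, x$origin[1L], x$origin[2L]))
  invisible(x)
}

# pixel coords -> continuous (1-based) grid coords
px_to_grid <- function(grid, pts) {
  pts <- matrix(pts, ncol = 2L)
  cbind((pts[, 1L] - grid$origin[1L]) * grid$supersample + 1,
        (pts[, 2L] - grid$origin[2L]) * grid$supersample + 1)
}

# continuous grid coords -> pixel coords
grid_to_px <- function(grid, g) {
  g <- matrix(g, ncol = 2L)
  cbind(x = grid$origin[1L] + (g[, 1L] - 1) / grid$supersample,
        y = grid$origin[2L] + (g[, 2L] - 1) / grid$supersample)
}

topology_error <- function(msg) {
  stop(errorCondition(msg, class = c("topology_error", "error")))
}

extraction_error <- function(msg) {
  stop(errorCondition(msg, class = c("midline_extraction_error", "error")))
}

# linear cell indices of an 8-connected one-cell-wide rasterization of a
# polyline (sampling step < 1 cell guarantees 8-connectivity after rounding)
rasterize_polyline_cells <- function(poly, grid) {
  g <- px_to_grid(grid, as_polyline(poly))
  n <- nrow(g)
  seg <- sqrt(rowSums((g[-1L, , drop = FALSE] - g[-n, , drop = FALSE])^2))
  steps <- pmax(1L, ceiling(seg / 0.4))
  t0 <- rep(seq_len(n - 1L), steps)
  tf <- unlist(lapply(steps, function(k) seq_len(k) / k), use.names = FALSE)
  gx <- c(g[1L, 1L], g[t0, 1L] + tf * (g[t0 + 1L, 1L] - g[t0, 1L]))
  gy <- c(g[1L, 2L], g[t0, 2L] + tf * (g[t0 + 1L, 2L] - g[t0, 2L]))
  i <- pmin(pmax(round(gx), 1), grid$nx)
  j <- pmin(pmax(round(gy), 1), grid$ny)
  unique(as.integer(i) + (as.integer(j) - 1L) * grid$nx)
}

# even-odd scanline fill of a closed polygon given in continuous grid coords;
# returns linear indices of cells whose centers are strictly interior
scanline_fill <- function(gpoly, grid) {
  n <- nrow(gpoly)
  x1 <- gpoly[, 1L]; y1 <- gpoly[, 2L]
  x2 <- gpoly[c(2:n, 1L), 1L]; y2 <- gpoly[c(2:n, 1L), 2L]
  keep <- y1 != y2
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  if (length(x1) == 0L) return(integer(0))
  jlo <- ceiling(pmin(y1, y2))
  jhi <- ceiling(pmax(y1, y2)) - 1  # half-open [ymin, ymax)
  jlo <- pmax(jlo, 1L); jhi <- pmin(jhi, grid$ny)
  cnt <- pmax(0, jhi - jlo + 1)
  if (sum(cnt) == 0L) return(integer(0))
  e <- rep.int(seq_along(x1), cnt)
  jj <- sequence(cnt) - 1L + rep.int(jlo, cnt)
  xx <- x1[e] + (jj - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
  rows <- split(xx, jj)
  out <- vector("list", length(rows))
  jvals <- as.integer(names(rows))
  for (k in seq_along(rows)) {
    xs <- sort(rows[[k]])
    m <- length(xs) %/% 2L * 2L
    if (m == 0L) next
    acc <- integer(0)
    for (p in seq(1L, m, by = 2L)) {
      i0 <- floor(xs[p]) + 1L          # strictly inside the left crossing
      i1 <- ceiling(xs[p + 1L]) - 1L   # strictly inside the right crossing
      i0 <- max(i0, 1L); i1 <- min(i1, grid$nx)
      if (i1 >= i0) acc <- c(acc, i0:i1)
    }
    if (length(acc)) out[[k]] <- acc + (jvals[k] - 1L) * grid$nx
  }
  as.integer(unlist(out, use.names = FALSE))
}

#' Rasterize a trimmed border pair into seed and domain masks
#'
#' Draws each border as an 8-connected one-cell-wide curve and fills the
#' interior of the closed region bounded by the two borders plus the two
#' straight end segments joining their endpoints. The domain excludes the
#' border cells and the end-segment cells.
#'
#' @param pair A trimmed `border_pair` (borders span endpoint-to-endpoint).
#' @param grid A [grid_spec()]; defaults to one fitted around `pair`.
#' @return A list with logical matrices `seed1` (upper border), `seed2`
#'   (lower border), `domain`, and the `grid`.
#' @export
rasterize_borders <- function(pair, grid = NULL) {
  stopifnot(inherits(pair, "border_pair"))
  if (is.null(grid)) grid <- grid_spec(pair)
  dims <- c(grid$nx, grid$ny)
  c1 <- rasterize_polyline_cells(pair$upper, grid)
  c2 <- rasterize_polyline_cells(pair$lower, grid)
  if (any(c1 %in% c2))
    topology_error("the two borders intersect or touch on the grid")
  seed1 <- matrix(FALSE, dims[1L], dims[2L]); seed1[c1] <- TRUE
  seed2 <- matrix(FALSE, dims[1L], dims[2L]); seed2[c2] <- TRUE
  up <- pair$upper; lo <- pair$lower
  gpoly <- px_to_grid(grid, rbind(up, lo[rev(seq_len(nrow(lo))), , drop = FALSE]))
  fill <- scanline_fill(gpoly, grid)
  endc <- c(rasterize_polyline_cells(rbind(up[nrow(up), ], lo[nrow(lo), ]), grid),
            rasterize_polyline_cells(rbind(lo[1L, ], up[1L, ]), grid))
  domain <- matrix(FALSE, dims[1L], dims[2L])
  domain[fill] <- TRUE
  domain[c1] <- FALSE; domain[c2] <- FALSE; domain[endc] <- FALSE
  if (!any(domain))
    topology_error("zero-width domain between the borders")
  list(seed1 = seed1, seed2 = seed2, domain = domain, grid = grid)
}

#' Grow the two border territories at equal speed
#'
#' Computes the exact Euclidean distance transform to each seed set and
#' labels every domain cell by the nearer seed (equal-speed isotropic
#' growth). Exact ties are assigned to the boundary set (label 0).
#'
#' @param seed1,seed2 Logical seed masks of identical dimensions.
#' @param domain Logical domain mask.
#' @param grid The [grid_spec()] the masks live on.
#' @return An object of class `territory_field` with integer `label` matrix
#'   (0 = none/tie, 1, 2), distance matrices `dist1`, `dist2` (grid units),
#'   `domain`, and `grid`.
#' @export
grow_territories <- function(seed1, seed2, domain, grid = NULL) {
  if (is.list(seed1) && !is.matrix(seed1) && missing(seed2)) {
    masks <- seed1
    seed2 <- masks$seed2; domain <- masks$domain
    grid <- masks$grid; seed1 <- masks$seed1
  }
  stopifnot(identical(dim(seed1), dim(seed2)),
            identical(dim(seed1), dim(domain)))
  if (!any(seed1) || !any(seed2)) stop("empty seed set")
  if (any(seed1 & seed2)) topology_error("seed sets overlap")
  dist1 <- unclass(EBImage::distmap(!seed1))
  dist2 <- unclass(EBImage::distmap(!seed2))
  dim(dist1) <- dim(seed1); dim(dist2) <- dim(seed2)
  label <- matrix(0L, nrow(seed1), ncol(seed1))
  di <- which(domain)
  d1 <- dist1[di]; d2 <- dist2[di]
  label[di[d1 < d2]] <- 1L
  label[di[d2 < d1]] <- 2L
  structure(list(label = label, dist1 = dist1, dist2 = dist2,
                 domain = domain, grid = grid),
            class = "territory_field")
}

#' @export
print.territory_field <- function(x, ...) {
  cat(sprintf("<territory_field> %d x %d cells: %d / %d / %d (seed1/seed2/tie) of %d domain cells\n",
              nrow(x$label), ncol(x$label),
              sum(x$label == 1L), sum(x$label == 2L),
              sum(x$domain & x$label == 0L), sum(x$domain)))
  invisible(x)
}

# bilinear interpolation of matrix M at continuous grid coords g (n x 2)
bilinear_at <- function(M, g) {
  nx <- nrow(M); ny <- ncol(M)
  i0 <- pmin(pmax(floor(g[, 1L]), 1L), nx - 1L)
  j0 <- pmin(pmax(floor(g[, 2L]), 1L), ny - 1L)
  fx <- pmin(pmax(g[, 1L] - i0, 0), 1)
  fy <- pmin(pmax(g[, 2L] - j0, 0), 1)
  l00 <- i0 + (j0 - 1L) * nx
  M[l00] * (1 - fx) * (1 - fy) + M[l00 + 1L] * fx * (1 - fy) +
    M[l00 + nx] * (1 - fx) * fy + M[l00 + nx + 1L] * fx * fy
}

# centered moving average with shrinking windows at the ends
smooth_polyline <- function(pts, k = 5L) {
  n <- nrow(pts)
  if (n < 3L || k < 3L) return(pts)
  h <- k %/% 2L
  out <- pts
  cx <- c(0, cumsum(pts[, 1L])); cy <- c(0, cumsum(pts[, 2L]))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  w <- hi - lo + 1
  out[, 1L] <- (cx[hi + 1L] - cx[lo]) / w
  out[, 2L] <- (cy[hi + 1L] - cy[lo]) / w
  out
}

#' Extract the central line from a territory field
#'
#' The meeting locus consists of the midpoints of every 4-neighbour cell pair
#' carrying opposite labels, plus the centers of exact-tie cells. The locus
#' is thinned to one point per grid cell, ordered by greedy nearest-neighbour
#' chaining started from the point closest to the proximal end line (jump
#' tolerance 3 grid cells), smoothed by a 5-point moving average, and
#' returned in image-pixel coordinates.
#'
#' @param field A `territory_field`.
#' @param proximal_line,distal_line The end lines (class `line2d`) bounding
#'   the domain.
#' @param smooth Moving-average window (points).
#' @param source Structure tag carried into the result.
#' @return An object of class `midline`: `points` (pixel-coordinate polyline
#'   ordered proximal to distal), `source`, and `equidistance_residual` (max
#'   over points of |distance to border 1 - distance to border 2|, px).
#' @export
extract_midline <- function(field, proximal_line, distal_line,
                            smooth = 5L, source = "outline") {
  stopifnot(inherits(field, "territory_field"))
  L <- field$label
  nx <- nrow(L); ny <- ncol(L)
  if (!any(L == 1L) || !any(L == 2L))
    extraction_error("both territories must be present in the domain")
  gpts <- vector("list", 3L)
  A <- L[-nx, , drop = FALSE]; B <- L[-1L, , drop = FALSE]
  m <- (A == 1L & B == 2L) | (A == 2L & B == 1L)
  if (any(m)) {
    ij <- which(m, arr.ind = TRUE)
    gpts[[1L]] <- cbind(ij[, 1L] + 0.5, ij[, 2L])
  }
  A <- L[, -ny, drop = FALSE]; B <- L[, -1L, drop = FALSE]
  m <- (A == 1L & B == 2L) | (A == 2L & B == 1L)
  if (any(m)) {
    ij <- which(m, arr.ind = TRUE)
    gpts[[2L]] <- cbind(ij[, 1L], ij[, 2L] + 0.5)
  }
  ties <- field$domain & L == 0L
  if (any(ties)) {
    ij <- which(ties, arr.ind = TRUE)
    gpts[[3L]] <- cbind(ij[, 1L], ij[, 2L])
  }
  g <- do.call(rbind, gpts[!vapply(gpts, is.null, logical(1))])
  if (is.null(g) || nrow(g) < 3L)
    extraction_error("territories do not meet inside the domain")
  # thin to one (averaged) point per grid cell
  key <- round(g[, 1L]) + (round(g[, 2L]) - 1) * nx
  sums <- rowsum(cbind(g, 1), group = key)
  g <- sums[, 1:2, drop = FALSE] / sums[, 3L]
  px <- grid_to_px(field$grid, g)
  start <- which.min(abs(line_point_offset(proximal_line, px)))
  tol <- 3 / field$grid$supersample  # 3 grid cells, in px
  res <- chain_nearest_cpp(px, start - 1L, tol)
  if (res$leftover > 0L)
    extraction_error(sprintf(
      "meeting locus disconnected: %d point(s) unreachable within the chaining tolerance",
      res$leftover))
  ord <- res$order + 1L
  pts <- smooth_polyline(px[ord, , drop = FALSE], smooth)
  gsm <- px_to_grid(field$grid, pts)
  d1 <- bilinear_at(field$dist1, gsm) / field$grid$supersample
  d2 <- bilinear_at(field$dist2, gsm) / field$grid$supersample
  structure(list(points = as_polyline(pts), source = source,
                 equidistance_residual = max(abs(d1 - d2)),
                 supersample = field$grid$supersample),
            class = "midline")
}

#' @export
print.midline <- function(x, ...) {
  cat(sprintf("<midline> %s: %d points, %.1f px long, equidistance residual %.3f px\n",
              x$source, nrow(x$points), arc_length(x$points),
              x$equidistance_residual))
  invisible(x)
}

#' Compute the central line of a border pair
#'
#' End-to-end territory-method midline: trims the borders to the landmark
#' endpoints, rasterizes, grows the two territories at equal speed, and
#' extracts the ordered central line.
#'
#' @param pair A `border_pair` (untrimmed).
#' @param landmarks A `landmark_set` (see [construct_landmarks()]).
#' @param supersample Grid cells per image pixel (see [grid_spec()]).
#' @param grid Optional explicit [grid_spec()]; built from the trimmed pair
#'   when `NULL`.
#' @return A `midline` (see [extract_midline()]).
#' @export
compute_midline <- function(pair, landmarks, supersample = 2L, grid = NULL) {
  stopifnot(inherits(pair, "border_pair"), inherits(landmarks, "landmark_set"))
  ep <- landmark_endpoints(landmarks, pair$structure)
  trimmed <- trim_to_endpoints(pair, ep$start_upper, ep$end_upper,
                               ep$start_lower, ep$end_lower)
  if (is.null(grid)) grid <- grid_spec(trimmed, supersample)
  masks <- rasterize_borders(trimmed, grid)
  field <- grow_territories(masks)
  extract_midline(field, landmarks$proximal_line, landmarks$distal_line,
                  source = pair$structure)
}
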