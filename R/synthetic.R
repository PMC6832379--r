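# Synthetic phantoms with known ground-truth geometry.
#
# Border pairs are emitted as exact offsets (+/- width/2 along the normal)
# of analytic centerlines -- a single circular arc (annular phantom) or
# three tangent-continuous circular arcs of equal arc length (femur-like
# "hockey stick" phantom) -- so every pipeline stage can be checked against
# closed-form truth. Tracing noise is isotropic Gaussian jitter on border
# vertices; no image-intensity simulation (the method consumes polylines).
# Borders carry a short overhang beyond the landmark endpoints, as an
# operator would trace past the anatomical marks, so that endpoint
# construction and trimming behave as on real annotations.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

jitter_polyline <- function(poly, sd) {
  if (sd <= 0) return(poly)
  poly + matrix(rnorm(length(poly), 0, sd), nrow(poly), 2L)
}

#' Concentric-arc (annular) phantom
#'
#' Two concentric circular arcs at radii `radius - width / 2` (lower border)
#' and `radius + width / 2` (upper border): the exact central line is the arc
#' of `radius`. Landmark vertices are inserted exactly at the nominal arc
#' ends; the borders extend a little beyond them (overhang).
#'
#' @param radius Central radius in px (`> width`).
#' @param width Border separation in px (`> 0`).
#' @param extent Angular extent of the measured arc, degrees.
#' @param n Vertices per border.
#' @param noise_sd Gaussian vertex jitter, px.
#' @param seed Optional RNG seed (restores the RNG state afterwards).
#' @param structure Structure tag for the emitted `border_pair`.
#' @param overhang Extra angular overhang beyond each landmark end, as a
#'   fraction of `extent`.
#' @return A list with `pair` (a `border_pair`), `landmarks` (a
#'   `landmark_set`; canal points coincide with the border endpoints), and
#'   `truth` (generator parameters, the arc `center`, and the border radii).
#' @export
generate_annular_pair <- function(radius, width, extent = 25, n = 400L,
                                  noise_sd = 0, seed = NULL,
                                  structure = "outline", overhang = 0.06) {
  if (!is.numeric(radius) || !is.numeric(width) || width <= 0)
    stop("radius and width must be positive")
  if (radius <= width)
    stop("radius must exceed width")
  with_seed(seed, {
    center <- c(0, 0)
    half <- extent / 2
    th_prox <- -90 - half
    th_dist <- -90 + half
    ov <- overhang * extent
    th <- sort(unique(c(seq(th_prox - ov, th_dist + ov, length.out = n),
                        th_prox, th_dist))) * pi / 180
    arc <- function(r) cbind(center[1L] + r * cos(th),
                             center[2L] + r * sin(th))
    upper <- arc(radius + width / 2)
    lower <- arc(radius - width / 2)
    i_prox <- which.min(abs(th - th_prox * pi / 180))
    i_dist <- which.min(abs(th - th_dist * pi / 180))
    upper <- jitter_polyline(upper, noise_sd)
    lower <- jitter_polyline(lower, noise_sd)
    p1 <- upper[i_dist, ]; p2 <- lower[i_dist, ]
    p3 <- lower[i_prox, ]; p4 <- upper[i_prox, ]
    landmarks <- base::structure(list(
      p1 = p1, p2 = p2, p3 = p3, p4 = p4,
      a = p1, b = p2, c = p4, d = p3,
      proximal_line = line_through(p3, p4),
      distal_line = line_through(p2, p1),
      angle_residual = 0),
      class = "landmark_set")
    list(pair = border_pair(upper, lower, structure),
         landmarks = landmarks,
         truth = list(radius = radius, width = width, extent = extent,
                      noise_sd = noise_sd, seed = seed, center = center,
                      upper_radius = radius + width / 2,
                      lower_radius = radius - width / 2))
  })
}

# exact point and heading after advancing ds along a circular arc
advance_arc <- function(p, phi, kappa, ds) {
  if (kappa == 0) {
    list(p = p + ds * c(cos(phi), sin(phi)), phi = phi)
  } else {
    ctr <- p + (1 / kappa) * c(-sin(phi), cos(phi))
    a <- kappa * ds
    v <- p - ctr
    rot <- c(cos(a) * v[1L] - sin(a) * v[2L],
             sin(a) * v[1L] + cos(a) * v[2L])
    list(p = ctr + rot, phi = phi + a)
  }
}

# evaluate a piecewise-arc chain at arc positions s (exact); breaks/kappas
# define curvature on each interval; state0 = list(p, phi) at s = 0
eval_arc_chain <- function(s, breaks, kappas, state0) {
  states <- vector("list", length(breaks))
  ref <- which(breaks == 0)
  states[[ref]] <- state0
  if (ref < length(breaks))
    for (i in (ref + 1):length(breaks))
      states[[i]] <- advance_arc(states[[i - 1L]]$p, states[[i - 1L]]$phi,
                                 kappas[i - 1L], breaks[i] - breaks[i - 1L])
  if (ref > 1L)
    for (i in (ref - 1):1)
      states[[i]] <- advance_arc(states[[i + 1L]]$p, states[[i + 1L]]$phi,
                                 kappas[i], breaks[i] - breaks[i + 1L])
  iv <- pmin(pmax(findInterval(s, breaks, rightmost.closed = TRUE), 1L),
             length(breaks) - 1L)
  pts <- matrix(0, length(s), 2L)
  phis <- numeric(length(s))
  for (k in seq_along(s)) {
    st <- advance_arc(states[[iv[k]]]$p, states[[iv[k]]]$phi,
                      kappas[iv[k]], s[k] - breaks[iv[k]])
    pts[k, ] <- st$p
    phis[k] <- st$phi
  }
  list(points = pts, phi = phis)
}

#' Three-arc femur-like phantom
#'
#' A centerline of three tangent-continuous circular arcs of equal arc
#' length (proximal, middle, distal radii), emulating the hockey-stick
#' lateral contour of an anteriorly bowed femur. The cortical outline and
#' medullary canal borders are exact normal offsets of this centerline, so
#' every segment radius is known in closed form. Landmark vertices sit
#' exactly at the segment-chain ends; borders overhang slightly beyond them.
#'
#' @param radii_mm Segment radii `c(proximal, middle, distal)` in mm, all
#'   positive.
#' @param segment_length_mm Arc length of each of the three segments, mm.
#' @param widths_mm Named pair `c(outline = , canal = )`: border separations
#'   in mm.
#' @param pixel_spacing mm per pixel.
#' @param noise_sd Gaussian vertex jitter in px applied to all borders.
#' @param vertex_spacing_px Approximate border vertex spacing, px.
#' @param overhang_mm Border overhang past each landmark end, mm.
#' @param seed Optional RNG seed.
#' @return An object of class `femur_phantom`: `outline` and `canal`
#'   (`border_pair`s), `landmarks` (exact for `noise_sd = 0`, otherwise
#'   reconstructed from the jittered marks via [construct_landmarks()]),
#'   `marks` (`p1`, `p2`, `p3` as an operator would place them), `truth`
#'   (generator parameters and exact segment radii), and the exact
#'   `centerline` polyline of the measured span.
#' @export
generate_three_arc_femur <- function(radii_mm = c(752, 1379, 599),
                                     segment_length_mm = 110,
                                     widths_mm = c(outline = 27, canal = 13),
                                     pixel_spacing = 0.15,
                                     noise_sd = 0,
                                     vertex_spacing_px = 2,
                                     overhang_mm = 8,
                                     seed = NULL) {
  if (length(radii_mm) != 3L || any(!is.finite(radii_mm)) || any(radii_mm <= 0))
    stop("radii_mm must be three positive radii (proximal, middle, distal)")
  if (segment_length_mm <= 0 || pixel_spacing <= 0)
    stop("segment_length_mm and pixel_spacing must be positive")
  if (any(widths_mm <= 0)) stop("widths must be positive")
  if (max(widths_mm) / 2 >= min(radii_mm))
    stop("infeasible tangency: half-width reaches a segment's center of curvature")
  with_seed(seed, {
    R <- radii_mm / pixel_spacing
    L <- segment_length_mm / pixel_spacing
    ov <- overhang_mm / pixel_spacing
    w_out <- unname(widths_mm[["outline"]]) / pixel_spacing
    w_can <- unname(widths_mm[["canal"]]) / pixel_spacing
    kappas <- 1 / R
    breaks <- c(-ov, 0, L, 2 * L, 3 * L, 3 * L + ov)
    kap <- c(kappas[1L], kappas[1L], kappas[2L], kappas[3L], kappas[3L])
    phi0 <- -sum(L * kappas) / 2  # roughly horizontal chord
    s <- sort(unique(c(seq(-ov, 3 * L + ov, by = vertex_spacing_px),
                       0, L, 2 * L, 3 * L, 3 * L + ov)))
    ch <- eval_arc_chain(s, breaks, kap, list(p = c(0, 0), phi = phi0))
    nrm <- cbind(-sin(ch$phi), cos(ch$phi))  # left normal (+y-ish: lower side)
    mk_border <- function(offset) ch$points + offset * nrm
    up_out <- mk_border(-w_out / 2); lo_out <- mk_border(+w_out / 2)
    up_can <- mk_border(-w_can / 2); lo_can <- mk_border(+w_can / 2)
    # translate into a positive image-like quadrant
    all_pts <- rbind(up_out, lo_out)
    shift <- 20 - c(min(all_pts[, 1L]), min(all_pts[, 2L]))
    tr <- function(m) sweep(m, 2L, -shift)
    up_out <- tr(up_out); lo_out <- tr(lo_out)
    up_can <- tr(up_can); lo_can <- tr(lo_can)
    cl <- tr(ch$points)
    i0 <- which(s == 0); i3 <- which(s == 3 * L)
    up_out <- jitter_polyline(up_out, noise_sd)
    lo_out <- jitter_polyline(lo_out, noise_sd)
    up_can <- jitter_polyline(up_can, noise_sd)
    lo_can <- jitter_polyline(lo_can, noise_sd)
    outline <- border_pair(up_out, lo_out, "outline")
    canal <- border_pair(up_can, lo_can, "canal")
    marks <- list(p1 = up_out[i3, ], p2 = lo_out[i3, ], p3 = lo_out[i0, ])
    landmarks <- if (noise_sd == 0) {
      normal_angle <- function(i) atan2(nrm[i, 2L], nrm[i, 1L]) * 180 / pi
      structure(list(p1 = up_out[i3, ], p2 = lo_out[i3, ],
                     p3 = lo_out[i0, ], p4 = up_out[i0, ],
                     a = up_can[i3, ], b = lo_can[i3, ],
                     c = up_can[i0, ], d = lo_can[i0, ],
                     proximal_line = line2d(cl[i0, ], normal_angle(i0)),
                     distal_line = line2d(cl[i3, ], normal_angle(i3)),
                     angle_residual = 0),
                class = "landmark_set")
    } else {
      construct_landmarks(outline, canal, marks$p1, marks$p2, marks$p3)
    }
    structure(list(
      outline = outline, canal = canal,
      landmarks = landmarks, marks = marks,
      centerline = cl[i0:i3, , drop = FALSE],
      mark_index = c(proximal = i0, distal = i3),
      truth = list(radii_mm = setNames(radii_mm, c("proximal", "middle", "distal")),
                   segment_length_mm = segment_length_mm,
                   widths_mm = widths_mm, pixel_spacing = pixel_spacing,
                   noise_sd = noise_sd, seed = seed,
                   overhang_mm = overhang_mm,
                   vertex_spacing_px = vertex_spacing_px)),
      class = "femur_phantom")
  })
}

#' @export
print.femur_phantom <- function(x, ...) {
  t <- x$truth
  cat(sprintf("<femur_phantom> radii %s mm, segments %.0f mm, spacing %.3g mm/px, noise %.2g px\n",
              paste(t$radii_mm, collapse = "/"), t$segment_length_mm,
              t$pixel_spacing, t$noise_sd))
  invisible(x)
}

# regenerate the phantom's borders with fresh tracing jitter
retrace_phantom <- function(phantom, tracing_sd) {
  t <- phantom$truth
  jit <- function(pair) border_pair(jitter_polyline(pair$upper, tracing_sd),
                                    jitter_polyline(pair$lower, tracing_sd),
                                    pair$structure)
  outline <- jit(phantom$outline)
  canal <- jit(phantom$canal)
  i0 <- phantom$mark_index[["proximal"]]
  i3 <- phantom$mark_index[["distal"]]
  list(outline = outline, canal = canal,
       marks = list(p1 = outline$upper[i3, ], p2 = outline$lower[i3, ],
                    p3 = outline$lower[i0, ]))
}

#' Simulated repeat measurements of one phantom
#'
#' Emulates the repeat-measurement protocol: each repeat independently
#' re-jitters the border tracings (and with them the marked points), rebuilds
#' the landmark set, extracts the midline and measures the four radii.
#'
#' @param phantom A noiseless `femur_phantom` (see
#'   [generate_three_arc_femur()]).
#' @param tracing_sd Per-repeat Gaussian tracing jitter, px.
#' @param repeats Number of repeats (`>= 2`).
#' @param seed Optional RNG seed.
#' @param structures Structures to measure, subset of
#'   `c("outline", "canal")`.
#' @param supersample Territory-grid supersampling factor.
#' @param subject Subject id recorded in the rows.
#' @return A measurement table (one row per structure x repeat) suitable for
#'   [reliability_report()].
#' @export
generate_repeat_set <- function(phantom, tracing_sd = 1, repeats = 3L,
                                seed = NULL,
                                structures = c("outline", "canal"),
                                supersample = 2L, subject = "phantom") {
  stopifnot(inherits(phantom, "femur_phantom"))
  if (repeats < 2L) stop("repeats must be >= 2")
  structures <- match.arg(structures, several.ok = TRUE)
  with_seed(seed, {
    rows <- vector("list", repeats * length(structures))
    k <- 0L
    for (r in seq_len(repeats)) {
      tr <- retrace_phantom(phantom, tracing_sd)
      lm <- construct_landmarks(tr$outline, tr$canal,
                                tr$marks$p1, tr$marks$p2, tr$marks$p3)
      for (st in structures) {
        ml <- compute_midline(tr[[st]], lm, supersample = supersample)
        mr <- measure_radii(ml, phantom$truth$pixel_spacing,
                            subject = subject, observer = "sim",
                            repeat_index = r)
        k <- k + 1L
        rows[[k]] <- as.data.frame(mr)
      }
    }
    do.call(rbind, rows)
  })
}
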