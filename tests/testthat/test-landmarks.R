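# Endpoint construction: distal line, equal-angle proximal line, trimming.

test_that("distal end line intersects the canal at the marked junction line", {
  canal <- border_pair(cbind(seq(0, 200, 10), 10), cbind(seq(0, 200, 10), 30),
                       "canal")
  got <- distal_line_and_canal_ends(c(100, 0), c(100, 40), canal)
  expect_equal(unname(got$a), c(100, 10))
  expect_equal(unname(got$b), c(100, 30))
  expect_error(distal_line_and_canal_ends(c(1, 2), c(1, 2), canal), "distinct")
  horiz <- line2d(c(0, -5), 0)
  expect_error(proximal_canal_ends(horiz, canal), "does not intersect")
})

test_that("canal endpoints on an annular phantom match closed-form circle-line crossings", {
  # canal borders: concentric arcs radii 880 / 920 about the origin
  canal <- border_pair(circle_points(c(0, 0), 880, -110, -70, 300L),
                       circle_points(c(0, 0), 920, -110, -70, 300L), "canal")
  p1 <- c(300, -600); p2 <- c(250, -900)
  got <- distal_line_and_canal_ends(p1, p2, canal)
  # oracle: intersect the infinite line with each circle analytically and
  # keep the crossing inside the arc's angular range nearest the distal end
  circle_line <- function(r) {
    d <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
    t2 <- 1; t1 <- 2 * sum(d * p1); t0 <- sum(p1^2) - r^2
    ts <- (-t1 + c(-1, 1) * sqrt(t1^2 - 4 * t2 * t0)) / 2
    pts <- rbind(p1 + ts[1L] * d, p1 + ts[2L] * d)
    ang <- atan2(pts[, 2L], pts[, 1L]) * 180 / pi
    pts[ang >= -110 & ang <= -70, , drop = FALSE]
  }
  expect_lt(sqrt(sum((got$a - circle_line(880)[1L, ])^2)), 0.5)
  expect_lt(sqrt(sum((got$b - circle_line(920)[1L, ])^2)), 0.5)
})

test_that("parallel borders give the perpendicular proximal line", {
  outline <- parallel_pair(0, 200, 0, 40, n = 41L)
  got <- equal_angle_proximal_line(c(60, 40), outline)
  expect_equal(abs(got$line$angle) %% 180, 90, tolerance = 1e-6)
  expect_equal(unname(got$p4), c(60, 0), tolerance = 1e-6)
  expect_lte(got$residual, 0.05)
})

test_that("anti-symmetric straight borders give the vertical symmetry line", {
  xs <- seq(-100, 80, length.out = 80)
  outline <- border_pair(cbind(xs, -20 + 0.2 * xs), cbind(xs, 20 - 0.2 * xs),
                         "outline")
  got <- equal_angle_proximal_line(c(0, 20), outline)
  expect_equal(abs(got$line$angle) %% 180, 90, tolerance = 0.06)
  expect_equal(unname(got$p4), c(0, -20), tolerance = 0.1)
  expect_lte(got$residual, 0.05)
})

test_that("equal-angle direction matches an exhaustive analytic sweep", {
  # smooth gently-curved polynomial borders with exact derivative tangents
  set.seed(41)
  for (k in 1:5) {
    cl <- runif(3, c(-30, -0.15, -4e-4), c(-10, 0.15, 4e-4))
    cu <- runif(3, c(10, -0.15, -4e-4), c(30, 0.15, 4e-4))
    ylow <- function(x) cl[1L] + cl[2L] * x + cl[3L] * x^2
    yup <- function(x) cu[1L] + cu[2L] * x + cu[3L] * x^2
    xs <- seq(-150, 150, length.out = 601L)
    outline <- border_pair(cbind(xs, yup(xs)), cbind(xs, ylow(xs)), "outline")
    x3 <- runif(1, -40, 40)
    p3 <- c(x3, ylow(x3))
    got <- equal_angle_proximal_line(p3, outline)
    expect_lte(got$residual, 0.05)
    # oracle: brute-force 0.01-degree sweep using analytic tangents
    tan_low <- atan(cl[2L] + 2 * cl[3L] * x3) * 180 / pi
    f <- function(phi) {
      th <- phi * pi / 180
      if (abs(cos(th)) < 1e-6) {
        xc <- x3
      } else {
        m <- tan(th)
        # line y = p3.y + m (x - x3) meets upper parabola: quadratic in x
        a <- cu[3L]; b <- cu[2L] - m; cc <- cu[1L] - p3[2L] + m * x3
        disc <- b^2 - 4 * a * cc
        if (disc < 0) return(NA_real_)
        roots <- if (abs(a) < 1e-12) -cc / b
                 else (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
        roots <- roots[roots >= -150 & roots <= 150]
        if (!length(roots)) return(NA_real_)
        xc <- roots[which.min(abs(roots - x3))]
      }
      tan_up <- atan(cu[2L] + 2 * cu[3L] * xc) * 180 / pi
      acute <- function(a, b) { d <- abs((a - b) %% 180); min(d, 180 - d) }
      abs(acute(phi, tan_low) - acute(phi, tan_up))
    }
    phis <- seq(tan_low + 30, tan_low + 150, by = 0.01)
    vals <- vapply(phis, f, numeric(1))
    # among sweep minima, apply the same disambiguation as the package:
    # the root nearest the perpendicular to the lower border
    cand <- phis[!is.na(vals) & vals <= min(vals, na.rm = TRUE) + 0.02]
    best <- cand[which.min(abs(cand - (tan_low + 90)))]
    diff_deg <- abs((got$line$angle - best) %% 180)
    expect_lt(min(diff_deg, 180 - diff_deg), 0.05 + 0.02)
  }
})

test_that("trimming clips borders exactly between the endpoints", {
  pair <- parallel_pair(0, 100, 0, 10, n = 11L)
  tr <- trim_to_endpoints(pair, c(10, 0), c(90, 0), c(10, 10), c(90, 10))
  expect_equal(range(tr$upper[, "x"]), c(10, 90))
  expect_equal(arc_length(tr$upper), 80)
  # trimming at existing vertices preserves them
  tr2 <- trim_to_endpoints(pair, c(20, 0), c(80, 0), c(20, 10), c(80, 10))
  expect_true(all(tr2$upper[, "x"] == seq(20, 80, 10)))
  expect_error(
    trim_to_endpoints(pair, c(10, 5), c(90, 0), c(10, 10), c(90, 10)),
    "upper")
})

test_that("trimmed arc length matches the analytic sub-arc length", {
  arc <- circle_points(c(0, 0), 500, -80, -10, 800L)
  arc_lo <- arc; arc_lo[, 2L] <- arc_lo[, 2L] + 60
  pair <- border_pair(arc, arc_lo, "outline")
  a <- c(500 * cos(-70 * pi / 180), 500 * sin(-70 * pi / 180))
  b <- c(500 * cos(-20 * pi / 180), 500 * sin(-20 * pi / 180))
  tr <- trim_to_endpoints(pair, a, b, a + c(0, 60), b + c(0, 60))
  expect_equal(arc_length(tr$upper), 500 * 50 * pi / 180, tolerance = 1e-3)
})

test_that("derived landmarks lie on their borders and solve the equal-angle condition", {
  ph <- generate_three_arc_femur(seed = 5)
  lm <- construct_landmarks(ph$outline, ph$canal,
                            ph$marks$p1, ph$marks$p2, ph$marks$p3)
  expect_lte(lm$angle_residual, 0.05)
  expect_lt(point_polyline_distance(lm$p4, ph$outline$upper), 0.5)
  expect_lt(point_polyline_distance(lm$a, ph$canal$upper), 0.5)
  expect_lt(point_polyline_distance(lm$b, ph$canal$lower), 0.5)
  expect_lt(point_polyline_distance(lm$c, ph$canal$upper), 0.5)
  expect_lt(point_polyline_distance(lm$d, ph$canal$lower), 0.5)
  # and the construction agrees with the phantom's analytic landmark set
  for (nm in c("p4", "a", "b", "c", "d"))
    expect_lt(sqrt(sum((lm[[nm]] - ph$landmarks[[nm]])^2)), 0.5)
})

test_that("landmark construction is equivariant under rigid motion", {
  ph <- generate_three_arc_femur(radii_mm = c(600, 1100, 500),
                                 segment_length_mm = 60, seed = 6)
  lm0 <- construct_landmarks(ph$outline, ph$canal,
                             ph$marks$p1, ph$marks$p2, ph$marks$p3)
  for (k in 1:3) {
    ang <- c(17, -33, 120)[k]
    shift <- rbind(c(40, -25), c(-300, 80), c(5, 5))[k, ]
    mv <- function(p) rigid_transform(matrix(p, ncol = 2L), ang, shift)
    mvb <- function(bp) border_pair(mv(bp$upper), mv(bp$lower), bp$structure)
    lm1 <- construct_landmarks(mvb(ph$outline), mvb(ph$canal),
                               mv(ph$marks$p1), mv(ph$marks$p2),
                               mv(ph$marks$p3))
    for (nm in c("p1", "p2", "p3", "p4", "a", "b", "c", "d"))
      expect_lt(max(abs(mv(lm0[[nm]]) - matrix(lm1[[nm]], ncol = 2L))), 1e-6)
  }
})
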