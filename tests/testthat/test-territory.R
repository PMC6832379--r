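# Rasterization, equal-speed territory growth, midline extraction.

test_that("rasterized domain of two parallel borders has the exact interior cell count", {
  pair <- parallel_pair(0, 100, 0, 10, n = 11L)
  masks <- rasterize_borders(pair, grid_spec(pair, supersample = 1L))
  expect_equal(sum(masks$domain), 9L * 99L)
  expect_false(any(masks$domain & (masks$seed1 | masks$seed2)))
})

test_that("intersecting or touching borders raise a topology error", {
  shared <- border_pair(rbind(c(0, 0), c(100, 10)), rbind(c(0, 0), c(100, -10)),
                        "outline")
  expect_error(rasterize_borders(shared), class = "topology_error")
  crossing <- border_pair(rbind(c(0, 0), c(100, 20)), rbind(c(0, 18), c(100, 2)),
                          "outline")
  expect_error(rasterize_borders(crossing), class = "topology_error")
})

test_that("annulus-sector domain area matches the closed form", {
  ph <- generate_annular_pair(900, 60, extent = 25, n = 600L)
  ep <- ph$landmarks
  tr <- trim_to_endpoints(ph$pair, ep$p4, ep$p1, ep$p3, ep$p2)
  masks <- rasterize_borders(tr, grid_spec(tr, supersample = 4L))
  theta <- 25 * pi / 180
  analytic <- (theta / 2) * (930^2 - 870^2)
  expect_equal(sum(masks$domain) / 16, analytic, tolerance = 0.02)
})

test_that("territory distances and labels follow the geometry", {
  pair <- parallel_pair(0, 100, 0, 10, n = 11L)
  grid <- grid_spec(pair, supersample = 1L)
  masks <- rasterize_borders(pair, grid)
  field <- grow_territories(masks)
  g <- px_to_grid <- function(p) round((p - grid$origin) * 1 + 1)
  at <- g(c(50, 3))
  expect_equal(field$dist1[at[1L], at[2L]], 3)
  expect_equal(field$dist2[at[1L], at[2L]], 7)
  expect_equal(field$label[at[1L], at[2L]], 1L)
  # mirror symmetry about the half-width line: labels swap
  flipped <- field$label[, rev(seq_len(ncol(field$label)))]
  dom <- field$domain & field$domain[, rev(seq_len(ncol(field$domain)))]
  expect_true(all((flipped == 3L - field$label)[dom & field$label != 0L]))
  expect_error(grow_territories(masks$seed1 & FALSE, masks$seed2, masks$domain),
               "empty seed")
})

test_that("labels equal brute-force nearest-seed assignment on random domains", {
  set.seed(51)
  for (dims in list(c(60L, 80L), c(200L, 150L), c(120L, 200L))) {
    nx <- dims[1L]; ny <- dims[2L]
    seed1 <- seed2 <- matrix(FALSE, nx, ny)
    seed1[sample(nx * ny, 40L)] <- TRUE
    free <- which(!seed1)
    seed2[sample(free, 40L)] <- TRUE
    domain <- matrix(TRUE, nx, ny) & !seed1 & !seed2
    field <- grow_territories(seed1, seed2, domain)
    idx1 <- which(seed1, arr.ind = TRUE)
    idx2 <- which(seed2, arr.ind = TRUE)
    cells <- which(domain, arr.ind = TRUE)
    lab_bf <- integer(nrow(cells))
    for (k in seq_len(nrow(cells))) {
      d1 <- min((idx1[, 1L] - cells[k, 1L])^2 + (idx1[, 2L] - cells[k, 2L])^2)
      d2 <- min((idx2[, 1L] - cells[k, 1L])^2 + (idx2[, 2L] - cells[k, 2L])^2)
      lab_bf[k] <- if (d1 < d2) 1L else if (d2 < d1) 2L else 0L
    }
    expect_identical(field$label[domain], lab_bf)
  }
})

test_that("midline of parallel straight borders lies at half width", {
  pair <- parallel_pair(0, 150, 0, 11, n = 16L)
  lms <- landmarks_from_endpoints(c(0, 0), c(150, 0), c(0, 11), c(150, 11))
  ml <- compute_midline(pair, lms, supersample = 2L)
  expect_lt(max(abs(ml$points[, "y"] - 5.5)), 0.5)
  expect_lte(ml$equidistance_residual, 1)
  # ordered proximal (x = 0 end) to distal
  expect_lt(ml$points[1L, "x"], ml$points[nrow(ml$points), "x"])
  expect_lt(abs(ml$points[1L, "x"]), 2)
  expect_lt(abs(ml$points[nrow(ml$points), "x"] - 150), 2)
})

test_that("midline of concentric arcs recovers the central radius within 1%", {
  ph <- generate_annular_pair(900, 60, extent = 25, n = 600L)
  ml <- compute_midline(ph$pair, ph$landmarks, supersample = 2L)
  f <- fit_circle(resample_uniform(ml$points, 300L))
  expect_equal(f$radius, 900, tolerance = 0.01)
  expect_lte(ml$equidistance_residual, 1)
})

test_that("supersampling refines the midline consistently", {
  ph <- generate_annular_pair(400, 40, extent = 35, n = 500L)
  ml2 <- compute_midline(ph$pair, ph$landmarks, supersample = 2L)
  ml4 <- compute_midline(ph$pair, ph$landmarks, supersample = 4L)
  expect_lte(ml2$equidistance_residual, 1)
  expect_lte(ml4$equidistance_residual, 0.5)
  pts <- resample_uniform(ml4$points, 200L)
  expect_lt(mean(point_polyline_distance(pts, ml2$points)), 0.5)
})

test_that("a straight shaft yields a straight-segment error from the radius fit", {
  pair <- parallel_pair(0, 300, 0, 12, n = 31L)
  lms <- landmarks_from_endpoints(c(0, 0), c(300, 0), c(0, 12), c(300, 12))
  ml <- compute_midline(pair, lms, supersample = 2L)
  expect_error(measure_radii(ml, 0.15), class = "straight_segment_error")
})
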