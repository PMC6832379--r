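# Shared fixtures: analytic curves, rigid motions, brute-force oracles and a
# byte-level DICOM writer. Everything is generated in code at test time.

`%||%` <- function(a, b) if (is.null(a)) b else a

# points on a circular arc (degrees), ordered by angle
circle_points <- function(center, radius, from, to, n) {
  th <- seq(from, to, length.out = n) * pi / 180
  cbind(center[1L] + radius * cos(th), center[2L] + radius * sin(th))
}

rigid_transform <- function(pts, angle_deg, shift) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  sweep(pts %*% t(R), 2L, -as.numeric(shift))
}

# independent brute-force line/segment intersection solver: solves the 2x2
# linear system per segment (different code path from the package's
# cross-product formulation)
brute_line_polyline <- function(line, poly) {
  hits <- NULL
  for (i in seq_len(nrow(poly) - 1L)) {
    p <- poly[i, ]; q <- poly[i + 1L, ]
    A <- cbind(line$dir, p - q)
    if (abs(det(A)) < 1e-12) next
    tu <- solve(A, p - line$anchor)
    if (tu[2L] >= -1e-12 && tu[2L] <= 1 + 1e-12) {
      pt <- p + tu[2L] * (q - p)
      hits <- rbind(hits, pt)
    }
  }
  if (is.null(hits)) return(hits)
  hits[!duplicated(round(hits, 6L)), , drop = FALSE]
}

# closed-form circumcircle of three points
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1L]; ay <- p1[2L]; bx <- p2[1L]; by <- p2[2L]
  cx <- p3[1L]; cy <- p3[2L]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

# straight horizontal border pair: upper at y0, lower at y0 + gap
parallel_pair <- function(x0 = 0, x1 = 100, y0 = 0, gap = 10, n = 2L,
                          structure = "outline") {
  border_pair(cbind(seq(x0, x1, length.out = n), y0),
              cbind(seq(x0, x1, length.out = n), y0 + gap),
              structure)
}

# landmark set for a parallel/annular pair built directly from endpoints
landmarks_from_endpoints <- function(p4, p1, p3, p2) {
  structure(list(p1 = p1, p2 = p2, p3 = p3, p4 = p4,
                 a = p1, b = p2, c = p4, d = p3,
                 proximal_line = line_through(p3, p4),
                 distal_line = line_through(p2, p1),
                 angle_residual = 0),
            class = "landmark_set")
}

# --- minimal DICOM writer (uncompressed little endian) ---------------------

dcm_u16 <- function(con, v) writeBin(as.integer(v), con, size = 2L,
                                     endian = "little")
dcm_u32 <- function(con, v) writeBin(as.integer(v), con, size = 4L,
                                     endian = "little")

dcm_element <- function(con, group, elem, vr, value_raw, explicit = TRUE) {
  dcm_u16(con, group); dcm_u16(con, elem)
  if (explicit) {
    writeChar(vr, con, eos = NULL)
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      dcm_u16(con, 0L)
      dcm_u32(con, length(value_raw))
    } else {
      dcm_u16(con, length(value_raw))
    }
  } else {
    dcm_u32(con, length(value_raw))
  }
  if (length(value_raw)) writeBin(value_raw, con)
}

dcm_str <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2L) r <- c(r, as.raw(0L))
  r
}
dcm_us <- function(v) writeBin(as.integer(v), raw(), size = 2L,
                               endian = "little")

# writes a tiny grayscale DICOM; pixel values are row-major 0,1,2,...
write_fixture_dicom <- function(path, rows = 4L, cols = 5L,
                                spacing = c(0.15, 0.15),
                                explicit = TRUE, with_spacing = TRUE) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeChar("DICM", con, eos = NULL)
  ts <- if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
  # file meta group (always explicit VR)
  dcm_element(con, 0x0002, 0x0010, "UI", dcm_str(ts), explicit = TRUE)
  # dataset
  dcm_element(con, 0x0028, 0x0010, "US", dcm_us(rows), explicit)
  dcm_element(con, 0x0028, 0x0011, "US", dcm_us(cols), explicit)
  if (with_spacing)
    dcm_element(con, 0x0028, 0x0030, "DS",
                dcm_str(sprintf("%g\\%g", spacing[1L], spacing[2L])), explicit)
  dcm_element(con, 0x0028, 0x0100, "US", dcm_us(16L), explicit)
  pix <- writeBin(as.integer(seq_len(rows * cols) - 1L), raw(), size = 2L,
                  endian = "little")
  dcm_element(con, 0x7FE0, 0x0010, "OW", pix, explicit)
  invisible(path)
}
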