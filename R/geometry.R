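# Planar geometry kernels for buffer statistics. All inputs are projected
# coordinates in metres; discs are closed (boundary included).

# Length of the part of each segment (x1,y1)-(x2,y2) inside the disc of
# radius r centred at (cx, cy). Vectorized over segments; exact (quadratic
# segment-circle intersection).
.segClipLength <- function(x1, y1, x2, y2, cx, cy, r) {
  px <- x1 - cx; py <- y1 - cy
  dx <- x2 - x1; dy <- y2 - y1
  a <- dx * dx + dy * dy
  b <- 2 * (px * dx + py * dy)
  cc <- px * px + py * py - r * r
  disc <- b * b - 4 * a * cc
  len <- numeric(length(a))
  ok <- a > 0 & disc > 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- pmax(0, (-b[ok] - sq) / (2 * a[ok]))
    t2 <- pmin(1, (-b[ok] + sq) / (2 * a[ok]))
    len[ok] <- sqrt(a[ok]) * pmax(0, t2 - t1)
  }
  len
}

# Total clipped length of a polyline (2-column vertex matrix) in the disc.
.polylineClipLength <- function(m, cx, cy, r) {
  n <- nrow(m)
  if (n < 2L) return(0)
  sum(.segClipLength(m[-n, 1], m[-n, 2], m[-1, 1], m[-1, 2], cx, cy, r))
}

# Distance from point (cx, cy) to each segment; vectorized.
.pointSegDistance <- function(x1, y1, x2, y2, cx, cy) {
  dx <- x2 - x1; dy <- y2 - y1
  a <- dx * dx + dy * dy
  t <- ifelse(a > 0, ((cx - x1) * dx + (cy - y1) * dy) / a, 0)
  t <- pmin(1, pmax(0, t))
  qx <- x1 + t * dx; qy <- y1 + t * dy
  sqrt((qx - cx)^2 + (qy - cy)^2)
}

# Distance from a point to the nearest vertex-pair segment of a polyline.
.pointPolylineDistance <- function(m, cx, cy) {
  n <- nrow(m)
  if (n < 2L) return(sqrt(min((m[, 1] - cx)^2 + (m[, 2] - cy)^2)))
  min(.pointSegDistance(m[-n, 1], m[-n, 2], m[-1, 1], m[-1, 2], cx, cy))
}

# Signed area of a ring (shoelace); vertices need not repeat the first point.
.ringArea <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# Signed area of the intersection of the disc (origin-centred after
# translation, radius r) with the triangle (centre, p1, p2), accumulated
# per directed polygon edge (Green's theorem decomposition into chord
# triangles and circular sectors). Exact up to floating point.
.edgeDiscArea <- function(p1x, p1y, p2x, p2y, r) {
  d1 <- sqrt(p1x * p1x + p1y * p1y)
  d2 <- sqrt(p2x * p2x + p2y * p2y)
  tol <- r * 1e-12
  in1 <- d1 <= r + tol
  in2 <- d2 <= r + tol
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  sector <- function(ax, ay, bx, by)
    r * r / 2 * atan2(cross(ax, ay, bx, by), ax * bx + ay * by)
  if (in1 && in2) return(cross(p1x, p1y, p2x, p2y) / 2)
  dx <- p2x - p1x; dy <- p2y - p1y
  a <- dx * dx + dy * dy
  if (a == 0) return(0)
  b <- 2 * (p1x * dx + p1y * dy)
  cc <- d1 * d1 - r * r
  disc <- b * b - 4 * a * cc
  if (disc <= 0) return(sector(p1x, p1y, p2x, p2y))
  sq <- sqrt(disc)
  t1 <- (-b - sq) / (2 * a)
  t2 <- (-b + sq) / (2 * a)
  if (in1 && !in2) {
    qx <- p1x + t2 * dx; qy <- p1y + t2 * dy
    return(cross(p1x, p1y, qx, qy) / 2 + sector(qx, qy, p2x, p2y))
  }
  if (!in1 && in2) {
    qx <- p1x + t1 * dx; qy <- p1y + t1 * dy
    return(sector(p1x, p1y, qx, qy) + cross(qx, qy, p2x, p2y) / 2)
  }
  # both endpoints outside: the segment may still traverse the disc
  if (t1 > 0 && t2 < 1 && t1 < t2) {
    q1x <- p1x + t1 * dx; q1y <- p1y + t1 * dy
    q2x <- p1x + t2 * dx; q2y <- p1y + t2 * dy
    sector(p1x, p1y, q1x, q1y) + cross(q1x, q1y, q2x, q2y) / 2 +
      sector(q2x, q2y, p2x, p2y)
  } else {
    sector(p1x, p1y, p2x, p2y)
  }
}

# Area of the intersection of a simple polygon with the closed disc of
# radius r centred at (cx, cy). Orientation-independent (absolute value).
.polygonDiscArea <- function(m, cx, cy, r) {
  x <- m[, 1] - cx
  y <- m[, 2] - cy
  n <- length(x)
  # drop a repeated closing vertex if present
  if (n > 1L && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  if (n < 3L) return(0)
  # fast paths on the bounding box
  bxmin <- min(x); bxmax <- max(x); bymin <- min(y); bymax <- max(y)
  ddx <- max(0, bxmin, -bxmax)
  ddy <- max(0, bymin, -bymax)
  if (ddx * ddx + ddy * ddy > r * r) return(0)  # box outside disc
  fx <- max(abs(bxmin), abs(bxmax)); fy <- max(abs(bymin), abs(bymax))
  if (fx * fx + fy * fy <= r * r) return(abs(.ringArea(cbind(x, y))))  # box inside
  j <- c(2:n, 1L)
  total <- 0
  for (i in seq_len(n))
    total <- total + .edgeDiscArea(x[i], y[i], x[j[i]], y[j[i]], r)
  abs(total)
}

# Clip an infinite line through (px, py) with direction angle theta to the
# axis-aligned box [0, E] x [0, E]; returns a 2 x 2 segment matrix or NULL.
.clipLineToBox <- function(px, py, theta, E) {
  dx <- cos(theta); dy <- sin(theta)
  ts <- c()
  if (abs(dx) > 1e-12) ts <- c(ts, (0 - px) / dx, (E - px) / dx)
  if (abs(dy) > 1e-12) ts <- c(ts, (0 - py) / dy, (E - py) / dy)
  if (!length(ts)) return(NULL)
  pts <- cbind(px + ts * dx, py + ts * dy)
  on <- pts[, 1] >= -1e-9 & pts[, 1] <= E + 1e-9 &
        pts[, 2] >= -1e-9 & pts[, 2] <= E + 1e-9
  pts <- pts[on, , drop = FALSE]
  ts <- ts[on]
  if (nrow(pts) < 2L) return(NULL)
  o <- order(ts)
  p1 <- pts[o[1], ]; p2 <- pts[o[length(o)], ]
  if (sum((p2 - p1)^2) < 1e-6) return(NULL)
  rbind(pmin(pmax(p1, 0), E), pmin(pmax(p2, 0), E))
}
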