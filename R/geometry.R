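# Rasterization and small-geometry helpers shared by the synthetic renderer
# and the tracking stages. All pixel coordinates are 1-based centres in the
# y-up image coordinate system CS_I; a point in mm maps to px as mm / mm_per_px.

#' Signal an error with a gait2d condition class
#' @noRd
gait2d_stop <- function(class, msg) {
  stop(structure(class = c(class, "gait2d_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Even-odd point-in-polygon test (vectorized over points)
#'
#' @param px,py numeric vectors of point coordinates.
#' @param poly n x 2 matrix of polygon vertices (closed implicitly).
#' @return logical vector, TRUE for points inside the polygon.
#' @export
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# distance from points to a segment a-b, vectorized
dist_point_segment <- function(px, py, a, b) {
  abx <- b[1] - a[1]; aby <- b[2] - a[2]
  len2 <- abx^2 + aby^2
  if (len2 == 0) return(sqrt((px - a[1])^2 + (py - a[2])^2))
  t <- ((px - a[1]) * abx + (py - a[2]) * aby) / len2
  t <- pmin(1, pmax(0, t))
  sqrt((px - a[1] - t * abx)^2 + (py - a[2] - t * aby)^2)
}

# Integer bounding box of a set of continuous px coordinates, clipped to
# the image; returns NULL when fully outside.
clip_bbox <- function(xr, yr, width, height, pad = 0) {
  x0 <- max(1L, floor(xr[1] - pad)); x1 <- min(width, ceiling(xr[2] + pad))
  y0 <- max(1L, floor(yr[1] - pad)); y1 <- min(height, ceiling(yr[2] + pad))
  if (x0 > x1 || y0 > y1) return(NULL)
  list(x0 = x0, x1 = x1, y0 = y0, y1 = y1)
}

# Rasterize a polygon (vertices in px) into pixel-centre coordinates.
# Returns a 2-column integer matrix of (x, y) pixels inside.
rasterize_polygon <- function(poly, width, height) {
  bb <- clip_bbox(range(poly[, 1]), range(poly[, 2]), width, height)
  if (is.null(bb)) return(cbind(x = integer(0), y = integer(0)))
  xs <- bb$x0:bb$x1; ys <- bb$y0:bb$y1
  px <- rep(xs, times = length(ys)); py <- rep(ys, each = length(xs))
  keep <- points_in_polygon(px, py, poly)
  cbind(x = px[keep], y = py[keep])
}

# Rasterize a capsule (segment a-b dilated by radius r, px units).
rasterize_capsule <- function(a, b, r, width, height) {
  bb <- clip_bbox(range(c(a[1], b[1])) + c(-r, r),
                  range(c(a[2], b[2])) + c(-r, r), width, height)
  if (is.null(bb)) return(cbind(x = integer(0), y = integer(0)))
  xs <- bb$x0:bb$x1; ys <- bb$y0:bb$y1
  px <- rep(xs, times = length(ys)); py <- rep(ys, each = length(xs))
  keep <- dist_point_segment(px, py, a, b) <= r
  cbind(x = px[keep], y = py[keep])
}

# Area centroid of a simple polygon (shoelace); vertices n x 2.
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Rotate points (n x 2) by theta_deg about a centre.
rotate_points <- function(pts, theta_deg, centre = c(0, 0)) {
  a <- theta_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  sweep(sweep(pts, 2, centre) %*% t(R), 2, centre, `+`)
}

# Angle (deg, CCW from +x) of a 2D vector.
vec_angle_deg <- function(v) atan2(v[2], v[1]) * 180 / pi

# Length of a closed pixel-chain contour (diagonal steps count sqrt(2)).
contour_length <- function(contour) {
  d <- diff(rbind(contour, contour[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}
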