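# Low-level vector / polyline / mesh geometry shared by all modules.
# Conventions: right-handed axes, z up, ground plane z = 0, lengths in cm,
# angles in degrees at the API surface (radians only inside closed formulas).

.EPS <- 1e-12

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < .EPS) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle between two 3D vectors
#'
#' Returns the unsigned angle between two nonzero vectors, in degrees,
#' in the closed interval [0, 180].
#'
#' @param u,v numeric length-3 vectors (cm).
#' @return angle in degrees.
#' @export
angle_between <- function(u, v) {
  nu <- vnorm(u); nv <- vnorm(v)
  if (nu < .EPS || nv < .EPS) stop("angle undefined for a zero vector", call. = FALSE)
  ct <- sum(u * v) / (nu * nv)
  rad2deg(acos(pmin(1, pmax(-1, ct))))
}

# Rotation matrix about +z by alpha degrees, counter-clockwise seen from +z.
rotation_z_matrix <- function(alpha_deg) {
  a <- deg2rad(alpha_deg)
  matrix(c(cos(a), -sin(a), 0,
           sin(a),  cos(a), 0,
           0,       0,      1), 3, 3, byrow = TRUE)
}

# Minimal rotation carrying unit vector a onto unit vector b (Rodrigues).
# The antiparallel case uses any axis perpendicular to a.
rotation_between <- function(a, b) {
  a <- unitize(a); b <- unitize(b)
  v <- cross3(a, b)
  s <- vnorm(v)
  c_ <- sum(a * b)
  if (s < 1e-14) {
    if (c_ > 0) return(diag(3))
    # 180 degrees: pick a stable perpendicular axis
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unitize(cross3(a, ref))
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  v <- v / s
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  th <- atan2(s, c_)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Total length of a polyline stored as an n x 3 matrix.
polyline_length <- function(p) {
  p <- as_points(p)
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# Coerce a points argument to a numeric n x 3 matrix with finite entries.
as_points <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3, byrow = TRUE)
  p <- as.matrix(p)
  if (ncol(p) != 3) stop("points must have 3 columns (x, y, z)", call. = FALSE)
  storage.mode(p) <- "double"
  if (!all(is.finite(p))) stop("non-finite coordinate encountered", call. = FALSE)
  dimnames(p) <- NULL
  p
}

triangle_area3 <- function(p1, p2, p3) 0.5 * vnorm(cross3(p2 - p1, p3 - p1))

# Perpendicular distance from point p to the infinite line through a with
# direction d.
point_line_distance <- function(p, a, d) {
  d <- unitize(d)
  w <- p - a
  vnorm(w - sum(w * d) * d)
}

# Signed shoelace area of an ordered planar polygon (n x 2).
shoelace_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  0.5 * abs(sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2]))
}

#' Area of the 2D convex hull of a point set
#'
#' @param xy numeric matrix with 2 columns. Fewer than 3 distinct points, or a
#'   collinear set, yields area 0.
#' @return hull area (same squared units as the input).
#' @export
convex_hull_area <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) return(0)
  idx <- grDevices::chull(xy[, 1], xy[, 2])
  if (length(idx) < 3) return(0)
  shoelace_area(xy[idx, , drop = FALSE])
}

# Arc-length position along a polyline of the point on it closest to p.
# Used to check that digitized leaf rows advance monotonically along the vein.
arc_position <- function(p, polyline) {
  poly <- as_points(polyline)
  best_d <- Inf; best_s <- 0; s0 <- 0
  for (i in seq_len(nrow(poly) - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    ab <- b - a
    L <- vnorm(ab)
    t <- if (L < .EPS) 0 else pmin(1, pmax(0, sum((p - a) * ab) / (L * L)))
    q <- a + t * ab
    d <- vnorm(p - q)
    if (d < best_d) {
      best_d <- d
      best_s <- s0 + t * L
    }
    s0 <- s0 + L
  }
  best_s
}
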