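## Internal geometry helpers shared across analyses.
## Coordinates are Angstrom throughout; boxes are orthorhombic edge lengths.

## Minimum-image displacement of b relative to a. `a`, `b` are n x 3
## matrices (or vectors recycled); `box` is NULL or length-3 numeric.
min_image_disp <- function(a, b, box = NULL) {
  d <- b - a
  if (!is.null(box)) {
    for (k in 1:3) {
      d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    }
  }
  d
}

min_image_dist <- function(a, b, box = NULL) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3)
  d <- min_image_disp(a, b, box)
  sqrt(rowSums(d * d))
}

## All pairwise minimum-image distances between rows of A (n x 3) and
## rows of B (m x 3); returns an n x m matrix.
cross_dist <- function(A, B, box = NULL) {
  n <- nrow(A); m <- nrow(B)
  out <- matrix(0, n, m)
  for (k in 1:3) {
    d <- outer(A[, k], B[, k], "-")
    if (!is.null(box)) d <- d - box[k] * round(d / box[k])
    out <- out + d * d
  }
  sqrt(out)
}

## Unique pair distances within A (upper triangle, as a vector).
self_dist <- function(A, box = NULL) {
  if (is.null(box)) return(as.numeric(stats::dist(A)))
  D <- cross_dist(A, A, box)
  D[upper.tri(D)]
}

vcross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

vnorm <- function(u) sqrt(rowSums(u * u))

## Dihedral angle (degrees, in (-180, 180]) for quadruples of points given
## as four n x 3 matrices. Sign follows the IUPAC convention.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  atan2(y, x) * 180 / pi
}

## Angle A-B-C in degrees for n x 3 matrices.
point_angle <- function(a, b, c, box = NULL) {
  u <- min_image_disp(b, a, box)
  v <- min_image_disp(b, c, box)
  cosang <- rowSums(u * v) / (vnorm(u) * vnorm(v))
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * 180 / pi
}
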