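#' Radial distribution function of a particle set
#'
#' Standard pair RDF with minimum-image distances and shell-volume /
#' ideal-gas normalization: g(r) in bin b equals the observed pair count
#' divided by the count expected for an ideal gas at the same number
#' density. `positions` may be a single `n x 3` matrix (one configuration)
#' or a list of such matrices (configurations are averaged).
#'
#' @param positions `n x 3` coordinate matrix (Angstrom) or list thereof.
#' @param box orthorhombic box edges (length 3, Angstrom); required.
#' @param bin_width histogram bin width (Angstrom, default 0.05).
#' @param r_max maximum distance; must not exceed half the shortest box
#'   edge (defaults to exactly that).
#' @return An object of class `rdf_profile`: list with `r` (bin centers),
#'   `g`, `edges`, `rho` (number density, atoms per cubic Angstrom), `n`
#'   (particles), `volume`.
#' @export
compute_rdf <- function(positions, box, bin_width = 0.05, r_max = NULL) {
  if (!is.list(positions)) positions <- list(positions)
  box <- as.numeric(box)
  stopifnot(length(box) == 3, all(box > 0), bin_width > 0)
  if (is.null(r_max)) r_max <- min(box) / 2
  if (r_max > min(box) / 2 + 1e-9)
    stop("r_max (", r_max, ") exceeds half the shortest box edge (",
         min(box) / 2, ")")
  n <- nrow(positions[[1]])
  if (n < 2) stop("need at least 2 particles for an RDF")
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  counts <- numeric(length(edges) - 1)
  block <- max(1L, floor(2e7 / n))   # bounded memory for the pair block
  for (cfg in positions) {
    stopifnot(nrow(cfg) == n)
    for (b0 in seq(1, n, by = block)) {
      rows <- b0:min(b0 + block - 1L, n)
      D <- cross_dist(cfg[rows, , drop = FALSE], cfg, box)
      D[cbind(seq_along(rows), rows)] <- Inf   # drop self pairs
      d <- D[D < r_max]
      counts <- counts + tabulate(findInterval(d, edges,
                                               rightmost.closed = TRUE),
                                  nbins = length(edges) - 1)
    }
  }
  ## ordered pairs were counted; revert to unique pairs and config-average
  counts <- counts / 2 / length(positions)
  V <- prod(box)
  rho <- n / V
  shell <- 4 / 3 * pi * diff(edges^3)
  ## pairs expected for ideal gas: n * rho * Vshell / 2 (unique pairs)
  g <- counts / (n * rho * shell / 2)
  structure(list(r = (edges[-1] + edges[-length(edges)]) / 2, g = g,
                 edges = edges, rho = rho, n = n, volume = V),
            class = "rdf_profile")
}

#' Construct an RDF profile from explicit values
#'
#' Useful for analytic inputs (e.g. g identically 1) and for rescaled
#' profiles from external sources.
#'
#' @param r bin centers (strictly increasing).
#' @param g g(r) values (non-negative).
#' @param rho number density used for the zeta-rescaling.
#' @return An `rdf_profile`.
#' @export
rdf_profile <- function(r, g, rho) {
  stopifnot(length(r) == length(g), all(diff(r) > 0), all(g >= -1e-12),
            rho > 0)
  structure(list(r = r, g = g, edges = NULL, rho = rho, n = NA_integer_,
                 volume = NA_real_),
            class = "rdf_profile")
}

#' @export
print.rdf_profile <- function(x, ...) {
  cat("RDF profile: ", length(x$r), " bins, r in [",
      format(min(x$r)), ", ", format(max(x$r)), "] Angstrom, rho = ",
      format(x$rho), " / Angstrom^3\n", sep = "")
  invisible(x)
}

#' @export
plot.rdf_profile <- function(x, ...) {
  graphics::plot(x$r, x$g, type = "l", xlab = "r [Angstrom]", ylab = "g(r)",
                 ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Translational order parameter T
#'
#' Measures deviation of pair structure from the ideal gas:
#' \deqn{T = \frac{1}{\zeta_c} \int_0^{\zeta_c} |g(\zeta) - 1| \, d\zeta}
#' where \eqn{\zeta = r \rho^{1/3}} is the density-rescaled distance. T = 0
#' for an ideal gas (g identically 1) and grows with long-range order; the
#' cutoff `zeta_c = 2.8` sits where the oxygen-oxygen RDF of water has
#' decayed to its asymptote. Integration is by the trapezoidal rule on the
#' profile's native bins after rescaling, with linear interpolation of the
#' final partial bin at `zeta_c`.
#'
#' @param rdf an `rdf_profile` whose rescaled range covers \[0, zeta_c\].
#' @param zeta_c dimensionless integration cutoff (default 2.8).
#' @return T (non-negative scalar).
#' @export
translational_order <- function(rdf, zeta_c = 2.8) {
  stopifnot(inherits(rdf, "rdf_profile"), zeta_c > 0)
  zeta <- rdf$r * rdf$rho^(1 / 3)
  if (max(zeta) < zeta_c)
    stop("RDF covers zeta up to ", format(max(zeta)),
         " only; zeta_c = ", zeta_c, " requires a larger r_max")
  y <- abs(rdf$g - 1)
  ## extend to zeta = 0 with the first bin's value (g there is typically 0
  ## inside the excluded volume; |g-1| = 1 is continued from the data)
  zz <- c(0, zeta)
  yy <- c(y[1], y)
  keep <- zz <= zeta_c
  zk <- zz[keep]; yk <- yy[keep]
  if (max(zk) < zeta_c) {    # interpolate the partial bin at zeta_c
    i <- sum(keep)
    ynext <- yy[i + 1]
    frac <- (zeta_c - zz[i]) / (zz[i + 1] - zz[i])
    zk <- c(zk, zeta_c)
    yk <- c(yk, yy[i] + frac * (ynext - yy[i]))
  }
  sum(diff(zk) * (yk[-1] + yk[-length(yk)]) / 2) / zeta_c
}

#' Tetrahedral order parameter q for explicit neighbor geometries
#'
#' Evaluates, for each center, the orientational order
#' \deqn{q = 1 - \frac{3}{8} \sum_{j<k} \left(\cos\psi_{jk} +
#'   \tfrac{1}{3}\right)^2}
#' over the six angles \eqn{\psi_{jk}} subtended at the center by its four
#' neighbors. q = 1 for a perfect tetrahedral arrangement, averages to 0
#' for directions uniform on the sphere, and reaches -3 when all four
#' neighbors coincide in direction.
#'
#' @param vecs a `4 x 3` matrix of neighbor displacement vectors from one
#'   center, or a `n_centers x 4 x 3` array for many centers.
#' @return Numeric vector of q values (one per center).
#' @export
tetrahedral_q <- function(vecs) {
  if (is.matrix(vecs)) vecs <- array(vecs, dim = c(1, dim(vecs)))
  stopifnot(length(dim(vecs)) == 3, dim(vecs)[2] == 4, dim(vecs)[3] == 3)
  u <- vecs / array(sqrt(apply(vecs^2, c(1, 2), sum)),
                    dim = dim(vecs))
  s <- 0
  for (j in 1:3) for (k in (j + 1):4) {
    uj <- matrix(u[, j, ], ncol = 3)
    uk <- matrix(u[, k, ], ncol = 3)
    s <- s + (rowSums(uj * uk) + 1 / 3)^2
  }
  1 - 3 / 8 * s
}

#' Orientational (tetrahedral) order parameter Q of an oxygen set
#'
#' For each selected central oxygen, finds its four nearest neighbor
#' oxygens (minimum image, searched among all oxygens) and evaluates the
#' per-molecule tetrahedral order q; Q is the mean over the selection.
#'
#' @param oxygens `n x 3` oxygen coordinates (Angstrom).
#' @param box optional orthorhombic box edges.
#' @param centers indices of central molecules (default all).
#' @return An object of class `order_parameters`: list with `Q` (mean), `q`
#'   (per-center values) and `centers`.
#' @export
orientational_order <- function(oxygens, box = NULL,
                                centers = seq_len(nrow(oxygens))) {
  oxygens <- as.matrix(oxygens)
  n <- nrow(oxygens)
  if (n < 5) stop("need at least 5 oxygens (each center needs 4 neighbors)")
  q <- numeric(length(centers))
  block <- 512L    # centers per distance block, keeps memory bounded
  for (b0 in seq(1, length(centers), by = block)) {
    ids <- centers[b0:min(b0 + block - 1L, length(centers))]
    D <- cross_dist(oxygens[ids, , drop = FALSE], oxygens, box)
    D[cbind(seq_along(ids), ids)] <- Inf
    vec <- array(0, dim = c(length(ids), 4, 3))
    for (i in seq_along(ids)) {
      nb <- order(D[i, ])[1:4]
      if (!all(is.finite(D[i, nb])))
        stop("center ", ids[i], " has fewer than 4 neighbors")
      vec[i, , ] <- min_image_disp(
        oxygens[rep(ids[i], 4), , drop = FALSE],
        oxygens[nb, , drop = FALSE], box)
    }
    q[b0:(b0 + length(ids) - 1L)] <- tetrahedral_q(vec)
  }
  structure(list(Q = mean(q), q = q, centers = centers),
            class = "order_parameters")
}

#' @export
print.order_parameters <- function(x, ...) {
  cat("Tetrahedral order: Q = ", format(x$Q), " over ", length(x$q),
      " centers (q range ", format(min(x$q)), " .. ", format(max(x$q)),
      ")\n", sep = "")
  invisible(x)
}

#' Select water oxygens in the vicinity of a solute
#'
#' Frame-wise selection of the oxygens whose minimum-image distance to the
#' nearest solute atom is at most `cutoff` (default 10 Angstrom, the shell
#' used for solvation-structure averages; 5 Angstrom probes the first
#' shells only). Membership is re-evaluated per frame.
#'
#' @param ens a [traj_ensemble()].
#' @param frame frame index.
#' @param solute atom indices of the solute (non-empty).
#' @param oxygens atom indices of the candidate water oxygens.
#' @param cutoff shell radius in Angstrom.
#' @return Sorted subset of `oxygens` inside the shell.
#' @export
select_vicinity <- function(ens, frame, solute, oxygens, cutoff = 10) {
  if (!length(solute)) stop("empty solute selection")
  stopifnot(cutoff > 0)
  co <- get_frame(ens, frame)
  D <- cross_dist(co[oxygens, , drop = FALSE], co[solute, , drop = FALSE],
                  ens$box)
  sort(oxygens[apply(D, 1, min) <= cutoff])
}
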