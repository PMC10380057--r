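## Ideal backbone geometry (Angstrom / degrees) used by the chain builder.
BB_GEOM <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
                omega = 180)

## Place atom D from reference atoms A, B, C (n x 3 matrices) given bond
## length |CD|, angle B-C-D (deg) and dihedral A-B-C-D (deg, length-n).
## Vectorized over frames.
nerf_place <- function(A, B, C, bond, angle, dihedral) {
  th <- angle * pi / 180
  ph <- -dihedral * pi / 180   # sign matches the IUPAC measurement convention
  bc <- C - B; bc <- bc / vnorm(bc)
  ab <- B - A
  n <- vcross(ab, bc); n <- n / vnorm(n)
  m <- vcross(n, bc)
  d <- cbind(-bond * cos(th), bond * sin(th) * cos(ph),
             bond * sin(th) * sin(ph))
  C + d[, 1] * bc + d[, 2] * m + d[, 3] * n
}

#' Build peptide backbones from dihedral angles
#'
#' Constructs N-CA-C backbone coordinates for every frame from per-residue
#' (phi, psi) matrices using ideal bond lengths (N-CA 1.458, CA-C 1.525,
#' C-N 1.329 Angstrom), ideal angles and omega = 180 degrees, by
#' sequential internal-coordinate (NeRF) placement vectorized over frames.
#'
#' @param phi,psi `nres x nframes` matrices of backbone dihedrals in
#'   degrees. `phi[1, ]` and `psi[nres, ]` are ignored (termini).
#' @return A `3*nres x 3 x nframes` coordinate array (atom order N1, CA1,
#'   C1, N2, ...).
#' @export
build_backbone <- function(phi, psi) {
  phi <- as.matrix(phi); psi <- as.matrix(psi)
  stopifnot(all(dim(phi) == dim(psi)))
  nres <- nrow(phi); nf <- ncol(phi)
  g <- BB_GEOM
  co <- array(NA_real_, dim = c(3 * nres, 3, nf))
  one <- function(v) matrix(rep(v, each = nf), nf, 3)
  ## residue 1 in a canonical frame
  N1 <- one(c(0, 0, 0))
  CA1 <- one(c(g$b_n_ca, 0, 0))
  a <- g$a_n_ca_c * pi / 180
  C1 <- one(c(g$b_n_ca - g$b_ca_c * cos(a), g$b_ca_c * sin(a), 0))
  co[1, , ] <- t(N1); co[2, , ] <- t(CA1); co[3, , ] <- t(C1)
  Nprev <- N1; CAprev <- CA1; Cprev <- C1
  for (i in seq_len(nres - 1)) {
    Ni <- nerf_place(Nprev, CAprev, Cprev, g$b_c_n, g$a_ca_c_n, psi[i, ])
    CAi <- nerf_place(CAprev, Cprev, Ni, g$b_n_ca, g$a_c_n_ca,
                      rep(g$omega, nf))
    Ci <- nerf_place(Cprev, Ni, CAi, g$b_ca_c, g$a_n_ca_c, phi[i + 1, ])
    r <- 3 * i
    co[r + 1, , ] <- t(Ni); co[r + 2, , ] <- t(CAi); co[r + 3, , ] <- t(Ci)
    Nprev <- Ni; CAprev <- CAi; Cprev <- Ci
  }
  co
}

#' Per-residue dihedral patterns for macrostates
#'
#' Builds the (phi, psi) pattern matrix of a macrostate: `"coil"` is an
#' extended polyproline-like conformation (-75, 150) that falls outside
#' both classifier windows; `"helix"` sets (-57, -47) on `helix_range`;
#' `"hairpin"` sets two strands to (-139, 135) joined by a chain-reversing
#' loop whose dihedrals are chosen so the built strands pair below 5.5
#' Angstrom and the loop flanks approach each other (salt-bridge-like
#' contact).
#'
#' @param n_res number of residues.
#' @param type `"coil"`, `"helix"` or `"hairpin"`.
#' @param helix_range residues set helical (default all, i.e. pure helix).
#' @param strand1,strand2 residue ranges of the two hairpin strands.
#' @return `n_res x 2` matrix (columns phi, psi) of mean dihedrals.
#' @export
macrostate_pattern <- function(n_res = 42,
                               type = c("coil", "helix", "hairpin"),
                               helix_range = seq_len(n_res),
                               strand1 = 17:21, strand2 = 30:34) {
  type <- match.arg(type)
  pat <- matrix(rep(c(-75, 150), each = n_res), n_res, 2,
                dimnames = list(NULL, c("phi", "psi")))
  jitter_scale <- rep(1, n_res)
  if (type == "helix") {
    pat[helix_range, 1] <- -57
    pat[helix_range, 2] <- -47
    jitter_scale[helix_range] <- 0.2
  } else if (type == "hairpin") {
    pat[c(strand1, strand2), 1] <- -139
    pat[c(strand1, strand2), 2] <- 135
    loop <- (max(strand1) + 1):(min(strand2) - 1)
    if (length(loop) < 2) stop("hairpin needs at least a 2-residue loop")
    if (length(loop) == 8) {
      ## chain-reversing 8-residue loop that pairs the flanking strands at
      ## ~4 Angstrom and brings the loop entry within salt-bridge range of
      ## the strand-2 side, without steric clashes
      pat[loop, ] <- matrix(c(-57, -47, -57, -47, -57, -47, -139, 135,
                              -57, -47, -90, 0, -75, 150, -75, 150),
                            8, 2, byrow = TRUE)
    } else {
      ## generic reversal for other loop lengths (not guaranteed to pair)
      loop_pat <- matrix(c(55, 40, 80, 0), 2, 2, byrow = TRUE)
      for (k in seq_along(loop))
        pat[loop[k], ] <- loop_pat[1 + (k - 1) %% 2, ]
    }
    jitter_scale[min(strand1):max(strand2)] <- 0.2
    attr(pat, "loop") <- loop
  }
  attr(pat, "jitter_scale") <- jitter_scale
  attr(pat, "type") <- type
  pat
}

#' Sample a discrete-state Markov chain
#'
#' Seeded simulation of a first-order Markov chain; the first state is
#' drawn from the stationary distribution of `P`.
#'
#' @param P row-stochastic transition matrix.
#' @param n number of steps (frames).
#' @param seed RNG seed.
#' @return Integer vector of state ids in `1:nrow(P)`.
#' @export
generate_markov_series <- function(P, n, seed = 1L) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-8))
    stop("P must be a row-stochastic square matrix")
  set.seed(seed)
  ev <- eigen(t(P))
  i <- which.min(abs(ev$values - 1))
  pi0 <- abs(Re(ev$vectors[, i])); pi0 <- pi0 / sum(pi0)
  s <- integer(n)
  s[1] <- sample.int(nrow(P), 1, prob = pi0)
  for (t in seq_len(n)[-1]) s[t] <- sample.int(nrow(P), 1, prob = P[s[t - 1], ])
  s
}

#' Macrostate specification for synthetic peptide trajectories
#'
#' @param patterns named list of `n_res x 2` dihedral pattern matrices
#'   (see [macrostate_pattern()]).
#' @param P row-stochastic Markov matrix between macrostates (same length
#'   as `patterns`).
#' @param n_frames frames to generate.
#' @param jitter_sd per-frame Gaussian jitter on every dihedral, degrees.
#' @param dt frame interval, ps.
#' @param seed RNG seed.
#' @return An object of class `macrostate_spec`.
#' @export
macrostate_spec <- function(patterns, P, n_frames = 1000, jitter_sd = 8,
                            dt = 100, seed = 1L) {
  stopifnot(is.list(patterns), length(patterns) == nrow(P),
            jitter_sd >= 0, n_frames >= 1)
  nres <- nrow(patterns[[1]])
  for (p in patterns) stopifnot(nrow(p) == nres, ncol(p) == 2)
  structure(list(patterns = patterns, P = as.matrix(P),
                 n_frames = as.integer(n_frames), jitter_sd = jitter_sd,
                 dt = dt, seed = as.integer(seed), n_res = nres),
            class = "macrostate_spec")
}

#' Default three-macrostate peptide specification
#'
#' A 42-residue peptide switching among a disordered extended coil, a
#' central helix (residues 10-21) and a beta-hairpin (strands 17-21 and
#' 30-34), mimicking the qualitative state structure of an intrinsically
#' disordered amyloid peptide. The Markov matrix has self-transition
#' probability `stay` and leaves states proportionally to the stationary
#' distribution `pi` (so `pi` is stationary by construction).
#'
#' @param n_frames frames to generate.
#' @param pi stationary distribution over (coil, helix, hairpin).
#' @param stay self-transition probability per frame.
#' @param jitter_sd dihedral jitter, degrees.
#' @param seed RNG seed.
#' @return A [macrostate_spec()].
#' @export
abeta_like_spec <- function(n_frames = 1000, pi = c(0.6, 0.3, 0.1),
                            stay = 0.95, jitter_sd = 8, seed = 1L) {
  stopifnot(length(pi) == 3, all(pi > 0), abs(sum(pi) - 1) < 1e-8,
            stay >= 0, stay < 1)
  P <- (1 - stay) * matrix(pi, 3, 3, byrow = TRUE) + stay * diag(3)
  P <- P / rowSums(P)
  pats <- list(coil = macrostate_pattern(42, "coil"),
               helix = macrostate_pattern(42, "helix", helix_range = 10:21),
               hairpin = macrostate_pattern(42, "hairpin"))
  macrostate_spec(pats, P, n_frames = n_frames, jitter_sd = jitter_sd,
                  seed = seed)
}

#' Realize a synthetic peptide trajectory from a macrostate specification
#'
#' Draws the macrostate sequence from the Markov matrix, builds every
#' frame's backbone from the macrostate's dihedral pattern plus Gaussian
#' jitter, and rejects self-colliding geometries (any nonbonded atom pair
#' closer than 1.5 Angstrom triggers a rebuild with fresh jitter; after 100
#' failed attempts for a frame an error is raised).
#'
#' @param spec a [macrostate_spec()].
#' @return A [traj_ensemble()] with attributes `macrostates` (ground-truth
#'   id per frame) and `macrostate_names`.
#' @export
realize_trajectory <- function(spec) {
  stopifnot(inherits(spec, "macrostate_spec"))
  ms <- generate_markov_series(spec$P, spec$n_frames, seed = spec$seed)
  nres <- spec$n_res; nf <- spec$n_frames
  phi_mean <- vapply(spec$patterns, function(p) p[, 1], numeric(nres))
  psi_mean <- vapply(spec$patterns, function(p) p[, 2], numeric(nres))
  ## structured residues fluctuate less than coil: per-residue jitter scale
  jsc <- vapply(spec$patterns, function(p) {
    s <- attr(p, "jitter_scale")
    if (is.null(s)) rep(1, nres) else s
  }, numeric(nres))
  build_frames <- function(idx) {
    sd_mat <- spec$jitter_sd * jsc[, ms[idx], drop = FALSE]
    phi <- phi_mean[, ms[idx], drop = FALSE] +
      matrix(stats::rnorm(nres * length(idx), 0, sd_mat), nres, length(idx))
    psi <- psi_mean[, ms[idx], drop = FALSE] +
      matrix(stats::rnorm(nres * length(idx), 0, sd_mat), nres, length(idx))
    build_backbone(phi, psi)
  }
  co <- build_frames(seq_len(nf))
  ## collision screening: nonbonded = chain separation > 3 atoms
  min_nonbonded <- function(m) {
    D <- as.matrix(stats::dist(m))
    D[abs(row(D) - col(D)) <= 3] <- Inf
    min(D)
  }
  for (f in seq_len(nf)) {
    att <- 0
    while (min_nonbonded(co[, , f]) < 1.5) {
      att <- att + 1
      if (att > 100) stop("frame ", f, ": no collision-free geometry in ",
                          "100 attempts")
      co[, , f] <- build_frames(f)[, , 1]
    }
  }
  top <- topology(name = rep(c("N", "CA", "C"), nres),
                  element = rep(c("N", "C", "C"), nres),
                  resname = "ALA", resid = rep(seq_len(nres), each = 3),
                  mol = "A")
  ens <- traj_ensemble(top, co, dt = spec$dt)
  attr(ens, "macrostates") <- ms
  attr(ens, "macrostate_names") <- names(spec$patterns)
  ens
}

#' Water-oxygen configurations across the order spectrum
#'
#' Generates point configurations spanning the limiting cases of the water
#' order parameters: `"ideal_gas"` (uniform positions; T ~ 0, Q ~ 0),
#' `"diamond_lattice"` (perfect 4-coordinated tetrahedral network; q = 1
#' at every site), `"perturbed_lattice"` (lattice plus Gaussian
#' displacements of standard deviation `jitter`).
#'
#' @param kind configuration type.
#' @param n requested number of oxygens. For lattices the nearest count
#'   compatible with whole conventional cells (8 sites each) is used, with
#'   a message.
#' @param density number density in atoms per cubic Angstrom (default
#'   0.0334, liquid water oxygen density).
#' @param jitter Gaussian displacement SD (Angstrom), lattice kinds only.
#' @param seed RNG seed.
#' @return List with `coords` (`n x 3`), `box` (edges), `kind`, `n`.
#' @export
generate_water_configuration <- function(kind = c("ideal_gas",
                                                  "diamond_lattice",
                                                  "perturbed_lattice"),
                                         n = 1000, density = 0.0334,
                                         jitter = 0.1, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n > 0, density > 0)
  set.seed(seed)
  if (kind == "ideal_gas") {
    L <- (n / density)^(1 / 3)
    co <- matrix(stats::runif(3 * n, 0, L), n, 3)
    return(list(coords = co, box = rep(L, 3), kind = kind, n = n))
  }
  m <- max(1L, round((n / 8)^(1 / 3)))
  n_act <- as.integer(8 * m^3)
  if (n_act != n)
    message("diamond lattice uses ", n_act, " sites (", m, "^3 cells of 8)")
  a <- (8 / density)^(1 / 3)
  fcc <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  basis <- rbind(c(0, 0, 0), c(.25, .25, .25))
  cell <- (fcc[rep(1:4, each = 2), ] + basis[rep(1:2, 4), ])
  grid <- as.matrix(expand.grid(0:(m - 1), 0:(m - 1), 0:(m - 1)))
  co <- matrix(0, n_act, 3)
  for (i in seq_len(nrow(grid)))
    co[(i - 1) * 8 + 1:8, ] <- a * (cell + matrix(grid[i, ], 8, 3,
                                                  byrow = TRUE))
  if (kind == "perturbed_lattice")
    co <- co + matrix(stats::rnorm(3 * n_act, 0, jitter), n_act, 3)
  list(coords = co, box = rep(m * a, 3), kind = kind, n = n_act)
}

#' Renewal-process hydrogen-bond traces with prescribed persistence
#'
#' Alternating on/off renewal process per bond: on-intervals are
#' Weibull(shape `beta`, scale `tau`) so the on-interval survival function
#' is the stretched exponential exp(-(t/tau)^beta); off-intervals are
#' exponential with mean `off_scale`. Continuous renewal times are
#' discretized onto the frame grid.
#'
#' @param n_bonds number of independent bond traces.
#' @param n_frames frames per trace.
#' @param dt frame interval, ps (default 0.5, resolving H-bond kinetics).
#' @param beta Weibull shape (stretching exponent), in (0, 1].
#' @param tau Weibull scale, ps.
#' @param off_scale mean off-interval, ps.
#' @param seed RNG seed.
#' @return An `hbond_traces` object.
#' @export
generate_hbond_traces <- function(n_bonds = 100, n_frames = 2000, dt = 0.5,
                                  beta = 0.5, tau = 10, off_scale = 200,
                                  seed = 1L) {
  stopifnot(beta > 0, beta <= 1, tau > 0, off_scale > 0, dt > 0)
  set.seed(seed)
  total <- n_frames * dt
  mean_on <- tau * gamma(1 + 1 / beta)
  p_on <- mean_on / (mean_on + off_scale)
  tgrid <- (seq_len(n_frames) - 1) * dt
  h <- matrix(0L, n_bonds, n_frames)
  for (b in seq_len(n_bonds)) {
    on <- stats::runif(1) < p_on
    t0 <- 0
    while (t0 < total) {
      len <- if (on) stats::rweibull(1, shape = beta, scale = tau)
             else stats::rexp(1, rate = 1 / off_scale)
      if (on) h[b, tgrid >= t0 & tgrid < t0 + len] <- 1L
      t0 <- t0 + len
      on <- !on
    }
  }
  new_hbond_traces(h, dt)
}

#' Toy ion configurations around reference atoms
#'
#' Places ions either uniformly in the box (flat g(r) ground truth) or in a
#' thin spherical shell of radius `r0` and full width `width` around
#' randomly chosen reference atoms (g(r) peak at `r0`). Ions landing within
#' 1 Angstrom of any reference atom are resampled.
#'
#' @param reference `m x 3` matrix of reference-atom coordinates.
#' @param n_ions number of ions.
#' @param placement `"uniform"` or `"shell"`.
#' @param box orthorhombic box edges.
#' @param r0,width shell radius and width, Angstrom (shell placement).
#' @param seed RNG seed.
#' @return `n_ions x 3` coordinate matrix.
#' @export
generate_ion_system <- function(reference, n_ions, placement = c("uniform",
                                                                 "shell"),
                                box, r0 = 2.2, width = 0.1, seed = 1L) {
  placement <- match.arg(placement)
  reference <- as.matrix(reference)
  box <- as.numeric(box)
  if (placement == "shell" && r0 >= min(box) / 2)
    stop("shell radius must be below half the box edge")
  set.seed(seed)
  draw <- function(k) {
    if (placement == "uniform") {
      matrix(stats::runif(3 * k, 0, rep(box, each = k)), k, 3)
    } else {
      ctr <- reference[sample.int(nrow(reference), k, replace = TRUE), ,
                       drop = FALSE]
      u <- matrix(stats::rnorm(3 * k), k, 3)
      u <- u / vnorm(u)
      r <- r0 + stats::runif(k, -width / 2, width / 2)
      (ctr + r * u) %% rep(box, each = k)
    }
  }
  co <- draw(n_ions)
  repeat {
    D <- cross_dist(co, reference, box)
    bad <- which(apply(D, 1, min) < 1)
    if (!length(bad)) break
    co[bad, ] <- draw(length(bad))
  }
  co
}
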