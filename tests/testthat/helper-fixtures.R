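## Shared fixtures and independent oracles, built in code at test time.

## Minimal peptide topology: N-CA-C backbone for n residues.
bb_topology <- function(n_res) {
  topology(name = rep(c("N", "CA", "C"), n_res),
           element = rep(c("N", "C", "C"), n_res),
           resname = "ALA", resid = rep(seq_len(n_res), each = 3))
}

## Ensemble with every residue at the same (phi, psi).
uniform_dihedral_ensemble <- function(n_res, phi, psi, n_frames = 1) {
  co <- build_backbone(matrix(phi, n_res, n_frames),
                       matrix(psi, n_res, n_frames))
  traj_ensemble(bb_topology(n_res), co)
}

## Random 3D rotation matrix (seeded by caller).
random_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}

## Independent exhaustive modularity oracle: recursively enumerates all set
## partitions of 1..n and scores them with a direct double-loop modularity
## sum (deliberately different code from the package's search).
oracle_best_modularity <- function(w, resolution = 1) {
  n <- nrow(w)
  m2 <- sum(w)
  k <- rowSums(w)
  score <- function(memb) {
    q <- 0
    for (i in 1:n) for (j in 1:n) {
      if (memb[i] == memb[j])
        q <- q + w[i, j] / m2 - resolution * k[i] * k[j] / m2^2
    }
    q
  }
  best <- -Inf
  recurse <- function(memb, nxt) {
    if (nxt > n) {
      q <- score(memb)
      if (q > best) best <<- q
      return(invisible())
    }
    for (c in 1:(max(memb[seq_len(nxt - 1)]) + 1)) {
      memb[nxt] <- c
      recurse(memb, nxt + 1)
    }
  }
  recurse(c(1L, rep(0L, n - 1)), 2L)
  best
}

## Two k-cliques (unit weights) joined by a single edge.
two_cliques_counts <- function(k = 5) {
  n <- 2 * k
  w <- matrix(0, n, n)
  w[1:k, 1:k] <- 1
  w[(k + 1):n, (k + 1):n] <- 1
  diag(w) <- 0
  w[k, k + 1] <- w[k + 1, k] <- 1
  w   # symmetric; usable directly as a count matrix
}

## Analytic conditional persistence of a stationary two-state telegraph
## process (exponential on/off with means tau_on, tau_off):
## P(on at t | on at 0).
telegraph_c <- function(t, tau_on, tau_off) {
  a <- 1 / tau_on; b <- 1 / tau_off
  p_on <- b / (a + b)
  p_on + (1 - p_on) * exp(-(a + b) * t)
}

## Kabsch RMSD after optimal superposition (closed-form via SVD).
rmsd_superposed <- function(A, B) {
  A <- scale(A, scale = FALSE); B <- scale(B, scale = FALSE)
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((A - B %*% t(R))^2)))
}
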