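#' Descriptor specification for state projection
#'
#' Controls how each trajectory frame is reduced to the descriptor triple
#' (Nalpha, Nbeta, dNC) and how that triple is binned into a discrete state:
#' Nalpha (number of helical residues) and Nbeta (number of sheet residues)
#' are used as exact integer counts; the end-to-end distance dNC is binned
#' by flooring at `dnc_bin` Angstrom resolution.
#'
#' The secondary-structure classifier is a backbone-dihedral window rule:
#' a residue is helical (H) when phi in \[-100, -30\] and psi in \[-80, -5\]
#' degrees within a run of at least `min_helix_run` consecutive such
#' residues; it is sheet (E) when phi in \[-180, -90\] and psi in
#' \[90, 180\] or \[-180, -170\] within a run of at least `min_strand_run`,
#' and (in the default paired-strand mode) some other strand run has at
#' least one inter-run C-alpha pair closer than `pair_cutoff` Angstrom.
#' Everything else, including chain termini without computable (phi, psi),
#' is coil (C).
#'
#' @param dnc_bin bin width for dNC in Angstrom (default 1).
#' @param dnc_atoms `"CA"` (distance between first and last C-alpha, the
#'   default) or `"NC"` (backbone N of the first residue to backbone C of
#'   the last).
#' @param paired_strands require strand pairing for an E assignment.
#' @param min_helix_run,min_strand_run minimum run lengths.
#' @param pair_cutoff C-alpha pairing cutoff in Angstrom.
#' @return An object of class `descriptor_spec`.
#' @export
descriptor_spec <- function(dnc_bin = 1, dnc_atoms = c("CA", "NC"),
                            paired_strands = TRUE, min_helix_run = 4L,
                            min_strand_run = 3L, pair_cutoff = 5.5) {
  stopifnot(dnc_bin > 0, min_helix_run >= 1, min_strand_run >= 1,
            pair_cutoff > 0)
  structure(list(dnc_bin = dnc_bin, dnc_atoms = match.arg(dnc_atoms),
                 paired_strands = paired_strands,
                 min_helix_run = as.integer(min_helix_run),
                 min_strand_run = as.integer(min_strand_run),
                 pair_cutoff = pair_cutoff),
            class = "descriptor_spec")
}

## Backbone atom bookkeeping for one molecule: indices of N, CA, C per
## residue, in residue order. Errors name the offending residue.
backbone_indices <- function(top, mol = NULL) {
  if (is.null(mol)) mol <- top$mol[1]
  sub <- which(top$mol == mol)
  resids <- unique(top$resid[sub])
  idx <- matrix(NA_integer_, length(resids), 3,
                dimnames = list(NULL, c("N", "CA", "C")))
  for (i in seq_along(resids)) {
    rs <- sub[top$resid[sub] == resids[i]]
    for (a in c("N", "CA", "C")) {
      j <- rs[top$name[rs] == a]
      if (length(j) != 1)
        stop("residue ", top$resname[rs[1]], resids[i], " (molecule ", mol,
             ") lacks a unique backbone atom ", a)
      idx[i, a] <- j
    }
  }
  list(resid = resids, idx = idx, mol = mol)
}

## phi/psi for all residues of one molecule over a set of frames.
## Returns nres x nframes matrices (NA at termini).
backbone_dihedrals <- function(ens, frames = seq_len(n_frames(ens)),
                               mol = NULL) {
  bb <- backbone_indices(ens$top, mol)
  nres <- length(bb$resid)
  nf <- length(frames)
  phi <- psi <- matrix(NA_real_, nres, nf)
  co <- ens$coords[, , frames, drop = FALSE]
  pick <- function(ai) {
    ## ai: atom index per residue-row; returns (nres_used*nf) x 3 matrix
    m <- co[ai, , , drop = FALSE]
    matrix(aperm(m, c(1, 3, 2)), ncol = 3)
  }
  if (nres >= 2) {
    ## phi_i = C(i-1)-N(i)-CA(i)-C(i) for i = 2..nres
    i <- 2:nres
    phi[i, ] <- dihedral_angle(pick(bb$idx[i - 1, "C"]), pick(bb$idx[i, "N"]),
                               pick(bb$idx[i, "CA"]), pick(bb$idx[i, "C"]))
    ## psi_i = N(i)-CA(i)-C(i)-N(i+1) for i = 1..nres-1
    j <- 1:(nres - 1)
    psi[j, ] <- dihedral_angle(pick(bb$idx[j, "N"]), pick(bb$idx[j, "CA"]),
                               pick(bb$idx[j, "C"]), pick(bb$idx[j + 1, "N"]))
  }
  list(phi = phi, psi = psi, bb = bb, frames = frames)
}

## Run-length labelling of one frame's window masks.
runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

classify_frame <- function(phi, psi, ca_xyz, spec, box = NULL) {
  n <- length(phi)
  lab <- rep("C", n)
  ok <- !is.na(phi) & !is.na(psi)
  hmask <- ok & phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5
  emask <- ok & phi >= -180 & phi <= -90 &
    ((psi >= 90 & psi <= 180) | (psi >= -180 & psi <= -170))
  hr <- runs_of(hmask)
  for (k in seq_len(nrow(hr)))
    if (hr[k, 2] - hr[k, 1] + 1L >= spec$min_helix_run)
      lab[hr[k, 1]:hr[k, 2]] <- "H"
  er <- runs_of(emask)
  keep <- er[, 2] - er[, 1] + 1L >= spec$min_strand_run
  er <- er[keep, , drop = FALSE]
  if (nrow(er)) {
    paired <- rep(TRUE, nrow(er))
    if (spec$paired_strands && nrow(er) >= 1) {
      paired[] <- FALSE
      if (nrow(er) >= 2) {
        for (a in seq_len(nrow(er) - 1)) for (b in (a + 1):nrow(er)) {
          da <- cross_dist(ca_xyz[er[a, 1]:er[a, 2], , drop = FALSE],
                           ca_xyz[er[b, 1]:er[b, 2], , drop = FALSE], box)
          if (min(da) < spec$pair_cutoff) paired[c(a, b)] <- TRUE
        }
      }
    }
    for (k in which(paired)) lab[er[k, 1]:er[k, 2]] <- "E"
  }
  lab
}

#' Assign secondary structure for one frame
#'
#' Applies the dihedral-window classifier of [descriptor_spec()] to one
#' frame of the ensemble and returns one label per residue: `"H"` (helix),
#' `"E"` (sheet/strand) or `"C"` (coil).
#'
#' @param ens a [traj_ensemble()] whose molecule `mol` has backbone N, CA, C
#'   atoms for every residue.
#' @param frame frame index.
#' @param spec a [descriptor_spec()].
#' @param mol molecule id; defaults to the first molecule in the topology.
#' @return Character vector of labels, named by residue index.
#' @export
assign_secondary_structure <- function(ens, frame, spec = descriptor_spec(),
                                       mol = NULL) {
  dih <- backbone_dihedrals(ens, frames = frame, mol = mol)
  ca <- ens$coords[dih$bb$idx[, "CA"], , frame, drop = TRUE]
  if (is.null(dim(ca))) ca <- matrix(ca, ncol = 3)
  lab <- classify_frame(dih$phi[, 1], dih$psi[, 1], ca, spec, ens$box)
  names(lab) <- dih$bb$resid
  lab
}

#' Per-frame descriptors: helical count, sheet count, end-to-end distance
#'
#' Computes the descriptor triple for one frame: `Nalpha` = number of
#' residues labelled H, `Nbeta` = number labelled E, and `dNC` = the
#' end-to-end distance in Angstrom (first to last residue; minimum image
#' when the ensemble has a box).
#'
#' @inheritParams assign_secondary_structure
#' @return Named numeric vector `c(Nalpha=, Nbeta=, dNC=)`.
#' @export
compute_descriptors <- function(ens, frame, spec = descriptor_spec(),
                                mol = NULL) {
  lab <- assign_secondary_structure(ens, frame, spec, mol)
  bb <- backbone_indices(ens$top, mol)
  ij <- if (spec$dnc_atoms == "CA") {
    c(bb$idx[1, "CA"], bb$idx[nrow(bb$idx), "CA"])
  } else c(bb$idx[1, "N"], bb$idx[nrow(bb$idx), "C"])
  p <- ens$coords[ij, , frame, drop = TRUE]
  dnc <- min_image_dist(p[1, , drop = FALSE], p[2, , drop = FALSE], ens$box)
  c(Nalpha = sum(lab == "H"), Nbeta = sum(lab == "E"), dNC = unname(dnc))
}

#' Project a trajectory onto discrete descriptor states
#'
#' Evaluates the descriptor triple on every frame, bins it (integer counts
#' as-is, dNC floored at `spec$dnc_bin` Angstrom) and assigns dense integer
#' state ids in order of first appearance. Identical binned triples always
#' map to the same state. Raw (unbinned) descriptor values are retained for
#' community averaging.
#'
#' @inheritParams assign_secondary_structure
#' @return An object of class `state_series`: a list with `states` (integer
#'   state id per frame, starting at 1), `raw` (data frame of per-frame
#'   Nalpha, Nbeta, dNC), `key` (data frame of binned triples per state id),
#'   `segments`, `dt` and the `spec` used.
#' @export
project_trajectory <- function(ens, spec = descriptor_spec(), mol = NULL) {
  nf <- n_frames(ens)
  dih <- backbone_dihedrals(ens, mol = mol)
  bb <- dih$bb
  nres <- length(bb$resid)
  nal <- nbe <- integer(nf)
  for (f in seq_len(nf)) {
    ca <- ens$coords[bb$idx[, "CA"], , f, drop = TRUE]
    lab <- classify_frame(dih$phi[, f], dih$psi[, f], ca, spec, ens$box)
    nal[f] <- sum(lab == "H")
    nbe[f] <- sum(lab == "E")
  }
  ij <- if (spec$dnc_atoms == "CA") {
    c(bb$idx[1, "CA"], bb$idx[nres, "CA"])
  } else c(bb$idx[1, "N"], bb$idx[nres, "C"])
  a <- t(ens$coords[ij[1], , ]); b <- t(ens$coords[ij[2], , ])
  if (nf == 1) { a <- matrix(a, ncol = 3); b <- matrix(b, ncol = 3) }
  dnc <- min_image_dist(a, b, ens$box)
  dbin <- as.integer(floor(dnc / spec$dnc_bin))
  keystr <- paste(nal, nbe, dbin, sep = "|")
  uniq <- unique(keystr)
  states <- match(keystr, uniq)
  parts <- do.call(rbind, strsplit(uniq, "|", fixed = TRUE))
  key <- data.frame(state = seq_along(uniq),
                    Nalpha = as.integer(parts[, 1]),
                    Nbeta = as.integer(parts[, 2]),
                    dNC_bin = as.integer(parts[, 3]))
  structure(list(states = states,
                 raw = data.frame(frame = seq_len(nf), Nalpha = nal,
                                  Nbeta = nbe, dNC = dnc),
                 key = key, segments = ens$segments, dt = ens$dt,
                 spec = spec),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  cat("Descriptor state series: ", length(x$states), " frames, ",
      nrow(x$key), " distinct states, ", nrow(x$segments), " segment(s)\n",
      sep = "")
  invisible(x)
}

#' Write per-frame descriptors and state ids to CSV
#'
#' @param series a `state_series` from [project_trajectory()].
#' @param path output CSV path.
#' @export
write_descriptors <- function(series, path) {
  d <- series$raw
  d$state <- series$states
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
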