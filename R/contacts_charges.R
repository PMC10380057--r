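#' Contact-probability map between two sets of groups
#'
#' Two groups are in contact in a frame when the minimum distance over all
#' their heavy-atom pairs is below `cutoff` (default 10 Angstrom). Contact
#' counts are normalized by the number of frames, giving per-pair contact
#' probabilities. Typical groupings: peptide residues vs peptide residues
#' (intramolecular map, symmetric) or residues vs monosaccharides/lipid
#' molecules (intermolecular map).
#'
#' @param ens a [traj_ensemble()].
#' @param groupsA,groupsB named lists of atom-index vectors.
#' @param cutoff contact cutoff, Angstrom.
#' @param frames frames to use (default all).
#' @param heavy_only drop hydrogens from each group (default TRUE).
#' @return An object of class `contact_map`: list with probability matrix
#'   `p` (rows = groupsA, cols = groupsB), `cutoff`, `n_frames`.
#' @export
contact_map <- function(ens, groupsA, groupsB = groupsA, cutoff = 10,
                        frames = seq_len(n_frames(ens)), heavy_only = TRUE) {
  stopifnot(cutoff > 0)
  strip <- function(gs, side) {
    lapply(seq_along(gs), function(i) {
      g <- gs[[i]]
      if (!length(g))
        stop("empty group ", if (!is.null(names(gs))) names(gs)[i] else i,
             " in ", side)
      if (heavy_only) {
        g2 <- g[ens$top$element[g] != "H"]
        if (!length(g2))
          stop("group ", if (!is.null(names(gs))) names(gs)[i] else i,
               " in ", side, " has no heavy atoms")
        g2
      } else g
    })
  }
  ga <- strip(groupsA, "groupsA"); gb <- strip(groupsB, "groupsB")
  hits <- matrix(0, length(ga), length(gb),
                 dimnames = list(names(groupsA), names(groupsB)))
  for (f in frames) {
    co <- ens$coords[, , f, drop = TRUE]
    for (i in seq_along(ga)) {
      A <- co[ga[[i]], , drop = FALSE]
      for (j in seq_along(gb)) {
        D <- cross_dist(A, co[gb[[j]], , drop = FALSE], ens$box)
        if (min(D) < cutoff) hits[i, j] <- hits[i, j] + 1
      }
    }
  }
  structure(list(p = hits / length(frames), cutoff = cutoff,
                 n_frames = length(frames)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("Contact map: ", nrow(x$p), " x ", ncol(x$p), " groups, cutoff ",
      x$cutoff, " Angstrom, ", x$n_frames, " frames, max probability ",
      format(max(x$p), digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
plot.contact_map <- function(x, ...) {
  graphics::image(seq_len(nrow(x$p)), seq_len(ncol(x$p)), x$p,
                  xlab = "group A", ylab = "group B",
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Group atom indices by residue
#'
#' Convenience for building contact-map groups: one group per residue of a
#' molecule, named `resname resid`.
#'
#' @param ens a [traj_ensemble()] (or a [topology()]).
#' @param mol molecule id (default first).
#' @return Named list of atom-index vectors.
#' @export
residue_groups <- function(ens, mol = NULL) {
  top <- if (inherits(ens, "traj_ensemble")) ens$top else ens
  if (is.null(mol)) mol <- top$mol[1]
  sub <- which(top$mol == mol)
  r <- top$resid[sub]
  sp <- split(sub, factor(r, levels = sort(unique(r))))
  names(sp) <- vapply(sp, function(ix)
    paste0(top$resname[ix[1]], top$resid[ix[1]]), "")
  sp
}

#' Ion radial distribution around a reference group
#'
#' g(r) of ion distances to the nearest atom of a reference group (e.g. the
#' carboxyl atoms of acidic side chains), normalized by the ions' bulk
#' number density and spherical shell volume. With a multi-atom reference
#' the spherical normalization is approximate near the group but correct at
#' large r, where g must approach 1 for a uniform ion distribution.
#'
#' @param ens a [traj_ensemble()] with a box.
#' @param ions atom indices of the ions.
#' @param reference atom indices of the reference group (non-empty).
#' @param bin_width histogram bin width, Angstrom.
#' @param r_max maximum distance (default half the shortest box edge).
#' @param frames frames to average (default all).
#' @return An `rdf_profile` (density = ion bulk density).
#' @export
ion_rdf <- function(ens, ions, reference, bin_width = 0.1, r_max = NULL,
                    frames = seq_len(n_frames(ens))) {
  if (!length(reference)) stop("empty reference group")
  if (!length(ions)) stop("no ions selected")
  if (is.null(ens$box)) stop("ion_rdf needs a periodic box")
  box <- ens$box
  if (is.null(r_max)) r_max <- min(box) / 2
  if (r_max > min(box) / 2 + 1e-9)
    stop("r_max exceeds half the shortest box edge")
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  counts <- numeric(length(edges) - 1)
  for (f in frames) {
    co <- ens$coords[, , f, drop = TRUE]
    D <- cross_dist(co[ions, , drop = FALSE],
                    co[reference, , drop = FALSE], box)
    d <- apply(D, 1, min)
    d <- d[d < r_max]
    counts <- counts + tabulate(findInterval(d, edges,
                                             rightmost.closed = TRUE),
                                nbins = length(edges) - 1)
  }
  counts <- counts / length(frames)
  rho <- length(ions) / prod(box)
  shell <- 4 / 3 * pi * diff(edges^3)
  g <- counts / (rho * shell)
  structure(list(r = (edges[-1] + edges[-length(edges)]) / 2, g = g,
                 edges = edges, rho = rho, n = length(ions),
                 volume = prod(box)),
            class = "rdf_profile")
}

#' Formal charge model for peptides and glycosaminoglycans
#'
#' Integer side-chain charges at physiological pH: Asp and Glu -1, Lys and
#' Arg +1, His neutral by default (set `his_charged = TRUE` for the
#' protonated His+ variant). Uncapped termini contribute +1 (N-terminus)
#' and -1 (C-terminus). Monosaccharide units of chondroitin-4-sulfate:
#' GalNAc(4S) -1 (sulfate), GlcUA -1 (carboxylate).
#'
#' @param his_charged model histidines as His+ (+1) instead of neutral.
#' @param capped TRUE when the peptide termini are capped (no terminal
#'   charges).
#' @return An object of class `charge_model`.
#' @export
charge_model <- function(his_charged = FALSE, capped = FALSE) {
  res <- c(D = -1, E = -1, K = +1, R = +1, H = if (his_charged) +1 else 0)
  sugars <- c("GalNAc4S" = -1, "GlcUA" = -1)
  structure(list(residue = res, sugars = sugars, capped = capped),
            class = "charge_model")
}

#' Net formal charge of a peptide sequence or sugar composition
#'
#' For a one-letter amino-acid sequence: sum of side-chain charges plus
#' terminal charges (+1/-1) unless the model is capped. For a
#' monosaccharide composition (named counts, e.g.
#' `c(GalNAc4S = 8, GlcUA = 8)`): sum of unit charges.
#'
#' @param x one-letter sequence string, or a named numeric vector of
#'   monosaccharide counts.
#' @param model a [charge_model()].
#' @return Integer net charge in units of e.
#' @export
net_charge <- function(x, model = charge_model()) {
  if (is.character(x) && length(x) == 1) {
    aa <- strsplit(toupper(x), "")[[1]]
    known <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    bad <- setdiff(aa, known)
    if (length(bad))
      stop("unknown residue code(s): ", paste(unique(bad), collapse = ", "))
    q <- sum(model$residue[aa], na.rm = TRUE)
    if (!model$capped) q <- q + 1 - 1 + 0  # +1 N-term, -1 C-term
    return(as.integer(round(q)))
  }
  if (is.numeric(x) && !is.null(names(x))) {
    bad <- setdiff(names(x), names(model$sugars))
    if (length(bad))
      stop("unknown monosaccharide(s): ", paste(bad, collapse = ", "))
    return(as.integer(round(sum(model$sugars[names(x)] * x))))
  }
  stop("x must be a sequence string or a named composition vector")
}
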