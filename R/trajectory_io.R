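#' Molecular topology
#'
#' A topology is a data frame describing atom identity: one row per atom with
#' columns `name` (atom name, e.g. `"CA"`), `element` (`"C"`, `"N"`, ...),
#' `resname` (three-letter residue or monosaccharide code), `resid`
#' (1-based residue index) and `mol` (molecule/chain identifier). An
#' optional `bonds` attribute holds a two-column matrix of bonded atom index
#' pairs (1-based).
#'
#' @param name,element,resname,resid,mol vectors of equal length, recycled
#'   where scalar.
#' @param bonds optional two-column integer matrix of bonded atom pairs.
#' @return An object of class `ctna_topology` (a data frame).
#' @export
topology <- function(name, element = substr(name, 1, 1), resname = "UNK",
                     resid = 1L, mol = "A", bonds = NULL) {
  top <- data.frame(name = as.character(name),
                    element = as.character(element),
                    resname = as.character(resname),
                    resid = as.integer(resid),
                    mol = as.character(mol),
                    stringsAsFactors = FALSE)
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (any(bonds < 1L) || any(bonds > nrow(top)))
      stop("bond indices out of range")
    attr(top, "bonds") <- bonds
  }
  class(top) <- c("ctna_topology", "data.frame")
  top
}

#' Trajectory ensemble
#'
#' Container for a coordinate trajectory: a topology plus a `natoms x 3 x
#' nframes` coordinate array in Angstrom, the frame interval `dt` in ps, an
#' optional orthorhombic box (three edge lengths, Angstrom) and a set of
#' `segments` marking independent trajectory pieces (e.g. separate
#' simulation runs concatenated into one ensemble). Transition counting
#' never pairs frames across segment boundaries.
#'
#' @param top a [topology()].
#' @param coords `natoms x 3 x nframes` array, or a list of `natoms x 3`
#'   matrices, or a single matrix (one frame). Angstrom.
#' @param dt frame interval in ps (must be positive).
#' @param box optional numeric of length 3: orthorhombic box edges (Angstrom).
#' @param segments optional two-column matrix of (start, end) frame indices
#'   (1-based, inclusive) that partition `1:nframes`; default one segment.
#' @return An object of class `traj_ensemble`.
#' @export
traj_ensemble <- function(top, coords, dt = 1.0, box = NULL, segments = NULL) {
  if (is.list(coords) && !is.array(coords))
    coords <- array(unlist(coords), dim = c(nrow(coords[[1]]), 3, length(coords)))
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1))
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (dim(coords)[1] != nrow(top))
    stop("coordinate rows (", dim(coords)[1], ") do not match topology atoms (",
         nrow(top), ")")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be > 0 ps")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive edge lengths")
  }
  nf <- dim(coords)[3]
  if (is.null(segments)) segments <- matrix(c(1L, nf), 1)
  segments <- matrix(as.integer(segments), ncol = 2)
  lens <- segments[, 2] - segments[, 1] + 1L
  covered <- unlist(mapply(seq, segments[, 1], segments[, 2], SIMPLIFY = FALSE))
  if (any(lens < 1L) || length(covered) != nf || anyDuplicated(covered) ||
      !setequal(covered, seq_len(nf)))
    stop("segments must partition frames 1..", nf, " without overlap")
  structure(list(top = top, coords = coords, dt = dt, box = box,
                 segments = segments),
            class = "traj_ensemble")
}

#' @export
print.traj_ensemble <- function(x, ...) {
  cat("Trajectory ensemble: ", n_atoms(x), " atoms, ", n_frames(x),
      " frame(s), dt = ", x$dt, " ps\n", sep = "")
  cat("  residues: ", length(unique(paste(x$top$mol, x$top$resid))),
      "; molecules: ", length(unique(x$top$mol)), "\n", sep = "")
  if (!is.null(x$box))
    cat("  box: ", paste(format(x$box), collapse = " x "), " Angstrom\n", sep = "")
  cat("  segments: ", nrow(x$segments), "\n", sep = "")
  invisible(x)
}

#' @rdname traj_ensemble
#' @param ens a `traj_ensemble`.
#' @export
n_frames <- function(ens) dim(ens$coords)[3]

#' @rdname traj_ensemble
#' @export
n_atoms <- function(ens) dim(ens$coords)[1]

#' @rdname traj_ensemble
#' @param frame frame index (1-based).
#' @return `get_frame`: a `natoms x 3` coordinate matrix.
#' @export
get_frame <- function(ens, frame) {
  if (frame < 1 || frame > n_frames(ens)) stop("frame out of range")
  ens$coords[, , frame, drop = TRUE]
}

guess_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         pdb = "pdb", ent = "pdb", xyz = "xyz", csv = "csv", txt = "csv",
         stop("cannot guess trajectory format from extension of '", path,
              "'; pass format explicitly"))
}

#' Read a structure or trajectory file
#'
#' Reads PDB (single- or multi-MODEL), chemistry XYZ, or the package's
#' whitespace CSV trajectory dialect (columns `frame atom x y z`, 1-based,
#' `#`-prefixed header lines carrying units, `dt`, box and atom identities).
#' Coordinates are returned in Angstrom. XYZ and CSV files without a
#' recorded frame interval default to `dt = 1` ps with a warning, because
#' kinetic analyses need the true stride.
#'
#' @param path file to read.
#' @param format one of `"pdb"`, `"xyz"`, `"csv"`; guessed from the file
#'   extension by default.
#' @param dt frame interval in ps; overrides any value recorded in the file.
#' @param top optional [topology()] to attach (useful for XYZ/CSV files that
#'   carry no residue information).
#' @return A [traj_ensemble()].
#' @export
read_structure <- function(path, format = guess_format(path), dt = NULL,
                           top = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format, c("pdb", "xyz", "csv"))
  ens <- switch(format,
                pdb = read_pdb_traj(path),
                xyz = read_xyz_traj(path),
                csv = read_csv_traj(path))
  if (!is.null(top)) {
    if (nrow(top) != n_atoms(ens)) stop("supplied topology does not match file")
    ens$top <- top
  }
  if (!is.null(dt)) {
    ens$dt <- dt
  } else if (isTRUE(attr(ens, "dt_defaulted"))) {
    warning("no frame interval recorded in '", path, "'; defaulting dt = 1 ps")
  }
  attr(ens, "dt_defaulted") <- NULL
  ens
}

read_pdb_traj <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("PDB parse error in '", path, "': ",
                                           conditionMessage(e)))
  at <- pdb$atom
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- substr(gsub("[^A-Za-z].*", "", at$elety[bad]), 1, 1)
  mol <- at$chain
  mol[is.na(mol) | mol == ""] <- "A"
  top <- topology(name = at$elety, element = elem, resname = at$resid,
                  resid = at$resno, mol = mol)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- ncol(xyz) / 3
  coords <- array(0, dim = c(na, 3, nf))
  for (f in seq_len(nf)) coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  ens <- traj_ensemble(top, coords, dt = 1.0)
  attr(ens, "dt_defaulted") <- TRUE
  ens
}

read_xyz_traj <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) %% 1 == 0]
  i <- 1L
  frames <- list(); elems <- NULL; dt <- NULL; box <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(na) || na < 1)
      stop("XYZ parse error at line ", i, ": expected atom count, got '",
           lines[i], "'")
    comment <- if (i + 1L <= length(lines)) lines[i + 1L] else ""
    m <- regmatches(comment, regexec("dt_ps=([0-9.eE+-]+)", comment))[[1]]
    if (length(m) == 2) dt <- as.numeric(m[2])
    m <- regmatches(comment, regexec(
      "box=([0-9.eE+-]+)[ ,]([0-9.eE+-]+)[ ,]([0-9.eE+-]+)", comment))[[1]]
    if (length(m) == 4) box <- as.numeric(m[2:4])
    if (i + 1L + na > length(lines))
      stop("XYZ parse error at line ", i, ": frame truncated (need ", na,
           " atom lines)")
    block <- lines[(i + 2L):(i + 1L + na)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    if (any(lengths(parts) < 4))
      stop("XYZ parse error at line ", i + 1L + which(lengths(parts) < 4)[1],
           ": expected 'element x y z'")
    el <- vapply(parts, `[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz))
      stop("XYZ parse error near line ", i + 2L, ": non-numeric coordinate")
    if (is.null(elems)) elems <- el
    else if (length(el) != length(elems))
      stop("XYZ parse error at line ", i, ": frame atom count changed")
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + na
  }
  if (!length(frames)) stop("XYZ parse error: no frames in file")
  top <- topology(name = paste0(elems, seq_along(elems)), element = elems)
  ens <- traj_ensemble(top, frames, dt = if (is.null(dt)) 1.0 else dt, box = box)
  if (is.null(dt)) attr(ens, "dt_defaulted") <- TRUE
  ens
}

read_csv_traj <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  dt <- NULL; box <- NULL; atoms <- NULL
  for (h in hdr) {
    if (grepl("^# *dt_ps", h)) dt <- as.numeric(sub("^# *dt_ps[ :=]+", "", h))
    if (grepl("^# *box", h))
      box <- as.numeric(strsplit(trimws(sub("^# *box[ :=]+", "", h)),
                                 "[[:space:]]+")[[1]])
    if (grepl("^# *atom ", h)) {
      p <- strsplit(trimws(sub("^# *atom ", "", h)), "[[:space:]]+")[[1]]
      atoms <- rbind(atoms, p)
    }
  }
  if (!length(body)) stop("CSV trajectory '", path, "' has no data rows")
  first <- strsplit(trimws(body[1]), "[[:space:],]+")[[1]]
  skip_names <- !is.na(suppressWarnings(as.numeric(first[1])))
  dat <- utils::read.table(text = body, header = !skip_names)
  if (ncol(dat) < 5) stop("CSV trajectory needs columns: frame atom x y z")
  names(dat)[1:5] <- c("frame", "atom", "x", "y", "z")
  nf <- max(dat$frame); na <- max(dat$atom)
  if (nrow(dat) != nf * na)
    stop("CSV parse error: expected ", nf * na, " rows (", nf, " frames x ",
         na, " atoms), found ", nrow(dat))
  ord <- order(dat$frame, dat$atom)
  coords <- array(t(as.matrix(dat[ord, c("x", "y", "z")])), dim = c(3, na, nf))
  coords <- aperm(coords, c(2, 1, 3))
  top <- if (!is.null(atoms) && nrow(atoms) == na) {
    topology(name = atoms[, 2], element = atoms[, 3], resname = atoms[, 4],
             resid = as.integer(atoms[, 5]), mol = atoms[, 6])
  } else topology(name = paste0("X", seq_len(na)), element = "X")
  ens <- traj_ensemble(top, coords, dt = if (is.null(dt)) 1.0 else dt,
                       box = if (length(box) == 3) box else NULL)
  if (is.null(dt)) attr(ens, "dt_defaulted") <- TRUE
  ens
}

#' Write a trajectory to disk
#'
#' Supported formats: multi-MODEL PDB (coordinates at the format's 1e-3
#' Angstrom precision), chemistry XYZ, and the CSV trajectory dialect
#' (exact round-trip: full double precision, topology and `dt` recorded in
#' `#` header lines).
#'
#' @param ens a [traj_ensemble()] with at least one frame.
#' @param path output file.
#' @param format `"pdb"`, `"xyz"` or `"csv"`; guessed from the extension.
#' @export
write_trajectory <- function(ens, path, format = guess_format(path)) {
  stopifnot(inherits(ens, "traj_ensemble"))
  if (n_frames(ens) < 1 || n_atoms(ens) < 1)
    stop("refusing to write an empty ensemble")
  format <- match.arg(format, c("pdb", "xyz", "csv"))
  switch(format,
         pdb = write_pdb_traj(ens, path),
         xyz = write_xyz_traj(ens, path),
         csv = write_csv_traj(ens, path))
  invisible(path)
}

write_pdb_traj <- function(ens, path) {
  nf <- n_frames(ens)
  xyz <- t(apply(ens$coords, 3, function(m) as.vector(t(m))))
  if (nf == 1) xyz <- matrix(xyz, nrow = 1)
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = xyz, type = "ATOM",
                     resno = ens$top$resid, resid = ens$top$resname,
                     elety = ens$top$name, chain = substr(ens$top$mol, 1, 1),
                     elesy = ens$top$element)
    TRUE
  }, error = function(e) stop("cannot write PDB '", path, "': ",
                              conditionMessage(e)))
  invisible(ok)
}

write_xyz_traj <- function(ens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  boxstr <- if (!is.null(ens$box))
    sprintf(" box=%g,%g,%g", ens$box[1], ens$box[2], ens$box[3]) else ""
  for (f in seq_len(n_frames(ens))) {
    cat(n_atoms(ens), "\n", file = con, sep = "")
    cat(sprintf("frame=%d units=angstrom dt_ps=%g%s\n", f, ens$dt, boxstr),
        file = con)
    m <- ens$coords[, , f, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 3)
    writeLines(sprintf("%-3s %14.8f %14.8f %14.8f", ens$top$element,
                       m[, 1], m[, 2], m[, 3]), con)
  }
}

write_csv_traj <- function(ens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cat("# ctna trajectory, units angstrom\n", file = con)
  cat(sprintf("# dt_ps: %.17g\n", ens$dt), file = con)
  if (!is.null(ens$box))
    cat(sprintf("# box: %.17g %.17g %.17g\n", ens$box[1], ens$box[2],
                ens$box[3]), file = con)
  writeLines(sprintf("# atom %d %s %s %s %d %s", seq_len(n_atoms(ens)),
                     ens$top$name, ens$top$element, ens$top$resname,
                     ens$top$resid, ens$top$mol), con)
  cat("frame atom x y z\n", file = con)
  for (f in seq_len(n_frames(ens))) {
    m <- ens$coords[, , f, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 3)
    writeLines(sprintf("%d %d %.17g %.17g %.17g", f, seq_len(nrow(m)),
                       m[, 1], m[, 2], m[, 3]), con)
  }
}
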