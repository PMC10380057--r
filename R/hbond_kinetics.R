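#' Geometric hydrogen-bond criteria
#'
#' Community-standard geometric definition: donor-acceptor heavy-atom
#' distance at most `dist_cutoff` (default 3.5 Angstrom) and donor-H-
#' acceptor angle at least `angle_min` (default 150 degrees).
#'
#' @param dist_cutoff donor-acceptor distance cutoff, Angstrom.
#' @param angle_min minimum D-H-A angle, degrees in (0, 180].
#' @return An object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(dist_cutoff = 3.5, angle_min = 150) {
  stopifnot(dist_cutoff > 0, angle_min > 0, angle_min <= 180)
  structure(list(dist_cutoff = dist_cutoff, angle_min = angle_min),
            class = "hbond_criteria")
}

## Hydrogens covalently attached to each donor heavy atom: from topology
## bonds when present, else a 1.2 Angstrom distance heuristic on frame 1.
donor_hydrogens <- function(ens, donors) {
  top <- ens$top
  hyd <- which(top$element == "H")
  if (!length(hyd))
    stop("no hydrogen atoms in the topology; H-bond detection needs ",
         "explicit hydrogens (add them or fix element assignments)")
  bonds <- attr(top, "bonds")
  out <- vector("list", length(donors))
  if (!is.null(bonds)) {
    for (i in seq_along(donors)) {
      d <- donors[i]
      hb <- c(bonds[bonds[, 1] == d, 2], bonds[bonds[, 2] == d, 1])
      out[[i]] <- intersect(hb, hyd)
    }
  } else {
    co <- get_frame(ens, 1)
    D <- cross_dist(co[donors, , drop = FALSE], co[hyd, , drop = FALSE],
                    ens$box)
    for (i in seq_along(donors)) out[[i]] <- hyd[D[i, ] < 1.2]
  }
  names(out) <- as.character(donors)
  out
}

#' Detect hydrogen bonds in one frame
#'
#' A donor-H..acceptor triple is bonded when the donor-acceptor distance is
#' within the cutoff and the D-H-A angle meets the minimum. Donor-attached
#' hydrogens come from topology bonds when available, otherwise from a 1.2
#' Angstrom covalent-distance heuristic.
#'
#' @param ens a [traj_ensemble()] with explicit hydrogens.
#' @param frame frame index.
#' @param donors indices of donor heavy atoms (N/O with attached H).
#' @param acceptors indices of acceptor heavy atoms.
#' @param criteria an [hbond_criteria()].
#' @return Data frame with columns donor, hydrogen, acceptor (atom indices),
#'   distance, angle; zero rows when no bond qualifies.
#' @export
detect_hbonds <- function(ens, frame, donors, acceptors,
                          criteria = hbond_criteria()) {
  dh <- donor_hydrogens(ens, donors)
  co <- get_frame(ens, frame)
  D <- cross_dist(co[donors, , drop = FALSE], co[acceptors, , drop = FALSE],
                  ens$box)
  res <- list()
  hits <- which(D <= criteria$dist_cutoff, arr.ind = TRUE)
  for (r in seq_len(nrow(hits))) {
    d <- donors[hits[r, 1]]; a <- acceptors[hits[r, 2]]
    if (d == a) next
    for (h in dh[[as.character(d)]]) {
      ang <- point_angle(co[d, , drop = FALSE], co[h, , drop = FALSE],
                         co[a, , drop = FALSE], ens$box)
      if (ang >= criteria$angle_min)
        res[[length(res) + 1L]] <- data.frame(donor = d, hydrogen = h,
                                              acceptor = a,
                                              distance = D[hits[r, 1],
                                                           hits[r, 2]],
                                              angle = ang)
    }
  }
  if (!length(res))
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric()))
  do.call(rbind, res)
}

#' Build binary hydrogen-bond existence traces over a trajectory
#'
#' Runs [detect_hbonds()] on every frame and assembles the bond-existence
#' matrix h\[bond, frame\] in \{0, 1\}. The candidate set is every
#' donor-H-acceptor triple observed bonded in at least one frame
#' (intermittent convention: a bond that breaks and later reforms
#' contributes to the same trace).
#'
#' @inheritParams detect_hbonds
#' @param frames frames to scan (default all).
#' @return An `hbond_traces` object: list with binary matrix `h`, `dt` (ps)
#'   and a data frame `bonds` of donor/hydrogen/acceptor identities.
#' @export
hbond_traces <- function(ens, donors, acceptors,
                         criteria = hbond_criteria(),
                         frames = seq_len(n_frames(ens))) {
  per_frame <- lapply(frames, function(f) {
    b <- detect_hbonds(ens, f, donors, acceptors, criteria)
    if (nrow(b)) paste(b$donor, b$hydrogen, b$acceptor) else character(0)
  })
  ids <- unique(unlist(per_frame))
  h <- matrix(0L, length(ids), length(frames))
  for (f in seq_along(frames)) h[match(per_frame[[f]], ids), f] <- 1L
  parts <- do.call(rbind, strsplit(ids, " "))
  bonds <- if (length(ids)) {
    data.frame(donor = as.integer(parts[, 1]),
               hydrogen = as.integer(parts[, 2]),
               acceptor = as.integer(parts[, 3]))
  } else data.frame(donor = integer(), hydrogen = integer(),
                    acceptor = integer())
  new_hbond_traces(h, ens$dt, bonds)
}

#' @rdname hbond_traces
#' @param h binary bond-by-frame matrix.
#' @param dt frame interval, ps.
#' @param bonds optional bond identity data frame.
#' @export
new_hbond_traces <- function(h, dt, bonds = NULL) {
  h <- matrix(as.integer(h), nrow = nrow(h))
  stopifnot(all(h %in% c(0L, 1L)), dt > 0)
  structure(list(h = h, dt = dt, bonds = bonds), class = "hbond_traces")
}

#' @export
print.hbond_traces <- function(x, ...) {
  cat("H-bond traces: ", nrow(x$h), " bonds x ", ncol(x$h),
      " frames, dt = ", x$dt, " ps, mean occupancy ",
      format(mean(x$h), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Intermittent hydrogen-bond autocorrelation
#'
#' Multi-origin autocorrelation of the binary existence function, pooled
#' over bonds:
#' \deqn{c(t) = \frac{\sum_b \sum_{t_0} h_b(t_0) h_b(t_0+t)}
#'   {\sum_b \sum_{t_0} h_b(t_0)^2}}
#' with the sums over all origins that keep \eqn{t_0 + t} inside the trace.
#' The intermittent convention is used: recrossings (break and reform)
#' correlate. c(0) = 1 whenever any bond exists.
#'
#' @param traces an `hbond_traces` object.
#' @param max_lag maximum lag in frames (must be < trace length).
#' @return Data frame with columns `t` (ps) and `c`.
#' @export
hbond_autocorrelation <- function(traces, max_lag = ncol(traces$h) %/% 2) {
  h <- traces$h
  Tn <- ncol(h)
  if (max_lag >= Tn) stop("max_lag must be smaller than the trace length")
  if (sum(h) == 0) stop("all traces are zero; no bonds to correlate")
  cc <- numeric(max_lag + 1)
  for (lag in 0:max_lag) {
    a <- h[, 1:(Tn - lag), drop = FALSE]
    b <- h[, (1 + lag):Tn, drop = FALSE]
    cc[lag + 1] <- sum(a * b) / sum(a * a)
  }
  data.frame(t = (0:max_lag) * traces$dt, c = cc)
}

#' Fit a stretched exponential to a relaxation curve
#'
#' Least-squares fit of \eqn{c(t) = \exp(-(t/\tau)^\beta)} with bounds
#' \eqn{\tau > 0}, \eqn{\beta \in (0, 1]}. The fit window runs from t = 0
#' to the first point where c drops below `floor` (default 0.01), cutting
#' off trailing noise. Initial guess: tau at the first 1/e crossing,
#' beta = 0.8. The object also carries the gamma-function mean lifetime.
#'
#' @param ct data frame with columns `t` (ps) and `c`, e.g. from
#'   [hbond_autocorrelation()], or a numeric vector of c values with `dt`.
#' @param dt frame interval in ps (only when `ct` is a bare vector).
#' @param floor fit-window floor on c.
#' @return An object of class `stretched_exp_fit` with elements `tau`,
#'   `beta`, `mean_lifetime` (all ps except beta), `residual_norm`,
#'   `fitted`, `data`.
#' @export
fit_stretched_exponential <- function(ct, dt = NULL, floor = 0.01) {
  if (is.numeric(ct) && is.null(dim(ct))) {
    if (is.null(dt)) stop("dt is required when ct is a bare vector")
    ct <- data.frame(t = (seq_along(ct) - 1) * dt, c = ct)
  }
  stopifnot(all(c("t", "c") %in% names(ct)))
  if (abs(ct$c[1] - 1) > 0.05)
    stop("c(0) = ", format(ct$c[1]), "; expected a curve starting near 1")
  below <- which(ct$c < floor)
  end <- if (length(below)) below[1] else nrow(ct)
  dat <- ct[1:end, ]
  if (nrow(dat) < 10) stop("need at least 10 usable points to fit")
  cross <- which(dat$c < exp(-1))
  tau0 <- if (length(cross)) max(dat$t[cross[1]], dat$t[2]) else
    max(dat$t) / 2
  fit <- tryCatch(
    minpack.lm::nlsLM(c ~ exp(-(t / tau)^beta), data = dat,
                      start = list(tau = tau0, beta = 0.8),
                      lower = c(tau = 1e-9, beta = 1e-3),
                      upper = c(tau = Inf, beta = 1),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("stretched-exponential fit failed: ",
                             conditionMessage(e)))
  co <- stats::coef(fit)
  structure(list(tau = unname(co["tau"]), beta = unname(co["beta"]),
                 mean_lifetime = mean_lifetime(co["tau"], co["beta"]),
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 fitted = stats::fitted(fit), data = dat),
            class = "stretched_exp_fit")
}

#' @export
print.stretched_exp_fit <- function(x, ...) {
  cat("Stretched-exponential fit: tau = ", format(x$tau, digits = 4),
      " ps, beta = ", format(x$beta, digits = 4),
      ", mean lifetime <tau> = ", format(x$mean_lifetime, digits = 4),
      " ps\n", sep = "")
  invisible(x)
}

#' @export
coef.stretched_exp_fit <- function(object, ...) {
  c(tau = object$tau, beta = object$beta,
    mean_lifetime = object$mean_lifetime)
}

#' @export
predict.stretched_exp_fit <- function(object, t = object$data$t, ...) {
  exp(-(t / object$tau)^object$beta)
}

#' @export
plot.stretched_exp_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$c, xlab = "t [ps]", ylab = "c(t)", ...)
  tt <- seq(0, max(x$data$t), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' Mean lifetime of a stretched exponential
#'
#' Closed form of the survival integral
#' \eqn{\int_0^\infty \exp(-(t/\tau)^\beta) dt}:
#' \deqn{\langle\tau\rangle = \frac{\tau}{\beta}\,\Gamma(1/\beta)}
#'
#' @param tau relaxation time, ps (> 0).
#' @param beta stretching exponent in (0, 1].
#' @return Mean lifetime in ps.
#' @export
mean_lifetime <- function(tau, beta) {
  if (any(tau <= 0)) stop("tau must be > 0")
  if (any(beta <= 0) || any(beta > 1)) stop("beta must be in (0, 1]")
  unname(tau / beta * gamma(1 / beta))
}
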