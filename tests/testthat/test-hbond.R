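make_dha_ensemble <- function(d, angle_deg) {
  ## donor O at origin, H on the x axis, acceptor at distance d from the
  ## donor such that the D-H-A angle equals angle_deg
  top <- topology(name = c("OD", "HD", "OA"), element = c("O", "H", "O"),
                  resid = 1:3)
  co <- array(0, c(3, 3, 1))
  co[2, , 1] <- c(0.96, 0, 0)
  ## place A by the law of cosines around H
  th <- angle_deg * pi / 180
  ha <- sqrt(d^2 + 0.96^2 - 2 * d * 0.96 * cos(0))  # solve via rotation below
  ## simpler: acceptor on a ray from H making angle th with H->D direction
  hd <- c(-1, 0, 0)
  ray <- c(cos(pi - th), sin(pi - th), 0)
  ## choose |HA| so that |DA| = d
  f <- function(L) sqrt(sum((c(0.96, 0, 0) + L * ray)^2)) - d
  L <- uniroot(f, c(0.01, d + 2))$root
  co[3, , 1] <- c(0.96, 0, 0) + L * ray
  traj_ensemble(top, co)
}

test_that("geometric criterion admits linear close bonds and rejects long or bent ones", {
  ens <- make_dha_ensemble(2.8, 180)
  hb <- detect_hbonds(ens, 1, donors = 1, acceptors = 3)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.8, tolerance = 1e-9)
  expect_equal(nrow(detect_hbonds(make_dha_ensemble(4.0, 180), 1, 1, 3)), 0)
  expect_equal(nrow(detect_hbonds(make_dha_ensemble(2.8, 120), 1, 1, 3)), 0)
  ## angle right at the default threshold is admitted
  expect_equal(nrow(detect_hbonds(make_dha_ensemble(2.8, 151), 1, 1, 3)), 1)
  top_noH <- topology(name = c("OD", "OA"), element = c("O", "O"))
  ens_noH <- traj_ensemble(top_noH, array(c(0, 3, 0, 0, 0, 0), c(2, 3, 1)))
  expect_error(detect_hbonds(ens_noH, 1, 1, 2), "hydrogen")
})

test_that("autocorrelation of degenerate traces matches hand results", {
  tr1 <- new_hbond_traces(matrix(1L, 1, 50), dt = 0.5)
  ct <- hbond_autocorrelation(tr1, max_lag = 20)
  expect_true(all(ct$c == 1))
  tr2 <- new_hbond_traces(matrix(c(1L, rep(0L, 29)), 1, 30), dt = 1)
  ct2 <- hbond_autocorrelation(tr2, max_lag = 10)
  expect_equal(ct2$c, c(1, rep(0, 10)))
  expect_error(hbond_autocorrelation(new_hbond_traces(matrix(0L, 2, 30),
                                                      dt = 1)),
               "no bonds")
  expect_error(hbond_autocorrelation(tr1, max_lag = 50), "max_lag")
})

test_that("estimated c(t) matches the analytic telegraph persistence curve", {
  tau_on <- 10; tau_off <- 40
  tr <- generate_hbond_traces(n_bonds = 400, n_frames = 4000, dt = 0.5,
                              beta = 1, tau = tau_on, off_scale = tau_off,
                              seed = 51)
  ct <- hbond_autocorrelation(tr, max_lag = 200)
  expected <- telegraph_c(ct$t, tau_on, tau_off)
  expect_lt(max(abs(ct$c - expected)), 0.02)
  ## c stays in [0, 1] and c(0) = 1
  expect_equal(ct$c[1], 1)
  expect_true(all(ct$c >= 0 & ct$c <= 1))
})

test_that("stretched-exponential fits recover generating parameters", {
  t <- seq(0, 200, by = 0.5)
  fit <- fit_stretched_exponential(data.frame(t = t, c = exp(-(t / 10)^0.5)))
  expect_equal(fit$tau, 10, tolerance = 0.01)
  expect_equal(fit$beta, 0.5, tolerance = 0.01)
  fit1 <- fit_stretched_exponential(data.frame(t = t, c = exp(-t / 16)))
  expect_gte(fit1$beta, 0.99)
  expect_equal(fit1$tau, 16, tolerance = 0.01)
  ## Gaussian noise sigma = 0.01: parameters within 5%
  set.seed(52)
  noisy <- exp(-(t / 10)^0.5) + rnorm(length(t), 0, 0.01)
  noisy[1] <- 1
  fit2 <- fit_stretched_exponential(data.frame(t = t, c = noisy))
  expect_equal(fit2$tau, 10, tolerance = 0.05)
  expect_equal(fit2$beta, 0.5, tolerance = 0.05)
})

test_that("renewal traces with exponential on-times fit as a pure exponential", {
  tr <- generate_hbond_traces(n_bonds = 300, n_frames = 3000, dt = 0.5,
                              beta = 1, tau = 10, off_scale = 400, seed = 53)
  fit <- fit_stretched_exponential(hbond_autocorrelation(tr, max_lag = 300))
  expect_gt(fit$beta, 0.9)
  expect_equal(fit$tau, 10, tolerance = 0.15)
})

test_that("fitted beta increases with the generating Weibull shape", {
  betas <- c(0.5, 0.7, 1.0)
  fitted <- vapply(betas, function(b) {
    tr <- generate_hbond_traces(n_bonds = 200, n_frames = 2000, dt = 0.5,
                                beta = b, tau = 10, off_scale = 400,
                                seed = 54)
    fit_stretched_exponential(hbond_autocorrelation(tr, max_lag = 400))$beta
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
})

test_that("mean lifetime follows the gamma closed form and its limits", {
  expect_equal(mean_lifetime(10, 1), 10)
  expect_equal(mean_lifetime(10, 0.5), 20)     # gamma(2) = 1
  ## continuity at beta -> 1
  expect_equal(mean_lifetime(7, 1 - 1e-6), 7, tolerance = 1e-4)
  expect_error(mean_lifetime(-1, 0.5), "tau")
  expect_error(mean_lifetime(1, 1.2), "beta")
})

test_that("gamma mean lifetime equals quadrature of the survival integral", {
  for (p in list(c(10, 0.5), c(16, 0.555), c(3, 0.9), c(25, 1))) {
    tau <- p[1]; beta <- p[2]
    quad <- integrate(function(u) exp(-(u / tau)^beta), 0, Inf,
                      rel.tol = 1e-10)$value
    expect_equal(mean_lifetime(tau, beta), quad, tolerance = 1e-6)
  }
})

test_that("lifetime inversion round-trips a liquid-water-like parameter pair", {
  beta <- 0.555; target <- 16.45
  tau <- uniroot(function(tt) mean_lifetime(tt, beta) - target,
                 c(0.1, 100), tol = 1e-12)$root
  expect_equal(mean_lifetime(tau, beta), target, tolerance = 1e-9)
  expect_true(tau > 0 && tau < target)   # beta < 1 stretches the mean up
})
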