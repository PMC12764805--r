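test_that("model builder produces the documented matrices", {
  rw <- ss_model("rw", dt = 120, sigma = 0.01, tau = 0.5)
  expect_equal(rw$F, diag(2))
  expect_equal(rw$G, diag(2))
  expect_equal(rw$H, diag(2))
  expect_equal(rw$Q, diag(0.01^2, 2))
  expect_equal(rw$R, diag(0.25, 2))

  uv <- ss_model("uv", dt = 120)
  expect_equal(uv$F[1, 3], 120)
  expect_equal(uv$F[2, 4], 120)
  expect_equal(uv$F[cbind(1:4, 1:4)], rep(1, 4))
  expect_equal(uv$H, cbind(diag(2), matrix(0, 2, 2)))

  expect_error(ss_model("rw", dt = 0), "dt")
  expect_error(ss_model("rw", V0 = matrix(c(1, 2, 3, 4), 2)), "V0")
})

test_that("filter reduces to exact observation as tau -> 0", {
  y <- sim_rw_obs(50, sigma = 0.05, tau = 0, seed = 2)
  m <- ss_model("rw", sigma = 0.05, tau = 1e-9)
  kf <- kalman_filter(m, y)
  expect_equal(kf$xf, unname(y), tolerance = 1e-6)
})

test_that("sigma = 0 with diffuse prior recovers the running mean", {
  set.seed(4)
  y <- cbind(rnorm(30), rnorm(30))
  m <- ss_model("rw", sigma = 0, tau = 1, x0 = c(0, 0),
                V0 = diag(1e8, 2))
  kf <- kalman_filter(m, y)
  run_mean <- apply(y, 2, function(v) cumsum(v) / seq_along(v))
  # agreement is limited by the finite diffuse prior in double precision
  expect_lt(max(abs(kf$xf - run_mean)), 1e-7)
})

test_that("filter and smoother match the batch joint-Gaussian solve", {
  for (kind in c("rw", "uv")) {
    sigma <- 0.3; tau <- 0.8
    set.seed(17)
    y <- sim_rw_obs(20, sigma = 1, tau = 0.5, seed = 17)
    flag <- rep(TRUE, 20)
    flag[c(7, 8, 13)] <- FALSE  # gaps
    yna <- y; yna[!flag, ] <- NA
    m <- ss_model(kind, dt = 2, sigma = sigma, tau = tau,
                  x0 = c(y[1, ], 0, 0)[1:(if (kind == "rw") 2 else 4)],
                  V0 = diag(25, if (kind == "rw") 2 else 4))
    kf <- kalman_smooth(kalman_filter(m, yna))
    oracle <- batch_lgss(m$F, m$G, m$H, m$Q, m$R, m$x0, m$V0, y, flag)
    expect_equal(kf$xs, unname(oracle$mean), tolerance = 1e-8)
    for (t in c(1, 5, 10, 20))
      expect_equal(kf$Vs[, , t], oracle$cov[[t]], tolerance = 1e-8)
    # filtered state at T equals smoothed at T (boundary condition)
    expect_equal(kf$xs[20, ], kf$xf[20, ], tolerance = 1e-12)
    # filtered state mid-series equals a batch solve on truncated data
    or10 <- batch_lgss(m$F, m$G, m$H, m$Q, m$R, m$x0, m$V0,
                       y[1:10, , drop = FALSE], flag[1:10])
    expect_equal(kf$xf[10, ], unname(or10$mean[10, ]), tolerance = 1e-8)
  }
})

test_that("smoothing never increases posterior uncertainty", {
  y <- sim_rw_obs(200, sigma = 0.1, tau = 0.5, seed = 5)
  m <- ss_model("rw", sigma = 0.1, tau = 0.5)
  kf <- kalman_smooth(kalman_filter(m, y))
  tr_f <- apply(kf$Vf, 3, function(v) sum(diag(v)))
  tr_s <- apply(kf$Vs, 3, function(v) sum(diag(v)))
  expect_true(all(tr_s <= tr_f + 1e-12))
})

test_that("likelihood matches closed forms and is translation invariant", {
  set.seed(9)
  T_ <- 40
  y <- cbind(3 + rnorm(T_, 0, 0.7), -2 + rnorm(T_, 0, 0.7))
  tau <- 0.7
  # sigma = 0, V0 = 0: predictions pinned at x0, iid Gaussian likelihood
  x0 <- c(3, -2)
  nll <- ss_nll(c(0, tau), y, x0 = x0, V0 = diag(0, 2))
  closed <- -sum(dnorm(y[, 1], x0[1], tau, log = TRUE)) -
    sum(dnorm(y[, 2], x0[2], tau, log = TRUE))
  expect_equal(nll, closed, tolerance = 1e-8)

  # translation invariance
  shift <- 57.3
  nll_shift <- ss_nll(c(0, tau), y + shift, x0 = x0 + shift,
                      V0 = diag(0, 2))
  expect_equal(nll, nll_shift, tolerance = 1e-8)

  # doubling tau on zero-residual data adds N log 2 per axis
  y0 <- matrix(rep(x0, each = T_), T_)
  n1 <- ss_nll(c(0, tau), y0, x0 = x0, V0 = diag(0, 2))
  n2 <- ss_nll(c(0, 2 * tau), y0, x0 = x0, V0 = diag(0, 2))
  expect_equal(n2 - n1, 2 * T_ * log(2), tolerance = 1e-8)

  expect_error(
    kalman_filter(ss_model("rw"), matrix(NA_real_, 5, 2)), "gap")
})

test_that("noise fitting enforces its precondition and recovers a sync tag", {
  expect_error(fit_noise(sim_rw_obs(5, 0.1, 0.5)), "10 observed steps")

  y <- sim_rw_obs(5000, sigma = 0, tau = 0.5, seed = 21)
  est <- fit_noise(y)
  expect_lt(est$sigma, 1e-3)
  expect_gt(est$tau, 0.45)
  expect_lt(est$tau, 0.55)
  expect_equal(est$convergence, 0)
})

test_that("gaps do not alter estimates before the first affected prediction", {
  y <- sim_rw_obs(100, sigma = 0.2, tau = 0.5, seed = 8)
  m <- ss_model("rw", sigma = 0.2, tau = 0.5)
  kf_full <- kalman_filter(m, y)
  y_gap <- y
  y_gap[60:65, ] <- NA
  kf_gap <- kalman_filter(m, y_gap)
  expect_equal(kf_gap$xf[1:59, ], kf_full$xf[1:59, ], tolerance = 1e-14)
  # during the gap, filtered equals predicted
  expect_equal(kf_gap$xf[60:65, ], kf_gap$xp[60:65, ], tolerance = 1e-14)
})

test_that("track_ssm methods are coherent", {
  y <- sim_rw_obs(800, sigma = 0.05, tau = 0.5, seed = 12)
  fit <- track_ssm(y, model = "rw", dt = 120)
  expect_s3_class(fit, "track_ssm")
  expect_named(coef(fit), c("sigma", "tau"))
  expect_equal(attr(logLik(fit), "df"), 2L)
  tr <- fitted(fit)
  expect_equal(nrow(tr), 800)
  expect_true(all(is.finite(tr$x)))
  r <- residuals(fit)
  expect_equal(dim(r), c(800, 2))
  pr <- predict(fit, n_ahead = 3)
  expect_equal(nrow(pr), 3)
  expect_true(all(diff(pr$Vxx) > 0))  # forecast variance grows
  s1 <- simulate(fit, seed = 1)
  s2 <- simulate(fit, seed = 1)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(800, 2))
  # fixed-parameter fit skips estimation
  fit2 <- track_ssm(y, model = "rw", dt = 120, sigma = 0.05, tau = 0.5)
  expect_null(fit2$noise)
  expect_equal(attr(logLik(fit2), "df"), 0L)
})

test_that("displacement series handles degenerate motions exactly", {
  # stationary, no noise: all displacements zero
  tr <- data.frame(time_s = seq(0, 20 * 3600, by = 3600), x = 5, y = 5)
  d <- displacement_series(tr, "hourly")
  expect_true(all(d$dt1_m == 0))

  # straight-line 0.1 m/h on the hourly grid
  tr2 <- data.frame(time_s = seq(0, 20 * 3600, by = 3600),
                    x = 0.1 * (0:20), y = 0)
  d2 <- displacement_series(tr2, "hourly")
  expect_equal(d2$dt1_m, rep(0.1, 20), tolerance = 1e-12)

  # intervals adjacent to unobserved ticks are flagged
  flags <- rep(TRUE, 21); flags[5] <- FALSE
  d3 <- displacement_series(tr2, "hourly", obs_flag = flags)
  expect_true(all(d3$flagged[4:5]))
  expect_false(any(d3$flagged[-(4:5)]))
})
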