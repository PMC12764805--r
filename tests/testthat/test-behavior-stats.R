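test_that("parallelism F test matches its definition and the GLM oracle", {
  set.seed(7)
  a <- data.frame(x = log2(c(1, 2, 4, 8)))
  a$y <- -1.2 * a$x + rnorm(4, 0, 0.05)
  b <- data.frame(x = log2(c(1, 2, 4, 8)))
  b$y <- -1.7 * b$x + 0.4 + rnorm(4, 0, 0.05)

  res <- parallelism_f_test(a, b)
  # two 4-point groups: df = (1, 4)
  expect_equal(res$df, c(1L, 4L))
  expect_gte(res$F, 0)
  orc <- interaction_f(a, b)
  expect_equal(res$F, unname(orc["F"]), tolerance = 1e-8)
  expect_equal(res$p, unname(orc["p"]), tolerance = 1e-8)

  # larger noisy fixture
  set.seed(11)
  g1 <- data.frame(x = runif(15), y = NA)
  g1$y <- 2 + 0.5 * g1$x + rnorm(15, 0, 0.3)
  g2 <- data.frame(x = runif(12), y = NA)
  g2$y <- 1 - 0.8 * g2$x + rnorm(12, 0, 0.3)
  res2 <- parallelism_f_test(g1, g2)
  orc2 <- interaction_f(g1, g2)
  expect_equal(res2$F, unname(orc2["F"]), tolerance = 1e-8)
  expect_equal(res2$df, c(1L, 27 - 4L))

  # identical groups: S1 = S2, F = 0, p = 1
  same <- parallelism_f_test(g1, g1)
  expect_lt(same$F, 1e-6)
  expect_gt(same$p, 1 - 1e-3)

  # perfect separate fits: degenerate flag, p reported as 0
  pa <- data.frame(x = 1:4, y = 1:4)
  pb <- data.frame(x = 1:4, y = 2 * (1:4))
  deg <- parallelism_f_test(pa, pb)
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)

  expect_error(parallelism_f_test(pa[1:2, ], pb), ">= 3")
  expect_error(parallelism_f_test(data.frame(x = c(1, 1, 1), y = 1:3), pb),
               "constant x")
})

test_that("rank-sum wrapper agrees with enumeration and handles ties", {
  r <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_lt(r$p, 0.15)
  p_exact <- brute_rank_sum_p(c(1, 2, 3), c(10, 11, 12))
  expect_equal(p_exact, 0.1)
  expect_lt(abs(r$p - p_exact), 0.05)

  set.seed(2)
  a <- rnorm(40); b <- rnorm(40)
  expect_gt(rank_sum_test(a, a)$p, 0.99)

  tied <- rank_sum_test(rep(1, 5), rep(1, 7))
  expect_true(tied$all_tied)
  expect_equal(tied$p, 1)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("VIF reports independence, duplication and orthogonality", {
  set.seed(5)
  X <- data.frame(t = rnorm(1000), b = rbinom(1000, 1, 0.3),
                  d = rbinom(1000, 1, 0.5))
  v <- vif(X)
  expect_true(all(v < 1.1))

  dup <- cbind(X, t2 = X$t)
  expect_true(is.infinite(vif(dup)["t"]))

  expect_error(vif(X[, 1, drop = FALSE]), "single covariate")
  expect_error(vif(data.frame(a = rnorm(10), b = 1)), "constant")

  # exactly orthogonal design columns have VIF 1
  Xo <- data.frame(a = rep(c(-1, 1), 50), b = rep(c(-1, -1, 1, 1), 25))
  expect_equal(unname(vif(Xo)), c(1, 1), tolerance = 1e-12)
})

test_that("displacement table applies the strict 2-m boulder rule", {
  ctr <- rbind(c(10, 0))
  disp <- data.frame(time_s = 3600 * (1:4),
                     x0 = c(8.1, 8.0, 10, 30), y0 = 0,
                     dt1_m = c(0.1, 0.2, 0.3, 0.4),
                     flagged = c(FALSE, FALSE, FALSE, TRUE))
  cov <- data.frame(time_s = 3600 * (0:5), temp_c = 16.4, boulder = 0L,
                    day = 1L)
  tab <- build_displacement_table(disp, cov, boulders = ctr,
                                  individual = "C9", season = "resting")
  # 1.9 m from the centroid counts as inside, exactly 2.0 m does not
  expect_equal(tab$boulder, c(1L, 0L, 1L))
  # gap-adjacent row dropped and tallied
  expect_equal(nrow(tab), 3L)
  expect_equal(attr(tab, "tallies")$gap_adjacent_dropped, 1L)

  bad_cov <- data.frame(time_s = 3600 * (0:5) + 1, temp_c = 1,
                        boulder = 0L, day = 0L)
  expect_error(build_displacement_table(disp, bad_cov), "misaligned")
})

test_that("gamma IRLS matches closed forms and the reference GLM", {
  set.seed(31)
  n <- 400
  # intercept-only: beta0 = log(mean(y))
  y <- rgamma(n, shape = 2, rate = 2 / 0.4)
  t0 <- data.frame(dt1_m = y, temp_c = 0, boulder = 0L, day = 0L)
  f0 <- fit_gamma_glm(t0, dt1_m ~ 1)
  expect_equal(unname(coef(f0)), log(mean(y)), tolerance = 1e-10)

  # full fixture vs stats::glm
  tab <- data.frame(temp_c = rnorm(n, 7.6, 2),
                    boulder = rbinom(n, 1, 0.4),
                    day = rbinom(n, 1, 0.5))
  mu <- exp(-1.5 + 0.12 * tab$temp_c - 0.15 * tab$boulder - 0.05 * tab$day)
  tab$dt1_m <- rgamma(n, shape = 2, rate = 2 / mu)
  fit <- fit_gamma_glm(tab)
  ref <- glm(dt1_m ~ temp_c + boulder + day, data = tab,
             family = Gamma(link = "log"),
             control = glm.control(epsilon = 1e-12))
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  sref <- summary(ref)
  expect_equal(unname(fit$coefficients[, 2]),
               unname(sref$coefficients[, 2]), tolerance = 1e-4)
  expect_equal(fit$dispersion, sref$dispersion, tolerance = 1e-6)

  # deviance is non-increasing over IRLS iterations, fitted means positive
  expect_true(all(diff(fit$deviance_trace) <= 1e-8))
  expect_true(all(fit$fitted > 0))

  # zero responses are replaced and tallied
  tabz <- tab
  tabz$dt1_m[1:3] <- 0
  fz <- fit_gamma_glm(tabz)
  expect_equal(fz$zero_replaced, 3L)

  expect_error(fit_gamma_glm(tab[1:30, ]), "n >")
})

test_that("season comparison reports direction and omits empty strata", {
  mk_tab <- function(id, season, mu, n = 200, pb = 0.5, seed = 1) {
    set.seed(seed)
    structure(data.frame(individual = id, time_s = 3600 * seq_len(n),
                         dt1_m = rgamma(n, 2, 2 / mu), temp_c = 10,
                         boulder = rbinom(n, 1, pb), day = 1L,
                         season = season),
              class = c("displacement_table", "data.frame"))
  }
  tabs <- list(mk_tab("C1", "resting", 0.05, seed = 1),
               mk_tab("D1", "growing", 0.3, seed = 2))
  rep <- season_comparison_report(tabs)
  bys <- rep$by_season
  expect_gt(bys$mean[bys$season == "growing"],
            bys$mean[bys$season == "resting"])
  expect_lt(rep$season_test$p, 0.001)

  # identical groups: non-significant
  tabs2 <- list(mk_tab("A", "resting", 0.1, seed = 3),
                mk_tab("B", "growing", 0.1, seed = 3))
  expect_gt(season_comparison_report(tabs2)$season_test$p, 0.2)

  # an individual never off the boulders is omitted from that table
  tabs3 <- list(mk_tab("A", "resting", 0.1, pb = 1, seed = 4),
                mk_tab("B", "growing", 0.1, seed = 5))
  rep3 <- season_comparison_report(tabs3)
  expect_equal(rep3$omitted_strata, 1L)
  expect_error(season_comparison_report(tabs[1]), ">= 2")
})
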