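test_that("Wald ratio arithmetic and error handling", {
  w <- mr_wald_ratio(0.25, 0.02, 0.5, 0.1)
  expect_equal(w$beta, 2.0)
  expect_equal(w$se, 0.4)
  expect_equal(mr_wald_ratio(0.25, 0.02, 0, 0.1)$beta, 0)
  expect_equal(mr_wald_ratio(-0.25, 0.02, 0.5, 0.1)$beta, -2.0)
  expect_error(mr_wald_ratio(0, 0.02, 0.5, 0.1), "nonzero")
})

test_that("IVW matches hand arithmetic and degenerates to the Wald ratio", {
  hs1 <- make_hs(0.25, 0.02, 0.5, 0.1)
  expect_equal(mr_ivw(hs1)$beta, mr_wald_ratio(0.25, 0.02, 0.5, 0.1)$beta)

  hs2 <- make_hs(c(1, 1), c(0.01, 0.01), c(1, 3), c(1, 1))
  fit_f <- mr_ivw(hs2, model = "fixed")
  expect_equal(fit_f$beta, 2.0)
  expect_equal(fit_f$se, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(fit_f$q_stat, 2)
  # multiplicative random effects inflates by sqrt(Q/(k-1)) = sqrt(2)
  fit_r <- mr_ivw(hs2)
  expect_equal(fit_r$se, 1, tolerance = 1e-12)

  # homogeneous ratios: Q = 0 and random = fixed
  hs3 <- make_hs(c(0.1, 0.2, 0.4), rep(0.01, 3), c(0.15, 0.3, 0.6),
                 rep(0.02, 3))
  fr <- mr_ivw(hs3)
  expect_equal(fr$beta, 1.5, tolerance = 1e-10)
  expect_equal(fr$q_stat, 0, tolerance = 1e-18)
  expect_equal(fr$se, mr_ivw(hs3, model = "fixed")$se)

  hs_bad <- make_hs(c(0.1, 1e-300), c(0.01, 0.01), c(0.1, 0.1), c(0.02, 0.02))
  hs_bad$snps$beta_x[2] <- 0
  expect_error(mr_ivw(hs_bad), "rs002")
})

test_that("IVW equals zero-intercept weighted least squares", {
  set.seed(5)
  for (rep in 1:5) {
    k <- sample(3:20, 1)
    hs <- make_hs(runif(k, 0.05, 0.3), runif(k, 0.005, 0.02),
                  rnorm(k, 0.05, 0.05), runif(k, 0.01, 0.05))
    s <- hs$snps
    oracle <- coef(lm(beta_y ~ 0 + beta_x, data = s, weights = 1 / s$se_y^2))
    expect_equal(mr_ivw(hs)$beta, unname(oracle), tolerance = 1e-10)
  }
})

test_that("Egger recovers an exact line and equals weighted least squares", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  hs <- make_hs(bx, rep(0.01, 4), 2 + 1 * bx, c(0.02, 0.03, 0.02, 0.04))
  fit <- mr_egger(hs)
  expect_equal(fit$beta, 1, tolerance = 1e-10)
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_equal(fit$q_stat, 0, tolerance = 1e-16)

  set.seed(9)
  hs2 <- make_hs(runif(6, 0.05, 0.3), runif(6, 0.005, 0.02),
                 rnorm(6, 0.1, 0.1), runif(6, 0.01, 0.05))
  s <- hs2$snps
  oracle <- coef(lm(beta_y ~ beta_x, data = s, weights = 1 / s$se_y^2))
  fit2 <- mr_egger(hs2)
  expect_equal(fit2$intercept, unname(oracle[1]), tolerance = 1e-10)
  expect_equal(fit2$beta, unname(oracle[2]), tolerance = 1e-10)

  expect_error(mr_egger(make_hs(c(0.1, 0.2), c(0.01, 0.01),
                                c(0.1, 0.2), c(0.02, 0.02))),
               "at least 3")
})

test_that("Egger slope is invariant to re-orienting any variant", {
  set.seed(21)
  hs <- make_hs(runif(6, 0.05, 0.3), runif(6, 0.005, 0.02),
                rnorm(6, 0.1, 0.1), runif(6, 0.01, 0.05))
  hs_flip <- hs
  hs_flip$snps$beta_x[3] <- -hs_flip$snps$beta_x[3]
  hs_flip$snps$beta_y[3] <- -hs_flip$snps$beta_y[3]
  expect_equal(mr_egger(hs_flip)$beta, mr_egger(hs)$beta, tolerance = 1e-12)
})

test_that("Egger intercept is well calibrated under InSIDE-null pleiotropy", {
  set.seed(42)
  hits <- 0L
  for (r in 1:500) {
    k <- 20L
    bx <- runif(k, 0.1, 0.4)
    sey <- runif(k, 0.02, 0.05)
    by <- 0.3 * bx + rnorm(k, 0, 0.03) + rnorm(k, 0, sey)  # balanced pleiotropy
    hs <- make_hs(bx, rep(0.01, k), by, sey)
    fit <- mr_egger(hs)
    if (abs(fit$intercept) < 3 * fit$intercept_se) hits <- hits + 1L
  }
  expect_gte(hits / 500, 0.95)
})

test_that("weighted median interpolates the cumulative weight midpoints", {
  # equal weights, odd k: the middle ratio
  hs <- make_hs(c(1, 1, 1), rep(0.01, 3), c(1, 2, 9), rep(1, 3))
  expect_equal(mr_weighted_median(hs, n_boot = 100, seed = 1)$beta, 2.0)

  # dominant weight pulls the estimate to its ratio:
  # sorted ratios {1,2,5} with weights {.01,.01,.98}:
  # midpoints {.005,.015,.51}; interpolation at 0.5 gives 2 + 3*0.485/0.495
  w <- c(0.98, 0.01, 0.01)
  bx <- sqrt(w)              # se_y = 1 so weights bx^2
  hs2 <- make_hs(bx, rep(0.01, 3), bx * c(5, 1, 2), rep(1, 3))
  expect_equal(mr_weighted_median(hs2, n_boot = 100, seed = 1)$beta,
               2 + 3 * 0.485 / 0.495, tolerance = 1e-10)

  # identical ratios are returned regardless of weights
  hs3 <- make_hs(c(0.5, 1, 2), rep(0.01, 3), 3 * c(0.5, 1, 2), rep(1, 3))
  expect_equal(mr_weighted_median(hs3, n_boot = 100, seed = 1)$beta, 3)
})

test_that("weighted median with equal weights equals the sample median", {
  set.seed(7)
  for (k in c(5, 9, 13)) {
    ratios <- rnorm(k, 1, 0.5)
    hs <- make_hs(rep(1, k), rep(0.01, k), ratios, rep(1, k))
    expect_equal(mr_weighted_median(hs, n_boot = 100, seed = 2)$beta,
                 median(ratios), tolerance = 1e-10)
  }
})

test_that("mode estimators find the dominant ratio cluster", {
  bx <- rep(1, 4)
  hs <- make_hs(bx, rep(0.01, 4), c(1.0, 1.01, 0.99, 5.0), rep(1, 4))
  fit <- mr_mode(hs, "simple", n_boot = 100, seed = 3)
  # independent dense-grid KDE oracle
  ratios <- c(1.0, 1.01, 0.99, 5.0)
  spread <- min(sd(ratios), IQR(ratios) / 1.349)
  h <- 0.9 * spread * length(ratios)^(-1 / 5)
  grid <- seq(min(ratios) - h, max(ratios) + h, length.out = 20001)
  dens <- sapply(grid, function(g) sum(dnorm((g - ratios) / h)) / h)
  oracle <- grid[which.max(dens)]
  expect_equal(fit$beta, oracle, tolerance = 0.02)
  expect_lt(abs(fit$beta - 1.0), 0.05)

  # identical ratios: the common value
  hs2 <- make_hs(c(0.5, 1, 2), rep(0.01, 3), 2 * c(0.5, 1, 2), rep(1, 3))
  expect_equal(mr_mode(hs2, "simple", n_boot = 100, seed = 3)$beta, 2)

  # a 10x-weight outlier pulls the weighted mode but not the simple mode
  bx3 <- c(1, 1, 1, sqrt(10))
  hs3 <- make_hs(bx3, rep(0.01, 4), bx3 * c(0.95, 1.0, 1.05, 3), rep(1, 4))
  simple <- mr_mode(hs3, "simple", n_boot = 100, seed = 4)$beta
  weighted <- mr_mode(hs3, "weighted", n_boot = 100, seed = 4)$beta
  expect_gt(weighted, simple)
})

test_that("bootstrap SEs are reproducible under a fixed seed", {
  set.seed(31)
  hs <- make_hs(runif(5, 0.1, 0.3), runif(5, 0.005, 0.02),
                rnorm(5, 0.1, 0.05), runif(5, 0.01, 0.05))
  a <- mr_weighted_median(hs, n_boot = 200, seed = 99)
  b <- mr_weighted_median(hs, n_boot = 200, seed = 99)
  expect_identical(a$se, b$se)
  m1 <- mr_mode(hs, "weighted", n_boot = 200, seed = 99)
  m2 <- mr_mode(hs, "weighted", n_boot = 200, seed = 99)
  expect_identical(m1$se, m2$se)
  expect_error(mr_weighted_median(hs, n_boot = 1, seed = 1), "at least 2")
  expect_warning(mr_weighted_median(hs, n_boot = 50, seed = 1), "n_boot")
})

test_that("all estimators are scale equivariant in the outcome", {
  set.seed(13)
  hs <- make_hs(runif(7, 0.1, 0.4), runif(7, 0.005, 0.02),
                rnorm(7, 0.2, 0.1), runif(7, 0.02, 0.06))
  cc <- 3
  hs_c <- hs
  hs_c$snps$beta_y <- cc * hs$snps$beta_y
  hs_c$snps$se_y <- cc * hs$snps$se_y
  for (fit_pair in list(
    list(mr_ivw(hs), mr_ivw(hs_c)),
    list(mr_egger(hs), mr_egger(hs_c)),
    list(mr_weighted_median(hs, 200, seed = 8),
         mr_weighted_median(hs_c, 200, seed = 8)),
    list(mr_mode(hs, "weighted", n_boot = 200, seed = 8),
         mr_mode(hs_c, "weighted", n_boot = 200, seed = 8)))) {
    expect_equal(fit_pair[[2]]$beta, cc * fit_pair[[1]]$beta,
                 tolerance = 1e-10)
    expect_equal(fit_pair[[2]]$se, cc * fit_pair[[1]]$se, tolerance = 1e-10)
  }
})

test_that("estimate objects expose coef, confint and the CI invariant", {
  hs <- make_hs(c(1, 1), c(0.01, 0.01), c(1, 3), c(1, 1))
  fit <- mr_ivw(hs)
  expect_equal(unname(coef(fit)), fit$beta)
  expect_equal(fit$ci_low, fit$beta - 1.96 * fit$se)
  expect_equal(fit$ci_high, fit$beta + 1.96 * fit$se)
  expect_equal(unname(confint(fit)[1, ]), c(fit$ci_low, fit$ci_high))
  df <- mr_all(make_hs(runif(4, 0.1, 0.3), rep(0.01, 4),
                       runif(4, 0.1, 0.3), rep(0.02, 4)),
               n_boot = 100, seed = 2)
  expect_equal(df$method,
               c("IVW", "MR-Egger", "Weighted median", "Weighted mode",
                 "Simple mode"))
  expect_true(all(df$ci_low <= df$beta & df$beta <= df$ci_high))
})
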