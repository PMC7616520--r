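make_panel <- function(ids, visits, coffee, tea, bmi = NULL) {
  d <- data.frame(individual_id = ids, visit = visits, coffee_cups = coffee,
                  tea_cups = tea)
  if (!is.null(bmi)) d$bmi <- bmi
  d
}

test_that("the consumption index is the re-standardized sum of beverage z-scores", {
  # proportional beverage patterns at one visit: index is the common z-score
  p <- make_panel(1:3, 1, c(0, 2, 4), c(0, 1, 2))
  out <- build_exposure_index(p)
  expect_equal(out$exposure_index, c(-1, 0, 1))

  # hand-computed non-proportional case: z(coffee) + z(tea), re-standardized
  p2 <- make_panel(1:3, 1, c(0, 2, 4), c(5, 1, 3))
  zc <- scale(c(0, 2, 4))[, 1]
  zt <- scale(c(5, 1, 3))[, 1]
  comb <- zc + zt
  expect_equal(build_exposure_index(p2)$exposure_index,
               (comb - mean(comb)) / sd(comb))

  # zero variance in a beverage names the visit
  p3 <- make_panel(1:3, 2, c(1, 2, 3), c(2, 2, 2))
  expect_error(build_exposure_index(p3), "tea_cups at visit 2")
})

test_that("the index is invariant to affine rescaling of raw cups", {
  set.seed(2)
  p <- make_panel(rep(1:20, 2), rep(1:2, each = 20),
                  rnorm(40, 2), rnorm(40, 3))
  a <- build_exposure_index(p)$exposure_index
  p$coffee_cups <- 10 * p$coffee_cups + 3
  p$tea_cups <- -2 * p$tea_cups + 1  # decreasing transform flips the z sign
  p$tea_cups <- -p$tea_cups          # restore orientation: net scale by 2
  b <- build_exposure_index(p)$exposure_index
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("rows missing one beverage fall back to the other", {
  p <- make_panel(1:4, 1, c(0, 1, 2, 3), c(4, NA, 2, 1))
  expect_message(out <- build_exposure_index(p), "single beverage")
  expect_false(anyNA(out$exposure_index))
})

test_that("TWFE recovers an exact two-way model and matches dummy-variable OLS", {
  # balanced 2x2 panel generated exactly as beta*x + alpha_i + gamma_t
  p <- expand.grid(individual_id = 1:2, visit = 1:2)
  p$exposure_index <- c(0.5, -0.5, -0.2, 0.9)
  p$bmi <- 2 * p$exposure_index + c(1, -1)[p$individual_id] +
    c(0.3, -0.3)[p$visit]
  fit <- twfe(p)
  expect_equal(fit$beta, 2, tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-10)

  # 5 individuals x 3 visits, unbalanced: LSDV oracle
  set.seed(8)
  p2 <- expand.grid(individual_id = 1:5, visit = 1:3)
  p2 <- p2[-c(3, 11), ]  # drop two visits
  p2$exposure_index <- rnorm(nrow(p2))
  p2$bmi <- -0.4 * p2$exposure_index + rnorm(5, 0, 1)[p2$individual_id] +
    c(0, 0.5, -0.5)[p2$visit] + rnorm(nrow(p2), 0, 0.3)
  fit2 <- twfe(p2)
  lsdv <- lm(bmi ~ exposure_index + factor(individual_id) + factor(visit),
             data = p2)
  expect_equal(fit2$beta, unname(coef(lsdv)["exposure_index"]),
               tolerance = 1e-8)
})

test_that("the within transformation is idempotent and shift invariant", {
  set.seed(15)
  p <- expand.grid(individual_id = 1:10, visit = 1:4)
  p$exposure_index <- rnorm(nrow(p))
  p$bmi <- 0.3 * p$exposure_index + rnorm(nrow(p))
  fit <- twfe(p)

  # demeaning an already demeaned panel changes nothing
  dm <- targetmr:::.two_way_demean(p$exposure_index, p$bmi,
                                   factor(p$individual_id), factor(p$visit))
  dm2 <- targetmr:::.two_way_demean(dm$x, dm$y, factor(p$individual_id),
                                    factor(p$visit))
  expect_equal(dm2$x, dm$x, tolerance = 1e-12)
  expect_equal(dm2$beta, dm$beta, tolerance = 1e-12)

  # adding any per-individual or per-visit constants to the outcome
  p2 <- p
  p2$bmi <- p2$bmi + runif(10)[p2$individual_id] * 5 +
    runif(4)[p2$visit] * 3
  expect_equal(twfe(p2)$beta, fit$beta, tolerance = 1e-8)
})

test_that("degenerate two-way variance collapses to the one-way clustered variance", {
  set.seed(16)
  n <- 60
  x <- rnorm(n)
  u <- rnorm(n)
  cl1 <- factor(rep(1:6, each = 10))
  singleton <- factor(seq_len(n))  # second dimension fully degenerate
  v1 <- targetmr:::.cluster_vcov_1w(x, u, cl1, k = 2)
  v2w <- targetmr:::.cluster_vcov_2w(x, u, cl1, singleton, k = 2)
  # the singleton-cluster component equals the intersection component, so
  # inclusion-exclusion returns exactly the first one-way variance
  expect_equal(v2w$v, v1, tolerance = 1e-12)
})

test_that("panel shape is validated", {
  p <- expand.grid(individual_id = 1:3, visit = 1:2)
  p$exposure_index <- rnorm(6)
  p$bmi <- rnorm(6)
  expect_error(twfe(rbind(p, p)), "duplicate")
  expect_error(twfe(p[p$visit == 1, ]), ">= 2 visits")
})

test_that("TWFE removes individual-level confounding that biases pooled OLS", {
  cfg <- sim_config(panel = list(n_individuals = 400L, n_visits = 3L,
                                 rho = 0.8))
  sim <- simulate_panel(cfg, 99)
  fit <- twfe(sim$panel)
  pooled <- unname(coef(lm(bmi ~ exposure_index, data = sim$panel))[2])
  expect_lt(abs(fit$beta - sim$beta_true), 0.1)
  expect_gt(abs(pooled - sim$beta_true), 3 * abs(fit$beta - sim$beta_true))
})
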