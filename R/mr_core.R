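# Univariable two-sample MR estimators on a harmonized set: Wald ratio,
# inverse-variance weighted, MR-Egger, weighted median, simple and weighted
# mode. All return objects of class "mr_estimate".

.new_mr_estimate <- function(method, beta, se, pval, n_snp, q_stat = NA_real_,
                             intercept = NULL, intercept_se = NULL,
                             intercept_pval = NULL, exposure = NA_character_,
                             outcome = NA_character_) {
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - .Z95 * se, ci_high = beta + .Z95 * se,
                 pval = pval, n_snp = n_snp, q_stat = q_stat,
                 intercept = intercept, intercept_se = intercept_se,
                 intercept_pval = intercept_pval,
                 exposure = exposure, outcome = outcome),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s MR estimate (%s -> %s)\n", x$method,
              x$exposure, x$outcome))
  cat(sprintf("  beta = %.*f (95%% CI %.*f, %.*f), se = %.*f, p = %.3g, %d SNP(s)\n",
              digits, x$beta, digits, x$ci_low, digits, x$ci_high,
              digits, x$se, x$pval, x$n_snp))
  if (!is.na(x$q_stat))
    cat(sprintf("  heterogeneity Q = %.*f\n", digits, x$q_stat))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %.*f (se %.*f, p = %.3g)\n", digits,
                x$intercept, digits, x$intercept_se, x$intercept_pval))
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) {
  stats::setNames(object$beta, object$method)
}

#' @export
confint.mr_estimate <- function(object, parm, level = 0.95, ...) {
  z <- if (level == 0.95) .Z95 else stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$beta - z * object$se, object$beta + z * object$se),
              nrow = 1, dimnames = list(object$method, c("low", "high")))
  m
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, beta = x$beta, se = x$se, ci_low = x$ci_low,
             ci_high = x$ci_high, pval = x$pval, n_snp = x$n_snp,
             q_stat = x$q_stat, stringsAsFactors = FALSE)
}

.check_hs <- function(data, min_snp, method) {
  stopifnot(inherits(data, "harmonized_set"))
  k <- nrow(data$snps)
  if (k < min_snp)
    .stopf("%s requires at least %d instrument(s); got %d", method, min_snp, k)
  z <- data$snps$beta_x == 0
  if (any(z))
    .stopf("%s: zero exposure beta for rsid(s): %s", method,
           paste(data$snps$rsid[z], collapse = ", "))
  invisible(k)
}

#' Wald ratio estimate for a single variant
#'
#' First-order ratio estimate `beta_y / beta_x` with standard error
#' `|se_y / beta_x|` (uncertainty in the exposure association is ignored,
#' the usual leading-order approximation).
#'
#' @param beta_x,se_x exposure association and SE.
#' @param beta_y,se_y outcome association and SE.
#' @return An `mr_estimate`.
#' @export
mr_wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  if (beta_x == 0) .stopf("mr_wald_ratio: beta_x must be nonzero")
  beta <- beta_y / beta_x
  se <- abs(se_y / beta_x)
  .new_mr_estimate("Wald ratio", beta, se, .z_pval(beta, se), 1L)
}

#' Inverse-variance weighted estimator
#'
#' Combines per-variant Wald ratios with weights `beta_x^2 / se_y^2`,
#' equivalently the zero-intercept weighted least-squares slope of
#' `beta_y` on `beta_x`. Under the default multiplicative random-effects
#' model the standard error is inflated by `max(1, sqrt(Q/(k-1)))` where
#' `Q` is Cochran's heterogeneity statistic.
#'
#' @param data a `harmonized_set`.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate` with slot `q_stat`.
#' @export
mr_ivw <- function(data, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  k <- .check_hs(data, 1L, "mr_ivw")
  s <- data$snps
  w <- s$beta_x^2 / s$se_y^2
  ratios <- s$beta_y / s$beta_x
  beta <- sum(w * ratios) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (ratios - beta)^2)
  if (model == "multiplicative_random" && k >= 2L)
    se <- se * max(1, sqrt(q / (k - 1L)))
  lab <- if (model == "fixed") "IVW (fixed)" else "IVW"
  .new_mr_estimate(lab, beta, se, .z_pval(beta, se), k, q_stat = q,
                   exposure = data$x_label, outcome = data$y_label)
}

#' MR-Egger regression
#'
#' Weighted least squares of `beta_y` on `beta_x` with an intercept,
#' weights `1/se_y^2`, after orienting every variant so that its exposure
#' beta is non-negative. The slope is the causal estimate, the intercept
#' the average directional pleiotropy. Standard errors carry a
#' multiplicative overdispersion factor of at least 1; p-values use the
#' t distribution with `k - 2` degrees of freedom.
#'
#' @param data a `harmonized_set` with at least 3 variants.
#' @return An `mr_estimate` with intercept slots.
#' @export
mr_egger <- function(data) {
  k <- .check_hs(data, 3L, "mr_egger")
  s <- data$snps
  flip <- sign(s$beta_x)
  bx <- abs(s$beta_x)
  by <- s$beta_y * flip
  w <- 1 / s$se_y^2
  fit <- stats::lm(by ~ bx, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma  # sqrt of weighted RSS / (k - 2)
  infl <- max(1, sigma) / sigma
  est <- sm$coefficients
  slope <- est["bx", "Estimate"]
  slope_se <- est["bx", "Std. Error"] * infl
  int <- est["(Intercept)", "Estimate"]
  int_se <- est["(Intercept)", "Std. Error"] * infl
  q <- sum(w * stats::residuals(fit)^2)
  .new_mr_estimate("MR-Egger", slope, slope_se,
                   2 * stats::pt(-abs(slope / slope_se), df = k - 2L),
                   k, q_stat = q, intercept = int, intercept_se = int_se,
                   intercept_pval = 2 * stats::pt(-abs(int / int_se), df = k - 2L),
                   exposure = data$x_label, outcome = data$y_label)
}

# weighted median of `x` with weights `w` by linear interpolation of the
# cumulative-weight midpoints at probability 1/2
.weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1L]) return(x[1L])
  if (0.5 >= s[length(s)]) return(x[length(x)])
  stats::approx(s, x, xout = 0.5, ties = "ordered")$y
}

# parametric bootstrap of any ratio-based estimator: resample per-SNP betas
# from normal(beta, se) and recompute
.boot_se <- function(s, n_boot, seed, fn) {
  if (n_boot < 2) .stopf("n_boot must be at least 2")
  if (n_boot < 100) .warnf("n_boot < 100 gives unstable bootstrap SEs")
  k <- nrow(s)
  .with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(k, s$beta_x, s$se_x)
      by <- stats::rnorm(k, s$beta_y, s$se_y)
      fn(bx, by)
    }, numeric(1))
    stats::sd(est)
  })
}

#' Weighted median estimator
#'
#' The weighted median of per-variant Wald ratios with inverse-variance
#' weights `beta_x^2 / se_y^2`; consistent when at least half the weight
#' comes from valid instruments. The SE comes from a parametric bootstrap
#' (per-variant betas resampled from their sampling distributions).
#'
#' @param data a `harmonized_set` with at least 3 variants.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap; the caller's RNG state is
#'   restored afterwards.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = NULL) {
  k <- .check_hs(data, 3L, "mr_weighted_median")
  s <- data$snps
  est_fn <- function(bx, by) .weighted_median(by / bx, bx^2 / s$se_y^2)
  beta <- est_fn(s$beta_x, s$beta_y)
  se <- .boot_se(s, n_boot, seed, est_fn)
  .new_mr_estimate("Weighted median", beta, se, .z_pval(beta, se), k,
                   exposure = data$x_label, outcome = data$y_label)
}

# KDE argmax of ratio estimates on a fixed 512-point grid
.mode_point <- function(ratios, w, phi) {
  n <- length(ratios)
  spread <- min(stats::sd(ratios), stats::IQR(ratios) / 1.349)
  h <- phi * 0.9 * spread * n^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(ratios[1L])  # all ratios identical
  grid <- seq(min(ratios) - h, max(ratios) + h, length.out = 512L)
  dens <- vapply(grid, function(g)
    sum(w * stats::dnorm((g - ratios) / h)) / h, numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimators
#'
#' Gaussian-kernel density of the per-variant Wald ratios with bandwidth
#' `phi * 0.9 * min(sd, IQR/1.349) * k^(-1/5)`; the estimate is the density
#' argmax on a fixed 512-point grid spanning `min(ratio) - h` to
#' `max(ratio) + h`. The simple mode uses unit weights, the weighted mode
#' uses `beta_x^2 / se_y^2`. SE by parametric bootstrap as for
#' [mr_weighted_median()]. If all ratios coincide, that common value is
#' returned.
#'
#' @param data a `harmonized_set` with at least 3 variants.
#' @param variant `"weighted"` or `"simple"`.
#' @param phi bandwidth multiplier (> 0, default 1).
#' @param n_boot,seed bootstrap controls as in [mr_weighted_median()].
#' @return An `mr_estimate`.
#' @export
mr_mode <- function(data, variant = c("weighted", "simple"), phi = 1,
                    n_boot = 1000, seed = NULL) {
  variant <- match.arg(variant)
  if (phi <= 0) .stopf("mr_mode: phi must be > 0")
  k <- .check_hs(data, 3L, "mr_mode")
  s <- data$snps
  est_fn <- function(bx, by) {
    w <- if (variant == "weighted") bx^2 / s$se_y^2 else rep(1, k)
    .mode_point(by / bx, w, phi)
  }
  beta <- est_fn(s$beta_x, s$beta_y)
  se <- .boot_se(s, n_boot, seed, est_fn)
  lab <- if (variant == "weighted") "Weighted mode" else "Simple mode"
  .new_mr_estimate(lab, beta, se, .z_pval(beta, se), k,
                   exposure = data$x_label, outcome = data$y_label)
}

#' Run the full univariable estimator suite
#'
#' IVW plus, when at least three instruments are available, MR-Egger,
#' weighted median and both modes.
#'
#' @param data a `harmonized_set`.
#' @param n_boot,seed bootstrap controls for median/mode SEs.
#' @param phi mode bandwidth multiplier.
#' @return data.frame with one row per method (method, beta, se, ci_low,
#'   ci_high, pval, n_snp, q_stat).
#' @export
mr_all <- function(data, n_boot = 1000, seed = 1, phi = 1) {
  fits <- list(mr_ivw(data))
  if (nrow(data$snps) >= 3L) {
    fits <- c(fits, list(
      mr_egger(data),
      mr_weighted_median(data, n_boot = n_boot, seed = seed),
      mr_mode(data, "weighted", phi = phi, n_boot = n_boot, seed = seed + 1L),
      mr_mode(data, "simple", phi = phi, n_boot = n_boot, seed = seed + 2L)))
  }
  do.call(rbind, lapply(fits, as.data.frame))
}
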