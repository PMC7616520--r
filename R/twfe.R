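# Two-way fixed-effects panel estimator with two-way cluster-robust
# standard errors, plus the visit-wise standardization that builds the
# combined consumption index from raw cup counts.

#' Build a standardized consumption index from cup counts
#'
#' Within each visit, z-scores the two beverage counts separately (mean 0,
#' sample SD 1 across the individuals observed at that visit), sums them,
#' and re-standardizes the sum. When one beverage is missing for a row (or
#' absent for a whole visit) the index falls back to the other alone; a
#' beverage with zero variance at a visit is an error. The index is
#' invariant to affine rescaling of the raw counts.
#'
#' @param panel data.frame with columns `individual_id`, `visit`,
#'   `coffee_cups`, `tea_cups` (either may contain `NA`), and any outcome
#'   columns, one row per individual-visit.
#' @param combine `"sum"` (default) or `"mean"` of the two z-scores before
#'   re-standardization (identical after re-standardization within visit;
#'   they differ under `scale_within = "global"`).
#' @param scale_within re-standardize the combined score `"visit"`-wise
#'   (default) or `"global"`ly across all rows.
#' @return `panel` with an added numeric column `exposure_index`.
#' @export
build_exposure_index <- function(panel, combine = c("sum", "mean"),
                                 scale_within = c("visit", "global")) {
  combine <- match.arg(combine)
  scale_within <- match.arg(scale_within)
  req <- c("individual_id", "visit", "coffee_cups", "tea_cups")
  miss <- setdiff(req, names(panel))
  if (length(miss))
    .stopf("build_exposure_index: missing column(s): %s",
           paste(miss, collapse = ", "))
  if (anyDuplicated(panel[c("individual_id", "visit")]))
    .stopf("build_exposure_index: duplicate (individual, visit) rows")
  zscore <- function(v, visit, what) {
    ok <- !is.na(v)
    if (sum(ok) < 2L) return(rep(NA_real_, length(v)))
    s <- stats::sd(v[ok])
    if (s == 0)
      .stopf("build_exposure_index: zero variance in %s at visit %s",
             what, as.character(visit))
    (v - mean(v[ok])) / s
  }
  n_single <- 0L
  raw <- rep(NA_real_, nrow(panel))
  for (vis in unique(panel$visit)) {
    i <- which(panel$visit == vis)
    zc <- zscore(panel$coffee_cups[i], vis, "coffee_cups")
    zt <- zscore(panel$tea_cups[i], vis, "tea_cups")
    both <- cbind(zc, zt)
    n_avail <- rowSums(!is.na(both))
    if (any(n_avail == 0L))
      .stopf("build_exposure_index: row(s) with no beverage data at visit %s",
             as.character(vis))
    n_single <- n_single + sum(n_avail == 1L)
    comb <- rowSums(both, na.rm = TRUE)
    if (combine == "mean") comb <- comb / n_avail
    raw[i] <- comb
  }
  if (n_single > 0L)
    message(sprintf(
      "build_exposure_index: %d row(s) used a single beverage", n_single))
  if (scale_within == "visit") {
    for (vis in unique(panel$visit)) {
      i <- which(panel$visit == vis)
      s <- stats::sd(raw[i])
      if (is.na(s) || s == 0)
        .stopf("build_exposure_index: zero variance of combined index at visit %s",
               as.character(vis))
      raw[i] <- (raw[i] - mean(raw[i])) / s
    }
  } else {
    s <- stats::sd(raw)
    if (is.na(s) || s == 0)
      .stopf("build_exposure_index: zero variance of combined index")
    raw <- (raw - mean(raw)) / s
  }
  panel$exposure_index <- raw
  panel
}

# alternating demeaning over two factors, iterated until the slope of
# y-tilde on x-tilde changes by less than tol
.two_way_demean <- function(x, y, f1, f2, tol = 1e-10, max_sweeps = 10000L) {
  beta_old <- Inf
  for (sweep in seq_len(max_sweeps)) {
    x <- x - stats::ave(x, f1)
    y <- y - stats::ave(y, f1)
    x <- x - stats::ave(x, f2)
    y <- y - stats::ave(y, f2)
    sxx <- sum(x^2)
    if (sxx == 0)
      .stopf("twfe: no within variation in the exposure after demeaning")
    beta <- sum(x * y) / sxx
    if (abs(beta - beta_old) < tol)
      return(list(x = x, y = y, beta = beta, sweeps = sweep))
    beta_old <- beta
  }
  .stopf("twfe: alternating demeaning did not converge in %d sweeps",
         max_sweeps)
}

# one-way cluster-robust variance of the slope in a no-intercept regression
# of u-generating y on x, with small-sample correction G/(G-1)*(N-1)/(N-k)
.cluster_vcov_1w <- function(x, u, cl, k) {
  n <- length(x)
  g <- length(unique(cl))
  meat <- sum(tapply(x * u, cl, sum)^2)
  dof <- if (n > k) (n - 1) / (n - k) else 1  # saturated model: skip dof term
  adj <- if (g > 1L) (g / (g - 1)) * dof else dof
  adj * meat / sum(x^2)^2
}

# two-way cluster-robust slope variance by inclusion-exclusion
.cluster_vcov_2w <- function(x, u, cl1, cl2, k) {
  v1 <- .cluster_vcov_1w(x, u, cl1, k)
  if (is.null(cl2)) return(list(v = v1, clamped = FALSE))
  v2 <- .cluster_vcov_1w(x, u, cl2, k)
  v12 <- .cluster_vcov_1w(x, u, interaction(cl1, cl2, drop = TRUE), k)
  v <- v1 + v2 - v12
  if (is.na(v) || v < 0) list(v = v1, clamped = TRUE)
  else list(v = v, clamped = FALSE)
}

#' Two-way fixed-effects panel regression
#'
#' Estimates `outcome = beta * exposure + individual effect + visit effect
#' + error` by the two-way within transformation (alternating demeaning
#' over individuals and visits, iterated to a coefficient-change tolerance
#' of 1e-10; unbalanced panels are handled naturally). The standard error
#' is two-way cluster-robust by inclusion-exclusion over individual and
#' visit one-way sandwich estimators on the demeaned regression; if the
#' combination turns non-positive it is clamped to the individual-clustered
#' variance with a warning. Each one-way component carries the small-sample
#' correction `G/(G-1) * (N-1)/(N-k)` with `k` the dummy-variable model
#' dimension (slope plus absorbed effects).
#'
#' @param panel data.frame with columns `individual_id`, `visit`, the
#'   exposure and the outcome; at least 2 visits for at least 2
#'   individuals.
#' @param outcome,exposure column names (defaults `"bmi"`,
#'   `"exposure_index"`).
#' @return An object of class `twfe_fit` with `beta`, `se`, `ci_low`,
#'   `ci_high`, `pval`, `n_obs`, `n_individuals`, `n_visits`, `sweeps`.
#' @export
twfe <- function(panel, outcome = "bmi", exposure = "exposure_index") {
  req <- c("individual_id", "visit", outcome, exposure)
  miss <- setdiff(req, names(panel))
  if (length(miss))
    .stopf("twfe: missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(panel[c("individual_id", "visit")]))
    .stopf("twfe: duplicate (individual, visit) rows")
  f_id <- factor(panel$individual_id)
  f_vis <- factor(panel$visit)
  multi_visit <- tabulate(f_id) >= 2L
  if (sum(multi_visit) < 2L || nlevels(f_vis) < 2L)
    .stopf("twfe: need >= 2 visits for >= 2 individuals")
  x <- as.numeric(panel[[exposure]])
  y <- as.numeric(panel[[outcome]])
  if (anyNA(x) || anyNA(y)) .stopf("twfe: missing exposure/outcome values")
  dm <- .two_way_demean(x, y, f_id, f_vis)
  u <- dm$y - dm$beta * dm$x
  k <- 1L + (nlevels(f_id) - 1L) + (nlevels(f_vis) - 1L) + 1L
  vv <- .cluster_vcov_2w(dm$x, u, f_id, f_vis, k)
  if (vv$clamped)
    .warnf("twfe: two-way variance non-positive; using individual-clustered variance")
  se <- sqrt(vv$v)
  structure(list(beta = dm$beta, se = se,
                 ci_low = dm$beta - .Z95 * se, ci_high = dm$beta + .Z95 * se,
                 pval = .z_pval(dm$beta, se),
                 n_obs = length(x), n_individuals = nlevels(f_id),
                 n_visits = nlevels(f_vis), sweeps = dm$sweeps,
                 residuals = u, exposure = exposure, outcome = outcome),
            class = "twfe_fit")
}

#' @export
print.twfe_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Two-way fixed-effects fit: %s ~ %s\n", x$outcome, x$exposure))
  cat(sprintf("  beta = %.*f (95%% CI %.*f, %.*f), two-way clustered se = %.*f, p = %.3g\n",
              digits, x$beta, digits, x$ci_low, digits, x$ci_high,
              digits, x$se, x$pval))
  cat(sprintf("  %d observations, %d individuals, %d visits\n", x$n_obs,
              x$n_individuals, x$n_visits))
  invisible(x)
}

#' @export
coef.twfe_fit <- function(object, ...) {
  stats::setNames(object$beta, object$exposure)
}

#' @export
confint.twfe_fit <- function(object, parm, level = 0.95, ...) {
  z <- if (level == 0.95) .Z95 else stats::qnorm(1 - (1 - level) / 2)
  matrix(c(object$beta - z * object$se, object$beta + z * object$se),
         nrow = 1, dimnames = list(object$exposure, c("low", "high")))
}

#' @export
residuals.twfe_fit <- function(object, ...) object$residuals
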