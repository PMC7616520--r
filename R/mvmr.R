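# Multivariable MR with two exposures by Q-heterogeneity minimization,
# testing for a direct effect of one exposure conditional on the other.

#' Q-heterogeneity objective for two-exposure multivariable MR
#'
#' `Q(b1, b2) = sum_j (beta_y_j - b1*beta_x_j - b2*beta_x2_j)^2 /
#' (se_y_j^2 + b1^2*se_x_j^2 + b2^2*se_x2_j^2)`. The effect-dependent
#' denominator propagates exposure-side sampling error, which is what makes
#' the minimizer robust to conditionally weak instruments.
#'
#' @param beta_pair numeric length-2: candidate direct effects of the
#'   primary and second exposure.
#' @param data a `harmonized_set` with both exposures observed.
#' @return The Q value (scalar, >= 0).
#' @export
qhet_objective <- function(beta_pair, data) {
  stopifnot(inherits(data, "harmonized_set"), length(beta_pair) == 2L)
  s <- data$snps
  if (is.null(s$beta_x2)) .stopf("qhet_objective: second exposure required")
  num <- (s$beta_y - beta_pair[1L] * s$beta_x - beta_pair[2L] * s$beta_x2)^2
  den <- s$se_y^2 + beta_pair[1L]^2 * s$se_x^2 + beta_pair[2L]^2 * s$se_x2^2
  sum(num / den)
}

# minimize Q over the free coordinate with the k-th coordinate fixed at v;
# expands the search interval until the minimum is interior
.profile_q <- function(data, k, v, center, span) {
  other <- if (k == 1L) 2L else 1L
  f <- function(u) {
    b <- numeric(2L)
    b[k] <- v
    b[other] <- u
    qhet_objective(b, data)
  }
  lo <- center - span
  hi <- center + span
  for (i in 1:12) {
    opt <- stats::optimize(f, c(lo, hi), tol = 1e-9)
    width <- hi - lo
    margin <- 0.01 * width
    if (opt$minimum > lo + margin && opt$minimum < hi - margin) break
    lo <- lo - width
    hi <- hi + width
  }
  opt$objective
}

# find v beyond `from` (in direction `dir` = +/-1) where the profile Q
# crosses `target`; bisection until the profile Q is within tol of target
.profile_limit <- function(data, k, from, dir, target, center, span,
                           tol = 1e-5) {
  step <- max(0.05, 0.25 * (abs(from) + 0.1))
  v_in <- from
  v_out <- from + dir * step
  for (i in 1:60) {
    if (.profile_q(data, k, v_out, center, span) >= target) break
    v_in <- v_out
    step <- step * 1.6
    v_out <- v_out + dir * step
    if (i == 60) return(dir * Inf)
  }
  for (i in 1:200) {
    mid <- (v_in + v_out) / 2
    qm <- .profile_q(data, k, mid, center, span)
    if (abs(qm - target) < tol) return(mid)
    if (qm < target) v_in <- mid else v_out <- mid
    if (abs(v_out - v_in) < 1e-12) break
  }
  (v_in + v_out) / 2
}

#' Fit two-exposure multivariable MR by Q minimization (MVMR-Qhet)
#'
#' Minimizes [qhet_objective()] over both direct effects by Nelder-Mead
#' from a per-exposure IVW initialization plus four perturbed restarts,
#' keeping the best minimum. Confidence intervals are profile-based by
#' default: the 95% bound for one coordinate is where the Q profile
#' (minimized over the other coordinate) exceeds the minimum by the
#' chi-square(1) critical value, located by bisection. A percentile
#' parametric bootstrap is available instead.
#'
#' @param data a `harmonized_set` with at least 3 variants and both
#'   exposures observed.
#' @param ci_method `"profile"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap replicates when `ci_method = "bootstrap"`.
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `mvmr_estimate`: direct effects `beta`
#'   (named by exposure), `ci` (2 x 2 matrix), `q_min`, `n_snp`.
#' @export
mvmr_qhet <- function(data, ci_method = c("profile", "bootstrap"),
                      n_boot = 200, seed = NULL) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(data, "harmonized_set"))
  s <- data$snps
  if (is.null(s$beta_x2)) .stopf("mvmr_qhet: second exposure required")
  if (nrow(s) < 3L) .stopf("mvmr_qhet: requires at least 3 instruments")

  fit_point <- function(d) {
    ss <- d$snps
    ivw_slope <- function(bx) {
      w <- 1 / ss$se_y^2
      sum(w * bx * ss$beta_y) / sum(w * bx^2)
    }
    init <- c(ivw_slope(ss$beta_x), ivw_slope(ss$beta_x2))
    delta <- 0.5 * (abs(init) + 0.2)
    starts <- rbind(init,
                    init + c(delta[1L], 0), init - c(delta[1L], 0),
                    init + c(0, delta[2L]), init - c(0, delta[2L]))
    best <- NULL
    trace <- numeric(0)
    for (r in seq_len(nrow(starts))) {
      o <- stats::optim(starts[r, ], qhet_objective, data = d,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
      trace <- c(trace, o$value)
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (all(!is.finite(trace)))
      .stopf("mvmr_qhet: optimizer failed to converge; Q trace: %s",
             paste(signif(trace, 6), collapse = ", "))
    list(par = best$par, value = best$value, init = init)
  }

  pt <- fit_point(data)
  beta <- pt$par
  q_min <- pt$value
  crit <- stats::qchisq(0.95, df = 1)

  if (ci_method == "profile") {
    target <- q_min + crit
    span0 <- 2 * (max(abs(beta)) + 1)
    ci <- matrix(NA_real_, 2L, 2L)
    for (k in 1:2) {
      center <- beta[if (k == 1L) 2L else 1L]
      ci[k, 1L] <- .profile_limit(data, k, beta[k], -1, target, center, span0)
      ci[k, 2L] <- .profile_limit(data, k, beta[k], +1, target, center, span0)
    }
  } else {
    k_snp <- nrow(s)
    boot <- .with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        d2 <- data
        d2$snps$beta_x <- stats::rnorm(k_snp, s$beta_x, s$se_x)
        d2$snps$beta_x2 <- stats::rnorm(k_snp, s$beta_x2, s$se_x2)
        d2$snps$beta_y <- stats::rnorm(k_snp, s$beta_y, s$se_y)
        fit_point(d2)$par
      }, numeric(2))
    })
    ci <- t(apply(boot, 1L, stats::quantile, probs = c(0.025, 0.975)))
  }
  dimnames(ci) <- list(c(data$x_label, data$x2_label), c("low", "high"))
  structure(list(beta = stats::setNames(beta, c(data$x_label, data$x2_label)),
                 ci = ci, q_min = q_min, n_snp = nrow(s),
                 ci_method = ci_method, q_init = qhet_objective(pt$init, data),
                 outcome = data$y_label),
            class = "mvmr_estimate")
}

#' @export
print.mvmr_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("MVMR-Qhet direct effects on %s (%d SNPs, Q_min = %.2f, %s CI)\n",
              x$outcome, x$n_snp, x$q_min, x$ci_method))
  for (i in seq_along(x$beta))
    cat(sprintf("  %s: %.*f (95%% CI %.*f, %.*f)\n", names(x$beta)[i],
                digits, x$beta[i], digits, x$ci[i, 1L], digits, x$ci[i, 2L]))
  invisible(x)
}

#' @export
coef.mvmr_estimate <- function(object, ...) object$beta

#' @export
confint.mvmr_estimate <- function(object, parm, level = 0.95, ...) object$ci
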