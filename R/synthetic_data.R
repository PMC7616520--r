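# Structural-equation generator for the study's causal architecture:
# metabolism variants raise the circulating biomarker while lowering
# consumption (titration feedback), behavioral variants act through a
# latent lifestyle trait that is pleiotropic for the outcome. Emits
# three-cohort GWAS summary statistics and a confounded panel, and carries
# closed-form ground truth for every downstream estimator.
#
# Structural model (per individual i, genotypes g ~ Binomial(2, maf)):
#   L = sum_behav c_j g_ij + eps_L                     latent lifestyle
#   D = lambda_L * L - lambda_M * sum_met a_j g_ij + eps_D   consumption
#   P = pi_D * D + sum_met a_j g_ij + eps_P            plasma biomarker
#   B = theta_P * P + theta_L * L + theta_S * D + eps_B      outcome

#' Simulation configuration
#'
#' Defaults encode the study architecture at desk scale: 16 metabolism
#' variants and 8 behavioral variants, three non-overlapping GWAS cohorts
#' of 50,000, allele effects scaled so every variant passes genome-wide
#' selection at p < 5e-7, a negative biomarker effect on the outcome
#' (`theta_P`), positive lifestyle pleiotropy (`theta_L`) and a positive
#' direct consumption effect (`theta_S`, the "accompaniments" path). Allele
#' effects are specified per SD of genotype (`a_scale`, `c_scale`) so each
#' variant in a panel contributes equal variance; explicit `a_j`/`c_j`
#' vectors override this. Noise SDs are chosen so all four phenotypes have
#' unit variance at the defaults.
#'
#' @param m_metab,m_behav panel sizes.
#' @param maf_range allele-frequency interval; per-SNP frequencies are
#'   evenly spaced across it (deterministic) unless `maf_metab`/`maf_behav`
#'   are given.
#' @param maf_metab,maf_behav optional explicit frequency vectors.
#' @param a_scale per-variant SD contribution of a metabolism allele to the
#'   biomarker; `a_j = a_scale / sqrt(2 maf (1-maf))`.
#' @param c_scale per-variant SD contribution of a behavioral allele to the
#'   latent lifestyle trait.
#' @param a_j,c_j optional explicit per-allele effect vectors (override the
#'   scales).
#' @param lambda_M titration feedback strength: consumption decrease per
#'   unit metabolism allele score. Must satisfy `pi_D * lambda_M < 1`.
#' @param lambda_L lifestyle loading on consumption.
#' @param pi_D consumption-to-biomarker transfer (> 0).
#' @param theta_P,theta_L,theta_S outcome effects of the biomarker,
#'   lifestyle and consumption.
#' @param sigma_L,sigma_D,sigma_P,sigma_B noise SDs.
#' @param n_consumption,n_biomarker,n_outcome GWAS cohort sizes (>= 100).
#' @param panel list of panel-generator settings: `n_individuals`,
#'   `n_visits`, `beta` (true effect per SD of the consumption index),
#'   `rho` (individual-effect confounding strength in [0,1]),
#'   `sigma_alpha`, `sigma_e`, `attendance` (per-visit attendance
#'   probabilities, first visit always 1).
#' @param ld_mode `"identity"` (linkage equilibrium) or `"blocks"`
#'   (compound-symmetric LD within consecutive blocks, to exercise
#'   clumping).
#' @param ld_block_size,ld_block_rho block settings for `ld_mode =
#'   "blocks"`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(m_metab = 16L, m_behav = 8L,
                       maf_range = c(0.1, 0.5),
                       maf_metab = NULL, maf_behav = NULL,
                       a_scale = 0.075, c_scale = 0.094,
                       a_j = NULL, c_j = NULL,
                       lambda_M = 0.5, lambda_L = 0.4, pi_D = 0.25,
                       theta_P = -0.15, theta_L = 0.6, theta_S = 0.075,
                       sigma_L = 0.964, sigma_D = 0.904,
                       sigma_P = 0.933, sigma_B = 0.774,
                       n_consumption = 50000L, n_biomarker = 50000L,
                       n_outcome = 50000L,
                       panel = list(),
                       ld_mode = c("identity", "blocks"),
                       ld_block_size = 4L, ld_block_rho = 0.9) {
  ld_mode <- match.arg(ld_mode)
  if (is.null(maf_metab))
    maf_metab <- seq(maf_range[1L], maf_range[2L], length.out = m_metab)
  if (is.null(maf_behav))
    maf_behav <- seq(min(maf_range[1L] + 0.02, 0.5),
                     max(maf_range[2L] - 0.02, maf_range[1L] + 0.02),
                     length.out = m_behav)
  if (is.null(a_j)) a_j <- a_scale / sqrt(2 * maf_metab * (1 - maf_metab))
  if (is.null(c_j)) c_j <- c_scale / sqrt(2 * maf_behav * (1 - maf_behav))
  panel_defaults <- list(n_individuals = 1000L, n_visits = 4L, beta = -0.1,
                         rho = 0.5, sigma_alpha = 1, sigma_e = 0.5,
                         attendance = c(1, 0.6, 0.6, 0.5))
  panel <- utils::modifyList(panel_defaults, panel)
  cfg <- structure(list(
    m_metab = as.integer(m_metab), m_behav = as.integer(m_behav),
    maf_metab = maf_metab, maf_behav = maf_behav, a_j = a_j, c_j = c_j,
    lambda_M = lambda_M, lambda_L = lambda_L, pi_D = pi_D,
    theta_P = theta_P, theta_L = theta_L, theta_S = theta_S,
    sigma_L = sigma_L, sigma_D = sigma_D, sigma_P = sigma_P,
    sigma_B = sigma_B,
    n_consumption = as.integer(n_consumption),
    n_biomarker = as.integer(n_biomarker),
    n_outcome = as.integer(n_outcome),
    panel = panel, ld_mode = ld_mode,
    ld_block_size = as.integer(ld_block_size), ld_block_rho = ld_block_rho),
    class = "sim_config")
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param config a `sim_config` to validate.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$pi_D * config$lambda_M >= 1)
    .stopf("sim_config: unstable titration (pi_D * lambda_M must be < 1)")
  maf <- c(config$maf_metab, config$maf_behav)
  if (any(maf <= 0 | maf > 0.5))
    .stopf("sim_config: MAFs must lie in (0, 0.5]")
  if (any(c(config$n_consumption, config$n_biomarker, config$n_outcome) < 100))
    .stopf("sim_config: cohort sizes must be >= 100")
  if (length(config$a_j) != config$m_metab ||
      length(config$c_j) != config$m_behav)
    .stopf("sim_config: effect-vector lengths must match panel sizes")
  if (config$panel$rho < 0 || config$panel$rho > 1)
    .stopf("sim_config: panel confounding rho must lie in [0, 1]")
  invisible(config)
}

.snp_ids <- function(config) {
  c(sprintf("rs_met_%02d", seq_len(config$m_metab)),
    sprintf("rs_beh_%02d", seq_len(config$m_behav)))
}

#' Analytic ground truth implied by a configuration
#'
#' Closed-form second moments and per-variant reduced-form effects of the
#' structural model. Raw per-allele effects: a metabolism variant changes
#' consumption by `-lambda_M * a_j` and the biomarker by
#' `a_j * (1 - pi_D * lambda_M)` (opposite signs — the titration
#' signature); a behavioral variant changes consumption by `lambda_L * c_j`
#' and the biomarker by `pi_D` times that. Standardized betas divide by the
#' implied phenotype SDs, matching the SD-unit GWAS output.
#'
#' @param config a `sim_config`.
#' @return List with phenotype SDs (`sd_L`, `sd_D`, `sd_P`, `sd_B`),
#'   `cov_DP`, per-SNP table `snps` (raw and standardized effects on
#'   consumption/biomarker/outcome, panel, true Steiger label, true r² in
#'   both exposures), and standardized causal parameters (`theta_P_std`:
#'   biomarker -> outcome in SD/SD; `theta_S_std`: direct consumption ->
#'   outcome; plus the stratum-level IVW probability limits
#'   `plim_metab_consumption`, `plim_metab_biomarker`,
#'   `plim_behav_consumption`).
#' @export
ground_truth <- function(config) {
  validate_sim_config(config)
  cf <- config
  var_g_m <- 2 * cf$maf_metab * (1 - cf$maf_metab)
  var_g_b <- 2 * cf$maf_behav * (1 - cf$maf_behav)
  s2_GM <- sum(cf$a_j^2 * var_g_m)
  s2_GB <- sum(cf$c_j^2 * var_g_b)
  var_L <- s2_GB + cf$sigma_L^2
  var_D <- cf$lambda_L^2 * var_L + cf$lambda_M^2 * s2_GM + cf$sigma_D^2
  cov_D_GM <- -cf$lambda_M * s2_GM
  var_P <- cf$pi_D^2 * var_D + s2_GM + 2 * cf$pi_D * cov_D_GM + cf$sigma_P^2
  cov_DP <- cf$pi_D * var_D + cov_D_GM
  cov_LD <- cf$lambda_L * var_L
  cov_LP <- cf$pi_D * cov_LD
  var_B <- cf$theta_P^2 * var_P + cf$theta_L^2 * var_L +
    cf$theta_S^2 * var_D + cf$sigma_B^2 +
    2 * (cf$theta_P * cf$theta_L * cov_LP +
           cf$theta_P * cf$theta_S * cov_DP +
           cf$theta_L * cf$theta_S * cov_LD)
  sd_L <- sqrt(var_L); sd_D <- sqrt(var_D)
  sd_P <- sqrt(var_P); sd_B <- sqrt(var_B)

  # raw reduced-form per-allele effects
  eff_D <- c(-cf$lambda_M * cf$a_j, cf$lambda_L * cf$c_j)
  eff_P <- c(cf$a_j * (1 - cf$pi_D * cf$lambda_M),
             cf$pi_D * cf$lambda_L * cf$c_j)
  c_all <- c(rep(0, cf$m_metab), cf$c_j)
  eff_B <- cf$theta_P * eff_P + cf$theta_L * c_all + cf$theta_S * eff_D
  panel_lab <- rep(c("metabolism", "behavioral"), c(cf$m_metab, cf$m_behav))
  var_g <- c(var_g_m, var_g_b)
  r2_D <- eff_D^2 * var_g / var_D
  r2_P <- eff_P^2 * var_g / var_P
  snps <- data.frame(
    rsid = .snp_ids(cf), panel = panel_lab, maf = c(cf$maf_metab, cf$maf_behav),
    eff_D = eff_D, eff_P = eff_P, eff_B = eff_B,
    beta_D = eff_D / sd_D, beta_P = eff_P / sd_P, beta_B = eff_B / sd_B,
    r2_D = r2_D, r2_P = r2_P,
    steiger_label = ifelse(r2_P > r2_D, "biomarker_first", "consumption_first"),
    stringsAsFactors = FALSE)

  met <- panel_lab == "metabolism"
  beh <- !met
  list(sd_L = sd_L, sd_D = sd_D, sd_P = sd_P, sd_B = sd_B,
       cov_DP = cov_DP, snps = snps,
       theta_P = cf$theta_P, theta_L = cf$theta_L, theta_S = cf$theta_S,
       theta_P_std = cf$theta_P * sd_P / sd_B,
       theta_S_std = cf$theta_S * sd_D / sd_B,
       # per-stratum Wald-ratio probability limits (same for every SNP in
       # a stratum because allele effects are proportional within panel)
       plim_metab_consumption = (eff_B[met] / eff_D[met])[1L] * sd_D / sd_B,
       plim_metab_biomarker = (eff_B[met] / eff_P[met])[1L] * sd_P / sd_B,
       plim_behav_consumption = (eff_B[beh] / eff_D[beh])[1L] * sd_D / sd_B)
}

# genotype matrix for the combined panels; block mode induces compound-
# symmetric LD within consecutive blocks through a Gaussian copula
.simulate_genotypes <- function(config, n) {
  maf <- c(config$maf_metab, config$maf_behav)
  m <- length(maf)
  if (config$ld_mode == "identity") {
    g <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)
  } else {
    rho <- sqrt(config$ld_block_rho)
    g <- matrix(0L, n, m)
    j <- 1L
    while (j <= m) {
      jj <- j:min(j + config$ld_block_size - 1L, m)
      shared1 <- stats::rnorm(n)
      shared2 <- stats::rnorm(n)
      for (idx in jj) {
        z1 <- rho * shared1 + sqrt(1 - rho^2) * stats::rnorm(n)
        z2 <- rho * shared2 + sqrt(1 - rho^2) * stats::rnorm(n)
        g[, idx] <- (z1 < stats::qnorm(maf[idx])) + (z2 < stats::qnorm(maf[idx]))
      }
      j <- j + config$ld_block_size
    }
  }
  colnames(g) <- .snp_ids(config)
  g
}

#' Simulate one individual-level cohort
#'
#' Draws genotypes and the four phenotypes of the structural model.
#'
#' @param config a `sim_config`.
#' @param n cohort size.
#' @param seed RNG seed.
#' @return List with `g` (n x m genotype matrix, columns named by rsid)
#'   and numeric vectors `L`, `D`, `P`, `B`.
#' @export
simulate_cohort <- function(config, n, seed) {
  validate_sim_config(config)
  .with_seed(seed, {
    g <- .simulate_genotypes(config, n)
    im <- seq_len(config$m_metab)
    ib <- config$m_metab + seq_len(config$m_behav)
    score_M <- as.numeric(g[, im, drop = FALSE] %*% config$a_j)
    score_B <- as.numeric(g[, ib, drop = FALSE] %*% config$c_j)
    L <- score_B + stats::rnorm(n, 0, config$sigma_L)
    D <- config$lambda_L * L - config$lambda_M * score_M +
      stats::rnorm(n, 0, config$sigma_D)
    P <- config$pi_D * D + score_M + stats::rnorm(n, 0, config$sigma_P)
    B <- config$theta_P * P + config$theta_L * L + config$theta_S * D +
      stats::rnorm(n, 0, config$sigma_B)
    list(g = g, L = L, D = D, P = P, B = B)
  })
}

# per-SNP simple regression of a standardized phenotype on genotype
.gwas_scan <- function(g, y, trait, n) {
  y <- as.numeric(scale(y))
  gc <- sweep(g, 2L, colMeans(g))
  sxx <- colSums(gc^2)
  sxy <- as.numeric(crossprod(gc, y))
  beta <- sxy / sxx
  syy <- sum(y^2)  # y is centered by scale()
  sigma2 <- pmax(syy - beta * sxy, 0) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tval <- beta / se
  pval <- pmax(2 * stats::pt(-abs(tval), df = n - 2), 1e-300)
  summary_stats(data.frame(
    rsid = colnames(g),
    effect_allele = "A", other_allele = "G",
    eaf = colMeans(g) / 2,
    beta = beta, se = se, pval = pval, n = n,
    stringsAsFactors = FALSE), trait = trait, sd_units = TRUE)
}

#' Simulate a three-cohort GWAS trio
#'
#' Three independent cohorts (distinct sub-seeds drawn from `seed`) scanned
#' for consumption, the biomarker and the outcome respectively, phenotypes
#' standardized within cohort so betas are in SD units.
#'
#' @param config a `sim_config`.
#' @param seed RNG seed; three cohort sub-seeds are derived from it.
#' @return List with `summary_stats` elements `consumption`, `biomarker`,
#'   `outcome`; `ld` (identity r² matrix under linkage equilibrium,
#'   empirical genotype r² of the consumption cohort under block LD); and
#'   `truth` (see [ground_truth()]).
#' @export
simulate_gwas_trio <- function(config, seed) {
  validate_sim_config(config)
  sub <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, 3L))
  coh_D <- simulate_cohort(config, config$n_consumption, sub[1L])
  coh_P <- simulate_cohort(config, config$n_biomarker, sub[2L])
  coh_B <- simulate_cohort(config, config$n_outcome, sub[3L])
  ids <- .snp_ids(config)
  if (config$ld_mode == "identity") {
    ld <- diag(length(ids))
    dimnames(ld) <- list(ids, ids)
  } else {
    ld <- stats::cor(coh_D$g)^2
    ld[abs(ld) < 1e-12] <- 0
    diag(ld) <- 1
    ld <- (ld + t(ld)) / 2
  }
  list(consumption = .gwas_scan(coh_D$g, coh_D$D, "consumption",
                                config$n_consumption),
       biomarker = .gwas_scan(coh_P$g, coh_P$P, "biomarker",
                              config$n_biomarker),
       outcome = .gwas_scan(coh_B$g, coh_B$B, "outcome", config$n_outcome),
       ld = ld, truth = ground_truth(config))
}

#' Simulate a confounded longitudinal panel
#'
#' Individuals report coffee and tea cups at up to `n_visits` visits (the
#' first visit is always attended; later attendance is Bernoulli). Both cup
#' counts load on a per-individual consumption propensity; the outcome is
#' `beta * exposure_index + alpha_i + gamma_t + noise`, where
#' `exposure_index` is exactly the index [build_exposure_index()]
#' constructs and the individual effect `alpha_i` has correlation `rho`
#' with the consumption propensity (the confounding that defeats pooled
#' OLS but not the within estimator).
#'
#' @param config a `sim_config` (panel settings in `config$panel`).
#' @param seed RNG seed.
#' @return List with `panel` (data.frame: `individual_id`, `visit`,
#'   `coffee_cups`, `tea_cups`, `exposure_index`, `bmi`) and `beta_true`.
#' @export
simulate_panel <- function(config, seed) {
  validate_sim_config(config)
  pc <- config$panel
  if (pc$n_visits < 2L) .stopf("simulate_panel: need >= 2 visits")
  .with_seed(seed, {
    n <- pc$n_individuals
    att <- rep_len(pc$attendance, pc$n_visits)
    att[1L] <- 1
    z <- stats::rnorm(n)  # consumption propensity
    rows <- list()
    for (t in seq_len(pc$n_visits)) {
      here <- which(stats::runif(n) < att[t])
      coffee <- 2 + 1.0 * (z[here] + stats::rnorm(length(here), 0, 0.8))
      tea <- 3 + 1.5 * (0.7 * z[here] + stats::rnorm(length(here), 0, 0.9))
      rows[[t]] <- data.frame(individual_id = here, visit = t,
                              coffee_cups = coffee, tea_cups = tea)
    }
    panel <- do.call(rbind, rows)
    panel <- build_exposure_index(panel)
    gamma <- c(0, 0.2, -0.1, 0.3)[((seq_len(pc$n_visits) - 1L) %% 4L) + 1L]
    alpha <- pc$sigma_alpha *
      (pc$rho * z + sqrt(1 - pc$rho^2) * stats::rnorm(n))
    panel$bmi <- pc$beta * panel$exposure_index +
      alpha[panel$individual_id] + gamma[panel$visit] +
      stats::rnorm(nrow(panel), 0, pc$sigma_e)
    rownames(panel) <- NULL
    list(panel = panel, beta_true = pc$beta)
  })
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Simulation config: %d metabolism + %d behavioral variants\n",
    "  titration lambda_M = %g, lifestyle lambda_L = %g, transfer pi_D = %g\n",
    "  outcome effects: biomarker %g, lifestyle %g, direct consumption %g\n",
    "  cohorts: consumption %d, biomarker %d, outcome %d; LD mode %s\n"),
    x$m_metab, x$m_behav, x$lambda_M, x$lambda_L, x$pi_D,
    x$theta_P, x$theta_L, x$theta_S,
    x$n_consumption, x$n_biomarker, x$n_outcome, x$ld_mode))
  invisible(x)
}
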