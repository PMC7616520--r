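# Orchestrates the full contrast workflow: genome-wide MR on the
# behavioral exposure, biologically-motivated MR on the biomarker, TWFE
# triangulation, Steiger mechanism stratification with re-weighted
# estimates, MVMR direct-effect testing, and the pleiotropy-robust suite.

.wf_row <- function(analysis, exposure, outcome, fit, f_stat = NA_real_) {
  data.frame(analysis = analysis, exposure = exposure, outcome = outcome,
             method = fit$method, f_stat = f_stat, n_snp = fit$n_snp,
             estimate = fit$beta, se = fit$se, ci_low = fit$ci_low,
             ci_high = fit$ci_high, pval = fit$pval, stringsAsFactors = FALSE)
}

# joint instrument F for the primary exposure of a harmonized set
.hs_f_stat <- function(hs) {
  s <- hs$snps
  r2 <- sum(variance_explained(s$beta_x, s$se_x, n = s$n_x, mode = "tstat"))
  f_statistic(min(r2, 0.999), stats::median(s$n_x), nrow(s))
}

#' Run the full drug-target MR contrast workflow
#'
#' Executes, in order: p-value selection and greedy clumping of the
#' behavioral-exposure instruments; genome-wide IVW against the outcome;
#' biologically-motivated IVW using the named biomarker variants; TWFE on
#' the panel (when supplied); Steiger stratification of the genome-wide
#' instruments against the biomarker, with three estimates on the
#' biomarker-proximal (metabolism) stratum — consumption-weighted on the
#' outcome, biomarker-weighted on the outcome via [reweight_exposure()],
#' and biomarker-weighted on consumption itself — and two on the
#' behavior-proximal stratum (consumption on the outcome, consumption on
#' the biomarker); MVMR-Qhet on the union instrument set (ranked p-value
#' clumping across both exposures); and the pleiotropy-robust suite on the
#' full set and the behavior stratum.
#'
#' @param consumption,biomarker,outcome `summary_stats` for the behavioral
#'   exposure, the biomarker exposure and the outcome.
#' @param ld square r² matrix covering all selectable variants.
#' @param panel optional panel data.frame (see [build_exposure_index()];
#'   the TWFE rows are omitted when `NULL`).
#' @param bio_variants rsids of the biologically-motivated instruments; by
#'   default the two strongest biomarker associations.
#' @param p_threshold,clump_r2 selection and clumping thresholds.
#' @param n_boot,seed bootstrap controls for the median/mode estimators.
#' @return An object of class `workflow_report`: `rows` (tidy results
#'   table), `strata` (Steiger stratum counts), `instruments`,
#'   `steiger_records`, `provenance`.
#' @export
run_workflow <- function(consumption, biomarker, outcome, ld, panel = NULL,
                         bio_variants = NULL, p_threshold = 5e-7,
                         clump_r2 = 0.001, n_boot = 500, seed = 1) {
  stage <- "instrument selection"
  rows <- list()
  out <- tryCatch({
    sel <- clump_instruments(select_instruments(consumption, p_threshold),
                             ld, clump_r2)
    if (nrow(sel$snps) == 0L) .stopf("no instruments after clumping")

    stage <- "genome-wide MR"
    cons_sel <- consumption
    cons_sel$data <- cons_sel$data[cons_sel$data$rsid %in% sel$snps$rsid, ]
    hs_gw <- harmonize(cons_sel, outcome)
    rows$gw <- .wf_row("genome-wide MR", consumption$trait, outcome$trait,
                       mr_ivw(hs_gw), .hs_f_stat(hs_gw))

    stage <- "biologically-motivated MR"
    if (is.null(bio_variants)) {
      bd <- biomarker$data
      bio_variants <- bd$rsid[order(bd$pval)][1:2]
    }
    bio <- biomarker
    bio$data <- bio$data[bio$data$rsid %in% bio_variants, ]
    hs_bio <- harmonize(bio, outcome)
    rows$bio <- .wf_row("biologically-motivated MR", biomarker$trait,
                        outcome$trait, mr_ivw(hs_bio), .hs_f_stat(hs_bio))

    stage <- "two-way fixed effects"
    if (!is.null(panel)) {
      if (!"exposure_index" %in% names(panel))
        panel <- build_exposure_index(panel)
      tw <- twfe(panel)
      rows$twfe <- data.frame(analysis = "TWFE",
                              exposure = "consumption index",
                              outcome = "bmi", method = "TWFE",
                              f_stat = NA_real_, n_snp = NA_integer_,
                              estimate = tw$beta, se = tw$se,
                              ci_low = tw$ci_low, ci_high = tw$ci_high,
                              pval = tw$pval, stringsAsFactors = FALSE)
    }

    stage <- "Steiger stratification"
    hs2 <- merge_second_exposure(hs_gw, biomarker, missing_policy = "drop")
    strat <- steiger_stratify(hs2)
    behav <- strat$primary_first     # proximal to the behavioral exposure
    metab <- strat$secondary_first   # proximal to the biomarker

    stage <- "stratified MR (biomarker stratum)"
    if (!is.null(metab)) {
      rows$met_c <- .wf_row("metabolism stratum", consumption$trait,
                            outcome$trait, mr_ivw(metab), .hs_f_stat(metab))
      metab_p <- reweight_exposure(metab)
      rows$met_p <- .wf_row("metabolism stratum", biomarker$trait,
                            outcome$trait, mr_ivw(metab_p),
                            .hs_f_stat(metab_p))
      bio_on_cons <- harmonize(biomarker, consumption)
      bio_on_cons <- subset(bio_on_cons, metab$snps$rsid)
      rows$met_pc <- .wf_row("metabolism stratum", biomarker$trait,
                             consumption$trait, mr_ivw(bio_on_cons),
                             .hs_f_stat(bio_on_cons))
    }

    stage <- "stratified MR (behavior stratum)"
    if (!is.null(behav)) {
      rows$beh_c <- .wf_row("behavior stratum", consumption$trait,
                            outcome$trait, mr_ivw(behav), .hs_f_stat(behav))
      cons_on_bio <- harmonize(consumption, biomarker)
      cons_on_bio <- subset(cons_on_bio, behav$snps$rsid)
      rows$beh_cp <- .wf_row("behavior stratum", consumption$trait,
                             biomarker$trait, mr_ivw(cons_on_bio),
                             .hs_f_stat(cons_on_bio))
    }

    stage <- "multivariable MR"
    union_sel <- .mvmr_selection(consumption, biomarker, ld, p_threshold,
                                 clump_r2)
    cons_u <- consumption
    cons_u$data <- cons_u$data[cons_u$data$rsid %in% union_sel, ]
    hs_mv <- merge_second_exposure(harmonize(cons_u, outcome), biomarker,
                                   missing_policy = "drop")
    mv <- mvmr_qhet(hs_mv)
    rows$mvmr <- data.frame(analysis = "multivariable MR",
                            exposure = c(consumption$trait, biomarker$trait),
                            outcome = outcome$trait, method = "MVMR-Qhet",
                            f_stat = NA_real_, n_snp = mv$n_snp,
                            estimate = unname(mv$beta), se = NA_real_,
                            ci_low = mv$ci[, 1L], ci_high = mv$ci[, 2L],
                            pval = NA_real_, stringsAsFactors = FALSE)

    stage <- "pleiotropy-robust estimators"
    rob <- mr_all(hs_gw, n_boot = n_boot, seed = seed)
    rob <- rob[rob$method != "IVW", ]
    rows$rob <- data.frame(analysis = "pleiotropy-robust (all instruments)",
                           exposure = consumption$trait,
                           outcome = outcome$trait, method = rob$method,
                           f_stat = NA_real_, n_snp = rob$n_snp,
                           estimate = rob$beta, se = rob$se,
                           ci_low = rob$ci_low, ci_high = rob$ci_high,
                           pval = rob$pval, stringsAsFactors = FALSE)
    if (!is.null(behav) && nrow(behav$snps) >= 3L) {
      rob2 <- mr_all(behav, n_boot = n_boot, seed = seed + 10L)
      rob2 <- rob2[rob2$method != "IVW", ]
      rows$rob2 <- data.frame(analysis = "pleiotropy-robust (behavior stratum)",
                              exposure = consumption$trait,
                              outcome = outcome$trait, method = rob2$method,
                              f_stat = NA_real_, n_snp = rob2$n_snp,
                              estimate = rob2$beta, se = rob2$se,
                              ci_low = rob2$ci_low, ci_high = rob2$ci_high,
                              pval = rob2$pval, stringsAsFactors = FALSE)
    }

    structure(list(
      rows = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      strata = c(behavior = if (is.null(behav)) 0L else nrow(behav$snps),
                 metabolism = if (is.null(metab)) 0L else nrow(metab$snps),
                 excluded = nrow(strat$excluded)),
      instruments = sel,
      steiger_records = strat$records,
      provenance = list(p_threshold = p_threshold, clump_r2 = clump_r2,
                        seed = seed, n_boot = n_boot,
                        bio_variants = bio_variants)),
      class = "workflow_report")
  }, error = function(e) {
    .stopf("run_workflow failed at stage '%s': %s (partial rows: %s)",
           stage, conditionMessage(e),
           paste(names(rows), collapse = ", "))
  })
  out
}

# union selection for MVMR: variants passing the threshold for either
# exposure, ranked by their best p-value, then clumped
.mvmr_selection <- function(consumption, biomarker, ld, p_threshold,
                            clump_r2) {
  d1 <- consumption$data[consumption$data$pval < p_threshold,
                         c("rsid", "pval")]
  d2 <- biomarker$data[biomarker$data$pval < p_threshold, c("rsid", "pval")]
  both <- rbind(d1, d2)
  if (nrow(both) == 0L) .stopf("MVMR selection: no variant passes threshold")
  best <- stats::aggregate(pval ~ rsid, data = both, FUN = min)
  cand <- structure(list(snps = best[order(best$pval, best$rsid), ],
                         p_threshold = p_threshold, clump_r2 = NA_real_,
                         provenance = NULL), class = "instrument_set")
  clump_instruments(cand, ld, clump_r2)$snps$rsid
}

#' Run the workflow on freshly simulated data
#'
#' Convenience wrapper: simulates a GWAS trio and panel from `config` and
#' calls [run_workflow()]. The biologically-motivated variants are the two
#' largest-effect metabolism alleles.
#'
#' @param config a `sim_config`.
#' @param seed RNG seed (simulation and bootstrap).
#' @param with_panel include the TWFE stage?
#' @param ... passed on to [run_workflow()].
#' @return A `workflow_report`.
#' @export
run_workflow_synthetic <- function(config = sim_config(), seed = 1,
                                   with_panel = TRUE, ...) {
  trio <- simulate_gwas_trio(config, seed)
  panel <- if (with_panel) simulate_panel(config, seed + 500000L)$panel
  else NULL
  tr <- trio$truth$snps
  met <- tr[tr$panel == "metabolism", ]
  bio_variants <- met$rsid[order(-abs(met$eff_P))][1:2]
  run_workflow(trio$consumption, trio$biomarker, trio$outcome, trio$ld,
               panel = panel, bio_variants = bio_variants, seed = seed, ...)
}

#' @export
print.workflow_report <- function(x, digits = 3, ...) {
  cat("Drug-target MR workflow report\n")
  cat(sprintf("  instruments: %d (p < %g, clump r2 <= %g); strata: %d behavior / %d metabolism (%d excluded)\n",
              nrow(x$instruments$snps), x$provenance$p_threshold,
              x$provenance$clump_r2, x$strata[["behavior"]],
              x$strata[["metabolism"]], x$strata[["excluded"]]))
  df <- x$rows
  df$estimate <- sprintf("%.*f (%.*f, %.*f)", digits, df$estimate, digits,
                         df$ci_low, digits, df$ci_high)
  print(df[c("analysis", "exposure", "outcome", "method", "f_stat",
             "n_snp", "estimate")], row.names = FALSE)
  invisible(x)
}

#' Render a workflow report to a file
#'
#' Deterministic field ordering; the markdown variant mirrors the tidy
#' results table with estimates formatted as `beta (ci_low, ci_high)` to 3
#' decimals.
#'
#' @param report a `workflow_report`.
#' @param path output file path.
#' @param format `"tsv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "workflow_report"))
  df <- report$rows
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    fmt <- function(b, lo, hi) sprintf("%.3f (%.3f, %.3f)", b, lo, hi)
    lines <- c(
      "| Analysis | Exposure | Outcome | Method | F | SNPs | Estimate (95% CI) |",
      "|---|---|---|---|---|---|---|",
      sprintf("| %s | %s | %s | %s | %s | %s | %s |",
              df$analysis, df$exposure, df$outcome, df$method,
              ifelse(is.na(df$f_stat), "", sprintf("%.0f", df$f_stat)),
              ifelse(is.na(df$n_snp), "", as.character(df$n_snp)),
              fmt(df$estimate, df$ci_low, df$ci_high)))
    writeLines(lines, path)
  }
  invisible(path)
}
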