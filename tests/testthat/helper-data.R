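# fixtures built in code: small summary-statistic sets and harmonized sets

# consistent two-sided normal p-value, kept inside (0, 1]
p_from <- function(beta, se) pmax(2 * pnorm(-abs(beta / se)), 1e-300)

make_stats <- function(rsid, beta, se, ea = "A", oa = "G", eaf = 0.3,
                       n = 10000, trait = "trait", pval = NULL) {
  if (is.null(pval)) {
    pval <- p_from(beta, se)
  } else {
    # keep beta/se consistent with an explicitly chosen p-value
    beta <- sign(beta) * se * qnorm(pmin(pval, 1) / 2, lower.tail = FALSE)
  }
  summary_stats(data.frame(rsid = rsid, effect_allele = ea, other_allele = oa,
                           eaf = eaf, beta = beta, se = se, pval = pval,
                           n = n, stringsAsFactors = FALSE), trait = trait)
}

# harmonized set with aligned alleles throughout; optional second exposure
make_hs <- function(beta_x, se_x, beta_y, se_y, beta_x2 = NULL, se_x2 = NULL,
                    n = 10000) {
  k <- length(beta_x)
  rs <- sprintf("rs%03d", seq_len(k))
  ex <- make_stats(rs, beta_x, se_x, n = n, trait = "exposure")
  oy <- make_stats(rs, beta_y, se_y, n = n, trait = "outcome")
  hs <- harmonize(ex, oy)
  if (!is.null(beta_x2)) {
    e2 <- make_stats(rs, beta_x2, se_x2, n = n, trait = "exposure2")
    hs <- merge_second_exposure(hs, e2)
  }
  hs
}

# small, fast simulation configuration for unit tests
small_config <- function(...) {
  sim_config(n_consumption = 5000L, n_biomarker = 5000L, n_outcome = 5000L,
             panel = list(n_individuals = 300L, n_visits = 3L), ...)
}

write_stats_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
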