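# Per-variant directionality testing (Steiger), mechanism stratification of
# an instrument set, and exposure re-weighting ("scaling").

#' Steiger directionality test
#'
#' Compares the variance a variant explains in two traits. Correlations
#' `r_i = sqrt(r2_i)` are Fisher-transformed and the difference
#' standardized: `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`.
#' The assigned direction is by strict comparison of the r² values; an
#' exact tie is `"undetermined"`. All arguments are vectorized.
#'
#' @param r2_1,r2_2 variance explained in trait 1 and trait 2, in [0, 1).
#' @param n_1,n_2 the corresponding sample sizes (> 3).
#' @return data.frame with columns `r2_trait1`, `r2_trait2`, `z`, `pval`,
#'   `direction` (`"trait1_first"`, `"trait2_first"` or `"undetermined"`).
#' @export
steiger_test <- function(r2_1, n_1, r2_2, n_2) {
  if (any(r2_1 < 0 | r2_1 >= 1 | r2_2 < 0 | r2_2 >= 1))
    .stopf("steiger_test: r2 values must lie in [0, 1)")
  if (any(n_1 <= 3 | n_2 <= 3)) .stopf("steiger_test: requires n > 3")
  z <- (atanh(sqrt(r2_1)) - atanh(sqrt(r2_2))) /
    sqrt(1 / (n_1 - 3) + 1 / (n_2 - 3))
  direction <- ifelse(r2_1 > r2_2, "trait1_first",
                      ifelse(r2_2 > r2_1, "trait2_first", "undetermined"))
  data.frame(r2_trait1 = r2_1, r2_trait2 = r2_2, z = z,
             pval = 2 * stats::pnorm(-abs(z)), direction = direction,
             stringsAsFactors = FALSE)
}

#' Stratify instruments by Steiger direction between two exposures
#'
#' Computes each variant's variance explained in the primary and second
#' exposure of a two-exposure harmonized set and partitions the variants by
#' which exposure they are proximal to. Under the default `policy =
#' "point"` the strict r² comparison decides; `policy = "significant"`
#' additionally requires the Steiger p-value below `alpha`, excluding
#' non-significant variants. Exact ties are always excluded, never
#' arbitrarily assigned.
#'
#' @param data a `harmonized_set` carrying a second exposure (see
#'   [merge_second_exposure()]); the second exposure must be observed (no
#'   missing sentinels) for every variant.
#' @param policy `"point"` (default) or `"significant"`.
#' @param alpha significance level for `policy = "significant"`.
#' @param r2_mode `"tstat"` (default, frequency-free) or `"eaf"`, passed to
#'   [variance_explained()].
#' @return List with elements `primary_first` and `secondary_first`
#'   (harmonized subsets, `NULL` when empty), `records` (per-SNP Steiger
#'   table with `rsid`), and `excluded` (rsids removed with reasons).
#' @export
steiger_stratify <- function(data, policy = c("point", "significant"),
                             alpha = 0.05, r2_mode = c("tstat", "eaf")) {
  policy <- match.arg(policy)
  r2_mode <- match.arg(r2_mode)
  stopifnot(inherits(data, "harmonized_set"))
  s <- data$snps
  if (is.null(s$beta_x2) || any(s$x2_missing))
    .stopf("steiger_stratify: second exposure must be present for every SNP")
  r2_1 <- if (r2_mode == "tstat")
    variance_explained(s$beta_x, s$se_x, n = s$n_x, mode = "tstat")
  else variance_explained(s$beta_x, eaf = s$eaf_x, mode = "eaf")
  r2_2 <- if (r2_mode == "tstat")
    variance_explained(s$beta_x2, s$se_x2, n = s$n_x2, mode = "tstat")
  else .stopf("steiger_stratify: eaf mode unavailable for the second exposure")
  rec <- steiger_test(r2_1, s$n_x, r2_2, s$n_x2)
  rec <- cbind(rsid = s$rsid, rec, stringsAsFactors = FALSE)

  assign1 <- rec$direction == "trait1_first"
  assign2 <- rec$direction == "trait2_first"
  excl_reason <- ifelse(rec$direction == "undetermined", "tie", NA_character_)
  if (policy == "significant") {
    ns <- (assign1 | assign2) & rec$pval >= alpha
    excl_reason[ns] <- "not significant"
    assign1[ns] <- FALSE
    assign2[ns] <- FALSE
  }
  excluded <- data.frame(rsid = rec$rsid[!assign1 & !assign2],
                         reason = excl_reason[!assign1 & !assign2],
                         stringsAsFactors = FALSE)
  if (nrow(excluded)) message(sprintf(
    "steiger_stratify: excluded %d variant(s)", nrow(excluded)))
  mk <- function(keep) if (any(keep)) subset(data, rec$rsid[keep]) else NULL
  if (!any(assign1)) .warnf("steiger_stratify: primary-first stratum is empty")
  if (!any(assign2)) .warnf("steiger_stratify: secondary-first stratum is empty")
  list(primary_first = mk(assign1), secondary_first = mk(assign2),
       records = rec, excluded = excluded)
}

#' Swap the primary and second exposure of a harmonized set
#'
#' Returns a set whose primary exposure is the former second exposure
#' (betas, SEs and sample sizes swapped; outcome untouched). Running
#' [mr_ivw()] on the result gives the estimate "scaled" by the alternative
#' exposure. Applying the swap twice restores the original set.
#'
#' @param data a `harmonized_set` with a fully observed second exposure.
#' @return A `harmonized_set`.
#' @export
reweight_exposure <- function(data) {
  stopifnot(inherits(data, "harmonized_set"))
  s <- data$snps
  if (is.null(s$beta_x2) || any(is.na(s$beta_x2)) || any(s$x2_missing))
    .stopf("reweight_exposure: second exposure must be present for every SNP")
  tmp <- s[c("beta_x", "se_x", "n_x", "eaf_x")]
  s$beta_x <- s$beta_x2; s$se_x <- s$se_x2; s$n_x <- s$n_x2
  s$eaf_x <- s$eaf_x2
  s$beta_x2 <- tmp$beta_x; s$se_x2 <- tmp$se_x; s$n_x2 <- tmp$n_x
  s$eaf_x2 <- tmp$eaf_x
  .new_harmonized(s, data$dropped, data$x2_label, data$y_label,
                  x2_label = data$x_label)
}
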