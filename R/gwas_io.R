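# GWAS summary-statistic containers, delimited-file input, and allele
# harmonization across studies.

#' Construct a GWAS summary-statistics object
#'
#' Container for one trait's per-variant associations. Each record holds the
#' variant identifier, effect and other allele, optionally the effect-allele
#' frequency, the per-allele effect (in trait SD units when `sd_units` is
#' `TRUE`), its standard error, p-value and sample size.
#'
#' @param data data.frame with columns `rsid`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval`, `n` and optionally `eaf`.
#' @param trait character label for the trait.
#' @param sd_units logical; are betas on the standardized-trait scale?
#' @return An object of class `summary_stats`.
#' @export
summary_stats <- function(data, trait, sd_units = TRUE) {
  req <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pval", "n")
  miss <- setdiff(req, names(data))
  if (length(miss))
    .stopf("summary_stats: missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(data) == 0L) .stopf("summary_stats: no records")
  if (anyDuplicated(data$rsid))
    .stopf("summary_stats: duplicated rsid(s): %s",
           paste(unique(data$rsid[duplicated(data$rsid)]), collapse = ", "))
  data$effect_allele <- toupper(data$effect_allele)
  data$other_allele <- toupper(data$other_allele)
  bad <- !(data$effect_allele %in% c("A", "C", "G", "T")) |
    !(data$other_allele %in% c("A", "C", "G", "T")) |
    data$effect_allele == data$other_allele
  if (any(bad))
    .stopf("summary_stats: non-biallelic-SNP alleles for: %s",
           paste(data$rsid[bad], collapse = ", "))
  if (any(data$se <= 0)) .stopf("summary_stats: se must be > 0")
  if (!"eaf" %in% names(data)) data$eaf <- NA_real_
  if (any(!is.na(data$eaf) & (data$eaf <= 0 | data$eaf >= 1)))
    .stopf("summary_stats: eaf must lie in (0, 1)")
  if (any(data$pval <= 0 | data$pval > 1))
    .stopf("summary_stats: pval must lie in (0, 1]")
  # soft consistency check: |beta/se| against the two-sided normal p-value,
  # compared on the z scale with 10% relative tolerance
  z_obs <- abs(data$beta / data$se)
  z_imp <- stats::qnorm(pmin(data$pval, 1) / 2, lower.tail = FALSE)
  chk <- is.finite(z_imp) & z_obs > 0.1 & data$pval > 1e-290  # skip underflow
  off <- chk & abs(z_imp - z_obs) > 0.1 * pmax(z_obs, 1)
  if (any(off))
    .warnf("summary_stats('%s'): %d record(s) have p-values inconsistent with beta/se",
           trait, sum(off))
  rownames(data) <- NULL
  structure(list(trait = trait, sd_units = isTRUE(sd_units),
                 data = data[c("rsid", "effect_allele", "other_allele",
                               "eaf", "beta", "se", "pval", "n")]),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%d variants%s)\n", x$trait,
              nrow(x$data), if (x$sd_units) ", SD units" else ""))
  print(utils::head(x$data, 6L))
  if (nrow(x$data) > 6L) cat(sprintf("... %d more rows\n", nrow(x$data) - 6L))
  invisible(x)
}

#' Default column mapping for summary-statistic files
#'
#' Maps the package's canonical field names to file headers. Override any
#' element to absorb other header dialects.
#' @return Named character vector.
#' @export
default_column_map <- function() {
  c(rsid = "SNP", effect_allele = "EA", other_allele = "OA", eaf = "EAF",
    beta = "BETA", se = "SE", pval = "P", n = "N")
}

#' Read GWAS summary statistics from a delimited file
#'
#' Rows with unparseable or non-positive standard errors, unparseable betas,
#' or non-SNP alleles (indels, multi-allelic records) are skipped and
#' counted. Alleles are upper-cased. Gzip-compressed files are accepted.
#'
#' @param path file path (plain or `.gz`).
#' @param trait trait label; defaults to the file name.
#' @param column_map named character vector mapping canonical names
#'   (`rsid`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`,
#'   `n`) to file headers; see [default_column_map()]. `eaf` may be absent.
#' @param delimiter field separator, tab by default.
#' @param sd_units passed to [summary_stats()].
#' @return A `summary_stats` object.
#' @export
read_summary_stats <- function(path, trait = basename(path),
                               column_map = default_column_map(),
                               delimiter = "\t", sd_units = TRUE) {
  if (!file.exists(path)) .stopf("read_summary_stats: no such file: %s", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else path
  raw <- utils::read.delim(con, sep = delimiter, stringsAsFactors = FALSE,
                           check.names = FALSE)
  mandatory <- c("rsid", "effect_allele", "other_allele", "beta", "se",
                 "pval", "n")
  for (f in mandatory)
    if (!f %in% names(column_map) || !column_map[[f]] %in% names(raw))
      .stopf("read_summary_stats: column '%s' (mapped to '%s') not found in %s",
             f, if (f %in% names(column_map)) column_map[[f]] else "?", path)
  get_col <- function(f) raw[[column_map[[f]]]]
  d <- data.frame(rsid = as.character(get_col("rsid")),
                  effect_allele = toupper(as.character(get_col("effect_allele"))),
                  other_allele = toupper(as.character(get_col("other_allele"))),
                  beta = suppressWarnings(as.numeric(get_col("beta"))),
                  se = suppressWarnings(as.numeric(get_col("se"))),
                  pval = suppressWarnings(as.numeric(get_col("pval"))),
                  n = suppressWarnings(as.numeric(get_col("n"))),
                  stringsAsFactors = FALSE)
  d$eaf <- if ("eaf" %in% names(column_map) && column_map[["eaf"]] %in% names(raw))
    suppressWarnings(as.numeric(get_col("eaf"))) else NA_real_
  keep <- !is.na(d$beta) & !is.na(d$se) & d$se > 0 &
    d$effect_allele %in% c("A", "C", "G", "T") &
    d$other_allele %in% c("A", "C", "G", "T") &
    d$effect_allele != d$other_allele
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message(sprintf("read_summary_stats: skipped %d unparseable/non-SNP row(s)",
                    n_drop))
  d <- d[keep, , drop = FALSE]
  if (nrow(d) == 0L) .stopf("read_summary_stats: zero parseable rows in %s", path)
  # p-values of exactly 0 arise from underflow in source files; clamp
  d$pval[!is.na(d$pval) & d$pval == 0] <- 1e-300
  d$pval[is.na(d$pval)] <- .z_pval(d$beta[is.na(d$pval)], d$se[is.na(d$pval)])
  out <- summary_stats(d, trait = trait, sd_units = sd_units)
  attr(out, "n_skipped") <- n_drop
  out
}

#' Write summary statistics to a TSV file
#'
#' Inverse of [read_summary_stats()] under the default column map.
#' @param x `summary_stats` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(inherits(x, "summary_stats"))
  d <- x$data
  names(d) <- c("SNP", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.harmonized_columns <- c("rsid", "effect_allele", "other_allele", "eaf_x",
                         "beta_x", "se_x", "beta_y", "se_y", "n_x", "n_y")

.new_harmonized <- function(snps, dropped, x_label, y_label, x2_label = NULL) {
  rownames(snps) <- NULL
  structure(list(snps = snps, dropped = dropped, x_label = x_label,
                 y_label = y_label, x2_label = x2_label),
            class = "harmonized_set")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome association of every shared variant to the exposure's
#' effect allele. Swapped alleles negate the outcome beta (and reflect its
#' frequency); strand complements are resolved before the same rule; for
#' palindromic (A/T, C/G) variants, strand cannot be inferred from alleles,
#' so they are either dropped (`palindrome_policy = "drop"`) or kept only
#' when both effect-allele frequencies are informative — outside
#' `0.5 +/- eaf_window` on both sides — and aligned by frequency
#' concordance (`"infer"`, the default). Every removal is recorded with a
#' reason in the `dropped` slot.
#'
#' @param exposure,outcome `summary_stats` objects.
#' @param palindrome_policy `"infer"` or `"drop"`.
#' @param eaf_window half-width of the ambiguous frequency band around 0.5.
#' @return A `harmonized_set`: per-SNP exposure and outcome betas/SEs on a
#'   common effect allele, plus a drop log.
#' @export
harmonize <- function(exposure, outcome, palindrome_policy = c("infer", "drop"),
                      eaf_window = 0.08) {
  stopifnot(inherits(exposure, "summary_stats"), inherits(outcome, "summary_stats"))
  palindrome_policy <- match.arg(palindrome_policy)
  ex <- exposure$data
  oy <- outcome$data
  shared <- intersect(ex$rsid, oy$rsid)
  if (length(shared) == 0L)
    .stopf("harmonize: no shared rsids between '%s' and '%s'",
           exposure$trait, outcome$trait)
  ex <- ex[match(shared, ex$rsid), ]
  oy <- oy[match(shared, oy$rsid), ]

  keep <- logical(length(shared))
  reason <- character(length(shared))
  beta_y <- oy$beta
  eaf_y <- oy$eaf
  pal <- .is_palindromic(ex$effect_allele, ex$other_allele)

  same <- oy$effect_allele == ex$effect_allele & oy$other_allele == ex$other_allele
  swap <- oy$effect_allele == ex$other_allele & oy$other_allele == ex$effect_allele
  csame <- .complement(oy$effect_allele) == ex$effect_allele &
    .complement(oy$other_allele) == ex$other_allele
  cswap <- .complement(oy$effect_allele) == ex$other_allele &
    .complement(oy$other_allele) == ex$effect_allele

  for (i in seq_along(shared)) {
    if (pal[i]) {
      if (!(same[i] || swap[i] || csame[i] || cswap[i])) {
        reason[i] <- "allele mismatch"; next
      }
      if (palindrome_policy == "drop") { reason[i] <- "palindromic"; next }
      fx <- ex$eaf[i]; fy <- eaf_y[i]
      if (is.na(fx) || is.na(fy)) { reason[i] <- "palindrome without eaf"; next }
      if (abs(fx - 0.5) <= eaf_window || abs(fy - 0.5) <= eaf_window) {
        reason[i] <- "ambiguous palindrome"; next
      }
      # align by frequency: discordant frequencies imply the outcome effect
      # allele is the exposure's other allele (possibly on the other strand)
      if ((fx < 0.5) != (fy < 0.5)) {
        beta_y[i] <- -beta_y[i]
        eaf_y[i] <- 1 - eaf_y[i]
      }
      keep[i] <- TRUE
    } else if (same[i] || csame[i]) {
      keep[i] <- TRUE
    } else if (swap[i] || cswap[i]) {
      beta_y[i] <- -beta_y[i]
      if (!is.na(eaf_y[i])) eaf_y[i] <- 1 - eaf_y[i]
      keep[i] <- TRUE
    } else {
      reason[i] <- "allele mismatch"
    }
  }

  snps <- data.frame(rsid = shared,
                     effect_allele = ex$effect_allele,
                     other_allele = ex$other_allele,
                     eaf_x = ex$eaf,
                     beta_x = ex$beta, se_x = ex$se,
                     beta_y = beta_y, se_y = oy$se,
                     n_x = ex$n, n_y = oy$n,
                     pval_x = ex$pval,
                     stringsAsFactors = FALSE)[keep, , drop = FALSE]
  dropped <- data.frame(rsid = shared[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  if (nrow(snps) == 0L)
    .stopf("harmonize: every shared SNP was dropped (%s)",
           paste(unique(dropped$reason), collapse = "; "))
  .new_harmonized(snps, dropped, exposure$trait, outcome$trait)
}

#' Merge a second exposure into a harmonized set
#'
#' Populates `beta_x2`/`se_x2` using the same allele-alignment rules as
#' [harmonize()], aligned to the primary exposure's effect allele. Variants
#' absent from the second exposure are either dropped or retained with a
#' zero beta and a large sentinel SE (`missing_policy = "zero"`, flagged in
#' the `x2_missing` column).
#'
#' @param base a `harmonized_set`.
#' @param exposure2 `summary_stats` for the second exposure.
#' @param missing_policy `"drop"` or `"zero"`.
#' @param eaf_window ambiguity band for palindromic variants, as in
#'   [harmonize()].
#' @return A `harmonized_set` with second-exposure columns.
#' @export
merge_second_exposure <- function(base, exposure2,
                                  missing_policy = c("drop", "zero"),
                                  eaf_window = 0.08) {
  stopifnot(inherits(base, "harmonized_set"), inherits(exposure2, "summary_stats"))
  missing_policy <- match.arg(missing_policy)
  s <- base$snps
  e2 <- exposure2$data
  idx <- match(s$rsid, e2$rsid)
  beta2 <- se2 <- n2 <- eaf2 <- rep(NA_real_, nrow(s))
  x2_missing <- is.na(idx)
  drop_extra <- character(0)
  reason_extra <- character(0)
  for (i in seq_len(nrow(s))) {
    j <- idx[i]
    if (is.na(j)) next
    a1 <- s$effect_allele[i]; a2 <- s$other_allele[i]
    b1 <- e2$effect_allele[j]; b2 <- e2$other_allele[j]
    flip <- NA
    if (.is_palindromic(a1, a2)) {
      fx <- s$eaf_x[i]; f2 <- e2$eaf[j]
      if (is.na(fx) || is.na(f2) ||
          abs(fx - 0.5) <= eaf_window || abs(f2 - 0.5) <= eaf_window) {
        drop_extra <- c(drop_extra, s$rsid[i])
        reason_extra <- c(reason_extra, "ambiguous palindrome (second exposure)")
        next
      }
      flip <- (fx < 0.5) != (f2 < 0.5)
    } else if (b1 == a1 && b2 == a2) flip <- FALSE
    else if (b1 == a2 && b2 == a1) flip <- TRUE
    else if (.complement(b1) == a1 && .complement(b2) == a2) flip <- FALSE
    else if (.complement(b1) == a2 && .complement(b2) == a1) flip <- TRUE
    else {
      drop_extra <- c(drop_extra, s$rsid[i])
      reason_extra <- c(reason_extra, "allele mismatch (second exposure)")
      next
    }
    beta2[i] <- if (flip) -e2$beta[j] else e2$beta[j]
    se2[i] <- e2$se[j]
    n2[i] <- e2$n[j]
    eaf2[i] <- if (flip && !is.na(e2$eaf[j])) 1 - e2$eaf[j] else e2$eaf[j]
  }
  if (missing_policy == "zero") {
    beta2[x2_missing] <- 0
    se2[x2_missing] <- 1e3  # sentinel: effectively zero weight
    n2[x2_missing] <- NA_real_
  } else {
    drop_extra <- c(drop_extra, s$rsid[x2_missing])
    reason_extra <- c(reason_extra, rep("absent from second exposure",
                                        sum(x2_missing)))
    x2_missing <- x2_missing & FALSE
  }
  s$beta_x2 <- beta2
  s$se_x2 <- se2
  s$n_x2 <- n2
  s$eaf_x2 <- eaf2
  s$x2_missing <- x2_missing
  keep <- !s$rsid %in% drop_extra & !is.na(s$se_x2)
  dropped <- rbind(base$dropped,
                   data.frame(rsid = drop_extra, reason = reason_extra,
                              stringsAsFactors = FALSE))
  if (!any(keep))
    .stopf("merge_second_exposure: no SNPs retained")
  .new_harmonized(s[keep, , drop = FALSE], dropped, base$x_label, base$y_label,
                  x2_label = exposure2$trait)
}

#' Subset a harmonized set to named variants
#' @param x a `harmonized_set`.
#' @param rsids variants to keep.
#' @param ... unused.
#' @return A `harmonized_set` restricted to `rsids` (order preserved).
#' @export
subset.harmonized_set <- function(x, rsids, ...) {
  keep <- x$snps$rsid %in% rsids
  if (!any(keep)) .stopf("subset.harmonized_set: no matching rsids")
  .new_harmonized(x$snps[keep, , drop = FALSE], x$dropped, x$x_label,
                  x$y_label, x$x2_label)
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s%s\n", x$x_label, x$y_label,
              if (!is.null(x$x2_label)) paste0(" (+ ", x$x2_label, ")") else ""))
  cat(sprintf("  %d variants retained, %d dropped\n", nrow(x$snps),
              nrow(x$dropped)))
  invisible(x)
}

#' Number of variants in a harmonized set
#' @param x a `harmonized_set`.
#' @return Integer count.
#' @export
n_snps <- function(x) {
  stopifnot(inherits(x, "harmonized_set"))
  nrow(x$snps)
}

#' Write a harmonized set (and its drop log) to TSV
#' @param x `harmonized_set`.
#' @param path output path for the per-SNP table; the drop log goes to
#'   `paste0(path, ".dropped")` when any variant was removed.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(x, path) {
  stopifnot(inherits(x, "harmonized_set"))
  utils::write.table(x$snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(x$dropped) > 0L)
    utils::write.table(x$dropped, paste0(path, ".dropped"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
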