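# Instrument selection by p-value threshold, greedy LD clumping, and
# instrument-strength statistics (variance explained, F).

#' Select instruments by p-value threshold
#'
#' Retains exactly the variants with `pval < p_threshold` (strict), sorted
#' by ascending p-value.
#'
#' @param stats a `summary_stats` object.
#' @param p_threshold selection threshold in (0, 1); default `5e-7`.
#' @return An `instrument_set`: data.frame of `rsid`/`pval` plus the
#'   thresholds used and per-SNP provenance.
#' @export
select_instruments <- function(stats, p_threshold = 5e-7) {
  stopifnot(inherits(stats, "summary_stats"))
  if (!(p_threshold > 0 && p_threshold < 1))
    .stopf("select_instruments: p_threshold must lie in (0, 1)")
  d <- stats$data
  keep <- d$pval < p_threshold
  if (!any(keep))
    .warnf("select_instruments: no variant passes p < %g", p_threshold)
  sel <- d[keep, c("rsid", "pval")]
  sel <- sel[order(sel$pval, sel$rsid), , drop = FALSE]
  rownames(sel) <- NULL
  structure(list(snps = sel, p_threshold = p_threshold, clump_r2 = NA_real_,
                 provenance = data.frame(rsid = sel$rsid,
                                         status = rep("retained", nrow(sel)),
                                         clumped_by = rep(NA_character_,
                                                          nrow(sel)),
                                         stringsAsFactors = FALSE)),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %d variant(s), p < %g%s\n", nrow(x$snps),
              x$p_threshold,
              if (!is.na(x$clump_r2)) sprintf(", clumped at r2 <= %g", x$clump_r2)
              else ""))
  invisible(x)
}

.validate_ld <- function(ld) {
  if (!is.matrix(ld) || nrow(ld) != ncol(ld) ||
      is.null(rownames(ld)) || !identical(rownames(ld), colnames(ld)))
    .stopf("LD matrix must be square with matching rsid dimnames")
  if (max(abs(ld - t(ld))) > 1e-8) .stopf("LD matrix must be symmetric")
  if (any(abs(diag(ld) - 1) > 1e-8)) .stopf("LD matrix diagonal must be 1")
  if (any(ld < -1e-8 | ld > 1 + 1e-8)) .stopf("LD r2 values must lie in [0, 1]")
  invisible(ld)
}

#' Greedy LD clumping of a ranked instrument set
#'
#' Iterates candidates in ascending p-value order (rsid breaks ties) and
#' retains a variant iff its squared correlation with every previously
#' retained variant is at most `clump_r2`. The provenance records which
#' index variant removed each casualty.
#'
#' @param candidates an `instrument_set`.
#' @param ld square r² matrix with rsid dimnames covering all candidates.
#' @param clump_r2 retention threshold; default `0.001`.
#' @return The clumped `instrument_set`.
#' @export
clump_instruments <- function(candidates, ld, clump_r2 = 0.001) {
  stopifnot(inherits(candidates, "instrument_set"))
  .validate_ld(ld)
  snps <- candidates$snps
  missing <- setdiff(snps$rsid, rownames(ld))
  if (length(missing))
    .stopf("clump_instruments: candidate(s) missing from LD matrix: %s",
           paste(missing, collapse = ", "))
  ord <- order(snps$pval, snps$rsid)
  snps <- snps[ord, , drop = FALSE]
  retained <- character(0)
  status <- character(nrow(snps))
  clumped_by <- rep(NA_character_, nrow(snps))
  for (i in seq_len(nrow(snps))) {
    rs <- snps$rsid[i]
    if (length(retained)) {
      r2 <- ld[rs, retained]
      hit <- which(r2 > clump_r2)
      if (length(hit)) {
        status[i] <- "clumped-out"
        clumped_by[i] <- retained[hit[1L]]
        next
      }
    }
    status[i] <- "retained"
    retained <- c(retained, rs)
  }
  keep <- status == "retained"
  out <- snps[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(snps = out, p_threshold = candidates$p_threshold,
                 clump_r2 = clump_r2,
                 provenance = data.frame(rsid = snps$rsid, status = status,
                                         clumped_by = clumped_by,
                                         stringsAsFactors = FALSE)),
            class = "instrument_set")
}

#' Per-variant variance explained
#'
#' Two interchangeable approximations to the fraction of trait variance a
#' variant explains: `mode = "eaf"` uses the allele-frequency form
#' `2*eaf*(1-eaf)*beta^2` (betas must be in trait SD units);
#' `mode = "tstat"` uses `t^2/(t^2 + n - 2)` with `t = beta/se`, which
#' needs no frequency and is the default throughout the package.
#'
#' All arguments are vectorized.
#'
#' @param beta per-allele effect estimate(s).
#' @param se standard error(s); required for `mode = "tstat"`.
#' @param eaf effect-allele frequency(ies); required for `mode = "eaf"`.
#' @param n sample size(s); required for `mode = "tstat"` (must exceed 2).
#' @param mode `"tstat"` or `"eaf"`.
#' @return Numeric vector of r² fractions in [0, 1).
#' @export
variance_explained <- function(beta, se = NULL, eaf = NULL, n = NULL,
                               mode = c("tstat", "eaf")) {
  mode <- match.arg(mode)
  if (mode == "eaf") {
    if (is.null(eaf) || anyNA(eaf))
      .stopf("variance_explained(mode='eaf') requires eaf")
    return(2 * eaf * (1 - eaf) * beta^2)
  }
  if (is.null(se) || is.null(n) || anyNA(se) || anyNA(n))
    .stopf("variance_explained(mode='tstat') requires se and n")
  if (any(n <= 2)) .stopf("variance_explained(mode='tstat') requires n > 2")
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Instrument-strength F statistic
#'
#' Joint F statistic for `k` instruments explaining a combined fraction
#' `r2_total` of exposure variance in a sample of size `n`:
#' `F = (r2/(1-r2)) * (n-k-1)/k`. For approximately independent
#' (clumped) instruments, `r2_total` may be taken as the sum of per-SNP
#' values from [variance_explained()].
#'
#' @param r2_total combined variance explained, in [0, 1).
#' @param n exposure GWAS sample size.
#' @param k number of instruments.
#' @return The F statistic.
#' @export
f_statistic <- function(r2_total, n, k) {
  if (any(r2_total < 0) || any(r2_total >= 1))
    .stopf("f_statistic: r2_total must lie in [0, 1)")
  if (any(k < 1) || any(n <= k + 1))
    .stopf("f_statistic: requires n > k + 1 >= 2")
  (r2_total / (1 - r2_total)) * ((n - k - 1) / k)
}

#' Read / write a square LD matrix as TSV
#'
#' The file has a header row of rsids, one row per variant with the rsid in
#' the first column.
#' @param path file path.
#' @return `read_ld_matrix`: the validated r² matrix.
#' @export
read_ld_matrix <- function(path) {
  d <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1L]]
  storage.mode(m) <- "double"
  .validate_ld(m)
}

#' @rdname read_ld_matrix
#' @param ld square r² matrix with rsid dimnames.
#' @export
write_ld_matrix <- function(ld, path) {
  .validate_ld(ld)
  d <- data.frame(rsid = rownames(ld), ld, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
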