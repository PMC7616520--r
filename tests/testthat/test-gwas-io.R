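test_that("delimited summary files parse, normalize alleles and skip bad rows", {
  tf <- tempfile(fileext = ".tsv")
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"),
                   EA = c("a", "C", "G"), OA = c("g", "T", "A"),
                   EAF = c(0.2, 0.4, 0.45),
                   BETA = c(0.10, -0.05, 0.02),
                   SE = c(0.01, 0.012, 0.011),
                   P = p_from(c(0.10, -0.05, 0.02), c(0.01, 0.012, 0.011)),
                   N = 5000)
  write_stats_tsv(df, tf)
  ss <- read_summary_stats(tf, trait = "demo")
  expect_s3_class(ss, "summary_stats")
  expect_equal(nrow(ss$data), 3L)
  expect_equal(ss$data$effect_allele[1], "A")  # upper-cased
  expect_equal(ss$data$other_allele[1], "G")

  # se = 0 and indel rows are skipped with a count
  df2 <- df
  df2$SE[2] <- 0
  df2$EA[3] <- "AT"
  write_stats_tsv(df2, tf)
  expect_message(ss2 <- read_summary_stats(tf, trait = "demo"),
                 "skipped 2")
  expect_equal(ss2$data$rsid, "rs1")
  expect_equal(attr(ss2, "n_skipped"), 2L)

  # missing mandatory column is a configuration error
  write_stats_tsv(df[setdiff(names(df), "SE")], tf)
  expect_error(read_summary_stats(tf), "column 'se'")

  # zero parseable rows is an input error
  df3 <- df
  df3$BETA <- "x"
  write_stats_tsv(df3, tf)
  expect_error(suppressMessages(read_summary_stats(tf)), "zero parseable")
})

test_that("summary stats round-trip through TSV without loss", {
  ss <- make_stats(c("rs1", "rs2"), c(0.1, -0.2), c(0.01, 0.02))
  tf <- tempfile(fileext = ".tsv")
  write_summary_stats(ss, tf)
  back <- read_summary_stats(tf, trait = ss$trait)
  expect_equal(back$data, ss$data, tolerance = 1e-12)
})

test_that("summary_stats validates invariants and flags inconsistent p-values", {
  base <- data.frame(rsid = "rs1", effect_allele = "A", other_allele = "A",
                     eaf = 0.3, beta = 0.1, se = 0.01,
                     pval = p_from(0.1, 0.01), n = 1000)
  expect_error(summary_stats(base, "t"), "alleles")
  base$other_allele <- "G"
  base$se <- -1
  expect_error(summary_stats(base, "t"), "se")
  base$se <- 0.01
  base$pval <- 0.5  # wildly inconsistent with |beta/se| = 10
  expect_warning(summary_stats(base, "t"), "inconsistent")
  expect_error(summary_stats(rbind(base, base), "t"), "duplicated")
})

test_that("harmonization aligns swapped, complementary and palindromic alleles", {
  ex <- summary_stats(data.frame(
    rsid = c("rs_same", "rs_swap", "rs_comp", "rs_compswap", "rs_pal",
             "rs_pal_amb", "rs_mismatch"),
    effect_allele = c("A", "A", "A", "A", "A", "A", "A"),
    other_allele = c("G", "G", "G", "G", "T", "T", "G"),
    eaf = c(0.3, 0.3, 0.3, 0.3, 0.2, 0.50, 0.3),
    beta = 0.10, se = 0.01, pval = p_from(0.10, 0.01), n = 1e4), "exp")
  oy <- summary_stats(data.frame(
    rsid = c("rs_same", "rs_swap", "rs_comp", "rs_compswap", "rs_pal",
             "rs_pal_amb", "rs_mismatch"),
    effect_allele = c("A", "G", "T", "C", "A", "A", "A"),
    other_allele = c("G", "A", "C", "T", "T", "T", "C"),
    eaf = c(0.3, 0.7, 0.3, 0.7, 0.25, 0.52, 0.3),
    beta = c(-0.05, -0.05, -0.05, -0.05, -0.05, -0.05, -0.05),
    se = 0.02, pval = p_from(-0.05, 0.02), n = 1e4), "out")
  hs <- harmonize(ex, oy, palindrome_policy = "infer", eaf_window = 0.08)

  s <- hs$snps
  expect_equal(s$beta_y[s$rsid == "rs_same"], -0.05)
  expect_equal(s$beta_y[s$rsid == "rs_swap"], +0.05)   # swap flips sign
  expect_equal(s$beta_y[s$rsid == "rs_comp"], -0.05)   # complement identity
  expect_equal(s$beta_y[s$rsid == "rs_compswap"], +0.05)
  # palindrome with concordant informative frequencies is kept as aligned
  expect_equal(s$beta_y[s$rsid == "rs_pal"], -0.05)
  expect_equal(hs$dropped$reason[hs$dropped$rsid == "rs_pal_amb"],
               "ambiguous palindrome")
  expect_equal(hs$dropped$reason[hs$dropped$rsid == "rs_mismatch"],
               "allele mismatch")
  # dropped and retained partition the shared set exactly
  expect_setequal(c(s$rsid, hs$dropped$rsid), ex$data$rsid)

  # palindromic with discordant frequencies is sign-flipped
  oy2 <- oy
  oy2$data$eaf[oy2$data$rsid == "rs_pal"] <- 0.75
  hs2 <- harmonize(ex, oy2)
  expect_equal(hs2$snps$beta_y[hs2$snps$rsid == "rs_pal"], +0.05)

  # policy drop removes all palindromic variants
  hs3 <- harmonize(ex, oy, palindrome_policy = "drop")
  expect_false(any(c("rs_pal", "rs_pal_amb") %in% hs3$snps$rsid))
})

test_that("harmonizing an already-aligned pair is a no-op", {
  ex <- make_stats(c("rs1", "rs2"), c(0.1, 0.2), c(0.01, 0.01))
  oy <- make_stats(c("rs1", "rs2"), c(0.05, -0.03), c(0.02, 0.02))
  hs <- harmonize(ex, oy)
  expect_equal(hs$snps$beta_y, oy$data$beta)
  expect_equal(hs$snps$beta_x, ex$data$beta)
  expect_equal(nrow(hs$dropped), 0L)
})

test_that("negating exposure betas with swapped allele labels leaves IVW unchanged", {
  ex <- make_stats(sprintf("rs%d", 1:5), c(0.1, 0.2, -0.15, 0.08, 0.12),
                   rep(0.01, 5))
  oy <- make_stats(sprintf("rs%d", 1:5), c(0.02, 0.05, -0.01, 0.01, 0.04),
                   rep(0.02, 5))
  flipped <- ex
  flipped$data$beta <- -flipped$data$beta
  flipped$data$effect_allele <- ex$data$other_allele
  flipped$data$other_allele <- ex$data$effect_allele
  flipped$data$eaf <- 1 - ex$data$eaf
  b1 <- mr_ivw(harmonize(ex, oy))$beta
  b2 <- mr_ivw(harmonize(flipped, oy))$beta
  expect_equal(b1, b2, tolerance = 1e-12)
})

test_that("no shared rsids is an explicit error", {
  ex <- make_stats("rs1", 0.1, 0.01)
  oy <- make_stats("rs9", 0.1, 0.01)
  expect_error(harmonize(ex, oy), "no shared rsids")
})

test_that("second exposures merge under the same alignment rules", {
  hs <- make_hs(c(0.1, 0.2, 0.3), rep(0.01, 3), c(0.01, 0.02, 0.03),
                rep(0.02, 3))
  # aligned, swapped-allele, and absent records
  e2 <- summary_stats(data.frame(
    rsid = c("rs001", "rs002"),
    effect_allele = c("A", "G"), other_allele = c("G", "A"),
    eaf = c(0.3, 0.7), beta = c(0.5, 0.6), se = 0.05,
    pval = p_from(c(0.5, 0.6), 0.05), n = 9000), "exp2")

  m_drop <- merge_second_exposure(hs, e2, missing_policy = "drop")
  expect_equal(m_drop$snps$rsid, c("rs001", "rs002"))
  expect_equal(m_drop$snps$beta_x2, c(0.5, -0.6))  # swapped alleles negate
  expect_true("rs003" %in% m_drop$dropped$rsid)

  m_zero <- merge_second_exposure(hs, e2, missing_policy = "zero")
  expect_equal(nrow(m_zero$snps), 3L)
  expect_equal(m_zero$snps$beta_x2[m_zero$snps$rsid == "rs003"], 0)
  expect_true(m_zero$snps$x2_missing[m_zero$snps$rsid == "rs003"])
  expect_gte(m_zero$snps$se_x2[m_zero$snps$rsid == "rs003"], 100)
})

test_that("harmonized sets subset and serialize", {
  hs <- make_hs(c(0.1, 0.2, 0.3), rep(0.01, 3), c(0.01, 0.02, 0.03),
                rep(0.02, 3))
  sub <- subset(hs, c("rs002", "rs003"))
  expect_equal(n_snps(sub), 2L)
  tf <- tempfile()
  write_harmonized(hs, tf)
  back <- read.delim(tf)
  expect_equal(back$beta_x, hs$snps$beta_x)
})
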