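test_that("reconstructed allele-count tables reproduce published odds ratios", {
  # IGFBP7 region SNP: case alleles 26 B / 22 b, control 126 B / 18 b
  r <- snp_association(gt_from_allele_counts(26, 24, 126, 72))
  expect_equal(r$odds_ratio, 5.92, tolerance = 0.005)
  expect_equal(r$chi2, 24.25, tolerance = 0.001)
  expect_equal(r$freq_case, 26 / 48)
  expect_equal(r$freq_control, 126 / 144)
  # TMEM158 region SNP: 38/10 vs 59/85
  r2 <- snp_association(gt_from_allele_counts(38, 24, 59, 72))
  expect_equal(r2$odds_ratio, 5.47, tolerance = 0.005)
})

test_that("identical group frequencies give the null statistic", {
  t <- gt_from_rows(list(c(0L, 2L), c(2L, 0L)), list(c(0L, 2L), c(2L, 0L)))
  r <- snp_association(t)
  expect_equal(r$chi2, c(0, 0))
  expect_equal(r$p_value, c(1, 1))
  expect_equal(r$odds_ratio, c(1, 1))
})

test_that("allelic chi-square matches enumeration over all tiny cohorts", {
  combos <- expand.grid(c1 = 0:2, c2 = 0:2, n1 = 0:2, n2 = 0:2)
  for (i in seq_len(nrow(combos))) {
    x <- combos[i, ]
    t <- gt_from_rows(list(c(x$c1, 1L), c(x$c2, 1L)),
                      list(c(x$n1, 1L), c(x$n2, 1L)))
    r <- snp_association(t)[1, ]
    a <- x$c1 + x$c2; b <- 4 - a; cc <- x$n1 + x$n2; d <- 4 - cc
    obs <- rbind(c(a, b), c(cc, d))
    if (sum(colSums(obs) > 0) == 2) {
      expect_equal(r$chi2, chisq_table_oracle(obs), tolerance = 1e-12)
    } else {
      expect_equal(r$chi2, 0)
    }
  }
})

test_that("odds ratio is orientation invariant and at least 1", {
  set.seed(8)
  for (k in 1:25) {
    g_case <- sample(0:2, 10, replace = TRUE)
    g_ctrl <- sample(0:2, 14, replace = TRUE)
    t <- gt_from_rows(as.list(g_case), as.list(g_ctrl))
    tf <- gt_from_rows(as.list(2L - g_case), as.list(2L - g_ctrl))
    or1 <- snp_association(t)$odds_ratio
    or2 <- snp_association(tf)$odds_ratio
    expect_equal(or1, or2)
    if (!is.na(or1)) expect_gte(or1, 1)
  }
})

test_that("association statistics are invariant to animal ordering", {
  set.seed(9)
  cfg <- sim_config(n_snps = 50, n_controls_pool = 30, n_cases = 10, seed = 9,
                    n_assoc_snps = 5, n_epistatic_pairs = 2, n_genes = 40)
  coh <- simulate_cohort(cfg)
  t <- coh$genotypes
  perm <- sample(rownames(t$calls))
  tp <- subset_genotypes(t, animals = perm)
  expect_equal(snp_association(tp)[, -(1:3)], snp_association(t)[, -(1:3)],
               ignore_attr = TRUE)
})

test_that("dual significance rule is a strict conjunction over an empirical SD", {
  gd <- c(rep(0, 19), 5)
  rec <- data.frame(snp_id = sprintf("s%02d", 1:20), geno_diff = gd,
                    p_value = c(rep(0.5, 19), 1e-6))
  out <- significant_snps(rec)
  expect_identical(out$significant_ids, "s20")
  expect_true(out$records$passes_sd_rule[20])
  expect_false(any(out$records$passes_sd_rule[1:19]))

  # p passes but the genotype difference is only ~2 SD out: not significant
  set.seed(1)
  rec2 <- data.frame(snp_id = c(sprintf("s%02d", 1:20), "x"),
                     geno_diff = c(stats::rnorm(20, 0, 0.1), 0.22),
                     p_value = c(rep(0.5, 20), 5e-4))
  m <- mean(rec2$geno_diff); s <- sd(rec2$geno_diff)
  if (abs(0.22 - m) < 3 * s)  # construction check
    expect_length(significant_snps(rec2)$significant_ids, 0)

  # degenerate: all genotype differences equal, SD zero, nothing passes
  rec3 <- data.frame(snp_id = c("a", "b", "c"), geno_diff = c(1, 1, 1),
                     p_value = c(1e-9, 1e-9, 1e-9))
  expect_length(significant_snps(rec3)$significant_ids, 0)
  expect_error(significant_snps(rec3[1, ]), "2 finite")
})

test_that("9x2 epistasis chi-square matches the cell-by-cell oracle", {
  # joint-genotype counts: cases (4,2,0,2,4,0,0,0,0), controls (0,0,4,0,0,4,2,2,0)
  mk <- function(counts) {
    joint <- cbind(rep(0:2, each = 3), rep(0:2, 3))
    idx <- rep(seq_len(9), counts)
    lapply(idx, function(k) joint[k, ])
  }
  t <- gt_from_rows(mk(c(4, 2, 0, 2, 4, 0, 0, 0, 0)),
                    mk(c(0, 0, 4, 0, 0, 4, 2, 2, 0)))
  r <- epistasis_scan(t, c("s01", "s02"), p_threshold = 0.001)
  obs <- cbind(c(4, 2, 0, 2, 4, 0, 0, 0, 0), c(0, 0, 4, 0, 0, 4, 2, 2, 0))
  expect_equal(r$chi2, chisq_table_oracle(obs), tolerance = 1e-12)
  expect_identical(r$df, 8L)
  expect_equal(r$p_value, pchisq(chisq_table_oracle(obs), 8, lower.tail = FALSE))

  # random tiny instances, including missing calls and empty rows
  set.seed(14)
  for (k in 1:20) {
    gc <- matrix(sample(c(0:2, NA), 12, replace = TRUE, prob = c(rep(.3, 3), .1)), ncol = 2)
    gn <- matrix(sample(c(0:2, NA), 16, replace = TRUE, prob = c(rep(.3, 3), .1)), ncol = 2)
    t2 <- gt_from_rows(split(gc, row(gc)), split(gn, row(gn)))
    r2 <- epistasis_scan(t2, c("s01", "s02"))
    tab <- function(g) {
      ok <- !is.na(g[, 1]) & !is.na(g[, 2])
      tabulate(3 * g[ok, 1] + g[ok, 2] + 1, nbins = 9)
    }
    obs2 <- cbind(tab(gc), tab(gn))
    if (r2$degenerate) {
      expect_true(sum(rowSums(obs2) > 0) < 2 || any(colSums(obs2) == 0))
    } else {
      expect_equal(r2$chi2, chisq_table_oracle(obs2), tolerance = 1e-12)
    }
  }
})

test_that("identical joint distributions give a null pair; counts are C(n,2)", {
  rows <- list(c(0L, 0L), c(1L, 1L), c(2L, 2L), c(0L, 1L))
  t <- gt_from_rows(rows, c(rows, rows))
  r <- epistasis_scan(t, c("s01", "s02"))
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)

  set.seed(5)
  calls <- matrix(sample(0:2, 20 * 10, replace = TRUE), 20,
                  dimnames = list(paste0("a", 1:20), sprintf("s%02d", 1:10)))
  storage.mode(calls) <- "integer"
  t2 <- genotype_table(calls, data.frame(snp_id = colnames(calls),
                                         chrom = "chr1",
                                         pos = seq(1e5, 1e6, length.out = 10)),
                       setNames(rep(c("case", "control"), 10), rownames(calls)))
  r2 <- epistasis_scan(t2, colnames(calls))
  expect_equal(nrow(r2), choose(10, 2))
})

test_that("proximity flag marks same-chromosome pairs under 100 kb", {
  set.seed(6)
  calls <- matrix(sample(0:2, 12 * 3, replace = TRUE), 12,
                  dimnames = list(paste0("a", 1:12), c("s1", "s2", "s3")))
  storage.mode(calls) <- "integer"
  map <- data.frame(snp_id = c("s1", "s2", "s3"),
                    chrom = c("chr1", "chr1", "chr2"),
                    pos = c(1e6, 1e6 + 5e4, 1e6 + 2e4))
  t <- genotype_table(calls, map,
                      setNames(rep(c("case", "control"), 6), rownames(calls)))
  r <- epistasis_scan(t, c("s1", "s2", "s3"))
  flagged <- r$proximity_flag[r$snp_a == "s1" & r$snp_b == "s2"]
  expect_true(flagged)
  expect_false(any(r$proximity_flag[r$snp_b == "s3" | r$snp_a == "s3"]))
})

test_that("composite LD r2 follows the squared genotype correlation", {
  t <- gt_from_rows(list(c(0L, 0L, 0L), c(0L, 1L, 1L), c(2L, 2L, 0L)),
                    list(c(2L, 0L, 2L), c(0L, 1L, 1L)))
  expect_equal(ld_r2(t, "s01", "s01"), 1.0)
  # perfect negative correlation is still r2 = 1
  t2 <- gt_from_rows(list(c(0L, 2L), c(0L, 2L)), list(c(2L, 0L), c(2L, 0L)))
  expect_equal(ld_r2(t2, "s01", "s02"), 1.0)
  t3 <- gt_from_rows(list(c(0L, 1L), c(1L, 1L), c(2L, 0L), c(0L, 2L), c(1L, 1L)),
                     list())
  expect_equal(ld_r2(t3, "s01", "s02"), 5 / 7)
  t4 <- gt_from_rows(list(c(1L, 0L), c(1L, 1L), c(1L, 2L)), list())
  expect_true(is.na(ld_r2(t4, "s01", "s02")))
})
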