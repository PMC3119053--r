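test_that("acquisition removes probes undetectable in every hybridisation", {
  # ratio 1.5 everywhere: removed; ratio 2.5 in a single hybridisation: kept
  bad <- intensity_rows("p_bad", "gA", fg = rep(150, 20), bg = rep(100, 20))
  good <- intensity_rows("p_good", "gB", fg = c(250, rep(150, 19)),
                         bg = rep(100, 20))
  out <- acquire(rbind(bad, good))
  expect_false("gA" %in% out$gene_id)
  expect_true("gB" %in% out$gene_id)
  expect_equal(attr(out, "n_probes_snr_removed"), 1)
  expect_error(acquire(bad), "all probes")
})

test_that("multi-probe genes collapse to the most abundant probe", {
  p1 <- intensity_rows("p_lo", "gA", fg = rep(600, 4), bg = rep(100, 4))
  p2 <- intensity_rows("p_hi", "gA", fg = rep(900, 4), bg = rep(100, 4))
  out <- acquire(rbind(p1, p2))
  expect_equal(nrow(out), 4)
  expect_equal(attr(out, "n_probes_collapsed"), 1)
  expect_equal(unique(out$y), log2(800))
})

test_that("background correction floors at 1 before the log2 transform", {
  r <- intensity_rows("p1", "gA", fg = c(1024, 50), bg = c(0, 100))
  out <- acquire(r)
  expect_equal(out$y, c(10, 0))
})

test_that("EM-REML reproduces lme4 REML components on a shared fit", {
  skip_if_not_installed("lme4")
  cfg <- sim_config(n_genes = 40, n_de_genes = 4, seed = 9,
                    snr_fail_fraction = 0, duplicate_probe_fraction = 0)
  coh <- simulate_cohort(cfg)
  expr <- acquire(simulate_microarray(cfg, coh$truth))
  fit <- fit_normalization_model(expr, tol = 1e-9, max_iter = 10000)
  d <- expr
  d$cell <- interaction(d$array_id, d$print_block, d$dye)
  lf <- lme4::lmer(y ~ 0 + cell + (1 | gene_id) + (1 | array_id:gene_id) +
                     (1 | dye:gene_id) + (1 | variety:gene_id), data = d,
                   control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                               check.nobs.vs.nRE = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(lf))
  ref <- setNames(vc$vcov, vc$grp)
  expect_equal(fit$variance_components[["gene"]], ref[["gene_id"]], tolerance = 1e-4)
  expect_equal(fit$variance_components[["array_gene"]], ref[["array_id:gene_id"]],
               tolerance = 1e-4)
  expect_equal(fit$variance_components[["dye_gene"]], ref[["dye:gene_id"]],
               tolerance = 1e-4)
  expect_equal(fit$variance_components[["variety_gene"]], ref[["variety:gene_id"]],
               tolerance = 1e-4)
  expect_equal(fit$variance_components[["residual"]], ref[["Residual"]],
               tolerance = 1e-4)
})

test_that("the REML objective never decreases and components stay non-negative", {
  cfg <- sim_config(n_genes = 30, n_de_genes = 2, seed = 13)
  coh <- simulate_cohort(cfg)
  expr <- acquire(simulate_microarray(cfg, coh$truth))
  fit <- fit_normalization_model(expr)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_true(all(fit$variance_components >= 0))

  # record order must not matter
  set.seed(2)
  expr2 <- expr[sample(nrow(expr)), ]
  fit2 <- fit_normalization_model(expr2)
  expect_equal(fit2$variance_components, fit$variance_components, tolerance = 1e-8)
  expect_equal(fit2$normalized_expression, fit$normalized_expression,
               tolerance = 1e-8)
})

test_that("zero-noise data returns planted variety effects up to a gene constant", {
  cfg <- sim_config(n_genes = 40, n_de_genes = 4, de_effect_sd = 2,
                    noise_sds = c(gene = 0, array_gene = 0, dye_gene = 0,
                                  variety_gene = 0, residual = 0),
                    snr_fail_fraction = 0, duplicate_probe_fraction = 0, seed = 3)
  coh <- simulate_cohort(cfg)
  expr <- acquire(simulate_microarray(cfg, coh$truth))
  fit <- suppressWarnings(fit_normalization_model(expr))
  vg <- fit$variety_gene_solutions
  planted <- matrix(0, nrow(vg), 5, dimnames = dimnames(vg))
  for (r in seq_len(nrow(coh$truth$de_genes)))
    planted[coh$truth$de_genes$gene_id[r], c("PBW", "PBB")] <-
      coh$truth$de_genes$effect[r]
  expect_lt(max(abs((vg - rowMeans(vg)) - (planted - rowMeans(planted)))), 0.01)
})

test_that("contrast arithmetic reproduces the published worked examples", {
  ctr <- compute_contrasts(table1_expression())
  atrn <- ctr[ctr$gene_id == "ATRN", ]
  expect_equal(atrn$DE3, 8.42 - 6.15)            # 2.27
  expect_equal(atrn$DE5, 8.42 - (6.15 + 8.99) / 2)  # 0.85
  igfbp7 <- ctr[ctr$gene_id == "IGFBP7", ]
  expect_equal(igfbp7$DE3, 9.70 - 11.37)         # -1.67
  expect_equal(igfbp7$DE6, (9.70 + 10.35) / 2 - (11.37 + 10.70 + 9.87) / 3)
})

test_that("contrasts vanish for flat genes and ignore per-gene constants", {
  flat <- matrix(7.7, 3, 5, dimnames = list(paste0("g", 1:3), VARIETIES))
  expect_true(all(abs(as.matrix(compute_contrasts(flat)[, -1])) < 1e-12))
  x <- table1_expression()
  shifted <- x + matrix(c(1, -2, 0.5, 3), nrow(x), 5)
  expect_equal(compute_contrasts(shifted)[, -1], compute_contrasts(x)[, -1])
  expect_error(compute_contrasts(x[, 1:4]), "missing variety: RSB")
})

test_that("DE calling flags beyond 2.57 across-gene SDs, per contrast", {
  set.seed(31)
  vals <- matrix(rnorm(100 * 7, 0, 0.1), 100,
                 dimnames = list(NULL, paste0("DE", 1:7)))
  vals[1, 3] <- 10
  ctr <- data.frame(gene_id = sprintf("g%03d", 1:100), vals)
  de <- call_de(ctr)
  expect_true(de$de_DE3[1])
  expect_equal(sum(de$de_DE3), 1)
  expect_false(any(de$de_DE1[1], de$de_DE2[1], de$de_DE4[1]))
  expect_equal(de$n_de_contrasts[1], 1)
  expect_true("g001" %in% de_genes(de, 1))
  expect_length(de_genes(de, 4), 0)

  # standard-normal contrast values: flagged fraction near the 2.57 tail mass
  set.seed(32)
  big <- data.frame(gene_id = seq_len(20000),
                    matrix(rnorm(20000 * 7), 20000,
                           dimnames = list(NULL, paste0("DE", 1:7))))
  deb <- call_de(big)
  frac <- mean(as.matrix(deb[, paste0("de_DE", 1:7)]))
  expect_equal(frac, 2 * pnorm(-2.57), tolerance = 0.15)

  ctr0 <- data.frame(gene_id = c("a", "b", "c"),
                     matrix(c(rep(1, 3), rnorm(18)), 3,
                            dimnames = list(NULL, paste0("DE", 1:7))))
  expect_warning(call_de(ctr0), "zero standard deviation")
})

test_that("piebald-facing contrasts carry the top correlations for shared signal", {
  set.seed(41)
  n <- 300
  s <- rnorm(n, 0, sqrt(6))           # shared piebald signal
  noise <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, VARIETIES))
  x <- noise
  x[, c("PBW", "PBB", "RSW", "RSB")] <- x[, c("PBW", "PBB", "RSW", "RSB")] + s
  rownames(x) <- sprintf("g%03d", 1:n)
  cc <- contrast_correlations(call_de(compute_contrasts(x)))
  cors <- cc$correlations
  ut <- cors[upper.tri(cors)]
  top3 <- sort(ut, decreasing = TRUE)[3]
  expect_gte(cors["DE3", "DE5"], top3)
  expect_gte(cors["DE3", "DE6"], top3)
  expect_gte(cors["DE5", "DE6"], top3)
})

test_that("colour categories follow the piebald score and mark absent genes", {
  x <- table1_expression()
  cc <- contrast_correlations(call_de(compute_contrasts(x)),
                              all_genes = c(rownames(x), "GHOST"))
  expect_equal(cc$colours$colour_category[cc$colours$gene_id == "GHOST"], "absent")
  expect_equal(dim(cc$correlations), c(7, 7))
  # duplicated / anti-correlated columns
  ctr <- data.frame(gene_id = sprintf("g%d", 1:50),
                    matrix(rnorm(50 * 7), 50, dimnames = list(NULL, paste0("DE", 1:7))))
  ctr$DE2 <- ctr$DE1
  ctr$DE3 <- -ctr$DE1
  cc2 <- contrast_correlations(ctr)
  expect_equal(cc2$correlations["DE1", "DE2"], 1)
  expect_equal(cc2$correlations["DE1", "DE3"], -1)
})
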