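# Small builders and independent brute-force oracles shared across tests.

# genotype_table from per-animal genotype vectors
gt_from_rows <- function(case_rows, ctrl_rows, chrom = NULL, pos = NULL) {
  calls <- do.call(rbind, c(case_rows, ctrl_rows))
  storage.mode(calls) <- "integer"
  rownames(calls) <- c(sprintf("case%02d", seq_along(case_rows)),
                       sprintf("ctrl%02d", seq_along(ctrl_rows)))
  m <- ncol(calls)
  colnames(calls) <- sprintf("s%02d", seq_len(m))
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  map <- data.frame(snp_id = colnames(calls), chrom = chrom, pos = pos)
  labels <- stats::setNames(rep(c("case", "control"),
                                c(length(case_rows), length(ctrl_rows))),
                            rownames(calls))
  genotype_table(calls, map, labels)
}

# genotype_table realizing given B-allele counts per group at one SNP
gt_from_allele_counts <- function(b_case, n_case, b_ctrl, n_ctrl) {
  fill <- function(b, n) {
    g <- integer(n)
    g[seq_len(b %/% 2)] <- 2L
    if (b %% 2) g[b %/% 2 + 1] <- 1L
    g
  }
  gt_from_rows(as.list(fill(b_case, n_case)), as.list(fill(b_ctrl, n_ctrl)))
}

# Pearson chi-square by explicit cell-by-cell enumeration
chisq_table_oracle <- function(obs) {
  rt <- rowSums(obs); ct <- colSums(obs); n <- sum(obs)
  chi2 <- 0
  for (i in seq_len(nrow(obs))) for (j in seq_len(ncol(obs))) {
    e <- rt[i] * ct[j] / n
    if (e > 0) chi2 <- chi2 + (obs[i, j] - e)^2 / e
  }
  chi2
}

# per-pair per-SNP enumeration of mean IBS sharing
sharing_oracle <- function(calls) {
  n <- nrow(calls)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(calls), rownames(calls)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- c()
    for (s in seq_len(ncol(calls))) {
      gi <- calls[i, s]; gj <- calls[j, s]
      if (!is.na(gi) && !is.na(gj)) acc <- c(acc, (2 - abs(gi - gj)) / 2)
    }
    out[i, j] <- if (length(acc)) mean(acc) else NA_real_
  }
  out
}

# Table 1 normalized expression rows used as contrast-arithmetic inputs
table1_expression <- function() {
  m <- rbind(ATRN   = c(6.15, 8.42, 8.43, 8.99, 7.59),
             CD9    = c(9.63, 9.01, 9.32, 9.58, 8.33),
             IGFBP7 = c(11.37, 9.70, 10.35, 10.70, 9.87),
             KRT31  = c(14.06, 12.11, 11.25, 12.57, 12.77))
  colnames(m) <- c("NOR", "PBW", "PBB", "RSW", "RSB")
  m
}

# long-format intensity records for hand-built acquisition tests
intensity_rows <- function(probe_id, gene_id, fg, bg, n_hybs = length(fg)) {
  data.frame(hyb_id = sprintf("hyb%02d", seq_len(n_hybs)),
             array_id = sprintf("array%02d", seq_len(n_hybs)),
             print_block = 1L,
             dye = rep(c("red", "green"), length.out = n_hybs),
             variety = rep(VARIETIES, length.out = n_hybs),
             probe_id = probe_id, gene_id = gene_id,
             foreground = fg, background = bg,
             stringsAsFactors = FALSE)
}
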