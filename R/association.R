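#' Single-SNP allelic case-control association
#'
#' For every SNP, over non-missing calls: B-allele frequencies per group, the
#' genotype-mean difference (cases minus controls on the 0-2 scale), the
#' Pearson chi-square on the 2x2 allele-count table (no continuity
#' correction, 1 df), and the allelic odds ratio oriented to be >= 1. The
#' significance flags are filled by \code{\link{significant_snps}}.
#'
#' @param table A \code{\link{genotype_table}} with at least one case and one
#'   control.
#' @return Data frame of class \code{association_records} with one row per
#'   SNP: snp_id, chrom, pos, freq_case, freq_control, geno_diff, chi2, df,
#'   p_value, odds_ratio, passes_sd_rule, significant. SNPs with no calls in
#'   a group get missing statistics; their count is kept in attribute
#'   \code{n_degenerate} (with a warning).
#' @export
snp_association <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  cs <- case_ids(table); ct <- control_ids(table)
  if (!length(cs) || !length(ct)) stop("need at least one case and one control")
  gcase <- table$calls[cs, , drop = FALSE]
  gctrl <- table$calls[ct, , drop = FALSE]
  n_case <- colSums(!is.na(gcase))
  n_ctrl <- colSums(!is.na(gctrl))
  b_case <- colSums(gcase, na.rm = TRUE)
  b_ctrl <- colSums(gctrl, na.rm = TRUE)
  a <- as.numeric(b_case)               # case B alleles
  b <- 2 * n_case - a                   # case b alleles
  cc <- as.numeric(b_ctrl)              # control B alleles
  d <- 2 * n_ctrl - cc                  # control b alleles
  freq_case <- ifelse(n_case > 0, a / (2 * n_case), NA_real_)
  freq_control <- ifelse(n_ctrl > 0, cc / (2 * n_ctrl), NA_real_)
  geno_diff <- colMeans(gcase, na.rm = TRUE) - colMeans(gctrl, na.rm = TRUE)
  geno_diff[n_case == 0 | n_ctrl == 0] <- NA_real_
  n_tot <- a + b + cc + d
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  denom <- r1 * r2 * c1 * c2
  chi2 <- ifelse(denom > 0, n_tot * (a * d - b * cc)^2 / denom,
                 ifelse(r1 > 0 & r2 > 0, 0, NA_real_))
  p_value <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  or_raw <- ifelse(b * cc > 0, (a * d) / (b * cc), NA_real_)
  or_raw[!is.na(or_raw) & or_raw == 0] <- NA_real_   # zero cell: no pseudo-count
  odds_ratio <- ifelse(is.na(or_raw), NA_real_, pmax(or_raw, 1 / or_raw))
  n_degenerate <- sum(n_case == 0 | n_ctrl == 0)
  if (n_degenerate > 0)
    warning(n_degenerate, " SNP(s) with no calls in one group; statistics set missing")
  out <- data.frame(snp_id = colnames(table$calls),
                    chrom = table$map$chrom, pos = table$map$pos,
                    freq_case = freq_case, freq_control = freq_control,
                    geno_diff = as.numeric(geno_diff),
                    chi2 = chi2, df = 1L, p_value = p_value,
                    odds_ratio = odds_ratio,
                    passes_sd_rule = NA, significant = NA,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_degenerate") <- n_degenerate
  class(out) <- c("association_records", "data.frame")
  out
}

#' Dual significance rule for single-SNP association
#'
#' A SNP is significant when its genotype-mean difference lies beyond
#' \code{sd_multiplier} standard deviations from the mean of all genotype
#' differences (genome-wide empirical distribution) AND its allelic
#' chi-square p-value is below \code{p_threshold}.
#'
#' @param records Output of \code{\link{snp_association}}.
#' @param p_threshold Chi-square p-value cut-off (default 0.001).
#' @param sd_multiplier Outlier cut-off in standard deviations (default 3).
#' @return List with \code{records} (flags filled) and \code{significant_ids}.
#' @export
significant_snps <- function(records, p_threshold = 0.001, sd_multiplier = 3.0) {
  gd <- records$geno_diff
  ok <- is.finite(gd)
  if (sum(ok) < 2) stop("need >= 2 finite genotype differences")
  m <- mean(gd[ok]); s <- stats::sd(gd[ok])
  records$passes_sd_rule <- !is.na(gd) & abs(gd - m) > sd_multiplier * s
  records$significant <- records$passes_sd_rule &
    !is.na(records$p_value) & records$p_value < p_threshold
  list(records = records,
       significant_ids = records$snp_id[records$significant])
}

#' All-pairs two-locus epistasis contingency scan
#'
#' For every unordered pair of the given SNPs, builds the 9x2 contingency
#' table of joint-genotype counts (nine two-locus genotype combinations by
#' case/control) over animals non-missing at both loci, and computes the
#' Pearson chi-square with the degrees of freedom fixed at 8; cells with zero
#' expected count contribute nothing. Pairs on the same chromosome closer
#' than \code{proximity_bp} are flagged as possible linkage disequilibrium
#' rather than epistasis.
#'
#' @param table A \code{\link{genotype_table}}.
#' @param snp_ids SNPs to scan (>= 2, all present in the table).
#' @param p_threshold Significance cut-off (default 0.001).
#' @param proximity_bp Physical proximity flag threshold (default 100 kb).
#' @return Data frame with one row per unordered pair: snp_a, snp_b, chi2,
#'   df (8), p_value, proximity_flag, significant, degenerate. Pairs with
#'   fewer than two distinct observed joint genotypes get missing statistics
#'   and \code{degenerate = TRUE}.
#' @export
epistasis_scan <- function(table, snp_ids, p_threshold = 0.001,
                           proximity_bp = 1e5) {
  stopifnot(inherits(table, "genotype_table"))
  if (length(snp_ids) < 2) stop("need >= 2 SNPs to scan")
  missing_s <- setdiff(snp_ids, colnames(table$calls))
  if (length(missing_s)) stop("SNPs not in table: ", paste(missing_s, collapse = ", "))
  cs <- case_ids(table); ct <- control_ids(table)
  if (!length(cs) || !length(ct)) stop("need at least one case and one control")
  m <- length(snp_ids)
  g_case <- table$calls[cs, snp_ids, drop = FALSE]
  g_ctrl <- table$calls[ct, snp_ids, drop = FALSE]

  # genotype-class indicator matrices; crossprod gives all pairwise 3x3
  # joint-genotype counts in one shot
  indicator <- function(g) {
    n <- nrow(g)
    ind <- matrix(0, n, 3L * m)
    for (gt in 0:2) {
      hit <- which(!is.na(g) & g == gt, arr.ind = TRUE)
      ind[cbind(hit[, 1], 3L * (hit[, 2] - 1L) + gt + 1L)] <- 1
    }
    ind
  }
  cc_case <- crossprod(indicator(g_case))
  cc_ctrl <- crossprod(indicator(g_ctrl))

  pair_idx <- utils::combn(m, 2)
  ia <- pair_idx[1, ]; ib <- pair_idx[2, ]
  n_pairs <- length(ia)
  o_case <- matrix(0, n_pairs, 9)
  o_ctrl <- matrix(0, n_pairs, 9)
  k <- 0
  for (ga in 0:2) for (gb in 0:2) {
    k <- k + 1
    rows <- 3L * (ia - 1L) + ga + 1L
    cols <- 3L * (ib - 1L) + gb + 1L
    o_case[, k] <- cc_case[cbind(rows, cols)]
    o_ctrl[, k] <- cc_ctrl[cbind(rows, cols)]
  }
  row_tot <- o_case + o_ctrl
  c1 <- rowSums(o_case); c2 <- rowSums(o_ctrl)
  n_tot <- c1 + c2
  e_case <- row_tot * (c1 / n_tot)
  e_ctrl <- row_tot * (c2 / n_tot)
  sq <- function(o, e) {
    x <- (o - e)^2 / e
    x[e == 0] <- 0          # zero expected count contributes nothing
    x
  }
  chi2 <- rowSums(sq(o_case, e_case)) + rowSums(sq(o_ctrl, e_ctrl))
  degenerate <- rowSums(row_tot > 0) < 2 | c1 == 0 | c2 == 0
  chi2[degenerate] <- NA_real_
  p_value <- stats::pchisq(chi2, df = 8, lower.tail = FALSE)

  pos <- table$map$pos[match(snp_ids, table$map$snp_id)]
  chrom <- table$map$chrom[match(snp_ids, table$map$snp_id)]
  proximity_flag <- chrom[ia] == chrom[ib] & abs(pos[ia] - pos[ib]) < proximity_bp
  out <- data.frame(snp_a = snp_ids[ia], snp_b = snp_ids[ib],
                    chi2 = chi2, df = 8L, p_value = p_value,
                    proximity_flag = proximity_flag,
                    significant = !is.na(p_value) & p_value < p_threshold,
                    degenerate = degenerate,
                    stringsAsFactors = FALSE)
  class(out) <- c("epistasis_records", "data.frame")
  out
}

#' Composite linkage disequilibrium r-squared between two SNPs
#'
#' Squared Pearson correlation of the genotype codes over jointly non-missing
#' animals (composite LD, no phasing).
#'
#' @param table A \code{\link{genotype_table}}.
#' @param snp_a,snp_b SNP ids.
#' @return r-squared in [0, 1], or \code{NA} when either SNP has zero
#'   variance or fewer than two jointly observed animals.
#' @export
ld_r2 <- function(table, snp_a, snp_b) {
  stopifnot(inherits(table, "genotype_table"))
  for (s in c(snp_a, snp_b))
    if (!s %in% colnames(table$calls)) stop("SNP not in table: ", s)
  ga <- table$calls[, snp_a]; gb <- table$calls[, snp_b]
  ok <- !is.na(ga) & !is.na(gb)
  if (sum(ok) < 2) return(NA_real_)
  if (stats::sd(ga[ok]) == 0 || stats::sd(gb[ok]) == 0) return(NA_real_)
  stats::cor(ga[ok], gb[ok])^2
}

#' Write association or epistasis records to TSV
#'
#' @param records A data frame of records.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
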