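#' Map SNPs to their nearest gene with distance categories
#'
#' Distance is 0 for a SNP inside a gene's 1-based inclusive interval,
#' otherwise the distance to the nearer interval edge; the nearest gene on
#' the same chromosome wins, with ties broken towards the gene with the
#' smaller start (then lexicographically smaller id). Categories: intragenic
#' (distance 0), cis (<= \code{cis_bp}), proximal (<= \code{proximal_bp}),
#' distal beyond that; SNPs on chromosomes without genes are unmapped.
#'
#' @param snps Data frame with snp_id, chrom, pos (a \code{genotype_table}
#'   map, or the table itself).
#' @param genes Gene annotation data frame (gene_id, chrom, start, end).
#' @param cis_bp,proximal_bp,region_bp Distance thresholds in bp (defaults
#'   2,500 / 20,000 / 1,000,000).
#' @return Data frame: snp_id, nearest_gene_id, distance_bp, category,
#'   genes_within_region (comma-separated gene ids whose edge distance is
#'   <= \code{region_bp}).
#' @export
map_snps_to_genes <- function(snps, genes, cis_bp = 2500, proximal_bp = 20000,
                              region_bp = 1e6) {
  if (inherits(snps, "genotype_table")) snps <- snps$map
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  n <- nrow(snps)
  nearest <- rep(NA_character_, n)
  dist_bp <- rep(NA_real_, n)
  within <- rep("", n)
  for (ch in unique(snps$chrom)) {
    si <- which(snps$chrom == ch)
    gs <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(gs)) next
    # order genes by (start, gene_id) so which.min lands on the tie-rule winner
    gs <- gs[order(gs$start, gs$gene_id), , drop = FALSE]
    for (i in si) {
      p <- snps$pos[i]
      dd <- pmax(gs$start - p, p - gs$end, 0)
      k <- which.min(dd)
      nearest[i] <- gs$gene_id[k]
      dist_bp[i] <- dd[k]
      within[i] <- paste(gs$gene_id[dd <= region_bp], collapse = ",")
    }
  }
  category <- ifelse(is.na(dist_bp), "unmapped",
                     ifelse(dist_bp == 0, "intragenic",
                            ifelse(dist_bp <= cis_bp, "cis",
                                   ifelse(dist_bp <= proximal_bp, "proximal", "distal"))))
  data.frame(snp_id = snps$snp_id, nearest_gene_id = nearest,
             distance_bp = dist_bp, category = category,
             genes_within_region = within, stringsAsFactors = FALSE)
}

#' Call piebald-associated genes
#'
#' Merges differential expression with genetic association: a gene qualifies
#' via criterion (i) when it is DE in at least one contrast and has a SNP
#' within \code{cis_bp} of its interval, or via criterion (ii) when it is not
#' DE but a significantly associated SNP lies within \code{region_bp}. Each
#' qualifying gene is reported once with its criterion, the most associated
#' local SNP (smallest p-value within \code{region_bp}) and its DE summary.
#'
#' @param de_results Output of \code{\link{call_de}}.
#' @param assoc_records Output of \code{\link{snp_association}} (p-values are
#'   used for the best local SNP).
#' @param genes Gene annotation data frame (gene_id, chrom, start, end).
#' @param significant_ids SNP ids passing the dual association rule.
#' @param cis_bp,region_bp Distance thresholds (defaults 2,500 / 1,000,000).
#' @return Data frame: gene_id, criterion ("de_cis" or "assoc_region"),
#'   n_de_contrasts, best_snp, best_p, best_snp_distance_bp.
#' @export
call_piebald_genes <- function(de_results, assoc_records, genes,
                               significant_ids, cis_bp = 2500, region_bp = 1e6) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  de_n <- stats::setNames(rep(0L, nrow(genes)), genes$gene_id)
  hit <- intersect(de_results$gene_id, genes$gene_id)
  de_n[hit] <- de_results$n_de_contrasts[match(hit, de_results$gene_id)]

  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    sn <- assoc_records[assoc_records$chrom == g$chrom, , drop = FALSE]
    if (!nrow(sn)) next
    dd <- pmax(g$start - sn$pos, sn$pos - g$end, 0)
    has_cis <- any(dd <= cis_bp)
    local <- dd <= region_bp
    sig_local <- local & sn$snp_id %in% significant_ids
    is_de <- de_n[[g$gene_id]] >= 1
    criterion <- if (is_de && has_cis) "de_cis"
      else if (!is_de && any(sig_local)) "assoc_region"
      else NA_character_
    if (is.na(criterion)) next
    cand <- which(local & !is.na(sn$p_value))
    best <- if (length(cand)) cand[which.min(sn$p_value[cand])] else NA_integer_
    out[[i]] <- data.frame(
      gene_id = g$gene_id, criterion = criterion,
      n_de_contrasts = de_n[[g$gene_id]],
      best_snp = if (is.na(best)) NA_character_ else sn$snp_id[best],
      best_p = if (is.na(best)) NA_real_ else sn$p_value[best],
      best_snp_distance_bp = if (is.na(best)) NA_real_ else dd[best],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(gene_id = character(0), criterion = character(0),
                      n_de_contrasts = integer(0), best_snp = character(0),
                      best_p = numeric(0), best_snp_distance_bp = numeric(0),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
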