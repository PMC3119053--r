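#' Construct a genotype table
#'
#' Container for a biallelic SNP genotype matrix with its physical map and
#' case/control labels. Genotypes count copies of the B allele (0, 1, 2) with
#' \code{NA} for missing calls.
#'
#' @param calls Integer matrix, animals in rows, SNPs in columns. Row names are
#'   animal ids, column names SNP ids; values in \code{c(0, 1, 2, NA)}.
#' @param map Data frame with columns \code{snp_id}, \code{chrom}, \code{pos}
#'   (1-based bp), one row per column of \code{calls}, same order.
#' @param labels Character vector named by animal id with values \code{"case"},
#'   \code{"control"} or \code{"unlabelled"}. Animals absent from the vector
#'   are treated as unlabelled.
#' @return An object of class \code{genotype_table} with elements
#'   \code{calls}, \code{map}, \code{labels}.
#' @export
genotype_table <- function(calls, map, labels = NULL) {
  if (!is.matrix(calls)) stop("'calls' must be a matrix")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("'calls' must have animal row names and SNP column names")
  if (anyDuplicated(rownames(calls))) stop("duplicate animal ids")
  if (anyDuplicated(colnames(calls))) stop("duplicate SNP ids")
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  storage.mode(calls) <- "integer"
  map <- as.data.frame(map)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(map)))
    stop("'map' needs columns snp_id, chrom, pos")
  map <- map[, need]
  if (nrow(map) != ncol(calls) || !identical(as.character(map$snp_id), colnames(calls)))
    stop("map rows must match the SNP columns of 'calls' (same ids, same order)")
  if (any(map$pos < 1)) stop("positions must be 1-based (>= 1)")
  lab <- rep("unlabelled", nrow(calls))
  names(lab) <- rownames(calls)
  if (!is.null(labels)) {
    labels <- labels[names(labels) %in% names(lab)]
    if (!all(labels %in% c("case", "control", "unlabelled")))
      stop("labels must be 'case', 'control' or 'unlabelled'")
    lab[names(labels)] <- labels
  }
  structure(list(calls = calls, map = map, labels = lab),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d animals x %d SNPs (%d cases, %d controls)\n",
              nrow(x$calls), ncol(x$calls),
              sum(x$labels == "case"), sum(x$labels == "control")))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$calls)

case_ids <- function(table) names(table$labels)[table$labels == "case"]
control_ids <- function(table) names(table$labels)[table$labels == "control"]

#' Subset a genotype table
#'
#' @param table A \code{genotype_table}.
#' @param animals,snps Character vectors of ids to keep (default: all).
#' @return A \code{genotype_table}.
#' @export
subset_genotypes <- function(table, animals = NULL, snps = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  if (is.null(animals)) animals <- rownames(table$calls)
  if (is.null(snps)) snps <- colnames(table$calls)
  missing_a <- setdiff(animals, rownames(table$calls))
  if (length(missing_a)) stop("unknown animal ids: ", paste(missing_a, collapse = ", "))
  missing_s <- setdiff(snps, colnames(table$calls))
  if (length(missing_s)) stop("unknown SNP ids: ", paste(missing_s, collapse = ", "))
  calls <- table$calls[animals, snps, drop = FALSE]
  map <- table$map[match(snps, table$map$snp_id), , drop = FALSE]
  rownames(map) <- NULL
  genotype_table(calls, map, table$labels[animals])
}

#' Read genotypes from TSV (or VCF) with map and phenotype files
#'
#' The TSV genotype matrix has animals in rows and SNPs in columns with codes
#' 0/1/2/NA; the first column holds animal ids. The map file has columns
#' \code{snp_id}, \code{chrom}, \code{pos}; the phenotype file has columns
#' \code{animal_id}, \code{status} with status in case/control/unlabelled.
#' A VCF genotype input (detected by the \code{.vcf} extension) is restricted
#' to biallelic sites and converted to ALT-allele counts; \code{./.} becomes
#' missing.
#'
#' @param genotype_path Path to the genotype TSV or VCF.
#' @param map_path Path to the SNP map TSV (ignored for VCF input, which
#'   carries its own coordinates, unless given).
#' @param phenotype_path Path to the phenotype TSV (optional).
#' @return A \code{genotype_table}.
#' @export
read_genotypes <- function(genotype_path, map_path = NULL, phenotype_path = NULL) {
  if (!file.exists(genotype_path)) stop("no such file: ", genotype_path)
  if (grepl("\\.vcf(\\.gz)?$", genotype_path)) {
    res <- read_genotypes_vcf(genotype_path)
    calls <- res$calls
    map <- res$map
  } else {
    g <- utils::read.table(genotype_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
    calls <- as.matrix(g[, -1, drop = FALSE])
    rownames(calls) <- as.character(g[[1]])
    bad <- which(!(calls %in% c("0", "1", "2", NA)))
    if (length(bad))
      stop(sprintf("unknown genotype code in %s (entry %d)", genotype_path, bad[1]))
    storage.mode(calls) <- "integer"
    if (is.null(map_path)) stop("map_path required for TSV genotypes")
    map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    extra <- setdiff(map$snp_id, colnames(calls))
    if (length(extra))
      stop("map file ", map_path, " lists SNPs absent from the genotype matrix: ",
           paste(utils::head(extra, 5), collapse = ", "))
    miss <- setdiff(colnames(calls), map$snp_id)
    if (length(miss))
      stop("genotype matrix has SNPs absent from map ", map_path, ": ",
           paste(utils::head(miss, 5), collapse = ", "))
    map <- map[match(colnames(calls), map$snp_id), ]
  }
  labels <- NULL
  if (!is.null(phenotype_path)) {
    ph <- utils::read.table(phenotype_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    labels <- stats::setNames(as.character(ph$status), as.character(ph$animal_id))
  }
  genotype_table(calls, map, labels)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF input requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  biallelic <- !grepl(",", vcfR::getALT(v))
  v <- v[biallelic, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    x <- sub(":.*", "", x)
    ifelse(is.na(x) | grepl("\\.", x),
           NA_integer_,
           vapply(strsplit(x, "[/|]"), function(a) sum(a == "1"), integer(1)))
  }
  calls <- t(apply(gt, 1, count_alt))
  calls <- matrix(as.integer(calls), nrow = nrow(gt),
                  dimnames = dimnames(gt))
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  map <- data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]), stringsAsFactors = FALSE)
  calls <- t(calls)
  colnames(calls) <- ids
  list(calls = calls, map = map)
}

#' Write a genotype table to TSV files
#'
#' @param table A \code{genotype_table}.
#' @param genotype_path,map_path,phenotype_path Output paths.
#' @return Invisibly, the genotype path.
#' @export
write_genotypes <- function(table, genotype_path, map_path, phenotype_path) {
  g <- data.frame(animal_id = rownames(table$calls), table$calls,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(g, genotype_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$map, map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- data.frame(animal_id = names(table$labels), status = unname(table$labels))
  utils::write.table(ph, phenotype_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(genotype_path)
}

#' Quality-filter SNPs
#'
#' Applies per-SNP call-rate, minor-allele-frequency and polymorphism filters,
#' computed over labelled (case or control) animals only; SNP order is
#' preserved.
#'
#' @param table A \code{genotype_table}.
#' @param min_call_rate Minimum fraction of labelled animals with a call.
#' @param min_maf Minimum minor allele frequency among labelled animals.
#' @param require_polymorphic Drop SNPs with a single observed allele among
#'   labelled animals.
#' @return A filtered \code{genotype_table} (possibly with zero SNPs).
#' @export
filter_snps <- function(table, min_call_rate = 0, min_maf = 0,
                        require_polymorphic = TRUE) {
  stopifnot(inherits(table, "genotype_table"))
  stopifnot(min_call_rate >= 0, min_call_rate <= 1, min_maf >= 0, min_maf <= 1)
  lab <- names(table$labels)[table$labels %in% c("case", "control")]
  if (!length(lab)) lab <- rownames(table$calls)
  g <- table$calls[lab, , drop = FALSE]
  n_called <- colSums(!is.na(g))
  call_rate <- n_called / nrow(g)
  b <- colSums(g, na.rm = TRUE)
  freq <- ifelse(n_called > 0, b / (2 * n_called), NA_real_)
  maf <- pmin(freq, 1 - freq)
  keep <- call_rate >= min_call_rate
  keep <- keep & (min_maf == 0 | (!is.na(maf) & maf >= min_maf))
  if (require_polymorphic)
    keep <- keep & !is.na(maf) & maf > 0
  subset_genotypes(table, snps = colnames(table$calls)[keep])
}

#' Pairwise allele-sharing (mean IBS) matrix
#'
#' For each pair of animals the identity-by-state sharing is the mean over
#' SNPs where both have calls of \eqn{(2 - |g_i - g_j|)/2}, bounded in [0, 1].
#' Pairs with no jointly observed SNP get \code{NA}.
#'
#' @param table A \code{genotype_table} with at least two animals.
#' @return A symmetric matrix of class \code{sharing_matrix} with animal ids
#'   as dimnames; diagonal 1 for animals with at least one call.
#' @export
allele_sharing <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  g <- table$calls
  if (nrow(g) < 2) stop("allele sharing needs >= 2 animals")
  obs <- !is.na(g)
  # decompose sum |g_i - g_j| over genotype-class indicator cross products:
  # |0-1| = |1-2| = 1, |0-2| = 2
  i0 <- (g == 0L) & obs; i1 <- (g == 1L) & obs; i2 <- (g == 2L) & obs
  storage.mode(i0) <- storage.mode(i1) <- storage.mode(i2) <- "double"
  d01 <- tcrossprod(i0, i1)
  d12 <- tcrossprod(i1, i2)
  d02 <- tcrossprod(i0, i2)
  absdiff <- d01 + t(d01) + d12 + t(d12) + 2 * (d02 + t(d02))
  storage.mode(obs) <- "double"
  n_joint <- tcrossprod(obs)
  values <- 1 - absdiff / (2 * n_joint)
  values[n_joint == 0] <- NA_real_
  diag(values)[diag(n_joint) > 0] <- 1
  dimnames(values) <- list(rownames(g), rownames(g))
  structure(values, class = c("sharing_matrix", "matrix"))
}

#' Greedy matched-control selection by allele sharing
#'
#' Case by case, in the given order, the \code{k_per_case} unselected
#' candidates with the highest sharing are taken; once selected, a control is
#' removed from the pool for all later cases. Ties are broken by candidate
#' order in the matrix.
#'
#' @param matrix A \code{sharing_matrix} covering cases and candidates.
#' @param case_ids Case animal ids, processed in this order.
#' @param candidate_ids Candidate control ids (default: all non-case animals
#'   in the matrix).
#' @param k_per_case Controls selected per case (default 3).
#' @return List with \code{selected} (control ids in selection order) and
#'   \code{provenance} (named list case -> its k controls).
#' @export
select_controls <- function(matrix, case_ids, candidate_ids = NULL, k_per_case = 3) {
  stopifnot(inherits(matrix, "sharing_matrix") || is.matrix(matrix))
  ids <- rownames(matrix)
  if (is.null(candidate_ids)) candidate_ids <- setdiff(ids, case_ids)
  if (!all(case_ids %in% ids)) stop("sharing matrix does not cover all cases")
  if (!all(candidate_ids %in% ids)) stop("sharing matrix does not cover all candidates")
  if (k_per_case * length(case_ids) > length(candidate_ids))
    stop("candidate pool too small: need ", k_per_case * length(case_ids),
         ", have ", length(candidate_ids))
  pool <- candidate_ids
  provenance <- vector("list", length(case_ids))
  names(provenance) <- case_ids
  selected <- character(0)
  for (cs in case_ids) {
    if (length(pool) < k_per_case)
      stop("candidate pool exhausted at case ", cs)
    sh <- matrix[cs, pool]
    # order() is stable: ties resolve to earlier pool (matrix) order
    take <- pool[order(-sh)][seq_len(k_per_case)]
    provenance[[cs]] <- take
    selected <- c(selected, take)
    pool <- setdiff(pool, take)
  }
  list(selected = selected, provenance = provenance)
}
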