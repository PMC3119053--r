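#' Variety codes used throughout the expression analysis
#'
#' The five skin tissue classes hybridised on the array: white skin from a
#' non-pigmented sheep (NOR), black and white skin from a piebald animal
#' (PBB, PBW), and black and white skin from an Agouti recessive-black animal
#' (RSB, RSW).
#' @export
VARIETIES <- c("NOR", "PBW", "PBB", "RSW", "RSB")

hwe_probs <- function(p) c((1 - p)^2, 2 * p * (1 - p), p^2)

#' Build an epistasis penetrance table from marginal targets
#'
#' Constructs a saturated 3x3 penetrance table (probability of being a case
#' given the joint genotype at two loci, rows = copies of B at locus A,
#' columns = locus B) implied by a retrospective design: cases carry B at
#' frequency \code{case_freq} at each locus with a comonotone coupling of
#' weight \code{rho} between the loci, controls carry B independently at
#' \code{control_freq}. The implied genotype prior is the prevalence-weighted
#' mixture, so drawing case/control joint genotypes retrospectively from this
#' table reproduces the targeted marginals and dependence exactly.
#'
#' @param case_freq,control_freq B-allele frequencies in cases and controls.
#' @param prevalence Population case fraction used for the mixture.
#' @param rho Weight of the comonotone (same genotype at both loci) component
#'   in cases; 0 gives purely marginal effects.
#' @return List with \code{penetrance} and \code{prior}, both 3x3 matrices.
#' @export
epistasis_penetrance <- function(case_freq = 0.78, control_freq = 0.28,
                                 prevalence = 0.25, rho = 0.4) {
  stopifnot(case_freq > 0, case_freq < 1, control_freq > 0, control_freq < 1,
            prevalence > 0, prevalence < 1, rho >= 0, rho <= 1)
  mc <- hwe_probs(case_freq)
  m0 <- hwe_probs(control_freq)
  case_joint <- rho * diag(mc) + (1 - rho) * outer(mc, mc)
  ctrl_joint <- outer(m0, m0)
  prior <- prevalence * case_joint + (1 - prevalence) * ctrl_joint
  pen <- prevalence * case_joint / prior
  dimnames(pen) <- dimnames(prior) <- list(0:2, 0:2)
  list(penetrance = pen, prior = prior)
}

#' Simulation configuration
#'
#' Parameters of the synthetic cohort, microarray and TFBS generators. The
#' defaults mirror the study conditions of the piebald analysis: 24 cases and
#' a pool of 199 candidate controls (from which 72 are matched), a
#' 20-hybridisation dye-swap loop design over the five varieties, and planted
#' association, epistasis, differential-expression and TF-membership signals.
#'
#' @param n_cases,n_controls_pool Cohort sizes (cases; candidate controls).
#' @param n_snps,n_chromosomes,chrom_length_bp Marker panel geometry.
#' @param n_assoc_snps Number of SNPs with a planted case/control allele
#'   frequency difference.
#' @param assoc_freq_delta Planted absolute allele frequency difference.
#' @param n_epistatic_pairs Number of planted epistatic SNP pairs; pairs share
#'   a single hub SNP (star topology) so the hub gene accumulates pair counts.
#' @param epistasis_penetrance_table 3x3 matrix of case probabilities by joint
#'   genotype (copies of B at each locus).
#' @param epistasis_genotype_prior 3x3 joint genotype prior matching the
#'   penetrance table; defaults to the prior implied by
#'   \code{\link{epistasis_penetrance}} (or a Hardy-Weinberg 0.5 x 0.5 product
#'   when a custom penetrance table is supplied without a prior).
#' @param n_families Relatedness blocks; block allele frequencies follow a
#'   Balding-Nichols Beta distribution around the global frequency.
#' @param fst Differentiation of family blocks (Balding-Nichols F).
#' @param n_genes,n_de_genes Gene panel size and planted DE gene count.
#' @param de_effect_sd Planted log2 expression shift applied to the piebald
#'   varieties (PBW and PBB) of DE genes, alternating sign.
#' @param noise_sds Named standard deviations of the five random components of
#'   the normalization model: gene, array_gene, dye_gene, variety_gene,
#'   residual (log2-intensity units).
#' @param n_tfs,tfbs_density Number of transcription factors and decoy TFBS
#'   record density.
#' @param n_intersect_genes Planted intersection size: the epistatic hub gene
#'   plus this many minus one leaf genes are made TF targets.
#' @param missing_rate Fraction of genotype calls set missing.
#' @param snr_fail_fraction Fraction of probes whose signal-to-noise ratio is
#'   below 2 in every hybridisation (removed at acquisition).
#' @param duplicate_probe_fraction Fraction of genes printed with a second,
#'   less abundant probe (collapsed at acquisition).
#' @param seed Integer seed; identical seed and config give bit-identical
#'   outputs.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_cases = 24,
                       n_controls_pool = 199,
                       n_snps = 2000,
                       n_chromosomes = 5,
                       chrom_length_bp = 1e8,
                       n_assoc_snps = 20,
                       assoc_freq_delta = 0.4,
                       n_epistatic_pairs = 5,
                       epistasis_penetrance_table = NULL,
                       epistasis_genotype_prior = NULL,
                       n_families = 12,
                       fst = 0.05,
                       n_genes = 60,
                       n_de_genes = 8,
                       de_effect_sd = 2.0,
                       noise_sds = c(gene = 1.2, array_gene = 0.3,
                                     dye_gene = 0.3, variety_gene = 0.2,
                                     residual = 0.5),
                       n_tfs = 2,
                       tfbs_density = 0.05,
                       n_intersect_genes = 3,
                       missing_rate = 0,
                       snr_fail_fraction = 0.05,
                       duplicate_probe_fraction = 0.1,
                       seed = 1L) {
  if (is.null(epistasis_penetrance_table)) {
    ep <- epistasis_penetrance()
    epistasis_penetrance_table <- ep$penetrance
    if (is.null(epistasis_genotype_prior)) epistasis_genotype_prior <- ep$prior
  }
  if (is.null(epistasis_genotype_prior))
    epistasis_genotype_prior <- outer(hwe_probs(0.5), hwe_probs(0.5))
  cfg <- list(n_cases = as.integer(n_cases),
              n_controls_pool = as.integer(n_controls_pool),
              n_snps = as.integer(n_snps),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.numeric(chrom_length_bp),
              n_assoc_snps = as.integer(n_assoc_snps),
              assoc_freq_delta = as.numeric(assoc_freq_delta),
              n_epistatic_pairs = as.integer(n_epistatic_pairs),
              epistasis_penetrance_table = epistasis_penetrance_table,
              epistasis_genotype_prior = epistasis_genotype_prior,
              n_families = as.integer(n_families),
              fst = as.numeric(fst),
              n_genes = as.integer(n_genes),
              n_de_genes = as.integer(n_de_genes),
              de_effect_sd = as.numeric(de_effect_sd),
              noise_sds = noise_sds,
              n_tfs = as.integer(n_tfs),
              tfbs_density = as.numeric(tfbs_density),
              n_intersect_genes = as.integer(n_intersect_genes),
              missing_rate = as.numeric(missing_rate),
              snr_fail_fraction = as.numeric(snr_fail_fraction),
              duplicate_probe_fraction = as.numeric(duplicate_probe_fraction),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("n_cases", "n_controls_pool", "n_snps", "n_chromosomes",
           "n_families", "n_genes")
  for (f in pos)
    if (cfg[[f]] < 1) stop("'", f, "' must be >= 1")
  nn <- c("n_assoc_snps", "n_epistatic_pairs", "n_de_genes", "n_tfs")
  for (f in nn)
    if (cfg[[f]] < 0) stop("'", f, "' must be >= 0")
  probs <- c("assoc_freq_delta", "tfbs_density", "missing_rate",
             "snr_fail_fraction", "duplicate_probe_fraction", "fst")
  for (f in probs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("'", f, "' must be in [0, 1]")
  if (any(cfg$noise_sds < 0)) stop("noise_sds must be >= 0")
  if (length(cfg$noise_sds) != 5)
    stop("noise_sds needs 5 components (gene, array_gene, dye_gene, variety_gene, residual)")
  pen <- cfg$epistasis_penetrance_table
  if (!is.matrix(pen) || !all(dim(pen) == c(3, 3)) || any(pen < 0) || any(pen > 1))
    stop("epistasis_penetrance_table must be a 3x3 matrix of probabilities")
  if (cfg$n_assoc_snps + 2L * cfg$n_epistatic_pairs > cfg$n_snps)
    stop("configuration error: n_assoc_snps + 2*n_epistatic_pairs exceeds n_snps")
  n_planted_genes <- cfg$n_assoc_snps +
    (if (cfg$n_epistatic_pairs > 0) cfg$n_epistatic_pairs + 1L else 0L) +
    cfg$n_de_genes + 2L
  if (n_planted_genes > cfg$n_genes)
    stop("n_genes too small for the planted gene sets (need >= ", n_planted_genes, ")")
  if (cfg$de_effect_sd < 0) stop("de_effect_sd must be >= 0")
  if (abs(cfg$seed) > 2^31 - 1e4) stop("seed out of range")
  invisible(cfg)
}

# Place genes on a regular per-chromosome grid with jitter; keeps genes far
# apart so planted intragenic SNPs map uniquely to their gene.
place_genes <- function(cfg) {
  chrom <- rep(seq_len(cfg$n_chromosomes), length.out = cfg$n_genes)
  per <- table(factor(chrom, levels = seq_len(cfg$n_chromosomes)))
  start <- numeric(cfg$n_genes)
  for (ch in seq_len(cfg$n_chromosomes)) {
    k <- per[[ch]]
    if (k == 0) next
    centres <- cfg$chrom_length_bp * seq_len(k) / (k + 1)
    jit <- stats::runif(k, -0.2, 0.2) * cfg$chrom_length_bp / (k + 1)
    start[chrom == ch] <- round(centres + jit)
  }
  len <- round(stats::runif(cfg$n_genes, 5e3, 5e4))
  data.frame(gene_id = sprintf("gene%03d", seq_len(cfg$n_genes)),
             chrom = paste0("chr", chrom),
             start = pmax(1, start),
             end = pmax(1, start) + len,
             stringsAsFactors = FALSE)
}

sample_joint_genotypes <- function(n, hub_g, joint) {
  # draw leaf genotypes conditional on the shared hub genotype
  out <- integer(n)
  for (g in 0:2) {
    idx <- which(hub_g == g)
    if (!length(idx)) next
    pr <- joint[g + 1, ]
    if (sum(pr) <= 0) pr <- rep(1 / 3, 3)
    out[idx] <- sample(0:2, length(idx), replace = TRUE, prob = pr)
  }
  out
}

#' Simulate a case-control genotype cohort with planted signals
#'
#' Generates a cohort of cases and candidate controls genotyped at biallelic
#' SNPs. Null SNPs follow Hardy-Weinberg proportions at family-shifted
#' (Balding-Nichols) allele frequencies. Planted associated SNPs differ in
#' allele frequency between cases and controls by \code{assoc_freq_delta};
#' planted epistatic pairs share a hub SNP and draw joint genotypes
#' retrospectively from the configured penetrance table. Gene annotation, DE
#' genes, TF memberships and the planted intersection are fixed here so the
#' downstream generators and the truth record stay consistent.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{genotypes} (a \code{\link{genotype_table}}),
#'   \code{annotation} (BED-like gene data frame) and \code{truth} (planted
#'   signal record: assoc_snp_ids, epistatic_pairs, epistatic_genes, de_genes,
#'   tf_memberships, intersection_genes, planted_variance_components, ...).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_animals <- config$n_cases + config$n_controls_pool
  ids <- c(sprintf("case%03d", seq_len(config$n_cases)),
           sprintf("ctrl%03d", seq_len(config$n_controls_pool)))
  labels <- stats::setNames(rep(c("case", "control"),
                                c(config$n_cases, config$n_controls_pool)), ids)
  is_case <- labels == "case"

  genes <- place_genes(config)

  # carve up the gene panel into planted roles
  gi <- seq_len(config$n_genes)
  n_epi_genes <- if (config$n_epistatic_pairs > 0) config$n_epistatic_pairs + 1L else 0L
  epi_gene_idx <- utils::head(gi, n_epi_genes)          # hub first, then leaves
  gi <- setdiff(gi, epi_gene_idx)
  assoc_gene_idx <- utils::head(gi, config$n_assoc_snps)
  gi <- setdiff(gi, assoc_gene_idx)
  de_gene_idx <- utils::head(gi, config$n_de_genes)
  gi <- setdiff(gi, de_gene_idx)
  far_gene_idx <- utils::head(gi, 2L)                   # kept free of SNPs

  # SNP panel: positions uniform per chromosome, planted SNPs intragenic
  chrom_idx <- rep(seq_len(config$n_chromosomes), length.out = config$n_snps)
  pos <- round(stats::runif(config$n_snps, 1, config$chrom_length_bp))
  chrom <- paste0("chr", chrom_idx)
  # keep null SNPs out of the reserved windows around the far genes
  if (length(far_gene_idx)) {
    for (fg in far_gene_idx) {
      lo <- genes$start[fg] - 1.2e6; hi <- genes$end[fg] + 1.2e6
      bad <- which(chrom == genes$chrom[fg] & pos >= lo & pos <= hi)
      while (length(bad)) {
        pos[bad] <- round(stats::runif(length(bad), 1, config$chrom_length_bp))
        bad <- bad[pos[bad] >= lo & pos[bad] <= hi]
      }
    }
  }
  n_epi_snps <- n_epi_genes
  epi_snp_idx <- utils::head(seq_len(config$n_snps), n_epi_snps)
  assoc_snp_idx <- seq_len(config$n_assoc_snps) + n_epi_snps
  planted_gene_of_snp <- c(epi_gene_idx, assoc_gene_idx)
  planted_snp_idx <- c(epi_snp_idx, assoc_snp_idx)
  for (k in seq_along(planted_snp_idx)) {
    s <- planted_snp_idx[k]; g <- planted_gene_of_snp[k]
    chrom[s] <- genes$chrom[g]
    pos[s] <- round(stats::runif(1, genes$start[g], genes$end[g]))
  }
  snp_id <- sprintf("snp%05d", seq_len(config$n_snps))
  map <- data.frame(snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
                    stringsAsFactors = FALSE)

  # null genotypes: Balding-Nichols family frequencies around a global freq
  fam <- sample.int(config$n_families, n_animals, replace = TRUE)
  p_global <- stats::runif(config$n_snps, 0.1, 0.9)
  calls <- matrix(NA_integer_, n_animals, config$n_snps,
                  dimnames = list(ids, snp_id))
  if (config$n_families > 1 && config$fst > 0) {
    a <- p_global * (1 - config$fst) / config$fst
    b <- (1 - p_global) * (1 - config$fst) / config$fst
    pfam <- matrix(stats::rbeta(config$n_families * config$n_snps,
                                rep(a, each = config$n_families),
                                rep(b, each = config$n_families)),
                   nrow = config$n_families)
    pmat <- pfam[fam, , drop = FALSE]
  } else {
    pmat <- matrix(p_global, n_animals, config$n_snps, byrow = TRUE)
  }
  calls[] <- stats::rbinom(length(pmat), 2L, pmat)

  # planted associated SNPs: case frequency shifted by +/- delta
  assoc_dir <- rep(c(1, -1), length.out = length(assoc_snp_idx))
  for (k in seq_along(assoc_snp_idx)) {
    s <- assoc_snp_idx[k]
    if (assoc_dir[k] > 0) {
      p_ctrl <- stats::runif(1, 0.10, 0.95 - config$assoc_freq_delta)
      p_case <- p_ctrl + config$assoc_freq_delta
    } else {
      p_case <- stats::runif(1, 0.05, 0.90 - config$assoc_freq_delta)
      p_ctrl <- p_case + config$assoc_freq_delta
    }
    calls[is_case, s] <- stats::rbinom(sum(is_case), 2L, p_case)
    calls[!is_case, s] <- stats::rbinom(sum(!is_case), 2L, p_ctrl)
  }

  # planted epistatic pairs: hub + leaves, retrospective draw from the
  # penetrance table (joint distribution of each (hub, leaf) pair matches
  # pen * prior in cases and (1 - pen) * prior in controls)
  epistatic_pairs <- data.frame(snp_a = character(0), snp_b = character(0))
  if (config$n_epistatic_pairs > 0) {
    pen <- config$epistasis_penetrance_table
    prior <- config$epistasis_genotype_prior / sum(config$epistasis_genotype_prior)
    prev <- sum(pen * prior)
    if (prev <= 0 || prev >= 1)
      stop("penetrance/prior imply a degenerate prevalence")
    case_joint <- pen * prior / prev
    ctrl_joint <- (1 - pen) * prior / (1 - prev)
    hub_case <- sample(0:2, config$n_cases, replace = TRUE,
                       prob = rowSums(case_joint))
    hub_ctrl <- sample(0:2, config$n_controls_pool, replace = TRUE,
                       prob = rowSums(ctrl_joint))
    hub_snp <- epi_snp_idx[1]
    calls[is_case, hub_snp] <- hub_case
    calls[!is_case, hub_snp] <- hub_ctrl
    for (j in seq_len(config$n_epistatic_pairs)) {
      leaf <- epi_snp_idx[j + 1]
      calls[is_case, leaf] <- sample_joint_genotypes(config$n_cases, hub_case, case_joint)
      calls[!is_case, leaf] <- sample_joint_genotypes(config$n_controls_pool,
                                                      hub_ctrl, ctrl_joint)
    }
    epistatic_pairs <- data.frame(
      snp_a = snp_id[hub_snp],
      snp_b = snp_id[epi_snp_idx[-1]],
      stringsAsFactors = FALSE)
  }

  if (config$missing_rate > 0) {
    nmiss <- round(config$missing_rate * length(calls))
    calls[sample.int(length(calls), nmiss)] <- NA_integer_
  }

  # planted DE genes: alternating-sign shift in the piebald varieties
  de_genes <- data.frame(gene_id = character(0), effect = numeric(0),
                         varieties = character(0), stringsAsFactors = FALSE)
  if (config$n_de_genes > 0) {
    de_genes <- data.frame(
      gene_id = genes$gene_id[de_gene_idx],
      effect = config$de_effect_sd * rep(c(1, -1), length.out = config$n_de_genes),
      varieties = "PBW,PBB",
      stringsAsFactors = FALSE)
  }

  # TF memberships: intersection genes (hub + leaves) and the SNP-free far
  # genes; kept away from other epistatic-network genes so the planted
  # intersection is exactly recoverable
  intersection_idx <- integer(0)
  if (config$n_epistatic_pairs > 0 && config$n_tfs > 0 && config$n_intersect_genes > 0)
    intersection_idx <- utils::head(epi_gene_idx,
                                    min(config$n_intersect_genes, n_epi_genes))
  tf_memberships <- list()
  if (config$n_tfs > 0) {
    tf_names <- sprintf("TF%02d", seq_len(config$n_tfs))
    target_pool <- genes$gene_id[c(intersection_idx, far_gene_idx)]
    for (k in seq_len(config$n_tfs)) {
      tgt <- if (k == 1) target_pool else {
        keep <- seq_along(target_pool) %% config$n_tfs == (k - 1) %% config$n_tfs
        targets <- target_pool[keep]
        if (!length(targets)) target_pool[1] else targets
      }
      tf_memberships[[tf_names[k]]] <- tgt
    }
    # every intersection gene must be a TF target
    missed <- setdiff(genes$gene_id[intersection_idx], unlist(tf_memberships))
    if (length(missed))
      tf_memberships[[1]] <- union(tf_memberships[[1]], missed)
  }

  truth <- list(
    assoc_snp_ids = snp_id[assoc_snp_idx],
    assoc_freq_delta = config$assoc_freq_delta,
    epistatic_pairs = epistatic_pairs,
    epistatic_genes = stats::setNames(genes$gene_id[epi_gene_idx],
                                      snp_id[epi_snp_idx]),
    assoc_genes = stats::setNames(genes$gene_id[assoc_gene_idx],
                                  snp_id[assoc_snp_idx]),
    de_genes = de_genes,
    tf_memberships = tf_memberships,
    intersection_genes = genes$gene_id[intersection_idx],
    far_genes = genes$gene_id[far_gene_idx],
    families = stats::setNames(fam, ids),
    planted_variance_components = stats::setNames(config$noise_sds^2,
                                                  c("gene", "array_gene", "dye_gene",
                                                    "variety_gene", "residual")))
  list(genotypes = genotype_table(calls, map, labels),
       annotation = genes,
       truth = truth)
}

# Balanced round-robin loop design: every variety pair hybridised twice with
# dyes swapped between rounds; biological replicate 1 is used in round 1,
# replicate 2 in round 2. Each sample enters 4 hybridisations, twice per dye.
loop_design <- function() {
  v <- VARIETIES
  edges <- do.call(rbind, lapply(1:5, function(i)
    rbind(c(i, i %% 5 + 1), c(i, (i + 1) %% 5 + 1))))
  rows <- list()
  for (round in 1:2) {
    for (e in seq_len(nrow(edges))) {
      red <- if (round == 1) edges[e, 1] else edges[e, 2]
      green <- if (round == 1) edges[e, 2] else edges[e, 1]
      rows[[length(rows) + 1]] <- data.frame(
        hyb_id = sprintf("hyb%02d", (round - 1) * 10 + e),
        array_id = sprintf("array%02d", (round - 1) * 10 + e),
        red_variety = v[red], green_variety = v[green],
        red_sample = paste0(v[red], "_rep", round),
        green_sample = paste0(v[green], "_rep", round),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a two-colour loop-design microarray experiment
#'
#' Emits long-format intensity records for a 20-hybridisation dye-swap loop
#' over the five varieties. Each log2 foreground value is built as
#' mu + C + G + AG + DG + VG + e with components drawn at the configured
#' standard deviations; planted DE genes receive their variety-specific shifts
#' on top of the VG draw. Background values give each probe a fixed
#' signal-to-noise ratio, below 2 for the configured failing fraction.
#'
#' @param config A \code{\link{sim_config}}.
#' @param truth Truth record from \code{\link{simulate_cohort}}.
#' @return Data frame with columns hyb_id, array_id, print_block, dye,
#'   variety, probe_id, gene_id, foreground, background.
#' @export
simulate_microarray <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  design <- loop_design()
  gene_ids <- sprintf("gene%03d", seq_len(config$n_genes))

  sds <- config$noise_sds
  mu <- 8
  n_arrays <- nrow(design)
  array_eff <- stats::setNames(stats::rnorm(n_arrays, 0, 0.2), design$array_id)
  dye_eff <- c(red = -0.7, green = 0.7)

  n_dup <- round(config$duplicate_probe_fraction * config$n_genes)
  dup_genes <- utils::head(gene_ids, n_dup)
  probes <- data.frame(probe_id = paste0(gene_ids, "_p1"), gene_id = gene_ids,
                       probe_shift = 0, stringsAsFactors = FALSE)
  if (n_dup > 0)
    probes <- rbind(probes, data.frame(probe_id = paste0(dup_genes, "_p2"),
                                       gene_id = dup_genes, probe_shift = -1.5,
                                       stringsAsFactors = FALSE))
  n_probes <- nrow(probes)

  g_eff <- stats::setNames(stats::rnorm(config$n_genes, 0, sds[["gene"]]), gene_ids)
  ag_eff <- matrix(stats::rnorm(n_arrays * config$n_genes, 0, sds[["array_gene"]]),
                   n_arrays, config$n_genes, dimnames = list(design$array_id, gene_ids))
  dg_eff <- matrix(stats::rnorm(2 * config$n_genes, 0, sds[["dye_gene"]]),
                   2, config$n_genes, dimnames = list(c("red", "green"), gene_ids))
  vg_eff <- matrix(stats::rnorm(5 * config$n_genes, 0, sds[["variety_gene"]]),
                   5, config$n_genes, dimnames = list(VARIETIES, gene_ids))
  if (nrow(truth$de_genes) > 0) {
    for (r in seq_len(nrow(truth$de_genes))) {
      vs <- strsplit(truth$de_genes$varieties[r], ",")[[1]]
      vg_eff[vs, truth$de_genes$gene_id[r]] <-
        vg_eff[vs, truth$de_genes$gene_id[r]] + truth$de_genes$effect[r]
    }
  }

  # per-probe scanner signal-to-noise ratio, constant across hybridisations
  fail <- stats::runif(n_probes) < config$snr_fail_fraction
  snr <- ifelse(fail, stats::runif(n_probes, 1.2, 1.9),
                stats::runif(n_probes, 8, 40))

  # one record per hybridisation x channel x probe
  ch <- rbind(data.frame(design[, c("hyb_id", "array_id")], dye = "red",
                         variety = design$red_variety, stringsAsFactors = FALSE),
              data.frame(design[, c("hyb_id", "array_id")], dye = "green",
                         variety = design$green_variety, stringsAsFactors = FALSE))
  rec <- ch[rep(seq_len(nrow(ch)), each = n_probes), ]
  rec$print_block <- 1L
  rec$probe_id <- rep(probes$probe_id, nrow(ch))
  rec$gene_id <- rep(probes$gene_id, nrow(ch))
  pshift <- rep(probes$probe_shift, nrow(ch))
  y <- mu + array_eff[rec$array_id] + dye_eff[rec$dye] +
    g_eff[rec$gene_id] + pshift +
    ag_eff[cbind(rec$array_id, rec$gene_id)] +
    dg_eff[cbind(rec$dye, rec$gene_id)] +
    vg_eff[cbind(rec$variety, rec$gene_id)] +
    stats::rnorm(nrow(rec), 0, sds[["residual"]])
  rec$foreground <- 2^y
  rec$background <- rec$foreground / rep(snr, nrow(ch))
  rownames(rec) <- NULL
  rec[, c("hyb_id", "array_id", "print_block", "dye", "variety",
          "probe_id", "gene_id", "foreground", "background")]
}

#' Simulate a TF binding-site hit table
#'
#' Planted TF-gene memberships yield records with core and matrix similarity
#' 1.0; decoy records for non-member TF-gene combinations are added at the
#' configured density with similarities strictly below 1.
#'
#' @param config A \code{\link{sim_config}}.
#' @param truth Truth record from \code{\link{simulate_cohort}}.
#' @return Data frame with columns tf_name, gene_id, core_similarity,
#'   matrix_similarity.
#' @export
simulate_tfbs <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  empty <- data.frame(tf_name = character(0), gene_id = character(0),
                      core_similarity = numeric(0), matrix_similarity = numeric(0),
                      stringsAsFactors = FALSE)
  if (config$n_tfs == 0 || !length(truth$tf_memberships)) return(empty)
  planted <- do.call(rbind, lapply(names(truth$tf_memberships), function(tf)
    data.frame(tf_name = tf, gene_id = truth$tf_memberships[[tf]],
               core_similarity = 1, matrix_similarity = 1,
               stringsAsFactors = FALSE)))
  gene_ids <- sprintf("gene%03d", seq_len(config$n_genes))
  decoys <- empty
  if (config$tfbs_density > 0) {
    combos <- expand.grid(tf_name = names(truth$tf_memberships),
                          gene_id = gene_ids, stringsAsFactors = FALSE)
    member <- paste(planted$tf_name, planted$gene_id)
    combos <- combos[!(paste(combos$tf_name, combos$gene_id) %in% member), ]
    take <- stats::runif(nrow(combos)) < config$tfbs_density
    combos <- combos[take, , drop = FALSE]
    if (nrow(combos))
      decoys <- data.frame(combos,
                           core_similarity = stats::runif(nrow(combos), 0.75, 0.999),
                           matrix_similarity = stats::runif(nrow(combos), 0.75, 0.999),
                           stringsAsFactors = FALSE)
  }
  out <- rbind(planted, decoys)
  rownames(out) <- NULL
  out
}

#' Run all three generators
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with genotypes, annotation, truth, intensities, tfbs.
#' @export
simulate_all <- function(config) {
  cohort <- simulate_cohort(config)
  intensities <- simulate_microarray(config, cohort$truth)
  tfbs <- simulate_tfbs(config, cohort$truth)
  c(cohort, list(intensities = intensities, tfbs = tfbs))
}

#' Write a simulated data set to plain-text files
#'
#' Writes genotype, map, phenotype, intensity, TFBS and gene-annotation TSVs
#' plus a truth JSON, all of which round-trip through the package readers.
#'
#' @param sim Result of \code{\link{simulate_all}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of file paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             map = file.path(dir, "map.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             intensities = file.path(dir, "intensities.tsv"),
             tfbs = file.path(dir, "tfbs.tsv"),
             annotation = file.path(dir, "genes.tsv"),
             truth = file.path(dir, "truth.json"))
  write_genotypes(sim$genotypes, paths["genotypes"], paths["map"], paths["phenotypes"])
  utils::write.table(sim$intensities, paths["intensities"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$tfbs, paths["tfbs"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$families <- as.list(truth$families)
  truth$epistatic_genes <- as.list(truth$epistatic_genes)
  truth$assoc_genes <- as.list(truth$assoc_genes)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Read a gene annotation table
#'
#' BED-like TSV with 1-based inclusive coordinates and columns gene_id, chrom,
#' start, end (any order, header required).
#'
#' @param path Path to the TSV.
#' @return Data frame with gene_id, chrom, start, end.
#' @export
read_gene_annotation <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(g)))
    stop("gene annotation needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(g$gene_id)) stop("duplicate gene ids in ", path)
  if (any(g$start > g$end)) stop("gene with start > end in ", path)
  g[, need]
}

#' Read a TFBS hit table
#'
#' @param path TSV with columns tf_name, gene_id, core_similarity,
#'   matrix_similarity.
#' @return Data frame of TFBS records.
#' @export
read_tfbs <- function(path) {
  t <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("tf_name", "gene_id", "core_similarity", "matrix_similarity")
  if (!all(need %in% names(t)))
    stop("TFBS table needs columns: ", paste(need, collapse = ", "))
  if (any(t$core_similarity < 0 | t$core_similarity > 1) ||
      any(t$matrix_similarity < 0 | t$matrix_similarity > 1))
    stop("TFBS similarities must be in [0, 1]")
  t[, need]
}
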