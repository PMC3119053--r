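#' Pipeline configuration
#'
#' Collects every stage parameter with its canonical default (association p
#' 0.001 with a 3-SD genotype-difference rule, epistasis p 0.001 at 8 df,
#' signal-to-noise 2, DE threshold 2.57 SD, cis 2,500 bp, region 1,000,000
#' bp, proximity 100,000 bp, hub threshold 20, TFBS confidence 1.0, 3
#' matched controls per case) together with either a \code{simulate} block
#' (a \code{\link{sim_config}}) or input file paths. Unknown keys are
#' rejected.
#'
#' @param simulate Optional \code{\link{sim_config}}; when present, inputs
#'   are generated rather than read.
#' @param genotype_path,map_path,phenotype_path,intensity_path,tfbs_path,annotation_path
#'   Input files (ignored when \code{simulate} is given).
#' @param outdir Output directory.
#' @param seed Integer seed for the run.
#' @param assoc_p,sd_multiplier,epistasis_p,snr_min,de_sd,cis_bp,region_bp,proximity_bp,hub_threshold,tfbs_confidence,k_controls,min_call_rate,min_maf,require_polymorphic,exclude_proximal,tfbs_min_targets
#'   Stage parameters (see the stage functions for semantics).
#' @param ... Unknown keys raise an error.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(simulate = NULL,
                            genotype_path = NULL, map_path = NULL,
                            phenotype_path = NULL, intensity_path = NULL,
                            tfbs_path = NULL, annotation_path = NULL,
                            outdir = tempfile("piebaldnet_run_"),
                            seed = 1L,
                            assoc_p = 0.001, sd_multiplier = 3.0,
                            epistasis_p = 0.001, snr_min = 2.0, de_sd = 2.57,
                            cis_bp = 2500, region_bp = 1e6, proximity_bp = 1e5,
                            hub_threshold = 20, tfbs_confidence = 1.0,
                            tfbs_min_targets = 1,
                            k_controls = 3, min_call_rate = 0, min_maf = 0,
                            require_polymorphic = TRUE, exclude_proximal = FALSE,
                            ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration keys: ", paste(names(extra), collapse = ", "))
  if (is.null(simulate)) {
    paths <- list(genotype_path, map_path, phenotype_path, intensity_path,
                  tfbs_path, annotation_path)
    if (any(vapply(paths, is.null, logical(1))))
      stop("either a simulate block or all input paths are required")
  } else {
    stopifnot(inherits(simulate, "sim_config"))
  }
  structure(list(simulate = simulate,
                 genotype_path = genotype_path, map_path = map_path,
                 phenotype_path = phenotype_path, intensity_path = intensity_path,
                 tfbs_path = tfbs_path, annotation_path = annotation_path,
                 outdir = outdir, seed = as.integer(seed),
                 assoc_p = assoc_p, sd_multiplier = sd_multiplier,
                 epistasis_p = epistasis_p, snr_min = snr_min, de_sd = de_sd,
                 cis_bp = cis_bp, region_bp = region_bp,
                 proximity_bp = proximity_bp, hub_threshold = hub_threshold,
                 tfbs_confidence = tfbs_confidence,
                 tfbs_min_targets = tfbs_min_targets,
                 k_controls = k_controls, min_call_rate = min_call_rate,
                 min_maf = min_maf, require_polymorphic = require_polymorphic,
                 exclude_proximal = exclude_proximal),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds a flat mapping of \code{\link{pipeline_config}} keys;
#' an optional \code{simulate} sub-mapping holds \code{\link{sim_config}}
#' keys (a \code{penetrance} sub-key of nine numbers fills the 3x3 table by
#' row).
#'
#' @param path YAML file path.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    s <- y$simulate
    if (!is.null(s$penetrance)) {
      s$epistasis_penetrance_table <- matrix(as.numeric(s$penetrance), 3, 3,
                                             byrow = TRUE)
      s$penetrance <- NULL
    }
    if (!is.null(s$noise_sds)) s$noise_sds <- unlist(s$noise_sds)
    y$simulate <- do.call(sim_config, s)
  }
  do.call(pipeline_config, y)
}

pn_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the stages end-to-end: simulate or read inputs, allele-sharing
#' control matching, SNP quality filtering, single-SNP association with the
#' dual significance rule, the two-locus epistasis scan, microarray
#' acquisition and EM-REML normalization, the seven DE contrasts and DE
#' calls, SNP-to-gene mapping, the piebald-associated gene call, regulatory
#' and epistatic network construction, hub reduction, intersection, and
#' Cytoscape-compatible export. Every intermediate table is written as TSV
#' under \code{outdir} along with a JSON manifest (paths, row counts,
#' parameter echo, seed, stage wall-times). Re-running with an identical
#' configuration and seed reproduces identical output tables.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  manifest <- list(seed = config$seed,
                   parameters = unclass(config)[setdiff(names(config),
                                                        c("simulate"))],
                   stages = list())
  t_all <- proc.time()[["elapsed"]]
  res <- list()
  outputs <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      writeLines(paste("failed at stage:", name, "-", conditionMessage(e)),
                 file.path(config$outdir, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }

  # --- inputs -----------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- stage("simulate", simulate_all(config$simulate))
    indir <- file.path(config$outdir, "inputs")
    write_simulation(sim, indir)
    genotypes <- sim$genotypes
    intensities <- sim$intensities
    tfbs <- sim$tfbs
    annotation <- sim$annotation
    res$truth <- sim$truth
    pn_log("simulate", "%d animals x %d SNPs, %d intensity records, %d TFBS records",
           nrow(genotypes$calls), ncol(genotypes$calls), nrow(intensities), nrow(tfbs))
  } else {
    genotypes <- stage("read", read_genotypes(config$genotype_path,
                                              config$map_path,
                                              config$phenotype_path))
    intensities <- utils::read.table(config$intensity_path, header = TRUE,
                                     sep = "\t", stringsAsFactors = FALSE)
    tfbs <- read_tfbs(config$tfbs_path)
    annotation <- read_gene_annotation(config$annotation_path)
  }
  res$genotypes <- genotypes

  # --- control matching on the full marker panel ------------------------
  cases <- case_ids(genotypes)
  controls <- control_ids(genotypes)
  if (length(controls) > config$k_controls * length(cases)) {
    sharing <- stage("sharing", allele_sharing(genotypes))
    sel <- stage("match", select_controls(sharing, cases,
                                          candidate_ids = controls,
                                          k_per_case = config$k_controls))
    labels <- genotypes$labels
    labels[setdiff(controls, sel$selected)] <- "unlabelled"
    genotypes$labels <- labels
    res$matching <- sel
    pn_log("match", "selected %d of %d candidate controls for %d cases",
           length(sel$selected), length(controls), length(cases))
  } else {
    pn_log("match", "control pool (%d) not larger than %d x %d cases; keeping all",
           length(controls), config$k_controls, length(cases))
  }

  # --- SNP filtering on the matched cohort ------------------------------
  n_before <- ncol(genotypes$calls)
  genotypes <- stage("filter", filter_snps(genotypes,
                                           min_call_rate = config$min_call_rate,
                                           min_maf = config$min_maf,
                                           require_polymorphic = config$require_polymorphic))
  pn_log("filter", "%d of %d SNPs retained", ncol(genotypes$calls), n_before)
  res$filtered <- genotypes

  # --- single-SNP association -------------------------------------------
  assoc <- stage("assoc", {
    a <- snp_association(genotypes)
    significant_snps(a, p_threshold = config$assoc_p,
                     sd_multiplier = config$sd_multiplier)
  })
  res$association <- assoc$records
  res$significant_ids <- assoc$significant_ids
  outputs["association"] <- write_tsv(assoc$records,
                                      file.path(config$outdir, "association.tsv"))
  pn_log("assoc", "%d of %d SNPs pass the dual significance rule",
         length(assoc$significant_ids), nrow(assoc$records))

  # --- epistasis scan ----------------------------------------------------
  if (length(assoc$significant_ids) >= 2) {
    pairs <- stage("epistasis",
                   epistasis_scan(genotypes, assoc$significant_ids,
                                  p_threshold = config$epistasis_p,
                                  proximity_bp = config$proximity_bp))
    pn_log("epistasis", "%d pairs tested, %d significant",
           nrow(pairs), sum(pairs$significant))
  } else {
    pairs <- epistasis_empty()
    pn_log("epistasis", "fewer than 2 significant SNPs; scan skipped")
  }
  res$epistasis <- pairs
  outputs["epistasis"] <- write_tsv(pairs, file.path(config$outdir, "epistasis.tsv"))

  # --- expression --------------------------------------------------------
  expr <- stage("acquire", acquire(intensities, snr_min = config$snr_min))
  pn_log("acquire", "%d probes in, %d removed by SNR, %d collapsed; %d genes",
         attr(expr, "n_probes_in"), attr(expr, "n_probes_snr_removed"),
         attr(expr, "n_probes_collapsed"), length(unique(expr$gene_id)))
  fit <- stage("normalize", fit_normalization_model(expr))
  pn_log("normalize", "%s after %d EM iterations",
         if (fit$converged) "converged" else "NOT converged", fit$iterations)
  res$fit <- fit
  outputs["normalized"] <- write_tsv(
    data.frame(gene_id = rownames(fit$normalized_expression),
               fit$normalized_expression, check.names = FALSE),
    file.path(config$outdir, "normalized_expression.tsv"))
  jsonlite::write_json(as.list(fit$variance_components),
                       file.path(config$outdir, "variance_components.json"),
                       auto_unbox = TRUE, digits = NA)

  contrasts <- stage("contrasts", compute_contrasts(fit))
  de <- stage("de", call_de(contrasts, sd_threshold = config$de_sd))
  cc <- stage("correlations",
              contrast_correlations(de, sd_threshold = config$de_sd,
                                    all_genes = annotation$gene_id))
  res$de <- de
  res$correlations <- cc
  outputs["de"] <- write_tsv(de, file.path(config$outdir, "de_results.tsv"))
  outputs["colours"] <- write_tsv(cc$colours, file.path(config$outdir,
                                                        "gene_colours.tsv"))
  pn_log("de", "%d genes DE in >= 1 contrast, %d in >= 4",
         sum(de$n_de_contrasts >= 1), sum(de$n_de_contrasts >= 4))

  # --- annotation --------------------------------------------------------
  mappings <- stage("map", map_snps_to_genes(genotypes$map, annotation,
                                             cis_bp = config$cis_bp,
                                             region_bp = config$region_bp))
  res$mappings <- mappings
  outputs["snp_gene_map"] <- write_tsv(mappings,
                                       file.path(config$outdir, "snp_gene_map.tsv"))
  piebald <- stage("genes", call_piebald_genes(de, res$association, annotation,
                                               assoc$significant_ids,
                                               cis_bp = config$cis_bp,
                                               region_bp = config$region_bp))
  res$piebald_genes <- piebald
  outputs["piebald_genes"] <- write_tsv(piebald,
                                        file.path(config$outdir, "piebald_genes.tsv"))
  pn_log("genes", "%d piebald-associated genes (%d via DE+cis, %d via region association)",
         nrow(piebald), sum(piebald$criterion == "de_cis"),
         sum(piebald$criterion == "assoc_region"))

  # --- networks ----------------------------------------------------------
  candidates <- piebald$gene_id
  if (!length(candidates)) candidates <- annotation$gene_id
  reg <- stage("network_reg",
               build_regulatory_network(tfbs, candidates, cc$colours,
                                        min_confidence = config$tfbs_confidence,
                                        min_targets = config$tfbs_min_targets))
  epi <- stage("network_epi",
               build_epistatic_network(pairs, mappings, cc$colours,
                                       hub_threshold = config$hub_threshold,
                                       exclude_proximal = config$exclude_proximal))
  inter <- stage("intersect", intersect_networks(reg, epi$network))
  res$regulatory <- reg
  res$epistatic <- epi
  res$intersection <- inter
  pn_log("network", "regulatory %d nodes/%d edges; reduced epistatic %d/%d; %d hubs; %d intersection genes",
         igraph::vcount(reg), igraph::ecount(reg),
         igraph::vcount(epi$network), igraph::ecount(epi$network),
         sum(epi$hubs$n_pairs > config$hub_threshold), length(inter$genes))

  netdir <- file.path(config$outdir, "networks")
  dir.create(netdir, showWarnings = FALSE)
  for (nm in c("regulatory", "epistatic", "merged")) {
    g <- switch(nm, regulatory = reg, epistatic = epi$network,
                merged = inter$merged)
    outputs[paste0(nm, "_sif")] <- export_network(g, file.path(netdir, paste0(nm, ".sif")), "sif")
    outputs[paste0(nm, "_graphml")] <- export_network(g, file.path(netdir, paste0(nm, ".graphml")), "graphml")
    outputs[paste0(nm, "_attrs")] <- export_network(g, file.path(netdir, paste0(nm, "_nodes.tsv")), "attributes")
  }
  outputs["hubs"] <- write_tsv(epi$hubs, file.path(config$outdir, "hubs.tsv"))
  writeLines(inter$genes, file.path(config$outdir, "intersection_genes.txt"))
  outputs["intersection"] <- file.path(config$outdir, "intersection_genes.txt")

  manifest$outputs <- as.list(outputs)
  manifest$counts <- list(
    n_snps = ncol(genotypes$calls),
    n_cases = length(case_ids(genotypes)),
    n_controls = length(control_ids(genotypes)),
    n_significant_snps = length(assoc$significant_ids),
    n_epistasis_pairs = nrow(pairs),
    n_significant_pairs = sum(pairs$significant),
    n_genes_expression = nrow(fit$normalized_expression),
    n_piebald_genes = nrow(piebald),
    n_hubs = sum(epi$hubs$n_pairs > config$hub_threshold),
    n_intersection_genes = length(inter$genes))
  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t_all, 3)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

epistasis_empty <- function() {
  structure(data.frame(snp_a = character(0), snp_b = character(0),
                       chi2 = numeric(0), df = integer(0), p_value = numeric(0),
                       proximity_flag = logical(0), significant = logical(0),
                       degenerate = logical(0), stringsAsFactors = FALSE),
            class = c("epistasis_records", "data.frame"))
}
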