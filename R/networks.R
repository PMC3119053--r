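#' Build the TFBS-derived regulatory network
#'
#' Retains TFBS records whose core AND matrix similarity reach
#' \code{min_confidence} and whose gene is among the candidate genes; a TF
#' enters the network when it links at least \code{min_targets} candidate
#' genes. Gene nodes carry the expression colour category (over / under /
#' unchanged / absent); candidate genes without retained binding sites remain
#' as isolated nodes.
#'
#' @param tfbs TFBS data frame (tf_name, gene_id, core_similarity,
#'   matrix_similarity).
#' @param candidate_genes Character vector of gene ids (non-empty).
#' @param colours Optional colour table from
#'   \code{\link{contrast_correlations}} (gene_id, colour_category).
#' @param min_confidence Similarity threshold (default 1, i.e. 100%
#'   confidence).
#' @param min_targets Minimum candidate genes a TF must bind (default 1).
#' @return An \code{igraph} graph of class \code{gene_network}: vertex
#'   attributes \code{node_type} ("gene"/"tf") and \code{colour_category};
#'   edge attributes \code{edge_type} ("tfbs") and \code{direction}.
#' @export
build_regulatory_network <- function(tfbs, candidate_genes, colours = NULL,
                                     min_confidence = 1.0, min_targets = 1) {
  if (!length(candidate_genes)) stop("candidate_genes must be non-empty")
  candidate_genes <- unique(candidate_genes)
  keep <- tfbs$core_similarity >= min_confidence &
    tfbs$matrix_similarity >= min_confidence &
    tfbs$gene_id %in% candidate_genes
  hits <- unique(tfbs[keep, c("tf_name", "gene_id")])
  n_targets <- table(hits$tf_name)
  tfs <- names(n_targets)[n_targets >= min_targets]
  hits <- hits[hits$tf_name %in% tfs, , drop = FALSE]

  col_of <- function(ids) {
    out <- rep("absent", length(ids))
    if (!is.null(colours)) {
      j <- match(ids, colours$gene_id)
      out[!is.na(j)] <- colours$colour_category[j[!is.na(j)]]
    }
    out
  }
  nodes <- data.frame(
    name = c(candidate_genes, tfs),
    node_type = rep(c("gene", "tf"), c(length(candidate_genes), length(tfs))),
    colour_category = c(col_of(candidate_genes), rep("absent", length(tfs))),
    stringsAsFactors = FALSE)
  edges <- if (nrow(hits))
    data.frame(from = hits$tf_name, to = hits$gene_id,
               edge_type = "tfbs", direction = "tf->gene",
               n_pairs = NA_integer_, stringsAsFactors = FALSE)
  else
    data.frame(from = character(0), to = character(0),
               edge_type = character(0), direction = character(0),
               n_pairs = integer(0), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  class(g) <- c("gene_network", class(g))
  g
}

#' Build the epistasis-derived gene network with hub reduction
#'
#' Each significant SNP pair becomes an edge between the nearest genes of its
#' two SNPs (pairs collapsing onto a single gene are dropped as self-edges;
#' multiple pairs between the same two genes collapse to one edge annotated
#' with the pair count). A hub is a gene participating in strictly more than
#' \code{hub_threshold} significant pairs (counted per gene before edge
#' collapsing); the reduced network keeps the edges incident to at least one
#' hub.
#'
#' @param pairs Output of \code{\link{epistasis_scan}} (significant rows are
#'   used).
#' @param mappings Output of \code{\link{map_snps_to_genes}} covering every
#'   SNP in a significant pair.
#' @param colours Optional colour table (gene_id, colour_category).
#' @param hub_threshold Hub rule: pair count strictly greater than this
#'   (default 20).
#' @param exclude_proximal Drop proximity-flagged (<100 kb) pairs before
#'   network construction (default FALSE; such pairs may reflect linkage
#'   disequilibrium rather than epistasis).
#' @return List with \code{network} (reduced \code{gene_network}),
#'   \code{full_network}, and \code{hubs} (data frame gene_id, n_pairs).
#' @export
build_epistatic_network <- function(pairs, mappings, colours = NULL,
                                    hub_threshold = 20, exclude_proximal = FALSE) {
  sig <- pairs[!is.na(pairs$significant) & pairs$significant, , drop = FALSE]
  if (exclude_proximal) sig <- sig[!sig$proximity_flag, , drop = FALSE]
  lookup <- stats::setNames(mappings$nearest_gene_id, mappings$snp_id)
  for (s in unique(c(sig$snp_a, sig$snp_b)))
    if (!s %in% names(lookup) || is.na(lookup[[s]]))
      stop("no gene mapping for SNP ", s)
  gene_a <- unname(lookup[sig$snp_a])
  gene_b <- unname(lookup[sig$snp_b])

  # hub rule counts significant pairs per gene before collapsing to edges
  pair_counts <- table(c(gene_a, gene_b))
  # a pair whose two SNPs map to the same gene counts once for that gene
  self <- gene_a == gene_b
  if (any(self)) {
    dup <- table(gene_a[self])
    pair_counts[names(dup)] <- pair_counts[names(dup)] - dup
  }
  hubs <- data.frame(gene_id = names(pair_counts),
                     n_pairs = as.integer(pair_counts),
                     stringsAsFactors = FALSE)
  hubs <- hubs[order(-hubs$n_pairs, hubs$gene_id), , drop = FALSE]
  rownames(hubs) <- NULL
  hub_ids <- hubs$gene_id[hubs$n_pairs > hub_threshold]

  ga <- gene_a[!self]; gb <- gene_b[!self]
  lo <- pmin(ga, gb); hi <- pmax(ga, gb)
  key <- paste(lo, hi, sep = "\r")
  agg <- table(key)
  edge_lo <- sub("\r.*", "", names(agg))
  edge_hi <- sub(".*\r", "", names(agg))

  mk_network <- function(keep_edge) {
    el <- edge_lo[keep_edge]; eh <- edge_hi[keep_edge]
    if (!length(el)) {
      g <- igraph::make_empty_graph(0, directed = FALSE)
      g <- igraph::add_vertices(g, 0)
      g <- igraph::set_vertex_attr(g, "name", value = character(0))
      g <- igraph::set_vertex_attr(g, "node_type", value = character(0))
      g <- igraph::set_vertex_attr(g, "colour_category", value = character(0))
      class(g) <- c("gene_network", class(g))
      return(g)
    }
    node_ids <- sort(unique(c(el, eh)))
    col <- rep("absent", length(node_ids))
    if (!is.null(colours)) {
      j <- match(node_ids, colours$gene_id)
      col[!is.na(j)] <- colours$colour_category[j[!is.na(j)]]
    }
    nodes <- data.frame(name = node_ids, node_type = "gene",
                        colour_category = col, stringsAsFactors = FALSE)
    edges <- data.frame(from = el, to = eh, edge_type = "epistasis",
                        direction = NA_character_,
                        n_pairs = as.integer(agg[keep_edge]),
                        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
    class(g) <- c("gene_network", class(g))
    g
  }
  full <- mk_network(rep(TRUE, length(edge_lo)))
  reduced <- mk_network(edge_lo %in% hub_ids | edge_hi %in% hub_ids)
  list(network = reduced, full_network = full, hubs = hubs)
}

#' Intersect the regulatory and epistatic networks
#'
#' The intersecting landscape is the set of gene-typed nodes present in both
#' networks; TF nodes never count. By default only connected gene nodes
#' (degree >= 1) are considered, since isolated candidate genes are carried
#' in the regulatory network for colouring only.
#'
#' @param regulatory,epistatic \code{gene_network} objects.
#' @param connected_only Require degree >= 1 in each network (default TRUE).
#' @return List with \code{genes} (intersection ids, sorted) and
#'   \code{merged} (union network; vertex attribute \code{in_intersection}).
#' @export
intersect_networks <- function(regulatory, epistatic, connected_only = TRUE) {
  gene_side <- function(g) {
    v <- igraph::V(g)
    ids <- v$name[v$node_type == "gene"]
    if (connected_only) {
      deg <- igraph::degree(g)
      ids <- ids[deg[match(ids, v$name)] >= 1]
    }
    ids
  }
  genes <- sort(intersect(gene_side(regulatory), gene_side(epistatic)))

  vdf <- function(g) as.data.frame(igraph::vertex_attr(g), stringsAsFactors = FALSE)
  edf <- function(g) {
    e <- igraph::as_data_frame(g, what = "edges")
    if (!nrow(e)) return(e)
    e
  }
  nodes <- rbind(vdf(regulatory), vdf(epistatic))
  nodes <- nodes[!duplicated(nodes$name), , drop = FALSE]
  nodes$in_intersection <- nodes$name %in% genes
  edges <- rbind(edf(regulatory), edf(epistatic))
  merged <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  class(merged) <- c("gene_network", class(merged))
  list(genes = genes, merged = merged)
}

#' Export a gene network for Cytoscape
#'
#' Formats: \code{"sif"} writes one "nodeA edge_type nodeB" line per edge
#' (isolated nodes as single-column lines); \code{"graphml"} writes GraphML
#' with the node and edge attributes; \code{"attributes"} writes a
#' node-attribute TSV (id, node_type, colour_category, degree).
#'
#' @param network A \code{gene_network}.
#' @param path Output file path.
#' @param format One of "sif", "graphml", "attributes".
#' @return Invisibly, the path.
#' @export
export_network <- function(network, path, format = c("sif", "graphml", "attributes")) {
  format <- match.arg(format)
  if (format == "sif") {
    e <- igraph::as_data_frame(network, what = "edges")
    lines <- if (nrow(e)) paste(e$from, e$edge_type, e$to) else character(0)
    isolated <- igraph::V(network)$name[igraph::degree(network) == 0]
    writeLines(c(lines, isolated), path)
  } else if (format == "graphml") {
    g <- network
    class(g) <- "igraph"
    # GraphML attribute values may not be NA
    for (a in igraph::edge_attr_names(g)) {
      v <- igraph::edge_attr(g, a)
      v[is.na(v)] <- if (is.numeric(v)) -1 else ""
      igraph::edge_attr(g, a) <- v
    }
    igraph::write_graph(g, path, format = "graphml")
  } else {
    v <- igraph::V(network)
    df <- data.frame(id = v$name, node_type = v$node_type,
                     colour_category = v$colour_category,
                     degree = igraph::degree(network),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a SIF network file
#'
#' @param path SIF file written by \code{\link{export_network}}.
#' @return A \code{gene_network} (node/edge sets; attributes beyond the edge
#'   type are not stored in SIF).
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  edges <- do.call(rbind, lapply(parts[lengths(parts) >= 3], function(p)
    data.frame(from = p[1], to = p[3], edge_type = p[2], stringsAsFactors = FALSE)))
  isolated <- unlist(lapply(parts[lengths(parts) == 1], `[`, 1))
  if (is.null(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        edge_type = character(0), stringsAsFactors = FALSE)
  nodes <- unique(c(edges$from, edges$to, isolated))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  class(g) <- c("gene_network", class(g))
  g
}

#' Read a GraphML network file
#'
#' @param path GraphML file written by \code{\link{export_network}}.
#' @return A \code{gene_network} with its attributes.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  class(g) <- c("gene_network", class(g))
  g
}
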