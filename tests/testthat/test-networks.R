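toy_tfbs <- function() {
  data.frame(tf_name = c("TFa", "TFa", "TFb", "TFb"),
             gene_id = c("g1", "g2", "g2", "g9"),
             core_similarity = c(1, 1, 0.99, 1),
             matrix_similarity = c(1, 1, 1, 1), stringsAsFactors = FALSE)
}

test_that("the 100% confidence filter and candidate restriction shape edges", {
  net <- build_regulatory_network(toy_tfbs(), candidate_genes = c("g1", "g2", "g3"))
  e <- igraph::as_data_frame(net, what = "edges")
  # TFb-g2 fails core similarity 0.99; TFb-g9 targets a non-candidate
  expect_equal(nrow(e), 2)
  expect_setequal(setdiff(c(e$from, e$to), "TFa"), c("g1", "g2"))
  v <- igraph::as_data_frame(net, what = "vertices")
  expect_setequal(v$name[v$node_type == "tf"], "TFa")
  expect_true("g3" %in% v$name[v$node_type == "gene"])  # isolated candidate kept
  expect_equal(igraph::degree(net)[["g3"]], 0)

  empty <- build_regulatory_network(toy_tfbs()[0, ], candidate_genes = c("g1", "g2"))
  expect_equal(igraph::ecount(empty), 0)
  expect_equal(igraph::vcount(empty), 2)
})

test_that("gene nodes carry expression colours with absent as default", {
  cols <- data.frame(gene_id = c("g1", "g2"),
                     colour_category = c("over", "under"))
  net <- build_regulatory_network(toy_tfbs(), c("g1", "g2", "g3"), colours = cols)
  v <- igraph::as_data_frame(net, what = "vertices")
  expect_equal(v$colour_category[v$name == "g1"], "over")
  expect_equal(v$colour_category[v$name == "g3"], "absent")
})

make_pairs <- function(pairs_mat, significant = TRUE) {
  data.frame(snp_a = pairs_mat[, 1], snp_b = pairs_mat[, 2],
             chi2 = 30, df = 8L, p_value = 1e-5,
             proximity_flag = FALSE, significant = significant,
             degenerate = FALSE, stringsAsFactors = FALSE)
}

mapping_for <- function(snps, genes) {
  data.frame(snp_id = snps, nearest_gene_id = genes, distance_bp = 0,
             category = "intragenic", genes_within_region = genes,
             stringsAsFactors = FALSE)
}

test_that("the hub rule is a strict inequality on per-gene pair counts", {
  # hub gene H in 21 pairs; gene X in exactly 20
  snps <- c(sprintf("h%02d", 1:21), sprintf("x%02d", 1:20))
  pm <- rbind(cbind("sH", sprintf("h%02d", 1:21)),
              cbind("sX", sprintf("x%02d", 1:20)))
  maps <- mapping_for(c("sH", "sX", snps),
                      c("H", "X", paste0("leaf_", snps)))
  out <- build_epistatic_network(make_pairs(pm), maps, hub_threshold = 20)
  expect_equal(out$hubs$n_pairs[out$hubs$gene_id == "H"], 21)
  expect_equal(out$hubs$n_pairs[out$hubs$gene_id == "X"], 20)
  hub_ids <- out$hubs$gene_id[out$hubs$n_pairs > 20]
  expect_identical(hub_ids, "H")
  # reduced network holds exactly the 21 edges incident to the hub
  expect_equal(igraph::ecount(out$network), 21)
  expect_true(all(igraph::as_data_frame(out$network, "edges")$from == "H" |
                    igraph::as_data_frame(out$network, "edges")$to == "H"))
})

test_that("reduced edges are a subset of the full network and touch a hub", {
  set.seed(71)
  snps <- sprintf("s%02d", 1:12)
  pm <- t(combn(snps, 2))[sample(66, 30), ]
  maps <- mapping_for(snps, paste0("g", rep(1:6, each = 2)))
  out <- build_epistatic_network(make_pairs(pm), maps, hub_threshold = 8)
  full_e <- igraph::as_data_frame(out$full_network, "edges")
  red_e <- igraph::as_data_frame(out$network, "edges")
  key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_true(all(key(red_e) %in% key(full_e)))
  hubs <- out$hubs$gene_id[out$hubs$n_pairs > 8]
  expect_true(all(red_e$from %in% hubs | red_e$to %in% hubs))
  # self-collapsing pairs are dropped as edges
  expect_false(any(full_e$from == full_e$to))
})

test_that("multiple SNP pairs between two genes collapse with a pair count", {
  pm <- rbind(c("a1", "b1"), c("a2", "b2"), c("a1", "b2"))
  maps <- mapping_for(c("a1", "a2", "b1", "b2"), c("gA", "gA", "gB", "gB"))
  out <- build_epistatic_network(make_pairs(pm), maps, hub_threshold = 0)
  e <- igraph::as_data_frame(out$full_network, "edges")
  expect_equal(nrow(e), 1)
  expect_equal(e$n_pairs, 3)
  expect_equal(out$hubs$n_pairs[out$hubs$gene_id == "gA"], 3)
  expect_error(build_epistatic_network(make_pairs(rbind(c("a1", "zz"))), maps),
               "zz")
})

test_that("proximity-flagged pairs can be excluded from network input", {
  pm <- rbind(c("a1", "b1"), c("a2", "b2"))
  pr <- make_pairs(pm)
  pr$proximity_flag <- c(TRUE, FALSE)
  maps <- mapping_for(c("a1", "a2", "b1", "b2"), c("gA", "gC", "gB", "gD"))
  out <- build_epistatic_network(pr, maps, hub_threshold = 0,
                                 exclude_proximal = TRUE)
  e <- igraph::as_data_frame(out$full_network, "edges")
  expect_equal(nrow(e), 1)
  expect_setequal(c(e$from, e$to), c("gC", "gD"))
})

test_that("network intersection takes connected gene nodes only", {
  reg <- build_regulatory_network(
    data.frame(tf_name = "TFa", gene_id = c("B", "C"),
               core_similarity = 1, matrix_similarity = 1),
    candidate_genes = c("A", "B", "C", "D"))
  pm <- rbind(c("s1", "s2"), c("s1", "s3"))
  maps <- mapping_for(c("s1", "s2", "s3"), c("B", "C", "E"))
  epi <- build_epistatic_network(make_pairs(pm), maps, hub_threshold = 0)
  inter <- intersect_networks(reg, epi$network)
  expect_identical(inter$genes, c("B", "C"))
  # candidate D is a node in the regulatory network but isolated: not counted
  expect_false("D" %in% inter$genes)
  # the TF is never part of the intersection
  expect_false("TFa" %in% inter$genes)
  # idempotent under repetition and subset of both gene-node sets
  inter2 <- intersect_networks(reg, epi$network)
  expect_identical(inter2$genes, inter$genes)
  v <- igraph::as_data_frame(inter$merged, "vertices")
  expect_true(all(v$in_intersection[v$name %in% c("B", "C")]))

  loose <- intersect_networks(reg, epi$network, connected_only = FALSE)
  expect_true(all(inter$genes %in% loose$genes))
})

test_that("disjoint networks intersect to the empty set", {
  reg <- build_regulatory_network(toy_tfbs(), c("g1", "g2"))
  pm <- rbind(c("s1", "s2"))
  maps <- mapping_for(c("s1", "s2"), c("zz1", "zz2"))
  epi <- build_epistatic_network(make_pairs(pm), maps, hub_threshold = 0)
  expect_length(intersect_networks(reg, epi$network)$genes, 0)
})

test_that("SIF and GraphML exports round-trip node and edge sets", {
  net <- build_regulatory_network(toy_tfbs(), c("g1", "g2", "g3"))
  dir <- withr::local_tempdir()
  sif <- export_network(net, file.path(dir, "n.sif"), "sif")
  back <- read_sif(sif)
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
  expect_equal(igraph::ecount(back), igraph::ecount(net))

  gml <- export_network(net, file.path(dir, "n.graphml"), "graphml")
  back2 <- read_network_graphml(gml)
  expect_setequal(igraph::V(back2)$name, igraph::V(net)$name)
  expect_setequal(igraph::V(back2)$node_type, igraph::V(net)$node_type)
  expect_equal(igraph::ecount(back2), igraph::ecount(net))

  skip_if_not_installed("xml2")
  doc <- xml2::read_xml(gml)
  expect_equal(xml2::xml_name(doc), "graphml")
  ns <- xml2::xml_ns(doc)
  expect_true(any(grepl("graphml", unlist(ns))))

  attrs <- export_network(net, file.path(dir, "n_nodes.tsv"), "attributes")
  df <- read.table(attrs, header = TRUE, sep = "\t")
  expect_setequal(df$id, igraph::V(net)$name)
  expect_equal(df$degree[df$id == "TFa"], 2)
  expect_error(export_network(net, file.path(dir, "x"), "cys"))
})

test_that("a two-node network writes a single SIF line", {
  net <- build_regulatory_network(
    data.frame(tf_name = "TFa", gene_id = "g1",
               core_similarity = 1, matrix_similarity = 1),
    candidate_genes = "g1")
  dir <- withr::local_tempdir()
  sif <- export_network(net, file.path(dir, "t.sif"), "sif")
  expect_length(readLines(sif), 1)
})

test_that("node degree attribute equals incident stored edges", {
  net <- build_regulatory_network(toy_tfbs(), c("g1", "g2", "g3"))
  deg <- igraph::degree(net)
  e <- igraph::as_data_frame(net, "edges")
  for (v in names(deg))
    expect_equal(deg[[v]], sum(e$from == v) + sum(e$to == v))
})
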