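test_that("a 3-leaf tree with one duplication is typed correctly", {
  rt <- flag_dubious(reconcile(parse_newick("((a1_A,a2_A),b1_B);"),
                               parse_newick("(A,B)AB;")))
  h <- extract_homologies(rt)
  expect_equal(nrow(h), 3)
  para <- h[h$gene1 == "a1_A" & h$gene2 == "a2_A", ]
  expect_equal(para$type, "within_species_paralog")
  expect_true(para$tree_compliant)
  expect_equal(para$taxon, "A")
  orth <- h[h$gene2 == "b1_B", ]
  expect_equal(orth$type, rep("ortholog_one2many", 2))
  expect_true(all(orth$tree_compliant))
})

test_that("a congruent tree yields compliant one2one orthologues only", {
  rt <- flag_dubious(reconcile(parse_newick("((g1_A,g2_B),(g3_C,g4_D));"),
                               species_tree_4()))
  h <- extract_homologies(rt)
  expect_equal(nrow(h), choose(4, 2))
  expect_equal(unique(h$type), "ortholog_one2one")
  expect_true(all(h$tree_compliant))
})

test_that("dubious-node pairs are orthologues but not tree compliant", {
  rt <- flag_dubious(reconcile(parse_newick("((geneA_A,geneC_C),(geneB_B,geneD_D));"),
                               species_tree_4()))
  h <- extract_homologies(rt)
  # pairs related by the dubious root: one gene from each side
  left <- c("geneA_A", "geneC_C"); right <- c("geneB_B", "geneD_D")
  at_root <- (h$gene1 %in% left) != (h$gene2 %in% left)
  cross <- h[at_root, ]
  expect_equal(nrow(cross), 4)
  expect_true(all(grepl("^ortholog", cross$type)))
  expect_true(all(!cross$tree_compliant))
  inner <- h[!at_root, ]
  expect_true(all(inner$tree_compliant))
  expect_equal(unique(inner$taxon), "root")  # A-C and B-D also map to root
})

test_that("typing is symmetric and every unordered pair gets one type", {
  sim <- simulate_gene_family(species_tree_5(), dup_rate = 0.4, loss_rate = 0.1,
                              seed = 31)
  rt <- flag_dubious(reconcile(sim$gene_tree, species_tree_5()))
  h <- extract_homologies(rt)
  genes <- vapply(tree_leaves(rt), function(l) l$label, character(1))
  expect_equal(nrow(h), choose(length(genes), 2))
  expect_true(all(h$gene1 < h$gene2))
  expect_equal(anyDuplicated(paste(h$gene1, h$gene2)), 0L)
})

test_that("low-consistency duplications rescue orphan genes as orthologues", {
  # left: congruent 5-species subtree; right: a lone human gene duplicated
  # at the root. Consistency = 1/5 < 25%.
  gt <- parse_newick(paste0("(((((h1_human,m1_mouse),d1_dog),c1_chicken),",
                            "z1_zebrafish),h2_human);"))
  rt <- flag_dubious(reconcile(gt, species_tree_5()))
  expect_equal(rt[["event"]], "duplication")
  expect_equal(rt[["consistency"]], 0.2)
  h <- extract_homologies(rt)
  rescued <- h[h$gene1 == "h2_human" | h$gene2 == "h2_human", ]
  cross <- rescued[rescued$species1 != rescued$species2, ]
  expect_equal(nrow(cross), 4)
  expect_true(all(grepl("^ortholog", cross$type)))
  expect_true(all(!cross$tree_compliant))
  same <- rescued[rescued$species1 == rescued$species2, ]
  expect_equal(same$type, "within_species_paralog")
})

test_that("the rescue activates strictly below the consistency threshold", {
  # consistency 1/4 = 25% exactly: no rescue
  gt25 <- parse_newick("((((h1_human,m1_mouse),d1_dog),c1_chicken),h2_human);")
  rt25 <- flag_dubious(reconcile(gt25, species_tree_5()))
  expect_equal(rt25[["consistency"]], 0.25)
  h25 <- extract_homologies(rt25)
  cross25 <- h25[(h25$gene1 == "h2_human" | h25$gene2 == "h2_human") &
                 h25$species1 != h25$species2, ]
  expect_equal(unique(cross25$type), "between_species_paralog")
})

test_that("well-supported duplications keep their paralogue typing", {
  gt <- parse_newick("(((h1_human,m1_mouse),d1_dog),(h2_human,m2_mouse));")
  rt <- flag_dubious(reconcile(gt, species_tree_5()))
  expect_equal(rt[["event"]], "duplication")
  expect_equal(rt[["consistency"]], 2 / 3)
  h <- extract_homologies(rt)
  cross <- h[h$taxon == "eut" &
             (h$gene1 %in% c("h2_human", "m2_mouse") |
              h$gene2 %in% c("h2_human", "m2_mouse")), ]
  expect_true(all(grepl("paralog$", cross$type)))
  expect_true(all(cross$tree_compliant))
})

test_that("flag_dubious leaves orthologue pairs of supported duplications alone", {
  sim <- simulate_gene_family(species_tree_5(), dup_rate = 0.5, loss_rate = 0,
                              seed = 17)
  rt <- reconcile(sim$gene_tree, species_tree_5())
  h_raw <- extract_homologies(rt)
  h_flagged <- extract_homologies(flag_dubious(rt))
  orth <- function(df) {
    o <- df[grepl("^ortholog", df$type) & df$tree_compliant, ]
    paste(o$gene1, o$gene2, o$type)
  }
  expect_setequal(orth(h_raw), orth(h_flagged))
})

test_that("homology export round trips as TSV and OrthoXML", {
  rt <- flag_dubious(reconcile(parse_newick("((a1_A,a2_A),b1_B);"),
                               parse_newick("(A,B)AB;")))
  h <- extract_homologies(rt)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_homologies(h, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(h))
  xml <- withr::local_tempfile(fileext = ".xml")
  write_orthoxml(h, xml)
  doc <- xml2::read_xml(xml)
  expect_length(xml2::xml_find_all(doc, ".//*[local-name()='geneRef']"),
                2 * nrow(h))
})
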