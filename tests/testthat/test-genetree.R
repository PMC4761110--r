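test_that("a congruent one-gene-per-species tree is all speciations", {
  gt <- parse_newick("((g1_A,g2_B),(g3_C,g4_D));")
  rt <- reconcile(gt, species_tree_4())
  events <- c(rt[["event"]], rt$children[[1]][["event"]], rt$children[[2]][["event"]])
  expect_equal(events, rep("speciation", 3))
  expect_equal(rt[["mapping"]], "root")
  expect_equal(rt$children[[1]][["mapping"]], "AB")
})

test_that("a same-species cherry is a duplication under the species root", {
  rt <- reconcile(parse_newick("((a1_A,a2_A),b1_B);"), parse_newick("(A,B)AB;"))
  expect_equal(rt$children[[1]][["event"]], "duplication")
  expect_equal(duplication_consistency(rt$children[[1]]), 1)
  expect_equal(rt[["event"]], "speciation")
})

test_that("disjoint child species sets score 0 and become dubious", {
  rt <- reconcile(parse_newick("((geneA_A,geneC_C),(geneB_B,geneD_D));"),
                  species_tree_4())
  expect_equal(rt[["event"]], "duplication")
  expect_equal(rt[["consistency"]], 0)
  expect_equal(duplication_consistency(rt), 0)
  flagged <- flag_dubious(rt)
  expect_equal(flagged[["event"]], "dubious")
  expect_equal(flagged$children[[1]][["event"]], "speciation")
  # idempotence
  expect_true(trees_equal(flagged, flag_dubious(flagged), tags = TRUE))
})

test_that("consistency is intersection over union of child species sets", {
  # children {A,B} and {A,C}: intersection {A}, union {A,B,C} -> 1/3
  rt <- reconcile(parse_newick("((g1_A,g2_B),(g3_A,g4_C));"), species_tree_4())
  expect_equal(rt[["consistency"]], 1 / 3)
})

test_that("unknown species and non-binary trees are rejected", {
  expect_error(reconcile(parse_newick("(g1_A,g2_X);"), species_tree_4()),
               "species 'X'")
  expect_error(reconcile(parse_newick("(g1_A,g2_B,g3_C);"), species_tree_4()),
               "binary")
})

test_that("reconciliation matches the exhaustive oracle on small trees", {
  # exhaustive over all shapes x species assignments for n = 2, 3;
  # all 15 shapes with sampled assignments for n = 4..7
  species <- c("A", "B", "C", "D")
  newick <- "((A,B)AB,(C,D)CD)root;"
  st <- species_tree_4()
  check <- function(shape, assignment) {
    gt <- shape_to_tree(assign_species(shape, assignment))
    got <- recon_records(reconcile(gt, st))
    want <- oracle_reconcile(gt, newick)
    want <- want[order(vapply(want, `[[`, character(1), "leafset"))]
    expect_equal(lapply(got, `[`, c("leafset", "mapping", "event")), want)
  }
  for (n in 2:3) {
    shapes <- all_shapes(paste0("L", seq_len(n)))
    grid <- expand.grid(rep(list(species), n), stringsAsFactors = FALSE)
    for (shape in shapes) for (k in seq_len(nrow(grid)))
      check(shape, unlist(grid[k, ]))
  }
  set.seed(77)
  for (n in 4:7) {
    shapes <- all_shapes(paste0("L", seq_len(n)))
    for (shape in shapes[sample.int(length(shapes), min(15, length(shapes)))])
      for (r in 1:8) check(shape, sample(species, n, replace = TRUE))
  }
})

test_that("nodes are dated by their species-tree mapping", {
  st <- parse_newick("((A,B)AB[&&NHX:Age=90],C)root[&&NHX:Age=160];")
  st <- comparakit:::annotate_from_nhx(st)
  rt <- reconcile(parse_newick("((g1_A,g2_B),g3_C);"), st)
  expect_equal(date_node(rt$children[[1]], st), list(taxon = "AB", age = 90))
  expect_equal(date_node(rt, st), list(taxon = "root", age = 160))
  leaf <- rt$children[[1]]$children[[1]]
  expect_equal(date_node(leaf, st)$age, 0)
  # explicit calibration table overrides
  expect_equal(date_node(rt, st, ages = c(root = 150))$age, 150)
})

test_that("non-overlapping same-species rows under a duplication merge as a split", {
  st <- parse_newick("(A,B)AB;")
  gt <- parse_newick("((x1_A,x2_A),y_B);")
  rows <- list(
    msa_row("x1_A", "A", gi("A", "c1", 0, 120),
            paste0(strrep("A", 120), strrep("-", 180))),
    msa_row("x2_A", "A", gi("A", "c2", 0, 150),
            paste0(strrep("-", 150), strrep("C", 150))),
    msa_row("y_B", "B", gi("B", "c3", 0, 300), strrep("G", 300)))
  aln <- multiple_alignment(rows)
  rt <- flag_dubious(reconcile(gt, st))
  merged <- detect_gene_splits(rt, aln)
  expect_equal(count_gene_splits(merged), 1)
  expect_length(tree_leaves(merged), 2)
  composite <- tree_leaves(merged)[[1]]
  expect_equal(sort(composite$genes), c("x1_A", "x2_A"))
  expect_true(isTRUE(composite$split_event))
})

test_that("rows overlapping beyond the allowance are not merged", {
  st <- parse_newick("(A,B)AB;")
  gt <- parse_newick("((x1_A,x2_A),y_B);")
  rows <- list(
    msa_row("x1_A", "A", gi("A", "c1", 0, 200),
            paste0(strrep("A", 200), strrep("-", 100))),
    msa_row("x2_A", "A", gi("A", "c2", 0, 150),
            paste0(strrep("-", 150), strrep("C", 150))),  # 50-column overlap
    msa_row("y_B", "B", gi("B", "c3", 0, 300), strrep("G", 300)))
  aln <- multiple_alignment(rows)
  merged <- detect_gene_splits(flag_dubious(reconcile(gt, st)), aln)
  expect_equal(count_gene_splits(merged), 0)
  expect_length(tree_leaves(merged), 3)
})

test_that("leaves connected through a speciation node never merge", {
  # same species via dubious-free speciation path: A genes in both halves
  st <- species_tree_4()
  gt <- parse_newick("((x1_A,g2_B),(x2_A,g4_C));")
  rows <- list(
    msa_row("x1_A", "A", gi("A", "c1", 0, 100),
            paste0(strrep("A", 100), strrep("-", 100))),
    msa_row("x2_A", "A", gi("A", "c2", 0, 80),
            paste0(strrep("-", 120), strrep("C", 80))),
    msa_row("g2_B", "B", gi("B", "c3", 0, 200), strrep("G", 200)),
    msa_row("g4_C", "C", gi("C", "c4", 0, 200), strrep("T", 200)))
  rt <- flag_dubious(reconcile(gt, st))  # root is duplication cons 1 here?
  # root children species {A,B} and {A,C}: consistency 1/3, a duplication;
  # but the path runs through the two speciation children, blocking a merge
  merged <- detect_gene_splits(rt, comparakit::multiple_alignment(rows))
  expect_equal(count_gene_splits(merged), 0)
})

test_that("a missing alignment row is a contract violation", {
  st <- parse_newick("(A,B)AB;")
  rt <- reconcile(parse_newick("(x1_A,y_B);"), st)
  aln <- multiple_alignment(list(msa_row("x1_A", "A", gi("A", "c", 0, 5),
                                         "ACGTA")))
  expect_error(detect_gene_splits(rt, aln), "no row")
})

test_that("three planted splits are recovered as three split events", {
  sim <- simulate_gene_family(species_tree_5(), dup_rate = 0.2, loss_rate = 0,
                              seed = 9, plant_splits = 3)
  rt <- flag_dubious(reconcile(sim$gene_tree, species_tree_5()))
  merged <- detect_gene_splits(rt, sim$alignment)
  expect_equal(count_gene_splits(merged), 3)
  found <- lapply(attr(merged, "gene_splits"), sort)
  truth <- lapply(sim$truth_splits, sort)
  expect_setequal(vapply(found, paste, character(1), collapse = "+"),
                  vapply(truth, paste, character(1), collapse = "+"))
})
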