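test_that("AXT records are shifted to 0-based half-open coordinates", {
  path <- withr::local_tempfile(fileext = ".axt")
  writeLines(c("0 chr1 11 20 c1 101 110 + 55",
               "ACGTACGTAC", "ACGTACGTAC", ""), path)
  blocks <- read_axt(path)
  expect_length(blocks, 1)
  expect_equal(blocks[[1]]$ref$start, 10)
  expect_equal(blocks[[1]]$ref$end, 20)
  expect_equal(blocks[[1]]$qry$start, 100)
  expect_equal(blocks[[1]]$qry$end, 110)
  expect_equal(blocks[[1]]$score, 55)
})

test_that("empty AXT input gives an empty block list", {
  path <- withr::local_tempfile(fileext = ".axt")
  writeLines(c("# comment only", ""), path)
  expect_length(read_axt(path), 0)
})

test_that("AXT read/write/read is the identity on a synthetic file", {
  set.seed(42)
  blocks <- lapply(1:10, function(i) {
    s <- 1000 * i
    len <- sample(20:40, 1)
    seq1 <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
    alignment_block(gi("ref", "chr1", s, s + len),
                    gi("qry", "c2", s + 7, s + 7 + len,
                       strand = sample(c("+", "-"), 1)),
                    score = i * 10, ref_text = seq1, qry_text = seq1)
  })
  p1 <- withr::local_tempfile(fileext = ".axt")
  p2 <- withr::local_tempfile(fileext = ".axt")
  write_axt(blocks, p1)
  write_axt(read_axt(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("malformed AXT is rejected with the offending line number", {
  path <- withr::local_tempfile(fileext = ".axt")
  writeLines(c("0 chr1 11 20 c1 101 110 +", "ACGT", "ACGT"), path)
  expect_error(read_axt(path), "line 1")
  writeLines(c("0 chr1 11 20 c1 101 110 + 55", "ACGTACGTAC", "ACG"), path)
  expect_error(read_axt(path), "length")
})

test_that("MAF blocks map to column-indexed rows", {
  path <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("##maf version=1", "a score=1",
               "s human.chr1 3 8 + 100 ACGT--ACGT",
               "s mouse.chr2 5 10 + 200 ACGTTTACGT", ""), path)
  msa <- read_maf(path)
  expect_equal(msa$n_columns, 10)
  expect_length(msa$rows, 2)
  expect_equal(msa$rows[[1]]$segments[[1]]$start, 3)
  expect_equal(msa$rows[[1]]$segments[[1]]$end, 11)
})

test_that("minus-strand MAF rows convert to forward coordinates and back", {
  # 5 bp row on the minus strand: reverse-strand start 10, size 5, src 100
  # => forward interval [85, 90)
  path <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("a score=0",
               "s qry.sc1 10 5 - 100 ACGTT",
               "s ref.chr1 0 5 + 100 ACGTT", ""), path)
  msa <- read_maf(path)
  seg <- msa$rows[[1]]$segments[[1]]
  expect_equal(seg$start, 85)
  expect_equal(seg$end, 90)
  expect_equal(seg$strand, "-")
  out <- withr::local_tempfile(fileext = ".maf")
  write_maf(msa, out)
  expect_match(grep("qry", readLines(out), value = TRUE),
               "s qry.sc1 10 5 - 100 ACGTT", fixed = TRUE)
})

test_that("a MAF block with no rows is rejected", {
  path <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("##maf version=1", "a score=1", ""), path)
  expect_error(read_maf(path), "no 's' rows")
})

test_that("Newick and NHX trees survive round trips", {
  t1 <- parse_newick("(a,b);")
  expect_equal(tree_size(t1), 3)
  expect_length(tree_leaves(t1), 2)

  nhx <- "((a[&&NHX:S=human],b[&&NHX:S=mouse])[&&NHX:D=Y:SIS=100],c[&&NHX:S=dog]);"
  t2 <- parse_newick(nhx)
  path <- withr::local_tempfile(fileext = ".nhx")
  writeLines(nhx, path)
  t3 <- read_tree(path)
  expect_equal(t3$children[[1]][["event"]], "duplication")
  expect_equal(t3$children[[1]][["consistency"]], 1)
  write_tree(t3, path, "nhx")
  expect_true(trees_equal(t3, read_tree(path), tags = TRUE))
})

test_that("a 50-leaf random tree round trips structurally", {
  set.seed(7)
  grow <- function(n) {
    if (n == 1) return(tree_node(label = sprintf("t%d", sample.int(1e6, 1)),
                                 length = round(stats::runif(1), 4)))
    k <- sample.int(n - 1, 1)
    tree_node(children = list(grow(k), grow(n - k)),
              length = round(stats::runif(1), 4))
  }
  tr <- structure(grow(50), class = "ck_tree")
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree(tr, path)
  expect_true(trees_equal(tr, read_tree(path)))
})

test_that("EMF is column-oriented with an optional score column", {
  rows <- list(msa_row("r1", "human", gi("human", "chr1", 0, 4), "ACGT"),
               msa_row("r2", "mouse", gi("mouse", "chr2", 0, 4), "TGCA"))
  msa <- multiple_alignment(rows)
  path <- withr::local_tempfile(fileext = ".emf")
  write_emf(msa, path)
  body <- readLines(path)
  data_rows <- body[(match("DATA", body) + 1):(match("//", body) - 1)]
  expect_equal(data_rows, c("AT", "CG", "GC", "TA"))

  write_emf(msa, path, scores = c(1.5, 2, 2.5, 3))
  parsed <- read_emf(path)
  expect_equal(unname(parsed$texts), c("ACGT", "TGCA"))
  expect_equal(parsed$scores, c(1.5, 2, 2.5, 3))
})

test_that("OrthoXML export writes one group per pair and validates", {
  empty <- data.frame(gene1 = character(0), gene2 = character(0),
                      species1 = character(0), species2 = character(0),
                      type = character(0), taxon = character(0))
  path <- withr::local_tempfile(fileext = ".xml")
  write_orthoxml(empty, path)
  doc <- xml2::read_xml(path)
  expect_equal(xml2::xml_name(doc), "orthoXML")

  pairs <- data.frame(gene1 = "g1", gene2 = "g2", species1 = "human",
                      species2 = "mouse", type = "ortholog_one2one",
                      taxon = "euarchontoglires")
  write_orthoxml(pairs, path)
  doc <- xml2::read_xml(path)
  groups <- xml2::xml_find_all(doc, ".//*[local-name()='orthologGroup']")
  expect_length(groups, 1)
  refs <- xml2::xml_find_all(groups[[1]], ".//*[local-name()='geneRef']")
  expect_length(refs, 2)
})

test_that("fixedStep wiggle tracks round trip, NA gaps included", {
  track <- list(seq_name = "chr1", start = 0, step = 1,
                values = c(round(stats::runif(100), 3)))
  path <- withr::local_tempfile(fileext = ".wig")
  write_wig_fixedstep(track, path)
  back <- read_wig_fixedstep(path)
  expect_equal(back$values, track$values)
  expect_equal(back$seq_name, "chr1")

  gappy <- list(seq_name = "chr1", start = 10, step = 1,
                values = c(1, 2, NA, NA, 5, 6))
  write_wig_fixedstep(gappy, path)
  expect_equal(read_wig_fixedstep(path)$values, gappy$values)
})

test_that("BED round trips through the internal convention", {
  elems <- list(scored_element(gi("ref", "chr1", 100, 200), score = 3),
                scored_element(gi("ref", "chr2", 0, 50), score = 1))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(elems, path)
  back <- read_bed(path)
  expect_equal(back[[1]]$interval$start, 100)
  expect_equal(back[[1]]$interval$end, 200)
  expect_equal(back[[1]]$score, 3)
})

test_that("gap characters are normalised and intervals validated", {
  expect_error(gi("h", "chr1", 10, 10), "start < end")
  expect_error(gi("h", "chr1", -1, 10), "start < end")
  expect_error(gi("h", "chr1", 0, 10, "x"), "strand")
  r <- msa_row("r", "h", gi("h", "c", 0, 2), "A.C")
  expect_equal(r$text, "A-C")
  expect_error(multiple_alignment(list(
    msa_row("a", "h", gi("h", "c", 0, 3), "ACG"),
    msa_row("b", "m", gi("m", "c", 0, 2), "AC"))), "disagree")
})
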