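# Small shared fixture: a 2-row alignment anchored on "human" and a set of
# nets from a secondary genome, with texts carried on the blocks.
epo_fixture <- function() {
  ref_row <- msa_row("human.chr1", "human", gi("human", "chr1", 0, 10),
                     "ACGT-ACGTAC")
  other <- msa_row("dog.chr2", "dog", gi("dog", "chr2", 0, 11), "ACGTTACGTAC")
  multiple_alignment(list(ref_row, other))
}

test_that("an identical secondary under a gapless net copies the reference", {
  msa <- epo_fixture()
  blk1 <- alignment_block(gi("human", "chr1", 0, 10), gi("low", "sc1", 0, 10),
                          score = 10, ref_text = "ACGTACGTAC",
                          qry_text = "ACGTACGTAC")
  res <- project_secondary(msa, build_nets(build_chains(list(blk1))),
                           "low", "human")
  expect_equal(res$rows[[3]]$text, msa$rows[[1]]$text)
  expect_equal(attr(res, "dropped_insertions"), 0)
})

test_that("secondary insertions are dropped and reference gaps padded", {
  msa <- epo_fixture()
  # 1-base secondary insertion after reference position 4
  blk1 <- alignment_block(gi("human", "chr1", 0, 10), gi("low", "sc1", 0, 11),
                          pairs = matrix(c(5, 0, 1, 5, 0, 0), ncol = 3,
                                         byrow = TRUE),
                          score = 10, ref_text = "ACGTA-ACGTA",
                          qry_text = "ACGTATACGTA")
  res <- project_secondary(msa, build_nets(build_chains(list(blk1))),
                           "low", "human")
  sec <- res$rows[[3]]
  # the inserted T is gone; the reference-gap column got a padding gap
  expect_equal(sec$text, "ACGT-AACGTA")
  expect_equal(attr(res, "dropped_insertions"), 1)
  segs <- mosaic_segments(sec)
  expect_length(segs, 2)
  expect_equal(segs[[1]]$end, 5)
  expect_equal(segs[[2]]$start, 6)  # position 5 was the dropped insertion
})

test_that("pre-existing rows are bit-identical after projection", {
  msa <- epo_fixture()
  blk1 <- alignment_block(gi("human", "chr1", 2, 8), gi("low", "sc2", 10, 16),
                          score = 6, ref_text = "GTACGT", qry_text = "GTACGT")
  res <- project_secondary(msa, build_nets(build_chains(list(blk1))),
                           "low", "human")
  expect_equal(res$n_columns, msa$n_columns)
  for (i in seq_along(msa$rows))
    expect_identical(res$rows[[i]], msa$rows[[i]])
})

test_that("mosaic rows stitch segments from different scaffolds in column order", {
  msa <- epo_fixture()
  b1 <- alignment_block(gi("human", "chr1", 0, 4), gi("low", "scA", 100, 104),
                        score = 4, ref_text = "ACGT", qry_text = "ACGT")
  b2 <- alignment_block(gi("human", "chr1", 5, 10), gi("low", "scB", 50, 55),
                        score = 5, ref_text = "CGTAC", qry_text = "CGTAC")
  nets <- build_nets(build_chains(list(b1, b2)))
  res <- project_secondary(msa, nets, "low", "human")
  segs <- mosaic_segments(res$rows[[3]])
  expect_length(segs, 2)
  expect_equal(vapply(segs, function(s) s$seq_name, character(1)),
               c("scA", "scB"))
  expect_equal(segs[[2]]$start, 50)
})

test_that("gap-stripping the mosaic row recovers the nets' match-state bases", {
  msa <- epo_fixture()
  b1 <- alignment_block(gi("human", "chr1", 0, 6), gi("low", "sc1", 0, 7),
                        pairs = matrix(c(3, 0, 1, 3, 0, 0), ncol = 3,
                                       byrow = TRUE),
                        score = 6, ref_text = "ACG-TAC", qry_text = "ACGATAC")
  b2 <- alignment_block(gi("human", "chr1", 7, 10), gi("low", "sc1", 20, 23),
                        score = 3, ref_text = "TAC", qry_text = "GGC")
  nets <- build_nets(build_chains(list(b1, b2)))
  res <- project_secondary(msa, nets, "low", "human")
  stripped <- gsub("-", "", res$rows[[3]]$text, fixed = TRUE)
  # oracle: recompute match-state bases directly from the blocks
  oracle <- paste0("ACG", "TAC", "GGC")
  expect_equal(stripped, oracle)
})

test_that("an empty projection gives an all-gap row with zero segments", {
  msa <- epo_fixture()
  res <- project_secondary(msa, list(), "low", "human")
  expect_equal(res$rows[[3]]$text, strrep("-", msa$n_columns))
  expect_length(mosaic_segments(res$rows[[3]]), 0)
})

test_that("nets off the reference row are a contract violation", {
  msa <- epo_fixture()
  bad <- alignment_block(gi("human", "chr9", 0, 5), gi("low", "sc1", 0, 5),
                         score = 5, ref_text = "ACGTA", qry_text = "ACGTA")
  expect_error(project_secondary(msa, build_nets(build_chains(list(bad))),
                                 "low", "human"),
               "absent from the reference row")
})

test_that("only the top-level net contributes to each column", {
  msa <- epo_fixture()
  # strong net covers everything; weak net with different bases overlaps
  strong <- alignment_block(gi("human", "chr1", 0, 10), gi("low", "sc1", 0, 10),
                            score = 100, ref_text = "ACGTACGTAC",
                            qry_text = "AAAAAAAAAA")
  weak <- alignment_block(gi("human", "chr1", 2, 8), gi("low", "sc2", 0, 6),
                          score = 6, ref_text = "GTACGT", qry_text = "CCCCCC")
  nets <- build_nets(build_chains(list(strong, weak)))
  res <- project_secondary(msa, nets, "low", "human")
  expect_false(grepl("C", gsub("-", "", res$rows[[3]]$text)))
})
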