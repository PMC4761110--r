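#' Join compatible alignment blocks into chains
#'
#' Runs of blocks compatible in order and orientation on both genomes are
#' joined into chains. Two blocks are chainable when they share query
#' sequence and orientation, do not overlap, appear in the same order on
#' both genomes, and are separated by at most `max_chain_gap` on each
#' genome. Every input block ends up in exactly one chain. The chain score
#' is the total number of match-state bases over its blocks; substitution
#' matrix rescoring is deliberately out of scope.
#'
#' Minus-strand query coordinates are kept in query-strand space (the AXT
#' convention), so "increasing query coordinate" is the ordering test for
#' both orientations.
#'
#' @param blocks List of [alignment_block()]s, all on one reference
#'   sequence.
#' @param max_chain_gap Maximum separation (bp) on either genome between
#'   consecutive blocks of a chain. Default 300 kb.
#' @return List of chains (class `alignment_chain`), each with `blocks`,
#'   `score`, `ref_span`, `qry_span`.
#' @export
build_chains <- function(blocks, max_chain_gap = 300000) {
  if (length(blocks) == 0) return(list())
  ref_seqs <- unique(vapply(blocks, function(b) b$ref$seq_name, character(1)))
  if (length(ref_seqs) != 1)
    stop("build_chains requires blocks on a single reference sequence, got: ",
         paste(ref_seqs, collapse = ", "))
  ord <- order(vapply(blocks, function(b) b$ref$start, numeric(1)),
               vapply(blocks, function(b) b$qry$start, numeric(1)))
  blocks <- blocks[ord]
  chains <- list()  # each: list of block indices into `blocks`
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    best <- 0L; best_end <- -Inf
    for (k in seq_along(chains)) {
      last <- blocks[[chains[[k]][length(chains[[k]])]]]
      if (blocks_chainable(last, b, max_chain_gap) && last$ref$end > best_end) {
        best <- k; best_end <- last$ref$end  # tightest predecessor wins
      }
    }
    if (best > 0L) chains[[best]] <- c(chains[[best]], i)
    else chains[[length(chains) + 1L]] <- i
  }
  lapply(chains, function(idx) new_chain(blocks[idx]))
}

# Order/orientation/gap compatibility of consecutive chain members.
blocks_chainable <- function(a, b, max_gap) {
  if (a$qry$seq_name != b$qry$seq_name || a$qry$strand != b$qry$strand)
    return(FALSE)
  if (b$ref$start < a$ref$end || b$qry$start < a$qry$end) return(FALSE)
  (b$ref$start - a$ref$end) <= max_gap && (b$qry$start - a$qry$end) <= max_gap
}

new_chain <- function(blocks) {
  ref1 <- blocks[[1]]$ref; refn <- blocks[[length(blocks)]]$ref
  qs <- min(vapply(blocks, function(b) b$qry$start, numeric(1)))
  qe <- max(vapply(blocks, function(b) b$qry$end, numeric(1)))
  structure(list(
    blocks = blocks,
    score = sum(vapply(blocks, block_matched, numeric(1))),
    ref_span = gi(ref1$species, ref1$seq_name, ref1$start, refn$end),
    qry_span = gi(blocks[[1]]$qry$species, blocks[[1]]$qry$seq_name, qs, qe,
                  blocks[[1]]$qry$strand)),
    class = "alignment_chain")
}

#' @export
print.alignment_chain <- function(x, ...) {
  cat(sprintf("<chain of %d block(s), score %g, %s:%g-%g ~ %s:%g-%g(%s)>\n",
              length(x$blocks), x$score,
              x$ref_span$seq_name, x$ref_span$start, x$ref_span$end,
              x$qry_span$seq_name, x$qry_span$start, x$qry_span$end,
              x$qry_span$strand))
  invisible(x)
}

#' Select the best chain per reference region ("netting")
#'
#' Chains are considered in descending score order. A chain becomes a net
#' only where its reference span fits entirely inside unclaimed reference
#' space (a top-level net) or entirely inside one internal gap of an
#' already-placed net (a child net, one level deeper). Chains fitting
#' nowhere are dropped whole — no truncation. The result is the stringent
#' nested hierarchy of best-in-region alignments.
#'
#' @param chains List of `alignment_chain`s on one reference sequence.
#' @param min_score Optional score floor; chains below it are dropped.
#' @return Top-level forest: list of nets (class `alignment_net`), each
#'   with `chain`, `level`, and `children` occupying its internal
#'   reference gaps.
#' @export
build_nets <- function(chains, min_score = 0) {
  chains <- Filter(function(ch) ch$score >= min_score, chains)
  if (length(chains) == 0) return(list())
  ord <- order(-vapply(chains, function(ch) ch$score, numeric(1)),
               vapply(chains, function(ch) ch$ref_span$start, numeric(1)),
               vapply(chains, function(ch) ch$qry_span$seq_name, character(1)))
  forest <- list()
  for (ch in chains[ord]) forest <- place_chain(forest, ch, 1L)
  forest
}

# Recursive greedy placement; returns the updated forest (chain may be
# dropped when it overlaps placed nets without fitting a gap).
place_chain <- function(forest, chain, level) {
  s <- chain$ref_span$start; e <- chain$ref_span$end
  for (k in seq_along(forest)) {
    net <- forest[[k]]
    ns <- net$chain$ref_span$start; ne <- net$chain$ref_span$end
    if (s >= ns && e <= ne) {
      # inside this net's extent: must fit one internal gap
      for (g in chain_ref_gaps(net$chain)) {
        if (s >= g[1] && e <= g[2]) {
          net$children <- place_chain(net$children, chain, net$level + 1L)
          forest[[k]] <- net
          return(forest)
        }
      }
      return(forest)  # overlaps the net's blocks: dropped
    }
    if (s < ne && e > ns) return(forest)  # partial overlap: dropped
  }
  forest[[length(forest) + 1L]] <-
    structure(list(chain = chain, level = level, children = list()),
              class = "alignment_net")
  forest
}

# Reference-coordinate gaps between consecutive blocks of a chain.
chain_ref_gaps <- function(chain) {
  n <- length(chain$blocks)
  if (n < 2) return(list())
  gaps <- list()
  for (i in seq_len(n - 1)) {
    a <- chain$blocks[[i]]$ref$end; b <- chain$blocks[[i + 1]]$ref$start
    if (b > a) gaps[[length(gaps) + 1L]] <- c(a, b)
  }
  gaps
}

#' Flatten a net forest into a data frame
#'
#' @param nets Forest from [build_nets()].
#' @return Data frame with one row per net (level, score, spans).
#' @export
net_table <- function(nets) {
  rows <- list()
  walk <- function(net) {
    rows[[length(rows) + 1L]] <<- data.frame(
      level = net$level, score = net$chain$score,
      ref_seq = net$chain$ref_span$seq_name,
      ref_start = net$chain$ref_span$start, ref_end = net$chain$ref_span$end,
      qry_seq = net$chain$qry_span$seq_name,
      qry_start = net$chain$qry_span$start, qry_end = net$chain$qry_span$end,
      strand = net$chain$qry_span$strand, n_blocks = length(net$chain$blocks))
    for (ch in net$children) walk(ch)
  }
  for (n in nets) walk(n)
  if (length(rows) == 0) return(data.frame())
  do.call(rbind, rows)
}

#' All blocks of a net forest, top-level nets only or all levels
#' @param nets Forest from [build_nets()].
#' @param top_only Keep only level-1 nets.
#' @return List of [alignment_block()]s sorted by reference start.
#' @export
net_blocks <- function(nets, top_only = FALSE) {
  out <- list()
  walk <- function(net) {
    out <<- c(out, net$chain$blocks)
    if (!top_only) for (ch in net$children) walk(ch)
  }
  for (n in nets) walk(n)
  out[order(vapply(out, function(b) b$ref$start, numeric(1)))]
}
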