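#' First synteny pass: group consecutive collinear alignment blocks
#'
#' Scans blocks in reference order and joins consecutive blocks that are
#' in the same order and orientation on both genomes. To be included in a
#' group, a block must not be separated from the previous member by more
#' than `max_group_gap` on either genome (the bound is inclusive: a gap of
#' exactly `max_group_gap` still joins). Overlapping blocks have a
#' separation of zero.
#'
#' @param blocks List of [alignment_block()]s on one reference sequence.
#' @param max_group_gap Maximum separation in bp, default 200 kb.
#' @return List of collinear groups (class `collinear_group`), each with
#'   `members`, `ref_span`, `qry_span`, `orientation`.
#' @export
group_collinear <- function(blocks, max_group_gap = 200000) {
  if (length(blocks) == 0) return(list())
  ord <- order(vapply(blocks, function(b) b$ref$seq_name, character(1)),
               vapply(blocks, function(b) b$ref$start, numeric(1)),
               vapply(blocks, function(b) b$qry$start, numeric(1)))
  blocks <- blocks[ord]
  groups <- list(); current <- list(blocks[[1]])
  for (i in seq_along(blocks)[-1]) {
    prev <- current[[length(current)]]; b <- blocks[[i]]
    if (blocks_groupable(prev, b, max_group_gap)) {
      current[[length(current) + 1L]] <- b
    } else {
      groups[[length(groups) + 1L]] <- new_group(current)
      current <- list(b)
    }
  }
  groups[[length(groups) + 1L]] <- new_group(current)
  groups
}

# Same order and orientation on both genomes, separation within the bound
# on both genomes (inclusive; negative separations count as 0).
blocks_groupable <- function(a, b, max_gap) {
  if (a$ref$seq_name != b$ref$seq_name ||
      a$qry$seq_name != b$qry$seq_name ||
      a$qry$strand != b$qry$strand) return(FALSE)
  if (b$qry$start < a$qry$start) return(FALSE)  # order break on the query
  ref_gap <- max(0, b$ref$start - a$ref$end)
  qry_gap <- max(0, b$qry$start - a$qry$end)
  ref_gap <= max_gap && qry_gap <= max_gap
}

new_group <- function(members) {
  qs <- min(vapply(members, function(b) b$qry$start, numeric(1)))
  qe <- max(vapply(members, function(b) b$qry$end, numeric(1)))
  r1 <- members[[1]]$ref
  structure(list(
    members = members,
    ref_span = gi(r1$species, r1$seq_name,
                  members[[1]]$ref$start, members[[length(members)]]$ref$end),
    qry_span = gi(members[[1]]$qry$species, members[[1]]$qry$seq_name, qs, qe,
                  members[[1]]$qry$strand),
    orientation = if (members[[1]]$qry$strand == "+") "same" else "inverted"),
    class = "collinear_group")
}

#' Second synteny pass: join nascent groups into macro-synteny blocks
#'
#' Groups on the same (reference, query) sequence pair, in the same order
#' and orientation, are merged into one syntenic block when the material
#' between them — other groups or plain gap — represents strictly less
#' than `max_internal` on either genome. Merging is transitive: small
#' internal rearrangements (e.g. a local inversion) are absorbed into the
#' surrounding block.
#'
#' @param groups Output of [group_collinear()].
#' @param max_internal Strict bound (bp) on internal rearrangement span,
#'   default 3 Mb.
#' @return List of synteny blocks (class `synteny_block`), sorted by
#'   reference coordinate, each with `groups`, `ref_span`, `qry_span`,
#'   `orientation`.
#' @export
join_groups <- function(groups, max_internal = 3e6) {
  if (length(groups) == 0) return(list())
  ord <- order(vapply(groups, function(g) g$ref_span$seq_name, character(1)),
               vapply(groups, function(g) g$ref_span$start, numeric(1)))
  groups <- groups[ord]
  # open block per (ref seq, qry seq, orientation) key
  blocks <- list(); open <- list()
  key_of <- function(g) paste(g$ref_span$seq_name, g$qry_span$seq_name,
                              g$qry_span$strand, sep = "\r")
  for (g in groups) {
    key <- key_of(g)
    joined <- FALSE
    if (!is.null(open[[key]])) {
      last <- blocks[[open[[key]]]]
      if (groups_joinable(last, g, max_internal)) {
        blocks[[open[[key]]]] <- extend_block(last, g)
        joined <- TRUE
      }
    }
    if (!joined) {
      blocks[[length(blocks) + 1L]] <- new_synteny_block(g)
      open[[key]] <- length(blocks)
    }
  }
  blocks[order(vapply(blocks, function(b) b$ref_span$seq_name, character(1)),
               vapply(blocks, function(b) b$ref_span$start, numeric(1)))]
}

# Intervening material between the block so far and the next group must
# span < max_internal on both genomes (strict), with consistent order.
groups_joinable <- function(block, g, max_internal) {
  if (g$qry_span$start < block$qry_span$end &&
      g$qry_span$end > block$qry_span$start) return(FALSE)
  if (g$qry_span$start < block$qry_span$start) return(FALSE)  # order break
  ref_between <- max(0, g$ref_span$start - block$ref_span$end)
  qry_between <- max(0, g$qry_span$start - block$qry_span$end)
  ref_between < max_internal && qry_between < max_internal
}

new_synteny_block <- function(g) {
  structure(list(groups = list(g), ref_span = g$ref_span,
                 qry_span = g$qry_span, orientation = g$orientation),
            class = "synteny_block")
}

extend_block <- function(block, g) {
  block$groups[[length(block$groups) + 1L]] <- g
  rs <- block$ref_span
  block$ref_span <- gi(rs$species, rs$seq_name, rs$start,
                       max(rs$end, g$ref_span$end))
  qs <- block$qry_span
  block$qry_span <- gi(qs$species, qs$seq_name, min(qs$start, g$qry_span$start),
                       max(qs$end, g$qry_span$end), qs$strand)
  block
}

#' Build large-scale synteny blocks from pairwise alignment blocks
#'
#' Composition of the two passes: [group_collinear()] then
#' [join_groups()]. Input blocks are typically the top-level net blocks of
#' a pairwise comparison.
#'
#' @param blocks List of [alignment_block()]s.
#' @param max_group_gap Pass-1 inclusive separation bound (default 200 kb).
#' @param max_internal Pass-2 strict internal-rearrangement bound
#'   (default 3 Mb).
#' @return List of `synteny_block`s sorted by reference coordinate.
#' @export
build_synteny <- function(blocks, max_group_gap = 200000, max_internal = 3e6) {
  join_groups(group_collinear(blocks, max_group_gap), max_internal)
}

#' Tabulate synteny blocks
#' @param synteny List of `synteny_block`s.
#' @return Data frame with one row per block.
#' @export
synteny_table <- function(synteny) {
  if (length(synteny) == 0) return(data.frame())
  do.call(rbind, lapply(synteny, function(b) data.frame(
    ref_seq = b$ref_span$seq_name, ref_start = b$ref_span$start,
    ref_end = b$ref_span$end, qry_seq = b$qry_span$seq_name,
    qry_start = b$qry_span$start, qry_end = b$qry_span$end,
    orientation = b$orientation, n_groups = length(b$groups))))
}

#' @export
print.synteny_block <- function(x, ...) {
  cat(sprintf("<synteny_block %s:%g-%g ~ %s:%g-%g (%s), %d group(s)>\n",
              x$ref_span$seq_name, x$ref_span$start, x$ref_span$end,
              x$qry_span$seq_name, x$qry_span$start, x$qry_span$end,
              x$orientation, length(x$groups)))
  invisible(x)
}
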