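#' Multi-resolution conservation score store
#'
#' Per-base conservation scores are stored together with their averages
#' over 10, 100 and 500 bp windows so that a display of any region can be
#' served at the coarsest resolution that still gives at least one value
#' per pixel. Undefined (unaligned) positions are `NA` and are excluded
#' from window means; a window with no defined base is itself `NA`.
#' Trailing partial windows are averaged over their defined bases.
#'
#' @param scores Numeric vector of per-base scores, `NA` for positions
#'   without a score.
#' @param window_sizes Window sizes (bp) to precompute; the raw (1 bp)
#'   track is always kept.
#' @return Object of class `resolution_store` with `base_scores` and
#'   `windows` (named list of window-mean vectors, including `"1"`).
#' @export
build_store <- function(scores, window_sizes = c(10, 100, 500)) {
  scores <- as.numeric(scores)
  windows <- list(`1` = scores)
  for (w in window_sizes) {
    n_win <- ceiling(length(scores) / w)
    means <- vapply(seq_len(n_win), function(i) {
      chunk <- scores[((i - 1) * w + 1):min(i * w, length(scores))]
      if (all(is.na(chunk))) NA_real_ else mean(chunk, na.rm = TRUE)
    }, numeric(1))
    windows[[as.character(w)]] <- means
  }
  structure(list(base_scores = scores, windows = windows),
            class = "resolution_store")
}

#' @export
print.resolution_store <- function(x, ...) {
  cat(sprintf("<resolution_store: %d bp, windows {%s}>\n",
              length(x$base_scores), paste(names(x$windows), collapse = ", ")))
  invisible(x)
}

#' Pick the display resolution for a region
#'
#' The number of pixels available and the length of the region determine
#' the ideal resolution: the smallest stored window `w` such that
#' `ceiling(region_length / w) <= pixels`. When even the coarsest window
#' yields more values than pixels, the coarsest window is returned.
#'
#' @param region_length Region length in bp.
#' @param pixels Available pixels.
#' @param stored Stored window sizes (ascending).
#' @return Selected window size in bp.
#' @export
select_resolution <- function(region_length, pixels, stored = c(1, 10, 100, 500)) {
  stored <- sort(stored)
  for (w in stored) if (ceiling(region_length / w) <= pixels) return(w)
  stored[length(stored)]
}

#' Genome coverage of a constrained-element set
#'
#' @param elements List of [scored_element()]s (or `genomic_interval`s) on
#'   one genome.
#' @param genome_length Total genome length in bp.
#' @return List with `covered_bp` (union of the elements) and `fraction`.
#' @export
element_coverage <- function(elements, genome_length) {
  ir <- elements_to_iranges(elements)
  covered <- sum(vapply(ir, function(r)
    sum(IRanges::width(IRanges::reduce(r))), numeric(1)))
  list(covered_bp = covered, fraction = covered / genome_length)
}

#' Base-level overlap partition of two element sets
#'
#' Per-base union arithmetic on one genome: how many bases are covered
#' only by set A, by both, and only by set B. The three parts sum to the
#' coverage of the union of the two sets. Symmetric under swapping A and
#' B (with only-A/only-B exchanged).
#'
#' @param set_a,set_b Lists of [scored_element()]s on the same genome.
#' @return List with `only_a`, `shared`, `only_b` (bp).
#' @export
element_overlap <- function(set_a, set_b) {
  a <- elements_to_iranges(set_a); b <- elements_to_iranges(set_b)
  seqs <- union(names(a), names(b))
  only_a <- shared <- only_b <- 0
  empty <- IRanges::IRanges()
  for (s in seqs) {
    ra <- IRanges::reduce(if (s %in% names(a)) a[[s]] else empty)
    rb <- IRanges::reduce(if (s %in% names(b)) b[[s]] else empty)
    shared <- shared + sum(IRanges::width(IRanges::intersect(ra, rb)))
    only_a <- only_a + sum(IRanges::width(IRanges::setdiff(ra, rb)))
    only_b <- only_b + sum(IRanges::width(IRanges::setdiff(rb, ra)))
  }
  list(only_a = only_a, shared = shared, only_b = only_b)
}

# Named-by-sequence IRanges from scored elements / intervals (half-open
# internal coordinates become closed IRanges).
elements_to_iranges <- function(elements) {
  iv <- lapply(elements, function(e)
    if (inherits(e, "scored_element")) e$interval else e)
  seqs <- vapply(iv, function(x) x$seq_name, character(1))
  out <- list()
  for (s in unique(seqs)) {
    sub <- iv[seqs == s]
    out[[s]] <- IRanges::IRanges(
      start = vapply(sub, function(x) x$start + 1, numeric(1)),
      end = vapply(sub, function(x) x$end, numeric(1)))
  }
  out
}

#' Serialise a resolution store as TSV
#' @param store A `resolution_store`.
#' @param path Output path.
#' @export
write_store <- function(store, path) {
  out <- character(0)
  for (w in names(store$windows))
    out <- c(out, paste0(w, "\t",
                         paste(format(store$windows[[w]], scientific = FALSE,
                                      trim = TRUE),
                               collapse = ",")))
  writeLines(out, path)
  invisible(path)
}
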