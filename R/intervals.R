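#' Genomic interval
#'
#' The universal coordinate atom of the toolkit. Coordinates are 0-based,
#' half-open (`start` inclusive, `end` exclusive) on the forward strand of
#' the named sequence; `strand` records the orientation of the feature.
#' External dialects (AXT 1-based inclusive, MAF reverse-strand starts) are
#' converted at the file boundary, never inside the package.
#'
#' @param species Species label, e.g. `"human"`.
#' @param seq_name Sequence (chromosome/scaffold) name.
#' @param start 0-based inclusive start (bp).
#' @param end Exclusive end (bp); must satisfy `start < end`.
#' @param strand `"+"` or `"-"`.
#' @param seq_length Optional total length of the named sequence; required
#'   only by writers of dialects that store reverse-strand coordinates
#'   (MAF).
#' @return An object of class `genomic_interval`.
#' @examples
#' gi("human", "chr1", 0, 100)
#' @export
gi <- function(species, seq_name, start, end, strand = "+", seq_length = NA_integer_) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0 || start >= end)
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-', got '", strand, "'")
  structure(
    list(species = as.character(species), seq_name = as.character(seq_name),
         start = start, end = end, strand = strand,
         seq_length = as.numeric(seq_length)),
    class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s.%s:%g-%g(%s)\n", x$species, x$seq_name, x$start, x$end, x$strand))
  invisible(x)
}

#' @rdname gi
#' @param x A `genomic_interval`.
#' @export
gi_width <- function(x) x$end - x$start

#' Signed gap between two intervals on one sequence
#'
#' Distance from the end of `a` to the start of `b` (bp). Negative values
#' denote overlap; callers that need the separation used by the synteny
#' grouping rule clamp negatives to zero.
#' @param a,b `genomic_interval`s on the same sequence.
#' @return Numeric signed gap in bp.
#' @export
gi_gap <- function(a, b) {
  if (a$start <= b$start) b$start - a$end else a$start - b$end
}

#' Pairwise alignment block
#'
#' A locally aligned segment pair. The gap structure is run-length encoded:
#' each row of `pairs` is `(match, ref_gap, qry_gap)` meaning `match`
#' aligned columns, then `ref_gap` reference-only bases (insertion in the
#' reference / deletion in the query), then `qry_gap` query-only bases.
#' Row sums over `match + ref_gap` must equal the reference span and
#' `match + qry_gap` the query span.
#'
#' @param ref,qry `genomic_interval`s for the two genomes.
#' @param pairs Numeric matrix with columns `match`, `ref_gap`, `qry_gap`;
#'   defaults to a single gapless run covering both spans.
#' @param score Non-negative alignment score.
#' @param ref_text,qry_text Optional gapped sequence texts (used by AXT
#'   round trips and by low-coverage projection; synthesised blocks may
#'   omit them).
#' @return An object of class `alignment_block`.
#' @export
alignment_block <- function(ref, qry, pairs = NULL, score = 0,
                            ref_text = NULL, qry_text = NULL) {
  if (is.null(pairs)) {
    if (gi_width(ref) != gi_width(qry))
      stop("gapless block requires equal ref and qry widths")
    pairs <- matrix(c(gi_width(ref), 0, 0), ncol = 3)
  }
  pairs <- matrix(as.numeric(pairs), ncol = 3,
                  dimnames = list(NULL, c("match", "ref_gap", "qry_gap")))
  if (any(pairs < 0)) stop("negative run length in gap structure")
  if (sum(pairs[, "match"] + pairs[, "ref_gap"]) != gi_width(ref))
    stop("gap structure does not cover the reference span")
  if (sum(pairs[, "match"] + pairs[, "qry_gap"]) != gi_width(qry))
    stop("gap structure does not cover the query span")
  if (score < 0) stop("score must be non-negative")
  structure(list(ref = ref, qry = qry, pairs = pairs, score = as.numeric(score),
                 ref_text = ref_text, qry_text = qry_text),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("<block %s.%s:%g-%g ~ %s.%s:%g-%g(%s) score=%g>\n",
              x$ref$species, x$ref$seq_name, x$ref$start, x$ref$end,
              x$qry$species, x$qry$seq_name, x$qry$start, x$qry$end,
              x$qry$strand, x$score))
  invisible(x)
}

#' Number of match-state (aligned) bases in a block
#' @param block An `alignment_block`.
#' @export
block_matched <- function(block) sum(block$pairs[, "match"])

#' Scored interval (constrained element)
#'
#' @param interval A `genomic_interval`.
#' @param score Element score.
#' @param p_value Probability in `[0, 1]`.
#' @return An object of class `scored_element`.
#' @export
scored_element <- function(interval, score = NA_real_, p_value = NA_real_) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value must lie in [0, 1]")
  structure(list(interval = interval, score = as.numeric(score),
                 p_value = as.numeric(p_value)),
            class = "scored_element")
}

#' Multiple alignment container
#'
#' Column-indexed rows; each row is a (row id, species, ordered segment
#' list, gapped text) tuple. Rows of fragmented (low-coverage) genomes may
#' be mosaics of several segments, possibly from different scaffolds.
#'
#' @param rows List of rows as built by [msa_row()].
#' @return An object of class `multiple_alignment` with fields `rows` and
#'   `n_columns`.
#' @export
multiple_alignment <- function(rows) {
  if (length(rows) == 0) stop("a multiple alignment needs at least one row")
  nc <- unique(vapply(rows, function(r) nchar(r$text), numeric(1)))
  if (length(nc) != 1)
    stop("rows disagree on column count: ", paste(nc, collapse = ", "))
  for (r in rows) {
    ungapped <- nchar(gsub("-", "", r$text, fixed = TRUE))
    seglen <- sum(vapply(r$segments, gi_width, numeric(1)))
    if (length(r$segments) && ungapped != seglen)
      stop("row '", r$row_id, "': ungapped text length ", ungapped,
           " != total segment width ", seglen)
  }
  structure(list(rows = rows, n_columns = nc), class = "multiple_alignment")
}

#' @rdname multiple_alignment
#' @param row_id Unique row identifier.
#' @param species Species label.
#' @param segments List of `genomic_interval`s in row order.
#' @param text Gapped sequence text; `.` gap characters are normalised to
#'   `-` on construction.
#' @export
msa_row <- function(row_id, species, segments, text) {
  if (inherits(segments, "genomic_interval")) segments <- list(segments)
  list(row_id = row_id, species = species, segments = segments,
       text = gsub(".", "-", text, fixed = TRUE))
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment: %d rows x %d columns>\n",
              length(x$rows), x$n_columns))
  invisible(x)
}
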