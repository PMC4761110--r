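#' Project a secondary (low-coverage) genome into a multiple alignment
#'
#' Maps a fragmented/low-coverage genome into an existing
#' reference-anchored multiple alignment using its pairwise alignment nets
#' against the reference species. For every net block, a secondary base
#' aligned to a reference base is placed in that reference base's
#' alignment column; secondary bases inserted relative to the reference
#' are dropped (and counted); columns where the reference row is gapped —
#' deletions in the reference lineage — receive a padding gap in the
#' secondary row, as do columns outside any net. Existing rows and the
#' column count are never modified.
#'
#' Only top-level nets contribute; overlaps are resolved by score
#' (highest first, first writer per column wins). The resulting row is a
#' mosaic: an ordered list of segments possibly drawn from several
#' scaffolds.
#'
#' @param msa A [multiple_alignment()] with exactly one row for
#'   `reference_species`.
#' @param nets Net forest from [build_nets()], reference vs. secondary.
#' @param secondary_species Species label of the projected genome.
#' @param reference_species Species label of the anchoring row.
#' @return The alignment with one appended mosaic row;
#'   `attr(, "dropped_insertions")` counts secondary bases discarded as
#'   reference-relative insertions within the projected region.
#' @export
project_secondary <- function(msa, nets, secondary_species, reference_species) {
  ref_idx <- which(vapply(msa$rows, function(r) r$species, character(1)) ==
                   reference_species)
  if (length(ref_idx) != 1)
    stop("alignment must contain exactly one row for reference species '",
         reference_species, "', found ", length(ref_idx))
  ref_row <- msa$rows[[ref_idx]]
  if (length(ref_row$segments) != 1)
    stop("the reference row must be a single-segment row")
  seg <- ref_row$segments[[1]]
  if (seg$strand != "+")
    stop("reference rows on the minus strand are not supported")
  ref_chars <- strsplit(ref_row$text, "")[[1]]
  base_cols <- which(ref_chars != "-")  # column of the k-th reference base
  col_of <- function(pos) base_cols[pos - seg$start + 1]

  sec_chars <- rep("-", msa$n_columns)
  placed <- vector("list", msa$n_columns)  # (seq_name, pos, strand) per column
  dropped <- 0

  tops <- Filter(function(n) n$level == 1L, nets)
  tops <- tops[order(-vapply(tops, function(n) n$chain$score, numeric(1)))]
  for (net in tops) {
    sp <- net$chain$ref_span
    if (sp$seq_name != seg$seq_name || sp$start >= seg$end || sp$end <= seg$start)
      stop("net ", sp$seq_name, ":", sp$start, "-", sp$end,
           " references coordinates absent from the reference row")
    for (b in net$chain$blocks) {
      qchars <- if (!is.null(b$qry_text))
        strsplit(gsub("-", "", b$qry_text, fixed = TRUE), "")[[1]]
      else rep("N", gi_width(b$qry))
      ref_pos <- b$ref$start; qry_pos <- b$qry$start; qi <- 1L
      for (j in seq_len(nrow(b$pairs))) {
        m <- b$pairs[j, "match"]
        if (m > 0) for (k in seq_len(m)) {
          p <- ref_pos + k - 1
          if (p >= seg$start && p < seg$end) {
            col <- col_of(p)
            if (sec_chars[col] == "-") {
              sec_chars[col] <- qchars[qi + k - 1]
              placed[[col]] <- list(seq_name = b$qry$seq_name,
                                    pos = qry_pos + k - 1,
                                    strand = b$qry$strand)
            }
          }
        }
        ref_pos <- ref_pos + m + b$pairs[j, "ref_gap"]
        qg <- unname(b$pairs[j, "qry_gap"])
        if (qg > 0 && ref_pos > seg$start && ref_pos <= seg$end)
          dropped <- dropped + qg
        qry_pos <- qry_pos + m + qg
        qi <- qi + m + qg
      }
    }
  }

  segments <- columns_to_segments(placed, secondary_species)
  new_row <- msa_row(row_id = paste0(secondary_species, "_mosaic"),
                     species = secondary_species, segments = segments,
                     text = paste(sec_chars, collapse = ""))
  out <- multiple_alignment(c(msa$rows, list(new_row)))
  attr(out, "dropped_insertions") <- dropped
  out
}

# Collapse per-column placements into maximal contiguous segments.
columns_to_segments <- function(placed, species) {
  segments <- list(); open <- NULL
  for (col in seq_along(placed)) {
    p <- placed[[col]]
    if (is.null(p)) next
    if (!is.null(open) && p$seq_name == open$seq_name &&
        p$strand == open$strand && p$pos == open$last + 1) {
      open$last <- p$pos
    } else {
      if (!is.null(open))
        segments[[length(segments) + 1L]] <-
          gi(species, open$seq_name, open$first, open$last + 1, open$strand)
      open <- list(seq_name = p$seq_name, strand = p$strand,
                   first = p$pos, last = p$pos)
    }
  }
  if (!is.null(open))
    segments[[length(segments) + 1L]] <-
      gi(species, open$seq_name, open$first, open$last + 1, open$strand)
  segments
}

#' Ordered segment list of a mosaic row
#'
#' @param row An alignment row (e.g. the one appended by
#'   [project_secondary()]).
#' @return List of `genomic_interval`s in column order; empty for an
#'   all-gap projection.
#' @export
mosaic_segments <- function(row) row$segments
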