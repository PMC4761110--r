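#' Read a MAF alignment block
#'
#' Reads the first (or `which`-th) alignment block of a MAF file into a
#' [multiple_alignment()]. MAF `s` lines carry 0-based starts on the strand
#' of the row; minus-strand starts are measured from the reverse
#' complement and are converted here to forward-strand coordinates using
#' the source length field, so every internal interval is forward-strand
#' with the row orientation kept in `strand`.
#'
#' @param path Path to a MAF file.
#' @param which 1-based index of the alignment block to read.
#' @return A [multiple_alignment()].
#' @export
read_maf <- function(path, which = 1L) {
  lines <- readLines(path)
  blocks <- list(); current <- NULL
  flush <- function(cur, acc) if (!is.null(cur)) c(acc, list(cur)) else acc
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (startsWith(line, "a")) {
      blocks <- flush(current, blocks); current <- list()
    } else if (startsWith(line, "s ") || startsWith(line, "s\t")) {
      if (is.null(current))
        stop("MAF format error at line ", i, ": 's' line outside a block")
      f <- strsplit(trimws(line), "[ \t]+")[[1]]
      if (length(f) != 7)
        stop("MAF format error at line ", i, ": expected 7 fields on 's' line")
      current[[length(current) + 1L]] <- list(src = f[2],
        start = as.numeric(f[3]), size = as.numeric(f[4]), strand = f[5],
        src_size = as.numeric(f[6]), text = f[7], line = i)
    }
  }
  blocks <- flush(current, blocks)
  if (which > length(blocks)) stop("MAF file has only ", length(blocks), " block(s)")
  srows <- blocks[[which]]
  if (length(srows) == 0) stop("MAF format error: block ", which, " has no 's' rows")
  widths <- vapply(srows, function(s) nchar(s$text), numeric(1))
  if (length(unique(widths)) != 1)
    stop("MAF format error: rows of block ", which, " differ in column count")
  rows <- lapply(srows, function(s) {
    dot <- regexpr(".", s$src, fixed = TRUE)
    species <- if (dot > 0) substr(s$src, 1, dot - 1) else s$src
    seq_name <- if (dot > 0) substr(s$src, dot + 1, nchar(s$src)) else s$src
    if (s$strand == "-") {
      start <- s$src_size - (s$start + s$size); end <- s$src_size - s$start
    } else {
      start <- s$start; end <- s$start + s$size
    }
    ungapped <- nchar(gsub("[-.]", "", s$text))
    if (ungapped != s$size)
      stop("MAF format error at line ", s$line, ": size field ", s$size,
           " != ungapped text length ", ungapped)
    msa_row(row_id = s$src, species = species,
            segments = gi(species, seq_name, start, end, s$strand, s$src_size),
            text = s$text)
  })
  multiple_alignment(rows)
}

#' Write a multiple alignment as MAF
#'
#' Inverse of [read_maf()] for single-segment rows. A mosaic row (several
#' segments) is emitted as one `s` line per segment, with that segment's
#' bases at its columns and gaps elsewhere; standard MAF has no
#' single-line representation for mosaics.
#'
#' @param msa A [multiple_alignment()].
#' @param path Output path.
#' @param score Optional block score written on the `a` line.
#' @export
write_maf <- function(msa, path, score = 0) {
  out <- c("##maf version=1", sprintf("a score=%s", format(score, scientific = FALSE)))
  for (r in msa$rows) {
    if (length(r$segments) <= 1L) {
      out <- c(out, maf_s_line(r$species, r$segments, r$text))
    } else {
      cols <- segment_columns(r)
      chars <- strsplit(r$text, "")[[1]]
      for (k in seq_along(r$segments)) {
        text <- rep("-", length(chars))
        text[cols[[k]]] <- chars[cols[[k]]]
        out <- c(out, maf_s_line(r$species, r$segments[k],
                                 paste(text, collapse = "")))
      }
    }
  }
  writeLines(c(out, ""), path)
  invisible(path)
}

maf_s_line <- function(species, segments, text) {
  if (length(segments) == 0)
    stop("cannot write a MAF row with no segments")
  seg <- segments[[1]]
  size <- gi_width(seg)
  src_size <- if (is.na(seg$seq_length)) seg$end else seg$seq_length
  start <- if (seg$strand == "-") src_size - seg$end else seg$start
  sprintf("s %s.%s %g %g %s %g %s",
          species, seg$seq_name, start, size, seg$strand, src_size, text)
}

# Column indices (1-based) occupied by each segment of a row, in row order.
segment_columns <- function(row) {
  chars <- strsplit(row$text, "")[[1]]
  base_cols <- which(chars != "-")
  widths <- vapply(row$segments, gi_width, numeric(1))
  stops <- cumsum(widths); starts <- c(1, utils::head(stops, -1) + 1)
  lapply(seq_along(widths), function(k) base_cols[starts[k]:stops[k]])
}
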