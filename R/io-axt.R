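#' Read pairwise alignment blocks from an AXT file
#'
#' AXT carries 1-based inclusive coordinates; they are shifted to the
#' internal 0-based half-open convention on read. For minus-strand records
#' the query coordinates remain in query-strand (reverse-complement) space,
#' as in the dialect itself — AXT does not carry the chromosome length
#' needed to flip them to the forward strand.
#'
#' @param path Path to an AXT file.
#' @param ref_species,qry_species Species labels to attach to the two
#'   genomes (AXT records only sequence names).
#' @return List of [alignment_block()]s.
#' @export
read_axt <- function(path, ref_species = "ref", qry_species = "qry") {
  lines <- readLines(path)
  blocks <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || startsWith(line, "#")) { i <- i + 1L; next }
    fields <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (length(fields) != 9)
      stop("AXT format error at line ", i, ": expected 9 header fields, got ",
           length(fields))
    if (i + 2L > length(lines))
      stop("AXT format error at line ", i, ": truncated record")
    ref_text <- toupper(lines[i + 1L])
    qry_text <- toupper(lines[i + 2L])
    if (nchar(ref_text) != nchar(qry_text))
      stop("AXT format error at line ", i + 1L,
           ": sequence lines differ in length")
    rs <- as.numeric(fields[3]); re <- as.numeric(fields[4])
    qs <- as.numeric(fields[6]); qe <- as.numeric(fields[7])
    ref <- gi(ref_species, fields[2], rs - 1, re)
    qry <- gi(qry_species, fields[5], qs - 1, qe, strand = fields[8])
    pairs <- texts_to_pairs(ref_text, qry_text)
    if (sum(pairs[, "match"] + pairs[, "ref_gap"]) != gi_width(ref))
      stop("AXT format error at line ", i,
           ": reference span does not match sequence length")
    if (sum(pairs[, "match"] + pairs[, "qry_gap"]) != gi_width(qry))
      stop("AXT format error at line ", i,
           ": query span does not match sequence length")
    blocks[[length(blocks) + 1L]] <-
      alignment_block(ref, qry, pairs, score = as.numeric(fields[9]),
                      ref_text = ref_text, qry_text = qry_text)
    i <- i + 3L
  }
  blocks
}

#' Write alignment blocks as AXT
#'
#' Inverse of [read_axt()]. Blocks lacking sequence text are emitted with
#' `N` placeholders consistent with their gap structure. Blocks are written
#' sorted by (reference sequence, reference start) for reproducibility.
#'
#' @param blocks List of [alignment_block()]s.
#' @param path Output path.
#' @export
write_axt <- function(blocks, path) {
  ord <- order(vapply(blocks, function(b) b$ref$seq_name, character(1)),
               vapply(blocks, function(b) b$ref$start, numeric(1)))
  out <- character(0)
  for (k in seq_along(ord)) {
    b <- blocks[[ord[k]]]
    texts <- block_texts(b)
    out <- c(out,
             paste(k - 1L, b$ref$seq_name, b$ref$start + 1, b$ref$end,
                   b$qry$seq_name, b$qry$start + 1, b$qry$end,
                   b$qry$strand, format(b$score, scientific = FALSE)),
             texts$ref, texts$qry, "")
  }
  writeLines(out, path)
  invisible(path)
}

# Run-length gap structure from a pair of gapped texts.
texts_to_pairs <- function(ref_text, qry_text) {
  r <- strsplit(chartr(".", "-", ref_text), "")[[1]]
  q <- strsplit(chartr(".", "-", qry_text), "")[[1]]
  state <- ifelse(r == "-", 3L, ifelse(q == "-", 2L, 1L))  # 1 match, 2 ref_gap, 3 qry_gap
  if (any(r == "-" & q == "-")) stop("column gapped in both sequences")
  runs <- rle(state)
  pairs <- matrix(0, nrow = 0, ncol = 3)
  cur <- c(0, 0, 0)
  for (j in seq_along(runs$values)) {
    v <- runs$values[j]; len <- runs$lengths[j]
    if (v == 1L && (cur[2] > 0 || cur[3] > 0)) {
      pairs <- rbind(pairs, cur); cur <- c(0, 0, 0)
    }
    cur[v] <- cur[v] + len
  }
  pairs <- rbind(pairs, cur)
  colnames(pairs) <- c("match", "ref_gap", "qry_gap")
  pairs
}

# Gapped texts for a block, synthesising placeholders when absent.
block_texts <- function(b) {
  if (!is.null(b$ref_text) && !is.null(b$qry_text))
    return(list(ref = b$ref_text, qry = b$qry_text))
  ref <- character(0); qry <- character(0)
  for (j in seq_len(nrow(b$pairs))) {
    m <- b$pairs[j, "match"]; rg <- b$pairs[j, "ref_gap"]; qg <- b$pairs[j, "qry_gap"]
    ref <- c(ref, strrep("N", m), strrep("N", rg), strrep("-", qg))
    qry <- c(qry, strrep("N", m), strrep("-", rg), strrep("N", qg))
  }
  list(ref = paste(ref, collapse = ""), qry = paste(qry, collapse = ""))
}
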