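#' Write a multiple alignment in column-oriented EMF layout
#'
#' One `SEQ` header line per row segment (row index, species, sequence
#' name, 0-based half-open interval, strand), then a `DATA` section with
#' one output line per alignment column holding one character per row and,
#' when `scores` is given, a trailing numeric conservation-score column.
#' The dialect is self-documented here and in the README; it is not
#' claimed byte-compatible with any archive's EMF dumps.
#'
#' @param msa A [multiple_alignment()].
#' @param path Output path.
#' @param scores Optional numeric vector of per-column scores
#'   (length `n_columns`).
#' @export
write_emf <- function(msa, path, scores = NULL) {
  if (!is.null(scores) && length(scores) != msa$n_columns)
    stop("need one score per alignment column")
  out <- "##emf comparakit 1"
  for (i in seq_along(msa$rows)) {
    r <- msa$rows[[i]]
    for (seg in r$segments)
      out <- c(out, sprintf("SEQ %d %s %s %g %g %s", i, r$species,
                            seg$seq_name, seg$start, seg$end, seg$strand))
    if (length(r$segments) == 0)
      out <- c(out, sprintf("SEQ %d %s . 0 0 +", i, r$species))
  }
  out <- c(out, "DATA")
  mat <- do.call(rbind, lapply(msa$rows, function(r) strsplit(r$text, "")[[1]]))
  cols <- apply(mat, 2, paste, collapse = "")
  if (!is.null(scores))
    cols <- paste(cols, format(scores, scientific = FALSE, trim = TRUE))
  writeLines(c(out, cols, "//"), path)
  invisible(path)
}

#' Parse back an EMF file written by [write_emf()]
#'
#' @param path Path to an EMF file.
#' @return List with `texts` (named by `row<i>`), `species`, and `scores`
#'   (`NULL` when the file carries no score column).
#' @export
read_emf <- function(path) {
  lines <- readLines(path)
  seq_lines <- grep("^SEQ ", lines, value = TRUE)
  data_at <- match("DATA", lines)
  if (is.na(data_at)) stop("EMF format error: no DATA section")
  body <- lines[(data_at + 1L):(match("//", lines) - 1L)]
  fields <- strsplit(body, " ", fixed = TRUE)
  chars <- vapply(fields, `[`, character(1), 1)
  n_rows <- length(unique(vapply(strsplit(seq_lines, " "), `[`, character(1), 2)))
  texts <- vapply(seq_len(n_rows), function(i)
    paste(substr(chars, i, i), collapse = ""), character(1))
  scores <- if (all(lengths(fields) >= 2))
    as.numeric(vapply(fields, `[`, character(1), 2)) else NULL
  sp <- vapply(strsplit(seq_lines, " "), `[`, character(1), 3)
  idx <- as.integer(vapply(strsplit(seq_lines, " "), `[`, character(1), 2))
  list(texts = stats::setNames(texts, paste0("row", seq_len(n_rows))),
       species = sp[!duplicated(idx)], scores = scores)
}

#' Write homology pairs as OrthoXML
#'
#' Emits a minimal valid OrthoXML 0.3 document: one `species`/`gene`
#' listing per species and one `orthologGroup` (or `paralogGroup` for
#' paralogue types) per homology pair, each with two `geneRef` entries and
#' the homology type as a `property`.
#'
#' @param pairs Data frame of homology pairs as produced by
#'   [extract_homologies()] (columns `gene1`, `gene2`, `species1`,
#'   `species2`, `type`, `taxon`).
#' @param path Output path.
#' @export
write_orthoxml <- function(pairs, path) {
  doc <- xml2::xml_new_root("orthoXML",
    xmlns = "http://orthoXML.org/2011/", version = "0.3",
    origin = "comparakit", originVersion = "0.1.0")
  genes <- unique(data.frame(
    gene = c(pairs$gene1, pairs$gene2),
    species = c(pairs$species1, pairs$species2)))
  gene_id <- stats::setNames(seq_len(nrow(genes)), genes$gene)
  for (sp in unique(genes$species)) {
    sp_node <- xml2::xml_add_child(doc, "species", name = sp, NCBITaxId = "0")
    db <- xml2::xml_add_child(sp_node, "database", name = "comparakit", version = "1")
    gl <- xml2::xml_add_child(db, "genes")
    for (g in genes$gene[genes$species == sp])
      xml2::xml_add_child(gl, "gene", id = as.character(gene_id[[g]]), geneId = g)
  }
  groups <- xml2::xml_add_child(doc, "groups")
  if (nrow(pairs)) for (i in seq_len(nrow(pairs))) {
    kind <- if (grepl("paralog", pairs$type[i])) "paralogGroup" else "orthologGroup"
    grp <- xml2::xml_add_child(groups, kind)
    xml2::xml_add_child(grp, "property", name = "homology_type", value = pairs$type[i])
    xml2::xml_add_child(grp, "property", name = "taxon", value = pairs$taxon[i])
    xml2::xml_add_child(grp, "geneRef", id = as.character(gene_id[[pairs$gene1[i]]]))
    xml2::xml_add_child(grp, "geneRef", id = as.character(gene_id[[pairs$gene2[i]]]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write intervals as BED
#'
#' 3-column BED for plain intervals, 6-column when any element carries a
#' score or strand information is wanted. BED is natively 0-based
#' half-open, matching the internal convention.
#'
#' @param elements List of [genomic_interval()]s or [scored_element()]s.
#' @param path Output path.
#' @param six_col Force 6-column output (name, score, strand added).
#' @export
write_bed <- function(elements, path, six_col = FALSE) {
  iv <- lapply(elements, function(e) if (inherits(e, "scored_element")) e$interval else e)
  sc <- vapply(elements, function(e)
    if (inherits(e, "scored_element")) e$score else NA_real_, numeric(1))
  ord <- order(vapply(iv, function(x) x$species, character(1)),
               vapply(iv, function(x) x$seq_name, character(1)),
               vapply(iv, function(x) x$start, numeric(1)))
  six_col <- six_col || any(!is.na(sc))
  lines <- vapply(ord, function(i) {
    x <- iv[[i]]
    if (six_col)
      sprintf("%s\t%g\t%g\t%s\t%g\t%s", x$seq_name, x$start, x$end,
              paste0("elem", i), ifelse(is.na(sc[i]), 0, sc[i]), x$strand)
    else sprintf("%s\t%g\t%g", x$seq_name, x$start, x$end)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file into scored elements
#' @param path Path to a 3- or 6-column BED file.
#' @param species Species label to attach.
#' @return List of [scored_element()]s.
#' @export
read_bed <- function(path, species = "ref") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    strand <- if (length(f) >= 6) f[6] else "+"
    score <- if (length(f) >= 5) as.numeric(f[5]) else NA_real_
    scored_element(gi(species, f[1], as.numeric(f[2]), as.numeric(f[3]), strand),
                   score = score)
  })
}

#' Read a fixedStep wiggle track
#'
#' @param path Path to a wiggle file with `fixedStep` declaration lines.
#' @return List with `seq_name`, `start` (0-based position of the first
#'   value), `step`, and `values`. Multiple declaration blocks on one
#'   sequence are stitched, with `NA` filling unscored gaps.
#' @export
read_wig_fixedstep <- function(path) {
  lines <- readLines(path)
  seq_name <- NULL; step <- 1; vals <- numeric(0); offset <- 0; start0 <- NULL
  for (line in lines) {
    if (startsWith(line, "fixedStep")) {
      kv <- strsplit(strsplit(trimws(line), "[ \t]+")[[1]][-1], "=")
      opts <- stats::setNames(vapply(kv, `[`, character(1), 2),
                              vapply(kv, `[`, character(1), 1))
      seq_name <- opts[["chrom"]]
      step <- as.numeric(opts[["step"]] %||% "1")
      this_start <- as.numeric(opts[["start"]]) - 1  # wiggle is 1-based
      if (is.null(start0)) start0 <- this_start
      offset <- (this_start - start0) / step
      if (offset < length(vals)) stop("overlapping fixedStep declarations")
      if (offset > length(vals)) vals[(length(vals) + 1):offset] <- NA_real_
    } else if (nzchar(trimws(line)) && !startsWith(line, "track")) {
      if (is.null(seq_name)) stop("wiggle value before any fixedStep declaration")
      vals[length(vals) + 1L] <- as.numeric(line)
    }
  }
  list(seq_name = seq_name %||% NA_character_, start = start0 %||% 0,
       step = step, values = vals)
}

#' Write a fixedStep wiggle track
#' @param track List as returned by [read_wig_fixedstep()].
#' @param path Output path.
#' @export
write_wig_fixedstep <- function(track, path) {
  out <- character(0)
  vals <- track$values
  runs <- rle(is.na(vals))
  pos <- 0
  for (j in seq_along(runs$values)) {
    len <- runs$lengths[j]
    if (!runs$values[j]) {
      out <- c(out,
               sprintf("fixedStep chrom=%s start=%g step=%g", track$seq_name,
                       track$start + pos * track$step + 1, track$step),
               format(vals[(pos + 1):(pos + len)], scientific = FALSE, trim = TRUE))
    }
    pos <- pos + len
  }
  writeLines(out, path)
  invisible(path)
}

#' Read/write release cluster tables
#'
#' One cluster per line: `stable_id <TAB> version <TAB> member,member,...`.
#' Clusters without an assigned id use `.` in the id column.
#'
#' @param path Path to a cluster TSV.
#' @return List of clusters (`stable_id`, `version`, `members`).
#' @export
read_clusters <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    list(stable_id = if (f[1] == ".") NA_character_ else f[1],
         version = as.integer(f[2]),
         members = strsplit(f[3], ",", fixed = TRUE)[[1]])
  })
}

#' @rdname read_clusters
#' @param clusters List of clusters.
#' @export
write_clusters <- function(clusters, path) {
  writeLines(vapply(clusters, function(cl)
    sprintf("%s\t%d\t%s", ifelse(is.na(cl$stable_id), ".", cl$stable_id),
            cl$version %||% 1L, paste(sort(cl$members), collapse = ",")),
    character(1)), path)
  invisible(path)
}

#' Read/write member description tables
#'
#' TSV with columns family id, member id, free-text description.
#' @param path Path to a description TSV.
#' @return Data frame with columns `family`, `member`, `description`.
#' @export
read_descriptions <- function(path) {
  df <- utils::read.delim(path, header = FALSE, quote = "",
                          col.names = c("family", "member", "description"),
                          colClasses = "character")
  df
}

#' @rdname read_descriptions
#' @param df Data frame with columns `family`, `member`, `description`.
#' @export
write_descriptions <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
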