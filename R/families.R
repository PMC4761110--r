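#' Consensus name and score for a protein family
#'
#' The family name is the most frequent normalised description among
#' members with an *informative* description. The score is the percentage
#' of informative members whose normalised description matches the
#' consensus — contains it or is contained by it. Families scoring below
#' 40% are named `AMBIGUOUS`; families with no informative description at
#' all (score 0) are named `UNKNOWN`.
#'
#' Normalisation lowercases, strips punctuation, collapses whitespace and
#' removes isoform/fragment suffixes. Ties between equally frequent
#' candidates break toward the longer normalised description, then
#' lexicographically.
#'
#' @param descriptions Character vector of free-text member descriptions
#'   (or a data frame with a `description` column).
#' @param min_score Naming threshold in percent (default 40; `>=` keeps
#'   the consensus name).
#' @return List with `name`, `score` (percent, in `[0, 100]`) and
#'   `n_informative`.
#' @export
name_family <- function(descriptions, min_score = 40) {
  if (is.data.frame(descriptions)) descriptions <- descriptions$description
  informative <- descriptions[is_informative(descriptions)]
  if (length(informative) == 0)
    return(list(name = "UNKNOWN", score = 0, n_informative = 0L))
  norm <- vapply(informative, normalize_description, character(1),
                 USE.NAMES = FALSE)
  norm <- norm[nzchar(norm)]
  if (length(norm) == 0)
    return(list(name = "UNKNOWN", score = 0, n_informative = 0L))
  freq <- table(norm)
  best <- names(freq)[freq == max(freq)]
  consensus <- best[order(-nchar(best), best)][1]
  hits <- vapply(norm, function(d)
    grepl(consensus, d, fixed = TRUE) || grepl(d, consensus, fixed = TRUE),
    logical(1), USE.NAMES = FALSE)
  score <- 100 * sum(hits) / length(norm)
  name <- if (score >= min_score) consensus
          else if (score > 0) "AMBIGUOUS"
          else "UNKNOWN"
  list(name = name, score = score, n_informative = length(norm))
}

#' Informativeness of free-text protein descriptions
#'
#' A description is uninformative when empty or matching one of the
#' documented stop patterns: "uncharacterized"/"uncharacterised",
#' "hypothetical protein", "novel protein", "open reading frame", "cDNA"
#' clone labels, and bare accession-like tokens.
#'
#' @param descriptions Character vector.
#' @return Logical vector.
#' @export
is_informative <- function(descriptions) {
  d <- trimws(tolower(descriptions))
  stop_patterns <- c("^$", "uncharacteri[sz]ed", "hypothetical protein",
                     "novel protein", "open reading frame", "\\bcdna\\b",
                     "^[a-z]{0,4}[_-]?[0-9]{3,}(\\.[0-9]+)?$")
  keep <- !Reduce(`|`, lapply(stop_patterns, function(p) grepl(p, d)))
  keep & !is.na(d)
}

#' @rdname name_family
#' @param x A single description string.
#' @export
normalize_description <- function(x) {
  x <- tolower(x)
  x <- gsub("\\b(isoform|transcript variant)\\b.*$", "", x)
  x <- gsub("\\(fragment\\)|\\bfragment\\b", "", x)
  x <- gsub("[[:punct:]]", " ", x)
  trimws(gsub("[[:space:]]+", " ", x))
}

#' Name every family of a description table
#'
#' @param df Data frame with columns `family`, `member`, `description`
#'   (as read by [read_descriptions()]).
#' @param min_score Naming threshold in percent.
#' @return Data frame with one row per family: `family`, `name`, `score`,
#'   `n_members`, `n_informative`.
#' @export
name_families <- function(df, min_score = 40) {
  fams <- unique(df$family)
  do.call(rbind, lapply(fams, function(f) {
    sub <- df$description[df$family == f]
    res <- name_family(sub, min_score)
    data.frame(family = f, name = res$name, score = res$score,
               n_members = length(sub), n_informative = res$n_informative)
  }))
}
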