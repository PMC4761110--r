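#' Phylogenetic trees with per-node annotations
#'
#' Trees are held as recursive node lists: each node has `label`,
#' `length` (branch length to parent, `NA` when absent), `children`
#' (empty for leaves) and `nhx` (a named character vector of NHX tags).
#' Reconciliation annotates nodes in place with `species` (leaves),
#' `event`, `consistency`, `mapping` and `species_under`; the NHX writer
#' serialises these so annotated trees survive a round trip.
#'
#' @param label Node label (may be `""` for internal nodes).
#' @param children List of child nodes (empty for a leaf).
#' @param length Branch length, `NA` if absent.
#' @param nhx Named character vector of NHX tags.
#' @return A node; the root node of a tree carries class `ck_tree`.
#' @export
tree_node <- function(label = "", children = list(), length = NA_real_,
                      nhx = character(0)) {
  list(label = label, children = children, length = length, nhx = nhx)
}

#' Parse a Newick or NHX string
#'
#' @param text A single Newick/NHX description ending in `;`.
#' @return The root node, classed `ck_tree`.
#' @export
parse_newick <- function(text) {
  text <- trimws(text)
  if (!endsWith(text, ";")) stop("tree string must end with ';'")
  chars <- strsplit(substr(text, 1, nchar(text) - 1), "")[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(chars)) chars[pos] else ""
  parse_clade <- function() {
    children <- list()
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        children[[length(children) + 1L]] <- parse_clade()
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("malformed tree near position ", pos)
      }
    }
    label <- ""
    while (!peek() %in% c("", ",", ")", ":", "[", "(")) {
      label <- paste0(label, peek()); pos <<- pos + 1L
    }
    len <- NA_real_
    if (peek() == ":") {
      pos <<- pos + 1L
      num <- ""
      while (grepl("[-0-9.eE+]", peek())) { num <- paste0(num, peek()); pos <<- pos + 1L }
      len <- as.numeric(num)
    }
    nhx <- character(0)
    if (peek() == "[") {
      com <- ""
      pos <<- pos + 1L
      while (peek() != "]") {
        if (peek() == "") stop("unterminated comment in tree string")
        com <- paste0(com, peek()); pos <<- pos + 1L
      }
      pos <<- pos + 1L
      if (startsWith(com, "&&NHX")) {
        tags <- strsplit(sub("^&&NHX:?", "", com), ":", fixed = TRUE)[[1]]
        tags <- tags[nzchar(tags)]
        kv <- strsplit(tags, "=", fixed = TRUE)
        nhx <- stats::setNames(vapply(kv, function(p) paste(p[-1], collapse = "="),
                                      character(1)),
                               vapply(kv, `[`, character(1), 1))
      }
    }
    tree_node(label = label, children = children, length = len, nhx = nhx)
  }
  root <- parse_clade()
  if (pos <= length(chars)) stop("trailing characters after tree at position ", pos)
  structure(root, class = "ck_tree")
}

#' Serialise a tree to Newick/NHX
#'
#' @param tree Root node as returned by [parse_newick()] or built with
#'   [tree_node()].
#' @param dialect `"newick"` (labels and branch lengths only) or `"nhx"`
#'   (additionally writes NHX tag blocks; reconciliation annotations are
#'   exported as tags `S`, `D`, `DD`, `SIS` and `Ev`).
#' @return A single string ending in `;`.
#' @export
format_newick <- function(tree, dialect = c("newick", "nhx")) {
  dialect <- match.arg(dialect)
  fmt <- function(node) {
    core <- if (length(node$children))
      paste0("(", paste(vapply(node$children, fmt, character(1)), collapse = ","), ")",
             node$label)
    else node$label
    if (!is.na(node$length))
      core <- paste0(core, ":", format(node$length, scientific = FALSE))
    if (dialect == "nhx") {
      tags <- node_nhx_tags(node)
      if (length(tags))
        core <- paste0(core, "[&&NHX:",
                       paste(names(tags), tags, sep = "=", collapse = ":"), "]")
    }
    core
  }
  paste0(fmt(tree), ";")
}

# NHX tags for a node: explicit tags plus reconciliation annotations.
# Exact [[ ]] access throughout: partial matching must not let `species`
# pick up `species_under` on internal nodes.
node_nhx_tags <- function(node) {
  tags <- node[["nhx"]]
  if (!is.null(node[["species"]])) tags["S"] <- node[["species"]]
  ev <- node[["event"]]
  if (!is.null(ev)) {
    tags["D"] <- if (ev %in% c("duplication", "dubious")) "Y" else "N"
    if (ev == "dubious") tags["DD"] <- "Y"
    if (ev == "gene_split") tags["Ev"] <- "gene_split"
  }
  if (!is.null(node[["consistency"]]))
    tags["SIS"] <- format(round(100 * node[["consistency"]], 4), scientific = FALSE)
  if (!is.null(node[["mapping"]])) tags["Map"] <- node[["mapping"]]
  tags[!duplicated(names(tags), fromLast = TRUE)]
}

#' @rdname parse_newick
#' @param path File containing one tree description.
#' @param dialect `"newick"` or `"nhx"`; NHX tag blocks are parsed either
#'   way, the distinction only affects writing.
#' @export
read_tree <- function(path, dialect = c("newick", "nhx")) {
  text <- paste(readLines(path), collapse = "")
  tree <- parse_newick(text)
  annotate_from_nhx(tree)
}

#' @rdname format_newick
#' @param path Output path.
#' @export
write_tree <- function(tree, path, dialect = c("newick", "nhx")) {
  writeLines(format_newick(tree, match.arg(dialect)), path)
  invisible(path)
}

# Lift standard NHX tags back into first-class node fields after parsing.
annotate_from_nhx <- function(node) {
  t <- node$nhx
  if (!is.null(t) && length(t)) {
    if ("S" %in% names(t) && length(node$children) == 0) node$species <- unname(t["S"])
    if ("Ev" %in% names(t) && t["Ev"] == "gene_split") node$event <- "gene_split"
    else if ("DD" %in% names(t) && t["DD"] == "Y") node$event <- "dubious"
    else if ("D" %in% names(t)) node$event <- if (t["D"] == "Y") "duplication" else "speciation"
    if ("SIS" %in% names(t)) node$consistency <- as.numeric(t["SIS"]) / 100
    if ("Map" %in% names(t)) node$mapping <- unname(t["Map"])
  }
  node$children <- lapply(node$children, annotate_from_nhx)
  cls <- class(node); class(node) <- cls
  node
}

#' Leaves of a tree, left to right
#' @param tree A tree node.
#' @return List of leaf nodes.
#' @export
tree_leaves <- function(tree) {
  if (length(tree$children) == 0) return(list(tree))
  do.call(c, lapply(tree$children, tree_leaves))
}

#' Count all nodes of a tree
#' @param tree A tree node.
#' @export
tree_size <- function(tree) {
  1L + sum(vapply(tree$children, tree_size, integer(1)))
}

#' Structural equality of two trees
#'
#' Compares topology, labels and branch lengths (and NHX tags when
#' `tags = TRUE`); used by round-trip tests.
#' @param a,b Tree nodes.
#' @param tags Compare NHX tags too.
#' @export
trees_equal <- function(a, b, tags = FALSE) {
  if (a$label != b$label) return(FALSE)
  if (!identical(is.na(a$length), is.na(b$length))) return(FALSE)
  if (!is.na(a$length) && abs(a$length - b$length) > 1e-9) return(FALSE)
  if (length(a$children) != length(b$children)) return(FALSE)
  if (tags) {
    sort_tags <- function(x) if (length(x)) x[order(names(x))] else character(0)
    if (!identical(sort_tags(node_nhx_tags(a)), sort_tags(node_nhx_tags(b))))
      return(FALSE)
  }
  all(vapply(seq_along(a$children),
             function(i) trees_equal(a$children[[i]], b$children[[i]], tags),
             logical(1)))
}

#' @export
print.ck_tree <- function(x, ...) {
  cat(format_newick(x, "nhx"), "\n")
  invisible(x)
}
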