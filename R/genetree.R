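#' Reconcile a gene tree against a species tree
#'
#' Standard LCA (lowest-common-ancestor) reconciliation: each gene-tree
#' node is mapped to the species-tree LCA of the species under it. A node
#' is a duplication event when its mapping coincides with the mapping of
#' at least one child, otherwise a speciation. Duplication nodes get a
#' duplication consistency score: the fraction of species under the node
#' in which the duplication is observed in both copies
#' (intersection-over-union of the child species sets). A score of 0 means
#' the duplication is not supported by any extant species.
#'
#' Leaf species are taken from an NHX `S` tag when present, from
#' `species_map`, or from the suffix after the last `_` of the leaf label
#' (`gene1_human` is the gene `gene1` of species `human`).
#'
#' @param gene_tree Binary gene tree (root node, e.g. from [read_tree()]);
#'   non-binary trees are rejected.
#' @param species_tree Species tree whose leaf labels are species and
#'   whose internal labels name taxa (ancestral clades).
#' @param species_map Optional named character vector mapping leaf labels
#'   to species.
#' @return The gene tree with nodes annotated: `mapping` (species-tree
#'   node label), `event` (`speciation`/`duplication`), `consistency`
#'   (duplication nodes), `species_under`. Class `reconciled_tree`.
#' @export
reconcile <- function(gene_tree, species_tree, species_map = NULL) {
  sp <- index_species_tree(species_tree)
  annotate <- function(node) {
    if (length(node$children) == 0) {
      species <- leaf_species(node, species_map)
      if (!species %in% names(sp$leaf_id))
        stop("leaf '", node$label, "': species '", species,
             "' is not in the species tree")
      node$species <- species
      node$species_under <- species
      node$mapping <- sp$label[sp$leaf_id[[species]]]
      return(node)
    }
    if (length(node$children) != 2)
      stop("gene tree must be binary; node '", node$label, "' has ",
           length(node$children), " children")
    node$children <- lapply(node$children, annotate)
    under <- lapply(node$children, function(ch) ch$species_under)
    node$species_under <- sort(unique(unlist(under)))
    node$mapping <- sp$label[species_lca(sp, node$species_under)]
    child_maps <- vapply(node$children, function(ch) ch$mapping, character(1))
    if (any(child_maps == node$mapping)) {
      node$event <- "duplication"
      node$consistency <- length(intersect(under[[1]], under[[2]])) /
        length(union(under[[1]], under[[2]]))
    } else {
      node$event <- "speciation"
      node$consistency <- NULL
    }
    node
  }
  out <- annotate(gene_tree)
  class(out) <- unique(c("reconciled_tree", "ck_tree", class(out)))
  attr(out, "species_tree") <- species_tree
  out
}

leaf_species <- function(node, species_map = NULL) {
  if (!is.null(node$species)) return(node$species)
  if ("S" %in% names(node$nhx)) return(unname(node$nhx[["S"]]))
  if (!is.null(species_map) && node$label %in% names(species_map))
    return(unname(species_map[[node$label]]))
  if (grepl("_", node$label)) return(sub(".*_", "", node$label))
  stop("cannot determine the species of leaf '", node$label, "'")
}

# Flatten a species tree: labels, parent ids, depths, leaf index. Internal
# nodes without a label get one synthesised from their leaf set.
index_species_tree <- function(species_tree) {
  labels <- character(0); parent <- integer(0); depth <- integer(0)
  leaf_id <- list(); age <- numeric(0)
  walk <- function(node, par, d) {
    id <- length(labels) + 1L
    lab <- node$label
    if (!nzchar(lab))
      lab <- paste(vapply(tree_leaves(node), function(l) l$label, character(1)),
                   collapse = "|")
    labels[id] <<- lab; parent[id] <<- par; depth[id] <<- d
    age[id] <<- if ("Age" %in% names(node$nhx)) as.numeric(node$nhx[["Age"]])
                else NA_real_
    if (length(node$children) == 0) {
      if (!is.null(leaf_id[[node$label]]))
        stop("duplicated species-tree leaf '", node$label, "'")
      leaf_id[[node$label]] <<- id
      if (is.na(age[id])) age[id] <<- 0
    }
    for (ch in node$children) walk(ch, id, d + 1L)
  }
  walk(species_tree, 0L, 0L)
  list(label = labels, parent = parent, depth = depth, leaf_id = leaf_id,
       age = age)
}

# LCA node id of a set of species in an indexed species tree.
species_lca <- function(sp, species) {
  ids <- vapply(species, function(s) sp$leaf_id[[s]], integer(1))
  cur <- ids[1]
  for (id in ids[-1]) {
    a <- cur; b <- id
    while (a != b) {
      if (sp$depth[a] >= sp$depth[b]) a <- sp$parent[a] else b <- sp$parent[b]
    }
    cur <- a
  }
  cur
}

#' Duplication consistency score of a reconciled node
#'
#' Intersection-over-union of the species sets under the node's two
#' children. Defined for duplication (and dubious) nodes.
#'
#' @param node An annotated internal node of a [reconcile()]d tree.
#' @return Fraction in `[0, 1]`.
#' @export
duplication_consistency <- function(node) {
  if (length(node$children) != 2)
    stop("duplication consistency requires a binary internal node")
  a <- node$children[[1]]$species_under; b <- node$children[[2]]$species_under
  length(intersect(a, b)) / length(union(a, b))
}

#' Relabel unsupported duplications as dubious
#'
#' Every duplication node with consistency score 0 — a duplication
#' observed in no extant species — is relabelled `dubious`. Dubious nodes
#' are treated as speciations for orthology extraction, but pairs they
#' relate are marked non-compliant with the tree. Idempotent.
#'
#' @param tree A [reconcile()]d tree.
#' @return The tree with zero-consistency duplications relabelled.
#' @export
flag_dubious <- function(tree) {
  relabel <- function(node) {
    if (!is.null(node$event) && node$event == "duplication" &&
        !is.null(node$consistency) && node$consistency == 0)
      node$event <- "dubious"
    node$children <- lapply(node$children, relabel)
    node
  }
  out <- relabel(tree)
  class(out) <- class(tree); attributes(out) <- attributes(tree)
  out
}

#' Detect and merge split genes
#'
#' Assembly artefacts can split one true gene into two or more partial
#' annotations, which then appear in the family joined by spurious
#' duplication nodes. Candidates are pairs of same-species leaves whose
#' connecting path runs only through duplication/dubious nodes and whose
#' occupied alignment column ranges overlap by at most
#' `max_overlap_columns` (a small overlap tolerates boundary
#' over-prediction). Detected parts are merged into one composite leaf
#' carrying all component gene ids; the joining node is relabelled
#' `gene_split` (when the merge leaves it with a single child the node is
#' suppressed and the composite leaf carries the event). Merging cascades
#' transitively; events and consistency scores are recomputed afterwards.
#'
#' @param tree A [reconcile()]d (and typically [flag_dubious()]ed) tree.
#' @param family_alignment [multiple_alignment()] with one row per leaf,
#'   `row_id` matching the leaf label.
#' @param max_overlap_columns Largest tolerated overlap, in alignment
#'   columns. Default 10.
#' @return The merged tree; `attr(, "gene_splits")` lists one character
#'   vector of merged gene ids per split event, and composite leaves carry
#'   `genes` and `split_event = TRUE`.
#' @export
detect_gene_splits <- function(tree, family_alignment, max_overlap_columns = 10) {
  ranges <- row_occupancy(family_alignment)
  for (l in tree_leaves(tree))
    if (!l$label %in% names(ranges))
      stop("leaf '", l$label, "' has no row in the family alignment")
  splits <- list()
  repeat {
    cand <- find_split_candidate(tree, ranges, max_overlap_columns)
    if (is.null(cand)) break
    merged_genes <- sort(unique(c(cand$genes1, cand$genes2)))
    splits[[length(splits) + 1L]] <- merged_genes
    ranges[[cand$leaf1]] <- c(min(ranges[[cand$leaf1]][1], ranges[[cand$leaf2]][1]),
                              max(ranges[[cand$leaf1]][2], ranges[[cand$leaf2]][2]))
    ranges[[cand$leaf2]] <- NULL
    tree <- merge_leaf_pair(tree, cand$leaf1, cand$leaf2, merged_genes)
    names(ranges)[names(ranges) == cand$leaf1] <-
      paste(merged_genes, collapse = "+")
  }
  st <- attr(tree, "species_tree")
  if (!is.null(st) && length(splits)) tree <- rereconcile(tree, st)
  attr(tree, "gene_splits") <- splits
  tree
}

# First/last occupied (non-gap) column per alignment row, 1-based.
row_occupancy <- function(msa) {
  out <- list()
  for (r in msa$rows) {
    hits <- which(strsplit(r$text, "")[[1]] != "-")
    out[[r$row_id]] <- if (length(hits)) c(min(hits), max(hits)) else c(NA, NA)
  }
  out
}

# Deterministic first mergeable pair: same species, duplication/dubious
# path only, column overlap within the allowance.
find_split_candidate <- function(tree, ranges, max_overlap) {
  leaves <- tree_leaves(tree)
  info <- lapply(leaves, function(l) list(
    label = l$label, species = l$species %||% leaf_species(l),
    genes = l$genes %||% l$label))
  labs <- vapply(info, function(x) x$label, character(1))
  n <- length(leaves)
  if (n < 2) return(NULL)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (info[[i]]$species != info[[j]]$species) next
    r1 <- ranges[[labs[i]]]; r2 <- ranges[[labs[j]]]
    if (any(is.na(c(r1, r2)))) next
    overlap <- max(0, min(r1[2], r2[2]) - max(r1[1], r2[1]) + 1)
    if (overlap > max_overlap) next
    if (!path_all_duplication(tree, labs[i], labs[j])) next
    return(list(leaf1 = labs[i], leaf2 = labs[j],
                genes1 = info[[i]]$genes, genes2 = info[[j]]$genes))
  }
  NULL
}

# TRUE when every internal node on the path between two leaves (including
# the LCA) is a duplication, dubious, or gene_split node.
path_all_duplication <- function(tree, lab1, lab2) {
  ok <- NULL
  walk <- function(node) {
    # returns which of the two labels occur under node
    if (length(node$children) == 0)
      return(c(node$label == lab1, node$label == lab2))
    hit <- Reduce(`|`, lapply(node$children, walk))
    if (all(hit) && is.null(ok)) {
      ok <<- check_down(node, lab1) && check_down(node, lab2) &&
        (node$event %||% "speciation") %in% c("duplication", "dubious", "gene_split")
    }
    hit
  }
  check_down <- function(node, lab) {
    # all internal nodes strictly between `node` and leaf `lab` are dup-like
    if (length(node$children) == 0) return(node$label == lab)
    for (ch in node$children) {
      if (any(vapply(tree_leaves(ch), function(l) l$label == lab, logical(1)))) {
        if (length(ch$children) > 0 &&
            !(ch$event %||% "speciation") %in% c("duplication", "dubious", "gene_split"))
          return(FALSE)
        return(check_down(ch, lab))
      }
    }
    FALSE
  }
  walk(tree)
  isTRUE(ok)
}

# Merge leaf2 into leaf1: leaf1 becomes the composite leaf, leaf2 is
# removed, unary nodes are suppressed, the joining LCA gets event
# `gene_split` (carried by the composite leaf if the LCA is suppressed).
merge_leaf_pair <- function(tree, lab1, lab2, genes) {
  composite_label <- paste(genes, collapse = "+")
  surgery <- function(node) {
    if (length(node$children) == 0) {
      if (node$label == lab1) {
        node$genes <- genes
        node$label <- composite_label
        node$split_event <- TRUE
      }
      if (node$label == lab2) return(NULL)
      return(node)
    }
    child_has <- vapply(node$children, function(ch) {
      labs <- vapply(tree_leaves(ch), function(l) l$label, character(1))
      c(lab1 %in% labs, lab2 %in% labs)
    }, logical(2))
    is_lca <- all(rowSums(child_has) >= 1) && !any(colSums(child_has) == 2)
    kids <- Filter(Negate(is.null), lapply(node$children, surgery))
    if (is_lca) node$event <- "gene_split"
    if (length(kids) == 1) {
      kid <- kids[[1]]
      if (!is.null(node$event) && node$event == "gene_split" &&
          length(kid$children) == 0)
        kid$split_event <- TRUE
      return(kid)
    }
    node$children <- kids
    node
  }
  out <- surgery(tree)
  class(out) <- class(tree)
  attr(out, "species_tree") <- attr(tree, "species_tree")
  out
}

# Recompute mappings, events and consistency after surgery, preserving
# gene_split labels and the dubious flag.
rereconcile <- function(tree, species_tree) {
  keep <- collect_events(tree, "gene_split")
  out <- flag_dubious(reconcile(strip_annotations(tree), species_tree))
  res <- restore_gene_split(out, keep)
  class(res) <- class(out)
  attr(res, "species_tree") <- species_tree
  res
}

collect_events <- function(node, ev) {
  hits <- character(0)
  walk <- function(n) {
    if (!is.null(n$event) && n$event == ev && length(n$children))
      hits <<- c(hits, leafset_key(n))
    for (ch in n$children) walk(ch)
  }
  walk(node)
  hits
}

leafset_key <- function(node)
  paste(sort(vapply(tree_leaves(node), function(l) l$label, character(1))),
        collapse = ",")

strip_annotations <- function(node) {
  node$event <- NULL; node$consistency <- NULL
  node$mapping <- NULL; node$species_under <- NULL
  node$children <- lapply(node$children, strip_annotations)
  node
}

restore_gene_split <- function(node, keys) {
  if (length(node$children) && leafset_key(node) %in% keys)
    node$event <- "gene_split"
  node$children <- lapply(node$children, restore_gene_split, keys = keys)
  node
}

#' Number of gene-split events recorded on a tree
#' @param tree Output of [detect_gene_splits()].
#' @export
count_gene_splits <- function(tree) length(attr(tree, "gene_splits") %||% list())
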