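#' Extract typed homology pairs from a reconciled gene tree
#'
#' Every unordered pair of genes is related by exactly one node of the
#' tree — its LCA — and that node's event decides the relationship:
#'
#' * speciation (or dubious, or gene_split) LCA: orthologues, subtyped by
#'   copy counts at the node (`ortholog_one2one`, `ortholog_one2many`,
#'   `ortholog_many2many`);
#' * duplication LCA: paralogues (`within_species_paralog` when both genes
#'   belong to one species, `between_species_paralog` otherwise).
#'
#' Additionally, duplication nodes with a consistency score below
#' `min_consistency` (default 25%) are phylogenetically ambiguous: their
#' cross-species pairs are re-tagged as orthologues when at least one of
#' the two genes has no orthologue in the partner species through any
#' speciation/dubious node. Pairs from dubious or gene_split nodes and
#' pairs rescued by the low-consistency rule carry
#' `tree_compliant = FALSE`.
#'
#' @param tree A [reconcile()]d (and typically [flag_dubious()]ed) tree.
#' @param ages Optional named numeric vector of taxon ages (Myr) used to
#'   date each pair's LCA taxon; ages may also travel on the species tree
#'   as NHX `Age` tags.
#' @param min_consistency Threshold (fraction) below which duplication
#'   nodes trigger the non-compliant orthologue rescue. Default 0.25,
#'   strict (`consistency < min_consistency`).
#' @return Data frame with columns `gene1`, `gene2`, `species1`,
#'   `species2`, `type`, `taxon`, `age`, `tree_compliant`; `gene1 < gene2`
#'   lexicographically.
#' @export
extract_homologies <- function(tree, ages = NULL, min_consistency = 0.25) {
  st <- attr(tree, "species_tree")
  sp_idx <- if (!is.null(st)) index_species_tree(st) else NULL
  rows <- list()
  # leaf descriptor: one entry per gene (composite leaves expand)
  leaf_info <- function(node) {
    genes <- node$genes %||% node$label
    lapply(genes, function(g) list(gene = g, species = node$species))
  }
  emit <- function(node) {
    if (length(node$children) == 0) return(leaf_info(node))
    sides <- lapply(node$children, emit)
    ev <- node$event %||% "speciation"
    for (si in seq_along(sides)) for (sj in seq_along(sides)) {
      if (si >= sj) next
      for (l in sides[[si]]) for (r in sides[[sj]]) {
        orth <- ev %in% c("speciation", "dubious", "gene_split")
        if (orth) {
          n1 <- sum(vapply(sides[[si]], function(x) x$species == l$species, logical(1)))
          n2 <- sum(vapply(sides[[sj]], function(x) x$species == r$species, logical(1)))
          type <- if (n1 == 1 && n2 == 1) "ortholog_one2one"
                  else if (n1 == 1 || n2 == 1) "ortholog_one2many"
                  else "ortholog_many2many"
        } else {
          type <- if (l$species == r$species) "within_species_paralog"
                  else "between_species_paralog"
        }
        rows[[length(rows) + 1L]] <<- list(
          gene1 = l$gene, gene2 = r$gene, species1 = l$species,
          species2 = r$species, type = type,
          taxon = node$mapping %||% NA_character_,
          consistency = if (ev %in% c("duplication", "dubious"))
            node$consistency %||% NA_real_ else NA_real_,
          event = ev,
          tree_compliant = ev %in% c("speciation", "duplication"))
      }
    }
    do.call(c, sides)
  }
  emit(tree)
  if (length(rows) == 0)
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      species1 = character(0), species2 = character(0),
                      type = character(0), taxon = character(0),
                      age = numeric(0), tree_compliant = logical(0)))
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  # orthologue registry: gene -> species it already has orthologues in
  reg <- c(paste(df$gene1, df$species2), paste(df$gene2, df$species1))
  reg <- reg[grepl("^ortholog", rep(df$type, 2))]
  rescue <- df$event == "duplication" & !is.na(df$consistency) &
    df$consistency < min_consistency & df$species1 != df$species2 &
    (!(paste(df$gene1, df$species2) %in% reg) |
     !(paste(df$gene2, df$species1) %in% reg))
  if (any(rescue)) {
    df$type[rescue] <- "ortholog_many2many"
    df$tree_compliant[rescue] <- FALSE
  }
  df$age <- vapply(df$taxon, function(tx) taxon_age(tx, sp_idx, ages), numeric(1))
  swap <- df$gene1 > df$gene2
  tmp <- df$gene1[swap]; df$gene1[swap] <- df$gene2[swap]; df$gene2[swap] <- tmp
  tmp <- df$species1[swap]; df$species1[swap] <- df$species2[swap]
  df$species2[swap] <- tmp
  df <- df[order(df$gene1, df$gene2), ]
  rownames(df) <- NULL
  df[, c("gene1", "gene2", "species1", "species2", "type", "taxon", "age",
         "tree_compliant")]
}

taxon_age <- function(taxon, sp_idx, ages) {
  if (!is.null(ages) && taxon %in% names(ages)) return(unname(ages[[taxon]]))
  if (!is.null(sp_idx)) {
    hit <- match(taxon, sp_idx$label)
    if (!is.na(hit)) return(sp_idx$age[hit])
  }
  NA_real_
}

#' Phylogenetically date a reconciled node
#'
#' Returns the taxon the node maps to on the species tree — the most
#' recent common ancestor of the species underneath it — and its
#' calibration age in million years when the species tree carries ages
#' (NHX `Age` tags, or the `ages` argument; extant species have age 0).
#'
#' @param node An annotated node of a [reconcile()]d tree.
#' @param species_tree The species tree used for reconciliation.
#' @param ages Optional named numeric vector of taxon ages (Myr).
#' @return List with `taxon` and `age` (NA when no calibration exists).
#' @export
date_node <- function(node, species_tree, ages = NULL) {
  if (is.null(node$mapping))
    stop("node is not annotated; run reconcile() first")
  list(taxon = node$mapping,
       age = taxon_age(node$mapping, index_species_tree(species_tree), ages))
}

#' Write homology pairs as TSV
#' @param pairs Data frame from [extract_homologies()].
#' @param path Output path.
#' @export
write_homologies <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
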