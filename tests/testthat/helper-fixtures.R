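# Shared fixtures and independent oracles for the suite.

# 4-species tree with named ancestors, used throughout.
species_tree_4 <- function() parse_newick("((A,B)AB,(C,D)CD)root;")

species_tree_5 <- function()
  parse_newick("((((human,mouse)eug,dog)eut,chicken)amn,zebrafish)vert;")

# Gapless block helper.
blk <- function(rs, re, qs, qe, strand = "+", ref_seq = "chr1", qry_seq = "c1",
                score = re - rs) {
  alignment_block(gi("ref", ref_seq, rs, re), gi("qry", qry_seq, qs, qe, strand),
                  score = score)
}

# Assemble a chain directly from blocks (bypasses the gap bound so tests
# can craft chains with specific internal gaps).
new_chain_for_test <- function(blocks) comparakit:::new_chain(blocks)

# ---- independent reconciliation oracle (ape-based LCA labelling) --------

# Events and mappings per internal node, computed with ape's MRCA lookup
# rather than the package's species-tree index.
oracle_reconcile <- function(gene_tree, species_newick) {
  phy <- ape::read.tree(text = species_newick)
  map_of <- function(species_set) {
    if (length(species_set) == 1) return(species_set)
    mrca <- ape::getMRCA(phy, species_set)
    phy$node.label[mrca - ape::Ntip(phy)]
  }
  out <- list()
  walk <- function(node) {
    if (length(node$children) == 0)
      return(sub(".*_", "", node$label))
    under <- lapply(node$children, walk)
    all_sp <- sort(unique(unlist(under)))
    m <- map_of(all_sp)
    child_m <- vapply(under, function(u) map_of(sort(unique(u))), character(1))
    out[[length(out) + 1L]] <<- list(
      leafset = paste(sort(vapply(tree_leaves(node), function(l) l$label,
                                  character(1))), collapse = ","),
      mapping = m,
      event = if (any(child_m == m)) "duplication" else "speciation")
    all_sp
  }
  walk(gene_tree)
  out
}

# Flatten a reconciled tree to the same (leafset, mapping, event) records.
recon_records <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (length(node$children) == 0) return(invisible())
    ev <- node[["event"]]
    if (ev == "dubious") ev <- "duplication"  # oracle has no dubious notion
    out[[length(out) + 1L]] <<- list(
      leafset = paste(sort(vapply(tree_leaves(node), function(l) l$label,
                                  character(1))), collapse = ","),
      mapping = node[["mapping"]], event = ev)
    for (ch in node$children) walk(ch)
  }
  walk(tree)
  out[order(vapply(out, `[[`, character(1), "leafset"))]
}

# All rooted binary tree shapes over a label set (first label anchored to
# the left subtree to avoid mirror duplicates).
all_shapes <- function(labels) {
  n <- length(labels)
  if (n == 1) return(list(labels))
  shapes <- list()
  rest <- labels[-1]
  for (k in 0:(n - 2)) {
    combos <- if (k == 0) list(character(0)) else
      utils::combn(rest, k, simplify = FALSE)
    for (extra in combos) {
      left <- c(labels[1], extra)
      right <- setdiff(labels, left)
      for (ls in all_shapes(left)) for (rs in all_shapes(right))
        shapes[[length(shapes) + 1L]] <- list(ls, rs)
    }
  }
  shapes
}

# Nested shape with species-suffixed leaf labels -> tree_node structure.
shape_to_tree <- function(shape) {
  if (is.character(shape)) return(tree_node(label = shape))
  structure(tree_node(children = lapply(shape, shape_to_tree)), class = "ck_tree")
}

# Relabel shape leaves as gene_id _ species for a species assignment.
assign_species <- function(shape, species) {
  i <- 0L
  relabel <- function(s) {
    if (is.character(s)) {
      i <<- i + 1L
      return(sprintf("g%d_%s", i, species[i]))
    }
    lapply(s, relabel)
  }
  relabel(shape)
}

# ---- independent netting oracle (direct greedy interval bookkeeping) ----

# Greedy best-chain assignment with flat bookkeeping (extent + gap list
# per placed chain) instead of a nested forest; only meant for a handful
# of chains. A chain lands one level below the deepest placed chain that
# holds it inside an internal gap; it is dropped if any placed chain
# contains it outside a gap, or partially overlaps it at the target level.
oracle_nets <- function(chains) {
  chain_gaps <- function(ch) {
    g <- list(); bl <- ch$blocks
    if (length(bl) > 1) for (i in seq_len(length(bl) - 1)) {
      a <- bl[[i]]$ref$end; b <- bl[[i + 1]]$ref$start
      if (b > a) g[[length(g) + 1L]] <- c(a, b)
    }
    g
  }
  ord <- order(-vapply(chains, function(ch) ch$score, numeric(1)),
               vapply(chains, function(ch) ch$ref_span$start, numeric(1)),
               vapply(chains, function(ch) ch$qry_span$seq_name, character(1)))
  placed <- list()
  rows <- list()
  for (k in ord) {
    ch <- chains[[k]]
    s <- ch$ref_span$start; e <- ch$ref_span$end
    target <- 1L; blocked <- FALSE
    for (p in placed) {
      if (s >= p$s && e <= p$e) {
        in_gap <- length(p$gaps) &&
          any(vapply(p$gaps, function(g) s >= g[1] && e <= g[2], logical(1)))
        if (in_gap) target <- max(target, p$level + 1L) else blocked <- TRUE
      }
    }
    if (!blocked) for (p in placed)
      if (p$level == target && s < p$e && e > p$s && !(s >= p$s && e <= p$e))
        blocked <- TRUE
    if (!blocked) {
      placed[[length(placed) + 1L]] <- list(s = s, e = e, level = target,
                                            gaps = chain_gaps(ch))
      rows[[length(rows) + 1L]] <- data.frame(ref_start = s, ref_end = e,
                                              level = target)
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) return(data.frame())
  df[order(df$ref_start, df$level), , drop = FALSE]
}

# Flatten the package's net forest to (chain start, level) records.
net_records <- function(nets) {
  tb <- net_table(nets)
  if (nrow(tb) == 0) return(tb)
  tb[order(tb$ref_start, tb$level), c("ref_start", "ref_end", "level")]
}

# Event labels of all internal nodes of an annotated tree.
collect_all_events <- function(tree) {
  out <- character(0)
  walk <- function(node) {
    if (length(node$children)) {
      out <<- c(out, node[["event"]])
      for (ch in node$children) walk(ch)
    }
  }
  walk(tree)
  out
}

# ---- per-base bitmap oracle for interval arithmetic ---------------------

bitmap_overlap <- function(set_a, set_b, genome_length) {
  fill <- function(set) {
    v <- logical(genome_length)
    for (e in set) {
      iv <- if (inherits(e, "scored_element")) e$interval else e
      v[(iv$start + 1):iv$end] <- TRUE
    }
    v
  }
  a <- fill(set_a); b <- fill(set_b)
  list(only_a = sum(a & !b), shared = sum(a & b), only_b = sum(!a & b))
}

random_elements <- function(n, genome_length, max_len = 500) {
  lapply(seq_len(n), function(i) {
    s <- sample.int(genome_length - max_len, 1)
    scored_element(gi("ref", "chr1", s, s + sample.int(max_len, 1)),
                   score = stats::runif(1))
  })
}
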