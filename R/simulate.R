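#' Deterministic synthetic-data generators
#'
#' Every generator is a pure function of its arguments: the random stream
#' is seeded from `seed` plus a fixed per-generator tag, inside a local
#' RNG scope, so identical configurations always reproduce identical
#' fixtures and adding generators never perturbs existing ones. Each
#' generator returns both the data objects and a machine-readable truth
#' record.
#'
#' @name simulate
NULL

# Evaluate expr under a generator-local seeded RNG, restoring the caller's
# RNG state afterwards.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

seed_tags <- c(genomes = 101L, family = 211L, releases = 307L,
               scores = 401L, descriptions = 503L)

#' Simulate a rearranged genome pair with alignment-block truth
#'
#' A reference chromosome is partitioned into `n_rearrangements + 1`
#' syntenic segments; each segment is translocated to its own query
#' scaffold, inverted with probability `inv_prob`, and emitted as a run of
#' collinear alignment blocks with jitter gaps below the pass-1 grouping
#' bound. The truth table labels each planted segment, which
#' [build_synteny()] should recover one-for-one.
#'
#' @param seed Integer seed.
#' @param genome_length Reference length in bp (default 20 Mb).
#' @param n_rearrangements Number of breakpoints (default 4, i.e. 5
#'   segments).
#' @param min_segment Minimum planted segment length (default 1 Mb).
#' @param max_jitter_gap Largest within-segment inter-block gap (default
#'   150 kb, safely below the 200 kb grouping bound).
#' @param inv_prob Probability that a segment is inverted.
#' @param ref_species,qry_species Species labels.
#' @return List with `blocks` (list of [alignment_block()]s) and `truth`
#'   (data frame: one row per planted segment).
#' @export
simulate_rearranged_genomes <- function(seed = 1, genome_length = 2e7,
                                        n_rearrangements = 4,
                                        min_segment = 1e6,
                                        max_jitter_gap = 150000,
                                        inv_prob = 0.3,
                                        ref_species = "ref",
                                        qry_species = "qry") {
  local_seed(seed + seed_tags[["genomes"]], {
    n_seg <- n_rearrangements + 1
    if (genome_length < n_seg * min_segment)
      stop("genome too short for ", n_seg, " segments of >= ", min_segment, " bp")
    # segment boundaries: minimum lengths plus random slack
    slack <- genome_length - n_seg * min_segment
    extra <- if (n_seg > 1) {
      cuts <- sort(sample.int(slack + 1, n_seg - 1, replace = TRUE) - 1)
      diff(c(0, cuts, slack))
    } else slack
    seg_len <- min_segment + extra
    seg_start <- cumsum(c(0, seg_len[-n_seg]))
    inverted <- stats::runif(n_seg) < inv_prob
    qry_order <- sample.int(n_seg)
    blocks <- list(); truth <- list()
    for (s in seq_len(n_seg)) {
      qchr <- paste0("scaffold", qry_order[s])
      strand <- if (inverted[s]) "-" else "+"
      # cut the segment into blocks with jitter gaps on both genomes
      pos <- seg_start[s]; qpos <- 0; seg_end <- seg_start[s] + seg_len[s]
      covered_end <- pos
      while (pos < seg_end) {
        len <- min(round(stats::runif(1, 5e4, 4e5)), seg_end - pos)
        blocks[[length(blocks) + 1L]] <- alignment_block(
          ref = gi(ref_species, "chr1", pos, pos + len),
          qry = gi(qry_species, qchr, qpos, qpos + len, strand),
          score = len)
        covered_end <- pos + len
        gap <- round(stats::runif(1, 0, max_jitter_gap))
        pos <- pos + len + gap; qpos <- qpos + len + gap
      }
      # the truth span is the reference extent actually covered by blocks
      truth[[s]] <- data.frame(
        segment = s, ref_start = seg_start[s], ref_end = covered_end,
        qry_seq = qchr,
        orientation = if (inverted[s]) "inverted" else "same")
    }
    list(blocks = blocks, truth = do.call(rbind, truth))
  })
}

#' Simulate a gene family by birth-death duplication/loss
#'
#' One ancestral gene evolves along the species tree. On each branch every
#' gene lineage acquires `rpois(dup_rate)` duplications and is lost with
#' probability `loss_rate`. The truth record carries every planted
#' duplication, the definitional homology pair set (computed from the
#' known events, not from any reconciliation), and planted gene splits: a
#' planted split bisects one leaf's alignment row into two non-overlapping
#' partial rows joined by a spurious duplication node, emulating a
#' fragmented assembly.
#'
#' @param species_tree Species tree (root node).
#' @param dup_rate,loss_rate Expected duplications / loss probability per
#'   lineage per branch.
#' @param seed Integer seed.
#' @param aln_length Family alignment length in columns.
#' @param plant_dup_species Optionally force exactly one duplication on
#'   the terminal branch of this species (useful at rates 0).
#' @param plant_splits Number of leaves to bisect into planted gene
#'   splits.
#' @return List with `gene_tree` (binary, unannotated, leaf labels
#'   `gene_species`), `alignment` ([multiple_alignment()]),
#'   `truth_events`, `truth_pairs`, `truth_splits`.
#' @export
simulate_gene_family <- function(species_tree, dup_rate = 0, loss_rate = 0,
                                 seed = 1, aln_length = 300,
                                 plant_dup_species = NULL, plant_splits = 0) {
  local_seed(seed + seed_tags[["family"]], {
    counter <- new.env(); counter$n <- 0L
    events <- list()
    new_leaf <- function(species) {
      counter$n <- counter$n + 1L
      nd <- tree_node(label = sprintf("g%d_%s", counter$n, species))
      nd$species <- species; nd$true_event <- "leaf"
      nd
    }
    grow <- function(st_node, n_dup) {
      if (n_dup > 0) {
        nd <- tree_node(children = list(grow(st_node, 0L), grow(st_node, n_dup - 1L)))
        nd$true_event <- "duplication"
        events[[length(events) + 1L]] <<- list(event = "duplication",
                                               taxon = st_label(st_node))
        return(nd)
      }
      if (length(st_node$children) == 0) {
        extra <- if (!is.null(plant_dup_species) &&
                     st_node$label == plant_dup_species) {
          plant_dup_species <<- NULL  # plant exactly once
          1L
        } else 0L
        if (extra > 0) {
          nd <- tree_node(children = list(new_leaf(st_node$label),
                                          new_leaf(st_node$label)))
          nd$true_event <- "duplication"
          events[[length(events) + 1L]] <<- list(event = "duplication",
                                                 taxon = st_node$label)
          return(nd)
        }
        return(new_leaf(st_node$label))
      }
      kids <- list()
      for (ch in st_node$children) {
        if (stats::runif(1) < loss_rate) {
          events[[length(events) + 1L]] <<- list(event = "loss",
                                                 taxon = st_label(ch))
          next
        }
        sub <- grow(ch, stats::rpois(1, dup_rate))
        if (!is.null(sub)) kids[[length(kids) + 1L]] <- sub
      }
      if (length(kids) == 0) return(NULL)
      if (length(kids) == 1) return(kids[[1]])
      nd <- tree_node(children = kids)
      nd$true_event <- "speciation"
      nd
    }
    tree <- grow(species_tree, stats::rpois(1, dup_rate))
    if (is.null(tree)) stop("the whole family was lost; lower loss_rate")
    truth_pairs <- truth_homologies(tree)

    # alignment rows: full occupancy, then planted splits
    leaves <- tree_leaves(tree)
    rows <- lapply(leaves, function(l) {
      text <- paste(sample(c("A", "C", "G", "T"), aln_length, replace = TRUE),
                    collapse = "")
      msa_row(l$label, l$species,
              gi(l$species, paste0("ctg_", l$label), 0, aln_length), text)
    })
    truth_splits <- list()
    if (plant_splits > 0) {
      if (plant_splits > length(rows)) stop("more planted splits than leaves")
      victims <- sort(sample.int(length(rows), plant_splits))
      for (v in victims) {
        res <- plant_split(tree, rows, leaves[[v]]$label, aln_length)
        tree <- res$tree; rows <- res$rows
        truth_splits[[length(truth_splits) + 1L]] <- res$parts
      }
    }
    list(gene_tree = structure(tree, class = "ck_tree"),
         alignment = multiple_alignment(rows),
         truth_events = if (length(events))
           do.call(rbind, lapply(events, as.data.frame))
         else data.frame(event = character(0), taxon = character(0)),
         truth_pairs = truth_pairs,
         truth_splits = truth_splits)
  })
}

st_label <- function(node) {
  if (nzchar(node$label)) return(node$label)
  paste(vapply(tree_leaves(node), function(l) l$label, character(1)),
        collapse = "|")
}

# Definitional homology pairs from a truth tree with known events.
truth_homologies <- function(tree) {
  rows <- list()
  walk <- function(node) {
    if (length(node$children) == 0)
      return(list(list(gene = node$label, species = node$species)))
    sides <- lapply(node$children, walk)
    ev <- node$true_event
    for (si in seq_along(sides)) for (sj in seq_along(sides)) {
      if (si >= sj) next
      for (l in sides[[si]]) for (r in sides[[sj]]) {
        if (ev == "speciation") {
          n1 <- sum(vapply(sides[[si]], function(x) x$species == l$species,
                           logical(1)))
          n2 <- sum(vapply(sides[[sj]], function(x) x$species == r$species,
                           logical(1)))
          type <- if (n1 == 1 && n2 == 1) "ortholog_one2one"
                  else if (n1 == 1 || n2 == 1) "ortholog_one2many"
                  else "ortholog_many2many"
        } else {
          type <- if (l$species == r$species) "within_species_paralog"
                  else "between_species_paralog"
        }
        g <- sort(c(l$gene, r$gene))
        rows[[length(rows) + 1L]] <<- data.frame(gene1 = g[1], gene2 = g[2],
                                                 type = type)
      }
    }
    do.call(c, sides)
  }
  walk(tree)
  if (length(rows) == 0)
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      type = character(0)))
  df <- do.call(rbind, rows)
  df[order(df$gene1, df$gene2), , drop = FALSE]
}

# Bisect one leaf into two partial genes joined by a spurious duplication.
plant_split <- function(tree, rows, label, aln_length) {
  cut <- round(aln_length * stats::runif(1, 0.35, 0.65))
  lab1 <- paste0(label, "a"); lab2 <- paste0(label, "b")
  idx <- which(vapply(rows, function(r) r$row_id, character(1)) == label)
  full <- rows[[idx]]
  part <- function(lab, from, to) {
    chars <- rep("-", aln_length)
    chars[from:to] <- strsplit(full$text, "")[[1]][from:to]
    msa_row(lab, full$species,
            gi(full$species, paste0("ctg_", lab), 0, to - from + 1),
            paste(chars, collapse = ""))
  }
  rows[[idx]] <- part(lab1, 1, cut)
  rows[[length(rows) + 1L]] <- part(lab2, cut + 1, aln_length)
  species <- full$species
  splice <- function(node) {
    if (length(node$children) == 0) {
      if (node$label == label) {
        l1 <- tree_node(label = lab1); l1$species <- species
        l2 <- tree_node(label = lab2); l2$species <- species
        nd <- tree_node(children = list(l1, l2))
        nd$true_event <- "duplication"  # spurious: annotation artefact
        return(nd)
      }
      return(node)
    }
    node$children <- lapply(node$children, splice)
    node
  }
  list(tree = splice(tree), rows = rows, parts = c(lab1, lab2))
}

#' Simulate a release pair for stable-ID assignment
#'
#' Previous-release clusters carry stable IDs at version 1. A planted
#' fraction of clusters is split in two, another fraction is merged
#' pairwise, and the rest are copied unchanged; the truth records each new
#' cluster's expected status and the planted perfect-match ("kept")
#' fraction.
#'
#' @param seed Integer seed.
#' @param n_clusters Number of previous-release clusters.
#' @param split_fraction,merge_fraction Fractions of previous clusters
#'   split / consumed by pairwise merges.
#' @param id_prefix Stable-ID prefix.
#' @return List with `prev`, `new` (cluster lists) and `truth` (list with
#'   `status` per new cluster and `kept_fraction`).
#' @export
simulate_release_pair <- function(seed = 1, n_clusters = 20,
                                  split_fraction = 0, merge_fraction = 0,
                                  id_prefix = "CKT") {
  local_seed(seed + seed_tags[["releases"]], {
    n_split <- round(split_fraction * n_clusters)
    n_merge_pairs <- floor(round(merge_fraction * n_clusters) / 2)
    if (n_split + 2 * n_merge_pairs > n_clusters)
      stop("split and merge fractions exceed the cluster count")
    sizes <- sample(6:14, n_clusters, replace = TRUE)
    member_id <- 0L
    prev <- lapply(seq_len(n_clusters), function(i) {
      m <- sprintf("p%05d", member_id + seq_len(sizes[i]))
      member_id <<- member_id + sizes[i]
      list(stable_id = sprintf("%s%05d", id_prefix, i), version = 1L,
           members = m)
    })
    roles <- rep("kept", n_clusters)
    pick <- sample.int(n_clusters, n_split + 2 * n_merge_pairs)
    roles[pick[seq_len(n_split)]] <- "split"
    if (n_merge_pairs > 0)
      roles[pick[n_split + seq_len(2 * n_merge_pairs)]] <- "merge"
    new <- list(); status <- character(0)
    merge_buffer <- NULL
    for (i in seq_len(n_clusters)) {
      cl <- prev[[i]]
      if (roles[i] == "kept") {
        new[[length(new) + 1L]] <- list(members = cl$members)
        status <- c(status, "kept")
      } else if (roles[i] == "split") {
        k <- ceiling(length(cl$members) * 0.6)
        new[[length(new) + 1L]] <- list(members = cl$members[seq_len(k)])
        new[[length(new) + 1L]] <- list(members = cl$members[-seq_len(k)])
        status <- c(status, "inherited", "new")
      } else if (is.null(merge_buffer)) {
        merge_buffer <- cl$members
      } else {
        new[[length(new) + 1L]] <- list(members = c(merge_buffer, cl$members))
        status <- c(status, "inherited")
        merge_buffer <- NULL
      }
    }
    list(prev = prev, new = new,
         truth = list(status = status,
                      kept_fraction = mean(status == "kept")))
  })
}

#' Simulate a per-base conservation score track
#'
#' @param length Track length in bp (0 gives an empty track).
#' @param seed Integer seed.
#' @param na_fraction Fraction of positions left unscored (`NA`),
#'   emulating unaligned reference bases.
#' @param seq_name Sequence name of the track.
#' @return Track list (`seq_name`, `start`, `step`, `values`) as used by
#'   the wiggle reader/writer.
#' @export
simulate_score_track <- function(length, seed = 1, na_fraction = 0,
                                 seq_name = "chr1") {
  local_seed(seed + seed_tags[["scores"]], {
    values <- round(stats::runif(length, -5, 5), 3)
    if (na_fraction > 0 && length > 0)
      values[stats::runif(length) < na_fraction] <- NA_real_
    list(seq_name = seq_name, start = 0, step = 1, values = values)
  })
}

#' Simulate a family description set with a planted consensus
#'
#' @param seed Integer seed.
#' @param n_informative Number of members with informative descriptions.
#' @param consensus_fraction Fraction of informative members sharing the
#'   planted consensus description; [name_family()] should score the
#'   family at `100 * consensus_fraction`.
#' @param n_uninformative Members with stop-pattern descriptions.
#' @param consensus Planted consensus text.
#' @return List with `df` (family/member/description table) and `truth`
#'   (`score`, `consensus`).
#' @export
simulate_descriptions <- function(seed = 1, n_informative = 10,
                                  consensus_fraction = 0.6,
                                  n_uninformative = 3,
                                  consensus = "zinc finger protein 42") {
  local_seed(seed + seed_tags[["descriptions"]], {
    n_match <- round(consensus_fraction * n_informative)
    desc <- c(rep(consensus, n_match),
              sprintf("olfactory receptor %d", 100 + seq_len(n_informative - n_match)),
              rep("hypothetical protein", n_uninformative))
    df <- data.frame(family = "fam1",
                     member = sprintf("m%03d", seq_along(desc)),
                     description = desc)
    df <- df[sample.int(nrow(df)), , drop = FALSE]
    rownames(df) <- NULL
    list(df = df,
         truth = list(score = 100 * n_match / n_informative,
                      consensus = normalize_description(consensus)))
  })
}
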