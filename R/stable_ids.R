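#' Assign versioned stable identifiers across two releases
#'
#' A cluster's stable ID is decided exclusively by its protein content.
#' Members present in only one release (newcomers and retirees) are
#' ignored for matching: the comparison operates on each cluster's
#' *shared* member set, its members restricted to proteins present in
#' both releases.
#'
#' 1. Perfect matches — identical non-empty shared sets — keep their
#'    stable ID and version.
#' 2. Remaining candidate links (old/new cluster pairs with a non-empty
#'    shared-member overlap) represent splits and merges; they are
#'    resolved greedily, favouring larger families: links are processed
#'    by new-cluster size descending, then overlap size descending, then
#'    old stable ID ascending (ties broken by the lexicographically
#'    smallest member of the new cluster). Each old ID and each new
#'    cluster is used at most once; the matched new cluster inherits the
#'    old ID with its version increased by one.
#' 3. Unmatched new clusters receive fresh IDs at version 1.
#'
#' @param prev_clusters,new_clusters Lists of clusters, each a list with
#'   `members` (character vector) and, for previous clusters, `stable_id`
#'   and `version`.
#' @param id_prefix Prefix for freshly minted IDs.
#' @return List with `clusters` (new clusters with `stable_id`, `version`
#'   filled in) and `report` (data frame: one row per new cluster with
#'   `stable_id`, `version`, `status` in kept/inherited/new, and
#'   `n_members`).
#' @export
assign_stable_ids <- function(prev_clusters, new_clusters, id_prefix = "CKT") {
  check_unique_members(prev_clusters, "previous")
  check_unique_members(new_clusters, "new")
  prev_universe <- unlist(lapply(prev_clusters, `[[`, "members"))
  new_universe <- unlist(lapply(new_clusters, `[[`, "members"))
  shared_universe <- intersect(prev_universe, new_universe)
  shared_of <- function(cl) sort(intersect(cl$members, shared_universe))
  prev_shared <- lapply(prev_clusters, shared_of)
  new_shared <- lapply(new_clusters, shared_of)

  status <- rep("new", length(new_clusters))
  assigned_id <- rep(NA_character_, length(new_clusters))
  assigned_ver <- rep(NA_integer_, length(new_clusters))
  old_used <- rep(FALSE, length(prev_clusters))

  # pass 1: perfect matches keep id and version
  prev_key <- vapply(prev_shared, paste, character(1), collapse = "\r")
  for (j in seq_along(new_clusters)) {
    key <- paste(new_shared[[j]], collapse = "\r")
    if (!nzchar(key)) next
    hit <- which(prev_key == key & !old_used)
    if (length(hit)) {
      i <- hit[1]
      status[j] <- "kept"
      assigned_id[j] <- prev_clusters[[i]]$stable_id
      assigned_ver[j] <- prev_clusters[[i]]$version %||% 1L
      old_used[i] <- TRUE
    }
  }

  # pass 2: greedy split/merge resolution favouring larger families
  links <- list()
  for (i in seq_along(prev_clusters)) {
    if (old_used[i]) next
    for (j in seq_along(new_clusters)) {
      if (status[j] != "new") next
      ov <- length(intersect(prev_shared[[i]], new_shared[[j]]))
      if (ov > 0)
        links[[length(links) + 1L]] <- list(
          old = i, new = j, overlap = ov,
          new_size = length(new_clusters[[j]]$members),
          old_id = prev_clusters[[i]]$stable_id,
          new_key = min(new_clusters[[j]]$members))
    }
  }
  if (length(links)) {
    ord <- order(-vapply(links, `[[`, numeric(1), "new_size"),
                 -vapply(links, `[[`, numeric(1), "overlap"),
                 vapply(links, `[[`, character(1), "old_id"),
                 vapply(links, `[[`, character(1), "new_key"))
    new_taken <- rep(FALSE, length(new_clusters))
    for (l in links[ord]) {
      if (old_used[l$old] || new_taken[l$new]) next
      status[l$new] <- "inherited"
      assigned_id[l$new] <- prev_clusters[[l$old]]$stable_id
      assigned_ver[l$new] <- (prev_clusters[[l$old]]$version %||% 1L) + 1L
      old_used[l$old] <- TRUE
      new_taken[l$new] <- TRUE
    }
  }

  # pass 3: fresh ids, continuing after the largest existing suffix
  counter <- max(0, id_suffixes(prev_clusters, id_prefix))
  for (j in order(vapply(new_clusters, function(cl) min(cl$members), character(1)))) {
    if (status[j] != "new") next
    counter <- counter + 1
    assigned_id[j] <- sprintf("%s%05d", id_prefix, counter)
    assigned_ver[j] <- 1L
  }

  clusters <- lapply(seq_along(new_clusters), function(j) {
    cl <- new_clusters[[j]]
    cl$stable_id <- assigned_id[j]; cl$version <- assigned_ver[j]
    cl
  })
  report <- data.frame(
    stable_id = assigned_id, version = assigned_ver, status = status,
    n_members = vapply(new_clusters, function(cl) length(cl$members), integer(1)))
  if (anyDuplicated(assigned_id))
    stop("internal error: duplicate stable id assigned")
  list(clusters = clusters, report = report)
}

check_unique_members <- function(clusters, release) {
  members <- unlist(lapply(clusters, `[[`, "members"))
  dup <- members[duplicated(members)]
  if (length(dup))
    stop("member id(s) appear in several clusters of the ", release,
         " release: ", paste(unique(dup), collapse = ", "))
}

id_suffixes <- function(clusters, prefix) {
  ids <- vapply(clusters, function(cl) cl$stable_id %||% NA_character_,
                character(1))
  ids <- ids[!is.na(ids) & startsWith(ids, prefix)]
  suf <- suppressWarnings(as.numeric(sub(paste0("^", prefix), "", ids)))
  suf[!is.na(suf)]
}
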