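#' Parse an NCBI-taxdump-style taxonomy
#'
#' Reads `nodes.dmp` / `names.dmp` in the pipe-and-tab delimited taxdump
#' dialect and builds a rooted taxonomy tree supporting lineage and
#' lowest-common-ancestor queries. The root is the unique node whose parent
#' is itself. Taxa without a "scientific name" entry in `names` fall back to
#' their stringified taxon id.
#'
#' @param nodes path to a `nodes.dmp` file, or a character vector of its
#'   lines. Each row is `tax_id | parent_id | rank | ...`.
#' @param names path to a `names.dmp` file or its lines; only rows of name
#'   class `"scientific name"` are used. May be `NULL`.
#' @return A `taxonomy_tree` object: a list with `nodes` (data.frame of
#'   `id`, `parent`, `rank`, `name`) and `root` (the root taxon id).
#' @examples
#' tr <- parse_taxdump(c("1\t|\t1\t|\tno rank\t|", "2\t|\t1\t|\tspecies\t|"))
#' lca_depth(tr, 2, 2)
#' @export
parse_taxdump <- function(nodes, names = NULL) {
  node_lines <- as_lines(nodes)
  node_lines <- node_lines[nzchar(trimws(node_lines))]
  if (length(node_lines) == 0L) stop("empty nodes input")

  fields <- strsplit(node_lines, "|", fixed = TRUE)
  fields <- lapply(fields, function(f) trimws(f))
  nfield <- vapply(fields, length, integer(1))
  bad <- which(nfield < 3L)
  if (length(bad)) {
    stop(sprintf("malformed nodes row at line %d: expected at least 3 pipe-delimited fields",
                 bad[1]))
  }
  id <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 1L)))
  parent <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  rank <- vapply(fields, `[[`, "", 3L)
  bad <- which(is.na(id) | is.na(parent))
  if (length(bad)) {
    stop(sprintf("malformed nodes row at line %d: non-integer taxon id", bad[1]))
  }
  if (anyDuplicated(id)) {
    stop(sprintf("duplicate taxon id %d in nodes", id[anyDuplicated(id)]))
  }

  name <- as.character(id)
  if (!is.null(names)) {
    name_lines <- as_lines(names)
    name_lines <- name_lines[nzchar(trimws(name_lines))]
    if (length(name_lines)) {
      nf <- lapply(strsplit(name_lines, "|", fixed = TRUE), trimws)
      nn <- vapply(nf, length, integer(1))
      bad <- which(nn < 4L)
      if (length(bad)) {
        stop(sprintf("malformed names row at line %d: expected 4 pipe-delimited fields",
                     bad[1]))
      }
      nid <- suppressWarnings(as.integer(vapply(nf, `[[`, "", 1L)))
      ntxt <- vapply(nf, `[[`, "", 2L)
      nclass <- vapply(nf, `[[`, "", 4L)
      sci <- nclass == "scientific name"
      hit <- match(nid[sci], id)
      ok <- !is.na(hit)
      name[hit[ok]] <- ntxt[sci][ok]
    }
  }

  missing_parent <- setdiff(parent, id)
  if (length(missing_parent)) {
    stop(sprintf("structural error: parent taxon %d not present in nodes",
                 missing_parent[1]))
  }
  roots <- id[parent == id]
  if (length(roots) != 1L) {
    stop(sprintf("structural error: expected exactly one root (parent == self), found %d",
                 length(roots)))
  }

  tree <- structure(
    list(nodes = data.frame(id = id, parent = parent, rank = rank,
                            name = name, stringsAsFactors = FALSE),
         root = roots),
    class = "taxonomy_tree")

  # cycle check: every node must reach the root within |nodes| steps
  for (i in seq_along(id)) {
    cur <- id[i]
    steps <- 0L
    while (cur != tree$root) {
      cur <- parent[match(cur, id)]
      steps <- steps + 1L
      if (steps > length(id)) {
        stop(sprintf("structural error: cycle detected involving taxon %d", id[i]))
      }
    }
  }
  tree
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy_tree: %d taxa, root = %d\n", nrow(x$nodes), x$root))
  invisible(x)
}

#' Serialize a taxonomy tree in taxdump dialect
#'
#' Writes `nodes.dmp` and `names.dmp` files that [parse_taxdump()] reads back
#' into an identical tree.
#'
#' @param tree a `taxonomy_tree`.
#' @param dir output directory (created if needed).
#' @return Invisibly, a character vector with the two file paths.
#' @export
write_taxdump <- function(tree, dir) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nodes_path <- file.path(dir, "nodes.dmp")
  names_path <- file.path(dir, "names.dmp")
  n <- tree$nodes
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", n$id, n$parent, n$rank), nodes_path)
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", n$id, n$name),
             names_path)
  invisible(c(nodes = nodes_path, names = names_path))
}

#' Root-to-node lineage of a taxon
#'
#' @param tree a `taxonomy_tree`.
#' @param id a taxon id present in the tree.
#' @return A list with `path` (taxon ids ordered root first) and `depth`
#'   (number of edges from the root; the root has depth 0).
#' @export
taxon_lineage <- function(tree, id) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  ids <- tree$nodes$id
  if (!(id %in% ids)) stop(sprintf("unknown taxon id: %s", id))
  path <- integer(0)
  cur <- id
  repeat {
    path <- c(cur, path)
    if (cur == tree$root) break
    cur <- tree$nodes$parent[match(cur, ids)]
  }
  list(path = path, depth = length(path) - 1L)
}

#' Depth of the lowest common ancestor of two taxa
#'
#' The LCA is the deepest node lying on both root-to-taxon lineages; its
#' depth (edges from the root, root = 0) serves as a relatedness score:
#' larger depths mean the two taxa diverge lower in the tree.
#'
#' @param tree a `taxonomy_tree`.
#' @param a,b taxon ids present in the tree.
#' @return Integer LCA depth. Symmetric in `a` and `b`;
#'   `lca_depth(tree, x, x)` equals the depth of `x`.
#' @export
lca_depth <- function(tree, a, b) {
  pa <- taxon_lineage(tree, a)$path
  pb <- taxon_lineage(tree, b)$path
  k <- min(length(pa), length(pb))
  common <- which(pa[seq_len(k)] == pb[seq_len(k)])
  max(common) - 1L
}

# deepest ancestor of `id` having the given rank, or NA if none
rank_ancestor <- function(tree, id, rank = "phylum") {
  path <- taxon_lineage(tree, id)$path
  ranks <- tree$nodes$rank[match(path, tree$nodes$id)]
  hit <- which(ranks == rank)
  if (length(hit) == 0L) return(NA_integer_)
  path[max(hit)]
}

#' Rank candidate reference species by LCA depth
#'
#' Scores every candidate by the depth of its lowest common ancestor with the
#' query taxon and returns the top-scoring candidates, restricted (when
#' possible) to candidates sharing the query's phylum-rank ancestor. Higher
#' LCA depth means the candidate branches off closer to the query.
#'
#' Ties in score break by ascending taxon id, making the ranking invariant to
#' the order candidates are supplied in. If fewer than `min_n` candidates
#' pass the phylum filter the result is still returned, flagged with
#' `shortfall = TRUE` and a warning. A query lineage without a phylum-rank
#' node (e.g. protists in the NCBI tree) skips the phylum constraint with a
#' warning.
#'
#' @param tree a `taxonomy_tree`.
#' @param query_id taxon id of the query species. If absent from the tree an
#'   error of class `uco_path_error` is signalled, directing the caller to
#'   the sequence-based (UCO) selection route.
#' @param candidate_ids taxon ids of the candidate reference species.
#' @param min_n,max_n minimum / maximum number of species to report
#'   (defaults 3 and 5).
#' @return A `tax_selection` object: list with `query_id`, `ranked` (a
#'   data.frame of `species_id`, `name`, `lca_depth`, `rank`), `constraints`
#'   (`min_n`, `max_n`, `phylum_id`) and `shortfall`.
#' @export
select_by_taxonomy <- function(tree, query_id, candidate_ids,
                               min_n = 3L, max_n = 5L) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  if (length(candidate_ids) == 0L) stop("candidate_ids must be nonempty")
  if (min_n > max_n) stop("min_n must not exceed max_n")
  ids <- tree$nodes$id
  if (!(query_id %in% ids)) {
    stop(structure(
      class = c("uco_path_error", "error", "condition"),
      list(message = sprintf(
        "query taxon %s not in taxonomy; use UCO sequence-based selection instead",
        query_id), call = sys.call())))
  }
  missing <- setdiff(candidate_ids, ids)
  if (length(missing)) {
    stop(sprintf("unknown candidate taxon id: %s", missing[1]))
  }
  candidate_ids <- sort(unique(as.integer(candidate_ids)))

  phylum <- rank_ancestor(tree, query_id, "phylum")
  if (is.na(phylum)) {
    warning("query lineage has no phylum-rank node; phylum constraint skipped")
    keep <- candidate_ids
  } else {
    in_phylum <- vapply(candidate_ids, function(cid) {
      !is.na(ph <- rank_ancestor(tree, cid, "phylum")) && ph == phylum
    }, logical(1))
    keep <- candidate_ids[in_phylum]
  }

  score <- vapply(keep, function(cid) lca_depth(tree, query_id, cid), integer(1))
  ord <- order(-score, keep)
  keep <- keep[ord]
  score <- score[ord]
  n_take <- min(length(keep), max_n)
  shortfall <- length(keep) < min_n
  if (shortfall) {
    warning(sprintf("only %d candidate(s) satisfy the phylum constraint (min_n = %d)",
                    length(keep), min_n))
  }
  sel <- seq_len(n_take)
  idx <- match(keep[sel], tree$nodes$id)
  structure(
    list(query_id = query_id,
         ranked = data.frame(species_id = keep[sel],
                             name = tree$nodes$name[idx],
                             lca_depth = score[sel],
                             rank = tree$nodes$rank[idx],
                             stringsAsFactors = FALSE),
         constraints = list(min_n = min_n, max_n = max_n,
                            phylum_id = phylum),
         shortfall = shortfall),
    class = "tax_selection")
}

#' @export
print.tax_selection <- function(x, ...) {
  cat(sprintf("taxonomy-based selection for query taxon %d\n", x$query_id))
  print(x$ranked)
  invisible(x)
}
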