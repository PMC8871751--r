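# Perfect-phylogeny reconstruction of the rooted MSY haplotype tree from
# binary polarized sites, with variants mapped to branches.
#
# Under infinite-sites evolution every polymorphic site mutates exactly once,
# so the derived-carrier sets of all sites form a laminar family (pairwise
# nested or disjoint) relative to the all-ancestral root, and the rooted tree
# is unique up to the ordering of sites sharing an edge.

.binary_ingroup <- function(x, require_complete = TRUE) {
  if (!x$polarized) .stopf("matrix must be polarized")
  samples <- ingroup_samples(x)
  keep <- x$sites$ancestral_state != "unknown"
  if (any(!keep))
    message(sprintf("excluding %d site(s) with unknown ancestral state", sum(!keep)))
  m <- x$calls[samples, keep, drop = FALSE]
  if (anyNA(m)) {
    if (require_complete) .stopf("missing calls present; impute or exclude first")
    bad <- colSums(is.na(m)) > 0L
    .warnf("excluding %d site(s) with missing calls", sum(bad))
    m <- m[, !bad, drop = FALSE]
  }
  if (any(m < 0 | m > 1)) .stopf("non-binary calls present; filter heterozygous artifacts first")
  m
}

#' Four-gamete compatibility check
#'
#' Two binary sites are incompatible with a single tree when all four
#' gametes (00, 01, 10, 11) occur among the samples.
#'
#' @param x a polarized, complete (no missing calls) [call_matrix]
#' @return A `conflict_report`: list with `conflicting_pairs` (data.frame
#'   `site_a`, `site_b`) and `resolution` (sites dropped; empty here).
#' @export
four_gamete_check <- function(x) {
  m <- .binary_ingroup(x)
  pairs <- .gamete_conflicts(m, include_root = FALSE)
  structure(list(conflicting_pairs = pairs, resolution = character()),
            class = "conflict_report")
}

# all-pairs gamete test; include_root adds the implicit all-ancestral root
# (so the test becomes the rooted laminar-family criterion)
.gamete_conflicts <- function(m, include_root = TRUE) {
  p <- ncol(m)
  empty <- data.frame(site_a = character(), site_b = character(),
                      stringsAsFactors = FALSE)
  if (p < 2L) return(empty)
  M <- m
  n11 <- crossprod(M)            # both derived
  n10 <- crossprod(M, 1 - M)     # a derived, b ancestral
  n01 <- crossprod(1 - M, M)
  n00 <- crossprod(1 - M, 1 - M)
  if (include_root) n00 <- n00 + 1
  conflict <- n11 > 0 & n10 > 0 & n01 > 0 & n00 > 0
  conflict[lower.tri(conflict, diag = TRUE)] <- FALSE
  idx <- which(conflict, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  out <- data.frame(site_a = colnames(m)[idx[, 1]],
                    site_b = colnames(m)[idx[, 2]],
                    stringsAsFactors = FALSE)
  out[order(out$site_a, out$site_b), , drop = FALSE]
}

#' @export
print.conflict_report <- function(x, ...) {
  n <- nrow(x$conflicting_pairs)
  if (n == 0L && !length(x$resolution)) cat("conflict_report: no conflicts\n")
  else {
    cat(sprintf("conflict_report: %d conflicting site pair(s)\n", n))
    if (length(x$resolution))
      cat("  dropped:", paste(x$resolution, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reconstruct the rooted haplotype tree under perfect phylogeny
#'
#' Builds the unique rooted tree (up to ordering of sites sharing an edge)
#' in which every polymorphic site mutates on exactly one branch and the
#' root carries the all-ancestral vector (even if that vector is unobserved
#' among the ingroup). Sites with identical derived-carrier sets share one
#' edge; polytomies are represented explicitly. Compatibility is judged
#' against the rooted criterion (the four-gamete test with the implicit
#' all-ancestral root included); with `on_conflict = "greedy_drop"`,
#' conflicting sites are removed in increasing derived-carrier-count order
#' (ties broken by site_id) until the remainder is compatible.
#'
#' @param x a polarized [call_matrix] without missing calls at the sites used
#' @param on_conflict `"fail"` (default) or `"greedy_drop"`
#' @return list with `tree` (a `haplotype_tree`) and `conflicts`
#'   (a `conflict_report`).
#' @export
build_tree <- function(x, on_conflict = c("fail", "greedy_drop")) {
  on_conflict <- match.arg(on_conflict)
  m <- .binary_ingroup(x, require_complete = FALSE)
  mono <- colSums(m) == 0L
  if (any(mono)) m <- m[, !mono, drop = FALSE]

  conflicts <- .gamete_conflicts(m)
  dropped <- character()
  if (nrow(conflicts)) {
    if (on_conflict == "fail") {
      rep <- structure(list(conflicting_pairs = conflicts, resolution = character()),
                       class = "conflict_report")
      stop(structure(class = c("patrilineR_conflict", "error", "condition"),
                     list(message = sprintf(
                            "%d conflicting site pair(s); rerun with on_conflict = \"greedy_drop\" or inspect the report",
                            nrow(conflicts)),
                          call = sys.call(-1), report = rep)))
    }
    repeat {
      cur <- .gamete_conflicts(m)
      if (!nrow(cur)) break
      involved <- unique(c(cur$site_a, cur$site_b))
      cnt <- colSums(m[, involved, drop = FALSE])
      victim <- involved[order(cnt, involved)][1]
      dropped <- c(dropped, victim)
      m <- m[, setdiff(colnames(m), victim), drop = FALSE]
    }
  }
  report <- structure(list(conflicting_pairs = conflicts, resolution = dropped),
                      class = "conflict_report")
  tree <- .laminar_tree(m)
  list(tree = tree, conflicts = report)
}

# construct the haplotype tree from a compatible binary matrix
# (samples x sites, all-ancestral root implicit)
.laminar_tree <- function(m) {
  samples <- rownames(m)
  n <- nrow(m)
  # distinct derived-carrier sets, each becoming one edge/node
  if (ncol(m)) {
    keys <- apply(m, 2L, paste, collapse = "")
    grp <- split(colnames(m), factor(keys, levels = unique(keys)))
    sets <- lapply(names(grp), function(k) which(strsplit(k, "")[[1]] == "1"))
  } else {
    grp <- list(); sets <- list()
  }
  k <- length(sets)
  sizes <- lengths(sets)
  # parent of set i = smallest set strictly containing it, else the root
  parent_set <- rep(0L, k)            # 0 = root
  for (i in seq_len(k)) {
    # laminar family: the containing sets of i form a chain, so the
    # smallest strict superset (if any) is i's parent; else the root
    best <- 0L; best_size <- n + 1L
    for (j in seq_len(k)) {
      if (j != i && sizes[j] > sizes[i] && sizes[j] < best_size &&
          all(sets[[i]] %in% sets[[j]])) {
        best <- j; best_size <- sizes[j]
      }
    }
    parent_set[i] <- best
  }
  # deepest set containing each sample = its placement
  depth_of <- function(i) { d <- 0L; while (i != 0L) { d <- d + 1L; i <- parent_set[i] }; d }
  set_depth <- if (k) vapply(seq_len(k), depth_of, 1L) else integer()
  placement <- rep(0L, n)
  for (s in seq_len(n)) {
    containing <- which(vapply(seq_len(k), function(i) s %in% sets[[i]], TRUE))
    if (length(containing))
      placement[s] <- containing[which.max(set_depth[containing])]
  }
  # deterministic node ids: BFS from root, children ordered by smallest
  # descendant sample index (empty subtrees cannot occur)
  min_desc <- vapply(seq_len(k), function(i) min(sets[[i]]), 1L)
  children_of <- function(p) {
    ch <- which(parent_set == p)
    ch[order(min_desc[ch])]
  }
  id_of_set <- integer(k)
  order_sets <- integer(0)
  queue <- children_of(0L)
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    order_sets <- c(order_sets, cur)
    queue <- c(queue, children_of(cur))
  }
  id_of_set[order_sets] <- seq_along(order_sets) + 1L  # root is node 1
  nn <- k + 1L
  ps <- parent_set[order_sets]
  parent <- c(NA_integer_, ifelse(ps == 0L, 1L, id_of_set[pmax(ps, 1L)]))
  depth <- c(0L, set_depth[order_sets])
  members <- vector("list", nn)
  members[[1]] <- samples[placement == 0L]
  edge_sites <- vector("list", nn)
  edge_sites[[1]] <- character()
  for (i in seq_len(k)) {
    members[[id_of_set[i]]] <- samples[placement == i]
    edge_sites[[id_of_set[i]]] <- sort(grp[[i]])
  }
  nodes <- data.frame(node_id = seq_len(nn), parent = parent, depth = depth,
                      label = NA_character_,
                      n_members = lengths(members), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, members = members, edge_sites = edge_sites,
                 samples = samples, root = 1L),
            class = "haplotype_tree")
}

#' @export
print.haplotype_tree <- function(x, ...) {
  cat(sprintf("haplotype_tree: %d nodes, %d samples, %d sites on edges\n",
              nrow(x$nodes), length(x$samples),
              sum(lengths(x$edge_sites))))
  invisible(x)
}

# --- tree accessors -------------------------------------------------------

tree_children <- function(tree, node) {
  ch <- tree$nodes$node_id[!is.na(tree$nodes$parent) & tree$nodes$parent == node]
  ch
}

tree_path <- function(tree, node) {
  # node ids from root down to `node`
  path <- integer()
  while (!is.na(node)) {
    path <- c(node, path)
    node <- tree$nodes$parent[node]
  }
  path
}

tree_descendants <- function(tree, node) {
  out <- integer(); queue <- node
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    out <- c(out, cur)
    queue <- c(queue, tree_children(tree, cur))
  }
  out
}

# derived site_ids accumulated on the path root -> node
node_derived_sites <- function(tree, node) {
  unlist(tree$edge_sites[tree_path(tree, node)], use.names = FALSE)
}

#' Re-derive the sample-by-site binary matrix implied by a haplotype tree
#'
#' Walks each sample from the root to its node, collecting the variants on
#' the traversed branches. Used to verify that reconstruction is lossless.
#'
#' @param tree a `haplotype_tree`
#' @return binary matrix samples x sites (derived = 1)
#' @export
reconstruct_matrix <- function(tree) {
  sites <- sort(unique(unlist(tree$edge_sites)))
  m <- matrix(0L, length(tree$samples), length(sites),
              dimnames = list(tree$samples, sites))
  for (v in tree$nodes$node_id) {
    mem <- tree$members[[v]]
    if (!length(mem)) next
    d <- node_derived_sites(tree, v)
    m[mem, d] <- 1L
  }
  m
}

# --- export ---------------------------------------------------------------

.node_name <- function(tree, v) {
  lab <- tree$nodes$label[v]
  if (is.na(lab)) paste0("N", v) else gsub("[ (),;:]", "_", lab)
}

.newick <- function(tree, v) {
  ch <- tree_children(tree, v)
  inner <- if (length(ch))
    paste0("(", paste(vapply(ch, function(c) .newick(tree, c), ""), collapse = ","), ")")
  else ""
  blen <- length(tree$edge_sites[[v]])
  if (v == tree$root) paste0(inner, .node_name(tree, v))
  else paste0(inner, .node_name(tree, v), ":", blen)
}

tree_to_igraph <- function(tree) {
  nodes <- tree$nodes
  vertices <- data.frame(
    name = vapply(nodes$node_id, function(v) .node_name(tree, v), ""),
    frequency = nodes$n_members,
    size = 0.3 + 0.2 * sqrt(nodes$n_members),  # circle area ~ member count
    stringsAsFactors = FALSE)
  e <- nodes[!is.na(nodes$parent), , drop = FALSE]
  edges <- data.frame(
    from = vertices$name[e$parent],
    to = vertices$name[e$node_id],
    sites = vapply(e$node_id, function(v) paste(tree$edge_sites[[v]], collapse = ","), ""),
    mutations = vapply(e$node_id, function(v) length(tree$edge_sites[[v]]), 1L),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}

#' Export a haplotype tree
#'
#' @param tree a `haplotype_tree`
#' @param format `"table"` (lossless tab-delimited node/edge table),
#'   `"newick"` (branch lengths = mutation counts per edge), `"dot"` or
#'   `"graphml"` (node size attribute proportional to haplotype frequency).
#' @param file output path
#' @return `file`, invisibly.
#' @export
export_tree <- function(tree, format = c("table", "newick", "dot", "graphml"), file) {
  stopifnot(inherits(tree, "haplotype_tree"))
  format <- tryCatch(match.arg(format),
                     error = function(e) .stopf("unsupported export format: %s", format[1]))
  if (format == "table") {
    df <- data.frame(
      node_id = tree$nodes$node_id,
      label = ifelse(is.na(tree$nodes$label), "", tree$nodes$label),
      parent = ifelse(is.na(tree$nodes$parent), "", tree$nodes$parent),
      edge_sites = vapply(tree$nodes$node_id,
                          function(v) paste(tree$edge_sites[[v]], collapse = ","), ""),
      members = vapply(tree$nodes$node_id,
                       function(v) paste(tree$members[[v]], collapse = ","), ""),
      frequency = tree$nodes$n_members,
      stringsAsFactors = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "newick") {
    writeLines(paste0(.newick(tree, tree$root), ";"), file)
  } else {
    g <- tree_to_igraph(tree)
    igraph::write_graph(g, file, format = format)
  }
  invisible(file)
}

#' Import a haplotype tree from its table export
#'
#' @param file path to a table written by `export_tree(..., "table")`
#' @return A `haplotype_tree`; round-trips losslessly.
#' @export
import_tree <- function(file) {
  df <- utils::read.delim(file, colClasses = "character")
  need <- c("node_id", "label", "parent", "edge_sites", "members")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("tree table lacks column(s): %s", paste(miss, collapse = ", "))
  n <- nrow(df)
  raw_id <- as.integer(df$node_id)
  # node ids are positional throughout the package; remap arbitrary ids
  parent <- match(suppressWarnings(as.integer(df$parent)), raw_id)
  node_id <- seq_len(n)
  split_or_empty <- function(s) if (is.na(s) || s == "") character() else strsplit(s, ",")[[1]]
  members <- lapply(df$members, split_or_empty)
  edge_sites <- lapply(df$edge_sites, split_or_empty)
  depth <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L; p <- parent[i]
    while (!is.na(p)) { d <- d + 1L; p <- parent[p] }
    depth[i] <- d
  }
  root <- node_id[is.na(parent)]
  if (length(root) != 1L) .stopf("tree table must have exactly one root")
  nodes <- data.frame(node_id = node_id, parent = parent, depth = depth,
                      label = ifelse(df$label == "", NA_character_, df$label),
                      n_members = lengths(members), stringsAsFactors = FALSE)
  focus_empty <- !is.na(parent) & lengths(edge_sites) == 0L
  if (any(focus_empty))
    .warnf("imported tree has %d edge(s) carrying no sites", sum(focus_empty))
  structure(list(nodes = nodes, members = members, edge_sites = edge_sites,
                 samples = sort(unique(unlist(members))), root = root),
            class = "haplotype_tree")
}
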