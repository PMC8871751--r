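# shared fixture builders and independent oracles

# small hand-built matrix: `states` is a samples x sites integer matrix
# (0/1, -1 het, NA missing); depth/quality optional
toy_matrix <- function(states, outgroup = character(), depth = NULL,
                       quality = NULL, polarized = FALSE,
                       var_class = "SNV", alt = "G") {
  p <- ncol(states)
  sites <- data.frame(site_id = colnames(states) %||% sprintf("s%02d", seq_len(p)),
                      position = seq_len(p), var_class = var_class,
                      ref_allele = "A", alt_alleles = alt,
                      ancestral_state = if (polarized) "reference" else "unknown",
                      stringsAsFactors = FALSE)
  call_matrix(states, sites, outgroup_ids = outgroup, depth = depth,
              quality = quality, polarized = polarized)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical signature of a haplotype tree: one string per node recording the
# sorted edge-site set, the sorted node members, and the sorted subtree
# sample set; two trees are topologically identical (with identical
# variant-to-branch maps) iff their signatures match
tree_signature <- function(tree) {
  sig <- vapply(tree$nodes$node_id, function(v) {
    desc <- patrilineR:::tree_descendants(tree, v)
    sub <- sort(unlist(tree$members[desc]))
    paste(paste(sort(tree$edge_sites[[v]]), collapse = ","),
          paste(sort(tree$members[[v]]), collapse = ","),
          paste(sub, collapse = ","), sep = "|")
  }, "")
  sort(sig)
}

# restrict a truth tree to a subset of sites: drop other sites from edges,
# then merge any node whose edge became empty into its parent
restrict_tree <- function(tree, keep_sites) {
  nodes <- tree$nodes$node_id
  parent <- tree$nodes$parent
  edge <- lapply(tree$edge_sites, function(s) intersect(s, keep_sites))
  members <- tree$members
  alive <- rep(TRUE, length(nodes))
  repeat {
    victim <- which(alive & !is.na(parent) & lengths(edge) == 0L)[1]
    if (is.na(victim)) break
    p <- parent[victim]
    while (!alive[p]) p <- parent[p]
    members[[p]] <- c(members[[p]], members[[victim]])
    for (i in which(alive & !is.na(parent)))
      if (parent[i] == victim) parent[i] <- p
    alive[victim] <- FALSE
  }
  keep <- which(alive)
  remap <- match(seq_along(nodes), keep)
  nd <- data.frame(node_id = seq_along(keep),
                   parent = remap[parent[keep]],
                   depth = 0L, label = NA_character_,
                   n_members = lengths(members[keep]),
                   stringsAsFactors = FALSE)
  structure(list(nodes = nd, members = members[keep], edge_sites = edge[keep],
                 samples = tree$samples, root = remap[tree$root]),
            class = "haplotype_tree")
}

# independent random generator of perfect-phylogeny matrices: recursively
# partitions the sample set, hanging each block below a fresh edge with >= 1
# private sites; includes the all-ancestral haplotype when asked
random_laminar_matrix <- function(n_ht, n_sites, include_root_ht = TRUE) {
  stopifnot(n_sites >= n_ht - 1)
  samples <- sprintf("H%02d", seq_len(n_ht))
  m <- matrix(0L, n_ht, n_sites,
              dimnames = list(samples, sprintf("s%02d", seq_len(n_sites))))
  free <- seq_len(n_sites)
  blocks <- list(if (include_root_ht && n_ht > 1) 2:n_ht else seq_len(n_ht))
  while (length(blocks) && length(free)) {
    b <- blocks[[1]]; blocks <- blocks[-1]
    if (!length(b)) next
    # give this block some shared derived sites (an edge), then split it
    k <- sample(1:min(2L, length(free)), 1)
    if (length(b) < n_ht || !include_root_ht) {
      picked <- free[seq_len(k)]; free <- free[-seq_len(k)]
      m[b, picked] <- 1L
    }
    if (length(b) >= 2 && length(free)) {
      cut <- sample(seq_len(length(b) - 1L), 1)
      sh <- sample(b)
      blocks <- c(blocks, list(sh[seq_len(cut)]), list(sh[-seq_len(cut)]))
    }
  }
  # drop unused (monomorphic) sites
  m[, colSums(m) > 0, drop = FALSE]
}

# independent site-filter scan: literal per-rule loops over every site
brute_force_filter_scan <- function(x, cfg = filter_config()) {
  removed <- character()
  ig <- setdiff(x$samples, x$outgroup_ids)
  for (j in seq_len(nrow(x$sites))) {
    id <- x$sites$site_id[j]
    bad <- FALSE
    if (!is.null(x$depth)) {
      nlow <- 0
      for (s in x$samples)
        if (x$depth[s, j] < cfg$min_depth || x$quality[s, j] < cfg$min_quality)
          nlow <- nlow + 1
      if (nlow / length(x$samples) > cfg$max_low_quality_fraction) bad <- TRUE
    }
    ncall <- sum(!is.na(x$calls[, j]))
    if (ncall / length(x$samples) < cfg$min_call_rate) bad <- TRUE
    obs <- x$calls[ig, j]; obs <- obs[!is.na(obs)]
    if (length(obs) && all(obs == -1L)) bad <- TRUE
    if (length(strsplit(x$sites$alt_alleles[j], ",")[[1]]) > 1 &&
        x$sites$var_class[j] != "STR") bad <- TRUE
    if (length(obs) && all(obs >= 1L)) bad <- TRUE
    if (bad) removed <- c(removed, id)
  }
  removed
}

# true state of a cell in the simulation (for imputation accuracy checks)
sim_true_state <- function(truth, sample, site_id) {
  truth$true_matrix$calls[sample, site_id]
}
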