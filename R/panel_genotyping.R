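# Complexity-reduced marker backbones and consecutive panel genotyping.
#
# A backbone panel tags tree edges with one genotypable marker each; samples
# typed on the panel are placed on the deepest node whose root path is fully
# supported by derived calls. Placements at internal nodes carry a terminal
# '*' (the haplotype may branch off below once more carriers are sequenced).

#' Select a reduced marker backbone from a haplotype tree
#'
#' Guarantees full traceability for the focus lineages (one marker on every
#' edge of every root-to-focus path) and coarse resolution elsewhere (one
#' marker on the subtending edge of each coarse node only). When an edge
#' carries several sites the lexicographically smallest site_id is chosen.
#' Stage roles follow the consecutive genotyping workflow: markers on edges
#' leaving the root are `key`, markers on the next split are `clade`, and
#' all deeper markers are `ht`.
#'
#' @param tree a labeled `haplotype_tree`
#' @param focus node labels whose root paths must be fully covered
#' @param coarse node labels tagged only by their subtending edge
#' @return A `marker_panel` data.frame (`site_id`, `stage`, `edge_node`,
#'   `edge_label`).
#' @export
select_backbone <- function(tree, focus, coarse = character()) {
  stopifnot(inherits(tree, "haplotype_tree"))
  lab <- tree$nodes$label
  find_node <- function(l) {
    v <- tree$nodes$node_id[!is.na(lab) & strip_asterisk(lab) == strip_asterisk(l)]
    if (length(v) != 1L) .stopf("label not found in tree: %s", l)
    v
  }
  edges <- integer()                 # child node ids whose edge needs a marker
  for (f in focus) {
    path <- tree_path(tree, find_node(f))
    edges <- union(edges, setdiff(path, tree$root))
  }
  for (cn in coarse)
    edges <- union(edges, setdiff(find_node(cn), tree$root))
  if (!length(edges)) .stopf("no edges selected; give at least one focus or coarse label")
  edges <- sort(edges)
  site <- character(length(edges))
  for (i in seq_along(edges)) {
    s <- tree$edge_sites[[edges[i]]]
    if (!length(s))
      .stopf("edge above node %d ('%s') carries no sites; cannot place a marker",
             edges[i], lab[edges[i]] %||% "")
    site[i] <- sort(s)[1]
  }
  depth <- tree$nodes$depth[edges]
  stage <- ifelse(depth == 1L, "key", ifelse(depth == 2L, "clade", "ht"))
  structure(data.frame(site_id = site, stage = stage, edge_node = edges,
                       edge_label = ifelse(is.na(lab[edges]), "", lab[edges]),
                       stringsAsFactors = FALSE),
            class = c("marker_panel", "data.frame"))
}

#' Write / read a marker panel file
#' @param panel a `marker_panel`
#' @param path delimited file (`site_id`, `stage`, `edge_key`)
#' @export
write_panel <- function(panel, path) {
  out <- data.frame(site_id = panel$site_id, stage = panel$stage,
                    edge_key = panel$edge_label, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @param tree the labeled tree the panel refers to (edge keys are labels)
#' @export
read_panel <- function(path, tree) {
  df <- utils::read.delim(path, colClasses = "character")
  lab <- tree$nodes$label
  node <- vapply(df$edge_key, function(l) {
    v <- tree$nodes$node_id[!is.na(lab) & lab == l]
    if (length(v) != 1L) .stopf("panel edge key not found in tree: %s", l)
    v
  }, 1L)
  structure(data.frame(site_id = df$site_id, stage = df$stage,
                       edge_node = as.integer(node),
                       edge_label = df$edge_key, stringsAsFactors = FALSE),
            class = c("marker_panel", "data.frame"))
}

# calls: named character vector, values A/D/U/F (ancestral, derived,
# untested, failed); unnamed panel markers count as untested
.normalize_calls <- function(calls, panel) {
  val <- setNames(rep("U", nrow(panel)), panel$site_id)
  calls <- toupper(unlist(calls))
  bad <- setdiff(unique(calls), c("A", "D", "U", "F"))
  if (length(bad)) .stopf("invalid panel call symbol(s): %s", paste(bad, collapse = ", "))
  known <- intersect(names(calls), panel$site_id)
  val[known] <- calls[known]
  val[val == "F"] <- "U"            # assay dropout is handled like untested
  val
}

#' Place a panel-genotyped sample on the backbone tree
#'
#' Implements the consecutive testing procedure declaratively: the sample is
#' assigned to the deepest node such that every tested marker on the
#' root-to-node path is derived and every tested marker on edges leaving the
#' path is ancestral. Markers in clades other than the sample's derived
#' clade are auto-imputed ancestral before evaluation (and never count as
#' evidence). Derived markers on two or more disjoint branches — or an
#' ancestral call contradicting a derived call below it — yield
#' `node_label = "conflict"`. Any placement at an internal node carries a
#' terminal `"*"` and `resolved = FALSE`: panel markers cannot exclude an
#' un-ascertained private branch below it.
#'
#' @param calls named character vector of panel calls (`A`, `D`, `U`, `F`)
#' @param tree the labeled `haplotype_tree`
#' @param panel a `marker_panel` from [select_backbone()] or [read_panel()]
#' @param impute_other_clades auto-impute ancestral state in non-carried clades
#' @return list with `node_id`, `node_label`, `resolved`, `evidence`
#'   (derived markers on the root path), `conflicts` (derived markers off
#'   it, or contradicted calls), `imputed` (auto-imputed markers).
#' @export
assign_sample <- function(calls, tree, panel, impute_other_clades = TRUE) {
  stopifnot(inherits(tree, "haplotype_tree"), inherits(panel, "marker_panel"))
  val <- .normalize_calls(calls, panel)
  edge_of <- setNames(panel$edge_node, panel$site_id)

  # clade imputation: if exactly one clade-stage subtree holds a derived
  # marker, untested markers confined to the other clade subtrees are
  # imputed ancestral (they are uninformative for this sample)
  imputed <- character()
  clade_nodes <- panel$edge_node[panel$stage == "clade"]
  if (impute_other_clades && length(clade_nodes)) {
    in_subtree <- function(marker, roots) {
      any(vapply(roots, function(r) edge_of[marker] %in% tree_descendants(tree, r), TRUE))
    }
    derived_clades <- unique(unlist(lapply(clade_nodes, function(cn) {
      sub <- tree_descendants(tree, cn)
      if (any(val[panel$site_id[panel$edge_node %in% sub]] == "D")) cn else NULL
    })))
    if (length(derived_clades) == 1L) {
      others <- setdiff(clade_nodes, derived_clades)
      for (mk in panel$site_id)
        if (val[mk] == "U" && in_subtree(mk, others)) {
          val[mk] <- "A"
          imputed <- c(imputed, mk)
        }
    }
  }

  tested_d <- panel$site_id[val[panel$site_id] == "D"]
  tested_a <- setdiff(panel$site_id[val[panel$site_id] == "A"], imputed)
  derived_edges <- unique(edge_of[tested_d])

  finish <- function(node, label, resolved, evidence, conflicts) {
    list(node_id = node, node_label = label, resolved = resolved,
         evidence = sort(evidence), conflicts = sort(conflicts),
         imputed = sort(imputed))
  }
  label_of <- function(v) {
    l <- tree$nodes$label[v]
    if (is.na(l)) paste0("N", v) else l
  }

  if (!length(derived_edges)) {
    v <- tree$root
  } else {
    depths <- tree$nodes$depth[derived_edges]
    cand <- derived_edges[order(-depths, derived_edges)]
    best <- NULL; best_cover <- -1L
    for (v0 in cand) {
      cover <- sum(derived_edges %in% tree_path(tree, v0))
      if (cover > best_cover) { best <- v0; best_cover <- cover }
    }
    v <- best
    path <- tree_path(tree, v)
    off_path <- tested_d[!(edge_of[tested_d] %in% path)]
    contradicted <- tested_a[edge_of[tested_a] %in% setdiff(path, tree$root)]
    if (length(off_path) || length(contradicted)) {
      evidence <- tested_d[edge_of[tested_d] %in% path]
      return(finish(v, "conflict", FALSE, evidence,
                    c(off_path, contradicted)))
    }
  }
  path <- tree_path(tree, v)
  evidence <- tested_d[edge_of[tested_d] %in% path]
  is_leaf <- length(tree_children(tree, v)) == 0L
  if (is_leaf)
    finish(v, label_of(v), TRUE, evidence, character())
  else
    finish(v, paste0(strip_asterisk(label_of(v)), "*"), FALSE, evidence, character())
}

#' Place many panel-genotyped samples
#'
#' @param callset data.frame or matrix, rows = samples (rownames), columns =
#'   panel markers, entries in `A`/`D`/`U`/`F`.
#' @inheritParams assign_sample
#' @return data.frame (`sample`, `node_label`, `resolved`, `evidence`,
#'   `conflicts`), one row per sample.
#' @export
assign_samples <- function(callset, tree, panel, impute_other_clades = TRUE) {
  callset <- as.matrix(callset)
  res <- lapply(rownames(callset), function(s) {
    a <- assign_sample(setNames(callset[s, ], colnames(callset)),
                       tree, panel, impute_other_clades)
    data.frame(sample = s, node_label = a$node_label, resolved = a$resolved,
               evidence = paste(a$evidence, collapse = ","),
               conflicts = paste(a$conflicts, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Read / write a panel call grid
#' @param path delimited sample x marker grid with symbols A/D/U/F
#' @export
read_panel_calls <- function(path) {
  df <- utils::read.delim(path, row.names = 1L, colClasses = "character",
                          check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_panel_calls
#' @param callset matrix as in [assign_samples()]
#' @export
write_panel_calls <- function(callset, path) {
  df <- data.frame(sample = rownames(callset), as.data.frame(callset),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The bundled synthetic crown backbone tree
#'
#' A small labeled haplotype tree encoding the published marker-to-branch
#' relations of the crown backbone (key variants rAY/rAX; clade tests rA,
#' rW, fYR; the Ta path markers sPZ, fTY, fRL, fXT, fZK, fZW; the Ta-s /
#' Ta-b split markers sPY, qGB, qGC; and the recent subline variants qDK,
#' qFE, rAB, fWO). Branch relations that are not published — the exact
#' clade-to-marker mapping and the A-clade internal chain — are synthetic
#' stand-ins and configurable by supplying your own tree table.
#'
#' @return A labeled `haplotype_tree`.
#' @export
crown_backbone <- function() {
  path <- system.file("extdata", "synthetic_crown_backbone.tsv",
                      package = "patrilineR", mustWork = TRUE)
  import_tree(path)
}
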