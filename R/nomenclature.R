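# Hierarchical haplotype nomenclature: legacy stems anchor subtrees, every
# unanchored child appends exactly one character to its parent's label
# (a digit after a terminal letter, a lowercase letter after a terminal
# digit), and a terminal '*' marks a placement at an internal node that is
# not yet fully resolved by sequencing.

.validate_label <- function(label) {
  if (length(label) != 1L || is.na(label) ||
      !grepl("^[A-Za-z][A-Za-z0-9-]*\\*?$", label))
    .stopf("unparseable haplotype label: '%s'", as.character(label)[1])
  invisible(label)
}

strip_asterisk <- function(label) sub("\\*$", "", label)

#' Nesting test on haplotype names
#'
#' `TRUE` when `a` names the same node as `b` or an ancestor of it: after
#' stripping a terminal asterisk, `a` must be a prefix of (or equal to) `b`.
#' `"X*"` denotes the internal node X and is therefore compatible with any
#' descendant of X.
#'
#' @param a,b haplotype labels
#' @return logical
#' @export
is_ancestor_name <- function(a, b) {
  .validate_label(a); .validate_label(b)
  sa <- strip_asterisk(a); sb <- strip_asterisk(b)
  startsWith(sb, sa)
}

# comparable = one names an ancestor (or the same node) of the other
.names_nested <- function(a, b) is_ancestor_name(a, b) || is_ancestor_name(b, a)

# suffix alphabets: after a letter come digits (then letters as overflow),
# after a digit come lowercase letters (then digits); 36 symbols each
.suffix_seq <- function(parent_label) {
  last <- substr(parent_label, nchar(parent_label), nchar(parent_label))
  if (grepl("[0-9]", last)) c(letters, as.character(c(1:9, 0)))
  else c(as.character(c(1:9, 0)), letters)
}

#' Create a name registry
#'
#' @param node_key node identifiers (as in `tree$nodes$node_id`)
#' @param label the fixed legacy label anchored at each node
#' @return data.frame of class `name_registry`
#' @export
name_registry <- function(node_key = integer(), label = character()) {
  label <- as.character(label)
  for (l in label) .validate_label(l)
  if (anyDuplicated(label)) .stopf("registry labels must be unique")
  if (anyDuplicated(node_key)) .stopf("registry node keys must be unique")
  structure(data.frame(node_key = as.integer(node_key), label = label,
                       stringsAsFactors = FALSE),
            class = c("name_registry", "data.frame"))
}

# smallest member sample (by input order) in each node's subtree; drives
# the deterministic child ordering during naming
.min_desc_sample <- function(tree) {
  idx <- function(v) {
    mem <- unlist(tree$members[tree_descendants(tree, v)], use.names = FALSE)
    if (!length(mem)) Inf else min(match(mem, tree$samples))
  }
  vapply(tree$nodes$node_id, idx, 1)
}

#' Assign hierarchical names to all tree nodes
#'
#' Anchored nodes take their registry label verbatim; every other node gets
#' its parent's label plus one appended character, alternating character
#' class with the parent's terminal character (a digit starting at "1"
#' after a letter, a lowercase letter starting at "a" after a digit).
#' Children are named in deterministic order (by smallest member sample in
#' the subtree, following matrix input order). Existing labels on the tree
#' are kept, so renaming an already-named tree is a no-op.
#'
#' @param tree a `haplotype_tree`
#' @param registry a [name_registry] of legacy anchors (may be empty)
#' @param root_label label used for an unanchored root
#' @return The tree with `nodes$label` filled in.
#' @export
assign_names <- function(tree, registry = name_registry(), root_label = "R") {
  stopifnot(inherits(tree, "haplotype_tree"))
  if (!inherits(registry, "name_registry"))
    registry <- do.call(name_registry, as.list(registry))
  bad <- setdiff(registry$node_key, tree$nodes$node_id)
  if (length(bad))
    .stopf("registry anchors absent from tree: %s", paste(bad, collapse = ", "))
  labels <- tree$nodes$label
  labels[match(registry$node_key, tree$nodes$node_id)] <- registry$label
  ordkey <- .min_desc_sample(tree)
  if (is.na(labels[tree$root])) {
    .validate_label(root_label)
    labels[tree$root] <- root_label
  }
  queue <- tree$root
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    ch <- tree_children(tree, v)
    ch <- ch[order(ordkey[ch])]
    pending <- ch[is.na(labels[ch])]
    if (length(pending)) {
      alphabet <- .suffix_seq(strip_asterisk(labels[v]))
      taken <- labels[ch[!is.na(labels[ch])]]
      free <- paste0(strip_asterisk(labels[v]), alphabet)
      free <- setdiff(free, taken)
      if (length(pending) > length(free))
        .stopf("node %d has %d children needing suffixes; alphabet exhausted (max 36)",
               v, length(pending))
      labels[pending] <- free[seq_along(pending)]
    }
    queue <- c(queue, ch)
  }
  if (anyDuplicated(stats::na.omit(labels)))
    .stopf("name assignment produced duplicate labels; check registry anchors")
  tree$nodes$label <- labels
  tree
}

#' Extract the name registry of a labeled tree
#' @param tree a labeled `haplotype_tree`
#' @return A [name_registry] mapping every labeled node to its label.
#' @export
registry_of <- function(tree) {
  keep <- !is.na(tree$nodes$label)
  name_registry(tree$nodes$node_id[keep], tree$nodes$label[keep])
}

#' Validate a registry file or table
#'
#' Checks that labels are unique and parseable, and (when `tree` is given)
#' that every non-anchor child label extends its parent's label by exactly
#' one character.
#'
#' @param registry a [name_registry], data.frame, or path to a two-column
#'   delimited file (`node_key`, `label`)
#' @param tree optional labeled `haplotype_tree` to check structure against
#' @param anchors node keys exempt from the one-character rule (legacy stems)
#' @return data.frame of issues (zero rows when valid)
#' @export
check_registry <- function(registry, tree = NULL, anchors = integer()) {
  if (is.character(registry) && length(registry) == 1L)
    registry <- utils::read.delim(registry, colClasses = c("integer", "character"))
  issues <- data.frame(node_key = integer(), issue = character(),
                       stringsAsFactors = FALSE)
  note <- function(k, what) rbind(issues, data.frame(node_key = k, issue = what,
                                                     stringsAsFactors = FALSE))
  for (i in seq_len(nrow(registry))) {
    l <- registry$label[i]
    ok <- tryCatch({ .validate_label(l); TRUE }, error = function(e) FALSE)
    if (!ok) issues <- note(registry$node_key[i], "unparseable label")
  }
  dup <- duplicated(registry$label)
  if (any(dup))
    for (i in which(dup)) issues <- note(registry$node_key[i], "duplicate label")
  if (!is.null(tree)) {
    for (i in seq_len(nrow(registry))) {
      k <- registry$node_key[i]
      p <- tree$nodes$parent[match(k, tree$nodes$node_id)]
      if (is.na(p) || k %in% anchors) next
      pl <- registry$label[match(p, registry$node_key)]
      l <- strip_asterisk(registry$label[i])
      if (!is.na(pl) &&
          !(startsWith(l, strip_asterisk(pl)) &&
            nchar(l) == nchar(strip_asterisk(pl)) + 1L))
        issues <- note(k, "label does not extend parent by one character")
    }
  }
  issues
}

#' Write / read a registry file
#' @param registry a [name_registry]
#' @param path two-column tab-delimited file
#' @export
write_registry <- function(registry, path) {
  utils::write.table(registry, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  df <- utils::read.delim(path, colClasses = c("integer", "character"))
  name_registry(df$node_key, df$label)
}
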