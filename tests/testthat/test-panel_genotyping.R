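# backbone marker selection and consecutive panel placement

backbone_and_panel <- function() {
  bb <- crown_backbone()
  leaves <- bb$nodes$label[!bb$nodes$node_id %in% bb$nodes$parent]
  list(tree = bb, panel = select_backbone(bb, focus = leaves))
}

test_that("backbone selection covers focus paths and coarse subtending edges", {
  bb <- crown_backbone()
  # one focus leaf at depth 5: exactly one marker per path edge
  p <- select_backbone(bb, focus = "Ta-bA")
  expect_equal(nrow(p), 5L)
  expect_setequal(p$edge_label, c("C", "T", "Ta", "Ta-b", "Ta-bA"))
  # the lexicographically smallest site on a multi-site edge is chosen
  expect_equal(p$site_id[p$edge_label == "C"], "rAX")
  expect_equal(p$site_id[p$edge_label == "Ta"], "fRL")
  # stages follow the consecutive workflow
  expect_equal(p$stage, c("key", "clade", "ht", "ht", "ht"))
  # coarse nodes get their subtending edge only
  p2 <- select_backbone(bb, focus = "Ta-bA", coarse = "Ao-aD2")
  expect_setequal(setdiff(p2$edge_label, p$edge_label), "Ao-aD2")
  expect_equal(nrow(p2), 6L)
  expect_error(select_backbone(bb, focus = "NoSuch"), "not found")
})

test_that("panel cover matches an independent path enumeration on random trees", {
  for (seed in 61:66) {
    truth <- simulate_patrilines(sim_config(generations = 5, founders = 2,
                                            mu = 0.5, sites = 250, seed = seed))
    tree <- assign_names(build_tree(truth$true_matrix)$tree, name_registry(1L, "T"))
    if (nrow(tree$nodes) > 40 || nrow(tree$nodes) < 4) next
    labs <- tree$nodes$label
    occupied <- tree$nodes$node_id[tree$nodes$n_members > 0 &
                                     tree$nodes$node_id != tree$root]
    focus <- labs[occupied]
    panel <- select_backbone(tree, focus = focus)
    # independent enumeration: walk parent pointers from scratch
    want_edges <- integer()
    for (v in occupied) {
      w <- v
      while (!is.na(tree$nodes$parent[w])) {
        want_edges <- union(want_edges, w)
        w <- tree$nodes$parent[w]
      }
    }
    expect_setequal(panel$edge_node, want_edges)
    # minimality for the stated rule: exactly one marker per covered edge
    expect_equal(nrow(panel), length(want_edges))
    expect_equal(anyDuplicated(panel$edge_node), 0L)
  }
})

test_that("placement follows the consecutive-testing semantics", {
  bp <- backbone_and_panel()
  # derived down the Ta path, ancestral for the Ta-s / Ta-b markers: Ta*
  a <- assign_sample(c(rAX = "D", rW = "D", fRL = "D", sPY = "A", qGB = "A"),
                     bp$tree, bp$panel)
  expect_equal(a$node_label, "Ta*")
  expect_false(a$resolved)
  expect_setequal(a$evidence, c("rAX", "rW", "fRL"))
  expect_length(a$conflicts, 0L)
  # markers informative in the other clades were auto-imputed ancestral
  expect_true(all(c("rA", "fYR", "xA1A1") %in% a$imputed))
  expect_length(intersect(a$imputed, a$evidence), 0L)

  # crown keys derived, everything else ancestral: crown-root asterisk
  calls <- setNames(rep("A", nrow(bp$panel)), bp$panel$site_id)
  calls[["rAX"]] <- "D"
  a2 <- assign_sample(calls, bp$tree, bp$panel)
  expect_equal(a2$node_label, "C*")
  expect_false(a2$resolved)

  # a full derived path to a leaf resolves
  leafcalls <- c(rAX = "D", rW = "D", fRL = "D", qGB = "D", qDK = "D",
                 sPY = "A")
  a3 <- assign_sample(leafcalls, bp$tree, bp$panel)
  expect_equal(a3$node_label, "Ta-bA")
  expect_true(a3$resolved)

  # derived markers on two disjoint branches: conflict, never an exception
  a4 <- assign_sample(c(rAX = "D", rW = "D", rA = "D"), bp$tree, bp$panel)
  expect_equal(a4$node_label, "conflict")
  expect_false(a4$resolved)
  expect_true(length(a4$conflicts) >= 1L)

  # an ancestral call contradicting a derived call below it is a conflict too
  a5 <- assign_sample(c(rAX = "D", rW = "A", fRL = "D"), bp$tree, bp$panel)
  expect_equal(a5$node_label, "conflict")
  expect_true("rW" %in% a5$conflicts)
})

test_that("full panels reproduce the sequencing placement; withheld markers stop above", {
  for (seed in 71:74) {
    truth <- simulate_patrilines(sim_config(generations = 5, founders = 2,
                                            mu = 0.5, sites = 250, seed = seed))
    tree <- assign_names(build_tree(truth$true_matrix)$tree, name_registry(1L, "T"))
    occupied <- tree$nodes$node_id[tree$nodes$n_members > 0 &
                                     tree$nodes$node_id != tree$root]
    if (!length(occupied)) next
    panel <- select_backbone(tree, focus = tree$nodes$label[occupied])
    for (s in truth$samples) {
      v_true <- tree$nodes$node_id[vapply(tree$nodes$node_id, function(v)
        s %in% tree$members[[v]], TRUE)]
      calls <- setNames(ifelse(truth$true_matrix$calls[s, panel$site_id] == 1L,
                               "D", "A"), panel$site_id)
      a <- assign_sample(calls, tree, panel)
      expect_equal(a$node_id, v_true)
      expect_length(a$conflicts, 0L)
      # withhold everything below an ancestor: placement stops exactly there
      path <- patrilineR:::tree_path(tree, v_true)
      anc <- setdiff(path, c(tree$root, v_true))
      if (length(anc)) {
        stopat <- anc[length(anc)]
        below <- setdiff(patrilineR:::tree_descendants(tree, stopat), stopat)
        calls2 <- calls
        calls2[panel$site_id[panel$edge_node %in% below]] <- "U"
        a2 <- assign_sample(calls2, tree, panel)
        expect_equal(a2$node_id, stopat)
        expect_match(a2$node_label, "\\*$")
        expect_false(a2$resolved)
      }
    }
  }
})

test_that("adding a truthful tested marker never retreats the placement", {
  bp <- backbone_and_panel()
  truthful <- c(rAX = "D", rW = "D", fRL = "D", qGB = "D", qDK = "D")
  partial <- c(rAX = "D", rW = "D")
  depth_of <- function(a) bp$tree$nodes$depth[a$node_id]
  d_prev <- depth_of(assign_sample(partial, bp$tree, bp$panel))
  for (mk in setdiff(names(truthful), names(partial))) {
    partial[mk] <- truthful[[mk]]
    d_now <- depth_of(assign_sample(partial, bp$tree, bp$panel))
    expect_gte(d_now, d_prev)
    d_prev <- d_now
  }
})

test_that("panel files and call grids round-trip", {
  bp <- backbone_and_panel()
  f <- tempfile()
  write_panel(bp$panel, f)
  back <- read_panel(f, bp$tree)
  expect_equal(back$site_id, bp$panel$site_id)
  expect_equal(back$edge_node, bp$panel$edge_node)

  grid <- rbind(H1 = c(rAX = "D", rW = "D", fRL = "A"),
                H2 = c(rAX = "D", rW = "A", fRL = "U"))
  g <- tempfile()
  write_panel_calls(grid, g)
  expect_identical(read_panel_calls(g), grid)
  res <- assign_samples(grid, bp$tree, bp$panel)
  expect_equal(res$sample, c("H1", "H2"))
  expect_equal(res$node_label[1], "T*")
})
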