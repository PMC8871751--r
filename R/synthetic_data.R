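# Forward simulation of non-recombining haploid (MSY-like) inheritance
# through male genealogies: hierarchical mutations under infinite sites,
# genotyping noise, and recorded-pedigree paternity errors, with full
# ground truth for every pipeline stage.

#' Simulation configuration
#'
#' @param generations number of discrete generations (founders = generation 1;
#'   the extant generation is sampled).
#' @param founders number of founding males.
#' @param offspring_lambda mean of the zero-truncated Poisson son-number law
#'   (every male leaves at least one son, mimicking retained sire lines).
#' @param popular_sire when `TRUE`, one male per generation breeds at
#'   `popular_multiplier` times the base rate, reproducing the star-like
#'   expansions that dominant stallions leave in the haplotype tree.
#' @param popular_multiplier rate multiplier for the popular sire.
#' @param sites number of mutable sites (infinite-sites pool).
#' @param mu expected mutations per father-to-son transmission (Poisson).
#' @param founder_mutations private derived sites given to each founder
#'   before the first transmission (0 keeps all founders on the ancestral
#'   haplotype; positive values emulate foundation sires whose lineages
#'   diverged long before the recorded pedigree).
#' @param missing_rate,het_artifact_rate per-call probabilities used by
#'   [degrade_calls()].
#' @param paternity_error_rate per-recorded-transmission probability used by
#'   [perturb_pedigree()].
#' @param generation_interval_years years per transmission (calendar time =
#'   transmissions x interval).
#' @param seed integer seed; all outputs are deterministic given the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(generations = 6, founders = 3, offspring_lambda = 1.2,
                       popular_sire = FALSE, popular_multiplier = 3,
                       sites = 500, mu = 0.3, founder_mutations = 0,
                       missing_rate = 0.05, het_artifact_rate = 0.01,
                       paternity_error_rate = 0,
                       generation_interval_years = 8, seed = 1) {
  stopifnot(.is_count(generations), generations >= 1,
            .is_count(founders), founders >= 1,
            .is_count(sites), sites >= 1,
            is.numeric(mu), mu >= 0,
            .is_count(founder_mutations),
            .is_prob(missing_rate), .is_prob(het_artifact_rate),
            .is_prob(paternity_error_rate),
            is.numeric(offspring_lambda), offspring_lambda > 0,
            is.numeric(generation_interval_years), generation_interval_years > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Read / write a simulation configuration file
#'
#' Plain `key: value` text (YAML subset), one entry per [sim_config] field;
#' omitted fields take their defaults.
#'
#' @param path configuration file
#' @return A [sim_config].
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown))
    .stopf("unknown simulation config key(s): %s", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config a [sim_config]
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.rztpois <- function(n, lambda) {
  # zero-truncated Poisson by inversion of the conditional CDF
  u <- stats::runif(n, stats::dpois(0, lambda), 1)
  stats::qpois(u, lambda)
}

#' Simulate a male genealogy with haploid MSY inheritance
#'
#' Founders start from the ancestral haplotype (plus `founder_mutations`
#' private derived sites each); every father-to-son transmission adds
#' Poisson(`mu`) mutations at previously unmutated sites (infinite sites by
#' rejection; an error advises enlarging `sites` if the pool is exhausted).
#' Extant-generation males are the samples; an outgroup sample carries the
#' all-ancestral vector.
#'
#' @param config a [sim_config]
#' @return An `msy_sim` with the true/recorded pedigree, per-transmission
#'   mutation record, the error-free polarized [call_matrix] (`true_matrix`,
#'   outgroup `"OUT"`) and the independently constructed true haplotype
#'   tree (`true_tree`).
#' @export
simulate_patrilines <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    free <- seq_len(config$sites)        # unmutated site pool
    draw_new <- function(k, who) {
      if (k > length(free))
        .stopf("infinite-sites pool exhausted at %s; increase sites (currently %d)",
               who, config$sites)
      picked <- if (k) sort(sample(free, k)) else integer()
      free <<- setdiff(free, picked)
      picked
    }
    id <- function(g, i) sprintf("M%d_%d", g, i)
    ped <- list(); derived <- list(); mut <- list()
    gen_members <- vector("list", config$generations)
    for (i in seq_len(config$founders)) {
      nm <- id(1L, i)
      ped[[nm]] <- list(id = nm, father = NA_character_, generation = 1L)
      derived[[nm]] <- draw_new(config$founder_mutations, nm)
      mut[[nm]] <- derived[[nm]]
    }
    gen_members[[1]] <- vapply(seq_len(config$founders), function(i) id(1L, i), "")
    if (config$generations > 1L) {
      for (g in 2L:config$generations) {
        fathers <- gen_members[[g - 1L]]
        lam <- rep(config$offspring_lambda, length(fathers))
        if (config$popular_sire && length(fathers) > 1L)
          lam[sample(length(fathers), 1L)] <- config$offspring_lambda * config$popular_multiplier
        sons_per <- .rztpois(length(fathers), lam)
        k <- 0L
        for (fi in seq_along(fathers)) {
          f <- fathers[fi]
          for (s in seq_len(sons_per[fi])) {
            k <- k + 1L
            nm <- id(g, k)
            new_sites <- draw_new(stats::rpois(1L, config$mu), nm)
            ped[[nm]] <- list(id = nm, father = f, generation = g)
            derived[[nm]] <- sort(c(derived[[f]], new_sites))
            mut[[nm]] <- new_sites
          }
        }
        gen_members[[g]] <- vapply(seq_len(k), function(i) id(g, i), "")
      }
    }
    pedigree <- data.frame(
      id = names(ped),
      father = vapply(ped, function(p) p$father, ""),
      generation = vapply(ped, function(p) p$generation, 1L),
      stringsAsFactors = FALSE, row.names = NULL)
    samples <- gen_members[[config$generations]]
    true_matrix <- .truth_matrix(samples, derived, config$sites)
    true_tree <- .truth_tree(pedigree, mut, samples, config$sites)
    structure(list(config = config, pedigree = pedigree,
                   recorded_pedigree = pedigree,
                   samples = samples, derived = derived, mutations = mut,
                   true_matrix = true_matrix, true_tree = true_tree,
                   error_events = data.frame(son = character(),
                                             true_father = character(),
                                             recorded_father = character(),
                                             stringsAsFactors = FALSE)),
              class = "msy_sim")
  })
}

#' @export
print.msy_sim <- function(x, ...) {
  cat(sprintf("msy_sim: %d generations, %d founders, %d sampled males, %d segregating sites\n",
              x$config$generations, x$config$founders, length(x$samples),
              length(unique(unlist(x$derived[x$samples])))))
  if (nrow(x$error_events))
    cat(sprintf("  recorded pedigree carries %d paternity error(s)\n",
                nrow(x$error_events)))
  invisible(x)
}

.site_ids <- function(nsites) sprintf("v%04d", seq_len(nsites))

.truth_matrix <- function(samples, derived, nsites) {
  ids <- .site_ids(nsites)
  all_samples <- c(samples, "OUT")
  m <- matrix(0L, length(all_samples), nsites,
              dimnames = list(all_samples, ids))
  for (s in samples) m[s, derived[[s]]] <- 1L
  sites <- data.frame(site_id = ids, position = seq_len(nsites),
                      var_class = "SNV", ref_allele = "A", alt_alleles = "G",
                      ancestral_state = "reference", stringsAsFactors = FALSE)
  call_matrix(m, sites, outgroup_ids = "OUT", polarized = TRUE)
}

# true haplotype tree built directly from the transmission genealogy and
# mutation events (independent of the laminar-set reconstruction used by
# build_tree): prune lineages without sampled descendants, merge
# zero-mutation transmissions, contract unary unsampled chains
.truth_tree <- function(pedigree, mut, samples, nsites) {
  ids <- .site_ids(nsites)
  father <- setNames(pedigree$father, pedigree$id)
  keep <- unique(unlist(lapply(samples, function(s) {
    chain <- s
    while (!is.na(father[chain[1]])) chain <- c(father[chain[1]], chain)
    chain
  })))
  # node bookkeeping on pedigree ids plus a synthetic root
  parent <- setNames(ifelse(is.na(father[keep]), "ROOT", father[keep]), keep)
  edge <- lapply(keep, function(k) ids[mut[[k]]])
  names(edge) <- keep
  members <- setNames(vector("list", length(keep)), keep)
  for (s in samples) members[[s]] <- c(members[[s]], s)
  nodes <- c("ROOT", keep)
  parent <- c(setNames(NA_character_, "ROOT"), parent)
  edge$ROOT <- character()
  members$ROOT <- character()
  is_sampled <- setNames(nodes %in% samples, nodes)

  children_of <- function(v) nodes[!is.na(parent[nodes]) & parent[nodes] == v]
  # (1) merge zero-mutation edges upward
  repeat {
    merged <- FALSE
    for (v in setdiff(nodes, "ROOT")) {
      if (length(edge[[v]]) == 0L) {
        p <- parent[v]
        for (ch in children_of(v)) parent[ch] <- p
        members[[p]] <- c(members[[p]], members[[v]])
        nodes <- setdiff(nodes, v)
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  # (2) contract unary memberless chains, merging edge site sets
  repeat {
    done <- TRUE
    for (v in setdiff(nodes, "ROOT")) {
      ch <- children_of(v)
      if (length(ch) == 1L && length(members[[v]]) == 0L) {
        edge[[ch]] <- sort(c(edge[[v]], edge[[ch]]))
        parent[ch] <- parent[v]
        nodes <- setdiff(nodes, v)
        done <- FALSE
        break
      }
    }
    if (done) break
  }
  # deterministic ids: BFS, children by smallest member sample index
  min_desc <- function(v) {
    mem <- unlist(lapply(c(v, .desc(v)), function(w) members[[w]]))
    if (!length(mem)) Inf else min(match(mem, samples))
  }
  .desc <- function(v) {
    out <- character(); q <- children_of(v)
    while (length(q)) { cur <- q[1]; q <- q[-1]; out <- c(out, cur); q <- c(q, children_of(cur)) }
    out
  }
  order_nodes <- "ROOT"
  q <- children_of("ROOT")
  q <- q[order(vapply(q, min_desc, 1))]
  while (length(q)) {
    cur <- q[1]; q <- q[-1]
    order_nodes <- c(order_nodes, cur)
    ch <- children_of(cur)
    q <- c(q, ch[order(vapply(ch, min_desc, 1))])
  }
  idx <- setNames(seq_along(order_nodes), order_nodes)
  n <- length(order_nodes)
  depth <- integer(n)
  par_i <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    v <- order_nodes[i]
    if (!is.na(parent[v])) {
      par_i[i] <- idx[[parent[v]]]
      depth[i] <- depth[par_i[i]] + 1L
    }
  }
  nd <- data.frame(node_id = seq_len(n), parent = par_i, depth = depth,
                   label = NA_character_,
                   n_members = vapply(order_nodes, function(v) length(members[[v]]), 1L),
                   stringsAsFactors = FALSE)
  structure(list(nodes = nd,
                 members = lapply(order_nodes, function(v) members[[v]]),
                 edge_sites = lapply(order_nodes, function(v) edge[[v]]),
                 samples = samples, root = 1L),
            class = "haplotype_tree")
}

#' Overlay genotyping noise on the true call matrix
#'
#' Each ingroup call independently becomes missing (probability
#' `missing_rate`) or a heterozygous artifact (`het_artifact_rate`); depth
#' and quality fields are drawn such that clean calls pass and degraded
#' calls violate the default [filter_config()] thresholds. The outgroup is
#' never degraded. The result is unpolarized (reference = ancestral), as
#' produced by a variant caller.
#'
#' @param truth an `msy_sim`
#' @param config a [sim_config] (defaults to the one inside `truth`)
#' @return A [call_matrix] with depth/quality metadata.
#' @export
degrade_calls <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "msy_sim"))
  x <- truth$true_matrix
  with_seed(config$seed + 1103L, {
    n <- length(x$samples); p <- nrow(x$sites)
    depth <- matrix(3L + stats::rpois(n * p, 12), n, p)
    qual <- matrix(5L + stats::rpois(n * p, 45), n, p)
    dimnames(depth) <- dimnames(qual) <- dimnames(x$calls)
    ig <- ingroup_samples(x)
    u <- matrix(stats::runif(length(ig) * p), length(ig), p)
    miss <- u < config$missing_rate
    het <- !miss & u < config$missing_rate + config$het_artifact_rate
    calls <- x$calls
    calls[ig, ][miss] <- NA_integer_
    calls[ig, ][het] <- HET_CODE
    dsub <- depth[ig, , drop = FALSE]; qsub <- qual[ig, , drop = FALSE]
    nbad <- sum(miss)
    dsub[miss] <- sample(0:2, nbad, replace = TRUE)
    qsub[miss] <- sample(0:4, nbad, replace = TRUE)
    nhet <- sum(het)
    dsub[het] <- sample(0:2, nhet, replace = TRUE)
    qsub[het] <- sample(0:4, nhet, replace = TRUE)
    depth[ig, ] <- dsub; qual[ig, ] <- qsub
    x$calls <- calls
    x$depth <- depth
    x$quality <- qual
    x$polarized <- FALSE
    x$sites$ancestral_state <- "unknown"
    x
  })
}

#' Perturb the recorded pedigree with paternity errors
#'
#' Each recorded father link is independently replaced, with probability
#' `paternity_error_rate`, by a different male of the father's generation;
#' transmissions with no alternative father available are skipped (and
#' counted). All events are logged in `error_events`.
#'
#' @param truth an `msy_sim`
#' @param config a [sim_config] (defaults to the one inside `truth`)
#' @return The `msy_sim` with `recorded_pedigree` and `error_events` updated.
#' @export
perturb_pedigree <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "msy_sim"))
  with_seed(config$seed + 2927L, {
    ped <- truth$pedigree
    rec <- ped$father
    events <- list(); skipped <- 0L
    by_gen <- split(ped$id, ped$generation)
    for (i in seq_len(nrow(ped))) {
      if (is.na(ped$father[i])) next
      if (stats::runif(1) >= config$paternity_error_rate) next
      fgen <- ped$generation[i] - 1L
      alternatives <- setdiff(by_gen[[as.character(fgen)]], ped$father[i])
      if (!length(alternatives)) { skipped <- skipped + 1L; next }
      newf <- if (length(alternatives) == 1L) alternatives else sample(alternatives, 1L)
      rec[i] <- newf
      events[[length(events) + 1L]] <- data.frame(
        son = ped$id[i], true_father = ped$father[i], recorded_father = newf,
        stringsAsFactors = FALSE)
    }
    truth$recorded_pedigree <- transform(ped, father = rec)
    truth$error_events <- if (length(events)) do.call(rbind, events) else
      data.frame(son = character(), true_father = character(),
                 recorded_father = character(), stringsAsFactors = FALSE)
    if (skipped) message(sprintf("%d transmission(s) had no alternative father; left intact", skipped))
    truth
  })
}

#' Haplogroup rules derived from the true tree
#'
#' Emulates "previously described haplogroup-determining variants": one rule
#' per node at the requested depth of the true tree, requiring that node's
#' root-path sites derived and the sister clades' subtending sites ancestral.
#'
#' @param truth an `msy_sim`
#' @param depth tree depth of the haplogroup-defining nodes (1 = children of
#'   the root)
#' @return list of [hg_rule] objects
#' @export
sim_haplogroup_rules <- function(truth, depth = 1) {
  tree <- truth$true_tree
  nodes <- tree$nodes$node_id[tree$nodes$depth == depth]
  if (!length(nodes)) .stopf("true tree has no nodes at depth %d", depth)
  lapply(nodes, function(v) {
    others <- setdiff(nodes, v)
    hg_rule(sprintf("HG%d", v),
            derived = node_derived_sites(tree, v),
            ancestral = unlist(lapply(others, function(w) tree$edge_sites[[w]])))
  })
}

#' Ground-truth sample grouping
#'
#' @param truth an `msy_sim`
#' @param level `"haplotype"` (samples sharing a true haplotype) or
#'   `"clade"` (samples sharing the depth-1 true clade)
#' @return named character vector `sample -> group`
#' @export
sim_groups <- function(truth, level = c("haplotype", "clade")) {
  level <- match.arg(level)
  tree <- truth$true_tree
  out <- setNames(rep("unassigned", length(truth$samples)), truth$samples)
  if (level == "haplotype") {
    for (v in tree$nodes$node_id) {
      mem <- tree$members[[v]]
      if (length(mem)) out[mem] <- sprintf("HT%d", v)
    }
  } else {
    tops <- tree_children(tree, tree$root)
    out[tree$members[[tree$root]]] <- "basal"
    for (v in tops) {
      mem <- unlist(tree$members[tree_descendants(tree, v)])
      if (length(mem)) out[mem] <- sprintf("HG%d", v)
    }
  }
  out
}

#' Tail-male lines implied by a (recorded) pedigree
#'
#' @param truth an `msy_sim`
#' @param recorded use the recorded (possibly perturbed) pedigree rather
#'   than the true one
#' @param line_generation generation whose males act as foundation sires
#' @return list of `tail_male_line` objects, one per sampled male
#' @export
recorded_lines <- function(truth, recorded = TRUE, line_generation = 1) {
  ped <- if (recorded) truth$recorded_pedigree else truth$pedigree
  father <- setNames(ped$father, ped$id)
  gen <- setNames(ped$generation, ped$id)
  lapply(truth$samples, function(s) {
    chain <- s
    while (!is.na(father[chain[length(chain)]]) &&
           gen[chain[length(chain)]] > line_generation)
      chain <- c(chain, father[chain[length(chain)]])
    parse_tail_male(paste(chain[-1], collapse = " > "), sample = s)
  })
}
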