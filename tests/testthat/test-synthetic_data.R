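# forward simulator: limits, determinism, noise overlay, pedigree errors,
# and end-to-end recovery of the recoverable truth

test_that("mutation-free and saturated limits behave as expected", {
  still <- simulate_patrilines(sim_config(generations = 4, founders = 2,
                                          mu = 0, sites = 10, seed = 1))
  expect_equal(nrow(still$true_tree$nodes), 1L)
  expect_setequal(still$true_tree$members[[1]], still$samples)

  hot <- simulate_patrilines(sim_config(generations = 3, founders = 1,
                                        mu = 8, sites = 2000,
                                        offspring_lambda = 2, seed = 2))
  n_ht <- sum(hot$true_tree$nodes$n_members > 0)
  expect_equal(n_ht, length(hot$samples))  # every transmission mutated

  expect_error(simulate_patrilines(sim_config(generations = 4, founders = 2,
                                              mu = 5, sites = 6, seed = 3)),
               "increase sites")
})

test_that("simulation configs round-trip through key:value files", {
  cfg <- sim_config(generations = 7, founders = 4, mu = 0.25, sites = 123,
                    popular_sire = TRUE, seed = 31)
  f <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  back <- read_sim_config(f)
  expect_identical(back, cfg)
  writeLines(c("generations: 3", "bogus_knob: 1"), f)
  expect_error(read_sim_config(f), "unknown simulation config key")
})

test_that("everything is bit-identical under a fixed seed", {
  cfg <- sim_config(generations = 5, founders = 3, mu = 0.4, sites = 300,
                    missing_rate = 0.1, het_artifact_rate = 0.02,
                    paternity_error_rate = 0.2, seed = 77)
  a <- suppressMessages(perturb_pedigree(simulate_patrilines(cfg)))
  b <- suppressMessages(perturb_pedigree(simulate_patrilines(cfg)))
  expect_identical(a$pedigree, b$pedigree)
  expect_identical(a$true_matrix$calls, b$true_matrix$calls)
  expect_identical(a$recorded_pedigree, b$recorded_pedigree)
  expect_identical(a$error_events, b$error_events)
  expect_identical(degrade_calls(a)$calls, degrade_calls(b)$calls)
  # the caller's RNG stream is untouched
  set.seed(5); before <- runif(1)
  invisible(simulate_patrilines(cfg))
  set.seed(5)
  expect_identical(runif(1), before)
})

test_that("degradation hits the requested rates and spares the outgroup", {
  truth <- simulate_patrilines(sim_config(generations = 5, founders = 3,
                                          mu = 0.3, sites = 400, seed = 8))
  cfg <- truth$config

  cfg$missing_rate <- 0; cfg$het_artifact_rate <- 0
  clean <- degrade_calls(truth, cfg)
  expect_identical(clean$calls, truth$true_matrix$calls)

  cfg$missing_rate <- 1
  allmiss <- degrade_calls(truth, cfg)
  expect_true(all(is.na(allmiss$calls[truth$samples, ])))
  expect_false(anyNA(allmiss$calls["OUT", ]))

  cfg$missing_rate <- 0.1; cfg$het_artifact_rate <- 0
  deg <- degrade_calls(truth, cfg)
  n <- length(truth$samples) * nrow(deg$sites)
  frac <- sum(is.na(deg$calls[truth$samples, ])) / n
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(frac - 0.1), 3 * se)
  # flagged calls violate the default thresholds; clean calls pass
  flagged <- is.na(deg$calls[truth$samples, ])
  expect_true(all(deg$depth[truth$samples, ][flagged] < 3 |
                    deg$quality[truth$samples, ][flagged] < 5))
  expect_true(all(deg$depth[truth$samples, ][!flagged] >= 3 &
                    deg$quality[truth$samples, ][!flagged] >= 5))
})

test_that("pedigree perturbation respects its rate and logs every event", {
  truth <- simulate_patrilines(sim_config(generations = 4, founders = 3,
                                          mu = 0.2, sites = 200, seed = 12))
  cfg <- truth$config
  cfg$paternity_error_rate <- 0
  none <- perturb_pedigree(truth, cfg)
  expect_identical(none$recorded_pedigree, none$pedigree)
  expect_equal(nrow(none$error_events), 0L)

  cfg$paternity_error_rate <- 1
  all_err <- suppressMessages(perturb_pedigree(truth, cfg))
  ped <- all_err$pedigree; rec <- all_err$recorded_pedigree
  gen_sizes <- table(ped$generation)
  for (i in seq_len(nrow(ped))) {
    if (is.na(ped$father[i])) next
    if (gen_sizes[[as.character(ped$generation[i] - 1L)]] >= 2)
      expect_false(identical(rec$father[i], ped$father[i]))
  }
  # recorded differs from true exactly at the logged events
  changed <- which(rec$father != ped$father)
  expect_setequal(ped$id[changed], all_err$error_events$son)
  expect_identical(all_err$error_events$true_father,
                   ped$father[match(all_err$error_events$son, ped$id)])
})

test_that("pairwise haplotype differences match the transmission-distance expectation", {
  mu <- 0.3
  exp_sum <- 0; obs_sum <- 0
  for (seed in 1:60) {
    truth <- simulate_patrilines(sim_config(generations = 5, founders = 3,
                                            mu = mu, sites = 600, seed = seed))
    ped <- truth$pedigree
    father <- setNames(ped$father, ped$id)
    lineage <- function(s) {
      ch <- s
      while (!is.na(father[ch[1]])) ch <- c(father[ch[1]], ch)
      ch
    }
    groups <- split(truth$samples,
                    vapply(truth$samples, function(s) lineage(s)[1], ""))
    for (g in groups) {
      if (length(g) < 2) next
      for (i in seq_len(length(g) - 1)) for (j in (i + 1):length(g)) {
        li <- lineage(g[i]); lj <- lineage(g[j])
        shared <- sum(li %in% lj)     # transmissions to the common ancestor
        d <- (length(li) - shared) + (length(lj) - shared)
        exp_sum <- exp_sum + mu * d   # brute-force expectation over the pedigree
        obs_sum <- obs_sum + sum(truth$true_matrix$calls[g[i], ] !=
                                   truth$true_matrix$calls[g[j], ])
      }
    }
  }
  expect_gt(exp_sum, 500)
  expect_lt(abs(obs_sum - exp_sum) / exp_sum, 0.15)
})

test_that("the pipeline recovers the recoverable truth from degraded data", {
  n_ok_clean <- 0L
  for (seed in 401:410) {
    truth <- simulate_patrilines(sim_config(generations = 5, founders = 3,
                                            mu = 0.4, sites = 400,
                                            missing_rate = 0,
                                            het_artifact_rate = 0, seed = seed))
    deg <- degrade_calls(truth)
    x <- polarize(filter_variants(deg)$matrix, "OUT")
    res <- build_tree(x)
    if (identical(tree_signature(res$tree), tree_signature(truth$true_tree)))
      n_ok_clean <- n_ok_clean + 1L
  }
  expect_equal(n_ok_clean, 10L)  # no noise: full truth, every replicate

  n_ok <- 0L; n_rep <- 15L
  for (seed in 501:(500 + n_rep)) {
    truth <- simulate_patrilines(sim_config(generations = 5, founders = 3,
                                            mu = 0.4, sites = 400,
                                            missing_rate = 0.08,
                                            het_artifact_rate = 0.01,
                                            seed = seed))
    deg <- degrade_calls(truth)
    fil <- filter_variants(deg)
    x <- polarize(fil$matrix, "OUT")
    imp <- impute_by_group(x, sim_groups(truth, "haplotype"))
    res <- suppressWarnings(build_tree(imp$matrix))

    # oracle: which sites retain evidence after the mask? computed straight
    # from the mask and the filter thresholds, independent of the pipeline
    flagged <- is.na(deg$calls) | deg$calls == -1L
    frac <- colMeans(flagged)
    called <- colMeans(!is.na(deg$calls))
    survives <- frac <= 0.10 & called >= 0.75
    groups <- sim_groups(truth, "haplotype")
    residual <- vapply(seq_len(ncol(deg$calls)), function(j) {
      any(vapply(split(truth$samples, groups[truth$samples]),
                 function(mem) all(flagged[mem, j]), TRUE))
    }, TRUE)
    keep <- deg$sites$site_id[survives & !residual]
    want <- restrict_tree(truth$true_tree, keep)
    if (identical(tree_signature(res$tree), tree_signature(want)))
      n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / n_rep, 0.95)
})
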