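# loading, ascertainment filtering and outgroup polarization

test_that("loading rejects degenerate inputs and parses genotype symbols", {
  f <- tempfile(fileext = ".tsv")
  writeLines("site_id\tposition\tvar_class\tref_allele\talt_alleles\tS1", f)
  expect_error(load_call_matrix(f), f, fixed = TRUE)

  writeLines(c("site_id\tposition\tvar_class\tref_allele\talt_alleles\tS1\tS2\tS3",
               "sA\t10\tSNV\tA\tG\t0\t1\t./.",
               "sB\t20\tSNV\tC\tT\t0/0\t1|1\t0/1"), f)
  m <- load_call_matrix(f)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(sum(is.na(m$calls)), 1L)           # exactly one missing call
  expect_identical(m$calls["S3", "sA"], NA_integer_)
  expect_identical(m$calls["S1", "sB"], 0L)       # 0/0 accepted as haploid 0
  expect_identical(m$calls["S2", "sB"], 1L)       # 1|1 accepted as haploid 1
  expect_identical(m$calls["S3", "sB"], -1L)      # 0/1 is a haploid artifact

  writeLines(c("site_id\tposition\tvar_class\tref_allele\talt_alleles\tS1\tS1",
               "sA\t10\tSNV\tA\tG\t0\t1"), f)
  expect_error(load_call_matrix(f), "duplicate sample")

  expect_error(call_matrix(matrix(0L, 2, 0, dimnames = list(c("S1", "S2"), NULL)),
                           data.frame(site_id = character(), position = integer(),
                                      var_class = character(), ref_allele = character(),
                                      alt_alleles = character())),
               "zero sites")
})

test_that("VCF and matrix dialects round-trip call states exactly", {
  truth <- simulate_patrilines(sim_config(generations = 4, founders = 2,
                                          sites = 150, mu = 1,
                                          missing_rate = 0.05, seed = 42))
  deg <- degrade_calls(truth)
  stopifnot(length(deg$samples) >= 10)

  vcf <- tempfile(fileext = ".vcf")
  write_vcf(deg, vcf)
  back <- load_call_matrix(vcf, outgroup = "OUT")
  expect_identical(back$calls, deg$calls)
  expect_identical(back$depth, deg$depth)
  expect_identical(back$quality, deg$quality)
  expect_identical(back$sites$site_id, deg$sites$site_id)

  tsv <- tempfile(fileext = ".tsv")
  write_call_matrix(deg, tsv)
  back2 <- load_call_matrix(tsv, outgroup = "OUT")
  expect_identical(back2$calls, deg$calls)       # states survive; no metadata
  expect_null(back2$depth)
})

test_that("each filter rule fires exactly where the independent scan says", {
  # 10 samples, one site with depth 2 in 2 of them (20% > 10%)
  st <- matrix(1L, 10, 2, dimnames = list(paste0("S", 1:10), c("bad", "ok")))
  st[, 2] <- rep(c(0L, 1L), 5)
  dp <- matrix(30L, 10, 2, dimnames = dimnames(st)); dp[1:2, 1] <- 2L
  gq <- matrix(99L, 10, 2, dimnames = dimnames(st))
  st[1, 1] <- 0L                                   # not a reference error
  x <- toy_matrix(st, depth = dp, quality = gq)
  fr <- filter_variants(x)
  expect_equal(fr$report$site_id, "bad")
  expect_match(fr$report$reasons, "low_quality_fraction")

  # called in 7 of 10 samples (70% < 75%)
  st2 <- matrix(0L, 10, 2, dimnames = list(paste0("S", 1:10), c("thin", "ok")))
  st2[1:3, 1] <- NA; st2[c(1, 3, 5), 2] <- 1L
  fr2 <- filter_variants(toy_matrix(st2))
  expect_equal(fr2$report$site_id, "thin")
  expect_match(fr2$report$reasons, "call_rate")

  # seeded 20 x 100 matrix with planted violations of every rule
  set.seed(2024)
  st3 <- matrix(sample(0:1, 20 * 100, replace = TRUE, prob = c(.8, .2)), 20, 100,
                dimnames = list(paste0("S", 1:20), sprintf("v%03d", 1:100)))
  dp3 <- matrix(30L, 20, 100, dimnames = dimnames(st3))
  gq3 <- matrix(99L, 20, 100, dimnames = dimnames(st3))
  dp3[1:5, 3] <- 1L                               # low depth in 25%
  gq3[6:9, 7] <- 2L                               # low quality in 20%
  st3[1:8, 11] <- NA                              # 60% call rate
  st3[, 13] <- c(rep(-1L, 12), rep(NA, 8))        # heterozygous-only
  st3[, 17] <- 1L                                 # all-alternative: reference error
  x3 <- toy_matrix(st3, depth = dp3, quality = gq3)
  x3$sites$alt_alleles[23] <- "G,T"               # multi-allelic
  fr3 <- filter_variants(x3)
  expect_setequal(fr3$report$site_id, brute_force_filter_scan(x3))
  expect_true(all(c("v003", "v007", "v011", "v013", "v017", "v023")
                  %in% fr3$report$site_id))
  # removed + retained partitions the input; every removed site has a reason
  expect_equal(nrow(fr3$report) + nrow(fr3$matrix$sites), nrow(x3$sites))
  expect_true(all(nzchar(fr3$report$reasons)))
  # contractive and idempotent
  expect_true(all(fr3$matrix$sites$site_id %in% x3$sites$site_id))
  fr4 <- filter_variants(fr3$matrix)
  expect_equal(nrow(fr4$report), 0L)
  expect_identical(fr4$matrix$calls, fr3$matrix$calls)
  # surviving artifacts demoted to missing
  expect_false(any(fr3$matrix$calls == -1L, na.rm = TRUE))
})

test_that("polarization is outgroup-relative and an involution under allele flip", {
  st <- rbind(S1 = c(0L, 1L, 0L), S2 = c(1L, 1L, 0L), OUT = c(0L, 0L, 0L))
  colnames(st) <- c("a", "b", "c")
  x <- toy_matrix(st, outgroup = "OUT")
  pol <- polarize(x, "OUT")
  # outgroup carries the reference everywhere: polarized == raw coding
  expect_identical(pol$calls, x$calls)
  expect_true(all(pol$sites$ancestral_state == "reference"))

  # flip the outgroup allele at site b: ancestral/derived swap exactly there
  x2 <- x; x2$calls["OUT", "b"] <- 1L
  pol2 <- polarize(x2, "OUT")
  expect_identical(pol2$calls[c("S1", "S2"), "b"], 1L - pol$calls[c("S1", "S2"), "b"])
  expect_identical(pol2$calls[, c("a", "c")], pol$calls[, c("a", "c")])
  expect_equal(pol2$sites$ancestral_state, c("reference", "alternative", "reference"))

  # outgroup missing -> unknown ancestral state, flagged out of tree building
  x3 <- x; x3$calls["OUT", "c"] <- NA
  pol3 <- polarize(x3, "OUT")
  expect_equal(pol3$sites$ancestral_state[3], "unknown")

  expect_error(polarize(x, "S1"), "outgroup")
  expect_error(polarize(x, "nope"), "absent")

  # error-free simulated data: polarization recovers every true ancestral state
  truth <- simulate_patrilines(sim_config(generations = 4, founders = 2,
                                          sites = 80, mu = 1, seed = 5))
  cfg0 <- truth$config
  cfg0$missing_rate <- 0; cfg0$het_artifact_rate <- 0
  deg <- degrade_calls(truth, cfg0)
  pol4 <- polarize(deg, "OUT")
  expect_identical(pol4$calls, truth$true_matrix$calls)
  expect_true(all(pol4$sites$ancestral_state == "reference"))
})
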