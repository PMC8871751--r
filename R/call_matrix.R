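# Haploid sample x variant call matrices for the male-specific Y (MSY).
#
# Internal genotype coding in the `calls` integer matrix:
#   0, 1, 2, ...  allele index (0 = reference before polarization;
#                 0 = ancestral / 1 = derived once polarized)
#   -1            heterozygous artifact (impossible on a haploid locus,
#                 kept only until filtering demotes it)
#   NA            missing

HET_CODE <- -1L

#' Construct a haploid call matrix
#'
#' Container for haploid sample-by-variant genotype calls with optional
#' per-call read depth and genotype quality, used throughout the MSY
#' lineage-tracing pipeline.
#'
#' @param calls integer matrix (samples x sites); allele index per call,
#'   `-1` for a heterozygous artifact, `NA` for missing.
#' @param sites data.frame with columns `site_id`, `position`, `var_class`
#'   (one of `"SNV"`, `"indel"`, `"STR"`), `ref_allele`, `alt_alleles`
#'   (comma-separated string) and optionally `ancestral_state`.
#' @param samples character vector of sample identifiers (defaults to
#'   `rownames(calls)`).
#' @param outgroup_ids samples to treat as outgroups (must be a subset of
#'   `samples`).
#' @param depth,quality optional integer matrices of identical shape; when
#'   `NULL` (e.g. plain-matrix dialects without read-level metadata) every
#'   call is treated as passing the depth/quality thresholds.
#' @param polarized logical; `TRUE` once calls are coded ancestral/derived.
#' @return An object of class `call_matrix`.
#' @export
call_matrix <- function(calls, sites, samples = rownames(calls),
                        outgroup_ids = character(), depth = NULL,
                        quality = NULL, polarized = FALSE) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) .stopf("sample identifiers are required")
  samples <- as.character(samples)
  if (anyDuplicated(samples))
    .stopf("duplicate sample ID: %s", samples[duplicated(samples)][1])
  if (!is.data.frame(sites) || nrow(sites) == 0L)
    .stopf("zero sites: a call matrix needs at least one variant site")
  need <- c("site_id", "position", "var_class", "ref_allele", "alt_alleles")
  miss <- setdiff(need, names(sites))
  if (length(miss)) .stopf("sites table lacks column(s): %s", paste(miss, collapse = ", "))
  sites$site_id <- as.character(sites$site_id)
  if (anyDuplicated(sites$site_id))
    .stopf("duplicate site_id: %s", sites$site_id[duplicated(sites$site_id)][1])
  if (is.null(sites$ancestral_state)) sites$ancestral_state <- "unknown"
  if (nrow(calls) != length(samples) || ncol(calls) != nrow(sites))
    .stopf("calls grid is %d x %d but there are %d samples and %d sites",
           nrow(calls), ncol(calls), length(samples), nrow(sites))
  if (!all(outgroup_ids %in% samples))
    .stopf("outgroup id(s) not among samples: %s",
           paste(setdiff(outgroup_ids, samples), collapse = ", "))
  dimnames(calls) <- list(samples, sites$site_id)
  for (nm in c("depth", "quality")) {
    m <- get(nm)
    if (!is.null(m)) {
      m <- as.matrix(m); storage.mode(m) <- "integer"
      if (!all(dim(m) == dim(calls))) .stopf("%s matrix dimensions differ from calls", nm)
      dimnames(m) <- dimnames(calls)
      assign(nm, m)
    }
  }
  rownames(sites) <- NULL
  structure(list(samples = samples, sites = sites, calls = calls,
                 depth = depth, quality = quality,
                 outgroup_ids = as.character(outgroup_ids),
                 polarized = isTRUE(polarized)),
            class = "call_matrix")
}

#' @export
print.call_matrix <- function(x, ...) {
  cat(sprintf("call_matrix: %d samples x %d sites (%s)\n",
              length(x$samples), nrow(x$sites),
              if (x$polarized) "polarized" else "unpolarized"))
  if (length(x$outgroup_ids))
    cat("  outgroups:", paste(x$outgroup_ids, collapse = ", "), "\n")
  nm <- sum(is.na(x$calls))
  cat(sprintf("  missing calls: %d (%.1f%%)\n", nm, 100 * nm / length(x$calls)))
  invisible(x)
}

#' @export
dim.call_matrix <- function(x) dim(x$calls)

ingroup_samples <- function(x) setdiff(x$samples, x$outgroup_ids)

ingroup_calls <- function(x) x$calls[ingroup_samples(x), , drop = FALSE]

# keep a subset of sites (by index), preserving all parallel structures
subset_sites <- function(x, keep) {
  x$sites <- x$sites[keep, , drop = FALSE]
  rownames(x$sites) <- NULL
  x$calls <- x$calls[, keep, drop = FALSE]
  if (!is.null(x$depth)) x$depth <- x$depth[, keep, drop = FALSE]
  if (!is.null(x$quality)) x$quality <- x$quality[, keep, drop = FALSE]
  x
}

# ---------------------------------------------------------------------------
# loading / writing

.parse_gt <- function(gt) {
  # haploid "0"/"1", diploid-style "0/0", "1|1" accepted; "0/1" is a
  # heterozygous artifact; anything unparseable becomes missing
  out <- rep(NA_integer_, length(gt))
  gt <- sub(":.*$", "", gt)
  gt[is.na(gt)] <- "."
  hap <- grepl("^[0-9]+$", gt)
  out[hap] <- as.integer(gt[hap])
  dip <- grepl("^[0-9]+[/|][0-9]+$", gt)
  if (any(dip)) {
    a1 <- as.integer(sub("[/|].*$", "", gt[dip]))
    a2 <- as.integer(sub("^.*[/|]", "", gt[dip]))
    out[dip] <- ifelse(a1 == a2, a1, HET_CODE)
  }
  out
}

#' Load a haploid call matrix from VCF or a delimited site-by-sample table
#'
#' @param source path to a VCF file (plain or gzipped) or a tab-delimited
#'   matrix with rows = sites, columns = samples, `"."` for missing calls
#'   and leading columns `site_id`, `position`, `var_class`, `ref_allele`,
#'   `alt_alleles`.
#' @param dialect `"auto"` (by file extension), `"vcf"` or `"matrix"`.
#' @param outgroup sample identifiers to mark as outgroups.
#' @return A [call_matrix]. VCF `DP` and `GQ` FORMAT keys are honoured;
#'   the plain matrix dialect carries no read-level metadata and all its
#'   calls are treated as passing depth/quality thresholds.
#' @export
load_call_matrix <- function(source, dialect = c("auto", "vcf", "matrix"),
                             outgroup = character()) {
  dialect <- match.arg(dialect)
  if (!file.exists(source)) .stopf("file not found: %s", source)
  if (dialect == "auto")
    dialect <- if (grepl("\\.vcf(\\.gz)?$", source)) "vcf" else "matrix"
  if (dialect == "vcf") .load_vcf(source, outgroup) else .load_matrix(source, outgroup)
}

.load_vcf <- function(path, outgroup) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0L)
    .stopf("empty site list in VCF file: %s", path)
  id <- fix[, "ID"]
  id[is.na(id) | id == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(id) | id == "."]
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  alt[is.na(alt)] <- ""
  var_class <- ifelse(nchar(ref) == 1L &
                        vapply(strsplit(alt, ","), function(a) all(nchar(a) == 1L), TRUE),
                      "SNV", "indel")
  sites <- data.frame(site_id = id, position = as.integer(fix[, "POS"]),
                      var_class = var_class, ref_allele = ref, alt_alleles = alt,
                      stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L) .stopf("VCF has no sample genotypes: %s", path)
  samples <- colnames(gt)
  if (anyDuplicated(samples))
    .stopf("duplicate sample ID: %s", samples[duplicated(samples)][1])
  calls <- apply(gt, 2L, .parse_gt)
  calls <- matrix(as.integer(calls), nrow = nrow(gt),
                  dimnames = list(NULL, samples))
  grab <- function(key) {
    m <- tryCatch(vcfR::extract.gt(v, element = key, as.numeric = TRUE),
                  error = function(e) NULL)
    if (is.null(m)) return(NULL)
    m <- matrix(as.integer(round(m)), nrow = nrow(m), dimnames = dimnames(m))
    t(m)
  }
  dp <- grab("DP"); gq <- grab("GQ")
  call_matrix(t(calls), sites, samples = samples, outgroup_ids = outgroup,
              depth = dp, quality = gq)
}

.load_matrix <- function(path, outgroup) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  lead <- c("site_id", "position", "var_class", "ref_allele", "alt_alleles")
  miss <- setdiff(lead, names(tab))
  if (length(miss))
    .stopf("matrix dialect needs leading column(s) %s in %s",
           paste(miss, collapse = ", "), path)
  if (nrow(tab) == 0L) .stopf("empty site list in file: %s", path)
  samples <- names(tab)[!names(tab) %in% lead]
  if (length(samples) == 0L) .stopf("no sample columns in %s", path)
  if (anyDuplicated(samples))
    .stopf("duplicate sample ID: %s", samples[duplicated(samples)][1])
  sites <- data.frame(site_id = tab$site_id, position = as.integer(tab$position),
                      var_class = tab$var_class, ref_allele = tab$ref_allele,
                      alt_alleles = tab$alt_alleles, stringsAsFactors = FALSE)
  cell <- as.matrix(tab[, samples, drop = FALSE])
  calls <- apply(cell, 2L, .parse_gt)
  calls <- matrix(as.integer(calls), nrow = nrow(tab), dimnames = list(NULL, samples))
  call_matrix(t(calls), sites, samples = samples, outgroup_ids = outgroup)
}

#' Write a call matrix in the delimited site-by-sample dialect
#'
#' @param x a [call_matrix]
#' @param path output path (tab-delimited; `"."` marks missing calls,
#'   `"0/1"` a heterozygous artifact).
#' @export
write_call_matrix <- function(x, path) {
  cell <- t(x$calls)
  chr <- matrix(as.character(cell), nrow = nrow(cell))
  chr[is.na(cell)] <- "."
  chr[!is.na(cell) & cell == HET_CODE] <- "0/1"
  out <- cbind(x$sites[, c("site_id", "position", "var_class",
                           "ref_allele", "alt_alleles")],
               as.data.frame(chr, stringsAsFactors = FALSE))
  names(out) <- c("site_id", "position", "var_class", "ref_allele",
                  "alt_alleles", x$samples)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a call matrix as a minimal haploid VCF
#'
#' Emits `GT:DP:GQ` per call (haploid `0`/`1` genotypes, `0/1` for
#' heterozygous artifacts, `.` for missing); depth/quality default to
#' high passing values when the matrix carries none.
#'
#' @param x a [call_matrix]
#' @param path output path
#' @param contig contig name for the CHROM column
#' @export
write_vcf <- function(x, path, contig = "MSY") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", contig),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", x$samples), collapse = "\t")), con)
  dp <- x$depth %||% matrix(30L, nrow(x$calls), ncol(x$calls))
  gq <- x$quality %||% matrix(99L, nrow(x$calls), ncol(x$calls))
  for (j in seq_len(nrow(x$sites))) {
    g <- x$calls[, j]
    gt <- ifelse(is.na(g), ".", ifelse(g == HET_CODE, "0/1", as.character(g)))
    field <- paste(gt, dp[, j], gq[, j], sep = ":")
    writeLines(paste(c(contig, x$sites$position[j], x$sites$site_id[j],
                       x$sites$ref_allele[j],
                       ifelse(x$sites$alt_alleles[j] == "", ".", x$sites$alt_alleles[j]),
                       ".", "PASS", ".", "GT:DP:GQ", field), collapse = "\t"), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# filtering

#' Variant ascertainment filter configuration
#'
#' Defaults mirror the standard MSY ascertainment rules: a site is dropped
#' when calls with read depth < 3 or genotype quality < 5 exceed 10% of the
#' samples, or when it is called in fewer than 75% of the samples; sites that
#' are heterozygous-only, multi-allelic, or reference errors (every ingroup
#' call carries the alternative allele) are dropped as well.
#'
#' @param min_depth,min_quality per-call thresholds.
#' @param max_low_quality_fraction maximum tolerated fraction of samples with
#'   a call below either threshold.
#' @param min_call_rate minimum fraction of non-missing calls.
#' @param drop_heterozygous_only,drop_multiallelic,drop_reference_errors rule toggles.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 3, min_quality = 5,
                          max_low_quality_fraction = 0.10,
                          min_call_rate = 0.75,
                          drop_heterozygous_only = TRUE,
                          drop_multiallelic = TRUE,
                          drop_reference_errors = TRUE) {
  stopifnot(.is_count(min_depth), .is_count(min_quality),
            .is_prob(max_low_quality_fraction), .is_prob(min_call_rate))
  structure(list(min_depth = as.integer(min_depth),
                 min_quality = as.integer(min_quality),
                 max_low_quality_fraction = max_low_quality_fraction,
                 min_call_rate = min_call_rate,
                 drop_heterozygous_only = isTRUE(drop_heterozygous_only),
                 drop_multiallelic = isTRUE(drop_multiallelic),
                 drop_reference_errors = isTRUE(drop_reference_errors)),
            class = "filter_config")
}

#' Apply the variant-quality and ascertainment filters
#'
#' A site is removed when (a) the fraction of samples whose call has depth
#' below `min_depth` or quality below `min_quality` exceeds
#' `max_low_quality_fraction`, (b) its call rate falls below
#' `min_call_rate`, (c) all non-missing ingroup calls are heterozygous
#' artifacts, (d) it has more than one alternative allele, or (e) every
#' non-missing ingroup call carries the alternative allele (a reference
#' error: the reference assembly itself is the singleton). Heterozygous
#' artifacts surviving at retained sites are demoted to missing, which makes
#' the filter idempotent.
#'
#' @param x a [call_matrix]
#' @param config a [filter_config]
#' @return list with elements `matrix` (the filtered [call_matrix]) and
#'   `report` (data.frame `site_id`, `reasons`; one row per removed site).
#' @export
filter_variants <- function(x, config = filter_config()) {
  stopifnot(inherits(x, "call_matrix"), inherits(config, "filter_config"))
  ns <- length(x$samples)
  ig <- ingroup_calls(x)
  p <- nrow(x$sites)
  reasons <- vector("list", p)

  if (!is.null(x$depth) || !is.null(x$quality)) {
    dp <- x$depth %||% matrix(.Machine$integer.max, ns, p)
    gq <- x$quality %||% matrix(.Machine$integer.max, ns, p)
    bad <- (dp < config$min_depth) | (gq < config$min_quality)
    frac_bad <- colMeans(bad)
  } else frac_bad <- rep(0, p)

  call_rate <- colMeans(!is.na(x$calls))
  n_obs_ig <- colSums(!is.na(ig))
  het_only <- n_obs_ig > 0 &
    colSums(!is.na(ig) & ig == HET_CODE) == n_obs_ig
  n_allelic <- lengths(strsplit(ifelse(is.na(x$sites$alt_alleles), "",
                                       x$sites$alt_alleles), ","))
  # STR sites keep >= 2 observed length alleles prior to binarization
  multiallelic <- n_allelic > 1L & x$sites$var_class != "STR"
  alt_code <- if (x$polarized) 1L else 1L  # index >= 1 means non-reference
  ref_err <- n_obs_ig > 0 &
    colSums(!is.na(ig) & ig >= alt_code) == n_obs_ig

  for (j in seq_len(p)) {
    r <- character()
    if (frac_bad[j] > config$max_low_quality_fraction) r <- c(r, "low_quality_fraction")
    if (call_rate[j] < config$min_call_rate) r <- c(r, "call_rate")
    if (config$drop_heterozygous_only && het_only[j]) r <- c(r, "heterozygous_only")
    if (config$drop_multiallelic && multiallelic[j]) r <- c(r, "multiallelic")
    if (config$drop_reference_errors && ref_err[j]) r <- c(r, "reference_error")
    reasons[[j]] <- r
  }
  removed <- which(lengths(reasons) > 0L)
  report <- data.frame(site_id = x$sites$site_id[removed],
                       reasons = vapply(reasons[removed], paste,
                                        character(1), collapse = ","),
                       stringsAsFactors = FALSE)
  keep <- setdiff(seq_len(p), removed)
  if (length(keep)) x <- subset_sites(x, keep)
  else .stopf("all %d sites were removed by filtering", p)
  x$calls[!is.na(x$calls) & x$calls == HET_CODE] <- NA_integer_
  list(matrix = x, report = report)
}

#' Write a filter report
#' @param report the `report` element returned by [filter_variants()]
#' @param path output path (tab-delimited `site_id`, `reasons`)
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# polarization

#' Polarize alleles against an outgroup
#'
#' Sets each site's ancestral state to the allele carried by the outgroup
#' sample and recodes all calls as ancestral (0) / derived (1) relative to
#' it. Sites where the outgroup call is missing get
#' `ancestral_state = "unknown"` and are excluded from tree building unless
#' explicitly requested. STR sites are binarized as outgroup length vs any
#' other length; multistep STR evolution is not modeled.
#'
#' @param x a [call_matrix]
#' @param outgroup_id one of `x$outgroup_ids`
#' @return The polarized [call_matrix].
#' @export
polarize <- function(x, outgroup_id) {
  stopifnot(inherits(x, "call_matrix"))
  if (!outgroup_id %in% x$samples)
    .stopf("outgroup sample absent from matrix: %s", outgroup_id)
  if (!outgroup_id %in% x$outgroup_ids)
    .stopf("'%s' is not registered in outgroup_ids", outgroup_id)
  og <- x$calls[outgroup_id, ]
  known <- !is.na(og) & og != HET_CODE
  if (any(x$sites$var_class == "STR" & known))
    .warnf("STR site(s) binarized as outgroup length vs any other length; multistep STR evolution is not modeled")
  anc <- ifelse(!known, "unknown", ifelse(og == 0L, "reference", "alternative"))
  newcalls <- x$calls
  for (j in which(known)) {
    cj <- x$calls[, j]
    rec <- ifelse(is.na(cj) | cj == HET_CODE, cj, ifelse(cj == og[j], 0L, 1L))
    newcalls[, j] <- rec
  }
  x$calls <- newcalls
  x$sites$ancestral_state <- anc
  x$polarized <- TRUE
  x
}
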