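# Haplogroup assignment, within-group consensus imputation, and collapsing
# of samples into distinct MSY haplotypes.

#' Haplogroup-determining rule
#'
#' A haplogroup is recognised by the variants its members must carry in the
#' derived state and those they must carry in the ancestral state.
#'
#' @param hg_name haplogroup label (must parse under the nomenclature grammar)
#' @param derived site_ids required derived
#' @param ancestral site_ids required ancestral (disjoint from `derived`)
#' @return An `hg_rule` object.
#' @export
hg_rule <- function(hg_name, derived = character(), ancestral = character()) {
  .validate_label(hg_name)
  derived <- as.character(derived); ancestral <- as.character(ancestral)
  if (length(intersect(derived, ancestral)))
    .stopf("rule '%s': derived and ancestral site sets overlap", hg_name)
  if (!length(derived) && !length(ancestral))
    .stopf("rule '%s' names no sites", hg_name)
  structure(list(hg_name = hg_name, required_derived = derived,
                 required_ancestral = ancestral), class = "hg_rule")
}

.rule_satisfied <- function(calls_row, rule) {
  d <- calls_row[rule$required_derived]
  a <- calls_row[rule$required_ancestral]
  consistent <- all(is.na(d) | d == 1L) && all(is.na(a) | a == 0L)
  informative <- any(!is.na(c(d, a)))
  consistent && informative
}

#' Cluster samples into haplogroups by diagnostic variants
#'
#' Missing calls act as wildcards; a sample whose calls are consistent with
#' (and informative for) exactly one rule is assigned to it, a sample
#' matching no rule (including an all-missing sample) becomes
#' `"unassigned"`, and a sample satisfying two rules is an error because the
#' rules are then not mutually exclusive on this matrix.
#'
#' @param x a polarized [call_matrix]
#' @param rules list of [hg_rule] objects
#' @return Named character vector `sample -> hg_name`.
#' @export
assign_haplogroups <- function(x, rules) {
  stopifnot(inherits(x, "call_matrix"))
  if (!x$polarized) .stopf("matrix must be polarized before haplogroup assignment")
  if (!length(rules)) .stopf("no haplogroup rules supplied")
  rules <- lapply(rules, function(r) { stopifnot(inherits(r, "hg_rule")); r })
  used <- unique(unlist(lapply(rules, function(r)
    c(r$required_derived, r$required_ancestral))))
  unknown <- setdiff(used, x$sites$site_id)
  if (length(unknown)) {
    # diagnostic sites lost to upstream filtering are simply uninformative
    message(sprintf("%d rule site(s) absent from the matrix; ignored: %s",
                    length(unknown), paste(unknown, collapse = ", ")))
    rules <- lapply(rules, function(r) {
      r$required_derived <- intersect(r$required_derived, x$sites$site_id)
      r$required_ancestral <- intersect(r$required_ancestral, x$sites$site_id)
      r
    })
    rules <- rules[vapply(rules, function(r)
      length(r$required_derived) + length(r$required_ancestral) > 0L, TRUE)]
    if (!length(rules)) .stopf("no haplogroup rule retains any matrix site")
  }
  out <- setNames(rep("unassigned", length(x$samples)), x$samples)
  for (s in x$samples) {
    hits <- which(vapply(rules, function(r) .rule_satisfied(x$calls[s, ], r), TRUE))
    if (length(hits) > 1L)
      .stopf("sample '%s' satisfies multiple haplogroup rules: %s", s,
             paste(vapply(rules[hits], `[[`, "", "hg_name"), collapse = ", "))
    if (length(hits) == 1L) out[s] <- rules[[hits]]$hg_name
  }
  out
}

#' Impute missing calls by within-haplogroup consensus
#'
#' Replaces a missing call by the consensus of the sample's haplogroup at
#' that site: under `"unanimity"` only when every non-missing group member
#' agrees, under `"majority"` by strict majority (ties left missing).
#' Observed calls are never altered; unassigned samples are skipped.
#'
#' @param x a polarized [call_matrix]
#' @param groups named character vector `sample -> hg_name` (e.g. from
#'   [assign_haplogroups()]); samples mapped to `"unassigned"` are skipped.
#' @param mode `"unanimity"` (default) or `"majority"`.
#' @return list with `matrix` (imputed [call_matrix]) and `log`
#'   (data.frame `sample`, `site_id`, `filled_state`, `group`, `mode`).
#' @export
impute_by_group <- function(x, groups, mode = c("unanimity", "majority")) {
  stopifnot(inherits(x, "call_matrix"))
  mode <- match.arg(mode)
  if (mode == "majority")
    message("imputation mode 'majority': filled states follow the strict group majority, not unanimity")
  groups <- groups[names(groups) %in% x$samples]
  groups <- groups[groups != "unassigned"]
  log <- list()
  for (g in unique(groups)) {
    members <- names(groups)[groups == g]
    sub <- x$calls[members, , drop = FALSE]
    for (j in which(colSums(is.na(sub)) > 0L)) {
      obs <- sub[, j]; obs <- obs[!is.na(obs)]
      if (!length(obs)) next
      fill <- NA_integer_
      tab <- table(obs)
      if (mode == "unanimity") {
        if (length(tab) == 1L) fill <- as.integer(names(tab)[1])
      } else {
        top <- tab[tab == max(tab)]
        if (length(top) == 1L) fill <- as.integer(names(top)[1])
      }
      if (is.na(fill)) next
      holes <- members[is.na(x$calls[members, j])]
      x$calls[holes, j] <- fill
      log[[length(log) + 1L]] <- data.frame(
        sample = holes, site_id = x$sites$site_id[j],
        filled_state = fill, group = g, mode = mode,
        stringsAsFactors = FALSE)
    }
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(sample = character(), site_id = character(),
               filled_state = integer(), group = character(),
               mode = character(), stringsAsFactors = FALSE)
  list(matrix = x, log = log)
}

#' Write an imputation log
#' @param log the `log` element returned by [impute_by_group()]
#' @param path output path
#' @export
write_imputation_log <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# sites usable for haplotype construction: polarized, complete in ingroup
.usable_sites <- function(x, include_unpolarized = FALSE) {
  ig <- ingroup_calls(x)
  complete <- colSums(is.na(ig)) == 0L
  known <- if (include_unpolarized) rep(TRUE, nrow(x$sites))
           else x$sites$ancestral_state != "unknown"
  which(complete & known)
}

#' Collapse samples into distinct haplotypes
#'
#' Concatenates the allelic states of all usable sites per ingroup sample;
#' samples with identical state vectors form one haplotype. Sites with
#' residual missing calls (after imputation) are excluded from the vectors
#' and reported, as are sites with unknown ancestral state.
#'
#' @param x a polarized [call_matrix] (ideally after [impute_by_group()])
#' @return A `haplotype_set`: list of haplotypes, each with `ht_name`
#'   (unset), `state` (named 0/1 vector), `members`; the excluded site_ids
#'   are available as `attr(, "excluded_sites")`.
#' @export
build_haplotypes <- function(x) {
  stopifnot(inherits(x, "call_matrix"))
  if (!x$polarized) .stopf("matrix must be polarized before haplotype construction")
  usable <- .usable_sites(x)
  excluded <- setdiff(x$sites$site_id, x$sites$site_id[usable])
  if (length(excluded))
    message(sprintf("excluding %d site(s) with residual missingness or unknown ancestral state", length(excluded)))
  if (!length(usable)) .stopf("no usable sites remain for haplotype construction")
  ord <- usable[order(x$sites$position[usable])]
  samples <- ingroup_samples(x)
  m <- x$calls[samples, ord, drop = FALSE]
  key <- apply(m, 1L, paste, collapse = "")
  groups <- split(samples, factor(key, levels = unique(key)))
  hts <- lapply(groups, function(mem) {
    structure(list(ht_name = NA_character_,
                   state = m[mem[1], ],
                   members = mem), class = "haplotype")
  })
  names(hts) <- NULL
  structure(hts, class = "haplotype_set",
            excluded_sites = excluded,
            sites_used = x$sites$site_id[ord])
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d distinct haplotypes over %d sites\n",
              length(x), length(attr(x, "sites_used"))))
  for (h in x)
    cat(sprintf("  %s: %d member(s)\n",
                if (is.na(h$ht_name)) "<unnamed>" else h$ht_name,
                length(h$members)))
  invisible(x)
}

#' Write a haplotype table
#' @param hts a `haplotype_set` from [build_haplotypes()]
#' @param path output path (tab-delimited: name, member count, member list)
#' @export
write_haplotype_table <- function(hts, path) {
  df <- data.frame(
    ht_name = vapply(hts, function(h) if (is.na(h$ht_name)) "" else h$ht_name, ""),
    n_members = vapply(hts, function(h) length(h$members), 1L),
    members = vapply(hts, function(h) paste(h$members, collapse = ","), ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
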