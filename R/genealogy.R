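# Tail-male pedigree records, foundation-line congruence classification,
# and sire-line panel summary statistics.

#' Parse a tail-male line record
#'
#' A tail-male line is the ordered chain of paternal ancestors from the
#' most recent named ancestor of a sampled male back to the foundation
#' sire. Duplicate consecutive names are collapsed.
#'
#' @param record text, ancestors separated by `sep`
#' @param sample optional sample identifier the chain belongs to
#' @param sep separator (default `" > "`)
#' @return A `tail_male_line`: list with `sample`, `chain`,
#'   `foundation_sire` (the last chain element).
#' @export
parse_tail_male <- function(record, sample = NA_character_, sep = " > ") {
  if (length(record) != 1L || is.na(record) || !nzchar(trimws(record)))
    .stopf("empty tail-male record")
  parts <- trimws(strsplit(record, sep, fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (!length(parts)) .stopf("empty tail-male record")
  keep <- c(TRUE, parts[-1] != parts[-length(parts)])
  chain <- parts[keep]
  structure(list(sample = sample, chain = chain,
                 foundation_sire = chain[length(chain)]),
            class = "tail_male_line")
}

#' Serialize a tail-male line back to its string form
#' @param x a `tail_male_line`
#' @param sep separator
#' @export
format_tail_male <- function(x, sep = " > ") paste(x$chain, collapse = sep)

#' Read tail-male line records from a file
#'
#' One record per line: `sample<TAB>ancestor > ancestor > ... > foundation sire`.
#'
#' @param path UTF-8 text file
#' @return list of `tail_male_line` objects
#' @export
read_tail_male_lines <- function(path) {
  raw <- readLines(path, encoding = "UTF-8")
  raw <- raw[nzchar(trimws(raw))]
  lapply(raw, function(l) {
    bits <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(bits) < 2L) .stopf("expected 'sample<TAB>chain' in: %s", l)
    parse_tail_male(bits[2], sample = bits[1])
  })
}

# partition a label set into chains of mutually nested names; the number of
# chains is the number of paternally unrelated founders needed to explain
# the line
.label_chains <- function(labels) {
  labels <- unique(labels)
  labels <- labels[order(nchar(strip_asterisk(labels)), labels)]
  groups <- list()
  for (l in labels) {
    placed <- FALSE
    for (i in seq_along(groups)) {
      if (all(vapply(groups[[i]], .names_nested, TRUE, l))) {
        groups[[i]] <- c(groups[[i]], l)
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- l
  }
  groups
}

#' Classify the haplotype pattern of one foundation line
#'
#' Member haplotype labels are merged into groups in which every pair is
#' nested (ancestor-compatible; `"X*"` is compatible with any descendant of
#' X). One group with one label is `consistent`; one group with several
#' labels is `subline_consistent` — the derived labels are candidate de novo
#' subline haplotypes tied to their carrier sublines; two or more disjoint
#' groups mean at least two paternally unrelated stallions contributed and
#' the line is `incongruent`.
#'
#' @param members data.frame with columns `sample`, `ht_label`, `subline`
#'   (any extra columns are ignored; duplicated members are harmless)
#' @return list with `classification`, `distinct_hts`, `disjoint_groups`,
#'   `candidate_subline_events` (data.frame `ht_label`, `subline`).
#' @export
classify_line <- function(members) {
  stopifnot(is.data.frame(members), nrow(members) >= 1L,
            all(c("ht_label", "subline") %in% names(members)))
  for (l in unique(members$ht_label)) .validate_label(l)
  labels <- sort(unique(members$ht_label))
  groups <- .label_chains(labels)
  classification <- if (length(groups) >= 2L) "incongruent"
                    else if (length(labels) >= 2L) "subline_consistent"
                    else "consistent"
  events <- data.frame(ht_label = character(), subline = character(),
                       stringsAsFactors = FALSE)
  if (classification == "subline_consistent") {
    # the ancestor-most label is the line's base haplotype; deeper labels
    # are de novo candidates, attributed to the sublines carrying them
    base <- groups[[1]][1]
    derived <- setdiff(labels, base)
    uc <- unique(members[, c("ht_label", "subline")])
    events <- uc[uc$ht_label %in% derived, , drop = FALSE]
    events <- events[order(events$ht_label, events$subline), , drop = FALSE]
    rownames(events) <- NULL
  }
  list(classification = classification,
       distinct_hts = labels,
       disjoint_groups = groups,
       candidate_subline_events = events)
}

#' Classify every foundation line of a panel
#'
#' @param records data.frame with columns `foundation_sire`, `sample`,
#'   `ht_label`, `subline`
#' @return A `congruence_report` data.frame: one row per foundation line
#'   with its classification, distinct labels and disjoint group count;
#'   per-line details in `attr(, "details")`.
#' @export
classify_lines <- function(records) {
  stopifnot(all(c("foundation_sire", "ht_label", "subline") %in% names(records)))
  if (is.null(records$sample)) records$sample <- records$subline
  lines <- unique(records$foundation_sire)
  details <- lapply(lines, function(fs)
    classify_line(records[records$foundation_sire == fs, , drop = FALSE]))
  names(details) <- lines
  out <- data.frame(
    foundation_sire = lines,
    classification = vapply(details, `[[`, "", "classification"),
    n_distinct_hts = vapply(details, function(d) length(d$distinct_hts), 1L),
    n_disjoint_groups = vapply(details, function(d) length(d$disjoint_groups), 1L),
    ht_labels = vapply(details, function(d) paste(d$distinct_hts, collapse = ","), ""),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, details = details, class = c("congruence_report", "data.frame"))
}

#' @export
print.congruence_report <- function(x, ...) {
  cat(sprintf("congruence_report: %d foundation line(s), %d incongruent\n",
              nrow(x), sum(x$classification == "incongruent")))
  print.data.frame(x)
  invisible(x)
}

#' Read a sire-line panel fixture
#'
#' @param path tab-delimited file with columns `foundation_sire`, `subline`,
#'   `count`, `breed_or_registry`, `ht_label`, `remark`
#' @return validated data.frame
#' @export
read_line_records <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("foundation_sire", "subline", "count", "breed_or_registry",
            "ht_label", "remark")
  miss <- setdiff(need, names(df))
  if (length(miss)) .stopf("line records lack column(s): %s", paste(miss, collapse = ", "))
  df$count <- as.integer(df$count)
  if (any(is.na(df$count) | df$count < 1L))
    .stopf("every line record needs count >= 1")
  for (l in unique(df$ht_label)) .validate_label(l)
  df
}

#' The bundled occidental Arabian sire-line panel
#'
#' Machine-encoded summary of 145 genotyped males from 26 Arabian
#' foundation-sire lines (registered Arabians plus Arabian-derived lines
#' surviving in Shagya Arabians, Lipizzaners, Trakehners and other
#' breeds), one row per subline with its haplotype label and remark.
#' Within-row allocations of samples to sublines that the published table
#' leaves ambiguous were fixed so that all row and panel totals are
#' preserved; all summary statistics are invariant to that allocation.
#'
#' @return data.frame of line records (see [read_line_records()]).
#' @export
occidental_lines <- function() {
  read_line_records(system.file("extdata", "occidental_arabian_lines.tsv",
                                package = "patrilineR", mustWork = TRUE))
}

#' Summary statistics for a sire-line panel
#'
#' @param fixture line records (see [read_line_records()])
#' @param haplogroups labels used for the haplogroup rollup; a haplotype is
#'   counted under a haplogroup when the haplogroup label is a name-prefix
#'   ancestor of it.
#' @return list of summary statistics: totals, per-haplogroup sample and
#'   line counts, per-haplotype line counts, subline-HT label count,
#'   private haplotypes, and the congruence classification of every line.
#' @export
summarize_panel <- function(fixture,
                            haplogroups = c("Ao-aA", "Ta", "Ao-aD2")) {
  stopifnot(is.data.frame(fixture), nrow(fixture) >= 1L)
  per_line <- tapply(fixture$count, fixture$foundation_sire, sum)
  hg_member <- function(hg) vapply(fixture$ht_label, function(l)
    is_ancestor_name(hg, l), TRUE)
  hg_samples <- vapply(haplogroups, function(hg) sum(fixture$count[hg_member(hg)]), 1)
  hg_lines <- vapply(haplogroups, function(hg)
    length(unique(fixture$foundation_sire[hg_member(hg)])), 1L)
  in_any <- Reduce(`|`, lapply(haplogroups, hg_member))
  ht_lines <- tapply(fixture$foundation_sire, fixture$ht_label,
                     function(f) length(unique(f)))
  line_of_label <- tapply(fixture$foundation_sire, fixture$ht_label,
                          function(f) unique(f))
  private_hts <- names(ht_lines)[ht_lines == 1L]
  report <- classify_lines(fixture)
  list(total_samples = sum(fixture$count),
       n_lines = length(per_line),
       n_lines_multi = sum(per_line >= 2L),
       n_distinct_hts = length(unique(fixture$ht_label)),
       hg_samples = hg_samples,
       hg_lines = hg_lines,
       hg_total_samples = sum(fixture$count[in_any]),
       ht_lines = ht_lines,
       n_subline_ht_labels = length(unique(fixture$ht_label[fixture$remark == "subline-HT"])),
       private_hts = private_hts,
       congruence = report,
       n_incongruent = sum(report$classification == "incongruent"),
       incongruent_lines = report$foundation_sire[report$classification == "incongruent"])
}
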